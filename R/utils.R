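#' @importFrom stats pt pbinom rnorm rbeta runif fisher.test p.adjust prcomp
#'   hclust cutree as.dist cor ks.test t.test rbinom rlnorm anova lm sd
#'   setNames aggregate
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom methods new validObject is slot show
#' @importFrom utils read.delim write.table head
NULL

## Region categories of the Illumina 450K gene annotation, plus the merged
## promoter view (TSS200 u TSS1500) used for expression integration.
GENE_CATEGORIES <- c("TSS1500", "TSS200", "UTR5", "FirstExon", "Body", "UTR3")
REGION_CATEGORIES <- c(GENE_CATEGORIES, "Intergenic")
ISLAND_RELATIONS <- c("Island", "Shore", "Shelf", "OpenSea")
SAMPLE_GROUPS <- c("ALK_POS", "ALK_NEG", "CONTROL")

#' Round half away from zero to an integer percentage
#'
#' Percentages in summaries are computed as 100 * count / denominator and
#' rounded half-up (0.5 always rounds away from zero), not to even as
#' `round()` does.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
roundHalfUp <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Integer percentage of a count over a denominator
#'
#' @param count,denom non-negative counts; `denom` > 0.
#' @return `roundHalfUp(100 * count / denom)`.
#' @export
percentOf <- function(count, denom) {
  stopifnot(all(denom > 0), all(count >= 0))
  roundHalfUp(100 * count / denom)
}

## Reverse complement for plain character k-mers (A/C/G/T/N only);
## vectorised column-wise for equal-length inputs.
revcompChar <- function(x) {
  if (!length(x)) return(x)
  comp <- chartr("ACGTN", "TGCAN", x)
  k <- nchar(comp)
  if (all(k == k[1]))
    return(do.call(paste0, lapply(k[1]:1, function(i)
      substring(comp, i, i))))
  vapply(comp, function(s)
    paste(rev(strsplit(s, NULL)[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
}

## Canonical form of a k-mer: lexicographic min of itself and its reverse
## complement, so a motif and its opposite strand collapse to one key.
canonicalKmer <- function(x) {
  rc <- revcompChar(x)
  ifelse(x <= rc, x, rc)
}

## Derive a child seed from a run seed; keeps all derived seeds < 2^31.
childSeed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

## Row-wise Welch two-sample t-test on a numeric matrix.
## Zero-variance ties: if both groups have zero variance and equal means the
## probe is an exact tie (t = 0, p = 1); if means differ, variances are
## floored at `var_floor` and the row is flagged.
rowWelch <- function(m, idx_a, idx_b, var_floor = 1e-10) {
  na <- length(idx_a); nb <- length(idx_b)
  stopifnot(na >= 2, nb >= 2)
  xa <- m[, idx_a, drop = FALSE]
  xb <- m[, idx_b, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  tie <- (va + vb) == 0 & ma == mb
  floored <- (va + vb) == 0 & ma != mb
  va[floored] <- var_floor
  vb[floored] <- var_floor
  sa <- va / na; sb <- vb / nb
  se2 <- sa + sb
  se2[tie] <- 1 # avoid 0/0; overwritten below
  df <- se2^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1))
  tstat <- (ma - mb) / sqrt(se2)
  p <- 2 * pt(-abs(tstat), df)
  tstat[tie] <- 0
  p[tie] <- 1
  df[tie] <- na + nb - 2
  list(mean_a = ma, mean_b = mb, t = tstat, df = df, p = p,
       tie = tie, var_floored = floored)
}
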