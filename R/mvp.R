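#' Beta to M-value transform
#'
#' `m = log2((beta + epsilon) / (1 - beta + epsilon))`, the variance-
#' stabilising logit2 transform on which all differential testing runs.
#' `epsilon` guards the boundaries beta = 0 and beta = 1.
#'
#' @param beta numeric vector/matrix of fractions in \[0, 1\].
#' @param epsilon positive offset, default `1e-6`.
#' @return M-values, same shape as `beta`.
#' @examples
#' betaToM(0.8) # ~ 2
#' @export
betaToM <- function(beta, epsilon = 1e-6) {
  if (any(beta < 0 | beta > 1)) stop("beta must lie in [0, 1]")
  if (epsilon <= 0) stop("epsilon must be > 0")
  log2((beta + epsilon) / (1 - beta + epsilon))
}

#' Inverse of [betaToM()]
#'
#' @param m M-values.
#' @inheritParams betaToM
#' @return beta values.
#' @export
mToBeta <- function(m, epsilon = 1e-6) {
  r <- 2^m
  (r * (1 + epsilon) - epsilon) / (1 + r)
}

#' Call methylation variable positions (MVPs) between two groups
#'
#' Per probe: Welch two-sample t-test on M-values, Benjamini-Hochberg
#' adjustment across all tested probes, and the beta-scale group-mean
#' difference `delta_beta = mean(a) - mean(b)`. Probes identical in both
#' groups are exact ties (p = 1); probes with zero within-group variance but
#' differing means get a variance floor and are flagged.
#'
#' @param x [MethylExperiment-class], or a beta matrix (then `groups` is
#'   required).
#' @param group_a,group_b group labels to compare; `delta_beta` and
#'   `direction` are with respect to `group_a`.
#' @param groups named group vector when `x` is a bare matrix.
#' @param epsilon offset for [betaToM()].
#' @return data.frame with columns `probe_id`, `mean_beta_a`, `mean_beta_b`,
#'   `delta_beta`, `m_stat`, `df`, `p`, `p_adj`, `direction`, `var_floored`.
#' @export
callMVPs <- function(x, group_a, group_b, groups = NULL, epsilon = 1e-6) {
  if (is(x, "MethylExperiment")) {
    groups <- sampleGroups(x)
    beta <- betaValues(x)
  } else beta <- x
  if (is.null(groups)) stop("'groups' required for a bare matrix")
  idx_a <- which(groups[colnames(beta)] == group_a)
  idx_b <- which(groups[colnames(beta)] == group_b)
  if (length(idx_a) < 2 || length(idx_b) < 2)
    stop("each group needs at least 2 samples")
  m <- betaToM(beta, epsilon)
  w <- rowWelch(m, idx_a, idx_b)
  mean_a <- rowMeans(beta[, idx_a, drop = FALSE])
  mean_b <- rowMeans(beta[, idx_b, drop = FALSE])
  delta <- mean_a - mean_b
  data.frame(probe_id = rownames(beta),
             mean_beta_a = mean_a, mean_beta_b = mean_b,
             delta_beta = delta, m_stat = w$t, df = w$df, p = w$p,
             p_adj = stats::p.adjust(w$p, method = "BH"),
             direction = ifelse(delta > 0, "hyper", "hypo"),
             var_floored = w$var_floored,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter an MVP table to significant positions
#'
#' Strict thresholds on both scales: `p_adj < p_adj_max` and
#' `|delta_beta| > min_abs_delta`.
#'
#' @param mvp data.frame from [callMVPs()].
#' @param p_adj_max adjusted-p cutoff, default 0.01.
#' @param min_abs_delta beta-difference cutoff, default 0.2.
#' @return the significant subset, unchanged columns.
#' @export
filterMVPs <- function(mvp, p_adj_max = 0.01, min_abs_delta = 0.2) {
  stopifnot(p_adj_max > 0, p_adj_max < 1,
            min_abs_delta >= 0, min_abs_delta < 1)
  mvp[mvp$p_adj < p_adj_max & abs(mvp$delta_beta) > min_abs_delta, ,
      drop = FALSE]
}

#' Venn counts over three MVP probe-id sets
#'
#' @param set_ab,set_ac,set_bc character vectors of probe ids from the three
#'   pairwise group comparisons.
#' @return data.frame of the seven disjoint Venn regions plus the three set
#'   totals.
#' @export
vennCounts <- function(set_ab, set_ac, set_bc) {
  s1 <- unique(set_ab); s2 <- unique(set_ac); s3 <- unique(set_bc)
  ids <- unique(c(s1, s2, s3))
  in1 <- ids %in% s1; in2 <- ids %in% s2; in3 <- ids %in% s3
  data.frame(
    region = c("ab_only", "ac_only", "bc_only", "ab_ac", "ab_bc", "ac_bc",
               "ab_ac_bc", "ab_total", "ac_total", "bc_total"),
    count = c(sum(in1 & !in2 & !in3), sum(!in1 & in2 & !in3),
              sum(!in1 & !in2 & in3), sum(in1 & in2 & !in3),
              sum(in1 & !in2 & in3), sum(!in1 & in2 & in3),
              sum(in1 & in2 & in3), length(s1), length(s2), length(s3)),
    stringsAsFactors = FALSE)
}

#' Genomic distribution of an MVP set
#'
#' Tabulates significant probes over gene-region categories and CpG-island
#' relations, hyper and hypo separately. A probe multi-mapped to k
#' categories is counted once in each of those k categories.
#'
#' @param mvp_set filtered MVP data.frame (needs `probe_id`, `direction`).
#' @param manifest manifest data.frame.
#' @return list of two data.frames, `region` (columns `category`, `hyper`,
#'   `hypo`) and `island` (columns `island_relation`, `hyper`, `hypo`).
#' @export
genomicDistribution <- function(mvp_set, manifest) {
  dir <- stats::setNames(mvp_set$direction, mvp_set$probe_id)
  pr <- probeRegions(manifest)
  pr <- unique(pr[pr$probe_id %in% mvp_set$probe_id,
                  c("probe_id", "region_category")])
  tabulateDir <- function(keys, universe) {
    out <- data.frame(category = universe, hyper = 0L, hypo = 0L,
                      stringsAsFactors = FALSE)
    tab <- table(factor(keys$cat, levels = universe), keys$dir)
    if ("hyper" %in% colnames(tab)) out$hyper <- as.integer(tab[, "hyper"])
    if ("hypo" %in% colnames(tab)) out$hypo <- as.integer(tab[, "hypo"])
    out
  }
  region <- tabulateDir(
    data.frame(cat = pr$region_category, dir = dir[pr$probe_id]),
    REGION_CATEGORIES)
  isl <- manifest[manifest$probe_id %in% mvp_set$probe_id,
                  c("probe_id", "island_relation")]
  island <- tabulateDir(
    data.frame(cat = isl$island_relation, dir = dir[isl$probe_id]),
    ISLAND_RELATIONS)
  colnames(island)[1] <- "island_relation"
  list(region = region, island = island)
}
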