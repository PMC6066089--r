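#' Linear-scale fold change of group means
#'
#' @param expr_a_mean,expr_b_mean positive group means on the linear scale.
#' @return `expr_a_mean / expr_b_mean`.
#' @export
foldChange <- function(expr_a_mean, expr_b_mean) {
  if (any(expr_a_mean <= 0) || any(expr_b_mean <= 0))
    stop("expression means must be positive")
  expr_a_mean / expr_b_mean
}

#' Classify promoter-methylation / expression concordance
#'
#' Significant TSS DMRs are crossed with gene expression: a gene counts as
#' upregulated when the tumor/control ratio of linear-scale group means
#' exceeds `fold` (strict), downregulated below `1/fold` (strict). Four
#' classes result: hyper&down and hypo&up (concordant), hyper&up and
#' hypo&down (discordant). Denominators are the hyper- and hypomethylated
#' TSS counts; percentages are integer-rounded half-up.
#'
#' DMRs with an empty gene symbol are dropped from numerator and
#' denominator (their count is reported); genes with a symbol but absent
#' from the expression table stay in the denominator and count as
#' non-concordant.
#'
#' @param dmr significant DMR data.frame, restricted internally to
#'   `tss_categories`.
#' @param expr genes x samples expression matrix (linear scale, positive).
#' @param groups named sample-to-group vector for `expr` columns.
#' @param group_a tumor group; `group_b` the control group.
#' @param group_b control group label.
#' @param fold fold-change threshold, default 1.5.
#' @param tss_categories DMR categories treated as promoters (default the
#'   merged `"TSS"` view).
#' @return list with `summary` (data.frame: class, count, denominator,
#'   percent), `per_gene` (gene-level table), and `n_unmapped` (DMRs
#'   dropped for lack of a gene symbol).
#' @export
classifyConcordance <- function(dmr, expr, groups, group_a, group_b,
                                fold = 1.5, tss_categories = "TSS") {
  stopifnot(fold > 1)
  if (anyDuplicated(rownames(expr)))
    stop("duplicate gene rows in expression table")
  tss <- dmr[dmr$category %in% tss_categories, , drop = FALSE]
  n_unmapped <- sum(tss$gene == "")
  tss <- tss[tss$gene != "", , drop = FALSE]
  # one record per gene: keep the strongest (min p) promoter DMR
  tss <- tss[order(tss$p), ]
  tss <- tss[!duplicated(tss$gene), , drop = FALSE]

  idx_a <- which(groups[colnames(expr)] == group_a)
  idx_b <- which(groups[colnames(expr)] == group_b)
  if (!length(idx_a) || !length(idx_b))
    stop("expression table has no samples for the requested groups")

  present <- tss$gene %in% rownames(expr)
  ratio <- rep(NA_real_, nrow(tss))
  if (any(present)) {
    ea <- rowMeans(expr[tss$gene[present], idx_a, drop = FALSE])
    eb <- rowMeans(expr[tss$gene[present], idx_b, drop = FALSE])
    ratio[present] <- foldChange(ea, eb)
  }
  up <- !is.na(ratio) & ratio > fold
  down <- !is.na(ratio) & ratio < 1 / fold
  hyper <- tss$direction == "hyper"

  per_gene <- data.frame(gene = tss$gene, direction = tss$direction,
                         delta_beta = tss$delta_beta, ratio = ratio,
                         class = ifelse(hyper & down, "hyper_down",
                                 ifelse(!hyper & up, "hypo_up",
                                 ifelse(hyper & up, "hyper_up",
                                 ifelse(!hyper & down, "hypo_down",
                                        "none")))),
                         row.names = NULL, stringsAsFactors = FALSE)
  n_hyper <- sum(hyper); n_hypo <- sum(!hyper)
  cls <- data.frame(
    class = c("hyper_down", "hypo_up", "hyper_up", "hypo_down"),
    count = c(sum(hyper & down), sum(!hyper & up),
              sum(hyper & up), sum(!hyper & down)),
    denominator = c(n_hyper, n_hypo, n_hyper, n_hypo),
    stringsAsFactors = FALSE)
  cls$percent <- ifelse(cls$denominator > 0,
                        percentOf(cls$count, pmax(cls$denominator, 1)), 0)
  list(summary = cls, per_gene = per_gene, n_unmapped = n_unmapped)
}
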