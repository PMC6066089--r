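#' Per-sample z-score normalisation
#'
#' Centers each sample (column) to mean 0 and scales to population variance
#' 1, the global normalisation used before PCA and cross-cohort clustering
#' to absorb chip-intensity differences.
#'
#' @param beta numeric matrix, probes x samples.
#' @return matrix of the same shape; every column has mean 0 and population
#'   variance 1.
#' @export
zscoreSamples <- function(beta) {
  mu <- colMeans(beta)
  centered <- sweep(beta, 2, mu)
  sd_pop <- sqrt(colMeans(centered^2))
  if (any(sd_pop == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(beta)[sd_pop == 0], collapse = ", "))
  sweep(centered, 2, sd_pop, "/")
}

#' Select top-ranked probes from a statistics table
#'
#' Probes are ranked by ascending p; ties break by larger `|delta_beta|`,
#' then lexicographic `probe_id`, so the selection is deterministic. Either
#' a fixed fraction (count = `ceiling(fraction * n)`) or all probes with
#' `p < p_max` are returned.
#'
#' @param stat_table data.frame with `probe_id`, `p`, `delta_beta`.
#' @param fraction top fraction to keep (default 0.01).
#' @param p_max alternative absolute p cutoff; overrides `fraction` when
#'   given.
#' @return character vector of selected probe ids, in rank order.
#' @export
selectTopProbes <- function(stat_table, fraction = 0.01, p_max = NULL) {
  ord <- order(stat_table$p, -abs(stat_table$delta_beta),
               stat_table$probe_id)
  ranked <- stat_table[ord, , drop = FALSE]
  if (!is.null(p_max)) return(ranked$probe_id[ranked$p < p_max])
  stopifnot(fraction > 0, fraction <= 1)
  ranked$probe_id[seq_len(ceiling(fraction * nrow(ranked)))]
}

#' Hierarchical clustering of samples
#'
#' Default distance is 1 - Pearson correlation between sample columns with
#' average linkage, the standard recipe for methylation heatmaps. Euclidean
#' distance is available for z-scored data.
#'
#' @param mat numeric matrix, probes x samples (raw beta for
#'   percent-methylation views, z-scored for normalised views).
#' @param metric `"correlation"` (default) or `"euclidean"`.
#' @param linkage linkage method for [stats::hclust()], default
#'   `"average"`.
#' @param k optional number of flat clusters to cut.
#' @return list with `hclust` (the tree), `order` (leaf order),
#'   `height`, and `clusters` (named labels at `k`, or NULL).
#' @export
hierCluster <- function(mat, metric = c("correlation", "euclidean"),
                        linkage = "average", k = NULL) {
  metric <- match.arg(metric)
  if (metric == "correlation") {
    if (any(apply(mat, 2, stats::sd) == 0))
      stop("correlation metric undefined for constant sample(s)")
    d <- stats::as.dist(1 - stats::cor(mat))
  } else {
    d <- stats::dist(t(mat))
  }
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc, order = colnames(mat)[hc$order], height = hc$height,
       clusters = if (!is.null(k)) stats::cutree(hc, k = k) else NULL)
}

#' Export a sample dendrogram as a Newick string
#'
#' @param cl result of [hierCluster()] or an hclust object.
#' @return single Newick string.
#' @export
dendrogramNewick <- function(cl) {
  hc <- if (is.list(cl) && !is.null(cl$hclust)) cl$hclust else cl
  ape::write.tree(ape::as.phylo(hc))
}

#' Principal-component analysis of samples
#'
#' PCA of the sample-space covariance (samples as observations over probe
#' features). The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making coordinates reproducible
#' across runs and sample orderings.
#'
#' @param mat numeric matrix, probes x samples (normally the output of
#'   [zscoreSamples()]).
#' @param n_components number of components to keep (default all).
#' @return list with `coordinates` (samples x components),
#'   `explained_variance` (fraction per component, non-increasing),
#'   `rotation`, and `center`.
#' @export
pcaEmbed <- function(mat, n_components = NULL) {
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  rot <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  if (!is.null(n_components)) {
    n_components <- min(n_components, ncol(scores))
    scores <- scores[, seq_len(n_components), drop = FALSE]
    rot <- rot[, seq_len(n_components), drop = FALSE]
    ev <- ev[seq_len(n_components)]
  }
  list(coordinates = scores, explained_variance = ev, rotation = rot,
       center = pc$center)
}

#' Assign tumor samples to the nearest reference developmental stage
#'
#' For each tumor sample, the reference stage whose centroid (mean profile
#' over the selected probes) has minimal Euclidean distance. Ties break
#' deterministically to the first stage in input order and are flagged.
#'
#' @param tumor_mat probes x tumor-samples matrix (same normalisation as
#'   the references).
#' @param reference_mat probes x reference-samples matrix.
#' @param reference_stages named vector mapping reference sample id to stage
#'   name (a `REFERENCE_STAGE:` prefix is stripped if present).
#' @return list with `assignment` (data.frame: `sample_id`, `stage`,
#'   `distance`, `tie`) and `distances` (tumor x stage matrix).
#' @export
assignNearestStage <- function(tumor_mat, reference_mat, reference_stages) {
  stages_clean <- sub("^REFERENCE_STAGE:", "",
                      reference_stages[colnames(reference_mat)])
  stage_levels <- unique(stages_clean)
  centroids <- vapply(stage_levels, function(s)
    rowMeans(reference_mat[, stages_clean == s, drop = FALSE]),
    numeric(nrow(reference_mat)))
  d <- vapply(seq_along(stage_levels), function(j)
    sqrt(colSums((tumor_mat - centroids[, j])^2)),
    numeric(ncol(tumor_mat)))
  d <- matrix(d, nrow = ncol(tumor_mat),
              dimnames = list(colnames(tumor_mat), stage_levels))
  best <- apply(d, 1, which.min)   # first minimum in input order
  tie <- apply(d, 1, function(r) sum(r == min(r)) > 1)
  list(assignment = data.frame(sample_id = rownames(d),
                               stage = stage_levels[best],
                               distance = d[cbind(seq_len(nrow(d)), best)],
                               tie = tie, row.names = NULL,
                               stringsAsFactors = FALSE),
       distances = d)
}
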