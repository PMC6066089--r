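#' Aggregate probe beta values into annotated regions
#'
#' Per region and sample, the arithmetic mean of member-probe beta values.
#' Regions are formed from the manifest annotation:
#' \itemize{
#'   \item gene-linked categories (TSS1500, TSS200, UTR5, FirstExon, Body,
#'     UTR3): one region per gene x category, id `"<gene>|<category>"`;
#'   \item a merged promoter view `"<gene>|TSS"` (category `TSS`) pooling
#'     TSS200 and TSS1500 probes of a gene — the unit used for
#'     expression integration;
#'   \item CpG-island categories (Island, Shore, Shelf): runs of
#'     consecutive same-relation probes on a chromosome, split at gaps
#'     larger than `island_gap` bp, id `"<chrom>:<start>-<end>|<relation>"`.
#' }
#' OpenSea probes outside gene annotation contribute to no region.
#'
#' @param x [MethylExperiment-class], or a beta matrix with `manifest` and
#'   `groups` supplied.
#' @param manifest,groups used when `x` is a bare matrix.
#' @param tss_merged include the merged TSS view (default TRUE).
#' @param island_gap maximum intra-region probe gap in bp for island-type
#'   regions (default 2000).
#' @return [SummarizedExperiment::SummarizedExperiment] with assay `beta`
#'   (regions x samples) and rowData `region_id`, `category`, `gene`,
#'   `chrom`, `start`, `end`, `n_probes`.
#' @export
aggregateRegions <- function(x, manifest = NULL, groups = NULL,
                             tss_merged = TRUE, island_gap = 2000L) {
  if (is(x, "MethylExperiment")) {
    beta <- betaValues(x)
    manifest <- probeAnnotation(x)
    groups <- sampleGroups(x)
  } else beta <- x
  if (is.null(manifest)) stop("'manifest' required for a bare matrix")

  pr <- probeRegions(manifest)
  pr <- pr[pr$probe_id %in% rownames(beta), , drop = FALSE]

  gene_pr <- pr[pr$gene != "" & pr$region_category %in% GENE_CATEGORIES, ]
  memb <- data.frame(
    probe_id = gene_pr$probe_id,
    region_id = paste(gene_pr$gene, gene_pr$region_category, sep = "|"),
    category = gene_pr$region_category, gene = gene_pr$gene,
    chrom = gene_pr$chrom, pos = gene_pr$pos, stringsAsFactors = FALSE)

  if (tss_merged) {
    tss <- gene_pr[gene_pr$region_category %in% c("TSS200", "TSS1500"), ]
    if (nrow(tss))
      memb <- rbind(memb, data.frame(
        probe_id = tss$probe_id,
        region_id = paste(tss$gene, "TSS", sep = "|"),
        category = "TSS", gene = tss$gene, chrom = tss$chrom,
        pos = tss$pos, stringsAsFactors = FALSE))
  }

  isl <- manifest[manifest$probe_id %in% rownames(beta) &
                    manifest$island_relation %in% c("Island", "Shore",
                                                    "Shelf"), ]
  if (nrow(isl)) {
    isl <- isl[order(isl$chrom, isl$pos), ]
    new_run <- c(TRUE, isl$chrom[-1] != isl$chrom[-nrow(isl)] |
                   isl$island_relation[-1] != isl$island_relation[-nrow(isl)] |
                   diff(isl$pos) > island_gap)
    run <- cumsum(new_run)
    run_start <- stats::ave(isl$pos, run, FUN = min)
    run_end <- stats::ave(isl$pos, run, FUN = max)
    memb <- rbind(memb, data.frame(
      probe_id = isl$probe_id,
      region_id = sprintf("%s:%d-%d|%s", isl$chrom, run_start, run_end,
                          isl$island_relation),
      category = isl$island_relation, gene = "", chrom = isl$chrom,
      pos = isl$pos, stringsAsFactors = FALSE))
  }
  memb <- unique(memb)
  if (!nrow(memb)) stop("no aggregatable regions in manifest")

  bsub <- beta[memb$probe_id, , drop = FALSE]
  sums <- rowsum(bsub, memb$region_id)
  n <- as.vector(rowsum(rep(1, nrow(memb)), memb$region_id))
  rbeta_mat <- sums / n

  first <- match(rownames(rbeta_mat), memb$region_id)
  info <- data.frame(
    region_id = rownames(rbeta_mat),
    category = memb$category[first], gene = memb$gene[first],
    chrom = memb$chrom[first],
    start = vapply(split(memb$pos, memb$region_id), min, numeric(1)),
    end = vapply(split(memb$pos, memb$region_id), max, numeric(1)),
    n_probes = as.integer(n), stringsAsFactors = FALSE)

  SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = rbeta_mat),
    rowData = S4Vectors::DataFrame(info, row.names = info$region_id),
    colData = S4Vectors::DataFrame(
      group = if (!is.null(groups)) unname(groups[colnames(rbeta_mat)])
              else rep(NA_character_, ncol(rbeta_mat)),
      row.names = colnames(rbeta_mat)))
}

#' Call differentially methylated regions (DMRs)
#'
#' Welch t-test on M-transformed region means (same transform as probe-level
#' calling), Benjamini-Hochberg adjustment within each category family, then
#' the region filter: `p_adj < p_adj_max` (strict) and
#' `|delta_beta| >= min_abs_delta` (inclusive).
#'
#' @param regions SummarizedExperiment from [aggregateRegions()].
#' @param group_a,group_b group labels; `groups` overrides the colData
#'   mapping if given.
#' @param p_adj_max adjusted-p cutoff, default 0.05.
#' @param min_abs_delta beta-difference cutoff, default 0.15.
#' @param groups optional named group vector.
#' @param epsilon offset for [betaToM()].
#' @param filter return only significant regions (default TRUE).
#' @return data.frame with `region_id`, `category`, `gene`, `n_probes`,
#'   `mean_beta_a`, `mean_beta_b`, `delta_beta`, `m_stat`, `p`, `p_adj`,
#'   `direction`.
#' @export
callDMRs <- function(regions, group_a, group_b, p_adj_max = 0.05,
                     min_abs_delta = 0.15, groups = NULL, epsilon = 1e-6,
                     filter = TRUE) {
  if (is.null(groups))
    groups <- stats::setNames(
      as.character(SummarizedExperiment::colData(regions)$group),
      colnames(regions))
  beta <- SummarizedExperiment::assay(regions, "beta")
  info <- as.data.frame(SummarizedExperiment::rowData(regions))
  idx_a <- which(groups[colnames(beta)] == group_a)
  idx_b <- which(groups[colnames(beta)] == group_b)
  if (length(idx_a) < 2 || length(idx_b) < 2)
    stop("each group needs at least 2 samples")
  m <- betaToM(beta, epsilon)
  w <- rowWelch(m, idx_a, idx_b)
  mean_a <- rowMeans(beta[, idx_a, drop = FALSE])
  mean_b <- rowMeans(beta[, idx_b, drop = FALSE])
  delta <- mean_a - mean_b
  out <- data.frame(region_id = info$region_id, category = info$category,
                    gene = info$gene, n_probes = info$n_probes,
                    mean_beta_a = mean_a, mean_beta_b = mean_b,
                    delta_beta = delta, m_stat = w$t, p = w$p,
                    p_adj = NA_real_,
                    direction = ifelse(delta > 0, "hyper", "hypo"),
                    row.names = NULL, stringsAsFactors = FALSE)
  # BH within each category: regions of one category form one family
  for (cat in unique(out$category)) {
    i <- out$category == cat
    out$p_adj[i] <- stats::p.adjust(out$p[i], method = "BH")
  }
  if (filter) filterDMRs(out, p_adj_max, min_abs_delta) else out
}

#' Region-level significance filter
#'
#' Strict on adjusted p, inclusive on the beta difference.
#'
#' @param dmr data.frame from [callDMRs()].
#' @inheritParams callDMRs
#' @return the significant subset.
#' @export
filterDMRs <- function(dmr, p_adj_max = 0.05, min_abs_delta = 0.15) {
  dmr[dmr$p_adj < p_adj_max & abs(dmr$delta_beta) >= min_abs_delta, ,
      drop = FALSE]
}

#' Count DMRs per category and direction
#'
#' @param dmr filtered DMR data.frame.
#' @param categories category universe for the rows (defaults to those
#'   present).
#' @return data.frame `category`, `hyper`, `hypo`.
#' @export
countByCategory <- function(dmr, categories = NULL) {
  if (is.null(categories))
    categories <- sort(unique(dmr$category))
  out <- data.frame(category = categories, hyper = 0L, hypo = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(dmr)) {
    tab <- table(factor(dmr$category, levels = categories), dmr$direction)
    if ("hyper" %in% colnames(tab)) out$hyper <- as.integer(tab[, "hyper"])
    if ("hypo" %in% colnames(tab)) out$hypo <- as.integer(tab[, "hypo"])
  }
  out
}
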