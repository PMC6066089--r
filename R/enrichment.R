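#' Overlap enrichment of an MVP set against a genomic feature track
#'
#' Computes the percentage of set probes and of background probes lying
#' inside the track (half-open point-in-interval rule) and a Fisher exact
#' test on the 2x2 table of in/out x set/rest-of-background. The reported
#' `pct_in_background` is over the full background universe (all manifest
#' probes by default, mirroring an array-annotation control set); the test
#' contrasts the set with the background probes not in the set, so the two
#' groups are disjoint.
#'
#' @param mvp_set filtered MVP data.frame (needs `probe_id`), or a character
#'   vector of probe ids.
#' @param track [GenomicRanges::GRanges] feature track.
#' @param manifest manifest data.frame supplying probe coordinates.
#' @param background character vector of background probe ids (default: all
#'   manifest probes).
#' @param or_cap cap for degenerate odds ratios (default 1e6; capped values
#'   are flagged).
#' @return one-row data.frame: `n_set`, `n_background`, `pct_in_set`,
#'   `pct_in_background`, `odds_ratio`, `or_capped`, `fisher_p`.
#' @export
overlapEnrichment <- function(mvp_set, track, manifest,
                              background = manifest$probe_id,
                              or_cap = 1e6) {
  set_ids <- if (is.character(mvp_set)) mvp_set else mvp_set$probe_id
  set_ids <- unique(set_ids)
  if (!length(set_ids)) stop("empty MVP set")
  if (!length(track)) stop("empty track")
  background <- unique(background)
  gr <- probeGRanges(manifest)
  inside <- names(gr)[IRanges::overlapsAny(gr, track)]

  set_in <- sum(set_ids %in% inside)
  set_out <- length(set_ids) - set_in
  rest <- setdiff(background, set_ids)
  rest_in <- sum(rest %in% inside)
  rest_out <- length(rest) - rest_in
  bg_in <- sum(background %in% inside)

  tab <- matrix(c(set_in, set_out, rest_in, rest_out), nrow = 2)
  fp <- stats::fisher.test(tab)$p.value
  or <- (set_in * rest_out) / (set_out * rest_in)
  capped <- !is.finite(or) || or > or_cap
  if (capped) or <- or_cap
  data.frame(n_set = length(set_ids), n_background = length(background),
             pct_in_set = 100 * set_in / length(set_ids),
             pct_in_background = 100 * bg_in / length(background),
             odds_ratio = or, or_capped = capped, fisher_p = fp,
             stringsAsFactors = FALSE)
}

#' Detect epigenetic switching
#'
#' Epigenetic switching replaces Polycomb (H3K27me3) repression present in
#' stem cells by DNA hypermethylation in tumor cells at the same loci. A
#' probe is switched when it is (a) in the tumor-hypermethylated set and
#' (b) inside the reference Polycomb occupancy track.
#'
#' @param hyper_set filtered hypermethylated MVP data.frame or probe-id
#'   vector.
#' @param polycomb_track GRanges of Polycomb-occupied intervals.
#' @param manifest manifest data.frame.
#' @return list with `switched` (probe ids), `fraction` (switched /
#'   hyper-set size) and `per_gene` (data.frame `gene`, `n_switched`,
#'   HOX-cluster-style rollup over genes with at least one switched probe).
#' @export
detectSwitching <- function(hyper_set, polycomb_track, manifest) {
  ids <- if (is.character(hyper_set)) hyper_set else hyper_set$probe_id
  ids <- unique(ids)
  if (!length(ids)) stop("empty hypermethylated set")
  gr <- probeGRanges(manifest[manifest$probe_id %in% ids, , drop = FALSE])
  switched <- names(gr)[IRanges::overlapsAny(gr, polycomb_track)]
  pr <- probeRegions(manifest)
  pg <- unique(pr[pr$probe_id %in% switched & pr$gene != "",
                  c("probe_id", "gene")])
  per_gene <- if (nrow(pg)) {
    tab <- sort(table(pg$gene), decreasing = TRUE)
    data.frame(gene = names(tab), n_switched = as.integer(tab),
               row.names = NULL, stringsAsFactors = FALSE)
  } else data.frame(gene = character(0), n_switched = integer(0))
  list(switched = switched, fraction = length(switched) / length(ids),
       per_gene = per_gene)
}

#' ChIP-qPCR fold enrichment over a negative control region
#'
#' `fold = (signal/normaliser at target) / (signal/normaliser at control
#' region)`, where the normaliser is total H3 or input chromatin. With
#' quantities derived from Ct at 100% efficiency this is algebraically
#' `2^(ddCt)`.
#'
#' @param target_signal,target_norm ChIP and normaliser quantities at the
#'   target locus.
#' @param control_signal,control_norm same at the negative control region.
#' @return fold enrichment (numeric).
#' @export
chipFoldEnrichment <- function(target_signal, target_norm,
                               control_signal, control_norm) {
  q <- c(target_signal, target_norm, control_signal, control_norm)
  if (any(q <= 0)) stop("quantities must be > 0")
  (target_signal / target_norm) / (control_signal / control_norm)
}
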