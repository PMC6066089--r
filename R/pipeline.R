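#' Configuration for an end-to-end pipeline run
#'
#' Collects all stage thresholds (probe filter adj p < 0.01 and |delta
#' beta| > 0.2; region filter adj p < 0.05 and |delta beta| >= 0.15;
#' expression fold 1.5; k-mer size 8; 100-bp windows), the run seed and
#' stage toggles.
#'
#' @param outdir output directory (created if missing).
#' @param seed run seed; all randomness derives from it.
#' @param n_probes cohort size for the simulated input.
#' @param mvp_p_adj,mvp_min_delta probe-level filter thresholds.
#' @param dmr_p_adj,dmr_min_delta region-level filter thresholds.
#' @param fold expression fold-change threshold.
#' @param kmer_k k-mer size for motif scanning.
#' @param window_width motif window width in bp.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "mvp", "dmr", "cluster", "integrate", "enrich",
#'   "motif")`.
#' @return list of settings (class `pipeline_config`).
#' @export
pipelineConfig <- function(outdir = tempfile("alclmeth_run_"), seed = 7L,
                           n_probes = 4000L,
                           mvp_p_adj = 0.01, mvp_min_delta = 0.2,
                           dmr_p_adj = 0.05, dmr_min_delta = 0.15,
                           fold = 1.5, kmer_k = 8L, window_width = 100L,
                           stages = c("simulate", "mvp", "dmr", "cluster",
                                      "integrate", "enrich", "motif")) {
  stopifnot(mvp_p_adj > 0, mvp_p_adj < 1, dmr_p_adj > 0, dmr_p_adj < 1,
            mvp_min_delta >= 0, mvp_min_delta < 1,
            dmr_min_delta >= 0, dmr_min_delta < 1, fold > 1,
            kmer_k >= 4, window_width >= kmer_k)
  known <- c("simulate", "mvp", "dmr", "cluster", "integrate", "enrich",
             "motif")
  stopifnot(all(stages %in% known))
  structure(as.list(environment())[setdiff(ls(), "known")],
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes the enabled stages in dependency order (simulate -> MVP -> DMR
#' -> clustering/PCA -> expression integration -> feature enrichment and
#' switching -> motif scan), writes per-stage TSV artifacts plus a
#' machine-readable `report.json` under `cfg$outdir`, and returns the
#' report. Byte-identical outputs for a fixed seed.
#'
#' @param cfg a [pipelineConfig()].
#' @return the report, a named list, invisibly written as
#'   `<outdir>/report.json`.
#' @export
runPipeline <- function(cfg = pipelineConfig()) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  on <- function(s) s %in% cfg$stages
  report <- list(seed = cfg$seed,
                 thresholds = cfg[c("mvp_p_adj", "mvp_min_delta",
                                    "dmr_p_adj", "dmr_min_delta", "fold",
                                    "kmer_k", "window_width")])
  if (!on("simulate")) {
    writeReport(report, cfg$outdir)
    return(invisible(report))
  }

  ccfg <- cohortConfig(n_probes = cfg$n_probes, seed = cfg$seed)
  cohort <- generateCohort(ccfg)
  me <- cohort$experiment
  truth <- cohort$truth
  writeManifest(cohort$manifest, file.path(cfg$outdir, "manifest.tsv"))
  writeBetaMatrix(betaValues(me), file.path(cfg$outdir, "beta.tsv"))
  writeSampleSheet(sampleGroups(me), file.path(cfg$outdir, "samples.tsv"))
  report$simulate <- list(n_probes = nrow(me), n_samples = ncol(me),
                          n_truth_mvp = nrow(mvpTruth(truth)),
                          n_truth_dmr = nrow(dmrTruth(truth)))

  comparisons <- list(pos_ctrl = c("ALK_POS", "CONTROL"),
                      neg_ctrl = c("ALK_NEG", "CONTROL"),
                      pos_neg = c("ALK_POS", "ALK_NEG"))
  mvp_sets <- list()
  if (on("mvp")) {
    mvp_tabs <- lapply(comparisons, function(gg)
      callMVPs(me, gg[1], gg[2]))
    mvp_sets <- lapply(mvp_tabs, filterMVPs, p_adj_max = cfg$mvp_p_adj,
                       min_abs_delta = cfg$mvp_min_delta)
    for (nm in names(mvp_sets))
      writeTable(mvp_sets[[nm]],
                 file.path(cfg$outdir, sprintf("mvp_%s.tsv", nm)))
    venn <- vennCounts(mvp_sets$pos_ctrl$probe_id,
                       mvp_sets$neg_ctrl$probe_id,
                       mvp_sets$pos_neg$probe_id)
    dist <- genomicDistribution(mvp_sets$pos_ctrl, cohort$manifest)
    report$mvp <- list(
      n_significant = lapply(mvp_sets, nrow),
      venn = stats::setNames(as.list(venn$count), venn$region),
      region_distribution = dist$region, island_distribution = dist$island)
  }

  dmr_sets <- list()
  if (on("dmr")) {
    regions <- aggregateRegions(me)
    dmr_sets <- lapply(comparisons[1:2], function(gg)
      callDMRs(regions, gg[1], gg[2], p_adj_max = cfg$dmr_p_adj,
               min_abs_delta = cfg$dmr_min_delta))
    for (nm in names(dmr_sets))
      writeTable(dmr_sets[[nm]],
                 file.path(cfg$outdir, sprintf("dmr_%s.tsv", nm)))
    report$dmr <- lapply(dmr_sets, function(d) {
      cc <- countByCategory(d)
      list(n_significant = nrow(d),
           by_category = stats::setNames(
             lapply(seq_len(nrow(cc)), function(i)
               list(hyper = cc$hyper[i], hypo = cc$hypo[i])),
             cc$category))
    })
  }

  if (on("cluster") && on("mvp")) {
    top <- selectTopProbes(callMVPs(me, "ALK_POS", "CONTROL"),
                           fraction = 0.01)
    z <- zscoreSamples(betaValues(me)[top, , drop = FALSE])
    cl <- hierCluster(betaValues(me)[top, , drop = FALSE], k = 3)
    emb <- pcaEmbed(z, n_components = 3)
    writeTable(data.frame(sample_id = rownames(emb$coordinates),
                          round(emb$coordinates, 6)),
               file.path(cfg$outdir, "pca.tsv"))
    writeLines(dendrogramNewick(cl), file.path(cfg$outdir, "dendrogram.nwk"))
    report$cluster <- list(
      n_top_probes = length(top),
      explained_variance = round(emb$explained_variance, 6),
      clusters = as.list(cl$clusters))
  }

  if (on("integrate") && on("dmr")) {
    ge <- generateExpression(truth, cohort$manifest, sampleGroups(me), ccfg)
    truth <- ge$truth
    writeExpressionTable(ge$expr, file.path(cfg$outdir, "expression.tsv"))
    conc <- lapply(names(dmr_sets), function(nm) {
      gg <- comparisons[[nm]]
      classifyConcordance(dmr_sets[[nm]], ge$expr, sampleGroups(me),
                          gg[1], gg[2], fold = cfg$fold)
    })
    names(conc) <- names(dmr_sets)
    report$integrate <- lapply(conc, function(x) {
      s <- x$summary
      stats::setNames(lapply(seq_len(nrow(s)), function(i)
        list(count = s$count[i], denominator = s$denominator[i],
             percent = s$percent[i])), s$class)
    })
  }

  if (on("enrich") && on("mvp")) {
    track <- generateTracks(truth, cohort$manifest, cfg = ccfg)
    writeTrack(track, file.path(cfg$outdir, "polycomb.bed"))
    hyper <- mvp_sets$pos_ctrl[mvp_sets$pos_ctrl$direction == "hyper", ]
    enr <- overlapEnrichment(hyper, track, cohort$manifest)
    sw <- detectSwitching(hyper, track, cohort$manifest)
    report$enrich <- list(
      pct_in_set = enr$pct_in_set,
      pct_in_background = enr$pct_in_background,
      odds_ratio = enr$odds_ratio, fisher_p = enr$fisher_p,
      n_switched = length(sw$switched),
      switched_fraction = sw$fraction)
  }

  if (on("motif")) {
    seqs <- generateSequences(truth, width = cfg$window_width, cfg = ccfg)
    truth <- seqs$truth
    Biostrings::writeXStringSet(seqs$windows,
                                file.path(cfg$outdir, "windows.fa"))
    hits <- kmerEnrichment(seqs$windows, k = cfg$kmer_k,
                           seed = childSeed(cfg$seed, 7L))
    writeTable(hits, file.path(cfg$outdir, "motifs.tsv"))
    report$motif <- list(top_kmer = hits$kmer[1],
                         top_e_value = hits$e_value[1],
                         top_ap1_similarity = hits$ap1_similarity[1])
  }

  writeReport(report, cfg$outdir)
  invisible(report)
}

writeTable <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.6g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

writeReport <- function(report, outdir) {
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
}
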