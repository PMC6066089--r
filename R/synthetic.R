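#' Configuration for the synthetic ALCL-like cohort generator
#'
#' Defaults encode the study design the analysis assumes: two tumor groups
#' and one control group of 5 samples each, a bimodal (unmethylated /
#' methylated) beta baseline, spiked effects of beta difference 0.3 applied
#' to whole probe blocks, a 13% methylation-expression concordance rate and
#' a planted AP1-like motif.
#'
#' @param n_probes number of probes.
#' @param n_per_group samples per group (>= 2), default 5.
#' @param fraction_hyper,fraction_hypo target fractions of probes carrying
#'   hyper-/hypomethylation spikes (whole blocks are spiked, so realised
#'   counts can exceed the target by up to one block).
#' @param delta_beta spiked beta-scale effect size, default 0.3.
#' @param baseline_low_mean,baseline_high_mean means of the unmethylated
#'   and methylated baseline Beta components (0.1 / 0.85).
#' @param baseline_precision Beta precision of the baseline components.
#' @param noise_precision Beta precision of per-sample noise around the
#'   probe-group mean (larger = tighter).
#' @param shared_fraction probability a spiked block affects both tumor
#'   groups; otherwise one tumor group is picked at random.
#' @param concordance_rate probability a spiked promoter gene gets
#'   anti-correlated expression, default 0.13.
#' @param expr_fold expression fold planted for concordant genes (> 1.5).
#' @param expr_noise_sd lognormal sd of per-sample expression noise.
#' @param motif_plant_rate fraction of hypomethylated windows carrying the
#'   planted motif.
#' @param region_size_min,region_size_max probe-block sizes in the
#'   synthetic manifest (regions are these blocks).
#' @param ct_noise_sd Gaussian sd of simulated qPCR Ct noise.
#' @param seed integer run seed; every generator derives its own child
#'   seed from it.
#' @return list of validated settings (class `cohort_config`).
#' @export
cohortConfig <- function(n_probes = 10000L, n_per_group = 5L,
                         fraction_hyper = 0.02, fraction_hypo = 0.02,
                         delta_beta = 0.3,
                         baseline_low_mean = 0.1, baseline_high_mean = 0.85,
                         baseline_precision = 15, noise_precision = 150,
                         shared_fraction = 0.5, concordance_rate = 0.13,
                         expr_fold = 2.5, expr_noise_sd = 0.15,
                         motif_plant_rate = 0.3,
                         region_size_min = 2L, region_size_max = 8L,
                         ct_noise_sd = 0.1, seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(fraction_hyper, fraction_hypo, shared_fraction, concordance_rate,
          motif_plant_rate)
  stopifnot(n_probes >= 10, n_per_group >= 2,
            all(fr >= 0 & fr <= 1), fraction_hyper + fraction_hypo <= 1,
            delta_beta > 0, delta_beta <= 1,
            baseline_low_mean > 0, baseline_high_mean < 1,
            baseline_precision > 2, noise_precision > 2,
            expr_fold > 1, region_size_min >= 1,
            region_size_max >= region_size_min)
  structure(cfg, class = "cohort_config")
}

## Synthetic manifest laid out in probe blocks (the regions): each block
## has one gene/category (or is intergenic) and one island relation, with
## 5 kb gaps between blocks so island regions coincide with blocks.
makeSyntheticManifest <- function(cfg) {
  size_choices <- cfg$region_size_min:cfg$region_size_max
  sizes <- integer(0)
  while (sum(sizes) < cfg$n_probes) # sample() would misread length-1 ranges
    sizes <- c(sizes, size_choices[sample.int(length(size_choices), 1)])
  n_blocks <- length(sizes)
  block <- rep(seq_len(n_blocks), sizes)[seq_len(cfg$n_probes)]
  n <- length(block)

  is_intergenic <- stats::runif(n_blocks) < 0.15
  gene_id <- cumsum(!is_intergenic)
  genes <- ifelse(is_intergenic, "", sprintf("G%05d", gene_id))
  cats <- ifelse(is_intergenic, "Intergenic",
                 sample(GENE_CATEGORIES, n_blocks, replace = TRUE,
                        prob = c(0.15, 0.15, 0.1, 0.1, 0.4, 0.1)))
  isl <- sample(ISLAND_RELATIONS, n_blocks, replace = TRUE,
                prob = c(0.2, 0.2, 0.1, 0.5))

  chrom_of_block <- paste0("chr", ceiling(seq_len(n_blocks) / (n_blocks / 4)))
  spacing <- sample(20:200, n, replace = TRUE)
  pos <- integer(n); cur <- 0L; last_chr <- ""
  for (i in seq_len(n)) {
    b <- block[i]
    if (chrom_of_block[b] != last_chr) { cur <- 1000L; last_chr <- chrom_of_block[b] }
    else if (i > 1 && block[i - 1] != b) cur <- cur + 5000L
    else cur <- cur + spacing[i]
    pos[i] <- cur
  }
  data.frame(probe_id = sprintf("cg%06d", seq_len(n)),
             chrom = chrom_of_block[block], pos = pos, strand = "*",
             gene = genes[block], region_category = cats[block],
             island_relation = isl[block], block = block,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic ALCL-like cohort with ground truth
#'
#' Baseline probe methylation is a two-component Beta mixture whose mixing
#' weight follows the island relation (islands mostly unmethylated, open
#' sea mostly methylated). Differential effects are spiked into whole probe
#' blocks: hypermethylation into unmethylated blocks, hypomethylation into
#' methylated blocks, shifting the affected tumor groups' means by
#' `delta_beta` (truncated to \[0.02, 0.98\] with a warning when the shift
#' does not fit). Per-sample values are Beta-distributed around the
#' probe-group mean. Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [cohortConfig()].
#' @return list with `experiment` ([MethylExperiment-class]), `manifest`
#'   (data.frame, no block column), and `truth` ([CohortTruth-class]).
#' @export
generateCohort <- function(cfg = cohortConfig()) {
  set.seed(childSeed(cfg$seed, 1L))
  man <- makeSyntheticManifest(cfg)
  n <- nrow(man)

  p_high <- c(Island = 0.08, Shore = 0.35, Shelf = 0.6, OpenSea = 0.75)
  high <- stats::runif(n) < p_high[man$island_relation]
  shp <- function(mu) cbind(mu * cfg$baseline_precision,
                            (1 - mu) * cfg$baseline_precision)
  lo <- shp(cfg$baseline_low_mean); hi <- shp(cfg$baseline_high_mean)
  baseline <- ifelse(high, stats::rbeta(n, hi[1], hi[2]),
                     stats::rbeta(n, lo[1], lo[2]))
  baseline <- pmin(pmax(baseline, 0.02), 0.98)

  blocks <- unique(man$block)
  block_n <- as.integer(table(man$block)[as.character(blocks)])
  pickBlocks <- function(eligible, target) {
    if (target <= 0 || !length(eligible)) return(integer(0))
    eligible <- sample(eligible)
    sz <- block_n[match(eligible, blocks)]
    take <- which(cumsum(sz) - sz < target) # stop once target reached
    eligible[take]
  }
  bmean <- vapply(split(baseline, man$block), mean,
                  numeric(1))[as.character(blocks)]
  bmax <- vapply(split(baseline, man$block), max,
                 numeric(1))[as.character(blocks)]
  bmin <- vapply(split(baseline, man$block), min,
                 numeric(1))[as.character(blocks)]
  # eligible blocks can absorb the full shift without truncation
  low_blocks <- blocks[bmean < 0.4 & bmax + cfg$delta_beta <= 0.98]
  high_blocks <- blocks[bmean > 0.6 & bmin - cfg$delta_beta >= 0.02]
  hyper_blocks <- pickBlocks(low_blocks,
                             round(cfg$fraction_hyper * cfg$n_probes))
  hypo_blocks <- pickBlocks(setdiff(high_blocks, hyper_blocks),
                            round(cfg$fraction_hypo * cfg$n_probes))

  affectedOf <- function(k) {
    both <- stats::runif(k) < cfg$shared_fraction
    ifelse(both, "ALK_POS,ALK_NEG",
           ifelse(stats::runif(k) < 0.5, "ALK_POS", "ALK_NEG"))
  }
  block_dir <- stats::setNames(rep("", length(blocks)), blocks)
  block_aff <- block_dir
  block_dir[as.character(hyper_blocks)] <- "hyper"
  block_dir[as.character(hypo_blocks)] <- "hypo"
  block_aff[as.character(hyper_blocks)] <- affectedOf(length(hyper_blocks))
  block_aff[as.character(hypo_blocks)] <- affectedOf(length(hypo_blocks))

  dir <- block_dir[as.character(man$block)]
  aff <- block_aff[as.character(man$block)]
  shift <- ifelse(dir == "hyper", cfg$delta_beta,
                  ifelse(dir == "hypo", -cfg$delta_beta, 0))
  tumor_mean <- pmin(pmax(baseline + shift, 0.02), 0.98)
  realized <- tumor_mean - baseline
  if (any(dir != "" & abs(realized) < abs(shift) - 1e-12))
    warning("some spiked effects were truncated to keep means in ",
            "[0.02, 0.98]")

  group_means <- cbind(
    ALK_POS = ifelse(grepl("ALK_POS", aff), tumor_mean, baseline),
    ALK_NEG = ifelse(grepl("ALK_NEG", aff), tumor_mean, baseline),
    CONTROL = baseline)

  k <- cfg$n_per_group
  sample_ids <- c(sprintf("ALKpos_%d", 1:k), sprintf("ALKneg_%d", 1:k),
                  sprintf("CD3_%d", 1:k))
  groups <- stats::setNames(rep(c("ALK_POS", "ALK_NEG", "CONTROL"),
                                each = k), sample_ids)
  mu <- group_means[, rep(c("ALK_POS", "ALK_NEG", "CONTROL"), each = k)]
  beta <- matrix(stats::rbeta(length(mu), mu * cfg$noise_precision,
                              (1 - mu) * cfg$noise_precision),
                 nrow = n, dimnames = list(man$probe_id, sample_ids))

  spiked <- dir != ""
  mvp <- data.frame(probe_id = man$probe_id[spiked],
                    direction = dir[spiked], delta = realized[spiked],
                    affected = aff[spiked], stringsAsFactors = FALSE)
  dmr <- do.call(rbind, lapply(c(hyper_blocks, hypo_blocks), function(b) {
    i <- man$block == b
    rows <- data.frame(region_id = character(0), category = character(0),
                       gene = character(0), direction = character(0),
                       delta = numeric(0), affected = character(0),
                       n_probes = integer(0), stringsAsFactors = FALSE)
    g <- man$gene[i][1]; cat <- man$region_category[i][1]
    rel <- man$island_relation[i][1]
    mk <- function(id, category) data.frame(
      region_id = id, category = category, gene = g,
      direction = block_dir[as.character(b)],
      delta = mean(realized[i]), affected = block_aff[as.character(b)],
      n_probes = sum(i), stringsAsFactors = FALSE)
    if (g != "") rows <- rbind(rows, mk(paste(g, cat, sep = "|"), cat))
    if (rel != "OpenSea")
      rows <- rbind(rows, mk(sprintf("%s:%d-%d|%s", man$chrom[i][1],
                                     min(man$pos[i]), max(man$pos[i]), rel),
                             rel))
    rows
  }))
  if (is.null(dmr))
    dmr <- data.frame(region_id = character(0), category = character(0),
                      gene = character(0), direction = character(0),
                      delta = numeric(0), affected = character(0),
                      n_probes = integer(0), stringsAsFactors = FALSE)

  manifest <- man[, manifestColumns]
  truth <- new("CohortTruth", mvp = mvp, dmr = dmr,
               motif_windows = character(0),
               concordant_genes = character(0))
  list(experiment = MethylExperiment(beta, manifest, groups),
       manifest = manifest, truth = truth)
}

#' Generate an expression table coupled to the methylation truth
#'
#' Every gene in the manifest gets a lognormal baseline; a spiked promoter
#' gene (truth DMR in TSS200/TSS1500) is chosen concordant with probability
#' `concordance_rate`, in which case the affected tumor groups' expression
#' is divided (hypermethylated) or multiplied (hypomethylated) by
#' `expr_fold`; all samples get lognormal noise.
#'
#' @param truth [CohortTruth-class] from [generateCohort()].
#' @param manifest manifest data.frame.
#' @param groups named sample-to-group vector (defines the columns).
#' @param cfg the [cohortConfig()] used for the cohort.
#' @return list with `expr` (genes x samples matrix) and `truth` (updated
#'   with `concordant_genes`).
#' @export
generateExpression <- function(truth, manifest, groups,
                               cfg = cohortConfig()) {
  set.seed(childSeed(cfg$seed, 2L))
  genes <- setdiff(unique(unlist(strsplit(manifest$gene, ";"))), "")
  dmr <- dmrTruth(truth)
  prom <- dmr[dmr$category %in% c("TSS200", "TSS1500") & dmr$gene != "", ]
  prom <- prom[!duplicated(prom$gene), , drop = FALSE]
  skipped <- setdiff(prom$gene, genes)
  if (length(skipped))
    message("skipping ", length(skipped), " truth gene(s) absent from ",
            "manifest gene universe")
  prom <- prom[prom$gene %in% genes, , drop = FALSE]
  concordant <- prom$gene[stats::runif(nrow(prom)) < cfg$concordance_rate]

  base <- stats::rlnorm(length(genes), meanlog = log(100), sdlog = 1)
  names(base) <- genes
  expr <- matrix(rep(base, length(groups)), nrow = length(genes),
                 dimnames = list(genes, names(groups)))
  for (j in seq_len(nrow(prom))) {
    g <- prom$gene[j]
    if (!g %in% concordant) next
    fold <- if (prom$direction[j] == "hyper") 1 / cfg$expr_fold else
      cfg$expr_fold
    aff_groups <- strsplit(prom$affected[j], ",")[[1]]
    cols <- names(groups)[groups %in% aff_groups]
    expr[g, cols] <- expr[g, cols] * fold
  }
  noise <- matrix(stats::rlnorm(length(expr), 0, cfg$expr_noise_sd),
                  nrow = nrow(expr))
  expr <- expr * noise
  truth@concordant_genes <- concordant
  list(expr = expr, truth = truth)
}

#' Generate a chromatin feature track overlapping hypermethylated truth
#'
#' Short intervals are placed over `overlap_rate` of the hypermethylated
#' truth probes and over `background_rate` of all remaining probes,
#' emulating a Polycomb-occupancy track enriched at tumor-hypermethylated
#' sites.
#'
#' @param truth [CohortTruth-class].
#' @param manifest manifest data.frame.
#' @param overlap_rate fraction of hyper truth probes covered (default
#'   0.55).
#' @param background_rate fraction of all other probes covered (default
#'   0.33).
#' @param cfg [cohortConfig()] (supplies the seed).
#' @return [GenomicRanges::GRanges] track (merged).
#' @export
generateTracks <- function(truth, manifest, overlap_rate = 0.55,
                           background_rate = 0.33, cfg = cohortConfig()) {
  set.seed(childSeed(cfg$seed, 3L))
  mvp <- mvpTruth(truth)
  hyper <- mvp$probe_id[mvp$direction == "hyper"]
  others <- setdiff(manifest$probe_id, hyper)
  chosen <- c(sample(hyper, round(overlap_rate * length(hyper))),
              sample(others, round(background_rate * length(others))))
  ann <- manifest[manifest$probe_id %in% chosen, , drop = FALSE]
  if (!nrow(ann))
    return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(
    ann$chrom, IRanges::IRanges(pmax(ann$pos - 4L, 1L), ann$pos + 6L))
  GenomicRanges::reduce(gr)
}

#' Generate 100-bp windows with a planted motif
#'
#' Uniform-random background sequence per hypomethylated truth probe; the
#' motif (or its reverse complement) is inserted once at a random offset in
#' `plant_rate` of the windows. Window ids carrying the motif are recorded
#' in the truth set.
#'
#' @param truth [CohortTruth-class], or NULL when `window_ids` is given.
#' @param width window width, default 100.
#' @param motif planted motif, default the AP1 core `TGACTCA`.
#' @param plant_rate fraction of windows carrying the motif.
#' @param cfg [cohortConfig()] (supplies the seed).
#' @param window_ids optional explicit window ids (default: hypomethylated
#'   truth probes).
#' @return list with `windows` ([Biostrings::DNAStringSet]) and `truth`
#'   (updated with `motif_windows`).
#' @export
generateSequences <- function(truth = NULL, width = 100L, motif = "TGACTCA",
                              plant_rate = 0.3, cfg = cohortConfig(),
                              window_ids = NULL) {
  set.seed(childSeed(cfg$seed, 4L))
  if (is.null(truth))
    truth <- new("CohortTruth", mvp = data.frame(), dmr = data.frame(),
                 motif_windows = character(0),
                 concordant_genes = character(0))
  if (is.null(window_ids)) {
    mvp <- mvpTruth(truth)
    window_ids <- mvp$probe_id[mvp$direction == "hypo"]
  }
  n <- length(window_ids)
  if (!n) stop("no windows to generate")
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(bases, width, replace = TRUE), collapse = ""),
    character(1))
  planted <- sample(window_ids, round(plant_rate * n))
  w <- nchar(motif)
  for (id in planted) {
    i <- match(id, window_ids)
    ins <- if (stats::runif(1) < 0.5) motif else revcompChar(motif)
    off <- sample(width - w + 1, 1)
    substr(seqs[i], off, off + w - 1) <- ins
  }
  windows <- Biostrings::DNAStringSet(seqs)
  names(windows) <- window_ids
  truth@motif_windows <- planted
  list(windows = windows, truth = truth)
}

#' Generate a MethyLight Ct table from target PMR values
#'
#' Ct values are back-computed from chosen true PMR per group and gene
#' assuming 100% efficiency (`quantity = 2^-Ct`), with optional Gaussian Ct
#' noise; a true PMR of 0 yields a no-amplification flag for the gene
#' reaction.
#'
#' @param pmr_targets data.frame with `group`, `gene`, `pmr` (true PMR per
#'   group).
#' @param n_per_group samples per group.
#' @param n_replicates qPCR replicates per reaction.
#' @param ct_noise_sd Gaussian sd of Ct noise (0 = exact).
#' @param seed integer seed.
#' @return data.frame `sample_id`, `group`, `assay`, `replicate`, `ct`,
#'   `no_amplification`, including `M.SssI` reference rows.
#' @export
generateCtTable <- function(pmr_targets, n_per_group = 6L,
                            n_replicates = 3L, ct_noise_sd = 0,
                            seed = 1L) {
  set.seed(childSeed(seed, 5L))
  genes <- unique(pmr_targets$gene)
  groups <- unique(pmr_targets$group)
  alu_ref_ct <- 15; genex_ref_ct <- 18
  ref_ratio <- 2^(-genex_ref_ct) / 2^(-alu_ref_ct)
  rows <- list()
  addRows <- function(sid, grp, assay, ct0, noamp = FALSE) {
    ct <- if (noamp) rep(NA_real_, n_replicates) else
      ct0 + stats::rnorm(n_replicates, 0, ct_noise_sd)
    data.frame(sample_id = sid, group = grp, assay = assay,
               replicate = seq_len(n_replicates), ct = ct,
               no_amplification = noamp, stringsAsFactors = FALSE)
  }
  for (g in genes) {
    rows[[length(rows) + 1]] <- addRows("M.SssI", "REFERENCE", g,
                                        genex_ref_ct)
  }
  rows[[length(rows) + 1]] <- addRows("M.SssI", "REFERENCE", "Alu",
                                      alu_ref_ct)
  for (grp in groups) {
    for (i in seq_len(n_per_group)) {
      sid <- sprintf("%s_%d", grp, i)
      alu_ct <- alu_ref_ct + stats::runif(1, -1, 1)
      rows[[length(rows) + 1]] <- addRows(sid, grp, "Alu", alu_ct)
      for (g in genes) {
        pmr <- pmr_targets$pmr[pmr_targets$group == grp &
                                 pmr_targets$gene == g]
        if (pmr == 0) {
          rows[[length(rows) + 1]] <- addRows(sid, grp, g, NA, noamp = TRUE)
        } else {
          q <- (pmr / 100) * ref_ratio * 2^(-alu_ct)
          rows[[length(rows) + 1]] <- addRows(sid, grp, g, -log2(q))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a reference-stage cohort for stage-assignment experiments
#'
#' Each developmental stage carries its own signature probe set shifted
#' from a common baseline; reference samples are drawn per stage and tumor
#' samples are drawn from the distribution of one chosen stage.
#'
#' @param stages character vector of stage names, default the thymic
#'   series ETP -> committed progenitor -> preTCR -> DP -> SP.
#' @param tumor_stage the stage tumors are simulated from.
#' @param n_probes probes, default 500.
#' @param n_ref reference samples per stage, default 3.
#' @param n_tumor tumor samples, default 2.
#' @param signature_frac fraction of probes in each stage signature.
#' @param effect beta-scale shift of signature probes, default 0.35.
#' @param noise_precision Beta noise precision.
#' @param seed integer seed.
#' @return list with `experiment` ([MethylExperiment-class]; tumor group
#'   `ALK_POS`, references `REFERENCE_STAGE:<stage>`) and `tumor_stage`.
#' @export
generateStageCohort <- function(stages = c("ETP", "CD34_CD1a", "preTCR",
                                           "DP", "SP"),
                                tumor_stage = "ETP", n_probes = 500L,
                                n_ref = 3L, n_tumor = 2L,
                                signature_frac = 0.15, effect = 0.35,
                                noise_precision = 80, seed = 1L) {
  stopifnot(tumor_stage %in% stages)
  set.seed(childSeed(seed, 6L))
  baseline <- stats::runif(n_probes, 0.15, 0.85)
  sig_size <- floor(signature_frac * n_probes)
  free <- seq_len(n_probes)
  means <- matrix(baseline, n_probes, length(stages),
                  dimnames = list(NULL, stages))
  for (s in stages) {
    idx <- sample(free, sig_size)
    free <- setdiff(free, idx)
    sgn <- sample(c(-1, 1), sig_size, replace = TRUE)
    means[idx, s] <- pmin(pmax(baseline[idx] + sgn * effect, 0.02), 0.98)
  }
  cols <- c(unlist(lapply(stages, function(s) rep(s, n_ref))),
            rep(tumor_stage, n_tumor))
  ids <- c(unlist(lapply(stages, function(s) sprintf("%s_ref%d", s,
                                                     seq_len(n_ref)))),
           sprintf("tumor_%d", seq_len(n_tumor)))
  mu <- means[, cols]
  beta <- matrix(stats::rbeta(length(mu), mu * noise_precision,
                              (1 - mu) * noise_precision),
                 nrow = n_probes,
                 dimnames = list(sprintf("cg%06d", seq_len(n_probes)), ids))
  groups <- stats::setNames(
    c(paste0("REFERENCE_STAGE:", rep(stages, each = n_ref)),
      rep("ALK_POS", n_tumor)), ids)
  ann <- data.frame(probe_id = rownames(beta), chrom = "chr1",
                    pos = seq_len(n_probes) * 100L, strand = "*",
                    gene = "", region_category = "Intergenic",
                    island_relation = "OpenSea", stringsAsFactors = FALSE)
  list(experiment = MethylExperiment(beta, ann, groups),
       tumor_stage = tumor_stage)
}
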