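test_that("cohort generation is deterministic and honours the null config", {
  cfg <- cohortConfig(n_probes = 500, seed = 11)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(betaValues(a$experiment), betaValues(b$experiment))
  expect_identical(a$manifest, b$manifest)
  expect_identical(mvpTruth(a$truth), mvpTruth(b$truth))

  # null cohort: no spiked truth, group means differ only by noise
  null_cfg <- cohortConfig(n_probes = 500, fraction_hyper = 0,
                           fraction_hypo = 0, seed = 11)
  nc <- generateCohort(null_cfg)
  expect_equal(nrow(mvpTruth(nc$truth)), 0L)
  g <- sampleGroups(nc$experiment)
  bm <- betaValues(nc$experiment)
  gap <- rowMeans(bm[, g == "ALK_POS"]) - rowMeans(bm[, g == "CONTROL"])
  expect_lt(max(abs(gap)), 0.15) # pure sampling noise at n = 5
  expect_lt(abs(mean(gap)), 0.01)
})

test_that("spiked effects realise the configured beta difference", {
  cfg <- cohortConfig(n_probes = 10000, seed = 3)
  co <- generateCohort(cfg)
  tr <- mvpTruth(co$truth)
  expect_gt(nrow(tr), 100)
  expect_lt(abs(mean(abs(tr$delta)) - 0.3), 0.05)
  # empirical group-mean difference at truth probes tracks the spike
  g <- sampleGroups(co$experiment)
  bm <- betaValues(co$experiment)
  both <- tr[tr$affected == "ALK_POS,ALK_NEG", ]
  emp <- rowMeans(bm[both$probe_id, g == "ALK_POS"]) -
    rowMeans(bm[both$probe_id, g == "CONTROL"])
  expect_lt(abs(mean(abs(emp)) - 0.3), 0.05)
  # every truth probe/region exists in the manifest
  expect_true(all(tr$probe_id %in% co$manifest$probe_id))
})

test_that("expression coupling follows the concordance rate", {
  cfg <- cohortConfig(n_probes = 2000, region_size_min = 2,
                      region_size_max = 3, fraction_hyper = 0.1,
                      fraction_hypo = 0.1, shared_fraction = 1,
                      concordance_rate = 1, seed = 5)
  co <- generateCohort(cfg)
  ge <- generateExpression(co$truth, co$manifest,
                           sampleGroups(co$experiment), cfg)
  prom <- dmrTruth(co$truth)
  prom <- prom[prom$category %in% c("TSS200", "TSS1500") & prom$gene != "", ]
  prom <- prom[!duplicated(prom$gene), ]
  expect_gt(nrow(prom), 10)
  expect_setequal(concordantGenes(ge$truth), prom$gene)
  g <- sampleGroups(co$experiment)
  ratio <- rowMeans(ge$expr[prom$gene, g == "ALK_POS", drop = FALSE]) /
    rowMeans(ge$expr[prom$gene, g == "CONTROL", drop = FALSE])
  hyper <- prom$direction == "hyper"
  expect_true(all(ratio[hyper] < 1 / 1.5))
  expect_true(all(ratio[!hyper] > 1.5))

  # rate 0: nothing concordant
  cfg0 <- cohortConfig(n_probes = 2000, concordance_rate = 0, seed = 5)
  co0 <- generateCohort(cfg0)
  ge0 <- generateExpression(co0$truth, co0$manifest,
                            sampleGroups(co0$experiment), cfg0)
  expect_length(concordantGenes(ge0$truth), 0L)

  # intermediate rate lands inside the binomial 95% interval
  cfg13 <- cohortConfig(n_probes = 20000, region_size_min = 2,
                        region_size_max = 2, fraction_hyper = 0.1,
                        fraction_hypo = 0.1, concordance_rate = 0.13,
                        seed = 5)
  co13 <- generateCohort(cfg13)
  ge13 <- generateExpression(co13$truth, co13$manifest,
                             sampleGroups(co13$experiment), cfg13)
  prom13 <- dmrTruth(co13$truth)
  prom13 <- prom13[prom13$category %in% c("TSS200", "TSS1500") &
                     prom13$gene != "", ]
  n <- length(unique(prom13$gene))
  k <- length(concordantGenes(ge13$truth))
  ci <- qbinom(c(0.025, 0.975), n, 0.13)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("feature tracks cover the requested truth fractions", {
  cfg <- cohortConfig(n_probes = 2000, seed = 9)
  co <- generateCohort(cfg)
  hyper <- mvpTruth(co$truth)
  hyper <- hyper$probe_id[hyper$direction == "hyper"]
  gr_all <- probeGRanges(co$manifest)

  full <- generateTracks(co$truth, co$manifest, overlap_rate = 1,
                         background_rate = 0, cfg = cfg)
  hit <- names(gr_all)[IRanges::overlapsAny(gr_all, full)]
  expect_true(all(hyper %in% hit))
  expect_length(setdiff(hit, hyper), 0L)

  none <- generateTracks(co$truth, co$manifest, overlap_rate = 0,
                         background_rate = 0.2, cfg = cfg)
  hit0 <- names(gr_all)[IRanges::overlapsAny(gr_all, none)]
  expect_length(intersect(hit0, hyper), 0L)
})

test_that("motif windows plant the motif at the requested rate", {
  cfg <- cohortConfig(seed = 21)
  ids <- sprintf("w%03d", 1:500)

  all_planted <- generateSequences(window_ids = ids, plant_rate = 1,
                                   cfg = cfg)
  expect_setequal(motifTruth(all_planted$truth), ids)
  seqs <- as.character(all_planted$windows)
  has <- grepl("TGACTCA", seqs) | grepl("TGAGTCA", seqs)
  expect_true(all(has))

  # plant_rate 0: occurrences at the background expectation
  none <- generateSequences(window_ids = ids, plant_rate = 0, cfg = cfg)
  expect_length(motifTruth(none$truth), 0L)
  seqs0 <- as.character(none$windows)
  n_occ <- sum(lengths(gregexpr("TGACTCA", seqs0)) *
                 (regexpr("TGACTCA", seqs0) > 0)) +
    sum(lengths(gregexpr("TGAGTCA", seqs0)) *
          (regexpr("TGAGTCA", seqs0) > 0))
  lambda <- 500 * 2 * (100 - 7 + 1) / 4^7 # closed-form expectation
  expect_gte(n_occ, qpois(0.001, lambda))
  expect_lte(n_occ, qpois(0.999, lambda))

  # fixed seed reproduces the sequences byte for byte
  again <- generateSequences(window_ids = ids, plant_rate = 1, cfg = cfg)
  expect_identical(as.character(again$windows),
                   as.character(all_planted$windows))
})

test_that("Ct tables invert the PMR formula", {
  targets <- data.frame(group = c("ALCL", "ALCL", "CTRL", "CTRL"),
                        gene = c("LEF1", "TCF7", "LEF1", "TCF7"),
                        pmr = c(100, 25, 0, 80))
  ct <- generateCtTable(targets, n_per_group = 3, ct_noise_sd = 0, seed = 4)
  expect_true(all(ct$no_amplification[ct$group == "CTRL" &
                                        ct$assay == "LEF1"]))
  pm <- pmrFromCtTable(ct)
  got <- aggregate(pmr ~ group + gene, pm, mean)
  for (i in seq_len(nrow(targets))) {
    g <- got$pmr[got$group == targets$group[i] & got$gene == targets$gene[i]]
    expect_equal(g, targets$pmr[i], tolerance = 1e-9)
  }

  # noisy recovery: sd 0.1 over 6 replicates within 20% relative error
  noisy <- generateCtTable(data.frame(group = "ALCL", gene = "LEF1",
                                      pmr = 25),
                           n_per_group = 6, n_replicates = 6,
                           ct_noise_sd = 0.1, seed = 8)
  pmn <- pmrFromCtTable(noisy)
  expect_lt(abs(mean(pmn$pmr) - 25) / 25, 0.2)
})
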