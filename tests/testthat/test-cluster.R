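test_that("z-scoring centres each sample to mean 0, population variance 1", {
  x <- matrix(c(0, 0.5, 1, 0.2, 0.4, 0.9), 3, 2,
              dimnames = list(paste0("p", 1:3), c("s1", "s2")))
  z <- zscoreSamples(x)
  expect_equal(colMeans(z), c(s1 = 0, s2 = 0), tolerance = 1e-12)
  expect_equal(colMeans(z^2), c(s1 = 1, s2 = 1), tolerance = 1e-12)

  x[, 2] <- 0.5
  expect_error(zscoreSamples(x), "zero-variance")

  set.seed(1)
  r <- matrix(runif(1000), 100, 10)
  zr <- zscoreSamples(r)
  expect_lt(max(abs(colMeans(zr))), 1e-12)
  expect_lt(max(abs(colMeans(zr^2) - 1)), 1e-12)
})

test_that("top-probe selection ranks by p with deterministic ties", {
  set.seed(2)
  tab <- data.frame(probe_id = sprintf("cg%03d", 1:100),
                    p = runif(100), delta_beta = runif(100, -0.5, 0.5))
  top1 <- selectTopProbes(tab, fraction = 0.01)
  expect_equal(top1, tab$probe_id[which.min(tab$p)])

  # ties across the cut resolved by larger |delta|, then probe id
  tied <- data.frame(probe_id = c("cgB", "cgA", "cgC"),
                     p = c(0.01, 0.01, 0.01),
                     delta_beta = c(0.3, 0.3, 0.5))
  expect_equal(selectTopProbes(tied, fraction = 1 / 3), "cgC")
  expect_equal(selectTopProbes(tied, fraction = 2 / 3), c("cgC", "cgA"))

  # p_max route and brute-force equivalence on 1000 records
  big <- data.frame(probe_id = sprintf("cg%04d", 1:1000),
                    p = round(runif(1000), 2),
                    delta_beta = runif(1000, -1, 1))
  got <- selectTopProbes(big, fraction = 0.05)
  ord <- big[order(big$p, -abs(big$delta_beta), big$probe_id), ]
  expect_equal(got, ord$probe_id[1:50])
  expect_setequal(selectTopProbes(big, p_max = 0.1),
                  big$probe_id[big$p < 0.1])
})

test_that("hierarchical clustering merges by 1 - Pearson correlation", {
  # two identical samples and one distant one: the pair merges first
  set.seed(3)
  base <- runif(50)
  mat <- cbind(a = base, b = base, c = rev(base) + runif(50, 0, 0.1))
  cl <- hierCluster(mat)
  expect_equal(sort(cl$hclust$merge[1, ]), c(-2, -1))

  # 3-sample toy: merge heights match hand-computed correlations
  m <- cbind(s1 = c(0.1, 0.2, 0.9, 0.8),
             s2 = c(0.15, 0.25, 0.85, 0.75),
             s3 = c(0.9, 0.8, 0.1, 0.2))
  cl2 <- hierCluster(m)
  d12 <- 1 - cor(m[, 1], m[, 2])
  d13 <- 1 - cor(m[, 1], m[, 3])
  d23 <- 1 - cor(m[, 2], m[, 3])
  expect_equal(cl2$height[1], min(d12, d13, d23), tolerance = 1e-12)
  expect_equal(cl2$height[2], mean(c(d13, d23)), tolerance = 1e-12)

  expect_error(hierCluster(cbind(s1 = rep(1, 5), s2 = runif(5))),
               "constant")

  # invariance to per-sample affine scaling under the correlation metric
  scaled <- sweep(m, 2, c(2, 0.5, 3), "*")
  expect_equal(hierCluster(scaled)$height, cl2$height, tolerance = 1e-12)

  nwk <- dendrogramNewick(cl2)
  expect_match(nwk, "^\\(")
  expect_match(nwk, "s3")
})

test_that("strong 3-group structure is recovered exactly at k = 3", {
  co <- generateCohort(cohortConfig(n_probes = 3000, fraction_hyper = 0.05,
                                    fraction_hypo = 0.05,
                                    shared_fraction = 0.5, seed = 23))
  cl <- hierCluster(betaValues(co$experiment), k = 3)
  g <- sampleGroups(co$experiment)
  expect_equal(mclust::adjustedRandIndex(cl$clusters,
                                         g[names(cl$clusters)]), 1)
})

test_that("PCA has fixed signs, ordered variance and exact reconstruction", {
  set.seed(4)
  mat <- matrix(runif(200), 20, 10,
                dimnames = list(paste0("p", 1:20), paste0("s", 1:10)))
  z <- zscoreSamples(mat)
  pc <- pcaEmbed(z)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  # sign rule: the largest-magnitude loading of each component is positive
  for (j in seq_len(ncol(pc$rotation))) {
    v <- pc$rotation[, j]
    expect_gte(v[which.max(abs(v))], 0)
  }
  # full reconstruction
  rec <- pc$coordinates %*% t(pc$rotation) +
    matrix(pc$center, nrow(pc$coordinates), length(pc$center), byrow = TRUE)
  expect_equal(rec, unname(t(z)), tolerance = 1e-9, ignore_attr = TRUE)

  # data on a line: one component explains everything
  line <- outer(runif(30), c(1, 2, 3, 4))
  pl <- pcaEmbed(line + 1e-9)
  expect_gte(pl$explained_variance[1], 0.999)

  # two samples: a single informative component
  two <- pcaEmbed(mat[, 1:2])
  expect_lt(two$explained_variance[2], 1e-12)

  # sample reordering permutes coordinates but changes nothing else
  perm <- sample(ncol(z))
  pp <- pcaEmbed(z[, perm])
  expect_equal(pp$coordinates[colnames(z), , drop = FALSE],
               pc$coordinates, tolerance = 1e-9)
})

test_that("stage assignment picks the nearest centroid with tie flags", {
  set.seed(5)
  ref <- matrix(runif(40), 10, 4,
                dimnames = list(NULL, c("e1", "e2", "d1", "d2")))
  stages <- c(e1 = "REFERENCE_STAGE:ETP", e2 = "REFERENCE_STAGE:ETP",
              d1 = "REFERENCE_STAGE:DP", d2 = "REFERENCE_STAGE:DP")
  centroid_etp <- rowMeans(ref[, 1:2])
  tum <- cbind(t1 = centroid_etp)
  a <- assignNearestStage(tum, ref, stages)
  expect_equal(a$assignment$stage, "ETP")
  expect_equal(a$assignment$distance, 0)

  # exactly equidistant: first stage in input order wins, tie flagged
  ref2 <- matrix(c(0, 0, 1, 1), 2, 2, dimnames = list(NULL, c("x", "y")))
  stages2 <- c(x = "REFERENCE_STAGE:A", y = "REFERENCE_STAGE:B")
  mid <- cbind(t1 = c(0.5, 0.5))
  a2 <- assignNearestStage(mid, ref2, stages2)
  expect_equal(a2$assignment$stage, "A")
  expect_true(a2$assignment$tie)
})

test_that("tumors simulated from a stage are assigned back to it", {
  hits <- vapply(1:25, function(s) {
    st <- generateStageCohort(tumor_stage = "preTCR", seed = s)
    g <- sampleGroups(st$experiment)
    z <- zscoreSamples(betaValues(st$experiment))
    refs <- names(g)[startsWith(g, "REFERENCE_STAGE:")]
    tums <- names(g)[g == "ALK_POS"]
    a <- assignNearestStage(z[, tums, drop = FALSE],
                            z[, refs, drop = FALSE], g[refs])
    all(a$assignment$stage == "preTCR")
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
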