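test_that("manifest reader parses, validates and round-trips", {
  man <- tinyManifest()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeManifest(man, path)
  expect_equal(readManifest(path), man)

  # duplicated probe id
  bad <- man; bad$probe_id[2] <- bad$probe_id[1]
  writeManifest(bad, path)
  expect_error(readManifest(path), "duplicate probe_id")

  # missing column is named in the error
  writeLines(c("probe_id\tchrom\tpos", "cg1\tchr1\t10"), path)
  expect_error(readManifest(path), "strand")

  # unknown category string rejected
  bad <- man; bad$region_category[1] <- "Promoter"
  writeManifest(bad, path)
  expect_error(readManifest(path), "region_category")

  # Intergenic implies empty gene
  bad <- man; bad$gene[3] <- "XYZ"
  writeManifest(bad, path)
  expect_error(readManifest(path), "Intergenic")

  # 100-probe synthetic manifest round-trips field by field
  big <- randomManifest(100)
  # avoid Intergenic/gene clashes in the random fixture
  writeManifest(big, path)
  expect_equal(readManifest(path), big)
})

test_that("multi-mapped probes expand to one record per gene/category pair", {
  man <- tinyManifest()
  man$gene[1] <- "TCF7;GATA3"
  man$region_category[1] <- "TSS200;TSS1500"
  pr <- probeRegions(man)
  first <- pr[pr$probe_id == "cg000001", ]
  expect_equal(nrow(first), 2L)
  expect_setequal(first$gene, c("TCF7", "GATA3"))
  expect_setequal(first$region_category, c("TSS200", "TSS1500"))
  # a single gene recycles over several categories
  man2 <- tinyManifest()
  man2$region_category[2] <- "Body;UTR3"
  pr2 <- probeRegions(man2)
  expect_equal(sum(pr2$probe_id == "cg000002"), 2L)
  expect_true(all(pr2$gene[pr2$probe_id == "cg000002"] == "TCF7"))
})

test_that("beta matrix reader enforces range, NA policy and round-trips", {
  man <- tinyManifest()
  b <- matrix(c(0.1, 0.9, 0.5, 0.25), 2, 2,
              dimnames = list(man$probe_id[1:2], c("s1", "s2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeBetaMatrix(b, path)
  got <- readBetaMatrix(path, man)
  expect_equal(got, b)

  # out-of-range value raises, never silently clipped
  writeLines(c("probe_id\ts1", "cg000001\t1.2"), path)
  expect_error(readBetaMatrix(path), "\\[0, 1\\]")

  # NA: error by default, dropped on request
  writeLines(c("probe_id\ts1\ts2", "cg000001\tNA\t0.5",
               "cg000002\t0.2\t0.3"), path)
  expect_error(readBetaMatrix(path), "missing")
  expect_message(got <- readBetaMatrix(path, na = "drop"), "dropping 1")
  expect_equal(rownames(got), "cg000002")

  # probe missing from manifest is a reconciliation error
  writeLines(c("probe_id\ts1", "cg999999\t0.5"), path)
  expect_error(readBetaMatrix(path, man), "absent from manifest")

  # serialize/parse of a 1000 x 15 synthetic matrix is bitwise-stable text
  set.seed(42)
  big <- matrix(round(runif(1000 * 15), 6), 1000, 15,
                dimnames = list(sprintf("cg%06d", 1:1000),
                                sprintf("s%02d", 1:15)))
  writeBetaMatrix(big, path)
  first <- readLines(path)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeBetaMatrix(readBetaMatrix(path), path2)
  expect_identical(readLines(path2), first)
})

test_that("BED tracks keep 0-based half-open semantics", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", path)
  gr <- readTrack(path)
  expect_equal(GenomicRanges::start(gr), 101L) # 1-based closed encoding
  expect_equal(GenomicRanges::end(gr), 200L)

  # a point probe at 0-based pos p overlaps [s, e) iff s <= p < e
  man <- data.frame(probe_id = paste0("p", 1:4), chrom = "chr1",
                    pos = c(99L, 100L, 199L, 200L), strand = "*",
                    gene = "", region_category = "Intergenic",
                    island_relation = "OpenSea", stringsAsFactors = FALSE)
  hit <- IRanges::overlapsAny(probeGRanges(man), gr)
  expect_equal(unname(hit), c(FALSE, TRUE, TRUE, FALSE))

  # overlapping intervals are preserved raw
  writeLines(c("chr1\t10\t50", "chr1\t30\t80"), path)
  expect_length(readTrack(path), 2L)

  # zero-length interval is a format error
  writeLines("chr1\t100\t100", path)
  expect_error(readTrack(path))

  # 50-interval synthetic track round-trips
  set.seed(7)
  starts <- sort(sample.int(1e5, 50))
  gr <- GenomicRanges::GRanges("chr2",
                               IRanges::IRanges(starts, starts + 99L))
  writeTrack(gr, path)
  back <- readTrack(path)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
})

test_that("sample sheets and expression tables validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  groups <- c(s1 = "ALK_POS", s2 = "CONTROL", s3 = "REFERENCE_STAGE:ETP")
  writeSampleSheet(groups, path)
  expect_equal(readSampleSheet(path), groups)
  writeLines(c("sample_id\tgroup", "s1\tTUMOUR"), path)
  expect_error(readSampleSheet(path), "unknown group")

  expr <- matrix(c(1.5, 200.25, 3, 4), 2, 2,
                 dimnames = list(c("TCF7", "GATA3"), c("s1", "s2")))
  writeExpressionTable(expr, path)
  expect_equal(readExpressionTable(path), expr)
  writeLines(c("gene\ts1", "TCF7\t-1"), path)
  expect_error(readExpressionTable(path), "positive")
  writeLines(c("gene\ts1", "TCF7\t1", "TCF7\t2"), path)
  expect_error(readExpressionTable(path), "duplicate")
})

test_that("MethylExperiment validity guards beta range and group mapping", {
  man <- tinyManifest()
  b <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), 3, 2,
              dimnames = list(man$probe_id, c("s1", "s2")))
  me <- MethylExperiment(b, man, c(s1 = "ALK_POS", s2 = "CONTROL"))
  expect_s4_class(me, "MethylExperiment")
  expect_equal(betaValues(me), b)
  expect_equal(sampleGroups(me), c(s1 = "ALK_POS", s2 = "CONTROL"))
  expect_equal(probeAnnotation(me)$gene, man$gene)

  expect_error(MethylExperiment(b, man, c(s1 = "ALK_POS")), "without a group")
  b2 <- b; b2[1, 1] <- 1.5
  expect_error(MethylExperiment(b2, man, c(s1 = "ALK_POS", s2 = "CONTROL")),
               "\\[0, 1\\]")
})
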