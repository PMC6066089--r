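## Readers and writers for the flat-file dialects used throughout:
## tab-separated tables with a header, BED3 tracks, FASTA sequences.
## All floats are written with fixed 6-decimal formatting and deterministic
## column order so outputs are byte-reproducible.

manifestColumns <- c("probe_id", "chrom", "pos", "strand", "gene",
                     "region_category", "island_relation")

#' Read a probe-annotation manifest
#'
#' The manifest is a TSV with columns `probe_id`, `chrom`, `pos` (0-based),
#' `strand` (+/-/*), `gene`, `region_category`, `island_relation`. Genes and
#' region categories may be ";"-joined pairs (multi-mapped probes); they are
#' kept joined here and expanded by [probeRegions()].
#'
#' @param path file path.
#' @return data.frame with one row per probe.
#' @export
readManifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  miss <- setdiff(manifestColumns, colnames(df))
  if (length(miss))
    stop("manifest is missing required column(s): ",
         paste(miss, collapse = ", "))
  df <- df[, manifestColumns]
  df$pos <- suppressWarnings(as.integer(df$pos))
  if (anyNA(df$pos) || any(df$pos < 0))
    stop("manifest 'pos' must be a non-negative integer")
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe_id in manifest: ",
         paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "))
  if (!all(df$strand %in% c("+", "-", "*")))
    stop("manifest 'strand' must be one of +, -, *")
  cats <- unlist(strsplit(df$region_category, ";", fixed = TRUE))
  bad <- setdiff(cats, REGION_CATEGORIES)
  if (length(bad))
    stop("unknown region_category value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(df$island_relation, ISLAND_RELATIONS)
  if (length(bad))
    stop("unknown island_relation value(s): ", paste(bad, collapse = ", "))
  inter <- vapply(strsplit(df$region_category, ";", fixed = TRUE),
                  function(x) all(x == "Intergenic"), logical(1))
  if (any(inter & df$gene != ""))
    stop("Intergenic probes must have an empty gene")
  df
}

#' Write a probe-annotation manifest
#'
#' @param manifest data.frame as returned by [readManifest()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.table(manifest[, manifestColumns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expand multi-mapped probes to one (probe, gene, category) record each
#'
#' @param x a manifest data.frame or a [MethylExperiment-class].
#' @return data.frame with columns `probe_id`, `chrom`, `pos`, `gene`,
#'   `region_category`, `island_relation`; a probe annotated to k
#'   gene/category pairs contributes k rows.
#' @export
probeRegions <- function(x) {
  if (is(x, "MethylExperiment")) x <- probeAnnotation(x)
  genes <- strsplit(x$gene, ";", fixed = TRUE)
  cats <- strsplit(x$region_category, ";", fixed = TRUE)
  genes[lengths(genes) == 0] <- list("")
  k <- lengths(cats)
  # a single gene recycles over several categories
  genes <- Map(function(g, n) if (length(g) == 1L) rep(g, n) else g, genes, k)
  if (any(lengths(genes) != k))
    stop("gene and region_category lists differ in length for probe(s): ",
         paste(x$probe_id[lengths(genes) != k], collapse = ", "))
  idx <- rep(seq_len(nrow(x)), k)
  data.frame(probe_id = x$probe_id[idx], chrom = x$chrom[idx],
             pos = x$pos[idx], gene = unlist(genes),
             region_category = unlist(cats),
             island_relation = x$island_relation[idx],
             stringsAsFactors = FALSE)
}

#' Probe positions as a GRanges
#'
#' Probe coordinates are stored 0-based; the returned GRanges uses the
#' 1-based closed convention, so a probe at 0-based position p becomes the
#' width-1 range \[p+1, p+1\]. With BED-derived tracks this reproduces the
#' half-open rule: the probe overlaps \[s, e) iff s <= p < e.
#'
#' @param x manifest data.frame or [MethylExperiment-class].
#' @return named [GenomicRanges::GRanges].
#' @export
probeGRanges <- function(x) {
  if (is(x, "MethylExperiment")) x <- probeAnnotation(x)
  gr <- GenomicRanges::GRanges(x$chrom,
                               IRanges::IRanges(x$pos + 1L, x$pos + 1L))
  names(gr) <- x$probe_id
  gr
}

#' Read a beta-value matrix
#'
#' TSV with probe ids in the first column (`probe_id`) and one numeric column
#' per sample. Values outside \[0, 1\] raise an error; they are never clipped
#' silently. `NA` handling is explicit: the default errors, `na = "drop"`
#' removes probes containing any missing value with a message.
#'
#' @param path file path.
#' @param manifest optional manifest data.frame; when given, every probe must
#'   be present in it.
#' @param na `"error"` (default) or `"drop"`.
#' @return numeric matrix, probes x samples.
#' @export
readBetaMatrix <- function(path, manifest = NULL, na = c("error", "drop")) {
  na <- match.arg(na)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (colnames(df)[1] != "probe_id")
    stop("beta matrix must have 'probe_id' as its first column")
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe ids in beta matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("beta matrix contains non-numeric values")
  rownames(m) <- df$probe_id
  if (anyNA(m)) {
    if (na == "error")
      stop("beta matrix contains missing values (use na = 'drop' to mask)")
    bad <- rowSums(is.na(m)) > 0
    message("dropping ", sum(bad), " probe(s) with missing beta values")
    m <- m[!bad, , drop = FALSE]
  }
  if (any(m < 0 | m > 1))
    stop("beta values outside [0, 1]; refusing to clip silently")
  if (!is.null(manifest)) {
    missing_probes <- setdiff(rownames(m), manifest$probe_id)
    if (length(missing_probes))
      stop("probes absent from manifest: ",
           paste(utils::head(missing_probes, 5), collapse = ", "))
  }
  m
}

#' Write a beta-value matrix with fixed 6-decimal formatting
#'
#' @param beta numeric matrix, probes x samples.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBetaMatrix <- function(beta, path) {
  out <- data.frame(probe_id = rownames(beta),
                    apply(beta, 2, function(x) sprintf("%.6f", x)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("probe_id", colnames(beta))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id` and `group`; groups are `ALK_POS`,
#' `ALK_NEG`, `CONTROL` or `REFERENCE_STAGE:<name>`.
#'
#' @param path file path.
#' @return named character vector mapping sample id to group.
#' @export
readSampleSheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(df)))
    stop("sample sheet needs 'sample_id' and 'group' columns")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample sheet")
  ok <- df$group %in% SAMPLE_GROUPS | startsWith(df$group, "REFERENCE_STAGE:")
  if (!all(ok))
    stop("unknown group label(s): ",
         paste(unique(df$group[!ok]), collapse = ", "))
  stats::setNames(df$group, df$sample_id)
}

#' @rdname readSampleSheet
#' @param groups named character vector (sample id -> group).
#' @param path output file path.
#' @export
writeSampleSheet <- function(groups, path) {
  utils::write.table(data.frame(sample_id = names(groups),
                                group = unname(groups)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-expression table (linear scale)
#'
#' TSV with `gene` in the first column and one positive numeric column per
#' sample. Duplicate genes and non-positive values are rejected.
#'
#' @param path file path.
#' @return numeric matrix, genes x samples.
#' @export
readExpressionTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (colnames(df)[1] != "gene")
    stop("expression table must have 'gene' as its first column")
  if (anyDuplicated(df$gene)) stop("duplicate gene rows in expression table")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  if (!is.numeric(m) || anyNA(m) || any(m <= 0))
    stop("expression values must be positive reals")
  m
}

#' @rdname readExpressionTable
#' @param expr numeric matrix, genes x samples.
#' @export
writeExpressionTable <- function(expr, path) {
  out <- data.frame(gene = rownames(expr),
                    apply(expr, 2, function(x) sprintf("%.6f", x)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("gene", colnames(expr))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED3+ interval track
#'
#' Intervals are BED-native 0-based half-open on disk and returned as a
#' [GenomicRanges::GRanges] (1-based closed, the equivalent encoding).
#' Overlapping intervals are preserved as read; merge with
#' [GenomicRanges::reduce()] when needed.
#'
#' @param path BED file path.
#' @return GRanges.
#' @export
readTrack <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(GenomicRanges::width(gr) < 1))
    stop("BED interval with start >= end in ", path)
  gr
}

#' @rdname readTrack
#' @param track GRanges to write.
#' @export
writeTrack <- function(track, path) {
  rtracklayer::export(track, path, format = "BED")
  invisible(path)
}
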