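#' MethylExperiment: beta-value matrix with probe annotation and sample groups
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single `"beta"` assay of methylation fractions in \[0, 1\], per-probe
#' annotation in `rowData` (chromosome, 0-based position, strand, gene,
#' region category, CpG-island relation) and the sample-to-group mapping in
#' `colData$group`.
#'
#' Genes and region categories may be ";"-joined on a probe (real 450K
#' manifests multi-map probes); [probeRegions()] expands them to one
#' (probe, gene, category) record each.
#'
#' @slot .. see \code{SummarizedExperiment}; no additional slots.
#' @export
setClass("MethylExperiment", contains = "SummarizedExperiment")

setValidity("MethylExperiment", function(object) {
  msg <- character(0)
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- SummarizedExperiment::assay(object, "beta")
    if (!all(is.finite(b)))
      msg <- c(msg, "beta values must be finite")
    else if (any(b < 0 | b > 1))
      msg <- c(msg, "beta values must lie in [0, 1]")
  }
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("chrom", "pos", "strand", "gene", "region_category",
            "island_relation")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData missing column(s): ",
                         paste(miss, collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids (rownames) must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a MethylExperiment
#'
#' @param beta numeric matrix of methylation fractions, probes x samples,
#'   with probe ids as rownames and sample ids as colnames.
#' @param annotation data.frame of probe annotation as returned by
#'   [readManifest()] (columns `probe_id`, `chrom`, `pos`, `strand`, `gene`,
#'   `region_category`, `island_relation`).
#' @param groups named character vector or data.frame mapping sample id to
#'   group label (e.g. `ALK_POS`, `ALK_NEG`, `CONTROL`,
#'   `REFERENCE_STAGE:<name>`).
#' @return a [MethylExperiment-class] object.
#' @examples
#' b <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' ann <- data.frame(probe_id = paste0("cg", 1:3), chrom = "chr1",
#'                   pos = c(100L, 200L, 300L), strand = "*",
#'                   gene = c("G1", "G1", ""),
#'                   region_category = c("TSS200", "Body", "Intergenic"),
#'                   island_relation = c("Island", "OpenSea", "OpenSea"))
#' me <- MethylExperiment(b, ann, c(s1 = "ALK_POS", s2 = "CONTROL"))
#' @export
MethylExperiment <- function(beta, annotation, groups) {
  beta <- as.matrix(beta)
  if (is.data.frame(groups))
    groups <- stats::setNames(as.character(groups$group), groups$sample_id)
  if (is.null(names(groups)))
    stop("'groups' must be named by sample id")
  missing_samples <- setdiff(colnames(beta), names(groups))
  if (length(missing_samples))
    stop("samples without a group: ", paste(missing_samples, collapse = ", "))
  ann <- annotation[match(rownames(beta), annotation$probe_id), , drop = FALSE]
  if (anyNA(ann$probe_id))
    stop("probes absent from the manifest: ",
         paste(utils::head(rownames(beta)[is.na(ann$probe_id)], 5),
               collapse = ", "))
  rd <- S4Vectors::DataFrame(ann[, setdiff(colnames(ann), "probe_id"),
                                 drop = FALSE])
  rownames(rd) <- rownames(beta)
  cd <- S4Vectors::DataFrame(group = unname(groups[colnames(beta)]),
                             row.names = colnames(beta))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = beta), rowData = rd, colData = cd)
  new("MethylExperiment", se)
}

#' @describeIn MethylExperiment the beta-value matrix.
#' @param object,x a `MethylExperiment`.
#' @export
betaValues <- function(object) {
  SummarizedExperiment::assay(object, "beta")
}

#' @describeIn MethylExperiment named character vector of sample groups.
#' @export
sampleGroups <- function(object) {
  stats::setNames(as.character(SummarizedExperiment::colData(object)$group),
                  colnames(object))
}

#' @describeIn MethylExperiment probe annotation as a data.frame with a
#'   `probe_id` column (";"-joined multi-mappings kept as-is).
#' @export
probeAnnotation <- function(object) {
  rd <- as.data.frame(SummarizedExperiment::rowData(object))
  cbind(probe_id = rownames(object), rd, row.names = NULL,
        stringsAsFactors = FALSE)
}

setMethod("show", "MethylExperiment", function(object) {
  groups <- table(sampleGroups(object))
  cat("MethylExperiment:", nrow(object), "probes x", ncol(object),
      "samples\n")
  cat("  groups:",
      paste(sprintf("%s (%d)", names(groups), groups), collapse = ", "),
      "\n")
})

#' CohortTruth: ground truth of a synthetic cohort
#'
#' Records which probes and regions carry spiked methylation effects, which
#' sequence windows carry the planted motif and which genes were generated
#' with expression coupled to promoter methylation, so recovery of every
#' downstream stage can be scored.
#'
#' @slot mvp data.frame: `probe_id`, `direction` (hyper/hypo with respect to
#'   tumor vs control), realised `delta` on the beta scale, and `affected`
#'   (comma-joined subset of ALK_POS,ALK_NEG).
#' @slot dmr data.frame: `region_id`, `category`, `direction`, `delta`,
#'   `affected`, `n_probes`.
#' @slot motif_windows character vector of window ids carrying the planted
#'   motif.
#' @slot concordant_genes character vector of genes whose expression was
#'   coupled to promoter methylation.
#' @export
setClass("CohortTruth",
  representation(mvp = "data.frame", dmr = "data.frame",
                 motif_windows = "character",
                 concordant_genes = "character"))

setValidity("CohortTruth", function(object) {
  msg <- character(0)
  if (nrow(object@mvp) &&
      !all(c("probe_id", "direction", "delta", "affected") %in%
           colnames(object@mvp)))
    msg <- c(msg, "mvp truth needs probe_id/direction/delta/affected")
  if (nrow(object@mvp) && any(abs(object@mvp$delta) > 1))
    msg <- c(msg, "|delta| must be <= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortTruth", function(object) {
  cat("CohortTruth:", nrow(object@mvp), "spiked probes,",
      nrow(object@dmr), "spiked regions,",
      length(object@motif_windows), "motif windows,",
      length(object@concordant_genes), "concordant genes\n")
})

#' @describeIn CohortTruth spiked-probe truth table.
#' @param object a `CohortTruth`.
#' @export
mvpTruth <- function(object) object@mvp

#' @describeIn CohortTruth spiked-region truth table.
#' @export
dmrTruth <- function(object) object@dmr

#' @describeIn CohortTruth window ids carrying the planted motif.
#' @export
motifTruth <- function(object) object@motif_windows

#' @describeIn CohortTruth genes with methylation-coupled expression.
#' @export
concordantGenes <- function(object) object@concordant_genes
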