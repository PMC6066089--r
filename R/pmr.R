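#' Relative template quantity from a qPCR Ct value
#'
#' `quantity = (1 + efficiency)^(-ct)`; at the default 100% efficiency this
#' is `2^(-ct)`. A no-amplification reaction (NA ct) has quantity 0.
#'
#' @param ct numeric Ct values; NA means no amplification.
#' @param efficiency amplification efficiency in (0, 1\], default 1.
#' @return relative quantities on a linear scale.
#' @export
quantityFromCt <- function(ct, efficiency = 1) {
  stopifnot(efficiency > 0, efficiency <= 1)
  q <- (1 + efficiency)^(-ct)
  q[is.na(ct)] <- 0
  q
}

#' Percentage of methylated reference (PMR)
#'
#' MethyLight quantification:
#' `PMR = 100 * [(GeneX mean)/(Alu mean)]_sample /
#'  [(GeneX mean)/(Alu mean)]_M.SssI`,
#' with means taken over replicate quantities on the linear scale. The
#' M.SssI-treated fully methylated DNA is the reference. PMR can exceed 100
#' (flagged, never clipped) and is exactly 0 when the sample GeneX reaction
#' has no amplification.
#'
#' @param sample_genex,sample_alu replicate quantities of the sample's
#'   gene-specific and Alu control reactions.
#' @param ref_genex,ref_alu same for the M.SssI reference.
#' @return one-row data.frame: `pmr`, `exceeds_100`.
#' @export
computePMR <- function(sample_genex, sample_alu, ref_genex, ref_alu) {
  if (mean(sample_alu) <= 0 || mean(ref_alu) <= 0)
    stop("Alu normalisation quantity must be > 0")
  if (mean(ref_genex) <= 0)
    stop("reference GeneX quantity must be > 0")
  pmr <- 100 * (mean(sample_genex) / mean(sample_alu)) /
    (mean(ref_genex) / mean(ref_alu))
  data.frame(pmr = pmr, exceeds_100 = pmr > 100)
}

#' Compute PMR for every sample/gene in a Ct table
#'
#' @param ct_table data.frame with columns `sample_id`, `group`, `assay`
#'   (gene name or `"Alu"`), `replicate`, `ct` (NA = no amplification);
#'   reference rows have `sample_id == ref_sample`.
#' @param ref_sample sample id of the M.SssI-treated reference, default
#'   `"M.SssI"`.
#' @param efficiency passed to [quantityFromCt()].
#' @return data.frame `sample_id`, `group`, `gene`, `pmr`, `exceeds_100`.
#' @export
pmrFromCtTable <- function(ct_table, ref_sample = "M.SssI", efficiency = 1) {
  genes <- setdiff(unique(ct_table$assay), "Alu")
  samples <- setdiff(unique(ct_table$sample_id), ref_sample)
  qty <- function(sid, assay) {
    ct <- ct_table$ct[ct_table$sample_id == sid & ct_table$assay == assay]
    if (!length(ct)) stop("missing reactions for ", sid, "/", assay)
    quantityFromCt(ct, efficiency)
  }
  do.call(rbind, lapply(genes, function(g) {
    rg <- qty(ref_sample, g); ra <- qty(ref_sample, "Alu")
    do.call(rbind, lapply(samples, function(s) {
      rec <- computePMR(qty(s, g), qty(s, "Alu"), rg, ra)
      grp <- unique(ct_table$group[ct_table$sample_id == s])
      cbind(data.frame(sample_id = s, group = grp[1], gene = g,
                       stringsAsFactors = FALSE), rec)
    }))
  }))
}

#' Compare PMR values across groups
#'
#' One-way ANOVA over all groups; when ANOVA p < `alpha`, pairwise Welch
#' (unpaired, unequal-variance) t-tests of each group against the control
#' group. Degenerate data (zero variance everywhere) reports p = 1 with a
#' flag. Group means +/- SEM are always reported.
#'
#' @param pmr data.frame with `pmr` and `group` columns (one gene).
#' @param control_group label of the control group.
#' @param alpha ANOVA gate for the pairwise tests, default 0.05.
#' @return list with `anova` (data.frame `F`, `p`, `zero_variance`),
#'   `pairwise` (data.frame `group`, `t`, `p`, or NULL if not gated in),
#'   `group_stats` (data.frame `group`, `n`, `mean`, `sem`).
#' @export
comparePMRGroups <- function(pmr, control_group, alpha = 0.05) {
  stopifnot(control_group %in% pmr$group)
  gs <- do.call(rbind, lapply(split(pmr$pmr, pmr$group), function(v)
    data.frame(n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)))))
  gs <- cbind(group = rownames(gs), gs, row.names = NULL,
              stringsAsFactors = FALSE)
  zero_var <- all(stats::ave(pmr$pmr, pmr$group,
                             FUN = function(v) v - mean(v)) == 0)
  if (zero_var) {
    an <- data.frame(F = NA_real_, p = 1, zero_variance = TRUE)
  } else {
    fit <- stats::anova(stats::lm(pmr ~ group, data = pmr))
    an <- data.frame(F = fit$`F value`[1], p = fit$`Pr(>F)`[1],
                     zero_variance = FALSE)
  }
  pairwise <- NULL
  if (!is.na(an$p) && an$p < alpha) {
    others <- setdiff(unique(pmr$group), control_group)
    ctrl <- pmr$pmr[pmr$group == control_group]
    pairwise <- do.call(rbind, lapply(others, function(g) {
      tt <- stats::t.test(pmr$pmr[pmr$group == g], ctrl)
      data.frame(group = g, t = unname(tt$statistic), p = tt$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(anova = an, pairwise = pairwise, group_stats = gs)
}
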