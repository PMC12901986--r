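#' Collapse qPCR replicates to mean Cq values
#'
#' Technical qPCR replicates of one cDNA are averaged per
#' (sample, target, primer end). Undetected replicates are dropped from the
#' mean (with a note in `n_dropped`); groups where no replicate was detected
#' are kept with `detected = FALSE` and `cq = NA`, and propagate as missing
#' downstream with a warning rather than being imputed.
#'
#' @param table a `"cq_table"` data.frame (`sample`, `target`, `primer_end`,
#'   `replicate`, `cq`, `detected`).
#' @return data.frame per (sample, target, primer_end) with `cq`, `detected`,
#'   `n_detected`, `n_dropped`.
#' @export
collapse_replicates <- function(table) {
  dt <- data.table::as.data.table(table)
  need <- c("sample", "target", "primer_end", "cq")
  if (!all(need %in% names(dt))) {
    stop("cq table needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(dt$detected)) dt[, detected := is.finite(cq)]
  out <- dt[, .(cq = if (any(detected)) mean(cq[detected]) else NA_real_,
                detected = any(detected),
                n_detected = sum(detected),
                n_dropped = sum(!detected)),
            by = .(sample, target, primer_end)]
  if (any(!out$detected)) {
    bad <- out[detected == FALSE]
    warning("no detected replicate for ",
            paste(sprintf("%s/%s/%s", bad$sample, bad$target, bad$primer_end),
                  collapse = "; "), "; excluded downstream")
  }
  as.data.frame(out)
}

#' 5'-3' dCq transcript-integrity statistic
#'
#' `dCq = Cq(5' amplicon) - Cq(3' amplicon)`. With oligo-dT-primed reverse
#' transcription, degradation disconnects 5' regions from the poly(A) tail and
#' inflates the 5' Cq, so dCq grows with degradation. Unlike the historical
#' 3'/5' Cq *ratio*, the difference is invariant to expression level: Cq pairs
#' (25, 20) and (30, 25) represent the same amount of degradation and give the
#' same dCq = 5, while their ratios differ.
#'
#' @param cq5,cq3 detected mean Cq values (vectorized).
#' @return `cq5 - cq3` in cycles.
#' @export
five_three_dcq <- function(cq5, cq3) {
  if (any(!is.finite(cq5)) || any(!is.finite(cq3))) {
    stop("dCq requires detected Cq values at both primer ends")
  }
  cq5 - cq3
}

#' 5'-3' ddCq relative to empty-transfection controls
#'
#' Subtracts the mean control dCq from each treatment dCq, so the empty
#' control condition sits at 0 by construction and positive values mean more
#' degradation than control. Also reports the condition mean and its standard
#' error.
#'
#' @param treatment_dcq numeric treatment dCq values.
#' @param control_dcq numeric dCq values of the empty transfection controls
#'   (at least one required).
#' @return list with `ddcq` (per treatment value), `mean`, `sem`.
#' @export
five_three_ddcq <- function(treatment_dcq, control_dcq) {
  if (length(control_dcq) < 1 || all(!is.finite(control_dcq))) {
    stop("empty transfection control required to anchor ddCq")
  }
  dd <- treatment_dcq - mean(control_dcq, na.rm = TRUE)
  list(ddcq = dd,
       mean = mean(dd, na.rm = TRUE),
       sem = if (sum(is.finite(dd)) > 1)
         stats::sd(dd, na.rm = TRUE) / sqrt(sum(is.finite(dd))) else NA_real_)
}

#' Full 5'-3' integrity analysis of a Cq table
#'
#' Collapses replicates, computes per-(sample, target) dCq, and anchors ddCq
#' to the mean dCq of the empty-control samples per target. Samples missing a
#' detected value at either end are dropped with a warning.
#'
#' @param table a `"cq_table"`.
#' @param sample_sheet data.frame (`sample`, `condition`, `is_empty_control`);
#'   taken from the table's `"sample_sheet"` attribute when omitted.
#' @return list with `per_sample` (sample, target, condition, dcq_53, ddcq_53)
#'   and `per_condition` (condition, target, mean ddCq, SEM, n).
#' @export
integrity_analysis <- function(table, sample_sheet = NULL) {
  if (is.null(sample_sheet)) sample_sheet <- attr(table, "sample_sheet")
  if (is.null(sample_sheet)) stop("a sample sheet is required")
  coll <- data.table::as.data.table(collapse_replicates(table))
  wide <- data.table::dcast(coll[detected == TRUE], sample + target ~ primer_end,
                            value.var = "cq")
  if (!all(c("5p", "3p") %in% names(wide))) {
    stop("both 5p and 3p primer ends are required")
  }
  missing_end <- wide[is.na(`5p`) | is.na(`3p`)]
  if (nrow(missing_end)) {
    warning("dropping sample/target with a missing primer end: ",
            paste(sprintf("%s/%s", missing_end$sample, missing_end$target),
                  collapse = "; "))
    wide <- wide[!is.na(`5p`) & !is.na(`3p`)]
  }
  wide[, dcq_53 := five_three_dcq(`5p`, `3p`)]
  ss <- data.table::as.data.table(sample_sheet)
  wide <- merge(wide, ss[, .(sample, condition, is_empty_control)], by = "sample")
  if (!any(wide$is_empty_control)) {
    stop("empty transfection control required (no sample flagged is_empty_control)")
  }
  wide[, ddcq_53 := dcq_53 - mean(dcq_53[is_empty_control]), by = target]
  per_cond <- wide[, .(ddcq_53 = mean(ddcq_53),
                       sem = if (.N > 1) stats::sd(ddcq_53) / sqrt(.N) else NA_real_,
                       n = .N),
                   by = .(condition, target)]
  list(per_sample = as.data.frame(
         wide[, .(sample, target, condition, is_empty_control, dcq_53, ddcq_53)]),
       per_condition = as.data.frame(per_cond))
}

#' Conventional relative expression by ddCq
#'
#' Standard ddCq with a reference (housekeeping) gene:
#' `dCq = Cq(target) - Cq(reference)` per sample, `ddCq = dCq - mean(control
#' dCq)`, fold change `2^(-ddCq)`.
#'
#' @param target_cq named numeric, per-sample mean Cq of the target gene.
#' @param reference_cq named numeric, per-sample mean Cq of the reference
#'   gene; must cover every sample in `target_cq`.
#' @param is_control logical, same order/names as `target_cq`.
#' @return data.frame per sample (`dcq`, `ddcq`, `fold_change`) plus condition
#'   means as attributes `mean_fold_change` (control and treatment).
#' @export
relative_expression_ddcq <- function(target_cq, reference_cq, is_control) {
  if (!all(names(target_cq) %in% names(reference_cq))) {
    stop("reference gene must be measured in every sample")
  }
  reference_cq <- reference_cq[names(target_cq)]
  if (any(!is.finite(reference_cq))) stop("reference gene must be measured in every sample")
  if (!any(is_control)) stop("at least one control sample required")
  dcq <- target_cq - reference_cq
  ddcq <- dcq - mean(dcq[is_control])
  out <- data.frame(sample = names(target_cq), dcq = unname(dcq),
                    ddcq = unname(ddcq), fold_change = unname(2^(-ddcq)),
                    is_control = is_control, stringsAsFactors = FALSE)
  attr(out, "mean_fold_change") <-
    c(control = mean(out$fold_change[is_control]),
      treatment = if (any(!is_control)) mean(out$fold_change[!is_control]) else NA_real_)
  out
}
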