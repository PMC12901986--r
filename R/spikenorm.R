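#' Spike-in size factors (median-of-ratios on spike-ins only)
#'
#' Because spike-ins are added at fixed mass after RNA isolation, their counts
#' track only the per-sample sequencing scale — never the biology — so a
#' median-of-ratios estimator restricted to spike-in rows yields size factors
#' that remain valid under global mRNA depletion, where whole-library
#' estimators are blind. The reference is the per-spike geometric mean across
#' samples over spikes nonzero in all samples; each sample's factor is the
#' median over those spikes of count / reference.
#'
#' @param counts a [simulate_count_matrix()] object, or a numeric matrix with
#'   `spike_in` supplied.
#' @param spike_in logical per-gene flag (rows of the matrix); ignored for
#'   `count_matrix` input.
#' @return named per-sample size factors.
#' @export
spikein_size_factors <- function(counts, spike_in = NULL) {
  m <- count_input(counts, spike_in)
  sp <- m$counts[m$spike_in, , drop = FALSE]
  if (nrow(sp) == 0) stop("no spike-in rows present")
  use <- rowSums(sp == 0) == 0
  if (sum(use) < 1) stop("no spike-in has nonzero counts in all samples")
  sp <- sp[use, , drop = FALSE]
  ref <- exp(rowMeans(log(sp)))
  apply(sp / ref, 2, stats::median)
}

count_input <- function(counts, spike_in = NULL, biotype = NULL) {
  if (inherits(counts, "count_matrix")) {
    list(counts = counts$counts, spike_in = counts$spike_in,
         biotype = counts$biotype, design = counts$design)
  } else {
    if (is.null(spike_in)) stop("spike_in flags required for matrix input")
    list(counts = as.matrix(counts), spike_in = spike_in, biotype = biotype,
         design = NULL)
  }
}

#' Divide each sample by its size factor
#'
#' @param counts matrix or [simulate_count_matrix()] object.
#' @param factors per-sample positive factors (named or in column order).
#' @return normalized numeric matrix.
#' @export
normalize_counts <- function(counts, factors) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (!is.null(names(factors))) factors <- factors[colnames(m)]
  if (length(factors) != ncol(m)) stop("one factor per sample required")
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    stop("size factors must be positive")
  }
  sweep(m, 2, factors, "/")
}

#' Per-gene fold changes under a two-group contrast
#'
#' Moderated ratio estimator on normalized counts:
#' `log2fc = log2((mean_targeting + pseudocount) / (mean_control +
#' pseudocount))`, with `base_mean` the mean normalized count over all contrast
#' samples. Spike-in rows are excluded (they carry no biology); genes below
#' `min_count` in every contrast sample are filtered out. This deliberately
#' replaces a full negative-binomial GLM: the quantities of interest here are
#' normalization geometry and residual selection, not shrunken test
#' statistics.
#'
#' @param normalized matrix of spike-normalized counts.
#' @param targeting,control character vectors of sample ids (disjoint,
#'   non-empty).
#' @param spike_in logical per-gene flag.
#' @param biotype optional per-gene biotype (carried through for filtering).
#' @param pseudocount added to both group means (default 0.5).
#' @param min_count keep genes reaching this normalized count in at least one
#'   contrast sample (default 5).
#' @return a `"fold_change_table"` data.frame: `gene`, `base_mean`, `log2fc`,
#'   `biotype`.
#' @export
fold_change_table <- function(normalized, targeting, control,
                              spike_in, biotype = NULL,
                              pseudocount = 0.5, min_count = 5) {
  if (length(targeting) == 0 || length(control) == 0) {
    stop("both contrast sample sets must be non-empty")
  }
  if (length(intersect(targeting, control)) > 0) {
    stop("targeting and control sample sets overlap")
  }
  if (!all(c(targeting, control) %in% colnames(normalized))) {
    stop("contrast samples missing from the matrix")
  }
  keep <- !spike_in
  m <- normalized[keep, c(targeting, control), drop = FALSE]
  bt <- if (is.null(biotype)) rep(NA_character_, nrow(m)) else biotype[keep]
  pass <- apply(m, 1, max) >= min_count
  m <- m[pass, , drop = FALSE]
  bt <- bt[pass]
  mt <- rowMeans(m[, targeting, drop = FALSE])
  mc <- rowMeans(m[, control, drop = FALSE])
  out <- data.frame(gene = rownames(m),
                    base_mean = rowMeans(m),
                    log2fc = log2((mt + pseudocount) / (mc + pseudocount)),
                    biotype = bt,
                    stringsAsFactors = FALSE)
  class(out) <- c("fold_change_table", "data.frame")
  out
}

#' Abundance-depletion regression
#'
#' Ordinary least squares of `log2fc` on `log10(base_mean)` over (by default)
#' protein-coding genes, modelling the observation that highly abundant
#' transcripts are more depleted by collateral cleavage. Residuals above the
#' line flag transcripts that are less sensitive to cleavage or actively
#' upregulated.
#'
#' @param table a [fold_change_table()].
#' @param biotypes biotype filter (`NULL` keeps all rows).
#' @param log_base predictor log base, 10 (default, matching a log-scaled
#'   base-mean axis) or 2.
#' @return a `"regression_selection"` list: `slope`, `intercept`, `table`
#'   (gene, base_mean, log2fc, residual), `log_base`.
#' @export
abundance_depletion_fit <- function(table, biotypes = "protein_coding",
                                    log_base = 10) {
  tb <- as.data.frame(table)
  if (!is.null(biotypes) && !all(is.na(tb$biotype))) {
    tb <- tb[tb$biotype %in% biotypes, , drop = FALSE]
  }
  tb <- tb[tb$base_mean > 0, , drop = FALSE]
  if (nrow(tb) < 3) stop("need at least 3 genes after filtering")
  x <- log(tb$base_mean, base = log_base)
  if (stats::var(x) == 0) stop("degenerate predictor: all base means equal")
  fit <- stats::lm.fit(cbind(1, x), tb$log2fc)
  tb$residual <- unname(fit$residuals)
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 table = tb, log_base = log_base),
            class = "regression_selection")
}

#' @export
print.regression_selection <- function(x, ...) {
  cat(sprintf("<regression_selection> log2fc = %.4f %+.4f * log%d(base_mean), %d genes\n",
              x$intercept, x$slope, x$log_base, nrow(x$table)))
  invisible(x)
}

#' Select transcripts above the depletion regression line
#'
#' Flags genes whose residual exceeds a timepoint-dependent threshold:
#' 1 log2FC at 50 min, 2 log2FC at 200 and 1440 min (overridable). Selected
#' genes are those escaping the global depletion trend — stress-response
#' induction or cleavage insensitivity.
#'
#' @param fit an [abundance_depletion_fit()].
#' @param timepoint 50, 200 or 1440 (min); ignored when `threshold` is given.
#' @param threshold explicit residual threshold in log2FC units.
#' @return list with `genes` (character), `threshold`, and `table` including a
#'   logical `selected` column.
#' @export
select_outlier_transcripts <- function(fit, timepoint = NULL, threshold = NULL) {
  stopifnot(inherits(fit, "regression_selection"))
  if (is.null(threshold)) {
    if (is.null(timepoint)) stop("provide a timepoint or an explicit threshold")
    thr_map <- c("50" = 1, "200" = 2, "1440" = 2)
    threshold <- thr_map[as.character(timepoint)]
    if (is.na(threshold)) {
      stop("no default threshold for timepoint ", timepoint,
           " min; pass threshold= explicitly")
    }
  }
  tb <- fit$table
  tb$selected <- tb$residual > threshold
  list(genes = tb$gene[tb$selected], threshold = unname(threshold), table = tb)
}
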