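#' Simulate a 5'/3' RT-qPCR Cq table
#'
#' Models oligo-dT-primed reverse transcription: a molecule templates an
#' amplicon only if it carries no cut anywhere between the amplicon's 5'
#' boundary and the transcript 3' end (a break disconnects the amplicon from
#' the poly(A) tail that primes cDNA synthesis). The quantification cycle is
#' `Cq = cq_intercept - log(template) / log(1 + E)` plus Gaussian noise on the
#' Cq scale. Two input routes are supported: a deterministic per-sample
#' specification of expected template loss (exact closed-form behaviour, used
#' by the oracle tests) or a [simulate_fragment_pool()] whose poly(A)-anchored
#' fragments are counted directly.
#'
#' @param samples data.frame with columns `sample`, `condition`,
#'   `is_empty_control`, `n_molecules`, `cut_fraction_between` (fraction of
#'   molecules cut between the 5' amplicon and the 3' amplicon) and optionally
#'   `cut_fraction_3p` (fraction cut between the 3' amplicon and the poly(A)
#'   tail, affecting both ends). Ignored when `pool` is given.
#' @param pool optional [simulate_fragment_pool()]; template counts are then
#'   the number of molecules whose poly(A)-bearing fragment spans the
#'   amplicon's 5' boundary.
#' @param assay list with `target_id`, `amplicon_5p`, `amplicon_3p` (0-based
#'   half-open intervals; the 3' amplicon must lie 3' of the 5' amplicon).
#' @param efficiency per-cycle amplification efficiency E, `0 < E <= 1`.
#' @param cq_intercept Cq of a single template molecule.
#' @param noise_sd Gaussian noise on the Cq scale (cycles), default 0.15.
#' @param n_replicates technical qPCR replicates per (sample, end).
#' @param sample_id sample name used with `pool` input.
#' @param condition,is_empty_control metadata used with `pool` input.
#' @param seed integer seed.
#' @return a `"cq_table"` data.frame with columns `sample`, `target`,
#'   `primer_end` (`"5p"`/`"3p"`), `replicate`, `cq`, `detected` (zero
#'   template is reported undetected with `cq = NA`), plus a `"sample_sheet"`
#'   attribute (sample, condition, is_empty_control).
#' @export
simulate_cq_table <- function(samples = NULL, pool = NULL, assay,
                              efficiency = 1, cq_intercept = 38,
                              noise_sd = 0.15, n_replicates = 3L,
                              sample_id = "S1", condition = "targeting",
                              is_empty_control = FALSE, seed = 1L) {
  if (efficiency <= 0 || efficiency > 1) stop("efficiency must satisfy 0 < E <= 1")
  validate_assay(assay)
  if (is.null(samples) == is.null(pool)) {
    stop("provide exactly one of 'samples' or 'pool'")
  }
  if (!is.null(pool)) {
    tm <- cq_templates_from_pool(pool, assay)
    samples <- data.frame(sample = sample_id, condition = condition,
                          is_empty_control = is_empty_control,
                          template_5p = tm[["5p"]], template_3p = tm[["3p"]],
                          stringsAsFactors = FALSE)
  } else {
    if (!all(c("sample", "n_molecules", "cut_fraction_between") %in% names(samples))) {
      stop("samples needs columns sample, n_molecules, cut_fraction_between")
    }
    if (is.null(samples$cut_fraction_3p)) samples$cut_fraction_3p <- 0
    if (is.null(samples$condition)) samples$condition <- samples$sample
    if (is.null(samples$is_empty_control)) samples$is_empty_control <- FALSE
    samples$template_3p <- samples$n_molecules * (1 - samples$cut_fraction_3p)
    samples$template_5p <- samples$template_3p * (1 - samples$cut_fraction_between)
  }

  long <- data.table::rbindlist(lapply(c("5p", "3p"), function(end) {
    data.table::data.table(
      sample = rep(samples$sample, each = n_replicates),
      target = assay$target_id,
      primer_end = end,
      replicate = rep(seq_len(n_replicates), nrow(samples)),
      template = rep(samples[[paste0("template_", end)]], each = n_replicates))
  }))
  with_seed(substream_seed(seed, "qpcr"), {
    long[, detected := template > 0]
    long[, cq := NA_real_]
    long[detected == TRUE,
         cq := cq_intercept - log(template) / log(1 + efficiency) +
           if (noise_sd > 0) stats::rnorm(.N, 0, noise_sd) else 0]
  })
  long[, template := NULL]
  out <- as.data.frame(long)
  class(out) <- c("cq_table", "data.frame")
  attr(out, "sample_sheet") <- unique(samples[, c("sample", "condition", "is_empty_control")])
  out
}

validate_assay <- function(assay) {
  stopifnot(all(c("target_id", "amplicon_5p", "amplicon_3p") %in% names(assay)))
  if (assay$amplicon_3p[1] < assay$amplicon_5p[2]) {
    stop("amplicon_3p must lie 3' of amplicon_5p")
  }
  invisible(assay)
}

#' Effective qPCR template counts from a fragment pool
#'
#' For each primer pair, counts molecules whose poly(A)-bearing fragment
#' (the only fragment reverse-transcribed by oligo-dT priming) extends 5' of
#' the amplicon start — i.e. molecules with no cut between the amplicon and
#' the transcript 3' end.
#'
#' @param pool a [simulate_fragment_pool()] result.
#' @param assay assay definition as in [simulate_cq_table()].
#' @return named numeric `c("5p" = , "3p" = )` template counts.
#' @export
cq_templates_from_pool <- function(pool, assay) {
  validate_assay(assay)
  dt <- data.table::as.data.table(pool)[transcript_id == assay$target_id &
                                          has_native_polyA == TRUE]
  c("5p" = sum(dt$start <= assay$amplicon_5p[1]),
    "3p" = sum(dt$start <= assay$amplicon_3p[1]))
}
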