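#' Simulate a gene-by-sample count matrix with spike-ins
#'
#' Counts are negative-binomial with mean
#' `abundance * library_scale * 2^(log2FC)` for cellular genes in treated
#' samples and `abundance * library_scale` otherwise; spike-in means are
#' `spike abundance * library_scale` in every sample — spike-ins are added
#' after RNA isolation and are never depleted, which is what makes them an
#' absolute normalization anchor. The expected per-gene depletion follows
#' `log2FC = a + b * log10(abundance) + class_offset + gene_offset`, applied
#' only to biotypes listed in `affected_biotypes` (mitochondrial mRNAs and
#' nuclear ncRNAs are unaffected by default, as is the spike class always).
#'
#' @param tx a [build_transcriptome()] object.
#' @param depletion_spec list with elements `intercept` (a), `abundance_slope`
#'   (b, log2FC per log10 abundance), `class_offsets` (named numeric),
#'   `gene_offsets` (named numeric, per transcript id), and
#'   `affected_biotypes` (character).
#' @param design data.frame with columns `sample`, `condition`
#'   (one of untreated/empty/non_targeting/targeting) and optionally
#'   `timepoint`; `condition == "targeting"` receives the depletion.
#' @param library_scales per-sample positive factors (named by sample or in
#'   design order); default all 1.
#' @param dispersion negative-binomial dispersion (> 0); variance is
#'   `mu + dispersion * mu^2`.
#' @param seed integer seed.
#' @return an object of class `"count_matrix"`: list with `counts` (integer
#'   matrix genes x samples), `spike_in` (logical per gene), `design`,
#'   `library_scales`, and `true_log2fc` (expected per-gene log2FC in the
#'   targeting condition).
#' @export
simulate_count_matrix <- function(tx,
                                  depletion_spec = list(intercept = -1,
                                                        abundance_slope = 0,
                                                        class_offsets = NULL,
                                                        gene_offsets = NULL,
                                                        affected_biotypes = "protein_coding"),
                                  design,
                                  library_scales = NULL,
                                  dispersion = 0.05,
                                  seed = 1L) {
  stopifnot(inherits(tx, "transcriptome"))
  if (!all(c("sample", "condition") %in% names(design))) {
    stop("design needs 'sample' and 'condition' columns")
  }
  if (anyDuplicated(design$sample)) stop("sample ids must be unique")
  if (dispersion <= 0) stop("dispersion must be > 0")
  ns <- nrow(design)
  if (is.null(library_scales)) library_scales <- rep(1, ns)
  if (!is.null(names(library_scales))) library_scales <- library_scales[design$sample]
  if (any(!is.finite(library_scales)) || any(library_scales <= 0)) {
    stop("library_scales must be > 0 for every sample")
  }

  t <- tx$transcripts
  spec <- utils::modifyList(
    list(intercept = -1, abundance_slope = 0, class_offsets = NULL,
         gene_offsets = NULL, affected_biotypes = "protein_coding"),
    depletion_spec[!vapply(depletion_spec, is.null, logical(1))])

  lfc <- spec$intercept +
    spec$abundance_slope * log10(pmax(t$abundance, .Machine$double.eps))
  if (!is.null(spec$class_offsets)) {
    off <- spec$class_offsets[t$biotype]
    off[is.na(off)] <- 0
    lfc <- lfc + off
  }
  if (!is.null(spec$gene_offsets)) {
    off <- spec$gene_offsets[t$id]
    off[is.na(off)] <- 0
    lfc <- lfc + off
  }
  lfc[!(t$biotype %in% spec$affected_biotypes)] <- 0
  lfc[t$biotype == "spike_in"] <- 0   # spikes are never depleted

  treated <- design$condition == "targeting"
  mu <- outer(t$abundance, library_scales) *
    2^(outer(lfc, as.numeric(treated)))
  dimnames(mu) <- list(t$id, design$sample)
  with_seed(substream_seed(seed, "counts"), {
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     nrow = nrow(t), dimnames = list(t$id, design$sample))
  })
  structure(list(counts = counts,
                 spike_in = setNames(t$biotype == "spike_in", t$id),
                 biotype = setNames(t$biotype, t$id),
                 design = design,
                 library_scales = setNames(library_scales, design$sample),
                 true_log2fc = setNames(lfc, t$id),
                 true_means = mu),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " genes (", sum(x$spike_in),
      " spike-ins) x ", ncol(x$counts), " samples\n", sep = "")
  invisible(x)
}
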