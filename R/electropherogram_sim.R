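#' Simulate an electropherogram trace from a fragment pool
#'
#' The trace is a sum of Gaussian peaks in log10 fragment size, one per
#' distinct fragment length (mass-weighted: a fragment of length L contributes
#' L mass units) plus fixed ribosomal RNA peaks. Peak mass integrates to the
#' contributing RNA mass on the size axis, so total trace AUC is proportional
#' to total RNA mass. Degradation therefore moves mass out of the full-length
#' and rRNA peaks into a sub-18S smear, exactly the signature quantified by
#' [region_auc()].
#'
#' @param pool a [simulate_fragment_pool()] result.
#' @param rRNA_peaks data.frame with columns `size` (nt) and `mass`
#'   (same units as fragment mass); `NULL` uses 18S at 1900 nt and 28S at
#'   4700 nt with masses 2x and 4x the fragment-pool mass (intact total RNA is
#'   rRNA-dominated).
#' @param peak_width Gaussian sd in log10 size units.
#' @param grid strictly increasing size axis (nt).
#' @param noise_sd additive Gaussian noise on the fluorescence axis.
#' @param sample_id sample name carried on the trace.
#' @param seed integer seed (only used when `noise_sd > 0`).
#' @return an `"electropherogram"` data.frame with columns `size_nt`,
#'   `fluorescence` and a `sample_id` attribute.
#' @export
simulate_electropherogram <- function(pool, rRNA_peaks = NULL,
                                      peak_width = 0.04,
                                      grid = seq(50, 6000, by = 10),
                                      noise_sd = 0, sample_id = "S1",
                                      seed = 1L) {
  if (length(grid) < 2 || any(diff(grid) <= 0)) {
    stop("grid must be a strictly increasing size axis with >= 2 points")
  }
  dt <- data.table::as.data.table(pool)
  lens <- dt[, .N, by = .(len = end - start)]
  pool_mass <- sum(as.numeric(lens$len) * lens$N)
  if (is.null(rRNA_peaks)) {
    rRNA_peaks <- data.frame(size = c(1900, 4700),
                             mass = c(2, 4) * max(pool_mass, 1))
  }
  peaks <- rbind(
    if (nrow(lens)) data.frame(size = lens$len, mass = as.numeric(lens$len) * lens$N)
    else NULL,
    rRNA_peaks[, c("size", "mass")])

  fl <- numeric(length(grid))
  lg <- log10(grid)
  jacobian <- grid * log(10)   # d(log10 s)/ds^-1: converts log-size density to size axis
  for (i in seq_len(nrow(peaks))) {
    fl <- fl + peaks$mass[i] *
      stats::dnorm(lg, mean = log10(peaks$size[i]), sd = peak_width) / jacobian
  }
  if (noise_sd > 0) {
    with_seed(substream_seed(seed, "trace"), {
      fl <- pmax(fl + stats::rnorm(length(fl), 0, noise_sd), 0)
    })
  }
  electropherogram(grid, fl, sample_id)
}

#' Construct an electropherogram object
#'
#' @param size_nt strictly increasing fragment-size axis (nt).
#' @param fluorescence finite fluorescence values, same length.
#' @param sample_id sample name.
#' @return an `"electropherogram"` data.frame.
#' @export
electropherogram <- function(size_nt, fluorescence, sample_id = "S1") {
  if (length(size_nt) != length(fluorescence) || length(size_nt) < 2) {
    stop("size and fluorescence axes must have equal length >= 2")
  }
  if (any(diff(size_nt) <= 0)) stop("size axis must be strictly increasing")
  if (any(!is.finite(fluorescence))) stop("fluorescence must be finite")
  out <- data.frame(size_nt = size_nt, fluorescence = fluorescence)
  class(out) <- c("electropherogram", "data.frame")
  attr(out, "sample_id") <- sample_id
  out
}
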