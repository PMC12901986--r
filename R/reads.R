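#' Simulate long-read transcript-space alignments from a fragment pool
#'
#' Each fragment yields a Poisson(`depth`) number of reads: every fragment is
#' polyadenylated before reverse transcription, so sequencing samples
#' fragments by molar count, not by mass. A read spans its whole fragment with
#' probability `full_length_prob`; otherwise it is 5'- or
#' 3'-truncated (equal odds) by a uniform fraction of the fragment length.
#' Fragment termini created by a cleavage event are additionally
#' under-represented: a cut-created 5' end loses `cut_end_trim_5p` nt and a
#' cut-created 3' end loses `cut_end_trim_3p` nt (discrete uniform ranges).
#' This asymmetry — the downstream fragment's new 5' end recovers poorly while
#' the upstream fragment's new 3' end is rescued by polyadenylation — is what
#' produces the 10-20 nt coverage dips whose 5' boundary sits at the cleaved
#' uracil (see the methods vignette). Native transcript ends are untouched.
#' All records are primary, forward-strand, transcript-space.
#'
#' @param pool a [simulate_fragment_pool()] result (empty pools yield an empty
#'   alignment set with a warning).
#' @param depth mean reads per fragment (> 0).
#' @param full_length_prob probability a read spans its whole fragment.
#' @param truncation_frac_range uniform range of the truncated fraction.
#' @param cut_end_trim_5p,cut_end_trim_3p integer ranges of nt removed at
#'   cut-created fragment ends.
#' @param min_read_length reads shorter than this are dropped (unsequenceable).
#' @param seed integer seed.
#' @return an object of class `"alignment_set"`: a data.table with columns
#'   `read_id`, `transcript_id`, `tstart`, `tend` (0-based half-open),
#'   `is_primary`, `mapq`, `strand`; transcript lengths attached as the
#'   `"transcript_lengths"` attribute.
#' @export
simulate_read_alignments <- function(pool, depth = 1,
                                     full_length_prob = 0.97,
                                     truncation_frac_range = c(0.1, 0.5),
                                     cut_end_trim_5p = c(8L, 20L),
                                     cut_end_trim_3p = c(0L, 2L),
                                     min_read_length = 30L,
                                     seed = 1L) {
  if (depth <= 0) stop("depth must be > 0")
  lens <- attr(pool, "transcript_lengths")
  fr <- data.table::as.data.table(pool)
  if (nrow(fr) == 0) {
    warning("empty fragment pool: returning an empty alignment set")
    return(new_alignment_set(data.table::data.table(
      read_id = character(0), transcript_id = character(0),
      tstart = integer(0), tend = integer(0), is_primary = logical(0),
      mapq = integer(0), strand = character(0)), lens))
  }
  with_seed(substream_seed(seed, "reads"), {
    nreads <- stats::rpois(nrow(fr), depth)
    idx <- rep(seq_len(nrow(fr)), nreads)
    n <- length(idx)
    if (n == 0) {
      warning("no reads emitted at this depth")
      return(new_alignment_set(data.table::data.table(
        read_id = character(0), transcript_id = character(0),
        tstart = integer(0), tend = integer(0), is_primary = logical(0),
        mapq = integer(0), strand = character(0)), lens))
    }
    s <- fr$start[idx]
    e <- fr$end[idx]
    L <- lens[fr$transcript_id[idx]]
    # under-representation at cut-created ends
    cut5 <- s > 0L
    cut3 <- e < L
    s <- s + ifelse(cut5, r_discrete_unif(n, cut_end_trim_5p), 0L)
    e <- e - ifelse(cut3, r_discrete_unif(n, cut_end_trim_3p), 0L)
    # read-level truncation
    trunc <- stats::runif(n) >= full_length_prob
    side5 <- stats::runif(n) < 0.5
    frac <- stats::runif(n, truncation_frac_range[1], truncation_frac_range[2])
    cutlen <- as.integer(floor(frac * pmax(e - s, 0L)))
    s <- s + ifelse(trunc & side5, cutlen, 0L)
    e <- e - ifelse(trunc & !side5, cutlen, 0L)
    keep <- (e - s) >= min_read_length
    aln <- data.table::data.table(
      read_id = sprintf("read%07d", seq_len(sum(keep))),
      transcript_id = fr$transcript_id[idx][keep],
      tstart = as.integer(s[keep]), tend = as.integer(e[keep]),
      is_primary = TRUE, mapq = 60L, strand = "+")
  })
  new_alignment_set(aln, lens)
}

r_discrete_unif <- function(n, range) {
  if (range[1] == range[2]) return(rep(as.integer(range[1]), n))
  as.integer(range[1] + floor(stats::runif(n) * (range[2] - range[1] + 1L)))
}

new_alignment_set <- function(dt, transcript_lengths) {
  data.table::setattr(dt, "class", c("alignment_set", class(dt)))
  data.table::setattr(dt, "transcript_lengths", transcript_lengths)
  dt
}

#' @export
print.alignment_set <- function(x, ...) {
  cat("<alignment_set> ", nrow(x), " primary records on ",
      length(unique(x$transcript_id)), " transcripts\n", sep = "")
  invisible(x)
}
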