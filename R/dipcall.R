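#' Per-transcript coverage profile from primary alignments
#'
#' `depth[i]` counts primary records with `tstart <= i < tend` (0-based);
#' relative depth is depth divided by its mean over the transcript, so a
#' uniformly covered transcript sits at 1 everywhere and localized cleavage
#' shows as dips below 1.
#'
#' @param alignments an `"alignment_set"` (secondary/supplementary records are
#'   assumed already dropped on input).
#' @param transcript_id transcript to profile.
#' @param min_reads transcripts with fewer reads are flagged uncovered.
#' @return a `"coverage_profile"` list: `transcript_id`, `depth` (integer per
#'   position), `relative` (depth / mean depth), `n_reads`, `mean_depth`,
#'   `covered` (n_reads >= min_reads).
#' @export
transcript_coverage <- function(alignments, transcript_id, min_reads = 1L) {
  lens <- attr(alignments, "transcript_lengths")
  L <- unname(lens[transcript_id])
  if (length(L) != 1 || is.na(L)) stop("unknown transcript id: ", transcript_id)
  tid <- transcript_id
  dt <- data.table::as.data.table(alignments)[
    transcript_id == tid & is_primary == TRUE]
  depth <- integer(L)
  if (nrow(dt) > 0) {
    # +1 at each tstart, -1 at each tend (half-open), cumulated along the axis
    starts <- tabulate(dt$tstart + 1L, nbins = L)
    ends <- tabulate(dt$tend, nbins = L)
    depth <- as.integer(cumsum(starts) - cumsum(c(0L, utils::head(ends, -1L))))
  }
  md <- mean(depth)
  structure(list(transcript_id = transcript_id,
                 depth = depth,
                 relative = if (md > 0) depth / md else rep(NA_real_, L),
                 n_reads = nrow(dt),
                 mean_depth = md,
                 covered = nrow(dt) >= min_reads),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s: %d reads, mean depth %.1f over %d nt\n",
              x$transcript_id, x$n_reads, x$mean_depth, length(x$depth)))
  invisible(x)
}

#' Detect cleavage-associated coverage dips
#'
#' After running-median smoothing, a dip is a maximal run of positions where
#' smoothed depth falls below `depth_ratio_threshold` times the local baseline
#' (median of `baseline_window` positions flanking the run on each side).
#' Candidate runs closer than 3 positions are merged before the width test;
#' surviving runs must have width within `width_range` and lie at least
#' `edge_exclusion` nt from the transcript ends (coverage decays at ends for
#' library-preparation reasons unrelated to cleavage). Defaults bracket the
#' empirically observed 10-20 nt dip width with slack.
#'
#' @param profile a [transcript_coverage()].
#' @param smooth_window running-median window (odd, nt).
#' @param baseline_window flanking window per side used for the local baseline.
#' @param depth_ratio_threshold dip depth relative to baseline (default 0.5).
#' @param width_range admissible dip widths `c(min, max)` in nt.
#' @param edge_exclusion nt excluded at each transcript end.
#' @param min_mean_depth transcripts below this mean depth are skipped.
#' @param merge_gap runs separated by fewer positions than this are merged.
#' @return data.frame of dip calls: `transcript_id`, `start`, `end` (0-based
#'   half-open), `depth_ratio` (dip minimum / local baseline), `baseline`.
#' @export
detect_dips <- function(profile,
                        smooth_window = 5L,
                        baseline_window = 50L,
                        depth_ratio_threshold = 0.5,
                        width_range = c(8L, 30L),
                        edge_exclusion = 25L,
                        min_mean_depth = 20,
                        merge_gap = 3L) {
  empty <- data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), depth_ratio = numeric(0),
                      baseline = numeric(0), stringsAsFactors = FALSE)
  d <- profile$depth
  L <- length(d)
  if (profile$mean_depth < min_mean_depth) {
    message("skipping ", profile$transcript_id, ": mean depth ",
            round(profile$mean_depth, 1), " < ", min_mean_depth)
    return(empty)
  }
  sm <- as.numeric(stats::runmed(d, k = smoo_odd(smooth_window, L), endrule = "median"))

  # candidate positions against a wide rolling-median background
  bgk <- background_window_k(baseline_window, L)
  bg <- as.numeric(stats::runmed(sm, k = bgk, endrule = "median"))
  cand <- sm < depth_ratio_threshold * bg
  runs <- runs_from_logical(cand)
  if (nrow(runs) == 0) return(empty)
  runs <- merge_runs(runs, merge_gap)

  calls <- list()
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]; e <- runs$end[i]     # 1-based inclusive
    base <- local_baseline(sm, s, e, baseline_window)
    if (!is.finite(base) || base <= 0) next
    # refine to the maximal run below threshold x flanking baseline
    below <- sm < depth_ratio_threshold * base
    lo <- which.min(sm[s:e]) + s - 1L
    if (!below[lo]) next
    s2 <- lo; while (s2 > 1L && below[s2 - 1L]) s2 <- s2 - 1L
    e2 <- lo; while (e2 < L && below[e2 + 1L]) e2 <- e2 + 1L
    w <- e2 - s2 + 1L
    if (w < width_range[1] || w > width_range[2]) next
    if ((s2 - 1L) < edge_exclusion || (L - e2) < edge_exclusion) next
    calls[[length(calls) + 1L]] <- data.frame(
      transcript_id = profile$transcript_id,
      start = s2 - 1L, end = e2,            # to 0-based half-open
      depth_ratio = min(sm[s2:e2]) / base,
      baseline = base, stringsAsFactors = FALSE)
  }
  if (length(calls) == 0) return(empty)
  out <- unique(do.call(rbind, calls))
  out[order(out$start), , drop = FALSE]
}

background_window_k <- function(baseline_window, L) {
  k <- 2L * baseline_window + 1L
  if (k > L) k <- if (L %% 2L == 1L) L else L - 1L
  max(k, 3L)
}

smoo_odd <- function(k, L) {
  if (k %% 2L == 0L) k <- k + 1L
  min(k, if (L %% 2L == 1L) L else L - 1L)
}

runs_from_logical <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

merge_runs <- function(runs, gap) {
  if (nrow(runs) <= 1) return(runs)
  out <- runs[1, , drop = FALSE]
  for (i in 2:nrow(runs)) {
    if (runs$start[i] - out$end[nrow(out)] - 1L < gap) {
      out$end[nrow(out)] <- runs$end[i]
    } else {
      out <- rbind(out, runs[i, , drop = FALSE])
    }
  }
  out
}

local_baseline <- function(sm, s, e, bw) {
  L <- length(sm)
  left <- sm[max(1L, s - bw):max(1L, s - 1L)]
  if (s == 1L) left <- numeric(0)
  right <- if (e >= L) numeric(0) else sm[min(L, e + 1L):min(L, e + bw)]
  stats::median(c(left, right))
}

#' Assign cleavage positions to coverage dips
#'
#' The cleaved uracil is taken as the U closest to the dip's 5' boundary,
#' searching positions inside the dip and up to `upstream_search` nt 5' of it;
#' equidistant interior/upstream candidates resolve to the upstream one (the
#' cut is 3' of the U, so the U itself sits just outside the lost region).
#' Dips with no U in the window are kept with an absent position.
#'
#' @param dips a [detect_dips()] data.frame (possibly for many transcripts).
#' @param sequences named character of transcript sequences (RNA alphabet).
#' @param upstream_search nt searched 5' of the dip start (default 5).
#' @return the dip table with added columns `position` (0-based U index or
#'   NA), `dinucleotide` (context at (0, +1)), `context` (sequence window).
#' @export
assign_cleavage_sites <- function(dips, sequences, upstream_search = 5L) {
  n <- nrow(dips)
  pos <- rep(NA_integer_, n)
  dinuc <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    seqc <- strsplit(sequences[[dips$transcript_id[i]]], "", fixed = TRUE)[[1]]
    if (length(seqc) == 0) next
    s0 <- dips$start[i]                       # 0-based dip start
    win <- seq.int(max(0L, s0 - upstream_search), dips$end[i] - 1L)
    cand <- win[seqc[win + 1L] == "U"]
    if (length(cand) == 0) next
    dist <- abs(cand - s0)
    best <- cand[order(dist, cand)][1L]       # tie -> smaller index = upstream
    pos[i] <- best
    dinuc[i] <- paste0("U", if (best + 2L <= length(seqc)) seqc[best + 2L] else "")
  }
  dips$position <- pos
  dips$dinucleotide <- dinuc
  dips
}

#' Position frequency matrix and logo statistics around assigned sites
#'
#' Aligns sequence windows `[-flank, +flank]` around each assigned cleavage
#' position (position 0 is the U; windows extending past transcript ends are
#' excluded), and summarizes base composition per position, per-position
#' information content (`2 - Shannon entropy`, bits; no small-sample
#' correction unless requested) and the dinucleotide table at (0, +1).
#'
#' @param calls an [assign_cleavage_sites()] table (rows with `position` NA
#'   are ignored).
#' @param sequences named character of transcript sequences.
#' @param flank window half-width (default 5 nt).
#' @param small_sample_correction subtract the e(n) correction from the IC.
#' @return a `"context_summary"` list: `pfm` (4 x (2*flank+1), columns sum to
#'   1), `information` (bits per position), `dinucleotides` (named counts),
#'   `n_sites`.
#' @export
cleavage_context_pfm <- function(calls, sequences, flank = 5L,
                                 small_sample_correction = FALSE) {
  ok <- !is.na(calls$position)
  if (!any(ok)) stop("no assigned cleavage sites")
  calls <- calls[ok, , drop = FALSE]
  alphabet <- c("A", "C", "G", "U")
  width <- 2L * flank + 1L
  pfm <- matrix(0, nrow = 4, ncol = width,
                dimnames = list(alphabet, as.character(seq(-flank, flank))))
  dinucs <- character(0)
  n_used <- 0L
  for (i in seq_len(nrow(calls))) {
    seqc <- strsplit(sequences[[calls$transcript_id[i]]], "", fixed = TRUE)[[1]]
    p <- calls$position[i]
    if (p - flank < 0L || p + flank > length(seqc) - 1L) next  # truncated window
    win <- seqc[(p - flank):(p + flank) + 1L]
    m <- match(win, alphabet)
    pfm[cbind(m, seq_len(width))] <- pfm[cbind(m, seq_len(width))] + 1
    dinucs <- c(dinucs, paste0(win[flank + 1L], win[flank + 2L]))
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no assigned site has a full context window")
  counts <- pfm
  pfm <- sweep(pfm, 2, colSums(pfm), "/")
  ent <- apply(pfm, 2, function(p) {
    p <- p[p > 0]; -sum(p * log2(p))
  })
  ic <- 2 - ent
  if (small_sample_correction) ic <- pmax(ic - 3 / (2 * log(2) * n_used), 0)
  dn <- table(factor(dinucs, levels = paste0("U", alphabet)))
  structure(list(pfm = pfm, counts = counts, information = ic,
                 dinucleotides = setNames(as.integer(dn), names(dn)),
                 n_sites = n_used),
            class = "context_summary")
}

#' @export
print.context_summary <- function(x, ...) {
  us <- sum(x$dinucleotides[c("UC", "UG")]) / max(sum(x$dinucleotides), 1)
  cat(sprintf("<context_summary> %d sites, US fraction %.2f, IC(0) %.2f bits\n",
              x$n_sites, us, x$information[["0"]]))
  invisible(x)
}

#' Mapped-length statistics of an alignment set
#'
#' Per-read mapped length, reference transcript length and their ratio, with a
#' summary (median ratio and full-length fraction at ratio >= `full_cutoff`).
#' Transcripts in `exclusions` are removed before summarizing (extremely
#' abundant outliers such as histone transcripts distort the density
#' otherwise).
#'
#' @param alignments an `"alignment_set"`.
#' @param transcript_lengths named lengths; defaults to the attribute carried
#'   by the alignment set.
#' @param exclusions transcript ids to drop.
#' @param full_cutoff ratio above which a read counts as full length.
#' @return list with `per_read` (data.frame: read_id, transcript_id,
#'   mapped_length, reference_length, ratio) and `summary` (median_ratio,
#'   full_length_fraction, n_reads).
#' @export
mapped_length_stats <- function(alignments, transcript_lengths = NULL,
                                exclusions = character(0), full_cutoff = 0.9) {
  if (is.null(transcript_lengths)) {
    transcript_lengths <- attr(alignments, "transcript_lengths")
  }
  dt <- data.table::as.data.table(alignments)[is_primary == TRUE]
  dt <- dt[!transcript_id %in% exclusions]
  if (nrow(dt) > 0 && any(!dt$transcript_id %in% names(transcript_lengths))) {
    stop("lengths unknown for some retained transcripts")
  }
  per <- data.frame(read_id = dt$read_id,
                    transcript_id = dt$transcript_id,
                    mapped_length = dt$tend - dt$tstart,
                    reference_length = unname(transcript_lengths[dt$transcript_id]),
                    stringsAsFactors = FALSE)
  per$ratio <- per$mapped_length / per$reference_length
  list(per_read = per,
       summary = list(median_ratio = stats::median(per$ratio),
                      full_length_fraction = mean(per$ratio >= full_cutoff),
                      n_reads = nrow(per)))
}

#' Run the dip-calling pipeline over all transcripts
#'
#' Convenience wrapper: coverage, dip detection and cleavage-position
#' assignment for every transcript in an alignment set.
#'
#' @param alignments an `"alignment_set"`.
#' @param sequences named transcript sequences (for position assignment);
#'   `NULL` skips assignment.
#' @param ... knobs forwarded to [detect_dips()].
#' @param upstream_search forwarded to [assign_cleavage_sites()].
#' @return data.frame of dip calls across transcripts (zero rows if none).
#' @export
call_cleavage_dips <- function(alignments, sequences = NULL,
                               upstream_search = 5L, ...) {
  ids <- unique(alignments$transcript_id)
  calls <- lapply(ids, function(id) {
    prof <- transcript_coverage(alignments, id)
    detect_dips(prof, ...)
  })
  out <- do.call(rbind, c(calls, list(make.row.names = FALSE)))
  if (is.null(out) || nrow(out) == 0) {
    out <- data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), depth_ratio = numeric(0),
                      baseline = numeric(0), stringsAsFactors = FALSE)
  }
  if (!is.null(sequences) && nrow(out) > 0) {
    out <- assign_cleavage_sites(out, sequences, upstream_search)
  }
  out[order(out$transcript_id, out$start), , drop = FALSE]
}
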