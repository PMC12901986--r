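#' Simulate a collateral-cleavage fragment pool
#'
#' Draws molecules per transcript (Poisson with mean
#' `abundance * n_molecules_scale`), cuts each planted site independently with
#' probability `1 - exp(-A(t) * weight * class_multiplier * abundance_term)`
#' where `abundance_term = (abundance / median non-spike abundance)^slope`,
#' optionally adds a guide-directed cut on the target transcript (probability
#' `target_hazard`, active from t = 0), and partitions every molecule at its
#' realized cut positions. A cut at uracil index `p` places the fragment
#' boundary at `p + 1` (immediately 3' of the U), so fragment lengths always
#' sum to the transcript length.
#'
#' @param tx a [build_transcriptome()] object.
#' @param sites site annotation from [plant_cleavage_sites()] or
#'   [manual_sites()].
#' @param model a [cleavage_model()]; `timepoint` must appear in its
#'   activation curve.
#' @param timepoint minutes after delivery.
#' @param n_molecules_scale multiplier on abundance for the molecule draw.
#' @param seed integer seed.
#' @return an object of class `"fragment_pool"`: a data.table with columns
#'   `transcript_id`, `molecule` (integer, per transcript), `start`, `end`
#'   (0-based half-open), `has_native_polyA` (TRUE iff `end` equals the
#'   transcript length); attributes record the timepoint, seed, per-transcript
#'   molecule counts and realized cut counts per site.
#' @export
simulate_fragment_pool <- function(tx, sites, model, timepoint,
                                   n_molecules_scale = 1, seed = 1L) {
  stopifnot(inherits(tx, "transcriptome"), inherits(model, "cleavage_model"))
  A <- activation_at(model, timepoint)
  t <- tx$transcripts
  nonspike <- t$abundance[t$biotype != "spike_in"]
  ref <- stats::median(nonspike[nonspike > 0])
  if (!is.finite(ref) || ref <= 0) ref <- 1

  frags <- vector("list", nrow(t))
  n_mol <- integer(nrow(t))
  cut_counts <- vector("list", nrow(t))

  with_seed(substream_seed(seed, paste0("fragments@", timepoint)), {
    for (i in seq_len(nrow(t))) {
      L <- t$length[i]
      n <- stats::rpois(1L, t$abundance[i] * n_molecules_scale)
      n_mol[i] <- n
      if (n == 0) {
        frags[[i]] <- data.table::data.table(
          transcript_id = character(0), molecule = integer(0),
          start = integer(0), end = integer(0))
        next
      }
      st <- sites[[t$id[i]]]
      mult <- model$class_multipliers[[t$biotype[i]]]
      if (is.null(mult) || is.na(mult)) mult <- 0
      aterm <- (t$abundance[i] / ref)^model$abundance_slope

      cut_mol <- integer(0); cut_b <- integer(0)
      k <- if (is.null(st)) 0L else nrow(st)
      if (k > 0 && mult > 0 && A > 0) {
        p <- 1 - exp(-A * st$weight * mult * aterm)
        hit <- matrix(stats::runif(n * k), n, k) <
          matrix(p, n, k, byrow = TRUE)
        idx <- which(hit, arr.ind = TRUE)
        cut_mol <- idx[, 1L]
        cut_b <- st$position[idx[, 2L]] + 1L
        cut_counts[[i]] <- colSums(hit)
      } else if (k > 0) {
        cut_counts[[i]] <- rep(0L, k)
      }
      if (!is.null(model$target_id) && t$id[i] == model$target_id &&
          model$target_hazard > 0) {
        b <- target_cut_boundary(t$sequence[i], model)
        hit <- which(stats::runif(n) < model$target_hazard)
        cut_mol <- c(cut_mol, hit)
        cut_b <- c(cut_b, rep(b, length(hit)))
      }
      ev <- data.table::data.table(
        molecule = c(cut_mol, seq_len(n)),
        b = c(cut_b, rep(L, n)))
      # cuts at the terminal boundary are no-ops; drop duplicates
      ev <- unique(ev[b > 0 & b <= L])
      data.table::setorder(ev, molecule, b)
      ev[, start := data.table::shift(b, 1L, fill = 0L), by = molecule]
      frags[[i]] <- data.table::data.table(
        transcript_id = t$id[i], molecule = ev$molecule,
        start = as.integer(ev$start), end = as.integer(ev$b))
    }
  })

  pool <- data.table::rbindlist(frags)
  lens <- setNames(t$length, t$id)
  pool[, has_native_polyA := end == lens[transcript_id]]
  names(cut_counts) <- t$id
  data.table::setattr(pool, "class", c("fragment_pool", class(pool)))
  data.table::setattr(pool, "timepoint", timepoint)
  data.table::setattr(pool, "seed", seed)
  data.table::setattr(pool, "n_molecules", setNames(n_mol, t$id))
  data.table::setattr(pool, "transcript_lengths", lens)
  data.table::setattr(pool, "site_cut_counts", cut_counts)
  pool
}

target_cut_boundary <- function(sequence, model) {
  ps <- model$protospacer
  mid <- as.integer(floor((ps[1] + ps[2]) / 2))
  if (model$target_cut_mode == "protospacer") return(mid + 1L)
  seqc <- strsplit(sequence, "", fixed = TRUE)[[1]]
  us <- which(seqc == "U") - 1L
  us <- us[us <= mid]
  if (length(us) == 0) return(mid + 1L)
  max(us) + 1L
}

#' Realized cut fraction of a fragment pool
#'
#' Fraction of molecules carrying at least one cut (more than one fragment),
#' optionally restricted to a biotype via the transcriptome.
#'
#' @param pool a [simulate_fragment_pool()] result.
#' @param tx optional transcriptome for biotype filtering.
#' @param biotype optional biotype to restrict to.
#' @return a scalar in `[0, 1]`.
#' @export
cut_fraction <- function(pool, tx = NULL, biotype = NULL) {
  dt <- data.table::as.data.table(pool)
  if (!is.null(biotype)) {
    stopifnot(!is.null(tx))
    keep <- tx$transcripts$id[tx$transcripts$biotype == biotype]
    dt <- dt[transcript_id %in% keep]
  }
  if (nrow(dt) == 0) return(NA_real_)
  per <- dt[, .N, by = .(transcript_id, molecule)]
  mean(per$N > 1)
}
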