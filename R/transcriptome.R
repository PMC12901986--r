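#' Synthetic transcriptome with known ground truth
#'
#' Builds a set of transcript records (id, sequence over `{A,C,G,U}`, biotype,
#' true abundance in molecules per cell) plus a set of spike-in controls with
#' known relative concentrations. Biotype counts are the largest-remainder
#' rounding of `biotype_fractions * n_transcripts`, so class sizes are exact
#' and deterministic. Spike-in concentrations are log2-spaced over
#' `spike_dynamic_range`, emulating a single-mix commercial spike-in design
#' (92 RNAs over a ~2^20 range); spike "abundance" is scaled so the spike pool
#' carries a small, fixed share of the cellular RNA mass (spikes are added
#' after RNA isolation and are never cleaved).
#'
#' @param n_transcripts total number of transcripts (> 0).
#' @param biotype_fractions named numeric over
#'   `protein_coding`, `mito_mRNA`, `nuclear_ncRNA`, `spike_in`; must sum to 1
#'   (tolerance 1e-6).
#' @param abundance_lognormal_params named pair `c(meanlog=, sdlog=)` for the
#'   per-transcript abundance draw (molecules per cell).
#' @param seq_length_range integer pair; transcript lengths are uniform on it.
#' @param n_spikeins optional override for the spike-in count; when given, the
#'   remaining classes split `n_transcripts - n_spikeins` by their renormalized
#'   fractions.
#' @param spike_dynamic_range ratio between the most and least concentrated
#'   spike-in (default `2^20`).
#' @param spike_mass_share share of total non-spike abundance assigned to the
#'   spike pool (default 0.02).
#' @param seed integer seed; the same seed yields a byte-identical object.
#' @return an object of class `"transcriptome"`: a list with
#'   `$transcripts` (data.frame: id, sequence, biotype, abundance, length) and
#'   `$spike_in_concentrations` (named numeric).
#' @export
build_transcriptome <- function(n_transcripts = 200,
                                biotype_fractions = c(protein_coding = 0.80,
                                                      mito_mRNA = 0.05,
                                                      nuclear_ncRNA = 0.10,
                                                      spike_in = 0.05),
                                abundance_lognormal_params = c(meanlog = log(20), sdlog = 1.5),
                                seq_length_range = c(400L, 3000L),
                                n_spikeins = NULL,
                                spike_dynamic_range = 2^20,
                                spike_mass_share = 0.02,
                                seed = 1L) {
  if (n_transcripts <= 0) stop("n_transcripts must be > 0")
  classes <- c("protein_coding", "mito_mRNA", "nuclear_ncRNA", "spike_in")
  if (is.null(names(biotype_fractions)) ||
      !all(names(biotype_fractions) %in% classes)) {
    stop("biotype_fractions must be named with the known biotypes: ",
         paste(classes, collapse = ", "))
  }
  fr <- setNames(numeric(4), classes)
  fr[names(biotype_fractions)] <- biotype_fractions
  if (abs(sum(fr) - 1) > 1e-6) stop("biotype fractions must sum to 1")
  if (length(seq_length_range) != 2L || seq_length_range[1] < 2 ||
      seq_length_range[2] < seq_length_range[1]) {
    stop("seq_length_range must be an increasing pair of lengths >= 2")
  }

  if (is.null(n_spikeins)) {
    counts <- largest_remainder(fr, n_transcripts)
  } else {
    n_spikeins <- as.integer(n_spikeins)
    if (n_spikeins < 0 || n_spikeins > n_transcripts) {
      stop("n_spikeins must be between 0 and n_transcripts")
    }
    rest <- fr[classes != "spike_in"]
    rest <- if (sum(rest) > 0) rest / sum(rest) else
      setNames(rep(1 / 3, 3), classes[1:3])
    counts <- c(largest_remainder(rest, n_transcripts - n_spikeins),
                spike_in = n_spikeins)
    counts <- counts[classes]
  }

  prefix <- c(protein_coding = "PC", mito_mRNA = "MT",
              nuclear_ncRNA = "NC", spike_in = "SPK")
  biotype <- rep(classes, counts)
  id <- unlist(lapply(classes, function(cl) {
    if (counts[cl] == 0) return(character(0))
    sprintf("%s%04d", prefix[cl], seq_len(counts[cl]))
  }), use.names = FALSE)

  with_seed(substream_seed(seed, "transcriptome"), {
    lenvals <- seq.int(seq_length_range[1], seq_length_range[2])
    len <- lenvals[sample.int(length(lenvals), n_transcripts, replace = TRUE)]
    sequence <- random_rna(len)
    abundance <- stats::rlnorm(n_transcripts,
                               meanlog = abundance_lognormal_params[["meanlog"]],
                               sdlog = abundance_lognormal_params[["sdlog"]])
  })

  spike_conc <- numeric(0)
  nspk <- counts[["spike_in"]]
  if (nspk > 0) {
    spike_ids <- id[biotype == "spike_in"]
    spike_conc <- setNames(2^seq(0, log2(spike_dynamic_range), length.out = nspk),
                           spike_ids)
    nonspike_mass <- sum(abundance[biotype != "spike_in"])
    abundance[biotype == "spike_in"] <-
      spike_conc / sum(spike_conc) * spike_mass_share * nonspike_mass
  }

  tx <- list(
    transcripts = data.frame(id = id, sequence = sequence, biotype = biotype,
                             abundance = abundance, length = len,
                             stringsAsFactors = FALSE),
    spike_in_concentrations = spike_conc
  )
  class(tx) <- "transcriptome"
  validate_transcriptome(tx)
  tx
}

# Largest-remainder (Hamilton) apportionment of n among named fractions.
largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  left <- as.integer(round(n - sum(base)))
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(fractions))
}

random_rna <- function(lengths) {
  vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
  }, character(1))
}

validate_transcriptome <- function(tx) {
  t <- tx$transcripts
  if (anyDuplicated(t$id)) stop("transcript ids must be unique")
  if (any(nchar(t$sequence) == 0)) stop("sequences must be non-empty")
  if (any(t$abundance < 0)) stop("abundances must be >= 0")
  if (any(nchar(t$sequence) != t$length)) stop("length column inconsistent")
  spk <- t$id[t$biotype == "spike_in"]
  if (!setequal(spk, names(tx$spike_in_concentrations))) {
    stop("spike_in transcripts and spike_in_concentrations must match 1:1")
  }
  invisible(tx)
}

#' @export
print.transcriptome <- function(x, ...) {
  tab <- table(x$transcripts$biotype)
  cat("<transcriptome> ", nrow(x$transcripts), " transcripts (",
      paste(names(tab), tab, sep = ":", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Collateral cleavage model parameters
#'
#' Bundles the hazard model used by the molecule-level simulator: dinucleotide
#' site weights (position 0 is the cleaved uracil, position +1 the following
#' base; non-U position-0 contexts have weight 0 by construction), a Bernoulli
#' loop-accessibility mask standing in for single-stranded-loop structure, a
#' piecewise activation curve A(t) in `[0, 1]`, a mild abundance dependence of
#' the per-molecule hazard, per-biotype multipliers (spike-ins are added after
#' RNA isolation and therefore have multiplier 0, enforced), and an optional
#' guide-directed cut on a designated target transcript, active from t = 0.
#'
#' The default activation curve rises from near zero at delivery, peaks over
#' 100-200 min, and decays to a small residual by 24 h; defaults for the
#' hazard scale are calibrated so that at peak activation a typical mRNA is
#' mostly fragmented while at 0 min it is ~90% intact (see the methods
#' vignette for the calibration rationale).
#'
#' @param site_weights named non-negative numeric over `UA`, `UC`, `UG`, `UU`:
#'   relative hazard of a planted site by its (0, +1) dinucleotide.
#' @param loop_mask_fraction fraction of uracils designated accessible.
#' @param activation_curve data.frame with columns `time` (min) and `level`
#'   in `[0, 1]`; simulation timepoints must be listed here.
#' @param abundance_slope exponent of the per-transcript hazard multiplier
#'   `(abundance / median abundance)^abundance_slope`.
#' @param class_multipliers named non-negative numeric per biotype;
#'   `spike_in` must be 0.
#' @param target_id optional id of the guide-targeted transcript.
#' @param target_hazard per-molecule probability of a guide-directed cut.
#' @param protospacer 0-based half-open interval `c(start, end)` of the
#'   protospacer on the target transcript (required if `target_hazard > 0`).
#' @param target_cut_mode `"protospacer"` cuts at the protospacer midpoint;
#'   `"nearest_u"` at the closest uracil 5' of the midpoint. The experimental
#'   literature does not resolve which is real (the protospacer-coincident
#'   coverage dip may be a reverse-transcription artifact), so both are exposed.
#' @return an object of class `"cleavage_model"`.
#' @export
cleavage_model <- function(site_weights = c(UA = 1, UC = 10, UG = 10, UU = 1),
                           loop_mask_fraction = 0.35,
                           activation_curve = data.frame(
                             time = c(0, 50, 100, 200, 500, 1440),
                             level = c(0.05, 0.7, 1, 1, 0.2, 0.02)),
                           abundance_slope = 0.10,
                           class_multipliers = c(protein_coding = 0.13,
                                                 mito_mRNA = 0,
                                                 nuclear_ncRNA = 0,
                                                 spike_in = 0),
                           target_id = NULL,
                           target_hazard = 0,
                           protospacer = NULL,
                           target_cut_mode = c("protospacer", "nearest_u")) {
  target_cut_mode <- match.arg(target_cut_mode)
  if (any(site_weights < 0)) stop("site weights must be >= 0")
  if (!all(names(site_weights) %in% c("UA", "UC", "UG", "UU"))) {
    stop("site_weights must be named by U-dinucleotides UA/UC/UG/UU")
  }
  if (loop_mask_fraction < 0 || loop_mask_fraction > 1) {
    stop("loop_mask_fraction must be in [0, 1]")
  }
  if (!all(c("time", "level") %in% names(activation_curve))) {
    stop("activation_curve needs columns 'time' and 'level'")
  }
  if (any(activation_curve$level < 0 | activation_curve$level > 1)) {
    stop("activation levels must lie in [0, 1]")
  }
  if (any(class_multipliers < 0)) stop("class multipliers must be >= 0")
  if (!is.na(class_multipliers["spike_in"]) && class_multipliers[["spike_in"]] != 0) {
    stop("spike_in class multiplier must be 0: spike-ins are never cleaved")
  }
  if (target_hazard < 0 || target_hazard > 1) {
    stop("target_hazard is a per-molecule probability in [0, 1]")
  }
  if (target_hazard > 0 && (is.null(target_id) || is.null(protospacer))) {
    stop("target cleavage requires target_id and protospacer")
  }
  m <- list(site_weights = site_weights,
            loop_mask_fraction = loop_mask_fraction,
            activation_curve = activation_curve,
            abundance_slope = abundance_slope,
            class_multipliers = class_multipliers,
            target_id = target_id,
            target_hazard = target_hazard,
            protospacer = protospacer,
            target_cut_mode = target_cut_mode)
  class(m) <- "cleavage_model"
  m
}

activation_at <- function(model, timepoint) {
  i <- match(timepoint, model$activation_curve$time)
  if (is.na(i)) {
    stop("timepoint ", timepoint, " min not in activation curve; available: ",
         paste(model$activation_curve$time, collapse = ", "))
  }
  model$activation_curve$level[i]
}

#' Plant candidate cleavage sites on a transcriptome
#'
#' Sites are restricted to uracil positions flagged accessible by the loop
#' mask and whose (0, +1) dinucleotide has positive weight; among eligible
#' positions each is kept independently so that the expected number of sites
#' per transcript is `density * length / 1000`. A site's stored hazard weight
#' is `site_weights[dinucleotide]`. Positions are 0-based indices of the
#' cleaved uracil; the cut itself is modeled immediately 3' of it.
#'
#' @param tx a [build_transcriptome()] object.
#' @param model a [cleavage_model()].
#' @param density expected sites per kilobase (>= 0); the default 1.4 puts a median-length mRNA at ~85-90% fragmentation under full activation.
#' @param seed integer seed.
#' @return named list (by transcript id) of data.frames with columns
#'   `position`, `weight`, `dinucleotide`; transcripts without eligible
#'   uracils get a zero-row entry.
#' @export
plant_cleavage_sites <- function(tx, model, density = 1.4, seed = 1L) {
  stopifnot(inherits(tx, "transcriptome"), inherits(model, "cleavage_model"))
  if (density < 0) stop("density must be >= 0")
  t <- tx$transcripts
  with_seed(substream_seed(seed, "sites"), {
    out <- lapply(seq_len(nrow(t)), function(i) {
      seqc <- strsplit(t$sequence[i], "", fixed = TRUE)[[1]]
      L <- t$length[i]
      upos <- which(seqc == "U")
      upos <- upos[upos < L]                     # need a +1 base for context
      empty <- data.frame(position = integer(0), weight = numeric(0),
                          dinucleotide = character(0), stringsAsFactors = FALSE)
      if (length(upos) == 0) return(empty)
      accessible <- stats::runif(length(upos)) < model$loop_mask_fraction
      dinuc <- paste0("U", seqc[upos + 1L])
      w <- model$site_weights[dinuc]
      w[is.na(w)] <- 0
      elig <- which(accessible & w > 0)
      if (length(elig) == 0) return(empty)
      q <- min(1, density * L / 1000 / length(elig))
      keep <- elig[stats::runif(length(elig)) < q]
      if (length(keep) == 0) return(empty)
      data.frame(position = upos[keep] - 1L,    # 0-based U index
                 weight = unname(w[keep]),
                 dinucleotide = dinuc[keep],
                 stringsAsFactors = FALSE)
    })
  })
  names(out) <- t$id
  out
}

#' Specify cleavage sites explicitly
#'
#' Convenience constructor for a site annotation at user-chosen uracil
#' positions (e.g. for parameter-recovery tests with a known number of sites
#' per transcript). Positions that are not uracils are rejected.
#'
#' @param tx a [build_transcriptome()] object.
#' @param positions named list (by transcript id) of 0-based uracil indices.
#' @param weight hazard weight assigned to every site (default 10).
#' @return site annotation in the [plant_cleavage_sites()] format.
#' @export
manual_sites <- function(tx, positions, weight = 10) {
  t <- tx$transcripts
  out <- lapply(t$id, function(id) {
    pos <- positions[[id]]
    if (is.null(pos) || length(pos) == 0) {
      return(data.frame(position = integer(0), weight = numeric(0),
                        dinucleotide = character(0), stringsAsFactors = FALSE))
    }
    seqc <- strsplit(t$sequence[t$id == id], "", fixed = TRUE)[[1]]
    if (any(seqc[pos + 1L] != "U")) stop("manual site not at a U in ", id)
    nxt <- ifelse(pos + 2L <= length(seqc), seqc[pos + 2L], "")
    data.frame(position = as.integer(pos), weight = weight,
               dinucleotide = paste0("U", nxt), stringsAsFactors = FALSE)
  })
  names(out) <- t$id
  out
}
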