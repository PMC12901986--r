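# Shared fixture builders. Everything is generated in code; no data files.

# Transcriptome object from explicit sequences (for forced examples).
make_tx <- function(seqs, biotype = "protein_coding", abundance = 100) {
  n <- length(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("TX%03d", seq_len(n))
  biotype <- rep_len(biotype, n)
  abundance <- rep_len(abundance, n)
  tx <- list(
    transcripts = data.frame(id = ids, sequence = unname(seqs),
                             biotype = biotype, abundance = abundance,
                             length = nchar(seqs), stringsAsFactors = FALSE),
    spike_in_concentrations = setNames(abundance[biotype == "spike_in"],
                                       ids[biotype == "spike_in"]))
  class(tx) <- "transcriptome"
  collateralkit:::validate_transcriptome(tx)
}

random_rna_seq <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Flat single-biotype cohort: constant abundance, fixed length range.
make_flat_tx <- function(n_tx, len = c(1200, 1200), abundance = 300, seed = 1) {
  build_transcriptome(
    n_transcripts = n_tx,
    biotype_fractions = c(protein_coding = 1, mito_mRNA = 0,
                          nuclear_ncRNA = 0, spike_in = 0),
    abundance_lognormal_params = c(meanlog = log(abundance), sdlog = 0),
    seq_length_range = len, seed = seed)
}

# 1..3 uracil positions per transcript, >= min_edge from the ends and
# >= min_gap apart; the ground truth for dip-recovery scenarios.
plant_spaced_positions <- function(seqs, seed, min_edge = 100, min_gap = 80) {
  set.seed(seed)
  out <- list()
  for (id in names(seqs)) {
    sc <- strsplit(seqs[[id]], "", fixed = TRUE)[[1]]
    us <- which(sc == "U") - 1L
    us <- us[us >= min_edge & us <= length(sc) - min_edge - 1L]
    k <- sample(1:3, 1)
    pos <- integer(0)
    for (i in seq_len(k)) {
      ok <- if (length(pos)) us[apply(abs(outer(us, pos, "-")) >= min_gap, 1, all)] else us
      if (!length(ok)) break
      pos <- c(pos, if (length(ok) == 1) ok else sample(ok, 1))
    }
    out[[id]] <- sort(pos)
  }
  out
}

# Alignment set from explicit intervals (for coverage/dip unit tests).
make_aln <- function(transcript_id, tstart, tend, lengths) {
  n <- length(tstart)
  collateralkit:::new_alignment_set(
    data.table::data.table(
      read_id = sprintf("r%05d", seq_len(n)),
      transcript_id = rep_len(transcript_id, n),
      tstart = as.integer(tstart), tend = as.integer(tend),
      is_primary = TRUE, mapq = 60L, strand = "+"),
    lengths)
}

# Subset an alignment set to transcripts, keeping attributes.
aln_subset <- function(aln, ids) {
  a <- aln[aln$transcript_id %in% ids]
  attr(a, "transcript_lengths") <- attr(aln, "transcript_lengths")
  class(a) <- class(aln)
  a
}

# Cq table from explicit values (long format).
make_cq <- function(sample, target = "GAPDH", primer_end, cq,
                    replicate = NULL, detected = NULL) {
  n <- max(lengths(list(sample, primer_end, cq)))
  if (is.null(replicate)) replicate <- seq_len(n)
  if (is.null(detected)) detected <- is.finite(cq)
  out <- data.frame(sample = rep_len(sample, n), target = rep_len(target, n),
                    primer_end = rep_len(primer_end, n),
                    replicate = rep_len(replicate, n),
                    cq = rep_len(cq, n), detected = rep_len(detected, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("cq_table", "data.frame")
  out
}

# Standard 3 + 3 spike-in count-matrix world used by several suites.
count_world <- function(seed = 1, intercept = 0, gene_offsets = NULL,
                        library_scales = NULL, n = 500) {
  tx <- build_transcriptome(
    n_transcripts = n, n_spikeins = min(46, n %/% 2),
    biotype_fractions = c(protein_coding = 1, mito_mRNA = 0,
                          nuclear_ncRNA = 0, spike_in = 0),
    abundance_lognormal_params = c(meanlog = log(80), sdlog = 1.2),
    seed = seed)
  design <- data.frame(sample = c("c1", "c2", "c3", "t1", "t2", "t3"),
                       condition = rep(c("non_targeting", "targeting"), each = 3))
  cm <- simulate_count_matrix(
    tx, depletion_spec = list(intercept = intercept, gene_offsets = gene_offsets),
    design = design, library_scales = library_scales, dispersion = 0.05,
    seed = seed + 1)
  list(tx = tx, cm = cm, design = design)
}

# Match dip calls to planted truth within tol nt; returns recall/precision
# and positional errors.
score_dip_calls <- function(calls, truth, tol = 10) {
  tp <- 0L; errs <- numeric(0)
  for (id in names(truth)) {
    tr <- truth[[id]]
    if (!length(tr)) next
    cl <- calls[calls$transcript_id == id & !is.na(calls$position), , drop = FALSE]
    for (p in tr) {
      if (nrow(cl)) {
        d <- abs(cl$position - p)
        if (min(d) <= tol) { tp <- tp + 1L; errs <- c(errs, min(d)) }
      }
    }
  }
  n_true <- sum(lengths(truth))
  list(recall = tp / n_true,
       precision = if (nrow(calls)) tp / nrow(calls) else NA_real_,
       errors = errs, n_true = n_true, n_called = nrow(calls))
}

# Jaccard index of two dip-call interval sets (as position sets).
dip_jaccard <- function(calls1, calls2) {
  posset <- function(calls) {
    if (!nrow(calls)) return(character(0))
    unlist(lapply(seq_len(nrow(calls)), function(i)
      paste0(calls$transcript_id[i], ":", calls$start[i]:(calls$end[i] - 1L))))
  }
  a <- posset(calls1); b <- posset(calls2)
  if (!length(a) && !length(b)) return(NA_real_)
  length(intersect(a, b)) / length(union(a, b))
}
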