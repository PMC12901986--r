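#' Write a transcriptome to FASTA
#'
#' @param tx a [build_transcriptome()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcriptome_fasta <- function(tx, path) {
  seqs <- Biostrings::RNAStringSet(setNames(tx$transcripts$sequence,
                                            tx$transcripts$id))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA file (RNA or DNA alphabet; T is converted to U).
#' @return named character vector of RNA sequences.
#' @export
read_transcript_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  out <- chartr("Tt", "Uu", toupper(as.character(seqs)))
  setNames(out, sub("\\s.*$", "", names(seqs)))
}

paf_cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
              "tstart", "tend", "matches", "alnlen", "mapq")

#' Write an alignment set as PAF
#'
#' Emits the 12 mandatory PAF columns plus a `tp:A:P` tag; only primary
#' records are written (the simulator emits nothing else). Coordinates are
#' 0-based half-open, transcript space, forward strand.
#'
#' @param alignments an `"alignment_set"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(alignments, path) {
  lens <- attr(alignments, "transcript_lengths")
  dt <- data.table::as.data.table(alignments)[is_primary == TRUE]
  out <- data.table::data.table(
    qname = dt$read_id,
    qlen = dt$tend - dt$tstart,
    qstart = 0L,
    qend = dt$tend - dt$tstart,
    strand = dt$strand,
    tname = dt$transcript_id,
    tlen = unname(lens[dt$transcript_id]),
    tstart = dt$tstart,
    tend = dt$tend,
    matches = dt$tend - dt$tstart,
    alnlen = dt$tend - dt$tstart,
    mapq = dt$mapq,
    tp = "tp:A:P")
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read transcript-space alignments from PAF
#'
#' @param path PAF file.
#' @return an `"alignment_set"` with transcript lengths from column 7;
#'   records tagged secondary (`tp:A:S`) are dropped with a message.
#' @export
read_paf <- function(path) {
  dt <- if (file.exists(path) && file.size(path) == 0) {
    data.table::data.table()
  } else {
    tryCatch(
      data.table::fread(path, sep = "\t", header = FALSE, fill = TRUE),
      error = function(e) stop("malformed PAF '", path, "': ", conditionMessage(e)))
  }
  if (nrow(dt) == 0) {
    warning("empty PAF file: ", path)
    return(new_alignment_set(data.table::data.table(
      read_id = character(0), transcript_id = character(0),
      tstart = integer(0), tend = integer(0), is_primary = logical(0),
      mapq = integer(0), strand = character(0)), numeric(0)))
  }
  if (ncol(dt) < 12) {
    stop("malformed PAF '", path, "': expected >= 12 columns, got ", ncol(dt))
  }
  names(dt)[1:12] <- paf_cols
  bad <- which(!is.finite(dt$tstart) | !is.finite(dt$tend) | dt$tstart >= dt$tend)
  if (length(bad)) stop("malformed PAF record at line ", bad[1], " of ", path)
  n0 <- nrow(dt)
  if (ncol(dt) >= 13) {
    tags <- apply(as.matrix(dt[, 13:ncol(dt), drop = FALSE]), 1,
                  function(r) any(grepl("^tp:A:[SI]$", r)))
    dt <- dt[!tags]
  }
  if (nrow(dt) < n0) message("dropped ", n0 - nrow(dt), " non-primary PAF records")
  lens <- with(unique(dt[, .(tname, tlen)]), setNames(tlen, tname))
  new_alignment_set(data.table::data.table(
    read_id = dt$qname, transcript_id = dt$tname,
    tstart = as.integer(dt$tstart), tend = as.integer(dt$tend),
    is_primary = TRUE, mapq = as.integer(dt$mapq), strand = dt$strand),
    lens)
}

#' Parse alignments from PAF or SAM
#'
#' Secondary (0x100) and supplementary (0x800) records are dropped with a
#' logged count; coordinates are normalized to 0-based half-open. When a FASTA
#' is given, reference lengths are cross-checked against it.
#'
#' @param path alignment file.
#' @param format `"paf"` or `"sam"`.
#' @param fasta optional transcript FASTA for length validation.
#' @return an `"alignment_set"`.
#' @export
parse_alignments <- function(path, format = c("paf", "sam"), fasta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  aln <- if (format == "paf") read_paf(path) else read_sam(path)
  if (!is.null(fasta)) {
    seqs <- read_transcript_fasta(fasta)
    lens <- attr(aln, "transcript_lengths")
    common <- intersect(names(lens), names(seqs))
    if (length(setdiff(names(lens), names(seqs)))) {
      stop("alignment references missing from FASTA: ",
           paste(utils::head(setdiff(names(lens), names(seqs)), 3), collapse = ", "))
    }
    if (any(lens[common] != nchar(seqs[common]))) {
      stop("reference length mismatch between alignments and FASTA")
    }
  }
  aln
}

read_sam <- function(path) {
  for (pkg in c("Rsamtools", "GenomicAlignments")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("SAM input requires the ", pkg, " package")
    }
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "mapq", "flag", "strand"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  n0 <- length(rec$qname)
  if (n0 == 0) {
    warning("no alignment records in ", path)
    return(new_alignment_set(data.table::data.table(
      read_id = character(0), transcript_id = character(0),
      tstart = integer(0), tend = integer(0), is_primary = logical(0),
      mapq = integer(0), strand = character(0)), hdr))
  }
  keep <- bitwAnd(rec$flag, 0x100) == 0 & bitwAnd(rec$flag, 0x800) == 0 &
    bitwAnd(rec$flag, 0x4) == 0
  dropped <- sum(!keep & bitwAnd(rec$flag, 0x4) == 0)
  if (dropped > 0) message("dropped ", dropped, " secondary/supplementary records")
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar[keep])
  new_alignment_set(data.table::data.table(
    read_id = rec$qname[keep],
    transcript_id = as.character(rec$rname[keep]),
    tstart = rec$pos[keep] - 1L,                 # SAM is 1-based
    tend = rec$pos[keep] - 1L + width,
    is_primary = TRUE,
    mapq = as.integer(rec$mapq[keep]),
    strand = as.character(rec$strand[keep])), hdr)
}

#' Write/read a counts table as TSV
#'
#' Rows are transcript ids; columns are sample ids plus a logical `spike_in`
#' column (and `biotype` when known). Tab-separated with a header, UTF-8.
#'
#' @param counts a [simulate_count_matrix()] object or matrix.
#' @param path file path.
#' @param spike_in,biotype per-gene annotation for matrix input.
#' @return `path` invisibly (writer); a list with `counts`, `spike_in`,
#'   `biotype` (reader).
#' @export
write_counts_tsv <- function(counts, path, spike_in = NULL, biotype = NULL) {
  m <- count_input(counts, spike_in, biotype)
  dt <- data.table::data.table(gene = rownames(m$counts))
  dt <- cbind(dt, data.table::as.data.table(m$counts))
  dt[, spike_in := unname(m$spike_in)]
  if (!is.null(m$biotype)) dt[, biotype := unname(m$biotype)]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  meta <- intersect(c("gene", "spike_in", "biotype"), names(dt))
  samples <- setdiff(names(dt), meta)
  m <- as.matrix(dt[, ..samples])
  rownames(m) <- dt$gene
  list(counts = m,
       spike_in = setNames(dt$spike_in, dt$gene),
       biotype = if ("biotype" %in% names(dt)) setNames(dt$biotype, dt$gene) else NULL)
}

#' Write/read a Cq table as CSV
#'
#' Long format: `sample, target, primer_end, replicate, cq, detected`; the
#' undetected sentinel is an empty `cq` field with `detected = FALSE`. The
#' sample sheet travels as a separate CSV (`sample, condition,
#' is_empty_control`).
#'
#' @param table a `"cq_table"`.
#' @param path CSV path.
#' @param sample_sheet_path optional path for the sample sheet.
#' @return `path` invisibly (writer); a `"cq_table"` (reader).
#' @export
write_cq_csv <- function(table, path, sample_sheet_path = NULL) {
  data.table::fwrite(as.data.frame(table), path)
  ss <- attr(table, "sample_sheet")
  if (!is.null(sample_sheet_path) && !is.null(ss)) {
    data.table::fwrite(ss, sample_sheet_path)
  }
  invisible(path)
}

#' @rdname write_cq_csv
#' @param sample_sheet optional sample-sheet CSV path (reader).
#' @export
read_cq_csv <- function(path, sample_sheet = NULL) {
  dt <- as.data.frame(data.table::fread(path))
  dt$cq <- as.numeric(dt$cq)
  class(dt) <- c("cq_table", "data.frame")
  if (!is.null(sample_sheet)) {
    attr(dt, "sample_sheet") <- as.data.frame(data.table::fread(sample_sheet))
  }
  dt
}

#' Write/read an electropherogram trace as TSV
#'
#' Two tab-separated columns: `size_nt`, `fluorescence`.
#'
#' @param trace an [electropherogram()].
#' @param path TSV path.
#' @return `path` invisibly (writer); an `"electropherogram"` (reader).
#' @export
write_trace_tsv <- function(trace, path) {
  data.table::fwrite(as.data.frame(trace)[, c("size_nt", "fluorescence")],
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_trace_tsv
#' @param sample_id sample name attached on read.
#' @export
read_trace_tsv <- function(path, sample_id = basename(path)) {
  dt <- data.table::fread(path, sep = "\t")
  electropherogram(dt$size_nt, dt$fluorescence, sample_id)
}

#' Write dip calls / planted sites as BED6
#'
#' 0-based half-open intervals per the BED convention; `score` is
#' `round(1000 * (1 - depth_ratio))` (deeper dip, higher score; 1000 for
#' planted ground-truth sites), strand `+`, output sorted by (chrom, start)
#' regardless of input order. No header.
#'
#' @param calls data.frame with `transcript_id`, `start`, `end`, optionally
#'   `depth_ratio` and `position`.
#' @param path BED path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(calls, path) {
  if (nrow(calls) == 0) {
    file.create(path)
    return(invisible(path))
  }
  score <- if (!is.null(calls$depth_ratio)) {
    as.integer(round(1000 * (1 - calls$depth_ratio)))
  } else rep(1000L, nrow(calls))
  name <- if (!is.null(calls$position)) {
    ifelse(is.na(calls$position), paste0(calls$transcript_id, ":dip"),
           sprintf("%s:U%d", calls$transcript_id, calls$position))
  } else paste0(calls$transcript_id, ":site")
  bed <- data.table::data.table(chrom = calls$transcript_id,
                                start = calls$start, end = calls$end,
                                name = name, score = score, strand = "+")
  data.table::setorder(bed, chrom, start)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_sites_bed
#' @export
read_sites_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0)))
  }
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  stats::setNames(as.data.frame(dt),
                  c("transcript_id", "start", "end", "name", "score", "strand"))
}
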