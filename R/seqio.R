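## Read handling, quality trimming, two-read consensus assembly and
## Numt screening for Sanger-style COI barcodes.

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

#' A sequencing read with per-base Phred qualities
#'
#' @param read_id Read identifier.
#' @param bases IUPAC nucleotide string.
#' @param quals Integer vector of Phred scores, one per base.
#' @param orientation `"forward"` or `"reverse"` (reverse reads are
#'   stored as read off the machine and reverse-complemented on use).
#' @return Object of class `"quality_read"`.
#' @export
quality_read <- function(read_id, bases, quals, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  bases <- toupper(as.character(bases))
  quals <- as.integer(quals)
  bv <- strsplit(bases, "", fixed = TRUE)[[1]]
  if (length(bv) != length(quals))
    stop("read '", read_id, "': bases and quals differ in length")
  if (length(bv) && !all(bv %in% IUPAC_LETTERS))
    stop("read '", read_id, "': non-IUPAC characters: ",
         paste(unique(setdiff(bv, IUPAC_LETTERS)), collapse = ","))
  if (any(quals < 0L, na.rm = TRUE)) stop("Phred scores must be >= 0")
  structure(list(read_id = read_id, bases = bases, quals = quals,
                 orientation = orientation),
            class = "quality_read")
}

#' @export
print.quality_read <- function(x, ...) {
  cat(sprintf("<quality_read %s | %s | %d bp | mean Q %.1f>\n", x$read_id,
              x$orientation, nchar(x$bases),
              if (length(x$quals)) mean(x$quals) else NA_real_))
  invisible(x)
}

#' Trim or mask low-quality stretches of a read
#'
#' Every maximal run of at least `min_run` contiguous bases with quality
#' below `q_threshold` is removed: runs touching a read end are excised
#' (together with anything between the run and that end), interior runs
#' are masked to `N` so that codon coordinates downstream are preserved.
#'
#' @param read A [quality_read()].
#' @param min_run Minimum run length that triggers trimming (>= 1).
#' @param q_threshold Phred score below which a base counts as low
#'   quality. The default 20 is the conventional Sanger reliability floor.
#' @return A [quality_read()]; attribute `trimmed_ranges` lists excised
#'   0-based half-open intervals in the input's coordinates, attribute
#'   `masked_ranges` the interior runs replaced by `N`.
#' @export
trim_low_quality <- function(read, min_run = 5L, q_threshold = 20L) {
  stopifnot(inherits(read, "quality_read"))
  if (min_run < 1L) stop("min_run must be >= 1")
  if (q_threshold < 0L) stop("q_threshold must be >= 0")
  n <- length(read$quals)
  empty_ranges <- list()
  if (n == 0L) {
    attr(read, "trimmed_ranges") <- empty_ranges
    attr(read, "masked_ranges") <- empty_ranges
    return(read)
  }
  low <- read$quals < q_threshold
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_run)
  trimmed <- list(); masked <- list()
  keep_from <- 1L; keep_to <- n
  bv <- strsplit(read$bases, "", fixed = TRUE)[[1]]
  for (k in hit) {
    if (starts[k] == 1L) {                       # touches 5' end
      keep_from <- max(keep_from, ends[k] + 1L)
      trimmed[[length(trimmed) + 1L]] <- c(0L, ends[k])
    } else if (ends[k] == n) {                   # touches 3' end
      keep_to <- min(keep_to, starts[k] - 1L)
      trimmed[[length(trimmed) + 1L]] <- c(starts[k] - 1L, n)
    } else {                                     # interior: mask
      bv[starts[k]:ends[k]] <- "N"
      masked[[length(masked) + 1L]] <- c(starts[k] - 1L, ends[k])
    }
  }
  if (keep_from > keep_to) {
    out <- quality_read(read$read_id, "", integer(0), read$orientation)
  } else {
    out <- quality_read(read$read_id,
                        paste(bv[keep_from:keep_to], collapse = ""),
                        read$quals[keep_from:keep_to], read$orientation)
  }
  attr(out, "trimmed_ranges") <- trimmed
  attr(out, "masked_ranges") <- masked
  out
}

#' A consensus barcode sequence
#'
#' @param sample_id Sample identifier.
#' @param sequence IUPAC nucleotide string.
#' @param trimmed_ranges List of 0-based half-open intervals removed
#'   during quality trimming.
#' @return Object of class `"consensus_record"` with fields `sample_id`,
#'   `sequence`, `length`, `ambiguity_count`, `trimmed_ranges`. Typical
#'   COI barcodes run ~650 bp; a warning is emitted outside [150, 700].
#' @export
consensus_record <- function(sample_id, sequence, trimmed_ranges = list()) {
  sequence <- toupper(as.character(sequence))
  bv <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(bv) && !all(bv %in% IUPAC_LETTERS))
    stop("sample '", sample_id, "': non-IUPAC characters in consensus")
  len <- length(bv)
  if (len < 150L || len > 700L)
    warning("sample '", sample_id, "': consensus length ", len,
            " outside the expected barcode range [150, 700]")
  structure(list(sample_id = sample_id, sequence = sequence, length = len,
                 ambiguity_count = sum(!bv %in% c("A", "C", "G", "T")),
                 trimmed_ranges = trimmed_ranges),
            class = "consensus_record")
}

#' @export
print.consensus_record <- function(x, ...) {
  cat(sprintf("<consensus %s | %d bp | %d ambiguous>\n",
              x$sample_id, x$length, x$ambiguity_count))
  invisible(x)
}

#' Reverse-complement a nucleotide string
#' @param s IUPAC nucleotide string.
#' @return The reverse complement as a character string.
#' @export
rc_string <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Assemble a forward/reverse read pair into a consensus barcode
#'
#' The reverse read is reverse-complemented, the two reads are aligned
#' end-gap-free (match +1, mismatch -1, gap -2), and each overlap column
#' is resolved in favor of the clearly better-quality base; when the two
#' qualities are similar (difference below `similar_q_delta`) the 2-base
#' IUPAC ambiguity code is emitted instead (N if either base is N).
#' Flanks covered by a single read are copied from that read.
#'
#' @param fwd,rev [quality_read()] objects; `rev` is taken as the
#'   reverse-strand read regardless of its `orientation` field.
#' @param min_overlap Minimum alignment columns required (default 50;
#'   Sanger read pairs of a ~650 bp amplicon overlap almost fully).
#' @param similar_q_delta Phred difference below which two conflicting
#'   calls count as "similar quality" (default 10, a 10-fold error-rate
#'   ratio).
#' @param sample_id Consensus identifier; defaults to the forward read id
#'   stripped of a trailing `/1`, `_F` or `.f` tag.
#' @return A [consensus_record()].
#' @export
assemble_consensus <- function(fwd, rev, min_overlap = 50L,
                               similar_q_delta = 10L, sample_id = NULL) {
  stopifnot(inherits(fwd, "quality_read"), inherits(rev, "quality_read"))
  if (is.null(sample_id))
    sample_id <- sub("([/._][12FRfr])$", "", fwd$read_id)
  if (nchar(fwd$bases) == 0L || nchar(rev$bases) == 0L)
    stop("assembly failed for reads '", fwd$read_id, "' + '", rev$read_id,
         "': empty read")
  rseq <- rc_string(rev$bases)
  rq <- rev(rev$quals)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(fwd$bases), Biostrings::DNAString(rseq),
    type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 0, gapExtension = 2)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ncols <- length(ap)
  if (ncols < min_overlap)
    stop("assembly failed for reads '", fwd$read_id, "' + '", rev$read_id,
         "': overlap ", ncols, " < min_overlap ", min_overlap)
  fstart <- Biostrings::start(Biostrings::pattern(pa))
  sstart <- Biostrings::start(Biostrings::subject(pa))
  fv <- strsplit(fwd$bases, "")[[1]]
  sv <- strsplit(rseq, "")[[1]]
  out <- character(0)
  ## left flank from the forward read (dangling reverse prefix dropped)
  if (fstart > 1L) out <- fv[seq_len(fstart - 1L)]
  ip <- fstart; js <- sstart
  mid <- character(ncols)
  for (k in seq_len(ncols)) {
    pb <- ap[k]; sb <- as_[k]
    if (pb == "-") { mid[k] <- sb; js <- js + 1L; next }
    if (sb == "-") { mid[k] <- pb; ip <- ip + 1L; next }
    if (pb == sb) mid[k] <- pb
    else {
      qf <- fwd$quals[ip]; qr <- rq[js]
      if (abs(qf - qr) >= similar_q_delta) mid[k] <- if (qf >= qr) pb else sb
      else if (pb == "N" || sb == "N") mid[k] <- "N"
      else mid[k] <- Biostrings::mergeIUPACLetters(paste0(sort(c(pb, sb)), collapse = ""))
    }
    ip <- ip + 1L; js <- js + 1L
  }
  out <- c(out, mid)
  ## right flank from the reverse read (dangling forward suffix dropped)
  send <- js - 1L
  if (send < length(sv)) out <- c(out, sv[(send + 1L):length(sv)])
  tr <- c(attr(fwd, "trimmed_ranges"), attr(rev, "trimmed_ranges"))
  consensus_record(sample_id, paste(out, collapse = ""),
                   trimmed_ranges = if (is.null(tr)) list() else tr)
}

#' Screen a barcode for nuclear mitochondrial pseudogene (Numt) signals
#'
#' Translates the three forward frames under the vertebrate mitochondrial
#' genetic code and picks the frame with the fewest internal stop codons;
#' authentic COI has none, so any stop (or a gap run whose length is not
#' a multiple of 3 in the aligned form) flags a likely Numt.
#'
#' @param sequence Ungapped IUPAC nucleotide string (length >= 3).
#' @param aligned Optional aligned form of the same sequence (may contain
#'   `-` gaps and `?` padding) used for the frame-disruption check.
#' @param sample_id Identifier carried into the report.
#' @return Object of class `"numt_report"`: `sample_id`, `best_frame`
#'   (0-based), `internal_stop_count`, `gap_disruption`, `pass`.
#' @export
numt_screen <- function(sequence, aligned = NULL, sample_id = "") {
  sequence <- toupper(as.character(sequence))
  bv <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(bv) < 3L) stop("sequence shorter than one codon")
  if (!all(bv %in% IUPAC_LETTERS))
    stop("non-IUPAC characters in sequence: ",
         paste(unique(setdiff(bv, IUPAC_LETTERS)), collapse = ","))
  ## stop codons of the vertebrate mitochondrial code (TAA, TAG, AGA,
  ## AGG); codons containing ambiguity codes cannot be called as stops
  stops <- integer(3)
  for (f in 0:2) {
    n_cod <- (nchar(sequence) - f) %/% 3L
    if (n_cod < 1L) { stops[f + 1L] <- NA_integer_; next }
    cods <- substring(sequence, f + 1L + 3L * (seq_len(n_cod) - 1L),
                      f + 3L * seq_len(n_cod))
    stops[f + 1L] <- sum(cods %in% MITO_STOPS)
  }
  best <- which.min(stops) - 1L
  gap_disruption <- FALSE
  if (!is.null(aligned)) {
    av <- strsplit(toupper(aligned), "", fixed = TRUE)[[1]]
    ## internal gap runs only; leading/trailing '-' or '?' padding is not
    ## evidence about reading frame
    core <- range(which(!av %in% c("-", "?")))
    r <- rle(av[core[1]:core[2]] == "-")
    runs <- r$lengths[r$values]
    gap_disruption <- any(runs %% 3L != 0L)
  }
  structure(list(sample_id = sample_id, best_frame = best,
                 internal_stop_count = stops[best + 1L],
                 gap_disruption = gap_disruption,
                 pass = stops[best + 1L] == 0L && !gap_disruption),
            class = "numt_report")
}

#' @export
print.numt_report <- function(x, ...) {
  cat(sprintf("<numt_screen %s | frame %d | %d stops | gaps %s | %s>\n",
              x$sample_id, x$best_frame, x$internal_stop_count,
              x$gap_disruption, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

## ---- file I/O ----------------------------------------------------------

#' Read Sanger-style FASTQ (Phred+33) into quality_read objects
#'
#' Orientation is taken from the read id: ids ending in `/2`, `_R` or
#' `.r` are reverse reads, everything else forward.
#'
#' @param file FASTQ path.
#' @return List of [quality_read()] objects.
#' @export
read_fastq_reads <- function(file) {
  x <- Biostrings::readQualityScaledDNAStringSet(file)
  qs <- as(Biostrings::quality(x), "IntegerList")
  lapply(seq_along(x), function(i) {
    id <- names(x)[i]
    ori <- if (grepl("([/._][2Rr])$", id)) "reverse" else "forward"
    quality_read(id, as.character(x[[i]]), qs[[i]], ori)
  })
}

#' Write quality_read objects as FASTQ (Phred+33)
#' @param reads List of [quality_read()].
#' @param file Output path.
#' @export
write_fastq_reads <- function(reads, file) {
  dna <- Biostrings::DNAStringSet(vapply(reads, `[[`, "", "bases"))
  names(dna) <- vapply(reads, `[[`, "", "read_id")
  qual <- Biostrings::PhredQuality(vapply(reads, function(r)
    paste(intToUtf8(pmin(r$quals, 93L) + 33L, multiple = TRUE), collapse = ""), ""))
  qdna <- Biostrings::QualityScaledDNAStringSet(dna, qual)
  Biostrings::writeQualityScaledXStringSet(qdna, file)
  invisible(file)
}

#' Read pre-assembled barcode sequences from FASTA
#' @param file FASTA path.
#' @return Named character vector of sequences.
#' @export
read_barcode_fasta <- function(file) {
  x <- Biostrings::readBStringSet(file)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write consensus records to FASTA
#' @param records List of [consensus_record()] (or named character vector).
#' @param file Output path.
#' @export
write_consensus_fasta <- function(records, file) {
  if (is.list(records) && length(records) && inherits(records[[1]], "consensus_record")) {
    seqs <- vapply(records, `[[`, "", "sequence")
    names(seqs) <- vapply(records, `[[`, "", "sample_id")
  } else seqs <- records
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), file)
  invisible(file)
}

#' Tabular QC report for assembled consensus sequences
#'
#' @param records List of [consensus_record()].
#' @param numt_reports Optional list of [numt_screen()] results, matched
#'   by position.
#' @param file Optional TSV output path.
#' @return data.frame with sample_id, length, ambiguity_count, numt_pass
#'   and trimmed_ranges columns.
#' @export
qc_report <- function(records, numt_reports = NULL, file = NULL) {
  fmt_ranges <- function(rr)
    if (!length(rr)) "" else paste(vapply(rr, function(iv)
      sprintf("[%d,%d)", iv[1], iv[2]), ""), collapse = ";")
  df <- data.frame(
    sample_id = vapply(records, `[[`, "", "sample_id"),
    length = vapply(records, `[[`, 0L, "length"),
    ambiguity_count = vapply(records, `[[`, 0L, "ambiguity_count"),
    numt_pass = if (is.null(numt_reports)) NA else
      vapply(numt_reports, `[[`, TRUE, "pass"),
    trimmed_ranges = vapply(records, function(r) fmt_ranges(r$trimmed_ranges), ""),
    stringsAsFactors = FALSE)
  if (!is.null(file))
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
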