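## Local-alignment top-hit search against a reference database, and
## construction of the congener candidate set around the top hit.
##
## Search is exact Smith-Waterman (affine gaps) rather than heuristic
## seeded alignment: at desk scale (hundreds of references) exactness is
## affordable and fully testable. For larger batch runs an optional
## k-mer prescreen shortlists references by shared 8-mers before exact
## alignment of the shortlist (see `strategy`).

default_scoring <- function()
  list(match = 2, mismatch = -3, gap_open = 5, gap_extend = 2)

## IUPAC-aware substitution matrix: compatible ambiguity codes score as a
## match, N (and any pairing through it) always scores as a mismatch.
iupac_score_matrix <- function(scoring) {
  letters <- IUPAC_LETTERS
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP[letters], "")
  m <- matrix(scoring$mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  for (i in seq_along(letters)) for (j in seq_along(letters)) {
    if (letters[i] == "N" || letters[j] == "N") next
    if (length(intersect(sets[[i]], sets[[j]]))) m[i, j] <- scoring$match
  }
  m
}

#' Optimal local alignment of two barcode sequences
#'
#' Exact Smith-Waterman with affine gap penalties. `%identity` is the
#' percentage of identical columns over all alignment columns (gap
#' columns included in the denominator); `%coverage` is the percentage of
#' the *query* spanned by the alignment ("query cover" semantics, so a
#' short query fully contained in a long subject scores 100).
#'
#' @param query,subject Ungapped IUPAC strings.
#' @param scoring List with `match`, `mismatch` (score values) and
#'   `gap_open`, `gap_extend` (positive penalties); defaults are
#'   BLASTN-like (+2/-3, 5/2).
#' @param query_id,subject_accession,subject_species Labels carried into
#'   the report.
#' @return One-row data.frame (class `"hit_report"`): score,
#'   pct_identity, pct_coverage and 0-based half-open query/subject spans.
#' @export
local_align <- function(query, subject, scoring = default_scoring(),
                        query_id = "query", subject_accession = "subject",
                        subject_species = NA_character_) {
  if (!nchar(query) || !nchar(subject)) stop("empty sequence")
  if (scoring$gap_open < 0 || scoring$gap_extend <= 0)
    stop("gap penalties must be positive")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(query)), Biostrings::DNAString(toupper(subject)),
    type = "local", substitutionMatrix = iupac_score_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ncols <- length(ap)
  ident <- sum(ap == as_ & ap != "-")
  qr <- pa@pattern@range
  sr <- pa@subject@range
  data.frame(query_id = query_id, subject_accession = subject_accession,
             subject_species = subject_species,
             score = Biostrings::score(pa),
             pct_identity = 100 * ident / ncols,
             pct_coverage = 100 * (qr@width) / nchar(query),
             q_start = qr@start - 1L, q_end = qr@start + qr@width - 1L,
             s_start = sr@start - 1L, s_end = sr@start + sr@width - 1L,
             stringsAsFactors = FALSE)
}

kmer_presence <- function(seqs, width = 8L) {
  dna <- Biostrings::DNAStringSet(gsub("[^ACGT]", "A", toupper(seqs)))
  Biostrings::oligonucleotideFrequency(dna, width = width) > 0L
}

#' Precompute the k-mer prescreen index for a reference database
#'
#' Optional acceleration for [search_top_hits()] on large databases or
#' query batches; stores an 8-mer presence matrix inside the db object.
#'
#' @param db A [reference_db()].
#' @return The database with a `kmer_index` element.
#' @export
index_refdb <- function(db) {
  m <- kmer_presence(db$records$ungapped_seq)
  storage.mode(m) <- "double"  # avoid logical->double coercion per query
  db$kmer_index <- m
  db
}

#' Rank reference database hits for a query barcode
#'
#' Both query strands are searched; hits are ranked by alignment score,
#' ties broken by percent identity and then accession. With
#' `strategy = "seed"` (chosen automatically for databases above
#' `seed_threshold` records) candidate references are first shortlisted
#' by shared 8-mer counts and only the shortlist is aligned exactly,
#' mirroring the seeding idea of heuristic search tools; `"exhaustive"`
#' aligns every record.
#'
#' @param query A [consensus_record()] or an ungapped IUPAC string.
#' @param db A [reference_db()] (optionally from [index_refdb()]).
#' @param k Number of hits to return (>= 1).
#' @param scoring See [local_align()].
#' @param strategy `"auto"`, `"exhaustive"` or `"seed"`.
#' @param shortlist Shortlist size for the seed strategy.
#' @param seed_threshold Database size above which `"auto"` switches to
#'   the seed strategy.
#' @return data.frame of up to `k` hits with a `strand` column
#'   (`"+"`/`"-"`), best hit first.
#' @export
search_top_hits <- function(query, db, k = 5L, scoring = default_scoring(),
                            strategy = c("auto", "exhaustive", "seed"),
                            shortlist = 6L, seed_threshold = 30L) {
  strategy <- match.arg(strategy)
  if (k < 1L) stop("k must be >= 1")
  if (!nrow(db$records)) stop("empty reference database")
  qid <- if (inherits(query, "consensus_record")) query$sample_id else "query"
  qseq <- if (inherits(query, "consensus_record")) query$sequence else toupper(query)
  if (!nchar(qseq)) stop("empty query sequence")
  qrc <- rc_string(qseq)
  nrec <- nrow(db$records)
  if (strategy == "auto")
    strategy <- if (nrec > seed_threshold) "seed" else "exhaustive"

  if (strategy == "seed") {
    idxm <- if (!is.null(db$kmer_index)) db$kmer_index
            else kmer_presence(db$records$ungapped_seq)
    qp <- kmer_presence(c(qseq, qrc))
    storage.mode(qp) <- "double"
    shared <- idxm %*% t(qp)
    shared_f <- shared[, 1L]
    shared_r <- shared[, 2L]
    strand_guess <- ifelse(shared_f >= shared_r, "+", "-")
    best_shared <- pmax(shared_f, shared_r)
    cand <- order(best_shared, decreasing = TRUE)[seq_len(min(shortlist, nrec))]
  } else {
    cand <- seq_len(nrec)
    strand_guess <- NULL
  }

  mat <- iupac_score_matrix(scoring)
  refs <- Biostrings::DNAStringSet(db$records$ungapped_seq[cand])
  score_against <- function(q)
    Biostrings::pairwiseAlignment(refs, Biostrings::DNAString(q), type = "local",
                                  substitutionMatrix = mat,
                                  gapOpening = scoring$gap_open,
                                  gapExtension = scoring$gap_extend,
                                  scoreOnly = TRUE)
  if (strategy == "seed") {
    ## align the k-mer-preferred strand only; exact scores on the shortlist
    sc_f <- rep(-Inf, length(cand)); sc_r <- rep(-Inf, length(cand))
    gf <- strand_guess[cand] == "+"
    if (any(gf)) sc_f[gf] <- Biostrings::pairwiseAlignment(
      refs[gf], Biostrings::DNAString(qseq), type = "local",
      substitutionMatrix = mat, gapOpening = scoring$gap_open,
      gapExtension = scoring$gap_extend, scoreOnly = TRUE)
    if (any(!gf)) sc_r[!gf] <- Biostrings::pairwiseAlignment(
      refs[!gf], Biostrings::DNAString(qrc), type = "local",
      substitutionMatrix = mat, gapOpening = scoring$gap_open,
      gapExtension = scoring$gap_extend, scoreOnly = TRUE)
  } else {
    sc_f <- score_against(qseq)
    sc_r <- score_against(qrc)
  }
  best <- pmax(sc_f, sc_r)
  strand <- ifelse(sc_f >= sc_r, "+", "-")

  ## realign the score-competitive candidates to obtain identity/coverage
  kth <- sort(best, decreasing = TRUE)[min(k, length(best))]
  top <- which(best >= kth)
  hits <- do.call(rbind, lapply(top, function(i) {
    ri <- cand[i]
    h <- local_align(if (strand[i] == "+") qseq else qrc,
                     db$records$ungapped_seq[ri], scoring,
                     query_id = qid,
                     subject_accession = db$records$accession[ri],
                     subject_species = db$records$species[ri])
    h$strand <- strand[i]
    h
  }))
  ord <- order(-hits$score, -hits$pct_identity, hits$subject_accession)
  hits <- hits[ord, , drop = FALSE][seq_len(min(k, nrow(hits))), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Build the congener candidate database around a top-hit species
#'
#' Restricts the reference database to every species of the top hit's
#' genus (open-nomenclature entries keyed to that genus included) and
#' subsamples each species to between `n_min` and `n_max` records,
#' uniformly at random; species with `n_min` or fewer records keep all.
#' Deterministic given `seed`.
#'
#' @param top_hit_species Species label present in `db`.
#' @param db A [reference_db()].
#' @param n_min,n_max Per-species subsample bounds (defaults 2 and 8).
#' @param seed Integer seed for reproducible subsampling.
#' @return A [reference_db()] restricted to the candidate records.
#' @export
build_candidate_db <- function(top_hit_species, db, n_min = 2L, n_max = 8L,
                               seed = 1L) {
  if (n_min < 1L || n_min > n_max) stop("need 1 <= n_min <= n_max")
  rec <- db$records
  row <- which(rec$species == top_hit_species)
  if (!length(row))
    stop("species '", top_hit_species, "' not in database; known species: ",
         paste(sort(unique(rec$species)), collapse = ", "))
  genus <- rec$genus[row[1L]]
  species_set <- db$taxonomy[[genus]]
  keep <- integer(0)
  with_preserved_rng({
    set.seed(seed)
    for (sp in sort(species_set)) {
      idx <- which(rec$species == sp)
      if (length(idx) <= n_min) keep <- c(keep, idx)
      else {
        m <- sample(seq(n_min, min(n_max, length(idx))), 1L)
        keep <- c(keep, sort(sample(idx, m)))
      }
    }
  })
  subset_refdb(db, sort(keep))
}

## evaluate `expr` without disturbing the caller's RNG stream
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  eval.parent(substitute(expr))
}

#' Thread a query barcode into the reference alignment
#'
#' Aligns the query (end-gap-free) to the ungapped form of a reference
#' record and projects it through that record's gap pattern into
#' alignment coordinates. Columns the query does not cover are filled
#' with `?`; query insertions relative to the reference are dropped.
#'
#' @param query A [consensus_record()] or ungapped IUPAC string.
#' @param db A [reference_db()].
#' @param ref_accession Reference record to thread through; default is
#'   the query's best local-alignment hit.
#' @param scoring See [local_align()].
#' @return Single aligned string of length `db$alignment_length`;
#'   attribute `covered_columns` gives the number of non-`?` columns (a
#'   warning is emitted below 100).
#' @export
thread_query_onto_alignment <- function(query, db, ref_accession = NULL,
                                        scoring = default_scoring()) {
  if (!nrow(db$records)) stop("empty reference database")
  qseq <- if (inherits(query, "consensus_record")) query$sequence else toupper(query)
  if (is.null(ref_accession)) {
    hit <- search_top_hits(query, db, k = 1L, scoring = scoring)
    ref_accession <- hit$subject_accession[1L]
    if (hit$strand[1L] == "-") qseq <- rc_string(qseq)
  }
  ri <- match(ref_accession, db$records$accession)
  if (is.na(ri)) stop("unknown reference accession '", ref_accession, "'")
  refu <- db$records$ungapped_seq[ri]
  refa <- db$records$aligned_seq[ri]
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(qseq), Biostrings::DNAString(refu),
    type = "overlap", substitutionMatrix = iupac_score_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qchar <- rep("?", nchar(refu))
  nz <- as_ != "-"
  rpos <- pa@subject@range@start + cumsum(nz) - 1L  # ungapped ref position
  qchar[rpos[nz]] <- ifelse(ap[nz] == "-", "-", ap[nz])
  ## project through the reference's gap pattern into alignment columns
  rv <- strsplit(refa, "")[[1]]
  covered <- which(qchar != "?")
  lo <- if (length(covered)) min(covered) else Inf
  hi <- if (length(covered)) max(covered) else -Inf
  m <- !rv %in% c("-", "?")
  up_idx <- cumsum(m)
  out <- character(length(rv))
  out[m] <- qchar[up_idx[m]]
  out[!m] <- ifelse(up_idx[!m] >= lo & up_idx[!m] < hi, "-", "?")
  res <- paste(out, collapse = "")
  ncov <- sum(out != "?")
  if (ncov < 100L)
    warning("threaded query covers only ", ncov, " alignment columns")
  attr(res, "covered_columns") <- ncov
  res
}
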