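## Species-labeled, aligned COI reference databases.
##
## FASTA header dialect: `>accession|species|genus`, with spaces in the
## species name written as underscores. Open nomenclature ("Sphyrna sp.",
## "Rajiformes sp. BOLD AABB") is a legal species label; its genus field
## is then an arbitrary grouping key.

#' Build a reference database of aligned, species-labeled barcodes
#'
#' @param accession Character vector of unique sequence identifiers.
#' @param species Species labels (binomials or open nomenclature).
#' @param genus Genus (grouping key). Defaults to the first token of
#'   `species`.
#' @param aligned_seq Aligned sequences (IUPAC + `-` gaps), one shared
#'   length.
#' @param source_flags Optional character vector of per-record flags
#'   (e.g. `"suspected-mislabel"`), `""` for none.
#' @return Object of class `"reference_db"`: list with `records`
#'   (data.frame), `taxonomy` (genus -> species list) and
#'   `alignment_length`.
#' @export
reference_db <- function(accession, species, genus = NULL, aligned_seq,
                         source_flags = NULL) {
  n <- length(accession)
  if (anyDuplicated(accession)) stop("duplicate accessions")
  if (length(species) != n || length(aligned_seq) != n)
    stop("accession, species and aligned_seq must have equal length")
  if (is.null(genus))
    genus <- vapply(strsplit(species, " ", fixed = TRUE), `[[`, "", 1L)
  if (is.null(source_flags)) source_flags <- rep("", n)
  aligned_seq <- toupper(aligned_seq)
  L <- unique(nchar(aligned_seq))
  if (length(L) != 1L) stop("all aligned sequences must share one length")
  ungapped <- gsub("[-?]", "", aligned_seq)
  if (any(nchar(ungapped) < 100L))
    warning("records with ungapped length < 100: ",
            paste(accession[nchar(ungapped) < 100L], collapse = ", "))
  rec <- data.frame(accession = accession, species = species, genus = genus,
                    aligned_seq = aligned_seq, ungapped_seq = ungapped,
                    source_flags = source_flags, stringsAsFactors = FALSE)
  structure(list(records = rec,
                 taxonomy = lapply(split(rec$species, rec$genus), unique),
                 alignment_length = L),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db: %d records, %d species, %d genera, %d columns>\n",
              nrow(x$records), length(unique(x$records$species)),
              length(x$taxonomy), x$alignment_length))
  invisible(x)
}

#' @export
length.reference_db <- function(x) nrow(x$records)

#' Read a reference database from aligned FASTA
#'
#' Headers must follow `>accession|species|genus` (underscores for spaces
#' in names); a two-field header `>accession|species` derives the genus
#' from the species label.
#'
#' @param file FASTA path.
#' @return A [reference_db()].
#' @export
read_refdb_fasta <- function(file) {
  x <- Biostrings::readBStringSet(file)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop("malformed reference header(s): expected 'accession|species|genus'")
  fix <- function(s) gsub("_", " ", s, fixed = TRUE)
  species <- fix(vapply(parts, `[[`, "", 2L))
  genus <- vapply(seq_along(parts), function(i) {
    if (nf[i] >= 3L) fix(parts[[i]][3L])
    else strsplit(species[i], " ", fixed = TRUE)[[1L]][1L]
  }, "")
  reference_db(accession = vapply(parts, `[[`, "", 1L),
               species = species, genus = genus,
               aligned_seq = as.character(x))
}

#' Write a reference database as aligned FASTA
#' @param db A [reference_db()].
#' @param file Output path.
#' @export
write_refdb_fasta <- function(db, file) {
  und <- function(s) gsub(" ", "_", s, fixed = TRUE)
  seqs <- Biostrings::BStringSet(db$records$aligned_seq)
  names(seqs) <- paste(db$records$accession, und(db$records$species),
                       und(db$records$genus), sep = "|")
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}

#' Restrict a reference database to a subset of records
#' @param db A [reference_db()].
#' @param idx Row indices or logical mask.
#' @return A [reference_db()] over the selected records.
#' @export
subset_refdb <- function(db, idx) {
  r <- db$records[idx, , drop = FALSE]
  reference_db(r$accession, r$species, r$genus, r$aligned_seq, r$source_flags)
}

#' Species-to-label maps from a reference database
#' @param db A [reference_db()].
#' @return Named character vector accession -> species.
#' @export
refdb_species_map <- function(db)
  stats::setNames(db$records$species, db$records$accession)
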