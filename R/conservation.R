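## Market-composition tallies and conservation-status reporting.

STATUS_CATEGORIES <- c("CR", "EN", "VU", "NT", "LC", "DD", "NE", "absent")

#' Read a conservation-status table
#'
#' CSV with columns `species`, `common_name`, `status_global`,
#' `status_national`, `status_regional_1`, `status_regional_2`. Empty
#' cells and `-`/`NA` entries become `"absent"` (no listing at that
#' jurisdiction). Categories follow the IUCN vocabulary: CR, EN, VU, NT,
#' LC, DD, NE.
#'
#' @param file CSV path.
#' @return data.frame (class `"status_table"`).
#' @export
read_status_table <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("species", "common_name", "status_global", "status_national",
            "status_regional_1", "status_regional_2")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("status table lacks columns: ", paste(missing_cols, collapse = ", "))
  for (cl in grep("^status_", names(df), value = TRUE)) {
    v <- trimws(df[[cl]])
    v[v %in% c("", "-", "–", NA)] <- "absent"
    bad <- setdiff(unique(v), STATUS_CATEGORIES)
    if (length(bad))
      stop("unknown categories in ", cl, ": ", paste(bad, collapse = ", "))
    df[[cl]] <- v
  }
  if (anyDuplicated(df$species)) stop("duplicate species in status table")
  class(df) <- c("status_table", "data.frame")
  df
}

## round half away from zero (printed survey convention; base round()
## is round-half-even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Market-composition report from a batch of assignments
#'
#' Per-species counts and percentages (1 decimal, half-up), number of
#' distinct species, and optional per-group tallies (e.g. shark orders /
#' ray orders / teleosts).
#'
#' @param assignments A [batch_assign()] result, its `summary`
#'   data.frame, a list of assignment results, or a character vector of
#'   species.
#' @param group_map Optional named character vector species -> group.
#' @return List (class `"composition_report"`): `table` (species, count,
#'   percent, descending), `n_samples`, `n_species`, `groups` (or NULL).
#' @export
composition <- function(assignments, group_map = NULL) {
  sp <- assignment_species(assignments)
  if (!length(sp)) stop("no assignments to tally")
  cnt <- sort(table(sp), decreasing = TRUE)
  n <- sum(cnt)
  tab <- data.frame(species = names(cnt), count = as.integer(cnt),
                    percent = round_half_up(100 * as.integer(cnt) / n, 1),
                    stringsAsFactors = FALSE)
  groups <- NULL
  if (!is.null(group_map)) {
    unmapped <- setdiff(tab$species, names(group_map))
    if (length(unmapped))
      warning("species without a group mapping: ",
              paste(unmapped, collapse = ", "))
    g <- group_map[sp]
    g[is.na(g)] <- "unmapped"
    gc <- sort(table(g), decreasing = TRUE)
    groups <- data.frame(group = names(gc), count = as.integer(gc),
                         stringsAsFactors = FALSE)
  }
  structure(list(table = tab, n_samples = n, n_species = nrow(tab),
                 groups = groups),
            class = "composition_report")
}

assignment_species <- function(assignments) {
  if (is.character(assignments)) return(assignments)
  if (is.data.frame(assignments)) {
    df <- assignments
    if ("status" %in% names(df)) df <- df[df$status == "ok", , drop = FALSE]
    return(df$candidate_species)
  }
  if (is.list(assignments)) {
    if (!is.null(assignments$summary)) return(assignment_species(assignments$summary))
    ok <- vapply(assignments, inherits, TRUE, "assignment_result")
    return(vapply(assignments[ok], `[[`, "", "candidate_species"))
  }
  stop("cannot extract species from this object")
}

#' @export
print.composition_report <- function(x, ...) {
  cat(sprintf("Market composition: %d samples, %d species\n",
              x$n_samples, x$n_species))
  print(x$table, row.names = FALSE)
  if (!is.null(x$groups)) { cat("Groups:\n"); print(x$groups, row.names = FALSE) }
  invisible(x)
}

#' Fraction of species in a threat-category set at one jurisdiction
#'
#' `100 * |{species with status in category_set at scope}| /
#' |species_list|`, rounded half-up to an integer percent. DD, NE and
#' absent listings never count as threatened but remain in the
#' denominator; species missing from the table entirely are skipped with
#' a warning.
#'
#' @param species_list Distinct species to tally (e.g. the elasmobranchs
#'   found in a survey, restricted via a group map).
#' @param table A [read_status_table()] data.frame.
#' @param scope `"global"`, `"national"`, `"regional_1"` or
#'   `"regional_2"`.
#' @param category_set Categories counting toward the fraction; default
#'   the IUCN threatened set `{CR, EN, VU}`.
#' @return Integer percent; attribute `n_threatened` and `n_species`
#'   give the tally.
#' @export
threat_fractions <- function(species_list, table,
                             scope = c("global", "national",
                                       "regional_1", "regional_2"),
                             category_set = c("CR", "EN", "VU")) {
  scope <- match.arg(scope)
  species_list <- unique(species_list)
  if (!length(species_list)) stop("species_list is empty")
  bad <- setdiff(category_set, setdiff(STATUS_CATEGORIES, "absent"))
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  missing_sp <- setdiff(species_list, table$species)
  if (length(missing_sp)) {
    warning("species not in status table skipped: ",
            paste(missing_sp, collapse = ", "))
    species_list <- setdiff(species_list, missing_sp)
    if (!length(species_list)) stop("no species left to tally")
  }
  col <- paste0("status_", scope)
  st <- table[[col]][match(species_list, table$species)]
  n_thr <- sum(st %in% category_set)
  out <- as.integer(round_half_up(100 * n_thr / length(species_list)))
  attr(out, "n_threatened") <- n_thr
  attr(out, "n_species") <- length(species_list)
  out
}

#' Bundled southern-Brazil market survey fixtures
#'
#' `market_survey_samples()` returns the 63 market/fishing-vessel
#' "cação" samples of a southern-Brazil COI barcoding survey with their
#' species identifications, taxonomic groups and top-hit summary
#' statistics; `market_survey_status()` returns the conservation-status
#' table (global IUCN, national, and two state-level red lists) for the
#' 17 described elasmobranch species found there.
#'
#' @return A data.frame ([market_survey_samples()]) or a
#'   [read_status_table()] result ([market_survey_status()]).
#' @export
market_survey_samples <- function() {
  f <- system.file("extdata", "market_survey_samples.csv",
                   package = "coidentify", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' @rdname market_survey_samples
#' @export
market_survey_status <- function() {
  f <- system.file("extdata", "market_survey_status.csv",
                   package = "coidentify", mustWork = TRUE)
  read_status_table(f)
}

#' Write a threat-fraction report as JSON
#'
#' @param species_list Species to tally (see [threat_fractions()]).
#' @param table Status table.
#' @param file Output path.
#' @param category_sets Named list of category sets to report at every
#'   jurisdiction.
#' @return The report list, invisibly written as JSON if `jsonlite` is
#'   available, else as `dput` text.
#' @export
threat_report <- function(species_list, table, file = NULL,
                          category_sets = list(threatened = c("CR", "EN", "VU"),
                                               critically_endangered = "CR")) {
  scopes <- c("global", "national", "regional_1", "regional_2")
  rep <- lapply(category_sets, function(cs)
    stats::setNames(lapply(scopes, function(sc)
      as.integer(threat_fractions(species_list, table, sc, cs))), scopes))
  if (!is.null(file)) {
    if (requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(rep, file, auto_unbox = TRUE)
    else dput(rep, file)
  }
  invisible(rep)
}
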