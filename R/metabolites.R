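#' Load a genome-predicted metabolite database
#'
#' Reads a metabolite database from delimited text with columns `name`,
#' `formula`, `function`, `pathway_class`, `strains` plus 0/1 provenance and
#' detection flags. Every formula must parse (and is re-canonicalized to Hill
#' notation), every function label must appear in the controlled vocabulary,
#' `pathway_class` must be one of `biosynthetic`, `degradation`,
#' `spontaneous`, `secondary`, and duplicate (name, formula) rows are
#' rejected. With no arguments, returns the packaged database of the 43
#' annotated biosynthetic-pathway exometabolites of *Dinoroseobacter shibae*
#' and *Phaeobacter inhibens* with their detection, fragmentation and
#' environmental-DOM presence flags.
#'
#' @param path Path to a TSV metabolite database; `NULL` for the packaged one.
#' @param vocabulary A function-label vocabulary tibble from
#'   [function_groups()], used to validate labels.
#' @return A tibble with one row per metabolite record.
#' @examples
#' db <- metabolite_db()
#' nrow(db) # 43
#' @export
metabolite_db <- function(path = NULL, vocabulary = function_groups()) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_metabolites.tsv",
                        package = "exometab", mustWork = TRUE)
  }
  db <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("name", "formula", "function", "pathway_class", "strains")
  missing <- setdiff(required, names(db))
  if (length(missing)) {
    stop("metabolite database is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!nrow(db)) {
    return(db)
  }
  canonical <- tryCatch(parse_formula(db$formula)$formula, error = function(e) {
    bad <- which(vapply(db$formula, function(f) {
      inherits(tryCatch(parse_formula(f), error = identity), "error")
    }, TRUE))
    stop("invalid formula '", db$formula[bad[1]], "' in record '",
         db$name[bad[1]], "'", call. = FALSE)
  })
  db$formula <- canonical
  bad_label <- !db[["function"]] %in% vocabulary$function_label
  if (any(bad_label)) {
    stop("unknown function label '", db[["function"]][bad_label][1],
         "' in record '", db$name[bad_label][1], "'; vocabulary: ",
         paste(vocabulary$function_label, collapse = ", "), call. = FALSE)
  }
  classes <- c("biosynthetic", "degradation", "spontaneous", "secondary")
  if (!all(db$pathway_class %in% classes)) {
    stop("pathway_class must be one of: ", paste(classes, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(db[c("name", "formula")])) {
    stop("duplicate (name, formula) rows in metabolite database",
         call. = FALSE)
  }
  db
}

#' Controlled vocabulary mapping function labels to functional groups
#'
#' Each function label used in the metabolite database maps to exactly one
#' functional group (vitamin-related, quorum-sensing, amino-acid-related,
#' auxin-related, siderophore, defense-antibiotic, nucleoside, other).
#'
#' @param path Path to a two-column TSV (`function_label`, `group`); `NULL`
#'   for the packaged vocabulary.
#' @return A tibble with columns `function_label` and `group`.
#' @export
function_groups <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "function_groups.tsv",
                        package = "exometab", mustWork = TRUE)
  }
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Match detected formulas against a metabolite database
#'
#' A database record matches iff its canonical formula string equals one of
#' the detected formulas (structural isomers are indistinguishable at formula
#' level, so every match is putative). Records sharing a formula with another
#' record are flagged `formula_degenerate`.
#'
#' @param detected Character vector of canonical detected formula strings.
#' @param db A metabolite database tibble from [metabolite_db()].
#' @return The matching database rows with an added `formula_degenerate`
#'   logical column, in database order.
#' @examples
#' match_formulas("C17H20N4O6", metabolite_db())$name # Riboflavin
#' @export
match_formulas <- function(detected, db) {
  dup <- db$formula %in% db$formula[duplicated(db$formula)]
  out <- db[db$formula %in% detected, , drop = FALSE]
  out$formula_degenerate <- dup[db$formula %in% detected]
  out
}

#' Count matched metabolites per pathway class
#'
#' The four pathway classes partition the matched records, so the counts sum
#' to the number of distinct matched records.
#'
#' @param matches A match tibble from [match_formulas()] (one strain).
#' @return A tibble with columns `pathway_class` and `n`, all four classes
#'   always present (zero-filled).
#' @export
class_counts <- function(matches) {
  classes <- c("biosynthetic", "degradation", "spontaneous", "secondary")
  matches |>
    dplyr::distinct(.data$name, .data$formula, .keep_all = TRUE) |>
    dplyr::count(pathway_class = factor(.data$pathway_class, levels = classes),
                 .drop = FALSE) |>
    dplyr::mutate(pathway_class = as.character(.data$pathway_class))
}

#' Count matched metabolites per functional group
#'
#' Groups matched records by the controlled vocabulary and reports distinct
#' record counts plus percentages of the matched total (the denominator the
#' printed per-strain percentages use).
#'
#' @param matches A match tibble from [match_formulas()] (one strain).
#' @param vocabulary Vocabulary tibble from [function_groups()].
#' @return A tibble with columns `group`, `n`, `pct`.
#' @export
function_group_counts <- function(matches, vocabulary = function_groups()) {
  bad <- !matches[["function"]] %in% vocabulary$function_label
  if (any(bad)) {
    stop("function label '", matches[["function"]][bad][1],
         "' absent from the grouping vocabulary", call. = FALSE)
  }
  total <- nrow(dplyr::distinct(matches, .data$name, .data$formula))
  matches |>
    dplyr::distinct(.data$name, .data$formula, .keep_all = TRUE) |>
    dplyr::left_join(vocabulary, by = c("function" = "function_label")) |>
    dplyr::count(group = factor(.data$group, levels = unique(vocabulary$group)),
                 .drop = FALSE) |>
    dplyr::mutate(group = as.character(.data$group),
                  pct = if (total > 0) .data$n / total * 100 else 0)
}

#' Detection frequency of metabolites across sampled time points
#'
#' From a long presence table (one row per metabolite x sample column of the
#' detection matrix), computes per metabolite the fraction of non-excluded
#' sample time points in which it was detected, as a percentage, with the
#' denominator reported alongside.
#'
#' @param detections A tibble with columns `name`, a sample identifier
#'   (anything defining the columns of the detection matrix), and a logical
#'   `detected`.
#' @return A tibble with columns `name`, `n_detected`, `n_samples`,
#'   `frequency_pct`.
#' @export
detection_frequency <- function(detections) {
  if (!nrow(detections)) {
    stop("detection frequency is undefined for zero sample columns",
         call. = FALSE)
  }
  detections |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(n_detected = sum(.data$detected),
                     n_samples = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(frequency_pct = .data$n_detected / .data$n_samples * 100)
}

#' Shared and total metabolite counts between two strains
#'
#' Set cardinalities with the inclusion-exclusion identity
#' `n_total = n_a + n_b - n_shared` (holds by construction on sets and is
#' recomputed for the report).
#'
#' @param formulas_a,formulas_b Character vectors of the distinct matched
#'   formulas (or record keys) per strain.
#' @return A one-row tibble: `n_a`, `n_b`, `n_shared`, `n_total`.
#' @examples
#' shared_between_strains(c("A", "B"), c("B", "C"))
#' @export
shared_between_strains <- function(formulas_a, formulas_b) {
  a <- unique(formulas_a)
  b <- unique(formulas_b)
  tibble::tibble(n_a = length(a), n_b = length(b),
                 n_shared = length(intersect(a, b)),
                 n_total = length(union(a, b)))
}
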