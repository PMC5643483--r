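#' Annotation-only reporting pipeline on a metabolite database
#'
#' Runs the reporting half of the pipeline directly from a metabolite
#' database carrying per-strain detection flags (i.e. after spectra have been
#' assigned, blank-subtracted and matched): per-strain matched-record counts,
#' pathway-class counts, functional-group counts with percentages, the
#' shared/total breakdown between the two strains, and the overlap of the
#' identified formulas with each environmental DOM formula set.
#'
#' @param db Metabolite database tibble with `detected_dshibae` and
#'   `detected_pinhibens` flag columns; defaults to the packaged database.
#' @param dom_sets Named list of DOM formula sets to screen against.
#' @param vocabulary Function-label vocabulary from [function_groups()].
#' @return An object of class `"exometab_annotation"`: a list with elements
#'   `matches` (named list of per-strain match tibbles), `counts`,
#'   `class_counts`, `function_groups`, `shared`, `dom_overlap`, `table1`
#'   (the annotated report table from [render_table1()]) and `db`.
#'   `glance()` returns the headline counts as a one-row tibble.
#' @examples
#' ann <- run_annotation()
#' glance(ann)
#' @export
run_annotation <- function(db = metabolite_db(),
                           dom_sets = list(mesocosm = dom_set("mesocosm"),
                                           north_sea = dom_set("north_sea")),
                           vocabulary = function_groups()) {
  stopifnot(all(c("detected_dshibae", "detected_pinhibens") %in% names(db)))
  detected <- list(
    D_shibae = db$formula[db$detected_dshibae == 1],
    P_inhibens = db$formula[db$detected_pinhibens == 1])
  matches <- lapply(detected, match_formulas, db = db)
  counts <- tibble::tibble(
    strain = names(matches),
    n_detected = unname(vapply(matches, function(m) {
      nrow(dplyr::distinct(m, .data$name, .data$formula))
    }, 1L)))
  cls <- dplyr::bind_rows(lapply(matches, class_counts), .id = "strain")
  fg <- dplyr::bind_rows(
    lapply(matches, function_group_counts, vocabulary = vocabulary),
    .id = "strain")
  shared <- shared_between_strains(matches$D_shibae$formula,
                                   matches$P_inhibens$formula)
  dom <- dplyr::bind_rows(lapply(dom_sets, function(set) {
    dom_overlap(matches$D_shibae$formula, matches$P_inhibens$formula, set)
  }), .id = "dom_set")
  screens <- lapply(dom_sets, function(set) {
    screen_dom(dplyr::bind_rows(matches) |>
                 dplyr::distinct(.data$name, .data$formula, .keep_all = TRUE),
               set)
  })
  structure(list(matches = matches, counts = counts, class_counts = cls,
                 function_groups = fg, shared = shared, dom_overlap = dom,
                 table1 = render_table1(db, matches, screens), db = db),
            class = "exometab_annotation")
}

#' @export
print.exometab_annotation <- function(x, ...) {
  cat("<exometab_annotation>\n")
  cat(" detected records:",
      paste(x$counts$strain, x$counts$n_detected, collapse = ", "), "\n")
  cat(" shared:", x$shared$n_shared, "of", x$shared$n_total, "total\n")
  if (nrow(x$dom_overlap)) {
    cat(" DOM overlap:", paste(x$dom_overlap$dom_set, x$dom_overlap$n_total,
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname run_annotation
#' @param x An `exometab_annotation` object.
#' @param ... Unused.
#' @export
glance.exometab_annotation <- function(x, ...) {
  fg <- function(strain, group) {
    v <- x$function_groups
    n <- v$n[v$strain == strain & v$group == group]
    if (length(n)) n else 0L
  }
  dom <- function(set) {
    n <- x$dom_overlap$n_total[x$dom_overlap$dom_set == set]
    if (length(n)) n else NA_integer_
  }
  tibble::tibble(
    n_dshibae = x$counts$n_detected[x$counts$strain == "D_shibae"],
    n_pinhibens = x$counts$n_detected[x$counts$strain == "P_inhibens"],
    n_total = x$shared$n_total,
    n_shared = x$shared$n_shared,
    vitamin_dshibae = fg("D_shibae", "vitamin-related"),
    vitamin_pinhibens = fg("P_inhibens", "vitamin-related"),
    qs_dshibae = fg("D_shibae", "quorum-sensing"),
    qs_pinhibens = fg("P_inhibens", "quorum-sensing"),
    aa_dshibae = fg("D_shibae", "amino-acid-related"),
    aa_pinhibens = fg("P_inhibens", "amino-acid-related"),
    mesocosm_overlap = dom("mesocosm"),
    north_sea_overlap = dom("north_sea"))
}

#' Render the annotated metabolite report table
#'
#' One row per database metabolite with its formula, function, pathway
#' class, fragmentation flag, per-strain detection recomputed from the match
#' results, and per-DOM-set presence recomputed from the screening results.
#' Row order follows the database; column order is fixed, so a report built
#' from the packaged database round-trips to the packaged file byte for byte.
#'
#' @param db Metabolite database tibble.
#' @param matches Named list with elements `D_shibae` and `P_inhibens`
#'   holding the per-strain match tibbles.
#' @param screens Named list (`mesocosm`, `north_sea`) of screened match
#'   tibbles from [screen_dom()].
#' @return A tibble with the fixed report columns.
#' @export
render_table1 <- function(db, matches, screens) {
  present_in <- function(set_names) as.integer(db$name %in% set_names)
  tibble::tibble(
    name = db$name,
    formula = db$formula,
    `function` = db[["function"]],
    pathway_class = db$pathway_class,
    strains = db$strains,
    fragmentation_confirmed = db$fragmentation_confirmed,
    detected_dshibae = present_in(matches$D_shibae$name),
    detected_pinhibens = present_in(matches$P_inhibens$name),
    other_studies = db$other_studies,
    mesocosm = present_in(screens$mesocosm$name[screens$mesocosm$present]),
    north_sea = present_in(screens$north_sea$name[screens$north_sea$present]))
}

#' Full pipeline from simulated or measured peak lists to matched records
#'
#' Executes filter, optional internal recalibration, formula assignment,
#' blank subtraction, lysis-based sample exclusion, per-group formula union
#' and database matching, for a collection of sample/blank peak-list pairs.
#'
#' @param samples A list of sample entries; each entry is a list with
#'   elements `peaks` (sample peak tibble), `blank` (blank peak tibble or
#'   `NULL`), and metadata fields `strain`, `substrate`, `time_h`,
#'   `replicate` (any may be omitted), and optionally `lysis_flag` and
#'   `reference_mz` for recalibration.
#' @param db Metabolite database to match against.
#' @param cfg An [assignment_config()].
#' @param min_snr,mass_window Peak filter parameters ([filter_peaks()]).
#' @return A list with `assignments` (long tibble over all samples),
#'   `detections` (long sample x formula table after blank subtraction),
#'   `union` (per-strain distinct formulas, lysis-excluded), and `matches`
#'   (per-strain match tibbles).
#' @export
run_pipeline <- function(samples, db = metabolite_db(),
                         cfg = assignment_config(), min_snr = 5,
                         mass_window = c(92, 2000)) {
  per_sample <- purrr::imap(samples, function(s, i) {
    meta <- tibble::tibble(
      sample_id = if (!is.null(s$id)) s$id else as.character(i),
      strain = s$strain %||% NA_character_,
      substrate = s$substrate %||% NA_character_,
      time_h = s$time_h %||% NA_real_,
      replicate = s$replicate %||% 1L,
      lysis_flag = isTRUE(s$lysis_flag))
    pk <- filter_peaks(s$peaks, min_snr, mass_window)
    if (!is.null(s$reference_mz)) {
      pk <- calibrate_peaks(pk, s$reference_mz)
    }
    assigned <- assign_peaks(pk, cfg)
    sample_set <- formula_set(assigned)
    if (!is.null(s$blank) && nrow(s$blank)) {
      blank_assigned <- assign_peaks(filter_peaks(s$blank, min_snr,
                                                  mass_window), cfg)
      sample_set <- subtract_blank(sample_set, formula_set(blank_assigned))
    }
    list(assigned = dplyr::bind_cols(meta[rep(1, nrow(assigned)), ],
                                     assigned),
         detections = dplyr::bind_cols(meta[rep(1, length(sample_set)), ],
                                       tibble::tibble(formula = sample_set)))
  })
  empty_detections <- tibble::tibble(
    sample_id = character(), strain = character(), substrate = character(),
    time_h = numeric(), replicate = integer(), lysis_flag = logical(),
    formula = character())
  assignments <- dplyr::bind_rows(purrr::map(per_sample, "assigned"))
  detections <- dplyr::bind_rows(empty_detections,
                                 purrr::map(per_sample, "detections"))
  uni <- union_formulas(detections, .data$strain)
  matches <- lapply(stats::setNames(uni$formulas, uni$strain),
                    match_formulas, db = db)
  list(assignments = assignments, detections = detections, union = uni,
       matches = matches)
}
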