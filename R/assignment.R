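#' Configuration for molecular formula assignment
#'
#' Bundles the mass tolerance, element count ranges and plausibility filters
#' used by [enumerate_candidates()] and [assign_peaks()]. Defaults follow
#' common practice for 15 T FT-ICR dissolved organic matter work: 0.5 ppm
#' tolerance; C 1-100, H 1-200, N 0-6, O 0-40, S 0-3, P 0-2;
#' 0.3 <= H/C <= 2.5; O/C <= 1.2; 0 <= DBE <= 25; and integer DBE (the
#' even-electron rule for neutral molecules).
#'
#' @param tolerance_ppm Mass tolerance in ppm (> 0).
#' @param element_ranges Named list of `c(min, max)` integer count ranges for
#'   elements C, H, N, O, S, P. C min must be >= 1.
#' @param hc_range Allowed H/C ratio range.
#' @param oc_max Maximum allowed O/C ratio.
#' @param dbe_range Allowed double-bond-equivalent range.
#' @param require_integer_dbe Require integer DBE (reject odd-electron /
#'   charged compositions)?
#' @return A list of class `"assignment_config"`.
#' @examples
#' assignment_config(tolerance_ppm = 0.2)
#' @export
assignment_config <- function(tolerance_ppm = 0.5,
                              element_ranges = list(C = c(1, 100), H = c(1, 200),
                                                    N = c(0, 6), O = c(0, 40),
                                                    S = c(0, 3), P = c(0, 2)),
                              hc_range = c(0.3, 2.5),
                              oc_max = 1.2,
                              dbe_range = c(0, 25),
                              require_integer_dbe = TRUE) {
  stopifnot(tolerance_ppm > 0,
            all(c("C", "H", "N", "O", "S", "P") %in% names(element_ranges)),
            all(vapply(element_ranges, length, 1L) == 2),
            all(vapply(element_ranges, function(r) r[1] <= r[2], TRUE)),
            element_ranges$C[1] >= 1,
            length(hc_range) == 2, hc_range[1] <= hc_range[2],
            oc_max > 0,
            length(dbe_range) == 2, dbe_range[1] <= dbe_range[2])
  structure(list(tolerance_ppm = tolerance_ppm,
                 element_ranges = lapply(element_ranges, as.integer),
                 hc_range = hc_range, oc_max = oc_max,
                 dbe_range = dbe_range,
                 require_integer_dbe = isTRUE(require_integer_dbe)),
            class = "assignment_config")
}

#' @export
print.assignment_config <- function(x, ...) {
  rng <- vapply(x$element_ranges, function(r) paste0(r[1], ":", r[2]), "")
  cat("<assignment_config>\n",
      " tolerance_ppm: ", x$tolerance_ppm, "\n",
      " elements: ", paste(names(rng), rng, sep = "=", collapse = " "), "\n",
      " H/C: [", x$hc_range[1], ", ", x$hc_range[2], "]",
      "  O/C <= ", x$oc_max,
      "  DBE: [", x$dbe_range[1], ", ", x$dbe_range[2], "]",
      if (x$require_integer_dbe) " (integer)" else "", "\n", sep = "")
  invisible(x)
}

# apply the plausibility filters of a config to a candidate tibble with
# columns C,H,N,O,S,P and dbe
.apply_filters <- function(cand, cfg) {
  er <- cfg$element_ranges
  ok <- cand$H >= er$H[1] & cand$H <= er$H[2] &
    cand$C >= er$C[1] & cand$C <= er$C[2] &
    cand$H / cand$C >= cfg$hc_range[1] & cand$H / cand$C <= cfg$hc_range[2] &
    cand$O / cand$C <= cfg$oc_max &
    cand$dbe >= cfg$dbe_range[1] & cand$dbe <= cfg$dbe_range[2]
  if (cfg$require_integer_dbe) {
    ok <- ok & abs(cand$dbe - round(cand$dbe)) < 1e-9
  }
  cand[ok, , drop = FALSE]
}

#' Enumerate candidate molecular formulas for a neutral mass
#'
#' Exhaustively enumerates all CHNOSP formulas within the configured element
#' ranges whose monoisotopic mass lies within `tolerance_ppm` of the observed
#' neutral mass and which pass every plausibility filter. Nested loops run
#' over N, S, P and O; C and H are bounded analytically by the remaining mass,
#' which prunes the search without changing the result set relative to a
#' naive full enumeration. Candidates are sorted by increasing absolute mass
#' error, ties broken by heteroatom count (N+S+P) then Hill string.
#'
#' @param mass Observed neutral monoisotopic mass in Da (length 1).
#' @param cfg An [assignment_config()].
#' @return A tibble with columns `formula`, `mass` (theoretical), `error_ppm`
#'   (observed minus theoretical, relative to theoretical), `dbe`,
#'   `heteroatoms`, and the element counts. Zero rows when nothing matches.
#' @examples
#' enumerate_candidates(376.138284) # riboflavin C17H20N4O6
#' @export
enumerate_candidates <- function(mass, cfg = assignment_config()) {
  stopifnot(is.numeric(mass), length(mass) == 1, mass > 0)
  em <- .element_mass_vector()
  er <- cfg$element_ranges
  tol <- cfg$tolerance_ppm
  hi <- mass * (1 + tol * 1e-6)
  lo <- mass * (1 - tol * 1e-6)

  nspo <- expand.grid(N = er$N[1]:er$N[2], S = er$S[1]:er$S[2],
                      P = er$P[1]:er$P[2], O = er$O[1]:er$O[2],
                      KEEP.OUT.ATTRS = FALSE)
  base <- nspo$N * em["N"] + nspo$S * em["S"] + nspo$P * em["P"] +
    nspo$O * em["O"]
  # prune: leave room for at least Cmin carbons and Hmin hydrogens
  feasible <- base <= hi - er$C[1] * em["C"] - er$H[1] * em["H"]
  nspo <- nspo[feasible, , drop = FALSE]
  base <- base[feasible]
  if (!nrow(nspo)) {
    return(.empty_candidates())
  }
  # analytic carbon bound per NSPO combination, then expand the C dimension
  cmax <- pmin(er$C[2], floor((hi - base - er$H[1] * em["H"]) / em["C"]))
  nrep <- pmax(cmax - er$C[1] + 1L, 0L)
  idx <- rep.int(seq_len(nrow(nspo)), nrep)
  C <- unlist(lapply(seq_len(nrow(nspo)), function(i) {
    if (nrep[i] > 0) er$C[1]:cmax[i] else integer(0)
  }), use.names = FALSE)
  if (!length(C)) {
    return(.empty_candidates())
  }
  rem <- mass - base[idx] - C * em["C"]
  # the tolerance window is far narrower than one H mass, so at most one
  # integer H per (C,N,S,P,O) combination can land inside it
  H <- as.integer(round(rem / em["H"]))
  cand <- tibble::tibble(C = C, H = H, N = nspo$N[idx], O = nspo$O[idx],
                         S = nspo$S[idx], P = nspo$P[idx])
  cand$mass <- base[idx] + C * em["C"] + H * em["H"]
  cand <- cand[cand$H >= 1 & cand$mass >= lo & cand$mass <= hi, , drop = FALSE]
  if (!nrow(cand)) {
    return(.empty_candidates())
  }
  cand$dbe <- 1 + cand$C - cand$H / 2 + (cand$N + cand$P) / 2
  cand <- .apply_filters(cand, cfg)
  if (!nrow(cand)) {
    return(.empty_candidates())
  }
  cand$error_ppm <- (mass - cand$mass) / cand$mass * 1e6
  cand$heteroatoms <- cand$N + cand$S + cand$P
  cand$formula <- format_formula(cand)
  ord <- order(abs(cand$error_ppm), cand$heteroatoms, cand$formula)
  dplyr::select(cand[ord, ], "formula", "mass", "error_ppm", "dbe",
                "heteroatoms", "C", "H", "N", "O", "S", "P")
}

.empty_candidates <- function() {
  tibble::tibble(formula = character(), mass = numeric(),
                 error_ppm = numeric(), dbe = numeric(),
                 heteroatoms = integer(), C = integer(), H = integer(),
                 N = integer(), O = integer(), S = integer(), P = integer())
}

#' Select the accepted candidate from an enumerated, sorted candidate list
#'
#' Deterministic selection: smallest absolute mass error, ties broken by
#' fewest heteroatoms (N+S+P) then lexicographic Hill string — i.e. the first
#' row of [enumerate_candidates()] output. The result is flagged ambiguous
#' when a runner-up lies within 0.1 ppm of the accepted candidate's absolute
#' error, surfacing rather than hiding near-ties.
#'
#' @param cands A candidate tibble as returned by [enumerate_candidates()].
#' @return A one-row tibble with columns `formula` (`NA` when unassigned),
#'   `error_ppm`, `dbe`, `heteroatoms`, `ambiguous`, `n_candidates`.
#' @export
select_best <- function(cands) {
  if (!nrow(cands)) {
    return(tibble::tibble(formula = NA_character_, error_ppm = NA_real_,
                          dbe = NA_real_, heteroatoms = NA_integer_,
                          ambiguous = FALSE, n_candidates = 0L))
  }
  ambiguous <- nrow(cands) >= 2 &&
    abs(cands$error_ppm[2]) - abs(cands$error_ppm[1]) < 0.1
  tibble::tibble(formula = cands$formula[1], error_ppm = cands$error_ppm[1],
                 dbe = cands$dbe[1],
                 heteroatoms = as.integer(cands$heteroatoms[1]),
                 ambiguous = ambiguous, n_candidates = nrow(cands))
}

#' Assign molecular formulas to every peak of a filtered, calibrated spectrum
#'
#' Converts each peak's m/z to a neutral mass under the spectrum's ionization
#' mode, enumerates candidate formulas and accepts at most one per peak via
#' [select_best()]. Peaks without an acceptable candidate carry `NA` in
#' `formula` and are excluded from the spectrum's formula set.
#'
#' @param peaks A peak list tibble (already S/N- and window-filtered); its
#'   `mode` column is used unless `mode` is given.
#' @param cfg An [assignment_config()].
#' @param mode Optional ionization mode overriding the `mode` column.
#' @return The peak tibble with appended columns `neutral_mass`, `formula`,
#'   `error_ppm`, `dbe`, `heteroatoms`, `ambiguous`, `n_candidates`. A
#'   one-row summary tibble (assigned / unassigned / ambiguous counts and
#'   median absolute error) is attached as attribute `"summary"`, retrievable
#'   with `assignment_summary()`; the set of accepted formulas with
#'   `formula_set()`.
#' @export
assign_peaks <- function(peaks, cfg = assignment_config(), mode = NULL) {
  if (is.null(mode)) {
    stopifnot("mode" %in% names(peaks))
    mode <- peaks$mode
  }
  if (!nrow(peaks)) {
    out <- dplyr::mutate(peaks, neutral_mass = numeric(0),
                         formula = character(0), error_ppm = numeric(0),
                         dbe = numeric(0), heteroatoms = integer(0),
                         ambiguous = logical(0), n_candidates = integer(0))
  } else {
    nm <- neutral_mass(peaks$mz, mode)
    sel <- purrr::map_dfr(nm, function(m) select_best(enumerate_candidates(m, cfg)))
    out <- dplyr::bind_cols(peaks, tibble::tibble(neutral_mass = nm), sel)
  }
  smry <- tibble::tibble(
    n_peaks = nrow(out),
    n_assigned = sum(!is.na(out$formula)),
    n_unassigned = sum(is.na(out$formula)),
    n_ambiguous = sum(out$ambiguous),
    median_abs_error_ppm = stats::median(abs(out$error_ppm), na.rm = TRUE))
  attr(out, "summary") <- smry
  out
}

#' @rdname assign_peaks
#' @export
assignment_summary <- function(peaks) {
  attr(peaks, "summary")
}

#' @rdname assign_peaks
#' @export
formula_set <- function(peaks) {
  unique(peaks$formula[!is.na(peaks$formula)])
}

#' Union of assigned formula sets across samples
#'
#' Collapses a long detection table (one row per sample x accepted formula,
#' blank-subtracted) to the distinct formulas per group, excluding samples
#' flagged for suspected cell lysis. This is the set whose cardinality is the
#' "molecular formulas detected" headline count per strain or per
#' strain x substrate.
#'
#' @param detections A tibble with a `formula` column, optional `lysis_flag`
#'   logical column, and grouping columns.
#' @param ... Grouping columns (tidy-select), e.g. `strain` or
#'   `strain, substrate`.
#' @param exclude_lysis Drop rows with `lysis_flag == TRUE` before the union?
#' @return A tibble with the grouping columns, `n_formulas`, and a `formulas`
#'   list-column of the distinct formula strings.
#' @export
union_formulas <- function(detections, ..., exclude_lysis = TRUE) {
  df <- detections
  if (exclude_lysis && "lysis_flag" %in% names(df)) {
    df <- dplyr::filter(df, !.data$lysis_flag)
  }
  df <- dplyr::filter(df, !is.na(.data$formula))
  df |>
    dplyr::group_by(...) |>
    dplyr::summarise(formulas = list(unique(.data$formula)), .groups = "drop") |>
    dplyr::mutate(n_formulas = lengths(.data$formulas), .before = "formulas")
}
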