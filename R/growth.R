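#' Fit an exponential growth rate to a batch growth curve
#'
#' The growth rate is defined as the slope of the least-squares line through
#' `ln(value)` over the contiguous window of at least `min_points`
#' observations that maximizes R-squared (ties broken by longer window, then
#' earlier start) — the standard batch-culture estimator, deterministic given
#' the tie rules. Only strictly positive values can enter a window.
#'
#' @param data A data frame of one replicate's growth curve.
#' @param time,value Columns of `data` holding time (hours, strictly
#'   increasing) and the measured quantity (OD, cells/mL or relative
#'   fluorescence).
#' @param min_points Minimum window length (>= 4).
#' @return An object of class `"growth_fit"`: list with elements `rate`
#'   (per hour), `r_squared`, `window` (start/end times), `n_points`,
#'   `model` (the `lm` fit) and `data`. Methods: [tidy.growth_fit()],
#'   [glance.growth_fit()], [autoplot.growth_fit()], `print()`.
#' @examples
#' d <- data.frame(t = 0:7, od = 0.05 * exp(0.1 * (0:7)))
#' fit_growth_rate(d, t, od)$rate # 0.1
#' @export
fit_growth_rate <- function(data, time, value, min_points = 4) {
  stopifnot(min_points >= 4)
  t <- dplyr::pull(data, {{ time }})
  v <- dplyr::pull(data, {{ value }})
  stopifnot(length(t) == length(v), !is.unsorted(t, strictly = TRUE))
  n <- length(v)
  best <- NULL
  for (i in seq_len(n)) {
    if (v[i] <= 0) next
    for (j in i:n) {
      if (v[j] <= 0) break # windows must be contiguous in positive values
      len <- j - i + 1
      if (len < min_points) next
      tt <- t[i:j]
      lv <- log(v[i:j])
      # closed-form simple regression: R^2 = Sxy^2 / (Sxx * Syy)
      sxx <- sum((tt - mean(tt))^2)
      syy <- sum((lv - mean(lv))^2)
      sxy <- sum((tt - mean(tt)) * (lv - mean(lv)))
      # a zero-variance window carries no growth signal: R^2 is 0/0 there,
      # scored as 0 so constant stretches never outrank true log-linear ones
      # (an all-constant curve still returns slope 0 through the tie rules)
      r2 <- if (syy < 1e-12) 0 else sxy^2 / (sxx * syy)
      if (is.null(best) ||
          r2 > best$r2 + 1e-9 ||
          (abs(r2 - best$r2) <= 1e-9 &&
           (len > best$j - best$i + 1 ||
            (len == best$j - best$i + 1 && i < best$i)))) {
        best <- list(i = i, j = j, r2 = r2)
      }
    }
  }
  if (is.null(best)) {
    stop("no contiguous stretch of >= ", min_points,
         " positive values for rate fitting", call. = FALSE)
  }
  tt <- t[best$i:best$j]
  lv <- log(v[best$i:best$j])
  fit <- stats::lm(lv ~ tt)
  structure(list(rate = unname(stats::coef(fit)[2]),
                 r_squared = best$r2,
                 window = c(start = t[best$i], end = t[best$j]),
                 n_points = best$j - best$i + 1,
                 model = fit,
                 data = tibble::tibble(time = t, value = v)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> rate =", format(x$rate, digits = 4), "per h",
      " R^2 =", format(x$r_squared, digits = 4),
      " window [", x$window[1], ",", x$window[2], "] h (",
      x$n_points, "points )\n")
  invisible(x)
}

#' Broom-style methods for growth fits
#'
#' `tidy()` returns the per-term coefficients of the log-linear window fit;
#' `glance()` a one-row model summary.
#'
#' @param x A `growth_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.growth_fit <- function(x, ...) {
  # exact (noise-free) curves produce perfect fits; the precision warning
  # from summary.lm is expected there
  s <- suppressWarnings(summary(x$model))$coefficients
  tibble::tibble(term = c("log_intercept", "rate"),
                 estimate = unname(s[, 1]),
                 std_error = unname(s[, 2]),
                 statistic = unname(s[, 3]),
                 p_value = unname(s[, 4]))
}

#' @rdname tidy.growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(rate = x$rate, r_squared = x$r_squared,
                 window_start = unname(x$window[1]),
                 window_end = unname(x$window[2]),
                 n_points = x$n_points)
}

#' @rdname tidy.growth_fit
#' @importFrom ggplot2 autoplot
#' @param object A `growth_fit` object.
#' @export
autoplot.growth_fit <- function(object, ...) {
  win <- object$data$time >= object$window[1] & object$data$time <= object$window[2]
  pred <- exp(stats::predict(object$model))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = tibble::tibble(time = object$data$time[win],
                                             value = pred),
                       color = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "value (log scale)",
                  title = sprintf("rate = %.3g / h over [%g, %g] h",
                                  object$rate, object$window[1],
                                  object$window[2]))
}

#' Fit one growth rate per replicate curve
#'
#' Convenience wrapper around [fit_growth_rate()] for long tables of
#' replicate growth curves.
#'
#' @param data Long tibble of curves.
#' @param time,value Time and measurement columns.
#' @param ... Grouping columns identifying one curve (e.g. `arm, replicate`).
#' @return A tibble with the grouping columns plus `rate`, `r_squared`,
#'   `n_points`.
#' @export
fit_replicate_rates <- function(data, time, value, ...) {
  data |>
    dplyr::group_by(...) |>
    dplyr::group_modify(function(d, key) {
      glance.growth_fit(fit_growth_rate(d, {{ time }}, {{ value }}))[
        c("rate", "r_squared", "n_points")]
    }) |>
    dplyr::ungroup()
}

#' Growth stimulation of a treated arm relative to a control
#'
#' Percent enhancement `100 * (mean_treated - mean_control) / mean_control`
#' of replicate growth rates (or yields), with a two-sided two-sample
#' Student's t-test (equal variance). The significance threshold is reported,
#' not enforced. Arms whose data are essentially constant are handled
#' exactly: p = 1 when the means are equal, p = 0 otherwise.
#'
#' @param treated,control Numeric vectors of replicate rates or yields
#'   (>= 2 each).
#' @param alpha Reported significance threshold.
#' @return A one-row tibble: `percent_enhancement`, `p_value`, `significant`,
#'   `mean_treated`, `mean_control`, `n_treated`, `n_control`, `alpha`.
#' @examples
#' stimulation(c(1.22, 1.22, 1.22), c(1, 1, 1))$percent_enhancement # 22
#' @export
stimulation <- function(treated, control, alpha = 0.01) {
  if (length(treated) < 2 || length(control) < 2) {
    stop("need >= 2 replicates in each arm for the t-test", call. = FALSE)
  }
  pct <- 100 * (mean(treated) - mean(control)) / mean(control)
  p <- tryCatch(
    stats::t.test(treated, control, var.equal = TRUE)$p.value,
    error = function(e) {
      if (isTRUE(all.equal(mean(treated), mean(control)))) 1 else 0
    })
  tibble::tibble(percent_enhancement = pct, p_value = p,
                 significant = p < alpha,
                 mean_treated = mean(treated), mean_control = mean(control),
                 n_treated = length(treated), n_control = length(control),
                 alpha = alpha)
}

#' Convert cell abundance to biomass carbon
#'
#' `cells_per_ml * fg_c_per_cell` femtograms of carbon per mL, expressed in
#' mg C per liter (factor 1e-9). The default 50 fg C per cell is typical for
#' large, fast-growing heterotrophic bacteria.
#'
#' @param cells_per_ml Cell abundance (cells per mL, >= 0).
#' @param fg_c_per_cell Carbon content per cell (fg C, >= 0).
#' @return Biomass carbon in mg C per liter.
#' @examples
#' cells_to_carbon(1.39e9, 50) # 69.5 mg C / L
#' @export
cells_to_carbon <- function(cells_per_ml, fg_c_per_cell = 50) {
  if (any(cells_per_ml < 0) || any(fg_c_per_cell < 0)) {
    stop("cell abundance and per-cell carbon must be non-negative",
         call. = FALSE)
  }
  cells_per_ml * fg_c_per_cell * 1e-9
}

#' Carbon atoms per protein amino acid
#'
#' @return A tibble with columns `amino_acid` and `carbon_atoms`, from the
#'   packaged resource table.
#' @export
aa_carbon_table <- function() {
  readr::read_tsv(system.file("extdata", "aa_carbon_counts.tsv",
                              package = "exometab", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' Carbon bound in a dissolved amino acid pool
#'
#' Per-residue mode: sum over amino acids of concentration (uM) x carbon
#' atoms x 12.011 x 1e-3 mg C per liter (average atomic weight of carbon, as
#' appropriate for bulk budgets). Bulk mode (`aa_carbon_bulk()`): a single
#' total concentration is converted with a configurable mean
#' carbon-per-residue parameter, reported alongside.
#'
#' @param profile A tibble with columns `amino_acid` and `conc_um` (uM).
#' @param carbon_counts Carbon-count table, by default [aa_carbon_table()].
#' @return `aa_carbon()`: total mg C per liter. `aa_carbon_bulk()`: a one-row
#'   tibble with `mg_c_per_l` and the `mean_c_per_residue` used.
#' @examples
#' aa_carbon(data.frame(amino_acid = "glycine", conc_um = 100)) # 2.4022
#' @export
aa_carbon <- function(profile, carbon_counts = aa_carbon_table()) {
  if (!nrow(profile)) {
    return(0)
  }
  stopifnot(all(c("amino_acid", "conc_um") %in% names(profile)),
            all(profile$conc_um >= 0))
  missing <- setdiff(profile$amino_acid, carbon_counts$amino_acid)
  if (length(missing)) {
    stop("no carbon count for amino acid(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::left_join(profile, carbon_counts, by = "amino_acid")
  sum(joined$conc_um * joined$carbon_atoms * 12.011 * 1e-3)
}

#' @rdname aa_carbon
#' @param conc_um Bulk dissolved combined amino acid concentration (uM).
#' @param mean_c_per_residue Mean carbon atoms per amino acid residue used
#'   when only a bulk concentration is available.
#' @export
aa_carbon_bulk <- function(conc_um, mean_c_per_residue = 4.36) {
  stopifnot(conc_um >= 0, mean_c_per_residue > 0)
  tibble::tibble(mg_c_per_l = conc_um * mean_c_per_residue * 12.011 * 1e-3,
                 mean_c_per_residue = mean_c_per_residue)
}

#' Carbon mass balance and cell-lysis flag
#'
#' Compares the carbon bound in dissolved combined amino acids (DCAA) with
#' the carbon bound in bacterial biomass. A DCAA fraction above the threshold
#' indicates protein released by lysed cells; flagged samples are excluded
#' from the formula-set unions. The default threshold of 5% separates the
#' lysis regime (about 17-21% of biomass carbon) from the minimal-lysis
#' regime (< 1%).
#'
#' @param cells_per_ml Cell abundance (cells per mL, > 0), vectorized.
#' @param dcaa_c DCAA-bound carbon (mg C per liter), vectorized.
#' @param fg_c_per_cell Carbon per cell (fg C).
#' @param threshold Lysis flag threshold on the DCAA carbon fraction.
#' @return A tibble with columns `cells_per_ml`, `fg_c_per_cell`,
#'   `biomass_c`, `dcaa_c`, `dcaa_fraction`, `lysis_flag`.
#' @examples
#' lysis_check(1.39e9, 11.5) # fraction 0.165, flagged
#' @export
lysis_check <- function(cells_per_ml, dcaa_c, fg_c_per_cell = 50,
                        threshold = 0.05) {
  biomass_c <- cells_to_carbon(cells_per_ml, fg_c_per_cell)
  if (any(biomass_c <= 0)) {
    stop("biomass carbon must be positive for a mass balance", call. = FALSE)
  }
  stopifnot(all(dcaa_c >= 0))
  frac <- dcaa_c / biomass_c
  tibble::tibble(cells_per_ml = cells_per_ml, fg_c_per_cell = fg_c_per_cell,
                 biomass_c = biomass_c, dcaa_c = dcaa_c,
                 dcaa_fraction = frac, lysis_flag = frac > threshold)
}

#' Molar percentage composition of a component pool
#'
#' Each component's concentration divided by the pool total, times 100.
#' Scale-invariant; the output sums to 100 within 1e-9.
#'
#' @param x Named numeric vector of concentrations, or a two-column data
#'   frame (component, concentration). At least one value must be positive.
#' @return A tibble with columns `component` and `mol_pct`.
#' @examples
#' molpercent(c(glucose = 3, galactose = 1))
#' @export
molpercent <- function(x) {
  if (is.data.frame(x)) {
    comp <- as.character(x[[1]])
    conc <- x[[2]]
  } else {
    comp <- names(x)
    conc <- unname(x)
  }
  stopifnot(all(conc >= 0))
  if (sum(conc) <= 0) {
    stop("mol%% is undefined for an all-zero composition", call. = FALSE)
  }
  tibble::tibble(component = comp, mol_pct = conc / sum(conc) * 100)
}
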