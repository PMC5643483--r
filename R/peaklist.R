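#' Read a peak list from delimited text
#'
#' Reads one ionization-mode spectrum (one row per detected singly charged
#' ion) from a TSV or CSV file with header columns `mz`, `intensity`, `snr`
#' (case-insensitive; the delimiter is auto-detected from the header line).
#' Peaks are sorted by m/z and duplicate rows within 1e-6 Da are merged by
#' summing intensity and keeping the maximum signal-to-noise ratio; rows with
#' non-positive m/z or intensity, or negative S/N, are dropped with a message.
#'
#' @param path Path to the delimited text file.
#' @param mode Ionization mode, `"negative"` or `"positive"`; determines the
#'   adduct assumed downstream by [neutral_mass()].
#' @param strain,substrate,time_h,phase,replicate Sample metadata recorded as
#'   columns on the returned peak list.
#' @param is_blank `TRUE` for a sterile-control (blank) spectrum.
#' @return A tibble with columns `mz`, `intensity`, `snr`, `mode`, `strain`,
#'   `substrate`, `time_h`, `phase`, `replicate`, `is_blank`, sorted by
#'   strictly increasing `mz`.
#' @export
read_peaklist <- function(path, mode = c("negative", "positive"),
                          strain = NA_character_, substrate = NA_character_,
                          time_h = NA_real_, phase = NA_character_,
                          replicate = 1L, is_blank = FALSE) {
  mode <- match.arg(mode)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, col_types = readr::cols(.default = "c"))
  names(raw) <- tolower(names(raw))
  for (col in c("mz", "intensity", "snr")) {
    if (!col %in% names(raw)) {
      stop("peak list '", path, "' is missing required column '", col, "'",
           call. = FALSE)
    }
  }
  num <- lapply(raw[c("mz", "intensity", "snr")],
                function(x) suppressWarnings(as.numeric(x)))
  bad <- which(Reduce(`|`, lapply(num, is.na)))
  if (length(bad)) {
    stop("non-numeric value in '", path, "' at data line ", bad[1],
         " (file line ", bad[1] + 1L, ")", call. = FALSE)
  }
  pl <- tibble::tibble(mz = num$mz, intensity = num$intensity, snr = num$snr)
  n_in <- nrow(pl)
  pl <- dplyr::filter(pl, .data$mz > 0, .data$intensity > 0, .data$snr >= 0)
  if (nrow(pl) < n_in) {
    message("read_peaklist: dropped ", n_in - nrow(pl),
            " invalid row(s) of ", n_in, " in ", basename(path))
  }
  pl <- merge_peaks(pl)
  tibble::add_column(pl, mode = mode, strain = strain, substrate = substrate,
                     time_h = time_h, phase = phase,
                     replicate = as.integer(replicate), is_blank = is_blank)
}

# sort ascending by mz and merge runs of peaks closer than `tol` Da:
# intensity-weighted mean m/z, summed intensity, max snr
merge_peaks <- function(pl, tol = 1e-6) {
  pl <- dplyr::arrange(pl, .data$mz)
  if (nrow(pl) < 2) {
    return(pl)
  }
  grp <- cumsum(c(1, diff(pl$mz) > tol))
  pl |>
    dplyr::group_by(grp = grp) |>
    dplyr::summarise(
      mz = sum(.data$mz * .data$intensity) / sum(.data$intensity),
      intensity = sum(.data$intensity),
      snr = max(.data$snr),
      .groups = "drop") |>
    dplyr::select(-"grp")
}

#' Filter peaks by signal-to-noise ratio and mass window
#'
#' Retains peaks with `snr >= min_snr` and `mass_window[1] <= mz <=
#' mass_window[2]` (both boundaries inclusive). Defaults reproduce the
#' standard FT-ICR-MS processing rule: minimum S/N of 5 within the detected
#' window of 92 to 2,000 Da. Idempotent and order-preserving.
#'
#' @param peaks A peak list tibble (columns `mz` and `snr` required).
#' @param min_snr Minimum signal-to-noise ratio (inclusive).
#' @param mass_window Numeric length-2 vector, inclusive m/z window in Da.
#' @return The filtered peak list.
#' @examples
#' pl <- tibble::tibble(mz = c(91.9, 200, 200), intensity = 1,
#'                      snr = c(50, 4.9, 5))
#' filter_peaks(pl)
#' @export
filter_peaks <- function(peaks, min_snr = 5, mass_window = c(92, 2000)) {
  stopifnot(length(mass_window) == 2, mass_window[1] < mass_window[2])
  dplyr::filter(peaks, .data$snr >= min_snr,
                .data$mz >= mass_window[1], .data$mz <= mass_window[2])
}

#' Internally recalibrate a peak list against reference masses
#'
#' Matches each reference m/z to the closest observed peak within
#' `match_tol_ppm`, fits the least-squares linear model
#' `mz_corrected = slope * mz + intercept` on the matched pairs, and applies
#' it to every peak. With fewer than two matched references the spectrum is
#' returned unchanged, flagged uncalibrated, with a warning.
#'
#' @param peaks A peak list tibble.
#' @param reference_mz Numeric vector of reference m/z values (Da) from the
#'   internal calibration list.
#' @param match_tol_ppm Match tolerance between reference and observed peak.
#' @return The peak list with corrected `mz`, carrying a `calibration`
#'   attribute (one-row tibble: `calibrated`, `slope`, `intercept`,
#'   `n_matched`, `median_abs_ppm_before`, `median_abs_ppm_after`);
#'   retrieve it with `calibration()`.
#' @export
calibrate_peaks <- function(peaks, reference_mz, match_tol_ppm = 1) {
  obs <- peaks$mz
  matched_obs <- numeric(0)
  matched_ref <- numeric(0)
  for (ref in reference_mz) {
    if (!length(obs)) break
    i <- which.min(abs(obs - ref))
    if (abs(obs[i] - ref) / ref * 1e6 <= match_tol_ppm) {
      matched_obs <- c(matched_obs, obs[i])
      matched_ref <- c(matched_ref, ref)
    }
  }
  if (length(matched_ref) < 2) {
    warning("calibration failed: ", length(matched_ref),
            " reference mass(es) matched (need >= 2); spectrum left uncalibrated",
            call. = FALSE)
    attr(peaks, "calibration") <- tibble::tibble(
      calibrated = FALSE, slope = 1, intercept = 0,
      n_matched = length(matched_ref),
      median_abs_ppm_before = NA_real_, median_abs_ppm_after = NA_real_)
    return(peaks)
  }
  fit <- stats::lm(matched_ref ~ matched_obs)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (abs(slope - 1) > 1e-3) {
    warning("calibration slope ", format(slope),
            " outside the sanity bound 1 +/- 1e-3", call. = FALSE)
  }
  before <- stats::median(abs(matched_obs - matched_ref) / matched_ref * 1e6)
  corr_obs <- slope * matched_obs + intercept
  after <- stats::median(abs(corr_obs - matched_ref) / matched_ref * 1e6)
  peaks$mz <- slope * peaks$mz + intercept
  attr(peaks, "calibration") <- tibble::tibble(
    calibrated = TRUE, slope = slope, intercept = intercept,
    n_matched = length(matched_ref),
    median_abs_ppm_before = before, median_abs_ppm_after = after)
  peaks
}

#' @rdname calibrate_peaks
#' @export
calibration <- function(peaks) {
  attr(peaks, "calibration")
}

#' Convert between detected m/z and neutral mass
#'
#' Singly charged ions are assumed: positive mode is the protonated molecule
#' (`M = mz - m_proton`), negative mode the deprotonated molecule
#' (`M = mz + m_proton`), with the proton mass (atomic H minus one electron)
#' taken from [element_masses()]. `ionize_mass()` is the exact inverse.
#'
#' @param mz,neutral Numeric vectors of ion m/z or neutral mass (Da).
#' @param mode `"negative"` or `"positive"` (recycled).
#' @return Numeric vector of neutral masses (or ion m/z for `ionize_mass()`).
#' @examples
#' neutral_mass(377.14556, "positive") # riboflavin [M+H]+ -> 376.13828
#' @export
neutral_mass <- function(mz, mode) {
  mode <- match.arg(mode, c("negative", "positive"), several.ok = TRUE)
  mode <- rep_len(mode, length(mz))
  out <- ifelse(mode == "positive", mz - proton_mass(), mz + proton_mass())
  if (any(out <= 0)) {
    stop("non-positive neutral mass: m/z below the proton mass in positive mode",
         call. = FALSE)
  }
  out
}

#' @rdname neutral_mass
#' @export
ionize_mass <- function(neutral, mode) {
  mode <- match.arg(mode, c("negative", "positive"), several.ok = TRUE)
  mode <- rep_len(mode, length(neutral))
  stopifnot(all(neutral > 0))
  ifelse(mode == "positive", neutral + proton_mass(), neutral - proton_mass())
}

#' Subtract the sterile-control (blank) signal from a sample
#'
#' The default, deterministic rule operates after formula assignment: the
#' blank's formula set is removed from the sample's formula set by canonical
#' string identity. A mass-level variant for unassigned peak lists removes
#' every sample peak lying within `tol_ppm` of any blank peak.
#'
#' @param sample_formulas,blank_formulas Character vectors of canonical
#'   formula strings for the same mode and time point.
#' @return `subtract_blank()`: the sample formulas not present in the blank,
#'   original order preserved. `subtract_blank_mz()`: the sample peak tibble
#'   without blank-matched peaks.
#' @examples
#' subtract_blank(c("C6H12O6", "C2H4O2", "C5H5N5"), "C2H4O2")
#' @export
subtract_blank <- function(sample_formulas, blank_formulas) {
  sample_formulas[!sample_formulas %in% blank_formulas]
}

#' @rdname subtract_blank
#' @param sample_peaks,blank_peaks Peak list tibbles (column `mz`).
#' @param tol_ppm Mass tolerance for the peak-level variant.
#' @export
subtract_blank_mz <- function(sample_peaks, blank_peaks, tol_ppm = 0.5) {
  if (!nrow(blank_peaks)) {
    return(sample_peaks)
  }
  bmz <- sort(blank_peaks$mz)
  i <- findInterval(sample_peaks$mz, bmz)
  lo <- bmz[pmax(i, 1L)]
  hi <- bmz[pmin(i + 1L, length(bmz))]
  near <- pmin(abs(sample_peaks$mz - lo), abs(sample_peaks$mz - hi))
  dplyr::filter(sample_peaks, near / .data$mz * 1e6 > tol_ppm)
}
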