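# Seeded generators for every input the pipeline consumes, with ground-truth
# manifests so each stage is testable without external data.

#' Generate random plausible CHNOS decoy formulas
#'
#' Draws element counts and an integer DBE target, solves for the hydrogen
#' count, and keeps only compositions that pass the same plausibility filters
#' as real candidates (otherwise decoys would be trivially rejected and
#' recovery tests uninformative). Uses the current RNG state.
#'
#' @param n Number of decoys.
#' @param mass_range Allowed neutral mass window (Da).
#' @param exclude Canonical formulas that must not be generated (e.g. the
#'   database formulas, so decoys never collide with true records).
#' @param cfg An [assignment_config()] whose filters decoys must pass.
#' @param max_tries Rejection-sampling budget per decoy; exhausting it is a
#'   generation error.
#' @return Character vector of `n` distinct canonical formulas.
#' @export
simulate_decoy_formulas <- function(n, mass_range = c(92, 2000),
                                    exclude = character(),
                                    cfg = assignment_config(),
                                    max_tries = 1e4) {
  out <- character(0)
  tries <- 0
  cmax_mass <- floor(mass_range[2] / 12)
  while (length(out) < n) {
    tries <- tries + 1
    if (tries > max_tries) {
      stop("decoy generation failed plausibility ", max_tries,
           " times; configuration impossible", call. = FALSE)
    }
    C <- sample(seq(max(5, cfg$element_ranges$C[1]),
                    min(cfg$element_ranges$C[2], cmax_mass, 30)), 1)
    N <- sample(0:min(3, cfg$element_ranges$N[2]), 1)
    O <- sample(0:min(15, cfg$element_ranges$O[2]), 1)
    S <- sample(0:min(1, cfg$element_ranges$S[2]), 1)
    dbe <- sample(cfg$dbe_range[1]:min(cfg$dbe_range[2], C), 1)
    H <- 2 * (1 + C - dbe) + N
    if (H < cfg$element_ranges$H[1] || H > cfg$element_ranges$H[2]) next
    if (H / C < cfg$hc_range[1] || H / C > cfg$hc_range[2]) next
    if (O / C > cfg$oc_max) next
    f <- format_formula(data.frame(C = C, H = H, N = N, O = O, S = S, P = 0))
    m <- formula_mass(f)
    if (m < mass_range[1] || m > mass_range[2]) next
    if (f %in% exclude || f %in% out) next
    out <- c(out, f)
  }
  out
}

#' Simulate a sample/blank peak-list pair with a ground-truth manifest
#'
#' Emulates one ionization-mode FT-ICR-MS peak list of a culture supernatant:
#' `n_true` formulas drawn from the metabolite database plus `n_decoys`
#' random plausible CHNOS decoys, ionized under `mode`, with relative mass
#' error drawn from Normal(0, `ppm_sigma`), lognormal intensities, and S/N
#' drawn uniformly with a configurable fraction below the S/N = 5 filter
#' threshold. The sterile-control blank shares exactly `blank_contaminants`
#' contaminant formulas with the sample. Fully deterministic under `seed`.
#'
#' @param db Metabolite database tibble ([metabolite_db()]); required when
#'   `n_true > 0`.
#' @param n_true Number of database formulas in the sample (sampled without
#'   replacement; capped at `nrow(db)`).
#' @param n_decoys Number of decoy formulas.
#' @param ppm_sigma Standard deviation of the relative mass error (ppm).
#' @param mode Ionization mode for all peaks.
#' @param intensity_meanlog,intensity_sdlog Lognormal intensity parameters.
#' @param snr_range Uniform S/N range for peaks above the filter threshold.
#' @param low_snr_frac Fraction of sample peaks drawn with S/N below 5.
#' @param blank_contaminants Number of contaminant formulas present in both
#'   the sample and the blank.
#' @param mass_range Neutral mass window for decoys and contaminants.
#' @param cfg Assignment configuration used to certify decoys and to mark
#'   which true formulas pass the plausibility filters in the manifest.
#' @param seed Integer seed fixing all randomness; `NULL` uses the RNG as-is.
#' @return A list with elements `sample` (peak tibble), `blank` (peak
#'   tibble), and `manifest`: one row per sample peak with `formula`,
#'   `true_mass`, `mz`, `ppm_error`, `intensity`, `snr`, `role`
#'   (`"true"`, `"decoy"`, `"contaminant"`), `passes_filters`, `in_window`
#'   and `expected_detectable` (S/N >= 5, inside the mass window, passes the
#'   filters, and not a blank contaminant) — sufficient to recompute every
#'   expected downstream output.
#' @export
simulate_spectrum <- function(db = NULL, n_true = 0, n_decoys = 0,
                              ppm_sigma = 0.1,
                              mode = c("negative", "positive"),
                              intensity_meanlog = log(1e7),
                              intensity_sdlog = 1,
                              snr_range = c(5, 200), low_snr_frac = 0,
                              blank_contaminants = 0,
                              mass_range = c(92, 2000),
                              cfg = assignment_config(), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(ppm_sigma >= 0, n_true >= 0, n_decoys >= 0,
            blank_contaminants >= 0, low_snr_frac >= 0, low_snr_frac <= 1)
  if (!is.null(seed)) {
    set.seed(seed)
  }
  if (n_true > 0) {
    stopifnot(!is.null(db), nrow(db) > 0)
    n_true <- min(n_true, nrow(db))
    true_f <- sample(db$formula, n_true)
  } else {
    true_f <- character(0)
  }
  exclude <- if (!is.null(db)) db$formula else character(0)
  decoy_f <- simulate_decoy_formulas(n_decoys, mass_range, exclude, cfg)
  cont_f <- simulate_decoy_formulas(blank_contaminants, mass_range,
                                    c(exclude, decoy_f), cfg)
  formulas <- c(true_f, decoy_f, cont_f)
  role <- c(rep("true", length(true_f)), rep("decoy", length(decoy_f)),
            rep("contaminant", length(cont_f)))
  n <- length(formulas)
  if (!n) {
    empty <- tibble::tibble(mz = numeric(), intensity = numeric(),
                            snr = numeric(), mode = character(),
                            is_blank = logical())
    return(list(sample = empty, blank = empty,
                manifest = tibble::tibble(formula = character(),
                                          true_mass = numeric(),
                                          mz = numeric(), ppm_error = numeric(),
                                          intensity = numeric(), snr = numeric(),
                                          role = character(),
                                          passes_filters = logical(),
                                          in_window = logical(),
                                          expected_detectable = logical())))
  }
  true_mass <- formula_mass(formulas)
  err <- stats::rnorm(n, 0, ppm_sigma)
  mz <- ionize_mass(true_mass, mode) * (1 + err * 1e-6)
  intensity <- stats::rlnorm(n, intensity_meanlog, intensity_sdlog)
  snr <- stats::runif(n, max(5, snr_range[1]), snr_range[2])
  n_low <- round(low_snr_frac * n)
  if (n_low > 0) {
    low_idx <- sample.int(n, n_low)
    snr[low_idx] <- stats::runif(n_low, 0, 5)
  }
  counts <- parse_formula(formulas)
  counts$dbe <- formula_dbe(counts)
  passes <- counts$formula %in% .apply_filters(counts, cfg)$formula
  in_window <- true_mass >= mass_range[1] & true_mass <= mass_range[2]
  manifest <- tibble::tibble(
    formula = formulas, true_mass = true_mass, mz = mz, ppm_error = err,
    intensity = intensity, snr = snr, role = role,
    passes_filters = passes, in_window = in_window,
    expected_detectable = snr >= 5 & in_window & passes &
      role != "contaminant")
  sample_pl <- merge_peaks(tibble::tibble(mz = mz, intensity = intensity,
                                          snr = snr))
  sample_pl$mode <- mode
  sample_pl$is_blank <- FALSE
  # the blank re-observes the contaminant formulas with its own mass errors
  is_cont <- role == "contaminant"
  blank_err <- stats::rnorm(sum(is_cont), 0, ppm_sigma)
  blank_pl <- tibble::tibble(
    mz = ionize_mass(true_mass[is_cont], mode) * (1 + blank_err * 1e-6),
    intensity = stats::rlnorm(sum(is_cont), intensity_meanlog,
                              intensity_sdlog),
    snr = stats::runif(sum(is_cont), max(5, snr_range[1]), snr_range[2]))
  blank_pl <- merge_peaks(blank_pl)
  blank_pl$mode <- mode
  blank_pl$is_blank <- TRUE
  list(sample = sample_pl, blank = blank_pl, manifest = manifest)
}

#' Simulate Monod batch growth with substrate depletion
#'
#' Integrates the standard Monod batch model
#' `dX/dt = mu_max * S / (Ks + S) * X`,
#' `dS/dt = -(1 / yield) * mu_max * S / (Ks + S) * X`
#' with a fixed-step 4th-order Runge-Kutta scheme (`dt <= 0.01 / mu_max`
#' enforced for stability), then applies multiplicative lognormal observation
#' noise with the requested coefficient of variation. In the noise-free
#' signal, biomass is monotone non-decreasing and substrate monotone
#' non-increasing, and carbon is conserved:
#' `x(t) - x0 = yield * (s0 - s(t))`.
#'
#' @param mu_max Maximum specific growth rate (per hour, > 0).
#' @param ks Half-saturation (Monod) constant (mM, > 0).
#' @param yield_coeff Biomass yield (OD units per mM substrate, > 0).
#' @param s0,x0 Initial substrate (mM) and biomass (OD), both > 0.
#' @param dt Integration and output step (h); must satisfy
#'   `dt <= 0.01 / mu_max`.
#' @param t_end End time (h).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   observation noise (0 for none).
#' @param seed Integer seed; `NULL` uses the RNG as-is.
#' @return A tibble with columns `time_h`, `biomass`, `substrate` (noise-free
#'   signals) and `biomass_obs` (noisy observation).
#' @examples
#' sim <- simulate_batch_growth(mu_max = 0.3, dt = 0.02, t_end = 10)
#' @export
simulate_batch_growth <- function(mu_max = 0.3, ks = 0.1, yield_coeff = 0.2,
                                  s0 = 5, x0 = 0.01, dt = 0.02, t_end = 48,
                                  noise_cv = 0, seed = NULL) {
  if (any(c(mu_max, ks, yield_coeff, s0, x0, dt, t_end) <= 0)) {
    stop("all Monod parameters must be positive", call. = FALSE)
  }
  if (dt > 0.01 / mu_max + 1e-12) {
    stop("dt = ", dt, " exceeds the stability bound 0.01 / mu_max = ",
         format(0.01 / mu_max), call. = FALSE)
  }
  if (!is.null(seed)) {
    set.seed(seed)
  }
  deriv <- function(t, y, parms) {
    mu <- mu_max * y[2] / (ks + y[2])
    list(c(mu * y[1], -mu * y[1] / yield_coeff))
  }
  times <- seq(0, t_end, by = dt)
  sol <- deSolve::ode(y = c(x = x0, s = s0), times = times, func = deriv,
                      parms = NULL, method = "rk4")
  out <- tibble::tibble(time_h = sol[, "time"],
                        biomass = sol[, "x"],
                        substrate = pmax(sol[, "s"], 0))
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    out$biomass_obs <- out$biomass *
      stats::rlnorm(nrow(out), -sdlog^2 / 2, sdlog)
  } else {
    out$biomass_obs <- out$biomass
  }
  out
}

#' Simulate a diatom growth-stimulation experiment
#'
#' Emulates chlorophyll fluorescence curves of axenic diatom cultures grown
#' with and without a supplemented growth factor: the treated arm's true
#' exponential rate is the control rate times `stimulation_factor`, replicate
#' rates are perturbed by iid multiplicative lognormal noise, and each
#' replicate's curve is exact exponential growth at its realized rate. The
#' truth is recorded in the returned manifest.
#'
#' @param mu_control True control growth rate (per hour).
#' @param stimulation_factor Ratio of treated to control true rate (> 0).
#' @param n_replicates Replicates per arm (>= 2).
#' @param noise_cv Coefficient of variation of the replicate rate noise.
#' @param f0 Initial relative fluorescence.
#' @param t_end,dt_obs Duration and observation interval (h).
#' @param seed Integer seed; `NULL` uses the RNG as-is.
#' @return A list with `curves` (long tibble: `arm`, `replicate`, `time_h`,
#'   `fluorescence`) and `manifest` (one row per curve with the realized
#'   `true_rate` and the generating parameters).
#' @examples
#' sim <- simulate_diatom_experiment(stimulation_factor = 1.22, noise_cv = 0)
#' @export
simulate_diatom_experiment <- function(mu_control = 0.04,
                                       stimulation_factor = 1,
                                       n_replicates = 3, noise_cv = 0,
                                       f0 = 100, t_end = 168, dt_obs = 12,
                                       seed = NULL) {
  stopifnot(mu_control > 0, stimulation_factor > 0)
  if (n_replicates < 2) {
    stop("need >= 2 replicates per arm", call. = FALSE)
  }
  if (!is.null(seed)) {
    set.seed(seed)
  }
  times <- seq(0, t_end, by = dt_obs)
  sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
  arms <- tibble::tibble(
    arm = rep(c("control", "treated"), each = n_replicates),
    replicate = rep(seq_len(n_replicates), 2),
    base_rate = rep(c(mu_control, mu_control * stimulation_factor),
                    each = n_replicates))
  arms$true_rate <- arms$base_rate *
    (if (sdlog > 0) stats::rlnorm(nrow(arms), -sdlog^2 / 2, sdlog) else 1)
  curves <- arms |>
    dplyr::rowwise() |>
    dplyr::reframe(arm = .data$arm, replicate = .data$replicate,
                   time_h = times,
                   fluorescence = f0 * exp(.data$true_rate * times))
  manifest <- dplyr::select(arms, "arm", "replicate", "base_rate", "true_rate")
  manifest$stimulation_factor <- stimulation_factor
  manifest$noise_cv <- noise_cv
  list(curves = curves, manifest = manifest)
}
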