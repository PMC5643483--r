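test_that("enumeration finds the known formula for riboflavin's mass", {
  cands <- enumerate_candidates(376.138284)
  expect_true("C17H20N4O6" %in% cands$formula)
  # every candidate satisfies the tolerance definitionally
  expect_true(all(abs(cands$error_ppm) <= 0.5))
  recomputed <- abs(formula_mass(cands$formula) - 376.138284) /
    formula_mass(cands$formula) * 1e6
  expect_true(all(recomputed <= 0.5))
})

test_that("a bare-carbon mass yields no candidates under default filters", {
  # 12 C = 144 Da exactly, but H >= 1 and H/C >= 0.3 forbid pure carbon
  expect_equal(nrow(enumerate_candidates(144.0)), 0)
})

test_that("pruned enumeration equals the brute-force oracle", {
  set.seed(11)
  masses <- c(runif(10, 92, 800),
              formula_mass(replicate(10, random_plausible_formula())) *
                (1 + runif(10, -0.4, 0.4) * 1e-6))
  for (m in masses) {
    got <- enumerate_candidates(m)$formula
    want <- oracle_enumerate(m)
    expect_setequal(got, want)
  }
})

test_that("enlarging tolerance or element ranges never removes candidates", {
  set.seed(3)
  masses <- formula_mass(replicate(5, random_plausible_formula())) *
    (1 + runif(5, -0.3, 0.3) * 1e-6)
  for (m in masses) {
    base <- enumerate_candidates(m)$formula
    wider_tol <- enumerate_candidates(m, assignment_config(tolerance_ppm = 2))
    expect_true(all(base %in% wider_tol$formula))
    er <- assignment_config()$element_ranges
    er$N <- c(0, 10)
    er$S <- c(0, 5)
    wider_el <- enumerate_candidates(m, assignment_config(element_ranges = er))
    expect_true(all(base %in% wider_el$formula))
  }
})

test_that("selection is deterministic: |ppm| then heteroatoms then Hill string", {
  cand <- function(f, err, het) {
    tibble::tibble(formula = f, mass = 100, error_ppm = err, dbe = 1,
                   heteroatoms = het)
  }
  # primary key dominates
  two <- dplyr::bind_rows(cand("C4H8N2S", 0.1, 3), cand("C6H12", 0.3, 0))
  expect_equal(select_best(two)$formula, "C4H8N2S")
  # tie on |ppm|: fewer heteroatoms wins
  tie <- dplyr::bind_rows(cand("C6H12", 0.2, 0), cand("C4H8N2S", -0.2, 3))
  tie <- tie[order(abs(tie$error_ppm), tie$heteroatoms), ]
  expect_equal(select_best(tie)$formula, "C6H12")
  expect_true(select_best(tie)$ambiguous) # within 0.1 ppm of each other
  # empty input is the unassigned marker
  empty <- select_best(enumerate_candidates(144.0))
  expect_true(is.na(empty$formula))
  expect_equal(empty$n_candidates, 0L)
})

test_that("assignment of a clean synthetic spectrum recovers the truth", {
  db <- metabolite_db()
  sim <- simulate_spectrum(db, n_true = 20, ppm_sigma = 0, seed = 101)
  assigned <- assign_peaks(sim$sample)
  smry <- assignment_summary(assigned)
  expect_equal(smry$n_peaks, 20)
  eligible <- sim$manifest[sim$manifest$expected_detectable, ]
  hit <- assigned$formula[match(round(eligible$mz, 6),
                                round(assigned$mz, 6))]
  expect_equal(hit, eligible$formula)
  expect_true(all(eligible$formula %in% formula_set(assigned)))
})

test_that("assignment of an empty peak list is empty but well-formed", {
  empty <- tibble::tibble(mz = numeric(), intensity = numeric(),
                          snr = numeric(), mode = character())
  out <- assign_peaks(empty)
  expect_equal(nrow(out), 0)
  expect_true(all(c("formula", "error_ppm", "ambiguous") %in% names(out)))
  expect_equal(assignment_summary(out)$n_assigned, 0)
  expect_equal(formula_set(out), character(0))
})

test_that("unmatchable peaks stay unassigned and out of the formula set", {
  pl <- tibble::tibble(mz = ionize_mass(144.0, "negative"), intensity = 1,
                       snr = 10, mode = "negative")
  out <- assign_peaks(pl)
  expect_true(is.na(out$formula))
  expect_equal(formula_set(out), character(0))
})

test_that("every database formula at 0 ppm is recovered or explicitly
          unassigned, never misassigned", {
  db <- metabolite_db()
  dbe <- formula_dbe(db$formula)
  for (mode in c("negative", "positive")) {
    mz <- ionize_mass(formula_mass(db$formula), mode)
    out <- assign_peaks(tibble::tibble(mz = mz, intensity = 1, snr = 10),
                        mode = mode)
    recovered <- !is.na(out$formula) & out$formula == db$formula
    misassigned <- !is.na(out$formula) & out$formula != db$formula &
      !out$ambiguous
    expect_equal(sum(misassigned), 0)
    # the only losses are the two half-integer-DBE anion compositions,
    # rejected by the even-electron rule and left explicitly unassigned
    unrec <- db$formula[!recovered & !out$ambiguous]
    expect_true(all(unrec %in% db$formula[abs(dbe - round(dbe)) > 1e-9]))
  }
})

test_that("formula-set unions respect grouping and lysis exclusion", {
  det <- tibble::tibble(
    strain = c("A", "A", "A", "B", "B"),
    formula = c("X", "Y", "Y", "Y", "Z"),
    lysis_flag = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  uni <- union_formulas(det, strain)
  expect_equal(uni$n_formulas[uni$strain == "A"], 2)
  expect_equal(uni$n_formulas[uni$strain == "B"], 1) # lysis row excluded
  uni_all <- union_formulas(det, strain, exclude_lysis = FALSE)
  expect_equal(uni_all$n_formulas[uni_all$strain == "B"], 2)
  expect_equal(nrow(union_formulas(det[0, ], strain)), 0)
})
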