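test_that("the packaged metabolite database loads and validates", {
  db <- metabolite_db()
  expect_equal(nrow(db), 43)
  expect_equal(anyDuplicated(db$formula), 0)
  expect_true(all(db$pathway_class == "biosynthetic"))
  expect_true(all(db[["function"]] %in% function_groups()$function_label))
})

test_that("database validation rejects malformed inputs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  db <- metabolite_db()
  # bad formula propagates as a row error naming the record
  bad <- db
  bad$formula[3] <- "C6H9NOX"
  readr::write_tsv(bad, path)
  expect_error(metabolite_db(path), bad$name[3])
  # unknown function label lists the vocabulary
  bad <- db
  bad[["function"]][1] <- "mystery"
  readr::write_tsv(bad, path)
  expect_error(metabolite_db(path), "mystery")
  # duplicate (name, formula) rows rejected
  readr::write_tsv(dplyr::bind_rows(db, db[1, ]), path)
  expect_error(metabolite_db(path), "duplicate")
  # empty file with header loads as zero records
  readr::write_tsv(db[0, ], path)
  expect_equal(nrow(metabolite_db(path)), 0)
})

test_that("formula matching is exact, putative and monotone", {
  db <- metabolite_db()
  expect_equal(match_formulas("C17H20N4O6", db)$name, "Riboflavin")
  expect_equal(match_formulas("C14H18N2O4", db)$name, "Alpha-ribazole")
  expect_equal(nrow(match_formulas(character(0), db)), 0)
  # monotone: adding detected formulas never removes a match
  small <- match_formulas(c("C17H20N4O6"), db)
  bigger <- match_formulas(c("C17H20N4O6", "C8H9NO3"), db)
  expect_true(all(small$name %in% bigger$name))
  # isomer collisions are flagged
  iso <- dplyr::bind_rows(db, dplyr::mutate(db[1, ], name = "isomer twin"))
  m <- match_formulas(db$formula[1], iso)
  expect_true(all(m$formula_degenerate))
})

test_that("pathway classes partition the matches", {
  db <- metabolite_db()
  syn <- dplyr::mutate(db, pathway_class = rep(
    c("biosynthetic", "degradation", "spontaneous", "secondary"),
    length.out = nrow(db)))
  m <- match_formulas(syn$formula[1:10], syn)
  cc <- class_counts(m)
  expect_equal(sort(cc$pathway_class),
               sort(c("biosynthetic", "degradation", "spontaneous",
                      "secondary")))
  expect_equal(sum(cc$n), nrow(dplyr::distinct(m, name, formula)))
  empty <- class_counts(m[0, ])
  expect_equal(sum(empty$n), 0)
  expect_equal(nrow(empty), 4)
})

test_that("per-strain detected counts match the published table summary", {
  db <- metabolite_db()
  m_ds <- match_formulas(db$formula[db$detected_dshibae == 1], db)
  m_pi <- match_formulas(db$formula[db$detected_pinhibens == 1], db)
  expect_equal(sum(class_counts(m_ds)$n), 35)
  expect_equal(sum(class_counts(m_pi)$n), 36)
  sh <- shared_between_strains(m_ds$formula, m_pi$formula)
  expect_equal(sh$n_shared, 28)
  expect_equal(sh$n_total, 43)
  expect_equal(sh$n_total, sh$n_a + sh$n_b - sh$n_shared)
})

test_that("functional group counts reproduce the published subdivision", {
  db <- metabolite_db()
  fg_ds <- function_group_counts(
    match_formulas(db$formula[db$detected_dshibae == 1], db))
  fg_pi <- function_group_counts(
    match_formulas(db$formula[db$detected_pinhibens == 1], db))
  pick <- function(fg, g) fg$n[fg$group == g]
  expect_equal(pick(fg_ds, "vitamin-related"), 12)
  expect_equal(pick(fg_pi, "vitamin-related"), 10)
  expect_equal(pick(fg_ds, "quorum-sensing"), 5)
  expect_equal(pick(fg_pi, "quorum-sensing"), 6)
  expect_equal(pick(fg_ds, "amino-acid-related"), 10)
  expect_equal(pick(fg_pi, "amino-acid-related"), 9)
  # percentages of the strain total: 12/35 = 34%, 5/35 = 14%
  expect_equal(pick(fg_ds, "vitamin-related") / sum(fg_ds$n) * 100, 34.3,
               tolerance = 0.01)
  expect_equal(fg_ds$pct[fg_ds$group == "quorum-sensing"], 100 * 5 / 35,
               tolerance = 1e-9)
  # unmapped labels are a configuration error
  odd <- dplyr::mutate(db[1, ], `function` = "mystery")
  expect_error(function_group_counts(odd), "vocabulary")
})

test_that("shared_between_strains handles edge cases with
          inclusion-exclusion consistency", {
  expect_equal(shared_between_strains("X", "Y"),
               tibble::tibble(n_a = 1L, n_b = 1L, n_shared = 0L,
                              n_total = 2L))
  same <- shared_between_strains(c("X", "Y"), c("Y", "X"))
  expect_equal(same$n_shared, 2)
  expect_equal(same$n_total, 2)
})

test_that("detection frequencies are ratios of detected to sampled columns", {
  det <- tidyr::expand_grid(name = c("m1", "m2"), sample_id = 1:4)
  det$detected <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  freq <- detection_frequency(det)
  expect_equal(freq$frequency_pct[freq$name == "m1"], 50)
  expect_equal(freq$frequency_pct[freq$name == "m2"], 100)
  expect_equal(freq$n_samples, c(4L, 4L))
  expect_error(detection_frequency(det[0, ]), "zero")
})

test_that("observed detection frequency tracks the generating probability", {
  set.seed(19)
  p <- 0.6
  n_cols <- 20
  det <- tidyr::expand_grid(name = "m", sample_id = seq_len(n_cols))
  det$detected <- runif(n_cols) < p
  freq <- detection_frequency(det)
  # within the binomial 95% interval around p
  half <- 1.96 * sqrt(p * (1 - p) / n_cols) * 100
  expect_true(abs(freq$frequency_pct - 60) <= half + 1e-9)
})
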