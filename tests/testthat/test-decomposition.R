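test_that("ICD-10 classification uses the uppercased first letter", {
  expect_equal(classify_admission_type("S72.0"), "external")
  expect_equal(classify_admission_type(c("T10", "V01", "X60", "Y83")),
               rep("external", 4))
  expect_equal(classify_admission_type("R69"), "abnormality_NEC")
  expect_equal(classify_admission_type("j18.9"),
               classify_admission_type("J18.9"))
  expect_warning(out <- classify_admission_type(c("J18", "", "9A")),
                 class = "fairaudit_warning_unknown_code")
  expect_equal(out, c("respiratory", "unknown", "unknown"))
})

test_that("every letter maps to exactly one category and overrides apply", {
  map <- admission_type_map()
  expect_setequal(names(map), LETTERS)
  expect_false(any(is.na(map)))
  map2 <- admission_type_map(overrides = c(W = "external"))
  expect_equal(unname(map2[["W"]]), "external")
  expect_error(admission_type_map(overrides = c(WW = "x")),
               class = "fairaudit_error_config")
})

test_that("type maps round-trip through two-column text files", {
  map <- admission_type_map(overrides = c(U = "other"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_type_map(map, path)
  expect_identical(read_type_map(path), map)
})

test_that("decomposition matches the worked example", {
  # admissions typed [external x2, respiratory, digestive]; the two external
  # ones are the low-score subset
  tbl <- make_cohort(
    score = c(0.05, 0.08, 0.5, 0.6),
    outcome = rep(1L, 4),
    icd10 = c("S10", "T20", "J18", "K59")
  )
  dt <- decomposition_table(tbl, threshold = 0.1, n_boot = 0)
  ext <- dt[dt$category == "external", ]
  expect_equal(ext$A, 0.5)
  expect_equal(ext$B, 1.0)
  expect_equal(ext$diff, 0.5)
})

test_that("A and B proportions each sum to one and contrasts sum to zero", {
  set.seed(801)
  for (rep in 1:10) {
    tbl <- random_small_cohort(20)
    if (!any(tbl$outcome == 1)) next
    dt <- decomposition_table(tbl, threshold = 0.5, n_boot = 0)
    for (kind in unique(dt$event_kind)) {
      d <- dt[dt$event_kind == kind, ]
      expect_equal(sum(d$A), 1, tolerance = 1e-12)
      if (!anyNA(d$B)) {
        expect_equal(sum(d$B), 1, tolerance = 1e-12)
        expect_equal(sum(d$diff), 0, tolerance = 1e-12)
      }
    }
  }
})

test_that("an unreachable threshold flags B as undefined", {
  tbl <- make_cohort(score = c(0.5, 0.6), outcome = c(1L, 1L),
                     icd10 = c("J18", "K59"))
  dt <- decomposition_table(tbl, threshold = 0.01, n_boot = 50, seed = 1)
  expect_true(all(is.na(dt$B)))
  expect_true(all(is.na(dt$diff)))
  expect_error(decomposition_table(tbl, threshold = 0),
               class = "fairaudit_error_config")
  expect_error(decomposition_table(make_cohort(0.5, 0L)),
               class = "fairaudit_error_empty")
})

test_that("admissions and deaths are decomposed separately", {
  tbl <- make_cohort(
    score = c(0.05, 0.5, 0.05, 0.5),
    outcome = rep(1L, 4),
    event_kind = c("admission", "admission", "death_without_admission",
                   "death_without_admission"),
    icd10 = c("S10", "J18", "I21", "C50")
  )
  dt <- decomposition_table(tbl, threshold = 0.1, n_boot = 0)
  expect_setequal(unique(dt$event_kind),
                  c("admission", "death_without_admission"))
  adm <- dt[dt$event_kind == "admission", ]
  expect_setequal(adm$category, c("external", "respiratory"))
  dth <- dt[dt$event_kind == "death_without_admission", ]
  expect_setequal(dth$category, c("circulatory", "neoplasm"))
})

test_that("null generator gives B - A intervals that usually cover zero", {
  # score independent of admission category within events: every category's
  # contrast should cover 0 at roughly the nominal rate
  set.seed(802)
  # flatten the mixture so every demographic cell shares one weight vector
  mix <- default_type_mixture("admission")
  flat_row <- which(mix$age_band == "45-64" & mix$sex == "M" &
                      mix$simd_band == "affluent")
  for (letter in setdiff(names(mix), c("age_band", "sex", "simd_band"))) {
    mix[[letter]] <- mix[[letter]][flat_row]
  }
  covered <- 0; total <- 0
  for (seed in 1:5) {
    co <- generate_cohort(generator_config(n = 20000, seed = seed,
                                           admission_mixture = mix,
                                           death_mixture = mix))$cohort
    dt <- decomposition_table(co, threshold = 0.1, n_boot = 300,
                              seed = seed + 100)
    d <- dt[dt$event_kind == "admission" & dt$n_all >= 30 &
              !is.na(dt$diff), ]
    covered <- covered + sum(d$lower <= 0 & d$upper >= 0)
    total <- total + nrow(d)
  }
  expect_gt(covered / total, 0.85)
})
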