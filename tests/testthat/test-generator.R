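# marginal-recovery checks use 3 binomial SEs at the generated size
tol3 <- function(p, n) 3 * sqrt(p * (1 - p) / n)

test_that("generation is deterministic given the seed", {
  cfg <- generator_config(n = 500, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(generator_config(n = 500, seed = 43))
  expect_false(identical(a$cohort$score, c2$cohort$score))
})

test_that("configured marginals are recovered at n = 1e5", {
  n <- 1e5
  cfg <- generator_config(n = n, seed = 7)
  co <- generate_cohort(cfg)$cohort
  expect_lt(abs(mean(co$sex == "M") - 0.454), tol3(0.454, n))
  expect_lt(abs(mean(co$simd_decile <= 2) - 0.215), tol3(0.215, n))
  expect_lt(abs(mean(co$simd_decile >= 9) - 0.187), tol3(0.187, n))
  expect_lt(abs(mean(!is.na(co$ethnicity) & co$ethnicity == "white") - 0.668),
            tol3(0.668, n))
  expect_lt(abs(mean(is.na(co$ethnicity)) - 0.114), tol3(0.114, n))
  expect_lt(abs(mean(!is.na(co$urban_rural) & co$urban_rural == "urban") -
                  0.833), tol3(0.833, n))
  expect_lt(abs(mean(co$mainland_island == "island") - 0.0186),
            tol3(0.0186, n))
  expect_lt(abs(mean(co$age) - 43.3), 3 * 23.8 / sqrt(n))
  expect_lt(abs(sd(co$age) - 23.8), 3 * 23.8 / sqrt(2 * n))
})

test_that("score equals the true probability when distortion and noise are absent", {
  cfg <- generator_config(n = 2000, seed = 5, noise_sd = 0)
  out <- generate_cohort(cfg)
  expect_equal(out$cohort$score, out$truth$p, tolerance = 1e-12)
  # and outcomes are Bernoulli draws from p: score-band event rate matches
  cfg2 <- generator_config(n = 1e5, seed = 6)
  out2 <- generate_cohort(cfg2)
  band <- out2$cohort$score >= 0.08 & out2$cohort$score <= 0.12
  pbar <- mean(out2$cohort$score[band])
  rate <- mean(out2$cohort$outcome[band])
  expect_lt(abs(rate - pbar), 3 * sqrt(pbar * (1 - pbar) / sum(band)))
})

test_that("urban fraction depends on deprivation as configured", {
  co <- generate_cohort(generator_config(n = 1e5, seed = 8))$cohort
  most <- co$simd_decile <= 2 & !is.na(co$urban_rural)
  least <- co$simd_decile >= 9 & !is.na(co$urban_rural)
  expect_lt(abs(mean(co$urban_rural[most] == "urban") - 0.965),
            tol3(0.965, sum(most)))
  expect_lt(abs(mean(co$urban_rural[least] == "urban") - 0.919),
            tol3(0.919, sum(least)))
})

test_that("ethnicity missingness increases with age when the slope is positive", {
  co <- generate_cohort(generator_config(n = 1e5, seed = 9))$cohort
  miss_age <- mean(co$age[is.na(co$ethnicity)])
  obs_age <- mean(co$age[!is.na(co$ethnicity)])
  expect_gt(miss_age, obs_age)
})

test_that("admission-type mixtures are recovered per demographic cell", {
  co <- generate_cohort(generator_config(n = 1e5, seed = 10))$cohort
  mix <- default_type_mixture("admission")
  adm <- co[co$event_kind == "admission", ]
  first <- substr(adm$icd10_code, 1, 1)
  # check the two most extreme cells with decent counts
  cells <- list(
    list(sel = adm$age >= 65 & adm$sex == "M" & adm$simd_decile <= 5,
         row = mix$age_band == "65+" & mix$sex == "M" &
           mix$simd_band == "deprived"),
    list(sel = adm$age >= 15 & adm$age < 45 & adm$sex == "F" &
           adm$simd_decile > 5,
         row = mix$age_band == "15-44" & mix$sex == "F" &
           mix$simd_band == "affluent")
  )
  for (cell in cells) {
    n <- sum(cell$sel)
    expect_gt(n, 200)
    for (letter in c("I", "J", "S", "O")) {
      w <- mix[[letter]][cell$row]
      emp <- mean(first[cell$sel] == letter)
      expect_lt(abs(emp - w), 3 * sqrt(w * (1 - w) / n) + 1e-9)
    }
  }
})

test_that("deaths without admission exist and rise with age", {
  co <- generate_cohort(generator_config(n = 1e5, seed = 11))$cohort
  ev <- co[co$outcome == 1L, ]
  death <- ev$event_kind == "death_without_admission"
  expect_gt(sum(death), 100)
  expect_gt(mean(ev$age[death]), mean(ev$age[!death]))
})

test_that("injected miscalibration shifts only the named group", {
  co <- generate_cohort(generator_config(n = 5000, seed = 12))$cohort
  spec <- builtin_group_specs()$sex
  same <- inject_group_miscalibration(co, spec, "M", 0)
  expect_equal(same$score, co$score, tolerance = 1e-12)
  shifted <- inject_group_miscalibration(co, spec, "M", 1)
  m <- co$sex == "M"
  expect_equal(shifted$score[!m], co$score[!m], tolerance = 1e-15)
  expect_true(all(shifted$score[m] > co$score[m]))
  expect_identical(shifted$outcome, co$outcome)
  expect_error(inject_group_miscalibration(co, spec, "Q", 1),
               class = "fairaudit_error_group_label")
})

test_that("invalid generator configs fail with named errors", {
  expect_error(generator_config(n = 0), class = "fairaudit_error_config")
  expect_error(generator_config(male_fraction = 1.2),
               regexp = "male_fraction", class = "fairaudit_error_config")
  expect_error(generator_config(simd_weights = rep(0.1, 9)),
               regexp = "simd_weights", class = "fairaudit_error_config")
  expect_error(generator_config(ethnicity = c(white = 0.5, nonwhite = 0.2,
                                              missing = 0.2)),
               regexp = "ethnicity", class = "fairaudit_error_config")
  bad_mix <- default_type_mixture("admission")
  bad_mix$J <- bad_mix$J + 0.1
  expect_error(generator_config(admission_mixture = bad_mix),
               class = "fairaudit_error_config")
})

test_that("generator configs round-trip through YAML", {
  cfg <- generator_config(n = 1234, seed = 99, noise_sd = 0.3,
                          female_age_shift = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, path)
  back <- read_generator_config(path)
  expect_equal(back$n, cfg$n)
  expect_equal(back$risk, cfg$risk)
  expect_equal(back$female_age_shift, 5)
  expect_equal(as.data.frame(back$admission_mixture),
               as.data.frame(cfg$admission_mixture), tolerance = 1e-8)
  expect_identical(generate_cohort(back)$cohort,
                   generate_cohort(cfg)$cohort)
})
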