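test_that("FOR and FDR curves match hand enumeration on the worked example", {
  s <- c(0.05, 0.2, 0.4, 0.15, 0.9, 0.7)
  y <- c(0L, 1L, 0L, 0L, 1L, 1L)
  expect_equal(for_curve(s, y, grid = 0.5)$estimate, 0.25)
  expect_equal(fdr_curve(s, y, grid = 0.5)$estimate, 0)
  # all-negative outcomes
  expect_true(all(for_curve(s, rep(0L, 6), grid = c(0.3, 0.6))$estimate == 0))
  expect_true(all(fdr_curve(s, rep(0L, 6), grid = c(0.3, 0.6))$estimate == 1))
})

test_that("cutoffs with empty conditioning sets are undefined, not zero", {
  s <- c(0.4, 0.5, 0.6)
  y <- c(0L, 1L, 0L)
  f <- for_curve(s, y, grid = c(0.2, 0.5, 0.8))
  expect_true(is.na(f$estimate[1]))   # nothing below 0.2
  expect_equal(f$n_effective[1], 0)
  d <- fdr_curve(s, y, grid = c(0.2, 0.5, 0.8))
  expect_true(is.na(d$estimate[3]))   # nothing at/above 0.8
})

test_that("FDR complements precision and FOR complements the below-cutoff negative rate", {
  set.seed(701)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    s <- runif(n, 0.01, 0.99)
    y <- rbinom(n, 1, 0.4)
    grid <- cutoff_grid(0.1, 0.9, 0.1)
    f <- for_curve(s, y, grid)
    d <- fdr_curve(s, y, grid)
    for (k in seq_along(grid)) {
      below <- s < grid[k]
      if (any(below)) {
        expect_equal(f$estimate[k] + mean(y[below] == 0), 1,
                     tolerance = 1e-12)
      }
      if (any(!below)) {
        prec <- mean(y[!below] == 1)
        expect_equal(d$estimate[k], 1 - prec, tolerance = 1e-12)
      }
    }
  }
})

test_that("adjusted curve reproduces the hand stratified average", {
  # two strata with within-stratum FOR 0.25 and 0.75, reference 0.5/0.5
  tbl <- make_cohort(
    score = rep(0.1, 8),
    outcome = c(1L, 0L, 0L, 0L, 1L, 1L, 1L, 0L),
    age = c(rep(10L, 4), rep(40L, 4)),
    sex = rep("M", 8), simd = rep(1L, 8)
  )
  cv <- adjusted_rate_curve(tbl, rep(TRUE, 8), metric = "for", grid = 0.5,
                            reference = "self", n_boot = 0)
  expect_equal(cv$estimate, 0.5)
  expect_equal(cv$dropped_mass, 0)
})

test_that("self-standardisation to a matching reference equals the raw curve", {
  set.seed(702)
  tbl <- random_small_cohort(18)
  tbl$age <- rep(40L, 18)          # single stratum: self-reference is exact
  tbl$sex <- rep("M", 18)
  tbl$simd_decile <- rep(3L, 18)
  grid <- cutoff_grid(0.1, 0.9, 0.1)
  adj <- adjusted_rate_curve(tbl, rep(TRUE, 18), metric = "for",
                             grid = grid, reference = "self", n_boot = 0)
  raw <- for_curve(tbl$score, tbl$outcome, grid)
  both <- !is.na(adj$estimate) & !is.na(raw$estimate)
  expect_equal(adj$estimate[both], raw$estimate[both], tolerance = 1e-12)
})

test_that("reference choice changes the adjusted curve when strata differ", {
  co <- generate_cohort(generator_config(n = 20000, seed = 31))$cohort
  spec <- builtin_group_specs()$urban_rural
  g <- assign_group(co, spec)
  a <- g == "urban"; b <- g == "rural"
  grid <- cutoff_grid(0.05, 0.2, 0.05)
  adj_pool <- adjusted_rate_curve(co, a, metric = "for", grid = grid,
                                  reference = "pooled_pair", other_rows = b,
                                  n_boot = 0)
  adj_other <- adjusted_rate_curve(co, a, metric = "for", grid = grid,
                                   reference = "other_group", other_rows = b,
                                   n_boot = 0)
  expect_gt(max(abs(adj_pool$estimate - adj_other$estimate), na.rm = TRUE),
            1e-4)
  # groups defined by a stratum dimension share no strata with the other
  # group: standardising to the comparator is then impossible by design
  ga <- assign_group(co, builtin_group_specs()$age)
  expect_error(
    adjusted_rate_curve(co, ga == "over65", metric = "for", grid = grid,
                        reference = "other_group",
                        other_rows = ga == "under25", n_boot = 0),
    class = "fairaudit_error_no_overlap")
})

test_that("dropped reference mass is reported per cutoff", {
  tbl <- make_cohort(
    score = c(0.1, 0.1, 0.6, 0.6),
    outcome = c(0L, 1L, 0L, 1L),
    age = c(10L, 10L, 40L, 40L),
    sex = rep("M", 4), simd = rep(1L, 4)
  )
  # at c = 0.3 the age-40 stratum has nothing below cutoff: its reference
  # mass (0.5) is dropped there
  cv <- adjusted_rate_curve(tbl, rep(TRUE, 4), metric = "for",
                            grid = c(0.3, 0.9), reference = "self",
                            n_boot = 0)
  expect_equal(cv$dropped_mass, c(0.5, 0))
  expect_equal(cv$estimate, c(0.5, 0.5))
})

test_that("bootstrap intervals bracket the estimate and shrink with n", {
  set.seed(704)
  co <- generate_cohort(generator_config(n = 5000, seed = 32))$cohort
  grid <- cutoff_grid(0.05, 0.15, 0.05)
  cv <- adjusted_rate_curve(co, rep(TRUE, nrow(co)), metric = "for",
                            grid = grid, reference = "self",
                            n_boot = 200, seed = 1)
  ok <- !is.na(cv$estimate)
  expect_true(all(cv$lower[ok] <= cv$estimate[ok] + 1e-9))
  expect_true(all(cv$upper[ok] >= cv$estimate[ok] - 1e-9))
  expect_true(all(cv$se[ok] > 0))
  # determinism of the seeded bootstrap
  cv2 <- adjusted_rate_curve(co, rep(TRUE, nrow(co)), metric = "for",
                             grid = grid, reference = "self",
                             n_boot = 200, seed = 1)
  expect_identical(cv, cv2)
})
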