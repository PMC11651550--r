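# Build a valid cohort tibble from vectors, filling event metadata
# consistently with the schema invariants.
make_cohort <- function(score, outcome,
                        age = NULL, sex = NULL, simd = NULL,
                        event_kind = NULL, icd10 = NULL) {
  n <- length(score)
  age <- age %||% rep(40L, n)
  sex <- sex %||% rep(c("M", "F"), length.out = n)
  simd <- simd %||% rep(1:10, length.out = n)
  event_kind <- event_kind %||% ifelse(outcome == 1, "admission", "none")
  icd10 <- icd10 %||% ifelse(outcome == 1, "J00", NA_character_)
  tibble::tibble(
    id = sprintf("r%03d", seq_len(n)),
    age = as.integer(age), sex = sex, simd_decile = as.integer(simd),
    ethnicity = rep(c("white", "nonwhite", NA), length.out = n),
    urban_rural = rep(c("urban", "rural"), length.out = n),
    mainland_island = rep("mainland", n),
    score = score, outcome = as.integer(outcome),
    event_kind = event_kind, icd10_code = icd10
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Random small cohort with deliberately coarse covariates so that strata
# are shared between groups; caller controls the RNG state.
random_small_cohort <- function(n = NULL) {
  n <- n %||% sample(4:20, 1)
  score <- round(runif(n, 0.02, 0.98), 2)
  outcome <- rbinom(n, 1, 0.4)
  letters_pool <- c("S", "R", "J", "K", "I", "A")
  make_cohort(
    score, outcome,
    age = sample(c(10L, 40L, 70L), n, replace = TRUE),
    sex = sample(c("M", "F"), n, replace = TRUE),
    simd = sample(c(1L, 2L, 9L), n, replace = TRUE),
    event_kind = ifelse(outcome == 1,
                        sample(c("admission", "death_without_admission"),
                               n, replace = TRUE, prob = c(0.8, 0.2)),
                        "none"),
    icd10 = ifelse(outcome == 1,
                   paste0(sample(letters_pool, n, replace = TRUE), "08"),
                   NA_character_)
  )
}
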