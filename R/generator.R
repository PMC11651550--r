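ICD_LETTERS <- c("A", "C", "E", "F", "G", "I", "J", "K", "M", "N", "O",
                 "R", "S", "T", "V", "X", "Y")

# Cells over which admission-type mixtures are defined: coarse age band x sex
# x deprivation half (SIMD deciles 1-5 vs 6-10).
mixture_age_bands <- c(0, 15, 45, 65, Inf)
mixture_age_labels <- c("0-14", "15-44", "45-64", "65+")

mixture_cells <- function() {
  expand.grid(
    age_band = mixture_age_labels,
    sex = c("M", "F"),
    simd_band = c("deprived", "affluent"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
}

mixture_cell_index <- function(age, sex, simd_decile) {
  band <- findInterval(age, mixture_age_bands, rightmost.closed = FALSE)
  band <- pmin(pmax(band, 1L), 4L)
  sexi <- ifelse(sex == "M", 0L, 1L)
  depi <- ifelse(simd_decile <= 5L, 0L, 1L)
  band + 4L * sexi + 8L * depi
}

#' Default admission-type mixtures per demographic cell
#'
#' Weights over ICD-10 first letters for the primary diagnosis of an
#' admission (or primary cause of a death without prior admission), defined
#' per (age band, sex, deprivation half) cell. The defaults encode broad
#' clinical structure: external causes (letters S, T, V, X, Y) concentrated
#' in the young and in males, circulatory/neoplastic causes in the elderly,
#' obstetric codes only in females of reproductive age, and a substantial
#' "abnormality NEC" (letter R) share. Every row sums to 1.
#'
#' @param kind `"admission"` or `"death"`.
#' @return A tibble with cell-identifier columns (`age_band`, `sex`,
#'   `simd_band`) and one weight column per ICD-10 letter.
#' @export
default_type_mixture <- function(kind = c("admission", "death")) {
  kind <- match.arg(kind)
  base <- if (kind == "admission") {
    c(A = 0.07, C = 0.03, E = 0.02, F = 0.03, G = 0.02, I = 0.08, J = 0.12,
      K = 0.13, M = 0.04, N = 0.06, O = 0.03, R = 0.15, S = 0.10, T = 0.05,
      V = 0.02, X = 0.03, Y = 0.02)
  } else {
    c(A = 0.03, C = 0.25, E = 0.02, F = 0.03, G = 0.04, I = 0.30, J = 0.12,
      K = 0.06, M = 0.01, N = 0.03, O = 0.00, R = 0.05, S = 0.02, T = 0.01,
      V = 0.01, X = 0.01, Y = 0.01)
  }
  external <- c("S", "T", "V", "X", "Y")
  cells <- mixture_cells()
  w <- matrix(rep(base, each = nrow(cells)), nrow = nrow(cells),
              dimnames = list(NULL, names(base)))
  old <- cells$age_band == "65+"
  young <- cells$age_band %in% c("0-14", "15-44")
  child <- cells$age_band == "0-14"
  male <- cells$sex == "M"
  fertile <- cells$age_band == "15-44" & cells$sex == "F"
  deprived <- cells$simd_band == "deprived"
  w[old, "I"] <- w[old, "I"] * 2
  w[old, "J"] <- w[old, "J"] * 1.5
  w[old, "C"] <- w[old, "C"] * 2
  w[old, external] <- w[old, external] * 0.6
  w[child, c("A", "J")] <- w[child, c("A", "J")] * 1.5
  w[child, c("I", "C")] <- w[child, c("I", "C")] * 0.3
  w[young & male, external] <- w[young & male, external] * 1.4
  w[deprived, external] <- w[deprived, external] * 1.15
  w[, "O"] <- ifelse(fertile, w[, "O"], 0)
  w <- w / rowSums(w)
  dplyr::bind_cols(tibble::as_tibble(cells), tibble::as_tibble(w))
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("Config field '%s' must be a fraction in [0, 1].", name),
          class = "fairaudit_error_config")
  }
}

#' Configuration for the synthetic cohort generator
#'
#' The defaults emulate the descriptive structure of a national
#' emergency-admission audit cohort: marginal fractions for sex, deprivation
#' deciles, ethnicity (including non-random missingness that increases with
#' age), urban/rural residence depending on deprivation, island residence,
#' and a three-component age mixture tuned to mean 43.3 years, SD 23.8.
#' True one-year risk is logistic in age, sex and SIMD with individual
#' log-odds noise; the reported score equals the true probability unless a
#' per-group calibration distortion is configured.
#'
#' @param n Cohort size.
#' @param seed Integer seed; all draws flow from one seeded generator.
#' @param male_fraction Fraction male.
#' @param age_mixture List with `weights`, `means`, `sds` of the normal age
#'   mixture components; ages are rounded and clamped to 0..105.
#' @param female_age_shift Years added to female ages (default 0); a knob to
#'   create between-sex differences mediated purely through age.
#' @param simd_weights Probability weights for SIMD deciles 1..10.
#' @param ethnicity Named fractions `white`, `nonwhite`, `missing` (sum 1).
#' @param ethnicity_missing_age_slope Log-odds slope of ethnicity
#'   missingness per year of age (positive = older people more often
#'   missing); the intercept is calibrated so the overall missing fraction
#'   matches `ethnicity$missing`.
#' @param urban_by_quintile Urban fraction conditional on SIMD quintile
#'   (most deprived first).
#' @param urban_age_slope Log-odds slope of urban residence per year of age
#'   (centred at 43.3); default 0. A nonzero value makes the urban and
#'   rural groups differ in age distribution, a knob for studying effects
#'   mediated purely through age.
#' @param urban_rural_missing Fraction with missing urban/rural status.
#' @param island_fraction Fraction resident on islands.
#' @param risk Named log-odds coefficients: `intercept`, `age` (per year,
#'   centred at 43.3), `male`, `simd` (per decile, centred at 5.5; negative
#'   means more deprived = higher risk), and optional direct group effects
#'   `nonwhite`, `rural`, `island` (default 0: score independent of those
#'   groups given age, sex and SIMD).
#' @param noise_sd SD of individual log-odds deviations around the linear
#'   predictor (unexplained heterogeneity the score does capture).
#' @param calibration_distortion List of distortions, each a list with
#'   `variable`, `label` (a built-in group label), `shift` and `scale`
#'   applied to the reported score's log-odds for members of that group.
#'   Empty by default (score = true probability).
#' @param death Named list `intercept`, `age_slope`: log-odds (centred at
#'   age 60) that an event is a death without prior admission, rising with
#'   age.
#' @param admission_mixture,death_mixture Admission-type mixtures, see
#'   [default_type_mixture()].
#' @return A validated `generator_config` object.
#' @export
generator_config <- function(
    n = 1e5,
    seed = 1L,
    male_fraction = 0.454,
    age_mixture = list(weights = c(0.170, 0.615, 0.215),
                       means = c(9, 42, 74),
                       sds = c(7, 15, 9.5)),
    female_age_shift = 0,
    simd_weights = c(0.1075, 0.1075, rep(0.0996667, 6), 0.0935, 0.0935),
    ethnicity = c(white = 0.668, nonwhite = 0.218, missing = 0.114),
    ethnicity_missing_age_slope = 0.045,
    urban_by_quintile = c(0.965, 0.759, 0.759, 0.759, 0.919),
    urban_age_slope = 0,
    urban_rural_missing = 0.0007,
    island_fraction = 0.0186,
    risk = c(intercept = -2.65, age = 0.011, male = 0.10, simd = -0.03,
             nonwhite = 0, rural = 0, island = 0),
    noise_sd = 0.18,
    calibration_distortion = list(),
    death = c(intercept = -2.2, age_slope = 0.045),
    admission_mixture = default_type_mixture("admission"),
    death_mixture = default_type_mixture("death")) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    abort("Config field 'n' must be a positive integer.",
          class = "fairaudit_error_config")
  }
  check_fraction(male_fraction, "male_fraction")
  check_fraction(simd_weights, "simd_weights")
  check_fraction(ethnicity, "ethnicity")
  check_fraction(urban_by_quintile, "urban_by_quintile")
  check_fraction(urban_rural_missing, "urban_rural_missing")
  check_fraction(island_fraction, "island_fraction")
  if (length(simd_weights) != 10L) {
    abort("Config field 'simd_weights' must have 10 entries.",
          class = "fairaudit_error_config")
  }
  if (abs(sum(ethnicity) - 1) > 1e-6) {
    abort("Config field 'ethnicity' fractions must sum to 1.",
          class = "fairaudit_error_config")
  }
  if (!all(c("white", "nonwhite", "missing") %in% names(ethnicity))) {
    abort("Config field 'ethnicity' must name white, nonwhite and missing.",
          class = "fairaudit_error_config")
  }
  if (length(urban_by_quintile) != 5L) {
    abort("Config field 'urban_by_quintile' must have 5 entries.",
          class = "fairaudit_error_config")
  }
  am <- tibble::as_tibble(admission_mixture)
  dm <- tibble::as_tibble(death_mixture)
  for (mx in list(admission = am, death = dm)) {
    wsum <- rowSums(mx[ICD_LETTERS])
    if (any(abs(wsum - 1) > 1e-8)) {
      abort("Admission-type mixture rows must each sum to 1.",
            class = "fairaudit_error_config")
    }
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort("Config field 'noise_sd' must be >= 0.",
          class = "fairaudit_error_config")
  }
  needed <- c("intercept", "age", "male", "simd")
  if (!all(needed %in% names(risk))) {
    abort(sprintf("Config field 'risk' must name %s.",
                  paste(needed, collapse = ", ")),
          class = "fairaudit_error_config")
  }
  risk_full <- c(nonwhite = 0, rural = 0, island = 0)
  risk_full[names(risk)] <- risk
  structure(
    list(
      n = as.integer(n), seed = as.integer(seed),
      male_fraction = male_fraction, age_mixture = age_mixture,
      female_age_shift = female_age_shift,
      simd_weights = simd_weights / sum(simd_weights),
      ethnicity = ethnicity,
      ethnicity_missing_age_slope = ethnicity_missing_age_slope,
      urban_by_quintile = urban_by_quintile,
      urban_age_slope = urban_age_slope,
      urban_rural_missing = urban_rural_missing,
      island_fraction = island_fraction,
      risk = risk_full, noise_sd = noise_sd,
      calibration_distortion = calibration_distortion,
      death = death, admission_mixture = am, death_mixture = dm
    ),
    class = "generator_config"
  )
}

simd_quintile <- function(decile) (decile + 1L) %/% 2L

#' Generate a synthetic scored cohort with known ground truth
#'
#' Draws covariates from the configured marginals and dependence structure,
#' computes each individual's true one-year event probability `p` from the
#' logistic risk model plus individual log-odds noise, draws the outcome as
#' Bernoulli(`p`), assigns events an admission-or-death kind (death
#' probability rising with age) and an ICD-10 code whose first letter comes
#' from the demographic cell's mixture, and reports a score equal to `p`
#' unless a calibration distortion is configured. Reported scores are
#' clipped into (0.01, 0.99), mirroring the 1-99 display convention.
#'
#' @param config A [generator_config()].
#' @return A list with elements `cohort` (a validated cohort tibble) and
#'   `truth` (tibble `id`, `linear_predictor`, `p`). Deterministic given the
#'   config seed.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config")) {
    abort("`config` must be a generator_config object.",
          class = "fairaudit_error_config")
  }
  cfg <- config
  n <- cfg$n
  with_seed(cfg$seed, {
    sex <- ifelse(runif(n) < cfg$male_fraction, "M", "F")
    mix <- cfg$age_mixture
    comp <- sample.int(length(mix$weights), n, replace = TRUE,
                       prob = mix$weights)
    age_raw <- rnorm(n, mix$means[comp], mix$sds[comp])
    age_raw <- age_raw + ifelse(sex == "F", cfg$female_age_shift, 0)
    age <- pmin(pmax(round(age_raw), 0), 105)
    simd <- sample.int(10L, n, replace = TRUE, prob = cfg$simd_weights)

    # ethnicity missingness rises with age; intercept calibrated on the
    # realised ages so the configured overall missing fraction is matched
    miss_target <- cfg$ethnicity[["missing"]]
    slope <- cfg$ethnicity_missing_age_slope
    if (miss_target <= 0) {
      p_miss <- rep(0, n)
    } else {
      f <- function(m0) mean(plogis(m0 + slope * (age - 43.3))) - miss_target
      m0 <- uniroot(f, c(-30, 30))$root
      p_miss <- plogis(m0 + slope * (age - 43.3))
    }
    eth_missing <- runif(n) < p_miss
    p_white <- cfg$ethnicity[["white"]] /
      (cfg$ethnicity[["white"]] + cfg$ethnicity[["nonwhite"]])
    ethnicity <- ifelse(eth_missing, NA_character_,
                        ifelse(runif(n) < p_white, "white", "nonwhite"))

    ur_missing <- runif(n) < cfg$urban_rural_missing
    p_urban <- plogis(qlogis(cfg$urban_by_quintile[simd_quintile(simd)]) +
                        cfg$urban_age_slope * (age - 43.3))
    urban_rural <- ifelse(ur_missing, NA_character_,
                          ifelse(runif(n) < p_urban, "urban", "rural"))
    mainland_island <- ifelse(runif(n) < cfg$island_fraction,
                              "island", "mainland")

    rk <- cfg$risk
    lp <- rk[["intercept"]] +
      rk[["age"]] * (age - 43.3) +
      rk[["male"]] * (sex == "M") +
      rk[["simd"]] * (simd - 5.5) +
      rk[["nonwhite"]] * (!is.na(ethnicity) & ethnicity == "nonwhite") +
      rk[["rural"]] * (!is.na(urban_rural) & urban_rural == "rural") +
      rk[["island"]] * (mainland_island == "island") +
      rnorm(n, 0, cfg$noise_sd)
    p <- plogis(lp)

    lp_rep <- lp
    tbl_cov <- tibble::tibble(age = age, sex = sex, simd_decile = simd,
                              ethnicity = ethnicity,
                              urban_rural = urban_rural,
                              mainland_island = mainland_island)
    for (dist in cfg$calibration_distortion) {
      rows <- distortion_rows(tbl_cov, dist$variable, dist$label)
      scale <- dist$scale %||% 1
      shift <- dist$shift %||% 0
      lp_rep[rows] <- shift + scale * lp_rep[rows]
    }
    score <- pmin(pmax(plogis(lp_rep), 0.01), 0.99)

    outcome <- as.integer(runif(n) < p)
    p_death <- plogis(cfg$death[["intercept"]] +
                        cfg$death[["age_slope"]] * (age - 60))
    is_death <- outcome == 1L & runif(n) < p_death
    event_kind <- ifelse(outcome == 0L, "none",
                         ifelse(is_death, "death_without_admission",
                                "admission"))

    cell <- mixture_cell_index(age, sex, simd)
    u <- runif(n)
    letter <- rep(NA_character_, n)
    adm <- event_kind == "admission"
    dth <- event_kind == "death_without_admission"
    if (any(adm)) {
      letter[adm] <- draw_letters(cfg$admission_mixture, cell[adm], u[adm])
    }
    if (any(dth)) {
      letter[dth] <- draw_letters(cfg$death_mixture, cell[dth], u[dth])
    }
    icd10 <- ifelse(is.na(letter), NA_character_, paste0(letter, "00"))

    cohort <- tibble::tibble(
      id = sprintf("id%07d", seq_len(n)),
      age = as.integer(age), sex = sex, simd_decile = as.integer(simd),
      ethnicity = ethnicity, urban_rural = urban_rural,
      mainland_island = mainland_island,
      score = score, outcome = outcome, event_kind = event_kind,
      icd10_code = icd10
    )
    truth <- tibble::tibble(id = cohort$id, linear_predictor = lp, p = p)
    list(cohort = validate_cohort(cohort), truth = truth)
  })
}

# Rows belonging to a built-in group label on covariates only.
distortion_rows <- function(tbl, variable, label) {
  specs <- builtin_group_specs()
  if (!variable %in% names(specs)) {
    abort(sprintf("Unknown grouping variable '%s'.", variable),
          class = "fairaudit_error_group_label")
  }
  spec <- specs[[variable]]
  if (identical(label, spec$label_a)) {
    pred <- spec$predicate_a
  } else if (identical(label, spec$label_b)) {
    pred <- spec$predicate_b
  } else {
    abort(sprintf("Unknown group label '%s' for variable '%s'.",
                  label, variable),
          class = "fairaudit_error_group_label")
  }
  rows <- pred(tbl)
  rows[is.na(rows)] <- FALSE
  rows
}

# Inverse-CDF draw of ICD letters, one uniform per row, cell-specific weights.
draw_letters <- function(mixture, cell_idx, u) {
  w <- as.matrix(mixture[ICD_LETTERS])
  cum <- t(apply(w, 1L, cumsum))
  cum[, ncol(cum)] <- 1 + 1e-12
  idx <- rowSums(cum[cell_idx, , drop = FALSE] < u) + 1L
  ICD_LETTERS[pmin(idx, length(ICD_LETTERS))]
}

#' Shift reported scores in one group on the log-odds scale
#'
#' Applies a log-odds offset to the reported scores of the rows belonging to
#' one label of a group spec, leaving outcomes and all other rows untouched.
#' Used to test that group-wise calibration curves detect group-specific
#' distortion.
#'
#' @param cohort A cohort table.
#' @param spec A [group_spec()].
#' @param label One of the spec's two labels.
#' @param shift Log-odds offset added to the reported score.
#' @return The cohort with shifted scores (clipped into (0.01, 0.99)).
#' @export
inject_group_miscalibration <- function(cohort, spec, label, shift) {
  stopifnot(inherits(spec, "group_spec"))
  if (!label %in% c(spec$label_a, spec$label_b)) {
    abort(sprintf("Unknown group label '%s' for variable '%s'.",
                  label, spec$variable),
          class = "fairaudit_error_group_label")
  }
  g <- assign_group(cohort, spec)
  rows <- g == label
  out <- cohort
  out$score[rows] <- pmin(pmax(plogis(qlogis(out$score[rows]) + shift),
                               0.01), 0.99)
  out
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> n = %d, seed = %d, event model: logit-linear (age, sex, SIMD), noise sd %.3g\n",
              x$n, x$seed, x$noise_sd))
  invisible(x)
}
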