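#' Cutoff grid for curve metrics
#'
#' @param from,to,by Grid limits and step; defaults give the standard
#'   1%..99% percentage grid as probabilities `0.01, 0.02, ..., 0.99`.
#' @return Strictly increasing numeric vector inside (0, 1).
#' @export
cutoff_grid <- function(from = 0.01, to = 0.99, by = 0.01) {
  g <- seq(from, to, by = by)
  check_grid(g)
  g
}

check_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) == 0 ||
      any(grid <= 0) || any(grid >= 1) || any(diff(grid) <= 0)) {
    abort("Cutoff grid must be strictly increasing and inside (0, 1).",
          class = "fairaudit_error_grid")
  }
  invisible(grid)
}

#' Default age bands for stratification
#'
#' Five-year bands 0-4, 5-9, ..., 85-89, 90+. Fine enough to absorb age
#' confounding while keeping strata occupied in cohorts of realistic size.
#'
#' @return Numeric vector of lower band edges.
#' @export
default_age_bands <- function() seq(0, 90, by = 5)

# Printable stratum key per row over the requested subset of
# age band x sex x SIMD decile. Comparisons whose grouping variable is
# itself a stratum dimension (age, sex, deprivation) drop that dimension,
# otherwise no stratum could ever be shared between the two groups.
make_strata <- function(table, age_bands = default_age_bands(),
                        strata_vars = c("age", "sex", "simd")) {
  bad <- setdiff(strata_vars, c("age", "sex", "simd"))
  if (length(bad) || length(strata_vars) == 0) {
    abort("`strata_vars` must be a non-empty subset of age, sex, simd.",
          class = "fairaudit_error_config")
  }
  parts <- list()
  if ("age" %in% strata_vars) {
    band <- findInterval(table$age, age_bands)
    band[band < 1L] <- 1L
    parts$age <- sprintf("a%02d", band)
  }
  if ("sex" %in% strata_vars) parts$sex <- table$sex
  if ("simd" %in% strata_vars) {
    parts$simd <- sprintf("d%02d", table$simd_decile)
  }
  list(key = do.call(paste, c(parts, sep = "_")))
}

#' Empirical strata distribution of a group
#'
#' Probability weights over occupied age-band x sex x SIMD-decile cells,
#' used as the reference distribution for counterfactual reweighting and
#' direct standardisation.
#'
#' @param table A cohort table.
#' @param rows Logical row mask selecting the group (default all rows).
#' @param age_bands Lower edges of age bands, see [default_age_bands()].
#' @param strata_vars Subset of `c("age", "sex", "simd")` to stratify on;
#'   all three by default.
#' @return A tibble with columns `stratum` (key string) and `weight`
#'   (nonnegative, summing to 1), one row per occupied cell.
#' @export
strata_distribution <- function(table, rows = NULL,
                                age_bands = default_age_bands(),
                                strata_vars = c("age", "sex", "simd")) {
  rows <- rows %||% rep(TRUE, nrow(table))
  sub <- table[rows, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort("Cannot compute a strata distribution for an empty group.",
          class = "fairaudit_error_empty")
  }
  key <- make_strata(sub, age_bands, strata_vars)$key
  counts <- table(key)
  tibble::tibble(
    stratum = names(counts),
    weight = as.numeric(counts) / sum(counts)
  )
}

# --- binned stratified curve engine ---------------------------------------
#
# All curve metrics here depend on a score only through its position
# relative to the grid cutoffs, so a group reduces to per-stratum counts
# over (score bin, outcome) cells. Stratified bootstrap resampling within a
# stratum is then a multinomial draw over that stratum's occupied cells,
# which keeps n = 1e5 x 1000 replicates tractable.

# Per-stratum binned counts. Returns, per stratum key: n, cumulative total
# and event counts below each cutoff (rows = cutoffs).
bin_strata <- function(score, outcome, stratum_key, grid) {
  K <- length(grid)
  bin <- findInterval(score, grid) + 1L  # 1..K+1; bin <= k  <=>  score < grid[k]
  split_idx <- split(seq_along(score), stratum_key)
  lapply(split_idx, function(ii) {
    tot <- tabulate(bin[ii], nbins = K + 1L)
    ev <- if (is.null(outcome)) rep(0L, K + 1L) else
      tabulate(bin[ii][outcome[ii] == 1L], nbins = K + 1L)
    list(
      n = length(ii),
      n_event = sum(outcome[ii] == 1L),
      cum_tot = cumsum(tot)[seq_len(K)],
      cum_ev = cumsum(ev)[seq_len(K)],
      bin = bin[ii],
      event = if (is.null(outcome)) rep(0L, length(ii)) else outcome[ii]
    )
  })
}

# rate matrix (K x B) for one stratum given below-counts matrices
stratum_rate <- function(metric, n_s, tot_below, ev_below, ev_total) {
  if (metric == "cdf") {
    list(rate = tot_below / n_s,
         defined = matrix(TRUE, nrow(tot_below), ncol(tot_below)),
         cond = matrix(n_s, nrow(tot_below), ncol(tot_below)))
  } else if (metric == "for") {
    defined <- tot_below > 0
    rate <- ifelse(defined, ev_below / tot_below, 0)
    list(rate = rate, defined = defined, cond = tot_below)
  } else { # fdr
    above <- n_s - tot_below
    ev_above <- sweep(-ev_below, 2, as.numeric(ev_total), `+`)
    defined <- above > 0
    rate <- ifelse(defined, (above - ev_above) / above, 0)
    list(rate = rate, defined = defined, cond = above)
  }
}

# Weighted stratified curve with multinomial (within-stratum) bootstrap.
# weights: named vector over stratum keys, summing to 1 over the caller's
# reference distribution. Strata absent from `binned`, or with an empty
# conditioning set at a cutoff, are dropped there and the remaining weights
# renormalised; the dropped reference mass is reported per cutoff. Returns
# estimate/lower/upper/se/n_effective/dropped_mass, each length K.
strata_curve_boot <- function(binned, weights, grid, metric,
                              n_boot = 1000, seed = NULL, conf = 0.95) {
  K <- length(grid)
  keys <- names(binned)
  w <- weights[keys]
  w[is.na(w)] <- 0
  if (sum(w) <= 0) {
    abort("No overlap between reference strata and group strata.",
          class = "fairaudit_error_no_overlap")
  }

  num <- rep(0, K); wsum <- rep(0, K); n_eff <- rep(0, K)
  for (i in seq_along(binned)) {
    b <- binned[[i]]
    st <- stratum_rate(metric, b$n,
                       matrix(b$cum_tot, ncol = 1),
                       matrix(b$cum_ev, ncol = 1),
                       b$n_event)
    d <- st$defined[, 1]
    num <- num + ifelse(d, w[i] * st$rate[, 1], 0)
    wsum <- wsum + ifelse(d, w[i], 0)
    n_eff <- n_eff + st$cond[, 1]
  }
  estimate <- ifelse(wsum > 0, num / wsum, NA_real_)
  dropped <- 1 - wsum

  lower <- upper <- se <- rep(NA_real_, K)
  if (n_boot > 0) {
    reps <- with_seed(seed, {
      bnum <- matrix(0, K, n_boot); bw <- matrix(0, K, n_boot)
      for (i in seq_along(binned)) {
        b <- binned[[i]]
        cell <- b$bin + (K + 2L) * b$event
        cnt <- table(cell)
        cell_bin <- as.integer(names(cnt)) %% (K + 2L)
        cell_ev <- as.integer(names(cnt)) %/% (K + 2L)
        ord <- order(cell_bin)
        cnt <- as.integer(cnt)[ord]
        cell_bin <- cell_bin[ord]; cell_ev <- cell_ev[ord]
        draws <- rmultinom(n_boot, b$n, cnt / b$n)
        cum_all <- rbind(0, col_cumsum(draws))
        pos <- findInterval(seq_len(K), cell_bin)
        tot_below <- cum_all[pos + 1L, , drop = FALSE]
        evrows <- cell_ev == 1L
        if (any(evrows)) {
          cum_ev <- rbind(0, col_cumsum(draws[evrows, , drop = FALSE]))
          pos_ev <- findInterval(seq_len(K), cell_bin[evrows])
          ev_below <- cum_ev[pos_ev + 1L, , drop = FALSE]
          ev_total <- cum_ev[nrow(cum_ev), ]
        } else {
          ev_below <- matrix(0, K, n_boot)
          ev_total <- rep(0, n_boot)
        }
        st <- stratum_rate(metric, b$n, tot_below, ev_below, ev_total)
        bnum <- bnum + ifelse(st$defined, w[i] * st$rate, 0)
        bw <- bw + ifelse(st$defined, w[i], 0)
      }
      ifelse(bw > 0, bnum / bw, NA_real_)
    })
    alpha <- (1 - conf) / 2
    qs <- apply(reps, 1, function(r) {
      if (all(is.na(r))) return(c(NA_real_, NA_real_, NA_real_))
      c(quantile(r, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE),
        sd(r, na.rm = TRUE))
    })
    lower <- qs[1, ]; upper <- qs[2, ]; se <- qs[3, ]
  }
  list(estimate = estimate, lower = lower, upper = upper, se = se,
       n_effective = n_eff, dropped_mass = dropped)
}
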