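# Independent brute-force reference implementations: explicit loops over
# individuals and strata, no shared code with the package internals.

oracle_cdf <- function(scores, cutoff) {
  hits <- 0
  for (s in scores) if (s < cutoff) hits <- hits + 1
  hits / length(scores)
}

oracle_for <- function(scores, outcomes, cutoff) {
  num <- 0; den <- 0
  for (i in seq_along(scores)) {
    if (scores[i] < cutoff) {
      den <- den + 1
      if (outcomes[i] == 1) num <- num + 1
    }
  }
  if (den == 0) NA_real_ else num / den
}

oracle_fdr <- function(scores, outcomes, cutoff) {
  num <- 0; den <- 0
  for (i in seq_along(scores)) {
    if (scores[i] >= cutoff) {
      den <- den + 1
      if (outcomes[i] == 0) num <- num + 1
    }
  }
  if (den == 0) NA_real_ else num / den
}

oracle_auroc <- function(scores, outcomes) {
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# stratum label per row: loops, independent of make_strata
oracle_stratum <- function(table, age_bands) {
  out <- character(nrow(table))
  for (i in seq_len(nrow(table))) {
    band <- 0
    for (edge in age_bands) if (table$age[i] >= edge) band <- band + 1
    out[i] <- paste(band, table$sex[i], table$simd_decile[i], sep = "|")
  }
  out
}

# counterfactual CDF: target weights, source within-stratum CDFs
oracle_counterfactual <- function(table, target, source, cutoff, age_bands) {
  st <- oracle_stratum(table, age_bands)
  t_st <- st[target]; s_st <- st[source]
  s_scores <- table$score[source]
  total <- 0; wsum <- 0
  for (key in unique(t_st)) {
    w <- sum(t_st == key) / length(t_st)
    sel <- s_st == key
    if (sum(sel) == 0) next
    total <- total + w * oracle_cdf(s_scores[sel], cutoff)
    wsum <- wsum + w
  }
  if (wsum == 0) NA_real_ else total / wsum
}

# standardised FOR/FDR under the pooled-pair reference: weights from the
# pooled rows restricted to strata occupied by both groups
oracle_adjusted <- function(table, rows, other_rows, metric, cutoff,
                            age_bands) {
  st <- oracle_stratum(table, age_bands)
  common <- intersect(unique(st[rows]), unique(st[other_rows]))
  ref_st <- st[rows | other_rows]
  ref_st <- ref_st[ref_st %in% common]
  g_st <- st[rows]
  sc <- table$score[rows]; y <- table$outcome[rows]
  total <- 0; wsum <- 0
  for (key in unique(ref_st)) {
    w <- sum(ref_st == key) / length(ref_st)
    sel <- g_st == key
    if (sum(sel) == 0) next
    rate <- if (metric == "for") oracle_for(sc[sel], y[sel], cutoff)
            else oracle_fdr(sc[sel], y[sel], cutoff)
    if (is.na(rate)) next
    total <- total + w * rate
    wsum <- wsum + w
  }
  if (wsum == 0) NA_real_ else total / wsum
}

# decomposition proportions by explicit counting
oracle_decomposition <- function(categories, low) {
  cats <- sort(unique(categories))
  A <- B <- numeric(length(cats))
  for (k in seq_along(cats)) {
    A[k] <- sum(categories == cats[k]) / length(categories)
    if (any(low)) {
      B[k] <- sum(categories[low] == cats[k]) / sum(low)
    } else B[k] <- NA_real_
  }
  data.frame(category = cats, A = A, B = B)
}
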