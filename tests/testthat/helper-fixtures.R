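# Shared fixture builders and independent oracles for the test suite.

# A clean qPCR count row with chosen proportions (no noise, no censoring).
qpcr_row <- function(sample_id = "s1", total = 1e7,
                     p_b1 = 0.2, p_b2 = 0.1, p_d = 0.1, p_a1 = 0.2) {
  tibble::tibble(
    sample_id = sample_id, total_cfu = total,
    b1_cfu = p_b1 * total, b2_cfu = p_b2 * total, d_cfu = p_d * total,
    yjaa_cfu = (p_a1 + p_b2) * total
  )
}

# Independent Pearson chi-square oracle: direct sum over cells of
# (observed - expected)^2 / expected under the independence model.
brute_force_chisq <- function(x) {
  n <- sum(x)
  expected <- outer(rowSums(x), colSums(x)) / n
  sum((x - expected)^2 / expected)
}

# Independent two-sided exact p oracle for a 2x2 table: enumerate every
# table with the same margins using binomial coefficients directly.
enumerate_exact_p <- function(ka, na, kb, nb) {
  k <- ka + kb
  support <- max(0, k - nb):min(na, k)
  probs <- choose(na, support) * choose(nb, k - support) / choose(na + nb, k)
  p_obs <- choose(na, ka) * choose(nb, kb) / choose(na + nb, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Random small non-negative integer table with no zero margins.
random_table <- function(nr, nc) {
  repeat {
    x <- matrix(rpois(nr * nc, lambda = 3), nr, nc)
    if (all(rowSums(x) > 0) && all(colSums(x) > 0)) return(x)
  }
}

# Simulate, quantify and classify a cohort in one call.
classified_cohort <- function(templates = default_templates(),
                              n_per_template = 50,
                              noise = noise_model(), seed = 7) {
  co <- simulate_cohort(templates, n_per_template, noise, seed = seed)
  qpcr <- dplyr::select(co, "sample_id", "template", "species", "habitat",
                        "diet", dplyr::ends_with("_cfu"),
                        -dplyr::starts_with("true_"))
  compute_proportions(qpcr) |>
    apply_detection_thresholds(noise) |>
    classify_samples()
}
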