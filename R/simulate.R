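# Dirichlet draw via normalized gammas. A zero alpha drops that dimension:
# rgamma(shape = 0) is identically 0, so the proportion is fixed at 0.
rdirichlet_one <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) {
    # all concentrations zero in practice never happens for valid templates;
    # fall back to the mean direction
    return(alpha / sum(alpha))
  }
  g / sum(g)
}

#' Simulate a synthetic cohort of hosts, communities and qPCR readouts
#'
#' Draws, per template, `n_per_template` hosts with their latent ("true")
#' \emph{E. coli} communities and the noisy qPCR measurements of them.
#' Compositions are Dirichlet around the template mean, total loads
#' log-normal in log10 CFU/g, and measurements follow [simulate_qpcr()].
#' Randomness is fully determined by `seed` through per-sample substreams,
#' so the same call always returns the same tibble and enlarging
#' `n_per_template` leaves earlier samples unchanged.
#'
#' @param templates a tibble of community templates, as returned by
#'   [default_templates()] or built with [community_template()].
#' @param n_per_template number of samples to draw from each template.
#' @param noise a [noise_model()].
#' @param seed integer root seed.
#' @param a1_fraction fraction of phylogroup A belonging to the yjaA-positive
#'   A1 subgroup (default 0.5).
#' @return a tibble with one row per sample: host columns (`sample_id`,
#'   `template`, `species`, `habitat`, `diet`), the latent community
#'   (`true_p_a`, `true_p_b1`, `true_p_b2`, `true_p_d`, `true_a1_fraction`,
#'   `true_total_cfu`) and the measured counts (`total_cfu`, `b1_cfu`,
#'   `b2_cfu`, `d_cfu`, `yjaa_cfu`).
#' @export
#' @examples
#' cohort <- simulate_cohort(default_templates(), n_per_template = 5, seed = 1)
#' dplyr::count(cohort, template, species)
simulate_cohort <- function(templates, n_per_template, noise = noise_model(),
                            seed, a1_fraction = 0.5) {
  stopifnot(n_per_template >= 1, inherits(noise, "colitype_noise"))
  check_fraction(a1_fraction, "a1_fraction")
  lookup <- host_species_table()

  rows <- purrr::map(seq_len(nrow(templates)), function(t_idx) {
    tmpl <- templates[t_idx, ]
    alpha <- tmpl$concentration * tmpl$composition_mean[[1]]
    pool <- tmpl$species[[1]]
    # one substream per sample: draws are independent of n_per_template
    draws <- vapply(seq_len(n_per_template), function(i) {
      with_substream(derive_seed(seed, t_idx, i, 1), {
        c(sample.int(length(pool), 1),
          rdirichlet_one(alpha),
          10^rnorm(1, tmpl$log10_cfu_mean, tmpl$log10_cfu_sd))
      })
    }, numeric(6))
    species <- pool[draws[1, ]]
    host_idx <- match(species, lookup$species)
    tibble::tibble(
      sample_id = sprintf("%s_%04d", tmpl$enterocolitype,
                          seq_len(n_per_template)),
      template = tmpl$enterocolitype,
      species = species,
      habitat = lookup$habitat[host_idx],
      diet = lookup$diet[host_idx],
      true_p_a = draws[2, ],
      true_p_b1 = draws[3, ],
      true_p_b2 = draws[4, ],
      true_p_d = draws[5, ],
      true_a1_fraction = a1_fraction,
      true_total_cfu = draws[6, ],
      .qpcr_seed = vapply(seq_len(n_per_template),
                          function(i) derive_seed(seed, t_idx, i, 2),
                          integer(1))
    )
  }) |> dplyr::bind_rows()

  measured <- simulate_qpcr(rows, noise, seed = rows$.qpcr_seed)
  dplyr::select(measured, -".qpcr_seed")
}

#' Simulate qPCR measurement of latent communities
#'
#' Applies the measurement model to each latent community: every probe
#' count (16S total, B1, B2, D, yjaA) is the true count multiplied by an
#' independent log-normal error `10^Normal(0, log10_measurement_sd)`; the
#' yjaA probe targets the A1 subgroup together with B2, so its true count
#' is the A1 count plus the B2 count. Probe counts falling below
#' `probe_lod_fraction` of the measured total are censored to 0 (reported
#' as undetected, not an error).
#'
#' @param communities a tibble with columns `true_p_a`, `true_p_b1`,
#'   `true_p_b2`, `true_p_d`, `true_a1_fraction`, `true_total_cfu`, and
#'   optionally `sample_id`.
#' @param noise a [noise_model()].
#' @param seed integer root seed, or an integer vector with one derived
#'   seed per row.
#' @return the input tibble with measurement columns `total_cfu`,
#'   `b1_cfu`, `b2_cfu`, `d_cfu`, `yjaa_cfu` appended.
#' @export
#' @examples
#' comm <- tibble::tibble(true_p_a = 0.6, true_p_b1 = 0.2, true_p_b2 = 0.1,
#'                        true_p_d = 0.1, true_a1_fraction = 0.5,
#'                        true_total_cfu = 1e7)
#' simulate_qpcr(comm, noise_model(0), seed = 1)
simulate_qpcr <- function(communities, noise = noise_model(), seed) {
  stopifnot(inherits(noise, "colitype_noise"))
  n <- nrow(communities)
  seeds <- if (length(seed) == n) seed else
    vapply(seq_len(n), function(i) derive_seed(seed, i), integer(1))

  err <- t(vapply(seeds, function(s) {
    with_substream(s, 10^rnorm(5, 0, noise$log10_measurement_sd))
  }, numeric(5)))
  if (n == 1) err <- matrix(err, nrow = 1)

  total_true <- communities$true_total_cfu
  a1_true <- communities$true_p_a * communities$true_a1_fraction * total_true
  true_counts <- cbind(
    total = total_true,
    b1 = communities$true_p_b1 * total_true,
    b2 = communities$true_p_b2 * total_true,
    d = communities$true_p_d * total_true,
    yjaa = a1_true + communities$true_p_b2 * total_true
  )
  meas <- true_counts * err
  lod <- noise$probe_lod_fraction * meas[, "total"]
  for (probe in c("b1", "b2", "d", "yjaa")) {
    meas[meas[, probe] < lod, probe] <- 0
  }
  dplyr::mutate(
    communities,
    total_cfu = as.numeric(meas[, "total"]),
    b1_cfu = as.numeric(meas[, "b1"]),
    b2_cfu = as.numeric(meas[, "b2"]),
    d_cfu = as.numeric(meas[, "d"]),
    yjaa_cfu = as.numeric(meas[, "yjaa"])
  )
}

#' Simulate a panel of B2 strains with Bernoulli virulence genes
#'
#' Each of the 20 virulence-factor genes is drawn independently as
#' Bernoulli(prevalence) for each strain, reproducing the marginal gene
#' prevalences of a reference group.
#'
#' @param group_label origin group recorded on every strain, e.g.
#'   `"animal"`, `"human_exclusive"`, `"human_nonexclusive"`.
#' @param n_strains number of strains to draw.
#' @param gene_prevalences named numeric vector: per-gene presence
#'   probability. Names must be exactly the 20 genes of [vf_genes()].
#' @param seed integer root seed.
#' @return a tibble with `strain_id`, `origin_group` and one 0/1 column
#'   per gene.
#' @export
#' @examples
#' prev <- setNames(rep(0.5, 20), vf_genes())
#' simulate_strain_panel("animal", 3, prev, seed = 7)
simulate_strain_panel <- function(group_label, n_strains, gene_prevalences,
                                  seed) {
  stopifnot(n_strains >= 1)
  genes <- vf_genes()
  unknown <- setdiff(names(gene_prevalences), genes)
  if (length(unknown) > 0) {
    stop_colitype(sprintf("Unknown virulence gene(s): %s.",
                          paste(unknown, collapse = ", ")),
                  "colitype_unknown_gene")
  }
  missing <- setdiff(genes, names(gene_prevalences))
  if (length(missing) > 0) {
    stop_colitype(sprintf("Missing virulence gene(s): %s.",
                          paste(missing, collapse = ", ")),
                  "colitype_missing_gene")
  }
  check_fraction(gene_prevalences, "gene_prevalences")
  prev <- gene_prevalences[genes]

  mat <- t(vapply(seq_len(n_strains), function(i) {
    with_substream(derive_seed(seed, i), rbinom(length(genes), 1, prev))
  }, integer(length(genes))))
  colnames(mat) <- genes
  dplyr::bind_cols(
    tibble::tibble(
      strain_id = sprintf("%s_%04d", group_label, seq_len(n_strains)),
      origin_group = group_label
    ),
    tibble::as_tibble(mat)
  )
}
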