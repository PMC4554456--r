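#' The 20 extraintestinal virulence-factor genes
#'
#' Adhesins (papC, papGIII, sfa/foc, iha, hra, ibeA), iron-capture systems
#' (fyuA, irp2, iroN, aer, ireA), protectins (kpsMTII, neuC, ompT, traT)
#' and toxins (hlyC, cnf1, usp, sat, clbQ). `sfa/foc` is encoded as
#' `sfa_foc` in column names.
#'
#' @return character vector of the 20 gene names in fixed order.
#' @export
vf_genes <- function() {
  c("papC", "papGIII", "sfa_foc", "iha", "hra", "ibeA",
    "fyuA", "irp2", "iroN", "aer", "ireA",
    "kpsMTII", "neuC", "ompT", "traT",
    "hlyC", "cnf1", "usp", "sat", "clbQ")
}

#' Published prevalences of the 20 virulence genes in B2 commensal strains
#'
#' Per-gene prevalence (percent) of three origin groups of B2 strains:
#' human "exclusive" (n = 20, from samples where B2 exceeded 90% of the
#' population), human "non-exclusive" (n = 10) and animal (n = 13).
#'
#' @return a tibble with columns `gene`, `group`, `prevalence_percent`
#'   and `n`.
#' @export
#' @examples
#' reference_prevalences() |> dplyr::filter(group == "animal")
reference_prevalences <- function() {
  pct <- list(
    human_exclusive = c(45, 15, 50, 15, 35, 40, 95, 95, 80, 40, 20,
                        60, 60, 80, 50, 35, 30, 95, 20, 60),
    human_nonexclusive = c(40, 10, 10, 40, 10, 40, 90, 90, 60, 20, 40,
                           70, 50, 90, 80, 20, 10, 100, 30, 20),
    animal = c(0, 0, 15.38, 0, 38.46, 46.15, 84.62, 84.62, 46.15, 7.69,
               30.77, 61.54, 23.08, 84.62, 46.15, 7.69, 0, 46.15, 0, 15.38)
  )
  ns <- c(human_exclusive = 20L, human_nonexclusive = 10L, animal = 13L)
  purrr::imap(pct, function(p, g) {
    tibble::tibble(gene = vf_genes(), group = g, prevalence_percent = p,
                   n = ns[[g]])
  }) |> dplyr::bind_rows()
}

#' Virulence score of each strain
#'
#' The virulence score is the number of virulence factors present among
#' the 20 tested, i.e. the row sum of the gene indicators: an integer in
#' \[0, 20\].
#'
#' @param strains a tibble with the 20 gene columns of [vf_genes()]
#'   (0/1 values).
#' @return the input with an integer `vf_score` column appended.
#' @export
#' @examples
#' prev <- setNames(rep(1, 20), vf_genes())
#' simulate_strain_panel("animal", 2, prev, seed = 1) |> vf_score()
vf_score <- function(strains) {
  genes <- vf_genes()
  missing <- setdiff(genes, names(strains))
  if (length(missing) > 0) {
    stop_colitype(sprintf("Missing gene column(s): %s.",
                          paste(missing, collapse = ", ")),
                  "colitype_missing_gene")
  }
  vals <- as.matrix(strains[genes])
  if (!all(vals %in% c(0, 1))) {
    stop_colitype("Gene columns must be binary 0/1.", "colitype_bad_genes")
  }
  dplyr::mutate(strains, vf_score = as.integer(rowSums(vals)))
}

#' Reconstruct integer counts from printed percentages
#'
#' Given a prevalence printed as a percentage of `n` subjects, recovers
#' the integer count as `round(percent / 100 * n)` and checks consistency:
#' re-formatting the count as a percentage rounded to two decimals must
#' reproduce the printed value, else the pair is flagged (the count is
#' still returned).
#'
#' @param prevalence_percent printed percentage(s) in \[0, 100\].
#' @param n group size(s), >= 1.
#' @return a tibble with columns `prevalence_percent`, `n`, `count`,
#'   `consistent`.
#' @export
#' @examples
#' reconstruct_counts(c(46.15, 84.62, 0), 13)
reconstruct_counts <- function(prevalence_percent, n) {
  if (any(prevalence_percent < 0 | prevalence_percent > 100)) {
    stop_colitype("`prevalence_percent` must lie in [0, 100].",
                  "colitype_bad_fraction")
  }
  if (any(n < 1 | n != round(n))) {
    stop_colitype("`n` must be a positive integer.", "colitype_bad_counts")
  }
  out <- tibble::tibble(prevalence_percent = prevalence_percent, n = n)
  dplyr::mutate(
    out,
    count = as.integer(round(.data$prevalence_percent / 100 * .data$n)),
    consistent = round(100 * .data$count / .data$n, 2) ==
      round(.data$prevalence_percent, 2)
  )
}

#' Reconstruct a strain panel realizing published per-gene counts
#'
#' Builds a synthetic panel of `n` strains whose per-gene marginal counts
#' equal the counts reconstructed from printed percentages. Per-strain
#' gene combinations are not recoverable from marginals, so each gene's
#' positives are assigned to the first `count` strains - an arbitrary,
#' deterministic arrangement that preserves every marginal (and hence the
#' mean virulence score exactly) but no gene-gene correlation.
#'
#' @param prevalence a tibble with columns `gene`, `prevalence_percent`
#'   (one row per gene of [vf_genes()]), e.g. one group of
#'   [reference_prevalences()].
#' @param n number of strains in the group.
#' @param group_label origin group recorded on every strain.
#' @return a strain tibble as in [simulate_strain_panel()].
#' @export
#' @examples
#' animal <- dplyr::filter(reference_prevalences(), group == "animal")
#' panel <- reconstruct_strain_panel(animal, n = 13, group_label = "animal")
#' mean(vf_score(panel)$vf_score) # 6.3846
reconstruct_strain_panel <- function(prevalence, n, group_label) {
  genes <- vf_genes()
  if (!setequal(prevalence$gene, genes)) {
    stop_colitype("`prevalence` must contain exactly the 20 genes.",
                  "colitype_missing_gene")
  }
  counts <- reconstruct_counts(
    prevalence$prevalence_percent[match(genes, prevalence$gene)], n
  )$count
  mat <- vapply(counts, function(k) c(rep(1L, k), rep(0L, n - k)), integer(n))
  if (n == 1) mat <- matrix(mat, nrow = 1)
  colnames(mat) <- genes
  dplyr::bind_cols(
    tibble::tibble(strain_id = sprintf("%s_r%02d", group_label, seq_len(n)),
                   origin_group = group_label),
    tibble::as_tibble(mat)
  )
}

#' Per-group gene prevalences and virulence-score summaries
#'
#' Tabulates, for each origin group, the positive count and prevalence of
#' every gene, and the mean and standard deviation (n - 1 denominator) of
#' the virulence score. Because the score is the row sum of the gene
#' indicators, each group's mean score equals the sum of its per-gene
#' prevalence fractions exactly.
#'
#' @param strains a strain tibble with `origin_group` and the 20 gene
#'   columns.
#' @return a list of class `colitype_prevalence` with `genes` (per
#'   gene x group: `positive_count`, `n`, `prevalence`) and `scores` (per
#'   group: `n`, `mean_score`, `sd_score`); [tidy()] returns the gene
#'   table, [glance()] the score table.
#' @export
group_prevalence <- function(strains) {
  if (nrow(strains) == 0) {
    stop_colitype("`strains` is empty.", "colitype_empty_input")
  }
  scored <- vf_score(strains)
  genes_long <- scored |>
    tidyr::pivot_longer(dplyr::all_of(vf_genes()), names_to = "gene",
                        values_to = "present") |>
    dplyr::group_by(.data$origin_group, .data$gene) |>
    dplyr::summarise(positive_count = sum(.data$present),
                     n = dplyr::n(),
                     prevalence = .data$positive_count / .data$n,
                     .groups = "drop") |>
    dplyr::mutate(gene = factor(.data$gene, levels = vf_genes())) |>
    dplyr::arrange(.data$origin_group, .data$gene) |>
    dplyr::mutate(gene = as.character(.data$gene))
  scores <- scored |>
    dplyr::group_by(.data$origin_group) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_score = mean(.data$vf_score),
                     sd_score = sd(.data$vf_score),
                     .groups = "drop")
  structure(list(genes = genes_long, scores = scores),
            class = "colitype_prevalence")
}

#' @export
print.colitype_prevalence <- function(x, ...) {
  cat("Virulence-factor prevalence by origin group\n")
  print(x$scores)
  invisible(x)
}

#' @describeIn group_prevalence the per-gene prevalence tibble.
#' @param x,object a `colitype_prevalence` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.colitype_prevalence <- function(x, ...) x$genes

#' @describeIn group_prevalence the per-group score summary tibble.
#' @exportS3Method generics::glance
glance.colitype_prevalence <- function(x, ...) x$scores

# Two-sided exact hypergeometric p-value for a 2x2 table: the sum of the
# probabilities of all tables (with the same margins) no more likely than
# the observed one. The (1 + 1e-7) relative tolerance guards against
# floating-point ties, as in the conventional implementation.
exact_hypergeometric_p <- function(ka, na, kb, nb) {
  k_total <- ka + kb
  support <- max(0, k_total - nb):min(na, k_total)
  probs <- dhyper(support, na, nb, k_total)
  p_obs <- dhyper(ka, na, nb, k_total)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Compare a gene's prevalence between two groups
#'
#' Tests association in the 2x2 table (positives/negatives by group) two
#' ways: the exact hypergeometric test (the default inference for the
#' small group sizes typical of strain collections, 10-20 per group) and
#' the chi-square test, with Yates continuity correction switchable.
#'
#' @param positives_a,n_a positives and group size of the first group.
#' @param positives_b,n_b positives and group size of the second group.
#' @param correct apply continuity correction in the chi-square test
#'   (default TRUE, as `stats::chisq.test`).
#' @return a one-row tibble: the input counts, `p_exact`, `chisq`,
#'   `p_chisq`.
#' @export
#' @examples
#' compare_prevalence(29, 30, 6, 13) # usp, humans vs animals
compare_prevalence <- function(positives_a, n_a, positives_b, n_b,
                               correct = TRUE) {
  if (n_a == 0 || n_b == 0) {
    stop_colitype("Group sizes must be positive.", "colitype_bad_counts")
  }
  if (positives_a < 0 || positives_a > n_a || positives_b < 0 ||
      positives_b > n_b) {
    stop_colitype("Positives must lie in [0, n].", "colitype_bad_counts")
  }
  tab <- matrix(c(positives_a, n_a - positives_a,
                  positives_b, n_b - positives_b), nrow = 2)
  chs <- suppressWarnings(chisq.test(tab, correct = correct))
  tibble::tibble(
    positives_a = positives_a, n_a = n_a,
    positives_b = positives_b, n_b = n_b,
    p_exact = exact_hypergeometric_p(positives_a, n_a, positives_b, n_b),
    chisq = unname(chs$statistic),
    p_chisq = unname(chs$p.value)
  )
}

#' Compare virulence scores across groups
#'
#' Two groups are compared with the two-sided Wilcoxon rank-sum test,
#' three or more with the Kruskal-Wallis test. When every value in every
#' group is identical there is nothing to rank; the p-value is 1 by
#' convention.
#'
#' @param groups a list of two or more non-empty numeric vectors.
#' @return a one-row tibble with `method`, `statistic`, `p_value` and
#'   `n_groups`.
#' @export
#' @examples
#' compare_scores(list(c(1, 2, 3), c(101, 102, 103)))
compare_scores <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 ||
      any(lengths(groups) == 0)) {
    stop_colitype("`groups` must be a list of >= 2 non-empty vectors.",
                  "colitype_empty_input")
  }
  all_vals <- unlist(groups)
  if (length(unique(all_vals)) == 1) {
    method <- if (length(groups) == 2) "wilcoxon" else "kruskal-wallis"
    return(tibble::tibble(method = method, statistic = NA_real_,
                          p_value = 1, n_groups = length(groups)))
  }
  if (length(groups) == 2) {
    ht <- suppressWarnings(wilcox.test(groups[[1]], groups[[2]],
                                       alternative = "two.sided"))
    method <- "wilcoxon"
  } else {
    ht <- kruskal.test(groups)
    method <- "kruskal-wallis"
  }
  tibble::tibble(method = method, statistic = unname(ht$statistic),
                 p_value = ht$p.value, n_groups = length(groups))
}
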