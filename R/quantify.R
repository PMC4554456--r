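#' Convert a qPCR cycle threshold to an absolute count
#'
#' Standard-curve conversion `count = 10^((ct - intercept) / slope)`.
#' Amplification curves have negative slope (a ten-fold more concentrated
#' template crosses threshold `|slope|` cycles earlier), so the count is
#' monotone decreasing in CT.
#'
#' @param ct cycle-threshold value(s).
#' @param slope standard-curve slope, must be negative (around -3.32 for
#'   100% amplification efficiency).
#' @param intercept standard-curve intercept: the CT of one unit of
#'   template.
#' @return numeric counts (CFU/g on a calibrated curve).
#' @export
#' @examples
#' ct_to_count(31.36, slope = -3.32, intercept = 38) # 100
ct_to_count <- function(ct, slope, intercept) {
  if (!all(is.finite(slope)) || any(slope >= 0)) {
    stop_colitype("`slope` must be negative for an amplification curve.",
                  "colitype_bad_slope")
  }
  if (!all(is.finite(ct))) {
    stop_colitype("`ct` must be finite.", "colitype_bad_ct")
  }
  10^((ct - intercept) / slope)
}

#' Compute phylogroup proportions from qPCR counts
#'
#' The B1, B2 and D proportions are the probe counts as fractions of the
#' 16S-based total \emph{E. coli} count. Phylogroup A carries no specific
#' probe and is obtained by subtraction, `p_a = 1 - p_b1 - p_b2 - p_d`;
#' its yjaA-positive A1 subgroup comes from the yjaA probe (which counts
#' A1 together with B2) as `p_a1 = (yjaa - b2) / total`, and A0 is the
#' remainder of A. Measurement noise can push probe sums above the total:
#' negative subtraction results are clamped to 0 and probe proportions
#' above 1 are capped, with per-sample flags recording both events.
#'
#' @param counts a tibble of qPCR counts with columns `sample_id`,
#'   `total_cfu`, `b1_cfu`, `b2_cfu`, `d_cfu`, `yjaa_cfu` (all >= 0).
#'   Extra columns are carried through.
#' @return a tibble with one row per sample: `sample_id`, `ecoli_present`
#'   (FALSE when `total_cfu` is 0; such samples have `NA` proportions and
#'   are excluded from composition analyses, not errors), proportions
#'   `p_a`, `p_a1`, `p_a0`, `p_b1`, `p_b2`, `p_d`, and flags
#'   `flag_clamped` (negative subtraction clamped to 0) and `flag_capped`
#'   (probe proportion above 1 capped).
#' @export
#' @examples
#' counts <- tibble::tibble(sample_id = "s1", total_cfu = 1e7, b1_cfu = 2e6,
#'                          b2_cfu = 1e6, d_cfu = 1e6, yjaa_cfu = 3e6)
#' compute_proportions(counts)
compute_proportions <- function(counts) {
  needed <- c("sample_id", "total_cfu", "b1_cfu", "b2_cfu", "d_cfu", "yjaa_cfu")
  missing <- setdiff(needed, names(counts))
  if (length(missing) > 0) {
    stop_colitype(sprintf("`counts` is missing column(s): %s.",
                          paste(missing, collapse = ", ")),
                  "colitype_missing_column")
  }
  num <- counts[setdiff(needed, "sample_id")]
  if (any(vapply(num, function(x) any(!is.finite(x) | x < 0), logical(1)))) {
    stop_colitype("All counts must be finite and >= 0.", "colitype_bad_counts")
  }
  bad <- counts$total_cfu == 0 &
    (counts$b1_cfu > 0 | counts$b2_cfu > 0 | counts$d_cfu > 0 |
       counts$yjaa_cfu > 0)
  if (any(bad)) {
    stop_colitype(
      sprintf("Zero total with nonzero probe counts in sample(s): %s.",
              paste(counts$sample_id[bad], collapse = ", ")),
      "colitype_bad_counts"
    )
  }

  dplyr::mutate(
    counts,
    ecoli_present = .data$total_cfu > 0,
    .raw_b1 = ifelse(.data$ecoli_present, .data$b1_cfu / .data$total_cfu, NA_real_),
    .raw_b2 = ifelse(.data$ecoli_present, .data$b2_cfu / .data$total_cfu, NA_real_),
    .raw_d = ifelse(.data$ecoli_present, .data$d_cfu / .data$total_cfu, NA_real_),
    .raw_yjaa = ifelse(.data$ecoli_present, .data$yjaa_cfu / .data$total_cfu, NA_real_),
    flag_capped = dplyr::coalesce(
      .data$.raw_b1 > 1 | .data$.raw_b2 > 1 | .data$.raw_d > 1, FALSE),
    p_b1 = pmin(.data$.raw_b1, 1),
    p_b2 = pmin(.data$.raw_b2, 1),
    p_d = pmin(.data$.raw_d, 1),
    .raw_a = 1 - .data$p_b1 - .data$p_b2 - .data$p_d,
    flag_clamped = dplyr::coalesce(
      .data$.raw_a < 0 | .data$.raw_yjaa - .data$p_b2 < 0 |
        .data$.raw_yjaa - .data$p_b2 > .raw_a, FALSE),
    p_a = pmax(.data$.raw_a, 0),
    p_a1 = pmin(pmax(.data$.raw_yjaa - .data$p_b2, 0), .data$p_a),
    p_a0 = .data$p_a - .data$p_a1,
    .raw_b1 = NULL, .raw_b2 = NULL, .raw_d = NULL, .raw_yjaa = NULL,
    .raw_a = NULL
  ) |>
    dplyr::relocate("ecoli_present", "p_a", "p_a1", "p_a0", "p_b1", "p_b2",
                    "p_d", "flag_clamped", "flag_capped",
                    .after = "sample_id")
}

#' Apply compositional detection thresholds
#'
#' A probe-based phylogroup (B1, B2, D) counts as detected when its
#' proportion reaches 0.1% of the total population; phylogroup A, obtained
#' by subtraction, requires 15%. Thresholds are inclusive (the threshold
#' is the smallest detectable value). Undetected phylogroups keep their
#' numeric proportion; downstream categorization treats them as absent.
#'
#' @param profiles output of [compute_proportions()].
#' @param noise a [noise_model()] supplying `probe_lod_fraction` and
#'   `subtraction_lod_fraction`.
#' @return `profiles` with logical columns `detected_a`, `detected_b1`,
#'   `detected_b2`, `detected_d` and an integer `n_groups_detected`.
#' @export
#' @examples
#' counts <- tibble::tibble(sample_id = "s1", total_cfu = 1e7, b1_cfu = 2e6,
#'                          b2_cfu = 1e6, d_cfu = 1e6, yjaa_cfu = 3e6)
#' compute_proportions(counts) |> apply_detection_thresholds()
apply_detection_thresholds <- function(profiles, noise = noise_model()) {
  stopifnot(inherits(noise, "colitype_noise"))
  dplyr::mutate(
    profiles,
    detected_a = .data$ecoli_present & .data$p_a >= noise$subtraction_lod_fraction,
    detected_b1 = .data$ecoli_present & .data$p_b1 >= noise$probe_lod_fraction,
    detected_b2 = .data$ecoli_present & .data$p_b2 >= noise$probe_lod_fraction,
    detected_d = .data$ecoli_present & .data$p_d >= noise$probe_lod_fraction,
    n_groups_detected = .data$detected_a + .data$detected_b1 +
      .data$detected_b2 + .data$detected_d
  )
}
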