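# Fixed, documented column orders of the two indicator-table layouts.
# animal32: 14 phylogroup-category variables (no "minor A"/"absent A"
# column exists in this coding; samples in those states contribute no 1 in
# the phylogroup-A variable group), 3 CFU classes, 2 diversity classes,
# 9 animal species, 2 habitats, 2 diets.
ANIMAL32_COLUMNS <- c(
  "DA", "DB1", "DB2", "DD", "IA", "IB1", "IB2", "ID",
  "MB1", "MB2", "MD", "AB1", "AB2", "AD",
  "cfu_high", "cfu_intermediate", "cfu_low",
  "div_high", "div_low",
  "horse", "cow", "sheep", "pig", "wild_rabbit", "domesticated_rabbit",
  "deer", "boar", "chicken",
  "wild", "domesticated",
  "herbivorous", "omnivorous"
)

B2_SUBGROUPS <- c("I", "II", "III", "IV", "V", "VII", "VIII", "IX")

strain33_columns <- function() {
  c("human_exclusive", "human_nonexclusive", "animal",
    paste0("SG_", B2_SUBGROUPS), "SG_UA",
    vf_genes(), "vf_score_ge9")
}

#' Categorize a phylogroup's abundance within a sample
#'
#' Categories follow the compositional convention: dominant above 50% of
#' the population, intermediate within 10-50% (both bounds included),
#' minor below 10%, and absent when the phylogroup was not detected
#' regardless of its numeric proportion.
#'
#' @param proportion numeric proportion(s) in \[0, 1\].
#' @param detected logical detection flag(s).
#' @param dominant dominance threshold (strict, default 0.50).
#' @param intermediate_low lower bound of the intermediate class
#'   (inclusive, default 0.10).
#' @return character vector in
#'   `c("dominant", "intermediate", "minor", "absent")`.
#' @export
#' @examples
#' categorize_phylogroup(c(0.6, 0.5, 0.05, 0.3),
#'                       c(TRUE, TRUE, TRUE, FALSE))
categorize_phylogroup <- function(proportion, detected, dominant = 0.50,
                                  intermediate_low = 0.10) {
  ok <- is.na(proportion) | (proportion >= 0 & proportion <= 1)
  if (!all(ok)) {
    stop_colitype("`proportion` must lie in [0, 1].", "colitype_bad_fraction")
  }
  dplyr::case_when(
    is.na(proportion) | is.na(detected) ~ NA_character_,
    !detected ~ "absent",
    proportion > dominant ~ "dominant",
    proportion >= intermediate_low ~ "intermediate",
    .default = "minor"
  )
}

#' Classify total E. coli load
#'
#' High above 10^7 CFU/g (strictly), low below 10^6 CFU/g (strictly),
#' intermediate otherwise; the boundaries 10^6 and 10^7 fall in the
#' intermediate class.
#'
#' @param total_cfu positive total count(s), CFU per gram of feces.
#' @param cfu_high,cfu_low class boundaries, defaults 10^7 and 10^6 CFU/g.
#' @return character vector in `c("high", "intermediate", "low")`.
#' @export
#' @examples
#' classify_cfu(c(5e7, 5e6, 1e7, 5e5))
classify_cfu <- function(total_cfu, cfu_high = 1e7, cfu_low = 1e6) {
  if (any(!is.na(total_cfu) & (!is.finite(total_cfu) | total_cfu <= 0))) {
    stop_colitype("`total_cfu` must be positive.", "colitype_bad_counts")
  }
  dplyr::case_when(
    is.na(total_cfu) ~ NA_character_,
    total_cfu > cfu_high ~ "high",
    total_cfu < cfu_low ~ "low",
    .default = "intermediate"
  )
}

#' Assign enterocolitypes from dominance pattern and host domain
#'
#' Deterministic per-sample rule operationalizing the five enterocolitypes:
#' in humans, near-exclusive B2 (above 90%) or dominant B2 gives E4 and
#' dominant A gives E5; in animals, dominant B2 gives E1 (wild-herbivore
#' type), dominant B1 gives E2 (domesticated-herbivore type) and dominant
#' A gives E3 (omnivore type). A sample with no dominant phylogroup (or a
#' dominant D) is `"unassigned"`. CFU class and diversity are descriptive
#' characteristics of the types, not assignment criteria.
#'
#' @param is_human logical: host is human.
#' @param p_b2 numeric B2 proportion (for the 90% exclusivity rule).
#' @param category_a,category_b1,category_b2 abundance categories from
#'   [categorize_phylogroup()].
#' @param exclusivity exclusivity threshold on `p_b2` (strict, default
#'   0.90).
#' @return character vector in `c("E1".."E5", "unassigned")`.
#' @export
assign_enterocolitype <- function(is_human, p_b2, category_a, category_b1,
                                  category_b2, exclusivity = 0.90) {
  dplyr::case_when(
    is.na(category_b2) ~ NA_character_,
    is_human & !is.na(p_b2) & p_b2 > exclusivity ~ "E4",
    is_human & category_b2 == "dominant" ~ "E4",
    is_human & category_a == "dominant" ~ "E5",
    !is_human & category_b2 == "dominant" ~ "E1",
    !is_human & category_b1 == "dominant" ~ "E2",
    !is_human & category_a == "dominant" ~ "E3",
    .default = "unassigned"
  )
}

#' Derive per-sample categorical phenotypes
#'
#' Adds, per sample: the abundance category of each phylogroup, the CFU
#' class of the total load, the diversity class (high iff all four
#' phylogroups were detected), and the enterocolitype. Samples without
#' \emph{E. coli} (`ecoli_present == FALSE`) get `NA` phenotypes.
#'
#' @param profiles output of [apply_detection_thresholds()]; must carry
#'   `total_cfu` and either a `habitat` column or be joined with `hosts`.
#' @param hosts optional tibble with `sample_id`, `species`, `habitat`,
#'   `diet` to join on `sample_id`.
#' @param config a [pipeline_config()] supplying the classification
#'   thresholds.
#' @return the input with columns `category_a`, `category_b1`,
#'   `category_b2`, `category_d`, `cfu_class`, `diversity_class` and
#'   `enterocolitype` appended.
#' @export
#' @examples
#' simulate_cohort(default_templates(), 3, seed = 1) |>
#'   dplyr::select(sample_id, species, habitat, diet, dplyr::ends_with("_cfu")) |>
#'   compute_proportions() |>
#'   apply_detection_thresholds() |>
#'   classify_samples()
classify_samples <- function(profiles, hosts = NULL,
                             config = pipeline_config()) {
  if (!is.null(hosts)) {
    profiles <- dplyr::left_join(profiles, hosts, by = "sample_id")
  }
  if (!"habitat" %in% names(profiles)) {
    stop_colitype("Need a `habitat` column (join host metadata first).",
                  "colitype_missing_column")
  }
  dplyr::mutate(
    profiles,
    category_a = categorize_phylogroup(.data$p_a, .data$detected_a,
                                       config$dominant, config$intermediate_low),
    category_b1 = categorize_phylogroup(.data$p_b1, .data$detected_b1,
                                        config$dominant, config$intermediate_low),
    category_b2 = categorize_phylogroup(.data$p_b2, .data$detected_b2,
                                        config$dominant, config$intermediate_low),
    category_d = categorize_phylogroup(.data$p_d, .data$detected_d,
                                       config$dominant, config$intermediate_low),
    cfu_class = classify_cfu(ifelse(.data$ecoli_present, .data$total_cfu,
                                    NA_real_),
                             config$cfu_high, config$cfu_low),
    diversity_class = ifelse(.data$ecoli_present,
                             ifelse(.data$n_groups_detected == 4,
                                    "high", "low"),
                             NA_character_),
    enterocolitype = assign_enterocolitype(
      .data$habitat == "human", .data$p_b2, .data$category_a,
      .data$category_b1, .data$category_b2, config$exclusivity
    )
  )
}

indicator_cols <- function(value, levels) {
  out <- lapply(levels, function(l) as.integer(!is.na(value) & value == l))
  names(out) <- levels
  out
}

#' Build a binary indicator table for correspondence analysis
#'
#' Encodes each record as a row of 0/1 indicator variables ("present, 1;
#' absent, 0") in a fixed, documented column order, so tables are
#' byte-reproducible.
#'
#' The `"animal32"` layout (one row per fecal sample, 32 columns) encodes
#' the phylogroup abundance categories (`DA`, `DB1`, `DB2`, `DD`, `IA`,
#' `IB1`, `IB2`, `ID`, `MB1`, `MB2`, `MD`, `AB1`, `AB2`, `AD` - there is
#' deliberately no minor-A or absent-A column), the three CFU classes, the
#' two diversity classes, the nine animal species, the two habitats and
#' the two diets. The `"strain33"` layout (one row per B2 strain, 33
#' columns) encodes the three origin groups, the eight B2 subgroups plus
#' unassigned, the 20 virulence genes and a virulence score of 9 or more.
#'
#' @param data for `"animal32"`, classified samples from
#'   [classify_samples()] (samples without \emph{E. coli} are dropped);
#'   for `"strain33"`, a strain tibble with `strain_id`, `origin_group`,
#'   the 20 gene columns and optionally `b2_subgroup`.
#' @param variable_set `"animal32"` or `"strain33"`.
#' @return a tibble whose first column is the row identifier and whose
#'   remaining columns are 0/1 integers in the documented order.
#' @export
build_indicator_table <- function(data,
                                  variable_set = c("animal32", "strain33")) {
  variable_set <- match.arg(variable_set)
  if (variable_set == "animal32") {
    data <- dplyr::filter(data, .data$ecoli_present)
    species_levels <- ANIMAL32_COLUMNS[20:28]
    unknown <- setdiff(unique(data$species), species_levels)
    if (length(unknown) > 0) {
      stop_colitype(sprintf("Unknown species label(s) for animal32: %s.",
                            paste(unknown, collapse = ", ")),
                    "colitype_unknown_species")
    }
    cols <- c(
      list(
        DA = as.integer(data$category_a == "dominant"),
        DB1 = as.integer(data$category_b1 == "dominant"),
        DB2 = as.integer(data$category_b2 == "dominant"),
        DD = as.integer(data$category_d == "dominant"),
        IA = as.integer(data$category_a == "intermediate"),
        IB1 = as.integer(data$category_b1 == "intermediate"),
        IB2 = as.integer(data$category_b2 == "intermediate"),
        ID = as.integer(data$category_d == "intermediate"),
        MB1 = as.integer(data$category_b1 == "minor"),
        MB2 = as.integer(data$category_b2 == "minor"),
        MD = as.integer(data$category_d == "minor"),
        AB1 = as.integer(data$category_b1 == "absent"),
        AB2 = as.integer(data$category_b2 == "absent"),
        AD = as.integer(data$category_d == "absent")
      ),
      indicator_cols(data$cfu_class,
                     c("high", "intermediate", "low")) |>
        setNames(c("cfu_high", "cfu_intermediate", "cfu_low")),
      indicator_cols(data$diversity_class, c("high", "low")) |>
        setNames(c("div_high", "div_low")),
      indicator_cols(data$species, species_levels),
      indicator_cols(data$habitat, c("wild", "domesticated")),
      indicator_cols(data$diet, c("herbivorous", "omnivorous"))
    )
    out <- dplyr::bind_cols(tibble::tibble(sample_id = data$sample_id),
                            tibble::as_tibble(cols[ANIMAL32_COLUMNS]))
  } else {
    genes <- vf_genes()
    missing <- setdiff(c("strain_id", "origin_group", genes), names(data))
    if (length(missing) > 0) {
      stop_colitype(sprintf("Strain table is missing column(s): %s.",
                            paste(missing, collapse = ", ")),
                    "colitype_missing_column")
    }
    groups <- c("human_exclusive", "human_nonexclusive", "animal")
    unknown <- setdiff(unique(data$origin_group), groups)
    if (length(unknown) > 0) {
      stop_colitype(sprintf("Unknown origin group(s): %s.",
                            paste(unknown, collapse = ", ")),
                    "colitype_unknown_group")
    }
    subgroup <- if ("b2_subgroup" %in% names(data)) data$b2_subgroup else
      rep("UA", nrow(data))
    subgroup[is.na(subgroup) | !(subgroup %in% B2_SUBGROUPS)] <- "UA"
    score <- vf_score(data)$vf_score
    cols <- c(
      indicator_cols(data$origin_group, groups),
      indicator_cols(subgroup, c(B2_SUBGROUPS, "UA")) |>
        setNames(c(paste0("SG_", B2_SUBGROUPS), "SG_UA")),
      lapply(data[genes], as.integer),
      list(vf_score_ge9 = as.integer(score >= 9))
    )
    out <- dplyr::bind_cols(tibble::tibble(strain_id = data$strain_id),
                            tibble::as_tibble(cols[strain33_columns()]))
  }
  if (anyDuplicated(out[[1]])) {
    stop_colitype("Duplicate row identifiers in indicator table.",
                  "colitype_duplicate_id")
  }
  out
}
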