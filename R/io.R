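read_validated_tsv <- function(path, required, numeric_cols) {
  if (!file.exists(path)) {
    stop_colitype(sprintf("File not found: %s.", path), "colitype_io")
  }
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop_colitype(sprintf("%s: missing column(s): %s.", path,
                          paste(missing, collapse = ", ")),
                  "colitype_missing_column")
  }
  for (col in intersect(numeric_cols, names(tbl))) {
    val <- suppressWarnings(as.numeric(tbl[[col]]))
    bad <- which(is.na(val) & !is.na(tbl[[col]]) | !is.finite(val) | val < 0)
    if (length(bad) > 0) {
      stop_colitype(
        sprintf("%s: line %d, column `%s`: expected a non-negative number, got \"%s\".",
                path, bad[1] + 1, col, tbl[[col]][bad[1]]),
        "colitype_io"
      )
    }
    tbl[[col]] <- val
  }
  tbl
}

#' Read a per-sample qPCR count table
#'
#' Tab-separated, UTF-8, with case-sensitive header columns `sample_id`,
#' `total_cfu`, `b1_cfu`, `b2_cfu`, `d_cfu`, `yjaa_cfu` (CFU per gram;
#' non-negative). Validation errors cite the file, line and column.
#'
#' @param path path to the TSV file.
#' @return a tibble of qPCR counts ready for [compute_proportions()].
#' @export
read_qpcr_table <- function(path) {
  num <- c("total_cfu", "b1_cfu", "b2_cfu", "d_cfu", "yjaa_cfu")
  read_validated_tsv(path, c("sample_id", num), num)
}

#' Read a host metadata table
#'
#' Tab-separated with columns `sample_id` and `species`; `habitat` and
#' `diet` are derived from the fixed species lookup
#' ([host_species_table()]), and if present in the file are checked
#' against it.
#'
#' @param path path to the TSV file.
#' @return a tibble with `sample_id`, `species`, `habitat`, `diet`.
#' @export
read_host_table <- function(path) {
  tbl <- read_validated_tsv(path, c("sample_id", "species"), character(0))
  lookup <- host_species_table()
  bad <- which(!(tbl$species %in% lookup$species))
  if (length(bad) > 0) {
    stop_colitype(
      sprintf("%s: line %d, column `species`: unknown species \"%s\".",
              path, bad[1] + 1, tbl$species[bad[1]]),
      "colitype_unknown_species"
    )
  }
  joined <- dplyr::left_join(tbl[c("sample_id", "species")], lookup,
                             by = "species")
  for (col in c("habitat", "diet")) {
    if (col %in% names(tbl)) {
      bad <- which(tbl[[col]] != joined[[col]])
      if (length(bad) > 0) {
        stop_colitype(
          sprintf("%s: line %d, column `%s`: \"%s\" contradicts the species lookup (expected \"%s\").",
                  path, bad[1] + 1, col, tbl[[col]][bad[1]],
                  joined[[col]][bad[1]]),
          "colitype_io"
        )
      }
    }
  }
  joined
}

#' Read a per-strain binary virulence-gene table
#'
#' Tab-separated with columns `strain_id`, `origin_group`
#' (`human_exclusive`/`human_nonexclusive`/`animal`), all 20 gene columns
#' of [vf_genes()] with 0/1 values, and optionally `b2_subgroup`,
#' `o_type`, `colicin_phage`.
#'
#' @param path path to the TSV file.
#' @return a validated strain tibble.
#' @export
read_strain_table <- function(path) {
  tbl <- read_validated_tsv(path, c("strain_id", "origin_group"), character(0))
  missing <- setdiff(vf_genes(), names(tbl))
  if (length(missing) > 0) {
    stop_colitype(sprintf("%s: missing gene column(s): %s.", path,
                          paste(missing, collapse = ", ")),
                  "colitype_missing_gene")
  }
  groups <- c("human_exclusive", "human_nonexclusive", "animal")
  bad <- which(!(tbl$origin_group %in% groups))
  if (length(bad) > 0) {
    stop_colitype(
      sprintf("%s: line %d, column `origin_group`: unknown value \"%s\".",
              path, bad[1] + 1, tbl$origin_group[bad[1]]),
      "colitype_unknown_group"
    )
  }
  for (g in vf_genes()) {
    val <- suppressWarnings(as.numeric(tbl[[g]]))
    bad <- which(!(val %in% c(0, 1)))
    if (length(bad) > 0) {
      stop_colitype(
        sprintf("%s: line %d, column `%s`: gene values must be 0 or 1, got \"%s\".",
                path, bad[1] + 1, g, tbl[[g]][bad[1]]),
        "colitype_bad_genes"
      )
    }
    tbl[[g]] <- as.integer(val)
  }
  tbl
}

#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis in one place, with
#' defaults equal to the published values: dominance above 50%,
#' intermediate from 10%, B2 exclusivity above 90%, probe limit of
#' detection 0.1%, subtraction limit of detection 15%, and CFU class
#' boundaries at 10^6 and 10^7 CFU/g; plus the simulation templates,
#' noise model and seed used when the pipeline simulates its own cohort.
#'
#' @param dominant,intermediate_low,exclusivity classification thresholds
#'   (fractions).
#' @param cfu_low,cfu_high CFU class boundaries (CFU/g).
#' @param noise a [noise_model()] (also supplies the two LODs).
#' @param templates community templates for simulation.
#' @param n_per_template samples per template when simulating.
#' @param seed integer root seed.
#' @return a list of class `colitype_config`.
#' @export
pipeline_config <- function(dominant = 0.50, intermediate_low = 0.10,
                            exclusivity = 0.90, cfu_low = 1e6,
                            cfu_high = 1e7, noise = noise_model(),
                            templates = default_templates(),
                            n_per_template = 25, seed = 1L) {
  check_fraction(c(dominant, intermediate_low, exclusivity), "thresholds",
                 allow_zero = FALSE, allow_one = FALSE)
  if (!(intermediate_low < dominant && dominant < exclusivity)) {
    stop_colitype("Need intermediate_low < dominant < exclusivity.",
                  "colitype_bad_config")
  }
  if (!(cfu_low > 0 && cfu_low < cfu_high)) {
    stop_colitype("Need 0 < cfu_low < cfu_high.", "colitype_bad_config")
  }
  structure(
    list(dominant = dominant, intermediate_low = intermediate_low,
         exclusivity = exclusivity, cfu_low = cfu_low, cfu_high = cfu_high,
         noise = noise, templates = templates,
         n_per_template = n_per_template, seed = as.integer(seed)),
    class = "colitype_config"
  )
}

log_line <- function(con, ...) {
  msg <- sprintf(...)
  writeLines(msg, con)
  message(msg)
}

#' Run the end-to-end pipeline
#'
#' Quantifies phylogroup proportions, classifies samples, builds the
#' animal indicator table, fits the correspondence analysis and (when a
#' strain table is supplied) produces the virulence report, writing every
#' stage as TSV into `output_dir` together with a run log. Outputs are
#' deterministic given the config seed. A cohort in which no sample
#' contains \emph{E. coli} yields empty composition outputs and an
#' explanatory log line, not an error.
#'
#' @param config a [pipeline_config()].
#' @param qpcr,hosts tibbles from [read_qpcr_table()] /
#'   [read_host_table()]; when both are `NULL` a cohort is simulated from
#'   the config templates.
#' @param strains optional strain tibble from [read_strain_table()].
#' @param output_dir directory for outputs (created if needed).
#' @return invisibly, a named list of the stage tibbles.
#' @export
run_pipeline <- function(config = pipeline_config(), qpcr = NULL,
                         hosts = NULL, strains = NULL,
                         output_dir = tempfile("colitype_run_")) {
  stopifnot(inherits(config, "colitype_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(output_dir, "run_log.txt")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  log_line(con, "colitype %s | seed %d",
           as.character(utils::packageVersion("colitype")), config$seed)

  if (is.null(qpcr)) {
    cohort <- simulate_cohort(config$templates, config$n_per_template,
                              config$noise, seed = config$seed)
    qpcr <- dplyr::select(cohort, "sample_id", dplyr::ends_with("_cfu"),
                          -dplyr::starts_with("true_"))
    hosts <- dplyr::select(cohort, "sample_id", "species", "habitat", "diet")
    log_line(con, "simulated cohort: %d samples from %d templates",
             nrow(qpcr), nrow(config$templates))
  }
  log_line(con, "quantify: %d samples", nrow(qpcr))
  profiles <- compute_proportions(qpcr) |>
    apply_detection_thresholds(config$noise)
  log_line(con, "warnings: %d clamped, %d capped, %d without E. coli",
           sum(profiles$flag_clamped), sum(profiles$flag_capped),
           sum(!profiles$ecoli_present))
  phenotypes <- classify_samples(profiles, hosts, config = config)

  readr::write_tsv(profiles, file.path(output_dir, "profiles.tsv"))
  readr::write_tsv(phenotypes, file.path(output_dir, "phenotypes.tsv"))

  out <- list(profiles = profiles, phenotypes = phenotypes)
  # the animal indicator table excludes human samples by design
  animals <- dplyr::filter(phenotypes, .data$habitat != "human")
  with_ecoli <- dplyr::filter(animals, .data$ecoli_present)
  if (nrow(with_ecoli) == 0) {
    log_line(con, "no sample contains E. coli; composition analyses skipped")
  } else {
    if (nrow(animals) < nrow(phenotypes)) {
      log_line(con, "animal table: %d human samples set aside",
               nrow(phenotypes) - nrow(animals))
    }
    indicator <- build_indicator_table(animals, "animal32")
    # variables that never occur in this cohort carry no inertia; drop them
    occupied <- c(TRUE, colSums(indicator[, -1]) > 0)
    fit <- fit_ca(indicator[, occupied])
    coords <- tidy(fit)
    readr::write_tsv(indicator, file.path(output_dir, "indicator.tsv"))
    readr::write_tsv(coords, file.path(output_dir, "ca_coordinates.tsv"))
    log_line(con, "ca: %d rows, total inertia %.4f, F1-F2 %.1f%%",
             nrow(indicator), fit$total_inertia,
             100 * plane_summary(fit, seq_len(min(2, fit$n_axes))))
    out$indicator <- indicator
    out$ca <- fit
  }
  if (!is.null(strains)) {
    prev <- group_prevalence(strains)
    report <- dplyr::left_join(tidy(prev), glance(prev),
                               by = c("origin_group", "n"))
    readr::write_tsv(report, file.path(output_dir, "vf_report.tsv"))
    log_line(con, "vf-report: %d strains, %d groups", nrow(strains),
             nrow(glance(prev)))
    out$vf_report <- report
  }
  log_line(con, "done")
  invisible(out)
}
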