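#' Host species lookup table
#'
#' The nine animal species of the cohort plus humans, each with its fixed
#' habitat and diet. Species determines habitat and diet uniquely: e.g.
#' deer are wild herbivores, pigs domesticated omnivores, humans have the
#' dedicated habitat `"human"` and an omnivorous diet.
#'
#' @return a tibble with columns `species`, `habitat`
#'   (`wild`/`domesticated`/`human`) and `diet` (`herbivorous`/`omnivorous`).
#' @export
#' @examples
#' host_species_table()
host_species_table <- function() {
  tibble::tribble(
    ~species,              ~habitat,       ~diet,
    "pig",                 "domesticated", "omnivorous",
    "horse",               "domesticated", "herbivorous",
    "sheep",               "domesticated", "herbivorous",
    "cow",                 "domesticated", "herbivorous",
    "domesticated_rabbit", "domesticated", "herbivorous",
    "chicken",             "domesticated", "omnivorous",
    "wild_rabbit",         "wild",         "herbivorous",
    "boar",                "wild",         "omnivorous",
    "deer",                "wild",         "herbivorous",
    "human",               "human",        "omnivorous"
  )
}

#' Construct a community template
#'
#' A community template describes one enterocolitype as a generative
#' recipe: the expected phylogroup composition (A, B1, B2, D), a Dirichlet
#' concentration controlling between-host compositional spread, a
#' log-normal model for total \emph{E. coli} load, and the host species the
#' type is associated with.
#'
#' @param label enterocolitype label, one of `"E1"`..`"E5"`.
#' @param composition_mean numeric length-4 vector of expected proportions
#'   (A, B1, B2, D); must sum to 1.
#' @param concentration positive Dirichlet concentration; larger values
#'   give compositions tighter around `composition_mean`.
#' @param log10_cfu_mean,log10_cfu_sd mean and standard deviation of
#'   log10 total CFU per gram of feces; `log10_cfu_sd` must be positive.
#' @param species character vector of host species drawn uniformly for
#'   samples of this template; all must appear in [host_species_table()].
#' @return a one-row tibble (class `colitype_template` rows are plain
#'   tibble rows; templates are stacked with `dplyr::bind_rows()`).
#' @export
#' @examples
#' community_template("E4", c(0.02, 0.01, 0.95, 0.02), 200, 7.89, 0.52, "human")
community_template <- function(label, composition_mean, concentration,
                               log10_cfu_mean, log10_cfu_sd, species) {
  stopifnot(length(composition_mean) == 4)
  check_fraction(composition_mean, "composition_mean")
  if (abs(sum(composition_mean) - 1) > 1e-9) {
    stop_colitype("`composition_mean` must sum to 1 (tolerance 1e-9).",
                  "colitype_bad_template")
  }
  if (!is.finite(concentration) || concentration <= 0) {
    stop_colitype("`concentration` must be positive.", "colitype_bad_template")
  }
  if (!is.finite(log10_cfu_sd) || log10_cfu_sd <= 0) {
    stop_colitype("`log10_cfu_sd` must be positive.", "colitype_bad_template")
  }
  unknown <- setdiff(species, host_species_table()$species)
  if (length(unknown) > 0) {
    stop_colitype(sprintf("Unknown species: %s.", paste(unknown, collapse = ", ")),
                  "colitype_unknown_species")
  }
  tibble::tibble(
    enterocolitype   = label,
    composition_mean = list(setNames(as.numeric(composition_mean), PHYLOGROUPS)),
    concentration    = concentration,
    log10_cfu_mean   = log10_cfu_mean,
    log10_cfu_sd     = log10_cfu_sd,
    species          = list(species)
  )
}

#' Default enterocolitype templates
#'
#' One template per enterocolitype E1-E5. Compositions are illustrative
#' mixtures consistent with each type's defining dominance pattern (B2
#' dominant in wild herbivores for E1, B1 dominant in domesticated
#' herbivores for E2, A dominant in omnivores for E3, near-exclusive B2 in
#' humans for E4, A dominant in humans for E5); they are package defaults,
#' not measured cohort values. Total-load parameters for the human types
#' use the published human load (7.89 +/- 0.52 log10 CFU/g); animal types
#' use round values on the observed low/intermediate/high gradient.
#'
#' @param concentration Dirichlet concentration shared by all templates
#'   (default 200).
#' @return a tibble of five community templates.
#' @export
#' @examples
#' default_templates()
default_templates <- function(concentration = 200) {
  dplyr::bind_rows(
    community_template("E1", c(0.15, 0.05, 0.70, 0.10), concentration, 5.5, 1.0,
                       c("wild_rabbit", "deer")),
    community_template("E2", c(0.15, 0.60, 0.05, 0.20), concentration, 6.5, 0.5,
                       c("domesticated_rabbit", "horse", "sheep", "cow")),
    community_template("E3", c(0.60, 0.20, 0.05, 0.15), concentration, 7.3, 0.5,
                       c("boar", "pig", "chicken")),
    community_template("E4", c(0.02, 0.01, 0.95, 0.02), concentration, 7.89, 0.52,
                       "human"),
    community_template("E5", c(0.60, 0.15, 0.10, 0.15), concentration, 7.89, 0.52,
                       "human")
  )
}

#' qPCR measurement-noise and detection-threshold model
#'
#' @param log10_measurement_sd non-negative standard deviation of the
#'   multiplicative qPCR measurement error in log10 space (error is
#'   approximately constant on the CT scale, hence log-normal on counts).
#'   The default 0.03 log10 units corresponds to about a 0.1-cycle
#'   replicate SD on a standard curve of slope -3.32.
#' @param probe_lod_fraction limit of detection of the probe-based
#'   phylogroups (B1, B2, D) as a fraction of the total population;
#'   default 0.001 (0.1%).
#' @param subtraction_lod_fraction limit of detection of phylogroup A,
#'   which is obtained by subtraction; default 0.15 (15%).
#' @return a list of class `colitype_noise`.
#' @export
#' @examples
#' noise_model()              # study defaults
#' noise_model(0)             # noise-free measurement
noise_model <- function(log10_measurement_sd = 0.03,
                        probe_lod_fraction = 0.001,
                        subtraction_lod_fraction = 0.15) {
  if (!is.finite(log10_measurement_sd) || log10_measurement_sd < 0) {
    stop_colitype("`log10_measurement_sd` must be >= 0.", "colitype_bad_noise")
  }
  if (!(probe_lod_fraction >= 0 && probe_lod_fraction < subtraction_lod_fraction &&
        subtraction_lod_fraction < 1)) {
    stop_colitype(
      "Need 0 <= probe_lod_fraction < subtraction_lod_fraction < 1.",
      "colitype_bad_noise"
    )
  }
  structure(
    list(
      log10_measurement_sd = log10_measurement_sd,
      probe_lod_fraction = probe_lod_fraction,
      subtraction_lod_fraction = subtraction_lod_fraction
    ),
    class = "colitype_noise"
  )
}
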