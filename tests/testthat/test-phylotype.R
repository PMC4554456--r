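test_that("abundance categories partition [0,1] x detected", {
  expect_equal(
    categorize_phylogroup(c(0.60, 0.50, 0.05, 0.30, 0.10),
                          c(TRUE, TRUE, TRUE, FALSE, TRUE)),
    c("dominant", "intermediate", "minor", "absent", "intermediate")
  )
  # total and single-valued over a grid of proportions and both flags
  grid <- expand.grid(p = seq(0, 1, by = 0.01), det = c(TRUE, FALSE))
  cats <- categorize_phylogroup(grid$p, grid$det)
  expect_true(all(cats %in% c("dominant", "intermediate", "minor", "absent")))
  expect_true(all(cats[!grid$det] == "absent"))
  expect_error(categorize_phylogroup(1.2, TRUE),
               class = "colitype_bad_fraction")
})

test_that("CFU classes use strict bounds at 10^6 and 10^7", {
  expect_equal(classify_cfu(c(5e7, 5e6, 1e7, 1e6, 5e5)),
               c("high", "intermediate", "intermediate", "intermediate",
                 "low"))
  expect_error(classify_cfu(0), class = "colitype_bad_counts")
  expect_error(classify_cfu(-10), class = "colitype_bad_counts")
})

test_that("enterocolitype rule maps dominance and host domain", {
  # human, near-exclusive B2
  expect_equal(assign_enterocolitype(TRUE, 0.95, "minor", "absent",
                                     "dominant"), "E4")
  # human, B2 dominant but not exclusive
  expect_equal(assign_enterocolitype(TRUE, 0.6, "intermediate", "minor",
                                     "dominant"), "E4")
  expect_equal(assign_enterocolitype(TRUE, 0.1, "dominant", "minor",
                                     "minor"), "E5")
  # animals
  expect_equal(assign_enterocolitype(FALSE, 0.7, "minor", "minor",
                                     "dominant"), "E1")
  expect_equal(assign_enterocolitype(FALSE, 0.05, "intermediate", "dominant",
                                     "minor"), "E2")
  expect_equal(assign_enterocolitype(FALSE, 0.05, "dominant", "minor",
                                     "minor"), "E3")
  # no dominant group, or dominant D: unassigned
  expect_equal(assign_enterocolitype(FALSE, 0.3, "intermediate",
                                     "intermediate", "intermediate"),
               "unassigned")
  expect_equal(assign_enterocolitype(TRUE, 0.1, "minor", "minor", "minor"),
               "unassigned")
})

test_that("no dominant phylogroup implies unassigned in a classified cohort", {
  ph <- classified_cohort(n_per_template = 30, seed = 21)
  no_dom <- !(ph$category_a == "dominant" | ph$category_b1 == "dominant" |
                ph$category_b2 == "dominant" | ph$category_d == "dominant")
  expect_true(all(ph$enterocolitype[no_dom] == "unassigned"))
})

test_that("the animal32 indicator coding matches the documented layout", {
  pig <- tibble::tibble(
    sample_id = "pig1", ecoli_present = TRUE,
    p_a = 0.55, p_a1 = 0.2, p_a0 = 0.35, p_b1 = 0.3, p_b2 = 0, p_d = 0.05,
    flag_clamped = FALSE, flag_capped = FALSE, total_cfu = 5e7,
    detected_a = TRUE, detected_b1 = TRUE, detected_b2 = FALSE,
    detected_d = TRUE, n_groups_detected = 3L,
    species = "pig", habitat = "domesticated", diet = "omnivorous"
  )
  tab <- classify_samples(pig) |> build_indicator_table("animal32")
  expect_equal(ncol(tab), 33) # id column + 32 variables
  ones <- names(tab)[-1][unlist(tab[1, -1]) == 1]
  expect_setequal(ones, c("DA", "IB1", "MD", "AB2", "cfu_high", "div_low",
                          "pig", "domesticated", "omnivorous"))
})

test_that("indicator rows satisfy the exactly-one constraints per variable group", {
  ph <- classified_cohort(default_templates()[1:3, ], 40, seed = 5)
  tab <- build_indicator_table(ph, "animal32")
  expect_equal(names(tab)[-1], colitype:::ANIMAL32_COLUMNS)
  m <- as.matrix(tab[, -1])
  expect_true(all(m %in% c(0L, 1L)))
  one_of <- list(
    cfu = c("cfu_high", "cfu_intermediate", "cfu_low"),
    div = c("div_high", "div_low"),
    species = colitype:::ANIMAL32_COLUMNS[20:28],
    habitat = c("wild", "domesticated"),
    diet = c("herbivorous", "omnivorous")
  )
  for (grp in one_of) expect_true(all(rowSums(m[, grp]) == 1))
  # B1, B2, D each fall in exactly one of their four category columns
  for (g in c("B1", "B2", "D")) {
    cols <- paste0(c("D", "I", "M", "A"), g)
    expect_true(all(rowSums(m[, cols]) == 1))
  }
  # A has no minor/absent column: its two columns carry at most one 1
  expect_true(all(rowSums(m[, c("DA", "IA")]) <= 1))
})

test_that("human samples and unknown species are rejected by animal32", {
  ph <- classified_cohort(default_templates(), 5, seed = 2)
  expect_error(build_indicator_table(ph, "animal32"),
               class = "colitype_unknown_species")
  ph$species[ph$species == "human"] <- "okapi"
  expect_error(build_indicator_table(ph, "animal32"), "okapi")
})

test_that("the strain33 indicator table has 33 documented columns", {
  panels <- dplyr::bind_rows(
    reconstruct_strain_panel(
      dplyr::filter(reference_prevalences(), group == "human_exclusive"),
      20, "human_exclusive"),
    reconstruct_strain_panel(
      dplyr::filter(reference_prevalences(), group == "human_nonexclusive"),
      10, "human_nonexclusive"),
    reconstruct_strain_panel(
      dplyr::filter(reference_prevalences(), group == "animal"),
      13, "animal")
  )
  tab <- build_indicator_table(panels, "strain33")
  expect_equal(nrow(tab), 43)
  expect_equal(ncol(tab), 34) # id column + 33 variables
  m <- as.matrix(tab[, -1])
  expect_true(all(rowSums(m[, c("human_exclusive", "human_nonexclusive",
                                "animal")]) == 1))
  # without subgroup assignments every strain is SG_UA
  expect_true(all(m[, "SG_UA"] == 1))
  # score >= 9 column agrees with the computed score
  expect_equal(unname(m[, "vf_score_ge9"]),
               as.integer(vf_score(panels)$vf_score >= 9))
})

test_that("samples without E. coli are excluded from the indicator table", {
  ph <- classified_cohort(default_templates()[1, ], 10, seed = 3)
  ph$ecoli_present[1:2] <- FALSE
  tab <- build_indicator_table(ph, "animal32")
  expect_equal(nrow(tab), 8)
})
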