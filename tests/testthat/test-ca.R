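test_that("exact independence gives zero inertia and no informative axis", {
  fit <- fit_ca(matrix(10, 2, 2))
  expect_equal(fit$total_inertia, 0)
  expect_equal(fit$n_axes, 0)
  expect_length(fit$inertia_fractions, 0)
})

test_that("a diagonal 2x2 table has unit inertia on a single axis", {
  fit <- fit_ca(matrix(c(10, 0, 0, 10), 2))
  expect_equal(fit$total_inertia, 1)
  expect_equal(fit$n_axes, 1)
  expect_equal(fit$inertia_fractions, 1)
  # chi-square of this table is 20 on grand total 20
  expect_equal(glance(fit)$chisq, brute_force_chisq(matrix(c(10, 0, 0, 10), 2)))
})

test_that("total inertia equals Pearson chi-square over the grand total", {
  withr::with_seed(11, {
    for (i in 1:25) {
      x <- random_table(sample(2:8, 1), sample(2:8, 1))
      fit <- fit_ca(x)
      expect_lt(abs(fit$total_inertia * sum(x) - brute_force_chisq(x)), 1e-8)
      expect_lt(abs(sum(fit$principal_inertias) - fit$total_inertia), 1e-9)
    }
  })
})

test_that("axes are mass-orthogonal, centred, and reproducibly signed", {
  withr::with_seed(5, x <- random_table(7, 5))
  fit <- fit_ca(x)
  f <- fit$row_coordinates
  r <- fit$row_masses
  gram <- t(f) %*% (f * r)
  # weighted cross-products vanish off the diagonal...
  expect_true(all(abs(gram[upper.tri(gram)]) < 1e-8))
  # ...and the diagonal recovers the principal inertias
  expect_equal(unname(diag(gram)), fit$principal_inertias, tolerance = 1e-9)
  # mass-weighted centroid of row (and column) clouds is the origin
  expect_true(all(abs(colSums(f * r)) < 1e-9))
  expect_true(all(abs(colSums(fit$column_coordinates * fit$column_masses)) < 1e-9))
  # sign convention: largest-magnitude row coordinate positive on each axis
  for (j in seq_len(fit$n_axes)) {
    expect_gt(f[which.max(abs(f[, j])), j], 0)
  }
  expect_identical(fit_ca(x)$row_coordinates, f)
})

test_that("singular values descend and axis count respects the table rank", {
  withr::with_seed(7, x <- random_table(6, 4))
  fit <- fit_ca(x)
  expect_true(all(diff(fit$singular_values) <= 1e-12))
  expect_lte(fit$n_axes, min(dim(x)) - 1)
})

test_that("all-zero rows and columns are rejected by name", {
  x <- matrix(c(1, 0, 2, 0, 3, 0), 2, dimnames = list(c("a", "bad_row"), NULL))
  expect_error(fit_ca(x), "bad_row")
  y <- matrix(c(1, 2, 0, 0, 3, 4), 2,
              dimnames = list(NULL, c("c1", "bad_col", "c3")))
  expect_error(fit_ca(y), "bad_col")
  expect_error(fit_ca(matrix(-1, 2, 2)), class = "colitype_bad_table")
})

test_that("supplementary projection reproduces fitted rows and the centroid", {
  withr::with_seed(3, x <- random_table(5, 4))
  rownames(x) <- paste0("r", 1:5)
  colnames(x) <- paste0("c", 1:4)
  fit <- fit_ca(x)
  # self-consistency on every training row
  proj <- project_supplementary(fit, x)
  expect_true(all(abs(proj - fit$row_coordinates) < 1e-9))
  # a duplicate of an existing row lands on it
  dup <- x[2, , drop = FALSE]
  expect_true(all(abs(project_supplementary(fit, dup) -
                        fit$row_coordinates[2, ]) < 1e-9))
  # the column-mass profile is the centroid: the origin
  centroid <- matrix(fit$column_masses, nrow = 1,
                     dimnames = list("cm", names(fit$column_masses)))
  expect_true(all(abs(project_supplementary(fit, centroid)) < 1e-9))
  # column mismatch is an error
  bad <- dup
  colnames(bad) <- c("c1", "c2", "c3", "zz")
  expect_error(project_supplementary(fit, bad),
               class = "colitype_column_mismatch")
})

test_that("plane summaries add up the requested inertia fractions", {
  withr::with_seed(13, x <- random_table(6, 5))
  fit <- fit_ca(x)
  expect_equal(plane_summary(fit, 1), fit$inertia_fractions[1])
  expect_equal(plane_summary(fit, c(1, 2)),
               sum(fit$inertia_fractions[1:2]))
  expect_equal(plane_summary(fit, seq_len(fit$n_axes)), 1)
  expect_error(plane_summary(fit, fit$n_axes + 1),
               class = "colitype_bad_axis")
  one_axis <- fit_ca(matrix(c(10, 0, 0, 10), 2))
  expect_equal(plane_summary(one_axis, 1), 1)
})

test_that("tidy, glance and autoplot expose the fit", {
  withr::with_seed(17, x <- random_table(4, 3))
  fit <- fit_ca(x)
  td <- tidy(fit)
  expect_equal(nrow(td), (4 + 3) * fit$n_axes)
  expect_setequal(unique(td$point_type), c("row", "column"))
  gl <- glance(fit)
  expect_equal(gl$total_inertia, fit$total_inertia)
  expect_equal(gl$f1_f2_fraction, plane_summary(fit, c(1, 2)))
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    expect_s3_class(autoplot(fit), "ggplot")
  }
})

test_that("zero-noise animal enterocolitypes separate on the F1-F2 plane", {
  ph <- classified_cohort(default_templates()[1:3, ], 40, noise_model(0),
                          seed = 19)
  tab <- build_indicator_table(ph, "animal32")
  # drop indicator columns that never occur in this synthetic cohort
  tab <- tab[, c(TRUE, colSums(tab[, -1]) > 0)]
  fit <- fit_ca(tab)
  coords <- tibble::as_tibble(fit$row_coordinates[, 1:2],
                              .name_repair = ~c("f1", "f2"))
  coords$group <- ph$template[match(rownames(fit$row_coordinates),
                                    ph$sample_id)]
  cent <- coords |>
    dplyr::group_by(group) |>
    dplyr::summarise(f1 = mean(f1), f2 = mean(f2), .groups = "drop")
  d_between <- as.matrix(dist(cent[, c("f1", "f2")]))
  min_between <- min(d_between[upper.tri(d_between)])
  expect_gt(min_between, 0)
  disp <- coords |>
    dplyr::left_join(cent, by = "group", suffix = c("", "_c")) |>
    dplyr::summarise(d = mean(sqrt((f1 - f1_c)^2 + (f2 - f2_c)^2)))
  expect_lt(disp$d, min_between)
})
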