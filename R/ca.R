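as_ca_matrix <- function(table) {
  if (is.matrix(table)) {
    x <- table
    if (is.null(rownames(x))) rownames(x) <- paste0("row", seq_len(nrow(x)))
    if (is.null(colnames(x))) colnames(x) <- paste0("col", seq_len(ncol(x)))
    return(x)
  }
  df <- as.data.frame(table)
  is_num <- vapply(df, is.numeric, logical(1))
  x <- as.matrix(df[is_num])
  if (any(!is_num)) {
    ids <- df[[which(!is_num)[1]]]
    rownames(x) <- as.character(ids)
  } else if (is.null(rownames(x))) {
    rownames(x) <- paste0("row", seq_len(nrow(x)))
  }
  x
}

#' Correspondence analysis of a non-negative table
#'
#' Ordinates an indicator or contingency table by the chi-square distance:
#' the correspondence matrix `P = X / n` is centred on the independence
#' model and standardized, `S_ij = (P_ij - r_i c_j) / sqrt(r_i c_j)`, and
#' decomposed by SVD. Total inertia equals `sum(S^2)`, i.e. the Pearson
#' chi-square statistic of the table divided by its grand total. The
#' trivial axis of the uncentred problem is never produced; axes with
#' singular values below `1e-12` times the largest are truncated, and each
#' retained axis has its sign fixed by forcing its largest-magnitude row
#' coordinate positive, so results are reproducible.
#'
#' @param table a non-negative matrix, or a data frame whose non-numeric
#'   columns provide row labels (e.g. the output of
#'   [build_indicator_table()]).
#' @return an object of class `colitype_ca`: a list with
#'   `singular_values`, `principal_inertias`, `inertia_fractions`,
#'   `total_inertia`, `row_coordinates` and `column_coordinates`
#'   (principal coordinates, the symmetric map), `row_standard` and
#'   `column_standard` (standard coordinates), `row_masses`,
#'   `column_masses`, `n_axes` and the grand total `n`. Use [tidy()],
#'   [glance()], [autoplot()], [plane_summary()] and
#'   [project_supplementary()] on it.
#' @export
#' @examples
#' fit <- fit_ca(matrix(c(10, 0, 0, 10), 2))
#' fit$total_inertia # 1
fit_ca <- function(table) {
  x <- as_ca_matrix(table)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop_colitype("Table entries must be finite and >= 0.", "colitype_bad_table")
  }
  n <- sum(x)
  if (n <= 0) stop_colitype("Grand total must be positive.", "colitype_bad_table")
  zero_rows <- rownames(x)[rowSums(x) == 0]
  if (length(zero_rows) > 0) {
    stop_colitype(sprintf("All-zero row(s): %s.",
                          paste(zero_rows, collapse = ", ")),
                  "colitype_zero_margin")
  }
  zero_cols <- colnames(x)[colSums(x) == 0]
  if (length(zero_cols) > 0) {
    stop_colitype(sprintf("All-zero column(s): %s.",
                          paste(zero_cols, collapse = ", ")),
                  "colitype_zero_margin")
  }

  p <- x / n
  r <- rowSums(p)
  c_ <- colSums(p)
  s <- (p - tcrossprod(r, c_)) / sqrt(tcrossprod(r, c_))
  dec <- svd(s)

  kmax <- min(nrow(x), ncol(x)) - 1
  keep <- which(dec$d > 1e-12 * max(dec$d, 1e-300))
  keep <- head(keep, kmax)
  k <- length(keep)
  d <- dec$d[keep]
  u <- dec$u[, keep, drop = FALSE]
  v <- dec$v[, keep, drop = FALSE]

  row_std <- u / sqrt(r)
  col_std <- v / sqrt(c_)
  # principal coordinates = standard coordinates scaled by singular values
  row_pc <- sweep(row_std, 2, d, `*`)
  col_pc <- sweep(col_std, 2, d, `*`)

  if (k > 0) {
    # reproducible sign: largest-|.| row coordinate positive on each axis
    flip <- vapply(seq_len(k), function(j) {
      sign(row_pc[which.max(abs(row_pc[, j])), j])
    }, numeric(1))
    flip[flip == 0] <- 1
    row_std <- sweep(row_std, 2, flip, `*`)
    col_std <- sweep(col_std, 2, flip, `*`)
    row_pc <- sweep(row_pc, 2, flip, `*`)
    col_pc <- sweep(col_pc, 2, flip, `*`)
  }

  axis_names <- if (k > 0) paste0("F", seq_len(k)) else character(0)
  label <- function(m, rn) {
    dimnames(m) <- list(rn, axis_names)
    m
  }
  total_inertia <- sum(s^2)
  structure(
    list(
      singular_values = d,
      principal_inertias = d^2,
      inertia_fractions = if (k > 0 && sum(d^2) > 0) d^2 / sum(d^2) else numeric(0),
      total_inertia = total_inertia,
      row_coordinates = label(row_pc, rownames(x)),
      column_coordinates = label(col_pc, colnames(x)),
      row_standard = label(row_std, rownames(x)),
      column_standard = label(col_std, colnames(x)),
      row_masses = setNames(r, rownames(x)),
      column_masses = setNames(c_, colnames(x)),
      n_axes = k,
      n = n
    ),
    class = "colitype_ca"
  )
}

#' @export
print.colitype_ca <- function(x, ...) {
  cat(sprintf(
    "Correspondence analysis: %d x %d table, total inertia %.4f, %d axes\n",
    length(x$row_masses), length(x$column_masses), x$total_inertia, x$n_axes
  ))
  if (x$n_axes > 0) {
    cat("Inertia fractions:",
        paste(sprintf("%s %.1f%%", paste0("F", seq_len(min(4, x$n_axes))),
                      100 * x$inertia_fractions[seq_len(min(4, x$n_axes))]),
              collapse = ", "),
        if (x$n_axes > 4) "..." else "", "\n")
  }
  invisible(x)
}

#' Project supplementary rows onto fitted CA axes
#'
#' Places held-out rows on the axes of an existing fit via the transition
#' formula: each new row profile is multiplied by the column standard
#' coordinates. Re-projecting a fitted row reproduces its own principal
#' coordinates; a row proportional to the column-mass profile lands at the
#' origin (the centroid).
#'
#' @param result a `colitype_ca` fit.
#' @param new_rows matrix or data frame with exactly the fitted columns;
#'   every row sum must be positive.
#' @return a numeric matrix of principal coordinates (rows x axes).
#' @export
project_supplementary <- function(result, new_rows) {
  stopifnot(inherits(result, "colitype_ca"))
  x <- as_ca_matrix(new_rows)
  fitted_cols <- names(result$column_masses)
  if (!identical(colnames(x), fitted_cols)) {
    if (setequal(colnames(x), fitted_cols)) {
      x <- x[, fitted_cols, drop = FALSE]
    } else {
      stop_colitype("Columns of `new_rows` do not match the fitted table.",
                    "colitype_column_mismatch")
    }
  }
  rs <- rowSums(x)
  if (any(rs <= 0)) {
    stop_colitype("Every supplementary row must have a positive sum.",
                  "colitype_bad_table")
  }
  (x / rs) %*% result$column_standard
}

#' Fraction of total inertia carried by a set of axes
#'
#' @param result a `colitype_ca` fit.
#' @param axes integer axis indices (default `c(1, 2)`, the F1-F2 plane).
#' @return a single fraction in \[0, 1\].
#' @export
#' @examples
#' fit <- fit_ca(matrix(c(10, 2, 3, 1, 8, 5, 2, 2, 9), 3))
#' plane_summary(fit, c(1, 2))
plane_summary <- function(result, axes = c(1, 2)) {
  stopifnot(inherits(result, "colitype_ca"))
  axes <- as.integer(axes)
  if (length(axes) == 0 || any(axes < 1 | axes > result$n_axes)) {
    stop_colitype(sprintf("Axis index out of range (fit has %d axes).",
                          result$n_axes),
                  "colitype_bad_axis")
  }
  sum(result$inertia_fractions[axes])
}

#' @describeIn fit_ca tidy coordinates: one row per point and axis, with
#'   `point_type` (`"row"`/`"column"`), `label`, `axis`, principal and
#'   standard coordinates and (for points) the mass.
#' @param x,object a `colitype_ca` fit.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.colitype_ca <- function(x, ...) {
  long <- function(pc, std, masses, type) {
    if (ncol(pc) == 0) return(tibble::tibble())
    tibble::tibble(
      point_type = type,
      label = rep(rownames(pc), ncol(pc)),
      axis = rep(seq_len(ncol(pc)), each = nrow(pc)),
      coordinate = as.vector(pc),
      standard_coordinate = as.vector(std),
      mass = rep(unname(masses), ncol(pc))
    )
  }
  dplyr::bind_rows(
    long(x$row_coordinates, x$row_standard, x$row_masses, "row"),
    long(x$column_coordinates, x$column_standard, x$column_masses, "column")
  )
}

#' @describeIn fit_ca one-row summary: grand total, total inertia
#'   (chi-square / n), number of axes, and the F1 and F1-F2 inertia
#'   fractions.
#' @exportS3Method generics::glance
glance.colitype_ca <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    total_inertia = x$total_inertia,
    chisq = x$total_inertia * x$n,
    n_axes = x$n_axes,
    f1_fraction = if (x$n_axes >= 1) x$inertia_fractions[1] else NA_real_,
    f1_f2_fraction = if (x$n_axes >= 2) sum(x$inertia_fractions[1:2])
                     else if (x$n_axes == 1) x$inertia_fractions[1]
                     else NA_real_
  )
}

#' @describeIn fit_ca symmetric map of rows and columns on two axes.
#' @param axes pair of axis indices to display (default F1-F2).
#' @exportS3Method ggplot2::autoplot
autoplot.colitype_ca <- function(object, axes = c(1, 2), ...) {
  if (object$n_axes < max(axes)) {
    stop_colitype("Requested axes not available in this fit.",
                  "colitype_bad_axis")
  }
  dat <- tidy(object) |>
    dplyr::filter(.data$axis %in% axes) |>
    dplyr::mutate(which_axis = ifelse(.data$axis == axes[1], "x", "y")) |>
    tidyr::pivot_wider(id_cols = c("point_type", "label"),
                       names_from = "which_axis",
                       values_from = "coordinate")
  pct <- 100 * object$inertia_fractions[axes]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$point_type,
                                    shape = .data$point_type)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.6, size = 2.8, show.legend = FALSE) +
    ggplot2::labs(
      x = sprintf("F%d (%.1f%% of inertia)", axes[1], pct[1]),
      y = sprintf("F%d (%.1f%% of inertia)", axes[2], pct[2]),
      colour = NULL, shape = NULL
    ) +
    ggplot2::theme_minimal()
}
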