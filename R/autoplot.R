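#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods for morphometric results
#'
#' ggplot2 visualisations: `gpa_fit` shows the aligned landmark scatter
#' over the consensus; `shape_pca` shows a score scatter (`type =
#' "scores"`) or scree bar chart (`type = "scree"`); `trajectory_set` and
#' `trajectory_test` draw the group trajectories in the PC1-PC2 plane of
#' the pooled trajectory points; `cr_result` and `pls_result` show the
#' permutation null histogram with the observed statistic (`pls_result`
#' with `type = "scores"` shows the first score pair); `tps_grid` draws
#' the deformation grid with reference and target landmarks.
#'
#' @param object A fitted result.
#' @param ... Unused.
#' @return A ggplot object.
#' @name morphoplast-autoplot
NULL

#' @rdname morphoplast-autoplot
#' @method autoplot gpa_fit
#' @export
autoplot.gpa_fit <- function(object, ...) {
  tbl <- as_tibble(object$aligned)
  cons <- tibble::tibble(landmark = rownames(object$consensus),
                         x = object$consensus[, 1],
                         y = object$consensus[, 2])
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$landmark)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_point(data = cons, colour = "black", size = 2.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Procrustes-aligned landmarks",
                  x = NULL, y = NULL)
}

#' @rdname morphoplast-autoplot
#' @param type Plot flavour, see Details.
#' @param axes Which score axes to plot.
#' @param colour Optional factor column (from the attached factors) used to
#'   colour score points.
#' @method autoplot shape_pca
#' @export
autoplot.shape_pca <- function(object, type = c("scores", "scree"),
                               axes = c(1, 2), colour = NULL, ...) {
  type <- match.arg(type)
  if (type == "scree") {
    tbl <- tidy(object)
    return(ggplot2::ggplot(tbl, ggplot2::aes(
      x = factor(.data$axis, levels = .data$axis),
      y = .data$variance_fraction)) +
        ggplot2::geom_col() +
        ggplot2::labs(x = NULL, y = "variance fraction"))
  }
  tbl <- tibble::tibble(specimen = rownames(object$scores),
                        a = object$scores[, axes[1]],
                        b = object$scores[, axes[2]])
  if (!is.null(object$factors)) {
    tbl <- dplyr::left_join(tbl, object$factors, by = "specimen")
  }
  lab <- sprintf("PC%d (%.0f%%)", axes,
                 100 * object$variance_fractions[axes])
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$a, y = .data$b))
  p <- if (!is.null(colour) && colour %in% names(tbl)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]))
  } else {
    p + ggplot2::geom_point()
  }
  p + ggplot2::labs(x = lab[1], y = lab[2]) + ggplot2::coord_equal()
}

#' @noRd
trajectory_plot_data <- function(ts) {
  pts <- do.call(rbind, ts$points)
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr, nu = 0, nv = 2)
  sc <- ctr %*% sv$v
  tibble::tibble(
    group = rep(ts$groups, each = length(ts$levels)),
    level = rep(ts$levels, times = length(ts$groups)),
    PC1 = sc[, 1], PC2 = sc[, 2])
}

#' @rdname morphoplast-autoplot
#' @method autoplot trajectory_set
#' @export
autoplot.trajectory_set <- function(object, ...) {
  tbl <- trajectory_plot_data(object)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                    colour = .data$group)) +
    ggplot2::geom_path(ggplot2::aes(group = .data$group)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$level)) +
    ggplot2::scale_size_continuous(range = c(1, 3)) +
    ggplot2::labs(title = "Phenotypic trajectories",
                  size = object$order_factor, colour = object$group_factor)
}

#' @rdname morphoplast-autoplot
#' @method autoplot trajectory_test
#' @export
autoplot.trajectory_test <- function(object, ...) {
  autoplot(object$trajectories, ...)
}

#' @noRd
null_histogram <- function(null, observed, xlab) {
  ggplot2::ggplot(tibble::tibble(x = null), ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = observed, colour = "red",
                        linewidth = 1) +
    ggplot2::labs(x = xlab, y = "count")
}

#' @rdname morphoplast-autoplot
#' @method autoplot cr_result
#' @export
autoplot.cr_result <- function(object, ...) {
  null_histogram(object$null, object$observed, "covariance ratio (null)")
}

#' @rdname morphoplast-autoplot
#' @method autoplot pls_result
#' @export
autoplot.pls_result <- function(object, type = c("null", "scores"),
                                colour = "risk", ...) {
  type <- match.arg(type)
  if (type == "null") {
    if (is.null(object$null)) {
      stop("no null distribution; run integration_test()", call. = FALSE)
    }
    return(null_histogram(object$null, object$r_pls, "r-PLS (null)"))
  }
  tbl <- object$scores
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$xs, y = .data$ys))
  p <- if (colour %in% names(tbl)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]))
  } else {
    p + ggplot2::geom_point()
  }
  p + ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           colour = "purple") +
    ggplot2::labs(x = paste(object$partition$names[1], "block scores"),
                  y = paste(object$partition$names[2], "block scores"))
}

#' @rdname morphoplast-autoplot
#' @method autoplot tps_grid
#' @export
autoplot.tps_grid <- function(object, ...) {
  g <- object$grid
  ref <- tibble::tibble(x = object$reference[, 1],
                        y = object$reference[, 2])
  tgt <- tibble::tibble(x = object$target[, 1], y = object$target[, 2])
  ggplot2::ggplot(g, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(ggplot2::aes(group = .data$i), colour = "grey60",
                       linewidth = 0.3) +
    ggplot2::geom_path(ggplot2::aes(group = .data$j), colour = "grey60",
                       linewidth = 0.3) +
    ggplot2::geom_point(data = ref, colour = "grey30", size = 2) +
    ggplot2::geom_point(data = tgt, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Thin-plate-spline deformation",
                  x = NULL, y = NULL)
}

#' @importFrom rlang .data
NULL
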