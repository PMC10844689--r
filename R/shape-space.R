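#' Principal component analysis of Procrustes shape coordinates
#'
#' Eigen-decomposition of the covariance of flattened aligned coordinates.
#' Two-dimensional Procrustes superimposition removes four degrees of
#' freedom (two of translation, one each of rotation and scale), so at most
#' `min(n - 1, 2k - 4)` axes carry variance; trailing eigenvalues are
#' numerically null. Axis signs follow the largest-loading-positive
#' convention so repeated runs agree exactly.
#'
#' @param data An aligned `shape_data` (n >= 3).
#' @return A `shape_pca`: `eigenvalues`, `variance_fractions` (summing to 1
#'   over non-null axes), `loadings` (orthonormal columns), `scores`,
#'   `consensus` (mean configuration), `n_nonnull`.
#' @export
shape_pca <- function(data) {
  stopifnot(inherits(data, "shape_data"))
  if (!data$aligned) stop("data must be Procrustes-aligned", call. = FALSE)
  y <- coord_matrix(data)
  n <- nrow(y)
  if (n < 3L) stop("need at least 3 specimens", call. = FALSE)
  ctr <- colMeans(y)
  yc <- sweep(y, 2, ctr)
  sv <- svd(yc)
  eig <- sv$d^2 / (n - 1)
  nonnull <- eig > max(eig[1], .Machine$double.eps) * 1e-10
  load <- sv$v
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  scores <- yc %*% load
  rownames(scores) <- data$specimens
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  fr <- rep(0, length(eig))
  fr[nonnull] <- eig[nonnull] / sum(eig[nonnull])
  consensus <- unflatten_config(ctr, n_landmarks(data))
  dimnames(consensus) <- list(data$landmarks, c("x", "y"))
  structure(
    list(eigenvalues = eig, variance_fractions = fr, loadings = load,
         scores = scores, consensus = consensus,
         n_nonnull = sum(nonnull), landmarks = data$landmarks,
         factors = data$factors),
    class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("Shape PCA: ", nrow(x$scores), " specimens, ", x$n_nonnull,
      " non-null axes\n", sep = "")
  show <- seq_len(min(5L, x$n_nonnull))
  cat(paste0("PC", show, ": ",
             sprintf("%.1f%%", 100 * x$variance_fractions[show]),
             collapse = "  "), "\n")
  invisible(x)
}

#' Shape at a position along a principal component axis
#'
#' Reconstructs the landmark configuration `consensus + score * loading`
#' used as a thin-plate-spline target to visualise what an axis means.
#'
#' @param pca A [shape_pca()] result.
#' @param axis Axis index (within the non-null range).
#' @param magnitude `"min"` or `"max"` (the observed score extremes on that
#'   axis) or a number interpreted as a multiple of the axis score standard
#'   deviation.
#' @return A `k x 2` landmark configuration.
#' @export
axis_extreme_shapes <- function(pca, axis, magnitude = "max") {
  stopifnot(inherits(pca, "shape_pca"))
  if (axis < 1 || axis > pca$n_nonnull) {
    stop("axis ", axis, " is outside the non-null range 1..",
         pca$n_nonnull, call. = FALSE)
  }
  sc <- pca$scores[, axis]
  score <- if (identical(magnitude, "min")) {
    min(sc)
  } else if (identical(magnitude, "max")) {
    max(sc)
  } else {
    as.numeric(magnitude) * stats::sd(sc)
  }
  v <- pca$consensus + unflatten_config(score * pca$loadings[, axis],
                                        nrow(pca$consensus))
  dimnames(v) <- dimnames(pca$consensus)
  v
}

# TPS kernel U(r) = r^2 log(r^2), with the removable singularity U(0) = 0.
#' @noRd
tps_kernel <- function(r2) ifelse(r2 == 0, 0, r2 * log(r2))

#' @noRd
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
}

#' Thin-plate-spline deformation grid
#'
#' Fits the minimal-bending-energy 2-D interpolant mapping `reference`
#' landmarks exactly onto `target` landmarks (kernel `U(r) = r^2 log r^2`)
#' and warps a regular lattice over the reference bounding box to visualise
#' the deformation. The bending energy is the quadratic form of the warp
#' weights with the kernel matrix and is zero exactly when the map is
#' affine.
#'
#' @param reference,target `k x 2` configuration matrices (same k);
#'   reference must not be collinear.
#' @param lattice Integer lattice dimensions `c(nx, ny)`.
#' @param padding Fractional padding of the reference bounding box.
#' @return A `tps_grid`: `reference`, `target`, `affine` (3 x 2
#'   coefficients: intercept, x, y per output coordinate), `weights`
#'   (k x 2), `grid` (tibble of lattice points `x0, y0` and warped
#'   positions `x, y`), `bending_energy`, and `warp()`, a function mapping
#'   arbitrary points through the spline.
#' @export
tps_warp <- function(reference, target, lattice = c(24, 24),
                     padding = 0.1) {
  stopifnot(is.matrix(reference), is.matrix(target),
            nrow(reference) == nrow(target))
  k <- nrow(reference)
  kmat <- tps_kernel(pmax(cross_dist2(reference, reference), 0))
  pmat <- cbind(1, reference)
  l <- rbind(cbind(kmat, pmat),
             cbind(t(pmat), matrix(0, 3, 3)))
  rhs <- rbind(target, matrix(0, 3, 2))
  sol <- tryCatch(solve(l, rhs), error = function(e) {
    stop("singular TPS system: reference landmarks are collinear ",
         "or coincident", call. = FALSE)
  })
  w <- sol[seq_len(k), , drop = FALSE]
  a <- sol[k + 1:3, , drop = FALSE]
  be <- sum(diag(crossprod(w, kmat %*% w)))
  warp <- function(pts) {
    pts <- rbind(pts)
    cbind(1, pts) %*% a +
      tps_kernel(pmax(cross_dist2(pts, reference), 0)) %*% w
  }
  rng <- apply(reference, 2, range)
  pad <- padding * (rng[2, ] - rng[1, ])
  gx <- seq(rng[1, 1] - pad[1], rng[2, 1] + pad[1], length.out = lattice[1])
  gy <- seq(rng[1, 2] - pad[2], rng[2, 2] + pad[2], length.out = lattice[2])
  lat <- as.matrix(expand.grid(x0 = gx, y0 = gy))
  warped <- warp(lat)
  grid <- tibble::tibble(
    i = rep(seq_along(gx), times = length(gy)),
    j = rep(seq_along(gy), each = length(gx)),
    x0 = lat[, 1], y0 = lat[, 2],
    x = warped[, 1], y = warped[, 2])
  structure(
    list(reference = reference, target = target, affine = a, weights = w,
         grid = grid, bending_energy = max(be, 0), warp = warp),
    class = "tps_grid")
}

#' @export
print.tps_grid <- function(x, ...) {
  cat("<tps_grid> ", nrow(x$reference), " landmarks, bending energy ",
      format(x$bending_energy, digits = 4), "\n", sep = "")
  invisible(x)
}
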