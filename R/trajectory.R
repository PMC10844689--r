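#' Build phenotypic trajectories from cell mean shapes
#'
#' A phenotypic trajectory is the ordered path of a group's least-squares
#' mean shapes across an environmental gradient — here, a clone's mean
#' shapes connected in order of increasing predation risk.
#'
#' @param means A tibble from [fit_lsmeans()] containing the group and
#'   order columns and a `shape` list-column.
#' @param group_factor Name of the grouping column (e.g. `"clone"`).
#' @param order_factor Name of the ordering column (e.g. `"risk"`); its
#'   sorted unique values define the path order.
#' @return A `trajectory_set`: per group, an `L x 2k` matrix of flattened
#'   mean shapes in gradient order.
#' @export
build_trajectories <- function(means, group_factor, order_factor) {
  stopifnot(is.data.frame(means),
            all(c(group_factor, order_factor, "shape") %in% names(means)))
  groups <- unique(as.character(means[[group_factor]]))
  levels <- sort(unique(means[[order_factor]]))
  if (length(levels) < 2L) {
    stop("a trajectory needs at least two gradient levels", call. = FALSE)
  }
  pts <- lapply(groups, function(g) {
    sel <- means[as.character(means[[group_factor]]) == g, ]
    idx <- match(levels, sel[[order_factor]])
    if (anyNA(idx)) {
      stop("group ", g, " is missing gradient level(s): ",
           paste(levels[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    do.call(rbind, lapply(sel$shape[idx], function(m) as.vector(t(m))))
  })
  names(pts) <- groups
  structure(list(points = pts, groups = groups, levels = levels,
                 group_factor = group_factor, order_factor = order_factor),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("<trajectory_set> ", length(x$groups), " group(s) x ",
      length(x$levels), " ordered levels\n", sep = "")
  pd <- path_distance(x)
  for (g in x$groups) cat("  ", g, ": path distance ",
                          format(pd[[g]], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Trajectory attributes: magnitude, direction, shape
#'
#' `path_distance()` is the trajectory magnitude: the summed Euclidean
#' lengths of its segments in the flattened shape space.
#' `trajectory_angle()` is the angle in degrees between two trajectories'
#' directions; a direction is the first principal axis of a trajectory's
#' points, sign-oriented along the gradient (positive projection of the
#' last-minus-first chord), or the chord itself with `method = "chord"`.
#' `trajectory_shape_distance()` treats each trajectory's L points as a
#' configuration of L "landmarks" in shape space and returns the residual
#' root-sum-of-squares after full Procrustes superimposition (centering,
#' unit scaling, optimal rotation) of one onto the other.
#'
#' @param t A `trajectory_set` (returns a named vector) or an `L x d`
#'   matrix of ordered trajectory points (returns a scalar).
#' @return See above; angles are in `[0, 180]` degrees.
#' @export
path_distance <- function(t) {
  if (inherits(t, "trajectory_set")) {
    return(vapply(t$points, path_distance, numeric(1)))
  }
  stopifnot(is.matrix(t), nrow(t) >= 2L)
  sum(sqrt(rowSums((t[-1, , drop = FALSE] -
                      t[-nrow(t), , drop = FALSE])^2)))
}

#' @noRd
trajectory_direction <- function(pts, method = "principal-axis") {
  chord <- pts[nrow(pts), ] - pts[1, ]
  if (method == "chord") {
    nc <- sqrt(sum(chord^2))
    if (nc < 1e-12) stop("undefined direction: degenerate trajectory",
                         call. = FALSE)
    return(chord / nc)
  }
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr, nu = 0, nv = 1)
  if (sv$d[1] < 1e-12) {
    stop("undefined direction: all trajectory points identical",
         call. = FALSE)
  }
  v <- sv$v[, 1]
  if (sum(v * chord) < 0) v <- -v
  v
}

#' @rdname path_distance
#' @param t1,t2 Trajectory point matrices with equal dimensions, or a
#'   `trajectory_set` of exactly two groups.
#' @param method Direction definition: `"principal-axis"` (default) or
#'   `"chord"` (first-to-last difference vector).
#' @export
trajectory_angle <- function(t1, t2, method = c("principal-axis", "chord")) {
  method <- match.arg(method)
  if (inherits(t1, "trajectory_set")) {
    stopifnot(length(t1$points) == 2L)
    t2 <- t1$points[[2]]
    t1 <- t1$points[[1]]
  }
  stopifnot(all(dim(t1) == dim(t2)))
  d1 <- trajectory_direction(t1, method)
  d2 <- trajectory_direction(t2, method)
  acos(min(max(sum(d1 * d2), -1), 1)) * 180 / pi
}

#' @rdname path_distance
#' @export
trajectory_shape_distance <- function(t1, t2) {
  if (inherits(t1, "trajectory_set")) {
    stopifnot(length(t1$points) == 2L)
    t2 <- t1$points[[2]]
    t1 <- t1$points[[1]]
  }
  stopifnot(all(dim(t1) == dim(t2)))
  z1 <- sweep(t1, 2, colMeans(t1))
  z2 <- sweep(t2, 2, colMeans(t2))
  s1 <- sqrt(sum(z1^2))
  s2 <- sqrt(sum(z2^2))
  if (s1 < 1e-12 || s2 < 1e-12) {
    stop("degenerate (zero-size) trajectory", call. = FALSE)
  }
  z1 <- z1 / s1
  z2 <- z2 / s2
  rot <- optimal_rotation(z1, z2, allow_reflection = TRUE)
  sqrt(sum((z1 %*% rot - z2)^2))
}

#' Pairwise trajectory comparison with RRPP significance
#'
#' Compares each pair of group trajectories on three attributes: magnitude
#' (absolute difference in path distance), direction (angle between
#' trajectory directions) and shape (Procrustes distance between
#' size-standardized trajectories). Null distributions come from residual
#' randomization: residuals of the additive group + gradient model are
#' permuted across specimens, cell means and all attributes recomputed each
#' iteration; p-values are one-tailed `(b + 1) / (B + 1)`.
#'
#' @param data An aligned `shape_data` with factors attached; the
#'   group-by-gradient design must be fully crossed.
#' @param group_factor,order_factor Factor column names (e.g. `"clone"`,
#'   `"risk"`).
#' @param n_permutations Number of permutations B.
#' @param seed Optional integer seed.
#' @param method Direction definition, see [trajectory_angle()].
#' @return A `trajectory_test` object; `tidy()` gives one row per group
#'   pair with the three observed attributes and their p-values.
#' @export
trajectory_test <- function(data, group_factor = "clone",
                            order_factor = "risk",
                            n_permutations = 1000, seed = NULL,
                            method = c("principal-axis", "chord")) {
  stopifnot(inherits(data, "shape_data"))
  if (!data$aligned) stop("data must be Procrustes-aligned", call. = FALSE)
  method <- match.arg(method)
  fac <- data$factors
  stopifnot(all(c(group_factor, order_factor) %in% names(fac)))
  y <- coord_matrix(data)
  n <- nrow(y)
  grp <- factor(fac[[group_factor]])
  lev <- sort(unique(fac[[order_factor]]))
  ord <- factor(fac[[order_factor]], levels = lev)
  cell <- interaction(grp, ord, drop = FALSE, sep = "\r")
  counts <- table(cell)
  if (any(counts == 0L)) {
    stop("design not fully crossed; empty cell(s): ",
         paste(gsub("\r", " x ", names(counts)[counts == 0L]),
               collapse = "; "), call. = FALSE)
  }
  groups <- levels(grp)
  pairs <- utils::combn(groups, 2)
  pair_idx <- utils::combn(length(groups), 2)

  # rowsum() returns cells in factor-level order; resolve each group's
  # level rows once rather than per permutation
  counts_vec <- as.vector(counts)
  lev_idx <- lapply(groups, function(g) {
    match(paste(g, lev, sep = "\r"), levels(cell))
  })
  traj_from <- function(mat) {
    means <- rowsum(mat, cell) / counts_vec
    lapply(lev_idx, function(ix) means[ix, , drop = FALSE])
  }
  attrs_from <- function(pts) {
    pd <- vapply(pts, path_distance, numeric(1))
    out <- matrix(NA_real_, ncol(pair_idx), 3)
    for (m in seq_len(ncol(pair_idx))) {
      i <- pair_idx[1, m]
      j <- pair_idx[2, m]
      out[m, ] <- c(abs(pd[i] - pd[j]),
                    trajectory_angle(pts[[i]], pts[[j]], method),
                    trajectory_shape_distance(pts[[i]], pts[[j]]))
    }
    out
  }

  pts_obs <- traj_from(y)
  obs <- attrs_from(pts_obs)
  pd_obs <- vapply(pts_obs, path_distance, numeric(1))

  # reduced model for RRPP: additive group + gradient main effects
  x <- stats::model.matrix(~ g + o, data.frame(g = grp, o = ord))
  qx <- qr.Q(qr(x))
  fitted <- qx %*% crossprod(qx, y)
  resid <- y - fitted

  if (!is.null(seed)) set.seed(seed)
  b <- n_permutations
  exceed <- array(0L, dim(obs))
  tol <- 1e-8 * abs(obs)
  for (p in seq_len(b)) {
    # re-residualize the permuted residuals against the reduced design so
    # null cell means carry noise in exactly the subspace the observed
    # ones do (observed residuals are orthogonal to the reduced design;
    # raw permuted residuals are not, which double-counts main-effect
    # estimation noise and miscalibrates derived attribute statistics)
    rp <- resid[sample.int(n), , drop = FALSE]
    rp <- rp - qx %*% crossprod(qx, rp)
    null <- attrs_from(traj_from(fitted + rp))
    exceed <- exceed + (null >= obs - tol)
  }
  pval <- (exceed + 1) / (b + 1)

  comparisons <- tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    d_magnitude = obs[, 1], p_magnitude = pval[, 1],
    angle = obs[, 2], p_angle = pval[, 2],
    d_shape = obs[, 3], p_shape = pval[, 3])
  names(pts_obs) <- groups
  structure(
    list(comparisons = comparisons,
         path_distances = stats::setNames(pd_obs, groups),
         trajectories = structure(
           list(points = pts_obs, groups = groups, levels = lev,
                group_factor = group_factor, order_factor = order_factor),
           class = "trajectory_set"),
         n_permutations = b, seed = seed, method = method),
    class = "trajectory_test")
}

#' @export
print.trajectory_test <- function(x, ...) {
  cat("Phenotypic trajectory analysis (RRPP, ", x$n_permutations,
      " permutations, direction = ", x$method, ")\n", sep = "")
  cat("path distances:\n")
  print(round(x$path_distances, 5))
  print(as.data.frame(x$comparisons), digits = 4, row.names = FALSE)
  invisible(x)
}
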