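#' Centroid size
#'
#' The standard landmark size measure: the square root of the summed squared
#' distances of the landmarks to their centroid. The squared variant (the
#' raw sum of squared distances) and its logarithm are exposed because size
#' only ever enters downstream models as a covariate, where monotone
#' transforms are not interchangeable.
#'
#' @param config A `k x 2` coordinate matrix, or a `shape_data` object
#'   (returns one value per specimen).
#' @param variant `"cs"` (default), `"cs-squared"`, or `"log-cs"`.
#' @return A positive number, or a named vector for a dataset.
#' @export
#' @examples
#' sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
#' centroid_size(sq)                   # sqrt(2)
#' centroid_size(sq, "cs-squared")     # 2
centroid_size <- function(config, variant = c("cs", "cs-squared", "log-cs")) {
  variant <- match.arg(variant)
  if (inherits(config, "shape_data")) {
    cs <- apply(config$coords, 3, centroid_size, variant = variant)
    return(cs)
  }
  stopifnot(is.matrix(config), ncol(config) == 2)
  css <- sum(center_config(config)^2)
  if (css < .Machine$double.eps) {
    stop("degenerate configuration: all landmarks coincide", call. = FALSE)
  }
  switch(variant,
         "cs" = sqrt(css),
         "cs-squared" = css,
         "log-cs" = log(sqrt(css)))
}

#' Ordinary Procrustes alignment of one configuration onto another
#'
#' Optimally translates, scales (to unit centroid size) and rotates `target`
#' onto `reference`. Rotation comes from the SVD of the coordinate
#' cross-product; when `allow_reflection = FALSE` (the default) the
#' determinant is forced to +1, so chiral mismatches remain visible rather
#' than being silently absorbed. The returned Procrustes distance is the
#' root-sum-of-squares deviation between the aligned target and the
#' centered, unit-size reference.
#'
#' @param target,reference `k x 2` coordinate matrices with equal k.
#' @param allow_reflection Permit improper rotations?
#' @return A list with `aligned` (centered, unit-size, rotated target) and
#'   `procrustes_distance`.
#' @export
opa_align <- function(target, reference, allow_reflection = FALSE) {
  stopifnot(is.matrix(target), is.matrix(reference))
  if (nrow(target) != nrow(reference)) {
    stop("landmark count mismatch: ", nrow(target), " vs ", nrow(reference),
         call. = FALSE)
  }
  tc <- center_config(target) / centroid_size(target)
  rc <- center_config(reference) / centroid_size(reference)
  rot <- optimal_rotation(tc, rc, allow_reflection)
  aligned <- tc %*% rot
  dimnames(aligned) <- dimnames(target)
  list(aligned = aligned,
       procrustes_distance = sqrt(sum((aligned - rc)^2)))
}

#' Generalized Procrustes Analysis
#'
#' Iteratively superimposes all configurations: each is translated to the
#' origin, scaled to unit centroid size and rotated onto the current
#' consensus; the consensus is then the rescaled mean of the aligned
#' configurations. Iteration stops when the summed squared Procrustes
#' distance to the consensus changes by less than `tolerance`. The final
#' consensus is rotated onto its own principal axes (largest-magnitude
#' loading positive, proper rotation) so repeated runs and permuted inputs
#' give identical coordinates up to numerical error.
#'
#' @param data A `shape_data` object (n >= 2).
#' @param tolerance Convergence tolerance on the summed squared distance.
#' @param max_iter Maximum number of iterations; non-convergence yields a
#'   warning and `converged = FALSE`, not an error.
#' @param allow_reflection Permit improper rotations during alignment?
#' @param tangent Project the aligned configurations orthogonally onto the
#'   tangent hyperplane at the consensus (default). This linearises the
#'   unit-size constraint, so exactly four coordinate dimensions (two of
#'   translation, one each of rotation and scale) are null downstream and
#'   the mean of the aligned configurations equals the consensus exactly.
#' @return A `gpa_fit` list: `aligned` (a `shape_data`, `aligned = TRUE`,
#'   carrying pre-alignment centroid sizes), `consensus` (`k x 2`),
#'   `centroid_sizes`, `iterations`, `converged`, `tolerance`.
#' @export
gpa <- function(data, tolerance = 1e-10, max_iter = 100,
                allow_reflection = FALSE, tangent = TRUE) {
  stopifnot(inherits(data, "shape_data"))
  n <- n_specimens(data)
  if (n < 2L) stop("GPA needs at least two configurations", call. = FALSE)
  sizes <- apply(data$coords, 3, function(m) centroid_size(m))
  arr <- data$coords
  consensus <- center_config(arr[, , 1])
  consensus <- consensus / sqrt(sum(consensus^2))
  aligned <- arr
  q_old <- Inf
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    q <- 0
    for (i in seq_len(n)) {
      fit <- opa_align(arr[, , i], consensus, allow_reflection)
      aligned[, , i] <- fit$aligned
      q <- q + fit$procrustes_distance^2
    }
    mean_shape <- apply(aligned, c(1, 2), mean)
    consensus <- mean_shape / sqrt(sum(center_config(mean_shape)^2))
    if (abs(q_old - q) < tolerance) {
      converged <- TRUE
      break
    }
    q_old <- q
  }
  if (!converged) {
    warning("GPA did not converge in ", max_iter, " iterations",
            call. = FALSE)
  }
  # orientation convention: principal axes of the consensus, sign fixed
  sv <- svd(center_config(consensus))
  rot <- sv$v
  if (rot[which.max(abs(rot[, 1])), 1] < 0) rot[, 1] <- -rot[, 1]
  if (det(rot) < 0) rot[, 2] <- -rot[, 2]
  consensus <- consensus %*% rot
  for (i in seq_len(n)) aligned[, , i] <- aligned[, , i] %*% rot
  if (tangent) {
    cvec <- as.vector(t(consensus))
    flat <- flatten_configs(aligned)
    flat <- flat - (flat %*% cvec - 1) %*% rbind(cvec)
    aligned <- unflatten_configs(flat, dimnames(data$coords)[[1]])
  }
  out <- data
  out$coords <- aligned
  dimnames(out$coords) <- dimnames(data$coords)
  out$aligned <- TRUE
  out$centroid_sizes <- stats::setNames(sizes, data$specimens)
  dimnames(consensus) <- list(data$landmarks, c("x", "y"))
  structure(
    list(aligned = out, consensus = consensus,
         centroid_sizes = out$centroid_sizes,
         iterations = iterations, converged = converged,
         tolerance = tolerance),
    class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("<gpa_fit> ", n_specimens(x$aligned), " configurations, ",
      x$iterations, " iteration(s), ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  invisible(x)
}

#' Digitisation repeatability from replicate sessions
#'
#' Quantifies landmark placement error when every photograph is digitised
#' once in each of m sessions. After joint Procrustes superimposition, a
#' one-way Procrustes ANOVA on individual identity partitions the summed
#' squared coordinate variation into among-individual and within-individual
#' (session) components. Mean squares use the Procrustes shape degrees of
#' freedom (coordinate df times 2k - 4); the ratio is invariant to that
#' convention. Repeatability is the among-individual variance component over
#' the total, clamped to \[0, 1\].
#'
#' @param data A jointly aligned `shape_data` whose factors contain the two
#'   columns named below.
#' @param individual Name of the factor identifying the photographed
#'   individual (replicated across sessions).
#' @param session Name of the digitising-session factor.
#' @return A `repeatability_result` list: `ms_individual`,
#'   `ms_session_error`, `repeatability`, `n_specimens`, `m_sessions`.
#' @export
repeatability <- function(data, individual = "individual",
                          session = "session") {
  stopifnot(inherits(data, "shape_data"))
  if (!data$aligned) stop("data must be Procrustes-aligned", call. = FALSE)
  fac <- data$factors
  if (is.null(fac) || !all(c(individual, session) %in% names(fac))) {
    stop("factors must contain '", individual, "' and '", session, "'",
         call. = FALSE)
  }
  ind <- factor(fac[[individual]])
  counts <- table(ind)
  if (any(counts < 2L)) {
    stop("individual(s) with a single session: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  m <- unname(counts[1])
  if (any(counts != m)) {
    stop("all individuals must appear in the same number of sessions",
         call. = FALSE)
  }
  y <- coord_matrix(data)
  a <- nlevels(ind)
  d <- ncol(y) - 4L  # shape dimensions after 2-D superimposition
  grand <- colMeans(y)
  means <- rowsum(y, ind) / as.vector(counts)
  ss_among <- m * sum(sweep(means, 2, grand)^2)
  ss_within <- sum((y - means[ind, , drop = FALSE])^2)
  ms_among <- ss_among / ((a - 1) * d)
  ms_within <- ss_within / (a * (m - 1) * d)
  s2_among <- max((ms_among - ms_within) / m, 0)
  r <- s2_among / (s2_among + ms_within)
  structure(
    list(ms_individual = ms_among, ms_session_error = ms_within,
         repeatability = min(max(r, 0), 1),
         n_specimens = a, m_sessions = m),
    class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat("Digitisation repeatability: ",
      sprintf("%.1f%%", 100 * x$repeatability), " (",
      x$n_specimens, " individuals x ", x$m_sessions, " sessions)\n",
      sep = "")
  invisible(x)
}
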