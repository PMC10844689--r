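#' Landmark module partitions
#'
#' A partition names two disjoint landmark sets (each of at least two
#' landmarks) whose coordinate blocks are contrasted by the covariance-ratio
#' modularity test and the two-block PLS integration test. Two presets
#' cover the study's hypotheses on the six-landmark scheme: `"head-body"`
#' (head: rostrum, eye, neck vs lower body: mid-ventral, spine-base,
#' mid-dorsal) and `"dorsal-ventral"` (dorsal: eye, neck, mid-dorsal vs
#' ventral: rostrum, mid-ventral, spine-base).
#'
#' @param block_a,block_b Character vectors of landmark labels.
#' @param names Length-2 character vector naming the blocks.
#' @return A `module_partition` object.
#' @export
#' @examples
#' partition_preset("head-body")
module_partition <- function(block_a, block_b, names = c("A", "B")) {
  block_a <- as.character(block_a)
  block_b <- as.character(block_b)
  if (length(intersect(block_a, block_b))) {
    stop("blocks must be disjoint; shared: ",
         paste(intersect(block_a, block_b), collapse = ", "), call. = FALSE)
  }
  if (length(block_a) < 2L || length(block_b) < 2L) {
    stop("each block needs at least two landmarks", call. = FALSE)
  }
  structure(list(blocks = list(block_a, block_b), names = names),
            class = "module_partition")
}

#' @rdname module_partition
#' @param preset `"head-body"` or `"dorsal-ventral"`.
#' @export
partition_preset <- function(preset = c("head-body", "dorsal-ventral")) {
  preset <- match.arg(preset)
  switch(preset,
         "head-body" = module_partition(
           c("rostrum", "eye", "neck"),
           c("mid-ventral", "spine-base", "mid-dorsal"),
           names = c("head", "body")),
         "dorsal-ventral" = module_partition(
           c("eye", "neck", "mid-dorsal"),
           c("rostrum", "mid-ventral", "spine-base"),
           names = c("dorsal", "ventral")))
}

#' @export
print.module_partition <- function(x, ...) {
  cat("<module_partition>\n")
  for (i in 1:2) {
    cat("  ", x$names[i], ": ", paste(x$blocks[[i]], collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# Resolve a partition to flattened coordinate column indices.
#' @noRd
partition_cols <- function(partition, landmarks) {
  lapply(partition$blocks, function(blk) {
    idx <- match(blk, landmarks)
    if (anyNA(idx)) {
      stop("partition references unknown landmark(s): ",
           paste(blk[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    landmark_cols(idx)
  })
}

#' Covariance ratio between two landmark modules
#'
#' The covariance ratio (CR) compares the overall covariation between two
#' modules to the overall covariation within them. With the coordinate
#' covariance matrix partitioned into within-block parts S11, S22 and the
#' between-block part S12,
#' `CR = sqrt( sum(S12^2) / sqrt(sum(S11*^2) * sum(S22*^2)) )`,
#' where the starred sums exclude diagonal entries. Values well below the
#' landmark-reassignment null indicate modularity.
#'
#' @param data A `shape_data` object (typically Procrustes-aligned).
#' @param partition A [module_partition()].
#' @return The observed CR (non-negative scalar).
#' @export
covariance_ratio <- function(data, partition) {
  stopifnot(inherits(data, "shape_data"),
            inherits(partition, "module_partition"))
  if (n_specimens(data) <= 2L) stop("need n > 2 specimens", call. = FALSE)
  s <- stats::cov(coord_matrix(data))
  cols <- partition_cols(partition, data$landmarks)
  cr_from_cov(s, cols[[1]], cols[[2]])
}

#' @rdname covariance_ratio
#' @param sigma A coordinate covariance matrix.
#' @param cols_a,cols_b Column index vectors of the two blocks within
#'   `sigma`.
#' @export
cr_from_cov <- function(sigma, cols_a, cols_b) {
  s12 <- sigma[cols_a, cols_b, drop = FALSE]
  s11 <- sigma[cols_a, cols_a, drop = FALSE]
  s22 <- sigma[cols_b, cols_b, drop = FALSE]
  w1 <- sum(s11^2) - sum(diag(s11)^2)
  w2 <- sum(s22^2) - sum(diag(s22)^2)
  if (w1 <= 0 || w2 <= 0) {
    stop("undefined CR: a block has zero within-module covariation",
         call. = FALSE)
  }
  sqrt(sum(s12^2) / sqrt(w1 * w2))
}

#' Covariance-ratio modularity test
#'
#' Compares the observed CR to a null distribution obtained by randomly
#' re-assigning whole landmarks (each keeping its x and y together) to two
#' blocks of the observed sizes. Modularity is indicated by an observed CR
#' that is *small* relative to the null, so the p-value is the lower-tail
#' proportion. With `null = "sample"`, B random re-assignments are drawn
#' (with replacement; a warning is issued when fewer distinct assignments
#' exist than permutations requested) and `p = (b + 1) / (B + 1)`. With
#' `null = "exhaustive"`, every distinct assignment — including the
#' observed one — is enumerated and p is the plain null proportion, an
#' exact test.
#'
#' @inheritParams covariance_ratio
#' @param n_permutations Number of random re-assignments B.
#' @param seed Optional integer seed.
#' @param null `"sample"` (default) or `"exhaustive"`.
#' @return A `cr_result`: `observed`, `null` (distribution), `p`,
#'   `effect_size` (standard-normal deviate of the null), `partition`.
#' @export
modularity_test <- function(data, partition, n_permutations = 999,
                            seed = NULL, null = c("sample", "exhaustive")) {
  null <- match.arg(null)
  stopifnot(inherits(data, "shape_data"),
            inherits(partition, "module_partition"))
  s <- stats::cov(coord_matrix(data))
  cols <- partition_cols(partition, data$landmarks)
  observed <- cr_from_cov(s, cols[[1]], cols[[2]])
  pool <- match(unlist(partition$blocks), data$landmarks)
  p1 <- length(partition$blocks[[1]])
  n_distinct <- choose(length(pool), p1)
  if (null == "exhaustive") {
    combs <- utils::combn(pool, p1)
    nulldist <- apply(combs, 2, function(a) {
      b <- setdiff(pool, a)
      cr_from_cov(s, landmark_cols(a), landmark_cols(b))
    })
    p <- count_le(nulldist, observed) / length(nulldist)
  } else {
    if (n_distinct < n_permutations) {
      warning("only ", n_distinct, " distinct landmark re-assignments ",
              "exist; sampling with replacement", call. = FALSE)
    }
    if (!is.null(seed)) set.seed(seed)
    nulldist <- replicate(n_permutations, {
      a <- sample(pool, p1)
      cr_from_cov(s, landmark_cols(a),
                  landmark_cols(setdiff(pool, a)))
    })
    p <- (count_le(nulldist, observed) + 1) / (n_permutations + 1)
  }
  structure(
    list(observed = observed, null = nulldist, p = p,
         effect_size = (observed - mean(nulldist)) / stats::sd(nulldist),
         partition = partition, method = null),
    class = "cr_result")
}

#' @export
print.cr_result <- function(x, ...) {
  cat("Covariance-ratio modularity test (", x$partition$names[1], " | ",
      x$partition$names[2], ")\n", sep = "")
  cat(sprintf("CR = %.4f, p = %.4g (%s null, %d values), Z = %.3f\n",
              x$observed, x$p, x$method, length(x$null), x$effect_size))
  invisible(x)
}

#' Two-block partial least squares (singular warps)
#'
#' Extracts the pair of linear combinations — one over each block's
#' coordinates — with maximal covariance: the first singular vectors of the
#' between-block covariance matrix. Applied to landmark coordinates this is
#' singular warps analysis; the absolute correlation of the first score
#' pair (r-PLS) measures morphological integration. Singular-vector sign
#' is fixed so the first block vector's largest-magnitude component is
#' positive.
#'
#' @inheritParams covariance_ratio
#' @return A `pls_result`: `r_pls`, `singular_value`, `u`, `v` (first
#'   singular vectors over block-A / block-B coordinates), `scores`
#'   (tibble of per-specimen score pairs), `partition`; after
#'   [integration_test()], also `null` and `p`.
#' @export
pls_two_block <- function(data, partition) {
  stopifnot(inherits(data, "shape_data"),
            inherits(partition, "module_partition"))
  if (n_specimens(data) <= 2L) stop("need n > 2 specimens", call. = FALSE)
  y <- coord_matrix(data)
  cols <- partition_cols(partition, data$landmarks)
  xa <- scale(y[, cols[[1]], drop = FALSE], scale = FALSE)
  xb <- scale(y[, cols[[2]], drop = FALSE], scale = FALSE)
  s12 <- crossprod(xa, xb) / (nrow(y) - 1)
  sv <- svd(s12)
  if (sv$d[1] < 1e-14) {
    warning("zero cross-block covariance; r-PLS = 0", call. = FALSE)
    u <- rep(0, ncol(xa))
    v <- rep(0, ncol(xb))
    scores <- tibble::tibble(specimen = data$specimens,
                             xs = rep(0, nrow(y)), ys = rep(0, nrow(y)))
    return(structure(list(r_pls = 0, singular_value = 0, u = u, v = v,
                          scores = scores, partition = partition),
                     class = "pls_result"))
  }
  u <- sv$u[, 1]
  v <- sv$v[, 1]
  if (u[which.max(abs(u))] < 0) {
    u <- -u
    v <- -v
  }
  xs <- drop(xa %*% u)
  ys <- drop(xb %*% v)
  scores <- tibble::tibble(specimen = data$specimens, xs = xs, ys = ys)
  if (!is.null(data$factors)) {
    scores <- dplyr::left_join(scores, data$factors, by = "specimen")
  }
  structure(
    list(r_pls = abs(stats::cor(xs, ys)), singular_value = sv$d[1],
         u = u, v = v, scores = scores, partition = partition),
    class = "pls_result")
}

#' Two-block PLS integration test
#'
#' Builds the null distribution of r-PLS by randomly permuting specimens
#' (rows) of the second block relative to the first and re-running the PLS
#' each iteration. Integration is indicated by an observed r-PLS that is
#' *large* relative to the null (upper-tail p). `null = "exhaustive"`
#' enumerates all n! row permutations (identity included; exact p as plain
#' proportion) and is only feasible for very small n.
#'
#' @inheritParams modularity_test
#' @return A `pls_result` with `null`, `p` and `effect_size` filled in.
#' @export
integration_test <- function(data, partition, n_permutations = 999,
                             seed = NULL, null = c("sample", "exhaustive")) {
  null <- match.arg(null)
  obs <- pls_two_block(data, partition)
  y <- coord_matrix(data)
  cols <- partition_cols(partition, data$landmarks)
  xa <- scale(y[, cols[[1]], drop = FALSE], scale = FALSE)
  xb <- scale(y[, cols[[2]], drop = FALSE], scale = FALSE)
  n <- nrow(y)
  r_of <- function(idx) {
    xbp <- xb[idx, , drop = FALSE]
    sv <- svd(crossprod(xa, xbp) / (n - 1))
    if (sv$d[1] < 1e-14) return(0)
    abs(stats::cor(drop(xa %*% sv$u[, 1]), drop(xbp %*% sv$v[, 1])))
  }
  if (null == "exhaustive") {
    if (n > 8L) stop("exhaustive null infeasible for n > 8", call. = FALSE)
    perms <- all_permutations(n)
    nulldist <- apply(perms, 1, r_of)
    p <- count_ge(nulldist, obs$r_pls) / length(nulldist)
  } else {
    if (!is.null(seed)) set.seed(seed)
    nulldist <- replicate(n_permutations, r_of(sample.int(n)))
    p <- (count_ge(nulldist, obs$r_pls) + 1) / (n_permutations + 1)
  }
  obs$null <- nulldist
  obs$p <- p
  obs$effect_size <- (obs$r_pls - mean(nulldist)) / stats::sd(nulldist)
  obs$method <- null
  obs
}

#' @export
print.pls_result <- function(x, ...) {
  cat("Two-block PLS (", x$partition$names[1], " | ",
      x$partition$names[2], ")\n", sep = "")
  cat(sprintf("r-PLS = %.4f (first singular value %.4g)\n",
              x$r_pls, x$singular_value))
  if (!is.null(x$p)) {
    cat(sprintf("integration test: p = %.4g (%s null, %d values)\n",
                x$p, x$method, length(x$null)))
  }
  invisible(x)
}
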