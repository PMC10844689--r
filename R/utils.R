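# Internal geometry helpers shared across modules. Coordinates are stored as
# k x 2 matrices per specimen and flattened row-wise (x1, y1, x2, y2, ...) so
# that landmark i always owns columns 2i-1 and 2i of a flattened data matrix.

config_centroid <- function(x) colMeans(x)

center_config <- function(x) sweep(x, 2, colMeans(x))

config_cs <- function(x) {
  xc <- center_config(x)
  sqrt(sum(xc^2))
}

#' @noRd
flatten_configs <- function(arr) {
  # arr: k x 2 x n -> n x 2k matrix, row-wise landmark interleaving
  k <- dim(arr)[1]
  n <- dim(arr)[3]
  out <- t(apply(arr, 3, function(m) as.vector(t(m))))
  if (n == 1L) out <- matrix(out, nrow = 1L)
  lab <- dimnames(arr)[[1]]
  if (is.null(lab)) lab <- paste0("lm", seq_len(k))
  colnames(out) <- as.vector(rbind(paste0(lab, ".x"), paste0(lab, ".y")))
  rownames(out) <- dimnames(arr)[[3]]
  out
}

#' @noRd
unflatten_config <- function(v, k = length(v) / 2) {
  matrix(v, nrow = k, ncol = 2, byrow = TRUE)
}

#' @noRd
unflatten_configs <- function(mat, landmarks = NULL) {
  k <- ncol(mat) / 2
  arr <- array(NA_real_, c(k, 2, nrow(mat)),
               dimnames = list(landmarks, c("x", "y"), rownames(mat)))
  for (i in seq_len(nrow(mat))) arr[, , i] <- unflatten_config(mat[i, ], k)
  arr
}

# Optimal rotation (optionally improper) mapping X onto Y: argmin ||X R - Y||_F.
# Kabsch solution via SVD of X'Y; reflection suppressed by flipping the
# weakest singular direction.
#' @noRd
optimal_rotation <- function(x, y, allow_reflection = FALSE) {
  m <- crossprod(x, y)
  s <- svd(m)
  r <- tcrossprod(s$u, s$v)
  if (!allow_reflection && det(r) < 0) {
    d <- ncol(m)
    u <- s$u
    u[, d] <- -u[, d]
    r <- tcrossprod(u, s$v)
  }
  r
}

# Columns of the flattened matrix belonging to a set of landmark indices.
#' @noRd
landmark_cols <- function(idx) as.vector(rbind(2L * idx - 1L, 2L * idx))

# Fix the sign of a vector so its largest-magnitude component is positive.
#' @noRd
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

#' @noRd
perm_indices <- function(n_perm, n) {
  matrix(replicate(n_perm, sample.int(n)), nrow = n_perm, byrow = TRUE)
}

# All permutations of 1..n (n small); used by exhaustive null tests.
#' @noRd
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (pos in seq_len(n)) {
    for (j in seq_len(nrow(sub))) {
      r <- r + 1L
      row <- integer(n)
      row[pos] <- n
      row[-pos] <- sub[j, ]
      out[r, ] <- row
    }
  }
  out
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Tie-tolerant permutation counts: analytically tied statistics can differ
# at floating-point level depending on summation order, so comparisons use
# a small relative tolerance (ties count towards the null, the conservative
# convention for permutation tests).
#' @noRd
count_ge <- function(null, obs, rel = 1e-8) {
  sum(null >= obs - rel * abs(obs))
}

#' @noRd
count_le <- function(null, obs, rel = 1e-8) {
  sum(null <= obs + rel * abs(obs))
}
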