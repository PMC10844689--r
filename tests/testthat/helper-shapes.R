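# Shared fixture builders. Everything is generated in code under fixed
# seeds set inside each test.

random_config <- function(k = 6) {
  matrix(stats::rnorm(2 * k), ncol = 2)
}

# Apply a random similarity (rotation + translation + positive scale) and
# return the transformed configuration.
random_similarity <- function(cfg, reflect = FALSE) {
  th <- stats::runif(1, -pi, pi)
  rot <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  if (reflect) rot[, 1] <- -rot[, 1]
  sc <- exp(stats::runif(1, log(0.5), log(2)))
  shift <- stats::runif(2, -5, 5)
  sweep(sc * cfg %*% rot, 2, -shift)
}

# A dataset of iid Gaussian "shapes" already flagged as aligned; used where
# the linear-model machinery, not superimposition, is under test.
gaussian_shape_data <- function(n, k = 3, sd = 1, factors = NULL) {
  flat <- matrix(stats::rnorm(n * 2 * k, sd = sd), n)
  arr <- array(NA_real_, c(k, 2, n))
  for (i in seq_len(n)) arr[, , i] <- matrix(flat[i, ], k, byrow = TRUE)
  shape_data(arr, specimens = paste0("s", seq_len(n)), factors = factors,
             aligned = TRUE)
}

# Two-clone generator spec whose true response directions are a controlled
# angle apart in the Procrustes tangent space (direct neck term disabled so
# trajectories are straight lines along the directions).
two_clone_spec <- function(theta_deg, gain = 0.08, sd_within = 0.01,
                           digitisation_sd = 0.002,
                           replicates = 50, nuisance = NULL) {
  base <- daphnia_base_shape()
  pat1 <- matrix(0, 6, 2, dimnames = list(rownames(base), c("x", "y")))
  pat1["neck", ] <- c(1, 0.4)
  pat1["mid-dorsal", ] <- c(0.3, -0.6)
  pat2 <- matrix(0, 6, 2, dimnames = list(rownames(base), c("x", "y")))
  pat2["eye", ] <- c(0, 1)
  pat2["rostrum", ] <- c(0.2, 0.8)
  e <- tangent_directions(base, list(pat1, pat2))
  th <- theta_deg * pi / 180
  simulation_spec(
    base_shape = base,
    clones = list(A = e[, 1], B = cos(th) * e[, 1] + sin(th) * e[, 2]),
    clone_gains = c(A = gain, B = gain),
    instars = 2, neck_gain = 0,
    sd_within = sd_within, digitisation_sd = digitisation_sd,
    replicates = replicates, nuisance = nuisance)
}

# Single-cell null spec: no mean structure, just the block noise covariance.
null_noise_spec <- function(k = 6, base = NULL, modules = NULL,
                            rho_within = 0.3, rho_between = 0.3,
                            sd_within = 0.01, digitisation_sd = 0,
                            replicates = 40) {
  if (is.null(base)) {
    base <- matrix(c(cos(2 * pi * seq_len(k) / k),
                     sin(2 * pi * seq_len(k) / k)), ncol = 2)
    rownames(base) <- paste0("lm", seq_len(k))
  }
  if (is.null(modules)) {
    modules <- module_partition(rownames(base)[seq_len(k / 2)],
                                rownames(base)[(k / 2 + 1):k])
  }
  dir <- c(1, rep(0, 2 * k - 1))
  simulation_spec(
    base_shape = base, risk_levels = 0,
    clones = list(A = dir), clone_gains = c(A = 0),
    instars = 2, instar_offset = matrix(0, k, 2), neck_gain = 0,
    modules = modules, sd_within = sd_within,
    rho_within = rho_within, rho_between = rho_between,
    digitisation_sd = digitisation_sd,
    replicates = replicates, nuisance = NULL)
}

pairwise_max_distance <- function(aligned) {
  flat <- t(apply(aligned$coords, 3, function(m) as.vector(t(m))))
  max(stats::dist(flat))
}
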