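test_that("centroid size matches hand values, scales linearly, sums directly", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  expect_equal(centroid_size(sq), sqrt(2))
  expect_equal(centroid_size(sq, "cs-squared"), 2)
  expect_equal(centroid_size(sq, "log-cs"), log(sqrt(2)))

  set.seed(21)
  cfg <- random_config(6)
  for (c_scale in c(0.3, 2.4, 117)) {
    expect_equal(centroid_size(c_scale * cfg), c_scale * centroid_size(cfg))
  }
  # direct-summation oracle
  ctr <- colMeans(cfg)
  oracle <- 0
  for (i in seq_len(nrow(cfg))) oracle <- oracle + sum((cfg[i, ] - ctr)^2)
  expect_equal(centroid_size(cfg), sqrt(oracle), tolerance = 1e-12)

  expect_error(centroid_size(matrix(1, 4, 2)), "degenerate")
})

test_that("OPA removes similarity transforms and honours reflection flag", {
  set.seed(22)
  ref <- random_config(6)
  th <- 37 * pi / 180
  rot <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  target <- sweep(2.4 * ref %*% rot, 2, c(-5, 3))
  fit <- opa_align(target, ref)
  expect_lt(fit$procrustes_distance, 1e-10)
  expect_equal(colMeans(fit$aligned), c(0, 0), tolerance = 1e-12)
  expect_equal(centroid_size(fit$aligned), 1, tolerance = 1e-12)

  tri <- matrix(c(0, 0, 3, 0, 0, 1), ncol = 2, byrow = TRUE)
  mir <- tri %*% diag(c(-1, 1))
  expect_gt(opa_align(mir, tri, FALSE)$procrustes_distance, 0)
  expect_lt(opa_align(mir, tri, TRUE)$procrustes_distance, 1e-10)

  expect_error(opa_align(random_config(5), ref), "mismatch")
})

test_that("OPA distance matches a brute-force rotation grid search", {
  set.seed(23)
  for (rep in 1:3) {
    a <- random_config(6)
    b <- random_config(6)
    d_opa <- opa_align(a, b)$procrustes_distance
    ac <- scale(a, scale = FALSE)
    ac <- ac / sqrt(sum(ac^2))
    bc <- scale(b, scale = FALSE)
    bc <- bc / sqrt(sum(bc^2))
    grid <- seq(0, 2 * pi, by = 0.001 * pi / 180)
    d_grid <- min(vapply(grid, function(th) {
      r <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
      sqrt(sum((ac %*% r - bc)^2))
    }, numeric(1)))
    expect_equal(d_opa, d_grid, tolerance = 1e-6)
    expect_lte(d_opa, d_grid + 1e-12)
  }
})

test_that("Procrustes distance behaves as a metric on random triples", {
  set.seed(24)
  for (rep in 1:5) {
    a <- random_config(6)
    b <- random_config(6)
    c <- random_config(6)
    dab <- opa_align(a, b)$procrustes_distance
    dba <- opa_align(b, a)$procrustes_distance
    dac <- opa_align(a, c)$procrustes_distance
    dcb <- opa_align(c, b)$procrustes_distance
    expect_equal(dab, dba, tolerance = 1e-9)
    expect_lte(dab, dac + dcb + 1e-9)
  }
})

test_that("GPA collapses similarity-transformed copies of one shape", {
  set.seed(25)
  shape <- random_config(6)
  copies <- lapply(1:20, function(i) random_similarity(shape))
  d <- shape_data(copies)
  fit <- gpa(d)
  expect_true(fit$converged)
  expect_lt(pairwise_max_distance(fit$aligned), 1e-8)
  # consensus equals the shape up to a similarity transform
  expect_lt(opa_align(shape, fit$consensus)$procrustes_distance, 1e-8)
})

test_that("two-shape GPA matches a hand-run alternation and is order-symmetric", {
  set.seed(26)
  t1 <- random_config(6)
  t2 <- random_config(6)
  # oracle: alternate OPA onto the running mean until it stops moving
  cons <- scale(t1, scale = FALSE)
  cons <- cons / sqrt(sum(cons^2))
  for (it in 1:200) {
    a1 <- opa_align(t1, cons)$aligned
    a2 <- opa_align(t2, cons)$aligned
    m <- (a1 + a2) / 2
    m <- scale(m, scale = FALSE)
    cons_new <- m / sqrt(sum(m^2))
    if (sum((cons_new - cons)^2) < 1e-24) break
    cons <- cons_new
  }
  fit12 <- gpa(shape_data(list(a = t1, b = t2)))
  fit21 <- gpa(shape_data(list(b = t2, a = t1)))
  expect_lt(opa_align(cons, fit12$consensus)$procrustes_distance, 1e-8)
  expect_equal(fit12$consensus, fit21$consensus, tolerance = 1e-10)
})

test_that("GPA output is invariant to input nuisance and specimen order", {
  set.seed(27)
  base <- replicate(8, daphnia_base_shape() + 0.05 * random_config(6),
                    simplify = FALSE)
  names(base) <- paste0("s", 1:8)
  d <- shape_data(base)
  fit <- gpa(d)
  # arbitrary per-specimen similarity nuisance
  nuis <- shape_data(lapply(base, random_similarity))
  fit_n <- gpa(nuis)
  expect_equal(fit_n$aligned$coords, fit$aligned$coords, tolerance = 1e-8)
  # specimen permutation
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  dp <- shape_data(base[perm])
  fit_p <- gpa(dp)
  expect_equal(fit_p$aligned$coords[, , d$specimens],
               fit$aligned$coords, tolerance = 1e-8)
})

test_that("aligned configurations average exactly to the consensus", {
  set.seed(28)
  d <- shape_data(replicate(10, random_config(6), simplify = FALSE))
  fit <- gpa(d)
  mean_cfg <- apply(fit$aligned$coords, c(1, 2), mean)
  expect_equal(unname(mean_cfg), unname(fit$consensus), tolerance = 1e-9)
  expect_equal(centroid_size(fit$consensus), 1, tolerance = 1e-9)
  expect_equal(max(abs(apply(fit$aligned$coords, 3, colMeans))), 0,
               tolerance = 1e-9)
})

test_that("repeatability is 1 for identical sessions and ~0 for unrelated ones", {
  set.seed(29)
  cfgs <- replicate(30, random_config(6), simplify = FALSE)
  both <- c(cfgs, cfgs)
  fac <- data.frame(
    specimen = paste0("s", seq_along(both)),
    individual = rep(paste0("i", 1:30), 2),
    session = rep(c("a", "b"), each = 30))
  d <- shape_data(both, factors = fac)
  fit <- gpa(d)
  r <- repeatability(fit$aligned)
  expect_equal(r$repeatability, 1)
  expect_equal(r$ms_session_error, 0, tolerance = 1e-15)

  # sessions drawn independently from the among-individual distribution
  n <- 200
  flat <- matrix(rnorm(2 * n * 12), 2 * n)
  arr <- aperm(array(flat, c(2 * n, 2, 6)), c(3, 2, 1))
  d0 <- shape_data(arr, specimens = paste0("s", seq_len(2 * n)),
                   factors = data.frame(
                     specimen = paste0("s", seq_len(2 * n)),
                     individual = rep(paste0("i", seq_len(n)), 2),
                     session = rep(c("a", "b"), each = n)),
                   aligned = TRUE)
  r0 <- repeatability(d0)
  expect_lt(abs(r0$repeatability), 0.05)

  expect_error(repeatability(
    attach_factors(d0, within(as.data.frame(d0$factors),
                              individual <- specimen))),
    "single session")
})

test_that("repeatability recovers a 9:1 variance-component ratio", {
  set.seed(30)
  n <- 500
  k <- 6
  ind_dev <- matrix(rnorm(n * 2 * k, sd = 3), n)     # among-individual, 9s^2
  noise <- matrix(rnorm(2 * n * 2 * k, sd = 1), 2 * n)  # session error, s^2
  flat <- ind_dev[rep(seq_len(n), 2), ] + noise
  arr <- aperm(array(flat, c(2 * n, 2, k)), c(3, 2, 1))
  d <- shape_data(arr, specimens = paste0("s", seq_len(2 * n)),
                  factors = data.frame(
                    specimen = paste0("s", seq_len(2 * n)),
                    individual = rep(paste0("i", seq_len(n)), 2),
                    session = rep(c("a", "b"), each = n)),
                  aligned = TRUE)
  r <- repeatability(d)
  expect_equal(r$repeatability, 0.9, tolerance = 0.025)
  expect_equal(r$m_sessions, 2L)
  expect_equal(tidy(r)$repeatability, r$repeatability)
})
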