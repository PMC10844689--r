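test_that("partitions validate blocks and resolve by label", {
  p <- partition_preset("head-body")
  expect_setequal(p$blocks[[1]], c("rostrum", "eye", "neck"))
  expect_setequal(p$blocks[[2]], c("mid-ventral", "spine-base", "mid-dorsal"))
  p2 <- partition_preset("dorsal-ventral")
  expect_setequal(p2$blocks[[1]], c("eye", "neck", "mid-dorsal"))
  expect_error(module_partition(c("a", "b"), c("b", "c")), "disjoint")
  expect_error(module_partition("a", c("b", "c")), "at least two")
})

test_that("CR matches closed forms and a brute-force summation oracle", {
  # block-diagonal population covariance: no between-module covariation
  s0 <- as.matrix(Matrix::bdiag(diag(6) + 0.5, diag(6) + 0.5))
  expect_equal(cr_from_cov(s0, 1:6, 7:12), 0)
  # compound symmetry, all off-diagonals c, 6|6 coordinates
  cs <- matrix(0.4, 12, 12)
  diag(cs) <- 1
  expect_equal(cr_from_cov(cs, 1:6, 7:12), sqrt(6 / 5), tolerance = 1e-12)
  # brute-force elementwise oracle on random data
  set.seed(51)
  y <- matrix(rnorm(50 * 12), 50)
  s <- cov(y)
  a <- 1:6
  b <- 7:12
  num <- 0
  for (i in a) for (j in b) num <- num + s[i, j]^2
  w1 <- 0
  for (i in a) for (j in a) if (i != j) w1 <- w1 + s[i, j]^2
  w2 <- 0
  for (i in b) for (j in b) if (i != j) w2 <- w2 + s[i, j]^2
  expect_equal(cr_from_cov(s, a, b), sqrt(num / sqrt(w1 * w2)),
               tolerance = 1e-12)
  # degenerate within-block covariance is an error
  expect_error(cr_from_cov(diag(12), 1:6, 7:12), "undefined CR")
})

test_that("modularity test: exhaustive null equals an enumeration oracle and
           matches C(6,3) = 20 assignments", {
  set.seed(52)
  sim <- simulate_shapes(null_noise_spec(rho_within = 0.7,
                                         rho_between = 0.1,
                                         replicates = 60), seed = 52)
  part <- sim$data |> (\(d) module_partition(d$landmarks[1:3],
                                             d$landmarks[4:6]))()
  res <- modularity_test(sim$data, part, null = "exhaustive")
  expect_length(res$null, 20L)
  # oracle: enumerate all 3-subsets directly
  y <- t(apply(sim$data$coords, 3, function(m) as.vector(t(m))))
  s <- cov(y)
  combs <- combn(6, 3)
  cols <- function(i) as.vector(rbind(2 * i - 1, 2 * i))
  crs <- apply(combs, 2, function(a) {
    cr_from_cov(s, cols(a), cols(setdiff(1:6, a)))
  })
  expect_equal(sort(res$null), sort(crs), tolerance = 1e-12)
  expect_equal(res$p, mean(crs <= res$observed * (1 + 1e-8)))
  # strong modular signal is detected even at this granularity
  expect_lt(res$p, 0.11)
  # sampling mode warns when the assignment space is smaller than B
  expect_warning(modularity_test(sim$data, part, n_permutations = 99,
                                 seed = 1),
                 "sampling with replacement")
})

test_that("PLS recovers exact linear relations and the analytic SVD", {
  set.seed(53)
  # block B an exact similarity transform of block A: r-PLS = 1
  n <- 40
  xa <- matrix(rnorm(n * 6), n)
  th <- 0.7
  qrot <- as.matrix(Matrix::bdiag(
    cbind(c(cos(th), sin(th)), c(-sin(th), cos(th))),
    cbind(c(cos(th), sin(th)), c(-sin(th), cos(th))),
    cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))))
  y <- cbind(xa, 2.5 * xa %*% qrot)
  arr <- aperm(array(y, c(n, 2, 6)), c(3, 2, 1))
  d <- shape_data(arr, specimens = paste0("s", 1:n), aligned = TRUE)
  part <- module_partition(d$landmarks[1:3], d$landmarks[4:6])
  res <- pls_two_block(d, part)
  expect_equal(res$r_pls, 1, tolerance = 1e-10)
  # singular vectors match an independent svd of the sample cross-covariance
  s12 <- cov(y)[1:6, 7:12]
  sv <- svd(s12)
  u1 <- sv$u[, 1] * sign(sv$u[which.max(abs(sv$u[, 1])), 1])
  expect_equal(abs(sum(res$u * u1)), 1, tolerance = 1e-10)
  expect_equal(res$singular_value, sv$d[1], tolerance = 1e-12)

  # independent blocks at large n: r-PLS near zero
  set.seed(54)
  y2 <- matrix(rnorm(10000 * 12), 10000)
  d2 <- shape_data(aperm(array(y2, c(10000, 2, 6)), c(3, 2, 1)),
                   specimens = paste0("s", 1:10000), aligned = TRUE)
  expect_lt(pls_two_block(d2, part)$r_pls, 0.05)
})

test_that("integration test: exhaustive n = 6 null equals the 720-permutation
           oracle", {
  set.seed(55)
  sim <- simulate_shapes(null_noise_spec(rho_within = 0.4,
                                         rho_between = 0.3,
                                         replicates = 6), seed = 55)
  part <- module_partition(sim$data$landmarks[1:3],
                           sim$data$landmarks[4:6])
  res <- integration_test(sim$data, part, null = "exhaustive")
  expect_length(res$null, factorial(6))
  # oracle: direct enumeration with its own svd + correlation computation
  y <- t(apply(sim$data$coords, 3, function(m) as.vector(t(m))))
  xa <- scale(y[, 1:6], scale = FALSE)
  xb <- scale(y[, 7:12], scale = FALSE)
  perms <- morphoplast:::all_permutations(6)
  rs <- apply(perms, 1, function(ix) {
    sv <- svd(crossprod(xa, xb[ix, ]) / 5)
    abs(cor(xa %*% sv$u[, 1], xb[ix, ] %*% sv$v[, 1]))
  })
  expect_equal(sort(res$null), sort(rs), tolerance = 1e-10)
  expect_equal(res$p, mean(rs >= res$r_pls * (1 - 1e-8)))
})

test_that("CR and r-PLS are invariant to block order, specimen order, and
           within-block rotation", {
  set.seed(56)
  sim <- simulate_shapes(null_noise_spec(rho_within = 0.5,
                                         rho_between = 0.2,
                                         replicates = 80), seed = 56)
  d <- sim$data
  part <- module_partition(d$landmarks[1:3], d$landmarks[4:6])
  swap <- module_partition(d$landmarks[4:6], d$landmarks[1:3])
  expect_equal(covariance_ratio(d, part), covariance_ratio(d, swap),
               tolerance = 1e-12)
  expect_equal(pls_two_block(d, part)$r_pls,
               pls_two_block(d, swap)$r_pls, tolerance = 1e-10)
  # specimen reordering
  ix <- sample(n_specimens(d))
  d2 <- shape_data(d$coords[, , ix], specimens = d$specimens[ix])
  expect_equal(covariance_ratio(d2, part), covariance_ratio(d, part),
               tolerance = 1e-12)
  # orthogonal rotation applied within one block leaves r-PLS unchanged
  y <- t(apply(d$coords, 3, function(m) as.vector(t(m))))
  qrot <- qr.Q(qr(matrix(rnorm(36), 6)))
  y3 <- y
  y3[, 1:6] <- y[, 1:6] %*% qrot
  d3 <- shape_data(aperm(array(y3, c(nrow(y), 2, 6)), c(3, 2, 1)),
                   specimens = d$specimens, aligned = TRUE)
  p3 <- module_partition(d3$landmarks[1:3], d3$landmarks[4:6])
  expect_equal(pls_two_block(d3, p3)$r_pls,
               pls_two_block(d, part)$r_pls, tolerance = 1e-10)
})

test_that("zero cross-covariance yields r-PLS 0 with a warning", {
  n <- 20
  y <- cbind(matrix(rnorm(n * 6), n), matrix(0, n, 6))
  y[, 7] <- 1e-20 * seq_len(n)  # block B essentially constant
  d <- shape_data(aperm(array(y, c(n, 2, 6)), c(3, 2, 1)),
                  specimens = paste0("s", 1:n), aligned = TRUE)
  part <- module_partition(d$landmarks[1:3], d$landmarks[4:6])
  expect_warning(res <- pls_two_block(d, part), "zero cross-block")
  expect_equal(res$r_pls, 0)
})
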