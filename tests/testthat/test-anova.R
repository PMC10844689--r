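test_that("saturated group separation gives R2 = 1 and the minimal p", {
  set.seed(31)
  g1 <- random_config(4)
  g2 <- random_config(4)
  cfgs <- c(replicate(8, scale(g1, scale = FALSE), simplify = FALSE),
            replicate(8, scale(g2, scale = FALSE), simplify = FALSE))
  d <- shape_data(cfgs, specimens = paste0("s", 1:16),
                  factors = data.frame(specimen = paste0("s", 1:16),
                                       group = rep(c("a", "b"), each = 8)),
                  aligned = TRUE)
  fit <- procrustes_anova(d, ~ group, n_permutations = 199, seed = 31)
  tbl <- tidy(fit)
  expect_equal(tbl$Rsq[tbl$term == "group"], 1, tolerance = 1e-12)
  expect_equal(tbl$SS[tbl$term == "Residuals"], 0, tolerance = 1e-12)
  expect_equal(tbl$p[tbl$term == "group"], 1 / 200)
})

test_that("RRPP p equals the exhaustive-enumeration p on a tiny design", {
  set.seed(32)
  n <- 7
  grp <- factor(c("a", "a", "a", "b", "b", "b", "b"))
  d <- gaussian_shape_data(n, k = 3,
                           factors = data.frame(specimen = paste0("s", 1:n),
                                                group = grp))
  perms <- morphoplast:::all_permutations(n)
  fit <- procrustes_anova(d, ~ group, perm_matrix = perms)
  # independent oracle: group SS of mean + permuted centered residuals
  y <- t(apply(d$coords, 3, function(m) as.vector(t(m))))
  yc <- scale(y, scale = FALSE)
  ss_of <- function(mat) {
    gm <- rowsum(mat, grp) / as.vector(table(grp))
    sum(as.vector(table(grp)) * rowSums(sweep(gm, 2, colMeans(mat))^2))
  }
  ss_obs <- ss_of(y)
  ss_perm <- apply(perms, 1, function(ix) ss_of(yc[ix, , drop = FALSE]))
  # analytically tied statistics are counted as ties (tolerant comparison)
  expect_equal(tidy(fit)$p[1], mean(ss_perm >= ss_obs * (1 - 1e-8)))
  expect_equal(tidy(fit)$SS[1], ss_obs, tolerance = 1e-10)
})

test_that("a univariate response reproduces classical one-way ANOVA", {
  set.seed(33)
  n <- 18
  grp <- factor(rep(c("a", "b", "c"), each = 6))
  val <- rnorm(n) + c(a = 0, b = 1, c = 0.5)[grp]
  # variation confined to one coordinate; all others constant
  arr <- array(0, c(3, 2, n))
  arr[2, 1, ] <- 1  # non-degenerate fixed landmarks
  arr[3, 2, ] <- 1
  arr[1, 1, ] <- val
  d <- shape_data(arr, specimens = paste0("s", 1:n),
                  factors = data.frame(specimen = paste0("s", 1:n),
                                       group = grp), aligned = TRUE)
  classical <- anova(lm(val ~ grp))
  set.seed(99)
  perms <- morphoplast:::perm_indices(499, n)
  fit <- procrustes_anova(d, ~ group, perm_matrix = perms)
  tbl <- tidy(fit)
  expect_equal(tbl$F[1], classical$`F value`[1], tolerance = 1e-10)
  expect_equal(tbl$SS[1], classical$`Sum Sq`[1], tolerance = 1e-10)
  # permutation oracle on the univariate response with the same draws
  ssb <- function(v) anova(lm(v ~ grp))$`Sum Sq`[1]
  vc <- val - mean(val)
  exceed <- sum(apply(perms, 1, function(ix) ssb(mean(val) + vc[ix])) >=
                  ssb(val) * (1 - 1e-8))
  expect_equal(tbl$p[1], exceed / 499)
})

test_that("sequential SS is additive, seed-stable, and order-sensitive only
           under imbalance", {
  set.seed(34)
  sim <- simulate_shapes(simulation_spec(replicates = 4), seed = 34)
  al <- gpa(sim$data)$aligned
  f1 <- procrustes_anova(al, ~ instar + clone + risk, 99, seed = 5)
  t1 <- tidy(f1)
  expect_equal(sum(t1$SS[1:4]), t1$SS[t1$term == "Total"], tolerance = 1e-9)
  expect_equal(t1$df[t1$term == "Total"], n_specimens(al) - 1L)
  # identical seed, identical table
  expect_equal(tidy(procrustes_anova(al, ~ instar + clone + risk, 99,
                                     seed = 5)), t1)
  # balanced orthogonal design: term order does not change SS
  t2 <- tidy(procrustes_anova(al, ~ risk + clone + instar, 99, seed = 5))
  expect_equal(sort(t2$SS[1:3]), sort(t1$SS[1:3]), tolerance = 1e-9)
  # unbalanced data: sequential SS depends on order
  unb <- simulate_shapes(simulation_spec(replicates = "unbalanced"),
                         seed = 35)
  alu <- gpa(unb$data)$aligned
  u1 <- tidy(procrustes_anova(alu, ~ instar + clone + risk, 9, seed = 1))
  u2 <- tidy(procrustes_anova(alu, ~ risk + clone + instar, 9, seed = 1))
  expect_gt(abs(u1$SS[u1$term == "clone"] - u2$SS[u2$term == "clone"]), 0)
})

test_that("the study model runs with size as covariate and matches its dfs", {
  set.seed(36)
  sim <- simulate_shapes(simulation_spec(replicates = 4), seed = 36)
  fit <- gpa(sim$data)
  an <- procrustes_anova(fit$aligned, n_permutations = 49, seed = 1)
  tbl <- tidy(an)
  expect_equal(tbl$df[match(c("size", "instar", "clone", "risk",
                              "instar:risk", "clone:risk"), tbl$term)],
               c(1L, 1L, 2L, 5L, 5L, 10L))
  expect_true(all(tbl$p[1:6] > 0 & tbl$p[1:6] <= 1))
  # rank-deficient designs are reported, not silently dropped
  d2 <- fit$aligned
  d2$factors$clone2 <- d2$factors$clone
  expect_error(procrustes_anova(d2, ~ clone + clone2, 9),
               "aliased")
})

test_that("LS means equal arithmetic means under balance and means of cell
           means under imbalance", {
  set.seed(37)
  sim <- simulate_shapes(simulation_spec(replicates = 3), seed = 37)
  al <- gpa(sim$data)$aligned
  lsm <- fit_lsmeans(al, grouping = c("clone", "risk"),
                     average_over = "instar")
  expect_equal(nrow(lsm), 18L)
  expect_equal(lsm$risk, rep(sort(unique(al$factors$risk)), 3))
  # balanced: equals plain cell means
  y <- t(apply(al$coords, 3, function(m) as.vector(t(m))))
  sel <- al$factors$clone == "Carlos" & al$factors$risk == 0
  direct <- colMeans(y[sel, ])
  pick <- lsm$clone == "Carlos" & lsm$risk == 0
  expect_equal(as.vector(t(lsm$shape[[which(pick)]])), unname(direct),
               tolerance = 1e-12)

  # 2x2 toy with imbalance: LS mean = mean of cell means, not pooled mean
  arr <- array(0, c(3, 2, 6))
  arr[1, 1, ] <- c(1, 2, 3, 4, 10, 20)
  arr[2, 2, ] <- 1
  fac <- data.frame(specimen = paste0("s", 1:6),
                    g = c("a", "a", "a", "a", "b", "b"),
                    h = c("u", "u", "u", "v", "u", "v"))
  d <- shape_data(arr, specimens = fac$specimen, factors = fac,
                  aligned = TRUE)
  lsm2 <- fit_lsmeans(d, grouping = "g", average_over = "h")
  expect_equal(lsm2$shape[[1]][1, 1], (mean(c(1, 2, 3)) + 4) / 2)
  expect_equal(lsm2$shape[[2]][1, 1], (10 + 20) / 2)
  # empty cells are named
  expect_error(fit_lsmeans(d, grouping = "g",
                           average_over = NULL), NA)
  fac_bad <- within(fac, h[6] <- "u")
  db <- shape_data(arr, specimens = fac$specimen, factors = fac_bad,
                   aligned = TRUE)
  expect_error(fit_lsmeans(db, grouping = "g", average_over = "h"),
               "empty design cell")
})
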