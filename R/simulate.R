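#' Stylized six-landmark Daphnia body outline
#'
#' A hexagonal lateral-view outline (head at the top, dorsal side to the
#' right) in body-length units, carrying the canonical landmark labels. It
#' is a synthetic stand-in for visual and simulation purposes and carries
#' no claim of matching real specimens.
#'
#' @return A `6 x 2` labelled coordinate matrix.
#' @export
daphnia_base_shape <- function() {
  m <- matrix(c(
     0.05, 0.95,   # eye
     0.20, 0.78,   # neck
     0.28, 0.42,   # mid-dorsal
     0.10, 0.00,   # spine-base
    -0.22, 0.45,   # mid-ventral
    -0.10, 0.90),  # rostrum
    ncol = 2, byrow = TRUE)
  dimnames(m) <- list(daphnia_landmarks(), c("x", "y"))
  m
}

#' Orthonormal shape-change directions in the Procrustes tangent space
#'
#' Turns landmark displacement patterns into unit vectors of the flattened
#' shape space that are orthogonal to the similarity transformations of the
#' base shape (x/y translation, rotation, scaling) and to each other. Mean
#' displacements along such directions survive Procrustes superimposition
#' undistorted to first order, which is what makes trajectory ground truth
#' well defined.
#'
#' @param base A `k x 2` base configuration.
#' @param patterns A list of `k x 2` displacement matrices.
#' @return A `2k x length(patterns)` matrix of orthonormal direction
#'   vectors.
#' @export
tangent_directions <- function(base, patterns) {
  k <- nrow(base)
  ctr <- center_config(base)
  rot90 <- cbind(c(0, 1), c(-1, 0))
  sim <- cbind(
    as.vector(t(cbind(rep(1, k), rep(0, k)))),
    as.vector(t(cbind(rep(0, k), rep(1, k)))),
    as.vector(t(ctr %*% rot90)),
    as.vector(t(ctr)))
  qsim <- qr.Q(qr(sim))
  out <- NULL
  for (p in patterns) {
    v <- as.vector(t(p))
    v <- v - qsim %*% crossprod(qsim, v)
    if (!is.null(out)) v <- v - out %*% crossprod(out, v)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10) {
      stop("displacement pattern is a similarity transform (no shape ",
           "change) or duplicates an earlier pattern", call. = FALSE)
    }
    out <- cbind(out, v / nv)
  }
  out
}

# Default clone response directions: a shared integrated pattern (neck
# outward, mid-dorsal caudal, spine posterior, rostrum inward) and a
# head-height pattern mixed in for the divergent clone.
#' @noRd
default_clone_directions <- function(base) {
  k <- nrow(base)
  lm <- rownames(base)
  pat <- function(...) {
    m <- matrix(0, k, 2, dimnames = list(lm, c("x", "y")))
    d <- list(...)
    for (nm in names(d)) m[nm, ] <- d[[nm]]
    m
  }
  induced <- pat("neck" = c(0.8, 0.3), "mid-dorsal" = c(0.2, -0.5),
                 "spine-base" = c(0.1, -0.4), "rostrum" = c(0.3, -0.2))
  head_height <- pat("eye" = c(0, 0.7), "rostrum" = c(0, 0.6),
                     "neck" = c(0, 0.3))
  e <- tangent_directions(base, list(induced, head_height))
  theta <- 40 * pi / 180
  list("Carlos" = e[, 1],
       "Cletus" = cos(theta) * e[, 1] + sin(theta) * e[, 2],
       "Chardonnay" = e[, 1])
}

#' Specify a synthetic shape-plasticity experiment
#'
#' Defines the generative model for landmark data with the statistical
#' structure the analyses assume: a factorial design of clones x instars x
#' ordered predation-risk levels; cell mean shapes that displace along
#' clone-specific directions with risk (plus a direct neck-landmark
#' displacement, the inducible-defence signature); correlated within-cell
#' landmark noise with a modular block structure; and per-specimen nuisance
#' rotation, translation and scaling that superimposition must remove.
#' Defaults emulate the study design: 3 clones (one strong inducer) x
#' 2 instars x 6 risk levels, 12 replicates per cell.
#'
#' @param base_shape `k x 2` labelled base configuration.
#' @param risk_levels Ordered predator-cue concentrations (uL/mL).
#' @param clones Named list of unit direction vectors (length 2k) in shape
#'   space, one per clone.
#' @param clone_gains Named numeric response gains (shape-space
#'   displacement at risk = 1).
#' @param instars Instar labels.
#' @param instar_offset `k x 2` displacement added to the second instar's
#'   means (mild elongation by default).
#' @param neck_gain Direct displacement of the neck landmark per unit risk,
#'   in body-length units.
#' @param response Risk-response form: `"linear"` (default) or
#'   `"saturating"` (Michaelis-Menten-like, normalised to 1 at risk 1).
#' @param modules A [module_partition()] defining the noise covariance
#'   blocks.
#' @param sd_within Per-coordinate landmark noise standard deviation.
#' @param rho_within,rho_between Noise correlations within / between
#'   modules (the implied covariance must be positive semi-definite;
#'   validated here).
#' @param digitisation_sd Independent landmark placement error added to
#'   every coordinate.
#' @param replicates Per-cell replicate count: a single integer, a vector
#'   over cells (clone varying fastest, then instar, then risk), or
#'   `"unbalanced"` for a deterministic 4-20 spread.
#' @param nuisance `NULL` to disable, or a list with `rotation` (max
#'   |angle| in radians), `translation` (max |shift| per axis) and `scale`
#'   (range of log-uniform scale factors).
#' @return A `simulation_spec` object with the implied population
#'   coordinate covariance in `$sigma`.
#' @export
simulation_spec <- function(base_shape = daphnia_base_shape(),
                            risk_levels = c(0, 0.1, 0.25, 0.5, 0.75, 1),
                            clones = NULL,
                            clone_gains = c("Carlos" = 0.10,
                                            "Cletus" = 0.04,
                                            "Chardonnay" = 0.04),
                            instars = c(2, 3),
                            instar_offset = NULL,
                            neck_gain = 0.08,
                            response = c("linear", "saturating"),
                            modules = partition_preset("head-body"),
                            sd_within = 0.01,
                            rho_within = 0.3,
                            rho_between = 0.1,
                            digitisation_sd = 0.003,
                            replicates = 12,
                            nuisance = list(rotation = pi,
                                            translation = 0.5,
                                            scale = c(0.7, 1.4))) {
  response <- match.arg(response)
  k <- nrow(base_shape)
  lm <- rownames(base_shape) %||% paste0("lm", seq_len(k))
  rownames(base_shape) <- lm
  clones <- clones %||% default_clone_directions(base_shape)
  stopifnot(length(clones) >= 1, !is.null(names(clones)))
  clone_gains <- clone_gains[names(clones)]
  if (anyNA(clone_gains)) {
    stop("clone_gains must name every clone", call. = FALSE)
  }
  if (is.null(instar_offset)) {
    instar_offset <- matrix(0, k, 2, dimnames = list(lm, c("x", "y")))
    if (all(c("eye", "spine-base") %in% lm)) {
      instar_offset["eye", 2] <- 0.02
      instar_offset["spine-base", 2] <- -0.02
    }
  }
  # population coordinate covariance: modular correlation + placement error
  blk <- integer(2 * k)
  cols <- partition_cols(modules, lm)
  blk[cols[[1]]] <- 1L
  blk[cols[[2]]] <- 2L
  rho <- matrix(rho_between, 2 * k, 2 * k)
  for (b in 1:2) rho[blk == b, blk == b] <- rho_within
  rho[blk == 0L, ] <- 0
  rho[, blk == 0L] <- 0
  diag(rho) <- 1
  sigma <- sd_within^2 * rho + digitisation_sd^2 * diag(2 * k)
  ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-12) {
    stop("implied coordinate covariance is not positive semi-definite ",
         "(min eigenvalue ", format(ev), "); adjust rho_within/rho_between",
         call. = FALSE)
  }
  n_cells <- length(clones) * length(instars) * length(risk_levels)
  if (identical(replicates, "unbalanced")) {
    replicates <- rep_len(c(4L, 7L, 12L, 16L, 20L, 9L), n_cells)
  }
  replicates <- rep_len(as.integer(replicates), n_cells)
  if (any(replicates < 1L)) stop("replicates must be >= 1", call. = FALSE)
  structure(
    list(base_shape = base_shape, risk_levels = risk_levels,
         clones = clones, clone_gains = clone_gains, instars = instars,
         instar_offset = instar_offset, neck_gain = neck_gain,
         response = response, modules = modules, sigma = sigma,
         sd_within = sd_within, rho_within = rho_within,
         rho_between = rho_between, digitisation_sd = digitisation_sd,
         replicates = replicates, nuisance = nuisance, landmarks = lm),
    class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("<simulation_spec> ", length(x$clones), " clone(s) x ",
      length(x$instars), " instar(s) x ", length(x$risk_levels),
      " risk level(s), ", sum(x$replicates), " specimens\n", sep = "")
  invisible(x)
}

#' @noRd
risk_response <- function(spec, risk) {
  switch(spec$response,
         linear = risk,
         saturating = (risk / (0.25 + risk)) / (1 / 1.25))
}

# True (noise-free) cell mean configuration, flattened.
#' @noRd
true_cell_mean <- function(spec, clone, instar, risk) {
  k <- nrow(spec$base_shape)
  mu <- as.vector(t(spec$base_shape))
  if (length(spec$instars) > 1L && instar == spec$instars[2]) {
    mu <- mu + as.vector(t(spec$instar_offset))
  }
  mu <- mu + spec$clone_gains[[clone]] * risk_response(spec, risk) *
    spec$clones[[clone]]
  if (spec$neck_gain != 0 && "neck" %in% spec$landmarks) {
    i <- match("neck", spec$landmarks)
    nd <- c(0.8, 0.3)
    nd <- nd / sqrt(sum(nd^2))
    mu[c(2 * i - 1, 2 * i)] <- mu[c(2 * i - 1, 2 * i)] +
      spec$neck_gain * risk * nd
  }
  mu
}

#' Simulate a landmark dataset with known ground truth
#'
#' Draws specimens cell by cell: mean shape plus correlated landmark noise
#' (the spec's block covariance, digitisation error folded in), then an
#' optional per-specimen nuisance rotation/translation/scaling that only
#' Procrustes superimposition can remove. Identical seeds give bit-identical
#' datasets.
#'
#' @param spec A [simulation_spec()].
#' @param seed Optional integer seed.
#' @return A list: `data` (a raw `shape_data` with factors attached) and
#'   `truth`, the deterministic ground truth — true cell means, the true
#'   clone trajectories (attributes of the Procrustes-superimposed true
#'   means, averaged over instar), true path distances and pairwise
#'   angles, and the population covariance-ratio and r-PLS closed forms.
#' @export
simulate_shapes <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(spec$base_shape)
  cells <- expand.grid(clone = names(spec$clones), instar = spec$instars,
                       risk = spec$risk_levels,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ev <- eigen(spec$sigma, symmetric = TRUE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  coords <- list()
  fac <- list()
  sid <- 0L
  for (ci in seq_len(nrow(cells))) {
    mu <- true_cell_mean(spec, cells$clone[ci], cells$instar[ci],
                         cells$risk[ci])
    nrep <- spec$replicates[ci]
    noise <- matrix(stats::rnorm(nrep * 2 * k), nrep) %*% rt
    for (r in seq_len(nrep)) {
      sid <- sid + 1L
      cfg <- unflatten_config(mu + noise[r, ], k)
      if (!is.null(spec$nuisance)) {
        th <- stats::runif(1, -spec$nuisance$rotation,
                           spec$nuisance$rotation)
        rot <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
        sc <- exp(stats::runif(1, log(spec$nuisance$scale[1]),
                               log(spec$nuisance$scale[2])))
        shift <- stats::runif(2, -spec$nuisance$translation,
                              spec$nuisance$translation)
        cfg <- sweep(sc * cfg %*% rot, 2, -shift)
      }
      coords[[sid]] <- cfg
      fac[[sid]] <- data.frame(
        specimen = sprintf("%s_i%s_r%s_%02d", cells$clone[ci],
                           cells$instar[ci], cells$risk[ci], r),
        clone = cells$clone[ci], instar = cells$instar[ci],
        risk = cells$risk[ci], stringsAsFactors = FALSE)
    }
  }
  factors <- tibble::as_tibble(do.call(rbind, fac))
  arr <- array(unlist(coords), c(k, 2, sid),
               dimnames = list(spec$landmarks, c("x", "y"),
                               factors$specimen))
  data <- shape_data(arr, factors = factors)
  list(data = data, truth = simulation_truth(spec, cells))
}

# Deterministic ground truth: attributes of the GPA-superimposed true cell
# means (instar-averaged per clone) plus population closed forms.
#' @noRd
simulation_truth <- function(spec, cells) {
  k <- nrow(spec$base_shape)
  mu <- t(vapply(seq_len(nrow(cells)), function(ci) {
    true_cell_mean(spec, cells$clone[ci], cells$instar[ci], cells$risk[ci])
  }, numeric(2 * k)))
  ids <- sprintf("cell%03d", seq_len(nrow(cells)))
  traj <- NULL
  pd <- NULL
  prs <- NULL
  if (nrow(cells) >= 2L && length(spec$risk_levels) >= 2L) {
    mdata <- shape_data(unflatten_configs(mu, spec$landmarks),
                        specimens = ids,
                        factors = cbind(specimen = ids, cells))
    fit <- gpa(mdata)
    lsm <- fit_lsmeans(fit$aligned, grouping = c("clone", "risk"),
                       average_over = if (length(spec$instars) > 1) "instar")
    traj <- build_trajectories(lsm, "clone", "risk")
    pd <- path_distance(traj)
    prs <- if (length(traj$groups) >= 2) {
      pairs <- utils::combn(traj$groups, 2)
      tibble::tibble(
        group1 = pairs[1, ], group2 = pairs[2, ],
        angle = apply(pairs, 2, function(pr) {
          trajectory_angle(traj$points[[pr[1]]], traj$points[[pr[2]]])
        }))
    }
  }
  cm <- tibble::as_tibble(cells)
  cm$shape <- lapply(seq_len(nrow(mu)), function(i) {
    m <- unflatten_config(mu[i, ], k)
    dimnames(m) <- list(spec$landmarks, c("x", "y"))
    m
  })
  list(cell_means = cm, trajectories = traj, path_distances = pd,
       pairwise_angles = prs,
       cr = tryCatch(closed_form_cr(spec, spec$modules),
                     error = function(e) NA_real_),
       r_pls = closed_form_rpls(spec, spec$modules))
}

#' Population closed forms for the generator's covariance
#'
#' `closed_form_cr()` evaluates the covariance ratio on the spec's exact
#' population coordinate covariance matrix; `closed_form_rpls()` evaluates
#' the population first-pair PLS correlation
#' `u1' S12 v1 / sqrt(u1' S11 u1 * v1' S22 v1)` with `u1, v1` the first
#' singular vectors of `S12`. Sample statistics converge to these values
#' as n grows, which is what the recovery tests check.
#'
#' @param spec A [simulation_spec()].
#' @param partition A [module_partition()] over the spec's landmarks.
#' @return A scalar.
#' @export
closed_form_cr <- function(spec, partition = spec$modules) {
  stopifnot(inherits(spec, "simulation_spec"))
  cols <- partition_cols(partition, spec$landmarks)
  cr_from_cov(spec$sigma, cols[[1]], cols[[2]])
}

#' @rdname closed_form_cr
#' @export
closed_form_rpls <- function(spec, partition = spec$modules) {
  stopifnot(inherits(spec, "simulation_spec"))
  cols <- partition_cols(partition, spec$landmarks)
  s <- spec$sigma
  s12 <- s[cols[[1]], cols[[2]], drop = FALSE]
  sv <- svd(s12)
  if (sv$d[1] < 1e-14) return(0)
  u <- sv$u[, 1]
  v <- sv$v[, 1]
  num <- drop(t(u) %*% s12 %*% v)
  den <- sqrt(drop(t(u) %*% s[cols[[1]], cols[[1]]] %*% u) *
                drop(t(v) %*% s[cols[[2]], cols[[2]]] %*% v))
  abs(num / den)
}
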