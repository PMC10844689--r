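#' Procrustes ANOVA with residual randomization (RRPP)
#'
#' Linear-model decomposition of shape variation. The response is the
#' n x 2k matrix of Procrustes-aligned coordinates; sums of squares are
#' sequential (type I): each term's SS is the drop in residual sum of
#' squared Procrustes distances when the term is added to the model built
#' from all preceding terms. Significance uses residual randomization in a
#' permutation procedure: for every term, the residuals of its reduced
#' model (all preceding terms) are randomly re-assigned to specimens, the
#' term SS recomputed, and the p-value taken as `(b + 1) / (B + 1)` where
#' `b` counts permutations with a statistic at least as large as observed.
#' The effect size Z is the observed SS expressed as a standard-normal
#' deviate of its permutation distribution.
#'
#' The term `size` refers to centroid size (as recorded by [gpa()]),
#' transformed according to `size_variant`. A `risk` covariate is treated
#' as a categorical factor with its declared ordered levels, matching the
#' degrees of freedom of a risk gradient sampled at discrete
#' concentrations.
#'
#' @param data An aligned `shape_data` with factors attached.
#' @param formula One-sided model formula over factor columns, `size`, and
#'   interactions, e.g. `~ size + instar + clone + risk + risk:instar +
#'   risk:clone` (the default). Order matters: sums of squares are
#'   sequential.
#' @param n_permutations Number of random permutations B.
#' @param seed Optional integer seed for the permutation draw.
#' @param effect_type Statistic compared across permutations: term `"SS"`
#'   (default) or `"F"` recomputed per permutation.
#' @param size_variant Centroid-size transform used for the `size` term.
#' @param perm_matrix Optional integer matrix of permutations (rows) to use
#'   instead of random draws. Supplying the *complete* enumeration
#'   (including the identity) yields an exact test: p is then the plain
#'   proportion of enumerated statistics at least as large as observed.
#' @return A `procrustes_anova` object; `tidy()` returns the ANOVA table
#'   (term, df, SS, MS, Rsq, F, Z, p plus Residuals/Total rows).
#' @export
procrustes_anova <- function(data, formula = stats::as.formula(
                               "~ size + instar + clone + risk + risk:instar + risk:clone"),
                             n_permutations = 10000, seed = NULL,
                             effect_type = c("SS", "F"),
                             size_variant = c("cs", "cs-squared", "log-cs"),
                             perm_matrix = NULL) {
  stopifnot(inherits(data, "shape_data"))
  if (!data$aligned) stop("data must be Procrustes-aligned", call. = FALSE)
  effect_type <- match.arg(effect_type)
  size_variant <- match.arg(size_variant)
  if (is.null(perm_matrix) && n_permutations < 1) {
    stop("n_permutations must be >= 1", call. = FALSE)
  }
  y <- coord_matrix(data)
  n <- nrow(y)
  mf <- build_model_frame(data, formula, size_variant)
  trm <- stats::terms(formula)
  labels <- attr(trm, "term.labels")
  x <- stats::model.matrix(trm, mf)
  assign <- attr(x, "assign")

  # sequential orthonormal basis per term
  qacc <- matrix(1 / sqrt(n), n, 1)
  qlist <- vector("list", length(labels))
  df <- integer(length(labels))
  for (j in seq_along(labels)) {
    cj <- x[, assign == j, drop = FALSE]
    cj <- cj - qacc %*% crossprod(qacc, cj)
    sv <- svd(cj)
    keep <- sv$d > max(sv$d[1], 1) * 1e-9
    if (!any(keep)) {
      stop("rank-deficient design: term '", labels[j],
           "' is aliased with preceding terms", call. = FALSE)
    }
    qlist[[j]] <- sv$u[, keep, drop = FALSE]
    df[j] <- sum(keep)
    qacc <- cbind(qacc, qlist[[j]])
  }
  df_res <- n - 1L - sum(df)
  if (df_res < 1L) stop("model saturates the data (no residual df)",
                        call. = FALSE)

  ss_total <- sum(y^2) - sum(crossprod(matrix(1 / sqrt(n), n, 1), y)^2)
  ss <- vapply(qlist, function(q) sum(crossprod(q, y)^2), numeric(1))
  ss_res <- ss_total - sum(ss)
  ms <- ss / df
  ms_res <- ss_res / df_res
  f_obs <- ms / ms_res

  # reduced-model residuals per term (intercept + preceding terms)
  fitted_red <- vector("list", length(labels))
  resid_red <- vector("list", length(labels))
  qr_red <- matrix(1 / sqrt(n), n, 1)
  for (j in seq_along(labels)) {
    fitted_red[[j]] <- qr_red %*% crossprod(qr_red, y)
    resid_red[[j]] <- y - fitted_red[[j]]
    qr_red <- cbind(qr_red, qlist[[j]])
  }

  exhaustive <- !is.null(perm_matrix)
  if (exhaustive) {
    stopifnot(ncol(perm_matrix) == n)
    perms <- perm_matrix
  } else {
    if (!is.null(seed)) set.seed(seed)
    perms <- perm_indices(n_permutations, n)
  }
  b <- nrow(perms)
  ss_null <- matrix(NA_real_, b, length(labels))
  f_null <- if (effect_type == "F") matrix(NA_real_, b, length(labels))
  for (p in seq_len(b)) {
    idx <- perms[p, ]
    for (j in seq_along(labels)) {
      rp <- resid_red[[j]][idx, , drop = FALSE]
      ssp <- sum(crossprod(qlist[[j]], rp)^2)
      ss_null[p, j] <- ssp
      if (effect_type == "F") {
        ystar <- fitted_red[[j]] + rp
        tot <- sum(ystar^2) -
          sum(crossprod(matrix(1 / sqrt(n), n, 1), ystar)^2)
        expl <- sum(crossprod(qacc[, -1, drop = FALSE], ystar)^2)
        f_null[p, j] <- (ssp / df[j]) / ((tot - expl) / df_res)
      }
    }
  }
  stat_obs <- if (effect_type == "SS") ss else f_obs
  stat_null <- if (effect_type == "SS") ss_null else f_null
  pval <- vapply(seq_along(labels), function(j) {
    cnt <- count_ge(stat_null[, j], stat_obs[j])
    if (exhaustive) cnt / b else (cnt + 1) / (b + 1)
  }, numeric(1))
  z <- (ss - colMeans(ss_null)) / apply(ss_null, 2, stats::sd)

  table <- tibble::tibble(
    term = c(labels, "Residuals", "Total"),
    df = c(df, df_res, n - 1L),
    SS = c(ss, ss_res, ss_total),
    MS = c(ms, ms_res, NA_real_),
    Rsq = c(ss / ss_total, ss_res / ss_total, NA_real_),
    F = c(f_obs, NA_real_, NA_real_),
    Z = c(z, NA_real_, NA_real_),
    p = c(pval, NA_real_, NA_real_))
  structure(
    list(table = table, n = n, n_permutations = b, seed = seed,
         effect_type = effect_type, exhaustive = exhaustive,
         formula = formula, null_ss = ss_null),
    class = "procrustes_anova")
}

# Model frame for ANOVA/trajectory designs: factor columns as factors,
# risk as an ordered-level categorical, 'size' from recorded centroid sizes.
#' @noRd
build_model_frame <- function(data, formula, size_variant = "cs") {
  vars <- all.vars(formula)
  fac <- data$factors
  mf <- list()
  for (v in vars) {
    if (v == "size") {
      cs <- data$centroid_sizes
      if (is.null(cs)) {
        stop("'size' requested but no centroid sizes recorded; run gpa()",
             call. = FALSE)
      }
      mf$size <- switch(size_variant,
                        "cs" = cs, "cs-squared" = cs^2, "log-cs" = log(cs))
    } else {
      if (is.null(fac) || !v %in% names(fac)) {
        stop("model term '", v, "' is not an attached factor", call. = FALSE)
      }
      col <- fac[[v]]
      mf[[v]] <- if (is.numeric(col) && v == "risk") {
        factor(col, levels = sort(unique(col)))
      } else {
        factor(col)
      }
    }
  }
  as.data.frame(mf, check.names = FALSE)
}

#' @export
print.procrustes_anova <- function(x, ...) {
  cat("Procrustes ANOVA (RRPP, ", x$n_permutations,
      if (x$exhaustive) " exhaustive" else " random",
      " permutations, statistic = ", x$effect_type, ")\n", sep = "")
  print(as.data.frame(x$table), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Least-squares mean shapes per design cell
#'
#' Mean flattened Procrustes coordinates per cell of the grouping factors.
#' With `average_over` factors, the LS mean of a grouping cell is the
#' unweighted average of its subcell arithmetic means — equal to the plain
#' cell mean under balance but not under unbalanced replication.
#'
#' @param data An aligned `shape_data` with factors attached.
#' @param grouping Character vector of factor names defining the cells.
#' @param average_over Optional further factor names averaged over with
#'   equal weight.
#' @return A tibble with the grouping columns, replicate count `n`, and a
#'   `shape` list-column of `k x 2` mean configurations.
#' @export
fit_lsmeans <- function(data, grouping, average_over = NULL) {
  stopifnot(inherits(data, "shape_data"))
  if (!data$aligned) stop("data must be Procrustes-aligned", call. = FALSE)
  fac <- data$factors
  stopifnot(all(c(grouping, average_over) %in% names(fac)))
  y <- coord_matrix(data)
  all_fac <- c(grouping, average_over)
  cell <- interaction(fac[all_fac], drop = FALSE, sep = "\r")
  counts <- table(cell)
  if (any(counts == 0L)) {
    empty <- gsub("\r", " x ", names(counts)[counts == 0L])
    stop("empty design cell(s): ", paste(empty, collapse = "; "),
         call. = FALSE)
  }
  sub_means <- rowsum(y, cell) / as.vector(counts)
  key <- do.call(rbind, strsplit(rownames(sub_means), "\r", fixed = TRUE))
  gkey <- apply(key[, seq_along(grouping), drop = FALSE], 1, paste,
                collapse = "\r")
  ls <- rowsum(sub_means, gkey)
  gl <- table(gkey)
  ls <- ls / as.vector(gl)
  nrep <- as.vector(rowsum(as.vector(counts), gkey))
  gparts <- do.call(rbind, strsplit(rownames(ls), "\r", fixed = TRUE))
  out <- tibble::as_tibble(stats::setNames(
    as.data.frame(gparts, stringsAsFactors = FALSE), grouping))
  # restore original column types (numeric risk etc.)
  for (g in grouping) {
    if (is.numeric(fac[[g]])) out[[g]] <- as.numeric(out[[g]])
  }
  out$n <- nrep
  out$shape <- lapply(seq_len(nrow(ls)), function(i) {
    m <- unflatten_config(ls[i, ], n_landmarks(data))
    dimnames(m) <- list(data$landmarks, c("x", "y"))
    m
  })
  dplyr::arrange(out, dplyr::across(dplyr::all_of(grouping)))
}
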