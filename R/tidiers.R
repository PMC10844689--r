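#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and summarize fitted morphometric results
#'
#' Broom-style accessors. `tidy()` returns the per-term, per-pair or
#' per-axis table of a result; `glance()` returns a one-row model summary.
#'
#' @param x A fitted result (`procrustes_anova`, `trajectory_test`,
#'   `cr_result`, `pls_result`, `shape_pca`, `gpa_fit`,
#'   `repeatability_result`).
#' @param ... Unused.
#' @return A tibble.
#' @name morphoplast-tidiers
NULL

#' @rdname morphoplast-tidiers
#' @method tidy procrustes_anova
#' @export
tidy.procrustes_anova <- function(x, ...) x$table

#' @rdname morphoplast-tidiers
#' @method glance procrustes_anova
#' @export
glance.procrustes_anova <- function(x, ...) {
  tibble::tibble(n = x$n, n_permutations = x$n_permutations,
                 effect_type = x$effect_type,
                 total_SS = x$table$SS[x$table$term == "Total"])
}

#' @rdname morphoplast-tidiers
#' @method tidy trajectory_test
#' @export
tidy.trajectory_test <- function(x, ...) x$comparisons

#' @rdname morphoplast-tidiers
#' @method glance trajectory_test
#' @export
glance.trajectory_test <- function(x, ...) {
  tibble::tibble(n_groups = length(x$path_distances),
                 n_levels = length(x$trajectories$levels),
                 n_permutations = x$n_permutations, method = x$method)
}

#' @rdname morphoplast-tidiers
#' @method tidy cr_result
#' @export
tidy.cr_result <- function(x, ...) {
  tibble::tibble(statistic = x$observed, p.value = x$p,
                 effect_size = x$effect_size,
                 null_mean = mean(x$null), null_sd = stats::sd(x$null),
                 n_null = length(x$null))
}

#' @rdname morphoplast-tidiers
#' @method tidy pls_result
#' @export
tidy.pls_result <- function(x, ...) {
  tibble::tibble(statistic = x$r_pls, singular_value = x$singular_value,
                 p.value = x$p %||% NA_real_,
                 n_null = if (is.null(x$null)) 0L else length(x$null))
}

#' @rdname morphoplast-tidiers
#' @method tidy shape_pca
#' @export
tidy.shape_pca <- function(x, ...) {
  ax <- seq_len(x$n_nonnull)
  tibble::tibble(axis = paste0("PC", ax),
                 eigenvalue = x$eigenvalues[ax],
                 variance_fraction = x$variance_fractions[ax],
                 cumulative = cumsum(x$variance_fractions[ax]))
}

#' @rdname morphoplast-tidiers
#' @method glance gpa_fit
#' @export
glance.gpa_fit <- function(x, ...) {
  tibble::tibble(n = n_specimens(x$aligned),
                 k = n_landmarks(x$aligned),
                 iterations = x$iterations, converged = x$converged,
                 tolerance = x$tolerance)
}

#' @rdname morphoplast-tidiers
#' @method tidy repeatability_result
#' @export
tidy.repeatability_result <- function(x, ...) {
  tibble::tibble(ms_individual = x$ms_individual,
                 ms_session_error = x$ms_session_error,
                 repeatability = x$repeatability,
                 n_specimens = x$n_specimens, m_sessions = x$m_sessions)
}
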