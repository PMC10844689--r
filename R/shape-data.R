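#' Landmark labels of the six-landmark Daphnia scheme
#'
#' The digitisation scheme places six landmarks on a lateral-view specimen:
#' the centre of the eye, the neckteeth region (or the corresponding area in
#' controls), the dorsal midpoint of the carapace, the base of the apical
#' spine, the ventral midpoint of the carapace, and the rostrum. Module
#' partitions are defined over these labels, never over indices, so analyses
#' survive landmark re-ordering.
#'
#' @return Character vector of length 6 in the canonical digitisation order.
#' @export
#' @examples
#' daphnia_landmarks()
daphnia_landmarks <- function() {
  c("eye", "neck", "mid-dorsal", "spine-base", "mid-ventral", "rostrum")
}

#' Assemble a landmark shape dataset
#'
#' `shape_data` is the package's central container: a stack of k-landmark,
#' 2-D configurations with optional per-specimen factors. Coordinates live in
#' a `k x 2 x n` array; [as_tibble()][tibble::as_tibble] renders the long
#' tidy view (one row per specimen-landmark).
#'
#' @param coords A `k x 2 x n` numeric array, or a list of `k x 2` matrices.
#' @param specimens Character vector of n unique specimen ids. Defaults to
#'   array dimnames or `s1..sn`.
#' @param landmarks Character vector of k landmark labels. Defaults to array
#'   dimnames or `lm1..lmk`.
#' @param factors Optional data frame with a `specimen` column; see
#'   [attach_factors()].
#' @param aligned Logical; `TRUE` only for Procrustes-superimposed data.
#' @param centroid_sizes Optional numeric vector of n pre-alignment centroid
#'   sizes (populated by [gpa()]).
#' @return A `shape_data` object.
#' @export
#' @examples
#' tri <- matrix(c(0, 0, 1, 0, 0, 1), ncol = 2, byrow = TRUE)
#' shape_data(list(a = tri, b = tri * 2))
shape_data <- function(coords, specimens = NULL, landmarks = NULL,
                       factors = NULL, aligned = FALSE,
                       centroid_sizes = NULL) {
  if (is.list(coords)) {
    specimens <- specimens %||% names(coords) %||%
      paste0("s", seq_along(coords))
    coords <- array(unlist(coords),
                    dim = c(nrow(coords[[1]]), 2L, length(coords)))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 2L)
  k <- dim(coords)[1]
  n <- dim(coords)[3]
  if (k < 3L) stop("at least 3 landmarks are required (k >= 3)", call. = FALSE)
  if (!all(is.finite(coords))) {
    stop("all landmark coordinates must be finite", call. = FALSE)
  }
  specimens <- as.character(specimens %||% dimnames(coords)[[3]] %||%
                              paste0("s", seq_len(n)))
  landmarks <- as.character(landmarks %||% dimnames(coords)[[1]] %||%
                              paste0("lm", seq_len(k)))
  if (anyDuplicated(specimens)) {
    stop("duplicate specimen ids: ",
         paste(unique(specimens[duplicated(specimens)]), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(length(specimens) == n, length(landmarks) == k)
  dimnames(coords) <- list(landmarks, c("x", "y"), specimens)
  out <- structure(
    list(coords = coords, landmarks = landmarks, specimens = specimens,
         factors = NULL, aligned = isTRUE(aligned),
         centroid_sizes = centroid_sizes, provenance = character()),
    class = "shape_data")
  if (!is.null(factors)) out <- attach_factors(out, factors)
  out
}

#' @export
print.shape_data <- function(x, ...) {
  cat("<shape_data> ", n_specimens(x), " specimens x ", n_landmarks(x),
      " landmarks (", if (x$aligned) "Procrustes-aligned" else "raw",
      ")\n", sep = "")
  cat("landmarks: ", paste(x$landmarks, collapse = ", "), "\n", sep = "")
  if (!is.null(x$factors)) {
    cat("factors:   ",
        paste(setdiff(names(x$factors), "specimen"), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of specimens / landmarks in a shape dataset
#' @param data A `shape_data` object.
#' @return An integer.
#' @export
n_specimens <- function(data) dim(data$coords)[3]

#' @rdname n_specimens
#' @export
n_landmarks <- function(data) dim(data$coords)[1]

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Long tidy view of a shape dataset
#'
#' One row per specimen-landmark with columns `specimen`, `landmark`, `x`,
#' `y`, joined with any attached factors.
#'
#' @param x A `shape_data` object.
#' @param ... Unused.
#' @return A tibble.
#' @method as_tibble shape_data
#' @export
as_tibble.shape_data <- function(x, ...) {
  k <- n_landmarks(x)
  n <- n_specimens(x)
  xs <- as.vector(x$coords[, 1, ])
  ys <- as.vector(x$coords[, 2, ])
  tbl <- tibble::tibble(
    specimen = rep(x$specimens, each = k),
    landmark = rep(x$landmarks, times = n),
    x = xs, y = ys)
  if (!is.null(x$factors)) {
    tbl <- dplyr::left_join(tbl, x$factors, by = "specimen")
  }
  tbl
}

#' Build a shape dataset from a long tibble
#'
#' Inverse of [as_tibble.shape_data()]: expects columns `specimen`,
#' `landmark`, `x`, `y`; any further columns are attached as factors.
#'
#' @param tbl A data frame in long format.
#' @param landmarks Optional landmark ordering (default: order of first
#'   appearance).
#' @param aligned Logical flag, see [shape_data()].
#' @return A `shape_data` object.
#' @export
as_shape_data <- function(tbl, landmarks = NULL, aligned = FALSE) {
  stopifnot(all(c("specimen", "landmark", "x", "y") %in% names(tbl)))
  landmarks <- landmarks %||% unique(as.character(tbl$landmark))
  specimens <- unique(as.character(tbl$specimen))
  k <- length(landmarks)
  counts <- table(factor(tbl$specimen, specimens))
  if (any(counts != k)) {
    bad <- names(counts)[counts != k]
    miss <- setdiff(landmarks, tbl$landmark[tbl$specimen == bad[1]])
    stop("specimen ", bad[1], " has ", counts[bad[1]], " of ", k,
         " landmarks (missing: ", paste(miss, collapse = ", "), ")",
         call. = FALSE)
  }
  arr <- array(NA_real_, c(k, 2, length(specimens)),
               dimnames = list(landmarks, c("x", "y"), specimens))
  i <- cbind(match(as.character(tbl$landmark), landmarks), 1L,
             match(as.character(tbl$specimen), specimens))
  arr[i] <- tbl$x
  i[, 2] <- 2L
  arr[i] <- tbl$y
  extra <- setdiff(names(tbl), c("specimen", "landmark", "x", "y"))
  fac <- if (length(extra)) {
    dplyr::distinct(dplyr::select(tbl, dplyr::all_of(c("specimen", extra))))
  }
  shape_data(arr, factors = fac, aligned = aligned)
}

#' Attach a per-specimen factor table
#'
#' Joins experimental factors (e.g. clone, instar, predation risk) onto a
#' shape dataset. Every specimen must have exactly one factor row; the join
#' is keyed on specimen id, so row order in `factors` is irrelevant.
#'
#' @param data A `shape_data` object.
#' @param factors Data frame with a `specimen` column plus factor columns.
#'   A `risk` column is kept numeric but validated against its declared
#'   ordered level set when present.
#' @return `data` with factors attached.
#' @export
attach_factors <- function(data, factors) {
  stopifnot(inherits(data, "shape_data"), "specimen" %in% names(factors))
  factors <- tibble::as_tibble(factors)
  factors$specimen <- as.character(factors$specimen)
  if (anyDuplicated(factors$specimen)) {
    stop("duplicate factor rows for: ",
         paste(unique(factors$specimen[duplicated(factors$specimen)]),
               collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(data$specimens, factors$specimen)
  if (length(missing)) {
    stop("no factor row for specimen(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  data$factors <- factors[match(data$specimens, factors$specimen), ]
  data
}

#' Replicate counts per design cell
#'
#' @param data A `shape_data` object with factors attached.
#' @param ... Factor columns defining the cells (tidy-select); defaults to
#'   all attached factors.
#' @return A tibble of cell factor levels and replicate counts `n`.
#' @export
design_cells <- function(data, ...) {
  stopifnot(inherits(data, "shape_data"))
  if (is.null(data$factors)) stop("no factors attached", call. = FALSE)
  fac <- dplyr::select(data$factors, -"specimen")
  sel <- rlang::enquos(...)
  if (length(sel)) fac <- dplyr::select(data$factors, !!!sel)
  dplyr::count(fac, dplyr::across(dplyr::everything()))
}

#' Mirror selected configurations
#'
#' Reflects the chosen specimens about a coordinate axis, as done at ingest
#' so that all animals face the same direction. A `horizontal` mirror flips
#' x (reflection about the vertical axis x = 0); `vertical` flips y.
#' Mirroring is an explicit ingest step because downstream Procrustes
#' alignment forbids reflection by default.
#'
#' @param data A `shape_data` object.
#' @param axis `"horizontal"` or `"vertical"`.
#' @param which Character vector of specimen ids to mirror (default: all).
#' @return The dataset with the selected configurations reflected; the
#'   operation is recorded in the provenance log.
#' @export
mirror_configurations <- function(data, axis = c("horizontal", "vertical"),
                                  which = NULL) {
  stopifnot(inherits(data, "shape_data"))
  axis <- match.arg(axis)
  which <- which %||% data$specimens
  unknown <- setdiff(which, data$specimens)
  if (length(unknown)) {
    stop("unknown specimen id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  col <- if (axis == "horizontal") 1L else 2L
  data$coords[, col, which] <- -data$coords[, col, which]
  data$provenance <- c(
    data$provenance,
    paste0("mirrored ", length(which), " specimen(s) about the ",
           axis, " axis"))
  data
}

# n x 2k flattened coordinate matrix of a dataset.
#' @noRd
coord_matrix <- function(data) flatten_configs(data$coords)

# Replace coordinates from a flattened matrix, preserving metadata.
#' @noRd
set_coords <- function(data, mat) {
  data$coords <- unflatten_configs(mat, data$landmarks)
  dimnames(data$coords)[[3]] <- data$specimens
  data
}
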