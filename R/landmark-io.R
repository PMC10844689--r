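#' Read and write TPS landmark files
#'
#' Reads the community-standard TPS format: each record is an `LM=k` line,
#' k whitespace-separated coordinate lines, and an `ID=` line. `IMAGE=` and
#' `SCALE=` lines are tolerated and ignored. Coordinates digitised in image
#' convention (y increasing downward) can be converted to math convention at
#' ingest with `y_down = TRUE`.
#'
#' @param path Path to a TPS file.
#' @param landmarks Optional landmark labels (length k) applied to every
#'   record; defaults to `lm1..lmk`.
#' @param y_down If `TRUE`, negate y at ingest to convert from image to math
#'   convention.
#' @return A `shape_data` object, one configuration per record in file order.
#' @export
read_tps <- function(path, landmarks = NULL, y_down = FALSE) {
  stopifnot(file.exists(path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  recs <- list()
  ids <- character()
  i <- 1L
  rec <- 0L
  while (i <= length(lines)) {
    rec <- rec + 1L
    if (!grepl("^LM\\s*=", lines[i])) {
      stop("record ", rec, ": expected 'LM=' line, got '", lines[i], "'",
           call. = FALSE)
    }
    k <- as.integer(sub("^LM\\s*=\\s*", "", lines[i]))
    i <- i + 1L
    coords <- matrix(NA_real_, k, 2)
    for (j in seq_len(k)) {
      if (i > length(lines) || grepl("^(ID|LM|IMAGE|SCALE)\\s*=", lines[i])) {
        stop("record ", rec, ": LM=", k, " but only ", j - 1L,
             " coordinate line(s) found", call. = FALSE)
      }
      xy <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1]]))
      if (length(xy) != 2L || anyNA(xy)) {
        stop("record ", rec, ": malformed coordinate line '", lines[i], "'",
             call. = FALSE)
      }
      coords[j, ] <- xy
      i <- i + 1L
    }
    id <- NA_character_
    while (i <= length(lines) && !grepl("^LM\\s*=", lines[i])) {
      if (grepl("^ID\\s*=", lines[i])) id <- sub("^ID\\s*=\\s*", "", lines[i])
      i <- i + 1L
    }
    if (is.na(id)) id <- paste0("s", rec)
    recs[[rec]] <- coords
    ids[rec] <- id
  }
  ks <- vapply(recs, nrow, integer(1))
  if (length(unique(ks)) > 1L) {
    stop("records disagree on landmark count: ",
         paste(unique(ks), collapse = ", "), call. = FALSE)
  }
  arr <- array(unlist(recs), c(ks[1], 2, length(recs)))
  if (y_down) arr[, 2, ] <- -arr[, 2, ]
  out <- shape_data(arr, specimens = ids, landmarks = landmarks)
  if (y_down) out$provenance <- "y axis flipped at ingest (image convention)"
  out
}

#' @rdname read_tps
#' @param data A `shape_data` object to write.
#' @param digits Significant digits written.
#' @export
write_tps <- function(data, path, digits = 15) {
  stopifnot(inherits(data, "shape_data"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_specimens(data))) {
    m <- data$coords[, , i]
    writeLines(c(paste0("LM=", n_landmarks(data)),
                 paste(format(m[, 1], digits = digits, trim = TRUE),
                       format(m[, 2], digits = digits, trim = TRUE)),
                 paste0("ID=", data$specimens[i])), con)
  }
  invisible(path)
}

#' Read and write landmark CSV files
#'
#' Two dialects are supported. `long`: columns `specimen, landmark, x, y`
#' (one row per specimen-landmark). `wide`: one row per specimen with a
#' `specimen` column and columns `x1..xk, y1..yk` in landmark order. Both
#' parse to the same dataset.
#'
#' @param path Path to a CSV file.
#' @param dialect `"long"` or `"wide"`.
#' @param landmarks Optional landmark labels; for the wide dialect these
#'   name landmarks `1..k`.
#' @return A `shape_data` object.
#' @export
read_landmarks_csv <- function(path, dialect = c("long", "wide"),
                               landmarks = NULL) {
  dialect <- match.arg(dialect)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (dialect == "long") {
    return(as_shape_data(tbl[c("specimen", "landmark", "x", "y")],
                         landmarks = landmarks))
  }
  xcols <- grep("^x[0-9]+$", names(tbl), value = TRUE)
  ycols <- grep("^y[0-9]+$", names(tbl), value = TRUE)
  k <- length(xcols)
  if (k == 0L || length(ycols) != k) {
    stop("wide dialect requires matched x1..xk / y1..yk columns",
         call. = FALSE)
  }
  xcols <- paste0("x", seq_len(k))
  ycols <- paste0("y", seq_len(k))
  if (anyNA(as.matrix(tbl[c(xcols, ycols)]))) {
    bad <- which(is.na(as.matrix(tbl[c(xcols, ycols)])), arr.ind = TRUE)
    stop("specimen ", tbl$specimen[bad[1, 1]], " is missing landmark ",
         (bad[1, 2] - 1L) %% k + 1L, call. = FALSE)
  }
  arr <- array(NA_real_, c(k, 2, nrow(tbl)))
  arr[, 1, ] <- t(as.matrix(tbl[xcols]))
  arr[, 2, ] <- t(as.matrix(tbl[ycols]))
  shape_data(arr, specimens = tbl$specimen, landmarks = landmarks)
}

#' @rdname read_landmarks_csv
#' @param data A `shape_data` object to write.
#' @export
write_landmarks_csv <- function(data, path, dialect = c("long", "wide")) {
  stopifnot(inherits(data, "shape_data"))
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    tbl <- as_tibble(data)[c("specimen", "landmark", "x", "y")]
  } else {
    mat <- coord_matrix(data)
    k <- n_landmarks(data)
    tbl <- tibble::as_tibble(mat[, landmark_cols(seq_len(k)), drop = FALSE])
    names(tbl) <- as.vector(rbind(paste0("x", seq_len(k)),
                                  paste0("y", seq_len(k))))
    tbl <- tbl[c(paste0("x", seq_len(k)), paste0("y", seq_len(k)))]
    tbl <- dplyr::bind_cols(tibble::tibble(specimen = data$specimens), tbl)
  }
  readr::write_csv(tbl, path)
  invisible(path)
}

#' Read a per-specimen factor table
#'
#' Expects columns `specimen, clone, instar, risk` and optionally `session`.
#' `risk` is validated against the declared ordered level set.
#'
#' @param path Path to a CSV file.
#' @param risk_levels Ordered set of admissible risk levels (predator-cue
#'   concentrations in uL/mL).
#' @return A tibble suitable for [attach_factors()].
#' @export
read_factor_table <- function(path,
                              risk_levels = c(0, 0.1, 0.25, 0.5, 0.75, 1)) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot("specimen" %in% names(tbl))
  if ("risk" %in% names(tbl)) {
    bad <- setdiff(unique(tbl$risk), risk_levels)
    if (length(bad)) {
      stop("risk level(s) outside the declared set: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  tbl$specimen <- as.character(tbl$specimen)
  tbl
}
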