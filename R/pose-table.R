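#' Pose-tracking table
#'
#' A `pose_tbl` is a tidy per-frame, per-body-part table of tracked
#' coordinates with columns `frame` (0-based integer), `animal`, `bodypart`,
#' `x`, `y` and `likelihood`, plus attributes carrying the frame rate, the
#' coordinate units (`"px"` or `"mm"`) and the [body_part_scheme()].
#' Missing detections are encoded as `likelihood = 0` (never dropped), so
#' frame indices stay aligned with video time. Coordinates use the image
#' convention: origin at the top-left of the frame, y increasing downward.
#'
#' @param data A data frame with the columns listed above.
#' @param frame_rate Acquisition frame rate in Hz.
#' @param units `"px"` or `"mm"`.
#' @param scheme A [body_part_scheme()].
#' @return A `pose_tbl` (tibble subclass).
#' @export
pose_tbl <- function(data, frame_rate, units = c("px", "mm"), scheme) {
  units <- match.arg(units)
  stopifnot(is.numeric(frame_rate), frame_rate > 0)
  need <- c("frame", "animal", "bodypart", "x", "y", "likelihood")
  if (!all(need %in% names(data))) {
    stop("pose data must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  data <- tibble::as_tibble(data[need])
  bad <- !is.na(data$likelihood) &
    (data$likelihood < 0 | data$likelihood > 1)
  if (any(bad)) stop("likelihoods must lie in [0, 1]", call. = FALSE)
  data$likelihood[is.na(data$likelihood)] <- 0
  counts <- table(paste(data$animal, data$bodypart))
  if (length(unique(counts)) > 1L) {
    stop("all body parts must share an identical frame count", call. = FALSE)
  }
  data <- dplyr::arrange(data, .data$frame, .data$animal, .data$bodypart)
  structure(data,
            class = c("pose_tbl", class(tibble::tibble())),
            frame_rate = frame_rate, units = units, scheme = scheme)
}

#' @rdname pose_tbl
#' @param x A `pose_tbl`.
#' @export
frame_rate <- function(x) attr(x, "frame_rate")

#' @rdname pose_tbl
#' @export
pose_units <- function(x) attr(x, "units")

#' @rdname pose_tbl
#' @export
pose_scheme <- function(x) attr(x, "scheme")

#' @export
print.pose_tbl <- function(x, ...) {
  sc <- pose_scheme(x)
  cat(sprintf("<pose_tbl> %d frames, %d animal(s), %s, %.4g fps\n",
              n_frames(x), length(sc$animal_ids), pose_units(x),
              frame_rate(x)))
  NextMethod()
}

#' Number of frames in a pose table
#' @param pose A `pose_tbl`.
#' @return Integer frame count.
#' @export
n_frames <- function(pose) length(unique(pose$frame))

# Internal wide-matrix view: list(x, y, lik) with one column per
# (animal, bodypart), frames in rows; `parts` records the column key.
# All numerical stages work on this view and convert back at the edges.
pose_matrices <- function(pose) {
  key <- paste(pose$animal, pose$bodypart, sep = "\r")
  parts <- unique(tibble::tibble(animal = pose$animal,
                                 bodypart = pose$bodypart, key = key))
  frames <- sort(unique(pose$frame))
  fi <- match(pose$frame, frames)
  pi <- match(key, parts$key)
  shape <- c(length(frames), nrow(parts))
  m <- function(v) {
    out <- matrix(NA_real_, shape[1], shape[2])
    out[cbind(fi, pi)] <- v
    out
  }
  list(x = m(pose$x), y = m(pose$y), lik = m(pose$likelihood),
       parts = parts[c("animal", "bodypart")], frames = frames,
       frame_rate = frame_rate(pose), units = pose_units(pose),
       scheme = pose_scheme(pose))
}

pose_from_matrices <- function(pm) {
  nf <- length(pm$frames); np <- nrow(pm$parts)
  dat <- tibble::tibble(
    frame = rep(pm$frames, times = np),
    animal = rep(pm$parts$animal, each = nf),
    bodypart = rep(pm$parts$bodypart, each = nf),
    x = as.vector(pm$x), y = as.vector(pm$y),
    likelihood = pmin(1, pmax(0, as.vector(pm$lik))))
  pose_tbl(dat, pm$frame_rate, pm$units, pm$scheme)
}

# column indices of one animal's part within a pose_matrices view
pm_col <- function(pm, animal, bodypart) {
  i <- which(pm$parts$animal == animal & pm$parts$bodypart == bodypart)
  if (length(i) != 1L) {
    stop("body part not tracked: ", animal, "/", bodypart, call. = FALSE)
  }
  i
}

#' Read a DeepLabCut-style tracking table
#'
#' Parses the CSV dialects written by DeepLabCut: single-animal files have a
#' 3-level column header (scorer / bodyparts / coords), multi-animal files a
#' 4-level header (scorer / individuals / bodyparts / coords). The coords
#' level must contain `x`, `y` and `likelihood` for every tracked part.
#' Cells that are empty in the file become `likelihood = 0` so that frame
#' indices remain aligned with video time.
#'
#' @param path Path to the CSV file.
#' @param scheme A [body_part_scheme()]; every label must be present in the
#'   file for every animal.
#' @param dialect `"dlc_single"` (3 header rows) or `"dlc_multi"` (4 header
#'   rows).
#' @param frame_rate Frame rate in Hz to attach to the table.
#' @return A [pose_tbl()] in pixel units.
#' @export
read_pose_table <- function(path, scheme,
                            dialect = c("dlc_single", "dlc_multi"),
                            frame_rate = 25) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  n_header <- if (dialect == "dlc_single") 3L else 4L
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) <= n_header) stop("no data rows in ", path, call. = FALSE)
  hdr <- raw[seq_len(n_header), -1, drop = FALSE]
  body <- raw[-seq_len(n_header), , drop = FALSE]
  if (dialect == "dlc_single") {
    animal <- rep(scheme$animal_ids[1], ncol(hdr))
    part <- unlist(hdr[2, ], use.names = FALSE)
    coord <- unlist(hdr[3, ], use.names = FALSE)
  } else {
    animal <- unlist(hdr[2, ], use.names = FALSE)
    part <- unlist(hdr[3, ], use.names = FALSE)
    coord <- unlist(hdr[4, ], use.names = FALSE)
  }
  keep <- coord %in% c("x", "y", "likelihood")
  animal <- animal[keep]; part <- part[keep]; coord <- coord[keep]
  vals <- body[, -1, drop = FALSE][, keep, drop = FALSE]
  # schema check: every (animal, part) needs x, y and likelihood
  for (a in scheme$animal_ids) {
    for (p in scheme$labels) {
      have <- coord[animal == a & part == p]
      if (!all(c("x", "y", "likelihood") %in% have)) {
        stop(sprintf("body part '%s' (animal '%s') lacks %s columns", p, a,
                     paste(setdiff(c("x", "y", "likelihood"), have),
                           collapse = "/")), call. = FALSE)
      }
    }
  }
  num <- matrix(NA_real_, nrow(vals), ncol(vals))
  for (j in seq_len(ncol(vals))) {
    v <- vals[[j]]
    v[v == ""] <- NA
    suppressWarnings(nv <- as.numeric(v))
    bad <- which(!is.na(v) & is.na(nv))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' at data row %d, column %d",
                   v[bad[1]], bad[1], j + 1L), call. = FALSE)
    }
    num[, j] <- nv
  }
  nf <- nrow(num)
  rows <- list()
  k <- 1L
  for (a in scheme$animal_ids) {
    for (p in scheme$labels) {
      ix <- which(animal == a & part == p & coord == "x")[1]
      iy <- which(animal == a & part == p & coord == "y")[1]
      il <- which(animal == a & part == p & coord == "likelihood")[1]
      lik <- num[, il]
      xx <- num[, ix]; yy <- num[, iy]
      miss <- is.na(xx) | is.na(yy) | is.na(lik)
      lik[miss] <- 0
      xx[is.na(xx)] <- 0; yy[is.na(yy)] <- 0
      rows[[k]] <- tibble::tibble(frame = seq_len(nf) - 1L, animal = a,
                                  bodypart = p, x = xx, y = yy,
                                  likelihood = lik)
      k <- k + 1L
    }
  }
  pose_tbl(dplyr::bind_rows(rows), frame_rate = frame_rate, units = "px",
           scheme = scheme)
}

#' Write a pose table in the DeepLabCut CSV dialect
#'
#' @param pose A [pose_tbl()].
#' @param path Output CSV path.
#' @param dialect Header layout; `"dlc_multi"` adds the `individuals` level.
#' @param scorer Scorer name written to the first header level.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(pose, path,
                             dialect = c("dlc_single", "dlc_multi"),
                             scorer = "ethomotif") {
  dialect <- match.arg(dialect)
  sc <- pose_scheme(pose)
  if (dialect == "dlc_single" && length(sc$animal_ids) > 1L) {
    stop("dlc_single dialect cannot hold two animals", call. = FALSE)
  }
  pm <- pose_matrices(pose)
  cols <- list(); animal <- c(); part <- c(); coord <- c()
  for (a in sc$animal_ids) {
    for (p in sc$labels) {
      i <- pm_col(pm, a, p)
      cols <- c(cols, list(pm$x[, i], pm$y[, i], pm$lik[, i]))
      animal <- c(animal, rep(a, 3)); part <- c(part, rep(p, 3))
      coord <- c(coord, c("x", "y", "likelihood"))
    }
  }
  mat <- do.call(cbind, cols)
  hdr <- rbind(c("scorer", rep(scorer, ncol(mat))))
  if (dialect == "dlc_multi") {
    hdr <- rbind(hdr, c("individuals", animal))
  }
  hdr <- rbind(hdr, c("bodyparts", part), c("coords", coord))
  body <- cbind(format(pm$frames, trim = TRUE, scientific = FALSE),
                matrix(formatC(mat, format = "g", digits = 15),
                       nrow(mat), ncol(mat)))
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(rbind(hdr, body), con, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a pixel-space pose table to millimeters
#'
#' Divides all coordinates by the arena's `px_per_mm`; likelihoods are left
#' untouched. The conversion is a pure similarity transform, so all
#' inter-point distance ratios are preserved exactly.
#'
#' @param pose A [pose_tbl()] in pixel units.
#' @param arena An [arena_spec()] carrying `px_per_mm`.
#' @return The converted `pose_tbl` in mm units.
#' @export
to_mm <- function(pose, arena) {
  if (pose_units(pose) == "mm") {
    warning("pose table already in mm; returning unchanged")
    return(pose)
  }
  out <- pose
  out$x <- pose$x / arena$px_per_mm
  out$y <- pose$y / arena$px_per_mm
  attr(out, "units") <- "mm"
  out
}

#' Write and read per-frame behavioral annotation tables
#'
#' Annotation tables are per-frame boolean flags, one column per behavior
#' key (`<animal>_<trait>` for individual traits, `<a>.<b>_<trait>` for
#' dyadic ones). On disk they are flat CSVs with a `frame` column and 0/1
#' values; column order is deterministic (animals first, traits
#' alphabetical within animal, dyadic keys last).
#'
#' @param annot A data frame with a `frame` column and logical columns.
#' @param path Output (input) CSV path.
#' @return `write_annotations()` returns `path` invisibly;
#'   `read_annotations()` returns a tibble of logicals with a `frame`
#'   column.
#' @export
write_annotations <- function(annot, path) {
  stopifnot("frame" %in% names(annot))
  keys <- sort(setdiff(names(annot), "frame"))
  out <- annot[c("frame", keys)]
  for (k in keys) out[[k]] <- as.integer(out[[k]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  for (k in setdiff(names(out), "frame")) out[[k]] <- out[[k]] > 0
  out
}
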