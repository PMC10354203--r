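#' Body-part labeling scheme
#'
#' The standard top-down mouse labeling scheme tracks 11 body parts per
#' animal: the nose, both ears, three points along the spine (`spine_1`,
#' `center`, `spine_2`), the tail base, and all four extremities. The
#' annotators require the head and spine labels; the extremities enrich the
#' kinematic feature set.
#'
#' @param animal_ids Character vector of one or two animal identifiers.
#' @param labels Character vector of 11 body-part labels per animal.
#' @return An object of class `body_part_scheme` with elements `labels` and
#'   `animal_ids`.
#' @export
#' @examples
#' body_part_scheme("mouse")
body_part_scheme <- function(animal_ids = "mouse",
                             labels = ethomotif_body_parts()) {
  stopifnot(is.character(animal_ids), length(animal_ids) %in% c(1L, 2L))
  if (anyDuplicated(animal_ids) > 0) {
    stop("animal_ids must be unique", call. = FALSE)
  }
  if (length(labels) != 11L || anyDuplicated(labels) > 0) {
    stop("exactly 11 unique body-part labels are required per animal",
         call. = FALSE)
  }
  required <- c("nose", "left_ear", "right_ear", "spine_1", "center",
                "spine_2", "tail_base")
  missing <- setdiff(required, labels)
  if (length(missing) > 0) {
    stop("scheme is missing required body parts: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(labels = labels, animal_ids = animal_ids),
            class = "body_part_scheme")
}

#' Default 11-part mouse labels
#'
#' @return Character vector of the 11 default body-part labels.
#' @export
ethomotif_body_parts <- function() {
  c("nose", "left_ear", "right_ear", "spine_1", "center", "spine_2",
    "tail_base", "front_left_leg", "front_right_leg", "back_left_leg",
    "back_right_leg")
}

#' @export
print.body_part_scheme <- function(x, ...) {
  cat("<body_part_scheme> ", length(x$animal_ids), " animal(s): ",
      paste(x$animal_ids, collapse = ", "), "\n", sep = "")
  cat("  parts: ", paste(x$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Arena geometry and pixel calibration
#'
#' Describes the arena in which the session was recorded. Circular arenas
#' are given by a center and radius; polygonal arenas by their vertices.
#' `px_per_mm` calibrates raw pixel tracking to millimeters; it must be
#' measured by the user (e.g. from an object of known size in the frame)
#' and supplied here.
#'
#' @param shape `"circular"` or `"polygonal"`.
#' @param center Numeric length-2 arena center, in mm.
#' @param radius Arena radius in mm (circular arenas).
#' @param vertices Two-column matrix of vertices in mm (polygonal arenas).
#' @param px_per_mm Positive pixel-to-millimeter scale factor.
#' @return An `arena_spec` object.
#' @export
#' @examples
#' arena_spec("circular", center = c(190, 190), radius = 190, px_per_mm = 2)
arena_spec <- function(shape = c("circular", "polygonal"),
                       center = c(0, 0), radius = NULL, vertices = NULL,
                       px_per_mm = 1) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(px_per_mm), length(px_per_mm) == 1L, px_per_mm > 0,
            length(center) == 2L)
  if (shape == "circular") {
    if (is.null(radius) || radius <= 0) {
      stop("circular arenas need a positive radius", call. = FALSE)
    }
  } else {
    if (is.null(vertices) || nrow(vertices) < 3L) {
      stop("polygonal arenas need at least 3 vertices", call. = FALSE)
    }
    vertices <- as.matrix(vertices)
  }
  structure(list(shape = shape, center = as.numeric(center), radius = radius,
                 vertices = vertices, px_per_mm = px_per_mm),
            class = "arena_spec")
}

#' @export
print.arena_spec <- function(x, ...) {
  cat("<arena_spec> ", x$shape,
      if (x$shape == "circular") sprintf(", radius %.1f mm", x$radius)
      else sprintf(", %d vertices", nrow(x$vertices)),
      sprintf(", %.3g px/mm", x$px_per_mm), "\n", sep = "")
  invisible(x)
}

# Signed distance from points to the arena boundary: positive outside.
# For circles this is |p - center| - R; for polygons, the distance to the
# boundary with sign from point-in-polygon.
arena_signed_distance <- function(arena, x, y) {
  if (arena$shape == "circular") {
    sqrt((x - arena$center[1])^2 + (y - arena$center[2])^2) - arena$radius
  } else {
    v <- arena$vertices
    n <- nrow(v)
    d2 <- rep(Inf, length(x))
    for (i in seq_len(n)) {
      a <- v[i, ]
      b <- v[if (i == n) 1L else i + 1L, ]
      ab <- b - a
      len2 <- sum(ab^2)
      t <- pmin(1, pmax(0, ((x - a[1]) * ab[1] + (y - a[2]) * ab[2]) / len2))
      px <- a[1] + t * ab[1]
      py <- a[2] + t * ab[2]
      d2 <- pmin(d2, (x - px)^2 + (y - py)^2)
    }
    inside <- point_in_polygon(x, y, v)
    sqrt(d2) * ifelse(inside, -1, 1)
  }
}

point_in_polygon <- function(x, y, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    xj <- v[j, 1]; yj <- v[j, 2]
    cross <- (yi > y) != (yj > y)
    xint <- (xj - xi) * (y - yi) / (yj - yi) + xi
    inside <- xor(inside, cross & (x < xint))
    j <- i
  }
  inside
}
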