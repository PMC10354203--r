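#' Egocentric alignment of body-part coordinates
#'
#' Per frame and per animal, applies the rigid transform (translation plus
#' rotation, no scaling) that puts the animal's `center` at the origin and
#' its `spine_1` on the positive y axis. Translational and rotational
#' variance is thereby removed, leaving pure posture. If `center` and
#' `spine_1` coincide in a frame the rotation is undefined; the previous
#' frame's rotation is reused (and the first frame falls back to the
#' identity rotation).
#'
#' @param pose A [pose_tbl()].
#' @return A wide tibble: `frame` plus `<animal>.<part>_x` /
#'   `<animal>.<part>_y` egocentric coordinates.
#' @export
egocentric_align <- function(pose) {
  pm <- pose_matrices(pose)
  sc <- pm$scheme
  out <- list(frame = pm$frames)
  for (a in sc$animal_ids) {
    ic <- pm_col(pm, a, "center")
    is1 <- pm_col(pm, a, "spine_1")
    vx <- pm$x[, is1] - pm$x[, ic]
    vy <- pm$y[, is1] - pm$y[, ic]
    theta <- atan2(vy, vx)
    deg <- vx == 0 & vy == 0
    if (any(deg)) {
      message(sum(deg), " frame(s) with center == spine_1 for '", a,
              "'; reusing previous rotation")
      theta[deg] <- NA
      theta <- fill_forward(theta, default = pi / 2)
    }
    phi <- pi / 2 - theta  # rotate spine axis onto +y
    cphi <- cos(phi); sphi <- sin(phi)
    for (p in sc$labels) {
      ip <- pm_col(pm, a, p)
      dx <- pm$x[, ip] - pm$x[, ic]
      dy <- pm$y[, ip] - pm$y[, ic]
      out[[paste0(a, ".", p, "_x")]] <- cphi * dx - sphi * dy
      out[[paste0(a, ".", p, "_y")]] <- sphi * dx + cphi * dy
    }
  }
  tibble::as_tibble(out)
}

fill_forward <- function(v, default) {
  if (is.na(v[1])) v[1] <- default
  for (i in seq_along(v)[-1]) if (is.na(v[i])) v[i] <- v[i - 1]
  v
}

#' Pairwise distances between all tracked body parts
#'
#' Euclidean distance per frame for every unordered pair of body parts,
#' within and across animals.
#'
#' @param pose A [pose_tbl()].
#' @return A wide tibble: `frame` plus one
#'   `"<animal>.<part>__<animal>.<part>"` column per pair.
#' @export
pairwise_distances <- function(pose) {
  pm <- pose_matrices(pose)
  np <- nrow(pm$parts)
  keys <- paste(pm$parts$animal, pm$parts$bodypart, sep = ".")
  out <- list(frame = pm$frames)
  for (i in seq_len(np - 1)) {
    for (j in (i + 1):np) {
      out[[paste0(keys[i], "__", keys[j])]] <-
        sqrt((pm$x[, i] - pm$x[, j])^2 + (pm$y[, i] - pm$y[, j])^2)
    }
  }
  tibble::as_tibble(out)
}

#' Default joint-angle triplets
#'
#' Four anatomical angles per animal: the head angle (vertex at the nose),
#' the neck (vertex at `spine_1`), and two spine angles (vertices at
#' `center` and `spine_2`).
#'
#' @return Named list of character triplets `(a, vertex, b)`.
#' @export
default_angle_triplets <- function() {
  list(head = c("left_ear", "nose", "right_ear"),
       neck = c("nose", "spine_1", "center"),
       spine_mid = c("spine_1", "center", "spine_2"),
       spine_back = c("center", "spine_2", "tail_base"))
}

#' Joint angles at anatomical vertices
#'
#' The angle at the vertex of each `(a, vertex, b)` triplet, in radians
#' within \[0, pi\]. Degenerate frames (a zero-length limb) yield `NA`.
#'
#' @param pose A [pose_tbl()].
#' @param triplets Named list of part-name triplets; defaults to
#'   [default_angle_triplets()].
#' @return A wide tibble: `frame` plus `<animal>.<triplet name>` columns.
#' @export
joint_angles <- function(pose, triplets = default_angle_triplets()) {
  pm <- pose_matrices(pose)
  out <- list(frame = pm$frames)
  for (a in pm$scheme$animal_ids) {
    for (nm in names(triplets)) {
      tr <- triplets[[nm]]
      ia <- pm_col(pm, a, tr[1]); iv <- pm_col(pm, a, tr[2])
      ib <- pm_col(pm, a, tr[3])
      ux <- pm$x[, ia] - pm$x[, iv]; uy <- pm$y[, ia] - pm$y[, iv]
      wx <- pm$x[, ib] - pm$x[, iv]; wy <- pm$y[, ib] - pm$y[, iv]
      nu <- sqrt(ux^2 + uy^2); nw <- sqrt(wx^2 + wy^2)
      cosang <- (ux * wx + uy * wy) / (nu * nw)
      cosang[nu == 0 | nw == 0] <- NA
      out[[paste0(a, ".", nm)]] <- acos(pmin(1, pmax(-1, cosang)))
    }
  }
  tibble::as_tibble(out)
}

area_polygons <- function() {
  list(
    full = c("nose", "right_ear", "front_right_leg", "back_right_leg",
             "tail_base", "back_left_leg", "front_left_leg", "left_ear"),
    head = c("nose", "right_ear", "spine_1", "left_ear"),
    torso = c("spine_1", "front_right_leg", "spine_2", "front_left_leg"),
    back = c("center", "back_right_leg", "tail_base", "back_left_leg"))
}

#' Body-region areas
#'
#' Shoelace polygon areas of four anatomical regions per animal and frame:
#' the full body outline (all external parts: nose, ears, legs, tail
#' base), the head (nose, ears, `spine_1`), the torso (`spine_1`, both
#' front legs, `spine_2`), and the back (`center`, both back legs, tail
#' base). Vertices follow a fixed anatomical cycle and the absolute value
#' is taken, so areas are non-negative.
#'
#' @param pose A [pose_tbl()].
#' @return A wide tibble: `frame` plus `<animal>.area_<region>` columns in
#'   squared coordinate units.
#' @export
body_areas <- function(pose) {
  pm <- pose_matrices(pose)
  polys <- area_polygons()
  out <- list(frame = pm$frames)
  for (a in pm$scheme$animal_ids) {
    for (nm in names(polys)) {
      idx <- vapply(polys[[nm]], function(p) pm_col(pm, a, p), integer(1))
      xs <- pm$x[, idx, drop = FALSE]
      ys <- pm$y[, idx, drop = FALSE]
      nxt <- c(seq_along(idx)[-1], 1L)
      out[[paste0(a, ".area_", nm)]] <-
        abs(rowSums(xs * ys[, nxt, drop = FALSE] -
                      xs[, nxt, drop = FALSE] * ys)) / 2
    }
  }
  tibble::as_tibble(out)
}

#' Finite-difference time derivatives
#'
#' First-order derivatives are computed as consecutive-frame differences
#' scaled by the frame rate; higher orders are finite differences of the
#' lower order. The first frame is padded by repetition so every series
#' keeps full length.
#'
#' @param tbl A tibble with a `frame` column and numeric feature columns
#'   (or a bare numeric vector).
#' @param frame_rate Frames per second.
#' @param order Derivative order (>= 1).
#' @return Object of the same shape with differentiated values, in
#'   unit/s^order.
#' @export
time_derivatives <- function(tbl, frame_rate, order = 1) {
  stopifnot(order >= 1)
  d1 <- function(v) {
    dv <- diff(v) * frame_rate
    c(dv[1], dv)
  }
  dn <- function(v) {
    for (k in seq_len(order)) v <- d1(v)
    v
  }
  if (is.numeric(tbl)) return(dn(tbl))
  out <- tbl
  for (nm in setdiff(names(tbl), "frame")) out[[nm]] <- dn(tbl[[nm]])
  out
}

#' Body-part speeds
#'
#' Speed of each tracked part in arena-frame (not egocentric) coordinates,
#' so locomotion is captured: the Euclidean displacement between
#' consecutive frames times the frame rate, first frame padded by
#' repetition.
#'
#' @param pose A [pose_tbl()].
#' @return A wide tibble: `frame` plus `<animal>.<part>` speed columns in
#'   unit/s.
#' @export
part_speeds <- function(pose) {
  pm <- pose_matrices(pose)
  fr <- pm$frame_rate
  out <- list(frame = pm$frames)
  keys <- paste(pm$parts$animal, pm$parts$bodypart, sep = ".")
  for (j in seq_len(ncol(pm$x))) {
    disp <- sqrt(diff(pm$x[, j])^2 + diff(pm$y[, j])^2) * fr
    out[[keys[j]]] <- c(disp[1], disp)
  }
  tibble::as_tibble(out)
}

#' Extract the full kinematic feature bundle
#'
#' Computes egocentric coordinates, all pairwise distances, joint angles,
#' body areas, part speeds, and first derivatives of distances and areas
#' for a (preprocessed) pose table.
#'
#' @param pose A [pose_tbl()].
#' @param triplets Angle triplets, see [joint_angles()].
#' @return A `feature_bundle`: list of tibbles `ego`, `dist`, `angles`,
#'   `areas`, `speeds`, `dist_deriv`, `area_deriv`, with attributes
#'   `frame_rate` and `scheme`.
#' @export
extract_features <- function(pose, triplets = default_angle_triplets()) {
  fr <- frame_rate(pose)
  dist <- pairwise_distances(pose)
  areas <- body_areas(pose)
  structure(list(
    ego = egocentric_align(pose),
    dist = dist,
    angles = joint_angles(pose, triplets),
    areas = areas,
    speeds = part_speeds(pose),
    dist_deriv = time_derivatives(dist, fr, 1),
    area_deriv = time_derivatives(areas, fr, 1)),
    class = "feature_bundle", frame_rate = fr, scheme = pose_scheme(pose))
}

#' @export
print.feature_bundle <- function(x, ...) {
  cat("<feature_bundle> ", nrow(x$dist), " frames; ",
      ncol(x$dist) - 1L, " distances, ", ncol(x$angles) - 1L, " angles, ",
      ncol(x$areas) - 1L, " areas\n", sep = "")
  invisible(x)
}

# distance column lookup tolerant to pair order
dist_col <- function(dist, a1, p1, a2, p2) {
  k1 <- paste0(a1, ".", p1, "__", a2, ".", p2)
  k2 <- paste0(a2, ".", p2, "__", a1, ".", p1)
  if (k1 %in% names(dist)) dist[[k1]] else dist[[k2]]
}
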