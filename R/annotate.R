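#' Rule-based annotation thresholds
#'
#' All distance thresholds are in millimeters and speed thresholds in
#' mm/s; the pose table must therefore be in mm units (see [to_mm()]).
#' Every annotation additionally requires a tracking likelihood of at
#' least `likelihood_gate` on all involved body parts. Comparisons use
#' strict inequalities throughout.
#'
#' @param contact_mm Contact distance for the dyadic annotators.
#' @param still_speed_mms Center speed below which the animal counts as
#'   standing still.
#' @param head_move_speed_mms Nose/ear speed above which the head counts
#'   as moving.
#' @param wall_sniff_mm Maximum nose-to-wall distance for wall sniffing.
#' @param climb_overhang_mm Distance beyond the arena boundary that counts
#'   as climbing.
#' @param likelihood_gate Minimum tracking likelihood on involved parts.
#' @return A `rule_thresholds` object.
#' @export
rule_thresholds <- function(contact_mm = 15, still_speed_mms = 40,
                            head_move_speed_mms = 20, wall_sniff_mm = 10,
                            climb_overhang_mm = 5, likelihood_gate = 0.85) {
  stopifnot(contact_mm > 0, still_speed_mms > 0, head_move_speed_mms > 0,
            wall_sniff_mm > 0, climb_overhang_mm > 0,
            likelihood_gate > 0, likelihood_gate <= 1)
  structure(list(contact_mm = contact_mm,
                 still_speed_mms = still_speed_mms,
                 head_move_speed_mms = head_move_speed_mms,
                 wall_sniff_mm = wall_sniff_mm,
                 climb_overhang_mm = climb_overhang_mm,
                 likelihood_gate = likelihood_gate),
            class = "rule_thresholds")
}

lik_series <- function(pm, animal, part) pm$lik[, pm_col(pm, animal, part)]

#' Annotate dyadic social behaviors
#'
#' Per-frame rule evaluation of the five dyadic traits for a two-animal
#' session: nose-to-nose and (directional) nose-to-tail contact are single
#' distance thresholds; nose-to-body uses the minimum distance between one
#' animal's nose and any of the other's body parts except nose and tail
#' base; side-by-side requires both the noses and the tail bases to be in
#' contact; side-reverse-side requires both directional nose-to-tail
#' distances to be in contact. Every flag requires the likelihood gate on
#' all involved parts. Annotators are independent: several can be true in
#' the same frame.
#'
#' @param features A [extract_features()] bundle for `pose`.
#' @param pose The two-animal [pose_tbl()] (mm units).
#' @param thr A [rule_thresholds()].
#' @return Annotation tibble: `frame` plus logical columns
#'   `<A>-<B>_nose_to_nose`, `<a>_nose_to_tail`, `<a>_nose_to_body`,
#'   `<A>-<B>_side_by_side`, `<A>-<B>_side_reverse_side`.
#' @export
annotate_dyadic <- function(features, pose, thr = rule_thresholds()) {
  sc <- pose_scheme(pose)
  if (length(sc$animal_ids) != 2L) {
    stop("dyadic annotation needs exactly two animals", call. = FALSE)
  }
  a <- sc$animal_ids[1]; b <- sc$animal_ids[2]
  pm <- pose_matrices(pose)
  g <- thr$likelihood_gate
  dist <- features$dist
  pair <- paste0(a, "-", b)
  ok <- function(...) {
    liks <- list(...)
    Reduce(`&`, lapply(liks, function(l) l >= g))
  }
  lik <- function(an, p) lik_series(pm, an, p)
  out <- tibble::tibble(frame = dist$frame)
  out[[paste0(pair, "_nose_to_nose")]] <-
    dist_col(dist, a, "nose", b, "nose") < thr$contact_mm &
    ok(lik(a, "nose"), lik(b, "nose"))
  for (pr in list(c(a, b), c(b, a))) {
    out[[paste0(pr[1], "_nose_to_tail")]] <-
      dist_col(dist, pr[1], "nose", pr[2], "tail_base") < thr$contact_mm &
      ok(lik(pr[1], "nose"), lik(pr[2], "tail_base"))
    # nose-to-body: any eligible part of the partner except nose/tail base
    body_parts <- setdiff(sc$labels, c("nose", "tail_base"))
    hit <- rep(FALSE, nrow(dist))
    for (p in body_parts) {
      hit <- hit | (dist_col(dist, pr[1], "nose", pr[2], p) < thr$contact_mm &
                      ok(lik(pr[2], p)))
    }
    out[[paste0(pr[1], "_nose_to_body")]] <- hit & ok(lik(pr[1], "nose"))
  }
  out[[paste0(pair, "_side_by_side")]] <-
    dist_col(dist, a, "nose", b, "nose") < thr$contact_mm &
    dist_col(dist, a, "tail_base", b, "tail_base") < thr$contact_mm &
    ok(lik(a, "nose"), lik(b, "nose"), lik(a, "tail_base"),
       lik(b, "tail_base"))
  out[[paste0(pair, "_side_reverse_side")]] <-
    dist_col(dist, a, "nose", b, "tail_base") < thr$contact_mm &
    dist_col(dist, b, "nose", a, "tail_base") < thr$contact_mm &
    ok(lik(a, "nose"), lik(b, "nose"), lik(a, "tail_base"),
       lik(b, "tail_base"))
  out
}

#' Annotate individual behaviors
#'
#' Per-frame rule evaluation of the individual traits for each animal:
#' look-around (standing still with the head moving), wall sniffing
#' (still, nose within `wall_sniff_mm` of the arena boundary, head
#' moving), and wall climbing (nose beyond the boundary by more than
#' `climb_overhang_mm`). "Still" means center speed below
#' `still_speed_mms`; "head moving" means nose and both ear speeds above
#' `head_move_speed_mms`. Polygonal arenas use the signed distance to the
#' boundary. The likelihood gate applies to all involved parts.
#'
#' @param features A [extract_features()] bundle for `pose`.
#' @param pose A [pose_tbl()] in mm units.
#' @param arena An [arena_spec()] in mm.
#' @param thr A [rule_thresholds()].
#' @return Annotation tibble: `frame` plus `<animal>_look_around`,
#'   `<animal>_wall_sniff`, `<animal>_climb` logical columns.
#' @export
annotate_individual <- function(features, pose, arena,
                                thr = rule_thresholds()) {
  if (missing(arena) || is.null(arena)) {
    stop("individual annotation requires the arena geometry", call. = FALSE)
  }
  sc <- pose_scheme(pose)
  pm <- pose_matrices(pose)
  sp <- features$speeds
  g <- thr$likelihood_gate
  out <- tibble::tibble(frame = sp$frame)
  for (a in sc$animal_ids) {
    lik <- function(p) lik_series(pm, a, p)
    head_gate <- lik("nose") >= g & lik("left_ear") >= g &
      lik("right_ear") >= g
    still <- sp[[paste0(a, ".center")]] < thr$still_speed_mms &
      lik("center") >= g
    head_moving <- sp[[paste0(a, ".nose")]] > thr$head_move_speed_mms &
      sp[[paste0(a, ".left_ear")]] > thr$head_move_speed_mms &
      sp[[paste0(a, ".right_ear")]] > thr$head_move_speed_mms & head_gate
    nose_out <- arena_signed_distance(
      arena, pm$x[, pm_col(pm, a, "nose")], pm$y[, pm_col(pm, a, "nose")])
    out[[paste0(a, "_look_around")]] <- still & head_moving
    out[[paste0(a, "_wall_sniff")]] <- still & head_moving &
      (-nose_out) < thr$wall_sniff_mm & lik("nose") >= g
    out[[paste0(a, "_climb")]] <- nose_out > thr$climb_overhang_mm &
      lik("nose") >= g
  }
  out
}

#' The fixed 26-feature set of the huddle classifier
#'
#' One animal's per-frame feature vector: seven adjacent head/spine
#' distances, the spine stretch (nose to tail base), four limb-anchor
#' distances, the four body areas with their first derivatives, and six
#' body-part speeds. The order is fixed and versioned; models store it and
#' refuse feature tables that do not match.
#'
#' @param features A [extract_features()] bundle.
#' @param animal Animal id; defaults to the first in the scheme.
#' @return Tibble of 26 named feature columns plus `frame`.
#' @export
huddle_features <- function(features, animal = NULL) {
  sc <- attr(features, "scheme")
  if (is.null(animal)) animal <- sc$animal_ids[1]
  d <- features$dist
  pairs <- list(c("nose", "left_ear"), c("nose", "right_ear"),
                c("left_ear", "spine_1"), c("right_ear", "spine_1"),
                c("spine_1", "center"), c("center", "spine_2"),
                c("spine_2", "tail_base"), c("nose", "tail_base"),
                c("front_left_leg", "spine_1"), c("front_right_leg", "spine_1"),
                c("back_left_leg", "spine_2"), c("back_right_leg", "spine_2"))
  out <- tibble::tibble(frame = d$frame)
  for (p in pairs) {
    out[[paste0("dist_", p[1], "_", p[2])]] <-
      dist_col(d, animal, p[1], animal, p[2])
  }
  for (r in c("full", "head", "torso", "back")) {
    out[[paste0("area_", r)]] <- features$areas[[paste0(animal, ".area_", r)]]
    out[[paste0("area_", r, "_deriv")]] <-
      features$area_deriv[[paste0(animal, ".area_", r)]]
  }
  for (p in c("nose", "left_ear", "right_ear", "center", "spine_2",
              "tail_base")) {
    out[[paste0("speed_", p)]] <- features$speeds[[paste0(animal, ".", p)]]
  }
  stopifnot(ncol(out) - 1L == 26L)
  out
}

#' Names of the 26 huddle-classifier features
#' @return Character vector of length 26.
#' @export
huddle_feature_names <- function() {
  c("dist_nose_left_ear", "dist_nose_right_ear", "dist_left_ear_spine_1",
    "dist_right_ear_spine_1", "dist_spine_1_center", "dist_center_spine_2",
    "dist_spine_2_tail_base", "dist_nose_tail_base",
    "dist_front_left_leg_spine_1", "dist_front_right_leg_spine_1",
    "dist_back_left_leg_spine_2", "dist_back_right_leg_spine_2",
    "area_full", "area_full_deriv", "area_head", "area_head_deriv",
    "area_torso", "area_torso_deriv", "area_back", "area_back_deriv",
    "speed_nose", "speed_left_ear", "speed_right_ear", "speed_center",
    "speed_spine_2", "speed_tail_base")
}

#' Annotate a full session (rules plus optional classifier) and smooth
#'
#' Convenience wrapper: runs the individual annotators (and the dyadic
#' ones when two animals are tracked), optionally the huddle classifier,
#' then applies Kleinberg burst smoothing to every annotator's output.
#'
#' @param pose A [pose_tbl()] in mm units.
#' @param arena An [arena_spec()].
#' @param thr A [rule_thresholds()].
#' @param huddle_model Optional [train_huddle()] model; adds an
#'   `<animal>_huddle` column per animal.
#' @param kleinberg A [kleinberg_params()], or `NULL` to skip smoothing.
#' @return Annotation tibble (`frame` plus logical columns).
#' @export
annotate_session <- function(pose, arena, thr = rule_thresholds(),
                             huddle_model = NULL,
                             kleinberg = kleinberg_params()) {
  features <- extract_features(pose)
  sc <- pose_scheme(pose)
  annot <- annotate_individual(features, pose, arena, thr)
  if (length(sc$animal_ids) == 2L) {
    annot <- dplyr::left_join(annot, annotate_dyadic(features, pose, thr),
                              by = "frame")
  }
  if (!is.null(huddle_model)) {
    for (a in sc$animal_ids) {
      annot[[paste0(a, "_huddle")]] <-
        predict_huddle(huddle_model, huddle_features(features, a))
    }
  }
  if (!is.null(kleinberg)) annot <- smooth_annotations(annot, kleinberg)
  annot
}
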