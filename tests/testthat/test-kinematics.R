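single_frame_pose <- function(xy, fr = 10) {
  parts <- ethomotif_body_parts()
  stopifnot(nrow(xy) == 11)
  dat <- tibble::tibble(frame = 0L, animal = "m", bodypart = parts,
                        x = xy[, 1], y = xy[, 2], likelihood = 0.99)
  pose_tbl(dat, fr, "mm", body_part_scheme("m"))
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

test_that("egocentric alignment is the identity on aligned frames and
           removes global motion", {
  tmpl <- mouse_posture_template()  # already centered, spine_1 on +y
  pose <- single_frame_pose(tmpl)
  ego <- egocentric_align(pose)
  for (i in seq_len(11)) {
    p <- ethomotif_body_parts()[i]
    expect_equal(ego[[paste0("m.", p, "_x")]], unname(tmpl[i, 1]),
                 tolerance = 1e-12)
    expect_equal(ego[[paste0("m.", p, "_y")]], unname(tmpl[i, 2]),
                 tolerance = 1e-12)
  }
  # translate by (50, 30) and rotate 90 degrees: same egocentric coords
  moved <- single_frame_pose(sweep(tmpl %*% t(rot2(pi / 2)), 2,
                                   c(-50, -30)))
  ego2 <- egocentric_align(moved)
  expect_equal(as.matrix(ego2[-1]), as.matrix(ego[-1]), tolerance = 1e-9)
  # rigid transform: all pairwise distances preserved
  s <- small_session()
  d_before <- as.matrix(pairwise_distances(s$pose)[-1])
  eg <- egocentric_align(s$pose)
  ego_pose <- s$pose
  for (p in ethomotif_body_parts()) {
    sel <- ego_pose$bodypart == p
    ego_pose$x[sel] <- eg[[paste0("mouse.", p, "_x")]]
    ego_pose$y[sel] <- eg[[paste0("mouse.", p, "_y")]]
  }
  d_after <- as.matrix(pairwise_distances(ego_pose)[-1])
  expect_equal(d_after, d_before, tolerance = 1e-9)
})

test_that("pairwise distances are exact and satisfy the triangle inequality", {
  tmpl <- mouse_posture_template()
  tmpl[1, ] <- c(0, 0)   # nose
  tmpl[2, ] <- c(3, 4)   # left_ear
  tmpl[3, ] <- c(0, 0)   # right_ear coincides with nose
  d <- pairwise_distances(single_frame_pose(tmpl))
  expect_equal(ethomotif:::dist_col(d, "m", "nose", "m", "left_ear"), 5)
  expect_equal(ethomotif:::dist_col(d, "m", "nose", "m", "right_ear"), 0)
  s <- small_session()
  dd <- pairwise_distances(s$pose)
  pm <- ethomotif:::pose_matrices(s$pose)
  keys <- paste(pm$parts$animal, pm$parts$bodypart, sep = ".")
  set.seed(1)
  for (rep in 1:300) {
    t <- sample(nrow(dd), 1)
    ijk <- sample(11, 3)
    g <- function(i, j) {
      k1 <- paste0(keys[i], "__", keys[j]); k2 <- paste0(keys[j], "__", keys[i])
      (if (k1 %in% names(dd)) dd[[k1]] else dd[[k2]])[t]
    }
    expect_lte(g(ijk[1], ijk[3]),
               g(ijk[1], ijk[2]) + g(ijk[2], ijk[3]) + 1e-9)
  }
})

test_that("joint angles hit the textbook cases and are rotation invariant", {
  tmpl <- mouse_posture_template()
  # collinear: nose, spine_1, center on one line -> angle pi at spine_1
  tmpl[1, ] <- c(0, 30); tmpl[4, ] <- c(0, 18); tmpl[5, ] <- c(0, 0)
  a <- joint_angles(single_frame_pose(tmpl))
  expect_equal(a$m.neck, pi, tolerance = 1e-9)
  # right angle at the vertex
  tmpl[1, ] <- c(1, 18); tmpl[5, ] <- c(0, 17)
  tmpl[4, ] <- c(0, 18)
  a2 <- joint_angles(single_frame_pose(tmpl))
  expect_equal(a2$m.neck, pi / 2, tolerance = 1e-9)
  # degenerate limb -> NA
  tmpl[1, ] <- tmpl[4, ]
  expect_true(is.na(joint_angles(single_frame_pose(tmpl))$m.neck))
  # global rotation leaves every angle unchanged
  s <- small_session()
  base <- joint_angles(s$pose)
  rot_pose <- s$pose
  xy <- cbind(s$pose$x, s$pose$y) %*% t(rot2(0.83))
  rot_pose$x <- xy[, 1]; rot_pose$y <- xy[, 2]
  expect_equal(as.matrix(joint_angles(rot_pose)[-1]), as.matrix(base[-1]),
               tolerance = 1e-10)
})

test_that("body areas equal shoelace and fan-triangulation oracles", {
  # unit square as the back region: center, back legs, tail base
  tmpl <- mouse_posture_template()
  tmpl[5, ] <- c(0, 0); tmpl[11, ] <- c(1, 0)
  tmpl[7, ] <- c(1, 1); tmpl[10, ] <- c(0, 1)
  ar <- body_areas(single_frame_pose(tmpl))
  expect_equal(ar$m.area_back, 1)
  # right triangle with legs 4 and 3 (degenerate fourth vertex)
  tmpl[5, ] <- c(0, 0); tmpl[11, ] <- c(4, 0)
  tmpl[7, ] <- c(0, 3); tmpl[10, ] <- c(0, 0)
  expect_equal(body_areas(single_frame_pose(tmpl))$m.area_back, 6)
  # random convex quadrilaterals vs a signed-triangle-fan oracle
  set.seed(2)
  for (i in 1:100) {
    ang <- sort(runif(4, 0, 2 * pi))
    r <- runif(4, 5, 20)
    quad <- cbind(r * cos(ang), r * sin(ang))
    tmpl[5, ] <- quad[1, ]; tmpl[11, ] <- quad[2, ]
    tmpl[7, ] <- quad[3, ]; tmpl[10, ] <- quad[4, ]
    fan <- 0
    for (j in 2:3) {
      v1 <- quad[j, ] - quad[1, ]; v2 <- quad[j + 1, ] - quad[1, ]
      fan <- fan + (v1[1] * v2[2] - v1[2] * v2[1]) / 2
    }
    expect_equal(body_areas(single_frame_pose(tmpl))$m.area_back, abs(fan),
                 tolerance = 1e-9)
  }
})

test_that("time derivatives recover closed-form kinematics", {
  parts <- ethomotif_body_parts()
  n <- 100
  static <- dplyr::bind_rows(lapply(parts, function(p) {
    tibble::tibble(frame = 0:(n - 1), animal = "m", bodypart = p,
                   x = 5, y = -2, likelihood = 0.99)
  }))
  sp <- part_speeds(pose_tbl(static, 25, "mm", body_part_scheme("m")))
  expect_equal(max(as.matrix(sp[-1])), 0)
  # uniform motion: 2 mm/frame at 25 fps = 50 mm/s
  uni <- dplyr::bind_rows(lapply(parts, function(p) {
    tibble::tibble(frame = 0:(n - 1), animal = "m", bodypart = p,
                   x = 2 * (0:(n - 1)), y = 0, likelihood = 0.99)
  }))
  spu <- part_speeds(pose_tbl(uni, 25, "mm", body_part_scheme("m")))
  expect_equal(unique(round(spu$m.nose, 9)), 50)
  # circular motion: constant speed, acceleration magnitude v^2 / r
  fr <- 100; rad <- 50; omega <- 2
  t <- (0:(20 * fr - 1)) / fr
  circ <- dplyr::bind_rows(lapply(parts, function(p) {
    tibble::tibble(frame = seq_along(t) - 1L, animal = "m", bodypart = p,
                   x = rad * cos(omega * t), y = rad * sin(omega * t),
                   likelihood = 0.99)
  }))
  pose <- pose_tbl(circ, fr, "mm", body_part_scheme("m"))
  v <- part_speeds(pose)$m.nose
  interior <- 10:(length(v) - 10)
  expect_lt(diff(range(v[interior])), 1e-6 * mean(v))
  # acceleration from x/y component derivatives
  ax <- time_derivatives(rad * cos(omega * t), fr, 2)
  ay <- time_derivatives(rad * sin(omega * t), fr, 2)
  a_mag <- sqrt(ax^2 + ay^2)[interior]
  expect_lt(abs(mean(a_mag) - rad * omega^2) / (rad * omega^2), 0.05)
})

test_that("features transform correctly under scaling", {
  s <- small_session()
  scaled <- s$pose
  scaled$x <- scaled$x * 3; scaled$y <- scaled$y * 3
  f1 <- extract_features(s$pose)
  f3 <- extract_features(scaled)
  expect_equal(as.matrix(f3$dist[-1]), 3 * as.matrix(f1$dist[-1]),
               tolerance = 1e-9)
  expect_equal(as.matrix(f3$areas[-1]), 9 * as.matrix(f1$areas[-1]),
               tolerance = 1e-9)
  expect_equal(as.matrix(f3$speeds[-1]), 3 * as.matrix(f1$speeds[-1]),
               tolerance = 1e-9)
  expect_equal(as.matrix(f3$angles[-1]), as.matrix(f1$angles[-1]),
               tolerance = 1e-9)
})
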