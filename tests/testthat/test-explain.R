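stats_fixture <- function() {
  fixture("window_stats", function() {
    s <- small_session()
    f <- extract_features(s$pose)
    arena <- arena_spec("circular", c(200, 200), 190)
    annot <- annotate_individual(f, s$pose, arena)
    starts <- seq(0, 580, by = 10)
    list(stats = window_stats(f, annot, starts, 10), features = f,
         annot = annot, starts = starts, session = s)
  })
}

test_that("window statistics have the exact registry dimensions", {
  fx <- stats_fixture()
  expect_equal(ncol(fx$stats) - 1L, 52L)  # single animal
  d <- small_dyad()
  annot_d <- annotate_dyadic(d$features, d$pose)
  annot_d <- dplyr::left_join(
    annot_d, annotate_individual(d$features, d$pose,
                                 arena_spec("circular", c(200, 200), 190)),
    by = "frame")
  st_d <- window_stats(d$features, annot_d, seq(0, 480, by = 10), 10)
  expect_equal(ncol(st_d) - 1L, 111L)  # dyad
})

test_that("window means equal brute-force averages and frozen windows are
           degenerate", {
  fx <- stats_fixture()
  # mean speed feature equals the brute-force mean over the window
  i <- 5
  w <- (fx$starts[i] + 1):(fx$starts[i] + 10)
  expect_equal(fx$stats$mouse.speed_nose[i],
               mean(fx$features$speeds$mouse.nose[w]), tolerance = 1e-10)
  expect_equal(fx$stats$mouse.area_full[i],
               mean(fx$features$areas$mouse.area_full[w]),
               tolerance = 1e-10)
  # annotator features are window fractions in [0, 1]
  expect_true(all(fx$stats$mouse.annot_climb >= 0 &
                    fx$stats$mouse.annot_climb <= 1))
  expect_equal(fx$stats$mouse.annot_look_around[i],
               mean(fx$annot$mouse_look_around[w]))
  # frozen window: speed-type stats zero, annotator fractions in {0, 1}
  parts <- ethomotif_body_parts()
  frozen <- dplyr::bind_rows(lapply(seq_along(parts), function(j) {
    tibble::tibble(frame = 0:19, animal = "m", bodypart = parts[j],
                   x = 200 + mouse_posture_template()[j, 1],
                   y = 200 + mouse_posture_template()[j, 2],
                   likelihood = 0.99)
  }))
  pose_f <- pose_tbl(frozen, 10, "mm", body_part_scheme("m"))
  ff <- extract_features(pose_f)
  af <- annotate_individual(ff, pose_f, arena_spec("circular",
                                                   c(200, 200), 190))
  sf <- window_stats(ff, af, c(0, 10), 10)
  deriv_cols <- grep("speed_|\\.ddist_|\\.darea_|\\.dspine",
                     names(sf), value = TRUE)
  expect_equal(max(abs(as.matrix(sf[deriv_cols]))), 0)
  expect_true(all(unlist(sf[grep("annot_", names(sf))]) %in% c(0, 1)))
})

test_that("a planted linear rule is learned with grouped cross-validation", {
  set.seed(21)
  n <- 600
  x <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  labels <- 1L + (x[, 2] > 0) + 2L * (x[, 5] > 0)  # 4 classes from f2, f5
  vids <- paste0("vid", rep(1:12, length.out = n))
  fit <- suppressMessages(
    fit_cluster_explainer(tibble::as_tibble(x), labels, vids, nfolds = 6,
                          seed = 2))
  expect_gte(mean(fit$cv_report$balanced_accuracy), 0.9)
  # grouped CV: no video on both sides of any fold
  for (f in unique(fit$fold_by_video)) {
    tr_vids <- names(fit$fold_by_video)[fit$fold_by_video != f]
    te_vids <- names(fit$fold_by_video)[fit$fold_by_video == f]
    expect_length(intersect(tr_vids, te_vids), 0)
  }
  # permuted labels land near chance (1/4)
  set.seed(3)
  fitp <- suppressMessages(
    fit_cluster_explainer(tibble::as_tibble(x), sample(labels), vids,
                          nfolds = 6, seed = 2, nrounds = 30))
  expect_lt(abs(mean(fitp$cv_report$balanced_accuracy) - 0.25), 0.1)
  expect_equal(fit$per_cluster$chance, rep(0.25, 4))
})

test_that("permutation SHAP is additive and recovers planted features", {
  set.seed(22)
  n <- 300
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  labels <- 1L + (x[, 2] > 0) + 2L * (x[, 5] > 0)
  vids <- paste0("v", rep(1:10, length.out = n))
  fit <- suppressMessages(
    fit_cluster_explainer(tibble::as_tibble(x), labels, vids, nfolds = 5,
                          seed = 4, nrounds = 40))
  rep_ <- shap_explain(fit, tibble::as_tibble(x[1:40, ]), background = 30,
                       n_perm = 6, seed = 1)
  expect_lt(shap_additivity_error(rep_), 1e-3)
  expect_setequal(utils::head(rep_$global$feature, 2), c("f2", "f5"))
  # seed determinism
  rep2 <- shap_explain(fit, tibble::as_tibble(x[1:40, ]), background = 30,
                       n_perm = 6, seed = 1)
  expect_identical(rep_$attributions, rep2$attributions)
})

test_that("SHAP reproduces the closed form of a linear model", {
  set.seed(23)
  n <- 200
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("g", 1:4)))
  x <- scale(x, scale = FALSE)  # zero-mean features
  lin <- function(m) 2 * m[, 1]
  rep_ <- shap_explain(lin, tibble::as_tibble(x), background = x,
                       n_perm = 4, seed = 2)
  phi <- rep_$attributions[, , 1]
  expect_equal(phi[, 1], 2 * x[, 1] - mean(2 * x[, 1]), tolerance = 1e-6)
  expect_lt(max(abs(phi[, 2:4])), 1e-6)
  # duplicated feature columns share credit roughly equally
  xd <- cbind(x, g5 = x[, 1])
  lin2 <- function(m) m[, 1] + m[, 5]
  repd <- shap_explain(lin2, tibble::as_tibble(xd), background = xd,
                       n_perm = 30, seed = 3)
  m1 <- repd$global$mean_abs_shap[repd$global$feature == "g1"]
  m5 <- repd$global$mean_abs_shap[repd$global$feature == "g5"]
  expect_lt(abs(m1 - m5) / max(m1, m5), 0.2)
})
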