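#' Directional Z-score against a control group
#'
#' For each observation X, the number of control-group standard
#' deviations above or below the control mean, multiplied by `direction`
#' so that larger scores always reflect more of the behavior of interest:
#' `z = direction * (X - mu_control) / sd_control`. The control SD uses
#' the sample convention (denominator n - 1).
#'
#' @param values Numeric vector of per-subject measurements.
#' @param control Logical mask of control subjects (or indices).
#' @param direction `+1` or `-1`.
#' @param measure Name used in error messages.
#' @return Numeric vector of z-scores, one per subject.
#' @export
directional_z <- function(values, control, direction = 1,
                          measure = "measure") {
  stopifnot(direction %in% c(-1, 1))
  ctrl <- values[control]
  if (length(ctrl) < 2) {
    stop("need at least two control subjects for '", measure, "'",
         call. = FALSE)
  }
  s <- stats::sd(ctrl)
  if (!is.finite(s) || s == 0) {
    stop("control group SD is zero for '", measure, "'", call. = FALSE)
  }
  direction * (values - mean(ctrl)) / s
}

#' Composite Z-score specification
#'
#' A set of (measure, direction) tests plus the control condition label.
#' Two presets mirror common use: `"physiology"` combines relative
#' adrenal weight and day-21 body weight (both `+1`), and
#' `"social_interaction"` combines the look-around, huddle, speed,
#' nose-to-tail and nose-to-body readouts of the focal animal, with
#' speed, nose-to-tail and nose-to-body flipped (`-1`) since stress
#' decreases them.
#'
#' @param tests Tibble/data frame with columns `measure` and `direction`.
#' @param control Condition label of the control group.
#' @return A `zscore_spec` object.
#' @export
zscore_spec <- function(tests, control = "control") {
  tests <- tibble::as_tibble(tests)
  stopifnot(all(c("measure", "direction") %in% names(tests)),
            all(tests$direction %in% c(-1, 1)))
  structure(list(tests = tests, control = control), class = "zscore_spec")
}

#' @rdname zscore_spec
#' @param preset `"physiology"` or `"social_interaction"`.
#' @export
zscore_preset <- function(preset = c("physiology", "social_interaction"),
                          control = "control") {
  preset <- match.arg(preset)
  tests <- switch(preset,
    physiology = tibble::tibble(
      measure = c("adrenal_weight_relative", "body_weight_day21"),
      direction = c(1, 1)),
    social_interaction = tibble::tibble(
      measure = c("look_around", "huddle", "speed", "nose_to_tail",
                  "nose_to_body"),
      direction = c(1, 1, -1, -1, -1)))
  zscore_spec(tests, control)
}

#' Composite Z-scores across a battery of tests
#'
#' Computes each test's directional z-score against the control group and
#' averages them per subject: `Z_total = sum(z_test_i) / n_tests`.
#'
#' @param data Tibble with one row per subject: a `condition` column plus
#'   one column per measure in the spec.
#' @param spec A [zscore_spec()].
#' @return A `zscore_report` tibble: the input identifiers, one `z_*`
#'   column per test, and `z_total`.
#' @export
composite_z <- function(data, spec) {
  missing <- setdiff(spec$tests$measure, names(data))
  if (length(missing) > 0) {
    stop("measures absent from data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ctrl <- data$condition == spec$control
  out <- data[intersect(c("subject", "video", "condition"), names(data))]
  zs <- matrix(0, nrow(data), nrow(spec$tests))
  for (i in seq_len(nrow(spec$tests))) {
    m <- spec$tests$measure[i]
    zs[, i] <- directional_z(data[[m]], ctrl, spec$tests$direction[i], m)
    out[[paste0("z_", m)]] <- zs[, i]
  }
  out$z_total <- rowMeans(zs)
  structure(out, class = c("zscore_report", class(tibble::tibble())))
}

#' Pearson correlation with linear-model outlier exclusion
#'
#' Ordinary Pearson correlation after excluding points whose residual
#' from the least-squares line exceeds `outlier_sd` residual standard
#' deviations.
#'
#' @param x,y Numeric vectors.
#' @param outlier_sd Exclusion threshold in residual SDs.
#' @return Tibble: `r`, `p`, `n_used`, `n_excluded`.
#' @export
pearson_correlation <- function(x, y, outlier_sd = 5) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant series; correlation undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  r <- stats::residuals(fit)
  ok <- abs(r) <= outlier_sd * stats::sd(r)
  if (sum(ok) < 3) stop("fewer than three points after outlier exclusion",
                        call. = FALSE)
  ct <- stats::cor.test(x[ok], y[ok])
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value,
                 n_used = sum(ok), n_excluded = sum(!ok))
}
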