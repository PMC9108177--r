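# Nomogram construction on top of a multivariate Cox fit, survival
# prediction from total points, and calibration curves.

#' Build a nomogram from a multivariate Cox fit
#'
#' Each covariate's contribution `beta * x` is rescaled to a 0-100 point
#' scale where 100 points correspond to the largest effect range
#' (`max_j |beta_j| * range_j`) over the observed covariate ranges. The
#' reference value of each covariate (0 points) is the end of its range
#' with the smallest sign-adjusted contribution, so points are always
#' non-negative. Predicted survival at time `t` is
#' `S0(t)^exp(lp)` with the Breslow baseline `S0`.
#'
#' @param fit A multivariate [cox_fit()] (all covariates numeric).
#' @param ranges Optional named list of `c(min, max)` per covariate;
#'   defaults to the observed ranges of the fitting data.
#' @return Object of class `nomogram_model` with the per-covariate point
#'   scale, the points-to-linear-predictor map and the baseline survival
#'   function.
#' @export
build_nomogram <- function(fit, ranges = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  beta <- stats::coef(fit$fit)
  covs <- names(beta)
  dat <- fit$data[, covs, drop = FALSE]
  if (is.null(ranges)) {
    ranges <- lapply(dat, range)
  }
  ranges <- ranges[covs]
  span <- map_dbl(ranges, function(r) diff(range(r)))
  if (any(span == 0)) {
    abort(sprintf("covariate '%s' has zero range", covs[span == 0][1]))
  }
  effect_range <- abs(beta) * span
  max_range <- max(effect_range)
  x_ref <- map_dbl(seq_along(covs), function(j) {
    r <- ranges[[j]]
    if (beta[j] > 0) min(r) else max(r)
  })
  names(x_ref) <- covs
  bh <- survival::basehaz(fit$fit, centered = FALSE)
  scale_tbl <- tibble(
    term = covs, beta = unname(beta), x_ref = unname(x_ref),
    x_min = map_dbl(ranges, min), x_max = map_dbl(ranges, max),
    max_points = unname(100 * effect_range / max_range)
  )
  structure(list(
    fit = fit, scale = scale_tbl, max_range = max_range,
    lp0 = sum(beta * x_ref),
    baseline = tibble(time = bh$time, s0 = exp(-bh$hazard))
  ), class = "nomogram_model")
}

#' @method tidy nomogram_model
#' @export
tidy.nomogram_model <- function(x, ...) x$scale

#' Points assigned to covariate values
#'
#' @param model A `nomogram_model`.
#' @param newdata Data frame of covariate values (columns named as in the
#'   fit).
#' @return Matrix of per-covariate points plus a `total` column.
#' @export
nomogram_points <- function(model, newdata) {
  sc <- model$scale
  pts <- vapply(seq_len(nrow(sc)), function(j) {
    100 * sc$beta[j] * (newdata[[sc$term[j]]] - sc$x_ref[j]) / model$max_range
  }, numeric(nrow(newdata)))
  pts <- matrix(pts, nrow = nrow(newdata),
                dimnames = list(NULL, sc$term))
  cbind(pts, total = rowSums(pts))
}

#' Predicted survival from a nomogram
#'
#' @param object A `nomogram_model`.
#' @param newdata Data frame of covariate values; defaults to the fitting
#'   data.
#' @param times Horizons (months) at which to evaluate survival.
#' @param ... Unused.
#' @return Matrix (samples x times) of predicted survival probabilities.
#' @method predict nomogram_model
#' @export
predict.nomogram_model <- function(object, newdata = NULL,
                                   times = c(12, 36, 60), ...) {
  if (is.null(newdata)) newdata <- object$fit$data
  pts <- nomogram_points(object, newdata)
  lp <- object$lp0 + pts[, "total"] * object$max_range / 100
  s0 <- km_step(object$baseline$time, object$baseline$s0, times)
  out <- vapply(seq_along(times), function(j) s0[j]^exp(lp), numeric(length(lp)))
  out <- matrix(out, nrow = length(lp), dimnames = list(NULL, as.character(times)))
  out
}

#' @method autoplot nomogram_model
#' @export
autoplot.nomogram_model <- function(object, ...) {
  sc <- object$scale
  df <- bind_rows(map(seq_len(nrow(sc)), function(j) {
    tibble(term = sc$term[j],
           points = c(0, sc$max_points[j]),
           value = if (sc$beta[j] > 0) c(sc$x_min[j], sc$x_max[j])
                   else c(sc$x_max[j], sc$x_min[j]))
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$points, .data$term)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$value, 3)),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "points", y = NULL) +
    ggplot2::theme_minimal()
}

#' Calibration of predicted survival probabilities
#'
#' Samples are binned by predicted survival at the horizon; each bin's
#' observed survival is its Kaplan-Meier estimate at the horizon, with
#' optional bootstrap percentile intervals.
#'
#' @param predicted Numeric vector of predicted survival probabilities in
#'   (0, 1), aligned with `clinical` rows or named by sample id.
#' @param clinical Clinical tibble.
#' @param time Horizon in months.
#' @param n_bins Number of equal-count bins (default 3).
#' @param bootstrap Bootstrap replicates for the CI (default 200; 0
#'   disables).
#' @param seed Seed for the bootstrap.
#' @return Tibble per bin: `bin`, `n`, `mean_pred`, `observed`, `ci_low`,
#'   `ci_high`.
#' @export
calibration_curve <- function(predicted, clinical, time, n_bins = 3,
                              bootstrap = 200, seed = 1L) {
  clinical <- validate_clinical(clinical)
  if (!is.null(names(predicted))) predicted <- predicted[clinical$sample_id]
  if (any(predicted <= 0 | predicted >= 1)) {
    abort("predictions must lie strictly in (0, 1)")
  }
  qs <- quantile(predicted, probs = seq(0, 1, length.out = n_bins + 1))
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  qs <- unique(qs) # constant or heavily tied predictions collapse bins
  bin <- cut(predicted, qs, labels = FALSE)
  # renumber so only occupied bins remain (ties can empty a quantile bin)
  bin <- match(bin, sort(unique(bin)))
  n_bins <- max(bin)
  km_at <- function(tt, ee) {
    sf <- survival::survfit(survival::Surv(tt, ee) ~ 1)
    km_step(sf$time, sf$surv, time)
  }
  with_preserved_seed(seed, function() {
    bind_rows(map(seq_len(n_bins), function(b) {
      idx <- which(bin == b)
      if (!length(idx)) {
        return(tibble(bin = b, n = 0L, mean_pred = NA_real_,
                      observed = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
      }
      obs <- km_at(clinical$time[idx], clinical$event[idx])
      ci <- c(NA_real_, NA_real_)
      if (bootstrap > 0 && length(idx) > 1) {
        boots <- map_dbl(seq_len(bootstrap), function(r) {
          take <- sample(idx, length(idx), replace = TRUE)
          km_at(clinical$time[take], clinical$event[take])
        })
        ci <- unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE))
      }
      tibble(bin = b, n = length(idx), mean_pred = mean(predicted[idx]),
             observed = obs, ci_low = ci[1], ci_high = ci[2])
    }))
  })
}

#' Plot a calibration curve
#'
#' @param calib Tibble from [calibration_curve()].
#' @return A ggplot object.
#' @export
plot_calibration <- function(calib) {
  ggplot2::ggplot(calib, ggplot2::aes(.data$mean_pred, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.01) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "predicted survival", y = "observed survival (KM)") +
    ggplot2::theme_minimal()
}
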