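# Cox models, Kaplan-Meier estimates, log-rank tests, Harrell's C and
# time-dependent ROC/AUC. Model fitting is delegated to the survival
# package; this layer standardizes inputs, validation and tidy outputs.

align_covariates <- function(clinical, covariates) {
  if (is.matrix(covariates)) covariates <- as.data.frame(covariates)
  covariates <- as.data.frame(covariates)
  if (!is.null(rownames(covariates)) &&
      all(clinical$sample_id %in% rownames(covariates))) {
    covariates <- covariates[clinical$sample_id, , drop = FALSE]
  } else if (nrow(covariates) != nrow(clinical)) {
    abort("covariates must have rownames matching sample_id or align row-wise")
  }
  covariates
}

#' Fit a Cox proportional-hazards model
#'
#' Wraps `survival::coxph` (Efron tie handling by default) with the
#' pipeline's conventions: the short-survivor exclusion is applied, rows
#' with missing covariates are dropped case-wise with a logged count,
#' constant covariates and monotone-likelihood fits are errors, and the
#' result carries a tidy per-covariate table with Wald intervals.
#'
#' @param clinical Clinical tibble (`sample_id`, `time`, `event`).
#' @param covariates Data frame or matrix of covariates (one row per
#'   sample, aligned by rownames or row order).
#' @param ties Tie handling, `"efron"` (default) or `"breslow"`.
#' @return Object of class `cox_fit`; see [tidy()] and [glance()].
#' @export
cox_fit <- function(clinical, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  clinical <- apply_exclusions(clinical)
  covariates <- align_covariates(clinical, covariates)
  keep <- complete.cases(covariates)
  if (any(!keep)) {
    inform(sprintf("dropping %d sample(s) with missing covariates", sum(!keep)))
    clinical <- clinical[keep, ]; covariates <- covariates[keep, , drop = FALSE]
  }
  if (sum(clinical$event) < 1) abort("need at least one event")
  num <- vapply(covariates, is.numeric, logical(1))
  const <- vapply(seq_along(covariates), function(j) {
    length(unique(covariates[[j]])) < 2L
  }, logical(1))
  if (any(const)) {
    abort(sprintf("covariate '%s' is constant: no information",
                  names(covariates)[const][1]))
  }
  df <- cbind(data.frame(.time = clinical$time, .event = clinical$event),
              covariates)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = df, ties = ties,
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w))) {
        abort(paste("Cox fit failed:", conditionMessage(w)))
      }
      invokeRestart("muffleWarning")
    }
  )
  if (anyNA(stats::coef(fit)) || any(abs(stats::coef(fit)) > 20)) {
    abort(sprintf("monotone likelihood (perfect separation) on covariate '%s'",
                  names(stats::coef(fit))[which.max(abs(stats::coef(fit)))]))
  }
  sm <- summary(fit)
  table <- tibble(
    term = rownames(sm$coefficients),
    beta = sm$coefficients[, "coef"],
    hr = sm$conf.int[, "exp(coef)"],
    ci_low = sm$conf.int[, "lower .95"],
    ci_high = sm$conf.int[, "upper .95"],
    se = sm$coefficients[, "se(coef)"],
    z = sm$coefficients[, "z"],
    p_value = sm$coefficients[, "Pr(>|z|)"]
  )
  structure(list(fit = fit, table = table,
                 loglik = fit$loglik[2], n = fit$n, n_events = fit$nevent,
                 ties = ties, data = df), class = "cox_fit")
}

#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, ...) x$table

#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, loglik = x$loglik,
         concordance = unname(x$fit$concordance["concordance"]), ties = x$ties)
}

#' @method print cox_fit
#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties): n = %d, events = %d\n", x$ties, x$n, x$n_events))
  print(x$table)
  invisible(x)
}

#' @method autoplot cox_fit
#' @export
autoplot.cox_fit <- function(object, ...) {
  df <- object$table
  ggplot2::ggplot(df, ggplot2::aes(.data$hr, .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with Greenwood standard errors, optionally per
#' group.
#'
#' @param clinical Clinical tibble.
#' @param group Optional grouping vector aligned with `clinical` rows (or
#'   named by sample id).
#' @return Tibble with `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`, `std_err`; the underlying `survfit` object is attached as the
#'   `"survfit"` attribute.
#' @export
km_estimate <- function(clinical, group = NULL) {
  clinical <- validate_clinical(clinical)
  if (nrow(clinical) < 1) abort("need at least one subject")
  if (is.null(group)) {
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = clinical)
    grp <- rep("all", length(sf$time))
  } else {
    if (!is.null(names(group))) group <- group[clinical$sample_id]
    clinical$.group <- group
    sf <- survival::survfit(survival::Surv(time, event) ~ .group, data = clinical)
    grp <- rep(sub("^\\.group=", "", names(sf$strata)), sf$strata)
  }
  out <- tibble(group = grp, time = sf$time, n_risk = sf$n.risk,
                n_event = sf$n.event, n_censor = sf$n.censor,
                surv = sf$surv, std_err = sf$std.err * sf$surv)
  attr(out, "survfit") <- sf
  out
}

#' Plot Kaplan-Meier curves
#'
#' @param km Tibble from [km_estimate()].
#' @return A ggplot object.
#' @export
plot_km <- function(km) {
  ggplot2::ggplot(km, ggplot2::aes(.data$time, .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability") +
    ggplot2::theme_minimal()
}

# Evaluate a right-continuous KM step function at arbitrary times.
# left = TRUE gives the left limit S(t-).
km_step <- function(times, surv, t, left = FALSE) {
  map_dbl(t, function(tt) {
    if (left) {
      i <- sum(times < tt - 1e-12)
    } else {
      i <- sum(times <= tt + 1e-12)
    }
    if (i == 0) 1 else surv[i]
  })
}

#' Log-rank test
#'
#' Standard observed-minus-expected statistic over pooled event times,
#' with the k-group generalization (`df = k - 1`).
#'
#' @param clinical Clinical tibble.
#' @param group Grouping vector aligned with `clinical` rows (or named by
#'   sample id), defining >= 2 non-empty groups.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(clinical, group) {
  clinical <- validate_clinical(clinical)
  if (!is.null(names(group))) group <- group[clinical$sample_id]
  if (anyNA(group)) abort("group has missing values")
  g <- factor(group)
  if (nlevels(g) < 2) abort("need at least two non-empty groups")
  clinical$.group <- g
  sd <- survival::survdiff(survival::Surv(time, event) ~ .group, data = clinical)
  df <- nlevels(g) - 1L
  tibble(statistic = sd$chisq, df = df,
         p_value = pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Harrell's concordance index
#'
#' Fraction of usable (orderable under right censoring) sample pairs in
#' which the higher-risk score belongs to the sample that fails first;
#' score ties contribute `tie_policy` (default 0.5). Higher score must
#' mean higher predicted risk.
#'
#' @param scores Numeric risk scores aligned with `clinical` rows (or
#'   named by sample id).
#' @param clinical Clinical tibble.
#' @param tie_policy Credit for score-tied usable pairs (default 0.5).
#' @return Tibble with `c_index`, `se`, `ci_low`, `ci_high`, `n_pairs`.
#' @export
harrell_c <- function(scores, clinical, tie_policy = 0.5) {
  clinical <- validate_clinical(clinical)
  if (!is.null(names(scores))) scores <- scores[clinical$sample_id]
  cc <- survival::concordance(
    survival::Surv(clinical$time, clinical$event) ~ scores, reverse = TRUE)
  cnt <- cc$count
  usable <- cnt[["concordant"]] + cnt[["discordant"]] + cnt[["tied.x"]]
  if (usable == 0) abort("no usable pairs under censoring")
  c_index <- (cnt[["concordant"]] + tie_policy * cnt[["tied.x"]]) / usable
  se <- sqrt(cc$var)
  tibble(c_index = c_index, se = se,
         ci_low = pmax(0, c_index - qnorm(0.975) * se),
         ci_high = pmin(1, c_index + qnorm(0.975) * se),
         n_pairs = unname(usable))
}

#' Time-dependent ROC and AUC under censoring
#'
#' Cumulative-case / dynamic-control estimator: at horizon `t`, cases are
#' subjects with an observed event by `t` and controls are subjects still
#' at risk beyond `t`. Inverse-probability-of-censoring weights from the
#' Kaplan-Meier estimate of the censoring distribution make the estimator
#' consistent under independent censoring; the AUC integrates the
#' weighted ROC curve over all score thresholds by the trapezoidal rule.
#' Without censoring it reduces exactly to the rank-sum AUC.
#'
#' @param scores Risk scores (higher = higher risk), aligned with
#'   `clinical` rows or named by sample id.
#' @param clinical Clinical tibble.
#' @param times Evaluation horizons in months (default 12, 36, 60).
#' @return Tibble with `time`, `auc`, `n_cases`, `n_controls`; `auc` is
#'   `NA` when a horizon has no cases or no controls.
#' @export
time_dependent_auc <- function(scores, clinical, times = c(12, 36, 60)) {
  clinical <- validate_clinical(clinical)
  if (!is.null(names(scores))) scores <- scores[clinical$sample_id]
  if (anyNA(scores)) abort("scores have missing values")
  cens_fit <- survival::survfit(
    survival::Surv(time, 1 - event) ~ 1, data = clinical)
  G_times <- cens_fit$time; G_surv <- cens_fit$surv

  bind_rows(map(times, function(t0) {
    is_case <- clinical$time <= t0 & clinical$event == 1
    is_ctrl <- clinical$time > t0
    if (!any(is_case) || !any(is_ctrl)) {
      return(tibble(time = t0, auc = NA_real_,
                    n_cases = sum(is_case), n_controls = sum(is_ctrl)))
    }
    w_case <- 1 / km_step(G_times, G_surv, clinical$time[is_case], left = TRUE)
    w_ctrl <- rep(1 / km_step(G_times, G_surv, t0), sum(is_ctrl))
    s_case <- scores[is_case]; s_ctrl <- scores[is_ctrl]
    thr <- sort(unique(scores), decreasing = TRUE)
    sens <- map_dbl(thr, function(cc) sum(w_case[s_case >= cc])) / sum(w_case)
    fpr <- map_dbl(thr, function(cc) sum(w_ctrl[s_ctrl >= cc])) / sum(w_ctrl)
    xs <- c(0, fpr, 1); ys <- c(0, sens, 1)
    auc <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
    tibble(time = t0, auc = auc,
           n_cases = sum(is_case), n_controls = sum(is_ctrl))
  }))
}
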