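# Cox fits, Kaplan-Meier, log-rank, concordance and time-dependent AUC.

test_that("degenerate covariates are rejected", {
  clin <- make_clinical(30, seed = 1, censor = 60)
  expect_error(cox_fit(clin, data.frame(flat = rep(1, 30))), "constant")
})

test_that("cox_fit recovers a true hazard ratio of 2", {
  withr::with_seed(55, {
    n <- 2000
    grp <- rbinom(n, 1, 0.5)
    clin <- make_clinical(n, lp = log(2) * grp, censor = 110)
  })
  expect_lt(mean(clin$event == 0), 0.3)
  fit <- cox_fit(clin, data.frame(group = grp))
  expect_lt(abs(tidy(fit)$beta - log(2)), 0.1)
  expect_gt(tidy(fit)$hr, 1)
})

test_that("cox_fit is unbiased under the null", {
  betas <- vapply(1:300, function(i) {
    withr::with_seed(6000 + i, {
      n <- 100
      grp <- rep(0:1, each = n / 2)
      clin <- make_clinical(n)
    })
    tidy(cox_fit(clin, data.frame(group = grp)))$beta
  }, numeric(1))
  expect_lt(abs(mean(betas)), 0.05)
})

test_that("cox_fit matches an independent Breslow Newton-Raphson when untied", {
  # independent single-covariate partial-likelihood maximizer (Breslow)
  breslow_beta <- function(time, event, x) {
    beta <- 0
    ord <- order(time)
    time <- time[ord]; event <- event[ord]; x <- x[ord]
    for (it in 1:50) {
      eta <- exp(beta * x)
      U <- 0; I <- 0
      for (i in which(event == 1)) {
        risk <- time >= time[i]
        s0 <- sum(eta[risk])
        s1 <- sum(eta[risk] * x[risk])
        s2 <- sum(eta[risk] * x[risk]^2)
        U <- U + x[i] - s1 / s0
        I <- I + s2 / s0 - (s1 / s0)^2
      }
      step <- U / I
      beta <- beta + step
      if (abs(step) < 1e-10) break
    }
    beta
  }
  withr::with_seed(77, {
    n <- 120
    x <- rnorm(n)
    t_ev <- rexp(n, exp(0.6 * x) / 24) + 1 # continuous, no ties
    t_c <- runif(n, 1, 100)
    clin <- tibble::tibble(sample_id = sprintf("p%03d", 1:n),
                           time = pmin(t_ev, t_c),
                           event = as.integer(t_ev <= t_c))
  })
  stopifnot(!anyDuplicated(clin$time[clin$event == 1]))
  fit <- cox_fit(clin, data.frame(x = x), ties = "breslow")
  expect_equal(tidy(fit)$beta, breslow_beta(clin$time, clin$event, x),
               tolerance = 1e-6)
})

test_that("cox_fit CI coverage is close to nominal", {
  hits <- vapply(1:500, function(i) {
    withr::with_seed(9000 + i, {
      n <- 120
      grp <- rep(0:1, each = n / 2)
      clin <- make_clinical(n, lp = log(2) * grp, censor = 110)
    })
    tab <- tidy(cox_fit(clin, data.frame(group = grp)))
    tab$ci_low <= 2 && 2 <= tab$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.92)
  expect_lte(mean(hits), 0.98)
})

test_that("km_estimate matches the hand product-limit computation", {
  clin <- tibble::tibble(sample_id = c("a", "b", "c"),
                         time = c(1, 1.5, 2), event = c(1, 0, 1))
  km <- km_estimate(clin)
  expect_equal(km$surv[km$time == 1], 2 / 3)
  expect_equal(km$surv[km$time == 2], 0) # 2/3 * (1 - 1/1)

  none <- km_estimate(tibble::tibble(sample_id = c("x", "y"),
                                     time = c(5, 9), event = c(0, 0)))
  expect_true(all(none$surv == 1))

  clin2 <- make_clinical(150, seed = 8, censor = 60)
  km2 <- km_estimate(clin2)
  expect_true(all(diff(km2$surv) <= 1e-12))
  orc <- oracle_km(clin2$time, clin2$event)
  expect_equal(km2$surv[km2$n_event > 0], orc$surv, tolerance = 1e-12)
})

test_that("log-rank behaves as its O-E tabulation and is label-symmetric", {
  clin <- make_clinical(80, seed = 12, censor = 60)
  # duplicated data in both groups: statistic exactly 0
  dup <- dplyr::bind_rows(clin, dplyr::mutate(clin, sample_id = paste0(sample_id, "_b")))
  grp <- rep(c("g1", "g2"), each = 80)
  expect_equal(logrank_test(dup, grp)$statistic, 0, tolerance = 1e-12)

  # hand-tabulated toy
  toy <- tibble::tibble(sample_id = sprintf("t%d", 1:6),
                        time = c(2, 4, 5, 7, 9, 12),
                        event = c(1, 1, 0, 1, 1, 0))
  g <- c("a", "b", "a", "b", "a", "b")
  z <- oracle_logrank_z(toy$time, toy$event, g == "a")
  lr <- logrank_test(toy, g)
  expect_equal(lr$statistic, z^2, tolerance = 1e-10)
  expect_equal(lr$df, 1L)
  # swapping labels leaves the statistic unchanged
  swapped <- logrank_test(toy, ifelse(g == "a", "b", "a"))
  expect_equal(swapped$statistic, lr$statistic)
})

test_that("harrell_c matches pair enumeration and its null is 0.5", {
  clin <- make_clinical(150, seed = 31, censor = 60)
  withr::with_seed(32, scores <- rnorm(150))
  mine <- harrell_c(scores, clin)
  expect_equal(mine$c_index,
               oracle_harrell(scores, clin$time, clin$event), tolerance = 1e-12)

  # perfect risk ranking without censoring
  clin_nc <- make_clinical(50, seed = 33)
  perfect <- rank(-clin_nc$time) # earliest death = highest risk
  expect_equal(harrell_c(perfect, clin_nc)$c_index, 1)

  cs <- vapply(1:300, function(i) {
    withr::with_seed(7000 + i, {
      clin_i <- make_clinical(100, censor = 70)
      s <- rnorm(100)
    })
    harrell_c(s, clin_i)$c_index
  }, numeric(1))
  expect_lt(abs(mean(cs) - 0.5), 0.02)
})

test_that("time-dependent AUC reduces to the rank-sum AUC without censoring", {
  clin <- make_clinical(120, seed = 41)
  withr::with_seed(42, scores <- clin$time * -0.1 + rnorm(120))
  for (t0 in c(12, 24)) {
    mine <- time_dependent_auc(scores, clin, times = t0)$auc
    cases <- scores[clin$time <= t0 & clin$event == 1]
    controls <- scores[clin$time > t0]
    expect_equal(mine, ranksum_auc(cases, controls), tolerance = 1e-10)
  }
})

test_that("time-dependent AUC is near 0.5 for uninformative scores", {
  withr::with_seed(51, {
    clin <- make_clinical(500, censor = 70)
    scores <- rnorm(500)
  })
  auc <- time_dependent_auc(scores, clin, times = c(12, 24))$auc
  expect_true(all(abs(auc - 0.5) < 0.05))
})

test_that("AUC is invariant under monotone score transforms and flags empty strata", {
  clin <- make_clinical(100, seed = 61, censor = 60)
  withr::with_seed(62, scores <- rnorm(100))
  a <- time_dependent_auc(scores, clin, times = 12)
  b <- time_dependent_auc(exp(scores * 2) + 3, clin, times = 12)
  expect_equal(a$auc, b$auc, tolerance = 1e-12)
  # horizon beyond follow-up: no controls -> NA
  far <- time_dependent_auc(scores, clin, times = max(clin$time) + 1)
  expect_true(is.na(far$auc))
})
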