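mk_clinical <- function(time, event, ids = sprintf("S%02d", seq_along(time))) {
  data.frame(sample_id = ids, time = time, event = as.integer(event),
             stringsAsFactors = FALSE)
}

test_that("km_curve matches the hand product-limit table and trivia", {
  # times 2(e) 4(c) 6(e) 6(e) 8(c) 10(e):
  #   S(2) = 5/6; S(6) = 5/6 * 2/4 = 5/12; S(10) = 0
  cl <- mk_clinical(c(2, 4, 6, 6, 8, 10), c(1, 0, 1, 1, 0, 1))
  km <- km_curve(cl)
  expect_equal(km$time, c(0, 2, 6, 10))
  expect_equal(km$survival, c(1, 5 / 6, 5 / 12, 0), tolerance = 1e-12)
  expect_equal(km$n_risk, c(6, 6, 4, 1))
  expect_true(all(diff(km$survival) <= 0))

  # no events -> flat at 1
  cl0 <- mk_clinical(c(5, 8, 12), c(0, 0, 0))
  expect_equal(km_curve(cl0)$survival, 1)

  # single event among n: drop to (n-1)/n
  cl1 <- mk_clinical(c(3, 6, 9, 12), c(1, 0, 0, 0))
  expect_equal(km_curve(cl1)$survival, c(1, 3 / 4))
})

test_that("km_curve agrees with survival::survfit on a random fixture", {
  skip_if_not_installed("survival")
  set.seed(8)
  cl <- mk_clinical(round(rexp(40, 0.02), 1), rbinom(40, 1, 0.7))
  km <- km_curve(cl)
  sf <- survival::survfit(survival::Surv(cl$time, cl$event) ~ 1)
  at_events <- sf$n.event > 0
  expect_equal(km$survival[-1], sf$surv[at_events], tolerance = 1e-12)
})

test_that("logrank matches survdiff, including tied event times", {
  skip_if_not_installed("survival")
  # 12-sample toy with ties
  time <- c(2, 2, 3, 5, 5, 7, 8, 8, 9, 11, 12, 12)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0, 1, 0)
  group <- c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0)
  lr <- logrank_test(time, event, group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  expect_equal(lr$chisq, sd$chisq, tolerance = 1e-10)
  expect_equal(lr$p, 1 - pchisq(sd$chisq, 1), tolerance = 1e-10)
  expect_equal(lr$observed, sd$obs[2])
  expect_equal(lr$expected, sd$exp[2])
})

test_that("cox fit equals survival::coxph (Breslow) on toys", {
  skip_if_not_installed("survival")
  set.seed(12)
  for (i in 1:5) {
    n <- 60
    x <- setNames(rnorm(n), sprintf("S%02d", 1:n))
    t0 <- rexp(n, 0.02 * exp(0.5 * x))
    cens <- runif(n, 0, 100)
    cl <- mk_clinical(pmin(t0, cens), t0 <= cens, names(x))
    fit <- fit_cox_univariate(x, cl)
    or <- survival::coxph(survival::Surv(cl$time, cl$event) ~ x,
                          ties = "breslow")
    expect_equal(fit$log_hr, unname(coef(or)), tolerance = 1e-7)
    expect_equal(fit$se, unname(sqrt(vcov(or)[1, 1])), tolerance = 1e-7)
  }
})

test_that("cox null and degenerate behavior", {
  # identical survival in both groups: hr ~ 1, logrank ~ 0
  time <- rep(c(3, 6, 9, 12), 2)
  event <- rep(c(1, 1, 0, 1), 2)
  x <- setNames(rep(c(0, 1), each = 4), sprintf("S%d", 1:8))
  cl <- mk_clinical(time, event, names(x))
  fit <- fit_cox_univariate(x, cl)
  expect_equal(fit$hr, 1, tolerance = 1e-6)
  expect_equal(fit$logrank_p, 1, tolerance = 1e-6)

  expect_error(fit_cox_univariate(x, mk_clinical(time, rep(0, 8), names(x))),
               "events")
  # complete separation -> boundary flag
  xs <- setNames(c(1, 1, 1, 1, 0, 0, 0, 0), names(x))
  cls <- mk_clinical(c(1, 2, 3, 4, 50, 60, 70, 80), rep(1, 8), names(xs))
  fit2 <- suppressWarnings(fit_cox_univariate(xs, cls))
  expect_true(fit2$boundary)
  expect_lte(abs(fit2$log_hr), 15)
})

test_that("cox recovers a planted log hazard within 3 SE (20 seeds)", {
  devs <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_config(
      n_samples_per_subtype = c(TN = 134, HER2p = 133, luminal = 133),
      n_probes = 60, n_planted_tn = 0, n_planted_luminal_only = 0,
      effect_delta = 0.2, noise_sd = 0.05, n_prognostic = 1,
      hazard_log_hr = 0.7, censor_rate = 0.3, seed = 6000 + s,
      n_background_genes = 0))
    b <- co$betas[co$truth$prognostic_probes, ]
    x <- setNames(as.numeric(b > median(b)), names(b))
    fit <- fit_cox_univariate(x, co$clinical)
    (fit$log_hr - 0.7) / fit$se
  }, numeric(1))
  expect_true(all(abs(devs) <= 3))
  expect_lt(abs(mean(devs)), 1)       # centered: no systematic bias
})

test_that("site_directions assigns favorable states and skips flat sites", {
  co <- generate_cohort(cohort_config(
    n_samples_per_subtype = c(TN = 134, HER2p = 133, luminal = 133),
    n_probes = 100, n_planted_tn = 0, n_planted_luminal_only = 0,
    effect_delta = 0.2, noise_sd = 0.05, n_prognostic = 20,
    hazard_log_hr = 1.0, censor_rate = 0.3, seed = 41,
    n_background_genes = 0))
  dirs <- site_directions(co$betas[co$truth$prognostic_probes, ],
                          co$clinical, alpha = 0.01)
  # unfavorable state is high methylation for every planted site
  expect_gte(mean(dirs$favorable_state == "low"), 0.9)
  expect_gte(mean(dirs$significant), 0.8)

  # forced example: high-beta group with hr > 1 -> favorable low
  expect_identical(dirs$favorable_state[which.max(dirs$hr)], "low")

  # flat site skipped
  b2 <- co$betas[co$truth$prognostic_probes[1:3], ]
  b2[1, ] <- 0.5
  dirs2 <- site_directions(b2, co$clinical)
  expect_identical(attr(dirs2, "skipped"), rownames(b2)[1])
  expect_equal(nrow(dirs2), 2)
})

test_that("prognostic_scores is the mean favorable indicator per sample", {
  # 4 sites, 4 samples, hand-checkable states
  b <- rbind(s1 = c(0.1, 0.2, 0.8, 0.9),
             s2 = c(0.9, 0.8, 0.2, 0.1),
             s3 = c(0.1, 0.9, 0.2, 0.8),
             s4 = c(0.2, 0.1, 0.9, 0.8))
  colnames(b) <- sprintf("P%d", 1:4)
  dirs <- data.frame(probe_id = rownames(b),
                     favorable_state = c("low", "high", "low", "low"),
                     hr = c(2, 0.5, 2, 2), log_hr = log(c(2, .5, 2, 2)),
                     p = rep(0.001, 4), significant = TRUE, tie = FALSE)
  sc <- prognostic_scores(b, dirs)
  # medians: s1 .5, s2 .5, s3 .5, s4 .5; favorable hits per sample:
  # P1: s1 low(yes) s2 high(yes... s2 value .9>med -> state high, fav high -> 1)
  expect_equal(sc$score, c(1, 0.75, 0.25, 0), tolerance = 1e-12)
  expect_equal(sc$n_sites_used, rep(4, 4))
  # invariance to site order
  sc2 <- prognostic_scores(b[c(3, 1, 4, 2), ], dirs[c(3, 1, 4, 2), ])
  expect_equal(sc2$score, sc$score)
  # perfect favorable sample
  b2 <- b; b2[, 1] <- c(0.05, 0.95, 0.05, 0.05)
  expect_equal(prognostic_scores(b2, dirs)$score[1], 1)
  expect_error(prognostic_scores(b, dirs[dirs$hr > 10, ]), "no sites")
})

test_that("stratify_and_test separates planted risk groups and handles nulls", {
  co <- generate_cohort(cohort_config(
    n_samples_per_subtype = c(TN = 134, HER2p = 133, luminal = 133),
    n_probes = 100, n_planted_tn = 0, n_planted_luminal_only = 0,
    effect_delta = 0.2, noise_sd = 0.05, n_prognostic = 20,
    hazard_log_hr = 1.0, censor_rate = 0.3, seed = 43,
    n_background_genes = 0))
  dirs <- site_directions(co$betas[co$truth$prognostic_probes, ],
                          co$clinical, alpha = 0.01)
  sc <- prognostic_scores(co$betas[co$truth$prognostic_probes, ], dirs)
  st <- stratify_and_test(sc, co$clinical)
  expect_lt(st$logrank_p, 0.01)
  expect_gt(st$hr, 1)      # low-score group carries the excess hazard
  expect_equal(sort(unique(as.character(st$groups))), c("high", "low"))

  # two samples -> one per group
  sc2 <- data.frame(sample_id = co$clinical$sample_id[1:2],
                    score = c(0.2, 0.8), n_sites_used = 2)
  st2 <- suppressWarnings(stratify_and_test(sc2, co$clinical[1:2, ]))
  expect_equal(as.vector(table(st2$groups)), c(1, 1))
  expect_error(stratify_and_test(
    data.frame(sample_id = co$clinical$sample_id[1:4], score = rep(0.5, 4)),
    co$clinical), "constant")
})

test_that("null stratification p-values are not anti-conservative", {
  ps <- vapply(1:30, function(s) {
    set.seed(3000 + s)
    n <- 60
    ids <- sprintf("S%02d", 1:n)
    cl <- mk_clinical(rexp(n, 0.02), rbinom(n, 1, 0.7), ids)
    sc <- data.frame(sample_id = ids, score = runif(n), n_sites_used = 10)
    stratify_and_test(sc, cl)$logrank_p
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps), 0.25)
})
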