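pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(s2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}

test_that("moderated t with d0 = 0 equals the ordinary pooled t", {
  b <- toy_betas(20, 6, seed = 8)
  ga <- colnames(b)[1:3]; gb <- colnames(b)[4:6]
  res <- moderated_t_test(b, ga, gb, prior_df = 0)
  for (i in c(1, 7, 20)) {
    or <- pooled_t_oracle(b[i, ga], b[i, gb])
    expect_equal(res$t_mod[i], or$t, tolerance = 1e-12)
    expect_equal(res$p[i], or$p, tolerance = 1e-12)
  }
  expect_equal(res$df_total, rep(4, 20) * 1)
})

test_that("moderated t with d0 = Inf uses the prior variance alone", {
  b <- toy_betas(50, 8, seed = 9)
  ga <- colnames(b)[1:4]; gb <- colnames(b)[5:8]
  res <- moderated_t_test(b, ga, gb, prior_df = Inf)
  s0_2 <- attr(res, "s0_2")
  expected <- res$delta_beta / sqrt(s0_2 * (1 / 4 + 1 / 4))
  expect_equal(res$t_mod, expected, tolerance = 1e-12)
})

test_that("estimated prior tracks limma's eBayes on a common fixture", {
  skip_if_not_installed("limma")
  co <- small_cohort(seed = 17, n_probes = 1000)
  lab <- co$labels
  ga <- names(lab)[lab == "luminal"]; gb <- names(lab)[lab == "TN"]
  res <- moderated_t_test(co$betas, ga, gb)
  design <- cbind(1, c(rep(1, length(ga)), rep(0, length(gb))))
  fit <- limma::eBayes(limma::lmFit(co$betas[, c(ga, gb)], design))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 0.05)
  expect_equal(attr(res, "s0_2"), fit$s2.prior, tolerance = 0.02)
  expect_equal(res$t_mod, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("identical group means give t = 0, p = 1", {
  b <- toy_betas(5, 3, seed = 2)
  b2 <- cbind(b, b + 0)
  colnames(b2) <- sprintf("S%02d", 1:6)
  res <- moderated_t_test(b2, colnames(b2)[1:3], colnames(b2)[4:6])
  expect_equal(res$t_mod, rep(0, 5))
  expect_equal(res$p, rep(1, 5))
})

test_that("zero-variance probes are handled without division by zero", {
  set.seed(3)
  b <- matrix(0.5 + rnorm(60, 0, 0.02), 10, 6,
              dimnames = list(sprintf("cg%02d", 1:10), sprintf("S%d", 1:6)))
  b[1, ] <- 0.5
  b[2, 1:3] <- 0.2; b[2, 4:6] <- 0.8     # zero variance, nonzero delta
  res <- moderated_t_test(b, colnames(b)[1:3], colnames(b)[4:6])
  expect_true(all(is.finite(res$t_mod)))
  expect_equal(res$t_mod[1], 0)
  expect_gt(abs(res$t_mod[2]), 10)
})

test_that("groups must be disjoint and large enough", {
  b <- toy_betas(4, 4)
  expect_error(moderated_t_test(b, colnames(b)[1:2], colnames(b)[2:3]),
               "disjoint")
  expect_error(moderated_t_test(b, colnames(b)[1], colnames(b)[2:3]), ">= 2")
})

test_that("bh_adjust matches the hand example and the brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.4), 0.4)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(123)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("derive_signature applies the intersection and concordance rules", {
  mk <- function(ids, p_adj, dir) {
    data.frame(probe_id = ids, delta_beta = ifelse(dir == "hyper", .1, -.1),
               s2 = .01, t_mod = 1, df_total = 10, p = p_adj, p_adj = p_adj,
               direction = dir, stringsAsFactors = FALSE)
  }
  ids <- c("x", "y", "z", "w")
  a <- mk(ids, c(0.001, 0.001, 0.001, 0.5), c("hyper", "hypo", "hyper", "hyper"))
  b <- mk(ids, c(0.001, 0.5, 0.001, 0.001), c("hyper", "hypo", "hypo", "hyper"))
  sig <- derive_signature(a, b, alpha = 0.01)
  expect_identical(sig$hyper_cpgs, "x")       # z discordant, y not sig in b
  expect_length(sig$hypo_cpgs, 0)
  expect_length(derive_signature(a, b, alpha = 0)$probes$probe_id, 0)
  expect_error(derive_signature(a, b[1:3, ], 0.01), "universe")
})

test_that("derive_signature is monotone in alpha", {
  co <- small_cohort(seed = 19)
  lab <- co$labels
  lum <- moderated_t_test(co$betas, names(lab)[lab == "luminal"],
                          names(lab)[lab == "TN"])
  her <- moderated_t_test(co$betas, names(lab)[lab == "HER2p"],
                          names(lab)[lab == "TN"])
  alphas <- c(1e-6, 1e-4, 0.01, 0.05, 0.2)
  sigs <- lapply(alphas, function(a) derive_signature(lum, her, a)$probes$probe_id)
  for (i in seq_len(length(alphas) - 1)) {
    expect_true(all(sigs[[i]] %in% sigs[[i + 1]]))
  }
})

test_that("signature recovers planted TN sites and excludes luminal-only sites", {
  co <- small_cohort(seed = 23)
  lab <- co$labels
  lum <- moderated_t_test(co$betas, names(lab)[lab == "luminal"],
                          names(lab)[lab == "TN"])
  her <- moderated_t_test(co$betas, names(lab)[lab == "HER2p"],
                          names(lab)[lab == "TN"])
  sig <- derive_signature(lum, her, 0.01, co$annotation)
  sens <- mean(co$truth$tn_probes %in% sig$probes$probe_id)
  leak <- mean(co$truth$luminal_only_probes %in% sig$probes$probe_id)
  expect_gte(sens, 0.9)
  expect_lte(leak, 0.05)
  # direction truth agrees with reported directions
  found <- sig$probes[sig$probes$probe_id %in% co$truth$tn_probes, ]
  expect_identical(setNames(found$direction, found$probe_id),
                   co$truth$tn_direction[found$probe_id])
  # genes map through annotation
  expect_true(all(grepl("^GTN", sig$genes)))
})

test_that("overall_profile_anova behaves at the null and under shift", {
  co <- small_cohort(seed = 29, effect_delta = 0, n_planted_tn = 0,
                     n_planted_luminal_only = 0, hazard_log_hr = 0,
                     n_prognostic = 0)
  r <- overall_profile_anova(co$betas, co$labels)
  expect_gt(r$p, 1e-4)            # no systematic group difference planted
  expect_false(r$degenerate)
  expect_length(r$sample_means, 120)

  shifted <- co$betas
  lab <- co$labels
  shifted[, lab == "TN"] <- pmin(shifted[, lab == "TN"] + 0.2, 1)
  r2 <- overall_profile_anova(shifted, lab)
  expect_lt(r2$p, 0.001)

  # degenerate case: zero within-group variance
  b <- matrix(rep(c(0.2, 0.2, 0.8, 0.8), each = 2), 2, 4,
              dimnames = list(c("cg1", "cg2"), sprintf("S%d", 1:4)))
  lab2 <- setNames(factor(c("TN", "TN", "luminal", "luminal"),
                          levels = c("TN", "HER2p", "luminal")),
                   colnames(b))
  expect_true(overall_profile_anova(b, lab2)$degenerate)
  expect_error(overall_profile_anova(b, lab2[c(1, 2, 3)]), "every sample")
})

test_that("anova p-values are near-uniform at the null over seeds", {
  ps <- vapply(1:60, function(s) {
    co <- small_cohort(seed = 500 + s, n_probes = 60, n_planted_tn = 0,
                       n_planted_luminal_only = 0, effect_delta = 0,
                       n_prognostic = 0, hazard_log_hr = 0,
                       n_samples_per_subtype = c(TN = 8, HER2p = 8,
                                                 luminal = 8),
                       n_background_genes = 0)
    overall_profile_anova(co$betas, co$labels)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.2)
})
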