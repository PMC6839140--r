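test_that("two samples merge at their pairwise distance; duplicates at zero", {
  b <- toy_betas(6, 2)
  hc <- hierarchical_cluster(b)
  expect_equal(hc$height, sqrt(sum((b[, 1] - b[, 2])^2)))

  b3 <- cbind(b, dup = b[, 1])
  hc3 <- hierarchical_cluster(b3)
  expect_equal(min(hc3$height), 0)
  first <- hc3$merge[1, ]
  expect_setequal(hc3$labels[-first], c(colnames(b)[1], "dup"))
})

test_that("Ward merge heights match the Lance-Williams recurrence", {
  for (seed in c(1, 2, 3)) {
    b <- toy_betas(10, 6, seed = seed)
    D <- dist(t(b))
    hc <- hierarchical_cluster(b, "euclidean")
    expect_equal(hc$height, ward_heights_oracle(D), tolerance = 1e-10)
    expect_true(all(diff(hc$height) >= -1e-12))   # non-decreasing heights

    Dc <- as.dist(1 - cor(b))
    hc2 <- hierarchical_cluster(b, "one_minus_r")
    expect_equal(hc2$height, ward_heights_oracle(Dc), tolerance = 1e-10)
  }
})

test_that("correlation distance rejects constant samples by name", {
  b <- toy_betas(5, 3)
  b[, 2] <- 0.4
  expect_error(hierarchical_cluster(b, "one_minus_r"), colnames(b)[2])
})

test_that("purity_curve computes majority fractions and honors the tie order", {
  # k = 1 with 6 TN + 4 luminal -> purity 0.6
  set.seed(5)
  b <- toy_betas(12, 10)
  lab <- setNames(factor(c(rep("TN", 6), rep("luminal", 4)),
                         levels = c("TN", "HER2p", "luminal")), colnames(b))
  hc <- hierarchical_cluster(b)
  pc <- purity_curve(hc, lab, max_k = 3)
  expect_equal(pc$summary$overall_weighted_purity[1], 0.6)
  expect_equal(pc$per_cutoff$purity_fraction[1], 0.6)
  expect_identical(pc$per_cutoff$majority_class[1], "TN")

  # all one label -> purity 1 everywhere
  lab1 <- setNames(factor(rep("TN", 10), levels = levels(lab)), colnames(b))
  pc1 <- purity_curve(hc, lab1, max_k = 5)
  expect_true(all(pc1$summary$overall_weighted_purity == 1))

  # 2-2 tie broken by label priority TN > HER2p > luminal
  b4 <- toy_betas(8, 4, seed = 30)
  lab4 <- setNames(factor(c("TN", "TN", "luminal", "luminal"),
                          levels = c("TN", "HER2p", "luminal")), colnames(b4))
  hc4 <- hierarchical_cluster(b4)
  pc4 <- purity_curve(hc4, lab4, max_k = 1)
  expect_identical(pc4$per_cutoff$majority_class, "TN")
  expect_equal(pc4$per_cutoff$purity_fraction, 0.5)
})

test_that("weighted purity is non-decreasing in k (refinement property)", {
  for (seed in c(3, 11, 27)) {
    co <- small_cohort(seed = seed, n_probes = 150, n_planted_tn = 10,
                       n_planted_luminal_only = 10, n_prognostic = 5,
                       n_samples_per_subtype = c(TN = 10, HER2p = 10,
                                                 luminal = 10))
    hc <- hierarchical_cluster(co$betas)
    pc <- purity_curve(hc, co$labels, max_k = 10)
    expect_true(all(diff(pc$summary$overall_weighted_purity) >= -1e-12))
    # sizes sum to n at every cutoff
    sums <- tapply(pc$per_cutoff$size, pc$per_cutoff$cutoff, sum)
    expect_true(all(sums == 30))
  }
})

test_that("pca_project matches the covariance eigendecomposition on a toy", {
  b <- toy_betas(5, 4, seed = 12)
  pr <- pca_project(b, k = 3)
  X <- scale(t(b), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(X))
  expl <- ev$values / sum(ev$values)
  expect_equal(pr$explained, expl[1:3], tolerance = 1e-10)
  # scores equal projections onto eigenvectors up to sign
  for (j in 1:3) {
    expect_equal(unname(abs(pr$scores[, j])),
                 abs(as.vector(X %*% ev$vectors[, j])), tolerance = 1e-8)
  }
  # orthogonality of score columns
  g <- crossprod(pr$scores)
  expect_equal(g[upper.tri(g)], rep(0, 3), tolerance = 1e-8)
  # sign convention: largest-|loading| positive
  for (j in 1:3) expect_gt(pr$loadings[which.max(abs(pr$loadings[, j])), j], 0)
})

test_that("collinear data loads entirely on the first component", {
  t_par <- seq(0, 1, length.out = 6)
  b <- rbind(cg1 = 0.1 + 0.5 * t_par, cg2 = 0.2 + 0.3 * t_par,
             cg3 = 0.7 - 0.4 * t_par)
  colnames(b) <- sprintf("S%d", 1:6)
  pr <- suppressWarnings(pca_project(b, k = 2))
  expect_equal(pr$explained[1], 1, tolerance = 1e-10)
})

test_that("linear_separation is perfect on well-separated blobs", {
  set.seed(6)
  n <- 30
  scores <- rbind(cbind(rnorm(n, -3, 0.5), rnorm(n, 0, 0.5)),
                  cbind(rnorm(n, 3, 0.5), rnorm(n, 0, 0.5)))
  rownames(scores) <- sprintf("S%02d", 1:(2 * n))
  colnames(scores) <- c("PC1", "PC2")
  proj <- list(scores = scores)
  lab <- setNames(factor(rep(c("TN", "nonTN"), each = n)), rownames(scores))
  fit <- linear_separation(proj, lab, n_components = 2)
  expect_equal(fit$accuracy, 1)
  # boundary normal is along PC1 when only PC1 differs
  expect_gt(abs(fit$w[1]) / (abs(fit$w[2]) + 1e-9), 5)
  expect_error(linear_separation(proj, setNames(rep("TN", 2 * n),
                                                rownames(scores))),
               "two classes")
})

test_that("identical class distributions give chance-level separation", {
  accs <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    sc <- cbind(rnorm(40), rnorm(40))
    rownames(sc) <- sprintf("S%02d", 1:40)
    lab <- setNames(factor(rep(c("TN", "nonTN"), 20)), rownames(sc))
    linear_separation(list(scores = sc), lab, 2)$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.45)
  expect_lt(mean(accs), 0.7)   # training accuracy on noise sits above 0.5
})

test_that("signature clustering separates TN with high purity (planted cohort)", {
  co <- small_cohort(seed = 37)
  lab <- co$labels
  lum <- moderated_t_test(co$betas, names(lab)[lab == "luminal"],
                          names(lab)[lab == "TN"])
  her <- moderated_t_test(co$betas, names(lab)[lab == "HER2p"],
                          names(lab)[lab == "TN"])
  sig <- derive_signature(lum, her, 0.01)
  sb <- co$betas[sig$probes$probe_id, ]
  hc <- hierarchical_cluster(sb)
  pc <- purity_curve(hc, tn_binary_labels(lab), max_k = 10)
  expect_true(all(pc$summary$max_cluster_purity[3:10] >= 0.9))
  # PC1 separates TN from the rest linearly
  pr <- pca_project(sb, k = 2)
  fit <- linear_separation(pr, tn_binary_labels(lab), n_components = 2)
  expect_gte(fit$accuracy, 0.95)
})
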