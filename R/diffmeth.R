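## diffmeth: empirical-Bayes moderated two-sample t per probe, BH control,
## intersection signature derivation, and the overall-profile ANOVA.
##
## The moderated t follows the standard empirical-Bayes construction: the
## per-probe pooled residual variance s^2 (d = n_a + n_b - 2 df) is shrunk
## toward a prior (d0, s0^2) estimated across probes by matching the first
## two moments of log s^2 to a scaled log-F distribution, giving the
## posterior variance s~^2 = (d0 s0^2 + d s^2) / (d0 + d) and
## t = delta / (s~ sqrt(1/n_a + 1/n_b)) on d0 + d degrees of freedom.

## Newton inversion of the trigamma function (for the prior df estimate).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

## Moment-match (d0, s0^2) from per-probe variances s2 with d residual df:
## e = log(s2) - digamma(d/2) + log(d/2) has mean log(s0^2) + digamma(d0/2)
## - log(d0/2) and variance trigamma(d/2) + trigamma(d0/2).
estimate_variance_prior <- function(s2, d) {
  pos <- s2 > 0 & is.finite(s2)
  if (sum(pos) < 2) return(list(d0 = Inf, s0_2 = mean(s2[pos], 1)))
  z <- log(s2[pos])
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- stats::var(e) - trigamma(d / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s0_2 <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Empirical-Bayes moderated two-sample t test per probe
#'
#' Contrast orientation: `delta_beta` is mean(group_a) - mean(group_b). In
#' the subtype contrasts of this pipeline `group_a` is the non-TN group and
#' `group_b` is TN, so `direction = "hyper"` means higher methylation in the
#' non-TN group relative to TN.
#'
#' @param betas probes x samples beta matrix (dense).
#' @param group_a,group_b disjoint character vectors of sample ids, each of
#'   size >= 2.
#' @param prior_df override for the prior degrees of freedom d0: `NULL`
#'   (default) estimates (d0, s0^2) across probes; `0` gives the ordinary
#'   pooled t; `Inf` fully trusts the prior variance.
#' @return data.frame with columns probe_id, delta_beta, s2, t_mod,
#'   df_total, p, p_adj, direction; prior estimates attached as attributes
#'   `d0` and `s0_2`.
#' @export
moderated_t_test <- function(betas, group_a, group_b, prior_df = NULL) {
  assert_beta_matrix(betas)
  if (length(intersect(group_a, group_b))) {
    stop("groups must be disjoint", call. = FALSE)
  }
  miss <- setdiff(c(group_a, group_b), colnames(betas))
  if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 samples", call. = FALSE)

  A <- betas[, group_a, drop = FALSE]
  B <- betas[, group_b, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  ssa <- rowSums((A - ma)^2); ssb <- rowSums((B - mb)^2)
  d <- na + nb - 2
  s2 <- (ssa + ssb) / d
  delta <- ma - mb

  if (is.null(prior_df)) {
    prior <- estimate_variance_prior(s2, d)
  } else if (prior_df == 0) {
    prior <- list(d0 = 0, s0_2 = NA_real_)
  } else {
    prior <- list(d0 = prior_df,
                  s0_2 = estimate_variance_prior(s2, d)$s0_2)
  }
  d0 <- prior$d0; s0_2 <- prior$s0_2
  if (is.infinite(d0)) {
    s_post <- rep(s0_2, length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s_post <- s2
    df_total <- d
  } else {
    s_post <- (d0 * s0_2 + d * s2) / (d0 + d)
    df_total <- d0 + d
  }
  se <- sqrt(s_post * (1 / na + 1 / nb))
  t_mod <- ifelse(se > 0, delta / se, 0)
  p <- 2 * stats::pt(-abs(t_mod), df = min(df_total, 1e6))
  p[se == 0 & delta == 0] <- 1
  res <- data.frame(probe_id = rownames(betas), delta_beta = delta, s2 = s2,
                    t_mod = t_mod, df_total = df_total, p = p,
                    p_adj = bh_adjust(p),
                    direction = ifelse(delta > 0, "hyper", "hypo"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "d0") <- d0
  attr(res, "s0_2") <- s0_2
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR adjustment with monotonicity enforcement; output is
#' in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || min(p) < 0 || max(p) > 1) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  adj
}

#' Derive the TN-specific signature from two subtype contrasts
#'
#' A probe enters the signature when it is significant (`p_adj < alpha`) in
#' BOTH the luminal-vs-TN and HER2p-vs-TN contrasts with the same
#' direction; discordant-direction probes are excluded. Directions are in
#' the non-TN-relative-to-TN orientation of [moderated_t_test()].
#'
#' @param luminal_vs_tn,her2p_vs_tn results of [moderated_t_test()] over the
#'   same probe universe.
#' @param alpha BH-adjusted significance threshold (default 0.01).
#' @param annot optional probe annotation used to map signature probes to
#'   gene symbols.
#' @return list of class `signature_set` with `hyper_cpgs`, `hypo_cpgs`,
#'   `genes` and a `probes` data.frame (probe_id, direction).
#' @export
derive_signature <- function(luminal_vs_tn, her2p_vs_tn, alpha = 0.01,
                             annot = NULL) {
  if (!setequal(luminal_vs_tn$probe_id, her2p_vs_tn$probe_id)) {
    stop("contrasts cover different probe universes", call. = FALSE)
  }
  b <- her2p_vs_tn[match(luminal_vs_tn$probe_id, her2p_vs_tn$probe_id), ]
  a <- luminal_vs_tn
  sig <- a$p_adj < alpha & b$p_adj < alpha
  concord <- a$direction == b$direction
  keep <- sig & concord
  hyper <- a$probe_id[keep & a$direction == "hyper"]
  hypo <- a$probe_id[keep & a$direction == "hypo"]
  genes <- character(0)
  if (!is.null(annot)) {
    g <- annot$gene_symbol[match(c(hyper, hypo), annot$probe_id)]
    genes <- sort(unique(g[!is.na(g) & g != ""]))
  }
  structure(list(hyper_cpgs = hyper, hypo_cpgs = hypo, genes = genes,
                 probes = data.frame(
                   probe_id = c(hyper, hypo),
                   direction = rep(c("hyper", "hypo"),
                                   c(length(hyper), length(hypo))),
                   stringsAsFactors = FALSE)),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature_set:", length(x$hyper_cpgs), "hyper +", length(x$hypo_cpgs),
      "hypo CpGs;", length(x$genes), "genes\n")
  invisible(x)
}

#' Overall methylation profile ANOVA across subtypes
#'
#' Each sample is summarized by its mean beta over all probes; a one-way
#' fixed-effects ANOVA compares these means across the subtype groups.
#'
#' @param betas probes x samples beta matrix.
#' @param labels named subtype factor over the samples.
#' @return list with `sample_means` (named vector), `group_means`, `F`,
#'   `df` (c(between, within)), `p` and `degenerate` (TRUE when the
#'   within-group variance is zero, leaving F undefined).
#' @export
overall_profile_anova <- function(betas, labels) {
  assert_beta_matrix(betas)
  labels <- labels[colnames(betas)]
  if (anyNA(labels)) stop("labels must cover every sample", call. = FALSE)
  labels <- droplevels(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop("need >= 2 subtype groups", call. = FALSE)
  if (any(tab < 2)) stop("need >= 2 samples per subtype", call. = FALSE)
  m <- colMeans(betas)
  grand <- mean(m)
  gm <- tapply(m, labels, mean)
  ss_between <- sum(tab * (gm - grand)^2)
  ss_within <- sum((m - gm[as.character(labels)])^2)
  df1 <- length(tab) - 1
  df2 <- length(m) - length(tab)
  if (ss_within == 0) {
    return(list(sample_means = m, group_means = gm, F = NA_real_,
                df = c(df1, df2), p = NA_real_, degenerate = TRUE))
  }
  Fstat <- (ss_between / df1) / (ss_within / df2)
  list(sample_means = m, group_means = gm, F = Fstat, df = c(df1, df2),
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE), degenerate = FALSE)
}
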