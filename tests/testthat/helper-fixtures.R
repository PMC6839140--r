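# Shared fixture builders. Everything is generated in code; no stored data.

# Small planted cohort used across modules (fast: ~0.2 s to generate).
small_cohort <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(n_samples_per_subtype = c(TN = 40, HER2p = 40, luminal = 40),
         n_probes = 800, n_planted_tn = 30, n_planted_luminal_only = 30,
         effect_delta = 0.25, noise_sd = 0.05, n_prognostic = 10,
         hazard_log_hr = 0.8, censor_rate = 0.3, seed = seed),
    list(...))
  generate_cohort(do.call(cohort_config, args))
}

# Deterministic toy beta matrix with named dims.
toy_betas <- function(nr = 5, nc = 4, seed = 42) {
  set.seed(seed)
  m <- matrix(runif(nr * nc, 0.05, 0.95), nr, nc,
              dimnames = list(sprintf("cg%03d", seq_len(nr)),
                              sprintf("S%02d", seq_len(nc))))
  m
}

tn_binary_labels <- function(labels) {
  setNames(factor(ifelse(labels == "TN", "TN", "nonTN"),
                  levels = c("TN", "nonTN")), names(labels))
}

# Brute-force step-up BH (the definitional oracle).
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- Inf
  for (i in n:1) {
    prev <- min(prev, n * p[o[i]] / i)
    adj[o[i]] <- min(prev, 1)
  }
  adj
}

# Brute-force pairwise-concordance AUC with ties counted one half.
auc_oracle <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Lance-Williams Ward recurrence (ward.D2 form) on a distance matrix:
# d(k, i+j) = sqrt(((n_i+n_k) d_ki^2 + (n_j+n_k) d_kj^2 - n_k d_ij^2) / n_ijk)
ward_heights_oracle <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(Inf, NA, NA)
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      if (D[i, j] < best[1]) best <- c(D[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, best[1])
    for (k in active) {
      if (k == i || k == j) next
      ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[k]
      D[i, k] <- D[k, i] <- sqrt(((ni + nk) * D[k, i]^2 +
                                  (nj + nk) * D[k, j]^2 -
                                  nk * D[i, j]^2) / (ni + nj + nk))
    }
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  heights
}
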