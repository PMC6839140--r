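## synthetic_cohort: deterministic generator of methylation / expression /
## clinical cohorts with planted structure, so every downstream stage is
## testable without any download.
##
## Betas are logistic-transformed Gaussians on the M scale whose Gaussian
## mean is solved (Gauss-Hermite quadrature + Newton) so that the expected
## beta equals the requested group mean exactly; group effects therefore
## land on the beta scale as stated while composing additively on M.

#' Build and validate a synthetic cohort configuration
#'
#' @param n_samples_per_subtype named integer vector with entries TN, HER2p,
#'   luminal.
#' @param n_probes total probe count.
#' @param n_planted_tn CpGs truly differential in TN vs both other subtypes.
#' @param n_planted_luminal_only CpGs differential only in luminal vs TN.
#' @param effect_delta beta-scale group-mean shift for planted sites.
#' @param noise_sd within-group beta-scale dispersion.
#' @param meth_expr_rho target (negative) correlation between a planted
#'   promoter CpG and its gene's expression.
#' @param n_prognostic count of survival-informative sites (drawn from
#'   non-differential probes).
#' @param hazard_log_hr per-site log hazard ratio of the unfavorable
#'   (above-median) methylation state.
#' @param censor_rate administrative censoring fraction in \[0, 1).
#' @param seed RNG seed for the sample-level draws; the cohort is a pure
#'   function of the config.
#' @param structure_seed RNG seed for the cohort-invariant structure
#'   (probe baselines, planted directions, gene map, QC flags). Defaults to
#'   `seed`. A discovery/validation pair is generated with the same
#'   `structure_seed` and different `seed`s, so both cohorts share the same
#'   planted biology but have independent samples.
#' @param snp_frac,crossreactive_frac,sex_frac fractions of non-planted
#'   probes carrying QC flags / sex-chromosome assignment.
#' @param det_fail_rate per-entry detection failure rate on non-planted
#'   probes.
#' @param n_background_genes expression-only noise genes mapped to random
#'   non-planted probes (exercises the probe-to-gene collapse).
#' @param baseline_median_months baseline median overall survival.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples_per_subtype = c(TN = 40, HER2p = 40, luminal = 40),
                          n_probes = 2000,
                          n_planted_tn = 50,
                          n_planted_luminal_only = 50,
                          effect_delta = 0.2,
                          noise_sd = 0.05,
                          meth_expr_rho = -0.7,
                          n_prognostic = 20,
                          hazard_log_hr = 1.0,
                          censor_rate = 0.3,
                          seed = 1L,
                          structure_seed = NULL,
                          snp_frac = 0.02,
                          crossreactive_frac = 0.02,
                          sex_frac = 0.02,
                          det_fail_rate = 0.001,
                          n_background_genes = 50,
                          baseline_median_months = 72) {
  cfg <- list(n_samples_per_subtype = n_samples_per_subtype,
              n_probes = as.integer(n_probes),
              n_planted_tn = as.integer(n_planted_tn),
              n_planted_luminal_only = as.integer(n_planted_luminal_only),
              effect_delta = effect_delta, noise_sd = noise_sd,
              meth_expr_rho = meth_expr_rho,
              n_prognostic = as.integer(n_prognostic),
              hazard_log_hr = hazard_log_hr, censor_rate = censor_rate,
              seed = as.integer(seed),
              structure_seed = if (is.null(structure_seed)) as.integer(seed)
              else as.integer(structure_seed),
              snp_frac = snp_frac, crossreactive_frac = crossreactive_frac,
              sex_frac = sex_frac, det_fail_rate = det_fail_rate,
              n_background_genes = as.integer(n_background_genes),
              baseline_median_months = baseline_median_months)
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid cohort config: field '", field, "' ", why, call. = FALSE)
  }
  n <- cfg$n_samples_per_subtype
  if (is.null(names(n)) || !setequal(names(n), SUBTYPE_LEVELS)) {
    fail("n_samples_per_subtype", "must be named TN, HER2p, luminal")
  }
  if (any(n < 0)) fail("n_samples_per_subtype", "must be non-negative")
  counts <- c("n_probes", "n_planted_tn", "n_planted_luminal_only",
              "n_prognostic", "n_background_genes")
  for (f in counts) if (is.na(cfg[[f]]) || cfg[[f]] < 0) fail(f, "must be >= 0")
  if (cfg$n_planted_tn + cfg$n_planted_luminal_only > cfg$n_probes) {
    fail("n_planted_tn", "+ n_planted_luminal_only exceeds n_probes")
  }
  if (cfg$effect_delta < 0 || cfg$effect_delta >= 1) {
    fail("effect_delta", "must be in [0, 1)")
  }
  if (cfg$noise_sd <= 0) fail("noise_sd", "must be > 0")
  if (cfg$meth_expr_rho < -1 || cfg$meth_expr_rho > 1) {
    fail("meth_expr_rho", "must be in [-1, 1]")
  }
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1) {
    fail("censor_rate", "must be in [0, 1)")
  }
  invisible(cfg)
}

## Gauss-Hermite nodes/weights by Golub-Welsch (eigen of the Jacobi matrix).
gauss_hermite <- function(n = 20) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

## E[sigmoid2(N(m, sd))] for vectors m, sd via 20-node Gauss-Hermite.
expected_beta <- function(m, sd_m, gh) {
  z <- outer(sd_m * sqrt(2), gh$nodes)           # n x k deviations
  vals <- m_to_beta(m + z)
  as.vector(vals %*% gh$weights) / sqrt(pi)
}

## Solve, per element, for the M-scale Gaussian mean whose expected beta is
## `target` at dispersion sd_m. Newton iteration, vectorized.
m_mean_for_target <- function(target, sd_m, gh = gauss_hermite(20)) {
  if (!length(target)) return(numeric(0))
  m <- beta_to_m(target)
  for (it in 1:30) {
    e <- expected_beta(m, sd_m, gh)
    ## derivative of E wrt m: E[b(1-b)ln2]
    z <- outer(sd_m * sqrt(2), gh$nodes)
    b <- m_to_beta(m + z)
    de <- as.vector((b * (1 - b) * log(2)) %*% gh$weights) / sqrt(pi)
    step <- (e - target) / pmax(de, 1e-12)
    m <- m - step
    if (max(abs(e - target)) < 1e-10) break
  }
  m
}

#' Generate a synthetic cohort
#'
#' Produces a beta matrix with three receptor-defined subtypes, planted
#' TN-differential and luminal-only differential CpGs (beta-scale shift
#' `effect_delta`), expression negatively correlated with planted promoter
#' CpGs, and right-censored exponential survival whose log hazard is
#' `hazard_log_hr` per unfavorable (above-median) prognostic site. Identical
#' configs (including seed) give bit-identical cohorts.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with elements `betas`,
#'   `expression`, `labels`, `receptor_status`, `clinical`, `annotation`,
#'   `detection_p`, `truth`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  ## structure phase: everything a second cohort from the same population
  ## must share (baselines, planted directions, gene map, QC flags)
  set.seed(config$structure_seed)

  ns <- config$n_samples_per_subtype[SUBTYPE_LEVELS]
  n_samp <- sum(ns)
  labels <- factor(rep(SUBTYPE_LEVELS, times = ns), levels = SUBTYPE_LEVELS)
  sample_ids <- sprintf("S%04d", seq_len(n_samp))
  names(labels) <- sample_ids
  probe_ids <- sprintf("cg%06d", seq_len(config$n_probes))

  np <- config$n_probes
  idx_tn <- seq_len(config$n_planted_tn)
  idx_lum <- seq_len(config$n_planted_luminal_only) + config$n_planted_tn
  idx_free <- setdiff(seq_len(np), c(idx_tn, idx_lum))
  ## prognostic sites sit on planted TN CpGs first (prognostic signature
  ## sites, as in a prognostic-CpG panel), spilling over to free probes
  idx_prog <- utils::head(c(idx_tn, idx_free), config$n_prognostic)
  if (length(idx_prog) < config$n_prognostic) {
    stop("not enough probes for n_prognostic", call. = FALSE)
  }
  idx_prog_free <- setdiff(idx_prog, idx_tn)

  ## baseline per-probe means: bimodal background, mid-range planted probes
  mu0 <- numeric(np)
  comp <- sample(c("lo", "hi", "mid"), np, replace = TRUE,
                 prob = c(0.45, 0.45, 0.10))
  mu0[comp == "lo"] <- runif(sum(comp == "lo"), 0.05, 0.25)
  mu0[comp == "hi"] <- runif(sum(comp == "hi"), 0.75, 0.95)
  mu0[comp == "mid"] <- runif(sum(comp == "mid"), 0.35, 0.65)
  mu0[c(idx_tn, idx_lum)] <- runif(length(idx_tn) + length(idx_lum), 0.25, 0.75)
  mu0[idx_prog_free] <- runif(length(idx_prog_free), 0.35, 0.65)

  d <- config$effect_delta
  dir_tn <- sample(c(-1, 1), length(idx_tn), replace = TRUE)
  dir_tn[mu0[idx_tn] + dir_tn * d > 0.97] <- -1
  dir_tn[mu0[idx_tn] + dir_tn * d < 0.03] <- 1
  ## prognostic sites overlapping the planted TN set share one orientation
  ## (TN hypermethylated), so their unfavorable above-median states add up
  ## instead of cancelling in the hazard
  overlap <- which(idx_tn %in% idx_prog)
  if (length(overlap)) {
    mu0[idx_tn[overlap]] <- runif(length(overlap), 0.25,
                                  min(0.7, 0.95 - d))
    dir_tn[overlap] <- 1
  }
  dir_lum <- sample(c(-1, 1), length(idx_lum), replace = TRUE)
  dir_lum[mu0[idx_lum] + dir_lum * d > 0.97] <- -1
  dir_lum[mu0[idx_lum] + dir_lum * d < 0.03] <- 1

  ## group target means (probes x 3)
  mu <- matrix(mu0, np, 3, dimnames = list(probe_ids, SUBTYPE_LEVELS))
  mu[idx_tn, "TN"] <- mu0[idx_tn] + dir_tn * d
  mu[idx_lum, "luminal"] <- mu0[idx_lum] + dir_lum * d

  ## Gaussian M-scale parameters matched to the beta-scale targets
  gh <- gauss_hermite(20)
  sd_m <- config$noise_sd / (log(2) * mu * (1 - mu))
  m_mean <- matrix(m_mean_for_target(as.vector(mu), as.vector(sd_m), gh),
                   np, 3, dimnames = dimnames(mu))

  ## gene map: planted TN genes plus background genes on non-planted probes
  gene_of_probe <- rep("", np)
  gene_of_probe[idx_tn] <- sprintf("GTN%04d", seq_along(idx_tn))
  bg_pool <- setdiff(idx_free, idx_prog)
  n_bg <- min(config$n_background_genes, length(bg_pool))
  idx_bg <- if (n_bg > 0) sample(bg_pool, n_bg) else integer(0)
  gene_of_probe[idx_bg] <- sprintf("GBG%04d", seq_len(n_bg))

  ## annotation: QC flags and sex chromosomes only on free probes so the
  ## planted structure survives filtering
  annot <- data.frame(probe_id = probe_ids, gene_symbol = gene_of_probe,
                      chromosome = sprintf("chr%d", 1 + (seq_len(np) %% 22)),
                      snp_flag = rep(0L, np), crossreactive_flag = rep(0L, np),
                      stringsAsFactors = FALSE)
  flag_pool <- setdiff(idx_free, c(idx_prog, idx_bg))
  take <- function(pool, frac) {
    k <- min(length(pool), round(frac * np))
    if (k > 0) sample(pool, k) else integer(0)
  }
  i_snp <- take(flag_pool, config$snp_frac)
  flag_pool <- setdiff(flag_pool, i_snp)
  i_cr <- take(flag_pool, config$crossreactive_frac)
  flag_pool <- setdiff(flag_pool, i_cr)
  i_sex <- take(flag_pool, config$sex_frac)
  annot$snp_flag[i_snp] <- 1L
  annot$crossreactive_flag[i_cr] <- 1L
  annot$chromosome[i_sex] <- sample(c("chrX", "chrY"), length(i_sex),
                                    replace = TRUE)

  ## sample phase: draws that are independent between cohorts sharing the
  ## same structure (distinct derived stream so structure_seed == seed does
  ## not replay the structure draws)
  set.seed(bitwXor(config$seed, 123456789L))

  betas <- matrix(NA_real_, np, n_samp, dimnames = list(probe_ids, sample_ids))
  for (g in SUBTYPE_LEVELS) {
    cols <- which(labels == g)
    if (!length(cols)) next
    z <- matrix(rnorm(np * length(cols)), np, length(cols))
    betas[, cols] <- m_to_beta(m_mean[, g] + sd_m[, g] * z)
  }

  ## expression: planted TN genes anti-correlated with their probe
  rho <- config$meth_expr_rho
  expr_genes <- c(gene_of_probe[idx_tn], gene_of_probe[idx_bg])
  expression <- NULL
  if (length(expr_genes) && n_samp >= 3) {
    src <- c(idx_tn, idx_bg)
    zb <- t(scale(t(betas[src, , drop = FALSE])))
    zb[is.na(zb)] <- 0
    eps <- matrix(rnorm(length(src) * n_samp), length(src), n_samp)
    expression <- matrix(rho * zb + sqrt(1 - rho^2) * eps,
                         length(src), n_samp,
                         dimnames = list(expr_genes, sample_ids))
  }

  ## detection p-values: mostly tiny, sporadic failures on flaggable probes
  detection_p <- matrix(runif(np * n_samp, 0, 0.005), np, n_samp,
                        dimnames = list(probe_ids, sample_ids))
  if (config$det_fail_rate > 0 && length(flag_pool)) {
    n_fail <- stats::rbinom(1, length(flag_pool) * n_samp,
                            config$det_fail_rate)
    if (n_fail > 0) {
      cells <- cbind(sample(flag_pool, n_fail, replace = TRUE),
                     sample(n_samp, n_fail, replace = TRUE))
      detection_p[cells] <- runif(n_fail, 0.05, 1)
    }
  }

  ## survival: exponential times, log hazard = hazard_log_hr * sum of
  ## centered unfavorable-state indicators over prognostic sites
  lambda0 <- log(2) / config$baseline_median_months
  lp <- rep(0, n_samp)
  if (length(idx_prog)) {
    bp <- betas[idx_prog, , drop = FALSE]
    med <- apply(bp, 1, stats::median)
    unfav <- sweep(bp, 1, med, ">") * 1
    lp <- config$hazard_log_hr * colSums(unfav - 0.5)
  }
  rate <- lambda0 * exp(lp)
  t_event <- rexp(n_samp, rate = rate)
  time <- t_event
  event <- rep(1L, n_samp)
  if (config$censor_rate > 0) {
    cens_prob <- function(tau) mean((1 - exp(-rate * tau)) / (rate * tau))
    tau <- uniroot(function(x) cens_prob(x) - config$censor_rate,
                   lower = 1e-6, upper = 1e8, tol = 1e-8)$root
    cens <- runif(n_samp, 0, tau)
    event <- as.integer(t_event <= cens)
    time <- pmin(t_event, cens)
  }
  clinical <- cap_survival(data.frame(sample_id = sample_ids,
                                      time = time, event = event,
                                      stringsAsFactors = FALSE))

  receptor_status <- data.frame(
    sample_id = sample_ids,
    er = ifelse(labels == "luminal", "+", "-"),
    pr = ifelse(labels == "luminal", "+", "-"),
    her2 = ifelse(labels == "HER2p", "+", "-"),
    stringsAsFactors = FALSE)

  truth <- list(
    tn_probes = probe_ids[idx_tn],
    ## direction in the signature convention: hyper = higher in non-TN
    ## relative to TN, i.e. opposite to the TN-group shift
    tn_direction = setNames(ifelse(dir_tn > 0, "hypo", "hyper"),
                            probe_ids[idx_tn]),
    luminal_only_probes = probe_ids[idx_lum],
    prognostic_probes = probe_ids[idx_prog],
    ## positive hazard_log_hr makes the above-median state unfavorable
    prognostic_favorable = setNames(
      rep(if (config$hazard_log_hr >= 0) "low" else "high",
          length(idx_prog)), probe_ids[idx_prog]))

  structure(list(betas = betas, expression = expression, labels = labels,
                 receptor_status = receptor_status, clinical = clinical,
                 annotation = annot, detection_p = detection_p,
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

## Save/restore .Random.seed so generate_cohort is a pure function that does
## not disturb the caller's RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a synthetic cohort to disk as plain-text fixtures
#'
#' Emits the beta matrix, expression matrix, probe annotation, receptor
#' status and clinical tables in the TSV dialects the readers consume, plus
#' a `manifest.txt` of key=path lines.
#'
#' @param cohort a [generate_cohort()] result.
#' @param directory output directory (created if absent).
#' @return named character vector of written paths (the manifest), invisibly.
#' @export
write_fixture <- function(cohort, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create fixture directory: ", directory, call. = FALSE)
  }
  paths <- c(betas = file.path(directory, "betas.tsv"),
             annotation = file.path(directory, "annotation.tsv"),
             receptor_status = file.path(directory, "receptor_status.tsv"),
             clinical = file.path(directory, "clinical.tsv"))
  write_beta_matrix(cohort$betas, paths["betas"])
  write_annotation(cohort$annotation, paths["annotation"])
  write_tsv(cohort$receptor_status, paths["receptor_status"])
  write_clinical(cohort$clinical, paths["clinical"])
  if (!is.null(cohort$expression)) {
    paths["expression"] <- file.path(directory, "expression.tsv")
    write_real_matrix(cohort$expression, paths["expression"], id_col = "gene_id")
  }
  if (!is.null(cohort$detection_p)) {
    paths["detection_p"] <- file.path(directory, "detection_p.tsv")
    write_real_matrix(cohort$detection_p, paths["detection_p"],
                      id_col = "probe_id")
  }
  manifest <- file.path(directory, "manifest.txt")
  writeLines(paste0(names(paths), "=", paths), manifest)
  invisible(paths)
}

#' Write an unbounded real-valued matrix (expression, detection p) to TSV
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param id_col header name for the identifier column.
#' @return `path`, invisibly.
#' @export
write_real_matrix <- function(m, path, id_col = "gene_id") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(m)), collapse = "\t"), con)
  if (nrow(m)) {
    chr <- format(m, trim = TRUE, digits = 17)
    chr[is.na(m)] <- "null"
    writeLines(paste(rownames(m), apply(chr, 1, paste, collapse = "\t"),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read an unbounded real-valued matrix written by [write_real_matrix()]
#'
#' @param path input path.
#' @return numeric matrix with dimnames; `NA` for null/empty cells.
#' @export
read_real_matrix <- function(path) {
  lines <- read_tsv_lines(path)
  if (!length(lines)) stop("empty matrix file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  body <- fields[-1]
  ids <- vapply(body, `[[`, character(1), 1L)
  cells <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  cells[cells %in% c("", "null", "NA")] <- NA_character_
  matrix(suppressWarnings(as.numeric(cells)), nrow = length(body),
         byrow = TRUE, dimnames = list(ids, header[-1]))
}
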