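## survival: Kaplan-Meier estimation, logrank testing, univariate Cox
## proportional hazards (Breslow ties, Newton-Raphson), per-site favorable
## directions, the averaged 0/1 prognostic score, and median-split
## stratification.

## Align a clinical table to a vector of sample ids.
align_clinical <- function(clinical, sample_ids) {
  i <- match(sample_ids, clinical$sample_id)
  if (anyNA(i)) stop("clinical data missing for sample(s): ",
                     paste(utils::head(sample_ids[is.na(i)], 5),
                           collapse = ", "), call. = FALSE)
  clinical[i, , drop = FALSE]
}

#' Kaplan-Meier product-limit estimator
#'
#' @param clinical data.frame with columns sample_id, time, event.
#' @param group optional named factor/character splitting samples into
#'   groups; one curve per group.
#' @return data.frame with columns group, time, n_risk, n_event, survival;
#'   each curve starts at S(0) = 1 and steps only at event times
#'   (right-continuous, non-increasing).
#' @export
km_curve <- function(clinical, group = NULL) {
  if (is.null(group)) {
    grp <- rep("all", nrow(clinical))
  } else {
    grp <- as.character(group[clinical$sample_id])
    if (anyNA(grp)) stop("group must cover every sample", call. = FALSE)
  }
  out <- list()
  for (g in unique(grp)) {
    sel <- grp == g
    time <- clinical$time[sel]; event <- clinical$event[sel]
    ut <- sort(unique(time[event == 1]))
    s <- 1
    rows <- data.frame(group = g, time = 0, n_risk = sum(sel), n_event = 0,
                       survival = 1)
    for (t in ut) {
      n_risk <- sum(time >= t)
      d <- sum(time == t & event == 1)
      s <- s * (1 - d / n_risk)
      rows <- rbind(rows, data.frame(group = g, time = t, n_risk = n_risk,
                                     n_event = d, survival = s))
    }
    out[[g]] <- rows
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Two-group logrank test
#'
#' Classical observed-minus-expected statistic over the event-time risk
#' sets, with the hypergeometric variance (ties-corrected).
#'
#' @param time,event numeric vectors of follow-up and event indicators.
#' @param group binary indicator (0/1 or logical) per sample.
#' @return list with `chisq`, `p`, `observed` and `expected` for group 1.
#' @export
logrank_test <- function(time, event, group) {
  g <- as.integer(group)
  if (!all(g %in% 0:1)) stop("group must be binary", call. = FALSE)
  if (length(unique(g)) < 2) stop("both groups must be present", call. = FALSE)
  ut <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) return(list(chisq = 0, p = 1, observed = O, expected = E))
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Univariate Cox proportional-hazards fit
#'
#' Newton-Raphson maximization of the Breslow-ties partial likelihood for a
#' single covariate. Convergence at gradient magnitude < 1e-8 or 50
#' iterations. For a binary covariate the reported `logrank_p` is the
#' classical logrank test; otherwise it is the partial-likelihood score
#' test at beta = 0.
#'
#' @param covariate named numeric vector per sample.
#' @param clinical data.frame with sample_id, time, event.
#' @return list with `log_hr`, `hr`, `se`, `wald_p`, `logrank_p`,
#'   `converged` and `boundary` (monotone-likelihood flag; `log_hr` is then
#'   capped at +/-15).
#' @export
fit_cox_univariate <- function(covariate, clinical) {
  cl <- align_clinical(clinical, names(covariate))
  x <- as.numeric(covariate)
  if (any(!is.finite(x))) stop("covariate must be finite", call. = FALSE)
  time <- cl$time; event <- cl$event
  if (sum(event) < 2) stop("need >= 2 events", call. = FALSE)
  if (stats::sd(x) == 0) stop("covariate has zero variance", call. = FALSE)

  ## Breslow log partial likelihood derivatives at beta
  derivs <- function(beta) {
    r <- exp(beta * x)
    ll <- 0; U <- 0; I <- 0
    for (t in sort(unique(time[event == 1]))) {
      at_risk <- time >= t
      dead <- time == t & event == 1
      d <- sum(dead)
      s0 <- sum(r[at_risk])
      s1 <- sum(r[at_risk] * x[at_risk])
      s2 <- sum(r[at_risk] * x[at_risk]^2)
      ll <- ll + beta * sum(x[dead]) - d * log(s0)
      U <- U + sum(x[dead]) - d * s1 / s0
      I <- I + d * (s2 / s0 - (s1 / s0)^2)
    }
    list(ll = ll, U = U, I = I)
  }

  score0 <- derivs(0)
  beta <- 0; converged <- FALSE; boundary <- FALSE
  for (it in 1:50) {
    dv <- derivs(beta)
    if (dv$I <= 1e-12) { boundary <- TRUE; break }
    step <- dv$U / dv$I
    step <- max(min(step, 2), -2)        # damp huge early steps
    beta <- beta + step
    if (abs(beta) > 15) { beta <- sign(beta) * 15; boundary <- TRUE; break }
    if (abs(dv$U) < 1e-8) { converged <- TRUE; break }
  }
  if (boundary) {
    warning("monotone partial likelihood; hazard ratio capped")
  }
  info <- derivs(beta)$I
  se <- if (info > 0) 1 / sqrt(info) else NA_real_
  wald_p <- if (is.na(se)) NA_real_ else
    2 * stats::pnorm(-abs(beta / se))

  is_binary <- all(x %in% c(0, 1))
  if (is_binary) {
    lr <- logrank_test(time, event, x)
    logrank_p <- lr$p
  } else {
    chisq <- if (score0$I > 0) score0$U^2 / score0$I else 0
    logrank_p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  list(log_hr = beta, hr = exp(beta), se = se, wald_p = wald_p,
       logrank_p = logrank_p, converged = converged, boundary = boundary)
}

#' Per-site favorable methylation direction by univariate survival
#'
#' Each signature site is dichotomized at its median beta across samples
#' (ties to the low group); a univariate Cox fit of the high-vs-low
#' indicator determines the hazard ratio, and the favorable state is the
#' group with the lower hazard (HR exactly 1 ties to `"low"` with a flag).
#' Significance at logrank p < `alpha`.
#'
#' @param betas signature probes x samples beta matrix.
#' @param clinical data.frame with sample_id, time, event.
#' @param alpha logrank significance threshold (default 0.01).
#' @return data.frame with probe_id, favorable_state, hr, log_hr, p,
#'   significant, tie flag; zero-variance sites are skipped and listed in
#'   attribute `"skipped"`.
#' @export
site_directions <- function(betas, clinical, alpha = 0.01) {
  assert_beta_matrix(betas)
  cl <- align_clinical(clinical, colnames(betas))
  if (ncol(betas) < 10 || sum(cl$event) < 2) {
    stop("need >= 10 samples with >= 2 events", call. = FALSE)
  }
  rows <- list(); skipped <- character(0)
  for (p in rownames(betas)) {
    b <- betas[p, ]
    med <- stats::median(b)
    high <- as.numeric(b > med)
    if (length(unique(high)) < 2) { skipped <- c(skipped, p); next }
    fit <- suppressWarnings(
      fit_cox_univariate(setNames(high, colnames(betas)), cl))
    tie <- fit$hr == 1
    rows[[p]] <- data.frame(
      probe_id = p,
      favorable_state = if (fit$hr >= 1) "low" else "high",
      hr = fit$hr, log_hr = fit$log_hr, p = fit$logrank_p,
      significant = fit$logrank_p < alpha, tie = tie,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame(probe_id = character(0), favorable_state = character(0),
                  hr = numeric(0), log_hr = numeric(0), p = numeric(0),
                  significant = logical(0), tie = logical(0))
  attr(out, "skipped") <- skipped
  out
}

#' Averaged per-sample prognostic score
#'
#' Per sample and site, the indicator is 1 when the sample's dichotomized
#' state (above/below the site median) equals the site's favorable state,
#' else 0; the score is the mean indicator over sites. Scores lie in
#' \[0, 1\] and are invariant to site ordering.
#'
#' @param betas signature probes x samples beta matrix.
#' @param directions data.frame from [site_directions()].
#' @param use_only_significant restrict to sites with `significant == TRUE`
#'   (default TRUE).
#' @return data.frame with sample_id, score, n_sites_used.
#' @export
prognostic_scores <- function(betas, directions, use_only_significant = TRUE) {
  d <- directions
  if (use_only_significant) d <- d[d$significant, , drop = FALSE]
  if (!nrow(d)) stop("no sites available for scoring", call. = FALSE)
  miss <- setdiff(d$probe_id, rownames(betas))
  if (length(miss)) stop("direction sites absent from betas: ",
                         paste(utils::head(miss, 5), collapse = ", "),
                         call. = FALSE)
  B <- betas[d$probe_id, , drop = FALSE]
  med <- apply(B, 1, stats::median)
  high <- sweep(B, 1, med, `>`)
  fav_high <- d$favorable_state == "high"
  fav <- high == fav_high            # recycles fav_high down columns
  data.frame(sample_id = colnames(betas), score = colMeans(fav),
             n_sites_used = nrow(d), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Stratify samples by prognostic score and test survival separation
#'
#' Samples are split at the median score (ties to the low-score group); the
#' groups are compared by Kaplan-Meier curves, the logrank test, and a Cox
#' fit of the low-vs-high indicator (HR > 1 means the low-score group has
#' the higher hazard).
#'
#' @param scores data.frame from [prognostic_scores()].
#' @param clinical data.frame with sample_id, time, event.
#' @return list with `groups` (named factor low/high), `logrank_p`, `hr`
#'   (low vs high), `cox` (full fit), `km` (stacked KM curves).
#' @export
stratify_and_test <- function(scores, clinical) {
  s <- setNames(scores$score, scores$sample_id)
  if (stats::sd(s) == 0) stop("prognostic scores are constant", call. = FALSE)
  med <- stats::median(s)
  grp <- factor(ifelse(s <= med, "low", "high"), levels = c("high", "low"))
  if (length(unique(grp)) < 2) {
    ## all mass at the median; split strictly below/above-or-equal instead
    grp <- factor(ifelse(s < med, "low", "high"), levels = c("high", "low"))
  }
  cl <- align_clinical(clinical, names(s))
  ind <- setNames(as.numeric(grp == "low"), names(s))
  ## degenerate inputs (e.g. two samples, < 2 events) still stratify but
  ## cannot support a Cox fit
  cox <- tryCatch(suppressWarnings(fit_cox_univariate(ind, cl)),
                  error = function(e) list(hr = NA_real_, log_hr = NA_real_,
                                           se = NA_real_, wald_p = NA_real_,
                                           logrank_p = NA_real_,
                                           converged = FALSE, boundary = FALSE))
  lr <- logrank_test(cl$time, cl$event, ind)
  km <- km_curve(cl, group = grp)
  list(groups = grp, logrank_p = lr$p, hr = cox$hr, cox = cox, km = km)
}
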