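## preprocess: probe QC filtering, peak-based normalization on the M scale,
## and probe-to-gene collapse by strongest negative methylation-expression
## correlation.

#' Filter probes by detection quality, QC flags and sex chromosomes
#'
#' Entries whose detection p-value exceeds `detection_threshold` are masked
#' to `NA`; probes flagged SNP-associated or cross-reactive, or mapped to
#' chromosome X/Y, are removed entirely; finally any probe left with a
#' missing entry (pre-existing or masked) is removed, keeping downstream
#' matrices dense (complete-case rule). Each removed probe is tallied once,
#' by the first matching category in the order detection, SNP,
#' cross-reactive, sex chromosome.
#'
#' @param betas probes x samples beta matrix.
#' @param annot probe annotation data.frame covering every probe
#'   (see [read_annotation()]).
#' @param detection_p optional probes x samples matrix of detection
#'   p-values.
#' @param detection_threshold entries with detection p above this are
#'   masked (default 0.01).
#' @return list with `betas` (filtered matrix, values untouched) and
#'   `report` (one-row data.frame of category tallies).
#' @export
filter_probes <- function(betas, annot, detection_p = NULL,
                          detection_threshold = 0.01) {
  assert_beta_matrix(betas)
  missing_annot <- setdiff(rownames(betas), annot$probe_id)
  if (length(missing_annot)) {
    stop("probes missing from annotation: ",
         paste(utils::head(missing_annot, 5), collapse = ", "),
         if (length(missing_annot) > 5) ", ..." else "", call. = FALSE)
  }
  a <- annot[match(rownames(betas), annot$probe_id), ]

  if (!is.null(detection_p)) {
    if (!all(rownames(betas) %in% rownames(detection_p)) ||
        !all(colnames(betas) %in% colnames(detection_p))) {
      stop("detection_p must cover all probes and samples", call. = FALSE)
    }
    dp <- detection_p[rownames(betas), colnames(betas), drop = FALSE]
    betas[dp > detection_threshold] <- NA_real_
  }

  has_null <- rowSums(is.na(betas)) > 0
  is_snp <- a$snp_flag == 1L
  is_cr <- a$crossreactive_flag == 1L
  is_sex <- a$chromosome %in% c("chrX", "chrY", "X", "Y")

  cat_det <- has_null
  cat_snp <- !cat_det & is_snp
  cat_cr <- !cat_det & !cat_snp & is_cr
  cat_sex <- !cat_det & !cat_snp & !cat_cr & is_sex
  drop <- cat_det | cat_snp | cat_cr | cat_sex

  report <- data.frame(
    n_input_probes = nrow(betas),
    n_removed_detection = sum(cat_det),
    n_removed_snp = sum(cat_snp),
    n_removed_crossreactive = sum(cat_cr),
    n_removed_sex_chromosome = sum(cat_sex),
    n_retained = sum(!drop))
  list(betas = betas[!drop, , drop = FALSE], report = report)
}

## Locate the two principal modes of a sample's M-value density: the highest
## local maximum below 0 (unmethylated peak) and above 0 (methylated peak).
## Returns c(lo, hi) or NULL when either side has no mode.
find_m_peaks <- function(m) {
  d <- stats::density(m, n = 512)
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  px <- d$x[is_max]
  py <- y[is_max]
  lo <- px[px < 0]
  hi <- px[px >= 0]
  if (!length(lo) || !length(hi)) return(NULL)
  c(lo = lo[which.max(py[px < 0])], hi = hi[which.max(py[px >= 0])])
}

#' Peak-based normalization of a beta matrix
#'
#' Per sample, betas are mapped to M values, the unmethylated and methylated
#' density modes are located by kernel density estimation, and the sample's
#' M values are affinely rescaled so its two peaks land on the cohort-median
#' peak positions, then mapped back to betas. The affine map on M is
#' monotone, so within-sample beta rankings are preserved. Samples whose M
#' density lacks a mode on either side of 0 are passed through unscaled with
#' a warning.
#'
#' @param betas probes x samples beta matrix (no missing values).
#' @return normalized beta matrix; per-sample peak positions and affine
#'   coefficients are attached as attribute `"peaks"`.
#' @export
peak_normalize <- function(betas) {
  assert_beta_matrix(betas)
  if (anyNA(betas)) stop("peak_normalize requires a dense matrix; filter first",
                         call. = FALSE)
  if (nrow(betas) < 30) {
    stop("peak_normalize needs >= 30 probes per sample for density estimation",
         call. = FALSE)
  }
  M <- beta_to_m(betas)
  peaks <- lapply(seq_len(ncol(M)), function(j) find_m_peaks(M[, j]))
  ok <- !vapply(peaks, is.null, logical(1))
  if (!any(ok)) {
    warning("no sample has a two-peak M density; matrix returned unscaled")
    return(betas)
  }
  pl <- vapply(peaks[ok], `[[`, numeric(1), "lo")
  ph <- vapply(peaks[ok], `[[`, numeric(1), "hi")
  target <- c(lo = stats::median(pl), hi = stats::median(ph))

  out <- M
  coef <- data.frame(sample_id = colnames(M), peak_lo = NA_real_,
                     peak_hi = NA_real_, slope = 1, intercept = 0,
                     scaled = ok, stringsAsFactors = FALSE)
  for (j in which(ok)) {
    p <- peaks[[j]]
    b <- (target["hi"] - target["lo"]) / (p["hi"] - p["lo"])
    a <- target["lo"] - b * p["lo"]
    out[, j] <- a + b * M[, j]
    coef$peak_lo[j] <- p["lo"]; coef$peak_hi[j] <- p["hi"]
    coef$slope[j] <- b; coef$intercept[j] <- a
  }
  if (any(!ok)) {
    warning("unimodal M density; sample(s) passed through unscaled: ",
            paste(colnames(M)[!ok], collapse = ", "))
  }
  res <- m_to_beta(out)
  dimnames(res) <- dimnames(betas)
  attr(res, "peaks") <- coef
  res
}

#' Collapse probes to genes by strongest negative expression correlation
#'
#' For each gene with at least one annotated probe and measured expression,
#' the Pearson correlation between each candidate probe's betas and the
#' gene's expression is computed over the shared samples; the probe with the
#' minimum correlation is kept as the gene's methylation probe (the most
#' negative candidate; when no candidate is negative the minimum is still
#' kept and flagged). Genes with zero-variance expression are skipped.
#'
#' @param betas probes x samples beta matrix.
#' @param expression genes x samples numeric matrix.
#' @param annot probe annotation with `gene_symbol` (empty = unannotated).
#' @return list with `gene_betas` (genes x samples matrix), `provenance`
#'   (data.frame gene, chosen_probe, chosen_r, n_candidates,
#'   all_nonnegative) and `skipped` (data.frame gene, reason).
#' @export
collapse_to_genes <- function(betas, expression, annot) {
  assert_beta_matrix(betas)
  shared <- intersect(colnames(betas), colnames(expression))
  if (length(shared) < 3) {
    stop("need >= 3 shared samples between betas and expression",
         call. = FALSE)
  }
  a <- annot[annot$probe_id %in% rownames(betas) & annot$gene_symbol != "", ]
  genes <- intersect(unique(a$gene_symbol), rownames(expression))
  prov <- list(); skipped <- list(); rows <- list()
  for (g in genes) {
    ex <- expression[g, shared]
    if (stats::sd(ex) == 0 || anyNA(ex)) {
      skipped[[g]] <- data.frame(gene = g, reason = "zero-variance or missing expression")
      next
    }
    cand <- a$probe_id[a$gene_symbol == g]
    r <- vapply(cand, function(p) {
      b <- betas[p, shared]
      if (stats::sd(b, na.rm = TRUE) == 0) return(NA_real_)
      stats::cor(b, ex, use = "complete.obs")
    }, numeric(1))
    if (all(is.na(r))) {
      if (length(cand) == 1L) {
        pick <- cand
      } else {
        skipped[[g]] <- data.frame(gene = g, reason = "no computable correlation")
        next
      }
    } else {
      pick <- cand[which.min(r)]
    }
    rows[[g]] <- betas[pick, , drop = FALSE]
    prov[[g]] <- data.frame(gene = g, chosen_probe = pick,
                            chosen_r = unname(r[pick]),
                            n_candidates = length(cand),
                            all_nonnegative = all(is.na(r)) || min(r, na.rm = TRUE) >= 0)
  }
  gene_betas <- if (length(rows)) {
    m <- do.call(rbind, rows)
    rownames(m) <- names(rows)
    m
  } else {
    matrix(numeric(0), 0, ncol(betas), dimnames = list(NULL, colnames(betas)))
  }
  list(gene_betas = gene_betas,
       provenance = if (length(prov)) do.call(rbind, prov) else
         data.frame(gene = character(0), chosen_probe = character(0),
                    chosen_r = numeric(0), n_candidates = integer(0),
                    all_nonnegative = logical(0)),
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(gene = character(0), reason = character(0)))
}
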