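## pipeline_cli: orchestrate discovery -> validation -> survival ->
## enrichment from a single flat key=value configuration, writing every
## stage's outputs as TSV under a run directory.

#' Read a flat key=value pipeline configuration file
#'
#' Lines are `key=value`; '#' comments and blank lines are ignored. Values
#' `true`/`false` become logical, numeric-looking values numeric.
#'
#' @param path path to the config file.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  if (any(lengths(kv) != 2)) stop("malformed config line(s)", call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- trimws(vapply(kv, `[[`, character(1), 2))
  out <- lapply(vals, function(v) {
    if (v %in% c("true", "TRUE", "True")) return(TRUE)
    if (v %in% c("false", "FALSE", "False")) return(FALSE)
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  })
  names(out) <- keys
  out
}

pipeline_defaults <- function() {
  list(alpha_dm = 0.01, alpha_surv = 0.01, distance = "euclidean",
       max_k = 10, seed = 1, detection_threshold = 0.01,
       skip_peak_normalize = FALSE, n_trees = 200, n_trees_scan = 25,
       use_only_significant = TRUE)
}

#' Run the full signature discovery and evaluation pipeline
#'
#' Stages: preprocess (filter + peak normalization) -> differential
#' methylation (luminal vs TN and HER2p vs TN) -> signature derivation ->
#' hierarchical clustering with purity curve + PCA/linear separation ->
#' tree-ensemble classification (train on discovery, score on validation
#' when provided) -> per-site survival directions, averaged prognostic
#' score and stratification -> Fisher enrichment (when gene sets are
#' provided). When the signature is empty, downstream stages are skipped
#' with a logged notice rather than failing, so null-simulation runs
#' complete. All outputs are TSVs under `out_dir`; re-running an identical
#' config is bit-identical.
#'
#' @param config named list (see [read_pipeline_config()]) or path to a
#'   key=value config file. Required keys: `discovery_betas`, `annotation`,
#'   `receptor_status`, `clinical`, `out_dir`. Optional: `validation_betas`,
#'   `validation_receptor_status`, `detection_p`, `expression`,
#'   `gene_sets`, plus the tuning keys with defaults `alpha_dm` 0.01,
#'   `alpha_surv` 0.01, `distance` euclidean, `max_k` 10, `seed` 1,
#'   `detection_threshold` 0.01, `skip_peak_normalize` false, `n_trees`
#'   200, `n_trees_scan` 25.
#' @return invisibly, a list with the in-memory stage results and the
#'   summary data.frame.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_pipeline_config(config)
  }
  cfg <- utils::modifyList(pipeline_defaults(), config)
  req <- c("discovery_betas", "annotation", "receptor_status", "clinical",
           "out_dir")
  miss <- setdiff(req, names(cfg))
  if (length(miss)) stop("config missing key(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  for (k in c("discovery_betas", "annotation", "receptor_status", "clinical",
              "validation_betas", "validation_receptor_status",
              "detection_p", "expression", "gene_sets")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]])) {
      stop("config path does not exist (", k, "): ", cfg[[k]], call. = FALSE)
    }
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  ## provenance hash covers the analysis-relevant configuration; out_dir is
  ## excluded so identical analyses in different run directories hash alike
  hcfg <- cfg[setdiff(sort(names(cfg)), "out_dir")]
  cfg_string <- paste(names(hcfg), vapply(hcfg, paste, character(1)),
                      sep = "=", collapse = "\n")
  prov <- function(stage) provenance_line(stage, cfg_string)
  note <- function(...) message("[methcap] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  summary_rows <- list()
  add_summary <- function(key, value) {
    summary_rows[[length(summary_rows) + 1]] <<- data.frame(
      key = key, value = as.character(value), stringsAsFactors = FALSE)
  }

  ## ---- inputs -------------------------------------------------------
  res <- list()
  stage("read_inputs", {
    res$betas <- read_beta_matrix(cfg$discovery_betas)
    res$annot <- read_annotation(cfg$annotation)
    rs <- utils::read.delim(text = paste(read_tsv_lines(cfg$receptor_status),
                                         collapse = "\n"),
                            stringsAsFactors = FALSE)
    res$labels <- assign_subtypes(rs)
    res$clinical <- read_clinical(cfg$clinical)
    res$detection_p <- if (!is.null(cfg$detection_p))
      read_real_matrix(cfg$detection_p) else NULL
  })
  res$betas <- res$betas[, intersect(colnames(res$betas), names(res$labels)),
                         drop = FALSE]
  note("discovery: ", nrow(res$betas), " probes x ", ncol(res$betas),
       " labeled samples")

  ## ---- preprocess ---------------------------------------------------
  stage("preprocess", {
    filt <- filter_probes(res$betas, res$annot, res$detection_p,
                          cfg$detection_threshold)
    res$filter_report <- filt$report
    res$betas <- filt$betas
    if (!isTRUE(cfg$skip_peak_normalize)) {
      res$betas <- suppressWarnings(peak_normalize(res$betas))
      attr(res$betas, "peaks") <- NULL
    }
  })
  write_tsv(res$filter_report, file.path(cfg$out_dir, "filter_report.tsv"),
            prov("preprocess"))
  note("retained ", nrow(res$betas), " probes after filtering")

  ## ---- differential methylation + signature -------------------------
  lab <- res$labels[colnames(res$betas)]
  stage("diffmeth", {
    res$lum_vs_tn <- moderated_t_test(res$betas,
                                      names(lab)[lab == "luminal"],
                                      names(lab)[lab == "TN"])
    res$her2_vs_tn <- moderated_t_test(res$betas,
                                       names(lab)[lab == "HER2p"],
                                       names(lab)[lab == "TN"])
    res$signature <- derive_signature(res$lum_vs_tn, res$her2_vs_tn,
                                      alpha = cfg$alpha_dm, annot = res$annot)
  })
  for (nm in c("lum_vs_tn", "her2_vs_tn")) {
    write_tsv(res[[nm]][, c("probe_id", "delta_beta", "t_mod", "p", "p_adj",
                            "direction")],
              file.path(cfg$out_dir, paste0(nm, ".tsv")), prov("diffmeth"))
  }
  write_tsv(res$signature$probes,
            file.path(cfg$out_dir, "signature_probes.tsv"), prov("diffmeth"))
  writeLines(res$signature$genes, file.path(cfg$out_dir, "signature_genes.txt"))
  n_sig <- nrow(res$signature$probes)
  add_summary("n_signature_cpgs", n_sig)
  add_summary("n_signature_hyper", length(res$signature$hyper_cpgs))
  add_summary("n_signature_hypo", length(res$signature$hypo_cpgs))
  add_summary("n_signature_genes", length(res$signature$genes))
  ova <- overall_profile_anova(res$betas, lab)
  add_summary("overall_profile_anova_p", format(ova$p, digits = 6))

  if (n_sig < 2) {
    note("signature empty or too small (", n_sig,
         " probes); downstream stages skipped")
    add_summary("downstream", "skipped: signature too small")
    summary <- do.call(rbind, summary_rows)
    write_tsv(summary, file.path(cfg$out_dir, "summary.tsv"), prov("summary"))
    return(invisible(c(res, list(summary = summary))))
  }

  sig_betas <- res$betas[res$signature$probes$probe_id, , drop = FALSE]
  tn_binary <- factor(ifelse(lab == "TN", "TN", "nonTN"),
                      levels = c("TN", "nonTN"))
  names(tn_binary) <- names(lab)

  ## ---- clustering, purity, PCA --------------------------------------
  stage("cluster_purity", {
    hc <- hierarchical_cluster(sig_betas, distance = cfg$distance)
    res$purity_three <- purity_curve(hc, lab, max_k = cfg$max_k)
    res$purity_binary <- purity_curve(hc, tn_binary, max_k = cfg$max_k)
    res$pca <- pca_project(sig_betas, k = min(3, ncol(sig_betas) - 1))
    res$separation <- linear_separation(res$pca, tn_binary, n_components = 2)
  })
  write_tsv(res$purity_binary$summary,
            file.path(cfg$out_dir, "purity_tn_binary.tsv"), prov("cluster"))
  write_tsv(res$purity_three$summary,
            file.path(cfg$out_dir, "purity_three_class.tsv"), prov("cluster"))
  add_summary("max_cluster_purity_tn_k3",
              format(res$purity_binary$summary$max_cluster_purity[
                min(3, nrow(res$purity_binary$summary))], digits = 4))
  add_summary("pca_linear_separation_accuracy",
              format(res$separation$accuracy, digits = 4))

  ## ---- classification ------------------------------------------------
  stage("classify", {
    res$ensemble <- train_tree_ensemble(t(sig_betas), tn_binary,
                                        seed = cfg$seed,
                                        n_trees = cfg$n_trees,
                                        n_trees_scan = cfg$n_trees_scan)
    add_summary("classifier_oob_error", format(res$ensemble$oob_error,
                                               digits = 4))
    add_summary("classifier_max_leaves", res$ensemble$max_leaves)
    if (!is.null(cfg$validation_betas)) {
      vb <- read_beta_matrix(cfg$validation_betas)
      vrs <- utils::read.delim(
        text = paste(read_tsv_lines(cfg$validation_receptor_status),
                     collapse = "\n"), stringsAsFactors = FALSE)
      vlab <- assign_subtypes(vrs)
      shared_probes <- intersect(rownames(vb), res$signature$probes$probe_id)
      vb <- vb[shared_probes, intersect(colnames(vb), names(vlab)),
               drop = FALSE]
      vt <- factor(ifelse(vlab[colnames(vb)] == "TN", "TN", "nonTN"),
                   levels = c("TN", "nonTN"))
      names(vt) <- colnames(vb)
      feats <- t(vb)[, res$ensemble$feature_names, drop = FALSE]
      scores <- predict_scores(res$ensemble, feats)
      res$validation_scores <- scores
      roc <- roc_auc(scores, vt)
      res$validation_auc <- roc$auc
      pred <- ifelse(scores >= 0.5, "TN", "nonTN")
      cm <- confusion_counts(pred, vt)
      met <- confusion_metrics(cm$tp, cm$fn, cm$fp, cm$tn)
      res$validation_report <- data.frame(
        tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn,
        f1_tn = met$f1_tn, f1_nontn = met$f1_nontn, mcc = met$mcc,
        auc = roc$auc, n_correct = met$n_correct)
      write_tsv(res$validation_report,
                file.path(cfg$out_dir, "classifier_report.tsv"),
                prov("classify"))
      write_tsv(roc$roc, file.path(cfg$out_dir, "roc_points.tsv"),
                prov("classify"))
      add_summary("validation_auc", format(roc$auc, digits = 4))
      add_summary("validation_f1_tn", format(met$f1_tn, digits = 4))
    }
  })

  ## ---- survival -------------------------------------------------------
  stage("survival", {
    cl <- res$clinical[res$clinical$sample_id %in% colnames(sig_betas), ]
    sb <- sig_betas[, cl$sample_id, drop = FALSE]
    res$directions <- site_directions(sb, cl, alpha = cfg$alpha_surv)
    n_signif <- sum(res$directions$significant)
    add_summary("n_prognostic_sites", n_signif)
    use_sig <- isTRUE(cfg$use_only_significant) && n_signif > 0
    if (nrow(res$directions) > 0 && (n_signif > 0 || !cfg$use_only_significant)) {
      res$scores <- prognostic_scores(sb, res$directions,
                                      use_only_significant = use_sig)
      write_tsv(res$scores, file.path(cfg$out_dir, "prognostic_scores.tsv"),
                prov("survival"))
      if (stats::sd(res$scores$score) > 0) {
        res$stratification <- stratify_and_test(res$scores, cl)
        write_tsv(res$stratification$km,
                  file.path(cfg$out_dir, "km_curves.tsv"), prov("survival"))
        add_summary("stratification_logrank_p",
                    format(res$stratification$logrank_p, digits = 6))
        add_summary("stratification_hr",
                    format(res$stratification$hr, digits = 4))
      } else {
        note("prognostic scores constant; stratification skipped")
        add_summary("stratification", "skipped: constant scores")
      }
    } else {
      note("no significant prognostic sites; survival scoring skipped")
      add_summary("stratification", "skipped: no prognostic sites")
    }
    write_tsv(res$directions, file.path(cfg$out_dir, "site_directions.tsv"),
              prov("survival"))
  })

  ## ---- enrichment -----------------------------------------------------
  if (!is.null(cfg$gene_sets) && length(res$signature$genes)) {
    stage("enrichment", {
      universe <- sort(unique(res$annot$gene_symbol[
        res$annot$probe_id %in% rownames(res$betas) &
          res$annot$gene_symbol != ""]))
      coll <- read_gmt(cfg$gene_sets, universe)
      res$enrichment <- fisher_enrich(res$signature$genes, coll)
      write_tsv(res$enrichment[, setdiff(names(res$enrichment), "genes")],
                file.path(cfg$out_dir, "enrichment.tsv"), prov("enrich"))
      add_summary("top_enriched_set",
                  if (nrow(res$enrichment)) res$enrichment$set_id[1] else "")
    })
  }

  summary <- do.call(rbind, summary_rows)
  write_tsv(summary, file.path(cfg$out_dir, "summary.tsv"), prov("summary"))
  note("pipeline complete; outputs in ", cfg$out_dir)
  invisible(c(res, list(summary = summary)))
}
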