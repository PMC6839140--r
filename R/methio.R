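## methio: file formats and subtype assignment.
##
## All files are plain TSV with an explicit dialect: tab separator, no
## quoting, '#'-prefixed comment lines ignored. Missing beta entries are
## written as "null" and read back as NA ("NA" and empty cells also parse
## as missing).

#' Read a probes x samples beta-value matrix from TSV
#'
#' First column holds probe identifiers, the header row holds sample
#' identifiers. Empty cells and the tokens `null`/`NA` become `NA`. Input
#' ordering of probes and samples is preserved.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix (probes x samples) with dimnames; `NA` for missing.
#' @export
read_beta_matrix <- function(path) {
  lines <- read_tsv_lines(path)
  if (!length(lines)) stop("empty beta matrix file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  sample_ids <- header[-1]
  ncol_expected <- length(header)
  body <- fields[-1]
  if (!length(body)) {
    m <- matrix(numeric(0), nrow = 0, ncol = length(sample_ids),
                dimnames = list(character(0), sample_ids))
    return(m)
  }
  nf <- lengths(body)
  ## trailing empty fields are dropped by strsplit; re-pad rows that end in
  ## tabs, but flag genuinely ragged rows with their line number
  bad <- which(nf != ncol_expected)
  for (i in bad) {
    raw <- lines[i + 1L]
    ntab <- lengths(regmatches(raw, gregexpr("\t", raw, fixed = TRUE)))
    if (ntab + 1L == ncol_expected) {
      body[[i]] <- c(body[[i]], rep("", ncol_expected - nf[i]))
    } else {
      stop("ragged row at line ", i + 1L, " of ", path, ": expected ",
           ncol_expected, " fields, found ", ntab + 1L, call. = FALSE)
    }
  }
  probe_ids <- vapply(body, `[[`, character(1), 1L)
  cells <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  cells[cells %in% c("", "null", "NA")] <- NA_character_
  vals <- suppressWarnings(as.numeric(cells))
  bad_num <- which(is.na(vals) & !is.na(cells))
  if (length(bad_num)) {
    stop("non-numeric beta value '", cells[bad_num[1]], "' in ", path,
         call. = FALSE)
  }
  m <- matrix(vals, nrow = length(body), ncol = length(sample_ids),
              byrow = TRUE, dimnames = list(probe_ids, sample_ids))
  oob <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(oob)) {
    stop("beta value out of [0,1] at probe ", probe_ids[oob[1, 1]],
         ", sample ", sample_ids[oob[1, 2]], ": ", m[oob[1, , drop = FALSE]],
         call. = FALSE)
  }
  assert_beta_matrix(m)
  m
}

#' Write a beta-value matrix to TSV
#'
#' Inverse of [read_beta_matrix()]; `NA` entries are written as `null`.
#'
#' @param betas probes x samples numeric matrix with dimnames.
#' @param path output path.
#' @param provenance optional provenance string written as a comment line.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(betas, path, provenance = NULL) {
  assert_beta_matrix(betas)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  writeLines(paste(c("probe_id", colnames(betas)), collapse = "\t"), con)
  if (nrow(betas)) {
    chr <- format(betas, trim = TRUE, digits = 17)
    chr[is.na(betas)] <- "null"
    writeLines(paste(rownames(betas), apply(chr, 1, paste, collapse = "\t"),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Assign breast cancer subtypes from receptor status
#'
#' Immunohistochemistry rule: ER+ or PR+ (any HER2) is luminal;
#' ER-PR-HER2+ is HER2p; ER-PR-HER2- is TN. Samples whose deciding markers
#' are unknown are excluded (HER2 status is only deciding when ER and PR are
#' both negative).
#'
#' @param receptor_status data.frame with columns `sample_id`, `er`, `pr`,
#'   `her2`, each status one of `"+"`, `"-"`, `"unknown"` (or `NA`).
#' @return named factor (levels TN, HER2p, luminal) over the classifiable
#'   samples; excluded samples and their reasons are attached as attribute
#'   `"excluded"` (data.frame sample_id, reason).
#' @export
assign_subtypes <- function(receptor_status) {
  req <- c("sample_id", "er", "pr", "her2")
  if (!all(req %in% names(receptor_status))) {
    stop("receptor_status needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  norm <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- "unknown"
    if (!all(x %in% c("+", "-", "unknown"))) {
      stop("receptor status values must be '+', '-' or 'unknown'",
           call. = FALSE)
    }
    x
  }
  er <- norm(receptor_status$er)
  pr <- norm(receptor_status$pr)
  her2 <- norm(receptor_status$her2)
  id <- as.character(receptor_status$sample_id)

  cls <- rep(NA_character_, length(id))
  reason <- rep(NA_character_, length(id))
  for (i in seq_along(id)) {
    if (er[i] == "+" || pr[i] == "+") {
      cls[i] <- "luminal"
    } else if (er[i] == "unknown" || pr[i] == "unknown") {
      reason[i] <- "ER or PR status unknown with no positive marker"
    } else if (her2[i] == "+") {
      cls[i] <- "HER2p"
    } else if (her2[i] == "-") {
      cls[i] <- "TN"
    } else {
      reason[i] <- "HER2 status unknown for ER-/PR- sample"
    }
  }
  keep <- !is.na(cls)
  labels <- factor(cls[keep], levels = SUBTYPE_LEVELS)
  names(labels) <- id[keep]
  attr(labels, "excluded") <- data.frame(sample_id = id[!keep],
                                         reason = reason[!keep],
                                         stringsAsFactors = FALSE)
  labels
}

#' Read a clinical survival table from TSV
#'
#' Expects columns `sample_id`, `os_months`, `os_event`. Ten-year capping is
#' applied at read time: times above 120 months become 120 with the event
#' indicator set to 0 (the event, if any, happened outside the analysis
#' window), so every downstream survival computation sees capped data.
#'
#' @param path path to the TSV file.
#' @param cap_months analysis horizon in months (default 120 = 10 years).
#' @return data.frame with columns sample_id, time, event.
#' @export
read_clinical <- function(path, cap_months = 120) {
  lines <- read_tsv_lines(path)
  if (!length(lines)) stop("empty clinical file: ", path, call. = FALSE)
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE)
  req <- c("sample_id", "os_months", "os_event")
  if (!all(req %in% names(df))) {
    stop("clinical file needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(sample_id = as.character(df$sample_id),
                    time = as.numeric(df$os_months),
                    event = as.integer(df$os_event),
                    stringsAsFactors = FALSE)
  cap_survival(out, cap_months)
}

#' Apply the 10-year analysis horizon to a survival table
#'
#' @param clinical data.frame with columns sample_id, time, event.
#' @param cap_months horizon; times beyond it are administratively censored.
#' @return capped data.frame.
#' @export
cap_survival <- function(clinical, cap_months = 120) {
  if (any(is.na(clinical$time)) || any(clinical$time <= 0)) {
    stop("survival times must be positive and non-missing", call. = FALSE)
  }
  if (!all(clinical$event %in% c(0L, 1L))) {
    stop("event indicator must be 0 or 1", call. = FALSE)
  }
  over <- clinical$time > cap_months
  clinical$event[over] <- 0L
  clinical$time[over] <- cap_months
  clinical
}

#' Write a clinical survival table to TSV
#'
#' @param clinical data.frame with columns sample_id, time, event.
#' @param path output path.
#' @param provenance optional provenance comment line.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path, provenance = NULL) {
  df <- data.frame(sample_id = clinical$sample_id,
                   os_months = clinical$time,
                   os_event = clinical$event)
  write_tsv(df, path, provenance)
}

#' Read probe annotation from TSV
#'
#' Columns: probe_id, gene_symbol (may be empty), chromosome, snp_flag,
#' crossreactive_flag (flags 0/1).
#'
#' @param path path to the TSV file.
#' @return data.frame, one row per probe.
#' @export
read_annotation <- function(path) {
  lines <- read_tsv_lines(path)
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE,
                          colClasses = c(probe_id = "character",
                                         gene_symbol = "character",
                                         chromosome = "character"))
  req <- c("probe_id", "gene_symbol", "chromosome", "snp_flag",
           "crossreactive_flag")
  if (!all(req %in% names(df))) {
    stop("annotation needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$probe_id)) {
    stop("duplicated probe_id in annotation", call. = FALSE)
  }
  df$gene_symbol[is.na(df$gene_symbol)] <- ""
  df
}

#' Write probe annotation to TSV
#'
#' @param annot data.frame as returned by [read_annotation()].
#' @param path output path.
#' @param provenance optional provenance comment line.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annot, path, provenance = NULL) {
  write_tsv(annot, path, provenance)
}
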