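## Internal helpers shared across modules.

SUBTYPE_LEVELS <- c("TN", "HER2p", "luminal")

#' Convert beta values to M values
#'
#' M = log2(beta / (1 - beta)). Values are clamped away from 0 and 1 so the
#' transform stays finite.
#'
#' @param beta numeric vector or matrix of methylation fractions in \[0, 1\].
#' @param eps clamp margin.
#' @return same shape as `beta`, on the M scale.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Convert M values back to beta values
#'
#' @param m numeric vector or matrix on the M scale.
#' @return methylation fractions in (0, 1).
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}

## Round half away from zero to `digits` decimals (display convention for
## confusion-matrix metrics; base round() is round-half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Validate a probes x samples beta matrix: numeric, dimnames present and
## unique, finite entries in [0, 1] (NA allowed).
assert_beta_matrix <- function(x, what = "beta matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if ((nrow(x) > 0 && is.null(rownames(x))) ||
      (ncol(x) > 0 && is.null(colnames(x)))) {
    stop(what, " must carry probe rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) stop(what, ": duplicated probe ids", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop(what, ": duplicated sample ids", call. = FALSE)
  v <- x[!is.na(x)]
  if (length(v) && (min(v) < 0 || max(v) > 1)) {
    stop(what, ": values outside [0, 1]", call. = FALSE)
  }
  invisible(x)
}

## Deterministic 32-bit FNV-1a hash of a character scalar, as hex. Used for
## provenance headers so outputs are diffable across identical configs.
## The prime multiply is decomposed as 16777619 = 2^24 + 2^8 + 0x93 to stay
## exact in double arithmetic.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 0x811c9dc5
  for (b in bytes) {
    ## xor touches only the low byte, keeping h representable as a double
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    h <- (h * 0x93 + h * 256 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## Write a data.frame as headered TSV with optional provenance comment lines.
write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(paste0("# ", provenance), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

## Read all non-comment lines of a TSV, split on tab. No quoting dialect.
read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines[!startsWith(lines, "#")]
}

provenance_line <- function(stage, config_string) {
  paste0("methcap stage=", stage, " config_hash=", fnv1a32(config_string))
}
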