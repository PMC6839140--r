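## enrichment: one-sided Fisher's exact (hypergeometric tail)
## over-representation of a query gene list against a gene-set collection,
## with BH FDR and the GeneRatio (hits / query size).

#' Build a gene-set collection
#'
#' @param sets named list of character vectors (set members).
#' @param universe background gene symbols; set members outside it are
#'   dropped.
#' @param names optional descriptive names per set id.
#' @return list of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe, names = NULL) {
  if (!length(universe)) stop("universe is empty", call. = FALSE)
  universe <- unique(as.character(universe))
  if (is.null(base::names(sets)) || anyDuplicated(base::names(sets))) {
    stop("sets must have unique names", call. = FALSE)
  }
  sets <- lapply(sets, function(s) intersect(unique(as.character(s)), universe))
  structure(list(sets = sets, universe = universe,
                 set_names = if (is.null(names))
                   setNames(base::names(sets), base::names(sets)) else names),
            class = "gene_set_collection")
}

#' Read a gene-set collection from a GMT file
#'
#' One set per line: set_id, description, then member genes, tab-separated.
#'
#' @param path path to the GMT file.
#' @param universe background gene symbols.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, universe) {
  lines <- read_tsv_lines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, function(f) if (length(f) >= 2) f[[2]] else "",
                 character(1))
  sets <- lapply(fields, function(f) if (length(f) > 2) f[-(1:2)] else character(0))
  names(sets) <- ids
  gene_set_collection(sets, universe, names = setNames(desc, ids))
}

#' Fisher's exact over-representation analysis
#'
#' For each set, with N = universe size, K = set size, n = query size (in
#' universe) and k = hits, the one-sided p-value is the hypergeometric
#' upper tail P(X >= k). BH adjustment is applied across all tested sets;
#' rows are sorted by adjusted then raw p. GeneRatio is k / n. Query genes
#' outside the universe are dropped (recorded in attribute `"dropped"`).
#'
#' @param query_genes character vector of genes of interest.
#' @param collection a [gene_set_collection()].
#' @param alpha significance threshold on the raw p (default 0.01).
#' @return data.frame with set_id, name, k, K, n, N, gene_ratio, p, p_adj,
#'   significant, genes (comma-joined hits).
#' @export
fisher_enrich <- function(query_genes, collection, alpha = 0.01) {
  uni <- collection$universe
  q <- unique(as.character(query_genes))
  dropped <- setdiff(q, uni)
  q <- intersect(q, uni)
  if (!length(q)) stop("query has no genes in the universe", call. = FALSE)
  N <- length(uni); n <- length(q)
  rows <- lapply(names(collection$sets), function(id) {
    members <- collection$sets[[id]]
    K <- length(members)
    hits <- intersect(q, members)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, name = unname(collection$set_names[id]),
               k = k, K = K, n = n, N = N, gene_ratio = k / n, p = p,
               genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p < alpha
  out <- out[order(out$p_adj, out$p, out$set_id), ]
  rownames(out) <- NULL
  out <- out[, c("set_id", "name", "k", "K", "n", "N", "gene_ratio", "p",
                 "p_adj", "significant", "genes")]
  attr(out, "dropped") <- dropped
  out
}
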