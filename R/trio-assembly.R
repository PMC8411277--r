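# Steps 2-3 of the pipeline: map interaction hits through the
# enhancer:gene association table, score miRNA-gene Spearman correlation,
# control the FDR per miRNA family (Benjamini-Hochberg), and write the
# trio table.

#' Expand interaction hits into (miRNA, gene, enhancer) candidates
#'
#' Each hit is expanded over all genes linked to its enhancer.  Hits on
#' enhancers absent from the link table are skipped; the number skipped is
#' attached as the `"n_unlinked"` attribute and reported via a message.
#'
#' @param hits data.frame of deduplicated hits (family, mature_mirna,
#'   enhancer_id, method, and pi when present).
#' @param links data.frame from [read_enhancer_gene_links()].
#' @return data.frame of unique candidates: family, mature_mirna,
#'   gene_name, enhancer_id, method, pi.
#' @export
hits_to_candidates <- function(hits, links) {
  if (is.null(hits$pi)) hits$pi <- NA_real_
  keep_cols <- c("family", "mature_mirna", "enhancer_id", "method", "pi")
  hits <- hits[, keep_cols, drop = FALSE]
  linked <- hits$enhancer_id %in% links$enhancer_id
  n_unlinked <- sum(!linked)
  if (n_unlinked > 0L) {
    message(sprintf("%d hit(s) on enhancers absent from the link table skipped",
                    n_unlinked))
  }
  out <- merge(hits[linked, , drop = FALSE], links, by = "enhancer_id")
  out <- out[, c("family", "mature_mirna", "gene_name", "enhancer_id",
                 "method", "pi"), drop = FALSE]
  out <- out[!duplicated(out[, c("mature_mirna", "gene_name", "enhancer_id",
                                 "method")]), , drop = FALSE]
  out <- out[order(out$mature_mirna, out$enhancer_id, out$gene_name), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unlinked") <- n_unlinked
  out
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' rho is the Pearson correlation of average ranks (ties handled by
#' midranks); the two-sided p-value uses the t approximation with n-2
#' degrees of freedom.  For rho == +/-1 the p-value is set to the smallest
#' positive double.  Zero variance in either vector yields rho = NA
#' (callers drop such candidates).
#'
#' @param x,y Numeric vectors of equal length (n >= 3 for a p-value).
#' @return list with elements rho and p.
#' @export
spearman_scc <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    stop("expression vectors must be finite with no missing values")
  }
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero variance vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1 - 1e-12) {
    return(list(rho = sign(rho), p = .Machine$double.xmin))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Benjamini-Hochberg adjustment within miRNA-family groups
#'
#' Candidates are grouped by family; within each group of size m the
#' standard step-up adjustment is applied:
#' `p_adj(i) = min_{j >= i} (m * p(j) / j)`, capped at 1.  m is the number
#' of candidate gene pairs of that miRNA family, not the global count.
#'
#' @param candidates data.frame with columns family and p_raw.
#' @return `candidates` with a p_adj column added.
#' @export
bh_adjust_per_mirna <- function(candidates) {
  p_adj <- rep(NA_real_, nrow(candidates))
  for (fam in unique(candidates$family)) {
    idx <- which(candidates$family == fam)
    p_adj[idx] <- stats::p.adjust(candidates$p_raw[idx], method = "BH")
  }
  candidates$p_adj <- p_adj
  candidates
}

#' Assemble miRNA-enhancer-gene trios
#'
#' For every candidate, the expression of the miRNA family is correlated
#' (Spearman) with the expression of the gene across samples; p-values are
#' BH-adjusted per miRNA family and trios with `p_adj < fdr` are kept.
#' With `positive_only = TRUE` (the default; the method models activation)
#' the correlation must also be positive.  Candidates whose miRNA or gene
#' is absent from its expression table, or whose expression has zero
#' variance, are dropped and counted in attributes.
#'
#' @param candidates data.frame from [hits_to_candidates()].
#' @param mirna_expr Matrix, miRNA families x samples.
#' @param gene_expr Matrix, genes x samples (same sample order).
#' @param fdr FDR threshold (default 0.05).
#' @param positive_only Require scc > 0 (default TRUE).
#' @param min_samples Minimum sample count (default 8).
#' @return data.frame of trios: family, mature_mirna, gene_name,
#'   enhancer_id, scc, p_raw, p_adj, pi, method.  Attributes n_missing and
#'   n_degenerate count dropped candidates.
#' @export
assemble_trios <- function(candidates, mirna_expr, gene_expr, fdr = 0.05,
                           positive_only = TRUE, min_samples = 8L) {
  check_expression_compat(mirna_expr, gene_expr, min_samples)
  empty <- data.frame(family = character(0), mature_mirna = character(0),
                      gene_name = character(0), enhancer_id = character(0),
                      scc = numeric(0), p_raw = numeric(0), p_adj = numeric(0),
                      pi = numeric(0), method = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(candidates) == 0L) {
    attr(empty, "n_missing") <- 0L
    attr(empty, "n_degenerate") <- 0L
    return(empty)
  }
  present <- candidates$family %in% rownames(mirna_expr) &
    candidates$gene_name %in% rownames(gene_expr)
  n_missing <- sum(!present)
  if (n_missing > 0L) {
    message(sprintf("%d candidate(s) missing from expression tables dropped",
                    n_missing))
  }
  cand <- candidates[present, , drop = FALSE]
  scc <- p_raw <- rep(NA_real_, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    res <- suppressWarnings(
      spearman_scc(mirna_expr[cand$family[i], ], gene_expr[cand$gene_name[i], ]))
    scc[i] <- res$rho
    p_raw[i] <- res$p
  }
  degenerate <- is.na(scc)
  n_degenerate <- sum(degenerate)
  if (n_degenerate > 0L) {
    warning(sprintf("%d candidate(s) with zero-variance expression dropped",
                    n_degenerate))
  }
  cand <- cand[!degenerate, , drop = FALSE]
  cand$scc <- scc[!degenerate]
  cand$p_raw <- p_raw[!degenerate]
  if (nrow(cand) > 0L) {
    cand <- bh_adjust_per_mirna(cand)
    keep <- cand$p_adj < fdr
    if (positive_only) keep <- keep & cand$scc > 0
    cand <- cand[keep, , drop = FALSE]
  } else {
    cand$p_adj <- numeric(0)
  }
  out <- cand[, c("family", "mature_mirna", "gene_name", "enhancer_id",
                  "scc", "p_raw", "p_adj", "pi", "method"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_missing") <- n_missing
  attr(out, "n_degenerate") <- n_degenerate
  out
}

TRIO_FILE <- "mir_enh_gene_trios.tsv"

#' Write / read the trio table
#'
#' The output schema is: `mature_mirna`, `Gene.Name`, `enhancer`,
#' `corr (miRNA, gene)`, `p.value adj`, and a final `PI` column present
#' only when the trios come from the seed_match_needle approach.
#'
#' @param records data.frame from [assemble_trios()].
#' @param path Output file path.
#' @param with_pi Include the PI column; defaults to TRUE when any record
#'   has method `"seed_needle"`.
#' @return `path`, invisibly.
#' @export
write_trios <- function(records, path,
                        with_pi = any(records$method == "seed_needle")) {
  out <- data.frame(
    mature_mirna = records$mature_mirna,
    `Gene.Name` = records$gene_name,
    enhancer = records$enhancer_id,
    `corr (miRNA, gene)` = records$scc,
    `p.value adj` = records$p_adj,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  if (isTRUE(with_pi)) out$PI <- records$pi
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @param path Path to a trio TSV.
#' @return `read_trios` returns a data.frame with the internal column
#'   names (mature_mirna, gene_name, enhancer_id, scc, p_adj, and pi when
#'   present).
#' @rdname write_trios
#' @export
read_trios <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  out <- data.frame(
    mature_mirna = as.character(df[["mature_mirna"]]),
    gene_name = as.character(df[["Gene.Name"]]),
    enhancer_id = as.character(df[["enhancer"]]),
    scc = df[["corr (miRNA, gene)"]],
    p_adj = df[["p.value adj"]],
    stringsAsFactors = FALSE
  )
  if ("PI" %in% names(df)) out$pi <- df[["PI"]]
  out
}
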