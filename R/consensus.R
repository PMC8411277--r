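# Use-case consensus logic: combine the duplex detection methods and the
# two promoter-aggregation modes, require multi-gene enhancers, and rescue
# highly correlated pairs.

#' Gene-expression proxy from promoter-level expression
#'
#' Promoter-level quantification (e.g. CAGE) gives several expression rows
#' per gene.  Two proxies for gene expression are supported:
#' `best_promoter` picks the promoter row with the highest Spearman
#' correlation with the given miRNA vector (ties: first promoter in input
#' order); `sum_promoters` sums expression over promoters per sample.
#'
#' @param promoter_matrix Numeric matrix, promoters x samples, for one gene.
#' @param mirna_vector miRNA expression across the same samples (required
#'   for `best_promoter`).
#' @param mode `"best_promoter"` or `"sum_promoters"`.
#' @return Numeric vector of length ncol(promoter_matrix).
#' @export
gene_expression_proxy <- function(promoter_matrix, mirna_vector = NULL,
                                  mode = c("best_promoter", "sum_promoters")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(promoter_matrix), nrow(promoter_matrix) >= 1L)
  if (mode == "sum_promoters") {
    return(colSums(promoter_matrix))
  }
  if (is.null(mirna_vector)) {
    stop("best_promoter mode requires the miRNA expression vector")
  }
  sccs <- apply(promoter_matrix, 1L, function(row) {
    suppressWarnings(spearman_scc(row, mirna_vector)$rho)
  })
  sccs[is.na(sccs)] <- -Inf
  promoter_matrix[which.max(sccs), ]
}

.trio_key <- function(trios) {
  paste(trios$mature_mirna, trios$gene_name, trios$enhancer_id, sep = "\r")
}

.pair_key <- function(trios) {
  paste(trios$mature_mirna, trios$gene_name, sep = "\r")
}

.multi_gene_enhancers <- function(links, min_genes = 2L) {
  tab <- tapply(links$gene_name, links$enhancer_id,
                function(g) length(unique(g)))
  names(tab)[tab >= min_genes]
}

#' Consensus over duplex-based trios
#'
#' Combines the four trio sets that result from crossing the two duplex
#' detection methods (seed-match/alignment and miRanda) with the two
#' promoter-aggregation modes (a = best promoter, b = summed promoters).
#' A trio is kept when all of the following hold:
#' (1) its miRNA:enhancer duplex is predicted by both methods;
#' (2) its enhancer is linked to at least `min_genes` distinct genes in
#'     the association table;
#' (3) its miRNA-gene pair is present under both aggregation modes.
#' Independently, any trio from any of the four sets with
#' `scc >= scc_rescue` is added back (unconditional union).
#' With `rescue_min_enhancers` set, trios whose miRNA-gene pair is
#' supported by at least that many distinct enhancers (across the four
#' sets) bypass requirement (3).
#'
#' @param trios_needle_a,trios_needle_b,trios_miranda_a,trios_miranda_b
#'   Trio data.frames (columns mature_mirna, gene_name, enhancer_id, scc).
#' @param links Enhancer:gene association table.
#' @param scc_rescue Correlation threshold for the rescue union
#'   (default 0.8).
#' @param min_genes Multi-gene requirement (default 2).
#' @param rescue_min_enhancers Optional integer; `Inf` disables (default).
#' @return data.frame of consensus trios (unique mature_mirna, gene_name,
#'   enhancer_id rows, with the maximal scc observed across input sets).
#' @export
consensus_duplex <- function(trios_needle_a, trios_needle_b,
                             trios_miranda_a, trios_miranda_b,
                             links, scc_rescue = 0.8, min_genes = 2L,
                             rescue_min_enhancers = Inf) {
  sets <- list(needle_a = trios_needle_a, needle_b = trios_needle_b,
               miranda_a = trios_miranda_a, miranda_b = trios_miranda_b)
  all_trios <- do.call(rbind, lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    if (nrow(s) == 0L) {
      return(data.frame(mature_mirna = character(0), gene_name = character(0),
                        enhancer_id = character(0), scc = numeric(0),
                        set = character(0), stringsAsFactors = FALSE))
    }
    data.frame(mature_mirna = s$mature_mirna, gene_name = s$gene_name,
               enhancer_id = s$enhancer_id, scc = s$scc, set = nm,
               stringsAsFactors = FALSE)
  }))
  if (nrow(all_trios) == 0L) {
    return(all_trios[, c("mature_mirna", "gene_name", "enhancer_id", "scc")])
  }

  duplex_key <- function(df) paste(df$mature_mirna, df$enhancer_id, sep = "\r")
  needle <- all_trios[all_trios$set %in% c("needle_a", "needle_b"), ]
  miranda <- all_trios[all_trios$set %in% c("miranda_a", "miranda_b"), ]
  both_methods <- intersect(unique(duplex_key(needle)),
                            unique(duplex_key(miranda)))

  mode_a <- all_trios[all_trios$set %in% c("needle_a", "miranda_a"), ]
  mode_b <- all_trios[all_trios$set %in% c("needle_b", "miranda_b"), ]
  both_modes <- intersect(unique(.pair_key(mode_a)), unique(.pair_key(mode_b)))

  multi <- .multi_gene_enhancers(links, min_genes)

  pair_enh_count <- tapply(all_trios$enhancer_id, .pair_key(all_trios),
                           function(e) length(unique(e)))
  bypass_pairs <- names(pair_enh_count)[pair_enh_count >= rescue_min_enhancers]

  keep <- duplex_key(all_trios) %in% both_methods &
    all_trios$enhancer_id %in% multi &
    (.pair_key(all_trios) %in% both_modes |
       .pair_key(all_trios) %in% bypass_pairs)
  rescued <- all_trios$scc >= scc_rescue
  out <- all_trios[keep | rescued, , drop = FALSE]
  if (nrow(out) == 0L) {
    return(out[, c("mature_mirna", "gene_name", "enhancer_id", "scc")])
  }
  # one row per trio; keep the maximal scc seen across the input sets
  out <- out[order(.trio_key(out), -out$scc), , drop = FALSE]
  out <- out[!duplicated(.trio_key(out)), , drop = FALSE]
  out <- out[order(out$mature_mirna, out$gene_name, out$enhancer_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("mature_mirna", "gene_name", "enhancer_id", "scc")]
}

#' Consensus over triplex-based trios
#'
#' Keeps trios that (1) lie on an enhancer associated with at least
#' `min_genes` distinct genes and (2) are found under both
#' promoter-aggregation modes (a and b).
#'
#' @param trios_a,trios_b Trio data.frames from the two aggregation modes.
#' @param links Enhancer:gene association table.
#' @param min_genes Multi-gene requirement (default 2).
#' @return data.frame of consensus trios with the maximal scc across modes.
#' @export
consensus_triplex <- function(trios_a, trios_b, links, min_genes = 2L) {
  cols <- c("mature_mirna", "gene_name", "enhancer_id", "scc")
  norm <- function(s) {
    if (nrow(s) == 0L) {
      return(data.frame(mature_mirna = character(0), gene_name = character(0),
                        enhancer_id = character(0), scc = numeric(0),
                        stringsAsFactors = FALSE))
    }
    data.frame(mature_mirna = s$mature_mirna, gene_name = s$gene_name,
               enhancer_id = s$enhancer_id, scc = s$scc,
               stringsAsFactors = FALSE)
  }
  a <- norm(trios_a); b <- norm(trios_b)
  in_both <- intersect(.trio_key(a), .trio_key(b))
  multi <- .multi_gene_enhancers(links, min_genes)
  both <- rbind(a, b)
  keep <- .trio_key(both) %in% in_both & both$enhancer_id %in% multi
  out <- both[keep, , drop = FALSE]
  if (nrow(out) == 0L) return(out[, cols])
  out <- out[order(.trio_key(out), -out$scc), , drop = FALSE]
  out <- out[!duplicated(.trio_key(out)), , drop = FALSE]
  out <- out[order(out$mature_mirna, out$gene_name, out$enhancer_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, cols]
}
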