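# Independent oracles used by the property and acceptance tests.  Each one
# recomputes the quantity under test by a different route than the package
# implementation (enumeration, memoized recursion, naive scans, explicit
# set algebra).

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")

# ---- global alignment -------------------------------------------------

# exhaustive enumeration of every gapped global alignment; feasible only
# for tiny sequences (Delannoy growth).  Scores an alignment by summing
# column scores and charging each maximal gap run open + extend * len.
enumerate_align_best <- function(query, target, params) {
  q <- strsplit(query, "")[[1]]
  t <- strsplit(target, "")[[1]]
  score_alignment <- function(aq, at) {
    s <- 0
    run <- NULL  # "q" gap in query, "t" gap in target
    for (k in seq_along(aq)) {
      if (aq[k] == "-") {
        s <- s - params$gap_extend - if (identical(run, "q")) 0 else params$gap_open
        run <- "q"
      } else if (at[k] == "-") {
        s <- s - params$gap_extend - if (identical(run, "t")) 0 else params$gap_open
        run <- "t"
      } else {
        s <- s + if (aq[k] == at[k]) params$match else params$mismatch
        run <- NULL
      }
    }
    s
  }
  best <- -Inf
  rec <- function(i, j, aq, at) {
    if (i > length(q) && j > length(t)) {
      best <<- max(best, score_alignment(aq, at))
      return(invisible())
    }
    if (i <= length(q) && j <= length(t)) rec(i + 1, j + 1, c(aq, q[i]), c(at, t[j]))
    if (i <= length(q)) rec(i + 1, j, c(aq, q[i]), c(at, "-"))
    if (j <= length(t)) rec(i, j + 1, c(aq, "-"), c(at, t[j]))
  }
  rec(1L, 1L, character(0), character(0))
  best
}

# memoized top-down recursion over (i, j, gap-state); same cost model,
# different algorithmic route than the bottom-up matrices in the package.
memo_align_best <- function(query, target, params) {
  q <- strsplit(query, "")[[1]]
  t <- strsplit(target, "")[[1]]
  n <- length(q); m <- length(t)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  go <- function(i, j, state) {
    # best score for aligning q[i..n] vs t[j..m], `state` = gap run we are
    # currently inside ("none", "qgap" = gap in query, "tgap" = gap in target)
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > n && j > m) return(0)
    cand <- -Inf
    if (i <= n && j <= m) {
      s <- if (q[i] == t[j]) params$match else params$mismatch
      cand <- max(cand, s + go(i + 1, j + 1, "none"))
    }
    if (i <= n) {  # q[i] against a gap in the target
      open <- if (state == "tgap") 0 else params$gap_open
      cand <- max(cand, -open - params$gap_extend + go(i + 1, j, "tgap"))
    }
    if (j <= m) {  # t[j] against a gap in the query
      open <- if (state == "qgap") 0 else params$gap_open
      cand <- max(cand, -open - params$gap_extend + go(i, j + 1, "qgap"))
    }
    memo[[key]] <- cand
    cand
  }
  go(1L, 1L, "none")
}

# ---- seed scan --------------------------------------------------------

naive_scan_seed <- function(enhancer_seq, seed_fwd, seed_rc) {
  hits <- list()
  for (form in list(c(seed_fwd, "forward"), c(seed_rc, "reverse_complement"))) {
    pat <- form[1]
    k <- nchar(pat)
    if (nchar(enhancer_seq) < k) next
    for (off in 0:(nchar(enhancer_seq) - k)) {
      if (substr(enhancer_seq, off + 1, off + k) == pat) {
        hits[[length(hits) + 1]] <- data.frame(
          offset = off, orientation = form[2], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    return(data.frame(offset = integer(0), orientation = character(0),
                      stringsAsFactors = FALSE))
  }
  if (seed_rc == seed_fwd) out <- out[out$orientation == "forward", ]
  out <- out[order(out$offset, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- miRanda-style local duplex --------------------------------------

# brute force over all (query substring, target substring) pairs, each
# globally aligned by memoized recursion under the duplex scoring with
# absolute miRNA positions driving the seed scaling.
brute_local_duplex_best <- function(mirna_seq, target_seq, params) {
  mirna_seq <- mirtrio::dna_to_rna(mirna_seq)
  q <- rev(strsplit(mirna_seq, "")[[1]])   # 3'->5'
  t <- strsplit(toupper(target_seq), "")[[1]]
  n <- length(q); m <- length(t)
  colscore <- function(qi, tj) {
    mirna_pos <- n - qi + 1
    wc <- (q[qi] == "A" && t[tj] == "T") || (q[qi] == "U" && t[tj] == "A") ||
      (q[qi] == "G" && t[tj] == "C") || (q[qi] == "C" && t[tj] == "G")
    wob <- (q[qi] == "G" && t[tj] == "T") || (q[qi] == "U" && t[tj] == "G")
    s <- if (wc) params$match_score else if (wob) params$wobble_score
         else params$mismatch_score
    if (mirna_pos %in% params$seed_range) s * params$seed_scale else s
  }
  glob <- function(a1, a2, b1, b2) {
    memo <- new.env(hash = TRUE, parent = emptyenv())
    go <- function(i, j, state) {
      key <- paste(i, j, state)
      if (!is.null(memo[[key]])) return(memo[[key]])
      if (i > a2 && j > b2) return(0)
      cand <- -Inf
      if (i <= a2 && j <= b2) {
        cand <- max(cand, colscore(i, j) + go(i + 1, j + 1, "none"))
      }
      if (i <= a2) {
        open <- if (state == "tgap") 0 else params$gap_open
        cand <- max(cand, open + params$gap_extend + go(i + 1, j, "tgap"))
      }
      if (j <= b2) {
        open <- if (state == "qgap") 0 else params$gap_open
        cand <- max(cand, open + params$gap_extend + go(i, j + 1, "qgap"))
      }
      memo[[key]] <- cand
      cand
    }
    go(a1, b1, "none")
  }
  best <- 0
  for (a1 in 1:n) for (a2 in a1:n) for (b1 in 1:m) for (b2 in b1:m) {
    best <- max(best, glob(a1, a2, b1, b2))
  }
  best
}

# ---- triplex ----------------------------------------------------------

# O(n*m*L) enumerator over motifs, strands, diagonals and windows, using
# cumulative sums per diagonal; maximality is decided by pairwise
# containment checks over the collected window list.
brute_find_triplexes <- function(mirna, enhancer, params) {
  mseq <- mirtrio::dna_to_rna(mirna$mature_seq)
  eseq <- mirtrio::rna_to_dna(enhancer$seq)
  mir <- strsplit(mseq, "")[[1]]
  n <- length(mir)
  m <- nchar(eseq)
  strands <- list(`+` = strsplit(eseq, "")[[1]],
                  `-` = strsplit(mirtrio::reverse_complement(eseq), "")[[1]])
  rows <- list()
  for (motif in params$motifs) {
    tfo <- if (motif == "antiparallel_purine") rev(mir) else mir
    for (strand in names(strands)) {
      pur <- strands[[strand]]
      for (d in (1 - n):(m - 1)) {
        lo <- max(1, 1 - d); hi <- min(n, m - d)
        if (hi - lo + 1 < params$min_length) next
        v <- mirtrio::position_valid(tfo[lo:hi], pur[(lo:hi) + d], motif)
        gd <- pur[(lo:hi) + d] == "G"
        ce <- c(0, cumsum(!v)); cg <- c(0, cumsum(gd))
        wins <- list()
        for (a0 in seq_along(v)) {
          for (b0 in a0:length(v)) {
            len <- b0 - a0 + 1
            if (len < params$min_length) next
            errs <- ce[b0 + 1] - ce[a0]
            g <- cg[b0 + 1] - cg[a0]
            if (errs / len <= params$max_error_rate &&
                g / len >= params$min_guanine_rate) {
              wins[[length(wins) + 1]] <- c(a = lo + a0 - 1, b = lo + b0 - 1,
                                            errs = errs, g = g)
            }
          }
        }
        if (length(wins) == 0) next
        W <- do.call(rbind, wins)
        if (params$merge_overlaps == "maximal_only" && nrow(W) > 1) {
          keep <- rep(TRUE, nrow(W))
          for (i in seq_len(nrow(W))) for (j in seq_len(nrow(W))) {
            if (i != j && W[j, "a"] <= W[i, "a"] && W[j, "b"] >= W[i, "b"] &&
                (W[j, "b"] - W[j, "a"]) > (W[i, "b"] - W[i, "a"])) {
              keep[i] <- FALSE
            }
          }
          W <- W[keep, , drop = FALSE]
        }
        for (r in seq_len(nrow(W))) {
          a <- W[r, "a"]; b <- W[r, "b"]; len <- b - a + 1
          if (motif == "antiparallel_purine") {
            tfo_start <- n - b; tfo_end <- n - a + 1
          } else {
            tfo_start <- a - 1; tfo_end <- b
          }
          if (strand == "+") {
            tts_start <- a + d - 1; tts_end <- b + d
          } else {
            tts_start <- m - (b + d); tts_end <- m - (a + d) + 1
          }
          rows[[length(rows) + 1]] <- data.frame(
            tfo_start = tfo_start, tfo_end = tfo_end,
            tts_start = tts_start, tts_end = tts_end,
            strand = strand, motif = motif, length = len,
            errors = W[r, "errs"], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(tfo_start = integer(0), tfo_end = integer(0),
                      tts_start = integer(0), tts_end = integer(0),
                      strand = character(0), motif = character(0),
                      length = integer(0), errors = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$motif, out$strand, out$tts_start, out$tfo_start, out$length), ,
      drop = FALSE]
}

triplex_hit_key <- function(h) {
  if (nrow(h) == 0) return(character(0))
  sort(paste(h$motif, h$strand, h$tfo_start, h$tfo_end, h$tts_start,
             h$tts_end, h$errors, sep = "|"))
}

# canonical Hoogsteen triplet rules as an explicit 48-entry truth table
# (16 RNA x purine-base pairs x 3 motifs)
hoogsteen_table <- local({
  grid <- expand.grid(rna = c("A", "C", "G", "U"),
                      pur = c("A", "C", "G", "T"), stringsAsFactors = FALSE)
  valid <- list(
    parallel_pyrimidine = c("U|A", "C|G"),
    antiparallel_purine = c("A|A", "G|G"),
    mixed_GT            = c("G|G", "U|A")
  )
  do.call(rbind, lapply(names(valid), function(mo) {
    data.frame(rna = grid$rna, pur = grid$pur, motif = mo,
               valid = paste(grid$rna, grid$pur, sep = "|") %in% valid[[mo]],
               stringsAsFactors = FALSE)
  }))
})

# ---- consensus set algebra -------------------------------------------

make_trio_df <- function(mirna, gene, enhancer, scc) {
  data.frame(mature_mirna = mirna, gene_name = gene, enhancer_id = enhancer,
             scc = scc, stringsAsFactors = FALSE)
}

random_trio_set <- function(n, enh_ids, scc_range = c(-0.5, 0.95)) {
  if (n == 0) return(make_trio_df(character(0), character(0), character(0),
                                  numeric(0)))
  make_trio_df(sprintf("M%d-mat", sample(1:4, n, TRUE)),
               sprintf("G%d", sample(1:5, n, TRUE)),
               sample(enh_ids, n, TRUE),
               round(runif(n, scc_range[1], scc_range[2]), 3))
}

oracle_consensus_duplex <- function(na, nb, ma, mb, links, scc_rescue = 0.8,
                                    min_genes = 2) {
  sets <- list(na = na, nb = nb, ma = ma, mb = mb)
  all <- unique(do.call(rbind, lapply(sets, function(s)
    s[, c("mature_mirna", "gene_name", "enhancer_id")])))
  keep <- character(0)
  key <- function(df) paste(df$mature_mirna, df$gene_name, df$enhancer_id)
  gene_count <- function(e) {
    length(unique(links$gene_name[links$enhancer_id == e]))
  }
  for (i in seq_len(nrow(all))) {
    tr <- all[i, ]
    dk <- function(s) any(s$mature_mirna == tr$mature_mirna &
                            s$enhancer_id == tr$enhancer_id)
    pk <- function(s) any(s$mature_mirna == tr$mature_mirna &
                            s$gene_name == tr$gene_name)
    rule1 <- (dk(na) || dk(nb)) && (dk(ma) || dk(mb))
    rule2 <- gene_count(tr$enhancer_id) >= min_genes
    rule3 <- (pk(na) || pk(ma)) && (pk(nb) || pk(mb))
    rescued <- any(vapply(sets, function(s)
      any(s$mature_mirna == tr$mature_mirna & s$gene_name == tr$gene_name &
            s$enhancer_id == tr$enhancer_id & s$scc >= scc_rescue),
      logical(1)))
    if ((rule1 && rule2 && rule3) || rescued) keep <- c(keep, key(tr))
  }
  sort(keep)
}

oracle_consensus_triplex <- function(a, b, links, min_genes = 2) {
  key <- function(df) paste(df$mature_mirna, df$gene_name, df$enhancer_id)
  inter <- intersect(key(a), key(b))
  both <- unique(rbind(a[, c("mature_mirna", "gene_name", "enhancer_id")],
                       b[, c("mature_mirna", "gene_name", "enhancer_id")]))
  keep <- character(0)
  for (i in seq_len(nrow(both))) {
    tr <- both[i, ]
    if (!(key(tr) %in% inter)) next
    ng <- length(unique(links$gene_name[links$enhancer_id == tr$enhancer_id]))
    if (ng >= min_genes) keep <- c(keep, key(tr))
  }
  sort(keep)
}

# ---- statistics -------------------------------------------------------

mc_perm_spearman_p <- function(x, y, n_perm = 2000) {
  obs <- abs(cor(rank(x), rank(y)))
  hits <- 0
  for (k in seq_len(n_perm)) {
    if (abs(cor(rank(x), rank(sample(y)))) >= obs - 1e-12) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}
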