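# Deterministic generator of complete toy input bundles with planted,
# recoverable signal: a miniature genome, enhancers (BED + FASTA), mature
# miRNAs (multi-FASTA and per-family folders), seed tables, an
# enhancer:gene association table and expression tables.  Every stage of
# the pipeline, and the end-to-end CLI, can be exercised without any
# external download.

#' Fixture configuration
#'
#' Defaults describe a small but realistic world: 24 enhancers of 300 bp
#' on one chromosome, 6 miRNA families (one mature form each), 15 genes,
#' 12 samples, and 3 planted trios (two via a duplex seed site, one via a
#' triplex site) with target Spearman correlation 0.9 between the planted
#' miRNA and its gene.  Everything else is independent noise.
#'
#' @param rng_seed Integer seed; the whole bundle is a deterministic
#'   function of it.
#' @param n_enhancers,enhancer_len,n_mirnas,n_genes,promoters_per_gene,n_samples
#'   World dimensions (`n_samples >= 8`).
#' @param planted_trios data.frame with columns mirna, enhancer, gene
#'   (1-based indices), mechanism (`"seed_site"` / `"triplex_site"`) and
#'   target_scc.
#' @param noise_sd Amplitude of the log-scale expression jitter.  The
#'   jitter is bounded so it never reorders samples: ranks, and therefore
#'   Spearman correlations, are set exactly by the calibrated permutation.
#' @param mature_len Length of generated mature miRNAs (default 21).
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(rng_seed = 1L, n_enhancers = 24L,
                           enhancer_len = 300L, n_mirnas = 6L,
                           n_genes = 15L, promoters_per_gene = 1L,
                           n_samples = 12L,
                           planted_trios = data.frame(
                             mirna = 1:3, enhancer = 1:3, gene = 1:3,
                             mechanism = c("seed_site", "seed_site",
                                           "triplex_site"),
                             target_scc = 0.9,
                             stringsAsFactors = FALSE),
                           noise_sd = 0.25, mature_len = 21L) {
  stopifnot(n_samples >= 8L, n_enhancers >= 1L, n_mirnas >= 1L, n_genes >= 1L)
  if (nrow(planted_trios) > 0L) {
    stopifnot(max(planted_trios$mirna) <= n_mirnas,
              max(planted_trios$enhancer) <= n_enhancers,
              max(planted_trios$gene) <= n_genes)
  }
  if (mature_len > enhancer_len) {
    stop("planted site would be longer than the enhancer")
  }
  structure(list(rng_seed = as.integer(rng_seed), n_enhancers = n_enhancers,
                 enhancer_len = enhancer_len, n_mirnas = n_mirnas,
                 n_genes = n_genes, promoters_per_gene = promoters_per_gene,
                 n_samples = n_samples, planted_trios = planted_trios,
                 noise_sd = noise_sd, mature_len = mature_len),
            class = "fixture_config")
}

.random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# greedy rank calibration: start from a perfectly correlated permutation
# and apply random transpositions, accepting a swap only when it moves the
# Spearman correlation closer to the target.  With n distinct ranks the
# achievable grid is fine enough (adjacent-rank swap: 12/(n^3 - n)) that
# the walk settles within ~0.01 of the target.
.calibrate_ranks <- function(base_rank, target, tol = 0.005,
                             max_iter = 5000L) {
  n <- length(base_rank)
  if (target >= 1) return(base_rank)
  cur <- base_rank
  cur_err <- abs(1 - target)
  for (iter in seq_len(max_iter)) {
    if (cur_err <= tol) break
    ij <- sample.int(n, 2L)
    new <- cur
    new[ij] <- new[rev(ij)]
    new_err <- abs(stats::cor(new, base_rank) - target)
    if (new_err < cur_err) {
      cur <- new
      cur_err <- new_err
    }
  }
  cur
}

# rank vector -> non-negative expression values on a log scale, with a
# rank-preserving jitter (amplitude strictly below half the rank spacing)
.ranks_to_expression <- function(ranks, noise_sd) {
  amp <- min(noise_sd, 0.5) * 0.49
  log2expr <- 1 + 0.5 * ranks + amp * stats::runif(length(ranks), -1, 1)
  round(2^log2expr, 6)
}

#' Generate a complete fixture bundle on disk
#'
#' Writes: `db/chr1.fa` (genome, one chromosome), `enhancers.bed`,
#' `enhancers.fa`, `mature_mirnas.fa` (headers carry `family=` tags),
#' `mature_seqs/<family>/<mature>.fa` (per-family folder layout),
#' `seeds_forward.tsv`, `seeds_reverse.tsv`, `enh_gene.tsv`,
#' `gene_expression.tsv`, `mirna_expression.tsv`, a
#' `promoter_expression.tsv` when `promoters_per_gene > 1`, and
#' `planted_trios.tsv` (the ground truth).
#'
#' Planted signal: a `seed_site` trio embeds the full mature miRNA (as
#' DNA) in its enhancer, so the exact seed occurs and the extension
#' alignment clears the percent-identity threshold, and the miRanda scan
#' sees a perfectly complementary site on the opposite strand; a
#' `triplex_site` trio uses a pyrimidine-rich miRNA and embeds the
#' corresponding purine-strand target (U->A, C->G) in its enhancer.
#' Planted miRNA-gene expression pairs share ranks calibrated to the
#' target Spearman correlation; decoys are independent.
#'
#' @param cfg [fixture_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, file `paths`, and the `truth`
#'   data.frame of planted trios.
#' @export
generate_fixture <- function(cfg, dir) {
  stopifnot(inherits(cfg, "fixture_config"))
  set.seed(cfg$rng_seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "db"), showWarnings = FALSE)

  families <- sprintf("Mir%d", seq_len(cfg$n_mirnas))
  matures <- sprintf("%s-mat", families)
  genes <- sprintf("Gene%02d", seq_len(cfg$n_genes))
  samples <- sprintf("S%02d", seq_len(cfg$n_samples))
  planted <- cfg$planted_trios

  triplex_mirnas <- if (nrow(planted) > 0L) {
    planted$mirna[planted$mechanism == "triplex_site"]
  } else integer(0)

  mature_seq <- vapply(seq_len(cfg$n_mirnas), function(k) {
    if (k %in% triplex_mirnas) {
      # pyrimidine-rich TFO; C fraction keeps the target's guanine rate high
      .random_seq(cfg$mature_len, alphabet = c("U", "U", "C", "C", "U"))
    } else {
      .random_seq(cfg$mature_len, alphabet = c("A", "C", "G", "U"))
    }
  }, character(1))
  seed_fwd <- rna_to_dna(substr(mature_seq, 2L, 8L))
  seed_rc <- reverse_complement(seed_fwd)

  # enhancer sequences with planted sites
  plant_at <- function(seq, site) {
    off <- min(60L, nchar(seq) - nchar(site))
    if (off < 0L) stop("planted site is longer than the enhancer")
    paste0(substr(seq, 1L, off), site,
           substr(seq, off + nchar(site) + 1L, nchar(seq)))
  }
  enh_seq <- vapply(seq_len(cfg$n_enhancers), function(e)
    .random_seq(cfg$enhancer_len), character(1))
  if (nrow(planted) > 0L) {
    for (r in seq_len(nrow(planted))) {
      k <- planted$mirna[r]; e <- planted$enhancer[r]
      site <- if (planted$mechanism[r] == "seed_site") {
        rna_to_dna(mature_seq[k])
      } else {
        # purine-strand triplex target: U -> A, C -> G; other bases random
        chars <- strsplit(mature_seq[k], "")[[1]]
        paste(ifelse(chars == "U", "A",
                     ifelse(chars == "C", "G",
                            sample(c("A", "C", "G", "T"), length(chars),
                                   replace = TRUE))), collapse = "")
      }
      enh_seq[e] <- plant_at(enh_seq[e], site)
    }
  }

  # genome: enhancers tiled along one chromosome with random spacers
  gap <- 50L
  starts <- gap + (seq_len(cfg$n_enhancers) - 1L) * (cfg$enhancer_len + gap)
  ends <- starts + cfg$enhancer_len
  chrom_parts <- character(2L * cfg$n_enhancers + 1L)
  for (e in seq_len(cfg$n_enhancers)) {
    chrom_parts[2L * e - 1L] <- .random_seq(gap)
    chrom_parts[2L * e] <- enh_seq[e]
  }
  chrom_parts[2L * cfg$n_enhancers + 1L] <- .random_seq(gap)
  chrom <- paste(chrom_parts, collapse = "")
  enhancer_id <- format_enhancer_id("chr1", starts, ends)

  # enhancer:gene links (cyclic assignment keeps planted trio r on gene r)
  links <- data.frame(
    enhancer_id = enhancer_id,
    gene_name = genes[(seq_len(cfg$n_enhancers) - 1L) %% cfg$n_genes + 1L],
    stringsAsFactors = FALSE)

  # expression: planted pairs share calibrated ranks; decoys independent
  mir_ranks <- lapply(seq_len(cfg$n_mirnas), function(k) sample.int(cfg$n_samples))
  gene_ranks <- lapply(seq_len(cfg$n_genes), function(g) sample.int(cfg$n_samples))
  if (nrow(planted) > 0L) {
    for (r in seq_len(nrow(planted))) {
      k <- planted$mirna[r]; g <- planted$gene[r]
      gene_ranks[[g]] <- .calibrate_ranks(mir_ranks[[k]], planted$target_scc[r])
    }
  }
  mirna_expr <- t(vapply(mir_ranks, .ranks_to_expression, numeric(cfg$n_samples),
                         noise_sd = cfg$noise_sd))
  rownames(mirna_expr) <- families
  colnames(mirna_expr) <- samples

  npro <- cfg$promoters_per_gene
  if (npro > 1L) {
    pro_rows <- list()
    for (g in seq_len(cfg$n_genes)) {
      for (p in seq_len(npro)) {
        rk <- if (p == 1L) gene_ranks[[g]] else sample.int(cfg$n_samples)
        pro_rows[[sprintf("%s|p%d", genes[g], p)]] <-
          .ranks_to_expression(rk, cfg$noise_sd)
      }
    }
    promoter_expr <- do.call(rbind, pro_rows)
    colnames(promoter_expr) <- samples
    gene_expr <- t(vapply(seq_len(cfg$n_genes), function(g) {
      colSums(promoter_expr[sprintf("%s|p%d", genes[g], seq_len(npro)), ,
                            drop = FALSE])
    }, numeric(cfg$n_samples)))
    rownames(gene_expr) <- genes
    colnames(gene_expr) <- samples
  } else {
    promoter_expr <- NULL
    gene_expr <- t(vapply(gene_ranks, .ranks_to_expression,
                          numeric(cfg$n_samples), noise_sd = cfg$noise_sd))
    rownames(gene_expr) <- genes
    colnames(gene_expr) <- samples
  }

  # --- write the bundle ---
  paths <- list(
    genome_dir = file.path(dir, "db"),
    enhancers_bed = file.path(dir, "enhancers.bed"),
    enhancers_fasta = file.path(dir, "enhancers.fa"),
    mature_fasta = file.path(dir, "mature_mirnas.fa"),
    mature_dirs = file.path(dir, "mature_seqs"),
    seeds_fwd = file.path(dir, "seeds_forward.tsv"),
    seeds_rc = file.path(dir, "seeds_reverse.tsv"),
    links = file.path(dir, "enh_gene.tsv"),
    gene_expr = file.path(dir, "gene_expression.tsv"),
    mirna_expr = file.path(dir, "mirna_expression.tsv"),
    truth = file.path(dir, "planted_trios.tsv")
  )
  write_fasta(c(chr1 = chrom), file.path(dir, "db", "chr1.fa"))
  writeLines(sprintf("chr1\t%d\t%d", starts, ends), paths$enhancers_bed)
  write_fasta(stats::setNames(enh_seq, enhancer_id), paths$enhancers_fasta)
  write_fasta(stats::setNames(
    mature_seq, sprintf("%s family=%s", matures, families)), paths$mature_fasta)
  for (k in seq_len(cfg$n_mirnas)) {
    fd <- file.path(paths$mature_dirs, families[k])
    dir.create(fd, recursive = TRUE, showWarnings = FALSE)
    write_fasta(stats::setNames(mature_seq[k], matures[k]),
                file.path(fd, paste0(matures[k], ".fa")))
  }
  utils::write.table(data.frame(families, seed_fwd), paths$seeds_fwd,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(data.frame(families, seed_rc), paths$seeds_rc,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(links, paths$links, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_expr <- function(m, path) {
    df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = TRUE)
  }
  write_expr(gene_expr, paths$gene_expr)
  write_expr(mirna_expr, paths$mirna_expr)
  if (!is.null(promoter_expr)) {
    paths$promoter_expr <- file.path(dir, "promoter_expression.tsv")
    write_expr(promoter_expr, paths$promoter_expr)
  }

  truth <- if (nrow(planted) > 0L) {
    data.frame(
      family = families[planted$mirna],
      mature_mirna = matures[planted$mirna],
      enhancer_id = enhancer_id[planted$enhancer],
      gene_name = genes[planted$gene],
      mechanism = planted$mechanism,
      target_scc = planted$target_scc,
      stringsAsFactors = FALSE)
  } else {
    data.frame(family = character(0), mature_mirna = character(0),
               enhancer_id = character(0), gene_name = character(0),
               mechanism = character(0), target_scc = numeric(0),
               stringsAsFactors = FALSE)
  }
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(list(dir = dir, paths = paths, truth = truth))
}
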