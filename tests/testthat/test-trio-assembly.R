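mk_hits <- function(mirna, enhancer, method = "miranda", pi = NA_real_,
                    family = sub("-mat$", "", mirna)) {
  data.frame(family = family, mature_mirna = mirna, enhancer_id = enhancer,
             method = method, pi = pi, stringsAsFactors = FALSE)
}

test_that("hits_to_candidates expands hits over linked genes", {
  links <- data.frame(enhancer_id = c("e1", "e1", "e2"),
                      gene_name = c("G1", "G2", "G3"),
                      stringsAsFactors = FALSE)
  hits <- mk_hits("MirA-mat", "e1")
  cand <- hits_to_candidates(hits, links)
  expect_identical(nrow(cand), 2L)
  expect_setequal(cand$gene_name, c("G1", "G2"))

  # unlinked enhancers are skipped and counted
  hits2 <- rbind(hits, mk_hits("MirA-mat", "e9"))
  expect_message(cand2 <- hits_to_candidates(hits2, links), "1 hit")
  expect_identical(attr(cand2, "n_unlinked"), 1L)
  expect_identical(nrow(cand2), 2L)
})

test_that("candidate count equals sum over hits of linked gene counts", {
  set.seed(401)
  for (k in 1:20) {
    n_enh <- sample(3:8, 1)
    enh_ids <- sprintf("e%d", 1:n_enh)
    links <- data.frame(
      enhancer_id = sample(enh_ids, 12, TRUE),
      gene_name = sprintf("G%d", sample(1:6, 12, TRUE)),
      stringsAsFactors = FALSE)
    links <- links[!duplicated(links), ]
    hits <- do.call(rbind, lapply(sample(enh_ids, 4, TRUE), function(e)
      mk_hits(sprintf("Mir%d-mat", sample(1:3, 1)), e)))
    hits <- hits[!duplicated(hits[, c("mature_mirna", "enhancer_id")]), ]
    cand <- suppressMessages(hits_to_candidates(hits, links))
    expected <- sum(vapply(seq_len(nrow(hits)), function(i)
      length(unique(links$gene_name[links$enhancer_id == hits$enhancer_id[i]])),
      integer(1)))
    expect_identical(nrow(cand), as.integer(expected))
  }
})

test_that("spearman_scc matches Pearson-on-ranks with t-approximation", {
  expect_equal(spearman_scc(1:8, 1:8)$rho, 1)
  expect_equal(spearman_scc(1:8, 8:1)$rho, -1)
  expect_equal(spearman_scc(1:8, 1:8)$p, .Machine$double.xmin)

  s <- spearman_scc(1:8, c(2, 1, 4, 3, 6, 5, 8, 7))
  expect_equal(s$rho, cor(1:8, c(2, 1, 4, 3, 6, 5, 8, 7)))  # already ranks
  expect_equal(round(s$rho, 4), 0.9048)

  # ties handled by average ranks: agree with cor(method = "spearman")
  set.seed(402)
  for (k in 1:25) {
    x <- sample(1:5, 10, TRUE); y <- sample(1:5, 10, TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_scc(x, y)$rho, cor(x, y, method = "spearman"))
  }
  expect_warning(s0 <- spearman_scc(rep(1, 8), 1:8), "zero variance")
  expect_true(is.na(s0$rho))
})

test_that("t-approximation p-values track a permutation oracle", {
  # documented tolerance: the t approximation at n = 8..12 is compared to a
  # Monte-Carlo permutation p-value within +/- 0.05 (or factor 3 below 0.01)
  set.seed(403)
  for (k in 1:12) {
    n <- sample(8:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    s <- spearman_scc(x, y)
    p_mc <- mc_perm_spearman_p(x, y, n_perm = 1500)
    if (p_mc > 0.01) {
      expect_lt(abs(s$p - p_mc), 0.05)
    } else {
      expect_lt(s$p, 3 * p_mc)
    }
  }
})

test_that("per-miRNA BH adjustment matches hand computation and its
           invariants", {
  cand <- data.frame(family = c("M1", "M1", "M1", "M2"),
                     p_raw = c(0.01, 0.02, 0.03, 0.2),
                     stringsAsFactors = FALSE)
  adj <- bh_adjust_per_mirna(cand)
  # group of 3: step-up gives (0.03, 0.03, 0.03); group of 1: unchanged
  expect_equal(adj$p_adj, c(0.03, 0.03, 0.03, 0.2))
  expect_true(all(adj$p_adj >= adj$p_raw))

  # permutation invariance
  set.seed(404)
  perm <- sample(nrow(cand))
  adj2 <- bh_adjust_per_mirna(cand[perm, ])
  expect_equal(adj2$p_adj, adj$p_adj[perm])

  # grouping matters: per-family m, not the global count
  lone <- bh_adjust_per_mirna(data.frame(family = "Mx", p_raw = 0.04))
  expect_equal(lone$p_adj, 0.04)
})

mk_expr <- function(rows, n = 12, seed = 1) {
  set.seed(seed)
  m <- matrix(exp(rnorm(length(rows) * n)), length(rows), n,
              dimnames = list(rows, sprintf("S%02d", 1:n)))
  m
}

test_that("assemble_trios keeps planted signal and honors fdr boundaries", {
  me <- mk_expr("MirA", seed = 405)
  ge <- mk_expr(c("G1", "G2"), seed = 406)
  ge["G1", ] <- me["MirA", ] * 2 + 1   # monotone link -> scc 1
  cand <- data.frame(family = "MirA", mature_mirna = "MirA-mat",
                     gene_name = c("G1", "G2"), enhancer_id = "e1",
                     method = "miranda", pi = NA_real_,
                     stringsAsFactors = FALSE)
  trios <- assemble_trios(cand, me, ge)
  expect_identical(trios$gene_name, "G1")
  expect_equal(trios$scc, 1)

  # fdr = 1 keeps all candidates (sign filter off), fdr = 0 keeps none
  all_k <- assemble_trios(cand, me, ge, fdr = 1, positive_only = FALSE)
  expect_identical(nrow(all_k), 2L)
  expect_identical(nrow(assemble_trios(cand, me, ge, fdr = 0)), 0L)

  # containment: trios are a subset of candidates
  key <- function(d) paste(d$mature_mirna, d$gene_name, d$enhancer_id)
  expect_true(all(key(trios) %in% key(cand)))

  # empty candidates -> empty trios
  expect_identical(nrow(assemble_trios(cand[0, ], me, ge)), 0L)

  # missing features are dropped and counted
  cand_bad <- cand; cand_bad$gene_name <- c("G1", "NOPE")
  expect_message(t2 <- assemble_trios(cand_bad, me, ge), "missing")
  expect_identical(attr(t2, "n_missing"), 1L)
})

test_that("positive_only keeps activation-consistent trios only", {
  me <- mk_expr("MirA", seed = 407)
  ge <- mk_expr(c("Gup", "Gdown"), seed = 408)
  ge["Gup", ] <- me["MirA", ] + 0.5
  ge["Gdown", ] <- max(me["MirA", ]) - me["MirA", ] + 0.5
  cand <- data.frame(family = "MirA", mature_mirna = "MirA-mat",
                     gene_name = c("Gup", "Gdown"), enhancer_id = "e1",
                     method = "miranda", pi = NA_real_,
                     stringsAsFactors = FALSE)
  pos <- assemble_trios(cand, me, ge)
  expect_identical(pos$gene_name, "Gup")
  both <- assemble_trios(cand, me, ge, positive_only = FALSE)
  expect_setequal(both$gene_name, c("Gup", "Gdown"))
})

test_that("write_trios emits the documented schema and round-trips", {
  trios <- data.frame(family = "MirA", mature_mirna = "MirA-mat",
                      gene_name = "G1", enhancer_id = "chr1:0-10",
                      scc = 0.95, p_raw = 1e-4, p_adj = 2e-4, pi = 88.5,
                      method = "seed_needle", stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_trios(trios, p)
  header <- strsplit(readLines(p, n = 1), "\t")[[1]]
  expect_identical(header, c("mature_mirna", "Gene.Name", "enhancer",
                             "corr (miRNA, gene)", "p.value adj", "PI"))
  back <- read_trios(p)
  expect_identical(back$mature_mirna, trios$mature_mirna)
  expect_equal(back$scc, trios$scc)
  expect_equal(back$pi, trios$pi)

  # non-seed methods: 5 columns, no PI
  trios$method <- "miranda"
  write_trios(trios, p)
  expect_identical(length(strsplit(readLines(p, n = 1), "\t")[[1]]), 5L)

  # 0 records -> header-only file
  write_trios(trios[0, ], p, with_pi = FALSE)
  expect_identical(length(readLines(p)), 1L)
})
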