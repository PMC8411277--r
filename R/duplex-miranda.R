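# Approach 2: miRanda-style miRNA:DNA duplex scan.  A local complementarity
# alignment between the miRNA read 3'->5' and the target strand read 5'->3'
# is computed by dynamic programming; columns pairing miRNA seed positions
# 2-8 are up-weighted, and hits are filtered on score and (optionally) on a
# simplified nearest-neighbor duplex energy.

#' miRanda-style duplex scan parameters
#'
#' Defaults follow the published miRanda constants: Watson-Crick match +5,
#' G:U wobble (G:T on the DNA target) +1, mismatch -3, gap open -9, gap
#' extend -4, a 4x scale on alignment columns pairing miRNA positions 2-8
#' (5'-end numbering), score cutoff 140 and energy cutoff -1.0 kcal/mol.
#'
#' @param match_score,wobble_score,mismatch_score Column scores.
#' @param gap_open,gap_extend Gap scores (negative); a gap run of length L
#'   scores `gap_open + gap_extend * L`.
#' @param seed_scale Multiplier for substitution columns in the seed.
#' @param seed_range miRNA positions (1-based from the 5' end) that count
#'   as seed (default 2:8).
#' @param score_threshold Minimum alignment score for a hit.
#' @param energy_threshold Maximum duplex energy (kcal/mol) for a hit.
#' @param energy_model `"simple_stack"` or `"none"`.
#' @return list of parameters.
#' @export
miranda_params <- function(match_score = 5, wobble_score = 1,
                           mismatch_score = -3, gap_open = -9,
                           gap_extend = -4, seed_scale = 4,
                           seed_range = 2:8, score_threshold = 140,
                           energy_threshold = -1.0,
                           energy_model = c("simple_stack", "none")) {
  stopifnot(score_threshold > 0, seed_scale >= 1)
  list(match_score = match_score, wobble_score = wobble_score,
       mismatch_score = mismatch_score, gap_open = gap_open,
       gap_extend = gap_extend, seed_scale = seed_scale,
       seed_range = as.integer(seed_range),
       score_threshold = score_threshold,
       energy_threshold = energy_threshold,
       energy_model = match.arg(energy_model))
}

# pair type of an (RNA base, DNA target base) column in an antiparallel
# duplex: "wc", "wobble" or "mismatch"
.pair_type <- function(rna_base, dna_base) {
  wc <- (rna_base == "A" & dna_base == "T") |
        (rna_base == "U" & dna_base == "A") |
        (rna_base == "G" & dna_base == "C") |
        (rna_base == "C" & dna_base == "G")
  wob <- (rna_base == "G" & dna_base == "T") |
         (rna_base == "U" & dna_base == "G")
  ifelse(wc, "wc", ifelse(wob, "wobble", "mismatch"))
}

#' Best local miRNA:DNA duplex alignment
#'
#' Smith-Waterman-style local alignment of the miRNA (3'->5') against the
#' target (5'->3'), i.e. of the reversed miRNA against the target with
#' complementarity scoring.  Substitution columns whose miRNA position lies
#' in the seed range are multiplied by `seed_scale` (positive and negative
#' scores alike, as in miRanda).  Deterministic traceback (diagonal, up,
#' left).
#'
#' @param mirna_seq Mature miRNA (RNA alphabet; T accepted and read as U).
#' @param target_seq DNA target window (5'->3').
#' @param params [miranda_params()].
#' @return list with elements score, pairs (data.frame: mirna_pos 1-based
#'   from the 5' end, target_pos 1-based, pair_type), target_start,
#'   target_end (0-based half-open on the target).
#' @export
duplex_align <- function(mirna_seq, target_seq, params = miranda_params()) {
  mirna_seq <- dna_to_rna(mirna_seq)
  target_seq <- rna_to_dna(target_seq)
  if (nchar(mirna_seq) == 0L || nchar(target_seq) == 0L) stop("empty sequence")
  mir <- strsplit(mirna_seq, "")[[1]]
  n <- length(mir)
  q <- rev(mir)                       # query row i pairs miRNA position n-i+1
  t <- strsplit(target_seq, "")[[1]]
  m <- length(t)
  mirna_pos_of <- function(i) n - i + 1L

  # precomputed substitution matrix S[i, j]: scaled column score for
  # pairing query row i (miRNA position n-i+1) with target position j
  ty_mat <- matrix(.pair_type(rep(q, times = m), rep(t, each = n)), n, m)
  S <- matrix(params$mismatch_score, n, m)
  S[ty_mat == "wc"] <- params$match_score
  S[ty_mat == "wobble"] <- params$wobble_score
  seed_rows <- which((n - seq_len(n) + 1L) %in% params$seed_range)
  S[seed_rows, ] <- S[seed_rows, , drop = FALSE] * params$seed_scale
  colscore <- function(i, j) S[i, j]
  gi <- params$gap_open + params$gap_extend
  ge <- params$gap_extend
  NEG <- -1e18
  M <- matrix(0, n + 1L, m + 1L)      # local: alignments may start anywhere
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- colscore(i, j)
      M[i + 1L, j + 1L] <- max(0, s + max(M[i, j], X[i, j], Y[i, j]))
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] + gi, X[i, j + 1L] + ge,
                               Y[i, j + 1L] + gi)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] + gi, X[i + 1L, j] + gi,
                               Y[i + 1L, j] + ge)
    }
  }
  best <- which(M == max(M), arr.ind = TRUE)
  best <- unname(best[order(best[, 1], best[, 2]), , drop = FALSE][1, ])  # deterministic
  score <- max(M)
  pairs <- data.frame(mirna_pos = integer(0), target_pos = integer(0),
                      pair_type = character(0), stringsAsFactors = FALSE)
  tstart <- tend <- 0L
  if (score > 0) {
    i <- as.integer(best[1]) - 1L; j <- as.integer(best[2]) - 1L
    tend <- j
    state <- "M"
    tol <- 1e-9
    rows <- list()
    while (i > 0L || j > 0L) {
      if (state == "M") {
        v <- M[i + 1L, j + 1L]
        if (abs(v) < tol) break
        s <- colscore(i, j)
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_pos = mirna_pos_of(i), target_pos = j,
          pair_type = .pair_type(q[i], t[j]), stringsAsFactors = FALSE)
        prev <- c(M[i, j], X[i, j], Y[i, j])
        state <- c("M", "X", "Y")[which(abs(prev - (v - s)) < tol)[1]]
        i <- i - 1L; j <- j - 1L
        if (state == "M" && abs(M[i + 1L, j + 1L]) < tol) break
      } else if (state == "X") {
        v <- X[i + 1L, j + 1L]
        prev <- c(M[i, j + 1L] + gi, X[i, j + 1L] + ge, Y[i, j + 1L] + gi)
        state <- c("M", "X", "Y")[which(abs(prev - v) < tol)[1]]
        i <- i - 1L
      } else {
        v <- Y[i + 1L, j + 1L]
        prev <- c(M[i + 1L, j] + gi, X[i + 1L, j] + gi, Y[i + 1L, j] + ge)
        state <- c("M", "X", "Y")[which(abs(prev - v) < tol)[1]]
        j <- j - 1L
      }
    }
    tstart <- j
    pairs <- do.call(rbind, rev(rows))
    rownames(pairs) <- NULL
  }
  list(score = score, pairs = pairs,
       target_start = tstart, target_end = tend)
}

# nearest-neighbor stack table for an RNA/DNA hybrid, keyed by the two
# adjacent miRNA bases read 5'->3' (Watson-Crick stacks; approximate
# Sugimoto-style delta-G37 in kcal/mol).  Wobble-containing stacks get a
# fixed weak contribution.  All entries are negative, which is what makes
# the energy monotone in the number of paired columns.
.STACK_DG <- c(
  AA = -1.0, AC = -2.1, AG = -1.8, AU = -0.9,
  CA = -0.9, CC = -2.1, CG = -1.7, CU = -0.9,
  GA = -1.3, GC = -2.7, GG = -2.9, GU = -1.1,
  UA = -0.6, UC = -1.5, UG = -1.6, UU = -0.2
)
.WOBBLE_STACK_DG <- -0.5

#' Simplified duplex free-energy estimate
#'
#' Sums nearest-neighbor stack contributions over adjacent paired columns
#' of a duplex alignment (both columns Watson-Crick or wobble, consecutive
#' on both strands).  This is a deliberately simplified surrogate, not a
#' folding energy: no initiation, loop or dangling-end terms.  It is
#' monotone: adding a paired column never makes the energy less negative.
#'
#' @param pairs data.frame as returned in `duplex_align()$pairs`.
#' @param mirna_seq The miRNA sequence the positions refer to.
#' @return Energy in kcal/mol (0 for an empty pairing).
#' @export
estimate_duplex_energy <- function(pairs, mirna_seq) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(0)
  mirna_seq <- dna_to_rna(mirna_seq)
  mir <- strsplit(mirna_seq, "")[[1]]
  paired <- pairs[pairs$pair_type %in% c("wc", "wobble"), , drop = FALSE]
  if (nrow(paired) < 2L) return(0)
  paired <- paired[order(paired$mirna_pos), , drop = FALSE]
  e <- 0
  for (k in seq_len(nrow(paired) - 1L)) {
    a <- paired[k, ]; b <- paired[k + 1L, ]
    # stack requires adjacency on both strands (note: miRNA 5'->3' runs
    # antiparallel to the target, so target positions decrease)
    if (b$mirna_pos - a$mirna_pos != 1L) next
    if (a$target_pos - b$target_pos != 1L) next
    if (a$pair_type == "wc" && b$pair_type == "wc") {
      key <- paste0(mir[a$mirna_pos], mir[b$mirna_pos])
      e <- e + .STACK_DG[[key]]
    } else {
      e <- e + .WOBBLE_STACK_DG
    }
  }
  unname(e)
}

#' miRanda-style detection of miRNA:enhancer duplexes
#'
#' Each enhancer is scanned in both orientations (the + strand as written
#' and its reverse complement, modeling the two possible duplex
#' orientations).  A hit requires score >= `score_threshold` and, unless
#' `energy_model = "none"`, energy <= `energy_threshold`.  One best hit per
#' (mature miRNA, enhancer) pair is reported (maximal score, ties to the
#' smallest + strand start).  Site coordinates are always on the + strand.
#'
#' @param mirnas data.frame from [load_mirna_set()].
#' @param enhancers data.frame with enhancer_id and seq columns.
#' @param params [miranda_params()].
#' @return data.frame of duplex hits: family, mature_mirna, enhancer_id,
#'   site_start, site_end, orientation, method ("miranda"), score, energy.
#' @export
detect_miranda <- function(mirnas, enhancers, params = miranda_params()) {
  empty <- data.frame(family = character(0), mature_mirna = character(0),
                      enhancer_id = character(0), site_start = integer(0),
                      site_end = integer(0), orientation = character(0),
                      method = character(0), score = numeric(0),
                      energy = numeric(0), stringsAsFactors = FALSE)
  if (nrow(mirnas) == 0L || nrow(enhancers) == 0L) return(empty)
  if (any(is.na(enhancers$seq))) stop("enhancer sequences not attached")
  rows <- list()
  for (k in seq_len(nrow(mirnas))) {
    mi <- mirnas[k, ]
    for (e in seq_len(nrow(enhancers))) {
      enh <- enhancers[e, ]
      elen <- nchar(enh$seq)
      best <- NULL
      for (ori in c("forward", "reverse_complement")) {
        tseq <- if (ori == "forward") enh$seq else reverse_complement(enh$seq)
        aln <- duplex_align(mi$mature_seq, tseq, params)
        if (aln$score < params$score_threshold) next
        en <- if (params$energy_model == "none") NA_real_
              else estimate_duplex_energy(aln$pairs, mi$mature_seq)
        if (params$energy_model != "none" && en > params$energy_threshold) next
        if (ori == "forward") {
          s <- aln$target_start; epos <- aln$target_end
        } else {
          s <- elen - aln$target_end; epos <- elen - aln$target_start
        }
        cand <- list(start = s, end = epos, orientation = ori,
                     score = aln$score, energy = en)
        if (is.null(best) || cand$score > best$score ||
            (cand$score == best$score && cand$start < best$start)) {
          best <- cand
        }
      }
      if (!is.null(best)) {
        rows[[length(rows) + 1L]] <- data.frame(
          family = mi$family, mature_mirna = mi$mature_name,
          enhancer_id = enh$enhancer_id,
          site_start = best$start, site_end = best$end,
          orientation = best$orientation, method = "miranda",
          score = best$score, energy = best$energy, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
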