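# Approach 1: exact seed matching in enhancer sequences, extension of the
# matched site so it can host the full mature miRNA, affine-gap global
# alignment (Needleman-Wunsch), and a strict percent-identity filter.

#' Default global-alignment parameters
#'
#' The DNA defaults of the EMBOSS-style global aligner: match +5,
#' mismatch -4, gap open 10, gap extend 0.5 (penalties are positive; a gap
#' run of length L costs `gap_open + gap_extend * L`, end gaps included).
#'
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Affine gap penalties (positive).
#' @return list of parameters.
#' @export
needle_params <- function(match = 5, mismatch = -4, gap_open = 10,
                          gap_extend = 0.5) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

#' Find all exact seed occurrences in an enhancer sequence
#'
#' Scans for the forward seed and its reverse complement; overlapping
#' occurrences are kept.  The reverse-complement form models binding of the
#' miRNA to the opposite strand without ever flipping the enhancer.
#'
#' @param enhancer_seq Enhancer sequence (+ strand, DNA).
#' @param seed_fwd Forward seed (DNA, >= 4 nt).
#' @param seed_rc Reverse-complement seed; computed from `seed_fwd` when NULL.
#' @return data.frame with columns offset (0-based match start) and
#'   orientation (`"forward"` / `"reverse_complement"`), sorted by offset.
#' @export
scan_seed <- function(enhancer_seq, seed_fwd, seed_rc = NULL) {
  seed_fwd <- toupper(seed_fwd)
  if (nchar(seed_fwd) < 4L) {
    stop("seed shorter than 4 nt would match almost everywhere")
  }
  if (is.null(seed_rc)) seed_rc <- reverse_complement(seed_fwd)
  seed_rc <- toupper(seed_rc)
  enhancer_seq <- toupper(enhancer_seq)

  find_all <- function(pat) {
    # zero-width lookahead keeps overlapping occurrences
    hits <- gregexpr(paste0("(?=", pat, ")"), enhancer_seq, perl = TRUE)[[1]]
    if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
  }
  fwd <- find_all(seed_fwd)
  rc <- find_all(seed_rc)
  if (seed_rc == seed_fwd) rc <- integer(0)  # palindromic seed: report once
  out <- data.frame(
    offset = c(fwd, rc),
    orientation = c(rep("forward", length(fwd)),
                    rep("reverse_complement", length(rc))),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$offset, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extension window around a seed match
#'
#' The seed site is extended by `flank` bp (default 14) on the side where
#' the remainder of the mature miRNA would lie: downstream of the site for
#' forward matches (the seed sits at the miRNA 5' end, which pairs at the
#' site 5' end on the + strand reading), upstream for reverse-complement
#' matches.  The window is clipped to the enhancer.
#'
#' @param offset 0-based match start.
#' @param seed_len Seed length.
#' @param orientation `"forward"` or `"reverse_complement"`.
#' @param enhancer_len Enhancer length.
#' @param flank Extension in bp (default 14).
#' @return Integer vector `c(start, end)`, 0-based half-open.
#' @export
extension_window <- function(offset, seed_len, orientation, enhancer_len,
                             flank = 14L) {
  if (orientation == "forward") {
    c(offset, min(enhancer_len, offset + seed_len + flank))
  } else {
    c(max(0L, offset - flank), offset + seed_len)
  }
}

#' Affine-gap global alignment (Needleman-Wunsch)
#'
#' Optimal global alignment of two DNA sequences under affine gap costs
#' (a gap run of length L costs `gap_open + gap_extend * L`; end gaps are
#' penalized like internal gaps).  Traceback ties are broken
#' deterministically: diagonal, then up (gap in target), then left.
#'
#' @param query,target DNA sequences (ACGTN).
#' @param params Parameters from [needle_params()].
#' @return list of class `alignment_result` with elements aligned_query,
#'   aligned_target (gapped strings), score, matches, alignment_length,
#'   percent_identity.
#' @export
global_align <- function(query, target, params = needle_params()) {
  query <- toupper(query); target <- toupper(target)
  if (nchar(query) == 0L || nchar(target) == 0L) stop("empty sequence")
  .check_alphabet(c(query, target), DNA_ALPHABET, "alignment input")
  q <- strsplit(query, "")[[1]]
  t <- strsplit(target, "")[[1]]
  n <- length(q); m <- length(t)
  gi <- params$gap_open + params$gap_extend   # cost of first gap residue
  ge <- params$gap_extend
  NEG <- -1e18

  # M: q[i] aligned to t[j]; X: gap in target (q[i] consumed);
  # Y: gap in query (t[j] consumed)
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  if (n >= 1L) X[2L:(n + 1L), 1L] <- -(params$gap_open + ge * seq_len(n))
  if (m >= 1L) Y[1L, 2L:(m + 1L)] <- -(params$gap_open + ge * seq_len(m))

  sub <- function(a, b) if (a == b) params$match else params$mismatch
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sub(q[i], t[j])
      M[i + 1L, j + 1L] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - gi, X[i, j + 1L] - ge,
                               Y[i, j + 1L] - gi)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - gi, X[i + 1L, j] - gi,
                               Y[i + 1L, j] - ge)
    }
  }
  # corners where only gap states are reachable
  for (i in seq_len(n)) Y[i + 1L, 1L] <- NEG
  for (j in seq_len(m)) X[1L, j + 1L] <- NEG

  finals <- c(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  state <- c("M", "X", "Y")[which.max(finals)]  # ties: M, then X, then Y
  score <- max(finals)

  aq <- character(0); at <- character(0)
  i <- n; j <- m
  tol <- 1e-9
  while (i > 0L || j > 0L) {
    if (state == "M") {
      s <- sub(q[i], t[j])
      v <- M[i + 1L, j + 1L] - s
      prev <- c(M[i, j], X[i, j], Y[i, j])
      state <- c("M", "X", "Y")[which(abs(prev - v) < tol)[1]]
      aq <- c(q[i], aq); at <- c(t[j], at)
      i <- i - 1L; j <- j - 1L
    } else if (state == "X") {
      v <- X[i + 1L, j + 1L]
      prev <- c(M[i, j + 1L] - gi, X[i, j + 1L] - ge, Y[i, j + 1L] - gi)
      state <- c("M", "X", "Y")[which(abs(prev - v) < tol)[1]]
      aq <- c(q[i], aq); at <- c("-", at)
      i <- i - 1L
    } else {
      v <- Y[i + 1L, j + 1L]
      prev <- c(M[i + 1L, j] - gi, X[i + 1L, j] - gi, Y[i + 1L, j] - ge)
      state <- c("M", "X", "Y")[which(abs(prev - v) < tol)[1]]
      aq <- c("-", aq); at <- c(t[j], at)
      j <- j - 1L
    }
  }
  matches <- sum(aq == at & aq != "-")
  alen <- length(aq)
  structure(list(
    aligned_query = paste(aq, collapse = ""),
    aligned_target = paste(at, collapse = ""),
    score = score,
    matches = matches,
    alignment_length = alen,
    percent_identity = 100 * matches / alen
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(x$aligned_query, "\n", x$aligned_target, "\n", sep = "")
  cat(sprintf("score %.1f, identity %d/%d (%.1f%%)\n",
              x$score, x$matches, x$alignment_length, x$percent_identity))
  invisible(x)
}

#' Seed-match + global-alignment detection of miRNA:enhancer duplexes
#'
#' For every exact seed occurrence, the full mature miRNA (as DNA;
#' reverse-complemented for reverse-complement matches so both strings are
#' in target-strand orientation) is globally aligned to the extension
#' window, and the site is kept when percent identity strictly exceeds
#' `pi_threshold`.  One best hit (maximal PI, ties to the smallest start)
#' is reported per (mature miRNA, enhancer) pair.
#'
#' @param mirnas data.frame from [load_mirna_set()] (seed columns required).
#' @param enhancers data.frame from [read_bed()] with sequences attached,
#'   or any data.frame with enhancer_id and seq columns.
#' @param pi_threshold Percent-identity cutoff, strict (default 50).
#' @param params Alignment parameters ([needle_params()]).
#' @param flank Seed extension in bp (default 14).
#' @return data.frame of duplex hits: family, mature_mirna, enhancer_id,
#'   site_start, site_end, orientation, method ("seed_needle"), score, pi.
#' @export
detect_seed_needle <- function(mirnas, enhancers, pi_threshold = 50,
                               params = needle_params(), flank = 14L) {
  empty <- data.frame(family = character(0), mature_mirna = character(0),
                      enhancer_id = character(0), site_start = integer(0),
                      site_end = integer(0), orientation = character(0),
                      method = character(0), score = numeric(0), pi = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(mirnas) == 0L || nrow(enhancers) == 0L) return(empty)
  if (any(is.na(enhancers$seq))) stop("enhancer sequences not attached")
  if (any(is.na(mirnas$seed_fwd))) {
    stop("seed sequences are required for seed_match_needle detection")
  }
  rows <- list()
  for (k in seq_len(nrow(mirnas))) {
    mi <- mirnas[k, ]
    mature_dna <- rna_to_dna(mi$mature_seq)
    for (e in seq_len(nrow(enhancers))) {
      enh <- enhancers[e, ]
      mats <- scan_seed(enh$seq, mi$seed_fwd, mi$seed_rc)
      if (nrow(mats) == 0L) next
      best <- NULL
      for (r in seq_len(nrow(mats))) {
        w <- extension_window(mats$offset[r], nchar(mi$seed_fwd),
                              mats$orientation[r], nchar(enh$seq), flank)
        window_seq <- substr(enh$seq, w[1] + 1L, w[2])
        qry <- if (mats$orientation[r] == "forward") mature_dna
               else reverse_complement(mature_dna)
        aln <- global_align(qry, window_seq, params)
        if (aln$percent_identity <= pi_threshold) next
        cand <- list(start = w[1], end = w[2], orientation = mats$orientation[r],
                     score = aln$score, pi = aln$percent_identity)
        if (is.null(best) || cand$pi > best$pi ||
            (cand$pi == best$pi && cand$start < best$start)) {
          best <- cand
        }
      }
      if (!is.null(best)) {
        rows[[length(rows) + 1L]] <- data.frame(
          family = mi$family, mature_mirna = mi$mature_name,
          enhancer_id = enh$enhancer_id,
          site_start = best$start, site_end = best$end,
          orientation = best$orientation, method = "seed_needle",
          score = best$score, pi = best$pi, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
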