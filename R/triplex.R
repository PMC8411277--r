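# Approach 3: RNA:DNA:DNA triplex site search.  The miRNA (triplex-forming
# oligo, TFO) is scanned against each strand of the enhancer duplex taken
# as the candidate purine strand, under canonical Hoogsteen triplet rules,
# with a tolerated error rate and a minimum site length (defaults relaxed
# for ~22-nt miRNAs: error rate 0.19, minimum length 11).

#' Triplex search parameters
#'
#' @param max_error_rate Maximum fraction of invalid triplet positions in
#'   a site (default 0.19).
#' @param min_length Minimum site length in nt (default 11, >= 5).
#' @param motifs Subset of `"parallel_pyrimidine"`, `"antiparallel_purine"`,
#'   `"mixed_GT"` (default all three).
#' @param min_guanine_rate Minimum guanine fraction on the purine strand of
#'   the target site (default 0.1).
#' @param merge_overlaps `"maximal_only"` (drop hits contained in a longer
#'   valid hit on the same diagonal/motif/strand) or `"all"`.
#' @return list of parameters.
#' @export
triplex_params <- function(max_error_rate = 0.19, min_length = 11L,
                           motifs = c("parallel_pyrimidine",
                                      "antiparallel_purine", "mixed_GT"),
                           min_guanine_rate = 0.1,
                           merge_overlaps = c("maximal_only", "all")) {
  motifs <- match.arg(motifs, several.ok = TRUE)
  stopifnot(min_length >= 5L, max_error_rate >= 0, max_error_rate < 0.5)
  list(max_error_rate = max_error_rate, min_length = as.integer(min_length),
       motifs = motifs, min_guanine_rate = min_guanine_rate,
       merge_overlaps = match.arg(merge_overlaps))
}

#' Hoogsteen triplet validity
#'
#' Canonical triplet rules, with the DNA duplex represented by its purine
#' strand base: parallel pyrimidine motif allows U.A:T and C.G:C (RNA U
#' over duplex A, RNA C over duplex G); antiparallel purine motif allows
#' A.A:T and G.G:C; the mixed GT motif allows G.G:C and U.A:T.  Everything
#' else is an error position.  Vectorized over bases.
#'
#' @param rna_base RNA base(s) of the TFO (A/C/G/U).
#' @param purine_strand_base Purine-strand DNA base(s) (A/C/G/T).
#' @param motif One motif name.
#' @return Logical vector.
#' @export
position_valid <- function(rna_base, purine_strand_base, motif) {
  r <- toupper(rna_base)
  d <- toupper(purine_strand_base)
  switch(motif,
    parallel_pyrimidine = (r == "U" & d == "A") | (r == "C" & d == "G"),
    antiparallel_purine = (r == "A" & d == "A") | (r == "G" & d == "G"),
    mixed_GT            = (r == "G" & d == "G") | (r == "U" & d == "A"),
    stop("unknown motif: ", motif)
  )
}

# per-overlap-length template of candidate (a, b) window bounds with the
# minimum-length filter already applied; shared across diagonals
.window_template <- function(L, min_length) {
  a <- rep.int(seq_len(L), L)
  b <- rep(seq_len(L), each = L)
  len <- b - a + 1L
  keep <- len >= min_length
  list(a = a[keep], b = b[keep], len = len[keep])
}

# enumerate valid windows on one (motif, strand, diagonal) validity vector.
# valid: logical vector over the overlap; gpur: logical, purine base == G.
# Returns a 2-column integer matrix of (a, b) 1-based inclusive bounds.
.valid_windows <- function(valid, gpur, tmpl, max_error_rate,
                           min_guanine_rate) {
  ce <- c(0L, cumsum(!valid))
  cg <- c(0L, cumsum(gpur))
  err <- ce[tmpl$b + 1L] - ce[tmpl$a]
  gn <- cg[tmpl$b + 1L] - cg[tmpl$a]
  ok <- err <= max_error_rate * tmpl$len & gn >= min_guanine_rate * tmpl$len
  if (!any(ok)) return(NULL)
  cbind(a = tmpl$a[ok], b = tmpl$b[ok])
}

# drop windows strictly contained in another window of the same set
.maximal_windows <- function(w) {
  if (nrow(w) <= 1L) return(w)
  contained <- vapply(seq_len(nrow(w)), function(i) {
    any(w[, 1L] <= w[i, 1L] & w[, 2L] >= w[i, 2L] &
          (w[, 1L] < w[i, 1L] | w[, 2L] > w[i, 2L]))
  }, logical(1))
  w[!contained, , drop = FALSE]
}

#' Find triplex sites between one miRNA and one enhancer
#'
#' Both enhancer strands are evaluated as the candidate purine strand; TFO
#' windows are scanned forward along the purine strand for the parallel
#' motifs (parallel_pyrimidine, mixed_GT) and reversed for the antiparallel
#' purine motif.  A site is an equal-length gapless pairing of a miRNA
#' window and a purine-strand window with at most `max_error_rate` invalid
#' triplets, length >= `min_length`, and purine-strand guanine fraction >=
#' `min_guanine_rate`.  TTS coordinates are always reported on the + strand.
#'
#' @param mirna One-row data.frame (family, mature_name, mature_seq) or a
#'   list with those fields.
#' @param enhancer One-row data.frame with enhancer_id and seq.
#' @param params [triplex_params()].
#' @return data.frame of hits: family, mature_mirna, enhancer_id,
#'   tfo_start, tfo_end (0-based half-open on the miRNA), tts_start,
#'   tts_end (0-based half-open on the + strand), strand ("+"/"-" = which
#'   strand is the purine strand), motif, length, errors, error_rate,
#'   guanine_rate; sorted by (tts_start, length desc, motif).
#' @export
find_triplexes <- function(mirna, enhancer, params = triplex_params()) {
  empty <- data.frame(family = character(0), mature_mirna = character(0),
                      enhancer_id = character(0), tfo_start = integer(0),
                      tfo_end = integer(0), tts_start = integer(0),
                      tts_end = integer(0), strand = character(0),
                      motif = character(0), length = integer(0),
                      errors = integer(0), error_rate = numeric(0),
                      guanine_rate = numeric(0), stringsAsFactors = FALSE)
  mseq <- dna_to_rna(mirna$mature_seq)
  eseq <- rna_to_dna(enhancer$seq)
  n <- nchar(mseq); m <- nchar(eseq)
  if (n == 0L || m == 0L) return(empty)
  mir <- strsplit(mseq, "")[[1]]
  plus <- strsplit(eseq, "")[[1]]
  minus <- strsplit(reverse_complement(eseq), "")[[1]]

  # (a, b) window templates, one per possible overlap length
  templates <- vector("list", min(n, m))
  if (min(n, m) >= params$min_length) {
    for (L in params$min_length:min(n, m)) {
      templates[[L]] <- .window_template(L, params$min_length)
    }
  }

  rows <- list()
  for (motif in params$motifs) {
    tfo <- if (motif == "antiparallel_purine") rev(mir) else mir
    for (strand in c("+", "-")) {
      pur <- if (strand == "+") plus else minus
      # validity of every (TFO position, purine position) pair at once;
      # diagonals are then plain matrix extractions
      V <- matrix(position_valid(rep(tfo, times = m), rep(pur, each = n),
                                 motif), n, m)
      gvec <- pur == "G"
      for (d in (1L - n):(m - 1L)) {
        i0 <- max(1L, 1L - d)
        i1 <- min(n, m - d)
        if (i1 - i0 + 1L < params$min_length) next
        idx <- i0:i1
        valid <- V[cbind(idx, idx + d)]
        gpur <- gvec[idx + d]
        w <- .valid_windows(valid, gpur, templates[[length(idx)]],
                            params$max_error_rate, params$min_guanine_rate)
        if (is.null(w)) next
        if (params$merge_overlaps == "maximal_only") w <- .maximal_windows(w)
        ia <- idx[w[, 1L]]; ib <- idx[w[, 2L]]     # scanned-TFO 1-based
        ja <- ia + d; jb <- ib + d                 # purine-strand 1-based
        len <- ib - ia + 1L
        ce <- c(0L, cumsum(!valid)); cg <- c(0L, cumsum(gpur))
        errs <- ce[w[, 2L] + 1L] - ce[w[, 1L]]
        grate <- (cg[w[, 2L] + 1L] - cg[w[, 1L]]) / len
        # map scanned-TFO coords back to the original miRNA, and
        # purine-strand coords to the + strand
        if (motif == "antiparallel_purine") {
          tfo_start <- n - ib; tfo_end <- n - ia + 1L
        } else {
          tfo_start <- ia - 1L; tfo_end <- ib
        }
        if (strand == "+") {
          tts_start <- ja - 1L; tts_end <- jb
        } else {
          tts_start <- m - jb; tts_end <- m - ja + 1L
        }
        rows[[length(rows) + 1L]] <- list(
          tfo_start = tfo_start, tfo_end = tfo_end,
          tts_start = tts_start, tts_end = tts_end,
          strand = strand, motif = motif, length = len,
          errors = errs, error_rate = errs / len, guanine_rate = grate)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- data.frame(
    family = mirna$family, mature_mirna = mirna$mature_name,
    enhancer_id = enhancer$enhancer_id,
    tfo_start = unlist(lapply(rows, `[[`, "tfo_start")),
    tfo_end = unlist(lapply(rows, `[[`, "tfo_end")),
    tts_start = unlist(lapply(rows, `[[`, "tts_start")),
    tts_end = unlist(lapply(rows, `[[`, "tts_end")),
    strand = unlist(lapply(rows, function(r) rep(r$strand, length(r$tfo_start)))),
    motif = unlist(lapply(rows, function(r) rep(r$motif, length(r$tfo_start)))),
    length = unlist(lapply(rows, `[[`, "length")),
    errors = unlist(lapply(rows, `[[`, "errors")),
    error_rate = unlist(lapply(rows, `[[`, "error_rate")),
    guanine_rate = unlist(lapply(rows, `[[`, "guanine_rate")),
    stringsAsFactors = FALSE)
  out <- out[order(out$tts_start, -out$length, out$motif, out$strand,
                   out$tfo_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Triplex detection over all miRNA/enhancer pairs
#'
#' Runs [find_triplexes()] for every pair and reduces the result to the
#' single best hit per (mature miRNA, enhancer) pair for trio assembly:
#' longest site, then lowest error rate, then smallest tts_start.  The full
#' hit list is attached as the `"all_hits"` attribute (audit trail).
#'
#' @param mirnas data.frame from [load_mirna_set()].
#' @param enhancers data.frame with enhancer_id and seq columns.
#' @param params [triplex_params()].
#' @return data.frame of best hits with a `method` column set to
#'   `"triplexator"`, plus attribute `all_hits`.
#' @export
detect_triplexator <- function(mirnas, enhancers, params = triplex_params()) {
  all_rows <- list()
  for (k in seq_len(nrow(mirnas))) {
    for (e in seq_len(nrow(enhancers))) {
      h <- find_triplexes(mirnas[k, ], enhancers[e, ], params)
      if (nrow(h) > 0L) all_rows[[length(all_rows) + 1L]] <- h
    }
  }
  if (length(all_rows) == 0L) {
    empty <- find_triplexes(list(family = character(0),
                                 mature_name = character(0),
                                 mature_seq = ""),
                            list(enhancer_id = character(0), seq = ""),
                            params)
    empty$method <- character(0)
    attr(empty, "all_hits") <- empty
    return(empty)
  }
  all_hits <- do.call(rbind, all_rows)
  rownames(all_hits) <- NULL
  o <- order(all_hits$mature_mirna, all_hits$enhancer_id,
             -all_hits$length, all_hits$error_rate, all_hits$tts_start)
  sorted <- all_hits[o, , drop = FALSE]
  key <- paste(sorted$mature_mirna, sorted$enhancer_id, sep = "\r")
  best <- sorted[!duplicated(key), , drop = FALSE]
  best <- best[order(best$enhancer_id, best$mature_mirna), , drop = FALSE]
  best$method <- "triplexator"
  rownames(best) <- NULL
  attr(best, "all_hits") <- all_hits
  best
}
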