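# Readers/writers for the external formats consumed by the pipeline and the
# canonical in-memory representations every other module works on:
#   * enhancers      -> data.frame (enhancer_id, chrom, start, end, seq)
#   * mature miRNAs  -> data.frame (family, mature_name, mature_seq, seed_fwd, seed_rc)
#   * expression     -> numeric matrix, features x samples
#   * enh:gene links -> data.frame (enhancer_id, gene_name)
# Coordinates are BED-style throughout: 0-based start, exclusive end.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
RNA_ALPHABET <- c("A", "C", "G", "U", "N")

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and record order is preserved.  Record ids are
#' the header token before the first whitespace; the full header line is
#' kept in the `"headers"` attribute so callers can recover annotations
#' such as `family=` tags.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences, with attribute
#'   `headers` (full header lines, same order).  Duplicate ids trigger a
#'   warning; the last record wins.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ids <- character(0)
  headers <- character(0)
  seqs <- list()
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, ">")) {
      hdr <- sub("^>", "", ln)
      id <- strsplit(trimws(hdr), "\\s+")[[1]][1]
      ids <- c(ids, id)
      headers <- c(headers, hdr)
      seqs[[length(ids)]] <- character(0)
      cur <- length(ids)
    } else {
      if (is.null(cur)) {
        stop(sprintf("malformed FASTA in '%s': sequence line before header at line %d",
                     path, i))
      }
      seqs[[cur]] <- c(seqs[[cur]], gsub("\\s", "", ln))
    }
  }
  out <- toupper(vapply(seqs, paste0, character(1), collapse = ""))
  if (anyDuplicated(ids)) {
    warning(sprintf("duplicate FASTA ids in '%s': %s (last record wins)", path,
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    keep <- !duplicated(ids, fromLast = TRUE)
    out <- out[keep]
    ids <- ids[keep]
    headers <- headers[keep]
  }
  names(out) <- ids
  attr(out, "headers") <- headers
  out
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line width for wrapping (default 70).
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Format / parse enhancer identifiers
#'
#' Enhancer ids are `"chrom:start-end"` with the same 0-based half-open
#' numbers as the BED line they came from.
#'
#' @param chrom,start,end Coordinate components.
#' @rdname enhancer_id
#' @export
format_enhancer_id <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

#' @param id Character vector of `"chrom:start-end"` ids.
#' @return `parse_enhancer_id` returns a data.frame with columns chrom,
#'   start, end.
#' @rdname enhancer_id
#' @export
parse_enhancer_id <- function(id) {
  m <- regmatches(id, regexec("^(.+):([0-9]+)-([0-9]+)$", id))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("malformed enhancer id(s): ", paste(id[bad], collapse = ", "))
  }
  data.frame(
    chrom = vapply(m, `[[`, character(1), 2L),
    start = as.integer(vapply(m, `[[`, character(1), 3L)),
    end   = as.integer(vapply(m, `[[`, character(1), 4L)),
    stringsAsFactors = FALSE
  )
}

#' Read a BED3+ file of enhancer coordinates
#'
#' Lines starting with `track`, `browser` or `#` are skipped; columns past
#' the third are ignored.  Starts are 0-based, ends exclusive (BED
#' convention).
#'
#' @param path Path to a BED file.
#' @return data.frame with columns enhancer_id, chrom, start, end, seq
#'   (seq is `NA` until [attach_sequences()] fills it).
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(track|browser|#)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(enhancer_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_ok <- vapply(fields, length, integer(1)) >= 3L
  if (any(!ncol_ok)) {
    stop(sprintf("BED line %d in '%s' has fewer than 3 tab-separated columns",
                 lineno[which(!ncol_ok)[1]], path))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- as.integer(vapply(fields, `[[`, character(1), 2L))
  end <- as.integer(vapply(fields, `[[`, character(1), 3L))
  bad <- is.na(start) | is.na(end) | start < 0L | start >= end
  if (any(bad)) {
    stop(sprintf("BED line %d in '%s': invalid interval (need 0 <= start < end)",
                 lineno[which(bad)[1]], path))
  }
  data.frame(
    enhancer_id = format_enhancer_id(chrom, start, end),
    chrom = chrom, start = start, end = end,
    seq = NA_character_, stringsAsFactors = FALSE
  )
}

#' Attach sequences to enhancer regions
#'
#' Sequences come either from a per-chromosome genome directory (FASTA files
#' named `<chrom>.fa` / `<chrom>.fasta`, or a multi-FASTA keyed by
#' chromosome) or from an enhancer FASTA keyed by enhancer id.  Sequences
#' are always the + strand of the reference; the operation is idempotent.
#'
#' @param regions data.frame as returned by [read_bed()].
#' @param genome_dir Directory with one FASTA per chromosome (optional).
#' @param enhancer_fasta Path to a FASTA keyed by `"chrom:start-end"` ids
#'   (optional; exactly one of the two sources must be given).
#' @return `regions` with the `seq` column filled.
#' @export
attach_sequences <- function(regions, genome_dir = NULL, enhancer_fasta = NULL) {
  if (is.null(genome_dir) == is.null(enhancer_fasta)) {
    stop("provide exactly one of genome_dir or enhancer_fasta")
  }
  if (!is.null(enhancer_fasta)) {
    seqs <- read_fasta(enhancer_fasta)
    missing <- setdiff(regions$enhancer_id, names(seqs))
    if (length(missing) > 0L) {
      stop("enhancer FASTA is missing ids: ", paste(missing, collapse = ", "))
    }
    regions$seq <- unname(seqs[regions$enhancer_id])
  } else {
    chroms <- unique(regions$chrom)
    chrom_seq <- lapply(chroms, function(ch) {
      for (ext in c(".fa", ".fasta")) {
        p <- file.path(genome_dir, paste0(ch, ext))
        if (file.exists(p)) {
          fa <- read_fasta(p)
          return(unname(fa[1L]))
        }
      }
      stop(sprintf("no FASTA for chromosome '%s' under '%s'", ch, genome_dir))
    })
    names(chrom_seq) <- chroms
    for (i in seq_len(nrow(regions))) {
      cs <- chrom_seq[[regions$chrom[i]]]
      if (regions$end[i] > nchar(cs)) {
        stop(sprintf("region %s extends past chromosome end (%d nt)",
                     regions$enhancer_id[i], nchar(cs)))
      }
      regions$seq[i] <- substr(cs, regions$start[i] + 1L, regions$end[i])
    }
  }
  bad <- nchar(regions$seq) != regions$end - regions$start
  if (any(bad)) {
    stop("sequence length mismatch for: ",
         paste(regions$enhancer_id[bad], collapse = ", "))
  }
  regions$seq <- toupper(regions$seq)
  regions
}

.check_alphabet <- function(seq, allowed, what = "sequence") {
  chars <- unique(strsplit(paste0(seq, collapse = ""), "")[[1]])
  bad <- setdiff(chars, allowed)
  if (length(bad) > 0L) {
    stop(sprintf("invalid character(s) in %s: %s", what,
                 paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Alphabet conversions and reverse complement
#'
#' `rna_to_dna` applies U->T, `dna_to_rna` applies T->U;
#' `reverse_complement` complements (A<->T, C<->G, N->N; U treated as T)
#' and reverses.  Input alphabet is ACGTUN, case-insensitive.
#'
#' @param seq Character vector of sequences.
#' @return Character vector of converted sequences.
#' @rdname alphabet
#' @export
rna_to_dna <- function(seq) {
  seq <- toupper(seq)
  .check_alphabet(seq, c(DNA_ALPHABET, "U"))
  chartr("U", "T", seq)
}

#' @rdname alphabet
#' @export
dna_to_rna <- function(seq) {
  seq <- toupper(seq)
  .check_alphabet(seq, c(DNA_ALPHABET, "U"))
  chartr("T", "U", seq)
}

#' @rdname alphabet
#' @export
reverse_complement <- function(seq) {
  seq <- rna_to_dna(seq)
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Read a 2-column headerless seed table
#'
#' Column 1: miRNA family name; column 2: seed as a DNA sequence
#' (U already replaced by T).
#'
#' @param path Path to a tab-delimited file.
#' @return Named character vector, family -> uppercase seed.
#' @export
read_seed_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop(sprintf("seed file '%s' needs 2 tab-separated columns", path))
  seeds <- toupper(df[[2]])
  .check_alphabet(seeds, DNA_ALPHABET, sprintf("seeds in '%s'", path))
  stats::setNames(seeds, df[[1]])
}

#' Assemble the mature-miRNA table
#'
#' Combines a mature-sequence FASTA with (optional) forward /
#' reverse-complement seed tables into the canonical miRNA data.frame.  The
#' family of a mature sequence is taken, in order of precedence, from
#' `family_map`, from a `family=<name>` tag on the FASTA header, or from
#' the record id itself.
#'
#' Consistency checks: `seed_rc` must equal the reverse complement of
#' `seed_fwd`; a seed that does not occur inside its mature sequence
#' (after U->T) yields a warning only, since seeds are user input.
#'
#' @param mature_fasta Path to a FASTA of mature miRNA sequences (RNA or
#'   DNA alphabet; stored as RNA).
#' @param seeds_fwd,seeds_rc Named vectors as from [read_seed_table()], or
#'   paths, or NULL (modes that do not use seeds).
#' @param family_map Optional data.frame with columns mature_name, family.
#' @return data.frame with columns family, mature_name, mature_seq (RNA),
#'   seed_fwd, seed_rc (DNA; NA when no seeds supplied).
#' @export
load_mirna_set <- function(mature_fasta, seeds_fwd = NULL, seeds_rc = NULL,
                           family_map = NULL) {
  fa <- read_fasta(mature_fasta)
  headers <- attr(fa, "headers")
  mature_name <- names(fa)
  mature_seq <- dna_to_rna(unname(fa))
  .check_alphabet(mature_seq, RNA_ALPHABET, "mature miRNA sequences")

  family <- mature_name
  tag <- regmatches(headers, regexec("family=(\\S+)", headers))
  has_tag <- vapply(tag, length, integer(1)) == 2L
  family[has_tag] <- vapply(tag[has_tag], `[[`, character(1), 2L)
  if (!is.null(family_map)) {
    idx <- match(mature_name, family_map$mature_name)
    family[!is.na(idx)] <- family_map$family[idx[!is.na(idx)]]
  }

  if (is.character(seeds_fwd) && length(seeds_fwd) == 1L && file.exists(seeds_fwd)) {
    seeds_fwd <- read_seed_table(seeds_fwd)
  }
  if (is.character(seeds_rc) && length(seeds_rc) == 1L && file.exists(seeds_rc)) {
    seeds_rc <- read_seed_table(seeds_rc)
  }
  seed_fwd <- seed_rc <- rep(NA_character_, length(mature_name))
  if (!is.null(seeds_fwd)) {
    seed_fwd <- unname(seeds_fwd[family])
    if (!is.null(seeds_rc)) {
      seed_rc <- unname(seeds_rc[family])
      have_both <- !is.na(seed_fwd) & !is.na(seed_rc)
      bad <- have_both & seed_rc != reverse_complement(seed_fwd)
      if (any(bad)) {
        stop("reverse-complement seed mismatch for: ",
             paste(unique(family[bad]), collapse = ", "))
      }
    }
    seed_rc[is.na(seed_rc) & !is.na(seed_fwd)] <-
      reverse_complement(seed_fwd[is.na(seed_rc) & !is.na(seed_fwd)])
    in_mature <- is.na(seed_fwd) |
      mapply(grepl, seed_fwd, rna_to_dna(mature_seq), MoreArgs = list(fixed = TRUE))
    if (any(!in_mature)) {
      warning("seed not found inside mature sequence for: ",
              paste(mature_name[!in_mature], collapse = ", "))
    }
  }
  data.frame(family = family, mature_name = mature_name,
             mature_seq = mature_seq, seed_fwd = seed_fwd, seed_rc = seed_rc,
             stringsAsFactors = FALSE)
}

#' Read a per-family mature-miRNA directory layout
#'
#' Accepts the "one folder per miRNA family, one FASTA per mature sequence"
#' layout and flattens it: the folder name is the family, the FASTA file
#' name (without extension) is the mature name.
#'
#' @param dir Path to the directory of per-family folders.
#' @return list with elements `fasta` (named character vector of mature
#'   sequences) and `family_map` (data.frame mature_name, family).
#' @export
read_mature_dirs <- function(dir) {
  fams <- list.dirs(dir, recursive = FALSE, full.names = TRUE)
  if (length(fams) == 0L) stop(sprintf("no family folders under '%s'", dir))
  seqs <- character(0)
  map <- list()
  for (fd in sort(fams)) {
    fam <- basename(fd)
    files <- sort(list.files(fd, pattern = "\\.(fa|fasta)$", full.names = TRUE))
    for (f in files) {
      nm <- sub("\\.(fa|fasta)$", "", basename(f))
      fa <- read_fasta(f)
      seqs[[nm]] <- unname(fa[1L])
      map[[length(map) + 1L]] <- data.frame(mature_name = nm, family = fam,
                                            stringsAsFactors = FALSE)
    }
  }
  list(fasta = seqs, family_map = do.call(rbind, map))
}

#' Read an expression table (features x samples)
#'
#' First column: feature id (gene name, promoter id, or miRNA family name);
#' remaining columns: samples.  Values must be finite and non-negative.
#'
#' @param path Path to a TSV with a header row.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 2L) stop(sprintf("expression table '%s' needs >= 2 columns", path))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  if (anyNA(m) || any(!is.finite(m))) {
    stop(sprintf("expression table '%s' contains missing or non-finite values", path))
  }
  if (any(m < 0)) {
    stop(sprintf("expression table '%s' contains negative values", path))
  }
  m
}

#' Read the enhancer:gene association table
#'
#' Two tab-separated columns: enhancer id, gene name.  A header row is
#' auto-detected: the first row is treated as a header when its first field
#' does not parse as a `"chrom:start-end"` id.  Duplicate pairs are
#' collapsed with a warning.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns enhancer_id, gene_name (unique pairs).
#' @export
read_enhancer_gene_links <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop(sprintf("link table '%s' needs 2 tab-separated columns", path))
  looks_like_id <- grepl("^.+:[0-9]+-[0-9]+$", df[1, 1])
  if (!looks_like_id && nrow(df) > 0L) df <- df[-1, , drop = FALSE]
  out <- data.frame(enhancer_id = df[[1]], gene_name = df[[2]],
                    stringsAsFactors = FALSE)
  dup <- duplicated(out)
  if (any(dup)) {
    warning(sprintf("%d duplicate enhancer:gene pairs collapsed in '%s'",
                    sum(dup), path))
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Validate that two expression tables can be correlated
#'
#' Both matrices must have identical sample ordering and at least
#' `min_samples` samples.
#'
#' @param mirna_expr,gene_expr Matrices from [read_expression_table()].
#' @param min_samples Minimum sample count (default 8).
#' @return TRUE invisibly, or an error.
#' @export
check_expression_compat <- function(mirna_expr, gene_expr, min_samples = 8L) {
  if (!identical(colnames(mirna_expr), colnames(gene_expr))) {
    stop("miRNA and gene expression tables must share an identical sample ordering")
  }
  if (ncol(gene_expr) < min_samples) {
    stop(sprintf("expression tables have %d samples; >= %d required",
                 ncol(gene_expr), min_samples))
  }
  invisible(TRUE)
}
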