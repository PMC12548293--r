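#' Reverse complement of character motifs
#'
#' @param x character vector of DNA strings (A/C/G/T).
#' @return character vector of reverse complements.
#' @keywords internal
#' @noRd
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonicalize a microsatellite motif
#'
#' Combines data from complementary strands by mapping every motif to the
#' lexicographic minimum of the motif and its reverse complement. Rotations
#' are deliberately not merged, so GA/TC and AG/CT remain distinct motif
#' classes.
#'
#' @param motif character vector of repeat units (1-6 bp, alphabet ACGT).
#' @return character vector of canonical motifs, same length as `motif`.
#' @examples
#' canonicalize_motif(c("T", "TG", "A", "TC", "CT"))
#' @export
canonicalize_motif <- function(motif) {
  if (length(motif) == 0L) return(character(0))
  if (any(is.na(motif)) || any(!nzchar(motif)))
    stop("motif must be a non-empty string")
  if (any(nchar(motif) > 6L))
    stop("motif longer than 6 bp is not supported")
  if (any(grepl("[^ACGT]", motif)))
    stop("motif contains characters outside the ACGT alphabet")
  rc <- revcomp_chr(motif)
  ifelse(rc < motif, rc, motif)
}

## Scan one chromosome (character string) for maximal perfect repeats of one
## motif size. Contract: maximal period-k runs over ACGT; motif = unit at the
## leftmost base of the run and must be primitive (not a power of a shorter
## unit); unit_count = floor(run_length / k); a run whose tract overlaps an
## already reported same-size locus has its start advanced past that locus
## (greedy left-to-right), motif and unit count recomputed. Returns a
## data.frame with 0-based half-open coordinates.
scan_one_k <- function(chars, k, min_units) {
  n <- length(chars)
  if (n < k * min_units) return(NULL)
  valid <- chars %in% c("A", "C", "G", "T")
  i <- seq_len(n - k)
  eq <- (chars[i] == chars[i + k]) & valid[i] & valid[i + k]
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths + k >= k * min_units)
  if (!any(keep)) return(NULL)
  starts <- starts[keep]
  tract_end <- ends[keep] + k     # inclusive 1-based end of periodic tract
  out_start <- integer(0); out_uc <- integer(0); out_motif <- character(0)
  last_end <- 0L                   # inclusive 1-based end of last reported locus
  for (j in seq_along(starts)) {
    s <- starts[j]
    if (s <= last_end) s <- last_end + 1L
    uc <- (tract_end[j] - s + 1L) %/% k
    if (uc < min_units) next
    motif <- paste(chars[s:(s + k - 1L)], collapse = "")
    if (!is_primitive_motif(motif)) next
    out_start <- c(out_start, s)
    out_uc <- c(out_uc, uc)
    out_motif <- c(out_motif, motif)
    last_end <- s + uc * k - 1L
  }
  if (length(out_start) == 0L) return(NULL)
  data.frame(
    start = out_start - 1L,                 # 0-based
    end = out_start - 1L + out_uc * k,      # half-open
    motif = out_motif,
    unit_count = out_uc,
    stringsAsFactors = FALSE
  )
}

## TRUE unless the motif is a power of a shorter unit (e.g. "AA", "AAA").
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d != 0L) next
    unit <- substr(motif, 1L, d)
    if (strrep(unit, k %/% d) == motif) return(FALSE)
  }
  TRUE
}

#' Catalog perfect mono-/di-/tri-nucleotide repeats in a reference
#'
#' Finds every maximal perfect tandem repeat of motif size 1-3 meeting the
#' per-size minimum unit counts. Repeats must be perfect (no interruptions);
#' ambiguous bases (N) terminate runs. Motifs are primitive, so a
#' homopolymer is reported only at motif size 1. Loci of the same motif size
#' never overlap; overlaps across motif sizes are allowed (a mononucleotide
#' run inside a dinucleotide context is reported at both sizes when each
#' meets its threshold).
#'
#' @param reference a `Biostrings::DNAStringSet`, a named character vector of
#'   sequences, or the path to a (optionally gzipped) FASTA file.
#' @param min_units integer vector of minimum unit counts for motif sizes
#'   1, 2, 3 (defaults mono >= 5, di >= 3, tri >= 3).
#' @return a `data.frame` sorted by (chrom, start, motif size) with columns
#'   `chrom`, `start`, `end` (0-based half-open), `locus_id`, `motif`,
#'   `canonical_motif`, `unit_count`.
#' @examples
#' scan_reference(c(chr1 = "GGAAAAAGG"))
#' @export
scan_reference <- function(reference, min_units = c(5L, 3L, 3L)) {
  seqs <- as_named_sequences(reference)
  if (length(min_units) != 3L || any(min_units < 2L))
    stop("min_units must give minimum unit counts >= 2 for motif sizes 1-3")
  min_units <- as.integer(min_units)
  res <- vector("list", 3L * length(seqs))
  idx <- 0L
  for (chrom in names(seqs)) {
    chars <- strsplit(toupper(seqs[[chrom]]), "", fixed = TRUE)[[1]]
    for (k in 1:3) {
      d <- scan_one_k(chars, k, min_units[k])
      if (is.null(d)) next
      d$chrom <- chrom
      idx <- idx + 1L
      res[[idx]] <- d
    }
  }
  if (idx == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), locus_id = character(0),
                      motif = character(0), canonical_motif = character(0),
                      unit_count = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res[seq_len(idx)])
  out$canonical_motif <- canonicalize_motif(out$motif)
  out$locus_id <- paste(out$chrom, out$start, out$motif, sep = "_")
  out <- out[order(out$chrom, out$start, nchar(out$motif)),
             c("chrom", "start", "end", "locus_id", "motif",
               "canonical_motif", "unit_count")]
  rownames(out) <- NULL
  out
}

## Normalize the accepted reference representations to a named list of
## plain character sequences.
as_named_sequences <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      is.null(names(reference)) && file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (methods::is(reference, "DNAStringSet")) {
    seqs <- as.character(reference)
    names(seqs) <- sub("\\s.*$", "", names(reference))
    return(as.list(seqs))
  }
  if (is.character(reference)) {
    if (length(reference) == 0L) stop("reference is empty")
    if (is.null(names(reference)))
      names(reference) <- paste0("seq", seq_along(reference))
    return(as.list(reference))
  }
  stop("reference must be a DNAStringSet, named character vector, or FASTA path")
}

#' Write / read a microsatellite catalog as BED-like TSV
#'
#' Columns: chrom, start, end, locus_id, motif, canonical_motif, unit_count,
#' with BED 0-based half-open coordinates and no header.
#'
#' @param catalog a catalog `data.frame` from [scan_reference()].
#' @param path output (or input) file path.
#' @return `write_catalog` returns `path` invisibly; `read_catalog` returns
#'   the catalog `data.frame`.
#' @export
write_catalog <- function(catalog, path) {
  write.table(catalog[, c("chrom", "start", "end", "locus_id", "motif",
                          "canonical_motif", "unit_count")],
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("chrom", "start", "end", "locus_id", "motif",
                                "canonical_motif", "unit_count"))
  d$start <- as.integer(d$start); d$end <- as.integer(d$end)
  d$unit_count <- as.integer(d$unit_count)
  d
}
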