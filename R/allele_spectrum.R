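#' Measure the repeat length a read supports at a microsatellite locus
#'
#' The observed unit count is measured by sequence pattern matching rather
#' than from the CIGAR, because aligners place indels within repeats
#' ambiguously. The read must contain, in order, at least `min_flank`
#' reference-matching anchor bases on both sides of the tract; the unit
#' count is the number of consecutive motif copies between the located
#' anchors. A read lacking either anchor (e.g. one that ends inside the
#' tract) yields no observation.
#'
#' @param read_seq read sequence (character scalar).
#' @param locus one row of a catalog from [scan_reference()].
#' @param reference the reference sequences (any form accepted by
#'   [scan_reference()]); anchors are taken from the locus's chromosome.
#' @param min_flank minimum anchor length on each side (default 5).
#' @return integer observed unit count (>= 0), or `NA_integer_` for
#'   no-observation.
#' @export
measure_read_repeat_length <- function(read_seq, locus, reference,
                                       min_flank = 5L) {
  seqs <- as_named_sequences(reference)
  chrom_seq <- seqs[[locus$chrom]]
  if (is.null(chrom_seq)) return(NA_integer_)
  anchors <- locus_anchors(locus, chrom_seq, min_flank)
  if (is.null(anchors)) return(NA_integer_)
  count_units_between_anchors(read_seq, locus$motif,
                              anchors$left, anchors$right)
}

## Reference anchor sequences flanking the tract, or NULL when the locus sits
## too close to the sequence edge to anchor.
locus_anchors <- function(locus, chrom_seq, min_flank) {
  s <- locus$start; e <- locus$end      # 0-based half-open
  if (s - min_flank < 0L || e + min_flank > nchar(chrom_seq)) return(NULL)
  list(left = substr(chrom_seq, s - min_flank + 1L, s),
       right = substr(chrom_seq, e + 1L, e + min_flank))
}

## Core anchor-based unit counter. Tries every occurrence of the left anchor
## and accepts the first at which consecutive motif copies run directly into
## the right anchor. Returns NA when no occurrence qualifies.
count_units_between_anchors <- function(read_seq, motif, left, right) {
  k <- nchar(motif)
  # overlapping occurrences (a periodic flank can contain the anchor at
  # overlapping offsets)
  hits <- gregexpr(paste0("(?=", left, ")"), read_seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(NA_integer_)
  fl <- nchar(left); fr <- nchar(right); n <- nchar(read_seq)
  for (p in hits) {
    at <- p + fl                         # first base after the left anchor
    u <- 0L
    while (at + k - 1L <= n &&
           substr(read_seq, at, at + k - 1L) == motif) {
      u <- u + 1L
      at <- at + k
    }
    if (at + fr - 1L <= n && substr(read_seq, at, at + fr - 1L) == right)
      return(u)
  }
  NA_integer_
}

#' Build per-locus allele-length spectra from aligned reads
#'
#' Converts alignments into one repeat-length histogram per catalog locus.
#' Unmapped, secondary, supplementary and duplicate-marked records and
#' records below `min_mapq` are ignored. A read contributes one observation
#' to a locus only when it spans the tract with intact anchors (see
#' [measure_read_repeat_length()]). Loci with fewer than `min_depth`
#' observations are emitted flagged `insufficient` and are excluded from
#' downstream statistics; loci with zero observations are omitted.
#'
#' @param alignments path to a SAM/BAM file, or a data.frame as returned by
#'   [read_alignments()].
#' @param catalog microsatellite catalog from [scan_reference()].
#' @param reference the reference sequences the catalog was scanned from.
#' @param sample_id sample label recorded in the output.
#' @param min_flank anchor length (default 5).
#' @param min_mapq minimum mapping quality (default 20).
#' @param min_depth minimum spanning observations per locus (default 10).
#' @return a spectra table: data.frame with columns `sample_id`, `locus_id`,
#'   `chrom`, `start`, `motif`, `canonical_motif`, `ref_units`,
#'   `total_reads`, `insufficient` and the list-column `spectrum` (named
#'   integer vector, names = observed unit counts).
#' @export
extract_spectra <- function(alignments, catalog, reference, sample_id,
                            min_flank = 5L, min_mapq = 20L, min_depth = 10L) {
  if (nrow(catalog) == 0L) stop("catalog is empty")
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  fl <- alignments$flag
  drop <- bitwAnd(fl, 0x4L) > 0L | bitwAnd(fl, 0x100L) > 0L |
    bitwAnd(fl, 0x800L) > 0L | bitwAnd(fl, 0x400L) > 0L |
    alignments$mapq < min_mapq | is.na(alignments$chrom)
  reads <- alignments[!drop, , drop = FALSE]
  seqs <- as_named_sequences(reference)
  spectra <- vector("list", nrow(catalog))
  n_obs <- integer(nrow(catalog))
  if (nrow(reads) > 0L) {
    read_gr <- GenomicRanges::GRanges(
      reads$chrom,
      IRanges::IRanges(reads$pos, width = nchar(reads$seq) + 20L))
    loc_gr <- GenomicRanges::GRanges(
      catalog$chrom,
      IRanges::IRanges(pmax(1L, catalog$start - min_flank + 1L),
                       catalog$end + min_flank))
    hits <- GenomicRanges::findOverlaps(loc_gr, read_gr,
                                        type = "within")
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    for (i in unique(q)) {
      locus <- catalog[i, ]
      chrom_seq <- seqs[[locus$chrom]]
      anchors <- locus_anchors(locus, chrom_seq, min_flank)
      if (is.null(anchors)) next
      obs <- vapply(reads$seq[s[q == i]], function(sq)
        count_units_between_anchors(sq, locus$motif,
                                    anchors$left, anchors$right),
        integer(1), USE.NAMES = FALSE)
      obs <- obs[!is.na(obs)]
      if (length(obs) == 0L) next
      tab <- table(obs)
      spectra[[i]] <- setNames(as.integer(tab), names(tab))
      n_obs[i] <- length(obs)
    }
  }
  keep <- n_obs > 0L
  if (!any(keep)) {
    warning("no locus had any spanning observation")
  }
  out <- data.frame(
    sample_id = sample_id,
    locus_id = catalog$locus_id[keep],
    chrom = catalog$chrom[keep],
    start = catalog$start[keep],
    motif = catalog$motif[keep],
    canonical_motif = catalog$canonical_motif[keep],
    ref_units = catalog$unit_count[keep],
    total_reads = n_obs[keep],
    insufficient = n_obs[keep] < min_depth,
    stringsAsFactors = FALSE
  )
  out$spectrum <- spectra[keep]
  rownames(out) <- NULL
  out
}

#' Allele proportions of one spectrum
#'
#' @param counts named integer vector (names = unit counts).
#' @return named numeric vector of proportions summing to 1.
#' @export
spectrum_proportions <- function(counts) {
  total <- sum(as.numeric(counts))
  if (total <= 0) stop("empty spectrum")
  counts / total
}
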