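#' Read alignments from SAM or BAM into a flat data.frame
#'
#' SAM input is converted with `Rsamtools::asBam()` and read back with
#' `Rsamtools::scanBam()`. Only the fields the pipeline consumes are kept.
#'
#' @param path path to a SAM or BAM file.
#' @return data.frame with columns `qname`, `flag`, `chrom`, `pos`, `mapq`,
#'   `cigar`, `seq` (`chrom` is `NA` and `pos` 0 for unmapped records).
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, dest,
                                             overwrite = TRUE,
                                             indexDestination = FALSE))
  } else {
    bam <- path
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1]]
  data.frame(
    qname = res$qname,
    flag = res$flag,
    chrom = as.character(res$rname),
    pos = ifelse(is.na(res$pos), 0L, res$pos),
    mapq = ifelse(is.na(res$mapq), 0L, res$mapq),
    cigar = ifelse(is.na(res$cigar), "*", res$cigar),
    seq = as.character(res$seq),
    stringsAsFactors = FALSE
  )
}

#' Write a read table as SAM
#'
#' @param reads data.frame with columns `qname`, `flag`, `chrom`, `pos`,
#'   `mapq`, `cigar`, `seq` and optionally `rnext`, `pnext`, `tlen`.
#'   Unmapped records use `chrom = "*"`, `pos = 0`.
#' @param seqlengths named integer vector of reference sequence lengths for
#'   the header.
#' @param path output path (conventionally `.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, seqlengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  rnext <- if ("rnext" %in% names(reads)) reads$rnext else "*"
  pnext <- if ("pnext" %in% names(reads)) reads$pnext else 0L
  tlen <- if ("tlen" %in% names(reads)) reads$tlen else 0L
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*",
                  reads$qname, as.integer(reads$flag), reads$chrom,
                  as.integer(reads$pos), as.integer(reads$mapq),
                  reads$cigar, rnext, as.integer(pnext), as.integer(tlen),
                  reads$seq)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (or list) of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

## Serialize a named integer count vector to "units:count,..." sorted by units.
spectrum_to_string <- function(counts) {
  u <- as.integer(names(counts))
  o <- order(u)
  paste(sprintf("%d:%d", u[o], as.integer(counts[o])), collapse = ",")
}

## Inverse of spectrum_to_string.
string_to_spectrum <- function(s) {
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  counts <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  names(counts) <- vapply(parts, `[`, character(1), 1)
  counts
}

#' Write / read per-locus allele spectra in the .dis-like TSV dialect
#'
#' One row per locus, tab-separated, with header: `sample_id`, `locus_id`,
#' `chrom`, `start`, `motif`, `canonical_motif`, `ref_units`, `spectrum`.
#' The `spectrum` field is a comma-separated list of `units:count` pairs
#' sorted by units. Loci flagged insufficient are not written unless
#' `include_insufficient = TRUE`.
#'
#' @param spectra a spectra table as returned by [extract_spectra()].
#' @param path file path.
#' @param include_insufficient keep below-depth loci in the output?
#' @return `write_dis` returns `path` invisibly; `read_dis` the spectra table.
#' @export
write_dis <- function(spectra, path, include_insufficient = FALSE) {
  d <- spectra
  if (!include_insufficient && "insufficient" %in% names(d))
    d <- d[!d$insufficient, , drop = FALSE]
  out <- data.frame(
    sample_id = d$sample_id, locus_id = d$locus_id, chrom = d$chrom,
    start = d$start, motif = d$motif, canonical_motif = d$canonical_motif,
    ref_units = d$ref_units,
    spectrum = vapply(d$spectrum, spectrum_to_string, character(1)),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dis
#' @export
read_dis <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(spectrum = "character"))
  d$spectrum <- lapply(d$spectrum, string_to_spectrum)
  d$total_reads <- vapply(d$spectrum, function(x) sum(as.integer(x)),
                          integer(1))
  d$insufficient <- rep(FALSE, nrow(d))
  d
}
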