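## Local alignment of read sequences against the plasmid, both strands.
## Scoring: match +1, mismatch -2, gap -3 per gapped base (declared
## constants). Returns best-strand score and subject start per read.
align_to_plasmid <- function(seqs, plasmid_seq) {
  subject <- Biostrings::DNAString(plasmid_seq)
  mat <- matrix(-2, 5, 5,
                dimnames = list(c("A", "C", "G", "T", "N"),
                                c("A", "C", "G", "T", "N")))
  diag(mat) <- 1
  mat["N", ] <- -2; mat[, "N"] <- -2
  pat_fwd <- Biostrings::DNAStringSet(seqs)
  pat_rev <- Biostrings::reverseComplement(pat_fwd)
  aln_f <- Biostrings::pairwiseAlignment(
    pat_fwd, subject, type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 3)
  aln_r <- Biostrings::pairwiseAlignment(
    pat_rev, subject, type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 3)
  sf <- Biostrings::score(aln_f); sr <- Biostrings::score(aln_r)
  use_r <- sr > sf
  data.frame(
    score = ifelse(use_r, sr, sf),
    plasmid_pos = ifelse(
      use_r,
      BiocGenerics::start(Biostrings::subject(aln_r)),
      BiocGenerics::start(Biostrings::subject(aln_f))),
    plasmid_strand = ifelse(use_r, "-", "+"),
    stringsAsFactors = FALSE
  )
}

#' Extract chimeric read-pair evidence of a transgene integration
#'
#' Selects read pairs in which exactly one mate is mapped to the host
#' genome (with sufficient mapping quality) while its mate is unmapped,
#' re-aligns the unmapped mates against the plasmid reference with a gapped
#' local aligner, and keeps pairs whose plasmid hit reaches at least
#' `min_score_frac` of the maximum attainable score (read length x match
#' score). With host-referenced input the reciprocal pass of the procedure
#' (plasmid-mapped mates whose partners are re-checked against the host) is
#' implicit: the retained pairs are exactly those with one host-supported
#' and one plasmid-supported mate.
#'
#' @param alignments host-referenced SAM/BAM path or a data.frame from
#'   [read_alignments()].
#' @param plasmid plasmid reference: FASTA path, `DNAStringSet`, or named
#'   character vector (single sequence).
#' @param min_mapq minimum mapping quality of the host-mapped mate.
#' @param min_score_frac minimum fraction of the maximum attainable
#'   alignment score (default 0.8).
#' @return data.frame of evidence records: `read_id`, `host_chrom`,
#'   `host_pos`, `host_strand`, `plasmid_pos`, `plasmid_strand`, `score`.
#'   The number of realigned-but-discarded mates is attached as attribute
#'   `"n_below_score"`.
#' @export
find_chimeric_pairs <- function(alignments, plasmid, min_mapq = 20L,
                                min_score_frac = 0.8) {
  plasmid_seqs <- as_named_sequences(plasmid)
  if (length(plasmid_seqs) == 0L || !nzchar(plasmid_seqs[[1]]))
    stop("plasmid reference is empty")
  plasmid_seq <- plasmid_seqs[[1]]
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  a <- alignments
  a <- a[bitwAnd(a$flag, 0x100L) == 0L & bitwAnd(a$flag, 0x800L) == 0L, ,
         drop = FALSE]
  unmapped <- bitwAnd(a$flag, 0x4L) > 0L
  paired_tab <- table(a$qname)
  singletons <- names(paired_tab)[paired_tab != 2L]
  if (length(singletons))
    warning(length(singletons), " read name(s) without exactly one mate ",
            "pair were skipped")
  a <- a[!a$qname %in% singletons, , drop = FALSE]
  unmapped <- bitwAnd(a$flag, 0x4L) > 0L
  st <- tapply(unmapped, a$qname, sum)
  cand <- names(st)[st == 1L]
  if (length(cand) == 0L) {
    out <- data.frame(read_id = character(0), host_chrom = character(0),
                      host_pos = integer(0), host_strand = character(0),
                      plasmid_pos = integer(0), plasmid_strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
    attr(out, "n_below_score") <- 0L
    return(out)
  }
  sel <- a[a$qname %in% cand, , drop = FALSE]
  mapped <- sel[bitwAnd(sel$flag, 0x4L) == 0L, , drop = FALSE]
  unm <- sel[bitwAnd(sel$flag, 0x4L) > 0L, , drop = FALSE]
  keep_q <- mapped$qname[mapped$mapq >= min_mapq]
  mapped <- mapped[mapped$qname %in% keep_q, , drop = FALSE]
  unm <- unm[unm$qname %in% keep_q, , drop = FALSE]
  if (nrow(unm) == 0L) {
    out <- data.frame(read_id = character(0), host_chrom = character(0),
                      host_pos = integer(0), host_strand = character(0),
                      plasmid_pos = integer(0), plasmid_strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
    attr(out, "n_below_score") <- 0L
    return(out)
  }
  unm <- unm[match(mapped$qname, unm$qname), , drop = FALSE]
  hits <- align_to_plasmid(unm$seq, plasmid_seq)
  ok <- hits$score >= min_score_frac * nchar(unm$seq)
  out <- data.frame(
    read_id = mapped$qname[ok],
    host_chrom = mapped$chrom[ok],
    host_pos = mapped$pos[ok],
    host_strand = ifelse(bitwAnd(mapped$flag[ok], 0x10L) > 0L, "-", "+"),
    plasmid_pos = hits$plasmid_pos[ok],
    plasmid_strand = hits$plasmid_strand[ok],
    score = hits$score[ok],
    stringsAsFactors = FALSE
  )
  attr(out, "n_below_score") <- sum(!ok)
  out
}

#' Cluster chimeric evidence into integration-site calls
#'
#' Single-linkage clustering of host-mapped positions: evidence records on
#' the same chromosome separated by at most `window` bp join one cluster;
#' clusters supported by at least `min_support` pairs become calls spanning
#' the minimum to maximum supporting host position.
#'
#' @param evidence data.frame from [find_chimeric_pairs()].
#' @param window maximum gap between neighboring supporting positions
#'   (default 1000 bp).
#' @param min_support minimum supporting pairs per call (default 3).
#' @return data.frame of calls: `host_chrom`, `start`, `end`,
#'   `n_supporting`, `mean_score`, `max_score`, `n_forward`, `n_reverse`.
#' @export
cluster_evidence <- function(evidence, window = 1000L, min_support = 3L) {
  empty <- data.frame(host_chrom = character(0), start = integer(0),
                      end = integer(0), n_supporting = integer(0),
                      mean_score = numeric(0), max_score = numeric(0),
                      n_forward = integer(0), n_reverse = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(evidence) == 0L) return(empty)
  ev <- evidence[order(evidence$host_chrom, evidence$host_pos), ,
                 drop = FALSE]
  new_cluster <- c(TRUE, ev$host_chrom[-1] != ev$host_chrom[-nrow(ev)] |
                     diff(ev$host_pos) > window)
  ev$cluster <- cumsum(new_cluster)
  calls <- do.call(rbind, lapply(split(ev, ev$cluster), function(g) {
    data.frame(
      host_chrom = g$host_chrom[1],
      start = min(g$host_pos),
      end = max(g$host_pos),
      n_supporting = nrow(g),
      mean_score = mean(g$score),
      max_score = max(g$score),
      n_forward = sum(g$host_strand == "+"),
      n_reverse = sum(g$host_strand == "-"),
      stringsAsFactors = FALSE
    )
  }))
  calls <- calls[calls$n_supporting >= min_support, , drop = FALSE]
  rownames(calls) <- NULL
  if (nrow(calls) == 0L) empty else calls
}

#' Write integration calls as BED
#'
#' @param calls data.frame from [cluster_evidence()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_integration_bed <- function(calls, path) {
  write.table(data.frame(calls$host_chrom, calls$start - 1L, calls$end,
                         sprintf("integration_%d", seq_len(nrow(calls))),
                         calls$n_supporting),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
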