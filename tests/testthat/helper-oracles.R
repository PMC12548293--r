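# Independent oracles used to cross-check the implementation. They share the
# declared contracts but not the implementation mechanics.

# Exhaustive microsatellite scan: tests every start position and unit size
# with explicit per-start unit counting, then applies the same declared
# greedy overlap rule. The implementation uses shifted-vector comparisons
# and run-length encoding instead.
oracle_scan <- function(seqs, min_units = c(5L, 3L, 3L)) {
  res <- list()
  for (chrom in names(seqs)) {
    chars <- strsplit(toupper(seqs[[chrom]]), "", fixed = TRUE)[[1]]
    n <- length(chars)
    ok <- chars %in% c("A", "C", "G", "T")
    for (k in 1:3) {
      if (n < k + 1L) next
      # prefilter: a run of >= 2 units needs the first unit to repeat
      eq <- chars[seq_len(n - k)] == chars[seq_len(n - k) + k] &
        ok[seq_len(n - k)] & ok[seq_len(n - k) + k]
      unit_count_at <- function(s) {
        L <- k
        while (s + L <= n && ok[s + L] && chars[s + L] == chars[s + L - k])
          L <- L + 1L
        L %/% k
      }
      primitive <- function(m) {
        if (k == 1L) return(TRUE)
        if (k == 2L) return(substr(m, 1, 1) != substr(m, 2, 2))
        !(substr(m, 1, 1) == substr(m, 2, 2) &&
            substr(m, 2, 2) == substr(m, 3, 3))
      }
      starts <- which(eq)
      starts <- starts[vapply(starts, function(s) {
        all(ok[s:(s + k - 1L)]) &&
          (s == 1L || !ok[s - 1L] || chars[s - 1L] != chars[s - 1L + k])
      }, logical(1))]
      last_end <- 0L
      for (s in sort(starts)) {
        s2 <- if (s <= last_end) last_end + 1L else s
        uc <- unit_count_at(s2)
        if (uc < min_units[k]) next
        motif <- paste(chars[s2:(s2 + k - 1L)], collapse = "")
        if (!primitive(motif)) next
        res[[length(res) + 1L]] <- data.frame(
          chrom = chrom, start = s2 - 1L, end = s2 - 1L + uc * k,
          motif = motif, unit_count = uc, stringsAsFactors = FALSE)
        last_end <- s2 + uc * k - 1L
      }
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      unit_count = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start, nchar(out$motif)), ]
  rownames(out) <- NULL
  out
}

# Brute-force somatic filter: evaluates every rule independently and keeps
# records passing all of them.
oracle_filter <- function(v) {
  keep <- v$tumor_depth >= 10 & v$normal_depth >= 10 &
    v$tumor_alt_reads >= 3 & v$normal_alt_reads == 0 &
    !sub("^chr", "", v$chrom) %in% c("X", "Y", "M", "MT") &
    !v$in_dbsnp & v$shared_tumor_count < 2
  v[keep, , drop = FALSE]
}

# Exhaustive homopolymer-run recomputation for reporter indel context:
# regex-scans the sequence for A/T runs and reports the run length at a
# position (0 when the base does not belong to an A/T run).
oracle_at_run_length <- function(seq, pos0) {
  m <- gregexpr("A+|T+", seq)[[1]]
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    if (pos0 >= starts[i] && pos0 < starts[i] + lens[i]) return(lens[i])
  }
  0L
}

# Random i.i.d. uniform ACGT sequence (unconstrained, unlike the package's
# repeat-free simulator), for stress-testing the scanner.
random_sequence <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Catalog comparison helper ignoring locus_id / canonical columns.
catalog_core <- function(cat) {
  d <- cat[, c("chrom", "start", "end", "motif", "unit_count")]
  d <- d[order(d$chrom, d$start, nchar(d$motif)), ]
  rownames(d) <- NULL
  d
}

# Random variant generator with planted rule violations for filter tests.
random_variants <- function(n, seed) {
  set.seed(seed)
  data.frame(
    chrom = sample(c(as.character(1:19), "X", "Y", "M", "chr5"), n, TRUE),
    pos = sample.int(1e6, n),
    ref = sample(c("A", "C", "G", "T"), n, TRUE),
    alt = sample(c("A", "C", "G", "T"), n, TRUE),
    sample_id = sample(c("t1", "t2"), n, TRUE),
    tumor_depth = sample(5:40, n, TRUE),
    normal_depth = sample(5:40, n, TRUE),
    tumor_alt_reads = sample(0:10, n, TRUE),
    normal_alt_reads = sample(0:2, n, TRUE),
    in_dbsnp = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.2, 0.8)),
    shared_tumor_count = sample(0:3, n, TRUE),
    stringsAsFactors = FALSE
  )
}

# A small deterministic catalog of synthetic loci (no sequence needed) used
# by slippage-simulation tests.
synthetic_catalog <- function(motifs, unit_counts) {
  grid <- expand.grid(motif = motifs, unit_count = unit_counts,
                      stringsAsFactors = FALSE)
  data.frame(
    chrom = "sim",
    start = seq_len(nrow(grid)) * 1000L,
    end = seq_len(nrow(grid)) * 1000L +
      nchar(grid$motif) * grid$unit_count,
    locus_id = sprintf("L%04d", seq_len(nrow(grid))),
    motif = grid$motif,
    canonical_motif = canonicalize_motif(grid$motif),
    unit_count = grid$unit_count,
    stringsAsFactors = FALSE
  )
}
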