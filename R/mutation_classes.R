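## Chromosome-name dialects ("chr7", "MT") normalized to bare names ("7","M").
normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  x[x == "MT"] <- "M"
  x
}

#' Filter somatic variant calls by the post-calling criteria
#'
#' Retains exactly the variants passing all rules: total read depth >= 10 in
#' both tumor and normal, >= 3 variant-supporting reads in the tumor and
#' none in the normal, autosomal location (chromosomes X, Y and M are
#' excluded), absence from dbSNP, and not shared by two or more tumors.
#' Rules are evaluated in a fixed order and each rejected variant is tallied
#' under the first rule it fails; the retained set is independent of rule
#' order.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `sample_id`, `tumor_depth`, `normal_depth`, `tumor_alt_reads`,
#'   `normal_alt_reads`, `in_dbsnp` (logical), `shared_tumor_count`
#'   (integer).
#' @param min_depth minimum total depth in tumor and normal (default 10).
#' @param min_tumor_alt minimum tumor variant-supporting reads (default 3).
#' @param max_normal_alt maximum normal variant-supporting reads (default 0).
#' @param exclude_chroms chromosomes removed from analysis.
#' @return list with `retained` (passing variants), `rejected` (with a
#'   `reason` column naming the first failed rule), and `tally` (per-rule
#'   rejection counts in rule order).
#' @export
filter_somatic <- function(variants, min_depth = 10L, min_tumor_alt = 3L,
                           max_normal_alt = 0L,
                           exclude_chroms = c("X", "Y", "M")) {
  need <- c("tumor_depth", "normal_depth", "tumor_alt_reads",
            "normal_alt_reads")
  miss <- need[!need %in% names(variants)]
  if (length(miss)) stop("missing depth fields: ", paste(miss, collapse = ", "))
  if (anyNA(variants[need]))
    stop("missing (NA) depth values in input records")
  chrom <- normalize_chrom(variants$chrom)
  rules <- list(
    tumor_depth = variants$tumor_depth < min_depth,
    normal_depth = variants$normal_depth < min_depth,
    tumor_alt_reads = variants$tumor_alt_reads < min_tumor_alt,
    normal_alt_reads = variants$normal_alt_reads > max_normal_alt,
    chromosome = chrom %in% exclude_chroms,
    dbsnp = as.logical(variants$in_dbsnp),
    shared_tumors = variants$shared_tumor_count >= 2L
  )
  fail <- do.call(cbind, rules)
  first_fail <- apply(fail, 1L, function(r) {
    w <- which(r)
    if (length(w)) names(rules)[w[1]] else NA_character_
  })
  keep <- is.na(first_fail)
  tally <- data.frame(
    rule = names(rules),
    n_rejected = vapply(names(rules),
                        function(r) sum(first_fail == r, na.rm = TRUE),
                        integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  rejected <- variants[!keep, , drop = FALSE]
  rejected$reason <- first_fail[!keep]
  list(retained = variants[keep, , drop = FALSE],
       rejected = rejected, tally = tally)
}

#' The 96 trinucleotide substitution classes, COSMIC display order
#' @return character vector like `"A[C>A]A"`, length 96.
#' @export
sbs96_classes <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    unlist(lapply(bases, function(p)
      paste0(p, "[", s, "]", bases)))))
}

#' Classify single-base substitutions into SBS96 classes
#'
#' Base substitutions are described using the pyrimidine base of the
#' mutated Watson-Crick pair: a purine reference base reverse-complements
#' the trinucleotide context and the substitution before classification.
#'
#' @param ref,alt single reference/alternate bases (vectors).
#' @param context trinucleotide reference context centered on the mutated
#'   base (vector).
#' @return character vector of class labels (`"A[C>T]A"` style);
#'   `NA` where the context contains an ambiguous base.
#' @examples
#' classify_sbs96("G", "A", "TGT")  # "A[C>T]A"
#' @export
classify_sbs96 <- function(ref, alt, context) {
  stopifnot(length(ref) == length(alt), length(ref) == length(context))
  if (length(ref) == 0L) return(character(0))
  context <- toupper(context)
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(nchar(ref) != 1L | nchar(alt) != 1L))
    stop("ref and alt must be single bases")
  if (any(substr(context, 2L, 2L) != ref))
    stop("context center does not match ref")
  bad <- grepl("[^ACGT]", context) | !alt %in% c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pur <- ref %in% c("A", "G")
  ctx <- context; a <- alt; r <- ref
  if (any(pur & !bad)) {
    sel <- pur & !bad
    ctx[sel] <- revcomp_chr(context[sel])
    a[sel] <- comp[alt[sel]]
    r[sel] <- comp[ref[sel]]
  }
  out <- paste0(substr(ctx, 1L, 1L), "[", r, ">", a, "]",
                substr(ctx, 3L, 3L))
  out[bad] <- NA_character_
  out
}

#' The 83 indel classes
#'
#' Labels follow the `size:kind:context:category` convention with display
#' categories: 1-bp deletions by base (C/T, pyrimidine of the mutated pair)
#' and homopolymer length 1..5,6 (6 = "6+", run counted including the
#' deleted base); 1-bp insertions with adjacent-run length 0..4,5 (5 =
#' "5+"); longer deletions/insertions at tandem repeats by size 2,3,4,5
#' (5 = "5+") and repeat-unit count (deletions 1..6 including the deleted
#' copy, insertions 0..5); deletions with no tandem copy by flanking
#' microhomology length.
#'
#' @return character vector of 83 labels (e.g. `"1:Del:T:6"`,
#'   `"2:Del:R:1"`, `"3:Del:M:2"`).
#' @export
id83_classes <- function() {
  c(sprintf("1:Del:%s:%d", rep(c("C", "T"), each = 6), 1:6),
    sprintf("1:Ins:%s:%d", rep(c("C", "T"), each = 6), 0:5),
    sprintf("%d:Del:R:%d", rep(2:5, each = 6), 1:6),
    sprintf("%d:Ins:R:%d", rep(2:5, each = 6), 0:5),
    "2:Del:M:1",
    sprintf("3:Del:M:%d", 1:2),
    sprintf("4:Del:M:%d", 1:3),
    sprintf("5:Del:M:%d", 1:5))
}

## Longest run of base `b` in string `sq` ending at 1-based position `p0`
## going leftward / starting at `p0` going rightward.
run_left <- function(sq, p0, b) {
  n <- 0L; i <- p0
  while (i >= 1L && substr(sq, i, i) == b) { n <- n + 1L; i <- i - 1L }
  n
}
run_right <- function(sq, p0, b) {
  n <- 0L; i <- p0; len <- nchar(sq)
  while (i <= len && substr(sq, i, i) == b) { n <- n + 1L; i <- i + 1L }
  n
}

## Count tandem copies of `s` ending just before 1-based position `p`
## (leftward) in string `seq`.
copies_left <- function(seq, p, s) {
  k <- nchar(s); n <- 0L
  while (p - k >= 1L && substr(seq, p - k, p - 1L) == s) {
    n <- n + 1L; p <- p - k
  }
  n
}
copies_right <- function(seq, p, s) {
  k <- nchar(s); n <- 0L
  while (p + k - 1L <= nchar(seq) && substr(seq, p, p + k - 1L) == s) {
    n <- n + 1L; p <- p + k
  }
  n
}

## Left-align an indel: event sequence `s` deleted at (or inserted before)
## 1-based position `p` of `seq`. Returns list(pos, seq) with the canonical
## leftmost representation.
left_align_indel <- function(seq, p, s) {
  k <- nchar(s)
  while (p > 1L && substr(seq, p - 1L, p - 1L) == substr(s, k, k)) {
    s <- paste0(substr(s, k, k), substr(s, 1L, k - 1L))
    p <- p - 1L
  }
  list(pos = p, seq = s)
}

#' Classify a small indel into its ID83 class
#'
#' VCF-style records (anchor base shared by ref and alt) are normalized and
#' left-aligned before classification, so equivalent right-shifted
#' representations classify identically. 1-bp events are classified by base
#' (A/T events as T, C/G as C) and homopolymer run length; longer deletions
#' by the tandem-copy count of the deleted sequence in the reference when a
#' tandem copy exists, else by the longest microhomology between the
#' deleted sequence and its flanks; insertions analogously without the
#' microhomology branch.
#'
#' @param chrom,pos,ref,alt vectors describing indels in VCF convention
#'   (1-based `pos`; `ref`/`alt` share their first base).
#' @param reference reference sequences (any form accepted by
#'   [scan_reference()]).
#' @return character vector of ID83 labels (see [id83_classes()]).
#' @export
classify_id83 <- function(chrom, pos, ref, alt, reference) {
  seqs <- as_named_sequences(reference)
  n <- length(pos)
  out <- character(n)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(n)) {
    sq <- seqs[[as.character(chrom[i])]]
    if (is.null(sq)) stop("chromosome not in reference: ", chrom[i])
    r <- toupper(ref[i]); a <- toupper(alt[i])
    if (nchar(r) == nchar(a)) stop("not an indel at row ", i)
    is_del <- nchar(r) > nchar(a)
    if (is_del) {
      s <- substr(r, nchar(a) + 1L, nchar(r))
      p <- pos[i] + nchar(a)              # first deleted base, 1-based
    } else {
      s <- substr(a, nchar(r) + 1L, nchar(a))
      p <- pos[i] + nchar(r)              # insertion before this base
    }
    la <- left_align_indel(sq, p, s)
    p <- la$pos; s <- la$seq
    k <- nchar(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    if (k == 1L) {
      b <- chars[1]
      base_lab <- if (b %in% c("C", "G")) "C" else "T"
      rl <- run_left(sq, p - 1L, b)
      rr <- run_right(sq, if (is_del) p + 1L else p, b)
      if (is_del) {
        out[i] <- sprintf("1:Del:%s:%d", base_lab,
                          max(1L, min(rl + 1L + rr, 6L)))
      } else {
        out[i] <- sprintf("1:Ins:%s:%d", base_lab, min(rl + rr, 5L))
      }
    } else {
      size_lab <- min(k, 5L)
      if (is_del) {
        reps <- copies_left(sq, p, s) + 1L + copies_right(sq, p + k, s)
        if (reps >= 2L) {
          out[i] <- sprintf("%d:Del:R:%d", size_lab, min(reps, 6L))
        } else {
          after <- substr(sq, p + k, min(nchar(sq), p + 2L * k - 1L))
          before <- substr(sq, max(1L, p - k), p - 1L)
          mh_r <- 0L
          while (mh_r < k - 1L && mh_r < nchar(after) &&
                 substr(s, mh_r + 1L, mh_r + 1L) ==
                 substr(after, mh_r + 1L, mh_r + 1L)) mh_r <- mh_r + 1L
          mh_l <- 0L
          nb <- nchar(before)
          while (mh_l < k - 1L && mh_l < nb &&
                 substr(s, k - mh_l, k - mh_l) ==
                 substr(before, nb - mh_l, nb - mh_l)) mh_l <- mh_l + 1L
          mh <- max(mh_r, mh_l)
          if (mh >= 1L) {
            out[i] <- sprintf("%d:Del:M:%d", size_lab,
                              min(mh, if (k >= 5L) 5L else k - 1L))
          } else {
            out[i] <- sprintf("%d:Del:R:1", size_lab)
          }
        }
      } else {
        reps <- copies_left(sq, p, s) + copies_right(sq, p, s)
        out[i] <- sprintf("%d:Ins:R:%d", size_lab, min(reps, 5L))
      }
    }
  }
  out
}

#' Trinucleotide context of positions in a reference
#'
#' @param chrom,pos chromosome and 1-based position vectors.
#' @param reference reference sequences.
#' @return character vector of trinucleotides (`NA` at sequence edges).
#' @export
reference_context <- function(chrom, pos, reference) {
  seqs <- as_named_sequences(reference)
  vapply(seq_along(pos), function(i) {
    sq <- seqs[[as.character(chrom[i])]]
    if (is.null(sq) || pos[i] < 2L || pos[i] + 1L > nchar(sq))
      return(NA_character_)
    substr(sq, pos[i] - 1L, pos[i] + 1L)
  }, character(1))
}

#' Build SBS96/ID83 mutation matrices per sample
#'
#' Classifies filtered variants and tallies per-sample count vectors over
#' the 96 substitution and 83 indel classes, together with
#' proportion-normalized profiles, the 6-class collapsed substitution
#' spectrum, and the substitution-versus-indel split.
#'
#' @param variants data.frame with `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `sample_id`.
#' @param reference reference sequences.
#' @return list with matrices `sbs96`, `id83` (classes x samples, counts),
#'   `sbs96_prop`, `id83_prop` (columns sum to 1 where counts exist),
#'   `sbs6` (6 x samples), `bs_indel` (2 x samples), and `unclassified`
#'   (count of SNVs with ambiguous context per sample).
#' @export
build_matrices <- function(variants, reference) {
  samples <- unique(variants$sample_id)
  cls96 <- sbs96_classes(); cls83 <- id83_classes()
  sbs <- matrix(0L, 96L, length(samples), dimnames = list(cls96, samples))
  id <- matrix(0L, 83L, length(samples), dimnames = list(cls83, samples))
  uncl <- setNames(integer(length(samples)), samples)
  if (nrow(variants)) {
    is_snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L
    snv <- variants[is_snv, , drop = FALSE]
    ind <- variants[!is_snv, , drop = FALSE]
    if (nrow(snv)) {
      ctx <- reference_context(snv$chrom, snv$pos, reference)
      lab <- classify_sbs96(snv$ref, snv$alt, ctx)
      for (s in samples) {
        sel <- snv$sample_id == s
        tab <- table(factor(lab[sel], levels = cls96))
        sbs[, s] <- as.integer(tab)
        uncl[s] <- sum(sel & is.na(lab))
      }
    }
    if (nrow(ind)) {
      lab <- classify_id83(ind$chrom, ind$pos, ind$ref, ind$alt, reference)
      for (s in samples) {
        tab <- table(factor(lab[ind$sample_id == s], levels = cls83))
        id[, s] <- as.integer(tab)
      }
    }
  } else {
    warning("no variants: matrices are all zero, normalization skipped")
  }
  norm <- function(m) {
    apply(m, 2L, function(col) if (sum(col) > 0) col / sum(col) else col)
  }
  sub6 <- sub("^.\\[(.+)\\].$", "\\1", cls96)
  sbs6 <- rowsum(sbs, sub6)
  list(
    sbs96 = sbs, id83 = id,
    sbs96_prop = norm(sbs), id83_prop = norm(id),
    sbs6 = sbs6,
    bs_indel = rbind(BS = colSums(sbs), indel = colSums(id)),
    unclassified = uncl
  )
}

#' Read somatic variants from a tabular file
#'
#' Expects a TSV with columns `chrom`, `pos`, `ref`, `alt`, `sample_id`,
#' `tumor_depth`, `normal_depth`, `tumor_alt_reads`, `normal_alt_reads` and
#' optionally `in_dbsnp`, `shared_tumor_count` (defaulted to
#' FALSE/0 when absent or supplied via a flags sidecar TSV keyed by
#' `chrom:pos:ref:alt`).
#'
#' @param path variant TSV path.
#' @param flags_path optional sidecar TSV with columns `key`, `in_dbsnp`,
#'   `shared_tumor_count`.
#' @return data.frame of somatic variant records.
#' @export
read_somatic_table <- function(path, flags_path = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!"in_dbsnp" %in% names(d)) d$in_dbsnp <- FALSE
  if (!"shared_tumor_count" %in% names(d)) d$shared_tumor_count <- 0L
  if (!is.null(flags_path)) {
    fl <- read.delim(flags_path, stringsAsFactors = FALSE)
    key <- paste(normalize_chrom(d$chrom), d$pos, d$ref, d$alt, sep = ":")
    idx <- match(key, fl$key)
    d$in_dbsnp <- ifelse(is.na(idx), d$in_dbsnp, fl$in_dbsnp[idx])
    d$shared_tumor_count <- ifelse(is.na(idx), d$shared_tumor_count,
                                   fl$shared_tumor_count[idx])
  }
  d$in_dbsnp <- as.logical(d$in_dbsnp)
  d
}

#' Read somatic variants from a VCF with per-sample AD/DP fields
#'
#' Uses the vcfR package (Suggests) to extract tumor/normal depths and
#' alt-supporting read counts.
#'
#' @param path uncompressed or gzipped VCF path.
#' @param tumor,normal sample column names in the VCF.
#' @param sample_id label to record; defaults to the tumor column name.
#' @param flags_path optional flags sidecar (see [read_somatic_table()]).
#' @return data.frame of somatic variant records.
#' @export
read_somatic_vcf <- function(path, tumor, normal, sample_id = tumor,
                             flags_path = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, "AD")
  alt_reads <- function(col) {
    vapply(strsplit(ad[, col], ",", fixed = TRUE),
           function(x) as.integer(x[2]), integer(1))
  }
  d <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, sample_id = sample_id,
    tumor_depth = as.integer(dp[, tumor]),
    normal_depth = as.integer(dp[, normal]),
    tumor_alt_reads = alt_reads(tumor),
    normal_alt_reads = alt_reads(normal),
    in_dbsnp = FALSE, shared_tumor_count = 0L,
    stringsAsFactors = FALSE
  )
  if (!is.null(flags_path)) {
    fl <- read.delim(flags_path, stringsAsFactors = FALSE)
    key <- paste(normalize_chrom(d$chrom), d$pos, d$ref, d$alt, sep = ":")
    idx <- match(key, fl$key)
    d$in_dbsnp <- ifelse(is.na(idx), FALSE, as.logical(fl$in_dbsnp[idx]))
    d$shared_tumor_count <- ifelse(is.na(idx), 0L,
                                   fl$shared_tumor_count[idx])
  }
  d
}
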