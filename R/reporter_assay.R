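#' Reporter-gene reference with homopolymer context
#'
#' Wraps a reporter coding sequence (such as the bacterial rpsL gene used in
#' transgenic mutation assays) together with a precomputed homopolymer map:
#' for every position, the length of the maximal same-base run containing
#' it. The map supplies the (A)n / (T)n context for indel classification.
#'
#' @param seq coding sequence (character scalar over ACGT).
#' @param name reference name.
#' @return list of class `reporter_reference` with `name`, `seq`, `bases`
#'   (character vector) and `run_len` (integer vector, per position).
#' @export
reporter_reference <- function(seq, name = "reporter") {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stop("reporter sequence must be over ACGT")
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  r <- rle(bases)
  run_len <- rep(r$lengths, r$lengths)
  starts0 <- cumsum(c(0L, r$lengths[-length(r$lengths)]))  # 0-based run starts
  run_start <- rep(starts0, r$lengths)
  structure(list(name = name, seq = seq, bases = bases, run_len = run_len,
                 run_start = run_start),
            class = "reporter_reference")
}

## Watson-Crick pair class of a single-base substitution.
subst_pair_class <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- ref %in% c("C", "T")
  r <- ifelse(flip, comp[ref], ref)
  a <- ifelse(flip, comp[alt], alt)
  key <- paste0(r, ">", a)
  map <- c("G>A" = "G:C>A:T", "A>G" = "A:T>G:C", "G>T" = "G:C>T:A",
           "G>C" = "G:C>C:G", "A>T" = "A:T>T:A", "A>C" = "A:T>C:G")
  unname(map[key])
}

## Homopolymer run length relevant to an indel: for deletions, the run of
## the deleted base containing the position; for insertions, the longest
## adjacent run of the inserted base (positions flanking the insertion
## point). `pos` is 0-based.
indel_run_length <- function(ref_obj, pos, base, kind) {
  n <- length(ref_obj$bases)
  if (kind == "deletion") {
    if (ref_obj$bases[pos + 1L] != base) return(0L)
    return(ref_obj$run_len[pos + 1L])
  }
  best <- 0L
  for (p in c(pos, pos + 1L)) {      # 1-based neighbors of the insertion point
    if (p >= 1L && p <= n && ref_obj$bases[p] == base)
      best <- max(best, ref_obj$run_len[p])
  }
  best
}

#' Classify reporter-gene mutations into the assay class scheme
#'
#' Substitutions map to the six Watson-Crick pair classes (C>T and G>A both
#' give G:C>A:T). Single-base indels of A or T lying in an A/T homopolymer
#' run of length >= 2 become `1-indel_(A)n` with that run length; 2-bp
#' indels removing/adding two bases of an A/T run become `2-indel_(A)n`;
#' other 1-bp indels are `1-indel`; indels larger than 2 bp are
#' `>2bp_indel`; anything else is `other`. Indel positions are normalized
#' to the leftmost coordinate of the containing run before classification
#' (placement within a homopolymer is ambiguous).
#'
#' @param mutations data.frame with columns `colony_id`, `kind`
#'   (`substitution`/`deletion`/`insertion`), `position` (0-based offset in
#'   the coding sequence), `ref_allele`, `alt_allele` (empty string on
#'   exactly one side for indels).
#' @param reference a [reporter_reference()].
#' @return the input with added columns `class` and `run_length` (0 when no
#'   A/T-run context applies).
#' @export
classify_reporter_mutation <- function(mutations, reference) {
  stopifnot(inherits(reference, "reporter_reference"))
  m <- mutations
  cls <- character(nrow(m)); runl <- integer(nrow(m))
  for (i in seq_len(nrow(m))) {
    kind <- m$kind[i]; pos <- m$position[i]
    ref <- m$ref_allele[i]; alt <- m$alt_allele[i]
    if (kind == "substitution") {
      if (nchar(ref) != 1L || nchar(alt) != 1L || ref == alt)
        stop("malformed substitution at row ", i)
      if (reference$bases[pos + 1L] != ref)
        stop("ref_allele mismatch with reference at position ", pos)
      cls[i] <- subst_pair_class(ref, alt); runl[i] <- 0L
      next
    }
    allele <- if (kind == "deletion") ref else alt
    len <- nchar(allele)
    if (kind == "deletion") {
      if (substr(reference$seq, pos + 1L, pos + len) != ref)
        stop("ref_allele mismatch with reference at position ", pos)
    }
    bases_u <- unique(strsplit(allele, "", fixed = TRUE)[[1]])
    at_run <- length(bases_u) == 1L && bases_u %in% c("A", "T")
    rl <- if (at_run) indel_run_length(reference, pos, bases_u, kind) else 0L
    if (rl >= 2L) {
      # indel placement inside a homopolymer is ambiguous: normalize the
      # position to the run's leftmost coordinate
      anchor <- if (kind == "deletion") pos + 1L else
        if (pos >= 1L && reference$bases[pos] == bases_u) pos else pos + 1L
      if (anchor <= length(reference$bases) &&
          reference$bases[anchor] == bases_u)
        m$position[i] <- reference$run_start[anchor]
    }
    if (len == 1L && at_run && rl >= 2L) {
      cls[i] <- "1-indel_(A)n"; runl[i] <- rl
    } else if (len == 1L) {
      cls[i] <- "1-indel"; runl[i] <- 0L
    } else if (len == 2L && at_run && rl >= 2L) {
      cls[i] <- "2-indel_(A)n"; runl[i] <- rl
    } else if (len > 2L) {
      cls[i] <- ">2bp_indel"; runl[i] <- 0L
    } else {
      cls[i] <- "other"; runl[i] <- 0L
    }
  }
  m$class <- cls
  m$run_length <- runl
  m
}

#' All classes of the reporter mutation scheme, in display order
#' @return character vector of class labels.
#' @export
reporter_classes <- function() {
  c("G:C>A:T", "A:T>G:C", "G:C>T:A", "G:C>C:G", "A:T>T:A", "A:T>C:G",
    "1-indel", "1-indel_(A)n", "2-indel_(A)n", ">2bp_indel", "other")
}

#' Mutant frequency and class spectrum of a reporter assay
#'
#' Per mouse, the overall mutant frequency is the number of Km/Sm-resistant
#' mutant colonies divided by the number of Km-resistant colonies screened;
#' the per-class MF apportions it by the proportion of each mutation class
#' among the classified mutations of that mouse. Group values are per-mouse
#' means (`mode = "per_mouse"`, the default) or a single pooled computation
#' over all colonies of the group (`mode = "pooled"`). Two-group
#' comparisons use the Mann-Whitney U test on per-mouse overall MFs.
#'
#' @param counts data.frame with columns `mouse_id`, `group`, `n_km`,
#'   `n_kmsm`.
#' @param classified classified mutations (from
#'   [classify_reporter_mutation()]) with a `mouse_id` column; may be
#'   omitted to compute overall MFs only.
#' @param mode `"per_mouse"` or `"pooled"` group aggregation.
#' @return list of class `mf_table` with `per_mouse` (mouse-level overall
#'   MF), `class_mf` (class x group matrix of MFs on the natural scale),
#'   `overall` (group overall MFs), and `comparisons` (pairwise
#'   Mann-Whitney p-values on per-mouse MFs, when >= 2 groups). Multiply by
#'   1e5 for the conventional display scale.
#' @export
compute_assay_mf <- function(counts, classified = NULL,
                             mode = c("per_mouse", "pooled")) {
  mode <- match.arg(mode)
  if (any(counts$n_km <= 0)) stop("n_km must be positive for every mouse")
  if (any(counts$n_kmsm > counts$n_km))
    stop("n_kmsm cannot exceed n_km")
  counts$mf <- counts$n_kmsm / counts$n_km
  groups <- unique(counts$group)
  cls <- reporter_classes()
  class_mf <- matrix(0, nrow = length(cls), ncol = length(groups),
                     dimnames = list(cls, groups))
  if (!is.null(classified)) {
    for (g in groups) {
      mice <- counts[counts$group == g, , drop = FALSE]
      if (mode == "per_mouse") {
        per_mouse_mat <- sapply(seq_len(nrow(mice)), function(i) {
          mm <- classified[classified$mouse_id == mice$mouse_id[i], ,
                           drop = FALSE]
          tot <- nrow(mm)
          if (tot == 0L) {
            if (mice$n_kmsm[i] > 0L)
              warning("mouse ", mice$mouse_id[i],
                      " has mutant colonies but no classified mutations; ",
                      "per-class MF undefined, treated as 0")
            return(setNames(numeric(length(cls)), cls))
          }
          mice$mf[i] * table(factor(mm$class, levels = cls)) / tot
        })
        class_mf[, g] <- rowMeans(per_mouse_mat)
      } else {
        mm <- classified[classified$mouse_id %in% mice$mouse_id, ,
                         drop = FALSE]
        tot <- nrow(mm)
        pooled_mf <- sum(mice$n_kmsm) / sum(mice$n_km)
        if (tot > 0L)
          class_mf[, g] <- pooled_mf *
            table(factor(mm$class, levels = cls)) / tot
      }
    }
  }
  overall <- vapply(groups, function(g) {
    if (mode == "per_mouse") mean(counts$mf[counts$group == g])
    else sum(counts$n_kmsm[counts$group == g]) /
      sum(counts$n_km[counts$group == g])
  }, numeric(1))
  comparisons <- NULL
  if (length(groups) >= 2L) {
    pairs <- utils::combn(groups, 2L)
    comparisons <- data.frame(
      group1 = pairs[1, ], group2 = pairs[2, ],
      p_value = apply(pairs, 2L, function(p) {
        x <- counts$mf[counts$group == p[1]]
        y <- counts$mf[counts$group == p[2]]
        if (length(x) < 1L || length(y) < 1L) return(NA_real_)
        suppressWarnings(wilcox.test(x, y)$p.value)
      }),
      stringsAsFactors = FALSE
    )
  }
  structure(list(per_mouse = counts, class_mf = class_mf,
                 overall = overall, comparisons = comparisons,
                 mode = mode),
            class = "mf_table")
}

#' @export
print.mf_table <- function(x, ...) {
  cat("Reporter assay mutant frequencies (x1e-5), mode =", x$mode, "\n")
  print(round(x$class_mf * 1e5, 2))
  cat("overall:\n"); print(round(x$overall * 1e5, 2))
  invisible(x)
}

#' Adenine 1-bp indel MF stratified by homopolymer run length
#'
#' Partitions the `1-indel_(A)n` mutant frequency by the length of the
#' containing A/T run (2 up to the longest observed run). The bucket MFs
#' sum exactly to the total `1-indel_(A)n` MF of each group.
#'
#' @param classified classified mutations with `mouse_id`.
#' @param counts per-mouse counts table (`mouse_id`, `group`, `n_km`,
#'   `n_kmsm`).
#' @param mode `"per_mouse"` or `"pooled"` (see [compute_assay_mf()]).
#' @return data.frame `group`, `run_length`, `mf` (natural scale).
#' @export
adenine_indel_by_runlength <- function(classified, counts,
                                       mode = c("per_mouse", "pooled")) {
  mode <- match.arg(mode)
  counts$mf <- counts$n_kmsm / counts$n_km
  groups <- unique(counts$group)
  runs <- if (nrow(classified)) {
    seq(2L, max(2L, max(classified$run_length[classified$class ==
                                                "1-indel_(A)n"], 2L)))
  } else 2L
  out <- expand.grid(group = groups, run_length = runs,
                     stringsAsFactors = FALSE)
  out$mf <- 0
  for (g in groups) {
    mice <- counts[counts$group == g, , drop = FALSE]
    bucket <- setNames(numeric(length(runs)), runs)
    if (mode == "per_mouse") {
      for (i in seq_len(nrow(mice))) {
        mm <- classified[classified$mouse_id == mice$mouse_id[i], ,
                         drop = FALSE]
        tot <- nrow(mm)
        if (tot == 0L) next
        an <- mm[mm$class == "1-indel_(A)n", , drop = FALSE]
        tab <- table(factor(an$run_length, levels = runs))
        bucket <- bucket + mice$mf[i] * as.numeric(tab) / tot / nrow(mice)
      }
    } else {
      mm <- classified[classified$mouse_id %in% mice$mouse_id, , drop = FALSE]
      tot <- nrow(mm)
      if (tot > 0L) {
        an <- mm[mm$class == "1-indel_(A)n", , drop = FALSE]
        tab <- table(factor(an$run_length, levels = runs))
        bucket <- setNames((sum(mice$n_kmsm) / sum(mice$n_km)) *
                             as.numeric(tab) / tot, names(tab))
      }
    }
    out$mf[out$group == g] <- bucket[as.character(out$run_length[out$group == g])]
  }
  out
}

#' Positional deletion/insertion hotspot profile
#'
#' Per-position mutant frequencies of deletions and insertions along the
#' reporter coding sequence, scaled by per-mouse MF in the same way as the
#' class spectrum, annotated with the homopolymer run context.
#'
#' @inheritParams adenine_indel_by_runlength
#' @param reference a [reporter_reference()].
#' @return data.frame `group`, `position` (0-based), `ref_base`,
#'   `run_length`, `del_mf`, `ins_mf`.
#' @export
hotspot_profile <- function(classified, counts, reference,
                            mode = c("per_mouse", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(inherits(reference, "reporter_reference"))
  counts$mf <- counts$n_kmsm / counts$n_km
  groups <- unique(counts$group)
  npos <- length(reference$bases)
  res <- list()
  for (g in groups) {
    mice <- counts[counts$group == g, , drop = FALSE]
    del <- setNames(numeric(npos), seq_len(npos) - 1L)
    ins <- del
    add_mouse <- function(mm, w) {
      tot <- nrow(mm)
      if (tot == 0L) return(invisible())
      for (j in seq_len(tot)) {
        p <- as.character(mm$position[j])
        if (mm$kind[j] == "deletion")
          del[p] <<- del[p] + w / tot
        else if (mm$kind[j] == "insertion")
          ins[p] <<- ins[p] + w / tot
      }
    }
    if (mode == "per_mouse") {
      for (i in seq_len(nrow(mice)))
        add_mouse(classified[classified$mouse_id == mice$mouse_id[i], ,
                             drop = FALSE],
                  mice$mf[i] / nrow(mice))
    } else {
      add_mouse(classified[classified$mouse_id %in% mice$mouse_id, ,
                           drop = FALSE],
                sum(mice$n_kmsm) / sum(mice$n_km))
    }
    res[[g]] <- data.frame(
      group = g, position = seq_len(npos) - 1L,
      ref_base = reference$bases, run_length = reference$run_len,
      del_mf = as.numeric(del), ins_mf = as.numeric(ins),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Read a transcribed mutant-frequency table
#'
#' Reads a published-style mutant-frequency table (class rows, group
#' columns, values on the x1e-5 display scale, `-` meaning not detected)
#' into a data.frame with numeric columns (`-` becomes `NA`).
#'
#' @param path TSV path; defaults to the packaged reference table for the
#'   rpsL assay in MMR-deficient mice.
#' @return data.frame with a `class` column and one numeric column per
#'   group.
#' @export
read_mf_table <- function(path = system.file("extdata",
                                             "rpsl_mf_published.tsv",
                                             package = "msirep")) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq(2L, ncol(d)))
    d[[j]] <- suppressWarnings(as.numeric(ifelse(d[[j]] == "-", NA, d[[j]])))
  d
}
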