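## Run code under a private, seeded RNG stream, restoring the caller's RNG
## state afterwards so generators are pure functions of (parameters, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

## Derive a child seed below 2^31 from a parent seed and a string/integer
## label, so per-sample/per-locus streams are independent of list order.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(paste0(label)) * seq_along(utf8ToInt(paste0(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Replication-slippage model
#'
#' Per-read slippage probability at a locus of n repeat units is
#' `p(n) = min(0.5, p0 * (n - n_min + 1)^gamma * genotype_multiplier)`.
#' A slipped read changes length by -1 unit with probability `d1`, +1 unit
#' with probability `i1`, and otherwise by a larger step whose magnitude is
#' geometric (halving mass per extra unit) with the sign drawn in the d1:i1
#' ratio. Contraction dominates by default (deletions occur more often than
#' insertions at microsatellites in MMR-deficient tissue).
#'
#' @param p0 slippage probability at the minimum cataloged length
#'   (default 0.002).
#' @param gamma length exponent (default 1.5); p(n) is nondecreasing in n
#'   for gamma >= 0.
#' @param d1 probability of a -1-unit step (default 0.7).
#' @param i1 probability of a +1-unit step (default 0.2).
#' @param genotype_multiplier scalar >= 1 applied to p(n); models the
#'   MMR-deficient condition (default 1 = MMR-proficient).
#' @param n_min minimum cataloged repeat length anchoring p0 (default 5).
#' @return list of class `slippage_model`.
#' @export
slippage_model <- function(p0 = 0.002, gamma = 1.5, d1 = 0.7, i1 = 0.2,
                           genotype_multiplier = 1, n_min = 5L) {
  stopifnot(p0 >= 0, p0 <= 1, d1 >= 0, i1 >= 0, d1 + i1 <= 1,
            genotype_multiplier >= 1, gamma >= 0)
  structure(list(p0 = p0, gamma = gamma, d1 = d1, i1 = i1,
                 genotype_multiplier = genotype_multiplier,
                 n_min = as.integer(n_min)),
            class = "slippage_model")
}

#' Per-read slippage probability at repeat length n
#' @param model a [slippage_model()].
#' @param n integer vector of repeat unit counts.
#' @return numeric vector of probabilities (capped at 0.5).
#' @export
slippage_prob <- function(model, n) {
  pmin(0.5, model$p0 * pmax(0, n - model$n_min + 1)^model$gamma *
         model$genotype_multiplier)
}

## Draw slippage steps (nonzero integers) for n reads.
draw_steps <- function(model, n) {
  if (n == 0L) return(integer(0))
  u <- runif(n)
  step <- integer(n)
  step[u < model$d1] <- -1L
  step[u >= model$d1 & u < model$d1 + model$i1] <- 1L
  big <- step == 0L
  if (any(big)) {
    m <- 2L + rgeom(sum(big), 0.5)
    neg <- runif(sum(big)) < model$d1 / (model$d1 + model$i1)
    step[big] <- ifelse(neg, -m, m)
  }
  step
}

#' Simulate a reference with planted microsatellites
#'
#' Generates random background sequence in which no mono-, di- or
#' trinucleotide periodicity can extend (each base differs from the bases
#' 1, 2 and 3 positions back, with constraints relaxed only where a planted
#' repeat forces it), then plants perfect repeats at the requested
#' coordinates. Because the background is repeat-free by construction,
#' [scan_reference()] on the output recovers exactly the planted loci that
#' meet the scan thresholds; this is verified before returning.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param planted data.frame with columns `chrom`, `start` (0-based),
#'   `motif`, `units`; plants must not overlap and must be separated by at
#'   least 4 bp.
#' @param seed integer seed.
#' @param max_mono_run longest homopolymer allowed in the background
#'   (default 2; use 1 for a background with no repeated bases at all,
#'   e.g. when every homopolymer site should be a planted one).
#' @return list with `sequences` (named character vector) and `truth`
#'   (catalog data.frame in [scan_reference()] layout).
#' @export
simulate_reference <- function(chrom_lengths = c(chr1 = 10000L),
                               planted = NULL, seed = 1L,
                               max_mono_run = 2L) {
  bases <- c("A", "C", "G", "T")
  if (is.null(planted))
    planted <- data.frame(chrom = character(0), start = integer(0),
                          motif = character(0), units = integer(0),
                          stringsAsFactors = FALSE)
  planted$end <- planted$start + nchar(planted$motif) * planted$units
  for (chrom in unique(planted$chrom)) {
    p <- planted[planted$chrom == chrom, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    if (nrow(p) > 1L && any(p$start[-1] - p$end[-nrow(p)] < 4L))
      stop("planted loci overlap or are closer than 4 bp on ", chrom)
    if (any(p$start < 3L) || any(p$end > chrom_lengths[chrom] - 3L))
      stop("planted locus too close to the end of ", chrom)
  }
  sequences <- with_seed(seed, {
    out <- setNames(character(length(chrom_lengths)), names(chrom_lengths))
    for (chrom in names(chrom_lengths)) {
      len <- chrom_lengths[[chrom]]
      s <- character(len)
      p <- planted[planted$chrom == chrom, , drop = FALSE]
      in_plant <- logical(len)
      for (j in seq_len(nrow(p))) {
        idx <- (p$start[j] + 1L):p$end[j]
        s[idx] <- strsplit(strrep(p$motif[j], p$units[j]), "",
                           fixed = TRUE)[[1]]
        in_plant[idx] <- TRUE
      }
      # background filling rules:
      #  - no base may equal a plant base at distance 1-3 (so no periodic
      #    run of motif size 1-3 ever crosses a plant junction);
      #  - in background, a distance-k equality is forbidden once the
      #    running k-periodic tract would reach 4 (mono), 5 (di) or 7
      #    (tri) bp -- all safely below the scan thresholds of 5, 6, 9.
      streak <- function(i, k) {
        m <- 0L; j <- i - 1L
        while (j - k >= 1L && nzchar(s[j]) && nzchar(s[j - k]) &&
               s[j] == s[j - k]) { m <- m + 1L; j <- j - 1L }
        m
      }
      cap <- c(max_mono_run, 2L, 3L)  # forbid equality when chain >= cap
      for (i in seq_len(len)) {
        if (in_plant[i]) next
        plant_forb <- character(0)
        soft_forb <- character(0)
        for (k in 1:3) {
          if (i - k >= 1L && in_plant[i - k])
            plant_forb <- c(plant_forb, s[i - k])
          if (i + k <= len && in_plant[i + k])
            plant_forb <- c(plant_forb, s[i + k])
          if (i - k >= 1L && !in_plant[i - k] &&
              streak(i, k) >= cap[k] - 1L)
            soft_forb <- c(soft_forb, s[i - k])
        }
        choices <- setdiff(bases, c(plant_forb, soft_forb))
        if (length(choices) == 0L)
          choices <- setdiff(bases, plant_forb)
        s[i] <- choices[sample.int(length(choices), 1L)]
      }
      out[chrom] <- paste(s, collapse = "")
    }
    out
  })
  truth <- scan_reference(sequences)
  if (nrow(planted)) {
    key_t <- paste(truth$chrom, truth$start, truth$motif, truth$unit_count)
    key_p <- paste(planted$chrom, planted$start, planted$motif,
                   planted$units)
    min_u <- c(5L, 3L, 3L)[nchar(planted$motif)]
    expected <- key_p[planted$units >= min_u]
    if (!setequal(key_t, expected))
      stop("internal error: scan of simulated reference does not match ",
           "the planted truth")
  } else if (nrow(truth)) {
    stop("internal error: repeat-free background contains cataloged loci")
  }
  list(sequences = sequences, truth = truth)
}

#' Simulate per-locus allele spectra under a slippage model
#'
#' For every catalog locus, reads are drawn whose allele equals the
#' reference unit count plus a slippage step occurring with probability
#' p(n) (see [slippage_model()]). The random stream is split
#' hierarchically per locus, so adding a locus does not perturb the draws
#' at other loci. Optionally also emits the reads as SAM records with
#' intact flanks for round-trip testing against [extract_spectra()].
#'
#' @param catalog catalog data.frame ([scan_reference()] layout).
#' @param model a [slippage_model()].
#' @param depth reads drawn per locus (integer, or function(n_loci)
#'   returning integer vector).
#' @param seed integer seed.
#' @param sample_id sample label.
#' @param reference named sequences; required when `emit_sam = TRUE`.
#' @param emit_sam also build a read table + SAM-writable records?
#' @param flank flank length included in emitted reads (default 20).
#' @return list with `spectra` (spectra table as in [extract_spectra()]),
#'   `truth` (per-locus data.frame: `locus_id`, `p_slip`, `n_slipped`), and
#'   when `emit_sam` is set, `reads` (data.frame writable by [write_sam()])
#'   and `read_truth` (read-level alleles).
#' @export
simulate_locus_spectra <- function(catalog, model, depth = 50L, seed = 1L,
                                   sample_id = "S1", reference = NULL,
                                   emit_sam = FALSE, flank = 20L) {
  stopifnot(inherits(model, "slippage_model"))
  n_loci <- nrow(catalog)
  depths <- if (is.function(depth)) depth(n_loci) else
    rep_len(as.integer(depth), n_loci)
  p <- slippage_prob(model, catalog$unit_count)
  spectra_list <- vector("list", n_loci)
  truth_slipped <- integer(n_loci)
  reads <- NULL; read_truth <- NULL
  if (emit_sam) {
    if (is.null(reference)) stop("reference is required for SAM emission")
    seqs <- as_named_sequences(reference)
    reads_acc <- vector("list", n_loci)
    rt_acc <- vector("list", n_loci)
  }
  for (i in seq_len(n_loci)) {
    alleles <- with_seed(
      child_seed(seed, paste0(sample_id, ":", catalog$locus_id[i])), {
        a <- rep(catalog$unit_count[i], depths[i])
        slip <- runif(depths[i]) < p[i]
        a[slip] <- a[slip] + draw_steps(model, sum(slip))
        pmax(0L, a)
      })
    truth_slipped[i] <- sum(alleles != catalog$unit_count[i])
    tab <- table(alleles)
    spectra_list[[i]] <- setNames(as.integer(tab), names(tab))
    if (emit_sam) {
      locus <- catalog[i, ]
      chrom_seq <- seqs[[locus$chrom]]
      k <- nchar(locus$motif)
      lf <- substr(chrom_seq, locus$start - flank + 1L, locus$start)
      rf <- substr(chrom_seq, locus$end + 1L, locus$end + flank)
      n_ref <- locus$unit_count
      cigar <- vapply(alleles, function(a) {
        if (a == n_ref) sprintf("%dM", 2L * flank + n_ref * k)
        else if (a < n_ref)
          sprintf("%dM%dD%dM", flank + a * k, (n_ref - a) * k, flank)
        else sprintf("%dM%dI%dM", flank + n_ref * k, (a - n_ref) * k, flank)
      }, character(1))
      reads_acc[[i]] <- data.frame(
        qname = sprintf("%s_%s_r%03d", sample_id, locus$locus_id,
                        seq_along(alleles)),
        flag = 0L, chrom = locus$chrom,
        pos = locus$start - flank + 1L, mapq = 60L, cigar = cigar,
        seq = paste0(lf, strrep(locus$motif, alleles), rf),
        stringsAsFactors = FALSE
      )
      rt_acc[[i]] <- data.frame(
        qname = reads_acc[[i]]$qname, locus_id = locus$locus_id,
        allele = alleles, stringsAsFactors = FALSE
      )
    }
  }
  spectra <- data.frame(
    sample_id = sample_id,
    locus_id = catalog$locus_id, chrom = catalog$chrom,
    start = catalog$start, motif = catalog$motif,
    canonical_motif = catalog$canonical_motif,
    ref_units = catalog$unit_count,
    total_reads = depths,
    insufficient = rep(FALSE, n_loci),
    stringsAsFactors = FALSE
  )
  spectra$spectrum <- spectra_list
  out <- list(
    spectra = spectra,
    truth = data.frame(locus_id = catalog$locus_id, p_slip = p,
                       n_slipped = truth_slipped, stringsAsFactors = FALSE)
  )
  if (emit_sam) {
    out$reads <- do.call(rbind, reads_acc)
    out$read_truth <- do.call(rbind, rt_acc)
  }
  out
}

#' Simulate a microsatellite-stable/unstable cohort
#'
#' Normal samples are drawn from the stable model and tumor samples from
#' the unstable model over a shared catalog, producing spectra tables ready
#' for [build_baseline()] and [score_msi()].
#'
#' @param catalog shared catalog.
#' @param n_normal,n_tumor cohort sizes.
#' @param stable_model,unstable_model [slippage_model()]s for the two
#'   conditions.
#' @param depth reads per locus.
#' @param seed integer seed.
#' @return list with `normals` and `tumors` (lists of spectra tables) and
#'   `truth` (per-sample generator assignment).
#' @export
simulate_msi_cohort <- function(catalog, n_normal, n_tumor,
                                stable_model = slippage_model(),
                                unstable_model =
                                  slippage_model(genotype_multiplier = 5),
                                depth = 50L, seed = 1L) {
  normals <- lapply(seq_len(n_normal), function(i) {
    sid <- sprintf("N%02d", i)
    simulate_locus_spectra(catalog, stable_model, depth,
                           seed = child_seed(seed, sid),
                           sample_id = sid)$spectra
  })
  tumors <- lapply(seq_len(n_tumor), function(i) {
    sid <- sprintf("T%02d", i)
    simulate_locus_spectra(catalog, unstable_model, depth,
                           seed = child_seed(seed, sid),
                           sample_id = sid)$spectra
  })
  list(
    normals = normals, tumors = tumors,
    truth = data.frame(
      sample_id = c(sprintf("N%02d", seq_len(n_normal)),
                    sprintf("T%02d", seq_len(n_tumor))),
      condition = rep(c("stable", "unstable"), c(n_normal, n_tumor)),
      stringsAsFactors = FALSE)
  )
}

#' Default reporter mutation class weights
#'
#' Proportions of the reporter mutation classes emulating the spectrum of
#' untreated MMR-deficient small intestine (dominated by 1-bp adenine-run
#' deletions, with G:C>A:T the leading substitution).
#'
#' @return named numeric vector over [reporter_classes()] summing to 1.
#' @export
default_reporter_weights <- function() {
  w <- c("G:C>A:T" = 2.64, "A:T>G:C" = 0.94, "G:C>T:A" = 0.37,
         "G:C>C:G" = 0.16, "A:T>T:A" = 0.22, "A:T>C:G" = 0.49,
         "1-indel" = 1.18, "1-indel_(A)n" = 22.82, "2-indel_(A)n" = 0.21,
         ">2bp_indel" = 0.58, "other" = 0)
  w / sum(w)
}

#' Simulate a synthetic reporter coding sequence
#'
#' Builds a reporter-like coding sequence with planted adenine runs of the
#' requested lengths (one run per length by default, emulating a reporter
#' gene whose longest adenine tract has six bases) embedded in
#' repeat-poor background.
#'
#' @param run_lengths adenine run lengths to plant (default 2:6).
#' @param length total sequence length (default 400).
#' @param seed integer seed.
#' @return a [reporter_reference()].
#' @export
simulate_reporter_reference <- function(run_lengths = 2:6, length = 400L,
                                        seed = 1L) {
  gap <- (length - sum(run_lengths)) %/% (length(run_lengths) + 1L)
  start <- gap
  planted <- data.frame(chrom = "reporter",
                        start = cumsum(c(gap, head(run_lengths, -1) + gap)),
                        motif = "A", units = run_lengths,
                        stringsAsFactors = FALSE)
  # plant via the repeat-free simulator so each run is exact and maximal;
  # background homopolymers are capped at 1 so the planted adenine runs are
  # the only (A)n sites with run length >= 2
  sim <- simulate_reference(c(reporter = as.integer(length)),
                            planted = planted, seed = seed,
                            max_mono_run = 1L)
  reporter_reference(sim$sequences[["reporter"]], name = "synthetic_reporter")
}

#' Simulate reporter-assay mutant colonies
#'
#' Draws, per mouse, a binomial number of mutant colonies at the generating
#' mutant frequency and assigns each mutant a mutation class from the
#' weight table; adenine-run 1-bp indels pick their run with probability
#' proportional to run length to the power `runlength_power` and are
#' deletions with probability `del_prob`. Every realized mutation is
#' consistent with its generating class on the reference.
#'
#' @param reference a [reporter_reference()].
#' @param n_mice number of mice.
#' @param group group label.
#' @param n_km Km-resistant colonies screened per mouse (default 2e5).
#' @param mf generating mutant frequency (default 28.88e-5).
#' @param class_weights named weights over [reporter_classes()].
#' @param runlength_power exponent of the run-length weighting (default 4).
#' @param del_prob probability that a 1-bp adenine-run event is a deletion
#'   (default 0.9; deletions dominate).
#' @param seed integer seed.
#' @return list with `mutations` (colony mutation calls; `true_class`
#'   records the generating class), `counts` (per-mouse n_km/n_kmsm), and
#'   `truth` (the generating class weights).
#' @export
simulate_reporter_colonies <- function(reference, n_mice = 5L,
                                       group = "msh2ko_control",
                                       n_km = 200000L, mf = 28.88e-5,
                                       class_weights =
                                         default_reporter_weights(),
                                       runlength_power = 4,
                                       del_prob = 0.9, seed = 1L) {
  stopifnot(inherits(reference, "reporter_reference"))
  cls <- reporter_classes()
  w <- setNames(numeric(length(cls)), cls)
  w[names(class_weights)] <- class_weights
  w <- w / sum(w)
  bases <- reference$bases
  runs <- unique(data.frame(start = reference$run_start,
                            len = reference$run_len,
                            base = bases[reference$run_start + 1L]))
  at_runs <- runs[runs$base %in% c("A", "T") & runs$len >= 2L, ,
                  drop = FALSE]
  iso <- which(reference$run_len == 1L) - 1L          # 0-based positions
  with_seed(seed, {
    counts <- data.frame(
      mouse_id = sprintf("%s_m%d", group, seq_len(n_mice)),
      group = group,
      n_km = as.integer(n_km),
      n_kmsm = rbinom(n_mice, as.integer(n_km), mf),
      stringsAsFactors = FALSE
    )
    muts <- list()
    for (i in seq_len(n_mice)) {
      n_mut <- counts$n_kmsm[i]
      if (n_mut == 0L) next
      classes <- sample(cls, n_mut, replace = TRUE, prob = w)
      rows <- lapply(seq_len(n_mut), function(j) {
        cl <- classes[j]
        if (cl %in% cls[1:6]) {
          pair <- strsplit(cl, ">", fixed = TRUE)[[1]]
          refs <- strsplit(pair[1], ":", fixed = TRUE)[[1]]
          alts <- strsplit(pair[2], ":", fixed = TRUE)[[1]]
          pos0 <- sample(which(bases %in% refs), 1L) - 1L
          ref_b <- bases[pos0 + 1L]
          alt_b <- if (ref_b == refs[1]) alts[1] else alts[2]
          data.frame(kind = "substitution", position = pos0,
                     ref_allele = ref_b, alt_allele = alt_b,
                     stringsAsFactors = FALSE)
        } else if (cl %in% c("1-indel_(A)n", "2-indel_(A)n")) {
          nbase <- if (cl == "1-indel_(A)n") 1L else 2L
          wt <- at_runs$len^runlength_power
          r <- at_runs[sample.int(nrow(at_runs), 1L, prob = wt), ]
          b <- r$base
          if (nbase == 1L && runif(1) >= del_prob) {
            data.frame(kind = "insertion", position = r$start,
                       ref_allele = "", alt_allele = b,
                       stringsAsFactors = FALSE)
          } else {
            data.frame(kind = "deletion", position = r$start,
                       ref_allele = strrep(b, nbase), alt_allele = "",
                       stringsAsFactors = FALSE)
          }
        } else if (cl == "1-indel") {
          pos0 <- sample(iso, 1L)
          data.frame(kind = "deletion", position = pos0,
                     ref_allele = bases[pos0 + 1L], alt_allele = "",
                     stringsAsFactors = FALSE)
        } else if (cl == ">2bp_indel") {
          pos0 <- sample.int(length(bases) - 3L, 1L) - 1L
          data.frame(kind = "deletion", position = pos0,
                     ref_allele = substr(reference$seq, pos0 + 1L,
                                         pos0 + 3L),
                     alt_allele = "", stringsAsFactors = FALSE)
        } else {  # "other": 2-bp deletion outside any A/T run
          repeat {
            pos0 <- sample.int(length(bases) - 2L, 1L) - 1L
            del <- substr(reference$seq, pos0 + 1L, pos0 + 2L)
            if (!del %in% c("AA", "TT")) break
          }
          data.frame(kind = "deletion", position = pos0, ref_allele = del,
                     alt_allele = "", stringsAsFactors = FALSE)
        }
      })
      d <- do.call(rbind, rows)
      d$mouse_id <- counts$mouse_id[i]
      d$colony_id <- sprintf("%s_c%04d", counts$mouse_id[i],
                             seq_len(nrow(d)))
      d$true_class <- classes
      muts[[i]] <- d
    }
    mutations <- if (length(muts)) do.call(rbind, muts) else
      data.frame(kind = character(0), position = integer(0),
                 ref_allele = character(0), alt_allele = character(0),
                 mouse_id = character(0), colony_id = character(0),
                 true_class = character(0), stringsAsFactors = FALSE)
    rownames(mutations) <- NULL
    list(mutations = mutations, counts = counts,
         truth = list(class_weights = w, mf = mf,
                      runlength_power = runlength_power))
  })
}

#' Simulate a paired-end read set over a transgene insertion
#'
#' Builds a modified genome in which `copies` tandem copies of the plasmid
#' are inserted at a single host locus, samples fragments across it, and
#' emits a host-referenced SAM-style read table: mates lying entirely in
#' host-derived sequence are mapped (coordinates lifted back to host);
#' mates touching plasmid sequence are emitted unmapped. Pairs internal to
#' the tandem array are both unmapped and carry no host signal; only
#' junction-flanking pairs are informative.
#'
#' @param host named character vector (single host sequence).
#' @param plasmid named character vector (single plasmid sequence).
#' @param insertion_pos 0-based host offset of the insertion point
#'   (`NULL` = no insertion, transgene-free control).
#' @param copies tandem plasmid copies (default 3).
#' @param frag_mean,frag_sd fragment-size distribution (default 300 +/- 30).
#' @param read_len read length (default 100).
#' @param depth mean sequence coverage of the modified genome (default 30).
#' @param seed integer seed.
#' @return list with `reads` (data.frame for [write_sam()]), `seqlengths`
#'   (host header lengths), and `truth` (junction coordinate and insert
#'   size).
#' @export
simulate_integration_readset <- function(host, plasmid,
                                         insertion_pos = NULL,
                                         copies = 3L, frag_mean = 300,
                                         frag_sd = 30, read_len = 100L,
                                         depth = 30, seed = 1L) {
  host_name <- names(host)[1]
  host_seq <- host[[1]]
  plasmid_seq <- plasmid[[1]]
  hlen <- nchar(host_seq)
  ins_len <- if (is.null(insertion_pos)) 0L else
    as.integer(copies) * nchar(plasmid_seq)
  genome <- if (is.null(insertion_pos)) host_seq else
    paste0(substr(host_seq, 1L, insertion_pos),
           strrep(plasmid_seq, copies),
           substr(host_seq, insertion_pos + 1L, hlen))
  glen <- nchar(genome)
  n_frag <- max(1L, round(glen * depth / (2 * read_len)))
  with_seed(seed, {
    fl <- pmax(2L * read_len, round(rnorm(n_frag, frag_mean, frag_sd)))
    fs <- floor(runif(n_frag, 1, glen - fl + 1))
    fe <- fs + fl - 1L
    m1s <- fs; m1e <- fs + read_len - 1L
    m2s <- fe - read_len + 1L; m2e <- fe
    # host mapping status: interval must avoid the inserted region entirely
    map_host <- function(s, e) {
      if (is.null(insertion_pos))
        return(list(mapped = rep(TRUE, length(s)), pos = s))
      before <- e <= insertion_pos
      after <- s > insertion_pos + ins_len
      list(mapped = before | after, pos = ifelse(before, s, s - ins_len))
    }
    h1 <- map_host(m1s, m1e); h2 <- map_host(m2s, m2e)
    seq1 <- substring(genome, m1s, m1e)
    seq2 <- revcomp_chr(substring(genome, m2s, m2e))
    flag1 <- 1L + 64L + ifelse(h1$mapped, 0L, 4L) +
      ifelse(h2$mapped, 0L, 8L) + 32L
    flag2 <- 1L + 128L + ifelse(h2$mapped, 0L, 4L) +
      ifelse(h1$mapped, 0L, 8L) + ifelse(h2$mapped, 16L, 0L)
    reads <- data.frame(
      qname = rep(sprintf("frag%06d", seq_len(n_frag)), 2L),
      flag = c(flag1, flag2),
      chrom = c(ifelse(h1$mapped, host_name, "*"),
                ifelse(h2$mapped, host_name, "*")),
      pos = c(ifelse(h1$mapped, h1$pos, 0L),
              ifelse(h2$mapped, h2$pos, 0L)),
      mapq = c(ifelse(h1$mapped, 60L, 0L), ifelse(h2$mapped, 60L, 0L)),
      cigar = c(ifelse(h1$mapped, sprintf("%dM", read_len), "*"),
                ifelse(h2$mapped, sprintf("%dM", read_len), "*")),
      seq = c(seq1, seq2),
      stringsAsFactors = FALSE
    )
    list(reads = reads,
         seqlengths = setNames(hlen, host_name),
         truth = list(junction = insertion_pos, insert_len = ins_len,
                      copies = if (is.null(insertion_pos)) 0L else copies,
                      frag_mean = frag_mean))
  })
}
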