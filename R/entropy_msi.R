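#' Shannon entropy of an allele-length spectrum
#'
#' Quantifies allelic diversity at a microsatellite locus as
#' \eqn{SE = -\sum_i p_i \log_2 p_i} over the distinct observed unit counts,
#' where \eqn{p_i} are read proportions. SE is reported in bits. SE = 0
#' indicates complete stability (all reads share one repeat length); higher
#' values indicate the coexistence of multiple lengths.
#'
#' @param spectrum a named count vector (names = unit counts), or a bare
#'   numeric vector of counts/proportions.
#' @return Shannon entropy in bits (nonnegative scalar).
#' @examples
#' shannon_entropy(c(`10` = 37))            # 0
#' shannon_entropy(c(`12` = 50, `13` = 50)) # 1
#' @export
shannon_entropy <- function(spectrum) {
  x <- as.numeric(spectrum)
  if (length(x) == 0L || sum(x) <= 0) stop("empty spectrum")
  p <- x / sum(x)
  p <- p[p > 0]
  -sum(p * log2(p)) + 0  # "+ 0" normalizes the signed zero of a point mass
}

#' Per-locus Shannon entropy for a spectra table
#'
#' Computes SE (bits) for every locus of a spectra table, skipping loci
#' flagged insufficient.
#'
#' @param spectra spectra table from [extract_spectra()] or [read_dis()].
#' @return data.frame with columns `sample_id`, `locus_id`, `se`, `depth`.
#' @export
locus_entropy <- function(spectra) {
  d <- spectra
  if ("insufficient" %in% names(d)) d <- d[!d$insufficient, , drop = FALSE]
  data.frame(
    sample_id = d$sample_id,
    locus_id = d$locus_id,
    se = vapply(d$spectrum, shannon_entropy, numeric(1)),
    depth = vapply(d$spectrum, function(x) sum(as.integer(x)), integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Stratify per-locus entropies by motif and repeat length
#'
#' Groups loci by (canonical motif, reference unit count) per sample,
#' combining complementary-strand motifs through canonicalization, and
#' summarizes mean and SD of SE. For exome data (`assay = "WES"`), strata
#' containing fewer than `min_stratum_loci` loci are excluded from the
#' output; the exclusions are attached as attribute `"excluded"`.
#'
#' @param entropies data.frame from [locus_entropy()].
#' @param catalog the catalog the spectra were built against.
#' @param assay `"WGS"` or `"WES"`; the stratum-size exclusion applies to
#'   WES only.
#' @param min_stratum_loci stratum size cutoff for WES (default 10).
#' @return data.frame with `sample_id`, `canonical_motif`, `unit_count`,
#'   `mean_se`, `sd_se`, `n_loci`.
#' @export
summarize_strata <- function(entropies, catalog, assay = c("WGS", "WES"),
                             min_stratum_loci = 10L) {
  assay <- match.arg(assay)
  idx <- match(entropies$locus_id, catalog$locus_id)
  if (anyNA(idx))
    stop("locus_id not found in catalog: ",
         paste(head(entropies$locus_id[is.na(idx)]), collapse = ", "))
  d <- data.frame(
    sample_id = entropies$sample_id,
    canonical_motif = catalog$canonical_motif[idx],
    unit_count = catalog$unit_count[idx],
    se = entropies$se,
    stringsAsFactors = FALSE
  )
  agg <- do.call(rbind, lapply(
    split(d, list(d$sample_id, d$canonical_motif, d$unit_count),
          drop = TRUE),
    function(g) data.frame(
      sample_id = g$sample_id[1],
      canonical_motif = g$canonical_motif[1],
      unit_count = g$unit_count[1],
      mean_se = mean(g$se),
      sd_se = if (nrow(g) > 1L) sd(g$se) else 0,
      n_loci = nrow(g),
      stringsAsFactors = FALSE
    )))
  agg <- agg[order(agg$sample_id, agg$canonical_motif, agg$unit_count), ]
  rownames(agg) <- NULL
  excluded <- agg[0, ]
  if (assay == "WES") {
    small <- agg$n_loci < min_stratum_loci
    excluded <- agg[small, , drop = FALSE]
    excluded$reason <- if (nrow(excluded)) {
      sprintf("n_loci < %d (WES stratum exclusion)", min_stratum_loci)
    } else character(0)
    agg <- agg[!small, , drop = FALSE]
    rownames(agg) <- NULL
  }
  attr(agg, "excluded") <- excluded
  agg
}

#' Linear trend of entropy versus repeat length for one motif class
#'
#' Ordinary least squares of per-locus SE on reference unit count for all
#' loci of one canonical motif, with a 95% confidence interval on the slope
#' from the standard error and the t quantile. Mirrors the per-motif
#' scatterplot fits used to compare instability growth across genotypes.
#'
#' @param entropies data.frame from [locus_entropy()].
#' @param catalog the matching catalog.
#' @param canonical_motif motif class to fit (e.g. `"A"`, `"CA"`).
#' @param conf_level confidence level (default 0.95).
#' @return one-row data.frame: `canonical_motif`, `slope` (SE bits per
#'   repeat unit), `intercept`, `slope_ci_low`, `slope_ci_high`, `n_points`.
#' @export
fit_motif_trend <- function(entropies, catalog, canonical_motif,
                            conf_level = 0.95) {
  idx <- match(entropies$locus_id, catalog$locus_id)
  if (anyNA(idx)) stop("locus_id not found in catalog")
  sel <- catalog$canonical_motif[idx] == canonical_motif
  x <- catalog$unit_count[idx][sel]
  y <- entropies$se[sel]
  if (length(unique(x)) < 3L)
    stop("insufficient data: need >= 3 distinct unit_count values, have ",
         length(unique(x)))
  fit <- lm(y ~ x)
  ci <- confint(fit, "x", level = conf_level)
  data.frame(
    canonical_motif = canonical_motif,
    slope = unname(coef(fit)["x"]),
    intercept = unname(coef(fit)["(Intercept)"]),
    slope_ci_low = ci[1, 1],
    slope_ci_high = ci[1, 2],
    n_points = length(x),
    stringsAsFactors = FALSE
  )
}

## Total variation distance between two spectra given as named count or
## proportion vectors; computed over the union of unit counts.
tv_distance <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  keys <- union(names(p), names(q))
  pv <- ifelse(keys %in% names(p), p[keys], 0)
  qv <- ifelse(keys %in% names(q), q[keys], 0)
  0.5 * sum(abs(pv - qv))
}

#' Build a tumor-only MSI baseline from normal samples
#'
#' Pools the allele spectra of microsatellite-stable normal samples per
#' locus and derives a per-locus instability threshold tau. Only loci
#' covered (at sufficient depth) in every contributing sample are retained;
#' dropped loci are recorded in attribute `"dropped"`. tau is the mean plus
#' three standard deviations of the leave-one-out instability distances of
#' the normals (total variation distance of each normal against the pool of
#' the others). With a single normal sample tau falls back to
#' `tau_single`.
#'
#' @param normals a list of spectra tables (one per normal sample), or one
#'   spectra table containing several `sample_id`s.
#' @param tau_single global default threshold used when only one normal is
#'   available (default 0.1).
#' @return an object of class `msi_baseline`: list with `loci` (data.frame
#'   `locus_id`, `tau`), `pooled` (named list of pooled proportion vectors),
#'   and `samples` (contributing sample ids).
#' @export
build_baseline <- function(normals, tau_single = 0.1) {
  if (is.data.frame(normals)) normals <- split(normals, normals$sample_id)
  if (length(normals) == 0L) stop("at least one normal sample is required")
  normals <- lapply(normals, function(d) {
    if ("insufficient" %in% names(d)) d[!d$insufficient, , drop = FALSE] else d
  })
  if (is.null(names(normals)))
    names(normals) <- vapply(normals, function(d) d$sample_id[1], character(1))
  ids <- Reduce(intersect, lapply(normals, `[[`, "locus_id"))
  all_ids <- Reduce(union, lapply(normals, `[[`, "locus_id"))
  dropped <- setdiff(all_ids, ids)
  if (length(ids) == 0L) stop("no locus is covered in every normal sample")
  per_sample <- lapply(normals, function(d) {
    sp <- d$spectrum[match(ids, d$locus_id)]
    names(sp) <- ids
    sp
  })
  pooled <- lapply(ids, function(id) {
    counts <- lapply(per_sample, `[[`, id)
    keys <- Reduce(union, lapply(counts, names))
    tot <- setNames(numeric(length(keys)), keys)
    for (ct in counts) tot[names(ct)] <- tot[names(ct)] + as.numeric(ct)
    tot / sum(tot)
  })
  names(pooled) <- ids
  n <- length(per_sample)
  tau <- if (n == 1L) {
    rep(tau_single, length(ids))
  } else {
    vapply(ids, function(id) {
      counts <- lapply(per_sample, `[[`, id)
      d <- vapply(seq_len(n), function(i) {
        others <- counts[-i]
        keys <- Reduce(union, lapply(others, names))
        pool <- setNames(numeric(length(keys)), keys)
        for (ct in others) pool[names(ct)] <- pool[names(ct)] + as.numeric(ct)
        tv_distance(as.numeric(counts[[i]]) |>
                      setNames(names(counts[[i]])), pool)
      }, numeric(1))
      mean(d) + 3 * sd(d)
    }, numeric(1), USE.NAMES = FALSE)
  }
  out <- list(
    loci = data.frame(locus_id = ids, tau = tau, stringsAsFactors = FALSE),
    pooled = pooled,
    samples = names(normals)
  )
  attr(out, "dropped") <- dropped
  class(out) <- "msi_baseline"
  out
}

#' Score a tumor-only sample against an MSI baseline
#'
#' For every locus present in both the sample and the baseline, the
#' instability distance d is the total variation distance between the
#' sample's allele proportions and the pooled normal proportions. A locus is
#' called unstable when d strictly exceeds `max(tau, tau_floor)` (ties are
#' stable). The MSI score is the proportion of unstable loci among the
#' evaluated loci.
#'
#' @param spectra spectra table of one sample.
#' @param baseline an `msi_baseline` from [build_baseline()].
#' @param tau_floor minimum instability threshold (default 0.05).
#' @return list of class `msi_result` with `summary` (one-row data.frame:
#'   `sample_id`, `n_evaluated`, `n_unstable`, `msi_score`) and `loci`
#'   (per-locus audit table with `d`, `tau`, `unstable`).
#' @export
score_msi <- function(spectra, baseline, tau_floor = 0.05) {
  stopifnot(inherits(baseline, "msi_baseline"))
  d <- spectra
  if ("insufficient" %in% names(d)) d <- d[!d$insufficient, , drop = FALSE]
  ids <- intersect(d$locus_id, baseline$loci$locus_id)
  if (length(ids) == 0L)
    stop("no locus overlaps between sample and baseline")
  sp <- d$spectrum[match(ids, d$locus_id)]
  tau <- baseline$loci$tau[match(ids, baseline$loci$locus_id)]
  dist <- vapply(seq_along(ids), function(i) {
    tv_distance(as.numeric(sp[[i]]) |> setNames(names(sp[[i]])),
                baseline$pooled[[ids[i]]])
  }, numeric(1))
  thr <- pmax(tau, tau_floor)
  unstable <- dist > thr
  res <- list(
    summary = data.frame(
      sample_id = d$sample_id[1],
      n_evaluated = length(ids),
      n_unstable = sum(unstable),
      msi_score = sum(unstable) / length(ids),
      stringsAsFactors = FALSE
    ),
    loci = data.frame(locus_id = ids, d = dist, tau = thr,
                      unstable = unstable, stringsAsFactors = FALSE)
  )
  class(res) <- "msi_result"
  res
}

#' @export
print.msi_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("MSI result for %s: %d/%d loci unstable (score %.4f, SE in bits, TV-distance calls)\n",
              s$sample_id, s$n_unstable, s$n_evaluated, s$msi_score))
  invisible(x)
}

#' @export
print.msi_baseline <- function(x, ...) {
  cat(sprintf("MSI baseline: %d loci from %d normal sample(s)\n",
              nrow(x$loci), length(x$samples)))
  invisible(x)
}
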