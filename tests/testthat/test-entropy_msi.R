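test_that("shannon entropy matches closed-form values and bounds", {
  expect_identical(shannon_entropy(c(`10` = 37)), 0)
  expect_equal(shannon_entropy(c(`12` = 50, `13` = 50)), 1)
  expect_equal(shannon_entropy(c(`9` = 25, `10` = 50, `11` = 25)), 1.5)
  expect_error(shannon_entropy(integer(0)), "empty")
  # 0 <= SE <= log2(k); invariant to length labels; merge-invariance
  set.seed(5)
  for (i in 1:25) {
    k <- sample(2:8, 1)
    counts <- setNames(sample(1:50, k, replace = TRUE),
                       sample(5:40, k))
    se <- shannon_entropy(counts)
    expect_gte(se, 0)
    expect_lte(se, log2(k) + 1e-12)
    relabeled <- setNames(as.integer(counts), sample(100:200, k))
    expect_equal(shannon_entropy(relabeled), se)
    expect_equal(shannon_entropy(counts * 3L), se)
  }
})

test_that("strata combine complementary motifs and apply the WES size rule", {
  cat1 <- rbind(synthetic_catalog("A", 10), synthetic_catalog("T", 10))
  cat1$locus_id <- sprintf("L%02d", seq_len(nrow(cat1)))
  # 6 A-loci at SE 0.2 and 6 T-loci at SE 0.4, same unit count
  cat1 <- cat1[rep(1:2, each = 6), ]
  cat1$locus_id <- sprintf("L%02d", 1:12)
  ent <- data.frame(sample_id = "S", locus_id = cat1$locus_id,
                    se = rep(c(0.2, 0.4), each = 6), depth = 50L)
  st <- summarize_strata(ent, cat1, assay = "WGS")
  expect_equal(nrow(st), 1L)
  expect_equal(st$canonical_motif, "A")
  expect_equal(st$n_loci, 12L)
  expect_equal(st$mean_se, 0.3)
  # a 9-locus stratum survives WGS but is excluded (and logged) under WES
  st_wes <- summarize_strata(ent[1:9, ], cat1[1:9, ], assay = "WES")
  expect_equal(nrow(st_wes), 0L)
  excl <- attr(st_wes, "excluded")
  expect_equal(excl$n_loci, 9L)
  st_wgs <- summarize_strata(ent[1:9, ], cat1[1:9, ], assay = "WGS")
  expect_equal(st_wgs$n_loci, 9L)
  # all-zero entropies give zero means and SDs
  ent0 <- ent; ent0$se <- 0
  st0 <- summarize_strata(ent0, cat1, assay = "WGS")
  expect_true(all(st0$mean_se == 0) && all(st0$sd_se == 0))
  expect_error(summarize_strata(
    data.frame(sample_id = "S", locus_id = "nope", se = 1, depth = 5),
    cat1), "not found")
})

test_that("motif trend recovers exact linear relationships", {
  cat1 <- synthetic_catalog("CA", 5:14)
  ent <- data.frame(sample_id = "S", locus_id = cat1$locus_id,
                    se = 0.1 * cat1$unit_count, depth = 50L)
  tr <- suppressWarnings(fit_motif_trend(ent, cat1, "CA"))
  expect_equal(tr$slope, 0.1, tolerance = 1e-10)
  expect_equal(tr$intercept, 0, tolerance = 1e-10)
  expect_true(tr$slope_ci_low <= tr$slope && tr$slope <= tr$slope_ci_high)
  # constant SE -> slope 0
  ent$se <- 0.3
  expect_equal(suppressWarnings(fit_motif_trend(ent, cat1, "CA"))$slope, 0,
               tolerance = 1e-10)
  expect_error(fit_motif_trend(ent[1:2, ], cat1[1:2, ], "CA"),
               "insufficient")
})

test_that("baseline pooling and leave-one-out thresholds behave as declared", {
  cat1 <- synthetic_catalog("A", 8:12)
  one <- simulate_locus_spectra(cat1, slippage_model(p0 = 0.1),
                                depth = 40, seed = 1, sample_id = "N1")$spectra
  b1 <- build_baseline(list(one))
  # single normal: pooled spectrum equals that sample's proportions
  for (id in b1$loci$locus_id) {
    sp <- one$spectrum[[match(id, one$locus_id)]]
    expect_equal(b1$pooled[[id]],
                 setNames(as.numeric(sp) / sum(sp), names(sp)))
  }
  expect_true(all(b1$loci$tau == 0.1))  # global single-sample default
  # identical normals: all leave-one-out distances 0, tau collapses to 0
  # and the floor governs at scoring time
  two <- one; two$sample_id <- "N2"
  b2 <- build_baseline(list(one, two))
  expect_true(all(b2$loci$tau == 0))
  res <- score_msi(one, b2)
  expect_equal(res$summary$msi_score, 0)
  expect_true(all(res$loci$tau == 0.05))
  expect_error(build_baseline(list()), "at least one")
})

test_that("pooled baseline proportions recover the generating distribution", {
  cat1 <- synthetic_catalog("A", c(10, 14))
  model <- slippage_model(p0 = 0.3, gamma = 0, d1 = 0.7, i1 = 0.3)
  normals <- lapply(1:10, function(i)
    simulate_locus_spectra(cat1, model, depth = 100, seed = 100 + i,
                           sample_id = sprintf("N%02d", i))$spectra)
  b <- build_baseline(normals)
  for (i in seq_len(nrow(cat1))) {
    pooled <- b$pooled[[cat1$locus_id[i]]]
    n_ref <- cat1$unit_count[i]
    # p(slip) = 0.3 with P(-1)=0.7: expected mass at ref-1 = 0.21
    expect_equal(unname(pooled[as.character(n_ref)]), 0.7,
                 tolerance = 0.05)
    expect_equal(unname(pooled[as.character(n_ref - 1L)]), 0.21,
                 tolerance = 0.05)
  }
})

test_that("msi scoring hits the boundary cases exactly", {
  cat1 <- synthetic_catalog("A", 8:12)
  norm <- simulate_locus_spectra(cat1, slippage_model(p0 = 0), depth = 30,
                                 seed = 2, sample_id = "N1")$spectra
  b <- build_baseline(list(norm))
  # identical sample -> 0
  same <- norm; same$sample_id <- "T0"
  expect_equal(score_msi(same, b)$summary$msi_score, 0)
  # every locus shifted by one unit (point mass) -> d = 1 everywhere -> 1
  shifted <- norm
  shifted$sample_id <- "T1"
  shifted$spectrum <- lapply(seq_len(nrow(norm)), function(i)
    setNames(norm$spectrum[[i]], as.integer(names(norm$spectrum[[i]])) - 1L))
  res <- score_msi(shifted, b)
  expect_equal(res$summary$msi_score, 1)
  expect_true(all(res$loci$d == 1))
  expect_error(score_msi(shifted[0, ], b), "no locus overlaps")
})

test_that("msi score is monotone in per-locus distances and order-invariant", {
  cat1 <- synthetic_catalog("A", 6:15)
  norm <- simulate_locus_spectra(cat1, slippage_model(p0 = 0.05),
                                 depth = 50, seed = 3,
                                 sample_id = "N1")$spectra
  b <- build_baseline(list(norm))
  tum <- simulate_locus_spectra(cat1,
                                slippage_model(p0 = 0.3,
                                               genotype_multiplier = 1.5),
                                depth = 50, seed = 4,
                                sample_id = "T1")$spectra
  r1 <- score_msi(tum, b)
  perm <- tum[sample(nrow(tum)), ]
  r2 <- score_msi(perm, b)
  expect_equal(r1$summary$msi_score, r2$summary$msi_score)
  # raising tau_floor can only reduce the score
  expect_lte(score_msi(tum, b, tau_floor = 0.3)$summary$msi_score,
             r1$summary$msi_score)
})

test_that("stratum mean SE increases with slippage rate and repeat length", {
  cat1 <- synthetic_catalog("A", rep(6:25, each = 10))
  cat1$locus_id <- sprintf("L%04d", seq_len(nrow(cat1)))
  model_lo <- slippage_model(p0 = 0.002, genotype_multiplier = 1)
  model_hi <- slippage_model(p0 = 0.002, genotype_multiplier = 5)
  sp_lo <- simulate_locus_spectra(cat1, model_lo, depth = 50, seed = 9,
                                  sample_id = "LO")$spectra
  sp_hi <- simulate_locus_spectra(cat1, model_hi, depth = 50, seed = 9,
                                  sample_id = "HI")$spectra
  st_lo <- summarize_strata(locus_entropy(sp_lo), cat1)
  st_hi <- summarize_strata(locus_entropy(sp_hi), cat1)
  # Spearman correlation of mean SE with unit count, within condition
  ct <- suppressWarnings(
    cor.test(st_hi$unit_count, st_hi$mean_se, method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  # higher slippage multiplier -> higher mean SE at matched strata
  merged <- merge(st_lo, st_hi, by = "unit_count")
  expect_gt(mean(merged$mean_se.y > merged$mean_se.x), 0.9)
})
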