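test_that("reporter mutation classes follow the assay scheme", {
  ref <- reporter_reference("GGCTAAAAAATCGGTCATGC")  # (A)6 at offset 4..9
  muts <- data.frame(
    colony_id = sprintf("c%d", 1:7),
    kind = c("substitution", "substitution", "deletion", "deletion",
             "deletion", "insertion", "deletion"),
    position = c(1L, 4L, 5L, 15L, 2L, 6L, 16L),
    ref_allele = c("G", "A", "A", "C", "CTA", "", "AT"),
    alt_allele = c("A", "T", "", "", "", "A", ""),
    stringsAsFactors = FALSE
  )
  cl <- classify_reporter_mutation(muts, ref)
  expect_equal(cl$class,
               c("G:C>A:T", "A:T>T:A", "1-indel_(A)n", "1-indel",
                 ">2bp_indel", "1-indel_(A)n", "other"))
  expect_equal(cl$run_length[3], 6L)
  expect_equal(cl$run_length[6], 6L)
  # ambiguous placement normalized to the run start
  expect_equal(cl$position[3], 4L)
  # strand symmetry of substitution classes
  expect_equal(classify_reporter_mutation(
    data.frame(colony_id = "x", kind = "substitution", position = 11L,
               ref_allele = "C", alt_allele = "T"), ref)$class, "G:C>A:T")
  expect_error(classify_reporter_mutation(
    data.frame(colony_id = "x", kind = "substitution", position = 0L,
               ref_allele = "A", alt_allele = "T"), ref), "mismatch")
})

test_that("classification equals the exhaustive run-length oracle on random sets", {
  ref <- simulate_reporter_reference(seed = 19)
  sim <- simulate_reporter_colonies(ref, n_mice = 6, seed = 23)
  cl <- classify_reporter_mutation(sim$mutations, ref)
  expect_equal(cl$class, cl$true_class)
  an <- cl[cl$class %in% c("1-indel_(A)n", "2-indel_(A)n"), ]
  for (i in seq_len(nrow(an)))
    expect_equal(an$run_length[i],
                 oracle_at_run_length(ref$seq, an$position[i]))
  # every mutation receives exactly one class from the declared set
  expect_true(all(cl$class %in% reporter_classes()))
})

test_that("mutant frequency arithmetic and conservation hold", {
  counts <- data.frame(mouse_id = "m1", group = "g", n_km = 200000L,
                       n_kmsm = 5L)
  mf <- compute_assay_mf(counts)
  expect_equal(unname(mf$overall["g"]), 2.5e-5)
  # proportional split: 10 mutations, 6 of one class
  cl <- data.frame(mouse_id = "m1",
                   class = rep(c("G:C>A:T", "1-indel"), c(6, 4)))
  counts2 <- data.frame(mouse_id = "m1", group = "g", n_km = 1000000L,
                        n_kmsm = 10L)
  mf2 <- compute_assay_mf(counts2, cl)
  expect_equal(unname(mf2$class_mf["G:C>A:T", "g"]), 0.6e-5)
  expect_equal(sum(mf2$class_mf[, "g"]), unname(mf2$overall["g"]))
  expect_error(compute_assay_mf(data.frame(mouse_id = "m", group = "g",
                                           n_km = 0L, n_kmsm = 0L)),
               "positive")
  expect_error(compute_assay_mf(data.frame(mouse_id = "m", group = "g",
                                           n_km = 10L, n_kmsm = 11L)),
               "exceed")
})

test_that("per-class MF sums to overall MF for simulated cohorts in both modes", {
  ref <- simulate_reporter_reference(seed = 3)
  sim <- simulate_reporter_colonies(ref, n_mice = 5, seed = 31)
  cl <- classify_reporter_mutation(sim$mutations, ref)
  for (mode in c("per_mouse", "pooled")) {
    mf <- compute_assay_mf(sim$counts, cl, mode = mode)
    expect_equal(sum(mf$class_mf[, 1]), unname(mf$overall[1]),
                 tolerance = 1e-12)
  }
})

test_that("two-group comparison reports a Mann-Whitney p-value", {
  ref <- simulate_reporter_reference(seed = 3)
  a <- simulate_reporter_colonies(ref, n_mice = 5, group = "control",
                                  mf = 5e-5, seed = 1)
  b <- simulate_reporter_colonies(ref, n_mice = 5, group = "treated",
                                  mf = 50e-5, seed = 2)
  counts <- rbind(a$counts, b$counts)
  mf <- compute_assay_mf(counts)
  expect_equal(nrow(mf$comparisons), 1L)
  ref_p <- suppressWarnings(wilcox.test(
    a$counts$n_kmsm / a$counts$n_km,
    b$counts$n_kmsm / b$counts$n_km)$p.value)
  expect_equal(mf$comparisons$p_value, ref_p)
})

test_that("adenine run-length buckets conserve the (A)n total", {
  ref <- simulate_reporter_reference(seed = 3)
  sim <- simulate_reporter_colonies(ref, n_mice = 5, seed = 37)
  cl <- classify_reporter_mutation(sim$mutations, ref)
  for (mode in c("per_mouse", "pooled")) {
    mf <- compute_assay_mf(sim$counts, cl, mode = mode)
    ab <- adenine_indel_by_runlength(cl, sim$counts, mode = mode)
    expect_equal(sum(ab$mf), unname(mf$class_mf["1-indel_(A)n", 1]),
                 tolerance = 1e-12)
  }
  # all-at-one-run concentration: entire (A)n MF in that bucket
  cl6 <- cl[cl$class == "1-indel_(A)n" & cl$run_length == 6L, ]
  ab6 <- adenine_indel_by_runlength(cl6, sim$counts)
  expect_true(all(ab6$mf[ab6$run_length < 6] == 0))
  # empty input -> all buckets zero
  ab0 <- adenine_indel_by_runlength(cl[0, ], sim$counts)
  expect_true(all(ab0$mf == 0))
})

test_that("hotspot profile is positionally exact and conserves class totals", {
  ref <- reporter_reference("GGCTAAAAAATCGGTCATGC")
  counts <- data.frame(mouse_id = "m1", group = "g", n_km = 100000L,
                       n_kmsm = 2L)
  muts <- data.frame(colony_id = c("c1", "c2"), mouse_id = "m1",
                     kind = c("deletion", "insertion"),
                     position = c(5L, 6L),
                     ref_allele = c("A", ""), alt_allele = c("", "A"),
                     stringsAsFactors = FALSE)
  cl <- classify_reporter_mutation(muts, ref)
  hp <- hotspot_profile(cl, counts, ref)
  # both normalized to the run start (position 4)
  expect_equal(hp$del_mf[hp$position == 4], 1e-5)
  expect_equal(hp$ins_mf[hp$position == 4], 1e-5)
  expect_equal(sum(hp$del_mf) + sum(hp$ins_mf), 2e-5)
  expect_true(all(hp$run_length[hp$position %in% 4:9] == 6L))
})

test_that("the transcribed MF table reproduces the printed marginals", {
  tbl <- read_mf_table()
  expect_true(all(c("class", "msh2ko_control") %in% names(tbl)))
  bs <- tbl$msh2ko_control[tbl$class == "BS total"]
  ind <- tbl$msh2ko_control[tbl$class == "Indel total"]
  # the class rows sum to the printed totals within rounding
  sub_rows <- tbl$class %in% c("G:C>A:T", "A:T>G:C", "G:C>T:A", "G:C>C:G",
                               "A:T>T:A", "A:T>C:G")
  expect_equal(sum(tbl$msh2ko_control[sub_rows], na.rm = TRUE), bs,
               tolerance = 0.01)
  indel_rows <- tbl$class %in% c("1-indel", "1-indel_(A)n", "2-indel_(A)n",
                                 ">2bp_indel", "other")
  expect_equal(sum(tbl$msh2ko_control[indel_rows], na.rm = TRUE), ind,
               tolerance = 0.01)
})
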