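test_that("somatic filtering applies every rule and tallies first failures", {
  base <- data.frame(chrom = "5", pos = 100L, ref = "C", alt = "T",
                     sample_id = "t1", tumor_depth = 10L,
                     normal_depth = 10L, tumor_alt_reads = 3L,
                     normal_alt_reads = 0L, in_dbsnp = FALSE,
                     shared_tumor_count = 1L, stringsAsFactors = FALSE)
  expect_equal(nrow(filter_somatic(base)$retained), 1L)
  lowt <- base; lowt$tumor_depth <- 9L
  r <- filter_somatic(lowt)
  expect_equal(nrow(r$retained), 0L)
  expect_equal(r$rejected$reason, "tumor_depth")
  shared <- base; shared$shared_tumor_count <- 2L
  expect_equal(filter_somatic(shared)$rejected$reason, "shared_tumors")
  sex <- base; sex$chrom <- "chrX"
  expect_equal(filter_somatic(sex)$rejected$reason, "chromosome")
  nn <- base; nn$normal_alt_reads <- 1L
  expect_equal(filter_somatic(nn)$rejected$reason, "normal_alt_reads")
  expect_error(filter_somatic(base[, -6]), "missing depth")
})

test_that("filtering equals the independent brute-force oracle and partitions input", {
  v <- random_variants(1000L, 77)
  res <- filter_somatic(v)
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, d$sample_id,
                           d$tumor_depth, d$normal_depth)
  expect_setequal(key(res$retained), key(oracle_filter(v)))
  # retained + rejected partition the input; tally sums to rejected count
  expect_equal(nrow(res$retained) + nrow(res$rejected), nrow(v))
  expect_equal(sum(res$tally$n_rejected), nrow(res$rejected))
})

test_that("SBS96 classification follows the pyrimidine convention", {
  expect_equal(classify_sbs96("G", "A", "TGT"), "A[C>T]A")
  expect_equal(classify_sbs96("C", "T", "ACA"), "A[C>T]A")
  expect_equal(classify_sbs96("A", "C", "GAC"), "G[T>G]C")
  expect_true(is.na(classify_sbs96("C", "T", "NCA")))
  expect_error(classify_sbs96("C", "T", "AAA"), "center")
})

test_that("all 192 strand-substitution-context combinations map 2-to-1 onto 96", {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(five = bases, ref = bases, three = bases,
                      alt = bases, stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  lab <- classify_sbs96(grid$ref, grid$alt,
                        paste0(grid$five, grid$ref, grid$three))
  expect_equal(length(lab), 192L)
  tab <- table(lab)
  expect_equal(length(tab), 96L)
  expect_true(all(tab == 2L))
  expect_setequal(names(tab), sbs96_classes())
  # strand invariance: complementing every record leaves the labels fixed
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc_ctx <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(paste0(grid$five, grid$ref, grid$three))))
  lab_rc <- classify_sbs96(unname(comp[grid$ref]), unname(comp[grid$alt]),
                           rc_ctx)
  expect_equal(lab_rc, lab)
})

test_that("ID83 classification handles homopolymers, repeats and microhomology", {
  ref <- c(chrA = paste0("GCGTAC", strrep("T", 8), "GACGTC",
                         strrep("CA", 7), "GTGACGGT",
                         "CCTAGTACGC", "GCAATCGGAT"))
  # deletion of one T from a T x 8 run -> category 6+
  expect_equal(classify_id83("chrA", 6L, "CT", "C", ref), "1:Del:T:6")
  # deletion of one A from no-run context (isolated base)
  s <- ref[[1]]
  pos_a <- as.integer(regexpr("GACG", s))  # the A in GACG, isolated
  expect_equal(classify_id83("chrA", pos_a, substr(s, pos_a, pos_a + 1),
                             substr(s, pos_a, pos_a), ref), "1:Del:T:1")
  # deletion of CA from (CA)7 -> size 2, repeat-unit top category
  pos_ca <- as.integer(regexpr("CACACACACACACA", s)) - 1L
  expect_equal(classify_id83("chrA", pos_ca, substr(s, pos_ca, pos_ca + 2),
                             substr(s, pos_ca, pos_ca), ref), "2:Del:R:6")
  # insertion of CA into (CA)7 -> size 2 insertion at repeats, 5+
  expect_equal(classify_id83("chrA", pos_ca, substr(s, pos_ca, pos_ca),
                             paste0(substr(s, pos_ca, pos_ca), "CA"), ref),
               "2:Ins:R:5")
  # TAG deletion flanked by TA: microhomology length 2
  pos_tag <- as.integer(regexpr("TAGTA", s)) - 1L
  expect_equal(classify_id83("chrA", pos_tag,
                             substr(s, pos_tag, pos_tag + 3),
                             substr(s, pos_tag, pos_tag), ref), "3:Del:M:2")
  # C insertion next to a single C -> homopolymer length 1
  pos_c <- as.integer(regexpr("GCAAT", s))
  expect_equal(classify_id83("chrA", pos_c + 1L, "C", "CC", ref),
               "1:Ins:C:1")
})

test_that("ID83 labels are invariant to right-shifted indel representations", {
  ref <- c(chrA = "GGCTTTTTTTTGACCACACACACACAGTGACG")
  # the same T deletion written at every position within the run
  t_start <- as.integer(regexpr("TTTTTTTT", ref[[1]]))
  labs <- vapply(0:7, function(off) {
    p <- t_start - 1L + off
    classify_id83("chrA", p, substr(ref[[1]], p, p + 1L),
                  substr(ref[[1]], p, p), ref)
  }, character(1))
  expect_true(all(labs == "1:Del:T:6"))
  # CA deletion written at two equivalent offsets
  ca_start <- as.integer(regexpr("CACACACACACA", ref[[1]]))
  l1 <- classify_id83("chrA", ca_start - 1L,
                      substr(ref[[1]], ca_start - 1L, ca_start + 1L),
                      substr(ref[[1]], ca_start - 1L, ca_start - 1L), ref)
  l2 <- classify_id83("chrA", ca_start + 3L,
                      substr(ref[[1]], ca_start + 3L, ca_start + 5L),
                      substr(ref[[1]], ca_start + 3L, ca_start + 3L), ref)
  expect_equal(l1, l2)
})

test_that("matrices recover generating class proportions from simulated variants", {
  # draw SNVs from a known SBS96 profile concentrated on 4 classes and
  # check multinomial recovery of the proportions
  set.seed(123)
  profile <- c("A[C>T]A" = 0.4, "T[C>A]G" = 0.3, "C[T>C]C" = 0.2,
               "G[C>G]T" = 0.1)
  n <- 2000L
  draws <- sample(names(profile), n, TRUE, prob = profile)
  parse <- regmatches(draws, regexec("(.)\\[(.)>(.)\\](.)", draws))
  five <- vapply(parse, `[`, character(1), 2)
  refb <- vapply(parse, `[`, character(1), 3)
  altb <- vapply(parse, `[`, character(1), 4)
  three <- vapply(parse, `[`, character(1), 5)
  # build a reference holding each variant context at known offsets;
  # separator G/T pairs prevent context bleed
  ctx <- paste0(five, refb, three)
  seqs <- c(chrV = paste0("GT", paste(ctx, collapse = "GT"), "GT"))
  pos <- 2L + (seq_len(n) - 1L) * 5L + 2L
  variants <- data.frame(chrom = "chrV", pos = pos, ref = refb, alt = altb,
                         sample_id = "s1", stringsAsFactors = FALSE)
  m <- build_matrices(variants, seqs)
  expect_equal(sum(m$sbs96[, "s1"]), n)
  got <- m$sbs96_prop[names(profile), "s1"]
  expect_equal(unname(got), unname(profile), tolerance = 0.08)
  expect_equal(sum(m$sbs96_prop[, "s1"]), 1)
  # 6-class collapse agrees with direct substitution tallies
  expect_equal(unname(m$sbs6["C>T", "s1"]),
               sum(draws == "A[C>T]A"))
  expect_equal(unname(m$bs_indel["BS", "s1"]), n)
  # empty input warns and yields zero matrices
  expect_warning(m0 <- build_matrices(variants[0, ], seqs), "no variants")
  expect_true(all(m0$sbs96 == 0))
})
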