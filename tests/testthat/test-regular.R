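test_that("a planted 20-homopolymer is recovered nearly exactly", {
  gen <- plant_regular(400, data.frame(seq = strrep("C", 20), pos = 180),
                       seed = 20)
  reg <- detect_regions(pb_spectrum(gen$sequence))
  hit <- reg[reg$e >= 180 & reg$s <= 199, , drop = FALSE]
  expect_equal(nrow(hit), 1)
  covered <- min(hit$e, 199) - max(hit$s, 180) + 1
  expect_gte(covered, 0.9 * 20)
})

test_that("detection thresholds realize the 7-nt minimum length", {
  # runs of 4 are invisible; a run of 5 is reported as the 7-nt region that
  # includes its flanking opposite-class bases; longer runs scale up
  for (q in c(4, 5, 7)) {
    gen <- plant_regular(300, data.frame(seq = strrep("C", q), pos = 140),
                         seed = 100 + q)
    reg <- detect_regions(pb_spectrum(gen$sequence))
    over <- reg[reg$e >= 140 & reg$s <= 139 + q, , drop = FALSE]
    if (q == 4) {
      expect_equal(nrow(over), 0)
    } else {
      expect_equal(nrow(over), 1)
      expect_equal(over$length, q + 2)
      expect_equal(over$s, 139)
      grepl_core <- substr(over$binary, 2, q + 1)
      expect_identical(grepl_core, strrep("S", q))
    }
  }
})

test_that("regularity-free null backgrounds yield no regions", {
  fp <- vapply(1:20, function(sd) {
    gen <- plant_regular(300, seed = 1000 + sd)
    nrow(detect_regions(pb_spectrum(gen$sequence)))
  }, integer(1))
  expect_lte(sum(fp), 1)  # allow at most one false positive over 20 seeds
})

test_that("regions mirror under reverse complement", {
  gen <- plant_regular(300,
                       data.frame(seq = "CTAATTTTTGTATTTTTAG", pos = 120),
                       seed = 21)
  fwd <- detect_regions(pb_spectrum(gen$sequence))
  rev <- detect_regions(pb_spectrum(reverse_complement(gen$sequence)))
  expect_equal(nrow(fwd), nrow(rev))
  L <- 300
  expect_equal(sort(L - fwd$e + 1), sort(rev$s))
  expect_equal(sort(L - fwd$s + 1), sort(rev$e))
  expect_setequal(vapply(fwd$quaternary, reverse_complement, ""),
                  rev$quaternary)
})

test_that("detection is deterministic and independent of promoter naming", {
  gen <- plant_regular(250, data.frame(seq = strrep("G", 9), pos = 100),
                       seed = 23)
  r1 <- detect_regions(pb_spectrum(gen$sequence))
  r2 <- detect_regions(pb_spectrum(gen$sequence))
  expect_identical(r1, r2)
  set_a <- detect_regions_set(c(foo = gen$sequence))
  set_b <- detect_regions_set(c(bar = gen$sequence))
  expect_identical(set_a[-1], set_b[-1])
})

test_that("coverage_fraction and length_histogram follow their definitions", {
  regions <- data.frame(s = c(101, 401), e = c(200, 450),
                        length = c(100, 50))
  expect_equal(coverage_fraction(regions, 1000), 0.15)
  expect_equal(coverage_fraction(regions[0, ], 1000), 0)
  bad <- data.frame(s = c(1, 50), e = c(60, 80))
  expect_error(coverage_fraction(bad, 100), "overlap")
  h <- length_histogram(data.frame(length = c(7, 7, 9)))
  expect_equal(as.integer(h[c("7", "9")]), c(2L, 1L))
  expect_length(length_histogram(data.frame(length = numeric(0))), 0)
})

test_that("coverage of planted tracts matches the planted total", {
  tr <- data.frame(seq = c(strrep("C", 12), strrep("T", 10)),
                   pos = c(80, 200))
  gen <- plant_regular(300, tr, seed = 24)
  reg <- detect_regions(pb_spectrum(gen$sequence))
  cov <- coverage_fraction(reg, 300)
  planted <- (12 + 10 + 4) / 300  # tracts plus one boundary site each side
  expect_equal(cov, planted, tolerance = 0.35)
})

test_that("region_catalog ranks, counts and annotates per definition", {
  recs <- setNames(c(rep("AACCCCCAAATT", 4), rep("AAGGGGTTTTAA", 6)),
                   paste0("p", 1:10))
  regions <- data.frame(promoter_id = "p1", s = 2, e = 8, length = 7,
                        n_support = 5, binary = "WSSSSSW",
                        quaternary = "ACCCCCA")
  cat0 <- region_catalog(regions, recs)
  expect_equal(cat0$n_promoters, 4)
  expect_equal(cat0$promoter_pct, 0.4)
  expect_equal(cat0$mean_copies, 1)
  expect_true(is.na(cat0$pct_in_transposon))
  # 3 of 4 occurrences inside annotated repeats
  rpt <- data.frame(promoter_id = paste0("p", 1:3), start = 1, end = 12,
                    family = "AluY", strand = "+", name = "AluY")
  cat1 <- region_catalog(regions, recs, repeats = rpt)
  expect_equal(cat1$pct_in_transposon, 0.75)
})

test_that("forward/reverse planted clusters have reverse-complement motifs", {
  el <- "CTAATTTTTGTATTTTTAG"
  fwd_recs <- setNames(vapply(1:4, function(i)
    plant_regular(260, data.frame(seq = el, pos = 60 + 30 * i),
                  seed = 400 + i)$sequence, ""), paste0("f", 1:4))
  rev_recs <- setNames(vapply(1:4, function(i)
    plant_regular(260, data.frame(seq = reverse_complement(el),
                                  pos = 60 + 30 * i),
                  seed = 500 + i)$sequence, ""), paste0("r", 1:4))
  cat_f <- region_catalog(detect_regions_set(fwd_recs), fwd_recs)
  cat_r <- region_catalog(detect_regions_set(rev_recs), rev_recs)
  expect_identical(cat_f$sequence[1], el)
  expect_identical(cat_r$sequence[1], reverse_complement(el))
  expect_equal(cat_f$mean_copies[1], 1)
  expect_equal(cat_f$promoter_pct[1], 1)
})
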