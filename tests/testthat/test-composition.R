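test_that("expand_degenerate enumerates IUPAC consensi exactly", {
  tata <- expand_degenerate("HWHWWWWR")
  expect_length(tata, 576)
  expect_false(anyDuplicated(tata) > 0)
  expect_identical(expand_degenerate("ACGT"), "ACGT")
  expect_length(expand_degenerate("NN"), 16)
  expect_error(expand_degenerate("AXC"), "unknown IUPAC")
})

test_that("expansion cardinality equals the product of code cardinalities", {
  card <- c(A = 1, C = 1, G = 1, T = 1, R = 2, Y = 2, S = 2, W = 2, K = 2,
            M = 2, B = 3, D = 3, H = 3, V = 3, N = 4)
  set.seed(3)
  for (i in 1:10) {
    cons <- paste(sample(names(card), sample(1:5, 1), replace = TRUE),
                  collapse = "")
    got <- expand_degenerate(cons)
    expect_length(got, prod(card[strsplit(cons, "")[[1]]]))
    # every member matches the consensus position-wise (regex oracle)
    rex <- paste0("^", gsub("([RYSWKMBDHVN])", "", cons), "")
    iupac <- list(R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                  K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                  H = "[ACT]", V = "[ACG]", N = "[ACGT]")
    pat <- paste0("^", paste(vapply(strsplit(cons, "")[[1]], function(ch)
      if (ch %in% names(iupac)) iupac[[ch]] else ch, ""), collapse = ""), "$")
    expect_true(all(grepl(pat, got)))
  }
})

test_that("tata_catalog applies the 44-member exclusion list", {
  excl <- system.file("extdata", "tata_exclusions_synthetic.txt",
                      package = "promspec")
  cat <- tata_catalog(exclusions = excl)
  expect_length(cat$expanded, 576)
  expect_length(cat$excluded, 44)
  expect_length(cat$active, 532)
  expect_warning(tata_catalog(exclusions = "GGGGGGGG"), "not in the expanded")
})

test_that("scan_tata labels by in-window exact match only", {
  cat <- tata_catalog()   # no exclusions
  # 60-mer, window [-40,-19] = sites 21..42 for the match start;
  # all-G background cannot combine with the insert into extra matches
  bg <- strrep("G", 60)
  put <- function(s, at, word) {
    v <- strsplit(s, "")[[1]]
    v[at:(at + nchar(word) - 1)] <- strsplit(word, "")[[1]]
    paste(v, collapse = "")
  }
  hit <- put(bg, 30, "TATAAAAG")
  res <- scan_tata(hit, cat)
  expect_identical(res$label, "TATA")
  expect_identical(res$positions, site_to_pos(30L, 60L))
  expect_identical(scan_tata(bg, cat)$label, "TATA-less")
  expect_identical(scan_tata(strrep("C", 60), cat)$label, "TATA-less")
  out_of_window <- put(bg, 50, "TATAAAAG")
  expect_identical(scan_tata(out_of_window, cat)$label, "TATA-less")
  expect_error(scan_tata("ACGT", cat), "window")
})

test_that("scan_tata ignores content outside the search window", {
  cat <- tata_catalog()
  set.seed(11)
  core <- strsplit(rand_dna(60), "")[[1]]
  lab0 <- scan_tata(paste(core, collapse = ""), cat)$label
  for (i in 1:5) {
    v <- core
    # mutate only sites outside [21, 49] (window starts plus match width)
    idx <- c(1:20, 50:60)
    v[idx] <- strsplit(rand_dna(length(idx)), "")[[1]]
    expect_identical(scan_tata(paste(v, collapse = ""), cat)$label, lab0)
  }
})

test_that("base_composition matches degenerate and symmetric cases", {
  b <- base_composition(setNames(rep("ACGT", 10), paste0("p", 1:10)))
  expect_equal(b$A, c(1, 0, 0, 0))
  expect_equal(b$T, c(0, 0, 0, 1))
  expect_equal(b$position, -4:-1)
  b2 <- base_composition(c(x = "AA", y = "TT"))
  expect_equal(b2$A, c(0.5, 0.5))
  expect_equal(b2$T, c(0.5, 0.5))
  expect_error(base_composition(character(0)), "empty")
})

test_that("base_composition of iid-uniform sequences is 1/4 within 3 SE", {
  set.seed(4)
  n <- 400
  recs <- setNames(vapply(1:n, function(i) rand_dna(30), ""),
                   paste0("p", 1:n))
  b <- base_composition(recs)
  # 120 simultaneous binomial checks: use a 4.5 SE bound so the joint
  # false-alarm probability stays ~1e-4, and 3 SE at the single position -1
  se <- sqrt(0.25 * 0.75 / n)
  devs <- abs(as.matrix(b[, c("A", "C", "G", "T")]) - 0.25)
  expect_true(all(devs < 4.5 * se))
  expect_true(all(devs[b$position == -1, ] < 3 * se))
  expect_equal(unname(rowSums(b[, c("A", "C", "G", "T")])), rep(1, nrow(b)))
})

test_that("dinucleotide_profile counts overlapping occurrences", {
  d <- dinucleotide_profile(c(x = "CGCGCG"), "CG", window_width = 11)
  expect_equal(d$CG, rep(3 / 5, 6))  # window clips to the whole sequence
  d0 <- dinucleotide_profile(c(x = strrep("A", 20)), "CG", window_width = 5)
  expect_true(all(d0$CG == 0))
  expect_error(dinucleotide_profile(c(x = "ACGT"), "CGT"), "length 2")
})

test_that("dinucleotide density of iid-uniform sequences is about 1/16", {
  set.seed(5)
  recs <- setNames(vapply(1:200, function(i) rand_dna(40), ""),
                   paste0("p", 1:200))
  d <- dinucleotide_profile(recs, c("CG", "AT"), window_width = 41)
  expect_true(all(abs(colMeans(d[, c("CG", "AT")]) - 1 / 16) < 0.01))
})
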