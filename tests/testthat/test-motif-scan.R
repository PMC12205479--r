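test_that("log-odds scores follow the closed forms", {
  uni <- pwm_motif("uni", matrix(0.25, 4, 5), pseudocount = 0)
  expect_true(all(abs(log_odds(uni)) < 1e-12))
  hard <- pwm_motif("A1", matrix(c(1, 0, 0, 0), 4, 1), pseudocount = 0.01)
  # prob 1 pre-pseudocount for A against uniform background
  expect_equal(unname(log_odds(hard)["A", 1]), log(4 * (0.99 + 0.01 / 4)),
               tolerance = 1e-12)
  # reverse complement: reversed, base-swapped matrix
  m <- random_pwm(6, seed = 3)
  rc <- reverse_complement_pwm(m)
  expect_equal(unname(log_odds(rc)),
               unname(log_odds(m)[4:1, 6:1]), tolerance = 1e-12)
})

test_that("score p-values match exhaustive enumeration", {
  # packaged consensus motifs as 0/1-style PWMs: lattice-valued scores,
  # agreement must be exact at every achievable score (ties count as >=)
  for (pat in nitrate_motifs()[c("NLP7", "DREB26", "ANAC032",
                                 "ARF_TGTCTC")]) {
    pw <- iupac_to_pwm(pat)
    sc <- enum_scores(pw)
    for (t in sc[round(seq(1, length(sc), length.out = 6))]) {
      expect_equal(score_pvalue(pw, t), enum_pvalue(pw, t),
                   tolerance = 1e-8)
    }
  }
  # smooth random matrices at tail thresholds (the scanning regime)
  for (k in c(5, 7)) {
    pw <- random_pwm(k, seed = k)
    sc <- enum_scores(pw)
    for (t in sc[c(2, 8, 40)]) {
      expect_equal(score_pvalue(pw, t), enum_pvalue(pw, t),
                   tolerance = 1e-8)
    }
  }
})

test_that("score p-value edge cases and monotonicity hold", {
  pw <- iupac_to_pwm("TGTCTCTC")
  lo <- log_odds(pw)
  expect_equal(score_pvalue(pw, sum(apply(lo, 2, max))), 4^-8,
               tolerance = 1e-10)
  expect_equal(score_pvalue(pw, sum(apply(lo, 2, max)) + 1), 0)
  expect_equal(score_pvalue(pw, sum(apply(lo, 2, min))), 1)
  pn <- iupac_to_pwm("TGNCYYTT")
  lon <- log_odds(pn)
  expect_equal(score_pvalue(pn, sum(apply(lon, 2, max))), 16 / 4^8,
               tolerance = 1e-10)
  ts <- seq(sum(apply(lo, 2, min)), sum(apply(lo, 2, max)), length.out = 9)
  ps <- vapply(ts, function(t) score_pvalue(pw, t), numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("scanning recovers planted, reverse-complement and IUPAC sites", {
  sp <- synth_spec(seed = 5, seq_length = 3000,
                   planted_motifs = data.frame(motif = "TGTCTC",
                                               position = -500,
                                               strand = "+"))
  g <- gen_promoter(sp)
  h <- scan_sequence(g$region, iupac_pattern("ARF", "TGTCTC"))
  planted <- h[h$start == -500 & h$strand == "+", ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$end, -494)

  # GAGACA on the forward strand is a minus-strand TGTCTC hit
  h2 <- scan_sequence("AAAGAGACAAAA", iupac_pattern("ARF", "TGTCTC"))
  expect_equal(h2$strand, "-")
  expect_equal(h2$start, 3)

  # IUPAC semantics: N matches anything, Y matches C/T
  h3 <- scan_sequence("TGACTCTT", iupac_pattern("NLP7", "TGNCYYTT"))
  expect_true(any(h3$start == 0 & h3$strand == "+"))

  # motif longer than region: empty, not an error
  expect_equal(nrow(scan_sequence("ACGT", iupac_pattern("NLP7",
                                                        "TGNCYYTT"))), 0)
})

test_that("windows containing N are skipped", {
  pw <- read_pwm_table(nrc_fixture("synthetic_arf_like_pwm"))
  # every length-8 window of this sequence crosses the central N
  h <- scan_sequence("TGTCGGNCTTTT", pw, p_cutoff = 1)
  expect_equal(nrow(h), 0)
  h2 <- scan_sequence("TNTCTC", iupac_pattern("ARF", "TGTCTC"))
  expect_equal(nrow(h2), 0)
})

test_that("a sequence and its reverse complement give mirror hit sets", {
  sp <- synth_spec(seed = 9, seq_length = 2000)
  g <- gen_promoter(sp)
  seqs <- c(g$region$sequence, revcomp_chr(g$region$sequence))
  pw <- read_pwm_table(nrc_fixture("synthetic_arf_like_pwm"))
  for (motif in list(pw, iupac_pattern("ARF", "TGTCNN"))) {
    hf <- scan_sequence(seqs[1], motif,
                        p_cutoff = if (inherits(motif, "pwm_motif"))
                          1e-3 else 1)
    hr <- scan_sequence(seqs[2], motif,
                        p_cutoff = if (inherits(motif, "pwm_motif"))
                          1e-3 else 1)
    L <- nchar(seqs[1])
    k <- motif$length
    # a + hit at s maps to a - hit at L - s - k on the reverse complement
    key_f <- sort(paste(ifelse(hf$strand == "+", "-", "+"),
                        L - hf$start - k))
    key_r <- sort(paste(hr$strand, hr$start))
    expect_identical(key_f, key_r)
  }
})

test_that("Benjamini-Hochberg adjustment follows the step-up formula", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 0)), "p-values")
})

test_that("the paired-TGTCNN rule uses a strict gap bound on neighbours", {
  mkhits <- function(starts) {
    data.frame(gene_id = "g", motif = "ARF_TGTCNN", kind = "iupac",
               start = starts, end = starts + 6, strand = "+",
               score = 1, p_value = 0.01, q_value = NA,
               chrom = NA, abs_start = starts, abs_end = starts + 6,
               stringsAsFactors = FALSE)
  }
  expect_equal(nrow(find_arf_pairs(mkhits(c(0, 16)))), 1)   # gap 10
  expect_equal(find_arf_pairs(mkhits(c(0, 16)))$gap, 10)
  expect_equal(nrow(find_arf_pairs(mkhits(c(0, 20)))), 0)   # gap 14, strict
  # three hits each within gap of the next: adjacent pairing only
  expect_equal(nrow(find_arf_pairs(mkhits(c(0, 10, 20)))), 2)
  expect_error(find_arf_pairs(rbind(mkhits(0),
                                    transform(mkhits(20), gene_id = "h"))),
               "single region")
})

test_that("candidate-site calling retains planted sites with flags", {
  sp <- synth_spec(seed = 21, seq_length = 3000,
                   planted_motifs = data.frame(
                     motif = c("TGTCTC", "TGTCAA", "TGACTCTT"),
                     position = c(-500, -484, -200),
                     strand = c("+", "+", "+")),
                   peak_coverage = 1)
  g <- gen_promoter(sp)
  res <- call_candidate_sites(list(g$region), nitrate_motifs(),
                              peaks = g$peaks)
  arf <- res$hits[res$hits$motif == "ARF_TGTCTC" & res$hits$start == -500, ]
  expect_equal(nrow(arf), 1)
  expect_true(arf$in_open_chromatin)
  nlp <- res$hits[res$hits$motif == "NLP7" & res$hits$start == -200, ]
  expect_equal(nrow(nlp), 1)
  # the two planted TGTCNN sites 10 bp apart come back as a composite pair
  expect_true(any(res$arf_pairs$start1 == -500 &
                  res$arf_pairs$start2 == -484 & res$arf_pairs$gap == 10))
  # sites outside peaks are not flagged
  sp0 <- synth_spec(seed = 21, seq_length = 3000,
                    planted_motifs = sp$planted_motifs, peak_coverage = 0)
  g0 <- gen_promoter(sp0)
  res0 <- call_candidate_sites(list(g0$region), nitrate_motifs(),
                               peaks = g0$peaks)
  expect_false(any(res0$hits$in_open_chromatin))
})

test_that("PWM hits above the p-value cutoff are absent from the output", {
  pw <- read_pwm_table(nrc_fixture("synthetic_arf_like_pwm"))
  sp <- synth_spec(seed = 33, seq_length = 5000)
  g <- gen_promoter(sp)
  strict <- call_candidate_sites(list(g$region), list(pw), p_cutoff = 1e-4)
  loose <- call_candidate_sites(list(g$region), list(pw), p_cutoff = 1e-2)
  expect_true(all(strict$hits$p_value <= 1e-4))
  expect_gte(nrow(loose$hits), nrow(strict$hits))
})

test_that("MEME and probability-table readers reproduce a motif", {
  pw <- read_pwm_table(nrc_fixture("synthetic_arf_like_pwm"),
                       name = "synthARF")
  expect_s3_class(pw, "pwm_motif")
  expect_equal(pw$length, 8)
  meme <- c("MEME version 4", "", "ALPHABET= ACGT", "",
            "Background letter frequencies",
            "A 0.30 C 0.20 G 0.20 T 0.30", "",
            "MOTIF synth_test", "letter-probability matrix: alength= 4 w= 3",
            " 0.90 0.05 0.03 0.02", " 0.10 0.60 0.20 0.10",
            " 0.25 0.25 0.25 0.25")
  path <- withr::local_tempfile(fileext = ".meme")
  writeLines(meme, path)
  got <- read_meme(path, pseudocount = 0)[["synth_test"]]
  expect_equal(got$length, 3)
  expect_equal(unname(got$probs["A", 1]), 0.90)
  expect_equal(unname(got$background), c(0.3, 0.2, 0.2, 0.3))
})
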