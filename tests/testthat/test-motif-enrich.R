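test_that("degenerate motif counting is overlap-aware and N-safe", {
  expect_equal(count_motif("GGAGG", "GGNGG"), 1L)
  expect_equal(count_motif("GGGGGGG", "GGNGG"), 3L)   # starts 0, 1, 2
  expect_equal(count_motif("ACGTACGT", "GGNGG"), 0L)
  expect_equal(count_motif("GGG", "GGNGG"), 0L)       # motif longer than seq
  expect_equal(count_motif("GGNGG", "GGNGG"), 0L)     # N in sequence matches nothing
  # GGCGGTGGAGG: hits at starts 0 (GGCGG), 3 (GGTGG) and 6 (GGAGG)
  expect_equal(count_motif(c("GGAGG", "GGCGGTGGAGG"), "GGNGG"), c(1L, 3L))
})

test_that("motif counting agrees with a brute-force scanner on random cases", {
  set.seed(101)
  motifs <- c("GGNGG", "GGNGGNGG", "CNCCNNCNCC", "CGNCGNCG", "RYN")
  for (i in 1:300) {
    s <- rand_dna(sample(10:60, 1))
    m <- sample(motifs, 1)
    expect_equal(count_motif(s, m), bf_count_motif(s, m), label = paste(s, m))
  }
  # a GC-rich alphabet to exercise frequent hits
  for (i in 1:100) {
    s <- paste(sample(c("G", "C"), 40, replace = TRUE), collapse = "")
    expect_equal(count_motif(s, "GGNGG"), bf_count_motif(s, "GGNGG"))
  }
})

test_that("an overlapping-motif containment inequality holds", {
  set.seed(7)
  for (i in 1:50) {
    s <- paste(sample(c("G", "A"), 60, replace = TRUE), collapse = "")
    n_long <- count_motif(s, "GGNGGNGG")
    # each disjoint GGNGGNGG instance carries two GGNGG hits
    expect_gte(count_motif(s, "GGNGG"), 2 * floor(n_long / 2))
  }
})

test_that("density and enrichment arithmetic", {
  expect_equal(density_per_kb(5, 1000), 5)
  expect_equal(density_per_kb(0, 1000), 0)
  expect_equal(density_per_kb(3, 700), 3 / 700 * 1000)
  expect_equal(enrichment_ratio(1, 1), 1)
  expect_error(enrichment_ratio(1, 0), "background")
  # density of a concatenation is the length-weighted mean of part densities
  s1 <- "GGAGGAAAAA"; s2 <- "GGAGGGGAGGAAAAAAAAAA"
  d1 <- density_per_kb(count_motif(s1, "GGNGG"), nchar(s1))
  d2 <- density_per_kb(count_motif(s2, "GGNGG"), nchar(s2))
  dcat <- density_per_kb(count_motif(s1, "GGNGG") + count_motif(s2, "GGNGG"),
                         nchar(s1) + nchar(s2))
  expect_equal(dcat, (d1 * nchar(s1) + d2 * nchar(s2)) / (nchar(s1) + nchar(s2)))
})

test_that("chi-squared test matches the textbook statistic", {
  eq <- chisq_motif_test(10, 1010, 100, 10100)  # equal proportions
  expect_equal(eq$chi2_stat, 0)
  expect_equal(eq$p_value, 1)
  t1 <- chisq_motif_test(20, 1000, 10, 10000)
  expect_equal(t1$chi2_stat,
               bf_chisq(matrix(c(20, 980, 10, 9990), 2, byrow = TRUE)),
               tolerance = 1e-12)
  expect_equal(t1$p_value, stats::pchisq(t1$chi2_stat, 1, lower.tail = FALSE))
  # doubling every cell doubles the statistic and shrinks p
  t2 <- chisq_motif_test(40, 2000, 20, 20000)
  expect_equal(t2$chi2_stat, 2 * t1$chi2_stat, tolerance = 1e-12)
  expect_lt(t2$p_value, t1$p_value)
  # degenerate table
  d <- chisq_motif_test(0, 1000, 0, 10000)
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)
  expect_error(chisq_motif_test(5, 4, 0, 10), "exceeds")
})

test_that("a stratum identical to its background is unenriched", {
  set.seed(21)
  rg <- data.frame(event_id = paste0("e", 1:20), event_type = "RI",
                   region_label = "RI_ASE", chrom = "chr1", strand = "+",
                   start = (0:19) * 300L, end = (0:19) * 300L + 200L,
                   clipped = FALSE,
                   sequence = replicate(20, rand_dna(200)),
                   stringsAsFactors = FALSE)
  strata <- data.frame(event_id = rg$event_id, stratum = "dpsi_pos",
                       stringsAsFactors = FALSE)
  mt <- motif_enrichment_table(rg, strata,
                               data.frame(name = "GGNGG", pattern = "GGNGG"))
  pos <- mt[mt$stratum == "dpsi_pos", ]
  expect_equal(pos$enrichment, 1)
  expect_gt(pos$p_value, 0.9)
  # empty stratum is flagged, not tested
  neg <- mt[mt$stratum == "dpsi_neg", ]
  expect_true(neg$degenerate)
  # absent motif: zero density everywhere
  mt2 <- motif_enrichment_table(rg, strata,
                                data.frame(name = "x",
                                           pattern = "CGNCGNCGNCGNCGNCG"))
  expect_true(all(mt2$count == 0))
})

test_that("positional profiles normalize per offset", {
  p <- positional_profile("AAAAAAAGGAGGAAA", 0,
                          data.frame(name = "GGNGG", pattern = "GGNGG"))
  expect_equal(p$offset, 7)
  expect_equal(p$fraction, 1)
  # two motifs, one occurrence each at the same anchored offset
  mots <- data.frame(name = c("m1", "m2"), pattern = c("GGAGG", "GGNGG"))
  p2 <- positional_profile("AAGGAGGAA", 2, mots)
  expect_equal(p2$offset, c(0, 0))
  expect_equal(p2$fraction, c(0.5, 0.5))
  # fractions at every populated offset sum to one
  set.seed(3)
  seqs <- replicate(10, paste(sample(c("G", "A", "C"), 50, TRUE), collapse = ""))
  p3 <- positional_profile(seqs, rep(10, 10), sr45_motifs())
  if (nrow(p3)) {
    sums <- as.vector(tapply(p3$fraction, p3$offset, sum))
    expect_equal(sums, rep(1, length(sums)))
  }
})

test_that("k-mer over-representation ranks planted k-mers first", {
  set.seed(12)
  bg <- replicate(60, rand_dna(80))
  test <- vapply(replicate(40, rand_dna(80)), function(s) {
    # plant GGAGGA at three positions per sequence (~20x background rate)
    for (pos in c(5, 35, 65)) substr(s, pos, pos + 5) <- "GGAGGA"
    s
  }, "")
  tab <- kmer_overrepresentation(test, bg, 6)
  expect_equal(tab$kmer[1], "GGAGGA")
  expect_lt(tab$p_value[1], 1e-10)
  # test == background: no k-mer looks enriched
  tab0 <- kmer_overrepresentation(bg, bg, 6)
  expect_true(all(tab0$p_value >= 0.5 - 1e-12))
  # k-mer absent from background gets the pseudocount rate, finite p
  tabp <- kmer_overrepresentation("AAAAAA", c("CCCCCC", "GGGGGG"), 6)
  expect_true(all(is.finite(tabp$p_value)) && all(tabp$p_value > 0))
})

test_that("W-box scan reports presence and a binomial tail oracle", {
  bgf <- c(TTTGAC = 1e-4, TTGACC = 1e-4, TTGACT = 1e-4)
  ws <- wbox_scan(c(g1 = "AATTGACCAA", g2 = "AAAAAAAAAA"),
                  background_freqs = bgf)
  expect_true(ws$presence["g1", "TTGACC"])
  expect_false(any(unlist(ws$presence["g2", ])))
  # 100 genes, one exact TTTGAC each, 500 nt upstream windows
  set.seed(8)
  ups <- vapply(1:100, function(i) {
    s <- gsub("TTTGAC|TTGACC|TTGACT", "AAAAAA", rand_dna(500))
    substr(s, 200, 205) <- "TTTGAC"
    s
  }, "")
  names(ups) <- paste0("g", 1:100)
  ws2 <- wbox_scan(ups, background_freqs = bgf)
  row <- ws2$tests[ws2$tests$motif == "TTTGAC", ]
  npos <- 100 * (500 - 6 + 1)
  expect_equal(row$count, 100)
  expect_equal(row$p_value,
               stats::pbinom(99, npos, 1e-4, lower.tail = FALSE))
  # a sequence shorter than the motif simply scores absent
  ws3 <- wbox_scan(c(g = "TTT"), background_freqs = bgf)
  expect_false(any(unlist(ws3$presence)))
})
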