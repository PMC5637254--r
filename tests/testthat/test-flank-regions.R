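bounds <- function(gene_id = "g1", start = 0, end = 10000) {
  data.frame(gene_id = gene_id, chrom = "chr1", strand = "+",
             start = start, end = end, stringsAsFactors = FALSE)
}

region_map <- function(rg) {
  stats::setNames(lapply(seq_len(nrow(rg)),
                         function(i) c(rg$start[i], rg$end[i])),
                  rg$region_label)
}

test_that("retained-intron windows match hand-computed coordinates", {
  ev <- toy_catalogue("RI", "chr1", "+", c(ri_start = 1000, ri_end = 1100))
  rg <- extract_flank_regions(ev, bounds(), window = 50)
  m <- region_map(rg)
  expect_equal(m$RI_UE, c(950, 1000))
  expect_equal(m$RI_ASE, c(1000, 1100))
  expect_equal(m$RI_DE, c(1100, 1150))
  expect_false(any(rg$clipped))
  # minus strand: upstream exon flips to the genomic right
  evm <- toy_catalogue("RI", "chr1", "-", c(ri_start = 1000, ri_end = 1100))
  mm <- region_map(extract_flank_regions(evm, bounds(), window = 50))
  expect_equal(mm$RI_UE, c(1100, 1150))
  expect_equal(mm$RI_ASE, c(1000, 1100))
  expect_equal(mm$RI_DE, c(950, 1000))
})

test_that("alternative 5' site windows match hand-computed coordinates", {
  ev <- toy_catalogue("A5", "chr1", "+",
                      c(alt_a = 500, alt_b = 560, shared = 800))
  m <- region_map(extract_flank_regions(ev, bounds(), window = 50))
  expect_equal(m$A5_UE, c(450, 500))
  expect_equal(m$A5_ASE, c(500, 560))
  expect_equal(m$A5_DI5, c(560, 610))
  expect_equal(m$A5_DI3, c(750, 800))
  expect_equal(m$A5_DE, c(800, 850))

  # mirrored through L = 1300: minus-strand intervals are the reflection
  L <- 1300
  evm <- toy_catalogue("A5", "chr1", "-",
                       c(shared = L - 800, alt_a = L - 560, alt_b = L - 500))
  mm <- region_map(extract_flank_regions(evm, bounds(), window = 50))
  refl <- function(iv) c(L - iv[2], L - iv[1])
  for (lab in c("UE", "ASE", "DI5", "DI3", "DE"))
    expect_equal(mm[[paste0("A5_", lab)]], refl(m[[paste0("A5_", lab)]]),
                 label = lab)
})

test_that("alternative 3' site windows sit on the correct intron/exon sides", {
  ev <- toy_catalogue("A3", "chr1", "+",
                      c(shared = 300, alt_a = 500, alt_b = 560))
  m <- region_map(extract_flank_regions(ev, bounds(), window = 50))
  expect_equal(m$A3_UE, c(250, 300))   # exon side of the shared 5'ss
  expect_equal(m$A3_UI5, c(300, 350))  # first 50 nt of the intron
  expect_equal(m$A3_UI3, c(450, 500))  # last 50 nt before the proximal 3'ss
  expect_equal(m$A3_ASE, c(500, 560))
  expect_equal(m$A3_DE, c(560, 610))
})

test_that("skipped-exon windows cover all seven region classes", {
  ev <- toy_catalogue("SE", "chr1", "+",
                      c(i1_start = 1000, i1_end = 1200,
                        i2_start = 1260, i2_end = 1500))
  m <- region_map(extract_flank_regions(ev, bounds(), window = 50))
  expect_equal(m$SE_UE, c(950, 1000))
  expect_equal(m$SE_UI5, c(1000, 1050))
  expect_equal(m$SE_UI3, c(1150, 1200))
  expect_equal(m$SE_ASE, c(1200, 1260))
  expect_equal(m$SE_DI5, c(1260, 1310))
  expect_equal(m$SE_DI3, c(1450, 1500))
  expect_equal(m$SE_DE, c(1500, 1550))
})

test_that("short introns split their end windows at the midpoint", {
  # A3 with a 60 nt intron between the shared 5'ss and the proximal 3'ss
  ev <- toy_catalogue("A3", "chr1", "+",
                      c(shared = 300, alt_a = 360, alt_b = 420))
  m <- region_map(extract_flank_regions(ev, bounds(), window = 50))
  expect_equal(m$A3_UI5, c(300, 330))
  expect_equal(m$A3_UI3, c(330, 360))
  # no nucleotide shared between the two windows
  expect_equal(m$A3_UI5[2], m$A3_UI3[1])
})

test_that("windows clip at gene bounds and are flagged", {
  ev <- toy_catalogue("RI", "chr1", "+", c(ri_start = 30, ri_end = 130))
  rg <- extract_flank_regions(ev, bounds(start = 0, end = 200), window = 50)
  m <- region_map(rg)
  expect_equal(m$RI_UE, c(0, 30))
  expect_true(rg$clipped[rg$region_label == "RI_UE"])
  expect_false(rg$clipped[rg$region_label == "RI_ASE"])
  # anchors outside the gene span are an error
  expect_error(extract_flank_regions(ev, bounds(start = 50, end = 200)),
               "bounds")
})

test_that("sequences come back in sense orientation, uppercase", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "acgtaacc"))
  rg <- data.frame(event_id = "e", event_type = "RI",
                   region_label = "RI_ASE", chrom = "chr1",
                   strand = c("+", "-"), start = 0L, end = 4L,
                   clipped = FALSE, stringsAsFactors = FALSE)
  out <- fetch_sequences(rg, genome)
  expect_equal(out$sequence, c("ACGT", "ACGT"))  # ACGT is its own revcomp
  rg$start <- 4L; rg$end <- 8L
  out2 <- fetch_sequences(rg, genome)
  expect_equal(out2$sequence, c("AACC", "GGTT"))
  # involution on random sequences
  set.seed(1)
  s <- replicate(20, rand_dna(30))
  expect_equal(spliceflank:::revcomp(spliceflank:::revcomp(s)), s)
  # beyond chromosome end
  rg$end <- 9L
  expect_error(fetch_sequences(rg, genome), "beyond")
})

test_that("BED output is 0-based half-open with composite names", {
  rg <- data.frame(event_id = "ev1", event_type = "RI",
                   region_label = "RI_UE", chrom = "chr1", strand = "+",
                   start = 950L, end = 1000L, clipped = FALSE,
                   stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".bed")
  write_bed(rg, path)
  expect_equal(readLines(path), "chr1\t950\t1000\tev1|RI_UE\t0\t+")
  write_bed(rg[0, ], path)
  expect_equal(length(readLines(path)), 0L)
  # duplicated regions from merged events collapse before statistics
  expect_equal(nrow(dedupe_regions(rbind(rg, rg))), 1L)
})
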