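test_that("GTF coordinates convert to 0-based half-open with strand preserved", {
  gtf <- write_toy_gtf(c(
    gtf_exon("chr1", 101, 200, "+", "g1", "g1.t1"),
    gtf_exon("chr1", 1, 100, "+", "g2", "g2.t1"),
    gtf_exon("chr1", 201, 300, "+", "g2", "g2.t1"),
    gtf_exon("chr1", 1, 100, "-", "g3", "g3.t1"),
    gtf_exon("chr1", 201, 300, "-", "g3", "g3.t1")))
  tx <- parse_gtf(gtf)
  expect_equal(unname(tx[["g1.t1"]]$exons), cbind(100L, 200L),
               ignore_attr = TRUE)
  expect_equal(unname(tx[["g2.t1"]]$exons[, 1]), c(0L, 200L))
  expect_equal(unname(tx[["g2.t1"]]$exons[, 2]), c(100L, 300L))
  # minus strand: identical genomic intervals, strand flag only
  expect_equal(tx[["g3.t1"]]$exons, tx[["g2.t1"]]$exons)
  expect_equal(tx[["g3.t1"]]$strand, "-")
  expect_equal(unname(tx_introns <- spliceflank:::tx_introns(tx[["g2.t1"]])),
               cbind(100L, 200L), ignore_attr = TRUE)
})

test_that("malformed GTF lines are reported by line number", {
  gtf <- write_toy_gtf(c(gtf_exon("chr1", 1, 100, "+", "g1", "g1.t1"),
                         "chr1 exon broken line"))
  expect_error(parse_gtf(gtf), "line 2")
})

test_that("each event class is found with correct anchors and inclusion side", {
  # retained intron: single-exon isoform retains the intron
  ri <- build_events(make_models(
    make_tx("A", "g1", "chr1", "+", rbind(c(0, 100), c(200, 300))),
    make_tx("B", "g1", "chr1", "+", rbind(c(0, 300)))))
  expect_equal(nrow(ri), 1L)
  expect_equal(ri$event_type, "RI")
  expect_equal(ri$anchors[[1]], c(ri_start = 100, ri_end = 200))
  expect_equal(ri$inclusion_tx[[1]], "B")
  expect_equal(ri$exclusion_tx[[1]], "A")

  # alternative 5' splice sites sharing the intron 3' end at 200
  a5 <- build_events(make_models(
    make_tx("A", "g1", "chr1", "+", rbind(c(0, 100), c(200, 300))),
    make_tx("B", "g1", "chr1", "+", rbind(c(0, 140), c(200, 300)))))
  expect_equal(a5$event_type, "A5")
  expect_equal(a5$anchors[[1]], c(alt_a = 100, alt_b = 140, shared = 200))
  expect_equal(a5$inclusion_tx[[1]], "B")   # exon extends to the proximal site

  # same structure on the minus strand is an alternative 3' site event
  a3 <- build_events(make_models(
    make_tx("A", "g1", "chr1", "-", rbind(c(0, 100), c(200, 300))),
    make_tx("B", "g1", "chr1", "-", rbind(c(0, 140), c(200, 300)))))
  expect_equal(a3$event_type, "A3")

  # skipped exon with identical flanking splice sites
  se <- build_events(make_models(
    make_tx("A", "g1", "chr1", "+",
            rbind(c(0, 100), c(150, 200), c(260, 360))),
    make_tx("B", "g1", "chr1", "+", rbind(c(0, 100), c(260, 360)))))
  expect_equal(se$event_type, "SE")
  expect_equal(se$anchors[[1]],
               c(i1_start = 100, i1_end = 150, i2_start = 200, i2_end = 260))
  expect_equal(se$inclusion_tx[[1]], "A")

  # a skipped-exon pair must not additionally produce alt-site events
  expect_equal(nrow(se), 1L)

  # single-isoform gene yields nothing
  none <- build_events(make_models(
    make_tx("A", "g1", "chr1", "+", rbind(c(0, 100), c(200, 300)))))
  expect_equal(nrow(none), 0L)
})

test_that("construction is order-independent and merges duplicate events", {
  txs <- list(
    make_tx("A", "g1", "chr1", "+", rbind(c(0, 100), c(200, 300))),
    make_tx("B", "g1", "chr1", "+", rbind(c(0, 300))),
    make_tx("C", "g1", "chr1", "+", rbind(c(0, 320))))  # same retention
  ev1 <- build_events(do.call(make_models, txs))
  ev2 <- build_events(do.call(make_models, rev(txs)))
  expect_identical(ev1, ev2)
  expect_equal(nrow(ev1), 1L)
  expect_setequal(ev1$inclusion_tx[[1]], c("B", "C"))
})

test_that("catalogue round-trips through the TSV dialect", {
  ev <- build_events(make_models(
    make_tx("A", "g1", "chr1", "+",
            rbind(c(0, 100), c(150, 200), c(260, 360))),
    make_tx("B", "g1", "chr1", "+", rbind(c(0, 100), c(260, 360))),
    make_tx("C", "g2", "chr2", "-", rbind(c(10, 110), c(210, 310))),
    make_tx("D", "g2", "chr2", "-", rbind(c(10, 310)))))
  path <- tempfile(fileext = ".tsv")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(back$event_id, ev$event_id)
  expect_equal(back$anchors, ev$anchors)
  expect_equal(back$inclusion_tx, ev$inclusion_tx)
  expect_equal(back$exclusion_tx, ev$exclusion_tx)

  # empty catalogue -> header-only file, reads back empty
  empty <- build_events(make_models(
    make_tx("A", "g1", "chr1", "+", rbind(c(0, 100)))))
  write_events(empty, path)
  expect_equal(nrow(read_events(path)), 0L)

  # unknown event type token
  tab <- read_tsv_strict <- utils::read.table(path, sep = "\t", header = TRUE)
  writeLines(c("event_id\tgene_id\tevent_type\tchrom\tstrand\tanchors\tinclusion_tx\texclusion_tx",
               "e1\tg1\tXX\tchr1\t+\tri_start=1;ri_end=2\ta\tb"), path)
  expect_error(read_events(path), "XX")
})

test_that("reflecting the annotation reflects every event (strand symmetry)", {
  cfg <- sim_config(seed = 11, events_per_type = c(A3 = 4, A5 = 4, RI = 4, SE = 4))
  sim <- make_genome_annotation(cfg)
  ev <- build_events(sim$transcripts)
  L <- nchar(sim$genome[[1]])
  mev <- build_events(mirror_models(sim$transcripts, L))
  expect_equal(nrow(mev), nrow(ev))
  expect_equal(table(mev$event_type), table(ev$event_type))
  # each mirrored event's anchor set is the reflection of an original one
  key <- function(e) vapply(seq_len(nrow(e)), function(i)
    paste(e$event_type[i], paste(sort(unname(e$anchors[[i]])), collapse = "-")),
    "")
  mkey <- vapply(seq_len(nrow(mev)), function(i)
    paste(mev$event_type[i],
          paste(sort(L - unname(mev$anchors[[i]])), collapse = "-")), "")
  expect_setequal(mkey, key(ev))
})

test_that("generator truth table matches the built catalogue exactly", {
  cfg <- sim_config(seed = 4, events_per_type = c(A3 = 5, A5 = 5, RI = 5, SE = 5))
  sim <- make_genome_annotation(cfg)
  gtf <- tempfile(fileext = ".gtf")
  write_gtf(sim$transcripts, gtf)
  ev <- build_events(parse_gtf(gtf))
  expect_identical(sort(ev$event_id), sort(sim$truth$event_id))
  expect_equal(as.vector(table(ev$event_type)[c("A3", "A5", "RI", "SE")]),
               rep(5L, 4))
  # inclusion sides agree with the planted truth
  m <- merge(as.data.frame(ev[, c("event_id", "gene_id")]),
             sim$truth[, c("event_id", "inclusion_tx")], by = "event_id")
  built_inc <- ev$inclusion_tx[match(m$event_id, ev$event_id)]
  expect_true(all(mapply(function(b, t) t %in% b, built_inc, m$inclusion_tx)))
})
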