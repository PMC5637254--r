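.IUPAC <- c(A = "A", C = "C", G = "G", T = "T", N = "[ACGT]",
            R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]",
            M = "[AC]", B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]")

# Translate an IUPAC-degenerate pattern into a base regular expression in
# which N (and other ambiguity codes) expand to explicit base classes, so an
# N in the *scanned sequence* never matches anything.
motif_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1L]]
  .assert(all(chars %in% names(.IUPAC)),
          "pattern %s contains non-IUPAC characters", pattern)
  paste(.IUPAC[chars], collapse = "")
}

#' Count (overlapping) occurrences of a degenerate motif
#'
#' Counts every start position at which the motif matches, overlapping
#' occurrences included (the only self-consistent convention for periodic
#' degenerate motifs such as GGNGGNGG). `N` in the motif matches any base;
#' `N` in the sequence matches nothing.
#'
#' @param sequence Character vector of A/C/G/T/N sequences.
#' @param pattern IUPAC-degenerate motif string (length >= 2).
#' @return Integer vector of occurrence counts (0 when the motif is longer
#'   than the sequence).
#' @export
count_motif <- function(sequence, pattern) {
  .assert(nchar(pattern) >= 2, "motif must have length >= 2")
  rx <- sprintf("(?=%s)", motif_regex(pattern))
  vapply(toupper(sequence), function(s) {
    m <- gregexpr(rx, s, perl = TRUE)[[1L]]
    if (m[1L] == -1L) 0L else length(m)
  }, 0L, USE.NAMES = FALSE)
}

#' Start offsets of motif occurrences (0-based)
#'
#' @inheritParams count_motif
#' @return List of integer vectors of 0-based start offsets, one per
#'   sequence.
#' @export
motif_positions <- function(sequence, pattern) {
  rx <- sprintf("(?=%s)", motif_regex(pattern))
  lapply(toupper(sequence), function(s) {
    m <- gregexpr(rx, s, perl = TRUE)[[1L]]
    if (m[1L] == -1L) integer() else as.integer(m) - 1L
  })
}

#' Motif density per kilobase
#'
#' @param total_count Occurrence count.
#' @param total_length Scanned nucleotides (> 0).
#' @return count / length x 1000.
#' @export
density_per_kb <- function(total_count, total_length) {
  .assert(all(total_length > 0), "total_length must be > 0")
  total_count / total_length * 1000
}

#' Enrichment ratio of two densities
#'
#' @param test_density,background_density Densities (background > 0).
#' @return test / background.
#' @export
enrichment_ratio <- function(test_density, background_density) {
  .assert(all(background_density > 0), "background density must be > 0")
  test_density / background_density
}

#' Chi-squared test of motif enrichment
#'
#' Pearson chi-squared (1 df, no continuity correction) on the 2x2 table of
#' motif hits vs non-hit scan positions in the test and background region
#' sets. Degenerate tables (a zero row or column) return stat 0, p 1,
#' flagged.
#'
#' @param test_count,test_scan_positions Hits and scannable start positions
#'   in the test set.
#' @param bg_count,bg_scan_positions Same for the background set.
#' @return list(chi2_stat, p_value, degenerate).
#' @export
chisq_motif_test <- function(test_count, test_scan_positions,
                             bg_count, bg_scan_positions) {
  .assert(test_count <= test_scan_positions && bg_count <= bg_scan_positions,
          "count exceeds scan positions")
  tab <- matrix(c(test_count, test_scan_positions - test_count,
                  bg_count, bg_scan_positions - bg_count),
                nrow = 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(chi2_stat = 0, p_value = 1, degenerate = TRUE))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2_stat = unname(ct$statistic), p_value = unname(ct$p.value),
       degenerate = FALSE)
}

#' The degenerate motifs examined around splicing events
#'
#' The fixed purine/pyrimidine-rich patterns quantified around events
#' (GGNGG and its extensions plus the pyrimidine counterparts).
#'
#' @return data.frame with columns `name`, `pattern`.
#' @export
sr45_motifs <- function() {
  data.frame(
    name = c("GGNNNNGGNGG", "GGNGGNGG", "GGNGG",
             "CNNCNNCNNCNNC", "CNCCNNCNCC", "CGNCGNCG"),
    pattern = c("GGNNNNGGNGG", "GGNGGNGG", "GGNGG",
                "CNNCNNCNNCNNC", "CNCCNNCNCC", "CGNCGNCG"),
    stringsAsFactors = FALSE)
}

#' Read a motif table (`name<TAB>pattern`, no header)
#'
#' @param path File path.
#' @return data.frame `name`, `pattern`.
#' @export
read_motifs <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("name", "pattern"))
  df
}

# Aggregate counts / lengths / scan positions of a motif over sequences.
.motif_totals <- function(seqs, pattern) {
  m <- nchar(pattern)
  lens <- nchar(seqs)
  list(count = sum(count_motif(seqs, pattern)),
       total_length = sum(lens),
       scan_positions = sum(pmax(lens - m + 1L, 0L)))
}

#' Motif enrichment over region classes, stratified by delta-psi sign
#'
#' For every motif x event type x region label x stratum (dpsi > 0,
#' dpsi < 0), computes density per kb in the stratum's regions, the
#' background density over the *same region class across all events of the
#' catalogue* (the control set), the density enrichment ratio, and a
#' chi-squared test on scan positions. Regions are deduplicated on
#' (chrom, interval, strand, label) first.
#'
#' @param regions Region data.frame with sequences, covering all events
#'   (the background); see [extract_flank_regions()], [fetch_sequences()].
#' @param event_strata data.frame with columns `event_id`, `stratum`
#'   (`"dpsi_pos"` / `"dpsi_neg"`) for the significant events; see
#'   [sas_strata()].
#' @param motifs data.frame `name`, `pattern` (default [sr45_motifs()]).
#' @return data.frame, one row per combination: counts, lengths, densities,
#'   `enrichment`, `chi2_stat`, `p_value`, `degenerate`.
#' @export
motif_enrichment_table <- function(regions, event_strata,
                                   motifs = sr45_motifs()) {
  .assert("sequence" %in% names(regions), "regions lack sequences")
  regions <- dedupe_regions(regions)
  strata <- c("dpsi_pos", "dpsi_neg")
  combos <- unique(regions[, c("event_type", "region_label")])
  rows <- list()
  for (mi in seq_len(nrow(motifs))) {
    pat <- motifs$pattern[mi]
    for (ci in seq_len(nrow(combos))) {
      et <- combos$event_type[ci]; rl <- combos$region_label[ci]
      bgr <- regions[regions$event_type == et & regions$region_label == rl, ]
      bg <- .motif_totals(bgr$sequence, pat)
      for (st in strata) {
        ids <- event_strata$event_id[event_strata$stratum == st]
        tr <- bgr[bgr$event_id %in% ids, , drop = FALSE]
        empty <- nrow(tr) == 0L
        tt <- if (empty) list(count = 0L, total_length = 0L,
                              scan_positions = 0L)
              else .motif_totals(tr$sequence, pat)
        dens <- if (tt$total_length > 0) tt$count / tt$total_length * 1000 else NA_real_
        bdens <- if (bg$total_length > 0) bg$count / bg$total_length * 1000 else NA_real_
        enr <- if (!is.na(dens) && !is.na(bdens) && bdens > 0) dens / bdens else NA_real_
        test <- if (empty || tt$scan_positions == 0L)
          list(chi2_stat = NA_real_, p_value = NA_real_, degenerate = TRUE)
        else chisq_motif_test(tt$count, tt$scan_positions,
                              bg$count, bg$scan_positions)
        rows[[length(rows) + 1L]] <- data.frame(
          motif = motifs$name[mi], event_type = et, region_label = rl,
          stratum = st, n_regions = nrow(tr), count = tt$count,
          total_length = tt$total_length,
          scan_positions = tt$scan_positions,
          density_per_kb = dens, bg_count = bg$count,
          bg_total_length = bg$total_length,
          bg_scan_positions = bg$scan_positions,
          background_density_per_kb = bdens, enrichment = enr,
          chi2_stat = test$chi2_stat, p_value = test$p_value,
          degenerate = test$degenerate, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Delta-psi sign strata of called events
#'
#' @param sas A `sas_result` (see [call_sas()]).
#' @return data.frame `event_id`, `stratum` for called events with non-zero
#'   delta-psi.
#' @export
sas_strata <- function(sas) {
  s <- sas[sas$is_sas & !is.na(sas$delta_psi) & sas$delta_psi != 0, ]
  data.frame(event_id = s$event_id,
             stratum = ifelse(s$delta_psi > 0, "dpsi_pos", "dpsi_neg"),
             stringsAsFactors = FALSE)
}

#' Positional profile of motif occurrences around an anchor
#'
#' For sequences sharing an anchor coordinate, tabulates per offset the
#' fraction of all profiled-motif occurrence starts contributed by each
#' motif (fractions at an occupied offset sum to 1).
#'
#' @param sequences Character vector.
#' @param anchors Integer vector, 0-based anchor offset within each
#'   sequence (occurrence offset = start - anchor).
#' @param motifs data.frame `name`, `pattern`.
#' @return data.frame `offset`, `motif`, `count`, `fraction`.
#' @export
positional_profile <- function(sequences, anchors, motifs = sr45_motifs()) {
  .assert(length(anchors) == length(sequences),
          "one anchor offset per sequence required")
  recs <- list()
  for (mi in seq_len(nrow(motifs))) {
    pos <- motif_positions(sequences, motifs$pattern[mi])
    offs <- unlist(Map(function(p, a) p - a, pos, as.list(anchors)))
    if (length(offs))
      recs[[length(recs) + 1L]] <-
        data.frame(offset = offs, motif = motifs$name[mi],
                   stringsAsFactors = FALSE)
  }
  if (length(recs) == 0L)
    return(data.frame(offset = integer(), motif = character(),
                      count = integer(), fraction = numeric()))
  d <- do.call(rbind, recs)
  agg <- stats::aggregate(list(count = rep(1L, nrow(d))),
                          by = d[, c("offset", "motif")], FUN = sum)
  tot <- stats::aggregate(list(total = agg$count),
                          by = agg["offset"], FUN = sum)
  agg <- merge(agg, tot, by = "offset")
  agg$fraction <- agg$count / agg$total
  agg$total <- NULL
  agg[order(agg$offset, agg$motif), ]
}

#' Exhaustive k-mer over-representation of a test set vs background
#'
#' A simple declared stand-in for de novo motif discovery: every k-mer
#' observed in the test sequences is scored by a one-sided binomial tail on
#' its test count, with per-position success probability equal to its
#' background match frequency (+1 pseudocount on background counts for
#' k-mers unseen in the background).
#'
#' @param test_seqs,background_seqs Character vectors.
#' @param k K-mer length.
#' @return data.frame `kmer`, `test_count`, `test_density`, `bg_count`,
#'   `bg_density` (per kb), `p_value`, sorted by p then kmer.
#' @export
kmer_overrepresentation <- function(test_seqs, background_seqs, k) {
  if (length(test_seqs) == 0L || length(background_seqs) == 0L)
    return(data.frame(kmer = character(), test_count = integer(),
                      test_density = numeric(), bg_count = integer(),
                      bg_density = numeric(), p_value = numeric()))
  .assert(k <= min(nchar(c(test_seqs, background_seqs))),
          "k exceeds the shortest sequence")
  count_kmers <- function(seqs) {
    kms <- unlist(lapply(toupper(seqs), function(s) {
      n <- nchar(s) - k + 1L
      if (n < 1L) return(character())
      substring(s, seq_len(n), seq_len(n) + k - 1L)
    }))
    kms <- kms[!grepl("[^ACGT]", kms)]
    table(kms)
  }
  tc <- count_kmers(test_seqs); bc <- count_kmers(background_seqs)
  tpos <- sum(pmax(nchar(test_seqs) - k + 1L, 0L))
  bpos <- sum(pmax(nchar(background_seqs) - k + 1L, 0L))
  tlen <- sum(nchar(test_seqs)); blen <- sum(nchar(background_seqs))
  kmers <- names(tc)
  bcount <- as.integer(bc[kmers]); bcount[is.na(bcount)] <- 0L
  rate <- pmax(bcount, 1L) / bpos   # +1 pseudocount for unseen k-mers
  p <- stats::pbinom(as.integer(tc) - 1L, tpos, rate, lower.tail = FALSE)
  out <- data.frame(kmer = kmers, test_count = as.integer(tc),
                    test_density = as.integer(tc) / tlen * 1000,
                    bg_count = bcount, bg_density = bcount / blen * 1000,
                    p_value = p, stringsAsFactors = FALSE)
  out[order(out$p_value, out$kmer), ]
}

#' W-box promoter scan
#'
#' Scans upstream (promoter-side) sense sequences for exact W-box core
#' occurrences, reporting per-gene presence and, per motif, the total
#' occurrence count across the gene set with a one-sided binomial tail
#' p-value against the supplied genome-background per-position frequency.
#'
#' @param upstream_seqs Named character vector, one upstream sequence per
#'   gene (conventionally the 500 nt upstream of the annotated gene start).
#' @param wbox_motifs Exact motifs to scan (defaults to the W-box cores).
#' @param background_freqs Named numeric, per-position background match
#'   frequency for each motif.
#' @return list `presence` (gene x motif logical data.frame) and `tests`
#'   (data.frame `motif`, `count`, `scan_positions`, `p_value`).
#' @export
wbox_scan <- function(upstream_seqs,
                      wbox_motifs = c("TTTGAC", "TTGACC", "TTGACT"),
                      background_freqs) {
  .assert(!is.null(names(upstream_seqs)), "upstream_seqs must be named by gene")
  .assert(all(wbox_motifs %in% names(background_freqs)),
          "background frequency missing for motif(s): %s",
          paste(setdiff(wbox_motifs, names(background_freqs)), collapse = ", "))
  counts <- vapply(wbox_motifs, function(m) count_motif(upstream_seqs, m),
                   integer(length(upstream_seqs)))
  counts <- matrix(counts, nrow = length(upstream_seqs),
                   dimnames = list(names(upstream_seqs), wbox_motifs))
  presence <- as.data.frame(counts > 0L)
  tests <- do.call(rbind, lapply(wbox_motifs, function(m) {
    npos <- sum(pmax(nchar(upstream_seqs) - nchar(m) + 1L, 0L))
    cnt <- sum(counts[, m])
    data.frame(motif = m, count = cnt, scan_positions = npos,
               p_value = stats::pbinom(cnt - 1L, npos, background_freqs[[m]],
                                       lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  list(presence = presence, tests = tests)
}
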