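# Independent brute-force oracles and small fixture builders.

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   N = c("A", "C", "G", "T"),
                   R = c("A", "G"), Y = c("C", "T"))

# Position-by-position motif scan, overlapping occurrences counted.
bf_count_motif <- function(seq, pattern) {
  s <- strsplit(toupper(seq), "")[[1L]]
  p <- strsplit(toupper(pattern), "")[[1L]]
  m <- length(p); L <- length(s)
  if (L < m) return(0L)
  hits <- 0L
  for (i in seq_len(L - m + 1L)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!(s[i + j - 1L] %in% IUPAC_SETS[[p[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- hits + 1L
  }
  hits
}

# Textbook Pearson chi-squared on a 2x2 table of counts.
bf_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Hypergeometric upper tail P(X >= k) by direct summation.
bf_hyper_tail <- function(k, K, U, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(U - K, n - i)) / choose(U, n)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Hand-built transcript model container.
make_tx <- function(transcript_id, gene_id, chrom, strand, exons) {
  list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
       strand = strand,
       exons = cbind(start = as.integer(exons[, 1L]),
                     end = as.integer(exons[, 2L])))
}

make_models <- function(...) {
  txs <- list(...)
  names(txs) <- vapply(txs, `[[`, "", "transcript_id")
  structure(txs, class = "transcript_models")
}

# One-row event catalogue built directly from its fields.
toy_catalogue <- function(event_type, chrom, strand, anchors,
                          gene_id = "g1", inclusion = "t1",
                          exclusion = "t2") {
  out <- data.frame(
    event_id = sprintf("%s;%s:%s:%s:%s", gene_id, event_type, chrom,
                       paste(anchors[order(anchors)], collapse = "-"), strand),
    gene_id = gene_id, event_type = event_type, chrom = chrom,
    strand = strand, stringsAsFactors = FALSE)
  out$anchors <- list(anchors)
  out$inclusion_tx <- list(inclusion)
  out$exclusion_tx <- list(exclusion)
  class(out) <- c("event_catalogue", "data.frame")
  out
}

# Two-isoform quant table: one inclusion and one exclusion transcript.
toy_quant <- function(inc_tpm, exc_tpm, samples = NULL) {
  samples <- samples %||% paste0("s", seq_along(inc_tpm))
  q <- data.frame(transcript_id = c("t1", "t2"), stringsAsFactors = FALSE)
  for (i in seq_along(samples)) q[[samples[i]]] <- c(inc_tpm[i], exc_tpm[i])
  q
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mirror a transcript set through genomic coordinate L (reflection with
# strand flip) — the reverse-complement-symmetry oracle.
mirror_models <- function(txs, L) {
  out <- lapply(unclass(txs), function(t) {
    ex <- cbind(start = L - t$exons[, 2L], end = L - t$exons[, 1L])
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    t$exons <- ex
    t$strand <- if (t$strand == "+") "-" else "+"
    t
  })
  structure(out, class = "transcript_models")
}

write_toy_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_exon <- function(chrom, start1, end1, strand, gene, tx) {
  sprintf("%s\tsrc\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
          chrom, start1, end1, strand, gene, tx)
}
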