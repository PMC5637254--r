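#' Build an alternative-splicing event catalogue from transcript models
#'
#' Events are generated pairwise from same-gene transcripts that differ by
#' exactly one local splicing structure, then deduplicated on
#' (type, chrom, strand, anchor coordinates) with transcript sets unioned:
#' \describe{
#'   \item{RI}{retained intron: one transcript splices an intron that lies
#'     strictly inside an exon of the other.}
#'   \item{SE}{skipped exon: one transcript skips an internal exon the other
#'     includes, with identical flanking splice sites.}
#'   \item{A5/A3}{alternative 5'/3' splice site: two introns sharing one
#'     boundary and differing at the other, the shorter-intron transcript's
#'     exon covering the span between the two alternative sites.}
#' }
#' The inclusion form is fixed so that a positive delta-psi means more
#' inclusion of the alternative sequence in the perturbed condition: RI -
#' intron-retaining transcripts; SE - exon-including transcripts; A5/A3 - the
#' shorter-intron transcripts (whose exon extends closest to the opposite
#' splice site).
#'
#' @param transcripts A `transcript_models` object (see [parse_gtf()]).
#' @return An `event_catalogue`: a data.frame with columns `event_id`,
#'   `gene_id`, `event_type`, `chrom`, `strand`, plus list-columns `anchors`
#'   (named numeric genomic boundary coordinates, 0-based), `inclusion_tx`
#'   and `exclusion_tx` (character vectors). Single-isoform genes contribute
#'   no events.
#' @export
build_events <- function(transcripts) {
  .assert(length(transcripts) >= 1L, "no transcripts supplied")
  gid <- vapply(transcripts, `[[`, "", "gene_id")
  acc <- new.env(parent = emptyenv())
  for (txs in split(unname(transcripts), gid)) {
    if (length(txs) < 2L) next
    n <- length(txs)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      .pair_events(txs[[i]], txs[[j]], acc)
      .pair_events(txs[[j]], txs[[i]], acc)
    }
  }
  evs <- as.list(acc)
  if (length(evs) == 0L) {
    out <- data.frame(event_id = character(), gene_id = character(),
                      event_type = character(), chrom = character(),
                      strand = character(), stringsAsFactors = FALSE)
    out$anchors <- list(); out$inclusion_tx <- list(); out$exclusion_tx <- list()
    class(out) <- c("event_catalogue", "data.frame")
    return(out)
  }
  evs <- lapply(evs, function(e) {
    both <- intersect(e$inclusion_tx, e$exclusion_tx)
    if (length(both)) {
      warning(sprintf("event %s: transcripts on both sides dropped: %s",
                      e$event_id, paste(both, collapse = ",")))
      e$inclusion_tx <- setdiff(e$inclusion_tx, both)
      e$exclusion_tx <- setdiff(e$exclusion_tx, both)
    }
    e$inclusion_tx <- sort(unique(e$inclusion_tx))
    e$exclusion_tx <- sort(unique(e$exclusion_tx))
    e
  })
  keep <- vapply(evs, function(e)
    length(e$inclusion_tx) > 0L && length(e$exclusion_tx) > 0L, NA)
  evs <- evs[keep]
  out <- data.frame(
    event_id = vapply(evs, `[[`, "", "event_id"),
    gene_id = vapply(evs, `[[`, "", "gene_id"),
    event_type = vapply(evs, `[[`, "", "event_type"),
    chrom = vapply(evs, `[[`, "", "chrom"),
    strand = vapply(evs, `[[`, "", "strand"),
    stringsAsFactors = FALSE)
  out$anchors <- unname(lapply(evs, `[[`, "anchors"))
  out$inclusion_tx <- unname(lapply(evs, `[[`, "inclusion_tx"))
  out$exclusion_tx <- unname(lapply(evs, `[[`, "exclusion_tx"))
  out <- out[order(out$event_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("event_catalogue", "data.frame")
  out
}

# Emit events where t1 is the "spliced/long" side; called for both orders.
.pair_events <- function(t1, t2, acc) {
  in1 <- tx_introns(t1); in2 <- tx_introns(t2)
  if (nrow(in1) == 0L) return(invisible())
  for (k in seq_len(nrow(in1))) {
    s <- unname(in1[k, 1L]); e <- unname(in1[k, 2L])
    # RI: t2 has an exon strictly containing t1's intron [s, e)
    ri <- which(t2$exons[, 1L] < s & t2$exons[, 2L] > e)
    if (length(ri))
      .add_event(acc, t1, "RI", c(ri_start = s, ri_end = e),
                 inclusion = t2$transcript_id, exclusion = t1$transcript_id)
    if (nrow(in2)) {
      # SE: t2 has adjacent introns [s, c) and [d, e) around an internal exon
      if (nrow(in2) >= 2L) {
        for (m in seq_len(nrow(in2) - 1L)) {
          if (in2[m, 1L] == s && in2[m + 1L, 2L] == e &&
              in2[m, 2L] < in2[m + 1L, 1L]) {
            .add_event(acc, t1, "SE",
                       c(i1_start = s, i1_end = unname(in2[m, 2L]),
                         i2_start = unname(in2[m + 1L, 1L]), i2_end = e),
                       inclusion = t2$transcript_id,
                       exclusion = t1$transcript_id)
          }
        }
      }
      # Alternative splice sites: introns sharing one boundary.
      for (m in seq_len(nrow(in2))) {
        s2 <- unname(in2[m, 1L]); e2 <- unname(in2[m, 2L])
        if (e2 == e && s2 > s) {
          # t2's intron is shorter at the genomic-left boundary; its exon
          # must cover the span [s, s2) between the alternative sites.
          exl <- which(t2$exons[, 2L] == s2)
          if (length(exl) && any(t2$exons[exl, 1L] <= s)) {
            type <- if (t1$strand == "+") "A5" else "A3"
            .add_event(acc, t1, type, c(alt_a = s, alt_b = s2, shared = e),
                       inclusion = t2$transcript_id,
                       exclusion = t1$transcript_id)
          }
        }
        if (s2 == s && e2 < e) {
          exr <- which(t2$exons[, 1L] == e2)
          if (length(exr) && any(t2$exons[exr, 2L] >= e)) {
            type <- if (t1$strand == "+") "A3" else "A5"
            .add_event(acc, t1, type, c(shared = s, alt_a = e2, alt_b = e),
                       inclusion = t2$transcript_id,
                       exclusion = t1$transcript_id)
          }
        }
      }
    }
  }
  invisible()
}

.add_event <- function(acc, tx, type, anchors, inclusion, exclusion) {
  id <- sprintf("%s;%s:%s:%s:%s", tx$gene_id, type, tx$chrom,
                paste(anchors[order(anchors)], collapse = "-"), tx$strand)
  if (is.null(acc[[id]])) {
    acc[[id]] <- list(event_id = id, gene_id = tx$gene_id, event_type = type,
                      chrom = tx$chrom, strand = tx$strand, anchors = anchors,
                      inclusion_tx = inclusion, exclusion_tx = exclusion)
  } else {
    acc[[id]]$inclusion_tx <- c(acc[[id]]$inclusion_tx, inclusion)
    acc[[id]]$exclusion_tx <- c(acc[[id]]$exclusion_tx, exclusion)
  }
  invisible()
}

#' @export
print.event_catalogue <- function(x, ...) {
  cat(sprintf("event_catalogue: %d events (%s)\n", nrow(x),
              paste(sprintf("%s=%d", names(table(x$event_type)),
                            as.integer(table(x$event_type))), collapse = ", ")))
  invisible(x)
}

.EVENT_TYPES <- c("A3", "A5", "RI", "SE")

#' Write / read an event catalogue as TSV
#'
#' Round-trip stable dialect: anchors as semicolon-separated `name=pos`
#' pairs, transcript sets comma-separated.
#'
#' @param events An `event_catalogue`.
#' @param path Output (input) file path.
#' @return `write_events` returns `path` invisibly; `read_events` returns an
#'   `event_catalogue`.
#' @export
write_events <- function(events, path) {
  df <- data.frame(
    event_id = events$event_id, gene_id = events$gene_id,
    event_type = events$event_type, chrom = events$chrom,
    strand = events$strand,
    anchors = vapply(events$anchors, function(a)
      paste(sprintf("%s=%d", names(a), as.integer(a)), collapse = ";"), ""),
    inclusion_tx = vapply(events$inclusion_tx, paste, "", collapse = ","),
    exclusion_tx = vapply(events$exclusion_tx, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  write_tsv_strict(df, path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- read_tsv_strict(path, colClasses = "character")
  bad <- setdiff(unique(df$event_type), .EVENT_TYPES)
  .assert(length(bad) == 0L, "unknown event_type token(s): %s",
          paste(bad, collapse = ", "))
  out <- df[, c("event_id", "gene_id", "event_type", "chrom", "strand")]
  out$anchors <- lapply(df$anchors, function(s) {
    if (!nzchar(s)) return(numeric())
    kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
    stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                    vapply(kv, `[`, "", 1L))
  })
  out$inclusion_tx <- lapply(strsplit(df$inclusion_tx, ",", fixed = TRUE),
                             function(x) x[nzchar(x)])
  out$exclusion_tx <- lapply(strsplit(df$exclusion_tx, ",", fixed = TRUE),
                             function(x) x[nzchar(x)])
  rownames(out) <- NULL
  class(out) <- c("event_catalogue", "data.frame")
  out
}
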