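.REGION_LABELS <- list(
  A5 = c("UE", "ASE", "DI5", "DI3", "DE"),
  A3 = c("UE", "UI5", "UI3", "ASE", "DE"),
  RI = c("UE", "ASE", "DE"),
  SE = c("UE", "UI5", "UI3", "ASE", "DI5", "DI3", "DE"))

#' Extract labeled splice-flanking windows around events
#'
#' For every event, extracts the fixed 50-nt (or event-defined, for ASE)
#' windows around its splice sites, in transcript (5'->3') orientation:
#' upstream/downstream exon windows (UE, DE) abut their splice sites on the
#' exon side; intron-end windows (UI5/DI5 start at, UI3/DI3 end at, their
#' splice sites) lie inside the introns; ASE is the event-defined span
#' (alternative region, retained intron, or skipped exon). Region sets per
#' type: A5 = UE, ASE, DI5, DI3, DE; A3 = UE, UI5, UI3, ASE, DE;
#' RI = UE, ASE, DE; SE = UE, UI5, UI3, ASE, DI5, DI3, DE.
#'
#' When an intron is shorter than twice the window its two end windows are
#' truncated at the intron midpoint so no nucleotide is counted twice;
#' windows are clipped at the annotated gene span (never padded), and any
#' region shorter than its nominal window is marked `clipped`.
#'
#' @param events An `event_catalogue` (or a one-row slice).
#' @param gene_bounds data.frame from [gene_bounds()] (gene_id, start, end).
#' @param window Fixed window width in nucleotides (default 50).
#' @return data.frame with columns `event_id`, `event_type`, `region_label`
#'   (e.g. `"RI_ASE"`), `chrom`, `strand`, `start`, `end` (0-based
#'   half-open), `clipped`.
#' @export
extract_flank_regions <- function(events, gene_bounds, window = 50) {
  .assert(window >= 1, "window must be >= 1")
  gb <- stats::setNames(split(gene_bounds, seq_len(nrow(gene_bounds))),
                        gene_bounds$gene_id)
  rows <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, , drop = FALSE]
    b <- gb[[ev$gene_id]]
    .assert(!is.null(b), "gene %s absent from gene_bounds", ev$gene_id)
    .event_regions(ev, b$start, b$end, window)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Windows in transcript orientation relative to a boundary coordinate p
# (0-based half-open boundary): "up" = the window ending at p on the
# transcript-upstream side, "dn" = the window starting at p downstream.
.win_up <- function(p, w, strand) if (strand == "+") c(p - w, p) else c(p, p + w)
.win_dn <- function(p, w, strand) if (strand == "+") c(p, p + w) else c(p - w, p)

.event_regions <- function(ev, gstart, gend, w) {
  a <- ev$anchors[[1L]]
  st <- ev$strand
  type <- ev$event_type
  .assert(all(a >= gstart & a <= gend),
          "event %s anchors outside gene bounds", ev$event_id)
  plus <- st == "+"
  regs <- list()
  add <- function(label, iv, fixed = TRUE) {
    regs[[length(regs) + 1L]] <<- list(label = label, start = iv[1L],
                                       end = iv[2L], fixed = fixed)
  }
  if (type == "RI") {
    s <- a[["ri_start"]]; e <- a[["ri_end"]]
    add("UE", .win_up(if (plus) s else e, w, st))
    add("ASE", c(s, e), fixed = FALSE)
    add("DE", .win_dn(if (plus) e else s, w, st))
  } else if (type == "A5" || type == "A3") {
    if ("shared" %in% names(a) && which(names(a) == "shared") == 3L) {
      # alternative boundaries genomically left of the shared one
      alt_lo <- a[["alt_a"]]; alt_hi <- a[["alt_b"]]; sh <- a[["shared"]]
      # transcript-upstream alternative site
      up_alt <- if (plus) alt_lo else alt_hi
      dn_alt <- if (plus) alt_hi else alt_lo
      ase <- c(alt_lo, alt_hi)
      short_intron <- c(alt_hi, sh)  # shared boundary on the genomic right
    } else {
      sh <- a[["shared"]]; alt_lo <- a[["alt_a"]]; alt_hi <- a[["alt_b"]]
      up_alt <- if (plus) alt_lo else alt_hi
      dn_alt <- if (plus) alt_hi else alt_lo
      ase <- c(alt_lo, alt_hi)
      short_intron <- c(sh, alt_lo)  # shared boundary on the genomic left
    }
    ilen <- short_intron[2L] - short_intron[1L]
    mid <- short_intron[1L] + ilen %/% 2L
    if (type == "A5") {
      # up_alt/dn_alt are the two alternative 5' sites (dn_alt proximal to
      # the shared 3' site); short intron runs dn_alt -> shared.
      add("UE", .win_up(up_alt, w, st))
      add("ASE", ase, fixed = FALSE)
      di5 <- .win_dn(dn_alt, w, st)
      di3 <- .win_up(sh, w, st)
      if (ilen < 2L * w) {
        if (plus) { di5 <- c(short_intron[1L], mid); di3 <- c(mid, short_intron[2L]) }
        else { di5 <- c(mid, short_intron[2L]); di3 <- c(short_intron[1L], mid) }
      }
      add("DI5", di5); add("DI3", di3)
      add("DE", .win_dn(sh, w, st))
    } else {
      # A3: shared 5' site; up_alt/dn_alt are the alternative 3' sites
      # (up_alt proximal to the shared 5' site); short intron shared -> up_alt.
      add("UE", .win_up(sh, w, st))
      ui5 <- .win_dn(sh, w, st)
      ui3 <- .win_up(up_alt, w, st)
      if (ilen < 2L * w) {
        if (plus) { ui5 <- c(short_intron[1L], mid); ui3 <- c(mid, short_intron[2L]) }
        else { ui5 <- c(mid, short_intron[2L]); ui3 <- c(short_intron[1L], mid) }
      }
      add("UI5", ui5); add("UI3", ui3)
      add("ASE", ase, fixed = FALSE)
      add("DE", .win_dn(dn_alt, w, st))
    }
  } else if (type == "SE") {
    i1 <- c(a[["i1_start"]], a[["i1_end"]])
    i2 <- c(a[["i2_start"]], a[["i2_end"]])
    exon <- c(a[["i1_end"]], a[["i2_start"]])
    ui <- if (plus) i1 else i2   # transcript-upstream intron
    di <- if (plus) i2 else i1
    ui_5 <- .win_dn(if (plus) ui[1L] else ui[2L], w, st)  # first w nt of upstream intron
    ui_3 <- .win_up(if (plus) ui[2L] else ui[1L], w, st)  # last w nt, abuts exon
    if (ui[2L] - ui[1L] < 2L * w) {
      mid <- ui[1L] + (ui[2L] - ui[1L]) %/% 2L
      if (plus) { ui_5 <- c(ui[1L], mid); ui_3 <- c(mid, ui[2L]) }
      else { ui_5 <- c(mid, ui[2L]); ui_3 <- c(ui[1L], mid) }
    }
    di_5 <- .win_dn(if (plus) di[1L] else di[2L], w, st)
    di_3 <- .win_up(if (plus) di[2L] else di[1L], w, st)
    if (di[2L] - di[1L] < 2L * w) {
      mid <- di[1L] + (di[2L] - di[1L]) %/% 2L
      if (plus) { di_5 <- c(di[1L], mid); di_3 <- c(mid, di[2L]) }
      else { di_5 <- c(mid, di[2L]); di_3 <- c(di[1L], mid) }
    }
    add("UE", .win_up(if (plus) ui[1L] else ui[2L], w, st))
    add("UI5", ui_5); add("UI3", ui_3)
    add("ASE", exon, fixed = FALSE)
    add("DI5", di_5); add("DI3", di_3)
    add("DE", .win_dn(if (plus) di[2L] else di[1L], w, st))
  } else stop("unknown event type: ", type)

  df <- do.call(rbind, lapply(regs, function(r) {
    s0 <- max(r$start, gstart); e0 <- min(r$end, gend)
    .assert(e0 > s0, "event %s region %s empty after clipping",
            ev$event_id, r$label)
    clipped <- r$fixed && (e0 - s0) < w
    data.frame(event_id = ev$event_id, event_type = ev$event_type,
               region_label = paste(ev$event_type, r$label, sep = "_"),
               chrom = ev$chrom, strand = ev$strand,
               start = as.integer(s0), end = as.integer(e0),
               clipped = clipped, stringsAsFactors = FALSE)
  }))
  df
}

#' Attach sense-strand sequences to regions
#'
#' @param regions data.frame from [extract_flank_regions()].
#' @param genome A named `DNAStringSet` (one entry per chromosome) or a path
#'   to a FASTA file.
#' @return `regions` with an uppercase `sequence` column, reverse-
#'   complemented for minus-strand regions (sense orientation).
#' @export
fetch_sequences <- function(regions, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  nm <- sub("\\s.*$", "", names(genome))
  names(genome) <- nm
  .assert(all(regions$chrom %in% nm), "chromosome(s) missing from genome: %s",
          paste(setdiff(regions$chrom, nm), collapse = ", "))
  lens <- stats::setNames(Biostrings::width(genome), nm)
  .assert(all(regions$end <= lens[regions$chrom]) && all(regions$start >= 0),
          "region interval beyond chromosome end")
  seqs <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    s <- Biostrings::subseq(genome[[regions$chrom[i]]],
                            start = regions$start[i] + 1L,
                            end = regions$end[i])
    if (regions$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs[i] <- toupper(as.character(s))
  }
  regions$sequence <- seqs
  regions
}

#' Deduplicate regions shared between merged events
#'
#' Regions identical in (chrom, interval, strand, label) are collapsed to
#' one row (first occurrence kept) so that density denominators never count
#' a nucleotide twice.
#'
#' @param regions Region data.frame.
#' @return Deduplicated data.frame.
#' @export
dedupe_regions <- function(regions) {
  key <- with(regions, paste(chrom, start, end, strand, region_label))
  regions[!duplicated(key), , drop = FALSE]
}

#' Write regions as BED6
#'
#' 0-based half-open intervals, name = `event_id|region_label`, score 0.
#'
#' @param regions Region data.frame.
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  if (nrow(regions) == 0L) { file.create(path); return(invisible(path)) }
  lines <- sprintf("%s\t%d\t%d\t%s|%s\t0\t%s", regions$chrom, regions$start,
                   regions$end, regions$event_id, regions$region_label,
                   regions$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write region sequences as FASTA
#'
#' Headers are `event_id|region_label`.
#'
#' @param regions Region data.frame with a `sequence` column.
#' @param path Output path.
#' @export
write_region_fasta <- function(regions, path) {
  .assert("sequence" %in% names(regions), "regions lack sequences")
  ss <- Biostrings::DNAStringSet(regions$sequence)
  names(ss) <- paste(regions$event_id, regions$region_label, sep = "|")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
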