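#' Parse transcript models from a GTF annotation
#'
#' Reads the exon features of a GTF file and assembles one transcript model per
#' transcript. GTF coordinates are 1-based inclusive; internally all intervals
#' are 0-based half-open, with exons sorted in ascending genomic order.
#'
#' @param gtf_path Path to a GTF file whose exon features carry `gene_id` and
#'   `transcript_id` attributes.
#' @return An object of class `transcript_models`: a named list with one
#'   element per transcript, each a list with fields `transcript_id`,
#'   `gene_id`, `chrom`, `strand` (`"+"` or `"-"`) and `exons` (a two-column
#'   integer matrix of 0-based half-open intervals, ascending, columns
#'   `start`/`end`).
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste0("chr1\tsrc\texon\t101\t200\t.\t+\t.\t",
#'                   "gene_id \"g1\"; transcript_id \"g1.t1\";"), gtf)
#' tx <- parse_gtf(gtf)
#' tx[["g1.t1"]]$exons  # [100, 200)
#' @export
parse_gtf <- function(gtf_path) {
  .assert(file.exists(gtf_path), "GTF file not found: %s", gtf_path)
  # Line-level validation so malformed lines are reported by number;
  # rtracklayer then does the actual parsing.
  lines <- readLines(gtf_path, warn = FALSE)
  body <- !grepl("^#", lines) & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 9)) {
    bad <- which(body)[which(nfield < 9)[1L]]
    stop(sprintf("malformed GTF line %d in %s: expected 9 tab-separated fields",
                 bad, gtf_path), call. = FALSE)
  }
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type == "exon", , drop = FALSE]
  .assert(nrow(df) > 0, "no exon features in %s", gtf_path)
  .assert(all(!is.na(df$transcript_id)) && all(!is.na(df$gene_id)),
          "exon feature missing gene_id/transcript_id in %s", gtf_path)
  out <- lapply(split(df, df$transcript_id), function(d) {
    .assert(length(unique(d$seqnames)) == 1L && length(unique(d$strand)) == 1L,
            "transcript %s spans multiple chromosomes or strands",
            d$transcript_id[1L])
    strand <- as.character(d$strand[1L])
    .assert(strand %in% c("+", "-"),
            "transcript %s has no strand", d$transcript_id[1L])
    ex <- cbind(start = as.integer(d$start) - 1L, end = as.integer(d$end))
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    .assert(all(ex[, 2L] > ex[, 1L]),
            "transcript %s has an empty exon", d$transcript_id[1L])
    if (nrow(ex) > 1L)
      .assert(all(ex[-1L, 1L] > ex[-nrow(ex), 2L]),
              "transcript %s has overlapping or adjacent exons",
              d$transcript_id[1L])
    list(transcript_id = d$transcript_id[1L],
         gene_id = d$gene_id[1L],
         chrom = as.character(d$seqnames[1L]),
         strand = strand,
         exons = ex)
  })
  structure(out, class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat(sprintf("transcript_models: %d transcripts, %d genes\n",
              length(x), length(unique(vapply(x, `[[`, "", "gene_id")))))
  invisible(x)
}

# Intron intervals (0-based half-open) of one transcript model.
tx_introns <- function(tx) {
  ex <- tx$exons
  if (nrow(ex) < 2L) return(matrix(integer(), ncol = 2L,
                                   dimnames = list(NULL, c("start", "end"))))
  cbind(start = ex[-nrow(ex), 2L], end = ex[-1L, 1L])
}

#' Genomic span of each gene
#'
#' @param transcripts A `transcript_models` object.
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (0-based half-open union span of all exons of the gene).
#' @export
gene_bounds <- function(transcripts) {
  gid <- vapply(transcripts, `[[`, "", "gene_id")
  res <- lapply(split(unname(transcripts), gid), function(txs) {
    data.frame(gene_id = txs[[1L]]$gene_id, chrom = txs[[1L]]$chrom,
               strand = txs[[1L]]$strand,
               start = min(vapply(txs, function(t) as.numeric(t$exons[1L, 1L]), 0)),
               end = max(vapply(txs, function(t)
                 as.numeric(t$exons[nrow(t$exons), 2L]), 0)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Genes annotated without introns
#'
#' A gene is intronless when every one of its transcripts is a single exon.
#'
#' @param transcripts A `transcript_models` object.
#' @return Character vector of intronless gene ids.
#' @export
intronless_genes <- function(transcripts) {
  gid <- vapply(transcripts, `[[`, "", "gene_id")
  nex <- vapply(transcripts, function(t) nrow(t$exons), 0L)
  mono <- tapply(nex, gid, function(n) all(n == 1L))
  names(mono)[mono]
}
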