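#' Direction-wise differential-expression filter
#'
#' Splits a gene-level table into genes elevated in the mutant
#' (fold change >= `min_fc`, inclusive) and genes reduced in the mutant
#' (fold change <= 1/`min_fc`), both at significance strictly below
#' `max_sig`. Fold changes are mutant/control ratios; in the factor-centric
#' vocabulary, "factor-downregulated" genes are the ones elevated in the
#' mutant and vice versa.
#'
#' @param table data.frame with columns `gene_id`, `fold_change` (> 0),
#'   `significance` (FDR or p, in [0, 1]).
#' @param min_fc Fold-change cutoff (inclusive, default 2).
#' @param max_sig Significance cutoff (strict, default 0.1).
#' @return list(up_in_mutant, down_in_mutant) of gene-id character vectors.
#' @export
filter_de <- function(table, min_fc = 2, max_sig = 0.1) {
  .assert(all(c("gene_id", "fold_change", "significance") %in% names(table)),
          "DE table needs gene_id, fold_change, significance")
  bad <- !is.na(table$fold_change) & table$fold_change <= 0
  if (any(bad)) {
    warning(sprintf("%d row(s) with non-positive fold change rejected", sum(bad)))
    table <- table[!bad, , drop = FALSE]
  }
  ok <- !is.na(table$fold_change) & !is.na(table$significance) &
    table$significance < max_sig
  list(up_in_mutant = sort(unique(table$gene_id[ok & table$fold_change >= min_fc])),
       down_in_mutant = sort(unique(table$gene_id[ok & table$fold_change <= 1 / min_fc])))
}

#' Direction-wise consensus across sources
#'
#' Intersects the up- and down-regulated sets across all sources (e.g.
#' alignment/quantification pipelines).
#'
#' @param set_lists List (length >= 2) of lists with elements
#'   `up_in_mutant`, `down_in_mutant` (as returned by [filter_de()]).
#' @return list(up_common, down_common).
#' @export
consensus <- function(set_lists) {
  .assert(length(set_lists) >= 2L, "need at least 2 sources")
  list(up_common = sort(Reduce(intersect,
                               lapply(set_lists, `[[`, "up_in_mutant"))),
       down_common = sort(Reduce(intersect,
                                 lapply(set_lists, `[[`, "down_in_mutant"))))
}

#' Select immunoprecipitation-enriched transcripts
#'
#' Per quantification method, keeps genes whose IP/control fold change is at
#' least `min_fc` with significance strictly below `max_sig` in *both*
#' transgenic lines (genes missing a line in a method are excluded from that
#' method); the final set is the intersection across methods.
#'
#' @param rip_tables Named list, one data.frame per method with columns
#'   `gene_id`, `line`, `fold_change`, `significance` (long format, one row
#'   per gene x line).
#' @param min_fc Fold-change cutoff (inclusive).
#' @param max_sig Significance cutoff (strict).
#' @return list with `genes` (the intersection), `per_method` (named list of
#'   per-method gene sets) and `provenance` (filter parameters).
#' @export
select_sars <- function(rip_tables, min_fc = 2, max_sig = 0.1) {
  .assert(length(rip_tables) >= 1L, "need at least one RIP table")
  per_method <- lapply(rip_tables, function(tab) {
    .assert(all(c("gene_id", "line", "fold_change", "significance") %in%
                  names(tab)),
            "RIP table needs gene_id, line, fold_change, significance")
    lines <- unique(tab$line)
    pass <- tab[!is.na(tab$fold_change) & !is.na(tab$significance) &
                  tab$fold_change >= min_fc & tab$significance < max_sig, ]
    keep <- tapply(pass$line, pass$gene_id,
                   function(l) all(lines %in% l))
    sort(names(keep)[keep])
  })
  list(genes = sort(Reduce(intersect, per_method)),
       per_method = per_method,
       provenance = list(min_fc = min_fc, max_sig = max_sig,
                         methods = names(rip_tables)))
}

#' Fisher's exact test of overlap between two gene sets
#'
#' Two-sided Fisher's exact test on the 2x2 table
#' \[\[|A&B|, |A\\B|\], \[|B\\A|, |U\\(A|B)|\]\].
#'
#' @param set_a,set_b Gene-id vectors (subsets of `universe`).
#' @param universe Gene-id vector.
#' @return list(odds_ratio, p_value, table).
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  .assert(length(universe) > 0, "empty universe")
  universe <- unique(universe)
  a <- unique(intersect(set_a, universe))
  b <- unique(intersect(set_b, universe))
  .assert(length(setdiff(set_a, universe)) == 0 &&
            length(setdiff(set_b, universe)) == 0,
          "set members outside the universe")
  n_ab <- length(intersect(a, b))
  tab <- matrix(c(n_ab, length(a) - n_ab,
                  length(b) - n_ab,
                  length(universe) - length(union(a, b))),
                nrow = 2L, byrow = TRUE)
  if (length(a) == 0L || length(b) == 0L)
    return(list(odds_ratio = NA_real_, p_value = 1, table = tab))
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}

#' Term enrichment of a gene set (hypergeometric)
#'
#' For every term, reports the actual number of set genes annotated with the
#' term, the expected number |set| x K / |U| (K = term genes in the
#' universe), the fold of enrichment actual/expected, and the hypergeometric
#' upper-tail p-value. Terms with no universe genes are skipped.
#'
#' @param gene_set Gene-id vector (subset of `universe`).
#' @param term_map data.frame with columns `gene_id`, `term`.
#' @param universe Gene-id vector.
#' @return data.frame `term`, `actual`, `term_total`, `expected`, `fold`,
#'   `p_value`, sorted by p.
#' @export
term_enrichment <- function(gene_set, term_map, universe) {
  .assert(all(c("gene_id", "term") %in% names(term_map)),
          "term map needs gene_id, term")
  universe <- unique(universe)
  gene_set <- unique(intersect(gene_set, universe))
  u <- length(universe); n <- length(gene_set)
  tm <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  rows <- lapply(split(tm$gene_id, tm$term), function(genes) {
    genes <- unique(genes)
    K <- length(genes)
    if (K == 0L) return(NULL)
    k <- length(intersect(gene_set, genes))
    expected <- n * K / u
    data.frame(actual = k, term_total = K, expected = expected,
               fold = if (expected > 0) k / expected else NA_real_,
               p_value = stats::phyper(k - 1, K, u - K, n, lower.tail = FALSE))
  })
  keep <- !vapply(rows, is.null, NA)
  out <- do.call(rbind, rows[keep])
  if (is.null(out))
    return(data.frame(term = character(), actual = integer(),
                      term_total = integer(), expected = numeric(),
                      fold = numeric(), p_value = numeric()))
  out <- cbind(data.frame(term = names(rows)[keep], stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  out[order(out$p_value, out$term), ]
}

#' Read / write plain gene-set and table files
#'
#' Gene sets are one id per line; DE tables are TSV with columns `gene_id`,
#' `fold_change`, `significance`; RIP tables additionally have `line`; term
#' maps are TSV `gene_id`, `term`.
#'
#' @param path File path.
#' @return Character vector (`read_gene_set`) or data.frame.
#' @export
read_gene_set <- function(path) {
  x <- readLines(path, warn = FALSE)
  x[nzchar(x)]
}

#' @rdname read_gene_set
#' @param genes Character vector.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' @rdname read_gene_set
#' @export
read_de_table <- function(path) read_tsv_strict(path)

#' @rdname read_gene_set
#' @export
read_rip_table <- function(path) read_tsv_strict(path)

#' @rdname read_gene_set
#' @export
read_term_map <- function(path) read_tsv_strict(path, colClasses = "character")
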