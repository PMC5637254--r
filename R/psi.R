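#' Read an isoform abundance (TPM) table / condition map
#'
#' The quantification table is a TSV with a `transcript_id` column and one
#' numeric column per sample; the condition map is a TSV with columns
#' `sample` and `condition`.
#'
#' @param path File path.
#' @return `read_quant`: data.frame with `transcript_id` plus sample columns.
#'   `read_conditions`: data.frame with `sample`, `condition`.
#' @export
read_quant <- function(path) {
  q <- read_tsv_strict(path)
  .assert("transcript_id" %in% names(q), "quant table lacks transcript_id column")
  num <- setdiff(names(q), "transcript_id")
  for (s in num) {
    q[[s]] <- as.numeric(q[[s]])
    .assert(all(!is.na(q[[s]])) && all(q[[s]] >= 0),
            "sample %s has missing or negative abundances", s)
  }
  q
}

#' @rdname read_quant
#' @export
read_conditions <- function(path) {
  cm <- read_tsv_strict(path, colClasses = "character")
  .assert(all(c("sample", "condition") %in% names(cm)),
          "condition map needs columns sample, condition")
  cm
}

.quant_matrix <- function(quant) {
  m <- as.matrix(quant[, setdiff(names(quant), "transcript_id"), drop = FALSE])
  rownames(m) <- quant$transcript_id
  m
}

.event_tx <- function(event_row) {
  c(event_row$inclusion_tx[[1L]], event_row$exclusion_tx[[1L]])
}

.check_tx_present <- function(txids, qm) {
  missing <- setdiff(txids, rownames(qm))
  .assert(length(missing) == 0L, "transcript(s) absent from quant table: %s",
          paste(missing, collapse = ", "))
}

#' Percent spliced-in of one event in one sample
#'
#' psi = sum TPM(inclusion transcripts) / sum TPM(all event transcripts);
#' `NA` when the event is unexpressed in the sample (denominator zero), since
#' a 0/0 ratio carries no inclusion information.
#'
#' @param event One-row slice of an `event_catalogue`.
#' @param quant Quantification table (see [read_quant()]).
#' @param sample Sample column name.
#' @return psi in [0, 1], or `NA`.
#' @export
compute_psi <- function(event, quant, sample) {
  qm <- .quant_matrix(quant)
  .assert(sample %in% colnames(qm), "sample %s not in quant table", sample)
  inc <- event$inclusion_tx[[1L]]; exc <- event$exclusion_tx[[1L]]
  .check_tx_present(c(inc, exc), qm)
  num <- sum(qm[inc, sample]); den <- num + sum(qm[exc, sample])
  if (den == 0) NA_real_ else num / den
}

#' Total mean TPM of an event
#'
#' Sum over all transcripts involved in the event of their mean TPM across
#' all samples (the abundance filter statistic for SAS calling).
#'
#' @inheritParams compute_psi
#' @return Non-negative scalar.
#' @export
event_total_mean_tpm <- function(event, quant) {
  qm <- .quant_matrix(quant)
  txs <- .event_tx(event)
  .check_tx_present(txs, qm)
  sum(rowMeans(qm[txs, , drop = FALSE]))
}

#' Difference of mean psi between conditions
#'
#' Mean of non-missing per-replicate psi in the mutant condition minus the
#' mean in the control condition.
#'
#' @inheritParams compute_psi
#' @param condition_map data.frame `sample`, `condition`.
#' @param control,mutant Condition labels.
#' @return delta-psi in [-1, 1], or `NA` if a condition has only missing psi.
#' @export
delta_psi <- function(event, quant, condition_map,
                      control = "control", mutant = "mutant") {
  psis <- .event_psis(event, quant, condition_map, control, mutant)
  pc <- psis$control[!is.na(psis$control)]
  pm <- psis$mutant[!is.na(psis$mutant)]
  if (length(pc) == 0L || length(pm) == 0L) return(NA_real_)
  mean(pm) - mean(pc)
}

.event_psis <- function(event, quant, condition_map, control, mutant) {
  qm <- .quant_matrix(quant)
  .assert(all(condition_map$sample %in% colnames(qm)),
          "condition map sample(s) missing from quant table: %s",
          paste(setdiff(condition_map$sample, colnames(qm)), collapse = ", "))
  inc <- event$inclusion_tx[[1L]]; exc <- event$exclusion_tx[[1L]]
  .check_tx_present(c(inc, exc), qm)
  one <- function(s) {
    num <- sum(qm[inc, s]); den <- num + sum(qm[exc, s])
    if (den == 0) NA_real_ else num / den
  }
  sc <- condition_map$sample[condition_map$condition == control]
  sm <- condition_map$sample[condition_map$condition == mutant]
  .assert(length(sc) >= 1L && length(sm) >= 1L,
          "need at least one sample in each of conditions %s and %s",
          control, mutant)
  list(control = stats::setNames(vapply(sc, one, 0), sc),
       mutant = stats::setNames(vapply(sm, one, 0), sm))
}

#' Replicate-label permutation test on |delta-psi|
#'
#' Two-sided test of a difference in mean psi between two replicate groups by
#' permuting replicate labels. When the number of distinct equal-size
#' relabelings `choose(n, n1)` is at most `n_perm` all are enumerated and
#' p = #\{|dpsi*| >= |dpsi_obs|\} / #relabelings (the observed labeling is in
#' the enumeration, so p >= 1/#relabelings); otherwise `n_perm` Monte-Carlo
#' relabelings are drawn under `seed` and p = (1 + #exceed) / (1 + n_perm).
#'
#' Note the granularity floor: with equal group sizes every relabeling has a
#' group-swapped complement with identical |dpsi*|, so the smallest exact p
#' with 3v3 replicates is 2/20 = 0.1 — this test cannot reach p < 0.05 on a
#' 3v3 design (see [call_sas()] for the default small-sample test).
#'
#' @param psi_control,psi_mutant Numeric replicate psi values (NAs dropped).
#' @param n_perm Permutation budget.
#' @param seed RNG seed for Monte-Carlo sampling.
#' @return p-value in (0, 1].
#' @export
permutation_test <- function(psi_control, psi_mutant, n_perm = 10000,
                             seed = 1) {
  pc <- psi_control[!is.na(psi_control)]
  pm <- psi_mutant[!is.na(psi_mutant)]
  if (length(pc) < 2L || length(pm) < 2L) {
    warning("fewer than 2 non-missing replicates in a group; p undefined")
    return(NA_real_)
  }
  x <- c(pc, pm); n <- length(x); n1 <- length(pm)
  obs <- abs(mean(pm) - mean(pc))
  tol <- 1e-12
  stat <- function(idx_m) {
    abs(mean(x[idx_m]) - mean(x[-idx_m]))
  }
  n_relab <- choose(n, n1)
  if (n_relab <= n_perm) {
    idx <- utils::combn(n, n1)
    stats_all <- apply(idx, 2L, stat)
    sum(stats_all >= obs - tol) / n_relab
  } else {
    with_seed(seed, {
      exceed <- sum(vapply(seq_len(n_perm), function(i)
        stat(sample.int(n, n1)) >= obs - tol, NA))
      (1 + exceed) / (1 + n_perm)
    })
  }
}

# Welch t-test on per-replicate psi; falls back to the exact permutation
# test when the statistic is undefined (both groups constant).
.welch_psi_test <- function(pc, pm, n_perm = 10000, seed = 1) {
  pc <- pc[!is.na(pc)]; pm <- pm[!is.na(pm)]
  if (length(pc) < 2L || length(pm) < 2L) return(NA_real_)
  tryCatch(stats::t.test(pm, pc)$p.value,
           error = function(e)   # essentially constant data
             suppressWarnings(permutation_test(pc, pm, n_perm = n_perm,
                                               seed = seed)))
}

#' Per-event psi table with delta-psi, significance and abundance
#'
#' Computes, for every event, per-sample psi, condition means, delta-psi
#' (mutant minus control), a two-group p-value on the replicate psi values,
#' and the event's total mean TPM. [apply_sas_filter()] adds the SAS flag.
#'
#' @inheritParams delta_psi
#' @param events An `event_catalogue`.
#' @param test `"welch"` (default; Welch t-test on per-replicate psi, the
#'   small-sample default since a 3v3 label permutation cannot reach
#'   p < 0.05) or `"permutation"` (see [permutation_test()]).
#' @param n_perm,seed Passed to [permutation_test()].
#' @return data.frame, one row per event: `event_id`, `event_type`,
#'   `gene_id`, `psi_<sample>` columns, `mean_psi_control`,
#'   `mean_psi_mutant`, `delta_psi`, `p_value`, `total_mean_tpm`.
#' @export
psi_event_table <- function(events, quant, condition_map,
                            control = "control", mutant = "mutant",
                            test = c("welch", "permutation"),
                            n_perm = 10000, seed = 1) {
  test <- match.arg(test)
  qm <- .quant_matrix(quant)
  .assert(all(condition_map$sample %in% colnames(qm)),
          "condition map sample(s) missing from quant table: %s",
          paste(setdiff(condition_map$sample, colnames(qm)), collapse = ", "))
  sc <- condition_map$sample[condition_map$condition == control]
  sm <- condition_map$sample[condition_map$condition == mutant]
  .assert(length(sc) >= 1L && length(sm) >= 1L,
          "need >=1 sample per condition (%s, %s)", control, mutant)
  samples <- c(sc, sm)
  rows <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, , drop = FALSE]
    inc <- ev$inclusion_tx[[1L]]; exc <- ev$exclusion_tx[[1L]]
    .check_tx_present(c(inc, exc), qm)
    num <- colSums(qm[inc, samples, drop = FALSE])
    den <- num + colSums(qm[exc, samples, drop = FALSE])
    psi <- ifelse(den == 0, NA_real_, num / den)
    pc <- psi[sc]; pm <- psi[sm]
    mc <- if (all(is.na(pc))) NA_real_ else mean(pc, na.rm = TRUE)
    mm <- if (all(is.na(pm))) NA_real_ else mean(pm, na.rm = TRUE)
    dps <- if (is.na(mc) || is.na(mm)) NA_real_ else mm - mc
    p <- if (sum(!is.na(pc)) < 2L || sum(!is.na(pm)) < 2L) NA_real_
         else if (test == "welch") .welch_psi_test(pc, pm, n_perm, seed)
         else suppressWarnings(permutation_test(pc, pm, n_perm, seed))
    c(psi, mean_psi_control = mc, mean_psi_mutant = mm, delta_psi = dps,
      p_value = p,
      total_mean_tpm = sum(rowMeans(qm[c(inc, exc), , drop = FALSE])))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out)[seq_along(samples)] <- paste0("psi_", samples)
  cbind(data.frame(event_id = events$event_id,
                   event_type = events$event_type,
                   gene_id = events$gene_id, stringsAsFactors = FALSE),
        out)
}

#' Flag significant, abundance-filtered splicing events
#'
#' An event is flagged when its p-value is strictly below `alpha` and its
#' total mean TPM is at least `min_tpm` (inclusive), the selection rule for
#' condition-dependent (SAS) events.
#'
#' @param tab Output of [psi_event_table()].
#' @param alpha Significance cutoff (strict).
#' @param min_tpm Abundance cutoff (inclusive).
#' @return `tab` with a logical `is_sas` column appended.
#' @export
apply_sas_filter <- function(tab, alpha = 0.05, min_tpm = 10) {
  tab$is_sas <- !is.na(tab$p_value) & tab$p_value < alpha &
    tab$total_mean_tpm >= min_tpm
  tab
}

#' Call condition-dependent alternative-splicing (SAS) events
#'
#' Runs [psi_event_table()] then [apply_sas_filter()] and returns a classed
#' result with print/summary/plot methods; the summary partitions called
#' events by event type and the sign of delta-psi.
#'
#' @inheritParams psi_event_table
#' @inheritParams apply_sas_filter
#' @return A `sas_result`: the flagged table with attributes `alpha`,
#'   `min_tpm`, `test`.
#' @export
call_sas <- function(events, quant, condition_map,
                     control = "control", mutant = "mutant",
                     alpha = 0.05, min_tpm = 10,
                     test = c("welch", "permutation"),
                     n_perm = 10000, seed = 1) {
  test <- match.arg(test)
  tab <- psi_event_table(events, quant, condition_map, control, mutant,
                         test = test, n_perm = n_perm, seed = seed)
  tab <- apply_sas_filter(tab, alpha = alpha, min_tpm = min_tpm)
  structure(tab, class = c("sas_result", "data.frame"),
            alpha = alpha, min_tpm = min_tpm, test = test,
            control = control, mutant = mutant)
}

#' @export
print.sas_result <- function(x, ...) {
  cat(sprintf("sas_result: %d events tested, %d called (p < %g, TPM >= %g, %s test)\n",
              nrow(x), sum(x$is_sas), attr(x, "alpha"), attr(x, "min_tpm"),
              attr(x, "test")))
  invisible(x)
}

#' @export
summary.sas_result <- function(object, ...) {
  sas <- object[object$is_sas, , drop = FALSE]
  tab <- table(factor(sas$event_type, levels = .EVENT_TYPES),
               factor(ifelse(sas$delta_psi > 0, "dpsi_pos", "dpsi_neg"),
                      levels = c("dpsi_pos", "dpsi_neg")))
  out <- list(n_tested = nrow(object), n_sas = nrow(sas),
              by_type_sign = tab)
  class(out) <- "summary.sas_result"
  out
}

#' @export
print.summary.sas_result <- function(x, ...) {
  cat(sprintf("%d events tested, %d called SAS\n", x$n_tested, x$n_sas))
  print(x$by_type_sign)
  invisible(x)
}

#' @export
plot.sas_result <- function(x, ...) {
  s <- summary(x)
  graphics::barplot(t(s$by_type_sign), beside = TRUE,
                    legend.text = c("dpsi > 0", "dpsi < 0"),
                    xlab = "event type", ylab = "called events", ...)
  invisible(x)
}

#' @rdname call_sas
#' @param sas A `sas_result`.
#' @param path Output TSV path.
#' @export
write_sas_table <- function(sas, path) {
  write_tsv_strict(as.data.frame(sas), path)
}
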