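#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. Defaults mirror
#' the study design at toy scale: 200 two-isoform genes (50 planted events
#' of each class), three biological replicates per condition, logit-normal
#' replicate noise on psi, log-normal gene expression, and a three-pipeline
#' / two-method support-table design.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @param events_per_type Named counts of planted events (A3, A5, RI, SE);
#'   one two-isoform gene per event.
#' @param exon_length_range,intron_length_range Integer ranges (nt).
#' @param ase_span_range Length range of the alternative region between
#'   alternative splice sites (nt).
#' @param n_replicates Replicates per condition.
#' @param frac_events_shifted Fraction of events given a non-zero planted
#'   delta-psi (random sign).
#' @param delta_psi_magnitude |delta-psi| planted on shifted events.
#' @param control_psi_range Range of control-condition mean psi.
#' @param psi_noise_sd Logit-scale replicate noise SD.
#' @param gene_tpm_log_mean,gene_tpm_log_sd Log-normal gene TPM parameters.
#' @param upstream_pad Intergenic pad upstream of each gene (nt), sized for
#'   promoter scans.
#' @param n_de_genes,n_de_up,n_de_down,de_fold,de_fold_noise_sd,de_concordance
#'   Differential-expression support-table parameters (3 pseudo-pipelines).
#' @param n_rip_genes,n_rip_planted,rip_fold,rip_concordance RIP
#'   support-table parameters (2 methods x 2 lines).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       events_per_type = c(A3 = 50, A5 = 50, RI = 50, SE = 50),
                       exon_length_range = c(120, 300),
                       intron_length_range = c(150, 400),
                       ase_span_range = c(30, 80),
                       n_replicates = 3,
                       frac_events_shifted = 0.5,
                       delta_psi_magnitude = 0.4,
                       control_psi_range = c(0.2, 0.8),
                       psi_noise_sd = 0.2,
                       gene_tpm_log_mean = 3,
                       gene_tpm_log_sd = 1,
                       upstream_pad = 600,
                       n_de_genes = 1000, n_de_up = 100, n_de_down = 100,
                       de_fold = 4, de_fold_noise_sd = 0.15,
                       de_concordance = 1,
                       n_rip_genes = 1000, n_rip_planted = 150,
                       rip_fold = 4, rip_concordance = 1) {
  cfg <- as.list(environment())
  .assert(all(cfg$events_per_type >= 0) &&
            all(names(cfg$events_per_type) %in% .EVENT_TYPES),
          "events_per_type must be named counts over A3/A5/RI/SE")
  .assert(cfg$intron_length_range[1L] >= 20 && cfg$exon_length_range[1L] >= 20 &&
            cfg$ase_span_range[1L] >= 15,
          "exon/intron/alternative-span lengths must accommodate motif planting")
  .assert(cfg$frac_events_shifted >= 0 && cfg$frac_events_shifted <= 1,
          "frac_events_shifted in [0,1]")
  structure(cfg, class = "sim_config")
}

.rint <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(seq(range[1L], range[2L]), n, replace = TRUE)
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic genome, annotation and event truth table
#'
#' Lays out one two-isoform gene per planted event along a single synthetic
#' chromosome of random sequence (strands alternate), each gene realizing
#' exactly one A3/A5/RI/SE event; byte-identical outputs under the same
#' seed.
#'
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return list with `genome` (named character, one chromosome),
#'   `transcripts` (a `transcript_models` object), and `truth` (data.frame:
#'   `gene_id`, `event_type`, `event_id`, `strand`, `inclusion_tx`,
#'   `exclusion_tx`, `control_psi`, `delta_psi`).
#' @export
make_genome_annotation <- function(config, seed = config$seed) {
  with_seed(seed, {
    types <- rep(names(config$events_per_type), config$events_per_type)
    n <- length(types)
    .assert(n >= 1L, "no events requested")
    types <- sample(types)              # interleave types along the chromosome
    strands <- sample(c("+", "-"), n, replace = TRUE)
    psi0 <- stats::runif(n, config$control_psi_range[1L],
                         config$control_psi_range[2L])
    shifted <- stats::runif(n) < config$frac_events_shifted
    sign <- sample(c(-1, 1), n, replace = TRUE)
    dpsi <- ifelse(shifted, sign * config$delta_psi_magnitude, 0)
    # keep the mutant mean psi inside (0.05, 0.95)
    mut <- psi0 + dpsi
    flip <- shifted & (mut < 0.05 | mut > 0.95)
    dpsi[flip] <- -dpsi[flip]

    txs <- list()
    truth <- vector("list", n)
    cursor <- 0L
    pieces <- character(2L * n + 1L)
    for (i in seq_len(n)) {
      cursor <- cursor + config$upstream_pad
      pieces[2L * i - 1L] <- .rand_dna(config$upstream_pad)
      g <- .gene_structure(types[i], strands[i], config)
      gid <- sprintf("g%04d", i)
      off <- cursor
      mk <- function(suffix, exons) {
        ex <- exons + off
        storage.mode(ex) <- "integer"
        list(transcript_id = paste0(gid, ".", suffix), gene_id = gid,
             chrom = "chr1", strand = strands[i], exons = ex)
      }
      t_inc <- mk("t1", g$inclusion_exons)
      t_exc <- mk("t2", g$exclusion_exons)
      txs[[t_inc$transcript_id]] <- t_inc
      txs[[t_exc$transcript_id]] <- t_exc
      anchors <- g$anchors + off
      eid <- sprintf("%s;%s:chr1:%s:%s", gid, types[i],
                     paste(anchors[order(anchors)], collapse = "-"),
                     strands[i])
      truth[[i]] <- data.frame(
        gene_id = gid, event_type = types[i], event_id = eid,
        strand = strands[i], inclusion_tx = t_inc$transcript_id,
        exclusion_tx = t_exc$transcript_id,
        control_psi = psi0[i], delta_psi = dpsi[i],
        stringsAsFactors = FALSE)
      pieces[2L * i] <- .rand_dna(g$span)
      cursor <- cursor + g$span
    }
    pieces[2L * n + 1L] <- .rand_dna(200L)
    genome <- c(chr1 = paste(pieces, collapse = ""))
    list(genome = genome,
         transcripts = structure(txs, class = "transcript_models"),
         truth = do.call(rbind, truth))
  })
}

# Gene-local exon layouts (0-based, gene starts at 0). The event type is
# strand-dependent for alternative sites: an intron pair sharing its
# genomic-right boundary is A5 on "+" and A3 on "-".
.gene_structure <- function(type, strand, config) {
  ex <- function() .rint(1L, config$exon_length_range)
  iv <- function() .rint(1L, config$intron_length_range)
  d <- .rint(1L, config$ase_span_range)
  if (type == "RI") {
    L1 <- ex(); I <- iv(); L2 <- ex()
    inc <- cbind(start = 0L, end = L1 + I + L2)      # intron-retaining
    exc <- cbind(start = c(0L, L1 + I), end = c(L1, L1 + I + L2))
    list(inclusion_exons = inc, exclusion_exons = exc,
         anchors = c(ri_start = L1, ri_end = L1 + I), span = L1 + I + L2)
  } else if (type == "SE") {
    L1 <- ex(); I1 <- iv(); L2 <- d; I2 <- iv(); L3 <- ex()
    b <- L1; c_ <- b + I1; dd <- c_ + L2; e <- dd + I2
    inc <- cbind(start = c(0L, c_, e), end = c(b, dd, e + L3))
    exc <- cbind(start = c(0L, e), end = c(b, e + L3))
    list(inclusion_exons = inc, exclusion_exons = exc,
         anchors = c(i1_start = b, i1_end = c_, i2_start = dd, i2_end = e),
         span = e + L3)
  } else {
    # alternative splice sites: genomic-left alternatives if (A5 on +) or
    # (A3 on -); genomic-right alternatives otherwise.
    left_alts <- (type == "A5") == (strand == "+")
    L1 <- ex(); I <- iv(); L2 <- ex()
    if (left_alts) {
      s1 <- L1; s2 <- L1 + d; e <- s2 + I
      inc <- cbind(start = c(0L, e), end = c(s2, e + L2))  # exon to s2
      exc <- cbind(start = c(0L, e), end = c(s1, e + L2))
      anchors <- c(alt_a = s1, alt_b = s2, shared = e)
    } else {
      s <- L1; e1 <- s + I; e2 <- e1 + d
      inc <- cbind(start = c(0L, e1), end = c(s, e2 + L2)) # exon from e1
      exc <- cbind(start = c(0L, e2), end = c(s, e2 + L2))
      anchors <- c(shared = s, alt_a = e1, alt_b = e2)
    }
    span <- max(inc[, 2L], exc[, 2L])
    list(inclusion_exons = inc, exclusion_exons = exc,
         anchors = anchors, span = span)
  }
}

#' Write a synthetic genome / annotation to disk
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @param transcripts A `transcript_models` object.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- unlist(lapply(transcripts, function(tx) {
    sprintf("%s\tspliceflank\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
            tx$chrom, tx$exons[, 1L] + 1L, tx$exons[, 2L], tx$strand,
            tx$gene_id, tx$transcript_id)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Plant motif instances into genomic regions at a target density
#'
#' Writes degenerate-motif instances (N positions filled with random bases)
#' at random positions of the given regions' sense-strand sequence until the
#' overlap-counted occurrence total equals `round(density x length / 1000)`.
#' Pre-existing chance occurrences count toward the target, so the final
#' measured density is exact by construction; every candidate write is
#' accepted only if it adds exactly one occurrence (otherwise reverted), and
#' sequence length is always preserved.
#'
#' @param genome Named character vector.
#' @param regions data.frame `chrom`, `start`, `end`, `strand`
#'   (non-overlapping).
#' @param motif IUPAC-degenerate pattern.
#' @param target_density Target occurrences per kb over the region total.
#' @param seed RNG seed.
#' @return The modified genome (named character vector).
#' @export
plant_motifs <- function(genome, regions, motif, target_density, seed = 1) {
  m <- nchar(motif)
  .assert(all(regions$end - regions$start >= m),
          "all regions must be at least as long as the motif")
  with_seed(seed, {
    sense <- character(nrow(regions))
    for (i in seq_len(nrow(regions))) {
      s <- substr(genome[[regions$chrom[i]]], regions$start[i] + 1L,
                  regions$end[i])
      sense[i] <- if (regions$strand[i] == "-") revcomp(s) else s
    }
    counts <- count_motif(sense, motif)
    total_len <- sum(nchar(sense))
    target <- round(target_density * total_len / 1000)
    if (sum(counts) > target) {
      warning("pre-existing occurrences already exceed the target density")
    } else {
      need <- target - sum(counts)
      chars <- strsplit(toupper(motif), "")[[1L]]
      attempts <- 0L
      while (need > 0L) {
        attempts <- attempts + 1L
        .assert(attempts <= 200L * target + 200L,
                "could not reach target density (infeasible)")
        i <- sample.int(nrow(regions), 1L,
                        prob = nchar(sense) - m + 1L)
        pos <- sample.int(nchar(sense[i]) - m + 1L, 1L)
        inst <- vapply(chars, function(ch) {
          opts <- setdiff(strsplit(.IUPAC[[ch]], "")[[1L]], c("[", "]"))
          if (length(opts) == 1L) opts else sample(opts, 1L)
        }, "")
        cand <- sense[i]
        substr(cand, pos, pos + m - 1L) <- paste(inst, collapse = "")
        newc <- count_motif(cand, motif)
        if (newc == counts[i] + 1L) {
          sense[i] <- cand; counts[i] <- newc; need <- need - 1L
        }
      }
    }
    for (i in seq_len(nrow(regions))) {
      gseq <- if (regions$strand[i] == "-") revcomp(sense[i]) else sense[i]
      g <- genome[[regions$chrom[i]]]
      substr(g, regions$start[i] + 1L, regions$end[i]) <- gseq
      genome[[regions$chrom[i]]] <- g
    }
    genome
  })
}

#' Simulate replicate isoform abundances for planted events
#'
#' Per gene and sample, gene TPM is log-normal; each replicate's psi is
#' logit-normal around the condition mean (control mean, or control +
#' planted delta-psi for the mutant, clamped to (0.01, 0.99)); isoform TPMs
#' are gene TPM x (psi, 1 - psi) for the inclusion and exclusion isoforms.
#' With `psi_noise_sd = 0` replicate psi equals the condition mean exactly.
#'
#' @param truth Truth table from [make_genome_annotation()].
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return list `quant` (data.frame `transcript_id` + sample columns) and
#'   `conditions` (data.frame `sample`, `condition` with levels
#'   control/mutant).
#' @export
simulate_quant <- function(truth, config, seed = config$seed) {
  with_seed(seed, {
    nrep <- config$n_replicates
    samples <- c(paste0("control_", seq_len(nrep)),
                 paste0("mutant_", seq_len(nrep)))
    cond <- rep(c("control", "mutant"), each = nrep)
    clamp <- function(x) pmin(pmax(x, 0.01), 0.99)
    qm <- matrix(0, nrow = 2L * nrow(truth), ncol = length(samples),
                 dimnames = list(NULL, samples))
    txids <- character(2L * nrow(truth))
    for (i in seq_len(nrow(truth))) {
      mu <- c(control = clamp(truth$control_psi[i]),
              mutant = clamp(truth$control_psi[i] + truth$delta_psi[i]))
      for (j in seq_along(samples)) {
        g_tpm <- stats::rlnorm(1L, config$gene_tpm_log_mean,
                               config$gene_tpm_log_sd)
        m <- mu[[cond[j]]]
        psi <- if (config$psi_noise_sd == 0) m
               else stats::plogis(stats::qlogis(m) +
                                    stats::rnorm(1L, 0, config$psi_noise_sd))
        qm[2L * i - 1L, j] <- g_tpm * psi
        qm[2L * i, j] <- g_tpm * (1 - psi)
      }
      txids[2L * i - 1L] <- truth$inclusion_tx[i]
      txids[2L * i] <- truth$exclusion_tx[i]
    }
    quant <- cbind(data.frame(transcript_id = txids,
                              stringsAsFactors = FALSE),
                   as.data.frame(qm))
    list(quant = quant,
         conditions = data.frame(sample = samples, condition = cond,
                                 stringsAsFactors = FALSE))
  })
}

#' Simulate multi-pipeline DE and multi-method RIP support tables
#'
#' Three pseudo-pipeline differential-expression tables with planted up/down
#' gene sets, and two quantification-method RIP tables (two transgenic lines
#' each) with a planted bound set. Planted genes pass the selection filters
#' (fold with small multiplicative noise, small significance) in each source
#' independently with probability `de_concordance` / `rip_concordance`;
#' null genes get fold ~ 1 and uniform significance.
#'
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return list `de` (named list of 3 data.frames: `gene_id`,
#'   `fold_change`, `significance`), `rip` (named list of 2 long-format
#'   data.frames with `line` in line1/line2), and `truth`
#'   (list(de_up, de_down, rip)).
#' @export
simulate_support_tables <- function(config, seed = config$seed) {
  with_seed(seed, {
    de_genes <- sprintf("deg%05d", seq_len(config$n_de_genes))
    planted <- sample(de_genes, config$n_de_up + config$n_de_down)
    up <- planted[seq_len(config$n_de_up)]
    down <- planted[config$n_de_up + seq_len(config$n_de_down)]
    fold_noise <- function(n) exp(stats::rnorm(n, 0, config$de_fold_noise_sd))
    one_de <- function() {
      fc <- fold_noise(config$n_de_genes)
      sig <- stats::runif(config$n_de_genes)
      hit_up <- de_genes %in% up & stats::runif(config$n_de_genes) < config$de_concordance
      hit_dn <- de_genes %in% down & stats::runif(config$n_de_genes) < config$de_concordance
      fc[hit_up] <- config$de_fold * fold_noise(sum(hit_up))
      fc[hit_dn] <- fold_noise(sum(hit_dn)) / config$de_fold
      sig[hit_up | hit_dn] <- stats::runif(sum(hit_up | hit_dn), 0, 0.05)
      data.frame(gene_id = de_genes, fold_change = fc, significance = sig,
                 stringsAsFactors = FALSE)
    }
    de <- list(pipelineA = one_de(), pipelineB = one_de(),
               pipelineC = one_de())
    rip_genes <- sprintf("ripg%05d", seq_len(config$n_rip_genes))
    rip_planted <- sample(rip_genes, config$n_rip_planted)
    one_rip <- function() {
      hit <- rip_genes %in% rip_planted &
        stats::runif(config$n_rip_genes) < config$rip_concordance
      one_line <- function(line) {
        fc <- fold_noise(config$n_rip_genes)
        sig <- stats::runif(config$n_rip_genes)
        fc[hit] <- config$rip_fold * fold_noise(sum(hit))
        sig[hit] <- stats::runif(sum(hit), 0, 0.05)
        data.frame(gene_id = rip_genes, line = line, fold_change = fc,
                   significance = sig, stringsAsFactors = FALSE)
      }
      rbind(one_line("line1"), one_line("line2"))
    }
    list(de = de, rip = list(methodA = one_rip(), methodB = one_rip()),
         truth = list(de_up = sort(up), de_down = sort(down),
                      rip = sort(rip_planted)))
  })
}
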