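# Seeded simulator: random transcriptomes with implanted PHAS loci (phased
# duplex stacks with the 2-nt 3' overhang geometry), trigger miRNA sites
# whose cleavage sets the register, matching degradome peaks, and a truth
# table for benchmarking.

#' Simulation configuration
#'
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @param n_transcripts Number of random transcripts.
#' @param min_len,max_len Transcript length range (nt, uniform).
#' @param gc_fraction GC content of the random sequence.
#' @param n_loci Number of implanted PHAS loci (at most one per transcript).
#' @param p Cycle length of the implanted phasiRNAs (21 or 24).
#' @param duplexes_per_locus Number of consecutive phased duplexes.
#' @param base_abundance Read count of the first (5'-most) duplex.
#' @param decay Geometric decay ratio of abundance across cycles.
#' @param antisense_fraction Probability that a duplex also emits its
#'   antisense star read (offset -2 nt per the 2-nt 3' overhang).
#' @param noise_per_transcript Number of background small RNA reads drawn
#'   per transcript (lengths sampled from 20/21/22/24 nt).
#' @param offregister_fraction Fraction of a locus transcript's noise reads
#'   placed inside the locus at an off-register offset.
#' @param mirna_length Trigger miRNA length (21 or 22 nt).
#' @param trigger_mismatches Mismatches implanted into each trigger site
#'   (never at small RNA positions 9-11).
#' @param peak_height Degradome read count at each implanted cleavage site.
#' @param background_rate Expected degradome background 5' ends per nt
#'   (Poisson).
#' @param tag_length Degradome tag length (nt).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_transcripts = 10L, min_len = 1500L,
                       max_len = 3000L, gc_fraction = 0.42, n_loci = 3L,
                       p = 21L, duplexes_per_locus = 8L,
                       base_abundance = 20, decay = 0.7,
                       antisense_fraction = 1, noise_per_transcript = 8L,
                       offregister_fraction = 0.2, mirna_length = 22L,
                       trigger_mismatches = 2L, peak_height = 50,
                       background_rate = 0.02, tag_length = 20L) {
  cfg <- list(seed = as.integer(seed), n_transcripts = as.integer(n_transcripts),
              min_len = as.integer(min_len), max_len = as.integer(max_len),
              gc_fraction = gc_fraction, n_loci = as.integer(n_loci),
              p = as.integer(p), duplexes_per_locus = as.integer(duplexes_per_locus),
              base_abundance = base_abundance, decay = decay,
              antisense_fraction = antisense_fraction,
              noise_per_transcript = as.integer(noise_per_transcript),
              offregister_fraction = offregister_fraction,
              mirna_length = as.integer(mirna_length),
              trigger_mismatches = as.integer(trigger_mismatches),
              peak_height = peak_height, background_rate = background_rate,
              tag_length = as.integer(tag_length))
  stopifnot(cfg$n_transcripts >= 1L, cfg$min_len <= cfg$max_len,
            cfg$gc_fraction >= 0, cfg$gc_fraction <= 1, cfg$n_loci >= 0L,
            cfg$p >= 2L, cfg$duplexes_per_locus >= 1L, cfg$decay > 0,
            cfg$antisense_fraction >= 0, cfg$antisense_fraction <= 1,
            cfg$offregister_fraction >= 0, cfg$offregister_fraction <= 1,
            cfg$mirna_length >= 18L, cfg$mirna_length <= 30L,
            cfg$trigger_mismatches >= 0L, cfg$peak_height >= 0,
            cfg$background_rate >= 0)
  structure(cfg, class = "sim_config")
}

# run expr with a private RNG stream seeded from `seed`
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.random_seq <- function(len, gc) {
  paste(sample(c("A", "T", "G", "C"), len, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Simulate a transcriptome with implanted PHAS loci
#'
#' Each implanted locus sits on its own transcript.  A trigger miRNA site is
#' written so that the inferred cleavage position (opposite miRNA positions
#' 10/11) falls exactly at the locus start, which therefore defines the
#' register.  Phased duplexes are laid head-to-tail downstream of the
#' cleavage site with geometrically decaying abundance; antisense partners
#' cover `[pos - 2, pos + p - 2)` so their effective position (+2 offset)
#' matches the sense register.  Background reads are sampled from the
#' transcript itself (so they align exactly), with a configured fraction
#' placed off-register inside loci.  The degradome gets a peak of
#' `peak_height` at each cleavage position plus Poisson background.
#'
#' @param cfg A [sim_config()].
#' @return List: `transcripts` (DNAStringSet), `srna` (seq/count),
#'   `mirnas` (named DNAStringSet), `degradome` (seq/count), `truth`
#'   (one row per locus), `placements` (where each simulated small RNA was
#'   generated, in mapped-read form), `cfg`.
#' @export
simulate_phas <- function(cfg = sim_config()) .with_seed(cfg$seed, {
  p <- cfg$p
  span <- cfg$duplexes_per_locus * p
  tlen <- cfg$min_len +
    sample.int(cfg$max_len - cfg$min_len + 1L, cfg$n_transcripts,
               replace = TRUE) - 1L
  tx_ids <- sprintf("TX%04d|g%d_i1", seq_len(cfg$n_transcripts),
                    seq_len(cfg$n_transcripts))
  seqs <- vapply(tlen, .random_seq, character(1), gc = cfg$gc_fraction)
  if (cfg$n_loci > cfg$n_transcripts) {
    stop("infeasible: n_loci exceeds n_transcripts (one locus per transcript)")
  }
  Lm <- cfg$mirna_length
  min_start <- Lm            # trigger site [start + 10 - Lm, start + 10)
  # leave room for a full default-width scan window (10 cycles) at the
  # locus anchor, not just for the implanted duplex span
  margin <- max(span, 10L * p)
  locus_tx <- if (cfg$n_loci > 0L)
    sample(seq_len(cfg$n_transcripts), cfg$n_loci) else integer(0)
  truth <- list(); placements <- list(); mirnas <- character(0)
  deg_peaks <- list()
  for (li in seq_along(locus_tx)) {
    ti <- locus_tx[li]
    if (tlen[ti] < min_start + margin + 1L) {
      stop("infeasible: locus of ", span, " nt plus trigger site and scan ",
           "window does not fit transcript of ", tlen[ti], " nt")
    }
    start <- min_start +
      sample.int(tlen[ti] - margin - min_start + 1L, 1L) - 1L
    mir <- .random_seq(Lm, 0.5)
    site_start <- start + 10L - Lm
    site <- revcomp(mir)
    # implant mismatches outside miRNA positions 9-11 so the cleavage
    # signal stays clean; site offset of miRNA position j is Lm - j
    if (cfg$trigger_mismatches > 0L) {
      jj <- sample(setdiff(seq_len(Lm), 9:11), cfg$trigger_mismatches)
      sb <- .split_bases(site)
      qb <- .split_bases(mir)
      sb[Lm - jj + 1L] <- qb[jj]     # target base = query base: never pairs
      site <- paste(sb, collapse = "")
    }
    substr(seqs[ti], site_start + 1L, site_start + Lm) <- site
    mid <- sprintf("miR-sim%d", li)
    mirnas[mid] <- mir
    phas_seq <- character(0); phas_cnt <- numeric(0)
    for (d in seq_len(cfg$duplexes_per_locus)) {
      pos <- start + (d - 1L) * p
      cnt <- max(1, round(cfg$base_abundance * cfg$decay^(d - 1L)))
      sseq <- substr(seqs[ti], pos + 1L, pos + p)
      placements[[length(placements) + 1L]] <- data.frame(
        seq = sseq, count = cnt, transcript_id = tx_ids[ti],
        start = pos, strand = "sense", len = p, origin = "phased",
        stringsAsFactors = FALSE)
      phas_seq <- c(phas_seq, sseq); phas_cnt <- c(phas_cnt, cnt)
      if (runif(1) <= cfg$antisense_fraction) {
        aseq <- revcomp(substr(seqs[ti], pos - 1L, pos + p - 2L))
        acnt <- max(1, round(cnt * 0.6))
        placements[[length(placements) + 1L]] <- data.frame(
          seq = aseq, count = acnt, transcript_id = tx_ids[ti],
          start = pos - 2L, strand = "antisense", len = p,
          origin = "phased", stringsAsFactors = FALSE)
        phas_seq <- c(phas_seq, aseq); phas_cnt <- c(phas_cnt, acnt)
      }
    }
    truth[[li]] <- data.frame(
      transcript_id = tx_ids[ti], start = start, end = start + span,
      register = start %% p, p = p,
      phasirna_seqs = paste(sprintf("%s:%g", phas_seq, phas_cnt),
                            collapse = ";"),
      trigger_id = mid, site_start = site_start, site_end = site_start + Lm,
      cleavage_position = start, stringsAsFactors = FALSE)
    deg_peaks[[li]] <- data.frame(ti = ti, pos = start,
                                  count = cfg$peak_height)
  }
  # background small RNAs, sampled from the (final) transcript sequence
  noise_lens <- c(20L, 21L, 22L, 24L)
  for (ti in seq_len(cfg$n_transcripts)) {
    nn <- cfg$noise_per_transcript
    if (nn == 0L) next
    has_locus <- ti %in% locus_tx
    len <- sample(noise_lens, nn, replace = TRUE)
    pos <- sample.int(tlen[ti] - max(noise_lens) + 1L, nn,
                      replace = TRUE) - 1L
    if (has_locus) {
      inloc <- runif(nn) < cfg$offregister_fraction
      if (any(inloc)) {
        tr <- truth[[match(ti, locus_tx)]]
        cyc <- sample.int(cfg$duplexes_per_locus, sum(inloc),
                          replace = TRUE) - 1L
        off <- sample.int(p - 1L, sum(inloc), replace = TRUE)
        pos[inloc] <- pmin(tr$start + cyc * p + off,
                           tlen[ti] - len[inloc])
      }
    }
    strand <- sample(c("sense", "antisense"), nn, replace = TRUE,
                     prob = c(0.8, 0.2))
    window <- substr(rep(seqs[ti], nn), pos + 1L, pos + len)
    anti <- strand == "antisense"
    if (any(anti)) window[anti] <- revcomp(window[anti])
    placements[[length(placements) + 1L]] <- data.frame(
      seq = window, count = sample.int(3L, nn, replace = TRUE),
      transcript_id = tx_ids[ti], start = pos, strand = strand, len = len,
      origin = "noise", stringsAsFactors = FALSE)
  }
  placements <- if (length(placements) > 0L) do.call(rbind, placements) else
    cbind(.empty_mapped(), data.frame(origin = character()))
  srna <- if (nrow(placements) > 0L)
    stats::aggregate(count ~ seq, data = placements, FUN = sum) else
    data.frame(seq = character(), count = numeric())
  srna <- srna[order(-srna$count, srna$seq), , drop = FALSE]
  rownames(srna) <- NULL
  # degradome: implanted cleavage peaks + Poisson background 5' ends
  deg <- list()
  for (pk in deg_peaks) {
    deg[[length(deg) + 1L]] <- data.frame(
      seq = substr(seqs[pk$ti], pk$pos + 1L, pk$pos + cfg$tag_length),
      count = pk$count, stringsAsFactors = FALSE)
  }
  for (ti in seq_len(cfg$n_transcripts)) {
    nbg <- rpois(1L, cfg$background_rate * (tlen[ti] - cfg$tag_length))
    if (nbg > 0L) {
      pos <- sample.int(tlen[ti] - cfg$tag_length + 1L, nbg, replace = TRUE) - 1L
      deg[[length(deg) + 1L]] <- data.frame(
        seq = substr(rep(seqs[ti], nbg), pos + 1L, pos + cfg$tag_length),
        count = 1, stringsAsFactors = FALSE)
    }
  }
  degradome <- if (length(deg) > 0L) {
    d <- stats::aggregate(count ~ seq, data = do.call(rbind, deg), FUN = sum)
    d[order(-d$count, d$seq), , drop = FALSE]
  } else data.frame(seq = character(), count = numeric())
  rownames(degradome) <- NULL
  transcripts <- Biostrings::DNAStringSet(seqs)
  names(transcripts) <- tx_ids
  truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(transcript_id = character(), start = integer(),
               end = integer(), register = integer(), p = integer(),
               phasirna_seqs = character(), trigger_id = character(),
               site_start = integer(), site_end = integer(),
               cleavage_position = integer(), stringsAsFactors = FALSE)
  mir_set <- Biostrings::DNAStringSet(mirnas)
  list(transcripts = transcripts, srna = srna, mirnas = mir_set,
       degradome = degradome, truth = truth, placements = placements,
       cfg = cfg)
})

#' Write a simulation to disk
#'
#' Emits the five files the pipeline consumes: `transcripts.fasta`, the
#' small RNA and degradome libraries as collapsed FASTA (`_x<count>` header
#' dialect), `mirna.fasta`, and `truth.tsv`.
#'
#' @param sim [simulate_phas()] output.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the five paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(transcripts = file.path(dir, "transcripts.fasta"),
             srna = file.path(dir, "srna_collapsed.fasta"),
             mirna = file.path(dir, "mirna.fasta"),
             degradome = file.path(dir, "degradome_collapsed.fasta"),
             truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(sim$transcripts, paths["transcripts"])
  .write_collapsed <- function(df, prefix, path) {
    set <- Biostrings::DNAStringSet(df$seq)
    names(set) <- sprintf("%s%d_x%g", prefix, seq_len(nrow(df)), df$count)
    Biostrings::writeXStringSet(set, path)
  }
  .write_collapsed(sim$srna, "sr", paths["srna"])
  .write_collapsed(sim$degradome, "dg", paths["degradome"])
  Biostrings::writeXStringSet(sim$mirnas, paths["mirna"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Compare called loci (and trigger calls) with the simulation truth
#'
#' A called locus matches a truth locus when they sit on the same
#' transcript, their intervals overlap, and the registers agree.  Trigger
#' recovery asks, per truth locus, whether the implanted miRNA owns the
#' top valid-read trigger-consistent site on that transcript.
#'
#' @param loci [call_loci()] output.
#' @param truth Truth table from [simulate_phas()].
#' @param trigger_calls Optional [call_triggers()] output.
#' @return List: `recall`, `precision`, `register_accuracy` (fraction of
#'   matched truth loci among interval-overlapping ones), `n_truth`,
#'   `n_called`, and (with trigger calls) `trigger_recovery`.
#' @export
evaluate_calls <- function(loci, truth, trigger_calls = NULL) {
  n_truth <- nrow(truth); n_called <- nrow(loci)
  overlap_hit <- logical(n_truth); full_hit <- logical(n_truth)
  called_ok <- logical(n_called)
  for (i in seq_len(n_truth)) {
    same <- which(loci$transcript_id == truth$transcript_id[i] &
                    loci$p == truth$p[i])
    ov <- same[loci$start[same] < truth$end[i] &
                 loci$end[same] > truth$start[i]]
    overlap_hit[i] <- length(ov) > 0L
    reg <- ov[loci$best_register[ov] == truth$register[i]]
    full_hit[i] <- length(reg) > 0L
    called_ok[reg] <- TRUE
  }
  out <- list(
    recall = if (n_truth == 0L) NA_real_ else mean(full_hit),
    precision = if (n_called == 0L) NA_real_ else mean(called_ok),
    register_accuracy = if (!any(overlap_hit)) NA_real_ else
      sum(full_hit) / sum(overlap_hit),
    n_truth = n_truth, n_called = n_called)
  if (!is.null(trigger_calls)) {
    rec <- vapply(seq_len(n_truth), function(i) {
      tc <- trigger_calls[trigger_calls$transcript_id ==
                            truth$transcript_id[i] &
                            trigger_calls$valid_reads > 0, , drop = FALSE]
      if (nrow(tc) == 0L) return(FALSE)
      top <- tc[which.max(tc$valid_reads), ]
      top$small_rna_id == truth$trigger_id[i] && top$trigger_consistent
    }, logical(1))
    out$trigger_recovery <- if (n_truth == 0L) NA_real_ else mean(rec)
  }
  out
}
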