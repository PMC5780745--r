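# The phasing statistics: hypergeometric window P-value, phase score,
# transcriptome scan, window extension/merging, FDR and locus calling.

#' Configuration for the phasing scan
#'
#' @param p Cycle length in nt: the phasiRNA length being scanned for,
#'   21 or 24 in plants (any p >= 2 is accepted).
#' @param m Number of phases (cycles) per window; the window spans `p * m`
#'   nt.  Default 10.
#' @param extension Nucleotides added to both ends of each significant
#'   window before merging.  Default 100.
#' @param min_phase_score Minimum maximal phase score for a merged region to
#'   be called a locus.  Default 5.
#' @param alpha Threshold on the Benjamini-Hochberg corrected P-value.
#'   Default 0.05.
#' @param window_p Raw P-value threshold a window must pass to be extended
#'   and merged.  Default 0.05.
#' @param min_unique_phased Minimum number of phased unique reads (k) for a
#'   window to receive a non-zero phase score.  Default 3.
#' @param multimap Placement policy for multi-mapping reads, `"all"` or
#'   `"unique"` (see [align_exact()]).
#' @return A list of class `phase_config`.
#' @export
phase_config <- function(p = 21L, m = 10L, extension = 100L,
                         min_phase_score = 5, alpha = 0.05,
                         window_p = 0.05, min_unique_phased = 3L,
                         multimap = "all") {
  p <- as.integer(p); m <- as.integer(m)
  stopifnot(p >= 2L, m >= 2L, extension >= 0L, min_phase_score >= 0,
            alpha > 0, alpha <= 1, min_unique_phased >= 1L)
  structure(list(p = p, m = m, extension = as.integer(extension),
                 min_phase_score = min_phase_score, alpha = alpha,
                 window_p = window_p,
                 min_unique_phased = as.integer(min_unique_phased),
                 multimap = multimap),
            class = "phase_config")
}

#' Effective phase position of a mapped read
#'
#' Sense reads keep their 5' start; antisense reads get a +2 nt offset so
#' that the two strands of a Dicer duplex (2-nt 3' overhangs) fall in the
#' same register.
#'
#' @param start 0-based sense-strand start position(s).
#' @param strand `"sense"` or `"antisense"`, recycled.
#' @return Integer vector of effective positions.
#' @export
effective_position <- function(start, strand) {
  as.integer(start) + ifelse(strand == "antisense", 2L, 0L)
}

#' Hypergeometric phasing P-value of a window
#'
#' Upper-tail probability `P(X >= k)` of observing at least `k` in-register
#' unique reads when `n` distinct read positions are drawn from the `p * m`
#' positions of a window of which `m` are in register:
#' `sum_{x=k}^{min(m,n)} C(m,x) C((p-1)m, n-x) / C(pm, n)`.
#'
#' @param k Number of phased unique reads (successes observed).
#' @param n Total number of unique reads of length `p` in the window.
#' @param m Number of phases per window.
#' @param p Cycle length in nt.
#' @return P-value(s) in `[0, 1]`; vectorized over `k` and `n`.
#' @export
phasing_p_value <- function(k, n, m = 10L, p = 21L) {
  k <- as.integer(k); n <- as.integer(n); m <- as.integer(m); p <- as.integer(p)
  nmax <- max(length(k), length(n))
  k <- rep_len(k, nmax); n <- rep_len(n, nmax)
  if (any(k < 0L | n < 0L | k > pmin(n, m) | n > p * m)) {
    stop("invalid domain: need 0 <= k <= min(n, m) and n <= p * m")
  }
  stats::phyper(k - 1L, m, (p - 1L) * m, n, lower.tail = FALSE)
}

#' Phase score of a window
#'
#' For a window with at least `min_k` (default 3) phased unique reads the
#' score is `(k - 2) * log(1 + m * sum_P / (1 + sum_U))`, where `sum_P` is
#' the total abundance of phased reads and `sum_U` the total abundance of
#' non-phased (off-register) reads of the scanned length in the window.
#' Below the gate the score is reported as 0 so that thresholding is total.
#'
#' @param k Number of phased unique reads.
#' @param sum_P Total abundance of phased reads.
#' @param sum_U Total abundance of non-phased reads.
#' @param m Abundance-ratio multiplier; equals the number of phases
#'   (default 10).
#' @param min_k Gate below which the score is 0 (default 3).
#' @return Non-negative score(s); vectorized.
#' @export
phase_score <- function(k, sum_P, sum_U, m = 10L, min_k = 3L) {
  s <- (k - 2) * log1p(m * sum_P / (1 + sum_U))
  ifelse(k < min_k, 0, s)
}

#' Scan one transcript for phased windows
#'
#' Windows are anchored at every distinct effective position of a length-`p`
#' read whose window `[anchor, anchor + p*m)` lies fully on the transcript
#' (a window anchored where no read starts in register has `k = 0`, so this
#' anchor set is result-equivalent to scanning every nucleotide).  Within a
#' window only reads of length exactly `p` are counted: `k`/`n` count unique
#' sequences (phased / total), `sum_P`/`sum_U` count abundance of phased /
#' off-register reads.
#'
#' @param mapped Mapped reads on this transcript ([align_exact()] rows).
#' @param transcript_len Transcript length in nt.
#' @param cfg A [phase_config()].
#' @return data.frame of window statistics, one row per anchor.
#' @export
scan_transcript <- function(mapped, transcript_len, cfg = phase_config()) {
  p <- cfg$p; m <- cfg$m; span <- p * m
  empty <- data.frame(transcript_id = character(), window_start = integer(),
                      p = integer(), m = integer(), k = integer(),
                      n = integer(), sum_P = numeric(), sum_U = numeric(),
                      p_value = numeric(), phase_score = numeric(),
                      stringsAsFactors = FALSE)
  lp <- mapped[mapped$len == p, , drop = FALSE]
  if (nrow(lp) == 0L) return(empty)
  eff <- effective_position(lp$start, lp$strand)
  anchors <- sort(unique(eff[eff >= 0L & eff + span <= transcript_len]))
  if (length(anchors) == 0L) return(empty)
  rows <- lapply(anchors, function(a) {
    inw <- eff >= a & eff < a + span
    e <- eff[inw]
    phased <- (e - a) %% p == 0L
    k <- length(unique(lp$seq[inw][phased]))
    n <- length(unique(lp$seq[inw]))
    sum_P <- sum(lp$count[inw][phased])
    sum_U <- sum(lp$count[inw][!phased])
    # clamp to the hypergeometric domain; exceeding it needs several unique
    # sequences stacked on one position, outside the model's sampling scheme
    k_s <- min(k, m); n_s <- min(n, span)
    data.frame(transcript_id = lp$transcript_id[1L], window_start = a,
               p = p, m = m, k = k, n = n, sum_P = sum_P, sum_U = sum_U,
               p_value = phasing_p_value(k_s, n_s, m, p),
               phase_score = phase_score(k, sum_P, sum_U, m,
                                         cfg$min_unique_phased),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extend significant windows and merge overlaps
#'
#' Windows with raw P-value below `cfg$window_p` are extended by
#' `cfg$extension` nt on both sides, clipped to the transcript, and
#' transitively overlapping intervals are merged.  Each merged region keeps
#' the minimum raw P-value, the maximum phase score, and the anchor and
#' register of its best-scoring member window (ties: lower P, then leftmost).
#'
#' @param windows Window statistics from [scan_transcript()] (one
#'   transcript).
#' @param transcript_len Transcript length in nt.
#' @param cfg A [phase_config()].
#' @return data.frame of merged regions with 0-based half-open `start`/`end`.
#' @export
extend_and_merge <- function(windows, transcript_len, cfg = phase_config()) {
  empty <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), p = integer(),
                      best_window_start = integer(), best_register = integer(),
                      k = integer(), n = integer(),
                      max_phase_score = numeric(), min_p_value = numeric(),
                      stringsAsFactors = FALSE)
  sig <- windows[windows$p_value < cfg$window_p, , drop = FALSE]
  if (nrow(sig) == 0L) return(empty)
  span <- cfg$p * cfg$m
  lo <- pmax(sig$window_start - cfg$extension, 0L)
  hi <- pmin(sig$window_start + span + cfg$extension, transcript_len)
  ir <- IRanges::IRanges(start = lo + 1L, end = hi)    # 1-based closed
  red <- IRanges::reduce(ir, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  rows <- lapply(seq_along(red), function(i) {
    mem <- sig[revmap[[i]], , drop = FALSE]
    best <- order(-mem$phase_score, mem$p_value, mem$window_start)[1L]
    data.frame(transcript_id = mem$transcript_id[1L],
               start = IRanges::start(red)[i] - 1L,
               end = IRanges::end(red)[i],
               p = cfg$p,
               best_window_start = mem$window_start[best],
               best_register = mem$window_start[best] %% cfg$p,
               k = mem$k[best], n = mem$n[best],
               max_phase_score = max(mem$phase_score),
               min_p_value = min(mem$p_value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg correction over merged regions
#'
#' Adds an `fdr` column: BH-adjusted values of the regions' minimum raw
#' P-values, computed across all transcripts jointly.
#'
#' @param regions Merged regions (all transcripts row-bound).
#' @return `regions` with an `fdr` column.
#' @export
fdr_correct <- function(regions) {
  regions$fdr <- if (nrow(regions) == 0L) numeric(0) else
    stats::p.adjust(regions$min_p_value, method = "BH")
  regions
}

# transcript id as used in locus names: pipe and whitespace become "_"
sanitize_id <- function(id) gsub("_+", "_", gsub("[|[:space:]]+", "_", id))

#' Call PHAS loci from corrected merged regions
#'
#' Regions with `max_phase_score >= cfg$min_phase_score` and
#' `fdr < cfg$alpha` become loci, named
#' `P<p>_<transcript id with '|' replaced by '_'>_<serial>` with serials
#' assigned per transcript in ascending coordinate order.
#'
#' @param regions Output of [fdr_correct()].
#' @param cfg A [phase_config()].
#' @return data.frame of loci with a `name` column.
#' @export
call_loci <- function(regions, cfg = phase_config()) {
  keep <- regions$max_phase_score >= cfg$min_phase_score &
    regions$fdr < cfg$alpha
  loci <- regions[keep, , drop = FALSE]
  if (nrow(loci) == 0L) {
    loci$name <- character(0)
    return(loci[, c("name", setdiff(names(loci), "name")), drop = FALSE])
  }
  loci <- loci[order(loci$transcript_id, loci$start), , drop = FALSE]
  serial <- stats::ave(seq_len(nrow(loci)), loci$transcript_id,
                       FUN = seq_along)
  loci$name <- sprintf("P%d_%s_%d", loci$p, sanitize_id(loci$transcript_id),
                       serial)
  rownames(loci) <- NULL
  loci[, c("name", setdiff(names(loci), "name")), drop = FALSE]
}

#' Extract the phasiRNAs of a called locus
#'
#' All length-`p` reads whose effective position lies in
#' `[locus$start, locus$end)` and is congruent to the locus register
#' (mod `p`) are reported, serial-numbered 1..N in 5'->3' order of effective
#' position (ties: sense before antisense), and named
#' `<locus name>_siR<serial>`.
#'
#' @param locus One row of [call_loci()] output.
#' @param mapped Mapped reads on the locus transcript.
#' @return data.frame of phasiRNAs.
#' @export
extract_phasirnas <- function(locus, mapped) {
  p <- locus$p
  lp <- mapped[mapped$len == p & mapped$transcript_id == locus$transcript_id, ,
               drop = FALSE]
  empty <- data.frame(name = character(), locus_name = character(),
                      transcript_id = character(), seq = character(),
                      length = integer(), strand = character(),
                      position = integer(), abundance = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(lp) == 0L) return(empty)
  eff <- effective_position(lp$start, lp$strand)
  keep <- eff >= locus$start & eff < locus$end &
    (eff - locus$best_register) %% p == 0L
  lp <- lp[keep, , drop = FALSE]; eff <- eff[keep]
  if (nrow(lp) == 0L) return(empty)
  ord <- order(eff, lp$strand != "sense", lp$seq)
  lp <- lp[ord, , drop = FALSE]; eff <- eff[ord]
  data.frame(name = sprintf("%s_siR%d", locus$name, seq_len(nrow(lp))),
             locus_name = locus$name,
             transcript_id = lp$transcript_id,
             seq = lp$seq, length = lp$len, strand = lp$strand,
             position = eff, abundance = lp$count,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full PHAS locus discovery on a transcriptome
#'
#' Scans every transcript with [scan_transcript()], extends and merges
#' significant windows, applies the Benjamini-Hochberg correction across all
#' merged regions, calls loci and extracts their phasiRNAs.
#'
#' @param mapped Mapped reads for the whole transcriptome.
#' @param transcripts Named [Biostrings::DNAStringSet].
#' @param cfg A [phase_config()].
#' @return List with `windows`, `regions` (FDR-corrected), `loci` and
#'   `phasirnas` data.frames.
#' @export
find_phas_loci <- function(mapped, transcripts, cfg = phase_config()) {
  tlen <- Biostrings::width(transcripts)
  names(tlen) <- names(transcripts)
  by_tx <- split(mapped, mapped$transcript_id)
  windows <- do.call(rbind, c(lapply(names(by_tx), function(tx) {
    scan_transcript(by_tx[[tx]], tlen[[tx]], cfg)
  }), list(scan_transcript(.empty_mapped(), 0L, cfg))))
  regions <- do.call(rbind, c(lapply(split(windows, windows$transcript_id),
                                     function(w) {
    extend_and_merge(w, tlen[[w$transcript_id[1L]]], cfg)
  }), list(extend_and_merge(scan_transcript(.empty_mapped(), 0L, cfg),
                            0L, cfg))))
  rownames(windows) <- rownames(regions) <- NULL
  regions <- fdr_correct(regions)
  loci <- call_loci(regions, cfg)
  phasirnas <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
    extract_phasirnas(loci[i, ], by_tx[[loci$transcript_id[i]]])
  }))
  if (is.null(phasirnas)) {
    phasirnas <- extract_phasirnas(
      data.frame(name = "x", transcript_id = "x", start = 0L, end = 0L,
                 p = cfg$p, best_register = 0L), .empty_mapped())
  }
  list(windows = windows, regions = regions, loci = loci,
       phasirnas = phasirnas)
}
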