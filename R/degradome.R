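# Degradome (PARE) support: 5'-end profiles, ungapped complementarity scan,
# the valid-read criterion, and the trigger / phasiRNA-target filter rules.

#' Build a degradome 5'-end profile
#'
#' Takes the 5'-most `tag_length` nt of each unique degradome read (PARE
#' tags are fixed length), places the tags on the sense strand of the
#' transcriptome by exact full-length matching, and accumulates the read
#' counts at each 5'-end position.  Multi-mapping tags contribute their full
#' count at every location.
#'
#' @param reads data.frame with `seq` and `count` (from [collapse_reads()]).
#' @param transcripts Named [Biostrings::DNAStringSet].
#' @param tag_length Tag length in nt (default 20); shorter reads are
#'   dropped.
#' @return data.frame `transcript_id`, `pos` (0-based 5'-end), `count`.
#' @export
build_degradome_profile <- function(reads, transcripts, tag_length = 20L) {
  empty <- data.frame(transcript_id = character(), pos = integer(),
                      count = numeric(), stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(empty)
  tags <- data.frame(seq = substr(reads$seq, 1L, tag_length),
                     count = reads$count, stringsAsFactors = FALSE)
  tags <- tags[nchar(tags$seq) == tag_length, , drop = FALSE]
  if (nrow(tags) == 0L) return(empty)
  tags <- stats::aggregate(count ~ seq, data = tags, FUN = sum)
  hits <- .match_width_group(tags$seq, transcripts, "sense")
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  prof <- stats::aggregate(
    count ~ transcript_id + pos,
    data = data.frame(transcript_id = hits$transcript_id,
                      pos = hits$start,
                      count = tags$count[hits$read_i],
                      stringsAsFactors = FALSE),
    FUN = sum)
  prof <- prof[order(prof$transcript_id, prof$pos), , drop = FALSE]
  rownames(prof) <- NULL
  prof
}

# pairing weight lookup, indexed by [small-RNA base, transcript sense base]
# for a site on the transcript's sense strand: the reversed small RNA is
# laid along the site 5'->3', so q at site offset i faces sense base t and
# pairs when q == complement(t); G:U wobble = (G,T) or (T,G).
.pair_weights <- function(gu = 1) {
  b <- c("A", "C", "G", "T", "N")
  W <- matrix(1, 5, 5, dimnames = list(b, b))
  W["A", "T"] <- W["T", "A"] <- W["C", "G"] <- W["G", "C"] <- 0
  W["G", "T"] <- W["T", "G"] <- gu
  W
}

# mismatch weights of an ungapped query laid at every offset of subject
.scan_offsets <- function(qrev, subject, W) {
  L <- length(qrev)
  n_off <- length(subject) - L + 1L
  if (n_off < 1L) return(numeric(0))
  mm <- numeric(n_off)
  for (j in seq_len(L)) {
    mm <- mm + W[qrev[j], subject[j:(j + n_off - 1L)]]
  }
  mm
}

.split_bases <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# human-readable pairing string: "|" Watson-Crick, "o" G:U wobble, "." other;
# written 5'->3' along the small RNA
.pairing_string <- function(q, site_sense) {
  tgt <- rev(.split_bases(site_sense))         # base facing sRNA position j
  qb <- .split_bases(q)
  W <- .pair_weights(gu = 0.5)
  w <- vapply(seq_along(qb), function(j) W[qb[j], tgt[j]], numeric(1))
  paste(ifelse(w == 0, "|", ifelse(w == 0.5, "o", ".")), collapse = "")
}

#' Find ungapped complementary sites of a small RNA on a transcript
#'
#' Slides the small RNA over both strands of the transcript and reports
#' every ungapped placement with at most `max_mismatches` mismatch weight.
#' A mismatch is any non-Watson-Crick pair; a G:U wobble counts as a full
#' mismatch by default (`gu_weight = 0.5` makes it half).
#'
#' @param small_rna Small RNA sequence (18-30 nt, 5'->3').
#' @param small_rna_id Identifier reported in the output.
#' @param transcripts Named [Biostrings::DNAStringSet].
#' @param max_mismatches Maximum total mismatch weight.
#' @param gu_weight Mismatch weight of a G:U pair (1 or 0.5).
#' @return data.frame: `small_rna_id`, `transcript_id`, `site_start`,
#'   `site_end` (0-based half-open, sense coordinates), `target_strand`,
#'   `mismatches`, `pairing`.
#' @export
find_complementary_sites <- function(small_rna, small_rna_id, transcripts,
                                     max_mismatches = 3, gu_weight = 1) {
  small_rna <- chartr("U", "T", toupper(small_rna))
  L <- nchar(small_rna)
  stopifnot(L >= 18L, L <= 30L)
  W <- .pair_weights(gu = gu_weight)
  qrev <- rev(.split_bases(small_rna))
  out <- list()
  for (ti in seq_along(transcripts)) {
    tseq <- as.character(transcripts[[ti]])
    tlen <- nchar(tseq)
    for (strand in c("sense", "antisense")) {
      sub <- if (strand == "sense") tseq else revcomp(tseq)
      mm <- .scan_offsets(qrev, .split_bases(sub), W)
      hit <- which(mm <= max_mismatches)
      if (length(hit) == 0L) next
      s <- hit - 1L                       # 0-based on scanned strand
      if (strand == "antisense") s <- tlen - (s + L)   # back to sense coords
      site_seq <- substr(rep(tseq, length(s)), s + 1L, s + L)
      pair_seq <- if (strand == "sense") site_seq else revcomp(site_seq)
      out[[length(out) + 1L]] <- data.frame(
        small_rna_id = small_rna_id,
        transcript_id = names(transcripts)[ti],
        site_start = as.integer(s), site_end = as.integer(s + L),
        target_strand = strand,
        mismatches = mm[hit],
        pairing = vapply(pair_seq, .pairing_string, character(1),
                         q = small_rna, USE.NAMES = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(small_rna_id = character(), transcript_id = character(),
                      site_start = integer(), site_end = integer(),
                      target_strand = character(), mismatches = numeric(),
                      pairing = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$transcript_id, res$site_start, res$target_strand), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Count valid degradome reads at a binding site
#'
#' A valid read is a degradome read whose 5' end lies opposite small RNA
#' positions 9-11 (1-based from the small RNA 5' end); for a site paired to
#' the sense interval `[s, e)` the transcript position opposite small RNA
#' position `j` is `e - j`.  Sites on the antisense strand get 0 with
#' `strand_flag = TRUE`: the degradome covers only the sense, polyadenylated
#' strand.
#'
#' @param site One row of [find_complementary_sites()] output.
#' @param profile [build_degradome_profile()] output.
#' @return List: `valid_reads`, `breakdown` (named counts at positions
#'   9, 10, 11), `cleavage_position` (0-based transcript position opposite
#'   position 10, i.e. the 5' end of the 3' cleavage product),
#'   `strand_flag`.
#' @export
count_valid_reads <- function(site, profile) {
  cleavage <- site$site_end - 10L
  if (site$target_strand == "antisense") {
    return(list(valid_reads = 0, breakdown = c(`9` = 0, `10` = 0, `11` = 0),
                cleavage_position = cleavage, strand_flag = TRUE))
  }
  pos <- site$site_end - c(9L, 10L, 11L)
  sel <- profile$transcript_id == site$transcript_id & profile$pos %in% pos
  counts <- vapply(pos, function(x) {
    sum(profile$count[sel][profile$pos[sel] == x])
  }, numeric(1))
  names(counts) <- c("9", "10", "11")
  list(valid_reads = sum(counts), breakdown = counts,
       cleavage_position = cleavage, strand_flag = FALSE)
}

# shared site -> TargetCall expansion
.site_calls <- function(sites, profile) {
  if (nrow(sites) == 0L) {
    sites$valid_reads <- numeric(0); sites$reads_at_9 <- numeric(0)
    sites$reads_at_10 <- numeric(0); sites$reads_at_11 <- numeric(0)
    sites$cleavage_position <- integer(0)
    return(sites)
  }
  vr <- lapply(seq_len(nrow(sites)), function(i) {
    count_valid_reads(sites[i, ], profile)
  })
  sites$valid_reads <- vapply(vr, `[[`, numeric(1), "valid_reads")
  sites$reads_at_9 <- vapply(vr, function(x) x$breakdown[["9"]], numeric(1))
  sites$reads_at_10 <- vapply(vr, function(x) x$breakdown[["10"]], numeric(1))
  sites$reads_at_11 <- vapply(vr, function(x) x$breakdown[["11"]], numeric(1))
  sites$cleavage_position <- vapply(vr, `[[`, integer(1), "cleavage_position")
  sites
}

#' Identify candidate miRNA triggers of PHAS loci
#'
#' Scans each miRNA against every transcript hosting a called locus (both
#' strands) and keeps sites passing the conserved-miRNA rule: at least one
#' valid degradome read OR fewer than 4 mismatches.  A site is flagged
#' trigger-consistent when its inferred cleavage position lies within one
#' cycle length of the best-window anchor of a locus on that transcript —
#' cleavage between small RNA positions 10/11 is what sets the phasing
#' register.
#'
#' @param mirnas Named [Biostrings::DNAStringSet] (or named character) of
#'   miRNA sequences.
#' @param loci [call_loci()] output.
#' @param transcripts Named [Biostrings::DNAStringSet].
#' @param profile [build_degradome_profile()] output.
#' @param scan_max_mismatches Mismatch-weight cap of the site scan
#'   (default 6; must be >= 4 so degradome-supported, poorly paired sites
#'   can still be reported under the OR rule).
#' @param gu_weight Mismatch weight of a G:U pair.
#' @return data.frame of trigger calls with `trigger_consistent` and
#'   `locus_name` of the nearest locus.
#' @export
call_triggers <- function(mirnas, loci, transcripts, profile,
                          scan_max_mismatches = 6, gu_weight = 1) {
  mirnas <- Biostrings::DNAStringSet(chartr("U", "T", toupper(
    as.character(mirnas))))
  tx_ids <- unique(loci$transcript_id)
  sites <- do.call(rbind, c(list(find_complementary_sites(
    strrep("A", 21), "none", Biostrings::DNAStringSet(), 0)),
    lapply(names(mirnas), function(mid) {
      find_complementary_sites(as.character(mirnas[[mid]]), mid,
                               transcripts[tx_ids], scan_max_mismatches,
                               gu_weight)
    })))
  calls <- .site_calls(sites, profile)
  calls <- calls[calls$valid_reads >= 1 | calls$mismatches < 4, ,
                 drop = FALSE]
  calls$locus_name <- character(nrow(calls))
  calls$trigger_consistent <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    lx <- loci[loci$transcript_id == calls$transcript_id[i], , drop = FALSE]
    d <- abs(calls$cleavage_position[i] - lx$best_window_start)
    j <- which.min(d)
    calls$locus_name[i] <- lx$name[j]
    calls$trigger_consistent[i] <- d[j] <= lx$p[j]
  }
  rownames(calls) <- NULL
  calls
}

#' Identify phasiRNA targets supported by the degradome
#'
#' Scans each phasiRNA against the transcriptome (both strands) and keeps
#' sites passing the phasiRNA-target rule: at least one valid degradome
#' read AND fewer than 4 mismatches.  `is_cis` marks targets on the
#' phasiRNA's own source transcript.
#'
#' @param phasirnas phasiRNA table ([extract_phasirnas()] rows); distinct
#'   sequences are scanned once under the name of their first occurrence.
#' @param transcripts Named [Biostrings::DNAStringSet].
#' @param profile [build_degradome_profile()] output.
#' @param gu_weight Mismatch weight of a G:U pair.
#' @return data.frame of target calls with an `is_cis` column.
#' @export
call_phasirna_targets <- function(phasirnas, transcripts, profile,
                                  gu_weight = 1) {
  uq <- phasirnas[!duplicated(phasirnas$seq), , drop = FALSE]
  sites <- do.call(rbind, c(list(find_complementary_sites(
    strrep("A", 21), "none", Biostrings::DNAStringSet(), 0)),
    lapply(seq_len(nrow(uq)), function(i) {
      find_complementary_sites(uq$seq[i], uq$name[i], transcripts,
                               max_mismatches = 3.5, gu_weight = gu_weight)
    })))
  calls <- .site_calls(sites, profile)
  calls <- calls[calls$valid_reads >= 1 & calls$mismatches < 4, ,
                 drop = FALSE]
  src <- uq$transcript_id[match(calls$small_rna_id, uq$name)]
  calls$is_cis <- !is.na(src) & calls$transcript_id == src
  rownames(calls) <- NULL
  calls
}
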