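# Reading/writing the formats the pipeline touches, read collapsing with the
# degradome-style QC, and exact-match alignment of small RNAs to transcripts.

#' Read a transcriptome FASTA
#'
#' Loads transcript sequences, upper-cases them and converts U to T, so that
#' downstream matching is always over the DNA alphabet.  Transcript ids are
#' the full header lines (first whitespace-delimited token and any remainder
#' are kept verbatim, matching assembler-style ids such as
#' `"TR101427|c8_g4_i1"`).
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by transcript id.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1", "acgu"), fa)
#' read_transcripts(fa)
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  # read as RNA-tolerant text first: Biostrings DNA parser rejects U
  txt <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- toupper(as.character(txt))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("transcript(s) with non-ACGTN characters after U->T conversion: ",
         paste(utils::head(names(txt)[bad], 3), collapse = ", "))
  }
  ids <- names(txt)
  if (anyDuplicated(ids)) {
    stop("duplicate transcript id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Reverse complement of character sequences
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# Parse a collapsed-FASTA header count suffix ("name_x12" or "name-12").
# Returns NA when no suffix is recognized.
.parse_count_suffix <- function(ids) {
  n <- rep(NA_real_, length(ids))
  mx <- regmatches(ids, regexpr("_x[0-9]+$", ids))
  has_x <- grepl("_x[0-9]+$", ids)
  n[has_x] <- as.numeric(sub("^_x", "", regmatches(ids, regexpr("_x[0-9]+$", ids))))
  dash <- !has_x & grepl("-[0-9]+$", ids)
  n[dash] <- as.numeric(sub("^.*-", "", ids[dash]))
  n
}

# Load one small RNA file as (seq, count, quality-filtered) character data.
.read_srna_file <- function(path, dialect = c("auto", "collapsed", "plain"),
                            min_quality = 20L) {
  dialect <- match.arg(dialect)
  first <- readLines(path, n = 1L)
  is_fastq <- length(first) > 0 && startsWith(first, "@")
  if (is_fastq) {
    fq <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      # informational notice emitted while re-wrapping the quality track
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    quals <- methods::as(Biostrings::quality(fq), "IntegerList")
    keep <- vapply(quals, function(q) all(q >= min_quality), logical(1))
    data.frame(seq = suppressWarnings(as.character(fq))[keep],
               count = rep(1, sum(keep)),
               stringsAsFactors = FALSE)
  } else {
    fa <- Biostrings::readBStringSet(path, format = "fasta")
    seqs <- chartr("U", "T", toupper(as.character(fa)))
    counts <- .parse_count_suffix(names(fa))
    if (dialect == "collapsed" && anyNA(counts)) {
      stop("collapsed-FASTA dialect forced but header(s) lack a parsable ",
           "count suffix in ", path)
    }
    if (dialect == "plain") counts[] <- NA_real_
    counts[is.na(counts)] <- 1
    data.frame(seq = unname(seqs), count = counts, stringsAsFactors = FALSE)
  }
}

#' Collapse small RNA reads to unique sequences
#'
#' Reads FASTQ and/or (collapsed) FASTA small RNA files and collapses them to
#' unique sequences with summed abundances.  FASTQ reads containing any base
#' below Q20 (Phred+33) are discarded before adapter trimming.  When a
#' 3' adapter is given, it is located as the leftmost exact match of its
#' first 8 nt and the read is truncated there.  Reads outside
#' `[min_len, max_len]` after trimming are discarded.  Collapsed-FASTA
#' headers carrying a trailing `_x<count>` or `-<count>` are auto-detected
#' and their counts summed.
#'
#' @param paths Character vector of FASTQ/FASTA paths.
#' @param min_len,max_len Length window kept after trimming (nt).
#' @param adapter3 Optional 3' adapter sequence (`NULL` for none).
#' @param dialect `"auto"` (default), `"collapsed"` (count suffix required)
#'   or `"plain"` (header suffixes ignored).
#' @param min_quality Minimum Phred score; any lower base drops the read.
#' @return A data.frame with columns `seq` and `count`, ordered by
#'   decreasing count then sequence.
#' @export
collapse_reads <- function(paths, min_len = 18L, max_len = 30L,
                           adapter3 = NULL, dialect = "auto",
                           min_quality = 20L) {
  parts <- lapply(paths, .read_srna_file, dialect = dialect,
                  min_quality = min_quality)
  reads <- do.call(rbind, parts)
  if (is.null(reads) || nrow(reads) == 0L) {
    return(data.frame(seq = character(), count = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (!is.null(adapter3) && nzchar(adapter3)) {
    key <- toupper(substr(chartr("U", "T", adapter3), 1L, 8L))
    hit <- regexpr(key, reads$seq, fixed = TRUE)
    trim <- as.integer(hit) > 0L
    reads$seq[trim] <- substr(reads$seq[trim], 1L, as.integer(hit)[trim] - 1L)
  }
  len <- nchar(reads$seq)
  reads <- reads[len >= min_len & len <= max_len, , drop = FALSE]
  if (nrow(reads) == 0L) {
    return(data.frame(seq = character(), count = numeric(),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(count ~ seq, data = reads, FUN = sum)
  agg <- agg[order(-agg$count, agg$seq), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

# empty mapped-read table with the canonical column set
.empty_mapped <- function() {
  data.frame(seq = character(), count = numeric(),
             transcript_id = character(), start = integer(),
             strand = character(), len = integer(),
             stringsAsFactors = FALSE)
}

# Exact full-length matches of constant-width patterns on one strand.
# Small pattern sets use base fixed-string search (no per-call index build);
# large sets build a Biostrings PDict (Aho-Corasick) once and stream the
# transcripts through it.  Both paths return identical hit tables.
.match_width_group <- function(seqs, transcripts, strand,
                               pdict_threshold = 100L) {
  pats <- if (strand == "antisense") revcomp(seqs) else seqs
  ok <- !grepl("[^ACGT]", pats)
  if (!any(ok)) return(NULL)
  idx <- which(ok)
  tx_names <- names(transcripts)
  if (length(idx) < pdict_threshold) {
    txt <- as.character(transcripts)
    out <- list()
    for (i in idx) {
      g <- gregexpr(pats[i], txt, fixed = TRUE, useBytes = TRUE)
      for (ti in seq_along(g)) {
        st <- g[[ti]]
        if (st[1L] == -1L) next
        out[[length(out) + 1L]] <- data.frame(
          read_i = i, transcript_id = tx_names[ti],
          start = as.integer(st) - 1L, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
    return(if (length(out) > 0L) do.call(rbind, out) else NULL)
  }
  # one matchPDict call over all transcripts concatenated with N spacers
  # (patterns are N-free, so no match can bridge two transcripts)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats[idx]))
  spacer <- max(nchar(pats)) + 1L
  w <- Biostrings::width(transcripts)
  offsets <- cumsum(c(0L, utils::head(w + spacer, -1L)))   # 0-based starts
  big <- Biostrings::DNAString(paste(as.character(transcripts),
                                     collapse = strrep("N", spacer)))
  m <- Biostrings::matchPDict(pd, big)
  starts <- IRanges::start(m)             # IntegerList, one element per pattern
  nhit <- lengths(starts)
  if (sum(nhit) == 0L) return(NULL)
  g <- unlist(starts, use.names = FALSE) - 1L              # 0-based global
  ti <- findInterval(g, offsets)
  data.frame(read_i = rep(idx, nhit),
             transcript_id = tx_names[ti],
             start = g - offsets[ti],
             strand = strand,
             stringsAsFactors = FALSE)
}

#' Exact-match alignment of unique reads to a transcriptome
#'
#' Reports every exact, full-length occurrence of each unique read on the
#' sense strand, and of its reverse complement (reported as
#' `strand = "antisense"`), across all transcripts.  Coordinates are 0-based
#' half-open on the sense strand.  Multi-mapping reads are reported at every
#' location; with `multimap = "unique"` reads with more than one placement
#' are dropped entirely.
#'
#' @param reads data.frame with `seq` and `count` (from [collapse_reads()]).
#' @param transcripts Named [Biostrings::DNAStringSet].
#' @param multimap `"all"` (default) or `"unique"`.
#' @return data.frame of mapped reads: `seq`, `count`, `transcript_id`,
#'   `start`, `strand`, `len`.
#' @export
align_exact <- function(reads, transcripts, multimap = c("all", "unique")) {
  multimap <- match.arg(multimap)
  if (nrow(reads) == 0L || length(transcripts) == 0L) return(.empty_mapped())
  hits <- list()
  for (w in sort(unique(nchar(reads$seq)))) {
    sel <- which(nchar(reads$seq) == w)
    for (strand in c("sense", "antisense")) {
      h <- .match_width_group(reads$seq[sel], transcripts, strand)
      if (!is.null(h)) {
        h$read_i <- sel[h$read_i]
        hits[[length(hits) + 1L]] <- h
      }
    }
  }
  if (length(hits) == 0L) return(.empty_mapped())
  hits <- do.call(rbind, hits)
  if (multimap == "unique") {
    n_per_read <- table(hits$read_i)
    keep <- hits$read_i %in% as.integer(names(n_per_read)[n_per_read == 1L])
    hits <- hits[keep, , drop = FALSE]
  }
  out <- data.frame(
    seq = reads$seq[hits$read_i],
    count = reads$count[hits$read_i],
    transcript_id = hits$transcript_id,
    start = hits$start,
    strand = hits$strand,
    len = nchar(reads$seq[hits$read_i]),
    stringsAsFactors = FALSE)
  out <- out[order(out$transcript_id, out$start, out$strand, out$seq), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Import small RNA alignments from a SAM file
#'
#' Converts primary and secondary alignments with `NM == 0` and a
#' full-length match (`<len>M` CIGAR) into the mapped-read table used by the
#' phasing scan.  FLAG 16 becomes `strand = "antisense"`; 1-based `POS` is
#' converted to a 0-based start.  Soft-clipped or gapped records are skipped
#' and counted.  Read abundances are taken from a `_x<count>`/`-<count>`
#' suffix on the query name when present, else 1, and records for the same
#' sequence are collapsed by summing counts per unique sequence first.
#'
#' @param path SAM file with headers (`@SQ` lines).
#' @param transcripts Named [Biostrings::DNAStringSet]; reference names must
#'   be a subset of its names.
#' @return data.frame as [align_exact()], with an attribute
#'   `"skipped"` giving the number of non-full-length records skipped.
#' @export
import_sam <- function(path, transcripts) {
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  rec <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(rec$pos)
  if (n == 0L) {
    out <- .empty_mapped()
    attr(out, "skipped") <- 0L
    return(out)
  }
  rname <- as.character(rec$rname)
  unknown <- setdiff(unique(rname), names(transcripts))
  if (length(unknown) > 0L) {
    stop("SAM reference(s) not in transcriptome: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }
  seqs <- as.character(rec$seq)
  qlen <- nchar(seqs)
  full <- rec$cigar == paste0(qlen, "M")
  nm <- rec$tag$NM
  nm0 <- !is.na(nm) & nm == 0L
  keep <- full & nm0
  skipped <- sum(!full)
  anti <- bitwAnd(rec$flag, 16L) != 0L
  # BAM stores the read as aligned to the forward reference strand; recover
  # the original read sequence for antisense placements
  read_seq <- seqs
  read_seq[anti] <- revcomp(seqs[anti])
  counts <- .parse_count_suffix(rec$qname)
  counts[is.na(counts)] <- 1
  out <- data.frame(
    seq = read_seq[keep],
    count = counts[keep],
    transcript_id = rname[keep],
    start = rec$pos[keep] - 1L,
    strand = ifelse(anti[keep], "antisense", "sense"),
    len = qlen[keep],
    stringsAsFactors = FALSE)
  # one count per unique sequence: de-duplicate repeated (seq, placement)
  out <- unique(out)
  out <- out[order(out$transcript_id, out$start, out$strand, out$seq), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Verify mapped reads against the transcript sequence
#'
#' Checks the placement invariant: a sense read equals the covered transcript
#' interval; an antisense read equals its reverse complement.
#'
#' @param mapped Mapped-read data.frame.
#' @param transcripts Named [Biostrings::DNAStringSet].
#' @return Logical vector, one per row.
#' @export
verify_mapped <- function(mapped, transcripts) {
  if (nrow(mapped) == 0L) return(logical(0))
  txt <- as.character(transcripts)[mapped$transcript_id]
  window <- substr(txt, mapped$start + 1L, mapped$start + mapped$len)
  ifelse(mapped$strand == "sense", mapped$seq == window,
         mapped$seq == revcomp(window))
}
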