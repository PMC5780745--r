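# Fixture builders shared across test files.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

as_dss <- function(...) {
  x <- c(...)
  out <- Biostrings::DNAStringSet(unname(unlist(x)))
  names(out) <- names(x)
  out
}

# a mapped-read row in the canonical column order
mapped_row <- function(seq, count, transcript_id, start, strand) {
  data.frame(seq = seq, count = count, transcript_id = transcript_id,
             start = as.integer(start), strand = strand, len = nchar(seq),
             stringsAsFactors = FALSE)
}

# n_phased distinct 21-mers stacked head-to-tail from position a
phased_stack <- function(a, n_phased, p = 21L, tx = "t1", count = 10,
                         seed = 99) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_phased), function(i) {
    mapped_row(random_dna(p), count, tx, a + (i - 1L) * p, "sense")
  }))
}

profile_at <- function(pos, count, tx = "t1") {
  data.frame(transcript_id = rep_len(tx, length(pos)),
             pos = as.integer(pos), count = count,
             stringsAsFactors = FALSE)
}

# 2x2 grid fixture crossing (valid degradome reads) x (< 4 mismatches):
# q1 pairs with 0 mismatches and has a degradome peak, q2 pairs with 0
# mismatches and no peak, q3 has 4 mismatches and a peak, q4 has 4
# mismatches and no peak.
grid_world <- function() {
  set.seed(107)
  qs <- replicate(4, random_dna(21))
  mutate <- function(q, nmut) {
    site <- revcomp(q)
    sb <- strsplit(site, "")[[1]]
    qb <- strsplit(q, "")[[1]]
    jj <- c(2L, 4L, 6L, 8L)[seq_len(nmut)]
    sb[21L - jj + 1L] <- qb[jj]     # target base := query base -> mismatch
    paste(sb, collapse = "")
  }
  sites <- c(mutate(qs[1], 0), mutate(qs[2], 0), mutate(qs[3], 4),
             mutate(qs[4], 4))
  tx_seq <- paste0(random_dna(40),
                   paste0(sites, collapse = random_dna(30)), random_dna(40))
  starts <- 40L + (0:3) * (21L + 30L)
  tx <- as_dss(t1 = tx_seq)
  deg_pos <- starts + 21L - 10L               # opposite position 10
  prof <- profile_at(deg_pos[c(1, 3)], c(10, 10))
  list(qs = qs, tx = tx, prof = prof, starts = starts)
}

write_fasta_lines <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}

write_fastq <- function(seqs, quals) {
  f <- tempfile(fileext = ".fq")
  writeLines(as.vector(rbind(paste0("@r", seq_along(seqs)), seqs, "+",
                             quals)), f)
  f
}
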