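# Result writers: loci TSV, phasiRNA FASTA, GFF3, targets TSV.
# Coordinates are 0-based half-open internally and 1-based inclusive in all
# text outputs.

#' Write called loci as TSV
#'
#' @param loci [call_loci()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci_tsv <- function(loci, path) {
  out <- data.frame(name = loci$name, transcript = loci$transcript_id,
                    start = loci$start + 1L, end = loci$end,
                    p = loci$p, k = loci$k, n = loci$n,
                    max_phase_score = loci$max_phase_score,
                    p_value = loci$min_p_value, fdr = loci$fdr,
                    best_window_start = loci$best_window_start + 1L,
                    register = loci$best_register,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write phasiRNAs as FASTA
#'
#' Headers carry the phasiRNA name and the abundance as a `count=` attribute.
#'
#' @param phasirnas [extract_phasirnas()] output (row-bound).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phasirna_fasta <- function(phasirnas, path) {
  set <- Biostrings::DNAStringSet(phasirnas$seq)
  names(set) <- sprintf("%s count=%g", phasirnas$name, phasirnas$abundance)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write loci and phasiRNAs as GFF3
#'
#' Loci are emitted as `siRNA_locus` features and phasiRNAs as `siRNA`
#' features with a `Parent` attribute.
#'
#' @param loci,phasirnas Locus and phasiRNA tables.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(loci, phasirnas, path) {
  if (nrow(loci) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr_loci <- GenomicRanges::GRanges(
    seqnames = loci$transcript_id,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = "+",
    type = "siRNA_locus", source = "phasr",
    ID = loci$name,
    score = loci$max_phase_score)
  gr <- gr_loci
  if (nrow(phasirnas) > 0L) {
    gr_si <- GenomicRanges::GRanges(
      seqnames = phasirnas$transcript_id,
      ranges = IRanges::IRanges(start = phasirnas$position + 1L,
                                width = phasirnas$length),
      strand = ifelse(phasirnas$strand == "sense", "+", "-"),
      type = "siRNA", source = "phasr",
      ID = phasirnas$name,
      score = phasirnas$abundance)
    gr_si$Parent <- phasirnas$locus_name
    gr <- suppressWarnings(c(gr, gr_si))
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write target calls as TSV
#'
#' @param calls [call_triggers()] or [call_phasirna_targets()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_targets_tsv <- function(calls, path) {
  out <- calls
  if (nrow(out) > 0L) {
    out$site_start <- out$site_start + 1L   # 1-based inclusive on output
    out$cleavage_position <- out$cleavage_position + 1L
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
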