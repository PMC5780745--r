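---
title: "Detecting PHAS loci and phasiRNAs with phasr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting PHAS loci and phasiRNAs with phasr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasr)
```

## The problem

Phased secondary siRNAs (phasiRNAs) are plant small RNAs produced when a
miRNA cleaves a precursor transcript, RDR6 converts one cleavage product to
double-stranded RNA, and a Dicer-like enzyme chops it into consecutive 21-
or 24-nt duplexes. Because dicing starts at the cleavage point, the
resulting reads stack head-to-tail: their 5' ends share a residue class
modulo the cycle length *p*. A transcript region producing such reads is a
PHAS locus, and the shared residue class is its *register*. `phasr` finds
these loci on a transcriptome from small RNA reads, and uses degradome
(PARE) 5'-end data to identify the trigger miRNA of each locus and the
targets of its phasiRNAs.

## The window statistics

Reads are first collapsed to unique sequences with summed counts and placed
on the transcripts by exact, full-length matching on both strands. A read
on the antisense strand is assigned an *effective position* `start + 2`:
Dicer duplexes carry 2-nt 3' overhangs, so the antisense partner of a
duplex starting at `s` covers `[s - 2, s + p - 2)` and the +2 offset puts
both partners in the same register.

Candidate windows span `m` cycles (default `m = 10`, i.e. 210 or 240 nt)
and are anchored at every distinct effective position of a length-*p* read.
Anchoring at every nucleotide instead would add only windows with zero
in-register reads, so the result set is identical at far lower cost. Within
a window only reads of length exactly *p* are visible to the statistic:

* `k` — unique sequences whose effective position is congruent to the
  anchor (mod *p*),
* `n` — all unique length-*p* sequences in the window,
* `sum_P` / `sum_U` — summed abundance of the in-register and off-register
  reads.

The window P-value is the upper tail of a hypergeometric distribution: the
probability that, when `n` distinct positions are occupied among the
`p * m` positions of the window of which `m` are in register, at least `k`
fall in register,

$$P(X \ge k) \;=\; \sum_{x=k}^{\min(m,n)}
  \frac{\binom{m}{x}\binom{(p-1)m}{\,n-x\,}}{\binom{pm}{n}}.$$

With `p = 21` the numerator constants are the familiar `20m` and `21m`;
keeping them as `(p-1)m` and `pm` lets the same code scan 24-nt loci. The
phase score of a window is

$$\mathrm{score} \;=\; (k-2)\,
  \ln\!\left(1 + m\,\frac{\sum_i P_i}{1+\sum_i U_i}\right),$$

reported as 0 when `k < 3` — the score is only meaningful with at least
three independent phased sequences, and reporting 0 rather than `NA` keeps
thresholding total. The multiplier is `m` (10 by default), which matches
the constant 10 used in the 10-cycle formulation.

Degenerate inputs are handled by clamping to the model's domain: a window
can in principle hold more than `m` unique phased sequences (several
distinct reads on one position) or more than `p * m` unique sequences; `k`
and `n` are capped at `m` and `p * m` for the P-value only, the reported
counts keep their raw values.

## From windows to loci

Windows with raw `P < 0.05` are extended 100 bp on both sides, clipped to
the transcript, and transitively overlapping intervals are merged. Each
merged region keeps the minimum raw P-value of its member windows and the
anchor/register of the best-scoring member (ties broken by lower P, then by
leftmost anchor). Benjamini–Hochberg correction is applied across all
merged regions of the run — the merged region, not the window, is the unit
of multiple testing, and its test statistic is its minimum member P-value.
Regions with a maximal phase score of at least 5 and corrected `P < 0.05`
become loci.

Loci are named `P<p>_<transcript>_<serial>` with serials assigned per
transcript in coordinate order and `|` in transcript ids replaced by `_`
(so `TR101427|c8_g4_i1` yields `P21_TR101427_c8_g4_i1_1`). Every length-*p*
read inside a locus whose effective position matches the register is
reported as a phasiRNA named `<locus>_siR<serial>`, numbered 5'→3' with
sense reads before antisense at equal positions. The 21- and 24-nt scans
run independently; a transcript may host loci of both classes.

## Degradome support

PARE tags (the 5'-most 20 nt of each read, configurable) are placed on the
sense strand by exact matching and their counts accumulated per 5'-end
position. Binding sites of a small RNA are found by an ungapped
complementarity scan of both strands; a mismatch is any non-Watson–Crick
pair, with G:U wobble counted as a full mismatch by default (a weight of
0.5 is available — the choice is a convention, not a measurement). No
gapped or bulged sites are considered.

For a site paired to the sense interval `[s, e)`, the transcript position
opposite small-RNA position `j` (1-based from its 5' end) is `e - j`. A
*valid read* is a degradome 5' end at positions opposite 9–11, and the
inferred cleavage position — between small-RNA positions 10 and 11 — is
`e - 10`. Sites on the antisense strand get zero valid reads by
construction: the degradome protocol sequences the polyadenylated sense
strand only.

Two filter rules are deliberately different:

* **miRNA triggers (OR):** a site is kept when it has at least one valid
  read *or* fewer than 4 mismatches. Conserved miRNAs may pair imperfectly
  yet show clear cleavage, and vice versa.
* **phasiRNA targets (AND):** a site is kept only with at least one valid
  read *and* fewer than 4 mismatches.

A trigger site is additionally flagged *trigger-consistent* when its
inferred cleavage position lies within one cycle length of the locus'
best-window anchor. The register alone cannot serve here: it is a residue
class, so every position is trivially within `p - 1` of it; the anchor of
the maximal-score window is the concrete position the cleavage should set.
Targets on the phasiRNA's own source transcript are `cis`, all others
`trans`, and the two counts always partition the calls.

## The simulator

`simulate_phas()` builds the complete test world: random transcripts of
configurable length and GC content; per locus a trigger miRNA whose
complementary site is written into the sequence such that the cleavage
position equals the locus start (which therefore defines the register, with
any configured site mismatches implanted away from positions 9–11);
head-to-tail sense/antisense duplexes with geometrically decaying abundance
(ratio 0.7 by default, a plausible decay for phasiRNA stacks, chosen once
as a simulation knob rather than a biological claim); background reads
sampled from the transcript itself in lengths 20/21/22/24 so that the
length-*p* filter is exercised, a configured fraction of them placed
off-register inside loci; and a degradome with a peak of configured height
at each cleavage site plus Poisson background. The truth table records
every implanted locus, its register, phasiRNA sequences, trigger and
cleavage position.

What the simulator does *not* model: sequencing errors, expression-level
realism, isoforms/splicing, multi-locus transcripts, RNA structure, and
partial degradation of precursors. Passing the recovery benchmarks
therefore shows the statistics and plumbing are correct under the stated
geometry and noise, not that real libraries will behave as cleanly.

Loci are placed so that a full default-width scan window (10 cycles) fits
at the locus anchor — without that margin a locus near the 3' end would be
undetectable by construction, which would measure geometry rather than
method. Determinism is part of the contract: a fixed seed yields
byte-identical output files, and the simulator restores the caller's RNG
state.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `p` | 21 (and 24) | cycle length, nt |
| `m` | 10 | cycles per window; window spans `p*m` nt |
| `window_p` | 0.05 | raw P to extend/merge a window |
| `extension` | 100 nt | flank added before merging |
| `min_phase_score` | 5 | locus score threshold |
| `alpha` | 0.05 | threshold on BH-corrected P |
| `min_unique_phased` | 3 | `k` gate for a non-zero score |
| `multimap` | `all` | multi-mappers count at every site (or `unique`) |
| `gu_weight` | 1 | mismatch weight of a G:U pair |
| `tag_length` | 20 nt | degradome tag prefix used for matching |

Multi-mapping reads contribute their full count at every placement by
default; `unique` mode drops them entirely. Raw summed counts are used for
`sum_P`/`sum_U` — per-library normalized abundances are carried by the I/O
layer for reporting but never enter the statistics, since the scoring as
defined operates on read counts.

## Problem sizes used in the checks

The bundled checks run the full pipeline on 200 seeded replicates (three
1.2–1.6 kb transcripts, one implanted 21-nt locus of six duplexes, six
background reads per transcript, degradome peak:background 10:1) and
require ≥95% locus recovery with the correct register and ≥95% trigger
recovery; a null control with 500 × 2 kb transcripts at 50 uniform
background reads each must call loci on at most 1% of transcripts. These
sizes were chosen as the smallest worlds in which every code path
(multi-length noise, antisense placements, off-register contamination,
degradome background) is exercised.

## Known limitations

* Transcriptome mode only: no genome scanning, no splice awareness.
* Exact, zero-mismatch small-RNA alignment; a SNP between the sRNA library
  and the assembly hides a read from the scan.
* The complementarity scan is ungapped; bulged miRNA sites are missed.
* The degradome valid-read criterion is implemented as stated (positions
  9–11, ≥1 read); no T-plot categories or site-level statistics beyond it.
* Locus boundaries come from window extension/merging and so overshoot the
  true duplex span by up to `extension` on each side.
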