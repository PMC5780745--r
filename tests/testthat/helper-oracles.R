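# Independent oracles used across the suite.

# Upper-tail hypergeometric by direct enumeration of the tail terms
# sum_{x=k}^{min(m,n)} C(m,x) C((p-1)m, n-x) / C(pm, n), in log space.
# Independent of stats::phyper.
hyper_tail_enum <- function(k, n, m, p) {
  if (k == 0L) return(1)
  xs <- k:min(m, n)
  xs <- xs[n - xs <= (p - 1L) * m]
  if (length(xs) == 0L) return(0)
  sum(exp(lchoose(m, xs) + lchoose((p - 1L) * m, n - xs) -
            lchoose(p * m, n)))
}

# Same tail computed with exact rational arithmetic through the system
# python3's fractions module; returns numeric vector, one per (k, n) pair.
# p and m are scalars.
hyper_tail_exact_py <- function(k, n, m, p) {
  stopifnot(length(k) == length(n))
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  stopifnot(nzchar(py))
  script <- '
import sys
from fractions import Fraction
from math import comb
m, p = int(sys.argv[1]), int(sys.argv[2])
for line in sys.stdin:
    k, n = map(int, line.split())
    tot = comb(p * m, n)
    tail = sum(comb(m, x) * comb((p - 1) * m, n - x)
               for x in range(k, min(m, n) + 1))
    print(float(Fraction(tail, tot)))
'
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  on.exit(unlink(sf))
  out <- system2(py, c(sf, m, p), stdout = TRUE,
                 input = paste(k, n))
  as.numeric(out)
}

# geometry of a Dicer duplex with 2-nt 3' overhangs: the sense strand
# covers [s, s+p) and the antisense partner covers [s-2, s+p-2)
duplex_placements <- function(s, p) {
  data.frame(start = c(s, s - 2L), strand = c("sense", "antisense"),
             len = p)
}
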