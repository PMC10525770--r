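# Complex-argument Bessel functions J0, J1 by power series.
# Base R's besselJ is real-only; the Womersley solution needs J at
# z = i^(3/2) * alpha with alpha up to ~30 for the harmonics in play.
# The alternating series loses ~|Im z| digits to cancellation, which still
# leaves ~1e-8 relative accuracy at the largest Womersley numbers used here.

.besselJ0_complex <- function(z) {
  z <- as.complex(z)
  term <- rep(1 + 0i, length(z))
  s <- term
  q <- -(z / 2)^2
  for (k in 1:80) {
    term <- term * q / k^2
    s <- s + term
    if (all(Mod(term) < 1e-18 * pmax(Mod(s), 1e-300))) break
  }
  s
}

.besselJ1_complex <- function(z) {
  z <- as.complex(z)
  term <- z / 2
  s <- term
  q <- -(z / 2)^2
  for (k in 1:80) {
    term <- term * q / (k * (k + 1))
    s <- s + term
    if (all(Mod(term) < 1e-18 * pmax(Mod(s), 1e-300))) break
  }
  s
}
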