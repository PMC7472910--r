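# Constant-probability observers used throughout the staircase tests.
obs_const <- function(p) function(d) p

# Brute-force Fisher oracle: enumerate every table with the observed margins
# and sum the conditional probabilities of the upper tail, straight from the
# factorial formula (independent of phyper).
fisher_enum_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; N <- m1 + m2
  xs <- max(0, k - m2):min(k, m1)
  pr <- vapply(xs, function(x) {
    exp(lfactorial(m1) + lfactorial(m2) + lfactorial(k) + lfactorial(N - k) -
          lfactorial(N) - lfactorial(x) - lfactorial(m1 - x) -
          lfactorial(k - x) - lfactorial(m2 - k + x))
  }, numeric(1))
  sum(pr[xs >= a])
}
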