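# Brute-force oracles kept deliberately independent of the package internals.

# Order parameter by direct complex summation
brute_force_z <- function(phi, n) {
  s <- 0 + 0i
  for (p in phi) s <- s + complex(modulus = 1, argument = n * p)
  s / length(phi)
}

# Phase unwrapping used only to measure slopes in tests
unwrap_for_test <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  cumsum(c(p[1], dp))
}

# Rand index by explicit enumeration of all pairs
enumerate_rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0L
  total <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + 1L
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a == same_b) agree <- agree + 1L
    }
  }
  agree / total
}
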