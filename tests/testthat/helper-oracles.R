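# Independent brute-force oracles, kept free of the code paths they check.

# Expected firing count by exhaustive enumeration of the 2^n on/off
# configurations of effective (active and un-vetoed) dendritic inputs, each
# dendrite effective with probability (1 - p_veto) * x / y.
enum_expected_firing <- function(x, p_veto, n = 4, m = 3, y = 100, N = 8750) {
  q <- (1 - p_veto) * x / y
  total <- 0
  for (bits in 0:(2^n - 1)) {
    on <- sum(bitwAnd(bits, 2^(0:(n - 1))) > 0)
    if (on >= m) total <- total + q^on * (1 - q)^(n - on)
  }
  N * total
}

# Hypergeometric tail P(at least `min_hits` of the x active mossy fibers in a
# draw of `contacts` from y) by direct summation of the mass function.
enum_hyper_tail <- function(x, contacts, min_hits, y = 100) {
  js <- min_hits:min(contacts, x)
  if (length(js) == 0 || min_hits > x) return(0)
  sum(choose(x, js) * choose(y - x, contacts - js)) / choose(y, contacts)
}

# Binomial overlap spectrum by exhaustive enumeration of the 2^n membership
# vectors of a synapse across n other patterns.
enum_overlap_spectrum <- function(n_other, p) {
  if (n_other == 0) return(1)
  props <- numeric(n_other + 1)
  for (bits in 0:(2^n_other - 1)) {
    k <- sum(bitwAnd(bits, 2^(0:(n_other - 1))) > 0)
    props[k + 1] <- props[k + 1] + p^k * (1 - p)^(n_other - k)
  }
  props
}

total_variation <- function(p, q) sum(abs(p - q)) / 2
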