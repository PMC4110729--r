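# Shared fixtures and independent oracles, all built in code.

# two-gene toggle: each gene is the NOT of the other
toggle_network <- function() {
  boolean_network(inputs = list(2L, 1L),
                  truth_tables = list(c(1L, 0L), c(1L, 0L)),
                  node_names = c("g1", "g2"))
}

# one-gene identity: D(0) = 0, D(1) = 1
identity_network <- function() {
  boolean_network(inputs = list(1L), truth_tables = list(c(0L, 1L)))
}

# every truth table all-zero: D is the constant map to state 0
constant_network <- function(n = 3L) {
  boolean_network(inputs = lapply(seq_len(n), function(i) i),
                  truth_tables = rep(list(c(0L, 0L)), n))
}

# ring of copy gates: node i takes the value node i-1 had
copy_chain_network <- function(n = 4L) {
  boolean_network(inputs = as.list(c(n, seq_len(n - 1L))),
                  truth_tables = rep(list(c(0L, 1L)), n))
}

# a random small network with at least `min_attractors` attractors
random_multiattractor_net <- function(n, q = 2L, min_attractors = 2L,
                                      max_tries = 500L) {
  for (i in seq_len(max_tries)) {
    net <- generate_critical_rbn(n, q)
    if (length(find_attractors(net)) >= min_attractors) return(net)
  }
  stop("no multi-attractor network found")
}

# Independent brute-force oracle for the noisy one-step kernel: enumerate
# every flip mask; an all-zero mask takes the deterministic step, any other
# mask jumps to the flipped state. Uses intToBits, not the package's
# bit helpers or Hamming-matrix construction.
brute_force_transition <- function(net, p_e) {
  n <- net$n
  N <- 2L^n
  Dm <- vapply(0:(N - 1L), function(s) synchronous_update(net, s), integer(1))
  P <- matrix(0, N, N)
  for (x in 0:(N - 1L)) {
    for (m in 0:(N - 1L)) {
      h <- sum(as.integer(intToBits(m)))
      dest <- if (m == 0L) Dm[x + 1L] else bitwXor(x, m)
      P[x + 1L, dest + 1L] <- P[x + 1L, dest + 1L] + p_e^h * (1 - p_e)^(n - h)
    }
  }
  P
}
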