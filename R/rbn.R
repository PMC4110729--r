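#' Network sensitivity of a random Boolean network ensemble
#'
#' For networks where every node has `q` inputs and each truth-table entry is
#' 1 with probability `p_N`, the expected number of nodes affected by a
#' single-bit perturbation after one step is `s = 2 q p_N (1 - p_N)`. At
#' `s = 1` the network is *critical*: a flipped bit is propagated on average
#' to exactly one other node, the boundary between the ordered (`s < 1`,
#' perturbations die out) and chaotic (`s > 1`, perturbations grow) regimes.
#'
#' @param q in-degree per node (integer >= 1).
#' @param p_N probability that a truth-table entry is 1, in (0, 1).
#' @return The sensitivity `s` as a number.
#' @examples
#' sensitivity(q = 2, p_N = 0.5)  # 1: the critical point
#' @export
sensitivity <- function(q, p_N) {
  if (!is.numeric(q) || length(q) != 1L || q < 1 || q != round(q)) {
    stop("'q' must be a single integer >= 1")
  }
  if (!is.numeric(p_N) || length(p_N) != 1L || p_N <= 0 || p_N >= 1) {
    stop("'p_N' must lie strictly in (0, 1)")
  }
  2 * q * p_N * (1 - p_N)
}

#' Truth-table bias that makes a given in-degree critical
#'
#' Solves `2 q p (1 - p) = 1` for the bias `p`, so that
#' `sensitivity(q, critical_bias(q)) == 1`. The quadratic has two roots
#' symmetric about 1/2; the lower root (sparse expression) is returned by
#' default. For `q = 1` the sensitivity cannot exceed 1/2, so no critical
#' bias exists; `p = 0.5` (the maximizer) is returned with a warning.
#'
#' @param q in-degree (integer >= 1).
#' @param branch_root `"lower"` (default) or `"upper"` root of the quadratic.
#' @return The bias `p_N` in (0, 1).
#' @examples
#' critical_bias(2)  # 0.5 (double root)
#' critical_bias(4)  # ~0.1464
#' @export
critical_bias <- function(q, branch_root = c("lower", "upper")) {
  branch_root <- match.arg(branch_root)
  if (!is.numeric(q) || length(q) != 1L || q < 1 || q != round(q)) {
    stop("'q' must be a single integer >= 1")
  }
  if (q == 1) {
    warning("no bias achieves s = 1 at q = 1 (maximum s = 0.5); returning 0.5")
    return(0.5)
  }
  disc <- 1 - 2 / q
  p <- (1 - sqrt(disc)) / 2
  if (branch_root == "upper") p <- 1 - p
  p
}

#' Generate a random Boolean network in the critical regime
#'
#' Each node receives `q` distinct input nodes sampled uniformly (optionally
#' including itself) and a truth table whose entries are independent
#' Bernoulli(`p_N`) draws. With `p_N = critical_bias(q)` (the default) the
#' resulting ensemble sits on the critical line `s = 1`.
#'
#' Randomness is taken from R's global RNG; call `set.seed()` (or pass
#' `seed`) for reproducible networks.
#'
#' @param n node count.
#' @param q in-degree per node.
#' @param p_N truth-table bias; defaults to `critical_bias(q)`.
#' @param allow_self_input may a node be its own input? Default `TRUE`.
#' @param seed optional integer; if given, `set.seed(seed)` is called first.
#' @param node_names optional node identifiers.
#' @return A [boolean_network()].
#' @examples
#' net <- generate_critical_rbn(n = 8, q = 2, seed = 1)
#' length(find_attractors(net))
#' @export
generate_critical_rbn <- function(n, q, p_N = NULL,
                                  allow_self_input = TRUE,
                                  seed = NULL, node_names = NULL) {
  stopifnot(n >= 1, q >= 1)
  if (is.null(p_N)) p_N <- critical_bias(q)
  if (p_N <= 0 || p_N >= 1) stop("'p_N' must lie strictly in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  avail <- if (allow_self_input) n else n - 1L
  if (q > avail) {
    stop("cannot wire q = ", q, " distinct inputs per node with n = ", n,
         if (!allow_self_input) " and self-inputs disallowed" else "")
  }
  inputs <- vector("list", n)
  tts <- vector("list", n)
  ntt <- bitwShiftL(1L, q)
  for (i in seq_len(n)) {
    cand <- if (allow_self_input) seq_len(n) else setdiff(seq_len(n), i)
    inputs[[i]] <- sample(cand, q)
    tts[[i]] <- as.integer(stats::rbinom(ntt, 1L, p_N))
  }
  boolean_network(inputs, tts, node_names)
}

#' Measure perturbation spread empirically (Derrida one-step estimate)
#'
#' Monte-Carlo estimate of the analytic sensitivity: sample states `x`
#' uniformly, flip one uniformly chosen bit to get `x'`, and average the
#' Hamming distance between `D(x)` and `D(x')`. For critical networks the
#' ensemble mean converges to 1.
#'
#' @param net a [boolean_network()].
#' @param samples number of sampled (state, flip) pairs.
#' @return The mean one-step Hamming spread (a number).
#' @examples
#' set.seed(1)
#' net <- generate_critical_rbn(10, 2)
#' empirical_derrida_sensitivity(net, samples = 1000)
#' @export
empirical_derrida_sensitivity <- function(net, samples = 10000L) {
  stopifnot(inherits(net, "boolean_network"), samples >= 1)
  N <- bitwShiftL(1L, net$n)
  x <- sample.int(N, samples, replace = TRUE) - 1L
  bit <- sample.int(net$n, samples, replace = TRUE)
  xp <- bitwXor(x, bitwShiftL(1L, bit - 1L))
  mean(hamming_codes(apply_network(net, x), apply_network(net, xp), net$n))
}
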