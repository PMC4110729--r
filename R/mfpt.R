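#' Noisy state-transition matrix of a Boolean network
#'
#' Builds the row-stochastic `2^n x 2^n` Markov matrix of the network's
#' dynamics under uniform per-gene flip noise. In one time step, with
#' probability `(1 - p_e)^n` no gene flips and the deterministic update `D`
#' is taken; otherwise the state jumps directly to the perturbed state, a
#' pattern of `h >= 1` flips occurring with the binomial weight
#' `p_e^h (1 - p_e)^(n - h)`. Hence for `y != x`
#' `p_xy = p_e^h_xy (1 - p_e)^(n - h_xy) + (1 - p_e)^n [y = D(x)]`,
#' and the only self-mass is `(1 - p_e)^n` when `x` is a fixed point of `D`.
#' Rows sum to 1 exactly; for `0 < p_e < 1` the flip kernel has full support
#' so the chain is irreducible and every passage time below is finite.
#'
#' @param net a [boolean_network()].
#' @param p_e per-gene flip probability per step, in (0, 1).
#' @param cap refuse networks with more than `cap` nodes (default 12; the
#'   matrix is dense, `4^n` entries). Raising the cap is an explicit opt-in.
#' @return An object of class `noisy_transition_matrix`: list with `p` (the
#'   dense matrix, states in code order `0 .. 2^n - 1`), `p_e` and `n`.
#' @examples
#' idnet <- boolean_network(list(1L), list(c(0L, 1L)))  # 1-gene identity
#' transition_matrix(idnet, p_e = 0.1)$p                # rows (.9,.1)/(.1,.9)
#' @export
transition_matrix <- function(net, p_e, cap = 12L) {
  stopifnot(inherits(net, "boolean_network"))
  if (!is.numeric(p_e) || length(p_e) != 1L || p_e <= 0 || p_e >= 1) {
    stop("'p_e' must lie strictly in (0, 1)")
  }
  if (net$n > cap) {
    stop("dense 2^", net$n, " x 2^", net$n, " transition matrix exceeds the ",
         "cap (n <= ", cap, "); raise 'cap' explicitly to proceed")
  }
  n <- net$n
  N <- bitwShiftL(1L, n)
  codes <- 0:(N - 1L)
  pc <- popcount_table(n)
  H <- matrix(pc[bitwXor(rep(codes, times = N), rep(codes, each = N)) + 1L], N, N)
  P <- p_e^H * (1 - p_e)^(n - H)
  diag(P) <- 0                                   # h = 0 is not a flip event
  det_idx <- cbind(codes + 1L, apply_network(net, codes) + 1L)
  P[det_idx] <- P[det_idx] + (1 - p_e)^n
  structure(list(p = P, p_e = p_e, n = n), class = "noisy_transition_matrix")
}

#' @export
print.noisy_transition_matrix <- function(x, ...) {
  cat(sprintf("Noisy transition matrix: %d x %d states, p_e = %g\n",
              nrow(x$p), ncol(x$p), x$p_e))
  invisible(x)
}

#' First-passage probability at a given step
#'
#' `F_k(x, y)` is the probability that, starting from state `x`, the chain
#' visits state `y` for the first time at step `k`. The base case is
#' `F_1(x, y) = p_xy`; for `k >= 2` the recursion sums over intermediate
#' states that are not `y`:
#' `F_k(x, y) = sum_{z != y} p_xz F_{k-1}(z, y)`.
#'
#' @param tm a [transition_matrix()].
#' @param x,y integer state codes, `x != y`.
#' @param k step number (integer >= 1).
#' @return The probability `F_k(x, y)`.
#' @examples
#' idnet <- boolean_network(list(1L), list(c(0L, 1L)))
#' tm <- transition_matrix(idnet, 0.1)
#' first_passage_probability(tm, 0L, 1L, 1)  # 0.1
#' first_passage_probability(tm, 0L, 1L, 2)  # 0.9 * 0.1
#' @export
first_passage_probability <- function(tm, x, y, k) {
  stopifnot(inherits(tm, "noisy_transition_matrix"))
  if (k < 1 || k != round(k)) stop("'k' must be an integer >= 1")
  N <- nrow(tm$p)
  x <- as.integer(x); y <- as.integer(y)
  stopifnot(x >= 0L, x < N, y >= 0L, y < N, x != y)
  f <- tm$p[, y + 1L]          # F_1(., y)
  if (k > 1) {
    Pq <- tm$p
    Pq[, y + 1L] <- 0          # exclude paths through y
    for (i in seq_len(k - 1L)) f <- as.vector(Pq %*% f)
  }
  f[x + 1L]
}

# mean hitting times of 'target' (0-based codes) from every state;
# exact solve of m = 1 + P[,-T] m restricted to non-target states
hitting_times <- function(tm, target) {
  N <- nrow(tm$p)
  target <- as.integer(target)
  keep <- setdiff(seq_len(N), target + 1L)
  A <- -tm$p[keep, keep, drop = FALSE]
  diag(A) <- diag(A) + 1
  m <- tryCatch(solve(A, rep(1, length(keep))),
                error = function(e) stop("target set unreachable: hitting-",
                                         "time system is singular (",
                                         conditionMessage(e), ")"))
  out <- numeric(N)
  out[keep] <- m
  out
}

#' Mean first passage time between state sets
#'
#' Exact mean number of noisy steps until the chain first enters
#' `target_states`, starting uniformly over `source_states`. Computed by
#' solving the absorbing-chain linear system
#' `m_x = 1 + sum_{z not in target} p_xz m_z`, which equals the series
#' `sum_k k F_k` of the first-passage distribution.
#'
#' @param tm a [transition_matrix()].
#' @param source_states,target_states disjoint nonempty sets of integer
#'   state codes.
#' @return The MFPT (a number; average over source states).
#' @examples
#' idnet <- boolean_network(list(1L), list(c(0L, 1L)))
#' mfpt_states(transition_matrix(idnet, 0.1), 0L, 1L)  # 1 / p_e = 10
#' @export
mfpt_states <- function(tm, source_states, target_states) {
  stopifnot(inherits(tm, "noisy_transition_matrix"))
  source_states <- as.integer(source_states)
  target_states <- as.integer(target_states)
  if (length(source_states) == 0L || length(target_states) == 0L) {
    stop("source and target sets must be nonempty")
  }
  if (length(intersect(source_states, target_states)) > 0L) {
    stop("source and target sets must be disjoint")
  }
  m <- hitting_times(tm, target_states)
  mean(m[source_states + 1L])
}

#' Truncated-series MFPT (cross-validation oracle)
#'
#' Sums `k * F_k(x, target)` directly from the first-passage recursion.
#' This is a slow independent check of [mfpt_states()], not the production
#' path. Truncating when the undistributed tail *mass* is small is not
#' enough — that mass sits at steps of order `k`, contributing roughly
#' `tail * k` to the sum — so iteration continues until a geometric bound
#' on the remaining series (`tail * (k + 1 + r/(1-r))` with `r` the
#' observed tail decay ratio) drops below `tol`, or `K` terms are reached.
#'
#' @param tm a [transition_matrix()].
#' @param x source state code.
#' @param target_states target state codes (first entry to any counts).
#' @param K maximum number of terms (default `1e5`).
#' @param tol bound on the truncation error of the sum (default `1e-8`).
#' @return The truncated sum, with attributes `tail_mass` (first-passage
#'   mass beyond the truncation), `error_bound` and `terms`. Warns if the
#'   error bound still exceeds `tol` at `K`.
#' @export
mfpt_series_oracle <- function(tm, x, target_states, K = 1e5, tol = 1e-8) {
  stopifnot(inherits(tm, "noisy_transition_matrix"))
  N <- nrow(tm$p)
  x <- as.integer(x)
  target_states <- as.integer(target_states)
  stopifnot(x >= 0L, x < N, !(x %in% target_states))
  Pq <- tm$p
  tcol <- target_states + 1L
  f <- as.vector(rowSums(tm$p[, tcol, drop = FALSE]))  # F_1(., T)
  Pq[, tcol] <- 0
  total <- f[x + 1L]
  cum <- f[x + 1L]
  k <- 1L
  bound <- Inf
  while (k < K) {
    tail_prev <- 1 - cum
    f <- as.vector(Pq %*% f)
    k <- k + 1L
    total <- total + k * f[x + 1L]
    cum <- cum + f[x + 1L]
    tail <- 1 - cum
    if (tail <= 0) { bound <- 0; break }
    r <- tail / tail_prev
    if (r < 1) {
      bound <- tail * (k + 1 + r / (1 - r))
      if (bound < tol) break
    }
  }
  if (bound > tol) {
    warning(sprintf(
      "series truncated at K = %d with error bound %.3g > tol", k, bound))
  }
  structure(total, tail_mass = 1 - cum, error_bound = bound, terms = k)
}

#' Monte-Carlo MFPT (simulation oracle)
#'
#' Simulates the noisy process directly — per step, flip each gene
#' independently with probability `p_e`; if no gene flips apply the
#' deterministic update `D`, otherwise take the flipped state — and records
#' the number of steps until `target_states` is first hit. An independent
#' stochastic check of the analytic chain.
#'
#' @param net a [boolean_network()].
#' @param p_e per-gene flip probability.
#' @param source single starting state code.
#' @param target_states target state codes.
#' @param reps number of independent chains (default 1000).
#' @param max_steps per-chain step cap; chains still running are censored
#'   with a truncation warning (default `1e6`).
#' @return A list with `mean`, `stderr`, `reps` and `censored`.
#' @examples
#' idnet <- boolean_network(list(1L), list(c(0L, 1L)))
#' set.seed(1)
#' mfpt_monte_carlo(idnet, 0.1, 0L, 1L, reps = 500)$mean  # near 10
#' @export
mfpt_monte_carlo <- function(net, p_e, source, target_states,
                             reps = 1000L, max_steps = 1e6) {
  stopifnot(inherits(net, "boolean_network"), reps >= 1)
  n <- net$n
  N <- bitwShiftL(1L, n)
  source <- as.integer(source)
  target_states <- as.integer(target_states)
  stopifnot(length(source) == 1L, source >= 0L, source < N)
  Dm <- state_map(net)
  s <- rep(source, reps)
  steps <- integer(reps)
  active <- rep(TRUE, reps)
  t <- 0L
  while (any(active) && t < max_steps) {
    t <- t + 1L
    na <- sum(active)
    mask <- integer(na)
    for (b in seq_len(n)) {
      mask <- mask + bitwShiftL(as.integer(stats::runif(na) < p_e), b - 1L)
    }
    sa <- s[active]
    nz <- mask != 0L
    sa[!nz] <- Dm[sa[!nz] + 1L]
    sa[nz] <- bitwXor(sa[nz], mask[nz])
    s[active] <- sa
    hit <- active
    hit[active] <- sa %in% target_states
    steps[hit] <- t
    active[hit] <- FALSE
  }
  censored <- sum(active)
  if (censored > 0L) {
    warning(censored, " chain(s) did not reach the target within ",
            max_steps, " steps; estimate is truncated from below")
    steps[active] <- t
  }
  list(mean = mean(steps), stderr = stats::sd(steps) / sqrt(reps),
       reps = reps, censored = censored)
}

#' Pairwise mean first passage times between attractors
#'
#' Entry `(i, j)` is the exact mean number of noisy steps to first reach any
#' state of attractor `j`, starting uniformly over the states of attractor
#' `i`; the diagonal is 0 by convention. One linear solve per target
#' attractor yields all sources at once. Forward and reverse entries are in
#' general different — the asymmetry that encodes directional transitions —
#' while separations appear as large values in both directions.
#'
#' @param net a [boolean_network()].
#' @param p_e per-gene flip probability.
#' @param attractor_set an [find_attractors()] result for `net`; computed if
#'   missing.
#' @param tm optionally, a precomputed [transition_matrix()].
#' @param cap passed to [transition_matrix()].
#' @return An object of class `mfpt_matrix`: list with `values` (`k x k`
#'   numeric matrix), `attractor_set`, `p_e`.
#' @examples
#' toggle <- boolean_network(list(2L, 1L), list(c(1L, 0L), c(1L, 0L)))
#' attractor_mfpt_matrix(toggle, p_e = 0.05)
#' @export
attractor_mfpt_matrix <- function(net, p_e, attractor_set = NULL,
                                  tm = NULL, cap = 12L) {
  stopifnot(inherits(net, "boolean_network"))
  if (is.null(attractor_set)) attractor_set <- find_attractors(net)
  k <- length(attractor_set$attractors)
  if (k < 2L) stop("need at least 2 attractors for an MFPT matrix, got ", k)
  if (is.null(tm)) tm <- transition_matrix(net, p_e, cap = cap)
  M <- matrix(0, k, k)
  for (j in seq_len(k)) {
    m <- hitting_times(tm, attractor_set$attractors[[j]]$states)
    for (i in seq_len(k)) {
      if (i != j) M[i, j] <- mean(m[attractor_set$attractors[[i]]$states + 1L])
    }
  }
  ids <- paste0("A", seq_len(k))
  dimnames(M) <- list(from = ids, to = ids)
  structure(list(values = M, attractor_set = attractor_set, p_e = tm$p_e),
            class = "mfpt_matrix")
}

#' @export
print.mfpt_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("Attractor MFPT matrix (%d attractors, p_e = %g):\n",
              nrow(x$values), x$p_e))
  print(signif(x$values, digits))
  invisible(x)
}
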