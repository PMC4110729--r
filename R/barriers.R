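#' Transitory single-bit-flip transition matrix (Villani measure)
#'
#' A cheap alternative to the MFPT barrier: for each attractor `i`, perturb
#' every state of its cycle by every possible single-bit flip
#' (`cycle_length x n` flips in all), relax each perturbed state under the
#' noise-free dynamics `D`, and record which attractor it lands in.
#' `P[i, j]` is the fraction of those flips that end in attractor `j`; flips
#' that relax back home are counted in `P[i, i]`, so rows sum to 1 exactly
#' (each row is a rational with denominator `cycle_length x n`).
#'
#' @param net a [boolean_network()].
#' @param attractor_set a [find_attractors()] result for `net`; computed if
#'   missing.
#' @return A `k x k` numeric matrix with rows summing to 1.
#' @examples
#' toggle <- boolean_network(list(2L, 1L), list(c(1L, 0L), c(1L, 0L)))
#' transitory_flip_matrix(toggle)  # both flips of 01 land on the 00/11 cycle
#' @export
transitory_flip_matrix <- function(net, attractor_set = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  if (is.null(attractor_set)) attractor_set <- find_attractors(net)
  k <- length(attractor_set$attractors)
  n <- net$n
  P <- matrix(0, k, k)
  for (i in seq_len(k)) {
    states <- attractor_set$attractors[[i]]$states
    flips <- bitwXor(rep(states, each = n),
                     bitwShiftL(1L, rep(seq_len(n), times = length(states)) - 1L))
    dest <- attractor_set$basin_map[flips + 1L]
    P[i, ] <- tabulate(dest, nbins = k) / length(flips)
  }
  ids <- paste0("A", seq_len(k))
  dimnames(P) <- list(from = ids, to = ids)
  P
}

#' Mean Hamming distance between two attractors
#'
#' The bitwise Hamming distance, lifted to attractors as the mean over all
#' cross pairs of cycle states (symmetric by construction; point attractors
#' reduce to the plain state distance). A `"min"` variant returns the
#' closest approach of the two cycles instead.
#'
#' @param att_i,att_j attractors (lists with a `states` field of integer
#'   codes, as produced by [find_attractors()]).
#' @param n node count of the network the attractors belong to.
#' @param method `"mean"` (default) or `"min"`.
#' @return A number in `[0, n]`.
#' @examples
#' attractor_hamming(list(states = 1L), list(states = 2L), n = 2)  # 2
#' @export
attractor_hamming <- function(att_i, att_j, n, method = c("mean", "min")) {
  method <- match.arg(method)
  si <- as.integer(att_i$states); sj <- as.integer(att_j$states)
  d <- hamming_codes(rep(si, times = length(sj)), rep(sj, each = length(si)), n)
  if (method == "mean") mean(d) else min(d)
}

#' Correlation between two barrier measures
#'
#' Pearson correlation and least-squares line for paired barrier
#' measurements over attractor pairs (for example transitory-flip
#' probability against MFPT, or Hamming distance against the mean of the
#' forward and reverse MFPT).
#'
#' @param xs,ys numeric vectors of equal length (>= 3) with nonzero variance.
#' @return List with `pearson_r`, `slope`, `intercept`, `n`.
#' @examples
#' barrier_correlation(1:5, 2 * (1:5) + 3)  # r = 1, slope = 2
#' @export
barrier_correlation <- function(xs, ys) {
  stopifnot(length(xs) == length(ys))
  ok <- is.finite(xs) & is.finite(ys)
  xs <- xs[ok]; ys <- ys[ok]
  if (length(xs) < 3L) stop("need at least 3 finite points")
  if (stats::var(xs) == 0 || stats::var(ys) == 0) {
    stop("correlation undefined: a measure has zero variance")
  }
  fit <- stats::lm.fit(cbind(1, xs), ys)
  list(pearson_r = stats::cor(xs, ys),
       slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       n = length(xs))
}
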