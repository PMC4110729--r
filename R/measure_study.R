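#' Compare epigenetic-barrier measures over an ensemble
#'
#' Generates critical random Boolean networks, keeps those with at least
#' `min_attractors` attractors, and tabulates three barrier measures for
#' their attractor pairs: the exact MFPT, the transitory single-bit-flip
#' probability ([transitory_flip_matrix()]) and the attractor Hamming
#' distance ([attractor_hamming()]).
#'
#' Two tables are returned. `directed` has one row per ordered attractor
#' pair `(i, j)` with `mfpt` and `flip_p` — the scatter in which the flip
#' probability falls off as MFPT grows. `pairs` has one row per unordered
#' pair with `hamming` and `avg_mfpt` (the mean of the forward and reverse
#' MFPT) — the scatter in which only a weak positive correlation with
#' Hamming distance survives, the asymmetry of MFPT being carried by network
#' dynamics rather than state-space geometry.
#'
#' @param n_networks accepted networks (default 100).
#' @param n_nodes node count per network (default 8).
#' @param q in-degree (default 2).
#' @param p_e per-gene flip probability (default 0.01).
#' @param min_attractors acceptance floor (default 2; use 5 to restrict to
#'   richer landscapes).
#' @param seed optional integer passed to `set.seed()`.
#' @param max_attempts attempt budget (default `200 * n_networks`).
#' @return A list with data frames `directed` and `pairs`, plus `networks`
#'   (accepted count) and `attempts`.
#' @seealso [barrier_correlation()]
#' @examples
#' study <- barrier_measure_study(n_networks = 5, seed = 1)
#' barrier_correlation(study$pairs$hamming, study$pairs$avg_mfpt)$pearson_r
#' @export
barrier_measure_study <- function(n_networks = 100L, n_nodes = 8L, q = 2L,
                                  p_e = 0.01, min_attractors = 2L,
                                  seed = NULL,
                                  max_attempts = 200L * n_networks) {
  if (!is.null(seed)) set.seed(seed)
  directed <- list()
  pairs <- list()
  accepted <- 0L
  attempts <- 0L
  while (accepted < n_networks && attempts < max_attempts) {
    attempts <- attempts + 1L
    net <- generate_critical_rbn(n_nodes, q)
    aset <- find_attractors(net)
    k <- length(aset)
    if (k < min_attractors) next
    accepted <- accepted + 1L
    mm <- attractor_mfpt_matrix(net, p_e, attractor_set = aset)
    Pf <- transitory_flip_matrix(net, aset)
    ij <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    H <- vapply(seq_len(nrow(ij)), function(r) {
      attractor_hamming(aset$attractors[[ij[r, 1]]],
                        aset$attractors[[ij[r, 2]]], n = net$n)
    }, 0)
    od <- which(diag(k) == 0, arr.ind = TRUE)
    directed[[accepted]] <- data.frame(
      network_id = accepted, from = od[, 1], to = od[, 2],
      mfpt = mm$values[od], flip_p = Pf[od])
    pairs[[accepted]] <- data.frame(
      network_id = accepted, attractor_i = ij[, 1], attractor_j = ij[, 2],
      hamming = H,
      avg_mfpt = (mm$values[ij] + mm$values[ij[, 2:1, drop = FALSE]]) / 2)
  }
  if (accepted < n_networks) {
    warning(sprintf("accepted only %d/%d networks within the attempt budget",
                    accepted, n_networks))
  }
  list(directed = do.call(rbind, directed), pairs = do.call(rbind, pairs),
       networks = accepted, attempts = attempts)
}
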