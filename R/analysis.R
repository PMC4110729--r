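#' Full attractor-landscape analysis of one network
#'
#' The package's central per-network computation: enumerate attractors and
#' basins, build the noisy transition matrix, compute all pairwise attractor
#' MFPTs exactly, and orient and classify every attractor pair as
#' directional, separate or neither. This is the quantity ensemble studies
#' aggregate over networks.
#'
#' @param net a [boolean_network()].
#' @param p_e per-gene flip probability per step (default 0.01).
#' @param dir_ratio_threshold,sep_threshold classification thresholds, see
#'   [classify_pair()].
#' @param cap dense-matrix node cap, see [transition_matrix()].
#' @return An object of class `mfpt_analysis`: list with `network`,
#'   `attractors` (an `attractor_set`), `mfpt` (an `mfpt_matrix`), `pairs`
#'   (a [pair_records()] data frame) and `params`.
#' @examples
#' toggle <- boolean_network(list(2L, 1L), list(c(1L, 0L), c(1L, 0L)))
#' fit <- mfpt_analysis(toggle, p_e = 0.05)
#' fit
#' summary(fit)
#' @export
mfpt_analysis <- function(net, p_e = 0.01, dir_ratio_threshold = 10,
                          sep_threshold = 1e3, cap = 12L) {
  stopifnot(inherits(net, "boolean_network"))
  aset <- find_attractors(net)
  if (length(aset) < 2L) {
    stop("network has a single attractor; no pairs to analyze")
  }
  mm <- attractor_mfpt_matrix(net, p_e, attractor_set = aset, cap = cap)
  pairs <- pair_records(mm, dir_ratio_threshold, sep_threshold)
  structure(
    list(network = net, attractors = aset, mfpt = mm, pairs = pairs,
         params = list(p_e = p_e, dir_ratio_threshold = dir_ratio_threshold,
                       sep_threshold = sep_threshold)),
    class = "mfpt_analysis"
  )
}

#' @export
print.mfpt_analysis <- function(x, ...) {
  cat(sprintf("MFPT landscape analysis (%d nodes, p_e = %g)\n",
              x$network$n, x$params$p_e))
  cat(sprintf("  %d attractors, %d pairs: %d directional, %d separate, %d neither\n",
              length(x$attractors), nrow(x$pairs),
              sum(x$pairs$label == "directional"),
              sum(x$pairs$label == "separate"),
              sum(x$pairs$label == "neither")))
  invisible(x)
}

#' @export
summary.mfpt_analysis <- function(object, ...) {
  out <- list(
    n = object$network$n,
    p_e = object$params$p_e,
    attractors = length(object$attractors),
    kinds = table(vapply(object$attractors$attractors, `[[`, "", "kind")),
    basin_sizes = vapply(object$attractors$attractors, `[[`, 0L, "basin_size"),
    mfpt_range = range(object$mfpt$values[object$mfpt$values > 0]),
    label_counts = table(factor(object$pairs$label,
                                levels = c("directional", "separate", "neither"))),
    thresholds = object$params[c("dir_ratio_threshold", "sep_threshold")]
  )
  class(out) <- "summary.mfpt_analysis"
  out
}

#' @export
print.summary.mfpt_analysis <- function(x, ...) {
  cat(sprintf("Landscape summary: %d-node network, p_e = %g\n", x$n, x$p_e))
  cat(sprintf("  attractors: %d (%s)\n", x$attractors,
              paste(sprintf("%d %s", x$kinds, names(x$kinds)), collapse = ", ")))
  cat(sprintf("  basin sizes: %s\n", paste(x$basin_sizes, collapse = ", ")))
  cat(sprintf("  MFPT range: %.3g - %.3g steps\n",
              x$mfpt_range[1], x$mfpt_range[2]))
  cat(sprintf("  pair labels (dir ratio >= %g, separation >= %g): %s\n",
              x$thresholds$dir_ratio_threshold, x$thresholds$sep_threshold,
              paste(sprintf("%d %s", x$label_counts, names(x$label_counts)),
                    collapse = ", ")))
  invisible(x)
}

#' @describeIn mfpt_analysis scatter of oriented pairs in the
#'   (forward, reverse) MFPT plane on log10 axes, with the directional and
#'   separate regions marked.
#' @param x an `mfpt_analysis`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mfpt_analysis <- function(x, ...) {
  p <- x$pairs
  sep <- x$params$sep_threshold
  col <- c(directional = "#D55E00", separate = "#0072B2", neither = "grey40")
  graphics::plot(p$forward, p$reverse, log = "xy",
                 xlab = "forward MFPT (steps)", ylab = "reverse MFPT (steps)",
                 pch = 19, col = col[p$label], ...)
  graphics::abline(0, 1, untf = TRUE, lty = 2, col = "grey70")
  graphics::abline(v = sep, h = sep, lty = 3, col = "grey70")
  graphics::legend("topleft", legend = names(col), col = col, pch = 19,
                   bty = "n", cex = 0.9)
  invisible(x)
}

#' Simulate the noisy Boolean dynamics
#'
#' Draws trajectories of the noisy process underlying the MFPT analysis:
#' per step, each gene flips independently with probability `p_e`; when no
#' gene flips the deterministic update `D` is applied, otherwise the state
#' jumps to the flipped state.
#'
#' @param object a [boolean_network()].
#' @param nsim number of steps to simulate (default 100).
#' @param seed optional seed passed to `set.seed()`.
#' @param from starting state (integer code or bit vector); default 0.
#' @param p_e per-gene flip probability (default 0.01).
#' @param ... unused.
#' @return Integer vector of `nsim + 1` state codes (including the start).
#' @examples
#' toggle <- boolean_network(list(2L, 1L), list(c(1L, 0L), c(1L, 0L)))
#' simulate(toggle, nsim = 10, seed = 1, p_e = 0.2)
#' @export
simulate.boolean_network <- function(object, nsim = 100L, seed = NULL,
                                     from = 0L, p_e = 0.01, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  if (length(from) == n && all(from %in% c(0, 1)) && n > 1L) {
    from <- encode_state(from)
  }
  Dm <- state_map(object)
  out <- integer(nsim + 1L)
  out[1L] <- as.integer(from)
  s <- out[1L]
  for (t in seq_len(nsim)) {
    mask <- 0L
    for (b in seq_len(n)) {
      mask <- mask + bitwShiftL(as.integer(stats::runif(1) < p_e), b - 1L)
    }
    s <- if (mask == 0L) Dm[s + 1L] else bitwXor(s, mask)
    out[t + 1L] <- s
  }
  out
}
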