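#' Orient an attractor pair by its smaller MFPT
#'
#' The direction with the smaller MFPT is called *forward*; ties keep the
#' `(i -> j)` direction as forward and are flagged.
#'
#' @param mfpt_ij,mfpt_ji finite positive MFPTs of the two directions.
#' @return List with `forward`, `reverse`, `swapped` (`TRUE` if `j -> i` is
#'   the forward direction) and `tie`.
#' @examples
#' orient_pair(5000, 5)  # forward 5, reverse 5000, swapped
#' @export
orient_pair <- function(mfpt_ij, mfpt_ji) {
  stopifnot(is.finite(mfpt_ij), is.finite(mfpt_ji), mfpt_ij > 0, mfpt_ji > 0)
  if (mfpt_ji < mfpt_ij) {
    list(forward = mfpt_ji, reverse = mfpt_ij, swapped = TRUE, tie = FALSE)
  } else {
    list(forward = mfpt_ij, reverse = mfpt_ji, swapped = FALSE,
         tie = mfpt_ij == mfpt_ji)
  }
}

#' Classify an oriented attractor pair
#'
#' Attractor pairs fall into landscape regions that matter for lineage-tree
#' structure: a pair is **separate** when even its forward (easier) direction
#' is slow, `forward >= sep_threshold` — a high epigenetic barrier in both
#' directions; it is **directional** when the reverse direction is at least
#' `dir_ratio_threshold` times slower than the forward one while the forward
#' transition itself is fast (`forward < sep_threshold`) — one-way movement,
#' as in differentiation. Everything else is **neither**.
#'
#' @param forward,reverse oriented MFPTs (`forward <= reverse`), or the
#'   unoriented pair (orientation is applied first, so the label is invariant
#'   to argument order).
#' @param dir_ratio_threshold minimum reverse/forward ratio for a directional
#'   label (default 10).
#' @param sep_threshold minimum forward MFPT for a separate label
#'   (default `1e3`, the pruning threshold used for MFPT graphs).
#' @return `"separate"`, `"directional"` or `"neither"`.
#' @examples
#' classify_pair(5, 5000)     # directional
#' classify_pair(2000, 3000)  # separate
#' classify_pair(10, 20)      # neither
#' @export
classify_pair <- function(forward, reverse, dir_ratio_threshold = 10,
                          sep_threshold = 1e3) {
  stopifnot(dir_ratio_threshold > 0, sep_threshold > 0)
  o <- orient_pair(forward, reverse)
  if (o$forward >= sep_threshold) return("separate")
  if (o$reverse / o$forward >= dir_ratio_threshold) return("directional")
  "neither"
}

#' Oriented, classified records for all attractor pairs
#'
#' Expands an [attractor_mfpt_matrix()] into one row per unordered attractor
#' pair, oriented ([orient_pair()]) and labelled ([classify_pair()]).
#'
#' @param mm an `mfpt_matrix`.
#' @inheritParams classify_pair
#' @return A data frame with columns `attractor_i`, `attractor_j` (indices,
#'   `i` the forward source), `forward`, `reverse`, `tie`, `label`.
#' @export
pair_records <- function(mm, dir_ratio_threshold = 10, sep_threshold = 1e3) {
  stopifnot(inherits(mm, "mfpt_matrix"))
  k <- nrow(mm$values)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  recs <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    o <- orient_pair(mm$values[i, j], mm$values[j, i])
    if (o$swapped) { tmp <- i; i <- j; j <- tmp }
    data.frame(attractor_i = i, attractor_j = j,
               forward = o$forward, reverse = o$reverse, tie = o$tie,
               label = classify_pair(o$forward, o$reverse,
                                     dir_ratio_threshold, sep_threshold))
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Two-dimensional MFPT density grid
#'
#' Histogram of attractor pairs over `(log10 forward, log10 reverse)`. Since
#' orientation guarantees `reverse >= forward`, all mass lies on or above the
#' diagonal. Grids built on identical breaks can be subtracted with
#' [density_difference()].
#'
#' @param forward,reverse positive MFPT vectors (same length), or a
#'   [pair_records()] data frame passed as `forward`.
#' @param breaks common bin edges on the log10 axis (used for both axes);
#'   default 40 bins spanning the pooled data range. Values falling outside
#'   are counted in the edge bins.
#' @param normalize divide counts by the number of pairs so total mass is 1.
#' @return An object of class `density_grid`: list with `counts` (rows =
#'   forward bins, cols = reverse bins), `breaks`, `n_pairs`, `normalized`.
#' @export
density_grid <- function(forward, reverse = NULL, breaks = NULL,
                         normalize = FALSE) {
  if (is.data.frame(forward)) {
    reverse <- forward$reverse
    forward <- forward$forward
  }
  stopifnot(length(forward) == length(reverse), length(forward) > 0)
  if (any(forward <= 0) || any(reverse <= 0)) {
    stop("MFPT values must be positive to take log10")
  }
  lf <- log10(forward); lr <- log10(reverse)
  if (is.null(breaks)) {
    rng <- range(c(lf, lr))
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = 41L)
  }
  nb <- length(breaks) - 1L
  bin <- function(v) pmin(pmax(findInterval(v, breaks,
                                            rightmost.closed = TRUE), 1L), nb)
  counts <- matrix(0, nb, nb)
  tab <- table(factor(bin(lf), levels = seq_len(nb)),
               factor(bin(lr), levels = seq_len(nb)))
  counts <- matrix(as.numeric(tab), nb, nb)
  if (normalize) counts <- counts / length(forward)
  structure(list(counts = counts, breaks = breaks,
                 n_pairs = length(forward), normalized = normalize),
            class = "density_grid")
}

#' Difference of two normalized density grids
#'
#' Elementwise `a - b` for grids on identical breaks; highlights where one
#' ensemble (say, networks with two embedded switches) places more attractor
#' pairs than another (no switches). Entries sum to zero.
#'
#' @param grid_a,grid_b normalized [density_grid()]s with identical breaks.
#' @return A `density_grid` whose `counts` is the signed difference.
#' @export
density_difference <- function(grid_a, grid_b) {
  stopifnot(inherits(grid_a, "density_grid"), inherits(grid_b, "density_grid"))
  if (!isTRUE(all.equal(grid_a$breaks, grid_b$breaks))) {
    stop("density grids have mismatched bin edges")
  }
  if (!grid_a$normalized || !grid_b$normalized) {
    stop("both grids must be normalized before differencing")
  }
  structure(list(counts = grid_a$counts - grid_b$counts,
                 breaks = grid_a$breaks,
                 n_pairs = c(grid_a$n_pairs, grid_b$n_pairs),
                 normalized = TRUE, difference = TRUE),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("%s grid: %d x %d bins, log10 range [%.2f, %.2f], mass %.4g\n",
              if (isTRUE(x$difference)) "MFPT density difference"
              else "MFPT density",
              nrow(x$counts), ncol(x$counts),
              min(x$breaks), max(x$breaks), sum(x$counts)))
  invisible(x)
}

#' @describeIn density_grid image plot of the grid (forward on x, reverse on
#'   y, log10 axes).
#' @param x a `density_grid`.
#' @param ... passed to [graphics::image()].
#' @export
plot.density_grid <- function(x, ...) {
  mids <- (x$breaks[-1] + x$breaks[-length(x$breaks)]) / 2
  col <- if (isTRUE(x$difference)) {
    grDevices::hcl.colors(33, "Blue-Red 3")
  } else {
    grDevices::hcl.colors(33, "YlOrRd", rev = TRUE)
  }
  zlim <- if (isTRUE(x$difference)) {
    c(-1, 1) * max(abs(x$counts), 1e-12)
  } else NULL
  args <- list(x = mids, y = mids, z = x$counts, col = col,
               xlab = "log10 forward MFPT", ylab = "log10 reverse MFPT", ...)
  if (!is.null(zlim)) args$zlim <- zlim
  do.call(graphics::image, args)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' MFPT graphs and pruning
#'
#' `mfpt_graph()` turns an attractor MFPT matrix into a weighted directed
#' graph (nodes = attractors, edge weight = MFPT). `prune_mfpt_graph()`
#' removes edges whose MFPT exceeds a threshold, leaving the node set
#' unchanged — raising the threshold progressively isolates groups of
#' attractors, mimicking the increasing stability of differentiating cells.
#'
#' @param mm an `mfpt_matrix`.
#' @param graph an [igraph::graph] from `mfpt_graph()`.
#' @param threshold prune edges with `weight > threshold` (default `1e3`).
#' @return An [igraph::graph] with edge attribute `weight`.
#' @export
mfpt_graph <- function(mm) {
  stopifnot(inherits(mm, "mfpt_matrix"))
  igraph::graph_from_adjacency_matrix(mm$values, mode = "directed",
                                      weighted = TRUE, diag = FALSE)
}

#' @rdname mfpt_graph
#' @export
prune_mfpt_graph <- function(graph, threshold = 1e3) {
  stopifnot(igraph::is_igraph(graph), threshold > 0)
  igraph::delete_edges(graph, which(igraph::E(graph)$weight > threshold))
}
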