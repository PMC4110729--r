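#' Multistable switch motifs
#'
#' Four two-gene switch motifs recur in differentiation networks:
#'
#' * `BS`   — bistable (toggle) switch: each gene is inhibited by its
#'   partner and activated by its other input, combined by OR
#'   (`f = other | !partner`); no self-feedback loops;
#' * `MI00` — mutual inhibition gated by an external activator
#'   (`f = other & !partner`); no feedback loops;
#' * `MI0+` — mutual inhibition plus one positive self-feedback loop
#'   (one gene's activating input is its own output);
#' * `MI++` — mutual inhibition plus two positive self-feedback loops
#'   (`u' = u & !v`, `v' = v & !u`; sometimes called a tristable switch).
#'
#' Both motif nodes carry the same two-input truth table, with the partner
#' gene on the low-order (`2^0`) input and the activating input (external
#' signal or self-feedback) on the high-order slot. In this package's
#' high-bit-first storage the tables are `[1,0,1,1]` (`BS`) and `[0,0,1,0]`
#' (mutual inhibition); the same functions written with the partner bit
#' first — the circuit diagrams' convention — read `[1,1,0,1]` and
#' `[0,1,0,0]`, returned as `figure_table`.
#'
#' @param kind one of `"BS"`, `"MI00"`, `"MI0+"`, `"MI++"` (case-insensitive;
#'   `"MI+0"` is an accepted alias for `"MI0+"`).
#' @return `motif_kind()`: the canonical kind string. `motif_definition()`:
#'   a list with `name`, `truth_table` (length-4, package convention:
#'   activating input is the high bit), `figure_table` (same function,
#'   partner bit first) and `feedback_loops` (0, 0, 1 or 2).
#' @examples
#' motif_definition("bs")
#' motif_definition("MI++")$truth_table
#' @export
motif_kind <- function(kind) {
  stopifnot(is.character(kind), length(kind) == 1L)
  k <- toupper(trimws(kind))
  if (k == "MI+0") k <- "MI0+"
  if (!k %in% c("BS", "MI00", "MI0+", "MI++")) {
    stop("unknown motif kind '", kind, "'; expected BS, MI00, MI0+ or MI++")
  }
  k
}

#' @rdname motif_kind
#' @export
motif_definition <- function(kind) {
  k <- motif_kind(kind)
  bs <- k == "BS"
  list(
    name = k,
    truth_table = if (bs) c(1L, 0L, 1L, 1L) else c(0L, 0L, 1L, 0L),
    figure_table = if (bs) c(1L, 1L, 0L, 1L) else c(0L, 1L, 0L, 0L),
    feedback_loops = switch(k, "BS" = 0L, "MI00" = 0L, "MI0+" = 1L, "MI++" = 2L)
  )
}

#' Build a standalone two-node motif network
#'
#' Returns the isolated two-gene switch as a runnable network for inspection
#' and exhaustive attractor enumeration, wired exactly as an embedded copy:
#' the partner gene on each node's low-order (`2^0`) input, and the
#' activating high-order input either the node's own output (the first node
#' for `MI0+`, both for `MI++`) or an external signal. External signals are
#' clamped to the constant `clamp` (default 0) by reducing the truth table
#' over that slot. Under this wiring `BS` is bistable (two point attractors
#' plus the alternating cycle) and `MI++` is tristable (three point
#' attractors: both genes off, or exactly one on).
#'
#' @inheritParams motif_kind
#' @param clamp value (0 or 1) applied to external input slots. `MI00` needs
#'   `clamp = 1` (an active external signal) to show its bistability; with
#'   the default 0 both genes switch off.
#' @return A 2-node [boolean_network()] with nodes `"A"` and `"B"`.
#' @examples
#' find_attractors(motif_network("MI++"))  # three point attractors
#' @export
motif_network <- function(kind, clamp = 0L) {
  def <- motif_definition(kind)
  stopifnot(clamp %in% c(0L, 1L))
  tt <- def$truth_table
  # reduce the table over a clamped high-order input: remaining single
  # input is the partner on the 2^0 slot
  reduce_high <- function(tt, clamp) tt[2L * clamp + (1:2)]
  self_fb <- c(def$feedback_loops >= 1L, def$feedback_loops >= 2L)
  inputs <- vector("list", 2L)
  tts <- vector("list", 2L)
  for (i in 1:2) {
    partner <- 3L - i
    if (self_fb[i]) {
      inputs[[i]] <- c(i, partner)  # self on 2^1, partner on 2^0
      tts[[i]] <- tt
    } else {
      inputs[[i]] <- partner        # external 2^1 slot clamped away
      tts[[i]] <- reduce_high(tt, as.integer(clamp))
    }
  }
  boolean_network(inputs, tts, node_names = c("A", "B"))
}

#' Embed multistable switch copies into a network
#'
#' Implants `copies` identical two-gene switches into `net` by truth-table
#' replacement and rewiring, leaving every non-selected node untouched. Per
#' copy, two distinct nodes are drawn uniformly at random; each gets the
#' motif truth table, and its low-order (`2^0`, last-listed) input slot is
#' rewired to the partner's output, forming the mutual inhibition. The
#' high-order slot is rewired to the node's own output for motif nodes
#' carrying a positive self-feedback loop (the first node of the pair for
#' `MI0+`, both for `MI++`) and otherwise keeps its original source, which
#' acts as the switch's external signal. Selected nodes whose in-degree is
#' not 2 have their input list truncated to its first two entries, or
#' extended with a uniformly drawn extra input, before rewiring (motif
#' tables are length 4); this adjustment is recorded.
#'
#' Randomness comes from R's global RNG; seed with `set.seed()` for
#' reproducible embeddings.
#'
#' @param net a [boolean_network()].
#' @inheritParams motif_kind
#' @param copies number of identical switch copies to embed (0, 1 or 2);
#'   `copies = 0` returns the network unchanged.
#' @return A list with `network` (the modified [boolean_network()]) and
#'   `record`, a list with one entry per copy: `nodes` (the selected pair,
#'   cross-wired first to second and back), `rewired` (text description) and
#'   `degree_adjusted` (selected nodes whose in-degree was forced to 2).
#' @examples
#' set.seed(1)
#' net <- generate_critical_rbn(8, 2)
#' emb <- embed_motifs(net, "MI0+", copies = 1)
#' emb$record[[1]]$nodes
#' @export
embed_motifs <- function(net, kind, copies = 1L) {
  stopifnot(inherits(net, "boolean_network"), copies %in% 0:2)
  if (copies == 0L) return(list(network = net, record = list()))
  def <- motif_definition(kind)
  if (net$n < 2L * copies) {
    stop("embedding ", copies, " switch cop", if (copies > 1) "ies" else "y",
         " needs at least ", 2L * copies, " nodes, got ", net$n)
  }
  chosen <- sample.int(net$n, 2L * copies)
  record <- vector("list", copies)
  for (cp in seq_len(copies)) {
    pair <- chosen[c(2L * cp - 1L, 2L * cp)]
    adjusted <- integer(0)
    # force in-degree 2 before rewiring
    for (u in pair) {
      k <- length(net$inputs[[u]])
      if (k != 2L) {
        adjusted <- c(adjusted, u)
        if (k > 2L) {
          net$inputs[[u]] <- net$inputs[[u]][1:2]
        } else {
          extra <- sample.int(net$n, 2L - k)
          net$inputs[[u]] <- c(net$inputs[[u]], extra)
        }
      }
    }
    for (s in 1:2) {
      u <- pair[s]; v <- pair[3L - s]
      net$truth_tables[[u]] <- def$truth_table
      has_self <- def$feedback_loops >= s  # node 1 first for MI0+
      hi <- if (has_self) u else net$inputs[[u]][1L]
      net$inputs[[u]] <- c(hi, v)          # 2^1 slot, then 2^0 = partner
    }
    record[[cp]] <- list(
      nodes = pair,
      rewired = sprintf(
        "2^0 inputs cross-wired %d<->%d; 2^1 slot: %s",
        pair[1], pair[2],
        switch(def$name,
               "BS" = , "MI00" = "original sources retained",
               "MI0+" = sprintf("self-loop on node %d", pair[1]),
               "MI++" = "self-loops on both nodes")),
      degree_adjusted = adjusted
    )
  }
  # re-validate and return a fresh object
  net <- boolean_network(net$inputs, net$truth_tables, net$node_names)
  list(network = net, record = record)
}
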