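#' Construct a synchronous Boolean network
#'
#' A Boolean gene regulatory network is a set of `n` nodes (genes), each with
#' an ordered list of input nodes and a truth table giving the node's next
#' value for every combination of its inputs. All nodes update simultaneously
#' (synchronous dynamics), so the network defines a total deterministic map
#' `D` over the `2^n` states.
#'
#' Input lists are ordered **most-significant bit first**: for a node with
#' inputs `(a, b)`, the truth-table entry used at a given state is
#' `truth_tables[[i]][2*bit(a) + bit(b) + 1]`. The *last* listed input is the
#' low-order ("2^0") input slot, the slot used when wiring switch motifs.
#' Zero-input nodes are permitted (truth table of length one, a constant).
#'
#' @param inputs list of integer vectors; `inputs[[i]]` are the (1-based)
#'   indices of node `i`'s regulators, most-significant first.
#' @param truth_tables list of 0/1 vectors; `truth_tables[[i]]` has length
#'   `2^length(inputs[[i]])`, entry `t + 1` giving node `i`'s next value when
#'   its inputs spell the binary number `t`.
#' @param node_names optional character vector of node identifiers.
#' @return An object of class `boolean_network` with fields `n`, `node_names`,
#'   `inputs`, `truth_tables`.
#' @examples
#' # the two-gene toggle: each gene is the NOT of the other
#' toggle <- boolean_network(
#'   inputs       = list(2L, 1L),
#'   truth_tables = list(c(1L, 0L), c(1L, 0L))
#' )
#' find_attractors(toggle)
#' @seealso [synchronous_update()], [find_attractors()], [read_network_json()]
#' @export
boolean_network <- function(inputs, truth_tables, node_names = NULL) {
  stopifnot(is.list(inputs), is.list(truth_tables))
  n <- length(inputs)
  if (n < 1L) stop("a network needs at least one node")
  if (length(truth_tables) != n) {
    stop("'inputs' and 'truth_tables' must have one entry per node")
  }
  if (is.null(node_names)) node_names <- paste0("x", seq_len(n))
  if (length(node_names) != n) stop("'node_names' must have length n")
  inputs <- lapply(inputs, as.integer)
  truth_tables <- lapply(truth_tables, as.integer)
  for (i in seq_len(n)) {
    k <- length(inputs[[i]])
    if (k > 0L && (any(inputs[[i]] < 1L) | any(inputs[[i]] > n))) {
      stop(sprintf("node %d: input index out of range [1, %d]", i, n))
    }
    if (length(truth_tables[[i]]) != bitwShiftL(1L, k)) {
      stop(sprintf("node %d: truth table must have length 2^%d = %d",
                   i, k, bitwShiftL(1L, k)))
    }
    if (!all(truth_tables[[i]] %in% c(0L, 1L))) {
      stop(sprintf("node %d: truth-table entries must be 0 or 1", i))
    }
  }
  structure(
    list(n = n, node_names = node_names, inputs = inputs,
         truth_tables = truth_tables),
    class = "boolean_network"
  )
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Synchronous Boolean network: %d nodes, %s states\n",
              x$n, format(2^x$n, big.mark = ",")))
  k <- lengths(x$inputs)
  cat(sprintf("In-degree: %s\n",
              if (length(unique(k)) == 1L) unique(k)
              else paste0(min(k), "-", max(k))))
  show <- seq_len(min(x$n, 8L))
  for (i in show) {
    cat(sprintf("  %s <- f(%s) : [%s]\n", x$node_names[i],
                paste(x$node_names[x$inputs[[i]]], collapse = ","),
                paste(x$truth_tables[[i]], collapse = ",")))
  }
  if (x$n > 8L) cat(sprintf("  ... and %d more nodes\n", x$n - 8L))
  invisible(x)
}

# evaluate the deterministic map D on a vector of integer state codes
apply_network <- function(net, codes) {
  codes <- as.integer(codes)
  nxt <- integer(length(codes))
  for (i in seq_len(net$n)) {
    idx <- integer(length(codes))
    for (j in net$inputs[[i]]) {
      idx <- bitwShiftL(idx, 1L) + state_bit(codes, j)
    }
    nxt <- nxt + bitwShiftL(net$truth_tables[[i]][idx + 1L], i - 1L)
  }
  nxt
}

#' Apply one synchronous update step
#'
#' Computes `D(state)`: every node reads its inputs in the current state and
#' takes the value its truth table assigns, all simultaneously.
#'
#' @param net a [boolean_network()].
#' @param state either integer state code(s) in `[0, 2^n)` or a 0/1 bit vector
#'   of length `n` (node 1 first).
#' @return The next state, in the same representation as the input.
#' @examples
#' toggle <- boolean_network(list(2L, 1L), list(c(1L, 0L), c(1L, 0L)))
#' synchronous_update(toggle, c(0, 0))  # both genes switch on
#' synchronous_update(toggle, 0L)       # same step, integer coding
#' @export
synchronous_update <- function(net, state) {
  stopifnot(inherits(net, "boolean_network"))
  N <- bitwShiftL(1L, net$n)
  if (length(state) == net$n && all(state %in% c(0, 1)) && net$n > 1L) {
    return(decode_state(apply_network(net, encode_state(state)), net$n)[1L, ])
  }
  state <- as.integer(state)
  if (any(state < 0L) || any(state >= N)) {
    stop("state dimension mismatch: codes must lie in [0, ", N, ")")
  }
  apply_network(net, state)
}

#' Tabulate the deterministic map over all states
#'
#' @param net a [boolean_network()].
#' @return Integer vector of length `2^n`; entry `s + 1` is `D(s)`.
#' @export
state_map <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  apply_network(net, 0:(bitwShiftL(1L, net$n) - 1L))
}

#' Follow a noise-free trajectory into its attractor
#'
#' Iterates `D` from `start` until a previously visited state recurs; the
#' cycle entered is the attractor of `start`'s basin.
#'
#' @inheritParams synchronous_update
#' @param start starting state (integer code or bit vector).
#' @return A list with `states` (integer codes of the attractor cycle, in
#'   visit order) and `transient_length` (steps taken before entering the
#'   cycle; 0 if `start` lies on it).
#' @examples
#' toggle <- boolean_network(list(2L, 1L), list(c(1L, 0L), c(1L, 0L)))
#' trajectory_to_attractor(toggle, 0L)  # the 00 <-> 11 two-cycle
#' @export
trajectory_to_attractor <- function(net, start) {
  stopifnot(inherits(net, "boolean_network"))
  if (length(start) == net$n && all(start %in% c(0, 1)) && net$n > 1L) {
    start <- encode_state(start)
  }
  s <- as.integer(start)
  stopifnot(length(s) == 1L, s >= 0L, s < bitwShiftL(1L, net$n))
  seen <- s
  repeat {
    s <- apply_network(net, s)
    hit <- match(s, seen)
    if (!is.na(hit)) {
      return(list(states = seen[hit:length(seen)], transient_length = hit - 1L))
    }
    seen <- c(seen, s)
  }
}

#' Enumerate all attractors and basins exhaustively
#'
#' Visits all `2^n` states of the deterministic map (memoizing resolved
#' states) and returns the complete attractor set: every point and cyclic
#' attractor, the basin map assigning each state to its attractor, and basin
#' sizes. Attractors are ordered canonically by their smallest member state
#' code, so results are reproducible across runs and platforms.
#'
#' @param net a [boolean_network()].
#' @param cap exhaustive-enumeration cap on `n` (default 20); raising it is an
#'   explicit opt-in to `2^n` memory and time.
#' @return An object of class `attractor_set`: a list with `attractors` (each
#'   a list with `states` — the cycle rotated to start at its smallest code —,
#'   `kind` (`"point"` or `"cyclic"`) and `basin_size`), `basin_map` (integer
#'   vector of length `2^n`, attractor index per state), and `n`.
#' @examples
#' toggle <- boolean_network(list(2L, 1L), list(c(1L, 0L), c(1L, 0L)))
#' find_attractors(toggle)  # two point attractors and one 2-cycle
#' @export
find_attractors <- function(net, cap = 20L) {
  stopifnot(inherits(net, "boolean_network"))
  if (net$n > cap) {
    stop("exhaustive enumeration over 2^", net$n, " states exceeds the cap (",
         cap, "); raise 'cap' explicitly to proceed")
  }
  Dm <- state_map(net)
  N <- length(Dm)
  attr_of <- integer(N)        # 0 = unresolved
  onpath <- integer(N)         # position in the current path, 0 = off path
  path <- integer(N)
  cycles <- list()
  for (s0 in seq_len(N)) {
    if (attr_of[s0] > 0L) next
    s <- s0 - 1L
    len <- 0L
    while (attr_of[s + 1L] == 0L && onpath[s + 1L] == 0L) {
      len <- len + 1L
      path[len] <- s
      onpath[s + 1L] <- len
      s <- Dm[s + 1L]
    }
    if (attr_of[s + 1L] > 0L) {
      a <- attr_of[s + 1L]
    } else {
      first <- onpath[s + 1L]
      cycles[[length(cycles) + 1L]] <- path[first:len]
      a <- length(cycles)
    }
    if (len > 0L) {
      idx <- path[seq_len(len)]
      attr_of[idx + 1L] <- a
      onpath[idx + 1L] <- 0L
    }
  }
  # canonical order: by smallest member state code
  mins <- vapply(cycles, min, integer(1))
  ord <- order(mins)
  relabel <- integer(length(cycles))
  relabel[ord] <- seq_along(cycles)
  basin_map <- relabel[attr_of]
  sizes <- tabulate(basin_map, nbins = length(cycles))
  attractors <- lapply(seq_along(ord), function(k) {
    cyc <- cycles[[ord[k]]]
    i0 <- which.min(cyc)
    cyc <- c(cyc[i0:length(cyc)], cyc[seq_len(i0 - 1L)])
    list(states = cyc,
         kind = if (length(cyc) == 1L) "point" else "cyclic",
         basin_size = sizes[k])
  })
  structure(list(attractors = attractors, basin_map = basin_map, n = net$n),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  k <- length(x$attractors)
  cat(sprintf("Attractor set: %d attractor%s over %s states\n",
              k, if (k == 1L) "" else "s", format(2^x$n, big.mark = ",")))
  for (i in seq_len(k)) {
    a <- x$attractors[[i]]
    cat(sprintf("  [%d] %-6s {%s}  basin %d (%.1f%%)\n", i, a$kind,
                paste(format_state(a$states, x$n), collapse = ","),
                a$basin_size, 100 * a$basin_size / 2^x$n))
  }
  invisible(x)
}

#' @export
length.attractor_set <- function(x) length(x$attractors)
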