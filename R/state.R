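#' State encoding for synchronous Boolean networks
#'
#' A network of `n` genes has `2^n` states. Throughout the package a state is
#' identified with its integer code in `[0, 2^n)`, where **node 1 is the
#' least-significant bit** (bit `2^0`), node 2 is bit `2^1`, and so on.
#' `decode_state()` and `encode_state()` convert between integer codes and
#' 0/1 bit vectors under this convention.
#'
#' @param code integer state code(s) in `[0, 2^n)`.
#' @param n number of nodes.
#' @param bits 0/1 vector of length `n` (node 1 first) or a matrix with `n`
#'   columns, one row per state.
#' @return `decode_state()` returns an integer matrix with one row per code and
#'   `n` columns; `encode_state()` returns integer code(s).
#' @examples
#' decode_state(5L, 3)          # 1 0 1  (bits of nodes 1..3)
#' encode_state(c(1, 0, 1))     # 5
#' @export
decode_state <- function(code, n) {
  code <- as.integer(code)
  stopifnot(all(code >= 0L), all(code < bitwShiftL(1L, n)))
  m <- vapply(seq_len(n), function(j) state_bit(code, j), integer(length(code)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(code))
  m
}

#' @rdname decode_state
#' @export
encode_state <- function(bits) {
  if (is.matrix(bits)) {
    return(as.integer(bits %*% bitwShiftL(1L, seq_len(ncol(bits)) - 1L)))
  }
  bits <- as.integer(bits)
  stopifnot(all(bits %in% c(0L, 1L)))
  sum(bitwShiftL(bits, seq_along(bits) - 1L))
}

# bit of node j (1-based) in state code(s) s
state_bit <- function(s, j) bitwAnd(bitwShiftR(s, j - 1L), 1L)

# population counts for all states 0 .. 2^n - 1
popcount_table <- function(n) {
  s <- 0:(bitwShiftL(1L, n) - 1L)
  pc <- integer(length(s))
  for (b in seq_len(n)) pc <- pc + state_bit(s, b)
  pc
}

# Hamming distance between two vectors of state codes
hamming_codes <- function(x, y, n) {
  z <- bitwXor(as.integer(x), as.integer(y))
  pc <- integer(length(z))
  for (b in seq_len(n)) pc <- pc + state_bit(z, b)
  pc
}

# pretty bit-string (node 1 leftmost) for messages and labels
format_state <- function(code, n) {
  vapply(code, function(s) paste(state_bit(s, seq_len(n)), collapse = ""), "")
}
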