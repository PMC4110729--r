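#' Read and write networks in the package JSON dialect
#'
#' The on-disk JSON form is
#' `{"nodes": [names], "inputs": [[int, ...], ...], "truth_tables": [[0|1, ...], ...]}`
#' with **0-based** input indices (converted to R's 1-based indexing on read),
#' inputs listed most-significant first, and truth tables indexed by the
#' binary number the inputs spell. The format round-trips bit-exactly.
#'
#' @param net a [boolean_network()].
#' @param path file path.
#' @return `read_network_json()` returns a `boolean_network`;
#'   `write_network_json()` returns `path` invisibly.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "boolean_network"))
  obj <- list(
    nodes = net$node_names,
    inputs = lapply(net$inputs, function(v) v - 1L),
    truth_tables = net$truth_tables
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  for (f in c("nodes", "inputs", "truth_tables")) {
    if (is.null(obj[[f]])) stop("network JSON is missing field '", f, "'")
  }
  boolean_network(
    inputs = lapply(obj$inputs, function(v) as.integer(v) + 1L),
    truth_tables = lapply(obj$truth_tables, as.integer),
    node_names = as.character(unlist(obj$nodes))
  )
}

#' Read and write BoolNet-style rule text
#'
#' Interchange format used by Boolean-network tools: a header line
#' `targets, factors` followed by one `target, expression` line per node,
#' with `&` (and), `|` (or), `!` (not) and parentheses. On write, each
#' node's function is emitted as a disjunction of minterms over its inputs in
#' stored order, so non-constant rules round-trip bit-exactly; constant rules
#' are written as `0` or `1` (their input wiring is dynamically irrelevant
#' and is not preserved). On read, a rule's inputs are taken in order of
#' first appearance in the expression, most-significant first.
#'
#' @param net a [boolean_network()].
#' @param path file path.
#' @return `read_network_rules()` returns a `boolean_network`;
#'   `write_network_rules()` returns `path` invisibly.
#' @export
write_network_rules <- function(net, path) {
  stopifnot(inherits(net, "boolean_network"))
  lines <- "targets, factors"
  for (i in seq_len(net$n)) {
    tt <- net$truth_tables[[i]]
    vars <- net$node_names[net$inputs[[i]]]
    expr <- if (all(tt == 0L)) {
      "0"
    } else if (all(tt == 1L) && length(vars) == 0L) {
      "1"
    } else {
      ones <- which(tt == 1L) - 1L
      terms <- vapply(ones, function(t) {
        bits <- rev(state_bit(t, seq_along(vars)))  # most-significant first
        lits <- ifelse(bits == 1L, vars, paste0("!", vars))
        paste0("(", paste(lits, collapse = " & "), ")")
      }, "")
      paste(terms, collapse = " | ")
    }
    lines <- c(lines, paste0(net$node_names[i], ", ", expr))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_network_rules
#' @export
read_network_rules <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (grepl("^targets\\s*,\\s*factors$", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  parts <- regmatches(lines, regexpr(",", lines), invert = TRUE)
  targets <- vapply(parts, function(p) trimws(p[1]), "")
  exprs <- vapply(parts, function(p) trimws(p[2]), "")
  if (anyDuplicated(targets)) stop("duplicate target gene in rule file")
  bad <- grepl("[^A-Za-z0-9_.!&| ()]", exprs)
  if (any(bad)) {
    stop("unsupported characters in rule expression for: ",
         paste(targets[bad], collapse = ", "))
  }
  inputs <- vector("list", length(targets))
  tts <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    e <- str2lang(exprs[i])
    vars <- all.vars(e)  # order of first appearance = most-significant first
    if (!all(vars %in% targets)) {
      stop("rule for ", targets[i], " references unknown gene(s): ",
           paste(setdiff(vars, targets), collapse = ", "))
    }
    inputs[[i]] <- match(vars, targets)
    k <- length(vars)
    tt <- integer(bitwShiftL(1L, k))
    for (t in seq_along(tt) - 1L) {
      env <- list2env(stats::setNames(
        as.list(as.logical(rev(state_bit(t, seq_len(max(k, 1L)))[seq_len(k)]))),
        vars))
      tt[t + 1L] <- as.integer(isTRUE(as.logical(eval(e, env))))
    }
    tts[[i]] <- tt
  }
  boolean_network(inputs = inputs, truth_tables = tts, node_names = targets)
}
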