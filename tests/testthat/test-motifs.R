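test_that("motif definitions encode inhibition by the partner gene", {
  bs <- motif_definition("BS")
  expect_identical(bs$truth_table, c(1L, 0L, 1L, 1L))
  expect_identical(bs$figure_table, c(1L, 1L, 0L, 1L))
  for (k in c("MI00", "MI0+", "MI++")) {
    d <- motif_definition(k)
    expect_identical(d$truth_table, c(0L, 0L, 1L, 0L))
    expect_identical(d$figure_table, c(0L, 1L, 0L, 0L))
  }
  # stored and figure tables are the same function with the input
  # bits swapped: entry (hi, lo) maps to entry (lo, hi)
  swap <- c(1L, 3L, 2L, 4L)
  for (k in c("BS", "MI00", "MI++")) {
    d <- motif_definition(k)
    expect_identical(d$truth_table, d$figure_table[swap])
  }
  # semantics: the partner (low bit) inhibits, the high bit activates
  mi <- motif_definition("MI00")$truth_table
  expect_identical(mi[2L * 1L + 0L + 1L], 1L)  # activator on, partner off -> on
  expect_identical(mi[2L * 1L + 1L + 1L], 0L)  # partner on silences the gene
  expect_identical(
    vapply(c("BS", "MI00", "MI0+", "MI++"),
           function(k) motif_definition(k)$feedback_loops, 0L),
    c(BS = 0L, MI00 = 0L, `MI0+` = 1L, `MI++` = 2L))
  # names are case-insensitive and MI+0 aliases MI0+
  expect_identical(motif_kind("bs"), "BS")
  expect_identical(motif_kind("mi+0"), "MI0+")
  expect_error(motif_kind("XYZ"), "unknown motif")
})

test_that("standalone switches are multistable under exhaustive enumeration", {
  bs <- find_attractors(motif_network("BS"))
  expect_gte(sum(vapply(bs$attractors, `[[`, "", "kind") == "point"), 2L)
  # the tristable switch: exactly three attractors, all points
  mi <- find_attractors(motif_network("MI++"))
  expect_length(mi, 3L)
  expect_true(all(vapply(mi$attractors, `[[`, "", "kind") == "point"))
  # MI0+ is bistable in isolation
  expect_length(find_attractors(motif_network("MI0+")), 2L)
  # MI00 needs its external activator on to toggle
  expect_length(find_attractors(motif_network("MI00", clamp = 0L)), 1L)
  expect_gte(length(find_attractors(motif_network("MI00", clamp = 1L))), 2L)
  expect_error(motif_network("nope"), "unknown motif")
})

test_that("embedding rewires exactly the selected pair", {
  set.seed(21)
  net <- generate_critical_rbn(10, 2L)
  emb <- embed_motifs(net, "MI0+", copies = 1L)
  out <- emb$network
  pair <- emb$record[[1]]$nodes
  expect_identical(out$n, net$n)
  # untouched nodes keep wiring and logic bit-for-bit
  for (i in setdiff(1:10, pair)) {
    expect_identical(out$inputs[[i]], net$inputs[[i]])
    expect_identical(out$truth_tables[[i]], net$truth_tables[[i]])
  }
  # motif nodes carry the motif table and mutual 2^0 cross-wiring
  for (s in 1:2) {
    u <- pair[s]; v <- pair[3 - s]
    expect_identical(out$truth_tables[[u]], c(0L, 0L, 1L, 0L))
    expect_identical(out$inputs[[u]][2], v)   # last-listed input = 2^0 slot
  }
  # MI0+: the first node of the pair carries the positive self-loop,
  # the second keeps its original high-order source (external signal)
  expect_identical(out$inputs[[pair[1]]][1], pair[1])
  expect_identical(out$inputs[[pair[2]]][1], net$inputs[[pair[2]]][1])
})

test_that("an embedded MI++ pair is a tristable island", {
  set.seed(25)
  net <- generate_critical_rbn(8, 2L)
  emb <- embed_motifs(net, "MI++", copies = 1L)
  pair <- emb$record[[1]]$nodes
  # both nodes read only themselves and each other: u' = u & !v, v' = v & !u
  expect_setequal(emb$network$inputs[[pair[1]]], pair)
  expect_setequal(emb$network$inputs[[pair[2]]], pair)
  # the pair admits the three switch states 00, 10, 01 as invariant patterns
  Dm <- state_map(emb$network)
  ubit <- function(s, j) bitwAnd(bitwShiftR(s, j - 1L), 1L)
  for (s in 0:(2^8 - 1)) {
    u <- ubit(s, pair[1]); v <- ubit(s, pair[2])
    s2 <- Dm[s + 1L]
    expect_identical(ubit(s2, pair[1]), bitwAnd(u, 1L - v))
    expect_identical(ubit(s2, pair[2]), bitwAnd(v, 1L - u))
  }
})

test_that("feedback rewiring differs by motif kind", {
  set.seed(22)
  net <- generate_critical_rbn(8, 2L)
  for (kind in c("BS", "MI00", "MI0+", "MI++")) {
    set.seed(33)  # same node selection for every kind
    emb <- embed_motifs(net, kind, copies = 1L)
    pair <- emb$record[[1]]$nodes
    self_loops <- vapply(1:2, function(s) {
      emb$network$inputs[[pair[s]]][1] == pair[s]
    }, TRUE)
    expected <- switch(kind, BS = 0L, MI00 = 0L, `MI0+` = 1L, `MI++` = 2L)
    expect_identical(sum(self_loops), expected)
    tab <- motif_definition(kind)$truth_table
    for (u in pair) expect_identical(emb$network$truth_tables[[u]], tab)
  }
})

test_that("zero copies is the identity and two copies are disjoint", {
  set.seed(23)
  net <- generate_critical_rbn(9, 2L)
  expect_identical(embed_motifs(net, "BS", copies = 0L)$network, net)
  emb2 <- embed_motifs(net, "MI++", copies = 2L)
  nodes <- unlist(lapply(emb2$record, `[[`, "nodes"))
  expect_length(nodes, 4L)
  expect_identical(anyDuplicated(nodes), 0L)
  # both pairs mutually cross-wired on the 2^0 slot
  for (rec in emb2$record) {
    p <- rec$nodes
    expect_identical(emb2$network$inputs[[p[1]]][2], p[2])
    expect_identical(emb2$network$inputs[[p[2]]][2], p[1])
  }
  expect_error(embed_motifs(generate_critical_rbn(3, 2L), "BS", copies = 2L),
               "at least 4 nodes")
})

test_that("embedding is reproducible under a fixed seed", {
  net <- generate_critical_rbn(8, 2L, seed = 77)
  set.seed(5)
  a <- embed_motifs(net, "MI++", 2L)
  set.seed(5)
  b <- embed_motifs(net, "MI++", 2L)
  expect_identical(a, b)
})

test_that("nodes with in-degree other than 2 are adjusted before rewiring", {
  net <- boolean_network(
    inputs = list(c(2L, 3L, 4L), 1L, c(1L, 2L), c(2L, 3L)),
    truth_tables = list(rep(0:1, 4), c(1L, 0L), c(0L, 1L, 1L, 0L),
                        c(1L, 0L, 0L, 1L)))
  set.seed(6)
  emb <- embed_motifs(net, "MI00", copies = 2L)
  expect_true(all(lengths(emb$network$inputs[unlist(lapply(emb$record,
                                                           `[[`, "nodes"))]) == 2L))
  adjusted <- unlist(lapply(emb$record, `[[`, "degree_adjusted"))
  expect_setequal(adjusted, c(1L, 2L))  # the degree-3 and degree-1 nodes
})
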