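#' Ensemble configuration
#'
#' Bundles every parameter of the Monte-Carlo protocol: generate a critical
#' RBN, embed 0/1/2 switch copies, keep the network only if it has at least
#' `min_attractors` attractors, compute its MFPT landscape, classify pairs,
#' and repeat until `networks_per_type` networks are accepted for each
#' network type.
#'
#' The nine canonical network types are `"none"` (no switch) and
#' `"<motif>x<copies>"` for each motif in `BS`, `MI00`, `MI0+`, `MI++` and
#' one or two copies (e.g. `"MI0+x2"`). Motif names are matched
#' case-insensitively; `MI+0` is accepted for `MI0+`.
#'
#' @param networks_per_type accepted networks per type (default 200, a
#'   scaled-down version of the full 5000-network protocol).
#' @param network_types character vector of types (default: all nine).
#' @param min_attractors acceptance floor on the attractor count (default 5).
#' @param n_range node counts, drawn uniformly per attempt (default `8:10`).
#' @param q in-degree (default 2).
#' @param p_N truth-table bias; default `critical_bias(q)` (critical regime).
#' @param p_e per-gene flip probability (default 0.01).
#' @param dir_ratio_threshold,sep_threshold pair-classification thresholds.
#' @param master_seed integer seed from which independent per-type streams
#'   are derived (default 1).
#' @param max_attempts_per_network attempt budget, as a multiple of
#'   `networks_per_type` (default 100).
#' @param allow_self_input passed to [generate_critical_rbn()].
#' @return An object of class `ensemble_config` (a validated list).
#' @export
ensemble_config <- function(networks_per_type = 200L,
                            network_types = all_network_types(),
                            min_attractors = 5L,
                            n_range = 8:10, q = 2L, p_N = NULL,
                            p_e = 0.01,
                            dir_ratio_threshold = 10, sep_threshold = 1e3,
                            master_seed = 1L,
                            max_attempts_per_network = 100L,
                            allow_self_input = TRUE) {
  stopifnot(networks_per_type >= 1L, min_attractors >= 2L,
            all(n_range >= 2L), q >= 1L, max_attempts_per_network >= 1L)
  network_types <- vapply(network_types, normalize_network_type, "",
                          USE.NAMES = FALSE)
  if (anyDuplicated(network_types)) stop("duplicate network types")
  if (is.null(p_N)) p_N <- critical_bias(q)
  structure(
    list(networks_per_type = as.integer(networks_per_type),
         network_types = network_types,
         min_attractors = as.integer(min_attractors),
         n_range = as.integer(n_range), q = as.integer(q), p_N = p_N,
         p_e = p_e, dir_ratio_threshold = dir_ratio_threshold,
         sep_threshold = sep_threshold,
         master_seed = as.integer(master_seed),
         max_attempts_per_network = as.integer(max_attempts_per_network),
         allow_self_input = allow_self_input),
    class = "ensemble_config"
  )
}

#' @rdname ensemble_config
#' @export
all_network_types <- function() {
  c("none", paste0(rep(c("BS", "MI00", "MI0+", "MI++"), each = 2), "x", 1:2))
}

normalize_network_type <- function(type) {
  t <- trimws(type)
  if (tolower(t) == "none") return("none")
  m <- regmatches(t, regexec("^(.+)[xX]([12])$", t))[[1]]
  if (length(m) != 3L) {
    stop("cannot parse network type '", type,
         "'; expected 'none' or '<motif>x<1|2>'")
  }
  paste0(motif_kind(m[2]), "x", m[3])
}

parse_network_type <- function(type) {
  if (type == "none") return(list(motif = NA_character_, copies = 0L))
  m <- regmatches(type, regexec("^(.+)x([12])$", type))[[1]]
  list(motif = m[2], copies = as.integer(m[3]))
}

# deterministic per-type seed stream derived from the master seed and the
# type's position in the canonical list, so each type reproduces in isolation
type_seed <- function(master_seed, type) {
  idx <- match(type, all_network_types())
  if (is.na(idx)) idx <- 100L + (utf8ToInt(substr(type, 1, 1)) %% 26L)
  as.integer((as.numeric(master_seed) * 131L + idx * 7919L) %% 2147483647)
}

#' Run the search for one network type
#'
#' Repeats generate / embed / enumerate / accept / analyze until
#' `networks_per_type` networks with at least `min_attractors` attractors
#' have been accepted (or the attempt budget runs out). The RNG stream is
#' seeded from `master_seed` and the type's canonical index, so each type is
#' reproducible independently of which other types run.
#'
#' @param type a network type string (see [ensemble_config()]).
#' @param config an [ensemble_config()].
#' @param partial_ok if `FALSE` (default) an exhausted attempt budget is an
#'   error; if `TRUE` it produces a warning and a partial result.
#' @return A list with `pairs` (classified pair records across accepted
#'   networks, with `network_id`, `type`, `motif`, `copies`, `n_nodes`
#'   columns), `attempts`, `accepted`, `seed`.
#' @export
run_type <- function(type, config, partial_ok = FALSE) {
  stopifnot(inherits(config, "ensemble_config"))
  type <- normalize_network_type(type)
  spec <- parse_network_type(type)
  seed <- type_seed(config$master_seed, type)
  set.seed(seed)
  target <- config$networks_per_type
  budget <- config$max_attempts_per_network * target
  accepted <- 0L
  attempts <- 0L
  tables <- vector("list", target)
  while (accepted < target && attempts < budget) {
    attempts <- attempts + 1L
    n <- if (length(config$n_range) > 1L) {
      sample(config$n_range, 1L)
    } else config$n_range
    net <- generate_critical_rbn(n, config$q, config$p_N,
                                 allow_self_input = config$allow_self_input)
    if (spec$copies > 0L) {
      net <- embed_motifs(net, spec$motif, spec$copies)$network
    }
    aset <- find_attractors(net)
    if (length(aset) < config$min_attractors) next
    mm <- attractor_mfpt_matrix(net, config$p_e, attractor_set = aset)
    pr <- pair_records(mm, config$dir_ratio_threshold, config$sep_threshold)
    accepted <- accepted + 1L
    tables[[accepted]] <- cbind(
      data.frame(type = type, network_id = accepted, n_nodes = n,
                 motif = if (is.na(spec$motif)) "none" else spec$motif,
                 copies = spec$copies),
      pr)
  }
  if (accepted < target) {
    msg <- sprintf("type %s: attempt budget (%d) exhausted with %d/%d accepted",
                   type, budget, accepted, target)
    if (!partial_ok) stop(msg)
    warning(msg)
  }
  list(pairs = do.call(rbind, tables[seq_len(accepted)]),
       attempts = attempts, accepted = accepted, seed = seed)
}

#' Run the full multi-type ensemble
#'
#' Runs [run_type()] for every configured network type (a failing type is
#' recorded and does not abort the others) and aggregates region proportions
#' — the fraction of attractor pairs labelled separate and directional — per
#' type, with bootstrap confidence intervals over networks.
#'
#' @param config an [ensemble_config()].
#' @param bootstrap number of bootstrap resamples for the per-type region
#'   proportion CIs (default 1000; 0 disables).
#' @return An object of class `switch_ensemble`: list with `pairs` (all pair
#'   records), `summary` (per-type data frame: accepted, attempts, pair
#'   counts, `frac_separate`, `frac_directional` and 95% CIs), `config`,
#'   `errors` (per-type failure messages, if any) and `provenance`.
#' @examples
#' cfg <- ensemble_config(networks_per_type = 2, min_attractors = 2,
#'                        n_range = 6L, network_types = c("none", "BSx2"),
#'                        master_seed = 7)
#' ens <- run_ensemble(cfg, bootstrap = 100)
#' ens$summary
#' @export
run_ensemble <- function(config, bootstrap = 1000L) {
  stopifnot(inherits(config, "ensemble_config"))
  results <- list()
  errors <- list()
  for (type in config$network_types) {
    res <- tryCatch(run_type(type, config, partial_ok = TRUE),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors[[type]] <- conditionMessage(res)
    } else {
      results[[type]] <- res
    }
  }
  pairs <- do.call(rbind, c(lapply(results, `[[`, "pairs"),
                            list(make.row.names = FALSE)))
  summ <- do.call(rbind, lapply(names(results), function(type) {
    r <- results[[type]]
    fr <- region_fractions(r$pairs, bootstrap = bootstrap)
    cbind(data.frame(type = type, accepted = r$accepted,
                     attempts = r$attempts, n_pairs = nrow(r$pairs),
                     seed = r$seed),
          fr)
  }))
  rownames(summ) <- NULL
  structure(
    list(pairs = pairs, summary = summ, config = config, errors = errors,
         provenance = list(
           package_version = as.character(utils::packageVersion("switchscape")),
           r_version = R.version.string,
           master_seed = config$master_seed,
           parameters = unclass(config),
           timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))),
    class = "switch_ensemble"
  )
}

#' Region statistics with bootstrap confidence intervals
#'
#' Summarizes how attractor pairs populate the separate and directional
#' landscape regions, on two scales: the *fraction* of pairs carrying each
#' label, and the mean *count* of such pairs per network — the scale on
#' which ensemble density plots accumulate mass (networks of different
#' types differ strongly in how many attractor pairs they produce, so the
#' two scales can disagree). Percentile 95% CIs are obtained by resampling
#' networks (not pairs) with replacement.
#'
#' @param pairs a pair-record data frame with `label` and `network_id`.
#' @param bootstrap resample count (0 disables; CIs are then `NA`).
#' @return One-row data frame: `frac_separate`, `sep_lo`, `sep_hi`,
#'   `frac_directional`, `dir_lo`, `dir_hi`, `separate_per_network`,
#'   `spn_lo`, `spn_hi`, `directional_per_network`, `dpn_lo`, `dpn_hi`.
#' @export
region_fractions <- function(pairs, bootstrap = 1000L) {
  stat <- function(labels, n_nets) {
    c(frac_sep = mean(labels == "separate"),
      frac_dir = mean(labels == "directional"),
      spn = sum(labels == "separate") / n_nets,
      dpn = sum(labels == "directional") / n_nets)
  }
  if (!nrow(pairs)) {
    out <- as.data.frame(as.list(rep(NA_real_, 12)))
    names(out) <- c("frac_separate", "sep_lo", "sep_hi", "frac_directional",
                    "dir_lo", "dir_hi", "separate_per_network", "spn_lo",
                    "spn_hi", "directional_per_network", "dpn_lo", "dpn_hi")
    return(out)
  }
  by_net <- split(pairs$label, pairs$network_id)
  est <- stat(pairs$label, length(by_net))
  ci <- matrix(NA_real_, 2, 4)
  if (bootstrap > 0L && nrow(pairs)) {
    bs <- vapply(seq_len(bootstrap), function(b) {
      pick <- sample.int(length(by_net), replace = TRUE)
      stat(unlist(by_net[pick], use.names = FALSE), length(pick))
    }, numeric(4))
    ci <- apply(bs, 1L, stats::quantile, probs = c(0.025, 0.975))
  }
  data.frame(frac_separate = est[["frac_sep"]],
             sep_lo = ci[1, 1], sep_hi = ci[2, 1],
             frac_directional = est[["frac_dir"]],
             dir_lo = ci[1, 2], dir_hi = ci[2, 2],
             separate_per_network = est[["spn"]],
             spn_lo = ci[1, 3], spn_hi = ci[2, 3],
             directional_per_network = est[["dpn"]],
             dpn_lo = ci[1, 4], dpn_hi = ci[2, 4])
}

#' Bootstrap contrast of a region proportion between two types
#'
#' Percentile bootstrap (resampling networks independently within each type)
#' for the difference in a region proportion between two network types, e.g.
#' the two-switch minus no-switch contrast in the fraction of well-separated
#' pairs.
#'
#' @param ensemble a [run_ensemble()] result.
#' @param type_a,type_b network type strings; the contrast is `a - b`.
#' @param region `"separate"` or `"directional"`.
#' @param measure `"per_network"` (default): difference in mean region pairs
#'   per network, the scale on which density plots accumulate;
#'   `"fraction"`: difference in the fraction of pairs labelled `region`.
#' @param bootstrap resample count (default 1000).
#' @return List with `estimate`, `ci` (length-2, 95%), `region`, `measure`,
#'   `types`.
#' @export
compare_types <- function(ensemble, type_a, type_b,
                          region = c("separate", "directional"),
                          measure = c("per_network", "fraction"),
                          bootstrap = 1000L) {
  stopifnot(inherits(ensemble, "switch_ensemble"))
  region <- match.arg(region)
  measure <- match.arg(measure)
  type_a <- normalize_network_type(type_a)
  type_b <- normalize_network_type(type_b)
  pa <- ensemble$pairs[ensemble$pairs$type == type_a, ]
  pb <- ensemble$pairs[ensemble$pairs$type == type_b, ]
  if (!nrow(pa) || !nrow(pb)) stop("no pairs recorded for a requested type")
  ba <- split(pa$label, pa$network_id)
  bb <- split(pb$label, pb$network_id)
  stat <- function(by_net) {
    hits <- vapply(by_net, function(l) sum(l == region), 0)
    if (measure == "per_network") mean(hits)
    else sum(hits) / sum(lengths(by_net))
  }
  est <- stat(ba) - stat(bb)
  diffs <- vapply(seq_len(bootstrap), function(b) {
    stat(ba[sample.int(length(ba), replace = TRUE)]) -
      stat(bb[sample.int(length(bb), replace = TRUE)])
  }, 0)
  list(estimate = est,
       ci = unname(stats::quantile(diffs, c(0.025, 0.975))),
       region = region, measure = measure, types = c(type_a, type_b))
}

#' Per-type MFPT density grid from an ensemble
#'
#' @param ensemble a [run_ensemble()] result.
#' @param type a network type present in the ensemble.
#' @param breaks common log10 bin edges (default: 40 bins over 0..8).
#' @param normalize passed to [density_grid()] (default `TRUE` so grids of
#'   different types can be differenced).
#' @return A [density_grid()].
#' @export
ensemble_density <- function(ensemble, type,
                             breaks = seq(0, 8, length.out = 41L),
                             normalize = TRUE) {
  stopifnot(inherits(ensemble, "switch_ensemble"))
  type <- normalize_network_type(type)
  p <- ensemble$pairs[ensemble$pairs$type == type, ]
  if (!nrow(p)) stop("no pairs recorded for type ", type)
  density_grid(p$forward, p$reverse, breaks = breaks, normalize = normalize)
}

#' @export
print.switch_ensemble <- function(x, ...) {
  cat(sprintf("Switch ensemble: %d type(s), %d accepted networks, %d pairs\n",
              length(unique(x$pairs$type)),
              sum(x$summary$accepted), nrow(x$pairs)))
  cat(sprintf("  p_e = %g, n in {%s}, q = %d, min attractors = %d, seed = %d\n",
              x$config$p_e, paste(x$config$n_range, collapse = ","),
              x$config$q, x$config$min_attractors, x$config$master_seed))
  print(x$summary[, c("type", "accepted", "attempts", "n_pairs",
                      "frac_separate", "frac_directional",
                      "separate_per_network", "directional_per_network")],
        row.names = FALSE, digits = 3)
  if (length(x$errors)) {
    cat("Failed types:\n")
    for (t in names(x$errors)) cat("  ", t, ": ", x$errors[[t]], "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.switch_ensemble <- function(object, ...) object$summary

#' @describeIn run_ensemble bar plot of region proportions by type with
#'   bootstrap CIs.
#' @param x a `switch_ensemble`.
#' @param ... unused.
#' @export
plot.switch_ensemble <- function(x, ...) {
  s <- x$summary
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  for (reg in c("separate", "directional")) {
    est <- s[[paste0("frac_", reg)]]
    lo <- s[[if (reg == "separate") "sep_lo" else "dir_lo"]]
    hi <- s[[if (reg == "separate") "sep_hi" else "dir_hi"]]
    bp <- graphics::barplot(est, names.arg = s$type, las = 2,
                            ylim = c(0, max(hi, est, na.rm = TRUE) * 1.1),
                            ylab = paste("fraction", reg))
    if (!all(is.na(lo))) graphics::arrows(bp, lo, bp, hi, angle = 90,
                                          code = 3, length = 0.03)
  }
  invisible(x)
}

#' Write ensemble outputs to disk
#'
#' Emits `pairs.csv` (all classified pair records), `summary.csv` (per-type
#' region proportions) and `provenance.json` (all parameters, seeds,
#' versions) into `dir`.
#'
#' @param ensemble a [run_ensemble()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "switch_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(ensemble$pairs, file.path(dir, "pairs.csv"),
                   row.names = FALSE)
  utils::write.csv(ensemble$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(ensemble$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
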