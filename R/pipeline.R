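## Configuration-driven orchestration: fit -> reconstruct -> events -> LTT
## -> climate correlation, with file-based inputs and outputs.  Every
## default is materialised into the echoed config so a run log suffices to
## reproduce the analysis.

pipeline_defaults <- function() {
  list(max_range_size = NULL, models = list("DEC"),
       root_prior = "uniform", event_time_rule = "midpoint",
       density_bandwidth = 1, grid_step = 0.1, loess_span = 0.25,
       slope_delta = 0.1, period_boundaries = list(),
       period_labels = list("All"), n_starts = 3, seed = 1)
}

#' Read and validate an analysis configuration
#'
#' The configuration is a single YAML file naming the inputs (tree, tip
#' ranges, temperature CSV), the area set and adjacency, the epoch
#' boundaries and multiplier matrices, the model families to fit, and the
#' analysis settings (root prior, density bandwidth, loess span, slope
#' step, period boundaries, seed, optimiser starts).  All defaults are
#' materialised at load time; relative paths resolve against the config
#' file's directory.  Validation fails before any computation: referenced
#' files must exist and every area pair needs a multiplier in every epoch
#' (supply full matrices under `matrix`, or a complete `pairs` map such as
#' `WNA-EA: 0.5`).
#'
#' @param path YAML config file.
#' @return validated config list of class `biogeo_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  validate_config(cfg, base)
}

#' @rdname read_config
#' @param cfg a config list (as parsed from YAML).
#' @param base directory against which relative paths resolve.
#' @export
validate_config <- function(cfg, base = ".") {
  defs <- pipeline_defaults()
  for (k in names(defs))
    if (is.null(cfg[[k]])) cfg[[k]] <- defs[[k]]
  for (k in c("areas", "tree", "tip_ranges", "temperature", "epochs"))
    if (is.null(cfg[[k]])) stop("config is missing required field '", k, "'")
  for (k in c("tree", "tip_ranges", "temperature")) {
    p <- cfg[[k]]
    if (!file.exists(p)) {
      p2 <- file.path(base, p)
      if (!file.exists(p2)) stop("config ", k, " file not found: ", p)
      cfg[[k]] <- p2
    }
  }
  adj <- lapply(cfg$adjacent %||% list(), unlist)
  areas <- area_set(unlist(cfg$areas), adjacent = adj)
  if (is.null(cfg$max_range_size)) cfg$max_range_size <- areas$n
  boundaries <- as.numeric(unlist(cfg$epochs$boundaries %||% list()))
  mults <- lapply(cfg$epochs$multipliers, config_multiplier_matrix,
                  areas = areas)
  epochs <- epoch_schedule(areas, boundaries, mults)
  cfg$models <- as.list(unlist(cfg$models))
  bad <- setdiff(unlist(cfg$models),
                 c("DEC", "DEC+J", "BAYAREALIKE", "BAYAREALIKE+J"))
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "))
  if (length(unlist(cfg$period_labels)) !=
      length(unlist(cfg$period_boundaries)) + 1L)
    stop("need one period label per period (boundaries + 1)")
  structure(c(cfg, list(.areas = areas, .epochs = epochs)),
            class = "biogeo_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one epoch's multipliers: either `matrix` (list of rows, area order) or a
# complete `pairs` map like `WNA-EA: 0.5`
config_multiplier_matrix <- function(spec, areas) {
  n <- areas$n
  if (!is.null(spec$matrix)) {
    m <- do.call(rbind, lapply(spec$matrix, unlist))
    if (!all(dim(m) == n))
      stop("epoch multiplier matrix must be ", n, "x", n)
    dimnames(m) <- list(areas$codes, areas$codes)
    return(m)
  }
  if (!is.null(spec$pairs)) {
    m <- matrix(NA_real_, n, n, dimnames = list(areas$codes, areas$codes))
    diag(m) <- 0
    for (key in names(spec$pairs)) {
      ab <- strsplit(key, "-", fixed = TRUE)[[1]]
      if (length(ab) != 2 || !all(ab %in% areas$codes))
        stop("bad pair key '", key, "' (expected e.g. ",
             areas$codes[1], "-", areas$codes[2], ")")
      m[ab[1], ab[2]] <- m[ab[2], ab[1]] <- as.numeric(spec$pairs[[key]])
    }
    miss <- which(is.na(m) & row(m) != col(m), arr.ind = TRUE)
    if (nrow(miss))
      stop("missing multiplier for pair(s): ",
           paste(unique(paste(areas$codes[pmin(miss[, 1], miss[, 2])],
                              areas$codes[pmax(miss[, 1], miss[, 2])],
                              sep = "-")), collapse = ", "))
    return(m)
  }
  stop("each epoch needs a 'matrix' or a 'pairs' entry")
}

parse_model_spec <- function(spec) {
  with_j <- grepl("\\+J$", spec)
  list(family = sub("\\+J$", "", spec), with_j = with_j)
}

#' Build a fit object from fixed parameters (no optimisation)
#'
#' Computes the likelihood once at the supplied parameter values and wraps
#' it in a `biogeo_fit` so downstream stages ([ancestral_ranges()], event
#' extraction) can run on externally chosen or previously fitted
#' parameters.
#'
#' @inheritParams fit_biogeo
#' @param d,e,j model parameters.
#' @return a `biogeo_fit`.
#' @export
biogeo_fit_fixed <- function(tree, tip_ranges, areas, family, d, e, j = 0,
                             epochs = NULL, max_range_size = areas$n,
                             root_prior = NULL) {
  if (is.null(epochs)) epochs <- uniform_epochs(areas)
  tip_ranges <- coerce_tip_ranges(tip_ranges, areas)
  space <- state_space(areas, max_range_size)
  model <- biogeo_model(family, d, e, j)
  lnL <- prune_likelihood(tree, tip_ranges, space, model, epochs,
                          root_prior)
  n <- ape::Ntip(tree)
  k <- if (j > 0) 3L else 2L
  structure(list(model = model, lnL = lnL, k = k, n = n,
                 AICc = -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1),
                 converged = TRUE, starts = list(), with_j = j > 0,
                 tree = tree, tip_ranges = tip_ranges, areas = areas,
                 space = space, epochs = epochs, root_prior = root_prior,
                 fingerprint = data_fingerprint(tree, tip_ranges)),
            class = "biogeo_fit")
}

pipeline_context <- function(cfg) {
  areas <- cfg$.areas
  epochs <- cfg$.epochs
  trees <- read_chronogram(cfg$tree)
  main_tree <- if (inherits(trees, "phylo")) trees else trees[[1]]
  list(cfg = cfg, areas = areas, epochs = epochs,
       trees = if (inherits(trees, "phylo")) list(trees) else trees,
       tree = main_tree,
       tip_ranges = read_tip_ranges(cfg$tip_ranges, areas),
       temperature = read_temperature(cfg$temperature),
       root_prior = if (identical(cfg$root_prior, "uniform")) NULL else
         as.numeric(unlist(cfg$root_prior)))
}

stage_fit <- function(ctx, out_dir) {
  cfg <- ctx$cfg
  fits <- lapply(cfg$models, function(spec) {
    ms <- parse_model_spec(spec)
    fit_biogeo(ctx$tree, ctx$tip_ranges, ctx$areas, family = ms$family,
               epochs = ctx$epochs, with_j = ms$with_j,
               max_range_size = cfg$max_range_size,
               root_prior = ctx$root_prior,
               n_starts = cfg$n_starts, seed = cfg$seed)
  })
  names(fits) <- unlist(cfg$models)
  cmp <- compare_models(fits)
  jsonlite::write_json(
    list(fits = lapply(names(fits), function(nm) {
      f <- fits[[nm]]
      list(name = nm, family = f$model$family, d = f$model$d,
           e = f$model$e, j = f$model$j, with_j = f$with_j,
           lnL = f$lnL, k = f$k, n = f$n, AICc = f$AICc,
           converged = f$converged)
    }),
    best = cmp$model[1]),
    file.path(out_dir, "fits.json"),
    auto_unbox = TRUE, digits = 12, pretty = TRUE)
  write_tsv_c(as.data.frame(cmp), file.path(out_dir, "aicc.tsv"))
  fits
}

best_fit_from_json <- function(ctx, out_dir) {
  fj <- jsonlite::read_json(file.path(out_dir, "fits.json"),
                            simplifyVector = FALSE)
  cand <- Filter(function(f) identical(f$name, fj$best), fj$fits)
  if (!length(cand)) stop("fits.json does not contain its own best model")
  f <- cand[[1]]
  biogeo_fit_fixed(ctx$tree, ctx$tip_ranges, ctx$areas, family = f$family,
                   d = f$d, e = f$e, j = f$j, epochs = ctx$epochs,
                   max_range_size = ctx$cfg$max_range_size,
                   root_prior = ctx$root_prior)
}

stage_ancestral <- function(ctx, out_dir, fit = NULL) {
  if (is.null(fit)) fit <- best_fit_from_json(ctx, out_dir)
  recon <- ancestral_ranges(fit)
  ntot <- nrow(recon$marginal)
  df <- data.frame(
    node = seq_len(ntot),
    age_ma = recon$ages,
    is_tip = seq_len(ntot) <= recon$ntip,
    map_range = state_label(recon$space, recon$map_mask),
    map_prob = recon$marginal[cbind(seq_len(ntot), recon$map)],
    corner_range = ifelse(is.na(recon$corner_map), "",
                          state_label(recon$space,
                                      ifelse(is.na(recon$corner_map_mask), 0L,
                                             recon$corner_map_mask))))
  write_tsv_c(df, file.path(out_dir, "ancestral.tsv"))
  recon
}

stage_events <- function(ctx, out_dir, recon = NULL, fit = NULL) {
  cfg <- ctx$cfg
  if (is.null(recon)) recon <- stage_ancestral(ctx, out_dir, fit = fit)
  events <- extract_events(recon)
  write_events_tsv(events, file.path(out_dir, "events.tsv"))
  dens <- event_density(events, bandwidth = cfg$density_bandwidth,
                        grid_step = cfg$grid_step)
  write_tsv_c(dens$grid, file.path(out_dir, "density.tsv"))
  root_age <- max(recon$ages)
  periods <- make_periods(unlist(cfg$period_boundaries),
                          unlist(cfg$period_labels), root_age)
  write_tsv_c(period_summary(events, periods),
              file.path(out_dir, "periods.tsv"))
  list(events = events, density = dens, periods = periods)
}

stage_ltt <- function(ctx, out_dir) {
  curves <- lapply(ctx$trees, ltt_curve)
  write_ltt_tsv(curves, file.path(out_dir, "ltt.tsv"))
  curves
}

stage_correlate <- function(ctx, out_dir, ev = NULL) {
  cfg <- ctx$cfg
  if (is.null(ev)) {
    events <- read_events_tsv(file.path(out_dir, "events.tsv"))
    dens <- event_density(events, bandwidth = cfg$density_bandwidth,
                          grid_step = cfg$grid_step)
  } else {
    events <- ev$events
    dens <- ev$density
  }
  curve <- fit_temperature(ctx$temperature, span = cfg$loess_span)
  corr <- correlate_events_climate(events, dens, curve,
                                   delta = cfg$slope_delta)
  jsonlite::write_json(
    lapply(corr, function(r) {
      base <- list(status = r$status, n = r$n)
      if (r$status == "ok")
        base <- c(base, list(slope = r$slope, intercept = r$intercept,
                             r_squared = r$r_squared, p_value = r$p_value,
                             ci_lower = unname(r$ci[1]),
                             ci_upper = unname(r$ci[2])))
      base
    }),
    file.path(out_dir, "correlation.json"),
    auto_unbox = TRUE, digits = 12, pretty = TRUE)
  corr
}

#' Read back an events TSV written by [write_events_tsv()]
#'
#' @param path events.tsv path.
#' @return a `biogeo_events` frame.
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  class(ev) <- c("biogeo_events", "data.frame")
  ev
}

#' Run the full analysis pipeline
#'
#' Executes fit, ancestral reconstruction, event extraction, event density,
#' period summary, LTT and climate correlation on the inputs named in the
#' config, writing `fits.json`, `aicc.tsv`, `ancestral.tsv`, `events.tsv`,
#' `density.tsv`, `periods.tsv`, `ltt.tsv`, `correlation.json` and
#' `run_log.txt` (package version, seed and a full config echo including
#' materialised defaults) into `out_dir`.  A failing stage aborts with the
#' stage name in the error.  Given the same config and seed, outputs are
#' byte-identical across runs.
#'
#' @param config path to a YAML config, or a validated `biogeo_config`.
#' @param out_dir output directory (created if needed).
#' @param seed optional override of the config seed.
#' @return (invisibly) a list with the in-memory stage results.
#' @export
run_full <- function(config, out_dir, seed = NULL) {
  cfg <- if (inherits(config, "biogeo_config")) config else
    read_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ctx <- with_stage("load", pipeline_context(cfg))
  fits <- with_stage("fit", stage_fit(ctx, out_dir))
  cmp <- compare_models(fits)
  best <- fits[[match(cmp$model[1], vapply(fits, function(f)
    model_name(f$model), character(1)))]]
  recon <- with_stage("ancestral", stage_ancestral(ctx, out_dir, fit = best))
  ev <- with_stage("events", stage_events(ctx, out_dir, recon = recon))
  ltt <- with_stage("ltt", stage_ltt(ctx, out_dir))
  # the correlate stage reads events.tsv back so that standalone stage runs
  # are bit-identical to a full run
  corr <- with_stage("correlate", stage_correlate(ctx, out_dir))
  echo <- cfg
  echo$.areas <- NULL; echo$.epochs <- NULL
  writeLines(c(
    paste0("paleorange ", as.character(utils::packageVersion("paleorange"))),
    paste0("seed: ", cfg$seed),
    "config:",
    yaml::as.yaml(echo)),
    file.path(out_dir, "run_log.txt"))
  invisible(list(fits = fits, comparison = cmp, recon = recon,
                 events = ev$events, density = ev$density,
                 periods = ev$periods, ltt = ltt, correlation = corr))
}

#' Run one pipeline stage on files
#'
#' Stages: `"fit"`, `"ancestral"`, `"events"`, `"ltt"`, `"correlate"`.
#' Later stages read the earlier stages' outputs (e.g. `fits.json`) from
#' `out_dir`, so each stage can be re-run independently with results
#' identical to [run_full()]'s.
#'
#' @inheritParams run_full
#' @param stage stage name.
#' @return the stage's in-memory result, invisibly.
#' @export
run_stage <- function(config, stage, out_dir, seed = NULL) {
  cfg <- if (inherits(config, "biogeo_config")) config else
    read_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ctx <- pipeline_context(cfg)
  res <- switch(stage,
    fit = stage_fit(ctx, out_dir),
    ancestral = stage_ancestral(ctx, out_dir),
    events = stage_events(ctx, out_dir),
    ltt = stage_ltt(ctx, out_dir),
    correlate = stage_correlate(ctx, out_dir),
    stop("unknown stage: ", stage))
  invisible(res)
}

#' Write a complete synthetic fixture directory
#'
#' Simulates a chronogram, a range history under a given model and epoch
#' schedule, and a temperature series, and writes them as plain-text files
#' (Newick tree, tip-range TSV, true-event TSV, node/corner state TSV,
#' temperature CSV) together with a JSON manifest recording the seed and
#' every parameter.
#'
#' @param dir output directory.
#' @param seed integer seed; sub-stages use fixed offsets from it.
#' @param n_extant,birth,death,fossil_sampling tree parameters
#'   (see [simulate_chronogram()]).
#' @param model a [biogeo_model()].
#' @param epochs an [epoch_schedule()].
#' @param root_range root range string or bitmask.
#' @param trend,noise_sd,step temperature parameters
#'   (see [simulate_temperature()]); default trend spans the tree with a
#'   cooling break.
#' @return (invisibly) the `biogeo_history`.
#' @export
simulate_fixture <- function(dir, seed, n_extant = 20, birth = 0.1,
                             death = 0, fossil_sampling = 0,
                             model = biogeo_model("DEC", 0.01, 0.002),
                             epochs, root_range,
                             trend = NULL, noise_sd = 0.3, step = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_chronogram(n_extant, birth, death, fossil_sampling,
                              seed = seed)
  # fixtures must be fully observable: no dead (null-range) tips
  hist <- simulate_history(tree, model, epochs, root_range,
                           seed = seed + 1000L, require_alive = TRUE)
  root_age <- max(node_ages(tree))
  if (is.null(trend))
    trend <- data.frame(age = c(root_age * 1.05, root_age * 0.6,
                                root_age * 0.3, 0),
                        temperature = c(18, 22, 12, 8))
  temp <- simulate_temperature(trend, noise_sd = noise_sd, step = step,
                               seed = seed + 2000L)
  write_chronogram(tree, file.path(dir, "tree.nwk"))
  write_tip_ranges(hist$tip_ranges, hist$areas,
                   file.path(dir, "tip_ranges.tsv"))
  write_events_tsv(hist$events, file.path(dir, "true_events.tsv"))
  # nodes are keyed by their descendant tip sets, which survive Newick
  # round-trips (ape node numbers do not)
  states <- data.frame(
    clade = node_keys(tree),
    range = vapply(hist$node_states, mask_label, character(1),
                   areas = hist$areas),
    corner_range = ifelse(is.na(hist$corner_states), "",
                          vapply(ifelse(is.na(hist$corner_states), 0L,
                                        hist$corner_states),
                                 mask_label, character(1),
                                 areas = hist$areas)))
  write_tsv_c(states, file.path(dir, "node_states.tsv"))
  write_temperature(temp, file.path(dir, "temperature.csv"))
  jsonlite::write_json(
    list(seed = seed, n_extant = n_extant, birth = birth, death = death,
         fossil_sampling = fossil_sampling,
         model = list(family = model$family, d = model$d, e = model$e,
                      j = model$j),
         root_range = mask_label(
           if (is.character(root_range))
             range_mask(epochs$areas, root_range) else root_range,
           epochs$areas),
         boundaries = epochs$boundaries,
         noise_sd = noise_sd, step = step),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = 12,
    pretty = TRUE)
  invisible(hist)
}

#' Rebuild a true-history object from a fixture's node-state table
#'
#' Reads the `node_states.tsv` written by [simulate_fixture()] so that
#' [extract_events()] can run on the TRUE states without re-simulating.
#'
#' @param path node_states.tsv path.
#' @param tree the fixture's chronogram.
#' @param areas the fixture's [area_set()].
#' @return a minimal `biogeo_history` (no event log).
#' @export
read_history_states <- function(path, tree, areas) {
  st <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = character(0))
  to_mask <- function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_integer_)
    if (s == "(null)") return(0L)
    range_mask(areas, s)
  }
  idx <- match(node_keys(tree), st$clade)
  if (anyNA(idx))
    stop("node_states file does not cover every clade of the tree")
  node_states <- vapply(st$range, to_mask, integer(1))[idx]
  corner_states <- vapply(st$corner_range, to_mask, integer(1))[idx]
  structure(list(tree = tree, areas = areas,
                 space = state_space(areas),
                 node_states = node_states,
                 corner_states = corner_states),
            class = "biogeo_history")
}

# stable per-node identifiers: the sorted descendant tip labels
node_keys <- function(tree) {
  ntip <- ape::Ntip(tree)
  keys <- character(ntip + tree$Nnode)
  keys[seq_len(ntip)] <- tree$tip.label
  post <- ape::reorder.phylo(tree, "postorder")$edge
  sets <- vector("list", ntip + tree$Nnode)
  sets[seq_len(ntip)] <- as.list(tree$tip.label)
  for (k in seq_len(nrow(post))) {
    v <- post[k, 1]
    sets[[v]] <- c(sets[[v]], sets[[post[k, 2]]])
  }
  for (v in (ntip + 1):(ntip + tree$Nnode))
    keys[v] <- paste(sort(unlist(sets[[v]])), collapse = "|")
  keys
}
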