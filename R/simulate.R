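## Forward simulators: every stage of the analysis is testable on data with
## a known generating process and a ground-truth event log.

#' Simulate a birth-death chronogram, optionally with fossil tips
#'
#' Wraps [ape::rphylo()] (birth-death conditioned on the number of extant
#' tips).  With `death > 0`, extinct lineages are retained as fossil tips
#' with probability `1 - exp(-fossil_sampling * L)` where `L` is the
#' extinct lineage's terminal branch length (a Poisson fossilisation model
#' applied to its terminal branch); unsampled extinct lineages are pruned.
#' `fossil_sampling = 0` yields an ultrametric tree.
#'
#' @param n_extant number of extant tips (>= 2).
#' @param birth,death speciation and extinction rates, events/Ma,
#'   `birth > death >= 0`.
#' @param fossil_sampling fossil recovery rate, per Ma of extinct terminal
#'   branch.
#' @param seed optional integer seed (uses and restores a private RNG
#'   stream).
#' @return a chronogram (`phylo`).
#' @export
simulate_chronogram <- function(n_extant, birth, death = 0,
                                fossil_sampling = 0, seed = NULL) {
  if (n_extant < 2) stop("n_extant must be >= 2")
  if (!(birth > death) || death < 0) stop("need birth > death >= 0")
  run <- function() {
    tr <- ape::rphylo(n_extant, birth = birth, death = death,
                      fossils = death > 0 && fossil_sampling > 0)
    if (death > 0 && fossil_sampling > 0) {
      ages <- node_ages(tr)
      extinct <- which(ages[seq_len(ape::Ntip(tr))] > 1e-9)
      if (length(extinct)) {
        tl <- tr$edge.length[match(extinct, tr$edge[, 2])]
        keep_p <- 1 - exp(-fossil_sampling * tl)
        drop <- extinct[stats::runif(length(extinct)) >= keep_p]
        if (length(drop))
          tr <- ape::drop.tip(tr, drop)
      }
    }
    tr
  }
  tr <- if (is.null(seed)) run() else local_rng(seed, run())
  validate_chronogram(tr)
}

#' Simulate range evolution along a chronogram
#'
#' Forward simulation of the anagenetic gain/loss process by Gillespie
#' jumps with epoch-correct piecewise-constant rates (waiting times are
#' redrawn at each epoch boundary, which is exact for piecewise-constant
#' rates), and cladogenetic outcomes drawn from
#' [cladogenesis_distribution()] with random child assignment.  Every
#' anagenetic jump and every cladogenetic vicariance or founder event is
#' logged as a typed, timed, scoped event; subset-sympatry and copy
#' outcomes change no range union and are recorded only through the corner
#' states.  A lineage that loses its last area is dead: it keeps the null
#' range to its tip.
#'
#' @param tree a chronogram.
#' @param model a [biogeo_model()].
#' @param epochs an [epoch_schedule()].
#' @param root_range root range as bitmask or range string.
#' @param max_range_size cap on range size.
#' @param seed optional integer seed.
#' @param require_alive condition the simulation on every tip being
#'   observable (no dead, null-range tips) by redrawing the history up to
#'   `max_tries` times; errors if the condition is never met.
#' @param max_tries retry budget for `require_alive`.
#' @return object of class `biogeo_history`: `tree`, `model`, `epochs`,
#'   `space`, `areas`, `node_states` and `corner_states` (bitmask per ape
#'   node; corners `NA` at the root), `tip_ranges` (named bitmasks),
#'   `events` (a `biogeo_events` frame of the TRUE history, exact times),
#'   `has_dead` flag and `seed`.
#' @export
simulate_history <- function(tree, model, epochs, root_range,
                             max_range_size = epochs$areas$n, seed = NULL,
                             require_alive = FALSE, max_tries = 100) {
  areas <- epochs$areas
  space <- state_space(areas, max_range_size)
  if (is.character(root_range)) root_range <- range_mask(areas, root_range)
  if (root_range == 0L) stop("root range must be nonempty")
  if (space$lookup[root_range + 1L] == 0L)
    stop("root range exceeds max_range_size")
  tree <- validate_chronogram(tree)
  run <- function() {
    for (i in seq_len(if (require_alive) max_tries else 1L)) {
      h <- simulate_history_impl(tree, model, epochs, space, root_range)
      if (!require_alive || !h$has_dead) return(h)
    }
    stop("no fully observable history in ", max_tries,
         " tries; lower the extinction rate or enlarge the root range")
  }
  h <- if (is.null(seed)) run() else local_rng(seed, run())
  h$seed <- seed
  h
}

simulate_history_impl <- function(tree, model, epochs, space, root_range) {
  areas <- epochs$areas
  n <- areas$n
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  clado <- lapply(seq_along(epochs$multipliers), function(k)
    clado_tables(space, model, epochs$multipliers[[k]]))
  node_states <- rep(NA_integer_, nnode)
  corner_states <- rep(NA_integer_, nnode)
  node_states[root] <- root_range
  rows <- list()
  emit <- function(time, type, scope, source, detail, node)
    rows[[length(rows) + 1L]] <<- data.frame(
      time_ma = time, type = type, scope = scope,
      source = mask_label(source, areas), detail = detail, node = node)

  evolve_branch <- function(state, from_age, to_age, node) {
    segs <- epoch_segments(epochs, from_age, to_age)
    for (si in seq_len(segs$n)) {
      t <- segs$from[si]
      m <- epochs$multipliers[[segs$epoch[si]]]
      repeat {
        if (state == 0L) return(0L)
        occ <- which(bitwAnd(state, bits) != 0L)
        gain_rate <- rep(0, n)
        if (length(occ) < space$max_range_size)
          for (b in setdiff(seq_len(n), occ))
            gain_rate[b] <- model$d * sum(m[occ, b])
        loss_rate <- ifelse(seq_len(n) %in% occ, model$e, 0)
        tot <- sum(gain_rate) + sum(loss_rate)
        if (tot <= 0) break
        wait <- stats::rexp(1, tot)
        if (t - wait <= segs$to[si]) break   # next epoch (or branch end)
        t <- t - wait
        pick <- sample.int(2 * n, 1, prob = c(gain_rate, loss_rate))
        if (pick <= n) {
          emit(t, "dispersal",
               transition_scope(areas, state, gained = bits[pick]),
               state, mask_label(bits[pick], areas), node)
          state <- bitwOr(state, bits[pick])
        } else {
          a <- pick - n
          emit(t, "extinction", "n/a", state, mask_label(bits[a], areas),
               node)
          state <- bitwAnd(state, bitwNot(bits[a]))
        }
      }
    }
    state
  }

  # preorder over internal nodes
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  for (v in unique(edges[, 1])) {
    s <- node_states[v]
    ch <- edges[edges[, 1] == v, 2]
    if (s == 0L) {                        # dead lineage: propagate null
      corner_states[ch] <- 0L
      node_states[ch] <- 0L
      next
    }
    tb <- clado[[epoch_at(epochs, ages[v])]][[space$lookup[s + 1L]]]
    pick <- sample.int(length(tb$p), 1, prob = tb$p)
    cl <- space$masks[tb$l[pick]]
    cr <- space$masks[tb$r[pick]]
    if (tb$type[pick] == "vicariance") {
      emit(ages[v], "vicariance",
           transition_scope(areas, s, partition = list(cl, cr)),
           s, paste(mask_label(cl, areas), mask_label(cr, areas),
                    sep = " | "), v)
    } else if (tb$type[pick] == "founder") {
      gained <- if (bitwAnd(cl, bitwNot(s)) != 0L) cl else cr
      emit(ages[v], "dispersal",
           transition_scope(areas, s, gained = gained),
           s, mask_label(gained, areas), v)
    }
    corner_states[ch[1]] <- cl
    corner_states[ch[2]] <- cr
    node_states[ch[1]] <- evolve_branch(cl, ages[v], ages[ch[1]], ch[1])
    node_states[ch[2]] <- evolve_branch(cr, ages[v], ages[ch[2]], ch[2])
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time_ma = numeric(0), type = character(0),
               scope = character(0), source = character(0),
               detail = character(0), node = integer(0))
  ev <- ev[order(-ev$time_ma, ev$node), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("biogeo_events", "data.frame")
  tips <- stats::setNames(node_states[seq_len(ntip)], tree$tip.label)
  structure(list(tree = tree, model = model, epochs = epochs, space = space,
                 areas = areas, root_range = root_range,
                 node_states = node_states, corner_states = corner_states,
                 tip_ranges = tips, events = ev,
                 has_dead = any(tips == 0L)),
            class = "biogeo_history")
}

#' @export
print.biogeo_history <- function(x, ...) {
  cat("Simulated range history (", model_name(x$model), "): ",
      ape::Ntip(x$tree), " tips, root range ",
      mask_label(x$root_range, x$areas), ", ", nrow(x$events),
      " true events\n", sep = "")
  if (x$has_dead) cat("  NOTE: contains dead (null-range) tip(s)\n")
  invisible(x)
}

#' Replay a simulated history and check it against the recorded tip ranges
#'
#' Re-derives every node and tip range by applying the logged anagenetic
#' events to each lineage's corner range, and checks corner ranges against
#' the logged cladogenetic events (copy/subset-sympatry outcomes, which log
#' no event, must leave the corners inside the parent with at least one
#' daughter equal to the parent).  Used by the test suite to enforce the
#' simulator's internal consistency.
#'
#' @param history a `biogeo_history`.
#' @return named bitmask vector of replayed tip ranges; errors on any
#'   inconsistency.
#' @export
replay_history <- function(history) {
  tree <- history$tree
  areas <- history$areas
  ntip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  ev <- history$events
  bits <- bitwShiftL(1L, seq_len(areas$n) - 1L)
  state <- rep(NA_integer_, ntip + tree$Nnode)
  state[ntip + 1L] <- history$root_range
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  for (v in unique(edges[, 1])) {
    s <- state[v]
    ch <- edges[edges[, 1] == v, 2]
    cl <- history$corner_states[ch[1]]
    cr <- history$corner_states[ch[2]]
    node_ev <- ev[ev$node == v & ev$time_ma == ages[v] &
                    ev$type %in% c("vicariance", "dispersal"), , drop = FALSE]
    if (s == 0L) {
      if (cl != 0L || cr != 0L) stop("corners of a dead lineage not null")
    } else if (nrow(node_ev) == 0L) {
      if (bitwOr(cl, cr) != bitwOr(s, bitwOr(cl, cr)) ||
          (cl != s && cr != s))
        stop("eventless cladogenesis at node ", v,
             " is not a copy/subset outcome")
    } else if (node_ev$type[1] == "vicariance") {
      if (bitwAnd(cl, cr) != 0L || bitwOr(cl, cr) != s)
        stop("logged vicariance at node ", v, " does not match corners")
    } else {
      gained <- range_mask(areas, node_ev$detail[1])
      if (!((cl == s && cr == gained) || (cr == s && cl == gained)))
        stop("logged founder event at node ", v, " does not match corners")
    }
    for (k in seq_along(ch)) {
      cur <- if (k == 1L) cl else cr
      br <- ev[ev$node == ch[k] & ev$type %in%
                 c("dispersal", "extinction") & ev$time_ma < ages[v] &
                 ev$time_ma > ages[ch[k]], , drop = FALSE]
      if (nrow(br)) {
        br <- br[order(-br$time_ma), , drop = FALSE]
        for (i in seq_len(nrow(br))) {
          delta <- range_mask(areas, br$detail[i])
          src <- if (br$source[i] == "(null)") 0L else
            range_mask(areas, br$source[i])
          if (src != cur)
            stop("event source mismatch on branch above node ", ch[k])
          cur <- if (br$type[i] == "dispersal") bitwOr(cur, delta)
                 else bitwAnd(cur, bitwNot(delta))
        }
      }
      state[ch[k]] <- cur
    }
  }
  replayed <- stats::setNames(state[seq_len(ntip)], tree$tip.label)
  if (!identical(as.integer(replayed), as.integer(history$tip_ranges)))
    stop("replayed tip ranges differ from the recorded ones")
  replayed
}

#' Drop dead (null-range) tips from a simulated history
#'
#' A lineage that lost its last area is unobservable; for fitting, such
#' tips are pruned from the tree and the range table, exactly as unsampled
#' extinct lineages are absent from real data.
#'
#' @param history a `biogeo_history`.
#' @return list with elements `tree` and `tip_ranges` covering only the
#'   observable tips; errors if fewer than 2 tips survive.
#' @export
prune_dead_tips <- function(history) {
  dead <- names(history$tip_ranges)[history$tip_ranges == 0L]
  if (length(dead) > ape::Ntip(history$tree) - 2L)
    stop("fewer than 2 observable tips survive")
  tree <- if (length(dead)) ape::drop.tip(history$tree, dead) else
    history$tree
  list(tree = validate_chronogram(tree),
       tip_ranges = history$tip_ranges[tree$tip.label])
}

#' Simulate a paleotemperature scatter series
#'
#' Piecewise-linear trend through the supplied knots, evaluated on a
#' regular age grid, plus iid Gaussian noise.
#'
#' @param trend data.frame with columns `age` (Ma) and `temperature`
#'   (degrees C): the knots of the piecewise-linear trend, any order.
#' @param noise_sd Gaussian noise standard deviation, degrees C.
#' @param step age grid step, Ma.
#' @param seed optional integer seed.
#' @return a `temperature_series` data.frame (columns `age_ma`,
#'   `temperature_c`).
#' @export
simulate_temperature <- function(trend, noise_sd = 0.5, step = 0.5,
                                 seed = NULL) {
  stopifnot(is.data.frame(trend), all(c("age", "temperature") %in%
                                        names(trend)))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (step <= 0) stop("step must be > 0")
  rng <- range(trend$age)
  if (diff(rng) <= 0) stop("trend must span a nonempty age interval")
  age <- seq(rng[1], rng[2], by = step)
  base <- stats::approx(trend$age, trend$temperature, xout = age)$y
  noise <- if (is.null(seed)) stats::rnorm(length(age), 0, noise_sd) else
    local_rng(seed, stats::rnorm(length(age), 0, noise_sd))
  temperature_series(age, base + noise)
}
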