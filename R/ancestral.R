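#' Marginal ancestral range reconstruction
#'
#' Computes, for every node, the marginal posterior distribution over range
#' states under a fitted model, by combining inside (pruning) and outside
#' conditional likelihoods propagated with the same epoch-aware branch
#' transitions and cladogenetic weights as the likelihood itself.  Also
#' computes, for every non-root node, the marginal of its "corner" state —
#' the lineage's range immediately after the cladogenesis at its parent.
#'
#' MAP states take the argmax of the marginal; exact ties resolve to the
#' smallest state index (fewest areas, then lexically first bitmask).
#'
#' @param fit a [fit_biogeo()] result (or any list with the same fields,
#'   e.g. one built from fixed parameters).
#' @return an object of class `biogeo_recon` with elements `marginal`
#'   (nodes x states matrix), `map` (state index per node), `map_mask`,
#'   `corner_marginal`, `corner_map`, `corner_map_mask` (NA rows for the
#'   root), `ages`, `lnL` and references to the fit inputs.
#' @export
ancestral_ranges <- function(fit) {
  space <- fit$space; model <- fit$model; epochs <- fit$epochs
  pt <- prep_tree(fit$tree, fit$tip_ranges, space)
  prop <- make_propagator(space, model, epochs)
  S <- length(space$masks)
  nnode <- pt$ntip + pt$tree$Nnode
  root <- pt$ntip + 1L
  clado <- lapply(seq_along(epochs$multipliers), function(k)
    clado_tables(space, model, epochs$multipliers[[k]]))
  epoch_of_node <- epoch_at(epochs, pt$ages)

  ## inside pass (postorder), keeping per-edge transition matrices
  inside <- matrix(0, nnode, S)
  up <- matrix(NA_real_, nnode, S)       # child partial propagated to parent
  Pmat <- vector("list", nnode)          # per child id
  for (i in seq_len(pt$ntip)) inside[i, pt$tip_states[i]] <- 1
  edges <- pt$post
  parent_of <- integer(nnode)
  parent_of[edges[, 2]] <- edges[, 1]
  kids <- split(seq_len(nrow(edges)), edges[, 1])
  vorder <- as.integer(names(kids))[order(match(as.integer(names(kids)),
                                                edges[, 1]))]
  for (v in vorder) {
    ei <- kids[[as.character(v)]]
    for (k in ei) {
      ch <- edges[k, 2]
      Pmat[[ch]] <- branch_matrix(prop, pt$ages[v], pt$ages[ch])
      up[ch, ] <- as.numeric(Pmat[[ch]] %*% inside[ch, ])
    }
    tb_all <- clado[[epoch_of_node[v]]]
    ch1 <- edges[ei[1], 2]; ch2 <- edges[ei[2], 2]
    res <- numeric(S)
    for (s in seq_len(S)) {
      tb <- tb_all[[s]]
      if (length(tb$l))
        res[s] <- sum(tb$p * up[ch1, tb$l] * up[ch2, tb$r])
    }
    sc <- max(res)
    if (!is.finite(sc) || sc <= 0)
      stop("non-finite or zero partial likelihood at node ", v,
           "; data may be impossible under this model")
    inside[v, ] <- res / sc
  }

  ## outside pass (preorder)
  prior <- root_prior_vec(space, fit$root_prior)
  outside <- matrix(0, nnode, S)
  corner_marg <- matrix(NA_real_, nnode, S)
  outside[root, ] <- prior
  for (v in rev(vorder)) {
    ei <- kids[[as.character(v)]]
    ch1 <- edges[ei[1], 2]; ch2 <- edges[ei[2], 2]
    tb_all <- clado[[epoch_of_node[v]]]
    for (pair in list(c(ch1, ch2), c(ch2, ch1))) {
      x <- pair[1]; sib <- pair[2]
      co <- numeric(S)
      for (s in seq_len(S)) {
        w <- outside[v, s]
        if (w <= 0) next
        tb <- tb_all[[s]]
        if (!length(tb$l)) next
        contrib <- w * tb$p * up[sib, tb$r]
        # accumulate over duplicate left indices
        for (ii in seq_along(tb$l)) co[tb$l[ii]] <- co[tb$l[ii]] + contrib[ii]
      }
      cm <- co * up[x, ]
      tot <- sum(cm)
      if (tot > 0) corner_marg[x, ] <- cm / tot
      outside[x, ] <- as.numeric(crossprod(Pmat[[x]], co))
      sc <- max(outside[x, ])
      if (sc > 0) outside[x, ] <- outside[x, ] / sc
    }
  }

  marg <- inside * outside
  tot <- rowSums(marg)
  if (any(tot <= 0)) stop("zero marginal mass at node(s) ",
                          paste(which(tot <= 0), collapse = ", "))
  marg <- marg / tot
  map <- apply(marg, 1, which.max)
  corner_map <- suppressWarnings(apply(corner_marg, 1, function(r)
    if (anyNA(r)) NA_integer_ else which.max(r)))
  structure(list(
    marginal = marg, map = as.integer(map),
    map_mask = space$masks[map],
    corner_marginal = corner_marg,
    corner_map = as.integer(corner_map),
    corner_map_mask = ifelse(is.na(corner_map), NA_integer_,
                             space$masks[corner_map]),
    ages = pt$ages, tree = fit$tree, space = space, areas = fit$areas,
    epochs = epochs, model = model, ntip = pt$ntip
  ), class = "biogeo_recon")
}

#' @export
print.biogeo_recon <- function(x, ...) {
  root <- x$ntip + 1L
  cat("Ancestral range reconstruction (", model_name(x$model), ")\n",
      sep = "")
  cat("  root age ", format(x$ages[root], digits = 6), " Ma, root MAP range ",
      state_label(x$space, x$map_mask[root]), " (p = ",
      format(x$marginal[root, x$map[root]], digits = 4), ")\n", sep = "")
  invisible(x)
}

## ---- event extraction -------------------------------------------------------

#' Extract biogeographic events from a reconstruction or simulated history
#'
#' Reads a deterministic event list off MAP (or true) node and corner
#' ranges.  At each internal node, disjoint corners whose union is the
#' parent range give one vicariance event at the node age; a corner lying
#' outside the parent range gives one founder dispersal at the node age.
#' Along each branch, every area gained between the corner and the child
#' node's range is one dispersal event, and every area lost one extinction
#' event, all placed at the branch midpoint age (gains before losses, areas
#' in area-set order; the source range grows as gains are applied).
#' Dispersal/vicariance scopes come from [transition_scope()]; extinction
#' scope is `"n/a"`.  Events are sorted by age, oldest first.
#'
#' @param x a `biogeo_recon` (from [ancestral_ranges()]) or a
#'   `biogeo_history` (from [simulate_history()], in which case the TRUE
#'   states are used, bypassing inference).
#' @param ... unused.
#' @return data.frame of class `biogeo_events` with columns `time_ma`,
#'   `type`, `scope`, `source`, `detail`, `node`.
#' @export
extract_events <- function(x, ...) UseMethod("extract_events")

#' @export
extract_events.biogeo_recon <- function(x, ...) {
  extract_events_core(x$tree, x$areas, x$space, x$map_mask,
                      x$corner_map_mask, x$ages, x$ntip)
}

#' @export
extract_events.biogeo_history <- function(x, ...) {
  extract_events_core(x$tree, x$areas, x$space, x$node_states,
                      x$corner_states, node_ages(x$tree), ape::Ntip(x$tree))
}

extract_events_core <- function(tree, areas, space, node_mask, corner_mask,
                                ages, ntip) {
  bits <- bitwShiftL(1L, seq_len(areas$n) - 1L)
  rows <- list()
  emit <- function(time, type, scope, source, detail, node)
    rows[[length(rows) + 1L]] <<- data.frame(
      time_ma = time, type = type, scope = scope,
      source = mask_label(source, areas), detail = detail, node = node)
  edges <- tree$edge
  root <- ntip + 1L
  ## cladogenetic events, read from parent vs corner ranges
  for (v in root:(ntip + tree$Nnode)) {
    ch <- edges[edges[, 1] == v, 2]
    par <- node_mask[v]
    cl <- corner_mask[ch[1]]; cr <- corner_mask[ch[2]]
    if (is.na(par) || par == 0L) next    # dead lineage: nothing observable
    if (bitwAnd(cl, cr) == 0L && bitwOr(cl, cr) == par && cl != 0L &&
        cr != 0L && cl != par) {
      emit(ages[v], "vicariance",
           transition_scope(areas, par, partition = list(cl, cr)),
           par, paste(mask_label(cl, areas), mask_label(cr, areas),
                      sep = " | "), v)
    } else {
      for (crn in c(cl, cr)) {
        extra <- bitwAnd(crn, bitwNot(par))
        if (extra == 0L) next            # sympatry / subset sympatry
        if (crn != extra || mask_size(extra) != 1L)
          stop("inconsistent corner state at node ", v, ": corner ",
               mask_label(crn, areas), " vs parent ", mask_label(par, areas))
        emit(ages[v], "dispersal",
             transition_scope(areas, par, gained = extra),
             par, mask_label(extra, areas), v)
      }
    }
  }
  ## anagenetic events, read from corner vs child-node ranges
  for (k in seq_len(nrow(edges))) {
    v <- edges[k, 1]; ch <- edges[k, 2]
    from <- corner_mask[ch]; to <- node_mask[ch]
    if (is.na(from) || is.na(to) || from == to) next
    mid <- (ages[v] + ages[ch]) / 2
    cur <- from
    for (b in which(bitwAnd(bitwAnd(to, bitwNot(from)), bits) == bits)) {
      emit(mid, "dispersal",
           transition_scope(areas, cur, gained = bits[b]),
           cur, mask_label(bits[b], areas), ch)
      cur <- bitwOr(cur, bits[b])
    }
    for (a in which(bitwAnd(bitwAnd(from, bitwNot(to)), bits) == bits)) {
      emit(mid, "extinction", "n/a", cur, mask_label(bits[a], areas), ch)
      cur <- bitwAnd(cur, bitwNot(bits[a]))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time_ma = numeric(0), type = character(0),
               scope = character(0), source = character(0),
               detail = character(0), node = integer(0))
  out <- out[order(-out$time_ma, out$node), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("biogeo_events", "data.frame")
  out
}

#' @export
print.biogeo_events <- function(x, ...) {
  cat("Biogeographic events:", nrow(x), "total (",
      sum(x$type == "dispersal"), "dispersal,",
      sum(x$type == "vicariance"), "vicariance,",
      sum(x$type == "extinction"), "extinction )\n")
  print.data.frame(x, digits = 6)
  invisible(x)
}

## ---- event density ----------------------------------------------------------

#' Kernel density of event times
#'
#' Gaussian kernel density over event ages with reflection at age 0, scaled
#' so that the curve integrates to the event count (not to 1): the curve is
#' an events-per-Ma intensity comparable across event types.
#'
#' @param events a `biogeo_events` frame (or any frame with `time_ma` and
#'   `type`).
#' @param bandwidth kernel standard deviation, Ma.
#' @param grid_step evaluation grid step, Ma.
#' @param types event types to evaluate; default all present.
#' @return object of class `event_density`: list with `grid` (data.frame
#'   `age` plus one column per type), `at_events` (density of each event's
#'   own type at its own time), `bandwidth`, `grid_step`.  Types with no
#'   events get an all-zero column.
#' @export
event_density <- function(events, bandwidth = 1, grid_step = 0.1,
                          types = NULL) {
  stopifnot(bandwidth > 0, grid_step > 0)
  if (is.null(types)) types <- unique(events$type)
  tmax <- if (nrow(events)) max(events$time_ma) + 5 * bandwidth else
    5 * bandwidth
  age <- seq(0, tmax, by = grid_step)
  grid <- data.frame(age = age)
  for (ty in types) {
    ti <- events$time_ma[events$type == ty]
    grid[[ty]] <- event_kde(age, ti, bandwidth)
  }
  at_events <- if (nrow(events)) {
    vapply(seq_len(nrow(events)), function(i)
      event_kde(events$time_ma[i],
                events$time_ma[events$type == events$type[i]], bandwidth),
      numeric(1))
  } else numeric(0)
  structure(list(grid = grid, at_events = at_events,
                 bandwidth = bandwidth, grid_step = grid_step,
                 types = types),
            class = "event_density")
}

# reflected-at-zero Gaussian KDE scaled to integrate to length(times)
event_kde <- function(x, times, bandwidth) {
  if (!length(times)) return(rep(0, length(x)))
  vapply(x, function(t)
    sum(stats::dnorm((t - times) / bandwidth) +
        stats::dnorm((t + times) / bandwidth)) / bandwidth,
    numeric(1))
}

#' Evaluate an event-density curve at arbitrary ages
#'
#' @param dens an [event_density()] object.
#' @param ages ages in Ma.
#' @param type event type (must be one of the densities computed).
#' @param events the events the density was built from.
#' @return numeric densities.
#' @export
density_at <- function(dens, ages, type, events) {
  if (!type %in% dens$types) stop("no density computed for type ", type)
  event_kde(ages, events$time_ma[events$type == type], dens$bandwidth)
}

#' @export
plot.event_density <- function(x, xlab = "Age (Ma)",
                               ylab = "Events / Ma", ...) {
  g <- x$grid
  graphics::matplot(g$age, as.matrix(g[, -1, drop = FALSE]), type = "l",
                    xlim = rev(range(g$age)), xlab = xlab, ylab = ylab, ...)
  graphics::legend("topleft", legend = x$types, lty = seq_along(x$types),
                   col = seq_along(x$types), bty = "n")
  invisible(x)
}

## ---- period summaries -------------------------------------------------------

#' Build labeled warm/cold periods from boundary ages
#'
#' @param boundaries interior boundary ages, Ma, strictly decreasing.
#' @param labels one label per period (`length(boundaries) + 1`), oldest
#'   first.
#' @param oldest age at which the oldest period starts (e.g. the root age).
#' @return data.frame with columns `label`, `age_start`, `age_end`.
#' @export
make_periods <- function(boundaries, labels, oldest) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) && any(diff(boundaries) >= 0))
    stop("period boundaries must be strictly decreasing")
  if (length(labels) != length(boundaries) + 1L)
    stop("need one label per period (", length(boundaries) + 1L, ")")
  if (length(boundaries) && (boundaries[1] >= oldest || boundaries[length(boundaries)] <= 0))
    stop("period boundaries must lie strictly inside (0, ", oldest, ")")
  edges <- c(oldest, boundaries, 0)
  data.frame(label = as.character(labels),
             age_start = edges[-length(edges)], age_end = edges[-1])
}

#' Count events per period, type and scope
#'
#' Tabulates events into labeled age intervals (periods), split by event
#' type and intercontinental/adjacent scope.  An event belongs to the
#' period whose interval `(age_end, age_start]` contains its time; the
#' oldest period is closed at its old end.
#'
#' @param events a `biogeo_events` frame.
#' @param periods data.frame with columns `label`, `age_start`, `age_end`
#'   (see [make_periods()]); intervals must not overlap and are checked to
#'   cover every event.
#' @return data.frame with one row per period x type x scope combination
#'   (zeros included) and a `count` column.
#' @export
period_summary <- function(events, periods) {
  stopifnot(all(c("label", "age_start", "age_end") %in% names(periods)))
  p <- periods[order(-periods$age_start), , drop = FALSE]
  if (any(p$age_start <= p$age_end))
    stop("each period needs age_start > age_end")
  if (nrow(p) > 1 && any(p$age_end[-nrow(p)] > p$age_start[-1] + 1e-9))
    stop("periods must not leave gaps")
  if (nrow(p) > 1 && any(p$age_end[-nrow(p)] < p$age_start[-1] - 1e-9))
    stop("periods must not overlap")
  types <- c("dispersal", "vicariance", "extinction")
  scopes <- c("intercontinental", "adjacent", "n/a")
  out <- expand.grid(label = p$label, type = types, scope = scopes,
                     stringsAsFactors = FALSE)
  out$count <- 0L
  if (nrow(events)) {
    idx <- vapply(events$time_ma, function(t) {
      w <- which(t <= p$age_start + 1e-9 & t > p$age_end - 1e-9 &
                   (t > p$age_end | p$age_end == 0))
      if (!length(w)) NA_integer_ else w[1]
    }, integer(1))
    if (anyNA(idx))
      stop("event(s) outside the period range: ",
           paste(events$time_ma[is.na(idx)], collapse = ", "))
    for (i in seq_len(nrow(events))) {
      r <- out$label == p$label[idx[i]] & out$type == events$type[i] &
        out$scope == events$scope[i]
      out$count[r] <- out$count[r] + 1L
    }
  }
  # drop combinations that cannot occur
  out <- out[!(out$type != "extinction" & out$scope == "n/a") &
               !(out$type == "extinction" & out$scope != "n/a"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write events to TSV
#'
#' @param events a `biogeo_events` frame.
#' @param path output path.
#' @export
write_events_tsv <- function(events, path) {
  write_tsv_c(as.data.frame(events), path)
  invisible(path)
}
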