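#' Specify a range-evolution model
#'
#' The anagenetic process gains single areas at rate
#' `d * sum(multipliers from occupied areas)` and loses single occupied
#' areas at rate `e`, identically for both families.  The families differ
#' at cladogenesis: DEC allows subset sympatry and (singleton) vicariance,
#' BAYAREALIKE copies the parental range to both daughters.  A positive `j`
#' adds founder-event outcomes in which one daughter jumps to a single
#' unoccupied area reachable in the node's epoch, each weighted `j`
#' relative to the unit weight of the family's own outcomes.
#'
#' @param family `"DEC"` or `"BAYAREALIKE"`.
#' @param d base per-pair dispersal (area gain) rate, events/Ma.
#' @param e per-area extinction (range loss) rate, events/Ma.
#' @param j founder-event weight, >= 0; 0 disables the +J component.
#' @return an object of class `biogeo_model`.
#' @export
biogeo_model <- function(family = c("DEC", "BAYAREALIKE"), d, e, j = 0) {
  family <- match.arg(family)
  if (d < 0 || e < 0 || j < 0)
    stop("d, e and j must be non-negative")
  structure(list(family = family, d = d, e = e, j = j),
            class = "biogeo_model")
}

#' @export
print.biogeo_model <- function(x, ...) {
  cat(model_name(x), ": d = ", format(x$d, digits = 6),
      ", e = ", format(x$e, digits = 6),
      if (x$j > 0) paste0(", j = ", format(x$j, digits = 6)), "\n", sep = "")
  invisible(x)
}

model_name <- function(model) {
  paste0(model$family, if (model$j > 0) "+J")
}

#' Anagenetic rate matrix over the range state space
#'
#' Builds the instantaneous rate matrix for one epoch: a range `R` gains an
#' unoccupied area `b` at rate `d * sum_{a in R} m[a, b]` (when the
#' enlarged range respects `max_range_size`), loses any occupied area at
#' rate `e`, and the null range is absorbing.  Rows sum to zero.
#'
#' @param space a [state_space()].
#' @param model a [biogeo_model()].
#' @param multipliers one epoch's multiplier matrix (see
#'   [epoch_schedule()]).
#' @return dense rate matrix, states x states, dimnames = state labels.
#' @export
build_Q <- function(space, model, multipliers) {
  n <- space$areas$n
  S <- length(space$masks)
  m <- as.matrix(multipliers)
  if (!all(dim(m) == n)) stop("multiplier matrix must be ", n, "x", n)
  if (any(m[row(m) != col(m)] < 0 | m[row(m) != col(m)] > 1))
    stop("multipliers must lie in [0, 1]")
  Q <- matrix(0, S, S, dimnames = list(space$labels, space$labels))
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  for (i in seq_len(S)) {
    R <- space$masks[i]
    if (R == 0L) next                       # null range is absorbing
    occ <- which(bitwAnd(R, bits) != 0L)
    if (space$sizes[i] < space$max_range_size) {
      for (b in setdiff(seq_len(n), occ)) {
        rate <- model$d * sum(m[occ, b])
        if (rate > 0)
          Q[i, space$lookup[bitwOr(R, bits[b]) + 1L]] <- rate
      }
    }
    if (model$e > 0) {
      for (a in occ)
        Q[i, space$lookup[bitwAnd(R, bitwNot(bits[a])) + 1L]] <- model$e
    }
    Q[i, i] <- -sum(Q[i, -i])
  }
  Q
}

## ---- propagators: per-epoch matrix exponentials ---------------------------

# Precompute, per epoch, the rate matrix and (when well-conditioned) its
# eigendecomposition so repeated branch transitions cost O(S^2).  Falls
# back to Matrix::expm for defective or ill-conditioned Q.
make_propagator <- function(space, model, epochs) {
  per_epoch <- lapply(epochs$multipliers, function(m) {
    Q <- build_Q(space, model, m)
    eg <- tryCatch(eigen(Q), error = function(e) NULL)
    ok <- FALSE
    Vinv <- NULL
    if (!is.null(eg)) {
      Vinv <- tryCatch(solve(eg$vectors), error = function(e) NULL)
      if (!is.null(Vinv)) {
        recon <- eg$vectors %*% (eg$values * Vinv)
        ok <- max(abs(Re(recon) - Q)) < 1e-9 * (1 + max(abs(Q))) &&
          max(abs(Im(recon))) < 1e-9 * (1 + max(abs(Q)))
      }
    }
    list(Q = Q, ok = ok,
         V = if (ok) eg$vectors, vals = if (ok) eg$values,
         Vinv = if (ok) Vinv)
  })
  list(space = space, model = model, epochs = epochs, per_epoch = per_epoch)
}

segment_matrix <- function(prop, epoch, dt) {
  pe <- prop$per_epoch[[epoch]]
  if (dt <= 0) return(diag(nrow(pe$Q)))
  P <- if (pe$ok) {
    Re(pe$V %*% (exp(pe$vals * dt) * pe$Vinv))
  } else {
    as.matrix(Matrix::expm(pe$Q * dt))
  }
  P[P < 0] <- 0
  P
}

# propagate a conditional-likelihood vector (indexed by state at the young
# end) backwards to the old end of the interval (start_age, end_age)
propagate_vec <- function(prop, start_age, end_age, x) {
  segs <- epoch_segments(prop$epochs, start_age, end_age)
  for (i in rev(seq_len(segs$n))) {         # young -> old
    dt <- segs$from[i] - segs$to[i]
    if (dt <= 0) next
    pe <- prop$per_epoch[[segs$epoch[i]]]
    x <- if (pe$ok) {
      y <- Re(pe$V %*% (exp(pe$vals * dt) * (pe$Vinv %*% x)))
      y
    } else {
      as.matrix(Matrix::expm(pe$Q * dt)) %*% x
    }
    x[x < 0] <- 0
  }
  as.numeric(x)
}

#' Branch transition probabilities under an epoch schedule
#'
#' Cuts the branch at every epoch boundary it crosses and composes the
#' per-segment matrix exponentials in chronological (old to young) order.
#' Rows index the state at the old end of the branch.
#'
#' @param space a [state_space()].
#' @param model a [biogeo_model()].
#' @param epochs an [epoch_schedule()].
#' @param start_age,end_age branch endpoint ages in Ma,
#'   `start_age > end_age >= 0`.
#' @return row-stochastic probability matrix, states x states.
#' @export
branch_transition <- function(space, model, epochs, start_age, end_age) {
  if (start_age < end_age)
    stop("inverted ages: start_age must be >= end_age")
  prop <- make_propagator(space, model, epochs)
  branch_matrix(prop, start_age, end_age)
}

branch_matrix <- function(prop, start_age, end_age) {
  segs <- epoch_segments(prop$epochs, start_age, end_age)
  P <- NULL
  for (i in seq_len(segs$n)) {             # old -> young
    dt <- segs$from[i] - segs$to[i]
    if (dt <= 0) next
    Pi <- segment_matrix(prop, segs$epoch[i], dt)
    P <- if (is.null(P)) Pi else P %*% Pi
  }
  if (is.null(P)) P <- diag(length(prop$space$masks))
  dimnames(P) <- list(prop$space$labels, prop$space$labels)
  P
}

## ---- cladogenesis ----------------------------------------------------------

#' Cladogenetic outcome distribution at a node
#'
#' Enumerates the ordered daughter-range pairs a parent range can produce
#' and their probabilities.  For DEC a single-area parent is copied to both
#' daughters; a wider parent produces, for each single area `a` in the
#' parent, one subset-sympatry outcome `(parent, {a})` and one vicariance
#' outcome `({a}, parent \ {a})`, each with unit weight.  BAYAREALIKE
#' copies the parent regardless of size.  With `j > 0`, founder outcomes
#' `(parent, {b})` are added for every area `b` outside the parent whose
#' incoming multiplier from some parent area is positive in the node's
#' epoch, each with weight `j`.  Weights are normalised to probabilities.
#'
#' The likelihood machinery treats daughter order symmetrically (each
#' ordered outcome is averaged over the two child assignments), so tree
#' likelihoods do not depend on which child is "left".
#'
#' @param space a [state_space()].
#' @param model a [biogeo_model()].
#' @param parent parent range bitmask (nonempty).
#' @param multipliers the multiplier matrix of the node's epoch; used only
#'   to restrict founder targets, `NULL` means unrestricted.
#' @return data.frame with columns `left`, `right` (state indices),
#'   `left_label`, `right_label`, `type` and `prob`.
#' @export
cladogenesis_distribution <- function(space, model, parent,
                                      multipliers = NULL) {
  raw <- clado_raw(space, model, parent, multipliers)
  data.frame(left = state_index(space, raw$l),
             right = state_index(space, raw$r),
             left_label = state_label(space, raw$l),
             right_label = state_label(space, raw$r),
             type = raw$type, prob = raw$w / sum(raw$w))
}

# bare enumeration of cladogenetic outcomes (masks + weights), ordered as
# printed by cladogenesis_distribution
clado_raw <- function(space, model, parent, multipliers = NULL) {
  if (parent == 0L) stop("cladogenesis is undefined for the null range")
  if (space$lookup[parent + 1L] == 0L)
    stop("parent range is not in the state space")
  n <- space$areas$n
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  occ <- which(bitwAnd(parent, bits) != 0L)
  l <- integer(0); r <- integer(0); type <- character(0); w <- numeric(0)
  if (model$family == "BAYAREALIKE" || length(occ) == 1L) {
    l <- parent; r <- parent; type <- "sympatry"; w <- 1
  } else {
    for (a in occ) {
      l <- c(l, parent, bits[a])
      r <- c(r, bits[a], bitwAnd(parent, bitwNot(bits[a])))
      type <- c(type, "subset_sympatry", "vicariance")
      w <- c(w, 1, 1)
    }
  }
  if (model$j > 0) {
    m <- if (is.null(multipliers)) NULL else as.matrix(multipliers)
    for (b in setdiff(seq_len(n), occ)) {
      if (is.null(m) || any(m[occ, b] > 0)) {
        l <- c(l, parent); r <- c(r, bits[b])
        type <- c(type, "founder"); w <- c(w, model$j)
      }
    }
  }
  list(l = l, r = r, type = type, w = w)
}

# symmetrised cladogenesis tables for one epoch: per parent state index, a
# list(l, r, p, type) such that sum over rows of p * f(l) * g(r) averages
# the two child assignments of every ordered outcome (duplicate (l, r)
# rows are allowed; they simply add).  Null parent gets an empty table.
clado_tables <- function(space, model, multipliers) {
  lapply(seq_along(space$masks), function(i) {
    mask <- space$masks[i]
    if (mask == 0L)
      return(list(l = integer(0), r = integer(0), p = numeric(0),
                  type = character(0)))
    raw <- clado_raw(space, model, mask, multipliers)
    p <- raw$w / sum(raw$w)
    li <- space$lookup[raw$l + 1L]
    ri <- space$lookup[raw$r + 1L]
    list(l = c(li, ri), r = c(ri, li), p = c(p, p) / 2,
         type = c(raw$type, raw$type))
  })
}

# same content as clado_tables, flattened to parallel vectors over all
# parent states for vectorised combination in the pruning hot path
clado_flat <- function(space, model, multipliers) {
  tabs <- clado_tables(space, model, multipliers)
  list(s = rep(seq_along(tabs), vapply(tabs, function(t) length(t$l),
                                       integer(1))),
       l = unlist(lapply(tabs, `[[`, "l")),
       r = unlist(lapply(tabs, `[[`, "r")),
       p = unlist(lapply(tabs, `[[`, "p")))
}

## ---- pruning likelihood ----------------------------------------------------

# shared tree bookkeeping for likelihood computations
prep_tree <- function(tree, tip_ranges, space) {
  tree <- validate_chronogram(tree)
  ntip <- ape::Ntip(tree)
  missing <- setdiff(tree$tip.label, names(tip_ranges))
  if (length(missing))
    stop("tip(s) missing from the range table: ",
         paste(missing, collapse = ", "))
  masks <- as.integer(tip_ranges[tree$tip.label])
  if (any(masks == 0L)) stop("tips cannot have the null range")
  if (any(space$lookup[masks + 1L] == 0L))
    stop("some tip ranges exceed max_range_size")
  list(tree = tree, ntip = ntip, ages = node_ages(tree),
       tip_states = space$lookup[masks + 1L],
       post = ape::reorder.phylo(tree, "postorder")$edge)
}

root_prior_vec <- function(space, root_prior = NULL) {
  S <- length(space$masks)
  if (is.null(root_prior)) {
    p <- rep(1 / (S - 1), S)
    p[space$masks == 0L] <- 0
    p
  } else {
    if (length(root_prior) != S || any(root_prior < 0))
      stop("root_prior must be a non-negative vector over all states")
    root_prior / sum(root_prior)
  }
}

#' Tree log-likelihood by pruning
#'
#' Felsenstein pruning with epoch-aware branch transitions and
#' cladogenetic mixing at every internal node.  Tip conditional
#' likelihoods are indicator vectors at the observed ranges (tips may sit
#' at positive ages); daughter partials are propagated to the parent's age
#' with [branch_transition()] semantics and combined through the
#' symmetrised cladogenetic distribution of the node's epoch; the root sums
#' against the root prior (default: uniform over nonempty states).
#'
#' @param tree a chronogram.
#' @param tip_ranges named integer vector of range bitmasks
#'   (see [read_tip_ranges()]).
#' @param space a [state_space()].
#' @param model a [biogeo_model()].
#' @param epochs an [epoch_schedule()].
#' @param root_prior optional prior vector over states.
#' @return log-likelihood (scalar).
#' @export
prune_likelihood <- function(tree, tip_ranges, space, model, epochs,
                             root_prior = NULL) {
  pt <- prep_tree(tree, tip_ranges, space)
  prop <- make_propagator(space, model, epochs)
  S <- length(space$masks)
  nnode <- pt$ntip + pt$tree$Nnode
  nepoch <- length(epochs$multipliers)
  # founder reachability is the only epoch dependence; with j = 0 one
  # table serves every epoch
  clado <- if (model$j == 0) rep(list(clado_flat(space, model,
                                                 epochs$multipliers[[1]])),
                                 nepoch)
           else lapply(seq_len(nepoch), function(k)
             clado_flat(space, model, epochs$multipliers[[k]]))
  partial <- matrix(0, nnode, S)
  logscale <- numeric(nnode)
  for (i in seq_len(pt$ntip)) partial[i, pt$tip_states[i]] <- 1
  edges <- pt$post
  kids <- split(seq_len(nrow(edges)), edges[, 1])
  for (v in as.integer(names(kids))[order(match(as.integer(names(kids)),
                                                edges[, 1]))]) {
    ei <- kids[[as.character(v)]]
    ups <- lapply(ei, function(k) {
      c_id <- edges[k, 2]
      propagate_vec(prop, pt$ages[v], pt$ages[c_id], partial[c_id, ])
    })
    fl <- clado[[epoch_at(epochs, pt$ages[v])]]
    xl <- ups[[1]]; xr <- ups[[2]]
    res <- numeric(S)
    agg <- rowsum(fl$p * xl[fl$l] * xr[fl$r], fl$s)
    res[as.integer(rownames(agg))] <- agg
    sc <- max(res)
    if (!is.finite(sc) || sc <= 0) {
      if (sc == 0) {
        # data impossible under this model
        return(-Inf)
      }
      stop("non-finite partial likelihood at node ", v)
    }
    partial[v, ] <- res / sc
    logscale[v] <- log(sc) +
      sum(logscale[edges[ei, 2]])
  }
  root <- pt$ntip + 1L
  prior <- root_prior_vec(space, root_prior)
  lik <- sum(prior * partial[root, ])
  if (lik <= 0) return(-Inf)
  ll <- log(lik) + logscale[root]
  if (!is.finite(ll)) stop("non-finite log-likelihood")
  ll
}

## ---- maximum-likelihood fit -------------------------------------------------

data_fingerprint <- function(tree, tip_ranges) {
  o <- order(names(tip_ranges))
  list(tips = names(tip_ranges)[o],
       masks = as.integer(tip_ranges[o]),
       tree_len = round(sum(tree$edge.length), 9),
       ntip = ape::Ntip(tree))
}

#' Fit a range-evolution model by maximum likelihood
#'
#' Maximises [prune_likelihood()] over `d`, `e` (and `j` when
#' `with_j = TRUE`) with bounded multi-start optimisation on the log scale
#' (`d, e` in `[1e-9, 10]` events/Ma, `j` in `[1e-9, 100]`).  Start points
#' are drawn deterministically from `seed`, so a fit is reproducible.
#'
#' @param tree a chronogram.
#' @param tip_ranges named integer bitmask vector, or a data frame/named
#'   character vector of range strings (converted with [range_mask()]).
#' @param areas an [area_set()].
#' @param family `"DEC"` or `"BAYAREALIKE"`.
#' @param epochs an [epoch_schedule()]; default single unconstrained epoch.
#' @param with_j fit the founder-event weight `j` as a third parameter.
#' @param max_range_size cap on range size (default: number of areas).
#' @param root_prior optional prior over states.
#' @param n_starts number of optimiser starts (first one from a fixed
#'   heuristic, the rest random on the log scale).
#' @param seed integer seed for the start points.
#' @return an object of class `biogeo_fit` with elements `model`, `lnL`,
#'   `k`, `n`, `AICc`, `converged`, `starts` (trace of every start) and the
#'   data needed by downstream methods.  Methods: `print`, `summary`,
#'   `coef`, `logLik`.
#' @examples
#' \donttest{
#' areas <- area_set(c("A", "B"), adjacent = list(c("A", "B")))
#' tr <- ape::read.tree(text = "((t1:5,t2:5):5,t3:10);")
#' rng <- c(t1 = range_mask(areas, "A"), t2 = range_mask(areas, "B"),
#'          t3 = range_mask(areas, "A"))
#' fit <- fit_biogeo(tr, rng, areas, family = "DEC", n_starts = 2)
#' }
#' @export
fit_biogeo <- function(tree, tip_ranges, areas, family = c("DEC", "BAYAREALIKE"),
                       epochs = NULL, with_j = FALSE,
                       max_range_size = areas$n, root_prior = NULL,
                       n_starts = 5, seed = 1) {
  family <- match.arg(family)
  if (is.null(epochs)) epochs <- uniform_epochs(areas)
  tip_ranges <- coerce_tip_ranges(tip_ranges, areas)
  space <- state_space(areas, max_range_size)
  tree <- validate_chronogram(tree)
  n <- ape::Ntip(tree)
  k <- if (with_j) 3L else 2L
  if (n <= k + 1L)
    stop("need more tips (", n, ") than parameters + 1 (", k + 1L, ")")
  lb <- log(c(1e-9, 1e-9, if (with_j) 1e-9))
  ub <- log(c(10, 10, if (with_j) 100))
  nll <- function(par) {
    p <- exp(par)
    m <- biogeo_model(family, d = p[1], e = p[2],
                      j = if (with_j) p[3] else 0)
    ll <- tryCatch(prune_likelihood(tree, tip_ranges, space, m, epochs,
                                    root_prior),
                   error = function(err) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- list(log(c(0.01, 0.01, if (with_j) 0.1)))
  if (n_starts > 1) {
    rs <- local_rng(seed, {
      lapply(seq_len(n_starts - 1), function(i)
        stats::runif(k, log(1e-4), log(1)))
    })
    starts <- c(starts, rs)
  }
  trace <- lapply(starts, function(s0) {
    opt <- tryCatch(
      stats::optim(s0, nll, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = 500)),
      error = function(err) list(par = s0, value = nll(s0),
                                 convergence = 99L))
    list(par = exp(opt$par), lnL = -opt$value,
         convergence = opt$convergence)
  })
  best <- trace[[which.max(vapply(trace, `[[`, numeric(1), "lnL"))]]
  model <- biogeo_model(family, d = best$par[1], e = best$par[2],
                        j = if (with_j) best$par[3] else 0)
  lnL <- best$lnL
  aicc <- -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  structure(list(
    model = model, lnL = lnL, k = k, n = n, AICc = aicc,
    converged = best$convergence == 0L,
    starts = trace, with_j = with_j,
    tree = tree, tip_ranges = tip_ranges, areas = areas, space = space,
    epochs = epochs, root_prior = root_prior,
    fingerprint = data_fingerprint(tree, tip_ranges)
  ), class = "biogeo_fit")
}

coerce_tip_ranges <- function(tip_ranges, areas) {
  if (is.data.frame(tip_ranges)) {
    tip_ranges <- stats::setNames(tip_ranges[[2]], tip_ranges[[1]])
  }
  if (is.character(tip_ranges)) {
    tip_ranges <- vapply(tip_ranges, function(r) range_mask(areas, r),
                         integer(1))
  }
  storage.mode(tip_ranges) <- "integer"
  tip_ranges
}

#' @export
print.biogeo_fit <- function(x, ...) {
  cat("Range-evolution fit:", model_name(x$model), "\n")
  cat("  tips:", x$n, " states:", length(x$space$masks),
      " epochs:", length(x$epochs$multipliers), "\n")
  cat("  lnL =", format(x$lnL, digits = 8),
      " AICc =", format(x$AICc, digits = 8),
      " (k =", x$k, ")\n")
  print(x$model)
  if (!x$converged) cat("  WARNING: optimiser did not converge\n")
  invisible(x)
}

#' @export
summary.biogeo_fit <- function(object, ...) {
  s <- list(model = model_name(object$model),
            coef = coef.biogeo_fit(object),
            lnL = object$lnL, k = object$k, n = object$n,
            AICc = object$AICc, converged = object$converged,
            starts = do.call(rbind, lapply(object$starts, function(t)
              data.frame(d = t$par[1], e = t$par[2],
                         j = if (length(t$par) > 2) t$par[3] else 0,
                         lnL = t$lnL, convergence = t$convergence))))
  class(s) <- "summary.biogeo_fit"
  s
}

#' @export
print.summary.biogeo_fit <- function(x, ...) {
  cat("Model:", x$model, " lnL =", format(x$lnL, digits = 8),
      " AICc =", format(x$AICc, digits = 8), "\n")
  cat("Coefficients:\n")
  print(x$coef)
  cat("Optimiser starts:\n")
  print(x$starts)
  invisible(x)
}

#' @export
coef.biogeo_fit <- function(object, ...) {
  p <- c(d = object$model$d, e = object$model$e)
  if (object$with_j) p <- c(p, j = object$model$j)
  p
}

#' @export
logLik.biogeo_fit <- function(object, ...) {
  structure(object$lnL, df = object$k, nobs = object$n, class = "logLik")
}

#' Rank fitted models by AICc
#'
#' @param ... `biogeo_fit` objects (or a single list of them), all fitted
#'   to the same tree and tip ranges.
#' @return data.frame of class `biogeo_aicc` sorted by AICc (ties broken
#'   by fewer parameters) with a `dAICc` column relative to the best model.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1]], "biogeo_fit"))
    fits <- fits[[1]]
  stopifnot(all(vapply(fits, inherits, logical(1), "biogeo_fit")))
  if (length(fits) > 1L) {
    fp <- fits[[1]]$fingerprint
    for (f in fits[-1])
      if (!isTRUE(all.equal(fp, f$fingerprint)))
        stop("fits were made on different data; refusing to compare")
  }
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(model = model_name(f$model), d = f$model$d, e = f$model$e,
               j = f$model$j, lnL = f$lnL, k = f$k, AICc = f$AICc)))
  tab <- tab[order(tab$AICc, tab$k), , drop = FALSE]
  tab$dAICc <- tab$AICc - tab$AICc[1]
  tab$best <- seq_len(nrow(tab)) == 1L
  rownames(tab) <- NULL
  class(tab) <- c("biogeo_aicc", "data.frame")
  tab
}

#' @export
print.biogeo_aicc <- function(x, ...) {
  cat("Model comparison (AICc):\n")
  print.data.frame(x, digits = 6)
  invisible(x)
}

# run code with a private RNG stream, restoring the caller's state
local_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}
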