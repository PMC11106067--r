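# Shared fixtures and the independent exhaustive-enumeration oracle.

areas3 <- function() area_set(c("A", "B", "C"), adjacent = list(c("A", "B")))

areas2 <- function() area_set(c("A", "B"), adjacent = list(c("A", "B")))

# exhaustive-enumeration log-likelihood: sums over every assignment of a
# state to every internal node; cladogenesis handled by direct summation
# over the printed outcome distribution with the two child assignments at
# weight 1/2 each.  Deliberately written as plain nested sums, independent
# of the pruning recursion.
enum_loglik <- function(tree, tip_masks, space, model, epochs,
                        want_marginals = FALSE) {
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  S <- length(space$masks)
  prior <- rep(1 / (S - 1), S)
  prior[space$masks == 0] <- 0
  edges <- tree$edge
  internal <- (ntip + 1):(ntip + tree$Nnode)
  P <- lapply(seq_len(nrow(edges)), function(k)
    branch_transition(space, model, epochs,
                      ages[edges[k, 1]], ages[edges[k, 2]]))
  tip_state <- space$lookup[tip_masks[tree$tip.label] + 1]
  grid <- do.call(expand.grid, rep(list(seq_len(S)), length(internal)))
  marg <- matrix(0, ntip + tree$Nnode, S)
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    st <- integer(ntip + tree$Nnode)
    st[internal] <- as.integer(grid[g, ])
    st[seq_len(ntip)] <- tip_state
    p <- prior[st[ntip + 1]]
    if (p == 0) next
    for (v in internal) {
      mask <- space$masks[st[v]]
      if (mask == 0) { p <- 0; break }
      ch <- edges[edges[, 1] == v, 2]
      ei <- which(edges[, 1] == v)
      mult <- epochs$multipliers[[epoch_at(epochs, ages[v])]]
      cd <- cladogenesis_distribution(space, model, mask, mult)
      cv <- sum(cd$prob * 0.5 *
        (P[[ei[1]]][cbind(cd$left, st[ch[1]])] *
           P[[ei[2]]][cbind(cd$right, st[ch[2]])] +
         P[[ei[1]]][cbind(cd$right, st[ch[1]])] *
           P[[ei[2]]][cbind(cd$left, st[ch[2]])]))
      p <- p * cv
      if (p == 0) break
    }
    if (p > 0) {
      tot <- tot + p
      if (want_marginals)
        for (v in internal) marg[v, st[v]] <- marg[v, st[v]] + p
    }
  }
  if (want_marginals) list(lnL = log(tot), marginal = marg / tot)
  else log(tot)
}

# random small likelihood instance over areas3(): tree with <= max_tips
# tips (non-ultrametric, so tips sit at distinct ages), random parameters,
# 1-3 epochs with random multipliers
random_instance <- function(max_tips = 4, family = NULL, j = NULL,
                            n_epochs = NULL) {
  areas <- areas3()
  ntips <- sample(3:max_tips, 1)
  tree <- ape::rtree(ntips)
  space <- state_space(areas, sample(2:3, 1))
  if (is.null(family)) family <- sample(c("DEC", "BAYAREALIKE"), 1)
  if (is.null(j)) j <- sample(c(0, round(stats::runif(1, 0.1, 2), 3)), 1)
  model <- biogeo_model(family, d = stats::runif(1, 0.01, 0.3),
                        e = stats::runif(1, 0, 0.2), j = j)
  if (is.null(n_epochs)) n_epochs <- sample(1:3, 1)
  root_age <- max(node_ages(tree))
  bnd <- if (n_epochs > 1)
    sort(stats::runif(n_epochs - 1, 0.05 * root_age, 0.9 * root_age),
         decreasing = TRUE) else numeric(0)
  mults <- lapply(seq_len(n_epochs), function(i) {
    m <- matrix(round(stats::runif(9), 2), 3, 3,
                dimnames = list(areas$codes, areas$codes))
    diag(m) <- 0
    m
  })
  epochs <- epoch_schedule(areas, bnd, mults)
  nonempty <- space$masks[space$masks > 0]
  tips <- stats::setNames(sample(nonempty, ntips, replace = TRUE),
                          tree$tip.label)
  list(tree = tree, space = space, model = model, epochs = epochs,
       tip_ranges = tips, areas = areas)
}
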