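test_that("a frozen chain yields point-mass marginals everywhere", {
  a3 <- areas3()
  ep <- uniform_epochs(a3)
  tr <- ape::read.tree(text = "((t1:2,t2:2):2,t3:4);")
  rng <- stats::setNames(rep(range_mask(a3, "A"), 3), tr$tip.label)
  fit <- biogeo_fit_fixed(tr, rng, a3, "DEC", d = 0, e = 0, epochs = ep)
  rec <- ancestral_ranges(fit)
  iA <- state_index(rec$space, range_mask(a3, "A"))
  expect_equal(unname(rec$marginal[, iA]), rep(1, 5))
  expect_equal(rec$map_mask, rep(range_mask(a3, "A"), 5))
})

test_that("node marginals equal brute-force posteriors", {
  set.seed(21)
  for (i in 1:4) {
    inst <- random_instance(max_tips = 4)
    fit <- biogeo_fit_fixed(inst$tree, inst$tip_ranges, inst$areas,
                            inst$model$family, d = inst$model$d,
                            e = inst$model$e, j = inst$model$j,
                            epochs = inst$epochs,
                            max_range_size = inst$space$max_range_size)
    rec <- ancestral_ranges(fit)
    oracle <- enum_loglik(inst$tree, inst$tip_ranges, inst$space,
                          inst$model, inst$epochs, want_marginals = TRUE)
    ntip <- ape::Ntip(inst$tree)
    internal <- (ntip + 1):(ntip + inst$tree$Nnode)
    expect_lt(max(abs(rec$marginal[internal, ] -
                        oracle$marginal[internal, ])), 1e-8)
    expect_equal(unname(rowSums(rec$marginal)),
                 rep(1, nrow(rec$marginal)), tolerance = 1e-9)
    # MAP is the argmax with smallest-index tie-break
    expect_equal(rec$map, apply(rec$marginal, 1, which.max))
  }
})

test_that("a cherry with disjoint singleton tips favors the union root", {
  a2 <- areas2()
  ep <- uniform_epochs(a2)
  tr <- ape::read.tree(text = "(t1:5,t2:5);")
  rng <- c(t1 = range_mask(a2, "A"), t2 = range_mask(a2, "B"))
  fit <- biogeo_fit_fixed(tr, rng, a2, "DEC", d = 0.2, e = 0.001,
                          epochs = ep)
  rec <- ancestral_ranges(fit)
  root_map <- rec$map_mask[3]
  expect_equal(state_label(rec$space, root_map), "A+B")
  # cross-check against the enumeration posterior
  oracle <- enum_loglik(tr, rng, state_space(a2), fit$model, ep,
                        want_marginals = TRUE)
  expect_lt(max(abs(rec$marginal[3, ] - oracle$marginal[3, ])), 1e-8)
})

## --- event extraction on hand-built states ---------------------------------

# minimal true-history object for extraction tests
hist_stub <- function(tree, areas, node_states, corner_states) {
  structure(list(tree = tree, areas = areas, space = state_space(areas),
                 node_states = node_states, corner_states = corner_states),
            class = "biogeo_history")
}

test_that("disjoint corners covering the parent give one vicariance event", {
  a6 <- fraxinus_areas()
  tr <- ape::read.tree(text = "(t1:5,t2:5);")   # node 3 at age 5
  st <- c(range_mask(a6, "EA"), range_mask(a6, "EU"),
          range_mask(a6, "EA,EU"))
  crn <- c(range_mask(a6, "EA"), range_mask(a6, "EU"), NA)
  ev <- extract_events(hist_stub(tr, a6, st, crn))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "vicariance")
  expect_equal(ev$time_ma, 5)
  expect_equal(ev$scope, "intercontinental")
  expect_equal(ev$source, "EU+EA")
})

test_that("an anagenetic gain lands mid-branch with the pair-table scope", {
  a6 <- fraxinus_areas()
  # t1's branch spans 42 -> 36 Ma (t2, at depth 42, sets the present);
  # corner WNA, child node WNA+EA
  tr <- ape::read.tree(text = "(t1:6,t2:42);")
  st <- c(range_mask(a6, "WNA,EA"), range_mask(a6, "WNA"),
          range_mask(a6, "WNA"))
  crn <- c(range_mask(a6, "WNA"), range_mask(a6, "WNA"), NA)
  ev <- extract_events(hist_stub(tr, a6, st, crn))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "dispersal")
  expect_equal(ev$time_ma, 39)                  # midpoint of 42..36
  expect_equal(ev$scope, "intercontinental")    # WNA-EA is an ocean pair
  expect_equal(ev$detail, "EA")
  expect_equal(ev$source, "WNA")
})

test_that("corners equal to node states give an empty event list", {
  a6 <- fraxinus_areas()
  tr <- ape::read.tree(text = "((t1:2,t2:2):2,t3:4);")
  m <- range_mask(a6, "EA")
  ev <- extract_events(hist_stub(tr, a6, rep(m, 5),
                                 c(m, m, m, NA, m)))   # NA corner = root
  expect_equal(nrow(ev), 0)
})

test_that("a corner outside the parent is a founder dispersal", {
  a6 <- fraxinus_areas()
  tr <- ape::read.tree(text = "(t1:5,t2:5);")
  st <- c(range_mask(a6, "EA"), range_mask(a6, "JP"), range_mask(a6, "EA"))
  crn <- c(range_mask(a6, "EA"), range_mask(a6, "JP"), NA)
  ev <- extract_events(hist_stub(tr, a6, st, crn))
  expect_equal(ev$type, "dispersal")
  expect_equal(ev$time_ma, 5)
  expect_equal(ev$scope, "adjacent")            # EA-JP adjacent
  # a multi-area corner outside the parent is inconsistent
  bad <- c(range_mask(a6, "EA"), range_mask(a6, "JP,EU"),
           range_mask(a6, "EA"))
  crn_bad <- c(range_mask(a6, "EA"), range_mask(a6, "JP,EU"), NA)
  expect_error(extract_events(hist_stub(tr, a6, bad, crn_bad)),
               "inconsistent corner")
})

test_that("multi-area branch changes decompose gains-then-losses", {
  a6 <- fraxinus_areas()
  tr <- ape::read.tree(text = "(t1:10,t2:10);")
  corner <- range_mask(a6, "WNA,ENA")
  child <- range_mask(a6, "ENA,EA")              # gains EA, loses WNA
  st <- c(child, corner, corner)
  crn <- c(corner, corner, NA)
  ev <- extract_events(hist_stub(tr, a6, st, crn))
  expect_equal(nrow(ev), 2)
  expect_equal(ev$type, c("dispersal", "extinction"))
  expect_equal(ev$time_ma, c(5, 5))
  expect_equal(ev$scope[2], "n/a")
  expect_equal(ev$detail, c("EA", "WNA"))
})

## --- event density and period summaries ------------------------------------

fake_events <- function(times, type = "dispersal",
                        scope = "intercontinental") {
  df <- data.frame(time_ma = times,
                   type = rep_len(type, length(times)),
                   scope = rep_len(scope, length(times)),
                   source = rep_len("EA", length(times)),
                   detail = rep_len("EU", length(times)),
                   node = seq_along(times))
  class(df) <- c("biogeo_events", "data.frame")
  df
}

test_that("a single kernel peaks at its event and integrates to one", {
  ev <- fake_events(10)
  d <- event_density(ev, bandwidth = 1, grid_step = 0.05)
  g <- d$grid
  expect_equal(g$age[which.max(g$dispersal)], 10, tolerance = 0.06)
  expect_equal(sum(g$dispersal) * d$grid_step, 1, tolerance = 0.02)
})

test_that("clustered events peak higher than spread events", {
  d1 <- event_density(fake_events(c(10, 10.1)), bandwidth = 1)
  d2 <- event_density(fake_events(c(10, 30)), bandwidth = 1)
  expect_gt(max(d1$grid$dispersal), max(d2$grid$dispersal))
})

test_that("the reflected KDE integrates to the event count", {
  set.seed(5)
  ev <- fake_events(runif(25, 0, 15))
  d <- event_density(ev, bandwidth = 1.2, grid_step = 0.02)
  expect_equal(sum(d$grid$dispersal) * d$grid_step, 25, tolerance = 0.5)
  # empty lists are a zero curve, not an error
  d0 <- event_density(fake_events(numeric(0)), types = "dispersal")
  expect_true(all(d0$grid$dispersal == 0))
})

test_that("period summaries tally events by interval, type and scope", {
  periods <- make_periods(c(34, 15), c("Warm I", "Cold I", "Warm II"), 52)
  ev <- rbind(fake_events(c(36, 35)),
              fake_events(10, type = "vicariance", scope = "adjacent"))
  class(ev) <- c("biogeo_events", "data.frame")
  tab <- period_summary(ev, periods)
  expect_equal(tab$count[tab$label == "Warm I" & tab$type == "dispersal" &
                           tab$scope == "intercontinental"], 2L)
  expect_equal(tab$count[tab$label == "Warm II" & tab$type == "vicariance" &
                           tab$scope == "adjacent"], 1L)
  expect_equal(sum(tab$count), nrow(ev))
  # empty events give an all-zero table
  tab0 <- period_summary(fake_events(numeric(0)), periods)
  expect_true(all(tab0$count == 0))
  # overlapping periods are rejected
  bad <- data.frame(label = c("a", "b"), age_start = c(52, 20),
                    age_end = c(15, 0))
  expect_error(period_summary(ev, bad), "overlap")
  expect_error(make_periods(c(15, 34), c("a", "b", "c"), 52), "decreasing")
})

test_that("a simulated history's own tally matches period counts", {
  a3 <- areas3()
  ep <- uniform_epochs(a3)
  tr <- simulate_chronogram(10, 0.15, seed = 31)
  h <- simulate_history(tr, biogeo_model("DEC", 0.05, 0.01, j = 0.5), ep,
                        "A,B", seed = 32)
  root_age <- max(node_ages(tr))
  periods <- make_periods(root_age / 2, c("old", "young"), root_age + 1)
  tab <- period_summary(h$events, periods)
  expect_equal(sum(tab$count), nrow(h$events))
  hand <- sum(h$events$time_ma <= root_age / 2 &
                h$events$type == "dispersal" &
                h$events$scope == "adjacent")
  expect_equal(tab$count[tab$label == "young" & tab$type == "dispersal" &
                           tab$scope == "adjacent"], hand)
})
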