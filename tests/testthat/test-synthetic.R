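test_that("tree simulation honours its contracts", {
  # pure birth, no fossil sampling: ultrametric with the requested tips
  tr <- simulate_chronogram(25, 0.2, seed = 1)
  expect_equal(ape::Ntip(tr), 25)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  # same seed, same Newick; different seed, different tree
  expect_identical(ape::write.tree(simulate_chronogram(10, 0.3, seed = 5)),
                   ape::write.tree(simulate_chronogram(10, 0.3, seed = 5)))
  expect_false(identical(
    ape::write.tree(simulate_chronogram(10, 0.3, seed = 5)),
    ape::write.tree(simulate_chronogram(10, 0.3, seed = 6))))
  expect_error(simulate_chronogram(1, 0.2), "n_extant")
  expect_error(simulate_chronogram(5, 0.1, death = 0.2), "birth > death")
})

test_that("fossil sampling keeps some extinct tips at positive ages", {
  tr <- simulate_chronogram(30, 0.25, death = 0.15, fossil_sampling = 5,
                            seed = 8)
  ages <- node_ages(tr)[seq_len(ape::Ntip(tr))]
  expect_gte(sum(ages > 1e-9), 1)           # at least one fossil retained
  expect_equal(sum(ages < 1e-9), 30)        # all extant tips kept
  # zero sampling rate prunes every extinct lineage
  tr0 <- simulate_chronogram(30, 0.25, death = 0.15, fossil_sampling = 0,
                             seed = 8)
  expect_true(ape::is.ultrametric(tr0, tol = 1e-8))
})

test_that("a frozen range process copies the root everywhere", {
  a3 <- areas3()
  ep <- uniform_epochs(a3)
  tr <- simulate_chronogram(8, 0.2, seed = 2)
  # a singleton root under DEC is copied at every node when d = e = 0
  h <- simulate_history(tr, biogeo_model("DEC", 0, 0), ep, "A", seed = 3)
  expect_true(all(h$tip_ranges == range_mask(a3, "A")))
  expect_equal(nrow(h$events), 0)
  # BAYAREALIKE copies any root range when frozen
  hb <- simulate_history(tr, biogeo_model("BAYAREALIKE", 0, 0), ep, "A,B",
                         seed = 3)
  expect_true(all(hb$tip_ranges == range_mask(a3, "A,B")))
  expect_equal(nrow(hb$events), 0)
})

test_that("a closed corridor is never crossed", {
  a3 <- areas3()
  m <- matrix(1, 3, 3, dimnames = list(a3$codes, a3$codes))
  m[, "C"] <- 0                              # nothing disperses INTO C
  ep <- epoch_schedule(a3, numeric(0), list(m))
  tr <- simulate_chronogram(10, 0.2, seed = 4)
  cbit <- range_mask(a3, "C")
  for (s in 1:25) {
    h <- simulate_history(tr, biogeo_model("DEC", 0.3, 0.05, j = 1), ep,
                          "A,B", seed = s)
    expect_true(all(bitwAnd(h$node_states, cbit) == 0L, na.rm = TRUE))
  }
})

test_that("histories are reproducible and replayable", {
  a3 <- areas3()
  ep <- uniform_epochs(a3)
  tr <- simulate_chronogram(12, 0.15, seed = 6)
  h1 <- simulate_history(tr, biogeo_model("DEC", 0.05, 0.01, j = 0.5), ep,
                         "A", seed = 7)
  h2 <- simulate_history(tr, biogeo_model("DEC", 0.05, 0.01, j = 0.5), ep,
                         "A", seed = 7)
  expect_identical(h1$events, h2$events)
  expect_identical(h1$tip_ranges, h2$tip_ranges)
  # replay the log along the tree and recover every tip range
  for (s in 10:25) {
    h <- simulate_history(tr, biogeo_model("DEC", 0.08, 0.02, j = 0.3), ep,
                          "A,B", seed = s)
    expect_silent(replay_history(h))
  }
})

test_that("event times sit inside their branch age intervals", {
  a3 <- areas3()
  ep <- epoch_schedule(a3, 5, list(
    matrix(1, 3, 3, dimnames = list(a3$codes, a3$codes)),
    matrix(0.5, 3, 3, dimnames = list(a3$codes, a3$codes))))
  tr <- simulate_chronogram(15, 0.12, seed = 9)
  h <- simulate_history(tr, biogeo_model("DEC", 0.1, 0.03, j = 0.4), ep,
                        "A,B,C", seed = 10)
  ages <- node_ages(tr)
  edges <- tr$edge
  for (i in seq_len(nrow(h$events))) {
    ev <- h$events[i, ]
    if (ev$type == "vicariance" ||
        (ev$type == "dispersal" && ev$node > ape::Ntip(tr) &&
         ev$time_ma == ages[ev$node])) {
      expect_equal(ev$time_ma, ages[ev$node])
    } else {
      parent <- edges[match(ev$node, edges[, 2]), 1]
      expect_lt(ev$time_ma, ages[parent])
      expect_gt(ev$time_ma, ages[ev$node])
    }
  }
})

test_that("extraction of the true history matches the logged events", {
  a3 <- areas3()
  ep <- uniform_epochs(a3)
  for (s in 1:20) {
    tr <- simulate_chronogram(12, 0.1, seed = 40 + s)
    h <- simulate_history(tr, biogeo_model("DEC", 0.002, 3e-4, j = 0.3),
                          ep, "A,B", seed = 140 + s)
    ex <- extract_events(h)
    expect_equal(nrow(ex), nrow(h$events))
    expect_equal(sort(paste(ex$type, ex$scope)),
                 sort(paste(h$events$type, h$events$scope)))
  }
})

test_that("per-branch gain counts pass a Poisson dispersion check", {
  a6 <- fraxinus_areas()
  ep <- uniform_epochs(a6)
  cherry <- ape::read.tree(text = "(t1:1,t2:1);")
  counts <- integer(0)
  for (s in 1:500) {
    h <- simulate_history(cherry, biogeo_model("BAYAREALIKE", 0.004, 0),
                          ep, "EA", seed = 3000 + s)
    for (tip in 1:2)
      counts <- c(counts, sum(h$events$type == "dispersal" &
                                h$events$node == tip))
  }
  n <- length(counts)
  disp <- (n - 1) * stats::var(counts) / mean(counts)
  lim <- stats::qchisq(c(0.005, 0.995), df = n - 1)
  expect_gt(disp, lim[1])
  expect_lt(disp, lim[2])
})

test_that("temperature simulation is exact on the trend and reproducible", {
  trend <- data.frame(age = c(50, 34, 0), temperature = c(18, 16, 6))
  s0 <- simulate_temperature(trend, noise_sd = 0, step = 0.5)
  expect_equal(s0$temperature_c,
               approx(trend$age, trend$temperature, xout = s0$age_ma)$y)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_temperature(simulate_temperature(trend, 0.5, 0.5, seed = 3), f1)
  write_temperature(simulate_temperature(trend, 0.5, 0.5, seed = 3), f2)
  expect_identical(readLines(f1), readLines(f2))
  # a slope change in the trend shows up across the breakpoint
  s <- simulate_temperature(trend, noise_sd = 0.1, step = 0.25, seed = 4)
  fit <- fit_temperature(s, span = 0.15)
  # cooling toward the present: negative slopes, steeper after 34 Ma
  expect_lt(abs(slope_at(fit, 45) - (-2 / 16)), 0.1)
  expect_lt(abs(slope_at(fit, 15) - (-10 / 34)), 0.1)
  expect_error(simulate_temperature(data.frame(age = 1,
                                               temperature = 1)),
               "span|interval")
})

test_that("dead lineages are pruned for fitting", {
  a2 <- areas2()
  ep <- uniform_epochs(a2)
  tr <- simulate_chronogram(10, 0.1, seed = 12)
  # enough extinction that some (but not all) lineages die
  h <- simulate_history(tr, biogeo_model("DEC", 0.05, 0.03), ep, "A,B",
                        seed = 13)
  expect_true(h$has_dead)
  obs <- prune_dead_tips(h)
  expect_true(all(obs$tip_ranges > 0L))
  expect_equal(ape::Ntip(obs$tree), length(obs$tip_ranges))
})
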