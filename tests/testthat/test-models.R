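test_that("rate matrix entries follow the gain/loss rules", {
  a2 <- areas2()
  sp <- state_space(a2)
  m1 <- matrix(1, 2, 2, dimnames = list(a2$codes, a2$codes))
  Q <- build_Q(sp, biogeo_model("DEC", d = 0.1, e = 0.05), m1)
  expect_equal(Q["A", "A+B"], 0.1)
  expect_equal(Q["A", "(null)"], 0.05)
  expect_equal(Q["A+B", "A"], 0.05)
  expect_equal(unname(rowSums(Q)), rep(0, 4), tolerance = 1e-12)
  expect_true(all(Q["(null)", ] == 0))             # null absorbing
  # closed corridor: multiplier 0 removes the gain
  m0 <- m1; m0["A", "B"] <- 0
  Q0 <- build_Q(sp, biogeo_model("DEC", d = 0.1, e = 0.05), m0)
  expect_equal(Q0["A", "A+B"], 0)
  expect_equal(Q0["B", "A+B"], 0.1)                # other direction open
})

test_that("gain rates sum multipliers over source areas", {
  a3 <- areas3()
  sp <- state_space(a3)
  m <- matrix(1, 3, 3, dimnames = list(a3$codes, a3$codes))
  m["A", "C"] <- 1; m["B", "C"] <- 0.5
  Q <- build_Q(sp, biogeo_model("DEC", d = 0.02, e = 0), m)
  expect_equal(Q["A+B", "A+B+C"], 0.02 * (1 + 0.5))
})

test_that("max_range_size removes further gains", {
  sp <- state_space(areas3(), max_range_size = 2)
  m <- matrix(1, 3, 3, dimnames = list(areas3()$codes, areas3()$codes))
  Q <- build_Q(sp, biogeo_model("DEC", d = 0.1, e = 0.01), m)
  i <- state_index(sp, range_mask(areas3(), "A,B"))
  expect_equal(sum(Q[i, ] > 0), 2)                 # only the two losses
})

test_that("branch transitions compose across epoch boundaries", {
  a3 <- areas3()
  sp <- state_space(a3)
  model <- biogeo_model("DEC", d = 0.08, e = 0.03)
  m_old <- matrix(1, 3, 3, dimnames = list(a3$codes, a3$codes))
  m_new <- matrix(0.4, 3, 3, dimnames = list(a3$codes, a3$codes))
  ep <- epoch_schedule(a3, 30, list(m_old, m_new))
  # branch inside one epoch equals the plain matrix exponential
  P1 <- branch_transition(sp, model, ep, 40, 35)
  Qo <- build_Q(sp, model, m_old)
  expect_equal(P1, as.matrix(Matrix::expm(Qo * 5)), ignore_attr = TRUE,
               tolerance = 1e-10)
  # identical multipliers in every epoch collapse to a single epoch
  ep_same <- epoch_schedule(a3, 30, list(m_old, m_old))
  P2 <- branch_transition(sp, model, ep_same, 32, 28)
  expect_equal(P2, as.matrix(Matrix::expm(Qo * 4)), ignore_attr = TRUE,
               tolerance = 1e-10)
  # boundary-crossing branch equals a fine-grained piecewise product
  P3 <- branch_transition(sp, model, ep, 32, 28)
  Qn <- build_Q(sp, model, m_new)
  fine <- diag(nrow(Qo))
  ages <- seq(32, 28, length.out = 1001)
  for (i in seq_len(1000)) {
    mid <- (ages[i] + ages[i + 1]) / 2
    Qi <- if (mid > 30) Qo else Qn
    fine <- fine %*% as.matrix(Matrix::expm(Qi * (ages[i] - ages[i + 1])))
  }
  expect_equal(P3, fine, ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(unname(rowSums(P3)), rep(1, nrow(P3)), tolerance = 1e-9)
  expect_error(branch_transition(sp, model, ep, 28, 32), "inverted")
})

test_that("cladogenetic distributions match their definitions", {
  a2 <- areas2()
  sp <- state_space(a2)
  dec <- biogeo_model("DEC", 0.1, 0.05)
  # single-area parent: pure copy
  d1 <- cladogenesis_distribution(sp, dec, range_mask(a2, "A"))
  expect_equal(nrow(d1), 1)
  expect_equal(d1$prob, 1)
  expect_equal(d1$left_label, "A")
  expect_equal(d1$right_label, "A")
  # two-area parent: two subset-sympatry and two vicariance outcomes, 1/4
  d2 <- cladogenesis_distribution(sp, dec, range_mask(a2, "A,B"))
  expect_equal(nrow(d2), 4)
  expect_equal(d2$prob, rep(0.25, 4))
  expect_setequal(paste(d2$left_label, d2$right_label, d2$type),
                  c("A+B A subset_sympatry", "A+B B subset_sympatry",
                    "A B vicariance", "B A vicariance"))
  # BAYAREALIKE: copy regardless of size
  bal <- biogeo_model("BAYAREALIKE", 0.1, 0.05)
  d3 <- cladogenesis_distribution(sp, bal, range_mask(a2, "A,B"))
  expect_equal(d3$prob, 1)
  expect_equal(d3$left_label, "A+B")
  expect_equal(d3$right_label, "A+B")
  expect_error(cladogenesis_distribution(sp, dec, 0L), "null")
})

test_that("founder outcomes require a positive incoming multiplier", {
  a3 <- areas3()
  sp <- state_space(a3)
  mj <- biogeo_model("DEC", 0.1, 0.05, j = 1)
  m <- matrix(1, 3, 3, dimnames = list(a3$codes, a3$codes))
  m[, "C"] <- 0                                    # C unreachable
  d <- cladogenesis_distribution(sp, mj, range_mask(a3, "A"), m)
  expect_setequal(d$type, c("sympatry", "founder"))
  expect_false("C" %in% d$right_label[d$type == "founder"])
  # weights: copy 1, founder j each
  expect_equal(d$prob[d$type == "founder"], 1 / 2, tolerance = 1e-12)
})

test_that("pruning equals enumeration and respects degeneracies", {
  a3 <- areas3()
  sp <- state_space(a3)
  ep <- uniform_epochs(a3)
  # frozen chain: cherry, d = e = 0, both tips {A}
  cherry <- ape::read.tree(text = "(t1:5,t2:5);")
  rng <- c(t1 = range_mask(a3, "A"), t2 = range_mask(a3, "A"))
  ll <- prune_likelihood(cherry, rng, sp, biogeo_model("DEC", 0, 0), ep)
  expect_equal(ll, log(1 / (length(sp$masks) - 1)))
  # j = 0 founder weight is an exact no-op
  set.seed(1)
  for (i in 1:5) {
    inst <- random_instance(j = 0)
    m0 <- inst$model
    mj <- biogeo_model(m0$family, m0$d, m0$e, j = 0)
    expect_identical(
      prune_likelihood(inst$tree, inst$tip_ranges, inst$space, m0,
                       inst$epochs),
      prune_likelihood(inst$tree, inst$tip_ranges, inst$space, mj,
                       inst$epochs))
  }
  # 3-tip exhaustive check with nonzero rates
  set.seed(2)
  tr <- ape::rtree(3)
  tips <- stats::setNames(c(range_mask(a3, "A"), range_mask(a3, "B"),
                            range_mask(a3, "A,B")), tr$tip.label)
  mdl <- biogeo_model("DEC", 0.1, 0.05)
  expect_equal(prune_likelihood(tr, tips, sp, mdl, ep),
               enum_loglik(tr, tips, sp, mdl, ep), tolerance = 1e-10)
})

test_that("likelihood is invariant to relabeling areas", {
  set.seed(3)
  for (i in 1:5) {
    inst <- random_instance()
    perm <- sample(3)
    codes <- inst$areas$codes
    # rebuild everything under the permuted area order; the adjacent pair
    # is still A-B, whatever position those areas now occupy
    areas_p <- area_set(codes[perm], adjacent = list(c("A", "B")))
    sp_p <- state_space(areas_p, inst$space$max_range_size)
    remap <- function(mask) {
      old <- which(bitwAnd(mask, bitwShiftL(1L, 0:2)) != 0L)
      sum(bitwShiftL(1L, match(codes[old], areas_p$codes) - 1L))
    }
    mults_p <- lapply(inst$epochs$multipliers, function(m)
      m[areas_p$codes, areas_p$codes])
    ep_p <- epoch_schedule(areas_p, inst$epochs$boundaries, mults_p)
    tips_p <- stats::setNames(
      vapply(inst$tip_ranges, remap, numeric(1)), names(inst$tip_ranges))
    l1 <- prune_likelihood(inst$tree, inst$tip_ranges, inst$space,
                           inst$model, inst$epochs)
    l2 <- prune_likelihood(inst$tree, tips_p, sp_p, inst$model, ep_p)
    expect_equal(l1, l2, tolerance = 1e-9)
  }
})

test_that("likelihood does not depend on child ordering at nodes", {
  set.seed(4)
  inst <- random_instance(max_tips = 4)
  l1 <- prune_likelihood(inst$tree, inst$tip_ranges, inst$space,
                         inst$model, inst$epochs)
  rot <- ape::rotateConstr(inst$tree, rev(inst$tree$tip.label))
  l2 <- prune_likelihood(rot, inst$tip_ranges, inst$space,
                         inst$model, inst$epochs)
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("missing tips and null ranges are rejected with names", {
  a3 <- areas3()
  sp <- state_space(a3)
  tr <- ape::read.tree(text = "(t1:5,t2:5);")
  expect_error(
    prune_likelihood(tr, c(t1 = 1L), sp, biogeo_model("DEC", 0.1, 0.1),
                     uniform_epochs(a3)),
    "t2")
})

test_that("data simulated without dispersal pins the fitted d at the bound", {
  a3 <- areas3()
  ep <- uniform_epochs(a3)
  tr <- simulate_chronogram(8, 0.2, seed = 10)
  rng <- stats::setNames(rep(range_mask(a3, "A,B"), 8), tr$tip.label)
  fit <- fit_biogeo(tr, rng, a3, "BAYAREALIKE", epochs = ep,
                    n_starts = 2, seed = 1)
  expect_lt(coef(fit)["d"], 1e-6)
  # likelihood dominance: the d = 0 limit beats any positive d
  sp <- state_space(a3)
  expect_gte(fit$lnL,
             prune_likelihood(tr, rng, sp,
                              biogeo_model("BAYAREALIKE", 0.1, coef(fit)["e"]),
                              ep))
})

test_that("AICc follows the small-sample formula and ranks models", {
  # lnL -100 with k = 2 vs -99 with k = 3 at n = 54
  aicc2 <- -2 * -100 + 2 * 2 + 2 * 2 * 3 / (54 - 3)
  aicc3 <- -2 * -99 + 2 * 3 + 2 * 3 * 4 / (54 - 4)
  expect_equal(round(aicc2, 2), 204.24)
  expect_equal(round(aicc3, 2), 204.48)
  fake <- function(lnL, k, j = 0) {
    n <- 54
    structure(list(model = biogeo_model("DEC", 0.1, 0.1, j), lnL = lnL,
                   k = k, n = n,
                   AICc = -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1),
                   converged = TRUE, with_j = j > 0,
                   fingerprint = list(x = 1)),
              class = "biogeo_fit")
  }
  cmp <- compare_models(fake(-100, 2), fake(-99, 3, j = 0.5))
  expect_equal(cmp$model[1], "DEC")
  expect_equal(cmp$dAICc, c(0, aicc3 - aicc2), tolerance = 1e-9)
  # tie-break: equal AICc prefers fewer parameters
  f1 <- fake(-100, 2)
  f2 <- fake(-100 - (1 + 2 * 3 * 4 / 50 / 2 - 2 * 2 * 3 / 51 / 2), 3)
  f2$AICc <- f1$AICc
  expect_equal(compare_models(f2, f1)$k[1], 2)
  # single fit is trivially best
  expect_equal(compare_models(f1)$dAICc, 0)
  # different data are refused
  f3 <- fake(-90, 2)
  f3$fingerprint <- list(x = 2)
  expect_error(compare_models(f1, f3), "different data")
})

test_that("fits are reproducible for a fixed seed", {
  a3 <- areas3()
  ep <- uniform_epochs(a3)
  tr <- simulate_chronogram(10, 0.2, seed = 3)
  h <- simulate_history(tr, biogeo_model("DEC", 0.02, 0.005), ep, "A,B",
                        seed = 4, require_alive = TRUE)
  f1 <- fit_biogeo(tr, h$tip_ranges, a3, "DEC", epochs = ep,
                   n_starts = 3, seed = 7)
  f2 <- fit_biogeo(tr, h$tip_ranges, a3, "DEC", epochs = ep,
                   n_starts = 3, seed = 7)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$lnL, f2$lnL)
  expect_s3_class(logLik(f1), "logLik")
  expect_equal(attr(logLik(f1), "df"), 2)
})
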