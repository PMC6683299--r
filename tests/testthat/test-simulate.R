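test_that("scanpath simulation respects the chain and the AOI geometry", {
  lay <- tiny_layout()
  aois <- lead_aois(lay)
  # identity chain started in A is absorbing
  ident <- markov_chain(c("A", "B"), diag(2), start = c(1, 0))
  set.seed(1)
  sp <- simulate_scanpath(ident, 50, aois)
  expect_true(all(sp$aoi == "A"))
  expect_true(all(sp$x >= 0 & sp$x < 50))
  expect_true(all(sp$duration_ms > 0))
  expect_true(all(diff(sp$onset_ms) > 0))
  # single fixation: no transitions
  sp1 <- simulate_scanpath(ident, 1, aois)
  expect_equal(nrow(sp1), 1L)
  # truncated scatter makes the generating AOI exactly recoverable
  unif <- markov_chain(c("A", "B"), matrix(0.5, 2, 2))
  set.seed(2)
  sp2 <- simulate_scanpath(unif, 200, aois, scatter_sd = 40)
  expect_equal(assign_fixations(sp2, aois), sp2$aoi)
})

test_that("long-run empirical transitions match the generating chain", {
  lay <- tiny_layout()
  aois <- lead_aois(lay)
  unif <- markov_chain(c("A", "B"), matrix(0.5, 2, 2))
  set.seed(33)
  sp <- simulate_scanpath(unif, 10000, aois)
  tc <- count_transitions(sp$aoi, c("A", "B"))
  emp <- to_distribution(tc)$p
  expect_lt(sum(abs(emp - 0.25)) / 2, 0.02)   # total variation
})

test_that("study simulation emits the full counterbalanced trial grid", {
  sc <- simulation_scenario(seed = 5L)
  sim <- simulate_study(sc)
  ds <- sim$dataset
  expect_equal(nrow(ds$participants), 31L)
  expect_equal(sum(ds$participants$order_group == "history_first"), 16L)
  trials <- unique(ds$fixations[c("participant", "stimulus", "condition")])
  expect_equal(nrow(trials), 31L * 9L * 2L)
  expect_equal(nrow(ds$responses), 31L * 9L * 2L)
  # alternate assignment of order groups by participant index
  expect_equal(ds$participants$order_group[1:4],
               c("history_first", "history_last",
                 "history_first", "history_last"))
  # determinism: same seed, identical dataset
  sim2 <- simulate_study(sc)
  expect_identical(sim$dataset, sim2$dataset)
  sc3 <- sc; sc3$seed <- 6L
  expect_false(identical(simulate_study(sc3)$dataset$fixations$x,
                         sim$dataset$fixations$x))
})

test_that("simulated datasets round-trip through the i/o layer", {
  sc <- simulation_scenario(n_per_group = c(3L, 3L), n_stimuli = 2L,
                            fixations_mean = 12, seed = 9L)
  sim <- simulate_study(sc)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fixation_table(sim$dataset, path)
  back <- read_fixation_table(path)
  expect_equal(back$fixations, sim$dataset$fixations, tolerance = 1e-12)
})

test_that("accuracy model drives the response labels", {
  acc <- matrix(c(1, 0), 2, 2)
  sc <- simulation_scenario(n_per_group = c(3L, 3L), n_stimuli = 2L,
                            fixations_mean = 8, accuracy = acc, seed = 4L)
  sim <- simulate_study(sc)
  scored <- score_responses(sim$dataset, sc$answer_key)
  og <- sim$dataset$participants
  first <- og$participant[og$order_group == "history_first"]
  expect_true(all(scored$correct[scored$participant %in% first]))
  expect_false(any(scored$correct[!scored$participant %in% first]))
})

test_that("chain perturbation is a calibrated mixing", {
  base <- markov_chain(LETTERS[1:4], matrix(0.25, 4, 4) + 0.5 * diag(4) -
                         0.125, validate = FALSE)
  base <- markov_chain(LETTERS[1:4], base$P / rowSums(base$P))
  expect_equal(perturb_chain(base, 0)$P, base$P)
  alt <- base$P[, c(4, 1:3)]
  colnames(alt) <- LETTERS[1:4]
  expect_equal(perturb_chain(base, 1)$P, alt)
  half <- perturb_chain(base, 0.5)
  expect_equal(rowSums(half$P), rep(1, 4), ignore_attr = TRUE)
  # joint-distribution distance grows with the magnitude
  joint <- function(chain) {
    # stationary occupancy x rows = long-run pair distribution
    ev <- Re(eigen(t(chain$P))$vectors[, 1])
    pi <- ev / sum(ev)
    as.vector(t(chain$P * pi))
  }
  hds <- vapply(c(0, 0.25, 0.5, 1), function(m) {
    hellinger(joint(base), joint(perturb_chain(base, m)))
  }, numeric(1))
  expect_equal(hds[1], 0)
  expect_true(all(diff(hds) >= -1e-12))
  expect_gt(hds[4], hds[2])
})

test_that("pooled empirical transitions converge to the generating joint", {
  lay <- tiny_layout()
  aois <- lead_aois(lay)
  P <- rbind(c(0.7, 0.3), c(0.4, 0.6))
  chain <- markov_chain(c("A", "B"), P, start = c(4 / 7, 3 / 7))
  # stationary pi = (4/7, 3/7); joint = pi_i * P_ij
  joint <- as.vector(t(P * c(4 / 7, 3 / 7)))
  tv <- vapply(c(100, 1000, 10000), function(n) {
    set.seed(101)
    sp <- simulate_scanpath(chain, n, aois)
    emp <- to_distribution(count_transitions(sp$aoi, c("A", "B")))$p
    sum(abs(emp - joint)) / 2
  }, numeric(1))
  expect_lt(tv[3], 0.02)
  expect_lt(tv[3], tv[1])       # error shrinks with sample size
})
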