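test_that("group assignments validate their invariants", {
  expect_error(group_assignment(character(0), "p2"), "non-empty")
  expect_error(group_assignment(c("p1", "p2"), c("p2", "p3")), "disjoint")
  g <- group_assignment(c("p1", "p2"), "p3",
                        conditions = c("history", "no_history"))
  expect_equal(g$n1, 2L)
  expect_equal(g$n2, 1L)
})

test_that("observed distance honours identity, symmetry and disjointness", {
  lay <- tiny_layout()
  aois <- lead_aois(lay)
  # identical scanpaths in both groups -> 0
  fx <- rbind(
    fix_rows("p1", "ecg1", "history", "history_first", c(10, 60, 10), 50),
    fix_rows("p2", "ecg1", "history", "history_last", c(10, 60, 10), 50))
  ds <- study_dataset(fx)
  g <- group_assignment("p1", "p2")
  expect_identical(observed_distance(ds, g, aois, "ecg1"), 0)
  # swapping the group labels leaves Hd unchanged
  ds2 <- tiny_dataset()
  g12 <- group_assignment("p1", "p2")
  g21 <- group_assignment("p2", "p1")
  expect_equal(observed_distance(ds2, g12, aois, "ecg1"),
               observed_distance(ds2, g21, aois, "ecg1"))
  # disjoint AOI usage -> 1
  fx3 <- rbind(
    fix_rows("p1", "ecg1", "history", "history_first", c(10, 10, 10), 50),
    fix_rows("p2", "ecg1", "history", "history_last", c(60, 60, 60), 50))
  ds3 <- study_dataset(fx3)
  expect_identical(observed_distance(ds3, g, aois, "ecg1"), 1)
})

test_that("condition filters select each group's trials", {
  ds <- tiny_dataset()
  aois <- lead_aois(tiny_layout())
  g <- group_assignment("p1", "p2", conditions = c("history", "no_history"))
  # p1 history: A,B,A -> pairs A->B, B->A ; p2 no_history: B,A,A
  pr <- gazetrans:::participant_profiles(ds, aois, "ecg1")
  expect_true(all(c("A->B", "B->A") %in% pr$support))
  hd <- observed_distance(ds, g, aois, "ecg1")
  v1 <- c(`A->B` = 0.5, `B->A` = 0.5)              # p1 under history
  v2 <- c(`A->A` = 0.5, `B->A` = 0.5)              # p2 under no_history
  manual <- sqrt(sum((sqrt(c(0, 0.5, 0.5, 0)) -
                        sqrt(c(0.5, 0, 0.5, 0)))^2)) / sqrt(2)
  expect_equal(hd, manual, tolerance = 1e-12)
})

test_that("the permutation null is reproducible and add-one corrected", {
  sc <- simulation_scenario(n_per_group = c(4L, 4L), n_stimuli = 1L,
                            fixations_mean = 15, seed = 21L)
  sim <- simulate_study(sc)
  aois <- lead_aois(sc$layout)
  og <- sim$dataset$participants
  g <- group_assignment(og$participant[og$order_group == "history_first"],
                        og$participant[og$order_group == "history_last"])
  n1 <- permutation_null(sim$dataset, g, aois, "ecg1", n_perm = 50, seed = 3)
  n2 <- permutation_null(sim$dataset, g, aois, "ecg1", n_perm = 50, seed = 3)
  expect_identical(n1, n2)                       # bitwise determinism
  n3 <- permutation_null(sim$dataset, g, aois, "ecg1", n_perm = 50, seed = 4)
  expect_false(identical(n1, n3))

  res <- permutation_test(sim$dataset, g, aois, "ecg1", n_perm = 99, seed = 5)
  expect_gt(res$p_value, 0)                      # add-one rule: never zero
  expect_gte(res$p_value, 1 / 100)
  expect_lte(res$p_value, 1)
  expect_equal(res$d, (res$observed_hd - res$null_mean) / res$null_sd)
  # p equals the add-one formula on the stored null values
  expect_equal(res$p_value,
               (1 + sum(res$null >= res$observed_hd - 1e-12)) / 100)
})

test_that("degenerate designs behave as specified", {
  lay <- tiny_layout()
  aois <- lead_aois(lay)
  # identical data in all participants -> all null values 0 and p = 1
  fx <- rbind(
    fix_rows("p1", "ecg1", "history", "history_first", c(10, 60, 10), 50),
    fix_rows("p2", "ecg1", "history", "history_last", c(10, 60, 10), 50),
    fix_rows("p3", "ecg1", "history", "history_first", c(10, 60, 10), 50))
  ds <- study_dataset(fx)
  g <- group_assignment(c("p1", "p3"), "p2")
  res <- permutation_test(ds, g, aois, "ecg1", n_perm = 20, seed = 1)
  expect_true(all(res$null == 0))
  expect_identical(res$observed_hd, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$d, 0)
  # n_perm = 1: p in {0.5, 1}
  res1 <- permutation_test(ds, g, aois, "ecg1", n_perm = 1, seed = 1)
  expect_true(res1$p_value %in% c(0.5, 1))
  # a group with no transitions is an inference error naming the group
  fx2 <- rbind(
    fix_rows("p1", "ecg1", "history", "history_first", c(10, 60), 50),
    fix_rows("p2", "ecg2", "history", "history_last", c(10, 60), 50))
  ds2 <- study_dataset(fx2)
  expect_error(observed_distance(ds2, group_assignment("p1", "p2"),
                                 aois, "ecg1"),
               "group 2")
})

test_that("derived seeds are stable and order-independent", {
  s1 <- gazetrans:::derive_seed(42L, "ecg1", "lead", "order")
  s2 <- gazetrans:::derive_seed(42L, "ecg1", "lead", "order")
  s3 <- gazetrans:::derive_seed(42L, "ecg2", "lead", "order")
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_true(s1 >= 1 && s1 < 2^31)
})
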