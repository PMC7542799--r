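test_that("win-loss matrices tabulate bouts and honor the roster", {
  b <- data.frame(winner = c("A", "A", "B"), loser = c("B", "B", "C"))
  m <- build_winloss_matrix(b, roster = c("A", "B", "C"))
  expect_identical(m$ids, c("A", "B", "C"))
  expect_equal(m$counts["A", "B"], 2L, ignore_attr = TRUE)
  expect_equal(m$counts["B", "C"], 1L, ignore_attr = TRUE)
  expect_equal(sum(m$counts), 3L)
  expect_true(all(diag(m$counts) == 0))

  # roster member with no bouts gets all-zero row and column
  m2 <- build_winloss_matrix(b, roster = c("A", "B", "C", "D"))
  expect_true(all(m2$counts["D", ] == 0) && all(m2$counts[, "D"] == 0))

  # empty bout list with roster -> zero matrix; without roster -> error
  empty <- data.frame(winner = character(), loser = character())
  m0 <- build_winloss_matrix(empty, roster = c("A", "B"))
  expect_identical(dim(m0$counts), c(2L, 2L))
  expect_equal(sum(m0$counts), 0L)
  expect_error(build_winloss_matrix(empty), "roster")

  # participant outside roster is rejected with its id
  expect_error(build_winloss_matrix(b, roster = c("A", "B")), "C")
  # self-bouts are invalid
  expect_error(
    build_winloss_matrix(data.frame(winner = "A", loser = "A")),
    "winner equal to loser"
  )
})

test_that("generated bouts tabulate to the generator's own tally", {
  set.seed(42)
  cfg <- sim_config(epsilon = 0, bouts_per_dyad = 4)
  bouts <- simulate_bouts(LETTERS[1:6], cfg, "2000-01", "G1")
  m <- build_winloss_matrix(bouts[c("winner", "loser")])
  # independent recount by looping over the bout list
  for (w in m$ids) {
    for (l in m$ids) {
      expect_equal(m$counts[w, l],
                   sum(bouts$winner == w & bouts$loser == l),
                   ignore_attr = TRUE)
    }
  }
})

test_that("inconsistency counting matches direct below-diagonal sums", {
  ids <- c("A", "B", "C", "D")
  m <- transitive_winloss(ids)
  expect_equal(count_inconsistencies(m, ids), 0)
  # reversed order puts every entry below the diagonal: n(n-1)/2 of them
  expect_equal(count_inconsistencies(m, rev(ids)), 4 * 3 / 2)
  expect_error(count_inconsistencies(m, c("A", "B", "C", "C")),
               "permutation")
  expect_error(count_inconsistencies(m, c("A", "B")), "permutation")

  set.seed(7)
  for (i in 1:20) {
    rm5 <- random_winloss(5)
    ord <- sample(rm5$ids)
    expect_equal(count_inconsistencies(rm5, ord),
                 oracle_incon(rm5$counts, match(ord, rm5$ids)))
  }
})

test_that("order_hierarchy attains the exhaustive minimum on small matrices", {
  # transitive matrix: recovers the true order with zero inconsistencies
  m <- transitive_winloss(c("C", "A", "D", "B"))
  ord <- order_hierarchy(m)
  expect_identical(ord$ranked_ids, c("C", "A", "D", "B"))
  expect_equal(ord$inconsistencies, 0L)

  # one circular triad: minimum equals brute-force enumeration
  m5 <- transitive_winloss(LETTERS[1:5])
  m5$counts["E", "A"] <- 2L # E beats A, closing a cycle
  ord5 <- order_hierarchy(m5)
  expect_equal(ord5$inconsistencies, oracle_min_incon(m5$counts))

  # oracle equivalence over random matrices
  set.seed(11)
  for (i in 1:60) {
    n <- sample(3:6, 1)
    rm <- random_winloss(n)
    expect_equal(order_hierarchy(rm)$inconsistencies,
                 oracle_min_incon(rm$counts))
  }
})

test_that("stored inconsistencies always recount under the stored ordering", {
  set.seed(23)
  for (i in 1:25) {
    rm <- random_winloss(sample(2:7, 1))
    ord <- order_hierarchy(rm)
    expect_equal(ord$inconsistencies,
                 count_inconsistencies(rm, ord$ranked_ids))
  }
  # also for the local-search path (n > exhaustive limit)
  big <- random_winloss(11)
  ord <- order_hierarchy(big)
  expect_equal(ord$inconsistencies,
               count_inconsistencies(big, ord$ranked_ids))
  # local minimum is no worse than natural candidate orderings
  expect_lte(ord$inconsistencies, count_inconsistencies(big, big$ids))
  expect_lte(ord$inconsistencies, count_inconsistencies(big, rev(big$ids)))
})

test_that("tie-breaks honor prior order, then win proportion, then id", {
  # all-zero matrix with a prior: prior order is returned untouched
  empty <- data.frame(winner = character(), loser = character())
  m0 <- build_winloss_matrix(empty, roster = c("A", "B", "C"))
  ord <- order_hierarchy(m0, prior = c("B", "A", "C"))
  expect_identical(ord$ranked_ids, c("B", "A", "C"))
  expect_equal(ord$inconsistencies, 0L)

  # no prior: all-zero matrix falls back to lexicographic ids
  expect_identical(order_hierarchy(m0)$ranked_ids, c("A", "B", "C"))

  # win proportion outranks id when there is no prior
  b <- data.frame(winner = c("C", "C"), loser = c("A", "B"))
  mt <- build_winloss_matrix(b)
  expect_identical(order_hierarchy(mt)$ranked_ids[1], "C")

  # ids absent from the prior go after all prior members
  ord2 <- order_hierarchy(m0, prior = c("C", "B"))
  expect_identical(ord2$ranked_ids, c("C", "B", "A"))
})

test_that("ordering is deterministic given matrix and prior", {
  set.seed(99)
  rm <- random_winloss(9) # exercises the local-search path
  a <- order_hierarchy(rm, prior = c("D", "A", "I"))
  b <- order_hierarchy(rm, prior = c("D", "A", "I"))
  expect_identical(a$ranked_ids, b$ranked_ids)
  expect_identical(a$inconsistencies, b$inconsistencies)
})

test_that("build_ranks pools by window and chains priors across months", {
  set.seed(3)
  cfg <- sim_config(n_groups = 1, months = 3, start_size = 4, join_prob = 0,
                    epsilon = 0)
  sim <- simulate_regime(cfg)
  br <- build_ranks(sim$bouts)
  expect_length(br$orderings, 3)
  expect_identical(sort(unique(br$records$period)),
                   c("2000-01", "2000-02", "2000-03"))
  # with no upsets, inferred order matches the latent order each month
  truth <- sim$latent[sim$latent$period == "2000-02", ]
  got <- br$records[br$records$period == "2000-02", ]
  got <- got[match(truth$individual, got$individual), ]
  expect_equal(got$ordinal, truth$ordinal)
  # window = 3 pools everything into a single matrix labelled by first month
  br3 <- build_ranks(sim$bouts, window = 3)
  expect_length(br3$orderings, 1)
  expect_identical(br3$orderings[[1]]$period, "2000-01")
})
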