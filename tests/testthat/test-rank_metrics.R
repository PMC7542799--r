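test_that("proportional rank standardizes ordinal rank to [0, 1]", {
  expect_equal(proportional_rank(1:5, 5), c(1, 0.75, 0.5, 0.25, 0))
  expect_equal(proportional_rank(1:5, 9), c(1, 0.875, 0.75, 0.625, 0.5))
  expect_equal(proportional_rank(2, 5), 0.75)
  expect_equal(proportional_rank(5, 9), 0.5)
  for (n in c(2, 3, 10, 57)) {
    expect_equal(proportional_rank(1, n), 1)
    expect_equal(proportional_rank(n, n), 0)
  }
  expect_error(proportional_rank(6, 5), "out of range")
  expect_error(proportional_rank(0, 5), "out of range")
  expect_warning(p1 <- proportional_rank(1, 1), "undefined")
  expect_true(is.na(p1))
})

test_that("proportional rank is symmetric about the hierarchy midpoint", {
  for (n in 2:12) {
    k <- seq_len(n)
    expect_equal(proportional_rank(k, n) + proportional_rank(n + 1 - k, n),
                 rep(1, n))
  }
})

test_that("rank_table flattens orderings into per-individual records", {
  o1 <- structure(list(period = "2001-05", group = "G1", sex = "male",
                       ranked_ids = c("A", "B", "C", "D", "E"),
                       inconsistencies = 0L),
                  class = "hierarchy_ordering")
  rt <- rank_table(o1)
  expect_equal(rt$ordinal, 1:5)
  expect_equal(rt$proportional, c(1, 0.75, 0.5, 0.25, 0))
  expect_equal(rt$n, rep(5L, 5))

  # four joiners at the bottom: incumbents keep ordinals, proportionals rise
  o2 <- o1
  o2$period <- "2001-06"
  o2$ranked_ids <- c(o1$ranked_ids, c("F", "G", "H", "I"))
  rt2 <- rank_table(list(o1, o2))
  later <- rt2[rt2$period == "2001-06" & rt2$individual %in% o1$ranked_ids, ]
  expect_equal(later$ordinal, 1:5)
  expect_equal(later$proportional, c(1, 0.875, 0.75, 0.625, 0.5))

  # single-member hierarchy: ordinal 1, missing proportional
  lone <- structure(list(period = "2001-05", group = "G2", sex = "male",
                         ranked_ids = "Z", inconsistencies = 0L),
                    class = "hierarchy_ordering")
  rt1 <- suppressWarnings(rank_table(lone))
  expect_equal(rt1$ordinal, 1L)
  expect_true(is.na(rt1$proportional))

  # duplicate key and duplicate individual are errors
  expect_error(rank_table(list(o1, o1)), "uniquely keyed")
  dup <- o1
  dup$ranked_ids <- c("A", "A", "B")
  expect_error(rank_table(dup), "duplicate individual")
})

test_that("bottom joiners never change incumbent ordinals and raise their proportionals", {
  set.seed(5)
  for (i in 1:20) {
    n0 <- sample(3:8, 1)
    extra <- sample(1:5, 1)
    ids <- paste0("id", seq_len(n0 + extra))
    before <- structure(list(period = "p1", group = "g", sex = "f",
                             ranked_ids = ids[seq_len(n0)],
                             inconsistencies = 0L),
                        class = "hierarchy_ordering")
    after <- structure(list(period = "p2", group = "g", sex = "f",
                            ranked_ids = ids, inconsistencies = 0L),
                       class = "hierarchy_ordering")
    rt <- rank_table(list(before, after))
    pre <- rt[rt$period == "p1", ]
    post <- rt[rt$period == "p2" & rt$individual %in% pre$individual, ]
    expect_equal(post$ordinal, pre$ordinal)
    expect_equal(post$proportional[1], 1) # top stays at 1
    expect_true(all(post$proportional[-1] > pre$proportional[-1]))
  }
})

test_that("maternal rank lookup follows the convention period", {
  recs <- rank_table(list(
    structure(list(period = "2002-03", group = "G1", sex = "female",
                   ranked_ids = paste0("F", 1:7), inconsistencies = 0L),
              class = "hierarchy_ordering"),
    structure(list(period = "2002-07", group = "G1", sex = "female",
                   ranked_ids = paste0("F", c(2, 1, 3:7)),
                   inconsistencies = 0L),
              class = "hierarchy_ordering")
  ))
  # measurement-month convention: mother ranked 3 of 7 -> proportional 2/3
  got <- assign_maternal_rank("kid1", "F3", "2002-07", recs)
  expect_equal(got$ordinal, 3L)
  expect_equal(got$proportional, 2 / 3)
  expect_identical(got$immature, "kid1")

  # birth convention with mother absent that month -> missing marker
  expect_warning(
    miss <- assign_maternal_rank("kid1", "F3", "2002-07", recs,
                                 convention = "birth",
                                 birth_period = "2001-01"),
    "no rank record"
  )
  expect_true(is.na(miss$ordinal) && is.na(miss$proportional))
  expect_error(assign_maternal_rank("kid1", "F3", "2002-07", recs,
                                    convention = "birth"),
               "birth_period")

  # conventions agree whenever the mother's rank is constant across months
  same <- assign_maternal_rank("kid2", "F5", "2002-07", recs)
  born <- assign_maternal_rank("kid2", "F5", "2002-07", recs,
                               convention = "birth",
                               birth_period = "2002-03")
  expect_equal(same$ordinal, born$ordinal)
  expect_equal(same$proportional, born$proportional)
})

test_that("metric divergence is 1 at constant hierarchy size and tracks growth", {
  recs <- data.frame(
    individual = "A", period = sprintf("2000-%02d", 1:6), group = "G",
    sex = "m", ordinal = c(3, 1, 4, 2, 5, 3), n = 6,
    proportional = proportional_rank(c(3, 1, 4, 2, 5, 3), 6)
  )
  expect_equal(metric_divergence(recs, "A")$correlation, 1)

  # constant ordinal 5 while the hierarchy grows 5 -> 9: the ordinal
  # trajectory is flat while proportional rank climbs 0 -> 0.5
  grow <- data.frame(
    individual = "B", period = sprintf("2000-%02d", 1:5), group = "G",
    sex = "m", ordinal = 5L, n = 5:9,
    proportional = proportional_rank(5L, 5:9)
  )
  dv <- metric_divergence(grow, "B")
  expect_equal(dv$proportional[c(1, 5)], c(0, 0.5))
  expect_true(all(diff(dv$proportional) > 0))
  expect_true(is.na(dv$correlation)) # flat ordinal: correlation undefined

  expect_error(metric_divergence(recs[1, ], "A"), ">= 2 periods")

  # random trajectories match a textbook rank-correlation recomputation
  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:12, 8, replace = TRUE)
    k <- vapply(n, function(m) sample(m, 1), integer(1))
    r <- data.frame(individual = "X", period = sprintf("2001-%02d", 1:8),
                    group = "G", sex = "m", ordinal = k, n = n,
                    proportional = proportional_rank(k, n))
    expect_equal(metric_divergence(r, "X")$correlation,
                 cor(rank(-k), rank(r$proportional)) )
  }
})

test_that("ordinal and proportional ranks are perfectly anti-correlated within one hierarchy", {
  for (n in c(4, 9, 15)) {
    k <- seq_len(n)
    expect_equal(cor(k, proportional_rank(k, n), method = "spearman"), -1)
  }
})
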