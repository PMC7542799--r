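# Independent oracles used to check the package's computations. Each is a
# deliberately naive implementation (explicit enumeration, double loops) kept
# separate from the code paths under test.

# Below-diagonal count for one ordering, by explicit double loop over
# position pairs.
oracle_incon <- function(counts, ord) {
  n <- length(ord)
  s <- 0
  for (a in seq_len(n - 1)) {
    for (b in seq.int(a + 1, n)) {
      s <- s + counts[ord[b], ord[a]]
    }
  }
  s
}

# Global minimum inconsistency count by exhaustive recursive enumeration of
# all orderings.
oracle_min_incon <- function(counts) {
  n <- nrow(counts)
  best <- Inf
  rec <- function(remaining, ord) {
    if (length(remaining) == 0) {
      s <- oracle_incon(counts, ord)
      if (s < best) best <<- s
      return(invisible())
    }
    for (x in remaining) rec(setdiff(remaining, x), c(ord, x))
  }
  rec(seq_len(n), integer(0))
  best
}

# Two-tailed binomial p-value by direct enumeration of outcome
# probabilities (small-p-values method).
oracle_binom_p <- function(k, n, p0 = 0.5) {
  probs <- choose(n, 0:n) * p0^(0:n) * (1 - p0)^(n - (0:n))
  obs <- probs[k + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Two-sided Fisher p-value by hypergeometric enumeration over all tables
# with the observed margins.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  total <- sum(tab)
  a_range <- max(0, r1 + c1 - total):min(r1, c1)
  prob <- function(a) {
    choose(c1, a) * choose(total - c1, r1 - a) / choose(total, r1)
  }
  probs <- vapply(a_range, prob, numeric(1))
  obs <- prob(tab[1, 1])
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Random win-loss matrix over n individuals for property tests.
random_winloss <- function(n, max_bouts = 3) {
  ids <- LETTERS[seq_len(n)]
  counts <- matrix(0L, n, n, dimnames = list(winner = ids, loser = ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) counts[i, j] <- sample(0:max_bouts, 1)
    }
  }
  structure(list(period = NULL, group = NULL, sex = NULL, ids = ids,
                 counts = counts),
            class = "winloss_matrix")
}

# Perfectly transitive matrix: every higher-ranked individual beats every
# lower-ranked one exactly `wins` times, under the order of `ids`.
transitive_winloss <- function(ids, wins = 1L) {
  n <- length(ids)
  counts <- matrix(0L, n, n, dimnames = list(winner = ids, loser = ids))
  counts[upper.tri(counts)] <- wins
  structure(list(period = NULL, group = NULL, sex = NULL, ids = ids,
                 counts = counts),
            class = "winloss_matrix")
}

# Dataset with constant hierarchy size: ordinal and proportional columns are
# affine transforms of each other.
constant_n_dataset <- function(n, reps, family = "gaussian") {
  ordinal <- rep(seq_len(n), reps)
  d <- data.frame(ordinal = ordinal, n = n,
                  proportional = proportional_rank(ordinal, n))
  eta <- 0.3 - 0.2 * scale(d$ordinal)[, 1]
  d$y <- if (family == "binomial") {
    rbinom(nrow(d), 1, plogis(eta + rnorm(nrow(d))))
  } else {
    eta + rnorm(nrow(d))
  }
  d
}
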