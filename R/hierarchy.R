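#' Build a win-loss matrix from dyadic agonistic bouts
#'
#' Tabulates decided dyadic agonistic interactions into a square count matrix
#' for one (period, group, sex-class) cell: `counts[i, j]` is the number of
#' bouts in which individual `i` beat individual `j`. Hierarchies are
#' sex-specific, so all bouts in one matrix involve same-sex opponents.
#'
#' @param bouts Data frame of bouts with columns `winner` and `loser`
#'   (character ids) and, if the corresponding filter argument is supplied,
#'   `date` (Date or ISO string), `group` and `sex`.
#' @param period Year-month string `"YYYY-MM"` the matrix belongs to. When
#'   given, every bout must fall in that month (an out-of-period bout is an
#'   error, not silently dropped).
#' @param group,sex Group id and sex-class the matrix belongs to; validated
#'   against the bout columns when given.
#' @param roster Optional character vector of individuals that must appear in
#'   the matrix. Roster members without any bout get all-zero rows/columns;
#'   a bout participant missing from the roster is an error.
#' @return A `winloss_matrix`: list with `period`, `group`, `sex`, `ids`
#'   (ordered individual tokens) and `counts` (n x n integer matrix, zero
#'   diagonal).
#' @examples
#' b <- data.frame(winner = c("A", "A", "B"), loser = c("B", "B", "C"))
#' m <- build_winloss_matrix(b, roster = c("A", "B", "C"))
#' m$counts
#' @seealso [order_hierarchy()], [count_inconsistencies()]
#' @export
build_winloss_matrix <- function(bouts, period = NULL, group = NULL,
                                 sex = NULL, roster = NULL) {
  stopifnot(is.data.frame(bouts))
  if (nrow(bouts) > 0) {
    for (col in c("winner", "loser")) {
      if (!col %in% names(bouts)) stop("bouts must have a '", col, "' column")
    }
    same <- bouts$winner == bouts$loser
    if (any(same)) {
      stop("bout(s) with winner equal to loser: ",
           paste(unique(bouts$winner[same]), collapse = ", "))
    }
    if (!is.null(period)) {
      bp <- format(as.Date(bouts$date), "%Y-%m")
      if (any(bp != period)) {
        stop("bout(s) dated outside period ", period, ": ",
             paste(unique(bp[bp != period]), collapse = ", "))
      }
    }
    if (!is.null(group) && any(bouts$group != group)) {
      stop("bout(s) from a group other than ", group)
    }
    if (!is.null(sex) && any(bouts$sex != sex)) {
      stop("bout(s) from a sex-class other than ", sex)
    }
  }
  participants <- unique(c(bouts$winner, bouts$loser))
  if (is.null(roster)) {
    if (length(participants) == 0) {
      stop("no bouts and no roster: cannot determine matrix membership")
    }
    ids <- sort(participants)
  } else {
    missing <- setdiff(participants, roster)
    if (length(missing) > 0) {
      stop("bout participant(s) not on roster: ",
           paste(missing, collapse = ", "))
    }
    ids <- as.character(roster)
    if (anyDuplicated(ids)) stop("duplicate ids on roster")
  }
  counts <- table(factor(bouts$winner, levels = ids),
                  factor(bouts$loser, levels = ids))
  counts <- matrix(as.integer(counts), nrow = length(ids),
                   dimnames = list(winner = ids, loser = ids))
  structure(
    list(period = period, group = group, sex = sex, ids = ids,
         counts = counts),
    class = "winloss_matrix"
  )
}

#' @export
print.winloss_matrix <- function(x, ...) {
  cat(sprintf("Win-loss matrix: %d individuals, %d bouts [%s / %s / %s]\n",
              length(x$ids), sum(x$counts),
              x$period %||% "?", x$group %||% "?", x$sex %||% "?"))
  print(x$counts)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count entries below the diagonal under a candidate ordering
#'
#' The inconsistency score of an ordering: total bouts won by a lower-ranked
#' individual over a higher-ranked one, i.e. the sum of matrix entries that
#' fall below the diagonal once rows and columns are arranged in rank order.
#'
#' @param matrix A [`winloss_matrix`][build_winloss_matrix].
#' @param ordering Character vector, a permutation of `matrix$ids`, rank 1
#'   (most dominant) first.
#' @return Nonnegative integer count.
#' @export
count_inconsistencies <- function(matrix, ordering) {
  stopifnot(inherits(matrix, "winloss_matrix"))
  idx <- match(ordering, matrix$ids)
  if (length(ordering) != length(matrix$ids) || anyNA(idx) ||
      anyDuplicated(idx)) {
    stop("ordering is not a permutation of the matrix ids")
  }
  m <- matrix$counts[idx, idx, drop = FALSE]
  sum(m[lower.tri(m)])
}

# Lexicographic table of all permutations of 1..n (rows), cached per n.
perm_matrix <- function(n) {
  key <- paste0("perm", n)
  hit <- .domrank_cache[[key]]
  if (!is.null(hit)) return(hit)
  gen <- function(m) {
    if (m == 1L) return(matrix(1L, 1L, 1L))
    sub <- gen(m - 1L)
    k <- nrow(sub)
    out <- matrix(0L, k * m, m)
    for (first in seq_len(m)) {
      rest <- seq_len(m)[-first]
      out[(first - 1L) * k + seq_len(k), ] <-
        cbind(rep.int(first, k), matrix(rest[sub], k, m - 1L))
    }
    out
  }
  res <- gen(as.integer(n))
  .domrank_cache[[key]] <- res
  res
}

# For each position pair a < b, linear indices into an n x n count matrix
# selecting counts[ord[b], ord[a]] (a below-diagonal entry) for every
# permutation row at once. Cached per n; only needed for n <= 8.
perm_pair_index <- function(n) {
  key <- paste0("pairs", n)
  hit <- .domrank_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- perm_matrix(n)
  idx <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      k <- k + 1L
      idx[[k]] <- p[, b] + (p[, a] - 1L) * n
    }
  }
  .domrank_cache[[key]] <- idx
  idx
}

# Inconsistency score of every permutation of 1..n against count matrix m.
score_all_orderings <- function(m) {
  n <- nrow(m)
  v <- as.numeric(m)
  idx <- perm_pair_index(n)
  scores <- numeric(nrow(perm_matrix(n)))
  for (i in idx) scores <- scores + v[i]
  scores
}

incon_score <- function(m, ord) {
  mo <- m[ord, ord, drop = FALSE]
  sum(mo[lower.tri(mo)])
}

#' Infer the dominance order minimizing below-diagonal entries
#'
#' Places individuals in descending rank order so as to minimize the number
#' of matrix entries that fall below the diagonal (bouts won "upward" against
#' the ordering). For hierarchies of up to `exhaustive_limit` individuals the
#' global minimum is found by exhaustive search over all orderings; for
#' larger hierarchies a deterministic single-individual relocation descent is
#' run from the tie-break baseline until no move improves the score.
#'
#' Ties among equally minimal orderings are broken by preferring, position by
#' position, (1) the previous period's relative order when `prior` is
#' supplied, then (2) higher win proportion, then (3) lexicographic id. The
#' result is a deterministic function of `(matrix, prior)`.
#'
#' @param matrix A [`winloss_matrix`][build_winloss_matrix].
#' @param prior Previous period's `hierarchy_ordering` (or bare character
#'   vector of ids, rank 1 first) used for temporal continuity; ids absent
#'   from `prior` are placed after all prior members.
#' @param exhaustive_limit Largest hierarchy size searched exhaustively
#'   (default 8; 8! = 40320 candidate orderings).
#' @return A `hierarchy_ordering`: list with `period`, `group`, `sex`,
#'   `ranked_ids` (rank 1 first) and `inconsistencies`.
#' @examples
#' b <- data.frame(winner = c("A", "A", "B"), loser = c("B", "C", "C"))
#' order_hierarchy(build_winloss_matrix(b))
#' @export
order_hierarchy <- function(matrix, prior = NULL, exhaustive_limit = 8L) {
  stopifnot(inherits(matrix, "winloss_matrix"))
  ids <- matrix$ids
  n <- length(ids)
  if (n < 1) stop("empty matrix")
  prior_ids <- if (inherits(prior, "hierarchy_ordering")) {
    prior$ranked_ids
  } else {
    prior
  }
  wins <- rowSums(matrix$counts)
  losses <- colSums(matrix$counts)
  total <- wins + losses
  winprop <- ifelse(total > 0, wins / total, 0)
  prior_pos <- rep.int(1L, n)
  if (!is.null(prior_ids)) {
    prior_pos <- match(ids, prior_ids)
    prior_pos[is.na(prior_pos)] <- length(prior_ids) + 1L
  }
  baseline <- ids[order(prior_pos, -winprop, ids)]
  bidx <- match(baseline, ids)
  m <- matrix$counts[bidx, bidx, drop = FALSE]

  if (n == 1L) {
    ranked <- baseline
    best <- 0L
  } else if (n <= exhaustive_limit) {
    scores <- score_all_orderings(m)
    k <- which.min(scores) # first minimum = closest to tie-break baseline
    ranked <- baseline[perm_matrix(n)[k, ]]
    best <- scores[k]
  } else {
    ord <- seq_len(n)
    best <- incon_score(m, ord)
    repeat {
      improved <- FALSE
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (i == j) next
          cand <- append(ord[-i], ord[i], after = j - 1L)
          s <- incon_score(m, cand)
          if (s < best) {
            ord <- cand
            best <- s
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    ranked <- baseline[ord]
  }
  structure(
    list(period = matrix$period, group = matrix$group, sex = matrix$sex,
         ranked_ids = ranked, inconsistencies = as.integer(best)),
    class = "hierarchy_ordering"
  )
}

#' @export
print.hierarchy_ordering <- function(x, ...) {
  cat(sprintf("Hierarchy [%s / %s / %s]: %s (inconsistencies: %d)\n",
              x$period %||% "?", x$group %||% "?", x$sex %||% "?",
              paste(x$ranked_ids, collapse = " > "), x$inconsistencies))
  invisible(x)
}

#' Build monthly hierarchies and rank records from a bout table
#'
#' Splits bouts into (group, sex, period) cells, pools them over windows of
#' `window` calendar months, orders each cell with [order_hierarchy()] using
#' the previous window's ordering of the same group and sex as the prior, and
#' collects the resulting ranks with [rank_table()].
#'
#' @param bouts Data frame with columns `date`, `group`, `sex`, `winner`,
#'   `loser` (see [read_bouts()]).
#' @param window Number of consecutive calendar months pooled per matrix
#'   (default 1). Windows are anchored at the earliest bout month; a window's
#'   period label is its first month.
#' @param roster Optional data frame with columns `individual`, `group`,
#'   `sex` (and optionally `period`) forcing membership of zero-bout
#'   individuals in the relevant matrices.
#' @return List with `orderings` (list of `hierarchy_ordering`) and `records`
#'   (the rank table, see [rank_table()]).
#' @export
build_ranks <- function(bouts, window = 1L, roster = NULL) {
  stopifnot(is.data.frame(bouts), nrow(bouts) > 0, window >= 1)
  dt <- as.Date(bouts$date)
  mi <- month_index(dt)
  bin <- min(mi) + ((mi - min(mi)) %/% window) * window
  bouts$.period <- month_label(bin)
  cells <- split(bouts, list(bouts$group, bouts$sex), drop = TRUE, sep = "\r")
  orderings <- list()
  for (cell in cells) {
    g <- cell$group[1]
    s <- cell$sex[1]
    periods <- sort(unique(cell$.period))
    prior <- NULL
    for (p in periods) {
      sub <- cell[cell$.period == p, , drop = FALSE]
      ros <- roster_for(roster, g, s, p)
      wl <- build_winloss_matrix(sub[c("winner", "loser")], roster =
                                   if (is.null(ros)) NULL else
                                     union(ros, unique(c(sub$winner, sub$loser))))
      wl$period <- p
      wl$group <- g
      wl$sex <- s
      ord <- order_hierarchy(wl, prior = prior)
      orderings[[length(orderings) + 1L]] <- ord
      prior <- ord
    }
  }
  list(orderings = orderings, records = rank_table(orderings))
}

roster_for <- function(roster, group, sex, period) {
  if (is.null(roster)) return(NULL)
  keep <- roster$group == group
  if ("sex" %in% names(roster)) keep <- keep & roster$sex == sex
  if ("period" %in% names(roster)) keep <- keep & roster$period == period
  unique(roster$individual[keep])
}

# Months since year 0 and back; keeps window arithmetic calendar-safe.
month_index <- function(d) {
  lt <- as.POSIXlt(d)
  (lt$year + 1900L) * 12L + lt$mon
}

month_label <- function(idx) {
  sprintf("%04d-%02d", idx %/% 12L, idx %% 12L + 1L)
}
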