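#' Proportional rank from ordinal rank and hierarchy size
#'
#' Standardizes a simple ordinal rank `k` in a hierarchy of `n` individuals to
#' `1 - (k - 1) / (n - 1)`: the proportion of other hierarchy members the
#' individual outranks. 1 is the most dominant position and 0 the least. For
#' a single-member hierarchy (`n = 1`) the quantity is undefined (a lone
#' individual has no within-group competitors) and `NA` is returned with a
#' warning.
#'
#' @param ordinal Integer vector of simple ordinal ranks (1 = most dominant).
#' @param hierarchy_size Integer vector of hierarchy sizes `n`; recycled
#'   against `ordinal`.
#' @return Numeric vector in `[0, 1]`, `NA` where `hierarchy_size == 1`.
#' @examples
#' proportional_rank(1:5, 5) # 1, 0.75, 0.5, 0.25, 0
#' proportional_rank(5, 9)   # 0.5
#' @export
proportional_rank <- function(ordinal, hierarchy_size) {
  r <- cbind(ordinal, hierarchy_size) # recycle and length-check together
  k <- r[, 1]
  n <- r[, 2]
  if (any(n < 1)) stop("hierarchy_size must be >= 1")
  if (any(k < 1 | k > n)) stop("ordinal rank out of range 1..hierarchy_size")
  out <- ifelse(n == 1, NA_real_, 1 - (k - 1) / (n - 1))
  if (anyNA(out)) {
    warning("proportional rank undefined for hierarchy size 1; returning NA")
  }
  unname(out)
}

#' Rank records from a collection of hierarchy orderings
#'
#' Flattens `hierarchy_ordering` objects into one row per individual-period:
#' ordinal rank (position in the ordering, 1 first), hierarchy size, and
#' proportional rank.
#'
#' @param orderings A `hierarchy_ordering` or list of them, keyed uniquely by
#'   (period, group, sex).
#' @return Data frame with columns `individual`, `period`, `group`, `sex`,
#'   `ordinal`, `n`, `proportional`.
#' @export
rank_table <- function(orderings) {
  if (inherits(orderings, "hierarchy_ordering")) orderings <- list(orderings)
  stopifnot(length(orderings) > 0,
            all(vapply(orderings, inherits, logical(1), "hierarchy_ordering")))
  keys <- vapply(orderings, function(o) {
    paste(o$period %||% "", o$group %||% "", o$sex %||% "", sep = "\r")
  }, character(1))
  if (anyDuplicated(keys)) {
    stop("orderings are not uniquely keyed by (period, group, sex)")
  }
  rows <- lapply(orderings, function(o) {
    ids <- o$ranked_ids
    if (anyDuplicated(ids)) {
      stop("duplicate individual within one ordering: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    n <- length(ids)
    data.frame(
      individual = ids,
      period = o$period %||% NA_character_,
      group = o$group %||% NA_character_,
      sex = o$sex %||% NA_character_,
      ordinal = seq_len(n),
      n = n,
      proportional = if (n == 1) {
        suppressWarnings(proportional_rank(1L, 1L))
      } else {
        proportional_rank(seq_len(n), n)
      },
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Maternal rank record for an immature individual
#'
#' For traits measured in immatures, the mother's dominance rank is the
#' predictor. Returns the mother's rank record for the convention period:
#' the trait-measurement month (default) or the immature's birth month.
#'
#' @param immature_id Id of the immature individual (carried through to the
#'   output for joining).
#' @param mother_id Id of the mother.
#' @param trait_period Period `"YYYY-MM"` of the trait measurement.
#' @param records Rank table from [rank_table()].
#' @param convention `"measurement"` (default) or `"birth"`.
#' @param birth_period Immature's birth month; required when
#'   `convention = "birth"`.
#' @return One-row data frame: the mother's rank record with an `immature`
#'   column prepended. When the mother has no record for the convention
#'   period, ranks are `NA` and a warning is raised.
#' @export
assign_maternal_rank <- function(immature_id, mother_id, trait_period,
                                 records,
                                 convention = c("measurement", "birth"),
                                 birth_period = NULL) {
  convention <- match.arg(convention)
  period <- if (convention == "measurement") {
    trait_period
  } else {
    if (is.null(birth_period)) stop("birth convention requires birth_period")
    birth_period
  }
  hit <- records[records$individual == mother_id & records$period == period, ,
                 drop = FALSE]
  if (nrow(hit) > 1) {
    stop("mother ", mother_id, " has multiple rank records in ", period)
  }
  if (nrow(hit) == 0) {
    warning("no rank record for mother ", mother_id, " in ", period,
            "; returning missing ranks")
    hit <- data.frame(individual = mother_id, period = period,
                      group = NA_character_, sex = NA_character_,
                      ordinal = NA_integer_, n = NA_integer_,
                      proportional = NA_real_, stringsAsFactors = FALSE)
  }
  cbind(immature = immature_id, hit, row.names = NULL)
}

#' Divergence between ordinal and proportional rank trajectories
#'
#' Tracks one individual's simple ordinal and proportional ranks over time and
#' summarizes their disagreement as the rank correlation (Spearman) between
#' the negated ordinal trajectory and the proportional trajectory. When
#' hierarchy size is constant the two metrics are affinely related and the
#' correlation is exactly 1; values below 1 flag periods in which hierarchy
#' size changes drove the metrics apart.
#'
#' @param records Rank table from [rank_table()].
#' @param individual Id of the focal individual (needs >= 2 periods).
#' @return A `divergence_series`: list with `individual`, `periods`,
#'   `ordinal`, `proportional`, `n` and `correlation` (`NA` when either
#'   trajectory is constant, e.g. an unchanged ordinal rank while the
#'   hierarchy grows).
#' @export
metric_divergence <- function(records, individual) {
  sub <- records[records$individual == individual, , drop = FALSE]
  sub <- sub[order(sub$period), , drop = FALSE]
  if (nrow(sub) < 2) {
    stop("metric_divergence needs >= 2 periods for ", individual)
  }
  rho <- suppressWarnings(
    stats::cor(-sub$ordinal, sub$proportional, method = "spearman",
               use = "complete.obs")
  )
  structure(
    list(individual = individual, periods = sub$period,
         ordinal = sub$ordinal, proportional = sub$proportional,
         n = sub$n, correlation = rho),
    class = "divergence_series"
  )
}

#' @export
print.divergence_series <- function(x, ...) {
  cat(sprintf(
    "Rank-metric divergence for %s over %d periods (rank correlation: %s)\n",
    x$individual, length(x$periods),
    ifelse(is.na(x$correlation), "undefined", format(x$correlation))))
  print(data.frame(period = x$periods, ordinal = x$ordinal,
                   proportional = x$proportional, n = x$n))
  invisible(x)
}
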