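#' Compare ordinal and proportional rank models for one trait
#'
#' The core decision procedure: fit three models on an identical row set —
#' one with the simple ordinal rank term, one with the proportional rank
#' term, and a null model with no rank term — extract their AICs, and
#' classify the trait. An AIC difference of at least `threshold` (default 2)
#' between the two rank-metric models means one metric is preferred
#' (`"ORDINAL"` or `"PROPORTIONAL"`); otherwise the metrics are
#' `"INDISTINGUISHABLE"`. Each metric additionally `beats_null` when its AIC
#' is at least `threshold` below the null model's.
#'
#' Rows with a missing value in any column used by the triplet — including
#' rows whose proportional rank is undefined because the hierarchy had a
#' single member — are dropped before fitting so all three fits see the same
#' data.
#'
#' @param data Data frame holding the response, covariates and both rank
#'   columns.
#' @param spec A [model_spec()] template; its `rank_term` is overridden for
#'   each of the three fits.
#' @param threshold Positive AIC difference required to prefer one model over
#'   another (default 2).
#' @return A `metric_comparison`: list with `trait`, `sex`, `aic` (named
#'   vector: ordinal, proportional, null), `delta_metrics`
#'   (`AIC_ordinal - AIC_proportional`), `delta_preferred_null`
#'   (best metric AIC minus null AIC), `classification`, `beats_null`
#'   (named logical), `valid` (all fits converged), `n_rows`, and the three
#'   `fits`.
#' @examples
#' set.seed(1)
#' d <- data.frame(ordinal = rep(1:6, 10), n = rep(c(6, 12), each = 30))
#' d$proportional <- proportional_rank(d$ordinal, d$n)
#' d$y <- 3 - 0.5 * d$ordinal + rnorm(60, sd = 0.5)
#' compare_rank_metrics(d, model_spec("y", "gaussian"))
#' @export
compare_rank_metrics <- function(data, spec, threshold = 2) {
  stopifnot(inherits(spec, "model_spec"), threshold > 0)
  used <- spec_vars(spec, both_ranks = TRUE)
  miss <- setdiff(used, names(data))
  if (length(miss) > 0) {
    stop("dataset lacks column(s): ", paste(miss, collapse = ", "))
  }
  rows <- stats::complete.cases(data[used])
  d <- data[rows, , drop = FALSE]
  fits <- lapply(c("ordinal", "proportional", "none"), function(term) {
    s <- spec
    s$rank_term <- term
    fit_model(d, s)
  })
  names(fits) <- c("ordinal", "proportional", "null")
  valid <- all(vapply(fits, `[[`, logical(1), "converged"))
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  if (!valid) {
    cls <- "INVALID"
    delta <- NA_real_
    delta_null <- NA_real_
    beats <- c(ordinal = NA, proportional = NA)
  } else {
    delta <- aic[["ordinal"]] - aic[["proportional"]]
    delta_null <- min(aic[["ordinal"]], aic[["proportional"]]) - aic[["null"]]
    cls <- if (abs(delta) < threshold) {
      "INDISTINGUISHABLE"
    } else if (delta < 0) {
      "ORDINAL"
    } else {
      "PROPORTIONAL"
    }
    beats <- c(ordinal = aic[["ordinal"]] <= aic[["null"]] - threshold,
               proportional = aic[["proportional"]] <= aic[["null"]] - threshold)
  }
  structure(
    list(trait = spec$trait, sex = spec$sex, aic = aic,
         delta_metrics = delta, delta_preferred_null = delta_null,
         classification = cls, beats_null = beats, valid = valid,
         threshold = threshold, n_rows = nrow(d), fits = fits),
    class = "metric_comparison"
  )
}

#' @export
print.metric_comparison <- function(x, ...) {
  cat(sprintf("Trait '%s'%s: %s\n", x$trait,
              if (is.na(x$sex)) "" else paste0(" (", x$sex, ")"),
              x$classification))
  cat(sprintf("  AIC ordinal %.2f | proportional %.2f | null %.2f (n = %d)\n",
              x$aic[["ordinal"]], x$aic[["proportional"]], x$aic[["null"]],
              x$n_rows))
  if (x$valid) {
    cat(sprintf("  dAIC(ordinal - proportional) = %.2f; dAIC(best - null) = %.2f\n",
                x$delta_metrics, x$delta_preferred_null))
  }
  invisible(x)
}

#' @export
as.data.frame.metric_comparison <- function(x, ...) {
  data.frame(trait = x$trait, sex = x$sex,
             aic_ordinal = x$aic[["ordinal"]],
             aic_proportional = x$aic[["proportional"]],
             aic_null = x$aic[["null"]],
             delta = x$delta_metrics,
             classification = x$classification,
             stringsAsFactors = FALSE)
}

#' Exact two-tailed binomial test p-value
#'
#' Probability, under `Binomial(n, p0)`, of any outcome whose probability does
#' not exceed that of the observed count (the small-p-values method, as in
#' [stats::binom.test()]).
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p0 Null success probability (default 0.5).
#' @return p-value in (0, 1].
#' @examples
#' binomial_two_tailed(7, 7)  # 0.015625
#' binomial_two_tailed(4, 7)  # 1
#' @export
binomial_two_tailed <- function(k, n, p0 = 0.5) {
  stopifnot(length(k) == 1, length(n) == 1, k >= 0, k <= n, p0 > 0, p0 < 1)
  stats::binom.test(k, n, p = p0, alternative = "two.sided")$p.value
}

#' Two-sided Fisher exact test p-value for a 2x2 table
#'
#' Sums the hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed the observed table's, as in
#' [stats::fisher.test()].
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return p-value in (0, 1].
#' @examples
#' fisher_two_sided(matrix(c(7, 3, 0, 4), 2)) # 0.06993...
#' @export
fisher_two_sided <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  if (sum(table) == 0) stop("table has no observations")
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Tally metric classifications by sex and run exact tests
#'
#' Counts, per sex, how many traits were classified ORDINAL, PROPORTIONAL or
#' INDISTINGUISHABLE; tests each sex's ORDINAL share among classified traits
#' (those where one metric was preferred) against chance with a two-tailed
#' binomial test; and contrasts the sexes' ordinal/proportional splits with a
#' two-sided Fisher exact test on the 2x2 table.
#'
#' @param comparisons A data frame with columns `sex` and `classification`,
#'   or a list of [`metric_comparison`][compare_rank_metrics] objects.
#' @param p0 Null probability for the per-sex binomial tests (default 0.5).
#' @return A `tally_result`: list with `counts` (sex x classification
#'   matrix), `binomial_p` (named per sex; `NA` where a sex has no classified
#'   traits), `fisher_p` and `table` (the sex x metric 2x2; `NA`/`NULL` when
#'   fewer than two sexes have classified traits).
#' @examples
#' cls <- data.frame(
#'   sex = rep(c("male", "female"), c(7, 7)),
#'   classification = c(rep("ORDINAL", 7), rep("ORDINAL", 3),
#'                      rep("PROPORTIONAL", 4)))
#' tally_and_test(cls)
#' @export
tally_and_test <- function(comparisons, p0 = 0.5) {
  if (is.list(comparisons) && !is.data.frame(comparisons)) {
    comparisons <- do.call(rbind, lapply(comparisons, as.data.frame))
  }
  stopifnot(is.data.frame(comparisons),
            all(c("sex", "classification") %in% names(comparisons)))
  lev <- c("ORDINAL", "PROPORTIONAL", "INDISTINGUISHABLE")
  keep <- comparisons$classification %in% lev
  cmp <- comparisons[keep, , drop = FALSE]
  sexes <- sort(unique(cmp$sex))
  counts <- table(factor(cmp$sex, levels = sexes),
                  factor(cmp$classification, levels = lev))
  counts <- matrix(as.integer(counts), nrow = length(sexes),
                   dimnames = list(sex = sexes, classification = lev))
  binom_p <- vapply(sexes, function(s) {
    k <- counts[s, "ORDINAL"]
    n <- k + counts[s, "PROPORTIONAL"]
    if (n == 0) NA_real_ else binomial_two_tailed(k, n, p0)
  }, numeric(1))
  names(binom_p) <- sexes
  classified <- counts[, c("ORDINAL", "PROPORTIONAL"), drop = FALSE]
  usable <- rowSums(classified) > 0
  if (sum(usable) == 2) {
    tab <- classified[usable, , drop = FALSE]
    fisher_p <- fisher_two_sided(tab)
  } else {
    tab <- NULL
    fisher_p <- NA_real_
  }
  structure(
    list(counts = counts, binomial_p = binom_p, fisher_p = fisher_p,
         table = tab, p0 = p0),
    class = "tally_result"
  )
}

#' @export
print.tally_result <- function(x, ...) {
  cat("Classification tally by sex:\n")
  print(x$counts)
  cat("Binomial test (ordinal share vs p0 =", x$p0, "):\n")
  print(signif(x$binomial_p, 4))
  cat("Fisher exact test (sex x metric):",
      ifelse(is.na(x$fisher_p), "NA", signif(x$fisher_p, 4)), "\n")
  invisible(x)
}
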