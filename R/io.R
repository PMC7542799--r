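#' Read a table of dyadic agonistic bouts
#'
#' Expects a UTF-8 CSV with header `date,group,sex,winner,loser` and ISO
#' dates. Every malformed row (unparseable date, empty id, winner equal to
#' loser) is reported with its file line number; any malformed row aborts the
#' read.
#'
#' @param path Path to the CSV file.
#' @return Data frame of validated bouts with a `Date`-classed `date` column.
#' @export
read_bouts <- function(path) {
  need <- c("date", "group", "sex", "winner", "loser")
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("bout file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  df <- df[need]
  d <- suppressWarnings(as.Date(df$date, format = "%Y-%m-%d"))
  problems <- character()
  line <- seq_len(nrow(df)) + 1L # header is line 1
  bad_date <- is.na(d)
  if (any(bad_date)) {
    problems <- c(problems, paste0("line ", line[bad_date],
                                   ": unparseable date '",
                                   df$date[bad_date], "'"))
  }
  self <- !bad_date & df$winner == df$loser
  if (any(self)) {
    problems <- c(problems, paste0("line ", line[self],
                                   ": winner equals loser ('",
                                   df$winner[self], "')"))
  }
  blank <- df$winner == "" | df$loser == "" | df$group == "" | df$sex == ""
  if (any(blank)) {
    problems <- c(problems, paste0("line ", line[blank], ": empty field"))
  }
  if (length(problems) > 0) {
    stop("malformed bout row(s) in ", path, ":\n  ",
         paste(problems, collapse = "\n  "))
  }
  df$date <- d
  df
}

#' Write a bout table to CSV
#'
#' @param bouts Bout data frame (see [read_bouts()]).
#' @param path Output path; written atomically.
#' @export
write_bouts <- function(bouts, path) {
  out <- bouts[c("date", "group", "sex", "winner", "loser")]
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  write_atomic(out, path)
}

#' Read or write a rank table
#'
#' The rank CSV (`individual,period,group,sex,ordinal,n,proportional`) is the
#' join-key surface between hierarchy inference and trait tables.
#'
#' @param records Rank table from [rank_table()].
#' @param path File path.
#' @return `read_ranks()` returns the rank table data frame.
#' @export
write_ranks <- function(records, path) {
  need <- c("individual", "period", "group", "sex", "ordinal", "n",
            "proportional")
  stopifnot(all(need %in% names(records)))
  out <- records[need]
  out <- out[order(out$group, out$sex, out$period, out$ordinal), ,
             drop = FALSE]
  write_atomic(out, path)
}

#' @rdname write_ranks
#' @export
read_ranks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(individual = "character",
                                       period = "character",
                                       group = "character",
                                       sex = "character"))
  need <- c("individual", "period", "group", "sex", "ordinal", "n",
            "proportional")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("rank file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  df
}

#' Read a trait table
#'
#' Expects columns `individual`, `period`, `trait` plus any covariates.
#'
#' @param path Path to the CSV file.
#' @return Data frame.
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("individual", "period", "trait"), names(df))
  if (length(miss) > 0) {
    stop("trait file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  df$individual <- as.character(df$individual)
  df$period <- as.character(df$period)
  df
}

#' Write metric-comparison results (and optional tallies) to CSV
#'
#' One row per trait: `trait,sex,aic_ordinal,aic_proportional,aic_null,`
#' `delta,classification`, sorted by trait then sex, AICs rendered at fixed
#' precision. Files are written atomically (complete or not at all).
#'
#' @param comparisons List of [`metric_comparison`][compare_rank_metrics]
#'   objects or an equivalent data frame.
#' @param path Output CSV path.
#' @param tally Optional [`tally_result`][tally_and_test]; written as a
#'   companion CSV.
#' @param tally_path Path for the tally CSV (default: `path` with a
#'   `_tally.csv` suffix).
#' @param digits Decimal places for AIC columns (default 6).
#' @return Invisibly, the result data frame as written.
#' @export
write_results <- function(comparisons, path, tally = NULL,
                          tally_path = NULL, digits = 6) {
  if (is.list(comparisons) && !is.data.frame(comparisons)) {
    comparisons <- if (length(comparisons) == 0) {
      data.frame(trait = character(), sex = character(),
                 aic_ordinal = numeric(), aic_proportional = numeric(),
                 aic_null = numeric(), delta = numeric(),
                 classification = character(), stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(comparisons, as.data.frame))
    }
  }
  df <- comparisons[order(comparisons$trait, comparisons$sex), , drop = FALSE]
  for (col in c("aic_ordinal", "aic_proportional", "aic_null", "delta")) {
    df[[col]] <- round(df[[col]], digits)
  }
  write_atomic(df, path)
  if (!is.null(tally)) {
    if (is.null(tally_path)) {
      tally_path <- sub("\\.csv$", "_tally.csv", path)
      if (identical(tally_path, path)) tally_path <- paste0(path, "_tally.csv")
    }
    tl <- as.data.frame.table(tally$counts, responseName = "count")
    tl$binomial_p <- tally$binomial_p[as.character(tl$sex)]
    tl$fisher_p <- tally$fisher_p
    write_atomic(tl, tally_path)
  }
  invisible(df)
}

# Write a data frame as CSV via a temp file in the target directory so a
# failure never leaves a partial file behind.
write_atomic <- function(df, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

#' Read a run configuration
#'
#' A single JSON document holding IO paths, window settings, the AIC
#' preference threshold, the maternal-rank convention, a seed, simulator
#' settings (see [sim_config()]) and per-trait model blocks (each naming
#' `response`, `family`, `covariates`, optional `random` and `sex`).
#'
#' @param path Path to the JSON config.
#' @return List of settings merged over defaults, with `sim` (when present)
#'   converted to a [sim_config()] and a `config_hash` (MD5 of the file) for
#'   provenance logging.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  defaults <- list(threshold = 2, window = 1,
                   maternal_convention = "measurement")
  cfg <- utils::modifyList(defaults, cfg)
  if (!is.numeric(cfg$threshold) || cfg$threshold <= 0) {
    stop("config threshold must be a positive number")
  }
  if (!is.null(cfg$sim)) {
    if (is.null(cfg$sim$seed) && is.null(cfg$seed)) {
      stop("config must carry a seed when simulation is requested")
    }
    if (is.null(cfg$sim$seed)) cfg$sim$seed <- cfg$seed
    cfg$sim <- do.call(sim_config, cfg$sim)
  }
  cfg$config_hash <- unname(tools::md5sum(path))
  cfg
}
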