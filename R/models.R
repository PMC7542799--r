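#' Specify one candidate model for a trait
#'
#' Describes the response, error family, covariates, optional random-effect
#' grouping and which rank metric (if any) enters as the predictor of
#' interest. Three variants of a single spec — `rank_term` set to
#' `"ordinal"`, `"proportional"` and `"none"` — form the model triplet
#' compared by [compare_rank_metrics()].
#'
#' @param response Response expression as a string: a column name, or for the
#'   Cox family a `Surv()` expression such as `"survival::Surv(time, event)"`.
#' @param family One of `"gaussian"`, `"binomial"`, `"poisson"`, `"nbinom"`,
#'   `"cox"`.
#' @param covariates Character vector of fixed covariate column names.
#' @param random Optional column name for a random intercept grouping (fitted
#'   with glmmTMB under full maximum likelihood).
#' @param rank_term `"ordinal"`, `"proportional"` or `"none"`.
#' @param rank_cols Named character vector mapping the two rank-term states
#'   to dataset columns.
#' @param trait Label for the trait (defaults to `response`).
#' @param sex Sex label carried into tallies (`"male"`/`"female"`; optional).
#' @return A `model_spec` object.
#' @export
model_spec <- function(response,
                       family = c("gaussian", "binomial", "poisson",
                                  "nbinom", "cox"),
                       covariates = character(),
                       random = NULL,
                       rank_term = c("none", "ordinal", "proportional"),
                       rank_cols = c(ordinal = "ordinal",
                                     proportional = "proportional"),
                       trait = response,
                       sex = NA_character_) {
  family <- match.arg(family)
  rank_term <- match.arg(rank_term)
  stopifnot(is.character(response), length(response) == 1,
            all(c("ordinal", "proportional") %in% names(rank_cols)))
  structure(
    list(response = response, family = family,
         covariates = as.character(covariates), random = random,
         rank_term = rank_term, rank_cols = rank_cols,
         trait = trait, sex = sex),
    class = "model_spec"
  )
}

spec_formula <- function(spec) {
  rhs <- switch(spec$rank_term,
                ordinal = spec$rank_cols[["ordinal"]],
                proportional = spec$rank_cols[["proportional"]],
                none = character())
  rhs <- c(rhs, spec$covariates)
  if (!is.null(spec$random)) rhs <- c(rhs, sprintf("(1 | %s)", spec$random))
  if (length(rhs) == 0) rhs <- "1"
  stats::as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")),
                    env = globalenv())
}

# Columns a spec needs present (and non-missing) in the dataset.
spec_vars <- function(spec, both_ranks = FALSE) {
  resp <- all.vars(stats::as.formula(paste("~", spec$response)))
  rank <- if (both_ranks) {
    unname(spec$rank_cols)
  } else {
    switch(spec$rank_term,
           ordinal = spec$rank_cols[["ordinal"]],
           proportional = spec$rank_cols[["proportional"]],
           none = character())
  }
  unique(c(resp, rank, spec$covariates, spec$random))
}

#' Fit one candidate model and extract its likelihood and AIC
#'
#' Fits `spec` to `data` by full maximum likelihood (never restricted
#' likelihood, so AICs remain comparable across the rank-term variants of a
#' spec) and returns the maximized log-likelihood, the number of estimated
#' parameters (including any dispersion or variance components), and
#' `AIC = 2 * npar - 2 * logLik`. The Cox family uses the partial likelihood.
#'
#' Backends: [stats::glm()] for gaussian/binomial/poisson fixed-effect
#' models, [MASS::glm.nb()] for negative binomial, [survival::coxph()] for
#' Cox, and `glmmTMB::glmmTMB(..., REML = FALSE)` whenever `random` is set.
#' Non-convergence (including complete separation in binomial fits) is
#' flagged rather than raised.
#'
#' @param data Data frame containing every column the spec names.
#' @param spec A [model_spec()].
#' @return A `fit_result`: list with `logLik`, `npar`, `aic`, `converged`,
#'   `warnings` and the fitted `model` object.
#' @export
fit_model <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"), is.data.frame(data))
  miss <- setdiff(spec_vars(spec), names(data))
  if (length(miss) > 0) {
    stop("dataset lacks column(s): ", paste(miss, collapse = ", "))
  }
  fml <- spec_formula(spec)
  warns <- character()
  collect <- function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  fit <- withCallingHandlers(
    tryCatch({
      if (!is.null(spec$random)) {
        if (!requireNamespace("glmmTMB", quietly = TRUE)) {
          stop("random effects require the glmmTMB package")
        }
        fam <- switch(spec$family,
                      gaussian = stats::gaussian(),
                      binomial = stats::binomial(),
                      poisson = stats::poisson(),
                      nbinom = glmmTMB::nbinom2(),
                      cox = stop("random effects not supported for cox"))
        glmmTMB::glmmTMB(fml, data = data, family = fam, REML = FALSE)
      } else {
        switch(spec$family,
               gaussian = stats::glm(fml, data = data,
                                     family = stats::gaussian()),
               binomial = stats::glm(fml, data = data,
                                     family = stats::binomial()),
               poisson = stats::glm(fml, data = data,
                                    family = stats::poisson()),
               nbinom = MASS::glm.nb(fml, data = data),
               cox = survival::coxph(fml, data = data, ties = "efron"))
      }
    }, error = function(e) e),
    warning = collect
  )
  if (inherits(fit, "error")) {
    return(structure(
      list(logLik = NA_real_, npar = NA_integer_, aic = NA_real_,
           converged = FALSE, warnings = c(warns, conditionMessage(fit)),
           model = NULL),
      class = "fit_result"
    ))
  }
  ll <- stats::logLik(fit)
  npar <- as.integer(attr(ll, "df"))
  converged <- fit_converged(fit, warns)
  structure(
    list(logLik = as.numeric(ll), npar = npar,
         aic = 2 * npar - 2 * as.numeric(ll),
         converged = converged, warnings = warns, model = fit),
    class = "fit_result"
  )
}

fit_converged <- function(fit, warns) {
  bad <- grepl("numerically 0 or 1|did not converge|infinite|NaN|false convergence",
               warns, ignore.case = TRUE)
  if (any(bad)) return(FALSE)
  if (inherits(fit, "glmmTMB")) {
    return(isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess))
  }
  if (inherits(fit, "coxph")) {
    return(!anyNA(stats::coef(fit)))
  }
  if (inherits(fit, "glm")) {
    if (!isTRUE(fit$converged) || anyNA(stats::coef(fit))) return(FALSE)
    if (stats::family(fit)$family == "binomial") {
      # boundary fit (e.g. all successes, or complete separation): the MLE
      # pushes fitted probabilities to 0/1 and the likelihood is degenerate
      mu <- stats::fitted(fit)
      if (all(mu > 1 - 1e-8) || all(mu < 1e-8)) return(FALSE)
    }
    return(TRUE)
  }
  TRUE
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Model fit: logLik = %.4f, parameters = %s, AIC = %.4f%s\n",
              x$logLik, x$npar, x$aic,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}
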