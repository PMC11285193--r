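#' Small-sample Akaike Information Criterion
#'
#' `AICc = -2*loglik + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters (including the residual variance).
#' @param n Number of observations; must exceed `k + 1`.
#' @return The AICc value.
#' @examples
#' aicc(0, 2, 10) # 4 + 12/7
#' @export
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1))
    stop("contract error: AICc undefined for n <= k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' Normalised relative likelihoods `w_i = exp(-d_i/2) / sum_j exp(-d_j/2)`
#' with `d_i = AICc_i - min(AICc)`; computed with min-subtraction so large
#' values cannot overflow.
#'
#' @param aicc_values Numeric vector of AICc scores (at least one finite).
#' @return Weights summing to 1 (non-finite models get weight 0).
#' @examples
#' akaike_weights(c(100, 102)) # 0.731, 0.269
#' @export
akaike_weights <- function(aicc_values) {
  if (!any(is.finite(aicc_values)))
    stop("contract error: no finite AICc values", call. = FALSE)
  d <- aicc_values - min(aicc_values[is.finite(aicc_values)])
  w <- ifelse(is.finite(d), exp(-d / 2), 0)
  w / sum(w)
}

#' Compare candidate driver models for daily body-temperature summaries
#'
#' Ranks linear models of a daily body-temperature summary (e.g. maximum,
#' minimum or range of Tb per squirrel-day) against candidate predictor sets
#' built from day of year and daily ambient-temperature summaries, using AICc
#' and Akaike weights. Each model carries a per-individual random intercept
#' (fitted by maximum likelihood via lme4 so likelihoods are comparable
#' across fixed-effect structures); with a single individual the models
#' reduce to ordinary least squares.
#'
#' Parameter count convention: fixed effects (including the intercept) +
#' residual variance + random-intercept variance (when present).
#'
#' @param daily Data frame of daily summaries; must contain the response
#'   column, the predictors named in `candidates`, and `individual`.
#' @param response Name of the response column.
#' @param candidates List of character vectors of predictor names; use
#'   `character(0)` for the intercept-only model. Default: intercept-only,
#'   day_of_year, ta_max, and day_of_year + ta_max.
#' @return Object of class `model_comparison`: a data frame with one row per
#'   model (name, k, logLik, AICc, delta AICc, weight) sorted by AICc, with
#'   the fitted models in attribute `"fits"`.
#' @examples
#' d <- data.frame(max_tb = rnorm(40, 40), day_of_year = rep(150:169, 2),
#'                 ta_max = rnorm(40, 25), individual = rep(c("a", "b"), 20))
#' compare_tb_models(d, "max_tb")
#' @export
compare_tb_models <- function(daily, response = "max_tb",
                              candidates = list(
                                character(0),
                                "day_of_year",
                                "ta_max",
                                c("day_of_year", "ta_max"))) {
  if (!response %in% names(daily))
    stop("contract error: response column '", response, "' not found",
         call. = FALSE)
  preds <- unique(unlist(candidates))
  bad <- setdiff(preds, names(daily))
  if (length(bad))
    stop("contract error: unknown predictor name(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  daily <- daily[stats::complete.cases(daily[, c(response, preds,
                                                 "individual")]), ]
  n <- nrow(daily)
  multi_ind <- length(unique(daily$individual)) > 1
  rows <- list(); fits <- list()
  for (ci in seq_along(candidates)) {
    cand <- candidates[[ci]]
    rhs <- if (length(cand)) paste(cand, collapse = " + ") else "1"
    nm <- if (length(cand)) paste(cand, collapse = "+") else "(intercept)"
    if (multi_ind) {
      fml <- stats::as.formula(paste(response, "~", rhs, "+ (1 | individual)"))
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(fml, data = daily, REML = FALSE)))
      ll <- as.numeric(stats::logLik(fit))
      k <- length(lme4::fixef(fit)) + 2  # + resid var + RI var
    } else {
      fml <- stats::as.formula(paste(response, "~", rhs))
      fit <- stats::lm(fml, data = daily)
      ll <- as.numeric(stats::logLik(fit))
      k <- length(stats::coef(fit)) + 1
    }
    rows[[ci]] <- data.frame(model = nm,
                             predictors = rhs, k = k, loglik = ll,
                             aicc = aicc(ll, k, n))
    fits[[nm]] <- fit
  }
  tab <- do.call(rbind, rows)
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tab$weight <- akaike_weights(tab$aicc)
  tab <- tab[order(tab$aicc), ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  attr(tab, "n") <- n
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (n = ", attr(x, "n"), " squirrel-days)\n", sep = "")
  df <- as.data.frame(x)
  df$loglik <- round(df$loglik, 2)
  df$aicc <- round(df$aicc, 2)
  df$delta_aicc <- round(df$delta_aicc, 2)
  df$weight <- round(df$weight, 3)
  print(df[, c("model", "k", "loglik", "aicc", "delta_aicc", "weight")])
  invisible(x)
}
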