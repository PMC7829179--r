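#' Bias-corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1)/(n - k - 1)`; requires
#' `n > k + 1`.
#'
#' @param logLik model log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size.
#' @return AICc value (vectorized over its arguments).
#' @export
aicc <- function(logLik, k, n) {
  if (any(n <= k + 1)) stop("AICc requires n > k + 1")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)` with
#' `Delta_i = AICc_i - min(AICc)`; the weights sum to 1.
#'
#' @param aicc_values numeric vector of AICc values.
#' @return Numeric vector of weights.
#' @export
akaike_weights <- function(aicc_values) {
  if (!length(aicc_values)) stop("at least one model is required")
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Summary of a fitted model for information-theoretic comparison
#'
#' A light container decoupling model comparison from model fitting: any
#' fitting routine can be used as long as it reports a log-likelihood,
#' parameter count and sample size.  Variance components are optional and
#' only needed for [nakagawa_r2()].
#'
#' @param id model identifier.
#' @param predictors character vector of fixed-effect predictor names.
#' @param logLik log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size.
#' @param var_fixed,var_random,var_resid optional variance components
#'   (fixed-effect, random-effect, residual).
#' @return A list of class `model_summary`.
#' @export
model_summary <- function(id, predictors, logLik, k, n,
                          var_fixed = NA_real_, var_random = NA_real_,
                          var_resid = NA_real_) {
  if (n <= k + 1) stop("n must exceed k + 1 for AICc")
  structure(list(id = id, predictors = as.character(predictors),
                 logLik = logLik, k = k, n = n, var_fixed = var_fixed,
                 var_random = var_random, var_resid = var_resid),
            class = "model_summary")
}

#' Build a model summary from a fitted (mixed) model
#'
#' Works for `lm` fits and, when \pkg{lme4} is available, for
#' `(g)lmerMod` fits; variance components follow the marginal/conditional
#' R2 decomposition (fixed-effect variance = variance of the fixed-effect
#' linear predictor, random-effect variance = summed random-intercept/
#' slope variances, residual variance = sigma^2).
#'
#' @param fit fitted model object.
#' @param id model identifier (default: deparsed formula).
#' @param predictors fixed-effect predictor names (default: from the
#'   model terms).
#' @return A [model_summary()].
#' @export
summarize_fit <- function(fit, id = NULL, predictors = NULL) {
  ll <- as.numeric(logLik(fit))
  k <- attr(logLik(fit), "df")
  n <- nobs(fit)
  if (inherits(fit, "lm")) {
    if (is.null(predictors))
      predictors <- attr(terms(fit), "term.labels")
    if (is.null(id)) id <- deparse(formula(fit))
    Xb <- fitted(fit)
    return(model_summary(id, predictors, ll, k, n,
                         var_fixed = var(Xb), var_random = 0,
                         var_resid = summary(fit)$sigma^2))
  }
  if (inherits(fit, "merMod")) {
    if (!requireNamespace("lme4", quietly = TRUE))
      stop("lme4 is required to summarize merMod fits")
    if (is.null(predictors)) {
      tl <- attr(terms(fit), "term.labels")
      predictors <- tl[!grepl("\\|", tl)]
    }
    if (is.null(id)) id <- deparse(formula(fit))
    Xb <- as.vector(lme4::getME(fit, "X") %*% lme4::fixef(fit))
    vc <- lme4::VarCorr(fit)
    var_r <- sum(vapply(vc, function(v) sum(diag(v)), 0))
    var_e <- attr(vc, "sc")^2
    return(model_summary(id, predictors, ll, k, n,
                         var_fixed = var(Xb), var_random = var_r,
                         var_resid = var_e))
  }
  stop("unsupported model class: ", paste(class(fit), collapse = "/"))
}

#' Summed-weight variable importance over the retained model set
#'
#' Models within `delta_cut` AICc units of the best model are retained;
#' each predictor's importance is the sum of the Akaike weights of the
#' retained models containing it.  By default weights are renormalized
#' within the retained set (so a predictor present in every retained
#' model scores exactly 1); set `renormalize = FALSE` to sum the
#' full-set weights instead.  If the summaries carry variance components,
#' the mean marginal R2 over retained models is attached.
#'
#' @param models list of [model_summary()] objects sharing one response.
#' @param delta_cut AICc cutoff for the retained set (default 2).
#' @param renormalize renormalize weights within the retained set
#'   (default TRUE).
#' @return A list of class `importance_table`: `importance` (named
#'   vector), `models` (data.frame: id, aicc, delta, weight, retained),
#'   `mean_marginal_r2` (NA when variances are absent), `delta_cut`,
#'   `renormalized`.
#' @export
variable_importance <- function(models, delta_cut = 2, renormalize = TRUE) {
  stopifnot(length(models) > 0,
            all(vapply(models, inherits, TRUE, "model_summary")))
  ic <- vapply(models, function(m) aicc(m$logLik, m$k, m$n), 0)
  delta <- ic - min(ic)
  w_all <- akaike_weights(ic)
  keep <- delta < delta_cut
  w <- if (renormalize) {
    wk <- w_all; wk[!keep] <- 0; wk / sum(wk[keep])
  } else w_all
  preds <- sort(unique(unlist(lapply(models, function(m) m$predictors))))
  imp <- vapply(preds, function(p) {
    inmod <- vapply(models, function(m) p %in% m$predictors, TRUE)
    sum(w[keep & inmod])
  }, 0)
  r2m <- vapply(models, function(m) {
    tot <- m$var_fixed + m$var_random + m$var_resid
    if (is.na(tot) || tot <= 0) NA_real_ else m$var_fixed / tot
  }, 0)
  mean_r2 <- if (all(is.na(r2m[keep]))) NA_real_ else
    mean(r2m[keep], na.rm = TRUE)
  tab <- data.frame(
    id = vapply(models, function(m) as.character(m$id), ""),
    aicc = ic, delta = delta, weight = w_all, retained = keep,
    stringsAsFactors = FALSE)
  structure(list(importance = imp, models = tab,
                 mean_marginal_r2 = mean_r2, delta_cut = delta_cut,
                 renormalized = renormalize),
            class = "importance_table")
}

#' @export
print.importance_table <- function(x, ...) {
  cat("Variable importance (summed Akaike weights, dAICc <",
      x$delta_cut, if (x$renormalized) "renormalized" else "", ")\n")
  print(round(x$importance, 3))
  if (!is.na(x$mean_marginal_r2))
    cat(sprintf("Mean marginal R2 over retained models: %.3f\n",
                x$mean_marginal_r2))
  cat(sum(x$models$retained), "of", nrow(x$models), "models retained\n")
  invisible(x)
}

#' Marginal and conditional R-squared for mixed models
#'
#' Variance-component decomposition: marginal R2 (fixed effects only)
#' `= var_f/(var_f + var_r + var_e)`; conditional R2 (fixed plus random)
#' `= (var_f + var_r)/(var_f + var_r + var_e)`.
#'
#' @param var_fixed fixed-effect variance.
#' @param var_random random-effect variance.
#' @param var_resid residual variance.
#' @return Named numeric vector `c(marginal = , conditional = )`.
#' @export
nakagawa_r2 <- function(var_fixed, var_random, var_resid) {
  v <- c(var_fixed, var_random, var_resid)
  if (any(v < 0)) stop("variances must be non-negative")
  tot <- sum(v)
  if (tot == 0) stop("all variance components are zero")
  c(marginal = var_fixed / tot,
    conditional = (var_fixed + var_random) / tot)
}

#' Enumerate all-subsets predictor sets
#'
#' Dredge-style generation of every subset of the supplied predictors
#' (including the intercept-only model), for use with any fitter that
#' returns a [model_summary()].
#'
#' @param predictors character vector of candidate predictor names.
#' @param max_size cap on the number of predictors per model (default:
#'   all).
#' @return List of character vectors (the empty vector is the null
#'   model).
#' @export
predictor_subsets <- function(predictors, max_size = length(predictors)) {
  out <- list(character(0))
  for (s in seq_len(min(max_size, length(predictors)))) {
    cmb <- combn(predictors, s, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}
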