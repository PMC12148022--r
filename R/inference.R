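# climate hypothesis -> trait-table column
.clim_cols <- list("T_min" = "tmin_c", "P_dry" = "pdry_mm",
                   "VPD" = "vpd_kpa", "T_min+P_dry" = c("tmin_c", "pdry_mm"),
                   "Altitude" = "altitude_m")

#' Specification of one candidate mixed model
#'
#' @param name Model label (the climate hypothesis it encodes).
#' @param response `"log10_mr"` or `"fge"`.
#' @param climate Character vector of climate columns.
#' @param scope `"within"` (single species) or `"multispecies"`.
#' @param mr_predictor Include log10 MR as a fixed predictor (the
#'   frequency-of-gas-exchange models do, since FGE rises with MR).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, response, climate,
                       scope = c("within", "multispecies"),
                       mr_predictor = FALSE) {
  scope <- match.arg(scope)
  fixed <- "log10_mass"
  if (scope == "multispecies") fixed <- c(fixed, "species",
                                          "log10_mass:species")
  if (mr_predictor) {
    fixed <- c(fixed, "log10_mr")
    if (scope == "multispecies") fixed <- c(fixed, "log10_mr:species")
  }
  fixed <- c(fixed, climate)
  structure(list(name = name, response = response, fixed = fixed,
                 random = c("block", "channel"), scope = scope),
            class = "model_spec")
}

.build_set <- function(scope, response, mr_predictor) {
  lapply(names(.clim_cols), function(nm) {
    model_spec(nm, response, .clim_cols[[nm]], scope, mr_predictor)
  })
}

#' Candidate model sets for the MCA and hygric hypotheses
#'
#' Each set holds five a priori models of a trait against one climate
#' hypothesis: minimum temperature (`T_min`), dry-month precipitation
#' (`P_dry`), vapour pressure deficit (`VPD`), `T_min+P_dry`, and an
#' altitude-only null. Every model includes log10 body mass; the
#' metabolic cold adaptation (MCA) set models log10 metabolic rate, the
#' hygric set models frequency of gas exchange and additionally includes
#' log10 metabolic rate as a predictor. In `multispecies` scope, species
#' and its interaction with log10 mass (and, for the hygric set, with
#' log10 MR) enter as fixed effects. Measurement block and analyser
#' channel are crossed random intercepts in every model. Climate
#' variables are never mixed across hypotheses (they are collinear along
#' an altitudinal gradient), except for `T_min+P_dry`.
#'
#' @param scope `"within"` or `"multispecies"`.
#' @return A list of five [model_spec()] objects.
#' @export
build_mca_set <- function(scope = c("within", "multispecies")) {
  .build_set(match.arg(scope), "log10_mr", mr_predictor = FALSE)
}

#' @rdname build_mca_set
#' @export
build_hygric_set <- function(scope = c("within", "multispecies")) {
  .build_set(match.arg(scope), "fge", mr_predictor = TRUE)
}

spec_formula <- function(spec, random = TRUE) {
  rhs <- paste(spec$fixed, collapse = " + ")
  if (random && length(spec$random)) {
    rhs <- paste(rhs, paste(sprintf("(1 | %s)", spec$random),
                            collapse = " + "), sep = " + ")
  }
  as.formula(paste(spec$response, "~", rhs))
}

# Fit a Gaussian LMM, degrading gracefully when a grouping factor has a
# single level; returns list(fit, random_used, is_lmm)
.fit_mixed <- function(formula_fixed, random, data, reml = FALSE) {
  usable <- random[vapply(random, function(g)
    length(unique(data[[g]])) >= 2L, logical(1))]
  if (length(usable) < length(random)) {
    warning(sprintf("grouping factor(s) with < 2 levels dropped: %s",
                    paste(setdiff(random, usable), collapse = ", ")))
  }
  if (!length(usable)) {
    return(list(fit = lm(formula_fixed, data = data),
                random_used = character(), is_lmm = FALSE))
  }
  f <- as.formula(paste(deparse1(formula_fixed), "+",
                        paste(sprintf("(1 | %s)", usable),
                              collapse = " + ")))
  ctrl <- lme4::lmerControl(check.scaleX = "ignore",
                            check.conv.singular = "ignore")
  list(fit = lme4::lmer(f, data = data, REML = reml, control = ctrl),
       random_used = usable, is_lmm = TRUE)
}

#' Fit one candidate linear mixed model
#'
#' Gaussian LMM via [lme4::lmer()] with crossed random intercepts for
#' measurement block and channel. Full maximum likelihood (`"ML"`) is the
#' default because the candidate sets differ in their fixed effects;
#' `"REML"` is available for reporting variance components.
#' Denominator degrees of freedom use a containment-style approximation,
#' `n - (total random-effect levels) - (number of fixed coefficients)`,
#' and p-values are from the t distribution on those df (an
#' approximation, as always for LMMs).
#'
#' @param spec A [model_spec()].
#' @param data Trait table containing every referenced column (see
#'   [simulate_trait_table()] for the schema).
#' @param method `"ML"` or `"REML"`.
#' @return An object of class `fit_summary`: `coefficients` (data frame
#'   with estimate, se, df, t, p), `varcomp` (named variances incl.
#'   `resid`), `loglik`, `n_params`, `aic` (= -2 loglik + 2 n_params),
#'   `marginal_r2`, `converged`, `n`, `name`, and the underlying `fit`.
#' @export
fit_lmm <- function(spec, data, method = c("ML", "REML")) {
  method <- match.arg(method)
  vars <- unique(c(spec$response,
                   unlist(strsplit(spec$fixed, ":", fixed = TRUE)),
                   spec$random))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop(sprintf("data is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  f_fixed <- spec_formula(spec, random = FALSE)
  X <- model.matrix(f_fixed, data)
  if (qr(X)$rank < ncol(X)) {
    qrX <- qr(X)
    aliased <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop(sprintf("rank-deficient fixed effects; aliased term(s): %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }

  mixed <- .fit_mixed(f_fixed, spec$random, data,
                      reml = (method == "REML"))
  fit <- mixed$fit

  if (mixed$is_lmm) {
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp <- setNames(vc$vcov, ifelse(vc$grp == "Residual", "resid", vc$grp))
    n <- stats::nobs(fit)
    n_levels <- sum(vapply(lme4::getME(fit, "flist"), nlevels, integer(1)))
    # a boundary (singular) fit is a valid ML solution (a variance hit 0);
    # only genuine optimizer failures disqualify a model
    msgs <- unlist(fit@optinfo$conv$lme4$messages)
    conv <- !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  } else {
    beta <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    varcomp <- c(resid = summary(fit)$sigma^2)
    n <- stats::nobs(fit)
    n_levels <- 0L
    conv <- TRUE
  }
  df_denom <- max(1L, n - n_levels - length(beta))
  tval <- beta / se
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se), df = df_denom, t = unname(tval),
                      p = 2 * pt(-abs(unname(tval)), df_denom),
                      stringsAsFactors = FALSE)
  ll <- as.numeric(logLik(fit))
  n_params <- as.numeric(attr(logLik(fit), "df"))
  n <- as.numeric(n)
  var_fixed <- var(as.numeric(X %*% beta[colnames(X)]))
  out <- structure(
    list(name = spec$name, spec = spec, method = method,
         coefficients = coefs, varcomp = varcomp, var_fixed = var_fixed,
         loglik = ll, n_params = n_params, aic = -2 * ll + 2 * n_params,
         converged = conv, n = n, fit = fit),
    class = "fit_summary")
  out$marginal_r2 <- marginal_r2(out)
  out
}

#' @export
print.fit_summary <- function(x, ...) {
  cat(sprintf("<fit_summary> %s (%s, %s): n = %d, AIC = %.2f, marginal R2 = %.3f\n",
              x$name, x$spec$response, x$method, x$n, x$aic, x$marginal_r2))
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Marginal R-squared of a mixed-model fit
#'
#' The proportion of variance explained by the fixed effects:
#' \deqn{R^2_m = \frac{\sigma^2_{fixed}}{\sigma^2_{fixed} +
#'   \sum_g \sigma^2_g + \sigma^2_{resid}}}
#' where \eqn{\sigma^2_{fixed}} is the variance of the fixed-effect
#' linear predictor over the data and the sum runs over the random
#' intercept variances.
#'
#' @param fit A [fit_lmm()] `fit_summary` (or a list with numeric
#'   `var_fixed` and `varcomp` fields).
#' @return Marginal R-squared in [0, 1].
#' @export
marginal_r2 <- function(fit) {
  tot <- fit$var_fixed + sum(fit$varcomp)
  if (!is.finite(tot) || tot <= 0) {
    stop("zero total variance; marginal R2 undefined", call. = FALSE)
  }
  fit$var_fixed / tot
}

#' Akaike weights
#'
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} with
#' \eqn{\Delta_i = AIC_i - \min AIC}: the relative likelihood of each
#' model in a candidate set, normalised to sum to 1. Non-finite AICs are
#' excluded with a warning and reported as `NA`.
#'
#' @param aics Numeric vector of AIC values.
#' @return Weights, same length as `aics`.
#' @examples
#' akaike_weights(c(-84.53, -75.99, -75.23, -74.37, -74.14))
#' @export
akaike_weights <- function(aics) {
  ok <- is.finite(aics)
  if (!any(ok)) stop("need at least one finite AIC", call. = FALSE)
  if (!all(ok)) warning(sprintf("%d non-finite AIC(s) excluded", sum(!ok)))
  delta <- aics[ok] - min(aics[ok])
  rel <- exp(-delta / 2)
  out <- rep(NA_real_, length(aics))
  out[ok] <- rel / sum(rel)
  out
}

#' Fit and compare a candidate model set by AIC
#'
#' Rows with a missing value in *any* column referenced by *any* model in
#' the set are dropped once, before fitting, so every AIC refers to the
#' same data. Models that fail to converge are excluded from the ranking
#' with a warning.
#'
#' @param specs List of [model_spec()]s (e.g. [build_mca_set()]).
#' @param data Trait table.
#' @param method `"ML"` (default) or `"REML"`.
#' @return A `comparison_table` data frame sorted by AIC: `model`,
#'   `n_params`, `aic`, `delta_aic`, `weight`, `marginal_r2`; attributes
#'   `n_used` (rows fitted) and `fits` (the `fit_summary` list).
#' @export
compare_models <- function(specs, data, method = c("ML", "REML")) {
  method <- match.arg(method)
  vars <- unique(unlist(lapply(specs, function(s)
    c(s$response, unlist(strsplit(s$fixed, ":", fixed = TRUE)), s$random))))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop(sprintf("data is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  cc <- complete.cases(data[, vars])
  data2 <- data[cc, , drop = FALSE]
  fits <- lapply(specs, fit_lmm, data = data2, method = method)
  conv <- vapply(fits, `[[`, logical(1), "converged")
  if (!all(conv)) {
    warning(sprintf("non-converged model(s) excluded: %s",
                    paste(vapply(fits[!conv], `[[`, character(1), "name"),
                          collapse = ", ")))
  }
  kept <- fits[conv]
  tab <- data.frame(
    model = vapply(kept, `[[`, character(1), "name"),
    n_params = vapply(kept, `[[`, numeric(1), "n_params"),
    aic = vapply(kept, `[[`, numeric(1), "aic"),
    stringsAsFactors = FALSE)
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab$weight <- akaike_weights(tab$aic)
  tab$marginal_r2 <- vapply(kept, `[[`, numeric(1), "marginal_r2")
  tab <- tab[order(tab$aic), ]
  rownames(tab) <- NULL
  structure(tab, n_used = nrow(data2), fits = fits,
            class = c("comparison_table", "data.frame"))
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("Model comparison (n = %s)\n",
              attr(x, "n_used") %||% "?"))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Variance inflation factors
#'
#' For each term, `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from the
#' ordinary regression of term `j` on all other terms (with intercept).
#' Perfectly collinear terms report `Inf`.
#'
#' @param data Data frame holding the predictor columns.
#' @param terms Character vector of two or more column names.
#' @return Named numeric vector of VIFs (each >= 1).
#' @export
compute_vif <- function(data, terms) {
  if (length(terms) < 2L) stop_field("terms", "need at least two terms")
  missing_cols <- setdiff(terms, names(data))
  if (length(missing_cols)) {
    stop(sprintf("data is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  X <- data[, terms]
  vif <- vapply(terms, function(j) {
    r2 <- summary(lm(as.formula(paste(j, "~ .")), data = X))$r.squared
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  vif
}
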