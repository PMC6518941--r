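#' Specify a behavioural-trait or fitness model
#'
#' A light container pairing a response with a fixed-effect structure and a
#' random-intercept flag. Factor codings follow the standard reference
#' levels: ancestral arrangement, female sex and feeding season are the
#' zeros of the model.
#'
#' @param response response column name (e.g. `"log_hr"`, `"depth"`,
#'   `"dvm"`, `"S"`).
#' @param fixed character RHS of the fixed-effect formula, e.g.
#'   `"season * lg07 + season * length"`.
#' @param random_intercept include a per-fish random intercept
#'   (`(1 | fish_id)`)?
#' @param label optional display label.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(response, fixed, random_intercept = TRUE,
                       label = NULL) {
  structure(list(response = response, fixed = fixed,
                 random_intercept = random_intercept,
                 label = label %||% sprintf("%s ~ %s", response, fixed)),
            class = "model_spec")
}

#' Fit a behavioural-trait linear mixed model
#'
#' Fits `response ~ fixed + (1 | fish_id)` by maximum likelihood (ML, not
#' REML, so AIC values are comparable across fixed-effect structures).
#' Reports fixed-effect estimates with Wald standard errors and
#' normal-approximation p-values, the among-fish and residual variance
#' components, the intraclass correlation (ICC), and the Nakagawa-style
#' marginal R² (variance of fixed-effect predictions over total model
#' variance). Singular fits are flagged, not silently accepted.
#'
#' @param data long data frame with one row per fish-month and a `fish_id`
#'   column (and the covariates the spec references).
#' @param spec a [model_spec()], or a character RHS (with `response`
#'   supplied).
#' @param response response name when `spec` is a character RHS.
#' @return object of class `trait_fit`: list with `coefficients` (data
#'   frame `term, estimate, se, z, p`), `aic`, `var_id`, `var_res`, `icc`,
#'   `marginal_r2`, `singular`, `n_obs`, `n_fish`, `spec` and the
#'   underlying `fit`.
#' @export
fit_trait_lmm <- function(data, spec, response = NULL) {
  if (is.character(spec)) spec <- model_spec(response, spec)
  stopifnot(inherits(spec, "model_spec"))
  data <- droplevels(data[complete.cases(
    data[, c(spec$response, all.vars(as.formula(paste("~", spec$fixed))),
             if (spec$random_intercept) "fish_id")]), ])
  if (spec$random_intercept) {
    f <- as.formula(sprintf("%s ~ %s + (1 | fish_id)",
                            spec$response, spec$fixed))
    fit <- lme4::lmer(f, data = data, REML = FALSE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_id <- vc$vcov[vc$grp == "fish_id"]
    var_res <- vc$vcov[vc$grp == "Residual"]
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    singular <- lme4::isSingular(fit)
    n_fish <- lme4::ngrps(fit)[["fish_id"]]
    fixed_pred <- as.numeric(model.matrix(fit) %*% est)
  } else {
    f <- as.formula(sprintf("%s ~ %s", spec$response, spec$fixed))
    fit <- lm(f, data = data)
    var_id <- 0
    var_res <- sigma(fit)^2
    est <- coef(fit)
    singular <- any(is.na(est))
    est <- est[!is.na(est)]   # rank-deficient: aliased terms dropped
    se <- sqrt(diag(vcov(fit)))[names(est)]
    n_fish <- length(unique(data$fish_id %||% seq_len(nrow(data))))
    fixed_pred <- fitted(fit)
  }
  if (singular) warning("singular or rank-deficient fit", call. = FALSE)
  z <- est / se
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), z = unname(z),
                      p = unname(2 * pnorm(-abs(z))),
                      stringsAsFactors = FALSE)
  var_fixed <- var(fixed_pred)
  structure(list(coefficients = coefs, aic = AIC(fit),
                 var_id = var_id, var_res = var_res,
                 icc = var_id / (var_id + var_res),
                 marginal_r2 = var_fixed / (var_fixed + var_id + var_res),
                 singular = singular, n_obs = nrow(data), n_fish = n_fish,
                 spec = spec, fit = fit),
            class = "trait_fit")
}

#' @export
print.trait_fit <- function(x, ...) {
  cat(sprintf("trait model: %s%s\n", x$spec$label,
              if (x$spec$random_intercept) " + (1 | fish_id)" else ""))
  cat(sprintf("n = %d observations, %d fish; AIC (ML) = %.1f%s\n",
              x$n_obs, x$n_fish, x$aic,
              if (x$singular) " [singular]" else ""))
  print(format(x$coefficients, digits = 3), row.names = FALSE)
  cat(sprintf("var(fish) = %.3f, var(resid) = %.3f, ICC = %.2f, marginal R2 = %.2f\n",
              x$var_id, x$var_res, x$icc, x$marginal_r2))
  invisible(x)
}

#' @export
summary.trait_fit <- function(object, ...) object

#' @export
coef.trait_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Variance partition of a mixed fit
#'
#' @param fit a [fit_trait_lmm()] result.
#' @return named vector `icc` (among-fish variance fraction of the random
#'   part) and `marginal_r2` (fixed-effect variance fraction of the total).
#' @export
variance_partition <- function(fit) {
  stopifnot(inherits(fit, "trait_fit"))
  c(icc = fit$icc, marginal_r2 = fit$marginal_r2)
}

#' AIC model selection over candidate specifications
#'
#' Fits every candidate by ML on the complete cases shared by all
#' candidates (differing row sets are rejected) and ranks them by AIC;
#' ties break toward fewer parameters.
#'
#' @param candidates list of [model_spec()]s (at least 2).
#' @param data model data frame.
#' @return list of class `aic_selection`: `table` (data frame `label, aic,
#'   df, rank`), `selected` (the winning spec) and `fits`.
#' @export
aic_select <- function(candidates, data) {
  stopifnot(length(candidates) >= 2)
  vars <- unique(unlist(lapply(candidates, function(s)
    c(s$response, all.vars(as.formula(paste("~", s$fixed)))))))
  vars <- intersect(vars, names(data))
  cc <- complete.cases(data[, vars, drop = FALSE])
  d <- droplevels(data[cc, , drop = FALSE])
  fits <- lapply(candidates, function(s) fit_trait_lmm(d, s))
  ns <- vapply(fits, function(f) f$n_obs, numeric(1))
  if (length(unique(ns)) != 1)
    stopf("candidates were fitted on differing row sets")
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  df <- vapply(fits, function(f) attr(logLik(f$fit), "df"), numeric(1))
  ord <- order(aic, df)
  tab <- data.frame(label = vapply(candidates, `[[`, "", "label"),
                    aic = aic, df = df, stringsAsFactors = FALSE)
  tab$rank <- match(seq_len(nrow(tab)), ord)
  structure(list(table = tab[order(tab$rank), ],
                 selected = candidates[[ord[1]]],
                 selected_fit = fits[[ord[1]]], fits = fits),
            class = "aic_selection")
}

#' @export
print.aic_selection <- function(x, ...) {
  print(format(x$table, digits = 6), row.names = FALSE)
  cat("selected:", x$selected$label, "\n")
  invisible(x)
}

#' Select the minimum-AIC row of a precomputed ladder table
#'
#' For model ladders whose AICs are already known (e.g. published
#' comparison tables used as inputs), returns the winning row; ties break
#' toward fewer parameters when a `df` column is present.
#'
#' @param table data frame with columns `model` (or `label`) and `aic`,
#'   optionally `df`.
#' @return the selected row of `table`.
#' @export
select_min_aic <- function(table) {
  stopifnot("aic" %in% names(table))
  ord <- if ("df" %in% names(table)) order(table$aic, table$df)
         else order(table$aic)
  table[ord[1], , drop = FALSE]
}

#' Two-step AIC ladder
#'
#' Model selection in the order used for behavioural-trait inference:
#' step 1 keeps the full inversion-state structure fixed and chooses the
#' most parsimonious body-size/sex structure; step 2 keeps that winner's
#' size/sex terms and chooses the most parsimonious inversion-state
#' structure.
#'
#' @param data model data frame.
#' @param response response column.
#' @param inversion_full character RHS fragment with the full
#'   inversion-state structure (e.g.
#'   `"season * lg02 + season * lg07 + season * lg12"`).
#' @param size_sex_options character vector of candidate size/sex RHS
#'   fragments (e.g. `c("season * length + season * sex",
#'   "season * length + sex", "season * length")`).
#' @param inversion_options candidate inversion RHS fragments for step 2
#'   (include `""` to allow dropping the inversions entirely).
#' @param random_intercept passed to [model_spec()].
#' @return list with `step1`, `step2` ([aic_select()] results) and
#'   `selected` (final spec).
#' @export
aic_two_step <- function(data, response, inversion_full, size_sex_options,
                         inversion_options, random_intercept = TRUE) {
  join <- function(a, b) {
    parts <- c(a, b); parts <- parts[nzchar(parts)]
    if (!length(parts)) "1" else paste(parts, collapse = " + ")
  }
  step1 <- aic_select(lapply(size_sex_options, function(ss)
    model_spec(response, join(inversion_full, ss),
               random_intercept = random_intercept)), data)
  best_ss <- size_sex_options[[
    which(vapply(size_sex_options, function(ss)
      identical(join(inversion_full, ss), step1$selected$fixed),
      logical(1)))]]
  step2 <- aic_select(lapply(inversion_options, function(iv)
    model_spec(response, join(iv, best_ss),
               random_intercept = random_intercept)), data)
  list(step1 = step1, step2 = step2, selected = step2$selected)
}

#' Fit the linear selection (fitness-gradient) model
#'
#' Ordinary least-squares regression of relative fitness (relative
#' longevity S) on traits, the Lande-Arnold approach: coefficients are
#' selection differentials on the fitted scale. Dispersed fish must be
#' excluded upstream ([relative_longevity()] does this).
#'
#' @param data one row per fish with an `S` column and covariates.
#' @param fixed character RHS, e.g. `"lg12 + length"`.
#' @param response response column (default `"S"`).
#' @return object of class `selection_fit`: `coefficients` data frame,
#'   `r_squared`, `aic`, `n`, and the underlying `fit`. Rank deficiency is
#'   reported via the `singular` flag and a warning.
#' @export
fit_selection_model <- function(data, fixed, response = "S") {
  f <- as.formula(sprintf("%s ~ %s", response, fixed))
  d <- droplevels(data[complete.cases(
    data[, c(response, all.vars(as.formula(paste("~", fixed)))),
         drop = FALSE]), ])
  fit <- lm(f, data = d)
  est <- coef(fit)
  singular <- any(is.na(est))
  if (singular) warning("rank-deficient selection model", call. = FALSE)
  sm <- summary(fit)
  ct <- sm$coefficients
  coefs <- data.frame(term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
                      t = ct[, 3], p = ct[, 4], stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs, r_squared = sm$r.squared,
                 aic = AIC(fit), n = nrow(d), singular = singular,
                 formula = f, fit = fit),
            class = "selection_fit")
}

#' @export
print.selection_fit <- function(x, ...) {
  cat("selection model:", deparse(x$formula), sprintf("(n = %d)\n", x$n))
  print(format(x$coefficients, digits = 3), row.names = FALSE)
  cat(sprintf("multiple R2 = %.3f, AIC = %.1f%s\n", x$r_squared, x$aic,
              if (x$singular) " [rank-deficient]" else ""))
  invisible(x)
}

#' @export
coef.selection_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}
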