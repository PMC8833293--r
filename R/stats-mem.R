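# Mixed-effects ranking models, conditional r2, best-subset AIC search.

rank_col <- function(f) paste0("rank_", f)

# build benefit ~ stim_fraction + rank factors + (1 | patient)
mem_formula <- function(factors, include_stim = TRUE) {
  rhs <- c(if (include_stim) "stim_fraction",
           if (length(factors)) paste0("factor(", rank_col(factors), ")"),
           "(1 | patient)")
  stats::as.formula(paste("benefit ~", paste(rhs, collapse = " + ")))
}

#' Fit a contact-ranking mixed-effects model
#'
#' Models per-contact motor benefit (%) with a random intercept per
#' patient and fixed effects for the tolerated stimulation fraction and
#' the contact rankings of the requested factors. Ranks enter as
#' categorical predictors (reference level rank 1) because benefit does
#' not step linearly across ranks. Maximum likelihood is used by default
#' so AICs are comparable across fixed-effect structures.
#'
#' @param table an analysis table (see [assemble_analysis_table()] or
#'   [simulate_rank_table()]).
#' @param factors character subset of
#'   `c("erna", "beta", "hfo", "anatomy")` (may be empty for the
#'   covariate-only model).
#' @param include_stim include `stim_fraction` as a fixed covariate.
#' @param reml use REML instead of ML (never when comparing AICs).
#' @return An object of class `mem_fit`: `factors`, `coefficients`
#'   (fixed effects with SEs), `var_patient`, `var_residual`, `logLik`,
#'   `AIC`, `k`, `conditional_r2`, `marginal_r2`, `n_obs`, `converged`,
#'   and the underlying `lme4` `model`.
#' @export
fit_ranking_mem <- function(table, factors = character(),
                            include_stim = TRUE, reml = FALSE) {
  needed <- c("benefit", "patient", if (include_stim) "stim_fraction",
              if (length(factors)) rank_col(factors))
  miss <- setdiff(needed, names(table))
  if (length(miss))
    abort(paste("analysis table lacks columns:",
                paste(miss, collapse = ", ")), "ernarank_join_error")
  if (length(unique(table$patient)) < 2)
    abort("need at least 2 patients for a random patient intercept",
          "ernarank_usage_error")
  dat <- table[complete.cases(table[, needed, drop = FALSE]), ,
               drop = FALSE]
  fml <- mem_formula(factors, include_stim)
  converged <- TRUE
  fit <- withCallingHandlers(
    tryCatch(lme4::lmer(fml, data = dat, REML = reml),
             error = function(e) {
               converged <<- FALSE
               NULL
             }),
    warning = function(w) {
      if (grepl("converge|singular", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (is.null(fit))
    return(structure(list(factors = factors, converged = FALSE),
                     class = "mem_fit"))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) converged <- FALSE   # zero variance component: flag, keep diagnostics
  ll <- logLik(fit)
  vc <- lme4::VarCorr(fit)
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  X <- lme4::getME(fit, "X")
  var_fixed <- var(as.numeric(X %*% fe))
  var_patient <- as.numeric(vc$patient[1])
  var_resid <- attr(vc, "sc")^2
  tot <- var_fixed + var_patient + var_resid
  structure(list(
    factors = factors, model = fit,
    coefficients = data.frame(term = names(fe), estimate = fe,
                              se = se, row.names = NULL),
    var_fixed = var_fixed, var_patient = var_patient,
    var_residual = var_resid,
    logLik = as.numeric(ll), k = attr(ll, "df"),
    AIC = 2 * attr(ll, "df") - 2 * as.numeric(ll),
    conditional_r2 = if (tot > 0)
      (var_fixed + var_patient) / tot else NA_real_,
    marginal_r2 = if (tot > 0) var_fixed / tot else NA_real_,
    n_obs = nrow(dat), converged = converged, singular = singular),
    class = "mem_fit")
}

#' @export
print.mem_fit <- function(x, ...) {
  cat(sprintf(
    "<mem_fit> factors: %s | AIC %.1f | conditional r2 %.2f | n %d%s\n",
    if (length(x$factors)) paste(x$factors, collapse = "+") else "(none)",
    x$AIC, x$conditional_r2, x$n_obs,
    if (!x$converged) " | NOT CONVERGED" else ""))
  invisible(x)
}

#' Conditional and marginal r² of a ranking model
#'
#' Variance-partition definition: the fixed-effect variance is the
#' variance of the fixed-effect linear predictor over the data;
#' conditional r² = (fixed + random) / (fixed + random + residual),
#' marginal r² drops the random-intercept variance from the numerator.
#'
#' @param fit a `mem_fit`.
#' @return List with `conditional` and `marginal`; `NA` with an
#'   `undefined` flag when the total variance is zero.
#' @export
conditional_r2 <- function(fit) {
  if (!inherits(fit, "mem_fit") || is.null(fit$var_fixed))
    abort("conditional_r2 requires a fitted mem_fit",
          "ernarank_usage_error")
  tot <- fit$var_fixed + fit$var_patient + fit$var_residual
  if (tot == 0)
    return(list(conditional = NA_real_, marginal = NA_real_,
                undefined = TRUE))
  list(conditional = (fit$var_fixed + fit$var_patient) / tot,
       marginal = fit$var_fixed / tot, undefined = FALSE)
}

#' Screen nuisance covariates
#'
#' Fits one mixed model per candidate covariate (condition order,
#' stimulation fraction) with a random patient intercept and retains
#' candidates whose Wald p (Satterthwaite degrees of freedom) is below
#' `alpha`.
#'
#' @param table an analysis table.
#' @param candidates covariate column names to screen.
#' @param alpha retention threshold.
#' @return data.frame per candidate: `covariate`, `estimate`, `p`,
#'   `AIC`, `conditional_r2`, `converged`, `retained`.
#' @export
screen_nuisance_covariates <- function(table,
                                       candidates = c("order_index",
                                                      "stim_fraction"),
                                       alpha = 0.05) {
  res <- lapply(candidates, function(cv) {
    row <- data.frame(covariate = cv, estimate = NA_real_, p = NA_real_,
                      AIC = NA_real_, conditional_r2 = NA_real_,
                      converged = FALSE, retained = FALSE)
    dat <- table[complete.cases(table[, c("benefit", "patient", cv)]), ]
    fit <- tryCatch(suppressMessages(suppressWarnings(
      lmerTest::lmer(stats::as.formula(
        paste("benefit ~", cv, "+ (1 | patient)")),
        data = dat, REML = FALSE))),
      error = function(e) NULL)
    if (is.null(fit)) return(row)
    cf <- tryCatch(summary(fit)$coefficients,
                   error = function(e) NULL)
    if (is.null(cf) || !cv %in% rownames(cf) ||
        !"Pr(>|t|)" %in% colnames(cf))
      return(row)
    vc <- lme4::VarCorr(fit)
    var_fixed <- var(as.numeric(
      lme4::getME(fit, "X") %*% lme4::fixef(fit)))
    tot <- var_fixed + as.numeric(vc$patient[1]) + attr(vc, "sc")^2
    row$estimate <- cf[cv, "Estimate"]
    row$p <- cf[cv, "Pr(>|t|)"]
    row$AIC <- AIC(fit)
    row$conditional_r2 <- if (tot > 0)
      (var_fixed + as.numeric(vc$patient[1])) / tot else NA_real_
    row$converged <- TRUE
    row$retained <- is.finite(row$p) && row$p < alpha
    row
  })
  do.call(rbind, res)
}

#' Likelihood-ratio comparison of nested ranking models
#'
#' @param fit_small,fit_big `mem_fit`s on the same data, both ML, with
#'   `fit_small`'s factors a subset of `fit_big`'s.
#' @return List with `lr` (2 * delta logLik), `df` (parameter
#'   difference) and `p` (chi-squared upper tail; 1 when the models are
#'   identical).
#' @export
compare_nested_models <- function(fit_small, fit_big) {
  if (!all(fit_small$factors %in% fit_big$factors))
    abort("models are not nested (factor sets)",
          "ernarank_usage_error")
  if (fit_small$n_obs != fit_big$n_obs)
    abort("models were fitted to different data",
          "ernarank_usage_error")
  lr <- max(0, 2 * (fit_big$logLik - fit_small$logLik))
  df <- fit_big$k - fit_small$k
  p <- if (df > 0) pchisq(lr, df, lower.tail = FALSE) else 1
  list(lr = lr, df = df, p = p)
}

#' Holm step-down adjustment
#'
#' @param p raw p-values.
#' @return Holm-adjusted p-values (monotone, each >= raw).
#' @export
holm_adjust <- function(p) p.adjust(p, method = "holm")

#' Best-subset search over ranking factors
#'
#' Fits one ML mixed model for every non-empty subset of the ranking
#' factors (15 models for 4 factors), ranks them by AIC, and compares
#' the best model against each of its nested sub-models by
#' likelihood-ratio test with Holm adjustment.
#'
#' @param table an analysis table.
#' @param factors ranking factors to combine.
#' @param include_stim include the stimulation-fraction covariate.
#' @return An object of class `subset_result`: `summary` (one row per
#'   subset with AIC, logLik, conditional r², convergence),
#'   `best_subset`, `fits` (named list of `mem_fit`s) and
#'   `comparisons` (LRT of best vs its sub-models, Holm-adjusted).
#' @export
best_subset_search <- function(table,
                               factors = c("erna", "beta", "hfo",
                                           "anatomy"),
                               include_stim = TRUE) {
  subsets <- unlist(lapply(seq_along(factors), function(k)
    combn(factors, k, simplify = FALSE)), recursive = FALSE)
  names(subsets) <- vapply(subsets, paste, "", collapse = "+")
  fits <- lapply(subsets, function(s)
    fit_ranking_mem(table, s, include_stim = include_stim, reml = FALSE))
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(conv))
    abort("no subset model converged", "ernarank_usage_error")
  aics <- vapply(fits, function(f) f$AIC %||% NA_real_, numeric(1))
  smry <- data.frame(subset = names(subsets),
                     n_factors = lengths(subsets),
                     AIC = aics,
                     logLik = vapply(fits, function(f)
                       f$logLik %||% NA_real_, numeric(1)),
                     conditional_r2 = vapply(fits, function(f)
                       f$conditional_r2 %||% NA_real_, numeric(1)),
                     converged = conv, row.names = NULL)
  smry <- smry[order(smry$AIC), ]
  best_name <- smry$subset[which(smry$converged)[1]]
  best <- fits[[best_name]]
  subs <- names(subsets)[vapply(subsets, function(s)
    all(s %in% best$factors) && length(s) < length(best$factors),
    logical(1))]
  comparisons <- NULL
  if (length(subs)) {
    cmp <- lapply(subs, function(nm)
      compare_nested_models(fits[[nm]], best))
    comparisons <- data.frame(
      sub_model = subs,
      lr = vapply(cmp, `[[`, numeric(1), "lr"),
      df = vapply(cmp, `[[`, numeric(1), "df"),
      p = vapply(cmp, `[[`, numeric(1), "p"))
    comparisons$p_holm <- holm_adjust(comparisons$p)
  }
  structure(list(summary = smry, best_subset = best$factors,
                 fits = fits, comparisons = comparisons),
            class = "subset_result")
}

#' @export
print.subset_result <- function(x, ...) {
  cat("<subset_result> best subset:",
      paste(x$best_subset, collapse = "+"), "\n")
  print(utils::head(x$summary, 5))
  invisible(x)
}

#' Spearman correlations between neuronal signals
#'
#' Rank correlations between ERNA, beta and HFO power pooled over all
#' contacts, pairwise with missing pairs dropped.
#'
#' @param features data.frame with `erna_power`, `beta_power`,
#'   `hfo_power` columns (one row per contact).
#' @return data.frame per pair: `pair`, `rs`, `p`, `n`
#'   (`rs = NA` with fewer than 3 complete pairs).
#' @export
spearman_between_signals <- function(features) {
  vars <- c(erna = "erna_power", beta = "beta_power", hfo = "hfo_power")
  prs <- combn(names(vars), 2, simplify = FALSE)
  do.call(rbind, lapply(prs, function(pr) {
    x <- features[[vars[pr[1]]]]
    y <- features[[vars[pr[2]]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3)
      return(data.frame(pair = paste(pr, collapse = "-"),
                        rs = NA_real_, p = NA_real_, n = sum(ok)))
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                    exact = FALSE))
    data.frame(pair = paste(pr, collapse = "-"),
               rs = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  }))
}
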