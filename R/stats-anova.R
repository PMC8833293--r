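# Blocked repeated-measures ANOVA, Tukey pairwise comparisons, and
# within-hemisphere rank-1 contrasts.

#' Patient-blocked repeated-measures ANOVA
#'
#' Two-way fixed-effects ANOVA with a condition term and a patient-block
#' term; unbalanced data are handled by least squares with type-II sums
#' of squares. The error degrees of freedom are
#' `N - 1 - (c - 1) - (b - 1)`.
#'
#' @param table data.frame containing the response, condition and block
#'   columns.
#' @param response,condition,block column names.
#' @return An object of class `anova_result`: `F`, `p`, `df_factor`,
#'   `df_error`, `means` (per-level mean, SE, n), and the underlying
#'   `lm` fit (`model`) for post-hoc comparisons.
#' @export
rm_anova_blocked <- function(table, response = "benefit",
                             condition = "rank_benefit",
                             block = "patient") {
  dat <- table[complete.cases(table[, c(response, condition, block)]), ]
  dat$.y <- dat[[response]]
  dat$.cond <- factor(dat[[condition]])
  dat$.block <- factor(dat[[block]])
  if (nlevels(dat$.cond) < 2 || nlevels(dat$.block) < 2)
    abort("need at least 2 conditions and 2 blocks",
          "ernarank_design_error")
  fit <- lm(.y ~ .cond + .block, data = dat)
  if (any(is.na(coef(fit))))
    abort("aliased design: condition and block are confounded",
          "ernarank_design_error")
  a2 <- car::Anova(fit, type = 2)
  i <- match(".cond", rownames(a2))
  means <- do.call(rbind, lapply(split(dat$.y, dat$.cond), function(v)
    data.frame(mean = mean(v), se = sd(v) / sqrt(length(v)),
               n = length(v))))
  means <- data.frame(level = rownames(means), means, row.names = NULL)
  structure(list(F = a2$`F value`[i], p = a2$`Pr(>F)`[i],
                 df_factor = a2$Df[i],
                 df_error = a2$Df[nrow(a2)],
                 means = means, model = fit, condition = condition),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.1f, p = %.3g\n",
              x$df_factor, x$df_error, x$F, x$p))
  invisible(x)
}

#' Tukey-adjusted pairwise comparisons
#'
#' All pairwise differences between condition levels of a blocked ANOVA,
#' adjusted by the Tukey (studentized range) method on the model's
#' least-squares means.
#'
#' @param anova an [rm_anova_blocked()] result.
#' @return data.frame per comparison: `contrast`, `estimate`, `se`,
#'   `df`, `t`, `p_adj`.
#' @export
tukey_pairwise <- function(anova) {
  if (!inherits(anova, "anova_result"))
    abort("expected an anova_result", "ernarank_usage_error")
  em <- emmeans::emmeans(anova$model, ".cond")
  cmp <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                         adjust = "tukey"))
  data.frame(contrast = as.character(cmp$contrast),
             estimate = cmp$estimate, se = cmp$SE, df = cmp$df,
             t = cmp$t.ratio, p_adj = cmp$p.value)
}

#' Rank-1 versus lower-rank benefit contrasts
#'
#' Within-hemisphere paired contrasts of benefit at the factor's rank-1
#' contact against each of ranks 2-4, Holm-adjusted over the three
#' tests. Hemispheres lacking either member of a pair are dropped from
#' that contrast.
#'
#' @param table an analysis table.
#' @param factor one of `"erna"`, `"beta"`, `"hfo"`, `"anatomy"`,
#'   `"benefit"`.
#' @return data.frame per contrast: `comparison`, `n_pairs`,
#'   `mean_diff`, `t`, `df`, `p`, `p_holm`.
#' @export
first_vs_rest_contrasts <- function(table, factor = "erna") {
  col <- rank_col(factor)
  if (!col %in% names(table))
    abort(sprintf("analysis table lacks column '%s'", col),
          "ernarank_join_error")
  hemis <- split(table, table$hemisphere)
  res <- lapply(2:4, function(r) {
    pairs <- vapply(hemis, function(d) {
      b1 <- d$benefit[d[[col]] == 1]
      br <- d$benefit[d[[col]] == r]
      if (length(b1) == 1 && length(br) == 1 &&
          is.finite(b1) && is.finite(br)) b1 - br else NA_real_
    }, numeric(1))
    pairs <- pairs[is.finite(pairs)]
    if (length(pairs) < 2 || sd(pairs) == 0)
      return(data.frame(comparison = sprintf("rank1 - rank%d", r),
                        n_pairs = length(pairs),
                        mean_diff = mean(pairs), t = NA_real_,
                        df = NA_real_, p = NA_real_))
    tt <- t.test(pairs)
    data.frame(comparison = sprintf("rank1 - rank%d", r),
               n_pairs = length(pairs), mean_diff = mean(pairs),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_holm <- holm_adjust(out$p)
  out
}
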