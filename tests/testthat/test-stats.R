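test_that("ranking models recover structure, with the AIC identity holding", {
  tab <- simulate_rank_table(effects = c(erna = 12, beta = 0, hfo = 0,
                                         anatomy = 0), seed = 1)
  fit <- fit_ranking_mem(tab, "erna")
  expect_true(fit$converged)
  expect_equal(fit$AIC, 2 * fit$k - 2 * fit$logLik)
  co <- fit$coefficients
  r4 <- co$estimate[co$term == "factor(rank_erna)4"]
  expect_lt(r4, 0)
  expect_equal(fit$n_obs, 112)
  expect_true(fit$conditional_r2 > 0 && fit$conditional_r2 < 1)

  # shuffling the informative ranks within hemispheres worsens the AIC
  set.seed(7)
  shuf <- tab
  shuf$rank_erna <- ave(shuf$rank_erna, shuf$hemisphere,
                        FUN = sample)
  fit_s <- fit_ranking_mem(shuf, "erna")
  expect_gt(fit_s$AIC, fit$AIC)

  expect_error(fit_ranking_mem(tab[tab$patient == "P01", ], "erna"),
               class = "ernarank_usage_error")
})

test_that("conditional r2 partitions variance as documented", {
  fake <- structure(list(var_fixed = 1, var_patient = 1,
                         var_residual = 2, converged = TRUE),
                    class = "mem_fit")
  r <- conditional_r2(fake)
  expect_equal(r$conditional, 0.5)
  expect_equal(r$marginal, 0.25)

  lim <- structure(list(var_fixed = 3, var_patient = 0,
                        var_residual = 1e-12, converged = TRUE),
                   class = "mem_fit")
  expect_equal(conditional_r2(lim)$conditional, 1, tolerance = 1e-9)

  degen <- structure(list(var_fixed = 0, var_patient = 0,
                          var_residual = 0, converged = TRUE),
                     class = "mem_fit")
  expect_true(conditional_r2(degen)$undefined)
})

test_that("the best-subset search enumerates 15 models and compares nested fits", {
  tab <- simulate_rank_table(effects = c(erna = 14, beta = 0, hfo = 0,
                                         anatomy = 0), seed = 5)
  bs <- best_subset_search(tab)
  expect_equal(nrow(bs$summary), 15)
  expect_length(bs$fits, 15)
  expect_true("erna" %in% bs$best_subset)
  conv <- bs$summary$converged
  expect_equal(bs$summary$AIC[which(conv)[1]],
               min(bs$summary$AIC[conv]))
  # AIC identity on every emitted fit
  for (f in bs$fits)
    if (isTRUE(f$converged))
      expect_equal(f$AIC, 2 * f$k - 2 * f$logLik)
  if (!is.null(bs$comparisons))
    expect_true(all(bs$comparisons$p_holm >= bs$comparisons$p))
})

test_that("nested-model comparison is a chi-squared likelihood-ratio test", {
  tab <- simulate_rank_table(seed = 9)
  small <- fit_ranking_mem(tab, "erna")
  big <- fit_ranking_mem(tab, c("erna", "beta"))
  cmp <- compare_nested_models(small, big)
  expect_equal(cmp$lr, 2 * (big$logLik - small$logLik))
  expect_equal(cmp$df, big$k - small$k)
  expect_equal(cmp$p, pchisq(cmp$lr, cmp$df, lower.tail = FALSE))

  ident <- compare_nested_models(small, small)
  expect_equal(ident$lr, 0)
  expect_equal(ident$p, 1)

  expect_error(compare_nested_models(big, small),
               class = "ernarank_usage_error")
})

test_that("Holm adjustment matches the step-down oracle and is monotone", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  # independent step-down implementation with the monotonicity constraint
  holm_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    running <- 0
    for (i in seq_len(m)) {
      running <- max(running, (m - i + 1) * p[o[i]])
      adj[o[i]] <- min(1, running)
    }
    adj
  }
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    expect_equal(holm_adjust(p), holm_oracle(p), tolerance = 1e-12)
    expect_true(all(holm_adjust(p) >= p))
  }
})

test_that("Spearman correlations reproduce the rank formula", {
  f1 <- data.frame(erna_power = 1:8, beta_power = (1:8)^2,
                   hfo_power = 8:1)
  sp <- spearman_between_signals(f1)
  expect_equal(sp$rs[sp$pair == "erna-beta"], 1)
  expect_equal(sp$rs[sp$pair == "erna-hfo"], -1)

  f2 <- data.frame(erna_power = c(1, 2, 3, 4),
                   beta_power = c(1, 3, 2, 4),
                   hfo_power = c(NA, NA, 1, 2))
  sp2 <- spearman_between_signals(f2)
  expect_equal(sp2$rs[sp2$pair == "erna-beta"], 0.8)  # 1 - 6*2/60
  expect_true(is.na(sp2$rs[sp2$pair == "erna-hfo"]))  # < 3 pairs
})

test_that("the blocked ANOVA reproduces printed degrees of freedom and a SS oracle", {
  # 111 observations, 4 rank levels, 14 patient blocks -> error df 94
  tab <- simulate_rank_table(seed = 2)[-1, ]
  a1 <- rm_anova_blocked(tab, "benefit", "rank_erna", "patient")
  expect_equal(a1$df_factor, 3)
  expect_equal(a1$df_error, 94)

  # 168 observations, 6 categories, 14 blocks -> error df 149
  d6 <- data.frame(patient = rep(sprintf("P%02d", 1:14), each = 12),
                   cat = rep(1:6, 28), y = rnorm(168))
  a2 <- rm_anova_blocked(d6, "y", "cat", "patient")
  expect_equal(a2$df_error, 149)

  # balanced 3 blocks x 3 conditions: brute-force sums of squares
  set.seed(4)
  toy <- expand.grid(blk = factor(1:3), cond = factor(1:3))
  toy$y <- rnorm(9, mean = as.numeric(toy$cond))
  a3 <- rm_anova_blocked(toy, "y", "cond", "blk")
  gm <- mean(toy$y)
  ss_cond <- 3 * sum((tapply(toy$y, toy$cond, mean) - gm)^2)
  ss_blk <- 3 * sum((tapply(toy$y, toy$blk, mean) - gm)^2)
  ss_tot <- sum((toy$y - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_blk
  f_oracle <- (ss_cond / 2) / (ss_err / 4)
  expect_equal(a3$F, f_oracle, tolerance = 1e-9)
  expect_equal(a3$p, pf(f_oracle, 2, 4, lower.tail = FALSE),
               tolerance = 1e-9)

  # aliased design: condition constant within blocks
  bad <- data.frame(patient = rep(1:4, each = 2),
                    cond = rep(1:4, each = 2), y = rnorm(8))
  expect_error(rm_anova_blocked(bad, "y", "cond", "patient"),
               class = "ernarank_design_error")
})

test_that("Tukey comparisons collapse to the t-test at k = 2 and enumerate pairs", {
  set.seed(12)
  d2 <- data.frame(patient = factor(rep(1:10, 2)),
                   cond = rep(c("a", "b"), each = 10),
                   y = rnorm(20, rep(c(0, 1), each = 10)))
  a2 <- rm_anova_blocked(d2, "y", "cond", "patient")
  tk2 <- tukey_pairwise(a2)
  expect_equal(nrow(tk2), 1)
  # with k = 2 the Tukey p equals the model t-test p (q = t * sqrt(2))
  tt_p <- 2 * pt(-abs(tk2$t), tk2$df)
  expect_equal(tk2$p_adj, tt_p, tolerance = 1e-6)

  tab <- simulate_rank_table(seed = 6)
  a4 <- rm_anova_blocked(tab, "benefit", "rank_erna", "patient")
  tk4 <- tukey_pairwise(a4)
  expect_equal(nrow(tk4), 6)

  # identical level means with nonzero pooled variance: adjusted p near 1
  ya <- rnorm(8)
  yb <- rnorm(8)
  yb <- yb - mean(yb) + mean(ya)
  d_eq <- data.frame(patient = factor(rep(1:8, 2)),
                     cond = rep(c("a", "b"), each = 8),
                     y = c(ya, yb))
  tk_eq <- tukey_pairwise(rm_anova_blocked(d_eq, "y", "cond", "patient"))
  expect_gt(tk_eq$p_adj, 0.99)
})

test_that("covariate screening retains real effects and handles degenerate input", {
  tab <- simulate_rank_table(effects = c(erna = 10), stim_coef = 50,
                             reduction_probs = c(0.5, 0.25, 0.2, 0.05),
                             seed = 15)
  sc <- screen_nuisance_covariates(tab)
  expect_true(sc$retained[sc$covariate == "stim_fraction"])
  expect_true(all(c("AIC", "conditional_r2", "p") %in% names(sc)))

  const <- tab
  const$benefit <- 42
  sc0 <- screen_nuisance_covariates(const)
  expect_false(any(sc0$retained))
})

test_that("rank-1 contrasts find a strong rank-1 advantage with Holm control", {
  tab <- simulate_rank_table(effects = c(erna = 15), noise_sd = 8,
                             seed = 20)
  fr <- first_vs_rest_contrasts(tab, "erna")
  expect_equal(nrow(fr), 3)
  expect_true(all(fr$p_holm >= fr$p))
  expect_true(all(fr$mean_diff > 0))
  expect_true(all(fr$p_holm < 0.05))
})

test_that("a zero patient variance generator yields a near-zero variance estimate", {
  meds <- vapply(1:20, function(s) {
    tab <- simulate_rank_table(effects = c(erna = 10), patient_sd = 0,
                               noise_sd = 10, seed = 400 + s)
    fit <- fit_ranking_mem(tab, "erna")
    fit$var_patient / fit$var_residual
  }, numeric(1))
  expect_lt(median(meds), 0.1)
})
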