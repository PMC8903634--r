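test_that("Kaplan-Meier estimate matches the hand product-limit", {
  # event at 1 (3 at risk), censored at 2, event at 3 (1 at risk)
  km <- km_estimate(toy_surv(time = c(1, 2, 3), event = c(1, 0, 1)))
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 2], 2 / 3) # censoring: no step
  expect_equal(km$survival[km$time == 3], 0)

  none <- km_estimate(toy_surv(time = c(5, 6, 7), event = c(0, 0, 0)))
  expect_true(all(none$survival == 1))
  expect_error(km_estimate(toy_surv(numeric(0), integer(0))), "empty")

  # no censoring: empirical survivor function
  set.seed(50)
  t_all <- sort(rexp(25, 0.1))
  km_full <- km_estimate(toy_surv(time = t_all, event = rep(1L, 25)))
  emp <- vapply(km_full$time, function(t) mean(t_all > t), numeric(1))
  expect_equal(km_full$survival, emp, tolerance = 1e-12)
})

test_that("log-rank test agrees with its permutation oracle", {
  grp <- function(g, ids) {
    tibble::tibble(
      sample_id = ids, risk_score = 0,
      group = factor(g, levels = c("low", "high"))
    )
  }
  # identical survival copied into both groups: statistic 0, p = 1
  base <- toy_surv(time = c(3, 5, 8, 12), event = c(1, 1, 0, 1))
  both <- dplyr::bind_rows(
    dplyr::mutate(base, sample_id = paste0("A", sample_id)),
    dplyr::mutate(base, sample_id = paste0("B", sample_id))
  )
  lr0 <- logrank_test(
    grp(rep(c("low", "high"), each = 4), both$sample_id), both
  )
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  # 20-subject instance vs a 1e4-shuffle permutation null
  set.seed(51)
  n <- 20
  g <- rep(c("low", "high"), each = 10)
  surv <- toy_surv(
    time = rexp(n, 0.05 * exp(0.7 * (g == "high"))),
    event = rbinom(n, 1, 0.85)
  )
  obs <- logrank_test(grp(g, surv$sample_id), surv)
  chisq_of <- function(gg) {
    survival::survdiff(survival::Surv(surv$time, surv$event) ~ gg)$chisq
  }
  perm <- replicate(1e4, chisq_of(sample(g)))
  p_perm <- (1 + sum(perm >= obs$statistic - 1e-12)) / (1e4 + 1)
  mc_se <- sqrt(p_perm * (1 - p_perm) / 1e4)
  expect_lt(abs(obs$p - p_perm), 0.03 + 3 * mc_se)

  expect_error(
    logrank_test(grp(rep("low", n), surv$sample_id), surv),
    "two non-empty"
  )
})

test_that("multivariate Cox reduces to univariate and flags collinearity", {
  set.seed(52)
  n <- 60
  x <- rnorm(n)
  surv <- toy_surv(time = rexp(n, 0.02 * exp(0.5 * x)), event = rep(1L, n))
  covs <- tibble::tibble(sample_id = surv$sample_id, x = x)
  multi <- multivariate_cox(surv, covs)
  uni <- univariate_cox(x, surv)
  expect_equal(multi$beta, uni$beta, tolerance = 1e-8)
  expect_equal(multi$p, uni$p, tolerance = 1e-8)

  covs_dup <- dplyr::mutate(covs, x2 = x)
  expect_error(multivariate_cox(surv, covs_dup), "collinear")

  # listwise deletion of missing covariates
  covs_na <- covs
  covs_na$x[1:5] <- NA
  fit_na <- multivariate_cox(surv, covs_na)
  expect_equal(fit_na$n, n - 5)
})

test_that("Wilcoxon rank-sum: exact small-sample path and approximation agree", {
  ex <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(ex$p, 1 / 3)
  same <- suppressWarnings(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")

  set.seed(53)
  for (i in 1:10) {
    x <- rnorm(12)
    y <- rnorm(12, 0.5)
    p_exact <- wilcoxon_rank_sum(x, y)$p # tie-free n=12: exact path
    p_approx <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("significance stars follow the strict thresholds", {
  expect_equal(
    significance_stars(c(0.0005, 0.005, 0.03, 0.05, 0.2)),
    c("***", "**", "*", "", "")
  )
})

test_that("group contrasts annotate every variable with stars", {
  set.seed(54)
  strat <- suppressMessages(assign_groups(
    tibble::tibble(sample_id = sprintf("S%02d", 1:40), risk_score = rnorm(40)),
    0
  ))
  vals <- tibble::tibble(
    sample_id = rep(sprintf("S%02d", 1:40), 2),
    variable = rep(c("drugA", "drugB"), each = 40),
    value = c(
      2 + 2 * (strat$risk_score > 0) + rnorm(40, sd = 0.3),
      rnorm(40)
    )
  )
  res <- compare_by_group(vals, strat)
  expect_equal(nrow(res), 2)
  expect_equal(res$stars[res$variable == "drugA"], "***")

  vals_missing <- dplyr::mutate(vals,
    value = ifelse(variable == "drugB" & sample_id %in%
      strat$sample_id[strat$group == "high"], NA, value)
  )
  expect_error(compare_by_group(vals_missing, strat), "one risk group")
})

test_that("ssGSEA scores match a hand-rolled running sum on a toy matrix", {
  v <- matrix(c(5, 4, 3, 2, 1, 1, 2, 3, 4, 5), 5, 2,
    dimnames = list(sprintf("G%d", 1:5), c("S1", "S2"))
  )
  em <- toy_expr(v)
  sets <- list(top = c("G1", "G2"), bottom = c("G4", "G5"))
  sc <- ssgsea_scores(em, sets, alpha = 0.25)

  # independent computation: walk genes by decreasing rank
  brute <- function(expr_col, set, alpha = 0.25) {
    rnk <- rank(expr_col)
    ord <- order(rnk, decreasing = TRUE)
    genes <- names(expr_col)[ord]
    in_set <- genes %in% set
    w <- (rnk[ord])^alpha * in_set
    pos <- cumsum(w) / sum(w)
    neg <- cumsum(!in_set) / sum(!in_set)
    sum(pos - neg)
  }
  x1 <- v[, 1]
  for (nm in names(sets)) {
    expect_equal(
      sc$score[sc$sample_id == "S1" & sc$set == nm],
      brute(x1, sets[[nm]]),
      tolerance = 1e-12
    )
  }
  # monotonicity: the top-expressed set scores strictly higher
  s1 <- sc[sc$sample_id == "S1", ]
  expect_gt(s1$score[s1$set == "top"], s1$score[s1$set == "bottom"])

  # identical profiles yield identical scores
  v2 <- cbind(S1 = v[, 1], S2 = v[, 1])
  sc2 <- ssgsea_scores(toy_expr(v2), sets)
  expect_equal(
    sc2$score[sc2$sample_id == "S1"],
    sc2$score[sc2$sample_id == "S2"]
  )

  expect_warning(
    ssgsea_scores(em, list(top = c("G1"), alien = c("Z1"))),
    "skipped"
  )
  expect_error(
    suppressWarnings(ssgsea_scores(em, list(alien = "Z1"))),
    "no gene set"
  )
})
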