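test_that("univariate Cox matches the closed-form 4-observation solution", {
  # events at t=1 (x=1) and t=2 (x=0); score equation gives exp(2*beta) = 2
  surv <- toy_surv(time = c(1, 2, 3, 4), event = c(1, 1, 0, 0))
  fit <- univariate_cox(c(1, 0, 1, 0), surv)
  expect_equal(fit$beta, log(2) / 2, tolerance = 1e-3)
  expect_equal(fit$hr, exp(fit$beta))
  expect_true(fit$ci_low < fit$hr && fit$hr < fit$ci_high)

  expect_error(univariate_cox(rep(1, 4), surv), "constant")
  expect_error(
    univariate_cox(c(1, 0, 1, 0), toy_surv(c(1, 2, 3, 4), c(1, 0, 0, 0))),
    "2 events"
  )
})

test_that("univariate Cox is sign-equivariant and matches a grid maximizer", {
  set.seed(30)
  for (rep_i in 1:5) {
    n <- 8
    x <- rnorm(n)
    surv <- toy_surv(time = rexp(n, 0.2), event = rbinom(n, 1, 0.7))
    if (sum(surv$event) < 2) next
    fit <- tryCatch(univariate_cox(x, surv), error = function(e) NULL)
    if (is.null(fit)) next
    # brute-force maximum of the Breslow partial likelihood
    grid <- optimize(
      function(b) cox_pll(b, x, surv$time, surv$event),
      interval = c(-10, 10), maximum = TRUE, tol = 1e-9
    )$maximum
    expect_equal(fit$beta, grid, tolerance = 1e-4)
    neg <- univariate_cox(-x, surv)
    expect_equal(neg$beta, -fit$beta, tolerance = 1e-8)
  }
})

test_that("univariate screen keeps prognostic pairs and drops degenerates", {
  set.seed(31)
  n <- 120
  x_signal <- rbinom(n, 1, 0.5)
  surv <- toy_surv(
    time = rexp(n, 0.01 * exp(1.2 * x_signal)),
    event = rep(1L, n)
  )
  x_null <- rbinom(n, 1, 0.5)
  x_const <- rep(0L, n)
  values <- cbind("A|B" = x_signal, "C|D" = x_null, "E|F" = x_const)
  rownames(values) <- surv$sample_id
  pairs <- tibble::tibble(
    name = colnames(values),
    lnc_a = c("A", "C", "E"), lnc_b = c("B", "D", "F")
  )
  pm <- irlncPairs:::new_pair_matrix(values, pairs)
  expect_warning(kept <- screen_pairs(pm, surv), "degenerate")
  expect_true("A|B" %in% colnames(kept))
  expect_false("E|F" %in% colnames(kept))
  expect_error(screen_pairs(pm, surv, p_max = 0), "0, 1")
})

test_that("lasso limits: full shrinkage errors, lambda=0 matches coxph", {
  set.seed(32)
  n <- 80
  x <- rbinom(n, 1, 0.5)
  surv <- toy_surv(time = rexp(n, 0.02 * exp(0.9 * x)), event = rep(1L, n))
  values <- cbind("A|B" = x)
  rownames(values) <- surv$sample_id
  pm <- irlncPairs:::new_pair_matrix(
    values, tibble::tibble(name = "A|B", lnc_a = "A", lnc_b = "B")
  )
  expect_error(
    fit_lasso_cox(pm, surv, lambda = 10),
    "shrunk to zero"
  )
  m0 <- fit_lasso_cox(pm, surv, lambda = 0)
  unpen <- univariate_cox(x, surv)
  expect_equal(m0$pairs$beta, unpen$beta, tolerance = 1e-4)
})

test_that("cross-validated lasso recovers planted pairs deterministically", {
  sim <- default_sim()
  cfg <- sim_config(seed = 101L)
  pm_all <- build_pair_matrix(
    sim$expr[sim$truth$de_ids, ],
    samples = cohort_samples(sim$expr, "tumor")
  )
  surv <- simulate_survival(pm_all, sim$truth, cfg)
  pm <- filter_valid_pairs(pm_all)
  screened <- suppressWarnings(screen_pairs(pm, surv))
  m1 <- fit_lasso_cox(screened, surv, seed = 7L)
  m2 <- fit_lasso_cox(screened, surv, seed = 7L)
  expect_identical(m1$pairs, m2$pairs)
  expect_gte(sum(sim$truth$planted_pairs$name %in% m1$pairs$pair), 3)
  # CV metadata records the deviance path
  expect_s3_class(m1$cv$path, "tbl_df")
  expect_equal(m1$cv$folds, 10)
  # tidy/glance interface
  td <- tidy(m1)
  expect_equal(td$hr, exp(td$beta))
  expect_equal(glance(m1)$n_pairs, nrow(m1$pairs))
})

test_that("risk scores are exact dot products, invariant to sample order", {
  model <- structure(
    list(
      pairs = tibble::tibble(pair = c("A|B", "C|D"), beta = c(0.5, -1)),
      lambda = 0.1, cv = list()
    ),
    class = "signature_model"
  )
  values <- rbind(S1 = c(1L, 0L), S2 = c(0L, 1L), S3 = c(0L, 0L))
  colnames(values) <- c("A|B", "C|D")
  pm <- irlncPairs:::new_pair_matrix(
    values,
    tibble::tibble(
      name = colnames(values), lnc_a = c("A", "C"), lnc_b = c("B", "D")
    )
  )
  rs <- compute_risk_score(model, pm)
  expect_equal(rs$risk_score, c(0.5, -1, 0))

  # brute-force oracle on a random instance + permutation invariance
  set.seed(33)
  vals <- matrix(rbinom(40, 1, 0.5), 10, 4,
    dimnames = list(sprintf("S%02d", 1:10), c("A|B", "C|D", "E|F", "G|H"))
  )
  pm2 <- irlncPairs:::new_pair_matrix(
    vals,
    tibble::tibble(
      name = colnames(vals),
      lnc_a = c("A", "C", "E", "G"), lnc_b = c("B", "D", "F", "H")
    )
  )
  model2 <- structure(
    list(
      pairs = tibble::tibble(pair = colnames(vals), beta = rnorm(4)),
      lambda = 0, cv = list()
    ),
    class = "signature_model"
  )
  rs2 <- compute_risk_score(model2, pm2)
  brute <- vapply(seq_len(10), function(i) {
    s <- 0
    for (k in 1:4) s <- s + model2$pairs$beta[k] * vals[i, k]
    s
  }, numeric(1))
  expect_equal(rs2$risk_score, unname(brute))
  perm <- sample(10)
  rs_perm <- compute_risk_score(
    model2, irlncPairs:::new_pair_matrix(vals[perm, ], pair_info(pm2))
  )
  expect_equal(
    rs_perm$risk_score[match(rs2$sample_id, rs_perm$sample_id)],
    rs2$risk_score
  )

  model_missing <- model2
  model_missing$pairs$pair[1] <- "X|Y"
  expect_error(compute_risk_score(model_missing, pm2), "X\\|Y")
})
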