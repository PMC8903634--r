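# Shared fixtures for the test suite. Everything is generated in code.

# Tiny simulation: 10 genes, 12 samples; smoke-scale.
tiny_config <- function(seed = 11L, ...) {
  sim_config(
    n_normal = 6, n_tumor = 6, n_mrna = 6, n_immune = 3,
    n_lnc = 4, n_irlnc = 3, n_de = 2, n_planted_pairs = 1,
    seed = seed, ...
  )
}

# Mid-size cohort for power checks without default-scale cost.
mid_config <- function(seed = 21L, ...) {
  sim_config(
    n_normal = 40, n_tumor = 120, n_mrna = 60, n_immune = 20,
    n_lnc = 60, n_irlnc = 12, n_de = 8, n_planted_pairs = 3,
    seed = seed, ...
  )
}

# The default study-scale cohort, simulated once and cached per session.
.fixture_env <- new.env(parent = emptyenv())
default_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_expression(sim_config(seed = 101L))
  }
  .fixture_env$sim
}

# One full default-scale pipeline run, cached (used by several acceptance
# checks).
default_pipeline_run <- function() {
  if (is.null(.fixture_env$run)) {
    dir <- file.path(tempdir(), "irlnc-default-run")
    cfg <- pipeline_config(out_dir = dir, seed = 101L)
    .fixture_env$run <- suppressMessages(suppressWarnings(run_pipeline(cfg)))
  }
  .fixture_env$run
}

# small expr_matrix built by hand
toy_expr <- function(values, cohort = "tumor", batch = "b1") {
  expr_matrix(values, cohort = cohort, batch = batch)
}

# simple survival tibble
toy_surv <- function(time, event, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("S%02d", seq_along(time))
  tibble::tibble(sample_id = ids, time = time, event = event)
}

# brute-force BH step-up definition: q_i = min_{j: p_j >= p_i} p_j * m / rank_j
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranks <- integer(m)
  ranks[ord] <- seq_len(m)
  vapply(seq_len(m), function(i) {
    js <- which(p >= p[i] - 1e-15)
    min(1, min(p[js] * m / ranks[js]))
  }, numeric(1))
}

# Mann-Whitney AUC with half credit for ties
mw_auc <- function(case_scores, control_scores) {
  gt <- outer(case_scores, control_scores, ">")
  eq <- outer(case_scores, control_scores, "==")
  (sum(gt) + 0.5 * sum(eq)) / (length(case_scores) * length(control_scores))
}

# Cox partial log-likelihood (Breslow ties), for brute-force maximization
cox_pll <- function(beta, x, time, event) {
  eta <- beta * x
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + sum(eta[d]) - length(d) * log(sum(exp(eta[risk])))
  }
  ll
}
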