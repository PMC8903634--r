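#' Univariate Cox proportional-hazards fit
#'
#' Fits a single-covariate Cox model by maximum partial likelihood with
#' Breslow tie handling, returning the log hazard ratio with Wald standard
#' error, 95 percent confidence interval and two-sided p-value.
#'
#' @param x Numeric covariate, one value per row of `surv`, non-constant.
#' @param surv Survival tibble with columns `time` (> 0) and `event` (0/1);
#'   at least 2 events.
#' @param term Label recorded in the `term` column of the result.
#' @return A one-row tibble of class `cox_fit` with columns `term`, `beta`,
#'   `se`, `hr`, `ci_low`, `ci_high`, `p`, `n`, `events`.
#' @export
univariate_cox <- function(x, surv, term = "x") {
  if (length(x) != nrow(surv)) {
    stop("covariate length must match the survival table", call. = FALSE)
  }
  if (sum(surv$event) < 2) stop("need at least 2 events", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate fit: constant covariate", call. = FALSE)
  fit <- survival::coxph(
    survival::Surv(surv$time, surv$event) ~ x,
    ties = "breslow",
    control = survival::coxph.control(iter.max = 50)
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(stats::vcov(fit))))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15) {
    stop("univariate Cox fit did not converge (monotone likelihood?)",
      call. = FALSE
    )
  }
  tibble::new_tibble(
    tibble::tibble(
      term = term,
      beta = beta,
      se = se,
      hr = exp(beta),
      ci_low = exp(beta - stats::qnorm(0.975) * se),
      ci_high = exp(beta + stats::qnorm(0.975) * se),
      p = 2 * stats::pnorm(-abs(beta / se)),
      n = nrow(surv),
      events = sum(surv$event)
    ),
    class = "cox_fit"
  )
}

#' Screen pair features by univariate Cox p-value
#'
#' Fits [univariate_cox()] per pair column against survival and keeps pairs
#' with Wald `p < p_max`. Pairs with degenerate or non-convergent fits are
#' dropped with a warning.
#'
#' @param pm A `pair_matrix` whose rows match `surv$sample_id`.
#' @param surv Survival tibble (`sample_id`, `time`, `event`).
#' @param p_max Wald p-value threshold, in (0, 1] (default 0.05).
#' @return The screened `pair_matrix`, with a tibble of the per-pair fits in
#'   attribute `screen`.
#' @export
screen_pairs <- function(pm, surv, p_max = 0.05) {
  stopifnot(inherits(pm, "pair_matrix"))
  if (!is.numeric(p_max) || p_max <= 0 || p_max > 1) {
    stop("`p_max` must lie in (0, 1]", call. = FALSE)
  }
  surv <- surv[match(rownames(pm), surv$sample_id), , drop = FALSE]
  if (anyNA(surv$sample_id)) {
    stop("survival data missing for some pair-matrix samples", call. = FALSE)
  }
  fits <- purrr::map(colnames(pm), function(pr) {
    tryCatch(
      univariate_cox(pm[, pr], surv, term = pr),
      error = function(e) NULL
    )
  })
  failed <- vapply(fits, is.null, logical(1))
  if (any(failed)) {
    warning(sum(failed), " pair(s) dropped with degenerate univariate fits",
      call. = FALSE
    )
  }
  screen <- purrr::list_rbind(fits[!failed])
  keep <- screen$term[screen$p < p_max]
  if (length(keep) == 0) {
    stop("no pair passes the univariate screen at p < ", p_max, call. = FALSE)
  }
  out <- subset_pairs(pm, keep)
  attr(out, "screen") <- screen
  out
}

#' Fit the L1-penalized Cox signature
#'
#' Lasso-penalized Cox regression over the screened pair features,
#' maximizing the partial log-likelihood minus `lambda * sum(|beta|)` along a
#' descending lambda path. Unless `lambda` is given, lambda is chosen by
#' k-fold cross-validated partial-likelihood deviance with folds stratified
#' by event status and seeded for reproducibility; `rule = "1se"` selects
#' the sparser one-standard-error solution instead of the minimum.
#'
#' @param pm A `pair_matrix` (rows = samples).
#' @param surv Survival tibble (`sample_id`, `time`, `event`), >= 2 events.
#' @param k_folds Number of CV folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param rule `"min"` (default) or `"1se"`.
#' @param lambda Optional fixed penalty; skips cross-validation.
#' @return A `signature_model`: list with `pairs` (tibble `pair`, `beta`),
#'   `lambda`, and `cv` metadata (folds, seed, rule, lambda/deviance path).
#' @export
fit_lasso_cox <- function(pm, surv, k_folds = 10, seed = 1L, rule = c("min", "1se"),
                          lambda = NULL) {
  stopifnot(inherits(pm, "pair_matrix"), ncol(pm) >= 1)
  rule <- match.arg(rule)
  surv <- surv[match(rownames(pm), surv$sample_id), , drop = FALSE]
  if (anyNA(surv$sample_id)) {
    stop("survival data missing for some pair-matrix samples", call. = FALSE)
  }
  if (sum(surv$event) < 2) stop("need at least 2 events", call. = FALSE)
  x <- unclass(pm)
  attr(x, "pairs") <- NULL
  attr(x, "screen") <- NULL
  storage.mode(x) <- "double"
  # glmnet needs >= 2 columns; pad a zero dummy that can never be selected
  padded <- ncol(x) == 1
  if (padded) x <- cbind(x, ".dummy" = 0)
  y <- survival::Surv(surv$time, surv$event)
  cv_meta <- list(folds = NA_integer_, seed = NA_integer_, rule = rule)
  if (is.null(lambda)) {
    foldid <- stratified_folds(surv$event, k_folds, seed)
    cvfit <- glmnet::cv.glmnet(x, y,
      family = "cox", alpha = 1, foldid = foldid, standardize = FALSE
    )
    lambda <- if (rule == "min") cvfit$lambda.min else cvfit$lambda.1se
    fit <- cvfit$glmnet.fit
    cv_meta <- list(
      folds = k_folds, seed = as.integer(seed), rule = rule,
      path = tibble::tibble(
        lambda = cvfit$lambda, deviance = cvfit$cvm, se = cvfit$cvsd,
        nonzero = cvfit$nzero
      )
    )
  } else {
    if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
    # descend to the requested lambda so the coordinate solver is warm-started
    lam_seq <- sort(unique(c(exp(seq(log(1), log(max(lambda, 1e-4)), length.out = 30)), lambda)),
      decreasing = TRUE
    )
    fit <- glmnet::glmnet(x, y,
      family = "cox", alpha = 1, lambda = lam_seq,
      standardize = FALSE, thresh = 1e-12
    )
  }
  beta <- as.numeric(glmnet::coef.glmnet(fit, s = lambda, exact = FALSE))
  names(beta) <- rownames(glmnet::coef.glmnet(fit, s = lambda))
  if (padded) beta <- beta[names(beta) != ".dummy"]
  nz <- beta[beta != 0]
  if (length(nz) == 0) {
    stop("all coefficients shrunk to zero at lambda = ", signif(lambda, 3),
      "; extend the lambda path or lower the penalty",
      call. = FALSE
    )
  }
  structure(
    list(
      pairs = tibble::tibble(pair = names(nz), beta = unname(nz)),
      lambda = as.numeric(lambda),
      cv = cv_meta
    ),
    class = "signature_model"
  )
}

# event-stratified CV fold assignment, deterministic given seed
stratified_folds <- function(event, k, seed) {
  foldid <- integer(length(event))
  withr::with_seed(as.integer(seed), {
    for (grp in unique(event)) {
      idx <- which(event == grp)
      foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  foldid
}

#' @export
print.signature_model <- function(x, ...) {
  cat(
    "<signature_model> ", nrow(x$pairs), " pair(s), lambda = ",
    signif(x$lambda, 4), "\n",
    sep = ""
  )
  print(x$pairs, n = 10)
  invisible(x)
}

#' Tidy a fitted pair signature
#' @param x A `signature_model`.
#' @param ... Unused.
#' @return Tibble with columns `pair`, `beta`, `hr`.
#' @export
tidy.signature_model <- function(x, ...) {
  dplyr::mutate(x$pairs, hr = exp(.data$beta))
}

#' One-row summary of a fitted pair signature
#' @param x A `signature_model`.
#' @param ... Unused.
#' @return Tibble with `n_pairs`, `lambda`, `cv_folds`, `cv_rule`.
#' @export
glance.signature_model <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    lambda = x$lambda,
    cv_folds = x$cv$folds,
    cv_rule = x$cv$rule
  )
}

#' Per-sample risk score of a pair signature
#'
#' `score_i = sum_k beta_k * x_ik`, the signature's linear predictor over
#' the binary pair values.
#'
#' @param model A `signature_model`.
#' @param pm A `pair_matrix` containing every model pair as a column.
#' @return Tibble with columns `sample_id`, `risk_score`.
#' @export
compute_risk_score <- function(model, pm) {
  stopifnot(inherits(model, "signature_model"), inherits(pm, "pair_matrix"))
  missing_p <- setdiff(model$pairs$pair, colnames(pm))
  if (length(missing_p) > 0) {
    stop("pair matrix is missing model pair(s): ",
      paste(missing_p, collapse = ", "),
      call. = FALSE
    )
  }
  score <- as.numeric(
    unclass(pm)[, model$pairs$pair, drop = FALSE] %*% model$pairs$beta
  )
  tibble::tibble(sample_id = rownames(pm), risk_score = score)
}
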