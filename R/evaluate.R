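#' Kaplan-Meier survival estimate for one group
#'
#' Product-limit estimator: censored subjects leave the risk set without a
#' step in the curve.
#'
#' @param surv Survival tibble with `time`, `event` for the group.
#' @return A `km_estimate`: tibble with columns `time`, `n_risk`, `n_event`,
#'   `survival`, one row per distinct observed time.
#' @export
km_estimate <- function(surv) {
  if (nrow(surv) == 0) stop("empty group", call. = FALSE)
  fit <- survival::survfit(survival::Surv(surv$time, surv$event) ~ 1)
  tibble::new_tibble(
    tibble::tibble(
      time = fit$time,
      n_risk = fit$n.risk,
      n_event = fit$n.event,
      survival = fit$surv
    ),
    class = "km_estimate"
  )
}

#' Plot Kaplan-Meier curves by risk group
#'
#' @param surv Survival tibble with `sample_id`, `time`, `event`.
#' @param strat A `risk_stratification` from [assign_groups()].
#' @return A ggplot object with one step curve per risk group.
#' @export
plot_km_groups <- function(surv, strat) {
  d <- dplyr::inner_join(surv, strat, by = "sample_id")
  curves <- d |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ km_estimate(.x)) |>
    dplyr::ungroup()
  start <- dplyr::distinct(curves, .data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  ggplot2::ggplot(
    dplyr::bind_rows(start, curves),
    ggplot2::aes(x = .data$time, y = .data$survival, colour = .data$group)
  ) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "days", y = "survival probability", colour = "risk")
}

#' Two-group log-rank test between risk groups
#'
#' Standard one-degree-of-freedom log-rank chi-square: observed minus
#' expected events accumulated over event times with hypergeometric
#' variance.
#'
#' @param strat A `risk_stratification`.
#' @param surv Survival tibble with `sample_id`, `time`, `event`.
#' @return A tibble with `statistic`, `p`, and per-group `n_low`, `n_high`,
#'   `events_low`, `events_high`.
#' @export
logrank_test <- function(strat, surv) {
  d <- dplyr::inner_join(surv, strat, by = "sample_id")
  if (dplyr::n_distinct(d$group) < 2) {
    stop("log-rank test needs two non-empty groups", call. = FALSE)
  }
  if (sum(d$event) < 1) stop("no events observed", call. = FALSE)
  sd_fit <- survival::survdiff(
    survival::Surv(d$time, d$event) ~ d$group
  )
  stat <- sd_fit$chisq
  tibble::tibble(
    statistic = stat,
    p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    n_low = sum(d$group == "low"),
    n_high = sum(d$group == "high"),
    events_low = sum(d$event[d$group == "low"]),
    events_high = sum(d$event[d$group == "high"])
  )
}

#' Multivariate Cox independence analysis
#'
#' Joint Cox proportional-hazards fit (Breslow ties) of the risk score
#' together with clinical covariates, after listwise deletion of rows with
#' missing covariate values. Used to ask whether the signature remains
#' prognostic once age, stage, grade or residual-disease status are
#' accounted for.
#'
#' @param surv Survival tibble (`sample_id`, `time`, `event`).
#' @param covariates Tibble with `sample_id` and one column per covariate;
#'   numeric columns enter as-is, character/factor columns as treatment
#'   contrasts.
#' @return A `cox_fit` tibble with one row per model term.
#' @export
multivariate_cox <- function(surv, covariates) {
  d <- dplyr::inner_join(surv[c("sample_id", "time", "event")], covariates,
    by = "sample_id"
  )
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (sum(d$event) < 2) stop("need at least 2 events", call. = FALSE)
  terms <- setdiff(names(d), c("sample_id", "time", "event"))
  if (length(terms) == 0) stop("no covariates supplied", call. = FALSE)
  mm <- stats::model.matrix(
    stats::reformulate(terms),
    data = d
  )[, -1, drop = FALSE]
  qr_rank <- qr(mm)$rank
  if (qr_rank < ncol(mm)) {
    keep_rank <- qr(mm)$pivot[seq_len(qr_rank)]
    stop("collinear covariate column(s): ",
      paste(colnames(mm)[-keep_rank], collapse = ", "),
      call. = FALSE
    )
  }
  fit <- survival::coxph(
    survival::Surv(d$time, d$event) ~ mm,
    ties = "breslow"
  )
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  tibble::new_tibble(
    tibble::tibble(
      term = colnames(mm),
      beta = unname(beta),
      se = unname(se),
      hr = exp(unname(beta)),
      ci_low = exp(unname(beta) - stats::qnorm(0.975) * unname(se)),
      ci_high = exp(unname(beta) + stats::qnorm(0.975) * unname(se)),
      p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
      n = nrow(d),
      events = sum(d$event)
    ),
    class = "cox_fit"
  )
}

#' Wilcoxon rank-sum test between two samples
#'
#' Exact enumeration when both groups have at most 12 observations and the
#' pooled data are tie-free; otherwise the normal approximation with tie and
#' continuity correction. Two-sided.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @return A tibble with `statistic` (Mann-Whitney U of `x`), `p`, `n_x`,
#'   `n_y`, `median_x`, `median_y`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 12 && length(y) <= 12 && !ties
  wt <- stats::wilcox.test(x, y,
    exact = exact, correct = TRUE, alternative = "two.sided"
  )
  tibble::tibble(
    statistic = unname(wt$statistic),
    p = wt$p.value,
    n_x = length(x),
    n_y = length(y),
    median_x = stats::median(x),
    median_y = stats::median(y)
  )
}

#' Significance stars for a p-value
#'
#' `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05 (all
#' strict), otherwise the empty string.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star annotations.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Compare per-sample values between risk groups
#'
#' Wilcoxon rank-sum contrast of any per-sample quantity (clinical factor,
#' drug IC50-like score, enrichment score) between high- and low-risk
#' groups, with significance stars. Accepts an optional grouping column
#' `variable` in `values` to contrast many quantities at once.
#'
#' @param values Tibble with `sample_id`, `value`, and optionally
#'   `variable`.
#' @param strat A `risk_stratification`.
#' @return A tibble with one row per variable: `variable`, the Wilcoxon
#'   columns of [wilcoxon_rank_sum()] (high group first), and `stars`.
#' @export
compare_by_group <- function(values, strat) {
  if (!"variable" %in% names(values)) values$variable <- "value"
  d <- dplyr::inner_join(values, strat, by = "sample_id") |>
    dplyr::filter(!is.na(.data$value))
  res <- d |>
    dplyr::group_by(.data$variable) |>
    dplyr::group_modify(function(g, key) {
      hi <- g$value[g$group == "high"]
      lo <- g$value[g$group == "low"]
      if (length(hi) == 0 || length(lo) == 0) {
        stop("variable '", key$variable,
          "' has no non-missing values in one risk group",
          call. = FALSE
        )
      }
      wilcoxon_rank_sum(hi, lo)
    }) |>
    dplyr::ungroup()
  dplyr::mutate(res, stars = significance_stars(.data$p))
}

#' Single-sample gene-set enrichment scores
#'
#' Rank-based running-sum enrichment per sample and gene set: genes are
#' ranked by expression (largest rank = highest expression) and walked in
#' decreasing order; in-set genes increment the running sum by their rank
#' value raised to `alpha` (normalized over the set), out-of-set genes
#' decrement it by a fixed step. The score is the sum of the running-sum
#' deviations over all positions. Sets sharing no gene with the matrix are
#' skipped with a warning.
#'
#' @param expr An [expr_matrix()] (typically the tumor slice).
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param alpha Rank-weighting exponent (default 0.25).
#' @param normalize If `TRUE`, min-max normalize each set's scores across
#'   samples.
#' @return A tibble with columns `sample_id`, `set`, `score`.
#' @export
ssgsea_scores <- function(expr, sets, alpha = 0.25, normalize = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"), is.list(sets))
  genes <- rownames(expr)
  usable <- purrr::keep(sets, ~ length(intersect(.x, genes)) > 0)
  skipped <- setdiff(names(sets), names(usable))
  if (length(skipped) > 0) {
    warning("gene set(s) with no overlap skipped: ",
      paste(skipped, collapse = ", "),
      call. = FALSE
    )
  }
  if (length(usable) == 0) stop("no gene set overlaps the matrix", call. = FALSE)
  v <- unclass(expr)
  out <- purrr::map(colnames(v), function(s) {
    rnk <- rank(v[, s], ties.method = "average")
    ord <- order(rnk, decreasing = TRUE)
    scores <- vapply(usable, function(set) {
      in_set <- genes[ord] %in% set
      w <- rnk[ord]^alpha
      w[!in_set] <- 0
      pos <- cumsum(w) / sum(w)
      step_out <- if (any(!in_set)) 1 / sum(!in_set) else 0
      neg <- cumsum(ifelse(in_set, 0, step_out))
      sum(pos - neg)
    }, numeric(1))
    tibble::tibble(sample_id = s, set = names(usable), score = unname(scores))
  }) |>
    purrr::list_rbind()
  if (normalize) {
    out <- out |>
      dplyr::group_by(.data$set) |>
      dplyr::mutate(
        score = (.data$score - min(.data$score)) /
          max(max(.data$score) - min(.data$score), .Machine$double.eps)
      ) |>
      dplyr::ungroup()
  }
  out
}
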