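#' Time-dependent ROC curve (cumulative cases / dynamic controls)
#'
#' At horizon `t`, cases are subjects with an observed event by `t`
#' (`time <= t`, `event = 1`) and controls are subjects still at risk past
#' `t` (`time > t`). Censoring before the horizon is handled by weighting
#' cases with the inverse Kaplan-Meier estimate of the censoring survivor
#' function evaluated just before their event time. Sensitivity and
#' specificity are evaluated at every observed score threshold
#' (classification rule: score strictly greater than the threshold) and the
#' AUC is the trapezoidal area under the resulting curve. With no censoring
#' the estimator reduces exactly to the empirical (Mann-Whitney) ROC of the
#' binary by-horizon status.
#'
#' @param scores Tibble with columns `sample_id`, `risk_score`.
#' @param surv Survival tibble with `sample_id`, `time`, `event`.
#' @param horizon Evaluation time in days, within the follow-up range.
#' @return A `time_roc`: list with `horizon`, `auc`, and `curve`, a tibble
#'   of `threshold` (descending), `sensitivity`, `specificity`.
#' @export
time_dependent_roc <- function(scores, surv, horizon) {
  d <- dplyr::inner_join(scores, surv, by = "sample_id")
  if (nrow(d) == 0) stop("no samples shared between scores and survival", call. = FALSE)
  is_case <- d$time <= horizon & d$event == 1
  is_control <- d$time > horizon
  if (!any(is_case)) stop("no cases by horizon ", horizon, call. = FALSE)
  if (!any(is_control)) stop("no controls past horizon ", horizon, call. = FALSE)
  # KM of the censoring distribution, left-continuous at event times
  cens_fit <- survival::survfit(
    survival::Surv(d$time, 1 - d$event) ~ 1
  )
  g_minus <- function(t) {
    vapply(t, function(ti) {
      s <- c(1, cens_fit$surv)[findInterval(ti - 1e-9, cens_fit$time) + 1]
      max(s, 1e-12)
    }, numeric(1))
  }
  w <- numeric(nrow(d))
  w[is_case] <- 1 / g_minus(d$time[is_case])
  thresholds <- c(Inf, sort(unique(d$risk_score), decreasing = TRUE), -Inf)
  case_w <- sum(w[is_case])
  n_ctrl <- sum(is_control)
  curve <- tibble::tibble(
    threshold = thresholds,
    sensitivity = vapply(thresholds, function(c) {
      sum(w[is_case & d$risk_score > c]) / case_w
    }, numeric(1)),
    specificity = vapply(thresholds, function(c) {
      sum(is_control & d$risk_score <= c) / n_ctrl
    }, numeric(1))
  )
  fpr <- 1 - curve$specificity
  auc <- sum(diff(fpr) * (utils::head(curve$sensitivity, -1) +
    utils::tail(curve$sensitivity, -1)) / 2)
  structure(
    list(horizon = horizon, auc = auc, curve = curve),
    class = "time_roc"
  )
}

#' @export
print.time_roc <- function(x, ...) {
  cat(
    "<time_roc> horizon = ", x$horizon, " days, AUC = ",
    round(x$auc, 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' Choose the prognostic horizon by maximal AUC
#'
#' Computes [time_dependent_roc()] at each candidate horizon (1, 3 and 5
#' years by default) and returns the horizon with the largest AUC; ties go
#' to the longest horizon. Horizons without both cases and controls are
#' skipped with a warning.
#'
#' @param scores,surv As in [time_dependent_roc()].
#' @param horizons Numeric vector of candidate horizons in days.
#' @return A list with `horizon`, `roc` (the winning `time_roc`), and
#'   `aucs`, a tibble of all computable horizons.
#' @export
select_horizon <- function(scores, surv, horizons = c(365, 1095, 1825)) {
  rocs <- purrr::map(horizons, function(h) {
    tryCatch(time_dependent_roc(scores, surv, h), error = function(e) {
      warning("horizon ", h, " skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
  })
  ok <- !vapply(rocs, is.null, logical(1))
  if (!any(ok)) stop("no horizon is computable", call. = FALSE)
  rocs <- rocs[ok]
  aucs <- tibble::tibble(
    horizon = horizons[ok],
    auc = vapply(rocs, function(r) r$auc, numeric(1))
  )
  # max AUC, ties toward the longest horizon
  best <- which(aucs$auc >= max(aucs$auc) - 1e-12)
  best <- best[which.max(aucs$horizon[best])]
  list(horizon = aucs$horizon[best], roc = rocs[[best]], aucs = aucs)
}

#' Youden-optimal cutoff of a time-dependent ROC curve
#'
#' Maximizes the Youden index `J = sensitivity + specificity - 1` over the
#' observed score thresholds; ties go to the lowest threshold (larger
#' high-risk group). A flat curve (`J = 0` everywhere) falls back to the
#' median score with a warning.
#'
#' @param roc A `time_roc`.
#' @return The cutoff (a score value).
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "time_roc"))
  curve <- dplyr::filter(roc$curve, is.finite(.data$threshold))
  j <- curve$sensitivity + curve$specificity - 1
  if (all(abs(j) < 1e-12)) {
    warning("flat ROC curve; falling back to the median score", call. = FALSE)
    return(stats::median(curve$threshold))
  }
  cand <- which(j >= max(j) - 1e-12)
  min(curve$threshold[cand])
}

#' Assign high/low risk groups at a score cutoff
#'
#' High risk iff `risk_score > cutoff` (strict); a score equal to the cutoff
#' is low risk. Errors if either group ends up empty.
#'
#' @param scores Tibble with `sample_id`, `risk_score`.
#' @param cutoff Finite score cutoff.
#' @param horizon Optional horizon (days) recorded alongside the grouping.
#' @return A `risk_stratification`: tibble with columns `sample_id`,
#'   `risk_score`, `group` (factor low/high) and attributes `cutoff`,
#'   `horizon`.
#' @export
assign_groups <- function(scores, cutoff, horizon = NA_real_) {
  if (!is.finite(cutoff)) stop("`cutoff` must be finite", call. = FALSE)
  out <- dplyr::mutate(
    scores,
    group = factor(ifelse(.data$risk_score > cutoff, "high", "low"),
      levels = c("low", "high")
    )
  )
  counts <- table(out$group)
  if (any(counts == 0)) {
    stop("risk group '", names(counts)[counts == 0][1],
      "' is empty at cutoff ", signif(cutoff, 4),
      call. = FALSE
    )
  }
  message("risk groups: ", counts[["high"]], " high / ", counts[["low"]], " low")
  tibble::new_tibble(out,
    cutoff = cutoff, horizon = horizon,
    class = "risk_stratification"
  )
}

#' One-row summary of a risk stratification
#' @param x A `risk_stratification`.
#' @param ... Unused.
#' @return Tibble with `cutoff`, `horizon`, `n_high`, `n_low`.
#' @export
glance.risk_stratification <- function(x, ...) {
  tibble::tibble(
    cutoff = attr(x, "cutoff"),
    horizon = attr(x, "horizon"),
    n_high = sum(x$group == "high"),
    n_low = sum(x$group == "low")
  )
}

#' Plot a time-dependent ROC curve
#' @param object A `time_roc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.time_roc <- function(object, ...) {
  ggplot2::ggplot(
    object$curve,
    ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)
  ) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf(
        "%.1f-year ROC, AUC = %.3f", object$horizon / 365, object$auc
      )
    )
}
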