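#' Two-group differential expression test for one gene
#'
#' Log2 fold change is `mean(tumor) - mean(normal)` (inputs already on the
#' log2 scale); the p-value comes from the Wilcoxon rank-sum test — exact
#' enumeration when both groups have at most 12 samples and the data are
#' tie-free, otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param tumor,normal Numeric vectors of log2 expression, each of
#'   length 2 or more.
#' @return A list with `log2fc` and `p`.
#' @export
two_group_test <- function(tumor, normal) {
  if (length(tumor) < 2 || length(normal) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  log2fc <- mean(tumor) - mean(normal)
  ties <- anyDuplicated(c(tumor, normal)) > 0
  exact <- length(tumor) <= 12 && length(normal) <= 12 && !ties
  p <- stats::wilcox.test(tumor, normal,
    exact = exact, correct = TRUE, alternative = "two.sided"
  )$p.value
  list(log2fc = log2fc, p = p)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values: with order statistics `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the input
#' order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Differential expression of irlncRNAs between tumor and normal
#'
#' Runs [two_group_test()] per gene across the cohorts of `m` and adjusts
#' p-values with [bh_adjust()] across the whole gene family supplied.
#'
#' @param m An [expr_matrix()] restricted to the genes of interest
#'   (typically the irlncRNAs), containing both cohorts.
#' @return A tibble with columns `gene_id`, `log2fc`, `p`, `fdr`,
#'   `direction` (`"up"` iff `log2fc > 0`).
#' @export
de_irlnc <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  info <- sample_info(m)
  tum <- info$cohort == "tumor"
  if (sum(tum) < 2 || sum(!tum) < 2) {
    stop("need >= 2 samples per cohort", call. = FALSE)
  }
  v <- unclass(m)
  res <- purrr::map(rownames(m), function(g) {
    tt <- two_group_test(v[g, tum], v[g, !tum])
    tibble::tibble(gene_id = g, log2fc = tt$log2fc, p = tt$p)
  }) |>
    purrr::list_rbind()
  res$fdr <- bh_adjust(res$p)
  res$direction <- ifelse(res$log2fc > 0, "up", "down")
  res
}

#' Select differentially expressed irlncRNAs
#'
#' Retains genes with `|log2fc| > fc_min` and `fdr < fdr_max` (both strict).
#' The fold-change filter is two-sided, so both up- and down-regulated genes
#' qualify.
#'
#' @param results DE tibble from [de_irlnc()].
#' @param fc_min Absolute log2 fold-change threshold (default 2).
#' @param fdr_max FDR threshold (default 0.05).
#' @return The retained rows of `results`, with up/down counts reported via
#'   message.
#' @export
select_de_irlnc <- function(results, fc_min = 2, fdr_max = 0.05) {
  keep <- dplyr::filter(results, abs(.data$log2fc) > fc_min, .data$fdr < fdr_max)
  if (nrow(keep) == 0) {
    stop("no gene passes |log2fc| > ", fc_min, " and FDR < ", fdr_max,
      "; consider relaxing the thresholds",
      call. = FALSE
    )
  }
  message(
    nrow(keep), " DE gene(s): ", sum(keep$direction == "up"), " up, ",
    sum(keep$direction == "down"), " down"
  )
  keep
}
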