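#' Pearson correlation with a t-distribution p-value
#'
#' Sample Pearson coefficient with the classical two-sided test:
#' `t = r * sqrt((n - 2) / (1 - r^2))` against Student's t with `n - 2`
#' degrees of freedom; a perfect correlation (`|r| = 1`) yields `p = 0`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, both with nonzero
#'   variance.
#' @return A list with elements `r`, `p` and `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  p <- pearson_p(r, n)
  list(r = r, p = p, n = n)
}

# vectorized p-value for Pearson r at sample size n
pearson_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  p <- numeric(length(r))
  exact <- abs(r) >= 1 - 1e-15
  p[exact] <- 0
  tt <- r[!exact] * sqrt((n - 2) / (1 - r[!exact]^2))
  p[!exact] <- 2 * stats::pt(-abs(tt), df = n - 2)
  p
}

#' Screen lncRNAs for immune-related co-expression
#'
#' Identifies immune-related lncRNAs (irlncRNAs): a lncRNA is retained iff
#' some immune gene correlates with it with r above `r_min` and p below
#' `p_max` (both strict). By default the correlation is signed, following the screen's
#' wording of a coefficient "more than" the threshold; set
#' `use_absolute = TRUE` to screen on `|r|`. No multiple-testing correction
#' is applied to the p threshold.
#'
#' @param immune_expr [expr_matrix()] slice of immune genes.
#' @param lnc_expr [expr_matrix()] slice of lncRNAs, same sample columns.
#' @param r_min Correlation threshold (default 0.4).
#' @param p_max P-value threshold (default 0.001).
#' @param use_absolute If `TRUE`, screen on `|r| > r_min`.
#' @return A list with `irlnc_ids` (character vector) and `correlations`, a
#'   tibble of all passing (immune_gene, lnc, r, p, n) records.
#' @export
extract_irlnc <- function(immune_expr, lnc_expr, r_min = 0.4, p_max = 0.001,
                          use_absolute = FALSE) {
  stopifnot(inherits(immune_expr, "expr_matrix"), inherits(lnc_expr, "expr_matrix"))
  if (!identical(colnames(immune_expr), colnames(lnc_expr))) {
    stop("immune and lncRNA slices must share the same sample columns",
      call. = FALSE
    )
  }
  n <- ncol(immune_expr)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  # genes x genes correlation via one matrix product on sample-space vectors
  rmat <- suppressWarnings(stats::cor(t(unclass(immune_expr)), t(unclass(lnc_expr))))
  rmat[is.na(rmat)] <- 0 # zero-variance genes can never pass
  stat <- if (use_absolute) abs(rmat) else rmat
  pmat <- matrix(pearson_p(as.vector(rmat), n), nrow(rmat), ncol(rmat))
  pass <- stat > r_min & pmat < p_max
  hits <- which(pass, arr.ind = TRUE)
  correlations <- tibble::tibble(
    immune_gene = rownames(rmat)[hits[, 1]],
    lnc = colnames(rmat)[hits[, 2]],
    r = rmat[hits],
    p = pmat[hits],
    n = n
  ) |>
    dplyr::arrange(.data$lnc, dplyr::desc(.data$r))
  irlnc_ids <- intersect(colnames(rmat), unique(correlations$lnc))
  if (length(irlnc_ids) == 0) {
    warning("no lncRNA passed the co-expression screen", call. = FALSE)
  }
  list(irlnc_ids = irlnc_ids, correlations = correlations)
}
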