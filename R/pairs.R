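#' Binary within-sample comparison of two expression values
#'
#' The pair-feature primitive: 1 if the first lncRNA is expressed strictly
#' above the second in this sample, otherwise 0 (ties fall to 0).
#'
#' @param expr_a,expr_b Finite expression values.
#' @return Integer 0/1 (vectorized over inputs).
#' @export
binarize_pair <- function(expr_a, expr_b) {
  if (any(!is.finite(expr_a)) || any(!is.finite(expr_b))) {
    stop("expression values must be finite", call. = FALSE)
  }
  as.integer(expr_a > expr_b)
}

#' Build the samples-by-pairs 0-1 matrix
#'
#' For every unordered pair of genes \{a, b\} with `a < b` lexicographically,
#' creates a binary column named `"a|b"` holding [binarize_pair()] of the two
#' genes' expression per sample. With `k` genes this yields `choose(k, 2)`
#' columns. Because only the within-sample ordering of the two genes enters,
#' the matrix is invariant under any strictly increasing per-sample
#' transformation of expression.
#'
#' @param expr An [expr_matrix()] restricted to the candidate genes (>= 2).
#' @param samples Optional character vector of sample ids to use (default:
#'   all columns of `expr`); typically the tumor samples with survival data.
#' @return A `pair_matrix`: integer matrix, samples in rows, pair columns,
#'   with a `pairs` attribute tibble (`name`, `lnc_a`, `lnc_b`).
#' @export
build_pair_matrix <- function(expr, samples = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (nrow(expr) < 2) stop("need at least 2 genes to form pairs", call. = FALSE)
  v <- unclass(expr)
  attr(v, "samples") <- NULL
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(v))
    if (length(missing_s) > 0) {
      stop("samples absent from expression matrix: ",
        paste(utils::head(missing_s, 5), collapse = ", "),
        call. = FALSE
      )
    }
    v <- v[, samples, drop = FALSE]
  }
  genes <- sort(rownames(v))
  idx <- utils::combn(length(genes), 2)
  pairs <- tibble::tibble(
    lnc_a = genes[idx[1, ]],
    lnc_b = genes[idx[2, ]]
  ) |>
    dplyr::mutate(name = paste(.data$lnc_a, .data$lnc_b, sep = "|")) |>
    dplyr::select("name", "lnc_a", "lnc_b")
  values <- matrix(0L, ncol(v), nrow(pairs),
    dimnames = list(colnames(v), pairs$name)
  )
  for (j in seq_len(nrow(pairs))) {
    values[, j] <- binarize_pair(v[pairs$lnc_a[j], ], v[pairs$lnc_b[j], ])
  }
  new_pair_matrix(values, pairs)
}

new_pair_matrix <- function(values, pairs) {
  stopifnot(
    is.matrix(values), all(values %in% c(0L, 1L)),
    !anyDuplicated(colnames(values)), identical(colnames(values), pairs$name)
  )
  structure(values,
    pairs = pairs,
    class = c("pair_matrix", "matrix", "array")
  )
}

#' Pair metadata of a pair matrix
#' @param pm A `pair_matrix`.
#' @return Tibble with columns `name`, `lnc_a`, `lnc_b`.
#' @export
pair_info <- function(pm) {
  stopifnot(inherits(pm, "pair_matrix"))
  attr(pm, "pairs")
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat("<pair_matrix> ", nrow(x), " samples x ", ncol(x), " pair features\n",
    sep = ""
  )
  invisible(x)
}

# column-subset a pair_matrix by pair name, keeping metadata in sync
subset_pairs <- function(pm, keep_names) {
  pairs <- pair_info(pm)
  v <- unclass(pm)
  attr(v, "pairs") <- NULL
  v <- v[, keep_names, drop = FALSE]
  new_pair_matrix(v, pairs[match(keep_names, pairs$name), , drop = FALSE])
}

#' Tidy a pair matrix into long form
#' @param x A `pair_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `sample_id`, `pair`, `value`.
#' @export
tidy.pair_matrix <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "pair", values_to = "value")
}

#' Filter pairs to valid matches by ones-fraction
#'
#' A pair is a valid match when the fraction of samples scored 1 lies in
#' `[low, high]` (inclusive). Pairs with near-constant 0/1 profiles carry no
#' prognostic contrast and are removed.
#'
#' @param pm A `pair_matrix`.
#' @param low,high Inclusive ones-fraction bounds (defaults 0.20 / 0.80).
#' @return The filtered `pair_matrix`.
#' @export
filter_valid_pairs <- function(pm, low = 0.20, high = 0.80) {
  stopifnot(inherits(pm, "pair_matrix"), ncol(pm) > 0, low <= high)
  frac <- colMeans(pm)
  keep <- colnames(pm)[frac >= low & frac <= high]
  if (length(keep) == 0) {
    stop("no pair has a ones-fraction in [", low, ", ", high, "]", call. = FALSE)
  }
  subset_pairs(pm, keep)
}
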