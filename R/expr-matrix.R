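#' Construct an expression matrix with cohort and batch labels
#'
#' The central expression container of the package: a genes-by-samples
#' numeric matrix on the log2(count + 1) scale, carrying per-sample cohort
#' (`"normal"` or `"tumor"`) and batch labels. All downstream stages (cohort
#' merging, batch adjustment, biotype partition, co-expression screening,
#' differential expression, pair construction) consume this class.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique, non-empty rownames (gene ids) and colnames (sample ids). All
#'   values must be finite.
#' @param cohort Character vector of per-sample labels, each `"normal"` or
#'   `"tumor"`, recycled if length 1.
#' @param batch Character vector of per-sample batch labels (opaque strings),
#'   recycled if length 1.
#'
#' @return An object of class `expr_matrix`: the value matrix with a
#'   `samples` attribute (tibble with columns `sample_id`, `cohort`,
#'   `batch`).
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'   dimnames = list(c("G1", "G2"), c("S1", "S2", "S3"))
#' )
#' em <- expr_matrix(m, cohort = "tumor", batch = "b1")
#' sample_info(em)
#' @export
expr_matrix <- function(values, cohort, batch = "batch1") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(dimnames(values))) dimnames(values) <- list(NULL, NULL)
  if (is.null(rownames(values))) {
    if (nrow(values) > 0) {
      stop("`values` must have gene rownames", call. = FALSE)
    }
    rownames(values) <- character(0)
  }
  if (is.null(colnames(values))) {
    if (ncol(values) > 0) {
      stop("`values` must have sample colnames", call. = FALSE)
    }
    colnames(values) <- character(0)
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate gene ids: ", paste(utils::head(dup, 5), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    stop("duplicate sample ids: ", paste(utils::head(dup, 5), collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(is.finite(values))) {
    stop("expression values must all be finite", call. = FALSE)
  }
  n <- ncol(values)
  cohort <- as.character(rep_len(cohort, n))
  batch <- as.character(rep_len(batch, n))
  if (!all(cohort %in% c("normal", "tumor"))) {
    stop("cohort labels must be 'normal' or 'tumor'", call. = FALSE)
  }
  structure(
    values,
    samples = tibble::tibble(
      sample_id = colnames(values),
      cohort = cohort,
      batch = batch
    ),
    class = c("expr_matrix", "matrix", "array")
  )
}

#' Per-sample metadata of an expression matrix
#'
#' @param x An `expr_matrix`.
#' @return A tibble with columns `sample_id`, `cohort`, `batch`.
#' @export
sample_info <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  attr(x, "samples")
}

#' @export
print.expr_matrix <- function(x, ...) {
  info <- sample_info(x)
  cat(
    "<expr_matrix> ", nrow(x), " genes x ", ncol(x), " samples (",
    sum(info$cohort == "normal"), " normal / ",
    sum(info$cohort == "tumor"), " tumor; ",
    dplyr::n_distinct(info$batch), " batch(es))\n",
    sep = ""
  )
  invisible(x)
}

# Subset an expr_matrix keeping labels consistent; i = genes, j = samples.
#' @export
`[.expr_matrix` <- function(x, i, j, drop = FALSE) {
  info <- sample_info(x)
  v <- unclass(x)
  attr(v, "samples") <- NULL
  v <- v[i, j, drop = FALSE]
  if (!missing(j)) {
    keep <- match(colnames(v), info$sample_id)
    info <- info[keep, , drop = FALSE]
  }
  expr_matrix(v, cohort = info$cohort, batch = info$batch)
}

#' Tidy an expression matrix into long form
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `cohort`, `batch`,
#'   `expression`.
#' @export
tidy.expr_matrix <- function(x, ...) {
  long <- tibble::as_tibble(unclass(x), rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id",
      names_to = "sample_id", values_to = "expression"
    )
  dplyr::left_join(long, sample_info(x), by = "sample_id") |>
    dplyr::select(
      "gene_id", "sample_id", "cohort", "batch", "expression"
    )
}

# internal: samples of one cohort
cohort_samples <- function(x, which) {
  info <- sample_info(x)
  info$sample_id[info$cohort == which]
}
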