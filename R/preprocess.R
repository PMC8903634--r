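#' Merge expression cohorts by column concatenation
#'
#' Combines several cohorts (e.g. normal and tumor) measured on the same
#' genes into one matrix. Gene order follows the first input; later inputs
#' are realigned by gene id. Cohort and batch labels are preserved.
#'
#' @param matrices List of [expr_matrix()] objects with identical gene sets
#'   (order may differ) and disjoint sample ids.
#' @return A single merged [expr_matrix()].
#' @export
merge_cohorts <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  purrr::walk(matrices, function(m) stopifnot(inherits(m, "expr_matrix")))
  ref_genes <- rownames(matrices[[1]])
  for (m in matrices[-1]) {
    diff_n <- length(union(ref_genes, rownames(m))) -
      length(intersect(ref_genes, rownames(m)))
    if (diff_n > 0) {
      stop("gene sets differ between cohorts (symmetric difference: ",
        diff_n, " genes)",
        call. = FALSE
      )
    }
  }
  aligned <- lapply(matrices, function(m) unclass(m)[ref_genes, , drop = FALSE])
  values <- do.call(cbind, aligned)
  info <- dplyr::bind_rows(lapply(matrices, sample_info))
  if (anyDuplicated(info$sample_id)) {
    stop("sample ids shared between cohorts: ",
      paste(utils::head(unique(
        info$sample_id[duplicated(info$sample_id)]
      ), 5), collapse = ", "),
      call. = FALSE
    )
  }
  expr_matrix(values, cohort = info$cohort, batch = info$batch)
}

#' Location-scale batch adjustment
#'
#' Per gene and per batch, centers and scales expression to remove additive
#' and multiplicative batch effects, then restores the gene's grand mean and
#' pooled standard deviation so the overall location/scale of each gene is
#' unchanged. Batches with fewer than 2 samples are passed through with a
#' warning. This is a deliberately simple location-scale adjustment, not an
#' empirical-Bayes batch model; it fully removes constant per-batch shifts.
#'
#' Tumor/normal status is never used as a covariate, so true cohort signal is
#' only protected when batches are not confounded with cohort; a batch that
#' is more than 95 percent one cohort triggers a confounding warning.
#'
#' @param m An [expr_matrix()] with at least one batch of size >= 2 when
#'   multiple batches are present.
#' @return An [expr_matrix()] of identical dimensions.
#' @export
batch_adjust <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  info <- sample_info(m)
  batches <- split(seq_len(ncol(m)), info$batch)
  if (length(batches) == 1) {
    return(m)
  }
  conf <- vapply(batches, function(idx) {
    max(prop.table(table(info$cohort[idx])))
  }, numeric(1))
  if (any(conf > 0.95 & lengths(batches) > 1)) {
    warning("batch(es) ",
      paste(names(batches)[conf > 0.95 & lengths(batches) > 1], collapse = ", "),
      " are >95% one cohort; batch adjustment may absorb cohort signal",
      call. = FALSE
    )
  }
  small <- lengths(batches) < 2
  if (any(small)) {
    warning("batch(es) with <2 samples passed through unadjusted: ",
      paste(names(batches)[small], collapse = ", "),
      call. = FALSE
    )
  }
  v <- unclass(m)
  attr(v, "samples") <- NULL
  adj <- v
  grand_mean <- rowMeans(v)
  # pooled within-batch sd per gene, (n_b - 1)-weighted
  big <- batches[!small]
  ss <- matrix(0, nrow(v), length(big))
  dfree <- 0
  for (k in seq_along(big)) {
    idx <- big[[k]]
    mu_b <- rowMeans(v[, idx, drop = FALSE])
    ss[, k] <- rowSums((v[, idx, drop = FALSE] - mu_b)^2)
    dfree <- dfree + length(idx) - 1
  }
  pooled_sd <- sqrt(rowSums(ss) / max(dfree, 1))
  for (idx in big) {
    mu_b <- rowMeans(v[, idx, drop = FALSE])
    sd_b <- apply(v[, idx, drop = FALSE], 1, stats::sd)
    z <- sweep(v[, idx, drop = FALSE], 1, mu_b, "-")
    scale_fac <- ifelse(sd_b > 0, pooled_sd / sd_b, 1)
    z <- sweep(z, 1, scale_fac, "*")
    adj[, idx] <- sweep(z, 1, grand_mean, "+")
  }
  expr_matrix(adj, cohort = info$cohort, batch = info$batch)
}

#' Partition an expression matrix into mRNA and lncRNA submatrices
#'
#' Splits genes by annotated biotype class: protein-coding genes go to the
#' mRNA matrix, lncRNA-class genes to the lncRNA matrix; genes annotated
#' `other` or absent from the annotation are excluded (count reported via
#' message).
#'
#' @param m An [expr_matrix()].
#' @param ann Annotation tibble with columns `gene_id`, `biotype` (as from
#'   [read_gtf_annotation()]).
#' @return A named list with elements `mrna` and `lnc`, both [expr_matrix()].
#' @export
partition_by_biotype <- function(m, ann) {
  stopifnot(inherits(m, "expr_matrix"))
  biotype <- ann$biotype[match(rownames(m), ann$gene_id)]
  biotype[is.na(biotype)] <- "other"
  n_excluded <- sum(!biotype %in% c("protein_coding", "lncRNA"))
  if (n_excluded > 0) {
    message(n_excluded, " gene(s) excluded from biotype partition")
  }
  if (!any(biotype == "lncRNA")) {
    stop("no lncRNA-class genes after biotype partition", call. = FALSE)
  }
  list(
    mrna = m[biotype == "protein_coding", ],
    lnc = m[biotype == "lncRNA", ]
  )
}
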