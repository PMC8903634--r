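#' Read a log2-scale expression matrix from TSV
#'
#' Expects a tab-separated file whose header row holds sample ids and whose
#' first column holds gene ids; the body must be numeric. Values are passed
#' through unchanged — the caller asserts they are on the log2(count + 1)
#' scale.
#'
#' @param path Path to the TSV file.
#' @param cohort_label Cohort assigned to every sample in the file
#'   (`"normal"` or `"tumor"`).
#' @param batch_label Batch label assigned to every sample in the file.
#' @return An [expr_matrix()].
#' @export
read_expression_matrix <- function(path, cohort_label, batch_label) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("expression file '", path, "' has no data", call. = FALSE)
  }
  gene_ids <- df[[1]]
  body <- df[-1]
  num <- suppressWarnings(
    vapply(body, as.numeric, numeric(nrow(body)))
  )
  num <- matrix(num, nrow = nrow(body), dimnames = list(gene_ids, names(body)))
  bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(
      "non-numeric expression value at gene '", gene_ids[bad[1, 1]],
      "', sample '", colnames(num)[bad[1, 2]], "'",
      call. = FALSE
    )
  }
  if (anyNA(num)) {
    stop("missing expression values are not allowed", call. = FALSE)
  }
  expr_matrix(num, cohort = cohort_label, batch = batch_label)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: first column `gene_id`, one column
#' per sample. Cohort and batch labels are not stored in the file; they are
#' re-supplied on read.
#'
#' @param x An [expr_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- tibble::as_tibble(unclass(x), rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

# Default GTF biotypes mapped to the lncRNA class.
default_lnc_biotypes <- function() {
  c(
    "lncRNA", "lincRNA", "antisense", "processed_transcript",
    "sense_intronic", "sense_overlapping"
  )
}

#' Read gene annotation from a GTF file
#'
#' Parses gene records of an Ensembl-dialect GTF and assigns each gene a
#' biotype class: `"lncRNA"` if its GTF biotype is in `lnc_biotypes`,
#' `"protein_coding"` for protein-coding genes, `"other"` otherwise. When a
#' record carries both `gene_biotype` and `gene_type` attributes,
#' `gene_biotype` wins.
#'
#' @param path Path to a GTF file (1-based inclusive coordinates).
#' @param lnc_biotypes Character vector of GTF biotypes treated as lncRNA.
#' @return A tibble with columns `gene_id`, `symbol`, `biotype`.
#' @export
read_gtf_annotation <- function(path, lnc_biotypes = default_lnc_biotypes()) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_gtf_annotation() requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  md <- as.data.frame(gr)
  if ("type" %in% names(md)) {
    md <- md[as.character(md$type) == "gene", , drop = FALSE]
  }
  if (nrow(md) == 0 || is.null(md$gene_id)) {
    stop("no gene records parsed from '", path, "'", call. = FALSE)
  }
  raw_biotype <- rep(NA_character_, nrow(md))
  if (!is.null(md$gene_type)) raw_biotype <- as.character(md$gene_type)
  if (!is.null(md$gene_biotype)) {
    gb <- as.character(md$gene_biotype)
    raw_biotype <- ifelse(is.na(gb), raw_biotype, gb)
  }
  symbol <- if (!is.null(md$gene_name)) as.character(md$gene_name) else md$gene_id
  ann <- tibble::tibble(
    gene_id = as.character(md$gene_id),
    symbol = dplyr::coalesce(symbol, .data$gene_id),
    biotype = dplyr::case_when(
      raw_biotype %in% lnc_biotypes ~ "lncRNA",
      raw_biotype %in% "protein_coding" ~ "protein_coding",
      TRUE ~ "other"
    )
  )
  ann <- dplyr::distinct(ann, .data$gene_id, .keep_all = TRUE)
  if (nrow(ann) == 0) stop("no genes parsed from '", path, "'", call. = FALSE)
  ann
}

#' Read a plain-text gene list
#'
#' One gene identifier per line; blank lines and surrounding whitespace are
#' ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of unique gene ids, file order preserved.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x)]
  if (length(x) == 0) stop("gene list '", path, "' is empty", call. = FALSE)
  unique(x)
}

#' Write a plain-text gene list
#' @param genes Character vector of gene ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT semantics: each line is `name<TAB>description<TAB>gene1...`.
#' Duplicate genes within a set are collapsed.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (one per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("GMT file '", path, "' is empty", call. = FALSE)
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop("GMT line with fewer than 3 fields: '",
        substr(ln, 1, 40), "'",
        call. = FALSE
      )
    }
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(
    lines, function(ln) strsplit(ln, "\t", fixed = TRUE)[[1]][1], character(1)
  )
  if (any(lengths(sets) == 0)) stop("GMT contains an empty set", call. = FALSE)
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

clinical_covariate_cols <- c("age", "grade", "stage", "residual", "vital")

#' Read a clinical/survival table from TSV
#'
#' Requires columns `sample_id`, `time` (days, strictly positive) and `event`
#' (0/1). Optional covariates `age`, `grade`, `stage`, `residual`, `vital`
#' may be missing (empty string reads as `NA`). Rows with non-positive
#' follow-up time are dropped with a warning stating the count.
#'
#' @param path Path to the TSV file.
#' @return A tibble (one row per sample) with the columns above.
#' @export
read_clinical_table <- function(path) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), progress = FALSE
  )
  required <- c("sample_id", "time", "event")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("clinical table is missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(df) == 0) stop("clinical table '", path, "' is empty", call. = FALSE)
  out <- tibble::tibble(
    sample_id = df$sample_id,
    time = as.numeric(df$time),
    event = as.integer(df$event)
  )
  for (cv in clinical_covariate_cols) {
    out[[cv]] <- if (cv %in% names(df)) {
      if (cv == "age") as.numeric(df[[cv]]) else df[[cv]]
    } else {
      if (cv == "age") NA_real_ else NA_character_
    }
  }
  if (anyNA(out$time) || anyNA(out$event)) {
    stop("time/event may not be missing", call. = FALSE)
  }
  if (!all(out$event %in% c(0L, 1L))) {
    stop("event must be 0 or 1", call. = FALSE)
  }
  if (anyDuplicated(out$sample_id)) {
    stop("duplicate sample ids in clinical table", call. = FALSE)
  }
  bad <- out$time <= 0
  if (any(bad)) {
    warning(sum(bad), " clinical row(s) with non-positive time dropped",
      call. = FALSE
    )
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Write a clinical/survival table as TSV
#' @param clin Tibble as returned by [read_clinical_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clin, path) {
  readr::write_tsv(clin, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read per-sample drug sensitivity scores from TSV
#'
#' Wide TSV: first column `sample_id`, one column per drug, IC50-like real
#' scores (lower = more sensitive).
#'
#' @param path Path to the TSV file.
#' @return A long tibble with columns `sample_id`, `drug`, `score`.
#' @export
read_drug_scores <- function(path) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  if (!"sample_id" %in% names(df)) {
    stop("drug score table is missing required column: sample_id", call. = FALSE)
  }
  if (ncol(df) < 2 || nrow(df) == 0) {
    stop("drug score table '", path, "' has no scores", call. = FALSE)
  }
  long <- tidyr::pivot_longer(df, -"sample_id",
    names_to = "drug", values_to = "score"
  )
  if (!all(is.finite(long$score))) {
    stop("drug scores must all be finite", call. = FALSE)
  }
  long
}

#' Write per-sample drug sensitivity scores as TSV
#' @param scores Long tibble with columns `sample_id`, `drug`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drug_scores <- function(scores, path) {
  wide <- tidyr::pivot_wider(scores,
    names_from = "drug", values_from = "score"
  )
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

# Minimal Ensembl-dialect GTF writer for synthetic annotation fixtures.
write_gtf_annotation <- function(ann, path) {
  n <- nrow(ann)
  start <- seq_len(n) * 10000L
  lines <- sprintf(
    paste0(
      "chr1\tsynthetic\tgene\t%d\t%d\t.\t+\t.\t",
      "gene_id \"%s\"; gene_name \"%s\"; gene_biotype \"%s\";"
    ),
    start, start + 999L, ann$gene_id, ann$symbol, ann$biotype_gtf
  )
  writeLines(lines, path)
  invisible(path)
}
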