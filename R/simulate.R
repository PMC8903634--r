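#' Synthetic cohort configuration
#'
#' Parameters of the synthetic two-cohort generator. Defaults describe a
#' desk-scale cohort: 60 normal and 300 tumor samples; 500 mRNAs of which
#' 100 are immune genes; 300 lncRNAs of which 40 are planted immune-related
#' (co-expressed with the immune genes through a shared latent factor) and
#' 20 of those are differentially expressed (+3 log2 units in tumor); 5
#' planted prognostic pairs at log-hazard 0.8 each; exponential survival at
#' baseline hazard 1e-4 events/day with uniform censoring over 10 years; two
#' batches with additive offsets 0 and +0.6, interleaved within each cohort
#' so batch is not confounded with tumor status.
#'
#' @param n_normal,n_tumor Sample counts per cohort.
#' @param n_mrna,n_immune,n_lnc Gene counts (immune genes are a subset of
#'   the mRNAs).
#' @param n_irlnc Number of lncRNAs co-expressed with the immune program.
#' @param n_de Number of planted irlncRNAs differentially expressed in
#'   tumor; must be at least `2 * n_planted_pairs`.
#' @param de_shift Tumor-vs-normal shift on DE genes, log2 units.
#' @param n_planted_pairs Number of pairs whose binary indicator drives the
#'   hazard.
#' @param pair_betas Log-hazard per planted pair indicator (recycled to
#'   `n_planted_pairs`).
#' @param baseline_hazard Baseline event rate, events/day.
#' @param censor_max Upper bound of the uniform censoring time, days
#'   (`Inf` disables censoring).
#' @param batch_shifts Named numeric vector of additive per-batch offsets.
#' @param noise_sd Residual standard deviation, log2 units.
#' @param seed Integer seed; the full bundle is deterministic given it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_normal = 60, n_tumor = 300,
                       n_mrna = 500, n_immune = 100, n_lnc = 300,
                       n_irlnc = 40, n_de = 20, de_shift = 3,
                       n_planted_pairs = 5, pair_betas = 0.8,
                       baseline_hazard = 1e-4, censor_max = 3650,
                       batch_shifts = c(batchA = 0, batchB = 0.6),
                       noise_sd = 0.5, seed = 1L) {
  cfg <- list(
    n_normal = n_normal, n_tumor = n_tumor,
    n_mrna = n_mrna, n_immune = n_immune, n_lnc = n_lnc,
    n_irlnc = n_irlnc, n_de = n_de, de_shift = de_shift,
    n_planted_pairs = n_planted_pairs,
    pair_betas = rep_len(pair_betas, n_planted_pairs),
    baseline_hazard = baseline_hazard, censor_max = censor_max,
    batch_shifts = batch_shifts, noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(
    cfg$n_normal, cfg$n_tumor, cfg$n_mrna, cfg$n_immune, cfg$n_lnc,
    cfg$n_irlnc, cfg$n_de, cfg$n_planted_pairs
  )
  if (any(counts <= 0) || any(counts != round(counts))) {
    stop("all counts must be positive integers", call. = FALSE)
  }
  if (cfg$n_immune > cfg$n_mrna) stop("n_immune must be <= n_mrna", call. = FALSE)
  if (cfg$n_de > cfg$n_irlnc || cfg$n_irlnc > cfg$n_lnc) {
    stop("need n_de <= n_irlnc <= n_lnc", call. = FALSE)
  }
  if (2 * cfg$n_planted_pairs > cfg$n_de) {
    stop("need n_de >= 2 * n_planted_pairs (pairs are disjoint DE genes)",
      call. = FALSE
    )
  }
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd <= 0) {
    stop("noise_sd must be > 0", call. = FALSE)
  }
  if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be > 0", call. = FALSE)
  if (!all(is.finite(cfg$pair_betas))) stop("pair_betas must be finite", call. = FALSE)
  if (is.null(names(cfg$batch_shifts)) || length(cfg$batch_shifts) < 1) {
    stop("batch_shifts must be a named vector", call. = FALSE)
  }
  if (abs(cfg$seed) > 2^31 - 100) stop("seed too large", call. = FALSE)
  invisible(cfg)
}

sim_gene_ids <- function(cfg) {
  list(
    mrna = sprintf("MR%04d", seq_len(cfg$n_mrna)),
    lnc = sprintf("LN%04d", seq_len(cfg$n_lnc))
  )
}

#' Simulate the two-cohort expression matrix
#'
#' Generates log2-scale expression for normal and tumor samples with planted
#' structure: a per-sample latent immune factor `f ~ N(0, 1)` loads with
#' unit weight on every immune gene and on each planted immune-related
#' lncRNA (so their population correlation is
#' `1 / (1 + noise_sd^2) > 0.6` at the default noise level); non-planted
#' lncRNAs and non-immune mRNAs are independent noise around gene-specific
#' baselines; `de_shift` is added to the DE lncRNAs in tumor samples only;
#' per-batch offsets are added last. Genes paired in the hazard model share
#' a baseline so their binary comparison is balanced. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `expr` (merged [expr_matrix()]), `annotation`
#'   (tibble `gene_id`, `symbol`, `biotype`, `biotype_gtf`), `immune_genes`
#'   (character vector), and `truth` (list: `irlnc_ids`, `de_ids`,
#'   `planted_pairs` tibble with betas).
#' @export
simulate_expression <- function(config) {
  validate_sim_config(config)
  ids <- sim_gene_ids(config)
  immune <- ids$mrna[seq_len(config$n_immune)]
  irlnc <- ids$lnc[seq_len(config$n_irlnc)]
  de_ids <- irlnc[seq_len(config$n_de)]
  pair_idx <- seq_len(2 * config$n_planted_pairs)
  planted_pairs <- tibble::tibble(
    lnc_a = de_ids[pair_idx[c(TRUE, FALSE)]],
    lnc_b = de_ids[pair_idx[c(FALSE, TRUE)]],
    beta = config$pair_betas
  ) |>
    dplyr::mutate(name = paste(.data$lnc_a, .data$lnc_b, sep = "|")) |>
    dplyr::select("name", "lnc_a", "lnc_b", "beta")

  n <- config$n_normal + config$n_tumor
  genes <- c(ids$mrna, ids$lnc)
  sample_ids <- c(
    sprintf("N%03d", seq_len(config$n_normal)),
    sprintf("T%03d", seq_len(config$n_tumor))
  )
  cohort <- rep(c("normal", "tumor"), c(config$n_normal, config$n_tumor))
  # interleave batches within each cohort: batch never proxies tumor status
  batch_names <- names(config$batch_shifts)
  batch <- unlist(lapply(c(config$n_normal, config$n_tumor), function(k) {
    rep_len(batch_names, k)
  }))

  values <- withr::with_seed(config$seed, {
    mu <- stats::runif(length(genes), 2, 6)
    names(mu) <- genes
    # paired hazard genes share a baseline so their 0/1 comparison is ~50/50
    for (i in seq_len(nrow(planted_pairs))) {
      mu[planted_pairs$lnc_b[i]] <- mu[planted_pairs$lnc_a[i]]
    }
    f <- stats::rnorm(n)
    v <- matrix(stats::rnorm(length(genes) * n, sd = config$noise_sd),
      length(genes), n,
      dimnames = list(genes, sample_ids)
    )
    v <- v + mu
    loaded <- c(immune, irlnc)
    v[loaded, ] <- v[loaded, ] + rep(f, each = length(loaded))
    v[de_ids, cohort == "tumor"] <- v[de_ids, cohort == "tumor"] + config$de_shift
    v + rep(config$batch_shifts[batch], each = length(genes))
  })

  annotation <- tibble::tibble(
    gene_id = genes,
    symbol = genes,
    biotype = rep(c("protein_coding", "lncRNA"), c(config$n_mrna, config$n_lnc)),
    biotype_gtf = rep(c("protein_coding", "lncRNA"), c(config$n_mrna, config$n_lnc))
  )
  list(
    expr = expr_matrix(values, cohort = cohort, batch = batch),
    annotation = annotation,
    immune_genes = immune,
    truth = list(
      irlnc_ids = irlnc,
      de_ids = de_ids,
      planted_pairs = planted_pairs
    )
  )
}

#' Simulate survival driven by planted pair features
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(sum_k beta_k * x_ik)` where `x_ik` are the binary
#' planted-pair values taken from `pair_matrix`; censoring times are uniform
#' on `(0, censor_max)`; observed time is the minimum and the event
#' indicator records which came first. Age is Normal(60, 10) rounded;
#' grade/stage/residual are drawn from fixed frequency tables and vital
#' status mirrors the event indicator. Deterministic given
#' `config$seed + 1`.
#'
#' @param pair_matrix A `pair_matrix` over the modelling samples containing
#'   every planted pair as a column.
#' @param truth The `truth` element of [simulate_expression()].
#' @param config The same [sim_config()].
#' @return A survival tibble (`sample_id`, `time`, `event`, `age`, `grade`,
#'   `stage`, `residual`, `vital`) with the per-sample latent log-hazard in
#'   attribute `latent_risk`.
#' @export
simulate_survival <- function(pair_matrix, truth, config) {
  validate_sim_config(config)
  missing_p <- setdiff(truth$planted_pairs$name, colnames(pair_matrix))
  if (length(missing_p) > 0) {
    stop("planted pair(s) missing from the pair matrix: ",
      paste(missing_p, collapse = ", "),
      call. = FALSE
    )
  }
  x <- unclass(pair_matrix)[, truth$planted_pairs$name, drop = FALSE]
  lp <- as.numeric(x %*% truth$planted_pairs$beta)
  n <- nrow(x)
  out <- withr::with_seed(config$seed + 1L, {
    t_event <- stats::rexp(n, rate = config$baseline_hazard * exp(lp))
    t_cens <- if (is.finite(config$censor_max)) {
      stats::runif(n, 0, config$censor_max)
    } else {
      rep(Inf, n)
    }
    event <- as.integer(t_event <= t_cens)
    tibble::tibble(
      sample_id = rownames(x),
      time = pmin(t_event, t_cens),
      event = event,
      age = pmin(pmax(round(stats::rnorm(n, 60, 10)), 25), 90),
      grade = sample(c("G1", "G2", "G3"), n, TRUE, prob = c(0.1, 0.3, 0.6)),
      stage = sample(c("I", "II", "III", "IV"), n, TRUE,
        prob = c(0.05, 0.10, 0.60, 0.25)
      ),
      residual = sample(c("R0", "R1"), n, TRUE, prob = c(0.4, 0.6)),
      vital = ifelse(event == 1, "Dead", "Alive")
    )
  })
  attr(out, "latent_risk") <- tibble::tibble(
    sample_id = rownames(x), latent_risk = lp
  )
  out
}

#' Write a complete synthetic input bundle to disk
#'
#' Simulates a cohort and writes every file the readers consume: normal and
#' tumor expression TSVs, a GTF annotation, the immune gene list, the
#' clinical table, a drug-score table (two drugs mildly coupled to the
#' latent risk, one pure-noise drug), an immune-cell GMT (three disjoint
#' 20-gene sets drawn from the immune genes), plus the ground truth as JSON.
#' Byte-identical across runs with the same config.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of the file paths written.
#' @export
generate_fixture_bundle <- function(config, out_dir) {
  validate_sim_config(config)
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory '", out_dir, "'", call. = FALSE)
  sim <- simulate_expression(config)
  info <- sample_info(sim$expr)
  paths <- c(
    expr_normal = file.path(out_dir, "expr_normal.tsv"),
    expr_tumor = file.path(out_dir, "expr_tumor.tsv"),
    annotation = file.path(out_dir, "annotation.gtf"),
    immune_genes = file.path(out_dir, "immune_genes.txt"),
    clinical = file.path(out_dir, "clinical.tsv"),
    drug_scores = file.path(out_dir, "drug_scores.tsv"),
    immune_sets = file.path(out_dir, "immune_sets.gmt"),
    truth = file.path(out_dir, "ground_truth.json")
  )
  write_expression_matrix(
    sim$expr[, info$sample_id[info$cohort == "normal"]], paths[["expr_normal"]]
  )
  tumor_ids <- info$sample_id[info$cohort == "tumor"]
  write_expression_matrix(sim$expr[, tumor_ids], paths[["expr_tumor"]])
  write_gtf_annotation(sim$annotation, paths[["annotation"]])
  write_gene_list(sim$immune_genes, paths[["immune_genes"]])

  pm <- build_pair_matrix(
    sim$expr[sim$truth$de_ids, ],
    samples = tumor_ids
  )
  surv <- simulate_survival(pm, sim$truth, config)
  write_clinical_table(surv, paths[["clinical"]])

  lp <- attr(surv, "latent_risk")$latent_risk
  drugs <- withr::with_seed(config$seed + 2L, {
    tibble::tibble(
      sample_id = rep(tumor_ids, 3),
      drug = rep(c("Cisplatin", "Paclitaxel", "ControlDrug"), each = length(tumor_ids)),
      score = c(
        2 + 0.3 * lp + stats::rnorm(length(lp), sd = 0.5),
        3 + 0.3 * lp + stats::rnorm(length(lp), sd = 0.5),
        4 + stats::rnorm(length(lp), sd = 0.5)
      )
    )
  })
  write_drug_scores(drugs, paths[["drug_scores"]])

  set_size <- min(20, config$n_immune %/% 3)
  if (set_size < 1) stop("too few immune genes for gene sets", call. = FALSE)
  sets <- list(
    Tcell = sim$immune_genes[seq_len(set_size)],
    Bcell = sim$immune_genes[set_size + seq_len(set_size)],
    NKcell = sim$immune_genes[2 * set_size + seq_len(set_size)]
  )
  write_gmt(sets, paths[["immune_sets"]])

  jsonlite::write_json(
    list(
      irlnc_ids = sim$truth$irlnc_ids,
      de_ids = sim$truth$de_ids,
      planted_pairs = sim$truth$planted_pairs,
      latent_risk = attr(surv, "latent_risk")
    ),
    paths[["truth"]],
    digits = NA
  )
  paths
}
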