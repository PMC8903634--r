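#' Default pipeline configuration
#'
#' Assembles the full configuration of [run_pipeline()]: either simulated
#' inputs (the default) or paths to on-disk inputs, the screening and model
#' thresholds (correlation screen r > 0.4 at p < 0.001, |log2FC| > 2 at
#' FDR < 0.05, valid-match ones-fraction between 0.20 and 0.80, univariate screen
#' p < 0.05, 10-fold CV, horizons 365/1095/1825 days), and the top-level
#' seed from which every stage's randomness is derived (simulation uses the
#' seed itself, survival seed + 1, drug scores seed + 2, CV folds seed + 3).
#'
#' @param out_dir Directory where stage artifacts and the manifest are
#'   written.
#' @param seed Integer top-level seed.
#' @param simulate If `TRUE`, inputs come from [sim_config()]; otherwise
#'   `inputs` must name the files.
#' @param sim Optional [sim_config()] (defaults to `sim_config(seed = seed)`).
#' @param inputs Named list of file paths (`expr_normal`, `expr_tumor`,
#'   `annotation`, `immune_genes`, `clinical`, optional `drug_scores`,
#'   `immune_sets`) used when `simulate = FALSE`.
#' @param corr_min,corr_p,use_absolute Co-expression screen parameters.
#' @param log2fc,fdr Differential-expression thresholds.
#' @param valid_low,valid_high Valid-match ones-fraction bounds.
#' @param screen_p Univariate Cox screen threshold.
#' @param folds Cross-validation folds for the lasso.
#' @param horizons Candidate ROC horizons, days.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = TRUE,
                            sim = NULL, inputs = NULL,
                            corr_min = 0.4, corr_p = 0.001, use_absolute = FALSE,
                            log2fc = 2, fdr = 0.05,
                            valid_low = 0.2, valid_high = 0.8,
                            screen_p = 0.05, folds = 10,
                            horizons = c(365, 1095, 1825)) {
  if (valid_low > valid_high) {
    stop("valid_low must be <= valid_high", call. = FALSE)
  }
  if (corr_min < 0 || corr_p <= 0 || log2fc < 0 || fdr <= 0 || screen_p <= 0) {
    stop("thresholds out of range", call. = FALSE)
  }
  if (simulate && is.null(sim)) sim <- sim_config(seed = seed)
  if (!simulate && is.null(inputs)) {
    stop("`inputs` must be supplied when simulate = FALSE", call. = FALSE)
  }
  structure(
    list(
      out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
      sim = sim, inputs = inputs,
      corr_min = corr_min, corr_p = corr_p, use_absolute = use_absolute,
      log2fc = log2fc, fdr = fdr,
      valid_low = valid_low, valid_high = valid_high,
      screen_p = screen_p, folds = folds, horizons = horizons
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Flat keys mirroring the arguments of [pipeline_config()]; `sim` may be a
#' nested mapping of [sim_config()] arguments and `inputs` a mapping of file
#' paths.
#'
#' @param path Path to the YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$horizons)) y$horizons <- as.numeric(y$horizons)
  do.call(pipeline_config, y)
}

# stage wrapper: on failure, halt naming the stage; on success, log rows
run_stage <- function(manifest, name, fun) {
  res <- tryCatch(fun(), error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
      call. = FALSE
    )
  })
  manifest$stages[[name]] <- res$count
  manifest$order <- c(manifest$order, name)
  list(manifest = manifest, value = res$value)
}

#' Run the full pair-signature pipeline
#'
#' Executes every stage end-to-end: simulate or read inputs, merge cohorts,
#' batch-adjust, partition by biotype, screen immune-related lncRNAs,
#' differential expression, pair construction and valid-match filtering on
#' the tumor samples with survival data, univariate Cox screen, lasso Cox
#' signature, risk scoring, ROC horizon selection, Youden cutoff, risk-group
#' assignment, and downstream evaluation (log-rank, multivariate Cox with
#' age/grade/stage/residual, drug-score and immune-enrichment contrasts
#' when those inputs exist). Stage outputs are persisted under
#' `config$out_dir` and a manifest records the config hash, seed and
#' per-stage counts; reruns with the same config are byte-identical.
#'
#' @param config A `pipeline_config` or path to its YAML form.
#' @return A list of the pipeline results (`irlnc`, `de`, `model`, `scores`,
#'   `stratification`, `logrank`, `cox`, `contrasts`, `manifest`,
#'   `manifest_path`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory '", out_dir, "'", call. = FALSE)
  }
  hashable <- config[setdiff(names(config), "out_dir")]
  manifest <- list(
    config_hash = rlang::hash(hashable),
    seed = config$seed, stages = list(), order = character()
  )

  # --- inputs -------------------------------------------------------------
  if (config$simulate) {
    st <- run_stage(manifest, "simulate", function() {
      sim <- simulate_expression(config$sim)
      list(value = sim, count = c(
        genes = nrow(sim$expr), samples = ncol(sim$expr)
      ))
    })
    manifest <- st$manifest
    sim <- st$value
    expr <- sim$expr
    annotation <- sim$annotation
    immune_genes <- sim$immune_genes
    truth <- sim$truth
    clin <- NULL # survival simulated after pair construction
    drug_scores <- NULL
    immune_sets <- NULL
  } else {
    st <- run_stage(manifest, "read", function() {
      inp <- config$inputs
      mats <- list(
        read_expression_matrix(inp$expr_normal, "normal", "normal_batch"),
        read_expression_matrix(inp$expr_tumor, "tumor", "tumor_batch")
      )
      list(
        value = list(
          mats = mats,
          annotation = read_gtf_annotation(inp$annotation),
          immune_genes = read_gene_list(inp$immune_genes),
          clin = read_clinical_table(inp$clinical),
          drug_scores = if (!is.null(inp$drug_scores)) {
            read_drug_scores(inp$drug_scores)
          },
          immune_sets = if (!is.null(inp$immune_sets)) {
            read_gmt(inp$immune_sets)
          }
        ),
        count = c(files = length(unlist(inp)))
      )
    })
    manifest <- st$manifest
    expr <- merge_cohorts(st$value$mats)
    annotation <- st$value$annotation
    immune_genes <- st$value$immune_genes
    clin <- st$value$clin
    drug_scores <- st$value$drug_scores
    immune_sets <- st$value$immune_sets
    truth <- NULL
  }

  # --- preprocess ---------------------------------------------------------
  st <- run_stage(manifest, "batch_adjust", function() {
    adj <- batch_adjust(expr)
    list(value = adj, count = c(genes = nrow(adj), samples = ncol(adj)))
  })
  manifest <- st$manifest
  expr <- st$value

  st <- run_stage(manifest, "partition", function() {
    parts <- partition_by_biotype(expr, annotation)
    list(value = parts, count = c(
      mrna = nrow(parts$mrna), lnc = nrow(parts$lnc)
    ))
  })
  manifest <- st$manifest
  parts <- st$value

  # --- irlncRNA screen ----------------------------------------------------
  st <- run_stage(manifest, "irlnc_screen", function() {
    imm <- intersect(immune_genes, rownames(parts$mrna))
    if (length(imm) == 0) stop("no immune genes present in the mRNA matrix")
    res <- extract_irlnc(parts$mrna[imm, ], parts$lnc,
      r_min = config$corr_min, p_max = config$corr_p,
      use_absolute = config$use_absolute
    )
    readr::write_tsv(res$correlations, file.path(out_dir, "correlations.tsv"),
      progress = FALSE
    )
    list(value = res, count = c(irlnc = length(res$irlnc_ids)))
  })
  manifest <- st$manifest
  irlnc <- st$value

  # --- differential expression --------------------------------------------
  st <- run_stage(manifest, "diffexpr", function() {
    de <- de_irlnc(parts$lnc[irlnc$irlnc_ids, ])
    sel <- select_de_irlnc(de, fc_min = config$log2fc, fdr_max = config$fdr)
    readr::write_tsv(de, file.path(out_dir, "de_table.tsv"), progress = FALSE)
    list(
      value = list(table = de, selected = sel),
      count = c(
        tested = nrow(de), de = nrow(sel),
        up = sum(sel$direction == "up"), down = sum(sel$direction == "down")
      )
    )
  })
  manifest <- st$manifest
  de <- st$value

  # --- pair features ------------------------------------------------------
  tumor_ids <- cohort_samples(expr, "tumor")
  st <- run_stage(manifest, "pairs", function() {
    pm_all <- build_pair_matrix(parts$lnc[de$selected$gene_id, ],
      samples = tumor_ids
    )
    if (config$simulate) {
      clin <<- simulate_survival(pm_all, truth, config$sim)
      lp <- attr(clin, "latent_risk")$latent_risk
      drug_scores <<- withr::with_seed(config$seed + 2L, tibble::tibble(
        sample_id = rep(tumor_ids, 3),
        drug = rep(c("Cisplatin", "Paclitaxel", "ControlDrug"),
          each = length(tumor_ids)
        ),
        score = c(
          2 + 0.3 * lp + stats::rnorm(length(lp), sd = 0.5),
          3 + 0.3 * lp + stats::rnorm(length(lp), sd = 0.5),
          4 + stats::rnorm(length(lp), sd = 0.5)
        )
      ))
      set_size <- min(20, config$sim$n_immune %/% 3)
      immune_sets <<- list(
        Tcell = immune_genes[seq_len(set_size)],
        Bcell = immune_genes[set_size + seq_len(set_size)],
        NKcell = immune_genes[2 * set_size + seq_len(set_size)]
      )
      write_clinical_table(clin, file.path(out_dir, "clinical.tsv"))
    }
    modelled <- intersect(rownames(pm_all), clin$sample_id)
    pm_all <- build_pair_matrix(parts$lnc[de$selected$gene_id, ],
      samples = modelled
    )
    pm <- filter_valid_pairs(pm_all, config$valid_low, config$valid_high)
    list(value = pm, count = c(candidates = ncol(pm_all), valid = ncol(pm)))
  })
  manifest <- st$manifest
  pm <- st$value

  # --- signature ----------------------------------------------------------
  st <- run_stage(manifest, "signature", function() {
    screened <- screen_pairs(pm, clin, p_max = config$screen_p)
    model <- fit_lasso_cox(screened, clin,
      k_folds = config$folds, seed = config$seed + 3L
    )
    jsonlite::write_json(
      list(
        pairs = model$pairs, lambda = model$lambda,
        cv = model$cv[c("folds", "seed", "rule")]
      ),
      file.path(out_dir, "signature.json"),
      digits = NA, auto_unbox = TRUE
    )
    list(
      value = list(screened = screened, model = model),
      count = c(screened = ncol(screened), signature = nrow(model$pairs))
    )
  })
  manifest <- st$manifest
  model <- st$value$model

  # --- stratification -----------------------------------------------------
  st <- run_stage(manifest, "stratify", function() {
    scores <- compute_risk_score(model, pm)
    readr::write_tsv(scores, file.path(out_dir, "risk_scores.tsv"),
      progress = FALSE
    )
    sel <- select_horizon(scores, clin, horizons = config$horizons)
    readr::write_tsv(sel$roc$curve,
      file.path(out_dir, sprintf("roc_%dd.tsv", sel$horizon)),
      progress = FALSE
    )
    cutoff <- youden_cutoff(sel$roc)
    strat <- assign_groups(scores, cutoff, horizon = sel$horizon)
    readr::write_tsv(tibble::as_tibble(strat),
      file.path(out_dir, "stratification.tsv"),
      progress = FALSE
    )
    list(
      value = list(scores = scores, sel = sel, strat = strat),
      count = c(
        horizon = sel$horizon,
        auc_x1000 = round(1000 * sel$roc$auc),
        high = sum(strat$group == "high"), low = sum(strat$group == "low")
      )
    )
  })
  manifest <- st$manifest
  strat <- st$value$strat
  scores <- st$value$scores
  sel <- st$value$sel

  # --- evaluation ---------------------------------------------------------
  st <- run_stage(manifest, "evaluate", function() {
    lr <- logrank_test(strat, clin)
    covs <- dplyr::inner_join(scores, clin, by = "sample_id") |>
      dplyr::transmute(
        sample_id = .data$sample_id,
        risk_score = .data$risk_score,
        age = .data$age,
        grade_ord = as.integer(factor(.data$grade, c("G1", "G2", "G3"))),
        stage_ord = as.integer(factor(.data$stage, c("I", "II", "III", "IV"))),
        residual_r1 = as.integer(.data$residual == "R1")
      )
    cox <- multivariate_cox(clin, covs)
    readr::write_tsv(cox, file.path(out_dir, "multivariate_cox.tsv"),
      progress = FALSE
    )
    contrasts <- list()
    if (!is.null(drug_scores)) {
      contrasts$drugs <- compare_by_group(
        dplyr::rename(drug_scores, variable = "drug", value = "score"), strat
      )
      readr::write_tsv(contrasts$drugs,
        file.path(out_dir, "drug_contrasts.tsv"),
        progress = FALSE
      )
    }
    if (!is.null(immune_sets)) {
      tumor_expr <- expr[, intersect(tumor_ids, clin$sample_id)]
      enr <- ssgsea_scores(tumor_expr, immune_sets)
      contrasts$immune <- compare_by_group(
        dplyr::rename(enr, variable = "set", value = "score"), strat
      )
      readr::write_tsv(contrasts$immune,
        file.path(out_dir, "immune_contrasts.tsv"),
        progress = FALSE
      )
    }
    lr_out <- dplyr::mutate(lr, stars = significance_stars(.data$p))
    readr::write_tsv(lr_out, file.path(out_dir, "logrank.tsv"), progress = FALSE)
    list(
      value = list(logrank = lr, cox = cox, contrasts = contrasts),
      count = c(
        logrank_p_neglog10 = round(-log10(max(lr$p, 1e-300)), 2),
        cox_terms = nrow(cox)
      )
    )
  })
  manifest <- st$manifest
  evalres <- st$value

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  list(
    irlnc = irlnc, de = de, pair_matrix = pm, model = model,
    scores = scores, horizon = sel, stratification = strat,
    logrank = evalres$logrank, cox = evalres$cox,
    contrasts = evalres$contrasts, truth = truth,
    manifest = manifest, manifest_path = manifest_path
  )
}
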