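test_that("config invariants are enforced before sampling", {
  expect_error(sim_config(n_immune = 600, n_mrna = 500), "n_immune")
  expect_error(sim_config(n_de = 50, n_irlnc = 40), "n_de")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(n_planted_pairs = 15, n_de = 20), "planted_pairs")
})

test_that("expression simulation is deterministic given the seed", {
  a <- simulate_expression(tiny_config(seed = 5L))
  b <- simulate_expression(tiny_config(seed = 5L))
  expect_identical(unclass(a$expr), unclass(b$expr))
  c <- simulate_expression(tiny_config(seed = 6L))
  expect_false(identical(unclass(a$expr), unclass(c$expr)))
})

test_that("planted co-expression approaches 1 in the noiseless limit", {
  sim <- simulate_expression(tiny_config(seed = 3L, noise_sd = 1e-6))
  v <- unclass(sim$expr)
  # non-DE planted irlncRNA vs an immune gene: shared factor, no DE variance
  non_de <- setdiff(sim$truth$irlnc_ids, sim$truth$de_ids)[1]
  r <- cor(v[sim$immune_genes[1], ], v[non_de, ])
  expect_gt(r, 0.999999)
})

test_that("planted tumor-normal shift is recovered at large n", {
  cfg <- sim_config(
    n_normal = 200, n_tumor = 200, n_mrna = 20, n_immune = 10,
    n_lnc = 20, n_irlnc = 6, n_de = 4, n_planted_pairs = 2,
    de_shift = 3, noise_sd = 0.5, seed = 9L
  )
  sim <- simulate_expression(cfg)
  v <- unclass(sim$expr)
  info <- sample_info(sim$expr)
  diffs <- rowMeans(v[sim$truth$de_ids, info$cohort == "tumor"]) -
    rowMeans(v[sim$truth$de_ids, info$cohort == "normal"])
  expect_true(all(abs(diffs - 3) < 0.2))
})

test_that("survival generator honors censoring and the null case", {
  sim <- simulate_expression(mid_config(seed = 31L))
  pm <- build_pair_matrix(
    sim$expr[sim$truth$de_ids, ],
    samples = cohort_samples(sim$expr, "tumor")
  )
  # no censoring limit: every subject has an event
  cfg_inf <- mid_config(seed = 31L, censor_max = Inf)
  surv_inf <- simulate_survival(pm, sim$truth, cfg_inf)
  expect_equal(mean(surv_inf$event), 1)

  # all-zero betas: survival is unrelated to any later grouping
  truth0 <- sim$truth
  truth0$planted_pairs$beta <- 0
  surv0 <- simulate_survival(pm, truth0, mid_config(seed = 31L))
  half <- tibble::tibble(
    sample_id = surv0$sample_id,
    risk_score = 0,
    group = factor(rep(c("low", "high"), length.out = nrow(surv0)),
      levels = c("low", "high")
    )
  )
  lr <- logrank_test(half, surv0)
  expect_lt(lr$statistic, 8) # ~chi-square(1) under the null
  expect_gt(lr$p, 0.001)

  # planted pair missing from matrix
  pm_missing <- build_pair_matrix(
    sim$expr[sim$truth$de_ids[-(1:2)], ],
    samples = rownames(pm)
  )
  expect_error(
    simulate_survival(pm_missing, sim$truth, mid_config(seed = 31L)),
    "missing"
  )
})

test_that("univariate Cox refits recover the planted pair log-hazards", {
  cfg <- sim_config(
    n_normal = 20, n_tumor = 400, n_mrna = 20, n_immune = 10,
    n_lnc = 20, n_irlnc = 6, n_de = 4, n_planted_pairs = 2,
    pair_betas = 0.8, seed = 41L
  )
  sim <- simulate_expression(cfg)
  pm <- build_pair_matrix(
    sim$expr[sim$truth$de_ids, ],
    samples = cohort_samples(sim$expr, "tumor")
  )
  surv <- simulate_survival(pm, sim$truth, cfg)
  for (pr in sim$truth$planted_pairs$name) {
    fit <- univariate_cox(pm[, pr], surv)
    expect_lt(abs(fit$beta - 0.8), 0.25)
  }
})

test_that("fixture bundles are complete, readable and byte-deterministic", {
  cfg <- tiny_config(seed = 13L)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- generate_fixture_bundle(cfg, dir1)
  p2 <- generate_fixture_bundle(cfg, dir2)
  expect_length(p1, 8)
  expect_true(all(file.exists(p1)))
  for (nm in names(p1)) {
    expect_identical(readBin(p1[[nm]], "raw", file.size(p1[[nm]])),
      readBin(p2[[nm]], "raw", file.size(p2[[nm]])),
      label = paste("bundle file", nm)
    )
  }
  # every file round-trips through its reader
  em <- read_expression_matrix(p1[["expr_tumor"]], "tumor", "b")
  expect_equal(ncol(em), cfg$n_tumor)
  skip_if_not_installed("rtracklayer")
  ann <- read_gtf_annotation(p1[["annotation"]])
  expect_equal(nrow(ann), cfg$n_mrna + cfg$n_lnc)
  expect_equal(sum(ann$biotype == "lncRNA"), cfg$n_lnc)
  expect_length(read_gene_list(p1[["immune_genes"]]), cfg$n_immune)
  clin <- read_clinical_table(p1[["clinical"]])
  expect_equal(nrow(clin), cfg$n_tumor)
  expect_s3_class(read_drug_scores(p1[["drug_scores"]]), "tbl_df")
  expect_length(read_gmt(p1[["immune_sets"]]), 3)

  # different seed changes the expression files
  p3 <- generate_fixture_bundle(tiny_config(seed = 14L), withr::local_tempdir())
  expect_false(identical(
    readLines(p1[["expr_tumor"]]), readLines(p3[["expr_tumor"]])
  ))
})

test_that("planted irlncRNAs pass the screen and decoys do not", {
  sim <- default_sim()
  parts <- partition_by_biotype(sim$expr, sim$annotation)
  res <- extract_irlnc(parts$mrna[sim$immune_genes, ], parts$lnc)
  truth <- sim$truth$irlnc_ids
  recall <- mean(truth %in% res$irlnc_ids)
  decoys <- setdiff(rownames(parts$lnc), truth)
  fp <- mean(decoys %in% res$irlnc_ids)
  expect_gte(recall, 0.9)
  expect_lte(fp, 0.05)
})
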