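test_that("identical configuration and seed reproduce the study exactly", {
  cfg <- tiny_config(seed = 11)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$proteome, s2$proteome)
  expect_identical(s1$ntpm, s2$ntpm)
  expect_identical(s1$donor_samples, s2$donor_samples)
  expect_identical(s1$genesets, s2$genesets)
  expect_identical(s1$truth$genes, s2$truth$genes)
})

test_that("configuration validation rejects bad inputs", {
  expect_error(sim_config(n_subjects = 0), "positive integer")
  expect_error(sim_config(n_proteins = -5), "positive integer")
  expect_error(sim_config(voxel_size_mm = 0), "voxel_size_mm")
  expect_error(sim_config(n_true_pos = 300, n_true_neg = 300,
                          n_proteins = 500), "exceeds")
  expect_error(sim_config(protein_noise_sd = -1), "noise scales")
  expect_error(sim_config(seed = 2^31), "seed")
})

test_that("default planted effect is three times the detectable slope", {
  cfg <- sim_config()
  expect_equal(cfg$effect_size_sd, 3 * (qnorm(0.975) + qnorm(0.8)) / sqrt(85))
})

test_that("zero measurement noise makes regional MWF proportional to the planted gradient", {
  cfg <- zero_noise(tiny_config(seed = 4))
  truth <- simulate_truth(cfg)
  cohort <- simulate_cohort(cfg, truth)
  myelin <- truth$region_myelin
  for (i in c(1, 17, 40)) {
    vals <- sapply(names(myelin), function(r)
      cohort[[paste0("mwf_region_", r)]][i])
    ratio <- vals / myelin[names(myelin)]
    expect_equal(diff(range(ratio)), 0, tolerance = 1e-12)
  }
})

test_that("sample mean age is within 3 standard errors of the uniform[22,94] mean", {
  cfg <- sim_config(seed = 2)
  cohort <- simulate_cohort(cfg)
  mu <- (22 + 94) / 2
  se <- (94 - 22) / sqrt(12) / sqrt(nrow(cohort))
  expect_lt(abs(mean(cohort$age_protein) - mu), 3 * se)
  expect_true(all(cohort$age_protein >= 22 & cohort$age_protein <= 94))
})

test_that("cohort support constraints hold across seeds", {
  for (seed in 1:10) {
    cohort <- simulate_cohort(tiny_config(seed = seed))
    expect_true(all(cohort$egfr > 0))
    expect_true(all(cohort$mwf_global > 0 & cohort$mwf_global < 1))
    expect_true(all(cohort$sex %in% c(0, 1)))
  }
})

test_that("planted positive effects give log2 abundance tracking MWF after covariate adjustment", {
  cfg <- zero_noise(tiny_config(seed = 9))
  truth <- simulate_truth(cfg)
  cohort <- simulate_cohort(cfg, truth)
  prot <- simulate_proteome(cfg, cohort, truth)
  pos_gene <- truth$genes$gene_symbol[truth$genes$true_beta > 0][1]
  row <- prot[prot$gene_symbol == pos_gene, ][1, ]
  x <- log2(as.numeric(row[cohort$subject_id]))
  covars <- cbind(1, cohort$age_protein, cohort$sex, cohort$egfr)
  rx <- residuals(lm.fit(covars, x))
  ry <- residuals(lm.fit(covars, cohort$mwf_global))
  expect_equal(cor(rx, ry, method = "spearman"), 1)
  expect_true(all(as.matrix(prot[, cohort$subject_id]) > 0))
})

test_that("proteome generation rejects a mismatched cohort", {
  cfg <- tiny_config(seed = 1)
  truth <- simulate_truth(cfg)
  cohort <- simulate_cohort(cfg, truth)
  expect_error(simulate_proteome(cfg, cohort[1:10, ], truth), "n_subjects")
})

test_that("nTPM values are non-negative for every seed and boosted types exceed z = 2", {
  hits <- 0L; total <- 0L
  for (seed in 1:25) {
    cfg <- tiny_config(seed = seed, frac_specific = 0.3)
    truth <- simulate_truth(cfg)
    ntpm <- simulate_ntpm(cfg, truth)
    m <- as.matrix(ntpm[, -1])
    expect_true(all(m >= 0))
    single <- truth$genes$gene_symbol[truth$genes$planted_category == "single"]
    for (g in single) {
      z <- geometric_zscores(m[ntpm$gene_symbol == g, ])
      total <- total + 1L
      if (z[truth$enriched_cells[[g]]] >= 2) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("a gene with no planted enrichment and zero scatter is flat across cell types", {
  cfg <- zero_noise(tiny_config(seed = 3))
  truth <- simulate_truth(cfg)
  ntpm <- simulate_ntpm(cfg, truth)
  flat <- truth$genes$gene_symbol[truth$genes$planted_category == "none"][1]
  vals <- as.numeric(ntpm[ntpm$gene_symbol == flat, -1])
  expect_equal(diff(range(vals)), 0)
})

test_that("gene-set construction rejects empty sets and round-trips through GMT", {
  expect_error(gene_set_library(list(a = character(0))), "non-empty")
  expect_error(gene_set_library(list()), "uniquely named")
  cfg <- tiny_config(seed = 5)
  lib <- simulate_genesets(cfg, simulate_truth(cfg))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(lib, path)
  lib2 <- read_gmt(path)
  expect_identical(lib$sets, lib2$sets)
})

test_that("zero jitter and zero probe noise put samples at labeled voxel centers with affinely related probes", {
  cfg <- zero_noise(tiny_config(seed = 6))
  truth <- simulate_truth(cfg)
  vol <- simulate_label_volume(cfg)
  regions <- region_table(cfg)
  donors <- simulate_donors(cfg, truth, vol, regions)
  assigned <- assign_samples(donors$samples, vol, regions)
  expect_true(all(!is.na(assigned$region_id)))
  expect_true(all(assigned$dist_mm == 0))
  expect_identical(as.integer(assigned$region_id),
                   as.integer(assigned$region_planted))
  # with no noise, any two probes of a gene differ only by gain and offset
  p1 <- donors$samples$MBP_p1
  p2 <- donors$samples$MBP_p2
  expect_equal(abs(cor(p1, p2)), 1, tolerance = 1e-12)
})

test_that("a single-donor sample set is valid but leaves stability undefined", {
  cfg <- zero_noise(tiny_config(seed = 8, n_donors = 1))
  truth <- simulate_truth(cfg)
  vol <- simulate_label_volume(cfg)
  regions <- region_table(cfg)
  donors <- simulate_donors(cfg, truth, vol, regions)
  expect_equal(length(unique(donors$samples$donor_id)), 1L)
  assigned <- assign_samples(donors$samples, vol, regions)
  profiles <- regional_profiles(assigned, "MBP_p1")
  profiles$probe_id <- "MBP_p1"
  expect_error(differential_stability(profiles), "at least 2 donors")
})

test_that("planted white-matter regions always exceed planted deep-gray regions", {
  for (seed in 1:10) {
    cfg <- tiny_config(seed = seed)
    truth <- simulate_truth(cfg)
    regions <- region_table(cfg)
    wm <- truth$region_myelin[as.character(
      regions$region_id[regions$tissue_class == "white_matter"])]
    dgm <- truth$region_myelin[as.character(
      regions$region_id[regions$tissue_class == "deep_gray"])]
    expect_gt(min(wm), max(dgm))
  }
})
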