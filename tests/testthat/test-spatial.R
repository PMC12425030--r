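# small handmade volume: two labeled boxes in a 10^3 grid of 2 mm voxels
toy_volume <- function() {
  labels <- array(0L, c(10, 10, 10))
  labels[2:3, 2:3, 2:3] <- 1L
  labels[7:8, 7:8, 7:8] <- 2L
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- -9
  label_volume(labels, aff)
}
toy_regions <- data.frame(region_id = 1:2, name = c("wm", "dgm"),
                          tissue_class = c("white_matter", "deep_gray"))

center_of <- function(vol, i, j, k)
  drop(vol$affine %*% c(i - 1, j - 1, k - 1, 1))[1:3]

samples_at <- function(xyz) {
  xyz <- matrix(xyz, ncol = 3)
  data.frame(donor_id = "D1",
             sample_id = sprintf("s%d", seq_len(nrow(xyz))),
             mni_x = xyz[, 1], mni_y = xyz[, 2], mni_z = xyz[, 3])
}

test_that("a sample at a labeled voxel center is assigned to that region", {
  vol <- toy_volume()
  s <- samples_at(rbind(center_of(vol, 2, 2, 2), center_of(vol, 7, 8, 7)))
  a <- assign_samples(s, vol, toy_regions)
  expect_identical(a$region_id, c(1L, 2L))
  expect_identical(a$dist_mm, c(0, 0))
})

test_that("samples just inside and just outside the distance tolerance split correctly", {
  vol <- toy_volume()
  edge <- center_of(vol, 3, 2, 2)  # boundary voxel of region 1
  near <- edge + c(1 + 1.9, 0, 0)   # 1.9 mm beyond the voxel boundary zone
  # place along +x: voxel half-width is 1 mm, so in-voxel test fails beyond
  # 1 mm; center distance is 2.9 mm -> unassigned at the default tolerance
  a_near <- assign_samples(samples_at(edge + c(1.9, 0, 0)), vol, toy_regions)
  expect_identical(a_near$region_id, 1L)
  expect_equal(a_near$dist_mm, 1.9, tolerance = 1e-9)
  a_far <- assign_samples(samples_at(edge + c(2.6, 0, 0)), vol, toy_regions)
  expect_true(is.na(a_far$region_id))
  expect_true(is.na(assign_samples(samples_at(near), vol,
                                   toy_regions)$region_id))
})

test_that("assignment equals the brute-force exhaustive oracle on random samples", {
  vol <- toy_volume()
  set.seed(55)
  xyz <- cbind(runif(120, -10, 10), runif(120, -10, 10), runif(120, -10, 10))
  # add guaranteed in-voxel and borderline cases
  xyz <- rbind(xyz, center_of(vol, 2, 3, 2), center_of(vol, 8, 7, 8) + 0.4,
               center_of(vol, 3, 3, 3) + c(2.9, 0, 0))
  s <- samples_at(xyz)
  a <- assign_samples(s, vol, toy_regions)
  expect_identical(a$region_id, assign_oracle(s, vol))
})

test_that("growing the tolerance never unassigns or flips an in-voxel assignment", {
  vol <- toy_volume()
  set.seed(56)
  s <- samples_at(cbind(runif(80, -10, 10), runif(80, -10, 10),
                        runif(80, -10, 10)))
  a0 <- assign_samples(s, vol, toy_regions, max_dist_mm = 0)
  a2 <- assign_samples(s, vol, toy_regions, max_dist_mm = 2)
  a9 <- assign_samples(s, vol, toy_regions, max_dist_mm = 9)
  expect_true(all(a0$dist_mm[!is.na(a0$region_id)] == 0))
  keep <- !is.na(a0$region_id)
  expect_identical(a2$region_id[keep], a0$region_id[keep])
  keep2 <- !is.na(a2$region_id)
  expect_identical(a9$region_id[keep2], a2$region_id[keep2])
})

test_that("non-finite coordinates are rejected with the sample named", {
  vol <- toy_volume()
  s <- samples_at(rbind(c(0, 0, 0), c(NA, 1, 1)))
  expect_error(assign_samples(s, vol, toy_regions), "s2")
})

test_that("regional profiles equal a brute-force group-by and are idempotent", {
  assigned <- data.frame(
    donor_id = c("D1", "D1", "D1", "D2", "D2"),
    sample_id = paste0("s", 1:5),
    region_id = c(1L, 1L, 2L, 1L, NA),
    probeA = c(1, 3, 5, 10, 99))
  pr <- regional_profiles(assigned, "probeA")
  expect_equal(pr$mean_expr[pr$donor_id == "D1" & pr$region_id == 1], 2)
  expect_equal(pr$mean_expr[pr$donor_id == "D1" & pr$region_id == 2], 5)
  expect_equal(pr$mean_expr[pr$donor_id == "D2" & pr$region_id == 1], 10)
  expect_equal(nrow(pr), 3)  # the unassigned sample contributes nothing
  # duplicating a sample with identical expression leaves its region's mean
  # unchanged (sample 3 is alone in its region)
  dup <- rbind(assigned, assigned[3, ])
  expect_equal(regional_profiles(dup, "probeA")$mean_expr, pr$mean_expr)
  expect_error(regional_profiles(assigned, "nope"), "unknown probe")
})

test_that("identical regional rankings give DS = 1 and DS matches the rank oracle", {
  profiles <- rbind(
    data.frame(probe_id = "p1", donor_id = "D1", region_id = 1:5,
               mean_expr = c(1, 2, 3, 4, 5)),
    data.frame(probe_id = "p1", donor_id = "D2", region_id = 1:5,
               mean_expr = c(10, 20, 30, 40, 50)))
  ds <- differential_stability(profiles)
  expect_equal(ds$ds$ds, 1)
  set.seed(60)
  rnd <- do.call(rbind, lapply(c("p1", "p2", "p3"), function(p)
    do.call(rbind, lapply(c("D1", "D2", "D3"), function(d)
      data.frame(probe_id = p, donor_id = d, region_id = 1:8,
                 mean_expr = sample(1:4, 8, replace = TRUE))))))  # forces ties
  ds2 <- differential_stability(rnd)
  orc <- ds_oracle(rnd)
  expect_equal(ds2$ds$ds, orc$ds, tolerance = 1e-12)
})

test_that("DS is invariant under monotone transforms of a probe's values", {
  set.seed(61)
  base <- do.call(rbind, lapply(c("D1", "D2", "D3", "D4"), function(d)
    data.frame(probe_id = "p1", donor_id = d, region_id = 1:7,
               mean_expr = rnorm(7))))
  ds0 <- differential_stability(base)$ds$ds
  for (f in list(exp, function(x) 3 * x + 11)) {
    tr <- base; tr$mean_expr <- f(tr$mean_expr)
    expect_equal(differential_stability(tr)$ds$ds, ds0, tolerance = 1e-12)
  }
})

test_that("donor pairs with too few common regions are skipped with a warning", {
  profiles <- rbind(
    data.frame(probe_id = "p1", donor_id = "D1", region_id = 1:5,
               mean_expr = 1:5),
    data.frame(probe_id = "p1", donor_id = "D2", region_id = 1:5,
               mean_expr = 5:1),
    data.frame(probe_id = "p1", donor_id = "D3", region_id = 8:9,
               mean_expr = c(1, 2)))
  w <- capture_warnings(ds <- differential_stability(profiles))
  expect_match(w, "common regions", all = TRUE)
  expect_length(w, 2)  # D3 shares too few regions with both other donors
  expect_equal(ds$ds$n_pairs, 1L)
  # a probe with no valid pair at all is never selected
  two <- rbind(profiles[profiles$donor_id != "D3", ],
               data.frame(probe_id = "p2", donor_id = c("D1", "D2"),
                          region_id = c(1L, 2L), mean_expr = c(1, 2)))
  expect_warning(ds2 <- differential_stability(two), "common regions")
  expect_equal(ds2$selected, "p1")
  expect_true(is.na(ds2$ds$ds[ds2$ds$probe_id == "p2"]))
})

test_that("donor aggregation is an unweighted mean of donor means", {
  profiles <- data.frame(donor_id = c("D1", "D2", "D1"),
                         region_id = c(1L, 1L, 2L),
                         mean_expr = c(3, 7, 4))
  agg <- aggregate_donors(profiles)
  expect_equal(unname(agg["1"]), 5)  # (3+7)/2 regardless of sample counts
  expect_equal(unname(agg["2"]), 4)  # single donor -> identity
  set.seed(62)
  rnd <- data.frame(donor_id = sample(paste0("D", 1:4), 60, replace = TRUE),
                    region_id = sample(1:6, 60, replace = TRUE),
                    mean_expr = rnorm(60))
  rnd <- rnd[!duplicated(rnd[, 1:2]), ]
  agg2 <- aggregate_donors(rnd)
  for (r in unique(rnd$region_id)) {
    expect_equal(unname(agg2[as.character(r)]),
                 mean(rnd$mean_expr[rnd$region_id == r]))
  }
})

test_that("an exact linear relation gives r = 1 with the planted slope and intercept", {
  mrna <- setNames(c(1, 2, 3, 4, 5), 1:5)
  mwf <- 2 * mrna + 1
  res <- spatial_correlation(mwf, mrna)
  expect_equal(res$r, 1)
  expect_equal(res$slope, 2)
  expect_equal(res$intercept, 1)
  expect_equal(res$p_value, 0)
})

test_that("r is symmetric under axis swap but the slope is not; p matches either way", {
  set.seed(63)
  a <- setNames(rnorm(10), 1:10)
  b <- setNames(a + rnorm(10, 0, 0.5), 1:10)
  r1 <- spatial_correlation(a, b)
  r2 <- spatial_correlation(b, a)
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(r1$slope, r2$slope)))
})

test_that("permuting one axis centers the correlation at zero", {
  set.seed(64)
  mwf <- setNames(runif(12), 1:12)
  mrna <- setNames(mwf + rnorm(12, 0, 0.05), 1:12)
  rs <- replicate(500, {
    spatial_correlation(mwf, setNames(sample(mrna), names(mrna)))$r
  })
  expect_lt(abs(mean(rs)), 4 / sqrt(11) / sqrt(500) * 3 + 0.02)
})

test_that("degenerate spatial inputs are rejected", {
  expect_error(spatial_correlation(setNames(1:2, 1:2), setNames(1:2, 1:2)),
               "insufficient regions")
  expect_error(spatial_correlation(setNames(rep(1, 5), 1:5),
                                   setNames(rnorm(5), 1:5)), "degenerate")
  expect_error(spatial_correlation(setNames(1:5, 1:5),
                                   setNames(1:5, 6:10)),
               "insufficient regions")
})

test_that("the pipeline's spatial stage recovers a strong planted gradient at default noise", {
  r_ok <- 0L
  for (seed in 1:20) {
    cfg <- tiny_config(seed = seed)
    truth <- simulate_truth(cfg)
    vol <- simulate_label_volume(cfg)
    regions <- region_table(cfg)
    cohort <- simulate_cohort(cfg, truth)
    donors <- simulate_donors(cfg, truth, vol, regions)
    assigned <- assign_samples(donors$samples, vol, regions)
    gp <- donors$probes$probe_id[donors$probes$gene_symbol == "MBP"]
    profiles <- do.call(rbind, lapply(gp, function(p) {
      pr <- regional_profiles(assigned, p); pr$probe_id <- p; pr
    }))
    ds <- suppressWarnings(differential_stability(profiles))
    agg <- aggregate_donors(profiles[profiles$probe_id == ds$selected, ])
    mwf_cols <- grep("^mwf_region_", names(cohort), value = TRUE)
    rmwf <- setNames(colMeans(cohort[, mwf_cols]),
                     sub("^mwf_region_", "", mwf_cols))
    if (spatial_correlation(rmwf, agg)$r >= 0.9) r_ok <- r_ok + 1L
  }
  expect_gte(r_ok / 20, 0.9)
})
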