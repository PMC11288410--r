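test_that("generated files round-trip through the ingest readers", {
  cfg <- synth_config(n_sites = 6, levels_per_site = c(1, 2),
                      n_regions = 2, type_pool_size = 20,
                      count_range = c(5, 60), seed = 101)
  dir <- withr::local_tempdir()
  sim <- generate_synthetic(cfg, dir = dir)
  expect_no_warning({
    rec <- read_assemblage(sim$paths$assemblage)
    dts <- read_c14_dates(sim$paths$dates)
    cv <- read_cal_curve(sim$paths$curve)
  })
  expect_equal(nrow(rec), nrow(sim$assemblage))
  expect_true(all(rec$type_code %in% colnames(sim$profiles)))
  expect_equal(nrow(dts), nrow(sim$dates))
  expect_s3_class(cv, "cal_curve")
  # ground truth partitions contexts and profiles sum to 1
  expect_equal(sort(unique(sim$ground_truth$context)),
               sort(unique(rec$context)))
  expect_equal(unname(rowSums(sim$profiles)), rep(1, 2))
})

test_that("a fixed seed reproduces the files byte-for-byte", {
  cfg <- synth_config(n_sites = 4, n_regions = 2, type_pool_size = 12,
                      count_range = c(5, 40), seed = 202)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_synthetic(cfg, dir = d1)
  generate_synthetic(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("disjoint regional pools give zero between-region similarity", {
  cfg <- synth_config(n_sites = 6, levels_per_site = c(1, 1),
                      n_regions = 2, type_pool_size = 16,
                      concentration = 1, count_range = c(50, 100),
                      seed = 303)
  sim <- generate_synthetic(cfg)
  # supports are disjoint by construction
  on1 <- colnames(sim$profiles)[sim$profiles[1, ] > 0]
  on2 <- colnames(sim$profiles)[sim$profiles[2, ] > 0]
  expect_length(intersect(on1, on2), 0)
  sim$assemblage$type_code <- encode_type(sim$assemblage)
  sim$assemblage$context <- paste(sim$assemblage$site_id,
                                  sim$assemblage$level_id, sep = ":")
  B <- binary_from_sets(split(sim$assemblage$type_code,
                              sim$assemblage$context))
  J <- jaccard_matrix(B)
  region <- stats::setNames(sim$ground_truth$region,
                            sim$ground_truth$context)[rownames(B)]
  cross <- outer(region, region, "!=")
  expect_true(all(J[cross] == 0))
})

test_that("one concentrated region yields high within-bin similarity", {
  # single region, strong concentration, large samples: all contexts draw
  # from one profile, so every pairwise Jaccard is substantial
  for (s in c(11, 12, 13)) {
    cfg <- synth_config(n_sites = 5, levels_per_site = c(1, 1),
                        n_regions = 1, type_pool_size = 10,
                        concentration = 1, count_range = c(100, 200),
                        seed = s)
    sim <- generate_synthetic(cfg)
    sim$assemblage$type_code <- encode_type(sim$assemblage)
    sim$assemblage$context <- paste(sim$assemblage$site_id,
                                    sim$assemblage$level_id, sep = ":")
    B <- binary_from_sets(split(sim$assemblage$type_code,
                                sim$assemblage$context))
    J <- jaccard_matrix(B)
    expect_gte(min(J[upper.tri(J)]), 0.5)
  }
})

test_that("recovery experiment finds planted regions when supports are disjoint", {
  cfg <- synth_config(n_sites = 9, levels_per_site = c(1, 2),
                      n_regions = 3, type_pool_size = 24,
                      concentration = 1, count_range = c(40, 120),
                      error_range = c(20, 40), seed = 404)
  rep <- suppressMessages(recovery_experiment(cfg))
  multi <- rep$per_bin[rep$per_bin$n_regions_present >= 2, , drop = FALSE]
  expect_gt(nrow(multi), 0)
  expect_true(all(multi$ari == 1))
  expect_equal(multi$n_communities, multi$n_regions_present)
})

test_that("community recovery degrades monotonically with mixing", {
  mean_ari <- vapply(c(1, 0.5, 0), function(conc) {
    aris <- vapply(1:5, function(s) {
      cfg <- synth_config(n_sites = 9, levels_per_site = c(1, 1),
                          n_regions = 3, type_pool_size = 24,
                          concentration = conc, count_range = c(40, 120),
                          error_range = c(20, 40), seed = 500 + s)
      rep <- suppressMessages(recovery_experiment(cfg))
      multi <- rep$per_bin[rep$per_bin$n_regions_present >= 2, ,
                           drop = FALSE]
      if (nrow(multi) == 0) NA_real_ else mean(multi$ari)
    }, numeric(1))
    mean(aris, na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean_ari[1], mean_ari[2] - 0.05)
  expect_gte(mean_ari[2], mean_ari[3] - 0.05)
  expect_gte(mean_ari[1], 0.9)
  expect_lte(mean_ari[3], 0.5)
})

test_that("turnover sign tracks a planted node schedule", {
  sets <- list(b1 = c("A", "B", "C", "D"),
               b2 = c("A", "B", "E", "F", "G"),  # half replaced, one added
               b3 = c("A", "B"))                 # pure loss
  t <- ntr(sets)
  expect_gt(t$ntr[1], 0)
  expect_lt(t$ntr[2], 0)
})

test_that("the config validates its ranges", {
  expect_error(synth_config(n_sites = 3, seed = 1, concentration = 2))
  expect_error(synth_config(n_sites = 3), "seed")
  expect_error(synth_config(cal_range = c(7000, 8000), seed = 1))
})
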