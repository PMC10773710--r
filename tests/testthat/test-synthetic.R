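test_that("noiseless generation evaluates the Lorentz curve exactly", {
  cfg <- campaign_config(n_treatments = "N0", varieties = 1, reps = 1,
                         stages = "V6", spad_noise_sd = 0, seed = 1)
  profiles <- generate_profiles(cfg, ground_truth())
  expect_equal(profiles$leaf_position, 1:6)
  expect_equal(profiles$spad, lorentz_evaluate(1:6, 39.16, 4, 6.51),
               tolerance = 1e-15)
})

test_that("generation is bit-identical for identical seeds", {
  a <- make_campaign(seed = 42, varieties = 3)
  b <- make_campaign(seed = 42, varieties = 3)
  c <- make_campaign(seed = 43, varieties = 3)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$reflectance, b$reflectance)
  expect_false(identical(a$profiles$spad, c$profiles$spad))
})

test_that("adding plots does not change earlier plots' draws", {
  small <- campaign_config(n_treatments = "N0", varieties = 2, reps = 1,
                           stages = "V6", seed = 9)
  big <- campaign_config(n_treatments = "N0", varieties = 5, reps = 1,
                         stages = "V6", seed = 9)
  ps <- generate_profiles(small, ground_truth())
  pb <- generate_profiles(big, ground_truth())
  shared <- unique(ps$plot_id)
  expect_identical(ps, pb[pb$plot_id %in% shared, ])
})

test_that("generated SPAD is non-negative and the mean at n_m matches spad_m", {
  cfg <- campaign_config(n_treatments = "N0", varieties = 334, reps = 3,
                         stages = "V6", spad_noise_sd = 2, seed = 17)
  profiles <- generate_profiles(cfg, ground_truth())
  expect_true(all(profiles$spad >= 0))
  at_peak <- profiles$spad[profiles$leaf_position == 4]   # n_m for N0/V6
  n <- length(at_peak)
  expect_gte(n, 1000)
  se <- 2 / sqrt(n)
  expect_lt(abs(mean(at_peak) - 39.16), 3 * se)
})

test_that("missing ground-truth parameters raise a configuration error naming the gap", {
  cfg <- campaign_config(n_treatments = c("N0", "N9"), varieties = 1,
                         reps = 1, stages = "V6", seed = 1)
  expect_error(generate_profiles(cfg, ground_truth()), "N9/V6")
})

test_that("reflectance links NDRE deterministically to sensitive-leaf SPAD", {
  cmp <- make_campaign(seed = 8, stage = "V9", varieties = 10, reps = 1,
                       reflectance_noise_sd = 0)
  sens <- cmp$truth$sensitive[["V9"]]
  spad_s <- cmp$profiles$spad[cmp$profiles$leaf_position == sens]
  ndre <- with(cmp$reflectance, (nir - red_edge) / (nir + red_edge))

  # noiseless link, unclamped range: the map SPAD -> NDRE is exactly linear
  expect_equal(pearson_r(ndre, spad_s)$r, 1, tolerance = 1e-9)
  expect_equal(ndre, cmp$truth$link[["a0"]] + cmp$truth$link[["a1"]] * spad_s,
               tolerance = 1e-12)

  # all bands strictly inside (0, 1)
  bands <- as.matrix(cmp$reflectance[, c("blue", "green", "red", "red_edge", "nir")])
  expect_true(all(bands > 0 & bands < 1))
})

test_that("reflectance generation requires the sensitive leaf position", {
  cmp <- make_campaign(seed = 2, stage = "R1", varieties = 2)
  chopped <- cmp$profiles[cmp$profiles$leaf_position != 12, ]
  expect_error(generate_reflectance(chopped, cmp$truth, cmp$cfg),
               "sensitive leaf position 12")
})

test_that("CCCI tracks the sensitive leaf better than the most distant one", {
  hits <- 0L
  for (seed in 1:20) {
    cmp <- make_campaign(seed = seed, stage = "R1", varieties = 10, reps = 1)
    vt <- build_vi_table(cmp$reflectance)
    sens <- cmp$truth$sensitive[["R1"]]
    far <- 20  # R1 range is 6..20; leaf 20 is farthest from 12
    s_sens <- cmp$profiles$spad[cmp$profiles$leaf_position == sens]
    s_far <- cmp$profiles$spad[cmp$profiles$leaf_position == far]
    if (pearson_r(vt$CCCI, s_sens)$r > pearson_r(vt$CCCI, s_far)$r) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 19L)   # >= 95% of replicates
})

test_that("campaigns round-trip exactly through CSV/JSON files", {
  cmp <- make_campaign(seed = 4, stage = "V6", varieties = 3)
  dir <- withr::local_tempdir()
  write_campaign(cmp$profiles, cmp$reflectance, dir, truth = cmp$truth)
  back <- read_campaign(dir)
  expect_equal(back$profiles, cmp$profiles)
  expect_equal(back$reflectance, cmp$reflectance)
  expect_equal(back$truth$params[order(back$truth$params$n_treatment,
                                       back$truth$params$stage), ],
               cmp$truth$params[order(cmp$truth$params$n_treatment,
                                      cmp$truth$params$stage), ],
               ignore_attr = TRUE)
  expect_equal(back$truth$sensitive[c("V6", "V9", "R1", "R2")],
               cmp$truth$sensitive)
})

test_that("empty campaigns round-trip as schema-valid empty files", {
  cmp <- make_campaign(seed = 4, stage = "V6", varieties = 1)
  dir <- withr::local_tempdir()
  write_campaign(cmp$profiles[0, ], cmp$reflectance[0, ], dir)
  back <- read_campaign(dir)
  expect_equal(nrow(back$profiles), 0L)
  expect_equal(names(back$profiles), names(cmp$profiles))
  expect_equal(nrow(back$reflectance), 0L)
})

test_that("malformed numeric cells raise a parse error naming the row", {
  dir <- withr::local_tempdir()
  writeLines(
    c("plot_id,variety,n_treatment,stage,leaf_position,spad",
      "p1,C1,N0,V6,1,33.1",
      "p1,C1,N0,V6,2,not_a_number"),
    file.path(dir, "spad_profiles.csv")
  )
  writeLines("plot_id,stage,blue,green,red,red_edge,nir",
             file.path(dir, "plot_reflectance.csv"))
  expect_error(read_campaign(dir), "row 2")
  expect_error(read_campaign(dir), "spad")
})

test_that("config invariants are enforced", {
  expect_error(campaign_config(spad_noise_sd = -1), ">= 0")
  expect_error(
    campaign_config(stages = "V6", leaf_ranges = list(V6 = c(1L, 2L))),
    "at least 3 positions"
  )
  expect_error(ground_truth(params = data.frame(
    n_treatment = "N0", stage = "V6", spad_m = -5, n_m = 4, b = 6
  )), "spad_m > 0")
})
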