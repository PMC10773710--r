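test_that("describe_profiles finds the peak and the bell shape", {
  cfg <- campaign_config(n_treatments = "N0", varieties = 2, reps = 1,
                         stages = "V6", spad_noise_sd = 0, seed = 1)
  profiles <- generate_profiles(cfg, ground_truth())
  d <- describe_profiles(profiles)
  expect_equal(d$peak_position, 4)       # generating n_m for N0/V6
  expect_true(d$bell_shaped)

  rising <- data.frame(plot_id = "p", variety = "C1", n_treatment = "N0",
                       stage = "V6", leaf_position = 1:6, spad = 30 + 1:6)
  expect_false(describe_profiles(rising)$bell_shaped)

  # duplicating a plot leaves the group summary unchanged
  twin <- rising
  twin$plot_id <- "q"
  both <- describe_profiles(rbind(rising, twin))
  expect_equal(both$peak_position, describe_profiles(rising)$peak_position)
  expect_equal(both$mean_canopy_spad, describe_profiles(rising)$mean_canopy_spad)
})

test_that("rank_vis orders by descending r with alphabetical ties", {
  cmp <- make_campaign(seed = 5, stage = "R1", varieties = 10, reps = 1,
                       reflectance_noise_sd = 0)
  vt <- build_vi_table(cmp$reflectance)
  ds <- stage_dataset(cmp$profiles, vt, "R1")
  ranking <- rank_vis(ds)

  expect_true(all(diff(ranking$r) <= 1e-15))
  # CCCI is an increasing affine map of NDRE: identical r, alphabetical order
  rc <- ranking[ranking$vi %in% c("CCCI", "NDRE"), ]
  expect_equal(rc$r[1], rc$r[2], tolerance = 1e-12)
  expect_identical(rc$vi, c("CCCI", "NDRE"))
  expect_equal(diff(rc$rank), 1L)

  # with the NDRE-driven generator the NDRE family tops the ranking
  expect_true(all(c("CCCI", "NDRE") %in% ranking$vi[1:3]))
})

test_that("rank_vis enforces the minimum plot count and drops constant indices", {
  cmp <- make_campaign(seed = 5, stage = "R1", varieties = 10, reps = 1)
  vt <- build_vi_table(cmp$reflectance)
  ds2 <- stage_dataset(cmp$profiles[cmp$profiles$plot_id %in%
                                      cmp$reflectance$plot_id[1:2], ],
                       vt[1:2, ], "R1")
  expect_error(rank_vis(ds2), "at least 3 plots")

  ds <- stage_dataset(cmp$profiles, vt, "R1")
  ds$vi$DVI <- 0.4   # constant column is excluded, not ranked
  ranking <- rank_vis(ds)
  expect_false("DVI" %in% ranking$vi)
  expect_identical(attr(ranking, "excluded"), "DVI")
})

test_that("find_sensitive_leaf recovers the generative position and reports a profile", {
  cmp <- make_campaign(seed = 6, stage = "V9", varieties = 10, reps = 3)
  vt <- build_vi_table(cmp$reflectance)
  ds <- stage_dataset(cmp$profiles, vt, "V9")
  sl <- find_sensitive_leaf(ds, "CCCI")
  expect_equal(sl$position, 4)           # designated sensitive leaf for V9
  expect_equal(nrow(sl$profile), 9L)     # one row per leaf position
  expect_equal(sl$r, max(sl$profile$r))
  expect_error(find_sensitive_leaf(ds, "NOPE"), "unknown vegetation index")
})

test_that("find_sensitive_leaf with a single position returns that position", {
  vi <- data.frame(matrix(rnorm(4 * 17), 4, 17))
  names(vi) <- vi_names()
  leaf <- matrix(vi$CCCI * 2 + rnorm(4, sd = 0.1), ncol = 1,
                 dimnames = list(NULL, "7"))
  ds <- manual_dataset("V6", paste0("p", 1:4), rowMeans(leaf), leaf, vi)
  expect_equal(find_sensitive_leaf(ds, "CCCI")$position, 7L)
})

test_that("fit_inversion recovers exact linear relationships", {
  vi <- data.frame(matrix(0.5, 3, 17))
  names(vi) <- vi_names()
  vi$CCCI <- c(0, 1, 2)
  leaf <- matrix(2 + 3 * vi$CCCI, ncol = 1, dimnames = list(NULL, "5"))
  ds <- manual_dataset("V6", paste0("p", 1:3), as.numeric(leaf), leaf, vi)

  m <- fit_inversion(ds, "CCCI", target = "sensitive_leaf", position = 5)
  expect_equal(m$intercept, 2, tolerance = 1e-10)
  expect_equal(m$slope, 3, tolerance = 1e-10)
  expect_equal(m$train$r2, 1, tolerance = 1e-12)
  expect_equal(m$train$rmse, 0, tolerance = 1e-10)
  expect_true(m$resubstitution)
})

test_that("training R2 equals the squared VI correlation and matches normal equations", {
  cmp <- make_campaign(seed = 7, stage = "R2", varieties = 10, reps = 1)
  vt <- build_vi_table(cmp$reflectance)
  ds <- stage_dataset(cmp$profiles, vt, "R2")
  ids <- ds$plot_id
  m <- fit_inversion(ds, "CCCI", target = "canopy_mean",
                     train_ids = ids[1:40], test_ids = ids[41:70])

  x <- ds$vi$CCCI[1:40]
  y <- ds$canopy_spad[1:40]
  expect_equal(m$train$r2, pearson_r(x, y)$r^2, tolerance = 1e-12)
  # closed-form normal equations
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(m$slope, slope, tolerance = 1e-10)
  expect_equal(m$intercept, mean(y) - slope * mean(x), tolerance = 1e-10)
  expect_false(m$resubstitution)
  expect_error(
    fit_inversion(ds, "CCCI", train_ids = ids[1:40], test_ids = ids[40:70]),
    "disjoint"
  )
})

test_that("compare_models reproduces the relative R2 improvement arithmetic", {
  fake <- function(r2, target) {
    list(stage = "V6", vi_name = "CCCI", target = target,
         test = list(r2 = r2, rmse = 4), test_ids = paste0("p", 1:10))
  }
  pairs <- list(c(0.59, 0.44, 34), c(0.67, 0.65, 3),
                c(0.60, 0.50, 20), c(0.76, 0.74, 3))
  for (p in pairs) {
    cmpx <- compare_models(fake(p[1], "sensitive_leaf"),
                           fake(p[2], "canopy_mean"))
    expect_equal(cmpx$improvement_pct, p[3])
  }
  same <- compare_models(fake(0.5, "sensitive_leaf"), fake(0.5, "canopy_mean"))
  expect_equal(same$improvement_pct, 0)

  other <- fake(0.5, "canopy_mean")
  other$test_ids <- paste0("q", 1:10)
  expect_error(compare_models(fake(0.6, "sensitive_leaf"), other),
               "same test plots")
})

test_that("predict_spad_map applies the linear model with missing propagation", {
  cmp <- make_campaign(seed = 9, stage = "V6", varieties = 5, reps = 1)
  vt <- build_vi_table(cmp$reflectance)
  ds <- stage_dataset(cmp$profiles, vt, "V6")
  m <- fit_inversion(ds, "CCCI", target = "canopy_mean")

  pred <- predict_spad_map(m, vt)
  expect_equal(pred$predicted_spad, m$intercept + m$slope * vt$CCCI)

  # higher VI -> higher prediction when slope > 0
  if (m$slope > 0) {
    o <- order(vt$CCCI)
    expect_true(all(diff(pred$predicted_spad[o]) >= 0))
  }

  vt2 <- vt
  vt2$CCCI[3] <- NA
  pred2 <- predict_spad_map(m, vt2)
  expect_true(is.na(pred2$predicted_spad[3]))
  expect_equal(attr(pred2, "n_missing"), 1L)

  zero <- vt
  zero$CCCI <- 0
  expect_equal(predict_spad_map(m, zero)$predicted_spad,
               rep(m$intercept, nrow(zero)))
})
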