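test_that("replicate expansion reproduces the design arithmetic", {
  obs <- expand_replicates(the_records, replicates = 8, seed = 1)
  expect_equal(nrow(obs$features), 90L * 8L)
  expect_true(all(obs$responses >= 0 & obs$responses <= 100))
  obs2 <- expand_replicates(the_records, replicates = 8, seed = 1)
  expect_identical(obs$responses, obs2$responses)
  obs3 <- expand_replicates(the_records, replicates = 8, seed = 2)
  expect_false(identical(obs$responses, obs3$responses))
  expect_error(expand_replicates(the_records, replicates = 0), "positive")
})

test_that("zero standard error collapses replicates onto the printed mean", {
  rec <- toy_records()[3, ]
  rec$contamination_se <- 0
  obs <- expand_replicates(rec, replicates = 20, seed = 5)
  expect_equal(unique(obs$responses[, "contamination"]),
               rec$contamination_mean)
  expect_gt(stats::sd(obs$responses[, "germination"]), 0)
})

test_that("sample means converge to the printed means (law of large numbers)", {
  rec <- the_records[the_records$disinfectant == "NaOCl" &
                       the_records$concentration == 1.5 &
                       the_records$time_min == 5, ]
  n_rep <- 1e4
  obs <- expand_replicates(rec, replicates = n_rep, seed = 99)
  for (resp in c("contamination", "germination")) {
    mu <- rec[[paste0(resp, "_mean")]]
    sd_pt <- rec[[paste0(resp, "_se")]] * sqrt(8)
    expect_lt(abs(mean(obs$responses[, resp]) - mu), 4 * sd_pt / sqrt(n_rep))
  }
})

test_that("benchmark surfaces are exact at zero noise and carry their truth", {
  bm <- make_benchmark_surface("germ_peak", noise_sd = 0, seed = 3)
  conc <- bm$table$provenance$concentration
  tim <- bm$table$provenance$time_min
  expect_equal(bm$table$responses[, "germination"],
               bm$surface$germination(conc, tim), ignore_attr = TRUE)
  expect_equal(bm$table$responses[, "contamination"],
               bm$surface$contamination(conc, tim), ignore_attr = TRUE)
  # grid argmax of the noiseless germination sits at the grid point
  # nearest the surface's peak
  peak <- c(6, 12)
  i_max <- which.max(bm$table$responses[, "germination"])
  d <- (conc - peak[1])^2 + (tim - peak[2])^2
  expect_equal(i_max, which.min(d))
  # truth's ideal input is interior to the domain
  expect_true(bm$surface$optimum_input["conc"] >
                bm$surface$conc_range[1] &&
              bm$surface$optimum_input["conc"] < bm$surface$conc_range[2])
  expect_error(make_benchmark_surface("nope"), "unknown")
})

test_that("benchmark sampling is seeded and bounded", {
  a <- make_benchmark_surface("sharp_peak", noise_sd = 5, seed = 8)
  b <- make_benchmark_surface("sharp_peak", noise_sd = 5, seed = 8)
  expect_identical(a$table$responses, b$table$responses)
  expect_true(all(a$table$responses >= 0 & a$table$responses <= 100))
})
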