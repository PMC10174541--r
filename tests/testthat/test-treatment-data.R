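test_that("packaged tables load with every printed cell intact", {
  rec <- the_records
  expect_equal(nrow(rec), 90L)
  expect_equal(as.vector(table(rec$disinfectant)[disinfectant_info()$label]),
               rep(15L, 6))

  naocl_ctrl <- rec[rec$disinfectant == "NaOCl" & rec$concentration == 0 &
                      rec$time_min == 5, ]
  expect_equal(naocl_ctrl$contamination_mean, 96.8)
  expect_equal(naocl_ctrl$germination_mean, 16.6)

  ca <- rec[rec$disinfectant == "CaClO2" & rec$concentration == 9 &
              rec$time_min == 10, ]
  expect_equal(ca$germination_mean, 91.66)
  expect_equal(ca$contamination_mean, 4.16)

  # loading then re-serializing reproduces the fixtures byte-for-byte
  tmp <- withr::local_tempdir()
  src <- system.file("extdata", package = "sterilopt")
  for (f in list.files(src, pattern = "^table.*csv$")) {
    tab <- utils::read.csv(file.path(src, f), colClasses = "character")
    out <- file.path(tmp, f)
    utils::write.csv(tab, out, row.names = FALSE, quote = FALSE)
    expect_identical(readLines(out)[-1], readLines(file.path(src, f))[-1])
  }
})

test_that("loader fails loudly on missing or corrupt fixtures", {
  tmp <- withr::local_tempdir()
  expect_error(load_treatment_tables(tmp), "table1_naocl")
  src <- system.file("extdata", package = "sterilopt")
  for (f in list.files(src, pattern = "^table.*csv$")) {
    file.copy(file.path(src, f), tmp)
  }
  bad <- utils::read.csv(file.path(tmp, "table3_hgcl2.csv"))
  bad$contamination_mean[4] <- 150  # out of percent range
  utils::write.csv(bad, file.path(tmp, "table3_hgcl2.csv"), row.names = FALSE)
  expect_error(load_treatment_tables(tmp), "table3_hgcl2")
})

test_that("dataset extrema match the study's own statements", {
  rec <- the_records
  naocl <- rec[rec$disinfectant == "NaOCl", ]
  expect_equal(min(naocl$contamination_mean), 7.0)
  ca <- rec[rec$disinfectant == "CaClO2", ]
  expect_equal(max(ca$germination_mean), 91.66)
  h2o2 <- rec[rec$disinfectant == "H2O2", ]
  expect_equal(min(h2o2$contamination_mean), 1.04)
  # the tables do contain a zero-contamination cell (Ca(ClO)2 7% x 5 min)
  expect_equal(min(rec$contamination_mean), 0)
  expect_equal(unique(rec$contamination_mean[rec$concentration == 0]), 96.8)
})

test_that("feature encoding maps each record to a single active slot", {
  rec <- toy_records()
  X <- encode_features(rec)
  expect_equal(dim(X), c(8L, 7L))
  expect_equal(colnames(X), feature_names())
  # control: all concentration slots zero, time carried through
  expect_equal(unname(X[1, ]), c(0, 0, 0, 0, 0, 0, 5))
  # active H2O2 record: slot 4 carries the dose
  expect_equal(unname(X[7, ]), c(0, 0, 0, 10, 0, 0, 5))
  X90 <- encode_features(the_records)
  expect_equal(dim(X90), c(90L, 7L))
  expect_true(all(rowSums(X90[, 1:6] != 0) <= 1))
})

test_that("min-max scaler hits endpoints, inverts, and zeroes constants", {
  X <- cbind(a = c(5, 10, 15), b = c(3, 3, 3), c = c(-1, 0, 3))
  sc <- fit_scaler(X)
  S <- apply_scaler(sc, X)
  expect_equal(unname(S[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(S[, "b"]), c(0, 0, 0))
  expect_equal(range(S[, "c"]), c(0, 1))
  back <- invert_scaler(sc, S)
  expect_equal(unname(back[, "a"]), unname(X[, "a"]))
  expect_equal(unname(back[, "c"]), unname(X[, "c"]))
  expect_equal(unname(back[, "b"]), c(3, 3, 3))  # constants restored too
  expect_error(fit_scaler(X[1, , drop = FALSE]), "2 rows")
})

test_that("stratified split partitions rows and is reproducible", {
  obs <- expand_replicates(the_records, replicates = 3, seed = 7)
  sp <- split_train_test(obs, 0.8, seed = 42)
  n <- nrow(obs$features)
  expect_equal(length(sp$train_idx), floor(0.8 * n))
  expect_setequal(c(sp$train_idx, sp$test_idx), seq_len(n))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  for (side in list(sp$train, sp$test)) {
    expect_setequal(unique(side$provenance$disinfectant),
                    disinfectant_info()$label)
  }
  sp2 <- split_train_test(obs, 0.8, seed = 42)
  expect_identical(sp$train_idx, sp2$train_idx)
  sp3 <- split_train_test(obs, 0.8, seed = 43)
  expect_false(identical(sp$train_idx, sp3$train_idx))
})
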