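# Stage 3: score every family x response x subset by R2 / RMSE / MBE and
# flag the best family by mean test R2.

source(file.path("analysis", "00_config.R"))

sp <- get_split()
sets <- lapply(CFG$models, function(kind) {
  suppressWarnings(
    fit_surrogates(sp$train, kind, seed = stage_seed(CFG$seed, 3L))
  )
})
names(sets) <- CFG$models

metrics <- compare_models(sets, sp$train, sp$test)
print(metrics, digits = 3)
message("best family by mean test R2: ", toupper(attr(metrics, "best_model")))
utils::write.csv(metrics, file.path(OUT_DIR, "metrics.csv"),
                 row.names = FALSE)
message("wrote ", file.path(OUT_DIR, "metrics.csv"))
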