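# Stage 4: input-importance ranking by variable removal (VSE / VSR) for
# the GRNN surrogate: retrain without each input, compare test RMSE.

source(file.path("analysis", "00_config.R"))

obs <- get_observations()
sens <- suppressWarnings(
  sensitivity_analysis(obs, "grnn", CFG$train_fraction,
                       seed = stage_seed(CFG$seed, 2L))
)
print(sens, digits = 3)
utils::write.csv(sens, file.path(OUT_DIR, "sensitivity.csv"),
                 row.names = FALSE)
message("wrote ", file.path(OUT_DIR, "sensitivity.csv"))
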