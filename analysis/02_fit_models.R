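# Stage 2: stratified 80/20 split and one surrogate family per model type
# (MLP, GRNN, RBF), each fitted separately to contamination rate and seed
# germination percentage on min-max scaled inputs.

source(file.path("analysis", "00_config.R"))

sp <- get_split()
message("split: ", nrow(sp$train$features), " train / ",
        nrow(sp$test$features), " test rows, every disinfectant in both")

for (kind in CFG$models) {
  t0 <- Sys.time()
  set <- suppressWarnings(
    fit_surrogates(sp$train, kind, seed = stage_seed(CFG$seed, 3L))
  )
  path <- file.path(OUT_DIR, paste0("model_", kind, ".json"))
  write_surrogates(set, path)
  message(sprintf("%s fitted in %.1fs -> %s", toupper(kind),
                  as.numeric(Sys.time() - t0, units = "secs"), path))
  if (kind == "grnn") {
    message("  GRNN widths (scaled-input metric): contamination ",
            signif(set$models$contamination$sigma, 3), ", germination ",
            signif(set$models$germination$sigma, 3))
  }
}
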