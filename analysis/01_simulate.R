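# Stage 1: expand the printed treatment tables (mean +/- SE per
# disinfectant x concentration x immersion time) into a replicate-level
# dataset, and export it.

source(file.path("analysis", "00_config.R"))

records <- load_treatment_tables()
message(nrow(records), " printed treatment rows across ",
        length(unique(records$disinfectant)), " disinfectant tables")

obs <- get_observations()
message("expanded to ", nrow(obs$features), " replicate observations (",
        CFG$replicates, " per treatment, per-datapoint sd = SE*sqrt(8), ",
        "truncated to [0, 100])")

out <- cbind(obs$provenance, obs$features, obs$responses)
utils::write.csv(out, file.path(OUT_DIR, "observations.csv"),
                 row.names = FALSE)
message("wrote ", file.path(OUT_DIR, "observations.csv"))
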