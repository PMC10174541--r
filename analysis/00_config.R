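# Shared settings for the numbered analysis scripts. Each script is a thin
# driver over the sterilopt package and can be rerun independently: every
# stage re-derives its inputs from the master seed.

library(sterilopt)

MASTER_SEED <- 1L
OUT_DIR <- file.path("results", "run")
dir.create(OUT_DIR, recursive = TRUE, showWarnings = FALSE)

CFG <- run_config(
  seed = MASTER_SEED, replicates = 8L, train_fraction = 0.8,
  models = c("mlp", "grnn", "rbf"), pop_size = 85L, generations = 800L,
  crossover_rate = 0.70, mutation_rate = 0.01, out_dir = OUT_DIR
)

get_observations <- function() {
  expand_replicates(load_treatment_tables(), CFG$replicates,
                    seed = stage_seed(CFG$seed, 1L))
}

get_split <- function(obs = get_observations()) {
  split_train_test(obs, CFG$train_fraction, seed = stage_seed(CFG$seed, 2L))
}
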