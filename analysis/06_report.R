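# Stage 6: one markdown report reproducing the layouts of the study's
# metric, optimization and sensitivity tables, with deltas (reproduced
# minus published) for every comparable cell.

source(file.path("analysis", "00_config.R"))

# report_run() consumes the artifacts written by stages 1-5 plus the
# resolved configuration
jsonlite::write_json(unclass(CFG), file.path(OUT_DIR, "config.json"),
                     auto_unbox = TRUE, digits = NA)
path <- report_run(OUT_DIR)
message("wrote ", path)
cat(readLines(path)[1:12], sep = "\n")
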