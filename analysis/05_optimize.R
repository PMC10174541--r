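# Stage 5: NSGA-II over the GRNN surrogate, one scenario per disinfectant
# (its tested concentration x time box, other slots frozen at 0), with
# ideal-point selection against the subset's observed best values.

source(file.path("analysis", "00_config.R"))

records <- load_treatment_tables()
obs <- get_observations()
full <- suppressWarnings(
  fit_surrogates(obs, "grnn", seed = stage_seed(CFG$seed, 4L))
)

ideal <- list()
for (lab in disinfectant_info()$label) {
  sc <- make_scenario(records, lab)
  pr <- evolve(
    full, sc, pop_size = CFG$pop_size, generations = CFG$generations,
    crossover_rate = CFG$crossover_rate, mutation_rate = CFG$mutation_rate,
    seed = stage_seed(CFG$seed, 10L + match(lab, disinfectant_info()$label))
  )
  print(pr)
  front <- cbind(as.data.frame(pr$front$X),
                 as.data.frame(pr$front$objectives))
  utils::write.csv(front,
                   file.path(OUT_DIR, paste0("pareto_", tolower(lab), ".csv")),
                   row.names = FALSE)
  ideal[[lab]] <- data.frame(
    disinfectant = lab,
    concentration = pr$ideal$x[sc$slot], time_min = pr$ideal$x[7],
    contamination = pr$ideal$objectives[1],
    germination = pr$ideal$objectives[2],
    m = pr$m, n = pr$n, distance = pr$ideal$distance
  )
}
ideal <- do.call(rbind, ideal)
rownames(ideal) <- NULL
utils::write.csv(ideal, file.path(OUT_DIR, "ideal_points.csv"),
                 row.names = FALSE)
message("wrote ", file.path(OUT_DIR, "ideal_points.csv"))

# Pareto front figure (one panel per disinfectant), vector output
svg_path <- file.path(OUT_DIR, "pareto_fronts.svg")
grDevices::svg(svg_path, width = 9, height = 6)
op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
for (lab in disinfectant_info()$label) {
  front <- utils::read.csv(
    file.path(OUT_DIR, paste0("pareto_", tolower(lab), ".csv"))
  )
  graphics::plot(
    front$contamination, front$germination, pch = 20, col = "grey40",
    xlab = "contamination (%)", ylab = "germination (%)", main = lab
  )
  row <- ideal[ideal$disinfectant == lab, ]
  graphics::points(row$contamination, row$germination, pch = 19,
                   col = "black", cex = 1.6)
  graphics::points(row$m, row$n, pch = 4, col = "red")
}
graphics::par(op)
grDevices::dev.off()
message("wrote ", svg_path)
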