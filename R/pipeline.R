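#' Resolved configuration for a full pipeline run
#'
#' @param seed Master seed; per-stage seeds are derived from it by a fixed
#'   rule so stages are independently reproducible.
#' @param replicates Replicates simulated per treatment.
#' @param train_fraction Training share of the 80/20-style split.
#' @param models Surrogate families to fit and compare.
#' @param pop_size,generations,crossover_rate,mutation_rate GA settings.
#' @param out_dir Output directory for run artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, replicates = 8L, train_fraction = 0.8,
                       models = c("mlp", "grnn", "rbf"), pop_size = 85L,
                       generations = 800L, crossover_rate = 0.70,
                       mutation_rate = 0.01, out_dir = tempfile("run")) {
  structure(
    list(
      seed = as.integer(seed), replicates = as.integer(replicates),
      train_fraction = train_fraction, models = models,
      pop_size = as.integer(pop_size),
      generations = as.integer(generations),
      crossover_rate = crossover_rate, mutation_rate = mutation_rate,
      out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Derive a stage seed from the master seed
#'
#' Fixed affine derivation (mod 2^31 - 1) so each pipeline stage draws
#' from its own reproducible stream.
#'
#' @param seed Master seed.
#' @param stage Integer stage index.
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + 104729 * stage) %% 2147483647)
}

write_run_csv <- function(x, dir, name) {
  utils::write.csv(x, file.path(dir, name), row.names = FALSE)
}

#' Run the complete analysis pipeline
#'
#' Executes the full workflow: load the packaged treatment tables, expand
#' them to replicate level, split stratified 80/20, fit the requested
#' surrogate families to both responses, score them (picking the best by
#' mean test R2), rank input importance for the best family, and run the
#' NSGA-II search for every disinfectant scenario with the best family
#' retrained on the full expanded dataset. All tabular artifacts plus the
#' resolved configuration are written to `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the split, fitted sets, metrics report,
#'   sensitivity report and per-disinfectant `pareto_result`s.
#' @export
run_all <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    say(sprintf("[%s] done in %.1fs", name,
                as.numeric(Sys.time() - t0, units = "secs")))
    out
  }
  jsonlite::write_json(
    unclass(config), file.path(config$out_dir, "config.json"),
    auto_unbox = TRUE, digits = NA
  )

  records <- stage("load", load_treatment_tables())
  obs <- stage("expand", expand_replicates(
    records, config$replicates, stage_seed(config$seed, 1L)
  ))
  stage("export", write_run_csv(
    cbind(obs$provenance, obs$features, obs$responses),
    config$out_dir, "observations.csv"
  ))
  sp <- stage("split", split_train_test(
    obs, config$train_fraction, stage_seed(config$seed, 2L)
  ))
  sets <- stage("train", {
    out <- lapply(config$models, function(k) {
      fit_surrogates(sp$train, k, seed = stage_seed(config$seed, 3L))
    })
    names(out) <- config$models
    out
  })
  metrics <- stage("evaluate", compare_models(sets, sp$train, sp$test))
  best <- attr(metrics, "best_model")
  say("best model by mean test R2: ", toupper(best))
  write_run_csv(metrics, config$out_dir, "metrics.csv")
  sens <- stage("sensitivity", sensitivity_analysis(
    obs, best, config$train_fraction, stage_seed(config$seed, 2L)
  ))
  write_run_csv(sens, config$out_dir, "sensitivity.csv")

  full_set <- stage("refit", fit_surrogates(
    obs, best, seed = stage_seed(config$seed, 4L)
  ))
  write_surrogates(full_set, file.path(config$out_dir, "best_model.json"))
  pareto <- stage("optimize", {
    out <- lapply(disinfectant_info()$label, function(lab) {
      evolve(
        full_set, make_scenario(records, lab),
        pop_size = config$pop_size, generations = config$generations,
        crossover_rate = config$crossover_rate,
        mutation_rate = config$mutation_rate,
        seed = stage_seed(config$seed, 10L + match(
          lab, disinfectant_info()$label
        ))
      )
    })
    names(out) <- disinfectant_info()$label
    out
  })
  for (lab in names(pareto)) {
    pr <- pareto[[lab]]
    write_run_csv(
      cbind(as.data.frame(pr$front$X), as.data.frame(pr$front$objectives)),
      config$out_dir, paste0("pareto_", tolower(lab), ".csv")
    )
  }
  ideal <- do.call(rbind, lapply(names(pareto), function(lab) {
    pr <- pareto[[lab]]
    data.frame(
      disinfectant = lab,
      concentration = pr$ideal$x[pr$scenario$slot],
      time_min = pr$ideal$x[7],
      contamination = pr$ideal$objectives[1],
      germination = pr$ideal$objectives[2],
      m = pr$m, n = pr$n, distance = pr$ideal$distance
    )
  }))
  write_run_csv(ideal, config$out_dir, "ideal_points.csv")
  invisible(list(
    config = config, records = records, observations = obs, split = sp,
    sets = sets, metrics = metrics, best_model = best,
    sensitivity = sens, pareto = pareto, ideal_points = ideal
  ))
}

read_reference <- function(name) {
  utils::read.csv(
    system.file("extdata", name, package = "sterilopt"),
    stringsAsFactors = FALSE
  )
}

md_table <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = digits,
                                                 format = "g"))
  lines <- c(
    paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    vapply(seq_len(nrow(df)), function(i) {
      paste0("| ", paste(unlist(df[i, ]), collapse = " | "), " |")
    }, character(1))
  )
  lines
}

#' Summarize a completed run against the published reference values
#'
#' Reads the artifacts written by [run_all()] and produces one markdown
#' document reproducing the layouts of the study's metric, optimization
#' and sensitivity tables, with deltas (reproduced minus published) for
#' every comparable cell.
#'
#' @param out_dir Directory of a completed run.
#' @param file Output path; defaults to `report.md` inside `out_dir`.
#' @return The report path, invisibly.
#' @export
report_run <- function(out_dir, file = file.path(out_dir, "report.md")) {
  need <- c("config.json", "metrics.csv", "sensitivity.csv",
            "ideal_points.csv")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing)) {
    stop("incomplete run, missing artifacts: ", paste(missing,
                                                      collapse = ", "))
  }
  cfg <- jsonlite::read_json(file.path(out_dir, "config.json"),
                             simplifyVector = TRUE)
  metrics <- utils::read.csv(file.path(out_dir, "metrics.csv"))
  sens <- utils::read.csv(file.path(out_dir, "sensitivity.csv"))
  ideal <- utils::read.csv(file.path(out_dir, "ideal_points.csv"))

  ref_m <- read_reference("reference_metrics.csv")
  metrics$model <- toupper(metrics$model)
  mm <- merge(metrics, ref_m, by = c("model", "response", "subset"),
              suffixes = c("", "_ref"))
  mm$r2_delta <- mm$r2 - mm$r2_ref
  mm$rmse_delta <- mm$rmse - mm$rmse_ref
  mm <- mm[order(mm$model, mm$response, rev(mm$subset)), ]

  ref_o <- read_reference("reference_optima.csv")
  oo <- merge(ideal, ref_o, by = "disinfectant", suffixes = c("", "_ref"))
  oo$contamination_delta <- oo$contamination - oo$contamination_ref
  oo$germination_delta <- oo$germination - oo$germination_ref

  ref_s <- read_reference("reference_sensitivity.csv")
  ss <- merge(sens, ref_s, by = c("response", "input"),
              suffixes = c("", "_ref"))
  ss$rank_delta <- ss$rank - ss$rank_ref

  lines <- c(
    "# Sterilization surrogate-optimization run report",
    "",
    paste0("Seed: ", cfg$seed, "; replicates/treatment: ", cfg$replicates,
           "; train fraction: ", cfg$train_fraction),
    paste0("GA: population ", cfg$pop_size, ", ", cfg$generations,
           " generations, crossover ", cfg$crossover_rate, ", mutation ",
           cfg$mutation_rate),
    "",
    "## Model comparison (reproduced vs published)",
    "",
    md_table(mm[, c("model", "response", "subset", "r2", "r2_ref",
                    "r2_delta", "rmse", "rmse_ref", "rmse_delta")]),
    "",
    "## Optimized scenarios (ideal points, reproduced vs published)",
    "",
    md_table(oo[, c("disinfectant", "concentration", "time_min",
                    "contamination", "contamination_ref",
                    "contamination_delta", "germination",
                    "germination_ref", "germination_delta")]),
    "",
    "## Input sensitivity ranks (reproduced vs published)",
    "",
    md_table(ss[, c("response", "input", "vsr", "vsr_ref", "rank",
                    "rank_ref", "rank_delta")])
  )
  writeLines(lines, file)
  invisible(file)
}
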