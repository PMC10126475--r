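# End-to-end orchestration: simulate -> extract -> importance -> cluster ->
# train/eval -> transfer, with per-stage manifests for reproducibility.

#' Run the full analysis pipeline on simulated data
#'
#' Executes every stage on a simulated experiment: (1) simulate markers,
#' weather and trials (`n_trials` testcross trials for the importance
#' analysis — the first doubles as the single-trial modeling panel — plus a
#' calibration source trial and a domain-shifted testcross target trial);
#' (2) extract feature tensors; (3) importance analysis and redundancy
#' pruning; (4) genotype clustering; (5) cross-validated with/without
#' genotype models on the first trial; (6) the four-model transfer
#' comparison. Every stage writes its artifacts plus a `manifest.json`
#' holding the seed, package version and MD5 of each file, so a rerun with
#' the same configuration is byte-identical and verifiably so.
#'
#' @param out_dir Output directory.
#' @param sim A [sim_config()]; its `seed` is overridden by `seed`.
#' @param rnng An [rnng_config()] for the modeling stages.
#' @param n_trials Testcross trials simulated for the importance stage
#'   (default 3).
#' @param n_pcs,q Importance-analysis knobs (defaults 5, 0.25).
#' @param k_range Candidate cluster counts (default `1:10`).
#' @param ft_epochs Fine-tuning epochs in the transfer stage (default 150).
#' @param stages Stages to run (subset of simulate, extract, importance,
#'   cluster, train, transfer); earlier artifacts are read from `out_dir`
#'   when a stage is skipped.
#' @param seed Master seed.
#' @return A `pipeline_result` list with the key objects and the manifest
#'   paths, invisibly.
#' @export
run_pipeline <- function(out_dir,
                         sim = sim_config(n_hybrids = 60, n_markers = 300,
                                          n_cal_hybrids = 20,
                                          points_per_plot = 120),
                         rnng = rnng_config(hidden = 16, epochs = 60,
                                            batch_size = 32),
                         n_trials = 3, n_pcs = 5, q = 0.25,
                         k_range = 1:8, ft_epochs = 150,
                         stages = c("simulate", "extract", "importance",
                                    "cluster", "train", "transfer"),
                         seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim$seed <- seed
  validate_sim_config(sim)
  catalog <- default_catalog()
  trial_names <- c(paste0("tc", seq_len(n_trials)), "cal", "target")

  stage_dir <- function(s) file.path(out_dir, s)
  manifest <- function(s, params = list()) {
    d <- stage_dir(s)
    files <- sort(list.files(d, recursive = TRUE, full.names = TRUE))
    files <- files[basename(files) != "manifest.json"]
    md5 <- tools::md5sum(files)
    names(md5) <- sub(paste0("^", d, "/?"), "", names(md5))
    jsonlite::write_json(
      list(stage = s, seed = seed,
           version = as.character(utils::packageVersion("phenocast")),
           params = params, files = as.list(md5)),
      file.path(d, "manifest.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }

  # --- simulate -----------------------------------------------------------
  if ("simulate" %in% stages) {
    markers <- simulate_markers(sim)
    weather <- simulate_weather(sim)
    trials <- list()
    for (i in seq_len(n_trials)) {
      nm <- paste0("tc", i)
      trials[[nm]] <- simulate_trial(sim, markers, weather, panel = "tc",
                                     trial_id = sprintf("Tc-%d", i),
                                     year = 2018L + i)
    }
    trials$cal <- simulate_trial(sim, markers, weather, panel = "cal",
                                 trial_id = "Cal-1", year = 2019L)
    trials$target <- simulate_trial(sim, markers, weather, panel = "tc",
                                    trial_id = "Tc-target", year = 2019L,
                                    apply_shift = TRUE)
    d <- stage_dir("simulate")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_markers(markers, file.path(d, "markers.csv"))
    for (nm in names(trials)) write_trial(trials[[nm]], file.path(d, nm))
    manifest("simulate", params = unclass(sim))
  } else {
    d <- stage_dir("simulate")
    markers <- read_markers(file.path(d, "markers.csv"))
    trials <- setNames(
      lapply(trial_names, function(nm) read_trial(file.path(d, nm))),
      trial_names)
  }

  # --- extract ------------------------------------------------------------
  if ("extract" %in% stages) {
    tensors <- lapply(trials, extract_features, catalog = catalog)
    d <- stage_dir("extract")
    for (nm in names(tensors)) write_tensor(tensors[[nm]], file.path(d, nm))
    manifest("extract")
  } else {
    d <- stage_dir("extract")
    tensors <- setNames(
      lapply(trial_names, function(nm) read_tensor(file.path(d, nm))),
      trial_names)
  }

  # --- importance ---------------------------------------------------------
  if ("importance" %in% stages) {
    rep_tensors <- tensors[seq_len(n_trials)]
    red <- redundant_features(rep_tensors, n_pcs = n_pcs, q = q)
    d <- stage_dir("importance")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(bind_rows(red$importance, .id = "trial"),
                     file.path(d, "importance.csv"))
    jsonlite::write_json(list(redundant = red$redundant, q = q,
                              n_pcs = n_pcs),
                         file.path(d, "redundant.json"),
                         auto_unbox = TRUE, digits = NA)
    importance_report(red, file.path(d, "report.md"))
    manifest("importance", params = list(n_pcs = n_pcs, q = q))
    redundant <- red$redundant
  } else {
    redundant <- unlist(jsonlite::read_json(
      file.path(stage_dir("importance"), "redundant.json"),
      simplifyVector = TRUE)$redundant)
  }
  pruned <- lapply(tensors, drop_features, drop = redundant)

  # --- cluster ------------------------------------------------------------
  if ("cluster" %in% stages) {
    gc_fit <- genotype_clusters(markers, n_components = min(10, nrow(markers) - 1),
                                k_range = k_range,
                                seed = substream_seed(seed, "cluster"))
    d <- stage_dir("cluster")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(gc_fit$assignment, file.path(d, "assignment.csv"))
    readr::write_csv(as_tibble(gc_fit$curve), file.path(d, "wcss.csv"))
    jsonlite::write_json(list(chosen_k = gc_fit$chosen_k,
                              no_elbow = gc_fit$no_elbow),
                         file.path(d, "chosen_k.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest("cluster", params = list(k_range = k_range))
  } else {
    d <- stage_dir("cluster")
    asg <- readr::read_csv(file.path(d, "assignment.csv"),
                           show_col_types = FALSE)
    ck <- jsonlite::read_json(file.path(d, "chosen_k.json"),
                              simplifyVector = TRUE)
    gc_fit <- structure(list(assignment = asg, k = as.integer(ck$chosen_k),
                             chosen_k = as.integer(ck$chosen_k),
                             wcss = NA_real_),
                        class = c("genotype_clusters", "cluster_assignment"))
  }

  # --- train: with/without genotype on the first trial --------------------
  eval_a <- eval_b <- NULL
  if ("train" %in% stages) {
    trial1 <- trials[[1]]
    tensor1 <- pruned[[1]]
    cfg <- rnng
    cfg$seed <- substream_seed(seed, "train_ab")
    static <- plot_clusters(trial1$records, gc_fit)
    cv_a <- rnng_cv(tensor1, trial1$biomass, trial1$records, static = NULL,
                    config = cfg)
    cv_b <- rnng_cv(tensor1, trial1$biomass, trial1$records, static = static,
                    config = cfg)
    eval_a <- cv_a$eval
    eval_b <- cv_b$eval
    d <- stage_dir("train")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(eval_a$predictions, file.path(d, "model_a_predictions.csv"))
    readr::write_csv(eval_b$predictions, file.path(d, "model_b_predictions.csv"))
    jsonlite::write_json(
      list(model_a = as.list(eval_a$metrics), model_b = as.list(eval_b$metrics)),
      file.path(d, "metrics.json"), auto_unbox = TRUE, digits = NA)
    write_model(cv_b$folds[[1]], file.path(d, "model_b_fold1.json"))
    manifest("train", params = unclass(cfg))
  }

  # --- transfer -----------------------------------------------------------
  transfer <- NULL
  if ("transfer" %in% stages) {
    cfg <- rnng
    transfer <- run_transfer_experiment(
      trials$cal, trials$target, clusters = gc_fit,
      config = cfg, ft_epochs = ft_epochs,
      seed = substream_seed(seed, "transfer"),
      source_tensor = pruned$cal, target_tensor = pruned$target)
    d <- stage_dir("transfer")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(tidy(transfer), file.path(d, "comparison.csv"))
    readr::write_csv(tidy(transfer$selections$genomic),
                     file.path(d, "selection_genomic.csv"))
    readr::write_csv(tidy(transfer$selections$phenotype),
                     file.path(d, "selection_phenotype.csv"))
    transfer_table_md(transfer, file.path(d, "comparison.md"))
    manifest("transfer", params = list(ft_epochs = ft_epochs))
  }

  invisible(structure(
    list(out_dir = out_dir, trials = trials, tensors = pruned,
         redundant = redundant, clusters = gc_fit,
         eval_no_genotype = eval_a, eval_with_genotype = eval_b,
         transfer = transfer, seed = seed),
    class = "pipeline_result"))
}

# Human-readable importance report with variance-explained tables.
importance_report <- function(red, path) {
  lines <- c("# Feature importance and redundancy report", "")
  lines <- c(lines, sprintf("- trials analyzed: %d", length(red$flags)),
             sprintf("- PCs aggregated: %d; low-importance quantile q = %.2f",
                     red$n_pcs, red$q),
             sprintf("- redundant features (flagged in > half of trials): %s",
                     if (length(red$redundant) == 0) "none" else
                       paste(red$redundant, collapse = ", ")),
             "")
  for (i in seq_along(red$importance)) {
    lines <- c(lines, sprintf("## Trial %d", i), "",
               "date | source | lowest-importance feature",
               "---- | ------ | -------------------------")
    low <- red$importance[[i]] %>%
      group_by(.data$date, .data$source) %>%
      dplyr::slice_min(.data$importance, n = 1, with_ties = FALSE) %>%
      ungroup()
    lines <- c(lines, sprintf("%s | %s | %s (%.4f)", low$date, low$source,
                              low$feature, low$importance), "")
  }
  writeLines(lines, path)
  invisible(path)
}

# Markdown comparison table in the style of a four-model transfer study.
transfer_table_md <- function(transfer, path) {
  tb <- tidy(transfer)
  lines <- c(
    "Model | Training samples (target) | Training hybrids (target) | R2 prediction | RMSE (g/m2) | R2 ranking",
    "----- | ------------------------- | ------------------------- | ------------- | ----------- | ----------",
    sprintf("%s | %d | %d | %.3f | %.1f | %.3f",
            tb$model, tb$n_target_train, tb$n_target_hybrids,
            tb$r2_prediction, tb$rmse, tb$r2_ranking))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a directory of pipeline input CSVs
#'
#' Schema-checks every CSV a simulated (or user-supplied) trial directory
#' should contain and cross-references IDs (plots vs biomass, hybrids vs
#' markers). Reports *all* violations, not just the first.
#'
#' @param dir Directory holding `records.csv`, `biomass.csv`,
#'   `weather.csv`, `spectra.csv`, `clouds.csv` (a [write_trial()] layout).
#' @param markers_path Optional path to a marker CSV for hybrid
#'   cross-referencing.
#' @return A tibble of violations (`file`, `problem`); zero rows when clean.
#' @export
validate_inputs <- function(dir, markers_path = NULL) {
  problems <- list()
  note <- function(file, problem) {
    problems[[length(problems) + 1]] <<- tibble(file = file, problem = problem)
  }
  need <- list(
    records.csv = c("trial", "year", "plot_id", "hybrid_id", "replicate"),
    biomass.csv = c("plot_id", "fresh_biomass"),
    weather.csv = c("day", "t_min", "t_max", "precipitation", "radiation"),
    clouds.csv = c("plot_id", "date", "x", "y", "z", "is_ground")
  )
  tabs <- list()
  for (f in names(need)) {
    p <- file.path(dir, f)
    if (!file.exists(p)) {
      note(f, "file missing")
      next
    }
    tb <- readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
    missing <- setdiff(need[[f]], names(tb))
    if (length(missing) > 0) {
      note(f, sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
    }
    tabs[[f]] <- tb
  }
  rec <- tabs$records.csv
  if (!is.null(rec) && all(c("trial", "plot_id") %in% names(rec))) {
    if (anyDuplicated(rec[c("trial", "plot_id")])) {
      note("records.csv", "duplicate (trial, plot_id) pairs")
    }
  }
  bm <- tabs$biomass.csv
  if (!is.null(bm) && "fresh_biomass" %in% names(bm)) {
    if (any(bm$fresh_biomass <= 0, na.rm = TRUE)) {
      note("biomass.csv", "non-positive fresh_biomass values")
    }
    if (!is.null(rec) && "plot_id" %in% names(rec) &&
        "plot_id" %in% names(bm)) {
      orphan <- setdiff(rec$plot_id, bm$plot_id)
      if (length(orphan) > 0) {
        note("biomass.csv", sprintf("plots without biomass: %s",
                                    paste(head(orphan, 5), collapse = ", ")))
      }
    }
  }
  wx <- tabs$weather.csv
  if (!is.null(wx) && all(c("t_min", "t_max", "day") %in% names(wx))) {
    if (any(wx$t_min > wx$t_max, na.rm = TRUE)) {
      note("weather.csv", "t_min exceeds t_max on some days")
    }
    if (length(wx$day) > 0 && any(diff(sort(wx$day)) != 1)) {
      note("weather.csv", "days are not contiguous")
    }
  }
  if (!is.null(markers_path) && file.exists(markers_path) && !is.null(rec) &&
      "hybrid_id" %in% names(rec)) {
    mk <- read_markers(markers_path)
    orphan <- setdiff(unique(rec$hybrid_id), rownames(mk))
    if (length(orphan) > 0) {
      note("records.csv", sprintf("hybrids absent from markers: %s",
                                  paste(head(orphan, 5), collapse = ", ")))
    }
  }
  if (length(problems) == 0) {
    tibble(file = character(0), problem = character(0))
  } else {
    bind_rows(problems)
  }
}
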