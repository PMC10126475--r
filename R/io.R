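# Plain-text readers/writers for every artifact, so each stage of the
# pipeline can be cached, inspected, and re-consumed.

#' Write / read a simulated trial as CSV files
#'
#' Writes `records.csv`, `biomass.csv`, `weather.csv`, `dates.csv`,
#' `spectra.csv` (wide: one row per plot-date, columns = wavelengths),
#' `clouds.csv` (XYZ with ground label), and `truth.json`.
#'
#' @param trial A `trial_data`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(trial$records, file.path(dir, "records.csv"))
  readr::write_csv(trial$biomass, file.path(dir, "biomass.csv"))
  readr::write_csv(trial$weather, file.path(dir, "weather.csv"))
  readr::write_csv(trial$dates, file.path(dir, "dates.csv"))
  readr::write_csv(trial$spectra, file.path(dir, "spectra.csv"))
  readr::write_csv(trial$clouds, file.path(dir, "clouds.csv"))
  truth <- trial$truth
  truth$hybrid_latents <- as.list(truth$hybrid_latents)
  truth$canopy_height <- NULL
  jsonlite::write_json(
    c(truth, list(trial_id = trial$trial_id, panel = trial$panel,
                  shifted = trial$shifted)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_trial
#' @export
read_trial <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  spec_types <- readr::cols(plot_id = readr::col_character(),
                            .default = readr::col_double())
  structure(
    list(
      records = readr::read_csv(file.path(dir, "records.csv"),
                                show_col_types = FALSE),
      biomass = readr::read_csv(file.path(dir, "biomass.csv"),
                                show_col_types = FALSE),
      weather = readr::read_csv(file.path(dir, "weather.csv"),
                                show_col_types = FALSE),
      dates = readr::read_csv(file.path(dir, "dates.csv"),
                              show_col_types = FALSE),
      spectra = readr::read_csv(file.path(dir, "spectra.csv"),
                                col_types = spec_types),
      clouds = readr::read_csv(file.path(dir, "clouds.csv"),
                               show_col_types = FALSE),
      truth = truth,
      trial_id = truth$trial_id, panel = truth$panel,
      shifted = isTRUE(truth$shifted)
    ),
    class = "trial_data"
  )
}

#' Write / read a marker matrix as CSV
#'
#' One row per hybrid, first column `hybrid_id`, remaining columns markers.
#'
#' @param markers A `marker_matrix` (or plain matrix with rownames).
#' @param path CSV path.
#' @return `path` / the matrix.
#' @export
write_markers <- function(markers, path) {
  df <- as_tibble(unclass(as.matrix(markers)))
  df <- dplyr::bind_cols(tibble(hybrid_id = rownames(markers)), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$hybrid_id
  class(m) <- c("marker_matrix", "matrix", "array")
  m
}

#' Write / read a feature tensor as long CSV plus a JSON schema sidecar
#'
#' @param tensor A `feature_tensor`.
#' @param dir Output directory.
#' @return `dir` / the tensor.
#' @export
write_tensor <- function(tensor, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tidy(tensor), file.path(dir, "features.csv"))
  jsonlite::write_json(
    list(features = tensor$features, dates = tensor$dates),
    file.path(dir, "schema.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_tensor
#' @export
read_tensor <- function(dir) {
  schema <- jsonlite::read_json(file.path(dir, "schema.json"),
                                simplifyVector = TRUE)
  long <- readr::read_csv(file.path(dir, "features.csv"),
                          show_col_types = FALSE)
  feats <- as_tibble(schema$features)
  dates <- as_tibble(schema$dates)
  plot_ids <- unique(long$plot_id)
  tensor <- assemble_feature_tensor(
    long, tibble(plot_id = plot_ids), dates, validate_catalog(feats))
  imput <- long %>% filter(.data$imputed)
  if (nrow(imput) > 0) {
    ip <- match(imput$plot_id, tensor$plot_ids)
    jf <- match(imput$feature, tensor$features$name)
    kd <- match(imput$date, tensor$dates$date)
    tensor$imputed[cbind(ip, jf, kd)] <- TRUE
  }
  tensor
}

#' Serialize / restore a trained model as a JSON archive
#'
#' Weights, configuration, schema fingerprint, normalization statistics and
#' training history in one plain-text file.
#'
#' @param model An `rnng_model`.
#' @param path File path (`.json`).
#' @return `path` / the model.
#' @export
write_model <- function(model, path) {
  ser <- list(
    params = model$params,
    config = unclass(model$config),
    fingerprint = model$fingerprint,
    norm = model$norm,
    history = model$history,
    best_epoch = model$best_epoch,
    n_parameters = model$n_parameters
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  ser$history <- jsonlite::read_json(path, simplifyVector = TRUE)$history
  params <- ser$params
  params$w_h <- as.numeric(params$w_h)
  params$w_s <- as.numeric(params$w_s)
  params$b_out <- as.numeric(params$b_out)
  as_mat <- function(m) if (is.matrix(m)) m else matrix(m, nrow = 1)
  params$layers <- lapply(params$layers, function(l) {
    list(W = as_mat(l$W), U = as_mat(l$U), b = as.numeric(l$b))
  })
  fp <- ser$fingerprint
  fp$cluster_levels <- as.integer(fp$cluster_levels)
  structure(
    list(params = params,
         config = do.call(rnng_config, ser$config),
         fingerprint = fp,
         norm = list(mu = unlist(ser$norm$mu), sigma = unlist(ser$norm$sigma),
                     y_mu = ser$norm$y_mu, y_sd = ser$norm$y_sd),
         history = as_tibble(ser$history),
         best_epoch = ser$best_epoch,
         n_parameters = ser$n_parameters),
    class = "rnng_model")
}
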