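# Plain-text session interchange: a session directory holds
#   meta.json      recording metadata (fs, layout, config)
#   signal.tsv     samples x channels signal matrix
#   joystick.tsv   x / y joystick trace
#   trials.csv     event table (trial, target_index, target_time_s,
#                  cursor_time_s, onset_time_s, hit_time_s)
#   truth.json + latent.tsv   optional generator ground truth
# Everything is human-readable and diff-able; large matrices go through
# data.table for speed.

#' Write a session to a directory
#'
#' @param session an `ecog_session`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(fs = session$fs, n_channels = nrow(session$signal),
               n_samples = ncol(session$signal),
               n_directions = session$n_directions,
               max_radial_extension = session$max_radial_extension,
               config = unclass(session$config))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  sig <- data.table::as.data.table(t(session$signal))
  data.table::setnames(sig, paste0("ch", seq_len(nrow(session$signal))))
  data.table::fwrite(sig, file.path(path, "signal.tsv"), sep = "\t")
  joy <- data.table::data.table(x = session$joystick[1, ],
                                y = session$joystick[2, ])
  data.table::fwrite(joy, file.path(path, "joystick.tsv"), sep = "\t")
  tr <- session$trials
  ev <- data.frame(trial = tr$trial, target_index = tr$target_index,
                   target_time_s = tr$target_time,
                   cursor_time_s = tr$cursor_time,
                   onset_time_s = tr$onset_time %||% NA,
                   hit_time_s = tr$hit_time %||% NA)
  data.table::fwrite(ev, file.path(path, "trials.csv"))
  if (!is.null(session$truth)) {
    tru <- session$truth
    jsonlite::write_json(
      list(directions = tru$directions, onset_step = tru$onset_step,
           onset_time = tru$onset_time, move_time = tru$move_time,
           motor_channels = tru$motor_channels,
           active_features = tru$active_features,
           feature_mod_sd = tru$feature_mod_sd,
           coefs = lapply(tru$coefs, function(k)
             list(A = k$A, S = k$S, order = k$order))),
      file.path(path, "truth.json"), digits = NA)
    data.table::fwrite(data.table::as.data.table(tru$latent),
                       file.path(path, "latent.tsv"), sep = "\t")
  }
  invisible(path)
}

#' Read a session from a directory
#'
#' Validates the layout (missing pieces produce errors naming the file) and
#' the invariants: all event times inside the recording, target indices
#' below the number of directions.
#'
#' @param path session directory written by [write_session()].
#' @return an `ecog_session`.
#' @export
read_session <- function(path) {
  need <- c("meta.json", "signal.tsv", "joystick.tsv", "trials.csv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing)) {
    stop("session at ", path, " is missing: ",
         paste(missing, collapse = ", "))
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  sig <- t(as.matrix(data.table::fread(file.path(path, "signal.tsv"))))
  joy <- as.matrix(data.table::fread(file.path(path, "joystick.tsv")))
  ev <- data.table::fread(file.path(path, "trials.csv"),
                          data.table = FALSE)
  trials <- data.frame(trial = ev$trial, target_index = ev$target_index,
                       target_time = ev$target_time_s,
                       cursor_time = ev$cursor_time_s,
                       onset_time = ev$onset_time_s,
                       hit_time = ev$hit_time_s)
  duration <- ncol(sig) / meta$fs
  if (any(trials$target_time < 0 | trials$cursor_time > duration,
          na.rm = TRUE)) {
    stop("trial event times fall outside the recording")
  }
  if (any(trials$target_index < 0 |
            trials$target_index >= meta$n_directions)) {
    stop("target_index out of range for ", meta$n_directions, " directions")
  }
  truth <- NULL
  if (file.exists(file.path(path, "truth.json"))) {
    tj <- jsonlite::read_json(file.path(path, "truth.json"),
                              simplifyVector = FALSE)
    as_mat <- function(x) do.call(rbind, lapply(x, function(r)
      as.numeric(unlist(r))))
    truth <- list(
      directions = as.integer(unlist(tj$directions)),
      onset_step = as.integer(unlist(tj$onset_step)),
      onset_time = as.numeric(unlist(tj$onset_time)),
      move_time = as.numeric(unlist(tj$move_time)),
      motor_channels = as.integer(unlist(tj$motor_channels)),
      active_features = as.integer(unlist(tj$active_features)),
      feature_mod_sd = as.numeric(unlist(tj$feature_mod_sd)),
      coefs = lapply(tj$coefs, function(k)
        list(A = as_mat(k$A), S = as_mat(k$S),
             order = as.integer(unlist(k$order)))))
    if (file.exists(file.path(path, "latent.tsv"))) {
      truth$latent <- as.matrix(data.table::fread(
        file.path(path, "latent.tsv")))
      dimnames(truth$latent) <- NULL
    }
    truth$window_steps <- lapply(truth$onset_step,
                                 function(s) (s - 10L):(s - 1L))
  }
  cfg <- meta$config
  if (!is.null(cfg)) class(cfg) <- "sim_config"
  structure(list(signal = unname(sig), joystick = rbind(x = joy[, 1],
                                                        y = joy[, 2]),
                 fs = meta$fs, trials = trials,
                 max_radial_extension = meta$max_radial_extension,
                 n_directions = meta$n_directions, truth = truth,
                 config = cfg),
            class = "ecog_session")
}

#' Write a feature series as TSV
#'
#' One row per 100 ms step: `step_time` plus one column per
#' (channel, band) feature.
#'
#' @param features a [feature_series()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  dt <- data.table::data.table(step_time = features$step_times)
  dt <- cbind(dt, data.table::as.data.table(features$values))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a feature series from TSV
#'
#' @param path file written by [write_features()].
#' @return a [feature_series()].
#' @export
read_features <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE)
  cols <- setdiff(names(dt), "step_time")
  parts <- regmatches(cols, regexec("^ch([0-9]+)_(mu|beta|gamma|lmp)$",
                                    cols))
  if (any(lengths(parts) != 3)) {
    stop("unrecognized feature columns in ", path)
  }
  labels <- data.frame(
    channel = as.integer(vapply(parts, `[`, character(1), 2)),
    band = vapply(parts, `[`, character(1), 3))
  feature_series(as.matrix(dt[cols]), dt$step_time, labels)
}

#' Serialize a direction model set to JSON
#'
#' The documented structure is a list of per-direction models; each model
#' carries `T`, `M`, `lambda` and, per slice and node, the temporal/spatial
#' parent indices and coefficients, plus the shared standardization scaler.
#'
#' @param models a `direction_model_set`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_direction_models <- function(models, path) {
  ser <- list(
    n_directions = models$n_directions, lambda = models$lambda,
    scaler = models$scaler,
    models = lapply(models$models, function(m)
      list(direction = m$direction, T = m$T, M = m$M, lambda = m$lambda,
           n_trials = m$n_trials,
           slices = lapply(m$slices, function(sl) lapply(sl, function(nd)
             list(tpar = nd$tpar, tcoef = nd$tcoef,
                  spar = nd$spar, scoef = nd$scoef))))))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a direction model set from JSON
#'
#' @param path file written by [write_direction_models()].
#' @return a `direction_model_set`.
#' @export
read_direction_models <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  scaler <- list(
    center = do.call(rbind, lapply(ser$scaler$center, unlist)),
    scale = do.call(rbind, lapply(ser$scaler$scale, unlist)))
  models <- lapply(ser$models, function(m) {
    structure(list(
      T = m$T, M = m$M, lambda = m$lambda, direction = m$direction,
      n_trials = m$n_trials, scaler = scaler,
      slices = lapply(m$slices, function(sl) lapply(sl, function(nd)
        list(tpar = as.integer(unlist(nd$tpar)),
             tcoef = as.numeric(unlist(nd$tcoef)),
             spar = as.integer(unlist(nd$spar)),
             scoef = as.numeric(unlist(nd$scoef)))))),
      class = "mtvdbn_model")
  })
  structure(list(models = models, lambda = ser$lambda, scaler = scaler,
                 n_directions = ser$n_directions),
            class = "direction_model_set")
}
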