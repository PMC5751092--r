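# Fixed-format storage: one CSV per trial (header row naming the 14
# channels) plus a JSON sidecar with metadata and ground truth; models and
# reports as JSON.

#' Write a trial to CSV + JSON sidecar
#'
#' The CSV holds one row per sample and one column per channel; the sidecar
#' carries metadata, the ground-truth transition intervals (0-based,
#' half-open sample indices) and the run-length-encoded posture timeline.
#'
#' @param trial A `sensor_trial`.
#' @param dir Output directory (created if needed).
#' @param stem File stem; defaults to
#'   `trial_s<subject>_a<activity>[_p<position>]`.
#' @return The stem path, invisibly.
#' @export
write_trial <- function(trial, dir, stem = NULL) {
  stopifnot(inherits(trial, "sensor_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(stem))
    stem <- sprintf("trial_s%02d_a%02d%s", trial$subject_id, trial$activity_id,
                    if (is.na(trial$position_id)) ""
                    else sprintf("_p%d", trial$position_id))
  path <- file.path(dir, stem)
  readr::write_csv(tibble::as_tibble(as.data.frame(trial$signal)),
                   paste0(path, ".csv"))
  r <- rle(trial$truth_posture)
  jsonlite::write_json(list(
    subject_id = trial$subject_id, activity_id = trial$activity_id,
    position_id = trial$position_id, sample_rate = trial$sample_rate,
    seed = trial$seed,
    transitions = trial$transitions,
    posture_rle = list(lengths = r$lengths, values = r$values)
  ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a trial written by [write_trial()]
#'
#' @param stem Path stem (no extension) or the `.csv` path.
#' @return A `sensor_trial`.
#' @export
read_trial <- function(stem) {
  stem <- sub("\\.(csv|json)$", "", stem)
  sig <- as.matrix(readr::read_csv(paste0(stem, ".csv"),
                                   show_col_types = FALSE))
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  tr <- meta$transitions
  tr <- if (is.null(tr) || !length(tr))
    tibble::tibble(onset = integer(), offset = integer(),
                   direction = character())
  else tibble::as_tibble(tr)
  structure(list(
    subject_id = meta$subject_id, activity_id = meta$activity_id,
    position_id = if (is.null(meta$position_id)) NA_integer_
    else meta$position_id,
    sample_rate = meta$sample_rate, signal = sig, transitions = tr,
    truth_posture = inverse.rle(structure(
      list(lengths = as.integer(meta$posture_rle$lengths),
           values = meta$posture_rle$values), class = "rle")),
    seed = meta$seed
  ), class = "sensor_trial")
}

#' Write a whole dataset to disk
#'
#' @param dataset A `sist_dataset`.
#' @param dir Output directory; trials go to `dir/trials`, the trial index
#'   to `dir/index.csv`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sist_dataset"))
  dir.create(file.path(dir, "trials"), showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(dataset$trials))
    write_trial(dataset$trials[[i]], file.path(dir, "trials"),
                stem = sprintf("trial_%03d", i))
  readr::write_csv(dataset$index, file.path(dir, "index.csv"))
  invisible(dir)
}

elm_to_list <- function(m) {
  list(kind = "elm", a = m$a, b = m$b, beta = as.numeric(m$beta),
       n_hidden = m$n_hidden, input_dim = m$input_dim, n_train = m$n_train,
       seed = m$seed, ridge = m$ridge, feature_names = m$feature_names)
}

mlp_to_list <- function(m) {
  list(kind = "mlp", W1 = m$W1, th1 = m$th1, W2 = as.numeric(m$W2),
       th2 = m$th2, n_hidden = m$n_hidden, input_dim = m$input_dim,
       n_train = m$n_train, seed = m$seed, epochs_run = m$epochs_run,
       feature_names = m$feature_names,
       control = unclass(m$control))
}

classifier_from_list <- function(l) {
  if (l$kind == "elm") {
    structure(list(a = matrix(unlist(l$a), nrow = l$n_hidden),
                   b = as.numeric(l$b),
                   beta = matrix(as.numeric(l$beta), ncol = 1),
                   n_hidden = l$n_hidden, input_dim = l$input_dim,
                   n_train = l$n_train, seed = l$seed,
                   ridge = if (is.null(l$ridge)) 0 else l$ridge,
                   feature_names = l$feature_names), class = "elm")
  } else {
    structure(list(W1 = matrix(unlist(l$W1), ncol = l$n_hidden),
                   th1 = as.numeric(l$th1),
                   W2 = matrix(as.numeric(l$W2), ncol = 1),
                   th2 = l$th2, n_hidden = l$n_hidden,
                   input_dim = l$input_dim, n_train = l$n_train,
                   seed = l$seed, epochs_run = l$epochs_run,
                   control = do.call(mlp_control, l$control[
                     c("learn_rate", "momentum", "max_epochs", "patience",
                       "val_fraction")]),
                   feature_names = l$feature_names), class = "mlp")
  }
}

stage_to_list <- function(s) {
  list(classifier = if (inherits(s$classifier, "elm"))
    elm_to_list(s$classifier) else mlp_to_list(s$classifier),
    bounds = as.data.frame(s$bounds), selected = as.data.frame(s$selected),
    k = s$k)
}

stage_from_list <- function(l) {
  list(classifier = classifier_from_list(l$classifier),
       bounds = structure(tibble::as_tibble(l$bounds),
                          class = c("norm_bounds", "tbl_df", "tbl",
                                    "data.frame")),
       selected = tibble::as_tibble(l$selected), k = l$k)
}

#' Serialize a cascade model to JSON
#'
#' @param model A `cascade_model`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cascade_model"))
  ctl <- unclass(model$control)
  ctl$mlp <- unclass(ctl$mlp)
  jsonlite::write_json(list(
    stage1 = stage_to_list(model$stage1), stage2 = stage_to_list(model$stage2),
    k = model$k, control = ctl, epoch_length = model$epoch_length,
    sample_rate = model$sample_rate, seed = model$seed
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a cascade model written by [write_model()]
#'
#' @param path `.json` path.
#' @return A `cascade_model`.
#' @export
read_model <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  ctl <- l$control
  mlp <- do.call(mlp_control, ctl$mlp[c("learn_rate", "momentum", "max_epochs",
                                        "patience", "val_fraction")])
  control <- do.call(cascade_control, c(
    ctl[c("gate_enter", "gate_hangover", "classifier", "bins", "mrmr_pool",
          "mrmr_depth", "ffs_patience", "ffs_max_features", "ffs_hidden",
          "ffs_subsample", "elm_hidden", "mlp_hidden", "elm_ridge",
          "balance_max")],
    list(mlp = mlp)))
  structure(list(stage1 = stage_from_list(l$stage1),
                 stage2 = stage_from_list(l$stage2), k = l$k,
                 control = control, epoch_length = l$epoch_length,
                 sample_rate = l$sample_rate, seed = l$seed),
            class = "cascade_model")
}
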