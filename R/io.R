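# File I/O: trial-set containers, reports, run configurations.
#
# The native container is an RDS file holding the `X` (trials x channels x
# samples), `y` (labels) and `sfreq` entries; a plain-text CSV layout (one
# row per trial-channel, with a JSON sidecar for metadata) is provided for
# interoperability. HDF5/NPZ readers are not bundled -- converting from those
# containers is a two-line job in any scientific Python/R session and keeps
# this package dependency-light (see README).

#' Save a trial set
#'
#' @param trials a [raw_trialset()].
#' @param path output file; `.rds` or `.csv` (a `.json` metadata sidecar is
#'   written next to a CSV).
#' @param layout `"rds"` or `"csv"`; inferred from the extension by default.
#' @export
save_trialset <- function(trials, path, layout = NULL) {
  layout <- layout %||% guess_layout(path)
  if (!inherits(trials, "raw_trialset"))
    amanet_abort("amanet_io_error", "trials must be a raw_trialset")
  if (layout == "rds") {
    saveRDS(list(X = trials$data, y = trials$labels, sfreq = trials$sfreq,
                 channel_names = trials$channel_names), path)
  } else if (layout == "csv") {
    d <- dim(trials$data)
    flat <- matrix(aperm(trials$data, c(3, 2, 1)), nrow = d[1] * d[2],
                   byrow = TRUE)
    df <- data.frame(trial = rep(seq_len(d[1]), each = d[2]),
                     label = rep(trials$labels, each = d[2]),
                     channel = rep(seq_len(d[2]), d[1]))
    utils::write.csv(cbind(df, flat), path, row.names = FALSE)
    jsonlite::write_json(list(sfreq = trials$sfreq, n_trials = d[1],
                              n_channels = d[2], n_samples = d[3],
                              channel_names = trials$channel_names),
                         sidecar_path(path), auto_unbox = TRUE, digits = NA)
  } else {
    amanet_abort("amanet_io_error", sprintf("unknown layout '%s'", layout))
  }
  invisible(path)
}

guess_layout <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("rds", "csv")) ext
  else amanet_abort("amanet_io_error", sprintf(
    "cannot infer layout from extension '.%s'; pass layout=", ext))
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path, ignore.case = TRUE)

#' Load a trial set
#'
#' Validates the container schema (`X` of shape `n x C x T`, `y` of length
#' `n`, scalar `sfreq`) and remaps labels to contiguous `0 .. K-1`, recording
#' the mapping in attribute `"label_map"`.
#'
#' @param path input file written by [save_trialset()].
#' @param layout `"rds"` or `"csv"`; inferred from the extension by default.
#' @return a [raw_trialset()].
#' @export
load_trialset <- function(path, layout = NULL) {
  if (!file.exists(path))
    amanet_abort("amanet_io_error", sprintf("file not found: %s", path))
  layout <- layout %||% guess_layout(path)
  if (layout == "rds") {
    obj <- readRDS(path)
    for (key in c("X", "y", "sfreq")) {
      if (is.null(obj[[key]]))
        amanet_abort("amanet_io_error", sprintf(
          "container is missing required entry '%s'", key))
    }
    X <- obj$X; y <- obj$y; sfreq <- obj$sfreq
    channel_names <- obj$channel_names
  } else {
    df <- utils::read.csv(path)
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    n <- meta$n_trials; C <- meta$n_channels; Tn <- meta$n_samples
    vals <- as.matrix(df[, -(1:3), drop = FALSE])
    X <- array(0, dim = c(n, C, Tn))
    for (i in seq_len(nrow(df)))
      X[df$trial[i], df$channel[i], ] <- vals[i, ]
    y <- df$label[df$channel == 1]
    sfreq <- meta$sfreq
    channel_names <- meta$channel_names
    if (length(channel_names) == 0) channel_names <- NULL
  }
  if (length(dim(X)) != 3L)
    amanet_abort("amanet_io_error", "X must be a trials x channels x samples array")
  if (length(y) != dim(X)[1])
    amanet_abort("amanet_dim_error", sprintf(
      "y has length %d but X holds %d trials", length(y), dim(X)[1]))
  uy <- sort(unique(as.integer(y)))
  mapped <- match(as.integer(y), uy) - 1L
  ts <- raw_trialset(X, mapped, sfreq, channel_names)
  attr(ts, "label_map") <- stats::setNames(seq_along(uy) - 1L, uy)
  if (!identical(uy, seq_along(uy) - 1L))
    message(sprintf("labels remapped: %s",
                    paste(sprintf("%d->%d", uy, seq_along(uy) - 1L),
                          collapse = ", ")))
  ts
}

fold_to_json <- function(f) {
  list(fold_id = f$fold_id, window_accuracy = f$window_accuracy,
       trial_accuracy = f$trial_accuracy, kappa = f$kappa,
       confusion = f$confusion, loss_curve = f$loss_curve,
       bank_hash = f$bank_hash %||% NA_character_)
}

#' Save a cross-validation report or sweep table
#'
#' Reports are serialized to JSON (schema version 1, confusion matrices as
#' integer arrays, no timestamps so repeated runs are byte-identical); sweep
#' tables go to CSV.
#'
#' @param report a `cv_report` or a sweep `data.frame`.
#' @param path output path (`.json` for reports, `.csv` for tables).
#' @export
save_report <- function(report, path) {
  if (inherits(report, "cv_report")) {
    out <- list(schema = "amanet-cv-report/1",
                n_folds = report$n_folds,
                split_level = report$split_level,
                mean_accuracy = report$mean_accuracy,
                sd_accuracy = report$sd_accuracy,
                mean_kappa = report$mean_kappa,
                sd_kappa = report$sd_kappa,
                mean_trial_accuracy = report$mean_trial_accuracy,
                folds = lapply(report$folds, fold_to_json))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else if (is.data.frame(report)) {
    utils::write.csv(report, path, row.names = FALSE)
  } else {
    amanet_abort("amanet_io_error", "report must be a cv_report or a data.frame")
  }
  invisible(path)
}

#' Load a report saved by [save_report()]
#'
#' @param path a `.json` report or `.csv` table.
#' @return a list (reports) or data.frame (tables).
#' @export
load_report <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    scalars <- c("schema", "n_folds", "split_level", "mean_accuracy",
                 "sd_accuracy", "mean_kappa", "sd_kappa",
                 "mean_trial_accuracy")
    out <- lapply(obj[intersect(scalars, names(obj))], function(v)
      if (is.null(v)) NA else v)
    out$folds <- lapply(obj$folds, function(f) {
      cm <- do.call(rbind, lapply(f$confusion, unlist))
      list(fold_id = f$fold_id,
           window_accuracy = f$window_accuracy,
           trial_accuracy = f$trial_accuracy,
           kappa = f$kappa,
           confusion = matrix(as.integer(cm), nrow(cm), ncol(cm)),
           loss_curve = as.numeric(unlist(f$loss_curve)),
           bank_hash = f$bank_hash)
    })
    out
  } else if (ext == "csv") {
    utils::read.csv(path)
  } else {
    amanet_abort("amanet_io_error", sprintf("unknown report extension '.%s'", ext))
  }
}

#' Assemble a run configuration
#'
#' A serializable bundle of augmentation, model and training settings plus
#' optional synthetic-data parameters; round-trips losslessly through JSON.
#'
#' @param aug an [aug_config()] (or named list of overrides).
#' @param model a [model_config()] (or named list of overrides).
#' @param train a [train_config()] (or named list of overrides).
#' @param simulate named list passed to [make_separable_spec()] for the
#'   `simulate` command (`n_channels`, `difficulty`, `n_trials_per_class`,
#'   `seed`).
#' @return an object of class `run_config`.
#' @export
run_config <- function(aug = list(), model = list(), train = list(),
                       simulate = list()) {
  mk <- function(ctor, x) {
    if (inherits(x, c("aug_config", "model_config", "train_config"))) return(x)
    do.call(ctor, x)
  }
  structure(list(aug = mk(aug_config, aug), model = mk(model_config, model),
                 train = mk(train_config, train), simulate = simulate),
            class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path JSON file path.
#' @export
save_run_config <- function(cfg, path) {
  jsonlite::write_json(lapply(unclass(cfg), unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(aug = as.list(obj$aug %||% list()),
             model = as.list(obj$model %||% list()),
             train = as.list(obj$train %||% list()),
             simulate = as.list(obj$simulate %||% list()))
}
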