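# Readers and writers. Two epoch container formats are supported: "rds"
# (single R-native file) and "dir" (a directory of plain-text files:
# meta.json, data.csv with one row per channel/sample/event cell in long
# layout, and events.csv). Event tables travel as CSV with headers
# stimID_1..stimID_q, trgtID, seqID; an absent/all-missing trgtID column
# means binary mode.

#' Write an epoch container
#'
#' @param epochs an [epoch_array].
#' @param events the matching [event_table].
#' @param path output file (`format = "rds"`) or directory (`format = "dir"`).
#' @param format `"rds"` or `"dir"` (plain text).
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, events, path, format = c("rds", "dir")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(list(data = epochs$data, fs = epochs$fs,
                 channel_names = epochs$channel_names, t0 = epochs$t0,
                 stimID = events$stimID, trgtID = events$trgtID,
                 seqID = events$seqID,
                 n_repetitions = attr(events, "n_repetitions")),
            path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    d <- dim(epochs$data)
    meta <- list(fs = epochs$fs, t0 = epochs$t0,
                 channel_names = epochs$channel_names,
                 dims = list(channels = d[1], samples = d[2], events = d[3]),
                 n_repetitions = attr(events, "n_repetitions"))
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
               file.path(path, "meta.json"))
    # long layout: sample index fastest, then event, one column per channel
    flat <- matrix(aperm(epochs$data, c(2L, 3L, 1L)), ncol = d[1])
    df <- data.frame(event = rep(seq_len(d[3]), each = d[2]),
                     sample = rep(seq_len(d[2]), d[3]))
    df[epochs$channel_names] <- as.data.frame(flat)
    utils::write.csv(df, file.path(path, "data.csv"), row.names = FALSE)
    write_events_csv(events, file.path(path, "events.csv"))
  }
  invisible(path)
}

#' Read an epoch container
#'
#' @param path file or directory written by [write_epochs].
#' @param format `"rds"` or `"dir"`.
#' @return list with `epochs` and `events`, validated.
#' @export
read_epochs <- function(path, format = c("rds", "dir")) {
  format <- match.arg(format)
  if (format == "rds") {
    x <- readRDS(path)
    req <- c("data", "fs", "seqID", "stimID")
    miss <- setdiff(req, names(x))
    if (length(miss))
      stop_named(paste0("missing_", miss[1]),
                 paste("container lacks field(s):", paste(miss, collapse = ", ")))
    epochs <- epoch_array(x$data, x$fs, x$channel_names, x$t0 %||% 0)
    events <- event_table(x$stimID, x$trgtID, x$seqID)
    attr(events, "n_repetitions") <- x$n_repetitions
  } else {
    meta <- jsonlite::fromJSON(file.path(path, "meta.json"))
    df <- utils::read.csv(file.path(path, "data.csv"), check.names = FALSE)
    d <- c(meta$dims$channels, meta$dims$samples, meta$dims$events)
    flat <- as.matrix(df[, meta$channel_names, drop = FALSE])
    data <- aperm(array(as.numeric(flat), c(d[2], d[3], d[1])), c(3L, 1L, 2L))
    epochs <- epoch_array(data, meta$fs, meta$channel_names, meta$t0 %||% 0)
    events <- read_events_csv(file.path(path, "events.csv"))
    attr(events, "n_repetitions") <- meta$n_repetitions
  }
  v <- validate_epochs(epochs, events)
  if (!v$ok)
    stop("invalid container: ", paste(names(v$violations), collapse = ", "))
  list(epochs = epochs, events = events)
}

#' Write an event table as CSV
#'
#' Columns `stimID_1..stimID_q`, `trgtID` (empty in binary mode) and
#' `seqID`.
#'
#' @param events an [event_table].
#' @param path output CSV path.
#' @export
write_events_csv <- function(events, path) {
  q <- ncol(events$stimID)
  df <- as.data.frame(events$stimID)
  names(df) <- paste0("stimID_", seq_len(q))
  df$trgtID <- if (is.null(events$trgtID)) NA_integer_ else events$trgtID
  df$seqID <- events$seqID
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an event table from CSV
#'
#' @param path CSV written by [write_events_csv] (or hand-made with the same
#'   headers).
#' @return an [event_table]; an absent or all-missing `trgtID` column yields
#'   binary mode.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path)
  sc <- grep("^stimID(_\\d+)?$", names(df), value = TRUE)
  if (!length(sc)) stop_named("missing_stimID", "no stimID column(s)")
  if (!"seqID" %in% names(df)) stop_named("missing_seqID", "no seqID column")
  stim <- unname(as.matrix(df[sc]))
  trgt <- if ("trgtID" %in% names(df) && !all(is.na(df$trgtID)))
    df$trgtID else NULL
  event_table(stim, trgt, df$seqID)
}

#' Write decoding outputs
#'
#' Produces a readable prediction file (`decoded.txt`: the spelled string
#' when an alphabet is configured, one class index per line otherwise), a
#' per-class score table (`scores.csv`) and, if metrics are supplied, a
#' `metrics.json`.
#'
#' @param predictions result of [predict.erp_decoder].
#' @param dir output directory (created if needed).
#' @param alphabet optional character vector for readable output.
#' @param metrics optional list (e.g. a [cross_validate_decoder] result)
#'   serialized as JSON.
#' @return `dir`, invisibly.
#' @export
write_predictions <- function(predictions, dir, alphabet = NULL,
                              metrics = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  txt <- if (!is.null(alphabet)) map_alphabet(predictions$class, alphabet)
         else as.character(predictions$class)
  writeLines(txt, file.path(dir, "decoded.txt"))
  scores <- attr(predictions, "scores")
  if (!is.null(scores)) {
    sdf <- as.data.frame(scores)
    names(sdf) <- paste0("class_", seq_len(ncol(sdf)))
    utils::write.csv(cbind(predictions["class"], sdf),
                     file.path(dir, "scores.csv"), row.names = FALSE)
  }
  if (!is.null(metrics))
    writeLines(metrics_json(metrics), file.path(dir, "metrics.json"))
  invisible(dir)
}

#' Serialize metrics deterministically
#'
#' Stable JSON serialization (full precision, unboxed scalars) so identical
#' configurations and seeds reproduce bit-identical metrics files.
#'
#' @param metrics a list of metrics (e.g. from [cross_validate_decoder]).
#' @return a JSON string.
#' @export
metrics_json <- function(metrics) {
  as.character(jsonlite::toJSON(metrics, auto_unbox = TRUE, digits = NA,
                                matrix = "rowmajor"))
}

#' Read a run configuration (YAML or JSON)
#'
#' Top-level keys may be `preprocess`, `decoder`, `io`, `folds`, `seed`;
#' unknown keys are rejected. The `decoder` section is passed to
#' [decoder_config].
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return a list with a validated `decoder` entry.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  allowed <- c("preprocess", "decoder", "io", "folds", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop_named("unknown_config_keys",
               paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  if (!is.null(cfg$decoder)) cfg$decoder <- do.call(decoder_config, cfg$decoder)
  cfg
}
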