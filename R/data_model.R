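#' Epoched multichannel recordings
#'
#' Container for epoched electrophysiological data: a numeric tensor of size
#' channels x samples x events together with the sampling rate, channel
#' labels, and the epoch start time relative to event onset.
#'
#' @param data numeric array `[d1 channels x m samples x E events]`. A matrix
#'   is treated as a single epoch.
#' @param fs sampling rate in Hz.
#' @param channel_names optional character vector of length `d1`.
#' @param t0 epoch start time relative to event onset, in seconds
#'   (default 0: the first sample coincides with the event onset).
#' @return an object of class `epoch_array`.
#' @export
epoch_array <- function(data, fs, channel_names = NULL, t0 = 0) {
  if (is.matrix(data)) data <- array(data, c(nrow(data), ncol(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a channels x samples x events array")
  d <- dim(data)
  if (d[1] < 1L || d[2] < 2L || d[3] < 1L)
    stop("need at least 1 channel, 2 samples and 1 event")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(d[1]))
  if (length(channel_names) != d[1])
    stop("`channel_names` must have one entry per channel")
  structure(
    list(data = data, fs = fs, channel_names = as.character(channel_names),
         t0 = as.numeric(t0)),
    class = "epoch_array"
  )
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_array> %d channels x %d samples x %d events @ %g Hz (t0 = %g s)\n",
              d[1], d[2], d[3], x$fs, x$t0))
  invisible(x)
}

#' @export
dim.epoch_array <- function(x) dim(x$data)

# Subset events (third dimension), keeping metadata.
subset_epochs <- function(epochs, idx) {
  epoch_array(epochs$data[, , idx, drop = FALSE], epochs$fs,
              epochs$channel_names, epochs$t0)
}

#' Per-event stimulus bookkeeping
#'
#' An event table links each epoch to the stimulated class(es) (`stimID`),
#' the attended target class of its trial/sequence (`trgtID`, absent in
#' binary single-trial mode), and a sequence identifier (`seqID`) grouping
#' the epochs that jointly encode one selection. Identifiers are 1-based;
#' in `stimID` a 0 is allowed as padding for ragged rows of simultaneously
#' highlighted classes (matrix spellers highlight a whole row or column of
#' characters at once) and is ignored.
#'
#' @param stimID integer vector of length E or matrix `[E x q]` (q classes
#'   highlighted simultaneously per event).
#' @param trgtID integer vector of length E, or `NULL` for binary mode.
#' @param seqID integer vector of length E.
#' @return an object of class `event_table`.
#' @export
event_table <- function(stimID, trgtID = NULL, seqID) {
  if (!is.matrix(stimID)) stimID <- matrix(as.integer(stimID), ncol = 1L)
  storage.mode(stimID) <- "integer"
  E <- nrow(stimID)
  seqID <- as.integer(seqID)
  if (length(seqID) != E) stop("`seqID` must have one entry per event")
  if (!is.null(trgtID)) {
    trgtID <- as.integer(trgtID)
    if (length(trgtID) != E) stop("`trgtID` must have one entry per event")
  }
  structure(list(stimID = stimID, trgtID = trgtID, seqID = seqID),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events, %d simultaneous stimulus column(s), %d sequence(s)%s\n",
              nrow(x$stimID), ncol(x$stimID), length(unique(x$seqID)),
              if (is.null(x$trgtID)) " [binary mode]" else ""))
  invisible(x)
}

n_events <- function(events) nrow(events$stimID)

subset_events <- function(events, idx) {
  event_table(events$stimID[idx, , drop = FALSE],
              if (!is.null(events$trgtID)) events$trgtID[idx],
              events$seqID[idx])
}

# TRUE for each event whose stimID row contains class `cl` (0-padding ignored).
stim_hits <- function(events, cl) {
  rowSums(events$stimID == cl) > 0L
}

# E x C logical membership matrix: event e stimulated class c.
stim_hit_matrix <- function(events, C) {
  E <- n_events(events)
  hit <- matrix(FALSE, E, C)
  q <- ncol(events$stimID)
  for (j in seq_len(q)) {
    v <- events$stimID[, j]
    ok <- v >= 1L & v <= C
    hit[cbind(which(ok), v[ok])] <- TRUE
  }
  hit
}

# Per-event condition: TRUE = target (sequence mode: the sequence's target
# class was among the highlighted classes; binary mode: stimID == 1).
event_is_target <- function(events) {
  if (is.null(events$trgtID)) {
    events$stimID[, 1] == 1L
  } else {
    rowSums(events$stimID == events$trgtID) > 0L
  }
}

#' Validate an epoch/event pair
#'
#' Checks the structural contract shared by all downstream routines and
#' infers the number of classes and the decoding mode. Failures are itemized
#' with stable names rather than raised, so callers can report all problems
#' at once.
#'
#' @param epochs an [epoch_array].
#' @param events an [event_table].
#' @param alphabet optional character vector mapping classes to characters;
#'   when present its length must equal the inferred class count.
#' @return a list with elements `ok` (logical), `violations` (named character
#'   vector), `warnings`, `mode` (`"sequence"` or `"binary"`), `C` (classes)
#'   and `s` (number of sequences).
#' @export
validate_epochs <- function(epochs, events, alphabet = NULL) {
  viol <- character(0)
  warn <- character(0)
  E <- dim(epochs$data)[3]
  if (E != n_events(events))
    viol <- c(viol, event_count_mismatch =
                sprintf("%d epochs but %d event rows", E, n_events(events)))
  if (!all(is.finite(epochs$data)))
    viol <- c(viol, nonfinite_data = "epoch data contain NaN/Inf")

  mode <- if (is.null(events$trgtID)) "binary" else "sequence"
  C <- if (!is.null(alphabet)) length(alphabet) else
    suppressWarnings(max(events$stimID, na.rm = TRUE))
  if (!is.finite(C) || C < 1) C <- 0L

  s <- length(unique(events$seqID))
  if (any(events$stimID < 0L, na.rm = TRUE) ||
      (C > 0 && any(events$stimID > C, na.rm = TRUE)) ||
      any(is.na(events$stimID)))
    viol <- c(viol, stimid_out_of_range =
                sprintf("stimID values must lie in 1..%d (0 = padding)", C))
  if (mode == "binary") {
    if (ncol(events$stimID) != 1L || !all(events$stimID %in% c(1L, 2L)))
      viol <- c(viol, invalid_binary_labels =
                  "binary mode requires a single stimID column with values in {1,2}")
  } else {
    bad <- tapply(events$trgtID, events$seqID, function(v) length(unique(v)) > 1L)
    if (any(bad))
      viol <- c(viol, inconsistent_target =
                  sprintf("trgtID differs within sequence(s): %s",
                          paste(names(bad)[bad], collapse = ", ")))
    if (!is.null(alphabet) &&
        suppressWarnings(max(events$stimID, na.rm = TRUE)) > length(alphabet))
      viol <- c(viol, alphabet_size_mismatch =
                  "alphabet shorter than the largest stimID")
    # A target class that is never highlighted in its own sequence cannot be
    # decoded from that sequence; flagged, not fatal.
    if (!any(names(viol) == "inconsistent_target") && C > 0) {
      for (sq in unique(events$seqID)) {
        i <- events$seqID == sq
        tg <- events$trgtID[i][1]
        if (!is.na(tg) && tg >= 1L && !any(events$stimID[i, , drop = FALSE] == tg))
          warn <- c(warn, target_unstimulated =
                      sprintf("target %d never stimulated in sequence %d", tg, sq))
      }
    }
  }
  list(ok = length(viol) == 0L, violations = viol, warnings = warn,
       mode = mode, C = as.integer(C), s = s)
}

#' Map class indices to display characters
#'
#' With an alphabet assigned to the classes `1..C`, decoded class indices
#' become readable output, e.g. spelled words.
#'
#' @param class_indices integer vector of class indices in `1..length(alphabet)`.
#' @param alphabet character vector of C unique single characters.
#' @return a single string of `length(class_indices)` characters.
#' @export
map_alphabet <- function(class_indices, alphabet) {
  if (length(class_indices) == 0L) return("")
  if (anyDuplicated(alphabet)) stop("alphabet characters must be unique")
  if (any(class_indices < 1L | class_indices > length(alphabet)))
    stop_named("alphabet_index_out_of_range", "class index outside 1..C")
  paste(alphabet[class_indices], collapse = "")
}

#' Inverse of [map_alphabet]
#'
#' @param string a string of characters, all present in `alphabet`.
#' @param alphabet character vector of C unique single characters.
#' @return integer vector of class indices.
#' @export
alphabet_index <- function(string, alphabet) {
  if (nchar(string) == 0L) return(integer(0))
  chars <- strsplit(string, "")[[1]]
  idx <- match(chars, alphabet)
  if (anyNA(idx))
    stop_named("alphabet_index_out_of_range", "character not in alphabet")
  idx
}
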