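#' Build per-condition model-signal templates
#'
#' Model signals are template epochs repeated according to each training
#' epoch's condition (target vs. nontarget). Two kinds are supported:
#'
#' * `impulse`: the template block is the `m x m` identity matrix, so each
#'   model signal is an impulse at one sample point and the canonical
#'   coefficients in `B` directly mirror arbitrary component time courses
#'   (`I_m B = B`).
#' * `average`: the template block is the condition-mean epoch (transposed
#'   to `m x d1`), i.e. the noise-reduced average brain response itself.
#'
#' With `contrast = 1`, nontarget epochs receive a sign of -1 so the CCA
#' optimizes the target-minus-nontarget difference wave; with
#' `contrast = 0` only the target condition is represented.
#'
#' @param epochs an [epoch_array] of training data.
#' @param events the matching [event_table].
#' @param config a [decoder_config].
#' @return an object of class `condition_templates` with fields `kind`, `m`,
#'   `d2`, `target`/`nontarget` blocks (`NULL` for impulse kind), and the
#'   condition signs.
#' @export
build_templates <- function(epochs, events, config) {
  m <- dim(epochs$data)[2]
  is_t <- event_is_target(events)
  if (!any(is_t))
    stop_named("missing_condition_epochs", "no target-condition epochs available")
  if (config$model == "impulse") {
    tmpl <- list(kind = "impulse", m = m, d2 = m,
                 target = NULL, nontarget = NULL)
  } else {
    tgt <- t(apply(epochs$data[, , is_t, drop = FALSE], c(1L, 2L), mean))
    ntg <- NULL
    if (config$contrast == 1L) {
      if (!any(!is_t))
        stop_named("missing_condition_epochs",
                   "contrast = 1 with average model needs nontarget epochs")
      ntg <- if (config$contrast_template == "negated_target") tgt
             else t(apply(epochs$data[, , !is_t, drop = FALSE], c(1L, 2L), mean))
    }
    tmpl <- list(kind = "average", m = m, d2 = dim(epochs$data)[1],
                 target = tgt, nontarget = ntg)
  }
  tmpl$signs <- c(target = 1, nontarget = -1)
  structure(tmpl, class = "condition_templates")
}

# Stack the transposed epochs listed in `idx` (epoch-major, time-minor):
# rows 1..m are epoch idx[1], etc.
stack_epochs <- function(epochs, idx) {
  d <- dim(epochs$data)
  sub <- epochs$data[, , idx, drop = FALSE]
  matrix(aperm(sub, c(2L, 3L, 1L)), nrow = d[2] * length(idx), ncol = d[1])
}

# Model-signal block stack for given per-epoch signs: impulse -> signed
# identity blocks; average -> signed condition blocks.
stack_model_blocks <- function(templates, signs) {
  m <- templates$m
  nE <- length(signs)
  if (templates$kind == "impulse") {
    Y <- matrix(0, m * nE, m)
    Y[cbind(seq_len(m * nE), rep.int(seq_len(m), nE))] <- rep(signs, each = m)
    Y
  } else {
    Y <- templates$target[rep.int(seq_len(m), nE), , drop = FALSE]
    neg <- signs < 0
    if (any(neg)) {
      rows_neg <- which(rep(neg, each = m))
      Y[rows_neg, ] <- templates$nontarget[rep.int(seq_len(m), sum(neg)), , drop = FALSE]
    }
    Y * rep(signs, each = m)
  }
}

#' Assemble the concatenated CCA training matrices
#'
#' Concatenates training epochs into the brain-signal matrix `X`
#' (`n x d1`, `n = included epochs * m`, epoch-major and time-minor) and the
#' matching model-signal matrix `Y` (`n x d2`). With `contrast = 0` only
#' target-condition epochs are included (all signs +1); with `contrast = 1`
#' all epochs are included and nontarget blocks are multiplied by -1.
#'
#' @inheritParams build_templates
#' @param templates output of [build_templates].
#' @return list with `X`, `Y`, `included` (epoch indices) and `signs`.
#' @export
assemble_training <- function(epochs, events, templates, config) {
  is_t <- event_is_target(events)
  if (config$contrast == 0L) {
    idx <- which(is_t)
    signs <- rep(1, length(idx))
  } else {
    idx <- seq_len(n_events(events))
    signs <- ifelse(is_t, 1, -1)
  }
  if (length(idx) == 0L)
    stop_named("missing_condition_epochs", "no epochs included in training")
  list(X = stack_epochs(epochs, idx),
       Y = stack_model_blocks(templates, signs),
       included = idx, signs = signs)
}

#' Model-signal sequence for one hypothesized class
#'
#' At test time a sequence of model signals `Y_c` is generated for each
#' candidate class `c`: under `contrast = 1` every epoch of the sequence is
#' included, with sign +1 where class `c` was among the stimulated classes
#' and -1 elsewhere; under `contrast = 0` only the epochs in which `c` was
#' stimulated are included (sign +1). If `c` was never stimulated in the
#' sequence and `contrast = 0`, the included set is empty and the function
#' returns zero rows with the condition name `"class_unstimulated"` attached
#' (feature producers emit zero features with a warning in that case).
#'
#' @param seq_events [event_table] restricted to one sequence.
#' @param class_c candidate class index.
#' @param templates output of [build_templates].
#' @param config a [decoder_config].
#' @return list with `idx` (included epoch positions within the sequence),
#'   `signs`, and `Y` (`length(idx)*m x d2`).
#' @export
model_sequence <- function(seq_events, class_c, templates, config) {
  hit <- stim_hits(seq_events, class_c)
  if (config$contrast == 0L) {
    idx <- which(hit)
    signs <- rep(1, length(idx))
  } else {
    idx <- seq_len(n_events(seq_events))
    signs <- ifelse(hit, 1, -1)
  }
  out <- list(idx = idx, signs = signs,
              Y = if (length(idx)) stack_model_blocks(templates, signs)
                  else matrix(0, 0L, templates$d2))
  if (length(idx) == 0L) attr(out, "condition") <- "class_unstimulated"
  out
}
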