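#' Select the number of canonical components
#'
#' Either a fixed count `k` (capped at the number of available components)
#' or, with a p-value threshold, the number of leading components whose
#' canonical correlations are significant at that level (floored at 1 so a
#' decoder always has at least one component).
#'
#' @param cca a [cca_fit] result.
#' @param config a [decoder_config].
#' @return integer `k`.
#' @export
select_components <- function(cca, config) {
  comp <- config$components
  if (comp$type == "k") return(min(comp$value, cca$d))
  pv <- cca$pvals
  if (anyNA(pv)) stop_named("cca_n_too_small",
                            "p-value component selection needs valid p-values")
  lead <- which(pv >= comp$value)
  k <- if (length(lead)) lead[1] - 1L else cca$d
  max(1L, k)
}

#' Activation patterns (forward model) of spatial filters
#'
#' Transforms the backward model `U = XA` into the forward model
#' `X = U (A^-1)' + eps`: the activation pattern of component `j` is the
#' `j`th column of `Cov(X) A_k Cov(U_k)^-1`, which characterizes how the
#' component projects onto the sensors and is interpretable (unlike filter
#' weights). When `A` is square and invertible this reduces to the columns
#' of `(A^-1)'`. Columns are scaled to unit maximum absolute value.
#'
#' @param A_k `d1 x k` matrix of spatial filters.
#' @param X training data matrix `n x d1` (rows = observations) from which
#'   the covariance is estimated.
#' @return `d1 x k` matrix of activation patterns.
#' @export
activation_patterns <- function(A_k, X) {
  X <- as.matrix(X)
  Cx <- stats::cov(X)
  Xc <- sweep(X, 2L, colMeans(X))
  Cu <- stats::cov(Xc %*% A_k)
  Cui <- tryCatch(solve(Cu), error = function(e)
    stop_named("singular_component_covariance",
               "component covariance is singular"))
  P <- Cx %*% A_k %*% Cui
  scl <- apply(abs(P), 2L, max)
  scl[scl == 0] <- 1
  sweep(P, 2L, scl, "/")
}

# Component time courses in model-signal space: what Y_c B_k looks like for
# one target (+) or nontarget (-, before sign flip) epoch block.
component_courses <- function(templates, B_k) {
  if (templates$kind == "impulse") {
    list(target = B_k, nontarget = B_k)
  } else {
    list(target = templates$target %*% B_k,
         nontarget = if (is.null(templates$nontarget)) NULL
                     else templates$nontarget %*% B_k)
  }
}

# Canonical variate of a stacked sequence, centered with the training means.
sequence_variate <- function(dec, epochs, idx) {
  Xs <- stack_epochs(epochs, idx)
  sweep(Xs, 2L, dec$x_means) %*% dec$A_k
}

# R features for one candidate class given the sequence's canonical variate
# Uhat (nE*m x k) and the event hit vector.
r_features_one <- function(dec, Uhat, hit) {
  k <- ncol(Uhat)
  m <- dec$m
  ct <- dec$courses
  if (dec$config$contrast == 0L) {
    if (!any(hit)) return(structure(rep(0, k), unstimulated = TRUE))
    rows <- which(rep(hit, each = m))
    U <- Uhat[rows, , drop = FALSE]
    V <- ct$target[rep.int(seq_len(m), sum(hit)), , drop = FALSE]
  } else {
    U <- Uhat
    V <- ct$target[rep.int(seq_len(m), length(hit)), , drop = FALSE]
    neg <- which(rep(!hit, each = m))
    if (length(neg))
      V[neg, ] <- -ct$nontarget[rep.int(seq_len(m), sum(!hit)), , drop = FALSE]
  }
  vapply(seq_len(k), function(i) safe_cor(U[, i], V[, i]), numeric(1))
}

# U features: per component, the mean canonical epoch over the epochs in
# which the candidate class was stimulated, concatenated component-major.
u_features_one <- function(dec, Uhat, hit) {
  k <- ncol(Uhat)
  m <- dec$m
  if (!any(hit)) return(structure(rep(0, k * m), unstimulated = TRUE))
  w <- as.numeric(hit) / sum(hit)
  out <- numeric(k * m)
  for (i in seq_len(k)) {
    Ui <- matrix(Uhat[, i], nrow = m)
    out[((i - 1L) * m + 1L):(i * m)] <- as.numeric(Ui %*% w)
  }
  out
}

# Feature matrix (one row per candidate class) for one sequence.
sequence_features <- function(dec, epochs, seq_events, classes) {
  Uhat <- sequence_variate(dec, epochs, seq_len(dim(epochs$data)[3]))
  hitm <- stim_hit_matrix(seq_events, dec$C)
  nfeat <- if (dec$config$feature_space == "R") dec$k else dec$k * dec$m
  out <- matrix(0, length(classes), nfeat)
  unstim <- logical(length(classes))
  for (j in seq_along(classes)) {
    hit <- hitm[, classes[j]]
    f <- if (dec$config$feature_space == "R") r_features_one(dec, Uhat, hit)
         else u_features_one(dec, Uhat, hit)
    unstim[j] <- isTRUE(attr(f, "unstimulated"))
    out[j, ] <- f
  }
  if (any(unstim))
    warning(sprintf("class_unstimulated: class(es) %s never stimulated in this sequence; zero features",
                    paste(classes[unstim], collapse = ", ")),
            call. = FALSE)
  out
}

#' Correlation (R) features for one sequence and class
#'
#' The k Pearson correlation coefficients between the columns of the
#' canonical variate of the concatenated sequence epochs (`Uhat = Xhat A_k`)
#' and the columns of the model-signal variate for the hypothesized class
#' (`Vhat_c = Yhat_c B_k`). A class never stimulated in the sequence (with
#' `contrast = 0`) yields zero features with a warning; components with
#' numerically constant variates yield a correlation of 0.
#'
#' @param decoder a fitted [fit_erp_decoder] object.
#' @param epochs [epoch_array] of one sequence.
#' @param events matching [event_table] (one sequence).
#' @param class_c hypothesized class.
#' @return numeric vector of length k.
#' @export
features_R <- function(decoder, epochs, events, class_c) {
  dec <- decoder; dec$config$feature_space <- "R"
  as.numeric(sequence_features(dec, epochs, events, class_c))
}

#' Canonical-variate (U) features for one sequence and class
#'
#' For each of the k components, the m-sample canonical epochs of the events
#' in which the hypothesized class was stimulated are averaged; the k
#' averaged epochs are concatenated component-major into a `k*m` vector.
#'
#' @inheritParams features_R
#' @return numeric vector of length `k * m`.
#' @export
features_U <- function(decoder, epochs, events, class_c) {
  dec <- decoder; dec$config$feature_space <- "U"
  as.numeric(sequence_features(dec, epochs, events, class_c))
}

# Split epochs/events by sequence, preserving first-appearance order.
split_sequences <- function(epochs, events) {
  ids <- unique(events$seqID)
  lapply(ids, function(sq) {
    i <- which(events$seqID == sq)
    list(seqID = sq, epochs = subset_epochs(epochs, i),
         events = subset_events(events, i),
         trgt = if (!is.null(events$trgtID)) events$trgtID[i][1] else NA_integer_)
  })
}

#' Fit an ERP decoder
#'
#' Runs the full training pipeline: template building, concatenation of the
#' brain-signal and model-signal matrices, CCA, component selection,
#' activation-pattern computation, training-feature extraction and (unless
#' the maximum-correlation rule is used) classifier training.
#'
#' In sequence mode the classifier is trained on one instance per
#' (sequence, candidate class) pair, labeled positive when the candidate is
#' the sequence's target: all C classes of every training sequence
#' contribute, giving 1 positive and C-1 negative instances per sequence.
#' In binary mode (empty `trgtID`) each epoch is one instance with features
#' computed against the positive-class template and label `stimID == 1`.
#'
#' @param epochs an [epoch_array] of training data.
#' @param events the matching [event_table].
#' @param config a [decoder_config].
#' @return an object of class `erp_decoder`.
#' @export
fit_erp_decoder <- function(epochs, events, config = decoder_config()) {
  v <- validate_epochs(epochs, events, config$alphabet)
  if (!v$ok)
    stop("invalid epoch/event pair: ",
         paste(names(v$violations), collapse = ", "))
  templates <- build_templates(epochs, events, config)
  asm <- assemble_training(epochs, events, templates, config)
  cca <- cca_fit(asm$X, asm$Y)
  k <- select_components(cca, config)
  A_k <- cca$A[, seq_len(k), drop = FALSE]
  B_k <- cca$B[, seq_len(k), drop = FALSE]
  C <- if (v$mode == "binary") 2L else v$C

  dec <- structure(list(
    A_k = A_k, B_k = B_k, k = k, rho = cca$rho, pvals = cca$pvals,
    d = cca$d, templates = templates, config = config,
    x_means = cca$means$x, m = dim(epochs$data)[2], C = C,
    mode = v$mode, channel_names = epochs$channel_names,
    courses = component_courses(templates, B_k),
    patterns = activation_patterns(A_k, asm$X),
    classifier = NULL, classifier_state = NULL
  ), class = "erp_decoder")

  contract <- if (is.character(config$classifier) &&
                  config$classifier == "maxcorr") NULL
              else resolve_classifier(config$classifier)
  if (!is.null(contract)) {
    tf <- training_features(dec, epochs, events)
    dec$classifier <- contract
    dec$classifier_state <- contract$fit(tf$x, tf$y)
  }
  dec
}

training_features <- function(dec, epochs, events) {
  if (dec$mode == "binary") {
    feats <- binary_features(dec, epochs)
    list(x = feats, y = events$stimID[, 1] == 1L)
  } else {
    seqs <- split_sequences(epochs, events)
    xs <- vector("list", length(seqs))
    ys <- vector("list", length(seqs))
    for (i in seq_along(seqs)) {
      s <- seqs[[i]]
      xs[[i]] <- sequence_features(dec, s$epochs, s$events, seq_len(dec$C))
      ys[[i]] <- seq_len(dec$C) == s$trgt
    }
    list(x = do.call(rbind, xs), y = unlist(ys))
  }
}

# Per-epoch features in binary mode: each epoch against the positive-class
# template with sign +1.
binary_features <- function(dec, epochs) {
  E <- dim(epochs$data)[3]
  m <- dec$m
  Uhat <- sequence_variate(dec, epochs, seq_len(E))
  ct <- dec$courses$target
  if (dec$config$feature_space == "R") {
    out <- matrix(0, E, dec$k)
    for (e in seq_len(E)) {
      rows <- ((e - 1L) * m + 1L):(e * m)
      out[e, ] <- vapply(seq_len(dec$k), function(i)
        safe_cor(Uhat[rows, i], ct[, i]), numeric(1))
    }
  } else {
    out <- matrix(0, E, dec$k * m)
    for (e in seq_len(E)) {
      rows <- ((e - 1L) * m + 1L):(e * m)
      out[e, ] <- as.numeric(Uhat[rows, , drop = FALSE])
    }
  }
  out
}

#' @export
print.erp_decoder <- function(x, ...) {
  clf <- if (is.null(x$classifier)) "maxcorr" else x$classifier$name %||% "custom"
  cat(sprintf("<erp_decoder> %s mode, %d classes, k = %d of %d components (%s model, contrast %d), %s features, %s classifier\n",
              x$mode, x$C, x$k, x$d, x$templates$kind, x$config$contrast,
              x$config$feature_space, clf))
  invisible(x)
}

#' Predict intentions from new epochs
#'
#' Sequence mode: for each sequence, scores for all C candidate classes are
#' computed (classifier posterior of "is the target", or the mean
#' correlation across components for the maximum-correlation rule) and the
#' argmax is returned; ties break deterministically to the lowest class
#' index. Binary mode: a per-epoch class with its posterior (the
#' maximum-correlation rule predicts class 1 iff the mean correlation is
#' positive, which is biased under class imbalance).
#'
#' @param object a fitted `erp_decoder`.
#' @param epochs an [epoch_array] of test data.
#' @param events matching [event_table]; `trgtID` is ignored if present.
#' @param ... unused.
#' @return a data frame with one row per sequence (`seqID`, `class`,
#'   `score`, and `char` when an alphabet is configured) or per epoch in
#'   binary mode (`event`, `class`, `posterior`). The full per-class score
#'   matrix is attached as attribute `"scores"`.
#' @export
predict.erp_decoder <- function(object, epochs, events, ...) {
  if (dim(epochs$data)[1] != length(object$channel_names))
    stop("channel count differs from the training data")
  if (dim(epochs$data)[2] != object$m)
    stop("epoch length differs from the training data")
  if (object$mode == "binary") return(predict_binary(object, epochs, events))

  seqs <- split_sequences(epochs, events)
  if (any(vapply(seqs, function(s) dim(s$epochs$data)[3], 1L) == 0L))
    stop("sequence with zero epochs")
  scores <- matrix(0, length(seqs), object$C)
  cls <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    feats <- sequence_features(object, seqs[[i]]$epochs, seqs[[i]]$events,
                               seq_len(object$C))
    sc <- if (is.null(object$classifier)) rowMeans(feats)
          else object$classifier$predict_posterior(object$classifier_state, feats)
    scores[i, ] <- sc
    cls[i] <- which.max(sc)
  }
  out <- data.frame(seqID = vapply(seqs, `[[`, 1L, "seqID"),
                    class = cls,
                    score = scores[cbind(seq_along(cls), cls)])
  if (!is.null(object$config$alphabet))
    out$char <- object$config$alphabet[cls]
  attr(out, "scores") <- scores
  out
}

predict_binary <- function(object, epochs, events) {
  feats <- binary_features(object, epochs)
  if (is.null(object$classifier)) {
    sc <- rowMeans(feats)
    cls <- ifelse(sc > 0, 1L, 2L)
    post <- sc
  } else {
    post <- object$classifier$predict_posterior(object$classifier_state, feats)
    cls <- ifelse(post >= 0.5, 1L, 2L)
  }
  out <- data.frame(event = seq_len(nrow(feats)), class = cls,
                    posterior = post)
  attr(out, "scores") <- cbind(post, if (is.null(object$classifier)) -post
                               else 1 - post)
  out
}

#' Cross-validated decoding accuracy
#'
#' Partitions the data into folds by a seeded permutation -- whole sequences
#' in sequence mode (a test sequence never contributes epochs, templates,
#' CCA statistics or classifier training to its own fold's model) or
#' class-stratified epochs in binary mode -- refits the decoder on each
#' training fold and scores the held-out part. Binary mode additionally
#' reports per-class accuracies, which exposes any bias toward the larger
#' class under imbalance.
#'
#' @param epochs an [epoch_array].
#' @param events the matching [event_table].
#' @param config a [decoder_config].
#' @param n_folds number of folds (>= 2, and at most the number of
#'   sequences, or the minority class count in binary mode).
#' @param seed integer seed controlling the fold assignment.
#' @return list with `mode`, `fold_accuracy`, `mean_accuracy`, `n_folds`,
#'   `seed`, and in binary mode `per_class_accuracy` (fold x class) and
#'   `mean_per_class`.
#' @export
cross_validate_decoder <- function(epochs, events, config = decoder_config(),
                                   n_folds = 10, seed = 1) {
  if (n_folds < 2L) stop("`n_folds` must be at least 2")
  v <- validate_epochs(epochs, events, config$alphabet)
  if (!v$ok)
    stop("invalid epoch/event pair: ", paste(names(v$violations), collapse = ", "))

  if (v$mode == "binary") {
    return(cv_binary(epochs, events, config, n_folds, seed))
  }
  seqs <- unique(events$seqID)
  if (n_folds > length(seqs))
    stop("`n_folds` exceeds the number of sequences")
  perm <- with_seed(seed, sample(seqs))
  fold_of <- rep_len(seq_len(n_folds), length(perm))
  acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    test_seqs <- perm[fold_of == f]
    te <- events$seqID %in% test_seqs
    dec <- fit_erp_decoder(subset_epochs(epochs, !te),
                           subset_events(events, !te), config)
    pr <- predict(dec, subset_epochs(epochs, te), subset_events(events, te))
    truth <- vapply(pr$seqID, function(sq)
      events$trgtID[events$seqID == sq][1], 1L)
    acc[f] <- mean(pr$class == truth)
  }
  list(mode = "sequence", fold_accuracy = acc, mean_accuracy = mean(acc),
       n_folds = n_folds, seed = seed)
}

cv_binary <- function(epochs, events, config, n_folds, seed) {
  y <- events$stimID[, 1]
  if (n_folds > min(table(y)))
    stop("`n_folds` exceeds the minority class count")
  fold_of <- integer(n_events(events))
  with_seed(seed, for (cl in c(1L, 2L)) {
    i <- sample(which(y == cl))
    fold_of[i] <- rep_len(seq_len(n_folds), length(i))
  })
  acc <- numeric(n_folds)
  pc <- matrix(0, n_folds, 2L, dimnames = list(NULL, c("class1", "class2")))
  for (f in seq_len(n_folds)) {
    te <- fold_of == f
    dec <- fit_erp_decoder(subset_epochs(epochs, !te),
                           subset_events(events, !te), config)
    pr <- predict(dec, subset_epochs(epochs, te), subset_events(events, te))
    truth <- y[te]
    acc[f] <- mean(pr$class == truth)
    for (cl in c(1L, 2L)) pc[f, cl] <- mean(pr$class[truth == cl] == cl)
  }
  list(mode = "binary", fold_accuracy = acc, mean_accuracy = mean(acc),
       per_class_accuracy = pc, mean_per_class = colMeans(pc),
       n_folds = n_folds, seed = seed)
}

# Keep the first r repetition blocks of each sequence. One repetition block
# is E_seq / n_repetitions consecutive events.
truncate_repetitions <- function(epochs, events, r, n_repetitions) {
  keep <- logical(n_events(events))
  for (sq in unique(events$seqID)) {
    i <- which(events$seqID == sq)
    per_rep <- length(i) / n_repetitions
    if (per_rep != round(per_rep))
      stop("sequence length not divisible by `n_repetitions`")
    if (r > n_repetitions)
      stop_named("insufficient_repetitions",
                 "requested more repetitions than available")
    keep[i[seq_len(r * per_rep)]] <- TRUE
  }
  list(epochs = subset_epochs(epochs, keep), events = subset_events(events, keep))
}

#' Decoding accuracy as a function of stimulus repetitions
#'
#' For each requested repetition count `r`, the held-out test sequences of
#' every cross-validation fold are truncated to their first `r` repetition
#' blocks (training is unchanged) and re-scored, tracing how accuracy grows
#' with the number of stimulus repetitions.
#'
#' @inheritParams cross_validate_decoder
#' @param reps_list integer vector of repetition counts to evaluate.
#' @param n_repetitions number of repetition blocks each sequence contains
#'   (generators attach this as attribute `n_repetitions` on the event
#'   table).
#' @return data frame with columns `repetitions` and `mean_accuracy`;
#'   per-fold accuracies are attached as attribute `"folds"`.
#' @export
repetition_curve <- function(epochs, events, config = decoder_config(),
                             reps_list, n_folds = 10, seed = 1,
                             n_repetitions = attr(events, "n_repetitions")) {
  if (is.null(n_repetitions))
    stop("`n_repetitions` must be supplied (or attached to `events`)")
  if (any(reps_list > n_repetitions))
    stop_named("insufficient_repetitions",
               "requested more repetitions than available")
  seqs <- unique(events$seqID)
  if (n_folds < 2L) stop("`n_folds` must be at least 2")
  perm <- with_seed(seed, sample(seqs))
  fold_of <- rep_len(seq_len(n_folds), length(perm))
  accs <- matrix(0, n_folds, length(reps_list))
  for (f in seq_len(n_folds)) {
    test_seqs <- perm[fold_of == f]
    te <- events$seqID %in% test_seqs
    dec <- fit_erp_decoder(subset_epochs(epochs, !te),
                           subset_events(events, !te), config)
    te_ep <- subset_epochs(epochs, te)
    te_ev <- subset_events(events, te)
    truth_for <- function(pr) vapply(pr$seqID, function(sq)
      events$trgtID[events$seqID == sq][1], 1L)
    for (j in seq_along(reps_list)) {
      tr <- truncate_repetitions(te_ep, te_ev, reps_list[j], n_repetitions)
      pr <- predict(dec, tr$epochs, tr$events)
      accs[f, j] <- mean(pr$class == truth_for(pr))
    }
  }
  out <- data.frame(repetitions = reps_list, mean_accuracy = colMeans(accs))
  attr(out, "folds") <- accs
  out
}
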