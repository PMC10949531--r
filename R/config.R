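#' Decoder configuration
#'
#' Collects every method option of the decoder in one validated object.
#'
#' @param model model-signal type: `"impulse"` (identity matrices of size
#'   m x m, letting each canonical component take an arbitrary time course)
#'   or `"average"` (condition-mean epochs as templates).
#' @param contrast 0 or 1. With `contrast = 1` nontarget epochs enter the
#'   CCA with sign-flipped model signals, so the spatial filter is optimized
#'   for the target-minus-nontarget difference wave; with `contrast = 0`
#'   only target epochs are used.
#' @param components either a fixed component count `k` (numeric, >= 1) or a
#'   p-value threshold written `"p:0.05"`; the leading components whose
#'   canonical correlations are significant at that level are kept (at least
#'   one).
#' @param feature_space `"R"` (the k Pearson correlations between the
#'   canonical variates of data and model sequence) or `"U"` (the k averaged
#'   canonical epochs concatenated, k*m features).
#' @param classifier `"maxcorr"`, `"lda"`, `"svm"`, `"nb"`, or a custom
#'   classifier: a list with functions `fit(x, y)` and
#'   `predict_posterior(state, x)` returning positive-class probabilities.
#'   `"maxcorr"` is only applicable with `feature_space = "R"`.
#' @param alphabet optional character vector assigning a display character to
#'   each class.
#' @param contrast_template how nontarget epochs are paired with average
#'   model signals under `contrast = 1`: `"condition"` (negated nontarget
#'   mean, the default) or `"negated_target"` (negated target mean).
#' @param seed integer seed recorded in the configuration.
#' @return an object of class `decoder_config`.
#' @export
decoder_config <- function(model = c("impulse", "average"),
                           contrast = 1,
                           components = 3,
                           feature_space = c("R", "U"),
                           classifier = "maxcorr",
                           alphabet = NULL,
                           contrast_template = c("condition", "negated_target"),
                           seed = 1L) {
  model <- match.arg(model)
  feature_space <- match.arg(feature_space)
  contrast_template <- match.arg(contrast_template)
  if (!contrast %in% c(0, 1)) stop("`contrast` must be 0 or 1")

  comp <- parse_components(components)
  if (is.character(classifier)) {
    classifier <- match.arg(classifier, c("maxcorr", "lda", "svm", "nb"))
    if (classifier == "maxcorr" && feature_space != "R")
      stop_named("maxcorr_requires_R",
                 "the maximum-correlation classifier is only applicable to the R feature set")
  } else if (!is.list(classifier) ||
             !all(c("fit", "predict_posterior") %in% names(classifier))) {
    stop("custom classifier must be a list with `fit` and `predict_posterior`")
  }
  structure(list(model = model, contrast = as.integer(contrast),
                 components = comp, feature_space = feature_space,
                 classifier = classifier, alphabet = alphabet,
                 contrast_template = contrast_template,
                 seed = as.integer(seed)),
            class = "decoder_config")
}

parse_components <- function(components) {
  if (is.list(components) && !is.null(components$type)) return(components)
  if (is.character(components)) {
    if (!grepl("^p:", components)) stop("character `components` must look like \"p:0.05\"")
    p <- as.numeric(sub("^p:", "", components))
    if (!is.finite(p) || p <= 0 || p >= 1) stop("p-threshold must lie in (0,1)")
    return(list(type = "p", value = p))
  }
  k <- as.integer(components)
  if (is.na(k) || k < 1L) stop("fixed component count must be >= 1")
  list(type = "k", value = k)
}

#' @export
print.decoder_config <- function(x, ...) {
  comp <- if (x$components$type == "k") sprintf("k = %d", x$components$value)
          else sprintf("p < %g", x$components$value)
  clf <- if (is.character(x$classifier)) x$classifier else "custom"
  cat(sprintf("<decoder_config> model = %s, contrast = %d, %s, features = %s, classifier = %s\n",
              x$model, x$contrast, comp, x$feature_space, clf))
  invisible(x)
}
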