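# Binary classifiers with posterior outputs. Each classifier is a list
# implementing the contract
#   fit(x, y)                -> fitted state (y logical, TRUE = positive)
#   predict_posterior(st, x) -> P(positive) in [0, 1] per row of x
# Custom classifiers supplied in a decoder_config must satisfy the same
# contract.

#' Shrinkage-regularized linear discriminant analysis
#'
#' Pooled-covariance LDA with automatic analytic shrinkage of the
#' (maximum-likelihood) pooled covariance toward the scaled identity
#' `nu * I`, `nu = trace(S)/d`, using the Ledoit-Wolf-style intensity
#' `lambda = (1/n^2) sum_i ||z_i z_i' - S||_F^2 / ||S - nu I||_F^2`
#' clipped to `[0, 1]` (`z_i` are the within-class centered samples). This
#' keeps the discriminant well-defined when the feature dimension exceeds
#' the sample count, as with concatenated canonical-variate features. The
#' posterior follows the discriminant's logistic link, including the
#' log-prior-ratio offset.
#'
#' @return a classifier contract (list with `fit` and `predict_posterior`).
#' @export
clf_lda <- function() {
  list(
    name = "lda",
    fit = function(x, y) {
      x <- as.matrix(x); y <- as.logical(y)
      if (length(unique(y)) < 2L)
        stop_named("single_class_input", "LDA needs both classes present")
      n <- nrow(x); d <- ncol(x)
      mu1 <- colMeans(x[y, , drop = FALSE])
      mu0 <- colMeans(x[!y, , drop = FALSE])
      Z <- x
      Z[y, ] <- sweep(x[y, , drop = FALSE], 2L, mu1)
      Z[!y, ] <- sweep(x[!y, , drop = FALSE], 2L, mu0)
      S <- crossprod(Z) / n
      nu <- sum(diag(S)) / d
      num <- (sum(rowSums(Z^2)^2) - n * sum(S^2)) / n^2
      den <- sum((S - diag(nu, d))^2)
      lambda <- if (den > 1e-300) min(1, max(0, num / den)) else 1
      Ssh <- (1 - lambda) * S + diag(lambda * nu, d)
      Ssh <- Ssh + diag(1e-12 * max(nu, 1), d)  # floor for all-degenerate input
      w <- solve(Ssh, mu1 - mu0)
      b <- -sum(w * (mu1 + mu0)) / 2 + log(sum(y) / sum(!y))
      list(w = w, b = b, lambda = lambda)
    },
    predict_posterior = function(st, x) {
      as.numeric(stats::plogis(as.matrix(x) %*% st$w + st$b))
    }
  )
}

#' Linear soft-margin support vector machine
#'
#' Linear SVM (libsvm via \pkg{e1071}) whose box constraint is set from the
#' training data by the heuristic `C = 1 / mean_i ||x_i||^2`, which
#' compensates feature scaling (scaling all features by `a` scales `C` by
#' `1/a^2` and leaves the margin classifier's decisions unchanged).
#' Posterior probabilities come from a Platt-style logistic calibration of
#' the decision values, fit on the training decision values themselves
#' (no inner cross-validation; BCI training sets are small).
#'
#' @return a classifier contract.
#' @export
clf_svm <- function() {
  list(
    name = "svm",
    fit = function(x, y) {
      x <- as.matrix(x); y <- as.logical(y)
      if (length(unique(y)) < 2L)
        stop_named("single_class_input", "SVM needs both classes present")
      msq <- mean(rowSums(x^2))
      if (!is.finite(msq) || msq <= 0)
        stop_named("degenerate_features", "all-zero feature matrix")
      C <- 1 / msq
      yf <- factor(y, levels = c(FALSE, TRUE))
      fit <- e1071::svm(x, yf, kernel = "linear", cost = C, scale = FALSE)
      dv <- attr(stats::predict(fit, x, decision.values = TRUE),
                 "decision.values")[, 1]
      flip <- mean(dv[y]) < mean(dv[!y])  # libsvm decision sign is label-order dependent
      if (flip) dv <- -dv
      if (stats::sd(dv) < 1e-12) {
        platt <- NULL; p0 <- mean(y)
      } else {
        platt <- suppressWarnings(
          stats::glm(y ~ dv, family = stats::binomial()))
        p0 <- NULL
      }
      list(svm = fit, flip = flip, platt = platt, p0 = p0, C = C)
    },
    predict_posterior = function(st, x) {
      x <- as.matrix(x)
      dv <- attr(stats::predict(st$svm, x, decision.values = TRUE),
                 "decision.values")[, 1]
      if (st$flip) dv <- -dv
      if (is.null(st$platt)) return(rep(st$p0, nrow(x)))
      as.numeric(stats::predict(st$platt, data.frame(dv = dv),
                                type = "response"))
    }
  )
}

#' Gaussian naive Bayes
#'
#' Independent Gaussian class-conditional densities per feature with class
#' priors taken from the training frequencies; per-class, per-feature
#' variances are floored at 1e-12 so degenerate features never produce
#' non-finite posteriors.
#'
#' @return a classifier contract.
#' @export
clf_nb <- function() {
  list(
    name = "nb",
    fit = function(x, y) {
      x <- as.matrix(x); y <- as.logical(y)
      if (length(unique(y)) < 2L)
        stop_named("single_class_input", "naive Bayes needs both classes present")
      stats_for <- function(m) {
        v <- apply(m, 2L, stats::var)
        list(mu = colMeans(m), var = pmax(v, 1e-12))
      }
      list(pos = stats_for(x[y, , drop = FALSE]),
           neg = stats_for(x[!y, , drop = FALSE]),
           logprior = c(pos = log(mean(y)), neg = log(mean(!y))))
    },
    predict_posterior = function(st, x) {
      x <- as.matrix(x)
      ll <- function(cl) {
        rowSums(sweep(-0.5 * sweep(x, 2L, cl$mu)^2, 2L, cl$var, "/") -
                  matrix(0.5 * log(2 * pi * cl$var), nrow(x), ncol(x), byrow = TRUE))
      }
      lp <- ll(st$pos) + st$logprior["pos"]
      ln <- ll(st$neg) + st$logprior["neg"]
      mx <- pmax(lp, ln)
      as.numeric(exp(lp - mx) / (exp(lp - mx) + exp(ln - mx)))
    }
  )
}

#' Maximum-correlation class decision
#'
#' Decision rule for the R feature space without any trained state: the
#' class whose mean correlation feature (averaged across the k components)
#' is maximal wins; ties break to the lowest class index.
#'
#' @param feats numeric matrix `[C classes x k]` of correlation features
#'   (one row per candidate class).
#' @return list with `class` (index) and `scores` (per-class mean
#'   correlations).
#' @export
maxcorr_predict <- function(feats) {
  feats <- as.matrix(feats)
  scores <- rowMeans(feats)
  list(class = which.max(scores), scores = scores)
}

# Resolve a decoder_config classifier field to a contract (or NULL for maxcorr).
resolve_classifier <- function(classifier) {
  if (is.list(classifier)) return(classifier)
  switch(classifier,
         maxcorr = NULL,
         lda = clf_lda(),
         svm = clf_svm(),
         nb = clf_nb(),
         stop("unknown classifier: ", classifier))
}
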