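# Two well-separated Gaussian clouds (6 sigma apart).
clouds <- function(n = 200, d = 2, sep = 6, seed = 20) {
  set.seed(seed)
  y <- rep(c(FALSE, TRUE), each = n / 2)
  x <- matrix(rnorm(n * d), n, d)
  x[y, 1] <- x[y, 1] + sep
  list(x = x, y = y)
}

test_that("shrinkage LDA separates clouds and survives redundant features", {
  cl <- clouds()
  lda <- clf_lda()
  st <- lda$fit(cl$x, cl$y)
  p <- lda$predict_posterior(st, cl$x)
  expect_gte(mean((p >= 0.5) == cl$y), 0.99)
  expect_true(all(p >= 0 & p <= 1))
  # duplicated feature column: no failure, decisions unchanged (posteriors
  # agree closely; exact equality is not expected since the shrinkage
  # target tr(S)/d changes with the duplicated column)
  st2 <- lda$fit(cbind(cl$x[, 1], cl$x[, 1]), cl$y)
  p1 <- lda$predict_posterior(lda$fit(cl$x[, 1, drop = FALSE], cl$y),
                              cl$x[, 1, drop = FALSE])
  p2 <- lda$predict_posterior(st2, cbind(cl$x[, 1], cl$x[, 1]))
  expect_equal(p1 >= 0.5, p2 >= 0.5)
  expect_lt(max(abs(p1 - p2)), 1e-3)
  # mirror-symmetric classes: posterior at the origin is 1/2
  set.seed(21)
  xs <- matrix(rnorm(100), 50, 2) + 2
  xm <- rbind(xs, -xs)
  ym <- rep(c(TRUE, FALSE), each = 50)
  stm <- lda$fit(xm, ym)
  expect_equal(lda$predict_posterior(stm, matrix(0, 1, 2)), 0.5,
               tolerance = 1e-6)
  expect_error(lda$fit(cl$x, rep(TRUE, 200)), class = "single_class_input")
})

test_that("linear SVM uses the scale-compensating box-constraint heuristic", {
  cl <- clouds(seed = 22)
  svm <- clf_svm()
  st <- svm$fit(cl$x, cl$y)
  p <- svm$predict_posterior(st, cl$x)
  expect_gte(mean((p >= 0.5) == cl$y), 0.99)
  # scaling features by 10 scales C by 1/100 and keeps decisions unchanged
  st10 <- svm$fit(cl$x * 10, cl$y)
  expect_equal(st10$C, st$C / 100, tolerance = 1e-9)
  p10 <- svm$predict_posterior(st10, cl$x * 10)
  expect_equal(p10 >= 0.5, p >= 0.5)
  # balanced mirrored data: posterior at origin near 1/2
  set.seed(23)
  xs <- matrix(rnorm(200), 100, 2) + 1.5
  xm <- rbind(xs, -xs)
  ym <- rep(c(TRUE, FALSE), each = 100)
  stm <- svm$fit(xm, ym)
  expect_equal(svm$predict_posterior(stm, matrix(0, 1, 2)), 0.5,
               tolerance = 0.05)
  # determinism: identical data give identical fitted parameters
  expect_equal(svm$fit(cl$x, cl$y)$svm$coefs, st$svm$coefs)
})

test_that("naive Bayes posteriors match closed-form Bayes arithmetic", {
  nb <- clf_nb()
  # hand-computed fixture: one feature, two points per class
  x <- matrix(c(0, 2, 10, 12), 4, 1)
  y <- c(TRUE, TRUE, FALSE, FALSE)
  st <- nb$fit(x, y)
  # class-conditionals: N(1, var 2) and N(11, var 2), priors 1/2
  xq <- matrix(c(1, 6, 11), 3, 1)
  dens <- function(mu) stats::dnorm(xq, mu, sqrt(2))
  oracle <- dens(1) / (dens(1) + dens(11))
  expect_equal(nb$predict_posterior(st, xq), as.numeric(oracle),
               tolerance = 1e-9)
  # symmetric classes: posterior at 0 is 1/2
  set.seed(24)
  xs <- matrix(c(rnorm(500, -1), rnorm(500, 1)), 1000, 1)
  ys <- rep(c(TRUE, FALSE), each = 500)
  sts <- nb$fit(xs, ys)
  # with identical class-conditionals the posterior equals the prior
  x2 <- matrix(rnorm(1000), 1000, 1)
  y2 <- rep(c(TRUE, FALSE), c(200, 800))
  st2 <- nb$fit(x2, y2)
  p2 <- nb$predict_posterior(st2, matrix(0, 1, 1))
  expect_equal(p2, 0.2, tolerance = 0.05)
  expect_true(all(nb$predict_posterior(sts, matrix(seq(-3, 3, 0.5))) >= 0))
})

test_that("maximum-correlation decision takes the argmax with low-index ties", {
  feats <- rbind(c(0.5, 0.4, 0.3), c(0.1, 0.05, 0), c(0.02, 0.1, 0.05))
  expect_equal(maxcorr_predict(feats)$class, 1L)
  expect_equal(maxcorr_predict(matrix(0.2, 4, 3))$class, 1L)  # tie-break
  # equals brute-force argmax over independently computed means
  set.seed(25)
  f <- matrix(rnorm(36 * 3), 36, 3)
  expect_equal(maxcorr_predict(f)$class,
               which.max(apply(f, 1, mean)))
  expect_equal(maxcorr_predict(f)$scores, rowMeans(f))
})

test_that("LDA and SVM handle n << dims (U-style features)", {
  set.seed(26)
  n <- 40; d <- 120
  y <- rep(c(TRUE, FALSE), each = n / 2)
  x <- matrix(rnorm(n * d), n, d)
  x[y, 1:10] <- x[y, 1:10] + 2
  for (clf in list(clf_lda(), clf_svm())) {
    st <- clf$fit(x, y)
    p <- clf$predict_posterior(st, x)
    expect_true(all(is.finite(p)) && all(p >= 0 & p <= 1))
    expect_gt(mean((p >= 0.5) == y), 0.9)
  }
})
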