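fake_cca <- function(pvals, d = length(pvals)) {
  structure(list(d = d, pvals = pvals), class = "cca_result")
}

test_that("component selection caps, counts leading significances, floors at 1", {
  expect_equal(select_components(fake_cca(rep(0, 8)), decoder_config(components = 3)), 3L)
  expect_equal(select_components(fake_cca(rep(0, 2)), decoder_config(components = 10)), 2L)
  expect_equal(select_components(fake_cca(c(1e-9, 0.2, 0.7)),
                                 decoder_config(components = "p:0.05")), 1L)
  expect_equal(select_components(fake_cca(c(0.9, 0.9)),
                                 decoder_config(components = "p:0.05")), 1L)
  expect_equal(select_components(fake_cca(c(1e-9, 1e-9, 1e-9)),
                                 decoder_config(components = "p:0.05")), 3L)
})

test_that("noiseless sequences decode perfectly and maxcorr matches brute force", {
  tr <- small_rsvp(seed = 5, noiseless = TRUE)
  te <- small_rsvp(seed = 6, noiseless = TRUE)
  dec <- fit_erp_decoder(tr$epochs, tr$events, decoder_config())
  pr <- predict(dec, te$epochs, te$events)
  expect_equal(pr$class, truth_of(te, pr))
  # brute-force recomputation of the maxcorr scores via cor() on the
  # canonical variates, independent of the package's feature path
  i <- te$events$seqID == pr$seqID[1]
  ep <- ccaerp:::subset_epochs(te$epochs, i)
  ev <- ccaerp:::subset_events(te$events, i)
  Xhat <- ccaerp:::stack_epochs(ep, seq_len(sum(i)))
  Uhat <- sweep(Xhat, 2, dec$x_means) %*% dec$A_k
  tmpl <- build_templates(tr$epochs, tr$events, dec$config)
  for (cl in c(1L, 4L)) {
    ms <- model_sequence(ev, cl, tmpl, dec$config)
    Vhat <- ms$Y %*% dec$B_k
    rr <- vapply(seq_len(dec$k), function(j) cor(Uhat[, j], Vhat[, j]),
                 numeric(1))
    expect_equal(attr(pr, "scores")[1, cl], mean(rr), tolerance = 1e-10)
  }
})

test_that("all-zero test data give equal scores and the class-1 tie-break", {
  tr <- small_rsvp(seed = 7)
  dec <- fit_erp_decoder(tr$epochs, tr$events, decoder_config())
  z <- tr$epochs
  z$data[] <- 0
  pr <- predict(dec, z, tr$events)
  expect_true(all(pr$class == 1L))
  expect_true(all(abs(attr(pr, "scores")) < 1e-12))
})

test_that("predictions are invariant to global channel permutation and rescaling", {
  tr <- small_rsvp(seed = 8)
  te <- small_rsvp(seed = 9)
  cfg <- decoder_config()
  base <- predict(fit_erp_decoder(tr$epochs, tr$events, cfg),
                  te$epochs, te$events)
  p <- c(5, 3, 8, 1, 7, 2, 6, 4)
  tr2 <- tr; te2 <- te
  tr2$epochs$data <- tr$epochs$data[p, , ] * 3.7
  te2$epochs$data <- te$epochs$data[p, , ] * 3.7
  perm <- predict(fit_erp_decoder(tr2$epochs, tr2$events, cfg),
                  te2$epochs, te2$events)
  expect_equal(perm$class, base$class)
  expect_equal(attr(perm, "scores"), attr(base, "scores"), tolerance = 1e-6)
})

test_that("predict ignores test-set target labels (no leakage)", {
  tr <- small_rsvp(seed = 10)
  te <- small_rsvp(seed = 11)
  dec <- fit_erp_decoder(tr$epochs, tr$events, decoder_config())
  pr1 <- predict(dec, te$epochs, te$events)
  scr <- te$events
  scr$trgtID <- rev(scr$trgtID)
  pr2 <- predict(dec, te$epochs, scr)
  expect_identical(pr1$class, pr2$class)
})

test_that("activation patterns obey the whitened-data identity and recover
           a planted topography", {
  set.seed(30)
  X <- matrix(rnorm(4000), 1000, 4)
  X <- X %*% solve(chol(stats::cov(X)))  # exactly white
  A <- matrix(rnorm(16), 4, 4)
  P <- activation_patterns(A, X)
  ref <- t(solve(A))
  for (j in 1:4)
    expect_equal(abs(cor(P[, j], ref[, j])), 1, tolerance = 1e-8)
  # planted single dominant source at high SNR
  p <- sim_params(layout = "rsvp", n_classes = 6, n_sequences = 6,
                  n_repetitions = 5, seed = 31,
                  noise_ar_sd = 0.3, noise_sensor_sd = 0.15)
  p$erp[[1]]$amplitude <- 0
  sim <- simulate_speller(p)
  dec <- fit_erp_decoder(sim$epochs, sim$events, decoder_config(contrast = 0))
  expect_gt(abs(cor(dec$patterns[, 1], sim$truth$topographies[[2]])), 0.95)
})

test_that("binary mode fits per-epoch decoders on imbalanced labels", {
  sim <- simulate_binary(sim_params(layout = "binary", epoch_s = 0.6,
                                    n_epochs = 200, snr_scale = 2, seed = 32))
  expect_equal(sum(sim$events$stimID == 1L), 40L)
  dec <- fit_erp_decoder(sim$epochs, sim$events,
                         decoder_config(classifier = "lda"))
  expect_equal(dec$mode, "binary")
  pr <- predict(dec, sim$epochs, sim$events)
  expect_equal(nrow(pr), 200L)
  expect_true(all(pr$class %in% c(1L, 2L)))
  expect_true(all(pr$posterior >= 0 & pr$posterior <= 1))
  # training-set accuracy should be well above the majority-class rate
  expect_gt(mean(pr$class == sim$events$stimID[, 1]), 0.85)
})

test_that("an unstimulated class yields zero features and a warning", {
  sim <- small_rsvp(seed = 33)
  cfg <- decoder_config(contrast = 0)
  dec <- fit_erp_decoder(sim$epochs, sim$events, cfg)
  i <- which(sim$events$seqID == 1L)
  keep <- i[sim$events$stimID[i, 1] != 5L]  # drop every event of class 5
  ep <- ccaerp:::subset_epochs(sim$epochs, keep)
  ev <- ccaerp:::subset_events(sim$events, keep)
  expect_warning(f <- features_R(dec, ep, ev, 5L), "class_unstimulated")
  expect_equal(f, rep(0, dec$k))
  expect_warning(fu <- features_U(dec, ep, ev, 5L), "class_unstimulated")
  expect_equal(fu, rep(0, dec$k * dec$m))
})

test_that("U features average the canonical epochs of the attended class", {
  sim <- small_rsvp(seed = 34, noiseless = TRUE)
  # target-only fit: B columns are then clean canonical target courses
  dec <- fit_erp_decoder(sim$epochs, sim$events,
                         decoder_config(feature_space = "U", contrast = 0,
                                        classifier = "lda"))
  i <- which(sim$events$seqID == 2L)
  ep <- ccaerp:::subset_epochs(sim$epochs, i)
  ev <- ccaerp:::subset_events(sim$events, i)
  cl <- sim$truth$targets[2]
  f <- features_U(dec, ep, ev, cl)
  # manual recomputation: mean of the class's canonical epochs
  hit <- ccaerp:::stim_hits(ev, cl)
  Xhat <- ccaerp:::stack_epochs(ep, seq_along(i))
  Uhat <- sweep(Xhat, 2, dec$x_means) %*% dec$A_k
  man <- c(vapply(seq_len(dec$k), function(j)
    rowMeans(matrix(Uhat[, j], nrow = dec$m)[, hit, drop = FALSE]),
    numeric(dec$m)))
  expect_equal(f, as.numeric(man), tolerance = 1e-10)
  # averaged canonical epoch matches the impulse time course at high SNR
  expect_gt(abs(cor(f[seq_len(dec$m)], dec$B_k[, 1])), 0.95)
})

test_that("cross-validation is deterministic and refuses bad fold counts", {
  sim <- small_rsvp(seed = 35)
  cfg <- decoder_config()
  cv1 <- cross_validate_decoder(sim$epochs, sim$events, cfg, n_folds = 3, seed = 9)
  cv2 <- cross_validate_decoder(sim$epochs, sim$events, cfg, n_folds = 3, seed = 9)
  expect_identical(cv1, cv2)
  expect_error(cross_validate_decoder(sim$epochs, sim$events, cfg, n_folds = 1))
  expect_error(cross_validate_decoder(sim$epochs, sim$events, cfg, n_folds = 7))
})

test_that("the repetition curve equals plain cross-validation at full count", {
  sim <- small_rsvp(seed = 36)
  cfg <- decoder_config()
  rc <- repetition_curve(sim$epochs, sim$events, cfg, reps_list = c(2L, 5L),
                         n_folds = 3, seed = 4)
  cv <- cross_validate_decoder(sim$epochs, sim$events, cfg, n_folds = 3, seed = 4)
  expect_equal(rc$mean_accuracy[rc$repetitions == 5L], cv$mean_accuracy)
  expect_error(repetition_curve(sim$epochs, sim$events, cfg, reps_list = 6L,
                                n_folds = 3, seed = 4),
               class = "insufficient_repetitions")
})

test_that("maxcorr refuses the U feature space", {
  expect_error(decoder_config(feature_space = "U", classifier = "maxcorr"),
               class = "maxcorr_requires_R")
})
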