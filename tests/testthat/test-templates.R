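# Hand-built epochs with known condition means: 2 channels, 4 samples.
toy_epochs <- function() {
  m1 <- rbind(c(1, 2, 3, 4), c(0, 1, 0, 1))    # target mean
  m2 <- rbind(c(4, 3, 2, 1), c(1, 0, 1, 0))    # nontarget mean
  dat <- array(0, c(2, 4, 6))
  dat[, , 1] <- m1 + 1; dat[, , 2] <- m1 - 1    # mean = m1
  dat[, , 3] <- m2 + 2; dat[, , 4] <- m2 - 2
  dat[, , 5] <- m2 + 0; dat[, , 6] <- m2 + 0    # mean = m2
  ep <- epoch_array(dat, 10)
  ev <- event_table(stimID = c(1L, 1L, 2L, 2L, 2L, 2L),
                    trgtID = rep(1L, 6), seqID = rep(1L, 6))
  list(ep = ep, ev = ev, m1 = m1, m2 = m2)
}

test_that("impulse templates are identity blocks", {
  toy <- toy_epochs()
  tm <- build_templates(toy$ep, toy$ev, decoder_config(model = "impulse"))
  expect_equal(tm$d2, 4L)
  expect_equal(ccaerp:::stack_model_blocks(tm, 1), diag(4))
  expect_equal(ccaerp:::stack_model_blocks(tm, c(1, -1)),
               rbind(diag(4), -diag(4)))
})

test_that("average templates equal the analytic condition means", {
  toy <- toy_epochs()
  cfg <- decoder_config(model = "average", contrast = 1)
  tm <- build_templates(toy$ep, toy$ev, cfg)
  expect_equal(tm$target, t(toy$m1))
  expect_equal(tm$nontarget, t(toy$m2))
  # contrast = 0: only the target template is built
  tm0 <- build_templates(toy$ep, toy$ev, decoder_config(model = "average",
                                                        contrast = 0))
  expect_null(tm0$nontarget)
  # the negated-target alternative pairs nontargets with the target mean
  cfg_nt <- decoder_config(model = "average", contrast = 1,
                           contrast_template = "negated_target")
  expect_equal(build_templates(toy$ep, toy$ev, cfg_nt)$nontarget, t(toy$m1))
})

test_that("training assembly counts rows and signs correctly", {
  # 10 target + 50 nontarget epochs, m = 40
  dat <- array(rnorm(3 * 40 * 60), c(3, 40, 60))
  ep <- epoch_array(dat, 50)
  ev <- event_table(stimID = rep(c(1L, 2L), c(10, 50)),
                    trgtID = rep(1L, 60), seqID = rep(1L, 60))
  cfg0 <- decoder_config(model = "average", contrast = 0)
  a0 <- assemble_training(ep, ev, build_templates(ep, ev, cfg0), cfg0)
  expect_equal(nrow(a0$X), 400L)
  expect_true(all(a0$signs == 1))

  cfg1 <- decoder_config(model = "average", contrast = 1)
  tm1 <- build_templates(ep, ev, cfg1)
  a1 <- assemble_training(ep, ev, tm1, cfg1)
  expect_equal(nrow(a1$X), 2400L)
  # nontarget rows of Y equal the negated nontarget template block
  expect_equal(a1$Y[401:440, ], -tm1$nontarget)
  # X rows are the transposed epochs, epoch-major
  expect_equal(a1$X[1:40, ], t(dat[, , 1]))
  expect_equal(a1$X[41:80, ], t(dat[, , 2]))

  # impulse model: Y is a stack of +-identity blocks
  cfgI <- decoder_config(model = "impulse", contrast = 1)
  aI <- assemble_training(ep, ev, build_templates(ep, ev, cfgI), cfgI)
  expect_equal(aI$Y[1:40, ], diag(40))
  expect_equal(aI$Y[401:440, ], -diag(40))
})

test_that("test-time model sequences follow the selection rules", {
  # matrix-speller-like: 12 events, class 7 highlighted in events 2 and 9
  stim <- matrix(0L, 12, 6)
  stim[] <- rep(1:6, each = 12)  # filler classes
  stim[2, 1] <- 7L; stim[9, 3] <- 7L
  ev <- event_table(stim, trgtID = rep(7L, 12), seqID = rep(1L, 12))
  ep <- epoch_array(array(rnorm(2 * 4 * 12), c(2, 4, 12)), 10)
  cfg0 <- decoder_config(model = "impulse", contrast = 0)
  tm <- build_templates(ep, ev, cfg0)
  ms0 <- model_sequence(ev, 7L, tm, cfg0)
  expect_equal(ms0$idx, c(2L, 9L))
  expect_true(all(ms0$signs == 1))

  cfg1 <- decoder_config(model = "impulse", contrast = 1)
  ms1 <- model_sequence(ev, 7L, tm, cfg1)
  expect_length(ms1$idx, 12L)
  expect_equal(sum(ms1$signs == 1), 2L)
  expect_equal(sum(ms1$signs == -1), 10L)

  # class never stimulated, contrast 0 -> named condition
  ms_un <- model_sequence(ev, 9L, tm, cfg0)
  expect_equal(attr(ms_un, "condition"), "class_unstimulated")
  expect_equal(nrow(ms_un$Y), 0L)

  # binary-like single epoch, class 1 -> one positive block
  evb <- event_table(matrix(1L), NULL, 1L)
  msb <- model_sequence(evb, 1L, tm, cfg0)
  expect_equal(msb$Y, diag(4))
})
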