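make_feats <- function(targets, values, sds = NA_real_) {
  data.frame(feature = targets$feature, amplitude_pA = targets$amplitude_pA,
             frequency_Hz = targets$frequency_Hz, value = values, sd = sds)
}

test_that("the weighted absolute-error score is zero at a perfect match", {
  tg <- experimental_targets()
  feats <- make_feats(tg, tg$exp)
  expect_identical(score_features(feats, tg), 0)
})

test_that("the published FF1 6-pA burst column scores 17.72 against the targets", {
  tg <- experimental_targets()
  tg6 <- tg[tg$feature == "burst" & tg$amplitude_pA == 6, ]
  ref <- reference_features()
  ff1 <- ref$FF1[ref$feature == "burst" & ref$amplitude_pA == 6]
  feats <- make_feats(tg6, ff1)
  expect_equal(score_features(feats, tg6), 17.72, tolerance = 1e-9)
})

test_that("a 1-ms latency error weighs like a 1-Hz frequency error", {
  tg <- data.frame(feature = "latency", amplitude_pA = 10,
                   frequency_Hz = NA_real_, exp = 31.9, weight = 1000)
  feats <- make_feats(tg, 32.9)  # 1 ms off
  expect_equal(score_features(feats, tg), 1.0)
})

test_that("missing simulated conditions raise a configuration error", {
  tg <- experimental_targets()
  feats <- make_feats(tg[-1, ], tg$exp[-1])
  expect_error(score_features(feats, tg), "missing simulated feature")
})

test_that("the SD-penalized burst score reduces to the plain score at zero SD", {
  tg <- experimental_targets()
  bt <- tg[tg$feature == "burst", ]
  set.seed(7)
  vals <- bt$exp + stats::rnorm(nrow(bt), 0, 4)
  feats0 <- make_feats(bt, vals, sds = 0)
  expect_equal(score_bursts_sd(feats0, bt), score_features(feats0, bt),
               tolerance = 1e-12)
  # and exceeds it whenever any SD is positive, by the (sd + 1) factor
  sds <- stats::runif(nrow(bt), 0, 3)
  feats1 <- make_feats(bt, vals, sds = sds)
  expect_gt(score_bursts_sd(feats1, bt), score_features(feats1, bt))
  hand <- sum(abs(vals - bt$exp) * bt$weight * (sds + 1))
  expect_equal(score_bursts_sd(feats1, bt), hand, tolerance = 1e-12)
})

test_that("single-condition SD penalty follows |diff| * w * (sd + 1)", {
  tg <- data.frame(feature = "burst", amplitude_pA = 6, frequency_Hz = 4.04,
                   exp = 50, weight = 1)
  expect_equal(score_bursts_sd(make_feats(tg, 52, sds = 0.5), tg), 3.0)
  # perfect means: nonzero SDs multiply a zero difference
  expect_identical(score_bursts_sd(make_feats(tg, 50, sds = 2.5), tg), 0)
})

test_that("fitness specs compose the published feature combinations", {
  expect_equal(fitness_spec("FF1")$features, "burst")
  expect_setequal(fitness_spec("FF2")$features, c("burst", "mean_frequency"))
  expect_setequal(fitness_spec("FF3")$features, c("burst", "latency"))
  expect_setequal(fitness_spec("FF4")$features,
                  c("burst", "mean_frequency", "latency"))
  expect_equal(nrow(fitness_spec("FF1")$targets), 14)
  expect_equal(nrow(fitness_spec("FF4")$targets), 20)
  expect_true(fitness_spec("FF1")$sd_penalty)
  expect_error(fitness_spec("custom"), "features")
})

test_that("a never-spiking individual scores the sum of the burst targets", {
  spec <- fitness_spec("FF1")
  res <- evaluate_individual(silent_params(), spec, solver = fast_solver())
  expect_false(res$sentinel)
  expect_equal(res$score, sum(spec$targets$exp), tolerance = 1e-9)
})

test_that("evaluation is deterministic and bounded-domain guarded", {
  spec <- fitness_spec("FF3")
  p <- published_individual("FF3")
  r1 <- evaluate_individual(p, spec, solver = fast_solver())
  r2 <- evaluate_individual(p, spec, solver = fast_solver())
  expect_identical(r1$score, r2$score)
  expect_true(is.finite(r1$score))
  # out-of-bounds parameters get the worst-score sentinel, not a crash
  out <- p
  out$C_m <- 50
  rs <- evaluate_individual(out, spec, solver = fast_solver())
  expect_true(rs$sentinel)
  expect_gt(rs$score, r1$score)
  expect_true(is.finite(rs$score))
})
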