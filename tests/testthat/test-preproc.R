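make_rec <- function(duration_s = 3.5, fs = 500, n_ch = 3, seed = 1) {
  set.seed(seed)
  recording(matrix(rnorm(n_ch * duration_s * fs, sd = 10), nrow = n_ch), fs)
}

test_that("segmentation counts epochs and drops the partial tail", {
  es <- segment_epochs(make_rec(180), 1)
  expect_equal(dim(es$epochs), c(180, 3, 500))
  es <- segment_epochs(make_rec(3.5), 1)
  expect_equal(dim(es$epochs)[1], 3)
  expect_error(segment_epochs(make_rec(0.5), 1), "shorter than one epoch")
})

test_that("artifact rejection applies absolute and transition thresholds", {
  rec <- make_rec(5, seed = 2)
  rec$data <- rec$data * 0.5                       # quiet baseline
  rec$data[2, 1210] <- 150                         # absolute hit in epoch 3
  es <- reject_artifacts(segment_epochs(rec, 1))
  expect_true(es$artifact_mask[3])
  expect_equal(sum(es$artifact_mask), 1)           # transition hits epoch 3 only

  quiet <- make_rec(2, seed = 3)
  quiet$data <- 30 * sin(outer(1:3, 2 * pi * 5 * (1:1000) / 500))  # max 30, small steps
  es2 <- reject_artifacts(segment_epochs(quiet, 1))
  expect_false(any(es2$artifact_mask))
  expect_error(
    reject_artifacts(segment_epochs(quiet, 1), abs_thresh_uV = 1),
    "no clean epochs")
})

test_that("rejection is monotone: lowering thresholds never unmasks", {
  # epoch e carries a tone of amplitude 40 + 10 e, straddling both thresholds
  fs <- 500
  amps <- 40 + 10 * (1:12)
  x <- unlist(lapply(amps, function(a) a * sin(2 * pi * 10 * (1:fs) / fs)))
  rec <- recording(rbind(x, -x / 2), fs)
  es <- segment_epochs(rec, 1)
  masks <- lapply(c(160, 130, 100, 70), function(th) {
    tryCatch(reject_artifacts(es, th, th / 2)$artifact_mask,
             error = function(e) rep(TRUE, 12))
  })
  for (k in 2:length(masks)) {
    expect_true(all(masks[[k]] | !masks[[k - 1]]))  # stricter masks a superset
    expect_gte(sum(masks[[k]]), sum(masks[[k - 1]]))
  }
})

test_that("rejection mask recovers injected ground truth exactly", {
  sp <- coupling_spec(8, NULL, duration_s = 60, seed = 21)
  rec <- generate_coupled_channels(sp)
  dirty <- inject_artifacts(rec, n_events = 3, amplitude_uV = 150, seed = 6)
  es <- reject_artifacts(segment_epochs(dirty, 1))
  expect_equal(which(es$artifact_mask), attr(dirty, "artifact_epochs"))
  # sub-threshold events are invisible
  dirty2 <- inject_artifacts(rec, n_events = 3, amplitude_uV = 10, seed = 6)
  es2 <- reject_artifacts(segment_epochs(dirty2, 1))
  expect_false(any(es2$artifact_mask))
})

test_that("band-pass keeps a 10 Hz tone and attenuates 40 Hz as designed", {
  fs <- 500
  t10 <- test_epoch_sinusoid(10, fs, 1000)
  rec <- recording(rbind(t10, t10), fs)
  es <- bandpass_fir(segment_epochs(rec, 2))
  y <- es$epochs[1, 1, ]
  p <- Mod(fft(y))^2
  f <- (seq_along(y) - 1) * fs / length(y)
  inband <- (f >= 7 & f <= 13) | (f >= fs - 13 & f <= fs - 7)
  expect_lt(sum(p[!inband]) / sum(p[inband]), 1e-2)

  t40 <- test_epoch_sinusoid(40, fs, 1000)
  rec40 <- recording(rbind(t40, t40), fs)
  es40 <- bandpass_fir(segment_epochs(rec40, 2))
  mid <- 300:700                                    # away from edge transients
  measured <- sqrt(mean(es40$epochs[1, 1, mid]^2)) / sqrt(mean(t40[mid]^2))
  taps <- fconnet:::fir_bandpass_taps(fs, 7, 13, fconnet:::default_fir_order(fs, 7))
  designed <- fconnet:::fir_zero_phase_response(taps, 40, fs)
  expect_lt(measured, 1e-3)                         # deep stopband
  expect_equal(measured, designed, tolerance = 0.5) # same order of magnitude
})

test_that("band-pass maps zero to zero and validates the band", {
  rec <- recording(matrix(0, 2, 1000), 500)
  es <- bandpass_fir(segment_epochs(rec, 1))
  expect_equal(max(abs(es$epochs)), 0)
  expect_error(bandpass_fir(segment_epochs(make_rec(2), 1), 7, 300), "Nyquist|fs/2")
})

test_that("common average reference zeroes channel means and is idempotent", {
  es <- segment_epochs(make_rec(3, n_ch = 5, seed = 8), 1)
  es$epochs <- es$epochs + 42                       # constant offset
  ref <- rereference_common_average(es)
  sums <- apply(ref$epochs, c(1, 3), sum)
  expect_lt(max(abs(sums)), 1e-9)
  again <- rereference_common_average(ref)
  expect_equal(again$epochs, ref$epochs, tolerance = 1e-12)
})

test_that("the preprocessing pipeline logs its applied step order", {
  es <- preprocess(make_rec(3, seed = 9))
  expect_match(es$steps[1], "segment")
  expect_match(es$steps[2], "reject")
  expect_match(es$steps[3], "rereference")
  expect_match(es$steps[4], "bandpass")
  es2 <- preprocess(make_rec(3, seed = 9),
                    order = c("segment", "rereference", "filter"))
  expect_length(es2$steps, 3)
})
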