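band_epoch_set <- function(n_ch = 2, n_ep = 4, seed = 1, coupled = NULL) {
  sp <- coupling_spec(n_ch, coupled, duration_s = n_ep, seed = seed)
  preprocess(generate_coupled_channels(sp))
}

test_that("pearson matrix honours sign conventions and flags zero variance", {
  set.seed(1)
  x <- rnorm(200)
  ep <- rbind(x, x, -x, rnorm(200))
  r <- pearson_matrix(ep)
  expect_equal(r[1, 2], 1)
  expect_equal(r[1, 3], 1)                         # |r| of anti-correlated pair
  expect_equal(unname(diag(r)), rep(0, 4))
  expect_true(isSymmetric(r))
  rp <- pearson_matrix(ep, mode = "positive")
  expect_equal(rp[1, 3], 0)                        # clipped instead of folded
  expect_error(pearson_matrix(rbind(x, rep(1, 200))), "zero-variance channel")
})

test_that("independent long noise stays under the Fisher sampling bound", {
  set.seed(2)
  Tn <- 40000
  ep <- rbind(rnorm(Tn), rnorm(Tn))
  expect_lt(pearson_matrix(ep)[1, 2], 3 / sqrt(Tn))
})

test_that("coherence is 1 for identical channels and biased ~1/K for noise", {
  es <- band_epoch_set(n_ch = 4, n_ep = 6, seed = 3)
  es$epochs[, 2, ] <- es$epochs[, 1, ]             # duplicate channel
  coh <- coherence_matrix(es)
  expect_equal(coh[1, 2], 1, tolerance = 1e-10)
  expect_true(all(coh >= 0 & coh <= 1))

  # independent white noise, 60 epochs: bias level ~ 1/K
  set.seed(4)
  rec <- recording(matrix(rnorm(2 * 60 * 500), 2), 500)
  esn <- segment_epochs(rec, 1)
  esn$band_hz <- c(7, 13)
  cn <- coherence_matrix(esn)
  expect_lt(cn[1, 2], 0.1)
  expect_gt(cn[1, 2], 1 / 60 / 5)
  expect_error(coherence_matrix(segment_epochs(recording(matrix(rnorm(1000), 2), 500), 1)),
               "multiple epochs")
})

test_that("hilbert phase recovers instantaneous frequency and quadrature lag", {
  fs <- 500
  x <- test_epoch_sinusoid(10, fs, 500)
  phi <- hilbert_phase(x)
  keep <- which(attr(phi, "keep"))
  expect_true(all(phi > -pi & phi <= pi))
  dphi <- diff(phi[keep])
  dphi <- (dphi + pi) %% (2 * pi) - pi             # unwrap steps
  inst_freq <- mean(dphi) * fs / (2 * pi)
  expect_equal(inst_freq, 10, tolerance = 0.05)

  phc <- hilbert_phase(cos(2 * pi * 10 * seq_len(500) / fs))
  dlag <- (phc[keep] - phi[keep] + pi) %% (2 * pi) - pi
  expect_equal(mean(dlag), pi / 2, tolerance = 0.01)
  expect_error(hilbert_phase(rep(1, 100)), "constant")
})

test_that("phase order parameter detects locking including constant pi lag", {
  es <- band_epoch_set(n_ch = 3, n_ep = 3, seed = 5)
  es$epochs[, 2, ] <- es$epochs[, 1, ]
  es$epochs[, 3, ] <- -es$epochs[, 1, ]            # phase-shifted by pi
  P <- phase_order_matrix(es)
  expect_equal(P[1, 2], 1, tolerance = 1e-9)
  expect_equal(P[1, 3], 1, tolerance = 1e-9)
  expect_true(all(P >= 0 & P <= 1 + 1e-12))
})

test_that("phase order index of iid uniform phases matches the resultant law", {
  # E[R] for T uniform unit vectors is sqrt(pi)/(2 sqrt(T)); oracle by MC
  Tn <- 400
  set.seed(6)
  ours <- replicate(200, {
    phi_u <- runif(Tn, -pi, pi); phi_v <- runif(Tn, -pi, pi)
    phase_order_index(phi_u, phi_v)
  })
  expect_equal(mean(ours), sqrt(pi) / (2 * sqrt(Tn)), tolerance = 0.05)
})

test_that("phase order and coherence are amplitude-invariant, correlation scale-invariant", {
  es <- band_epoch_set(n_ch = 4, n_ep = 4, seed = 7,
                       coupled = list(c(1, 2, 0.6)))
  scaled <- es
  gains <- c(3, 0.2, 10, 1)
  for (ch in 1:4) scaled$epochs[, ch, ] <- es$epochs[, ch, ] * gains[ch]
  for (est in c("correlation", "coherence", "phase_order")) {
    w1 <- subject_connectivity(es, est)$weights
    w2 <- subject_connectivity(scaled, est)$weights
    expect_equal(w1, w2, tolerance = 1e-9)
  }
})

test_that("delay embedding has the stated geometry", {
  expect_equal(dim(embed_delay(rnorm(500), 10, 10)), c(410, 10))
  x <- c(1, 2, 3)
  expect_equal(embed_delay(x, 2, 1), cbind(c(1, 2), c(2, 3)))
  expect_equal(embed_delay(x, 1, 5), matrix(x, ncol = 1))
  expect_error(embed_delay(rnorm(50), 10, 10), "too short")
})

test_that("correlation integral equals a brute-force double loop", {
  set.seed(8)
  V <- matrix(rnorm(10 * 3), 10)
  W <- ceiling(0.1 * nrow(V))
  for (r in c(0.5, 1.5, 3)) {
    brute <- local({
      num <- 0; den <- 0
      for (t in 1:9) for (s in (t + 1):10) {
        if (s - t > W) { den <- den + 1; num <- num + (sqrt(sum((V[t, ] - V[s, ])^2)) < r) }
      }
      num / den
    })
    expect_equal(correlation_integral(V, r), brute)
  }
  big_r <- 1e6
  expect_equal(correlation_integral(V, big_r), 1)
  expect_equal(correlation_integral(V, 0), 0)
})

test_that("critical radius hits the p_ref quantile and round-trips", {
  expect_true(fconnet:::radius_at_quantile(sample(1:100), 0.25) > 25 &&
              fconnet:::radius_at_quantile(sample(1:100), 0.25) < 26)
  d <- runif(50)
  expect_gt(fconnet:::radius_at_quantile(d, 1), max(d))
  set.seed(9)
  V <- matrix(rnorm(60 * 4), 60)
  r <- critical_radius(V, p_ref = 0.2)
  np <- length(fconnet:::admissible_distances(V, ceiling(0.1 * 60)))
  expect_equal(correlation_integral(V, r), 0.2, tolerance = 1 / np + 1e-12)
  expect_warning(critical_radius(matrix(rnorm(10 * 2), 10), p_ref = 1e-6),
                 "resolution")
})

test_that("synchronization likelihood matches the exhaustive oracle", {
  set.seed(10)
  for (k in 1:5) {
    xi <- rnorm(20); xj <- rnorm(20)
    p <- sl_params(p_ref = 0.2, lag_L = 1, embed_e = 2, theiler_w = 0.1)
    expect_equal(sl_pair(xi, xj, p),
                 oracle_sl_pair(xi, xj, p_ref = 0.2, lag = 1, dim = 2))
  }
})

test_that("sync likelihood is 1 for identical channels", {
  x <- fconnet:::bandlimited_noise(500, 500, 7, 13)
  expect_equal(sl_pair(x, x), 1)
})

test_that("subject_connectivity averages clean epochs and validates names", {
  es <- band_epoch_set(n_ch = 3, n_ep = 2, seed = 11)
  per_epoch <- lapply(1:2, function(k) pearson_matrix(matrix(es$epochs[k, , ], nrow = 3)))
  cm <- subject_connectivity(es, "correlation")
  expect_equal(cm$weights, unname((per_epoch[[1]] + per_epoch[[2]]) / 2),
               ignore_attr = TRUE)
  expect_equal(cm$n_epochs_used, 2L)
  es1 <- es
  es1$artifact_mask[2] <- TRUE
  cm1 <- subject_connectivity(es1, "correlation")
  expect_equal(cm1$weights, unname(per_epoch[[1]]), ignore_attr = TRUE)
  expect_equal(cm1$n_epochs_used, 1L)
  expect_error(subject_connectivity(es, "granger"), "valid estimators")
})

test_that("all estimators return symmetric bounded matrices on one cohort member", {
  es <- band_epoch_set(n_ch = 6, n_ep = 4, seed = 12,
                       coupled = list(c(1, 2, 0.7), c(3, 4, 0.3)))
  for (est in c("correlation", "coherence", "phase_order", "sync_likelihood")) {
    w <- subject_connectivity(es, est)$weights
    expect_equal(w, t(w), tolerance = 1e-12)
    expect_true(all(w >= 0 & w <= 1 + 1e-9), label = est)
    expect_equal(unname(diag(w)), rep(0, 6))
  }
})

test_that("every estimator separates planted from absent coupling (AUC > 0.9)", {
  sp <- coupling_spec(8, list(c(1, 2, 0.8), c(3, 4, 0.8)), duration_s = 20)
  cs <- cohort_spec(list(n_subjects = 5, spec = sp),
                    list(n_subjects = 5, spec = sp), seed = 13)
  ess <- lapply(generate_cohort(cs), preprocess)
  coupled <- rbind(c(1, 2), c(3, 4))
  uncoupled <- rbind(c(1, 3), c(1, 4), c(2, 3), c(5, 6), c(5, 7), c(6, 7),
                     c(7, 8), c(5, 8))
  for (est in c("correlation", "coherence", "phase_order", "sync_likelihood")) {
    ws <- lapply(ess, function(es) subject_connectivity(es, est)$weights)
    pos <- unlist(lapply(ws, function(w) w[coupled]))
    neg <- unlist(lapply(ws, function(w) w[uncoupled]))
    auc <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
    expect_gt(auc, 0.9)
  }
})
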