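#' Specification of one synthetic subject's coupled alpha-band channels
#'
#' Describes a resting-EEG-like multichannel signal: every channel carries a
#' band-limited oscillation (alpha band by default) plus broadband Gaussian
#' sensor noise, and selected channel pairs share a latent band-limited
#' oscillator ("common drive") whose mixing weight encodes the coupling
#' strength. For a single edge of strength `s` between otherwise noise-free
#' channels the population Pearson correlation of the pair is exactly `s`.
#'
#' @param n_channels number of channels (>= 2).
#' @param coupling_edges planted coupling graph: a data.frame with columns
#'   `i`, `j`, `strength` (1-based channel indices, strength in `[0, 1]`), or
#'   a list of `c(i, j, strength)` triples, or `NULL` for no coupling.
#'   The summed strength incident to any one channel must not exceed 1 (the
#'   channel's unit signal variance is split between its intrinsic oscillator
#'   and its shared drives).
#' @param oscillator_freq_hz center frequency of the oscillators in Hz
#'   (default 10, the middle of the 7-13 Hz alpha band).
#' @param osc_bw_hz full bandwidth of the oscillators in Hz (default 6, so
#'   the default band is 7-13 Hz).
#' @param noise_sd standard deviation of the additive white sensor noise, uV.
#' @param amplitude_uV RMS amplitude of the oscillatory signal component, uV.
#' @param fs_hz sampling rate in Hz; must exceed twice the oscillator
#'   frequency.
#' @param duration_s recording duration in seconds.
#' @param seed integer seed; the generator is fully deterministic given the
#'   spec.
#'
#' @return An object of class `coupling_spec`.
#' @seealso [generate_coupled_channels()], [cohort_spec()]
#' @export
coupling_spec <- function(n_channels, coupling_edges = NULL,
                          oscillator_freq_hz = 10, osc_bw_hz = 6,
                          noise_sd = 5, amplitude_uV = 15,
                          fs_hz = 500, duration_s = 60, seed = 1L) {
  if (!is.numeric(n_channels) || length(n_channels) != 1 || n_channels < 2) {
    stop_fc("`n_channels` must be a single number >= 2")
  }
  n_channels <- as.integer(n_channels)
  edges <- normalize_edges(coupling_edges, n_channels)
  if (!is.numeric(oscillator_freq_hz) || oscillator_freq_hz <= 0) {
    stop_fc("`oscillator_freq_hz` must be positive")
  }
  if (!is.numeric(osc_bw_hz) || osc_bw_hz <= 0 ||
      osc_bw_hz >= 2 * oscillator_freq_hz) {
    stop_fc("`osc_bw_hz` must be in (0, 2*oscillator_freq_hz)")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop_fc("`noise_sd` must be >= 0")
  }
  if (!is.numeric(amplitude_uV) || amplitude_uV <= 0) {
    stop_fc("`amplitude_uV` must be > 0")
  }
  if (!is.numeric(fs_hz) || fs_hz <= 2 * oscillator_freq_hz) {
    stop_fc("`fs_hz` must exceed twice `oscillator_freq_hz` (Nyquist)")
  }
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop_fc("`duration_s` must be positive")
  }
  # per-channel variance budget: intrinsic oscillator gets 1 - sum(s)
  tot <- channel_coupling_totals(edges, n_channels)
  if (any(tot > 1 + 1e-12)) {
    bad <- which(tot > 1 + 1e-12)[1]
    stop_fc(paste0(
      "`coupling_edges`: total coupling strength at channel %d is %.3f > 1; ",
      "the per-channel sum of edge strengths must not exceed 1"), bad, tot[bad])
  }
  structure(
    list(n_channels = n_channels, coupling_edges = edges,
         oscillator_freq_hz = oscillator_freq_hz, osc_bw_hz = osc_bw_hz,
         noise_sd = noise_sd, amplitude_uV = amplitude_uV,
         fs_hz = fs_hz, duration_s = duration_s, seed = as.integer(seed)),
    class = "coupling_spec"
  )
}

normalize_edges <- function(edges, n_channels) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0)) {
    return(data.frame(i = integer(), j = integer(), strength = numeric()))
  }
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e) {
      if (length(e) != 3) stop_fc("`coupling_edges` triples must be (i, j, strength)")
      data.frame(i = e[1], j = e[2], strength = e[3])
    }))
  }
  if (!is.data.frame(edges) || !all(c("i", "j", "strength") %in% names(edges))) {
    stop_fc("`coupling_edges` must have columns i, j, strength")
  }
  edges$i <- as.integer(edges$i); edges$j <- as.integer(edges$j)
  if (any(edges$i == edges$j)) stop_fc("`coupling_edges`: self-edges (i == j) not allowed")
  if (any(edges$i < 1 | edges$j < 1 | edges$i > n_channels | edges$j > n_channels)) {
    stop_fc("`coupling_edges`: channel indices must be in 1..n_channels")
  }
  if (any(edges$strength < 0 | edges$strength > 1)) {
    stop_fc("`coupling_edges`: strengths must lie in [0, 1]")
  }
  # canonical i < j, detect duplicates
  swap <- edges$i > edges$j
  tmp <- edges$i[swap]; edges$i[swap] <- edges$j[swap]; edges$j[swap] <- tmp
  if (anyDuplicated(edges[c("i", "j")])) {
    stop_fc("`coupling_edges`: duplicate edges")
  }
  edges[order(edges$i, edges$j), , drop = FALSE]
}

channel_coupling_totals <- function(edges, n_channels) {
  tot <- numeric(n_channels)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      tot[edges$i[k]] <- tot[edges$i[k]] + edges$strength[k]
      tot[edges$j[k]] <- tot[edges$j[k]] + edges$strength[k]
    }
  }
  tot
}

# Exactly band-limited unit-variance Gaussian noise: complex Gaussian Fourier
# coefficients on the bins inside [low, high] Hz, Hermitian-symmetrized,
# inverse FFT. Random phase comes with the coefficients.
bandlimited_noise <- function(n, fs_hz, low_hz, high_hz) {
  freqs <- (seq_len(n) - 1) * fs_hz / n
  half <- 2:(floor(n / 2) + 1)  # positive-frequency bins (excluding DC)
  keep <- half[freqs[half] >= low_hz & freqs[half] <= high_hz]
  if (length(keep) == 0) stop_fc("band [%g, %g] Hz contains no FFT bin at this length", low_hz, high_hz)
  spec <- complex(real = rep(0, n), imaginary = rep(0, n))
  spec[keep] <- complex(real = rnorm(length(keep)), imaginary = rnorm(length(keep)))
  # mirror for a real signal (skip Nyquist self-conjugate subtlety: make it real)
  nyq <- if (n %% 2 == 0) n / 2 + 1 else NA_integer_
  if (!is.na(nyq) && nyq %in% keep) spec[nyq] <- complex(real = Re(spec[nyq]), imaginary = 0)
  mirror <- n - keep + 2
  mirror_ok <- mirror >= 2 & mirror <= n & (is.na(nyq) | keep != nyq)
  spec[mirror[mirror_ok]] <- Conj(spec[keep[mirror_ok]])
  x <- Re(fft(spec, inverse = TRUE)) / n
  x / sd(x)
}

#' Generate one subject's coupled multichannel recording
#'
#' Each channel is built as
#' `amplitude_uV * (sqrt(1 - c_i) * o_i + sum_e sqrt(s_e) * z_e) + noise_sd * eps`
#' where `o_i` is the channel's intrinsic band-limited oscillator, `z_e` the
#' latent oscillator shared by the channels of coupling edge `e` (strength
#' `s_e`), `c_i` the channel's total coupling, and `eps` white Gaussian noise.
#' All oscillators are independent unit-variance band-limited Gaussian
#' processes with random phases drawn from the spec seed, so the output is
#' bit-reproducible.
#'
#' @param spec a [coupling_spec()].
#' @param subject_id,group passed through to the [recording()].
#' @return A [recording()].
#' @export
generate_coupled_channels <- function(spec, subject_id = "s01", group = "unknown") {
  if (!inherits(spec, "coupling_spec")) stop_fc("`spec` must be a coupling_spec")
  n <- round(spec$fs_hz * spec$duration_s)
  if (n < 2) stop_fc("`duration_s` too short for any samples")
  low <- spec$oscillator_freq_hz - spec$osc_bw_hz / 2
  high <- spec$oscillator_freq_hz + spec$osc_bw_hz / 2
  edges <- spec$coupling_edges
  tot <- channel_coupling_totals(edges, spec$n_channels)
  data <- with_local_seed(spec$seed, {
    osc <- vapply(seq_len(spec$n_channels), function(i) {
      bandlimited_noise(n, spec$fs_hz, low, high)
    }, numeric(n))
    lat <- if (nrow(edges)) {
      vapply(seq_len(nrow(edges)), function(e) {
        bandlimited_noise(n, spec$fs_hz, low, high)
      }, numeric(n))
    } else NULL
    x <- t(osc) * sqrt(pmax(1 - tot, 0))  # channels x samples
    if (!is.null(lat)) {
      for (e in seq_len(nrow(edges))) {
        w <- sqrt(edges$strength[e])
        x[edges$i[e], ] <- x[edges$i[e], ] + w * lat[, e]
        x[edges$j[e], ] <- x[edges$j[e], ] + w * lat[, e]
      }
    }
    x <- x * spec$amplitude_uV
    if (spec$noise_sd > 0) {
      x <- x + matrix(rnorm(length(x), sd = spec$noise_sd), nrow = nrow(x))
    }
    x
  })
  recording(data, spec$fs_hz, subject_id = subject_id, group = group)
}

#' Specification of a two-group synthetic cohort
#'
#' @param group_a,group_b lists with elements `n_subjects` (>= 2) and
#'   `spec` (a [coupling_spec()]); all subjects of a group share the coupling
#'   topology but receive independent noise and oscillator phases.
#' @param seed integer cohort seed from which per-subject seeds are derived.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_a, group_b, seed = 1L) {
  for (g in list(group_a, group_b)) {
    if (!is.list(g) || is.null(g$n_subjects) || is.null(g$spec)) {
      stop_fc("each group must be list(n_subjects=, spec=)")
    }
    if (g$n_subjects < 2) stop_fc("`n_subjects` must be >= 2 per group (group statistics undefined otherwise)")
    if (!inherits(g$spec, "coupling_spec")) stop_fc("group `spec` must be a coupling_spec")
  }
  structure(list(group_a = group_a, group_b = group_b, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a labelled cohort of recordings
#'
#' @param cspec a [cohort_spec()].
#' @return A list of [recording()] objects with subject ids `A01..`, `B01..`
#'   and group labels `"A"`/`"B"`.
#' @export
generate_cohort <- function(cspec) {
  if (!inherits(cspec, "cohort_spec")) stop_fc("`cspec` must be a cohort_spec")
  n_a <- cspec$group_a$n_subjects
  n_b <- cspec$group_b$n_subjects
  seeds <- derive_seeds(cspec$seed, n_a + n_b)
  recs <- vector("list", n_a + n_b)
  for (k in seq_len(n_a)) {
    sp <- cspec$group_a$spec
    sp$seed <- seeds[k]
    recs[[k]] <- generate_coupled_channels(sp, subject_id = sprintf("A%02d", k), group = "A")
  }
  for (k in seq_len(n_b)) {
    sp <- cspec$group_b$spec
    sp$seed <- seeds[n_a + k]
    recs[[n_a + k]] <- generate_coupled_channels(
      sp, subject_id = sprintf("B%02d", k), group = "B")
  }
  recs
}

#' Planted two-group coupling topology
#'
#' The default cohort geometry for the package's planted-difference studies:
#' a perfect matching — channels (1,2), (3,4), ... are coupled pairwise at
#' the group coupling scale, every channel belonging to exactly one edge.
#' Both groups share this edge set; only the strength differs, which is the
#' cleanest realization of "same topology, weaker coupling". Downstream the
#' two groups nevertheless differ in binarized network topology (not just
#' weights), because coupling strength shapes the common-average-reference
#' residue and the dispersion of per-epoch correlations that rank the
#' remaining edges.
#'
#' @param n_channels even channel count >= 4.
#' @param scale coupling strength of every matched pair, in `(0, 1]`.
#' @return Edge data.frame suitable for [coupling_spec()].
#' @export
two_group_edges <- function(n_channels = 16, scale = 0.8) {
  if (n_channels < 4 || n_channels %% 2 != 0) stop_fc("`n_channels` must be even and >= 4")
  if (scale <= 0 || scale > 1) stop_fc("`scale` must be in (0, 1]")
  data.frame(i = seq(1, n_channels, by = 2), j = seq(2, n_channels, by = 2),
             strength = scale)
}

#' Convenience constructor for the planted-difference cohort
#'
#' Builds a [cohort_spec()] with the [two_group_edges()] topology at two
#' group coupling scales (defaults 0.8 vs 0.4, 14 vs 16 subjects, 16
#' channels, 60 s at 500 Hz).
#'
#' @param n_a,n_b subjects per group.
#' @param scale_a,scale_b group coupling scales.
#' @param n_channels channels per subject.
#' @param duration_s recording length in seconds.
#' @param noise_sd_a,noise_sd_b white-noise SD per group, uV.
#' @param seed cohort seed.
#' @return A [cohort_spec()].
#' @export
two_group_cohort_spec <- function(n_a = 14, n_b = 16, scale_a = 0.8,
                                  scale_b = 0.4, n_channels = 16,
                                  duration_s = 60, noise_sd_a = 5,
                                  noise_sd_b = 5, seed = 1L) {
  spec_a <- coupling_spec(n_channels, two_group_edges(n_channels, scale_a),
                          noise_sd = noise_sd_a, duration_s = duration_s)
  spec_b <- coupling_spec(n_channels, two_group_edges(n_channels, scale_b),
                          noise_sd = noise_sd_b, duration_s = duration_s)
  cohort_spec(list(n_subjects = n_a, spec = spec_a),
              list(n_subjects = n_b, spec = spec_b), seed = seed)
}

#' Inject rectangular artifact transients into a recording
#'
#' Adds `n_events` rectangular pulses of the given amplitude (each 0.1 s
#' long, on one random channel, at a random position inside a distinct
#' 1-epoch window) and records the ground-truth contaminated epoch indices in
#' `attr(rec, "artifact_epochs")`. Pulses above the rejection thresholds are
#' detectable by [reject_artifacts()]; sub-threshold pulses are not.
#'
#' @param rec a [recording()].
#' @param n_events number of transients; must not exceed the number of
#'   epochs.
#' @param amplitude_uV pulse amplitude in uV.
#' @param seed integer seed.
#' @param epoch_len_s epoch length used to define windows (default 1 s).
#' @return The contaminated [recording()] with attribute `artifact_epochs`.
#' @export
inject_artifacts <- function(rec, n_events, amplitude_uV = 150, seed = 1L,
                             epoch_len_s = 1) {
  stopifnot(inherits(rec, "recording"))
  n_epochs <- floor(rec_duration_s(rec) / epoch_len_s)
  if (n_events > n_epochs) {
    stop_fc("n_events (%d) exceeds the number of epochs (%d)", n_events, n_epochs)
  }
  if (n_events == 0) {
    attr(rec, "artifact_epochs") <- integer()
    return(rec)
  }
  spe <- round(epoch_len_s * rec$fs_hz)          # samples per epoch
  pulse_len <- max(2L, round(0.1 * rec$fs_hz))   # 0.1 s rectangle
  with_local_seed(seed, {
    epochs <- sort(sample.int(n_epochs, n_events))
    for (e in epochs) {
      ch <- sample.int(n_channels(rec), 1)
      start <- (e - 1) * spe + sample.int(spe - pulse_len, 1)
      idx <- start + seq_len(pulse_len)
      rec$data[ch, idx] <- rec$data[ch, idx] + amplitude_uV
    }
    attr(rec, "artifact_epochs") <- epochs
    rec
  })
}
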