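# Synthetic three-condition ERP generator: 1/f background noise plus
# class-dependent Gaussian-windowed component effects with known topography,
# so every pipeline stage can be tested against ground truth.

#' Simulated ERP component effect
#'
#' A component effect is a Gaussian-envelope bump (optionally carrying an
#' oscillation) at a fixed latency, with a class-dependent peak amplitude and
#' a fixed spatial topography. The envelope SD defaults to a quarter of the
#' component's analysis-window width, so the effect is concentrated where the
#' extraction windows look.
#'
#' @param name component name.
#' @param center_ms peak latency relative to stimulus onset, ms.
#' @param sd_ms envelope standard deviation, ms.
#' @param amplitude named numeric vector: peak scalp amplitude in microvolts
#'   per class label, measured at the component's peak electrode (the
#'   topography entry of largest magnitude).
#' @param topography unit-norm spatial pattern over channels, or `NULL` for a
#'   default deterministic pattern assigned by [sim_config()].
#' @param jitter_sd_ms per-trial latency jitter SD, ms.
#' @param carrier_hz optional oscillation frequency under the envelope
#'   (phase-locked at the envelope centre); `NA` for a plain bump.
#' @return list describing the component.
#' @export
sim_component <- function(name, center_ms, sd_ms, amplitude,
                          topography = NULL, jitter_sd_ms = 5, carrier_hz = NA) {
  list(name = name, center_ms = center_ms, sd_ms = sd_ms,
       amplitude = amplitude, topography = topography,
       jitter_sd_ms = jitter_sd_ms, carrier_hz = carrier_hz)
}

# default component effects: amplitudes (uV) per condition chosen once as a
# clearly separable but physiologically plausible ERP effect set. Point
# components get field-typical deflection widths (tens of ms) so their
# spectra stay inside the 1-30 Hz analysis band — the 5-sample extraction
# window samples the deflection around its peak, it does not bound its
# duration; range components use SD = window width / 4.
default_sim_components <- function(labels = c("Ug", "Tg", "Sc")) {
  amp <- function(...) stats::setNames(c(...), labels)
  list(
    sim_component("N70",       70, 10,  amp(-5.0, -3.5, -2.0)),
    sim_component("P120",     120, 12,  amp( 4.0,  5.5,  2.5)),
    sim_component("N170_P200", 185, 7.5, amp(-8.0, -5.0, -2.0)),
    sim_component("P300",     300, 40,  amp( 7.0,  4.0,  2.0)),
    sim_component("P400_700", 550, 75,  amp( 6.0,  3.5,  1.5)))
}

# deterministic unit-norm topography: Gaussian profile over the channel axis
default_topography <- function(n_channels, i, n_components) {
  center <- (i / (n_components + 1)) * (n_channels + 1)
  v <- exp(-((seq_len(n_channels) - center)^2) / (2 * (n_channels / 6)^2))
  v / sqrt(sum(v^2))
}

#' Synthetic-data configuration
#'
#' Describes the generative world: channel count, sampling rate, epoch span,
#' trials per class, component effects, 1/f background-noise model and
#' artifact-planting rate. Defaults mirror a 60-channel, 500 Hz,
#' 98-trials-per-condition acquisition with three intention conditions.
#'
#' @param n_channels number of channels (default 60).
#' @param sampling_rate Hz (default 500).
#' @param pre_ms,post_ms epoch span around stimulus onset (default
#'   200 / 800 ms, i.e. 501 samples at 500 Hz with onset at sample 100).
#' @param trials_per_class trials per condition (default 98).
#' @param labels condition labels.
#' @param components list of [sim_component()] effects; components without a
#'   topography get a deterministic default.
#' @param noise_rms background-noise RMS in microvolts (default 5).
#' @param noise_exponent spectral exponent alpha of the 1/f^alpha background
#'   (default 1, pink).
#' @param artifact_rate fraction of trials given a planted excursion beyond
#'   +/-75 uV (default 0).
#' @param seed RNG seed; generation is bit-reproducible given the config.
#' @return object of class `SimConfig`.
#' @export
sim_config <- function(n_channels = 60L, sampling_rate = 500,
                       pre_ms = 200, post_ms = 800,
                       trials_per_class = 98L,
                       labels = c("Ug", "Tg", "Sc"),
                       components = default_sim_components(labels),
                       noise_rms = 5, noise_exponent = 1,
                       artifact_rate = 0, seed = 1L) {
  if (artifact_rate < 0 || artifact_rate > 1) stop("artifact_rate must be in [0, 1]")
  for (i in seq_along(components)) {
    comp <- components[[i]]
    if (is.null(comp$topography))
      components[[i]]$topography <-
        default_topography(n_channels, i, length(components))
    else if (abs(sum(comp$topography^2) - 1) > 1e-8)
      stop(sprintf("topography of component '%s' must have unit norm", comp$name))
    missing <- setdiff(labels, names(components[[i]]$amplitude))
    if (length(missing) > 0)
      stop(sprintf("component '%s' lacks amplitudes for: %s",
                   comp$name, paste(missing, collapse = ", ")))
  }
  structure(list(n_channels = as.integer(n_channels),
                 sampling_rate = sampling_rate,
                 pre_ms = pre_ms, post_ms = post_ms,
                 trials_per_class = as.integer(trials_per_class),
                 labels = labels, components = components,
                 noise_rms = noise_rms, noise_exponent = noise_exponent,
                 artifact_rate = artifact_rate, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Named simulation presets
#'
#' `paper`-scale: 60 channels, 98 trials per condition, three conditions.
#' `small`: 8 channels, 30 trials per condition — fast enough for CI.
#' `recovery`: 4 channels, 100 trials per class, two conditions, three
#' point components with no latency jitter over white background noise — a
#' low-dimensional, well-conditioned world (D = 60 after windowing) where
#' the analytic discriminant direction is both known exactly and estimable. `multiband`: two conditions whose effects are band-limited
#' oscillations at delta/theta/alpha/beta carriers inside the 400-700 ms
#' window, so each frequency band carries an independent signal.
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @return a [sim_config()].
#' @export
sim_preset <- function(name = c("paper", "small", "recovery", "multiband"),
                       seed = 1L) {
  name <- match.arg(name)
  two <- c("Ug", "Sc")
  amp2 <- function(a, b) stats::setNames(c(a, b), two)
  switch(name,
    paper = sim_config(seed = seed),
    small = sim_config(n_channels = 8L, trials_per_class = 30L, seed = seed),
    recovery = sim_config(
      n_channels = 4L, trials_per_class = 100L, labels = two,
      components = list(
        sim_component("N70",   70, 10, amp2(-9, -1), jitter_sd_ms = 0),
        sim_component("P120", 120, 12, amp2( 9,  1), jitter_sd_ms = 0),
        sim_component("P300", 300, 40, amp2( 8,  0), jitter_sd_ms = 0)),
      noise_exponent = 0, seed = seed),
    multiband = sim_config(
      n_channels = 8L, trials_per_class = 30L, labels = two,
      components = list(
        sim_component("delta_osc", 550, 60, amp2(6, 2), carrier_hz = 2.5,
                      jitter_sd_ms = 0),
        sim_component("theta_osc", 480, 40, amp2(2, 6), carrier_hz = 6,
                      jitter_sd_ms = 0),
        sim_component("alpha_osc", 620, 35, amp2(6, 2), carrier_hz = 10.5,
                      jitter_sd_ms = 0),
        sim_component("beta_osc",  500, 30, amp2(2, 5), carrier_hz = 20,
                      jitter_sd_ms = 0)),
      seed = seed))
}

# full-length power spectrum (per FFT bin) of the background noise,
# normalized so mean(S) = rms^2, i.e. marginal variance = rms^2
noise_spectrum <- function(config, Tn) {
  k2 <- (Tn - 1) %/% 2
  f <- (1:k2) * config$sampling_rate / Tn
  s_half <- f^(-config$noise_exponent)
  s <- c(0, s_half, if (Tn %% 2 == 0) s_half[k2] else NULL, rev(s_half))
  s <- s[1:Tn]
  s * config$noise_rms^2 / mean(s)
}

# one N x T matrix of stationary Gaussian noise with spectrum S (rows iid)
gen_noise <- function(n_channels, Tn, S) {
  k2 <- (Tn - 1) %/% 2
  Z <- matrix(0 + 0i, Tn, n_channels)
  a <- matrix(stats::rnorm(k2 * n_channels), k2)
  b <- matrix(stats::rnorm(k2 * n_channels), k2)
  amp <- sqrt(S[2:(k2 + 1)] / 2)
  Z[2:(k2 + 1), ] <- amp * (a + 1i * b)
  Z[Tn:(Tn - k2 + 1), ] <- Conj(Z[2:(k2 + 1), ])
  if (Tn %% 2 == 0)
    Z[k2 + 2, ] <- sqrt(S[k2 + 2]) * stats::rnorm(n_channels)
  t(Re(stats::mvfft(Z, inverse = TRUE))) / sqrt(Tn)
}

# component waveform on a time axis (ms relative to onset), given a realized
# centre latency
component_wave <- function(comp, t_ms, center_ms) {
  w <- exp(-((t_ms - center_ms)^2) / (2 * comp$sd_ms^2))
  if (!is.na(comp$carrier_hz))
    w <- w * cos(2 * pi * comp$carrier_hz * (t_ms - center_ms) / 1000)
  w
}

#' Generate a synthetic epoch set with ground truth
#'
#' Each trial is 1/f background noise (independent across channels; no
#' volume-conduction model) plus the class's component effects; latency
#' jitter is drawn per trial and component. Trials marked as artifacts get a
#' planted 150 uV spike at a random channel and sample, guaranteed to exceed
#' the 75 uV rejection threshold. Generation is bit-reproducible from the
#' config seed.
#'
#' @param config a [sim_config()].
#' @return list with `epochs` (an [epoch_set()], trial order: all trials of
#'   label 1, then label 2, ...) and `truth` (class `GroundTruth`): the
#'   planted artifact trial indices (1-based), and per unordered class pair
#'   the analytic discriminant direction and clean mean-difference vector in
#'   the default component space (see [analytic_direction()]).
#' @export
simulate_epochs <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  rate <- config$sampling_rate
  Tn <- as.integer(round((config$pre_ms + config$post_ms) / 1000 * rate)) + 1L
  onset <- as.integer(round(config$pre_ms / 1000 * rate))
  t_ms <- ((0:(Tn - 1)) - onset) * 1000 / rate
  for (comp in config$components)
    if (comp$center_ms < t_ms[1] || comp$center_ms > t_ms[Tn])
      stop(sprintf("component '%s' lies outside the epoch", comp$name))
  S <- noise_spectrum(config, Tn)
  labels <- rep(config$labels, each = config$trials_per_class)
  n <- length(labels)
  trials <- vector("list", n)
  artifact_ids <- integer(0)
  withr::with_seed(config$seed, {
    for (i in seq_len(n)) {
      m <- gen_noise(config$n_channels, Tn, S)
      for (comp in config$components) {
        jit <- if (comp$jitter_sd_ms > 0) stats::rnorm(1, 0, comp$jitter_sd_ms) else 0
        # amplitude is scalp microvolts at the peak electrode: scale the
        # unit-norm topography so its largest entry carries the full amplitude
        a <- comp$amplitude[[labels[i]]] / max(abs(comp$topography))
        m <- m + a * outer(comp$topography,
                           component_wave(comp, t_ms, comp$center_ms + jit))
      }
      if (config$artifact_rate > 0 && stats::runif(1) < config$artifact_rate) {
        ch <- sample.int(config$n_channels, 1)
        sp <- sample.int(Tn, 1)
        m[ch, sp] <- m[ch, sp] + sample(c(-150, 150), 1)
        artifact_ids <- c(artifact_ids, i)
      }
      trials[[i]] <- m
    }
  })
  epochs <- epoch_set(trials, labels, sampling_rate = rate, onset_index = onset)
  windows <- tryCatch(
    component_windows(rate, onset, Tn),
    error = function(e) NULL)
  pairs <- if (length(config$labels) >= 2) utils::combn(config$labels, 2, simplify = FALSE)
           else list()
  directions <- NULL
  if (!is.null(windows)) {
    directions <- lapply(pairs, function(p) analytic_direction(config, p, windows))
    names(directions) <- vapply(pairs, paste, "", collapse = "-vs-")
  }
  truth <- structure(list(artifact_ids = artifact_ids,
                          directions = directions,
                          windows = windows, config = config),
                     class = "GroundTruth")
  list(epochs = epochs, truth = truth)
}

# expected waveform of a component under Gaussian latency jitter: numeric
# quadrature over the jitter distribution (exact when jitter is 0)
expected_wave <- function(comp, t_ms) {
  if (comp$jitter_sd_ms <= 0)
    return(component_wave(comp, t_ms, comp$center_ms))
  nodes <- seq(-4, 4, length.out = 41)
  wts <- stats::dnorm(nodes)
  wts <- wts / sum(wts)
  w <- numeric(length(t_ms))
  for (q in seq_along(nodes))
    w <- w + wts[q] * component_wave(comp, t_ms,
                                     comp$center_ms + nodes[q] * comp$jitter_sd_ms)
  w
}

#' Analytic discriminant direction implied by a simulation config
#'
#' Returns the noise-whitened clean mean-difference direction
#' `Sigma^{-1} (mu_1 - mu_2)` in the vectorized component space defined by
#' `windows`, where `Sigma` is the exact covariance of the 1/f background
#' noise restricted to the window samples (block-diagonal over channels,
#' which are generated independently) and the mean difference is the expected
#' clean signal difference between the pair's classes (jitter integrated
#' out). This is the Bayes-optimal linear direction for the generator's
#' Gaussian world and the target of the parameter-recovery tests.
#'
#' @param config a [sim_config()].
#' @param pair character vector of two class labels from the config.
#' @param windows a [component_windows()] object in the config's trial
#'   coordinates.
#' @return unit-norm numeric vector of length `n_channels * T'` with
#'   attribute `mean_diff` (the unwhitened planted difference). A zero vector
#'   (identical class specs) carries attribute `degenerate = TRUE`.
#' @export
analytic_direction <- function(config, pair, windows) {
  stopifnot(inherits(config, "SimConfig"), length(pair) == 2)
  if (!all(pair %in% config$labels)) stop("pair labels not in config")
  rate <- config$sampling_rate
  Tn <- as.integer(round((config$pre_ms + config$post_ms) / 1000 * rate)) + 1L
  onset <- as.integer(round(config$pre_ms / 1000 * rate))
  t_ms <- ((0:(Tn - 1)) - onset) * 1000 / rate
  sel <- unlist(lapply(seq_len(nrow(windows)), function(i)
    (windows$start[i] + 1L):windows$end[i]))
  # exact autocovariance of the synthesis spectrum, then restrict to windows
  S <- noise_spectrum(config, Tn)
  r <- Re(stats::fft(S, inverse = TRUE)) / Tn
  R_sel <- matrix(r[abs(outer(sel, sel, "-")) + 1L], length(sel))
  # expected clean mean difference, channels x selected samples
  diff_cs <- matrix(0, config$n_channels, length(sel))
  for (comp in config$components) {
    da <- (comp$amplitude[[pair[1]]] - comp$amplitude[[pair[2]]]) /
      max(abs(comp$topography))
    if (da == 0) next
    diff_cs <- diff_cs + da * outer(comp$topography, expected_wave(comp, t_ms)[sel])
  }
  p <- as.vector(t(diff_cs))                      # channel-major vectorization
  if (all(p == 0)) {
    warning("identical class specifications for this pair; direction undefined")
    return(structure(p, degenerate = TRUE, mean_diff = p))
  }
  w_cs <- t(solve(R_sel, t(diff_cs)))             # per-channel whitening
  w <- as.vector(t(w_cs))
  structure(w / sqrt(sum(w^2)), mean_diff = p)
}
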