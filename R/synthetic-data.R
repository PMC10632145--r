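#' Simulation configuration for synthetic recordings
#'
#' Defines the acquisition and stimulation conditions emulated by the
#' generator: 2 volumes/s sampling, one randomly chosen target every 30 s,
#' 0.5-s stimuli in the wild-type-like condition (0.3 s in the
#' mutant-like condition), double-exponential photobleaching, i.i.d. Gaussian
#' sensor noise, randomly missing samples, and per-edge trial-to-trial
#' response reliability.
#'
#' @param dt Seconds per sample (default 0.5).
#' @param duration Recording length in seconds.
#' @param isi Seconds between stimulation events (default 30; must be at
#'   least the 30-s post-stimulus window).
#' @param stim_duration Stimulus duration in seconds (0.5 WT-like,
#'   0.3 mutant-like).
#' @param noise_sd Gaussian noise SD in raw fluorescence units.
#' @param baseline Baseline fluorescence in raw units.
#' @param bleach Either `NULL` (no photobleaching) or
#'   `list(a = c(a1, a2), rate = c(r1, r2))` giving the multiplicative
#'   double-exponential decay `a1 e^(-r1 t) + a2 e^(-r2 t)` (amplitudes sum
#'   to 1 at t = 0).
#' @param missing_fraction Fraction of samples randomly missing, in [0, 0.5).
#' @param response_probability Per-edge, per-trial probability that a
#'   stimulation of the upstream neuron elicits the downstream response.
#' @param auto_peak Peak dF/F0 of the stimulated neuron's autoresponse.
#' @param strain Strain label, e.g. `"WT"`, `"unc-31"` or `"control"`.
#' @param seed Integer seed; mandatory, every stochastic call consumes it.
#' @return A `sim_config` object.
#' @export
sim_config <- function(dt = 0.5, duration = 1800, isi = 30,
                       stim_duration = 0.5, noise_sd = 1, baseline = 100,
                       bleach = list(a = c(0.2, 0.8), rate = c(1 / 100, 1 / 2000)),
                       missing_fraction = 0.02, response_probability = 0.7,
                       auto_peak = 1.0, strain = "WT", seed) {
  stopifnot(dt > 0, duration > 0, isi >= 30, stim_duration > 0)
  stopifnot(missing_fraction >= 0, missing_fraction < 0.5)
  stopifnot(response_probability >= 0, response_probability <= 1)
  if (missing(seed)) stop("sim_config requires an explicit integer seed")
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (!is.null(bleach)) {
    stopifnot(length(bleach$a) == 2L, length(bleach$rate) == 2L,
              all(bleach$a >= 0), all(bleach$rate >= 0))
  }
  structure(list(dt = dt, duration = duration, isi = isi,
                 stim_duration = stim_duration, noise_sd = noise_sd,
                 baseline = baseline, bleach = bleach,
                 missing_fraction = missing_fraction,
                 response_probability = response_probability,
                 auto_peak = auto_peak, strain = strain,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Autoresponse template of a stimulated neuron
#'
#' Double-exponential calcium transient (rise time constant `tau_rise`, decay
#' `tau_decay`), normalized to the requested peak dF/F0. This is the
#' generator's model for the modest calcium responses evoked by direct
#' stimulation and the default drive waveform for network simulations.
#'
#' @param dt Sampling interval in seconds.
#' @param peak Peak dF/F0 (default 1).
#' @param tau_rise,tau_decay Time constants in seconds.
#' @param t_max Template length in seconds.
#' @return Numeric vector of dF/F0 values starting at stimulus onset.
#' @export
autoresponse_template <- function(dt = 0.5, peak = 1, tau_rise = 1,
                                  tau_decay = 8, t_max = 30) {
  tg <- seq(0, t_max - dt, by = dt)
  f <- exp(-tg / tau_decay) - exp(-tg / tau_rise)
  peak * f / max(f)
}

#' Generate a ground-truth signal-propagation network
#'
#' Draws a directed network whose edges carry ground-truth propagation
#' kernels. Each ordered pair (no self-edges) is an edge with probability
#' `edge_density`; an edge is inhibitory (negative kernel integral) with
#' probability `frac_inhibitory` and extrasynaptic (functionally present but
#' absent from the matched connectome) with probability `frac_extrasynaptic`.
#' Kernels are one- or two-rate chains with rates log-uniform in `rate_band`;
#' a fraction of edges get a second opposite-sign chain (saturating
#' transmission). Edge DC gains are drawn uniformly from `gain_band`, chosen
#' so desk-scale networks remain stable as linear systems.
#'
#' @param n_neurons Number of neurons (>= 2).
#' @param edge_density Probability of each ordered pair being an edge.
#' @param frac_inhibitory Probability that an edge is inhibitory.
#' @param frac_extrasynaptic Probability that an edge is extrasynaptic.
#' @param seed Integer seed.
#' @param rate_band Log-uniform band for kernel decay rates (1/s).
#' @param gain_band Uniform band for absolute DC gains.
#' @param frac_saturating Probability that an edge kernel is saturating
#'   (two opposite-sign chains).
#' @return A `ground_truth_network` with fields `n_neurons`, `labels`,
#'   `edges` (data.frame: from, to, inhibitory, extrasynaptic) and `kernels`
#'   (list parallel to the edge rows).
#' @export
gen_ground_truth <- function(n_neurons, edge_density, frac_inhibitory = 0.11,
                             frac_extrasynaptic = 0, seed,
                             rate_band = c(0.05, 1), gain_band = c(0.08, 0.2),
                             frac_saturating = 0.25) {
  stopifnot(n_neurons >= 2, edge_density >= 0, edge_density <= 1)
  stopifnot(frac_inhibitory >= 0, frac_inhibitory <= 1)
  stopifnot(frac_extrasynaptic >= 0, frac_extrasynaptic <= 1)
  if (missing(seed)) stop("gen_ground_truth requires an explicit seed")
  set.seed(seed)
  labels <- sprintf("N%03d", seq_len(n_neurons))
  pairs <- expand.grid(from = seq_len(n_neurons), to = seq_len(n_neurons))
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  is_edge <- stats::runif(nrow(pairs)) < edge_density
  edges <- pairs[is_edge, , drop = FALSE]
  rownames(edges) <- NULL
  ne <- nrow(edges)
  edges$inhibitory <- if (ne) stats::runif(ne) < frac_inhibitory else logical(0)
  edges$extrasynaptic <- if (ne) stats::runif(ne) < frac_extrasynaptic else logical(0)

  draw_rates <- function(len, band) {
    exp(stats::runif(len, log(band[1]), log(band[2])))
  }
  kernels <- vector("list", ne)
  for (i in seq_len(ne)) {
    gain <- stats::runif(1, gain_band[1], gain_band[2])
    s <- if (edges$inhibitory[i]) -1 else 1
    len <- sample(1:2, 1)
    rates <- draw_rates(len, rate_band)
    chains <- list(list(c = s * gain * prod(rates), rates = rates))
    if (stats::runif(1) < frac_saturating) {
      # opposite-sign faster chain with a smaller absolute integral
      r2 <- draw_rates(1, c(mean(rate_band), rate_band[2] * 4))
      chains[[2]] <- list(c = -s * 0.3 * gain * prod(r2), rates = r2)
    }
    kernels[[i]] <- prop_kernel(chains)
  }

  net <- structure(list(n_neurons = n_neurons, labels = labels,
                        edges = edges, kernels = kernels),
                   class = "ground_truth_network")
  rho <- network_spectral_radius(net)
  if (rho >= 1) {
    stop(sprintf(paste0("requested edge density yields an unstable linear ",
                        "network (DC-gain spectral radius %.3f >= 1); ",
                        "reduce edge_density or gain_band"), rho))
  }
  net
}

#' Spectral radius of the network's DC-gain matrix
#' @param net A `ground_truth_network`.
#' @return Largest eigenvalue modulus of the matrix of kernel integrals.
#' @export
network_spectral_radius <- function(net) {
  G <- matrix(0, net$n_neurons, net$n_neurons)
  for (i in seq_len(nrow(net$edges))) {
    G[net$edges$to[i], net$edges$from[i]] <- kernel_integral(net$kernels[[i]])
  }
  if (all(G == 0)) return(0)
  max(Mod(eigen(G, only.values = TRUE)$values))
}

#' Network response of the ground-truth kernel network to a drive
#'
#' Solves the linear signal-propagation system x_i = drive * 1{i = j} +
#' sum_edges k_e * x_from(e) by fixed-point (Neumann-series) iteration, which
#' converges whenever the DC-gain spectral radius is below 1. With
#' `max_hops = 1` only direct edges contribute (no recursive re-propagation);
#' with `max_hops = Inf` the full effective response over all network paths
#' is returned.
#'
#' @param net A `ground_truth_network`.
#' @param j Driven neuron index.
#' @param drive Drive waveform (dF/F0).
#' @param dt Sampling interval in seconds.
#' @param max_hops Number of propagation steps (1 = direct only).
#' @param gates Optional logical vector over edges (per-trial reliability
#'   draws); gated-off edges do not transmit.
#' @param tol Convergence tolerance on the max absolute update.
#' @return Matrix (length(drive) x n_neurons) of dF/F0 responses.
#' @export
network_response <- function(net, j, drive, dt, max_hops = 1, gates = NULL,
                             tol = 1e-10) {
  n <- net$n_neurons
  L <- length(drive)
  ne <- nrow(net$edges)
  if (is.null(gates)) gates <- rep(TRUE, ne)
  kv <- lapply(net$kernels, eval_kernel, t_grid = (seq_len(L) - 1) * dt)
  x <- matrix(0, L, n)
  x[, j] <- drive
  if (ne == 0L || max_hops < 1) return(x)
  hop <- 0
  repeat {
    xn <- matrix(0, L, n)
    xn[, j] <- drive
    for (e in seq_len(ne)) {
      if (!gates[e]) next
      src <- x[, net$edges$from[e]]
      if (all(src == 0)) next
      xn[, net$edges$to[e]] <- xn[, net$edges$to[e]] +
        stats::convolve(src, rev(kv[[e]]), type = "open")[seq_len(L)] * dt
    }
    hop <- hop + 1
    done <- max(abs(xn - x)) < tol || hop >= max_hops || hop > 10 * n
    x <- xn
    if (done) break
  }
  x
}

#' Ground-truth correlation matrix of the kernel network
#'
#' Drives each neuron of `drive_set` through the ground-truth kernel network
#' and averages the per-drive Pearson correlation matrices of the responses,
#' exactly as the kernel-atlas prediction does. Serves as the synthetic
#' stand-in for observed spontaneous-activity correlations.
#'
#' @inheritParams network_response
#' @param drive_set Neuron indices to drive (default all).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
true_correlations <- function(net, drive, dt, drive_set = seq_len(net$n_neurons),
                              max_hops = 1) {
  n <- net$n_neurons
  acc <- matrix(0, n, n)
  for (j in drive_set) {
    A <- network_response(net, j, drive, dt, max_hops = max_hops)
    C <- suppressWarnings(stats::cor(A))
    C[!is.finite(C)] <- 0
    diag(C) <- 1
    acc <- acc + C
  }
  out <- acc / length(drive_set)
  dimnames(out) <- list(net$labels, net$labels)
  out
}

#' Simulate spontaneous network activity
#'
#' Generates "spontaneous" dF/F0 activity as the stationary response of the
#' linear kernel network to independent Gaussian drive in every neuron:
#' x = eta + K * x, solved by fixed-point iteration with full-trace
#' convolutions. The correlation matrix of this activity is the synthetic
#' analogue of spontaneous-activity correlations measured without
#' stimulation, against which network predictions are scored.
#'
#' @param net A `ground_truth_network`.
#' @param duration Simulated time in seconds.
#' @param dt Sampling interval in seconds.
#' @param drive_sd SD of the intrinsic Gaussian drive of driver neurons.
#' @param n_drivers Number of intrinsically active driver neurons (sampled
#'   at random); spontaneous dynamics in the worm are dominated by a small
#'   subset of neurons, and the remaining neurons receive only weak
#'   background drive (`background_frac * drive_sd`). `NULL` makes every
#'   neuron a driver.
#' @param background_frac Relative drive SD of non-driver neurons.
#' @param seed Integer seed.
#' @param smooth_tau Optional time constant (s) of an exponential filter
#'   applied to the white drive so intrinsic activity has calcium-like
#'   autocorrelation (default 2 s).
#' @return Matrix (time x neuron) of spontaneous dF/F0 activity; the driver
#'   indices are attached as attribute `drivers`.
#' @export
simulate_spontaneous <- function(net, duration = 1800, dt = 0.5,
                                 drive_sd = 0.1, n_drivers = NULL,
                                 background_frac = 0.1, seed,
                                 smooth_tau = 2) {
  if (missing(seed)) stop("simulate_spontaneous requires an explicit seed")
  set.seed(seed)
  n <- net$n_neurons
  L <- round(duration / dt)
  sds <- rep(drive_sd, n)
  drivers <- seq_len(n)
  if (!is.null(n_drivers) && n_drivers < n) {
    drivers <- sample.int(n, n_drivers)
    sds[-drivers] <- background_frac * drive_sd
  }
  eta <- matrix(stats::rnorm(L * n), L, n) %*% diag(sds, n)
  if (!is.null(smooth_tau) && smooth_tau > 0) {
    a <- exp(-dt / smooth_tau)
    eta <- apply(eta, 2, function(e) as.numeric(stats::filter(e, a,
                                                              method = "recursive")))
  }
  ne <- nrow(net$edges)
  if (ne == 0L) return(eta)
  kv <- lapply(net$kernels, eval_kernel, t_grid = (seq_len(L) - 1) * dt)
  x <- eta
  for (it in seq_len(10 * n)) {
    xn <- eta
    for (e in seq_len(ne)) {
      xn[, net$edges$to[e]] <- xn[, net$edges$to[e]] +
        stats::convolve(x[, net$edges$from[e]], rev(kv[[e]]),
                        type = "open")[seq_len(L)] * dt
    }
    if (max(abs(xn - x)) < 1e-9 * max(abs(xn))) { x <- xn; break }
    x <- xn
  }
  colnames(x) <- net$labels
  x
}

bleach_curve <- function(bleach, t) {
  if (is.null(bleach)) return(rep(1, length(t)))
  a <- bleach$a / sum(bleach$a)
  a[1] * exp(-bleach$rate[1] * t) + a[2] * exp(-bleach$rate[2] * t)
}

#' Simulate a stimulation-response recording
#'
#' Generates raw fluorescence `F[t, i] = baseline * (1 + s_i(t)) * bleach(t)
#' + noise`, where the dF/F0 signal `s` contains the stimulated neuron's
#' autoresponse for every stimulation event and, for each ground-truth edge
#' j -> i, the convolution of the propagation kernel with the autoresponse,
#' gated per trial by a Bernoulli(`response_probability`) draw. One target is
#' selected uniformly at random per inter-stimulus interval. Downstream
#' responses come from the direct ground-truth kernels only (no recursive
#' re-propagation), keeping the per-pair ground truth interpretable.
#'
#' @param net A `ground_truth_network`.
#' @param cfg A `sim_config`.
#' @param propagation `"direct"` (default) generates downstream responses
#'   from direct ground-truth kernels only, keeping per-pair ground truth
#'   interpretable; `"network"` propagates recursively through the linear
#'   kernel network, so responses are effective (all-paths) signals.
#' @return A `recording` object: `traces` (time x neuron raw fluorescence),
#'   `mask` (TRUE = missing), `time`, `dt`, `strain`, `labels` and `stim`
#'   (data.frame: time_s, target_index, duration_s, on_target).
#' @export
simulate_recording <- function(net, cfg, propagation = c("direct", "network")) {
  propagation <- match.arg(propagation)
  stopifnot(inherits(net, "ground_truth_network"), inherits(cfg, "sim_config"))
  rho <- network_spectral_radius(net)
  if (rho >= 1) stop(sprintf("network unstable (spectral radius %.3f)", rho))
  set.seed(cfg$seed)
  n <- net$n_neurons
  tg <- seq(0, cfg$duration - cfg$dt, by = cfg$dt)
  nt <- length(tg)
  # one target per isi window, first stimulus after a full pre-window
  stim_times <- seq(cfg$isi, cfg$duration - cfg$dt, by = cfg$isi)
  stim <- data.frame(time_s = stim_times,
                     target_index = sample.int(n, length(stim_times),
                                               replace = TRUE),
                     duration_s = cfg$stim_duration,
                     on_target = TRUE)

  template <- autoresponse_template(cfg$dt, peak = cfg$auto_peak)
  horizon <- 2L * length(template)           # response support per event
  s <- matrix(0, nt, n)
  edge_from <- net$edges$from; edge_to <- net$edges$to
  # precompute kernel values per edge on the horizon grid
  kvals <- lapply(net$kernels, eval_kernel,
                  t_grid = (seq_len(horizon) - 1) * cfg$dt)
  add_into <- function(col, i0, v) {
    idx <- i0 + seq_along(v) - 1L
    ok <- idx <= nt
    s[idx[ok], col] <<- s[idx[ok], col] + v[ok]
  }
  u_pad <- c(template, numeric(horizon - length(template)))
  for (ev in seq_len(nrow(stim))) {
    j <- stim$target_index[ev]
    i0 <- round(stim$time_s[ev] / cfg$dt) + 1L
    gates <- stats::runif(nrow(net$edges)) <= cfg$response_probability
    if (propagation == "direct") {
      add_into(j, i0, template)
      for (e in which(edge_from == j)) {
        if (!gates[e]) next
        resp <- stats::convolve(u_pad, rev(kvals[[e]]),
                                type = "open")[seq_len(horizon)] * cfg$dt
        add_into(edge_to[e], i0, resp)
      }
    } else {
      X <- network_response(net, j, u_pad, cfg$dt, max_hops = Inf,
                            gates = gates)
      for (i in seq_len(n)) {
        if (any(X[, i] != 0)) add_into(i, i0, X[, i])
      }
    }
  }

  Fmat <- cfg$baseline * (1 + s) * bleach_curve(cfg$bleach, tg) +
    matrix(stats::rnorm(nt * n, sd = cfg$noise_sd), nt, n)
  mask <- matrix(stats::runif(nt * n) < cfg$missing_fraction, nt, n)
  structure(list(traces = Fmat, mask = mask, time = tg, dt = cfg$dt,
                 strain = cfg$strain, labels = net$labels, stim = stim),
            class = "recording")
}

#' Simulate a control recording without stimulation
#'
#' Identical generative model to [simulate_recording] but with an empty
#' stimulation log; control recordings provide the empirical null
#' distributions for the connectivity statistics.
#'
#' @inheritParams simulate_recording
#' @return A `recording` with zero stimulation events.
#' @export
simulate_control <- function(net, cfg) {
  stopifnot(inherits(net, "ground_truth_network"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- net$n_neurons
  tg <- seq(0, cfg$duration - cfg$dt, by = cfg$dt)
  nt <- length(tg)
  Fmat <- cfg$baseline * bleach_curve(cfg$bleach, tg) +
    matrix(stats::rnorm(nt * n, sd = cfg$noise_sd), nt, n)
  mask <- matrix(stats::runif(nt * n) < cfg$missing_fraction, nt, n)
  stim <- data.frame(time_s = numeric(0), target_index = integer(0),
                     duration_s = numeric(0), on_target = logical(0))
  structure(list(traces = Fmat, mask = mask, time = tg, dt = cfg$dt,
                 strain = cfg$strain, labels = net$labels, stim = stim),
            class = "recording")
}

#' Generate a connectome matched to a ground-truth network
#'
#' Every non-extrasynaptic functional edge is wired with a positive integer
#' synapse count; `extra_anatomy_edges` additional anatomical-only edges
#' (wired but functionally silent) are added on non-functional pairs.
#' Synapse counts are drawn independently of the functional kernel gains,
#' reflecting the observation that bare anatomical weights are poor
#' predictors of functional strength. Edge signs follow the functional
#' inhibitory flags. A symmetric gap-junction matrix with `gap_edges`
#' unordered contacts can be added.
#'
#' @param net A `ground_truth_network`.
#' @param extra_anatomy_edges Number of anatomical-only chemical edges.
#' @param seed Integer seed.
#' @param gap_edges Number of symmetric gap-junction contacts (default 0).
#' @param count_lambda Poisson rate for synapse counts (counts are
#'   `1 + Poisson(count_lambda)`).
#' @return A `connectome` object (see [connectome]).
#' @export
gen_connectome <- function(net, extra_anatomy_edges = 0, seed,
                           gap_edges = 0, count_lambda = 3) {
  stopifnot(inherits(net, "ground_truth_network"))
  if (missing(seed)) stop("gen_connectome requires an explicit seed")
  set.seed(seed)
  n <- net$n_neurons
  chem <- matrix(0, n, n, dimnames = list(net$labels, net$labels))
  sgn <- matrix(1, n, n, dimnames = list(net$labels, net$labels))
  wired <- net$edges[!net$edges$extrasynaptic, , drop = FALSE]
  for (i in seq_len(nrow(wired))) {
    chem[wired$to[i], wired$from[i]] <- 1 + stats::rpois(1, count_lambda)
    sgn[wired$to[i], wired$from[i]] <- if (wired$inhibitory[i]) -1 else 1
  }
  if (extra_anatomy_edges > 0) {
    free <- which(chem == 0 & row(chem) != col(chem))
    # exclude functional (incl. extrasynaptic) pairs so the invariant
    # "extrasynaptic edges are absent from the connectome" holds
    if (nrow(net$edges) > 0) {
      fun_idx <- net$edges$to + (net$edges$from - 1L) * n
      free <- setdiff(free, fun_idx)
    }
    pick <- sample(free, min(extra_anatomy_edges, length(free)))
    chem[pick] <- 1 + stats::rpois(length(pick), count_lambda)
  }
  gap <- matrix(0, n, n, dimnames = list(net$labels, net$labels))
  if (gap_edges > 0) {
    up <- which(upper.tri(gap))
    pick <- sample(up, min(gap_edges, length(up)))
    gap[pick] <- 1 + stats::rpois(length(pick), count_lambda)
    gap <- gap + t(gap)
  }
  connectome(chem = chem, gap = gap, sign = sgn, labels = net$labels)
}
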