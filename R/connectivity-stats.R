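#' Build empirical null distributions from control recordings
#'
#' Pseudo-stimulation times are placed on the stimulus schedule (one every
#' `isi` seconds) in recordings that lack stimulation; for every pseudo-event
#' and neuron, the same per-observation summaries used for real pairs are
#' computed and pooled: the mean post-window dF/F0 and the maximum absolute
#' causal second derivative in the post window. Their SDs provide the sigma
#' in the equivalence margin epsilon = 1.2 sigma.
#'
#' @param controls List of control `recording`s with empty stimulation logs.
#' @param isi Pseudo-stimulation spacing in seconds (default 30).
#' @return A `null_distributions` object: `amp_samples`, `deriv_samples`,
#'   `sigma_amp`, `sigma_deriv`.
#' @export
build_null <- function(controls, isi = 30) {
  if (length(controls) == 0L)
    stop("no control recordings supplied; generate them with simulate_control()")
  amp <- c(); drv <- c()
  for (rec in controls) {
    stopifnot(inherits(rec, "recording"))
    if (nrow(rec$stim) > 0)
      stop("null distributions must be built from recordings lacking stimulation")
    prep <- preprocess_recording(rec)
    times <- seq(isi, max(rec$time) - isi + rec$dt / 2, by = isi)
    times <- times[times + 30 <= max(rec$time) + rec$dt / 2]
    for (tt in times) {
      for (j in seq_along(rec$labels)) {
        w <- response_window(prep$smoothed, tt, j)
        amp <- c(amp, response_amplitude(w))
        drv <- c(drv, max(abs(second_derivative(w)[w$t >= 0])))
      }
    }
  }
  if (length(amp) < 100)
    warning(sprintf("only %d null samples; 100 or more are recommended",
                    length(amp)))
  structure(list(amp_samples = amp, deriv_samples = drv,
                 sigma_amp = stats::sd(amp), sigma_deriv = stats::sd(drv)),
            class = "null_distributions")
}

#' Observation summaries for one ordered neuron pair
#'
#' Collects the per-observation summaries (mean post-window dF/F0 and max
#' |second derivative|) for all retained observations of an ordered
#' (stimulated, downstream) pair from a screen result.
#'
#' @param screen A `screen_result` from [apply_inclusion].
#' @param stim,down Neuron labels of the ordered pair.
#' @return List with numeric vectors `amp` and `deriv` (length = n_obs).
#' @export
pair_observations <- function(screen, stim, down) {
  tab <- screen$table
  keep <- tab$included & tab$stim_neuron == stim & tab$down_neuron == down
  list(amp = tab$amplitude[keep], deriv = tab$deriv_max[keep])
}

#' Two-sided KS p-values of a pair against the empirical null
#'
#' Compares the pair's pooled per-observation summaries (amplitude and second
#' derivative) with the corresponding null samples using two-sided two-sample
#' Kolmogorov-Smirnov tests.
#'
#' @param obs List with `amp` and `deriv` summary vectors (n_obs >= 1).
#' @param null A `null_distributions`.
#' @return Named vector `c(p_amp, p_deriv)`.
#' @export
ks_pair_pvalues <- function(obs, null) {
  stopifnot(inherits(null, "null_distributions"))
  if (length(null$amp_samples) == 0L) stop("empty null distribution")
  if (length(obs$amp) < 1L) stop("pair has no observations")
  p_amp <- suppressWarnings(
    stats::ks.test(obs$amp, null$amp_samples)$p.value)
  p_drv <- suppressWarnings(
    stats::ks.test(obs$deriv, null$deriv_samples)$p.value)
  c(p_amp = p_amp, p_deriv = p_drv)
}

#' Combine two p-values with Fisher's method
#'
#' The fused p-value is the upper-tail probability of a chi-square
#' distribution with 4 degrees of freedom at -2(ln p1 + ln p2). Zero inputs
#' are clamped to the smallest positive representable value.
#'
#' @param p_amp,p_deriv p-values in (0, 1].
#' @return Fused p-value.
#' @export
fisher_combine <- function(p_amp, p_deriv) {
  clamp <- function(p) {
    if (any(p == 0)) message("p-value of 0 clamped to the smallest positive double")
    pmax(p, .Machine$double.xmin)
  }
  stat <- -2 * (log(clamp(p_amp)) + log(clamp(p_deriv)))
  stats::pchisq(stat, df = 4, lower.tail = FALSE)
}

#' Storey-Tibshirani q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0, 0.05, ..., 0.90
#' with a cubic smoother evaluated at the largest lambda (clipped to (0, 1]),
#' then computes q_i = min over p_j >= p_i of pi0 * m * p_j / rank(p_j).
#' q-values are monotone non-decreasing in p and capped at 1. Among calls
#' with q <= q_c, approximately a q_c fraction would have appeared in a
#' recording lacking any stimulation.
#'
#' @param p Numeric vector of p-values.
#' @return Numeric vector of q-values in the input order.
#' @export
storey_qvalues <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m == 0L) return(numeric(0))
  if (m < 10) warning("fewer than 10 p-values; pi0 estimate will be unstable")
  lambda <- seq(0, 0.90, by = 0.05)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  pi0 <- if (m >= 4) {
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    stats::predict(fit, x = 0.90)$y
  } else pi0_l[1]
  pi0 <- min(max(pi0, 1 / m), 1)
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- pmin(cummin(pi0 * m * p[o] / seq(m, 1)), 1)
  q
}

welch_tost <- function(x, y, eps) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se <- sqrt(vx / nx + vy / ny)
  if (!is.finite(se) || se == 0) return(1)
  df <- (vx / nx + vy / ny)^2 /
    ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  d <- mean(x) - mean(y)
  p_lower <- stats::pt((d + eps) / se, df, lower.tail = FALSE) # H0: d <= -eps
  p_upper <- stats::pt((d - eps) / se, df)                     # H0: d >= +eps
  max(p_lower, p_upper)
}

#' TOST equivalence p-value of a pair against the null
#'
#' Two one-sided Welch t-tests of the pair's mean summary against the null
#' sample with equivalence margin epsilon = `eps_factor` * sigma, where sigma
#' is the SD of the corresponding null summary distribution. The amplitude
#' and second-derivative summaries are tested separately (per-summary p_eq =
#' max of the two one-sided p-values) and fused with Fisher's method.
#'
#' @param obs List with `amp` and `deriv` summary vectors.
#' @param null A `null_distributions`.
#' @param eps_factor Margin multiplier on the null SD (default 1.2).
#' @return Equivalence p-value `p_eq`; 1 when n_obs < 2 (equivalence cannot
#'   be claimed from a single observation).
#' @export
tost_pair_pvalue <- function(obs, null, eps_factor = 1.2) {
  stopifnot(inherits(null, "null_distributions"), eps_factor >= 0)
  if (length(obs$amp) < 2L) {
    message("fewer than 2 observations: p_eq = 1")
    return(1)
  }
  p_amp <- welch_tost(obs$amp, null$amp_samples,
                      eps_factor * null$sigma_amp)
  p_drv <- welch_tost(obs$deriv, null$deriv_samples,
                      eps_factor * null$sigma_deriv)
  fisher_combine(p_amp, p_drv)
}

#' Classify neuron pairs from their q-values
#'
#' A pair is `connected` when q < `alpha`, `non_connected` when q_eq <
#' `alpha` and q >= `alpha`, and `undetermined` otherwise (neither test gives
#' confidence for a determination). No pair can carry both labels.
#'
#' @param stats A data.frame with columns `q` and `q_eq`.
#' @param alpha Significance threshold (default 0.05).
#' @return The data.frame with a `label` column added.
#' @export
classify_pairs <- function(stats, alpha = 0.05) {
  stopifnot(all(c("q", "q_eq") %in% names(stats)))
  stats$label <- ifelse(stats$q < alpha, "connected",
                        ifelse(stats$q_eq < alpha, "non_connected",
                               "undetermined"))
  stats
}

#' Pair-statistics table for a set of screened observations
#'
#' Groups retained observations by ordered pair and computes per-pair
#' statistics: n_obs, mean amplitude, KS p-values against the null, the
#' Fisher-fused p, Storey-Tibshirani q, TOST equivalence p_eq and q_eq, and
#' the connected / non_connected / undetermined label.
#'
#' @param screen A `screen_result` (or a list of them, pooled).
#' @param null A `null_distributions`.
#' @param eps_factor Equivalence margin multiplier (default 1.2).
#' @param alpha Significance threshold (default 0.05).
#' @return A data.frame, one row per measured ordered pair.
#' @export
pair_stats_table <- function(screen, null, eps_factor = 1.2, alpha = 0.05) {
  screens <- if (inherits(screen, "screen_result")) list(screen) else screen
  tabs <- do.call(rbind, lapply(seq_along(screens), function(i) {
    tb <- screens[[i]]$table
    if (nrow(tb)) tb$.src <- i
    tb
  }))
  keep <- tabs[tabs$included, , drop = FALSE]
  if (nrow(keep) == 0L)
    return(data.frame(stim = character(0), down = character(0),
                      n_obs = integer(0), amp_mean = numeric(0),
                      p_amp = numeric(0), p_deriv = numeric(0),
                      p = numeric(0), q = numeric(0), p_eq = numeric(0),
                      q_eq = numeric(0), label = character(0)))
  key <- paste(keep$stim_neuron, keep$down_neuron, sep = "\r")
  out <- lapply(unique(key), function(k) {
    rows <- keep[key == k, , drop = FALSE]
    obs <- list(amp = numeric(0), deriv = numeric(0))
    for (src in unique(rows$.src)) {
      o <- pair_observations(screens[[src]], rows$stim_neuron[1],
                             rows$down_neuron[1])
      obs$amp <- c(obs$amp, o$amp); obs$deriv <- c(obs$deriv, o$deriv)
    }
    pk <- ks_pair_pvalues(obs, null)
    data.frame(stim = rows$stim_neuron[1], down = rows$down_neuron[1],
               n_obs = length(obs$amp), amp_mean = mean(obs$amp),
               p_amp = pk[["p_amp"]], p_deriv = pk[["p_deriv"]],
               p = fisher_combine(pk[["p_amp"]], pk[["p_deriv"]]),
               p_eq = suppressMessages(
                 tost_pair_pvalue(obs, null, eps_factor)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$q <- storey_qvalues(out$p)
  out$q_eq <- storey_qvalues(out$p_eq)
  out <- classify_pairs(out, alpha)
  out[, c("stim", "down", "n_obs", "amp_mean", "p_amp", "p_deriv", "p", "q",
          "p_eq", "q_eq", "label")]
}

#' Screen for purely extrasynaptic-dependent connections
#'
#' Returns the ordered pairs that are functionally connected in the wild-type
#' atlas (q < alpha) and functionally non-connected in the
#' dense-core-vesicle-release-deficient mutant atlas (q_eq < alpha), with the
#' additional condition q(mutant) > alpha to exclude small responses that
#' still differ significantly from the control distribution. Pairs absent
#' from one atlas are excluded and counted in a message.
#'
#' @param wt,mut Pair-statistics data.frames (from [pair_stats_table]).
#' @param alpha Significance threshold (default 0.05).
#' @return Subset of merged pairs passing the screen, with both atlases' q
#'   columns.
#' @export
extrasynaptic_screen <- function(wt, mut, alpha = 0.05) {
  m <- merge(wt, mut, by = c("stim", "down"), suffixes = c("_wt", "_mut"))
  dropped <- nrow(wt) + nrow(mut) - 2 * nrow(m)
  if (dropped > 0)
    message(sprintf("%d pair rows present in only one atlas were excluded",
                    dropped))
  hits <- m$q_wt < alpha & m$q_eq_mut < alpha & m$q_mut > alpha
  m[hits, c("stim", "down", "q_wt", "q_mut", "q_eq_mut", "amp_mean_wt")]
}
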