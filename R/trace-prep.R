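#' Raw fluorescence trace set
#'
#' Container for a time x neuron fluorescence matrix with a missing-value
#' mask and sampling interval.
#'
#' @param F Numeric matrix, time x neuron.
#' @param mask Logical matrix of the same shape; TRUE marks missing samples.
#' @param dt Sampling interval in seconds.
#' @param labels Neuron identifiers (NA = unidentified).
#' @return A `trace_set` object.
#' @export
trace_set <- function(F, mask = NULL, dt, labels = NULL) {
  F <- as.matrix(F)
  if (is.null(mask)) mask <- matrix(FALSE, nrow(F), ncol(F))
  if (is.null(labels)) labels <- colnames(F)
  if (is.null(labels)) labels <- sprintf("N%03d", seq_len(ncol(F)))
  stopifnot(dt > 0, all(dim(mask) == dim(F)))
  if (any(!is.finite(F[!mask])))
    stop("non-finite fluorescence at samples not marked missing")
  structure(list(F = F, mask = mask, dt = dt, labels = labels),
            class = "trace_set")
}

#' Convert a recording to a trace set
#' @param rec A `recording`.
#' @return A `trace_set` sharing the recording's traces, mask and dt.
#' @export
as_trace_set <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  trace_set(rec$traces, rec$mask, rec$dt, rec$labels)
}

#' Interpolate missing samples (pre-processing step 1)
#'
#' Interior gaps are filled linearly between the neighbouring present time
#' points; gaps at either end are held at the nearest present value. This is
#' the only non-causal stage of the pre-processing chain.
#'
#' @param tr A `trace_set`.
#' @return A `trace_set` with an all-false mask; present samples unchanged.
#' @export
interpolate_missing <- function(tr) {
  stopifnot(inherits(tr, "trace_set"))
  F <- tr$F
  nt <- nrow(F)
  for (j in seq_len(ncol(F))) {
    miss <- tr$mask[, j]
    if (!any(miss)) next
    present <- which(!miss)
    if (length(present) < 2L)
      stop(sprintf("trace %s has fewer than 2 present samples",
                   tr$labels[j]))
    F[miss, j] <- stats::approx(present, F[present, j], xout = which(miss),
                                rule = 2)$y
  }
  trace_set(F, NULL, tr$dt, tr$labels)
}

fit_bleach_baseline <- function(y, t, n_irls = 4) {
  # robust double-exponential baseline fit b(t) = A*(a1 e^{-r1 t} + (1-a1) e^{-r2 t});
  # iterative reweighting drives the fit to the baseline by down-weighting
  # samples more than 1 SD above the current fit (calcium transients are
  # positive excursions).
  obj <- function(par, w) {
    A <- exp(par[1]); a1 <- stats::plogis(par[2])
    r1 <- exp(par[3]); r2 <- exp(par[4])
    b <- A * (a1 * exp(-r1 * t) + (1 - a1) * exp(-r2 * t))
    sum(w * (y - b)^2)
  }
  eval_b <- function(par) {
    A <- exp(par[1]); a1 <- stats::plogis(par[2])
    exp(par[1]) * (a1 * exp(-exp(par[3]) * t) + (1 - a1) * exp(-exp(par[4]) * t))
  }
  Tlen <- max(t)
  par <- c(log(max(mean(y[seq_len(max(3, length(y) %/% 20))]), 1e-8)), 0,
           log(5 / max(Tlen, 1)), log(0.2 / max(Tlen, 1)))
  w <- rep(1, length(y))
  ok <- TRUE
  for (it in seq_len(n_irls)) {
    fit <- tryCatch(
      stats::optim(par, obj, w = w, method = "L-BFGS-B",
                   lower = c(-20, -15, -25, -25), upper = c(30, 15, 5, 5),
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit)) { ok <- FALSE; break }
    par <- fit$par
    res <- y - eval_b(par)
    s <- stats::sd(res)
    if (!is.finite(s) || s == 0) break
    w <- ifelse(res > s, 0.02, 1)
  }
  if (!ok) {
    # fall back to a single exponential
    obj1 <- function(p, w) {
      b <- exp(p[1]) * exp(-exp(p[2]) * t)
      sum(w * (y - b)^2)
    }
    fit <- stats::optim(c(par[1], par[4]), obj1, w = w, method = "L-BFGS-B",
                        lower = c(-20, -25), upper = c(30, 5))
    A <- exp(fit$par[1]); r <- exp(fit$par[2])
    return(list(b = A * exp(-r * t), single = TRUE, rates = r))
  }
  list(b = eval_b(par), single = FALSE,
       rates = sort(exp(par[3:4])))
}

#' Correct photobleaching (pre-processing step 2)
#'
#' Fits a double exponential to the baseline of each trace (a robust,
#' iteratively reweighted fit that down-weights positive excursions, i.e.
#' calcium transients) and divides it out, renormalized so the baseline's
#' initial value is preserved. If the double-exponential fit fails the stage
#' falls back to a single exponential and flags it in a message.
#'
#' @param tr A `trace_set` without missing values (run
#'   [interpolate_missing] first).
#' @return A bleach-corrected `trace_set`.
#' @export
correct_photobleach <- function(tr) {
  stopifnot(inherits(tr, "trace_set"))
  if (any(tr$mask)) tr <- interpolate_missing(tr)
  F <- tr$F
  t <- (seq_len(nrow(F)) - 1) * tr$dt
  Tlen <- max(t)
  for (j in seq_len(ncol(F))) {
    fit <- fit_bleach_baseline(F[, j], t)
    if (fit$single)
      message(sprintf("trace %s: double-exponential fit failed, used single exponential",
                      tr$labels[j]))
    tau_slow <- 1 / min(fit$rates)
    if (is.finite(tau_slow) && tau_slow < 1e6 && Tlen < 10 * tau_slow &&
        tau_slow < 100 * Tlen)
      warning(sprintf("trace %s: recording (%.0f s) shorter than 10x the slow bleach timescale (%.0f s)",
                      tr$labels[j], Tlen, tau_slow), call. = FALSE)
    b <- fit$b
    F[, j] <- F[, j] / b * b[1]
  }
  trace_set(F, NULL, tr$dt, tr$labels)
}

#' Remove outlier samples (pre-processing step 3)
#'
#' Samples more than `k` standard deviations from the per-trace mean are
#' marked missing and re-interpolated; the mean and SD are then re-estimated
#' once and the detection repeated (one re-estimation pass). Constant traces
#' (zero SD) pass through unchanged.
#'
#' @param tr A `trace_set`.
#' @param k SD multiplier (default 5).
#' @return A `trace_set` with outliers replaced by interpolation.
#' @export
remove_outliers <- function(tr, k = 5) {
  stopifnot(inherits(tr, "trace_set"), k > 0)
  if (any(tr$mask)) tr <- interpolate_missing(tr)
  F <- tr$F
  for (pass in 1:2) {
    mask <- matrix(FALSE, nrow(F), ncol(F))
    for (j in seq_len(ncol(F))) {
      s <- stats::sd(F[, j])
      if (!is.finite(s) || s == 0) next
      mask[, j] <- abs(F[, j] - mean(F[, j])) > k * s
    }
    if (!any(mask)) break
    F <- interpolate_missing(trace_set(F, mask, tr$dt, tr$labels))$F
  }
  trace_set(F, NULL, tr$dt, tr$labels)
}

sg_causal_weights <- function(m, order, deriv = 0, dt = 1) {
  # least-squares polynomial fit over the m most recent samples, evaluated at
  # the window's final position; returns weights over x = (t-m+1)..t
  x <- seq_len(m) - 1
  X <- outer(x, 0:order, `^`)
  H <- solve(crossprod(X), t(X))        # (order+1) x m
  if (deriv == 0) return(as.numeric(X[m, , drop = FALSE] %*% H))
  # derivative of the fitted polynomial of given order at the final position
  dcoef <- numeric(order + 1)
  for (p in deriv:order) {
    dcoef[p + 1] <- prod(seq(p, p - deriv + 1)) * x[m]^(p - deriv)
  }
  as.numeric(dcoef %*% H) / dt^deriv
}

apply_causal_filter <- function(y, m, order, deriv = 0, dt = 1) {
  n <- length(y)
  w <- sg_causal_weights(m, order, deriv, dt)
  out <- as.numeric(stats::filter(y, rev(w), method = "convolution", sides = 1))
  # head: shrunken causal windows of the same form
  for (i in seq_len(min(m - 1L, n))) {
    mi <- i
    oi <- min(order, mi - 1L)
    if (oi < deriv) { out[i] <- 0; next }
    wi <- sg_causal_weights(mi, oi, deriv, dt)
    out[i] <- sum(wi * y[seq_len(i)])
  }
  out
}

#' Causal Savitzky-Golay smoothing (pre-processing step 4)
#'
#' Order-1 polynomial smoothing with a 13-sample window (6.5 s at 0.5-s
#' sampling) evaluated at the window's final position, so the filter is fully
#' "in the past" and does not smear activity onsets forward in time. The
#' first 12 samples use shrunken causal windows of the same form. Smoothed
#' traces are used for display and statistics; kernel fitting runs on the
#' original, non-smoothed traces.
#'
#' @param tr A `trace_set`.
#' @param window Window length in samples (default 13).
#' @param order Polynomial order (default 1).
#' @return A smoothed `trace_set`.
#' @export
smooth_causal <- function(tr, window = 13, order = 1) {
  stopifnot(inherits(tr, "trace_set"))
  if (nrow(tr$F) < window)
    stop(sprintf("trace length %d shorter than the %d-sample filter window",
                 nrow(tr$F), window))
  if (any(tr$mask)) tr <- interpolate_missing(tr)
  F <- apply(tr$F, 2, apply_causal_filter, m = window, order = order)
  trace_set(F, NULL, tr$dt, tr$labels)
}

#' Run the full pre-processing chain on a recording
#'
#' interpolate -> photobleach-correct -> outlier-remove -> smooth, in the
#' fixed pipeline order. Returns both the smoothed traces (for statistics and
#' display) and the unsmoothed traces after the first three steps (for kernel
#' fitting), plus the original missing mask (used by the inclusion criteria).
#'
#' @param rec A `recording`.
#' @param k Outlier SD multiplier.
#' @return List with `smoothed` and `raw` `trace_set`s and `mask_orig`.
#' @export
preprocess_recording <- function(rec, k = 5) {
  tr <- as_trace_set(rec)
  tr <- interpolate_missing(tr)
  tr <- suppressWarnings(correct_photobleach(tr))
  tr <- remove_outliers(tr, k = k)
  list(smoothed = smooth_causal(tr), raw = tr, mask_orig = rec$mask)
}

#' Extract a dF/F0 response window around a stimulus
#'
#' F0 is the mean fluorescence over the 30 s preceding the stimulus; the
#' window holds dF/F0 = (F - F0)/F0 over t in [-30, +30) s (half-open,
#' stimulus at t = 0). A shorter available window is flagged via the
#' `truncated` field.
#'
#' @param tr A `trace_set`.
#' @param stim_time Stimulus time in seconds (grid origin at 0).
#' @param neuron Neuron index or label.
#' @param half_width Window half width in seconds (default 30).
#' @return A `response_window`: `values`, `t`, `dt`, `F0`, `truncated`.
#' @export
response_window <- function(tr, stim_time, neuron, half_width = 30) {
  stopifnot(inherits(tr, "trace_set"))
  if (is.character(neuron)) neuron <- match(neuron, tr$labels)
  stopifnot(!is.na(neuron), neuron >= 1, neuron <= ncol(tr$F))
  dt <- tr$dt
  i_stim <- round(stim_time / dt) + 1L
  nw <- round(half_width / dt)
  i_lo <- i_stim - nw
  i_hi <- i_stim + nw - 1L
  truncated <- i_lo < 1L || i_hi > nrow(tr$F)
  i_lo_c <- max(i_lo, 1L); i_hi_c <- min(i_hi, nrow(tr$F))
  pre_idx <- seq(i_lo_c, i_stim - 1L)
  if (length(pre_idx) < 2L) stop("no pre-stimulus baseline available")
  F0 <- mean(tr$F[pre_idx, neuron])
  if (!is.finite(F0) || F0 <= 0)
    stop(sprintf("invalid baseline F0 = %g for neuron %s", F0,
                 tr$labels[neuron]))
  idx <- seq(i_lo_c, i_hi_c)
  structure(list(values = (tr$F[idx, neuron] - F0) / F0,
                 t = (idx - i_stim) * dt, dt = dt, F0 = F0,
                 truncated = truncated, neuron = tr$labels[neuron]),
            class = "response_window")
}

#' Post-stimulus part of a response window
#' @param w A `response_window`.
#' @return Numeric vector of dF/F0 values at t >= 0.
#' @export
window_post <- function(w) w$values[w$t >= 0]

#' Temporal second derivative of a response window
#'
#' Savitzky-Golay differentiation with the same causal 13-sample window used
#' for smoothing, polynomial order 2, evaluated at the window's final
#' position. Exact for quadratics; units 1/s^2.
#'
#' @param w A `response_window` (or any numeric series via `values`/`dt`).
#' @param window Window length in samples (default 13).
#' @return Numeric series of second-derivative estimates.
#' @export
second_derivative <- function(w, window = 13) {
  if (inherits(w, "response_window")) {
    y <- w$values; dt <- w$dt
  } else {
    stop("second_derivative expects a response_window")
  }
  if (length(y) < window)
    warning("window shorter than the differentiation filter; head estimates shrink")
  apply_causal_filter(y, m = min(window, length(y)), order = 2, deriv = 2,
                      dt = dt)
}
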