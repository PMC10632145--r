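#' Fit a signal-propagation kernel to a stimulus-response pair
#'
#' Least-squares fit of `downstream ~ (k * upstream)` over the post-stimulus
#' window, with the kernel parametrized as a sum of at most `max_chains`
#' exponential-convolution chains (two chains of opposite sign represent
#' saturating transmission). Chain lengths 1-3 and chain counts 1-`max_chains`
#' are compared by a small-sample information criterion (AICc); decay rates
#' are bounded in `rate_bounds` and the optimizer is restarted from log-spaced
#' rate initializations. Fits are intended to run on the original,
#' non-smoothed traces. When the downstream neuron failed response detection
#' the kernel is taken to be zero by convention; the zero model also competes
#' in selection, so a flat downstream trace returns the zero kernel.
#'
#' @param upstream Numeric vector, upstream dF/F0 over the response window.
#' @param downstream Numeric vector of the same length.
#' @param dt Sampling interval in seconds.
#' @param max_chains Maximum number of chains in the sum (default 2).
#' @param rate_bounds Two-element vector of rate bounds in 1/s; the default
#'   `c(1/60, 10)` reflects a 30-s window sampled at 0.5 s.
#' @param downstream_responded Logical; `FALSE` forces the zero kernel.
#' @param n_starts Number of multistart rate initializations per model.
#' @return A `prop_kernel`, with attributes `rss` (residual sum of squares),
#'   `r2` (fraction of downstream variance explained) and `converged`.
#' @export
fit_kernel <- function(upstream, downstream, dt, max_chains = 2,
                       rate_bounds = c(1 / 60, 10),
                       downstream_responded = TRUE, n_starts = 3) {
  stopifnot(length(upstream) == length(downstream), dt > 0)
  stopifnot(all(is.finite(upstream)), all(is.finite(downstream)))
  if (!downstream_responded) return(zero_kernel())
  n <- length(downstream)
  lb <- log(rate_bounds[1]); ub <- log(rate_bounds[2])

  rss0 <- sum(downstream^2)   # zero-kernel model
  tgrid <- (seq_len(n) - 1) * dt

  build_kernel <- function(par, lens) {
    chains <- list(); ofs <- 0L
    for (l in lens) {
      chains[[length(chains) + 1L]] <-
        list(c = par[ofs + 1L], rates = exp(par[ofs + 1L + seq_len(l)]))
      ofs <- ofs + 1L + l
    }
    prop_kernel(chains)
  }
  kv_of <- function(par, lens) {
    kv <- numeric(n); ofs <- 0L
    for (l in lens) {
      kv <- kv + eval_chain_fast(par[ofs + 1L], exp(par[ofs + 1L + seq_len(l)]),
                                 tgrid)
      ofs <- ofs + 1L + l
    }
    kv
  }
  objective <- function(par, lens) {
    kv <- kv_of(par, lens)
    if (any(!is.finite(kv))) return(1e12)
    pred <- stats::convolve(upstream, rev(kv), type = "open")[seq_len(n)] * dt
    v <- sum((downstream - pred)^2)
    if (!is.finite(v)) 1e12 else v
  }

  # Models: chain-length tuples; one chain of length 1..3, and for two-chain
  # (saturating) kernels the light combinations that cover fast+slow shapes.
  model_lens <- list(1L, 2L, 3L)
  if (max_chains >= 2) model_lens <- c(model_lens, list(c(1L, 1L), c(1L, 2L), c(2L, 2L)))

  start_rates <- exp(seq(lb + 0.5, ub - 0.5, length.out = max(n_starts, 2)))
  best <- list(rss = rss0, k = zero_kernel(), npar = 0L, converged = TRUE)
  aicc <- function(rss, npar) {
    kk <- npar + 1  # + residual variance
    n * log(max(rss, 1e-300) / n) + 2 * kk + 2 * kk * (kk + 1) / max(n - kk - 1, 1)
  }
  best_ic <- aicc(rss0, 0L)

  for (lens in model_lens) {
    npar <- length(lens) + sum(lens)
    for (g0 in start_rates) {
      par0 <- numeric(0)
      for (ci in seq_along(lens)) {
        l <- lens[ci]
        rates0 <- pmin(pmax(g0 * (2^(seq_len(l) - 1)) * (if (ci == 2) 3 else 1),
                            rate_bounds[1] * 1.01), rate_bounds[2] * 0.99)
        # closed-form initial coefficient: project downstream on the c=1 chain
        probe <- prop_kernel(list(list(c = 1, rates = rates0)))
        pv <- apply_kernel(probe, upstream, dt)
        c0 <- if (sum(pv^2) > 0) sum(pv * downstream) / sum(pv^2) else 0
        if (ci == 2) c0 <- -0.3 * c0
        par0 <- c(par0, c0, log(rates0))
      }
      lower <- rep(-Inf, npar); upper <- rep(Inf, npar)
      ofs <- 0L
      for (l in lens) {
        lower[ofs + 1L + seq_len(l)] <- lb
        upper[ofs + 1L + seq_len(l)] <- ub
        ofs <- ofs + 1L + l
      }
      fit <- tryCatch(
        stats::optim(par0, objective, lens = lens, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = 300)),
        error = function(e) NULL)
      if (is.null(fit)) next
      ic <- aicc(fit$value, npar)
      if (ic < best_ic) {
        best_ic <- ic
        best <- list(rss = fit$value, k = build_kernel(fit$par, lens),
                     npar = npar, converged = fit$convergence == 0)
      }
    }
  }

  k <- best$k
  sst <- sum((downstream - mean(downstream))^2)
  attr(k, "rss") <- best$rss
  attr(k, "r2") <- if (sst > 0) 1 - best$rss / sst else NA_real_
  attr(k, "converged") <- best$converged
  k
}

#' Average kernels across trials on a reference grid
#'
#' The trial-averaged kernel <k(t)>_trials used by the kernel atlas is
#' represented numerically: trial kernels are evaluated on a common grid and
#' averaged. The result is wrapped so it can be applied like any kernel.
#'
#' @param kernels List of `prop_kernel`s (zero kernels count as zeros).
#' @param t_max Grid extent in seconds.
#' @param dt Grid step in seconds.
#' @return A `numeric_kernel` object (values on the grid) usable by
#'   [apply_kernel_numeric].
#' @export
average_kernels <- function(kernels, t_max = 60, dt = 0.5) {
  tg <- seq(0, t_max, by = dt)
  vals <- vapply(kernels, eval_kernel, numeric(length(tg)), t_grid = tg)
  structure(list(t = tg, values = rowMeans(vals), dt = dt),
            class = "numeric_kernel")
}

#' Apply a numerically represented kernel to an upstream trace
#' @param k A `numeric_kernel` from [average_kernels].
#' @param upstream Numeric vector on the same sampling grid.
#' @param dt Sampling interval in seconds (must match the kernel grid).
#' @return Convolution output of the same length as `upstream`.
#' @export
apply_kernel_numeric <- function(k, upstream, dt) {
  stopifnot(inherits(k, "numeric_kernel"))
  if (abs(dt - k$dt) > 1e-12) stop("dt mismatch between kernel grid and trace")
  L <- length(upstream)
  kv <- k$values
  if (length(kv) < L) kv <- c(kv, numeric(L - length(kv)))
  kv <- kv[seq_len(L)]
  stats::convolve(upstream, rev(kv), type = "open")[seq_len(L)] * dt
}
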