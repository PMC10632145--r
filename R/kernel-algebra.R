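#' Canonical kernel term a * theta(t) * t^n * exp(-gamma t)
#'
#' The building block of the symbolic kernel representation. Successive
#' convolutions of causal decaying exponentials always stay within the span of
#' these terms, which is what makes the kernel algebra closed and exact.
#'
#' @param a Coefficient (any real).
#' @param n Non-negative integer power of t.
#' @param gamma Decay rate in 1/s, strictly positive.
#' @return An object of class `canonical_term`.
#' @export
canonical_term <- function(a, n, gamma) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a))
  stopifnot(n >= 0, n == round(n))
  stopifnot(gamma > 0)
  structure(list(a = a, n = as.integer(n), gamma = gamma),
            class = "canonical_term")
}

#' Signal-propagation kernel as a sum of exponential-convolution chains
#'
#' A kernel is k(t) = sum_m c_m (theta(t) e^(-g_m0 t)) * (theta(t) e^(-g_m1 t)) * ...
#' where `*` is convolution and theta the Heaviside step; each summand is a
#' "chain". Two chains of opposite sign represent saturating transmission.
#' The canonical expansion into `canonical_term`s is computed symbolically and
#' cached.
#'
#' @param chains List of chains, each a `list(c = coefficient, rates = numeric
#'   vector of positive decay rates)`. An empty list gives the zero kernel.
#' @return An object of class `prop_kernel`.
#' @export
prop_kernel <- function(chains = list()) {
  for (ch in chains) {
    stopifnot(is.list(ch), !is.null(ch$c), !is.null(ch$rates))
    stopifnot(length(ch$rates) >= 1L, all(ch$rates > 0))
  }
  k <- structure(list(chains = chains), class = "prop_kernel")
  k$canonical <- to_canonical(k)
  k
}

#' The zero kernel
#'
#' Used for neuron pairs whose downstream response fell below detection: the
#' convention is that their propagation kernel is identically zero.
#' @return A `prop_kernel` with no chains.
#' @export
zero_kernel <- function() prop_kernel(list())

#' @export
is_zero_kernel <- function(k) length(k$chains) == 0L

#' @export
print.prop_kernel <- function(x, ...) {
  if (is_zero_kernel(x)) {
    cat("<zero kernel>\n")
    return(invisible(x))
  }
  cat(sprintf("<kernel: %d chain(s), integral %.4g>\n",
              length(x$chains), kernel_integral(x)))
  for (ch in x$chains) {
    cat(sprintf("  c = %.4g, rates = [%s] 1/s\n", ch$c,
                paste(signif(ch$rates, 4), collapse = ", ")))
  }
  invisible(x)
}

#' Convolve a canonical term with a normalized decaying exponential
#'
#' Applies the closed-form rules for convolving a term a*theta(t)*t^n*e^(-gi t)
#' with the normalized exponential gn*theta(t)*e^(-gn t):
#' \itemize{
#'   \item n = 0, gi != gn: splits into two simple exponentials with
#'     coefficients +/- a*gn/(gn - gi) at rates gi and gn.
#'   \item n = 0, gi = gn: a single t*e^(-gi t) term with coefficient a*gi.
#'   \item n >= 1, gi = gn: power raised to n+1, coefficient a*gi/(n+1).
#'   \item n >= 1, gi != gn: one power-n term at rate gi plus a recursive
#'     convolution of the power-(n-1) term.
#' }
#' Equal rates are detected by exact comparison: distinct-rate and equal-rate
#' chains are distinct model classes in the fitting code, so near-duplicates
#' do not arise there, and exact comparison avoids the unstable gn - gi -> 0
#' limit of the distinct-rate rule.
#'
#' @param term A `canonical_term`.
#' @param gamma_n Rate of the normalized exponential factor (1/s).
#' @return A list of `canonical_term`s whose sum is the convolution.
#' @export
convolve_exp <- function(term, gamma_n) {
  stopifnot(inherits(term, "canonical_term"), gamma_n > 0)
  a <- term$a; n <- term$n; gi <- term$gamma
  if (n == 0L) {
    if (gi == gamma_n) {
      return(list(canonical_term(a * gi, 1L, gi)))
    }
    cmu <- a * gamma_n / (gamma_n - gi)
    return(list(canonical_term(cmu, 0L, gi),
                canonical_term(-cmu, 0L, gamma_n)))
  }
  if (gi == gamma_n) {
    return(list(canonical_term(a * gi / (n + 1), n + 1L, gi)))
  }
  cmu <- a * gamma_n / (gamma_n - gi)
  head_term <- canonical_term(cmu, n, gi)
  # Recursion: the residual term is -n*a/(gn-gi) * t^(n-1)e^(-gi t) convolved
  # with the same normalized exponential.
  tail_terms <- convolve_exp(canonical_term(-n * a / (gamma_n - gi), n - 1L, gi),
                             gamma_n)
  c(list(head_term), tail_terms)
}

merge_canonical <- function(terms) {
  if (length(terms) == 0L) return(list())
  key <- vapply(terms, function(tm) paste(tm$n, format(tm$gamma, digits = 17)),
                character(1))
  out <- list()
  for (k in unique(key)) {
    grp <- terms[key == k]
    a <- sum(vapply(grp, `[[`, numeric(1), "a"))
    out[[length(out) + 1L]] <- canonical_term(a, grp[[1]]$n, grp[[1]]$gamma)
  }
  out
}

#' Expand a kernel into canonical terms
#'
#' Folds each chain left to right: the first factor c*theta(t)e^(-g0 t) is a
#' single canonical term, and every further (unnormalized) exponential factor
#' is applied through [convolve_exp] with the normalized exponential followed
#' by division by its rate. Terms sharing (n, gamma) are merged.
#'
#' @param k A `prop_kernel`.
#' @return List of `canonical_term`s.
#' @export
to_canonical <- function(k) {
  stopifnot(inherits(k, "prop_kernel"))
  all_terms <- list()
  for (ch in k$chains) {
    terms <- list(canonical_term(ch$c, 0L, ch$rates[1]))
    for (g in ch$rates[-1]) {
      terms <- do.call(c, lapply(terms, convolve_exp, gamma_n = g))
      # chain factors are unnormalized theta(t)e^(-g t); undo the normalization
      terms <- lapply(terms, function(tm) { tm$a <- tm$a / g; tm })
    }
    all_terms <- c(all_terms, terms)
  }
  merge_canonical(all_terms)
}

#' Evaluate a kernel on a time grid
#'
#' @param k A `prop_kernel`.
#' @param t_grid Sorted numeric vector of times in seconds.
#' @return Numeric vector of kernel values; exactly 0 for t < 0.
#' @export
eval_kernel <- function(k, t_grid) {
  stopifnot(inherits(k, "prop_kernel"))
  out <- numeric(length(t_grid))
  pos <- t_grid >= 0
  tp <- t_grid[pos]
  for (tm in k$canonical) {
    # t^n * exp(-g t) computed in log space where possible to stay
    # overflow-safe at large g*t (underflows cleanly to 0)
    v <- tm$a * exp(tm$n * log(pmax(tp, .Machine$double.xmin)) - tm$gamma * tp)
    if (tm$n > 0) v[tp == 0] <- 0
    out[pos] <- out[pos] + v
  }
  out
}

#' Integral of a kernel over t in [0, Inf)
#'
#' Each unnormalized factor theta(t)e^(-g t) integrates to 1/g, so a chain
#' integrates to c * prod(1/rates); equivalently each canonical term
#' integrates to a * n! / gamma^(n+1).
#'
#' @param k A `prop_kernel`.
#' @param use_canonical Integrate the canonical expansion instead of the
#'   chain product form (the two must agree; used for cross-checks).
#' @return Scalar integral.
#' @export
kernel_integral <- function(k, use_canonical = FALSE) {
  if (is_zero_kernel(k)) return(0)
  if (use_canonical) {
    return(sum(vapply(k$canonical, function(tm)
      tm$a * factorial(tm$n) / tm$gamma^(tm$n + 1), numeric(1))))
  }
  sum(vapply(k$chains, function(ch) ch$c * prod(1 / ch$rates), numeric(1)))
}

# Fast numeric canonical expansion of one chain, used in fitting inner loops:
# terms held as a 3-column matrix (a, n, gamma), no S3 overhead. Same
# convolution rules as convolve_exp.
chain_terms_fast <- function(cc, rates) {
  terms <- matrix(c(cc, 0, rates[1]), 1, 3)
  conv_one <- function(a, nn, gi, gn) {
    out <- matrix(0, 0, 3)
    repeat {
      if (nn == 0) {
        if (gi == gn) return(rbind(out, c(a * gi, 1, gi)))
        cmu <- a * gn / (gn - gi)
        return(rbind(out, c(cmu, 0, gi), c(-cmu, 0, gn)))
      }
      if (gi == gn) return(rbind(out, c(a * gi / (nn + 1), nn + 1, gi)))
      cmu <- a * gn / (gn - gi)
      out <- rbind(out, c(cmu, nn, gi))
      a <- -nn * a / (gn - gi)
      nn <- nn - 1
    }
  }
  for (g in rates[-1]) {
    nxt <- vector("list", nrow(terms))
    for (r in seq_len(nrow(terms))) {
      nxt[[r]] <- conv_one(terms[r, 1], terms[r, 2], terms[r, 3], g)
    }
    terms <- do.call(rbind, nxt)
    terms[, 1] <- terms[, 1] / g
  }
  terms
}

eval_chain_fast <- function(cc, rates, t) {
  terms <- chain_terms_fast(cc, rates)
  out <- numeric(length(t))
  for (r in seq_len(nrow(terms))) {
    out <- out + terms[r, 1] * t^terms[r, 2] * exp(-terms[r, 3] * t)
  }
  out
}

#' Apply a kernel to an upstream activity trace
#'
#' Discrete causal convolution (k * u)(t) ~ dt * sum_s k(s) u(t - s) on the
#' sampling grid of the trace.
#'
#' @param k A `prop_kernel`.
#' @param upstream Numeric vector, upstream dF/F0 (causal, finite).
#' @param dt Sampling interval in seconds.
#' @return Numeric vector of the same length as `upstream`.
#' @export
apply_kernel <- function(k, upstream, dt) {
  stopifnot(is.numeric(upstream), all(is.finite(upstream)), dt > 0)
  L <- length(upstream)
  if (is_zero_kernel(k) || L == 0L) return(numeric(L))
  kv <- eval_kernel(k, (seq_len(L) - 1) * dt)
  if (L == 1L) return(kv * upstream * dt)
  out <- stats::convolve(upstream, rev(kv), type = "open")[seq_len(L)] * dt
  out
}

#' Remove saturation terms from a kernel
#'
#' Saturating transmission is represented by a second chain of sign opposite
#' to the dominant one; it delays the apparent kernel peak and masks the true
#' rise time. The dominant chain is the one with the largest absolute
#' integral; chains whose integral opposes its sign are dropped.
#'
#' @param k A `prop_kernel`.
#' @return A `prop_kernel` containing only the non-saturating chains.
#' @export
desaturate_kernel <- function(k) {
  if (length(k$chains) <= 1L) return(k)
  ints <- vapply(k$chains, function(ch) ch$c * prod(1 / ch$rates), numeric(1))
  dom <- which.max(abs(ints))
  keep <- sign(ints) == sign(ints[dom])
  prop_kernel(k$chains[keep])
}

#' Rise time of a kernel
#'
#' After removing saturation terms, the rise time is the interval between the
#' earliest time at which |k| reaches 1/e of its peak value and the time of
#' the peak; it is 0 when the peak sits at t = 0 (instantaneous transmission,
#' e.g. a single decaying exponential).
#'
#' @param k A non-zero `prop_kernel`.
#' @param dt_grid Resolution of the evaluation grid in seconds.
#' @param t_max Upper end of the search grid in seconds; defaults to ten times
#'   the slowest timescale, capped at 600 s.
#' @return Rise time in seconds.
#' @export
rise_time <- function(k, dt_grid = 1e-3, t_max = NULL) {
  if (is_zero_kernel(k)) stop("rise time is undefined for the zero kernel")
  kd <- desaturate_kernel(k)
  rates <- unlist(lapply(kd$chains, `[[`, "rates"))
  if (is.null(t_max)) t_max <- min(600, 10 / min(rates))
  tg <- seq(0, t_max, by = dt_grid)
  v <- abs(eval_kernel(kd, tg))
  ipk <- which.max(v)
  if (ipk == 1L) return(0)
  thr <- v[ipk] / exp(1)
  i0 <- which(v >= thr)[1]
  tg[ipk] - tg[i0]
}

#' Stereotypy of a functional connection
#'
#' Trial-to-trial consistency of a connection: every pair of single-trial
#' kernels is compared round-robin by convolving both with the same stimulus
#' and correlating the outputs; the result is the mean Pearson correlation
#' over all unordered kernel pairs and all stimuli.
#'
#' @param kernels List of at least two `prop_kernel`s (one per trial).
#' @param stimuli List of stimulus input series (numeric vectors).
#' @param dt Sampling interval in seconds.
#' @return Mean Pearson correlation (scalar).
#' @export
stereotypy <- function(kernels, stimuli, dt) {
  if (length(kernels) < 2L)
    stop("stereotypy requires at least two kernels (stimulus-response events)")
  if (!is.list(stimuli)) stimuli <- list(stimuli)
  stopifnot(length(stimuli) >= 1L)
  cors <- c()
  for (stim in stimuli) {
    outs <- lapply(kernels, apply_kernel, upstream = stim, dt = dt)
    for (i in seq_len(length(outs) - 1L)) {
      for (j in seq(i + 1L, length(outs))) {
        cors <- c(cors, stats::cor(outs[[i]], outs[[j]]))
      }
    }
  }
  mean(cors)
}
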