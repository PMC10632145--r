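test_that("convolution rules match the closed forms", {
  # equal rates: simple exponential convolved with its own normalized
  # exponential gives c*gamma * t * exp(-gamma t)
  out <- convolve_exp(canonical_term(1, 0, 0.7), 0.7)
  expect_length(out, 1)
  expect_equal(out[[1]]$a, 0.7)
  expect_equal(out[[1]]$n, 1L)
  expect_equal(out[[1]]$gamma, 0.7)

  # distinct rates split into +/- gn/(gn - gi) exponential pair
  out <- convolve_exp(canonical_term(1, 0, 1), 2)
  expect_length(out, 2)
  expect_equal(sapply(out, `[[`, "a"), c(2, -2))
  expect_equal(sapply(out, `[[`, "gamma"), c(1, 2))

  # power term with equal rates raises the power
  out <- convolve_exp(canonical_term(3, 2, 0.5), 0.5)
  expect_length(out, 1)
  expect_equal(out[[1]]$a, 3 * 0.5 / 3)
  expect_equal(out[[1]]$n, 3L)

  # distinct-rate rules agree with direct numerical convolution
  dt <- 5e-4; tg <- seq(0, 40, dt)
  for (case in list(c(1, 2), c(0.3, 1.7), c(2, 0.11))) {
    num <- trap_conv(exp(-case[1] * tg), case[2] * exp(-case[2] * tg), dt)
    terms <- convolve_exp(canonical_term(1, 0, case[1]), case[2])
    sym <- Reduce(`+`, lapply(terms, function(tm)
      tm$a * tg^tm$n * exp(-tm$gamma * tg)))
    expect_lt(max(abs(sym - num)) / max(abs(num)), 1e-6)
  }
})

test_that("canonical expansion reproduces repeated-rate chains and integrals", {
  # triple convolution at one rate collapses to (1/2) t^2 exp(-g t)
  k <- prop_kernel(list(list(c = 1, rates = c(0.8, 0.8, 0.8))))
  expect_length(k$canonical, 1)
  expect_equal(k$canonical[[1]]$n, 2L)
  expect_equal(k$canonical[[1]]$a, 0.5)
  expect_equal(kernel_integral(k, use_canonical = TRUE), 1 / 0.8^3)

  # integral identity: chain product form vs canonical term-by-term integrals
  set.seed(41)
  for (i in 1:25) {
    k <- random_kernel()
    expect_equal(kernel_integral(k, use_canonical = TRUE),
                 kernel_integral(k), tolerance = 1e-10)
  }
})

test_that("symbolic evaluation matches numerical convolution of the factors", {
  set.seed(7)
  dt <- 1e-3; tg <- seq(0, 40, dt)
  for (i in 1:20) {
    k <- random_kernel()
    num <- kernel_conv_oracle(k, tg, dt)
    sym <- eval_kernel(k, tg)
    expect_lt(max(abs(sym - num)) / max(abs(num)), 1e-6)
  }
})

test_that("kernels are causal and convolution order is irrelevant", {
  k <- prop_kernel(list(list(c = 1.5, rates = c(0.2, 1.1, 0.6))))
  expect_identical(eval_kernel(k, c(-10, -0.5)), c(0, 0))
  tg <- seq(0, 30, 0.05)
  kab <- prop_kernel(list(list(c = 1, rates = c(0.3, 2))))
  kba <- prop_kernel(list(list(c = 1, rates = c(2, 0.3))))
  expect_equal(eval_kernel(kab, tg), eval_kernel(kba, tg), tolerance = 1e-12)
})

test_that("apply_kernel is linear and matches the closed-form step response", {
  dt <- 0.01
  u_step <- rep(1, 3000)
  g <- 0.4; a <- 1.3
  k <- prop_kernel(list(list(c = a, rates = g)))
  out <- apply_kernel(k, u_step, dt)
  tg <- (seq_along(u_step) - 1) * dt
  expect_equal(out, a * (1 - exp(-g * tg)) / g, tolerance = 5e-3)
  # linearity is exact
  u <- sin(seq(0, 4, length.out = 200))
  expect_equal(apply_kernel(k, 3.7 * u, 0.5), 3.7 * apply_kernel(k, u, 0.5))
  # zero kernel maps everything to zero
  expect_identical(apply_kernel(zero_kernel(), u, 0.5), numeric(length(u)))
})

test_that("rise time follows the peak/e definition with desaturation", {
  # single decaying exponential peaks at t = 0
  expect_equal(rise_time(prop_kernel(list(list(c = 2, rates = 0.5)))), 0)
  # t*exp(-g t): dense-grid oracle
  g <- 0.8
  k <- prop_kernel(list(list(c = 1, rates = c(g, g))))
  tg <- seq(0, 60, 1e-4)
  v <- abs(eval_kernel(k, tg))
  ipk <- which.max(v)
  oracle <- tg[ipk] - tg[which(v >= v[ipk] / exp(1))[1]]
  expect_equal(rise_time(k, dt_grid = 1e-4), oracle, tolerance = 1e-3)
  # saturating pair whose desaturated part is a pure exponential: rise 0
  ksat <- prop_kernel(list(list(c = 1, rates = 0.3),
                           list(c = -0.5, rates = 2)))
  expect_gt(rise_time(ksat, t_max = 60) - 0, -1e-12)  # defined
  expect_equal(rise_time(ksat), 0)
  expect_error(rise_time(zero_kernel()), "undefined")
})

test_that("stereotypy equals the brute-force round-robin oracle", {
  dt <- 0.5
  stimuli <- list(autoresponse_template(dt),
                  autoresponse_template(dt, tau_rise = 0.5, tau_decay = 4))
  k1 <- prop_kernel(list(list(c = 0.5, rates = 0.3)))
  k2 <- prop_kernel(list(list(c = 0.8, rates = 1.2)))
  k3 <- prop_kernel(list(list(c = 0.4, rates = c(0.3, 0.7))))
  kernels <- list(k1, k2, k3)
  # brute-force loop oracle
  vals <- c()
  for (s in stimuli) {
    outs <- lapply(kernels, apply_kernel, upstream = s, dt = dt)
    for (i in 1:2) for (j in (i + 1):3)
      vals <- c(vals, cor(outs[[i]], outs[[j]]))
  }
  expect_equal(stereotypy(kernels, stimuli, dt), mean(vals))
  # identical kernels are perfectly stereotyped; sign flip gives -1
  expect_equal(stereotypy(list(k1, k1), stimuli, dt), 1.0)
  km <- prop_kernel(list(list(c = -0.5, rates = 0.3)))
  expect_equal(stereotypy(list(k1, km), stimuli, dt), -1.0)
  expect_error(stereotypy(list(k1), stimuli, dt), "at least two")
})

test_that("longer chains add flexibility without overfitting", {
  dt <- 0.5
  u <- autoresponse_template(dt)
  rss_for_len <- function(y, len) {
    obj <- function(par) {
      kv <- sigprop:::eval_chain_fast(par[1], exp(par[-1]),
                                      (seq_along(u) - 1) * dt)
      pred <- stats::convolve(u, rev(kv), type = "open")[seq_along(u)] * dt
      sum((y - pred)^2)
    }
    best <- Inf
    starts <- lapply(c(0.1, 0.4, 1), function(g0) log(rep(g0, len)))
    if (len > 1) {
      # shorter-chain optima padded with near-delta factors
      for (g0 in c(0.1, 0.4, 1)) {
        starts <- c(starts, list(log(c(rep(g0, len - 1), 1e3))),
                    list(log(c(g0, rep(1e3, len - 1)))))
      }
    }
    for (s0 in starts) {
      probe <- sigprop:::eval_chain_fast(1, exp(s0), (seq_along(u) - 1) * dt)
      pv <- stats::convolve(u, rev(probe), type = "open")[seq_along(u)] * dt
      c0 <- if (sum(pv^2) > 0) sum(pv * y) / sum(pv^2) else 0.1
      fit <- optim(c(c0, s0), obj, method = "L-BFGS-B",
                   lower = c(-Inf, rep(log(1 / 60), len)),
                   upper = c(Inf, rep(log(1e4), len)),
                   control = list(maxit = 500))
      best <- min(best, fit$value)
    }
    best
  }
  # data from a short chain: longer chains still fit essentially perfectly
  # (an extra near-delta factor reproduces the shorter chain up to grid
  # discretization), so extending the chain causes no overfitting blow-up
  y1 <- apply_kernel(prop_kernel(list(list(c = 0.2, rates = 0.4))), u, dt)
  expect_lt(rss_for_len(y1, 2), 1e-2 * sum(y1^2))
  expect_lt(rss_for_len(y1, 3), 1e-2 * sum(y1^2))
  # data from a long chain: longer chains genuinely fit better
  y3 <- apply_kernel(prop_kernel(list(list(c = 0.2, rates = c(0.4, 0.5, 0.7)))),
                     u, dt)
  r1 <- rss_for_len(y3, 1); r2 <- rss_for_len(y3, 2); r3 <- rss_for_len(y3, 3)
  expect_lt(r2, r1)
  expect_lte(r3, r2 * (1 + 1e-6))
})
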