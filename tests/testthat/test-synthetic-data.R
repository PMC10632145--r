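test_that("network generation honours density and sign fractions", {
  # empty and complete graphs
  expect_equal(nrow(gen_ground_truth(10, 0, seed = 1)$edges), 0)
  net_full <- gen_ground_truth(10, 1, frac_inhibitory = 0,
                               seed = 1, gain_band = c(0.01, 0.05))
  expect_equal(nrow(net_full$edges), 90)
  ints <- vapply(net_full$kernels, kernel_integral, numeric(1))
  expect_true(all(ints > 0))
  expect_false(any(net_full$edges$from == net_full$edges$to))

  # inhibitory fraction across seeds follows the binomial draw
  fr <- vapply(1:20, function(s) {
    net <- gen_ground_truth(50, 0.1, frac_inhibitory = 0.11, seed = s)
    mean(net$edges$inhibitory)
  }, numeric(1))
  # binomial oracle: mean of Bin(ne, 0.11)/ne over 20 seeds, ne ~ 245
  expect_lt(abs(mean(fr) - 0.11), 2 * sqrt(0.11 * 0.89 / (245 * 20)) + 0.01)
  # inhibitory edges have negative kernel integrals
  net <- gen_ground_truth(30, 0.2, frac_inhibitory = 0.5, seed = 4)
  ints <- vapply(net$kernels, kernel_integral, numeric(1))
  expect_true(all(sign(ints) == ifelse(net$edges$inhibitory, -1, 1)))
})

test_that("unstable networks are rejected with a diagnostic", {
  expect_error(gen_ground_truth(20, 0.9, seed = 2, gain_band = c(0.5, 0.9)),
               "unstable")
})

test_that("recordings are reproducible and follow the stimulus schedule", {
  net <- gen_ground_truth(5, 0.2, seed = 3)
  cfg <- sim_config(duration = 600, seed = 9)
  r1 <- simulate_recording(net, cfg)
  r2 <- simulate_recording(net, cfg)
  expect_identical(r1, r2)
  # one stimulus per isi window, none in the final pre-window-less stretch
  expect_equal(nrow(r1$stim), floor(600 / 30) - 1)
  expect_true(all(diff(r1$stim$time_s) == 30))
  c1 <- simulate_control(net, cfg)
  expect_identical(c1, simulate_control(net, cfg))
  expect_equal(nrow(c1$stim), 0)
})

test_that("downstream responses equal the kernel convolution of the autoresponse", {
  k <- prop_kernel(list(list(c = 0.3, rates = 0.4)))
  net <- toy_single_edge_net(k)
  cfg <- sim_config(duration = 300, noise_sd = 0, bleach = NULL,
                    missing_fraction = 0, response_probability = 1, seed = 5)
  rec <- simulate_recording(net, cfg)
  s <- rec$traces / cfg$baseline - 1     # back out dF/F0
  # pick a stimulation of neuron 1 whose 60-s response window contains no
  # other stimulation of neuron 1
  ev1 <- which(rec$stim$target_index == 1)
  clean <- ev1[vapply(ev1, function(e) !any(abs(rec$stim$time_s[ev1] -
    rec$stim$time_s[e]) %in% c(30, 60) &
    rec$stim$time_s[ev1] > rec$stim$time_s[e]), logical(1))]
  ev <- clean[1]
  stopifnot(is.finite(ev))
  i0 <- round(rec$stim$time_s[ev] / cfg$dt) + 1L
  tmpl <- autoresponse_template(cfg$dt)
  L <- 120
  num <- trap_conv(c(tmpl, numeric(L - length(tmpl))),
                   eval_kernel(k, (seq_len(L) - 1) * cfg$dt), cfg$dt)
  got <- s[i0 + seq_len(L) - 1L, 2]
  # left-Riemann generator vs trapezoid oracle differ by O(dt); compare to
  # the generator's own rule exactly
  gen <- stats::convolve(c(tmpl, numeric(L - length(tmpl))),
                         rev(eval_kernel(k, (seq_len(L) - 1) * cfg$dt)),
                         type = "open")[seq_len(L)] * cfg$dt
  expect_lt(max(abs(got - gen)), 1e-8)
  # against the continuous-convolution (trapezoid) oracle the generator's
  # 0.5-s left-Riemann rule carries an O(dt * gamma) discretization bias
  expect_lt(max(abs(got - num)), 0.2 * max(abs(num)))
  expect_gt(cor(got, num), 0.99)
  # a network with no edges leaves non-stimulated neurons silent
  net0 <- gen_ground_truth(4, 0, seed = 1)
  rec0 <- simulate_recording(net0, cfg)
  s0 <- rec0$traces / cfg$baseline - 1
  stimmed <- unique(rec0$stim$target_index)
  for (i in setdiff(1:4, stimmed)) expect_equal(max(abs(s0[, i])), 0)
})

test_that("trial gating follows the response probability", {
  k <- prop_kernel(list(list(c = 0.5, rates = 0.5)))
  net <- toy_single_edge_net(k, n = 2)
  # force every stimulus onto neuron 1 by using a 2-neuron net and counting
  # only events that targeted neuron 1
  cfg <- sim_config(duration = 3630, noise_sd = 0, bleach = NULL,
                    missing_fraction = 0, response_probability = 0.5,
                    seed = 21)
  rec <- simulate_recording(net, cfg)
  ev1 <- which(rec$stim$target_index == 1)
  s <- rec$traces / cfg$baseline - 1
  responded <- vapply(ev1, function(ev) {
    i0 <- round(rec$stim$time_s[ev] / cfg$dt) + 1L
    any(abs(s[i0 + 1:20, 2]) > 1e-6)
  }, logical(1))
  n <- length(ev1)
  expect_gt(n, 30)
  expect_lt(abs(mean(responded) - 0.5), 2.5 * sqrt(0.25 / n))
})

test_that("control fluctuations match the configured noise level", {
  net <- gen_ground_truth(3, 0, seed = 1)
  for (sd0 in c(1, 2)) {
    cfg <- sim_config(duration = 600, noise_sd = sd0, bleach = NULL,
                      missing_fraction = 0, seed = 31)
    ctl <- simulate_control(net, cfg)
    expect_lt(abs(sd(ctl$traces[, 1]) - sd0) / sd0, 0.1)
  }
})

test_that("connectomes contain wired functional edges plus anatomical extras", {
  net <- gen_ground_truth(12, 0.1, frac_extrasynaptic = 0.4, seed = 6)
  wired <- net$edges[!net$edges$extrasynaptic, ]
  extra <- 3
  conn <- gen_connectome(net, extra_anatomy_edges = extra, seed = 7)
  expect_equal(sum(conn$chem > 0), nrow(wired) + extra)
  expect_true(all(conn$chem == round(conn$chem)) && all(conn$chem >= 0))
  expect_equal(conn$gap, t(conn$gap))
  # every wired functional edge is present with at least one synapse
  for (r in seq_len(nrow(wired)))
    expect_gte(conn$chem[wired$to[r], wired$from[r]], 1)
  # extrasynaptic edges are absent from the connectome
  es <- net$edges[net$edges$extrasynaptic, ]
  for (r in seq_len(nrow(es)))
    expect_equal(conn$chem[es$to[r], es$from[r]], 0,
                 ignore_attr = TRUE)
  # all edges extrasynaptic, no extras -> empty connectome
  net_es <- gen_ground_truth(6, 0.3, frac_extrasynaptic = 1, seed = 8)
  expect_equal(sum(gen_connectome(net_es, 0, seed = 9)$chem), 0)
})

test_that("network propagation mode reduces to the direct mode at one hop", {
  net <- gen_ground_truth(6, 0.25, seed = 12)
  drive <- autoresponse_template(0.5)
  pad <- c(drive, numeric(60))
  for (j in 1:3) {
    x1 <- network_response(net, j, pad, 0.5, max_hops = 1)
    xi <- network_response(net, j, pad, 0.5, max_hops = Inf)
    # direct mode equals the first Neumann term; full mode adds higher hops
    direct <- matrix(0, length(pad), net$n_neurons)
    direct[, j] <- pad
    for (e in which(net$edges$from == j)) {
      kv <- eval_kernel(net$kernels[[e]], (seq_along(pad) - 1) * 0.5)
      direct[, net$edges$to[e]] <- direct[, net$edges$to[e]] +
        stats::convolve(pad, rev(kv), type = "open")[seq_along(pad)] * 0.5
    }
    expect_equal(x1, direct, tolerance = 1e-12)
    expect_true(max(abs(xi - x1)) < max(abs(x1)))  # corrections are smaller
  }
})
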