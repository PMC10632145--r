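# A cheap synthetic null built directly from summary draws: many tests only
# need the distributional machinery, not full recordings.
direct_null <- function(n = 2000, sd_amp = 0.004, sd_drv = 0.002, seed = 1) {
  set.seed(seed)
  structure(list(amp_samples = rnorm(n, 0, sd_amp),
                 deriv_samples = abs(rnorm(n, 0.004, sd_drv)),
                 sigma_amp = sd_amp, sigma_deriv = sd_drv),
            class = "null_distributions")
}

test_that("null distributions come from control recordings on the schedule", {
  net <- gen_ground_truth(6, 0, seed = 1)
  ctl <- simulate_control(net, sim_config(duration = 600, bleach = NULL,
                                          seed = 50))
  null <- suppressWarnings(build_null(list(ctl)))
  expect_s3_class(null, "null_distributions")
  expect_lt(abs(mean(null$amp_samples)), 3 * null$sigma_amp /
              sqrt(length(null$amp_samples) / 10))
  # determinism
  null2 <- suppressWarnings(build_null(list(ctl)))
  expect_identical(null, null2)
  # doubling the noise roughly doubles sigma_amp
  ctl2 <- simulate_control(net, sim_config(duration = 600, bleach = NULL,
                                           noise_sd = 2, seed = 50))
  null_2x <- suppressWarnings(build_null(list(ctl2)))
  expect_lt(abs(null_2x$sigma_amp / null$sigma_amp - 2), 0.2)
  # stimulated recordings are rejected; empty input instructs the user
  rec <- simulate_recording(net, sim_config(duration = 600, seed = 51))
  expect_error(build_null(list(rec)), "lacking stimulation")
  expect_error(build_null(list()), "simulate_control")
})

test_that("KS pair p-values are calibrated under the null and powered at 10 sigma", {
  null <- direct_null()
  set.seed(2)
  ps <- replicate(200, {
    obs <- list(amp = rnorm(10, 0, null$sigma_amp),
                deriv = abs(rnorm(10, 0.004, null$sigma_deriv)))
    ks_pair_pvalues(obs, null)[["p_amp"]]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  # strong separation
  obs <- list(amp = rnorm(10, 10 * null$sigma_amp, null$sigma_amp),
              deriv = abs(rnorm(10, 0.004, null$sigma_deriv)))
  expect_lt(ks_pair_pvalues(obs, null)[["p_amp"]], 1e-3)
  # single observation drawn from the null cannot be distinguished
  obs1 <- list(amp = null$amp_samples[7], deriv = null$deriv_samples[7])
  expect_gt(ks_pair_pvalues(obs1, null)[["p_amp"]], 0.5)
  expect_error(ks_pair_pvalues(list(amp = numeric(0), deriv = numeric(0)),
                               null), "no observations")
})

test_that("Fisher combination matches the chi-square oracle and is monotone", {
  expect_equal(fisher_combine(1, 1), 1)
  # independent oracle: survival function of chisq_4
  p <- fisher_combine(0.05, 0.05)
  expect_equal(p, 1 - pchisq(-2 * (log(0.05) + log(0.05)), df = 4))
  seqp <- 10^seq(-1, -8)
  vals <- vapply(seqp, function(x) fisher_combine(x, x), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[length(vals)], 1e-10)
  expect_message(p0 <- fisher_combine(0, 0.5), "clamped")
  expect_gte(p0, 0)
})

test_that("Storey-Tibshirani q-values behave like the published recipe", {
  expect_equal(storey_qvalues(rep(1, 50)), rep(1, 50))
  # brute-force oracle for the min-over-tail definition at fixed pi0
  set.seed(3)
  p <- runif(40)
  q <- storey_qvalues(p)
  m <- length(p)
  lambda <- seq(0, 0.9, 0.05)
  pi0_l <- sapply(lambda, function(l) mean(p > l) / (1 - l))
  pi0 <- min(max(predict(smooth.spline(lambda, pi0_l, df = 3), x = 0.9)$y,
                 1 / m), 1)
  q_oracle <- sapply(p, function(pi) {
    min(sapply(which(p >= pi), function(j)
      pi0 * m * p[j] / rank(p)[j]))
  })
  expect_equal(q, pmin(q_oracle, 1), tolerance = 1e-12)
  # q is monotone in p
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # uniform p: pi0 estimate near 1
  set.seed(4)
  q_null <- storey_qvalues(runif(2000))
  pi0_hat <- attr(q_null, "pi0")
  p2 <- runif(2000)
  pi0_l <- sapply(lambda, function(l) mean(p2 > l) / (1 - l))
  pi0_hat <- predict(smooth.spline(lambda, pi0_l, df = 3), x = 0.9)$y
  expect_lt(abs(pi0_hat - 1), 0.15)
})

test_that("q-values estimate the realized false-discovery proportion", {
  # mixed simulation: q <= q_c implies about q_c of the calls are nulls
  set.seed(5)
  m0 <- 1500; m1 <- 500
  z <- c(rnorm(m0), rnorm(m1, mean = 3.2))
  p <- 1 - pnorm(z)
  truth_null <- rep(c(TRUE, FALSE), c(m0, m1))
  q <- storey_qvalues(p)
  sel <- q <= 0.1
  fdp <- sum(truth_null & sel) / max(sum(sel), 1)
  expect_lt(fdp, 0.1 + 2 * sqrt(0.1 * 0.9 / sum(sel)) + 0.02)
})

test_that("TOST equivalence p-values move the right way", {
  null <- direct_null()
  set.seed(6)
  # matching distributions with many observations: equivalence detected
  obs_eq <- list(amp = rnorm(200, 0, null$sigma_amp),
                 deriv = abs(rnorm(200, 0.004, null$sigma_deriv)))
  expect_lt(tost_pair_pvalue(obs_eq, null), 0.01)
  # 3-sigma shift: equivalence clearly rejected
  obs_far <- list(amp = rnorm(10, 3 * null$sigma_amp, null$sigma_amp),
                  deriv = abs(rnorm(10, 0.004, null$sigma_deriv)) +
                    3 * null$sigma_deriv)
  expect_gt(tost_pair_pvalue(obs_far, null), 0.5)
  # zero margin can never support equivalence
  expect_gte(sigprop:::welch_tost(rnorm(20), rnorm(1000), eps = 0), 0.5)
  # single observation: no equivalence claim
  expect_message(
    p1 <- tost_pair_pvalue(list(amp = 0.1, deriv = 0.1), null), "fewer")
  expect_equal(p1, 1)
})

test_that("pair classification follows the q-threshold rules exclusively", {
  df <- data.frame(q = c(0.01, 0.5, 0.5, 0.01),
                   q_eq = c(0.5, 0.01, 0.5, 0.01))
  out <- classify_pairs(df)
  expect_equal(out$label,
               c("connected", "non_connected", "undetermined", "connected"))
  expect_false(any(out$label == "connected" & out$label == "non_connected"))
})

test_that("the extrasynaptic screen applies all three q conditions", {
  wt <- data.frame(stim = c("A", "A", "B", "C"), down = c("B", "C", "C", "A"),
                   q = c(0.01, 0.01, 0.01, 0.5), q_eq = 0.5,
                   amp_mean = 0.2)
  mut <- data.frame(stim = c("A", "A", "B"), down = c("B", "C", "C"),
                    q = c(0.5, 0.01, 0.01), q_eq = c(0.01, 0.01, 0.5),
                    amp_mean = 0.05)
  hits <- suppressMessages(extrasynaptic_screen(wt, mut))
  # A->B: connected in WT, equivalent in mutant, q_mut > 0.05 -> hit
  # A->C: q_mut < 0.05 violates the additional condition
  # B->C: not equivalent in the mutant
  # C->A: absent from the mutant atlas
  expect_equal(nrow(hits), 1)
  expect_equal(hits$stim, "A"); expect_equal(hits$down, "B")
})

test_that("pair tables carry calibrated statistics end to end", {
  k <- prop_kernel(list(list(c = 0.5 * 0.4, rates = 0.4)))
  net <- toy_single_edge_net(k, n = 4)
  cfg <- sim_config(duration = 1500, seed = 60)
  rec <- simulate_recording(net, cfg)
  ctls <- lapply(1:2, function(i)
    simulate_control(net, sim_config(duration = 900, seed = 70 + i,
                                     strain = "control")))
  null <- suppressWarnings(build_null(ctls))
  scr <- quiet_screen(rec)
  tab <- pair_stats_table(scr, null)
  expect_true(all(c("p", "q", "p_eq", "q_eq", "label") %in% names(tab)))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_true(all(tab$q >= 0 & tab$q <= 1))
  # the planted edge is the most significant pair when measured
  edge_row <- tab[tab$stim == "N001" & tab$down == "N002", ]
  if (nrow(edge_row) && edge_row$n_obs >= 3) {
    expect_lt(edge_row$p, min(tab$p[!(tab$stim == "N001" &
                                        tab$down == "N002")]) + 1e-6)
  }
  # no pair is both connected and non-connected by construction
  expect_false(any(tab$q < 0.05 & tab$label == "non_connected"))
})
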