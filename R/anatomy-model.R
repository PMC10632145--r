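#' Directed weighted connectome
#'
#' @param chem Post x pre matrix of chemical synapse counts/weights
#'   (`chem[i, j]` = synapses from j onto i), non-negative.
#' @param gap Symmetric matrix of gap-junction contact counts.
#' @param sign Post x pre matrix of +1/-1 polarities (used where chem > 0).
#' @param labels Neuron labels.
#' @return A `connectome` object.
#' @export
connectome <- function(chem, gap = NULL, sign = NULL, labels = NULL) {
  chem <- as.matrix(chem)
  n <- nrow(chem)
  stopifnot(ncol(chem) == n, all(chem >= 0))
  if (is.null(gap)) gap <- matrix(0, n, n)
  if (is.null(sign)) sign <- matrix(1, n, n)
  stopifnot(all(dim(gap) == n), all(dim(sign) == n))
  if (max(abs(gap - t(gap))) > 1e-12) stop("gap-junction matrix must be symmetric")
  stopifnot(all(sign[chem > 0] %in% c(-1, 1)))
  if (is.null(labels)) labels <- rownames(chem)
  if (is.null(labels)) labels <- sprintf("N%03d", seq_len(n))
  dimnames(chem) <- dimnames(gap) <- dimnames(sign) <- list(labels, labels)
  structure(list(chem = chem, gap = gap, sign = sign, labels = labels),
            class = "connectome")
}

#' Minimal anatomical path lengths (hop matrix)
#'
#' Iterative composition over the binarized union of chemical and
#' gap-junction edges: a pair is connected at n hops if it is unconnected at
#' fewer hops but connected through an intermediate neuron of the cumulative
#' connectome. The result equals the breadth-first-search hop distance on the
#' binarized directed graph; unreachable pairs are Inf.
#'
#' @param conn A `connectome`.
#' @return Matrix `l` with `l[i, j]` = minimal hops from j to i (0 on the
#'   diagonal, Inf when unreachable).
#' @export
hop_distances <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  n <- nrow(conn$chem)
  B <- (conn$chem > 0) | (conn$gap > 0)
  diag(B) <- FALSE
  l <- matrix(Inf, n, n, dimnames = dimnames(conn$chem))
  diag(l) <- 0
  reach <- B
  l[B] <- 1
  k <- 1L
  Bnum <- B * 1
  cur <- Bnum
  while (k < n) {
    cur <- (cur %*% Bnum) > 0   # pairs connected in exactly <= k+1 compositions
    new <- cur & !is.finite(l)
    if (!any(new)) break
    k <- k + 1L
    l[new] <- k
  }
  l
}

#' Biophysical parameters of the connectome-constrained model
#'
#' Leaky-integrator neurons coupled by ohmic gap junctions and graded
#' chemical synapses with first-order activation kinetics. Units: voltage in
#' mV, conductance in pS, capacitance in pF, current in fA, time in seconds
#' (a consistent set: pS x mV = fA and pF x mV/s = fA).
#'
#' @param capacitance Membrane capacitance (pF).
#' @param g_leak Leak conductance (pS).
#' @param e_leak Leak reversal (mV).
#' @param g_gap Conductance per gap-junction contact (pS).
#' @param g_syn Conductance per chemical synapse (pS).
#' @param e_exc,e_inh Excitatory / inhibitory synaptic reversals (mV).
#' @param a_r,a_d Synaptic activation rise / decay rates (1/s).
#' @param beta Activation sigmoid slope (1/mV).
#' @param v_th Sigmoid midpoint (mV); `NULL` solves it per neuron so the
#'   activation is half-maximal at rest.
#' @return A `biophys_params` object.
#' @export
biophys_params <- function(capacitance = 1, g_leak = 10, e_leak = -35,
                           g_gap = 100, g_syn = 100, e_exc = 0, e_inh = -70,
                           a_r = 1, a_d = 5, beta = 0.125, v_th = NULL) {
  stopifnot(capacitance > 0, g_leak > 0, g_gap > 0, g_syn > 0,
            a_r > 0, a_d > 0, beta > 0)
  structure(list(capacitance = capacitance, g_leak = g_leak, e_leak = e_leak,
                 g_gap = g_gap, g_syn = g_syn, e_exc = e_exc, e_inh = e_inh,
                 a_r = a_r, a_d = a_d, beta = beta, v_th = v_th),
            class = "biophys_params")
}

#' Threshold on predicted responses deemed "large" (mV, i.e. 0.1 V)
#' @export
DV_LARGE_THRESHOLD <- 100

biophys_equilibrium <- function(conn, p) {
  n <- nrow(conn$chem)
  s_star <- 0.5 * p$a_r / (0.5 * p$a_r + p$a_d)
  Gg <- p$g_gap * conn$gap
  Gs <- p$g_syn * conn$chem * s_star
  Erev <- ifelse(conn$sign > 0, p$e_exc, p$e_inh)
  A <- diag(p$g_leak + rowSums(Gg) + rowSums(Gs), n) - Gg
  b <- p$g_leak * p$e_leak + rowSums(Gs * Erev)
  V <- solve(A, b)
  list(V = as.numeric(V), s = rep(s_star, n))
}

#' Simulate the connectome-constrained biophysical model
#'
#' Integrates C dV_i/dt = -G_leak (V_i - E_leak) - sum_j g_gap Gap_ij (V_i -
#' V_j) - sum_j g_syn Chem_ij s_j (V_i - E_rev(sign_ij)) + I_i with
#' ds_j/dt = a_r phi(V_j)(1 - s_j) - a_d s_j and a logistic phi. The network
#' starts at its computed resting equilibrium (solved algebraically); a step
#' current is injected into the stimulated neuron for the stimulus duration.
#'
#' @param conn A `connectome`.
#' @param p A `biophys_params`.
#' @param stim Stimulated neuron index or label (or `NULL` for no input).
#' @param current Injected current amplitude in fA.
#' @param duration Stimulus duration in seconds.
#' @param t_max Simulated time span in seconds.
#' @param dt Output sampling interval in seconds.
#' @param atol,rtol Integrator tolerances.
#' @return List with `t`, `dV` (time x neuron matrix of V - V_rest in mV),
#'   `V_rest`.
#' @export
biophys_simulate <- function(conn, p = biophys_params(), stim = NULL,
                             current = 1e4, duration = 0.5, t_max = 30,
                             dt = 0.1, atol = 1e-10, rtol = 1e-10) {
  stopifnot(inherits(conn, "connectome"), inherits(p, "biophys_params"))
  n <- nrow(conn$chem)
  if (is.character(stim)) stim <- match(stim, conn$labels)
  eq <- biophys_equilibrium(conn, p)
  v_th <- if (is.null(p$v_th)) eq$V else rep(p$v_th, length.out = n)
  Erev <- ifelse(conn$sign > 0, p$e_exc, p$e_inh)
  Gg <- p$g_gap * conn$gap
  gap_rowsum <- rowSums(Gg)
  Gs <- p$g_syn * conn$chem
  GsE <- Gs * Erev
  Ivec <- numeric(n)
  if (!is.null(stim)) Ivec[stim] <- current
  rhs <- function(t, y, parms) {
    V <- y[seq_len(n)]; s <- y[n + seq_len(n)]
    phi <- stats::plogis(p$beta * (V - v_th))
    I_ext <- if (t <= duration) Ivec else numeric(n)
    dV <- (-p$g_leak * (V - p$e_leak) -
             (gap_rowsum * V - as.numeric(Gg %*% V)) -
             (as.numeric(Gs %*% s) * V - as.numeric(GsE %*% s)) +
             I_ext) / p$capacitance
    ds <- p$a_r * phi * (1 - s) - p$a_d * s
    list(c(dV, ds))
  }
  times <- seq(0, t_max, by = dt)
  sol <- deSolve::ode(y = c(eq$V, eq$s), times = times, func = rhs,
                      parms = NULL, method = "lsoda", atol = atol,
                      rtol = rtol)
  if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol)))
    stop(sprintf("integration failed (max |V| = %.3g mV)",
                 max(abs(sol[, 1 + seq_len(n)]), na.rm = TRUE)))
  Vt <- sol[, 1 + seq_len(n), drop = FALSE]
  dV <- sweep(Vt, 2, eq$V)
  colnames(dV) <- conn$labels
  list(t = times, dV = dV, V_rest = eq$V)
}

#' Peak-response matrix of the biophysical model
#'
#' Entry (i, j) is the peak of neuron i's voltage excursion (signed by the
#' direction of the excursion) under in-silico stimulation of neuron j.
#' Responses above `DV_LARGE_THRESHOLD` (100 mV = 0.1 V) are the model's
#' "large predicted response" class.
#'
#' @inheritParams biophys_simulate
#' @return n x n matrix of signed peak dV values (mV); diagonal = the
#'   stimulated neurons' own responses.
#' @export
dv_response_matrix <- function(conn, p = biophys_params(), current = 1e4,
                               duration = 0.5, t_max = 30, dt = 0.1) {
  n <- nrow(conn$chem)
  out <- matrix(0, n, n, dimnames = dimnames(conn$chem))
  for (j in seq_len(n)) {
    sim <- biophys_simulate(conn, p, stim = j, current = current,
                            duration = duration, t_max = t_max, dt = dt)
    for (i in seq_len(n)) {
      v <- sim$dV[, i]
      out[i, j] <- v[which.max(abs(v))]
    }
  }
  out
}

default_subtype <- function(labels) sub("[LR]$", "", labels)

#' Assign synaptic polarities from a sign table
#'
#' Edges present in the table receive its sign; entries are aggregated across
#' members of a cellular subtype (by default, labels stripped of a trailing
#' L/R) by majority vote, with ties and absent or ambiguous entries set
#' excitatory (+1).
#'
#' @param conn A `connectome`.
#' @param sign_table Data.frame with columns `pre`, `post`, `sign` (may be
#'   empty or partial; may reference subtype names).
#' @param subtype_of Function mapping a label to its subtype name.
#' @return The connectome with an updated `sign` matrix.
#' @export
assign_polarities <- function(conn, sign_table = NULL,
                              subtype_of = default_subtype) {
  stopifnot(inherits(conn, "connectome"))
  n <- nrow(conn$chem)
  sgn <- matrix(1, n, n, dimnames = dimnames(conn$chem))
  if (!is.null(sign_table) && nrow(sign_table) > 0) {
    st <- sign_table
    st$pre <- subtype_of(as.character(st$pre))
    st$post <- subtype_of(as.character(st$post))
    agg <- stats::aggregate(sign ~ pre + post, data = st, FUN = sum)
    sub_pre <- subtype_of(conn$labels)
    for (r in seq_len(nrow(agg))) {
      s <- if (agg$sign[r] < 0) -1 else 1   # majority; ties (sum 0) -> +1
      ii <- which(sub_pre == agg$post[r])
      jj <- which(sub_pre == agg$pre[r])
      sgn[ii, jj] <- s
    }
  }
  conn$sign <- sgn
  conn
}

#' Through-origin agreement between measured and predicted responses
#'
#' Fits the through-origin line measured = m * predicted by least squares and
#' reports R^2 = 1 - SS_res / SS_tot with SS_tot about the measured mean.
#' R^2 of 1 is perfect agreement; R^2 can be negative when the line fits
#' worse than the measured mean.
#'
#' @param measured,predicted Paired finite numeric vectors.
#' @return An `agreement_report`: `slope`, `r2`, `n`.
#' @export
r2_agreement <- function(measured, predicted) {
  stopifnot(length(measured) == length(predicted),
            all(is.finite(measured)), all(is.finite(predicted)))
  if (all(predicted == 0)) stop("all predicted responses are zero")
  m <- sum(measured * predicted) / sum(predicted^2)
  ss_res <- sum((measured - m * predicted)^2)
  ss_tot <- sum((measured - mean(measured))^2)
  structure(list(slope = m, r2 = 1 - ss_res / ss_tot, n = length(measured)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement: slope m = %.4g, R^2 = %.4g, n = %d>\n",
              x$slope, x$r2, x$n))
  invisible(x)
}

#' Fit connectome weights and signs to functional measurements
#'
#' Optimizes the signed weight of every existing chemical edge so the
#' biophysical model's peak-response matrix best matches the measured
#' pair-amplitude table (least squares after the through-origin scaling fit).
#' Edges absent from the wiring diagram stay exactly zero (mask constraint);
#' weight magnitudes are bounded; the optimizer is restarted from seeded
#' perturbations of the anatomical weights.
#'
#' @param conn A `connectome`; its `chem > 0` mask defines the free edges.
#' @param measured Matrix of measured pair amplitudes (post x pre), same
#'   shape as `conn$chem`; non-measured entries NA.
#' @param p A `biophys_params`.
#' @param max_weight Bound on absolute edge weights.
#' @param n_starts Number of multistarts.
#' @param maxit Optimizer iterations per start.
#' @param seed Integer seed for the start perturbations.
#' @param ... Passed to [dv_response_matrix] (current, duration, t_max, dt).
#' @return List with `connectome` (fitted weights and signs) and `report`
#'   (an `agreement_report`; `converged` attribute flags optimizer status).
#' @export
fit_weights <- function(conn, measured, p = biophys_params(),
                        max_weight = 50, n_starts = 2, maxit = 150,
                        seed = 1, ...) {
  stopifnot(inherits(conn, "connectome"),
            all(dim(measured) == dim(conn$chem)))
  mask <- which(conn$chem > 0)
  if (length(mask) == 0L) stop("connectome has no chemical edges to fit")
  meas_idx <- which(is.finite(measured) & row(measured) != col(measured))
  y <- measured[meas_idx]
  set.seed(seed)
  predict_from <- function(w) {
    cc <- conn
    cc$chem[] <- 0
    cc$chem[mask] <- abs(w)
    cc$sign[mask] <- ifelse(w >= 0, 1, -1)
    dv_response_matrix(cc, p, ...)[meas_idx]
  }
  objective <- function(w) {
    pred <- tryCatch(predict_from(w), error = function(e) NULL)
    if (is.null(pred) || all(pred == 0)) return(1e12)
    m <- sum(y * pred) / sum(pred^2)
    sum((y - m * pred)^2)
  }
  w_anat <- conn$chem[mask] * ifelse(conn$sign[mask] >= 0, 1, -1)
  best <- NULL
  for (st in seq_len(n_starts)) {
    w0 <- if (st == 1) w_anat else
      w_anat * exp(stats::rnorm(length(mask), sd = 0.3))
    fit <- tryCatch(
      stats::optim(w0, objective, method = "L-BFGS-B",
                   lower = -max_weight, upper = max_weight,
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("weight fitting failed on all starts")
  w <- best$par
  cc <- conn
  cc$chem[] <- 0
  cc$chem[mask] <- abs(w)
  cc$sign[mask] <- ifelse(w >= 0, 1, -1)
  pred_full <- dv_response_matrix(cc, p, ...)
  rep <- r2_agreement(y, pred_full[meas_idx])
  attr(rep, "converged") <- best$convergence == 0
  list(connectome = cc, report = rep, dv = pred_full)
}
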