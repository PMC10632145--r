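#' Write a recording to a plain-text container
#'
#' The container is a directory holding traces.csv (time x neuron), mask.csv,
#' time.csv, stim.csv (columns time_s, target_index, duration_s, on_target)
#' and meta.yaml (dt, strain, labels).
#'
#' @param rec A `recording`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- as.data.frame(rec$traces); names(tr) <- rec$labels
  utils::write.csv(tr, file.path(dir, "traces.csv"), row.names = FALSE)
  mk <- as.data.frame(rec$mask * 1L); names(mk) <- rec$labels
  utils::write.csv(mk, file.path(dir, "mask.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time = rec$time), file.path(dir, "time.csv"),
                   row.names = FALSE)
  utils::write.csv(rec$stim, file.path(dir, "stim.csv"), row.names = FALSE)
  yaml::write_yaml(list(dt = rec$dt, strain = rec$strain,
                        labels = as.list(rec$labels)),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a recording from its plain-text container
#' @param dir Directory written by [write_recording].
#' @return A `recording`.
#' @export
read_recording <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  traces <- as.matrix(utils::read.csv(file.path(dir, "traces.csv"),
                                      check.names = FALSE))
  mask <- as.matrix(utils::read.csv(file.path(dir, "mask.csv"),
                                    check.names = FALSE)) > 0
  tm <- utils::read.csv(file.path(dir, "time.csv"))$time
  stim <- utils::read.csv(file.path(dir, "stim.csv"))
  structure(list(traces = unname(traces), mask = unname(mask), time = tm,
                 dt = meta$dt, strain = meta$strain,
                 labels = unlist(meta$labels), stim = stim),
            class = "recording")
}

#' Write a connectome to a CSV edge list
#'
#' Columns: pre, post, type (chem/gap), count, sign. Gap junctions are
#' written once per unordered pair.
#'
#' @param conn A `connectome`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(conn, path) {
  stopifnot(inherits(conn, "connectome"))
  rows <- list()
  idx <- which(conn$chem > 0, arr.ind = TRUE)
  if (nrow(idx)) {
    rows[[1]] <- data.frame(pre = conn$labels[idx[, 2]],
                            post = conn$labels[idx[, 1]], type = "chem",
                            count = conn$chem[idx],
                            sign = conn$sign[idx])
  }
  gidx <- which(conn$gap > 0 & upper.tri(conn$gap), arr.ind = TRUE)
  if (nrow(gidx)) {
    rows[[length(rows) + 1L]] <- data.frame(
      pre = conn$labels[gidx[, 2]], post = conn$labels[gidx[, 1]],
      type = "gap", count = conn$gap[gidx], sign = 1)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pre = character(0), post = character(0), type = character(0),
               count = numeric(0), sign = numeric(0))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a connectome from a CSV edge list
#' @param path CSV written by [write_connectome] (or any file with columns
#'   pre, post, type, count, sign).
#' @param labels Optional neuron label universe; defaults to the labels seen.
#' @return A `connectome`.
#' @export
read_connectome <- function(path, labels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(labels)) labels <- sort(unique(c(df$pre, df$post)))
  n <- length(labels)
  chem <- gap <- matrix(0, n, n, dimnames = list(labels, labels))
  sgn <- matrix(1, n, n, dimnames = list(labels, labels))
  for (r in seq_len(nrow(df))) {
    i <- match(df$post[r], labels); j <- match(df$pre[r], labels)
    if (df$type[r] == "chem") {
      chem[i, j] <- chem[i, j] + df$count[r]
      sgn[i, j] <- df$sign[r]
    } else {
      gap[i, j] <- gap[i, j] + df$count[r]
      gap[j, i] <- gap[i, j]
    }
  }
  connectome(chem, gap, sgn, labels)
}

#' Average connectomes after per-dataset total-count normalization
#'
#' Combines several count matrices into one set of weights: each dataset is
#' scaled to a common total synapse count (the mean of the totals) and the
#' scaled matrices are averaged arithmetically.
#'
#' @param conns List of `connectome`s over the same label set.
#' @return A `connectome` with averaged chem and gap weights; signs are taken
#'   from the first connectome.
#' @export
average_connectomes <- function(conns) {
  stopifnot(length(conns) >= 1L)
  totals <- vapply(conns, function(cc) sum(cc$chem) + sum(cc$gap), numeric(1))
  target <- mean(totals[totals > 0])
  scl <- ifelse(totals > 0, target / totals, 1)
  chem <- Reduce(`+`, Map(function(cc, s) cc$chem * s, conns, scl)) /
    length(conns)
  gap <- Reduce(`+`, Map(function(cc, s) cc$gap * s, conns, scl)) /
    length(conns)
  connectome(chem, gap, conns[[1]]$sign, conns[[1]]$labels)
}

#' Run configuration for the full pipeline
#'
#' Plain key-value configuration with explicit seeds for every stochastic
#' stage; round-trips losslessly through YAML.
#'
#' @param n_neurons,edge_density,frac_inhibitory,frac_extrasynaptic Network
#'   generation settings.
#' @param gain_band Uniform band of absolute edge DC gains; the default
#'   `c(0.3, 0.7)` makes downstream responses comparable in amplitude to
#'   autoresponses, as observed for connected pairs.
#' @param duration,n_recordings,n_controls Recording settings (seconds /
#'   counts).
#' @param q_threshold Atlas significance threshold (default 0.05).
#' @param eps_factor Equivalence margin multiplier (default 1.2).
#' @param kernel_fit `"trial"` fits one kernel per stimulus-response event
#'   and averages; `"pair"` fits a single kernel on the trial-averaged
#'   windows of each pair (faster; used for simulation-oriented runs).
#' @param propagation `"direct"` or `"network"` response generation in the
#'   simulated recordings (see [simulate_recording]); the ground-truth
#'   correlation reference uses the same propagation depth.
#' @param observed `"drive"` scores predictions against ground-truth
#'   single-drive correlations; `"spontaneous"` scores them against the
#'   correlation matrix of simulated driver-dominated spontaneous activity
#'   (see [simulate_spontaneous]).
#' @param n_drivers Number of intrinsically active neurons in the
#'   spontaneous reference.
#' @param top_n Number of in-silico drivers selected greedily for the
#'   kernel and anatomy predictions; `NULL` drives all neurons.
#' @param seed Master seed; stage seeds are derived deterministically.
#' @param out_dir Output directory.
#' @param strain Strain label for the simulated recordings.
#' @return A `run_config` object (a named list).
#' @export
run_config <- function(n_neurons = 10, edge_density = 0.12,
                       frac_inhibitory = 0.11, frac_extrasynaptic = 0,
                       gain_band = c(0.3, 0.7),
                       duration = 1200, n_recordings = 2, n_controls = 2,
                       q_threshold = 0.05, eps_factor = 1.2,
                       kernel_fit = c("trial", "pair"),
                       propagation = c("direct", "network"),
                       observed = c("drive", "spontaneous"),
                       n_drivers = 3, top_n = NULL, seed = 1,
                       out_dir = tempfile("sigprop_run_"), strain = "WT") {
  structure(list(n_neurons = n_neurons, edge_density = edge_density,
                 frac_inhibitory = frac_inhibitory,
                 frac_extrasynaptic = frac_extrasynaptic,
                 gain_band = gain_band,
                 duration = duration, n_recordings = n_recordings,
                 n_controls = n_controls, q_threshold = q_threshold,
                 eps_factor = eps_factor,
                 kernel_fit = match.arg(kernel_fit),
                 propagation = match.arg(propagation),
                 observed = match.arg(observed), n_drivers = n_drivers,
                 top_n = top_n, seed = as.integer(seed),
                 out_dir = out_dir, strain = strain),
            class = "run_config")
}

#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

#' Run the full synthetic-data pipeline
#'
#' Generates a ground-truth network and matched connectome, simulates
#' stimulation-response and control recordings, preprocesses them, applies
#' the inclusion criteria, computes the pair-statistics atlas, fits
#' trial-averaged kernels for responding pairs, predicts activity
#' correlations from the kernel atlas, and compares against the biophysical
#' anatomy model and the bare synapse-count baseline. Writes the atlas and
#' kernel tables, correlation matrices and a run manifest to `cfg$out_dir`.
#'
#' @param cfg A `run_config`.
#' @param write_outputs Write CSV artifacts (default TRUE).
#' @return List with `net`, `connectome`, `stats` (atlas table), `atlas`
#'   (kernel atlas), `correlations` (list: observed, kernel, anatomy,
#'   counts), `agreement` (named numeric), and `manifest`.
#' @export
run_pipeline <- function(cfg = run_config(), write_outputs = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  seed <- cfg$seed
  net <- gen_ground_truth(cfg$n_neurons, cfg$edge_density,
                          cfg$frac_inhibitory, cfg$frac_extrasynaptic,
                          seed = seed, gain_band = cfg$gain_band)
  conn <- gen_connectome(net, extra_anatomy_edges = 2, seed = seed + 1)

  mk_cfg <- function(s, strain) sim_config(duration = cfg$duration,
                                           strain = strain, seed = s)
  recs <- lapply(seq_len(cfg$n_recordings), function(i)
    simulate_recording(net, mk_cfg(seed + 10 + i, cfg$strain),
                       propagation = cfg$propagation))
  controls <- lapply(seq_len(cfg$n_controls), function(i)
    simulate_control(net, mk_cfg(seed + 100 + i, "control")))

  null <- suppressWarnings(build_null(controls))
  th <- classifier_thresholds()
  screens <- lapply(recs, function(r)
    suppressMessages(apply_inclusion(r, th)))
  stats_tab <- pair_stats_table(screens, null, cfg$eps_factor,
                                cfg$q_threshold)

  # kernels for pairs with retained observations: either one fit per
  # stimulus-response event (averaged afterwards) or one fit on the
  # trial-averaged windows; pairs above the q threshold carry the zero
  # kernel in the atlas, so no fit is run for them
  kernels <- list()
  zero_avg <- average_kernels(list(zero_kernel()))
  for (r in seq_len(nrow(stats_tab))) {
    if (stats_tab$q[r] > cfg$q_threshold) { kernels[[r]] <- zero_avg; next }
    stim_lab <- stats_tab$stim[r]; down_lab <- stats_tab$down[r]
    ups <- list(); downs <- list(); oks <- logical(0); dt_w <- 0.5
    for (sc in screens) {
      tb <- sc$table
      keep <- tb$included & tb$stim_neuron == stim_lab &
        tb$down_neuron == down_lab
      for (ev in tb$event[keep]) {
        wnd <- sc$windows[[sprintf("ev%d_%s_%s", ev, stim_lab, down_lab)]]
        if (is.null(wnd) || is.null(wnd$up_raw)) next
        ups[[length(ups) + 1L]] <- window_post(wnd$up_raw)
        downs[[length(downs) + 1L]] <- window_post(wnd$down_raw)
        oks <- c(oks, detect_autoresponse(wnd$down, th))
        dt_w <- wnd$down$dt
      }
    }
    kernels[[r]] <- if (length(ups) == 0L) {
      average_kernels(list(zero_kernel()))
    } else if (cfg$kernel_fit == "pair") {
      L <- min(lengths(ups))
      up_m <- rowMeans(vapply(ups, `[`, numeric(L), seq_len(L)))
      dn_m <- rowMeans(vapply(downs, `[`, numeric(L), seq_len(L)))
      average_kernels(list(
        fit_kernel(up_m, dn_m, dt = dt_w, n_starts = 2,
                   downstream_responded = any(oks))))
    } else {
      average_kernels(lapply(seq_along(ups), function(i)
        fit_kernel(ups[[i]], downs[[i]], dt = dt_w, n_starts = 2,
                   downstream_responded = oks[i])))
    }
  }
  atlas <- kernel_atlas(net$labels,
                        data.frame(stim = stats_tab$stim,
                                   down = stats_tab$down, q = stats_tab$q),
                        kernels, cfg$q_threshold)

  drive <- autoresponse_template(dt = 0.5)
  obs_corr <- if (cfg$observed == "spontaneous") {
    sp <- simulate_spontaneous(net, duration = cfg$duration, seed = seed + 200,
                               n_drivers = cfg$n_drivers)
    C <- stats::cor(sp); diag(C) <- 1
    C
  } else {
    true_correlations(net, drive, 0.5,
                      max_hops = if (cfg$propagation == "network") Inf else 1)
  }
  if (is.null(cfg$top_n)) {
    kern_corr <- predict_correlations(atlas, seq_len(cfg$n_neurons), drive, 0.5)
    anat_corr <- anatomy_correlations(conn,
                                      drive_set = seq_len(cfg$n_neurons))
  } else {
    sel <- select_top_n(atlas, obs_corr, cfg$top_n, drive, 0.5)
    kern_corr <- predict_correlations(atlas, sel, drive, 0.5)
    anat_corr <- anatomy_top_n(conn, obs_corr, cfg$top_n)$corr
  }
  count_corr <- count_correlation_baseline(conn)

  agreement <- c(
    kernel = tryCatch(corr_agreement(kern_corr, obs_corr),
                      error = function(e) NA_real_),
    anatomy = tryCatch(corr_agreement(anat_corr, obs_corr),
                       error = function(e) NA_real_),
    counts = tryCatch(corr_agreement(count_corr, obs_corr),
                      error = function(e) NA_real_))

  manifest <- list(config = unclass(cfg), seed = seed,
                   n_pairs = nrow(stats_tab),
                   n_connected = sum(stats_tab$label == "connected"),
                   package_version = as.character(utils::packageVersion("sigprop")))
  out <- list(net = net, connectome = conn, stats = stats_tab, atlas = atlas,
              correlations = list(observed = obs_corr, kernel = kern_corr,
                                  anatomy = anat_corr, counts = count_corr),
              agreement = agreement, manifest = manifest)
  if (write_outputs) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    export_atlas(stats_tab, atlas, cfg$out_dir)
    write_connectome(conn, file.path(cfg$out_dir, "connectome.csv"))
    for (nm in names(out$correlations)) {
      utils::write.csv(out$correlations[[nm]],
                       file.path(cfg$out_dir, sprintf("corr_%s.csv", nm)),
                       row.names = FALSE)
    }
    yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  }
  out
}

#' Correlation prediction from the biophysical anatomy model
#'
#' Drives each neuron of `drive_set` in silico through the biophysical model
#' and averages the per-drive Pearson correlation matrices of the resulting
#' voltage excursions, analogously to the kernel-based prediction.
#'
#' @param conn A `connectome`.
#' @param p A `biophys_params`.
#' @param drive_set Neuron indices to drive (default all).
#' @param ... Passed to [biophys_simulate].
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
anatomy_correlations <- function(conn, p = biophys_params(),
                                 drive_set = seq_len(nrow(conn$chem)), ...) {
  per <- anatomy_drive_correlations(conn, p, drive_set, ...)
  out <- Reduce(`+`, per) / length(per)
  dimnames(out) <- list(conn$labels, conn$labels)
  out
}

anatomy_drive_correlations <- function(conn, p = biophys_params(),
                                       drive_set = seq_len(nrow(conn$chem)),
                                       ...) {
  lapply(drive_set, function(j) {
    sim <- biophys_simulate(conn, p, stim = j, ...)
    C <- suppressWarnings(stats::cor(sim$dV))
    C[!is.finite(C)] <- 0
    diag(C) <- 1
    C
  })
}

#' Top-n driver selection for the biophysical anatomy model
#'
#' Greedy forward selection of the `n` in-silico driven neurons whose
#' averaged per-drive correlation matrices best agree with a target, the
#' anatomy-model counterpart of [select_top_n].
#'
#' @param conn A `connectome`.
#' @param target Target correlation matrix.
#' @param n Number of drivers.
#' @param p A `biophys_params`.
#' @param ... Passed to [biophys_simulate].
#' @return List with `drivers` (indices) and `corr` (predicted matrix).
#' @export
anatomy_top_n <- function(conn, target, n, p = biophys_params(), ...) {
  per <- anatomy_drive_correlations(conn, p, seq_len(nrow(conn$chem)), ...)
  res <- greedy_top_n_matrices(per, target, n)
  dimnames(res$corr) <- list(conn$labels, conn$labels)
  res
}

#' Export the atlas tables
#'
#' Writes the pair-statistics atlas CSV (stim, down, n_obs, amp_mean, p_amp,
#' p_deriv, p, q, p_eq, q_eq, label) and an edge-list view (stim, down,
#' amp_mean, q, label) suitable for graph tools.
#'
#' @param stats Pair-statistics data.frame.
#' @param atlas A `kernel_atlas` (optional; reserved for kernel serialization).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
export_atlas <- function(stats, atlas = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(stats, file.path(dir, "atlas.csv"), row.names = FALSE)
  utils::write.csv(stats[, c("stim", "down", "amp_mean", "q", "label")],
                   file.path(dir, "atlas_edges.csv"), row.names = FALSE)
  invisible(dir)
}
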