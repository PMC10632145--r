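#' Kernel atlas for network simulation
#'
#' Holds the trial-averaged kernel for every ordered neuron pair together
#' with its q-value; pairs with q above the threshold are considered not
#' connected and carry the zero kernel.
#'
#' @param labels Neuron labels.
#' @param pairs Data.frame with columns `stim`, `down`, `q`.
#' @param kernels List of `prop_kernel`s (or `numeric_kernel`s from
#'   [average_kernels]) parallel to the rows of `pairs`.
#' @param q_threshold Pairs with q above this carry the zero kernel.
#' @return A `kernel_atlas` object.
#' @export
kernel_atlas <- function(labels, pairs, kernels, q_threshold = 0.05) {
  stopifnot(nrow(pairs) == length(kernels))
  km <- vector("list", length(labels)^2)
  dim(km) <- c(length(labels), length(labels))
  dimnames(km) <- list(down = labels, stim = labels)
  for (r in seq_len(nrow(pairs))) {
    i <- match(pairs$down[r], labels); j <- match(pairs$stim[r], labels)
    if (is.na(i) || is.na(j)) stop("atlas pair label not in label set")
    km[[i, j]] <- if (!is.na(pairs$q[r]) && pairs$q[r] > q_threshold)
      zero_kernel() else kernels[[r]]
  }
  structure(list(labels = labels, kernels = km, q_threshold = q_threshold),
            class = "kernel_atlas")
}

atlas_response <- function(atlas, j, drive, dt) {
  n <- length(atlas$labels)
  A <- matrix(0, length(drive), n)
  A[, j] <- drive
  for (i in seq_len(n)) {
    if (i == j) next
    k <- atlas$kernels[[i, j]]
    if (is.null(k)) next
    A[, i] <- if (inherits(k, "numeric_kernel"))
      apply_kernel_numeric(k, drive, dt) else apply_kernel(k, drive, dt)
  }
  A
}

#' Predict spontaneous-activity correlations from a kernel atlas
#'
#' For each driven neuron j, the responses of all neurons are computed by
#' convolving the trial-averaged kernels with the drive waveform (the driven
#' neuron's own activity is the waveform itself); the Pearson correlation
#' matrix of the resulting activities is computed per drive, and the final
#' prediction is the mean over drives. Neurons with constant activity under
#' a drive contribute correlation 0 for that drive.
#'
#' @param atlas A `kernel_atlas`.
#' @param drive_set Neuron indices or labels to drive.
#' @param drive_waveform Activity transient imposed on the driven neuron.
#' @param dt Sampling interval in seconds.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
predict_correlations <- function(atlas, drive_set, drive_waveform, dt) {
  stopifnot(inherits(atlas, "kernel_atlas"))
  if (length(drive_set) == 0L) stop("empty drive set")
  if (is.character(drive_set)) drive_set <- match(drive_set, atlas$labels)
  stopifnot(!anyNA(drive_set))
  n <- length(atlas$labels)
  acc <- matrix(0, n, n)
  for (j in drive_set) {
    A <- atlas_response(atlas, j, drive_waveform, dt)
    C <- suppressWarnings(stats::cor(A))
    C[!is.finite(C)] <- 0
    diag(C) <- 1
    acc <- acc + C
  }
  out <- acc / length(drive_set)
  dimnames(out) <- list(atlas$labels, atlas$labels)
  out
}

#' Agreement between two correlation matrices
#'
#' Pearson correlation between the off-diagonal upper-triangle entries of
#' the predicted and observed matrices.
#'
#' @param pred,obs Correlation matrices over the same neuron set.
#' @return Scalar agreement in [-1, 1].
#' @export
corr_agreement <- function(pred, obs) {
  stopifnot(all(dim(pred) == dim(obs)))
  ut <- upper.tri(pred)
  x <- pred[ut]; y <- obs[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("corr_agreement undefined for a constant matrix")
  stats::cor(x, y)
}

#' Greedy top-n driver selection
#'
#' Selects the `n` driving neurons whose predicted correlation matrix best
#' agrees with a target: greedy forward selection, at each step adding the
#' neuron that maximizes [corr_agreement], with deterministic ties broken by
#' neuron label order.
#'
#' @param atlas A `kernel_atlas`.
#' @param target_corr Target correlation matrix.
#' @param n Number of drivers to select.
#' @param drive_waveform Drive transient.
#' @param dt Sampling interval in seconds.
#' @return Character vector of selected neuron labels, in selection order.
#' @export
select_top_n <- function(atlas, target_corr, n, drive_waveform, dt) {
  stopifnot(n >= 1)
  labels <- atlas$labels
  if (n > length(labels)) stop("n exceeds the number of neurons in the atlas")
  cand_order <- order(labels)
  selected <- integer(0)
  for (step in seq_len(n)) {
    best <- NULL; best_score <- -Inf
    for (cidx in cand_order) {
      if (cidx %in% selected) next
      score <- tryCatch(
        corr_agreement(predict_correlations(atlas, c(selected, cidx),
                                            drive_waveform, dt), target_corr),
        error = function(e) -Inf)
      if (score > best_score) { best_score <- score; best <- cidx }
    }
    selected <- c(selected, best)
  }
  labels[selected]
}

# Greedy forward selection over cached per-drive correlation matrices;
# shared by the anatomy-model top-n route.
greedy_top_n_matrices <- function(per_drive, target, n) {
  sel <- integer(0)
  for (s in seq_len(n)) {
    best <- NULL; best_score <- -Inf
    for (cand in setdiff(seq_along(per_drive), sel)) {
      M <- Reduce(`+`, per_drive[c(sel, cand)]) / (length(sel) + 1)
      score <- tryCatch(corr_agreement(M, target), error = function(e) -Inf)
      if (score > best_score) { best_score <- score; best <- cand }
    }
    sel <- c(sel, best)
  }
  list(drivers = sel,
       corr = Reduce(`+`, per_drive[sel]) / length(sel))
}

#' Correlation matrix predicted directly from synapse counts
#'
#' The bare-anatomy baseline: the symmetrized, max-normalized chemical
#' synapse count matrix with a unit diagonal, read as a correlation
#' prediction. No dynamics are involved; this is the weakest of the three
#' prediction routes and serves as the comparison floor for the kernel-based
#' and biophysical predictions.
#'
#' @param conn A `connectome`.
#' @return Symmetric matrix in [0, 1] with unit diagonal.
#' @export
count_correlation_baseline <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  W <- conn$chem + t(conn$chem) + conn$gap
  if (max(W) > 0) W <- W / max(W)
  diag(W) <- 1
  W
}
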