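#' Autoresponse classifier thresholds
#'
#' The classifier that decides whether a stimulation evoked a detectable
#' calcium response inspects the dF/F0 transient and its temporal second
#' derivative: both must exceed their thresholds jointly for a contiguous
#' `min_contig` seconds. The same thresholds are applied to every animal,
#' strain, neuron and stimulation event within a run.
#'
#' @param amp dF/F0 amplitude threshold (default 0.1).
#' @param deriv Second-derivative threshold in 1/s^2 (default 0.002,
#'   matching three times the null SD of the causal second-derivative
#'   statistic under the generator's default noise; see
#'   [calibrate_thresholds]).
#' @param min_contig Required contiguous duration in seconds (default 4).
#' @return A `classifier_thresholds` object.
#' @export
classifier_thresholds <- function(amp = 0.1, deriv = 0.002, min_contig = 4) {
  stopifnot(amp > 0, deriv > 0, min_contig > 0)
  structure(list(amp = amp, deriv = deriv, min_contig = min_contig),
            class = "classifier_thresholds")
}

#' Calibrate the derivative threshold on control recordings
#'
#' Sets the second-derivative threshold to `n_sd` times the SD of the causal
#' second-derivative statistic over pseudo-stimulation windows of control
#' (no-stimulation) recordings, so that a response must rise well above what
#' sensor noise alone produces.
#'
#' @param controls List of control `recording`s (empty stimulation logs).
#' @param amp Amplitude threshold to carry through.
#' @param n_sd Multiplier on the null SD (default 3).
#' @param min_contig Contiguity requirement in seconds.
#' @param isi Pseudo-stimulation spacing in seconds.
#' @return A `classifier_thresholds` object.
#' @export
calibrate_thresholds <- function(controls, amp = 0.1, n_sd = 3,
                                 min_contig = 4, isi = 30) {
  d2 <- c()
  for (rec in controls) {
    stopifnot(inherits(rec, "recording"))
    if (nrow(rec$stim) > 0) stop("calibration requires control recordings")
    prep <- preprocess_recording(rec)
    times <- seq(isi, max(rec$time) - isi, by = isi)
    for (tt in times) {
      for (j in seq_along(rec$labels)) {
        w <- response_window(prep$smoothed, tt, j)
        dd <- second_derivative(w)
        d2 <- c(d2, dd[w$t >= 0])
      }
    }
  }
  classifier_thresholds(amp = amp, deriv = n_sd * stats::sd(d2),
                        min_contig = min_contig)
}

longest_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Detect an autoresponse in a response window
#'
#' TRUE iff there is a contiguous interval of at least `min_contig` seconds
#' in the post-stimulus window where dF/F0 exceeds the amplitude threshold
#' and |second derivative| exceeds the derivative threshold jointly (the
#' stricter, jointly-contiguous reading of the two-threshold rule).
#'
#' @param w A `response_window` covering the post-stimulus period.
#' @param th A `classifier_thresholds`.
#' @return Logical.
#' @export
detect_autoresponse <- function(w, th = classifier_thresholds()) {
  stopifnot(inherits(w, "response_window"),
            inherits(th, "classifier_thresholds"))
  post <- w$t >= 0
  need <- ceiling(th$min_contig / w$dt)
  if (sum(post) < need) {
    warning("post-stimulus window shorter than the contiguity requirement")
    return(FALSE)
  }
  v <- w$values[post]
  d2 <- second_derivative(w)[post]
  ok <- (v > th$amp) & (abs(d2) > th$deriv)
  longest_run(ok) >= need
}

#' Mean post-stimulus response amplitude of a window
#'
#' The per-observation response summary <dF/F0>_t: the mean of dF/F0 over
#' the 30-s post-stimulus window. Pair-level amplitudes are means of this
#' across observations.
#'
#' @param w A `response_window`.
#' @return Scalar mean post-stimulus dF/F0.
#' @export
response_amplitude <- function(w) mean(window_post(w))

max_contig_missing <- function(miss) {
  if (length(miss) == 0L) return(0L)
  longest_run(miss)
}

#' Apply the inclusion criteria to a recording
#'
#' Builds the table of stimulus-response observations entering the analysis.
#' Excluded are (a) stimulation events whose stimulated neuron shows no
#' autoresponse, (b) downstream traces with a contiguous missing segment
#' longer than `gap_frac` of the response window, and (c) traces without an
#' identity label. Counts per exclusion reason are reported in a message.
#' With `rid_override = TRUE` observations are admitted even when the
#' upstream trace is unusable, and downstream windows with dF/F0 > 2 are
#' excluded instead (the policy used for stimulation targets too dim to
#' yield their own calcium trace).
#'
#' @param rec A `recording`.
#' @param th A `classifier_thresholds`.
#' @param prep Optional precomputed [preprocess_recording] output.
#' @param gap_frac Maximum tolerated contiguous missing fraction (default
#'   0.05).
#' @param rid_override Logical; admit windows without an upstream trace and
#'   apply the dF/F0 > 2 exclusion (default FALSE).
#' @return A `screen_result`: `table` (one row per retained or excluded
#'   observation) and `windows` (named list with smoothed and raw up/down
#'   windows for retained observations).
#' @export
apply_inclusion <- function(rec, th = classifier_thresholds(), prep = NULL,
                            gap_frac = 0.05, rid_override = FALSE) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(prep)) prep <- preprocess_recording(rec)
  sm <- prep$smoothed; raw <- prep$raw; mask0 <- prep$mask_orig
  n <- ncol(sm$F)
  labelled <- !is.na(sm$labels) & nzchar(sm$labels)
  rows <- list(); windows <- list()
  counts <- c(no_autoresponse = 0L, missing_gap = 0L, unlabeled = 0L,
              amp_cap = 0L, retained = 0L)
  for (ev in seq_len(nrow(rec$stim))) {
    tt <- rec$stim$time_s[ev]
    j <- rec$stim$target_index[ev]
    up_w <- tryCatch(response_window(sm, tt, j), error = function(e) NULL)
    auto_ok <- !is.null(up_w) && detect_autoresponse(up_w, th)
    event_ok <- auto_ok || (rid_override && is.null(up_w))
    nw <- round(30 / rec$dt)
    i_stim <- round(tt / rec$dt) + 1L
    idx <- seq(max(i_stim - nw, 1L), min(i_stim + nw - 1L, nrow(sm$F)))
    for (i in seq_len(n)) {
      if (i == j) next
      reason <- NA_character_
      if (!event_ok) {
        reason <- "no_autoresponse"
      } else if (!labelled[i]) {
        reason <- "unlabeled"
      } else if (max_contig_missing(mask0[idx, i]) > gap_frac * length(idx)) {
        reason <- "missing_gap"
      }
      amp <- NA_real_; deriv_max <- NA_real_
      if (is.na(reason)) {
        dw <- response_window(sm, tt, i)
        if (rid_override && any(window_post(dw) > 2)) {
          reason <- "amp_cap"
        } else {
          amp <- response_amplitude(dw)
          deriv_max <- max(abs(second_derivative(dw)[dw$t >= 0]))
          key <- sprintf("ev%d_%s_%s", ev, sm$labels[j], sm$labels[i])
          windows[[key]] <- list(up = up_w, down = dw,
                                 up_raw = tryCatch(response_window(raw, tt, j),
                                                   error = function(e) NULL),
                                 down_raw = response_window(raw, tt, i))
        }
      }
      included <- is.na(reason)
      if (included) counts["retained"] <- counts["retained"] + 1L
      else counts[reason] <- counts[reason] + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        event = ev, time_s = tt, stim_neuron = sm$labels[j],
        down_neuron = sm$labels[i], autoresponse_ok = auto_ok,
        included = included, reason = reason, amplitude = amp,
        deriv_max = deriv_max, stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event = integer(0), time_s = numeric(0),
               stim_neuron = character(0), down_neuron = character(0),
               autoresponse_ok = logical(0), included = logical(0),
               reason = character(0), amplitude = numeric(0),
               deriv_max = numeric(0))
  message(sprintf(
    "inclusion: %d retained; excluded %d (no autoresponse), %d (missing gap), %d (unlabeled), %d (amplitude cap)",
    counts["retained"], counts["no_autoresponse"], counts["missing_gap"],
    counts["unlabeled"], counts["amp_cap"]))
  structure(list(table = tab, windows = windows, counts = counts),
            class = "screen_result")
}
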