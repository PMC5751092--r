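# Preprocessing: translation-invariant wavelet denoising, epoching, and the
# automatic annotator that replaces the study's manual raters.

#' Translation-invariant wavelet denoising
#'
#' Cycle-spinning wavelet shrinkage applied independently per channel:
#' an orthogonal wavelet with 4 vanishing moments, 4 decomposition levels,
#' soft universal threshold, averaged over all 2^levels decimation phases.
#'
#' The underlying transform is periodic. With `boundary = "reflect"` (the
#' default) the signal is first padded by reflection so that recordings whose
#' first and last samples differ (a trial that starts standing and ends
#' seated) do not inherit a spurious wrap-around step; the padding is cropped
#' after reconstruction. With `boundary = "periodic"` the operator acts on
#' the raw signal and is exactly covariant under circular shifts.
#'
#' @param x Numeric matrix (samples x channels) or a `sensor_trial`.
#' @param levels Decomposition depth.
#' @param boundary `"reflect"` (pad by reflection, no wrap artifact) or
#'   `"periodic"` (exact circular-shift covariance).
#' @return Same shape/type as `x` with denoised channels.
#' @export
denoise <- function(x, levels = 4L, boundary = c("reflect", "periodic")) {
  boundary <- match.arg(boundary)
  if (inherits(x, "sensor_trial")) {
    x$signal <- denoise(x$signal, levels = levels, boundary = boundary)
    return(x)
  }
  x <- as_numeric_matrix(x)
  if (!all(is.finite(x))) abort("`x` must be finite.")
  if (nrow(x) < 2^(levels + 1))
    abort(sprintf("need at least %d samples for %d decomposition levels.",
                  2^(levels + 1), levels))
  n <- nrow(x)
  if (boundary == "reflect") {
    # pad to a multiple of 2^levels with at least `pad` reflected samples
    pad <- min(n, 512L)
    block <- 2^levels
    total <- ceiling((n + 2L * pad) / block) * block
    lpad <- pad
    rpad <- total - n - lpad
    if (rpad > n) rpad <- n  # clamp; total then shrinks to a valid multiple
    total <- floor((n + lpad + rpad) / block) * block
    rpad <- total - n - lpad
    xp <- rbind(x[lpad:1, , drop = FALSE], x,
                x[n:(n - rpad + 1L), , drop = FALSE])
    out <- .ti_denoise_cpp(xp, as.integer(levels))[lpad + seq_len(n), ,
                                                   drop = FALSE]
  } else {
    out <- .ti_denoise_cpp(x, as.integer(levels))
  }
  dimnames(out) <- dimnames(x)
  out
}

#' Cut a signal into non-overlapping epochs
#'
#' @param x Numeric matrix (samples x channels).
#' @param epoch_length Samples per epoch (default 100 = 0.2 s at 500 Hz).
#' @return List of channels x epoch_length matrices; trailing remainder
#'   samples are discarded (floor rule).
#' @export
epoch_signal <- function(x, epoch_length = 100L) {
  x <- as_numeric_matrix(x)
  epoch_length <- as.integer(epoch_length)
  if (epoch_length < 2) abort("`epoch_length` must be >= 2.")
  if (nrow(x) < epoch_length)
    abort("signal shorter than one epoch.")
  ne <- nrow(x) %/% epoch_length
  lapply(seq_len(ne), function(e) {
    t(x[((e - 1L) * epoch_length + 1L):(e * epoch_length), , drop = FALSE])
  })
}

#' Annotate sit-to-stand transitions from the knee angle
#'
#' Finds downward crossings of the 45 degree knee angle (the SiSt midpoint
#' convention) and grows each into a region bounded where the smoothed knee
#' angular velocity magnitude falls below 5% of the event's peak. Stand-to-sit
#' events cross 45 degrees upward and are ignored.
#'
#' @param knee_angle Numeric vector, knee angle in degrees (denoised).
#' @param sample_rate Sampling rate in Hz.
#' @param midpoint_angle Crossing angle in degrees.
#' @param velocity_fraction Region boundary as a fraction of peak velocity.
#' @return Tibble with `onset`, `offset` (0-based half-open samples) and
#'   `midpoint` (0-based sample of the first sample at/after the crossing).
#'   Empty tibble when no crossing exists.
#' @export
annotate_transitions <- function(knee_angle, sample_rate = 500,
                                 midpoint_angle = 45,
                                 velocity_fraction = 0.05) {
  stopifnot(is.numeric(knee_angle))
  n <- length(knee_angle)
  # smoothed angle and central-difference angular velocity for the coarse pass
  w <- max(3L, round(0.2 * sample_rate))
  if (w %% 2 == 0) w <- w + 1L
  sm <- stats::filter(knee_angle, rep(1 / w, w), sides = 2)
  na <- is.na(sm)
  sm[na] <- knee_angle[na]
  sm <- as.numeric(sm)
  half <- (w - 1L) %/% 2L
  idx <- seq_len(n)
  ip <- pmin(idx + half, n)
  im <- pmax(idx - half, 1L)
  vel <- (sm[ip] - sm[im]) / ((ip - im) / sample_rate)

  above <- knee_angle >= midpoint_angle
  cross <- which(above[-n] & !above[-1]) + 1L  # first sample below 45
  out <- list()
  last_off <- -1L
  half_win <- round(2.5 * sample_rate)
  min_run <- max(1L, round(0.1 * sample_rate))
  for (cs in cross) {
    if (cs <= last_off) next
    lo <- max(1L, cs - half_win)
    hi <- min(n, cs + half_win)
    wv <- abs(vel[lo:hi])
    peak <- max(wv)
    if (peak <= 0) next

    # coarse boundaries: maximal above-threshold run through the crossing,
    # bridging sub-0.1 s dips (noise robustness)
    below <- wv < velocity_fraction * peak
    r <- rle(below)
    r$values[r$values & r$lengths < min_run] <- FALSE
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    pos <- cs - lo + 1L
    kk <- which(!r$values & starts <= pos & ends >= pos)
    if (!length(kk)) next
    on1 <- lo + starts[kk] - 1L
    off1 <- lo + ends[kk] - 1L

    # refine by fitting a logistic to the event (plus a short margin) and
    # evaluating the 5%-of-peak-velocity rule on the fitted profile; the
    # coarse boundaries remain the fallback
    width <- (off1 - on1) / sample_rate
    marg <- round(min(max(0.1 * width, 0.1), 0.5) * sample_rate)
    flo <- max(1L, on1 - marg)
    fhi <- min(n, off1 + marg)
    fit <- try(suppressWarnings({
      tt <- (flo:fhi) / sample_rate
      yy <- sm[flo:fhi]
      st0 <- min(yy)
      sp0 <- max(yy) - st0
      r0 <- 2 * u05 / max(width, 0.2)
      stats::nls(yy ~ st + sp / (1 + exp(r * (tt - t0))),
                 start = list(st = st0, sp = sp0, r = r0,
                              t0 = cs / sample_rate),
                 control = stats::nls.control(maxiter = 100, warnOnly = TRUE))
    }), silent = TRUE)
    onset <- on1 - 1L
    offset <- off1
    if (!inherits(fit, "try-error")) {
      cf <- stats::coef(fit)
      if (is.finite(cf["r"]) && cf["r"] > 0 && cf["sp"] > 0) {
        hw <- u05 / cf["r"]  # half-width where fitted velocity hits 5% of peak
        o1 <- round((cf["t0"] - hw) * sample_rate)
        o2 <- round((cf["t0"] + hw) * sample_rate)
        if (o1 >= 0 && o2 > o1 && o2 <= n) {
          onset <- as.integer(o1)
          offset <- as.integer(o2)
        }
      }
    }
    last_off <- max(offset, off1)
    out[[length(out) + 1L]] <- tibble::tibble(
      onset = onset, offset = offset, midpoint = cs - 1L)  # 0-based half-open
  }
  if (!length(out))
    return(tibble::tibble(onset = integer(), offset = integer(),
                          midpoint = integer()))
  dplyr::bind_rows(out)
}

#' Majority-vote epoch labels from transition regions
#'
#' An epoch is labelled 1 iff at least 50% of its samples lie inside a region
#' (exact 50/50 ties label 1, favouring sensitivity).
#'
#' @param regions Tibble/data frame with `onset`, `offset` in 0-based
#'   half-open samples.
#' @param n_epochs Number of epochs.
#' @param epoch_length Samples per epoch.
#' @return Integer vector of 0/1 labels, length `n_epochs`.
#' @export
label_epochs <- function(regions, n_epochs, epoch_length = 100L) {
  n_epochs <- as.integer(n_epochs)
  epoch_length <- as.integer(epoch_length)
  labels <- integer(n_epochs)
  if (is.null(regions) || nrow(regions) == 0) return(labels)
  total <- n_epochs * epoch_length
  if (any(regions$onset < 0) || any(regions$offset > total))
    abort("region exceeds trial length.")
  starts <- (seq_len(n_epochs) - 1L) * epoch_length  # 0-based epoch starts
  for (r in seq_len(nrow(regions))) {
    ov <- pmin(starts + epoch_length, regions$offset[r]) -
      pmax(starts, regions$onset[r])
    labels[ov >= epoch_length / 2] <- 1L
  }
  labels
}

#' Majority-vote sitting labels from the posture timeline
#'
#' @param truth_posture Character/factor vector of per-sample posture codes.
#' @param n_epochs Number of epochs.
#' @param epoch_length Samples per epoch.
#' @return Integer vector of 0/1 labels (1 = sitting majority; ties label 1).
#' @export
label_sitting <- function(truth_posture, n_epochs, epoch_length = 100L) {
  n_epochs <- as.integer(n_epochs)
  epoch_length <- as.integer(epoch_length)
  sit <- as.integer(truth_posture == "sit")
  vapply(seq_len(n_epochs), function(e) {
    idx <- ((e - 1L) * epoch_length + 1L):(e * epoch_length)
    as.integer(mean(sit[idx]) >= 0.5)
  }, integer(1))
}

#' Epoch a trial and derive its ground-truth labels
#'
#' Denoises the trial, runs the automatic annotator on the knee channel, and
#' produces per-epoch sitting and transition labels.
#'
#' @param trial A `sensor_trial`.
#' @param epoch_length Samples per epoch.
#' @param denoise_first Denoise before annotating (recommended).
#' @return An `epoched_trial`: list with `n_epochs`, `epoch_length`,
#'   `sit_labels`, `transition_labels`, `regions`, `midpoints`, the denoised
#'   `signal`, and the parent trial's metadata.
#' @export
epoch_trial <- function(trial, epoch_length = 100L, denoise_first = TRUE) {
  stopifnot(inherits(trial, "sensor_trial"))
  sig <- if (denoise_first) denoise(trial$signal) else trial$signal
  n_epochs <- nrow(sig) %/% epoch_length
  regions <- annotate_transitions(sig[, "knee_deg"], trial$sample_rate)
  structure(list(
    subject_id = trial$subject_id,
    activity_id = trial$activity_id,
    position_id = trial$position_id,
    sample_rate = trial$sample_rate,
    epoch_length = as.integer(epoch_length),
    n_epochs = as.integer(n_epochs),
    signal = sig,
    regions = regions,
    midpoints = regions$midpoint,
    sit_labels = label_sitting(trial$truth_posture, n_epochs, epoch_length),
    transition_labels = label_epochs(regions, n_epochs, epoch_length),
    truth_transitions = trial$transitions
  ), class = "epoched_trial")
}
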