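# Synthetic orthosis-signal simulator.
#
# Generates 60 s, 14-channel recordings that follow a scripted activity
# protocol (10 activities, five initial seated leg positions, 34 trials per
# subject) with exact ground-truth transition intervals and a per-sample
# posture code. The kinematic model is deliberately coarse: the knee
# potentiometer follows a logistic trajectory through each sit-to-stand,
# segment inclinations are derived from the knee angle, accelerometers see the
# gravity projection of those inclinations plus a motion term, gyroscopes see
# the inclination rate, and insole force sensors ramp with the load fraction.

#' Channel names of the simulated orthosis
#'
#' Fixed 14-channel layout: thigh accelerometer (x, y, z, in g), thigh
#' gyroscope (pitch, roll, deg/s), the same for the shank, knee and ankle
#' potentiometers (deg), and heel/toe insole force sensors (N).
#'
#' @return Character vector of length 14.
#' @export
sist_channels <- function() {
  c("thigh_acc_x", "thigh_acc_y", "thigh_acc_z", "thigh_gyro_p", "thigh_gyro_r",
    "shank_acc_x", "shank_acc_y", "shank_acc_z", "shank_gyro_p", "shank_gyro_r",
    "knee_deg", "ankle_deg", "heel_n", "toe_n")
}

# Transition-duration distribution: normal(mu, sigma) truncated to [lo, hi].
# mu/sigma are moment-matched so the *truncated* law has mean 1.30 s and
# SD 0.55 s, the dataset-level statistics the generator is calibrated to.
DUR_MU <- 0.8277214
DUR_SIGMA <- 0.8564832
DUR_LO <- 0.5
DUR_HI <- 3.0

# Logistic steepness: the curve spans [-c, c] in logistic units over its full
# window, leaving endpoint offsets span/(1 + e^c) < 1 deg for spans <= 105 deg.
KNEE_STEEPNESS <- 4.9
# |u| where the logistic velocity falls to 5% of its peak; the ground-truth
# transition interval is the central fraction u05/steepness of the full window.
u05 <- log((78 + sqrt(78^2 - 4)) / 2)

#' Subject parameter set for the simulator
#'
#' @param subject_id Integer id.
#' @param body_mass Body mass in kg.
#' @param seated_knee_angle_by_position Named numeric of length 5
#'   (names `"0"`..`"4"`): seated knee angle in degrees for each initial leg
#'   position (0 = legs extended, 1 = bent under the chair, 2 = 90 deg,
#'   3 = crossed ankles, 4 = leg crossed over knee).
#' @param standing_knee_angle Standing knee angle in degrees.
#' @param transition_duration_mean,transition_duration_sd Location/scale (s) of
#'   the subject's truncated-normal transition-duration law on \[0.5, 3\] s.
#' @param gait_cadence_by_speed Named numeric (`slow`, `normal`, `fast`),
#'   steps/min.
#' @param noise_sd_per_channel Named numeric of length 14: additive white
#'   Gaussian noise SD per channel, in channel units.
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(subject_id,
                           body_mass = 65.77,
                           seated_knee_angle_by_position =
                             c("0" = 50, "1" = 110, "2" = 90, "3" = 90, "4" = 90),
                           standing_knee_angle = 5,
                           transition_duration_mean = DUR_MU,
                           transition_duration_sd = DUR_SIGMA,
                           gait_cadence_by_speed =
                             c(slow = 85, normal = 105, fast = 125),
                           noise_sd_per_channel = default_noise_sd()) {
  stopifnot(length(seated_knee_angle_by_position) == 5)
  if (is.null(names(seated_knee_angle_by_position)))
    names(seated_knee_angle_by_position) <- as.character(0:4)
  if (!identical(sort(names(seated_knee_angle_by_position)), as.character(0:4)))
    abort("`seated_knee_angle_by_position` must be named \"0\"..\"4\".")
  if (transition_duration_mean <= 0)
    abort("`transition_duration_mean` must be positive.")
  if (any(noise_sd_per_channel < 0))
    abort("noise SDs must be non-negative.")
  structure(list(
    subject_id = as.integer(subject_id),
    body_mass = body_mass,
    seated_knee_angle_by_position = seated_knee_angle_by_position,
    standing_knee_angle = standing_knee_angle,
    transition_duration_mean = transition_duration_mean,
    transition_duration_sd = transition_duration_sd,
    gait_cadence_by_speed = gait_cadence_by_speed,
    noise_sd_per_channel = noise_sd_per_channel
  ), class = "subject_params")
}

# Additive white-noise scales: accelerometers 0.05 g, gyroscopes 5 deg/s,
# potentiometers 0.5 deg, force sensors 2 N.
default_noise_sd <- function() {
  setNames(c(0.05, 0.05, 0.05, 5, 5, 0.05, 0.05, 0.05, 5, 5, 0.5, 0.5, 2, 2),
           sist_channels())
}

#' Draw a population of simulated subjects
#'
#' Subject parameters vary around the study population: body mass
#' normal(65.77, 10^2) kg truncated to \[45, 95\], seated knee angles jittered
#' by N(0, 3 deg), cadences by N(0, 5 steps/min), and the transition-duration
#' location by N(0, 0.05 s).
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @return List of [subject_params()] objects.
#' @export
sample_subjects <- function(n_subjects, seed = 1L) {
  stopifnot(n_subjects >= 1)
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      seated <- c("0" = 50, "1" = 110, "2" = 90, "3" = 90, "4" = 90) +
        rnorm(5, 0, 3)
      seated <- pmin(pmax(seated, 48), 120)
      subject_params(
        subject_id = i,
        body_mass = truncnorm::rtruncnorm(1, 45, 95, 65.77, 10),
        seated_knee_angle_by_position = seated,
        standing_knee_angle = truncnorm::rtruncnorm(1, 3, 8, 5, 1),
        transition_duration_mean = DUR_MU + rnorm(1, 0, 0.05),
        transition_duration_sd = DUR_SIGMA,
        gait_cadence_by_speed = c(slow = 85, normal = 105, fast = 125) +
          rnorm(3, 0, 5)
      )
    })
  })
}

#' Logistic knee-angle trajectory of a sit-to-stand
#'
#' Monotone non-increasing logistic curve from the seated to the standing knee
#' angle. The first/last samples are within 1 degree of the endpoint angles
#' (for angle spans up to ~105 deg at the default steepness) and the curve
#' crosses the midpoint angle exactly once, halfway through.
#'
#' @param duration_s Duration in seconds (full trajectory window).
#' @param seated_angle_deg,standing_angle_deg Endpoint angles, seated >
#'   standing.
#' @param sample_rate Sampling rate in Hz.
#' @param steepness Half-range of the logistic argument over the window.
#' @return Numeric vector of `round(duration_s * sample_rate)` angles (deg).
#' @export
knee_trajectory <- function(duration_s, seated_angle_deg, standing_angle_deg,
                            sample_rate, steepness = KNEE_STEEPNESS) {
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0)
    abort("`duration_s` must be a single positive number.")
  if (seated_angle_deg <= standing_angle_deg)
    abort("`seated_angle_deg` must exceed `standing_angle_deg`.")
  n <- round(duration_s * sample_rate)
  if (n < 2) abort("`duration_s` too short for the sample rate.")
  t <- (seq_len(n) - 1) / sample_rate
  t0 <- (n - 1) / 2 / sample_rate
  r <- 2 * steepness / duration_s
  standing_angle_deg +
    (seated_angle_deg - standing_angle_deg) / (1 + exp(r * (t - t0)))
}

# ---- activity scripting ------------------------------------------------------

ACT_WITH_POSITION <- c(1L, 2L, 3L, 4L, 6L, 7L, 8L)
ACT_SEATED_SET <- c(2L, 3L, 4L, 6L, 7L, 8L)  # repeated over the 5 positions

# Segment script for one activity. Transitions are placed at the scripted
# 20 s marks; `d` are the ground-truth durations, the full logistic window is
# d / (u05 / steepness) and the truth interval is its central part.
activity_segments <- function(activity_id, durations) {
  kf <- KNEE_STEEPNESS / u05  # full window / truth duration
  seg <- function(type, from, to, speed = NA_character_)
    list(type = type, from = from, to = to, speed = speed)
  tr <- function(type, at, d) seg(type, at, at + d * kf)
  switch(as.character(activity_id),
    "1" = list(seg("sit", 0, 60)),
    "2" = ,
    "6" = {
      s1 <- tr("sist", 20, durations[1]); s2 <- tr("stsi", 40, durations[2])
      list(seg("sit", 0, 20), s1, seg("stand", s1$to, 40), s2,
           seg("sit", s2$to, 60))
    },
    "3" = ,
    "7" = {
      spd <- if (activity_id == 7L) "fast" else "normal"
      s1 <- tr("sist", 20, durations[1]); s2 <- tr("stsi", 40, durations[2])
      # short balance pause between rising and walking
      list(seg("sit", 0, 20), s1, seg("stand", s1$to, s1$to + 2),
           seg("walk", s1$to + 2, s1$to + 10, spd),
           seg("stand", s1$to + 10, 40), s2, seg("sit", s2$to, 60))
    },
    "4" = {
      s1 <- tr("sist", 20, durations[1]); s2 <- tr("stsi", 48, durations[2])
      list(seg("sit", 0, 20), s1, seg("stand", s1$to, 40),
           seg("walk", 40, 48, "normal"), s2, seg("sit", s2$to, 60))
    },
    "5" = list(seg("walk", 0, 60, "normal")),
    "8" = {
      s2 <- tr("stsi", 40, durations[1])
      list(seg("stand", 0, 20), seg("walk", 20, 40, "normal"), s2,
           seg("sit", s2$to, 60))
    },
    "9" = list(seg("walk", 0, 60, "slow")),
    "10" = list(seg("walk", 0, 60, "fast")),
    abort(sprintf("unknown `activity_id` %s (must be 1..10).", activity_id))
  )
}

n_transitions_scripted <- function(activity_id) {
  # c(SiSt, StSi) counts per activity script
  switch(as.character(activity_id),
    "1" = c(0L, 0L), "2" = c(1L, 1L), "3" = c(1L, 1L), "4" = c(1L, 1L),
    "5" = c(0L, 0L), "6" = c(1L, 1L), "7" = c(1L, 1L), "8" = c(0L, 1L),
    "9" = c(0L, 0L), "10" = c(0L, 0L),
    abort("unknown `activity_id`."))
}

#' Simulate one 60 s orthosis trial
#'
#' Builds the posture timeline scripted for the activity, draws transition
#' durations from the subject's truncated-normal law, synthesises all 14
#' channels and records the ground truth exactly. The knee channel follows a
#' logistic trajectory through each transition; the recorded truth interval is
#' the central part of the trajectory where the angular velocity exceeds 5% of
#' its peak, so automatic annotation and ground truth share one definition.
#'
#' @param subject A [subject_params()] object.
#' @param activity_id Activity 1..10.
#' @param position_id Initial seated leg position 0..4. Required for
#'   activities that begin or end seated (1, 2, 3, 4, 6, 7, 8).
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   trials.
#' @param sample_rate Sampling rate in Hz.
#' @return A `sensor_trial`: list with `signal` (T x 14 matrix),
#'   `transitions` (tibble `onset`, `offset` in 0-based half-open samples,
#'   `direction`), `truth_posture` (per-sample code), and metadata.
#' @examples
#' subj <- sample_subjects(1, seed = 1)[[1]]
#' trial <- simulate_trial(subj, activity_id = 2, position_id = 2, seed = 7)
#' dim(trial$signal)
#' trial$transitions
#' @export
simulate_trial <- function(subject, activity_id, position_id = NULL,
                           seed = 1L, sample_rate = 500) {
  stopifnot(inherits(subject, "subject_params"))
  activity_id <- as.integer(activity_id)
  if (!activity_id %in% 1:10)
    abort(sprintf("unknown `activity_id` %d (must be 1..10).", activity_id))
  needs_pos <- activity_id %in% ACT_WITH_POSITION
  if (needs_pos && is.null(position_id))
    abort(sprintf("activity %d begins or ends seated: `position_id` required.",
                  activity_id))
  if (!is.null(position_id) && !position_id %in% 0:4)
    abort("`position_id` must be in 0..4.")

  with_seed(seed, {
    T <- round(60 * sample_rate)
    t <- (seq_len(T) - 1) / sample_rate

    ntr <- sum(n_transitions_scripted(activity_id))
    durations <- if (ntr > 0)
      truncnorm::rtruncnorm(ntr, DUR_LO, DUR_HI,
                            subject$transition_duration_mean,
                            subject$transition_duration_sd) else numeric()
    segs <- activity_segments(activity_id, durations)

    seated <- if (needs_pos)
      unname(subject$seated_knee_angle_by_position[as.character(position_id)])
    else NA_real_
    standg <- subject$standing_knee_angle
    kf <- KNEE_STEEPNESS / u05

    knee <- numeric(T)
    posture <- character(T)
    walk_speed <- rep(NA_character_, T)
    transitions <- list()

    for (sg in segs) {
      i0 <- floor(sg$from * sample_rate) + 1L
      i1 <- min(T, ceiling(sg$to * sample_rate))
      if (i1 < i0) next
      idx <- i0:i1
      tt <- t[idx]
      if (sg$type == "sit") {
        knee[idx] <- seated
        posture[idx] <- "sit"
      } else if (sg$type == "stand") {
        knee[idx] <- standg
        posture[idx] <- "stand"
      } else if (sg$type == "walk") {
        cad <- unname(subject$gait_cadence_by_speed[sg$speed])
        f <- cad / 120  # knee flexion cycles per second for one leg
        knee[idx] <- 22 + 18 * sin(2 * pi * f * tt)
        posture[idx] <- "walk"
        walk_speed[idx] <- sg$speed
      } else {  # sist / stsi
        dfull <- sg$to - sg$from
        dtruth <- dfull / kf
        tmid <- (sg$from + sg$to) / 2
        r <- 2 * KNEE_STEEPNESS / dfull
        curve <- standg + (seated - standg) / (1 + exp(r * (tt - tmid)))
        if (sg$type == "stsi")
          curve <- standg + (seated - standg) - (curve - standg)
        knee[idx] <- curve
        on_s <- round((tmid - dtruth / 2) * sample_rate)   # 0-based
        off_s <- round((tmid + dtruth / 2) * sample_rate)  # half-open
        inside <- idx[idx - 1L >= on_s & idx - 1L < off_s]
        # logistic tails keep the pre/post posture; the 5%-velocity core is
        # the transition proper
        posture[idx] <- if (sg$type == "sist") "sit" else "stand"
        posture[idx[tt >= tmid + dtruth / 2]] <-
          if (sg$type == "sist") "stand" else "sit"
        posture[inside] <- "transition"
        transitions[[length(transitions) + 1L]] <- tibble::tibble(
          onset = on_s, offset = off_s,
          direction = if (sg$type == "sist") "SiSt" else "StSi")
      }
    }

    signal <- synth_channels(knee, posture, walk_speed, t, subject,
                             seated, standg, sample_rate,
                             if (needs_pos) as.integer(position_id) else NA_integer_)

    transitions <- if (length(transitions)) dplyr::bind_rows(transitions)
    else tibble::tibble(onset = integer(), offset = integer(),
                        direction = character())
    structure(list(
      subject_id = subject$subject_id,
      activity_id = activity_id,
      position_id = if (needs_pos) as.integer(position_id) else NA_integer_,
      sample_rate = sample_rate,
      signal = signal,
      transitions = transitions,
      truth_posture = posture,
      seed = as.integer(seed)
    ), class = "sensor_trial")
  })
}

# Derive the remaining 13 channels from the knee angle and posture timeline.
synth_channels <- function(knee, posture, walk_speed, t, subject,
                           seated, standg, sample_rate, position_id) {
  T <- length(knee)
  nsd <- subject$noise_sd_per_channel
  is_walk <- posture == "walk"

  # fraction of the way from standing (0) to seated (1) on the knee channel
  ref_seated <- if (is.na(seated)) 90 else seated
  frac <- (knee - standg) / max(ref_seated - standg, 1)
  frac <- pmin(pmax(frac, 0), 1)

  # thigh pitch: ~90 deg (horizontal) seated, ~0 standing; swings while walking
  phi <- 90 * pmin(frac / max((90 - standg) / max(ref_seated - standg, 1), 1e-6), 1)
  # shank deviation from vertical: position-dependent offset that unwinds
  psi <- numeric(T)
  if (!is.na(position_id)) {
    pos_off <- c("0" = 35, "1" = -25, "2" = 0, "3" = 5, "4" = 10)
    psi <- frac * unname(pos_off[as.character(position_id)])
  }
  if (any(is_walk)) {
    cad <- rep(NA_real_, T)
    for (sp in c("slow", "normal", "fast")) {
      sel <- is_walk & walk_speed == sp
      cad[sel] <- unname(subject$gait_cadence_by_speed[sp])
    }
    fwalk <- cad / 120
    phi[is_walk] <- 15 + 12 * sin(2 * pi * fwalk[is_walk] * t[is_walk])
    psi[is_walk] <- 20 * sin(2 * pi * fwalk[is_walk] * t[is_walk] + pi / 3)
  }

  drate <- function(x) c(0, diff(x)) * sample_rate
  dphi <- drate(phi)
  dpsi <- drate(psi)

  drift <- function(amp, f0) amp * sin(2 * pi * f0 * t + runif(1, 0, 2 * pi))
  noise <- function(ch) rnorm(T, 0, nsd[[ch]])
  rad <- pi / 180

  # load fraction on the instrumented leg
  lf <- 1 - frac
  lf[posture == "sit"] <- 0.05
  weight <- subject$body_mass * 9.81 * 0.5
  heel <- weight * lf * 0.7
  toe <- weight * lf * 0.3
  if (any(is_walk)) {
    ph <- 2 * pi * (cad[is_walk] / 120) * t[is_walk]
    heel[is_walk] <- weight * 1.1 * pmax(0, sin(ph))
    toe[is_walk] <- weight * 0.7 * pmax(0, sin(ph - 2.2))
  }
  heel <- pmax(heel + 10 + noise("heel_n"), 0)
  toe <- pmax(toe + 4 + noise("toe_n"), 0)

  ankle <- 5 + 0.15 * (knee - standg)
  if (any(is_walk))
    ankle[is_walk] <- ankle[is_walk] +
      5 * sin(2 * pi * (cad[is_walk] / 120) * t[is_walk] + pi / 2)

  signal <- cbind(
    thigh_acc_x = sin(phi * rad) + 2e-5 * drate(dphi) +
      drift(0.02, 0.05) + noise("thigh_acc_x"),
    thigh_acc_y = drift(0.02, 0.07) + noise("thigh_acc_y"),
    thigh_acc_z = cos(phi * rad) + drift(0.02, 0.04) + noise("thigh_acc_z"),
    thigh_gyro_p = dphi + noise("thigh_gyro_p"),
    thigh_gyro_r = 0.3 * dphi + noise("thigh_gyro_r"),
    shank_acc_x = sin(psi * rad) + 2e-5 * drate(dpsi) +
      drift(0.02, 0.06) + noise("shank_acc_x"),
    shank_acc_y = drift(0.02, 0.05) + noise("shank_acc_y"),
    shank_acc_z = cos(psi * rad) + drift(0.02, 0.03) + noise("shank_acc_z"),
    shank_gyro_p = dpsi + noise("shank_gyro_p"),
    shank_gyro_r = 0.3 * dpsi + noise("shank_gyro_r"),
    knee_deg = pmin(pmax(knee + noise("knee_deg"), -5), 130),
    ankle_deg = ankle + noise("ankle_deg"),
    heel_n = heel,
    toe_n = toe
  )
  signal
}

#' Simulate the full multi-subject protocol
#'
#' Per subject: activities 2, 3, 4, 6, 7 and 8 once per each of the five
#' initial seated positions, plus activities 1, 5, 9 and 10 once each -- 34
#' trials of 60 s. Activity 1 (quiet sitting) uses position 2.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed; the whole dataset is deterministic under it.
#' @param sample_rate Sampling rate in Hz.
#' @return A `sist_dataset`: list with `trials` (list of `sensor_trial`) and
#'   `index` (tibble, one row per trial).
#' @export
simulate_dataset <- function(n_subjects, seed = 1L, sample_rate = 500) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    abort("`n_subjects` must be >= 1.")
  n_subjects <- as.integer(n_subjects)
  subjects <- sample_subjects(n_subjects, seed = seed)

  plan <- dplyr::bind_rows(
    tibble::tibble(activity_id = 1L, position_id = 2L),
    tidyr::expand_grid(activity_id = ACT_SEATED_SET, position_id = 0:4),
    tibble::tibble(activity_id = c(5L, 9L, 10L), position_id = NA_integer_)
  )
  index <- tidyr::expand_grid(subject_id = seq_len(n_subjects), plan) %>%
    mutate(trial_id = dplyr::row_number(), .before = 1)
  seeds <- child_seeds(seed + 1L, nrow(index))
  index$trial_seed <- seeds

  trials <- purrr::pmap(index, function(trial_id, subject_id, activity_id,
                                        position_id, trial_seed) {
    simulate_trial(subjects[[subject_id]], activity_id,
                   position_id = if (is.na(position_id)) NULL else position_id,
                   seed = trial_seed, sample_rate = sample_rate)
  })
  index$n_sist <- purrr::map_int(trials, ~ sum(.x$transitions$direction == "SiSt"))
  index$n_stsi <- purrr::map_int(trials, ~ sum(.x$transitions$direction == "StSi"))

  structure(list(trials = trials, index = index, subjects = subjects,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "sist_dataset")
}

#' @export
print.sensor_trial <- function(x, ...) {
  cat(sprintf("<sensor_trial> subject %d, activity %d%s, %d x %d @ %g Hz\n",
              x$subject_id, x$activity_id,
              if (is.na(x$position_id)) "" else sprintf(" (position %d)", x$position_id),
              nrow(x$signal), ncol(x$signal), x$sample_rate))
  if (nrow(x$transitions)) {
    cat(sprintf("  %d transition(s): %s\n", nrow(x$transitions),
                paste(sprintf("%s %.2f-%.2fs", x$transitions$direction,
                              x$transitions$onset / x$sample_rate,
                              x$transitions$offset / x$sample_rate),
                      collapse = ", ")))
  } else cat("  no transitions\n")
  invisible(x)
}

#' @export
print.sist_dataset <- function(x, ...) {
  cat(sprintf("<sist_dataset> %d subjects, %d trials, %.2f h, %d SiSt / %d StSi\n",
              length(x$subjects), nrow(x$index),
              nrow(x$index) * 60 / 3600, sum(x$index$n_sist), sum(x$index$n_stsi)))
  invisible(x)
}

#' Tidy a trial's signal into a long tibble
#'
#' @param x A `sensor_trial`.
#' @param ... Unused.
#' @return Tibble with `time_s`, `channel`, `value`, `posture`.
#' @export
as_tibble.sensor_trial <- function(x, ...) {
  T <- nrow(x$signal)
  tibble::tibble(
    time_s = rep((seq_len(T) - 1) / x$sample_rate, ncol(x$signal)),
    channel = rep(colnames(x$signal), each = T),
    value = as.vector(x$signal),
    posture = rep(x$truth_posture, ncol(x$signal))
  )
}

#' SiSt transition durations of a dataset
#'
#' @param dataset A `sist_dataset`.
#' @param direction `"SiSt"` (default) or `"StSi"`.
#' @return Numeric vector of durations in seconds.
#' @export
transition_durations <- function(dataset, direction = "SiSt") {
  stopifnot(inherits(dataset, "sist_dataset"))
  unlist(lapply(dataset$trials, function(tr) {
    sel <- tr$transitions$direction == direction
    (tr$transitions$offset[sel] - tr$transitions$onset[sel]) / tr$sample_rate
  }))
}
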