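# Synthetic single-lead ECG: each beat is a sum of five Gaussian waves
# (P, Q, R, S, T) in beat-phase coordinates, traversed at the beat's own
# RR interval. Subject identity lives in the wave parameters and heart
# rate; sessions, electrode placements and movement conditions perturb
# them the way acquisition factors would.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state, so cohort generation is
#' reproducible without clobbering the session RNG.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a named substream seed from a master seed
#'
#' Deterministic 31-bit hash combining the master seed with a key string
#' (e.g. "subject/S03/session/2"), so every recording draws from its own
#' named substream and partial regeneration is stable.
#'
#' @param master integer master seed.
#' @param ... character/numeric key components.
#' @return integer in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(master, ...) {
  key <- paste(vapply(list(...), as.character, ""), collapse = "/")
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% m
  as.integer((h * 65599 + as.numeric(master)) %% m + 1)
}

# Canonical PQRST wave parameters in beat phase (radians), amplitudes in
# mV (R wave ~ 1 mV), widths in radians.
canonical_waves <- function() {
  list(theta = c(P = -pi / 3, Q = -pi / 12, R = 0, S = pi / 12, T = pi / 2),
       a = c(P = 0.04, Q = -0.17, R = 1.0, S = -0.25, T = 0.3),
       b = c(P = 0.25, Q = 0.10, R = 0.10, S = 0.10, T = 0.40))
}

#' Construct a subject template
#'
#' @param theta named numeric of wave centres (radians, strictly increasing
#'   over P, Q, R, S, T).
#' @param a named numeric of wave amplitudes (mV).
#' @param b named numeric of wave widths (radians, all positive).
#' @param rr_mean mean RR interval in seconds (in \[0.5, 1.2\]).
#' @param rr_sd beat-to-beat RR standard deviation in seconds.
#' @param subject_id label.
#' @return object of class `subject_template`.
#' @export
subject_template <- function(theta, a, b, rr_mean, rr_sd, subject_id) {
  if (any(diff(theta) <= 0))
    stop("wave centres must be strictly increasing P < Q < R < S < T",
         call. = FALSE)
  if (any(b <= 0)) stop("wave widths must be positive", call. = FALSE)
  if (rr_mean < 0.5 || rr_mean > 1.2)
    stop("mean RR must lie in [0.5, 1.2] s", call. = FALSE)
  structure(list(theta = theta, a = a, b = b, rr_mean = rr_mean,
                 rr_sd = rr_sd, subject_id = as.character(subject_id)),
            class = "subject_template")
}

# Flatten template parameters into a comparable vector (per-block scaling
# keeps each parameter family on a similar footing).
template_param_vector <- function(t) {
  c(t$theta / 0.15, log(abs(t$a)) / 0.2, log(t$b) / 0.2, t$rr_mean / 0.05)
}

#' Distance between two subject templates
#'
#' Euclidean distance over scaled wave parameters and heart rate; used to
#' enforce pairwise distinguishability when sampling a cohort.
#' @param t1,t2 [subject_template()] objects.
#' @return nonnegative number.
#' @export
template_distance <- function(t1, t2) {
  sqrt(sum((template_param_vector(t1) - template_param_vector(t2))^2))
}

# One random template draw (no distinguishability constraint); assumes the
# RNG is already seeded by the caller.
draw_template <- function(subject_id, spread) {
  cw <- canonical_waves()
  for (try in 1:200) {
    theta <- cw$theta + rnorm(5, 0, spread$theta_sd)
    if (all(diff(theta) > 0.02)) break
  }
  if (any(diff(theta) <= 0.02))
    stop("could not draw ordered wave centres", call. = FALSE)
  a <- cw$a * exp(rnorm(5, 0, spread$amp_sd))
  b <- cw$b * exp(rnorm(5, 0, spread$width_sd))
  rr <- min(1.2, max(0.5, rnorm(1, spread$rr_mean, spread$rr_mean_sd)))
  rr_sd <- runif(1, spread$rr_sd_range[1], spread$rr_sd_range[2])
  subject_template(theta, a, b, rr, rr_sd, subject_id)
}

#' Sample a cohort of distinguishable subject templates
#'
#' Draws each subject's wave parameters from distributions centred on the
#' canonical PQRST values; a subject too close to an already-drawn one
#' (template distance below `min_distance`) is rejected and redrawn.
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @param spread list of spread parameters (see [cohort_spec()] defaults).
#' @param min_distance minimum pairwise [template_distance()] (default 2).
#' @param max_tries rejection budget per subject (default 200).
#' @return named list of [subject_template()].
#' @export
sample_subjects <- function(n, seed, spread = cohort_spec()$subject_spread,
                            min_distance = 2, max_tries = 200) {
  ids <- sprintf("S%02d", seq_len(n))
  with_seed(seed, {
    templates <- list()
    for (id in ids) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- draw_template(id, spread)
        if (all(vapply(templates, function(t)
          template_distance(t, cand) >= min_distance, logical(1)))) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("rejection budget exhausted while sampling subjects",
                    call. = FALSE)
      templates[[id]] <- cand
    }
    templates
  })
}

#' Acquisition context for one recording
#'
#' Bundles the session, placement and condition factors with the generator
#' parameters that encode their effects: session drift (relative wave
#' parameter perturbation, scaled per placement), placement gain / noise /
#' morphology transform, and movement artifact intensity keyed by the
#' proximity of the moved body part to the electrodes.
#'
#' @param session 1 or 2.
#' @param placement `"fingers"`, `"wrists"` or `"chest"`.
#' @param condition `"rest"` or a `move_*` condition.
#' @param params generator parameter list; see [cohort_spec()].
#' @return object of class `acq_context`.
#' @export
acquisition_context <- function(session, placement, condition,
                                params = cohort_spec()$acq_params) {
  placement <- match.arg(placement, ecg_placements())
  condition <- match.arg(condition, ecg_conditions())
  structure(list(session = as.integer(session), placement = placement,
                 condition = condition, params = params),
            class = "acq_context")
}

#' Movement artifact intensity for a placement/condition pair
#'
#' Maximal when the moved body part carries the electrodes (hand movement
#' at the wrists or fingers), minimal for distal pairs (hand movement at
#' the chest); rest is always 0.
#'
#' @param placement electrode placement.
#' @param condition acquisition condition.
#' @param params generator parameters.
#' @return artifact amplitude in mV.
#' @export
artifact_intensity <- function(placement, condition,
                               params = cohort_spec()$acq_params) {
  if (condition == "rest") return(0)
  params$artifact[[condition]][[placement]]
}

# Session-2 morphology drift: a fixed per-(subject, session, placement)
# relative perturbation of the wave parameters, larger for the chest
# (broader placement area => bigger electrode repositioning error).
apply_session_drift <- function(template, ctx, master_seed) {
  if (ctx$session == 1L) return(template)
  sd_eff <- ctx$params$session_drift_sd *
    ctx$params$placement[[ctx$placement]]$drift_mult
  if (sd_eff <= 0) return(template)
  seed <- derive_seed(master_seed, "drift", template$subject_id,
                      ctx$session, ctx$placement)
  with_seed(seed, {
    template$theta <- template$theta + rnorm(5, 0, sd_eff * 0.5)
    template$a <- template$a * exp(rnorm(5, 0, sd_eff))
    template$b <- template$b * exp(rnorm(5, 0, sd_eff))
    template$rr_mean <- min(1.2, max(0.5, template$rr_mean *
                                       exp(rnorm(1, 0, sd_eff))))
  })
  template
}

# Deterministic placement transform of the wave parameters: a crude lead
# change (gain, wave-width scaling, altered P/T amplitude ratios, and a
# shift of the P/T wave positions mimicking a different projection axis).
apply_placement <- function(template, ctx) {
  p <- ctx$params$placement[[ctx$placement]]
  template$b <- template$b * p$width_mult
  template$a <- template$a * p$gain
  template$a[c("P", "T")] <- template$a[c("P", "T")] * p$pt_amp_mult
  template$theta["T"] <- template$theta["T"] + p$theta_shift
  template$theta["P"] <- template$theta["P"] - p$theta_shift / 2
  template
}

# Band-limited burst artifact of unit scale: an on/off burst envelope
# modulating a mix of low-frequency (1-15 Hz) and broadband noise.
movement_artifact <- function(n, fs) {
  wn <- rnorm(n)
  bt <- signal::butter(2, c(1, 15) / (fs / 2), type = "pass")
  low <- as.numeric(signal::filter(bt, wn))
  low <- low / max(sd(low), 1e-12)
  env_raw <- as.numeric(signal::filter(
    signal::butter(2, 0.7 / (fs / 2), type = "low"), rnorm(n)))
  env <- as.numeric(env_raw > quantile(env_raw, 0.45))
  env * (0.85 * low + 0.15 * rnorm(n))
}

#' Synthesize one ECG recording
#'
#' Generates `round(duration * fs)` samples: Gaussian PQRST beats with
#' beat-to-beat RR drawn from the subject's N(rr_mean, rr_sd) truncated
#' positive, plus baseline wander, placement noise, and (under movement
#' conditions) band-limited artifact bursts scaled by
#' [artifact_intensity()]. Session 2 applies a fixed per-(subject,
#' session, placement) morphology drift.
#'
#' @param template a [subject_template()].
#' @param ctx an [acquisition_context()].
#' @param duration recording length in seconds (> 0).
#' @param fs sampling rate in Hz (default 500).
#' @param seed integer seed for this recording's noise stream.
#' @param master_seed seed used to derive the session-drift perturbation
#'   (defaults to `seed`).
#' @return a [raw_ecg()].
#' @export
synthesize_recording <- function(template, ctx, duration, fs = 500,
                                 seed = 1L, master_seed = seed) {
  stopifnot(inherits(template, "subject_template"),
            inherits(ctx, "acq_context"))
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive", call. = FALSE)
  n <- round(duration * fs)
  eff <- apply_placement(apply_session_drift(template, ctx, master_seed), ctx)
  p <- ctx$params$placement[[ctx$placement]]
  intensity <- artifact_intensity(ctx$placement, ctx$condition, ctx$params)

  samples <- with_seed(seed, {
    # beat-to-beat RR, truncated positive
    n_beats <- ceiling(duration / max(eff$rr_mean - 4 * eff$rr_sd, 0.3)) + 3
    rr <- rnorm(n_beats, eff$rr_mean, eff$rr_sd)
    rr <- pmax(rr, 0.3)
    while (sum(rr) < duration + eff$rr_mean) {
      extra <- pmax(rnorm(8, eff$rr_mean, eff$rr_sd), 0.3)
      rr <- c(rr, extra)
    }
    onsets <- c(0, cumsum(rr))
    t <- (seq_len(n) - 1) / fs
    beat <- findInterval(t, onsets)
    phase <- -pi + 2 * pi * (t - onsets[beat]) / rr[beat]
    z <- numeric(n)
    for (w in seq_along(eff$theta)) {
      dtheta <- phase - eff$theta[w]
      dtheta <- dtheta - 2 * pi * round(dtheta / (2 * pi))
      z <- z + eff$a[w] * exp(-dtheta^2 / (2 * eff$b[w]^2))
    }
    # baseline wander: two slow sinusoids, amplified under movement
    wander_amp <- ctx$params$wander_amp * (1 + 3 * intensity)
    z <- z + wander_amp * sin(2 * pi * 0.22 * t + runif(1, 0, 2 * pi)) +
      0.6 * wander_amp * sin(2 * pi * 0.09 * t + runif(1, 0, 2 * pi))
    z <- z + rnorm(n, 0, p$noise_sd)
    if (intensity > 0) z <- z + intensity * movement_artifact(n, fs)
    z
  })
  raw_ecg(samples, fs = fs, subject_id = template$subject_id,
          session = ctx$session, placement = ctx$placement,
          condition = ctx$condition)
}

#' Cohort specification and generator defaults
#'
#' Encodes the acquisition protocol: `n_subjects` participants, session 1
#' with a 10-minute rest block followed by three 2-minute movement blocks
#' (hands, feet, chest) at each of three simultaneous electrode
#' placements, and session 2 with a 5-minute rest block; all at 500 Hz.
#' `acq_params` holds the generator's synthetic-world parameters:
#' placement gain / noise / morphology transforms (dry finger electrodes
#' are noisiest; the chest has the largest session-to-session
#' repositioning drift), the session drift scale, and the movement
#' artifact intensity matrix ordered by electrode proximity.
#'
#' @param n_subjects number of subjects (default 20).
#' @param fs sampling rate in Hz (default 500).
#' @param rest1_duration session-1 rest block length in s (default 600).
#' @param move_duration movement block length in s (default 120).
#' @param rest2_duration session-2 rest block length in s (default 300).
#' @param placements placements to generate (default all three).
#' @param seed master seed (default 1).
#' @param subject_spread between-subject template spread parameters.
#' @param acq_params acquisition-factor parameters (see Details).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20, fs = 500,
                        rest1_duration = 600, move_duration = 120,
                        rest2_duration = 300,
                        placements = ecg_placements(), seed = 1L,
                        subject_spread = NULL, acq_params = NULL) {
  if (any(c(rest1_duration, move_duration, rest2_duration) <= 0))
    stop("durations must be strictly positive", call. = FALSE)
  if (is.null(subject_spread))
    subject_spread <- list(theta_sd = c(0.10, 0.035, 0.02, 0.035, 0.12)[1:5],
                           amp_sd = 0.25, width_sd = 0.20,
                           rr_mean = 0.85, rr_mean_sd = 0.10,
                           rr_sd_range = c(0.02, 0.05))
  if (is.null(acq_params))
    acq_params <- list(
      placement = list(
        fingers = list(gain = 0.6, noise_sd = 0.020, width_mult = 1.15,
                       pt_amp_mult = 0.80, theta_shift = 0.10,
                       drift_mult = 0.35),
        wrists  = list(gain = 0.8, noise_sd = 0.016, width_mult = 1.05,
                       pt_amp_mult = 0.95, theta_shift = 0.08,
                       drift_mult = 1.0),
        chest   = list(gain = 1.0, noise_sd = 0.012, width_mult = 0.82,
                       pt_amp_mult = 1.30, theta_shift = -0.14,
                       drift_mult = 1.4)),
      session_drift_sd = 0.10,
      wander_amp = 0.04,
      artifact = list(
        move_hands = list(fingers = 0.055, wrists = 0.070, chest = 0.010),
        move_feet  = list(fingers = 0.035, wrists = 0.045, chest = 0.015),
        move_chest = list(fingers = 0.030, wrists = 0.035, chest = 0.025)))
  structure(list(n_subjects = n_subjects, fs = fs,
                 rest1_duration = rest1_duration,
                 move_duration = move_duration,
                 rest2_duration = rest2_duration,
                 placements = placements, seed = as.integer(seed),
                 subject_spread = subject_spread, acq_params = acq_params),
            class = "cohort_spec")
}

#' Enumerate the recordings a cohort spec implies
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with one row per recording: subject_id, session,
#'   placement, condition, duration, fs and the derived seed.
#' @export
cohort_plan <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ids <- sprintf("S%02d", seq_len(spec$n_subjects))
  s1 <- expand.grid(subject_id = ids, session = 1L,
                    placement = spec$placements,
                    condition = ecg_conditions(),
                    stringsAsFactors = FALSE)
  s1$duration <- ifelse(s1$condition == "rest",
                        spec$rest1_duration, spec$move_duration)
  s2 <- expand.grid(subject_id = ids, session = 2L,
                    placement = spec$placements, condition = "rest",
                    stringsAsFactors = FALSE)
  s2$duration <- spec$rest2_duration
  plan <- rbind(s1, s2)
  plan <- plan[order(plan$subject_id, plan$session, plan$placement,
                     plan$condition), ]
  rownames(plan) <- NULL
  plan$fs <- spec$fs
  plan$seed <- mapply(function(su, se, pl, co)
    derive_seed(spec$seed, "rec", su, se, pl, co),
    plan$subject_id, plan$session, plan$placement, plan$condition)
  plan
}

#' Generate a labeled synthetic cohort
#'
#' Samples the subject templates, then synthesizes one recording per
#' (subject, session, placement, condition block) according to the
#' session plans. All randomness flows from the spec's master seed
#' through named substreams, so regeneration is byte-identical.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional directory; if given, recordings are written as
#'   CSV + JSON sidecars with a `manifest.csv` (see [write_recording()]).
#' @return list of class `ecg_cohort` with `recordings` (named list of
#'   [raw_ecg()]), `manifest` (the plan data.frame with a `key` column),
#'   `templates` and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  templates <- sample_subjects(spec$n_subjects,
                               derive_seed(spec$seed, "subjects"),
                               spread = spec$subject_spread)
  plan <- cohort_plan(spec)
  plan$key <- with(plan, paste(subject_id, session, placement, condition,
                               sep = "_"))
  recordings <- vector("list", nrow(plan))
  names(recordings) <- plan$key
  for (i in seq_len(nrow(plan))) {
    ctx <- acquisition_context(plan$session[i], plan$placement[i],
                               plan$condition[i], spec$acq_params)
    recordings[[i]] <- synthesize_recording(
      templates[[plan$subject_id[i]]], ctx, plan$duration[i],
      fs = spec$fs, seed = plan$seed[i], master_seed = spec$seed)
  }
  cohort <- structure(list(recordings = recordings, manifest = plan,
                           templates = templates, spec = spec,
                           cache = new.env(parent = emptyenv())),
                      class = "ecg_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.ecg_cohort <- function(x, ...) {
  cat(sprintf("<ecg_cohort> %d subjects, %d recordings (%.1f min of signal)\n",
              x$spec$n_subjects, length(x$recordings),
              sum(vapply(x$recordings, function(r)
                length(r$samples) / r$fs, numeric(1))) / 60))
  invisible(x)
}

#' Fetch one recording from a cohort
#'
#' @param cohort an `ecg_cohort`.
#' @param subject_id,session,placement,condition labels.
#' @return a [raw_ecg()].
#' @export
cohort_recording <- function(cohort, subject_id, session, placement,
                             condition = "rest") {
  key <- paste(subject_id, session, placement, condition, sep = "_")
  rec <- cohort$recordings[[key]]
  if (is.null(rec))
    stop(sprintf("no recording %s in cohort", key), call. = FALSE)
  rec
}
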