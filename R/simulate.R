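#' Simulator default parameters
#'
#' Magnitude and timing defaults for the synthetic-scenario generator.  The
#' values are engineering defaults chosen so that the confusability
#' structure seen in the field is reproduced — walking on uneven ground,
#' gravel, stairs and motorcycle bumps produce impact-like spikes that
#' overlap the stumble range, resting produces long low-variance stretches
#' confusable with coma — while the canonical accident morphologies stay
#' separable: a fall from height is a free-fall dip toward 0 g followed by
#' a 4–6 g impact and lying stillness; a stumble is a shallower 0.5 g dip,
#' a 2–3.5 g impact and a 2–3 s unsteady span followed by recovery.
#' They are configuration defaults, not measured values.
#'
#' All accelerations are in g (stationary magnitude about 1), durations in
#' seconds, angles in degrees.  Two-element vectors are uniform sampling
#' ranges.
#'
#' @return nested list of parameters, suitable for selective overriding via
#'   the `params` argument of the `simulate_*` functions.
#' @export
sim_params <- function() {
  list(
    dt = 0.1,
    axis_noise_sd = 0.01,
    rest = list(mean = 1.0, sd = 0.02, fidget_amp = c(1.1, 1.4),
                fidget_gap = c(4, 12), posture_pitch = 8),
    still_sd = 0.008,
    walk = list(amp = 0.3, freq = 2.0, noise_sd = 0.05),
    uneven = list(spike_amp = c(1.5, 2.5), spike_gap = c(0.5, 2)),
    gravel = list(spike_amp = c(1.5, 2.5), spike_gap = c(0.4, 1.5)),
    slope = list(spike_amp = c(1.5, 2.2), spike_gap = c(0.8, 2), pitch = 8),
    stairs = list(step_amp = c(1.8, 2.2), step_period = 0.7),
    motorcycle = list(vib_sd = 0.15, bump_amp = c(2.5, 3.5), bump_gap = c(1, 3)),
    fall = list(sway_dur = c(2, 4), sway_amp = 0.1, freefall_mean = 0.15,
                freefall_sd = 0.05, freefall_dur = c(0.3, 0.8),
                impact_amp = c(4, 6), impact_dur = c(0.1, 0.2),
                lying_pitch = 85),
    stumble = list(prewalk_dur = c(2, 3), span = c(2.2, 2.8), dip_mean = 0.5,
                   dip_sd = 0.05, dip_dur = c(0.2, 0.4),
                   impact_amp = c(2, 3.5), impact_dur = c(0.1, 0.2),
                   unsteady_amp = 0.4, tilt = 65),
    coma = list(pre_dur = 4, transient_dur = 1.5, sit_bump = c(1.2, 1.5),
                sit_pitch = 55, lying_pitch = 85, collapse_amp = c(2.5, 3.5),
                collapse_dur = 1.0),
    posture = list(drift_sd = 0.6, pull_slow = 0.6, pull_fast = 8),
    jitter = 1.0
  )
}

#' Scenario kinds and default durations
#'
#' The scenario catalogue mirrors the experimental tasks the detector is
#' meant to cover: walking on even/uneven/sloped surfaces, stairs, a gravel
#' trail, motorcycle riding over bumps, dropped falls from height,
#' directional stumbles, progressive and abrupt comas, and free seated rest.
#'
#' @return named numeric vector of default scenario durations in seconds.
#' @export
scenario_kinds <- function() {
  c(walk_even = 40, walk_uneven = 40, stairs = 40, slope = 30, gravel = 90,
    motorcycle = 50, rest = 120, fall_height = 10,
    stumble_fwd = 8, stumble_left = 8, stumble_right = 8, stumble_rear = 8,
    coma_progressive = 40, coma_abrupt = 40)
}

#' Default per-participant session plan
#'
#' One participant's session: the six ambulatory/riding tasks, two dropped
#' falls, four directional stumbles, one progressive and one abrupt coma,
#' and two minutes of free rest — 542 s, i.e. 5420 samples at 0.1 s,
#' matching the roughly 5500 samples per participant the windowing and
#' bookkeeping assume.  A 5-participant test split therefore carries 10
#' fall, 20 stumble and 10 coma target events.
#'
#' @return data frame with columns `kind` and `duration` (seconds).
#' @export
default_session_plan <- function() {
  kinds <- c("walk_even", "walk_uneven", "stairs", "slope", "gravel",
             "motorcycle", "fall_height", "stumble_fwd", "stumble_left",
             "coma_progressive", "fall_height", "stumble_right",
             "stumble_rear", "coma_abrupt", "rest")
  data.frame(kind = kinds, duration = unname(scenario_kinds()[kinds]))
}

merge_params <- function(base, override) {
  if (is.null(override) || !length(override)) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_params(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

# -- phase-level signal generators (consume the current RNG stream) --------

runif1 <- function(range) if (length(range) == 1L) range else stats::runif(1, range[1L], range[2L])

gen_still <- function(n, mean, sd) pmax(0, mean + stats::rnorm(n, 0, sd))

gen_walk <- function(n, p, dt) {
  phi <- stats::runif(1, 0, 2 * pi)
  tt <- (seq_len(n) - 1L) * dt
  pmax(0, 1 + p$amp * sin(2 * pi * p$freq * tt + phi) +
         stats::rnorm(n, 0, p$noise_sd))
}

add_spikes <- function(s, amp_range, gap_range, dt) {
  n <- length(s)
  t <- runif1(gap_range)
  while (t < n * dt) {
    i <- max(1L, min(n, round(t / dt) + 1L))
    amp <- runif1(amp_range)
    s[i] <- max(s[i], amp)
    if (i < n) s[i + 1L] <- max(s[i + 1L], 1 + (amp - 1) * 0.4)
    t <- t + runif1(gap_range)
  }
  s
}

add_steps <- function(s, amp_range, period, dt) {
  n <- length(s)
  idx <- round(seq(from = period / dt, to = n, by = period / dt))
  idx <- idx[idx >= 1 & idx <= n]
  s[idx] <- pmax(s[idx], vapply(idx, function(i) runif1(amp_range), numeric(1)))
  s
}

add_fidgets <- function(s, amp_range, gap_range, dt) {
  n <- length(s)
  t <- runif1(gap_range)
  while (t < n * dt) {
    i <- max(1L, min(n, round(t / dt) + 1L))
    amp <- runif1(amp_range)
    len <- min(n, i + 2L)
    s[i:len] <- pmax(s[i:len], amp - (0:(len - i)) * 0.1)
    t <- t + runif1(gap_range)
  }
  s
}

phase <- function(name, s, label, pitch_target = 0, roll_target = 0,
                  pull = NULL) {
  list(name = name, n = length(s), s = s, label = as.integer(label),
       pitch_target = pitch_target, roll_target = roll_target, pull = pull)
}

# Allocate samples: named fixed durations (seconds, possibly sampled from
# ranges beforehand) plus one filler that absorbs the remainder.
alloc_filler <- function(n_total, fixed_n, kind) {
  filler <- n_total - sum(fixed_n)
  if (filler < 1L) {
    stop_imufall(sprintf("duration too short for scenario '%s' (need > %.1f s)",
                         kind, sum(fixed_n) * 0.1),
                 "imufall_argument_error")
  }
  filler
}

build_phases <- function(kind, n_total, p) {
  dt <- p$dt
  lv <- status_levels()
  nsec <- function(range) max(1L, round(runif1(range) / dt))
  walk_p <- p$walk
  walk_p$amp <- walk_p$amp * p$jitter
  switch(
    kind,
    walk_even = list(phase("walk", gen_walk(n_total, walk_p, dt), lv["safe"])),
    walk_uneven = list(phase("walk_spiky",
                             add_spikes(gen_walk(n_total, walk_p, dt),
                                        p$uneven$spike_amp, p$uneven$spike_gap, dt),
                             lv["safe"])),
    gravel = list(phase("gravel",
                        add_spikes(gen_walk(n_total, walk_p, dt),
                                   p$gravel$spike_amp, p$gravel$spike_gap, dt),
                        lv["safe"])),
    slope = list(phase("slope",
                       add_spikes(gen_walk(n_total, walk_p, dt),
                                  p$slope$spike_amp, p$slope$spike_gap, dt),
                       lv["safe"], pitch_target = p$slope$pitch)),
    stairs = list(phase("stairs",
                        add_steps(gen_walk(n_total, walk_p, dt),
                                  p$stairs$step_amp, p$stairs$step_period, dt),
                        lv["safe"])),
    motorcycle = {
      s <- pmax(0, 1 + stats::rnorm(n_total, 0, p$motorcycle$vib_sd * p$jitter))
      s <- add_spikes(s, p$motorcycle$bump_amp, p$motorcycle$bump_gap, dt)
      list(phase("ride", s, lv["safe"]))
    },
    rest = list(phase("rest",
                      add_fidgets(gen_still(n_total, p$rest$mean, p$rest$sd),
                                  p$rest$fidget_amp, p$rest$fidget_gap, dt),
                      lv["safe"], pitch_target = p$rest$posture_pitch)),
    fall_height = {
      n_sway <- nsec(p$fall$sway_dur)
      n_ff <- nsec(p$fall$freefall_dur)
      n_imp <- nsec(p$fall$impact_dur)
      n_still <- alloc_filler(n_total, c(n_sway, n_ff, n_imp), kind)
      sway_p <- list(amp = p$fall$sway_amp, freq = 0.8, noise_sd = 0.02)
      list(
        phase("sway", gen_walk(n_sway, sway_p, dt), lv["safe"]),
        phase("freefall",
              gen_still(n_ff, p$fall$freefall_mean, p$fall$freefall_sd),
              lv["fall"], pitch_target = p$fall$lying_pitch,
              pull = p$posture$pull_fast),
        phase("impact", rep(runif1(p$fall$impact_amp), n_imp), lv["fall"],
              pitch_target = p$fall$lying_pitch, pull = p$posture$pull_fast),
        phase("post_impact_still", gen_still(n_still, 1, p$still_sd),
              lv["safe"], pitch_target = p$fall$lying_pitch,
              pull = p$posture$pull_fast))
    },
    coma_progressive = {
      n_pre <- max(1L, round(p$coma$pre_dur / dt))
      n_tr <- max(1L, round(p$coma$transient_dur / dt))
      n_still <- alloc_filler(n_total, c(n_pre, n_tr), kind)
      tr <- gen_still(n_tr, 1, 0.05)
      tr[ceiling(n_tr / 2)] <- runif1(p$coma$sit_bump)
      list(
        phase("rest", gen_still(n_pre, 1, p$rest$sd), lv["safe"],
              pitch_target = p$rest$posture_pitch),
        phase("sit_down", tr, lv["safe"], pitch_target = p$coma$sit_pitch,
              pull = p$posture$pull_fast),
        phase("still", gen_still(n_still, 1, p$still_sd), lv["coma"],
              pitch_target = p$coma$sit_pitch))
    },
    coma_abrupt = {
      n_pre <- max(1L, round(p$coma$pre_dur / dt))
      n_col <- max(2L, round(p$coma$collapse_dur / dt))
      n_still <- alloc_filler(n_total, c(n_pre, n_col), kind)
      n_dip <- max(1L, n_col %/% 2L)
      col <- c(gen_still(n_dip, 0.4, 0.05),
               rep(runif1(p$coma$collapse_amp), n_col - n_dip))
      list(
        phase("stand", gen_still(n_pre, 1, p$rest$sd), lv["safe"]),
        phase("collapse", col, lv["coma"], pitch_target = p$coma$lying_pitch,
              pull = p$posture$pull_fast),
        phase("still", gen_still(n_still, 1, p$still_sd), lv["coma"],
              pitch_target = p$coma$lying_pitch))
    },
    stop_imufall(sprintf("unknown scenario kind '%s'", kind),
                 "imufall_argument_error"))
}

build_stumble_phases <- function(direction, n_total, p) {
  dt <- p$dt
  lv <- status_levels()
  nsec <- function(range) max(1L, round(runif1(range) / dt))
  n_pre <- nsec(p$stumble$prewalk_dur)
  span <- runif1(p$stumble$span)          # total stumble-labelled span, 2-3 s
  n_dip <- nsec(p$stumble$dip_dur)
  n_imp <- nsec(p$stumble$impact_dur)
  n_uns <- max(1L, round(span / dt) - n_dip - n_imp)
  n_rec <- alloc_filler(n_total, c(n_pre, n_dip, n_imp, n_uns),
                        paste0("stumble_", direction))
  tgt <- switch(direction,
                fwd = c(p$stumble$tilt, 0),
                rear = c(-p$stumble$tilt, 0),
                left = c(0, -(p$stumble$tilt + 5)),
                right = c(0, p$stumble$tilt + 5),
                stop_imufall(sprintf("unknown stumble direction '%s'", direction),
                             "imufall_argument_error"))
  walk_p <- p$walk
  walk_p$amp <- walk_p$amp * p$jitter
  uns <- pmax(0, 1 + p$stumble$unsteady_amp *
                sin(2 * pi * 3 * (seq_len(n_uns) - 1L) * dt) +
                stats::rnorm(n_uns, 0, 0.1))
  list(
    phase("prewalk", gen_walk(n_pre, walk_p, dt), lv["safe"]),
    phase("dip", gen_still(n_dip, p$stumble$dip_mean, p$stumble$dip_sd),
          lv["stumble"], pitch_target = tgt[1L], roll_target = tgt[2L],
          pull = p$posture$pull_fast),
    phase("impact", rep(runif1(p$stumble$impact_amp), n_imp), lv["stumble"],
          pitch_target = tgt[1L], roll_target = tgt[2L],
          pull = p$posture$pull_fast),
    phase("unsteady", uns, lv["stumble"], pitch_target = tgt[1L],
          roll_target = tgt[2L]),
    phase("recover", gen_walk(n_rec, walk_p, dt), lv["safe"],
          pull = p$posture$pull_fast))
}

# Assemble phases into a recording: orientation follows a per-phase
# Ornstein-Uhlenbeck drift toward the phase's target posture, and the
# acceleration vector points along body-frame gravity with magnitude equal
# to the phase's SVMa series.
assemble_recording <- function(phases, scenario, p, participant_id) {
  dt <- p$dt
  n <- sum(vapply(phases, `[[`, integer(1), "n"))
  s <- unlist(lapply(phases, `[[`, "s"), use.names = FALSE)
  label <- rep(vapply(phases, `[[`, integer(1), "label"),
               vapply(phases, `[[`, integer(1), "n"))
  tgt_p <- rep(vapply(phases, `[[`, numeric(1), "pitch_target"),
               vapply(phases, `[[`, integer(1), "n"))
  tgt_r <- rep(vapply(phases, `[[`, numeric(1), "roll_target"),
               vapply(phases, `[[`, integer(1), "n"))
  pull <- rep(vapply(phases, function(ph) ph$pull %||% p$posture$pull_slow,
                     numeric(1)),
              vapply(phases, `[[`, integer(1), "n"))
  pitch <- roll <- numeric(n)
  pitch[1L] <- stats::rnorm(1, tgt_p[1L], 1)
  roll[1L] <- stats::rnorm(1, tgt_r[1L], 1)
  sdp <- p$posture$drift_sd * sqrt(dt)
  ep <- stats::rnorm(n, 0, sdp)
  er <- stats::rnorm(n, 0, sdp)
  for (i in seq_len(n)[-1L]) {
    pitch[i] <- pitch[i - 1L] + pull[i] * (tgt_p[i] - pitch[i - 1L]) * dt + ep[i]
    roll[i] <- roll[i - 1L] + pull[i] * (tgt_r[i] - roll[i - 1L]) * dt + er[i]
  }
  pitch <- pmin(90, pmax(-90, pitch))
  roll <- pmin(180, pmax(-180, roll))
  pr <- pitch * pi / 180
  rr <- roll * pi / 180
  nz <- p$axis_noise_sd
  ax <- s * (-sin(pr)) + if (nz > 0) stats::rnorm(n, 0, nz) else 0
  ay <- s * (cos(pr) * sin(rr)) + if (nz > 0) stats::rnorm(n, 0, nz) else 0
  az <- s * (cos(pr) * cos(rr)) + if (nz > 0) stats::rnorm(n, 0, nz) else 0
  ends <- cumsum(vapply(phases, `[[`, integer(1), "n"))
  starts <- c(0L, ends[-length(ends)])
  plan <- data.frame(
    scenario = scenario,
    phase = vapply(phases, `[[`, character(1), "name"),
    start = starts * dt,
    end = ends * dt,
    label = vapply(phases, `[[`, integer(1), "label"))
  imu_recording(t = (seq_len(n) - 1L) * dt, ax = ax, ay = ay, az = az,
                pitch = pitch, roll = roll, label = label,
                participant_id = participant_id, sampling_interval = dt,
                phase_plan = plan)
}

#' Simulate one labelled scenario
#'
#' Generates a synthetic IMU recording for a single scenario kind, together
#' with its machine-readable phase plan (attached as the `phase_plan`
#' attribute; see [phase_plan()]), the ground truth of phase boundaries and
#' per-phase labels against which detectors and tests are checked.
#' Identical `(kind, duration, params, seed)` yield bit-identical
#' recordings.
#'
#' @param kind scenario kind; one of `names(scenario_kinds())`, or
#'   `"stumble_<dir>"` with dir in fwd/left/right/rear.
#' @param duration scenario length in seconds; defaults to the catalogue
#'   value of [scenario_kinds()].
#' @param params nested list of overrides merged into [sim_params()].
#' @param seed integer RNG seed.
#' @param participant_id id stored on the recording.
#' @return an [imu_recording()] with a phase-plan attribute.
#' @examples
#' r <- simulate_scenario("fall_height", seed = 1)
#' phase_plan(r)
#' @export
simulate_scenario <- function(kind, duration = NULL, params = list(),
                              seed = 1, participant_id = "P01") {
  kinds <- scenario_kinds()
  if (!kind %in% names(kinds)) {
    stop_imufall(sprintf("unknown scenario kind '%s'", kind),
                 "imufall_argument_error")
  }
  p <- merge_params(sim_params(), params)
  duration <- duration %||% unname(kinds[kind])
  n_total <- max(1L, round(duration / p$dt))
  with_seed(seed, {
    phases <- if (startsWith(kind, "stumble_")) {
      build_stumble_phases(sub("^stumble_", "", kind), n_total, p)
    } else {
      build_phases(kind, n_total, p)
    }
    assemble_recording(phases, kind, p, participant_id)
  })
}

#' @rdname simulate_scenario
#' @export
simulate_fall <- function(params = list(), seed = 1, duration = NULL,
                          participant_id = "P01") {
  simulate_scenario("fall_height", duration = duration, params = params,
                    seed = seed, participant_id = participant_id)
}

#' @rdname simulate_scenario
#' @param direction stumble direction: `"fwd"`, `"left"`, `"right"` or
#'   `"rear"`.
#' @export
simulate_stumble <- function(direction = c("fwd", "left", "right", "rear"),
                             params = list(), seed = 1, duration = NULL,
                             participant_id = "P01") {
  direction <- match.arg(direction)
  simulate_scenario(paste0("stumble_", direction), duration = duration,
                    params = params, seed = seed,
                    participant_id = participant_id)
}

#' Simulate a cohort of participants
#'
#' Generates one recording per participant by concatenating the session
#' plan, with per-participant parameter jitter (walking amplitude and
#' vibration level multipliers) so participants differ.  The default plan
#' yields about 5500 samples per participant.  Per-participant seeds are
#' derived from the master seed, so the same `(n_participants, seed, plan)`
#' reproduce the cohort exactly and participant `i` is stable.
#'
#' @param n_participants number of participants (>= 1).
#' @param seed master integer seed.
#' @param plan data frame with columns `kind` and `duration` (seconds);
#'   defaults to [default_session_plan()].
#' @param params nested overrides merged into [sim_params()].
#' @return an [imu_dataset()]; each recording carries a concatenated phase
#'   plan with a `scenario_index` column.
#' @examples
#' ds <- simulate_cohort(2, seed = 1,
#'                       plan = data.frame(kind = "rest", duration = 2))
#' length(ds)
#' @export
simulate_cohort <- function(n_participants, seed = 1,
                            plan = default_session_plan(), params = list()) {
  if (n_participants < 1) {
    stop_imufall("n_participants must be >= 1", "imufall_argument_error")
  }
  if (is.null(plan) || nrow(plan) == 0L) {
    stop_imufall("session plan must contain at least one scenario",
                 "imufall_argument_error")
  }
  p_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                        n_participants))
  recs <- lapply(seq_len(n_participants), function(i) {
    draws <- with_seed(p_seeds[i], list(
      jitter = stats::runif(1, 0.9, 1.1),
      scen_seeds = sample.int(.Machine$integer.max - 1L, nrow(plan))))
    pid <- sprintf("P%02d", i)
    parts <- lapply(seq_len(nrow(plan)), function(k) {
      simulate_scenario(plan$kind[k], duration = plan$duration[k],
                        params = merge_params(params,
                                              list(jitter = draws$jitter)),
                        seed = draws$scen_seeds[k], participant_id = pid)
    })
    concat_recordings(parts, pid)
  })
  imu_dataset(recs, sampling_interval = merge_params(sim_params(), params)$dt)
}

concat_recordings <- function(parts, participant_id) {
  dt <- attr(parts[[1L]], "sampling_interval")
  offs <- 0
  plans <- list()
  dfs <- list()
  for (k in seq_along(parts)) {
    r <- parts[[k]]
    df <- as.data.frame(r)
    df$t <- df$t + offs
    pl <- phase_plan(r)
    pl$start <- pl$start + offs
    pl$end <- pl$end + offs
    pl$scenario_index <- k
    plans[[k]] <- pl
    dfs[[k]] <- df
    offs <- offs + nrow(r) * dt
  }
  all <- do.call(rbind, dfs)
  all$t <- (seq_len(nrow(all)) - 1L) * dt   # exact grid, no accumulation error
  imu_recording(t = all$t, ax = all$ax, ay = all$ay, az = all$az,
                pitch = all$pitch, roll = all$roll, label = all$label,
                participant_id = participant_id, sampling_interval = dt,
                phase_plan = do.call(rbind, plans))
}

#' Read or write a phase-plan sidecar
#'
#' The phase plan is the simulator's ground truth (phase boundaries and
#' labels).  It travels beside a sensor-log CSV as a structured JSON file;
#' it is not part of the CSV interchange format itself.
#'
#' @param recording an [imu_recording()] carrying a phase plan.
#' @param path sidecar file path.
#' @return `write_phase_plan()` invisibly returns `path`;
#'   `read_phase_plan()` returns the plan data frame.
#' @export
write_phase_plan <- function(recording, path) {
  plan <- phase_plan(recording)
  if (is.null(plan)) {
    stop_imufall("recording carries no phase plan", "imufall_argument_error")
  }
  jsonlite::write_json(plan, path, digits = NA)
  invisible(path)
}

#' @rdname write_phase_plan
#' @export
read_phase_plan <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
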