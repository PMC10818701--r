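# Shared fixtures, all generated in code.

# A flat, upright recording at `svma_g` with optional per-sample overrides.
flat_recording <- function(n, svma_g = 1, pitch = 0, roll = 0, label = 0L,
                           participant_id = "T01") {
  pr <- pitch * pi / 180
  rr <- roll * pi / 180
  imu_recording(t = (seq_len(n) - 1L) * 0.1,
                ax = svma_g * (-sin(pr)),
                ay = svma_g * cos(pr) * sin(rr),
                az = svma_g * cos(pr) * cos(rr),
                pitch = pitch, roll = roll, label = label,
                participant_id = participant_id)
}

# Noise-free archetype windows for the four classes: distinct, separable
# per-channel patterns built directly as an imu_windows object.
archetype_windows <- function(n_per_class = 50, noise = 0, seed = 1) {
  set.seed(seed)
  len <- 20L
  chans <- default_channels()
  shapes <- list(
    safe = list(s = rep(1, len), pitch = rep(0, len)),
    fall = list(s = c(rep(1, 6), rep(0.15, 4), rep(5, 2), rep(1, 8)),
                pitch = c(rep(0, 10), seq(10, 85, length.out = 10))),
    stumble = list(s = c(rep(1, 8), rep(0.5, 3), rep(2.5, 2), rep(1.2, 7)),
                   pitch = c(rep(0, 11), rep(40, 9))),
    coma = list(s = rep(1, len), pitch = rep(85, len)))
  n <- 4L * n_per_class
  x <- array(0, c(n, len, length(chans)),
             dimnames = list(NULL, NULL, chans))
  lab <- integer(n)
  i <- 0L
  for (k in 0:3) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      sh <- shapes[[k + 1L]]
      s <- sh$s + if (noise > 0) stats::rnorm(len, 0, noise) else 0
      pr <- sh$pitch * pi / 180
      ax <- s * (-sin(pr))
      az <- s * cos(pr)
      sv <- sqrt(ax^2 + az^2)
      x[i, , "ax"] <- ax
      x[i, , "az"] <- az
      x[i, , "pitch"] <- sh$pitch
      x[i, , "svma"] <- sv
      x[i, , "delta_svma"] <- c(0, diff(sv))
      x[i, , "svmo"] <- abs(sh$pitch)
      lab[i] <- k
    }
  }
  structure(list(x = x, label = lab, t_label = seq_len(n) * 2,
                 participant = rep("A", n), start = seq_len(n),
                 window_len = len, stride = 1L, label_pos = 10L,
                 channels = chans),
            class = "imu_windows")
}

# Handmade four-class recording for threshold calibration tests: rest,
# 3 g impact spikes (stumble), a full fall signature, lying stillness (coma).
calibration_recording <- function() {
  seg_rest <- flat_recording(200)                      # 20 s at 1 g upright
  n <- 200L
  s <- rep(1, n); lab <- rep(0L, n)
  spike_at <- seq(20, 180, by = 20)
  s[spike_at] <- 3; lab[spike_at] <- 2L                # stumble impacts
  seg_spike <- imu_recording(t = (seq_len(n) - 1L) * 0.1, ax = 0, ay = 0,
                             az = s, pitch = 0, roll = 0, label = lab)
  nf <- 60L                                            # fall: dip then 5 g
  sf <- c(rep(1, 20), rep(0.1, 6), rep(5, 2), rep(1, 32))
  labf <- c(rep(0L, 20), rep(1L, 8), rep(0L, 32))
  pitchf <- c(rep(0, 20), seq(0, 85, length.out = 10), rep(85, 30))
  prf <- pitchf * pi / 180
  seg_fall <- imu_recording(t = (seq_len(nf) - 1L) * 0.1,
                            ax = sf * (-sin(prf)), ay = 0,
                            az = sf * cos(prf), pitch = pitchf, roll = 0,
                            label = labf)
  seg_coma <- flat_recording(200, pitch = 85, label = 3L)  # 20 s lying still
  segs <- list(seg_rest, seg_spike, seg_fall, seg_coma)
  all <- do.call(rbind, lapply(segs, as.data.frame))
  imu_recording(t = (seq_len(nrow(all)) - 1L) * 0.1, ax = all$ax,
                ay = all$ay, az = all$az, pitch = all$pitch, roll = all$roll,
                label = all$label, participant_id = "CAL")
}
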