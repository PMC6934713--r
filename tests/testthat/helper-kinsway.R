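# Shared fixtures, all built in code.

# A small, fast simulation configuration for pipeline-level tests.
toy_sim_config <- function(seed = 1L, ...) {
  simulation_config(n_asd = 4, n_td = 4, sessions = 2L, n_poses = 3,
                    frames_range = c(800L, 1200L), rng_seed = seed, ...)
}

# A single-participant profile row, for direct simulate_recording tests.
toy_profile <- function(group = "ASD", age = 12, severity = 1,
                        id = "X001") {
  data.frame(participant_id = id, group = group, age_years = age,
             latent_severity = severity, stringsAsFactors = FALSE)
}

# A random valid recording with optional missing cells.
toy_recording <- function(T = 50, seed = 1, p_na = 0,
                          participant = "P1", session = 2, pose = 1) {
  set.seed(seed)
  m <- matrix(rnorm(T * 62), T, 62)
  if (p_na > 0) m[runif(T * 62) < p_na] <- NA
  if (p_na > 0) m[1, ] <- rnorm(62) # keep first row valid
  recording(m, participant, session, pose)
}

# Hand-built feature set: n_per participants per group, each contributing
# n_vec vectors per pose. Feature `signal_col` is shifted by `delta` for the
# ASD group; everything else is standard normal noise.
toy_features <- function(n_per = 6, n_vec = 4, poses = 1:2, p = 10,
                         signal_col = 1, delta = 3, seed = 1) {
  set.seed(seed)
  ids <- c(sprintf("A%02d", seq_len(n_per)), sprintf("T%02d", seq_len(n_per)))
  group <- rep(c("ASD", "TD"), each = n_per)
  meta <- expand.grid(participant_id = ids, pose_id = poses,
                      vec = seq_len(n_vec), stringsAsFactors = FALSE)
  meta <- meta[order(meta$participant_id, meta$pose_id), ]
  X <- matrix(rnorm(nrow(meta) * p), nrow(meta), p)
  colnames(X) <- sprintf("f%02d", seq_len(p))
  is_asd <- group[match(meta$participant_id, ids)] == "ASD"
  X[is_asd, signal_col] <- X[is_asd, signal_col] + delta
  structure(list(features = X,
                 meta = data.frame(participant_id = meta$participant_id,
                                   session = 2L, pose_id = meta$pose_id,
                                   stringsAsFactors = FALSE),
                 participants = data.frame(participant_id = ids,
                                           group = group,
                                           stringsAsFactors = FALSE)),
            class = "movement_features")
}

# Two-frame recording whose per-channel population variances are exactly
# `vars` (channel j takes values c(-s, s), s = sqrt(vars[j])).
recording_with_variances <- function(vars, participant, pose = 1,
                                     session = 2) {
  s <- sqrt(vars)
  recording(rbind(-s, s), participant, session, pose)
}
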