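# Shared fixtures: small synthetic streams built in code.

limb_stream <- function(n_reps = 5, amplitude = 2, noise_sd = 0, seed = 7,
                        ...) {
  generate_session(
    "bobath_handshake",
    synth_params(n_reps = n_reps, amplitude = amplitude,
                 noise_sd = noise_sd, seed = seed, ...))
}

hand_stream <- function(n_reps = 4, amplitude = 45, noise_sd = 0,
                        seed = 11, ...) {
  generate_session(
    "wrist_flex_ext",
    synth_params(n_reps = n_reps, amplitude = amplitude,
                 noise_sd = noise_sd, seed = seed, ...))
}

# Random rotation matrix (uniform via QR of a Gaussian matrix).
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qrd)
  d <- sign(diag(qr.R(qrd)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Filtered primary channel sliced to the ground-truth repetition windows
# (0-based half-open indices -> 1-based R slices).
gt_windows <- function(stream, filtered = TRUE) {
  x <- primary_channel(stream)
  if (filtered) x <- sliding_filter(x, 5)
  lapply(seq_len(nrow(stream$ground_truth)), function(i) {
    g <- stream$ground_truth[i, ]
    x[(g$start_index + 1):g$end_index]
  })
}
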