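# Shared fixtures: small, fast synthetic inputs built in code.

# Small noiseless local-wave world (64 px, 30 frames) for unit tests;
# acceptance tests use the full-size stated world.
small_local_params <- function(...) {
  args <- list(noise_sd = 0, n_frames = 30, image_size = 64, pixel_size = 4)
  over <- list(...)
  args[names(over)] <- over
  do.call(local_wave_params, args)
}

# A profile set built directly from a matrix (distances x times), bypassing
# image scanning, for tracker unit tests.
make_profile_set <- function(intensity, distances = NULL, times = NULL,
                             pixel_size = 1) {
  distances <- distances %||% ((seq_len(nrow(intensity)) - 1) * pixel_size)
  times <- times %||% (seq_len(ncol(intensity)) - 1)
  structure(list(distances = distances, times = times,
                 intensity = intensity,
                 n_lines_used = rep(1L, nrow(intensity)),
                 pixel_size = pixel_size),
            class = "profile_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian bump profile: baseline + height * exp(-(d - center)^2 / (2 s^2))
gauss_profile <- function(d, center, height, s, baseline = 0) {
  baseline + height * exp(-(d - center)^2 / (2 * s^2))
}
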