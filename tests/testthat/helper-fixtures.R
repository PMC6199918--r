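# Shared fixtures: everything is generated in code at test time.

# amplitude of a sinusoid measured away from the edges
mid_amplitude <- function(x, frac = 0.25) {
    n <- length(x)
    mid <- x[seq.int(floor(n * frac), ceiling(n * (1 - frac)))]
    (max(mid) - min(mid)) / 2
}

# analytic two-pass (zero-phase) Butterworth amplitude gain at frequency f
butter2pass_gain <- function(f, cutoff, order, mode = c("high", "low")) {
    mode <- match.arg(mode)
    r <- if (mode == "high") (f / cutoff)^(2 * order) / (1 + (f / cutoff)^(2 * order))
         else 1 / (1 + (f / cutoff)^(2 * order))
    r   # |H|^2: power gain per pass = amplitude gain for forward-backward
}

# brute-force reference for the causal front-padded convolution
conv_brute <- function(x_mat, taps) {
    n <- nrow(x_mat); T_bins <- ncol(x_mat); K <- length(taps)
    out <- matrix(0, n, T_bins)
    for (t in seq_len(T_bins)) for (k in seq_len(K)) {
        s <- t - k + 1L
        if (s >= 1L) out[, t] <- out[, t] + taps[k] * x_mat[, s]
    }
    out
}

# small single-path session with planted Gamma dynamics (see synth_config)
tiny_path_session <- function(trials = 10L, n_neural = 8L, seed = 1L,
                              t0 = 0.020, tau = 0.030) {
    pg <- data.frame(latent = 1L, emg = 1L, alpha = 1, beta = 1 / tau, t0 = t0)
    cfg <- synth_config(n_sessions = 1L, trials_per_session = trials,
                        n_neural = n_neural, n_emg = 1L, n_latents = 1L,
                        planted_gamma = pg, noise_sd_neural = 0,
                        noise_sd_emg = 0, seed = seed)
    synth_generate(cfg)
}

# build an arbitrary-parameter model without touching the RNG
manual_model <- function(spec, session_ids, params) {
    structure(list(spec = spec, session_ids = session_ids, params = params),
              class = "gammanet_model")
}
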