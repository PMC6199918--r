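#' Preprocessing configuration
#'
#' Parameters of the envelope extraction chain applied to raw recordings:
#' a zero-phase high-pass Butterworth on neural channels (movement-artifact
#' removal), Gaussian RMS envelopes on all channels, a zero-phase low-pass on
#' EMG envelopes, and downsampling to the analysis rate.
#'
#' @param hp_cutoff neural high-pass cutoff, Hz.
#' @param hp_order high-pass Butterworth order.
#' @param envelope_sigma Gaussian envelope kernel sigma, seconds.
#' @param emg_lp_cutoff EMG low-pass cutoff, Hz (1-5 Hz in practice).
#' @param lp_order low-pass Butterworth order.
#' @param out_rate output sampling rate after downsampling, Hz.
#'
#' @return A list of class `prep_config`.
#' @export
prep_config <- function(hp_cutoff = 20, hp_order = 3, envelope_sigma = 0.010,
                        emg_lp_cutoff = 5, lp_order = 3, out_rate = 100) {
    if (envelope_sigma <= 0) stop("`envelope_sigma` must be > 0")
    if (emg_lp_cutoff <= 0 || emg_lp_cutoff >= out_rate / 2)
        stop("`emg_lp_cutoff` must satisfy 0 < emg_lp_cutoff < out_rate/2")
    if (out_rate <= 0) stop("`out_rate` must be > 0")
    structure(list(hp_cutoff = hp_cutoff, hp_order = hp_order,
                   envelope_sigma = envelope_sigma,
                   emg_lp_cutoff = emg_lp_cutoff, lp_order = lp_order,
                   out_rate = out_rate),
              class = "prep_config")
}

# Odd-reflection padding used to suppress filter edge transients on short trials.
reflect_pad <- function(x, n_pad) {
    n <- length(x)
    n_pad <- min(n_pad, n - 1L)
    head_ext <- 2 * x[1] - x[seq(n_pad + 1L, 2L)]
    tail_ext <- 2 * x[n] - x[seq(n - 1L, n - n_pad)]
    c(head_ext, x, tail_ext)
}

#' Zero-phase Butterworth filter
#'
#' Applies an order-`order` Butterworth filter forward and backward
#' (zero net phase shift; the squared magnitude response), with odd-reflection
#' padding at both ends to suppress edge transients. The pad must outlast the
#' filter's impulse response, which scales with the cutoff period, so its
#' length is `max(3 * (order + 1), 8 * fs / cutoff)` samples (capped at the
#' signal length minus one). At the cutoff frequency the two-pass amplitude
#' gain is 0.5 (half power per pass).
#'
#' @param x numeric vector, one channel.
#' @param fs sampling rate, Hz.
#' @param cutoff cutoff frequency, Hz (must be below Nyquist).
#' @param order filter order (default 3).
#' @param mode `"high"` or `"low"`.
#' @return Filtered vector, same length as `x`.
#' @examples
#' fs <- 1000; t <- seq(0, 1, by = 1 / fs)
#' y <- zero_phase_butterworth(sin(2 * pi * 50 * t) + 1, fs, 20, 3, "high")
#' @export
zero_phase_butterworth <- function(x, fs, cutoff, order = 3, mode = c("high", "low")) {
    mode <- match.arg(mode)
    if (!all(is.finite(x))) stop("input contains non-finite values")
    if (cutoff <= 0 || cutoff >= fs / 2)
        stop(sprintf("cutoff (%g Hz) must be in (0, Nyquist = %g Hz)", cutoff, fs / 2))
    ba <- signal::butter(order, cutoff / (fs / 2), type = mode)
    n_pad <- max(3L * (order + 1L), ceiling(8 * fs / cutoff))
    n_pad <- min(n_pad, length(x) - 1L)
    xp <- reflect_pad(x, n_pad)
    y <- signal::filter(ba, xp)
    y <- rev(signal::filter(ba, rev(y)))
    y <- as.numeric(y)
    y[seq(n_pad + 1L, n_pad + length(x))]
}

gaussian_kernel <- function(sigma_s, fs) {
    half <- max(1L, ceiling(4 * sigma_s * fs))   # truncated at +/- 4 sigma
    t <- (-half:half) / fs
    k <- exp(-t^2 / (2 * sigma_s^2))
    k / sum(k)                                   # renormalized to unit sum
}

#' RMS envelope via Gaussian smoothing
#'
#' The envelope is `sqrt(g * x^2)` where `g` is a unit-sum Gaussian kernel
#' (sigma in seconds, truncated at four sigma): the running RMS power of the
#' signal. Edges are handled with odd-free reflection padding of half the
#' kernel length.
#'
#' @param x numeric vector, one channel (finite).
#' @param fs sampling rate, Hz.
#' @param sigma Gaussian sigma, seconds (default 0.010).
#' @return Nonnegative envelope, same length as `x`.
#' @export
rms_envelope <- function(x, fs, sigma = 0.010) {
    if (sigma <= 0) stop("`sigma` must be > 0")
    if (!all(is.finite(x))) stop("input contains non-finite values")
    k <- gaussian_kernel(sigma, fs)
    half <- (length(k) - 1L) %/% 2L
    x2 <- x^2
    n <- length(x2)
    # even (mirror) extension, folded as often as needed for wide kernels
    idx <- seq.int(1L - half, n + half)
    if (n == 1L) idx[] <- 1L
    else {
        period <- 2L * n - 2L
        q <- (idx - 1L) %% period
        idx <- ifelse(q < n, q + 1L, 2L * n - 1L - q)
    }
    sm <- stats::filter(x2[idx], k, sides = 2)
    sm <- as.numeric(sm)[half + seq_len(n)]
    sqrt(pmax(sm, 0))
}

#' Half-power frequency of the Gaussian envelope kernel
#'
#' For a Gaussian frequency response `exp(-f^2 / (2 sigma_f^2))`, returns the
#' frequency at which the power response falls to one half of its DC value:
#' `sigma_f * sqrt(2 * log(2))`.
#'
#' @param sigma_f frequency-domain sigma, Hz.
#' @return Half-power frequency, Hz.
#' @examples
#' halfpower_frequency(100 / pi)  # ~ 37.5 Hz
#' @export
halfpower_frequency <- function(sigma_f) {
    if (!is.numeric(sigma_f) || any(sigma_f <= 0)) stop("`sigma_f` must be > 0")
    sigma_f * sqrt(2 * log(2))
}

#' Zero-phase low-pass for EMG envelope targets
#'
#' Thin wrapper over [zero_phase_butterworth()] in low-pass mode; applied to
#' EMG envelopes before they become regression targets (and to neural
#' envelopes only when they feed the pointwise linear control decoder).
#'
#' @inheritParams zero_phase_butterworth
#' @export
lowpass_target <- function(x, fs, cutoff = 5, order = 3) {
    zero_phase_butterworth(x, fs, cutoff, order, mode = "low")
}

#' Downsample an envelope by integer stride
#'
#' Keeps every `(fs_in / fs_out)`-th sample starting from the first. The
#' envelope is assumed already band-limited by the Gaussian envelope kernel
#' (and, for EMG, the low-pass), so no additional anti-alias stage is applied.
#'
#' @param x numeric vector.
#' @param fs_in input rate, Hz.
#' @param fs_out output rate, Hz; `fs_in / fs_out` must be an integer.
#' @return Decimated vector. A 4-s trial at `fs_out = 100` yields 400 bins.
#' @export
downsample <- function(x, fs_in, fs_out) {
    ratio <- fs_in / fs_out
    if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1)
        stop(sprintf("fs_in (%g) must be an integer multiple of fs_out (%g)", fs_in, fs_out))
    x[seq(1L, length(x), by = round(ratio))]
}

#' Preprocess one raw trial
#'
#' Applies the full chain to a raw multichannel trial: neural channels are
#' high-pass filtered, enveloped and downsampled; EMG channels are enveloped,
#' low-pass filtered and downsampled.
#'
#' @param samples numeric matrix, time x channels, raw units.
#' @param fs sampling rate of `samples`, Hz.
#' @param neural_cols,emg_cols column indices of neural and EMG channels.
#' @param cfg a [prep_config()].
#' @return List with elements `neural` and `emg`, each bins x channels.
#' @export
preprocess_trial <- function(samples, fs, neural_cols, emg_cols, cfg = prep_config()) {
    stopifnot(is.matrix(samples))
    if (!all(is.finite(samples))) stop("raw trial contains non-finite values")
    prep_one <- function(col, is_emg) {
        x <- samples[, col]
        if (!is_emg) x <- zero_phase_butterworth(x, fs, cfg$hp_cutoff, cfg$hp_order, "high")
        env <- rms_envelope(x, fs, cfg$envelope_sigma)
        if (is_emg) env <- lowpass_target(env, fs, cfg$emg_lp_cutoff, cfg$lp_order)
        downsample(env, fs, cfg$out_rate)
    }
    list(neural = vapply(neural_cols, prep_one, numeric(length(downsample(samples[, 1], fs, cfg$out_rate))), is_emg = FALSE),
         emg    = vapply(emg_cols,    prep_one, numeric(length(downsample(samples[, 1], fs, cfg$out_rate))), is_emg = TRUE))
}

#' Assemble preprocessed trials into session tensors
#'
#' Stacks per-trial envelope matrices into a pair of aligned [trial_tensor()]s
#' (neural and EMG) sharing trial order and bin width.
#'
#' @param trials list of per-trial lists with elements `neural` and `emg`
#'   (bins x channels matrices, as from [preprocess_trial()]).
#' @param bin_width bin width in seconds.
#' @param session_id session label.
#' @param exclude optional integer vector of trial indices to drop (e.g.
#'   manually rejected artifact-contaminated trials).
#' @return List with `neural` and `emg` trial tensors.
#' @export
assemble_session <- function(trials, bin_width = 0.01, session_id = NULL, exclude = NULL) {
    if (length(trials) == 0L) stop("empty trial list")
    if (!is.null(exclude)) trials <- trials[-exclude]
    if (length(trials) == 0L) stop("all trials excluded")
    bins <- vapply(trials, function(tr) nrow(tr$neural), integer(1))
    if (length(unique(bins)) != 1L)
        stop(sprintf("ragged trials: trial %d has %d bins, expected %d",
                     which(bins != bins[1])[1], bins[bins != bins[1]][1], bins[1]))
    ebins <- vapply(trials, function(tr) nrow(tr$emg), integer(1))
    if (any(ebins != bins[1]))
        stop(sprintf("ragged trials: trial %d EMG has %d bins, expected %d",
                     which(ebins != bins[1])[1], ebins[ebins != bins[1]][1], bins[1]))
    stack <- function(field) {
        d3 <- ncol(trials[[1]][[field]])
        out <- array(0, c(length(trials), bins[1], d3))
        for (i in seq_along(trials)) {
            m <- trials[[i]][[field]]
            if (ncol(m) != d3) stop(sprintf("trial %d has %d %s channels, expected %d",
                                            i, ncol(m), field, d3))
            out[i, , ] <- m
        }
        out
    }
    neur <- stack("neural"); emg <- stack("emg")
    # zero-phase low-pass of a nonnegative envelope can undershoot slightly
    emg[emg < 0] <- 0
    neur[neur < 0] <- 0
    list(neural = trial_tensor(neur, bin_width, colnames(trials[[1]]$neural), session_id),
         emg    = trial_tensor(emg,  bin_width, colnames(trials[[1]]$emg),    session_id))
}
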