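#' Deterministic trial split by sequential groups of five
#'
#' Trials are taken in recording order and divided into sequential groups of
#' five; within each group the first three go to the Training set, the fourth
#' to Cross-Validation Set A and the fifth to Set B. There is no
#' randomization: the same trial numbers always land in the same sets. A
#' trailing partial group follows the same pattern truncated (its first up to
#' three trials train, a fourth goes to A). For `n` divisible by 5 the
#' proportions are exactly 60 / 20 / 20 percent.
#'
#' @param n_trials number of trials in the session (>= 5).
#' @return A list of class `split_assignment` with disjoint 1-based index
#'   vectors `train`, `a`, `b`.
#' @examples
#' split_trials(10)  # train 1,2,3,6,7,8; A 4,9; B 5,10
#' @export
split_trials <- function(n_trials) {
    if (n_trials < 5L) stop("`n_trials` must be >= 5 to form at least one group of five")
    pos <- ((seq_len(n_trials) - 1L) %% 5L) + 1L
    structure(list(train = which(pos <= 3L), a = which(pos == 4L), b = which(pos == 5L)),
              class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
    cat(sprintf("<split_assignment: %d train / %d A / %d B>\n",
                length(x$train), length(x$a), length(x$b)))
    invisible(x)
}

#' Run the full two-fold restart validation protocol
#'
#' Convenience wrapper: fits [gammanet()] in one of three modes and returns
#' the fitted object, whose `$score` is the session score (mean of the
#' held-out `A_max(B)` and `B_max(A)` R-squared values).
#'
#' * `"cnn"` — the Gamma-kernel (or naive, per `spec`) decoder on the data
#'   as given.
#' * `"linear"` — the pointwise linear control: neural envelopes are first
#'   low-pass filtered to the EMG target's bandwidth, then decoded by a single
#'   affine layer with no rectification ([linear_control()]).
#' * `"shuffle"` — the time-permutation null: neural time slices are shuffled
#'   across trials and bins ([shuffle_control()]) before the standard decoder
#'   is trained.
#'
#' @param neural,emg session data as in [gammanet()].
#' @param emg_channel EMG channel index or label.
#' @param spec a [network_spec()] (ignored for `"linear"`).
#' @param config a [training_config()].
#' @param mode one of `"cnn"`, `"linear"`, `"shuffle"`.
#' @param lp_cutoff low-pass cutoff for the linear control's inputs, Hz.
#' @param shuffle_seed RNG seed of the time permutation.
#' @return A fitted `gammanet` object.
#' @export
run_protocol <- function(neural, emg, emg_channel = 1L, spec = NULL,
                         config = training_config(),
                         mode = c("cnn", "linear", "shuffle"),
                         lp_cutoff = 5, shuffle_seed = NULL) {
    mode <- match.arg(mode)
    switch(mode,
           cnn = gammanet(neural, emg, emg_channel, spec, config),
           linear = linear_control(neural, emg, emg_channel, config, lp_cutoff),
           shuffle = {
               neural <- as_session_list(neural)
               seed <- shuffle_seed %||% config$seed
               shuffled <- lapply(seq_along(neural), function(i)
                   shuffle_control(neural[[i]], seed = seed + i - 1L))
               names(shuffled) <- names(neural)
               gammanet(shuffled, emg, emg_channel, spec, config)
           })
}

#' Pointwise linear control decoder
#'
#' The reference baseline: a one-layer affine decoder with no rectification
#' and no temporal memory, trained and validated under the identical restart
#' protocol. Its neural inputs are first low-pass filtered to the same
#' bandwidth as the EMG targets (they would otherwise be far noisier than the
#' targets); negative filter undershoot is clipped at zero to preserve the
#' envelope convention.
#'
#' @inheritParams run_protocol
#' @return A fitted `gammanet` object with a linear [linear_spec()].
#' @export
linear_control <- function(neural, emg, emg_channel = 1L,
                           config = training_config(), lp_cutoff = 5) {
    neural <- as_session_list(neural)
    fs <- 1 / neural[[1]]$bin_width
    lp <- lapply(neural, function(tt) {
        arr <- tt$data
        for (i in seq_len(dim(arr)[1])) for (c in seq_len(dim(arr)[3]))
            arr[i, , c] <- lowpass_target(arr[i, , c], fs, lp_cutoff)
        arr[arr < 0] <- 0
        trial_tensor(arr, tt$bin_width, tt$channel_labels, tt$session_id)
    })
    spec <- linear_spec(dim(neural[[1]]$data)[3], bin_width = neural[[1]]$bin_width)
    gammanet(lp, emg, emg_channel, spec, config)
}

#' Time-permutation shuffle control
#'
#' Applies one random permutation over all pooled (trial, bin) positions to
#' whole cross-channel time slices of a neural tensor: channels move together,
#' so instantaneous spatial statistics (per-channel mean, variance, and the
#' multiset of time slices) are preserved exactly while all temporal structure
#' is destroyed. Used as the last step of preprocessing for the null control.
#'
#' @param x a neural [trial_tensor()].
#' @param seed RNG seed; the permutation is deterministic given the seed.
#' @return A `trial_tensor` of the same shape with permuted time slices.
#' @export
shuffle_control <- function(x, seed = 1L) {
    stopifnot(inherits(x, "trial_tensor"))
    d <- dim(x$data)
    if (d[1] * d[2] < 2L) stop("need at least two pooled time points")
    m <- matrix(x$data, d[1] * d[2], d[3])   # rows are pooled (trial, bin) slices
    set.seed(seed)
    m <- m[sample.int(nrow(m)), , drop = FALSE]
    trial_tensor(array(m, d), x$bin_width, x$channel_labels, x$session_id)
}
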