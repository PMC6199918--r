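#' Trial-aligned envelope tensor
#'
#' The universal interchange object of the package: a `trials x bins x
#' channels` array of nonnegative signal envelopes (RMS power units) together
#' with the bin width and channel labels. All preprocessing output, synthetic
#' data, and decoder input use this container.
#'
#' @param data numeric array, `trials x bins x channels`, elementwise `>= 0`
#'   and finite.
#' @param bin_width bin width in seconds (`1 / output rate`; 0.01 for 100 Hz).
#' @param channel_labels optional character vector, one label per channel.
#' @param session_id optional session label (e.g. recording day).
#'
#' @return An object of class `trial_tensor`.
#' @examples
#' x <- trial_tensor(array(abs(rnorm(5 * 40 * 3)), c(5, 40, 3)), bin_width = 0.01)
#' dim(x$data)
#' @export
trial_tensor <- function(data, bin_width, channel_labels = NULL, session_id = NULL) {
    if (!is.array(data) || length(dim(data)) != 3L)
        stop("`data` must be a 3-d array (trials x bins x channels)")
    if (!all(is.finite(data))) stop("`data` must be finite")
    if (min(data) < 0) stop("envelope data must be nonnegative")
    if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
        stop("`bin_width` must be a positive scalar (seconds)")
    d <- dim(data)
    if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(d[3]))
    if (length(channel_labels) != d[3])
        stop("`channel_labels` must have one entry per channel")
    structure(
        list(data = data, bin_width = bin_width,
             channel_labels = as.character(channel_labels),
             session_id = session_id),
        class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
    d <- dim(x$data)
    cat(sprintf("<trial_tensor%s: %d trials x %d bins x %d channels, bin width %g ms>\n",
                if (is.null(x$session_id)) "" else paste0(" ", x$session_id),
                d[1], d[2], d[3], 1000 * x$bin_width))
    invisible(x)
}

#' @export
dim.trial_tensor <- function(x) dim(x$data)

n_trials <- function(x) dim(x$data)[1]
n_bins   <- function(x) dim(x$data)[2]

#' Subset trials of a trial tensor
#'
#' @param x a [trial_tensor()].
#' @param trials integer indices of trials to keep.
#' @return A `trial_tensor` with the selected trials.
#' @export
tensor_trials <- function(x, trials) {
    stopifnot(inherits(x, "trial_tensor"))
    trial_tensor(x$data[trials, , , drop = FALSE], x$bin_width,
                 x$channel_labels, x$session_id)
}
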