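#' SoftPlus-warped time
#'
#' The warped time variable on which the Gamma kernel is evaluated:
#' `t_f = ln(exp(theta * beta * (t - t0)) + 1) / (theta * beta)`,
#' a smooth rectifier of `t - t0`. Strictly positive for all `t`, monotone
#' increasing, and differentiable in both `t0` and `beta` everywhere, which is
#' what makes the kernel's onset delay trainable by gradient descent. For
#' arguments where `theta * beta * (t - t0) > 30` the asymptote `t - t0` is
#' used to avoid overflow (the discarded term is below `exp(-30)`).
#'
#' @param t time, seconds (vectorized).
#' @param t0 onset delay, seconds (> 0).
#' @param beta inverse time constant, 1/seconds (> 0).
#' @param theta corner sharpness constant (dimensionless, default 10).
#' @return Warped time, same length as `t`; strictly positive.
#' @examples
#' softplus_time(0.02, t0 = 0.02, beta = 50)     # log(2) / (theta * beta)
#' @export
softplus_time <- function(t, t0, beta, theta = 10) {
    if (beta <= 0 || theta <= 0) stop("`beta` and `theta` must be > 0")
    z <- theta * beta * (t - t0)
    tf <- numeric(length(z))
    big <- z > 30
    tf[big] <- (t[big] - t0)
    tf[!big] <- log1p(exp(z[!big])) / (theta * beta)
    # far below onset log1p(exp(z)) underflows; keep t_f strictly positive
    pmax(tf, .Machine$double.xmin)
}

#' Gamma-function filter parameters
#'
#' One causal unimodal convolution kernel `F(t) = alpha * beta^2 * t_f *
#' exp(-beta * t_f)` evaluated on SoftPlus-warped time `t_f`
#' ([softplus_time()]). The kernel is completely specified by three trainable
#' parameters: the area under the curve `alpha` (any sign), the inverse time
#' constant `beta` and the onset delay `t0`. `beta` and `t0` are stored on the
#' log scale so they remain positive under unconstrained optimization. The
#' `beta^2` factor keeps the area equal to `alpha` whenever the kernel support
#' fits inside the tap window, so changing the kernel's time scale does not
#' change the output variance.
#'
#' @param alpha area under the curve (signal units).
#' @param log_beta log inverse time constant; `beta = exp(log_beta)` in 1/s.
#' @param log_t0 log onset delay; `t0 = exp(log_t0)` in seconds.
#' @param theta corner sharpness (fixed, default 10).
#' @param n_taps kernel length in bins (default 30; 300 ms at 10 ms bins).
#' @param dt bin width, seconds (default 0.01).
#' @return A list of class `gamma_filter_params`.
#' @export
gamma_filter_params <- function(alpha, log_beta, log_t0, theta = 10,
                                n_taps = 30L, dt = 0.01) {
    if (theta <= 0) stop("`theta` must be > 0")
    if (n_taps < 1L) stop("`n_taps` must be >= 1")
    if (dt <= 0) stop("`dt` must be > 0")
    structure(list(alpha = alpha, log_beta = log_beta, log_t0 = log_t0,
                   theta = theta, n_taps = as.integer(n_taps), dt = dt),
              class = "gamma_filter_params")
}

#' Discretized Gamma kernel taps
#'
#' Samples the closed-form kernel at bin centers `t = k * dt`,
#' `k = 0 .. n_taps - 1`. Every tap has the sign of `alpha` (the warped time
#' is strictly positive), and `sum(taps) * dt` approximates `alpha` to within
#' discretization error whenever the kernel support `t0 + ~8/beta` fits inside
#' the tap window.
#'
#' @param p a [gamma_filter_params()].
#' @return Numeric vector of length `p$n_taps`.
#' @export
gamma_taps <- function(p) {
    t <- (seq_len(p$n_taps) - 1L) * p$dt
    beta <- exp(p$log_beta); t0 <- exp(p$log_t0)
    tf <- softplus_time(t, t0, beta, p$theta)
    p$alpha * beta^2 * tf * exp(-beta * tf)
}

# Taps plus analytic partial derivatives w.r.t. alpha, log_beta and log_t0.
# Derivation: with u = t_f, F = alpha * beta^2 * u * exp(-beta u),
#   dF/dalpha       = beta^2 u e^{-beta u}
#   dF/dbeta|_expl  = alpha beta u e^{-beta u} (2 - beta u)
#   dF/du           = alpha beta^2 e^{-beta u} (1 - beta u)
#   du/dbeta        = (-u + (t - t0) * sigmoid(theta beta (t - t0))) / beta
#   du/dt0          = -sigmoid(theta beta (t - t0))
# then chain through beta = exp(log_beta), t0 = exp(log_t0).
gamma_taps_grad <- function(p) {
    t <- (seq_len(p$n_taps) - 1L) * p$dt
    beta <- exp(p$log_beta); t0 <- exp(p$log_t0); theta <- p$theta
    z <- theta * beta * (t - t0)
    u <- softplus_time(t, t0, beta, theta)
    s <- 1 / (1 + exp(-pmin(pmax(z, -700), 700)))   # sigmoid, overflow-safe
    e <- exp(-beta * u)
    taps <- p$alpha * beta^2 * u * e
    d_alpha <- beta^2 * u * e
    dF_du <- p$alpha * beta^2 * e * (1 - beta * u)
    du_dbeta <- (-u + (t - t0) * s) / beta
    dF_dbeta <- p$alpha * beta * u * e * (2 - beta * u) + dF_du * du_dbeta
    d_log_beta <- beta * dF_dbeta
    d_log_t0 <- t0 * dF_du * (-s)
    list(taps = taps, d_alpha = d_alpha, d_log_beta = d_log_beta, d_log_t0 = d_log_t0)
}

#' Gamma layer parameters
#'
#' A rectangular `d_in x d_out` grid of Gamma filters sharing tap count, bin
#' width and corner sharpness: one kernel per input-output channel pair.
#' Stored as three `d_in x d_out` matrices (`alpha`, `log_beta`, `log_t0`).
#'
#' @param alpha,log_beta,log_t0 `d_in x d_out` numeric matrices.
#' @param theta corner sharpness (default 10).
#' @param n_taps kernel length in bins.
#' @param dt bin width, seconds.
#' @return A list of class `gamma_layer_params`.
#' @export
gamma_layer_params <- function(alpha, log_beta, log_t0, theta = 10,
                               n_taps = 30L, dt = 0.01) {
    stopifnot(is.matrix(alpha), is.matrix(log_beta), is.matrix(log_t0),
              all(dim(alpha) == dim(log_beta)), all(dim(alpha) == dim(log_t0)))
    structure(list(alpha = alpha, log_beta = log_beta, log_t0 = log_t0,
                   theta = theta, n_taps = as.integer(n_taps), dt = dt),
              class = "gamma_layer_params")
}

layer_filter <- function(layer, i, j) {
    gamma_filter_params(layer$alpha[i, j], layer$log_beta[i, j], layer$log_t0[i, j],
                        layer$theta, layer$n_taps, layer$dt)
}

#' Causal front-padded convolution
#'
#' `out[t] = sum_k taps[k] * x[t - k]` with implicit zeros in front: the
#' output has the same length as the input and `out[t]` depends only on
#' `x[s <= t]`. Applied independently to every trial.
#'
#' @param x numeric matrix (trials x bins) or 3-d array (trials x bins x 1).
#' @param taps numeric kernel, shorter than the trial length.
#' @return Same shape as `x`.
#' @export
causal_conv <- function(x, taps) {
    was_array <- is.array(x) && length(dim(x)) == 3L
    m <- if (was_array) {
        if (dim(x)[3] != 1L) stop("`x` must have a single channel")
        matrix(x, dim(x)[1], dim(x)[2])
    } else if (is.matrix(x)) x else matrix(x, nrow = 1L)
    out <- conv_causal_mat(m, as.numeric(taps))
    if (was_array) array(out, c(dim(out), 1L))
    else if (is.matrix(x)) out else as.numeric(out)
}

#' Gamma layer forward pass
#'
#' `out[, , j] = sum_i causal_conv(x[, , i], taps(filters[i, j]))`: each output
#' channel is the sum over input channels of causal convolutions with that
#' pair's Gamma kernel. Linear in the input and in each `alpha`.
#'
#' @param x trials x bins x d_in array.
#' @param layer a [gamma_layer_params()].
#' @return trials x bins x d_out array.
#' @export
gamma_layer_forward <- function(x, layer) {
    taps <- layer_taps_matrix(layer)
    conv_layer_forward(x, taps)
}

# taps for every (i, j) pair as an n_taps x d_in x d_out array
layer_taps_matrix <- function(layer) {
    d <- dim(layer$alpha)
    out <- array(0, c(layer$n_taps, d[1], d[2]))
    for (j in seq_len(d[2])) for (i in seq_len(d[1]))
        out[, i, j] <- gamma_taps(layer_filter(layer, i, j))
    out
}

# shared forward for gamma and naive layers: taps is n_taps x d_in x d_out
conv_layer_forward <- function(x, taps) {
    dx <- dim(x)
    d_in <- dim(taps)[2]; d_out <- dim(taps)[3]
    if (dx[3] != d_in)
        stop(sprintf("input has %d channels but layer expects %d", dx[3], d_in))
    if (dim(taps)[1] > dx[2]) stop("kernel longer than trial")
    out <- array(0, c(dx[1], dx[2], d_out))
    for (j in seq_len(d_out)) {
        acc <- matrix(0, dx[1], dx[2])
        for (i in seq_len(d_in))
            acc <- acc + conv_causal_mat(matrix(x[, , i], dx[1], dx[2]), taps[, i, j])
        out[, , j] <- acc
    }
    out
}

# backward through a conv layer: returns grad w.r.t. input and w.r.t. taps
conv_layer_backward <- function(x, taps, g_out) {
    dx <- dim(x)
    d_in <- dim(taps)[2]; d_out <- dim(taps)[3]; K <- dim(taps)[1]
    g_in <- array(0, c(dx[1], dx[2], d_in))
    g_taps <- array(0, dim(taps))
    for (j in seq_len(d_out)) {
        gj <- matrix(g_out[, , j], dx[1], dx[2])
        for (i in seq_len(d_in)) {
            xi <- matrix(x[, , i], dx[1], dx[2])
            g_in[, , i] <- g_in[, , i] + conv_causal_adj(gj, taps[, i, j])
            g_taps[, i, j] <- conv_tap_grad(xi, gj, K)
        }
    }
    list(g_in = g_in, g_taps = g_taps)
}

# chain tap gradients back to (alpha, log_beta, log_t0) matrices
gamma_param_grads <- function(layer, g_taps) {
    d <- dim(layer$alpha)
    g_alpha <- g_lb <- g_lt <- matrix(0, d[1], d[2])
    for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
        gr <- gamma_taps_grad(layer_filter(layer, i, j))
        gt <- g_taps[, i, j]
        g_alpha[i, j] <- sum(gt * gr$d_alpha)
        g_lb[i, j]    <- sum(gt * gr$d_log_beta)
        g_lt[i, j]    <- sum(gt * gr$d_log_t0)
    }
    list(alpha = g_alpha, log_beta = g_lb, log_t0 = g_lt)
}
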