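#' Decoder network specification
#'
#' Architecture of the six-layer decoder: session-dependent pointwise feature
#' layers (length 1 in time; default widths 27 -> 21 -> 15 -> 9) followed by
#' session-invariant temporal regression layers (default widths 9 -> 6 -> 3 ->
#' 1). The regression layers are either closed-form Gamma kernels
#' (`"gamma"`, default 300 ms span), unconstrained free kernels (`"naive"`,
#' default 10 bins = 100 ms), or absent (`"none"`), in which case the last
#' feature layer's raw output is the prediction — the configuration of the
#' pointwise linear control when `leaky_slope = 1`.
#'
#' A leaky ReLU follows every layer except the final one, whose raw output is
#' compared to the low-pass-filtered EMG target.
#'
#' @param feature_widths integer vector of feature-layer widths, starting at
#'   the number of neural channels.
#' @param regression_widths integer vector of regression-layer widths, ending
#'   in 1; its first entry must equal the last feature width.
#' @param regression_kind `"gamma"`, `"naive"` or `"none"`.
#' @param gamma_kernel_ms Gamma kernel span, ms (default 300).
#' @param naive_kernel_bins free-kernel length in bins (default 10).
#' @param leaky_slope leaky-ReLU negative slope (default 0.01; 1 = identity,
#'   i.e. no rectification).
#' @param bin_width bin width, seconds (default 0.01).
#' @param theta Gamma-kernel corner sharpness (default 10).
#' @return A list of class `network_spec`.
#' @examples
#' network_spec()                       # the default Gamma configuration
#' network_spec(regression_kind = "naive")
#' @export
network_spec <- function(feature_widths = c(27, 21, 15, 9),
                         regression_widths = c(9, 6, 3, 1),
                         regression_kind = c("gamma", "naive", "none"),
                         gamma_kernel_ms = 300, naive_kernel_bins = 10L,
                         leaky_slope = 0.01, bin_width = 0.01, theta = 10) {
    regression_kind <- match.arg(regression_kind)
    if (any(feature_widths <= 0)) stop("feature widths must be positive")
    if (regression_kind == "none") {
        regression_widths <- integer(0)
        if (tail(feature_widths, 1) != 1L)
            stop("without regression layers the last feature width must be 1")
    } else {
        if (any(regression_widths <= 0)) stop("regression widths must be positive")
        if (tail(regression_widths, 1) != 1L)
            stop("the final regression width must be 1 (single predicted channel)")
        if (regression_widths[1] != tail(feature_widths, 1))
            stop("first regression width must equal the last feature width")
    }
    n_taps <- max(1L, round(gamma_kernel_ms / 1000 / bin_width))
    structure(list(feature_widths = as.integer(feature_widths),
                   regression_widths = as.integer(regression_widths),
                   regression_kind = regression_kind,
                   gamma_kernel_ms = gamma_kernel_ms,
                   gamma_n_taps = as.integer(n_taps),
                   naive_kernel_bins = as.integer(naive_kernel_bins),
                   leaky_slope = leaky_slope, bin_width = bin_width,
                   theta = theta),
              class = "network_spec")
}

#' Pointwise linear decoder specification
#'
#' The control decoder: a single session-dependent affine layer with no
#' rectification and no temporal memory, mapping the (low-pass-filtered)
#' neural envelopes directly to the EMG target.
#'
#' @param n_channels number of neural input channels.
#' @param bin_width bin width, seconds.
#' @return A `network_spec` for the linear control.
#' @export
linear_spec <- function(n_channels, bin_width = 0.01) {
    network_spec(feature_widths = c(n_channels, 1L),
                 regression_kind = "none", leaky_slope = 1,
                 bin_width = bin_width)
}

lrelu <- function(x, slope) { y <- x; neg <- x < 0; y[neg] <- slope * x[neg]; y }
dlrelu <- function(x, slope) { d <- array(1, dim(x) %||% length(x)); d[x < 0] <- slope; d }
`%||%` <- function(a, b) if (is.null(a)) b else a

xavier <- function(fan_in, fan_out, n) {
    lim <- sqrt(6 / (fan_in + fan_out))
    runif(n, -lim, lim)
}

#' Build a decoder model
#'
#' Initializes all parameters: feature weights Xavier-uniform with zero
#' biases; Gamma kernels with `alpha` Xavier-uniform (the area governs output
#' variance, so only `alpha` needs variance-preserving initialization), onset
#' delay `t0 ~ U(5, 30) ms` and time-to-peak `1/beta ~ U(5, 30) ms`; naive
#' kernels Xavier-uniform with fan counted per tap. Deterministic given
#' `seed`: repeated restarts differ only in this initial condition.
#'
#' @param spec a [network_spec()].
#' @param session_ids character vector of session labels; one feature stack is
#'   created per session, the regression stack is shared.
#' @param seed integer RNG seed.
#' @return A list of class `gammanet_model` with elements `spec`,
#'   `session_ids` and `params`.
#' @export
build_model <- function(spec, session_ids, seed = 1L) {
    stopifnot(inherits(spec, "network_spec"), length(session_ids) >= 1L)
    session_ids <- as.character(session_ids)
    set.seed(seed)
    fw <- spec$feature_widths
    feature <- setNames(vector("list", length(session_ids)), session_ids)
    for (s in session_ids) {
        layers <- vector("list", length(fw) - 1L)
        for (l in seq_along(layers)) {
            d_in <- fw[l]; d_out <- fw[l + 1L]
            layers[[l]] <- list(W = matrix(xavier(d_in, d_out, d_in * d_out), d_in, d_out),
                                b = numeric(d_out))
        }
        feature[[s]] <- layers
    }
    rw <- spec$regression_widths
    n_reg <- max(0L, length(rw) - 1L)
    regression <- vector("list", n_reg)
    if (n_reg > 0L) for (l in seq_len(n_reg)) {
        d_in <- rw[l]; d_out <- rw[l + 1L]
        if (spec$regression_kind == "gamma") {
            regression[[l]] <- list(
                alpha    = matrix(xavier(d_in, d_out, d_in * d_out), d_in, d_out),
                log_beta = matrix(-log(runif(d_in * d_out, 0.005, 0.030)), d_in, d_out),
                log_t0   = matrix(log(runif(d_in * d_out, 0.005, 0.030)), d_in, d_out))
        } else {
            K <- spec$naive_kernel_bins
            regression[[l]] <- list(
                taps = array(xavier(d_in * K, d_out * K, d_in * d_out * K),
                             c(K, d_in, d_out)))
        }
    }
    structure(list(spec = spec, session_ids = session_ids,
                   params = list(feature = feature, regression = regression)),
              class = "gammanet_model")
}

#' @export
print.gammanet_model <- function(x, ...) {
    sp <- x$spec
    cat(sprintf("<gammanet_model: %d session(s); features %s; regression %s (%s); %d parameters>\n",
                length(x$session_ids),
                paste(sp$feature_widths, collapse = " -> "),
                if (length(sp$regression_widths)) paste(sp$regression_widths, collapse = " -> ") else "none",
                sp$regression_kind, length(flatten_params(x$params))))
    invisible(x)
}

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(vec, skel) {
    pos <- 0L
    walk <- function(x) {
        if (is.list(x)) return(lapply(x, walk))
        n <- length(x)
        out <- vec[pos + seq_len(n)]
        pos <<- pos + n
        dim(out) <- dim(x)
        out
    }
    walk(skel)
}

# Network regression layers convolve with dt * F(k * dt): the Riemann
# approximation of the continuous convolution integral. Only then does the
# discrete gain to a smooth input equal the kernel area alpha, which is what
# the beta^2 normalization exists for (rescaling the kernel in time leaves the
# output variance unchanged). Without the dt factor every layer would amplify
# by 1/dt (100x at 10 ms bins) and initialized stacks would start ~1e6 off.
reg_layer_taps <- function(spec, lp) {
    if (spec$regression_kind == "gamma") {
        layer <- gamma_layer_params(lp$alpha, lp$log_beta, lp$log_t0,
                                    theta = spec$theta, n_taps = spec$gamma_n_taps,
                                    dt = spec$bin_width)
        layer_taps_matrix(layer) * spec$bin_width
    } else lp$taps
}

as_session_list <- function(x) {
    if (inherits(x, "trial_tensor"))
        return(setNames(list(x), x$session_id %||% "s1"))
    stopifnot(is.list(x), !is.null(names(x)))
    x
}

#' Decoder forward pass
#'
#' Maps per-session neural tensors to a single predicted EMG envelope channel:
#' each session passes through its own pointwise feature stack, the resulting
#' feature tensors are concatenated across sessions along the trial axis, and
#' the shared temporal regression stack produces the prediction. A leaky ReLU
#' follows every layer except the final one.
#'
#' @param model a [build_model()] result.
#' @param sessions named list of [trial_tensor()]s (or plain 3-d arrays),
#'   one per session id known to the model.
#' @param cache keep intermediate activations for backpropagation (internal).
#' @return A list: `pred` (trials x bins matrix, concatenated across sessions
#'   in the order of `model$session_ids`), `trial_map` (named list of row
#'   indices per session), and `cache` if requested.
#' @export
decoder_forward <- function(model, sessions, cache = FALSE) {
    sessions <- as_session_list(sessions)
    unknown <- setdiff(names(sessions), model$session_ids)
    if (length(unknown))
        stop("unknown session id(s): ", paste(unknown, collapse = ", "))
    ids <- intersect(model$session_ids, names(sessions))
    spec <- model$spec; slope <- spec$leaky_slope
    n_reg <- length(model$params$regression)
    feat_out_width <- tail(spec$feature_widths, 1)

    feats <- vector("list", length(ids)); names(feats) <- ids
    fcache <- list(); trial_map <- list(); offset <- 0L
    T_bins <- NULL
    for (s in ids) {
        x <- sessions[[s]]
        arr <- if (inherits(x, "trial_tensor")) x$data else x
        dx <- dim(arr)
        if (dx[3] != spec$feature_widths[1])
            stop(sprintf("session %s has %d channels, spec expects %d",
                         s, dx[3], spec$feature_widths[1]))
        if (is.null(T_bins)) T_bins <- dx[2]
        else if (dx[2] != T_bins) stop("sessions disagree on bin count")
        A <- matrix(arr, dx[1] * dx[2], dx[3])
        zs <- list(); as_ <- list(A)
        n_feat <- length(model$params$feature[[s]])
        for (l in seq_len(n_feat)) {
            lp <- model$params$feature[[s]][[l]]
            Z <- sweep(A %*% lp$W, 2L, lp$b, `+`)
            final_layer <- (n_reg == 0L && l == n_feat)
            A <- if (final_layer) Z else lrelu(Z, slope)
            zs[[l]] <- Z; as_[[l + 1L]] <- A
        }
        feats[[s]] <- array(A, c(dx[1], dx[2], feat_out_width))
        if (cache) fcache[[s]] <- list(n = dx[1], zs = zs, as_ = as_)
        trial_map[[s]] <- offset + seq_len(dx[1]); offset <- offset + dx[1]
    }

    N <- offset
    H <- array(0, c(N, T_bins, feat_out_width))
    for (s in ids) H[trial_map[[s]], , ] <- feats[[s]]

    U <- H; rcache <- list()
    if (n_reg > 0L) for (l in seq_len(n_reg)) {
        taps <- reg_layer_taps(spec, model$params$regression[[l]])
        V <- conv_layer_forward(U, taps)
        if (cache) rcache[[l]] <- list(U = U, V = V, taps = taps)
        U <- if (l < n_reg) lrelu(V, slope) else V
    }
    pred <- matrix(U[, , 1L], N, T_bins)
    out <- list(pred = pred, trial_map = trial_map, session_order = ids)
    if (cache) out$cache <- list(feature = fcache, regression = rcache,
                                 H_dim = dim(H), ids = ids)
    out
}

# Backpropagate dLoss/dpred through the full decoder; returns gradients with
# the same nesting as model$params. Sessions whose trials have zero gradient
# (e.g. held-out sets) contribute nothing to their feature stacks, while all
# sessions accumulate on the shared regression stack.
decoder_backward <- function(model, fwd, g_pred) {
    spec <- model$spec; slope <- spec$leaky_slope
    cache <- fwd$cache
    n_reg <- length(model$params$regression)
    g_reg <- vector("list", n_reg)
    g <- array(g_pred, c(dim(g_pred), 1L))
    if (n_reg > 0L) for (l in rev(seq_len(n_reg))) {
        rc <- cache$regression[[l]]
        bw <- conv_layer_backward(rc$U, rc$taps, g)
        if (spec$regression_kind == "gamma") {
            layer <- gamma_layer_params(model$params$regression[[l]]$alpha,
                                        model$params$regression[[l]]$log_beta,
                                        model$params$regression[[l]]$log_t0,
                                        theta = spec$theta, n_taps = spec$gamma_n_taps,
                                        dt = spec$bin_width)
            # chain through the dt factor of the Riemann-scaled taps
            g_reg[[l]] <- gamma_param_grads(layer, bw$g_taps * spec$bin_width)
        } else {
            g_reg[[l]] <- list(taps = bw$g_taps)
        }
        g <- bw$g_in
        # layer l's input is lrelu(V_{l-1}); chain through that rectifier
        if (l > 1L) g <- g * dlrelu(cache$regression[[l - 1L]]$V, slope)
    }
    # g is now the gradient w.r.t. the concatenated feature output H
    g_feature <- setNames(vector("list", length(cache$ids)), cache$ids)
    for (s in cache$ids) {
        fc <- cache$feature[[s]]
        rows <- fwd$trial_map[[s]]
        d_out <- dim(g)[3]
        G <- matrix(g[rows, , , drop = FALSE], fc$n * dim(g)[2], d_out)
        n_feat <- length(model$params$feature[[s]])
        gl <- vector("list", n_feat)
        for (l in rev(seq_len(n_feat))) {
            final_layer <- (n_reg == 0L && l == n_feat)
            if (!final_layer) G <- G * dlrelu(fc$zs[[l]], slope)
            lp <- model$params$feature[[s]][[l]]
            gl[[l]] <- list(W = crossprod(fc$as_[[l]], G), b = colSums(G))
            if (l > 1L) G <- G %*% t(lp$W)
        }
        g_feature[[s]] <- gl
    }
    list(feature = g_feature, regression = g_reg)
}

#' Pointwise feature layer forward
#'
#' `leakyReLU(x W + b)` applied independently at every time bin: a learned
#' affine map with no temporal memory, used to compress session-specific
#' channels into shared features.
#'
#' @param x trials x bins x d_in array.
#' @param W d_in x d_out weight matrix.
#' @param b length-d_out bias vector.
#' @param slope leaky-ReLU negative slope (default 0.01).
#' @return trials x bins x d_out array.
#' @export
feature_layer_forward <- function(x, W, b = numeric(ncol(W)), slope = 0.01) {
    dx <- dim(x)
    if (dx[3] != nrow(W)) stop("channel count does not match weight rows")
    A <- lrelu(sweep(matrix(x, dx[1] * dx[2], dx[3]) %*% W, 2L, b, `+`), slope)
    array(A, c(dx[1], dx[2], ncol(W)))
}

#' Free-kernel (naive) convolution layer forward
#'
#' Causal front-padded convolution with unconstrained kernels (default 10
#' bins = 100 ms), summed over input channels — the same convolution operator
#' as the Gamma layer but with every tap a free parameter.
#'
#' @param x trials x bins x d_in array.
#' @param kernels n_taps x d_in x d_out array of free taps.
#' @return trials x bins x d_out array (pre-activation).
#' @export
naive_conv_layer_forward <- function(x, kernels) conv_layer_forward(x, kernels)
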