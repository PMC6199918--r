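#' Training configuration
#'
#' Full-batch ADAM on the sum-of-squares reconstruction error, excluding a
#' burn-in period at the start of every trial so the optimizer cannot exploit
#' the filters' startup transient. No L1/L2 regularization is used; early
#' stopping via per-step validation checkpoints takes its place.
#'
#' @param learning_rate ADAM learning rate (default 0.1).
#' @param steps number of optimization steps (default 1000).
#' @param adam_b1,adam_b2,adam_eps ADAM moment decay rates and epsilon
#'   (defaults 0.9, 0.999, 1e-8).
#' @param burn_in_s burn-in excluded from loss and metrics, seconds (default 1).
#' @param restarts number of training attempts from independent random
#'   initializations (default 16).
#' @param seed base RNG seed; attempt `k` uses `seed + k - 1`.
#' @return A list of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.1, steps = 1000L,
                            adam_b1 = 0.9, adam_b2 = 0.999, adam_eps = 1e-8,
                            burn_in_s = 1.0, restarts = 16L, seed = 1L) {
    if (steps < 1L) stop("`steps` must be >= 1")
    if (burn_in_s < 0) stop("`burn_in_s` must be >= 0")
    if (restarts < 1L) stop("`restarts` must be >= 1")
    structure(list(learning_rate = learning_rate, steps = as.integer(steps),
                   adam_b1 = adam_b1, adam_b2 = adam_b2, adam_eps = adam_eps,
                   burn_in_s = burn_in_s, restarts = as.integer(restarts),
                   seed = as.integer(seed)),
              class = "training_config")
}

#' Sum-of-squares reconstruction loss
#'
#' `sum((pred - target)^2)` over all trials and all time bins at or beyond the
#' burn-in, pooled. The first `burn_in_bins` bins of every trial are excluded.
#'
#' @param pred,target trials x bins numeric matrices.
#' @param burn_in_bins number of leading bins excluded (default 0).
#' @return Scalar loss.
#' @examples
#' sse_loss(matrix(1, 1, 3), matrix(c(0, -1, -1), 1), burn_in_bins = 0)  # 9
#' @export
sse_loss <- function(pred, target, burn_in_bins = 0L) {
    if (!all(dim(pred) == dim(target))) stop("`pred` and `target` shapes differ")
    if (burn_in_bins >= ncol(pred)) stop("`burn_in_bins` must be < bins")
    cols <- seq.int(burn_in_bins + 1L, ncol(pred))
    sum((pred[, cols, drop = FALSE] - target[, cols, drop = FALSE])^2)
}

#' Coefficient of determination and correlation, pooled over included bins
#'
#' `r_squared` returns `1 - SS_res / SS_tot` with the total sum of squares
#' about the target mean over all included (trial, bin) points pooled; it can
#' be negative for fits worse than the mean. `correlation` is the Pearson
#' correlation over the same pooled points.
#'
#' @inheritParams sse_loss
#' @return Scalar.
#' @export
r_squared <- function(pred, target, burn_in_bins = 0L) {
    if (!all(dim(pred) == dim(target))) stop("`pred` and `target` shapes differ")
    cols <- seq.int(burn_in_bins + 1L, ncol(pred))
    p <- as.vector(pred[, cols, drop = FALSE]); t <- as.vector(target[, cols, drop = FALSE])
    ss_tot <- sum((t - mean(t))^2)
    if (ss_tot == 0) stop("target variance is zero over the included bins; R^2 undefined")
    1 - sum((p - t)^2) / ss_tot
}

#' @rdname r_squared
#' @export
correlation <- function(pred, target, burn_in_bins = 0L) {
    if (!all(dim(pred) == dim(target))) stop("`pred` and `target` shapes differ")
    cols <- seq.int(burn_in_bins + 1L, ncol(pred))
    t <- as.vector(target[, cols, drop = FALSE])
    if (var(t) == 0) stop("target variance is zero over the included bins")
    cor(as.vector(pred[, cols, drop = FALSE]), t)
}

set_metrics <- function(pred, target, rows, burn_in_bins) {
    p <- pred[rows, , drop = FALSE]; t <- target[rows, , drop = FALSE]
    c(r2 = r_squared(p, t, burn_in_bins), corr = correlation(p, t, burn_in_bins))
}

# Assemble per-session EMG target channel into the concatenated (N x T) matrix
# matching decoder_forward's trial ordering.
concat_target <- function(emg_sessions, ids, trial_map, emg_channel) {
    T_bins <- n_bins(emg_sessions[[ids[1]]])
    N <- max(unlist(trial_map))
    target <- matrix(0, N, T_bins)
    for (s in ids) {
        tt <- emg_sessions[[s]]
        ch <- if (is.character(emg_channel)) match(emg_channel, tt$channel_labels) else emg_channel
        if (is.na(ch) || ch < 1 || ch > dim(tt$data)[3])
            stop("unknown EMG channel: ", emg_channel)
        target[trial_map[[s]], ] <- tt$data[, , ch]
    }
    target
}

#' Run one training attempt
#'
#' Full-batch ADAM from one random initialization. Gradients come only from
#' Training-set trials; after every step the pooled R-squared and correlation
#' on the Training, A and B sets are recorded (step 0 is the initial model).
#' The parameter vectors at the steps maximizing R-squared on A and on B are
#' retained as the `a_max` and `b_max` checkpoints. A non-finite loss aborts
#' the attempt, which is kept in the records flagged as non-convergent.
#'
#' @param model a freshly initialized [build_model()] result.
#' @param neural named list of neural [trial_tensor()]s, one per session.
#' @param emg named list of EMG trial tensors aligned with `neural`.
#' @param split named list of split assignments per session (see
#'   [split_trials()]).
#' @param emg_channel EMG channel index or label.
#' @param config a [training_config()].
#' @return A list of class `attempt_record`: `metrics` (data.frame with one
#'   row per recorded step), `theta_a_max`, `theta_b_max`, `a_max_step`,
#'   `b_max_step`, `converged`.
#' @export
train_attempt <- function(model, neural, emg, split, emg_channel = 1L,
                          config = training_config()) {
    neural <- as_session_list(neural); emg <- as_session_list(emg)
    ids <- model$session_ids
    if (!all(ids %in% names(neural)) || !all(ids %in% names(emg)))
        stop("every model session needs neural and EMG data")
    bw <- neural[[ids[1]]]$bin_width
    burn <- as.integer(round(config$burn_in_s / bw))
    skel <- model$params
    theta <- flatten_params(skel)
    mom <- vel <- numeric(length(theta))
    b1 <- config$adam_b1; b2 <- config$adam_b2; eps <- config$adam_eps
    lr <- config$learning_rate

    # concatenated row indices per set
    probe <- decoder_forward(model, neural)
    tmap <- probe$trial_map
    rows_of <- function(field) unlist(lapply(ids, function(s) tmap[[s]][split[[s]][[field]]]),
                                      use.names = FALSE)
    rows <- list(train = rows_of("train"), a = rows_of("a"), b = rows_of("b"))
    target <- concat_target(emg, ids, tmap, emg_channel)
    N <- nrow(target); T_bins <- ncol(target)
    mask <- matrix(0, N, T_bins)
    mask[rows$train, seq.int(burn + 1L, T_bins)] <- 1

    steps <- config$steps
    metr <- matrix(NA_real_, steps + 1L, 7L,
                   dimnames = list(NULL, c("loss", "r2_train", "r2_a", "r2_b",
                                           "corr_train", "corr_a", "corr_b")))
    best_a <- best_b <- -Inf
    theta_a <- theta_b <- theta
    a_step <- b_step <- 0L
    converged <- TRUE
    n_rec <- 0L

    for (step in 0:steps) {
        model$params <- unflatten_params(theta, skel)
        fwd <- decoder_forward(model, neural, cache = step < steps)
        pred <- fwd$pred
        loss <- sse_loss(pred[rows$train, , drop = FALSE],
                         target[rows$train, , drop = FALSE], burn)
        if (!is.finite(loss)) { converged <- FALSE; break }
        mt <- set_metrics(pred, target, rows$train, burn)
        ma <- set_metrics(pred, target, rows$a, burn)
        mb <- set_metrics(pred, target, rows$b, burn)
        metr[step + 1L, ] <- c(loss, mt["r2"], ma["r2"], mb["r2"],
                               mt["corr"], ma["corr"], mb["corr"])
        n_rec <- step + 1L
        if (ma["r2"] > best_a) { best_a <- ma["r2"]; theta_a <- theta; a_step <- step }
        if (mb["r2"] > best_b) { best_b <- mb["r2"]; theta_b <- theta; b_step <- step }
        if (step == steps) break
        g_pred <- 2 * (pred - target) * mask
        grads <- decoder_backward(model, fwd, g_pred)
        gvec <- flatten_params(grads)
        if (!all(is.finite(gvec))) { converged <- FALSE; break }
        mom <- b1 * mom + (1 - b1) * gvec
        vel <- b2 * vel + (1 - b2) * gvec^2
        tt <- step + 1L
        theta <- theta - lr * (mom / (1 - b1^tt)) / (sqrt(vel / (1 - b2^tt)) + eps)
    }
    structure(list(metrics = as.data.frame(metr[seq_len(max(n_rec, 1L)), , drop = FALSE]),
                   theta_a_max = theta_a, theta_b_max = theta_b,
                   a_max_step = a_step, b_max_step = b_step,
                   converged = converged),
              class = "attempt_record")
}

#' Fit a Gamma-kernel EMG decoder with restart cross-validation
#'
#' The top-level fitting function. Trials are split deterministically into
#' Training / Set A / Set B by sequential groups of five ([split_trials()]).
#' `config$restarts` training attempts are run from independent random
#' initializations ([train_attempt()]); within each attempt, the checkpoints
#' maximizing validation R-squared on A and on B are retained (early stop).
#' Among the `a_max` checkpoints, the one with the largest sum of Training and
#' Set-A R-squared is selected — without reading Set-B scores — and evaluated
#' once on B; symmetrically for `b_max` on A. The reported overall performance
#' is the mean of the two held-out scores. Exact ties in the selection sum
#' resolve to the lowest attempt index.
#'
#' @param neural a neural [trial_tensor()] or a named list of them (one per
#'   session).
#' @param emg the aligned EMG trial tensor(s); the selected channel must
#'   already be low-pass filtered (the preprocessing chain does this).
#' @param emg_channel EMG channel index or label (default 1); each EMG channel
#'   is decoded independently.
#' @param spec a [network_spec()]; defaults to the Gamma configuration with
#'   the input width taken from the data.
#' @param config a [training_config()].
#' @param split optional named list of precomputed split assignments.
#' @return An object of class `gammanet` with components `score`
#'   (session score), `attempts`, `model_a`/`model_b` (selected checkpoints as
#'   models), `spec`, `config`, `split`, plus bookkeeping. Methods: `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' \donttest{
#' syn <- synth_generate(synth_config(trials_per_session = 10, n_neural = 6,
#'                                    n_latents = 1, n_emg = 1))
#' fit <- gammanet(syn$sessions$s1$neural, syn$sessions$s1$emg,
#'                 spec = network_spec(feature_widths = c(6, 1),
#'                                     regression_widths = c(1, 1)),
#'                 config = training_config(steps = 50, restarts = 2))
#' print(fit)
#' }
#' @export
gammanet <- function(neural, emg, emg_channel = 1L, spec = NULL,
                     config = training_config(), split = NULL) {
    neural <- as_session_list(neural); emg <- as_session_list(emg)
    if (!identical(sort(names(neural)), sort(names(emg))))
        stop("`neural` and `emg` must cover the same sessions")
    ids <- names(neural)
    n_ch <- dim(neural[[1]]$data)[3]
    bw <- neural[[1]]$bin_width
    if (is.null(spec)) {
        # 27 channels gives the reference ladder 27 -> 21 -> 15 -> 9
        spec <- if (n_ch >= 9)
            network_spec(feature_widths = unique(round(seq(n_ch, 9, length.out = 4))),
                         regression_widths = c(9, 6, 3, 1), bin_width = bw)
        else
            network_spec(feature_widths = c(n_ch, n_ch),
                         regression_widths = c(n_ch, max(2L, n_ch %/% 2L), 1L),
                         bin_width = bw)
    }
    if (is.null(split))
        split <- lapply(neural, function(x) split_trials(n_trials(x)))
    if (is.null(names(split)) && length(split) == length(ids)) names(split) <- ids

    attempts <- vector("list", config$restarts)
    for (k in seq_len(config$restarts)) {
        model_k <- build_model(spec, ids, seed = config$seed + k - 1L)
        attempts[[k]] <- train_attempt(model_k, neural, emg, split,
                                       emg_channel, config)
    }
    if (!any(vapply(attempts, `[[`, logical(1), "converged")))
        warning("no training attempt converged; scores reflect best recorded checkpoints")

    sel <- select_checkpoints(attempts)
    skel <- build_model(spec, ids, seed = config$seed)$params
    model_a <- structure(list(spec = spec, session_ids = ids,
                              params = unflatten_params(attempts[[sel$a_attempt]]$theta_a_max, skel)),
                         class = "gammanet_model")
    model_b <- structure(list(spec = spec, session_ids = ids,
                              params = unflatten_params(attempts[[sel$b_attempt]]$theta_b_max, skel)),
                         class = "gammanet_model")
    structure(list(score = sel$score, attempts = attempts,
                   model_a = model_a, model_b = model_b,
                   spec = spec, config = config, split = split,
                   emg_channel = emg_channel, session_ids = ids,
                   bin_width = bw,
                   burn_in_bins = as.integer(round(config$burn_in_s / bw)),
                   neural = neural, emg = emg,
                   call = match.call()),
              class = "gammanet")
}

# A_max / B_max model selection across attempts. For each attempt the a_max
# checkpoint's selection sum is R2(train) + R2(A) at that step; the argmax
# attempt (ties -> lowest index) is evaluated on B by reading the already
# recorded trajectory row at the checkpoint step. Symmetric for b_max.
select_checkpoints <- function(attempts) {
    sum_a <- vapply(attempts, function(at) {
        r <- at$metrics[at$a_max_step + 1L, ]; r$r2_train + r$r2_a
    }, numeric(1))
    sum_b <- vapply(attempts, function(at) {
        r <- at$metrics[at$b_max_step + 1L, ]; r$r2_train + r$r2_b
    }, numeric(1))
    ia <- which.max(sum_a); ib <- which.max(sum_b)
    ra <- attempts[[ia]]$metrics[attempts[[ia]]$a_max_step + 1L, ]
    rb <- attempts[[ib]]$metrics[attempts[[ib]]$b_max_step + 1L, ]
    score <- structure(list(
        a_max_on_b = c(r2 = ra$r2_b, corr = ra$corr_b),
        b_max_on_a = c(r2 = rb$r2_a, corr = rb$corr_a),
        overall_r2 = (ra$r2_b + rb$r2_a) / 2,
        overall_corr = (ra$corr_b + rb$corr_a) / 2,
        a_attempt = ia, b_attempt = ib,
        a_step = attempts[[ia]]$a_max_step, b_step = attempts[[ib]]$b_max_step),
        class = "session_score")
    list(score = score, a_attempt = ia, b_attempt = ib)
}

#' @export
print.session_score <- function(x, ...) {
    cat(sprintf("A_max(B): R2 = %.4f (r = %.4f)   [attempt %d, step %d]\n",
                x$a_max_on_b["r2"], x$a_max_on_b["corr"], x$a_attempt, x$a_step))
    cat(sprintf("B_max(A): R2 = %.4f (r = %.4f)   [attempt %d, step %d]\n",
                x$b_max_on_a["r2"], x$b_max_on_a["corr"], x$b_attempt, x$b_step))
    cat(sprintf("overall:  R2 = %.4f, r = %.4f\n", x$overall_r2, x$overall_corr))
    invisible(x)
}

#' @export
print.gammanet <- function(x, ...) {
    sp <- x$spec
    cat("Gamma-kernel EMG decoder\n")
    cat(sprintf("  sessions: %d; EMG channel: %s; restarts: %d; steps: %d\n",
                length(x$session_ids), as.character(x$emg_channel),
                x$config$restarts, x$config$steps))
    cat(sprintf("  features %s | regression %s (%s)\n",
                paste(sp$feature_widths, collapse = " -> "),
                if (length(sp$regression_widths)) paste(sp$regression_widths, collapse = " -> ") else "none",
                sp$regression_kind))
    print(x$score)
    invisible(x)
}

#' @export
summary.gammanet <- function(object, ...) {
    at <- object$attempts
    tab <- data.frame(
        attempt = seq_along(at),
        converged = vapply(at, `[[`, logical(1), "converged"),
        a_max_step = vapply(at, `[[`, integer(1), "a_max_step"),
        b_max_step = vapply(at, `[[`, integer(1), "b_max_step"),
        r2_a_at_amax = vapply(at, function(a) a$metrics$r2_a[a$a_max_step + 1L], numeric(1)),
        r2_b_at_bmax = vapply(at, function(a) a$metrics$r2_b[a$b_max_step + 1L], numeric(1)))
    out <- list(score = object$score, attempts = tab, spec = object$spec)
    class(out) <- "summary.gammanet"
    out
}

#' @export
print.summary.gammanet <- function(x, ...) {
    print(x$score)
    cat("\nPer-attempt checkpoints:\n")
    print(x$attempts, row.names = FALSE)
    invisible(x)
}

#' Extract Gamma-kernel coefficients
#'
#' Returns the trained Gamma-kernel parameters of the selected checkpoint as a
#' long table: one row per (layer, input channel, output channel) with `alpha`
#' (area), `beta` (1/s), `t0` (s). Empty for naive/linear configurations.
#'
#' @param object a fitted [gammanet()] object.
#' @param model which selected checkpoint, `"a_max"` or `"b_max"`.
#' @param ... unused.
#' @export
coef.gammanet <- function(object, model = c("a_max", "b_max"), ...) {
    model <- match.arg(model)
    m <- if (model == "a_max") object$model_a else object$model_b
    kernel_table(m)
}

#' Kernel parameter table of a decoder model
#'
#' @param model a `gammanet_model`.
#' @return data.frame with columns layer, input, output, alpha, beta, t0
#'   (gamma kind) or tap values (naive kind).
#' @export
kernel_table <- function(model) {
    spec <- model$spec
    out <- list()
    for (l in seq_along(model$params$regression)) {
        lp <- model$params$regression[[l]]
        if (spec$regression_kind == "gamma") {
            d <- dim(lp$alpha)
            grid <- expand.grid(input = seq_len(d[1]), output = seq_len(d[2]))
            out[[l]] <- data.frame(layer = l, grid,
                                   alpha = as.vector(lp$alpha),
                                   beta = exp(as.vector(lp$log_beta)),
                                   t0 = exp(as.vector(lp$log_t0)))
        } else {
            d <- dim(lp$taps)
            grid <- expand.grid(tap = seq_len(d[1]), input = seq_len(d[2]),
                                output = seq_len(d[3]))
            out[[l]] <- data.frame(layer = l, grid, value = as.vector(lp$taps))
        }
    }
    if (!length(out)) return(data.frame())
    do.call(rbind, out)
}

#' Predict EMG envelopes from neural tensors
#'
#' @param object a fitted [gammanet()].
#' @param newdata named list of neural [trial_tensor()]s (defaults to the
#'   training data).
#' @param model which selected checkpoint to use.
#' @param ... unused.
#' @return trials x bins matrix of predicted EMG envelope, rows concatenated
#'   across sessions in model session order.
#' @export
predict.gammanet <- function(object, newdata = NULL,
                             model = c("a_max", "b_max"), ...) {
    model <- match.arg(model)
    m <- if (model == "a_max") object$model_a else object$model_b
    data <- if (is.null(newdata)) object$neural else as_session_list(newdata)
    decoder_forward(m, data)$pred
}

#' @export
fitted.gammanet <- function(object, ...) predict(object)

#' @export
residuals.gammanet <- function(object, model = c("a_max", "b_max"), ...) {
    model <- match.arg(model)
    pred <- predict(object, model = model)
    fwd <- decoder_forward(object$model_a, object$neural)
    target <- concat_target(object$emg, object$session_ids, fwd$trial_map,
                            object$emg_channel)
    target - pred
}

#' Plot reconstruction of selected trials
#'
#' Overlays the predicted EMG envelope (selected checkpoint) on the target for
#' a few trials; the burn-in period is shaded.
#'
#' @param x a fitted [gammanet()].
#' @param trials concatenated trial row indices to plot (default first 3).
#' @param model which checkpoint.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gammanet <- function(x, trials = 1:3, model = c("a_max", "b_max"), ...) {
    model <- match.arg(model)
    pred <- predict(x, model = model)
    fwd <- decoder_forward(x$model_a, x$neural)
    target <- concat_target(x$emg, x$session_ids, fwd$trial_map, x$emg_channel)
    trials <- trials[trials <= nrow(pred)]
    old <- graphics::par(mfrow = c(length(trials), 1), mar = c(2, 4, 1, 1))
    on.exit(graphics::par(old))
    tt <- (seq_len(ncol(pred)) - 1L) * x$bin_width
    for (i in trials) {
        graphics::plot(tt, target[i, ], type = "l", col = "black",
                       xlab = "time (s)", ylab = "EMG envelope", ...)
        graphics::lines(tt, pred[i, ], col = "red")
        graphics::abline(v = x$burn_in_bins * x$bin_width, lty = 3)
    }
    invisible(x)
}
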