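test_that("softplus time warp has the right anchors and limits", {
    theta <- 10
    # at t = t0 the exponent vanishes
    expect_equal(softplus_time(0.02, t0 = 0.02, beta = 50, theta = theta),
                 log(2) / (theta * 50), tolerance = 1e-12)
    # high-precision direct evaluation
    expect_equal(softplus_time(1, t0 = 0, beta = 1, theta = 10),
                 0.1 * log(exp(10) + 1), tolerance = 1e-10)
    expect_equal(softplus_time(1, t0 = 0, beta = 1, theta = 10),
                 1.00000453989, tolerance = 1e-8)
    # far below onset the warped time approaches zero from above
    tf_lo <- softplus_time(-100, t0 = 0.01, beta = 10, theta = theta)
    expect_gt(tf_lo, 0)
    expect_lt(tf_lo, 1e-12)
    # monotone increasing in t, strictly positive everywhere
    t <- seq(-0.5, 0.5, by = 0.001)
    tf <- softplus_time(t, 0.02, 30, theta)
    expect_true(all(diff(tf) > 0))
    expect_true(all(tf > 0))
    # overflow guard: large arguments follow the t - t0 asymptote
    expect_equal(softplus_time(5, 0.01, 100, 10), 5 - 0.01, tolerance = 1e-12)
})

test_that("positivity of warped time holds over random parameter draws", {
    set.seed(5)
    for (i in 1:200) {
        tf <- softplus_time(runif(1, -1, 1), exp(runif(1, -6, -2)),
                            exp(runif(1, 1, 5)), 10)
        expect_gt(tf, 0)
    }
})

test_that("gamma taps have alpha's sign, conserve area, and peak at 1/beta", {
    p0 <- gamma_filter_params(0, log(30), log(0.02))
    expect_equal(gamma_taps(p0), rep(0, 30))

    # area conservation over random draws: support inside the tap window and
    # time constant resolved by the grid (1/beta >= ~2 bins); sharper kernels
    # are under-sampled at 10 ms bins and their Riemann sum drifts beyond 2%
    set.seed(7)
    n_bad <- 0L
    for (i in 1:1000) {
        tau <- runif(1, 0.018, 0.035)
        t0 <- runif(1, 0.001, min(0.05, 0.3 - 8 * tau - 0.005))
        alpha <- runif(1, -2, 2); while (abs(alpha) < 0.05) alpha <- runif(1, -2, 2)
        stopifnot(t0 + 8 * tau < 0.3)
        p <- gamma_filter_params(alpha, -log(tau), log(t0))
        area <- sum(gamma_taps(p)) * p$dt
        if (abs(area - alpha) / abs(alpha) >= 0.02) n_bad <- n_bad + 1L
        expect_true(all(sign(gamma_taps(p)) == sign(alpha)))
    }
    expect_identical(n_bad, 0L)

    # peak located where t_f ~ 1/beta with value ~ alpha * beta / e
    p <- gamma_filter_params(1.5, -log(0.04), log(0.03), n_taps = 60)
    taps <- gamma_taps(p)
    k_peak <- which.max(taps)
    t_peak <- (k_peak - 1) * p$dt
    expect_lt(abs(t_peak - (0.03 + 0.04)), p$dt + 1e-9)
    expect_equal(max(taps), 1.5 * (1 / 0.04) / exp(1), tolerance = 0.05)
})

test_that("kernel area is invariant to the sampling rate", {
    area_at <- function(dt, n) {
        p <- gamma_filter_params(1.2, -log(0.03), log(0.02), n_taps = n, dt = dt)
        sum(gamma_taps(p)) * dt
    }
    a1 <- area_at(0.01, 30)
    a2 <- area_at(0.005, 60)
    expect_lt(abs(a2 - a1) / abs(a1), 0.01)
})

test_that("causal convolution matches impulse, causality and brute force", {
    taps <- rnorm(7)
    x <- matrix(0, 1, 40); x[1, 9] <- 1
    y <- causal_conv(x, taps)
    expect_equal(y[1, 9:15], taps)
    expect_equal(y[1, 1:8], rep(0, 8))

    set.seed(13)
    xr <- matrix(rnorm(4 * 50), 4, 50)
    expect_lt(max(abs(causal_conv(xr, taps) - conv_brute(xr, taps))), 1e-10)

    # strict causality: perturbation at bin j leaves bins < j unchanged exactly
    j <- 23L
    xp <- xr; xp[2, j] <- xp[2, j] + 100
    y0 <- causal_conv(xr, taps); y1 <- causal_conv(xp, taps)
    expect_identical(y1[, seq_len(j - 1L)], y0[, seq_len(j - 1L)])

    expect_error(causal_conv(matrix(0, 1, 5), rnorm(10)), "exceeds")
})

test_that("gamma layer forward equals the per-pair brute-force oracle", {
    set.seed(17)
    layer <- gamma_layer_params(alpha = matrix(rnorm(6), 3, 2),
                                log_beta = matrix(log(runif(6, 20, 80)), 3, 2),
                                log_t0 = matrix(log(runif(6, 0.005, 0.05)), 3, 2),
                                n_taps = 12, dt = 0.01)
    x <- array(rnorm(5 * 50 * 3), c(5, 50, 3))
    out <- gamma_layer_forward(x, layer)
    ref <- array(0, c(5, 50, 2))
    for (j in 1:2) for (i in 1:3) {
        taps <- gamma_taps(gammanet:::layer_filter(layer, i, j))
        ref[, , j] <- ref[, , j] + conv_brute(matrix(x[, , i], 5, 50), taps)
    }
    expect_lt(max(abs(out - ref)), 1e-10)

    # single-pair impulse reproduces the kernel
    l11 <- gamma_layer_params(matrix(0.8), matrix(log(40)), matrix(log(0.02)),
                              n_taps = 20, dt = 0.01)
    imp <- array(0, c(1, 40, 1)); imp[1, 1, 1] <- 1
    expect_equal(as.numeric(gamma_layer_forward(imp, l11)[1, 1:20, 1]),
                 gamma_taps(gammanet:::layer_filter(l11, 1, 1)))

    # linearity in alpha: doubling every alpha doubles the output exactly
    layer2 <- layer; layer2$alpha <- 2 * layer$alpha
    expect_equal(gamma_layer_forward(x, layer2), 2 * out, tolerance = 1e-14)

    expect_error(gamma_layer_forward(array(0, c(2, 50, 4)), layer), "channels")
})

test_that("analytic kernel gradients match central finite differences", {
    p <- gamma_filter_params(0.7, log(30), log(0.02), n_taps = 25)
    gr <- gammanet:::gamma_taps_grad(p)
    expect_equal(gr$taps, gamma_taps(p))
    h <- 1e-6
    for (field in c("alpha", "log_beta", "log_t0")) {
        pp <- p; pm <- p
        pp[[field]] <- pp[[field]] + h
        pm[[field]] <- pm[[field]] - h
        fd <- (gamma_taps(pp) - gamma_taps(pm)) / (2 * h)
        expect_lt(max(abs(fd - gr[[paste0("d_", field)]])), 1e-5)
    }

    # area conservation in differential form: d(area)/d(log beta) ~ 0 when the
    # kernel support is fully contained; checked on a fine grid where the
    # Riemann sum tracks the integral
    p2 <- gamma_filter_params(1.1, -log(0.02), log(0.02), n_taps = 150, dt = 0.002)
    gr2 <- gammanet:::gamma_taps_grad(p2)
    expect_lt(abs(sum(gr2$d_log_beta) * p2$dt), 0.01 * abs(p2$alpha))
})

test_that("whole-network gradients match finite differences", {
    set.seed(42)
    spec <- network_spec(feature_widths = c(4, 3, 2), regression_widths = c(2, 2, 1),
                         gamma_kernel_ms = 80, bin_width = 0.01)
    model <- build_model(spec, c("s1", "s2"), seed = 7)
    ns <- list(s1 = array(abs(rnorm(3 * 50 * 4)), c(3, 50, 4)),
               s2 = array(abs(rnorm(2 * 50 * 4)), c(2, 50, 4)))
    target <- matrix(rnorm(5 * 50), 5, 50)
    skel <- model$params
    theta <- gammanet:::flatten_params(skel)
    loss_at <- function(th) {
        model$params <- gammanet:::unflatten_params(th, skel)
        sum((decoder_forward(model, ns)$pred - target)^2)
    }
    model$params <- gammanet:::unflatten_params(theta, skel)
    fwd <- decoder_forward(model, ns, cache = TRUE)
    gvec <- gammanet:::flatten_params(
        gammanet:::decoder_backward(model, fwd, 2 * (fwd$pred - target)))
    h <- 1e-5
    fd <- vapply(seq_along(theta), function(i) {
        tp <- theta; tp[i] <- tp[i] + h
        tm <- theta; tm[i] <- tm[i] - h
        (loss_at(tp) - loss_at(tm)) / (2 * h)
    }, numeric(1))
    rel <- abs(fd - gvec) / pmax(abs(fd), 1e-4)
    expect_lt(max(rel), 1e-4)
})

test_that("zero-area filters give zero gradients for their time parameters", {
    spec <- network_spec(feature_widths = c(2, 1), regression_widths = c(1, 1),
                         gamma_kernel_ms = 100, bin_width = 0.01)
    model <- build_model(spec, "s1", seed = 1)
    model$params$regression[[1]]$alpha[] <- 0
    ns <- list(s1 = array(abs(rnorm(2 * 40 * 2)), c(2, 40, 2)))
    fwd <- decoder_forward(model, ns, cache = TRUE)
    expect_equal(fwd$pred, matrix(0, 2, 40))
    target <- matrix(rnorm(2 * 40), 2, 40)
    g <- gammanet:::decoder_backward(model, fwd, 2 * (fwd$pred - target))
    # taps scale with alpha, so the time parameters have no pull at alpha = 0 ...
    expect_equal(g$regression[[1]]$log_beta, matrix(0, 1, 1))
    expect_equal(g$regression[[1]]$log_t0, matrix(0, 1, 1))
    # ... while the area parameter still does
    expect_gt(abs(g$regression[[1]]$alpha), 0)
})
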