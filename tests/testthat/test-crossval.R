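test_that("trials split by sequential groups of five, no randomization", {
    s10 <- split_trials(10)
    expect_equal(s10$train, c(1L, 2L, 3L, 6L, 7L, 8L))
    expect_equal(s10$a, c(4L, 9L))
    expect_equal(s10$b, c(5L, 10L))

    s5 <- split_trials(5)
    expect_equal(s5$train, 1:3)
    expect_equal(s5$a, 4L)
    expect_equal(s5$b, 5L)

    # trailing partial group follows the pattern truncated
    s12 <- split_trials(12)
    expect_true(all(c(11L, 12L) %in% s12$train))
    expect_equal(s12$a, c(4L, 9L))

    expect_error(split_trials(4), ">= 5")

    # pure function: identical assignment every call
    expect_identical(split_trials(37), split_trials(37))

    # exact 60 / 20 / 20 proportions when n is divisible by 5
    for (n in c(5L, 20L, 60L, 100L)) {
        s <- split_trials(n)
        expect_equal(length(s$train) / n, 0.6)
        expect_equal(length(s$a) / n, 0.2)
        expect_equal(length(s$b) / n, 0.2)
        expect_equal(sort(c(s$train, s$a, s$b)), seq_len(n))
        expect_length(intersect(s$train, c(s$a, s$b)), 0)
        expect_length(intersect(s$a, s$b), 0)
    }
})

make_fake_attempt <- function(r2_train, r2_a, r2_b) {
    n <- length(r2_train)
    structure(list(
        metrics = data.frame(loss = rep(1, n), r2_train = r2_train,
                             r2_a = r2_a, r2_b = r2_b,
                             corr_train = sqrt(pmax(r2_train, 0)),
                             corr_a = sqrt(pmax(r2_a, 0)),
                             corr_b = sqrt(pmax(r2_b, 0))),
        theta_a_max = numeric(3), theta_b_max = numeric(3),
        a_max_step = which.max(r2_a) - 1L, b_max_step = which.max(r2_b) - 1L,
        converged = TRUE), class = "attempt_record")
}

test_that("checkpoint selection matches the hand-worked argmax", {
    # three attempts with hand-assigned trajectories (steps 0..2)
    a1 <- make_fake_attempt(r2_train = c(0.2, 0.5, 0.9),
                            r2_a = c(0.1, 0.6, 0.3),   # a_max at step 1: sum 0.5+0.6 = 1.1
                            r2_b = c(0.0, 0.2, 0.4))   # b_max at step 2: sum 0.9+0.4 = 1.3
    a2 <- make_fake_attempt(r2_train = c(0.1, 0.8, 0.7),
                            r2_a = c(0.0, 0.5, 0.1),   # a_max step 1: 0.8+0.5 = 1.3  <- winner
                            r2_b = c(0.0, 0.1, 0.2))   # b_max step 2: 0.7+0.2 = 0.9
    a3 <- make_fake_attempt(r2_train = c(0.0, 0.3, 0.2),
                            r2_a = c(0.2, 0.4, 0.1),   # 0.3+0.4 = 0.7
                            r2_b = c(0.1, 0.9, 0.3))   # 0.3+0.9 = 1.2
    sel <- gammanet:::select_checkpoints(list(a1, a2, a3))
    expect_equal(sel$a_attempt, 2L)
    expect_equal(sel$b_attempt, 1L)
    # the selected models are scored on the *other* set at their own step
    expect_equal(sel$score$a_max_on_b[["r2"]], 0.1)  # attempt 2, step 1, r2_b
    expect_equal(sel$score$b_max_on_a[["r2"]], 0.3)  # attempt 1, step 2, r2_a
    expect_equal(sel$score$overall_r2, (0.1 + 0.3) / 2)

    # exact tie resolves to the lowest attempt index
    b1 <- make_fake_attempt(c(0.5, 0.5), c(0.5, 0.4), c(0.2, 0.3))
    b2 <- make_fake_attempt(c(0.5, 0.5), c(0.5, 0.4), c(0.9, 0.1))
    sel_tie <- gammanet:::select_checkpoints(list(b1, b2))
    expect_equal(sel_tie$a_attempt, 1L)

    # a single attempt is chosen by construction
    sel1 <- gammanet:::select_checkpoints(list(a3))
    expect_equal(sel1$a_attempt, 1L)
    expect_equal(sel1$score$a_max_on_b[["r2"]], 0.9)
})

test_that("selection never reads the held-out set (information hygiene)", {
    syn <- tiny_path_session(trials = 10, n_neural = 6, seed = 5)
    neural <- syn$sessions$s1$neural
    emg <- syn$sessions$s1$emg
    spec <- network_spec(feature_widths = c(6, 1), regression_widths = c(1, 1))
    cfg <- training_config(steps = 40, restarts = 2, seed = 11)

    fit0 <- gammanet(neural, emg, spec = spec, config = cfg)

    # perturb Set-B targets only: A-side selection must be unchanged
    sp <- split_trials(10)
    emg_b <- emg
    set.seed(99)
    emg_b$data[sp$b, , ] <- emg_b$data[sp$b, , ] * 3 + 1
    fit_b <- gammanet(neural, emg_b, spec = spec, config = cfg)
    expect_identical(fit_b$score$a_attempt, fit0$score$a_attempt)
    expect_identical(fit_b$score$a_step, fit0$score$a_step)
    expect_identical(fit_b$model_a$params, fit0$model_a$params)

    # and symmetrically for Set A
    emg_a <- emg
    emg_a$data[sp$a, , ] <- emg_a$data[sp$a, , ] * 3 + 1
    fit_a <- gammanet(neural, emg_a, spec = spec, config = cfg)
    expect_identical(fit_a$score$b_attempt, fit0$score$b_attempt)
    expect_identical(fit_a$score$b_step, fit0$score$b_step)
    expect_identical(fit_a$model_b$params, fit0$model_b$params)
})

test_that("time shuffle preserves slice multiset and destroys autocorrelation", {
    syn <- tiny_path_session(trials = 8, n_neural = 5, seed = 6)
    x <- syn$sessions$s1$neural
    sh <- shuffle_control(x, seed = 42)
    d <- dim(x$data)

    m0 <- matrix(x$data, d[1] * d[2], d[3])
    m1 <- matrix(sh$data, d[1] * d[2], d[3])
    # identical multiset of cross-channel time slices (channels move together)
    key0 <- do.call(order, as.data.frame(m0))
    key1 <- do.call(order, as.data.frame(m1))
    expect_equal(m0[key0, ], m1[key1, ])
    # per-channel mean and variance invariant (up to summation order)
    expect_equal(colMeans(m0), colMeans(m1), tolerance = 1e-12)
    expect_equal(apply(m0, 2, var), apply(m1, 2, var), tolerance = 1e-12)
    expect_false(identical(m0, m1))

    # deterministic given the seed
    expect_identical(shuffle_control(x, seed = 42)$data, sh$data)

    # lag-1 autocorrelation collapses from smooth to none
    lag1 <- function(arr) {
        v <- as.vector(t(arr[, , 1])); cor(v[-1], v[-length(v)])
    }
    expect_gt(lag1(x$data), 0.9)
    expect_lt(abs(lag1(sh$data)), 0.1)
})

test_that("a pointwise linear map is recovered perfectly by the linear control", {
    # data generated by a pointwise linear map of smooth envelopes, no noise
    syn <- tiny_path_session(trials = 10, n_neural = 5, seed = 8)
    neural <- syn$sessions$s1$neural
    d <- dim(neural$data)
    set.seed(20)
    w <- runif(d[3], 0.1, 1)
    target <- array(0, c(d[1], d[2], 1))
    # the control low-pass filters its inputs; build the target from the
    # same filtered signals so the map stays exactly realizable
    fs <- 1 / neural$bin_width
    filt <- neural$data
    for (i in seq_len(d[1])) for (c in seq_len(d[3]))
        filt[i, , c] <- lowpass_target(neural$data[i, , c], fs, 5)
    filt[filt < 0] <- 0
    for (i in seq_len(d[1])) target[i, , 1] <- filt[i, , ] %*% w
    emg <- trial_tensor(pmax(target, 0), neural$bin_width, "emg1", "s1")

    fit <- linear_control(neural, emg,
                          config = training_config(steps = 150, restarts = 2, seed = 3))
    expect_gt(fit$score$overall_r2, 0.99)
})

test_that("run_protocol dispatches the three modes reproducibly", {
    syn <- tiny_path_session(trials = 5, n_neural = 4, seed = 9)
    neural <- syn$sessions$s1$neural
    emg <- syn$sessions$s1$emg
    spec <- network_spec(feature_widths = c(4, 1), regression_widths = c(1, 1))
    cfg <- training_config(steps = 15, restarts = 1, seed = 13)

    f1 <- run_protocol(neural, emg, spec = spec, config = cfg, mode = "cnn")
    f2 <- run_protocol(neural, emg, spec = spec, config = cfg, mode = "cnn")
    expect_identical(f1$score$overall_r2, f2$score$overall_r2)

    fl <- run_protocol(neural, emg, spec = spec, config = cfg, mode = "linear")
    expect_identical(fl$spec$regression_kind, "none")
    fs <- run_protocol(neural, emg, spec = spec, config = cfg, mode = "shuffle")
    expect_s3_class(fs, "gammanet")
})
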