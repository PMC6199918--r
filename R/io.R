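#' Write sessions to a plain-text directory container
#'
#' Persists a set of sessions in a documented hierarchical plain-text layout:
#'
#' ```
#' <dir>/meta.json                     # bin width, channel labels, shapes
#' <dir>/session_<id>/neural.csv       # (trials * bins) x channels
#' <dir>/session_<id>/emg.csv
#' ```
#'
#' Values are written with 17 significant digits, which round-trips IEEE
#' doubles exactly, so a written-then-read tensor is bit-identical. Rows are
#' pooled (trial, bin) positions in trial-major order.
#'
#' @param sessions named list of sessions, each a list with `neural` and `emg`
#'   [trial_tensor()]s.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sessions <- function(sessions, dir) {
    stopifnot(is.list(sessions), length(sessions) >= 1L)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    meta <- list()
    for (sid in names(sessions)) {
        sdir <- file.path(dir, paste0("session_", sid))
        dir.create(sdir, showWarnings = FALSE)
        for (grp in c("neural", "emg")) {
            tt <- sessions[[sid]][[grp]]
            stopifnot(inherits(tt, "trial_tensor"))
            d <- dim(tt$data)
            m <- matrix(tt$data, d[1] * d[2], d[3])
            lines <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
            writeLines(c(paste(tt$channel_labels, collapse = ","), lines),
                       file.path(sdir, paste0(grp, ".csv")))
            meta[[sid]][[grp]] <- list(trials = d[1], bins = d[2], channels = d[3],
                                       bin_width_s = tt$bin_width,
                                       channel_labels = tt$channel_labels)
        }
    }
    jsonlite::write_json(meta, file.path(dir, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' Read sessions from the plain-text directory container
#'
#' Inverse of [write_sessions()].
#'
#' @param dir directory written by [write_sessions()].
#' @return Named list of sessions with `neural` and `emg` [trial_tensor()]s.
#' @export
read_sessions <- function(dir) {
    meta_path <- file.path(dir, "meta.json")
    if (!file.exists(meta_path)) stop("no meta.json found in ", dir)
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    out <- list()
    for (sid in names(meta)) {
        sdir <- file.path(dir, paste0("session_", sid))
        sess <- list()
        for (grp in c("neural", "emg")) {
            mi <- meta[[sid]][[grp]]
            lines <- readLines(file.path(sdir, paste0(grp, ".csv")))
            labels <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
            m <- do.call(rbind, lapply(strsplit(lines[-1], ",", fixed = TRUE),
                                       as.numeric))
            arr <- array(m, c(mi$trials, mi$bins, mi$channels))
            sess[[grp]] <- trial_tensor(arr, mi$bin_width_s, labels, sid)
        }
        out[[sid]] <- sess
    }
    out
}

#' Write per-attempt metric trajectories as tidy CSV
#'
#' One row per (attempt, step, set) with the pooled R-squared and correlation.
#'
#' @param attempts list of [train_attempt()] records (e.g. `fit$attempts`).
#' @param path output CSV path.
#' @return The tidy data.frame, invisibly.
#' @export
write_metrics_csv <- function(attempts, path) {
    rows <- list()
    for (k in seq_along(attempts)) {
        m <- attempts[[k]]$metrics
        steps <- seq_len(nrow(m)) - 1L
        for (set in c("train", "a", "b")) {
            rows[[length(rows) + 1L]] <- data.frame(
                attempt = k, step = steps, set = set,
                r2 = m[[paste0("r2_", set)]], corr = m[[paste0("corr_", set)]])
        }
    }
    df <- do.call(rbind, rows)
    df$r2 <- signif(df$r2, 6); df$corr <- signif(df$corr, 6)
    write.csv(df, path, row.names = FALSE)
    invisible(df)
}

#' Write session scores as CSV
#'
#' @param scores named list of `session_score` objects (name = label), or a
#'   single score.
#' @param path output CSV path.
#' @return The data.frame, invisibly.
#' @export
write_scores_csv <- function(scores, path) {
    if (inherits(scores, "session_score")) scores <- list(score = scores)
    df <- do.call(rbind, lapply(names(scores), function(nm) {
        s <- scores[[nm]]
        data.frame(label = nm,
                   a_max_on_b_r2 = s$a_max_on_b["r2"], b_max_on_a_r2 = s$b_max_on_a["r2"],
                   overall_r2 = s$overall_r2, overall_corr = s$overall_corr,
                   a_attempt = s$a_attempt, b_attempt = s$b_attempt)
    }))
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, 6)
    write.csv(df, path, row.names = FALSE)
    invisible(df)
}
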