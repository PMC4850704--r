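# Experiment drivers composing the pipeline modules: short-term,
# time-effect and fatigue evaluations.

task_order <- c("flexion", "extension", "supination", "pronation")

# Canonical recording order (tasks in fixed order, levels ascending) so
# results do not depend on the order recordings appear in the session.
sort_recordings <- function(recs) {
  key <- order(match(vapply(recs, `[[`, character(1), "task"), task_order),
               vapply(recs, function(r)
                 ifelse(is.na(r$target_level), 9, r$target_level), numeric(1)))
  recs[key]
}

# Preprocess a list of recordings; returns filtered recordings and the
# per-recording artifact channel sets used for map interpolation.
prep_recordings <- function(recs, preprocess = TRUE, suppress_line = TRUE,
                            thresholds = quality_thresholds()) {
  bad <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    if (preprocess) {
      p <- preprocess_recording(recs[[i]], thresholds = thresholds,
                                suppress_line = suppress_line)
      recs[[i]] <- p$recording
      bad[[i]] <- p$quality$bad
    } else bad[[i]] <- integer(0)
  }
  list(recordings = recs, bad = bad)
}

# Subsample a class of a feature table to n rows (deterministic under the
# current RNG state).
subsample_class <- function(ft, class, n) {
  idx <- which(ft$class == class)
  if (length(idx) > n) {
    drop <- sample(idx, length(idx) - n)
    ft <- ft[-drop, , drop = FALSE]
  }
  ft
}

feature_cols <- function(ft)
  setdiff(colnames(ft), c("class", "recording", "task", "level", "window"))

#' Short-term identification protocol
#'
#' Trains and evaluates classifiers on the submaximal set alone: 20
#' torque-selected epochs per task x level, 60 rest (NoAct) epochs, and the
#' iterated balanced 50/50 LDA evaluation. Scheme `"task5"` classifies the
#' four tasks plus NoAct (effort levels mixed within each task class);
#' `"task_level13"` classifies the 13 task x level classes (NoAct
#' subsampled to the per-class count for balance). For `"task5"` the
#' per-effort-level sensitivity and precision of the mixed-level classifier
#' are tallied as well.
#'
#' @param session An [emg_session()] (or the list returned by
#'   [simulate_session()]).
#' @param feature_set `"I"`, `"I+CG"` or `"Diff"`.
#' @param scheme `"task5"` or `"task_level13"`.
#' @param n_iter Evaluation iterations (default 1000).
#' @param seed Seed controlling the whole run.
#' @param n_epochs,n_rest Epochs per task x level and total rest epochs.
#' @param window_s Analysis window, s.
#' @param preprocess,suppress_line Preprocessing switches (band-pass is
#'   always applied when `preprocess = TRUE`).
#' @param lambda LDA ridge.
#' @return An object of class `emg_protocol` with the [evaluate_iterated()]
#'   summary in `$evaluation` and, for `"task5"`, per-level indices in
#'   `$per_level`.
#' @export
run_short_term <- function(session, feature_set = "I+CG",
                           scheme = c("task5", "task_level13"),
                           n_iter = 1000, seed = 1,
                           n_epochs = 20, n_rest = 60, window_s = 0.250,
                           preprocess = TRUE, suppress_line = TRUE,
                           lambda = 1e-6) {
  scheme <- match.arg(scheme)
  if (!inherits(session, "emg_session")) session <- session$session
  sub <- sort_recordings(session_subset(session, "submaximal"))
  if (!length(sub)) stop("run_short_term: no submaximal recordings", call. = FALSE)
  pp <- prep_recordings(sub, preprocess, suppress_line)
  eps <- lapply(seq_along(pp$recordings), function(i)
    select_submax_epochs(pp$recordings[[i]], n = n_epochs,
                         window_s = window_s, recording_index = i))
  rest <- select_rest_epochs(pp$recordings, n_total = n_rest,
                             window_s = window_s)
  all_eps <- do.call(combine_epochs, c(eps, list(rest), scheme = scheme))
  ft <- build_feature_table(pp$recordings, all_eps, feature_set,
                            window_s = window_s, bad_channels = pp$bad)
  set.seed(seed)
  if (scheme == "task5") {
    y <- ifelse(ft$class == "NoAct", "NoAct", ft$task)
    n_min <- min(table(y))   # balance classes (NoAct can exceed the tasks)
    keep <- unlist(lapply(split(seq_along(y), y), function(ix)
      if (length(ix) > n_min) sort(sample(ix, n_min)) else ix))
    ft <- ft[sort(keep), , drop = FALSE]
    y <- y[sort(keep)]
    cond <- ifelse(is.na(ft$level), "NoAct",
                   sprintf("%02d", round(100 * ft$level)))
    ev <- evaluate_iterated(ft[, feature_cols(ft)], y, n_iter = n_iter,
                            seed = seed, lambda = lambda, condition = cond)
    per_level <- ev$condition
  } else {
    counts <- table(ft$class)
    ft <- subsample_class(ft, "NoAct", min(counts[names(counts) != "NoAct"]))
    ev <- evaluate_iterated(ft[, feature_cols(ft)], ft$class, n_iter = n_iter,
                            seed = seed, lambda = lambda)
    per_level <- NULL
  }
  structure(list(protocol = "short_term", feature_set = feature_set,
                 scheme = scheme, evaluation = ev, per_level = per_level,
                 n_iter = n_iter, seed = seed),
            class = "emg_protocol")
}

# Shared machinery for the time-effect and fatigue protocols: iterate
# custom balanced splits over precomputed feature tables.
index_summary <- function(per_iter) {
  list(per_iter = per_iter,
       mean = apply(per_iter, c(2, 3), mean, na.rm = TRUE),
       sd = apply(per_iter, c(2, 3), stats::sd, na.rm = TRUE),
       macro = colMeans(apply(per_iter, c(2, 3), mean, na.rm = TRUE),
                        na.rm = TRUE))
}

#' Time-effect protocol
#'
#' Trains on the submaximal set (half the epochs of every task x level plus
#' half the NoAct epochs, effort levels mixed) and validates under two
#' conditions: (A) the held-out 50 %MVC submaximal epochs with held-out
#' part-1 NoAct epochs, and (B) the time-effect set — the first 20 % TDC of
#' the endurance contractions — with NoAct epochs from the part-2 rest
#' prefixes. Comparing A and B isolates the effect of elapsed time
#' (gel drying, electrode-skin changes) on identification.
#'
#' @inheritParams run_short_term
#' @param n_val Validation observations per class and condition
#'   (default 10).
#' @return `emg_protocol` with `$condition_a` and `$condition_b` summaries.
#' @export
run_time_effect <- function(session, feature_set = "I+CG", n_iter = 1000,
                            seed = 1, n_epochs = 20, n_rest = 60,
                            n_val = 10, window_s = 0.250,
                            preprocess = TRUE, suppress_line = TRUE,
                            lambda = 1e-6) {
  if (!inherits(session, "emg_session")) session <- session$session
  sub <- sort_recordings(session_subset(session, "submaximal"))
  endu <- sort_recordings(session_subset(session, "endurance"))
  if (!length(endu)) stop("run_time_effect: no endurance recordings", call. = FALSE)
  pp_s <- prep_recordings(sub, preprocess, suppress_line)
  pp_e <- prep_recordings(endu, preprocess, suppress_line)

  eps_s <- lapply(seq_along(pp_s$recordings), function(i)
    select_submax_epochs(pp_s$recordings[[i]], n = n_epochs,
                         window_s = window_s, recording_index = i))
  rest_s <- select_rest_epochs(pp_s$recordings, n_total = n_rest,
                               window_s = window_s)
  ft_sub <- build_feature_table(pp_s$recordings,
                                do.call(combine_epochs, c(eps_s, list(rest_s))),
                                feature_set, window_s, pp_s$bad)
  eps_te <- lapply(seq_along(pp_e$recordings), function(i)
    time_effect_subset(pp_e$recordings[[i]], window_s = window_s,
                       recording_index = i))
  n_rest_b <- min(n_rest, 12 * length(pp_e$recordings))
  rest_te <- select_rest_epochs(pp_e$recordings, n_total = n_rest_b,
                                window_s = window_s)
  ft_te <- build_feature_table(pp_e$recordings,
                               do.call(combine_epochs, c(eps_te, list(rest_te))),
                               feature_set, window_s, pp_e$bad)
  fc <- feature_cols(ft_sub)
  lev <- c(task_order, "NoAct")
  y_sub <- factor(ifelse(ft_sub$class == "NoAct", "NoAct", ft_sub$task), lev)
  y_te <- factor(ifelse(ft_te$class == "NoAct", "NoAct", ft_te$task), lev)
  k <- length(lev)
  pi_a <- array(NA_real_, c(n_iter, k, 4),
                dimnames = list(NULL, lev, c("Acc", "S", "P", "SP")))
  pi_b <- pi_a
  groups_sub <- interaction(ft_sub$class, drop = TRUE)  # task_level or NoAct
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    # train: half of each task x level group, half of part-1 NoAct
    tr <- unlist(lapply(split(seq_len(nrow(ft_sub)), groups_sub),
                        function(ix) sample(ix, length(ix) %/% 2L)))
    va_pool <- setdiff(seq_len(nrow(ft_sub)), tr)
    fit <- train_lda(as.matrix(ft_sub[tr, fc]), y_sub[tr], lambda = lambda)
    # condition A: held-out 50 %MVC epochs + held-out NoAct, n_val per class
    va_a <- integer(0)
    for (l in lev) {
      pool <- va_pool[y_sub[va_pool] == l &
                        (l == "NoAct" | ft_sub$level[va_pool] %in% 0.50)]
      va_a <- c(va_a, sample(pool, min(n_val, length(pool))))
    }
    pred_a <- predict(fit, as.matrix(ft_sub[va_a, fc]))
    pi_a[it, , ] <- as.matrix(performance_indices(
      table(y_sub[va_a], pred_a))[, c("Acc", "S", "P", "SP")])
    # condition B: time-effect epochs + part-2 NoAct, n_val per class
    va_b <- integer(0)
    for (l in lev) {
      pool <- which(y_te == l)
      va_b <- c(va_b, sample(pool, min(n_val, length(pool))))
    }
    pred_b <- predict(fit, as.matrix(ft_te[va_b, fc]))
    pi_b[it, , ] <- as.matrix(performance_indices(
      table(y_te[va_b], pred_b))[, c("Acc", "S", "P", "SP")])
  }
  structure(list(protocol = "time_effect", feature_set = feature_set,
                 levels = lev,
                 condition_a = index_summary(pi_a),
                 condition_b = index_summary(pi_b),
                 n_iter = n_iter, seed = seed),
            class = "emg_protocol")
}

#' Muscle-fatigue protocol
#'
#' Splits each endurance contraction into five equal TDC segments, trains
#' on the first segment (0-20 % TDC, half its epochs; NoAct from the
#' part-2 rest prefixes) and validates on every segment separately with
#' equal class counts, tracking the performance indices along the
#' contraction.
#'
#' @inheritParams run_time_effect
#' @param k Number of TDC segments (default 5).
#' @return `emg_protocol` with `$segments`, a list of per-quintile
#'   summaries, and `$segment_mean`, the segments x indices macro matrix.
#' @export
run_fatigue <- function(session, feature_set = "I+CG", n_iter = 1000,
                        seed = 1, k = 5, n_val = 10, window_s = 0.250,
                        preprocess = TRUE, suppress_line = TRUE,
                        lambda = 1e-6) {
  if (!inherits(session, "emg_session")) session <- session$session
  endu <- sort_recordings(session_subset(session, "endurance"))
  if (length(endu) < 2L)
    stop("run_fatigue: need endurance recordings for the tasks", call. = FALSE)
  pp <- prep_recordings(endu, preprocess, suppress_line)
  segs <- lapply(pp$recordings, tdc_segments, k = k, window_s = window_s)
  # feature table over all contraction + rest windows of every recording
  eps <- list()
  for (i in seq_along(pp$recordings)) {
    rec <- pp$recordings[[i]]
    win <- as.integer(round(window_s * rec$fs))
    n_rest_w <- as.integer(rec$rest_s * rec$fs) %/% win
    all_w <- seq_len(ncol(rec$signals) %/% win)
    eps[[i]] <- structure(list(epochs = data.frame(
      recording = i, window = all_w,
      class = ifelse(all_w <= n_rest_w, "NoAct", rec$task),
      task = rec$task, level = NA_real_), scheme = "fatigue"),
      class = "epoch_set")
  }
  ft <- build_feature_table(pp$recordings, do.call(combine_epochs, eps),
                            feature_set, window_s, pp$bad)
  fc <- feature_cols(ft)
  tasks <- vapply(pp$recordings, `[[`, character(1), "task")
  lev <- c(intersect(task_order, tasks), "NoAct")
  kcl <- length(lev)
  # window pools: per class, per segment (NoAct pooled over recordings)
  pool <- function(cls, s) {
    if (cls == "NoAct") return(which(ft$class == "NoAct"))
    i <- which(tasks == cls)
    which(ft$recording == i & ft$window %in% segs[[i]][[s]])
  }
  n_tr <- min(vapply(seq_along(lev), function(ci)
    length(pool(lev[ci], 1L)), integer(1))) %/% 2L
  per_seg <- lapply(seq_len(k), function(s)
    array(NA_real_, c(n_iter, kcl, 4),
          dimnames = list(NULL, lev, c("Acc", "S", "P", "SP"))))
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    tr <- integer(0)
    for (cls in lev) tr <- c(tr, sample(pool(cls, 1L), n_tr))
    fit <- train_lda(as.matrix(ft[tr, fc]),
                     factor(ft$class[tr], lev), lambda = lambda)
    for (s in seq_len(k)) {
      va <- integer(0)
      for (cls in lev) {
        p <- setdiff(pool(cls, s), tr)
        va <- c(va, sample(p, min(n_val, length(p))))
      }
      pred <- predict(fit, as.matrix(ft[va, fc]))
      per_seg[[s]][it, , ] <- as.matrix(performance_indices(
        table(factor(ft$class[va], lev), pred))[, c("Acc", "S", "P", "SP")])
    }
  }
  segments <- lapply(per_seg, index_summary)
  segment_mean <- t(vapply(segments, `[[`, numeric(4), "macro"))
  rownames(segment_mean) <- sprintf("%d-%d%%TDC", (seq_len(k) - 1) * 100 %/% k,
                                    seq_len(k) * 100 %/% k)
  structure(list(protocol = "fatigue", feature_set = feature_set,
                 levels = lev, segments = segments,
                 segment_mean = segment_mean,
                 n_iter = n_iter, seed = seed),
            class = "emg_protocol")
}

#' @export
print.emg_protocol <- function(x, ...) {
  cat(sprintf("Protocol '%s' (feature set %s, %d iterations, seed %d)\n",
              x$protocol, x$feature_set, x$n_iter, x$seed))
  if (x$protocol == "short_term") {
    cat(sprintf("  macro: Acc %.3f  S %.3f  P %.3f  SP %.3f\n",
                x$evaluation$macro["Acc"], x$evaluation$macro["S"],
                x$evaluation$macro["P"], x$evaluation$macro["SP"]))
  } else if (x$protocol == "time_effect") {
    cat(sprintf("  condition A (same-part validation): S %.3f\n",
                x$condition_a$macro["S"]))
    cat(sprintf("  condition B (time-effect set):      S %.3f\n",
                x$condition_b$macro["S"]))
  } else if (x$protocol == "fatigue") {
    print(round(x$segment_mean, 3))
  }
  invisible(x)
}

#' @export
plot.emg_protocol <- function(x, index = "S", ...) {
  if (x$protocol == "fatigue") {
    graphics::plot(seq_len(nrow(x$segment_mean)), x$segment_mean[, index],
                   type = "b", xlab = "TDC segment", ylab = index,
                   ylim = c(0, 1), ...)
  } else if (x$protocol == "time_effect") {
    graphics::barplot(c(A = x$condition_a$macro[index],
                        B = x$condition_b$macro[index]),
                      ylab = index, ylim = c(0, 1), ...)
  } else {
    graphics::barplot(x$evaluation$mean[, index], ylab = index,
                      ylim = c(0, 1), las = 2, ...)
  }
  invisible(x)
}
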