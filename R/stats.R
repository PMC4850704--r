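#' Paired Student's t-test
#'
#' Classical two-sided paired t-test on the differences, as used for the
#' pairwise feature-set comparisons.
#'
#' @param a,b Paired numeric samples of equal length (n >= 2).
#' @return List with `t`, `df`, `p` and the mean difference `estimate`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  if (stats::sd(d) == 0)
    stop("paired_ttest: zero variance of the differences", call. = FALSE)
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, estimate = unname(ht$estimate))
}

# Greenhouse-Geisser adjusted p-value for an F statistic: both degrees of
# freedom are multiplied by epsilon.
gg_adjusted_p <- function(F, df1, df2, eps)
  stats::pf(F, eps * df1, eps * df2, lower.tail = FALSE)

#' Mixed-design repeated-measures ANOVA with sphericity handling
#'
#' One within-subject factor (the repeated measures, e.g. per-task or
#' per-segment indices) and one optional between-subject factor (e.g. the
#' feature set). Within-subject effects are accompanied by Mauchly's
#' sphericity test and the Greenhouse-Geisser epsilon; when Mauchly rejects
#' sphericity (p < 0.05) the reported `p_adj` uses the epsilon-corrected
#' degrees of freedom, otherwise the unadjusted p is kept. The
#' uncorrected and corrected p-values are both always reported.
#'
#' @param data Long-format data frame.
#' @param dv Column name of the response.
#' @param subject Column identifying subjects.
#' @param within Column of the repeated-measures factor.
#' @param between Optional column of the grouping factor (`NULL` for a
#'   purely within design).
#' @return An object of class `emg_rm_anova`: a data frame with one row per
#'   effect (`between`, `within`, `within:between`) and columns `F`, `df1`,
#'   `df2`, `p`, `mauchly_W`, `mauchly_p`, `epsilon_gg`, `p_gg`, `p_adj`,
#'   `df1_adj`, `df2_adj`.
#' @export
rm_anova_mixed <- function(data, dv, subject, within, between = NULL) {
  data[[subject]] <- factor(data[[subject]])
  data[[within]] <- factor(data[[within]])
  wl <- levels(data[[within]])
  k <- length(wl)
  subs <- levels(data[[subject]])
  # complete balanced wide table
  wide <- matrix(NA_real_, length(subs), k, dimnames = list(subs, wl))
  for (i in seq_len(nrow(data)))
    wide[as.character(data[[subject]][i]), as.character(data[[within]][i])] <-
      data[[dv]][i]
  if (anyNA(wide))
    stop("rm_anova_mixed: design is incomplete (missing cells)", call. = FALSE)
  grp <- NULL
  if (!is.null(between)) {
    g <- tapply(as.character(data[[between]]), data[[subject]],
                function(v) unique(v))
    if (any(lengths(g) != 1L))
      stop("rm_anova_mixed: a subject appears in several groups", call. = FALSE)
    grp <- factor(unlist(g[subs]))
    if (any(table(grp) < 2L))
      stop("rm_anova_mixed: need >= 2 subjects per group", call. = FALSE)
  }
  idata <- data.frame(measure = factor(wl, levels = wl))
  # type-III tests require sum-to-zero contrasts on the between factor
  mod <- if (is.null(grp)) stats::lm(wide ~ 1)
         else stats::lm(wide ~ grp, contrasts = list(grp = "contr.sum"))
  av <- car::Anova(mod, idata = idata, idesign = ~measure, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  uni <- s$univariate.tests
  sph <- s$sphericity.tests
  adj <- s$pval.adjustments
  effect_row <- function(name, label) {
    if (!name %in% rownames(uni)) return(NULL)
    F <- uni[name, "F value"]; df1 <- uni[name, "num Df"]
    df2 <- uni[name, "den Df"]; p <- uni[name, "Pr(>F)"]
    within_eff <- grepl("measure", name)
    W <- NA_real_; Wp <- NA_real_; eps <- NA_real_; p_gg <- NA_real_
    if (within_eff) {
      if (k == 2L) {                     # sphericity vacuous with 2 levels
        W <- 1; Wp <- 1; eps <- 1; p_gg <- p
      } else {
        W <- sph[name, "Test statistic"]; Wp <- sph[name, "p-value"]
        eps <- adj[name, "GG eps"]
        p_gg <- gg_adjusted_p(F, df1, df2, eps)
      }
    }
    use_gg <- within_eff && !is.na(Wp) && Wp < 0.05
    data.frame(effect = label, F = F, df1 = df1, df2 = df2, p = p,
               mauchly_W = W, mauchly_p = Wp, epsilon_gg = eps, p_gg = p_gg,
               p_adj = if (use_gg) p_gg else p,
               df1_adj = if (use_gg) eps * df1 else df1,
               df2_adj = if (use_gg) eps * df2 else df2,
               row.names = NULL)
  }
  rows <- rbind(
    if (!is.null(grp)) effect_row("grp", "between"),
    effect_row("measure", "within"),
    if (!is.null(grp)) effect_row("grp:measure", "within:between"))
  structure(rows, class = c("emg_rm_anova", "data.frame"))
}

#' @export
print.emg_rm_anova <- function(x, ...) {
  cat("Mixed repeated-measures ANOVA (Greenhouse-Geisser when Mauchly p < 0.05)\n")
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Compare two protocol runs index-by-index with a paired test
#'
#' Pairs the per-iteration macro values of a performance index from two
#' evaluations (e.g. two feature sets on the same session and seed) and
#' applies the paired t-test.
#'
#' @param eval_a,eval_b `emg_eval` objects from [evaluate_iterated()].
#' @param index One of `"Acc"`, `"S"`, `"P"`, `"SP"`.
#' @return The [paired_ttest()] result.
#' @export
compare_evaluations <- function(eval_a, eval_b, index = "S") {
  stopifnot(inherits(eval_a, "emg_eval"), inherits(eval_b, "emg_eval"))
  a <- apply(eval_a$per_iter[, , index, drop = FALSE], 1, mean, na.rm = TRUE)
  b <- apply(eval_b$per_iter[, , index, drop = FALSE], 1, mean, na.rm = TRUE)
  paired_ttest(a, b)
}
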