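# The statistical layer: paired t with Cohen's d, Mann-Whitney with rank
# effect size, Kruskal-Wallis with Dunn post hocs, and linear mixed models
# with per-term F tests (delegated to nlme) and Tukey-corrected pairwise
# contrasts.

#' Statistical test result container
#'
#' @param statistic_name one of "t", "U", "H", "F", "W".
#' @param statistic test statistic value.
#' @param df degrees of freedom (possibly fractional; length 2 for F).
#' @param p two-sided p-value.
#' @param effect_name effect-size label ("cohens_d", "rank_r",
#'   "epsilon_sq", "none").
#' @param effect effect-size value (NA when "none").
#' @param extra optional list of method-specific extras.
#' @return an object of class `stat_result`.
#' @export
stat_result <- function(statistic_name, statistic, df, p,
                        effect_name = "none", effect = NA_real_,
                        extra = list()) {
  structure(list(statistic_name = statistic_name, statistic = statistic,
                 df = df, p = p, effect_name = effect_name,
                 effect = effect, extra = extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s = %.4g, df = %s, p = %.4g",
              x$statistic_name, x$statistic,
              paste(signif(x$df, 4), collapse = ", "), x$p))
  if (x$effect_name != "none")
    cat(sprintf(", %s = %.3g", x$effect_name, x$effect))
  cat("\n")
  invisible(x)
}

#' Paired t test with Cohen's d
#'
#' t = mean(d) / SE(d) with df = n - 1; Cohen's d for the paired design
#' uses the SD of the differences (so d = t / sqrt(n)).
#'
#' @param x,y paired numeric samples of equal length >= 3, no missing
#'   pairs.
#' @return a [stat_result].
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || anyNA(x) || anyNA(y))
    abort_canicoh("x and y must be complete and of equal length",
                  "canicoh_invalid_input")
  n <- length(x)
  if (n < 3)
    abort_canicoh("need at least 3 pairs", "canicoh_degenerate_input")
  d <- x - y
  s <- stats::sd(d)
  if (s == 0)
    abort_canicoh("zero variance of pair differences",
                  "canicoh_degenerate_input")
  t <- mean(d) / (s / sqrt(n))
  stat_result("t", t, n - 1, 2 * stats::pt(-abs(t), n - 1),
              "cohens_d", mean(d) / s)
}

#' Mann-Whitney U test with rank effect size
#'
#' U is reported as max(U1, U2); p from the normal approximation with tie
#' correction (no continuity correction, so the effect size is exactly
#' r = |z| / sqrt(N)); df reported as N - 2 for parity with common
#' reporting.
#'
#' @param x,y independent samples, each >= 2 values.
#' @return a [stat_result]; `extra` holds U1, U2 and z.
#' @export
mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2)
    abort_canicoh("both samples need >= 2 values", "canicoh_invalid_input")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1)
    abort_canicoh("all values tied", "canicoh_degenerate_input")
  r <- rank(pooled)
  R1 <- sum(r[seq_len(n1)])
  U1 <- R1 - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  N <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
  z <- (U1 - n1 * n2 / 2) / sigma
  p <- 2 * stats::pnorm(-abs(z))
  stat_result("U", max(U1, U2), N - 2, p, "rank_r", abs(z) / sqrt(N),
              extra = list(U1 = U1, U2 = U2, z = z))
}

#' Kruskal-Wallis test with Dunn post hocs (Bonferroni)
#'
#' H with tie correction and a chi-square p at df = k - 1, followed by all
#' pairwise Dunn z tests with Bonferroni multiplier k (k - 1) / 2.
#'
#' @param groups list of >= 3 numeric samples, each >= 2 values.
#' @return a [stat_result]; `extra$dunn` is a data.frame of pairwise
#'   comparisons (group1, group2, z, p_adj).
#' @export
kruskal_dunn <- function(groups) {
  if (!is.list(groups) || length(groups) < 3)
    abort_canicoh("need at least 3 groups", "canicoh_invalid_input")
  if (any(vapply(groups, length, 0L) < 2))
    abort_canicoh("each group needs >= 2 values", "canicoh_invalid_input")
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  pooled <- unlist(groups)
  g <- rep(names(groups), vapply(groups, length, 0L))
  N <- length(pooled)
  r <- rank(pooled)
  Rbar <- tapply(r, g, mean)[names(groups)]
  n <- vapply(groups, length, 0L)
  H <- 12 / (N * (N + 1)) * sum(n * (Rbar - (N + 1) / 2)^2)
  ties <- table(pooled)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr > 0) H <- H / corr
  p <- stats::pchisq(H, k - 1, lower.tail = FALSE)
  # Dunn pairwise z with tie correction
  s2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  m <- k * (k - 1) / 2
  pairs <- utils::combn(names(groups), 2)
  dunn <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ])
  dunn$z <- (Rbar[dunn$group1] - Rbar[dunn$group2]) /
    sqrt(s2 * (1 / n[dunn$group1] + 1 / n[dunn$group2]))
  dunn$p_adj <- pmin(1, m * 2 * stats::pnorm(-abs(dunn$z)))
  rownames(dunn) <- NULL
  stat_result("H", H, k - 1, p, "none", extra = list(dunn = dunn))
}

#' Linear mixed model with per-term F tests
#'
#' REML fit delegated to [nlme::lme()]; each fixed term is reported with a
#' marginal F test using nlme's containment denominator degrees of freedom
#' (for balanced designs these coincide with the Kenward-Roger and
#' Satterthwaite approximations; neither approximation is available
#' offline, recorded as `df_method = "containment"`). When the grouping
#' factor has a single level the model degenerates to ordinary least
#' squares and classical F tests.
#'
#' @param table data.frame with the response, fixed-effect covariates, and
#'   grouping column.
#' @param fixed fixed-effects formula, e.g. `intelligibility ~ word_coh +
#'   speech_type`.
#' @param random random-effects one-sided formula, e.g. `~ 1 | subject`.
#' @param tukey_term optional factor term for Tukey-corrected pairwise
#'   contrasts.
#' @return list: `terms` (named list of [stat_result], one per fixed
#'   term), `fit`, `df_method`, and `tukey` (data.frame) when requested.
#' @export
fit_lmm <- function(table, fixed, random, tukey_term = NULL) {
  grp_var <- all.vars(random)[length(all.vars(random))]
  n_levels <- length(unique(table[[grp_var]]))
  if (n_levels < 2) {
    fit <- stats::lm(fixed, data = table)
    an <- stats::anova(fit)
    terms <- list()
    for (tm in setdiff(rownames(an), "Residuals")) {
      terms[[tm]] <- stat_result(
        "F", an[tm, "F value"],
        c(an[tm, "Df"], an["Residuals", "Df"]), an[tm, "Pr(>F)"])
    }
    return(list(terms = terms, fit = fit, df_method = "classical"))
  }
  fit <- tryCatch(
    nlme::lme(fixed = fixed, random = random, data = table,
              method = "REML"),
    error = function(e) abort_canicoh(
      paste("mixed model failed to converge:", conditionMessage(e)),
      "canicoh_nonconvergence"))
  # near-zero random-effect variance => flag singular fit, keep going
  re_sd <- suppressWarnings(
    tryCatch(as.numeric(nlme::VarCorr(fit)[1, "StdDev"]),
             error = function(e) NA_real_))
  singular <- is.finite(re_sd) && re_sd < 1e-6 * stats::sigma(fit)
  an <- stats::anova(fit, type = "marginal")
  terms <- list()
  for (tm in setdiff(rownames(an), "(Intercept)")) {
    terms[[tm]] <- stat_result(
      "F", an[tm, "F-value"], c(an[tm, "numDF"], an[tm, "denDF"]),
      an[tm, "p-value"])
  }
  out <- list(terms = terms, fit = fit, df_method = "containment",
              singular = singular)
  if (!is.null(tukey_term))
    out$tukey <- tukey_contrasts(fit, tukey_term, table,
                                 an[tukey_term, "denDF"])
  out
}

# Tukey-corrected pairwise comparisons of the levels of `term` from an lme
# fit: studentized-range p-values on the fixed-effect contrasts.
tukey_contrasts <- function(fit, term, table, den_df) {
  lv <- levels(factor(table[[term]]))
  k <- length(lv)
  beta <- nlme::fixef(fit)
  V <- stats::vcov(fit)
  # model matrix rows for each level at reference values of other terms
  mm <- function(level) {
    d <- table[1, , drop = FALSE]
    d[[term]] <- factor(level, levels = lv)
    stats::model.matrix(stats::formula(fit)[-2], d)
  }
  rows <- lapply(lv, mm)
  pairs <- utils::combn(k, 2)
  res <- data.frame(group1 = lv[pairs[1, ]], group2 = lv[pairs[2, ]])
  est <- se <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    L <- rows[[pairs[1, j]]] - rows[[pairs[2, j]]]
    est[j] <- drop(L %*% beta)
    se[j] <- sqrt(drop(L %*% V %*% t(L)))
  }
  res$estimate <- est
  res$t <- est / se
  res$df <- den_df
  res$p_adj <- stats::ptukey(abs(res$t) * sqrt(2), k, den_df,
                             lower.tail = FALSE)
  res
}

#' Read a paired-register table and run the paired comparisons
#'
#' Convenience wrapper over a table shaped like
#' [gen_paired_speech_table()]'s output (CSV or data.frame): paired t of
#' the ADS vs DDS speech rate, and of mean F0.
#'
#' @param table data.frame or path to a CSV with columns `ads_rate_hz`,
#'   `dds_rate_hz`, `ads_f0_hz`, `dds_f0_hz`.
#' @return list(rate = [stat_result], f0 = [stat_result]).
#' @export
paired_register_tests <- function(table) {
  if (is.character(table)) table <- utils::read.csv(table)
  list(rate = paired_t(table$ads_rate_hz, table$dds_rate_hz),
       f0 = paired_t(table$ads_f0_hz, table$dds_f0_hz))
}
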