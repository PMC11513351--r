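#' One-way analysis of variance
#'
#' Standard between/within decomposition by direct summation:
#' `ss_between = sum n_g (mean_g - grand)^2`,
#' `ss_within = sum sum (x - mean_g)^2`, F from the mean squares, p from
#' the upper tail of the F distribution.
#'
#' @param groups List of numeric vectors (>= 2 groups, each with >= 2
#'   values), e.g. per-variant fold accuracies.
#' @return An `anova_result`: sums of squares, degrees of freedom, mean
#'   squares, `f`, `p`.
#' @export
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 5)))
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes < 2))
    stop("every group needs at least 2 values", call. = FALSE)
  all_x <- unlist(groups, use.names = FALSE)
  grand <- mean(all_x)
  means <- vapply(groups, mean, numeric(1))
  ss_b <- sum(sizes * (means - grand)^2)
  ss_w <- sum(vapply(seq_along(groups),
                     function(g) sum((groups[[g]] - means[g])^2), numeric(1)))
  df_b <- length(groups) - 1L
  df_w <- length(all_x) - length(groups)
  ms <- f_from_sums(ss_b, df_b, ss_w, df_w)
  structure(list(ss_between = ss_b, ss_within = ss_w,
                 ss_total = ss_b + ss_w,
                 df_between = df_b, df_within = df_w,
                 df_total = df_b + df_w,
                 ms_between = ms$ms_b, ms_within = ms$ms_w, f = ms$f,
                 p = stats::pf(ms$f, df_b, df_w, lower.tail = FALSE)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4f, p = %.3g\n",
              x$df_between, x$df_within, x$f, x$p))
  cat(sprintf("  SS between %.4f, within %.4f, total %.4f\n",
              x$ss_between, x$ss_within, x$ss_total))
  invisible(x)
}

#' Mean squares and F-statistic from printed sums of squares
#'
#' Recovers `ms = ss / df` and `F = ms_between / ms_within` from a reported
#' ANOVA table row.
#'
#' @param ss_b,df_b Between-groups sum of squares and degrees of freedom.
#' @param ss_w,df_w Within-groups sum of squares and degrees of freedom.
#' @return List with `ms_b`, `ms_w`, `f`.
#' @export
#' @examples
#' f_from_sums(1423.19, 4, 1863.92, 155)$f  # ~29.59
f_from_sums <- function(ss_b, df_b, ss_w, df_w) {
  if (df_b <= 0 || df_w <= 0)
    stop("degrees of freedom must be positive", call. = FALSE)
  if (ss_b < 0 || ss_w <= 0)
    stop("sums of squares must be positive", call. = FALSE)
  ms_b <- ss_b / df_b
  ms_w <- ss_w / df_w
  list(ms_b = ms_b, ms_w = ms_w, f = ms_b / ms_w)
}

#' Games-Howell post-hoc pairwise comparisons
#'
#' For every pair of groups: mean difference, standard error
#' `sqrt(v_a / n_a + v_b / n_b)` from the per-group (unbiased) variances,
#' Welch-Satterthwaite degrees of freedom, p-value and confidence interval
#' from the studentized-range distribution with the full number of groups.
#' No equal-variance assumption. On two groups the point estimate and SE
#' coincide with a Welch two-sample comparison.
#'
#' @param groups Named list of numeric vectors (>= 2 values and positive
#'   variance each).
#' @param conf_level Confidence level (default 0.95).
#' @param bootstrap_bca Optional resample count: if positive, adds seeded
#'   bias estimates and BCa confidence intervals for each mean difference
#'   (an approximation layered on the analytic test).
#' @param seed Seed for the bootstrap.
#' @return Data frame with one row per pair: `group_a`, `group_b`,
#'   `mean_difference`, `standard_error`, `df`, `p`, `ci_low`, `ci_high`
#'   (and `bias`, `bca_low`, `bca_high` when bootstrapped);
#'   `method = "games_howell"` attribute.
#' @export
games_howell <- function(groups, conf_level = 0.95, bootstrap_bca = 0,
                         seed = 1L) {
  kk <- length(groups)
  if (kk < 2) stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_len(kk))
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group needs at least 2 values", call. = FALSE)
  vars <- vapply(groups, stats::var, numeric(1))
  if (any(vars <= 0)) stop("zero-variance group", call. = FALSE)
  means <- vapply(groups, mean, numeric(1))
  pairs <- utils::combn(kk, 2)
  out <- data.frame()
  for (pi in seq_len(ncol(pairs))) {
    a <- pairs[1, pi]; b <- pairs[2, pi]
    va <- vars[a] / sizes[a]; vb <- vars[b] / sizes[b]
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (sizes[a] - 1) + vb^2 / (sizes[b] - 1))
    diff <- means[a] - means[b]
    tstat <- abs(diff) / se
    p <- stats::ptukey(tstat * sqrt(2), kk, df, lower.tail = FALSE)
    qcrit <- stats::qtukey(conf_level, kk, df) / sqrt(2)
    row <- data.frame(group_a = names(groups)[a], group_b = names(groups)[b],
                      mean_difference = diff, standard_error = se,
                      df = df, p = p,
                      ci_low = diff - qcrit * se, ci_high = diff + qcrit * se,
                      stringsAsFactors = FALSE)
    out <- rbind(out, row)
  }
  if (bootstrap_bca > 0)
    out <- cbind(out, gh_bootstrap_bca(groups, pairs, bootstrap_bca,
                                       conf_level, seed))
  attr(out, "method") <- "games_howell"
  out
}

# seeded BCa bootstrap of each pairwise mean difference
gh_bootstrap_bca <- function(groups, pairs, n_boot, conf_level, seed) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  alpha <- (1 - conf_level) / 2
  res <- data.frame(bias = numeric(0), bca_low = numeric(0),
                    bca_high = numeric(0))
  for (pi in seq_len(ncol(pairs))) {
    xa <- groups[[pairs[1, pi]]]; xb <- groups[[pairs[2, pi]]]
    obs <- mean(xa) - mean(xb)
    boots <- replicate(n_boot,
      mean(sample(xa, replace = TRUE)) - mean(sample(xb, replace = TRUE)))
    bias <- mean(boots) - obs
    z0 <- stats::qnorm(mean(boots < obs))
    # jackknife acceleration over the pooled leave-one-out differences
    jk <- c(vapply(seq_along(xa), function(i) mean(xa[-i]) - mean(xb), numeric(1)),
            vapply(seq_along(xb), function(i) mean(xa) - mean(xb[-i]), numeric(1)))
    jm <- mean(jk)
    a_num <- sum((jm - jk)^3)
    a_den <- 6 * sum((jm - jk)^2)^1.5
    acc <- if (a_den > 0) a_num / a_den else 0
    adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - acc * (z0 + z)))
    qs <- stats::quantile(boots, c(adj(stats::qnorm(alpha)),
                                   adj(stats::qnorm(1 - alpha))),
                          names = FALSE, type = 7)
    res <- rbind(res, data.frame(bias = bias, bca_low = qs[1],
                                 bca_high = qs[2]))
  }
  res
}
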