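#' Grubbs test for a single outlier
#'
#' Two-sided Grubbs test: `G = max |x - mean| / sd` is compared with the
#' critical value derived from the t distribution,
#' `G_crit = (n-1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n-2)`. At most one observation is flagged per
#' invocation (the maximal deviation; an exact tie between two extremes is
#' broken by the lower index). Iterative removal repeats the test on the
#' reduced sample until no outlier remains.
#'
#' @param values numeric vector, `n >= 3`.
#' @param alpha significance level (default 0.05).
#' @param iterative repeat removal until no outlier is found (default
#'   FALSE).
#' @return a list of class `grubbs_result`: `statistic` (G), `critical`,
#'   `outlier_index` (NA if none), `outlier_value`, `alpha`, `n`; when
#'   `iterative`, `outlier_index`/`outlier_value` collect every removed
#'   point (indices refer to the original vector) and `statistic`/
#'   `critical` refer to the first round.
#' @examples
#' grubbs_test(c(1, 1.2, 0.9, 1.1, 5))
#' @export
grubbs_test <- function(values, alpha = 0.05, iterative = FALSE) {
  n <- length(values)
  if (n < 3) stop("Grubbs test needs at least 3 values, got ", n)
  if (any(!is.finite(values))) stop("values must be finite")
  one_pass <- function(x) {
    n <- length(x)
    s <- stats::sd(x)
    if (s == 0) return(list(G = 0, crit = Inf, idx = NA_integer_))
    dev <- abs(x - mean(x))
    G <- max(dev) / s
    tq <- stats::qt(1 - alpha / (2 * n), n - 2)
    crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
    list(G = G, crit = crit,
         idx = if (G > crit) which.max(dev) else NA_integer_)
  }
  first <- one_pass(values)
  idx_all <- if (!is.na(first$idx)) first$idx else integer(0)
  if (iterative && length(idx_all)) {
    remaining <- setdiff(seq_len(n), idx_all)
    while (length(remaining) >= 3) {
      p <- one_pass(values[remaining])
      if (is.na(p$idx)) break
      idx_all <- c(idx_all, remaining[p$idx])
      remaining <- remaining[-p$idx]
    }
  }
  structure(list(statistic = first$G, critical = first$crit,
                 outlier_index = if (length(idx_all)) idx_all else NA_integer_,
                 outlier_value = if (length(idx_all)) values[idx_all] else NA_real_,
                 alpha = alpha, n = n),
            class = "grubbs_result")
}

#' @export
print.grubbs_result <- function(x, ...) {
  cat(sprintf("<grubbs_result> G = %.3f (critical %.3f, alpha %g, n %d); ",
              x$statistic, x$critical, x$alpha, x$n))
  if (all(is.na(x$outlier_index))) cat("no outlier\n")
  else cat("outlier at index", paste(x$outlier_index, collapse = ", "), "\n")
  invisible(x)
}

#' Assemble a cohort table
#'
#' Long-format table of per-subject metrics for two-genotype comparisons.
#'
#' @param subject_id subject identifiers.
#' @param genotype `"WT"` or `"HET"` per subject.
#' @param metric metric name per row.
#' @param value metric value per row.
#' @return a data frame of class `cohort_table`.
#' @export
cohort_table <- function(subject_id, genotype, metric, value) {
  genotype <- as.character(genotype)
  stopifnot(all(genotype %in% c("WT", "HET")))
  df <- data.frame(subject_id = subject_id, genotype = genotype,
                   metric = as.character(metric), value = as.numeric(value))
  if (anyDuplicated(df[, c("subject_id", "metric")])) {
    stop("one value per subject x metric required")
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Pooled two-group Student t-test on a cohort metric
#'
#' Two-tailed pooled-variance (Student) t-test of WT versus HET for one
#' metric, wrapping [stats::t.test()] with `var.equal = TRUE`. The
#' degenerate case of two identical constant groups returns statistic 0
#' and p = 1 (constant groups with different means return an infinite
#' statistic and p = 0). Welch's correction is available via `welch`.
#'
#' @param table a [cohort_table()].
#' @param metric metric name to test.
#' @param welch use Welch's unequal-variance t instead of pooled (default
#'   FALSE).
#' @return a list of class `t_result`: `statistic` (WT minus HET
#'   direction), `df`, `p_value`, `mean` (named, per group), `sd`, `n`,
#'   `metric`.
#' @export
two_group_t <- function(table, metric, welch = FALSE) {
  sub <- table[table$metric == metric, ]
  if (!nrow(sub)) stop("no rows for metric ", metric)
  wt <- sub$value[sub$genotype == "WT"]
  het <- sub$value[sub$genotype == "HET"]
  if (length(wt) < 2 || length(het) < 2) stop("both groups need n >= 2")
  grp <- list(WT = wt, HET = het)
  out <- list(mean = vapply(grp, mean, numeric(1)),
              sd = vapply(grp, stats::sd, numeric(1)),
              n = vapply(grp, length, numeric(1)),
              metric = metric)
  if (stats::sd(wt) == 0 && stats::sd(het) == 0) {
    eq <- mean(wt) == mean(het)
    out$statistic <- if (eq) 0 else sign(mean(wt) - mean(het)) * Inf
    out$df <- length(wt) + length(het) - 2
    out$p_value <- if (eq) 1 else 0
  } else {
    tt <- stats::t.test(wt, het, var.equal = !welch)
    out$statistic <- unname(tt$statistic)
    out$df <- unname(tt$parameter)
    out$p_value <- tt$p.value
  }
  structure(out, class = "t_result")
}

#' @export
print.t_result <- function(x, ...) {
  cat(sprintf("<t_result> %s: t(%g) = %.3f, p = %.4g; WT %.3g (n=%d), HET %.3g (n=%d)\n",
              x$metric, x$df, x$statistic, x$p_value,
              x$mean[["WT"]], x$n[["WT"]], x$mean[["HET"]], x$n[["HET"]]))
  invisible(x)
}

#' Simulate a two-genotype band-power cohort
#'
#' Draws per-subject delta power as lognormal with a given between-subject
#' coefficient of variation; the HET group mean is the WT mean times
#' `effect`. Used for power checks of the two-group comparison under a
#' planted genotype effect.
#'
#' @param n_per_group subjects per genotype (default 8).
#' @param effect HET/WT mean ratio (default 1.5).
#' @param cv between-subject coefficient of variation (default 0.2).
#' @param baseline WT mean power in arbitrary units (default 1).
#' @param metric metric name used in the table.
#' @param seed optional integer seed.
#' @return a [cohort_table()].
#' @export
simulate_band_power_cohort <- function(n_per_group = 8, effect = 1.5,
                                       cv = 0.2, baseline = 1,
                                       metric = "delta_power", seed = NULL) {
  stopifnot(n_per_group >= 2, effect > 0, cv > 0)
  sdlog <- sqrt(log(1 + cv^2))
  gen <- function() {
    wt <- stats::rlnorm(n_per_group, log(baseline) - sdlog^2 / 2, sdlog)
    het <- stats::rlnorm(n_per_group, log(baseline * effect) - sdlog^2 / 2, sdlog)
    cohort_table(
      subject_id = sprintf("S%02d", seq_len(2 * n_per_group)),
      genotype = rep(c("WT", "HET"), each = n_per_group),
      metric = metric, value = c(wt, het)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
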