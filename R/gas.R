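#' Summarise cumulative gas production
#'
#' Per-fermenter final cumulative total (the maximum, equal to the last
#' observed week) plus per-treatment weekly mean cumulative series.
#'
#' @param gas a [gas_series_frame()] (or coercible data.frame with columns
#'   `sample_id`, `week`, `cumulative_gas_ml`).
#' @param metadata a [sample_metadata()] frame covering every gas sample.
#' @return list of class `"gas_summary"`: `samples` (sample_id, treatment,
#'   total_gas) and `weekly_means` (treatment, week, mean_cumulative).
#' @export
summarize_gas <- function(gas, metadata) {
  if (!inherits(gas, "gas_series"))
    gas <- gas_series_frame(gas$sample_id, gas$week, gas$cumulative_gas_ml)
  unknown <- setdiff(unique(gas$sample_id), metadata$sample_id)
  if (length(unknown))
    stop("gas sample(s) without metadata: ", paste(unknown, collapse = ", "))
  totals <- stats::aggregate(cumulative_gas_ml ~ sample_id, gas, max)
  names(totals)[2] <- "total_gas"
  totals$treatment <- metadata$treatment[match(totals$sample_id,
                                               metadata$sample_id)]
  totals <- totals[, c("sample_id", "treatment", "total_gas")]
  g2 <- merge(as.data.frame(gas),
              as.data.frame(metadata)[, c("sample_id", "treatment")],
              by = "sample_id")
  weekly <- stats::aggregate(cumulative_gas_ml ~ treatment + week, g2, mean)
  names(weekly)[3] <- "mean_cumulative"
  weekly <- weekly[order(weekly$treatment, weekly$week), ]
  rownames(weekly) <- NULL
  structure(list(samples = totals, weekly_means = weekly),
            class = "gas_summary")
}

#' @export
print.gas_summary <- function(x, ...) {
  cat("Cumulative gas totals by treatment (mL):\n")
  agg <- stats::aggregate(total_gas ~ treatment, x$samples, mean)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-6s mean %8.1f (n = %d)\n", agg$treatment[i],
                agg$total_gas[i],
                sum(x$samples$treatment == agg$treatment[i])))
  invisible(x)
}

#' Dose-response trend of total gas production
#'
#' Ordinary least squares of invaded-community total gas on dose. Doses
#' span three orders of magnitude, so the headline fit uses `log10(dose)`;
#' the raw-dose fit is reported alongside.
#'
#' @param summary a [summarize_gas()] result.
#' @param doses named vector mapping dose treatment labels to volume
#'   fractions; defaults to [treatment_dose()] over the summary's dose
#'   treatments.
#' @return list of class `"gas_trend"`: for each of `log10` and `raw`
#'   scales, slope, F vs intercept-only, df, p, R2.
#' @export
dose_trend <- function(summary, doses = NULL) {
  stopifnot(inherits(summary, "gas_summary"))
  df <- summary$samples
  if (is.null(doses)) {
    df$dose <- treatment_dose(df$treatment)
    df <- df[!is.na(df$dose), ]
  } else {
    df <- df[df$treatment %in% names(doses), ]
    df$dose <- unname(doses[df$treatment])
  }
  if (length(unique(df$dose)) < 3)
    stop("dose_trend needs >= 3 distinct doses")
  one <- function(x) {
    fit <- stats::lm(df$total_gas ~ x)
    an <- stats::anova(fit)
    sm <- summary(fit)
    r2 <- sm$r.squared
    if (stats::var(df$total_gas) == 0) r2 <- 0  # flat response
    list(slope = unname(stats::coef(fit)[2]),
         F = an[1, "F value"], df = c(an[1, "Df"], an[2, "Df"]),
         p = an[1, "Pr(>F)"], R2 = r2)
  }
  structure(list(log10 = one(log10(df$dose)), raw = one(df$dose),
                 n = nrow(df)), class = "gas_trend")
}

#' @export
print.gas_trend <- function(x, ...) {
  cat(sprintf("Gas ~ log10(dose): slope = %.2f, F(%d,%d) = %.2f, p = %.4g, R2 = %.2f\n",
              x$log10$slope, x$log10$df[1], x$log10$df[2], x$log10$F,
              x$log10$p, x$log10$R2))
  invisible(x)
}

#' Many-to-one (Dunnett-style) comparisons against a control community
#'
#' Compares each invasion treatment's mean total gas to a single pure
#' community (control), with family-wise error controlled through the
#' joint multivariate-t distribution of the max |t| statistic under a
#' common pooled variance. Critical values and adjusted p-values are
#' obtained by seeded Monte-Carlo integration of that null distribution
#' (group-mean and pooled-variance draws), which handles unbalanced
#' designs exactly and is fully reproducible. Adjusted p-values are
#' clamped from below at the raw two-sided p (a mathematical bound the
#' Monte-Carlo noise must not violate).
#'
#' @param summary a [summarize_gas()] result.
#' @param control_treatment the control community label (`"HP"` or
#'   `"LP"`).
#' @param treatments comparison treatments; default: the dose treatments
#'   present.
#' @param alpha family-wise significance level.
#' @param n_draws Monte-Carlo draws for the max-|t| null.
#' @param seed integer seed for the Monte-Carlo stream.
#' @return data.frame of class `"many_to_one"`: one row per treatment
#'   with mean difference, t, raw p, adjusted p and verdict
#'   (`"distinct"` / `"not distinct"` at `alpha`).
#' @export
many_to_one <- function(summary, control_treatment,
                        treatments = NULL, alpha = 0.05,
                        n_draws = 1e5, seed = 1L) {
  stopifnot(inherits(summary, "gas_summary"))
  df <- summary$samples
  if (is.null(treatments))
    treatments <- intersect(c("D10", "D1", "D0.1", "D0.01"),
                            unique(df$treatment))
  if (!control_treatment %in% df$treatment)
    stop("control treatment '", control_treatment, "' not in gas summary")
  ctrl <- df$total_gas[df$treatment == control_treatment]
  if (length(ctrl) < 2)
    stop("control treatment needs >= 2 replicates")
  groups <- lapply(treatments, function(tr) df$total_gas[df$treatment == tr])
  if (any(lengths(groups) < 2))
    stop("every comparison treatment needs >= 2 replicates")
  k <- length(groups)
  ns <- c(length(ctrl), lengths(groups))
  n_total <- sum(ns)
  dfree <- n_total - (k + 1)
  all_groups <- c(list(ctrl), groups)
  s2 <- sum(vapply(all_groups, function(g) sum((g - mean(g))^2),
                   numeric(1))) / dfree
  se <- sqrt(s2 * (1 / ns[-1] + 1 / ns[1]))
  diff <- vapply(groups, mean, numeric(1)) - mean(ctrl)
  if (s2 == 0) {
    # degenerate zero-variance data: equal means are unambiguously equal,
    # any nonzero difference unambiguously distinct
    tval <- ifelse(diff == 0, 0, Inf * sign(diff))
    p_raw <- ifelse(diff == 0, 1, 0)
  } else {
    tval <- diff / se
    p_raw <- 2 * stats::pt(-abs(tval), dfree)
  }

  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  z <- matrix(stats::rnorm(n_draws * (k + 1)), n_draws, k + 1)
  z <- sweep(z, 2, sqrt(1 / ns), "*")
  s_draw <- sqrt(stats::rchisq(n_draws, dfree) / dfree)
  tmax <- numeric(n_draws)
  for (j in seq_len(k)) {
    tj <- abs(z[, j + 1] - z[, 1]) / (s_draw * sqrt(1 / ns[j + 1] + 1 / ns[1]))
    tmax <- pmax(tmax, tj)
  }
  p_adj <- vapply(abs(tval), function(t0)
    (1 + sum(tmax >= t0)) / (1 + n_draws), numeric(1))
  p_adj <- pmax(p_adj, p_raw)
  out <- data.frame(treatment = treatments, control = control_treatment,
                    mean_diff = diff, t = tval, df = dfree,
                    p_raw = p_raw, p_adjusted = p_adj,
                    verdict = ifelse(p_adj < alpha, "distinct",
                                     "not distinct"),
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "n_draws") <- n_draws
  class(out) <- c("many_to_one", "data.frame")
  out
}

#' @export
print.many_to_one <- function(x, ...) {
  cat(sprintf("Many-to-one comparisons vs %s (alpha = %.2f):\n",
              x$control[1], attr(x, "alpha")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-6s diff %9.1f  t = %7.2f  p_adj = %.4g  %s\n",
                x$treatment[i], x$mean_diff[i], x$t[i], x$p_adjusted[i],
                x$verdict[i]))
  invisible(x)
}
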