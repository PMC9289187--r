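#' Fold stimulation of insulin secretion
#'
#' Ratio of stimulated (16.7 mM glucose) to basal (2.8 mM glucose) insulin
#' secretion, the standard index of beta-cell functional quality.
#'
#' @param basal Basal secretion (> 0), ng/MT.
#' @param stimulated Stimulated secretion, ng/MT.
#' @return `stimulated / basal` (vectorized).
#' @export
#' @examples
#' fold_stimulation(2, 6) # 3
fold_stimulation <- function(basal, stimulated) {
  if (any(!is.finite(basal)) || any(basal <= 0))
    stop("basal secretion must be positive", call. = FALSE)
  stimulated / basal
}

#' ROUT outlier detection for one group of measurements
#'
#' Robust outlier removal controlling a false-discovery rate `q` among the
#' flagged points, reduced to the one-sample (constant) model: the robust
#' center is the median; the robust scale (RSDR) is the 68.27th percentile of
#' absolute residuals with the small-sample correction `n / (n - 1)`;
#' two-tailed p-values come from the t distribution (df = n - 1) on the
#' studentized residuals; points are flagged stepping inward from the most
#' extreme residual while `p_i < q * (n - i + 1) / n`.
#'
#' @param values Numeric measurements (n >= 4 for any testing; fewer values
#'   are returned untouched with a warning).
#' @param q FDR level in (0, 0.5).
#' @return List with `kept`, `flagged` (disjoint, union = input), and the
#'   integer `flagged_idx` into the input.
#' @export
#' @examples
#' rout_outliers(c(rnorm(12), 50), q = 0.05)$flagged
rout_outliers <- function(values, q = 0.05) {
  assert_number(q, "q", lower = 1e-12, upper = 0.5 - 1e-12)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 4L) {
    warning("fewer than 4 values: outlier test skipped", call. = FALSE)
    return(list(kept = values, flagged = numeric(0), flagged_idx = integer(0)))
  }
  resid <- values - median(values)
  rsdr <- quantile(abs(resid), 0.6827, names = FALSE) * n / (n - 1)
  if (rsdr <= 0)
    return(list(kept = values, flagged = numeric(0), flagged_idx = integer(0)))
  tstat <- abs(resid) / rsdr
  p <- 2 * pt(tstat, df = n - 1, lower.tail = FALSE)
  ord <- order(p)           # most extreme (smallest p) first
  flagged_idx <- integer(0)
  for (i in seq_len(n)) {
    if (p[ord[i]] < q * (n - i + 1) / n) flagged_idx <- c(flagged_idx, ord[i])
    else break
  }
  list(kept = if (length(flagged_idx)) values[-flagged_idx] else values,
       flagged = values[flagged_idx],
       flagged_idx = sort(flagged_idx))
}

#' Two-sample Student's t-test (pooled variance)
#'
#' @param a,b Numeric samples, each with at least 2 values.
#' @param var_equal Pooled variance (default); `FALSE` for Welch.
#' @return Two-sided p-value.
#' @export
#' @examples
#' students_t(c(1, 2, 3), c(1, 2, 3)) # 1
students_t <- function(a, b, var_equal = TRUE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (var_equal) {
    sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
      (length(a) + length(b) - 2)
    if (sp2 <= 0) stop("zero pooled variance", call. = FALSE)
  }
  stats::t.test(a, b, var.equal = var_equal)$p.value
}

#' One-way ANOVA with Dunnett's many-to-one comparisons
#'
#' Fits the one-way layout, then compares every treatment group to the control
#' with Dunnett's procedure: adjusted p-values are
#' `P(max_j |T_j| >= |t_i|)` under the equicorrelated multivariate t
#' distribution with `df = N - k`, evaluated by adaptive numerical integration
#' (documented tolerance 1e-3). Adjusted p-values are never below the
#' unadjusted two-sample p-values.
#'
#' @param values Numeric responses.
#' @param groups Group labels (coerced to character), same length as `values`.
#' @param control Label of the control group.
#' @return Object of class `anova_dunnett`: list with `f_statistic`,
#'   `p_anova`, `df_resid`, and `comparisons` (data frame: `group, estimate,
#'   t, p_unadjusted, p_adjusted`).
#' @export
#' @examples
#' set.seed(1)
#' v <- c(rnorm(8), rnorm(8, 2))
#' anova_dunnett(v, rep(c("0", "10"), each = 8), control = "0")
anova_dunnett <- function(values, groups, control) {
  groups <- as.character(groups)
  control <- as.character(control)
  stopifnot(length(values) == length(groups))
  levs <- unique(groups)
  if (!control %in% levs) stop("control group not present", call. = FALSE)
  if (length(levs) < 2L) stop("need at least 2 groups", call. = FALSE)
  ns <- table(groups)
  if (any(ns < 2L)) stop("every group needs n >= 2", call. = FALSE)
  k <- length(levs)
  n_tot <- length(values)
  means <- tapply(values, groups, mean)
  ss_w <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df_resid <- n_tot - k
  s2 <- ss_w / df_resid
  if (s2 <= 0) stop("degenerate: zero within-group variance in all groups",
                    call. = FALSE)
  fit <- lm(values ~ factor(groups))
  av <- anova(fit)
  trt <- setdiff(levs, control)
  n0 <- ns[[control]]
  ti <- sapply(trt, function(g) {
    (means[[g]] - means[[control]]) / sqrt(s2 * (1 / ns[[g]] + 1 / n0))
  })
  # correlation of the comparison statistics (shared control)
  lam <- sapply(trt, function(g) sqrt(ns[[g]] / (ns[[g]] + n0)))
  m <- length(trt)
  corr <- outer(lam, lam)
  diag(corr) <- 1
  p_unadj <- 2 * pt(abs(ti), df_resid, lower.tail = FALSE)
  p_adj <- vapply(seq_len(m), function(i) {
    if (m == 1L) return(p_unadj[i])
    b <- abs(ti[i])
    pr <- with_seed(20240101, mvtnorm::pmvt(
      lower = rep(-b, m), upper = rep(b, m), df = df_resid, corr = corr,
      algorithm = mvtnorm::GenzBretz(abseps = 1e-4, maxpts = 50000)))
    min(1, max(p_unadj[i], 1 - as.numeric(pr)))
  }, 0)
  structure(list(f_statistic = av$`F value`[1], p_anova = av$`Pr(>F)`[1],
                 df_resid = df_resid, control = control,
                 comparisons = data.frame(group = trt,
                                          estimate = unlist(means[trt]) -
                                            means[[control]],
                                          t = ti, p_unadjusted = p_unadj,
                                          p_adjusted = p_adj,
                                          row.names = NULL)),
            class = "anova_dunnett")
}

#' @export
print.anova_dunnett <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.3f, p = %.3g (df resid %d); Dunnett vs '%s':\n",
              x$f_statistic, x$p_anova, x$df_resid, x$control))
  print(x$comparisons, digits = 4)
  invisible(x)
}

# Endpoints that are proliferation fractions: no outlier test is applied to
# these, matching reporting practice for proliferating-cell fractions.
is_prolif_endpoint <- function(endpoint) {
  grepl("^pct_prolif", endpoint)
}

#' Dose-response summary table for one endpoint
#'
#' Groups records by dose and reports per dose: n after ROUT cleaning, mean,
#' SEM, number of flagged outliers, and the Dunnett-adjusted p-value versus
#' the control dose. ROUT is skipped for proliferation-fraction endpoints
#' (`pct_prolif_*`). The dose with the maximal group mean is annotated as the
#' peak. The derived endpoint `fold_stimulation` is computed per record as
#' `stimulated_secretion / basal_secretion`.
#'
#' @param records Data frame with a `dose_uM` column and the endpoint column
#'   (functional records or per-MT quantifications merged with well
#'   metadata).
#' @param endpoint Endpoint column name, or `"fold_stimulation"`.
#' @param control_dose Control dose (default 0).
#' @param q ROUT FDR level.
#' @return Data frame of class `dose_response_table`: `endpoint, dose_uM, n,
#'   mean, sem, flagged_outliers, p_adjusted, is_peak`.
#' @export
dose_response_table <- function(records, endpoint, control_dose = 0,
                                q = 0.05) {
  stopifnot(is.data.frame(records), "dose_uM" %in% names(records))
  if (identical(endpoint, "fold_stimulation")) {
    if (!all(c("basal_secretion", "stimulated_secretion") %in% names(records)))
      stop("fold_stimulation needs basal_secretion and stimulated_secretion",
           call. = FALSE)
    records$fold_stimulation <- fold_stimulation(records$basal_secretion,
                                                 records$stimulated_secretion)
  }
  if (!endpoint %in% names(records))
    stop(sprintf("unknown endpoint '%s'; available: %s", endpoint,
                 paste(setdiff(names(records),
                               c("mt_id", "well", "donor", "dose_uM",
                                 "duration_days")), collapse = ", ")),
         call. = FALSE)
  doses <- sort(unique(records$dose_uM))
  skip_rout <- is_prolif_endpoint(endpoint)
  cleaned <- list()
  rows <- lapply(doses, function(d) {
    v <- records[[endpoint]][records$dose_uM == d]
    v <- v[!is.na(v)]
    flagged <- 0L
    if (!skip_rout && length(v) >= 4L) {
      r <- rout_outliers(v, q)
      flagged <- length(r$flagged)
      v <- r$kept
    }
    cleaned[[as.character(d)]] <<- v
    data.frame(endpoint = endpoint, dose_uM = d, n = length(v),
               mean = mean(v),
               sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
               flagged_outliers = flagged)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  if (length(doses) >= 2L && control_dose %in% doses &&
      all(vapply(cleaned, length, 0L) >= 2L)) {
    vals <- unlist(cleaned, use.names = FALSE)
    grp <- rep(names(cleaned), vapply(cleaned, length, 0L))
    # degenerate data (zero within-group variance) leaves p as NA
    ad <- tryCatch(anova_dunnett(vals, grp,
                                 control = as.character(control_dose)),
                   error = function(e) NULL)
    if (!is.null(ad)) {
      idx <- match(ad$comparisons$group, as.character(out$dose_uM))
      out$p_adjusted[idx] <- ad$comparisons$p_adjusted
    }
  }
  out$is_peak <- seq_len(nrow(out)) == which.max(out$mean)
  class(out) <- c("dose_response_table", "data.frame")
  out
}

#' @export
print.dose_response_table <- function(x, ...) {
  cat(sprintf("Dose response for '%s' (peak at %g uM):\n", x$endpoint[1],
              x$dose_uM[x$is_peak][1]))
  df <- as.data.frame(x)
  df$mean <- signif(df$mean, 4)
  df$sem <- signif(df$sem, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Plot a dose-response table
#'
#' Mean +/- SEM per dose with the peak dose marked.
#'
#' @param x A `dose_response_table`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dose_response_table <- function(x, ...) {
  up <- x$mean + ifelse(is.na(x$sem), 0, x$sem)
  lo <- x$mean - ifelse(is.na(x$sem), 0, x$sem)
  graphics::plot(x$dose_uM, x$mean, ylim = range(c(lo, up)), pch = 16,
                 xlab = "dose (uM)", ylab = x$endpoint[1], ...)
  graphics::arrows(x$dose_uM, lo, x$dose_uM, up, angle = 90, code = 3,
                   length = 0.04)
  graphics::points(x$dose_uM[x$is_peak], x$mean[x$is_peak], pch = 3, cex = 2)
  invisible(x)
}

#' Chronic insulin secretion rate
#'
#' Normalizes insulin accumulated in the culture medium over a collection
#' window of 24-72 hours to ng/MT/day.
#'
#' @param accumulated_ng Insulin accumulated over the window, ng/MT.
#' @param interval_days Collection interval, days (> 0).
#' @return Secretion rate, ng/MT/day (vectorized).
#' @export
#' @examples
#' chronic_secretion_rate(6, 3) # 2 ng/MT/day
chronic_secretion_rate <- function(accumulated_ng, interval_days) {
  if (any(interval_days <= 0)) stop("interval_days must be positive",
                                    call. = FALSE)
  accumulated_ng / interval_days
}
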