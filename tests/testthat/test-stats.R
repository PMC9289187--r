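test_that("fold stimulation is a guarded, scale-invariant ratio", {
  expect_equal(fold_stimulation(2, 6), 3)
  expect_equal(fold_stimulation(1.7, 1.7), 1)
  expect_error(fold_stimulation(0, 5), "positive")
  expect_error(fold_stimulation(-1, 5), "positive")
  expect_equal(fold_stimulation(2 * 13, 6 * 13), fold_stimulation(2, 6))
})

test_that("ROUT leaves constant and tiny samples untouched", {
  r <- rout_outliers(rep(3.2, 10), 0.05)
  expect_length(r$flagged, 0)
  expect_warning(r2 <- rout_outliers(c(1, 2, 3), 0.05), "fewer than 4")
  expect_equal(r2$kept, c(1, 2, 3))
})

test_that("ROUT flags a planted extreme point and partitions the input", {
  set.seed(123)
  v <- c(rnorm(12), 15)
  r <- rout_outliers(v, 0.05)
  expect_true(13 %in% r$flagged_idx)
  # kept and flagged partition the input
  expect_equal(sort(c(r$kept, r$flagged)), sort(v))
  set.seed(9)
  for (i in 1:20) {
    v <- rnorm(sample(6:20, 1))
    r <- rout_outliers(v, 0.05)
    expect_equal(sort(c(r$kept, r$flagged)), sort(v))
  }
})

test_that("students_t matches the textbook pooled formula", {
  expect_equal(students_t(c(1, 2, 3), c(1, 2, 3)), 1)
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(sample(4:12, 1)); b <- rnorm(sample(4:12, 1), 0.8)
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * pt(abs(tt), na + nb - 2, lower.tail = FALSE)
    expect_equal(students_t(a, b), p, tolerance = 1e-10)
  }
  expect_error(students_t(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("Dunnett adjustment is monotone and matches multcomp", {
  set.seed(31)
  v <- c(rnorm(8), rnorm(8, 1), rnorm(8, 0.5), rnorm(8, 2))
  g <- rep(c("ctrl", "d1", "d3", "d10"), each = 8)
  ad <- anova_dunnett(v, g, "ctrl")
  expect_true(all(ad$comparisons$p_adjusted >= ad$comparisons$p_unadjusted - 1e-9))
  expect_true(all(ad$comparisons$p_adjusted <= 1))
  # independent oracle: multcomp's glht on the same fit
  fit <- stats::aov(v ~ factor(g, levels = c("ctrl", "d1", "d3", "d10")))
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(
    `factor(g, levels = c("ctrl", "d1", "d3", "d10"))` = "Dunnett"))
  p_mc <- summary(gl)$test$pvalues
  ord <- match(c("d1", "d3", "d10"), ad$comparisons$group)
  expect_equal(unname(ad$comparisons$p_adjusted[ord]), unname(as.numeric(p_mc)),
               tolerance = 2e-3)
})

test_that("a 5-SD shifted group is detected with adjusted p < 0.001", {
  set.seed(17)
  v <- c(rnorm(8), rnorm(8), rnorm(8, 5))
  g <- rep(c("ctrl", "a", "b"), each = 8)
  ad <- anova_dunnett(v, g, "ctrl")
  expect_lt(ad$comparisons$p_adjusted[ad$comparisons$group == "b"], 0.001)
})

test_that("degenerate inputs to anova_dunnett error clearly", {
  expect_error(anova_dunnett(rep(1, 8), rep(c("a", "b"), each = 4), "a"),
               "zero within-group variance")
  expect_error(anova_dunnett(rnorm(8), rep("a", 8), "a"), "at least 2 groups")
  expect_error(anova_dunnett(rnorm(8), rep(c("a", "b"), each = 4), "zz"),
               "control")
})

test_that("dose-response tables summarize, clean, and annotate the peak", {
  set.seed(41)
  doses <- c(0, 1, 3.3, 5, 10)
  recs <- do.call(rbind, lapply(doses, function(d) {
    data.frame(mt_id = paste0(d, "_", 1:8), dose_uM = d,
               basal_secretion = rlnorm(8, log(0.5 + 0.05 * d), 0.1),
               stimulated_secretion = rlnorm(8, log(2 + 0.3 * d), 0.1),
               pct_prolif_total = rnorm(8, d, 0.3))
  }))
  tab <- dose_response_table(recs, "stimulated_secretion")
  expect_equal(nrow(tab), 5L)
  expect_true(tab$is_peak[tab$dose_uM == 10])
  expect_true(is.na(tab$p_adjusted[tab$dose_uM == 0]))
  expect_true(all(!is.na(tab$p_adjusted[tab$dose_uM > 0])))
  # mean and SEM equal a hand-rolled oracle on the cleaned values
  for (d in doses) {
    v <- recs$stimulated_secretion[recs$dose_uM == d]
    v <- rout_outliers(v, 0.05)$kept
    row <- tab[tab$dose_uM == d, ]
    expect_equal(row$mean, sum(v) / length(v))
    expect_equal(row$sem, sqrt(sum((v - mean(v))^2) / (length(v) - 1)) /
                   sqrt(length(v)))
  }
  # order invariance
  perm <- recs[sample(nrow(recs)), ]
  expect_equal(as.data.frame(dose_response_table(perm, "stimulated_secretion")),
               as.data.frame(tab))
  # single group: no comparisons
  one <- dose_response_table(recs[recs$dose_uM == 0, ], "basal_secretion")
  expect_equal(nrow(one), 1L)
  expect_true(is.na(one$p_adjusted))
  # unknown endpoint lists what exists
  expect_error(dose_response_table(recs, "nope"), "available")
})

test_that("no outlier removal is applied to proliferation fractions", {
  set.seed(6)
  recs <- data.frame(mt_id = as.character(1:8), dose_uM = 0,
                     pct_prolif_total = c(rnorm(7, 0.2, 0.05), 40)) # wild but kept
  tab <- dose_response_table(recs, "pct_prolif_total")
  expect_equal(tab$n, 8L)
  expect_equal(tab$flagged_outliers, 0L)
  # the same values under a non-proliferation endpoint are cleaned
  recs$atp_content <- recs$pct_prolif_total
  tab2 <- dose_response_table(recs, "atp_content")
  expect_equal(tab2$flagged_outliers, 1L)
})

test_that("fold stimulation is computed per record inside the table", {
  recs <- data.frame(mt_id = as.character(1:10), dose_uM = rep(c(0, 5), each = 5),
                     basal_secretion = rep(2, 10),
                     stimulated_secretion = rep(c(6, 9), each = 5))
  tab <- dose_response_table(recs, "fold_stimulation")
  expect_equal(tab$mean, c(3, 4.5))
  expect_true(tab$is_peak[2])
})

test_that("a strong intermediate-dose peak is annotated reliably", {
  # fold-stimulation engineered to peak at 3.3 uM with a >= 3 within-group-SD
  # margin over the runner-up dose
  dm <- dose_effect_model(basal_secretion_slope = 0.3,
                          stim_secretion_effect = 4,
                          stim_ec50 = 1.5, stim_hill = 4, endpoint_cv = 0.04)
  doses <- c(0, 1, 3.3, 5, 10)
  mu <- vapply(doses, function(d) {
    m <- isletmt:::functional_means_at_dose(dm, d)
    m$stimulated / m$basal
  }, numeric(1))
  margin <- max(mu) - max(mu[-which.max(mu)])
  sd_fold <- max(mu) * sqrt(2) * dm$endpoint_cv
  expect_gte(margin / sd_fold, 3)
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    recs <- do.call(rbind, lapply(doses, function(d)
      do.call(rbind, lapply(1:12, function(i)
        isletmt:::simulate_functional_record(paste0(d, "_", i), "w", d, 4,
                                             "donor", dm)))))
    tab <- dose_response_table(recs, "fold_stimulation")
    tab$dose_uM[tab$is_peak]
  }, numeric(1))
  expect_gte(mean(hits == 3.3), 0.95)
})

test_that("chronic secretion normalizes to ng/MT/day", {
  expect_equal(chronic_secretion_rate(6, 3), 2)
  expect_equal(chronic_secretion_rate(c(2, 4), c(1, 2)), c(2, 2))
  expect_error(chronic_secretion_rate(5, 0), "positive")
})
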