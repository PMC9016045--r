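random_cohort <- function(n1 = NULL, n2 = NULL, ties = TRUE) {
  n1 <- if (is.null(n1)) sample(1:12, 1) else n1
  n2 <- if (is.null(n2)) sample(1:12, 1) else n2
  if (ties && runif(1) < 0.5) {
    pool <- sample(1:6, n1 + n2, replace = TRUE)  # heavy ties
  } else pool <- rnorm(n1 + n2)
  list(pos = pool[seq_len(n1)], neg = pool[n1 + seq_len(n2)])
}

test_that("AUROC implements the tie-credited pairwise probability", {
  expect_equal(auroc(c(3, 4), c(1, 2)), 1)
  expect_equal(auroc(2, 2), 0.5)
  expect_equal(auroc(c(1, 3), c(2, 4)), 0.25)
  expect_error(auroc(numeric(0), 1), "non-empty")
})

test_that("AUROC equals U/(n1 n2) from the rank-based Mann-Whitney statistic", {
  set.seed(201)
  for (rep in 1:1000) {
    g <- random_cohort()
    expect_equal(auroc(g$pos, g$neg), oracle_auroc(g$pos, g$neg))
  }
})

test_that("AUROC is invariant under strictly increasing score transforms", {
  set.seed(202)
  for (rep in 1:50) {
    g <- random_cohort(ties = FALSE)
    f <- sample(list(function(x) exp(x), function(x) x^3,
                     function(x) 5 * x - 2), 1)[[1]]
    expect_equal(auroc(f(g$pos), f(g$neg)), auroc(g$pos, g$neg))
  }
})

test_that("ROC curve follows the strict score > threshold rule", {
  curve <- rocCurve(c(3, 4), c(1, 2))
  at2 <- curve[curve$threshold == 2, ]
  expect_equal(at2$sensitivity, 1)
  expect_equal(at2$specificity, 1)
  top <- curve[curve$threshold == 4, ]
  expect_equal(top$sensitivity, 0)
  expect_equal(top$specificity, 1)
  expect_true(all(diff(curve$sensitivity) <= 0))
})

test_that("trapezoidal area under the ROC curve equals the AUROC", {
  set.seed(203)
  for (rep in 1:500) {
    g <- random_cohort()
    curve <- rocCurve(g$pos, g$neg)
    fpr <- 1 - curve$specificity
    tpr <- curve$sensitivity
    o <- order(fpr, tpr)  # from (0, 0) at T = max score to (1, 1) at -Inf
    fpr <- fpr[o]; tpr <- tpr[o]
    area <- sum(diff(fpr) * (utils::head(tpr, -1) +
                               utils::tail(tpr, -1)) / 2)
    expect_equal(area, auroc(g$pos, g$neg), tolerance = 1e-10)
  }
})

test_that("Youden cutoff maximizes J with the stated tie rules", {
  cut <- youdenCutoff(rocCurve(c(3, 4), c(1, 2)))
  expect_equal(cut@t_opt, 2)
  expect_equal(cut@j, 1)
  expect_equal(c(cut@sensitivity, cut@specificity), c(1, 1))

  same <- youdenCutoff(rocCurve(c(2, 2), c(2, 2, 2)))
  expect_equal(same@j, 0)
  expect_equal(same@t_opt, 2)  # ties resolved toward higher specificity

  tied <- youdenCutoff(rocCurve(c(2, 3, 4), c(1, 2, 3)))
  expect_equal(tied@j, 1 / 3)
  expect_equal(tied@t_opt, 3)
  expect_equal(tied@specificity, 1)
  expect_equal(tied@sensitivity, 1 / 3)
})

test_that("Youden cutoff agrees with exhaustive search on random cohorts", {
  set.seed(204)
  for (rep in 1:500) {
    g <- random_cohort()
    cut <- youdenCutoff(rocCurve(g$pos, g$neg))
    ref <- oracle_youden(g$pos, g$neg)
    expect_equal(cut@t_opt, ref$t_opt)
    expect_equal(cut@j, ref$j)
    expect_equal(cut@sensitivity, ref$sensitivity)
    expect_equal(cut@specificity, ref$specificity)
  }
})

test_that("ROC/Youden agree with an independent ROC package on a cohort", {
  skip_if_not_installed("pROC")
  set.seed(205)
  pos <- rnorm(18, 1.2); neg <- rnorm(40)
  r <- pROC::roc(response = c(rep(1, 18), rep(0, 40)),
                 predictor = c(pos, neg), quiet = TRUE, direction = "<")
  expect_equal(auroc(pos, neg), as.numeric(pROC::auc(r)), tolerance = 1e-10)
  best <- pROC::coords(r, "best", best.method = "youden", transpose = FALSE)
  cut <- youdenCutoff(rocCurve(pos, neg))
  expect_equal(cut@sensitivity + cut@specificity,
               best$sensitivity + best$specificity, tolerance = 1e-10)
})

test_that("Wilcoxon branches: exact enumeration and corrected approximation", {
  w <- wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))
  expect_true(w$exact)
  expect_equal(w$p_value, 0.1)
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  set.seed(206)
  for (rep in 1:100) {
    a <- rnorm(6); b <- rnorm(6)
    pe <- wilcoxonRankSum(a, b, exact = TRUE)$p_value
    pa <- wilcoxonRankSum(a, b, exact = FALSE)$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
  # ties force the corrected normal approximation
  expect_false(wilcoxonRankSum(c(1, 1, 2), c(2, 3, 3))$exact)
})

score_table_from <- function(scores, labels, organ = "bowel",
                             grid = c(50, 95)) {
  do.call(rbind, lapply(grid, function(x)
    data.frame(patient_id = sprintf("P%02d", seq_along(scores)),
               organ = organ, percentile = x, score = scores, irae = labels,
               clinical_day = NA_real_)))
}

test_that("percentile selection takes the argmax with smallest-percentile ties", {
  # identical scores at every percentile: AUROC 0.5 everywhere -> grid minimum
  tab <- score_table_from(rep(1.5, 8), rep(c(0, 1), 4))
  sel <- selectOptimalPercentile(tab, "bowel")
  expect_equal(sel@opt_percentile, 50)
  expect_true(all(sel@scan$auroc == 0.5))

  # make percentile 95 informative only
  tab2 <- score_table_from(c(1, 1, 1, 1, 1, 1, 1, 1),
                           c(0, 0, 0, 0, 1, 1, 1, 1))
  tab2$score[tab2$percentile == 95 & tab2$irae == 1] <- 2
  sel2 <- selectOptimalPercentile(tab2, "bowel")
  expect_equal(sel2@opt_percentile, 95)
  expect_equal(sel2@auroc, 1)

  expect_error(selectOptimalPercentile(score_table_from(1:4, rep(1, 4)),
                                       "bowel"), "single-class")
})

test_that("diffuse-type cohorts give percentile-flat AUROC (monotone invariance)", {
  # positives are a uniform multiple of negatives at every percentile: the
  # score ordering, hence AUROC, is identical across the grid
  set.seed(207)
  base <- rlnorm(20, 0, 0.2)
  grid <- seq(50, 95, 5)
  tab <- do.call(rbind, lapply(grid, function(x) {
    q <- x / 100
    data.frame(patient_id = sprintf("P%02d", 1:20), organ = "thyroid",
               percentile = x,
               score = base * qlnorm(q, 0, 0.3) * ifelse(1:20 <= 6, 2, 1),
               irae = as.integer(1:20 <= 6), clinical_day = NA_real_)
  }))
  sel <- selectOptimalPercentile(tab, "thyroid")
  expect_lt(diff(range(sel@scan$auroc)), 1e-12)
  expect_equal(sel@opt_percentile, 50)
})

test_that("group comparison reports medians, p-value and significance", {
  set.seed(208)
  tab <- score_table_from(c(rnorm(6, 3, .2), rnorm(20, 2, .2)),
                          c(rep(1, 6), rep(0, 20)))
  sel <- selectOptimalPercentile(tab, "bowel")
  cmp <- compareGroups(tab, "bowel", sel)
  expect_gt(cmp$median_pos, cmp$median_neg)
  expect_true(cmp$significant)
  expect_equal(cmp$n_pos, 6)

  tab0 <- score_table_from(rnorm(8), rep(0, 8))
  expect_error(compareGroups(tab0, "bowel",
                             new("BiomarkerSelection", organ = "bowel",
                                 opt_percentile = 95, auroc = 0.5,
                                 scan = data.frame(percentile = 95,
                                                   auroc = 0.5))),
               "single-class")
})

test_that("score table takes the on-treatment max and supports censoring", {
  profiles <- rbind(
    data.frame(patient_id = "A", organ = "bowel", scan_day = -30,
               percentile = 95, suv_gml = 9, n_voxels = 10),
    data.frame(patient_id = "A", organ = "bowel", scan_day = 50,
               percentile = 95, suv_gml = 1.5, n_voxels = 10),
    data.frame(patient_id = "A", organ = "bowel", scan_day = 200,
               percentile = 95, suv_gml = 3.0, n_voxels = 10),
    data.frame(patient_id = "B", organ = "bowel", scan_day = -10,
               percentile = 95, suv_gml = 2, n_voxels = 10))
  truth <- data.frame(patient_id = "A", organ = "bowel", pattern = "focal",
                      onset_day = 40, clinical_day = 120, k = 2, f = .1)
  expect_message(tab <- buildScoreTable(profiles, truth), "excluding.*B")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$score, 3.0)  # baseline 9 excluded, max of on-treatment
  expect_equal(tab$irae, 1L)
  expect_equal(tab$clinical_day, 120)

  tabc <- suppressMessages(buildScoreTable(profiles, truth,
                                           censor_post_diagnosis = TRUE))
  expect_equal(tabc$score, 1.5)  # day-200 scan censored (after clinical day)
})

test_that("cohort percentages are recomputed from counts", {
  s <- cohortPrevalenceSummary(c(any = 18, bowel = 6, lung = 5, thyroid = 9),
                               58)
  expect_equal(s$percent, 100 * c(18, 6, 5, 9) / 58)
})
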