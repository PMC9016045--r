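#' Build the cohort score table
#'
#' One row per patient x organ x percentile with the patient's predictor
#' score: the maximum SUV_X\% over on-treatment scans (scan_day >= 0).
#' Baseline scans never enter the predictor. The irAE label is 1 when the
#' truth table records an event for that patient and organ; patients whose
#' irAE involve other organs are negatives for every target organ.
#'
#' @param profiles long-format profiles (patient_id, organ, scan_day,
#'   percentile, suv_gml).
#' @param truth truth/label table (patient_id, organ, clinical_day optional).
#' @param censor_post_diagnosis drop scans after the clinical detection day
#'   of that patient-organ event before taking the max (default keeps them).
#' @return data.frame (patient_id, organ, percentile, score, irae,
#'   clinical_day). Patients without on-treatment scans are dropped with a
#'   message.
#' @export
buildScoreTable <- function(profiles, truth, censor_post_diagnosis = FALSE) {
  on_tx <- profiles[profiles$scan_day >= 0, , drop = FALSE]
  dropped <- setdiff(unique(profiles$patient_id), unique(on_tx$patient_id))
  if (length(dropped))
    message("excluding patient(s) without on-treatment scans: ",
            paste(dropped, collapse = ", "))
  if (!nrow(on_tx)) stop("no on-treatment scans in the cohort", call. = FALSE)
  key <- function(df) paste(df$patient_id, df$organ)
  truth_key <- key(truth)
  clin <- stats::setNames(
    if (nrow(truth)) truth$clinical_day else numeric(0), truth_key)
  if (censor_post_diagnosis && nrow(truth)) {
    cd <- clin[key(on_tx)]
    keep <- is.na(cd) | on_tx$scan_day <= cd
    on_tx <- on_tx[keep, , drop = FALSE]
  }
  agg <- stats::aggregate(suv_gml ~ patient_id + organ + percentile,
                          data = on_tx, FUN = max)
  names(agg)[names(agg) == "suv_gml"] <- "score"
  agg$irae <- as.integer(key(agg) %in% truth_key)
  agg$clinical_day <- unname(clin[key(agg)])
  agg[order(agg$organ, agg$patient_id, agg$percentile), ]
}

#' Area under the ROC curve
#'
#' Probability that a random positive outscores a random negative, with ties
#' credited 1/2 (the Mann-Whitney identity AUROC = U / (n1 n2)). Higher
#' scores are treated as more irAE-like.
#'
#' @param pos_scores scores of irAE-positive patients (non-empty).
#' @param neg_scores scores of irAE-negative patients (non-empty).
#' @return AUROC in [0, 1].
#' @export
#' @examples
#' auroc(c(3, 4), c(1, 2))  # 1
#' auroc(c(1, 3), c(2, 4))  # 0.25
auroc <- function(pos_scores, neg_scores) {
  if (!length(pos_scores) || !length(neg_scores))
    stop("AUROC undefined: both score groups must be non-empty",
         call. = FALSE)
  mean(outer(pos_scores, neg_scores, ">") +
         0.5 * outer(pos_scores, neg_scores, "=="))
}

#' ROC curve under the score > threshold rule
#'
#' Candidate thresholds are the unique observed scores plus a -Inf sentinel;
#' a patient is called positive when score > T (strict, matching cutoff
#' statements like "SUV_95\% > 2.7 g/mL").
#'
#' @inheritParams auroc
#' @return data.frame (threshold, sensitivity, specificity), ordered by
#'   increasing threshold; sensitivity is non-increasing.
#' @export
rocCurve <- function(pos_scores, neg_scores) {
  if (!length(pos_scores) || !length(neg_scores))
    stop("ROC undefined: both score groups must be non-empty", call. = FALSE)
  thr <- c(-Inf, sort(unique(c(pos_scores, neg_scores))))
  data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(pos_scores > t), numeric(1)),
    specificity = vapply(thr, function(t) mean(neg_scores <= t), numeric(1)))
}

#' Youden-optimal cutoff
#'
#' Picks the threshold maximizing Youden's J = sensitivity + specificity - 1.
#' Ties are broken toward higher specificity, then lower threshold.
#'
#' @param curve a data.frame from [rocCurve()].
#' @param organ optional organ name for labelling.
#' @return A [CutoffResult-class].
#' @export
youdenCutoff <- function(curve, organ = NA_character_) {
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[order(-curve$specificity[best], curve$threshold[best])][1]
  new("CutoffResult", organ = organ, t_opt = curve$threshold[best],
      j = j[best], sensitivity = curve$sensitivity[best],
      specificity = curve$specificity[best])
}

#' Select the AUROC-optimal percentile for an organ
#'
#' Computes AUROC(x) for every percentile on the grid, using each patient's
#' max on-treatment SUV_x\% as the score, and returns the argmax
#' (SUV_OPT\%). AUROC ties are resolved toward the smallest percentile, the
#' more segmentation-robust choice.
#'
#' @param table score table from [buildScoreTable()].
#' @param organ organ name.
#' @return A [BiomarkerSelection-class]; its `scan` slot holds AUROC by
#'   percentile.
#' @export
selectOptimalPercentile <- function(table, organ) {
  tab <- table[table$organ == organ, , drop = FALSE]
  if (!nrow(tab)) stop("no rows for organ '", organ, "'", call. = FALSE)
  if (length(unique(tab$irae)) < 2)
    stop("single-class cohort: organ '", organ,
         "' lacks positives or negatives", call. = FALSE)
  grid <- sort(unique(tab$percentile))
  a <- vapply(grid, function(x) {
    sub <- tab[tab$percentile == x, ]
    auroc(sub$score[sub$irae == 1], sub$score[sub$irae == 0])
  }, numeric(1))
  opt <- grid[which(a >= max(a) - 1e-12)[1]]
  new("BiomarkerSelection", organ = organ, opt_percentile = opt,
      auroc = max(a), scan = data.frame(percentile = grid, auroc = a))
}

#' Scores at the selected percentile
#'
#' @param table score table from [buildScoreTable()].
#' @param selection a [BiomarkerSelection-class].
#' @return data.frame (patient_id, score, irae, clinical_day) at SUV_OPT\%.
#' @export
scoresAtOptimum <- function(table, selection) {
  sub <- table[table$organ == selection@organ &
                 table$percentile == selection@opt_percentile, ]
  sub[, c("patient_id", "score", "irae", "clinical_day")]
}

#' Wilcoxon rank-sum comparison
#'
#' Exact enumeration p-value when the combined sample size is at most 12 and
#' tie-free; otherwise the normal approximation with tie and continuity
#' correction (via [stats::wilcox.test()]).
#'
#' @param group_a,group_b numeric score vectors (non-empty).
#' @param exact override the exact/approximate choice.
#' @return list(statistic = Mann-Whitney U, p_value = two-sided p, exact).
#' @export
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
wilcoxonRankSum <- function(group_a, group_b, exact = NULL) {
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty", call. = FALSE)
  n <- length(group_a) + length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  if (is.null(exact)) exact <- n <= 12 && !ties
  res <- suppressWarnings(stats::wilcox.test(group_a, group_b, exact = exact,
                                             correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       exact = exact)
}

#' Compare irAE-positive and negative groups at SUV_OPT\%
#'
#' Dichotomizes patient maximum SUV_OPT\% by irAE status and tests the
#' difference with a Wilcoxon rank-sum test at alpha = 0.05.
#'
#' @param table score table from [buildScoreTable()].
#' @param organ organ name.
#' @param selection the organ's [BiomarkerSelection-class].
#' @return list(organ, median_pos, median_neg, n_pos, n_neg, p_value,
#'   significant, scores = the dichotomized per-patient table).
#' @export
compareGroups <- function(table, organ, selection) {
  sc <- scoresAtOptimum(table, selection)
  pos <- sc$score[sc$irae == 1]; neg <- sc$score[sc$irae == 0]
  if (!length(pos) || !length(neg))
    stop("single-class cohort: cannot compare groups for organ '", organ,
         "'", call. = FALSE)
  w <- wilcoxonRankSum(pos, neg)
  list(organ = organ, median_pos = stats::median(pos),
       median_neg = stats::median(neg), n_pos = length(pos),
       n_neg = length(neg), p_value = w$p_value,
       significant = w$p_value < 0.05, scores = sc)
}

#' Cohort prevalence summary
#'
#' Recomputes cohort percentages from event counts.
#'
#' @param counts named integer vector of patient counts.
#' @param n_total total cohort size.
#' @return data.frame (group, count, percent) with percent = 100 count / n.
#' @export
cohortPrevalenceSummary <- function(counts, n_total) {
  data.frame(group = names(counts), count = as.integer(counts),
             percent = 100 * as.numeric(counts) / n_total,
             row.names = NULL)
}
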