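#' Normative reference band from irAE-free baselines
#'
#' Sample mean and sd (n - 1 denominator) of one baseline SUV_OPT\% value per
#' patient, and the 95\% band \eqn{[\mu - 1.96\sigma, \mu + 1.96\sigma]}.
#' Eligible patients are those with no irAE of any organ, not merely none in
#' the target organ.
#'
#' @param baseline_values numeric, one baseline SUV_OPT\% per eligible patient.
#' @param organ organ name.
#' @return A [NormalRange-class].
#' @export
#' @examples
#' r <- normalRange(c(1, 2, 3), "bowel")
#' c(r@lo, r@hi)  # [0.04, 3.96]
normalRange <- function(baseline_values, organ) {
  n <- length(baseline_values)
  if (n < 2)
    stop("insufficient data: need >= 2 baseline patients, got ", n,
         call. = FALSE)
  mu <- mean(baseline_values)
  sigma <- stats::sd(baseline_values)
  new("NormalRange", organ = organ, mu = mu, sigma = sigma, n = as.integer(n),
      lo = mu - 1.96 * sigma, hi = mu + 1.96 * sigma)
}

#' Patient maximum over on-treatment scans
#'
#' The irAE predictor: the maximum SUV_OPT\% over scans with scan_day >= 0;
#' baseline scans are excluded.
#'
#' @param series data.frame (scan_day, value) for one patient and organ.
#' @return Maximum on-treatment value.
#' @export
patientMaxOnTreatment <- function(series) {
  on_tx <- series$value[series$scan_day >= 0]
  if (!length(on_tx))
    stop("exclusion: patient has no on-treatment scans", call. = FALSE)
  max(on_tx)
}

#' Monitor a longitudinal series against a normative band
#'
#' Flags scans whose SUV_OPT\% strictly exceeds the band's upper bound
#' (inflammation raises uptake, so only elevations are flagged; values equal
#' to the bound are not flags). Lead time is clinical_day minus the first
#' flagged day: positive when imaging flags the organ before clinical
#' detection.
#'
#' @param series data.frame (scan_day, value), days strictly increasing.
#' @param range the organ's [NormalRange-class].
#' @param clinical_day clinical irAE detection day (NA when none).
#' @return list(patient flags: data.frame(scan_day, value, flagged),
#'   first_flag_day, clinical_day, lead_time_days).
#' @export
monitorSeries <- function(series, range, clinical_day = NA_real_) {
  stopifnot(is(range, "NormalRange"), length(clinical_day) == 1L)
  if (is.unsorted(series$scan_day, strictly = TRUE))
    stop("scan days must be strictly increasing", call. = FALSE)
  flagged <- series$value > range@hi
  first_flag <- if (any(flagged)) series$scan_day[which(flagged)[1]] else
    NA_real_
  lead <- if (!is.na(first_flag) && !is.na(clinical_day))
    clinical_day - first_flag else NA_real_
  list(flags = data.frame(scan_day = series$scan_day, value = series$value,
                          flagged = flagged),
       first_flag_day = first_flag, clinical_day = clinical_day,
       lead_time_days = lead)
}

#' Extract one patient-organ longitudinal series
#'
#' @param profiles long-format profiles table.
#' @param patient_id,organ selectors.
#' @param percentile the percentile to track (the organ's SUV_OPT\%).
#' @return data.frame (scan_day, value) ordered by day.
#' @export
longitudinalSeries <- function(profiles, patient_id, organ, percentile) {
  sub <- profiles[profiles$patient_id == patient_id &
                    profiles$organ == organ &
                    profiles$percentile == percentile, ]
  sub <- sub[order(sub$scan_day), ]
  data.frame(scan_day = sub$scan_day, value = sub$suv_gml)
}

#' Cohort-level monitoring report
#'
#' Runs [monitorSeries()] for every patient x organ, joins the truth table,
#' and tabulates flags and lead times. Descriptive only: no inferential
#' comparison of imaging versus clinical detection timing is made.
#'
#' @param profiles long-format profiles table.
#' @param truth truth/label table (patient_id, organ, clinical_day).
#' @param ranges named list of [NormalRange-class] per organ.
#' @param percentiles named numeric, SUV_OPT\% per organ.
#' @return list(events: per-event data.frame (patient_id, organ, clinical_day,
#'   first_flag_day, lead_time_days, flagged_before_clinical),
#'   scans: per-scan data.frame (patient_id, organ, scan_day, value, flagged,
#'   clinical_day, lead_time_days), false_flag_rate: per-scan exceedance rate
#'   among event-free patient-organs, n_nonevent_scans).
#' @export
cohortMonitorReport <- function(profiles, truth, ranges, percentiles) {
  patients <- unique(profiles$patient_id)
  key <- function(p, o) paste(p, o)
  truth_key <- if (nrow(truth)) key(truth$patient_id, truth$organ) else
    character(0)
  events <- list(); scans <- list(); ff_flagged <- 0L; ff_total <- 0L
  for (p in patients) {
    for (organ in names(ranges)) {
      series <- longitudinalSeries(profiles, p, organ, percentiles[[organ]])
      if (!nrow(series)) next
      is_event <- key(p, organ) %in% truth_key
      clin <- if (is_event)
        truth$clinical_day[truth$patient_id == p & truth$organ == organ][1]
      else NA_real_
      mon <- monitorSeries(series, ranges[[organ]], clin)
      scans[[length(scans) + 1L]] <- data.frame(
        patient_id = p, organ = organ, scan_day = mon$flags$scan_day,
        value = mon$flags$value, flagged = mon$flags$flagged,
        clinical_day = clin, lead_time_days = mon$lead_time_days)
      if (is_event) {
        events[[length(events) + 1L]] <- data.frame(
          patient_id = p, organ = organ, clinical_day = clin,
          first_flag_day = mon$first_flag_day,
          lead_time_days = mon$lead_time_days,
          flagged_before_clinical = !is.na(mon$first_flag_day) &&
            mon$first_flag_day < clin)
      } else {
        ff_flagged <- ff_flagged + sum(mon$flags$flagged)
        ff_total <- ff_total + nrow(mon$flags)
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(patient_id = character(), organ = character(),
               clinical_day = numeric(), first_flag_day = numeric(),
               lead_time_days = numeric(),
               flagged_before_clinical = logical())
  list(events = events, scans = do.call(rbind, scans),
       false_flag_rate = if (ff_total) ff_flagged / ff_total else NA_real_,
       n_nonevent_scans = ff_total)
}
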