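#' Encapsulation (entrapment) efficiency
#'
#' EE% = 100 * entrapped / total added. Values above 100% are passed
#' through unmodified: with HPLC quantitation against external standards,
#' measured entrapped amounts can slightly exceed the nominal addition.
#'
#' @param entrapped_amount Amount of drug entrapped (mass or
#'   concentration), >= 0.
#' @param total_added Total amount added, same units, > 0.
#' @return Encapsulation efficiency, percent.
#' @examples
#' entrapment_efficiency(97.45, 100)
#' @export
entrapment_efficiency <- function(entrapped_amount, total_added) {
  stopifnot(is.numeric(entrapped_amount), is.numeric(total_added))
  if (any(total_added <= 0))
    stop("total_added must be > 0, got ", paste(total_added, collapse = ", "))
  if (any(entrapped_amount < 0))
    stop("entrapped_amount must be >= 0")
  100 * entrapped_amount / total_added
}

#' EPR amplitude records for radical-decay bookkeeping
#'
#' @param compound Character labels.
#' @param dose Absorbed dose, kGy, >= 0.
#' @param amplitude_initial Signal amplitude shortly after irradiation,
#'   arbitrary units, > 0.
#' @param amplitude_3months Signal amplitude after storage, a.u., >= 0.
#'   Growth (amplitude above initial) is allowed and shows up as negative
#'   decay.
#' @return A data.frame of class `"amplitude_records"`.
#' @export
amplitude_records <- function(compound, dose, amplitude_initial,
                              amplitude_3months) {
  n <- length(compound)
  stopifnot(length(dose) == n, length(amplitude_initial) == n,
            length(amplitude_3months) == n)
  if (any(dose < 0)) stop("dose must be >= 0 kGy")
  if (any(amplitude_initial <= 0))
    stop("amplitude_initial must be > 0 for every record")
  if (any(amplitude_3months < 0))
    stop("amplitude_3months must be >= 0")
  structure(data.frame(compound = compound, dose_kGy = dose,
                       amplitude_initial = amplitude_initial,
                       amplitude_3m = amplitude_3months),
            class = c("amplitude_records", "data.frame"))
}

#' EPR signal-amplitude decay over storage
#'
#' Per-record decay is 100 * (A0 - A3m) / A0, the percentage of the
#' initial radical signal lost over storage. The mean is taken over
#' irradiated records only by default: native (0 kGy) signals do not track
#' radiation-induced paramagnetic centers, so mixing them in would dilute
#' the quantity of interest. A record whose amplitude grew yields a
#' negative decay and is flagged.
#'
#' @param records An [amplitude_records()] data.frame.
#' @param irradiated_only Restrict the mean to dose > 0 records
#'   (default TRUE).
#' @return A list with `per_record` (records plus `decay_pct` and `grew`)
#'   and `mean_decay_pct`.
#' @examples
#' r <- amplitude_records("HON", 400, 71.2, 15.0)
#' epr_amplitude_decay(r)$per_record$decay_pct  # 78.93
#' @export
epr_amplitude_decay <- function(records, irradiated_only = TRUE) {
  stopifnot(inherits(records, "amplitude_records"))
  decay <- 100 * (records$amplitude_initial - records$amplitude_3m) /
    records$amplitude_initial
  per <- cbind(as.data.frame(records), decay_pct = decay, grew = decay < 0)
  sel <- if (irradiated_only) records$dose_kGy > 0 else rep(TRUE, nrow(records))
  if (!any(sel))
    stop("no records selected for the mean",
         if (irradiated_only) " (all doses are 0 kGy)" else "")
  list(per_record = per, mean_decay_pct = mean(decay[sel]))
}

#' Drug content relative to a reference, with propagated uncertainty
#'
#' Content percent is 100 * measured / reference. The standard deviation
#' is propagated by the first-order delta method for a ratio of
#' independent means:
#' \deqn{sd\% = 100 \frac{\mu_m}{\mu_r}
#'   \sqrt{(\sigma_m/\mu_m)^2 + (\sigma_r/\mu_r)^2}.}
#'
#' @param measured_mean,measured_sd Measured content and its s.d.
#' @param reference_mean,reference_sd Reference content and its s.d.;
#'   `reference_mean` must be > 0.
#' @return A list with `mean_pct` and `sd_pct`.
#' @examples
#' content_percent(100, 1, 100, 1)  # mean 100, sd sqrt(2)
#' @export
content_percent <- function(measured_mean, measured_sd,
                            reference_mean, reference_sd) {
  if (any(reference_mean <= 0))
    stop("reference_mean must be > 0, got ", reference_mean)
  if (any(measured_sd < 0) || any(reference_sd < 0))
    stop("standard deviations must be >= 0")
  mean_pct <- 100 * measured_mean / reference_mean
  sd_pct <- mean_pct * sqrt((measured_sd / measured_mean)^2 +
                            (reference_sd / reference_mean)^2)
  list(mean_pct = mean_pct, sd_pct = sd_pct)
}

#' Degradation-product peak-area fraction
#'
#' The summed areas of degradation-product peaks as a percentage of the
#' total peak area of the chromatogram.
#'
#' @param degradation_peak_areas Numeric vector of degradation peak
#'   areas, >= 0 (may be empty).
#' @param all_peak_areas_total Total peak area, > 0; must be at least the
#'   degradation sum (otherwise peaks are mislabeled).
#' @return Fraction in percent.
#' @examples
#' degradation_area_fraction(c(1, 2), 100)  # 3
#' @export
degradation_area_fraction <- function(degradation_peak_areas,
                                      all_peak_areas_total) {
  stopifnot(is.numeric(all_peak_areas_total), length(all_peak_areas_total) == 1L)
  if (all_peak_areas_total <= 0)
    stop("all_peak_areas_total must be > 0, got ", all_peak_areas_total)
  if (length(degradation_peak_areas) > 0 && any(degradation_peak_areas < 0))
    stop("peak areas must be >= 0")
  s <- sum(degradation_peak_areas)
  if (s > all_peak_areas_total)
    stop("degradation peak areas sum to ", s, ", exceeding the total ",
         all_peak_areas_total, "; peaks are mislabeled")
  100 * s / all_peak_areas_total
}
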