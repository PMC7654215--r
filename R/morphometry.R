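# Quantitative cell-biology procedures: cumulative population doubling
# from cell-count passages, and nuclear morphometric classification based
# on area and the nuclear irregularity index.

#' Nuclear irregularity index
#'
#' `NII = Asp - Arbx + Rr + Rou`: aspect ratio minus area/bounding-box
#' ratio plus radius ratio plus roundness.  Increases with nuclear shape
#' irregularity.  Vectorized.
#'
#' @param aspect Aspect ratio (Asp, >= 1).
#' @param areabox Area/bounding-box ratio (Arbx, in (0, 1\]).
#' @param radius_ratio Radius ratio (Rr, >= 1).
#' @param roundness Roundness (Rou, > 0).
#' @return Numeric vector of NII values.
#' @export
nii <- function(aspect, areabox, radius_ratio, roundness) {
  args <- list(aspect, areabox, radius_ratio, roundness)
  if (any(vapply(args, function(a) any(is.na(a)) || length(a) == 0L, TRUE)))
    stop_hb("hb_missing_metric", "all four shape metrics must be present")
  aspect - areabox + radius_ratio + roundness
}

#' Classify nuclei by size and irregularity against a control reference
#'
#' Area and NII are referenced to the control sample's mean and SD.  Size
#' is `small` below `mean - k_area * SD`, `large` above
#' `mean + k_area * SD`, otherwise normal; shape is `irregular` above
#' `mean + k_nii * SD` of the control NII (one-sided: NII increases with
#' irregularity), otherwise regular.  Classes: small+regular = `SR`,
#' small+irregular = `SI`, large+regular = `LR`, large+irregular = `LIr`,
#' any normal-sized nucleus = `N`.
#'
#' @param records Data.frame of nucleus records (`area`, `aspect`,
#'   `areabox`, `radius_ratio`, `roundness`).
#' @param control Data.frame of control nucleus records (same columns).
#' @param k_area,k_nii Threshold multipliers in control-SD units
#'   (defaults 2, the conventional ~95% reference band).
#' @return `records` with added `nii` and `class` columns; thresholds are
#'   attached as attribute `thresholds`.
#' @export
classify_nuclei <- function(records, control, k_area = 2, k_nii = 2) {
  if (nrow(control) == 0L)
    stop_hb("hb_bad_argument", "control sample must be nonempty")
  ctrl_nii <- nii(control$aspect, control$areabox, control$radius_ratio,
                  control$roundness)
  a_mean <- mean(control$area); a_sd <- stats::sd(control$area)
  n_mean <- mean(ctrl_nii); n_sd <- stats::sd(ctrl_nii)
  if (!is.finite(a_sd) || a_sd == 0 || !is.finite(n_sd) || n_sd == 0)
    stop_hb("hb_degenerate_control", "control SD is zero")
  records$nii <- nii(records$aspect, records$areabox, records$radius_ratio,
                     records$roundness)
  size <- ifelse(records$area < a_mean - k_area * a_sd, "small",
                 ifelse(records$area > a_mean + k_area * a_sd, "large",
                        "normal"))
  irregular <- records$nii > n_mean + k_nii * n_sd
  records$class <- ifelse(size == "small" & !irregular, "SR",
                   ifelse(size == "small" & irregular, "SI",
                   ifelse(size == "large" & !irregular, "LR",
                   ifelse(size == "large" & irregular, "LIr", "N"))))
  attr(records, "thresholds") <- list(
    area_mean = a_mean, area_sd = a_sd, nii_mean = n_mean, nii_sd = n_sd,
    k_area = k_area, k_nii = k_nii)
  records
}

#' Population doubling between two cell counts
#'
#' `PD = [log N(t) - log N(t0)] / log 2`, the number of doublings taking
#' the culture from `n_start` to `n_end` cells.
#'
#' @param n_start,n_end Positive cell counts.
#' @return Numeric PD value (negative when the population shrinks).
#' @export
population_doubling <- function(n_start, n_end) {
  if (any(n_start <= 0) || any(n_end <= 0))
    stop_hb("hb_bad_argument", "cell counts must be positive")
  (log(n_end) - log(n_start)) / log(2)
}

#' Cumulative population doubling over a growth series
#'
#' Running sum of per-passage PD values against culture day.
#'
#' @param series Data.frame with columns `day`, `n_start`, `n_end`
#'   (strictly increasing days, positive counts).
#' @return Data.frame with columns `day`, `pd`, `cpd`.
#' @export
cumulative_pd <- function(series) {
  if (nrow(series) == 0L)
    stop_hb("hb_bad_argument", "growth series must be nonempty")
  if (is.unsorted(series$day, strictly = TRUE))
    stop_hb("hb_bad_argument", "days must be strictly increasing")
  pd <- population_doubling(series$n_start, series$n_end)
  data.frame(day = series$day, pd = pd, cpd = cumsum(pd))
}
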