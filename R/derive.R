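#' Relative lens position
#'
#' RLP = (ACD + LT/2) / AL x 10: the position of the crystalline lens
#' midpoint along the eye's axis, relative to axial length. Although often
#' tabulated with an "mm" label, the quantity is a dimensionless ratio
#' scaled by 10; it is reported here without units.
#'
#' @param ACD anterior chamber depth, mm.
#' @param LT lens thickness, mm.
#' @param AL axial length, mm.
#' @return dimensionless RLP (vectorized).
#' @examples
#' relative_lens_position(3.68, 3.46, 25.16)  # ~2.15
#' @export
relative_lens_position <- function(ACD, LT, AL) {
  if (any(!is.finite(ACD) | ACD <= 0) || any(!is.finite(LT) | LT <= 0) ||
      any(!is.finite(AL) | AL <= 0))
    stop("ACD, LT and AL must be positive")
  if (any(ACD + LT >= AL))
    stop("ACD + LT must be smaller than AL")
  (ACD + LT / 2) / AL * 10
}

#' Mean blood pressure
#'
#' MBP = DBP + (SBP - DBP) / 3.
#'
#' @param SBP systolic blood pressure, mmHg.
#' @param DBP diastolic blood pressure, mmHg.
#' @return MBP in mmHg (vectorized).
#' @export
mean_blood_pressure <- function(SBP, DBP) {
  if (any(!is.finite(SBP) | !is.finite(DBP) | DBP <= 0))
    stop("blood pressures must be finite and positive")
  if (any(SBP <= DBP)) stop("SBP must exceed DBP")
  DBP + (SBP - DBP) / 3
}

#' Mean ocular perfusion pressure
#'
#' MOPP = 2/3 x MBP - IOP, the driving pressure for ocular blood flow.
#'
#' @inheritParams mean_blood_pressure
#' @param IOP intraocular pressure, mmHg (> 0).
#' @return MOPP in mmHg (vectorized).
#' @export
mopp <- function(SBP, DBP, IOP) {
  if (any(!is.finite(IOP) | IOP <= 0)) stop("IOP must be positive")
  (2 / 3) * mean_blood_pressure(SBP, DBP) - IOP
}

# round half away from zero to `digits` decimals (report-style rounding;
# base round() rounds half to even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Axial-length group
#'
#' Assigns eyes to AL1 (21.0-24.0 mm), AL2 (24.1-25.0 mm), AL3
#' (25.1-26.0 mm) or AL4 (26.1-28.5 mm). The bins are one-decimal report
#' intervals: AL is first rounded half-up to one decimal, then matched to
#' the closed intervals, so every value in \[21.0, 28.5\] is assignable
#' (24.04 -> AL1, 24.05 -> AL2). Values outside \[21.0, 28.5\] are flagged
#' `"out_of_range"` rather than silently grouped.
#'
#' @param AL axial length(s), mm.
#' @return character vector of `"AL1"`..`"AL4"` or `"out_of_range"`.
#' @export
al_group <- function(AL) {
  if (any(!is.finite(AL))) stop("AL must be finite")
  a <- round_half_up(AL, 1)
  out <- rep("out_of_range", length(a))
  out[a >= 21.0 & a <= 24.0] <- "AL1"
  out[a >= 24.1 & a <= 25.0] <- "AL2"
  out[a >= 25.1 & a <= 26.0] <- "AL3"
  out[a >= 26.1 & a <= 28.5] <- "AL4"
  out
}

#' Eye-level inclusion screen
#'
#' Applies the numeric inclusion/exclusion screens implementable from a
#' tabular record: age 17-20 years, AL 21.0-29 mm, astigmatism within
#' +/-3.00 D (if supplied), IOP <= 21 mmHg, OCTA signal strength > 6 and
#' motion artifact score < 3 (if supplied), plus boolean flags for
#' qualitative exclusions (`pathologic_myopia`, `ocular_disease`,
#' `surgery_history`, `systemic_disease`, `poor_image`) when present as
#' columns. Returns the first failing reason per eye.
#'
#' @param biometry data.frame with at least `age`, `AL`, `IOP`; optional
#'   `astigmatism`, `signal_strength`, `motion_score` and the boolean flag
#'   columns above.
#' @return data.frame with columns `included` (logical) and
#'   `exclusion_reason` (`""` when included).
#' @export
include_eye <- function(biometry) {
  need <- c("age", "AL", "IOP")
  miss <- setdiff(need, names(biometry))
  if (length(miss))
    stop("missing mandatory field(s): ", paste(miss, collapse = ", "))
  n <- nrow(biometry)
  reason <- rep("", n)
  fail <- function(reason, cond, label) ifelse(reason == "" & cond, label, reason)
  reason <- fail(reason, biometry$age < 17 | biometry$age > 20, "age")
  reason <- fail(reason, biometry$AL < 21.0 | biometry$AL > 29, "AL")
  if ("astigmatism" %in% names(biometry))
    reason <- fail(reason, abs(biometry$astigmatism) > 3.00, "astigmatism")
  reason <- fail(reason, biometry$IOP > 21, "IOP")
  if ("signal_strength" %in% names(biometry))
    reason <- fail(reason, biometry$signal_strength <= 6, "image quality")
  if ("motion_score" %in% names(biometry))
    reason <- fail(reason, biometry$motion_score >= 3, "image quality")
  for (flag in c("poor_image", "pathologic_myopia", "ocular_disease",
                 "surgery_history", "systemic_disease")) {
    if (flag %in% names(biometry))
      reason <- fail(reason, isTRUE_vec(biometry[[flag]]), flag)
  }
  data.frame(included = reason == "", exclusion_reason = reason,
             stringsAsFactors = FALSE)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Append derived indices to a cohort table
#'
#' Adds `RLP`, `MBP`, `MOPP`, `al_group`, `included`, `exclusion_reason`
#' columns computed from the biometry columns.
#'
#' @param cohort data.frame with biometry columns (`ACD`, `LT`, `AL`,
#'   `SBP`, `DBP`, `IOP`, `age`, ...).
#' @return the cohort with derived columns appended.
#' @export
derive_ocular <- function(cohort) {
  cohort$RLP <- relative_lens_position(cohort$ACD, cohort$LT, cohort$AL)
  cohort$MBP <- mean_blood_pressure(cohort$SBP, cohort$DBP)
  cohort$MOPP <- mopp(cohort$SBP, cohort$DBP, cohort$IOP)
  cohort$al_group <- al_group(cohort$AL)
  scr <- include_eye(cohort)
  cohort$included <- scr$included
  cohort$exclusion_reason <- scr$exclusion_reason
  cohort
}
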