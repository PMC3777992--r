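#' @include AllGenerics.R
NULL

#' Fit a qPCR input-dilution standard curve
#'
#' Ordinary least-squares fit of Ct against log10(dilution fraction) for
#' one locus's input-dilution wells.  The amplification base is
#' `b = 10^(-1/slope)` (2.0 for perfect doubling, i.e. slope -3.3219) and
#' the efficiency `b - 1`.
#'
#' @param wells data.frame of wells with columns `locus`, `role`,
#'   `dilution_fraction`, `ct`; only rows with `role == "input_dilution"`
#'   are used, and they must belong to a single locus.
#' @return a [StandardCurve-class].
#' @export
fitInputStandardCurve <- function(wells) {
  w <- wells[wells$role == "input_dilution", , drop = FALSE]
  if (nrow(w) == 0L) stop("no input-dilution wells supplied")
  locus <- unique(w$locus)
  if (length(locus) != 1L)
    stop("input wells span several loci: ", paste(locus, collapse = ", "))
  if (any(!is.finite(w$dilution_fraction) | w$dilution_fraction <= 0 |
            w$dilution_fraction > 1))
    stop("input dilution fractions must lie in (0, 1]")
  if (length(unique(w$dilution_fraction)) < 3L)
    stop("need at least 3 distinct dilution fractions, have ",
         length(unique(w$dilution_fraction)))
  if (any(w$ct <= 0)) stop("Ct values must be positive")
  fit <- stats::lm(ct ~ log10(dilution_fraction), data = w)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop(sprintf("standard curve failed for locus '%s': slope %.4g >= 0",
                 locus, slope))
  ssTot <- sum((w$ct - mean(w$ct))^2)
  r2 <- if (ssTot > 0) 1 - sum(stats::residuals(fit)^2) / ssTot else 1
  new("StandardCurve",
      locus = locus,
      slope = slope,
      intercept = unname(coef(fit)[1]),
      base = 10^(-1 / slope),
      efficiency = 10^(-1 / slope) - 1,
      rSquared = r2,
      ctRange = range(w$ct),
      nDilutions = length(unique(w$dilution_fraction)))
}

#' Invert a standard curve: IP Ct to pull-down efficacy
#'
#' The input-fraction equivalent of a Ct value:
#' `10^((ct - intercept) / slope)`.  Exact inverse of the fitted line, so
#' the Ct of the f-fraction input well maps back to f.
#'
#' @param curve a [StandardCurve-class].
#' @param ct numeric Ct values.
#' @return pull-down efficacies (fractions of input).
#' @export
pulldownEfficacy <- function(curve, ct) {
  stopifnot(is(curve, "StandardCurve"))
  10^((ct - curve@intercept) / curve@slope)
}

#' ChIP-qPCR relative enrichment
#'
#' Converts each IP replicate's Ct into a pull-down efficacy via the
#' locus's input-dilution curve, averages efficacies on the linear scale,
#' and reports the target's mean efficacy normalized to the control
#' locus's (alpha-actinin-style normalization).  The SEM of the ratio is
#' propagated to first order (delta method).  IP Ct values outside the
#' dilution-calibrated Ct range are flagged as extrapolated.
#'
#' @param ipWells data.frame of the target locus's IP wells (`role ==
#'   "ip"`, column `ct`).
#' @param curveTarget,curveControl [StandardCurve-class] objects for the
#'   target and control locus.
#' @param controlIpWells data.frame of the control locus's IP wells.
#' @return data.frame with one row: `locus`, `control_locus`,
#'   `pulldown_efficacy`, `efficacy_sem`, `control_efficacy`,
#'   `relative_enrichment`, `enrichment_sem`, `n_replicates`,
#'   `extrapolated`.
#' @export
chipQpcrEnrichment <- function(ipWells, curveTarget, curveControl,
                               controlIpWells) {
  stopifnot(is(curveTarget, "StandardCurve"),
            is(curveControl, "StandardCurve"))
  getIp <- function(wells, curve) {
    w <- wells[wells$role == "ip", , drop = FALSE]
    if (nrow(w) == 0L)
      stop("no IP wells for locus '", curve@locus, "'")
    list(eff = pulldownEfficacy(curve, w$ct),
         outside = any(w$ct < curve@ctRange[1] - 1e-9 |
                         w$ct > curve@ctRange[2] + 1e-9))
  }
  tg <- getIp(ipWells, curveTarget)
  ct <- getIp(controlIpWells, curveControl)
  mT <- mean(tg$eff); sT <- semOf(tg$eff)
  mC <- mean(ct$eff); sC <- semOf(ct$eff)
  rel <- mT / mC
  relSem <- if (is.na(sT) || is.na(sC)) NA_real_
    else rel * sqrt((sT / mT)^2 + (sC / mC)^2)
  extrap <- tg$outside || ct$outside
  if (extrap)
    warning("IP Ct outside the dilution-calibrated range for locus '",
            curveTarget@locus, "' or '", curveControl@locus,
            "'; enrichment is an extrapolation")
  data.frame(locus = curveTarget@locus,
             control_locus = curveControl@locus,
             pulldown_efficacy = mT,
             efficacy_sem = sT,
             control_efficacy = mC,
             relative_enrichment = rel,
             enrichment_sem = relSem,
             n_replicates = length(tg$eff),
             extrapolated = extrap,
             stringsAsFactors = FALSE)
}

#' Delta-delta-Ct relative expression
#'
#' Classic ddCt: per sample, `dCt = Ct(target) - Ct(control locus)`
#' (replicate-paired, then averaged); `ddCt = dCt(sample) -
#' dCt(reference)`; `fold = base^(-ddCt)` with base 2 by default.  The
#' reference sample's fold is exactly 1 by construction.  Replicate-level
#' folds (each replicate's dCt against the reference mean dCt) provide the
#' SEM on the fold scale.
#'
#' @param wells data.frame with columns `sample`, `locus`, `replicate`,
#'   `ct`.
#' @param targetLocus,controlLocus locus names (control defaults to
#'   RPL32).
#' @param referenceSample sample whose expression defines fold 1.
#' @param base amplification base; 2 for the classic method, or a fitted
#'   per-locus base for efficiency-corrected folds.
#' @return data.frame, one row per sample: `sample`, `d_ct`, `dd_ct`,
#'   `fold_change`, `fold_sem`, `n_replicates`, `is_reference`.
#' @export
ddctExpression <- function(wells, targetLocus, controlLocus = "RPL32",
                           referenceSample, base = 2) {
  need <- c("sample", "locus", "replicate", "ct")
  if (!all(need %in% names(wells)))
    stop("expression table needs columns sample, locus, replicate, ct")
  samples <- unique(wells$sample)
  if (!referenceSample %in% samples)
    stop("reference sample '", referenceSample, "' not in table")
  dctOf <- function(s) {
    w <- wells[wells$sample == s, , drop = FALSE]
    tg <- w[w$locus == targetLocus, , drop = FALSE]
    ctl <- w[w$locus == controlLocus, , drop = FALSE]
    if (nrow(ctl) == 0L)
      stop("sample '", s, "' is missing control locus '", controlLocus, "'")
    if (nrow(tg) == 0L)
      stop("sample '", s, "' is missing target locus '", targetLocus, "'")
    idx <- match(tg$replicate, ctl$replicate)
    if (anyNA(idx))
      stop("sample '", s, "' has unpaired replicates between loci")
    tg$ct - ctl$ct[idx]
  }
  refDct <- mean(dctOf(referenceSample))
  rows <- lapply(samples, function(s) {
    dct <- dctOf(s)
    ddct <- mean(dct) - refDct
    folds <- base^(-(dct - refDct))
    data.frame(sample = s,
               d_ct = mean(dct),
               dd_ct = ddct,
               fold_change = base^(-ddct),
               fold_sem = semOf(folds),
               n_replicates = length(dct),
               is_reference = s == referenceSample,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Beta-galactosidase activity from an OD574 time series
#'
#' Activity is the least-squares slope of OD574 against time (OD/min).
#' Optionally, readings after the OD has crossed a ceiling are dropped to
#' restrict the fit to the linear range.  Negative slopes are clamped to
#' zero and flagged.
#'
#' @param time_min read times, minutes (at least 3 distinct values).
#' @param od574 optical densities at 574 nm.
#' @param odCeiling optional linear-range ceiling; readings after the
#'   first one above it are dropped.
#' @return list with `activity` (OD/min), `clamped` (TRUE if a negative
#'   slope was clamped to 0), `n_points` used.
#' @export
betaGalActivity <- function(time_min, od574, odCeiling = NULL) {
  if (length(time_min) != length(od574))
    stop("time and OD vectors differ in length")
  if (!is.null(odCeiling)) {
    over <- which(od574 > odCeiling)
    if (length(over) > 1L) {
      keep <- seq_len(over[1])
      time_min <- time_min[keep]
      od574 <- od574[keep]
    }
  }
  if (length(unique(time_min)) < 3L)
    stop("need at least 3 distinct time points; have ",
         length(unique(time_min)))
  slope <- unname(coef(stats::lm(od574 ~ time_min))[2])
  clamped <- slope < 0
  list(activity = max(slope, 0), clamped = clamped,
       n_points = length(time_min))
}

#' Per-class pigment summary
#'
#' Mean and SEM of the OD480 endpoint per genotype class, optionally
#' normalized per fly.
#'
#' @param samples data.frame with columns `genotype_class`, `od480` and
#'   (if `perFly`) `flies_per_sample`.
#' @param perFly divide each sample's OD by its fly count.
#' @return data.frame with columns `genotype_class`, `mean`, `sem`, `n`.
#' @export
pigmentSummary <- function(samples, perFly = FALSE) {
  need <- c("genotype_class", "od480")
  if (!all(need %in% names(samples)))
    stop("pigment table needs columns genotype_class, od480")
  if (any(samples$od480 < 0)) stop("OD values must be >= 0")
  val <- samples$od480
  if (perFly) {
    if (!"flies_per_sample" %in% names(samples))
      stop("perFly = TRUE requires a flies_per_sample column")
    val <- val / samples$flies_per_sample
  }
  cls <- unique(samples$genotype_class)
  ns <- table(samples$genotype_class)[cls]
  if (any(ns < 2L))
    stop("genotype class '", cls[which(ns < 2L)[1]],
         "' has fewer than 2 samples; SEM undefined")
  out <- data.frame(
    genotype_class = cls,
    mean = as.numeric(tapply(val, samples$genotype_class, mean)[cls]),
    sem = as.numeric(tapply(val, samples$genotype_class, semOf)[cls]),
    n = as.integer(ns),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Genotype-class fold changes
#'
#' Per-class mean, SEM and fold change versus a designated control class
#' (e.g. C for the C/M/Z/M+Z depletion design, or WT for WT/KD), with the
#' ratio SEM propagated to first order.  The control class's fold is
#' exactly 1 with SEM 0 (a self-ratio carries no sampling error of its
#' own).  Class order is preserved as given.
#'
#' @param values data.frame with columns `genotype_class` and `value`
#'   (one row per replicate), or an already-summarized data.frame with
#'   columns `genotype_class`, `mean`, `sem`, `n`.
#' @param controlClass the reference class.
#' @return data.frame with columns `genotype_class`, `mean`, `sem`, `n`,
#'   `fold_change`, `fold_sem`.
#' @export
genotypeFoldChanges <- function(values, controlClass) {
  if (all(c("genotype_class", "value") %in% names(values))) {
    cls <- unique(values$genotype_class)
    summ <- data.frame(
      genotype_class = cls,
      mean = as.numeric(tapply(values$value, values$genotype_class,
                               mean)[cls]),
      sem = as.numeric(tapply(values$value, values$genotype_class,
                              semOf)[cls]),
      n = as.integer(table(values$genotype_class)[cls]),
      stringsAsFactors = FALSE)
  } else if (all(c("genotype_class", "mean", "sem", "n") %in%
                   names(values))) {
    summ <- values
  } else {
    stop("values must have columns (genotype_class, value) or ",
         "(genotype_class, mean, sem, n)")
  }
  if (any(summ$n < 2L))
    stop("every genotype class needs n >= 2")
  if (!controlClass %in% summ$genotype_class)
    stop("control class '", controlClass, "' absent")
  mC <- summ$mean[summ$genotype_class == controlClass]
  sC <- summ$sem[summ$genotype_class == controlClass]
  if (mC == 0) stop("control class mean is 0; folds undefined")
  summ$fold_change <- summ$mean / mC
  summ$fold_sem <- summ$fold_change *
    sqrt((summ$sem / summ$mean)^2 + (sC / mC)^2)
  isCtrl <- summ$genotype_class == controlClass
  summ$fold_change[isCtrl] <- 1
  summ$fold_sem[isCtrl] <- 0
  rownames(summ) <- NULL
  summ
}
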