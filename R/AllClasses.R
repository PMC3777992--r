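#' @include utils.R
NULL

#' Per-probe M-value track
#'
#' Holds one record per tiling-array probe: genomic position (width-1
#' ranges at the probe midpoint, 1-based in the `GRanges`, corresponding to
#' 0-based midpoints on disk), the M value (log2 ChIP/input), and the
#' uniqueness (mappability) flag.  `normalized` records whether the track
#' has been median-centered over unique probes.
#'
#' @slot probes `GRanges` with metadata columns `m` (numeric) and `unique`
#'   (logical).
#' @slot normalized single logical.
#' @exportClass MTrack
setClass("MTrack",
         slots = c(probes = "GRanges", normalized = "logical"))

setValidity("MTrack", function(object) {
  mc <- S4Vectors::mcols(object@probes)
  if (!all(c("m", "unique") %in% names(mc)))
    return("probes must carry metadata columns 'm' and 'unique'")
  if (!is.numeric(mc$m) || any(!is.finite(mc$m)))
    return("all M values must be finite")
  if (!is.logical(mc$unique) || anyNA(mc$unique))
    return("'unique' must be logical without NA")
  if (length(object@normalized) != 1L || is.na(object@normalized))
    return("'normalized' must be a single TRUE/FALSE")
  if (object@normalized && any(mc$unique)) {
    med <- stats::median(mc$m[mc$unique])
    if (abs(med) > 1e-9)
      return(sprintf("normalized track has unique-probe median %.3g != 0", med))
  }
  TRUE
})

#' Fixed-width binned enrichment track
#'
#' Mean M value per half-open genomic bin `[start, start + bin_width)`,
#' bins aligned to multiples of `bin_width` from arm coordinate 0.  Bins
#' with no retained probes are omitted, never zero-filled.
#'
#' @slot bins `GRanges` (width `binWidth`) with metadata columns `mean_m`
#'   and `n_probes`.
#' @slot binWidth bin width in bp.
#' @exportClass BinTrack
setClass("BinTrack",
         slots = c(bins = "GRanges", binWidth = "numeric"))

setValidity("BinTrack", function(object) {
  if (length(object@binWidth) != 1L || object@binWidth <= 0)
    return("binWidth must be a single positive number")
  mc <- S4Vectors::mcols(object@bins)
  if (!all(c("mean_m", "n_probes") %in% names(mc)))
    return("bins must carry 'mean_m' and 'n_probes'")
  if (length(object@bins)) {
    if (any(mc$n_probes < 1L))
      return("every emitted bin must contain at least one probe")
    start0 <- BiocGenerics::start(object@bins) - 1L
    if (any(start0 %% object@binWidth != 0))
      return("bin starts must be multiples of binWidth")
    if (any(BiocGenerics::width(object@bins) != object@binWidth))
      return("all bins must have width binWidth")
  }
  TRUE
})

#' Genome annotation: arms and labeled feature intervals
#'
#' The chromosome-arm table (name, length, telomere orientation,
#' pericentric border, chromosome-4 flag) together with transposable
#' element instances (family-labeled), piRNA clusters (id-labeled) and
#' optional named reporter loci.  All intervals are stored 1-based in
#' `GRanges` but read from and written to disk as 0-based half-open BED.
#'
#' @slot arms data.frame with columns `name`, `length`,
#'   `telomere_at_start`, `pericentric_border`, `is_chr4`.
#' @slot teInstances `GRanges` with metadata column `family`.
#' @slot pirnaClusters `GRanges` with metadata column `cluster_id`.
#' @slot reporterLoci `GRanges` with metadata column `name` (may be empty).
#' @exportClass FeatureSet
setClass("FeatureSet",
         slots = c(arms = "data.frame",
                   teInstances = "GRanges",
                   pirnaClusters = "GRanges",
                   reporterLoci = "GRanges"))

setValidity("FeatureSet", function(object) {
  ok <- tryCatch({ checkArmTable(object@arms); TRUE },
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) return(ok)
  arms <- object@arms
  checkWithin <- function(gr, what) {
    if (!length(gr)) return(TRUE)
    idx <- match(as.character(GenomeInfoDb::seqnames(gr)), arms$name)
    if (anyNA(idx))
      return(sprintf("%s reference unknown arms", what))
    if (any(BiocGenerics::start(gr) < 1L) ||
        any(BiocGenerics::end(gr) > arms$length[idx]))
      return(sprintf("%s extend beyond arm bounds", what))
    TRUE
  }
  for (chk in list(checkWithin(object@teInstances, "TE instances"),
                   checkWithin(object@pirnaClusters, "piRNA clusters"),
                   checkWithin(object@reporterLoci, "reporter loci")))
    if (!isTRUE(chk)) return(chk)
  fam <- S4Vectors::mcols(object@teInstances)$family
  if (length(object@teInstances) &&
      (is.null(fam) || any(is.na(fam) | fam == "")))
    return("every TE instance needs a non-empty family label")
  cid <- S4Vectors::mcols(object@pirnaClusters)$cluster_id
  if (length(object@pirnaClusters) &&
      (is.null(cid) || any(is.na(cid) | cid == "")))
    return("every piRNA cluster needs a non-empty cluster_id")
  TRUE
})

#' Bin-to-class membership
#'
#' For every bin of a [BinTrack], the set of class labels it belongs to.
#' Labels are sets, not a partition: a TE bin inside pericentric
#' heterochromatin carries both labels.  `euchromatin` appears exactly on
#' bins with no heterochromatic label.
#'
#' @slot bins the labeled bins (`GRanges`, same geometry as the source
#'   [BinTrack]).
#' @slot labels list of character vectors, parallel to `bins`.
#' @exportClass BinMembership
setClass("BinMembership",
         slots = c(bins = "GRanges", labels = "list"))

setValidity("BinMembership", function(object) {
  if (length(object@labels) != length(object@bins))
    return("labels must be parallel to bins")
  if (length(object@labels) &&
      any(vapply(object@labels, length, 1L) == 0L))
    return("every bin must carry at least one label")
  TRUE
})

#' Per-class and per-family enrichment summary for one condition
#'
#' @slot condition condition label (e.g. `"wild_type"`).
#' @slot stats data.frame with columns `label`, `type`
#'   (`class`/`te_family`/`cluster`/`subtelomere_arm`), `mean_m`,
#'   `n_bins`, `se`.
#' @slot uncovered labels present in the annotation but covered by no bin.
#' @exportClass EnrichmentProfile
setClass("EnrichmentProfile",
         slots = c(condition = "character",
                   stats = "data.frame",
                   uncovered = "character"))

setValidity("EnrichmentProfile", function(object) {
  need <- c("label", "type", "mean_m", "n_bins", "se")
  if (!all(need %in% names(object@stats)))
    return("stats must have columns label, type, mean_m, n_bins, se")
  if (nrow(object@stats) && any(object@stats$n_bins < 1L))
    return("profile entries require n_bins >= 1")
  TRUE
})

#' Wild-type versus mutant differential enrichment report
#'
#' @slot classes per-class summary: mean M in each condition, `delta_m`
#'   (mutant minus wild type) and `percent_decrease` (only where the
#'   wild-type mean exceeds `mFloor`; otherwise flagged undefined).
#' @slot features per-family / per-cluster deltas and directions.
#' @slot counts list with elements `te_families` and `clusters`, each a
#'   named vector `n_decreased`, `n_increased`, `n_unchanged`, `n_total`.
#' @slot mFloor reference-mean floor below which percent decrease is
#'   flagged undefined.
#' @slot minBins minimum bins per condition for a family to be compared.
#' @exportClass DifferentialReport
setClass("DifferentialReport",
         slots = c(classes = "data.frame",
                   features = "data.frame",
                   counts = "list",
                   mFloor = "numeric",
                   minBins = "numeric"))

setValidity("DifferentialReport", function(object) {
  for (nm in c("te_families", "clusters")) {
    ct <- object@counts[[nm]]
    if (is.null(ct)) next
    if (ct[["n_decreased"]] > ct[["n_total"]])
      return("n_decreased cannot exceed n_total")
  }
  TRUE
})

#' Cross-condition per-family correlation report
#'
#' @slot pairs per-family mean M in the two profiles.
#' @slot rSquared squared Pearson correlation of the paired means.
#' @slot nFamilies number of shared families used.
#' @slot changeLevelR Pearson correlation of per-family change (b - a)
#'   against the level in profile a.
#' @exportClass CorrelationReport
setClass("CorrelationReport",
         slots = c(pairs = "data.frame",
                   rSquared = "numeric",
                   nFamilies = "integer",
                   changeLevelR = "numeric"))

setValidity("CorrelationReport", function(object) {
  if (object@nFamilies < 3L) return("need at least 3 shared families")
  TRUE
})

#' qPCR input-dilution standard curve
#'
#' Least-squares fit of Ct against log10(input dilution fraction) for one
#' locus.  The amplification base is `b = 10^(-1/slope)` (2 for a perfect
#' doubling per cycle) and the efficiency is `b - 1`.
#'
#' @slot locus locus name.
#' @slot slope Ct per log10 dilution (negative for a valid curve).
#' @slot intercept fitted Ct at dilution fraction 1.
#' @slot base amplification base `b`.
#' @slot efficiency `b - 1`, as a fraction.
#' @slot rSquared r-squared of the fit.
#' @slot ctRange range of input Ct values spanned by the dilutions; IP Ct
#'   values outside it are flagged as extrapolated.
#' @slot nDilutions number of distinct dilution fractions.
#' @exportClass StandardCurve
setClass("StandardCurve",
         slots = c(locus = "character", slope = "numeric",
                   intercept = "numeric", base = "numeric",
                   efficiency = "numeric", rSquared = "numeric",
                   ctRange = "numeric", nDilutions = "integer"))

setValidity("StandardCurve", function(object) {
  if (object@slope >= 0) return("standard curve slope must be negative")
  if (object@nDilutions < 3L) return("need >= 3 distinct dilutions")
  if (object@base <= 1 || object@base > 2.5)
    return("amplification base must lie in (1, 2.5]")
  TRUE
})
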