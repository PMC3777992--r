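#' @include AllClasses.R
NULL

#' @name accessors
#' @title Accessors for hetprofile containers
#' @description Slot accessors for the package's S4 containers; user code
#'   should use these rather than `@`.
#' @param x an object of the documented class.
#' @return the corresponding component.
NULL

#' @rdname accessors
#' @export
setGeneric("probeRecords", function(x) standardGeneric("probeRecords"))
#' @rdname accessors
#' @export
setMethod("probeRecords", "MTrack", function(x) x@probes)

#' @rdname accessors
#' @export
setGeneric("mValues", function(x) standardGeneric("mValues"))
#' @rdname accessors
#' @export
setMethod("mValues", "MTrack", function(x) S4Vectors::mcols(x@probes)$m)

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setMethod("isNormalized", "MTrack", function(x) x@normalized)

#' @rdname accessors
#' @export
setGeneric("bins", function(x) standardGeneric("bins"))
#' @rdname accessors
#' @export
setMethod("bins", "BinTrack", function(x) x@bins)
#' @rdname accessors
#' @export
setMethod("bins", "BinMembership", function(x) x@bins)

#' @rdname accessors
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))
#' @rdname accessors
#' @export
setMethod("binWidth", "BinTrack", function(x) x@binWidth)

#' @rdname accessors
#' @export
setGeneric("arms", function(x) standardGeneric("arms"))
#' @rdname accessors
#' @export
setMethod("arms", "FeatureSet", function(x) x@arms)
#' @rdname accessors
#' @export
setMethod("arms", "SimConfig", function(x) x@arms)

#' @rdname accessors
#' @export
setGeneric("teInstances", function(x) standardGeneric("teInstances"))
#' @rdname accessors
#' @export
setMethod("teInstances", "FeatureSet", function(x) x@teInstances)

#' @rdname accessors
#' @export
setGeneric("pirnaClusters", function(x) standardGeneric("pirnaClusters"))
#' @rdname accessors
#' @export
setMethod("pirnaClusters", "FeatureSet", function(x) x@pirnaClusters)

#' @rdname accessors
#' @export
setGeneric("reporterLoci", function(x) standardGeneric("reporterLoci"))
#' @rdname accessors
#' @export
setMethod("reporterLoci", "FeatureSet", function(x) x@reporterLoci)

#' @rdname accessors
#' @export
setGeneric("membershipLabels", function(x) standardGeneric("membershipLabels"))
#' @rdname accessors
#' @export
setMethod("membershipLabels", "BinMembership", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("profileStats", function(x) standardGeneric("profileStats"))
#' @rdname accessors
#' @export
setMethod("profileStats", "EnrichmentProfile", function(x) x@stats)

#' @rdname accessors
#' @export
setGeneric("profileCondition", function(x) standardGeneric("profileCondition"))
#' @rdname accessors
#' @export
setMethod("profileCondition", "EnrichmentProfile", function(x) x@condition)

#' @rdname accessors
#' @export
setGeneric("uncoveredLabels", function(x) standardGeneric("uncoveredLabels"))
#' @rdname accessors
#' @export
setMethod("uncoveredLabels", "EnrichmentProfile", function(x) x@uncovered)

#' @rdname accessors
#' @export
setGeneric("classSummary", function(x) standardGeneric("classSummary"))
#' @rdname accessors
#' @export
setMethod("classSummary", "DifferentialReport", function(x) x@classes)

#' @rdname accessors
#' @export
setGeneric("featureSummary", function(x) standardGeneric("featureSummary"))
#' @rdname accessors
#' @export
setMethod("featureSummary", "DifferentialReport", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("directionCounts", function(x) standardGeneric("directionCounts"))
#' @rdname accessors
#' @export
setMethod("directionCounts", "DifferentialReport", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setMethod("rSquared", "CorrelationReport", function(x) x@rSquared)
#' @rdname accessors
#' @export
setMethod("rSquared", "StandardCurve", function(x) x@rSquared)

#' @rdname accessors
#' @export
setGeneric("curveSlope", function(x) standardGeneric("curveSlope"))
#' @rdname accessors
#' @export
setMethod("curveSlope", "StandardCurve", function(x) x@slope)

#' @rdname accessors
#' @export
setGeneric("curveIntercept", function(x) standardGeneric("curveIntercept"))
#' @rdname accessors
#' @export
setMethod("curveIntercept", "StandardCurve", function(x) x@intercept)

#' @rdname accessors
#' @export
setGeneric("amplificationBase", function(x) standardGeneric("amplificationBase"))
#' @rdname accessors
#' @export
setMethod("amplificationBase", "StandardCurve", function(x) x@base)

#' @rdname accessors
#' @export
setGeneric("amplificationEfficiency",
           function(x) standardGeneric("amplificationEfficiency"))
#' @rdname accessors
#' @export
setMethod("amplificationEfficiency", "StandardCurve",
          function(x) x@efficiency)

# ---- show methods ---------------------------------------------------------

setMethod("show", "MTrack", function(object) {
  mc <- S4Vectors::mcols(object@probes)
  cat(sprintf("MTrack: %d probes on %d arm(s); %s; %d unique\n",
              length(object@probes),
              length(unique(as.character(GenomeInfoDb::seqnames(object@probes)))),
              if (object@normalized) "normalized" else "not normalized",
              sum(mc$unique)))
  if (length(object@probes))
    cat(sprintf("  M: mean %.3f, range [%.3f, %.3f]\n",
                mean(mc$m), min(mc$m), max(mc$m)))
  invisible(NULL)
})

setMethod("show", "BinTrack", function(object) {
  cat(sprintf("BinTrack: %d bins of %g bp\n",
              length(object@bins), object@binWidth))
  if (length(object@bins))
    cat(sprintf("  mean_m: mean %.3f; probes per bin: median %g\n",
                mean(S4Vectors::mcols(object@bins)$mean_m),
                stats::median(S4Vectors::mcols(object@bins)$n_probes)))
  invisible(NULL)
})

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf(
    "FeatureSet: %d arm(s) (%.2f Mb), %d TE instances (%d families), %d piRNA clusters, %d reporter loci\n",
    nrow(object@arms), sum(object@arms$length) / 1e6,
    length(object@teInstances),
    length(unique(S4Vectors::mcols(object@teInstances)$family)),
    length(object@pirnaClusters), length(object@reporterLoci)))
  invisible(NULL)
})

setMethod("show", "BinMembership", function(object) {
  cat(sprintf("BinMembership: %d bins, %d distinct labels\n",
              length(object@bins),
              length(unique(unlist(object@labels)))))
  invisible(NULL)
})

setMethod("show", "EnrichmentProfile", function(object) {
  cat(sprintf("EnrichmentProfile ('%s'): %d entries (%d classes, %d TE families, %d clusters); %d uncovered\n",
              object@condition, nrow(object@stats),
              sum(object@stats$type == "class"),
              sum(object@stats$type == "te_family"),
              sum(object@stats$type == "cluster"),
              length(object@uncovered)))
  invisible(NULL)
})

setMethod("show", "DifferentialReport", function(object) {
  cat("DifferentialReport\n")
  cl <- object@classes
  for (i in seq_len(nrow(cl))) {
    pd <- if (isTRUE(cl$percent_defined[i]))
      sprintf("%.1f%% decrease", cl$percent_decrease[i]) else "percent n/a"
    cat(sprintf("  %-14s delta_m %+.3f (%s)\n",
                cl$label[i], cl$delta_m[i], pd))
  }
  for (nm in names(object@counts)) {
    ct <- object@counts[[nm]]
    cat(sprintf("  %s: %d of %d decreased\n",
                nm, ct[["n_decreased"]], ct[["n_total"]]))
  }
  invisible(NULL)
})

setMethod("show", "CorrelationReport", function(object) {
  cat(sprintf("CorrelationReport: %d families, R^2 = %.3f, change-vs-level r = %.3f\n",
              object@nFamilies, object@rSquared, object@changeLevelR))
  invisible(NULL)
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf("StandardCurve '%s': slope %.4f, intercept %.3f, base %.4f (eff. %.1f%%), R^2 %.4f\n",
              object@locus, object@slope, object@intercept, object@base,
              100 * object@efficiency, object@rSquared))
  invisible(NULL)
})
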