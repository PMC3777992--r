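#' @include simulate.R enrichment.R partition.R profiles.R assays.R io.R
NULL

#' Pipeline configuration
#'
#' Exactly one input source: a [SimConfig-class] (simulated study) or a
#' list of paths to real inputs (`armTable`, `teBed`, `clusterBed`, and a
#' named list `probeTables` with elements `wild_type` and `mutant`).
#'
#' @slot simConfig a [SimConfig-class] or `NULL`.
#' @slot inputs list of input paths (empty for simulated runs).
#' @slot binWidth bin width in bp.
#' @slot subtelWindow subtelomeric window width in bp.
#' @slot mFloor percent-decrease reference floor.
#' @slot minBins family coverage threshold.
#' @slot includeNonunique keep non-unique probes in bins.
#' @slot outdir output directory ("" to keep results in memory only).
#' @slot seed integer seed recorded in the manifest; for simulated runs it
#'   overrides the `SimConfig` seed.
#' @exportClass PipelineConfig
setClass("PipelineConfig",
         slots = c(simConfig = "ANY", inputs = "list",
                   binWidth = "numeric", subtelWindow = "numeric",
                   mFloor = "numeric", minBins = "numeric",
                   includeNonunique = "logical", outdir = "character",
                   seed = "integer"))

setValidity("PipelineConfig", function(object) {
  hasSim <- !is.null(object@simConfig)
  hasReal <- length(object@inputs) > 0L
  if (hasSim == hasReal)
    return("exactly one of simConfig or inputs must be given")
  if (hasSim && !is(object@simConfig, "SimConfig"))
    return("simConfig must be a SimConfig")
  if (hasReal) {
    need <- c("armTable", "probeTables")
    miss <- setdiff(need, names(object@inputs))
    if (length(miss))
      return(paste("inputs missing:", paste(miss, collapse = ", ")))
    pt <- object@inputs$probeTables
    if (!all(c("wild_type", "mutant") %in% names(pt)))
      return("inputs$probeTables needs elements wild_type and mutant")
  }
  if (object@binWidth <= 0) return("binWidth must be > 0")
  TRUE
})

#' Build a pipeline configuration
#'
#' @param simConfig a [SimConfig-class] for a simulated run (or NULL).
#' @param inputs list of real-input paths (see [PipelineConfig-class]).
#' @param binWidth,subtelWindow,mFloor,minBins,includeNonunique analysis
#'   parameters; the defaults are the package-wide ones (500-bp bins,
#'   50-kb subtelomeric windows, percent floor 0.1, 5-bin family
#'   coverage, non-unique probes excluded).
#' @param outdir output directory, or NULL to keep results in memory.
#' @param seed integer seed; for simulated runs it replaces the
#'   `SimConfig` seed so one flag reseeds the whole run.
#' @return a validated [PipelineConfig-class].
#' @export
pipelineConfig <- function(simConfig = NULL, inputs = list(),
                           binWidth = 500, subtelWindow = 50000,
                           mFloor = 0.1, minBins = 5,
                           includeNonunique = FALSE,
                           outdir = NULL, seed = 1L) {
  if (!is.null(simConfig)) {
    simConfig@seed <- as.integer(seed)
    methods::validObject(simConfig)
  }
  new("PipelineConfig", simConfig = simConfig, inputs = inputs,
      binWidth = binWidth, subtelWindow = subtelWindow, mFloor = mFloor,
      minBins = minBins, includeNonunique = includeNonunique,
      outdir = if (is.null(outdir)) "" else outdir,
      seed = as.integer(seed))
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipelineConfig()]; a
#' `simulate: default: true` block (optionally with `seed`) requests the
#' default synthetic study, while an `inputs:` block lists real paths.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's.
#' @return a [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  s <- if (!is.null(seed)) seed else if (!is.null(y$seed)) y$seed else 1L
  sim <- NULL
  if (!is.null(y$simulate)) sim <- defaultSimConfig(seed = as.integer(s))
  pipelineConfig(
    simConfig = sim,
    inputs = if (is.null(y$inputs)) list() else y$inputs,
    binWidth = if (is.null(y$bin_width)) 500 else y$bin_width,
    subtelWindow = if (is.null(y$subtel_window)) 50000 else y$subtel_window,
    mFloor = if (is.null(y$m_floor)) 0.1 else y$m_floor,
    minBins = if (is.null(y$min_bins)) 5 else y$min_bins,
    includeNonunique = isTRUE(y$include_nonunique),
    outdir = y$outdir, seed = as.integer(s))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

runManifest <- function(config, inputPaths = character(0)) {
  list(package = "hetprofile",
       version = as.character(utils::packageVersion("hetprofile")),
       r_version = as.character(getRversion()),
       seed = config@seed,
       bin_width = config@binWidth,
       subtel_window = config@subtelWindow,
       m_floor = config@mFloor,
       min_bins = config@minBins,
       include_nonunique = config@includeNonunique,
       mode = if (is.null(config@simConfig)) "real" else "simulated",
       input_md5 = if (length(inputPaths))
         as.list(tools::md5sum(inputPaths)) else list(),
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
}

#' Run the enrichment-profiling pipeline end to end
#'
#' Simulate (or load) probe signal for the two conditions, compute and
#' median-normalize M values, average into bins, assign bins to feature
#' classes, build per-condition profiles, and derive the differential
#' report, the cross-condition family correlation and the subtelomeric
#' series.  When the run is simulated, the planted truth ([simTruth()])
#' is attached.  With an output directory set, all reports plus a run
#' manifest are written; on error, partial outputs are removed.
#'
#' @param config a [PipelineConfig-class].
#' @return list with elements `annotation`, `profiles` (wild_type,
#'   mutant), `bins` and `membership` (the per-condition intermediate
#'   [BinTrack-class] / [BinMembership-class] objects), `differential`,
#'   `correlation`, `subtelomere` (per-condition series and windows),
#'   `truth` (simulated runs only) and `manifest`.
#' @export
runProfilePipeline <- function(config) {
  stopifnot(is(config, "PipelineConfig"))
  simulated <- !is.null(config@simConfig)
  conditions <- c("wild_type", "mutant")
  inputPaths <- character(0)

  if (simulated) {
    sc <- config@simConfig
    features <- stage("annotation", buildGenomeAnnotation(sc))
    probes <- stage("signal", lapply(
      setNames(conditions, conditions),
      function(cond) simulateProbeSignal(features, sc, cond)))
  } else {
    inp <- config@inputs
    inputPaths <- c(inp$armTable, inp$teBed, inp$clusterBed,
                    unlist(inp$probeTables))
    features <- stage("annotation", loadAnnotation(
      inp$armTable, teBed = inp$teBed, clusterBed = inp$clusterBed))
    probes <- stage("signal", lapply(
      setNames(conditions, conditions),
      function(cond) readProbeTable(inp$probeTables[[cond]],
                                    features@arms)))
  }

  tracks <- stage("m_values", lapply(probes, computeMValues))
  tracks <- stage("normalize", lapply(tracks, normalizeTrack))
  binned <- stage("binning", lapply(
    tracks, binTrack, binWidth = config@binWidth,
    includeNonunique = config@includeNonunique))
  memberships <- stage("membership", lapply(
    binned, assignBins, features = features,
    subtelWindow = config@subtelWindow))
  profiles <- stage("profiles", lapply(
    setNames(conditions, conditions),
    function(cond) classMeanProfile(binned[[cond]], memberships[[cond]],
                                    condition = cond,
                                    features = features)))
  differential <- stage("differential", differentialProfile(
    profiles$wild_type, profiles$mutant,
    mFloor = config@mFloor, minBins = config@minBins))
  correlation <- stage("correlation", tryCatch(
    crossConditionCorrelation(profiles$wild_type, profiles$mutant),
    error = function(e) NULL))
  windows <- subtelomericWindows(features, config@subtelWindow)
  subtel <- stage("subtelomere", lapply(
    binned, subtelomereProfile, windows = windows))

  result <- list(annotation = features, profiles = profiles,
                 bins = binned, membership = memberships,
                 differential = differential, correlation = correlation,
                 subtelomere = c(subtel, list(windows = windows)),
                 manifest = runManifest(config, inputPaths))
  if (simulated)
    result$truth <- stage("truth", simTruth(config@simConfig,
                                            binWidth = config@binWidth))

  if (nzchar(config@outdir)) {
    out <- config@outdir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    written <- character(0)
    tryCatch({
      writeAnnotation(features, file.path(out, "annotation"))
      for (cond in conditions) {
        writeBinTrack(binned[[cond]], file.path(out, paste0("bins_", cond)))
        utils::write.table(profiles[[cond]]@stats,
                           file.path(out, paste0("profile_", cond, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      writeDifferentialReport(differential, file.path(out, "differential"))
      if (!is.null(correlation))
        jsonlite::write_json(
          list(r_squared = correlation@rSquared,
               n_families = correlation@nFamilies,
               change_vs_level_r = correlation@changeLevelR),
          file.path(out, "correlation.json"),
          auto_unbox = TRUE, digits = NA)
      jsonlite::write_json(result$manifest,
                           file.path(out, "run_manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }, error = function(e) {
      unlink(out, recursive = TRUE)
      stop(sprintf("[stage report_writing] %s", conditionMessage(e)),
           call. = FALSE)
    })
  }
  result
}

#' Run the wet-lab assay computations end to end
#'
#' Simulates (or loads) a ChIP-qPCR plate, an expression table and the
#' reporter-assay tables, then runs every assay computation: standard
#' curves and relative enrichment per target locus, delta-delta-Ct
#' expression, beta-galactosidase activities with genotype fold changes,
#' and the pigment summary with fold changes.
#'
#' @param config a [PipelineConfig-class] (simulated mode), or paths in
#'   `inputs`: `qpcrCsv`, `expressionCsv`, `betaGalCsv`, `pigmentCsv`
#'   (each optional; omitted sections are skipped).
#' @return list with elements `qpcr` (curves + enrichment table),
#'   `expression`, `beta_gal` (activities + genotype summary), `pigment`
#'   (summary + folds) and `manifest`; sections without data are NULL.
#' @export
runAssayPipeline <- function(config) {
  stopifnot(is(config, "PipelineConfig"))
  simulated <- !is.null(config@simConfig)
  result <- list(qpcr = NULL, expression = NULL, beta_gal = NULL,
                 pigment = NULL)
  inputPaths <- character(0)

  readCsv <- function(path, what) {
    tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
             error = function(e)
               stop(what, ": malformed CSV '", path, "': ",
                    conditionMessage(e), call. = FALSE))
  }

  if (simulated) {
    sc <- config@simConfig
    plate <- stage("qpcr_sim", simulateQpcrPlate(sc, seed = config@seed + 11L))
    exprTab <- stage("expression_sim",
                     simulateExpressionTable(sc, seed = config@seed + 12L))
    reporter <- stage("reporter_sim",
                      simulateReporterTables(sc, seed = config@seed + 13L))
    betaGalTab <- reporter$beta_gal
    pigmentTab <- reporter$pigment
    control <- sc@qpcrControlLocus
    refSample <- sc@expressionTruth$sample[sc@expressionTruth$fold == 1][1]
    controlClass <- sc@assayControlClass
  } else {
    inp <- config@inputs
    plate <- if (!is.null(inp$qpcrCsv)) readCsv(inp$qpcrCsv, "qpcr") else NULL
    exprTab <- if (!is.null(inp$expressionCsv))
      readCsv(inp$expressionCsv, "expression") else NULL
    betaGalTab <- if (!is.null(inp$betaGalCsv))
      readCsv(inp$betaGalCsv, "beta_gal") else NULL
    pigmentTab <- if (!is.null(inp$pigmentCsv))
      readCsv(inp$pigmentCsv, "pigment") else NULL
    inputPaths <- unlist(inp[c("qpcrCsv", "expressionCsv", "betaGalCsv",
                               "pigmentCsv")], use.names = FALSE)
    control <- if (is.null(inp$qpcrControlLocus)) "alpha_actinin"
      else inp$qpcrControlLocus
    refSample <- inp$referenceSample
    controlClass <- if (is.null(inp$controlClass)) "C" else inp$controlClass
  }

  if (!is.null(plate)) {
    result$qpcr <- stage("qpcr", {
      loci <- unique(plate$locus)
      curves <- lapply(setNames(loci, loci), function(l)
        fitInputStandardCurve(plate[plate$locus == l, , drop = FALSE]))
      ctrlWells <- plate[plate$locus == control, , drop = FALSE]
      targets <- setdiff(loci, control)
      enr <- do.call(rbind, lapply(targets, function(l)
        chipQpcrEnrichment(plate[plate$locus == l, , drop = FALSE],
                           curves[[l]], curves[[control]], ctrlWells)))
      list(curves = curves, enrichment = enr)
    })
  }
  if (!is.null(exprTab)) {
    result$expression <- stage("expression", {
      loci <- unique(exprTab$locus)
      controlLocus <- if ("RPL32" %in% loci) "RPL32" else loci[2]
      target <- setdiff(loci, controlLocus)[1]
      ddctExpression(exprTab, targetLocus = target,
                     controlLocus = controlLocus,
                     referenceSample = refSample)
    })
  }
  if (!is.null(betaGalTab)) {
    result$beta_gal <- stage("beta_gal", {
      keys <- unique(betaGalTab[, c("genotype_class", "replicate")])
      acts <- vapply(seq_len(nrow(keys)), function(i) {
        sub <- betaGalTab[
          betaGalTab$genotype_class == keys$genotype_class[i] &
            betaGalTab$replicate == keys$replicate[i], , drop = FALSE]
        betaGalActivity(sub$time_min, sub$od574)$activity
      }, numeric(1))
      activities <- data.frame(genotype_class = keys$genotype_class,
                               replicate = keys$replicate,
                               value = acts, stringsAsFactors = FALSE)
      list(activities = activities,
           summary = genotypeFoldChanges(activities, controlClass))
    })
  }
  if (!is.null(pigmentTab)) {
    result$pigment <- stage("pigment", {
      summ <- pigmentSummary(pigmentTab)
      list(summary = summ,
           folds = genotypeFoldChanges(summ, controlClass))
    })
  }
  result$manifest <- runManifest(config, inputPaths)

  if (nzchar(config@outdir)) {
    dir.create(config@outdir, recursive = TRUE, showWarnings = FALSE)
    report <- list(
      qpcr = if (!is.null(result$qpcr)) result$qpcr$enrichment,
      expression = result$expression,
      beta_gal = if (!is.null(result$beta_gal)) result$beta_gal$summary,
      pigment = if (!is.null(result$pigment)) result$pigment$folds,
      manifest = result$manifest)
    jsonlite::write_json(report[!vapply(report, is.null, logical(1))],
                         file.path(config@outdir, "assay_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
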