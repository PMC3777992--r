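#' Synthetic-study configuration
#'
#' Full description of a simulated ChIP-array study with planted truth:
#' genome layout (arms, TE families, piRNA clusters), the true M value of
#' each feature class in the wild type, how the mutant condition shifts
#' each class, probe geometry and noise, and the truths behind the qPCR
#' and reporter assay simulations.
#'
#' @slot arms chromosome-arm table (`name`, `length`, `telomere_at_start`,
#'   `pericentric_border`, `is_chr4`).
#' @slot teFamilies one row per TE family: `family`, `n_instances`,
#'   `min_len`, `max_len`, `baseline_m`, `shift`.
#' @slot clusters one row per piRNA cluster: `cluster_id`, `min_len`,
#'   `max_len`, `baseline_m`, `shift`.
#' @slot classShift named numeric, shifts of the background classes
#'   (`pericentric`, `chromosome4`, `euchromatin`).
#' @slot shiftScale `"percent"` (mutant true M = wild type true M scaled
#'   by `1 - shift/100`; a positive shift is a percent decrease) or
#'   `"additive"` (shift added to M, log2 units).
#' @slot pericentricBaseline,chr4Baseline true M of pericentric /
#'   chromosome-4 background outside TEs and clusters (euchromatin is 0).
#' @slot subtelShift additive M change applied in the mutant within the
#'   subtelomeric windows (log2 units).
#' @slot subtelWindow subtelomeric window width, bp.
#' @slot probeSpacing probe spacing, bp.
#' @slot probeNoiseSd per-probe Gaussian noise on M, log2 units.
#' @slot nonuniqueFraction fraction of probes flagged non-unique.
#' @slot qpcrTruth one row per locus: `locus`, `enrichment` (true
#'   pull-down enrichment relative to the control locus), `ct_at_full_input`,
#'   `efficiency` (fraction; 1 = perfect doubling), `ct_noise_sd`, `n_ip`.
#' @slot qpcrControlLocus name of the normalization locus.
#' @slot qpcrDilutions input dilution fractions on the plate.
#' @slot qpcrInputReps technical replicates per input dilution.
#' @slot qpcrBasePulldown pull-down efficacy (input fraction) of the
#'   control locus.
#' @slot expressionTruth one row per sample: `sample`, `fold` (true
#'   expression fold change versus the reference sample).
#' @slot expressionReps replicates per sample in the expression table.
#' @slot expressionCtNoiseSd Ct noise of the expression simulation.
#' @slot assayTruth one row per (assay, genotype class): `assay`
#'   (`beta_gal`/`pigment`), `genotype_class`, `mean` (activity in OD/min
#'   for beta_gal, endpoint OD480 for pigment), `sdlog` (lognormal sd of
#'   the replicate noise), `n` (replicates).
#' @slot assayControlClass genotype class used as fold-change reference.
#' @slot seed integer seed; identical config + seed reproduces
#'   byte-identical outputs.
#' @exportClass SimConfig
setClass("SimConfig",
         slots = c(arms = "data.frame",
                   teFamilies = "data.frame",
                   clusters = "data.frame",
                   classShift = "numeric",
                   shiftScale = "character",
                   pericentricBaseline = "numeric",
                   chr4Baseline = "numeric",
                   subtelShift = "numeric",
                   subtelWindow = "numeric",
                   probeSpacing = "numeric",
                   probeNoiseSd = "numeric",
                   nonuniqueFraction = "numeric",
                   qpcrTruth = "data.frame",
                   qpcrControlLocus = "character",
                   qpcrDilutions = "numeric",
                   qpcrInputReps = "integer",
                   qpcrBasePulldown = "numeric",
                   expressionTruth = "data.frame",
                   expressionReps = "integer",
                   expressionCtNoiseSd = "numeric",
                   assayTruth = "data.frame",
                   assayControlClass = "character",
                   seed = "integer"))

setValidity("SimConfig", function(object) {
  ok <- tryCatch({ checkArmTable(object@arms); TRUE },
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) return(ok)
  if (object@probeSpacing <= 0) return("probe_spacing must be > 0")
  if (object@probeNoiseSd < 0) return("probe_noise_sd must be >= 0")
  if (object@nonuniqueFraction < 0 || object@nonuniqueFraction >= 1)
    return("nonunique_fraction must lie in [0, 1)")
  if (!object@shiftScale %in% c("percent", "additive"))
    return("shiftScale must be 'percent' or 'additive'")
  if (nrow(object@teFamilies)) {
    need <- c("family", "n_instances", "min_len", "max_len",
              "baseline_m", "shift")
    if (!all(need %in% names(object@teFamilies)))
      return("teFamilies needs columns family, n_instances, min_len, max_len, baseline_m, shift")
    if (any(object@teFamilies$min_len <= 0) ||
        any(object@teFamilies$max_len < object@teFamilies$min_len))
      return("TE length ranges must be positive with max_len >= min_len")
    if (anyDuplicated(object@teFamilies$family))
      return("duplicated TE family names")
  }
  if (nrow(object@clusters)) {
    need <- c("cluster_id", "min_len", "max_len", "baseline_m", "shift")
    if (!all(need %in% names(object@clusters)))
      return("clusters needs columns cluster_id, min_len, max_len, baseline_m, shift")
    if (any(object@clusters$min_len <= 0) ||
        any(object@clusters$max_len < object@clusters$min_len))
      return("cluster length ranges must be positive with max_len >= min_len")
    if (anyDuplicated(object@clusters$cluster_id))
      return("duplicated cluster ids")
  }
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed must be a single integer")
  TRUE
})

#' Build a synthetic-study configuration
#'
#' Lower-level constructor; most users start from [defaultSimConfig()] and
#' override fields.  See [SimConfig-class] for the meaning of each field.
#'
#' @param arms,teFamilies,clusters,classShift,shiftScale,pericentricBaseline
#'   see [SimConfig-class].
#' @param chr4Baseline,subtelShift,subtelWindow,probeSpacing,probeNoiseSd
#'   see [SimConfig-class].
#' @param nonuniqueFraction,qpcrTruth,qpcrControlLocus,qpcrDilutions see
#'   [SimConfig-class].
#' @param qpcrInputReps,qpcrBasePulldown,expressionTruth,expressionReps see
#'   [SimConfig-class].
#' @param expressionCtNoiseSd,assayTruth,assayControlClass,seed see
#'   [SimConfig-class].
#' @return a validated [SimConfig-class] object.
#' @export
simConfig <- function(arms,
                      teFamilies = emptyTeFamilies(),
                      clusters = emptyClusters(),
                      classShift = c(pericentric = 0, chromosome4 = 0,
                                     euchromatin = 0),
                      shiftScale = c("percent", "additive"),
                      pericentricBaseline = 1.0,
                      chr4Baseline = 0.9,
                      subtelShift = 0,
                      subtelWindow = 50000,
                      probeSpacing = 300,
                      probeNoiseSd = 0.3,
                      nonuniqueFraction = 0.15,
                      qpcrTruth = defaultQpcrTruth(),
                      qpcrControlLocus = "alpha_actinin",
                      qpcrDilutions = c(1, 0.1, 0.01, 0.001),
                      qpcrInputReps = 2L,
                      qpcrBasePulldown = 0.01,
                      expressionTruth = defaultExpressionTruth(),
                      expressionReps = 4L,
                      expressionCtNoiseSd = 0.1,
                      assayTruth = defaultAssayTruth(),
                      assayControlClass = "C",
                      seed = 1L) {
  shiftScale <- match.arg(shiftScale)
  cs <- c(pericentric = 0, chromosome4 = 0, euchromatin = 0)
  cs[names(classShift)] <- classShift
  new("SimConfig",
      arms = as.data.frame(arms), teFamilies = as.data.frame(teFamilies),
      clusters = as.data.frame(clusters), classShift = cs,
      shiftScale = shiftScale, pericentricBaseline = pericentricBaseline,
      chr4Baseline = chr4Baseline, subtelShift = subtelShift,
      subtelWindow = subtelWindow, probeSpacing = probeSpacing,
      probeNoiseSd = probeNoiseSd, nonuniqueFraction = nonuniqueFraction,
      qpcrTruth = as.data.frame(qpcrTruth),
      qpcrControlLocus = qpcrControlLocus, qpcrDilutions = qpcrDilutions,
      qpcrInputReps = as.integer(qpcrInputReps),
      qpcrBasePulldown = qpcrBasePulldown,
      expressionTruth = as.data.frame(expressionTruth),
      expressionReps = as.integer(expressionReps),
      expressionCtNoiseSd = expressionCtNoiseSd,
      assayTruth = as.data.frame(assayTruth),
      assayControlClass = assayControlClass,
      seed = as.integer(seed))
}

emptyTeFamilies <- function() {
  data.frame(family = character(), n_instances = integer(),
             min_len = numeric(), max_len = numeric(),
             baseline_m = numeric(), shift = numeric())
}

emptyClusters <- function() {
  data.frame(cluster_id = character(), min_len = numeric(),
             max_len = numeric(), baseline_m = numeric(), shift = numeric())
}

defaultQpcrTruth <- function() {
  data.frame(
    locus = c("alpha_actinin", "reporter_hsp70_wt", "reporter_hsp70_piwiKD"),
    enrichment = c(1, 4, 2),
    ct_at_full_input = c(22, 25, 25),
    efficiency = c(1, 1, 1),
    ct_noise_sd = c(0.15, 0.15, 0.15),
    n_ip = c(4L, 4L, 4L))
}

defaultExpressionTruth <- function() {
  data.frame(sample = c("control", "piwi_kd"), fold = c(1, 0.5))
}

defaultAssayTruth <- function() {
  data.frame(
    assay = rep(c("beta_gal", "pigment"), each = 4),
    genotype_class = rep(c("C", "M", "Z", "M+Z"), 2),
    mean = c(c(1, 2, 4, 6) / 600, c(0.15, 0.3, 0.5, 0.7)),
    sdlog = 0.2,
    n = 6L)
}

#' Default synthetic study: the piwi-mutant HP1a profiling conditions
#'
#' A desk-scale stand-in for the deposited larval arrays: a mostly
#' euchromatic genome (two major arms with pericentric blocks, one small
#' wholly heterochromatic chromosome-4-like arm), 83 TE families of which
#' 69 are Piwi-sensitive (13.4 percent decrease of their class mean in the
#' mutant) and 14 roo-like families with near-zero HP1a and no shift, and
#' 96 piRNA clusters of which 80 decrease by 8.7 percent and 16 (42AB-like)
#' increase.  Pericentric background decreases by 6.7 percent, the
#' chromosome-4-like arm by 5.7 percent, and the subtelomeric 50-kb windows
#' gain HP1a in the mutant.  qPCR and reporter-assay truths mirror the
#' companion wet-lab measurements (4-fold and 2-fold reporter-locus
#' enrichment, 2-fold expression knockdown, beta-gal genotype folds
#' 1/2/4/6).
#'
#' @param seed integer seed driving every random draw.
#' @return a [SimConfig-class] object.
#' @export
defaultSimConfig <- function(seed = 1L) {
  arms <- data.frame(
    name = c("arm2L", "arm2R", "chr4"),
    length = c(5000000L, 5000000L, 350000L),
    telomere_at_start = c(TRUE, FALSE, TRUE),
    pericentric_border = c(4650000L, 350000L, 350000L),
    is_chr4 = c(FALSE, FALSE, TRUE))
  sensNames <- c("gypsy5", "invader3", "DIVER2", "Bari1", "Invader1",
                 "mdg1", "HeT-A", "TART",
                 sprintf("TEfam%02d", seq_len(61)))
  insNames <- c("roo", "DMRP1", "XDMR", sprintf("quietTE%02d", seq_len(11)))
  te <- data.frame(
    family = c(sensNames, insNames),
    n_instances = 2L,
    min_len = 1500, max_len = 4000,
    baseline_m = c(seq(2.6, 0.5, length.out = length(sensNames)),
                   seq(0.02, 0.12, length.out = length(insNames))),
    shift = c(rep(13.4, length(sensNames)), rep(0, length(insNames))))
  nCl <- 96L
  up <- c(1L, seq(7L, 96L, length.out = 15L))  # 42AB-like increasers
  clShift <- rep(8.7, nCl)
  clShift[round(up)] <- -4.0
  cl <- data.frame(
    cluster_id = sprintf("cluster_%02d", seq_len(nCl)),
    min_len = 5000, max_len = 15000,
    baseline_m = seq(0.7, 1.6, length.out = nCl),
    shift = clShift)
  simConfig(arms = arms, teFamilies = te, clusters = cl,
            classShift = c(pericentric = 6.7, chromosome4 = 5.7,
                           euchromatin = 0),
            shiftScale = "percent",
            pericentricBaseline = 1.0, chr4Baseline = 0.9,
            subtelShift = 0.2, subtelWindow = 50000,
            probeSpacing = 300, probeNoiseSd = 0.3,
            nonuniqueFraction = 0.15, seed = seed)
}

#' @describeIn SimConfig-class compact description of a configuration
#' @param object a `SimConfig`
#' @export
setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d arm(s), %.2f Mb genome | %d TE families, %d piRNA clusters\n",
    nrow(object@arms), sum(object@arms$length) / 1e6,
    nrow(object@teFamilies), nrow(object@clusters)))
  cat(sprintf(
    "  probe spacing %g bp, noise sd %g, non-unique fraction %g, shift scale '%s', seed %d\n",
    object@probeSpacing, object@probeNoiseSd, object@nonuniqueFraction,
    object@shiftScale, object@seed))
  invisible(NULL)
})
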