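#' @include sim-config.R AllGenerics.R
NULL

# Per-condition RNG stream offsets; annotation layout uses the seed itself.
conditionSeedOffset <- function(condition) {
  switch(condition, wild_type = 1L, mutant = 2L,
         stop("unknown condition label: '", condition,
              "' (expected 'wild_type' or 'mutant')"))
}

#' Generate the genome annotation of a synthetic study
#'
#' Lays out TE instances and piRNA clusters uniformly over the configured
#' arms (arms weighted by length), deterministically for a given config and
#' seed.  Feature intervals may overlap each other and the pericentric
#' blocks, as real repeats do.
#'
#' @param config a [SimConfig-class].
#' @return a [FeatureSet-class].
#' @export
buildGenomeAnnotation <- function(config) {
  stopifnot(is(config, "SimConfig"))
  arms <- config@arms
  genomeBp <- sum(as.numeric(arms$length))
  featBp <- sum(config@teFamilies$n_instances * config@teFamilies$max_len) +
    sum(config@clusters$max_len)
  if (featBp > genomeBp)
    stop(sprintf(
      "annotation capacity exceeded: features request up to %.0f bp but the genome has %.0f bp",
      featBp, genomeBp))
  si <- armSeqinfo(arms)

  placeIntervals <- function(lens) {
    # uniform placement; arms chosen proportional to length, start uniform
    n <- length(lens)
    armIdx <- sample.int(nrow(arms), n, replace = TRUE,
                         prob = arms$length / genomeBp)
    maxStart <- arms$length[armIdx] - lens
    if (any(maxStart < 0))
      stop("a feature is longer than the arm it was placed on")
    start0 <- floor(runif(n, 0, maxStart + 1))
    GenomicRanges::GRanges(arms$name[armIdx],
                           IRanges::IRanges(start = start0 + 1,
                                            width = lens),
                           seqinfo = si)
  }

  withSeed(config@seed, {
    te <- GenomicRanges::GRanges(seqinfo = si)
    if (nrow(config@teFamilies)) {
      fam <- config@teFamilies
      famIdx <- rep(seq_len(nrow(fam)), fam$n_instances)
      lens <- round(runif(length(famIdx), fam$min_len[famIdx],
                          fam$max_len[famIdx]))
      te <- placeIntervals(lens)
      S4Vectors::mcols(te)$family <- fam$family[famIdx]
    }
    cl <- GenomicRanges::GRanges(seqinfo = si)
    if (nrow(config@clusters)) {
      cs <- config@clusters
      lens <- round(runif(nrow(cs), cs$min_len, cs$max_len))
      cl <- placeIntervals(lens)
      S4Vectors::mcols(cl)$cluster_id <- cs$cluster_id
    }
    new("FeatureSet", arms = arms, teInstances = te, pirnaClusters = cl,
        reporterLoci = GenomicRanges::GRanges(seqinfo = si))
  })
}

# Deterministic probe midpoints (0-based) for every arm.
probePositions <- function(arms, spacing) {
  pos <- lapply(seq_len(nrow(arms)), function(i) {
    seq.int(from = spacing %/% 2, to = arms$length[i] - 1L, by = spacing)
  })
  GenomicRanges::GRanges(
    rep(arms$name, lengths(pos)),
    IRanges::IRanges(start = unlist(pos) + 1L, width = 1L),
    seqinfo = armSeqinfo(arms))
}

# True M and class of each probe position under a condition.  Precedence
# when features overlap: TE family > piRNA cluster > pericentric /
# chromosome 4 background > euchromatin (0).  The subtelomeric additive
# shift is applied on top in the mutant.
trueSignal <- function(features, config, positions, condition) {
  conditionSeedOffset(condition)  # validates the label
  arms <- features@arms
  armIdx <- match(as.character(GenomeInfoDb::seqnames(positions)), arms$name)
  if (anyNA(armIdx)) stop("probe positions reference unknown arms")
  pos0 <- BiocGenerics::start(positions) - 1L

  m <- numeric(length(positions))
  cls <- rep("euchromatin", length(positions))
  shiftPct <- rep(unname(config@classShift["euchromatin"]),
                  length(positions))

  hetSide <- ifelse(arms$telomere_at_start[armIdx],
                    pos0 >= arms$pericentric_border[armIdx],
                    pos0 < arms$pericentric_border[armIdx])
  isChr4 <- arms$is_chr4[armIdx]
  pc <- hetSide & !isChr4
  m[pc] <- config@pericentricBaseline
  cls[pc] <- "pericentric"
  shiftPct[pc] <- config@classShift["pericentric"]
  m[isChr4] <- config@chr4Baseline
  cls[isChr4] <- "chromosome4"
  shiftPct[isChr4] <- config@classShift["chromosome4"]

  if (length(features@pirnaClusters)) {
    h <- GenomicRanges::findOverlaps(positions, features@pirnaClusters)
    ids <- S4Vectors::mcols(features@pirnaClusters)$cluster_id
    rowIdx <- match(ids[S4Vectors::subjectHits(h)],
                    config@clusters$cluster_id)
    q <- S4Vectors::queryHits(h)
    m[q] <- config@clusters$baseline_m[rowIdx]
    cls[q] <- paste0("cluster:", ids[S4Vectors::subjectHits(h)])
    shiftPct[q] <- config@clusters$shift[rowIdx]
  }
  if (length(features@teInstances)) {
    h <- GenomicRanges::findOverlaps(positions, features@teInstances)
    fams <- S4Vectors::mcols(features@teInstances)$family
    rowIdx <- match(fams[S4Vectors::subjectHits(h)],
                    config@teFamilies$family)
    q <- S4Vectors::queryHits(h)
    m[q] <- config@teFamilies$baseline_m[rowIdx]
    cls[q] <- paste0("TE:", fams[S4Vectors::subjectHits(h)])
    shiftPct[q] <- config@teFamilies$shift[rowIdx]
  }

  if (condition == "mutant") {
    if (config@shiftScale == "percent") {
      m <- m * (1 - shiftPct / 100)
    } else {
      m <- m + shiftPct
    }
    if (config@subtelShift != 0) {
      # the planted tip gain concerns the major arms, not chromosome 4
      win <- subtelomericWindows(features, config@subtelWindow)
      win <- win[!arms$is_chr4[match(S4Vectors::mcols(win)$arm, arms$name)]]
      inWin <- S4Vectors::queryHits(
        GenomicRanges::findOverlaps(positions, win))
      m[inWin] <- m[inWin] + config@subtelShift
    }
  }
  list(m = m, class = cls)
}

#' Simulate probe-level two-channel signal
#'
#' Emits one probe every `probeSpacing` bp along each arm.  Input
#' intensities are lognormal; the ChIP intensity is the input scaled by
#' `2^(true M + N(0, probeNoiseSd))`, so the probe-level M value is the
#' planted true M plus Gaussian noise.  A configured fraction of probes is
#' flagged non-unique.
#'
#' @param features a [FeatureSet-class], normally from
#'   [buildGenomeAnnotation()].
#' @param config the [SimConfig-class] used to build `features`.
#' @param condition `"wild_type"` or `"mutant"`.
#' @return a `GRanges` of probe records with metadata columns `chip`,
#'   `input` and `unique`, suitable for [computeMValues()].
#' @export
simulateProbeSignal <- function(features, config,
                                condition = c("wild_type", "mutant")) {
  stopifnot(is(features, "FeatureSet"), is(config, "SimConfig"))
  if (length(condition) != 1L || !condition %in% c("wild_type", "mutant"))
    stop("unknown condition label: '", paste(condition, collapse = ","),
         "' (expected 'wild_type' or 'mutant')")
  positions <- probePositions(features@arms, config@probeSpacing)
  truth <- trueSignal(features, config, positions, condition)
  withSeed(config@seed + conditionSeedOffset(condition), {
    n <- length(positions)
    input <- stats::rlnorm(n, meanlog = log(500), sdlog = 0.5)
    noise <- if (config@probeNoiseSd > 0)
      stats::rnorm(n, 0, config@probeNoiseSd) else 0
    chip <- input * 2^(truth$m + noise)
    uniq <- stats::runif(n) >= config@nonuniqueFraction
    gr <- positions
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      chip = chip, input = input, unique = uniq)
    gr
  })
}

#' Simulate a ChIP-qPCR plate
#'
#' For every locus in the configured truth, emits input-dilution wells at
#' the configured dilution fractions and IP wells whose Ct values derive
#' from the locus's amplification efficiency and its true pull-down
#' enrichment over the control locus, plus Gaussian Ct noise.
#'
#' @param config a [SimConfig-class] whose `qpcrTruth` defines at least the
#'   control locus and one target.
#' @param seed integer seed for the plate (independent of the array seed).
#' @return data.frame of wells with columns `locus`, `role`
#'   (`input_dilution`/`ip`), `dilution_fraction` (`NA` for IP wells),
#'   `ct`, `replicate`.
#' @export
simulateQpcrPlate <- function(config, seed = config@seed) {
  stopifnot(is(config, "SimConfig"))
  truth <- config@qpcrTruth
  if (nrow(truth) < 2L)
    stop("qpcr truth must define the control locus and at least one target")
  if (!config@qpcrControlLocus %in% truth$locus)
    stop("qpcr truth is missing the control locus '",
         config@qpcrControlLocus, "'")
  withSeed(seed, {
    out <- lapply(seq_len(nrow(truth)), function(i) {
      b <- 1 + truth$efficiency[i]
      slope <- -1 / log10(b)
      ct0 <- truth$ct_at_full_input[i]
      nInp <- length(config@qpcrDilutions) * config@qpcrInputReps
      inp <- data.frame(
        locus = truth$locus[i], role = "input_dilution",
        dilution_fraction = rep(config@qpcrDilutions,
                                each = config@qpcrInputReps),
        ct = ct0 + slope * log10(rep(config@qpcrDilutions,
                                     each = config@qpcrInputReps)),
        replicate = rep(seq_len(config@qpcrInputReps),
                        times = length(config@qpcrDilutions)))
      efficacy <- config@qpcrBasePulldown * truth$enrichment[i]
      ip <- data.frame(
        locus = truth$locus[i], role = "ip",
        dilution_fraction = NA_real_,
        ct = ct0 + slope * log10(efficacy),
        replicate = seq_len(truth$n_ip[i]))
      w <- rbind(inp, ip)
      if (truth$ct_noise_sd[i] > 0)
        w$ct <- w$ct + stats::rnorm(nrow(w), 0, truth$ct_noise_sd[i])
      w
    })
    do.call(rbind, out)
  })
}

#' Simulate a delta-delta-Ct expression table
#'
#' Emits target and control-locus Ct values per sample and replicate such
#' that the true expression fold change of each sample versus the
#' reference equals the configured truth.
#'
#' @param config a [SimConfig-class]; `expressionTruth` gives one row per
#'   sample with its true fold (the first row is the reference, fold 1).
#' @param seed integer seed.
#' @param targetLocus,controlLocus locus names written into the table.
#' @return data.frame with columns `sample`, `locus`, `replicate`, `ct`.
#' @export
simulateExpressionTable <- function(config, seed = config@seed,
                                    targetLocus = "piwi",
                                    controlLocus = "RPL32") {
  stopifnot(is(config, "SimConfig"))
  truth <- config@expressionTruth
  if (nrow(truth) < 2L) stop("expression truth needs >= 2 samples")
  withSeed(seed, {
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      nr <- config@expressionReps
      ctC <- 20
      ctT <- 25 - log2(truth$fold[i])
      d <- data.frame(
        sample = truth$sample[i],
        locus = rep(c(targetLocus, controlLocus), each = nr),
        replicate = rep(seq_len(nr), 2),
        ct = c(rep(ctT, nr), rep(ctC, nr)))
      if (config@expressionCtNoiseSd > 0)
        d$ct <- d$ct + stats::rnorm(nrow(d), 0, config@expressionCtNoiseSd)
      d
    })
    do.call(rbind, rows)
  })
}

#' Simulate replicate reporter-assay tables
#'
#' For each genotype class of each assay, draws replicate measurements
#' around the configured class mean with multiplicative lognormal noise
#' (mean-one, so class means are recovered without bias).  Beta-gal
#' replicates are emitted as OD574 time series linear in time (slope =
#' activity); pigment replicates as OD480 endpoints.
#'
#' @param config a [SimConfig-class] whose `assayTruth` covers at least two
#'   genotype classes including the control class.
#' @param seed integer seed.
#' @param times beta-gal read times in minutes.
#' @return list with data.frames `beta_gal` (columns `genotype_class`,
#'   `replicate`, `time_min`, `od574`) and `pigment` (columns
#'   `genotype_class`, `replicate`, `od480`, `flies_per_sample`).
#' @export
simulateReporterTables <- function(config, seed = config@seed,
                                   times = seq(0, 120, by = 15)) {
  stopifnot(is(config, "SimConfig"))
  truth <- config@assayTruth
  for (a in unique(truth$assay)) {
    sub <- truth[truth$assay == a, , drop = FALSE]
    if (length(unique(sub$genotype_class)) < 2L ||
        !config@assayControlClass %in% sub$genotype_class)
      stop("assay truth for '", a,
           "' needs >= 2 genotype classes including the control class '",
           config@assayControlClass, "'")
    if (any(sub$n < 2L))
      stop("assay '", a, "' has a genotype class with fewer than 2 ",
           "replicates; the SEM would be undefined")
  }
  lnoise <- function(n, sdlog) {
    if (sdlog <= 0) rep(1, n)
    else exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))  # mean-one lognormal
  }
  withSeed(seed, {
    bg <- truth[truth$assay == "beta_gal", , drop = FALSE]
    betaGal <- do.call(rbind, lapply(seq_len(nrow(bg)), function(i) {
      slopes <- bg$mean[i] * lnoise(bg$n[i], bg$sdlog[i])
      do.call(rbind, lapply(seq_len(bg$n[i]), function(r) {
        data.frame(genotype_class = bg$genotype_class[i], replicate = r,
                   time_min = times, od574 = 0.05 + slopes[r] * times)
      }))
    }))
    pg <- truth[truth$assay == "pigment", , drop = FALSE]
    pigment <- do.call(rbind, lapply(seq_len(nrow(pg)), function(i) {
      data.frame(genotype_class = pg$genotype_class[i],
                 replicate = seq_len(pg$n[i]),
                 od480 = pg$mean[i] * lnoise(pg$n[i], pg$sdlog[i]),
                 flies_per_sample = 5L)
    }))
    list(beta_gal = betaGal, pigment = pigment)
  })
}

#' Planted truth of a synthetic study
#'
#' The values every downstream estimator targets, derived from the
#' configuration alone.  Class and family means are the large-sample
#' expectations of the pipeline's estimator: the noise-free true M at the
#' probe positions, centered by the asymptotic median of the
#' noise-convolved M distribution (what [normalizeTrack()] converges to),
#' then binned and averaged per class exactly as the pipeline does.
#'
#' @param config a [SimConfig-class].
#' @param binWidth bin width used by the target pipeline.
#' @return list with elements `annotation` ([FeatureSet-class]),
#'   `profiles` (per-condition [EnrichmentProfile-class]), `differential`
#'   (a [DifferentialReport-class] of the true changes), `subtelomereDelta`
#'   (true mutant-minus-wild-type mean M over the subtelomeric windows),
#'   `medianOffset` (per-condition centering constants), `qpcr`,
#'   `expression` and `assayFolds` truths copied from the config.
#' @export
simTruth <- function(config, binWidth = 500) {
  stopifnot(is(config, "SimConfig"))
  features <- buildGenomeAnnotation(config)
  positions <- probePositions(config@arms, config@probeSpacing)
  conditions <- c("wild_type", "mutant")
  offsets <- numeric(0)
  profiles <- list()
  subMeans <- numeric(0)
  win <- subtelomericWindows(features, config@subtelWindow)
  win <- win[!config@arms$is_chr4[match(S4Vectors::mcols(win)$arm,
                                        config@arms$name)]]
  for (cond in conditions) {
    tm <- trueSignal(features, config, positions, cond)$m
    off <- asymptoticMedian(tm, config@probeNoiseSd)
    offsets[cond] <- off
    gr <- positions
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      m = tm - off, unique = TRUE)
    track <- new("MTrack", probes = gr, normalized = FALSE)
    bt <- binTrack(track, binWidth = binWidth)
    mem <- assignBins(bt, features, subtelWindow = config@subtelWindow)
    profiles[[cond]] <- classMeanProfile(bt, mem, condition = cond,
                                         features = features)
    sub <- subtelomereProfile(bt, win)
    subMeans[cond] <- mean(unlist(lapply(sub, function(d) d$mean_m)))
  }
  diffTruth <- differentialProfile(profiles$wild_type, profiles$mutant)
  assay <- config@assayTruth
  assayFolds <- do.call(rbind, lapply(unique(assay$assay), function(a) {
    sub <- assay[assay$assay == a, , drop = FALSE]
    ctrl <- sub$mean[sub$genotype_class == config@assayControlClass]
    data.frame(assay = a, genotype_class = sub$genotype_class,
               fold = sub$mean / ctrl)
  }))
  list(annotation = features,
       profiles = profiles,
       differential = diffTruth,
       subtelomereDelta = unname(subMeans["mutant"] - subMeans["wild_type"]),
       medianOffset = offsets,
       qpcr = config@qpcrTruth[, c("locus", "enrichment")],
       expression = config@expressionTruth,
       assayFolds = assayFolds)
}
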