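# Shared fixtures: small configurations and hand-rolled oracles.

tinyArms <- function() {
  data.frame(
    name = c("armA", "armB", "chr4L"),
    length = c(1000000L, 800000L, 100000L),
    telomere_at_start = c(TRUE, FALSE, TRUE),
    pericentric_border = c(850000L, 150000L, 100000L),
    is_chr4 = c(FALSE, FALSE, TRUE))
}

# Zero baselines, zero shifts, zero noise, all probes unique: the pipeline
# must propagate exact zeros through every stage.
nullSimConfig <- function(seed = 1L) {
  te <- data.frame(family = c("nullTE1", "nullTE2"), n_instances = 3L,
                   min_len = 2000, max_len = 5000, baseline_m = 0,
                   shift = 0)
  cl <- data.frame(cluster_id = c("c1", "c2"), min_len = 5000,
                   max_len = 10000, baseline_m = 0, shift = 0)
  simConfig(arms = tinyArms(), teFamilies = te, clusters = cl,
            classShift = c(pericentric = 0, chromosome4 = 0,
                           euchromatin = 0),
            shiftScale = "percent",
            pericentricBaseline = 0, chr4Baseline = 0, subtelShift = 0,
            probeSpacing = 300, probeNoiseSd = 0, nonuniqueFraction = 0,
            seed = seed)
}

# Planted-shift recovery study: two major arms plus a chromosome-4-like
# arm (~5 Mb), 30 TE families (26 shifted, 4 roo-like null), 20 clusters,
# probe spacing 300 bp, probe noise sd 0.3.
recoverySimConfig <- function(seed = 1L) {
  arms <- data.frame(
    name = c("armA", "armB", "chr4L"),
    length = c(2300000L, 2300000L, 250000L),
    telomere_at_start = c(TRUE, FALSE, TRUE),
    pericentric_border = c(2100000L, 200000L, 250000L),
    is_chr4 = c(FALSE, FALSE, TRUE))
  te <- data.frame(
    family = c(sprintf("fam%02d", 1:26), sprintf("quiet%d", 1:4)),
    n_instances = 4L, min_len = 2000, max_len = 5000,
    baseline_m = c(seq(0.6, 2.5, length.out = 26), rep(0.05, 4)),
    shift = c(rep(13.4, 26), rep(0, 4)))
  cl <- data.frame(
    cluster_id = sprintf("cl%02d", 1:20), min_len = 10000,
    max_len = 20000, baseline_m = seq(0.8, 1.5, length.out = 20),
    shift = 8.7)
  simConfig(arms = arms, teFamilies = te, clusters = cl,
            classShift = c(pericentric = 6.7, chromosome4 = 5.7,
                           euchromatin = 0),
            shiftScale = "percent",
            pericentricBaseline = 1.0, chr4Baseline = 0.9,
            subtelShift = 0.2, probeSpacing = 300, probeNoiseSd = 0.3,
            nonuniqueFraction = 0.15, seed = seed)
}

# One arm entirely covered by a single TE family: every probe sits at the
# family baseline, handy for exact-definition checks.
monoFamilyConfig <- function(baseline, noiseSd = 0, armLen = 1000000L,
                             shift = 0, spacing = 100, seed = 1L) {
  arms <- data.frame(name = "armA", length = armLen,
                     telomere_at_start = TRUE,
                     pericentric_border = armLen, is_chr4 = FALSE)
  te <- data.frame(family = "wholeArm", n_instances = 1L,
                   min_len = armLen, max_len = armLen,
                   baseline_m = baseline, shift = shift)
  simConfig(arms = arms, teFamilies = te,
            classShift = c(pericentric = 0, chromosome4 = 0,
                           euchromatin = 0),
            shiftScale = "percent",
            pericentricBaseline = 0, chr4Baseline = 0, subtelShift = 0,
            probeSpacing = spacing, probeNoiseSd = noiseSd,
            nonuniqueFraction = 0, seed = seed)
}

# Build a probe GRanges directly.
makeProbes <- function(chrom, pos0, chip, input, unique = TRUE,
                       arms = NULL) {
  si <- if (is.null(arms)) NULL else
    GenomeInfoDb::Seqinfo(seqnames = arms$name,
                          seqlengths = as.integer(arms$length))
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = pos0 + 1,
                                                width = 1L))
  if (!is.null(si)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(si)
    GenomeInfoDb::seqinfo(gr) <- si
  }
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    chip = chip, input = input,
    unique = rep_len(unique, length(gr)))
  gr
}

# Build an MTrack without going through computeMValues.
makeMTrack <- function(chrom, pos0, m, unique = TRUE, normalized = FALSE) {
  gr <- GenomicRanges::GRanges(rep_len(chrom, length(pos0)),
                               IRanges::IRanges(start = pos0 + 1,
                                                width = 1L))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    m = m, unique = rep_len(unique, length(gr)))
  new("MTrack", probes = gr, normalized = normalized)
}

# Build an EnrichmentProfile from label/mean/n/se vectors.
makeProfile <- function(label, mean_m, n_bins = 10L, se = 0.01,
                        condition = "x") {
  type <- ifelse(startsWith(label, "TE:"), "te_family",
           ifelse(startsWith(label, "cluster:"), "cluster",
            ifelse(startsWith(label, "subtelomere:"), "subtelomere_arm",
                   "class")))
  new("EnrichmentProfile", condition = condition,
      stats = data.frame(label = label, type = type, mean_m = mean_m,
                         n_bins = rep_len(as.integer(n_bins), length(label)),
                         se = rep_len(se, length(label)),
                         stringsAsFactors = FALSE),
      uncovered = character(0))
}

# Independent ordinary-least-squares slope/intercept (closed form).
olsOracle <- function(x, y) {
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - sl * mean(x), slope = sl)
}
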