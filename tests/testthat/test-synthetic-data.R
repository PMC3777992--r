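# Synthetic-data generator: determinism, planted truth, degenerate cases.

test_that("identical config and seed reproduce identical outputs", {
  cfg <- recoverySimConfig(seed = 42L)
  fs1 <- buildGenomeAnnotation(cfg)
  fs2 <- buildGenomeAnnotation(cfg)
  expect_identical(as.data.frame(teInstances(fs1)),
                   as.data.frame(teInstances(fs2)))
  expect_identical(as.data.frame(pirnaClusters(fs1)),
                   as.data.frame(pirnaClusters(fs2)))
  p1 <- simulateProbeSignal(fs1, cfg, "wild_type")
  p2 <- simulateProbeSignal(fs2, cfg, "wild_type")
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_identical(simulateQpcrPlate(cfg, seed = 5L),
                   simulateQpcrPlate(cfg, seed = 5L))
  expect_identical(simulateReporterTables(cfg, seed = 5L),
                   simulateReporterTables(cfg, seed = 5L))
  # a different seed must move the layout
  cfg2 <- recoverySimConfig(seed = 43L)
  expect_false(identical(
    as.data.frame(teInstances(buildGenomeAnnotation(cfg2))),
    as.data.frame(teInstances(fs1))))
})

test_that("annotation layout respects arms and capacity", {
  # degenerate: one arm, no features
  arms <- data.frame(name = "armA", length = 500000L,
                     telomere_at_start = TRUE,
                     pericentric_border = 400000L, is_chr4 = FALSE)
  fs <- buildGenomeAnnotation(simConfig(arms = arms, seed = 1L))
  expect_identical(nrow(arms(fs)), 1L)
  expect_identical(length(teInstances(fs)), 0L)
  expect_identical(length(pirnaClusters(fs)), 0L)

  # 50 placed instances all inside their arm, checked by exhaustive scan
  te <- data.frame(family = "f1", n_instances = 50L, min_len = 1000,
                   max_len = 9000, baseline_m = 1, shift = 0)
  cfg <- simConfig(arms = tinyArms(), teFamilies = te, seed = 3L)
  fs <- buildGenomeAnnotation(cfg)
  gr <- teInstances(fs)
  expect_identical(length(gr), 50L)
  armTab <- arms(fs)
  for (i in seq_along(gr)) {
    len <- armTab$length[armTab$name ==
                           as.character(GenomeInfoDb::seqnames(gr)[i])]
    expect_gte(BiocGenerics::start(gr)[i], 1L)
    expect_lte(BiocGenerics::end(gr)[i], len)
  }

  # asking for more feature bp than the genome holds
  teBig <- data.frame(family = "huge", n_instances = 300L,
                      min_len = 9000, max_len = 10000, baseline_m = 1,
                      shift = 0)
  expect_error(
    buildGenomeAnnotation(simConfig(arms = arms, teFamilies = teBig,
                                    seed = 1L)),
    "capacity")
})

test_that("probe signal encodes the planted true M", {
  # null: zero baselines, zero noise -> ChIP equals input, M exactly 0
  cfg0 <- nullSimConfig()
  fs0 <- buildGenomeAnnotation(cfg0)
  pr0 <- simulateProbeSignal(fs0, cfg0, "wild_type")
  expect_identical(S4Vectors::mcols(pr0)$chip, S4Vectors::mcols(pr0)$input)
  expect_identical(mValues(computeMValues(pr0)), rep(0, length(pr0)))

  # baseline M = 2, no noise -> ChIP/input = 4 at every covered probe
  cfg2 <- monoFamilyConfig(baseline = 2, noiseSd = 0)
  fs2 <- buildGenomeAnnotation(cfg2)
  pr2 <- simulateProbeSignal(fs2, cfg2, "wild_type")
  expect_equal(S4Vectors::mcols(pr2)$chip / S4Vectors::mcols(pr2)$input,
               rep(4, length(pr2)), tolerance = 1e-12)

  # mutant percent shift scales the mean: 13.4% on M = 2
  prm <- simulateProbeSignal(fs2, monoFamilyConfig(baseline = 2,
                                                   shift = 13.4),
                             "mutant")
  expect_equal(unique(round(log2(
    S4Vectors::mcols(prm)$chip / S4Vectors::mcols(prm)$input), 9)),
    2 * (1 - 0.134))

  expect_error(simulateProbeSignal(fs2, cfg2, "heterozygote"),
               "unknown condition")
})

test_that("noisy probe signal recovers the planted mean within 3 SE", {
  n <- 10000L
  cfg <- monoFamilyConfig(baseline = 1.2, noiseSd = 0.3,
                          armLen = 1000000L, spacing = 100, seed = 11L)
  fs <- buildGenomeAnnotation(cfg)
  pr <- simulateProbeSignal(fs, cfg, "wild_type")
  expect_identical(length(pr), n)
  m <- mValues(computeMValues(pr))
  expect_lt(abs(mean(m) - 1.2), 3 * 0.3 / sqrt(n))
})

test_that("qPCR plate is exact without noise and recoverable with it", {
  base <- data.frame(
    locus = c("alpha_actinin", "target"),
    enrichment = c(1, 1), ct_at_full_input = c(22, 25),
    efficiency = 1, ct_noise_sd = 0, n_ip = 4L)
  cfg <- simConfig(arms = tinyArms(), qpcrTruth = base, seed = 1L)
  plate <- simulateQpcrPlate(cfg, seed = 1L)
  # enrichment 1, base pulldown 1%: IP Ct equals the 1% input well's Ct
  for (l in base$locus) {
    ip <- plate[plate$locus == l & plate$role == "ip", ]
    inp1pc <- plate[plate$locus == l & plate$role == "input_dilution" &
                      plate$dilution_fraction == 0.01, ]
    expect_equal(unique(ip$ct), inp1pc$ct[1], tolerance = 1e-12)
  }

  # planted 2-fold enrichment survives the full computation exactly
  tr2 <- base; tr2$enrichment <- c(1, 2)
  cfg2 <- simConfig(arms = tinyArms(), qpcrTruth = tr2, seed = 1L)
  plate2 <- simulateQpcrPlate(cfg2, seed = 1L)
  curves <- lapply(split(plate2, plate2$locus), fitInputStandardCurve)
  enr <- chipQpcrEnrichment(plate2[plate2$locus == "target", ],
                            curves$target, curves$alpha_actinin,
                            plate2[plate2$locus == "alpha_actinin", ])
  expect_equal(enr$relative_enrichment, 2, tolerance = 1e-9)

  # noisy plates: mean over 100 replicate plates within 3 SE of truth
  # (the standard-curve error is shared within a plate, so recovery is
  # assessed across plates, not across IP wells of one plate)
  tr3 <- tr2; tr3$ct_noise_sd <- 0.15
  cfg3 <- simConfig(arms = tinyArms(), qpcrTruth = tr3, seed = 2L)
  ests <- vapply(1:100, function(s) {
    plate3 <- simulateQpcrPlate(cfg3, seed = 1000L + s)
    curves3 <- lapply(split(plate3, plate3$locus), fitInputStandardCurve)
    chipQpcrEnrichment(plate3[plate3$locus == "target", ],
                       curves3$target, curves3$alpha_actinin,
                       plate3[plate3$locus == "alpha_actinin", ]
                       )$relative_enrichment
  }, numeric(1))
  expect_lt(abs(mean(ests) - 2), 3 * sd(ests) / sqrt(length(ests)))

  # the control locus is mandatory
  trBad <- base[base$locus != "alpha_actinin", ]
  expect_error(
    simulateQpcrPlate(simConfig(arms = tinyArms(), qpcrTruth = trBad,
                                seed = 1L)),
    "at least one target|control locus")
})

test_that("reporter tables round-trip their planted fold changes", {
  truth0 <- data.frame(
    assay = rep(c("beta_gal", "pigment"), each = 4),
    genotype_class = rep(c("C", "M", "Z", "M+Z"), 2),
    mean = c(c(1, 2, 4, 6) / 600, c(0.2, 0.2, 0.2, 0.2)),
    sdlog = 0, n = 4L)
  cfg <- simConfig(arms = tinyArms(), assayTruth = truth0, seed = 1L)
  tabs <- simulateReporterTables(cfg, seed = 1L)
  acts <- do.call(rbind, lapply(
    split(tabs$beta_gal,
          list(tabs$beta_gal$genotype_class, tabs$beta_gal$replicate)),
    function(d) data.frame(genotype_class = d$genotype_class[1],
                           value = betaGalActivity(d$time_min,
                                                   d$od574)$activity)))
  folds <- genotypeFoldChanges(acts, controlClass = "C")
  expect_equal(folds$fold_change[match(c("C", "M", "Z", "M+Z"),
                                       folds$genotype_class)],
               c(1, 2, 4, 6), tolerance = 1e-9)
  # equal-activity classes give fold 1 everywhere
  pg <- pigmentSummary(tabs$pigment)
  pgF <- genotypeFoldChanges(pg, controlClass = "C")
  expect_equal(pgF$fold_change, rep(1, 4), tolerance = 1e-12)

  # SEM undefined for singleton classes
  truthBad <- truth0; truthBad$n[2] <- 1L
  expect_error(
    simulateReporterTables(simConfig(arms = tinyArms(),
                                     assayTruth = truthBad, seed = 1L)),
    "fewer than 2")
})

test_that("simTruth is derivable from the config alone and matches null", {
  cfg <- nullSimConfig()
  tr <- simTruth(cfg)
  expect_equal(tr$medianOffset, c(wild_type = 0, mutant = 0))
  expect_true(all(abs(classSummary(tr$differential)$delta_m) < 1e-12))
  expect_identical(simTruth(cfg)$differential@classes,
                   tr$differential@classes)
})
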