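# qPCR standard curves, relative enrichment, ddCt, beta-gal kinetics,
# pigment and genotype fold changes.

inputWells <- function(dilutions, ct, locus = "target") {
  data.frame(locus = locus, role = "input_dilution",
             dilution_fraction = dilutions, ct = ct,
             replicate = seq_along(dilutions))
}

ipWells <- function(ct, locus = "target") {
  data.frame(locus = locus, role = "ip", dilution_fraction = NA_real_,
             ct = ct, replicate = seq_along(ct))
}

test_that("a perfect 10-fold dilution series gives slope -3.3219, base 2", {
  w <- inputWells(c(1, 0.1, 0.01), c(10, 13.3219, 16.6439))
  cv <- fitInputStandardCurve(w)
  expect_equal(curveSlope(cv), -log2(10), tolerance = 1e-4)
  expect_equal(amplificationBase(cv), 2, tolerance = 1e-4)
  expect_equal(amplificationEfficiency(cv), 1, tolerance = 1e-4)
  expect_equal(rSquared(cv), 1, tolerance = 1e-9)

  # 2-fold steps with Ct increments of exactly 1: same slope on log10 axis
  w2 <- inputWells(c(1, 0.5, 0.25, 0.125), c(10, 11, 12, 13))
  expect_equal(curveSlope(fitInputStandardCurve(w2)), -1 / log10(2),
               tolerance = 1e-9)

  expect_error(fitInputStandardCurve(inputWells(c(1, 0.1), c(10, 13))),
               "3 distinct")
  expect_error(
    fitInputStandardCurve(inputWells(c(1, 0.1, 0.01), c(16, 13, 10))),
    "slope")
})

test_that("noisy curve fits equal the closed-form OLS oracle", {
  set.seed(19)
  for (i in 1:100) {
    dil <- rep(c(1, 0.1, 0.01, 0.001), each = 2)
    ct <- 12 - 3.4 * log10(dil) + stats::rnorm(length(dil), 0, 0.15)
    cv <- fitInputStandardCurve(inputWells(dil, ct))
    want <- olsOracle(log10(dil), ct)
    expect_equal(curveSlope(cv), unname(want["slope"]), tolerance = 1e-9)
    expect_equal(curveIntercept(cv), unname(want["intercept"]),
                 tolerance = 1e-9)
  }
})

test_that("curve inversion round-trips any valid fraction", {
  cv <- fitInputStandardCurve(
    inputWells(c(1, 0.1, 0.01), c(11, 14.5, 18)))
  for (f in c(1, 0.3, 0.1, 0.02, 0.005)) {
    ct <- curveIntercept(cv) + curveSlope(cv) * log10(f)
    expect_equal(pulldownEfficacy(cv, ct), f, tolerance = 1e-9)
  }
})

test_that("relative enrichment follows the efficacy-ratio definition", {
  mk <- function(locus, ct0) fitInputStandardCurve(inputWells(
    c(1, 0.1, 0.01), ct0 + c(0, log2(10), 2 * log2(10)), locus = locus))
  cvT <- mk("target", 25)
  cvC <- mk("alpha_actinin", 22)

  # IP Ct equal to the 1% input well inverts to efficacy 0.01
  ctAt <- function(cv, f) curveIntercept(cv) + curveSlope(cv) * log10(f)
  enr0 <- chipQpcrEnrichment(ipWells(ctAt(cvT, 0.01)), cvT, cvC,
                             ipWells(ctAt(cvC, 0.01), "alpha_actinin"))
  expect_equal(enr0$pulldown_efficacy, 0.01, tolerance = 1e-9)
  expect_equal(enr0$relative_enrichment, 1, tolerance = 1e-9)

  # efficacies 0.02 over 0.01 give enrichment exactly 2
  enr2 <- chipQpcrEnrichment(ipWells(ctAt(cvT, 0.02)), cvT, cvC,
                             ipWells(ctAt(cvC, 0.01), "alpha_actinin"))
  expect_equal(enr2$relative_enrichment, 2, tolerance = 1e-9)
  expect_false(enr2$extrapolated)

  # control locus against itself is exactly 1
  self <- chipQpcrEnrichment(ipWells(ctAt(cvC, 0.01), "alpha_actinin"),
                             cvC, cvC,
                             ipWells(ctAt(cvC, 0.01), "alpha_actinin"))
  expect_identical(self$relative_enrichment, 1)

  # an IP Ct outside the calibrated range is flagged
  expect_warning(
    enrX <- chipQpcrEnrichment(ipWells(ctAt(cvT, 0.0001)), cvT, cvC,
                               ipWells(ctAt(cvC, 0.01), "alpha_actinin")),
    "extrapolation")
  expect_true(enrX$extrapolated)
})

test_that("ddCt expression matches the 2^(-ddCt) definition", {
  wells <- data.frame(
    sample = rep(c("ref", "s1"), each = 2),
    locus = rep(c("piwi", "RPL32"), 2),
    replicate = 1L,
    ct = c(25, 20, 26, 20))
  out <- ddctExpression(wells, targetLocus = "piwi",
                        referenceSample = "ref")
  expect_identical(out$fold_change[out$sample == "ref"], 1)
  expect_true(out$is_reference[out$sample == "ref"])
  # one extra target cycle, control unchanged: half the expression
  expect_equal(out$fold_change[out$sample == "s1"], 0.5,
               tolerance = 1e-12)

  # random tables: elementwise agreement with a direct recomputation
  set.seed(23)
  for (i in 1:20) {
    ctT <- stats::runif(3, 20, 30)
    ctC <- stats::runif(3, 15, 25)
    w <- data.frame(sample = rep(c("ref", "a", "b"), each = 2),
                    locus = rep(c("t", "c"), 3), replicate = 1L,
                    ct = as.vector(rbind(ctT, ctC)))
    outR <- ddctExpression(w, targetLocus = "t", controlLocus = "c",
                           referenceSample = "ref")
    dct <- ctT - ctC
    want <- 2^(-(dct - dct[1]))
    expect_equal(outR$fold_change[match(c("ref", "a", "b"), outR$sample)],
                 want, tolerance = 1e-12)
  }

  # shifting both loci of one sample by a constant leaves folds unchanged
  wells2 <- wells
  wells2$ct[wells2$sample == "s1"] <- wells2$ct[wells2$sample == "s1"] + 3
  out2 <- ddctExpression(wells2, targetLocus = "piwi",
                         referenceSample = "ref")
  expect_equal(out2$fold_change, out$fold_change, tolerance = 1e-12)

  expect_error(
    ddctExpression(wells[wells$locus != "RPL32", ], targetLocus = "piwi",
                   referenceSample = "ref"),
    "missing control locus")
})

test_that("beta-gal activity is the least-squares OD slope", {
  expect_equal(betaGalActivity(c(0, 60, 120), c(0.1, 0.2, 0.3))$activity,
               1 / 600, tolerance = 1e-12)
  expect_identical(betaGalActivity(c(0, 60, 120), c(0.2, 0.2, 0.2))$activity,
                   0)

  # noisy series equals the closed-form OLS slope
  set.seed(29)
  t <- seq(0, 120, by = 15)
  od <- 0.05 + 0.002 * t + stats::rnorm(length(t), 0, 0.01)
  got <- betaGalActivity(t, od)
  expect_equal(got$activity, unname(olsOracle(t, od)["slope"]),
               tolerance = 1e-12)

  # negative slope clamps to zero with a flag
  dn <- betaGalActivity(c(0, 60, 120), c(0.3, 0.2, 0.1))
  expect_identical(dn$activity, 0)
  expect_true(dn$clamped)

  # invariances: uniform time shift; linear OD scaling
  expect_equal(betaGalActivity(t + 30, od)$activity, got$activity,
               tolerance = 1e-12)
  expect_equal(betaGalActivity(t, 2.5 * od)$activity, 2.5 * got$activity,
               tolerance = 1e-12)

  # linear-range ceiling drops saturated readings
  odSat <- c(0.1, 0.6, 1.2, 1.8, 1.9, 1.95, 1.97, 1.98, 1.99)
  full <- betaGalActivity(t, odSat)
  lin <- betaGalActivity(t, odSat, odCeiling = 1.5)
  expect_lt(lin$n_points, full$n_points)
  expect_gt(lin$activity, full$activity)

  expect_error(betaGalActivity(c(10, 10, 10), c(1, 2, 3)),
               "3 distinct time")
})

test_that("pigment summaries and genotype folds follow the formulas", {
  s <- data.frame(genotype_class = rep(c("C", "M"), each = 3),
                  od480 = c(0.2, 0.2, 0.2, 0.4, 0.5, 0.6),
                  flies_per_sample = 5L)
  ps <- pigmentSummary(s)
  expect_equal(ps$mean[ps$genotype_class == "C"], 0.2)
  expect_identical(ps$sem[ps$genotype_class == "C"], 0)
  expect_equal(ps$mean[ps$genotype_class == "M"], 0.5)
  expect_equal(ps$sem[ps$genotype_class == "M"],
               sd(c(0.4, 0.5, 0.6)) / sqrt(3), tolerance = 1e-12)
  perFly <- pigmentSummary(s, perFly = TRUE)
  expect_equal(perFly$mean, ps$mean / 5, tolerance = 1e-12)

  expect_error(pigmentSummary(
    data.frame(genotype_class = c("C", "C", "M"), od480 = c(1, 2, 3))),
    "fewer than 2")

  v <- data.frame(genotype_class = rep(c("C", "M", "Z", "M+Z"), each = 2),
                  value = rep(c(1, 2, 4, 6), each = 2))
  gf <- genotypeFoldChanges(v, controlClass = "C")
  expect_equal(gf$fold_change, c(1, 2, 4, 6), tolerance = 1e-12)
  expect_identical(gf$fold_sem[gf$genotype_class == "C"], 0)

  expect_error(genotypeFoldChanges(
    data.frame(genotype_class = rep("C", 2), value = 0:0 * 0),
    controlClass = "C"), "mean is 0")
  expect_error(genotypeFoldChanges(v, controlClass = "WT"), "absent")
})
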