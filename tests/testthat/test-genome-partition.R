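# Annotation parsing, serialization, bin-class assignment, subtelomeric
# windows.

writeTmp <- function(lines, ext = ".bed") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

armTsv <- function(arms) {
  p <- tempfile(fileext = ".tsv")
  write.table(arms, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

test_that("BED parsing validates and reports line numbers", {
  armPath <- armTsv(tinyArms())
  fs <- loadAnnotation(armPath,
                       teBed = writeTmp("armA\t100\t600\troo"))
  te <- teInstances(fs)
  expect_identical(BiocGenerics::start(te) - 1L, 100L)
  expect_identical(BiocGenerics::end(te), 600L)
  expect_identical(S4Vectors::mcols(te)$family, "roo")

  expect_error(
    loadAnnotation(armPath, teBed = writeTmp(c(
      "armA\t100\t600\troo", "armA\t100\t2000000\tgypsy5"))),
    "line 2.*beyond arm")
  expect_error(
    loadAnnotation(armPath, teBed = writeTmp("armZ\t0\t10\troo")),
    "line 1.*unknown")
  expect_error(
    loadAnnotation(armPath, teBed = writeTmp("armA\t600\t100\troo")),
    "invalid interval")
  expect_error(
    loadAnnotation(armPath, clusterBed = writeTmp("armA\t10\t20\t.")),
    "missing name")
})

test_that("annotation round-trips through write and load", {
  set.seed(33)
  armTab <- tinyArms()
  n <- 1000L
  armIdx <- sample.int(nrow(armTab), n, replace = TRUE)
  len <- sample(100:5000, n, replace = TRUE)
  start0 <- floor(runif(n, 0, armTab$length[armIdx] - len))
  te <- GenomicRanges::GRanges(
    armTab$name[armIdx],
    IRanges::IRanges(start = start0 + 1, width = len),
    family = sample(sprintf("fam%d", 1:40), n, replace = TRUE))
  fs <- featureSet(armTab, teInstances = te)
  dir <- tempfile()
  writeAnnotation(fs, dir)
  fs2 <- loadAnnotation(file.path(dir, "arms.tsv"),
                        teBed = file.path(dir, "te_instances.bed"))
  expect_identical(as.data.frame(teInstances(fs2)),
                   as.data.frame(teInstances(fs)))
  expect_identical(arms(fs2), arms(fs))
})

test_that("bins gain labels by the midpoint rule", {
  armTab <- data.frame(name = "armA", length = 2000000L,
                       telomere_at_start = TRUE,
                       pericentric_border = 1000000L, is_chr4 = FALSE)
  te <- GenomicRanges::GRanges("armA", IRanges::IRanges(201, 800),
                               family = "roo")
  fs <- featureSet(armTab, teInstances = te)
  bt <- binTrack(makeMTrack("armA", c(250, 850, 1200250), rep(1, 3)),
                 binWidth = 500)
  mem <- assignBins(bt, fs, subtelWindow = 50000)
  lab <- membershipLabels(mem)
  # bin [0,500): midpoint 250 inside the TE and the subtelomeric window
  expect_setequal(lab[[1]], c("TE:roo", "subtelomere:armA"))
  # bin [500,1000): midpoint 750 inside TE, still within the 50-kb window
  expect_setequal(lab[[2]], c("TE:roo", "subtelomere:armA"))
  # midpoint beyond the border: pericentric
  expect_setequal(lab[[3]], "pericentric")

  # with no features a tip bin is subtelomere + euchromatin
  fs0 <- featureSet(armTab)
  mem0 <- assignBins(bt, fs0, subtelWindow = 50000)
  expect_setequal(membershipLabels(mem0)[[1]],
                  c("subtelomere:armA", "euchromatin"))

  # straddling bins: a bin whose midpoint is outside the feature is out
  btEdge <- binTrack(makeMTrack("armA", c(999900), 1), binWidth = 500)
  # bin [999500,1000000): midpoint 999750 < border -> euchromatic side
  memEdge <- assignBins(btEdge, fs0, subtelWindow = 50000)
  expect_true("euchromatin" %in% membershipLabels(memEdge)[[1]])

  expect_error(
    assignBins(binTrack(makeMTrack("armQ", 100, 1)), fs0),
    "unknown arm")
})

test_that("crossing the pericentric border flips exactly that label", {
  armTab <- data.frame(name = "armA", length = 2000000L,
                       telomere_at_start = TRUE,
                       pericentric_border = 1000000L, is_chr4 = FALSE)
  fs <- featureSet(armTab)
  bt <- binTrack(makeMTrack("armA", c(999600, 1000100), c(1, 1)),
                 binWidth = 500)
  lab <- membershipLabels(assignBins(bt, fs))
  expect_identical(setdiff(lab[[2]], lab[[1]]), "pericentric")
  expect_identical(setdiff(lab[[1]], lab[[2]]), "euchromatin")
})

test_that("membership matches an exhaustive all-pairs overlap scan", {
  set.seed(55)
  armTab <- tinyArms()
  # random features
  nTe <- 150L; nCl <- 50L
  mkFeat <- function(n, minLen, maxLen) {
    armIdx <- sample.int(nrow(armTab), n, replace = TRUE)
    len <- sample(minLen:maxLen, n, replace = TRUE)
    start0 <- floor(runif(n, 0, armTab$length[armIdx] - len))
    data.frame(chrom = armTab$name[armIdx], start = start0,
               end = start0 + len)
  }
  teDf <- mkFeat(nTe, 500, 8000)
  teDf$family <- sprintf("fam%d", seq_len(nTe) %% 30)
  clDf <- mkFeat(nCl, 2000, 30000)
  clDf$id <- sprintf("cl%d", seq_len(nCl))
  fs <- featureSet(
    armTab,
    teInstances = GenomicRanges::GRanges(
      teDf$chrom, IRanges::IRanges(teDf$start + 1, teDf$end),
      family = teDf$family),
    pirnaClusters = GenomicRanges::GRanges(
      clDf$chrom, IRanges::IRanges(clDf$start + 1, clDf$end),
      cluster_id = clDf$id))
  # random bins from random probes
  n <- 4000L
  armIdx <- sample.int(nrow(armTab), n, replace = TRUE)
  pos0 <- floor(runif(n, 0, armTab$length[armIdx]))
  bt <- binTrack(makeMTrack(armTab$name[armIdx], pos0, stats::rnorm(n)),
                 binWidth = 500)
  mem <- assignBins(bt, fs, subtelWindow = 50000)

  b <- bins(bt)
  bChrom <- as.character(GenomeInfoDb::seqnames(b))
  bMid <- (BiocGenerics::start(b) - 1) + 250
  oracle <- character(length(b))
  for (i in seq_along(b)) {
    a <- armTab[armTab$name == bChrom[i], ]
    want <- character(0)
    if (a$is_chr4) want <- c(want, "chromosome4")
    hetSide <- if (a$telomere_at_start) bMid[i] >= a$pericentric_border
               else bMid[i] < a$pericentric_border
    if (hetSide && !a$is_chr4) want <- c(want, "pericentric")
    for (j in seq_len(nrow(teDf)))
      if (teDf$chrom[j] == bChrom[i] && bMid[i] >= teDf$start[j] &&
            bMid[i] < teDf$end[j])
        want <- c(want, paste0("TE:", teDf$family[j]))
    for (j in seq_len(nrow(clDf)))
      if (clDf$chrom[j] == bChrom[i] && bMid[i] >= clDf$start[j] &&
            bMid[i] < clDf$end[j])
        want <- c(want, paste0("cluster:", clDf$id[j]))
    winStart <- if (a$telomere_at_start) 0 else a$length - 50000
    if (bMid[i] >= winStart && bMid[i] < winStart + 50000)
      want <- c(want, paste0("subtelomere:", a$name))
    if (!any(want %in% c("pericentric", "chromosome4")) &&
          !any(startsWith(want, "TE:")) &&
          !any(startsWith(want, "cluster:")))
      want <- c(want, "euchromatin")
    oracle[i] <- paste(sort(unique(want)), collapse = "|")
  }
  got <- vapply(membershipLabels(mem),
                function(l) paste(sort(l), collapse = "|"), character(1))
  expect_identical(got, oracle)
})

test_that("subtelomeric windows follow orientation and truncation", {
  armTab <- data.frame(
    name = c("a1", "a2", "short"),
    length = c(1000000L, 1000000L, 30000L),
    telomere_at_start = c(TRUE, FALSE, TRUE),
    pericentric_border = c(900000L, 100000L, 20000L),
    is_chr4 = FALSE)
  win <- subtelomericWindows(featureSet(armTab), window = 50000)
  df <- data.frame(start = BiocGenerics::start(win) - 1L,
                   end = BiocGenerics::end(win))
  expect_identical(df$start, c(0L, 950000L, 0L))
  expect_identical(df$end, c(50000L, 1000000L, 30000L))
})
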