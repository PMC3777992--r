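#' @include AllGenerics.R
NULL

labelType <- function(label) {
  ifelse(startsWith(label, "TE:"), "te_family",
    ifelse(startsWith(label, "cluster:"), "cluster",
      ifelse(startsWith(label, "subtelomere:"), "subtelomere_arm", "class")))
}

#' Per-class and per-family mean enrichment
#'
#' For every membership label, the arithmetic mean of the member bins'
#' mean M, the bin count and the standard error (sd of bin means / sqrt of
#' bin count).  Besides the individual `TE:<family>`, `cluster:<id>` and
#' `subtelomere:<arm>` labels, aggregate classes `TE`, `piRNA_cluster` and
#' `subtelomere` (the union of the respective bins) are reported, matching
#' how whole-class decreases are quoted alongside per-family profiles.
#'
#' @param binTrack a [BinTrack-class].
#' @param membership the [BinMembership-class] for the same bins.
#' @param condition condition label stored in the profile.
#' @param features optional [FeatureSet-class]; when given, families and
#'   clusters covered by no bin are listed as uncovered.
#' @return an [EnrichmentProfile-class].
#' @export
classMeanProfile <- function(binTrack, membership, condition = "unknown",
                             features = NULL) {
  stopifnot(is(binTrack, "BinTrack"), is(membership, "BinMembership"))
  if (length(binTrack@bins) != length(membership@bins))
    stop("binTrack and membership cover different bins")
  labels <- membership@labels
  m <- S4Vectors::mcols(binTrack@bins)$mean_m
  reps <- lengths(labels)
  long <- data.frame(label = unlist(labels),
                     m = rep(m, reps))
  # aggregate classes over the union of family / cluster / subtelomere bins
  addAggregate <- function(long, prefix, agg) {
    has <- vapply(labels, function(l) any(startsWith(l, prefix)), logical(1))
    if (any(has))
      rbind(long, data.frame(label = agg, m = m[has]))
    else long
  }
  long <- addAggregate(long, "TE:", "TE")
  long <- addAggregate(long, "cluster:", "piRNA_cluster")
  long <- addAggregate(long, "subtelomere:", "subtelomere")

  means <- tapply(long$m, long$label, mean)
  ns <- tapply(long$m, long$label, length)
  ses <- tapply(long$m, long$label, semOf)
  stats <- data.frame(label = names(means),
                      type = labelType(names(means)),
                      mean_m = as.numeric(means),
                      n_bins = as.integer(ns),
                      se = as.numeric(ses),
                      row.names = NULL,
                      stringsAsFactors = FALSE)
  stats <- stats[order(stats$type, stats$label), , drop = FALSE]
  rownames(stats) <- NULL

  uncovered <- character(0)
  if (!is.null(features)) {
    expected <- c(
      paste0("TE:", unique(S4Vectors::mcols(features@teInstances)$family)),
      paste0("cluster:",
             unique(S4Vectors::mcols(features@pirnaClusters)$cluster_id)))
    uncovered <- setdiff(expected, stats$label)
  }
  new("EnrichmentProfile", condition = condition, stats = stats,
      uncovered = uncovered)
}

#' Wild-type versus mutant differential report
#'
#' Joins two enrichment profiles on their labels.  For every shared label,
#' `delta_m = mean_mut - mean_wt`.  `percent_decrease = 100 * (mean_wt -
#' mean_mut) / mean_wt` is reported only where the wild-type mean exceeds
#' `mFloor` (percentages of a near-zero reference are meaningless and are
#' flagged instead).  Families and clusters are compared only when covered
#' by at least `minBins` bins in both conditions; their direction is the
#' strict sign of `delta_m` (exact ties count as unchanged), and direction
#' counts are tallied per feature type.
#'
#' @param wt,mut [EnrichmentProfile-class] objects for the reference and
#'   altered condition.
#' @param mFloor reference-mean floor for percent decreases (default 0.1).
#' @param minBins minimum bin coverage per condition for family/cluster
#'   comparisons (default 5).
#' @return a [DifferentialReport-class].
#' @export
differentialProfile <- function(wt, mut, mFloor = 0.1, minBins = 5) {
  stopifnot(is(wt, "EnrichmentProfile"), is(mut, "EnrichmentProfile"))
  a <- wt@stats
  b <- mut@stats
  shared <- intersect(a$label, b$label)
  if (length(shared) == 0L)
    stop("the two profiles share no labels")
  ia <- match(shared, a$label)
  ib <- match(shared, b$label)
  joined <- data.frame(label = shared,
                       type = a$type[ia],
                       mean_wt = a$mean_m[ia],
                       mean_mut = b$mean_m[ib],
                       n_bins_wt = a$n_bins[ia],
                       n_bins_mut = b$n_bins[ib],
                       se_wt = a$se[ia],
                       se_mut = b$se[ib],
                       stringsAsFactors = FALSE)
  joined$delta_m <- joined$mean_mut - joined$mean_wt
  joined$percent_defined <- joined$mean_wt > mFloor
  joined$percent_decrease <- ifelse(
    joined$percent_defined,
    100 * (joined$mean_wt - joined$mean_mut) / joined$mean_wt,
    NA_real_)

  classes <- joined[joined$type == "class", , drop = FALSE]
  rownames(classes) <- NULL
  feat <- joined[joined$type %in% c("te_family", "cluster") &
                   joined$n_bins_wt >= minBins &
                   joined$n_bins_mut >= minBins, , drop = FALSE]
  feat$direction <- ifelse(feat$delta_m < 0, "decreased",
                           ifelse(feat$delta_m > 0, "increased",
                                  "unchanged"))
  rownames(feat) <- NULL
  countFor <- function(tp) {
    sub <- feat[feat$type == tp, , drop = FALSE]
    c(n_decreased = sum(sub$direction == "decreased"),
      n_increased = sum(sub$direction == "increased"),
      n_unchanged = sum(sub$direction == "unchanged"),
      n_total = nrow(sub))
  }
  new("DifferentialReport",
      classes = classes,
      features = feat,
      counts = list(te_families = countFor("te_family"),
                    clusters = countFor("cluster")),
      mFloor = mFloor, minBins = minBins)
}

#' Cross-condition per-family correlation
#'
#' Squared Pearson correlation of per-family mean M values between two
#' profiles (e.g. ovary versus larvae), over the families present in
#' both.  Also reports the correlation of the per-family change
#' (`b - a`) against the level in profile `a`, the check used to rule out
#' tissue-composition artifacts.
#'
#' @param a,b [EnrichmentProfile-class] objects sharing at least three TE
#'   families.
#' @return a [CorrelationReport-class].
#' @export
crossConditionCorrelation <- function(a, b) {
  stopifnot(is(a, "EnrichmentProfile"), is(b, "EnrichmentProfile"))
  fa <- a@stats[a@stats$type == "te_family", , drop = FALSE]
  fb <- b@stats[b@stats$type == "te_family", , drop = FALSE]
  shared <- intersect(fa$label, fb$label)
  if (length(shared) < 3L)
    stop("need at least 3 shared TE families; have ", length(shared))
  x <- fa$mean_m[match(shared, fa$label)]
  y <- fb$mean_m[match(shared, fb$label)]
  r <- suppressWarnings(stats::cor(x, y))  # NA for zero-variance input
  new("CorrelationReport",
      pairs = data.frame(label = shared, mean_a = x, mean_b = y,
                         stringsAsFactors = FALSE),
      rSquared = r^2,
      nFamilies = length(shared),
      changeLevelR = suppressWarnings(stats::cor(y - x, x)))
}

#' Ordered subtelomeric bin series
#'
#' For each subtelomeric window, the member bins (midpoint inside the
#' window) ordered telomere-to-centromere: ascending genomic start for
#' telomere-at-start arms, descending otherwise.
#'
#' @param binTrack a [BinTrack-class].
#' @param windows windows from [subtelomericWindows()].
#' @return named list (one element per arm) of data.frames with columns
#'   `start` (0-based bin start), `mean_m`, `n_probes` and the attribute
#'   `empty` flagging windows with no covered bin.
#' @export
subtelomereProfile <- function(binTrack, windows) {
  stopifnot(is(binTrack, "BinTrack"), is(windows, "GRanges"))
  gr <- binTrack@bins
  mid0 <- (BiocGenerics::start(gr) - 1) + binTrack@binWidth / 2
  midGr <- GenomicRanges::GRanges(
    as.character(GenomeInfoDb::seqnames(gr)),
    IRanges::IRanges(start = floor(mid0) + 1, width = 1L))
  out <- list()
  for (i in seq_along(windows)) {
    armName <- S4Vectors::mcols(windows)$arm[i]
    telStart <- S4Vectors::mcols(windows)$telomere_at_start[i]
    h <- S4Vectors::queryHits(
      GenomicRanges::findOverlaps(midGr, windows[i]))
    d <- data.frame(start = BiocGenerics::start(gr)[h] - 1L,
                    mean_m = S4Vectors::mcols(gr)$mean_m[h],
                    n_probes = S4Vectors::mcols(gr)$n_probes[h])
    d <- d[order(d$start, decreasing = !telStart), , drop = FALSE]
    rownames(d) <- NULL
    attr(d, "empty") <- nrow(d) == 0L
    out[[armName]] <- d
  }
  out
}
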