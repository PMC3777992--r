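#' @include AllGenerics.R
NULL

#' Construct a genome annotation from in-memory pieces
#'
#' @param arms chromosome-arm table (`name`, `length`, `telomere_at_start`,
#'   `pericentric_border`, `is_chr4`).
#' @param teInstances `GRanges` with a `family` metadata column (or NULL).
#' @param pirnaClusters `GRanges` with a `cluster_id` metadata column (or
#'   NULL).
#' @param reporterLoci `GRanges` with a `name` metadata column (or NULL).
#' @return a validated [FeatureSet-class].
#' @export
featureSet <- function(arms, teInstances = NULL, pirnaClusters = NULL,
                       reporterLoci = NULL) {
  arms <- checkArmTable(as.data.frame(arms))
  si <- armSeqinfo(arms)
  fix <- function(gr) {
    if (is.null(gr)) return(GenomicRanges::GRanges(seqinfo = si))
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(si)
    GenomeInfoDb::seqinfo(gr) <- si
    gr
  }
  new("FeatureSet", arms = arms, teInstances = fix(teInstances),
      pirnaClusters = fix(pirnaClusters), reporterLoci = fix(reporterLoci))
}

# Read and validate one labeled BED file (chrom, start0, end0, name),
# reporting offending line numbers.
readLabeledBed <- function(path, arms, what) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name"),
                           colClasses = c("character", "numeric", "numeric",
                                          "character"))
  armIdx <- match(bed$chrom, arms$name)
  bad <- which(is.na(armIdx))
  if (length(bad))
    stop(sprintf("%s line %d: unknown chromosome arm '%s'",
                 what, bad[1], bed$chrom[bad[1]]))
  bad <- which(bed$end <= bed$start | bed$start < 0)
  if (length(bad))
    stop(sprintf("%s line %d: invalid interval [%g, %g)",
                 what, bad[1], bed$start[bad[1]], bed$end[bad[1]]))
  bad <- which(bed$end > arms$length[armIdx])
  if (length(bad))
    stop(sprintf("%s line %d: interval end %g beyond arm '%s' length %d",
                 what, bad[1], bed$end[bad[1]], bed$chrom[bad[1]],
                 arms$length[armIdx[bad[1]]]))
  bad <- which(is.na(bed$name) | bed$name == "" | bed$name == ".")
  if (length(bad))
    stop(sprintf("%s line %d: missing name/label field", what, bad[1]))
  GenomicRanges::GRanges(bed$chrom,
                         IRanges::IRanges(start = bed$start + 1,
                                          end = bed$end),
                         seqinfo = armSeqinfo(arms),
                         label = bed$name)
}

#' Load a genome annotation from an arm table and BED files
#'
#' The arm table is a TSV with header columns `name`, `length`,
#' `telomere_at_start`, `pericentric_border`, `is_chr4`.  Feature BED
#' files are 4-column, 0-based half-open, with the name field carrying the
#' TE family, cluster id or reporter name.  Malformed or out-of-bounds
#' lines are reported with their line number.
#'
#' @param armTable path to the arm table TSV.
#' @param teBed,clusterBed,reporterBed paths to BED files (each optional).
#' @return a validated [FeatureSet-class].
#' @export
loadAnnotation <- function(armTable, teBed = NULL, clusterBed = NULL,
                           reporterBed = NULL) {
  arms <- utils::read.table(armTable, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  arms <- checkArmTable(arms)
  te <- cl <- rep <- NULL
  if (!is.null(teBed)) {
    te <- readLabeledBed(teBed, arms, "TE BED")
    S4Vectors::mcols(te) <- S4Vectors::DataFrame(
      family = S4Vectors::mcols(te)$label)
  }
  if (!is.null(clusterBed)) {
    cl <- readLabeledBed(clusterBed, arms, "cluster BED")
    S4Vectors::mcols(cl) <- S4Vectors::DataFrame(
      cluster_id = S4Vectors::mcols(cl)$label)
  }
  if (!is.null(reporterBed)) {
    rep <- readLabeledBed(reporterBed, arms, "reporter BED")
    S4Vectors::mcols(rep) <- S4Vectors::DataFrame(
      name = S4Vectors::mcols(rep)$label)
  }
  featureSet(arms, te, cl, rep)
}

#' Write a genome annotation to an arm table and BED files
#'
#' Inverse of [loadAnnotation()]: writes `arms.tsv`, `te_instances.bed`,
#' `pirna_clusters.bed` and (if present) `reporter_loci.bed` under `dir`,
#' 0-based half-open.
#'
#' @param features a [FeatureSet-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the named character vector of written paths.
#' @export
writeAnnotation <- function(features, dir) {
  stopifnot(is(features, "FeatureSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(arms = file.path(dir, "arms.tsv"))
  utils::write.table(features@arms, paths["arms"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeBed <- function(gr, labels, path) {
    df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                     start = BiocGenerics::start(gr) - 1L,
                     end = BiocGenerics::end(gr),
                     name = labels)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    path
  }
  if (length(features@teInstances))
    paths["te"] <- writeBed(features@teInstances,
                            S4Vectors::mcols(features@teInstances)$family,
                            file.path(dir, "te_instances.bed"))
  if (length(features@pirnaClusters))
    paths["clusters"] <- writeBed(
      features@pirnaClusters,
      S4Vectors::mcols(features@pirnaClusters)$cluster_id,
      file.path(dir, "pirna_clusters.bed"))
  if (length(features@reporterLoci))
    paths["reporters"] <- writeBed(
      features@reporterLoci,
      S4Vectors::mcols(features@reporterLoci)$name,
      file.path(dir, "reporter_loci.bed"))
  invisible(paths)
}

#' Subtelomeric windows of every arm
#'
#' For arms with the telomere at coordinate 0 the window is `[0, window)`;
#' otherwise `[length - window, length)`; arms shorter than the window are
#' covered whole.
#'
#' @param features a [FeatureSet-class].
#' @param window window width in bp (default 50000, i.e. the 50-kb
#'   sequence adjacent to the assembly end).
#' @return `GRanges` with metadata columns `arm` and `telomere_at_start`.
#' @export
subtelomericWindows <- function(features, window = 50000) {
  stopifnot(is(features, "FeatureSet"), window > 0)
  arms <- features@arms
  w <- pmin(window, arms$length)
  start0 <- ifelse(arms$telomere_at_start, 0, arms$length - w)
  GenomicRanges::GRanges(arms$name,
                         IRanges::IRanges(start = start0 + 1, width = w),
                         seqinfo = armSeqinfo(arms),
                         arm = arms$name,
                         telomere_at_start = arms$telomere_at_start)
}

#' Assign bins to feature classes
#'
#' A bin belongs to a feature interval iff its midpoint
#' (`start + binWidth/2`, 0-based) lies inside the interval.  Bins gain
#' the `pericentric` label when the midpoint is on the heterochromatic
#' side of the arm's border, `chromosome4` on chromosome-4-like arms,
#' `TE:<family>` and `cluster:<id>` labels per containing feature, and
#' `subtelomere:<arm>` within the subtelomeric window.  Labels are sets
#' (overlap allowed); `euchromatin` marks exactly the bins with no
#' heterochromatic label.
#'
#' @param binTrack a [BinTrack-class].
#' @param features a [FeatureSet-class] sharing the bin arms.
#' @param subtelWindow subtelomeric window width in bp.
#' @return a [BinMembership-class].
#' @export
assignBins <- function(binTrack, features, subtelWindow = 50000) {
  stopifnot(is(binTrack, "BinTrack"), is(features, "FeatureSet"))
  gr <- binTrack@bins
  arms <- features@arms
  armIdx <- match(as.character(GenomeInfoDb::seqnames(gr)), arms$name)
  if (anyNA(armIdx))
    stop("bin on unknown arm: '",
         as.character(GenomeInfoDb::seqnames(gr))[which(is.na(armIdx))[1]],
         "'")
  n <- length(gr)
  mid0 <- (BiocGenerics::start(gr) - 1) + binTrack@binWidth / 2
  midGr <- GenomicRanges::GRanges(
    as.character(GenomeInfoDb::seqnames(gr)),
    IRanges::IRanges(start = floor(mid0) + 1, width = 1L))

  labels <- vector("list", n)
  for (i in seq_len(n)) labels[[i]] <- character(0)
  addLabel <- function(idx, lab) {
    for (k in seq_along(idx)) {
      i <- idx[k]
      labels[[i]] <<- c(labels[[i]], lab[k])
    }
  }

  isChr4 <- arms$is_chr4[armIdx]
  if (any(isChr4))
    addLabel(which(isChr4), rep("chromosome4", sum(isChr4)))
  hetSide <- ifelse(arms$telomere_at_start[armIdx],
                    mid0 >= arms$pericentric_border[armIdx],
                    mid0 < arms$pericentric_border[armIdx])
  pc <- hetSide & !isChr4
  if (any(pc)) addLabel(which(pc), rep("pericentric", sum(pc)))

  if (length(features@teInstances)) {
    h <- GenomicRanges::findOverlaps(midGr, features@teInstances)
    fams <- S4Vectors::mcols(features@teInstances)$family
    addLabel(S4Vectors::queryHits(h),
             paste0("TE:", fams[S4Vectors::subjectHits(h)]))
  }
  if (length(features@pirnaClusters)) {
    h <- GenomicRanges::findOverlaps(midGr, features@pirnaClusters)
    ids <- S4Vectors::mcols(features@pirnaClusters)$cluster_id
    addLabel(S4Vectors::queryHits(h),
             paste0("cluster:", ids[S4Vectors::subjectHits(h)]))
  }
  win <- subtelomericWindows(features, subtelWindow)
  h <- GenomicRanges::findOverlaps(midGr, win)
  addLabel(S4Vectors::queryHits(h),
           paste0("subtelomere:",
                  S4Vectors::mcols(win)$arm[S4Vectors::subjectHits(h)]))

  het <- vapply(labels, function(l) {
    any(l %in% c("pericentric", "chromosome4")) ||
      any(startsWith(l, "TE:")) || any(startsWith(l, "cluster:"))
  }, logical(1))
  if (any(!het))
    addLabel(which(!het), rep("euchromatin", sum(!het)))
  labels <- lapply(labels, unique)
  new("BinMembership", bins = gr, labels = labels)
}
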