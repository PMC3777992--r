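#' @include AllGenerics.R
NULL

#' Read a probe table
#'
#' Five-column TSV with header `chrom, pos, chip, input, unique`; `pos` is
#' the 0-based probe midpoint.  Rows are validated (known arm, position
#' within the arm, positive intensities) with line numbers in error
#' messages.
#'
#' @param path path to the TSV.
#' @param arms chromosome-arm table the probes must lie on.
#' @return `GRanges` of probe records for [computeMValues()].
#' @export
readProbeTable <- function(path, arms) {
  arms <- checkArmTable(as.data.frame(arms))
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "chip", "input", "unique")
  if (!all(need %in% names(d)))
    stop("probe table needs columns: ", paste(need, collapse = ", "))
  armIdx <- match(d$chrom, arms$name)
  bad <- which(is.na(armIdx))
  if (length(bad))
    stop(sprintf("probe table line %d: unknown arm '%s'",
                 bad[1] + 1L, d$chrom[bad[1]]))
  bad <- which(d$pos < 0 | d$pos >= arms$length[armIdx])
  if (length(bad))
    stop(sprintf("probe table line %d: position %g outside arm '%s'",
                 bad[1] + 1L, d$pos[bad[1]], d$chrom[bad[1]]))
  bad <- which(!is.finite(d$chip) | !is.finite(d$input) |
                 d$chip <= 0 | d$input <= 0)
  if (length(bad))
    stop(sprintf("probe table line %d: non-positive intensity", bad[1] + 1L))
  GenomicRanges::GRanges(d$chrom,
                         IRanges::IRanges(start = d$pos + 1, width = 1L),
                         seqinfo = armSeqinfo(arms),
                         chip = d$chip, input = d$input,
                         unique = as.logical(d$unique))
}

#' Write a probe table
#'
#' Inverse of [readProbeTable()]; positions are written as 0-based
#' midpoints.
#'
#' @param probes `GRanges` of probe records (`chip`, `input`, `unique`).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeProbeTable <- function(probes, path) {
  mc <- S4Vectors::mcols(probes)
  d <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(probes)),
                  pos = BiocGenerics::start(probes) - 1L,
                  chip = mc$chip, input = mc$input,
                  unique = mc$unique)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a binned track as bedGraph plus a probe-count TSV
#'
#' `<prefix>.bedGraph` holds `chrom, start, end, mean_m` (0-based
#' half-open, via rtracklayer) and `<prefix>_counts.tsv` the per-bin probe
#' counts.
#'
#' @param binTrack a [BinTrack-class].
#' @param prefix output path prefix.
#' @return invisibly, the two paths.
#' @export
writeBinTrack <- function(binTrack, prefix) {
  stopifnot(is(binTrack, "BinTrack"))
  gr <- binTrack@bins
  bg <- GenomicRanges::granges(gr)
  S4Vectors::mcols(bg)$score <- S4Vectors::mcols(gr)$mean_m
  bgPath <- paste0(prefix, ".bedGraph")
  rtracklayer::export(bg, bgPath, format = "bedGraph")
  tsvPath <- paste0(prefix, "_counts.tsv")
  utils::write.table(
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
               start = BiocGenerics::start(gr) - 1L,
               end = BiocGenerics::end(gr),
               mean_m = S4Vectors::mcols(gr)$mean_m,
               n_probes = S4Vectors::mcols(gr)$n_probes),
    tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bedgraph = bgPath, counts = tsvPath))
}

#' Read a binned track written by [writeBinTrack()]
#'
#' @param prefix the path prefix used when writing.
#' @return a [BinTrack-class].
#' @export
readBinTrack <- function(prefix) {
  d <- utils::read.table(paste0(prefix, "_counts.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE)
  w <- unique(d$end - d$start)
  if (length(w) != 1L)
    stop("bin track has inconsistent bin widths: ",
         paste(w, collapse = ", "))
  gr <- GenomicRanges::GRanges(d$chrom,
                               IRanges::IRanges(start = d$start + 1,
                                                end = d$end),
                               mean_m = d$mean_m,
                               n_probes = as.integer(d$n_probes))
  new("BinTrack", bins = gr, binWidth = as.numeric(w))
}

#' Write probe signal as paired bedGraph tracks plus a uniqueness TSV
#'
#' @param probes `GRanges` probe records.
#' @param prefix output path prefix; writes `<prefix>_chip.bedGraph`,
#'   `<prefix>_input.bedGraph` and `<prefix>_unique.tsv`.
#' @return invisibly, the written paths.
#' @export
writeSignalTracks <- function(probes, prefix) {
  mc <- S4Vectors::mcols(probes)
  mk <- function(values, path) {
    gr <- GenomicRanges::granges(probes)
    S4Vectors::mcols(gr)$score <- values
    rtracklayer::export(gr, path, format = "bedGraph")
    path
  }
  chipPath <- mk(mc$chip, paste0(prefix, "_chip.bedGraph"))
  inputPath <- mk(mc$input, paste0(prefix, "_input.bedGraph"))
  uniqPath <- paste0(prefix, "_unique.tsv")
  utils::write.table(
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(probes)),
               pos = BiocGenerics::start(probes) - 1L,
               unique = mc$unique),
    uniqPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(chip = chipPath, input = inputPath, unique = uniqPath))
}

#' Export a differential report as TSV and JSON
#'
#' @param report a [DifferentialReport-class].
#' @param prefix path prefix; writes `<prefix>_classes.tsv`,
#'   `<prefix>_features.tsv` and `<prefix>.json`.
#' @return invisibly, the written paths.
#' @export
writeDifferentialReport <- function(report, prefix) {
  stopifnot(is(report, "DifferentialReport"))
  p1 <- paste0(prefix, "_classes.tsv")
  p2 <- paste0(prefix, "_features.tsv")
  p3 <- paste0(prefix, ".json")
  utils::write.table(report@classes, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report@features, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(classes = report@classes,
         counts = lapply(report@counts, as.list),
         m_floor = report@mFloor, min_bins = report@minBins),
    p3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(classes = p1, features = p2, json = p3))
}
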