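#' @include AllGenerics.R
NULL

#' Compute per-probe M values
#'
#' The M value of a probe is `log2(ChIP intensity / input intensity)`.
#' Probe order and uniqueness flags are preserved; the returned track is
#' not yet normalized.  Non-positive or non-finite intensities are
#' rejected with an error naming the offending record, never silently
#' log-transformed.
#'
#' @param probes `GRanges` of probe records with metadata columns `chip`,
#'   `input` (both strictly positive) and `unique` (logical), e.g. from
#'   [simulateProbeSignal()] or [readProbeTable()].
#' @return an [MTrack-class] with `normalized = FALSE`.
#' @examples
#' gr <- GenomicRanges::GRanges("arm", IRanges::IRanges(101, width = 1),
#'                              chip = 800, input = 200, unique = TRUE)
#' mValues(computeMValues(gr))  # 2
#' @export
computeMValues <- function(probes) {
  stopifnot(is(probes, "GRanges"))
  mc <- S4Vectors::mcols(probes)
  if (!all(c("chip", "input", "unique") %in% names(mc)))
    stop("probe records need metadata columns 'chip', 'input', 'unique'")
  bad <- which(!is.finite(mc$chip) | !is.finite(mc$input) |
                 mc$chip <= 0 | mc$input <= 0)
  if (length(bad))
    stop(sprintf(
      "non-positive or non-finite intensity at probe record %d (%s:%d, chip=%g, input=%g)%s",
      bad[1], as.character(GenomeInfoDb::seqnames(probes))[bad[1]],
      BiocGenerics::start(probes)[bad[1]] - 1L,
      mc$chip[bad[1]], mc$input[bad[1]],
      if (length(bad) > 1L)
        sprintf(" and %d more record(s)", length(bad) - 1L) else ""))
  out <- GenomicRanges::granges(probes)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    m = log2(mc$chip / mc$input),
    unique = as.logical(mc$unique))
  new("MTrack", probes = out, normalized = FALSE)
}

#' Median-normalize an M-value track
#'
#' Subtracts the median M of the uniquely mapping probes from every probe,
#' so that the typical (background) unique probe sits at M = 0.
#' Normalizing twice is an error; renormalizing an already-centered track
#' would be a no-op and almost certainly a pipeline bug.
#'
#' @param track an [MTrack-class] with `normalized = FALSE`.
#' @return the centered [MTrack-class] with `normalized = TRUE`.
#' @export
normalizeTrack <- function(track) {
  stopifnot(is(track, "MTrack"))
  if (track@normalized)
    stop("track is already normalized; refusing to normalize twice")
  if (length(track@probes) == 0L)
    stop("cannot normalize an empty track")
  mc <- S4Vectors::mcols(track@probes)
  if (!any(mc$unique))
    stop("cannot normalize: no uniquely mapping probes in track")
  med <- stats::median(mc$m[mc$unique])
  S4Vectors::mcols(track@probes)$m <- mc$m - med
  track@normalized <- TRUE
  methods::validObject(track)
  track
}

#' Average an M-value track into fixed-width bins
#'
#' Each probe is assigned to the half-open bin
#' `[floor(pos / binWidth) * binWidth, + binWidth)` from arm coordinate 0
#' (0-based midpoints), and the bin value is the arithmetic mean of its
#' member probes' M values.  Non-unique probes are excluded unless
#' requested; bins left without probes are omitted, not zero-filled.
#'
#' @param track an [MTrack-class].
#' @param binWidth bin width in bp (default 500).
#' @param includeNonunique keep probes flagged non-unique (default FALSE).
#' @return a [BinTrack-class].
#' @export
binTrack <- function(track, binWidth = 500, includeNonunique = FALSE) {
  stopifnot(is(track, "MTrack"))
  if (length(binWidth) != 1L || binWidth <= 0)
    stop("binWidth must be a single positive number")
  binWidth <- as.integer(binWidth)
  mc <- S4Vectors::mcols(track@probes)
  keep <- if (includeNonunique) rep(TRUE, length(track@probes)) else mc$unique
  gr <- track@probes[keep]
  m <- mc$m[keep]
  if (length(gr) == 0L)
    return(new("BinTrack",
               bins = GenomicRanges::GRanges(),
               binWidth = as.numeric(binWidth)))
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  pos0 <- BiocGenerics::start(gr) - 1L
  binStart0 <- (pos0 %/% binWidth) * binWidth
  key <- paste(chrom, binStart0, sep = "\r")
  sums <- rowsum(m, key, reorder = FALSE)
  counts <- rowsum(rep(1L, length(m)), key, reorder = FALSE)
  keyChrom <- sub("\r.*$", "", rownames(sums))
  keyStart <- as.numeric(sub("^.*\r", "", rownames(sums)))
  ord <- order(match(keyChrom, unique(chrom)), keyStart)
  outGr <- GenomicRanges::GRanges(
    keyChrom[ord],
    IRanges::IRanges(start = keyStart[ord] + 1, width = binWidth))
  S4Vectors::mcols(outGr) <- S4Vectors::DataFrame(
    mean_m = as.numeric(sums[ord] / counts[ord]),
    n_probes = as.integer(counts[ord]))
  new("BinTrack", bins = outGr, binWidth = as.numeric(binWidth))
}
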