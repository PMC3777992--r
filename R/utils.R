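# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so simulation calls never perturb the global stream.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single non-missing integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Large-sample limit of the sample median of {values + N(0, sd)}.
# For sd = 0 this is the plain median; otherwise the root t of
# mean(pnorm((t - values)/sd)) = 1/2, i.e. the median of the noise-convolved
# mixture.  Used to define the planted truth of median-centered tracks.
asymptoticMedian <- function(values, sd = 0) {
  stopifnot(length(values) > 0L, is.finite(sd), sd >= 0)
  if (sd == 0) return(stats::median(values))
  f <- function(t) mean(stats::pnorm((t - values) / sd)) - 0.5
  stats::uniroot(f,
                 lower = min(values) - 6 * sd,
                 upper = max(values) + 6 * sd,
                 tol = 1e-12)$root
}

# Seqinfo built from a chromosome-arm table.
armSeqinfo <- function(arms) {
  GenomeInfoDb::Seqinfo(seqnames = as.character(arms$name),
                        seqlengths = as.integer(arms$length))
}

# Standard error of the mean; NA for n < 2.
semOf <- function(x) {
  n <- sum(!is.na(x))
  if (n < 2L) return(NA_real_)
  stats::sd(x, na.rm = TRUE) / sqrt(n)
}

checkArmTable <- function(arms) {
  need <- c("name", "length", "telomere_at_start", "pericentric_border",
            "is_chr4")
  miss <- setdiff(need, names(arms))
  if (length(miss))
    stop("arm table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(arms) == 0L) stop("arm table is empty")
  if (anyDuplicated(arms$name)) stop("duplicated arm names in arm table")
  if (any(arms$length <= 0)) stop("arm lengths must be > 0")
  if (any(arms$pericentric_border <= 0 | arms$pericentric_border > arms$length))
    stop("pericentric_border must lie in (0, arm length]")
  invisible(arms)
}
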