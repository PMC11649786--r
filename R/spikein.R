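#' Compute per-sample spike-in scaling factors
#'
#' Exogenous spike-in read counts (e.g. reads uniquely mapped to the
#' E. coli K-12 genome) are turned into per-sample scaling factors within
#' each batch: `factor = min(batch counts) / sample count`, so the
#' batch-minimum sample has factor exactly 1 and every other sample is
#' scaled down (never up), mirroring read downsampling of alignments.
#'
#' @param table Data frame with columns `sample_id`, `batch`,
#'   `spike_count` (non-negative integers).
#' @return The input with an added `factor` column (0 < factor <= 1).
#' @export
compute_scaling_factors <- function(table) {
  req <- c("sample_id", "batch", "spike_count")
  if (!all(req %in% names(table))) {
    stop("table must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(paste(table$batch, table$sample_id)))
    stop("duplicate sample_id within a batch")
  zero <- table$spike_count <= 0
  if (any(zero)) {
    stop("cannot normalize sample(s) with zero spike-in count: ",
         paste(table$sample_id[zero], collapse = ", "))
  }
  out <- as.data.frame(table)[, req]
  out$factor <- stats::ave(as.numeric(out$spike_count), out$batch,
                           FUN = function(x) min(x) / x)
  out
}

#' Scale a count/coverage signal by a spike-in factor
#'
#' `mode = "expected"` multiplies the signal deterministically.
#' `mode = "thinning"` keeps each count unit independently with
#' probability `factor` (binomial thinning), emulating read downsampling;
#' it requires non-negative integer counts and is reproducible under
#' `seed`.
#'
#' @param signal Numeric vector of per-interval counts or coverage.
#' @param factor Scaling factor in (0, 1].
#' @param mode `"expected"` or `"thinning"`.
#' @param seed Integer seed used for thinning.
#' @return Scaled signal vector.
#' @export
apply_scaling <- function(signal, factor, mode = c("expected", "thinning"),
                          seed = 1L) {
  mode <- match.arg(mode)
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0 || factor > 1)
    stop("factor must be a single value in (0, 1]")
  if (mode == "expected") return(signal * factor)
  if (any(signal < 0) || any(signal != round(signal)))
    stop("thinning requires non-negative integer counts")
  if (factor == 1) return(signal)
  withr::with_seed(seed,
    stats::rbinom(length(signal), size = as.integer(round(signal)), prob = factor))
}
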