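#' Read a bedGraph coverage track
#'
#' bedGraph semantics: piecewise-constant non-negative signal over
#' 0-based half-open intervals; positions without a record read as 0.
#'
#' @param stream Path or character vector of bedGraph lines.
#' @return A `CoverageTrack`: per-chromosome sorted interval table.
#' @export
read_bedgraph <- function(stream) {
  lines <- if (length(stream) == 1L && !grepl("[\t\n ]", stream) &&
               file.exists(stream)) readLines(stream) else
    unlist(strsplit(stream, "\n", fixed = TRUE), use.names = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  rows <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(rows) < 4L)) stop("bedGraph record with fewer than 4 columns")
  dt <- data.table::data.table(
    chrom = vapply(rows, `[`, character(1), 1L),
    start = as.integer(vapply(rows, `[`, character(1), 2L)),
    end = as.integer(vapply(rows, `[`, character(1), 3L)),
    value = as.numeric(vapply(rows, `[`, character(1), 4L))
  )
  if (anyNA(dt$start) || anyNA(dt$end) || anyNA(dt$value))
    stop("non-numeric field in bedGraph")
  coverage_track(dt)
}

#' Construct a coverage track from an interval table
#'
#' @param intervals Data frame with `chrom`, `start`, `end`, `value`;
#'   intervals within a chromosome must not overlap.
#' @return An object of class `CoverageTrack`.
#' @export
coverage_track <- function(intervals) {
  dt <- data.table::as.data.table(intervals)[, c("chrom", "start", "end", "value")]
  data.table::setorder(dt, chrom, start)
  ov <- dt[, any(start[-1L] < end[-.N]), by = "chrom"]$V1
  if (any(ov)) stop("overlapping intervals within a chromosome")
  if (any(dt$value < 0)) stop("negative coverage value")
  structure(list(intervals = dt), class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack: %d interval(s) on %d chromosome(s)\n",
              nrow(x$intervals), length(unique(x$intervals$chrom))))
  invisible(x)
}

# integral of the track over [s, e) on one chromosome (vectorized over s/e)
.track_integral <- function(track, chr, s, e) {
  iv <- as.data.frame(track$intervals)
  iv <- iv[iv$chrom == chr, , drop = FALSE]
  if (nrow(iv) == 0L) return(numeric(length(s)))
  # cumulative area at interval breakpoints
  cum <- c(0, cumsum(as.numeric(iv$end - iv$start) * iv$value))
  at <- function(p) {
    # area of track from -Inf to position p
    i <- findInterval(p, iv$start)
    a <- cum[pmax(i, 0L) + 1L]
    inside <- i >= 1L & p < iv$end[pmax(i, 1L)] & p >= iv$start[pmax(i, 1L)]
    a[inside] <- cum[i[inside]] +
      (p[inside] - iv$start[i[inside]]) * iv$value[i[inside]]
    a
  }
  at(e) - at(s)
}

#' Partition two peak sets into A-only, B-only and co-bound
#'
#' Peaks are co-bound when their intersection spans at least
#' `min_overlap` bp (half-open intervals: `[100,200)` and `[200,300)` do
#' not overlap). Each peak is counted once even if it overlaps several
#' peaks in the other set; co-bound regions are the merged unions of all
#' overlapping pairs, so the partition is symmetric in A and B.
#'
#' @param setA,setB `PeakSet` objects.
#' @param min_overlap Minimum intersection length in bp (default 1).
#' @return List with counts `n_a_only`, `n_b_only`, `n_co_bound`, index
#'   vectors `a_only`/`b_only` and a data frame `co_bound` of merged
#'   regions (`chrom`, `start`, `end`).
#' @export
overlap_peak_sets <- function(setA, setB, min_overlap = 1L) {
  stopifnot(inherits(setA, "PeakSet"), inherits(setB, "PeakSet"))
  grA <- .peaks_gr(setA$peaks)
  grB <- .peaks_gr(setB$peaks)
  hits <- GenomicRanges::findOverlaps(grA, grB, minoverlap = min_overlap)
  qa <- unique(S4Vectors::queryHits(hits))
  qb <- unique(S4Vectors::subjectHits(hits))
  a_only <- setdiff(seq_along(grA), qa)
  b_only <- setdiff(seq_along(grB), qb)
  co <- if (length(hits)) {
    merged <- GenomicRanges::reduce(c(grA[qa], grB[qb]))
    # keep only merged regions that contain an actual overlapping pair
    merged[GenomicRanges::countOverlaps(merged, grA[qa]) > 0 &
             GenomicRanges::countOverlaps(merged, grB[qb]) > 0]
  } else GenomicRanges::GRanges()
  co_df <- data.frame(chrom = as.character(GenomicRanges::seqnames(co)),
                      start = GenomicRanges::start(co) - 1L,
                      end = GenomicRanges::end(co))
  list(n_a_only = length(a_only), n_b_only = length(b_only),
       n_co_bound = length(co), a_only = a_only, b_only = b_only,
       co_bound = co_df)
}

.peaks_gr <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(peaks$start + 1L, peaks$end))
}

#' Genes with a peak anchor in their promoter window
#'
#' @param peaks A `PeakSet`.
#' @param genes Named list of representative `TranscriptModel`s.
#' @param window `c(up, down)` bp around the TSS, strand-aware
#'   (default 1000/1000).
#' @return Character vector of bound gene ids.
#' @export
promoter_bound_genes <- function(peaks, genes, window = c(1000L, 1000L)) {
  stopifnot(inherits(peaks, "PeakSet"))
  pk <- peaks$peaks
  if (nrow(pk) == 0L || length(genes) == 0L) return(character(0))
  anchor <- peak_anchors(pk)
  bound <- vapply(genes, function(m) {
    sgn <- if (m$strand == "+") 1L else -1L
    d <- sgn * (anchor - m$tss)
    any(pk$chrom == m$chrom & d >= -window[1L] & d <= window[2L])
  }, logical(1))
  names(genes)[bound]
}

#' Compare peaks-per-gene burden between two gene groups
#'
#' Reports each group's median peak count and a two-sided Mann-Whitney
#' (Wilcoxon rank-sum) p-value with normal approximation and tie
#' correction for a location difference.
#'
#' @param groupA,groupB Disjoint character vectors of gene ids.
#' @param counts Named peaks-per-gene vector from [peaks_per_gene()];
#'   genes absent from `counts` are dropped.
#' @return List with `median_a`, `median_b`, `p_value`, `n_a`, `n_b`.
#' @export
compare_peak_burden <- function(groupA, groupB, counts) {
  if (length(intersect(groupA, groupB)) > 0L) stop("groups must be disjoint")
  xa <- counts[intersect(groupA, names(counts))]
  xb <- counts[intersect(groupB, names(counts))]
  if (length(xa) == 0L || length(xb) == 0L)
    stop("each group needs at least one gene with a count")
  wt <- stats::wilcox.test(xa, xb, alternative = "two.sided",
                           exact = FALSE, correct = TRUE)
  list(median_a = stats::median(xa), median_b = stats::median(xb),
       p_value = unname(wt$p.value), n_a = length(xa), n_b = length(xb))
}

#' Anchor-centered coverage signal matrix and mean profile
#'
#' For each anchor, mean coverage is computed in fixed-width bins
#' spanning `[-flank, +flank)` around the anchor position; minus-strand
#' anchor rows are reversed so column 1 is always 5'/upstream. Anchors on
#' chromosomes absent from the track give zero-filled rows (counted in
#' the `n_missing_chrom` attribute).
#'
#' @param track A `CoverageTrack`.
#' @param anchors Data frame with `chrom`, `pos` (0-based), and
#'   optionally `strand` (`+` assumed when absent).
#' @param flank Half-window in bp (default 4000); must be a multiple of
#'   `bin_width`.
#' @param bin_width Bin width in bp (default 50).
#' @return List with `matrix` (anchors x bins) and `profile` (column
#'   means); the matrix carries attribute `n_missing_chrom`.
#' @export
signal_matrix <- function(track, anchors, flank = 4000L, bin_width = 50L) {
  stopifnot(inherits(track, "CoverageTrack"))
  if (flank %% bin_width != 0L) stop("flank must be a multiple of bin_width")
  anchors <- as.data.frame(anchors)
  if (is.null(anchors$strand)) anchors$strand <- "+"
  nb <- as.integer(2L * flank / bin_width)
  edges_rel <- seq(-flank, flank, by = bin_width)
  mat <- matrix(0, nrow = nrow(anchors), ncol = nb)
  have <- unique(track$intervals$chrom)
  missing <- 0L
  for (i in seq_len(nrow(anchors))) {
    cm <- anchors$chrom[i]
    if (!(cm %in% have)) { missing <- missing + 1L; next }
    edges <- anchors$pos[i] + edges_rel
    v <- .track_integral(track, cm, edges[-length(edges)], edges[-1L]) / bin_width
    if (anchors$strand[i] == "-") v <- rev(v)
    mat[i, ] <- v
  }
  if (missing > 0L)
    warning(missing, " anchor(s) on chromosomes absent from the track")
  attr(mat, "n_missing_chrom") <- missing
  list(matrix = mat, profile = colMeans(mat))
}
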