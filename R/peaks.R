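#' Construct a peak set
#'
#' @param peaks Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `name`, `score`, `summit_offset`.
#' @param label Condition label (non-empty string).
#' @return An object of class `PeakSet`.
#' @export
peak_set <- function(peaks, label) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("label must be a non-empty string")
  peaks <- as.data.frame(peaks)
  for (col in c("name", "score", "summit_offset")) {
    if (is.null(peaks[[col]])) peaks[[col]] <- NA
  }
  if (nrow(peaks) && any(peaks$end <= peaks$start)) stop("peak with end <= start")
  so <- peaks$summit_offset
  bad <- !is.na(so) & (so < 0 | so >= peaks$end - peaks$start)
  if (any(bad)) stop("summit_offset outside peak interval")
  structure(list(label = label, peaks = peaks), class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet '%s': %d peak(s)\n", x$label, nrow(x$peaks)))
  invisible(x)
}

#' Read peaks from BED or narrowPeak text
#'
#' BED records need at least 3 whitespace-delimited columns; narrowPeak
#' needs 10, with column 10 as the summit offset from `start` (`-1`
#' meaning absent). Records with `end <= start` are rejected with their
#' line numbers (warning + `rejected` attribute on the result's peak
#' table); a non-integer coordinate is a hard parse error.
#'
#' @param stream Path to a file or a character vector of lines.
#' @param dialect `"bed"` or `"narrowPeak"`.
#' @param label Condition label for the resulting set.
#' @return A `PeakSet`; attribute `rejected` lists rejected line numbers.
#' @export
read_peaks <- function(stream, dialect = c("bed", "narrowPeak"),
                       label = "peaks") {
  dialect <- match.arg(dialect)
  lines <- if (length(stream) == 1L && !grepl("[\t\n ]", stream) &&
               file.exists(stream)) readLines(stream) else
    unlist(strsplit(stream, "\n", fixed = TRUE), use.names = FALSE)
  idx <- which(nzchar(lines) & !grepl("^(#|track|browser)", lines))
  min_cols <- if (dialect == "bed") 3L else 10L
  rows <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(rows)
  if (any(nf < min_cols)) {
    stop("record with fewer than ", min_cols, " columns at line ",
         idx[which(nf < min_cols)[1L]])
  }
  chrom <- vapply(rows, `[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(rows, `[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(rows, `[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("non-integer coordinate at line ", idx[which(is.na(start) | is.na(end))[1L]])
  }
  name <- if (all(nf >= 4L)) vapply(rows, `[`, character(1), 4L) else NA_character_
  score <- if (all(nf >= 5L))
    suppressWarnings(as.numeric(vapply(rows, `[`, character(1), 5L))) else NA_real_
  summit <- if (dialect == "narrowPeak") {
    s <- as.integer(vapply(rows, `[`, character(1), 10L))
    ifelse(s < 0L, NA_integer_, s)
  } else NA_integer_
  ok <- end > start
  rejected <- idx[!ok]
  if (length(rejected)) {
    warning(length(rejected), " record(s) with end <= start rejected (line ",
            paste(rejected, collapse = ", "), ")")
  }
  out <- peak_set(data.frame(chrom = chrom, start = start, end = end,
                             name = name, score = score,
                             summit_offset = summit)[ok, , drop = FALSE],
                  label = label)
  attr(out, "rejected") <- rejected
  out
}

# Anchor point of each peak: summit when present, interval midpoint else.
peak_anchors <- function(peaks) {
  mid <- peaks$start + (peaks$end - peaks$start) %/% 2L
  ifelse(is.na(peaks$summit_offset), mid, peaks$start + peaks$summit_offset)
}

.models_table <- function(models) {
  data.frame(
    gene_id = vapply(models, `[[`, character(1), "gene_id"),
    chrom = vapply(models, `[[`, character(1), "chrom"),
    strand = vapply(models, `[[`, character(1), "strand"),
    tss = vapply(models, `[[`, integer(1), "tss"),
    span_start = vapply(models, function(m) m$exons[1L, 1L], integer(1)),
    span_end = vapply(models, function(m) m$exons[nrow(m$exons), 2L], integer(1)),
    row.names = NULL
  )
}

# 3' end position (0-based) of a transcript in transcript orientation
.tes <- function(m) if (m$strand == "+") m$exons[nrow(m$exons), 2L] - 1L else m$exons[1L, 1L]

# which anchors fall inside any interval of the given feature matrix set
.anchor_in_feature <- function(chrom_a, anchor, models, feat) {
  hit <- logical(length(anchor))
  for (m in models) {
    iv <- m[[feat]]
    if (nrow(iv) == 0L) next
    same <- chrom_a == m$chrom
    if (!any(same)) next
    for (k in seq_len(nrow(iv))) {
      hit <- hit | (same & anchor >= iv[k, 1L] & anchor < iv[k, 2L])
    }
  }
  hit
}

#' Annotate peaks to genomic features and genes
#'
#' Each peak is located by its anchor (summit when present, else
#' midpoint) and assigned exactly one feature class by the precedence
#' `promoter > utr5 > utr3 > cds_exon > intron > tts > intergenic`,
#' evaluated against the representative transcripts. The promoter window
#' is strand-aware around the TSS; the `tts` window likewise around the
#' transcript 3' end. The assigned gene is the one whose TSS is nearest
#' to the anchor; intergenic peaks farther than `tss_radius` from every
#' TSS stay unassigned (`NA`).
#'
#' @param peaks A `PeakSet`.
#' @param genes Named list of representative `TranscriptModel`s
#'   (one per gene, from [select_representative_transcripts()]).
#' @param promoter_window `c(up, down)` bp around the TSS (default
#'   1000/1000).
#' @param tts_window `c(up, down)` bp around the transcript end
#'   (default 1000/1000).
#' @param tss_radius Maximum distance for gene assignment of intergenic
#'   peaks (default 1e5 bp).
#' @return Data frame with one row per peak: `chrom`, `anchor`,
#'   `feature_class`, `gene_id`, `distance_to_tss` (signed bp, positive
#'   downstream of the TSS in transcript orientation).
#' @export
annotate_peaks <- function(peaks, genes, promoter_window = c(1000L, 1000L),
                           tts_window = c(1000L, 1000L), tss_radius = 1e5) {
  stopifnot(inherits(peaks, "PeakSet"))
  if (length(genes) == 0L) stop("empty annotation")
  pk <- peaks$peaks
  anchor <- peak_anchors(pk)
  gt <- .models_table(genes)
  tes <- vapply(genes, .tes, integer(1))

  n <- length(anchor)
  is_prom <- logical(n); is_tts <- logical(n); in_span <- logical(n)
  for (j in seq_len(nrow(gt))) {
    same <- pk$chrom == gt$chrom[j]
    if (!any(same)) next
    sgn <- if (gt$strand[j] == "+") 1L else -1L
    d_tss <- sgn * (anchor - gt$tss[j])
    is_prom <- is_prom | (same & d_tss >= -promoter_window[1L] & d_tss <= promoter_window[2L])
    d_tes <- sgn * (anchor - tes[j])
    is_tts <- is_tts | (same & d_tes >= -tts_window[1L] & d_tes <= tts_window[2L])
    in_span <- in_span | (same & anchor >= gt$span_start[j] & anchor < gt$span_end[j])
  }
  in_u5 <- .anchor_in_feature(pk$chrom, anchor, genes, "utr5")
  in_u3 <- .anchor_in_feature(pk$chrom, anchor, genes, "utr3")
  in_cds <- .anchor_in_feature(pk$chrom, anchor, genes, "cds")
  in_exon <- .anchor_in_feature(pk$chrom, anchor, genes, "exons")
  in_cds_exon <- in_cds | (in_exon & !in_u5 & !in_u3)
  cls <- rep("intergenic", n)
  cls[is_tts] <- "tts"
  cls[in_span & !in_exon] <- "intron"
  cls[in_cds_exon] <- "cds_exon"
  cls[in_u3] <- "utr3"
  cls[in_u5] <- "utr5"
  cls[is_prom] <- "promoter"

  gene_id <- rep(NA_character_, n)
  dist <- rep(NA_integer_, n)
  for (cm in unique(pk$chrom)) {
    gi <- which(gt$chrom == cm)
    ai <- which(pk$chrom == cm)
    if (length(gi) == 0L || length(ai) == 0L) next
    dd <- abs(outer(anchor[ai], gt$tss[gi], `-`))
    best <- max.col(-dd, ties.method = "first")
    gene_id[ai] <- gt$gene_id[gi][best]
    sgn <- ifelse(gt$strand[gi][best] == "+", 1L, -1L)
    dist[ai] <- sgn * (anchor[ai] - gt$tss[gi][best])
    mind <- dd[cbind(seq_along(ai), best)]
    far <- cls[ai] == "intergenic" & mind > tss_radius
    gene_id[ai][far] <- NA_character_
    dist[ai][far] <- NA_integer_
  }
  data.frame(chrom = pk$chrom, anchor = anchor, feature_class = cls,
             gene_id = gene_id, distance_to_tss = dist,
             stringsAsFactors = FALSE)
}

#' Count peaks per gene
#'
#' Counts non-intergenic peaks per assigned gene; the counts sum to the
#' number of non-intergenic, gene-assigned peaks.
#'
#' @param annotation Output of [annotate_peaks()].
#' @return Named integer vector `gene_id -> peak count`.
#' @export
peaks_per_gene <- function(annotation) {
  keep <- annotation$feature_class != "intergenic" & !is.na(annotation$gene_id)
  if (!any(keep)) return(stats::setNames(integer(0), character(0)))
  tab <- table(annotation$gene_id[keep])
  stats::setNames(as.integer(tab), names(tab))
}

#' Genes containing at least one m6A peak
#'
#' @param counts Named peaks-per-gene vector from [peaks_per_gene()].
#' @return Character vector of m6A-positive gene ids.
#' @export
m6a_positive_genes <- function(counts) names(counts)[counts >= 1L]

#' Permutation test for a peak-count difference
#'
#' Tests whether two conditions' total peak counts differ. The statistic
#' is `|nA - nB|`; the null reassigns each of the `nA + nB` pooled peaks
#' to a condition with probability 1/2, and the p-value uses the add-one
#' correction `p = (1 + #{perm >= obs}) / (n_perm + 1)` so it is never 0.
#'
#' @param setA,setB `PeakSet` objects (or bare counts via `nA`/`nB`).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List with `statistic` (observed |nA-nB|), `p_value`, `nA`, `nB`.
#' @export
permutation_test_counts <- function(setA, setB, n_perm = 1000L, seed = 1L) {
  nA <- if (inherits(setA, "PeakSet")) nrow(setA$peaks) else as.integer(setA)
  nB <- if (inherits(setB, "PeakSet")) nrow(setB$peaks) else as.integer(setB)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  n <- nA + nB
  if (n == 0L) stop("both peak sets are empty")
  obs <- abs(nA - nB)
  perm <- withr::with_seed(seed, {
    x <- stats::rbinom(n_perm, size = n, prob = 0.5)
    abs(2L * x - n)
  })
  list(statistic = obs,
       p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
       nA = nA, nB = nB)
}

#' Filter a differential-expression table to significant genes
#'
#' Keeps genes with `|log2fc|` strictly greater than `lfc_threshold` and
#' adjusted p strictly below `padj_threshold` (defaults 1 and 0.01).
#'
#' @param table Data frame with columns `gene_id`, `log2fc`, `padj`.
#' @param lfc_threshold,padj_threshold Positive thresholds.
#' @return Character vector of retained gene ids.
#' @export
filter_deg <- function(table, lfc_threshold = 1, padj_threshold = 0.01) {
  req <- c("gene_id", "log2fc", "padj")
  if (!all(req %in% names(table)))
    stop("table must have columns: ", paste(req, collapse = ", "))
  if (lfc_threshold <= 0 || padj_threshold <= 0) stop("thresholds must be > 0")
  keep <- abs(table$log2fc) > lfc_threshold & table$padj < padj_threshold
  table$gene_id[keep & !is.na(keep)]
}

#' Cardinalities of every region of a Venn diagram
#'
#' For `n >= 2` named sets, returns the size of each of the `2^n - 1`
#' exclusive membership regions; the disjoint regions sum to the size of
#' the union.
#'
#' @param sets Named list of >= 2 character vectors.
#' @return Data frame with logical membership columns (one per set) and
#'   `count`, one row per non-empty membership combination.
#' @export
intersect_gene_sets <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(combos) <- names(sets)
  combos <- combos[rowSums(combos) > 0L, , drop = FALSE]
  combos$count <- apply(combos, 1L, function(row) {
    if (length(universe) == 0L) return(0L)
    sum(apply(member, 1L, function(m) all(m == row)))
  })
  rownames(combos) <- NULL
  combos
}
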