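#' Parse a GTF annotation into transcript models
#'
#' Reads GENCODE-style GTF (tab-separated, 1-based inclusive coordinates)
#' and builds one [`TranscriptModel`][transcript_model] per transcript that
#' has at least one exon. Coordinates are converted to the package-internal
#' 0-based half-open convention. Features lacking a `transcript_id`
#' attribute (e.g. bare `gene` rows) are ignored.
#'
#' Recognised feature types are `exon`, `CDS`, `five_prime_utr` and
#' `three_prime_utr`; everything else is skipped. Records with an unknown
#' strand symbol are rejected and reported via a warning; their line
#' numbers are returned in the `rejected` attribute.
#'
#' @param gtf Path to a GTF file, or a character vector of GTF lines.
#' @return A named list of `TranscriptModel` objects (names are
#'   transcript ids), with attribute `rejected` holding line numbers of
#'   rejected records.
#' @export
parse_annotation <- function(gtf) {
  lines <- if (length(gtf) == 1L && !grepl("\t", gtf) && file.exists(gtf)) {
    readLines(gtf)
  } else {
    unlist(strsplit(gtf, "\n", fixed = TRUE), use.names = FALSE)
  }
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(structure(list(), rejected = integer(0)))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    stop("malformed GTF line (expected 9 tab-separated columns) at line ",
         idx[which(nf != 9L)[1L]])
  }
  m <- matrix(unlist(fields, use.names = FALSE), ncol = 9L, byrow = TRUE)
  feature <- m[, 3L]
  use <- feature %in% c("exon", "CDS", "five_prime_utr", "three_prime_utr")
  strand <- m[, 7L]
  bad_strand <- use & !(strand %in% c("+", "-"))
  rejected <- idx[bad_strand]
  if (length(rejected)) {
    warning(length(rejected), " record(s) with unknown strand rejected (line ",
            paste(rejected, collapse = ", "), ")")
  }
  use <- use & !bad_strand
  if (!any(use)) return(structure(list(), rejected = rejected))

  attrs <- m[use, 9L]
  tid <- .gtf_attr(attrs, "transcript_id")
  gid <- .gtf_attr(attrs, "gene_id")
  has_tid <- !is.na(tid)
  dt <- data.table::data.table(
    chrom = m[use, 1L][has_tid],
    feature = feature[use][has_tid],
    # GTF 1-based inclusive -> 0-based half-open
    start = as.integer(m[use, 4L][has_tid]) - 1L,
    end = as.integer(m[use, 5L][has_tid]),
    strand = strand[use][has_tid],
    gene_id = gid[has_tid],
    transcript_id = tid[has_tid]
  )
  if (anyNA(dt$start) || anyNA(dt$end)) stop("non-integer coordinate in GTF")

  models <- lapply(split(dt, by = "transcript_id", sorted = TRUE), function(d) {
    ex <- d[d$feature == "exon", ]
    if (nrow(ex) == 0L) return(NULL)
    transcript_model(
      gene_id = d$gene_id[1L], transcript_id = d$transcript_id[1L],
      chrom = d$chrom[1L], strand = d$strand[1L],
      exons = .as_ivmat(ex$start, ex$end),
      cds = .feat_ivs(d, "CDS"),
      utr5 = .feat_ivs(d, "five_prime_utr"),
      utr3 = .feat_ivs(d, "three_prime_utr")
    )
  })
  models <- Filter(Negate(is.null), models)
  structure(models, rejected = rejected)
}

.gtf_attr <- function(attrs, key) {
  pat <- paste0(key, "[ =]+\"?([^\";]+)\"?")
  m <- regexec(pat, attrs)
  vapply(regmatches(attrs, m), function(x) if (length(x) >= 2L) x[2L] else NA_character_,
         character(1))
}

.as_ivmat <- function(start, end) {
  iv <- cbind(start = as.integer(start), end = as.integer(end))
  iv[order(iv[, 1L]), , drop = FALSE]
}

.feat_ivs <- function(d, feat) {
  f <- d[d$feature == feat, ]
  .as_ivmat(f$start, f$end)
}

#' Construct a transcript model
#'
#' Container for one transcript: strand, exon structure and (possibly
#' empty) CDS/UTR interval sets, all 0-based half-open and sorted by
#' genomic coordinate. The TSS is the 5'-most exon boundary in transcript
#' orientation: the first exon base on `+`, the last exon base on `-`.
#'
#' @param gene_id,transcript_id,chrom,strand Identifiers; strand is
#'   `"+"` or `"-"`.
#' @param exons,cds,utr5,utr3 Two-column integer matrices
#'   (`start`, `end`), 0-based half-open. UTR/CDS may have zero rows.
#' @return An object of class `TranscriptModel`.
#' @export
transcript_model <- function(gene_id, transcript_id, chrom, strand,
                             exons, cds = NULL, utr5 = NULL, utr3 = NULL) {
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1L)
  empty <- .as_ivmat(integer(0), integer(0))
  if (is.null(cds)) cds <- empty
  if (is.null(utr5)) utr5 <- empty
  if (is.null(utr3)) utr3 <- empty
  exons <- .as_ivmat(exons[, 1L], exons[, 2L])
  if (any(exons[, 2L] <= exons[, 1L])) stop("empty exon interval")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("overlapping exons in transcript ", transcript_id)
  tss <- unname(if (strand == "+") exons[1L, 1L] else exons[nrow(exons), 2L] - 1L)
  structure(
    list(gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
         strand = strand, exons = exons, cds = cds, utr5 = utr5,
         utr3 = utr3, tss = tss),
    class = "TranscriptModel"
  )
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (%s) %s:%d-%d [%s], %d exon(s)\n",
              x$transcript_id, x$gene_id, x$chrom,
              x$exons[1L, 1L], x$exons[nrow(x$exons), 2L], x$strand,
              nrow(x$exons)))
  invisible(x)
}

exon_length <- function(model) sum(model$exons[, 2L] - model$exons[, 1L])

#' Select one representative transcript per gene
#'
#' The representative is the isoform with the largest summed exon length
#' (not genomic span); ties are broken by the lexicographically smallest
#' `transcript_id`, so the result is independent of input order.
#'
#' @param models List of `TranscriptModel` objects.
#' @return Named list mapping `gene_id` to its representative
#'   `TranscriptModel`, genes sorted by id.
#' @export
select_representative_transcripts <- function(models) {
  if (length(models) == 0L) return(list())
  gid <- vapply(models, `[[`, character(1), "gene_id")
  len <- vapply(models, exon_length, numeric(1))
  tid <- vapply(models, `[[`, character(1), "transcript_id")
  picks <- lapply(split(seq_along(models), gid), function(i) {
    i <- i[order(-len[i], tid[i])]
    models[[i[1L]]]
  })
  picks[order(names(picks))]
}

#' Build a metagene coordinate model
#'
#' Defines the composite metagene axis used for positional m6A analysis:
#' a fixed-width upstream flank, scaled 5'UTR / CDS / 3'UTR segments, and
#' a fixed-width downstream flank. Region bins are per-transcript scaled;
#' flank bins are fixed at `flank_bin_bp` base pairs so flanks remain
#' comparable across transcripts.
#'
#' @param bins_utr5,bins_cds,bins_utr3 Bin counts per scaled region
#'   (defaults 100 each).
#' @param flank_bp Flank length in bp on each side (default 1000); 0
#'   disables flanks.
#' @param flank_bin_bp Width of one flank bin in bp (default 20, i.e. 50
#'   bins per 1 kb flank).
#' @return An object of class `MetageneModel` with per-region bin counts,
#'   cumulative `region_boundaries` and `total_bins`.
#' @export
build_metagene_model <- function(bins_utr5 = 100L, bins_cds = 100L,
                                 bins_utr3 = 100L, flank_bp = 1000L,
                                 flank_bin_bp = 20L) {
  if (bins_utr5 < 1L || bins_cds < 1L || bins_utr3 < 1L)
    stop("region bin counts must be >= 1")
  if (flank_bp < 0L) stop("flank_bp must be >= 0")
  if (flank_bin_bp < 1L) stop("flank_bin_bp must be >= 1")
  bins_flank <- if (flank_bp == 0L) 0L else as.integer(ceiling(flank_bp / flank_bin_bp))
  counts <- c(flank5 = bins_flank, utr5 = as.integer(bins_utr5),
              cds = as.integer(bins_cds), utr3 = as.integer(bins_utr3),
              flank3 = bins_flank)
  structure(
    list(bins = counts, flank_bp = as.integer(flank_bp),
         region_boundaries = cumsum(counts), total_bins = sum(counts)),
    class = "MetageneModel"
  )
}

#' @export
print.MetageneModel <- function(x, ...) {
  cat("MetageneModel:", paste(names(x$bins), x$bins, sep = "=", collapse = " "),
      sprintf("(total %d bins, flank %d bp)\n", x$total_bins, x$flank_bp))
  invisible(x)
}

# Spliced transcript-relative offset (0-based from the 5' end in transcript
# orientation) of a genomic position, or NA when intronic/outside exons.
.spliced_offset <- function(pos, model) {
  ex <- model$exons
  hit <- which(pos >= ex[, 1L] & pos < ex[, 2L])
  if (length(hit) == 0L) return(NA_integer_)
  w <- ex[, 2L] - ex[, 1L]
  off_plus <- (if (hit > 1L) sum(w[seq_len(hit - 1L)]) else 0L) + (pos - ex[hit, 1L])
  if (model$strand == "+") off_plus else sum(w) - 1L - off_plus
}

# Region segmentation of the spliced transcript, in transcript orientation.
# Transcripts with no annotated CDS are treated as all-CDS (body) so they
# still project; missing UTRs get zero length.
.region_lengths <- function(model) {
  L <- exon_length(model)
  u5 <- sum(model$utr5[, 2L] - model$utr5[, 1L])
  cds <- sum(model$cds[, 2L] - model$cds[, 1L])
  u3 <- sum(model$utr3[, 2L] - model$utr3[, 1L])
  if (cds == 0L && u5 == 0L && u3 == 0L) {
    c(utr5 = 0L, cds = L, utr3 = 0L)
  } else {
    # any exon sequence not covered by the annotated features is folded
    # into the 3'UTR segment so offsets always land in a region
    c(utr5 = u5, cds = cds, utr3 = L - u5 - cds)
  }
}

#' Project a genomic position onto the metagene axis
#'
#' Maps a single genomic point to a fractional metagene coordinate in
#' `[0, total_bins)`: flank positions use fixed-width bins, exonic
#' positions use the spliced transcript offset linearly rescaled within
#' the matching 5'UTR/CDS/3'UTR segment. Minus-strand transcripts are
#' mirrored so coordinate 0 is always the 5' flank end. Intronic
#' positions and positions outside flank and exons return `NA`.
#'
#' @param position 0-based genomic position (single integer).
#' @param model A `TranscriptModel`.
#' @param mg A `MetageneModel`.
#' @return Fractional bin coordinate, or `NA_real_`.
#' @export
project_to_metagene <- function(position, model, mg) {
  b <- mg$bins
  off0 <- c(0, cumsum(b))[seq_along(b)]  # bin offset of each region start
  names(off0) <- names(b)
  so <- .spliced_offset(position, model)
  if (!is.na(so)) {
    rl <- .region_lengths(model)
    if (so < rl["utr5"]) {
      reg <- "utr5"; rel <- so
    } else if (so < rl["utr5"] + rl["cds"]) {
      reg <- "cds"; rel <- so - rl["utr5"]
    } else {
      reg <- "utr3"; rel <- so - rl["utr5"] - rl["cds"]
    }
    if (rl[reg] == 0L) return(NA_real_)
    return(unname(off0[reg] + (rel / rl[reg]) * b[reg]))
  }
  if (mg$flank_bp == 0L) return(NA_real_)
  ex <- model$exons
  t_start <- ex[1L, 1L]; t_end <- ex[nrow(ex), 2L]
  if (model$strand == "+") {
    d5 <- t_start - 1L - position   # 0 for the base just upstream of TSS
    d3 <- position - t_end          # 0 for the base just downstream
  } else {
    d5 <- position - t_end
    d3 <- t_start - 1L - position
  }
  if (d5 >= 0L && d5 < mg$flank_bp) {
    # flank5 axis runs 5'-distal -> TSS; d5 = 0 is adjacent to the TSS
    rel <- mg$flank_bp - 1L - d5
    return(unname(off0["flank5"] + (rel / mg$flank_bp) * b["flank5"]))
  }
  if (d3 >= 0L && d3 < mg$flank_bp) {
    return(unname(off0["flank3"] + (d3 / mg$flank_bp) * b["flank3"]))
  }
  NA_real_
}

# Region band (name) of a metagene coordinate.
metagene_region <- function(coord, mg) {
  if (is.na(coord)) return(NA_character_)
  names(mg$bins)[findInterval(coord, c(0, cumsum(mg$bins)), rightmost.closed = TRUE)]
}
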