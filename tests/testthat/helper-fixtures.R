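# Shared fixtures and independent brute-force oracles.
# Oracles deliberately use a different computational route than the
# implementation (explicit base-by-base walks, all-pairs scans).

# A hand-laid 3-exon transcript: exons (0-based half-open)
# [1000,1200) [1500,1800) [2100,2500); 5'UTR = first 150 spliced bases,
# CDS = next 450, 3'UTR = last 300 (total spliced 900).
toy_transcript <- function(strand = "+", chrom = "chrT") {
  exons <- cbind(start = c(1000L, 1500L, 2100L),
                 end = c(1200L, 1800L, 2500L))
  # enumerate spliced bases in transcript orientation, slice regions,
  # then convert back to genomic interval runs
  bases <- unlist(lapply(seq_len(3), function(i) exons[i, 1]:(exons[i, 2] - 1)))
  if (strand == "-") bases <- rev(bases)
  runs <- function(b) {
    b <- sort(b)
    brk <- c(0, which(diff(b) != 1), length(b))
    t(vapply(seq_len(length(brk) - 1), function(i)
      c(b[brk[i] + 1], b[brk[i + 1]] + 1L), numeric(2)))
  }
  transcript_model("gToy", paste0("tToy", strand), chrom, strand,
                   exons = exons,
                   utr5 = runs(bases[1:150]),
                   cds = runs(bases[151:600]),
                   utr3 = runs(bases[601:900]))
}

# Brute-force metagene projection: walks every transcript base (and the
# flanks) to build a genomic-position -> coordinate lookup.
oracle_project_lookup <- function(model, mg) {
  exons <- model$exons
  bases <- unlist(lapply(seq_len(nrow(exons)), function(i)
    exons[i, 1]:(exons[i, 2] - 1)))
  if (model$strand == "-") bases <- rev(bases)  # now 5' -> 3'
  u5 <- sum(model$utr5[, 2] - model$utr5[, 1])
  cd <- sum(model$cds[, 2] - model$cds[, 1])
  L <- length(bases)
  u3 <- L - u5 - cd
  b <- mg$bins
  off <- c(0, cumsum(b))
  coord <- numeric(L)
  for (i in seq_len(L)) {
    s <- i - 1
    if (s < u5) coord[i] <- off[2] + s / u5 * b[["utr5"]]
    else if (s < u5 + cd) coord[i] <- off[3] + (s - u5) / cd * b[["cds"]]
    else coord[i] <- off[4] + (s - u5 - cd) / u3 * b[["utr3"]]
  }
  lut <- stats::setNames(coord, bases)
  if (mg$flank_bp > 0) {
    fb <- mg$flank_bp
    tss <- model$tss
    tes <- if (model$strand == "+") exons[nrow(exons), 2] - 1 else exons[1, 1]
    step <- if (model$strand == "+") 1L else -1L
    up <- tss - step * seq_len(fb)          # walking away 5'
    dn <- tes + step * seq_len(fb)          # walking away 3'
    cu <- off[1] + (fb - seq_len(fb)) / fb * b[["flank5"]]
    cd3 <- off[5] + (seq_len(fb) - 1) / fb * b[["flank3"]]
    keep_up <- !(up %in% bases)
    keep_dn <- !(dn %in% bases)
    lut <- c(lut, stats::setNames(cu[keep_up], up[keep_up]),
             stats::setNames(cd3[keep_dn], dn[keep_dn]))
  }
  lut
}

oracle_project <- function(pos, model, mg, lut = NULL) {
  if (is.null(lut)) lut <- oracle_project_lookup(model, mg)
  out <- unname(lut[as.character(pos)])
  out
}

# Brute-force peak classifier: per anchor, scans every gene and feature
# interval explicitly, then applies the class precedence.
oracle_classify <- function(chrom, anchor, genes,
                            promoter_window = c(1000, 1000),
                            tts_window = c(1000, 1000)) {
  in_any <- function(m, feat, a) {
    iv <- m[[feat]]
    nrow(iv) > 0 && any(a >= iv[, 1] & a < iv[, 2])
  }
  vapply(seq_along(anchor), function(i) {
    a <- anchor[i]
    flags <- c(promoter = FALSE, utr5 = FALSE, utr3 = FALSE,
               cds_exon = FALSE, intron = FALSE, tts = FALSE)
    for (m in genes) {
      if (m$chrom != chrom[i]) next
      sgn <- if (m$strand == "+") 1 else -1
      d <- sgn * (a - m$tss)
      if (d >= -promoter_window[1] && d <= promoter_window[2])
        flags["promoter"] <- TRUE
      tes <- if (m$strand == "+") m$exons[nrow(m$exons), 2] - 1 else m$exons[1, 1]
      dt <- sgn * (a - tes)
      if (dt >= -tts_window[1] && dt <= tts_window[2]) flags["tts"] <- TRUE
      if (in_any(m, "utr5", a)) flags["utr5"] <- TRUE
      if (in_any(m, "utr3", a)) flags["utr3"] <- TRUE
      in_ex <- in_any(m, "exons", a)
      if (in_any(m, "cds", a) ||
          (in_ex && !in_any(m, "utr5", a) && !in_any(m, "utr3", a)))
        flags["cds_exon"] <- TRUE
      span <- c(m$exons[1, 1], m$exons[nrow(m$exons), 2])
      if (a >= span[1] && a < span[2] && !in_ex) flags["intron"] <- TRUE
    }
    if (any(flags)) names(flags)[which(flags)[1]] else "intergenic"
  }, character(1))
}

# O(n^2) all-pairs overlap oracle
oracle_overlap <- function(pa, pb, min_overlap = 1) {
  hitA <- logical(nrow(pa)); hitB <- logical(nrow(pb))
  for (i in seq_len(nrow(pa))) {
    for (j in seq_len(nrow(pb))) {
      if (pa$chrom[i] != pb$chrom[j]) next
      ov <- min(pa$end[i], pb$end[j]) - max(pa$start[i], pb$start[j])
      if (ov >= min_overlap) { hitA[i] <- TRUE; hitB[j] <- TRUE }
    }
  }
  list(a_only = which(!hitA), b_only = which(!hitB))
}

# direct membership-count oracle for Venn regions
oracle_venn <- function(sets) {
  universe <- unique(unlist(sets))
  patterns <- vapply(universe, function(g)
    paste(as.integer(vapply(sets, function(s) g %in% s, logical(1))),
          collapse = ""), character(1))
  table(patterns)
}

# small random peak table on a toy genome
random_peaks <- function(n, chroms = c("chrT", "chrU"), max_pos = 50000,
                         min_w = 50, max_w = 400) {
  start <- sample.int(max_pos, n, replace = TRUE)
  w <- sample(min_w:max_w, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + w)
}

# parsed toy pipeline shared across tests (built once per test run)
toy_pipeline <- local({
  cache <- NULL
  function(seed = 11) {
    if (!is.null(cache) && cache$seed == seed) return(cache)
    cfg <- sim_config(seed = seed)
    ann <- sim_annotation(cfg)
    models <- parse_annotation(ann$gtf)
    genes <- select_representative_transcripts(models)
    cache <<- list(seed = seed, cfg = cfg, ann = ann, models = models,
                   genes = genes)
    cache
  }
})
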