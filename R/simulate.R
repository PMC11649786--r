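#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the planted-truth simulators. Defaults describe
#' a toy genome that runs through the whole pipeline in seconds while
#' keeping gene placement sparse enough that nearest-TSS gene assignment
#' is unambiguous: two 1.2 Mb chromosomes, 200 genes with 5'UTR/CDS/3'UTR
#' structure on both strands, peak region bias dominated by the 3'UTR
#' (as observed for m6A), and two conditions with unequal peak counts.
#'
#' @param seed Integer master seed (all generators derive from it).
#' @param n_genes Number of genes.
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param region_weights Sampling weights for peak placement over
#'   `flank5, utr5, cds, utr3, flank3` (non-negative, sum > 0).
#' @param peak_counts Named per-condition peak counts.
#' @param m6a_gene_fraction Fraction of genes eligible to carry peaks.
#' @param co_binding_fraction Fraction of genes promoter-bound by both
#'   ChIP factors.
#' @param single_bound_fraction Fraction bound by exactly one factor
#'   (split evenly between the two).
#' @param deg_fraction,deg_effect,deg_null_sd Differential-expression
#'   plant: fraction of true DEGs, their log2FC shift, and the null SD.
#' @param decay_k,decay_sigma,decay_times Decay plant: rate constant(s)
#'   per hour, multiplicative lognormal noise SD, and sampling times
#'   (hours, starting at 0).
#' @param synergy_delta Planted excess (percentage points) added to
#'   every combination cell of the dose matrix; 0 = exact Loewe
#'   additivity.
#' @return A validated `GeneratorConfig` list.
#' @export
sim_config <- function(seed = 1L, n_genes = 200L,
                       chrom_sizes = c(chr1 = 1.2e6, chr2 = 1.2e6),
                       region_weights = c(flank5 = 0.05, utr5 = 0.10,
                                          cds = 0.25, utr3 = 0.55,
                                          flank3 = 0.05),
                       peak_counts = c(hESC = 1000L, tNCC = 700L),
                       m6a_gene_fraction = 0.5,
                       co_binding_fraction = 0.3,
                       single_bound_fraction = 0.3,
                       deg_fraction = 0.1, deg_effect = 3,
                       deg_null_sd = 0.25,
                       decay_k = 0.2, decay_sigma = 0.05,
                       decay_times = c(0, 3, 6),
                       synergy_delta = 0) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (any(region_weights < 0) || sum(region_weights) <= 0)
    stop("region weights must be non-negative with positive sum")
  req <- c("flank5", "utr5", "cds", "utr3", "flank3")
  if (!all(req %in% names(region_weights)))
    stop("region_weights must name: ", paste(req, collapse = ", "))
  for (f in c(m6a_gene_fraction, co_binding_fraction, single_bound_fraction,
              deg_fraction)) {
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  }
  if (co_binding_fraction + single_bound_fraction > 1)
    stop("bound fractions exceed 1")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 chrom_sizes = chrom_sizes,
                 region_weights = region_weights[req],
                 peak_counts = peak_counts,
                 m6a_gene_fraction = m6a_gene_fraction,
                 co_binding_fraction = co_binding_fraction,
                 single_bound_fraction = single_bound_fraction,
                 deg_fraction = deg_fraction, deg_effect = deg_effect,
                 deg_null_sd = deg_null_sd, decay_k = decay_k,
                 decay_sigma = decay_sigma, decay_times = decay_times,
                 synergy_delta = synergy_delta),
            class = "GeneratorConfig")
}

# map a spliced interval [a, b) (transcript orientation) to genomic
# intervals, given exons_g sorted left-to-right genomically
.map_spliced_interval <- function(a, b, exons_g, strand) {
  ord <- if (strand == "+") seq_len(nrow(exons_g)) else rev(seq_len(nrow(exons_g)))
  out <- NULL
  c0 <- 0L
  for (i in ord) {
    gs <- exons_g[i, 1L]; ge <- exons_g[i, 2L]
    len <- ge - gs
    lo <- max(a, c0); hi <- min(b, c0 + len)
    if (hi > lo) {
      piece <- if (strand == "+") {
        c(gs + (lo - c0), gs + (hi - c0))
      } else {
        c(ge - (hi - c0), ge - (lo - c0))
      }
      out <- rbind(out, piece)
    }
    c0 <- c0 + len
  }
  if (is.null(out)) return(.as_ivmat(integer(0), integer(0)))
  .as_ivmat(out[, 1L], out[, 2L])
}

# genomic position (single base) of spliced offset s
.map_spliced_pos <- function(s, exons_g, strand) {
  iv <- .map_spliced_interval(s, s + 1L, exons_g, strand)
  iv[1L, 1L]
}

#' Generate a toy genome annotation with planted structure
#'
#' Places non-overlapping genes on both strands across the configured
#' chromosomes, each with 5'UTR / multi-exon CDS / 3'UTR structure and
#' 1-3 isoforms, exactly one of which (the full model) is the longest.
#' Inter-gene gaps are at least 6 kb so promoter windows and nearest-TSS
#' assignment never collide. Rerunning with the same config is
#' byte-identical.
#'
#' @param config A `GeneratorConfig`.
#' @return List with `gtf` (character vector of GTF lines) and `truth`
#'   (data frame: `gene_id`, `transcript_id` of the longest isoform,
#'   `chrom`, `strand`, `tss`, `span_start`, `span_end`, `n_isoforms`).
#' @export
sim_annotation <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  withr::with_seed(config$seed + 101L, {
    chroms <- names(config$chrom_sizes)
    cursor <- stats::setNames(rep(3000L, length(chroms)), chroms)
    gtf <- character(0)
    truth <- vector("list", config$n_genes)
    for (g in seq_len(config$n_genes)) {
      cm <- chroms[((g - 1L) %% length(chroms)) + 1L]
      strand <- sample(c("+", "-"), 1L)
      u5 <- sample(100:200, 1L)
      cds_len <- sample(500:1500, 1L)
      u3 <- sample(200:600, 1L)
      n_ex <- sample(1:3, 1L)
      spliced_len <- u5 + cds_len + u3
      # split spliced length into exons (each >= 150 bp)
      if (n_ex == 1L) {
        ex_len <- spliced_len
      } else {
        cuts <- sort(sample(seq(150L, spliced_len - 150L, by = 10L),
                            n_ex - 1L))
        ex_len <- diff(c(0L, cuts, spliced_len))
        if (any(ex_len < 50L)) { n_ex <- 1L; ex_len <- spliced_len }
      }
      introns <- if (n_ex > 1L) sample(150:400, n_ex - 1L, replace = TRUE) else integer(0)
      span <- sum(ex_len) + sum(introns)
      gap <- sample(6000:9000, 1L)
      g0 <- cursor[cm] + gap
      if (g0 + span + 3000L > config$chrom_sizes[cm])
        stop("chromosomes too small to place ", config$n_genes, " genes")
      cursor[cm] <- g0 + span
      exons_g <- matrix(0L, n_ex, 2L)
      p <- g0
      for (i in seq_len(n_ex)) {
        exons_g[i, ] <- c(p, p + ex_len[i])
        p <- p + ex_len[i] + (if (i < n_ex) introns[i] else 0L)
      }
      gid <- sprintf("G%04d", g)
      n_iso <- sample(1:3, 1L)
      tid_main <- sprintf("%s.t1", gid)
      utr5_g <- .map_spliced_interval(0L, u5, exons_g, strand)
      cds_g <- .map_spliced_interval(u5, u5 + cds_len, exons_g, strand)
      utr3_g <- .map_spliced_interval(u5 + cds_len, spliced_len, exons_g, strand)
      gtf <- c(gtf,
               .gtf_lines(cm, "exon", exons_g, strand, gid, tid_main),
               .gtf_lines(cm, "five_prime_utr", utr5_g, strand, gid, tid_main),
               .gtf_lines(cm, "CDS", cds_g, strand, gid, tid_main),
               .gtf_lines(cm, "three_prime_utr", utr3_g, strand, gid, tid_main))
      # shorter alternative isoforms: trim spliced length, exon lines only
      if (n_iso > 1L) {
        for (k in seq_len(n_iso - 1L)) {
          keep <- sample(seq(0.4, 0.8, by = 0.1), 1L)
          short <- max(150L, as.integer(floor(spliced_len * keep)))
          alt_g <- .map_spliced_interval(0L, short, exons_g, strand)
          gtf <- c(gtf, .gtf_lines(cm, "exon", alt_g, strand, gid,
                                   sprintf("%s.t%d", gid, k + 1L)))
        }
      }
      tss <- if (strand == "+") exons_g[1L, 1L] else exons_g[n_ex, 2L] - 1L
      truth[[g]] <- data.frame(gene_id = gid, transcript_id = tid_main,
                               chrom = cm, strand = strand, tss = tss,
                               span_start = exons_g[1L, 1L],
                               span_end = exons_g[n_ex, 2L],
                               n_isoforms = n_iso)
    }
    list(gtf = gtf, truth = do.call(rbind, truth))
  })
}

.gtf_lines <- function(chrom, feature, ivs, strand, gid, tid) {
  if (nrow(ivs) == 0L) return(character(0))
  sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
          chrom, feature, ivs[, 1L] + 1L, ivs[, 2L], strand, gid, tid)
}

#' Generate a peak set with planted region labels
#'
#' Draws peak anchors within a condition-specific subset of genes
#' according to the configured region-bias weights; widths are 100-300 bp
#' with the summit at the planted anchor. Anchors keep a small margin
#' from region boundaries so planted labels are unambiguous.
#'
#' @param config A `GeneratorConfig`.
#' @param condition Condition label (must name an entry of
#'   `config$peak_counts`).
#' @param genes Named list of representative `TranscriptModel`s from the
#'   parsed [sim_annotation()] output.
#' @return List with `narrowpeak` (character vector of narrowPeak
#'   lines), `truth` (data frame: `name`, `gene_id`, `region`, `anchor`)
#'   and `m6a_genes` (gene ids that received at least one peak).
#' @export
sim_peakset <- function(config, condition, genes) {
  stopifnot(inherits(config, "GeneratorConfig"))
  if (!condition %in% names(config$peak_counts))
    stop("unknown condition: ", condition)
  n <- config$peak_counts[[condition]]
  seed_off <- 200L + match(condition, names(config$peak_counts))
  withr::with_seed(config$seed + seed_off, {
    eligible <- sort(sample(names(genes),
                            max(1L, round(config$m6a_gene_fraction * length(genes)))))
    w <- config$region_weights
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      gid <- sample(eligible, 1L)
      m <- genes[[gid]]
      region <- sample(names(w), 1L, prob = w)
      rl <- .region_lengths(m)
      # region-internal margin keeps anchors away from boundaries
      anchor <- switch(region,
        flank5 = {
          d <- sample(30:970, 1L)
          if (m$strand == "+") m$tss - d else m$tss + d
        },
        flank3 = {
          tes <- .tes(m)
          d <- sample(30:970, 1L)
          if (m$strand == "+") tes + d else tes - d
        },
        utr5 = .map_spliced_pos(sample(seq(5L, rl["utr5"] - 5L), 1L),
                                m$exons, m$strand),
        cds = .map_spliced_pos(rl["utr5"] +
                                 sample(seq(5L, rl["cds"] - 5L), 1L),
                               m$exons, m$strand),
        utr3 = .map_spliced_pos(rl["utr5"] + rl["cds"] +
                                  sample(seq(5L, rl["utr3"] - 5L), 1L),
                                m$exons, m$strand))
      width <- sample(100:300, 1L)
      offset <- sample(20:(width - 20L), 1L)
      start <- max(0L, anchor - offset)
      rows[[i]] <- data.frame(chrom = m$chrom, start = start,
                              end = start + width,
                              name = sprintf("%s_peak_%d", condition, i),
                              summit = anchor - start,
                              gene_id = gid, region = region,
                              anchor = anchor)
    }
    d <- do.call(rbind, rows)
    np <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%.2f\t%.2f\t%.2f\t%d",
                  d$chrom, d$start, d$end, d$name, 100L, 5, 4, 3, d$summit)
    list(narrowpeak = np,
         truth = d[, c("name", "gene_id", "region", "anchor")],
         m6a_genes = sort(unique(d$gene_id)))
  })
}

#' Generate ChIP coverage tracks and peak sets for two factors
#'
#' Assigns each gene a binding status (co-bound by both factors, bound
#' by one, or unbound) and plants Gaussian promoter coverage bumps plus
#' matching peak intervals for each bound factor. With zero baseline and
#' high amplitude the planted promoter-bound sets are exactly
#' recoverable.
#'
#' @param config A `GeneratorConfig`.
#' @param genes Named list of representative `TranscriptModel`s.
#' @return List with `track_a`/`track_b` (bedGraph line vectors),
#'   `peaks_a`/`peaks_b` (narrowPeak line vectors) and `truth`
#'   (data frame: `gene_id`, `bound_a`, `bound_b`, `co_bound`, `tss`,
#'   `chrom`, `strand`).
#' @export
sim_chip <- function(config, genes) {
  stopifnot(inherits(config, "GeneratorConfig"))
  withr::with_seed(config$seed + 301L, {
    gid <- names(genes)
    n <- length(gid)
    status <- sample(c("both", "a", "b", "none"), n, replace = TRUE,
                     prob = c(config$co_binding_fraction,
                              config$single_bound_fraction / 2,
                              config$single_bound_fraction / 2,
                              1 - config$co_binding_fraction -
                                config$single_bound_fraction))
    tss <- vapply(genes, `[[`, integer(1), "tss")
    chrom <- vapply(genes, `[[`, character(1), "chrom")
    strand <- vapply(genes, `[[`, character(1), "strand")
    mk <- function(which_factor) {
      bound <- status == "both" | status == which_factor
      centers <- tss[bound] + sample(-50:50, sum(bound), replace = TRUE)
      amp <- stats::runif(sum(bound), 8, 12)
      bg <- character(0); np <- character(0)
      ord <- order(chrom[bound], centers)
      cb <- centers[ord]; ab <- amp[ord]; cmb <- chrom[bound][ord]
      gb <- gid[bound][ord]
      for (i in seq_along(cb)) {
        x0 <- seq(cb[i] - 600L, cb[i] + 575L, by = 25L)
        v <- ab[i] * exp(-((x0 + 12.5 - cb[i])^2) / (2 * 150^2))
        bg <- c(bg, sprintf("%s\t%d\t%d\t%.5f", cmb[i], x0, x0 + 25L, v))
        np <- c(np, sprintf("%s\t%d\t%d\t%s\t%d\t.\t%.2f\t%.2f\t%.2f\t%d",
                            cmb[i], cb[i] - 250L, cb[i] + 250L,
                            sprintf("%s_%s", which_factor, gb[i]),
                            100L, ab[i], 4, 3, 250L))
      }
      list(bg = bg, np = np)
    }
    fa <- mk("a"); fb <- mk("b")
    list(track_a = fa$bg, track_b = fb$bg,
         peaks_a = fa$np, peaks_b = fb$np,
         truth = data.frame(gene_id = gid,
                            bound_a = status %in% c("both", "a"),
                            bound_b = status %in% c("both", "b"),
                            co_bound = status == "both",
                            tss = tss, chrom = chrom, strand = strand))
  })
}

#' Generate a differential-expression table with planted DEGs
#'
#' Null genes get `log2fc ~ Normal(0, deg_null_sd)`; a `deg_fraction` of
#' genes is shifted by `+/- deg_effect`. P-values follow the Wald-style
#' transform `p = 2 * pnorm(-|log2fc| / deg_null_sd)` and are BH-adjusted.
#'
#' @param config A `GeneratorConfig`.
#' @param gene_ids Character vector of gene ids.
#' @return List with `table` (data frame `gene_id`, `log2fc`, `padj`)
#'   and `truth` (data frame `gene_id`, `is_deg`, `direction`).
#' @export
sim_de_table <- function(config, gene_ids) {
  stopifnot(inherits(config, "GeneratorConfig"))
  withr::with_seed(config$seed + 401L, {
    n <- length(gene_ids)
    is_deg <- seq_len(n) %in% sample(n, round(config$deg_fraction * n))
    dir <- sample(c(-1, 1), n, replace = TRUE)
    lfc <- stats::rnorm(n, 0, config$deg_null_sd) +
      ifelse(is_deg, dir * config$deg_effect, 0)
    p <- 2 * stats::pnorm(-abs(lfc) / config$deg_null_sd)
    padj <- stats::p.adjust(p, method = "BH")
    list(table = data.frame(gene_id = gene_ids, log2fc = lfc, padj = padj),
         truth = data.frame(gene_id = gene_ids, is_deg = is_deg,
                            direction = ifelse(is_deg, dir, 0)))
  })
}

#' Generate actinomycin-D decay series with planted rate constants
#'
#' Each series is `100 * exp(-k t)` at the configured times with
#' multiplicative lognormal noise at t > 0 (t = 0 is pinned at 100%,
#' matching normalized RT-qPCR time courses).
#'
#' @param config A `GeneratorConfig`.
#' @param n_series Number of series; `config$decay_k` is recycled over
#'   them.
#' @return List with `series` (data frame: `series_id`, `time_h`,
#'   `percent_remaining`) and `truth` (data frame: `series_id`, `k`).
#' @export
sim_decay_series <- function(config, n_series = 1L) {
  stopifnot(inherits(config, "GeneratorConfig"))
  withr::with_seed(config$seed + 501L, {
    ks <- rep_len(config$decay_k, n_series)
    tt <- config$decay_times
    out <- lapply(seq_len(n_series), function(i) {
      y <- 100 * exp(-ks[i] * tt)
      noise <- exp(stats::rnorm(length(tt), 0, config$decay_sigma))
      noise[tt == 0] <- 1
      data.frame(series_id = sprintf("S%03d", i), time_h = tt,
                 percent_remaining = y * noise)
    })
    list(series = do.call(rbind, out),
         truth = data.frame(series_id = sprintf("S%03d", seq_len(n_series)),
                            k = ks))
  })
}

#' Generate a dose-response matrix under Loewe additivity
#'
#' Builds two 4PL monotherapy curves, fills the combination cells with
#' the exact Loewe expected inhibition, then adds the planted
#' `synergy_delta` (percentage points) to every combination cell.
#' `delta = 0` therefore yields an exactly additive matrix.
#'
#' @param config A `GeneratorConfig`.
#' @param delta Planted excess; defaults to `config$synergy_delta`.
#' @param same_drug If `TRUE`, both axes use the same curve (a sham
#'   drug-with-itself combination, for which the Loewe expectation has
#'   the closed form `y(d1 + d2)`).
#' @return List with `matrix` (a `DoseResponseMatrix`), `fit_a`/`fit_b`
#'   (the true `DoseResponseFit` curves) and `truth` (list with
#'   `delta`).
#' @export
sim_dose_matrix <- function(config, delta = config$synergy_delta,
                            same_drug = FALSE) {
  stopifnot(inherits(config, "GeneratorConfig"))
  withr::with_seed(config$seed + 601L, {
    fit_a <- .dr_fit_obj(0, 100, 1, 1.2, degenerate = FALSE)
    fit_b <- if (same_drug) fit_a else .dr_fit_obj(0, 100, 0.5, 0.9,
                                                   degenerate = FALSE)
    doses_a <- c(0, 0.03, 0.1, 0.3, 1, 3) * fit_a$midpoint
    doses_b <- c(0, 0.03, 0.1, 0.3, 1, 3) * fit_b$midpoint
    drm <- dose_response_matrix(doses_a, doses_b,
                                matrix(0, length(doses_a), length(doses_b)))
    expected <- if (same_drug) {
      outer(doses_a, doses_b, function(x, y) fit_a$predict(x + y))
    } else {
      loewe_reference(drm, fit_a, fit_b, tol = 1e-9)
    }
    resp <- expected
    combo <- outer(doses_a > 0, doses_b > 0, `&`)
    resp[combo] <- resp[combo] + delta
    list(matrix = dose_response_matrix(doses_a, doses_b, resp),
         fit_a = fit_a, fit_b = fit_b, truth = list(delta = delta))
  })
}

#' Generate a spike-in count table
#'
#' Two batches of samples with lognormally varying spike-in depths,
#' mimicking per-batch efficiency differences in m6A RIP.
#'
#' @param config A `GeneratorConfig`.
#' @param n_batches,samples_per_batch Table shape.
#' @return Data frame: `sample_id`, `batch`, `spike_count`.
#' @export
sim_spike_table <- function(config, n_batches = 2L, samples_per_batch = 4L) {
  stopifnot(inherits(config, "GeneratorConfig"))
  withr::with_seed(config$seed + 701L, {
    do.call(rbind, lapply(seq_len(n_batches), function(b) {
      data.frame(
        sample_id = sprintf("b%d_s%d", b, seq_len(samples_per_batch)),
        batch = sprintf("batch%d", b),
        spike_count = as.integer(round(stats::rlnorm(samples_per_batch,
                                                     log(1e5), 0.4)))
      )
    }))
  })
}

#' Write the full synthetic fixture bundle to a directory
#'
#' Produces GTF, narrowPeak, bedGraph and TSV fixtures plus sidecar
#' ground-truth TSVs, all seed-deterministic.
#'
#' @param config A `GeneratorConfig`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of file paths written.
#' @export
sim_all <- function(config, dir) {
  stopifnot(inherits(config, "GeneratorConfig"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- sim_annotation(config)
  models <- parse_annotation(ann$gtf)
  genes <- select_representative_transcripts(models)
  paths <- list()
  w <- function(name, lines) {
    p <- file.path(dir, name)
    writeLines(lines, p)
    paths[[name]] <<- p
    p
  }
  tsv <- function(name, df) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
    p
  }
  w("annotation.gtf", ann$gtf)
  tsv("annotation_truth.tsv", ann$truth)
  for (cond in names(config$peak_counts)) {
    ps <- sim_peakset(config, cond, genes)
    w(sprintf("peaks_%s.narrowPeak", cond), ps$narrowpeak)
    tsv(sprintf("peaks_%s_truth.tsv", cond), ps$truth)
  }
  chip <- sim_chip(config, genes)
  w("chip_a.bedGraph", chip$track_a)
  w("chip_b.bedGraph", chip$track_b)
  w("chip_peaks_a.narrowPeak", chip$peaks_a)
  w("chip_peaks_b.narrowPeak", chip$peaks_b)
  tsv("chip_truth.tsv", chip$truth)
  de <- sim_de_table(config, names(genes))
  tsv("de_table.tsv", de$table)
  tsv("de_truth.tsv", de$truth)
  dec <- sim_decay_series(config, n_series = 12L)
  tsv("decay.tsv", dec$series)
  tsv("decay_truth.tsv", dec$truth)
  dm <- sim_dose_matrix(config)
  hdr <- paste(c("dose_a\\dose_b", dm$matrix$doses_b), collapse = "\t")
  body <- vapply(seq_along(dm$matrix$doses_a), function(i)
    paste(c(dm$matrix$doses_a[i],
            sprintf("%.6f", dm$matrix$response[i, ])), collapse = "\t"),
    character(1))
  w("dose_matrix.tsv", c(hdr, body))
  tsv("spikes.tsv", sim_spike_table(config))
  invisible(paths)
}
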