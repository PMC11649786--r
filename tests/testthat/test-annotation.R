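test_that("GTF parsing converts coordinates and handles strand", {
  gtf <- c(
    'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tx\texon\t101\t200\t.\t-\t.\tgene_id "g2"; transcript_id "t2";'
  )
  models <- parse_annotation(gtf)
  expect_equal(unname(models$t1$exons), cbind(100L, 200L), ignore_attr = TRUE)
  expect_equal(models$t1$tss, 100L)
  expect_equal(models$t2$tss, 199L)
})

test_that("GTF parser rejects malformed input", {
  expect_error(parse_annotation("chr1\texon\t101\t200"), "line 1")
  bad_strand <- c(
    'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tx\texon\t301\t400\t.\t?\t.\tgene_id "g1"; transcript_id "t9";'
  )
  expect_warning(models <- parse_annotation(bad_strand), "strand")
  expect_named(models, "t1")
  expect_equal(attr(models, "rejected"), 2L)
  # features without transcript_id are ignored
  no_tid <- 'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1";'
  expect_length(parse_annotation(no_tid), 0)
})

test_that("UTR/CDS partition matches hand enumeration on a 3-exon fixture", {
  for (strand in c("+", "-")) {
    m <- toy_transcript(strand)
    gtf <- c(
      sprintf('chrT\tx\texon\t%d\t%d\t.\t%s\t.\tgene_id "gToy"; transcript_id "tt";',
              m$exons[, 1] + 1, m$exons[, 2], strand),
      sprintf('chrT\tx\tfive_prime_utr\t%d\t%d\t.\t%s\t.\tgene_id "gToy"; transcript_id "tt";',
              m$utr5[, 1] + 1, m$utr5[, 2], strand),
      sprintf('chrT\tx\tCDS\t%d\t%d\t.\t%s\t.\tgene_id "gToy"; transcript_id "tt";',
              m$cds[, 1] + 1, m$cds[, 2], strand),
      sprintf('chrT\tx\tthree_prime_utr\t%d\t%d\t.\t%s\t.\tgene_id "gToy"; transcript_id "tt";',
              m$utr3[, 1] + 1, m$utr3[, 2], strand)
    )
    p <- parse_annotation(gtf)$tt
    expect_equal(p$exons, m$exons, ignore_attr = TRUE)
    expect_equal(p$utr5, m$utr5, ignore_attr = TRUE)
    expect_equal(p$cds, m$cds, ignore_attr = TRUE)
    expect_equal(p$utr3, m$utr3, ignore_attr = TRUE)
  }
})

test_that("representative selection maximizes exon sum with lexicographic ties", {
  mk <- function(tid, gid, len) transcript_model(gid, tid, "c", "+",
                                                 cbind(0L, as.integer(len)))
  sel <- select_representative_transcripts(list(mk("a", "g1", 900), mk("b", "g1", 1200)))
  expect_equal(sel$g1$transcript_id, "b")
  sel <- select_representative_transcripts(list(mk("tB", "g1", 1000), mk("tA", "g1", 1000)))
  expect_equal(sel$g1$transcript_id, "tA")
  expect_length(select_representative_transcripts(list()), 0)
})

test_that("representative selection agrees with brute force and ignores order", {
  withr::with_seed(42, {
    models <- list()
    for (g in 1:50) {
      for (t in seq_len(sample(1:4, 1))) {
        n_ex <- sample(1:3, 1)
        starts <- sort(sample.int(10000, n_ex)) * 10L
        ends <- starts + sample(50:500, n_ex, replace = TRUE)
        starts <- starts + cumsum(c(0L, rep(600L, n_ex - 1L)))
        ends <- ends + cumsum(c(0L, rep(600L, n_ex - 1L)))
        models[[length(models) + 1L]] <-
          transcript_model(sprintf("g%02d", g), sprintf("g%02d.t%d", g, t),
                           "c", "+", cbind(starts, ends))
      }
    }
    sel <- select_representative_transcripts(models)
    # brute force: scan all isoforms per gene
    gid <- vapply(models, `[[`, character(1), "gene_id")
    for (g in unique(gid)) {
      iso <- models[gid == g]
      lens <- vapply(iso, function(m) sum(m$exons[, 2] - m$exons[, 1]), numeric(1))
      tids <- vapply(iso, `[[`, character(1), "transcript_id")
      best <- tids[lens == max(lens)]
      expect_equal(sel[[g]]$transcript_id, min(best))
    }
    sel2 <- select_representative_transcripts(rev(models))
    expect_identical(vapply(sel, `[[`, character(1), "transcript_id"),
                     vapply(sel2, `[[`, character(1), "transcript_id"))
  })
})

test_that("metagene model bin bookkeeping", {
  mg <- build_metagene_model()
  expect_equal(mg$total_bins, 400L)
  expect_equal(unname(mg$bins), c(50L, 100L, 100L, 100L, 50L))
  mg0 <- build_metagene_model(flank_bp = 0)
  expect_equal(mg0$total_bins, 300L)
  mgc <- build_metagene_model(10, 10, 10, flank_bp = 100, flank_bin_bp = 10)
  expect_equal(unname(mgc$region_boundaries), c(10L, 20L, 30L, 40L, 50L))
  expect_error(build_metagene_model(bins_cds = 0), "bin counts")
})

test_that("projection boundary and midpoint conventions", {
  mg <- build_metagene_model()
  m <- toy_transcript("+")
  expect_equal(project_to_metagene(m$tss, m, mg), 50)       # first utr5 bin
  # CDS midpoint: spliced offset 150 + 225 -> bin 50 + 100 + 50
  mid_cds <- oracle_project_lookup(m, mg)
  pos <- as.integer(names(mid_cds)[which(abs(mid_cds - 200) < 1e-9)[1]])
  expect_equal(project_to_metagene(pos, m, mg), 200)
  # intronic -> NA; far away -> NA
  expect_true(is.na(project_to_metagene(1300L, m, mg)))
  expect_true(is.na(project_to_metagene(4000L, m, mg)))
})

test_that("projection matches the base-by-base oracle on both strands", {
  mg <- build_metagene_model()
  for (strand in c("+", "-")) {
    m <- toy_transcript(strand)
    lut <- oracle_project_lookup(m, mg)
    withr::with_seed(5, positions <- sample(0:4000, 1000, replace = TRUE))
    got <- vapply(positions, project_to_metagene, numeric(1), model = m, mg = mg)
    want <- oracle_project(positions, m, mg, lut)
    want[is.null(want)] <- NA_real_
    expect_equal(got, as.numeric(want))
  }
})

test_that("projection is order-preserving and mirror-symmetric", {
  mg <- build_metagene_model()
  mp <- toy_transcript("+")
  mm <- toy_transcript("-")
  # order preservation along transcript orientation
  pos <- c(100:2600)
  cp <- vapply(pos, project_to_metagene, numeric(1), model = mp, mg = mg)
  keep <- !is.na(cp)
  expect_true(all(diff(cp[keep]) >= 0))
  cm <- vapply(pos, project_to_metagene, numeric(1), model = mm, mg = mg)
  keepm <- !is.na(cm)
  expect_true(all(diff(rev(cm[keepm])) >= 0))
  # mirror: the fully reflected transcript on the minus strand projects
  # reflected positions to the same coordinates
  C <- 3500L
  refl_iv <- function(iv) cbind(C - iv[, 2], C - iv[, 1])
  mr <- transcript_model("g", "t", "chrT", "-",
                         exons = refl_iv(mp$exons), cds = refl_iv(mp$cds),
                         utr5 = refl_iv(mp$utr5), utr3 = refl_iv(mp$utr3))
  idx <- which(!is.na(cp))
  for (i in idx[seq(1, length(idx), by = 37)]) {
    expect_equal(project_to_metagene(C - 1L - pos[i], mr, mg), cp[i])
  }
})

test_that("bin midpoints round-trip into their own bin", {
  mg <- build_metagene_model(10, 10, 10, flank_bp = 100, flank_bin_bp = 10)
  m <- toy_transcript("+")
  lut <- oracle_project_lookup(m, mg)
  coords <- as.numeric(lut)
  pos <- as.integer(names(lut))
  for (bin in 0:(mg$total_bins - 1)) {
    inbin <- which(coords >= bin & coords < bin + 1)
    if (length(inbin) == 0) next
    p_mid <- pos[inbin[ceiling(length(inbin) / 2)]]
    expect_equal(floor(project_to_metagene(p_mid, m, mg)), bin)
  }
})

test_that("transcripts without UTR annotation still project", {
  mg <- build_metagene_model()
  m <- transcript_model("g", "t", "c", "+", cbind(100L, 400L))
  expect_equal(project_to_metagene(250L, m, mg),
               150 + (150 / 300) * 100)  # all-body transcript -> CDS band
  expect_false(is.na(project_to_metagene(150L, m, mg)))
})
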