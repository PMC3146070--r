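test_that("gene-body scores average the body and flag zero means", {
  g <- tiny_genome(c(chrI = 2000))
  trk <- coverage_track(list(chrI = c(rep(3.5, 1000), numeric(1000))), g)
  ann <- gene_annotation(data.frame(
    gene_id = c("in_cov", "outside"), chrom = "chrI",
    start = c(100, 1200), end = c(600, 1800), strand = c("+", "-")), g)
  sc <- gene_body_score(trk, ann)
  expect_equal(sc$mean_signal, c(3.5, 0))
  expect_equal(sc$log10_score[1], log10(3.5))
  expect_true(is.na(sc$log10_score[2]))

  # pseudocount makes the zero gene defined
  scp <- gene_body_score(trk, ann, pseudocount = 0.01)
  expect_equal(scp$log10_score[2], log10(0.01))

  bad <- data.frame(gene_id = "z", chrom = "chrI", start = 5, end = 5,
                    strand = "+")
  expect_error(gene_body_score(trk, gene_annotation(bad)), "end <= start")
})

test_that("scores equal brute-force slice means and ignore strand", {
  g <- tiny_genome(c(chrI = 3000, chrII = 2500))
  trk <- random_track(g, seed = 19)
  ann <- gene_annotation(data.frame(
    gene_id = sprintf("g%d", 1:6),
    chrom = rep(c("chrI", "chrII"), each = 3),
    start = c(0, 500, 2400, 10, 900, 2000),
    end = c(400, 1700, 3000, 600, 1500, 2500),
    strand = c("+", "-", "+", "-", "+", "-")), g)
  sc <- gene_body_score(trk, ann)
  expect_equal(sc$mean_signal, brute_gene_means(trk, ann), tolerance = 1e-12)

  flipped <- ann
  flipped$strand <- ifelse(ann$strand == "+", "-", "+")
  sc2 <- gene_body_score(trk, gene_annotation(flipped))
  expect_equal(sc2$mean_signal, sc$mean_signal)
})

test_that("scatter tables pair genes, drop undefined scores, flag highlights", {
  g <- tiny_genome(c(chrI = 2000))
  trk <- coverage_track(list(chrI = c(rep(2, 1500), numeric(500))), g)
  ann <- gene_annotation(data.frame(
    gene_id = c("a", "b", "zero"), chrom = "chrI",
    start = c(0, 600, 1600), end = c(500, 1100, 1900),
    strand = "+"), g)
  sc <- gene_body_score(trk, ann)

  st <- scatter_table(sc, sc)
  expect_equal(st$log10_a, st$log10_b)           # identity on the diagonal
  expect_equal(nrow(st), 2)                      # zero-score gene dropped
  expect_equal(attr(st, "dropped"), 1)
  expect_false(any(st$highlighted))              # empty highlight set

  st2 <- scatter_table(sc, sc, highlight = c("a"))
  expect_equal(st2$highlighted, st2$gene_id == "a")

  other <- sc
  other$gene_id <- paste0("x_", other$gene_id)
  expect_error(scatter_table(sc, other), "share no genes")
})

test_that("simulated germline marking separates classes in the scatter", {
  g <- toy_genome(4, 1e5, include_X = FALSE)
  ann <- annotate_genes(g, 30, seed = 23)
  mk <- function(model, seed) {
    r <- simulate_reads(g, ann, model, 1e5, seed = seed)
    median_scale(pileup(extend_reads(r, g), g))
  }
  sc_a <- gene_body_score(mk(enrichment_model("mes4_maintenance"), 31), ann)
  sc_b <- gene_body_score(mk(enrichment_model("transcription_coupled"), 32),
                          ann)
  st <- scatter_table(sc_a, sc_b,
                      highlight = ann$gene_id[ann$class == "germline"])
  med <- function(cls) median(st$log10_a[st$class == cls])
  expect_gt(med("germline") - med("soma"), 0)
})

test_that("chromosome summaries recover uniform and depleted X ratios", {
  g <- toy_genome(2, 50000, include_X = TRUE)
  unif <- coverage_track(lapply(chrom_lengths(g), function(l) rep(2, l)), g)
  expect_equal(chromosome_summary(unif)$x_autosome_ratio, 1)

  g_noX <- toy_genome(2, 50000, include_X = FALSE)
  unif2 <- coverage_track(lapply(chrom_lengths(g_noX),
                                 function(l) rep(1, l)), g_noX)
  expect_true(is.na(chromosome_summary(unif2)$x_autosome_ratio))

  # X-depleted simulation vs the closed-form mixture expectation
  gX <- toy_genome(5, 1e5, include_X = TRUE)
  ann <- annotate_genes(gX, 30, seed = 2)
  m <- enrichment_model("mes4_maintenance", background_fraction = 0.2,
                        x_weight_multiplier = 0.1)
  r <- simulate_reads(gX, ann, m, 2e5, seed = 41)
  trk <- median_scale(pileup(extend_reads(r, gX), gX))
  ratio <- chromosome_summary(trk)$x_autosome_ratio

  w <- m$class_weights[ann$class]
  w[is.na(w)] <- 0
  w <- as.numeric(w) * (ann$end - ann$start) *
    ifelse(gX$is_X[match(ann$chrom, gX$chrom)], m$x_weight_multiplier, 1)
  mass <- function(chroms) {
    len <- sum(gX$length[gX$chrom %in% chroms])
    bg <- m$background_fraction * len / genome_size(gX)
    gene <- (1 - m$background_fraction) *
      sum(w[ann$chrom %in% chroms]) / sum(w)
    (bg + gene) / len
  }
  expected <- mass("chrX") / mass(gX$chrom[!gX$is_X])
  expect_lt(abs(ratio - expected), 0.1)
})

test_that("enrichment calling recovers truth and is quantile-monotone", {
  g <- toy_genome(5, 1e5, include_X = TRUE)
  ann <- annotate_genes(g, 30, seed = 5)
  m <- enrichment_model("mes4_maintenance", background_fraction = 0,
                        class_weights = c(germline = 1, ubiquitous = 0,
                                          soma = 0),
                        x_weight_multiplier = 1)
  r <- simulate_reads(g, ann, m, 2e5, seed = 7)
  trk <- median_scale(pileup(extend_reads(r, g), g))
  sc <- gene_body_score(trk, ann)

  ce99 <- classify_enriched(sc, trk, 0.99)
  expect_setequal(ce99$enriched, ann$gene_id[ann$class == "germline"])
  ce90 <- classify_enriched(sc, trk, 0.90)
  expect_true(all(ce99$enriched %in% ce90$enriched))

  # all genes below threshold -> empty set
  flat <- coverage_track(lapply(chrom_lengths(g), function(l) rep(1, l)), g)
  sc_flat <- gene_body_score(flat, ann)
  expect_length(classify_enriched(sc_flat, flat, 0.5)$enriched, 0)
})

test_that("rank AUC matches pairwise enumeration", {
  set.seed(61)
  pos <- rnorm(25, 1)
  neg <- rnorm(40)
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + (p > n) + 0.5 * (p == n)
  expect_equal(rank_auc(pos, neg), wins / (25 * 40))
  expect_equal(rank_auc(c(2, 3), c(0, 1)), 1)
  expect_equal(rank_auc(c(0, 1), c(2, 3)), 0)
  expect_equal(rank_auc(c(1, 1), c(1, 1)), 0.5)
})
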