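# Shared fixtures and independent oracles. Oracles here deliberately use
# the slowest, most literal computation available so they stay independent
# of the package's vectorized implementations.

tiny_genome <- function(lens = c(chrI = 1000, chrII = 800),
                        is_X = rep(FALSE, length(lens))) {
  genome_model(names(lens), lens, is_X)
}

manual_annotation <- function(genome, df) {
  gene_annotation(df, genome)
}

# evenly spaced homogeneous genes on one chromosome, windows far enough
# apart that no 200 bp fragment can touch two windows
homogeneous_genes <- function(n = 30, gene_len = 1500, spacing = 2900,
                              first = 1000, strand = "+") {
  starts <- first + (seq_len(n) - 1) * spacing
  data.frame(gene_id = sprintf("g%02d", seq_len(n)), chrom = "chrI",
             start = starts, end = starts + gene_len,
             strand = rep(strand, length.out = n), class = "germline",
             stringsAsFactors = FALSE)
}

# O(n * L) per-base membership pileup oracle
brute_pileup <- function(intervals, genome) {
  lapply(stats::setNames(genome$chrom, genome$chrom), function(cn) {
    len <- genome$length[genome$chrom == cn]
    v <- numeric(len)
    sel <- which(intervals$chrom == cn)
    for (i in sel) {
      for (b in seq(intervals$start[i], intervals$end[i] - 1)) {
        v[b + 1] <- v[b + 1] + 1
      }
    }
    v
  })
}

# literal slice-and-mean gene-body score oracle
brute_gene_means <- function(track, genes) {
  vapply(seq_len(nrow(genes)), function(i) {
    v <- track$values[[genes$chrom[i]]]
    mean(v[(genes$start[i] + 1):genes$end[i]])
  }, 0)
}

# set-comprehension oracles for the gene-set definitions
brute_ubiquitous <- function(tags, tissues = c("germline", "muscle",
                                               "nerve", "gut"), thr = 1) {
  out <- character()
  for (i in seq_len(nrow(tags))) {
    if (all(vapply(tissues, function(t) tags[[t]][i] >= thr, TRUE)))
      out <- c(out, tags$gene[i])
  }
  out
}

brute_somatic <- function(tags, somatic = c("muscle", "nerve", "gut"),
                          soma_thr = 8, expr_thr = 1) {
  out <- character()
  for (i in seq_len(nrow(tags))) {
    any_soma <- any(vapply(somatic, function(t) tags[[t]][i] >= soma_thr,
                           TRUE))
    if (any_soma && tags$germline[i] < expr_thr) out <- c(out, tags$gene[i])
  }
  out
}

random_tag_table <- function(n_genes, seed) {
  set.seed(seed)
  tag_table(data.frame(
    gene = sprintf("t%03d", seq_len(n_genes)),
    germline = rpois(n_genes, 1.5), muscle = rpois(n_genes, 5),
    nerve = rpois(n_genes, 5), gut = rpois(n_genes, 5),
    stringsAsFactors = FALSE))
}

# random raw coverage track over a tiny genome
random_track <- function(genome, seed, scale = 10) {
  set.seed(seed)
  vals <- lapply(stats::setNames(genome$length, genome$chrom),
                 function(l) round(scale * runif(l), 3))
  coverage_track(vals, genome, sample_id = paste0("rand", seed))
}
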