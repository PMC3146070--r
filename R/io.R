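#' Read mapped reads from a BED file
#'
#' Accepts >= 3 tab-separated columns (chrom, start, end[, name, score,
#' strand]); strand defaults to "+" when absent. Coordinates are BED-native
#' 0-based half-open. Malformed lines raise a parse error naming the line;
#' when a genome is supplied, out-of-bounds or unknown chromosomes raise a
#' validation error (never silently clamped).
#'
#' @param path BED file path
#' @param genome optional `genome_model` to validate against
#' @param sample_id,replicate labels attached to the result
#' @return a `read_set`
#' @export
read_bed_reads <- function(path, genome = NULL, sample_id = basename(path),
                           replicate = 1L) {
  fields <- .read_tab_lines(path)
  if (length(fields) == 0L)
    return(read_set(data.frame(chrom = character(), start = numeric(),
                               end = numeric()), sample_id, replicate, genome))
  n <- lengths(fields)
  if (any(n < 3L))
    stop("parse error at line ", which(n < 3L)[1], ": fewer than 3 columns")
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad))
    stop("parse error at line ", bad[1], ": non-numeric coordinates")
  bad <- which(end <= start | start < 0)
  if (length(bad))
    stop("parse error at line ", bad[1], ": requires 0 <= start < end")
  name <- ifelse(n >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), ".")
  strand <- ifelse(n >= 6L, vapply(fields, function(f) f[min(6L, length(f))], ""), "+")
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop("parse error at line ", bad[1], ": strand must be '+' or '-'")
  read_set(data.frame(chrom = chrom, start = start, end = end, name = name,
                      strand = strand, stringsAsFactors = FALSE),
           sample_id = sample_id, replicate = replicate, genome = genome)
}

#' Write a read set as 6-column BED
#'
#' Deterministic output: the same in-memory set always produces identical
#' bytes (score column fixed at 0).
#'
#' @param reads a `read_set`
#' @param path output path
#' @export
write_bed_reads <- function(reads, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", reads$chrom,
                   as.integer(reads$start), as.integer(reads$end),
                   reads$name, reads$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation from BED + class sidecar TSV
#'
#' The BED carries coordinates and strand; the sidecar TSV
#' (`gene_id<TAB>class`, no header) carries expression classes. Genes in
#' the BED without a class entry get class "unassigned" with a warning;
#' class entries for unknown genes are an error.
#'
#' @param path_bed BED6 path (name column = gene id)
#' @param path_class_tsv optional class TSV path
#' @param genome optional `genome_model` for bounds validation
#' @return a `gene_annotation`
#' @export
read_gene_annotation <- function(path_bed, path_class_tsv = NULL,
                                 genome = NULL) {
  reads <- read_bed_reads(path_bed, genome = genome)
  df <- data.frame(gene_id = reads$name, chrom = reads$chrom,
                   start = reads$start, end = reads$end,
                   strand = reads$strand, stringsAsFactors = FALSE)
  if (!is.null(path_class_tsv)) {
    cls <- utils::read.table(path_class_tsv, sep = "\t", header = FALSE,
                             col.names = c("gene_id", "class"),
                             stringsAsFactors = FALSE)
    unknown <- setdiff(cls$gene_id, df$gene_id)
    if (length(unknown))
      stop("class table lists genes absent from the BED: ",
           paste(utils::head(unknown, 3), collapse = ", "))
    df$class <- cls$class[match(df$gene_id, cls$gene_id)]
    if (anyNA(df$class)) {
      warning(sum(is.na(df$class)), " gene(s) without a class entry; ",
              "set to 'unassigned'")
      df$class[is.na(df$class)] <- "unassigned"
    }
  }
  gene_annotation(df, genome)
}

#' Write a gene annotation as BED6 plus a class sidecar TSV
#' @param ann a `gene_annotation`
#' @param path_bed BED output path
#' @param path_class_tsv class TSV output path (gene_id, class; no header)
#' @export
write_gene_annotation <- function(ann, path_bed, path_class_tsv = NULL) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", ann$chrom,
                   as.integer(ann$start), as.integer(ann$end), ann$gene_id,
                   ann$strand)
  writeLines(lines, path_bed)
  if (!is.null(path_class_tsv))
    writeLines(sprintf("%s\t%s", ann$gene_id, ann$class), path_class_tsv)
  invisible(path_bed)
}

#' Write a coverage track as run-length-compressed bedGraph
#'
#' Zero-valued runs are omitted (gaps read back as 0). Values are emitted
#' with 6 decimal places, so a round trip reconstructs per-bp values to
#' within 5e-7.
#'
#' @param track a `coverage_track`
#' @param path output path
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=%s", track$sample_id), con)
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    if (!all(is.finite(v))) stop("track values must be finite")
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%.6f", chrom,
                         as.integer(starts[keep]), as.integer(ends[keep]),
                         r$values[keep]), con)
  }
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' Gaps are value 0 (pileup semantics). Overlapping intervals are a parse
#' error; out-of-bounds intervals a validation error.
#'
#' @param path bedGraph path
#' @param genome a `genome_model` (defines vector lengths)
#' @param sample_id sample label (default parsed from the track line)
#' @param normalization_state state to stamp on the result (a text file
#'   does not carry it; default "median_scaled")
#' @return a `coverage_track`
#' @export
read_bedgraph <- function(path, genome, sample_id = NULL,
                          normalization_state = "median_scaled") {
  .check_genome(genome)
  lines <- readLines(path)
  is_hdr <- grepl("^(track|#|browser)", lines)
  if (is.null(sample_id)) {
    m <- regmatches(lines[is_hdr], regexpr("name=\\S+", lines[is_hdr]))
    sample_id <- if (length(m)) sub("^name=", "", m[1]) else basename(path)
  }
  body <- lines[!is_hdr & nzchar(lines)]
  vals <- lapply(stats::setNames(genome$length, genome$chrom), numeric)
  if (length(body)) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(fields) != 4L))
      stop("parse error at line ", which(lengths(fields) != 4L)[1] +
             sum(is_hdr), ": expected 4 columns")
    chrom <- vapply(fields, `[`, "", 1L)
    start <- as.numeric(vapply(fields, `[`, "", 2L))
    end <- as.numeric(vapply(fields, `[`, "", 3L))
    val <- as.numeric(vapply(fields, `[`, "", 4L))
    if (anyNA(start) || anyNA(end) || anyNA(val))
      stop("parse error: non-numeric bedGraph fields")
    lens <- .chrom_length(genome, chrom)
    if (any(start < 0 | end <= start | end > lens))
      stop("bedGraph interval out of chromosome bounds")
    for (cn in unique(chrom)) {
      i <- chrom == cn
      o <- order(start[i])
      s <- start[i][o]; e <- end[i][o]
      if (any(s[-1] < e[-length(e)]))
        stop("parse error: overlapping bedGraph intervals on ", cn)
      v <- vals[[cn]]
      for (k in seq_along(s)) v[(s[k] + 1):e[k]] <- val[i][o][k]
      vals[[cn]] <- v
    }
  }
  coverage_track(vals, genome, sample_id = sample_id,
                 normalization_state = normalization_state)
}

#' Read an expression tag table from TSV
#'
#' Header row: `gene<TAB>tissue1<TAB>...`; counts must be nonnegative
#' integers.
#'
#' @param path TSV path
#' @return a `tag_table`
#' @export
read_tag_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  tag_table(df)
}

#' Write an expression tag table as TSV
#' @param tags a `tag_table`
#' @param path output path
#' @export
write_tag_table <- function(tags, path) {
  utils::write.table(tags, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a staining count table
#'
#' Expected columns: `genotype`, `assay`, `positive`, `total` (TSV with
#' header). Validates 0 <= positive <= total and total > 0.
#'
#' @param path TSV path
#' @return a validated data.frame
#' @export
read_stain_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("genotype", "assay", "positive", "total")
  if (!all(need %in% names(df)))
    stop("staining table needs columns: ", paste(need, collapse = ", "))
  if (any(df$total <= 0)) stop("staining row with total <= 0")
  if (any(df$positive < 0 | df$positive > df$total))
    stop("staining row with positive outside [0, total]")
  df
}

#' Read a qPCR Cp table
#'
#' Expected columns: `sample`, `Cp`, `dilution_factor`,
#' `role` in {chip, input} (TSV with header).
#'
#' @param path TSV path
#' @return a validated data.frame
#' @export
read_qpcr_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample", "Cp", "dilution_factor", "role")
  if (!all(need %in% names(df)))
    stop("qPCR table needs columns: ", paste(need, collapse = ", "))
  if (!all(df$role %in% c("chip", "input")))
    stop("qPCR role must be 'chip' or 'input'")
  if (any(df$dilution_factor < 1)) stop("dilution factors must be >= 1")
  df
}

# split non-empty, non-comment lines on tabs; returns list of field vectors
.read_tab_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  strsplit(lines, "\t", fixed = TRUE)
}
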