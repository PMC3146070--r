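#' Gene-set definition configuration
#'
#' Thresholds and tissue names used to build the expression-breadth gene
#' sets from SAGE-style tag counts: expressed means >= 1 tag; robustly
#' expressed in a somatic library means >= 8 tags.
#'
#' @param somatic_tissues somatic library names (default muscle, nerve, gut)
#' @param germline_tissue germline library name
#' @param expressed_threshold tags for "expressed" (default 1)
#' @param somatic_threshold tags for somatic expression (default 8)
#' @return a `geneset_config` list
#' @export
geneset_config <- function(somatic_tissues = c("muscle", "nerve", "gut"),
                           germline_tissue = "germline",
                           expressed_threshold = 1, somatic_threshold = 8) {
  if (length(somatic_tissues) == 0L) stop("somatic tissue list is empty")
  if (expressed_threshold < 1 || somatic_threshold < 1)
    stop("tag thresholds must be >= 1")
  structure(list(somatic_tissues = somatic_tissues,
                 germline_tissue = germline_tissue,
                 expressed_threshold = expressed_threshold,
                 somatic_threshold = somatic_threshold),
            class = "geneset_config")
}

.tag_matrix <- function(tags, tissues) {
  missing <- setdiff(tissues, names(tags))
  if (length(missing))
    stop("tag table is missing tissue column(s): ",
         paste(missing, collapse = ", "))
  m <- as.matrix(tags[, tissues, drop = FALSE])
  rownames(m) <- tags$gene
  m
}

#' Ubiquitously expressed genes
#'
#' Genes expressed (tag count >= `expressed_threshold`) in the germline
#' and in every somatic tissue.
#'
#' @param tags a `tag_table`
#' @param cfg a `geneset_config`
#' @return character vector of gene ids
#' @export
define_ubiquitous <- function(tags, cfg = geneset_config()) {
  m <- .tag_matrix(tags, c(cfg$germline_tissue, cfg$somatic_tissues))
  rownames(m)[rowSums(m >= cfg$expressed_threshold) == ncol(m)]
}

#' Soma-expressed, germline-silent genes
#'
#' Genes with >= `somatic_threshold` tags in at least one somatic library
#' and zero germline tags (germline count below `expressed_threshold`,
#' i.e. not expressed in germline).
#'
#' @param tags a `tag_table`
#' @param cfg a `geneset_config`
#' @return character vector of gene ids
#' @export
define_somatic <- function(tags, cfg = geneset_config()) {
  soma <- .tag_matrix(tags, cfg$somatic_tissues)
  germ <- .tag_matrix(tags, cfg$germline_tissue)[, 1]
  rownames(soma)[rowSums(soma >= cfg$somatic_threshold) >= 1 &
                   germ < cfg$expressed_threshold]
}

#' Germline-enriched genes from a published-style list, minus exclusions
#'
#' Plain set difference over gene ids (duplicates collapse); typically the
#' input is an externally curated germline-enriched list and the exclusion
#' is the spermatogenesis gene list.
#'
#' @param input character vector of gene ids
#' @param exclude character vector of gene ids to remove
#' @return character vector (unique, input order)
#' @export
define_germline_enriched <- function(input, exclude = character()) {
  setdiff(unique(input), exclude)
}

#' Larval/adult germline-specific genes
#'
#' The triple intersection of the germline-enriched list, the SAGE
#' germline-expressed genes (>= 1 tag), and the strictly maternal class.
#'
#' @param germline_enriched,sage_germline_expressed,strictly_maternal
#'   character vectors of gene ids
#' @return character vector of gene ids
#' @export
define_larval_adult_germline_specific <- function(germline_enriched,
                                                  sage_germline_expressed,
                                                  strictly_maternal) {
  intersect(intersect(unique(germline_enriched),
                      unique(sage_germline_expressed)),
            unique(strictly_maternal))
}

#' Germline-expressed genes by SAGE tag count
#'
#' Helper feeding [define_larval_adult_germline_specific()]: genes with
#' >= `expressed_threshold` tags in the germline library.
#'
#' @param tags a `tag_table`
#' @param cfg a `geneset_config`
#' @return character vector of gene ids
#' @export
sage_germline_expressed <- function(tags, cfg = geneset_config()) {
  germ <- .tag_matrix(tags, cfg$germline_tissue)[, 1]
  tags$gene[germ >= cfg$expressed_threshold]
}
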