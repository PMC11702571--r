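#' Load SNP-to-gene and gene-to-pathway annotation tables
#'
#' Reads the three tab-separated annotation files that drive pathway
#' scoring: a SNP-to-gene map (`snp_id`, `gene`), a gene-to-pathway map
#' (`gene`, `pathway_id`, `pathway_name`), and a reference file giving
#' each pathway's gene count in the annotation release (`pathway_id`,
#' `ref_gene_count`) plus one row with `pathway_id = "TOTAL"` carrying the
#' total number of annotated reference genes. SNPs whose `gene` field is
#' empty, `NA` or `"-"` (e.g. non-coding hits) are retained but flagged
#' unmapped and excluded from query gene sets.
#'
#' @param snp_gene_path,gene_pathway_path,reference_path File paths.
#' @return A list of class `annotation_catalog`: `snp_to_genes` (tibble),
#'   `gene_to_pathways` (tibble), `pathways` (id/name/ref size tibble),
#'   `reference_total`, `unmapped_snps`.
#' @export
load_annotations <- function(snp_gene_path, gene_pathway_path, reference_path) {
  read_checked <- function(path, need) {
    tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    missing <- setdiff(need, names(tbl))
    if (length(missing)) {
      abort(sprintf("`%s` is missing column(s): %s", path,
                    paste(missing, collapse = ", ")))
    }
    bad <- which(!stats::complete.cases(tbl[setdiff(need, "gene")]))
    if (length(bad)) {
      abort(sprintf("`%s`: malformed row(s) at line(s) %s (after header).",
                    path, paste(utils::head(bad, 5), collapse = ", ")))
    }
    tbl
  }
  sg <- read_checked(snp_gene_path, c("snp_id", "gene"))
  gp <- read_checked(gene_pathway_path, c("gene", "pathway_id", "pathway_name"))
  ref <- read_checked(reference_path, c("pathway_id", "ref_gene_count"))

  sg$gene[sg$gene %in% c("", "-")] <- NA_character_
  unmapped <- unique(sg$snp_id[is.na(sg$gene)])
  unmapped <- setdiff(unmapped, sg$snp_id[!is.na(sg$gene)])

  total_row <- ref$pathway_id == "TOTAL"
  if (!any(total_row)) {
    abort("Reference file must contain a `TOTAL` row with the reference gene count.")
  }
  reference_total <- as.integer(ref$ref_gene_count[total_row][1])
  pathways <- ref[!total_row, ]
  name_map <- gp[!duplicated(gp$pathway_id), c("pathway_id", "pathway_name")]
  pathways <- dplyr::left_join(pathways, name_map, by = "pathway_id")
  if (any(pathways$ref_gene_count > reference_total)) {
    abort("A pathway's reference gene count exceeds the reference total.")
  }

  structure(
    list(snp_to_genes = as_tibble(sg[!is.na(sg$gene), ]),
         gene_to_pathways = as_tibble(gp),
         pathways = as_tibble(pathways),
         reference_total = reference_total,
         unmapped_snps = unmapped),
    class = "annotation_catalog"
  )
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat("<annotation_catalog>\n")
  cat(sprintf("  %d SNP-gene links (%d unmapped SNPs), %d pathways, reference total %d genes\n",
              nrow(x$snp_to_genes), length(x$unmapped_snps),
              nrow(x$pathways), x$reference_total))
  invisible(x)
}

#' Pathway overrepresentation test
#'
#' For each pathway, cross-tabulates reference genes by pathway membership
#' and query membership and applies Fisher's exact test (one-sided
#' overrepresentation by default). The expected query count is the
#' pathway's share of the reference, `ref_size * n_query /
#' reference_total`, and fold enrichment is observed over expected.
#'
#' @param query_genes Character vector of query genes (e.g. the genes
#'   mapped from a SNP panel). Genes outside the reference universe are
#'   dropped with a warning.
#' @param catalog An [load_annotations()] catalog.
#' @param alternative `"greater"` (overrepresentation, default) or
#'   `"two.sided"`.
#' @return A tibble sorted by raw p-value: `pathway_id`, `pathway_name`,
#'   `ref_count`, `observed`, `expected`, `fold`, `direction`, `p_raw`,
#'   `fdr` (Benjamini-Hochberg, via [adjust_fdr()]).
#' @export
overrepresentation_test <- function(query_genes, catalog,
                                    alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(catalog, "annotation_catalog"))
  query_genes <- unique(query_genes)
  n_ref <- catalog$reference_total
  if (n_ref < length(query_genes)) {
    abort("The query is larger than the reference universe.")
  }
  if (nrow(catalog$pathways) == 0L) {
    return(adjust_fdr(tibble(pathway_id = character(), pathway_name = character(),
                             ref_count = integer(), observed = integer(),
                             expected = double(), fold = double(),
                             direction = character(), p_raw = double())))
  }
  n_query <- length(query_genes)

  res <- purrr::pmap_dfr(
    list(catalog$pathways$pathway_id, catalog$pathways$pathway_name,
         catalog$pathways$ref_gene_count),
    function(pid, pname, ref_count) {
      in_pw <- catalog$gene_to_pathways$gene[catalog$gene_to_pathways$pathway_id == pid]
      obs <- sum(query_genes %in% in_pw)
      expected <- ref_count * n_query / n_ref
      tab <- matrix(c(obs, ref_count - obs,
                      n_query - obs, n_ref - ref_count - (n_query - obs)),
                    2, 2)
      if (any(tab < 0)) {
        abort(sprintf(
          "Pathway `%s`: query and reference counts are inconsistent (is the query inside the reference universe?).",
          pid))
      }
      p <- fisher.test(tab, alternative = alternative)$p.value
      tibble(pathway_id = pid, pathway_name = pname,
             ref_count = as.integer(ref_count), observed = as.integer(obs),
             expected = expected,
             fold = if (expected > 0) obs / expected else NA_real_,
             direction = if (obs >= expected) "+" else "-",
             p_raw = p)
    })
  adjust_fdr(dplyr::arrange(res, .data$p_raw))
}

#' Benjamini-Hochberg adjustment of enrichment p-values
#'
#' Adds (or refreshes) an `fdr` column of step-up q-values.
#'
#' @param results A tibble with a `p_raw` column.
#' @return The same tibble with `fdr` filled.
#' @export
adjust_fdr <- function(results) {
  if (!"p_raw" %in% names(results)) abort("`results` must contain `p_raw`.")
  results$fdr <- p.adjust(results$p_raw, method = "BH")
  results
}

#' Map genes of a SNP panel through the annotation catalog
#'
#' @param snp_ids SNP identifiers.
#' @param catalog An annotation catalog.
#' @return Character vector of unique mapped genes (unmapped SNPs are
#'   skipped).
#' @export
query_genes_for_snps <- function(snp_ids, catalog) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  sg <- catalog$snp_to_genes
  unique(sg$gene[sg$snp_id %in% snp_ids])
}

#' Build pathway SNP subsets for pPRS construction
#'
#' A SNP belongs to a pathway's set when any of its mapped genes is
#' annotated to that pathway; a SNP can therefore appear in several sets.
#' Combined sets are unions of their member pathways' sets, and the
#' `other` set collects panel SNPs in none of the listed pathways
#' (including unmapped SNPs).
#'
#' @param snp_ids The SNP panel.
#' @param catalog An annotation catalog.
#' @param pathways Pathway ids to build sets for; defaults to all
#'   catalogued pathways.
#' @param combine Optional named list of pathway-id groups, e.g.
#'   `list(tgfb_grhr = c("P00052", "P06664"))`.
#' @return Named list of SNP-id character vectors (one per pathway, one
#'   per combined group, plus `other`).
#' @export
build_snp_sets <- function(snp_ids, catalog,
                           pathways = catalog$pathways$pathway_id,
                           combine = list()) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  unknown <- setdiff(unlist(c(pathways, combine)), catalog$pathways$pathway_id)
  if (length(unknown)) {
    abort(sprintf("Unknown pathway label(s): %s", paste(unknown, collapse = ", ")))
  }
  sg <- catalog$snp_to_genes[catalog$snp_to_genes$snp_id %in% snp_ids, ]
  gp <- catalog$gene_to_pathways
  one_set <- function(pid) {
    genes <- gp$gene[gp$pathway_id == pid]
    sort(unique(sg$snp_id[sg$gene %in% genes]))
  }
  sets <- lapply(setNames(pathways, pathways), one_set)
  for (lab in names(combine)) {
    sets[[lab]] <- sort(unique(unlist(lapply(combine[[lab]], one_set))))
  }
  in_any <- unique(unlist(lapply(setNames(pathways, pathways), one_set)))
  sets$other <- sort(setdiff(snp_ids, in_any))
  sets
}
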