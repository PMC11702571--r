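# Small design used throughout the unit tests: cheap to simulate but large
# enough for logistic asymptotics to hold approximately.
small_spec <- function(n_snps = 50L, q_causal = 4L, q_gxe = 2L,
                       n_cases = 600L, n_controls = 600L,
                       overlap = c(2L, 0L, 0L), q_pathway = sum(overlap), ...) {
  scenario_spec(n_snps = n_snps, q_causal = q_causal, q_gxe = q_gxe,
                q_pathway = q_pathway,
                pathway_overlap_gxe = overlap[1],
                pathway_overlap_gonly = overlap[2],
                pathway_overlap_null = overlap[3],
                n_cases = n_cases, n_controls = n_controls, ...)
}

# Hand-built weight set (bypasses estimation) for arithmetic tests.
manual_weights <- function(snp_ids, weights, ...) {
  out <- tibble::tibble(snp_id = snp_ids, weight = weights, ...)
  attr(out, "provenance") <- "catalog"
  attr(out, "ridged") <- FALSE
  class(out) <- c("prs_weights", class(out))
  out
}

# Toy annotation fixture: writes the three TSVs into a temp dir and
# returns their paths. Pathway pw1 = {geneA, geneB}, pw2 = {geneB, geneC};
# geneB sits in both pathways and snp3 maps to it.
write_toy_annotations <- function(dir = local_fixture_dir(),
                                  ref_total = 50L,
                                  ref_sizes = c(pw1 = 10L, pw2 = 5L)) {
  sg <- data.frame(
    snp_id = c("snp1", "snp2", "snp3", "snp4", "snp5"),
    gene = c("geneA", "geneA", "geneB", "geneC", "-")
  )
  gp <- data.frame(
    gene = c("geneA", "geneB", "geneB", "geneC"),
    pathway_id = c("pw1", "pw1", "pw2", "pw2"),
    pathway_name = c("Pathway one", "Pathway one", "Pathway two", "Pathway two")
  )
  ref <- data.frame(
    pathway_id = c(names(ref_sizes), "TOTAL"),
    ref_gene_count = c(unname(ref_sizes), ref_total)
  )
  paths <- list(
    snp_gene = file.path(dir, "snp_gene.tsv"),
    gene_pathway = file.path(dir, "gene_pathway.tsv"),
    reference = file.path(dir, "reference.tsv")
  )
  write.table(sg, paths$snp_gene, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(gp, paths$gene_pathway, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(ref, paths$reference, sep = "\t", row.names = FALSE, quote = FALSE)
  paths
}

# Catalog in which one pathway of size `k` sits in a reference universe of
# `n_total` genes named g1..gN; used by the hypergeometric oracle suite.
local_fixture_dir <- function() {
  d <- tempfile("fixture")
  dir.create(d)
  d
}

hypergeom_catalog <- function(n_total, k, dir = local_fixture_dir()) {
  genes <- paste0("g", seq_len(n_total))
  sg <- data.frame(snp_id = paste0("s", seq_len(n_total)), gene = genes)
  gp <- data.frame(gene = genes[seq_len(k)], pathway_id = "pw",
                   pathway_name = "oracle pathway")
  ref <- data.frame(pathway_id = c("pw", "TOTAL"), ref_gene_count = c(k, n_total))
  p <- list(sg = file.path(dir, "sg.tsv"), gp = file.path(dir, "gp.tsv"),
            ref = file.path(dir, "ref.tsv"))
  write.table(sg, p$sg, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(gp, p$gp, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(ref, p$ref, sep = "\t", row.names = FALSE, quote = FALSE)
  load_annotations(p$sg, p$gp, p$ref)
}

# Brute-force upper-tail hypergeometric probability by direct enumeration.
hypergeom_tail <- function(obs, n_total, k_pathway, n_query) {
  ks <- obs:min(k_pathway, n_query)
  sum(choose(k_pathway, ks) * choose(n_total - k_pathway, n_query - ks)) /
    choose(n_total, n_query)
}

# Direct logistic simulation (no cohort machinery) for interaction tests.
sim_gxe_data <- function(n, b0 = -0.5, bg = 0.3, be = 0.2, bge = 0) {
  g <- rnorm(n)
  e <- rbinom(n, 1, 0.5)
  d <- rbinom(n, 1, plogis(b0 + bg * g + be * e + bge * g * e))
  tibble::tibble(D = d, score = g, E = e)
}
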