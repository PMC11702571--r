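#' Read a genotype/dosage table
#'
#' Two dialects are supported. `"tsv-matrix"` is a tab-separated matrix
#' with an `id` column followed by one numeric dosage column per SNP.
#' `"plink-raw"` is the PLINK `.raw` additive recoding: whitespace-
#' separated `FID IID PAT MAT SEX PHENOTYPE` then SNP columns named
#' `<snp>_<counted allele>`; the allele suffix is stripped into a
#' `counted_allele` attribute (used to align scoring-file effect alleles)
#' and the `PHENOTYPE` column is ignored with a warning, since phenotypes
#' are taken from the phenotype table.
#'
#' Dosages must lie in `[0, 2]`; missing values are imputed to the column
#' mean and the imputation count is reported.
#'
#' @param path File path.
#' @param dialect `"tsv-matrix"` or `"plink-raw"`.
#' @return A tibble with an `id` column and one dosage column per SNP,
#'   possibly carrying a `counted_allele` attribute.
#' @export
read_genotype_table <- function(path, dialect = c("tsv-matrix", "plink-raw")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv-matrix") {
    tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (!"id" %in% names(tbl)) abort("tsv-matrix genotype files need an `id` column.")
    counted <- NULL
  } else {
    tbl <- readr::read_table(path, show_col_types = FALSE, progress = FALSE)
    fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    missing <- setdiff(c("FID", "IID"), names(tbl))
    if (length(missing)) abort("plink-raw files need FID and IID columns.")
    if ("PHENOTYPE" %in% names(tbl)) {
      warn("`PHENOTYPE` column in plink-raw input is ignored; phenotypes come from the phenotype table.")
    }
    snp_cols <- setdiff(names(tbl), fixed)
    counted <- sub("^.*_([A-Za-z0-9]+)$", "\\1", snp_cols)
    bare <- sub("_[A-Za-z0-9]+$", "", snp_cols)
    if (anyDuplicated(bare)) abort("Duplicated SNP ids in plink-raw header.")
    out <- tbl[snp_cols]
    names(out) <- bare
    tbl <- dplyr::bind_cols(tibble(id = tbl$IID), out)
    counted <- setNames(counted, bare)
  }
  snp_cols <- setdiff(names(tbl), "id")
  for (sc in snp_cols) {
    x <- as.double(tbl[[sc]])
    n_na <- sum(is.na(x))
    if (n_na) {
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      inform(sprintf("Imputed %d missing dosage(s) in `%s` to the column mean.", n_na, sc))
    }
    bad <- which(x < 0 | x > 2)
    if (length(bad)) {
      abort(sprintf("Dosage out of [0, 2] at row %d of column `%s` (value %g).",
                    bad[1], sc, x[bad[1]]))
    }
    tbl[[sc]] <- x
  }
  if (!is.null(counted)) attr(tbl, "counted_allele") <- counted
  tbl
}

#' Write / read a cohort as TSV
#'
#' One header row (`id`, `D`, `E`, covariates, then SNP ids), tab
#' separated. Truth labels of simulated cohorts are not serialised.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_cohort_tsv <- function(cohort, path) {
  readr::write_tsv(as_tibble(as.data.frame(cohort)), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read and validate a pipeline run configuration
#'
#' YAML or JSON (by file extension). Required fields: `workflow`
#' (`"simulate-study"` or `"real-data"`), `seed`, `out_dir`; workflow-
#' specific fields are validated before any computation, and all
#' referenced paths must exist.
#'
#' @param path Config file path.
#' @return A validated named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  need <- function(field) {
    if (is.null(cfg[[field]])) abort(sprintf("Config is missing required field `%s`.", field))
    cfg[[field]]
  }
  wf <- need("workflow")
  if (!wf %in% c("simulate-study", "real-data")) {
    abort("`workflow` must be \"simulate-study\" or \"real-data\".")
  }
  need("seed"); need("out_dir")
  if (!is.null(cfg$alpha)) check_prob(cfg$alpha, "alpha")
  path_fields <- if (wf == "real-data") {
    c("genotype_path", "phenotype_path", "snp_gene_path",
      "gene_pathway_path", "reference_path")
  } else {
    character(0)
  }
  for (f in path_fields) {
    p <- need(f)
    if (!file.exists(p)) abort(sprintf("Config path `%s` does not exist: %s", f, p))
  }
  if (!is.null(cfg$weights_path) && !file.exists(cfg$weights_path)) {
    abort(sprintf("Config path `weights_path` does not exist: %s", cfg$weights_path))
  }
  structure(cfg, class = "run_config")
}

#' Run an end-to-end workflow
#'
#' `"simulate-study"` runs the replicate power study for the configured
#' scenarios and writes the scenario-by-power table. `"real-data"` reads
#' genotype/phenotype/annotation files, obtains weights (from a scoring
#' file when `weights_path` is set, otherwise estimated in-sample),
#' selects overrepresented pathways at the configured FDR, builds pathway
#' SNP sets, computes standardized scores, and tests every score's
#' interaction with the exposure (raw p-values by default; set `p_adjust`
#' to a [stats::p.adjust()] method for an adjusted column). All tabular
#' outputs and a log with versions, seed and thresholds are written under
#' `out_dir`.
#'
#' @param config A `run_config` (see [read_run_config()]) or a named list
#'   with the same fields.
#' @return A list of result tables, invisibly the same objects written to
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_run_config(unclass(config))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("pprsxe %s | R %s", as.character(utils::packageVersion("pprsxe")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("workflow=%s seed=%s", cfg$workflow, cfg$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }
  out <- list()
  if (cfg$workflow == "simulate-study") {
    scen <- cfg$scenarios %||% 1:9
    n_reps <- cfg$n_reps %||% 1000L
    alpha <- cfg$alpha %||% 0.05
    out$power <- stage("power-study",
      run_power_study(scenarios = scen, n_reps = n_reps, alpha = alpha,
                      seed = cfg$seed))
    readr::write_tsv(as_tibble(as.data.frame(out$power)),
                     file.path(cfg$out_dir, "power.tsv"), progress = FALSE)
    log_lines <- c(log_lines,
                   sprintf("scenarios=%s n_reps=%d alpha=%g",
                           paste(scen, collapse = ","), n_reps, alpha))
  } else {
    geno <- stage("read-genotypes",
      read_genotype_table(cfg$genotype_path, cfg$genotype_dialect %||% "tsv-matrix"))
    pheno <- stage("read-phenotypes",
      readr::read_tsv(cfg$phenotype_path, show_col_types = FALSE, progress = FALSE))
    dat <- stage("merge", dplyr::inner_join(pheno, geno, by = "id"))
    covars <- cfg$covariates %||% character(0)
    exposure <- cfg$exposure %||% "E"
    snp_ids <- setdiff(names(geno), "id")
    weights <- stage("weights", {
      if (!is.null(cfg$weights_path)) {
        read_pgs_scorefile(cfg$weights_path)
      } else {
        estimate_weights(dat, snp_ids, covariates = covars,
                         provenance = "insample_fixed_snps")
      }
    })
    catalog <- stage("annotations",
      load_annotations(cfg$snp_gene_path, cfg$gene_pathway_path, cfg$reference_path))
    panel <- intersect(weights$snp_id, snp_ids)
    enr <- stage("enrichment",
      overrepresentation_test(query_genes_for_snps(panel, catalog), catalog))
    fdr_thr <- cfg$fdr_threshold %||% 0.05
    selected <- enr$pathway_id[enr$fdr < fdr_thr & enr$direction == "+"]
    if (length(selected) == 0L) selected <- enr$pathway_id
    combine <- cfg$combine %||% list()
    sets <- stage("snp-sets",
      build_snp_sets(panel, catalog, pathways = selected, combine = combine))
    sets <- sets[setdiff(names(sets), "other")]
    sets <- sets[lengths(sets) > 0]
    scores <- stage("scores",
      compute_scores(dat, weights, snp_sets = sets, standardize = TRUE))
    fit_dat <- dplyr::bind_cols(scores,
                                dat[c("D", exposure, covars)])
    score_cols <- setdiff(names(scores), "id")
    out$interactions <- purrr::map_dfr(score_cols, function(sc) {
      fit <- stage(paste0("interaction-", sc),
        fit_interaction(fit_dat, score = sc, exposure = exposure,
                        covariates = covars))
      td <- tidy(fit)
      ge <- td[td$term == "score:exposure", ]
      tibble(score = sc, or_gxe = ge$or, conf.low = ge$conf.low,
             conf.high = ge$conf.high, p_lrt = fit$p_lrt, p_wald = fit$p_wald,
             n = fit$n_used)
    })
    # raw p-values are the default (pathway scores are constructed a
    # priori); an adjustment column is added on request
    if (!is.null(cfg$p_adjust)) {
      out$interactions$p_adjusted <- p.adjust(out$interactions$p_lrt,
                                              method = cfg$p_adjust)
    }
    out$enrichment <- enr
    out$scores <- scores
    readr::write_tsv(enr, file.path(cfg$out_dir, "enrichment.tsv"), progress = FALSE)
    readr::write_tsv(as_tibble(as.data.frame(scores)),
                     file.path(cfg$out_dir, "scores.tsv"), progress = FALSE)
    readr::write_tsv(out$interactions,
                     file.path(cfg$out_dir, "interactions.tsv"), progress = FALSE)
    log_lines <- c(log_lines,
                   sprintf("panel=%d SNPs, pathways tested=%d, fdr_threshold=%g",
                           length(panel), nrow(enr), fdr_thr))
  }
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  invisible(out)
}
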