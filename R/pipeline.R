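#' Build a run configuration for the full pipeline
#'
#' Collects the input paths, comparative mode and thresholds used by
#' [run_all()]. A configuration can also be read from a YAML file with
#' [read_run_config()]; [run_all()] snapshots the configuration it ran
#' with into the run directory.
#'
#' @param manifest Path to the sample manifest TSV.
#' @param genes_bed Path to the gene model BED.
#' @param gmt Optional path to gene-set annotations (GMT); when absent the
#'   enrichment stage is skipped with a warning.
#' @param reference_list Optional path to a reference gene list (one
#'   symbol per line) for the list-overlap stage.
#' @param expression,expression_groups Optional paths to an expression
#'   matrix and its sample-to-group map; when absent the cross-reference
#'   stage is skipped.
#' @param mode Comparative mode, `"within_patient"` or `"cross_group"`.
#' @param min_samples Recurrence threshold for the group-exclusive and
#'   recurrent-CNA filters (default 2).
#' @param fdr_threshold Deregulation threshold for the expression
#'   cross-reference (default 0.05).
#' @param r1_scope Scope of the remodelled-only single-sample rule
#'   (`"group"` or `"cohort"`).
#' @param seed Seed recorded with the run (simulation, when used, draws
#'   from it).
#' @return A list of class `run_config`.
#' @export
run_config <- function(manifest, genes_bed, gmt = NULL,
                       reference_list = NULL, expression = NULL,
                       expression_groups = NULL,
                       mode = c("within_patient", "cross_group"),
                       min_samples = 2, fdr_threshold = 0.05,
                       r1_scope = c("group", "cohort"), seed = 1) {
  config <- list(manifest = manifest, genes_bed = genes_bed, gmt = gmt,
                 reference_list = reference_list, expression = expression,
                 expression_groups = expression_groups,
                 mode = match.arg(mode), min_samples = min_samples,
                 fdr_threshold = fdr_threshold,
                 r1_scope = match.arg(r1_scope), seed = as.integer(seed))
  for (f in c("manifest", "genes_bed")) {
    if (!file.exists(config[[f]])) {
      stop("run_config: required input '", f, "' not found: ", config[[f]])
    }
  }
  if (config$min_samples < 1) stop("run_config: min_samples must be >= 1")
  if (config$fdr_threshold <= 0 || config$fdr_threshold > 1) {
    stop("run_config: fdr_threshold must be in (0, 1]")
  }
  structure(config, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [run_config()].
#' @return A validated `run_config`. Relative input paths are resolved
#'   against the YAML file's directory.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(path)
  for (f in c("manifest", "genes_bed", "gmt", "reference_list",
              "expression", "expression_groups")) {
    if (!is.null(raw[[f]]) && !grepl("^(/|[A-Za-z]:)", raw[[f]])) {
      raw[[f]] <- file.path(base, raw[[f]])
    }
  }
  do.call(run_config, raw)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full comparative pipeline
#'
#' Orchestrates the stages over one cohort: load the manifest, variants
#' and CNA segments; global and comparative variant counting plus the
#' remodelled-only and group-exclusive gene filters; global and
#' comparative CNA counting, group-level Venn partitions, unique
#' fractions and recurrent-CNA gene lists; variant/CNA gene integration,
#' gene-set enrichment, reference-list overlap and expression
#' cross-referencing; and the tabular report (stratum summaries and
#' t-tests). All outputs are TSV files in `out_dir`, together with a YAML
#' snapshot of the configuration and a `run_log.txt`. Reruns with the
#' same configuration produce identical outputs.
#'
#' @param config A `run_config` (or path to a YAML file for
#'   [read_run_config()]).
#' @param out_dir Output directory, created if needed.
#' @param verbose Log stage progress to the console (default TRUE).
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_all <- function(config, out_dir, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }
  set.seed(config$seed)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))

  say("loading cohort from ", config$manifest)
  cohort <- load_cohort(config$manifest, config$genes_bed)

  say("variant analysis (mode = ", config$mode, ")")
  v_global <- count_variants(cohort, "global")
  v_comp <- count_variants(cohort, "comparative", mode = config$mode)
  goi_var <- remodelled_only_genes(cohort, r1_scope = config$r1_scope)
  goi_gx <- group_exclusive_recurrent_genes(cohort,
                                            min_samples = config$min_samples)
  write_tsv(v_global$per_sample,
            file.path(out_dir, "variant_counts_global.tsv"))
  write_tsv(v_comp$per_sample,
            file.path(out_dir, "variant_counts_comparative.tsv"))
  goi_gx_out <- goi_gx
  names(goi_gx_out)[names(goi_gx_out) == "n_patients"] <- "n_support"
  common <- c("gene", "category", "group", "supporting_samples", "keys")
  write_tsv(rbind(
    cbind(goi_var[common], flag = ifelse(goi_var$high_impact,
                                         "underline", "")),
    cbind(goi_gx_out[common], flag = ifelse(goi_gx_out$bold, "bold", ""))),
    file.path(out_dir, "goi_variants.tsv"))

  say("CNA analysis")
  c_global <- count_cna(cohort, "global")
  c_comp <- count_cna(cohort, "comparative", mode = config$mode)
  write_tsv(c_global$per_sample, file.path(out_dir, "cna_counts_global.tsv"))
  write_tsv(c_comp$per_sample,
            file.path(out_dir, "cna_counts_comparative.tsv"))
  gsets <- gene_cna_sets(cohort)
  venns <- list(
    COPD_R_vs_COPD_N = venn(gsets$per_stratum[["COPD.R"]],
                            gsets$per_stratum[["COPD.N"]]),
    NONCOPD_R_vs_NONCOPD_N = venn(gsets$per_stratum[["NON_COPD.R"]],
                                  gsets$per_stratum[["NON_COPD.N"]]))
  venn_df <- do.call(rbind, lapply(names(venns), function(nm) {
    s <- venns[[nm]]$sizes
    data.frame(comparison = nm, only_target = s[["only_a"]],
               shared = s[["shared"]], only_reference = s[["only_b"]],
               stringsAsFactors = FALSE)
  }))
  write_tsv(venn_df, file.path(out_dir, "venn.tsv"))
  locus_sets <- sample_locus_sets(cohort)
  m <- cohort$manifest
  stratum_loci <- function(g, mo) {
    unique(unlist(locus_sets[m$sample_id[m$group == g & m$morphology == mo]],
                  use.names = FALSE))
  }
  uf <- data.frame(
    comparison = c("COPD_R_vs_COPD_N", "NONCOPD_R_vs_NONCOPD_N"),
    unique_pct_genes = c(
      unique_fraction(gsets$per_stratum[["COPD.R"]],
                      gsets$per_stratum[["COPD.N"]]),
      unique_fraction(gsets$per_stratum[["NON_COPD.R"]],
                      gsets$per_stratum[["NON_COPD.N"]])),
    unique_pct_loci = c(
      unique_fraction(stratum_loci("COPD", "R"), stratum_loci("COPD", "N")),
      unique_fraction(stratum_loci("NON_COPD", "R"),
                      stratum_loci("NON_COPD", "N"))),
    stringsAsFactors = FALSE)
  write_tsv(uf, file.path(out_dir, "unique_fractions.tsv"))
  goi_cna <- rbind(
    recurrent_cna_genes(cohort, "COPD_R_vs_COPD_N",
                        min_samples = config$min_samples),
    recurrent_cna_genes(cohort, "COPD_R_vs_NONCOPD_R",
                        min_samples = config$min_samples))
  write_tsv(goi_cna, file.path(out_dir, "goi_cna.tsv"))

  say("integration")
  variant_goi_genes <- unique(c(goi_var$gene, goi_gx$gene))
  cna_goi_genes <- unique(goi_cna$gene)
  joint <- joint_genes(variant_goi_genes, cna_goi_genes)
  write_tsv(data.frame(
    gene = joint$union,
    in_variants = joint$union %in% variant_goi_genes,
    in_cna = joint$union %in% cna_goi_genes,
    joint = joint$union %in% joint$intersection),
    file.path(out_dir, "joint_genes.tsv"))
  enr <- NULL
  if (!is.null(config$gmt) && file.exists(config$gmt)) {
    enr <- enrich(joint$union, read_gmt(config$gmt),
                  background = cohort$gene_models$gene)
    write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  } else {
    warning("no GMT supplied; enrichment stage skipped")
    say("enrichment stage skipped (no GMT)")
  }
  overlap <- NULL
  if (!is.null(config$reference_list) &&
      file.exists(config$reference_list) && length(joint$union) > 0) {
    ref <- toupper(readLines(config$reference_list))
    overlap <- list_overlap(joint$union, ref)
    write_tsv(data.frame(gene = overlap$genes, stringsAsFactors = FALSE),
              file.path(out_dir, "overlap_genes.tsv"))
    write_tsv(data.frame(n_query = length(joint$union),
                         n_overlap = length(overlap$genes),
                         percentage = overlap$percentage),
              file.path(out_dir, "overlap.tsv"))
  }
  crossref <- NULL
  if (!is.null(config$expression) && file.exists(config$expression)) {
    expr <- read_expression(config$expression, config$expression_groups)
    crossref <- expression_crossref(joint$union, expr,
                                    fdr_threshold = config$fdr_threshold)
    write_tsv(crossref$results,
              file.path(out_dir, "expression_crossref.tsv"))
  } else {
    say("expression stage skipped (no matrix)")
  }

  say("report")
  summaries <- rbind(
    cbind(analysis = "variants_global", v_global$summary),
    cbind(analysis = "variants_comparative", v_comp$summary),
    cbind(analysis = "cna_global", c_global$summary),
    cbind(analysis = "cna_comparative", c_comp$summary))
  write_tsv(summaries, file.path(out_dir, "summary.tsv"))
  tests <- rbind(
    cbind(analysis = "variants_comparative",
          stratum_tests(v_comp$per_sample, "n_positions")),
    cbind(analysis = "cna_comparative",
          stratum_tests(c_comp$per_sample, "n_loci")))
  write_tsv(tests, file.path(out_dir, "tests.tsv"))
  say("done")
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(cohort = cohort, variant_counts = list(global = v_global,
                                                        comparative = v_comp),
                 goi_variants = goi_var, goi_group_exclusive = goi_gx,
                 cna_counts = list(global = c_global, comparative = c_comp),
                 venn = venns, unique_fractions = uf, goi_cna = goi_cna,
                 joint = joint, enrichment = enr, overlap = overlap,
                 crossref = crossref, summary = summaries, tests = tests))
}
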