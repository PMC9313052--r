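#' Configuration for the synthetic paired-morphology exome cohort
#'
#' The generator emulates the statistical structure the downstream
#' analyses assume: per patient, a large germline background of variant
#' calls identical between the non-remodelled (N) and remodelled (R)
#' sample; a minority of morphology-private calls; CNA segments whose
#' coordinates recur exactly between a patient's N and R; and an excess of
#' R-unique CNA in the COPD group. Defaults mirror the shape of the study
#' cohort this pipeline was built for: 4 non-COPD + 3 COPD patients,
#' roughly 465 variants and 100-260 CNA loci per sample.
#'
#' Remodelled samples' morphology-private calls are exactly the planted
#' remodelled-only calls recorded in the truth tables (any private R call
#' satisfies the remodelled-only predicate by definition, so they are all
#' tracked); generic untracked private calls are placed in N samples only.
#' All variant positions are drawn without replacement across the cohort
#' and CNA gene territories are allocated without replacement across
#' samples, so the only recurrent alterations are the deliberately planted
#' ones and truth recovery is exact. See the methods vignette.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_patients Named integer vector, patients per group
#'   (default 4 non-COPD, 3 COPD).
#' @param n_genes Number of non-overlapping gene models.
#' @param genome Named numeric vector of chromosome lengths (bp).
#' @param germline_shared_per_patient Variant keys identical between a
#'   patient's N and R samples.
#' @param private_variants_per_sample Untracked private calls per N sample.
#' @param remodelled_only_planted Named vector: planted remodelled-only
#'   calls per patient, by group.
#' @param group_exclusive_recurrent_planted Named vector: planted variant
#'   keys shared by the N and R of 2-3 patients of one group and absent
#'   from the other.
#' @param high_impact_prob Probability that a planted call draws a
#'   HIGH-impact consequence term (default 0.2).
#' @param cna_background_per_sample CNA segments shared (exact
#'   coordinates) between a patient's N and R.
#' @param cna_r_unique_mean Poisson mean of R-unique segments in non-COPD
#'   remodelled samples.
#' @param copd_r_unique_cna_excess Multiplicative factor (>= 1) applied to
#'   that mean in COPD remodelled samples (default 2.4, the fold increase
#'   the pipeline is designed to detect).
#' @param cna_recurrent_planted Genes planted with R-unique CNA in 2 or 3
#'   COPD patients (default 10; those in all 3 are the "bold" truth).
#' @param expression List: `n_samples_per_group`, `n_de_genes`,
#'   `log2fc_effect`, `noise_sd` for the whole-lung expression matrix.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_patients = c(NON_COPD = 4, COPD = 3),
                       n_genes = 2000,
                       genome = c(chr1 = 12e6, chr2 = 10e6, chr3 = 8e6),
                       germline_shared_per_patient = 440,
                       private_variants_per_sample = 25,
                       remodelled_only_planted = c(NON_COPD = 15, COPD = 40),
                       group_exclusive_recurrent_planted =
                         c(NON_COPD = 4, COPD = 6),
                       high_impact_prob = 0.2,
                       cna_background_per_sample = 100,
                       cna_r_unique_mean = 65,
                       copd_r_unique_cna_excess = 2.4,
                       cna_recurrent_planted = 10,
                       expression = list(n_samples_per_group = 20,
                                         n_de_genes = 30,
                                         log2fc_effect = 1.0,
                                         noise_sd = 0.2)) {
  config <- list(seed = as.integer(seed), n_patients = n_patients,
                 n_genes = n_genes, genome = genome,
                 germline_shared_per_patient = germline_shared_per_patient,
                 private_variants_per_sample = private_variants_per_sample,
                 remodelled_only_planted = remodelled_only_planted,
                 group_exclusive_recurrent_planted =
                   group_exclusive_recurrent_planted,
                 high_impact_prob = high_impact_prob,
                 cna_background_per_sample = cna_background_per_sample,
                 cna_r_unique_mean = cna_r_unique_mean,
                 copd_r_unique_cna_excess = copd_r_unique_cna_excess,
                 cna_recurrent_planted = cna_recurrent_planted,
                 expression = expression)
  validate_sim_config(config)
  structure(config, class = "sim_config")
}

validate_sim_config <- function(config) {
  counts <- c(config$n_genes, config$germline_shared_per_patient,
              config$private_variants_per_sample,
              config$remodelled_only_planted,
              config$group_exclusive_recurrent_planted,
              config$cna_background_per_sample, config$cna_r_unique_mean,
              config$cna_recurrent_planted)
  if (any(counts < 0)) stop("sim_config: all counts must be >= 0")
  if (config$copd_r_unique_cna_excess < 1) {
    stop("sim_config: copd_r_unique_cna_excess must be >= 1")
  }
  if (config$high_impact_prob < 0 || config$high_impact_prob > 1) {
    stop("sim_config: high_impact_prob must be in [0, 1]")
  }
  if (!identical(sort(names(config$n_patients)), sort(rp_groups))) {
    stop("sim_config: n_patients must be named NON_COPD and COPD")
  }
  if (any(config$n_patients < 1)) {
    stop("sim_config: at least one patient per group")
  }
  invisible(config)
}

#' Generate non-overlapping gene models for a synthetic genome
#'
#' Genes are spread over the configured chromosomes proportionally to
#' chromosome length, one gene per regularly spaced slot with a random
#' length (1.5-6 kb) and offset inside the slot, so models are disjoint by
#' construction and placement is deterministic given the seed.
#'
#' @param config A `sim_config`.
#' @return A gene model data frame (`gene`, `chrom`, `start`, `end`,
#'   `strand`; 0-based half-open).
#' @export
generate_gene_models <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  if (n == 0) {
    return(data.frame(gene = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  lens <- config$genome
  alloc <- floor(n * lens / sum(lens))
  rem <- n - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1
  rows <- list()
  idx <- 0
  for (ch in names(lens)) {
    n_c <- alloc[[ch]]
    if (n_c == 0) next
    spacing <- floor(lens[[ch]] / n_c)
    max_len <- min(6000, spacing - 200)
    if (max_len < 1500) {
      stop("genome too small for ", n, " gene models")
    }
    glen <- sample(1500:max_len, n_c, replace = TRUE)
    offset <- vapply(spacing - glen,
                     function(room) sample.int(room, 1) - 1L, 0L)
    start <- as.integer((seq_len(n_c) - 1) * spacing + offset)
    idx_c <- idx + seq_len(n_c)
    rows[[ch]] <- data.frame(
      gene = sprintf("G%05d", idx_c), chrom = ch, start = start,
      end = start + glen,
      strand = sample(c("+", "-"), n_c, replace = TRUE),
      stringsAsFactors = FALSE)
    idx <- idx + n_c
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Consequence vocabulary used by the generator, split by impact tier.
sim_conseq_high <- c("stop_gained", "frameshift_variant",
                     "splice_donor_variant")
sim_conseq_other <- c("missense_variant", "missense_variant",
                      "inframe_deletion", "synonymous_variant",
                      "splice_region_variant", "intron_variant")

## Draw alleles and consequence terms for n variant keys.
draw_alleles <- function(n, high_impact_prob) {
  bases <- c("A", "C", "G", "T")
  vtype <- sample(c("SNV", "INS", "DEL"), n, replace = TRUE,
                  prob = c(0.8, 0.1, 0.1))
  ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    b <- sample(bases, 1)
    if (vtype[i] == "SNV") {
      ref[i] <- b
      alt[i] <- sample(setdiff(bases, b), 1)
    } else {
      extra <- paste(sample(bases, sample(1:3, 1), replace = TRUE),
                     collapse = "")
      if (vtype[i] == "INS") {
        ref[i] <- b; alt[i] <- paste0(b, extra)
      } else {
        ref[i] <- paste0(b, extra); alt[i] <- b
      }
    }
  }
  high <- stats::runif(n) < high_impact_prob
  conseq <- character(n)
  conseq[high] <- sample(sim_conseq_high, sum(high), replace = TRUE)
  conseq[!high] <- sample(sim_conseq_other, sum(!high), replace = TRUE)
  data.frame(ref = ref, alt = alt, consequence = conseq,
             stringsAsFactors = FALSE)
}

#' Simulate a log2 expression matrix with planted differential genes
#'
#' Each gene gets a baseline drawn once, Gaussian noise per sample, and,
#' for the differential genes, a signed log2 fold-change shift added to
#' the COPD group.
#'
#' @param genes Character vector of gene symbols (matrix rows).
#' @param n_samples_per_group Samples per clinical group.
#' @param de_genes Named numeric vector: gene -> signed log2 fold change.
#' @param noise_sd Gaussian noise standard deviation (log2 units).
#' @param seed Optional seed; when NULL the current RNG stream is used.
#' @return A list with `expr` (an `rp_expression`) and `truth`
#'   (data frame gene, log2fc).
#' @export
simulate_expression <- function(genes, n_samples_per_group, de_genes,
                                noise_sd, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(names(de_genes) %in% genes))
  n <- n_samples_per_group
  samples <- c(sprintf("NC%03d", seq_len(n)), sprintf("CP%03d", seq_len(n)))
  group_map <- stats::setNames(rep(rp_groups, each = n), samples)
  baseline <- stats::rnorm(length(genes), mean = 8, sd = 2)
  values <- matrix(stats::rnorm(length(genes) * 2 * n, sd = noise_sd),
                   nrow = length(genes), ncol = 2 * n,
                   dimnames = list(genes, samples)) + baseline
  if (length(de_genes) > 0) {
    copd_cols <- which(group_map == "COPD")
    values[names(de_genes), copd_cols] <-
      values[names(de_genes), copd_cols] + de_genes
  }
  values <- round(values, 6)
  expr <- structure(list(values = values, group_map = group_map),
                    class = "rp_expression")
  truth <- data.frame(gene = names(de_genes), log2fc = unname(de_genes),
                      stringsAsFactors = FALSE)
  list(expr = expr, truth = truth)
}

#' Generate a synthetic cohort with truth tables
#'
#' Writes a complete, self-consistent input set for the pipeline into
#' `out_dir`: `manifest.tsv`, per-sample `*.vcf` and `*.seg` files,
#' `genes.bed`, `expression.tsv` + `expression_groups.tsv`, `sets.gmt`
#' (one planted gene-set term among decoys), `reference_list.txt` (a
#' synthetic stand-in for a curated protein list, partly overlapping the
#' planted genes), and `truth/*.tsv` tables recording every planted
#' alteration. Identical configurations (including the seed) produce
#' byte-identical files.
#'
#' @param config A `sim_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `config`, `manifest`,
#'   `gene_models`, `truth` (remodelled_only, group_exclusive,
#'   cna_recurrent, de_genes data frames) and `paths`.
#' @export
generate_cohort <- function(config, out_dir) {
  validate_sim_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  gene_models <- generate_gene_models(config)  # seeds the RNG stream
  if (nrow(gene_models) == 0) stop("generate_cohort: n_genes must be > 0")

  groups_of_patients <- rep(rp_groups, times = config$n_patients[rp_groups])
  patient_ids <- c(sprintf("A%d", seq_len(config$n_patients[["NON_COPD"]])),
                   sprintf("B%d", seq_len(config$n_patients[["COPD"]])))
  names(groups_of_patients) <- patient_ids

  ## -- variant keys ---------------------------------------------------------
  ## All positions are drawn without replacement from the concatenated gene
  ## bodies, so no two independently placed calls ever share a key.
  body_len <- gene_models$end - gene_models$start
  cum <- cumsum(body_len)
  total_body <- cum[length(cum)]

  gx_planted <- list()  # group -> data.frame(key_id, patients)
  n_gx_per_patient <- stats::setNames(rep(0L, length(patient_ids)),
                                      patient_ids)
  gx_support <- list()
  for (g in rp_groups) {
    n_k <- config$group_exclusive_recurrent_planted[[g]]
    pats_g <- patient_ids[groups_of_patients == g]
    supports <- list()
    if (n_k > 0) {
      sizes <- rep(c(2L, 3L), length.out = n_k)
      sizes <- pmin(sizes, length(pats_g))
      for (j in seq_len(n_k)) {
        supp <- sort(pats_g[sample.int(length(pats_g), sizes[j])])
        supports[[j]] <- supp
        n_gx_per_patient[supp] <- n_gx_per_patient[supp] + 1L
      }
    }
    gx_support[[g]] <- supports
  }
  ger_fresh <- config$germline_shared_per_patient - n_gx_per_patient
  if (any(ger_fresh < 0)) {
    stop("germline_shared_per_patient too small for the planted ",
         "group-exclusive keys")
  }
  ro_counts <- stats::setNames(
    config$remodelled_only_planted[groups_of_patients], patient_ids)
  n_gx_total <- sum(lengths(gx_support))
  n_priv <- config$private_variants_per_sample
  total_needed <- sum(ger_fresh) + length(patient_ids) * n_priv +
    sum(ro_counts) + n_gx_total
  if (total_needed > total_body) stop("genome too small for variant load")

  pool <- sample.int(total_body, total_needed)
  gene_row <- findInterval(pool - 1, c(0, cum)) # row index per position
  keys <- data.frame(
    chrom = gene_models$chrom[gene_row],
    pos = as.integer(gene_models$start[gene_row] +
                       (pool - c(0, cum)[gene_row])),
    gene = gene_models$gene[gene_row], stringsAsFactors = FALSE)
  keys <- cbind(keys, draw_alleles(nrow(keys), config$high_impact_prob))
  cursor <- 0L
  take <- function(n) {
    out <- keys[cursor + seq_len(n), , drop = FALSE]
    cursor <<- cursor + as.integer(n)
    out
  }

  gx_rows <- list()
  gx_keys_by_patient <- stats::setNames(
    vector("list", length(patient_ids)), patient_ids)
  for (g in rp_groups) {
    for (supp in gx_support[[g]]) {
      k <- take(1L)
      for (p in supp) {
        gx_keys_by_patient[[p]] <- rbind(gx_keys_by_patient[[p]], k)
      }
      gx_rows[[length(gx_rows) + 1]] <- data.frame(
        group = g, gene = k$gene,
        key = variant_key(k$chrom, k$pos, k$ref, k$alt),
        n_patients = length(supp),
        patients = paste(supp, collapse = ","), stringsAsFactors = FALSE)
    }
  }

  sample_calls <- list()
  ro_rows <- list()
  manifest_rows <- list()
  for (p in patient_ids) {
    g <- groups_of_patients[[p]]
    germline <- rbind(take(ger_fresh[[p]]), gx_keys_by_patient[[p]])
    privates <- take(n_priv)
    planted_ro <- take(ro_counts[[p]])
    n_id <- paste0(p, "_N"); r_id <- paste0(p, "_R")
    sample_calls[[n_id]] <- rbind(germline, privates)
    sample_calls[[r_id]] <- rbind(germline, planted_ro)
    if (nrow(planted_ro) > 0) {
      ro_rows[[p]] <- data.frame(
        patient_id = p, group = g, gene = planted_ro$gene,
        key = variant_key(planted_ro$chrom, planted_ro$pos,
                          planted_ro$ref, planted_ro$alt),
        stringsAsFactors = FALSE)
    }
    for (mo in c("N", "R")) {
      sid <- paste0(p, "_", mo)
      manifest_rows[[sid]] <- data.frame(
        sample_id = sid, patient_id = p, group = g, morphology = mo,
        variant_path = paste0(sid, ".vcf"), cna_path = paste0(sid, ".seg"),
        stringsAsFactors = FALSE)
    }
  }

  ## -- CNA segments ---------------------------------------------------------
  ## Each segment sits inside one gene territory with a patient-specific
  ## jitter; territories are handed out without replacement, except the
  ## deliberately planted recurrent genes.
  n_planted_cna <- config$cna_recurrent_planted
  copd_pats <- patient_ids[groups_of_patients == "COPD"]
  all_gene_syms <- gene_models$gene
  planted_cna_genes <- if (n_planted_cna > 0) {
    sort(all_gene_syms[sample.int(length(all_gene_syms), n_planted_cna)])
  } else character(0)
  cna_pool <- setdiff(all_gene_syms, planted_cna_genes)
  cna_pool <- cna_pool[sample.int(length(cna_pool))]
  cna_cursor <- 0L
  take_genes <- function(n) {
    if (cna_cursor + n > length(cna_pool)) {
      stop("n_genes too small for the configured CNA load")
    }
    out <- cna_pool[cna_cursor + seq_len(n)]
    cna_cursor <<- cna_cursor + as.integer(n)
    out
  }
  gene_segment <- function(gene_syms) {
    gm <- gene_models[match(gene_syms, gene_models$gene), , drop = FALSE]
    s <- gm$start + sample.int(150, nrow(gm), replace = TRUE) - 1L
    e <- gm$end - (sample.int(150, nrow(gm), replace = TRUE) - 1L)
    data.frame(chrom = gm$chrom, start = as.integer(s), end = as.integer(e),
               copy_state = sample(c("GAIN", "LOSS"), nrow(gm),
                                   replace = TRUE),
               gene = gene_syms, stringsAsFactors = FALSE)
  }
  cna_support <- list()  # planted gene -> supporting patients
  if (n_planted_cna > 0) {
    sizes <- rep(c(min(3L, length(copd_pats)), 2L),
                 length.out = n_planted_cna)
    for (j in seq_along(planted_cna_genes)) {
      cna_support[[planted_cna_genes[j]]] <-
        sort(copd_pats[sample.int(length(copd_pats), sizes[j])])
    }
  }
  sample_segs <- list()
  for (p in patient_ids) {
    g <- groups_of_patients[[p]]
    bg <- gene_segment(take_genes(config$cna_background_per_sample))
    u_mean <- config$cna_r_unique_mean *
      if (g == "COPD") config$copd_r_unique_cna_excess else 1
    n_u <- stats::rpois(1, u_mean)
    uniq <- gene_segment(take_genes(n_u))
    planted_here <- names(cna_support)[vapply(cna_support, function(s)
      p %in% s, TRUE)]
    planted_seg <- gene_segment(planted_here)
    sample_segs[[paste0(p, "_N")]] <- bg
    sample_segs[[paste0(p, "_R")]] <- rbind(bg, uniq, planted_seg)
  }
  cna_truth <- if (length(cna_support) > 0) {
    data.frame(gene = names(cna_support),
               n_samples = lengths(cna_support),
               patients = vapply(cna_support, paste, "", collapse = ","),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(0), n_samples = integer(0),
               patients = character(0), stringsAsFactors = FALSE)
  }
  cna_truth <- cna_truth[order(cna_truth$gene), , drop = FALSE]
  rownames(cna_truth) <- NULL

  ## -- expression -----------------------------------------------------------
  ex <- config$expression
  ro_truth <- if (length(ro_rows) > 0) do.call(rbind, ro_rows) else
    data.frame(patient_id = character(0), group = character(0),
               gene = character(0), key = character(0),
               stringsAsFactors = FALSE)
  rownames(ro_truth) <- NULL
  planted_pool <- unique(c(cna_truth$gene, ro_truth$gene))
  n_de <- min(ex$n_de_genes, length(all_gene_syms))
  de_from_planted <- planted_pool[seq_len(min(length(planted_pool), n_de))]
  extra <- setdiff(all_gene_syms, de_from_planted)
  n_extra <- n_de - length(de_from_planted)
  de_genes_v <- c(de_from_planted,
                  if (n_extra > 0) extra[sample.int(length(extra), n_extra)])
  de_lfc <- stats::setNames(
    ex$log2fc_effect * sample(c(-1, 1), length(de_genes_v), replace = TRUE),
    de_genes_v)
  sim_ex <- simulate_expression(all_gene_syms, ex$n_samples_per_group,
                                de_lfc, ex$noise_sd)

  ## -- gene sets and reference list ----------------------------------------
  gmt <- list(PLANTED_SET = sort(unique(c(cna_truth$gene,
                                          utils::head(ro_truth$gene, 20)))))
  for (j in 1:9) {
    gmt[[sprintf("DECOY_SET%02d", j)]] <-
      sort(all_gene_syms[sample.int(length(all_gene_syms),
                                    sample(40:80, 1))])
  }
  ref_planted <- planted_pool[seq_len(ceiling(length(planted_pool) / 2))]
  ref_list <- sort(unique(c(
    ref_planted,
    all_gene_syms[sample.int(length(all_gene_syms), 100)])))

  ## -- write everything -----------------------------------------------------
  manifest <- do.call(rbind, manifest_rows)
  rownames(manifest) <- NULL
  p_manifest <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, p_manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (sid in manifest$sample_id) {
    calls <- sample_calls[[sid]]
    write_vcf(calls, file.path(out_dir, paste0(sid, ".vcf")))
    segs <- sample_segs[[sid]]
    segs <- data.frame(sample = sid, segs[c("chrom", "start", "end",
                                            "copy_state")],
                       stringsAsFactors = FALSE)
    segs <- segs[order(segs$chrom, segs$start), , drop = FALSE]
    write_seg(segs, file.path(out_dir, paste0(sid, ".seg")))
  }
  p_bed <- file.path(out_dir, "genes.bed")
  write_gene_bed(gene_models, p_bed)
  p_expr <- file.path(out_dir, "expression.tsv")
  p_groups <- file.path(out_dir, "expression_groups.tsv")
  write_expression(sim_ex$expr, p_expr, p_groups)
  p_gmt <- file.path(out_dir, "sets.gmt")
  writeLines(vapply(names(gmt), function(tm) {
    paste(c(tm, "synthetic gene set", gmt[[tm]]), collapse = "\t")
  }, ""), p_gmt)
  p_ref <- file.path(out_dir, "reference_list.txt")
  writeLines(ref_list, p_ref)

  gx_truth <- if (length(gx_rows) > 0) do.call(rbind, gx_rows) else
    data.frame(group = character(0), gene = character(0), key = character(0),
               n_patients = integer(0), patients = character(0),
               stringsAsFactors = FALSE)
  rownames(gx_truth) <- NULL
  truth <- list(remodelled_only = ro_truth, group_exclusive = gx_truth,
                cna_recurrent = cna_truth, de_genes = sim_ex$truth)
  for (nm in names(truth)) {
    utils::write.table(truth[[nm]],
                       file.path(out_dir, "truth", paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  class(manifest) <- c("rp_manifest", "data.frame")
  manifest$variant_path <- file.path(out_dir,
                                     paste0(manifest$sample_id, ".vcf"))
  manifest$cna_path <- file.path(out_dir, paste0(manifest$sample_id, ".seg"))
  invisible(list(dir = out_dir, config = config, manifest = manifest,
                 gene_models = gene_models, truth = truth,
                 paths = list(manifest = p_manifest, genes_bed = p_bed,
                              expression = p_expr, groups = p_groups,
                              gmt = p_gmt, reference_list = p_ref)))
}
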