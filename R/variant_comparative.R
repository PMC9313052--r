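#' Reduce a variant to its minimal (normalized) representation
#'
#' Identity of small variants across samples is defined on the normalized
#' (chrom, pos, ref, alt) tuple, so that the same substitution or indel
#' written with padding bases in two call sets still matches. The common
#' suffix is trimmed first, then the common prefix is trimmed with the
#' position advanced; both alleles always retain at least one base.
#' Vectorized over its arguments.
#'
#' @param chrom Chromosome name(s).
#' @param pos 1-based VCF position(s).
#' @param ref Reference allele(s).
#' @param alt Single alternate allele(s); multi-allelic input must be split
#'   beforehand.
#' @return A list with components `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' normalize_variant("chr1", 100, "GCA", "GCC")  # -> pos 102, A, C
#' @export
normalize_variant <- function(chrom, pos, ref, alt) {
  n <- length(ref)
  pos <- as.integer(pos)
  if (any(ref == alt)) stop("ref == alt: not a variant")
  out_pos <- pos; out_ref <- ref; out_alt <- alt
  for (i in seq_len(n)) {
    r <- strsplit(out_ref[i], "", fixed = TRUE)[[1]]
    a <- strsplit(out_alt[i], "", fixed = TRUE)[[1]]
    # suffix trim
    while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # prefix trim, advancing pos
    p <- out_pos[i]
    while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]
      a <- a[-1]
      p <- p + 1L
    }
    out_ref[i] <- paste(r, collapse = "")
    out_alt[i] <- paste(a, collapse = "")
    out_pos[i] <- p
  }
  if (any(out_ref == out_alt)) stop("ref == alt after trimming: not a variant")
  list(chrom = chrom, pos = out_pos, ref = out_ref, alt = out_alt)
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Default consequence-to-impact tier table
#'
#' Maps controlled-vocabulary consequence terms to the four-tier impact
#' scale used to flag potentially disruptive protein effects. The table is
#' an ordinary data frame and can be edited or replaced by the user; terms
#' not listed fall back to `MODIFIER` with a warning.
#'
#' @return A data frame with columns `consequence` and `impact`.
#' @export
default_impact_table <- function() {
  data.frame(
    consequence = c(
      "stop_gained", "stop_lost", "start_lost", "frameshift_variant",
      "splice_acceptor_variant", "splice_donor_variant",
      "transcript_ablation",
      "missense_variant", "inframe_insertion", "inframe_deletion",
      "protein_altering_variant",
      "synonymous_variant", "stop_retained_variant", "start_retained_variant",
      "splice_region_variant",
      "intron_variant", "upstream_gene_variant", "downstream_gene_variant",
      "5_prime_UTR_variant", "3_prime_UTR_variant", "intergenic_variant",
      "non_coding_transcript_variant"),
    impact = c(rep("HIGH", 7), rep("MODERATE", 4), rep("LOW", 4),
               rep("MODIFIER", 7)),
    stringsAsFactors = FALSE)
}

#' Classify consequence terms into impact tiers
#'
#' @param consequence Character vector of consequence terms.
#' @param tier_table Lookup table, by default [default_impact_table()].
#' @return Character vector over `HIGH`, `MODERATE`, `LOW`, `MODIFIER`.
#'   Unknown terms map to `MODIFIER` with a warning.
#' @export
classify_impact <- function(consequence, tier_table = default_impact_table()) {
  idx <- match(consequence, tier_table$consequence)
  if (anyNA(idx)) {
    warning("unknown consequence term(s) mapped to MODIFIER: ",
            paste(unique(consequence[is.na(idx)]), collapse = ", "))
  }
  ifelse(is.na(idx), "MODIFIER", tier_table$impact[idx])
}

#' Annotate variant calls with overlapping genes
#'
#' A variant with reference allele of length L occupies the half-open
#' interval \[pos-1, pos-1+L) in 0-based coordinates; every gene model
#' overlapping that interval is attached. Intergenic variants keep an
#' empty gene set.
#'
#' @param calls Variant data frame (see [read_vcf()]).
#' @param gene_models Gene model data frame (see [read_gene_bed()]).
#' @return `calls` with the `genes` list column filled.
#' @export
annotate_genes <- function(calls, gene_models) {
  calls$genes <- rep(list(character(0)), nrow(calls))
  if (nrow(calls) == 0 || nrow(gene_models) == 0) return(calls)
  vr <- GenomicRanges::GRanges(
    calls$chrom,
    IRanges::IRanges(start = calls$pos, width = nchar(calls$ref)))
  gr <- GenomicRanges::GRanges(
    gene_models$chrom,
    IRanges::IRanges(start = gene_models$start + 1L, end = gene_models$end))
  hits <- GenomicRanges::findOverlaps(vr, gr)
  if (length(hits) > 0) {
    by_call <- split(gene_models$gene[S4Vectors::subjectHits(hits)],
                     S4Vectors::queryHits(hits))
    for (q in names(by_call)) {
      calls$genes[[as.integer(q)]] <- sort(unique(by_call[[q]]))
    }
  }
  calls
}

## ---- sample key sets ------------------------------------------------------

## Named list sample_id -> character vector of unique normalized variant keys.
sample_key_sets <- function(cohort) {
  lapply(cohort$variants, function(v) {
    unique(variant_key(v$chrom, v$pos, v$ref, v$alt))
  })
}

## Map from variant key to the union of annotated genes across all samples.
key_gene_map <- function(cohort) {
  env <- new.env(parent = emptyenv())
  for (v in cohort$variants) {
    if (nrow(v) == 0) next
    k <- variant_key(v$chrom, v$pos, v$ref, v$alt)
    for (i in seq_len(nrow(v))) {
      env[[k[i]]] <- sort(unique(c(env[[k[i]]], v$genes[[i]])))
    }
  }
  env
}

## Impact per key (max over records sharing the key, HIGH strongest).
key_impact_map <- function(cohort) {
  rank <- stats::setNames(seq_along(rp_impacts), rp_impacts)  # HIGH = 1
  env <- new.env(parent = emptyenv())
  for (v in cohort$variants) {
    if (nrow(v) == 0) next
    k <- variant_key(v$chrom, v$pos, v$ref, v$alt)
    for (i in seq_len(nrow(v))) {
      cur <- env[[k[i]]]
      if (is.null(cur) || rank[[v$impact[i]]] < rank[[cur]]) {
        env[[k[i]]] <- v$impact[i]
      }
    }
  }
  env
}

genes_of_keys <- function(keys, kg) {
  sort(unique(unlist(lapply(keys, function(k) kg[[k]]), use.names = FALSE)))
}

sample_field <- function(cohort, sample_id, field) {
  m <- cohort$manifest
  m[[field]][m$sample_id == sample_id]
}

partner_sample <- function(cohort, sample_id) {
  m <- cohort$manifest
  i <- which(m$sample_id == sample_id)
  j <- which(m$patient_id == m$patient_id[i] &
               m$morphology != m$morphology[i])
  if (length(j) != 1) {
    stop("sample '", sample_id, "' has no unique paired sample")
  }
  m$sample_id[j]
}

## Keys retained by a comparative analysis for one sample.
comparative_keys <- function(cohort, sets, sample_id,
                             mode = c("within_patient", "cross_group")) {
  mode <- match.arg(mode)
  keys <- sets[[sample_id]]
  if (mode == "within_patient") {
    ref <- sets[[partner_sample(cohort, sample_id)]]
  } else {
    m <- cohort$manifest
    other <- m$sample_id[m$group != sample_field(cohort, sample_id, "group")]
    ref <- unique(unlist(sets[other], use.names = FALSE))
  }
  setdiff(keys, ref)
}

#' Count variants per sample, globally or comparatively
#'
#' The global analysis counts every distinct variant position (normalized
#' key) and every gene carrying at least one variant, per sample. The
#' comparative analysis first removes keys identical to a reference set:
#' with `mode = "within_patient"` (the default) the reference is the
#' paired sample of the same patient, so identical positions between a
#' patient's N and R are removed; with `mode = "cross_group"` the
#' reference is the union of all samples of the other clinical group.
#'
#' @param cohort An `rp_cohort`.
#' @param analysis `"global"` or `"comparative"`.
#' @param mode Comparative reference, see above. Ignored for `"global"`.
#' @return A list with `per_sample` (sample_id, patient_id, group,
#'   morphology, n_positions, n_genes) and `summary` (stratum mean and SEM
#'   of both counts, see [stratum_summary()]).
#' @export
count_variants <- function(cohort, analysis = c("global", "comparative"),
                           mode = c("within_patient", "cross_group")) {
  analysis <- match.arg(analysis)
  mode <- match.arg(mode)
  sets <- sample_key_sets(cohort)
  kg <- key_gene_map(cohort)
  m <- cohort$manifest
  n_positions <- integer(nrow(m))
  n_genes <- integer(nrow(m))
  for (i in seq_len(nrow(m))) {
    sid <- m$sample_id[i]
    keys <- if (analysis == "global") sets[[sid]]
            else comparative_keys(cohort, sets, sid, mode)
    n_positions[i] <- length(keys)
    n_genes[i] <- length(genes_of_keys(keys, kg))
  }
  per_sample <- data.frame(sample_id = m$sample_id,
                           patient_id = m$patient_id,
                           group = m$group, morphology = m$morphology,
                           n_positions = n_positions, n_genes = n_genes,
                           stringsAsFactors = FALSE)
  list(per_sample = per_sample,
       summary = stratum_summary(per_sample, c("n_positions", "n_genes")))
}

#' Genes with variants private to a single remodelled sample
#'
#' Implements the remodelled-only filter: a variant key qualifies for a
#' clinical group when it is present in exactly one remodelled (R) sample
#' of that group and absent, at the same normalized position and alleles,
#' from that patient's non-remodelled (N) sample. Genes carrying at least
#' one qualifying key are reported per group, with their supporting sample,
#' keys, and the maximum impact tier; HIGH-impact genes carry the
#' `high_impact` flag (rendered underlined in the tabular reports).
#'
#' @param cohort An `rp_cohort` (paired).
#' @param r1_scope Scope of the "exactly one R sample" restriction:
#'   `"group"` (default) counts R samples within the clinical group,
#'   `"cohort"` across all R samples.
#' @return A data frame with columns `gene`, `category`, `group`,
#'   `supporting_samples`, `keys`, `max_impact`, `high_impact`.
#' @export
remodelled_only_genes <- function(cohort, r1_scope = c("group", "cohort")) {
  r1_scope <- match.arg(r1_scope)
  check_paired(cohort$manifest)
  sets <- sample_key_sets(cohort)
  kg <- key_gene_map(cohort)
  ki <- key_impact_map(cohort)
  m <- cohort$manifest
  rank <- stats::setNames(seq_along(rp_impacts), rp_impacts)
  rows <- list()
  for (g in rp_groups) {
    r_scope_ids <- if (r1_scope == "group") {
      m$sample_id[m$group == g & m$morphology == "R"]
    } else {
      m$sample_id[m$morphology == "R"]
    }
    r_group_ids <- m$sample_id[m$group == g & m$morphology == "R"]
    if (length(r_group_ids) == 0) next
    scope_keys <- unlist(sets[r_scope_ids], use.names = FALSE)
    key_count <- table(scope_keys)
    gene_hits <- list()  # gene -> list(samples, keys)
    for (sid in r_group_ids) {
      n_keys <- sets[[partner_sample(cohort, sid)]]
      for (k in sets[[sid]]) {
        if (key_count[[k]] != 1L) next     # present in >1 R sample in scope
        if (k %in% n_keys) next            # present in the paired N sample
        for (gene in kg[[k]]) {
          h <- gene_hits[[gene]]
          gene_hits[[gene]] <- list(samples = c(h$samples, sid),
                                    keys = c(h$keys, k))
        }
      }
    }
    for (gene in sort(names(gene_hits))) {
      h <- gene_hits[[gene]]
      impacts <- vapply(unique(h$keys), function(k) ki[[k]], "")
      max_imp <- rp_impacts[min(rank[impacts])]
      rows[[length(rows) + 1]] <- data.frame(
        gene = gene, category = "REMODELLED_ONLY", group = g,
        supporting_samples = paste(sort(unique(h$samples)), collapse = ","),
        keys = paste(sort(unique(h$keys)), collapse = ","),
        max_impact = max_imp, high_impact = max_imp == "HIGH",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene = character(0), category = character(0),
                      group = character(0), supporting_samples = character(0),
                      keys = character(0), max_impact = character(0),
                      high_impact = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Genes with recurrent variants exclusive to one clinical group
#'
#' Implements the group-exclusive recurrence filter: a variant key
#' qualifies for a group when it is identical in both the N and the R
#' sample of at least `min_samples` patients of that group and absent from
#' every sample of the other group. Genes carrying a qualifying key are
#' reported with the supporting patients; the `bold` flag marks genes
#' supported by 3 or more patients.
#'
#' @param cohort An `rp_cohort` (paired).
#' @param min_samples Minimum number of supporting patients (default 2).
#' @return A data frame with columns `gene`, `category`, `group`,
#'   `supporting_samples` (patient ids), `keys`, `n_patients`, `bold`.
#' @export
group_exclusive_recurrent_genes <- function(cohort, min_samples = 2) {
  check_paired(cohort$manifest)
  sets <- sample_key_sets(cohort)
  kg <- key_gene_map(cohort)
  m <- cohort$manifest
  rows <- list()
  for (g in rp_groups) {
    patients <- unique(m$patient_id[m$group == g])
    if (length(patients) == 0) next
    other_ids <- m$sample_id[m$group != g]
    other_keys <- unique(unlist(sets[other_ids], use.names = FALSE))
    # keys present in both N and R of each patient
    support <- list()  # key -> patient ids
    for (p in patients) {
      n_id <- m$sample_id[m$patient_id == p & m$morphology == "N"]
      r_id <- m$sample_id[m$patient_id == p & m$morphology == "R"]
      both <- intersect(sets[[n_id]], sets[[r_id]])
      for (k in both) support[[k]] <- c(support[[k]], p)
    }
    gene_hits <- list()
    for (k in names(support)) {
      if (length(support[[k]]) < min_samples) next
      if (k %in% other_keys) next
      for (gene in kg[[k]]) {
        h <- gene_hits[[gene]]
        gene_hits[[gene]] <- list(patients = c(h$patients, support[[k]]),
                                  keys = c(h$keys, k))
      }
    }
    for (gene in sort(names(gene_hits))) {
      h <- gene_hits[[gene]]
      np <- length(unique(h$patients))
      rows[[length(rows) + 1]] <- data.frame(
        gene = gene, category = "GROUP_EXCLUSIVE_RECURRENT", group = g,
        supporting_samples = paste(sort(unique(h$patients)), collapse = ","),
        keys = paste(sort(unique(h$keys)), collapse = ","),
        n_patients = np, bold = np >= 3, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene = character(0), category = character(0),
                      group = character(0), supporting_samples = character(0),
                      keys = character(0), n_patients = integer(0),
                      bold = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
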