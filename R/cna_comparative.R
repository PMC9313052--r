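#' Annotate CNA segments with overlapping genes
#'
#' Attaches to each segment every gene model whose interval overlaps it
#' (0-based half-open on both sides).
#'
#' @param segs Segment data frame (see [read_seg()]).
#' @param gene_models Gene model data frame.
#' @return `segs` with the `genes` list column filled.
#' @export
annotate_segment_genes <- function(segs, gene_models) {
  segs$genes <- rep(list(character(0)), nrow(segs))
  if (nrow(segs) == 0 || nrow(gene_models) == 0) return(segs)
  sr <- GenomicRanges::GRanges(
    segs$chrom, IRanges::IRanges(start = segs$start + 1L, end = segs$end))
  gr <- GenomicRanges::GRanges(
    gene_models$chrom,
    IRanges::IRanges(start = gene_models$start + 1L, end = gene_models$end))
  hits <- GenomicRanges::findOverlaps(sr, gr)
  if (length(hits) > 0) {
    by_seg <- split(gene_models$gene[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits))
    for (q in names(by_seg)) {
      segs$genes[[as.integer(q)]] <- sort(unique(by_seg[[q]]))
    }
  }
  segs
}

## Locus identity is exact coordinate identity (same start and end); the
## copy state is deliberately not part of the key (see the methods
## vignette). `strict = TRUE` adds the copy state to the key.
locus_key <- function(segs, strict = FALSE) {
  if (nrow(segs) == 0) return(character(0))
  k <- paste(segs$chrom, segs$start, segs$end, sep = ":")
  if (strict) k <- paste(k, segs$copy_state, sep = ":")
  k
}

sample_locus_sets <- function(cohort, strict = FALSE) {
  lapply(cohort$cna, function(s) unique(locus_key(s, strict)))
}

## Map locus key -> union of overlapped genes across samples.
locus_gene_map <- function(cohort, strict = FALSE) {
  env <- new.env(parent = emptyenv())
  for (s in cohort$cna) {
    if (nrow(s) == 0) next
    k <- locus_key(s, strict)
    for (i in seq_len(nrow(s))) {
      env[[k[i]]] <- sort(unique(c(env[[k[i]]], s$genes[[i]])))
    }
  }
  env
}

comparative_loci <- function(cohort, sets, sample_id,
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

#' Count CNA loci and genes per sample, globally or comparatively
#'
#' Mirrors [count_variants()] for copy-number segments. A locus is
#' identified by its exact start and end coordinates; the comparative
#' analysis removes loci whose coordinates are identical to a locus of the
#' reference (the paired sample with `mode = "within_patient"`, the union
#' of the other clinical group with `mode = "cross_group"`). Gene counts
#' are the number of distinct genes overlapped by at least one retained
#' segment.
#'
#' @param cohort An `rp_cohort`.
#' @param analysis `"global"` or `"comparative"`.
#' @param mode Comparative reference (ignored for `"global"`).
#' @param strict Also require an identical copy state for locus identity
#'   (default FALSE).
#' @return A list with `per_sample` (n_loci, n_genes per sample) and
#'   `summary` (stratum mean and SEM).
#' @export
count_cna <- function(cohort, analysis = c("global", "comparative"),
                      mode = c("within_patient", "cross_group"),
                      strict = FALSE) {
  analysis <- match.arg(analysis)
  mode <- match.arg(mode)
  sets <- sample_locus_sets(cohort, strict)
  lg <- locus_gene_map(cohort, strict)
  m <- cohort$manifest
  n_loci <- integer(nrow(m))
  n_genes <- integer(nrow(m))
  for (i in seq_len(nrow(m))) {
    sid <- m$sample_id[i]
    keys <- if (analysis == "global") sets[[sid]]
            else comparative_loci(cohort, sets, sid, mode)
    n_loci[i] <- length(keys)
    n_genes[i] <- length(genes_of_keys(keys, lg))
  }
  per_sample <- data.frame(sample_id = m$sample_id,
                           patient_id = m$patient_id,
                           group = m$group, morphology = m$morphology,
                           n_loci = n_loci, n_genes = n_genes,
                           stringsAsFactors = FALSE)
  list(per_sample = per_sample,
       summary = stratum_summary(per_sample, c("n_loci", "n_genes")))
}

#' Per-sample and per-stratum CNA gene sets
#'
#' @param cohort An `rp_cohort`.
#' @return A list with `per_sample` (named list sample_id -> gene vector)
#'   and `per_stratum` (named list "GROUP.MORPHOLOGY" -> union of the
#'   stratum's sample gene sets).
#' @export
gene_cna_sets <- function(cohort) {
  per_sample <- lapply(cohort$cna, function(s) {
    sort(unique(unlist(s$genes, use.names = FALSE)))
  })
  m <- cohort$manifest
  per_stratum <- list()
  for (g in rp_groups) {
    for (mo in rp_morphologies) {
      ids <- m$sample_id[m$group == g & m$morphology == mo]
      if (length(ids) == 0) next
      per_stratum[[paste(g, mo, sep = ".")]] <-
        sort(unique(unlist(per_sample[ids], use.names = FALSE)))
    }
  }
  list(per_sample = per_sample, per_stratum = per_stratum)
}

#' Two-set Venn partition
#'
#' @param set_a,set_b Character vectors (e.g. gene symbols).
#' @return A list with the three member sets `only_a`, `shared`, `only_b`
#'   and their `sizes` (named integer vector). The sizes always satisfy
#'   `|A union B| = only_a + shared + only_b`.
#' @export
venn <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  only_a <- setdiff(set_a, set_b)
  shared <- intersect(set_a, set_b)
  only_b <- setdiff(set_b, set_a)
  list(only_a = sort(only_a), shared = sort(shared), only_b = sort(only_b),
       sizes = c(only_a = length(only_a), shared = length(shared),
                 only_b = length(only_b)))
}

#' Percentage of a set that is absent from a reference set
#'
#' `100 * |target \ reference| / |target|`, reported to one decimal
#' (half-up). Used for statements of the form "x% of CNA were unique in
#' COPD R compared to COPD N".
#'
#' @param target_set Non-empty character vector.
#' @param reference_set Character vector.
#' @return A single percentage, rounded to one decimal.
#' @export
unique_fraction <- function(target_set, reference_set) {
  target_set <- unique(target_set)
  if (length(target_set) == 0) stop("unique_fraction: empty target set")
  pct <- 100 * length(setdiff(target_set, unique(reference_set))) /
    length(target_set)
  round_half_up(pct, 1)
}

#' Genes with recurrent remodelled-specific CNA in the COPD group
#'
#' For each COPD remodelled (R) sample, loci whose exact coordinates also
#' occur in the named reference are removed (comparative removal); a gene
#' qualifies when it is overlapped by a retained segment in at least
#' `min_samples` of the COPD R samples. The reference is either the COPD
#' non-remodelled samples (`"COPD_R_vs_COPD_N"`) or the non-COPD remodelled
#' samples (`"COPD_R_vs_NONCOPD_R"`). Genes supported by 3 or more samples
#' carry the `bold` flag.
#'
#' @param cohort An `rp_cohort`.
#' @param comparison Which reference side to remove against.
#' @param min_samples Minimum number of supporting COPD R samples
#'   (default 2).
#' @param strict Require identical copy state for locus identity.
#' @return A data frame with columns `gene`, `comparison`,
#'   `supporting_samples`, `n_samples`, `bold`.
#' @export
recurrent_cna_genes <- function(cohort,
                                comparison = c("COPD_R_vs_COPD_N",
                                               "COPD_R_vs_NONCOPD_R"),
                                min_samples = 2, strict = FALSE) {
  comparison <- match.arg(comparison)
  m <- cohort$manifest
  sets <- sample_locus_sets(cohort, strict)
  lg <- locus_gene_map(cohort, strict)
  target_ids <- m$sample_id[m$group == "COPD" & m$morphology == "R"]
  ref_ids <- if (comparison == "COPD_R_vs_COPD_N") {
    m$sample_id[m$group == "COPD" & m$morphology == "N"]
  } else {
    m$sample_id[m$group == "NON_COPD" & m$morphology == "R"]
  }
  ref_keys <- unique(unlist(sets[ref_ids], use.names = FALSE))
  support <- list()  # gene -> sample ids
  for (sid in target_ids) {
    retained <- setdiff(sets[[sid]], ref_keys)
    genes <- genes_of_keys(retained, lg)
    for (gene in genes) support[[gene]] <- c(support[[gene]], sid)
  }
  rows <- list()
  for (gene in sort(names(support))) {
    ns <- length(unique(support[[gene]]))
    if (ns < min_samples) next
    rows[[length(rows) + 1]] <- data.frame(
      gene = gene, comparison = comparison,
      supporting_samples = paste(sort(unique(support[[gene]])),
                                 collapse = ","),
      n_samples = ns, bold = ns >= 3, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(gene = character(0), comparison = character(0),
                      supporting_samples = character(0),
                      n_samples = integer(0), bold = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
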