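#' @keywords internal
"_PACKAGE"

## Controlled vocabularies shared across the package. Gene symbols are the
## join key between variants, CNA, gene sets and expression and are always
## upper-cased on read. Internal genomic coordinates are 0-based half-open
## everywhere; conversions happen exactly once, at the file boundary.
rp_groups <- c("NON_COPD", "COPD")
rp_morphologies <- c("N", "R")
rp_impacts <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

#' Read a cohort sample manifest
#'
#' The manifest is a tab-delimited table with one row per microdissected
#' sample and columns `sample_id`, `patient_id`, `group` (`NON_COPD` or
#' `COPD`), `morphology` (`N` for non-remodelled, `R` for remodelled),
#' `variant_path` and `cna_path`. Relative paths are resolved against the
#' directory containing the manifest.
#'
#' @param path Path to the manifest TSV.
#' @return A data frame of class `rp_manifest` with one validated row per
#'   sample. Duplicate (patient, morphology) combinations are an error;
#'   N/R pairing is checked later, when a paired analysis is requested
#'   (see [check_paired()]).
#' @export
read_manifest <- function(path) {
  required <- c("sample_id", "patient_id", "group", "morphology",
                "variant_path", "cna_path")
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("manifest '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[required]
  if (nrow(df) > 0) {
    bad_group <- setdiff(unique(df$group), rp_groups)
    if (length(bad_group) > 0) {
      stop("unknown group token(s) in manifest: ",
           paste(bad_group, collapse = ", "))
    }
    bad_morph <- setdiff(unique(df$morphology), rp_morphologies)
    if (length(bad_morph) > 0) {
      stop("unknown morphology token(s) in manifest: ",
           paste(bad_morph, collapse = ", "))
    }
    key <- paste(df$patient_id, df$morphology)
    if (anyDuplicated(key)) {
      stop("duplicate (patient_id, morphology) in manifest: ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
    }
    if (anyDuplicated(df$sample_id)) {
      stop("duplicate sample_id in manifest")
    }
    base <- dirname(path)
    resolve <- function(p) {
      ifelse(p == "" | grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
    }
    df$variant_path <- resolve(df$variant_path)
    df$cna_path <- resolve(df$cna_path)
  }
  class(df) <- c("rp_manifest", "data.frame")
  df
}

#' Check that every patient has exactly one N and one R sample
#'
#' Paired (within-patient) analyses require each patient to contribute one
#' non-remodelled and one remodelled sample.
#'
#' @param manifest An `rp_manifest` data frame.
#' @return The manifest, invisibly, if the pairing invariant holds.
#' @export
check_paired <- function(manifest) {
  for (p in unique(manifest$patient_id)) {
    m <- sort(manifest$morphology[manifest$patient_id == p])
    if (!identical(m, c("N", "R"))) {
      stop("patient '", p, "' does not have exactly one N and one R sample")
    }
  }
  invisible(manifest)
}

#' Read small variant calls from a VCF 4.2 file
#'
#' Multi-allelic records are split into one call per alternate allele and
#' each (pos, ref, alt) is reduced to its minimal representation with
#' [normalize_variant()]. Symbolic and breakend alternate alleles (`<DEL>`,
#' `]`/`[` notation, `*`) are outside the SNV/insertion/deletion model and
#' are skipped with a warning. A consequence term is taken from the INFO
#' key `CONSEQ` when present and classified into an impact tier with
#' [classify_impact()].
#'
#' @param path Path to a plain-text VCF 4.2 file.
#' @param impact_table Consequence-to-impact lookup, by default
#'   [default_impact_table()].
#' @return A data frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `vtype` (`SNV`/`INS`/`DEL`), `consequence`, `impact`, and a list column
#'   `genes` (empty; filled by [annotate_genes()]).
#' @export
read_vcf <- function(path, impact_table = default_impact_table()) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body_idx) {
    if (length(strsplit(lines[i], "\t", fixed = TRUE)[[1]]) < 8) {
      stop("malformed VCF record at line ", i, " of '", path, "'")
    }
  }
  if (length(body_idx) == 0) {
    return(empty_variant_frame())
  }
  fix <- vcfR::read.vcfR(path, verbose = FALSE)@fix

  chrom <- character(0); pos <- integer(0)
  ref <- character(0); alt <- character(0); conseq <- character(0)
  n_symbolic <- 0L
  info <- fix[, "INFO"]
  cq <- rep(NA_character_, nrow(fix))
  has_cq <- grepl("(^|;)CONSEQ=", info)
  cq[has_cq] <- sub(".*CONSEQ=([^;]+).*", "\\1", info[has_cq])
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (a in alts) {
      if (grepl("[][<>*]", a)) {
        n_symbolic <- n_symbolic + 1L
        next
      }
      chrom <- c(chrom, fix[i, "CHROM"])
      pos <- c(pos, as.integer(fix[i, "POS"]))
      ref <- c(ref, fix[i, "REF"])
      alt <- c(alt, a)
      conseq <- c(conseq, cq[i])
    }
  }
  if (n_symbolic > 0) {
    warning(n_symbolic, " symbolic/breakend ALT allele(s) skipped in '",
            path, "'")
  }
  if (length(chrom) == 0) {
    return(empty_variant_frame())
  }
  norm <- normalize_variant(chrom, pos, ref, alt)
  impact <- rep("MODIFIER", length(conseq))
  known <- !is.na(conseq)
  if (any(known)) {
    impact[known] <- classify_impact(conseq[known], impact_table)
  }
  out <- data.frame(chrom = norm$chrom, pos = norm$pos, ref = norm$ref,
                    alt = norm$alt,
                    vtype = variant_type(norm$ref, norm$alt),
                    consequence = conseq, impact = impact,
                    stringsAsFactors = FALSE)
  out$genes <- rep(list(character(0)), nrow(out))
  out
}

empty_variant_frame <- function() {
  out <- data.frame(chrom = character(0), pos = integer(0),
                    ref = character(0), alt = character(0),
                    vtype = character(0), consequence = character(0),
                    impact = character(0), stringsAsFactors = FALSE)
  out$genes <- list()
  out
}

variant_type <- function(ref, alt) {
  ifelse(nchar(alt) > nchar(ref), "INS",
         ifelse(nchar(alt) < nchar(ref), "DEL", "SNV"))
}

#' Write variant calls to a plain-text VCF 4.2 file
#'
#' Counterpart of [read_vcf()]; consequence terms are stored in the INFO
#' field under the key `CONSEQ` so that a write/read round trip is lossless.
#'
#' @param calls Variant data frame as returned by [read_vcf()].
#' @param path Output path.
#' @export
write_vcf <- function(calls, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CONSEQ,Number=1,Type=String,Description=\"Consequence term\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  if (nrow(calls) > 0) {
    ord <- order(calls$chrom, calls$pos, calls$ref, calls$alt)
    calls <- calls[ord, , drop = FALSE]
    info <- ifelse(is.na(calls$consequence), ".",
                   paste0("CONSEQ=", calls$consequence))
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                  "PASS", info, sep = "\t")
  } else {
    body <- character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read copy-number segments from a SEG-like file
#'
#' Expects a tab-delimited file with header `sample`, `chrom`, `start`,
#' `end`, `copy_state`. Input coordinates follow the SEG dialect (1-based,
#' inclusive) and are converted to the package-internal 0-based half-open
#' convention. Segments are sorted per sample and must not overlap within a
#' sample on the same chromosome; abutting segments are accepted.
#'
#' @param path Path to the segment file.
#' @return A data frame with columns `sample`, `chrom`, `start` (0-based),
#'   `end` (exclusive), `copy_state` and an empty `genes` list column.
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample", "chrom", "start", "end", "copy_state")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("segment file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[required]
  if (nrow(df) == 0) {
    df$genes <- list()
    return(df)
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stop("non-numeric segment coordinates in '", path, "'")
  }
  if (any(df$start >= df$end)) {
    stop("segment with start >= end in '", path, "'")
  }
  df$start <- df$start - 1L  # 1-based inclusive -> 0-based half-open
  df <- df[order(df$sample, df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  for (s in unique(df$sample)) {
    for (ch in unique(df$chrom[df$sample == s])) {
      seg <- df[df$sample == s & df$chrom == ch, , drop = FALSE]
      if (nrow(seg) > 1 &&
          any(seg$start[-1] < seg$end[-nrow(seg)])) {
        stop("overlapping segments for sample '", s, "' on ", ch,
             " in '", path, "'")
      }
    }
  }
  df$genes <- rep(list(character(0)), nrow(df))
  df
}

#' Write copy-number segments to a SEG-like file
#'
#' Converts internal 0-based half-open coordinates back to the 1-based
#' inclusive SEG dialect, so that [read_seg()] followed by `write_seg()`
#' is the identity on the external representation.
#'
#' @param segs Segment data frame in internal coordinates.
#' @param path Output path.
#' @export
write_seg <- function(segs, path) {
  out <- data.frame(sample = segs$sample, chrom = segs$chrom,
                    start = segs$start + 1L, end = segs$end,
                    copy_state = segs$copy_state,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene model from a BED file
#'
#' Accepts BED4 (chrom, start, end, name) or BED6 (adding score and strand).
#' BED coordinates are already 0-based half-open and are kept as-is. Gene
#' symbols are upper-cased; a strand other than `+`/`-` (or its absence) is
#' recorded as `unknown`. Strand is carried but ignored by all analyses.
#'
#' @param path Path to the BED file.
#' @return A data frame with columns `gene`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(data.frame(gene = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 4)) {
    stop("BED line with fewer than 4 fields at line ", which(n < 4)[1],
         " of '", path, "'")
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- as.integer(vapply(fields, `[[`, "", 2))
  end <- as.integer(vapply(fields, `[[`, "", 3))
  gene <- toupper(vapply(fields, `[[`, "", 4))
  strand <- vapply(fields, function(f) {
    if (length(f) >= 6 && f[[6]] %in% c("+", "-")) f[[6]] else "unknown"
  }, "")
  if (any(is.na(start)) || any(is.na(end))) {
    stop("non-numeric BED coordinates in '", path, "'")
  }
  if (any(start >= end)) {
    stop("BED interval with start >= end in '", path, "'")
  }
  df <- data.frame(gene = gene, chrom = chrom, start = start, end = end,
                   strand = strand, stringsAsFactors = FALSE)
  if (anyDuplicated(paste(df$gene, df$chrom))) {
    stop("duplicate (gene, chrom) in '", path, "'")
  }
  df
}

#' Write a gene model to a BED6 file
#'
#' @param genes Gene model data frame as from [read_gene_bed()].
#' @param path Output path.
#' @export
write_gene_bed <- function(genes, path) {
  strand <- ifelse(genes$strand %in% c("+", "-"), genes$strand, ".")
  writeLines(paste(genes$chrom, genes$start, genes$end, genes$gene, 0,
                   strand, sep = "\t"), path)
  invisible(path)
}

#' Read gene-set annotations from a GMT file
#'
#' Each line is `term<TAB>description<TAB>gene1<TAB>gene2...`. Gene symbols
#' are upper-cased. Terms with zero genes are dropped with a warning.
#'
#' @param path Path to the GMT file.
#' @return A named list mapping term to a character vector of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    genes <- unique(toupper(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      warning("GMT term '", f[1], "' has zero genes; dropped")
      next
    }
    out[[f[1]]] <- genes
  }
  out
}

#' Read a gene-by-sample expression matrix with its group map
#'
#' The matrix is a TSV whose first column (`gene`) holds gene symbols and
#' whose remaining columns are samples; values are assumed already
#' log2-transformed. The group map is a TSV with columns `sample_id` and
#' `group` assigning each expression sample to `NON_COPD` or `COPD`.
#'
#' @param path Path to the expression matrix TSV.
#' @param group_map_path Path to the sample-to-group TSV.
#' @return An object of class `rp_expression`: a list with `values`
#'   (numeric gene x sample matrix) and `group_map` (named character
#'   vector over the matrix samples).
#' @export
read_expression <- function(path, group_map_path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene") {
    stop("expression matrix must have 'gene' as its first column")
  }
  genes <- toupper(df$gene)
  values <- as.matrix(df[, -1, drop = FALSE])
  mode(values) <- "numeric"
  rownames(values) <- genes
  gm <- utils::read.delim(group_map_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(gm))) {
    stop("group map must have columns sample_id and group")
  }
  bad <- setdiff(unique(gm$group), rp_groups)
  if (length(bad) > 0) {
    stop("unknown group token(s) in group map: ", paste(bad, collapse = ", "))
  }
  missing <- setdiff(colnames(values), gm$sample_id)
  if (length(missing) > 0) {
    stop("expression sample(s) missing from group map: ",
         paste(missing, collapse = ", "))
  }
  group_map <- stats::setNames(gm$group, gm$sample_id)[colnames(values)]
  structure(list(values = values, group_map = group_map),
            class = "rp_expression")
}

#' Write an expression matrix and its group map
#'
#' @param expr An `rp_expression` object.
#' @param path Output path for the matrix TSV.
#' @param group_map_path Output path for the sample-to-group TSV.
#' @export
write_expression <- function(expr, path, group_map_path) {
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gm <- data.frame(sample_id = names(expr$group_map),
                   group = unname(expr$group_map), stringsAsFactors = FALSE)
  utils::write.table(gm, group_map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load a full cohort: manifest, per-sample variants and CNA segments
#'
#' Reads every sample's VCF and SEG file, normalizes variants, and
#' annotates both variants and segments with the overlapping genes of the
#' supplied gene model. This is the entry point for all paired analyses.
#'
#' @param manifest An `rp_manifest` (or path to a manifest TSV).
#' @param gene_models Gene model data frame (or path to a BED file).
#' @param require_paired Check the one-N-one-R-per-patient invariant
#'   (default TRUE; all within-patient analyses need it).
#' @return An object of class `rp_cohort`: a list with `manifest`,
#'   `gene_models`, `variants` (named list of per-sample variant frames)
#'   and `cna` (named list of per-sample segment frames).
#' @export
load_cohort <- function(manifest, gene_models, require_paired = TRUE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.character(gene_models)) gene_models <- read_gene_bed(gene_models)
  if (require_paired) check_paired(manifest)
  variants <- list()
  cna <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    calls <- read_vcf(manifest$variant_path[i])
    variants[[sid]] <- annotate_genes(calls, gene_models)
    segs <- read_seg(manifest$cna_path[i])
    cna[[sid]] <- annotate_segment_genes(segs, gene_models)
  }
  structure(list(manifest = manifest, gene_models = gene_models,
                 variants = variants, cna = cna),
            class = "rp_cohort")
}

#' @export
print.rp_cohort <- function(x, ...) {
  m <- x$manifest
  cat("rp_cohort:", nrow(m), "samples,",
      length(unique(m$patient_id)), "patients (",
      sum(m$group == "NON_COPD" & m$morphology == "N"), "non-COPD pairs /",
      sum(m$group == "COPD" & m$morphology == "N"), "COPD pairs ),",
      nrow(x$gene_models), "gene models\n")
  invisible(x)
}
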