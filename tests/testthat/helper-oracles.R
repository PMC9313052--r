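# Independent brute-force re-computations working directly on the raw
# files with nested loops; deliberately shares no code with the package
# internals. The generator emits alleles already in minimal form, so raw
# (chrom, pos, ref, alt) tuples are directly comparable to the package's
# normalized keys.

oracle_vcf_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    for (a in strsplit(f[5], ",", fixed = TRUE)[[1]]) {
      if (grepl("[][<>*]", a)) next
      out[[length(out) + 1]] <- data.frame(
        chrom = f[1], pos = as.integer(f[2]), ref = f[4], alt = a,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

oracle_vcf_keys <- function(path) {
  r <- oracle_vcf_records(path)
  unique(paste(r$chrom, r$pos, r$ref, r$alt, sep = ":"))
}

# genes overlapped by any record in `rec`, by nested-loop interval check
# (variant occupies [pos-1, pos-1+nchar(ref)) in 0-based half-open).
oracle_genes_of_records <- function(rec, genes) {
  hit <- character(0)
  for (i in seq_len(nrow(rec))) {
    v_start <- rec$pos[i] - 1
    v_end <- v_start + nchar(rec$ref[i])
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] == rec$chrom[i] &&
          genes$start[j] < v_end && v_start < genes$end[j]) {
        hit <- c(hit, genes$gene[j])
      }
    }
  }
  unique(hit)
}

oracle_seg_records <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$start <- as.integer(df$start) - 1L  # to 0-based half-open
  df
}

oracle_seg_loci <- function(path) {
  df <- oracle_seg_records(path)
  unique(paste(df$chrom, df$start, df$end, sep = ":"))
}

oracle_genes_of_segs <- function(segs, genes) {
  hit <- character(0)
  for (i in seq_len(nrow(segs))) {
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] == segs$chrom[i] &&
          genes$start[j] < segs$end[i] && segs$start[i] < genes$end[j]) {
        hit <- c(hit, genes$gene[j])
      }
    }
  }
  unique(hit)
}

oracle_setdiff <- function(a, b) {
  keep <- character(0)
  for (x in a) {
    found <- FALSE
    for (y in b) if (identical(x, y)) { found <- TRUE; break }
    if (!found) keep <- c(keep, x)
  }
  keep
}

oracle_venn_sizes <- function(a, b) {
  a <- unique(a); b <- unique(b)
  only_a <- length(oracle_setdiff(a, b))
  only_b <- length(oracle_setdiff(b, a))
  shared <- length(a) - only_a
  c(only_a = only_a, shared = shared, only_b = only_b)
}

oracle_unique_fraction <- function(target, reference) {
  target <- unique(target)
  pct <- 100 * length(oracle_setdiff(target, unique(reference))) /
    length(target)
  floor(pct * 10 + 0.5) / 10
}

# hypergeometric upper tail by direct summation of the probability mass
oracle_hyper_upper <- function(obs, n_bg, n_term, n_query) {
  total <- 0
  for (j in obs:min(n_term, n_query)) {
    total <- total + choose(n_term, j) * choose(n_bg - n_term, n_query - j) /
      choose(n_bg, n_query)
  }
  total
}

# Benjamini-Hochberg step-up by hand
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  ranked <- p[ord] * m / seq_len(m)
  for (i in seq_len(m)) adj[i] <- min(ranked[i:m], 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}
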