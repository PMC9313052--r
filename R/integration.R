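#' Intersection and union of variant and CNA gene-of-interest sets
#'
#' @param variant_genes,cna_genes Character vectors of gene symbols.
#' @return A list with `intersection`, `union` and their sizes.
#' @export
joint_genes <- function(variant_genes, cna_genes) {
  variant_genes <- unique(variant_genes)
  cna_genes <- unique(cna_genes)
  inter <- sort(intersect(variant_genes, cna_genes))
  uni <- sort(union(variant_genes, cna_genes))
  list(intersection = inter, union = uni,
       n_intersection = length(inter), n_union = length(uni))
}

#' Hypergeometric gene-set over-representation with a strength statistic
#'
#' For each term, `observed` is the number of query genes annotated to the
#' term, `expected` is `|query| * |term| / |background|`, and the strength
#' is `log10(observed / expected)` (0 when the observation matches the
#' expectation exactly). The p-value is the hypergeometric upper tail
#' P(X >= observed) drawing `|query|` genes from a population of
#' `|background|` containing `|term|` successes; FDR correction is
#' Benjamini-Hochberg over the reported terms. Terms with no observed
#' gene are omitted. Query genes outside the background are dropped with
#' a warning, and each term is intersected with the background.
#'
#' @param query_genes Character vector of gene symbols.
#' @param annotations Named list: term -> character vector of genes (e.g.
#'   from [read_gmt()]).
#' @param background Character vector, the gene universe (by default all
#'   genes of the supplied gene model in the pipeline).
#' @return A data frame with columns `term`, `observed`, `expected`,
#'   `strength`, `p`, `fdr`, sorted by `fdr` then `p`.
#' @export
enrich <- function(query_genes, annotations, background) {
  background <- unique(background)
  if (length(background) == 0) stop("enrich: empty background")
  query_genes <- unique(query_genes)
  outside <- setdiff(query_genes, background)
  if (length(outside) > 0) {
    warning(length(outside),
            " query gene(s) outside the background dropped")
    query_genes <- intersect(query_genes, background)
  }
  n_bg <- length(background)
  n_q <- length(query_genes)
  rows <- list()
  for (term in names(annotations)) {
    term_genes <- intersect(unique(annotations[[term]]), background)
    k <- length(term_genes)
    if (k == 0) next
    obs <- length(intersect(query_genes, term_genes))
    if (obs == 0) next
    expected <- n_q * k / n_bg
    p <- stats::phyper(obs - 1, k, n_bg - k, n_q, lower.tail = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      term = term, observed = obs, expected = expected,
      strength = log10(obs / expected), p = p, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(term = character(0), observed = integer(0),
                      expected = numeric(0), strength = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out <- out[order(out$fdr, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap of a gene list with a reference list
#'
#' Reports which query genes appear in a reference list (e.g. a catalogue
#' of cilia-associated proteins) and the percentage of the query covered,
#' to one decimal.
#'
#' @param query_genes Non-empty character vector.
#' @param reference_list Character vector.
#' @return A list with `genes` (the overlap) and `percentage`
#'   (100 * |overlap| / |query|, one decimal).
#' @export
list_overlap <- function(query_genes, reference_list) {
  query_genes <- unique(query_genes)
  if (length(query_genes) == 0) stop("list_overlap: empty query")
  ov <- sort(intersect(query_genes, unique(reference_list)))
  list(genes = ov,
       percentage = round_half_up(100 * length(ov) / length(query_genes), 1))
}

#' Cross-reference genes of interest against an expression matrix
#'
#' For each gene of interest present in the matrix, computes the log2
#' fold change as mean(COPD) - mean(non-COPD) on the (already
#' log2-transformed) values, a two-sample t-test p-value, and the BH FDR
#' over the detected genes. Genes absent from the matrix are reported as
#' not detected. A gene is called deregulated when its FDR falls below
#' `fdr_threshold`.
#'
#' @param goi_genes Character vector of genes of interest.
#' @param expr An `rp_expression` object (see [read_expression()]).
#' @param test_mode `"welch"` (default, unequal variances), `"student"`
#'   (pooled), or `"paired"` (requires equal group sizes, samples paired
#'   by their order within each group).
#' @param fdr_threshold Deregulation call threshold (default 0.05).
#' @return A list with `results` (gene, log2fc, p, fdr, deregulated),
#'   `undetected` (genes absent from the matrix), `n_detected` and
#'   `n_deregulated`.
#' @export
expression_crossref <- function(goi_genes, expr,
                                test_mode = c("welch", "student", "paired"),
                                fdr_threshold = 0.05) {
  test_mode <- match.arg(test_mode)
  goi_genes <- unique(goi_genes)
  copd <- colnames(expr$values)[expr$group_map == "COPD"]
  ctrl <- colnames(expr$values)[expr$group_map == "NON_COPD"]
  if (length(copd) < 2 || length(ctrl) < 2) {
    stop("expression_crossref: each group needs at least 2 samples")
  }
  if (test_mode == "paired" && length(copd) != length(ctrl)) {
    stop("paired test requires equal group sizes")
  }
  detected <- intersect(goi_genes, rownames(expr$values))
  undetected <- setdiff(goi_genes, detected)
  if (length(detected) == 0) {
    return(list(results = data.frame(gene = character(0), log2fc = numeric(0),
                                     p = numeric(0), fdr = numeric(0),
                                     deregulated = logical(0),
                                     stringsAsFactors = FALSE),
                undetected = sort(undetected), n_detected = 0L,
                n_deregulated = 0L))
  }
  log2fc <- numeric(length(detected))
  p <- numeric(length(detected))
  for (i in seq_along(detected)) {
    x <- expr$values[detected[i], copd]
    y <- expr$values[detected[i], ctrl]
    log2fc[i] <- mean(x) - mean(y)
    if (test_mode == "paired") {
      d <- x - y
      p[i] <- if (stats::var(d) == 0) {
        if (mean(d) == 0) 1 else 0
      } else stats::t.test(x, y, paired = TRUE)$p.value
    } else if (stats::var(x) == 0 && stats::var(y) == 0) {
      # zero-variance guard: no evidence either way when means agree
      p[i] <- if (log2fc[i] == 0) 1 else 0
    } else {
      p[i] <- stats::t.test(x, y,
                            var.equal = (test_mode == "student"))$p.value
    }
  }
  p_for_fdr <- pmax(p, .Machine$double.xmin)  # degenerate p = 0 guard
  fdr <- bh_fdr(p_for_fdr)
  results <- data.frame(gene = detected, log2fc = log2fc, p = p, fdr = fdr,
                        deregulated = fdr < fdr_threshold,
                        stringsAsFactors = FALSE)
  results <- results[order(results$fdr, results$p, results$gene), ,
                     drop = FALSE]
  rownames(results) <- NULL
  list(results = results, undetected = sort(undetected),
       n_detected = length(detected),
       n_deregulated = sum(results$deregulated))
}
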