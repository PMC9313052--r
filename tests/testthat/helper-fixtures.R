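# Builders for small hand-constructed cohorts, written to disk and loaded
# back through the package readers so every test exercises the real IO path.

tiny_genes <- function() {
  data.frame(
    gene = c("GA", "GB", "GC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(100L, 1000L, 500L),
    end = c(600L, 2000L, 1500L),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE)
}

# samples: named list sample_id -> list(patient, group, morph,
#   var = data.frame(chrom, pos, ref, alt[, consequence]),
#   seg = data.frame(chrom, start, end, copy_state))  # internal 0-based
build_cohort <- function(dir, samples, genes = tiny_genes(),
                         require_paired = TRUE) {
  rows <- list()
  for (sid in names(samples)) {
    s <- samples[[sid]]
    v <- s$var
    if (is.null(v)) {
      v <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE)
    }
    if (is.null(v$consequence)) {
      v$consequence <- rep("missense_variant", nrow(v))
    }
    write_vcf(v, file.path(dir, paste0(sid, ".vcf")))
    sg <- s$seg
    if (is.null(sg)) {
      sg <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), copy_state = character(0),
                       stringsAsFactors = FALSE)
    }
    sg <- data.frame(sample = rep(sid, nrow(sg)), sg,
                     stringsAsFactors = FALSE)
    write_seg(sg, file.path(dir, paste0(sid, ".seg")))
    rows[[sid]] <- data.frame(
      sample_id = sid, patient_id = s$patient, group = s$group,
      morphology = s$morph, variant_path = paste0(sid, ".vcf"),
      cna_path = paste0(sid, ".seg"), stringsAsFactors = FALSE)
  }
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  load_cohort(manifest_path, genes, require_paired = require_paired)
}

# A paired 5-patient skeleton (2 non-COPD, 3 COPD) with no calls; tests
# overwrite the var/seg entries they need.
skeleton_samples <- function() {
  out <- list()
  meta <- rbind(
    data.frame(patient = c("P1", "P2"), group = "NON_COPD"),
    data.frame(patient = c("P3", "P4", "P5"), group = "COPD"))
  for (i in seq_len(nrow(meta))) {
    for (mo in c("N", "R")) {
      sid <- paste0(meta$patient[i], "_", mo)
      out[[sid]] <- list(patient = meta$patient[i], group = meta$group[i],
                         morph = mo)
    }
  }
  out
}

snv <- function(chrom, pos, ref = "A", alt = "T") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# Small, fast simulation configuration used by oracle and property tests
# (<= 100 variants and <= 50 CNA segments per sample).
small_sim_config <- function(seed, ...) {
  args <- list(seed = seed, n_genes = 400,
               genome = c(chr1 = 3e6, chr2 = 2e6),
               germline_shared_per_patient = 60,
               private_variants_per_sample = 8,
               remodelled_only_planted = c(NON_COPD = 3, COPD = 6),
               group_exclusive_recurrent_planted = c(NON_COPD = 2, COPD = 3),
               cna_background_per_sample = 15,
               cna_r_unique_mean = 8,
               copd_r_unique_cna_excess = 2,
               cna_recurrent_planted = 4,
               expression = list(n_samples_per_group = 5, n_de_genes = 5,
                                 log2fc_effect = 1, noise_sd = 0.2))
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}
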