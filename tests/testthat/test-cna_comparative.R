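seg_row <- function(chrom, start, end, state = "GAIN") {
  data.frame(chrom = chrom, start = start, end = end, copy_state = state,
             stringsAsFactors = FALSE)
}

test_that("CNA counting uses exact-coordinate locus identity", {
  dir <- withr::local_tempdir()
  samples <- skeleton_samples()
  # P1: N and R fully identical coordinates -> comparative zero
  samples$P1_N$seg <- seg_row("chr1", 100, 600)
  samples$P1_R$seg <- seg_row("chr1", 100, 600, "LOSS")  # state ignored
  # P3: R has one shared and one private locus (shifted by 1 bp)
  samples$P3_N$seg <- seg_row("chr1", 100, 600)
  samples$P3_R$seg <- rbind(seg_row("chr1", 100, 600),
                            seg_row("chr1", 1000, 2000))
  cohort <- build_cohort(dir, samples)
  cg <- count_cna(cohort, "global")$per_sample
  expect_equal(cg$n_loci[cg$sample_id == "P2_N"], 0)   # no segments
  expect_equal(cg$n_genes[cg$sample_id == "P2_N"], 0)
  expect_equal(cg$n_loci[cg$sample_id == "P3_R"], 2)
  cc <- count_cna(cohort, "comparative")$per_sample
  expect_equal(cc$n_loci[cc$sample_id == "P1_N"], 0)
  expect_equal(cc$n_loci[cc$sample_id == "P1_R"], 0)
  expect_equal(cc$n_loci[cc$sample_id == "P3_R"], 1)
  expect_equal(cc$n_genes[cc$sample_id == "P3_R"], 1)  # GB
  # strict mode adds the copy state to the identity
  cs <- count_cna(cohort, "comparative", strict = TRUE)$per_sample
  expect_equal(cs$n_loci[cs$sample_id == "P1_R"], 1)
})

test_that("a shifted boundary breaks locus identity", {
  dir <- withr::local_tempdir()
  samples <- skeleton_samples()
  samples$P3_N$seg <- seg_row("chr1", 100, 600)
  samples$P3_R$seg <- seg_row("chr1", 101, 600)
  cohort <- build_cohort(dir, samples)
  cc <- count_cna(cohort, "comparative")$per_sample
  expect_equal(cc$n_loci[cc$sample_id == "P3_R"], 1)
})

test_that("venn partitions and unique fractions follow the set identities", {
  v <- venn(letters[1:5], letters[1:5])
  expect_equal(unname(v$sizes), c(0L, 5L, 0L))
  v <- venn(c("a", "b", "c", "d", "e"), c("d", "e", "f", "g"))
  expect_equal(unname(v$sizes), c(3L, 2L, 2L))
  expect_equal(v$shared, c("d", "e"))
  v <- venn(c("a", "b"), c("c", "d"))
  expect_equal(unname(v$sizes), c(2L, 0L, 2L))
  # |A u B| = only_a + shared + only_b on random sets
  set.seed(1)
  for (i in 1:20) {
    a <- sample(letters, sample(0:15, 1))
    b <- sample(letters, sample(1:15, 1))
    v <- venn(a, b)
    expect_equal(sum(v$sizes), length(union(a, b)))
  }

  expect_equal(unique_fraction(c("a", "b"), c("a", "b", "c")), 0)
  expect_equal(unique_fraction(c("a", "b"), c("c")), 100)
  expect_equal(unique_fraction(letters[1:10], letters[8:20]), 70)
  expect_error(unique_fraction(character(0), "a"), "empty target")
  expect_equal(unique_fraction(letters[1:4], character(0)), 100)
  # enlarging the reference never increases the unique fraction
  set.seed(2)
  for (i in 1:20) {
    target <- sample(letters, 10)
    ref <- sample(letters, 5)
    bigger <- union(ref, sample(letters, 8))
    expect_lte(unique_fraction(target, bigger),
               unique_fraction(target, ref))
  }
})

test_that("recurrent CNA genes respect threshold, bold rule and reference side", {
  dir <- withr::local_tempdir()
  samples <- skeleton_samples()
  # gene GA (chr1 100-600) altered in all three COPD R samples, private coords
  samples$P3_R$seg <- seg_row("chr1", 110, 590)
  samples$P4_R$seg <- seg_row("chr1", 120, 580)
  samples$P5_R$seg <- rbind(seg_row("chr1", 130, 570),
                            seg_row("chr2", 600, 1400))  # GC in one sample
  cohort <- build_cohort(dir, samples)
  for (cmp in c("COPD_R_vs_COPD_N", "COPD_R_vs_NONCOPD_R")) {
    goi <- recurrent_cna_genes(cohort, cmp)
    expect_equal(goi$gene, "GA")       # GC supported by only 1 sample
    expect_true(goi$bold)
    expect_equal(goi$n_samples, 3)
  }
  # removal against COPD N: give P4_N the exact coordinates of P4_R
  samples$P4_N$seg <- seg_row("chr1", 120, 580)
  goi <- recurrent_cna_genes(build_cohort(dir, samples), "COPD_R_vs_COPD_N")
  expect_equal(goi$n_samples, 2)       # P4's locus removed -> not bold
  expect_false(goi$bold)
  # the non-COPD reference side is indifferent to COPD N coordinates
  goi2 <- recurrent_cna_genes(build_cohort(dir, samples),
                              "COPD_R_vs_NONCOPD_R")
  expect_equal(goi2$n_samples, 3)
  # min_samples = 3 drops 2-sample support
  goi3 <- recurrent_cna_genes(build_cohort(dir, samples), "COPD_R_vs_COPD_N",
                              min_samples = 3)
  expect_equal(nrow(goi3), 0)
})

test_that("planted recurrent CNA truth is recovered exactly on synthetic cohorts", {
  dir <- withr::local_tempdir()
  sim <- generate_cohort(small_sim_config(31), dir)
  cohort <- load_cohort(sim$manifest, sim$gene_models)
  truth <- sim$truth$cna_recurrent
  for (cmp in c("COPD_R_vs_COPD_N", "COPD_R_vs_NONCOPD_R")) {
    goi <- recurrent_cna_genes(cohort, cmp)
    expect_setequal(goi$gene, truth$gene)
    expect_equal(goi$bold[order(goi$gene)],
                 (truth$n_samples >= 3)[order(truth$gene)])
  }
})

test_that("per-sample counts match the brute-force oracle on a synthetic cohort", {
  dir <- withr::local_tempdir()
  sim <- generate_cohort(small_sim_config(37), dir)
  cohort <- load_cohort(sim$manifest, sim$gene_models)
  genes <- sim$gene_models
  cg <- count_cna(cohort, "global")$per_sample
  cc <- count_cna(cohort, "comparative")$per_sample
  m <- cohort$manifest
  for (i in seq_len(nrow(m))) {
    segs <- oracle_seg_records(m$cna_path[i])
    loci <- unique(paste(segs$chrom, segs$start, segs$end, sep = ":"))
    expect_equal(cg$n_loci[i], length(loci))
    expect_equal(cg$n_genes[i], length(oracle_genes_of_segs(segs, genes)))
    j <- which(m$patient_id == m$patient_id[i] &
                 m$morphology != m$morphology[i])
    partner <- oracle_seg_loci(m$cna_path[j])
    kept <- oracle_setdiff(loci, partner)
    expect_equal(cc$n_loci[i], length(kept))
    kept_segs <- segs[paste(segs$chrom, segs$start, segs$end, sep = ":")
                      %in% kept, , drop = FALSE]
    expect_equal(cc$n_genes[i],
                 length(oracle_genes_of_segs(kept_segs, genes)))
  }
})
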