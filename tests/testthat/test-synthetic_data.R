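test_that("gene model generation is deterministic and disjoint", {
  expect_equal(nrow(generate_gene_models(small_sim_config(1, n_genes = 0))),
               0)
  cfg <- sim_config(seed = 7, n_genes = 100, genome = c(chr1 = 1e7))
  g1 <- generate_gene_models(cfg)
  g2 <- generate_gene_models(cfg)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 100)
  expect_true(all(g1$start < g1$end))
  # brute-force pairwise disjointness
  for (i in seq_len(nrow(g1) - 1)) {
    for (j in (i + 1):nrow(g1)) {
      if (g1$chrom[i] != g1$chrom[j]) next
      expect_true(g1$end[i] <= g1$start[j] || g1$end[j] <= g1$start[i])
    }
  }
  expect_error(
    generate_gene_models(sim_config(seed = 1, n_genes = 100,
                                    genome = c(chr1 = 1.5e5))),
    "genome too small")
})

test_that("identical configurations produce byte-identical cohorts", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- small_sim_config(11)
  generate_cohort(cfg, d1)
  generate_cohort(cfg, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) > 20)
  expect_identical(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("planted remodelled-only keys sit in R and never in the paired N", {
  dir <- withr::local_tempdir()
  sim <- generate_cohort(small_sim_config(3), dir)
  truth <- sim$truth$remodelled_only
  expect_true(nrow(truth) > 0)
  for (p in unique(truth$patient_id)) {
    r_keys <- oracle_vcf_keys(file.path(dir, paste0(p, "_R.vcf")))
    n_keys <- oracle_vcf_keys(file.path(dir, paste0(p, "_N.vcf")))
    planted <- truth$key[truth$patient_id == p]
    expect_true(all(planted %in% r_keys))
    expect_false(any(planted %in% n_keys))
  }
})

test_that("germline sharing between N and R is exact by construction", {
  dir <- withr::local_tempdir()
  cfg <- small_sim_config(5)
  sim <- generate_cohort(cfg, dir)
  gx <- sim$truth$group_exclusive
  for (p in unique(sim$manifest$patient_id)) {
    r_keys <- oracle_vcf_keys(file.path(dir, paste0(p, "_R.vcf")))
    n_keys <- oracle_vcf_keys(file.path(dir, paste0(p, "_N.vcf")))
    shared <- intersect(r_keys, n_keys)
    expect_equal(length(shared), cfg$germline_shared_per_patient)
    expect_equal(length(n_keys),
                 cfg$germline_shared_per_patient +
                   cfg$private_variants_per_sample)
  }
  # planted group-exclusive keys live inside the shared germline of exactly
  # the supporting patients
  for (i in seq_len(nrow(gx))) {
    supp <- strsplit(gx$patients[i], ",", fixed = TRUE)[[1]]
    for (p in unique(sim$manifest$patient_id)) {
      n_keys <- oracle_vcf_keys(file.path(dir, paste0(p, "_N.vcf")))
      expect_equal(gx$key[i] %in% n_keys, p %in% supp)
    }
  }
})

test_that("a cohort without private or planted calls has zero comparative counts", {
  dir <- withr::local_tempdir()
  cfg <- small_sim_config(2, private_variants_per_sample = 0,
                          remodelled_only_planted = c(NON_COPD = 0, COPD = 0))
  sim <- generate_cohort(cfg, dir)
  cohort <- load_cohort(sim$manifest, sim$gene_models)
  vc <- count_variants(cohort, "comparative")
  expect_true(all(vc$per_sample$n_positions == 0))
  expect_true(all(vc$per_sample$n_genes == 0))
})

test_that("raising the COPD excess factor raises the expected R-unique CNA count", {
  unique_copd_r <- function(excess, seed) {
    dir <- withr::local_tempdir()
    cfg <- small_sim_config(seed, copd_r_unique_cna_excess = excess,
                            germline_shared_per_patient = 5,
                            private_variants_per_sample = 0,
                            remodelled_only_planted = c(NON_COPD = 0,
                                                        COPD = 0),
                            cna_recurrent_planted = 0)
    sim <- generate_cohort(cfg, dir)
    m <- sim$manifest
    copd <- unique(m$patient_id[m$group == "COPD"])
    mean(vapply(copd, function(p) {
      r <- oracle_seg_loci(file.path(dir, paste0(p, "_R.seg")))
      n <- oracle_seg_loci(file.path(dir, paste0(p, "_N.seg")))
      length(oracle_setdiff(r, n))
    }, 0))
  }
  seeds <- 1:10
  lo <- vapply(seeds, function(s) unique_copd_r(1, s), 0)
  hi <- vapply(seeds, function(s) unique_copd_r(3, s), 0)
  expect_gt(mean(hi), mean(lo))
  # with excess 1 the two groups' unique counts agree in distribution
  cross <- vapply(seeds, function(s) {
    dir <- withr::local_tempdir()
    cfg <- small_sim_config(s + 100, copd_r_unique_cna_excess = 1,
                            germline_shared_per_patient = 5,
                            private_variants_per_sample = 0,
                            remodelled_only_planted = c(NON_COPD = 0,
                                                        COPD = 0),
                            cna_recurrent_planted = 0)
    sim <- generate_cohort(cfg, dir)
    m <- sim$manifest
    per_group <- function(g) {
      pats <- unique(m$patient_id[m$group == g])
      mean(vapply(pats, function(p) {
        r <- oracle_seg_loci(file.path(dir, paste0(p, "_R.seg")))
        n <- oracle_seg_loci(file.path(dir, paste0(p, "_N.seg")))
        length(oracle_setdiff(r, n))
      }, 0))
    }
    per_group("COPD") - per_group("NON_COPD")
  }, 0)
  se <- sd(cross) / sqrt(length(cross))
  expect_lt(abs(mean(cross)), 3 * se + 1e-9)
})
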