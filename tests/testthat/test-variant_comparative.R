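test_that("variant normalization trims suffix then prefix, advancing the position", {
  n <- normalize_variant("chr1", 100, "GCA", "GCC")
  expect_equal(n, list(chrom = "chr1", pos = 102L, ref = "A", alt = "C"))
  n <- normalize_variant("chr1", 100, "A", "T")
  expect_equal(n$pos, 100L)
  expect_equal(c(n$ref, n$alt), c("A", "T"))
  # suffix-first order makes this AT>A at 100, not TT>T at 101
  n <- normalize_variant("chr1", 100, "ATT", "AT")
  expect_equal(n, list(chrom = "chr1", pos = 100L, ref = "AT", alt = "A"))
  expect_error(normalize_variant("chr1", 100, "A", "A"), "not a variant")
  # vectorized form agrees with scalar calls
  n <- normalize_variant(c("chr1", "chr2"), c(100, 7), c("GCA", "CT"),
                         c("GCC", "CTT"))
  expect_equal(n$pos, c(102L, 7L))
  expect_equal(n$ref, c("A", "C"))   # CT>CTT reduces to C>CT
  expect_equal(n$alt, c("C", "CT"))
})

test_that("impact classification uses the tier table with a MODIFIER fallback", {
  expect_equal(classify_impact("stop_gained"), "HIGH")
  expect_equal(classify_impact("synonymous_variant"), "LOW")
  expect_equal(classify_impact(c("missense_variant", "intron_variant")),
               c("MODERATE", "MODIFIER"))
  expect_warning(imp <- classify_impact("weird_term"), "unknown")
  expect_equal(imp, "MODIFIER")
})

test_that("gene annotation attaches every overlapping model", {
  genes <- data.frame(
    gene = c("GA", "GB"), chrom = "chr1",
    start = c(100L, 190L), end = c(200L, 300L),  # GA and GB overlap
    strand = "+", stringsAsFactors = FALSE)
  calls <- data.frame(
    chrom = "chr1", pos = c(150L, 195L, 500L),
    ref = c("A", "AAAAAAAAAA", "G"), alt = c("T", "A", "C"),
    vtype = c("SNV", "DEL", "SNV"), consequence = NA, impact = "MODIFIER",
    stringsAsFactors = FALSE)
  a <- annotate_genes(calls, genes)
  expect_equal(a$genes[[1]], "GA")
  expect_equal(a$genes[[2]], c("GA", "GB"))  # deletion spans both
  expect_equal(a$genes[[3]], character(0))   # intergenic
})

test_that("global and comparative counting follow the set definitions", {
  dir <- withr::local_tempdir()
  samples <- list(
    P1_N = list(patient = "P1", group = "NON_COPD", morph = "N",
                var = rbind(snv("chr1", 150, "A", "T"),
                            snv("chr1", 1500, "C", "G"))),   # k1, k2
    P1_R = list(patient = "P1", group = "NON_COPD", morph = "R",
                var = rbind(snv("chr1", 1500, "C", "G"),
                            snv("chr2", 700, "G", "A"))),    # k2, k3
    P2_N = list(patient = "P2", group = "COPD", morph = "N",
                var = snv("chr1", 150, "A", "T")),
    P2_R = list(patient = "P2", group = "COPD", morph = "R",
                var = snv("chr1", 150, "A", "T")))
  cohort <- build_cohort(dir, samples)
  vg <- count_variants(cohort, "global")
  expect_equal(vg$per_sample$n_positions, c(2, 2, 1, 1))
  expect_equal(vg$per_sample$n_genes, c(2, 2, 1, 1))
  vc <- count_variants(cohort, "comparative")
  # N keeps k1, R keeps k3; the identical P2 pair drops to zero
  expect_equal(vc$per_sample$n_positions, c(1, 1, 0, 0))
  expect_equal(vc$per_sample$n_genes, c(1, 1, 0, 0))
  # cross-group removal: k1 is in both groups, k2/k3 only in NON_COPD
  vx <- count_variants(cohort, "comparative", mode = "cross_group")
  expect_equal(vx$per_sample$n_positions, c(1, 2, 0, 0))
})

test_that("a sample with no calls counts zero and equal samples give SEM 0", {
  dir <- withr::local_tempdir()
  samples <- list(
    P1_N = list(patient = "P1", group = "NON_COPD", morph = "N"),
    P1_R = list(patient = "P1", group = "NON_COPD", morph = "R"),
    P2_N = list(patient = "P2", group = "NON_COPD", morph = "N"),
    P2_R = list(patient = "P2", group = "NON_COPD", morph = "R"),
    P3_N = list(patient = "P3", group = "COPD", morph = "N",
                var = snv("chr1", 150)),
    P3_R = list(patient = "P3", group = "COPD", morph = "R"))
  cohort <- build_cohort(dir, samples)
  vg <- count_variants(cohort, "global")
  expect_equal(vg$per_sample$n_positions[1], 0)
  expect_equal(vg$per_sample$n_genes[1], 0)
  s <- vg$summary
  sem_nn <- s$sem[s$group == "NON_COPD" & s$morphology == "N" &
                    s$metric == "n_positions"]
  expect_equal(sem_nn, 0)  # two identical samples in the stratum
})

test_that("within-patient comparison requires paired samples", {
  dir <- withr::local_tempdir()
  samples <- list(
    P1_N = list(patient = "P1", group = "NON_COPD", morph = "N"),
    P1_R = list(patient = "P1", group = "NON_COPD", morph = "R"),
    P2_N = list(patient = "P2", group = "COPD", morph = "N"))
  cohort <- build_cohort(dir, samples, require_paired = FALSE)
  expect_error(count_variants(cohort, "comparative"), "paired")
})

test_that("conservation and label-swap symmetry hold on synthetic cohorts", {
  dir <- withr::local_tempdir()
  sim <- generate_cohort(small_sim_config(17), dir)
  cohort <- load_cohort(sim$manifest, sim$gene_models)
  vg <- count_variants(cohort, "global")$per_sample
  vc <- count_variants(cohort, "comparative")$per_sample
  m <- cohort$manifest
  for (i in seq_len(nrow(m))) {
    keys <- oracle_vcf_keys(m$variant_path[i])
    j <- which(m$patient_id == m$patient_id[i] &
                 m$morphology != m$morphology[i])
    partner <- oracle_vcf_keys(m$variant_path[j])
    n_shared <- length(keys) - length(oracle_setdiff(keys, partner))
    expect_equal(vg$n_positions[i], vc$n_positions[i] + n_shared)
  }
  # swapping one patient's N and R labels swaps its two comparative counts
  m2 <- read_manifest(sim$paths$manifest)
  pat <- m2$patient_id[1]
  sel <- m2$patient_id == pat
  m2$morphology[sel] <- rev(m2$morphology[sel])
  swapped <- structure(list(manifest = m2, gene_models = cohort$gene_models,
                            variants = cohort$variants, cna = cohort$cna),
                       class = "rp_cohort")
  vs <- count_variants(swapped, "comparative")$per_sample
  for (mo in c("N", "R")) {
    other <- setdiff(c("N", "R"), mo)
    expect_equal(vs$n_positions[vs$patient_id == pat & vs$morphology == mo],
                 vc$n_positions[vc$patient_id == pat &
                                  vc$morphology == other])
  }
})

test_that("remodelled-only filter enforces the single-R and paired-N rules", {
  dir <- withr::local_tempdir()
  samples <- skeleton_samples()
  # qualifying: in P3_R only, absent from P3_N
  samples$P3_R$var <- rbind(snv("chr1", 150, "A", "T"),
                            snv("chr1", 1500, "C", "G"),  # also in P4_R
                            snv("chr2", 700, "G", "A"))   # also in P3_N
  samples$P4_R$var <- snv("chr1", 1500, "C", "G")
  samples$P3_N$var <- snv("chr2", 700, "G", "A")
  # non-COPD side: qualifying call in P1_R
  samples$P1_R$var <- snv("chr2", 900, "T", "C")
  cohort <- build_cohort(dir, samples)
  goi <- remodelled_only_genes(cohort)
  copd <- goi[goi$group == "COPD", ]
  expect_equal(copd$gene, "GA")  # chr1:150 only; the other two are excluded
  expect_equal(copd$supporting_samples, "P3_R")
  expect_equal(goi$gene[goi$group == "NON_COPD"], "GC")
  # with cohort-wide scope a key present in an R sample of the other group
  # is no longer unique
  samples$P1_R$var <- snv("chr1", 150, "A", "T")
  cohort2 <- build_cohort(dir, samples)
  goi_group <- remodelled_only_genes(cohort2, r1_scope = "group")
  goi_cohort <- remodelled_only_genes(cohort2, r1_scope = "cohort")
  expect_true("GA" %in% goi_group$gene[goi_group$group == "COPD"])
  expect_false("GA" %in% goi_cohort$gene)
})

test_that("remodelled-only genes carry the maximum impact and HIGH flag", {
  dir <- withr::local_tempdir()
  samples <- skeleton_samples()
  samples$P3_R$var <- data.frame(
    chrom = "chr1", pos = c(150L, 160L), ref = "A", alt = "T",
    consequence = c("synonymous_variant", "stop_gained"),
    stringsAsFactors = FALSE)
  cohort <- build_cohort(dir, samples)
  goi <- remodelled_only_genes(cohort)
  expect_equal(goi$max_impact, "HIGH")
  expect_true(goi$high_impact)
})

test_that("group-exclusive recurrence needs >= 2 patients and full exclusivity", {
  dir <- withr::local_tempdir()
  k <- function() snv("chr1", 150, "A", "T")
  samples <- skeleton_samples()
  for (sid in c("P3_N", "P3_R", "P4_N", "P4_R")) samples[[sid]]$var <- k()
  cohort <- build_cohort(dir, samples)
  goi <- group_exclusive_recurrent_genes(cohort)
  expect_equal(goi$gene, "GA")
  expect_equal(goi$group, "COPD")
  expect_equal(goi$n_patients, 2)
  expect_false(goi$bold)

  # all three COPD patients -> bold
  for (sid in c("P5_N", "P5_R")) samples[[sid]]$var <- k()
  goi <- group_exclusive_recurrent_genes(build_cohort(dir, samples))
  expect_true(goi$bold)
  expect_equal(goi$n_patients, 3)

  # leaking into one non-COPD sample destroys exclusivity
  samples$P1_N$var <- k()
  goi <- group_exclusive_recurrent_genes(build_cohort(dir, samples))
  expect_equal(nrow(goi), 0)

  # present in N only (not R) of the second patient -> support drops to 1
  samples$P1_N$var <- NULL
  samples$P4_R$var <- NULL
  goi <- group_exclusive_recurrent_genes(build_cohort(dir, samples))
  expect_equal(goi$n_patients, 2)  # P3 and P5 still support it
})

test_that("planted synthetic truth is recovered without extras", {
  dir <- withr::local_tempdir()
  sim <- generate_cohort(small_sim_config(23), dir)
  cohort <- load_cohort(sim$manifest, sim$gene_models)
  ro <- remodelled_only_genes(cohort)
  truth <- sim$truth$remodelled_only
  for (g in c("NON_COPD", "COPD")) {
    expect_setequal(ro$gene[ro$group == g], truth$gene[truth$group == g])
  }
  gx <- group_exclusive_recurrent_genes(cohort)
  truth_gx <- sim$truth$group_exclusive
  for (g in c("NON_COPD", "COPD")) {
    expect_setequal(gx$gene[gx$group == g],
                    truth_gx$gene[truth_gx$group == g])
  }
  expect_equal(gx$bold[order(gx$gene)],
               (truth_gx$n_patients >= 3)[order(truth_gx$gene)])
})
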