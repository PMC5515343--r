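test_that("vectorised Fisher p equals stats::fisher.test and the oracle", {
  set.seed(3)
  tabs <- cbind(a = sample(0:60, 200, TRUE), b = sample(0:60, 200, TRUE),
                c = sample(0:60, 200, TRUE), d = sample(0:60, 200, TRUE))
  p <- fisher_exact_p(tabs[, 1], tabs[, 2], tabs[, 3], tabs[, 4])
  for (i in seq_len(50)) {
    ft <- fisher.test(matrix(tabs[i, ], 2, byrow = TRUE))
    expect_equal(p[i], ft$p.value, tolerance = 1e-12)
    expect_equal(p[i], oracle_fisher(tabs[i, 1], tabs[i, 2],
                                     tabs[i, 3], tabs[i, 4]),
                 tolerance = 1e-12)
  }
})

mkvar <- function(t_alt, t_depth, b_alt, b_depth, n_alt = 5, n_depth = 100,
                  rna_alt = 0, rna_depth = 50, gene = "PIK3CA", n = 1) {
  fieldscape:::as_variant_table(data.frame(
    patient = "P1", chrom = "1", pos = seq_len(n), ref = "A", alt = "G",
    t_ref = t_depth - t_alt, t_alt = t_alt,
    b_ref = b_depth - b_alt, b_alt = b_alt,
    n_ref = n_depth - n_alt, n_alt = n_alt,
    rna_ref = rna_depth - rna_alt, rna_alt = rna_alt,
    gene = gene, stringsAsFactors = FALSE))
}

test_that("somatic filter cascade applies the four rules", {
  keep <- filter_somatic_snvs(mkvar(40, 100, 0, 100))
  expect_true(keep$passes_somatic_filter)
  expect_lt(keep$fisher_p, 1e-10)

  low_vaf <- filter_somatic_snvs(mkvar(5, 100, 0, 100))
  expect_false(low_vaf$passes_somatic_filter)
  expect_equal(low_vaf$filter_reason, "low_tumor_vaf")

  blood <- filter_somatic_snvs(mkvar(40, 100, 8, 100))
  expect_false(blood$passes_somatic_filter)
  expect_equal(blood$filter_reason, "present_in_blood")

  thin <- filter_somatic_snvs(mkvar(8, 15, 0, 100))
  expect_equal(thin$filter_reason, "insufficient_coverage")

  zero <- filter_somatic_snvs(mkvar(0, 0, 0, 100))
  expect_false(zero$passes_somatic_filter)
  expect_equal(zero$filter_reason, "insufficient_coverage")

  notsig <- filter_somatic_snvs(mkvar(4, 25, 2, 25))
  expect_false(notsig$passes_somatic_filter)
  expect_equal(notsig$filter_reason, "not_significant")
})

test_that("raising the tumor VAF floor never admits more variants", {
  set.seed(9)
  cfg <- sim_config(n_patients = 1, n_somatic_snvs = 60, depth_mean = 120,
                    adjacent_vaf_scale = 0.1, seed = 33)
  v <- simulate_variants(cfg, 1)
  n_pass <- vapply(c(0, 0.1, 0.2, 0.3, 0.5),
                   function(th) sum(filter_somatic_snvs(
                     v, min_tumor_vaf = th)$passes_somatic_filter),
                   numeric(1))
  expect_true(all(diff(n_pass) <= 0))
})

test_that("burden classification matches the hand-written truth table", {
  for (n_det in c(0, 1, 2, 5, 10, 20)) {
    for (frac in c(0, 0.05, 0.1, 0.3, 0.5, 0.9, 1)) {
      k <- round(frac * n_det)
      achieved <- if (n_det > 0) k / n_det else NA
      call <- classify_exome_burden(variants_with_burden(n_det, k))
      want <- oracle_burden(n_det, achieved)
      expect_equal(call$category, want,
                   label = sprintf("n=%d frac=%.2f -> %s", n_det, frac,
                                   call$category))
      expect_equal(call$n_detected, n_det)
    }
  }
})

test_that("burden worked examples from the tier definitions", {
  expect_equal(classify_exome_burden(variants_with_burden(4, 3))$category,
               "high")     # 75% of detected above 1% VAF
  expect_equal(classify_exome_burden(variants_with_burden(1, 1))$category,
               "none")     # fewer than two detected
  expect_equal(classify_exome_burden(variants_with_burden(10, 1))$category,
               "low")      # exactly 10% above 1% VAF
  expect_equal(classify_exome_burden(variants_with_burden(10, 3))$category,
               "moderate")
})

test_that("RNA mutation scoring counts expressed and present loci", {
  # 10 loci: 6 with depth >= 10, of which 2 carry >= 2 variant reads
  depths <- c(rep(50, 6), rep(5, 4))
  alts <- c(3, 2, 0, 0, 0, 0, 4, 4, 0, 0)
  v <- fieldscape:::as_variant_table(data.frame(
    patient = "P1", chrom = "1", pos = 1:10, ref = "A", alt = "G",
    t_ref = 60, t_alt = 40, b_ref = 100, b_alt = 0,
    n_ref = 95, n_alt = 5,
    rna_ref = depths - alts, rna_alt = alts, stringsAsFactors = FALSE))
  sc <- rna_mutation_score(v)
  expect_equal(sc$expressed_fraction, 0.6)
  expect_equal(sc$mutant_expressed_fraction, 1 / 3)
  expect_equal(sc$n_present, 2)
  expect_true(sc$positive)

  v$rna_alt <- rep(1L, 10)
  v$rna_ref <- depths - 1L
  sc1 <- rna_mutation_score(v)
  expect_equal(sc1$n_present, 0)
  expect_false(sc1$positive)

  sc0 <- rna_mutation_score(v[0, ])
  expect_true(sc0$undefined)
  expect_false(sc0$positive)
})

test_that("gene recurrence report equals a group-by oracle", {
  v <- rbind(mkvar(40, 100, 0, 100, n_alt = 5, gene = "PIK3CA", n = 3),
             mkvar(40, 100, 0, 100, n_alt = 0, gene = "PIK3CA", n = 2),
             mkvar(40, 100, 0, 100, n_alt = 1, gene = "TP53", n = 2))
  v <- fieldscape:::as_variant_table(v)
  rep <- tumor_gene_recurrence_report(v)
  expect_equal(rep$gene, c("PIK3CA", "TP53"))
  expect_equal(rep$n_tumor, c(5L, 2L))
  expect_equal(rep$n_detected_in_adjacent, c(3L, 0L))

  set.seed(22)
  cfg <- sim_config(n_patients = 4, n_somatic_snvs = 25,
                    adjacent_vaf_scale = 0.1, seed = 10)
  rv <- do.call(rbind, lapply(1:4, function(i) simulate_variants(cfg, i)))
  rv <- fieldscape:::as_variant_table(rv)
  got <- tumor_gene_recurrence_report(rv)
  for (g in got$gene) {
    sub <- rv[rv$gene == g, ]
    expect_equal(got$n_tumor[got$gene == g], nrow(sub))
    expect_equal(got$n_detected_in_adjacent[got$gene == g],
                 sum(sub$n_alt >= 2))
  }
})
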