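test_that("normalized expression is transcripts per million", {
  expect_equal(normalize_expression(CLEAN_READS_FC, CLEAN_READS_FC), 1e6)
  expect_equal(normalize_expression(0, 100), 0)
  # direct arithmetic on the printed counts
  expect_equal(normalize_expression(MIR1_FC, CLEAN_READS_FC),
               1e6 * MIR1_FC / CLEAN_READS_FC)
  expect_equal(normalize_expression(MIR1_FC, CLEAN_READS_FC), 123464.1,
               tolerance = 1e-6)
  expect_error(normalize_expression(1, 0), class = "caprimir_domain_error")
})

test_that("log2 fold-change reproduces the miR-1 worked example", {
  ne1 <- normalize_expression(MIR1_FC, CLEAN_READS_FC)
  ne2 <- normalize_expression(MIR1_SMC, CLEAN_READS_SMC)
  expect_equal(round_half_up(log2_fold_change(ne1, ne2), 2), -2.37)
})

test_that("log2 fold-change handles zeros via the pseudocount rule", {
  expect_equal(log2_fold_change(5, 5), 0)
  expect_equal(log2_fold_change(8, 2), 2)
  expect_true(is.na(log2_fold_change(0, 0)))
  # pseudocount touches only zero entries
  expect_equal(log2_fold_change(0, 10, pseudo = 0.01), log2(0.01 / 10))
  expect_equal(log2_fold_change(10, 0, pseudo = 0.01), log2(10 / 0.01))
  expect_equal(log2_fold_change(3, 7), log2(3 / 7))
})

test_that("exact test matches the brute-force tail summation", {
  # symmetric center and the no-information case
  expect_equal(audic_claverie_p(7, 7, 1000, 1000), 1)
  expect_equal(audic_claverie_p(0, 0, 500, 2000), 1)
  # spot grid against the independent oracle
  for (x in c(0, 1, 5, 20, 100)) {
    for (y in c(0, 3, 17, 100)) {
      for (r in c(0.5, 1, 2)) {
        p <- audic_claverie_p(x, y, 1000, 1000 * r)
        po <- ac_p_oracle(x, y, 1000, 1000 * r)
        expect_equal(p, po, tolerance = 1e-9)
      }
    }
  }
  expect_error(audic_claverie_p(-1, 2, 10, 10), class = "caprimir_domain_error")
  # stable at library-scale counts
  p_big <- audic_claverie_p(MIR1_FC, MIR1_SMC, CLEAN_READS_FC, CLEAN_READS_SMC)
  expect_true(is.finite(p_big) && p_big >= 0 && p_big <= 1)
})

test_that("library swap negates log2fc and mirrors the test", {
  set.seed(31)
  x <- rpois(50, 40)
  y <- rpois(50, 60)
  n1 <- 1e5; n2 <- 2e5
  lfc <- log2_fold_change(normalize_expression(x, n1),
                          normalize_expression(y, n2))
  lfc_sw <- log2_fold_change(normalize_expression(y, n2),
                             normalize_expression(x, n1))
  expect_equal(lfc_sw, -lfc)
  # the test conditions on the library-1 count, so the swapped p
  # agrees closely (the pmfs match up to the factor N1/N2; the tail
  # conventions differ only at the observed point) but is exactly
  # invariant only at the symmetric center
  expect_equal(audic_claverie_p(30, 30, n1, n1), 1)
  p <- audic_claverie_p(x, y, n1, n2)
  p_sw <- audic_claverie_p(y, x, n2, n1)
  expect_true(all(pmax(p, p_sw) / pmin(p, p_sw) < 2.5))
  # up/down classes swap under the library swap
  ct <- count_table(sprintf("f%02d", 1:50), x * 40, y * 40, c(n1, n2) * 40)
  ct_sw <- count_table(sprintf("f%02d", 1:50), y * 40, x * 40, c(n2, n1) * 40)
  de <- de_table(ct)
  de_sw <- de_table(ct_sw)
  expect_equal(de_sw$de_class == "up", de$de_class == "down")
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  # order preserved
  p <- c(0.04, 0.001, 0.8)
  expect_equal(order(bh_fdr(p)), order(p))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "caprimir_domain_error")
})

test_that("DE classes follow the FDR and fold-change screen", {
  expect_equal(as.character(classify_de(0.0005, 1.5)), "up")
  expect_equal(as.character(classify_de(0.0005, 0.5)), "not_de")
  expect_equal(as.character(classify_de(0.1, 5)), "not_de")
  expect_equal(as.character(classify_de(0.0005, -1)), "down")
  expect_equal(as.character(scatter_class(30, 10)), "fold>2")
  expect_equal(as.character(scatter_class(10, 10)), "1/2<fold<=2")
  expect_equal(as.character(scatter_class(4, 10)), "fold<=1/2")
})

test_that("de_table runs the full procedure per feature", {
  ct <- count_table(c("a", "b", "c"), c(5, 100, 0), c(5, 10, 0),
                    c(1000, 1000))
  de <- de_table(ct)
  expect_s3_class(de, "mir_de")
  expect_equal(de$p[1], 1)
  expect_equal(as.character(de$de_class[1]), "not_de")
  # both-zero feature excluded from calling
  expect_true(is.na(de$log2fc[3]))
  expect_true(is.na(de$fdr[3]))
  expect_equal(as.character(de$de_class[3]), "not_de")
  g <- glance(de)
  expect_equal(g$n_features, 3)
  expect_equal(g$n_tested, 2)
  expect_s3_class(tidy(de), "tbl_df")
})

test_that("planted strong effects are recovered with high power", {
  sim <- simulate_libraries(n_features = 400, de_fraction = 0.25,
                            effect_log2 = 3, seed = 91)
  de <- de_table(sim$counts)
  joined <- merge(de, sim$truth, by = "feature")
  strong <- joined$de & joined$baseline_pm >= 50
  power <- mean(joined$de_class[strong] != "not_de")
  expect_gte(power, 0.9)
  # recovered direction matches the planted sign
  rec <- joined[strong & joined$de_class != "not_de", ]
  expect_true(all(sign(rec$log2fc) == sign(rec$effect_log2)))
})

test_that("null simulation keeps the empirical type-I error at bound", {
  sim <- simulate_libraries(n_features = 2000, de_fraction = 0,
                            seed = 17)
  de <- de_table(sim$counts)
  tested <- !(de$x == 0 & de$y == 0)
  for (alpha in c(0.01, 0.05)) {
    frac <- mean(de$p[tested] <= alpha)
    margin <- 3 * sqrt(alpha * (1 - alpha) / sum(tested))
    expect_lte(frac, alpha + margin)
  }
})
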