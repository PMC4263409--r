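toy_pm <- function(abundance, peptide_map, samples) {
  structure(list(abundance = abundance, peptide_map = peptide_map,
                 samples = samples), class = "peptide_matrix")
}

toy_samples <- function(n_anc = 2, n_pop = 2, n_rep = 2) {
  pops <- sprintf("EV%02d", seq_len(n_pop))
  data.frame(
    sample = c(sprintf("ANC_r%d", seq_len(n_anc)),
               as.vector(t(outer(pops, seq_len(n_rep), paste, sep = "_r")))),
    group = rep(c("ancestor", "evolved"), c(n_anc, n_pop * n_rep)),
    population = c(rep("ancestor", n_anc), rep(pops, each = n_rep)),
    stringsAsFactors = FALSE)
}

test_that("roll-up reproduces single peptides and is order- and shift-invariant", {
  s <- toy_samples()
  x <- matrix(c(5, 6, 7, 8, 9, 10), 1,
              dimnames = list("pep1", s$sample))
  pm <- toy_pm(x, data.frame(peptide_id = "pep1", protein_id = "P1"), s)
  expect_equal(unname(rollup_proteins(pm, align_samples = FALSE)["P1", ]),
               c(5, 6, 7, 8, 9, 10))

  x2 <- rbind(pep1 = c(5, 6, 7, 8, 9, 10), pep2 = c(7, 8, 9, 10, 11, 12))
  colnames(x2) <- s$sample
  map2 <- data.frame(peptide_id = c("pep1", "pep2"), protein_id = "P1")
  pm2 <- toy_pm(x2, map2, s)
  r2 <- rollup_proteins(pm2, align_samples = FALSE)
  # two peptides offset by a constant: protein follows their common shape
  expect_equal(unname(diff(r2["P1", ])), rep(1, 5))
  pm2r <- toy_pm(x2[2:1, ], map2[2:1, ], s)
  expect_equal(rollup_proteins(pm2r, align_samples = FALSE), r2)
  # adding a constant to one peptide leaves fold changes unchanged
  x3 <- x2; x3["pep2", ] <- x3["pep2", ] + 5
  r3 <- rollup_proteins(toy_pm(x3, map2, s), align_samples = FALSE)
  expect_equal(diff(r3["P1", ]), diff(r2["P1", ]))

  bad <- toy_pm(x2, map2[1, , drop = FALSE], s)
  expect_error(rollup_proteins(bad), "without a protein mapping")
})

test_that("planted effects come through the roll-up exactly at zero noise", {
  pm <- simulate_peptides(n_proteins = 6, planted_effects = c(1, 0, 0, -2, 0, 0),
                          noise_sd = 0, missing_rate = 0, seed = 4)
  prot <- rollup_proteins(pm, align_samples = FALSE)
  dt <- differential_test(prot, pm$samples)
  expect_equal(dt$log2fc, c(1, 0, 0, -2, 0, 0))
  fc_pop <- attr(dt, "per_population_fc")
  expect_equal(unname(fc_pop["P0001", ]), rep(1, 12))
  expect_equal(unname(fc_pop["P0004", ]), rep(-2, 12))
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(5)
  s <- toy_samples(n_anc = 2, n_pop = 1, n_rep = 2)
  for (i in 1:25) {
    y <- rnorm(4)
    m <- matrix(y, 1, dimnames = list("P1", s$sample))
    dt <- differential_test(m, s)
    tt <- t.test(y[3:4], y[1:2], var.equal = TRUE)
    expect_equal(dt$p_value, tt$p.value, tolerance = 1e-12)
  }
})

test_that("identical groups give p ~ 1 region and untestable proteins stay out", {
  s <- toy_samples(n_anc = 3, n_pop = 2, n_rep = 2)
  y <- c(1, 2, 3, 1, 3, 2, 2)  # same mean 2 and spread in both groups
  m <- matrix(y, 1, dimnames = list("P1", s$sample))
  dt <- differential_test(m, s)
  expect_equal(dt$log2fc, 0)
  expect_gt(dt$p_value, 0.9)

  # protein absent from the ancestor: emitted but never significant
  m2 <- rbind(P1 = y, P2 = c(NA, NA, NA, 5, 5, 9, 9))
  colnames(m2) <- s$sample
  dt2 <- differential_test(m2, s)
  expect_true(is.na(dt2$log2fc[2]))
  expect_false(dt2$testable[2])
  expect_equal(nrow(significance_filter(dt2)), 0L)
})

test_that("significance filter applies dual thresholds with stated boundaries", {
  rec <- data.frame(protein_id = paste0("P", 1:5),
                    log2fc = c(1.0, 0.5, 2.0, 0.7, -1.2),
                    p_value = c(0.005, 0.005, 0.02, 0.01, 0.01),
                    n_populations_detected = 12L, testable = TRUE,
                    stringsAsFactors = FALSE)
  sig <- significance_filter(rec)
  # p <= 0.01 passes at the boundary; |FC| = 0.7 fails at the boundary
  expect_setequal(sig$protein_id, c("P1", "P5"))
  expect_equal(sig$direction[order(sig$protein_id)], c("up", "down"))
  expect_equal(attr(sig, "direction_counts"), c(up = 1L, down = 1L))
})

test_that("null simulation keeps the type-I error near its nominal level", {
  pm <- simulate_peptides(n_proteins = 2000, peptides_per_protein_mean = 3,
                          planted_effects = numeric(2000),
                          noise_sd = 0.2, missing_rate = 0.02, seed = 8)
  dt <- differential_test(rollup_proteins(pm), pm$samples)
  rate <- mean(dt$p_value <= 0.01, na.rm = TRUE)
  se <- sqrt(0.01 * 0.99 / sum(!is.na(dt$p_value)))
  expect_lt(abs(rate - 0.01), 3 * se + 1e-8)
})

test_that("planted regulation is recovered and the heat map keeps missing cells", {
  effects <- c(rep(1.5, 20), rep(-1.5, 10), rep(0, 170))
  pm <- simulate_peptides(n_proteins = 200, planted_effects = effects,
                          noise_sd = 0.2, missing_rate = 0.05, seed = 12)
  dt <- differential_test(rollup_proteins(pm), pm$samples)
  sig <- significance_filter(dt)
  truth_pos <- names(pm$truth_effects)[effects != 0]
  sens <- mean(truth_pos %in% sig$protein_id)
  fdp <- mean(!sig$protein_id %in% truth_pos)
  expect_gte(sens, 0.95)
  expect_lte(fdp, 0.1)

  cls <- data.frame(protein_id = truth_pos,
                    class = rep(c("TCA cycle", "chaperones"), c(20, 10)),
                    stringsAsFactors = FALSE)
  ht <- functional_heatmap_table(sig, cls)
  expect_equal(ht$class, sort(ht$class))
  tca <- ht[ht$class == "TCA cycle", -(1:2)]
  expect_true(all(tca > 0, na.rm = TRUE))
  expect_equal(nrow(functional_heatmap_table(sig[0, , drop = FALSE])), 0L)

  # undetected protein x population cells stay NA, never zero
  pm$abundance[pm$peptide_map$protein_id == sig$protein_id[1],
               pm$samples$population == "EV05"] <- NA
  dt2 <- differential_test(rollup_proteins(pm), pm$samples)
  sig2 <- significance_filter(dt2)
  ht2 <- functional_heatmap_table(sig2, cls)
  expect_true(is.na(ht2[ht2$protein_id == sig$protein_id[1], "EV05"]))
})
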