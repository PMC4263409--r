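test_that("frequency floor is inclusive and validates its threshold", {
  calls <- make_calls(frequency = c(0.04, 0.05, 0.50))
  expect_equal(apply_frequency_floor(calls)$frequency, c(0.05, 0.50))
  expect_equal(nrow(apply_frequency_floor(calls[0, ])), 0L)
  expect_equal(nrow(apply_frequency_floor(calls, min_freq = 1.0)), 0L)
  expect_error(apply_frequency_floor(calls, 0), "min_freq")
  expect_error(apply_frequency_floor(calls, 1.2), "min_freq")
})

test_that("effect classification follows the bacterial code and indel frame rules", {
  # CTG and CTA are both Leu; TGG -> TGA gains a stop
  seqs <- "ATGCTGTGGTAA"
  expect_equal(classify_effect(seqs, 6, "G", "A"), "synonymous")
  expect_equal(classify_effect(seqs, 9, "G", "A"), "stop_gained")
  expect_equal(classify_effect(seqs, 5, "T", "A"), "nonsynonymous")
  # 4-nt deletion (anchor + 4) is a frameshift; 3-nt deletion is in-frame
  expect_equal(classify_effect(seqs, 2, "TGCTG", "T"), "frameshift")
  expect_equal(classify_effect(seqs, 2, "TGCT", "T"), "inframe_indel")
  expect_equal(classify_effect(seqs, 50, "A", "G"), "intergenic")
  expect_error(classify_effect(seqs, 6, "A", "C"), "does not match")
})

test_that("non-synonymous selection keeps exactly the protein-consequential classes", {
  calls <- make_calls(effect = c("synonymous", "nonsynonymous", "frameshift",
                                 "stop_gained", "inframe_indel", "intergenic"))
  kept <- select_nonsynonymous(calls)
  expect_setequal(kept$effect, c("nonsynonymous", "frameshift",
                                 "stop_gained", "inframe_indel"))
  expect_equal(nrow(select_nonsynonymous(make_calls(effect = "synonymous"))), 0L)
})

test_that("MA blacklist counts distinct lines at a site, not calls", {
  ma <- rbind(make_calls(population_id = paste0("MA", 1:4), position = 100L),
              make_calls(population_id = paste0("MA", 1:3), position = 200L),
              # duplicate calls in one line must not inflate the count
              make_calls(population_id = c("MA1", "MA1", "MA2", "MA3"),
                         position = 300L))
  bl <- build_ma_blacklist(ma, min_lines = 4)
  expect_equal(bl$position, 100L)
  expect_equal(bl$n_ma_lines, 4L)
  expect_equal(nrow(build_ma_blacklist(ma[0, ], 4)), 0L)
  expect_error(build_ma_blacklist(ma, min_lines = 0), "min_lines")

  calls <- make_calls(position = c(100L, 200L, 400L))
  out <- apply_blacklist(calls, bl)
  expect_equal(out$position, c(200L, 400L))
  expect_equal(attr(out, "n_removed"), 1L)
  expect_identical(apply_blacklist(calls, bl[0, ])$position, calls$position)
  all_bl <- data.frame(contig = "c1", position = c(100L, 200L, 400L))
  gone <- apply_blacklist(calls, all_bl)
  expect_equal(nrow(gone), 0L)
  expect_equal(attr(gone, "n_removed"), 3L)
})

test_that("Levene statistic handles degenerate spreads and matches brute force", {
  r <- levene_statistic(list(c(1, 1, 1), c(2, 2, 2)))
  expect_equal(r$W, 0)
  expect_equal(r$p_value, 1)
  r2 <- levene_statistic(list(c(0, 2), c(0, 2)))
  expect_equal(r2$W, 0)
  expect_equal(r2$p_value, 1)
  expect_false(levene_statistic(list(1, c(1, 2)))$testable)
  expect_error(levene_statistic(list(c(1, 2))), "2 groups")

  r3 <- levene_statistic(list(c(1, 2, 3, 4), c(2, 4, 6, 8)))
  o3 <- levene_oracle(list(c(1, 2, 3, 4), c(2, 4, 6, 8)))
  expect_equal(r3$W, o3$W, tolerance = 1e-12)
  expect_equal(r3$p_value, o3$p_value, tolerance = 1e-12)
})

test_that("Levene implementation agrees with independent references on random instances", {
  skip_if_not_installed("car")
  set.seed(42)
  for (i in 1:200) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j)
      rnorm(sample(2:8, 1), mean = runif(1, 0, 1), sd = runif(1, 0.01, 1)))
    mine <- levene_statistic(groups)
    oracle <- levene_oracle(groups)
    expect_equal(mine$W, oracle$W, tolerance = 1e-10)
    expect_equal(mine$p_value, oracle$p_value, tolerance = 1e-10)
    y <- unlist(groups)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    cl <- car::leveneTest(y, g, center = mean)
    expect_equal(mine$W, cl[1, "F value"], tolerance = 1e-10)
    expect_equal(mine$p_value, cl[1, "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("Levene artifact filter removes uniform sites and keeps treatment-structured ones", {
  pops <- two_treatment_pops(12)
  set.seed(7)
  # artifact-like site: ~0.120 +/- 0.003 in all 24 populations
  art <- make_calls(population_id = pops$population_id, position = 500L,
                    frequency = 0.12 + rnorm(24, 0, 0.003))
  # adaptive-like site: 0.4-0.8 in LB only
  lb <- pops$population_id[pops$treatment == "LB"]
  adp <- make_calls(population_id = lb, position = 900L,
                    frequency = runif(12, 0.4, 0.8))
  # sparse site: observed in a single population
  sparse <- make_calls(population_id = lb[1], position = 1300L, frequency = 0.3)
  res <- levene_artifact_filter(rbind(art, adp, sparse), pops)
  expect_equal(res$removed_sites$position, 500L)
  expect_setequal(res$kept$position, c(900L, 1300L))
  expect_false(res$results$testable[res$results$position == 1300])
  expect_error(levene_artifact_filter(art, pops[pops$treatment == "LB", ]),
               "2 treatments")
})

test_that("filters are subsets, idempotent, and monotone in their thresholds", {
  set.seed(11)
  for (i in 1:20) {
    calls <- make_calls(
      population_id = sample(paste0("p", 1:6), 40, replace = TRUE),
      position = sample(1:30, 40, replace = TRUE) * 10L,
      effect = sample(EFFECTS <- c("synonymous", "nonsynonymous", "frameshift"),
                      40, replace = TRUE),
      frequency = round(runif(40, 0.01, 1), 3))
    f <- runif(1, 0.02, 0.5)
    once <- apply_frequency_floor(calls, f)
    expect_true(nrow(once) <= nrow(calls))
    expect_identical(apply_frequency_floor(once, f), once)
    f_lo <- f / 2
    expect_gte(nrow(apply_frequency_floor(calls, f_lo)), nrow(once))

    ns <- select_nonsynonymous(calls)
    expect_identical(select_nonsynonymous(ns), ns)

    ma <- make_calls(
      population_id = sample(paste0("MA", 1:8), 40, replace = TRUE),
      position = sample(1:15, 40, replace = TRUE) * 10L)
    m <- sample(2:5, 1)
    bl_hi <- build_ma_blacklist(ma, m + 1L)
    bl_lo <- build_ma_blacklist(ma, m)
    expect_true(all(paste(bl_hi$contig, bl_hi$position) %in%
                      paste(bl_lo$contig, bl_lo$position)))
    kept <- apply_blacklist(calls, bl_lo)
    expect_identical(apply_blacklist(kept, bl_lo)$position, kept$position)
  }
})
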