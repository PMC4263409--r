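test_that("gene-by-population matrix counts calls and conserves column sums", {
  pops <- paste0("p", 1:3)
  expect_equal(dim(gene_mutation_matrix(make_calls()[0, ], pops)), c(0L, 3L))
  m1 <- gene_mutation_matrix(make_calls(population_id = "p1", gene_id = "gA"),
                             pops)
  expect_equal(m1["gA", "p1"], 1L)
  expect_equal(sum(m1), 1L)

  calls <- make_calls(population_id = c("p1", "p1", "p2", "p3"),
                      gene_id = c("gA", "gB", "gA", "gA"),
                      position = c(10L, 20L, 10L, 15L))
  m <- gene_mutation_matrix(calls, pops)
  expect_equal(unname(colSums(m)),
               as.vector(table(factor(calls$population_id, levels = pops))))
  expect_error(gene_mutation_matrix(make_calls(population_id = "zzz"), pops),
               "unknown population")
})

test_that("parallelism summary ranks by populations then mutations with gene-id ties", {
  pops <- paste0("p", 1:4)
  calls <- rbind(
    make_calls(population_id = c("p1", "p2", "p3"), gene_id = "gB",
               position = c(1L, 2L, 3L)),
    make_calls(population_id = c("p1", "p2", "p3"), gene_id = "gA",
               position = c(11L, 12L, 13L)),
    make_calls(population_id = c("p1", "p1", "p2"), gene_id = "gC",
               position = c(21L, 22L, 23L)))
  s <- parallelism_summary(gene_mutation_matrix(calls, pops), calls = calls)
  expect_equal(s$gene_id, c("gA", "gB", "gC"))  # tie gA/gB broken lexically
  expect_equal(s$n_populations, c(3L, 3L, 2L))
  expect_equal(s$n_mutations, c(3L, 3L, 3L))
  expect_equal(s$n_unique_alleles, c(3L, 3L, 3L))

  one <- parallelism_summary(gene_mutation_matrix(
    make_calls(population_id = "p1", gene_id = "g"), "p1"))
  expect_equal(one$n_populations, 1L)
  expect_equal(one$n_mutations, 1L)
})

test_that("histogram stores true counts and caps only the displayed value", {
  pops <- paste0("p", 1:3)
  singletons <- make_calls(population_id = "p1",
                           gene_id = paste0("g", 1:300),
                           position = seq_len(300) * 3L)
  m <- gene_mutation_matrix(singletons, pops)
  h <- parallelism_histogram(m, cap = 120)
  expect_equal(h$count, 300L)
  expect_equal(h$display_count, 120L)
  expect_equal(h$n_populations, 1L)
  expect_equal(nrow(parallelism_histogram(m[0, , drop = FALSE])), 0L)
  expect_error(parallelism_histogram(m, cap = 0), "cap")
  # total number of binned genes equals the summary's row count
  expect_equal(sum(h$count), nrow(parallelism_summary(m)))
})

test_that("cumulative gene frequency sums alleles and flags sums above one", {
  calls <- make_calls(population_id = "p1", gene_id = "gA",
                      position = c(10L, 20L, 30L),
                      frequency = c(0.30, 0.25, 0.20))
  cf <- cumulative_gene_frequency(calls, "gA", c("p1", "p2"))
  expect_equal(cf$cumulative_frequency, c(0.75, 0))
  expect_equal(cf$exceeds_one, c(FALSE, FALSE))

  fixed <- cumulative_gene_frequency(
    make_calls(population_id = "p1", gene_id = "gA", frequency = 1.0),
    "gA", "p1")
  expect_equal(fixed$cumulative_frequency, 1.0)
  expect_false(fixed$exceeds_one)

  over <- cumulative_gene_frequency(
    make_calls(population_id = "p1", gene_id = "gA",
               position = c(1L, 2L), frequency = c(0.7, 0.6)),
    "gA", "p1")
  expect_equal(over$cumulative_frequency, 1.3)
  expect_true(over$exceeds_one)
  expect_error(cumulative_gene_frequency(calls, "nope", "p1"), "unknown gene")
})

test_that("random-parallelism probability is exact in log space", {
  # independently evaluated: -12 * (log10(4565) + log10(5068)) = -88.3665...
  r <- random_parallelism_probability(c(4565, 5068), c(12, 12))
  expect_equal(r$log10_p, -12 * (log10(4565) + log10(5068)))
  expect_equal(round(r$log10_p, 2), -88.37)
  expect_equal(random_parallelism_probability(10, 1)$p, 0.1)
  expect_equal(random_parallelism_probability(1, 5)$p, 1.0)
  expect_error(random_parallelism_probability(0, 1), "gene counts")
  expect_error(random_parallelism_probability(c(10, 10), 1), "equal length")
})

test_that("Tukey-fence mutator flagging finds outlier populations", {
  counts <- c(57, 60, 55, 50, 52, 58, 61, 49, 54, 56, 310, 290)
  names(counts) <- paste0("p", 1:12)
  expect_setequal(flag_mutators(counts), c("p11", "p12"))
  same <- setNames(rep(50, 8), paste0("q", 1:8))
  expect_length(flag_mutators(same), 0L)
  expect_warning(flag_mutators(setNames(c(1, 100), c("a", "b"))), "fewer than")
  # median rule alternative
  expect_setequal(flag_mutators(counts, method = "median", multiplier = 4),
                  c("p11", "p12"))
})

test_that("unique allele spectrum deduplicates and localizes to domains", {
  calls <- make_calls(population_id = c("p1", "p2", "p3"),
                      gene_id = "gA", position = 100L)
  sp <- unique_allele_spectrum(calls, "gA")
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$n_populations, 3L)
  expect_equal(nrow(unique_allele_spectrum(calls, "gEmpty")), 0L)

  ann <- data.frame(gene_id = "gA", contig = "c1", start = 91L, end = 810L,
                    strand = "+", length_nt = 720L,
                    subsystem = "s", category = "c", stringsAsFactors = FALSE)
  dm <- arca_like_domains()
  calls2 <- make_calls(population_id = "p1", gene_id = "gA",
                       position = c(100L, 460L, 805L))
  sp2 <- suppressWarnings(
    unique_allele_spectrum(calls2, "gA", annotation = ann, domains = dm))
  # residues ceiling((pos-91+1)/3) = 4, 124, 239
  expect_equal(sp2$residue, c(4L, 124L, 239L))
  expect_warning(
    unique_allele_spectrum(calls2, "gA", annotation = ann, domains = dm),
    "outside")
  expect_equal(sp2$domain, c("receiver", "DNA_binding", "outside"))
})

test_that("loss-of-function bias of the rpoS-like driver shows in its spectrum", {
  lofs <- vapply(1:5, function(s) {
    ds <- simulate_experiment(small_config(seed = s))
    ann <- ds$annotations$sp1
    bhi <- ds$populations$population_id[ds$populations$species == "sp1" &
                                          ds$populations$treatment == "BHI"]
    sp <- unique_allele_spectrum(
      ds$variants[ds$variants$population_id %in% bhi, ], ann$gene_id[25])
    comp <- attr(sp, "effect_composition")
    sum(comp[c("stop_gained", "frameshift")], na.rm = TRUE) / sum(comp)
  }, numeric(1))
  expect_gte(mean(lofs), 0.6)
})
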