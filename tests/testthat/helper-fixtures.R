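# In-code fixtures shared across test files.

make_calls <- function(population_id = "p1", contig = "c1",
                       position = seq_along(frequency) * 10L,
                       ref = "A", alt = "G", vtype = "snp",
                       gene_id = "g1", effect = "nonsynonymous",
                       frequency = 0.5) {
  n <- max(lengths(list(population_id, position, frequency, effect, gene_id)))
  data.frame(population_id = rep_len(population_id, n),
             contig = rep_len(contig, n),
             position = rep_len(as.integer(position), n),
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             vtype = rep_len(vtype, n),
             gene_id = rep_len(gene_id, n),
             effect = rep_len(effect, n),
             frequency = rep_len(frequency, n),
             stringsAsFactors = FALSE)
}

two_treatment_pops <- function(n = 12L, species = "sp1") {
  do.call(rbind, lapply(c("LB", "BHI"), function(tr)
    data.frame(population_id = sprintf("%s_%s%d", species, tr, seq_len(n)),
               species = species, treatment = tr, replicate = seq_len(n),
               is_ma = FALSE, excluded = FALSE, stringsAsFactors = FALSE)))
}

# Small experiment for end-to-end tests: one species pair at reduced size.
small_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_genes_per_species = c(120L, 130L), ...)
  if (!"artifact_sites" %in% names(args)) args$artifact_sites <- 10L
  do.call(sim_config, args)
}

# Independent brute-force Levene oracle: one-way ANOVA on the absolute
# deviations from the group center, via lm/anova.
levene_oracle <- function(groups, center = mean) {
  z <- unlist(lapply(groups, function(x) abs(x - center(x))))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  a <- stats::anova(stats::lm(z ~ g))
  list(W = a[1, "F value"], p_value = a[1, "Pr(>F)"])
}
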