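#' Simulate a peptide abundance matrix with planted protein effects
#'
#' Emulates a label-free LC-MS population-proteomics design: one ancestor
#' group with replicate analyses plus evolved populations, each measured in
#' replicate. Peptide log2 abundances are
#' `protein baseline + planted group effect + peptide offset + N(0, noise_sd)`,
#' and entries are set missing independently at `missing_rate`. The planted
#' effect of a protein is added to every evolved sample, so the truth
#' log2 fold change (evolved - ancestor) equals the planted value exactly in
#' expectation.
#'
#' @param n_proteins number of proteins (default 488, a typical observed set).
#' @param peptides_per_protein_mean peptides per protein are
#'   `1 + Poisson(mean - 1)` (default 9, matching a few thousand peptides
#'   over a few hundred proteins).
#' @param n_populations evolved populations (default 12).
#' @param n_replicates replicates per group, ancestor included (default 3).
#' @param planted_effects numeric vector (length `n_proteins`) of true log2
#'   fold changes; zeros are nulls. Default all zero.
#' @param noise_sd residual sd of log2 abundances (default 0.1).
#' @param missing_rate independent missingness probability (default 0.05).
#' @param seed integer seed.
#' @return list of class `peptide_matrix`: `abundance` (peptides x samples,
#'   NA = missing), `peptide_map` (peptide_id, protein_id), `samples`
#'   (sample, group in {ancestor, evolved}, population), and
#'   `truth_effects`.
#' @export
simulate_peptides <- function(n_proteins = 488L,
                              peptides_per_protein_mean = 9,
                              n_populations = 12L,
                              n_replicates = 3L,
                              planted_effects = numeric(n_proteins),
                              noise_sd = 0.1,
                              missing_rate = 0.05,
                              seed = 1L) {
  if (missing_rate < 0 || missing_rate > 1)
    stop_input("missing_rate must lie in [0, 1]")
  if (n_replicates < 2L)
    stop_input("the ancestor group needs >= 2 replicates")
  if (length(planted_effects) != n_proteins)
    stop_input("planted_effects must have one entry per protein")
  with_seed(substream_seed(seed, "peptides"), {
    prot_ids <- sprintf("P%04d", seq_len(n_proteins))
    n_pep <- 1L + stats::rpois(n_proteins, max(peptides_per_protein_mean - 1, 0))
    protein_of <- rep(prot_ids, n_pep)
    pep_ids <- sprintf("pep%05d", seq_along(protein_of))

    pops <- sprintf("EV%02d", seq_len(n_populations))
    samples <- data.frame(
      sample = c(sprintf("ANC_r%d", seq_len(n_replicates)),
                 as.vector(t(outer(pops, seq_len(n_replicates),
                                   function(p, r) sprintf("%s_r%d", p, r))))),
      group = rep(c("ancestor", "evolved"),
                  c(n_replicates, n_populations * n_replicates)),
      population = c(rep("ancestor", n_replicates),
                     rep(pops, each = n_replicates)),
      stringsAsFactors = FALSE
    )

    baseline <- stats::rnorm(n_proteins, 25, 2)
    pep_offset <- stats::rnorm(length(pep_ids), 0, 1)
    effect_of_pep <- rep(planted_effects, n_pep)
    base_of_pep <- rep(baseline, n_pep)

    is_evolved <- samples$group == "evolved"
    mat <- base_of_pep + pep_offset +
      outer(effect_of_pep, as.numeric(is_evolved)) +
      matrix(stats::rnorm(length(pep_ids) * nrow(samples), 0, noise_sd),
             nrow = length(pep_ids))
    dimnames(mat) <- list(pep_ids, samples$sample)
    if (missing_rate > 0)
      mat[stats::runif(length(mat)) < missing_rate] <- NA_real_

    structure(list(abundance = mat,
                   peptide_map = data.frame(peptide_id = pep_ids,
                                            protein_id = protein_of,
                                            stringsAsFactors = FALSE),
                   samples = samples,
                   truth_effects = stats::setNames(planted_effects, prot_ids)),
              class = "peptide_matrix")
  })
}

#' Peptide-to-protein abundance roll-up
#'
#' Converts peptide-level log2 abundances into protein-level profiles.
#' Samples are first median-aligned (each sample shifted so its median over
#' observed peptides equals the grand median). Then, per protein, each
#' peptide is centered by its own across-sample mean, the centered peptides
#' are averaged per sample ignoring missing values, and the protein-level
#' grand mean (mean of its peptides' means) is added back. The default is
#' deterministic and invariant to peptide order; a median-based variant
#' (`method = "median_centered"`) uses medians for the per-sample summary.
#' A protein is observed in a sample only if at least one of its peptides
#' is; a single-peptide protein reproduces its peptide exactly (after
#' alignment).
#'
#' @param pm a `peptide_matrix` (or list with `abundance` and `peptide_map`).
#' @param method `"mean_centered"` (default) or `"median_centered"`.
#' @param align_samples median-align samples first (default TRUE).
#' @return protein x sample numeric matrix (NA where unobserved).
#' @export
rollup_proteins <- function(pm, method = c("mean_centered", "median_centered"),
                            align_samples = TRUE) {
  method <- match.arg(method)
  x <- pm$abundance
  map <- pm$peptide_map
  if (!all(rownames(x) %in% map$peptide_id))
    stop_input("peptide(s) without a protein mapping")
  if (align_samples) {
    med <- apply(x, 2L, stats::median, na.rm = TRUE)
    x <- sweep(x, 2L, med - stats::median(med))
  }
  prot_of <- stats::setNames(map$protein_id, map$peptide_id)[rownames(x)]
  rows_of <- split(seq_len(nrow(x)), prot_of)
  proteins <- names(rows_of)
  sumfun <- if (method == "mean_centered") {
    function(m) colMeans(m, na.rm = TRUE)
  } else {
    function(m) apply(m, 2L, stats::median, na.rm = TRUE)
  }
  out <- matrix(NA_real_, length(proteins), ncol(x),
                dimnames = list(proteins, colnames(x)))
  for (p in proteins) {
    m <- x[rows_of[[p]], , drop = FALSE]
    pep_means <- rowMeans(m, na.rm = TRUE)
    centered <- m - pep_means
    prof <- sumfun(centered) + mean(pep_means)
    prof[colSums(!is.na(m)) == 0L] <- NA_real_
    out[p, ] <- prof
  }
  out
}

#' Per-protein differential abundance test
#'
#' One-way analysis of variance of protein log2 abundance between the
#' ancestor and evolved samples (classic equal-variance F test). The default
#' two-group design pools all evolved samples; `design = "per_population"`
#' fits one group per evolved population plus the ancestor. The overall
#' log2 fold change is `mean(evolved) - mean(ancestor)`, and per-population
#' fold changes (`mean(population replicates) - mean(ancestor)`) are
#' attached for heat-map rendering. Proteins observed in fewer than two
#' ancestor replicates are untestable: their record is emitted with missing
#' fold change/p-value and they can never enter the significant set.
#'
#' @param protein_matrix protein x sample matrix from [rollup_proteins()].
#' @param samples sample table with `sample`, `group`, `population`.
#' @param design `"two_group"` (default) or `"per_population"`.
#' @return data.frame with `protein_id`, `log2fc`, `p_value`,
#'   `n_populations_detected`, `testable`; per-population fold changes in
#'   attribute `per_population_fc` (protein x population matrix).
#' @export
differential_test <- function(protein_matrix, samples,
                              design = c("two_group", "per_population")) {
  design <- match.arg(design)
  stopifnot(all(colnames(protein_matrix) == samples$sample))
  anc_cols <- samples$group == "ancestor"
  if (sum(anc_cols) < 2L) stop_input("need >= 2 ancestor samples")
  pops <- unique(samples$population[!anc_cols])

  n <- nrow(protein_matrix)
  log2fc <- p_value <- rep(NA_real_, n)
  npop_det <- integer(n)
  testable <- logical(n)
  fc_pop <- matrix(NA_real_, n, length(pops),
                   dimnames = list(rownames(protein_matrix), pops))

  for (i in seq_len(n)) {
    y <- protein_matrix[i, ]
    anc <- y[anc_cols & !is.na(y)]
    evo <- y[!anc_cols & !is.na(y)]
    pop_means <- tapply(y[!anc_cols], samples$population[!anc_cols],
                        mean, na.rm = TRUE)
    det <- !is.na(pop_means) & !is.nan(pop_means)
    npop_det[i] <- sum(det)
    if (length(anc) < 2L || length(evo) < 1L) next
    fc_pop[i, names(pop_means)[det]] <- pop_means[det] - mean(anc)
    log2fc[i] <- mean(evo) - mean(anc)
    grp <- if (design == "two_group") {
      factor(ifelse(anc_cols, "ancestor", "evolved"))
    } else {
      factor(ifelse(anc_cols, "ancestor", samples$population))
    }
    ok <- !is.na(y)
    grp_ok <- droplevels(grp[ok])
    if (nlevels(grp_ok) < 2L) next
    yy <- y[ok]
    if (stats::var(yy) == 0) {
      p_value[i] <- 1
    } else {
      p_value[i] <- tryCatch(
        stats::oneway.test(yy ~ grp_ok, var.equal = TRUE)$p.value,
        error = function(e) NA_real_)
    }
    testable[i] <- !is.na(p_value[i])
  }
  out <- data.frame(protein_id = rownames(protein_matrix),
                    log2fc = log2fc, p_value = p_value,
                    n_populations_detected = npop_det,
                    testable = testable, stringsAsFactors = FALSE)
  attr(out, "per_population_fc") <- fc_pop
  out
}

#' Dual-threshold significance filter
#'
#' A protein is called significant when `p <= p_max` (boundary inclusive)
#' AND `|log2fc| > min_abs_log2fc` (boundary exclusive). Direction follows
#' the sign of the fold change; up/down counts are attached as attribute
#' `direction_counts`.
#'
#' @param records output of [differential_test()].
#' @param p_max p-value ceiling (default 0.01).
#' @param min_abs_log2fc absolute log2 fold-change threshold (default 0.7).
#' @return the significant subset of `records` with a `direction` column.
#' @export
significance_filter <- function(records, p_max = 0.01, min_abs_log2fc = 0.7) {
  sig <- !is.na(records$p_value) & !is.na(records$log2fc) &
    records$p_value <= p_max & abs(records$log2fc) > min_abs_log2fc
  out <- records[sig, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  fc_pop <- attr(records, "per_population_fc")
  if (!is.null(fc_pop))
    attr(out, "per_population_fc") <- fc_pop[sig, , drop = FALSE]
  attr(out, "direction_counts") <- c(up = sum(out$direction == "up"),
                                     down = sum(out$direction == "down"))
  rownames(out) <- NULL
  out
}

#' Class-ordered per-population fold-change table
#'
#' Arranges the significant proteins' per-population log2 fold changes into
#' a heat-map-ready table, rows grouped by functional class then protein id.
#' Cells where the protein was not detected in a population stay missing
#' (NA) — they are never imputed as zero.
#'
#' @param records significant records from [significance_filter()] (with the
#'   `per_population_fc` attribute).
#' @param class_map data.frame with `protein_id` and `class`; unmapped
#'   proteins are grouped under `"other"`.
#' @return data.frame with `class`, `protein_id` and one column per
#'   population.
#' @export
functional_heatmap_table <- function(records, class_map = NULL) {
  fc <- attr(records, "per_population_fc")
  if (nrow(records) == 0L || is.null(fc))
    return(data.frame(class = character(), protein_id = character(),
                      stringsAsFactors = FALSE))
  cls <- rep("other", nrow(records))
  if (!is.null(class_map)) {
    m <- stats::setNames(class_map$class, class_map$protein_id)
    hit <- records$protein_id %in% names(m)
    cls[hit] <- unname(m[records$protein_id[hit]])
  }
  out <- data.frame(class = cls, protein_id = records$protein_id,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(fc[match(records$protein_id, rownames(fc)), ,
                                     drop = FALSE]))
  out <- out[order(out$class, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
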