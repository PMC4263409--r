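#' Gene-by-population mutation count matrix
#'
#' Entry (g, p) is the number of calls in gene g in population p. Genes with
#' no calls are omitted from the rows; intergenic calls are ignored. The
#' full population set is kept as columns so that presence counts are
#' comparable across genes.
#'
#' @param calls variant-call data.frame (filtered, analyzed populations).
#' @param populations character vector of analyzed population ids, or a
#'   population table with a `population_id` column.
#' @return integer matrix genes x populations.
#' @export
gene_mutation_matrix <- function(calls, populations) {
  if (is.data.frame(populations)) populations <- populations$population_id
  unknown <- setdiff(unique(calls$population_id), populations)
  if (length(unknown))
    stop_input("calls reference unknown population(s): ",
               paste(unknown, collapse = ", "))
  calls <- calls[calls$gene_id != "intergenic", , drop = FALSE]
  if (nrow(calls) == 0L)
    return(matrix(0L, 0L, length(populations),
                  dimnames = list(character(), populations)))
  tab <- table(factor(calls$gene_id),
               factor(calls$population_id, levels = populations))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m[order(rownames(m)), , drop = FALSE]
}

#' Per-gene parallelism summary
#'
#' For every mutated gene: the number of populations carrying at least one
#' mutation in the gene (presence), the total number of mutations, the
#' number of unique alleles, and per-treatment population counts. Sorted by
#' `n_populations` then `n_mutations` (descending) with `gene_id` as the
#' final, lexicographic tie-breaker so output is reproducible.
#'
#' @param matrix gene x population count matrix from [gene_mutation_matrix()].
#' @param calls optional calls used to count unique alleles per gene
#'   (deduplicated by position, ref, alt); without it `n_unique_alleles` is NA.
#' @param populations optional population table with `population_id` and
#'   `treatment` for the per-treatment columns.
#' @return data.frame, one row per mutated gene.
#' @export
parallelism_summary <- function(matrix, calls = NULL, populations = NULL) {
  if (nrow(matrix) == 0L)
    return(data.frame(gene_id = character(), n_populations = integer(),
                      n_mutations = integer(), n_unique_alleles = integer(),
                      stringsAsFactors = FALSE))
  out <- data.frame(
    gene_id = rownames(matrix),
    n_populations = as.integer(rowSums(matrix > 0)),
    n_mutations = as.integer(rowSums(matrix)),
    stringsAsFactors = FALSE
  )
  if (!is.null(calls)) {
    cc <- calls[calls$gene_id %in% out$gene_id, , drop = FALSE]
    u <- unique(cc[, c("gene_id", "position", "ref", "alt")])
    ua <- table(u$gene_id)
    out$n_unique_alleles <- as.integer(ua[out$gene_id])
  } else {
    out$n_unique_alleles <- NA_integer_
  }
  if (!is.null(populations)) {
    for (tr in unique(populations$treatment)) {
      cols <- intersect(populations$population_id[populations$treatment == tr],
                        colnames(matrix))
      out[[paste0("n_pop_", tr)]] <-
        as.integer(rowSums(matrix[, cols, drop = FALSE] > 0))
    }
  }
  out <- out[order(-out$n_populations, -out$n_mutations, out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Histogram of genes by number of mutated populations
#'
#' Bins genes by `n_populations`. A display cap (used in figures to keep the
#' singleton bin from dwarfing the parallel genes) affects only the
#' `display_count` column; `count` always stores the true value.
#'
#' @param matrix gene x population count matrix.
#' @param cap optional display cap (>= 1) applied to the rendered counts.
#' @return data.frame with `n_populations`, `count`, `display_count`.
#' @export
parallelism_histogram <- function(matrix, cap = NULL) {
  if (!is.null(cap) && cap < 1) stop_input("cap must be >= 1 or NULL")
  if (nrow(matrix) == 0L)
    return(data.frame(n_populations = integer(), count = integer(),
                      display_count = integer()))
  npop <- rowSums(matrix > 0)
  tab <- table(factor(npop, levels = seq_len(ncol(matrix))))
  out <- data.frame(n_populations = as.integer(names(tab)),
                    count = as.integer(tab))
  out <- out[out$count > 0, , drop = FALSE]
  out$display_count <- if (is.null(cap)) out$count else pmin(out$count, as.integer(cap))
  rownames(out) <- NULL
  out
}

#' Cumulative gene frequency per population
#'
#' Sums the frequencies of all alleles of one gene within each population —
#' the total fraction of the population carrying any mutation in the gene.
#' With co-segregating alleles and noisy frequency estimates the raw sum can
#' exceed 1; such sums are reported raw with `exceeds_one = TRUE` rather
#' than capped, since capping would hide data problems. Populations with no
#' allele in the gene report 0.
#'
#' @param calls variant-call data.frame.
#' @param gene_id gene to summarize.
#' @param populations analyzed population ids (character vector or table).
#' @param annotation optional `genome_annotation`; when given, `gene_id` is
#'   validated against it (a gene absent from the calls then reports all
#'   zeros), otherwise the gene must appear in `calls`.
#' @return data.frame with `population_id`, `cumulative_frequency`,
#'   `exceeds_one`.
#' @export
cumulative_gene_frequency <- function(calls, gene_id, populations,
                                      annotation = NULL) {
  if (is.data.frame(populations)) populations <- populations$population_id
  known <- if (!is.null(annotation)) gene_id %in% annotation$gene_id
           else gene_id %in% calls$gene_id
  if (!known) stop_input("unknown gene: ", gene_id)
  g <- calls[calls$gene_id == gene_id, , drop = FALSE]
  s <- tapply(g$frequency, factor(g$population_id, levels = populations), sum)
  s[is.na(s)] <- 0
  data.frame(population_id = populations,
             cumulative_frequency = as.numeric(s),
             exceeds_one = as.numeric(s) > 1,
             stringsAsFactors = FALSE)
}

#' Probability of random parallelism across populations
#'
#' The chance that, by chance alone, one mutation per population lands in
#' the same gene in every one of `n_s` independently evolved populations of
#' species s with `G_s` genes: `p = prod_s (1 / G_s)^(n_s)`. Computed in
#' log10 space so study-scale values (e.g. 12 + 12 populations over
#' 4565/5068-gene genomes) do not underflow.
#'
#' @param gene_counts vector of genome sizes `G_s` (>= 1).
#' @param n_populations vector of population counts `n_s` (>= 0), same length.
#' @return list with `log10_p` and `p` (0 when not representable).
#' @export
random_parallelism_probability <- function(gene_counts, n_populations) {
  if (length(gene_counts) != length(n_populations))
    stop_input("gene_counts and n_populations must have equal length")
  if (any(gene_counts < 1)) stop_input("gene counts must be >= 1")
  if (any(n_populations < 0)) stop_input("population counts must be >= 0")
  log10_p <- -sum(n_populations * log10(gene_counts))
  list(log10_p = log10_p, p = 10^log10_p)
}

#' Flag mutator populations
#'
#' A mutator population carries far more mutations than its replicate
#' populations. Within each group (typically species x treatment) a
#' population is flagged when its mutation count exceeds the Tukey fence
#' `Q3 + k * IQR`; alternatively `method = "median"` flags counts above
#' `multiplier * median`. Groups smaller than `min_group` are untestable:
#' nothing is flagged and a warning is raised.
#'
#' @param counts named numeric vector of per-population mutation counts.
#' @param groups factor/character of the same length assigning populations
#'   to groups; a single group when omitted.
#' @param method `"tukey"` (default) or `"median"`.
#' @param k Tukey fence multiplier (default 1.5).
#' @param multiplier median-rule multiplier (default 5).
#' @param min_group minimum group size for the default method (default 4).
#' @return character vector of flagged population ids.
#' @export
flag_mutators <- function(counts, groups = NULL, method = c("tukey", "median"),
                          k = 1.5, multiplier = 5, min_group = 4L) {
  method <- match.arg(method)
  if (is.null(names(counts)))
    names(counts) <- paste0("pop", seq_along(counts))
  if (is.null(groups)) groups <- rep("all", length(counts))
  flagged <- character()
  for (g in unique(groups)) {
    x <- counts[groups == g]
    if (length(x) < min_group) {
      warning("group '", g, "' has fewer than ", min_group,
              " populations; mutator flagging skipped")
      next
    }
    thr <- if (method == "tukey") {
      q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
      q[2L] + k * (q[2L] - q[1L])
    } else {
      multiplier * stats::median(x)
    }
    flagged <- c(flagged, names(x)[x > thr])
  }
  flagged
}

#' Protein domain map
#'
#' Ordered, non-overlapping, 1-based closed residue intervals with names,
#' used to localize alleles within a protein (e.g. the receiver domain,
#' residues 1-123, versus the DNA-binding domain, 124-238, of an arcA-like
#' response regulator).
#'
#' @param names domain names.
#' @param start,end 1-based closed residue bounds.
#' @return data.frame of class `domain_map`.
#' @export
domain_map <- function(names, start, end) {
  stopifnot(length(names) == length(start), length(start) == length(end),
            all(start >= 1), all(end >= start))
  o <- order(start)
  names <- names[o]; start <- start[o]; end <- end[o]
  if (length(start) > 1 && any(start[-1] <= end[-length(end)]))
    stop_input("domain intervals must not overlap")
  structure(data.frame(domain = names, start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("domain_map", "data.frame"))
}

#' Default receiver/DNA-binding domain map for an arcA-like regulator
#' @return a [domain_map()] with receiver 1-123 and DNA-binding 124-238.
#' @export
arca_like_domains <- function() {
  domain_map(c("receiver", "DNA_binding"), c(1L, 124L), c(123L, 238L))
}

#' Unique-allele spectrum of a gene
#'
#' Deduplicates the gene's calls by (position, ref, alt) and reports, per
#' unique allele, its effect class and the number of populations carrying
#' it; optionally assigns each allele to a protein domain from its
#' gene-relative residue position. The effect-class composition
#' distinguishes substitution-dominated spectra from loss-of-function-rich
#' (stop/frameshift) spectra.
#'
#' @param calls variant-call data.frame.
#' @param gene_id gene to profile.
#' @param annotation optional `genome_annotation` used to derive residue
#'   positions (`ceiling(offset / 3)` on the coding strand).
#' @param domains optional [domain_map()]; alleles outside every interval
#'   are assigned `"outside"` with a warning.
#' @return data.frame, one row per unique allele, with attributes
#'   `effect_composition` (table) and `domain_totals` (table, when domains
#'   are given).
#' @export
unique_allele_spectrum <- function(calls, gene_id, annotation = NULL,
                                   domains = NULL) {
  g <- calls[calls$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0L) {
    out <- data.frame(position = integer(), ref = character(),
                      alt = character(), effect = character(),
                      n_populations = integer(), stringsAsFactors = FALSE)
    attr(out, "effect_composition") <- table(character())
    return(out)
  }
  keyed <- paste(g$position, g$ref, g$alt, sep = "|")
  npop <- tapply(g$population_id, keyed, function(x) length(unique(x)))
  first <- g[!duplicated(keyed), , drop = FALSE]
  first_key <- keyed[!duplicated(keyed)]
  out <- data.frame(position = first$position, ref = first$ref,
                    alt = first$alt, effect = first$effect,
                    n_populations = as.integer(npop[first_key]),
                    stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    gs <- annotation$start[annotation$gene_id == gene_id]
    if (length(gs) == 1L)
      out$residue <- as.integer(ceiling((out$position - gs + 1L) / 3))
  }
  if (!is.null(domains)) {
    if (is.null(out$residue))
      stop_input("domain assignment requires an annotation for residue positions")
    idx <- findInterval(out$residue, domains$start)
    dom <- rep("outside", nrow(out))
    ok <- idx >= 1 & out$residue <= domains$end[pmax(idx, 1L)]
    dom[ok] <- domains$domain[idx[ok]]
    if (any(!ok))
      warning(sum(!ok), " allele(s) outside the domain map assigned 'outside'")
    out$domain <- dom
    attr(out, "domain_totals") <- table(out$domain)
  }
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "effect_composition") <- table(out$effect)
  out
}
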