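#' Subsystem enrichment score
#'
#' For each functional subsystem s the score is the ratio of the
#' subsystem's mutated-gene fraction to the genome-wide mutated-gene
#' fraction: `score_s = (m_s / g_s) / (M / G)`, where `m_s` of the
#' subsystem's `g_s` genes are mutated and `M` of the genome's `G` genes
#' are mutated. A score of 1 means the subsystem collects mutated genes at
#' exactly the genome-wide rate; `score - 1` (also reported) is the usual
#' plotted quantity. A gene counts as mutated when it has at least one call
#' in at least one analyzed population. When subsystems partition the
#' genome, the gene-count-weighted mean score is exactly 1.
#'
#' @param matrix gene x population count matrix ([gene_mutation_matrix()]).
#' @param annotation `genome_annotation` carrying `gene_id` and `subsystem`
#'   (and `category`) for every gene in the genome.
#' @return data.frame with one row per subsystem (`g_s > 0`): `subsystem`,
#'   `category`, `m_s`, `g_s`, `M`, `G`, `score`, `score_minus_1`. Empty
#'   with a warning when no gene is mutated (M = 0).
#' @export
subsystem_score <- function(matrix, annotation) {
  mutated <- rownames(matrix)[rowSums(matrix) > 0]
  mutated <- intersect(mutated, annotation$gene_id)
  G <- nrow(annotation)
  M <- length(mutated)
  if (M == 0L) {
    warning("no mutated genes: subsystem scores are undefined")
    return(data.frame(subsystem = character(), category = character(),
                      m_s = integer(), g_s = integer(), M = integer(),
                      G = integer(), score = numeric(),
                      score_minus_1 = numeric(), stringsAsFactors = FALSE))
  }
  g_s <- table(annotation$subsystem)
  m_s <- table(factor(annotation$subsystem[annotation$gene_id %in% mutated],
                      levels = names(g_s)))
  cat_of <- annotation$category[!duplicated(annotation$subsystem)]
  names(cat_of) <- annotation$subsystem[!duplicated(annotation$subsystem)]
  out <- data.frame(
    subsystem = names(g_s),
    category = unname(cat_of[names(g_s)]),
    m_s = as.integer(m_s),
    g_s = as.integer(g_s),
    M = M, G = G,
    stringsAsFactors = FALSE
  )
  out$score <- (out$m_s / out$g_s) / (M / G)
  out$score_minus_1 <- out$score - 1
  out <- out[order(-out$score, out$subsystem), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parallelism at gene, subsystem or category level
#'
#' Aggregates calls to the chosen level of the functional hierarchy
#' (gene -> subsystem -> category) and recomputes the parallelism summary on
#' the aggregated units. A unit is present in a population when any of its
#' genes carries a call there, so presence counts are monotone under
#' aggregation: a subsystem's `n_populations` is at least the maximum over
#' its genes.
#'
#' @param calls variant-call data.frame.
#' @param annotation `genome_annotation` carrying the hierarchy.
#' @param populations analyzed population ids or table.
#' @param level `"gene"`, `"subsystem"` or `"category"`.
#' @return parallelism summary data.frame at the chosen level.
#' @export
hierarchical_parallelism <- function(calls, annotation, populations,
                                     level = c("gene", "subsystem", "category")) {
  level <- match.arg(level)
  if (level != "gene") {
    map <- stats::setNames(annotation[[level]], annotation$gene_id)
    calls <- calls[calls$gene_id %in% names(map), , drop = FALSE]
    calls$gene_id <- unname(map[calls$gene_id])
  }
  m <- gene_mutation_matrix(calls, populations)
  out <- parallelism_summary(m, calls = calls,
                             populations = if (is.data.frame(populations))
                               populations else NULL)
  names(out)[names(out) == "gene_id"] <- if (level == "gene") "gene_id" else level
  out
}
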