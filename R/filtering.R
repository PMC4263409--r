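#' Apply the allele-frequency detection floor
#'
#' Pooled-sequencing polymorphism calls below a minimum frequency are within
#' the error rate of the pipeline and are discarded. The floor is inclusive:
#' a call at exactly `min_freq` is kept.
#'
#' @param calls variant-call data.frame.
#' @param min_freq minimum frequency in (0, 1] (default 0.05).
#' @return the calls with `frequency >= min_freq`, order preserved.
#' @export
apply_frequency_floor <- function(calls, min_freq = 0.05) {
  if (!is.numeric(min_freq) || length(min_freq) != 1L ||
      min_freq <= 0 || min_freq > 1)
    stop_input("min_freq must lie in (0, 1]")
  calls[calls$frequency >= min_freq, , drop = FALSE]
}

#' Classify the coding effect of a variant
#'
#' Translates the affected codon under the bacterial genetic code
#' (translation table 11): same amino acid is `synonymous`, a new stop codon
#' is `stop_gained`, any other amino-acid change `nonsynonymous`. Indels are
#' `frameshift` when the length change is not a multiple of three and
#' `inframe_indel` otherwise. An offset outside the gene is `intergenic`.
#'
#' @param gene_sequence coding sequence of the gene (5'->3', length a
#'   multiple of 3) as a character string or [Biostrings::DNAString].
#' @param offset 1-based position of the variant within the gene.
#' @param ref,alt reference and alternate alleles. For indels the first base
#'   is the anchor base, so `nchar` difference is the inserted/deleted length.
#' @return one of `"synonymous"`, `"nonsynonymous"`, `"stop_gained"`,
#'   `"frameshift"`, `"inframe_indel"`, `"intergenic"`.
#' @export
classify_effect <- function(gene_sequence, offset, ref, alt) {
  seq <- as.character(gene_sequence)
  n <- nchar(seq)
  if (offset < 1 || offset > n) return("intergenic")
  if (nchar(ref) != nchar(alt)) {
    d <- abs(nchar(ref) - nchar(alt))
    return(if (d %% 3L == 0L) "inframe_indel" else "frameshift")
  }
  if (nchar(ref) != 1L)
    stop_input("only single-nucleotide substitutions are classified as SNPs")
  if (n %% 3L != 0L)
    stop_input("gene length must be a multiple of 3 for coding classification")
  if (substr(seq, offset, offset) != ref)
    stop_input("ref allele does not match the gene sequence at this offset")
  codon_i <- (offset - 1L) %/% 3L
  codon <- substr(seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  pos_in_codon <- (offset - 1L) %% 3L + 1L
  alt_codon <- codon
  substr(alt_codon, pos_in_codon, pos_in_codon) <- alt
  code <- Biostrings::getGeneticCode("11")
  aa_ref <- code[[codon]]
  aa_alt <- code[[alt_codon]]
  if (aa_alt == "*" && aa_ref != "*") return("stop_gained")
  if (aa_alt == aa_ref) return("synonymous")
  "nonsynonymous"
}

#' Keep non-synonymous variant classes
#'
#' Restricts analysis to the effect classes with protein-level consequences:
#' amino-acid substitutions, stop gains, frameshifts and in-frame indels.
#' Synonymous and intergenic calls are dropped.
#'
#' @param calls variant-call data.frame with effects assigned.
#' @return subset of `calls`, order preserved.
#' @export
select_nonsynonymous <- function(calls) {
  calls[calls$effect %in% NONSYN_EFFECTS, , drop = FALSE]
}

#' Build the mutation-accumulation control blacklist
#'
#' MA lines pass through single-cell bottlenecks, so the same site recurring
#' in several independent lines cannot plausibly be a real recurrent
#' mutation; it marks a systematic pipeline artifact. Sites present in at
#' least `min_lines` distinct MA lines are blacklisted. Counting is over
#' lines, not calls, and sites are keyed by (contig, position) — the removal
#' is site-level, not allele-level.
#'
#' @param ma_calls variant calls from the MA lines.
#' @param min_lines minimum number of distinct lines (default 4).
#' @return data.frame with `contig`, `position`, `n_ma_lines`.
#' @export
build_ma_blacklist <- function(ma_calls, min_lines = 4L) {
  if (min_lines < 1) stop_input("min_lines must be >= 1")
  if (is.null(ma_calls) || nrow(ma_calls) == 0L)
    return(data.frame(contig = character(), position = integer(),
                      n_ma_lines = integer(), stringsAsFactors = FALSE))
  u <- unique(ma_calls[, c("contig", "position", "population_id")])
  counts <- stats::aggregate(population_id ~ contig + position, data = u,
                             FUN = function(x) length(unique(x)))
  names(counts)[3L] <- "n_ma_lines"
  out <- counts[counts$n_ma_lines >= min_lines, , drop = FALSE]
  out <- out[order(out$contig, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove blacklisted sites from a call set
#'
#' Drops every call whose (contig, position) is on the blacklist and reports
#' per-treatment removal counts for the provenance log.
#'
#' @param calls variant-call data.frame.
#' @param blacklist data.frame with `contig` and `position`
#'   (e.g. from [build_ma_blacklist()]).
#' @param populations optional population table with `population_id` and
#'   `treatment`, used for the per-treatment accounting.
#' @return the kept calls, with attributes `n_removed` and (when
#'   `populations` is given) `removed_by_treatment`.
#' @export
apply_blacklist <- function(calls, blacklist, populations = NULL) {
  if (is.null(blacklist) || nrow(blacklist) == 0L) {
    attr(calls, "n_removed") <- 0L
    return(calls)
  }
  bad <- site_key(calls$contig, calls$position) %in%
    site_key(blacklist$contig, blacklist$position)
  kept <- calls[!bad, , drop = FALSE]
  attr(kept, "n_removed") <- sum(bad)
  if (!is.null(populations) && sum(bad) > 0) {
    tr <- stats::setNames(populations$treatment, populations$population_id)
    attr(kept, "removed_by_treatment") <-
      table(tr[calls$population_id[bad]])
  }
  kept
}
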