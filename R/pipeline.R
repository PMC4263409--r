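#' Write a variant-call table
#'
#' Canonical tab-delimited interchange: one call per line with columns
#' `population_id, contig, position, ref, alt, vtype, gene_id, effect,
#' frequency`. Plain text, no quoting, so the body round-trips
#' byte-identically.
#'
#' @param calls variant-call data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variants <- function(calls, path) {
  validate_calls(calls)
  out <- calls[, VARIANT_COLUMNS, drop = FALSE]
  out$frequency <- formatC(out$frequency, format = "fg", digits = 15)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read variant calls from TSV or VCF
#'
#' TSV: the dialect written by [write_variants()]. Records with a frequency
#' outside (0, 1] are rejected with a message giving their line numbers;
#' unknown effect labels are an error. VCF: requires an `AF` INFO tag
#' (allele frequency) and optionally `GENE`, `EFFECT` and `VTYPE` tags;
#' positions follow the VCF convention and are kept in the internal 1-based
#' model; the population id is taken from `population_id` (the file holds
#' one population). No frequency floor is applied at read time — detection
#' filtering is an explicit pipeline stage.
#'
#' @param path `.tsv`/`.txt` or `.vcf` file.
#' @param population_id population label, required for VCF input.
#' @return variant-call data.frame.
#' @export
read_variants <- function(path, population_id = NULL) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE))
    return(read_variants_vcf(path, population_id))
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(position = "integer",
                                          frequency = "numeric"))
  missing <- setdiff(VARIANT_COLUMNS, names(raw))
  if (length(missing))
    stop_input("variant TSV missing columns: ", paste(missing, collapse = ", "))
  bad_f <- !is.finite(raw$frequency) | raw$frequency <= 0 | raw$frequency > 1
  if (any(bad_f)) {
    message("rejected ", sum(bad_f), " record(s) with frequency outside (0,1] ",
            "at line(s): ", paste(which(bad_f) + 1L, collapse = ", "))
    raw <- raw[!bad_f, , drop = FALSE]
  }
  bad_e <- setdiff(unique(raw$effect), EFFECT_LEVELS)
  if (length(bad_e))
    stop_input("unknown effect label(s): ", paste(bad_e, collapse = ", "))
  rownames(raw) <- NULL
  validate_calls(raw[, VARIANT_COLUMNS, drop = FALSE])
}

read_variants_vcf <- function(path, population_id) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_input("reading VCF requires the vcfR package")
  if (is.null(population_id))
    stop_input("population_id is required for VCF input")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  gene <- vcfR::extract.info(v, "GENE")
  effect <- vcfR::extract.info(v, "EFFECT")
  gene[is.na(gene)] <- "intergenic"
  effect[is.na(effect)] <- "intergenic"
  rl <- nchar(fix$REF); al <- nchar(fix$ALT)
  vtype <- ifelse(rl == al, "snp", ifelse(al > rl, "insertion", "deletion"))
  calls <- data.frame(population_id = population_id,
                      contig = fix$CHROM,
                      position = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, vtype = vtype,
                      gene_id = gene, effect = effect,
                      frequency = af, stringsAsFactors = FALSE)
  bad_f <- !is.finite(calls$frequency) | calls$frequency <= 0 |
    calls$frequency > 1
  if (any(bad_f)) {
    message("rejected ", sum(bad_f), " VCF record(s) with AF outside (0,1]")
    calls <- calls[!bad_f, , drop = FALSE]
  }
  rownames(calls) <- NULL
  validate_calls(calls)
}

#' Write the truth-label table of a simulated experiment
#' @param dataset an `experiment_dataset`.
#' @param path output TSV (contig, position, alt, role).
#' @return `path`, invisibly.
#' @export
write_truth <- function(dataset, path) {
  utils::write.table(dataset$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Pipeline configuration
#'
#' All stage parameters of [run_pipeline()], serialized verbatim into the
#' provenance log. Defaults follow the standard cascade: inclusive 0.05
#' frequency floor, MA blacklist at 4 lines, Levene filter at alpha 0.05
#' with mean centering and absent populations contributing frequency zero,
#' Tukey-fence mutator flagging. `exclude_populations` lists populations
#' whose calls are carried but omitted from all statistics. `product_blacklist`
#' drops genes whose ids appear in it (gene-category removals), empty by
#' default.
#'
#' @param min_freq frequency floor.
#' @param ma_min_lines MA blacklist threshold.
#' @param levene_alpha,levene_center,levene_min_per_group,levene_include_absent
#'   Levene-filter settings.
#' @param apply_levene,apply_blacklist per-stage switches (both default TRUE;
#'   each filter can be disabled per species via these switches when running
#'   species separately).
#' @param mutator_method,mutator_k mutator rule (Tukey fence by default).
#' @param exclude_populations population ids excluded from analysis.
#' @param product_blacklist gene ids removed outright.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_freq = 0.05,
                            ma_min_lines = 4L,
                            levene_alpha = 0.05,
                            levene_center = "mean",
                            levene_min_per_group = 2L,
                            levene_include_absent = TRUE,
                            apply_levene = TRUE,
                            apply_blacklist = TRUE,
                            mutator_method = "tukey",
                            mutator_k = 1.5,
                            exclude_populations = character(),
                            product_blacklist = character()) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the variant-identification and parallelism pipeline
#'
#' Executes the filtering cascade in its canonical order — frequency floor,
#' non-synonymous selection, MA-control blacklist, Levene's-test artifact
#' filter (per species, since frequency groups only make sense within one
#' genome) — then computes per-population mutation counts, mutator flags,
#' gene/subsystem/category parallelism, and a per-treatment summary of
#' mutation counts (mean with normal-approximation 95% CI). Every stage
#' appends a record (stage, parameters, input/removed/output counts) to the
#' provenance log so the accounting can be audited.
#'
#' @param dataset an `experiment_dataset` (simulated or assembled from
#'   files): `annotations`, `populations`, `variants`.
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report`: `filtered_calls`, `blacklist`,
#'   `levene` (per-species audit), `mutators`, `counts` (per population),
#'   `treatment_summary`, `parallelism` (per species x treatment summaries),
#'   `subsystem_scores` (per species), `provenance`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config()) {
  pops <- dataset$populations
  pops$excluded <- pops$excluded | pops$population_id %in% config$exclude_populations
  analyzed <- pops[!pops$excluded & !pops$is_ma, , drop = FALSE]
  ma_pops <- pops[pops$is_ma, , drop = FALSE]

  prov <- list()
  log_stage <- function(stage, n_in, n_removed, params = "") {
    prov[[length(prov) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_removed = n_removed,
      n_out = n_in - n_removed, params = params, stringsAsFactors = FALSE)
  }

  calls <- dataset$variants[dataset$variants$population_id %in%
                              analyzed$population_id, , drop = FALSE]
  ma_calls <- dataset$variants[dataset$variants$population_id %in%
                                 ma_pops$population_id, , drop = FALSE]
  log_stage("analyzed_populations", nrow(dataset$variants),
            nrow(dataset$variants) - nrow(calls),
            paste0("excluded=", paste(config$exclude_populations, collapse = ",")))

  # per-population raw counts (coding mutations), Fig-3-style, pre-filter
  n0 <- nrow(calls)
  calls <- apply_frequency_floor(calls, config$min_freq)
  ma_calls <- apply_frequency_floor(ma_calls, config$min_freq)
  log_stage("frequency_floor", n0, n0 - nrow(calls),
            paste0("min_freq=", config$min_freq))

  counts_total <- table(factor(calls$population_id,
                               levels = analyzed$population_id))

  n0 <- nrow(calls)
  calls <- select_nonsynonymous(calls)
  log_stage("select_nonsynonymous", n0, n0 - nrow(calls))

  if (length(config$product_blacklist)) {
    n0 <- nrow(calls)
    calls <- calls[!calls$gene_id %in% config$product_blacklist, , drop = FALSE]
    log_stage("product_blacklist", n0, n0 - nrow(calls),
              paste(config$product_blacklist, collapse = ","))
  }

  blacklist <- NULL
  if (config$apply_blacklist && nrow(ma_calls)) {
    blacklist <- build_ma_blacklist(ma_calls, config$ma_min_lines)
    n0 <- nrow(calls)
    calls <- apply_blacklist(calls, blacklist, populations = pops)
    log_stage("ma_blacklist", n0, attr(calls, "n_removed") %||% 0L,
              paste0("min_lines=", config$ma_min_lines,
                     " sites=", nrow(blacklist)))
  }

  levene_audit <- list()
  if (config$apply_levene) {
    for (sp in unique(analyzed$species)) {
      sp_pops <- analyzed[analyzed$species == sp, , drop = FALSE]
      if (length(unique(sp_pops$treatment)) < 2L) next
      sp_idx <- calls$population_id %in% sp_pops$population_id
      lf <- levene_artifact_filter(calls[sp_idx, , drop = FALSE], sp_pops,
                                   alpha = config$levene_alpha,
                                   min_per_group = config$levene_min_per_group,
                                   center = config$levene_center,
                                   include_absent = config$levene_include_absent)
      levene_audit[[sp]] <- lf
      n0 <- nrow(calls)
      calls <- rbind(calls[!sp_idx, , drop = FALSE], lf$kept)
      log_stage(paste0("levene_filter:", sp), n0, n0 - nrow(calls),
                paste0("alpha=", config$levene_alpha,
                       " center=", config$levene_center))
    }
    calls <- calls[order(calls$population_id, calls$contig, calls$position), ,
                   drop = FALSE]
    rownames(calls) <- NULL
  }

  counts_nonsyn <- table(factor(calls$population_id,
                                levels = analyzed$population_id))
  grp <- paste(analyzed$species, analyzed$treatment, sep = ":")
  mutators <- flag_mutators(
    stats::setNames(as.integer(counts_total), analyzed$population_id),
    groups = grp, method = config$mutator_method, k = config$mutator_k)

  counts <- data.frame(population_id = analyzed$population_id,
                       species = analyzed$species,
                       treatment = analyzed$treatment,
                       n_mutations = as.integer(counts_total),
                       n_nonsynonymous = as.integer(counts_nonsyn),
                       is_mutator = analyzed$population_id %in% mutators,
                       stringsAsFactors = FALSE)

  ci95 <- function(x) 1.96 * stats::sd(x) / sqrt(length(x))
  agg <- function(d) data.frame(
    mean_total = mean(d$n_mutations), ci_total = ci95(d$n_mutations),
    mean_nonsyn = mean(d$n_nonsynonymous), ci_nonsyn = ci95(d$n_nonsynonymous),
    mean_total_nonmut = mean(d$n_mutations[!d$is_mutator]),
    mean_nonsyn_nonmut = mean(d$n_nonsynonymous[!d$is_mutator]))
  treatment_summary <- do.call(rbind, lapply(
    split(counts, list(counts$species, counts$treatment), drop = TRUE),
    function(d) cbind(species = d$species[1L], treatment = d$treatment[1L],
                      n_populations = nrow(d), agg(d))))
  rownames(treatment_summary) <- NULL

  parallelism <- list()
  subsystem_scores <- list()
  for (sp in unique(analyzed$species)) {
    ann <- dataset$annotations[[sp]]
    for (tr in unique(analyzed$treatment[analyzed$species == sp])) {
      ids <- analyzed$population_id[analyzed$species == sp &
                                      analyzed$treatment == tr]
      cc <- calls[calls$population_id %in% ids, , drop = FALSE]
      m <- gene_mutation_matrix(cc, ids)
      parallelism[[paste(sp, tr, sep = ":")]] <-
        parallelism_summary(m, calls = cc)
      if (!is.null(ann))
        subsystem_scores[[paste(sp, tr, sep = ":")]] <-
          if (nrow(m)) subsystem_score(m, ann) else NULL
    }
  }

  structure(list(filtered_calls = calls,
                 blacklist = blacklist,
                 levene = levene_audit,
                 mutators = mutators,
                 counts = counts,
                 treatment_summary = treatment_summary,
                 parallelism = parallelism,
                 subsystem_scores = subsystem_scores,
                 provenance = do.call(rbind, prov),
                 config = config),
            class = "pipeline_report")
}
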