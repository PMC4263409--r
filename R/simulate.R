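#' Driver-gene specification for the experiment simulator
#'
#' Describes one "global regulator"-style driver gene: how often it is hit
#' per population in each medium, how many distinct co-segregating alleles it
#' carries when hit, the Beta distribution of its cumulative allele frequency,
#' and the per-medium probability that an allele is loss-of-function
#' (stop-gain or frameshift) rather than an amino-acid substitution.
#'
#' Defaults mimic the two repeated targets of selection in enterobacterial
#' rich-media evolution experiments: an arcA-like regulator hit in essentially
#' every population with substitution-only alleles, and an rpoS-like sigma
#' factor with a strongly loss-of-function-biased spectrum in one medium.
#'
#' @param gene_index index of the driver gene within each species' annotation.
#' @param hit_probability named numeric, per-treatment probability a
#'   population acquires mutations in the gene.
#' @param allele_count_kappa alleles per hit population are `1 + Poisson(kappa)`.
#' @param cumfreq_shape1,cumfreq_shape2 Beta parameters of the cumulative
#'   frequency of all alleles in a population (defaults Beta(9, 3), mean 0.75).
#' @param lof_bias named numeric, per-treatment probability that an allele is
#'   loss-of-function (stop_gained/frameshift).
#' @param name label used in truth records.
#' @return object of class `driver_spec`.
#' @export
driver_spec <- function(gene_index,
                        hit_probability = c(LB = 1.0, BHI = 0.75),
                        allele_count_kappa = 2,
                        cumfreq_shape1 = 9, cumfreq_shape2 = 3,
                        lof_bias = c(LB = 0, BHI = 0),
                        name = paste0("driver_g", gene_index)) {
  stopifnot(gene_index >= 1, allele_count_kappa >= 0,
            all(hit_probability >= 0 & hit_probability <= 1),
            all(lof_bias >= 0 & lof_bias <= 1),
            cumfreq_shape1 > 0, cumfreq_shape2 > 0)
  mean_cf <- cumfreq_shape1 / (cumfreq_shape1 + cumfreq_shape2)
  if (mean_cf <= 0 || mean_cf >= 1) stop_input("Beta mean must lie in (0,1)")
  structure(list(gene_index = as.integer(gene_index),
                 hit_probability = hit_probability,
                 allele_count_kappa = allele_count_kappa,
                 cumfreq_shape1 = cumfreq_shape1,
                 cumfreq_shape2 = cumfreq_shape2,
                 lof_bias = lof_bias,
                 name = name),
            class = "driver_spec")
}

#' Default driver set: arcA-like and rpoS-like regulators
#' @return list of two [driver_spec()] objects.
#' @export
default_drivers <- function() {
  list(
    driver_spec(10L, hit_probability = c(LB = 1.0, BHI = 0.75),
                allele_count_kappa = 2, lof_bias = c(LB = 0, BHI = 0),
                name = "arcA_like"),
    driver_spec(25L, hit_probability = c(LB = 0.4, BHI = 0.4),
                allele_count_kappa = 1, lof_bias = c(LB = 0, BHI = 0.8),
                name = "rpoS_like")
  )
}

#' Simulation configuration
#'
#' Collects the experiment-design parameters of the synthetic
#' evolve-and-resequence generator: two species-like genomes, replicate
#' populations evolved in two media, mutation-accumulation (MA) control
#' lines, mutator populations, driver genes, systematic artifact sites and
#' pooled-sequencing detection parameters.
#'
#' @param seed master seed; all stages draw from named substreams of it.
#' @param n_genes_per_species integer pair (desk scale defaults 500, 550;
#'   study scale 4565/5068).
#' @param n_populations_per_treatment replicate populations per
#'   species x medium (default 12).
#' @param treatments media labels (default `c("LB","BHI")`).
#' @param n_ma_lines MA control lines, species 1 only (default 12).
#' @param neutral_rate expected non-synonymous neutral ("hitchhiker")
#'   mutations per evolved population (default 15).
#' @param syn_ratio simulated synonymous:non-synonymous ratio (default 1/3).
#' @param mutator_populations data.frame(treatment, replicate) of populations
#'   with an elevated mutation rate; default two per medium in species 1
#'   (LB 4 & 11, BHI 6 & 10).
#' @param mutator_multiplier fold increase of the neutral rate in mutator
#'   populations (default 8).
#' @param driver_genes list of [driver_spec()]; default [default_drivers()].
#' @param artifact_sites number of systematic artifact sites per species
#'   (default 30).
#' @param artifact_base_frequency artifact frequency f0 (default 0.12).
#' @param artifact_noise_sd sd of artifact frequency across lines
#'   (default 0.005).
#' @param ma_rate expected mutations per MA line (default 8).
#' @param detection_floor minimum detectable allele frequency (default 0.05).
#' @param coverage_depth pooled-sequencing depth for binomial frequency
#'   noise (default 200).
#' @param gene_length_meanlog,gene_length_sdlog passed to [simulate_genome()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes_per_species = c(500L, 550L),
                       n_populations_per_treatment = 12L,
                       treatments = c("LB", "BHI"),
                       n_ma_lines = 12L,
                       neutral_rate = 15,
                       syn_ratio = 1 / 3,
                       mutator_populations = data.frame(
                         treatment = c("LB", "LB", "BHI", "BHI"),
                         replicate = c(4L, 11L, 6L, 10L)),
                       mutator_multiplier = 8,
                       driver_genes = default_drivers(),
                       artifact_sites = 30L,
                       artifact_base_frequency = 0.12,
                       artifact_noise_sd = 0.005,
                       ma_rate = 8,
                       detection_floor = 0.05,
                       coverage_depth = 200L,
                       gene_length_meanlog = log(300),
                       gene_length_sdlog = 0.35) {
  if (length(treatments) < 1) stop_input("treatments must be non-empty")
  if (neutral_rate < 0 || ma_rate < 0 || mutator_multiplier < 0 ||
      artifact_sites < 0 || syn_ratio < 0)
    stop_input("all rates must be >= 0")
  if (artifact_base_frequency - 5 * artifact_noise_sd <= 0 ||
      artifact_base_frequency + 5 * artifact_noise_sd >= 1)
    stop_input("artifact_base_frequency +/- 5 sd must lie inside (0,1)")
  if (detection_floor <= 0 || detection_floor > 1)
    stop_input("detection_floor must lie in (0,1]")
  for (d in driver_genes) {
    if (!inherits(d, "driver_spec")) stop_input("driver_genes must be driver_spec objects")
    if (any(d$gene_index > n_genes_per_species))
      stop_input("driver gene_index exceeds genome size")
    if (!all(treatments %in% names(d$hit_probability)))
      stop_input("driver hit_probability must cover every treatment")
  }
  structure(list(seed = as.integer(seed),
                 n_genes_per_species = as.integer(n_genes_per_species),
                 n_populations_per_treatment = as.integer(n_populations_per_treatment),
                 treatments = treatments,
                 n_ma_lines = as.integer(n_ma_lines),
                 neutral_rate = neutral_rate,
                 syn_ratio = syn_ratio,
                 mutator_populations = mutator_populations,
                 mutator_multiplier = mutator_multiplier,
                 driver_genes = driver_genes,
                 artifact_sites = as.integer(artifact_sites),
                 artifact_base_frequency = artifact_base_frequency,
                 artifact_noise_sd = artifact_noise_sd,
                 ma_rate = ma_rate,
                 detection_floor = detection_floor,
                 coverage_depth = as.integer(coverage_depth),
                 gene_length_meanlog = gene_length_meanlog,
                 gene_length_sdlog = gene_length_sdlog),
            class = "sim_config")
}

# Deterministic bases so that the same site always yields the same ref/alt
# pair; recurrent draws of one site across populations therefore represent
# the same allele, as for real recurrent mutations.
BASES <- c("A", "C", "G", "T")
ref_base_at <- function(position) BASES[(position %% 4L) + 1L]
alt_base_at <- function(position) BASES[((position + 1L) %% 4L) + 1L]

# Uniform coding positions (length-weighted over genes).
draw_coding_positions <- function(annotation, n) {
  if (n == 0L) return(integer())
  total <- sum(annotation$length_nt)
  offs <- sort(sample.int(total, n, replace = TRUE))
  cum <- cumsum(annotation$length_nt)
  gene <- findInterval(offs - 1L, c(0L, cum), rightmost.closed = FALSE)
  within <- offs - c(0L, cum)[gene] - 1L
  as.integer(annotation$start[gene] + within)
}

# Binomial pooled-sequencing resampling at depth, then detection floor.
resample_frequency <- function(f, depth) {
  stats::rbinom(length(f), depth, f) / depth
}

#' Simulate a complete evolve-and-resequence experiment
#'
#' Generates, for each species and medium, replicate evolved populations with
#' (a) Poisson-count neutral variants at uniform coding positions with
#' Beta(1,9) frequencies resampled binomially at the coverage depth and
#' truncated at the detection floor, (b) driver-gene alleles whose
#' frequencies are a Dirichlet partition of a Beta-distributed cumulative
#' frequency, (c) systematic artifact sites present in every evolved
#' population and every MA line at near-identical frequencies (no binomial
#' resampling: they model pipeline errors, not sampling noise), and (d) MA
#' control lines with private near-fixed variants. Every emitted variant
#' carries a truth label (`driver`, `neutral`, `artifact`, `ma_private`).
#'
#' @param config a [sim_config()].
#' @param genomes optional list of two `genome_annotation`s; simulated from
#'   the config when omitted.
#' @return list of class `experiment_dataset` with elements `annotations`
#'   (per species), `populations` (population table with species, treatment,
#'   replicate, `is_ma`, `excluded`), `variants`, and `truth`
#'   (contig, position, alt, role).
#' @export
simulate_experiment <- function(config = sim_config(), genomes = NULL) {
  if (!inherits(config, "sim_config")) stop_input("config must be a sim_config")
  n_species <- length(config$n_genes_per_species)
  species <- paste0("sp", seq_len(n_species))
  if (is.null(genomes)) {
    genomes <- lapply(seq_len(n_species), function(i)
      simulate_genome(config$n_genes_per_species[i],
                      config$gene_length_meanlog, config$gene_length_sdlog,
                      seed = config$seed,
                      contig = paste0(species[i], "_chr"),
                      species = species[i]))
  }
  names(genomes) <- species

  pops <- do.call(rbind, lapply(species, function(sp)
    do.call(rbind, lapply(config$treatments, function(tr)
      data.frame(population_id = sprintf("%s_%s%d", sp, tr,
                                         seq_len(config$n_populations_per_treatment)),
                 species = sp, treatment = tr,
                 replicate = seq_len(config$n_populations_per_treatment),
                 is_ma = FALSE, excluded = FALSE,
                 stringsAsFactors = FALSE)))))
  if (config$n_ma_lines > 0) {
    pops <- rbind(pops, data.frame(
      population_id = sprintf("MA%d", seq_len(config$n_ma_lines)),
      species = species[1L], treatment = "MA",
      replicate = seq_len(config$n_ma_lines),
      is_ma = TRUE, excluded = FALSE, stringsAsFactors = FALSE))
  }

  variants <- list()
  truth <- list()
  push <- function(v, role) {
    if (nrow(v)) {
      variants[[length(variants) + 1L]] <<- v
      truth[[length(truth) + 1L]] <<- data.frame(
        contig = v$contig, position = v$position, alt = v$alt, role = role,
        stringsAsFactors = FALSE)
    }
  }

  is_mutator <- function(tr, rep) {
    mp <- config$mutator_populations
    !is.null(mp) && nrow(mp) > 0 && any(mp$treatment == tr & mp$replicate == rep)
  }

  for (si in seq_len(n_species)) {
    sp <- species[si]; ann <- genomes[[sp]]
    evolved <- pops[pops$species == sp & !pops$is_ma, ]

    # -- neutral & synonymous hitchhikers ------------------------------------
    with_seed(substream_seed(config$seed, paste0("neutral:", sp)), {
      for (i in seq_len(nrow(evolved))) {
        p <- evolved[i, ]
        m <- if (si == 1L && is_mutator(p$treatment, p$replicate))
          config$mutator_multiplier else 1
        n_ns <- stats::rpois(1L, config$neutral_rate * m)
        n_syn <- stats::rpois(1L, config$neutral_rate * config$syn_ratio * m)
        pos <- draw_coding_positions(ann, n_ns + n_syn)
        if (length(pos)) {
          f0 <- stats::rbeta(length(pos), 1, 9)
          f <- resample_frequency(f0, config$coverage_depth)
          keep <- f >= config$detection_floor
          pos <- pos[keep]; f <- f[keep]
          eff <- rep(c("nonsynonymous", "synonymous"),
                     c(n_ns, n_syn))[keep]
          if (length(pos))
            push(make_variants(p$population_id, ann, pos, eff, f), "neutral")
        }
      }
    })

    # -- driver genes ---------------------------------------------------------
    with_seed(substream_seed(config$seed, paste0("drivers:", sp)), {
      for (d in config$driver_genes) {
        g <- ann[d$gene_index, ]
        for (i in seq_len(nrow(evolved))) {
          p <- evolved[i, ]
          if (stats::runif(1) > d$hit_probability[[p$treatment]]) next
          k <- 1L + stats::rpois(1L, d$allele_count_kappa)
          cf <- stats::rbeta(1L, d$cumfreq_shape1, d$cumfreq_shape2)
          f0 <- rdirichlet1(k) * cf
          f <- resample_frequency(f0, config$coverage_depth)
          keep <- f >= config$detection_floor
          if (!any(keep)) next
          pos <- g$start + sample.int(g$length_nt, k, replace = FALSE) - 1L
          lof <- stats::runif(k) < d$lof_bias[[p$treatment]]
          eff <- ifelse(lof,
                        ifelse(pos %% 3L == 0L, "stop_gained", "frameshift"),
                        "nonsynonymous")
          push(make_variants(p$population_id, ann, pos[keep], eff[keep], f[keep]),
               "driver")
        }
      }
    })

    # -- systematic artifact sites -------------------------------------------
    if (config$artifact_sites > 0) {
      with_seed(substream_seed(config$seed, paste0("artifacts:", sp)), {
        apos <- draw_coding_positions(ann, config$artifact_sites)
        while (anyDuplicated(apos))
          apos[duplicated(apos)] <- draw_coding_positions(ann, sum(duplicated(apos)))
        lines_here <- pops[pops$species == sp &
                             (!pops$is_ma | si == 1L), ]
        for (j in seq_along(apos)) {
          f <- config$artifact_base_frequency +
            stats::rnorm(nrow(lines_here), 0, config$artifact_noise_sd)
          f <- pmin(pmax(f, 1e-6), 1 - 1e-6)
          push(make_variants(lines_here$population_id, ann,
                             rep(apos[j], nrow(lines_here)),
                             rep("nonsynonymous", nrow(lines_here)), f),
               "artifact")
        }
      })
    }

    # -- MA private variants (species 1 only) ---------------------------------
    if (si == 1L && config$n_ma_lines > 0) {
      with_seed(substream_seed(config$seed, "ma_private"), {
        for (line in pops$population_id[pops$is_ma]) {
          n <- stats::rpois(1L, config$ma_rate)
          if (n == 0L) next
          pos <- draw_coding_positions(ann, n)
          f <- stats::runif(n, 0.8, 1.0)
          eff <- ifelse(stats::runif(n) < 3 / 4, "nonsynonymous", "synonymous")
          push(make_variants(line, ann, pos, eff, f), "ma_private")
        }
      })
    }
  }

  variants <- if (length(variants)) do.call(rbind, variants) else empty_variant_table()
  rownames(variants) <- NULL
  truth <- if (length(truth)) unique(do.call(rbind, truth)) else
    data.frame(contig = character(), position = integer(), alt = character(),
               role = character(), stringsAsFactors = FALSE)
  # a site drawn under two roles (e.g. a neutral hit landing on an artifact
  # site) keeps one label, by mechanism precedence
  prio <- match(truth$role, c("driver", "artifact", "ma_private", "neutral"))
  truth <- truth[order(prio), , drop = FALSE]
  truth <- truth[!duplicated(truth[, c("contig", "position", "alt")]), ,
                 drop = FALSE]
  truth <- truth[order(truth$contig, truth$position, truth$alt), , drop = FALSE]
  rownames(truth) <- NULL
  validate_calls(variants)
  structure(list(annotations = genomes, populations = pops,
                 variants = variants, truth = truth, config = config),
            class = "experiment_dataset")
}

# Vectorized variant construction (same semantics as make_variant).
make_variants <- function(population_id, annotation, positions, effects, freqs) {
  n <- length(positions)
  if (n == 0L) return(empty_variant_table())
  if (length(population_id) == 1L) population_id <- rep(population_id, n)
  ref <- vapply(positions, ref_base_at, "")
  alt <- vapply(positions, alt_base_at, "")
  vtype <- rep("snp", n)
  fs <- effects == "frameshift"
  del <- fs & positions %% 2L == 0L
  ins <- fs & !del
  infr <- effects == "inframe_indel"
  for (i in which(del)) {
    ref[i] <- paste0(vapply(positions[i] + 0:4, ref_base_at, ""), collapse = "")
    alt[i] <- substr(ref[i], 1L, 1L)
  }
  for (i in which(infr)) {
    ref[i] <- paste0(vapply(positions[i] + 0:3, ref_base_at, ""), collapse = "")
    alt[i] <- substr(ref[i], 1L, 1L)
  }
  alt[ins] <- paste0(ref[ins], "A")
  vtype[del | infr] <- "deletion"
  vtype[ins] <- "insertion"
  data.frame(population_id = population_id,
             contig = annotation$contig[1L],
             position = as.integer(positions),
             ref = ref, alt = alt, vtype = vtype,
             gene_id = genes_at_positions(annotation, positions),
             effect = effects,
             frequency = freqs,
             stringsAsFactors = FALSE)
}

#' Generations per transfer from the dilution factor
#'
#' In serial batch transfer the population regrows by the dilution factor
#' each day, so generations per transfer is `log2(dilution_factor)`; a
#' 100-fold daily dilution gives ~6.6 generations/day and a 40,000-fold
#' dilution ~15.3.
#'
#' @param dilution_factor fold dilution per transfer (> 1).
#' @param n_transfers number of transfers (>= 0).
#' @return list with `per_transfer` and `total` generations.
#' @export
generations_from_dilution <- function(dilution_factor, n_transfers) {
  if (!is.numeric(dilution_factor) || dilution_factor <= 1)
    stop_input("dilution_factor must be > 1")
  if (n_transfers < 0) stop_input("n_transfers must be >= 0")
  per <- log2(dilution_factor)
  list(per_transfer = per, total = per * n_transfers)
}
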