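#' Default subsystem catalogue
#'
#' A small hierarchical functional catalogue (subsystem -> category) in the
#' style of SEED subsystem assignments, used by [simulate_genome()] when no
#' catalogue is supplied. Twenty subsystems spread over five broad categories.
#'
#' @return data.frame with columns `subsystem` and `category`.
#' @export
default_subsystem_catalogue <- function() {
  data.frame(
    subsystem = c(
      "TCA cycle", "Glycolysis", "Pentose phosphate", "Fermentation",
      "Amino acid biosynthesis", "Amino acid degradation", "Peptidases",
      "ABC transporters", "Porins", "Efflux pumps",
      "Two-component systems", "Sigma factors", "Transcription factors",
      "DNA repair", "Replication", "Recombination",
      "Chaperones", "Heat shock", "Oxidative stress", "Acid stress"
    ),
    category = rep(c(
      "Carbohydrate metabolism", "Amino acid metabolism",
      "Membrane transport", "Regulation and signaling",
      "Stress response and repair"
    ), times = c(4, 3, 3, 3, 7)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a bacterial genome annotation
#'
#' Builds a single-contig gene catalogue: genes tile the contig left to right
#' with at least one intergenic nucleotide between consecutive genes,
#' coordinates are 1-based and closed, lengths are a whole number of codons
#' drawn from a log-normal distribution, and every gene is assigned to exactly
#' one subsystem (subsystems partition the gene set).
#'
#' @param n_genes number of genes (>= 1).
#' @param length_meanlog,length_sdlog log-normal parameters for gene length in
#'   codons (defaults: `log(300)` and `0.35`, a typical enterobacterial
#'   coding-length distribution).
#' @param subsystem_catalogue data.frame with columns `subsystem`, `category`;
#'   defaults to [default_subsystem_catalogue()].
#' @param seed integer seed; the same seed always yields the same annotation.
#' @param contig contig name.
#' @param species species label stored on the annotation.
#' @return data.frame of class `genome_annotation` with columns `gene_id`,
#'   `contig`, `start`, `end`, `strand`, `length_nt`, `subsystem`, `category`.
#' @export
simulate_genome <- function(n_genes,
                            length_meanlog = log(300),
                            length_sdlog = 0.35,
                            subsystem_catalogue = default_subsystem_catalogue(),
                            seed = 1L,
                            contig = "contig_1",
                            species = "sp1") {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    stop_input("n_genes must be a positive integer")
  n_genes <- as.integer(n_genes)
  stopifnot(all(c("subsystem", "category") %in% names(subsystem_catalogue)),
            nrow(subsystem_catalogue) >= 1)
  with_seed(substream_seed(seed, paste0("genome:", species)), {
    codons <- pmax(30L, as.integer(round(stats::rlnorm(n_genes, length_meanlog,
                                                       length_sdlog))))
    len_nt <- codons * 3L
    gaps <- 1L + stats::rpois(n_genes, 80)
    start <- integer(n_genes)
    pos <- 1L
    for (i in seq_len(n_genes)) {
      pos <- pos + gaps[i]
      start[i] <- pos
      pos <- pos + len_nt[i]
    }
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    sub_idx <- sample.int(nrow(subsystem_catalogue), n_genes, replace = TRUE)
    ann <- data.frame(
      gene_id = sprintf("%s_g%04d", species, seq_len(n_genes)),
      contig = contig,
      start = start,
      end = start + len_nt - 1L,
      strand = strand,
      length_nt = len_nt,
      subsystem = subsystem_catalogue$subsystem[sub_idx],
      category = subsystem_catalogue$category[sub_idx],
      stringsAsFactors = FALSE
    )
    class(ann) <- c("genome_annotation", "data.frame")
    attr(ann, "species") <- species
    ann
  })
}

# Map positions to gene ids for one annotation; returns "intergenic" outside
# genes. Positions and annotation must share the contig.
genes_at_positions <- function(annotation, positions) {
  idx <- findInterval(positions, annotation$start)
  gene <- rep("intergenic", length(positions))
  hit <- idx >= 1
  inside <- hit & positions <= annotation$end[pmax(idx, 1L)]
  gene[inside] <- annotation$gene_id[idx[inside]]
  gene
}

#' Write a genome annotation to GFF3
#'
#' Gene features carry `ID`, `subsystem` and `category` attributes so the
#' functional hierarchy round-trips through the file.
#'
#' @param annotation a `genome_annotation`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$contig,
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end),
    strand = annotation$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- annotation$gene_id
  S4Vectors::mcols(gr)$subsystem <- annotation$subsystem
  S4Vectors::mcols(gr)$category <- annotation$category
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a genome annotation
#'
#' Accepts either a GFF3 file (gene features with `ID`, `subsystem`,
#' `category` attributes) or a tab-delimited table with the annotation
#' columns. Coordinates are 1-based and closed throughout. Genes without a
#' subsystem are pooled into an explicit `"unassigned"` pseudo-subsystem with
#' a warning, so that subsystems always partition the gene set.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or TSV file.
#' @param species species label to attach.
#' @return a `genome_annotation` data.frame.
#' @export
read_annotation <- function(path, species = "sp1") {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    m <- S4Vectors::mcols(gr)
    ann <- data.frame(
      gene_id = as.character(m$ID),
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
    ann$length_nt <- ann$end - ann$start + 1L
    ann$subsystem <- if ("subsystem" %in% names(m)) as.character(m$subsystem) else NA_character_
    ann$category <- if ("category" %in% names(m)) as.character(m$category) else NA_character_
  } else {
    ann <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "contig", "start", "end")
    missing <- setdiff(need, names(ann))
    if (length(missing))
      stop_input("annotation TSV missing columns: ", paste(missing, collapse = ", "))
    if (is.null(ann$strand)) ann$strand <- "+"
    ann$length_nt <- ann$end - ann$start + 1L
    if (is.null(ann$subsystem)) ann$subsystem <- NA_character_
    if (is.null(ann$category)) ann$category <- NA_character_
  }
  if (anyDuplicated(ann$gene_id))
    stop_input("duplicate gene ids in annotation")
  na_sub <- is.na(ann$subsystem) | ann$subsystem == ""
  if (any(na_sub)) {
    warning(sum(na_sub), " gene(s) without subsystem assigned to 'unassigned'")
    ann$subsystem[na_sub] <- "unassigned"
    ann$category[na_sub] <- "unassigned"
  }
  ann <- ann[order(ann$contig, ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("genome_annotation", "data.frame")
  attr(ann, "species") <- species
  ann
}
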