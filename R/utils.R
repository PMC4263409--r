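#' @keywords internal
"_PACKAGE"

# Deterministic substream seeds: every stochastic stage draws from its own
# substream derived from (master seed, stage name) so single stages can be
# re-run reproducibly. Kept below 2^31-1 (R integers are 32-bit).
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (abs(seed) %% 2147483647) * 2654435 %% 2147483647) %% 2147483647)
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

# Dirichlet(1, ..., 1) draw via normalized exponentials.
rdirichlet1 <- function(k) {
  g <- stats::rexp(k)
  g / sum(g)
}

empty_variant_table <- function() {
  data.frame(
    population_id = character(), contig = character(),
    position = integer(), ref = character(), alt = character(),
    vtype = character(), gene_id = character(), effect = character(),
    frequency = numeric(), stringsAsFactors = FALSE
  )
}

VARIANT_COLUMNS <- c("population_id", "contig", "position", "ref", "alt",
                     "vtype", "gene_id", "effect", "frequency")

EFFECT_LEVELS <- c("synonymous", "nonsynonymous", "stop_gained", "frameshift",
                   "inframe_indel", "intergenic")

NONSYN_EFFECTS <- c("nonsynonymous", "stop_gained", "frameshift", "inframe_indel")

#' Validate a variant-call table
#'
#' Checks the structural invariants of the internal variant-call model:
#' required columns, frequencies in (0, 1], positions >= 1, known effect
#' labels, and ref/alt lengths consistent with the variant type.
#'
#' @param calls data.frame of variant calls.
#' @return `calls`, invisibly, if valid; otherwise an error.
#' @export
validate_calls <- function(calls) {
  missing <- setdiff(VARIANT_COLUMNS, names(calls))
  if (length(missing))
    stop_input("variant table missing columns: ", paste(missing, collapse = ", "))
  if (nrow(calls) == 0) return(invisible(calls))
  if (any(!is.finite(calls$frequency)) ||
      any(calls$frequency <= 0) || any(calls$frequency > 1))
    stop_input("variant frequencies must lie in (0, 1]")
  if (any(calls$position < 1))
    stop_input("variant positions must be >= 1")
  bad <- setdiff(unique(calls$effect), EFFECT_LEVELS)
  if (length(bad))
    stop_input("unknown effect label(s): ", paste(bad, collapse = ", "))
  rl <- nchar(calls$ref); al <- nchar(calls$alt)
  ok <- ifelse(calls$vtype == "snp", rl == al,
        ifelse(calls$vtype == "insertion", al > rl,
        ifelse(calls$vtype == "deletion", al < rl, NA)))
  if (any(is.na(ok)))
    stop_input("unknown vtype label(s): ",
               paste(setdiff(unique(calls$vtype), c("snp", "insertion", "deletion")),
                     collapse = ", "))
  if (!all(ok))
    stop_input("ref/alt allele lengths inconsistent with vtype")
  invisible(calls)
}

site_key <- function(contig, position) paste(contig, position, sep = ":")
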