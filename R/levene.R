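#' Levene's test for equality of spread
#'
#' Computes Levene's W on a list of groups: with `Z_ij = |x_ij - c_i|`
#' (`c_i` the group mean, or median for the Brown-Forsythe variant),
#' `W = ((N - k) / (k - 1)) * sum_i n_i (Zbar_i - Zbar)^2 /
#' sum_ij (Z_ij - Zbar_i)^2`, referred to the upper tail of F(k-1, N-k).
#'
#' Degenerate inputs are handled explicitly: if both the between- and
#' within-group sums of squares are zero (all deviations identical) the
#' spreads are indistinguishable and `W = 0, p = 1`; if any group has fewer
#' than two observations the test is not computable and `testable = FALSE`.
#'
#' @param groups list of >= 2 numeric vectors.
#' @param center `"mean"` (Levene's original test, default) or `"median"`
#'   (Brown-Forsythe).
#' @return list with `W`, `df1`, `df2`, `p_value`, `testable`.
#' @export
levene_statistic <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  if (!is.list(groups) || length(groups) < 2L)
    stop_input("levene_statistic requires >= 2 groups")
  k <- length(groups)
  n <- lengths(groups)
  if (any(n < 2L))
    return(list(W = NA_real_, df1 = k - 1L, df2 = sum(n) - k,
                p_value = NA_real_, testable = FALSE))
  cfun <- if (center == "mean") mean else stats::median
  Z <- lapply(groups, function(x) abs(x - cfun(x)))
  zbar_i <- vapply(Z, mean, numeric(1))
  zbar <- sum(unlist(Z)) / sum(n)
  N <- sum(n)
  between <- sum(n * (zbar_i - zbar)^2)
  within <- sum(vapply(seq_len(k), function(i) sum((Z[[i]] - zbar_i[i])^2),
                       numeric(1)))
  df1 <- k - 1L
  df2 <- N - k
  if (within == 0 && between == 0) {
    W <- 0; p <- 1
  } else if (within == 0) {
    W <- Inf; p <- 0
  } else {
    W <- (df2 / df1) * between / within
    p <- stats::pf(W, df1, df2, lower.tail = FALSE)
  }
  list(W = W, df1 = df1, df2 = df2, p_value = p, testable = TRUE)
}

#' Levene's-test filter for systematic artifact sites
#'
#' Systematic false positives (reference errors, misresolved duplications,
#' methylation-sensitive sites) recur at near-identical frequencies across
#' independently evolved populations, whereas genuine mutations arise at
#' different times and drift to different frequencies. For every site that
#' is observed in at least `min_per_group` populations of *each* treatment,
#' the per-treatment frequency vectors are compared with Levene's test and
#' the site is REMOVED when the spreads do not differ (`p >= alpha`).
#' Populations lacking a call at the site contribute frequency 0 ("absent"),
#' which makes treatment-restricted variants high-variance and artifacts
#' low-variance; set `include_absent = FALSE` to drop absent populations
#' instead. Sites observed too sparsely to test are retained (conservative
#' with respect to discovery).
#'
#' @param calls variant-call data.frame (evolved, analyzed populations only).
#' @param populations population table with `population_id` and `treatment`;
#'   used both for grouping and to supply the zero frequencies of absent
#'   populations.
#' @param alpha removal threshold on the Levene p-value (default 0.05).
#' @param min_per_group minimum populations per treatment in which the site
#'   must be observed for the test to run (default 2).
#' @param center passed to [levene_statistic()].
#' @param include_absent contribute 0 for populations without the call.
#' @return list with `kept` (calls), `removed_sites` (data.frame contig,
#'   position, W, p_value) and `results` (full audit table, one row per
#'   tested or untestable site).
#' @export
levene_artifact_filter <- function(calls, populations, alpha = 0.05,
                                   min_per_group = 2L,
                                   center = c("mean", "median"),
                                   include_absent = TRUE) {
  center <- match.arg(center)
  treatments <- unique(populations$treatment)
  if (length(treatments) < 2L)
    stop_input("levene_artifact_filter requires >= 2 treatments")
  if (nrow(calls) == 0L)
    return(list(kept = calls,
                removed_sites = data.frame(contig = character(),
                                           position = integer(),
                                           W = numeric(), p_value = numeric()),
                results = data.frame()))
  pop_tr <- stats::setNames(populations$treatment, populations$population_id)
  if (any(!calls$population_id %in% names(pop_tr)))
    stop_input("calls reference populations absent from the population table")

  key <- site_key(calls$contig, calls$position)
  # per site x population frequency (sum over co-located alleles)
  freq <- tapply(calls$frequency,
                 list(key = key, pop = calls$population_id), sum)
  sites <- rownames(freq)
  n_per_tr <- table(populations$treatment)

  res <- lapply(sites, function(s) {
    f <- freq[s, ]
    obs_pops <- names(f)[!is.na(f)]
    obs_by_tr <- table(factor(pop_tr[obs_pops], levels = treatments))
    if (any(obs_by_tr < min_per_group))
      return(data.frame(site = s, W = NA_real_, df1 = NA_integer_,
                        df2 = NA_integer_, p_value = NA_real_,
                        testable = FALSE, removed = FALSE))
    groups <- lapply(treatments, function(tr) {
      pops_tr <- populations$population_id[populations$treatment == tr]
      x <- f[pops_tr]
      if (include_absent) { x[is.na(x)] <- 0; unname(x) } else unname(x[!is.na(x)])
    })
    lt <- levene_statistic(groups, center = center)
    data.frame(site = s, W = lt$W, df1 = lt$df1, df2 = lt$df2,
               p_value = lt$p_value, testable = lt$testable,
               removed = isTRUE(lt$testable) && !is.na(lt$p_value) &&
                 lt$p_value >= alpha)
  })
  res <- do.call(rbind, res)
  parts <- strsplit(res$site, ":", fixed = TRUE)
  res$contig <- vapply(parts, `[`, "", 1L)
  res$position <- as.integer(vapply(parts, `[`, "", 2L))
  removed <- res[res$removed, c("contig", "position", "W", "p_value")]
  rownames(removed) <- NULL
  keep <- !(key %in% res$site[res$removed])
  list(kept = calls[keep, , drop = FALSE], removed_sites = removed,
       results = res[, c("contig", "position", "W", "df1", "df2",
                         "p_value", "testable", "removed")])
}
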