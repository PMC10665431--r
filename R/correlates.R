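#' Genome size-corrected COG category prevalence
#'
#' Normalises per-genome COG category counts into prevalences so that
#' genomes of different sizes are comparable. The default corrects by gene
#' count (category count / total annotated genes); `mode = "per_mb"`
#' instead reports genes per megabase of genome.
#'
#' @param cog_counts data.frame with `genome_id` plus one integer column per
#'   COG category letter, or a numeric matrix with genome rownames.
#' @param mode `"gene_count"` (proportions summing to 1 per genome) or
#'   `"per_mb"` (density per Mb; requires `genome_size`).
#' @param genome_size named numeric vector of genome sizes in bp (only for
#'   `mode = "per_mb"`).
#' @return data.frame `genome_id`, `category`, `prevalence` (long format).
#' @export
cog_prevalence <- function(cog_counts, mode = c("gene_count", "per_mb"),
                           genome_size = NULL) {
  mode <- match.arg(mode)
  m <- as_cog_matrix(cog_counts)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop_aux("genome(s) with zero annotated genes: ",
             paste(rownames(m)[totals == 0], collapse = ", "),
             class = "aux_invalid_cog")
  }
  if (mode == "gene_count") {
    prev <- m / totals
  } else {
    if (is.null(genome_size)) {
      stop_aux("mode 'per_mb' requires genome_size",
               class = "aux_invalid_cog")
    }
    gs <- genome_size[rownames(m)]
    if (anyNA(gs) || any(gs <= 0)) {
      stop_aux("genome_size must cover all genomes with positive values",
               class = "aux_invalid_cog")
    }
    prev <- m / (gs / 1e6)
  }
  data.frame(
    genome_id = rep(rownames(m), times = ncol(m)),
    category = rep(colnames(m), each = nrow(m)),
    prevalence = as.numeric(prev),
    stringsAsFactors = FALSE
  )
}

as_cog_matrix <- function(cog_counts) {
  if (is.data.frame(cog_counts)) {
    require_columns(cog_counts, "genome_id", "COG count table")
    m <- as.matrix(cog_counts[, setdiff(names(cog_counts), "genome_id"),
                              drop = FALSE])
    rownames(m) <- cog_counts$genome_id
  } else {
    m <- as.matrix(cog_counts)
  }
  if (!is.numeric(m) || any(m < 0)) {
    stop_aux("COG counts must be non-negative numbers",
             class = "aux_invalid_cog")
  }
  m
}

#' COG category enrichment between auxotrophs and prototrophs
#'
#' Per COG category, compares prevalence between the strict auxotroph class
#' (genomes unable to synthesize two or more compounds) and prototrophs
#' (zero auxotrophies) with a two-sided Mann-Whitney U test, Bonferroni
#' correction over the number of categories tested, and the log2-fold ratio
#' of group mean prevalences. Categories with zero mean prevalence in
#' either group get an undefined ratio flag.
#'
#' @param prev_auxotrophs,prev_prototrophs prevalence tables from
#'   [cog_prevalence()] (long format) for the two genome groups, each
#'   covering at least 2 genomes.
#' @param alpha significance level on the adjusted p value (default 0.01).
#' @return data.frame with one row per category: `category`,
#'   `mean_auxotroph`, `mean_prototroph`, `log2_ratio`, `p_raw`,
#'   `p_adjusted`, `direction` (auxotroph-enriched / prototroph-enriched /
#'   ns), `ratio_defined`.
#' @export
cog_enrichment <- function(prev_auxotrophs, prev_prototrophs, alpha = 0.01) {
  for (tab in list(prev_auxotrophs, prev_prototrophs)) {
    require_columns(tab, c("genome_id", "category", "prevalence"),
                    "prevalence table")
  }
  n_aux <- length(unique(prev_auxotrophs$genome_id))
  n_proto <- length(unique(prev_prototrophs$genome_id))
  if (n_aux < 2L || n_proto < 2L) {
    stop_aux("each group needs at least 2 genomes (got ", n_aux, " and ",
             n_proto, ")", class = "aux_invalid_input")
  }
  categories <- sort(union(prev_auxotrophs$category,
                           prev_prototrophs$category))
  rows <- lapply(categories, function(cat) {
    a <- prev_auxotrophs$prevalence[prev_auxotrophs$category == cat]
    p <- prev_prototrophs$prevalence[prev_prototrophs$category == cat]
    wt <- suppressWarnings(wilcox.test(a, p, alternative = "two.sided"))
    ma <- mean(a)
    mp <- mean(p)
    defined <- ma > 0 && mp > 0
    data.frame(category = cat, mean_auxotroph = ma, mean_prototroph = mp,
               log2_ratio = if (defined) log2(ma / mp) else NA_real_,
               p_raw = wt$p.value, ratio_defined = defined,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_raw * length(categories))
  sig <- out$p_adjusted < alpha
  out$direction <- ifelse(!sig, "ns",
                          ifelse(out$mean_auxotroph > out$mean_prototroph,
                                 "auxotroph-enriched", "prototroph-enriched"))
  out[, c("category", "mean_auxotroph", "mean_prototroph", "log2_ratio",
          "p_raw", "p_adjusted", "direction", "ratio_defined")]
}

#' Pearson correlation with two-sided test
#'
#' Used throughout the correlate analyses: genome size vs number of
#' auxotrophies, completeness vs auxotrophies, biosynthetic P-bond cost vs
#' per-compound auxotroph proportion. Vectors with zero variance yield an
#' undefined-correlation flag instead of a value.
#'
#' @param x,y numeric vectors of equal length >= 3; pairs with missing
#'   values are dropped.
#' @return list with `r`, `p`, `n` and `defined` (FALSE when either vector
#'   is constant).
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) != length(y) || length(x) < 3L) {
    stop_aux("need at least 3 complete pairs", class = "aux_invalid_input")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                defined = FALSE))
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       defined = TRUE)
}

#' Two-group comparison (Mann-Whitney or Welch t)
#'
#' Mann-Whitney U for rank-based contrasts (e.g. auxotrophy counts by
#' genome origin) and Welch's two-sample two-sided t-test for numeric
#' contrasts (e.g. genome size of assembled vs isolate genomes). Any
#' multiplicity correction is the caller's responsibility.
#'
#' @param x,y numeric vectors, each with at least 2 finite observations.
#' @param test `"mann_whitney"` or `"welch_t"`.
#' @return list with `statistic`, `p`, `test`.
#' @export
group_compare <- function(x, y, test = c("mann_whitney", "welch_t")) {
  test <- match.arg(test)
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop_aux("each group needs at least 2 finite observations",
             class = "aux_invalid_input")
  }
  if (test == "mann_whitney") {
    ht <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  } else {
    ht <- t.test(x, y, alternative = "two.sided", var.equal = FALSE)
  }
  list(statistic = unname(ht$statistic), p = ht$p.value, test = test)
}

#' Normality screen used before rank-based testing
#'
#' Shapiro-Wilk test on (a subsample of) the values; purely advisory — it
#' logs a message when the data look normal (in which case a t-test would
#' also have been defensible) and gates nothing.
#'
#' @param x numeric vector.
#' @param alpha level for the advisory message.
#' @return the `shapiro.test()` result, invisibly.
#' @export
normality_screen <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) > 5000L) x <- x[seq_len(5000L)]
  st <- shapiro.test(x)
  if (st$p.value >= alpha) {
    message("normality not rejected (Shapiro-Wilk p = ",
            signif(st$p.value, 3), "); rank-based tests remain valid")
  }
  invisible(st)
}
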