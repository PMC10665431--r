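#' Build a habitat ASV table
#'
#' @param habitat habitat name.
#' @param counts non-negative integer matrix, samples as rows (rownames =
#'   sample IDs), ASVs as columns (colnames = ASV ids).
#' @param asv_seqs named character vector (or `DNAStringSet`) of ASV
#'   sequences; every ASV in `counts` must have a sequence.
#' @return list of class `asv_table`.
#' @export
asv_table <- function(habitat, counts, asv_seqs) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) {
    stop_aux("ASV table has zero samples", class = "aux_invalid_asv_table")
  }
  if (!is_count(counts)) {
    stop_aux("counts must be non-negative integers",
             class = "aux_invalid_asv_table")
  }
  if (is.null(colnames(counts)) || is.null(rownames(counts))) {
    stop_aux("counts must have sample rownames and ASV colnames",
             class = "aux_invalid_asv_table")
  }
  asv_seqs <- setNames(as.character(asv_seqs), names(asv_seqs))
  missing <- setdiff(colnames(counts), names(asv_seqs))
  if (length(missing) > 0L) {
    stop_aux("ASV(s) in counts lack sequences: ",
             paste(missing, collapse = ", "),
             class = "aux_invalid_asv_table")
  }
  structure(list(habitat = habitat, counts = counts,
                 asv_seqs = asv_seqs[colnames(counts)]),
            class = "asv_table")
}

#' Percent identity implied by a mismatch allowance
#'
#' The matching criterion "at most `mismatches` substitutions over an
#' alignment of `length` bases" corresponds to a percent-identity cutoff of
#' `100 * (length - mismatches) / length`; one mismatch over a 250 bp
#' amplicon is 99.6% identity.
#'
#' @param length alignment length in bases.
#' @param mismatches allowed substitutions.
#' @return percent identity on the 0-100 scale.
#' @examples
#' mismatch_identity_pct(250, 1)  # 99.6
#' @export
mismatch_identity_pct <- function(length = 250, mismatches = 1) {
  if (any(length < 1) || any(mismatches < 0) || any(mismatches > length)) {
    stop_aux("need 0 <= mismatches <= length, length >= 1",
             class = "aux_invalid_input")
  }
  100 * (length - mismatches) / length
}

#' Match ASVs to reference 16S rRNA gene sequences
#'
#' Each ASV is slid gap-free along every reference; a reference qualifies
#' when it contains a window of ASV length within `max_mismatch`
#' substitutions (Hamming distance; indels are not considered at amplicon
#' scale). The best match minimises the distance; ties between genomes are
#' broken deterministically towards the lexicographically smallest
#' `genome_id` and flagged ambiguous. IUPAC ambiguity codes in references
#' match an ASV base whenever the code covers it.
#'
#' @param asv_seqs named character vector of ASV sequences (A/C/G/T, length
#'   >= 50).
#' @param references named character vector or `DNAStringSet` of reference
#'   16S sequences, names = genome ids.
#' @param max_mismatch maximum substitutions allowed (default 1, i.e. 99.6%
#'   identity for 250 bp fragments).
#' @return data.frame `asv_id`, `genome_id`, `mismatches`, `ambiguous`; ASVs
#'   with no qualifying reference are absent (their ids are kept in the
#'   `unmatched` attribute).
#' @export
match_asvs <- function(asv_seqs, references, max_mismatch = 1) {
  if (length(references) == 0L) {
    stop_aux("reference set is empty", class = "aux_invalid_input")
  }
  asv_seqs <- setNames(as.character(asv_seqs), names(asv_seqs))
  if (is.null(names(asv_seqs)) || any(names(asv_seqs) == "")) {
    stop_aux("ASV sequences must be named", class = "aux_invalid_input")
  }
  if (any(nchar(asv_seqs) < 50L)) {
    stop_aux("ASV sequences must be at least 50 nt",
             class = "aux_invalid_input")
  }
  if (any(grepl("[^ACGT]", asv_seqs))) {
    stop_aux("ASV sequences must contain only A/C/G/T",
             class = "aux_invalid_sequence")
  }
  refs <- Biostrings::DNAStringSet(references)  # errors on non-IUPAC
  if (is.null(names(refs))) {
    stop_aux("references must be named by genome_id",
             class = "aux_invalid_input")
  }
  refs <- refs[order(names(refs))]
  rows <- vector("list", length(asv_seqs))
  unmatched <- character(0)
  for (i in seq_along(asv_seqs)) {
    pat <- Biostrings::DNAString(asv_seqs[[i]])
    hit <- NULL
    for (mm in 0:max_mismatch) {
      n <- Biostrings::vcountPattern(pat, refs, max.mismatch = mm,
                                     with.indels = FALSE,
                                     fixed = c(pattern = TRUE,
                                               subject = FALSE))
      idx <- which(n > 0L)
      if (length(idx) > 0L) {
        hit <- data.frame(asv_id = names(asv_seqs)[i],
                          genome_id = names(refs)[idx[1L]],
                          mismatches = mm,
                          ambiguous = length(idx) > 1L,
                          stringsAsFactors = FALSE)
        break
      }
    }
    if (is.null(hit)) {
      unmatched <- c(unmatched, names(asv_seqs)[i])
    } else {
      rows[[i]] <- hit
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(asv_id = character(), genome_id = character(),
                      mismatches = integer(), ambiguous = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "unmatched") <- unmatched
  out
}

#' Filter ASVs on read depth and occupancy
#'
#' Retains ASVs with strictly more than `min_reads` total reads in the
#' habitat that occur (count > 0) in at least `min_occupancy` of the
#' samples.
#'
#' @param tab an [asv_table()].
#' @param min_reads exclusive total-read cutoff (default 10).
#' @param min_occupancy inclusive occupancy proportion (default 0.10).
#' @return list with `kept` (retained ASV ids), `table` (the `asv_table`
#'   restricted to them) and `stats` (per-ASV totals, occupancy, decision
#'   and rejection reason).
#' @export
filter_asvs <- function(tab, min_reads = 10, min_occupancy = 0.10) {
  stopifnot(inherits(tab, "asv_table"))
  totals <- colSums(tab$counts)
  occupancy <- colMeans(tab$counts > 0)
  keep <- totals > min_reads & occupancy >= min_occupancy
  reason <- rep(NA_character_, length(keep))
  reason[totals <= min_reads] <- "low_reads"
  reason[is.na(reason) & occupancy < min_occupancy] <- "low_occupancy"
  stats <- data.frame(asv_id = colnames(tab$counts),
                      total_reads = as.integer(totals),
                      occupancy = as.numeric(occupancy),
                      kept = keep,
                      reason = reason,
                      stringsAsFactors = FALSE)
  rownames(stats) <- NULL
  kept_tab <- tab
  kept_tab$counts <- tab$counts[, keep, drop = FALSE]
  kept_tab$asv_seqs <- tab$asv_seqs[colnames(kept_tab$counts)]
  list(kept = colnames(tab$counts)[keep], table = kept_tab, stats = stats)
}

#' Summarize auxotrophy prevalence for one habitat
#'
#' Taxon-level trait metrics (percent prototrophs, mean auxotrophy count,
#' share of single-compound auxotrophs) are computed over the deduplicated
#' set of matched genomes, so a taxon whose reads split across several ASVs
#' matching the same genome is counted once. Abundance metrics are computed
#' over the read counts of matched ASVs; `weighted_auxotroph_abundance`
#' additionally weights the auxotrophy trait by assigned reads.
#'
#' @param tab filtered [asv_table()].
#' @param matches match table from [match_asvs()].
#' @param profiles `aux_profiles` (or its `genomes` summary) covering every
#'   matched genome.
#' @return one-row data.frame with columns `habitat`, `n_samples`,
#'   `n_asvs`, `n_genomes`, `pct_asvs_with_genomes`, `abundance_covered`,
#'   `pct_prototrophs`, `mean_n_auxotrophies`, `pct_single_auxotrophy`,
#'   `weighted_auxotroph_abundance` (percentages on the 0-100 scale; trait
#'   columns `NA` when no ASV matched).
#' @export
summarize_habitat <- function(tab, matches, profiles) {
  stopifnot(inherits(tab, "asv_table"))
  if (inherits(profiles, "aux_profiles")) profiles <- profiles$genomes
  require_columns(profiles, c("genome_id", "n_auxotrophies"),
                  "genome summary")
  require_columns(matches, c("asv_id", "genome_id"), "match table")
  asvs <- colnames(tab$counts)
  matches <- matches[matches$asv_id %in% asvs, , drop = FALSE]
  total_reads <- sum(tab$counts)
  base <- data.frame(habitat = tab$habitat,
                     n_samples = nrow(tab$counts),
                     n_asvs = length(asvs),
                     stringsAsFactors = FALSE)
  if (nrow(matches) == 0L) {
    return(cbind(base, data.frame(
      n_genomes = 0L, pct_asvs_with_genomes = 0,
      abundance_covered = 0, pct_prototrophs = NA_real_,
      mean_n_auxotrophies = NA_real_, pct_single_auxotrophy = NA_real_,
      weighted_auxotroph_abundance = NA_real_)))
  }
  genomes <- unique(matches$genome_id)
  missing <- setdiff(genomes, profiles$genome_id)
  if (length(missing) > 0L) {
    stop_aux("matched genome(s) lack auxotrophy profiles: ",
             paste(missing, collapse = ", "), class = "aux_missing_pairs")
  }
  n_aux <- profiles$n_auxotrophies[match(genomes, profiles$genome_id)]
  matched_reads <- colSums(tab$counts[, matches$asv_id, drop = FALSE])
  asv_aux <- profiles$n_auxotrophies[match(matches$genome_id,
                                           profiles$genome_id)] >= 1
  aux_taxa <- n_aux >= 1
  cbind(base, data.frame(
    n_genomes = length(genomes),
    pct_asvs_with_genomes = 100 * nrow(matches) / length(asvs),
    abundance_covered = if (total_reads > 0) {
      100 * sum(matched_reads) / total_reads
    } else 0,
    pct_prototrophs = 100 * mean(n_aux == 0),
    mean_n_auxotrophies = mean(n_aux),
    pct_single_auxotrophy = if (any(aux_taxa)) {
      100 * mean(n_aux[aux_taxa] == 1)
    } else NA_real_,
    weighted_auxotroph_abundance = if (sum(matched_reads) > 0) {
      100 * sum(matched_reads[asv_aux]) / sum(matched_reads)
    } else NA_real_))
}

#' Pairwise habitat comparison of auxotrophy counts
#'
#' Two-sided Mann-Whitney U tests between every pair of habitats, with
#' Bonferroni correction over the number of pairs tested and a compact
#' letter display at `alpha`: habitats sharing a letter are not
#' significantly different.
#'
#' @param values numeric vector of per-taxon auxotrophy counts.
#' @param habitat grouping vector, same length as `values`.
#' @param alpha significance level for the letter display (default 0.05).
#' @return object of class `habitat_comparison`: list with `table`
#'   (`group1`, `group2`, `U`, `p_raw`, `p_adjusted`), `letters` (named
#'   character, one entry per habitat) and `n_pairs`.
#' @export
compare_habitats <- function(values, habitat, alpha = 0.05) {
  habitat <- as.character(habitat)
  stopifnot(length(values) == length(habitat))
  sizes <- table(habitat)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0L) {
    warning("excluding group(s) with fewer than 2 observations: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !(habitat %in% small)
    values <- values[keep]
    habitat <- habitat[keep]
  }
  groups <- sort(unique(habitat))
  if (length(groups) < 2L) {
    stop_aux("need at least two groups with >= 2 observations",
             class = "aux_invalid_input")
  }
  pairs <- combn(groups, 2)
  n_pairs <- ncol(pairs)
  rows <- apply(pairs, 2, function(pr) {
    x <- values[habitat == pr[1]]
    y <- values[habitat == pr[2]]
    wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
    data.frame(group1 = pr[1], group2 = pr[2],
               U = unname(wt$statistic), p_raw = wt$p.value,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- pmin(1, tab$p_raw * n_pairs)
  letters_out <- compact_letter_display(groups, tab, values, habitat, alpha)
  structure(list(table = tab, letters = letters_out, n_pairs = n_pairs),
            class = "habitat_comparison")
}

#' @export
print.habitat_comparison <- function(x, ...) {
  cat("Pairwise Mann-Whitney comparisons (Bonferroni x", x$n_pairs, ")\n")
  print(x$table, row.names = FALSE)
  cat("Letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = ", "), "\n")
  invisible(x)
}

# letters from maximal cliques of the non-significant-pair graph, ordered
# by group median so letter 'a' goes with the smallest values
compact_letter_display <- function(groups, tab, values, habitat, alpha) {
  k <- length(groups)
  ns <- diag(TRUE, k)
  dimnames(ns) <- list(groups, groups)
  for (i in seq_len(nrow(tab))) {
    sig <- tab$p_adjusted[i] < alpha
    ns[tab$group1[i], tab$group2[i]] <- !sig
    ns[tab$group2[i], tab$group1[i]] <- !sig
  }
  med <- vapply(groups, function(g) median(values[habitat == g]), numeric(1))
  ord <- order(med)
  cliques <- max_cliques(ns)
  # order cliques by their smallest-median member
  first <- vapply(cliques, function(cl) min(match(groups[cl], groups[ord])),
                  numeric(1))
  cliques <- cliques[order(first)]
  out <- setNames(rep("", k), groups)
  for (j in seq_along(cliques)) {
    out[cliques[[j]]] <- paste0(out[cliques[[j]]], letters[j])
  }
  out
}

# Bron-Kerbosch maximal cliques on a small logical adjacency matrix;
# group counts here are at most a few dozen habitats
max_cliques <- function(adj) {
  n <- nrow(adj)
  res <- list()
  bk <- function(r, p, x) {
    if (length(p) == 0L && length(x) == 0L) {
      res[[length(res) + 1L]] <<- r
      return(invisible())
    }
    for (v in p) {
      nb <- which(adj[v, ] & seq_len(n) != v)
      bk(c(r, v), intersect(p, nb), intersect(x, nb))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  res
}
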