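#' False-positive rate of auxotrophy calls against known prototrophies
#'
#' A false positive is a genome-compound pair experimentally known to be
#' synthesizable (`can_synthesize = TRUE`) but predicted auxotrophic. The
#' overall rate pools all labeled pairs; a per-compound breakdown and a
#' per-genome mean are also returned.
#'
#' @param profiles `aux_profiles` object (or its `calls` data.frame).
#' @param labels data.frame `genome_id`, `compound`, `can_synthesize`
#'   (logical); only `can_synthesize = TRUE` rows are used.
#' @return list with `overall` (proportion), `per_compound` (named numeric,
#'   compounds with at least one labeled pair), `per_genome_mean`
#'   (unweighted mean of per-genome FP proportions) and `n_pairs`.
#' @export
false_positive_rate <- function(profiles, labels) {
  joined <- join_labels(profiles, labels, can_synthesize = TRUE)
  if (nrow(joined) == 0L) {
    stop_aux("no labeled synthesizable pairs", class = "aux_no_labels")
  }
  fp <- joined$auxotrophic
  per_compound <- tapply(fp, joined$compound, mean)
  per_genome <- tapply(fp, joined$genome_id, mean)
  list(overall = mean(fp),
       per_compound = setNames(as.numeric(per_compound),
                               names(per_compound)),
       per_genome_mean = mean(per_genome),
       n_pairs = nrow(joined))
}

#' False-negative rate of auxotrophy calls against known auxotrophies
#'
#' A false negative is a labeled non-synthesizable pair predicted
#' prototrophic. For each genome the proportion of its known auxotrophies
#' that were missed is computed; the overall rate is the unweighted mean of
#' these per-genome proportions across genomes carrying at least one such
#' label.
#'
#' @inheritParams false_positive_rate
#' @return list with `overall`, `per_genome` (named numeric) and `n_pairs`.
#' @export
false_negative_rate <- function(profiles, labels) {
  joined <- join_labels(profiles, labels, can_synthesize = FALSE)
  if (nrow(joined) == 0L) {
    stop_aux("no labeled auxotrophic pairs", class = "aux_no_labels")
  }
  fn <- !joined$auxotrophic
  per_genome <- tapply(fn, joined$genome_id, mean)
  list(overall = mean(per_genome),
       per_genome = setNames(as.numeric(per_genome), names(per_genome)),
       n_pairs = nrow(joined))
}

#' Genome-level accuracy of prototroph / auxotroph classification
#'
#' Genome-level truth is derived from the labels: a genome is truly
#' prototrophic when it has no `can_synthesize = FALSE` label, truly
#' auxotrophic otherwise. Prototroph accuracy is the fraction of truly
#' prototrophic genomes predicted to have zero auxotrophies; auxotroph
#' accuracy is the fraction of truly auxotrophic genomes predicted
#' auxotrophic for at least one compound.
#'
#' @inheritParams false_positive_rate
#' @return list with `prototroph_accuracy`, `auxotroph_accuracy`,
#'   `n_prototrophs`, `n_auxotrophs` (either accuracy is `NaN` when its
#'   truth class is empty).
#' @export
genome_level_accuracy <- function(profiles, labels) {
  if (inherits(profiles, "aux_profiles")) {
    genomes <- profiles$genomes
  } else {
    stop_aux("profiles must be an aux_profiles object",
             class = "aux_invalid_input")
  }
  require_columns(labels, c("genome_id", "compound", "can_synthesize"),
                  "label table")
  labels <- drop_unmodeled_labels(labels)
  if (nrow(labels) == 0L) {
    stop_aux("empty label set", class = "aux_no_labels")
  }
  truly_aux <- tapply(!labels$can_synthesize, labels$genome_id, any)
  ids <- names(truly_aux)
  missing <- setdiff(ids, genomes$genome_id)
  if (length(missing) > 0L) {
    stop_aux("labeled genome(s) lack predictions: ",
             paste(missing, collapse = ", "), class = "aux_missing_pairs")
  }
  n_aux <- genomes$n_auxotrophies[match(ids, genomes$genome_id)]
  proto_ids <- !truly_aux
  list(
    prototroph_accuracy = mean(n_aux[proto_ids] == 0),
    auxotroph_accuracy = mean(n_aux[!proto_ids] >= 1),
    n_prototrophs = sum(proto_ids),
    n_auxotrophs = sum(!proto_ids)
  )
}

#' Sweep the missing-fraction threshold and select an operating point
#'
#' Re-profiles the evidence at each candidate threshold, computes
#' false-positive and false-negative rates and genome-level accuracies
#' against the labels, and selects the smallest threshold whose
#' false-positive rate does not exceed `fp_target` (the smallest qualifying
#' threshold maximises sensitivity subject to the FP constraint).
#'
#' @param evidence evidence table (see [profile_genomes()]).
#' @param db complete pathway database.
#' @param labels validation label table.
#' @param thresholds ascending numeric grid of thresholds (percent).
#' @param fp_target maximum tolerated false-positive proportion (default
#'   0.004, the published operating point).
#' @param genome_ids optional explicit genome set to profile.
#' @return object of class `aux_calibration`: list with `results` (one row
#'   per threshold: `threshold_percent`, `fp_rate`, `fn_rate`,
#'   `prototroph_accuracy`, `auxotroph_accuracy`), `selected`
#'   (threshold, or `NA` when none qualifies) and `fp_target`.
#' @export
threshold_sweep <- function(evidence, db, labels, thresholds = seq(10, 100, 5),
                            fp_target = 0.004, genome_ids = NULL) {
  if (length(thresholds) == 0L) {
    stop_aux("empty threshold grid", class = "aux_invalid_threshold")
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop_aux("thresholds must be strictly ascending",
             class = "aux_invalid_threshold")
  }
  if (fp_target < 0 || fp_target > 1) {
    stop_aux("fp_target must be a proportion in [0, 1]",
             class = "aux_invalid_threshold")
  }
  has_proto <- any(labels$can_synthesize)
  has_aux <- any(!labels$can_synthesize)
  rows <- lapply(thresholds, function(th) {
    prof <- profile_genomes(evidence, db, threshold_percent = th,
                            genome_ids = genome_ids)
    acc <- genome_level_accuracy(prof, labels)
    data.frame(
      threshold_percent = th,
      fp_rate = if (has_proto) false_positive_rate(prof, labels)$overall
                else NA_real_,
      fn_rate = if (has_aux) false_negative_rate(prof, labels)$overall
                else NA_real_,
      prototroph_accuracy = acc$prototroph_accuracy,
      auxotroph_accuracy = acc$auxotroph_accuracy
    )
  })
  results <- do.call(rbind, rows)
  qualifying <- which(!is.na(results$fp_rate) &
                        results$fp_rate <= fp_target)
  selected <- if (length(qualifying) > 0L) {
    results$threshold_percent[qualifying[1L]]
  } else {
    NA_real_
  }
  structure(list(results = results, selected = selected,
                 fp_target = fp_target),
            class = "aux_calibration")
}

#' @export
print.aux_calibration <- function(x, ...) {
  cat("Threshold calibration over", nrow(x$results), "grid point(s)\n")
  print(x$results, row.names = FALSE)
  if (is.na(x$selected)) {
    cat("No threshold met the FP target of", x$fp_target, "\n")
  } else {
    cat("Selected threshold:", x$selected, "% (FP target",
        x$fp_target, ")\n")
  }
  invisible(x)
}

# join predictions with labels of one phenotype class; errors on labeled
# pairs without a prediction, drops (with a warning) unmodeled compounds
join_labels <- function(profiles, labels, can_synthesize) {
  if (inherits(profiles, "aux_profiles")) profiles <- profiles$calls
  require_columns(profiles, c("genome_id", "compound", "auxotrophic"),
                  "profile table")
  require_columns(labels, c("genome_id", "compound", "can_synthesize"),
                  "label table")
  labels <- drop_unmodeled_labels(labels)
  if (anyDuplicated(labels[, c("genome_id", "compound")])) {
    stop_aux("duplicate (genome_id, compound) label pairs",
             class = "aux_invalid_labels")
  }
  labels <- labels[labels$can_synthesize == can_synthesize, , drop = FALSE]
  joined <- merge(labels, profiles, by = c("genome_id", "compound"),
                  all.x = TRUE)
  if (anyNA(joined$auxotrophic)) {
    bad <- joined[is.na(joined$auxotrophic), c("genome_id", "compound")]
    stop_aux("labeled pair(s) with no prediction: ",
             paste(bad$genome_id, bad$compound, sep = ":", collapse = ", "),
             class = "aux_missing_pairs")
  }
  joined
}

drop_unmodeled_labels <- function(labels) {
  unmodeled <- !(labels$compound %in% aux_compounds())
  if (any(unmodeled)) {
    warning("dropping ", sum(unmodeled),
            " label(s) for compounds outside the 18 modeled",
            call. = FALSE)
    labels <- labels[!unmodeled, , drop = FALSE]
  }
  labels
}
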