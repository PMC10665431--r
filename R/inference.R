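#' Evaluate a candidate protein hit for a biosynthetic step
#'
#' A hit supports a step when it is at least a medium-confidence candidate:
#' either (1) at least 40% identity and 70% coverage to a characterized
#' pathway protein, or (2) at least 30% identity and 80% coverage. In both
#' cases, when the protein also aligns to characterized proteins with other
#' functions, the bit score against the pathway protein must be strictly
#' higher than the bit score against the other-function protein; an absent
#' other-function alignment means there is no competing hit and the
#' identity/coverage branch alone decides. All boundaries are inclusive.
#'
#' @param identity percent identity in `[0, 100]` (vectorised).
#' @param coverage percent coverage in `[0, 100]`.
#' @param bits_pathway non-negative bit score of the alignment to pathway
#'   proteins.
#' @param bits_other bit score of the best alignment to an other-function
#'   protein, or `NA` when no such alignment exists.
#' @return logical vector: is the hit a valid medium-confidence candidate?
#' @examples
#' evaluate_candidate(40, 70, 120)                   # TRUE (branch 1 boundary)
#' evaluate_candidate(30, 80, 100, bits_other = 90)  # TRUE (branch 2)
#' evaluate_candidate(45, 90, 50, bits_other = 50)   # FALSE (tie loses)
#' @export
evaluate_candidate <- function(identity, coverage, bits_pathway,
                               bits_other = NA_real_) {
  n <- max(length(identity), length(coverage), length(bits_pathway),
           length(bits_other))
  identity <- rep_len(as.numeric(identity), n)
  coverage <- rep_len(as.numeric(coverage), n)
  bits_pathway <- rep_len(as.numeric(bits_pathway), n)
  bits_other <- rep_len(as.numeric(bits_other), n)
  if (any(!is.finite(identity)) || any(identity < 0 | identity > 100)) {
    stop_aux("identity must be a percent in [0, 100]",
             class = "aux_invalid_evidence")
  }
  if (any(!is.finite(coverage)) || any(coverage < 0 | coverage > 100)) {
    stop_aux("coverage must be a percent in [0, 100]",
             class = "aux_invalid_evidence")
  }
  if (any(!is.finite(bits_pathway)) || any(bits_pathway < 0)) {
    stop_aux("bits_pathway must be finite and non-negative",
             class = "aux_invalid_evidence")
  }
  if (any(!is.na(bits_other) & (!is.finite(bits_other) | bits_other < 0))) {
    stop_aux("bits_other must be finite and non-negative, or NA",
             class = "aux_invalid_evidence")
  }
  score_ok <- is.na(bits_other) | bits_pathway > bits_other
  ((identity >= 40 & coverage >= 70) | (identity >= 30 & coverage >= 80)) &
    score_ok
}

#' Call presence of one biosynthetic step from its evidence
#'
#' A step is present when at least one of its candidate hits passes
#' [evaluate_candidate()]; no evidence means absent.
#'
#' @param step_id the step identifier.
#' @param evidence data.frame of hit evidence with columns `step_id`,
#'   `identity`, `coverage`, `bits_pathway`, `bits_other`; rows for other
#'   steps are ignored.
#' @return logical scalar.
#' @export
call_step <- function(step_id, evidence) {
  evidence <- as_evidence(evidence, require_genome = FALSE)
  e <- evidence[evidence$step_id == step_id, , drop = FALSE]
  if (nrow(e) == 0L) return(FALSE)
  any(evaluate_candidate(e$identity, e$coverage, e$bits_pathway,
                         e$bits_other))
}

# normalise an evidence data.frame, adding bits_other = NA when absent
as_evidence <- function(evidence, require_genome = TRUE) {
  cols <- c(if (require_genome) "genome_id", "step_id", "identity",
            "coverage", "bits_pathway")
  require_columns(evidence, cols, "evidence table")
  if (is.null(evidence$bits_other)) evidence$bits_other <- NA_real_
  evidence
}

#' Missing-gene fraction of a pathway over its alternative routes
#'
#' Scores the pathway by its most complete route: among all routes, returns
#' the `(missing, total)` step counts of the route minimising
#' `missing / total` (ties broken by smaller `total`, then by the order
#' routes are listed). Step ids with no call are treated as absent. Route
#' comparison uses exact integer cross-multiplication, never floating-point
#' fractions.
#'
#' @param pathway an [pathway_definition()] object.
#' @param step_calls named logical vector of step presence calls.
#' @return integer vector `c(missing =, total =)`.
#' @examples
#' p <- pathway_definition("lysine", list(c("a", "b", "c"), c("d", "e", "f", "g")))
#' pathway_missing_fraction(p, c(a = TRUE, b = TRUE, c = FALSE,
#'                               d = TRUE, e = TRUE, f = TRUE, g = FALSE))
#' @export
pathway_missing_fraction <- function(pathway, step_calls) {
  if (!inherits(pathway, "aux_pathway")) {
    pathway <- pathway_definition(pathway$compound, pathway$routes)
  }
  best_m <- NA_integer_
  best_t <- NA_integer_
  for (route in pathway$routes) {
    total <- length(route)
    present <- step_calls[route]
    present[is.na(present)] <- FALSE
    missing <- total - sum(present)
    if (is.na(best_m) ||
        missing * best_t < best_m * total ||
        (missing * best_t == best_m * total && total < best_t)) {
      best_m <- as.integer(missing)
      best_t <- as.integer(total)
    }
  }
  c(missing = best_m, total = best_t)
}

#' Call a compound auxotrophy from a missing-gene fraction
#'
#' Auxotrophic when at least `threshold_percent` of the genes of the best
#' route are missing. The comparison `missing / total >= threshold / 100` is
#' evaluated in exact integer arithmetic (`missing * 100 >= threshold *
#' total`), so fractions lying exactly on the threshold (e.g. 2/5 at 40) are
#' always called auxotrophic, with no floating-point drift.
#'
#' @param missing,total integer step counts, `0 <= missing <= total`,
#'   `total >= 1` (vectorised).
#' @param threshold_percent threshold on the 0-100 scale (default 40, the
#'   calibrated value giving a 0.4% false-positive rate).
#' @return logical vector.
#' @examples
#' call_compound_auxotrophy(2, 5)  # TRUE: exactly 40% missing
#' call_compound_auxotrophy(1, 5)  # FALSE: 20% < 40%
#' @export
call_compound_auxotrophy <- function(missing, total, threshold_percent = 40) {
  if (!is_count(missing) || !is_count(total)) {
    stop_aux("missing and total must be non-negative integers",
             class = "aux_invalid_fraction")
  }
  n <- max(length(missing), length(total))
  missing <- rep_len(missing, n)
  total <- rep_len(total, n)
  if (any(total < 1)) {
    stop_aux("total must be >= 1", class = "aux_invalid_fraction")
  }
  if (any(missing > total)) {
    stop_aux("missing must not exceed total", class = "aux_invalid_fraction")
  }
  if (!is.numeric(threshold_percent) || length(threshold_percent) != 1L ||
      !is.finite(threshold_percent) ||
      threshold_percent < 0 || threshold_percent > 100) {
    stop_aux("threshold_percent must be a single value in [0, 100]",
             class = "aux_invalid_threshold")
  }
  missing * 100 >= threshold_percent * total
}

#' Profile genomes for amino acid auxotrophy
#'
#' Runs the full inference for a set of genomes: evidence rows are screened
#' with [evaluate_candidate()], steps with at least one valid candidate are
#' present, each compound is scored by its most complete route, and the
#' compound is called auxotrophic when at least `threshold_percent` of that
#' route's genes are missing.
#'
#' @param evidence data.frame with columns `genome_id`, `step_id`,
#'   `identity`, `coverage`, `bits_pathway`, `bits_other` (NA = no competing
#'   alignment).
#' @param db pathway database covering all 18 modeled compounds exactly once.
#' @param threshold_percent missing-fraction threshold (percent).
#' @param genome_ids genomes to profile; defaults to those present in
#'   `evidence`. Genomes with no evidence receive fully-missing profiles.
#' @return object of class `aux_profiles`: list with
#'   \describe{
#'     \item{calls}{data.frame `genome_id`, `compound`, `missing`, `total`,
#'       `missing_fraction`, `auxotrophic` (18 rows per genome).}
#'     \item{genomes}{data.frame `genome_id`, `n_auxotrophies`.}
#'     \item{threshold_percent}{the threshold used.}
#'   }
#' @export
profile_genomes <- function(evidence, db, threshold_percent = 40,
                            genome_ids = NULL) {
  validate_pathway_db(db, complete = TRUE)
  evidence <- as_evidence(evidence)
  if (is.null(genome_ids)) genome_ids <- unique(evidence$genome_id)
  genome_ids <- as.character(genome_ids)
  if (length(genome_ids) == 0L) {
    stop_aux("no genomes to profile", class = "aux_no_genomes")
  }

  routes <- pathway_route_table(db)
  routes$key <- paste(routes$compound, routes$route, sep = "\r")
  route_info <- unique(routes[, c("compound", "route", "route_len", "key")])

  if (nrow(evidence) > 0L) {
    pass <- evaluate_candidate(evidence$identity, evidence$coverage,
                               evidence$bits_pathway, evidence$bits_other)
    present <- unique(evidence[pass, c("genome_id", "step_id")])
  } else {
    present <- data.frame(genome_id = character(), step_id = character())
  }
  hits <- merge(present, routes[, c("step_id", "key")], by = "step_id")
  # genomes x routes matrix of present-step counts
  n_present <- table(factor(hits$genome_id, levels = genome_ids),
                     factor(hits$key, levels = route_info$key))
  n_present <- matrix(as.integer(n_present), nrow = length(genome_ids),
                      dimnames = list(genome_ids, route_info$key))

  calls <- vector("list", length(db))
  compounds <- vapply(unname(db), function(p) p$compound, character(1))
  for (i in seq_along(compounds)) {
    info <- route_info[route_info$compound == compounds[i], , drop = FALSE]
    info <- info[order(info$route), , drop = FALSE]
    miss <- matrix(rep(info$route_len, each = length(genome_ids)),
                   nrow = length(genome_ids)) -
      n_present[, info$key, drop = FALSE]
    tot <- info$route_len
    best <- rep(1L, length(genome_ids))
    if (nrow(info) > 1L) {
      for (j in 2L:nrow(info)) {
        bm <- miss[cbind(seq_along(best), best)]
        bt <- tot[best]
        better <- miss[, j] * bt < bm * tot[j] |
          (miss[, j] * bt == bm * tot[j] & tot[j] < bt)
        best[better] <- j
      }
    }
    m <- miss[cbind(seq_along(best), best)]
    t_ <- tot[best]
    calls[[i]] <- data.frame(
      genome_id = genome_ids,
      compound = compounds[i],
      missing = as.integer(m),
      total = as.integer(t_),
      missing_fraction = m / t_,
      auxotrophic = call_compound_auxotrophy(as.integer(m), as.integer(t_),
                                             threshold_percent),
      stringsAsFactors = FALSE
    )
  }
  calls <- do.call(rbind, calls)
  calls <- calls[order(match(calls$genome_id, genome_ids),
                       match(calls$compound, compounds)), , drop = FALSE]
  rownames(calls) <- NULL
  n_aux <- tapply(calls$auxotrophic, factor(calls$genome_id,
                                            levels = genome_ids), sum)
  genomes <- data.frame(genome_id = genome_ids,
                        n_auxotrophies = as.integer(n_aux),
                        stringsAsFactors = FALSE)
  rownames(genomes) <- NULL
  structure(list(calls = calls, genomes = genomes,
                 threshold_percent = threshold_percent),
            class = "aux_profiles")
}

#' @export
print.aux_profiles <- function(x, ...) {
  cat("Auxotrophy profiles:", nrow(x$genomes), "genome(s) x",
      length(unique(x$calls$compound)), "compounds at threshold",
      x$threshold_percent, "%\n")
  cat("  auxotrophic calls:", sum(x$calls$auxotrophic), "of",
      nrow(x$calls), "genome-compound pairs\n")
  invisible(x)
}

#' Profile a single genome
#'
#' @param genome_id genome identifier.
#' @inheritParams profile_genomes
#' @return one-genome `aux_profiles` object.
#' @export
profile_genome <- function(genome_id, evidence, db, threshold_percent = 40) {
  evidence <- as_evidence(evidence)
  profile_genomes(evidence[evidence$genome_id == genome_id, , drop = FALSE],
                  db, threshold_percent, genome_ids = genome_id)
}

#' Classify genomes as prototrophs or auxotrophs
#'
#' With `min_auxotrophies = 1` every genome is labeled: prototroph when it
#' has zero predicted auxotrophies, auxotroph otherwise. With a stricter
#' cutoff (e.g. 2, used for the streamlining contrasts), genomes whose
#' auxotrophy count falls between zero and the cutoff are excluded (`NA`).
#'
#' @param profiles an `aux_profiles` object, or its `genomes` data.frame.
#' @param min_auxotrophies minimum count to label a genome auxotrophic
#'   (>= 1).
#' @return data.frame `genome_id`, `n_auxotrophies`, `class` (factor with
#'   levels prototroph/auxotroph; `NA` = excluded).
#' @export
classify_genomes <- function(profiles, min_auxotrophies = 1) {
  if (inherits(profiles, "aux_profiles")) profiles <- profiles$genomes
  require_columns(profiles, c("genome_id", "n_auxotrophies"),
                  "genome summary")
  if (min_auxotrophies < 1) {
    stop_aux("min_auxotrophies must be >= 1", class = "aux_invalid_threshold")
  }
  n <- profiles$n_auxotrophies
  cls <- ifelse(n == 0, "prototroph",
                ifelse(n >= min_auxotrophies, "auxotroph", NA_character_))
  data.frame(genome_id = profiles$genome_id,
             n_auxotrophies = n,
             class = factor(cls, levels = c("prototroph", "auxotroph")),
             stringsAsFactors = FALSE)
}

#' Filter genome records for inclusion in the analysis
#'
#' Applies, in order: (1) completeness strictly greater than 95%; (2) no
#' signal of chimerism; (3) metagenome-assembled and single-amplified
#' genomes (MAG/SAG) must carry an assembled 16S rRNA gene (isolates are
#' exempt).
#'
#' @param records data.frame with columns `genome_id`, `origin`
#'   (isolate/MAG/SAG), `completeness`, `chimeric`, `has_16S`.
#' @param min_completeness completeness cutoff, exclusive (default 95).
#' @return list with `kept` (passing records), `rejected` (records plus a
#'   `reason` column), and `counts` (named integer vector of removals per
#'   rule, in application order).
#' @export
filter_genomes <- function(records, min_completeness = 95) {
  require_columns(records,
                  c("genome_id", "origin", "completeness", "chimeric",
                    "has_16S"),
                  "genome record table")
  reason <- rep(NA_character_, nrow(records))
  fail1 <- records$completeness <= min_completeness
  reason[fail1] <- "low_completeness"
  fail2 <- is.na(reason) & records$chimeric
  reason[fail2] <- "chimeric"
  fail3 <- is.na(reason) & records$origin %in% c("MAG", "SAG") &
    !records$has_16S
  reason[fail3] <- "assembled_without_16S"
  kept <- records[is.na(reason), , drop = FALSE]
  rejected <- records[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  counts <- c(low_completeness = sum(fail1),
              chimeric = sum(fail2),
              assembled_without_16S = sum(fail3))
  list(kept = kept, rejected = rejected, counts = counts)
}
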