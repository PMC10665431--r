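# independent oracles and tiny fixture builders used across test files

# exhaustive route enumeration with exact rational comparison: the
# reference result pathway_missing_fraction must reproduce
oracle_missing_fraction <- function(routes, step_calls) {
  best <- NULL
  for (route in routes) {
    total <- length(route)
    present <- step_calls[route]
    present[is.na(present)] <- FALSE
    missing <- total - sum(present)
    if (is.null(best) ||
        missing * best[2] < best[1] * total ||
        (missing * best[2] == best[1] * total && total < best[2])) {
      best <- c(missing, total)
    }
  }
  as.integer(best)
}

# random pathway with unique step ids across routes
random_pathway <- function(compound, max_routes = 6, max_steps = 10) {
  n_routes <- sample.int(max_routes, 1)
  routes <- lapply(seq_len(n_routes), function(r) {
    sprintf("%s_r%d_s%d", compound, r, seq_len(sample.int(max_steps, 1)))
  })
  pathway_definition(compound, routes)
}

# brute-force confusion tally over a prediction table and labels
oracle_confusion <- function(calls, labels) {
  fp <- 0L; tn <- 0L; fn <- 0L; tp <- 0L
  for (i in seq_len(nrow(labels))) {
    pred <- calls$auxotrophic[calls$genome_id == labels$genome_id[i] &
                                calls$compound == labels$compound[i]]
    stopifnot(length(pred) == 1L)
    if (labels$can_synthesize[i]) {
      if (pred) fp <- fp + 1L else tn <- tn + 1L
    } else {
      if (pred) tp <- tp + 1L else fn <- fn + 1L
    }
  }
  list(fp = fp, tn = tn, fn = fn, tp = tp)
}

# complete 18-compound database, one route of `steps_per` steps each
tiny_db <- function(steps_per = 3) {
  db <- lapply(aux_compounds(), function(cmp) {
    pathway_definition(cmp, list(sprintf("%s_s%d", cmp, seq_len(steps_per))))
  })
  names(db) <- aux_compounds()
  db
}

all_steps <- function(db) {
  unlist(lapply(db, function(p) unlist(p$routes)), use.names = FALSE)
}

passing_evidence <- function(genome_id, steps) {
  n <- length(steps)
  data.frame(genome_id = rep(genome_id, n), step_id = steps,
             identity = rep(80, n), coverage = rep(90, n),
             bits_pathway = rep(200, n), bits_other = rep(NA_real_, n),
             stringsAsFactors = FALSE)
}

failing_evidence <- function(genome_id, steps) {
  n <- length(steps)
  data.frame(genome_id = rep(genome_id, n), step_id = steps,
             identity = rep(20, n), coverage = rep(50, n),
             bits_pathway = rep(30, n), bits_other = rep(NA_real_, n),
             stringsAsFactors = FALSE)
}

read_tsv_helper <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

scratch_dir <- function() {
  d <- tempfile("auxtest")
  dir.create(d, recursive = TRUE)
  d
}

# random reference sequence helpers for matching tests
random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

substitute_at <- function(seq, pos) {
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}
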