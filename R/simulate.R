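#' Habitat specification for the synthetic community generator
#'
#' @param name habitat name.
#' @param n_samples number of samples sequenced.
#' @param n_taxa number of taxa (ASVs) planted in the habitat.
#' @param prevalence planted proportion of taxa that are auxotrophic for at
#'   least one compound.
#' @param meanlog,sdlog log-normal parameters of the taxon mean-abundance
#'   distribution.
#' @param reads_per_sample sequencing depth per sample (multinomial total).
#' @param unmatched_fraction fraction of ASVs carrying 3 substitutions so
#'   that they cannot be matched at the 1-mismatch cutoff (emulates taxa
#'   without representative genomes).
#' @return list of class `habitat_spec`.
#' @export
habitat_spec <- function(name, n_samples, n_taxa, prevalence,
                         meanlog = 0, sdlog = 1.5,
                         reads_per_sample = 10000,
                         unmatched_fraction = 0.05) {
  if (n_samples < 1) {
    stop_aux("habitat ", name, " must have at least 1 sample",
             class = "aux_invalid_config")
  }
  stopifnot(n_taxa >= 1, prevalence >= 0, prevalence <= 1,
            unmatched_fraction >= 0, unmatched_fraction <= 1)
  structure(list(name = name, n_samples = as.integer(n_samples),
                 n_taxa = as.integer(n_taxa), prevalence = prevalence,
                 meanlog = meanlog, sdlog = sdlog,
                 reads_per_sample = as.integer(reads_per_sample),
                 unmatched_fraction = unmatched_fraction),
            class = "habitat_spec")
}

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a mid-sized study: 500 genomes, all 18 compounds, a
#' per-genome-per-compound knockout probability of 0.05 (about 60% of
#' genomes auxotrophic for at least one compound, within the range observed
#' across real habitats), no evidence dropout, a 5% decoy rate, and three
#' habitats spanning low, intermediate and high auxotroph prevalence.
#' Identical configurations yield bit-identical outputs.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_genomes number of genomes.
#' @param compounds compounds to model (default all 18).
#' @param steps_per_route inclusive range of steps per route.
#' @param routes_per_compound inclusive range of alternative routes.
#' @param auxotrophy_rate per-genome probability that a compound's pathway
#'   is knocked out.
#' @param gene_dropout probability that an individual present gene's
#'   evidence row is deleted (emulates incomplete genomes).
#' @param decoy_rate probability that an absent step gains sub-threshold
#'   (failing) evidence.
#' @param knockout_fraction fraction of each route's steps removed by a
#'   knockout (ceiling; the default 0.5 keeps every route at or above the
#'   40% missing threshold, a "shallow" value < 0.4 exercises false
#'   negatives).
#' @param habitat_specs list of [habitat_spec()] objects.
#' @param cog_effect multiplicative prevalence shift applied to
#'   `cog_enriched` categories in genomes with >= 2 planted auxotrophies.
#' @param cog_enriched COG category letters planted as auxotroph-enriched
#'   (defaults J = translation, O = post-translational modification /
#'   protein turnover, the streamlining signature).
#' @param cog_depleted categories that absorb the enriched mass in
#'   auxotroph genomes, i.e. are planted prototroph-enriched (defaults:
#'   carbohydrate and amino acid transport/metabolism, transcription,
#'   signal transduction). Balancing the boost inside this set keeps the
#'   expected prevalence of every *unplanted* category identical between
#'   groups, so enrichment tests on them are calibrated at their nominal
#'   level.
#' @param size_model list `intercept`, `slope`, `sd` (bp) linking planted
#'   auxotrophy count to genome size.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_genomes = 500,
                       compounds = aux_compounds(),
                       steps_per_route = c(3, 10),
                       routes_per_compound = c(1, 3),
                       auxotrophy_rate = 0.05,
                       gene_dropout = 0,
                       decoy_rate = 0.05,
                       knockout_fraction = 0.5,
                       habitat_specs = default_habitat_specs(),
                       cog_effect = 1.5,
                       cog_enriched = c("J", "O"),
                       cog_depleted = c("E", "G", "K", "T"),
                       size_model = list(intercept = 5.2e6, slope = -2e5,
                                         sd = 4e5)) {
  as_compound(compounds)
  if (length(compounds) == 0L) {
    stop_aux("compound list must be non-empty", class = "aux_invalid_config")
  }
  if (!is.null(names(auxotrophy_rate)) || length(auxotrophy_rate) > 1L) {
    # per-compound knockout probabilities, named by compound
    if (is.null(names(auxotrophy_rate)) ||
        !all(names(auxotrophy_rate) %in% compounds)) {
      stop_aux("a vector auxotrophy_rate must be named by compound",
               class = "aux_invalid_config")
    }
    full <- setNames(rep(0, length(compounds)), compounds)
    full[names(auxotrophy_rate)] <- auxotrophy_rate
    auxotrophy_rate <- full
  }
  probs <- c(auxotrophy_rate, gene_dropout = gene_dropout,
             decoy_rate = decoy_rate)
  if (any(probs < 0 | probs > 1)) {
    stop_aux("rates must be probabilities in [0, 1]",
             class = "aux_invalid_config")
  }
  if (length(intersect(cog_enriched, cog_depleted)) > 0L) {
    stop_aux("cog_enriched and cog_depleted must be disjoint",
             class = "aux_invalid_config")
  }
  if (knockout_fraction <= 0 || knockout_fraction > 1) {
    stop_aux("knockout_fraction must be in (0, 1]",
             class = "aux_invalid_config")
  }
  stopifnot(length(steps_per_route) == 2L, steps_per_route[1] >= 1,
            diff(steps_per_route) >= 0,
            length(routes_per_compound) == 2L, routes_per_compound[1] >= 1,
            diff(routes_per_compound) >= 0,
            n_genomes >= 1)
  for (h in habitat_specs) stopifnot(inherits(h, "habitat_spec"))
  structure(list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
                 compounds = compounds,
                 steps_per_route = as.integer(steps_per_route),
                 routes_per_compound = as.integer(routes_per_compound),
                 auxotrophy_rate = auxotrophy_rate,
                 gene_dropout = gene_dropout, decoy_rate = decoy_rate,
                 knockout_fraction = knockout_fraction,
                 habitat_specs = habitat_specs, cog_effect = cog_effect,
                 cog_enriched = cog_enriched, cog_depleted = cog_depleted,
                 size_model = size_model),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_habitat_specs <- function() {
  list(habitat_spec("gut_like", 40, 150, 0.55),
       habitat_spec("soil_like", 40, 150, 0.05),
       habitat_spec("marine_like", 40, 150, 0.25))
}

cog_categories <- function() {
  c("J", "A", "K", "L", "B", "D", "Y", "V", "T", "M", "N", "Z", "W", "U",
    "O", "C", "G", "E", "F", "H", "I", "P", "Q")
}

cog_base_weights <- function() {
  w <- c(J = 0.060, A = 0.004, K = 0.070, L = 0.055, B = 0.004, D = 0.015,
         Y = 0.003, V = 0.020, T = 0.050, M = 0.060, N = 0.020, Z = 0.004,
         W = 0.006, U = 0.020, O = 0.040, C = 0.060, G = 0.080, E = 0.090,
         F = 0.030, H = 0.040, I = 0.040, P = 0.070, Q = 0.015)
  w / sum(w)
}

#' Generate a synthetic pathway database
#'
#' One definition per configured compound, with route and step counts drawn
#' uniformly from the configured ranges; step ids are globally unique.
#'
#' @param config a [sim_config()].
#' @return named list of [pathway_definition()] objects.
#' @export
generate_pathways <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pick <- function(rng) if (rng[1] == rng[2]) rng[1]
                        else sample(seq(rng[1], rng[2]), 1)
  with_seed(stage_seed(config$seed, 1L), {
    db <- lapply(config$compounds, function(cmp) {
      n_routes <- pick(config$routes_per_compound)
      routes <- lapply(seq_len(n_routes), function(r) {
        len <- pick(config$steps_per_route)
        sprintf("%s_r%d_s%02d", cmp, r, seq_len(len))
      })
      pathway_definition(cmp, routes)
    })
    names(db) <- config$compounds
    db
  })
}

#' Generate genome evidence, metadata and ground truth
#'
#' For each genome and compound, the compound's pathway is knocked out with
#' probability `auxotrophy_rate`: every route loses
#' `ceiling(knockout_fraction * length)` randomly chosen steps and the pair
#' is recorded as a planted auxotrophy. Surviving steps receive evidence
#' that passes [evaluate_candidate()]; `gene_dropout` then deletes evidence
#' rows independently, and absent steps gain failing decoy evidence with
#' probability `decoy_rate`. Genome size follows the configured linear
#' model in the planted auxotrophy count; COG counts are drawn from a
#' Dirichlet-multinomial in which genomes with two or more planted
#' auxotrophies have the `cog_enriched` categories up-weighted by
#' `cog_effect`, the excess absorbed by the `cog_depleted` categories, and
#' all other categories left at the prototroph expectation; every genome
#' gets a random 16S rRNA gene sequence (1200-1550 nt).
#'
#' @param config a [sim_config()].
#' @param pathways database from [generate_pathways()] (same config).
#' @return list with `evidence` (hit table), `records` (genome metadata),
#'   `cog_counts` (genome x category data.frame), `seqs_16S` (named
#'   character) and `truth` (planted auxotrophy matrix, per-genome counts,
#'   enriched categories, size model).
#' @export
generate_genomes <- function(config, pathways) {
  stopifnot(inherits(config, "sim_config"))
  validate_pathway_db(pathways)
  with_seed(stage_seed(config$seed, 2L), {
    n <- config$n_genomes
    ids <- sprintf("G%05d", seq_len(n))
    compounds <- config$compounds
    rate <- config$auxotrophy_rate
    if (length(rate) == 1L) rate <- setNames(rep(rate, length(compounds)),
                                             compounds)
    planted <- matrix(runif(n * length(compounds)) <
                        rep(rate[compounds], each = n),
                      nrow = n, dimnames = list(ids, compounds))

    routes <- pathway_route_table(pathways)
    steps <- routes$step_id
    step_compound <- setNames(routes$compound, routes$step_id)

    # knocked-out (genome, step) pairs for every planted auxotrophy
    knocked_g <- list()
    knocked_s <- list()
    hit_idx <- which(planted, arr.ind = TRUE)
    if (nrow(hit_idx) > 0L) {
      for (k in seq_len(nrow(hit_idx))) {
        cmp <- compounds[hit_idx[k, 2]]
        p <- pathways[[cmp]]
        lost <- unlist(lapply(p$routes, function(r) {
          sample(r, ceiling(config$knockout_fraction * length(r)))
        }), use.names = FALSE)
        knocked_g[[k]] <- rep(ids[hit_idx[k, 1]], length(lost))
        knocked_s[[k]] <- lost
      }
    }
    knocked <- paste(unlist(knocked_g), unlist(knocked_s), sep = "\r")

    grid_g <- rep(ids, each = length(steps))
    grid_s <- rep(steps, times = n)
    is_present <- !(paste(grid_g, grid_s, sep = "\r") %in% knocked)
    dropped <- is_present & runif(length(grid_g)) < config$gene_dropout
    keep <- is_present & !dropped
    absent <- !is_present | dropped

    n_keep <- sum(keep)
    bits_pathway <- runif(n_keep, 150, 450)
    has_other <- runif(n_keep) < 0.3
    evidence <- data.frame(
      genome_id = grid_g[keep],
      step_id = grid_s[keep],
      identity = runif(n_keep, 55, 95),
      coverage = runif(n_keep, 75, 100),
      bits_pathway = bits_pathway,
      bits_other = ifelse(has_other, bits_pathway * runif(n_keep, 0.3, 0.9),
                          NA_real_),
      stringsAsFactors = FALSE
    )
    decoy <- absent & runif(length(grid_g)) < config$decoy_rate
    n_dec <- sum(decoy)
    if (n_dec > 0L) {
      decoys <- data.frame(
        genome_id = grid_g[decoy],
        step_id = grid_s[decoy],
        identity = runif(n_dec, 10, 28),   # below both identity branches
        coverage = runif(n_dec, 30, 65),
        bits_pathway = runif(n_dec, 20, 60),
        bits_other = NA_real_,
        stringsAsFactors = FALSE
      )
      evidence <- rbind(evidence, decoys)
    }
    evidence <- evidence[order(evidence$genome_id, evidence$step_id), ,
                         drop = FALSE]
    rownames(evidence) <- NULL

    n_aux <- unname(rowSums(planted))
    sm <- config$size_model
    genome_size <- round(pmax(sm$intercept + sm$slope * n_aux +
                                rnorm(n, 0, sm$sd), 5e5))
    gene_count <- round(genome_size / 1100)
    records <- data.frame(
      genome_id = ids,
      origin = sample(c("isolate", "MAG", "SAG"), n, replace = TRUE,
                      prob = c(0.55, 0.35, 0.10)),
      completeness = round(runif(n, 95.5, 100), 2),
      chimeric = FALSE,
      has_16S = TRUE,
      genome_size = genome_size,
      gene_count = gene_count,
      phylum = sample(c("Bacteroidetes", "Firmicutes", "Proteobacteria",
                        "Actinobacteria"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    rownames(records) <- NULL

    cats <- cog_categories()
    base <- cog_base_weights()[cats]
    strict_aux <- n_aux >= 2
    # auxotroph composition: enriched categories boosted by cog_effect, the
    # excess mass drawn from the depleted set; unplanted categories keep
    # exactly the prototroph expectation (no compositional leakage)
    w_aux <- base
    w_aux[config$cog_enriched] <- base[config$cog_enriched] *
      config$cog_effect
    excess <- sum(w_aux) - 1
    dep <- base[config$cog_depleted]
    if (excess >= sum(dep)) {
      stop_aux("cog_effect too large: depleted categories cannot absorb ",
               "the enriched mass", class = "aux_invalid_config")
    }
    w_aux[config$cog_depleted] <- dep * (1 - excess / sum(dep))
    conc <- 400  # Dirichlet concentration: between-genome compositional noise
    cog <- matrix(0L, nrow = n, ncol = length(cats),
                  dimnames = list(ids, cats))
    n_annot <- round(gene_count * 0.85)
    for (i in seq_len(n)) {
      w <- if (strict_aux[i]) w_aux else base
      g <- rgamma(length(cats), shape = w * conc)
      cog[i, ] <- as.integer(rmultinom(1, n_annot[i], prob = g / sum(g)))
    }
    cog_counts <- data.frame(genome_id = ids, cog,
                             stringsAsFactors = FALSE, check.names = FALSE)
    rownames(cog_counts) <- NULL

    lens <- sample(1200:1550, n, replace = TRUE)
    bases <- sample(c("A", "C", "G", "T"), sum(lens), replace = TRUE)
    seqs <- vapply(split(bases, rep(seq_len(n), lens)), paste0,
                   character(1), collapse = "")
    seqs_16S <- setNames(unname(seqs), ids)

    list(evidence = evidence, records = records, cog_counts = cog_counts,
         seqs_16S = seqs_16S,
         truth = list(planted = planted,
                      n_auxotrophies = setNames(as.integer(n_aux), ids),
                      enriched_categories = config$cog_enriched,
                      depleted_categories = config$cog_depleted,
                      size_model = sm))
  })
}

#' Validation labels implied by the planted ground truth
#'
#' @param truth the `truth` element of [generate_genomes()] output.
#' @return data.frame `genome_id`, `compound`, `can_synthesize` covering
#'   every genome x compound pair.
#' @export
ground_truth_labels <- function(truth) {
  planted <- truth$planted
  data.frame(
    genome_id = rep(rownames(planted), times = ncol(planted)),
    compound = rep(colnames(planted), each = nrow(planted)),
    can_synthesize = !as.vector(planted),
    stringsAsFactors = FALSE
  )
}

#' Generate habitat ASV count tables with planted auxotroph prevalence
#'
#' For each configured habitat, taxa are sampled from the genome pool so
#' that the planted fraction of them are auxotrophs (>= 1 planted
#' auxotrophy). Each taxon's ASV is a 250 nt window of its genome's 16S
#' sequence carrying 0-1 substitutions; a configurable fraction instead
#' carries 3 substitutions and therefore cannot be matched at the
#' 1-mismatch cutoff. Read counts follow log-normal taxon means with
#' per-sample multinomial sampling.
#'
#' @param config a [sim_config()].
#' @param records genome metadata from [generate_genomes()].
#' @param seqs_16S named 16S sequences from [generate_genomes()].
#' @param truth ground truth from [generate_genomes()].
#' @return list with `tables` (named list of [asv_table()]), `references`
#'   (the 16S sequences, to use as the matching reference set) and `truth`
#'   (per-habitat data.frame of planted taxon assignments).
#' @export
generate_asv_dataset <- function(config, records, seqs_16S, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$habitat_specs) == 0L) {
    stop_aux("no habitat specifications configured",
             class = "aux_invalid_config")
  }
  with_seed(stage_seed(config$seed, 3L), {
    n_aux <- truth$n_auxotrophies[records$genome_id]
    aux_pool <- records$genome_id[n_aux >= 1]
    proto_pool <- records$genome_id[n_aux == 0]
    tables <- list()
    truth_rows <- list()
    for (spec in config$habitat_specs) {
      n_a <- round(spec$prevalence * spec$n_taxa)
      n_p <- spec$n_taxa - n_a
      if (n_a > length(aux_pool) || n_p > length(proto_pool)) {
        stop_aux("habitat ", spec$name, " requests more taxa (",
                 n_a, " auxotrophs / ", n_p, " prototrophs) than the ",
                 "genome pool provides", class = "aux_invalid_config")
      }
      taxa <- c(sample(aux_pool, n_a), sample(proto_pool, n_p))
      taxa <- sample(taxa)  # shuffle
      asv_ids <- sprintf("%s_asv%04d", spec$name, seq_along(taxa))
      n_sub <- ifelse(runif(length(taxa)) < spec$unmatched_fraction, 3L,
                      sample(0:1, length(taxa), replace = TRUE))
      seqs <- character(length(taxa))
      for (i in seq_along(taxa)) {
        full <- seqs_16S[[taxa[i]]]
        start <- sample.int(nchar(full) - 250L + 1L, 1)
        win <- strsplit(substr(full, start, start + 249L), "")[[1]]
        if (n_sub[i] > 0L) {
          pos <- sample.int(250L, n_sub[i])
          for (p in pos) {
            win[p] <- sample(setdiff(c("A", "C", "G", "T"), win[p]), 1)
          }
        }
        seqs[i] <- paste0(win, collapse = "")
      }
      names(seqs) <- asv_ids
      means <- rlnorm(length(taxa), spec$meanlog, spec$sdlog)
      counts <- t(vapply(seq_len(spec$n_samples), function(s) {
        as.integer(rmultinom(1, spec$reads_per_sample, prob = means))
      }, integer(length(taxa))))
      dimnames(counts) <- list(sprintf("%s_sample%03d", spec$name,
                                       seq_len(spec$n_samples)), asv_ids)
      tables[[spec$name]] <- asv_table(spec$name, counts, seqs)
      truth_rows[[spec$name]] <- data.frame(
        habitat = spec$name, asv_id = asv_ids, genome_id = taxa,
        n_substitutions = n_sub,
        planted_auxotroph = taxa %in% aux_pool,
        stringsAsFactors = FALSE
      )
    }
    habitat_truth <- do.call(rbind, unname(truth_rows))
    rownames(habitat_truth) <- NULL
    list(tables = tables, references = seqs_16S, truth = habitat_truth)
  })
}

#' Run the full synthetic study
#'
#' Convenience wrapper chaining [generate_pathways()], [generate_genomes()],
#' [generate_asv_dataset()] and [ground_truth_labels()].
#'
#' @param config a [sim_config()].
#' @return list of class `aux_simulation` with elements `config`,
#'   `pathways`, `evidence`, `records`, `cog_counts`, `seqs_16S`, `truth`,
#'   `labels`, `asv`.
#' @export
simulate_study <- function(config = sim_config()) {
  pathways <- generate_pathways(config)
  gen <- generate_genomes(config, pathways)
  asv <- generate_asv_dataset(config, gen$records, gen$seqs_16S, gen$truth)
  structure(list(config = config, pathways = pathways,
                 evidence = gen$evidence, records = gen$records,
                 cog_counts = gen$cog_counts, seqs_16S = gen$seqs_16S,
                 truth = gen$truth, labels = ground_truth_labels(gen$truth),
                 asv = asv),
            class = "aux_simulation")
}

#' @export
print.aux_simulation <- function(x, ...) {
  cat("Synthetic study: ", x$config$n_genomes, " genomes, ",
      length(x$config$compounds), " compounds, ",
      length(x$asv$tables), " habitat(s), seed ", x$config$seed, "\n",
      sep = "")
  invisible(x)
}
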