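# Tabular files are UTF-8 TSV: tab-separated, mandatory header row,
# '#'-prefixed comment lines ignored, '.' decimal point, empty field = NA.
# Percentages live on the 0-100 scale in files; proportions 0-1 in memory.

read_tsv_strict <- function(path) {
  if (!file.exists(path)) {
    stop_aux("file not found: ", path, class = "aux_io_error")
  }
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE,
             na.strings = "")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(path)
}

# coerce named columns to numeric, reporting 1-based data line numbers
# (header excluded) of unparseable fields
coerce_numeric_cols <- function(df, cols, path) {
  for (col in cols) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw) & raw != "")
    if (length(bad) > 0L) {
      stop_aux("malformed numeric field '", col, "' in ", path,
               " at data line(s) ", paste(bad, collapse = ", "),
               class = "aux_parse_error")
    }
    df[[col]] <- num
  }
  df
}

#' Read and write evidence tables
#'
#' TSV with header `genome_id`, `step_id`, `identity`, `coverage`,
#' `bits_pathway`, `bits_other`; an empty `bits_other` field means no
#' alignment to an other-function protein.
#'
#' @param path file path.
#' @return `read_evidence()`: validated evidence data.frame.
#' @export
read_evidence <- function(path) {
  df <- read_tsv_strict(path)
  require_columns(df, c("genome_id", "step_id", "identity", "coverage",
                        "bits_pathway"), paste0("evidence file ", path))
  if (is.null(df$bits_other)) df$bits_other <- NA_real_
  df <- coerce_numeric_cols(df, c("identity", "coverage", "bits_pathway",
                                  "bits_other"), path)
  df
}

#' @rdname read_evidence
#' @param evidence evidence data.frame.
#' @export
write_evidence <- function(evidence, path) {
  evidence <- as_evidence(evidence)
  write_tsv(evidence[, c("genome_id", "step_id", "identity", "coverage",
                         "bits_pathway", "bits_other")], path)
}

#' Read and write auxotrophy profiles
#'
#' Profiles are stored as two TSVs: per genome x compound calls
#' (`genome_id`, `compound`, `missing`, `total`, `missing_fraction`,
#' `auxotrophic`) and a per-genome summary (`genome_id`,
#' `n_auxotrophies`).
#'
#' @param calls_path,summary_path file paths.
#' @param threshold_percent threshold recorded in the object on read.
#' @return `read_profiles()`: an `aux_profiles` object.
#' @export
read_profiles <- function(calls_path, summary_path,
                          threshold_percent = NA_real_) {
  calls <- read_tsv_strict(calls_path)
  require_columns(calls, c("genome_id", "compound", "missing", "total",
                           "missing_fraction", "auxotrophic"),
                  paste0("profile file ", calls_path))
  calls <- coerce_numeric_cols(calls, c("missing", "total",
                                        "missing_fraction"), calls_path)
  calls$auxotrophic <- as.logical(calls$auxotrophic)
  genomes <- read_tsv_strict(summary_path)
  require_columns(genomes, c("genome_id", "n_auxotrophies"),
                  paste0("summary file ", summary_path))
  genomes <- coerce_numeric_cols(genomes, "n_auxotrophies", summary_path)
  genomes$n_auxotrophies <- as.integer(genomes$n_auxotrophies)
  structure(list(calls = calls, genomes = genomes,
                 threshold_percent = threshold_percent),
            class = "aux_profiles")
}

#' @rdname read_profiles
#' @param profiles an `aux_profiles` object.
#' @export
write_profiles <- function(profiles, calls_path, summary_path) {
  stopifnot(inherits(profiles, "aux_profiles"))
  write_tsv(profiles$calls, calls_path)
  write_tsv(profiles$genomes, summary_path)
  invisible(c(calls_path, summary_path))
}

#' Read and write validation label tables
#'
#' TSV with header `genome_id`, `compound`, `can_synthesize` (true/false).
#'
#' @param path file path.
#' @return `read_labels()`: label data.frame.
#' @export
read_labels <- function(path) {
  df <- read_tsv_strict(path)
  require_columns(df, c("genome_id", "compound", "can_synthesize"),
                  paste0("label file ", path))
  val <- tolower(as.character(df$can_synthesize))
  if (any(!val %in% c("true", "false"))) {
    stop_aux("can_synthesize must be true/false in ", path,
             class = "aux_parse_error")
  }
  df$can_synthesize <- val == "true"
  df
}

#' @rdname read_labels
#' @param labels label data.frame.
#' @export
write_labels <- function(labels, path) {
  labels$can_synthesize <- ifelse(labels$can_synthesize, "true", "false")
  write_tsv(labels, path)
}

#' Read and write ASV count matrices
#'
#' TSV with samples as rows: first column `sample_id`, remaining columns one
#' per ASV id, integer read counts.
#'
#' @param path file path.
#' @return `read_asv_counts()`: integer matrix, samples x ASVs.
#' @export
read_asv_counts <- function(path) {
  df <- read_tsv_strict(path)
  require_columns(df, "sample_id", paste0("count file ", path))
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "integer"
  if (anyNA(m)) {
    stop_aux("non-integer counts in ", path, class = "aux_parse_error")
  }
  m
}

#' @rdname read_asv_counts
#' @param counts samples x ASVs matrix.
#' @export
write_asv_counts <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts,
                   stringsAsFactors = FALSE, check.names = FALSE)
  write_tsv(df, path)
}

#' Read and write FASTA sequence files
#'
#' Standard (wrapped or unwrapped) FASTA via Biostrings; sequence names are
#' the first whitespace-delimited token of each header.
#'
#' @param path file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  setNames(as.character(seqs), names(seqs))
}

#' @rdname read_fasta
#' @param seqs named character vector of nucleotide sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 80L)
  invisible(path)
}

#' Read and write genome record tables
#'
#' TSV with header `genome_id`, `origin`, `completeness`, `chimeric`,
#' `has_16S`, `genome_size`, `gene_count`, `phylum`.
#'
#' @param path file path.
#' @return `read_genome_records()`: records data.frame.
#' @export
read_genome_records <- function(path) {
  df <- read_tsv_strict(path)
  require_columns(df, c("genome_id", "origin", "completeness", "chimeric",
                        "has_16S"), paste0("record file ", path))
  df <- coerce_numeric_cols(df, intersect(c("completeness", "genome_size",
                                            "gene_count"), names(df)),
                            path)
  df$chimeric <- as.logical(df$chimeric)
  df$has_16S <- as.logical(df$has_16S)
  df
}

#' @rdname read_genome_records
#' @param records records data.frame.
#' @export
write_genome_records <- function(records, path) {
  write_tsv(records, path)
}

#' Write a run manifest
#'
#' Every pipeline output directory carries exactly one `manifest.json`
#' recording the command, its parameters, MD5 digests of the input files,
#' the seed and threshold in effect, the package version and a timestamp.
#'
#' @param dir output directory.
#' @param command subcommand name.
#' @param params named list of parameters.
#' @param inputs character vector of input file paths to digest.
#' @param seed seed in effect (or `NULL`).
#' @param threshold threshold in effect (or `NULL`).
#' @return the manifest path, invisibly.
#' @export
write_run_manifest <- function(dir, command, params = list(),
                               inputs = character(), seed = NULL,
                               threshold = NULL) {
  digests <- if (length(inputs) > 0L) {
    as.list(setNames(unname(md5sum(inputs)), basename(inputs)))
  } else {
    structure(list(), names = character(0))
  }
  manifest <- list(
    command = command,
    params = params,
    input_digests = digests,
    seed = seed,
    threshold = threshold,
    tool = "auxotrophr",
    version = as.character(packageVersion("auxotrophr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Write a full synthetic study to disk
#'
#' Emits exactly the formats the pipeline consumes: `pathways.json`,
#' `evidence.tsv`, `records.tsv`, `cog_counts.tsv`, `labels.tsv`,
#' `refs_16S.fasta`, per-habitat `<habitat>_counts.tsv` and
#' `<habitat>_asvs.fasta`, plus `ground_truth.json` and a manifest.
#'
#' @param sim an `aux_simulation` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "aux_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    pathways = write_pathways(sim$pathways, file.path(dir, "pathways.json")),
    evidence = write_evidence(sim$evidence, file.path(dir, "evidence.tsv")),
    records = write_genome_records(sim$records,
                                   file.path(dir, "records.tsv")),
    cog = write_tsv(sim$cog_counts, file.path(dir, "cog_counts.tsv")),
    labels = write_labels(sim$labels, file.path(dir, "labels.tsv")),
    refs = write_fasta(sim$seqs_16S, file.path(dir, "refs_16S.fasta"))
  )
  for (tab in sim$asv$tables) {
    paths[paste0(tab$habitat, "_counts")] <-
      write_asv_counts(tab$counts,
                       file.path(dir, paste0(tab$habitat, "_counts.tsv")))
    paths[paste0(tab$habitat, "_asvs")] <-
      write_fasta(tab$asv_seqs,
                  file.path(dir, paste0(tab$habitat, "_asvs.fasta")))
  }
  truth <- list(
    planted = apply(sim$truth$planted, 1, function(row) {
      as.list(colnames(sim$truth$planted)[row])
    }),
    n_auxotrophies = as.list(sim$truth$n_auxotrophies),
    enriched_categories = sim$truth$enriched_categories,
    size_model = sim$truth$size_model,
    habitat = sim$asv$truth
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  paths["ground_truth"] <- file.path(dir, "ground_truth.json")
  write_run_manifest(dir, "simulate",
                     params = list(n_genomes = sim$config$n_genomes,
                                   auxotrophy_rate =
                                     sim$config$auxotrophy_rate),
                     seed = sim$config$seed)
  invisible(paths)
}
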