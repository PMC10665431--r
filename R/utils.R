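# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `code`, and restores the caller's
#' RNG state afterwards, so seeded generators never perturb user randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# deterministic per-stage sub-seed, kept within 32-bit integer range
stage_seed <- function(seed, stage) {
  (abs(as.integer(seed)) + 1000003L * as.integer(stage)) %% 2147483629L
}

stop_aux <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "auxotrophr_error")))
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_aux(what, " is missing required field(s): ",
             paste(missing, collapse = ", "),
             class = "aux_missing_field")
  }
  invisible(df)
}

is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == floor(x))
}
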