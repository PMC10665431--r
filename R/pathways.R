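#' Build a pathway definition
#'
#' A pathway definition models the biosynthesis of one compound as one or
#' more alternative routes, each an ordered set of enzymatic step
#' identifiers. A compound is scored against the route that is most complete
#' in a genome.
#'
#' @param compound one of [aux_compounds()].
#' @param routes non-empty list of non-empty character vectors of step ids;
#'   step ids must be unique within a route.
#' @return list of class `aux_pathway` with elements `compound`, `routes`.
#' @examples
#' pathway_definition("tryptophan", list(c("trpA", "trpB", "trpC")))
#' @export
pathway_definition <- function(compound, routes) {
  as_compound(compound)
  if (length(compound) != 1L) {
    stop_aux("compound must be a single name", class = "aux_invalid_pathway")
  }
  if (!is.list(routes) || length(routes) == 0L) {
    stop_aux("pathway for ", compound, " must have at least one route",
             class = "aux_invalid_pathway")
  }
  for (r in routes) {
    if (!is.character(r) || length(r) == 0L) {
      stop_aux("every route of ", compound, " must be a non-empty ",
               "character vector", class = "aux_invalid_pathway")
    }
    if (anyDuplicated(r)) {
      stop_aux("duplicate step id within a route of ", compound,
               class = "aux_invalid_pathway")
    }
  }
  structure(list(compound = compound, routes = unname(routes)),
            class = "aux_pathway")
}

#' Validate a pathway database
#'
#' @param db list of [pathway_definition()] objects.
#' @param complete when `TRUE`, require that all 18 modeled compounds are
#'   present exactly once (the contract for genome profiling).
#' @return `db`, invisibly.
#' @export
validate_pathway_db <- function(db, complete = FALSE) {
  if (!is.list(db) || length(db) == 0L) {
    stop_aux("pathway database is empty", class = "aux_invalid_pathway")
  }
  compounds <- vapply(db, function(p) p$compound, character(1))
  if (anyDuplicated(compounds)) {
    stop_aux("duplicate pathway for compound(s): ",
             paste(unique(compounds[duplicated(compounds)]), collapse = ", "),
             class = "aux_invalid_pathway")
  }
  if (complete) {
    missing <- setdiff(aux_compounds(), compounds)
    if (length(missing) > 0L) {
      stop_aux("pathway database lacks compound(s): ",
               paste(missing, collapse = ", "),
               class = "aux_invalid_pathway")
    }
  }
  invisible(db)
}

#' Read / write pathway definitions as JSON
#'
#' The on-disk format is a JSON array of objects
#' `{"compound": name, "routes": [[step, ...], ...]}`; definitions are
#' validated on load.
#'
#' @param path file path.
#' @return `read_pathways()` returns a named list of `aux_pathway` objects.
#' @export
read_pathways <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  db <- lapply(raw, function(p) {
    routes <- lapply(p$routes, function(r) unlist(r, use.names = FALSE))
    pathway_definition(p$compound, routes)
  })
  names(db) <- vapply(db, function(p) p$compound, character(1))
  validate_pathway_db(db)
  db
}

#' @rdname read_pathways
#' @param db pathway database (named list of `aux_pathway`).
#' @export
write_pathways <- function(db, path) {
  validate_pathway_db(db)
  out <- lapply(unname(db), function(p) {
    list(compound = p$compound, routes = lapply(p$routes, as.list))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# long table (compound, route, step_id, route_len) used by the vectorised
# profiler; route index preserves the order routes were listed in
pathway_route_table <- function(db) {
  rows <- lapply(unname(db), function(p) {
    lens <- lengths(p$routes)
    data.frame(
      compound = p$compound,
      route = rep(seq_along(p$routes), lens),
      step_id = unlist(p$routes, use.names = FALSE),
      route_len = rep(lens, lens),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
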