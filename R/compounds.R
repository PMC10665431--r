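#' The modeled biosynthesis compounds
#'
#' The pipeline models biosynthesis of 17 amino acids plus chorismate, the
#' precursor of the aromatic amino acids. Alanine, aspartate and glutamate
#' are excluded because they arise by transamination of central-metabolism
#' intermediates, whose substrate annotation is unreliable.
#'
#' @return Character vector of the 18 valid compound names.
#' @examples
#' aux_compounds()
#' @export
aux_compounds <- function() {
  c("arginine", "asparagine", "cysteine", "glutamine", "glycine",
    "histidine", "isoleucine", "leucine", "lysine", "methionine",
    "phenylalanine", "proline", "serine", "threonine", "tryptophan",
    "tyrosine", "valine", "chorismate")
}

#' Validate compound names
#'
#' @param compound character vector of compound names.
#' @return `compound`, invisibly, if all values are modeled compounds.
#' @examples
#' as_compound("tryptophan")
#' @export
as_compound <- function(compound) {
  bad <- setdiff(unique(compound), aux_compounds())
  if (length(bad) > 0L) {
    stop_aux("not modeled compound(s): ", paste(bad, collapse = ", "),
             class = "aux_invalid_compound")
  }
  compound
}

#' Amino acid biosynthetic cost table
#'
#' Energetic cost of synthesising one molecule of each amino acid, expressed
#' as high-energy phosphate bonds (P-bonds), after Akashi and Gojobori's
#' estimates for Escherichia coli / Bacillus subtilis metabolism. Chorismate
#' has no published P-bond cost and is therefore not included; cost-based
#' correlations run over the 17 amino acids unless a custom table is given.
#'
#' @param path optional path to a TSV with columns `compound` and `p_bonds`
#'   overriding the shipped constants.
#' @return data.frame with columns `compound`, `p_bonds`.
#' @examples
#' head(amino_acid_costs())
#' @export
amino_acid_costs <- function(path = NULL) {
  if (!is.null(path)) {
    tab <- read_tsv_strict(path)
    require_columns(tab, c("compound", "p_bonds"), "cost table")
    as_compound(tab$compound)
    if (any(!is.finite(tab$p_bonds)) || any(tab$p_bonds <= 0)) {
      stop_aux("p_bonds must be positive and finite",
               class = "aux_invalid_cost")
    }
    return(tab[, c("compound", "p_bonds")])
  }
  data.frame(
    compound = c("arginine", "asparagine", "cysteine", "glutamine",
                 "glycine", "histidine", "isoleucine", "leucine", "lysine",
                 "methionine", "phenylalanine", "proline", "serine",
                 "threonine", "tryptophan", "tyrosine", "valine"),
    p_bonds = c(27.3, 14.7, 24.7, 16.3, 11.7, 38.3, 32.3, 27.3, 30.3,
                34.3, 52.0, 20.3, 11.7, 18.7, 74.3, 50.0, 23.3),
    stringsAsFactors = FALSE
  )
}
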