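# SMILES handling and the organophosphate/carbamate substructure filters.
# Matching is delegated to OpenBabel's SMARTS engine via ChemmineOB; results
# are memoised per unique SMILES because annotation tables repeat structures.

#' SMARTS patterns of the organophosphate/carbamate filter
#'
#' In `literal` mode the patterns are the decision-tree substructures
#' exactly as written: phosphate `O=P(-O-R1)(-O-R2)-O-R3` and carbamate
#' `R1-O-C(=O)-N(-R1)-R2`, every R a non-hydrogen substituent. The
#' `relaxed` mode widens them to the thio analogues (P=S, and S-linked
#' substituents on phosphorus) and to carbamates with a single N-H;
#' pesticide sets contain both kinds (e.g. dimethoate, chlorpropham)
#' even though the literal patterns miss them.
#'
#' @param mode `"literal"` (default) or `"relaxed"`.
#' @return Named character vector with elements `phosphate` and
#'   `carbamate` holding SMARTS strings.
#' @export
#' @examples
#' op_carbamate_patterns("literal")
op_carbamate_patterns <- function(mode = c("literal", "relaxed")) {
  mode <- match.arg(mode)
  switch(mode,
    literal = c(
      phosphate = "[OX1]=P([OX2][!#1])([OX2][!#1])[OX2][!#1]",
      carbamate = "[!#1][OX2]C(=O)N([!#1])[!#1]"
    ),
    relaxed = c(
      phosphate = "[OX1,SX1]=P([OX2,SX2][!#1])([OX2,SX2][!#1])[OX2,SX2][!#1]",
      carbamate = "[!#1][OX2]C(=O)[#7][!#1]"
    )
  )
}

# Count unique SMARTS matches in one parsed molecule; NA_integer_ if the
# SMILES does not parse.
count_smarts <- function(smiles, smarts) {
  tryCatch(
    ChemmineOB::forEachMol("SMILES", smiles, function(mol) {
      ChemmineOB::smartsSearch_OB(list(mol), smarts, uniqueMatches = TRUE)
    })[[1]],
    error = function(e) NA_integer_
  )
}

#' Check SMILES strings for parseability
#'
#' @param smiles Character vector (NA allowed, reported as `FALSE`).
#' @return Logical vector: does each string parse to a molecule?
#' @export
#' @examples
#' is_valid_smiles(c("CCO", "C1CC", NA))
is_valid_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    ok <- tryCatch({
      ChemmineOB::forEachMol("SMILES", s, function(mol) TRUE)[[1]]
    }, error = function(e) FALSE)
    isTRUE(ok)
  }, logical(1), USE.NAMES = FALSE)
}

#' Match the phosphate and carbamate substructures
#'
#' Applies the two decision-tree patterns (see
#' [op_carbamate_patterns()]) to each structure. Matching is memoised
#' per unique SMILES, so large annotation tables with repeated
#' representative structures pay one OpenBabel call per structure and
#' pattern.
#'
#' @param smiles Character vector of valid SMILES.
#' @param mode `"literal"` or `"relaxed"`.
#' @return Tibble with columns `smiles`, `phosphate_hit`,
#'   `carbamate_hit` (logical), one row per input element.
#' @export
#' @examples
#' match_op_carbamate(c("CCOP(=O)(OCC)OCC", "CCO"))
match_op_carbamate <- function(smiles, mode = c("literal", "relaxed")) {
  mode <- match.arg(mode)
  pats <- op_carbamate_patterns(mode)
  uniq <- unique(smiles)
  bad <- uniq[!is_valid_smiles(uniq)]
  if (length(bad) > 0L) {
    stop("invalid SMILES: ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  hits <- vapply(uniq, function(s) {
    c(phosphate = count_smarts(s, pats[["phosphate"]]) > 0L,
      carbamate = count_smarts(s, pats[["carbamate"]]) > 0L)
  }, logical(2))
  idx <- match(smiles, uniq)
  tibble::tibble(
    smiles = smiles,
    phosphate_hit = unname(hits["phosphate", idx]),
    carbamate_hit = unname(hits["carbamate", idx])
  )
}
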