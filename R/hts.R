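# Cross-assay normalization of heterogeneous HTS readouts to 0-100 potency
# scores (most potent per dataset = 100) and the substance x model matrix.

#' Transform a raw readout to a monotone potency scale
#'
#' Composite scores and percentages are already monotone in potency and
#' pass through unchanged. Concentration readouts (AC50, LEL; uM) are
#' log-transformed as `-log10(value)` so that lower concentrations mean
#' higher potency. Ranks over `n_active` actives reverse to
#' `n_active - rank + 1` so rank 1 (most potent) maps to the largest
#' potency.
#'
#' @param value Raw readout values.
#' @param readout_type One of `composite_score`, `percent`, `ac50`,
#'   `rank`, `lel` (scalar, applies to the whole vector).
#' @param n_active Number of actives in the model; required for `rank`.
#' @return Numeric potency vector, strictly monotone in toxicological
#'   potency.
#' @export
#' @examples
#' potency_transform(0.1, "ac50")     # 1
#' potency_transform(1, "rank", 20)   # 20
potency_transform <- function(value, readout_type, n_active = NULL) {
  stopifnot(readout_type %in% readout_types)
  switch(readout_type,
    composite_score = ,
    percent = value,
    ac50 = ,
    lel = {
      if (any(value <= 0)) stop("concentration readouts must be > 0", call. = FALSE)
      -log10(value)
    },
    rank = {
      if (is.null(n_active)) stop("rank transform needs n_active", call. = FALSE)
      n_active - value + 1
    }
  )
}

#' Normalize potencies within one model dataset
#'
#' Min-max scaling of the actives' potencies to `[0, 100]`, anchoring
#' the most potent substance at exactly 100. With a single active, or
#' all potencies equal, every score is 100 (the most-potent anchor is
#' the only constraint the scale imposes).
#'
#' @param potency Potency values of the actives of one model.
#' @return Normalized scores in `[0, 100]`.
#' @export
#' @examples
#' normalize_dataset(c(1, -1, -3))  # 100 50 0
normalize_dataset <- function(potency) {
  if (length(potency) == 0L) stop("no active substances to normalize", call. = FALSE)
  rng <- range(potency)
  if (rng[1] == rng[2]) return(rep(100, length(potency)))
  # ratio first: (p - min)/(max - min) <= 1 exactly in floating point
  100 * pmin((potency - rng[1]) / (rng[2] - rng[1]), 1)
}

#' Normalize a stack of raw HTS tables
#'
#' Applies [potency_transform()] and [normalize_dataset()] per model.
#' Inactive and untested records are carried through without scores —
#' "not active" is an observed negative, "not tested" is absence of
#' data, and the two are never conflated.
#'
#' @param hts Validated raw HTS tibble (possibly several models).
#' @return Tibble `model_id, substance_code, readout_type, value,
#'   status, potency, normalized`.
#' @export
normalize_hts <- function(hts) {
  hts <- validate_hts(hts)
  dplyr::bind_rows(lapply(split(hts, hts$model_id), function(tbl) {
    active <- tbl$status == "active"
    tbl$potency <- NA_real_
    tbl$normalized <- NA_real_
    if (any(active)) {
      rt <- unique(tbl$readout_type[active])
      stopifnot(length(rt) == 1L)
      pot <- potency_transform(tbl$value[active], rt, n_active = sum(active))
      tbl$potency[active] <- pot
      tbl$normalized[active] <- normalize_dataset(pot)
    }
    tbl
  }))
}

#' Assemble the substance x model potency matrix
#'
#' One row per prioritized substance (in screening order: TTC
#' ascending, then HQ descending), one column per model, columns
#' grouped by toxicological domain (E endocrine, M metabolic, D
#' developmental, C cancer-related, H hepatotoxicity). Cells carry the
#' normalized score, `"not_active"`, or `"not_tested"`; substances
#' absent from every model are flagged — lack of HTS coverage is
#' reported, not hidden.
#'
#' @param scores Normalized scores from [normalize_hts()].
#' @param selection Ordered screening selection from
#'   [select_for_screening()] (or any tibble with `substance_code` in
#'   the desired row order).
#' @param domain_map Tibble `model_id, domain` covering every model in
#'   `scores`.
#' @param digits Rounding applied to displayed scores.
#' @return Tibble with `substance_code`, `no_hts_data` (logical) and one
#'   character column per model, named `domain.model_id`.
#' @export
assemble_matrix <- function(scores, selection, domain_map, digits = 1) {
  unknown <- setdiff(unique(scores$model_id), domain_map$model_id)
  if (length(unknown) > 0L) {
    stop("models missing from domain map: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  domain_map <- domain_map[order(domain_map$domain, domain_map$model_id), ]
  models <- domain_map$model_id[domain_map$model_id %in% unique(scores$model_id)]
  out <- tibble::tibble(substance_code = selection$substance_code)
  covered <- rep(FALSE, nrow(out))
  for (m in models) {
    sub <- scores[scores$model_id == m, ]
    idx <- match(out$substance_code, sub$substance_code)
    status <- sub$status[idx]
    status[is.na(status)] <- "not_tested"  # absent from the model's table
    cell <- ifelse(status == "active",
                   formatC(sub$normalized[idx], format = "f", digits = digits),
                   status)
    covered <- covered | status != "not_tested"
    dom <- domain_map$domain[domain_map$model_id == m]
    out[[paste(dom, m, sep = ".")]] <- cell
  }
  out$no_hts_data <- !covered
  out[, c("substance_code", "no_hts_data", setdiff(names(out), c("substance_code", "no_hts_data")))]
}
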