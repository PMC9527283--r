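# Independent oracles, deliberately written without reusing package internals:
# a brute-force re-statement of the four decision-tree steps, a molecular-graph
# substructure matcher built on ChemmineR atom/bond tables (not OpenBabel's
# SMARTS engine), and a nested-loop exposure calculator.

# Brute-force decision tree. Inputs are primitive: `excluded` flag, the six
# alert booleans, the substructure state as a label (so the oracle is
# independent of any pattern matching), and the Cramer class.
oracle_ttc <- function(excluded, ames, ca, substructure, cramer) {
  if (excluded) return(list(outcome = "excluded", value = NA_real_))
  n_ames <- 0; n_ca <- 0
  for (i in 1:3) {
    if (ames[i]) n_ames <- n_ames + 1
    if (ca[i]) n_ca <- n_ca + 1
  }
  if (n_ames >= 2 || n_ca >= 2) {
    return(list(outcome = "ttc_assigned", value = 0.0025))
  }
  if (substructure %in% c("phosphate", "carbamate")) {
    return(list(outcome = "ttc_assigned", value = 0.3))
  }
  value <- c(I = 30, II = 9, III = 1.5)[[cramer]]
  list(outcome = "ttc_assigned", value = value)
}

# --- molecular-graph matcher -------------------------------------------------

# Parse a SMILES into (atoms, bonds) via ChemmineR; hydrogens are implicit so
# every graph neighbor is a heavy ("non-hydrogen") substituent.
mol_graph <- function(smiles) {
  sdf <- ChemmineR::smiles2sdf(smiles)[[1]]
  atoms <- sub("_.*$", "", rownames(ChemmineR::atomblock(sdf)))
  bb <- ChemmineR::bondblock(sdf)
  bonds <- data.frame(a1 = bb[, 1], a2 = bb[, 2], order = bb[, 3])
  list(atoms = atoms, bonds = bonds)
}

graph_neighbors <- function(g, i) {
  hit <- g$bonds$a1 == i | g$bonds$a2 == i
  data.frame(
    atom = ifelse(g$bonds$a1[hit] == i, g$bonds$a2[hit], g$bonds$a1[hit]),
    order = g$bonds$order[hit]
  )
}

# Phosphate: P with a double-bonded O (literal) or O/S (relaxed), plus three
# single-bonded O (literal) or O/S (relaxed) linkers each bearing a further
# heavy substituent.
graph_phosphate <- function(g, mode) {
  linker_ok <- if (mode == "literal") "O" else c("O", "S")
  for (p in which(g$atoms == "P")) {
    nb <- graph_neighbors(g, p)
    dbl <- nb$atom[nb$order == 2 & g$atoms[nb$atom] %in% linker_ok]
    if (length(dbl) == 0) next
    linkers <- nb$atom[nb$order == 1 & g$atoms[nb$atom] %in% linker_ok]
    substituted <- 0
    for (l in linkers) {
      others <- graph_neighbors(g, l)
      if (any(others$atom != p)) substituted <- substituted + 1
    }
    if (substituted >= 3) return(TRUE)
  }
  FALSE
}

# Carbamate: C(=O) with a single-bonded O bearing a further heavy substituent
# and a single-bonded N with >= 2 (literal) or >= 1 (relaxed) heavy
# substituents besides the carbonyl carbon.
graph_carbamate <- function(g, mode) {
  need_n_subst <- if (mode == "literal") 2 else 1
  for (cc in which(g$atoms == "C")) {
    nb <- graph_neighbors(g, cc)
    if (!any(nb$order == 2 & g$atoms[nb$atom] == "O")) next
    esters <- nb$atom[nb$order == 1 & g$atoms[nb$atom] == "O"]
    amides <- nb$atom[nb$order == 1 & g$atoms[nb$atom] == "N"]
    ester_ok <- FALSE
    for (o in esters) {
      if (any(graph_neighbors(g, o)$atom != cc)) ester_ok <- TRUE
    }
    if (!ester_ok) next
    for (n in amides) {
      others <- graph_neighbors(g, n)
      if (sum(others$atom != cc) >= need_n_subst) return(TRUE)
    }
  }
  FALSE
}

oracle_match <- function(smiles, mode = "literal") {
  g <- mol_graph(smiles)
  list(phosphate = graph_phosphate(g, mode),
       carbamate = graph_carbamate(g, mode))
}

# --- nested-loop exposure oracle ---------------------------------------------

# Per-subject OIM for one substance, by explicit loops over subjects, days,
# diary rows, translation entries and concentration samples.
oracle_oim <- function(substance, consumption, concentrations, translation,
                       scenario) {
  conc_of <- function(commodity) {
    rows <- concentrations[concentrations$substance_code == substance &
                             concentrations$commodity_code == commodity, ]
    if (nrow(rows) == 0) return(NA_real_)
    vals <- numeric(0)
    for (r in seq_len(nrow(rows))) {
      v <- if (rows$result_type[r] == "VAL") {
        rows$value[r]
      } else if (scenario == "lower_bound") {
        0
      } else if (rows$result_type[r] == "ND_LOD") {
        rows$lod[r]
      } else {
        rows$loq[r]
      }
      vals <- c(vals, v)
    }
    mean(vals)
  }
  subjects <- unique(consumption$subject_id)
  out <- numeric(length(subjects))
  for (si in seq_along(subjects)) {
    rows_s <- consumption[consumption$subject_id == subjects[si], ]
    days <- unique(rows_s$day)
    day_intakes <- numeric(0)
    for (d in days) {
      rows_d <- rows_s[rows_s$day == d, ]
      intake <- 0
      for (r in seq_len(nrow(rows_d))) {
        tr <- translation[translation$food_code == rows_d$food_code[r], ]
        for (t in seq_len(nrow(tr))) {
          conc <- conc_of(tr$commodity_code[t])
          if (!is.na(conc)) {
            grams <- rows_d$amount[r] * tr$percent[t] / 100
            intake <- intake + grams * conc / rows_d$body_weight[r]
          }
        }
      }
      day_intakes <- c(day_intakes, intake)
    }
    out[si] <- sum(day_intakes) / length(day_intakes)
  }
  stats::setNames(out, subjects)
}

# Weighted mean by explicit loop (for cross-checking summaries).
oracle_weighted_mean <- function(x, w) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + w[i] * x[i]
    den <- den + w[i]
  }
  num / den
}
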