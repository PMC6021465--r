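#' Construct a proton-transfer reaction
#'
#' Reactions are written in the convention where the two neutral parents
#' are the reactants and an anion/cation pair are the products, e.g.
#' `G + P = G1- + P+`. A declaration in the reverse direction is inverted
#' on ingestion (stoichiometry negated, K inverted, dG negated). Each
#' reaction must conserve charge and, per parent compound, mass.
#'
#' @param reaction_id identifier (e.g. `"K1"`).
#' @param stoich named integer vector of coefficients over form ids;
#'   reactants negative, products positive.
#' @param forms `ionic_forms` table covering every participating form
#'   (supplies charges and parents for the conservation checks).
#' @param dG standard reaction free energy, kcal/mol (or `NA`).
#' @param K equilibrium constant (or `NA`). At least one of `dG`, `K`
#'   must be given; when both are, they must agree through
#'   K = exp(-dG/RT) within `consistency_tol` (relative, on K).
#' @param cond [thermo_conditions()] used for the dG/K conversion.
#' @param consistency_tol relative tolerance for the dG/K agreement check.
#' @return An object of class `nades_reaction` with fields `reaction_id`,
#'   `stoich`, `dG`, `K` (both always populated after construction).
#' @export
reaction <- function(reaction_id, stoich, forms, dG = NA_real_, K = NA_real_,
                     cond = thermo_conditions(), consistency_tol = 0.005) {
  stopifnot(is.character(reaction_id), length(reaction_id) == 1L,
            is.numeric(stoich), !is.null(names(stoich)),
            inherits(forms, "data.frame"))
  if (any(stoich != round(stoich))) stop("stoichiometric coefficients must be integers")
  stoich <- stats::setNames(as.integer(stoich), names(stoich))
  stoich <- stoich[stoich != 0L]
  if (length(stoich) == 0L) stop("empty stoichiometry")
  missing <- setdiff(names(stoich), forms$form_id)
  if (length(missing))
    stop("reaction ", reaction_id, " references unknown form(s): ",
         paste(missing, collapse = ", "))
  idx <- match(names(stoich), forms$form_id)
  charge <- forms$charge[idx]
  parent <- forms$parent[idx]

  dG <- as.numeric(dG); K <- as.numeric(K)
  if (is.na(dG) && is.na(K))
    stop("reaction ", reaction_id, ": at least one of dG, K must be given")
  if (!is.na(K) && K <= 0) stop("reaction ", reaction_id, ": K must be > 0")

  # direction convention: neutrals are reactants
  neutral_side <- sum(stoich[charge == 0L])
  if (neutral_side > 0L) {
    stoich <- -stoich
    if (!is.na(K)) K <- 1 / K
    if (!is.na(dG)) dG <- -dG
  }

  if (sum(stoich * charge) != 0L)
    stop("reaction ", reaction_id, " violates charge conservation")
  for (p in unique(parent))
    if (sum(stoich[parent == p]) != 0L)
      stop("reaction ", reaction_id, " violates mass conservation for parent ", p)

  if (!is.na(dG) && !is.na(K)) {
    if (abs(equilibrium_constant(dG, cond) / K - 1) > consistency_tol)
      stop(sprintf("reaction %s: dG = %g kcal/mol and K = %g disagree beyond %.2g relative",
                   reaction_id, dG, K, consistency_tol))
  } else if (is.na(K)) {
    K <- equilibrium_constant(dG, cond)
  } else {
    dG <- gibbs_from_K(K, cond)
  }

  structure(list(reaction_id = reaction_id, stoich = stoich, dG = dG, K = K),
            class = "nades_reaction")
}

#' @export
print.nades_reaction <- function(x, ...) {
  lhs <- names(x$stoich)[x$stoich < 0]
  rhs <- names(x$stoich)[x$stoich > 0]
  cat(sprintf("%s: %s = %s   K = %.4g  (dG = %.3f kcal/mol)\n", x$reaction_id,
              paste(lhs, collapse = " + "), paste(rhs, collapse = " + "),
              x$K, x$dG))
  invisible(x)
}

#' Enumerate the proton-transfer reactions of a binary NADES
#'
#' For each (anion of one parent, cation of the other parent) pair, one
#' reaction `neutral + neutral = anion + cation` is generated. Reactions
#' carry no K until one is assigned (via `K_values` or downstream from a
#' reaction table); reaction ids are `K1`, `K2`, ... in enumeration order
#' (anions of the acid x cations of the amino acid first, then anions of
#' the amino acid x cations of the acid).
#'
#' @param acid_forms,amino_forms `ionic_forms` tables of the two parents;
#'   each must contain its neutral parent form.
#' @param K_values optional numeric vector of equilibrium constants, one
#'   per enumerated reaction (recycled errors are not allowed).
#' @param cond [thermo_conditions()].
#' @return List of [reaction()] objects (with `K = NA` placeholders kept
#'   as plain skeletons when `K_values` is absent).
#' @export
enumerate_reactions <- function(acid_forms, amino_forms, K_values = NULL,
                                cond = thermo_conditions()) {
  for (ftab in list(acid_forms, amino_forms)) {
    if (!any(ftab$charge == 0L))
      stop("missing neutral parent form in one of the form tables")
    if (length(unique(ftab$parent)) != 1L)
      stop("each form table must belong to a single parent compound")
  }
  forms <- bind_forms(acid_forms, amino_forms)
  pair_stoich <- function(an_tab, cat_tab) {
    an_neutral <- an_tab$form_id[an_tab$charge == 0L]
    cat_neutral <- cat_tab$form_id[cat_tab$charge == 0L]
    anions <- an_tab$form_id[an_tab$charge == -1L]
    cations <- cat_tab$form_id[cat_tab$charge == 1L]
    out <- list()
    for (a in anions) for (c_ in cations)
      out[[length(out) + 1L]] <- stats::setNames(
        c(-1L, -1L, 1L, 1L), c(an_neutral, cat_neutral, a, c_))
    out
  }
  stoichs <- c(pair_stoich(acid_forms, amino_forms),
               pair_stoich(amino_forms, acid_forms))
  if (!is.null(K_values) && length(K_values) != length(stoichs))
    stop(sprintf("expected %d K values for %d enumerated reactions, got %d",
                 length(stoichs), length(stoichs), length(K_values)))
  lapply(seq_along(stoichs), function(j)
    reaction(paste0("K", j), stoichs[[j]], forms,
             K = if (is.null(K_values)) 1 else K_values[j], cond = cond))
}

#' Read a reaction table from CSV
#'
#' Columns: `reaction_id`, `stoichiometry` (signed tokens, e.g.
#' `"-1 G -1 P +1 G1- +1 P+"`), `dG_kcal`, `K` (either may be blank).
#'
#' @param path CSV file path.
#' @param forms `ionic_forms` table covering all participating forms.
#' @param cond [thermo_conditions()].
#' @return List of [reaction()] objects.
#' @seealso [nades_example_reactions()] for the packaged glutamic
#'   acid-proline system.
#' @export
read_reaction_table <- function(path, forms, cond = thermo_conditions()) {
  stopifnot(file.exists(path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "stoichiometry")
  if (!all(need %in% names(tab)))
    stop("reaction table must have columns reaction_id, stoichiometry")
  lapply(seq_len(nrow(tab)), function(i) {
    toks <- strsplit(trimws(tab$stoichiometry[i]), "\\s+")[[1]]
    if (length(toks) %% 2L != 0L)
      stop("bad stoichiometry string: ", tab$stoichiometry[i])
    co <- as.integer(toks[seq(1, length(toks), 2)])
    id <- toks[seq(2, length(toks), 2)]
    reaction(as.character(tab$reaction_id[i]), stats::setNames(co, id), forms,
             dG = if ("dG_kcal" %in% names(tab)) tab$dG_kcal[i] else NA_real_,
             K = if ("K" %in% names(tab)) tab$K[i] else NA_real_,
             cond = cond)
  })
}

#' Packaged glutamic acid-proline reaction system
#'
#' The three proton-transfer equilibria of the glutamic acid (G) /
#' proline (P) reference NADES with their equilibrium constants
#' (K1 = 1.62e5, K2 = 1.02e4, K3 = 6.17e2); free energies are derived
#' from K at 298.15 K.
#'
#' @return List with elements `compounds` (the two [compound()]s),
#'   `forms` (their bound `ionic_forms`), and `reactions`.
#' @export
nades_example_reactions <- function() {
  lib <- nades_compound_library()
  glu <- enumerate_ionic_forms(lib[["7"]], prefix = "G")
  pro <- enumerate_ionic_forms(lib[["A"]], prefix = "P")
  forms <- bind_forms(glu, pro)
  rxn <- read_reaction_table(system.file("extdata", "reactions_glu_pro.csv",
                                         package = "nadescreen", mustWork = TRUE),
                             forms)
  list(compounds = lib[c("7", "A")], forms = forms, reactions = rxn)
}
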