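#' @title NADES components and their ionic forms
#' @description Constructors and validators for the building blocks of a
#'   binary NADES: a compound (carboxylic acid or amino acid) with its
#'   declared ionizable sites, and the neutral/singly-ionized forms it can
#'   adopt in the liquid.
#' @name compounds
NULL

.inchikey_pattern <- "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"

#' Declare an ionizable site
#'
#' @param label short site label (e.g. `"COOH-1"`, `"NH2"`).
#' @param kind `"acidic"` (proton donor) or `"basic"` (proton acceptor).
#' @param micro_pKa optional site microacidity; must lie in (-5, 20) when
#'   given. Micro-pKa values are inputs (e.g. from an external predictor),
#'   never computed here.
#' @return A list of class `ionizable_site`.
#' @export
ionizable_site <- function(label, kind = c("acidic", "basic"), micro_pKa = NA_real_) {
  kind <- match.arg(kind)
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  micro_pKa <- as.numeric(micro_pKa)
  stopifnot(length(micro_pKa) == 1L)
  if (!is.na(micro_pKa) && (micro_pKa <= -5 || micro_pKa >= 20))
    stop(sprintf("micro_pKa %g for site '%s' outside the plausible (-5, 20) range", micro_pKa, label))
  structure(list(label = label, kind = kind, micro_pKa = micro_pKa),
            class = "ionizable_site")
}

#' Define a NADES component
#'
#' A component is either a carboxylic acid (at least two acidic sites;
#' amino-substituted diacids may also carry basic sites) or an amino acid
#' (at least one acidic and one basic site). Site declarations drive the
#' enumeration of ionic forms; nothing is inferred from structure.
#'
#' @param code short identifier, unique within a library (e.g. `"7"`, `"A"`).
#' @param name compound name.
#' @param inchikey 27-character uppercase InChIKey
#'   (`XXXXXXXXXXXXXX-XXXXXXXXXX-X`).
#' @param role `"carboxylic_acid"` or `"amino_acid"`.
#' @param sites list of [ionizable_site()] objects.
#' @return An object of class `nades_compound`.
#' @examples
#' glu <- compound("7", "Glutamic acid", "WHUUTDBJXJRKMK-UHFFFAOYSA-N",
#'                 "carboxylic_acid",
#'                 list(ionizable_site("COOH-a", "acidic", 2.16),
#'                      ionizable_site("COOH-g", "acidic", 4.15),
#'                      ionizable_site("NH2", "basic", 9.58)))
#' @export
compound <- function(code, name, inchikey,
                     role = c("carboxylic_acid", "amino_acid"), sites) {
  role <- match.arg(role)
  stopifnot(is.character(code), length(code) == 1L, nzchar(code),
            is.character(name), length(name) == 1L,
            is.character(inchikey), length(inchikey) == 1L)
  if (!grepl(.inchikey_pattern, inchikey))
    stop(sprintf("'%s' is not a valid InChIKey for compound %s", inchikey, code))
  if (!is.list(sites) || !all(vapply(sites, inherits, logical(1), "ionizable_site")))
    stop("sites must be a list of ionizable_site objects")
  kinds <- vapply(sites, `[[`, character(1), "kind")
  n_acid <- sum(kinds == "acidic"); n_base <- sum(kinds == "basic")
  if (role == "carboxylic_acid" && n_acid < 2)
    stop(sprintf("carboxylic acid '%s' must declare at least two acidic sites", code))
  if (role == "amino_acid" && (n_acid < 1 || n_base < 1))
    stop(sprintf("amino acid '%s' must declare at least one acidic and one basic site", code))
  labels <- vapply(sites, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("site labels must be unique within a compound")
  structure(list(code = code, name = name, inchikey = inchikey,
                 role = role, sites = sites),
            class = "nades_compound")
}

#' @export
print.nades_compound <- function(x, ...) {
  kinds <- vapply(x$sites, `[[`, character(1), "kind")
  cat(sprintf("<%s> %s (%s), %d acidic / %d basic site(s)\n",
              x$code, x$name, sub("_", " ", x$role),
              sum(kinds == "acidic"), sum(kinds == "basic")))
  invisible(x)
}

#' Enumerate the neutral and singly charged ionic forms of a compound
#'
#' Returns the neutral form plus one singly charged form per declared
#' site: an anion per acidic site (deprotonation) and a cation per basic
#' site (protonation). Multiply charged forms are never auto-enumerated;
#' only single proton-transfer events between the two parents of a binary
#' NADES are modelled, so each parent appears at charge -1, 0, or +1.
#'
#' Form identifiers follow the field's shorthand: the parent code for the
#' neutral form, `code1-`, `code2-`, ... for anions (numbered when the
#' parent has several acidic sites), `code+` (or `code1+`, ...) for
#' cations. Glutamic acid with two distinct carboxyls and one amine thus
#' yields four forms; proline yields three.
#'
#' @param comp a [compound()].
#' @param prefix label stem for form ids; defaults to the compound code.
#'   The reference glutamic acid-proline system uses `"G"` and `"P"`.
#' @return A data frame of class `ionic_forms` with columns `form_id`,
#'   `parent`, `charge`, `site`, `profile_ref` (NA placeholder).
#' @export
enumerate_ionic_forms <- function(comp, prefix = comp$code) {
  stopifnot(inherits(comp, "nades_compound"))
  if (length(comp$sites) == 0L)
    stop(sprintf("compound '%s' declares no ionizable sites; incomplete input", comp$code))
  kinds <- vapply(comp$sites, `[[`, character(1), "kind")
  labels <- vapply(comp$sites, `[[`, character(1), "label")
  acid_idx <- which(kinds == "acidic"); base_idx <- which(kinds == "basic")
  suffix <- function(i, n, sign) if (n > 1L) paste0(i, sign) else sign
  rows <- list(data.frame(form_id = prefix, parent = comp$code, charge = 0L,
                          site = NA_character_, stringsAsFactors = FALSE))
  for (i in seq_along(acid_idx))
    rows[[length(rows) + 1L]] <- data.frame(
      form_id = paste0(prefix, suffix(i, length(acid_idx), "-")),
      parent = comp$code, charge = -1L, site = labels[acid_idx[i]],
      stringsAsFactors = FALSE)
  for (i in seq_along(base_idx))
    rows[[length(rows) + 1L]] <- data.frame(
      form_id = paste0(prefix, suffix(i, length(base_idx), "+")),
      parent = comp$code, charge = 1L, site = labels[base_idx[i]],
      stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out$profile_ref <- NA_character_
  class(out) <- c("ionic_forms", "data.frame")
  out
}

#' Bind form tables of several compounds
#'
#' @param ... `ionic_forms` data frames (or a single list of them).
#' @return One `ionic_forms` data frame; form ids must be globally unique.
#' @export
bind_forms <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !is.data.frame(parts[[1]]))
    parts <- parts[[1]]
  out <- do.call(rbind, lapply(parts, as.data.frame))
  if (anyDuplicated(out$form_id))
    stop("duplicated form_id across compounds: ",
         paste(unique(out$form_id[duplicated(out$form_id)]), collapse = ", "))
  class(out) <- c("ionic_forms", "data.frame")
  out
}

#' Read a component library from CSV
#'
#' Expected columns: `code`, `name`, `inchikey`, `role`, `sites` where
#' `sites` holds semicolon-separated `label:kind[:pKa]` tokens, e.g.
#' `"COOH-1:acidic:2.16;NH2:basic:9.58"`.
#'
#' @param path CSV file path.
#' @return Named list of [compound()] objects (names are the codes).
#' @seealso [nades_compound_library()] for the packaged 27-compound library.
#' @export
read_compound_library <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("code", "name", "inchikey", "role", "sites")
  if (!all(need %in% names(tab)))
    stop("component library must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$code))
    stop("component codes must be unique in a library")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    toks <- strsplit(tab$sites[i], ";", fixed = TRUE)[[1]]
    sites <- lapply(toks, function(tok) {
      f <- strsplit(trimws(tok), ":", fixed = TRUE)[[1]]
      if (length(f) < 2L) stop("bad site token '", tok, "' for compound ", tab$code[i])
      ionizable_site(f[1], f[2], if (length(f) >= 3L) as.numeric(f[3]) else NA_real_)
    })
    compound(tab$code[i], tab$name[i], tab$inchikey[i], tab$role[i], sites)
  })
  names(out) <- tab$code
  out
}

#' Packaged component library
#'
#' The 27 study compounds (21 dicarboxylic/tricarboxylic acids, 6 amino
#' acids) with their InChIKeys and declared ionizable sites. Site
#' micro-pKa values, where present, are generic literature-scale
#' estimates supplied as inputs for the substituent-acidity analysis.
#'
#' @return Named list of [compound()] objects.
#' @export
nades_compound_library <- function() {
  read_compound_library(system.file("extdata", "compounds.csv",
                                    package = "nadescreen", mustWork = TRUE))
}
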