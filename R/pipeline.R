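#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML file with blocks `paths` (component CSV,
#' reaction CSV, sigma-profile manifest CSV, training CSV, solute
#' profile), `out_dir`, `conditions` (temperature), `params` (segment
#' interaction parameter overrides), `options` (calibration form,
#' reference and water solubilities, dominant-form cutoff, naive
#' no-dissociation mode) and `seed`. Every referenced input path must
#' exist at read time. Configurations round-trip unchanged through
#' [write_run_config()].
#'
#' @param path YAML configuration file.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg, base_dir = dirname(normalizePath(path)))
}

#' Build a pipeline configuration from a list
#'
#' @param cfg named list (see [read_run_config()] for the schema).
#' @param base_dir directory against which relative paths are resolved.
#' @return A validated list of class `run_config`.
#' @export
as_run_config <- function(cfg, base_dir = ".") {
  stopifnot(is.list(cfg), !is.null(cfg$paths), !is.null(cfg$out_dir))
  need <- c("compounds", "reactions", "manifest", "training", "solute_profile")
  missing <- setdiff(need, names(cfg$paths))
  if (length(missing))
    stop("config paths block is missing: ", paste(missing, collapse = ", "))
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  cfg$paths <- lapply(cfg$paths, resolve)
  for (nm in need)
    if (!file.exists(cfg$paths[[nm]]))
      stop("config path '", nm, "' does not exist: ", cfg$paths[[nm]])
  cfg$out_dir <- resolve(cfg$out_dir)
  defaults <- list(calibration_form = "linear", s_ref = 2.26, s_water = 0.120,
                   dominant_cutoff = 1e-4, no_dissociation = FALSE,
                   solver_tol = 1e-10)
  cfg$options <- utils::modifyList(defaults, as.list(cfg$options %||% list()))
  cfg$conditions <- utils::modifyList(list(T = 298.15), as.list(cfg$conditions %||% list()))
  cfg$params <- as.list(cfg$params %||% list())
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = c("run_config", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline configuration to YAML
#'
#' @param cfg a `run_config` (or compatible list).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  out <- unclass(cfg)
  yaml::write_yaml(out, path)
  invisible(path)
}

# assemble interaction params from config overrides
.config_params <- function(cfg) {
  cond <- thermo_conditions(T = as.numeric(cfg$conditions$T))
  do.call(interaction_params, c(cfg$params, list(cond = cond)))
}

# read the profile manifest into a named path vector
.read_manifest <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("form_id", "path") %in% names(tab)))
    stop("profile manifest must have columns form_id, path")
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(dirname(path), p)
  stats::setNames(vapply(tab$path, resolve, character(1), USE.NAMES = FALSE),
                  tab$form_id)
}

# speciate one pair and build its solvent mixture profile; forms with
# equilibrium mole fraction below `cutoff` are dropped (dominant-forms
# modelling) and the remaining composition renormalized
.pair_solvent <- function(acid_forms, amino_forms, reactions, manifest_paths,
                          cond, cutoff, no_dissociation = FALSE,
                          solver_tol = 1e-10, profile_cache = NULL) {
  forms <- bind_forms(acid_forms, amino_forms)
  if (no_dissociation) {
    x <- stats::setNames(ifelse(forms$charge == 0L, 0.5, 0), forms$form_id)
    spec_res <- NULL
  } else {
    comp <- stats::setNames(c(1, 1), unique(forms$parent))
    mix <- mixture_spec(comp, forms, cond)
    spec_res <- solve_speciation(mix, reactions, tol = solver_tol)
    x <- spec_res$x
  }
  keep <- x >= max(cutoff, 1e-12)
  xk <- x[keep] / sum(x[keep])
  profs <- lapply(names(xk), function(fid) {
    if (!is.null(profile_cache) && !is.null(profile_cache[[fid]]))
      return(profile_cache[[fid]])
    if (!fid %in% names(manifest_paths))
      stop("no sigma profile available for form '", fid, "'")
    read_sigma_profile(manifest_paths[[fid]], label = fid)
  })
  list(mixture = mixture_profile(profs, unname(xk)), speciation = spec_res,
       x_used = xk)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full screening pipeline
#'
#' Orchestrates the two-step screening procedure: for every solvent
#' pair named by the reaction table, solve the dissociation speciation
#' equilibria (or take the naive undissociated 1:1 composition in
#' `no_dissociation` mode), mix the sigma profiles of the dominant
#' forms by their equilibrium mole fractions, compute the solute's
#' infinite-dilution activity coefficient, calibrate computed
#' `ln gamma` against the experimental training solubilities, and rank
#' every pair by predicted solubility. All intermediate artifacts
#' (per-pair speciation CSVs, the gamma table, the ranked screen, a
#' plain-text report) are written under `out_dir`; the run is
#' deterministic for a fixed configuration and inputs.
#'
#' @param cfg a [read_run_config()] / [as_run_config()] object.
#' @return An object of class `nades_report`: `calibration`
#'   (the fitted [fit_calibration()] model), `screen` (ranked
#'   [predict_and_rank()] table), `gamma` (data frame of computed
#'   `ln gamma` per pair), `speciation` (list of per-pair results),
#'   `files` (paths written).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(cfg$out_dir, "speciation"), showWarnings = FALSE)
  cond <- thermo_conditions(T = as.numeric(cfg$conditions$T))
  params <- .config_params(cfg)

  lib <- .stage("components", read_compound_library(cfg$paths$compounds))
  forms_by_comp <- lapply(lib, enumerate_ionic_forms)
  all_forms <- bind_forms(forms_by_comp)

  reactions <- .stage("reactions",
                      read_reaction_table(cfg$paths$reactions, all_forms, cond))
  manifest <- .stage("manifest", .read_manifest(cfg$paths$manifest))
  solute <- .stage("solute profile",
                   read_sigma_profile(cfg$paths$solute_profile))
  training <- .stage("training table", read_training_table(cfg$paths$training))

  # group reactions into binary systems by the parent pair they couple
  parent_of <- stats::setNames(all_forms$parent, all_forms$form_id)
  role_of <- vapply(lib, `[[`, character(1), "role")
  pair_key <- vapply(reactions, function(r) {
    ps <- sort(unique(parent_of[names(r$stoich)]))
    if (length(ps) != 2L)
      stop("reaction ", r$reaction_id, " does not couple exactly two components")
    acid <- ps[role_of[ps] == "carboxylic_acid"]
    amino <- ps[role_of[ps] == "amino_acid"]
    if (length(acid) != 1L || length(amino) != 1L)
      stop("reaction ", r$reaction_id, " must couple one acid with one amino acid")
    paste(acid, amino, sep = "-")
  }, character(1))
  systems <- split(reactions, pair_key)

  spec_results <- list()
  gamma_tab <- data.frame()
  for (id in sort(names(systems))) {
    ps <- strsplit(id, "-", fixed = TRUE)[[1]]
    sol <- .stage(paste0("speciation/mixing [", id, "]"),
                  .pair_solvent(forms_by_comp[[ps[1]]], forms_by_comp[[ps[2]]],
                                systems[[id]], manifest, cond,
                                cutoff = cfg$options$dominant_cutoff,
                                no_dissociation = isTRUE(cfg$options$no_dissociation),
                                solver_tol = cfg$options$solver_tol))
    if (!is.null(sol$speciation)) {
      spec_results[[id]] <- sol$speciation
      write_speciation_csv(sol$speciation,
                           file.path(cfg$out_dir, "speciation",
                                     paste0(id, ".csv")))
    }
    lg <- .stage(paste0("activity [", id, "]"),
                 ln_gamma_infinite_dilution(solute, sol$mixture, params))
    gamma_tab <- rbind(gamma_tab, data.frame(
      nades_id = id, ln_gamma = as.numeric(lg),
      mean_area = sol$mixture$mean_area,
      n_forms_used = length(sol$x_used), stringsAsFactors = FALSE))
  }
  utils::write.csv(gamma_tab, file.path(cfg$out_dir, "gamma_table.csv"),
                   row.names = FALSE, quote = FALSE)

  records <- merge(training, gamma_tab[, c("nades_id", "ln_gamma")],
                   by = "nades_id")
  if (nrow(records) < 3L)
    stop("stage 'calibration' failed: fewer than 3 training NADES have computed ln gamma")
  cal <- .stage("calibration",
                fit_calibration(records, form = cfg$options$calibration_form))

  candidates <- stats::setNames(gamma_tab$ln_gamma, gamma_tab$nades_id)
  src <- ifelse(gamma_tab$nades_id %in% training$nades_id,
                "experimental", "estimated")
  screen <- .stage("screening",
                   predict_and_rank(cal, candidates,
                                    s_ref = cfg$options$s_ref,
                                    s_water = cfg$options$s_water,
                                    source = src))
  write_screening_csv(screen, file.path(cfg$out_dir, "screen_ranked.csv"))

  report_path <- file.path(cfg$out_dir, "report.txt")
  con <- file(report_path, "w")
  writeLines(c(
    "NADES screening report",
    "======================",
    sprintf("systems: %d (training: %d), mode: %s",
            nrow(gamma_tab), nrow(records),
            if (isTRUE(cfg$options$no_dissociation)) "naive (no dissociation)"
            else "dissociation-aware"),
    sprintf("calibration (%s): s = %.6g * ln(gamma) + %.6g, R^2 = %.4f, n = %d",
            cal$form, cal$slope, cal$intercept, cal$r_squared, cal$n),
    "",
    "rank  nades_id  s_pred[mg/mL]  pct_vs_ref  fold_vs_water  source",
    sprintf("%4d  %-8s  %13.2f  %10d  %13d  %s",
            seq_len(nrow(screen)), screen$nades_id, screen$s_pred,
            screen$pct_increase_vs_ref, screen$fold_vs_water, screen$source)),
    con)
  close(con)

  structure(list(calibration = cal, screen = screen, gamma = gamma_tab,
                 speciation = spec_results,
                 files = list(out_dir = cfg$out_dir,
                              gamma_table = file.path(cfg$out_dir, "gamma_table.csv"),
                              screen = file.path(cfg$out_dir, "screen_ranked.csv"),
                              report = report_path)),
            class = "nades_report")
}

#' @export
print.nades_report <- function(x, ...) {
  print(x$calibration)
  cat("\nTop of the ranked screen:\n")
  print(utils::head(as.data.frame(x$screen)[, c("nades_id", "s_pred_rounded",
                                                "pct_increase_vs_ref",
                                                "fold_vs_water", "source")], 5),
        row.names = FALSE)
  invisible(x)
}

#' Export the packaged fixture suite
#'
#' Writes a complete, self-consistent input set under `dest` so the
#' whole pipeline can run without external software: a component CSV
#' (six dicarboxylic acids, three amino acids drawn from the packaged
#' library), a reaction CSV with seeded equilibrium constants for all
#' 18 acid/amino-acid pairs, synthetic Gaussian sigma profiles for
#' every ionic form plus a synthetic solute stand-in for rutin
#' (`rutin_synthetic`), a training table whose solubilities are
#' generated from the pipeline's own computed `ln gamma` by a linear
#' law with known coefficients and Gaussian noise (15 training pairs;
#' the remaining 3 are screening-only), and a ready-to-run
#' `config.yaml`. The generating truth is written to `truth.yaml`.
#' Deterministic per seed.
#'
#' @param dest destination directory (created if needed).
#' @param seed integer master seed.
#' @return Invisibly, a list with the config path and the generating
#'   truth.
#' @export
export_fixtures <- function(dest, seed = 1L) {
  dir.create(dest, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dest, "profiles"), showWarnings = FALSE)

  acid_codes <- c("1", "7", "16", "17", "19", "21")
  amino_codes <- c("A", "D", "F")
  train_acids <- setdiff(acid_codes, "1")

  src_csv <- utils::read.csv(system.file("extdata", "compounds.csv",
                                         package = "nadescreen", mustWork = TRUE),
                             stringsAsFactors = FALSE, colClasses = "character")
  sel <- src_csv[src_csv$code %in% c(acid_codes, amino_codes), ]
  comp_path <- file.path(dest, "compounds.csv")
  utils::write.csv(sel, comp_path, row.names = FALSE, quote = TRUE)

  lib <- read_compound_library(comp_path)
  forms_by_comp <- lapply(lib, enumerate_ionic_forms)
  all_forms <- bind_forms(forms_by_comp)

  # one reaction set per pair, seeded K in the strongly product-favoured
  # regime typical of acid/amino-acid proton transfer; K is generated
  # from per-ion standard potentials so that stoichiometrically
  # dependent reaction sets (multi-site parents) stay thermodynamically
  # consistent
  rxn_rows <- list()
  systems <- list()
  for (a in acid_codes) for (b in amino_codes) {
    id <- paste(a, b, sep = "-")
    skel <- enumerate_reactions(forms_by_comp[[a]], forms_by_comp[[b]])
    ions <- unique(unlist(lapply(skel, function(r)
      names(r$stoich)[r$stoich > 0])))
    u <- .with_stream_seed(seed, paste0("K:", id),
                           stats::setNames(stats::runif(length(ions), 0.5, 3),
                                           ions))
    rxns <- lapply(seq_along(skel), function(j) {
      st <- skel[[j]]$stoich
      prod_ions <- names(st)[st > 0]
      reaction(paste0(id, ".K", j), st, all_forms,
               K = 10^sum(u[prod_ions]))
    })
    systems[[id]] <- rxns
    for (r in rxns)
      rxn_rows[[length(rxn_rows) + 1L]] <- data.frame(
        reaction_id = r$reaction_id,
        stoichiometry = paste(sprintf("%+d %s", r$stoich, names(r$stoich)),
                              collapse = " "),
        dG_kcal = NA_real_, K = r$K, stringsAsFactors = FALSE)
  }
  rxn_path <- file.path(dest, "reactions.csv")
  utils::write.csv(do.call(rbind, rxn_rows), rxn_path, row.names = FALSE,
                   quote = FALSE)

  prof_ids <- c(all_forms$form_id, "rutin_synthetic")
  profs <- make_profile_set(prof_ids, seed = seed)
  man_rows <- lapply(all_forms$form_id, function(fid) {
    fn <- file.path("profiles", paste0(gsub("[+]", "p", gsub("-", "m", fid)), ".txt"))
    write_sigma_profile(profs[[fid]], file.path(dest, fn))
    data.frame(form_id = fid, path = fn, stringsAsFactors = FALSE)
  })
  man_path <- file.path(dest, "manifest.csv")
  utils::write.csv(do.call(rbind, man_rows), man_path, row.names = FALSE,
                   quote = FALSE)
  solute_path <- file.path(dest, "profiles", "rutin_synthetic.txt")
  write_sigma_profile(profs[["rutin_synthetic"]], solute_path)

  # compute ln gamma through the real chain for the training pairs, then
  # lay a known linear law with noise over it
  cond <- thermo_conditions()
  params <- interaction_params(cond = cond)
  manifest <- .read_manifest(man_path)
  solute <- read_sigma_profile(solute_path)
  train_ids <- as.vector(outer(train_acids, amino_codes, paste, sep = "-"))
  lg <- vapply(train_ids, function(id) {
    ps <- strsplit(id, "-", fixed = TRUE)[[1]]
    sol <- .pair_solvent(forms_by_comp[[ps[1]]], forms_by_comp[[ps[2]]],
                         systems[[id]], manifest, cond, cutoff = 1e-4)
    as.numeric(ln_gamma_infinite_dilution(solute, sol$mixture, params))
  }, numeric(1))
  slope <- -0.45 / stats::sd(lg)
  intercept <- 1.2 - slope * mean(lg)
  noise_sd <- 0.08
  s_exp <- .with_stream_seed(seed, "training-sexp", {
    s <- slope * lg + intercept + stats::rnorm(length(lg), 0, noise_sd)
    for (tries in seq_len(100L)) {
      if (all(s > 0)) break
      bad <- s <= 0
      s[bad] <- slope * lg[bad] + intercept + stats::rnorm(sum(bad), 0, noise_sd)
    }
    pmax(s, 1e-3)
  })
  train_path <- file.path(dest, "training.csv")
  utils::write.csv(data.frame(nades_id = train_ids, s_exp_mg_per_ml = s_exp),
                   train_path, row.names = FALSE, quote = FALSE)
  truth <- list(slope = slope, intercept = intercept, noise_sd = noise_sd,
                ln_gamma = as.list(stats::setNames(lg, train_ids)))
  yaml::write_yaml(truth, file.path(dest, "truth.yaml"))

  cfg <- list(paths = list(compounds = "compounds.csv",
                           reactions = "reactions.csv",
                           manifest = "manifest.csv",
                           training = "training.csv",
                           solute_profile = file.path("profiles", "rutin_synthetic.txt")),
              out_dir = "out",
              conditions = list(T = 298.15),
              params = list(),
              options = list(calibration_form = "linear",
                             s_ref = 2.26, s_water = 0.120,
                             dominant_cutoff = 1e-4,
                             no_dissociation = FALSE),
              seed = as.integer(seed))
  cfg_path <- file.path(dest, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(list(config = cfg_path, truth = truth))
}
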