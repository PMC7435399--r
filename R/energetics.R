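# Nonbonded group-group interaction energies and the solvation-enthalpy
# estimator.
#
# Energies are cutoff-truncated Lennard-Jones plus Coulomb with optional
# uniform charge scaling (0.8 by default, the usual screening correction
# for ionic-liquid force fields). No reciprocal-space electrostatics: this
# module is an analysis/decomposition tool, not an MD engine.

# e^2 / (4 pi eps0) in kJ mol^-1 pm
COULOMB_KJ_PM <- 138935.4576

#' Nonbonded parameters for interaction-energy evaluation
#'
#' @param scale uniform charge scale factor in (0, 1]; applied as
#'   `scale^2` on each pair term (default 0.8).
#' @param cutoff pair cutoff, pm (default 800).
#' @param coulomb `"physical"` (kJ/mol with charges in e, distances pm) or
#'   `"reduced"` (`k_C = 1`).
#' @return a `NonbondedParams` list.
#' @export
nonbonded_params <- function(scale = 0.8, cutoff = 800,
                             coulomb = c("physical", "reduced")) {
  coulomb <- match.arg(coulomb)
  stopifnot(cutoff > 0, scale > 0, scale <= 1)
  structure(list(scale = scale, cutoff = cutoff, coulomb = coulomb,
                 k_c = if (coulomb == "physical") COULOMB_KJ_PM else 1),
            class = "NonbondedParams")
}

#' Group-group nonbonded interaction energy for one frame
#'
#' Sums `4 eps [(sigma/r)^12 - (sigma/r)^6] + k_C q_i q_j scale^2 / r`
#' over all cross pairs within the cutoff (minimum image). Lorentz-
#' Berthelot mixing: arithmetic-mean sigma, geometric-mean epsilon.
#' Intra-group pairs are never counted; overlapping groups are an error.
#'
#' @param frame n_atoms x 3 coordinates, pm.
#' @param topo a `Topology` providing charges and LJ parameters.
#' @param group_a,group_b disjoint atom index sets.
#' @param params a `NonbondedParams`.
#' @param box length-3 box edges, pm.
#' @return energy, kJ/mol.
#' @export
group_interaction_energy <- function(frame, topo, group_a, group_b,
                                     params, box) {
  if (length(intersect(group_a, group_b)) > 0)
    stop("groups overlap: cross-group energy is undefined")
  at <- topo$atoms
  both <- c(group_a, group_b)
  no_charge <- is.na(at$charge[both])
  no_lj <- is.na(at$sigma[both]) | is.na(at$epsilon[both])
  if (any(no_charge & no_lj))
    stop(sprintf("missing nonbonded parameters for atoms: %s",
                 paste(both[no_charge & no_lj], collapse = ", ")))
  qa <- at$charge[group_a]; qb <- at$charge[group_b]
  qa[is.na(qa)] <- 0; qb[is.na(qb)] <- 0
  sa <- at$sigma[group_a]; sb <- at$sigma[group_b]
  ea <- at$epsilon[group_a]; eb <- at$epsilon[group_b]
  sa[is.na(sa)] <- 0; sb[is.na(sb)] <- 0
  ea[is.na(ea)] <- 0; eb[is.na(eb)] <- 0
  pa <- frame[group_a, , drop = FALSE]
  pb <- frame[group_b, , drop = FALSE]
  e <- 0
  s2 <- params$scale^2
  for (i in seq_along(group_a)) {
    d <- minimum_image(matrix(pa[i, ], nrow(pb), 3, byrow = TRUE), pb, box)
    r <- sqrt(rowSums(d^2))
    inside <- r <= params$cutoff
    if (!any(inside)) next
    r <- r[inside]
    sig <- (sa[i] + sb[inside]) / 2
    eps <- sqrt(ea[i] * eb[inside])
    sr6 <- (sig / r)^6
    e <- e + sum(4 * eps * (sr6^2 - sr6)) +
      params$k_c * s2 * sum(qa[i] * qb[inside] / r)
  }
  e
}

#' Read a potential-energy trace
#'
#' Accepts a single-column numeric file, a `(step, energy)` two-column
#' CSV, or a LAMMPS thermo log (the `PotEng` column is extracted from
#' every thermo block).
#'
#' @param path file path.
#' @param format `"csv"` (auto single/two column) or `"lammps-log"`.
#' @return numeric vector of per-frame potential energies, kJ/mol.
#' @export
read_energy_trace <- function(path, format = c("csv", "lammps-log")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (format == "csv") {
    df <- read.csv(path, header = FALSE,
                   comment.char = "#", strip.white = TRUE)
    if (is.character(df[1, 1]) || is.na(suppressWarnings(as.numeric(df[1, 1]))))
      df <- df[-1, , drop = FALSE]          # tolerate a header line
    vals <- as.numeric(df[[ncol(df)]])
    if (any(is.na(vals))) stop(sprintf("non-numeric energy values in %s", path))
    vals
  } else {
    lines <- readLines(path)
    out <- numeric(0)
    col <- NA_integer_
    for (ln in lines) {
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(toks) == 0) next
      if ("PotEng" %in% toks) { col <- match("PotEng", toks); next }
      if (!is.na(col)) {
        v <- suppressWarnings(as.numeric(toks))
        if (length(v) >= col && !any(is.na(v[seq_len(col)])))
          out <- c(out, v[col])
        else col <- NA_integer_             # block ended
      }
    }
    if (length(out) == 0) stop(sprintf("no PotEng column found in %s", path))
    out
  }
}

#' Solvation enthalpy per glucose unit from three energy traces
#'
#' `dH_solv = (mean(E_solution) - mean(E_pureIL) - mean(E_vacuum)) /
#' n_units`. The three runs are independent simulations, so the standard
#' error propagates uncorrelated:
#' `SE = sqrt(se_sol^2 + se_il^2 + se_vac^2) / n_units`.
#'
#' @param e_sol,e_il,e_vac numeric energy traces, kJ/mol (solution, pure
#'   IL, solute strand in vacuum).
#' @param n_units glucose units of the strand (>= 1).
#' @return a `SolvationEnthalpy`: `dH` (kJ/mol per unit), `se`,
#'   `n_units`, `components` (the three trace means).
#' @export
solvation_enthalpy <- function(e_sol, e_il, e_vac, n_units = 1) {
  if (length(e_sol) == 0 || length(e_il) == 0 || length(e_vac) == 0)
    stop("empty energy trace")
  stopifnot(n_units >= 1)
  mns <- c(solution = mean(e_sol), pure_il = mean(e_il), vacuum = mean(e_vac))
  ses <- c(sd(e_sol) / sqrt(length(e_sol)),
           sd(e_il) / sqrt(length(e_il)),
           sd(e_vac) / sqrt(length(e_vac)))
  ses[is.na(ses)] <- 0                      # length-1 traces
  structure(list(dH = unname(mns[1] - mns[2] - mns[3]) / n_units,
                 se = sqrt(sum(ses^2)) / n_units,
                 n_units = n_units, components = mns),
            class = "SolvationEnthalpy")
}

#' @export
print.SolvationEnthalpy <- function(x, ...) {
  cat(sprintf("dH_solv = %.2f +/- %.2f kJ/mol per glucose unit (n_units = %d)\n",
              x$dH, x$se, x$n_units))
  invisible(x)
}

#' Export a solvation-enthalpy summary with interaction-energy components
#'
#' @param dh a `SolvationEnthalpy`.
#' @param path JSON output.
#' @param cellulose_anion,cellulose_cation optional interaction energies
#'   (kJ/mol per unit). When both are given, the summary also records
#'   whether the anion interaction dominates in magnitude (a diagnostic,
#'   not an assumption).
#' @export
write_dhsolv_json <- function(dh, path, cellulose_anion = NULL,
                              cellulose_cation = NULL) {
  out <- list(dH_solv_kj_per_mol_unit = dh$dH, se = dh$se,
              n_units = dh$n_units, components = as.list(dh$components))
  if (!is.null(cellulose_anion)) out$cellulose_anion <- cellulose_anion
  if (!is.null(cellulose_cation)) out$cellulose_cation <- cellulose_cation
  if (!is.null(cellulose_anion) && !is.null(cellulose_cation))
    out$anion_dominates <- abs(cellulose_anion) > abs(cellulose_cation)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
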