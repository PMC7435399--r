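# Solvation-enthalpy -> cellulose-solubility log model, and the carbene
# equilibrium helper.
#
# The model assumes the free energy of dissolution is dominated by the
# solvation enthalpy, with the entropic term folded into a constant:
# dH_solv - c1 ~= c2 * ln(S). Calibration regresses dH on ln(S) by
# ordinary least squares; prediction inverts the fitted line. Accuracy is
# semi-quantitative: a factor-of-two multiplicative band around the
# predicted solubility.

#' Calibrate the solubility log model
#'
#' Ordinary least squares of `dH = c2 * ln(S) + c1` on calibration pairs;
#' `R` is the Pearson correlation of `(ln S, dH)`.
#'
#' @param points data.frame with columns `S` (solubility, wt.-%, all > 0)
#'   and `dH` (kJ/mol per glucose unit); an optional `name` column labels
#'   calibration points. At least 3 points with non-identical `S`.
#' @param unit solubility unit of the calibration column; `"wtpct"`
#'   (default) or `"g_per_mol_il"`. Units are recorded on the model and
#'   never mixed in one fit.
#' @return a `SolubilityModel`: `c1`, `c2`, `R`, `points`, `unit`.
#' @export
fit_solubility_model <- function(points, unit = c("wtpct", "g_per_mol_il")) {
  unit <- match.arg(unit)
  stopifnot(is.data.frame(points), all(c("S", "dH") %in% names(points)))
  if (nrow(points) < 3) stop("need at least 3 calibration points")
  if (any(points$S <= 0)) stop("solubilities must be positive")
  if (length(unique(points$S)) < 2)
    stop("degenerate calibration: all solubilities identical")
  x <- log(points$S)
  fit <- lm(points$dH ~ x)
  structure(list(c1 = coef(fit)[[1]], c2 = coef(fit)[[2]],
                 R = cor(x, points$dH), points = points, unit = unit),
            class = "SolubilityModel")
}

#' @export
print.SolubilityModel <- function(x, ...) {
  cat(sprintf("Solubility model: dH = %.3f * ln(S) + %.3f  (R = %.4f, %d points, unit %s)\n",
              x$c2, x$c1, x$R, nrow(x$points), x$unit))
  invisible(x)
}

#' Predict cellulose solubility from a solvation enthalpy
#'
#' Inverts the calibrated line: `S = exp((dH - c1) / c2)`, with the
#' semi-quantitative factor-of-two band `[S/2, 2S]`.
#'
#' @param object a `SolubilityModel`.
#' @param dh solvation enthalpy, kJ/mol per glucose unit (vectorised).
#' @param ... unused.
#' @return a `SolubilityPrediction`: `S`, `lower`, `upper` (same unit as
#'   the calibration points).
#' @export
predict.SolubilityModel <- function(object, dh, ...) {
  if (object$c2 == 0) stop("model uninformative: c2 = 0")
  S <- exp((dh - object$c1) / object$c2)
  structure(list(S = S, lower = S / 2, upper = 2 * S, unit = object$unit),
            class = "SolubilityPrediction")
}

#' @export
print.SolubilityPrediction <- function(x, ...) {
  for (i in seq_along(x$S))
    cat(sprintf("S = %.3g %s  (factor-of-two band %.3g .. %.3g)\n",
                x$S[i], x$unit, x$lower[i], x$upper[i]))
  invisible(x)
}

#' Read calibration points / persist a model
#'
#' Calibration CSV columns: `name`, `solubility_wtpct`,
#' `dh_kj_per_mol_unit`. The model JSON stores the constants, correlation,
#' points and unit convention.
#'
#' @param path file path.
#' @return `read_calibration_csv`: a points data.frame;
#'   `read_model_json`: a `SolubilityModel`.
#' @export
read_calibration_csv <- function(path) {
  df <- read.csv(path)
  need <- c("solubility_wtpct", "dh_kj_per_mol_unit")
  if (!all(need %in% names(df)))
    stop(sprintf("calibration CSV needs columns: %s", paste(need, collapse = ", ")))
  data.frame(name = if (!is.null(df$name)) df$name else sprintf("pt%02d", seq_len(nrow(df))),
             S = df$solubility_wtpct, dH = df$dh_kj_per_mol_unit)
}

#' @rdname read_calibration_csv
#' @param model a `SolubilityModel`.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(c1 = model$c1, c2 = model$c2, R = model$R,
                            unit = model$unit, points = model$points),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_calibration_csv
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  structure(list(c1 = doc$c1, c2 = doc$c2, R = doc$R,
                 points = as.data.frame(doc$points), unit = doc$unit),
            class = "SolubilityModel")
}

#' Carbene-formation equilibrium constant from pKa values
#'
#' Proton transfer from the azolium cation (acidity `pka1`) to the anion's
#' base (conjugate acid acidity `pka2`): `log10 K = pka2 - pka1`. A more
#' acidic cation (lower pka1, e.g. imidazolium ~20 vs triazolium ~24) or a
#' more basic anion shifts the equilibrium toward the carbene.
#'
#' @param pka1 cation acidity.
#' @param pka2 acidity of the anion's conjugate acid.
#' @return a `CarbeneEquilibrium`: `pka1`, `pka2`, `log10_K`, `K`.
#' @export
carbene_log_k <- function(pka1, pka2) {
  stopifnot(is.finite(pka1), is.finite(pka2))
  structure(list(pka1 = pka1, pka2 = pka2, log10_K = pka2 - pka1,
                 K = 10^(pka2 - pka1)),
            class = "CarbeneEquilibrium")
}

#' @export
print.CarbeneEquilibrium <- function(x, ...) {
  cat(sprintf("Carbene equilibrium: log10 K = %.3g (pKa1 = %g, pKa2 = %g)\n",
              x$log10_K, x$pka1, x$pka2))
  invisible(x)
}
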