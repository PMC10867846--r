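#' @include AllClasses.R AllGenerics.R
NULL

#' Mass density of a liquid series
#'
#' rho = M / <V>, converted to g/mL (M in g/mol, volumes in bohr^3,
#' Avogadro's number in the conversion).
#'
#' @param series a \linkS4class{LiquidSeries}
#' @return density in g/mL
#' @export
massDensity <- function(series) {
  vbar <- mean(series@volumes)
  if (vbar <= 0) stop("non-positive average volume", call. = FALSE)
  series@totalMass / (AVOGADRO * vbar * BOHR3_IN_ML)
}

#' Analytic high-frequency dielectric constant (direct approximation)
#'
#' Under direct polarization the induced dipoles do not interact, so the
#' electronic susceptibility is additive and (Gaussian units)
#' eps_inf = 1 + 4 pi * sum(alpha) / <V>.
#'
#' @param series a \linkS4class{LiquidSeries} with \code{alphasTotal} set
#' @return unitless eps_inf
#' @export
epsilonInfinity <- function(series) {
  1 + 4 * pi * series@alphasTotal / mean(series@volumes)
}

#' Static dielectric constant from dipole fluctuations
#'
#' D = eps_inf + 4 pi (<mu.mu> - <mu>.<mu>) / (3 <V> k_B T), using the full
#' vector second moment of the total box dipole. Reports both D and its
#' reciprocal, since electrostatic screening scales with 1/D.
#'
#' @param series a \linkS4class{LiquidSeries} (>= 2 frames, T > 0)
#' @return list with \code{D}, \code{invD}, \code{epsInf},
#'   \code{fluctuation} (the 4pi var/3VkT term) and \code{stderr} (delta-
#'   method standard error of D from the frame-to-frame variance)
#' @export
dielectricFromFluctuations <- function(series) {
  if (nrow(series@dipoles) < 2)
    stop("at least two frames are required", call. = FALSE)
  if (series@temperature <= 0)
    stop("temperature must be positive", call. = FALSE)
  mu <- series@dipoles
  mubar <- colMeans(mu)
  dev2 <- rowSums(sweep(mu, 2, mubar)^2)
  varMu <- mean(dev2)                       # <|mu - <mu>|^2>
  pref <- 4 * pi / (3 * mean(series@volumes) * KBOLTZ_HARTREE *
                      series@temperature)
  epsInf <- epsilonInfinity(series)
  D <- epsInf + pref * varMu
  se <- pref * stats::sd(dev2) / sqrt(length(dev2))
  list(D = D, invD = 1 / D, epsInf = epsInf, fluctuation = pref * varMu,
       stderr = se)
}

#' Lorentz-Lorenz molecular polarizability from the refractive index
#'
#' alpha_M = (3 / (4 pi rho)) * (n^2 - 1) / (n^2 + 2), with rho the number
#' density of molecules. Units follow rho: molecules/Angstrom^3 gives
#' alpha in Angstrom^3.
#'
#' @param refractiveIndex n (>= 1)
#' @param numberDensity molecules per unit volume (> 0)
#' @return molecular polarizability in the reciprocal units of
#'   \code{numberDensity}
#' @export
#' @examples
#' lorentzLorenzAlpha(1.5, 0.006)  # ~11.7 Angstrom^3
lorentzLorenzAlpha <- function(refractiveIndex, numberDensity) {
  if (refractiveIndex < 1)
    stop("refractive index must be >= 1", call. = FALSE)
  if (numberDensity <= 0)
    stop("number density must be positive", call. = FALSE)
  n2 <- refractiveIndex^2
  3 / (4 * pi * numberDensity) * (n2 - 1) / (n2 + 2)
}

#' Invert the Lorentz-Lorenz relation
#' @param alphaM molecular polarizability
#' @param numberDensity molecules per unit volume
#' @return refractive index n
#' @export
lorentzLorenzIndex <- function(alphaM, numberDensity) {
  x <- 4 * pi * numberDensity * alphaM / 3
  if (x >= 1) stop("polarizability too large for a real index", call. = FALSE)
  sqrt((1 + 2 * x) / (1 - x))
}

#' Read a liquid time series from CSV plus metadata JSON
#'
#' CSV columns: frame, mux, muy, muz, volume. Units are declared in the
#' metadata JSON: \code{{"dipole_unit": "ebohr"|"debye", "volume_unit":
#' "bohr3"|"nm3", "temperature_K": ..., "total_mass_gmol": ...,
#' "alphas_total_bohr3": ...}}.
#'
#' @param csvPath CSV path
#' @param metaPath metadata JSON path
#' @return A \linkS4class{LiquidSeries}.
#' @export
readLiquidSeries <- function(csvPath, metaPath) {
  tab <- utils::read.csv(csvPath)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  mu <- as.matrix(tab[, c("mux", "muy", "muz")])
  if (identical(meta$dipole_unit, "debye")) mu <- mu / DEBYE_PER_AU
  vol <- tab$volume
  if (identical(meta$volume_unit, "nm3")) vol <- vol * NM3_IN_BOHR3
  LiquidSeries(mu, vol, meta$temperature_K,
               totalMass = if (is.null(meta$total_mass_gmol)) 0
                           else meta$total_mass_gmol,
               alphasTotal = if (is.null(meta$alphas_total_bohr3)) 0
                             else meta$alphas_total_bohr3)
}

#' Write a liquid time series to CSV plus metadata JSON
#' @param series a \linkS4class{LiquidSeries}
#' @param csvPath CSV path
#' @param metaPath metadata JSON path
#' @return invisibly, csvPath
#' @export
writeLiquidSeries <- function(series, csvPath, metaPath) {
  tab <- data.frame(frame = seq_len(nrow(series@dipoles)),
                    mux = series@dipoles[, 1], muy = series@dipoles[, 2],
                    muz = series@dipoles[, 3], volume = series@volumes)
  utils::write.csv(tab, csvPath, row.names = FALSE)
  jsonlite::write_json(list(dipole_unit = "ebohr", volume_unit = "bohr3",
                            temperature_K = series@temperature,
                            total_mass_gmol = series@totalMass,
                            alphas_total_bohr3 = series@alphasTotal),
                       metaPath, auto_unbox = TRUE, digits = NA)
  invisible(csvPath)
}
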