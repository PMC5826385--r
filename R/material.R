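#' Ogden-Prony brain material
#'
#' Constitutive constants for the brain tissue model: a first-order Ogden
#' strain energy density
#' \deqn{W = \frac{2\mu(t)}{\alpha^2}(\lambda_1^\alpha + \lambda_2^\alpha +
#'   \lambda_3^\alpha - 3)}
#' with shear relaxation modulus given by a two-term Prony series
#' \deqn{\mu(t) = \mu_0 (1 - \sum_{i=1}^2 C_i (1 - e^{-t/\tau_i})).}
#' Defaults are the neonatal porcine brain constants used in the
#' transection model: mu0 = 553 Pa, alpha = 0.01, C1 = 0.3322,
#' C2 = 0.3890, tau1 = 2.9572 s, tau2 = 0.1813 s, rho = 1.04 g/cm^3.
#' Poisson's ratio defaults to 0.495 (the nominal 0.49999 is softened for
#' explicit-dynamics stability; pass `nu = 0.49999` to override).
#'
#' @param mu0 Instantaneous shear modulus (Pa).
#' @param alpha Ogden exponent (dimensionless).
#' @param C1,C2 Prony relaxation moduli (dimensionless, 0 <= C1+C2 < 1).
#' @param tau1,tau2 Prony time constants (s).
#' @param rho Density (kg/m^3).
#' @param nu Poisson's ratio (0 < nu < 0.5).
#' @return List of class `ogden_prony`.
#' @export
ogden_prony_material <- function(mu0 = 553, alpha = 0.01,
                                 C1 = 0.3322, C2 = 0.3890,
                                 tau1 = 2.9572, tau2 = 0.1813,
                                 rho = 1040, nu = 0.495) {
  stopifnot(mu0 > 0, C1 >= 0, C2 >= 0, C1 + C2 < 1,
            tau1 > 0, tau2 > 0, rho > 0, nu > 0, nu < 0.5)
  structure(list(mu0 = mu0, alpha = alpha, C1 = C1, C2 = C2,
                 tau1 = tau1, tau2 = tau2, rho = rho, nu = nu),
            class = "ogden_prony")
}

#' Prony relaxation modulus mu(t)
#'
#' @param material An [ogden_prony_material()].
#' @param t Time(s) since load application (s); `Inf` gives the
#'   long-term modulus `mu0 * (1 - C1 - C2)`.
#' @return Shear modulus (Pa) at each `t`.
#' @export
prony_mu <- function(material, t) {
  with(material,
       mu0 * (1 - C1 * (1 - exp(-t / tau1)) - C2 * (1 - exp(-t / tau2))))
}

# Bulk modulus of the near-incompressibility penalty, from (mu0, nu).
bulk_modulus <- function(material) {
  with(material, 2 * mu0 * (1 + nu) / (3 * (1 - 2 * nu)))
}

#' Instantaneous Ogden principal stresses
#'
#' Principal Cauchy stresses of the first-order Ogden model with a
#' deviatoric/volumetric split: deviatoric response from the isochoric
#' stretches `lambda_i / J^(1/3)` with shear modulus `mu`, volumetric
#' response `K (J - 1)` from the penalty bulk modulus.
#'
#' @param lambda Matrix (n x 3) or length-3 vector of principal stretches.
#' @param mu Shear modulus (Pa) — pass [prony_mu()] output for a relaxed
#'   modulus.
#' @param alpha Ogden exponent.
#' @param K Bulk modulus (Pa); `NULL` drops the volumetric term
#'   (incompressible deviatoric response only).
#' @return Matrix (n x 3) of principal Cauchy stresses (Pa).
#' @export
ogden_stress <- function(lambda, mu, alpha, K = NULL) {
  lam <- if (is.matrix(lambda)) lambda else matrix(lambda, nrow = 1)
  if (any(lam <= 0)) abort("Non-positive principal stretch (element inversion).")
  J <- lam[, 1] * lam[, 2] * lam[, 3]
  lb <- lam / J^(1 / 3)
  pow <- lb^alpha
  dev <- (2 * mu / alpha) * (pow - rowMeans(pow))  # deviatoric Kirchhoff
  sig <- dev / J
  if (!is.null(K)) sig <- sig + K * (J - 1)
  sig
}

#' Ogden strain energy density
#'
#' @inheritParams ogden_stress
#' @return Energy density (Pa) per row, deviatoric part plus (when `K`
#'   supplied) the volumetric penalty `K/2 (J-1)^2`.
#' @export
ogden_energy <- function(lambda, mu, alpha, K = NULL) {
  lam <- if (is.matrix(lambda)) lambda else matrix(lambda, nrow = 1)
  J <- lam[, 1] * lam[, 2] * lam[, 3]
  lb <- lam / J^(1 / 3)
  W <- (2 * mu / alpha^2) * (rowSums(lb^alpha) - 3)
  if (!is.null(K)) W <- W + K / 2 * (J - 1)^2
  W
}

#' Viscoelastic Ogden-Prony stress along a stretch history
#'
#' Evaluates the relaxed principal Cauchy stresses for a principal-stretch
#' history sampled on a uniform time grid, using the standard
#' internal-variable (recursive exponential) update equivalent to the
#' hereditary integral of the Prony series acting on the deviatoric
#' Kirchhoff stress.  Principal directions are assumed fixed over the
#' history (sufficient for homogeneous laboratory deformations; the
#' simulator applies the same update tensorially).
#'
#' @param lambda Matrix (n_t x 3) of principal stretches over time.
#' @param material An [ogden_prony_material()].
#' @param time Uniform time grid (s), length n_t.
#' @param K Bulk modulus; default from the material, `NULL` to omit.
#' @return Matrix (n_t x 3) of principal Cauchy stresses (Pa).
#' @examples
#' m <- ogden_prony_material()
#' prony_mu(m, 0)       # = mu0
#' prony_mu(m, Inf)     # = mu0 * (1 - C1 - C2)
#' @export
ogden_prony_stress <- function(lambda, material, time,
                               K = bulk_modulus(material)) {
  stopifnot(nrow(lambda) == length(time))
  if (any(lambda <= 0)) abort("Non-positive principal stretch (element inversion).")
  n <- length(time)
  dt <- if (n > 1) time[2] - time[1] else 0
  J <- lambda[, 1] * lambda[, 2] * lambda[, 3]
  lb <- lambda / J^(1 / 3)
  pow <- lb^material$alpha
  tau_dev <- (2 * material$mu0 / material$alpha) * (pow - rowMeans(pow))
  h1 <- h2 <- rep(0, 3)
  out <- matrix(0, n, 3)
  e1 <- exp(-dt / material$tau1)
  e2 <- exp(-dt / material$tau2)
  for (i in seq_len(n)) {
    if (i > 1) {
      mid <- (tau_dev[i, ] + tau_dev[i - 1, ]) / 2
      h1 <- e1 * h1 + material$C1 * (1 - e1) * mid
      h2 <- e2 * h2 + material$C2 * (1 - e2) * mid
    }
    out[i, ] <- (tau_dev[i, ] - h1 - h2) / J[i]
    if (!is.null(K)) out[i, ] <- out[i, ] + K * (J[i] - 1)
  }
  out
}
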