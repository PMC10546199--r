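## Closed-form photon-transport quantities shared by the SFDI inversion and
## the speckle correction. Unit convention: every length is in mm; the
## wavelength argument is in nm and is converted to mm only when the
## wavenumber k0 = 2*pi*n/lambda is formed. Mixing nm and mm in the dynamic
## attenuation term is the likeliest implementation bug, hence the single
## conversion point in .k0().

.k0 <- function(wavelength, n) 2 * pi * n / (wavelength * 1e-6)

#' Construct an OpticalProperties object
#'
#' @param mua absorption coefficient(s), mm^-1.
#' @param musp reduced scattering coefficient(s), mm^-1.
#' @param wavelength wavelength(s), nm.
#' @return an \linkS4class{OpticalProperties} object.
#' @examples
#' opticalProperties(0.019, 1.07, 660)
#' @export
opticalProperties <- function(mua, musp, wavelength) {
  new("OpticalProperties", mua = as.numeric(mua), musp = as.numeric(musp),
      wavelength = as.numeric(wavelength))
}

#' Diffusion boundary terms for a given refractive index
#'
#' Effective reflection coefficient and boundary coefficient A of the
#' extrapolated-boundary diffusion model for a semi-infinite medium:
#' \deqn{R_{eff} = 0.0636 n + 0.668 + 0.710/n - 1.440/n^2}
#' \deqn{A = (1 - R_{eff}) / (2 (1 + R_{eff}))}
#'
#' @param n refractive index of the medium (> 0); 1.4 is typical soft tissue.
#' @return a \linkS4class{BoundaryTerms} object.
#' @examples
#' boundaryTerms(1.4)
#' @export
boundaryTerms <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
    stop("refractive index 'n' must be a single positive number")
  reff <- 0.0636 * n + 0.668 + 0.710 / n - 1.440 / n^2
  a <- (1 - reff) / (2 * (1 + reff))
  new("BoundaryTerms", n = n, reff = reff, a = a)
}

#' Effective attenuation coefficient in the spatial frequency domain
#'
#' \deqn{\mu_{eff}' = \sqrt{\mu_{eff}^2 + (2\pi f_x)^2}} with
#' \deqn{\mu_{eff} = \sqrt{3 (\mu_a + \tfrac{1}{3}\mu_s' k_0^2\, 6 D_b \tau)\,\mu_{tr}}}
#' where \eqn{k_0 = 2\pi n/\lambda} (lambda converted to mm) and
#' \eqn{\mu_{tr} = \mu_a + \mu_s'}. The dynamic term vanishes at
#' \eqn{\tau = 0} or \eqn{D_b = 0}, leaving the static effective attenuation.
#'
#' All arguments are vectorised with the usual recycling rules.
#'
#' @param mua absorption coefficient, mm^-1.
#' @param musp reduced scattering coefficient, mm^-1.
#' @param fx spatial frequency, mm^-1 (default 0).
#' @param db Brownian diffusion coefficient, mm^2/s (default 0).
#' @param tau correlation lag, s (default 0).
#' @param wavelength wavelength, nm (default 633, the LSI laser line).
#' @param n refractive index (default 1.4).
#' @return effective attenuation, mm^-1.
#' @export
mueffPrime <- function(mua, musp, fx = 0, db = 0, tau = 0,
                       wavelength = 633, n = 1.4) {
  if (is(mua, "OpticalProperties")) {
    op <- mua
    wavelength <- op@wavelength
    musp <- op@musp
    mua <- op@mua
  }
  stopifnot(all(mua > 0), all(musp > 0), all(fx >= 0), all(db >= 0),
            all(tau >= 0))
  mutr <- mua + musp
  muaDyn <- (1 / 3) * musp * .k0(wavelength, n)^2 * 6 * db * tau
  mueff2 <- 3 * (mua + muaDyn) * mutr
  sqrt(mueff2 + (2 * pi * fx)^2)
}

## Internal: normalized g1 for vector tau at fixed medium; a precomputed
## boundary coefficient avoids re-deriving it inside quadrature loops.
.g1n <- function(tau, mua, musp, db, wavelength, n, fx, a) {
  mutr <- mua + musp
  x0 <- mueffPrime(mua, musp, fx = fx, db = db, tau = 0,
                   wavelength = wavelength, n = n) / mutr
  xt <- mueffPrime(mua, musp, fx = fx, db = db, tau = tau,
                   wavelength = wavelength, n = n) / mutr
  ((x0 + 1) * (x0 + 3 * a)) / ((xt + 1) * (xt + 3 * a))
}

#' Normalized field autocorrelation g1(tau)
#'
#' Correlation-diffusion-equation field autocorrelation in the spatial
#' frequency domain, normalized to its tau = 0 value so the illumination
#' power and static prefactor cancel:
#' \deqn{g_1(\tau) = G_1(\tau)/G_1(0) \in (0, 1]}
#' with \eqn{G_1 \propto 3 A \mu_s'/\mu_{tr} / ((\mu_{eff}'/\mu_{tr}+1)(\mu_{eff}'/\mu_{tr}+3A))}.
#'
#' @inheritParams mueffPrime
#' @param tau correlation lag(s), s (vectorised).
#' @return g1 values in (0, 1]; exactly 1 at tau = 0 or db = 0.
#' @export
g1Normalized <- function(tau, mua, musp, db, fx = 0,
                         wavelength = 633, n = 1.4) {
  if (is(mua, "OpticalProperties")) {
    op <- mua
    wavelength <- op@wavelength
    musp <- op@musp
    mua <- op@mua
  }
  a <- boundaryTerms(n)@a
  .g1n(tau, mua, musp, db, wavelength, n, fx, a)
}

#' Diffuse reflectance forward model Rd(fx)
#'
#' Static (tau = 0) spatial-frequency-domain diffusion reflectance of a
#' homogeneous semi-infinite medium:
#' \deqn{R_d = \frac{3 A\, \mu_s'/\mu_{tr}}{(\mu_{eff}'/\mu_{tr} + 1)(\mu_{eff}'/\mu_{tr} + 3A)}}
#' This closed form generates the forward lookup tables used for optical
#' property inversion; it is decreasing in both fx and mua, and at fx = 0 is
#' invariant to a joint rescaling of (mua, musp).
#'
#' @inheritParams mueffPrime
#' @return diffuse reflectance in (0, 1); vectorised.
#' @examples
#' rdForward(0.019, 1.07, fx = 0)    # calibration phantom, planar
#' rdForward(0.019, 1.07, fx = 0.3)  # same medium, AC frequency
#' @export
rdForward <- function(mua, musp, fx = 0, n = 1.4) {
  if (is(mua, "OpticalProperties")) {
    op <- mua
    musp <- op@musp
    mua <- op@mua
  }
  mutr <- mua + musp
  if (any(!is.finite(mutr)) || any(mutr <= 0))
    stop("transport coefficient mua + musp must be finite and > 0")
  a <- boundaryTerms(n)@a
  x <- mueffPrime(mua, musp, fx = fx, n = n) / mutr
  3 * a * (musp / mutr) / ((x + 1) * (x + 3 * a))
}
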