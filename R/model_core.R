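#' ecmwave: travelling waves of tumour invasion into extracellular matrix
#'
#' A minimal model of tumour invasion in which tumour cells (density N)
#' proliferate logistically and move by diffusion obstructed by the
#' extracellular matrix (density M), which they degrade by mass action.
#' In nondimensional form the model reads
#' \deqn{\partial_t N = \partial_x[(1 - M)\,\partial_x N] + (1 - N)N, \qquad
#'       \partial_t M = -\kappa M N,}
#' with a single dimensionless parameter, the rescaled ECM degradation rate
#' \eqn{\kappa}.  The diffusivity \eqn{1 - M} vanishes where the matrix is at
#' maximal density, so the first equation is degenerate parabolic.
#'
#' The package provides three layers of machinery:
#' \itemize{
#'   \item a conservative method-of-lines PDE solver with front tracking and
#'     wave-speed estimation (\code{\link{solve_invasion}},
#'     \code{\link{track_front}}, \code{\link{estimate_speed}});
#'   \item construction of travelling-wave profiles as heteroclinic orbits of
#'     the desingularized phase-space system, by shooting from the unstable
#'     manifold of the invaded state (\code{\link{shoot}},
#'     \code{\link{find_alpha_for_target}},
#'     \code{\link{reconstruct_physical_profile}});
#'   \item characterization of the minimal wave speed
#'     (\code{\link{minimal_speed}}, \code{\link{speed_table}},
#'     \code{\link{g_concavity_check}}, \code{\link{compare_pde_ode}}).
#' }
#'
#' @name ecmwave-package
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Parameters and nondimensionalization
# ---------------------------------------------------------------------------

#' Dimensional model parameters
#'
#' Bundle of the dimensional parameters of the invasion model: tumour-cell
#' diffusivity \code{D_N} (length^2/time), maximal growth rate \code{rho}
#' (1/time), carrying capacity \code{K} (cells/volume), per-cell ECM
#' degradation rate \code{k} (volume/cells/time) and maximal ECM density
#' \code{M_max} (mass/volume).  All must be strictly positive.
#'
#' @param D_N tumour diffusivity in the absence of ECM.
#' @param rho maximal tumour growth rate.
#' @param K tumour carrying capacity.
#' @param k per-cell ECM degradation rate.
#' @param M_max ECM density that blocks all tumour movement.
#' @return an object of class \code{"ecm_dim_params"}.
#' @export
dimensional_params <- function(D_N, rho, K, k, M_max) {
  vals <- list(D_N = D_N, rho = rho, K = K, k = k, M_max = M_max)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("dimensional parameter '", nm, "' must be a strictly positive number",
           call. = FALSE)
  }
  structure(vals, class = "ecm_dim_params")
}

#' Reduce the dimensional model to its single dimensionless parameter
#'
#' Rescaling space, time and the two densities leaves one dimensionless
#' group, the rescaled ECM degradation rate \eqn{\kappa = (K/\rho)\,k}.
#'
#' @param p an \code{"ecm_dim_params"} object from
#'   \code{\link{dimensional_params}}.
#' @return an object of class \code{"ecm_model_params"} with element
#'   \code{kappa}.
#' @examples
#' nondimensionalize(dimensional_params(1, 0.5, 2, 0.25, 1))$kappa  # = 1
#' @export
nondimensionalize <- function(p) {
  stopifnot(inherits(p, "ecm_dim_params"))
  model_params(kappa = (p$K / p$rho) * p$k)
}

#' Dimensionless model parameters
#'
#' @param kappa rescaled ECM degradation rate, strictly positive.
#' @return an object of class \code{"ecm_model_params"}.
#' @export
model_params <- function(kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa <= 0)
    stop("'kappa' must be a strictly positive number", call. = FALSE)
  structure(list(kappa = kappa), class = "ecm_model_params")
}

# ---------------------------------------------------------------------------
# Steady states
# ---------------------------------------------------------------------------

#' Spatially homogeneous steady states of the model
#'
#' The model has the trivial state (0,0), the fully invaded state (1,0), the
#' tumour-free state at maximal ECM density (0,1), and a continuum of
#' tumour-free states (0, M) for M in [0,1).  The continuum is returned as a
#' sampler function; calling \code{steady_states(M_bar = 0.3)} instantiates
#' the member (0, 0.3).
#'
#' @param M_bar optional far-field ECM density in [0,1) at which to sample
#'   the tumour-free family.
#' @return a list with \code{states}, a data frame of the isolated states
#'   (columns \code{N}, \code{M}, \code{label}), and \code{family}, a
#'   function of \code{M_bar} returning a one-row data frame; if
#'   \code{M_bar} is supplied, also \code{sample}, the instantiated family
#'   member.
#' @export
steady_states <- function(M_bar = NULL) {
  states <- data.frame(
    N = c(0, 1, 0),
    M = c(0, 0, 1),
    label = c("trivial", "invaded", "tumour_free_max"),
    stringsAsFactors = FALSE
  )
  family <- function(M_bar) {
    if (!is.numeric(M_bar) || length(M_bar) != 1L || M_bar < 0 || M_bar >= 1)
      stop("the tumour-free family (0, M) is defined for M in [0, 1)",
           call. = FALSE)
    data.frame(N = 0, M = M_bar, label = "tumour_free_partial",
               stringsAsFactors = FALSE)
  }
  out <- list(states = states, family = family)
  if (!is.null(M_bar)) out$sample <- family(M_bar)
  out
}

# ---------------------------------------------------------------------------
# Desingularized vector field Jacobians (shared with the shooting module)
# ---------------------------------------------------------------------------

#' Jacobian of the desingularized travelling-wave system
#'
#' The desingularized first-order system in (n, p, m) is
#' \deqn{n' = p,\quad p' = -cp - (1-n)n(1-m),\quad m' = (\kappa/c) m(1-m) n.}
#' This returns its Jacobian matrix at an arbitrary state, used for the
#' equilibrium spectra and as the reference object for eigen-relation checks.
#'
#' @param state numeric vector \code{c(n, p, m)}.
#' @param c wave speed, positive.
#' @param kappa ECM degradation rate, positive.
#' @return a 3x3 numeric matrix.
#' @export
jacobian_desingularized <- function(state, c, kappa) {
  stopifnot(length(state) == 3L, c > 0, kappa > 0)
  n <- state[[1]]; m <- state[[3]]
  rbind(
    c(0, 1, 0),
    c(-(1 - 2 * n) * (1 - m), -c, (1 - n) * n),
    c((kappa / c) * m * (1 - m), 0, (kappa / c) * (1 - 2 * m) * n)
  )
}

# ---------------------------------------------------------------------------
# Equilibrium spectra
# ---------------------------------------------------------------------------

#' Spectrum of the invaded state (1, 0, 0)
#'
#' At the invaded equilibrium the desingularized system has eigenvalues
#' \eqn{\lambda_1 = (-c - \sqrt{c^2+4})/2 < 0},
#' \eqn{\lambda_2 = (-c + \sqrt{c^2+4})/2 > 0} and
#' \eqn{\lambda_3 = \kappa/c > 0}: a hyperbolic saddle with a two-dimensional
#' unstable manifold spanned by the eigenvectors of \eqn{\lambda_2} and
#' \eqn{\lambda_3}.  Heteroclinic trajectories must leave through this plane,
#' which is what makes a one-parameter shooting problem possible.
#'
#' Eigenvectors for \eqn{\lambda_{1,2}} are normalized to unit second
#' component, and the third to unit norm.
#'
#' @param c wave speed, positive.
#' @param kappa ECM degradation rate, positive.
#' @return an object of class \code{"ecm_spectrum"}: list with
#'   \code{eigenvalues} (length 3), \code{eigenvectors} (3x3 matrix, one
#'   eigenvector per column), and \code{mu = min(lambda2, lambda3)}, the gap
#'   exponent controlling the truncation error of the unstable-manifold
#'   expansion.
#' @export
spectrum_invaded <- function(c, kappa) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("wave speed 'c' must be strictly positive", call. = FALSE)
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop("'kappa' must be strictly positive", call. = FALSE)
  s <- sqrt(c^2 + 4)
  l1 <- (-c - s) / 2
  l2 <- (-c + s) / 2
  l3 <- kappa / c
  vecs <- cbind(
    c((c - s) / 2, 1, 0),
    c((c + s) / 2, 1, 0),
    c(0, 0, 1)
  )
  colnames(vecs) <- paste0("v", 1:3)
  structure(list(
    eigenvalues = c(lambda1 = l1, lambda2 = l2, lambda3 = l3),
    eigenvectors = vecs,
    mu = min(l2, l3),
    equilibrium = c(n = 1, p = 0, m = 0),
    c = c, kappa = kappa
  ), class = "ecm_spectrum")
}

#' Spectrum of a tumour-free state (0, 0, m)
#'
#' For m in [0,1) the equilibrium (0, 0, m) is non-hyperbolic, with
#' eigenvalues \eqn{\lambda_{1,2} = (-c \pm \sqrt{c^2 - 4(1-m)})/2} and
#' \eqn{\lambda_3 = 0} (the centre direction along the equilibrium family).
#' The pair is complex exactly when \eqn{c < 2\sqrt{1-m}}: the state is then
#' a stable spiral in the (n, p) directions, so approaching trajectories must
#' oscillate through n = 0 and no non-negative wave can connect to it.  This
#' transition is the origin of the lower speed bound.
#'
#' @param c wave speed, positive.
#' @param m_bar1 ECM density of the equilibrium, in [0, 1).
#' @return an object of class \code{"ecm_spectrum"} with an additional
#'   logical element \code{complex_pair}; when the pair is complex the
#'   \code{eigenvalues} vector is complex-valued.
#' @export
spectrum_tumour_free <- function(c, m_bar1) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("wave speed 'c' must be strictly positive", call. = FALSE)
  if (!is.numeric(m_bar1) || length(m_bar1) != 1L || m_bar1 < 0 || m_bar1 >= 1)
    stop("'m_bar1' must lie in [0, 1); the degenerate family (n, 0, 1) is ",
         "not a travelling-wave end state", call. = FALSE)
  disc <- c^2 - 4 * (1 - m_bar1)
  if (disc >= 0) {
    sq <- sqrt(disc)
    ev <- c(lambda1 = (-c - sq) / 2, lambda2 = (-c + sq) / 2, lambda3 = 0)
    complex_pair <- FALSE
  } else {
    sq <- sqrt(as.complex(disc))
    ev <- c(lambda1 = (-c - sq) / 2, lambda2 = (-c + sq) / 2,
            lambda3 = 0 + 0i)
    complex_pair <- TRUE
  }
  structure(list(
    eigenvalues = ev,
    complex_pair = complex_pair,
    equilibrium = c(n = 0, p = 0, m = m_bar1),
    c = c, m_bar1 = m_bar1
  ), class = "ecm_spectrum")
}

# ---------------------------------------------------------------------------
# Analytic thresholds and speed bounds
# ---------------------------------------------------------------------------

#' Critical degradation rate, critical far-field density and speed bounds
#'
#' For far-field ECM density \eqn{\bar m \in (0,1)} the critical degradation
#' rate is \eqn{\kappa^*(\bar m) = (1-\bar m)/\bar m}; equivalently, for a
#' given \eqn{\kappa} the critical far-field density is
#' \eqn{m^*(\kappa) = 1/(\kappa+1)}.  For \eqn{\kappa \le \kappa^*(\bar m)}
#' the effective reaction term seen by the wave is concave at the leading
#' edge and the minimal wave speed takes the linear-spreading value
#' \eqn{2\sqrt{1-\bar m}}; beyond the threshold it may exceed it.  In all
#' cases the minimal speed lies in \eqn{[2\sqrt{1-\bar m},\, 2]}.
#'
#' At \eqn{\bar m = 0} every \eqn{\kappa} is subcritical and
#' \code{kappa_star} is returned as \code{Inf}.
#'
#' @param kappa ECM degradation rate, positive.
#' @param m_bar far-field ECM density, in [0, 1).
#' @return an object of class \code{"ecm_thresholds"}: list with
#'   \code{kappa_star}, \code{m_star}, \code{c_lower}, \code{c_upper}.
#' @examples
#' th <- thresholds(1, 0.5)
#' th$kappa_star  # 1
#' th$m_star      # 0.5
#' @export
thresholds <- function(kappa, m_bar) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop("'kappa' must be strictly positive", call. = FALSE)
  if (!is.numeric(m_bar) || length(m_bar) != 1L || m_bar < 0 || m_bar >= 1)
    stop("'m_bar' must lie in [0, 1)", call. = FALSE)
  structure(list(
    kappa_star = if (m_bar == 0) Inf else (1 - m_bar) / m_bar,
    m_star = 1 / (kappa + 1),
    c_lower = 2 * sqrt(1 - m_bar),
    c_upper = 2,
    kappa = kappa, m_bar = m_bar
  ), class = "ecm_thresholds")
}

#' @export
print.ecm_spectrum <- function(x, ...) {
  cat("Equilibrium spectrum at (",
      paste(signif(x$equilibrium, 6), collapse = ", "), ")\n", sep = "")
  print(x$eigenvalues)
  if (isTRUE(x$complex_pair))
    cat("leading pair is complex: stable spiral, no non-negative connection\n")
  invisible(x)
}

#' @export
print.ecm_thresholds <- function(x, ...) {
  cat("kappa* =", x$kappa_star, " m* =", x$m_star,
      "\nminimal-speed bounds: [", x$c_lower, ",", x$c_upper, "]\n")
  invisible(x)
}
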