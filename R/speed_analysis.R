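# Characterization of the minimal wave speed c*_kappa(m_bar) by nested
# bisection: the outer loop bisects the speed, the inner loop (inside
# find_alpha_for_target) bisects the shooting parameter.  A speed is feasible
# when an admissible orbit with n > 0 connecting (1,0,0) to (0,0,m_bar)
# exists.

#' Minimal wave speed for a far-field ECM density
#'
#' Bisects the wave speed on the analytic bracket
#' \eqn{[2\sqrt{1-\bar m},\, 2]}.  The lower end is the linear-spreading
#' bound: below it the target equilibrium is a stable spiral and no
#' non-negative wave exists.  The upper end is always feasible.  A probe
#' speed is feasible iff \code{\link{find_alpha_for_target}} finds an
#' admissible orbit.  For \eqn{\kappa \le \kappa^*(\bar m)} the returned
#' speed equals the lower end to within \code{tol_c}; above the threshold a
#' positive margin opens up (resolvable once \eqn{\kappa} is well above
#' \eqn{\kappa^*}; see the vignette for the resolution floor).
#'
#' For \code{m_bar = 0} the Fisher-type value 2 is returned without search.
#'
#' @param kappa ECM degradation rate, positive.
#' @param m_bar far-field ECM density, in [0, 1).
#' @param tol_c bisection tolerance on the speed (default 1e-3).
#' @return an object of class \code{"ecm_minimal_speed"}: list with
#'   \code{c_star}, \code{bracket} (final infeasible/feasible pair),
#'   \code{alpha_at_cstar}, \code{m_bar}, \code{kappa}, \code{tol_c},
#'   \code{c_lower}, \code{margin = c_star - c_lower}.
#' @export
minimal_speed <- function(kappa, m_bar, tol_c = 1e-3) {
  if (!is.numeric(m_bar) || m_bar < 0 || m_bar >= 1)
    stop("'m_bar' must lie in [0, 1)", call. = FALSE)
  if (kappa <= 0) stop("'kappa' must be strictly positive", call. = FALSE)
  if (m_bar == 0) {
    return(structure(list(c_star = 2, bracket = c(NA_real_, 2),
                          alpha_at_cstar = 0, m_bar = 0, kappa = kappa,
                          tol_c = tol_c, c_lower = 2, margin = 0),
                     class = "ecm_minimal_speed"))
  }
  lo <- 2 * sqrt(1 - m_bar)
  hi <- 2
  f_hi <- find_alpha_for_target(hi, kappa, m_bar)
  if (!f_hi$feasible)
    stop("no admissible orbit found at c = 2, which always exists: ",
         "solver misconfiguration", call. = FALSE)
  alpha_feas <- f_hi$alpha
  while (hi - lo > tol_c) {
    mid <- (lo + hi) / 2
    f <- find_alpha_for_target(mid, kappa, m_bar)
    if (f$feasible) { hi <- mid; alpha_feas <- f$alpha } else lo <- mid
  }
  structure(list(c_star = (lo + hi) / 2, bracket = c(lo, hi),
                 alpha_at_cstar = alpha_feas, m_bar = m_bar, kappa = kappa,
                 tol_c = tol_c, c_lower = 2 * sqrt(1 - m_bar),
                 margin = (lo + hi) / 2 - 2 * sqrt(1 - m_bar)),
            class = "ecm_minimal_speed")
}

#' @export
print.ecm_minimal_speed <- function(x, ...) {
  cat(sprintf("c*(kappa = %g, m_bar = %g) = %.5f  (bounds [%.5f, 2], tol %g)\n",
              x$kappa, x$m_bar, x$c_star, x$c_lower, x$tol_c))
  invisible(x)
}

#' PDE-selected and ODE-minimal speeds over a parameter sweep
#'
#' For every pair (kappa, M_bar) runs the PDE simulation and fits the front
#' speed; for M_bar < 1 also computes the ODE minimal speed.  Solver errors
#' in a cell are caught, recorded and the sweep continues.  Monotonicity
#' flags summarize the two structural properties of the speed surface: the
#' PDE speed decreases along M_bar at fixed kappa and increases along kappa
#' at fixed M_bar.
#'
#' @param kappa_list,m_bar_list non-empty numeric vectors.
#' @param dx,t_end PDE discretization and final time.
#' @param tol_c tolerance for the ODE minimal-speed bisections.
#' @return data frame with columns \code{kappa}, \code{M_bar}, \code{c_pde},
#'   \code{c_ode}, \code{note}; monotonicity flags are attached as
#'   attributes \code{decreasing_in_M} and \code{increasing_in_kappa}.
#' @export
speed_table <- function(kappa_list, m_bar_list, dx = 0.1, t_end = 100,
                        tol_c = 1e-3) {
  if (!length(kappa_list) || !length(m_bar_list))
    stop("parameter lists must be non-empty", call. = FALSE)
  grid <- expand.grid(kappa = kappa_list, M_bar = m_bar_list,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    kap <- grid$kappa[i]; mb <- grid$M_bar[i]
    c_pde <- NA_real_; c_ode <- NA_real_; note <- ""
    pde <- try({
      sol <- solve_invasion(ic_params(M_bar = mb), kap, t_end = t_end, dx = dx)
      estimate_speed(track_front(sol))$c_hat
    }, silent = TRUE)
    if (inherits(pde, "try-error")) note <- paste0("pde: ", attr(pde, "condition")$message)
    else c_pde <- pde
    if (mb < 1) {
      ode <- try(minimal_speed(kap, mb, tol_c = tol_c)$c_star, silent = TRUE)
      if (inherits(ode, "try-error"))
        note <- paste(note, "ode:", attr(ode, "condition")$message)
      else c_ode <- ode
    }
    data.frame(kappa = kap, M_bar = mb, c_pde = c_pde, c_ode = c_ode,
               note = note, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  dec_M <- vapply(unique(tab$kappa), function(k) {
    v <- tab$c_pde[tab$kappa == k][order(tab$M_bar[tab$kappa == k])]
    v <- v[!is.na(v)]
    length(v) < 2 || all(diff(v) < 0)
  }, logical(1))
  inc_k <- vapply(unique(tab$M_bar), function(m) {
    v <- tab$c_pde[tab$M_bar == m][order(tab$kappa[tab$M_bar == m])]
    v <- v[!is.na(v)]
    length(v) < 2 || all(diff(v) > -2e-2 * v[-length(v)])
  }, logical(1))
  attr(tab, "decreasing_in_M") <- stats::setNames(dec_M, unique(tab$kappa))
  attr(tab, "increasing_in_kappa") <- stats::setNames(inc_k, unique(tab$M_bar))
  tab
}

#' Concavity of the effective leading-edge reaction term
#'
#' Along an admissible wave the ECM density is a function M(n) of the tumour
#' density, and the wave solves a generalized Fisher-type problem with
#' effective reaction \eqn{g(n) = (1-n)\,n\,(1 - M(n))}, with
#' \eqn{M(0) = \bar m} and \eqn{M(1) = 0}.  The sign of \eqn{g''(0)}
#' separates the regime where the minimal speed takes the linear value
#' \eqn{2\sqrt{g'(0)} = 2\sqrt{1-\bar m}} (concave at the edge,
#' \eqn{\kappa \le \kappa^*(\bar m) = (1-\bar m)/\bar m}) from the regime
#' where a faster minimal speed can be selected.  This check builds M(n)
#' parametrically from a shooting trajectory at (c, kappa, m_bar), forms g,
#' and estimates \eqn{g''(0)} by one-sided second differences at a ladder of
#' steps with Richardson extrapolation (g exists only for n >= 0).
#'
#' @param kappa ECM degradation rate.
#' @param m_bar far-field ECM density, in (0, 1).
#' @param c wave speed at which to construct the trajectory.
#' @param steps base step ladder for the one-sided differences.
#' @param Mn optional function M(n) to use instead of building one from a
#'   shooting trajectory (e.g. the frozen-ECM profile
#'   \code{function(n) m_bar}, for which g''(0) = -2(1 - m_bar) exactly).
#' @return an object of class \code{"ecm_g_concavity"}: list with
#'   \code{g2_0} (the extrapolated second derivative at 0), \code{sign},
#'   \code{kappa_star}, \code{subcritical} (is kappa <= kappa*),
#'   \code{consistent} (does sign(g''(0)) < 0 match subcriticality), and the
#'   raw ladder estimates.
#' @export
g_concavity_check <- function(kappa, m_bar, c,
                              steps = c(1e-2, 5e-3, 2.5e-3), Mn = NULL) {
  if (m_bar <= 0 || m_bar >= 1)
    stop("'m_bar' must lie strictly inside (0, 1)", call. = FALSE)
  if (is.null(Mn)) {
    f <- find_alpha_for_target(c, kappa, m_bar, dense = TRUE)
    if (!f$feasible)
      stop("no admissible trajectory at these parameters; the check is not ",
           "applicable", call. = FALSE)
    traj <- f$result$trajectory
    n <- traj$n; m <- traj$m
    if (any(diff(n) > 0))
      stop("non-monotone n along the trajectory; cannot invert n -> y",
           call. = FALSE)
    # M(n): monotone interpolation of m against n (n decreasing along y)
    Mn <- stats::approxfun(rev(n), rev(m), yleft = m_bar, yright = 0)
  }
  g <- function(nn) (1 - nn) * nn * (1 - Mn(nn))
  ladder <- vapply(steps, function(h) (g(2 * h) - 2 * g(h)) / h^2, numeric(1))
  # one-sided second difference has O(h) error: Richardson with ratio 2
  r1 <- ladder[-1] + diff(ladder) # 2*f(h/2) - f(h)
  g2 <- if (length(r1) >= 2) r1[length(r1)] + (r1[2] - r1[1]) else r1[1]
  ks <- (1 - m_bar) / m_bar
  structure(list(g2_0 = g2, sign = sign(g2), kappa_star = ks,
                 subcritical = kappa <= ks,
                 consistent = (kappa <= ks) == (g2 < 0),
                 ladder = stats::setNames(ladder, steps),
                 c = c, kappa = kappa, m_bar = m_bar),
            class = "ecm_g_concavity")
}

#' @export
print.ecm_g_concavity <- function(x, ...) {
  cat(sprintf("g''(0) = %.4f at (kappa = %g, m_bar = %g, c = %g); kappa* = %g\n",
              x$g2_0, x$kappa, x$m_bar, x$c, x$kappa_star))
  cat(if (x$consistent) "sign agrees with the kappa <= kappa* criterion\n"
      else "sign DISAGREES with the kappa <= kappa* criterion\n")
  invisible(x)
}

#' Align the PDE front profile with the shooting-constructed wave
#'
#' Runs the PDE to \code{t_end}, estimates the selected speed, constructs
#' the travelling wave at that speed by shooting (targeting m_bar = M_bar
#' for M_bar < 1, or the orbit into (0, 0, 1) for M_bar = 1), anchors both
#' profiles at their N = 0.5 crossing and reports sup-norm and L2
#' discrepancies for both fields over the overlap window.  If the estimated
#' speed falls below the minimal speed by estimation error, the shooting is
#' retried at the speed inflated by 2 percent and the report is flagged.
#'
#' @param kappa ECM degradation rate.
#' @param M_bar far-field ECM density in [0, 1].
#' @param dx,t_end PDE discretization and final time.
#' @param half_width half-width (in xi) of the comparison window around the
#'   front (default 30).
#' @return an object of class \code{"ecm_pde_ode_comparison"}: list with
#'   \code{c_hat}, \code{sup_N}, \code{sup_M}, \code{l2_N}, \code{l2_M},
#'   \code{retried}, plus the aligned profiles.
#' @export
compare_pde_ode <- function(kappa, M_bar, dx = 0.1, t_end = 100,
                            half_width = 30) {
  if (M_bar < 0 || M_bar > 1) stop("'M_bar' must lie in [0, 1]", call. = FALSE)
  sol <- solve_invasion(ic_params(M_bar = M_bar), kappa, t_end = t_end,
                        dx = dx)
  c_hat <- estimate_speed(track_front(sol))$c_hat

  wave_at <- function(cc) {
    if (M_bar < 1) {
      f <- find_alpha_for_target(cc, kappa, M_bar, dense = TRUE)
      if (!f$feasible) return(NULL)
      f$result
    } else {
      find_alpha1(cc, kappa)$result
    }
  }
  retried <- FALSE
  shot_res <- wave_at(c_hat)
  if (is.null(shot_res)) {
    retried <- TRUE
    shot_res <- wave_at(c_hat * 1.02)
    if (is.null(shot_res))
      stop("shooting infeasible at the estimated speed even after a 2% ",
           "inflation", call. = FALSE)
  }
  ode_prof <- reconstruct_physical_profile(shot_res)

  # PDE profile at the final stored time, centred at its N = 0.5 crossing
  i_last <- length(sol$times)
  Npde <- sol$N[i_last, ]; Mpde <- sol$M[i_last, ]
  tr <- track_front(sol)
  x_half <- tr$X[i_last]
  if (is.na(x_half)) stop("PDE front has no N = 0.5 crossing at t_end",
                          call. = FALSE)
  xi_pde <- sol$x - x_half

  grid <- seq(-half_width, half_width, by = sol$dx)
  # clamp to the supported ranges; outside the ODE trajectory the wave is at
  # its asymptotic states
  ode_N <- stats::approx(ode_prof$xi, ode_prof$N, xout = grid,
                         yleft = 1, yright = 0)$y
  ode_M <- stats::approx(ode_prof$xi, ode_prof$M, xout = grid,
                         yleft = 0, yright = attr(ode_prof, "m_bar"))$y
  pde_N <- stats::approx(xi_pde, Npde, xout = grid, rule = 2)$y
  pde_M <- stats::approx(xi_pde, Mpde, xout = grid, rule = 2)$y

  dN <- pde_N - ode_N; dM <- pde_M - ode_M
  structure(list(kappa = kappa, M_bar = M_bar, c_hat = c_hat,
                 retried = retried,
                 sup_N = max(abs(dN)), sup_M = max(abs(dM)),
                 l2_N = sqrt(mean(dN^2)), l2_M = sqrt(mean(dM^2)),
                 grid = grid, pde_N = pde_N, pde_M = pde_M,
                 ode_N = ode_N, ode_M = ode_M),
            class = "ecm_pde_ode_comparison")
}

#' @export
print.ecm_pde_ode_comparison <- function(x, ...) {
  cat(sprintf("PDE vs ODE wave at kappa = %g, M_bar = %g (c_hat = %.4f%s)\n",
              x$kappa, x$M_bar, x$c_hat,
              if (x$retried) ", shooting retried at +2%" else ""))
  cat(sprintf("  sup|dN| = %.4f  sup|dM| = %.4f  l2(N) = %.4f  l2(M) = %.4f\n",
              x$sup_N, x$sup_M, x$l2_N, x$l2_M))
  invisible(x)
}
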