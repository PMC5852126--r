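# Equilibrium and bifurcation analysis, built on the scalar reduction of the
# fixed-point system: at an equilibrium the gates sit on their steady-state
# curves (h = h_inf(V), n = n_inf(V), H = H_inf(V)), so fixed points are the
# roots in V of
#   F(V) = A(V) + gh * B(V) + Iapp = 0
# with A(V) the gh-independent current balance and B(V) = -H_inf(V)(V - Eh).
# F is linear in both gh and Iapp, which makes folds (F = 0, dF/dV = 0)
# solvable as a single scalar root find and the two-parameter fold curve
# explicit in V.

# A, B and their V-derivatives for the scalar-reduced equilibrium equation.
eq_reduction <- function(V, p) {
  gd <- gating_rates_d(V)
  g <- gd$g
  m3 <- g$m_inf^3
  A <- -p[["gNa"]] * m3 * g$h_inf * (V - p[["ENa"]]) -
    p[["gK"]] * g$n_inf^4 * (V - p[["EK"]]) -
    p[["gL"]] * (V - p[["EL"]])
  dA <- -p[["gNa"]] * ((3 * g$m_inf^2 * gd$d_m_inf * g$h_inf +
                          m3 * gd$d_h_inf) * (V - p[["ENa"]]) + m3 * g$h_inf) -
    p[["gK"]] * (4 * g$n_inf^3 * gd$d_n_inf * (V - p[["EK"]]) + g$n_inf^4) -
    p[["gL"]]
  B <- -g$H_inf * (V - p[["Eh"]])
  dB <- -(gd$d_H_inf * (V - p[["Eh"]]) + g$H_inf)
  list(A = A, dA = dA, B = B, dB = dB, g = g)
}

eq_F <- function(V, p) {
  r <- eq_reduction(V, p)
  r$A + p[["gh"]] * r$B + p[["Iapp"]]
}

# Build the full equilibrium object at a refined root V.
equilibrium_at <- function(V, p) {
  g <- gating_rates(V)
  s <- c(V = V, h = g$h_inf, n = g$n_inf, H = g$H_inf)
  ev <- eigen(ih_jacobian(s, p), only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  structure(list(state = s, eigenvalues = ev,
                 etype = classify_eigenvalues(ev),
                 stable = max(Re(ev)) < 0),
            class = "ih_equilibrium")
}

#' @export
print.ih_equilibrium <- function(x, ...) {
  cat(sprintf("equilibrium: V = %.6f mV, type %s\n", x$state[["V"]], x$etype))
  cat("eigenvalues (1/ms):", format(x$eigenvalues, digits = 6), "\n")
  invisible(x)
}

# Node / focus / saddle classification from eigenvalues. The leading pair
# (two largest real parts) decides node vs focus; a saddle has all-real
# eigenvalues of mixed sign.
classify_eigenvalues <- function(ev, im_tol = 1e-9) {
  ev <- ev[order(-Re(ev))]
  all_real <- all(abs(Im(ev)) < im_tol)
  if (all_real && max(Re(ev)) > 0 && min(Re(ev)) < 0) return("saddle")
  focus <- any(abs(Im(ev[1:2])) >= im_tol)
  paste0(if (max(Re(ev)) < 0) "stable_" else "unstable_",
         if (focus) "focus" else "node")
}

#' Find all equilibria of the model
#'
#' Reduces the fixed-point system to a scalar equation in V (the gates are
#' explicit functions of V at equilibrium), scans V for sign changes of the
#' current balance on a fine grid, refines each root, and classifies every
#' equilibrium by the eigenvalues of the analytic Jacobian. The model has
#' one or three equilibria in the studied parameter window.
#'
#' @param p parameters from [ih_params()]
#' @param V_range scan interval (mV)
#' @param V_step scan grid spacing (mV)
#' @return list of \code{ih_equilibrium} objects ordered by increasing V,
#'   each with fields \code{state}, \code{eigenvalues}, \code{etype}
#'   (stable_node, stable_focus, unstable_node, unstable_focus, saddle),
#'   and \code{stable}
#' @export
#' @examples
#' eqs <- find_equilibria(ih_params(Iapp = 0.08, gh = 0.02))
#' vapply(eqs, function(e) e$etype, "")
find_equilibria <- function(p, V_range = c(-100, 0), V_step = 0.01) {
  Vg <- seq(V_range[1], V_range[2], by = V_step)
  Fv <- eq_F(Vg, p)
  roots <- numeric(0)
  iz <- which(Fv == 0)
  roots <- c(roots, Vg[iz])
  sc <- which(Fv[-length(Fv)] * Fv[-1] < 0)
  for (i in sc) {
    r <- stats::uniroot(function(v) eq_F(v, p), c(Vg[i], Vg[i + 1]),
                        tol = 1e-13)
    roots <- c(roots, r$root)
  }
  lapply(sort(roots), equilibrium_at, p = p)
}

# Lower-branch equilibrium (smallest V). Returns NULL when absent is not
# possible here: there is always at least one root.
lower_equilibrium <- function(p) {
  find_equilibria(p)[[1]]
}

# ---- codim-1 conditions at fixed Iapp --------------------------------------

# Fold condition via the scalar reduction: at a fold F and dF/dV vanish
# simultaneously. Since F is linear in gh, eliminating gh gives the scalar
# condition G(V) = dA(V) + gh1(V) dB(V) with gh1(V) = -(A(V) + Iapp)/B(V).
fold_G <- function(V, p) {
  r <- eq_reduction(V, p)
  gh1 <- -(r$A + p[["Iapp"]]) / r$B
  list(G = r$dA + gh1 * r$dB, gh = gh1)
}

#' Locate folds (saddle-node points) of the equilibrium set at fixed Iapp
#'
#' Solves the simultaneous conditions (zero current balance, zero slope of
#' the scalar-reduced balance, equivalent to a zero eigenvalue of the full
#' Jacobian) by eliminating gh and root-finding in V. Returns every fold
#' whose gh lies in \code{gh_range}.
#'
#' @param p parameters (Iapp is taken from p; gh is ignored)
#' @param gh_range admissible gh interval (mS/cm2)
#' @param V_range,V_step scan window in V (mV)
#' @return data.frame with columns \code{gh}, \code{V}
#' @export
find_folds <- function(p, gh_range = c(0, 0.2), V_range = c(-100, -20),
                       V_step = 0.005) {
  Vg <- seq(V_range[1], V_range[2], by = V_step)
  fg <- fold_G(Vg, p)
  ok <- is.finite(fg$G)
  Vg <- Vg[ok]; G <- fg$G[ok]
  sc <- which(G[-length(G)] * G[-1] < 0)
  out <- data.frame(gh = numeric(0), V = numeric(0))
  for (i in sc) {
    r <- stats::uniroot(function(v) fold_G(v, p)$G, c(Vg[i], Vg[i + 1]),
                        tol = 1e-13)
    gh <- fold_G(r$root, p)$gh
    if (gh >= gh_range[1] && gh <= gh_range[2])
      out <- rbind(out, data.frame(gh = gh, V = r$root))
  }
  out[order(out$gh), , drop = FALSE]
}

# max Re over the leading complex pair of the lower-branch equilibrium;
# NA when the leading pair is real (no Hopf condition defined there).
lower_branch_pair <- function(p, gh) {
  p[["gh"]] <- gh
  eq <- lower_equilibrium(p)
  ev <- eq$eigenvalues
  list(re = Re(ev[1]), complex_pair = abs(Im(ev[1])) > 1e-9, eq = eq)
}

# Bisect a sign/indicator change of fun(gh) in [lo, hi] to tolerance tol.
bisect_gh <- function(fun, lo, hi, tol = 1e-9) {
  flo <- fun(lo)
  fhi <- fun(hi)
  if (flo == fhi) stop("bisection bracket does not straddle the event")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fun(mid) == flo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' One-parameter bifurcation sweep in gh at fixed Iapp
#'
#' Tracks all equilibrium branches over a gh grid, classifying each point,
#' and detects and refines the codim-1 events of the lower (resting) branch:
#' folds (zero eigenvalue; solved via the scalar reduction), Hopf points
#' (sign change of the real part of the leading complex pair; bisected to
#' 1e-9 in gh), and node-focus (NF) transitions (real-to-complex change of
#' the leading pair, bisected likewise).
#'
#' @param p parameters (Iapp from p)
#' @param gh_range sweep interval (mS/cm2)
#' @param n_grid number of grid points
#' @return list with \code{branches} (data.frame gh, V, etype, stable) and
#'   \code{points} (data.frame kind, gh, V) where kind is one of
#'   \code{"fold"}, \code{"hopf"}, \code{"nf"}
#' @export
#' @examples
#' sw <- sweep_1d(ih_params(Iapp = 0.08), gh_range = c(0, 0.05), n_grid = 101)
#' sw$points
sweep_1d <- function(p, gh_range = c(0, 0.1), n_grid = 201) {
  ghs <- seq(gh_range[1], gh_range[2], length.out = n_grid)
  rows <- list()
  lower <- vector("list", n_grid)
  for (i in seq_along(ghs)) {
    pi <- p
    pi[["gh"]] <- ghs[i]
    eqs <- find_equilibria(pi)
    lower[[i]] <- eqs[[1]]
    for (e in eqs)
      rows[[length(rows) + 1]] <- data.frame(
        gh = ghs[i], V = e$state[["V"]], etype = e$etype, stable = e$stable)
  }
  branches <- do.call(rbind, rows)

  points <- data.frame(kind = character(0), gh = numeric(0), V = numeric(0))
  folds <- find_folds(p, gh_range = gh_range)
  if (nrow(folds))
    points <- rbind(points, data.frame(kind = "fold", gh = folds$gh,
                                       V = folds$V))
  # Hopf and NF events on the lower branch between consecutive grid points
  for (i in seq_len(n_grid - 1)) {
    e1 <- lower[[i]]$eigenvalues[1]
    e2 <- lower[[i + 1]]$eigenvalues[1]
    c1 <- abs(Im(e1)) > 1e-9
    c2 <- abs(Im(e2)) > 1e-9
    if (c1 != c2) {
      gh_nf <- bisect_gh(function(g) lower_branch_pair(p, g)$complex_pair,
                         ghs[i], ghs[i + 1])
      points <- rbind(points, data.frame(
        kind = "nf", gh = gh_nf,
        V = lower_branch_pair(p, gh_nf)$eq$state[["V"]]))
    }
    if (c1 && c2 && sign(Re(e1)) != sign(Re(e2))) {
      gh_h <- bisect_gh(function(g) sign(lower_branch_pair(p, g)$re) > 0,
                        ghs[i], ghs[i + 1])
      points <- rbind(points, data.frame(
        kind = "hopf", gh = gh_h,
        V = lower_branch_pair(p, gh_h)$eq$state[["V"]]))
    }
  }
  # A fold makes the lowest-V equilibrium jump branches; a Hopf/NF indicator
  # flip bisected across that jump converges onto the fold itself. Drop
  # those artifacts.
  if (nrow(folds) && nrow(points)) {
    spurious <- points$kind != "fold" &
      vapply(points$gh, function(g) any(abs(g - folds$gh) < 5e-8), TRUE)
    points <- points[!spurious, , drop = FALSE]
  }
  list(branches = branches, points = points[order(points$gh), , drop = FALSE])
}

# ---- limit-cycle existence by simulation -----------------------------------

# Does a stable large-amplitude cycle persist at these parameters, starting
# from `state` (a point on or near the firing attractor)? Operational test:
# simulate `window` ms and require at least 2 spikes in the second half, so
# that a decaying transient that fires once or twice before settling to rest
# is not mistaken for sustained firing.
cycle_persists <- function(p, state, window = 2000, dt = 0.001) {
  run <- run_spike_train(p, stim_protocol("constant"), state,
                         t_end = window, dt = dt)
  sp <- run$spikes
  list(persists = sum(sp > window / 2) >= 2, state = run$state)
}

# A state on the firing attractor at parameters p (must be in the firing
# regime): long settle run, return final state.
firing_state <- function(p, t_settle = 1500, dt = 0.001) {
  x0 <- c(V = -55, h = 0.6, n = 0.3, H = 0.2)
  run <- run_spike_train(p, stim_protocol("constant"), x0,
                         t_end = t_settle, dt = dt)
  if (length(run$spikes) < 2)
    stop("parameters do not appear to lie in the firing regime")
  run$state
}

#' Lower boundary of stable limit-cycle existence (hysteresis bisection)
#'
#' Locates the gh value at fixed Iapp below which the large stable limit
#' cycle ceases to exist (the big saddle-homoclinic boundary, or the fold
#' itself in the SNIC case). Starting on the firing attractor at the top of
#' the bracket, gh is stepped down by bisection, each trial continuing from
#' the most recent cycle state, and spiking persistence is tested over a
#' simulation window.
#'
#' @param p parameters (Iapp from p)
#' @param gh_bracket interval straddling cycle existence (cycle must exist
#'   at the upper end and not at the lower end)
#' @param tol bisection tolerance in gh (mS/cm2)
#' @param window persistence-test window (ms)
#' @param dt integration step (ms)
#' @return the boundary gh (mS/cm2)
#' @export
locate_cycle_boundary <- function(p, gh_bracket, tol = 1e-6,
                                  window = 2000, dt = 0.001) {
  lo <- gh_bracket[1]
  hi <- gh_bracket[2]
  p_hi <- p
  p_hi[["gh"]] <- hi
  st <- firing_state(p_hi, dt = dt)
  p_lo <- p
  p_lo[["gh"]] <- lo
  if (cycle_persists(p_lo, st, window, dt)$persists)
    stop("invalid bracket: the cycle persists at the lower end")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    p_mid <- p
    p_mid[["gh"]] <- mid
    res <- cycle_persists(p_mid, st, window, dt)
    if (res$persists) {
      hi <- mid
      st <- res$state
    } else {
      lo <- mid
    }
  }
  (lo + hi) / 2
}

#' Classify a fold as SNIC or plain SN
#'
#' A fold of the resting branch is a saddle-node on an invariant circle
#' (SNIC) when firing switches on exactly at the fold (no cycle below it)
#' and a plain saddle-node (SN, with a coexistence window) when a stable
#' cycle already exists just below the fold. Tested by taking a state on
#' the firing attractor just above the fold and checking cycle persistence
#' at \code{gh_fold - delta}.
#'
#' \code{delta} sets the resolution below which cycle onset is treated as
#' coincident with the fold. It cannot be made arbitrarily small: in this
#' strongly time-scale-separated model the homoclinic boundary hugs the fold
#' curve, leaving exponentially thin coexistence slivers (e.g. ~7e-5 in gh at
#' Iapp = 0.08, where the fold is nevertheless a SNIC in the study's
#' classification), and passage times near the saddle-node ghost diverge.
#' The default 1e-4 is the smallest round value above those slivers and two
#' orders of magnitude below the wide coexistence windows (~1e-3) of the
#' plain-SN regime.
#'
#' @param p parameters (Iapp from p)
#' @param gh_fold fold location (mS/cm2)
#' @param delta offset below the fold at which persistence is tested
#' @param window,dt persistence-test settings as in [locate_cycle_boundary()].
#'   The window default is longer here than for the cycle boundary because
#'   just below a SNIC fold the saddle-node ghost stretches interspike
#'   passages to many hundreds of ms before the orbit is captured by the
#'   resting state; a short window mistakes those last slow loops for a
#'   persisting cycle.
#' @return "SNIC" or "SN"
#' @export
classify_fold_global <- function(p, gh_fold, delta = 1e-4,
                                 window = 6000, dt = 0.001) {
  p_up <- p
  p_up[["gh"]] <- gh_fold + 100 * delta
  st <- firing_state(p_up, dt = dt)
  p_dn <- p
  p_dn[["gh"]] <- gh_fold - delta
  if (cycle_persists(p_dn, st, window, dt)$persists) "SN" else "SNIC"
}

#' Classify a Hopf point as subcritical or supercritical
#'
#' Operational hysteresis test: subcritical if a stable large-amplitude
#' limit cycle coexists with the stable focus just below the Hopf point
#' (approached from the firing side), supercritical if no large cycle exists
#' below and the oscillation grows continuously from zero amplitude above.
#'
#' @param p parameters (Iapp from p)
#' @param gh_hopf Hopf location (mS/cm2)
#' @param delta test offset below the Hopf point
#' @param window,dt persistence-test settings
#' @return "sub" or "super"
#' @export
classify_hopf <- function(p, gh_hopf, delta = 5e-4,
                          window = 2000, dt = 0.001) {
  p_up <- p
  p_up[["gh"]] <- gh_hopf + 10 * delta
  st <- firing_state(p_up, dt = dt)
  p_dn <- p
  p_dn[["gh"]] <- gh_hopf - delta
  if (cycle_persists(p_dn, st, window, dt)$persists) "sub" else "super"
}

# ---- two-parameter curves and codim-2 points -------------------------------

# gh value of the codim-1 condition at one Iapp, used by the 2-parameter
# tracer. kind: "SN" (fold via scalar reduction), "Hopf", "NF" (bisection
# on the lower-branch eigenstructure within a local gh bracket).
codim1_gh_at <- function(p, iapp, kind, gh_seed, gh_halfwidth = 0.01) {
  p[["Iapp"]] <- iapp
  if (kind == "SN") {
    folds <- find_folds(p)
    if (!nrow(folds)) return(NULL)
    return(folds$gh[which.min(abs(folds$gh - gh_seed))])
  }
  lo <- max(0, gh_seed - gh_halfwidth)
  hi <- gh_seed + gh_halfwidth
  # scan the local bracket first: the Hopf condition is only defined where
  # the leading pair is complex, and the indicator may be NA at the edges
  ghs <- seq(lo, hi, length.out = 41)
  st <- lapply(ghs, function(g) lower_branch_pair(p, g))
  if (kind == "Hopf") {
    ind <- vapply(st, function(s) if (!s$complex_pair) NA else s$re > 0, NA)
  } else {
    ind <- vapply(st, function(s) s$complex_pair, NA)
  }
  flip <- which(!is.na(ind[-length(ind)]) & !is.na(ind[-1]) &
                  ind[-length(ind)] != ind[-1])
  if (!length(flip)) return(NULL)
  i <- flip[which.min(abs(ghs[flip] - gh_seed))]
  gh_star <- if (kind == "Hopf") {
    bisect_gh(function(g) {
      pr <- lower_branch_pair(p, g)
      isTRUE(pr$complex_pair && pr$re > 0)
    }, ghs[i], ghs[i + 1])
  } else {
    bisect_gh(function(g) lower_branch_pair(p, g)$complex_pair,
              ghs[i], ghs[i + 1])
  }
  # post-validate: a fold inside the bracket makes the lowest-V equilibrium
  # jump branches, and a flip bisected across that jump converges onto the
  # fold, where the branch is discontinuous; a genuine Hopf/NF point has the
  # same branch on both sides
  e_lo <- lower_branch_pair(p, gh_star - 1e-6)
  e_hi <- lower_branch_pair(p, gh_star + 1e-6)
  if (abs(e_lo$eq$state[["V"]] - e_hi$eq$state[["V"]]) > 1) return(NULL)
  if (kind == "Hopf" && !(e_lo$complex_pair && e_hi$complex_pair))
    return(NULL)
  gh_star
}

#' Trace a codimension-1 curve in the (Iapp, gh) plane
#'
#' Predictor-corrector continuation in Iapp: at each Iapp step the codim-1
#' defining condition (fold, Hopf, or node-focus transition of the lower
#' branch; or the cycle-existence boundary) is re-solved in gh, seeded by
#' the previous point. The curve is truncated, with the reason recorded as
#' an attribute, when the condition ceases to have a root in the local
#' bracket (a codim-2 endpoint or the domain edge).
#'
#' @param p base parameters
#' @param kind "SN", "Hopf", "NF", or "cycle_boundary"
#' @param iapp_range endpoints of the traced Iapp interval; tracing starts
#'   at \code{iapp_range[1]} and proceeds toward \code{iapp_range[2]}
#' @param gh_seed gh of a point on the curve at \code{iapp_range[1]}
#' @param step Iapp step size
#' @param gh_halfwidth local bracket half-width for the gh re-solve
#' @param ... further arguments to [locate_cycle_boundary()] for
#'   kind = "cycle_boundary"
#' @return data.frame (Iapp, gh) of class \code{"param_curve"}, possibly
#'   with attribute \code{truncated}
#' @export
trace_curve_2d <- function(p, kind = c("SN", "Hopf", "NF", "cycle_boundary"),
                           iapp_range, gh_seed, step = 1e-3,
                           gh_halfwidth = 0.01, ...) {
  kind <- match.arg(kind)
  iapps <- seq(iapp_range[1], iapp_range[2],
               by = step * sign(iapp_range[2] - iapp_range[1]))
  gh_prev <- gh_seed
  out <- data.frame(Iapp = numeric(0), gh = numeric(0))
  reason <- NULL
  for (ia in iapps) {
    gh <- if (kind == "cycle_boundary") {
      pi <- p
      pi[["Iapp"]] <- ia
      tryCatch(locate_cycle_boundary(
        pi, c(max(0, gh_prev - gh_halfwidth), gh_prev + gh_halfwidth), ...),
        error = function(e) NULL)
    } else {
      codim1_gh_at(p, ia, kind, gh_prev, gh_halfwidth)
    }
    if (is.null(gh) || !is.finite(gh)) {
      reason <- sprintf("condition lost at Iapp = %g", ia)
      break
    }
    out <- rbind(out, data.frame(Iapp = ia, gh = gh))
    gh_prev <- gh
  }
  class(out) <- c("param_curve", class(out))
  attr(out, "kind") <- kind
  if (!is.null(reason)) attr(out, "truncated") <- reason
  out
}

# Explicit V-parameterization of the fold curve: from F = 0 and dF/dV = 0,
# gh(V) = -dA/dB and Iapp(V) = -(A + gh B). Used as the backbone for the
# codim-2 searches (every point satisfies the fold condition to machine
# precision).
fold_curve_point <- function(V, p) {
  r <- eq_reduction(V, p)
  gh <- -r$dA / r$dB
  iapp <- -(r$A + gh * r$B)
  c(V = V, gh = gh, Iapp = iapp)
}

# Sum of 3x3 principal minors of a matrix: the coefficient whose vanishing,
# together with det = 0 (the fold condition), signals a double zero
# eigenvalue (Bogdanov-Takens).
principal_minors3 <- function(J) {
  idx <- utils::combn(4, 3)
  sum(apply(idx, 2, function(k) det(J[k, k, drop = FALSE])))
}

bt_condition <- function(V, p) {
  fp <- fold_curve_point(V, p)
  pp <- p
  pp[["gh"]] <- fp[["gh"]]
  pp[["Iapp"]] <- fp[["Iapp"]]
  g <- gating_rates(V)
  s <- c(V = V, h = g$h_inf, n = g$n_inf, H = g$H_inf)
  principal_minors3(ih_jacobian(s, pp))
}

#' Locate codimension-2 points
#'
#' \describe{
#'   \item{BT}{Bogdanov-Takens: the point on the fold curve where the
#'     Jacobian acquires a double zero eigenvalue. The fold curve is
#'     parameterized explicitly by the equilibrium voltage; along it the sum
#'     of 3x3 principal minors of the Jacobian (the second characteristic
#'     coefficient, whose vanishing together with the zero determinant gives
#'     the double zero) is bisected to a root.}
#'   \item{SNHO}{saddle-node homoclinic orbit: the point on the fold curve
#'     where the fold switches between SNIC and plain-SN character,
#'     bisected on the [classify_fold_global()] label.}
#'   \item{T}{meeting point of the two node-focus transition branches of
#'     the stable lower branch, bisected in Iapp on the existence of a
#'     focus segment in gh.}
#' }
#'
#' @param p base parameters
#' @param kind "BT", "SNHO", or "T"
#' @param V_bracket (BT, SNHO) bracket in equilibrium voltage along the fold
#'   curve; defaults cover the studied window
#' @param iapp_bracket (T) bracket in Iapp
#' @param tol bisection tolerance (V for BT/SNHO, Iapp for T)
#' @param ... persistence-test settings passed to [classify_fold_global()]
#'   for kind = "SNHO"
#' @return list with \code{kind}, \code{Iapp}, \code{gh}, and for BT/SNHO the
#'   equilibrium voltage \code{V}
#' @export
locate_codim2 <- function(p, kind = c("BT", "SNHO", "T"),
                          V_bracket = NULL, iapp_bracket = c(0.1, 0.2),
                          tol = NULL, ...) {
  kind <- match.arg(kind)
  if (kind == "BT") {
    # physical (gh >= 0) arc of the fold curve in the studied window
    if (is.null(V_bracket)) V_bracket <- c(-59.9, -59.1)
    if (is.null(tol)) tol <- 1e-10
    r <- stats::uniroot(function(v) bt_condition(v, p),
                        V_bracket, tol = tol)
    fp <- fold_curve_point(r$root, p)
    return(list(kind = "BT", Iapp = unname(fp[["Iapp"]]),
                gh = unname(fp[["gh"]]), V = r$root))
  }
  if (kind == "SNHO") {
    # between the SNIC regime (fold at Iapp = 0.08 sits at V ~ -59.61) and
    # the BT point (V ~ -59.45)
    if (is.null(V_bracket)) V_bracket <- c(-59.62, -59.47)
    if (is.null(tol)) tol <- 2e-4
    is_snic <- function(v) {
      fp <- fold_curve_point(v, p)
      pp <- p
      pp[["Iapp"]] <- fp[["Iapp"]]
      classify_fold_global(pp, fp[["gh"]], ...) == "SNIC"
    }
    lo <- V_bracket[1]
    hi <- V_bracket[2]
    slo <- is_snic(lo)
    shi <- is_snic(hi)
    if (slo == shi)
      stop("SNHO bracket does not straddle the SNIC/SN switch")
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (is_snic(mid) == slo) lo <- mid else hi <- mid
    }
    fp <- fold_curve_point((lo + hi) / 2, p)
    return(list(kind = "SNHO", Iapp = unname(fp[["Iapp"]]),
                gh = unname(fp[["gh"]]), V = (lo + hi) / 2))
  }
  # T point: the focus segment of the lower branch shrinks to zero width
  if (is.null(tol)) tol <- 1e-4
  focus_interval <- function(iapp) {
    pp <- p
    pp[["Iapp"]] <- iapp
    ghs <- c(seq(0, 0.003, by = 5e-6), seq(0.0035, 0.02, by = 5e-4))
    is_sf <- vapply(ghs, function(g) {
      pr <- lower_branch_pair(pp, g)
      pr$eq$etype == "stable_focus"
    }, TRUE)
    if (!any(is_sf)) return(NULL)
    range(ghs[is_sf])
  }
  lo <- iapp_bracket[1]
  hi <- iapp_bracket[2]
  if (is.null(focus_interval(lo)) || !is.null(focus_interval(hi)))
    stop("T bracket must have a focus segment at the lower end only")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (is.null(focus_interval(mid))) hi <- mid else lo <- mid
  }
  fi <- focus_interval(lo)
  list(kind = "T", Iapp = (lo + hi) / 2, gh = mean(fi))
}

#' Partition of the (Iapp, gh) plane into stable behaviors
#'
#' Labels each grid cell by the classification of its stable equilibrium
#' (node or focus) combined with stable-limit-cycle existence: "firing"
#' (no stable equilibrium), "coexistence" (stable equilibrium plus a
#' persisting cycle), "stable_focus", or "stable_node". Cycle existence is
#' tested by downward continuation in gh within each Iapp column (the state
#' on the firing attractor at the top of the column is carried down),
#' matching the hysteresis character of the coexistence band.
#'
#' @param p base parameters
#' @param iapp_grid,gh_grid grid vectors
#' @param window persistence-test window (ms)
#' @param dt integration step for the persistence tests (ms); the partition
#'   is a coarse map, so a larger step than the reference 0.001 ms is
#'   acceptable here and is the default
#' @return list with the grids and a character label matrix
#'   (rows = Iapp, cols = gh)
#' @export
stable_behavior_partition <- function(p, iapp_grid, gh_grid,
                                      window = 1000, dt = 0.005) {
  lab <- matrix(NA_character_, length(iapp_grid), length(gh_grid))
  for (i in seq_along(iapp_grid)) {
    pi <- p
    pi[["Iapp"]] <- iapp_grid[i]
    st <- NULL
    for (j in rev(seq_along(gh_grid))) {
      pj <- pi
      pj[["gh"]] <- gh_grid[j]
      eqs <- find_equilibria(pj)
      stable <- Filter(function(e) e$stable, eqs)
      if (length(stable) == 0) {
        lab[i, j] <- "firing"
        if (is.null(st))
          st <- tryCatch(firing_state(pj, dt = dt), error = function(e) NULL)
        next
      }
      cyc <- FALSE
      if (!is.null(st)) {
        res <- cycle_persists(pj, st, window, dt)
        cyc <- res$persists
        if (cyc) st <- res$state else st <- NULL
      }
      lab[i, j] <- if (cyc) "coexistence"
        else if (stable[[1]]$etype == "stable_focus") "stable_focus"
        else "stable_node"
    }
  }
  list(Iapp = iapp_grid, gh = gh_grid, labels = lab)
}
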