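#' Firing-rate drive
#'
#' Square-pulse firing drive: basal `f0` outside the stimulation epoch,
#' `f0 * f_stim` inside. The epoch is closed on the left and open on the
#' right, so the drive steps up exactly at `t_start`.
#'
#' @param t time (s), vectorised.
#' @param protocol a [stim_protocol()].
#' @param params an [ha_params()] set (supplies `f0`, `f_stim`).
#' @return dimensionless drive, same length as `t`.
#' @export
firing_rate <- function(t, protocol, params) {
  on <- t >= protocol$t_start & t < protocol$t_start + protocol$duration
  params$f0 * ifelse(on, params$f_stim, 1)
}

#' H1-triggered retrograde inhibition factor
#'
#' Square window: release is multiplied by `1 - s_strength` for
#' `t` inside `s_window` (closed left, open right), 1 elsewhere. This is the
#' phenomenological stand-in for the retrograde messenger acting back on the
#' histaminergic terminal after post-synaptic H1 activation; the window is
#' engaged by [simulate_evoked()] only when a stimulation occurs.
#'
#' @param t time (s), vectorised.
#' @param params an [ha_params()] set.
#' @return multiplicative factor in [0, 1], same length as `t`.
#' @export
s_factor <- function(t, params) {
  w <- params$s_window
  ifelse(t >= w[1] & t < w[2], 1 - params$s_strength, 1)
}

#' H3 autoreceptor feedback on release
#'
#' Multiplicative gain on the release flux,
#' `max(0, 1 - alpha * (gstar - gstar_eq) / gstar_eq)`: equal to 1 at the
#' reference active-G fraction, falling linearly as G-protein activation
#' rises above it, and clipped at zero so the flux stays nonnegative.
#'
#' @param gstar active G-protein fraction in [0, 1], vectorised.
#' @param params an [ha_params()] set (supplies `alpha`, `gstar_eq`).
#' @return factor >= 0, same length as `gstar`.
#' @export
release_inhibition <- function(gstar, params) {
  if (params$gstar_eq <= 0) stop("gstar_eq must be > 0")
  pmax(0, 1 - params$alpha * (gstar - params$gstar_eq) / params$gstar_eq)
}

# Raw flux computations shared by the rhs, the steady-state solver and
# ha_derivatives(). `drive` is the instantaneous firing drive, `sfac` the
# retrograde factor.
.fluxes <- function(state, params, drive, sfac) {
  mm <- function(V, K, s) V * s / (K + s)
  J_HTL   <- mm(params$V_HTL, params$K_HTL, state[["bHT"]])
  J_pool  <- params$k_pool_in * state[["cHT"]] -
             params$k_pool_out * state[["HTpool"]]
  J_HTDC  <- mm(params$V_HTDC, params$K_HTDC, state[["cHT"]])
  J_loss  <- params$k_cht_loss * state[["cHT"]]
  J_MAT   <- mm(params$V_MAT, params$K_MAT, state[["cHA"]])
  J_rel   <- params$k_rel * drive * state[["vHA"]] *
             release_inhibition(state[["gstar"]], params) * sfac
  J_HAT   <- mm(params$V_HAT, params$K_HAT, state[["eHA"]]) /
             (1 + state[["gHA"]] / params$K_HAT_gi)
  J_HNMTg <- mm(params$V_HNMT_g, params$K_HNMT_g, state[["gHA"]])
  J_HNMTc <- mm(params$V_HNMT_c, params$K_HNMT_c, state[["cHA"]])
  list(HTL = J_HTL, pool = J_pool, HTDC = J_HTDC, loss = J_loss,
       MAT = J_MAT, rel = J_rel, HAT = J_HAT,
       HNMTg = J_HNMTg, HNMTc = J_HNMTc)
}

# Unvalidated rhs used inside the integrator. `drive` and `sfac` are scalars
# held constant within a smooth segment.
.rhs <- function(state, params, drive, sfac) {
  fl <- .fluxes(state, params, drive, sfac)
  c(bHT    = 0,
    cHT    = fl$HTL - fl$pool - fl$HTDC - fl$loss,
    HTpool = fl$pool,
    cHA    = fl$HTDC - fl$MAT - fl$HNMTc,
    vHA    = fl$MAT - fl$rel,
    eHA    = fl$rel - fl$HAT,
    gHA    = fl$HAT - fl$HNMTg,
    bHA    = params$k_on * state[["eHA"]] * (1 - state[["bHA"]]) -
             params$k_off * state[["bHA"]],
    gstar  = params$k_Gact * state[["bHA"]] * (1 - state[["gstar"]]) -
             params$k_Gdeact * state[["tstar"]] * state[["gstar"]],
    tstar  = params$k_Tact * state[["gstar"]] * (1 - state[["tstar"]]) -
             params$k_Tdeact * state[["tstar"]])
}

#' Time derivatives of the model state
#'
#' One rate per state field. Fluxes: Michaelis-Menten histidine transport
#' (HTL, from clamped blood histidine), first-order pool exchange,
#' Michaelis-Menten synthesis (HTDC) with a first-order histidine sink,
#' Michaelis-Menten vesicular packaging, release
#' `k_rel * firing_rate(t) * vHA * release_inhibition(gstar) * s_factor(t)`,
#' Michaelis-Menten extracellular clearance with trans-side inhibition by
#' glial histamine, Michaelis-Menten N-methyltransferase degradation of the
#' glial and cytosolic pools, and mass-action receptor binding and
#' G-protein/RGS activation. Blood histidine is clamped (rate 0).
#'
#' @param state named numeric vector with fields bHT, cHT, HTpool, cHA, vHA,
#'   eHA, gHA, bHA, gstar, tstar (concentrations uM, fractions in [0, 1]).
#' @param t time (s).
#' @param params an [ha_params()] set.
#' @param protocol a [stim_protocol()].
#' @param engage_s whether the retrograde window applies (default: only when
#'   the protocol actually stimulates, `f_stim > 1`).
#' @return named numeric vector of rates (uM/s or 1/s), one per field.
#' @export
ha_derivatives <- function(state, t, params, protocol = stim_protocol(),
                           engage_s = params$f_stim > 1) {
  validate_params(params)
  validate_state(as.list(state))
  drive <- firing_rate(t, protocol, params)
  sfac <- if (engage_s) s_factor(t, params) else 1
  .rhs(state, params, drive, sfac)
}

#' Resting steady state of the model
#'
#' Solves the basal (unstimulated, retrograde window inactive) fixed point
#' by an analytic cascade: the supply flux fixes cytosolic histidine, a
#' scalar root solve gives cytosolic histamine, and the release/clearance
#' chain then yields each downstream compartment in closed form, with a
#' second scalar root solve for the G-protein fraction. The result is
#' verified against [ha_derivatives()]; the maximum absolute residual must
#' be below `tol`.
#'
#' Because the feedback factor is normalised to 1 at `gstar_eq` (the control
#' resting value), the resting extracellular concentration is independent of
#' the autoreceptor strength: feedback rescales the vesicular pool instead.
#'
#' @param params an [ha_params()] set.
#' @param tol residual tolerance (uM/s) for the fixed-point check.
#' @return named numeric vector: the steady model state.
#' @export
#' @examples
#' ss <- steady_state(ha_params())
#' ss[["eHA"]]  # 5.32 uM for the shipped control configuration
steady_state <- function(params, tol = 1e-8) {
  validate_params(params)
  mm <- function(V, K, s) V * s / (K + s)
  J <- mm(params$V_HTL, params$K_HTL, params$bHT)

  if (J == 0) {
    cHT <- 0
  } else {
    # HTDC(cHT) + k_cht_loss * cHT = J
    f <- function(c) mm(params$V_HTDC, params$K_HTDC, c) +
      params$k_cht_loss * c - J
    hi <- 1
    while (f(hi) < 0 && hi < 1e12) hi <- hi * 10
    if (f(hi) < 0) {
      stop("steady state infeasible: histidine supply exceeds the maximum ",
           "synthesis plus consumption capacity")
    }
    cHT <- stats::uniroot(f, c(0, hi), tol = 1e-14)$root
  }
  HTpool <- if (params$k_pool_out > 0) {
    params$k_pool_in * cHT / params$k_pool_out
  } else 0
  J_syn <- mm(params$V_HTDC, params$K_HTDC, cHT)

  if (J_syn == 0) {
    cHA <- 0
  } else {
    g <- function(c) mm(params$V_MAT, params$K_MAT, c) +
      mm(params$V_HNMT_c, params$K_HNMT_c, c) - J_syn
    if (params$V_MAT + params$V_HNMT_c <= J_syn) {
      stop("steady state infeasible: synthesis flux exceeds packaging plus ",
           "cytosolic metabolism capacity")
    }
    hi <- 1
    while (g(hi) < 0) hi <- hi * 10
    cHA <- stats::uniroot(g, c(0, hi), tol = 1e-14)$root
  }
  J_rel <- mm(params$V_MAT, params$K_MAT, cHA)

  if (J_rel == 0) {
    gHA <- 0; eHA <- 0
  } else {
    if (params$V_HNMT_g <= J_rel) {
      stop("steady state infeasible: release flux exceeds glial metabolism ",
           "capacity (glial histamine diverges)")
    }
    gHA <- params$K_HNMT_g * J_rel / (params$V_HNMT_g - J_rel)
    V_eff <- params$V_HAT / (1 + gHA / params$K_HAT_gi)
    if (V_eff <= J_rel) {
      stop("steady state infeasible: release flux exceeds effective ",
           "clearance capacity (extracellular histamine diverges)")
    }
    eHA <- params$K_HAT * J_rel / (V_eff - J_rel)
  }

  bHA <- params$k_on * eHA / (params$k_on * eHA + params$k_off)
  gstar <- if (bHA == 0 || params$k_Gact == 0) 0 else {
    h <- function(g) {
      tst <- params$k_Tact * g / (params$k_Tact * g + params$k_Tdeact)
      params$k_Gact * bHA * (1 - g) - params$k_Gdeact * tst * g
    }
    if (params$k_Gdeact == 0 || params$k_Tact == 0) 1
    else stats::uniroot(h, c(0, 1), tol = 1e-14)$root
  }
  tstar <- if (params$k_Tact * gstar + params$k_Tdeact == 0) 0 else {
    params$k_Tact * gstar / (params$k_Tact * gstar + params$k_Tdeact)
  }

  relfac <- release_inhibition(gstar, params)
  vHA <- if (J_rel == 0) 0 else {
    denom <- params$k_rel * params$f0 * relfac
    if (denom <= 0) {
      stop("steady state infeasible: basal release drive or feedback factor ",
           "is zero while packaging flux is positive")
    }
    J_rel / denom
  }

  ss <- c(bHT = params$bHT, cHT = cHT, HTpool = HTpool, cHA = cHA,
          vHA = vHA, eHA = eHA, gHA = gHA, bHA = bHA,
          gstar = gstar, tstar = tstar)
  resid <- .rhs(ss, params, drive = params$f0, sfac = 1)
  if (max(abs(resid)) > tol) {
    stop(sprintf(
      "steady-state solve did not converge: max |rate| = %.3g uM/s",
      max(abs(resid))))
  }
  ss
}
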