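#' Force parameters: size-based segregation and centripetal transport
#'
#' Both forces act on bound complexes only, by biasing the direction
#' distribution of their random-walk moves rather than by adding a
#' deterministic displacement, so single-occupancy exclusion and the
#' kinetic Monte Carlo scheme are preserved.
#'
#' Size-based segregation (SBS) is a repulsion between complexes of
#' different size classes: the short TCR-pMHC complex is pushed away from
#' long LFA-1-ICAM-1 complexes (and vice versa) lying within `R_force`.
#' The net repulsion direction is the sum of unit vectors pointing away
#' from every opposite-class complex in range (optionally decaying as 1/r).
#'
#' The centripetal force models complex coupling to contracting F-actin
#' arcs: when `coupling_enabled`, the move distribution of every bound
#' complex is tilted towards the lattice centre with magnitude
#' `centripetal_strength` for TCR-pMHC and
#' `centripetal_strength_adhesion` for LFA-1-ICAM-1. TCR microclusters
#' engage the arcs far more strongly than the adhesion complexes, which
#' experience mostly frictional coupling; the weaker default for the
#' adhesion pair lets the TCR-pMHC population claim the centre while
#' LFA-1-ICAM-1 settles into the surrounding ring. Setting
#' `coupling_enabled = FALSE` switches centripetal transport off for both
#' classes, reproducing the F-actin-arrest (retrograde-flow inhibition)
#' experiment.
#'
#' @param R_force SBS interaction radius in micrometres.
#' @param sbs_strength Dimensionless bias magnitude in `[0, 1]`.
#' @param centripetal_strength Dimensionless bias magnitude in `[0, 1]`
#'   for TCR-pMHC complexes.
#' @param centripetal_strength_adhesion Bias magnitude for LFA-1-ICAM-1
#'   complexes.
#' @param coupling_enabled Logical; `FALSE` switches centripetal transport
#'   off entirely.
#' @param kernel `"constant"` (unit vectors, no distance decay) or
#'   `"inverse_r"` (contributions weighted by 1/r).
#' @param force_update_interval Steps between recomputations of the cached
#'   SBS repulsion field; complexes move at most one node per step, so the
#'   field changes slowly on this scale.
#' @return A `force_params` list.
#' @export
force_params <- function(R_force = 0.5,
                         sbs_strength = 0.4,
                         centripetal_strength = 0.3,
                         centripetal_strength_adhesion = 0.03,
                         coupling_enabled = TRUE,
                         kernel = c("constant", "inverse_r"),
                         force_update_interval = 20L) {
  if (R_force < 0) stop("`R_force` must be >= 0", call. = FALSE)
  if (sbs_strength < 0 || sbs_strength > 1 ||
      centripetal_strength < 0 || centripetal_strength > 1 ||
      centripetal_strength_adhesion < 0 || centripetal_strength_adhesion > 1) {
    stop("force strengths must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(R_force = R_force,
         sbs_strength = sbs_strength,
         centripetal_strength = centripetal_strength,
         centripetal_strength_adhesion = centripetal_strength_adhesion,
         coupling_enabled = isTRUE(coupling_enabled),
         kernel = match.arg(kernel),
         force_update_interval = as.integer(force_update_interval)),
    class = "force_params"
  )
}

# candidate move set shared by all bias functions: stay, up (-y), down
# (+y), left (-x), right (+x)
MOVE_CANDIDATES <- c("stay", "up", "down", "left", "right")
MOVE_DX <- c(stay = 0, up = 0, down = 0, left = -1, right = 1)
MOVE_DY <- c(stay = 0, up = -1, down = 1, left = 0, right = 0)

bias_weights <- function(direction, strength) {
  w <- c(stay = 1, up = 0, down = 0, left = 0, right = 0)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0 || strength == 0) {
    w[] <- 1
  } else {
    d <- direction / nrm
    for (k in MOVE_CANDIDATES[-1]) {
      w[k] <- max(0, 1 + strength * (d[1] * MOVE_DX[k] + d[2] * MOVE_DY[k]))
    }
  }
  w / sum(w)
}

#' Size-based segregation move bias for one complex
#'
#' @param unit_xy Numeric length-2 position (um) of the complex.
#' @param opposite_xy Matrix (n x 2) of positions of opposite-size-class
#'   complexes, or `NULL`/empty for none.
#' @param params A [force_params()].
#' @return Named non-negative weights over `stay, up, down, left, right`
#'   summing to 1; uniform when no opposite-class complex is in range.
#' @examples
#' p <- force_params()
#' sbs_bias(c(0, 0), rbind(c(0.2, 0)), p) # pushed west, away from the east
#' @export
sbs_bias <- function(unit_xy, opposite_xy, params) {
  dir <- c(0, 0)
  if (!is.null(opposite_xy) && NROW(opposite_xy) > 0) {
    opposite_xy <- matrix(opposite_xy, ncol = 2)
    d <- cbind(unit_xy[1] - opposite_xy[, 1], unit_xy[2] - opposite_xy[, 2])
    r <- sqrt(rowSums(d^2))
    keep <- r > 0 & r <= params$R_force
    if (any(keep)) {
      wgt <- if (identical(params$kernel, "inverse_r")) 1 / r[keep] else 1
      dir <- colSums(d[keep, , drop = FALSE] / r[keep] * wgt)
    }
  }
  bias_weights(dir, params$sbs_strength)
}

#' Centripetal move bias for one complex
#'
#' @param unit_xy Numeric length-2 position (um) relative to the synapse
#'   centre.
#' @param params A [force_params()].
#' @return Named weights over the move candidates; uniform when coupling
#'   is disabled or the unit sits exactly at the centre.
#' @export
centripetal_bias <- function(unit_xy, params) {
  if (!params$coupling_enabled) {
    return(stats::setNames(rep(1 / 5, 5), MOVE_CANDIDATES))
  }
  bias_weights(-unit_xy, params$centripetal_strength)
}

#' Combine diffusion and force biases into one move distribution
#'
#' Elementwise product of the weight vectors, renormalised. Reduces to the
#' diffusion weights when both force biases are uniform. A degenerate
#' all-zero product falls back to "stay" with a warning.
#'
#' @param diffusion,sbs,centripetal Non-negative weight vectors over the
#'   same candidate set.
#' @return Normalised move distribution.
#' @export
combine_biases <- function(diffusion, sbs, centripetal) {
  stopifnot(length(diffusion) == length(sbs),
            length(diffusion) == length(centripetal))
  w <- diffusion * sbs * centripetal
  s <- sum(w)
  if (s <= 0) {
    warning("all-zero move weights; falling back to \"stay\"", call. = FALSE)
    w <- c(1, rep(0, length(w) - 1))
    names(w) <- names(diffusion)
    return(w)
  }
  w / s
}
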