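# Stop-and-go persistent random walk with white-matter anisotropy, crowding
# rules, and boundary retry logic.

#' Update migration persistence state
#'
#' Decrements each cell's remaining persistence time by `dt`; cells whose
#' persistence has elapsed reset: a new migration status is chosen (move with
#' probability `move_prob`, default an unbiased coin), a new persistence time
#' is sampled from an exponential distribution with the configured mean
#' (moving 42.6 min, stopped 70.1 min; moving runs in white matter are
#' lengthened by the factor 1.5), and a new heading is sampled from the
#' turning model of the local tissue class: uniform on `[0, 2pi)` in gray
#' matter, a normal deviation with standard deviation `sigma_theta` about the
#' current heading in white matter.
#'
#' @param pop a [new_population()] (modified in place).
#' @param domain a [tissue_domain()].
#' @param params a [parameter_set()].
#' @param dt step length (h).
#' @return `pop`, invisibly.
#' @export
update_persistence <- function(pop, domain, params, dt) {
  n <- pop$n
  if (!n) return(invisible(pop))
  i <- seq_len(n)
  pers <- pop$persist[i] - dt
  reset <- which(pers <= 0)
  if (length(reset)) {
    k <- length(reset)
    mv <- stats::runif(k) < params$move_prob
    cls <- pixel_class(domain, pop$x[reset], pop$y[reset])
    white <- cls == TISSUE["WHITE"]
    tau_p <- ifelse(mv,
                    stats::rexp(k, 1 / params$move_time_mean),
                    stats::rexp(k, 1 / params$stop_time_mean))
    tau_p[mv & white] <- tau_p[mv & white] * params$white_persistence_factor
    head_new <- ifelse(white,
                       pop$heading[reset] + stats::rnorm(k, 0, params$sigma_theta * pi / 180),
                       stats::runif(k, 0, 2 * pi))
    pop$moving[reset] <- mv
    pop$heading[reset] <- head_new
    pers[reset] <- tau_p
  }
  pop$persist[i] <- pers
  invisible(pop)
}

#' Attempt cell moves
#'
#' Moving cells advance `m * dt` along their heading. A cell may not enter
#' EMPTY space (brain edge, ventricles): it retries up to 10 random angles at
#' the same distance, then escalates the distance one cell diameter (25 um)
#' per round up to 3 diameters, and stays put if all attempts fail. A cell
#' headed into a density node at or above carrying capacity moves only if the
#' target node currently holds fewer cells than the origin node; crossings are
#' resolved sequentially in randomized order against live counters.
#'
#' @param pop a [new_population()] (modified in place).
#' @param m observed migration speed per cell (um/h), already including any
#'   anti-migratory factor.
#' @param dt step length (h).
#' @param domain a [tissue_domain()].
#' @param density integer vector of live cell counts per density node
#'   (updated in place transactionally).
#' @param capacity carrying capacity per density node.
#' @return the updated density vector, invisibly.
#' @export
attempt_move <- function(pop, m, dt, domain, density, capacity) {
  n <- pop$n
  if (!n) return(invisible(density))
  i <- seq_len(n)
  mob <- pop$moving[i] & m > 0
  if (!any(mob)) return(invisible(density))
  idx <- which(mob)
  step_len <- m[idx] * dt
  tx <- pop$x[idx] + step_len * cos(pop$heading[idx])
  ty <- pop$y[idx] + step_len * sin(pop$heading[idx])

  # boundary retries for targets in EMPTY space
  bad <- pixel_class(domain, tx, ty) == TISSUE["EMPTY"]
  if (any(bad)) {
    for (extra in 0:3) {
      if (!any(bad)) break
      for (att in 1:10) {
        if (!any(bad)) break
        bi <- which(bad)
        dist_b <- step_len[bi] + extra * CELL_DIAMETER_UM
        ang <- stats::runif(length(bi), 0, 2 * pi)
        cx <- pop$x[idx[bi]] + dist_b * cos(ang)
        cy <- pop$y[idx[bi]] + dist_b * sin(ang)
        ok <- pixel_class(domain, cx, cy) != TISSUE["EMPTY"]
        tx[bi[ok]] <- cx[ok]; ty[bi[ok]] <- cy[ok]
        bad[bi[ok]] <- FALSE
      }
    }
    # cells with no admissible target stay put
    if (any(bad)) { tx[bad] <- pop$x[idx[bad]]; ty[bad] <- pop$y[idx[bad]] }
  }

  from <- density_node_raw(domain, pop$x[idx], pop$y[idx])
  to <- density_node_raw(domain, tx, ty)
  same <- from == to
  # within-node moves never change density; commit directly
  if (any(same)) {
    w <- idx[same]
    pop$x[w] <- tx[same]; pop$y[w] <- ty[same]
  }
  cross <- which(!same)
  if (length(cross)) {
    nb <- length(density)
    f <- from[cross]; t <- to[cross]
    inc <- tabulate(t, nbins = nb)
    outc <- tabulate(f, nbins = nb)
    # moves whose admission cannot depend on the processing order: the target
    # stays below capacity (or below the origin count) even in the worst case
    ok <- (density[t] + inc[t] - 1L < capacity[t]) |
      (density[t] + inc[t] - 1L < density[f] - outc[f] + 1L)
    # moves that are refused under every order
    block <- !ok & (density[t] - outc[t] >= capacity[t]) &
      (density[t] - outc[t] >= density[f] + inc[f])
    commit <- cross[ok]
    if (length(commit)) {
      w <- idx[commit]
      pop$x[w] <- tx[commit]; pop$y[w] <- ty[commit]
      density <- density - tabulate(from[commit], nbins = nb) +
        tabulate(to[commit], nbins = nb)
    }
    rest <- cross[!ok & !block]
    if (length(rest)) {
      for (j in sample(rest)) {  # randomized order, live counters
        fj <- from[j]; tj <- to[j]
        if (density[tj] >= capacity[tj] && density[tj] >= density[fj]) next
        w <- idx[j]
        pop$x[w] <- tx[j]; pop$y[w] <- ty[j]
        density[fj] <- density[fj] - 1L
        density[tj] <- density[tj] + 1L
      }
    }
  }
  invisible(density)
}

#' Anti-migratory speed scaling
#'
#' Multiplies the effective migration speed by `factor` (default 0.1: speeds
#' reduced to 10% of their original value) while the treatment is on. The
#' inherited potential is untouched, so switching the treatment off restores
#' speeds exactly.
#'
#' @param m observed migration speeds (um/h).
#' @param factor multiplier in (0, 1].
#' @return scaled speeds.
#' @export
apply_anti_migratory <- function(m, factor = 0.1) {
  if (factor <= 0 || factor > 1) stop("anti-migratory factor must be in (0, 1]")
  m * factor
}
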