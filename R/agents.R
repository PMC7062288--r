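# Cell agents: population container, Hill-type PDGF response, observed
# phenotype, cycle progression / quiescence, division with exact inheritance,
# and activation of the recruitable progenitor field.

#' Cell lineage codes
#'
#' `1` = INFECTED (retrovirally transformed, PDGF-secreting), `2` = RECRUITED
#' (normal progenitor activated by PDGF; responds but does not secrete).
#' Inactive recruitable progenitors are held outside the active population
#' until activation.
#'
#' @format Named integer vector.
#' @export
LINEAGE <- c(INFECTED = 1L, RECRUITED = 2L)

CELL_DIAMETER_UM <- 25

#' Create an empty cell population
#'
#' The population is a growable column store (one vector per trait) wrapped in
#' an environment so the engine can update it in place. Traits: position
#' (um), lineage, inherited intermitotic time `tau` (h) and maximal migration
#' speed `v` (um/h), cycle progress in `[0, 1)`, quiescence flag, migration
#' state (moving/stopped, heading, remaining persistence time).
#'
#' @param capacity initial storage capacity.
#' @return object of class `cell_population`.
#' @export
new_population <- function(capacity = 1024L) {
  pop <- new.env(parent = emptyenv())
  pop$n <- 0L
  pop$cap <- as.integer(capacity)
  pop$next_id <- 1L
  for (nm in c("x", "y", "tau", "v", "cycle", "heading", "persist"))
    pop[[nm]] <- numeric(capacity)
  pop$id <- integer(capacity)
  pop$parent <- integer(capacity)
  pop$lineage <- integer(capacity)
  pop$quiescent <- logical(capacity)
  pop$moving <- logical(capacity)
  class(pop) <- "cell_population"
  pop
}

pop_grow <- function(pop, need) {
  while (pop$cap < need) {
    newcap <- pop$cap * 2L
    for (nm in c("x", "y", "tau", "v", "cycle", "heading", "persist",
                 "id", "parent", "lineage", "quiescent", "moving"))
      length(pop[[nm]]) <- newcap
    pop$cap <- newcap
  }
  invisible(pop)
}

#' Append cells to a population
#'
#' @param pop a [new_population()].
#' @param x,y positions (um).
#' @param tau,v inherited phenotype (intermitotic time h, max speed um/h).
#' @param lineage lineage codes (see [LINEAGE]).
#' @param cycle,heading,persist,moving,quiescent,parent optional initial state.
#' @return `pop`, invisibly (modified in place).
#' @export
pop_add <- function(pop, x, y, tau, v, lineage,
                    cycle = 0, heading = 0, persist = 0,
                    moving = FALSE, quiescent = FALSE, parent = 0L) {
  k <- length(x)
  if (!k) return(invisible(pop))
  pop_grow(pop, pop$n + k)
  idx <- pop$n + seq_len(k)
  pop$id[idx] <- pop$next_id - 1L + seq_len(k)
  pop$next_id <- pop$next_id + k
  pop$parent[idx] <- rep_len(as.integer(parent), k)
  pop$x[idx] <- x; pop$y[idx] <- y
  pop$tau[idx] <- rep_len(tau, k); pop$v[idx] <- rep_len(v, k)
  pop$lineage[idx] <- rep_len(as.integer(lineage), k)
  pop$cycle[idx] <- rep_len(cycle, k)
  pop$heading[idx] <- rep_len(heading, k)
  pop$persist[idx] <- rep_len(persist, k)
  pop$moving[idx] <- rep_len(moving, k)
  pop$quiescent[idx] <- rep_len(quiescent, k)
  pop$n <- pop$n + k
  invisible(pop)
}

# drop cells (logical mask over 1:n of cells to keep)
pop_keep <- function(pop, keep) {
  idx <- which(keep)
  for (nm in c("x", "y", "tau", "v", "cycle", "heading", "persist",
               "id", "parent", "lineage", "quiescent", "moving"))
    pop[[nm]][seq_along(idx)] <- pop[[nm]][idx]
  pop$n <- length(idx)
  invisible(pop)
}

#' Snapshot a population as a data.frame
#'
#' @param pop a [new_population()].
#' @return data.frame with one row per cell.
#' @export
cells_df <- function(pop) {
  i <- seq_len(pop$n)
  data.frame(
    id = pop$id[i], parent_id = pop$parent[i],
    lineage = names(LINEAGE)[pop$lineage[i]],
    x_um = pop$x[i], y_um = pop$y[i],
    tau_h = pop$tau[i], v_um_per_h = pop$v[i],
    cycle_progress = pop$cycle[i], quiescent = pop$quiescent[i],
    state = ifelse(pop$moving[i], "MOVING", "STOPPED"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.cell_population <- function(x, ...) {
  i <- seq_len(x$n)
  cat(sprintf("<cell_population> %d cells (%d infected, %d recruited), %d quiescent\n",
              x$n, sum(x$lineage[i] == LINEAGE["INFECTED"]),
              sum(x$lineage[i] == LINEAGE["RECRUITED"]), sum(x$quiescent[i])))
  invisible(x)
}

#' PDGF dose response
#'
#' Hill-type response giving the fraction of maximal activity at paracrine
#' PDGF concentration `C_PP`. Infected cells receive a constant autocrine
#' boost `p_a` on top of the paracrine signal:
#' `gamma = (p_a + C_PP) / (p_a + C_PP + K)`; recruited cells instead have a
#' lowered activation barrier through `beta` in (0.1, 1]:
#' `gamma = C_PP / (C_PP + beta * K)`, so for equal `C_PP > 0` a recruited
#' cell responds more strongly than the bare Hill curve yet is still inactive
#' at `C_PP = 0`.
#'
#' @param C_PP paracrine PDGF concentration(s), ng/mL.
#' @param lineage lineage codes (see [LINEAGE]) or `"INFECTED"`/`"RECRUITED"`.
#' @param K half-max concentration (ng/mL).
#' @param beta recruited-cell sensitivity in (0.1, 1].
#' @param p_a autocrine boost for infected cells (ng/mL).
#' @return response fraction(s) in `[0, 1)`.
#' @export
gamma_response <- function(C_PP, lineage, K, beta, p_a) {
  if (is.character(lineage)) lineage <- LINEAGE[lineage]
  stopifnot(all(C_PP >= 0), K > 0)
  infected <- lineage == LINEAGE["INFECTED"]
  out <- numeric(length(C_PP))
  out[infected] <- (p_a + C_PP[infected]) / (p_a + C_PP[infected] + K)
  out[!infected] <- C_PP[!infected] / (C_PP[!infected] + beta * K)
  out
}

#' Observed phenotype under local PDGF
#'
#' The observed proliferation rate and migration speed are the inherited
#' potentials scaled by the PDGF response, evaluated separately for
#' proliferation and migration with their own half-max and sensitivity:
#' `p = gamma_p / tau`, `m = v * gamma_m`.
#'
#' @param tau,v inherited phenotype (h, um/h).
#' @param C_PP local paracrine PDGF (ng/mL).
#' @param lineage lineage codes.
#' @param params a [parameter_set()] (uses `K_p`, `K_m`, `beta_p`, `beta_m`, `p_a`).
#' @return list with components `p` (1/h) and `m` (um/h).
#' @export
observed_phenotype <- function(tau, v, C_PP, lineage, params) {
  gp <- gamma_response(C_PP, lineage, params$K_p, params$beta_p, params$p_a)
  gm <- gamma_response(C_PP, lineage, params$K_m, params$beta_m, params$p_a)
  list(p = gp / tau, m = v * gm)
}

#' Advance the cell cycle and apply density quiescence
#'
#' Cells whose density node holds strictly more cells than its carrying
#' capacity are quiescent: cycle progress is frozen where it left off and no
#' division occurs. Otherwise progress accumulates at the observed
#' proliferation rate `p`; a cell crossing progress 1 emits a division event
#' and resets to 0.
#'
#' @param cycle current progress in `[0, 1)`.
#' @param p observed proliferation rate(s), 1/h.
#' @param dt step length (h).
#' @param local_count cell count at each cell's density node.
#' @param capacity carrying capacity at each cell's density node.
#' @return list with `cycle`, `quiescent` (logical) and `divide` (logical).
#' @export
advance_cycle <- function(cycle, p, dt, local_count, capacity) {
  quiescent <- local_count > capacity
  newcyc <- ifelse(quiescent, cycle, cycle + p * dt)
  divide <- !quiescent & newcyc >= 1
  newcyc[divide] <- 0
  list(cycle = newcyc, quiescent = quiescent, divide = divide)
}

#' Place daughter cells at division
#'
#' Each daughter is created one cell radius (12.5 um) from its parent at a
#' uniform random angle; if the position lands in EMPTY space the angle is
#' resampled (up to 10 times), after which the daughter is placed atop the
#' parent. Daughters inherit the parental phenotype exactly.
#'
#' @param domain a [tissue_domain()].
#' @param x,y parent positions (um).
#' @return list of daughter positions `x`, `y`.
#' @export
place_daughters <- function(domain, x, y) {
  k <- length(x)
  if (!k) return(list(x = numeric(0), y = numeric(0)))
  nx <- x; ny <- y
  todo <- rep(TRUE, k)
  for (attempt in 1:10) {
    if (!any(todo)) break
    ang <- stats::runif(sum(todo), 0, 2 * pi)
    cx <- x[todo] + CELL_RADIUS_UM * cos(ang)
    cy <- y[todo] + CELL_RADIUS_UM * sin(ang)
    ok <- pixel_class(domain, cx, cy) != TISSUE["EMPTY"]
    ti <- which(todo)
    nx[ti[ok]] <- cx[ok]; ny[ti[ok]] <- cy[ok]
    todo[ti[ok]] <- FALSE
  }
  # unresolved daughters sit atop the parent
  list(x = nx, y = ny)
}

#' Activation test for recruitable progenitors
#'
#' An inactive recruitable cell becomes RECRUITED (permanently) when the local
#' PDGF strictly exceeds the activation threshold (5e-4 ng/mL).
#'
#' @param C_PP_local local PDGF at each recruitable cell (ng/mL).
#' @param threshold activation threshold (ng/mL).
#' @return logical vector: activate?
#' @export
maybe_activate <- function(C_PP_local, threshold = 5e-4) {
  C_PP_local > threshold
}

# truncated-normal phenotype draws (resampling; degenerate sd -> constant)
draw_truncnorm <- function(n, mean, sd, lo, hi = Inf) {
  if (n == 0) return(numeric(0))
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lo), hi))
  out <- stats::rnorm(n, mean, sd)
  bad <- out < lo | out > hi
  guard <- 0L
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < lo | out > hi
    guard <- guard + 1L
    if (guard > 1000L) { out[bad] <- pmin(pmax(out[bad], lo), hi); break }
  }
  out
}

draw_phenotypes <- function(n, params) {
  list(tau = draw_truncnorm(n, params$tau_mean, params$sigma_tau, lo = 5),
       v = draw_truncnorm(n, params$v_mean, params$sigma_v, lo = 0, hi = 100))
}

#' Carrying capacity of every density node
#'
#' `kappa` in gray matter, `2 * kappa / 3` in white matter, 0 outside tissue.
#'
#' @param domain a [tissue_domain()].
#' @param kappa gray-matter capacity per node.
#' @return numeric vector over density nodes.
#' @export
node_capacity <- function(domain, kappa) {
  cl <- domain$density$class
  cap <- numeric(length(cl))
  cap[cl == TISSUE["GRAY"]] <- kappa
  cap[cl == TISSUE["WHITE"]] <- 2 * kappa / 3
  cap
}

# uniform sample of k points inside disc (site, radius) restricted to tissue
sample_disc_positions <- function(domain, site, radius, k) {
  xs <- numeric(k); ys <- numeric(k); got <- 0L
  guard <- 0L
  while (got < k) {
    m <- (k - got) * 2L
    r <- radius * sqrt(stats::runif(m))
    a <- stats::runif(m, 0, 2 * pi)
    cx <- site[1] + r * cos(a); cy <- site[2] + r * sin(a)
    ok <- pixel_class(domain, cx, cy) != TISSUE["EMPTY"]
    take <- min(sum(ok), k - got)
    if (take > 0) {
      sel <- which(ok)[seq_len(take)]
      xs[got + seq_len(take)] <- cx[sel]
      ys[got + seq_len(take)] <- cy[sel]
      got <- got + take
    }
    guard <- guard + 1L
    if (guard > 1000L) stop("injection disc contains no tissue")
  }
  list(x = xs, y = ys)
}

#' Initialize the cell populations
#'
#' Places the initial injection of infected and recruited cells uniformly in a
#' disc around the injection site, and seeds the inactive recruitable
#' progenitor field across the brain matter: each density node receives a
#' Poisson count with mean `rho_R`% of its carrying capacity, placed uniformly
#' within the node. Phenotypes are drawn from truncated normal distributions
#' (`tau >= 5` h, `0 <= v <= 100` um/h); zero spreads reproduce the
#' homogeneous model. Recruitable cells draw their phenotype at activation
#' time from the same distributions.
#'
#' @param domain a [tissue_domain()].
#' @param params a [parameter_set()].
#' @param seed optional integer seed (sets the RNG if given).
#' @return list with `pop` (active [new_population()]) and `recruitable`
#'   (list `x`, `y`, `hex` of inactive progenitors).
#' @export
init_population <- function(domain, params, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  site <- params$injection_site %||% c(domain$width_um / 2, domain$height_um / 2)
  if (pixel_class(domain, site[1], site[2]) == TISSUE["EMPTY"])
    stop("injection site lies outside tissue")

  pop <- new_population()
  n0 <- params$n_injected + params$n_recruited0
  pos <- sample_disc_positions(domain, site, params$injection_radius, n0)
  ph <- draw_phenotypes(n0, params)
  pop_add(pop, pos$x, pos$y, ph$tau, ph$v,
          lineage = rep(c(LINEAGE["INFECTED"], LINEAGE["RECRUITED"]),
                        c(params$n_injected, params$n_recruited0)),
          heading = stats::runif(n0, 0, 2 * pi))

  # recruitable field: Poisson(rho_R% of capacity) per density node
  cap <- node_capacity(domain, params$kappa)
  lambda <- params$rho_R / 100 * cap
  counts <- stats::rpois(length(lambda), lambda)
  tot <- sum(counts)
  rx <- numeric(tot); ry <- numeric(tot); got <- 0L
  d <- domain$density
  nodes <- which(counts > 0)
  for (nd in nodes) {
    k <- counts[nd]
    x0 <- ((nd - 1L) %% d$nx) * d$spacing
    y0 <- ((nd - 1L) %/% d$nx) * d$spacing
    # rejection sample onto tissue pixels within the node square
    cx <- stats::runif(k, x0, min(x0 + d$spacing, domain$width_um - 1e-9))
    cy <- stats::runif(k, y0, min(y0 + d$spacing, domain$height_um - 1e-9))
    for (attempt in 1:20) {
      bad <- pixel_class(domain, cx, cy) == TISSUE["EMPTY"]
      if (!any(bad)) break
      cx[bad] <- stats::runif(sum(bad), x0, min(x0 + d$spacing, domain$width_um - 1e-9))
      cy[bad] <- stats::runif(sum(bad), y0, min(y0 + d$spacing, domain$height_um - 1e-9))
    }
    ok <- pixel_class(domain, cx, cy) != TISSUE["EMPTY"]
    kk <- sum(ok)
    if (kk) {
      rx[got + seq_len(kk)] <- cx[ok]
      ry[got + seq_len(kk)] <- cy[ok]
      got <- got + kk
    }
  }
  rx <- rx[seq_len(got)]; ry <- ry[seq_len(got)]
  hx <- hex_node_raw(domain, rx, ry)
  ok <- !is.na(hx)  # drop cells on tissue slivers with no hex node
  list(pop = pop,
       recruitable = list(x = rx[ok], y = ry[ok], hex = hx[ok]))
}
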