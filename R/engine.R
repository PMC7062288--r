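# Engine: orchestrates one simulation — density rebuild, recruitable
# activation, the cell loop (quiescence/cycle, division, migration, PDGF
# secretion/consumption), field decay and diffusion, and treatments.

#' Create a simulation state
#'
#' Initializes the cell populations ([init_population()]), deposits the
#' initial PDGF bolus at the injection site, and precomputes the diffusion
#' operator. All subsequent evolution happens in place via [sim_step()].
#'
#' @param domain a [tissue_domain()].
#' @param params a [parameter_set()].
#' @param schedule a [treatment_schedule()] or `NULL`.
#' @param seed integer seed; the whole trajectory is reproducible given
#'   (`params`, `schedule`, `seed`).
#' @return an environment of class `simulation_state`.
#' @export
simulation_state <- function(domain, params, schedule = NULL, seed = 1L) {
  set.seed(as.integer(seed))
  st <- new.env(parent = emptyenv())
  st$domain <- domain; st$params <- params; st$schedule <- schedule
  st$seed <- as.integer(seed)
  st$time_h <- 0
  init <- init_population(domain, params)
  st$pop <- init$pop
  st$recruitable <- init$recruitable
  st$capacity <- node_capacity(domain, params$kappa)
  site <- params$injection_site %||% c(domain$width_um / 2, domain$height_um / 2)
  f <- pdgf_field(domain, D_p = params$D_p, r_d = params$r_d,
                  r_s = params$r_s, r_c = params$r_c)
  f <- deposit_initial_bolus(f, params$p0, site, params$injection_radius)
  st$conc <- f$conc
  st$diffop <- build_diffusion_operator(domain, params$D_p, params$dt)
  st$density <- tabulate(density_node_raw(domain, st$pop$x[seq_len(st$pop$n)],
                                          st$pop$y[seq_len(st$pop$n)]),
                         nbins = domain$density$n)
  st$log <- list(time_h = numeric(0), n_cells = integer(0),
                 births = integer(0), kills = integer(0),
                 activations = integer(0))
  st$tracking <- NULL
  class(st) <- "simulation_state"
  st
}

#' Advance a simulation by one time step
#'
#' Executes, in order: (1) density rebuild; (2) recruitable activation sweep
#' (newly recruited cells draw their phenotype now and enter the cell loop
#' next step); (3) the cell loop over active cells — quiescence and cycle
#' progression, divisions, stop-and-go migration under the density rules —
#' with daughters appended after the loop; (4) PDGF secretion (infected cells)
#' and consumption (all active cells) at post-move positions; (5) field decay
#' then diffusion; (6) anti-proliferative kill sweep while AP treatment is
#' active. Cells in regions below the PDGF activity cutoff skip cycle
#' progression and movement for the step.
#'
#' @param st a [simulation_state()] (modified in place).
#' @return `st`, invisibly.
#' @export
sim_step <- function(st) {
  params <- st$params; domain <- st$domain; dt <- params$dt
  pop <- st$pop
  n <- pop$n
  i <- seq_len(n)

  # (1) density rebuild
  node <- density_node_raw(domain, pop$x[i], pop$y[i])
  density <- tabulate(node, nbins = domain$density$n)

  # (2) recruitable activation sweep; activated cells are appended at the end
  # of the step (they enter the cell loop next step)
  activations <- 0L
  activated <- NULL
  rec <- st$recruitable
  if (length(rec$x)) {
    act <- maybe_activate(st$conc[rec$hex], params$activation_threshold)
    if (any(act)) {
      k <- sum(act)
      ph <- draw_phenotypes(k, params)
      activated <- list(x = rec$x[act], y = rec$y[act],
                        tau = ph$tau, v = ph$v,
                        heading = stats::runif(k, 0, 2 * pi))
      st$recruitable <- list(x = rec$x[!act], y = rec$y[!act],
                             hex = rec$hex[!act])
      activations <- k
    }
  }

  births <- 0L
  daughters <- NULL
  if (n) {
    hexid <- hex_node_raw(domain, pop$x[i], pop$y[i])
    hexid[is.na(hexid)] <- 1L  # isolated sliver fallback; concentration ~ arbitrary node
    C <- st$conc[hexid]
    low <- C < params$activation_threshold  # gamma <= cutoff: skip activity
    gp <- gamma_response(C, pop$lineage[i], params$K_p, params$beta_p, params$p_a)
    gm <- gamma_response(C, pop$lineage[i], params$K_m, params$beta_m, params$p_a)
    gp[low] <- 0; gm[low] <- 0

    # quiescence + cycle + division events
    adv <- advance_cycle(pop$cycle[i], gp / pop$tau[i], dt, density[node],
                         st$capacity[node])
    pop$cycle[i] <- adv$cycle
    pop$quiescent[i] <- adv$quiescent
    div <- which(adv$divide)
    births <- length(div)
    if (births) {
      dpos <- place_daughters(domain, pop$x[div], pop$y[div])
      daughters <- list(x = dpos$x, y = dpos$y, tau = pop$tau[div],
                        v = pop$v[div], lineage = pop$lineage[div],
                        parent = pop$id[div])
    }

    # migration
    x_pre <- pop$x[i]; y_pre <- pop$y[i]
    update_persistence(pop, domain, params, dt)
    m <- pop$v[i] * gm
    if (treatment_active(st$schedule, "AM", st$time_h))
      m <- apply_anti_migratory(m, st$schedule$am_factor)
    if (!params$quiescent_migrate) m[pop$quiescent[i]] <- 0
    density <- attempt_move(pop, m, dt, domain, density, st$capacity)

    # (4) PDGF secretion and consumption at post-move positions (hex ids are
    # reused for cells that did not change position this step)
    moved <- pop$x[i] != x_pre | pop$y[i] != y_pre
    hex2 <- hexid
    if (any(moved)) {
      h2 <- hex_node_raw(domain, pop$x[i][moved], pop$y[i][moved])
      h2[is.na(h2)] <- 1L
      hex2[moved] <- h2
    }
    inf <- pop$lineage[i] == LINEAGE["INFECTED"]
    if (any(inf))
      st$conc <- field_secrete(st$conc, hex2[inf], params$r_s, dt)
    st$conc <- field_consume(st$conc, hex2, params$r_c * params$r_s, dt)
  }

  if (!is.null(activated))
    pop_add(pop, activated$x, activated$y, activated$tau, activated$v,
            lineage = LINEAGE["RECRUITED"], heading = activated$heading)

  daughter_ids <- integer(0)
  if (births) {
    nb <- pop$n
    pop_add(pop, daughters$x, daughters$y, daughters$tau, daughters$v,
            lineage = daughters$lineage, parent = daughters$parent,
            heading = stats::runif(births, 0, 2 * pi))
    daughter_ids <- pop$id[nb + seq_len(births)]
  }
  if (!is.null(st$tracking))
    track_step(st, if (births) daughters$parent else integer(0), daughter_ids)

  # (5) decay then diffusion
  st$conc <- st$conc * exp(-params$r_d * dt / 24)
  st$conc <- field_diffuse(st$conc, st$diffop)

  # (6) anti-proliferative kill sweep
  kills <- 0L
  if (treatment_active(st$schedule, "AP", st$time_h) && pop$n) {
    j <- seq_len(pop$n)
    doomed <- !pop$quiescent[j] & pop$tau[j] < st$schedule$ap_threshold
    kills <- sum(doomed)
    if (kills) {
      if (!is.null(st$tracking)) track_drop(st, pop$id[j][doomed])
      pop_keep(pop, !doomed)
    }
  }

  if (pop$n > (params$max_cells %||% Inf))
    stop("population exceeded max_cells (", params$max_cells, "); aborting")
  st$time_h <- st$time_h + dt
  st$log$time_h <- c(st$log$time_h, st$time_h)
  st$log$n_cells <- c(st$log$n_cells, pop$n)
  st$log$births <- c(st$log$births, births)
  st$log$kills <- c(st$log$kills, kills)
  st$log$activations <- c(st$log$activations, activations)
  invisible(st)
}

#' Summarize a simulation state into a metric report
#'
#' @param st a [simulation_state()].
#' @param radial include radial phenotype profiles?
#' @return list of imaging-, population- and cell-scale metrics.
#' @export
metric_report <- function(st, radial = FALSE) {
  pop <- st$pop; domain <- st$domain
  grid <- density_grid(pop, domain, st$params$kappa)
  cr <- core_and_rim(grid)
  i <- seq_len(pop$n)
  n_i <- sum(pop$lineage[i] == LINEAGE["INFECTED"])
  n_r <- sum(pop$lineage[i] == LINEAGE["RECRUITED"])
  rep <- list(
    time_d = st$time_h / 24,
    n_cells = pop$n, n_infected = n_i, n_recruited = n_r,
    n_quiescent = sum(pop$quiescent[i]),
    n_recruitable_inactive = length(st$recruitable$x),
    diameter_mm = tumor_diameter(grid, 0.10),
    d_c_mm = unname(cr["d_c"]), d_r_mm = unname(cr["d_r"]),
    I_R_ratio = if (n_r > 0) n_i / n_r else NA_real_
  )
  if (pop$n) {
    hexid <- hex_node_raw(domain, pop$x[i], pop$y[i])
    hexid[is.na(hexid)] <- 1L
    C <- st$conc[hexid]
    rep$phenotypes <- phenotype_stats(pop, C, st$params, radial = radial)
    rep$ki67_pct <- ki67_index(pop, domain, C, st$params)
  }
  rep
}

#' Run a full simulation
#'
#' Steps the model to `params$end_day`, recording a [metric_report()] at each
#' requested day, with optional virtual cell tracking (see [record_tracks()]).
#'
#' @param domain a [tissue_domain()].
#' @param params a [parameter_set()].
#' @param schedule a [treatment_schedule()] or `NULL`.
#' @param record_days days at which to record metric reports (the end time is
#'   always recorded).
#' @param seed integer seed.
#' @param tracking `NULL` or a list with `start_day`, `duration_h`, `n_cells`
#'   (and optionally `region = c(lo, hi)` density fractions) enabling virtual
#'   cell tracking at the engine step cadence.
#' @param radial record radial phenotype profiles in each report?
#' @return list of class `gliosim_run`: `reports` (one per recorded day),
#'   `final` ([simulation_state()]), `log` (per-step counts data.frame),
#'   `tracks` (a track table, if tracking was enabled).
#' @export
simulate_tumor <- function(domain, params, schedule = NULL,
                           record_days = NULL, seed = 1L, tracking = NULL,
                           radial = FALSE) {
  st <- simulation_state(domain, params, schedule, seed)
  record_days <- sort(unique(c(record_days, params$end_day)))
  n_steps <- as.integer(round(params$end_day * 24 / params$dt))
  rec_steps <- as.integer(round(record_days * 24 / params$dt))
  reports <- vector("list", length(record_days))
  names(reports) <- paste0("day_", record_days)
  if (!is.null(tracking)) init_tracking(st, tracking)
  if (0L %in% rec_steps)
    reports[[which(rec_steps == 0L)]] <- metric_report(st, radial)
  if (n_steps > 0) for (s in seq_len(n_steps)) {
    if (!is.null(st$tracking)) maybe_start_tracking(st)
    sim_step(st)
    hit <- which(rec_steps == s)
    if (length(hit)) reports[[hit]] <- metric_report(st, radial)
  }
  structure(list(reports = reports, final = st,
                 log = as.data.frame(st$log),
                 tracks = if (!is.null(st$tracking)) tracks_df(st) else NULL,
                 record_days = record_days),
            class = "gliosim_run")
}

#' @export
print.gliosim_run <- function(x, ...) {
  cat("<gliosim_run>\n")
  for (r in x$reports)
    cat(sprintf("  day %5.2f: %6d cells, diameter %.2f mm (core %.2f, rim %.2f), I/R %s\n",
                r$time_d, r$n_cells, r$diameter_mm, r$d_c_mm, r$d_r_mm,
                ifelse(is.na(r$I_R_ratio), "NA", sprintf("%.2f", r$I_R_ratio))))
  invisible(x)
}

#' Validate bookkeeping invariants of a state
#'
#' Checks the density partition property (per-node counts sum to the number of
#' active agents), that no cell sits on EMPTY tissue, and field non-negativity.
#'
#' @param st a [simulation_state()].
#' @return `TRUE`, or an error describing the violated invariant.
#' @export
validate_state <- function(st) {
  pop <- st$pop; i <- seq_len(pop$n)
  dens <- tabulate(density_node_raw(st$domain, pop$x[i], pop$y[i]),
                   nbins = st$domain$density$n)
  if (sum(dens) != pop$n) stop("density partition violated")
  if (any(pixel_class(st$domain, pop$x[i], pop$y[i]) == TISSUE["EMPTY"]))
    stop("cell occupies EMPTY space")
  if (any(st$conc < 0)) stop("negative PDGF concentration")
  TRUE
}
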