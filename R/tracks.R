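# Virtual cell tracking during a simulation, and track-table statistics
# (per-cell speed, run/stop segmentation, population metrics) applicable to
# simulated and experimental-format tables alike.

# ---- engine-side tracking hooks ----

init_tracking <- function(st, spec) {
  tr <- new.env(parent = emptyenv())
  tr$t0 <- spec$start_day * 24
  tr$t1 <- tr$t0 + (spec$duration_h %||% 25)
  tr$n_cells <- spec$n_cells %||% 50L
  tr$region <- spec$region %||% c(0.01, 0.5)
  tr$started <- FALSE
  tr$cells <- integer(0)      # cell ids currently tracked
  tr$tracks <- integer(0)     # parallel track ids
  tr$next_track <- 1L
  tr$mother <- integer(0)     # track ids that ended in division
  tr$divided <- integer(0)    # track ids flagged divided (mother or daughter)
  tr$buf <- list()
  st$tracking <- tr
  invisible(st)
}

# choose tracked cells from the tumor rim once the window opens
maybe_start_tracking <- function(st) {
  tr <- st$tracking
  if (tr$started || st$time_h < tr$t0 - 1e-9) return(invisible(st))
  pop <- st$pop; i <- seq_len(pop$n)
  node <- density_node_raw(st$domain, pop$x[i], pop$y[i])
  dens <- tabulate(node, nbins = st$domain$density$n)
  cap <- st$capacity[node]
  frac <- ifelse(cap > 0, dens[node] / cap, Inf)
  in_rim <- frac >= tr$region[1] & frac < tr$region[2]
  cand <- which(in_rim)
  if (length(cand) < tr$n_cells) {
    warning(sprintf("only %d cells available in the tracking region (requested %d)",
                    length(cand), tr$n_cells))
    sel <- cand
  } else sel <- sample(cand, tr$n_cells)
  tr$cells <- pop$id[sel]
  tr$tracks <- tr$next_track - 1L + seq_along(sel)
  tr$next_track <- tr$next_track + length(sel)
  tr$started <- TRUE
  invisible(st)
}

# record one frame; handle division bookkeeping (mother track ends, the two
# post-division cells start fresh tracks flagged divided)
track_step <- function(st, parent_ids, daughter_ids) {
  tr <- st$tracking
  if (!tr$started || st$time_h > tr$t1 + 1e-9) return(invisible(st))
  if (length(parent_ids)) {
    hit <- which(parent_ids %in% tr$cells)
    for (j in hit) {
      k <- match(parent_ids[j], tr$cells)
      old <- tr$tracks[k]
      tr$mother <- c(tr$mother, old)
      tr$divided <- c(tr$divided, old, tr$next_track, tr$next_track + 1L)
      # parent continues under a new track id; daughter starts its own
      tr$tracks[k] <- tr$next_track
      tr$cells <- c(tr$cells, daughter_ids[j])
      tr$tracks <- c(tr$tracks, tr$next_track + 1L)
      tr$next_track <- tr$next_track + 2L
    }
  }
  pop <- st$pop
  idx <- match(tr$cells, pop$id[seq_len(pop$n)])
  ok <- !is.na(idx)
  if (any(ok)) {
    tr$buf[[length(tr$buf) + 1L]] <- data.frame(
      track_id = tr$tracks[ok], cell_id = tr$cells[ok],
      lineage = names(LINEAGE)[pop$lineage[idx[ok]]],
      t_h = st$time_h, x_um = pop$x[idx[ok]], y_um = pop$y[idx[ok]],
      stringsAsFactors = FALSE)
  }
  invisible(st)
}

track_drop <- function(st, ids) {
  tr <- st$tracking
  keep <- !(tr$cells %in% ids)
  tr$cells <- tr$cells[keep]; tr$tracks <- tr$tracks[keep]
  invisible(st)
}

tracks_df <- function(st) {
  tr <- st$tracking
  if (!length(tr$buf)) return(NULL)
  out <- do.call(rbind, tr$buf)
  out$divided <- out$track_id %in% tr$divided
  out$mother <- out$track_id %in% tr$mother
  out <- out[order(out$track_id, out$t_h), ]
  rownames(out) <- NULL
  attr(out, "n_divisions") <- length(tr$mother)
  attr(out, "n_start") <- length(unique(out$track_id[out$t_h <= min(out$t_h) + 1e-9]))
  out
}

#' Record single-cell tracks from a simulation
#'
#' Runs the engine with virtual tracking enabled: `n_cells` cells are sampled
#' from the tumor rim (density between 1% and 50% of carrying capacity) when
#' the window opens and their positions are recorded every engine step for
#' `duration_h` hours. Daughters are tracked after division: the mother's
#' track ends and both post-division cells start fresh tracks flagged
#' `divided`. Use a `dt` of 0.05 h to match the 3-minute frame cadence of the
#' experimental assay.
#'
#' @param domain a [tissue_domain()].
#' @param params a [parameter_set()] (its `dt` sets the frame cadence).
#' @param start_day day at which tracking starts.
#' @param duration_h tracking duration (h).
#' @param n_cells number of cells to sample.
#' @param schedule optional [treatment_schedule()].
#' @param seed integer seed.
#' @return a track table (data.frame: `track_id`, `cell_id`, `lineage`, `t_h`,
#'   `x_um`, `y_um`, `divided`, `mother`) with attributes `n_divisions` and
#'   `n_start`; frame cadence equals `params$dt`.
#' @export
record_tracks <- function(domain, params, start_day, duration_h = 25,
                          n_cells = 50L, schedule = NULL, seed = 1L) {
  params$end_day <- start_day + duration_h / 24
  run <- simulate_tumor(domain, params, schedule = schedule, seed = seed,
                        tracking = list(start_day = start_day,
                                        duration_h = duration_h,
                                        n_cells = n_cells))
  run$tracks
}

# ---- track-table statistics ----

track_frame_dt <- function(track) {
  ts <- sort(unique(track$t_h))
  if (length(ts) < 2) stop("track table needs at least two frames")
  dts <- diff(ts)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6))
    warning("non-uniform frame cadence; statistics assume the median interval")
  dt
}

# per-frame displacements for one track (ordered by time)
frame_disp <- function(x, y) sqrt(diff(x)^2 + diff(y)^2)

#' Per-cell migration speed
#'
#' Total distance traveled over the total time spent moving: per-frame
#' displacements below `resolution` count as stopped frames and are excluded
#' from both numerator and denominator. Cells that never move get `NA`.
#'
#' @param track a track table (see [record_tracks()]).
#' @param resolution stop-resolution threshold in um per frame.
#' @return data.frame `track_id`, `speed_um_h` (NA when the cell never moved).
#' @export
per_cell_speed <- function(track, resolution = 1) {
  dt <- track_frame_dt(track)
  res <- lapply(split(track, track$track_id), function(tt) {
    tt <- tt[order(tt$t_h), ]
    if (nrow(tt) < 2) return(NA_real_)
    d <- frame_disp(tt$x_um, tt$y_um)
    mov <- d >= resolution
    if (!any(mov)) return(NA_real_)
    sum(d[mov]) / (sum(mov) * dt)
  })
  data.frame(track_id = as.integer(names(res)),
             speed_um_h = unlist(res), row.names = NULL)
}

#' Segment tracks into directional runs and stops
#'
#' Frames with displacement below `resolution` are STOP frames; maximal blocks
#' of consecutive like frames form stops and runs, and moving blocks are
#' additionally split at turns — frame-to-frame heading changes larger than
#' `turn_threshold_deg` — so each run is directional. Each segment reports its
#' duration, mean speed (runs) and net heading.
#'
#' @inheritParams per_cell_speed
#' @param turn_threshold_deg heading change (degrees) splitting two runs;
#'   `Inf` disables turn splitting.
#' @return data.frame: `track_id`, `segment`, `type` (`"run"`/`"stop"`),
#'   `start_h`, `duration_h`, `mean_speed_um_h`, `net_heading_rad`.
#' @export
run_stop_segmentation <- function(track, resolution = 1,
                                  turn_threshold_deg = 15) {
  dt <- track_frame_dt(track)
  thr <- turn_threshold_deg * pi / 180
  out <- lapply(split(track, track$track_id), function(tt) {
    tt <- tt[order(tt$t_h), ]
    if (nrow(tt) < 2) return(NULL)
    d <- frame_disp(tt$x_um, tt$y_um)
    moving <- d >= resolution
    # segment labels: change at move/stop transitions and at sharp turns
    # between consecutive moving frames
    nfr <- length(d)
    newseg <- c(TRUE, moving[-1] != moving[-nfr])
    if (is.finite(thr) && nfr > 1) {
      head_f <- atan2(diff(tt$y_um), diff(tt$x_um))
      dh <- head_f[-1] - head_f[-nfr]
      turn <- abs(atan2(sin(dh), cos(dh))) > thr
      both_moving <- moving[-1] & moving[-nfr]
      newseg[-1] <- newseg[-1] | (turn & both_moving)
    }
    lab <- cumsum(newseg)
    r <- list(lengths = rle(lab)$lengths,
              values = moving[!duplicated(lab)])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(
      track_id = tt$track_id[1], segment = seq_along(r$values),
      type = ifelse(r$values, "run", "stop"),
      start_h = tt$t_h[starts],
      duration_h = r$lengths * dt,
      mean_speed_um_h = vapply(seq_along(r$values), function(k) {
        if (!r$values[k]) return(0)
        sum(d[starts[k]:ends[k]]) / (r$lengths[k] * dt)
      }, numeric(1)),
      net_heading_rad = vapply(seq_along(r$values), function(k) {
        atan2(tt$y_um[ends[k] + 1L] - tt$y_um[starts[k]],
              tt$x_um[ends[k] + 1L] - tt$x_um[starts[k]])
      }, numeric(1)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Population-level track statistics
#'
#' Mean per-cell speed, run/stop persistence statistics, turning angles
#' between successive run headings, the time- and cell-averaged MSD curve, and
#' the bulk proliferation rate: the number of division events divided by the
#' number of cells at the start of the observation window and the observation
#' time, in % per hour.
#'
#' Because consecutive same-state persistence periods are indistinguishable
#' in a trajectory (two back-to-back stops look like one long stop; two runs
#' separated by an undetected small turn look like one run), the observed
#' block means overestimate the underlying persistence means. Under
#' memoryless (exponential) persistence with state re-choice probability
#' `move_prob`, an observed stop is a geometric sum of underlying stop
#' periods, so `persistence_stop_min = mean_stop * move_prob`; similarly runs
#' are corrected by the probability that a reset produced a move with a turn
#' below the detection threshold (uniform turning assumed, i.e. gray matter).
#'
#' @inheritParams run_stop_segmentation
#' @param n_divisions,n_start override the division-event count and starting
#'   cell count (taken from table attributes when absent; `n_divisions` falls
#'   back to the number of mother tracks).
#' @param max_lag_frames maximum MSD lag, in frames.
#' @param move_prob probability that a persistence reset chooses "move"
#'   (used for the persistence-mean corrections).
#' @return list: `mean_speed_um_h`, `mean_run_h`, `mean_stop_h` (observed
#'   block means), `persistence_move_min`, `persistence_stop_min` (corrected
#'   underlying means), `turning_angles_rad`, `msd` (data.frame `lag_h`,
#'   `msd_um2`), `proliferation_rate_pct_h`.
#' @export
population_stats <- function(track, resolution = 1, n_divisions = NULL,
                             n_start = NULL, max_lag_frames = 100L,
                             move_prob = 0.5, turn_threshold_deg = 15) {
  dt <- track_frame_dt(track)
  spd <- per_cell_speed(track, resolution)
  seg <- run_stop_segmentation(track, resolution, turn_threshold_deg)
  runs <- seg[seg$type == "run", ]
  stops <- seg[seg$type == "stop", ]

  # turning angles between consecutive run headings within a track
  turns <- unlist(lapply(split(runs, runs$track_id), function(rr) {
    if (nrow(rr) < 2) return(numeric(0))
    d <- diff(rr$net_heading_rad)
    atan2(sin(d), cos(d))  # wrap to (-pi, pi]
  }), use.names = FALSE)

  # MSD averaged over cells and time origins
  by_track <- split(track, track$track_id)
  lags <- seq_len(min(max_lag_frames,
                      max(vapply(by_track, nrow, integer(1))) - 1L))
  msd_sum <- numeric(length(lags)); msd_n <- numeric(length(lags))
  for (tt in by_track) {
    tt <- tt[order(tt$t_h), ]
    nf <- nrow(tt)
    for (L in lags) {
      if (L >= nf) break
      dx <- tt$x_um[(1 + L):nf] - tt$x_um[1:(nf - L)]
      dy <- tt$y_um[(1 + L):nf] - tt$y_um[1:(nf - L)]
      msd_sum[L] <- msd_sum[L] + sum(dx^2 + dy^2)
      msd_n[L] <- msd_n[L] + (nf - L)
    }
  }
  msd <- data.frame(lag_h = lags * dt,
                    msd_um2 = ifelse(msd_n > 0, msd_sum / msd_n, NA_real_))

  n_div <- n_divisions %||% attr(track, "n_divisions") %||%
    if (!is.null(track$mother)) length(unique(track$track_id[track$mother])) else 0L
  n0 <- n_start %||% attr(track, "n_start") %||%
    length(unique(track$track_id[track$t_h <= min(track$t_h) + 1e-9]))
  obs_h <- diff(range(track$t_h))

  mean_run <- if (nrow(runs)) mean(runs$duration_h) else NA_real_
  mean_stop <- if (nrow(stops)) mean(stops$duration_h) else NA_real_
  q_run <- move_prob * min(turn_threshold_deg, 180) / 180
  list(mean_speed_um_h = mean(spd$speed_um_h, na.rm = TRUE),
       mean_run_h = mean_run, mean_stop_h = mean_stop,
       persistence_move_min = mean_run * (1 - q_run) * 60,
       persistence_stop_min = mean_stop * move_prob * 60,
       turning_angles_rad = turns,
       msd = msd,
       proliferation_rate_pct_h = 100 * n_div / (n0 * obs_h))
}

#' Write / read a track table CSV
#'
#' Long-format CSV used both for simulated tracks and for experimental data
#' in the same layout.
#'
#' @param track a track table.
#' @param path CSV path.
#' @return `path` (write) or the track table (read).
#' @export
write_tracks_csv <- function(track, path) {
  utils::write.csv(track, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
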