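straight_track <- function(speed = 20, hours = 10, dt = 0.05, id = 1L,
                           heading = 0) {
  t_h <- seq(0, hours, by = dt)
  data.frame(track_id = id, cell_id = id, lineage = "INFECTED", t_h = t_h,
             x_um = speed * t_h * cos(heading),
             y_um = speed * t_h * sin(heading),
             stringsAsFactors = FALSE)
}

test_that("per-cell speed is distance over time moving, not elapsed time", {
  # always moving straight at 20 um/h
  expect_equal(per_cell_speed(straight_track(20))$speed_um_h, 20)

  # 10 h at 30 um/h then 10 h stopped: speed is 30, not 15
  t_h <- seq(0, 20, by = 0.05)
  tr <- data.frame(track_id = 1L, cell_id = 1L, lineage = "INFECTED",
                   t_h = t_h, x_um = pmin(t_h, 10) * 30, y_um = 0)
  expect_equal(per_cell_speed(tr)$speed_um_h, 30)

  # all displacements below resolution: speed is missing, not zero
  tr2 <- straight_track(speed = 5)  # 0.25 um per frame < 1 um resolution
  expect_true(is.na(per_cell_speed(tr2)$speed_um_h))

  # stationary cell: all displacements zero
  tr3 <- straight_track(speed = 0)
  expect_true(is.na(per_cell_speed(tr3)$speed_um_h))
})

test_that("segmentation recovers constructed run/stop boundaries exactly", {
  dt <- 0.05
  # known runs: 2 h east, 1 h stop, 3 h north
  t_h <- seq(0, 6, by = dt)
  x <- pmin(t_h, 2) * 30
  y <- pmax(t_h - 3, 0) * 40
  tr <- data.frame(track_id = 1L, cell_id = 1L, lineage = "INFECTED",
                   t_h = t_h, x_um = x, y_um = y)
  seg <- run_stop_segmentation(tr)
  expect_equal(seg$type, c("run", "stop", "run"))
  expect_equal(seg$duration_h, c(2, 1, 3))
  expect_equal(seg$mean_speed_um_h, c(30, 0, 40))
  # run headings (stops have no meaningful heading)
  expect_equal(seg$net_heading_rad[seg$type == "run"], c(0, pi / 2),
               tolerance = 1e-9)

  # a sharp turn splits two runs even without an intervening stop
  t2 <- seq(0, 4, by = dt)
  tr2 <- data.frame(track_id = 1L, cell_id = 1L, lineage = "INFECTED",
                    t_h = t2, x_um = pmin(t2, 2) * 30,
                    y_um = pmax(t2 - 2, 0) * 30)
  seg2 <- run_stop_segmentation(tr2)
  expect_equal(seg2$type, c("run", "run"))
  expect_equal(seg2$duration_h, c(2, 2))

  # alternating one-frame move/stop
  n <- 20
  xs <- cumsum(rep(c(2, 0), n))
  tr3 <- data.frame(track_id = 1L, cell_id = 1L, lineage = "INFECTED",
                    t_h = seq_len(2 * n) * dt, x_um = xs, y_um = 0)
  seg3 <- run_stop_segmentation(tr3)
  expect_equal(seg3$duration_h, rep(dt, nrow(seg3)))

  # an all-stop track is one stop of full duration
  tr4 <- straight_track(0, hours = 5)
  seg4 <- run_stop_segmentation(tr4)
  expect_equal(nrow(seg4), 1)
  expect_equal(seg4$type, "stop")
  expect_equal(seg4$duration_h, 5)
})

test_that("population statistics follow their defining formulas", {
  # 100 cells, 10 divisions over 25 h -> 0.4 %/h
  trs <- do.call(rbind, lapply(1:100, function(i)
    straight_track(20, hours = 25, dt = 0.25, id = i,
                   heading = 2 * pi * i / 100)))
  ps <- population_stats(trs, n_divisions = 10, n_start = 100)
  expect_equal(ps$proliferation_rate_pct_h, 10 / (100 * 25) * 100)

  # straight-line tracks: zero turning, ballistic MSD
  expect_true(all(abs(ps$turning_angles_rad) < 1e-9))
  msd <- ps$msd
  fit <- stats::lm(log(msd_um2) ~ log(lag_h), data = msd)
  expect_equal(unname(stats::coef(fit)[2]), 2, tolerance = 1e-6)
  expect_equal(ps$mean_speed_um_h, 20)

  # no divisions: zero rate
  ps0 <- population_stats(trs, n_divisions = 0, n_start = 100)
  expect_equal(ps0$proliferation_rate_pct_h, 0)
})

test_that("persistence means are recovered from simulated walkers at n = 500", {
  # stop-and-go walkers in uniform gray matter, tracked at 3-min cadence
  dom <- gray_domain(6)
  par <- quick_params()
  n <- 500; dt <- 0.05
  set.seed(12)
  pop <- fixed_pop(rep(3000, n), rep(3000, n), persist = 0)
  cap <- node_capacity(dom, 1e9)
  dens <- integer(dom$density$n)
  frames <- vector("list", 600)
  for (s in seq_len(600)) {  # 30 h
    update_persistence(pop, dom, par, dt)
    dens <- attempt_move(pop, rep(30, n), dt, dom, dens, cap)
    frames[[s]] <- data.frame(track_id = seq_len(n), cell_id = seq_len(n),
                              lineage = "INFECTED", t_h = s * dt,
                              x_um = pop$x[1:n], y_um = pop$y[1:n])
  }
  tr <- do.call(rbind, frames)
  ps <- population_stats(tr, resolution = 1, move_prob = par$move_prob,
                         turn_threshold_deg = 15)
  expect_equal(ps$persistence_move_min, 42.6, tolerance = 0.10)
  expect_equal(ps$persistence_stop_min, 70.1, tolerance = 0.10)
  # per-cell speed recovers the imposed speed within 5%
  expect_equal(ps$mean_speed_um_h, 30, tolerance = 0.05)
})

test_that("engine tracking samples the rim and keeps consistent flags", {
  dom <- gray_domain(3)
  par <- quick_params(dt = 0.05, p0 = 400, K_p = 20, K_m = 20, p_a = 30,
                      tau_mean = 25, sigma_tau = 5, kappa = 20)
  run <- simulate_tumor(dom, par, seed = 13,
                        tracking = list(start_day = 1, duration_h = 12,
                                        n_cells = 25))
  tr <- run$tracks
  expect_false(is.null(tr))
  expect_true(all(c("track_id", "cell_id", "lineage", "t_h", "x_um", "y_um",
                    "divided", "mother") %in% names(tr)))
  # frames are strictly increasing per track at the engine cadence
  by_tr <- split(tr, tr$track_id)
  expect_true(all(vapply(by_tr, function(tt) all(diff(tt$t_h) > 0), logical(1))))
  # per-frame displacement never exceeds the maximal possible step (v <= 100)
  disp <- unlist(lapply(by_tr, function(tt)
    sqrt(diff(tt$x_um)^2 + diff(tt$y_um)^2)))
  expect_true(all(disp <= 100 * 0.05 + 1e-6))
  # every mother track is flagged divided; all requested cells were found
  expect_true(all(tr$divided[tr$mother]))
  expect_equal(attr(tr, "n_start"), 25)
  # tracked cells never leave tissue
  expect_true(all(pixel_class(dom, tr$x_um, tr$y_um) != TISSUE["EMPTY"]))
})

test_that("track CSV round-trips through the long format", {
  tr <- straight_track(20, 2)
  f <- tempfile(fileext = ".csv")
  write_tracks_csv(tr, f)
  back <- read_tracks_csv(f)
  expect_equal(back$x_um, tr$x_um)
  expect_equal(per_cell_speed(back)$speed_um_h, 20)
  unlink(f)
})
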