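# constructed density grids with known geometry
disc_counts <- function(dom, center_mm, r_mm, frac, kappa = 100) {
  d <- dom$density
  counts <- integer(d$n)
  inside <- (d$cx / 1000 - center_mm[1])^2 + (d$cy / 1000 - center_mm[2])^2 <=
    r_mm^2
  counts[inside] <- as.integer(round(frac * kappa))
  counts
}

test_that("tumor diameter recovers constructed discs and thresholds", {
  dom <- gray_domain(5)
  kappa <- 100

  # full-density disc of radius 1 mm reads ~2 mm
  g <- density_grid(NULL, dom, kappa,
                    counts = disc_counts(dom, c(2.5, 2.5), 1, 1))
  expect_equal(tumor_diameter(g, 0.10), 2.0, tolerance = 0.06)

  # empty grid reads 0
  g0 <- density_grid(NULL, dom, kappa, counts = integer(dom$density$n))
  expect_equal(tumor_diameter(g0), 0)

  # 5% disc is invisible at the 10% threshold but visible at 1%
  g5 <- density_grid(NULL, dom, kappa,
                     counts = disc_counts(dom, c(2.5, 2.5), 1, 0.05))
  expect_equal(tumor_diameter(g5, 0.10), 0)
  expect_gt(tumor_diameter(g5, 0.01), 1.8)

  # threshold monotonicity on a graded profile
  gr <- density_grid(NULL, dom, kappa,
                     counts = disc_counts(dom, c(2.5, 2.5), 2, 0.6) -
                       disc_counts(dom, c(2.5, 2.5), 1, 0.3))
  ths <- c(0.01, 0.1, 0.3, 0.5)
  ds <- vapply(ths, function(t) tumor_diameter(gr, t), numeric(1))
  expect_true(all(diff(ds) <= 1e-9))
})

test_that("core and rim follow the disc/annulus construction oracles", {
  dom <- gray_domain(5)
  kappa <- 100
  # uniform full-density disc: rim size ~ 0
  g <- density_grid(NULL, dom, kappa,
                    counts = disc_counts(dom, c(2.5, 2.5), 1, 1))
  cr <- core_and_rim(g)
  expect_equal(unname(cr["d_c"]), 2.0, tolerance = 0.06)
  expect_lt(cr["d_r"], 0.12)

  # 60% core of radius 1 mm inside a 5% annulus to 2 mm
  counts <- disc_counts(dom, c(2.5, 2.5), 2, 0.05)
  core <- disc_counts(dom, c(2.5, 2.5), 1, 0.60)
  counts[core > 0] <- core[core > 0]
  g2 <- density_grid(NULL, dom, kappa, counts = counts)
  cr2 <- core_and_rim(g2)
  expect_equal(unname(cr2["d_c"]), 2.0, tolerance = 0.06)
  expect_equal(unname(cr2["d_r"]), 2.0, tolerance = 0.12)

  # all-zero grid
  g0 <- density_grid(NULL, dom, kappa, counts = integer(dom$density$n))
  expect_equal(unname(core_and_rim(g0)), c(0, 0))
})

test_that("lineage ratio counts active cells and signals the degenerate case", {
  pop <- fixed_pop(c(1, 2, 3, 4), c(1, 2, 3, 4),
                   lineage = c(1, 1, 2, 2))
  expect_equal(lineage_ratio(pop), 1.0)
  pop2 <- fixed_pop(seq_len(6), seq_len(6), lineage = c(1, 2, 2, 2, 2, 2))
  expect_equal(lineage_ratio(pop2), 0.2)
  # the 17d benchmark: recruited 80% of labeled cells means I/R = 0.25
  pop3 <- fixed_pop(seq_len(100), seq_len(100),
                    lineage = rep(c(1, 2), c(20, 80)))
  expect_equal(lineage_ratio(pop3), 0.25)
  expect_error(lineage_ratio(fixed_pop(1, 1, lineage = 1)), "no recruited")
})

test_that("phenotype statistics split measured from potential correctly", {
  par <- quick_params()
  # homogeneous population at saturating PDGF: zero spread, means (1/tau, v)
  pop <- fixed_pop(runif(20, 0, 500), runif(20, 0, 500), tau = 40, v = 20)
  ps <- phenotype_stats(pop, rep(1e9, 20), par)
  expect_equal(ps$measured$p_mean, 1 / 40, tolerance = 1e-6)
  expect_equal(ps$measured$m_mean, 20, tolerance = 1e-6)
  expect_equal(ps$measured$p_sd, 0, tolerance = 1e-9)
  expect_equal(ps$potential$p_mean, 1 / 40)
  expect_equal(ps$potential$m_sd, 0)

  # zero PDGF, recruited-only: measured phenotypes vanish
  pop2 <- fixed_pop(1:10, 1:10, tau = 40, v = 20, lineage = 2)
  ps2 <- phenotype_stats(pop2, rep(0, 10), par)
  expect_equal(ps2$measured$p_mean, 0)
  expect_equal(ps2$measured$m_mean, 0)

  # two-phenotype mixture: means are the weighted average at saturation
  pop3 <- new_population()
  pop_add(pop3, 1:6, 1:6, tau = c(20, 20, 20, 40, 40, 40),
          v = c(10, 10, 10, 30, 30, 30), lineage = 1)
  ps3 <- phenotype_stats(pop3, rep(1e9, 6), par)
  expect_equal(ps3$measured$m_mean, 20, tolerance = 1e-6)
  expect_equal(ps3$potential$p_mean, mean(1 / c(20, 20, 20, 40, 40, 40)))

  # measured stats exclude quiescent cells
  pop4 <- new_population()
  pop_add(pop4, 1:4, 1:4, tau = 40, v = c(10, 10, 50, 50), lineage = 1,
          quiescent = c(FALSE, FALSE, TRUE, TRUE))
  ps4 <- phenotype_stats(pop4, rep(1e9, 4), par)
  expect_equal(ps4$measured$m_mean, 10, tolerance = 1e-6)
  expect_equal(ps4$potential$m_mean, 30)
})

test_that("Ki-67 index matches the uniform-phase expectation 20h / tau", {
  dom <- gray_domain(1)
  par <- quick_params(K_p = 5, beta_p = 1)
  make <- function(tau, n = 2000) {
    pop <- new_population()
    set.seed(7)
    # all in one density node, phases uniform, saturating PDGF
    pop_add(pop, runif(n, 10, 90), runif(n, 10, 90), tau = tau, v = 0,
            lineage = 2, cycle = runif(n))
    pop
  }
  p40 <- make(40)
  k40 <- ki67_index(p40, dom, rep(1e9, 2000), par)
  expect_equal(k40, 50, tolerance = 3 * 100 * sqrt(0.25 / 2000) / 50)
  p100 <- make(100)
  k100 <- ki67_index(p100, dom, rep(1e9, 2000), par)
  expect_equal(k100, 20, tolerance = 3 * 100 * sqrt(0.16 / 2000) / 20)

  # all quiescent: index 0
  pq <- new_population()
  pop_add(pq, 1:5, 1:5, tau = 40, v = 0, lineage = 1, cycle = 0.99,
          quiescent = TRUE)
  expect_equal(ki67_index(pq, dom, rep(1e9, 5), par), 0)
})

test_that("outcome classes use the published diameter bins", {
  expect_equal(as.character(classify_outcome(0.1)), "complete_response")
  expect_equal(as.character(classify_outcome(2.5)), "medium")
  expect_equal(as.character(classify_outcome(3.2)), "large")
  expect_equal(as.character(classify_outcome(c(0.49, 0.5, 2, 3, 3.01))),
               c("complete_response", "small", "small", "medium", "large"))
  expect_error(classify_outcome(-1))
})
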