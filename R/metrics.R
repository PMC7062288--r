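# Imaging-, population-, and phenotype-scale summaries of a simulation state.

#' Build a density grid snapshot
#'
#' Counts active cells per density node and attaches the node carrying
#' capacities; the grid is the pure-data input of the imaging metrics
#' ([tumor_diameter()], [core_and_rim()]).
#'
#' @param pop a [new_population()] (or `NULL` with `counts` given).
#' @param domain a [tissue_domain()].
#' @param kappa gray-matter carrying capacity.
#' @param counts optional precomputed counts per density node.
#' @return object of class `density_grid`: `counts`, `capacity`, node centers
#'   `cx`, `cy` (um), `nx`, `ny`, `spacing`.
#' @export
density_grid <- function(pop = NULL, domain, kappa, counts = NULL) {
  d <- domain$density
  if (is.null(counts)) {
    counts <- if (is.null(pop) || pop$n == 0) integer(d$n) else
      tabulate(density_node_raw(domain, pop$x[seq_len(pop$n)],
                                pop$y[seq_len(pop$n)]), nbins = d$n)
  }
  structure(list(counts = counts, capacity = node_capacity(domain, kappa),
                 cx = d$cx, cy = d$cy, nx = d$nx, ny = d$ny,
                 spacing = d$spacing),
            class = "density_grid")
}

#' Tumor diameter at a density threshold
#'
#' The imaging size proxy: nodes whose cell density reaches `threshold` times
#' their carrying capacity are suprathreshold. About the suprathreshold mass
#' centroid, the maximal suprathreshold radius is found in each of 360 angular
#' bins and the diameter is twice the mean of the per-bin maxima (bins without
#' suprathreshold nodes contribute zero radius). Returns 0 mm if no node is
#' suprathreshold.
#'
#' @param grid a [density_grid()].
#' @param threshold fraction of carrying capacity (default 0.10).
#' @param n_bins number of angular bins.
#' @return diameter in millimeters.
#' @export
tumor_diameter <- function(grid, threshold = 0.10, n_bins = 360L) {
  supra <- grid$capacity > 0 & grid$counts >= threshold * grid$capacity
  if (!any(supra)) return(0)
  w <- grid$counts[supra]
  x <- grid$cx[supra]; y <- grid$cy[supra]
  x0 <- sum(x * w) / sum(w); y0 <- sum(y * w) / sum(w)
  r <- sqrt((x - x0)^2 + (y - y0)^2)
  ang <- atan2(y - y0, x - x0)
  # each node is a square of side `spacing`: it subtends a finite angular
  # interval about the centroid, so sparse outer nodes still fill their bins
  half <- grid$spacing / 2
  delta <- ifelse(r <= half * sqrt(2), pi, asin(pmin(1, half * sqrt(2) / r)))
  rmax <- numeric(n_bins)
  lo <- floor((ang - delta + pi) / (2 * pi) * n_bins)
  hi <- floor((ang + delta + pi) / (2 * pi) * n_bins)
  for (k in order(r)) {
    idx <- (lo[k]:hi[k]) %% n_bins + 1L
    rmax[idx] <- r[k]  # ascending r: later (larger) overwrite
  }
  2 * mean(rmax) / 1000
}

#' Tumor core diameter and rim size
#'
#' The core is the region at `>= 50%` of carrying capacity and the rim extends
#' to `>= 1%`; the rim size is the difference between the average rim diameter
#' and the average core diameter.
#'
#' @param grid a [density_grid()].
#' @return named vector `c(d_c, d_r)` in millimeters.
#' @export
core_and_rim <- function(grid) {
  d_c <- tumor_diameter(grid, threshold = 0.50)
  rim <- tumor_diameter(grid, threshold = 0.01)
  c(d_c = d_c, d_r = max(rim - d_c, 0))
}

#' Infected-to-recruited cell ratio
#'
#' @param pop a [new_population()] of active cells.
#' @return `count(INFECTED) / count(RECRUITED)`.
#' @export
lineage_ratio <- function(pop) {
  i <- seq_len(pop$n)
  n_r <- sum(pop$lineage[i] == LINEAGE["RECRUITED"])
  if (n_r == 0) stop("lineage ratio undefined: no recruited cells")
  sum(pop$lineage[i] == LINEAGE["INFECTED"]) / n_r
}

#' Measured and potential phenotype statistics
#'
#' Measured values are each cell's observed proliferation rate and migration
#' speed at its local PDGF concentration; potential values are the inherited
#' maxima `(1/tau, v)`. Measured statistics are computed over non-quiescent
#' active cells; potential statistics over all active cells. Radial profiles
#' are binned at 100 um about the population centroid.
#'
#' @param pop a [new_population()].
#' @param C_PP local PDGF per cell (ng/mL).
#' @param params a [parameter_set()].
#' @param radial also compute radial profiles?
#' @return list with `measured` and `potential` (each mean/sd of `p` and `m`),
#'   and optionally `radial` (data.frame).
#' @export
phenotype_stats <- function(pop, C_PP, params, radial = FALSE) {
  i <- seq_len(pop$n)
  if (!length(i)) stop("phenotype statistics need at least one cell")
  obs <- observed_phenotype(pop$tau[i], pop$v[i], C_PP, pop$lineage[i], params)
  nq <- !pop$quiescent[i]
  sd0 <- function(z) if (length(z) > 1) stats::sd(z) else 0
  out <- list(
    measured = list(p_mean = mean(obs$p[nq]), p_sd = sd0(obs$p[nq]),
                    m_mean = mean(obs$m[nq]), m_sd = sd0(obs$m[nq])),
    potential = list(p_mean = mean(1 / pop$tau[i]), p_sd = sd0(1 / pop$tau[i]),
                     m_mean = mean(pop$v[i]), m_sd = sd0(pop$v[i]))
  )
  if (any(nq) == FALSE) out$measured <- list(p_mean = NA_real_, p_sd = NA_real_,
                                             m_mean = NA_real_, m_sd = NA_real_)
  if (radial) {
    x0 <- mean(pop$x[i]); y0 <- mean(pop$y[i])
    r <- sqrt((pop$x[i] - x0)^2 + (pop$y[i] - y0)^2)
    bin <- floor(r / 100)
    out$radial <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
      s <- bin == b
      data.frame(r_mm = (b + 0.5) * 0.1,
                 p_measured = mean(obs$p[s & nq]), m_measured = mean(obs$m[s & nq]),
                 p_potential = mean(1 / pop$tau[i][s]), m_potential = mean(pop$v[i][s]),
                 n = sum(s))
    }))
  }
  out
}

#' Ki-67 proliferation index
#'
#' A non-quiescent cell is Ki-67 positive when its remaining cycle time
#' `(1 - progress) * tau / gamma_p` is at most 20 hours (Ki-67 is expressed
#' only late in the cycle). The index is the percentage of positive cells
#' among the cells of the density node with the highest positive count (the
#' "area of highest activity"); quiescent cells are counted in the
#' denominator.
#'
#' @param pop a [new_population()].
#' @param domain a [tissue_domain()].
#' @param C_PP local PDGF per cell (ng/mL).
#' @param params a [parameter_set()].
#' @param window_h hours of cycle counted as Ki-67 positive.
#' @return percentage in `[0, 100]`.
#' @export
ki67_index <- function(pop, domain, C_PP, params, window_h = 20) {
  i <- seq_len(pop$n)
  if (!length(i)) stop("Ki-67 index needs at least one cell")
  gp <- gamma_response(C_PP, pop$lineage[i], params$K_p, params$beta_p, params$p_a)
  remaining <- ifelse(gp > 0, (1 - pop$cycle[i]) * pop$tau[i] / gp, Inf)
  positive <- !pop$quiescent[i] & remaining <= window_h
  if (!any(positive)) return(0)
  node <- density_node_raw(domain, pop$x[i], pop$y[i])
  pos_by_node <- tabulate(node[positive], nbins = domain$density$n)
  top <- which.max(pos_by_node)
  in_node <- node == top
  100 * sum(positive & in_node) / sum(in_node)
}

#' Classify end-of-treatment outcome from final diameter
#'
#' Bins: complete response `< 0.5` mm, small `0.5-2` mm, medium `2-3` mm,
#' large `> 3` mm.
#'
#' @param diameter_mm final tumor diameter(s), mm.
#' @return factor with levels `complete_response`, `small`, `medium`, `large`.
#' @export
classify_outcome <- function(diameter_mm) {
  stopifnot(all(diameter_mm >= 0))
  lv <- c("complete_response", "small", "medium", "large")
  cls <- ifelse(diameter_mm < 0.5, lv[1],
         ifelse(diameter_mm <= 2, lv[2],
         ifelse(diameter_mm <= 3, lv[3], lv[4])))
  factor(cls, levels = lv)
}
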