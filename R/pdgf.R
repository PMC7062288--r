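# PDGF concentration field on the hexagonal lattice: secretion and consumption
# by cells, then decay and diffusion each engine step.

#' Create an empty PDGF field on a domain's hex lattice
#'
#' The field stores one concentration (ng/mL) per hex node together with its
#' rate constants: diffusion coefficient `D_p` (cm^2/day), first-order decay
#' rate `r_d` (1/day), per-infected-cell secretion rate `r_s` (ng/mL/cell/day)
#' and per-cell consumption expressed as a fraction `r_c` of `r_s`.
#'
#' @param domain a [tissue_domain()].
#' @param D_p,r_d,r_s,r_c rate constants (see above).
#' @return object of class `pdgf_field`.
#' @export
pdgf_field <- function(domain, D_p = 5e-4, r_d = 0.1, r_s = 200, r_c = 0.1) {
  structure(list(domain = domain, conc = numeric(domain$hex$n),
                 D_p = D_p, r_d = r_d, r_s = r_s, r_c = r_c,
                 diffusion_op = NULL),
            class = "pdgf_field")
}

#' Deposit the initial PDGF bolus
#'
#' Sets every hex node within `radius` of `site` to concentration `p0`,
#' representing the injury response at the injection site. Values outside the
#' admissible initial range (100-600 ng/mL) trigger a warning.
#'
#' @param field a [pdgf_field()].
#' @param p0 bolus concentration (ng/mL).
#' @param site `c(x, y)` in micrometers; must lie in tissue.
#' @param radius bolus radius (um); `0` sets only the nearest node.
#' @return the modified field.
#' @export
deposit_initial_bolus <- function(field, p0, site, radius = 300) {
  dom <- field$domain
  if (pixel_class(dom, site[1], site[2]) == TISSUE["EMPTY"])
    stop("bolus site lies in EMPTY space")
  if (p0 < 100 || p0 > 600)
    warning("initial PDGF outside admissible range 100-600 ng/mL")
  h <- dom$hex
  if (radius <= 0) {
    field$conc[nearest_hex_node(dom, site[1], site[2])] <- p0
  } else {
    inside <- (h$x - site[1])^2 + (h$y - site[2])^2 <= radius^2
    field$conc[inside] <- p0
  }
  field
}

#' Secretion of PDGF by infected cells
#'
#' Each infected cell adds `r_s * dt` (converted from per-day to the step
#' length) to its nearest hex node.
#'
#' @param field a [pdgf_field()].
#' @param x,y positions (um) of the secreting (infected) cells.
#' @param dt step length in hours.
#' @return the modified field.
#' @export
secrete <- function(field, x, y, dt) {
  stopifnot(dt > 0)
  if (!length(x)) return(field)
  ids <- nearest_hex_node(field$domain, x, y)
  field$conc <- field_secrete(field$conc, ids, field$r_s, dt)
  field
}

field_secrete <- function(conc, hex_ids, r_s, dt) {
  cnt <- tabulate(hex_ids, nbins = length(conc))
  nz <- which(cnt > 0L)
  conc[nz] <- conc[nz] + cnt[nz] * (r_s * dt / 24)
  conc
}

#' Consumption of PDGF by all active cells
#'
#' Each cell removes `r_c * r_s * dt` from its nearest hex node, clipped so a
#' node is never driven below zero: when less PDGF is available than demanded,
#' all PDGF at the node is consumed.
#'
#' @inheritParams secrete
#' @param x,y positions (um) of all active (consuming) cells.
#' @return the modified field.
#' @export
consume <- function(field, x, y, dt) {
  stopifnot(dt > 0)
  if (!length(x)) return(field)
  ids <- nearest_hex_node(field$domain, x, y)
  field$conc <- field_consume(field$conc, ids, field$r_c * field$r_s, dt)
  field
}

field_consume <- function(conc, hex_ids, r_c_abs, dt) {
  cnt <- tabulate(hex_ids, nbins = length(conc))
  nz <- which(cnt > 0L)
  conc[nz] <- pmax(conc[nz] - cnt[nz] * (r_c_abs * dt / 24), 0)
  conc
}

#' First-order decay of the whole field
#'
#' Exponential form `C <- C * exp(-r_d * dt)` (step-size robust; the forward
#' Euler difference is O(dt^2)).
#'
#' @inheritParams secrete
#' @return the modified field.
#' @export
decay <- function(field, dt) {
  stopifnot(dt > 0)
  field$conc <- field$conc * exp(-field$r_d * dt / 24)
  field
}

#' Explicit diffusion on the hexagonal lattice
#'
#' Uses the standard second-order hex stencil
#' `laplacian(C)_i ~ (2 / (3 h^2)) * sum_j (C_j - C_i)` over the (up to 6)
#' neighbors of node `i`, with missing neighbors treated as no-flux so total
#' mass is conserved exactly in closed tissue. The update is sub-stepped to
#' satisfy the explicit stability bound `dt_sub <= 0.9 * (3 h^2) / (12 D_p)`.
#'
#' @inheritParams secrete
#' @return the modified field.
#' @export
diffuse <- function(field, dt) {
  stopifnot(dt > 0)
  op <- build_diffusion_operator(field$domain, field$D_p, dt)
  field$conc <- field_diffuse(field$conc, op)
  field
}

# Precompute the sub-step update matrix M = I + mu (A - diag(deg)); column sums
# of M are exactly 1 so each application conserves total mass.
build_diffusion_operator <- function(domain, D_p, dt) {
  h <- domain$hex$hx                    # center spacing, um
  D_um2_h <- D_p * 1e8 / 24             # cm^2/day -> um^2/h
  if (D_um2_h <= 0) return(list(M = NULL, nsub = 0L))
  dt_max <- 0.9 * 3 * h^2 / (12 * D_um2_h)
  nsub <- max(1L, as.integer(ceiling(dt / dt_max)))
  dt_sub <- dt / nsub
  mu <- 2 * D_um2_h * dt_sub / (3 * h^2)
  A <- domain$hex$adjacency
  M <- Matrix::Diagonal(domain$hex$n, 1 - mu * domain$hex$degree) + mu * A
  list(M = methods::as(M, "CsparseMatrix"), nsub = nsub)
}

field_diffuse <- function(conc, op) {
  if (is.null(op$M)) return(conc)
  for (i in seq_len(op$nsub)) conc <- as.numeric(op$M %*% conc)
  conc
}

#' Write a PDGF field snapshot as CSV
#'
#' Columns: node id, x, y (um), concentration (ng/mL).
#'
#' @param field a [pdgf_field()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  h <- field$domain$hex
  utils::write.csv(data.frame(node = seq_len(h$n), x_um = h$x, y_um = h$y,
                              conc = field$conc),
                   path, row.names = FALSE)
  invisible(path)
}

#' @export
print.pdgf_field <- function(x, ...) {
  cat(sprintf("<pdgf_field> %d hex nodes; total %.3g, max %.3g ng/mL\n",
              length(x$conc), sum(x$conc), max(x$conc)))
  cat(sprintf("  D_p %g cm2/day | r_d %g /day | r_s %g | r_c %g r_s\n",
              x$D_p, x$r_d, x$r_s, x$r_c))
  invisible(x)
}
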