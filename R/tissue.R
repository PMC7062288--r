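# Tissue domain: gray/white/non-tissue raster plus the two overlay lattices
# (coarse 100-um square density mesh, fine 25-um hexagonal PDGF mesh).

#' Tissue class codes
#'
#' Integer codes used throughout for the per-pixel tissue label:
#' `0` = EMPTY (outside brain, ventricles), `1` = GRAY matter, `2` = WHITE matter.
#' The raster file encoding is 8-bit grayscale: 0 = EMPTY, 128 = GRAY, 255 = WHITE.
#'
#' @format Named integer vector.
#' @export
TISSUE <- c(EMPTY = 0L, GRAY = 1L, WHITE = 2L)

# lattice geometry constants (um)
CELL_RADIUS_UM <- 12.5
HEX_SPACING_UM <- 25            # center-to-center, one cell diameter
DENSITY_SPACING_UM <- 100

#' Construct a TissueDomain from a tissue-class matrix
#'
#' Builds the full domain object: per-pixel tissue classes, the coarse square
#' density mesh (100 um spacing) used for carrying-capacity checks, and the
#' fine "pointy-top" hexagonal lattice (25 um center spacing, node radius equal
#' to the 12.5 um cell radius) used for PDGF dynamics. Hex and density nodes
#' whose location falls outside tissue are removed from the lattices.
#'
#' Coordinates are continuous 2D positions in micrometers with the origin at
#' the raster top-left, x rightwards, y downwards (image convention).
#'
#' @param class_mat integer matrix (rows = y, cols = x) of tissue codes
#'   (see [TISSUE]).
#' @param px_size pixel edge length in micrometers.
#' @return object of class `tissue_domain`.
#' @export
tissue_domain <- function(class_mat, px_size) {
  stopifnot(is.matrix(class_mat), px_size > 0)
  storage.mode(class_mat) <- "integer"
  if (!all(class_mat %in% TISSUE))
    stop("unknown tissue class value; admissible codes: 0 (EMPTY), 1 (GRAY), 2 (WHITE)")
  height_px <- nrow(class_mat); width_px <- ncol(class_mat)
  width_um <- width_px * px_size; height_um <- height_px * px_size

  dom <- list(
    class_mat = class_mat, px_size = px_size,
    width_px = width_px, height_px = height_px,
    width_um = width_um, height_um = height_um,
    density_spacing = DENSITY_SPACING_UM, hex_spacing = HEX_SPACING_UM
  )

  # ---- density mesh (square, 100 um) ----
  s <- DENSITY_SPACING_UM
  nx_d <- max(1L, as.integer(ceiling(width_um / s)))
  ny_d <- max(1L, as.integer(ceiling(height_um / s)))
  # node class = majority tissue class among its non-EMPTY pixels; EMPTY if none
  px_ix <- pmax(0L, as.integer(ceiling(((seq_len(width_px) - 0.5) * px_size) / s)) - 1L)
  px_iy <- pmax(0L, as.integer(ceiling(((seq_len(height_px) - 0.5) * px_size) / s)) - 1L)
  node_of_px <- outer(px_iy, px_ix, function(iy, ix) iy * nx_d + ix + 1L)
  n_d <- nx_d * ny_d
  cnt_gray  <- tabulate(node_of_px[class_mat == TISSUE["GRAY"]],  nbins = n_d)
  cnt_white <- tabulate(node_of_px[class_mat == TISSUE["WHITE"]], nbins = n_d)
  d_class <- integer(n_d)
  d_class[cnt_gray > 0 | cnt_white > 0] <- ifelse(
    cnt_white[cnt_gray > 0 | cnt_white > 0] > cnt_gray[cnt_gray > 0 | cnt_white > 0],
    TISSUE["WHITE"], TISSUE["GRAY"])
  dom$density <- list(
    nx = nx_d, ny = ny_d, spacing = s, n = n_d,
    class = d_class,
    cx = ((seq_len(n_d) - 1L) %% nx_d + 0.5) * s,
    cy = ((seq_len(n_d) - 1L) %/% nx_d + 0.5) * s
  )

  # ---- hexagonal lattice (pointy-top axial, offset rows) ----
  hx <- HEX_SPACING_UM
  hy <- HEX_SPACING_UM * sqrt(3) / 2
  n_rows <- as.integer(floor(height_um / hy)) + 1L
  n_cols <- as.integer(floor(width_um / hx)) + 1L
  rows <- rep(0:(n_rows - 1L), each = n_cols)
  cols <- rep(0:(n_cols - 1L), times = n_rows)
  xs <- cols * hx + (rows %% 2L) * (hx / 2)
  ys <- rows * hy
  keep <- xs < width_um & ys < height_um
  cls <- integer(length(xs))
  cls[keep] <- pixel_class(dom, xs[keep], ys[keep])
  keep <- keep & cls != TISSUE["EMPTY"]
  id_mat <- matrix(NA_integer_, nrow = n_rows, ncol = n_cols)
  id_mat[cbind(rows[keep] + 1L, cols[keep] + 1L)] <- seq_len(sum(keep))
  hex <- list(
    n = sum(keep), hx = hx, hy = hy, n_rows = n_rows, n_cols = n_cols,
    x = xs[keep], y = ys[keep], row = rows[keep], col = cols[keep],
    class = cls[keep], id_mat = id_mat
  )
  hex$adjacency <- hex_adjacency(hex)
  hex$degree <- Matrix::colSums(hex$adjacency)
  dom$hex <- hex

  class(dom) <- "tissue_domain"
  dom
}

# Symmetric sparse adjacency over the 6 hex neighbor directions.
hex_adjacency <- function(hex) {
  im <- hex$id_mat
  nr <- nrow(im); nc <- ncol(im)
  from <- integer(0); to <- integer(0)
  pair_up <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    from <<- c(from, a[ok]); to <<- c(to, b[ok])
  }
  # same row, right neighbor
  pair_up(im[, -nc, drop = FALSE], im[, -1, drop = FALSE])
  # row below: col offsets depend on row parity (even raster row r: below cols c-1,c;
  # odd row: cols c,c+1), rows of id_mat are 1-based so row i is raster row i-1
  even <- which(seq_len(nr - 1L) %% 2L == 1L)  # raster-even rows with a row below
  odd  <- which(seq_len(nr - 1L) %% 2L == 0L)
  if (length(even)) {
    pair_up(im[even, -1, drop = FALSE], im[even + 1L, -nc, drop = FALSE])  # down-left
    pair_up(im[even, , drop = FALSE],  im[even + 1L, , drop = FALSE])      # down-right
  }
  if (length(odd)) {
    pair_up(im[odd, , drop = FALSE],   im[odd + 1L, , drop = FALSE])       # down-left
    pair_up(im[odd, -nc, drop = FALSE], im[odd + 1L, -1, drop = FALSE])    # down-right
  }
  Matrix::sparseMatrix(i = c(from, to), j = c(to, from), x = 1,
                       dims = c(hex$n, hex$n))
}

#' Tissue class at continuous positions
#'
#' @param domain a [tissue_domain()].
#' @param x,y positions in micrometers. Positions outside the raster return EMPTY.
#' @return integer vector of tissue codes.
#' @export
pixel_class <- function(domain, x, y) {
  px <- domain$px_size
  cx <- floor(x / px) + 1
  cy <- floor(y / px) + 1
  out <- integer(length(x))
  ok <- cx >= 1 & cx <= domain$width_px & cy >= 1 & cy <= domain$height_px &
    x >= 0 & y >= 0
  out[ok] <- domain$class_mat[cbind(cy[ok], cx[ok])]
  out
}

# 0-based grid index with the tie rule "equidistant -> lower id":
# ceiling(x/s) - 1 maps exact multiples of s down to the lower cell.
grid_index0 <- function(x, s, nmax) {
  pmin(pmax(0, ceiling(x / s) - 1), nmax - 1L)
}

#' Nearest density-mesh node
#'
#' Maps positions to the coarse 100-um density mesh. Ties (points equidistant
#' between two node centers) resolve to the lower node id.
#'
#' @inheritParams pixel_class
#' @return integer node ids (1-based, row-major).
#' @export
nearest_density_node <- function(domain, x, y) {
  if (any(pixel_class(domain, x, y) == TISSUE["EMPTY"]))
    stop("illegal cell placement: position in EMPTY space or outside the domain")
  d <- domain$density
  ix <- grid_index0(x, d$spacing, d$nx)
  iy <- grid_index0(y, d$spacing, d$ny)
  as.integer(iy * d$nx + ix + 1L)
}

# internal unchecked version used in hot loops
density_node_raw <- function(domain, x, y) {
  d <- domain$density
  ix <- grid_index0(x, d$spacing, d$nx)
  iy <- grid_index0(y, d$spacing, d$ny)
  as.integer(iy * d$nx + ix + 1L)
}

#' Nearest hexagonal-lattice node
#'
#' Maps positions to the fine hex (PDGF) lattice; ties resolve to the lower
#' node id. Positions whose nearby hex nodes were all removed (deep inside
#' EMPTY space) raise an error.
#'
#' @inheritParams pixel_class
#' @return integer hex node ids.
#' @export
nearest_hex_node <- function(domain, x, y) {
  if (any(pixel_class(domain, x, y) == TISSUE["EMPTY"]))
    stop("illegal cell placement: position in EMPTY space or outside the domain")
  id <- hex_node_precise(domain, x, y)
  if (anyNA(id)) stop("position has no hex node (isolated tissue sliver)")
  id
}

# exact variant examining both bracketing columns so equidistant points
# resolve to the lower node id
hex_node_precise <- function(domain, x, y) {
  h <- domain$hex
  n <- length(x)
  nr <- h$n_rows; nc <- h$n_cols
  best_id <- rep(NA_integer_, n)
  best_d2 <- rep(Inf, n)
  r0 <- floor(y / h$hy)
  for (dr in 0:1) for (dc in 0:1) {
    r <- r0 + dr
    offs <- (r %% 2) * (h$hx / 2)
    cc <- floor((x - offs) / h$hx) + dc
    ok <- r >= 0 & r < nr & cc >= 0 & cc < nc
    id <- rep(NA_integer_, n)
    id[ok] <- h$id_mat[cc[ok] * nr + r[ok] + 1]
    has <- which(!is.na(id))
    if (!length(has)) next
    ih <- id[has]
    d2 <- (x[has] - h$x[ih])^2 + (y[has] - h$y[ih])^2
    upd <- d2 < best_d2[has] - 1e-9 |
      (abs(d2 - best_d2[has]) <= 1e-9 &
         (is.na(best_id[has]) | ih < best_id[has]))
    bu <- has[upd]
    best_id[bu] <- id[bu]
    best_d2[bu] <- d2[upd]
  }
  out <- best_id
  if (anyNA(out)) out[is.na(out)] <- hex_node_raw(domain, x[is.na(out)], y[is.na(out)])
  out
}

hex_node_raw <- function(domain, x, y) {
  h <- domain$hex
  n <- length(x)
  nr <- h$n_rows; nc <- h$n_cols
  best_id <- rep(NA_integer_, n)
  best_d2 <- rep(Inf, n)
  # the nearest node lies in one of the two bracketing rows (row spacing
  # ~21.65 um exceeds the in-row half spacing 12.5 um), at the rounded column
  r0 <- floor(y / h$hy)
  for (dr in 0:1) {
    r <- r0 + dr
    offs <- (r %% 2) * (h$hx / 2)
    cc <- round((x - offs) / h$hx)
    ok <- r >= 0 & r < nr & cc >= 0 & cc < nc
    id <- rep(NA_integer_, n)
    id[ok] <- h$id_mat[cc[ok] * nr + r[ok] + 1]
    has <- which(!is.na(id))
    if (!length(has)) next
    ih <- id[has]
    d2 <- (x[has] - h$x[ih])^2 + (y[has] - h$y[ih])^2
    upd <- d2 < best_d2[has] - 1e-9 |
      (abs(d2 - best_d2[has]) <= 1e-9 &
         (is.na(best_id[has]) | ih < best_id[has]))
    bu <- has[upd]
    best_id[bu] <- id[bu]
    best_d2[bu] <- d2[upd]
  }
  if (anyNA(best_id)) {
    # positions whose bracketing nodes were removed (EMPTY-adjacent): widen
    # the search to a 5x5 candidate block
    miss <- which(is.na(best_id))
    for (dr in -2:2) for (dc in -2:2) {
      if (!length(miss)) break
      r <- r0[miss] + dr
      cc <- round((x[miss] - (r %% 2) * (h$hx / 2)) / h$hx) + dc
      ok <- r >= 0 & r < nr & cc >= 0 & cc < nc
      id <- rep(NA_integer_, length(miss))
      id[ok] <- h$id_mat[cc[ok] * nr + r[ok] + 1]
      has <- which(!is.na(id))
      if (!length(has)) next
      mi <- miss[has]; ih <- id[has]
      d2 <- (x[mi] - h$x[ih])^2 + (y[mi] - h$y[ih])^2
      upd <- d2 < best_d2[mi]
      best_id[mi[upd]] <- ih[upd]
      best_d2[mi[upd]] <- d2[upd]
    }
  }
  best_id
}

#' Generate a synthetic brain tissue map
#'
#' Produces a reproducible gray-matter domain with an optional white-matter
#' band (a synthetic corpus callosum) and optional EMPTY holes standing in for
#' ventricles. The default rectangular outline keeps area arithmetic exact;
#' `shape = "ellipse"` clips the tissue to an inscribed ellipse for a more
#' brain-like outline.
#'
#' @param width_mm,height_mm domain size in millimeters.
#' @param tract `NULL` or a list with `y_mm` (band center), `thickness_mm`,
#'   and optionally `wiggle_mm` (sinusoidal amplitude of the band's centerline,
#'   randomized phase) for a gently curved tract.
#' @param ventricles `NULL` or a list of `list(x_mm, y_mm, r_mm)` discs set EMPTY.
#' @param px_size pixel size in micrometers (default 17.4, i.e. 14.5 mm / 833 px).
#' @param shape `"rect"` or `"ellipse"`.
#' @param seed integer seed controlling the randomized tract phase.
#' @return a [tissue_domain()].
#' @export
make_synthetic_brain <- function(width_mm, height_mm, tract = NULL,
                                 ventricles = NULL, px_size = 17.4,
                                 shape = c("rect", "ellipse"), seed = 1L) {
  if (width_mm <= 0 || height_mm <= 0) stop("non-positive domain dimensions")
  shape <- match.arg(shape)
  set.seed(as.integer(seed))
  w_px <- max(2L, as.integer(round(width_mm * 1000 / px_size)))
  h_px <- max(2L, as.integer(round(height_mm * 1000 / px_size)))
  mat <- matrix(TISSUE["GRAY"], nrow = h_px, ncol = w_px)

  xc <- (seq_len(w_px) - 0.5) * px_size / 1000  # mm
  yc <- (seq_len(h_px) - 0.5) * px_size / 1000

  if (!is.null(tract)) {
    stopifnot(!is.null(tract$y_mm), !is.null(tract$thickness_mm))
    if (tract$y_mm < 0 || tract$y_mm > height_mm)
      stop("tract geometry does not fit inside the domain")
    wig <- tract$wiggle_mm %||% 0
    phase <- stats::runif(1, 0, 2 * pi)
    center <- tract$y_mm + wig * sin(2 * pi * xc / width_mm + phase)
    half <- tract$thickness_mm / 2
    for (j in seq_len(w_px)) {
      in_band <- abs(yc - center[j]) <= half
      mat[in_band, j] <- TISSUE["WHITE"]
    }
  }
  if (shape == "ellipse") {
    a <- width_mm / 2; b <- height_mm / 2
    outside <- outer(yc, xc, function(y, x) ((x - a) / a)^2 + ((y - b) / b)^2 > 1)
    mat[outside] <- TISSUE["EMPTY"]
  }
  if (!is.null(ventricles)) {
    for (v in ventricles) {
      if (v$x_mm < 0 || v$x_mm > width_mm || v$y_mm < 0 || v$y_mm > height_mm)
        stop("ventricle geometry does not fit inside the domain")
      hole <- outer(yc, xc, function(y, x) (x - v$x_mm)^2 + (y - v$y_mm)^2 <= v$r_mm^2)
      mat[hole] <- TISSUE["EMPTY"]
    }
  }
  tissue_domain(mat, px_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a tissue raster (PGM or PNG)
#'
#' Accepts 8-bit grayscale rasters with the encoding 0 = EMPTY, 128 = GRAY,
#' 255 = WHITE (a tolerance of +-20 gray levels is allowed around each label).
#'
#' @param path file path (`.pgm` ASCII P2 / binary P5, or `.png`).
#' @param px_size pixel size in micrometers.
#' @return a [tissue_domain()].
#' @export
load_tissue_raster <- function(path, px_size = 17.4) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  if (px_size <= 0) stop("px_size must be > 0")
  ext <- tolower(tools::file_ext(path))
  gray <- switch(ext,
    png = {
      img <- png::readPNG(path)
      if (length(dim(img)) > 2) img <- img[, , 1]
      round(img * 255)
    },
    pgm = read_pgm(path),
    stop("unsupported raster format: .", ext, " (use .pgm or .png)")
  )
  cls <- matrix(NA_integer_, nrow(gray), ncol(gray))
  cls[abs(gray - 0) <= 20]   <- TISSUE["EMPTY"]
  cls[abs(gray - 128) <= 20] <- TISSUE["GRAY"]
  cls[abs(gray - 255) <= 20] <- TISSUE["WHITE"]
  if (anyNA(cls)) {
    bad <- sort(unique(gray[is.na(cls)]))
    stop("unknown label value(s) ", paste(utils::head(bad, 5), collapse = ", "),
         "; admissible encoding: 0 = EMPTY, 128 = GRAY, 255 = WHITE (+-20)")
  }
  if (length(unique(as.vector(cls))) < 2)
    warning("raster has a single tissue label")
  tissue_domain(cls, px_size)
}

#' Write a tissue raster
#'
#' Inverse of [load_tissue_raster()]: writes the domain's tissue classes with
#' the 0/128/255 encoding. PGM output is ASCII (P2).
#'
#' @param domain a [tissue_domain()].
#' @param path output path (`.pgm` or `.png`).
#' @return `path`, invisibly.
#' @export
write_tissue_raster <- function(domain, path) {
  gray <- matrix(0L, domain$height_px, domain$width_px)
  gray[domain$class_mat == TISSUE["GRAY"]] <- 128L
  gray[domain$class_mat == TISSUE["WHITE"]] <- 255L
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(gray / 255, path)
  } else if (ext == "pgm") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(gray), nrow(gray)), "255"), con)
    write(t(gray), con, ncolumns = ncol(gray))
  } else stop("unsupported raster format: .", ext)
  invisible(path)
}

# minimal PGM reader (P2 ASCII / P5 binary); no installed package reads PGM
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  toks <- character(0)
  # read header tokens, skipping comments
  while (length(toks) < 4) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0) stop("truncated PGM header")
    if (ch == "#") { repeat { c2 <- readChar(con, 1L, useBytes = TRUE)
      if (length(c2) == 0 || c2 == "\n") break } ; next }
    if (grepl("\\s", ch)) next
    tok <- ch
    repeat {
      c2 <- readChar(con, 1L, useBytes = TRUE)
      if (length(c2) == 0 || grepl("\\s", c2)) break
      tok <- paste0(tok, c2)
    }
    toks <- c(toks, tok)
  }
  magic <- toks[1]
  w <- as.integer(toks[2]); h <- as.integer(toks[3]); maxv <- as.integer(toks[4])
  if (is.na(w) || is.na(h) || maxv > 255) stop("unsupported PGM header")
  n <- w * h
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n))
  } else if (magic == "P2") {
    rest <- readChar(con, file.info(path)$size, useBytes = TRUE)
    as.integer(strsplit(trimws(rest), "\\s+")[[1]])[seq_len(n)]
  } else stop("not a PGM file (magic ", magic, ")")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' @export
print.tissue_domain <- function(x, ...) {
  n_g <- sum(x$class_mat == TISSUE["GRAY"])
  n_w <- sum(x$class_mat == TISSUE["WHITE"])
  cat(sprintf("<tissue_domain> %d x %d px (%.2f x %.2f mm), px %.2f um\n",
              x$width_px, x$height_px, x$width_um / 1000, x$height_um / 1000,
              x$px_size))
  cat(sprintf("  gray %d px, white %d px, empty %d px\n", n_g, n_w,
              x$width_px * x$height_px - n_g - n_w))
  cat(sprintf("  density mesh %d x %d (100 um); hex lattice %d nodes (25 um)\n",
              x$density$nx, x$density$ny, x$hex$n))
  invisible(x)
}
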