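# Hexagonal lattice geometry and the idealized vessel cross-section.
#
# Sites live on an odd-row-offset hexagonal grid with unit pitch (1 site =
# 2 um physically).  All geometry (distances, angles, rays) is done on the
# real-space site centres, so adjacent sites are at distance exactly 1.

# occupancy codes
.LUMEN <- 0L
.SMC   <- 1L
.ECM   <- 2L
.IEL   <- 3L
.MP    <- 4L
.EXT   <- 5L

# layer codes
.LY_LUMEN <- 0L
.LY_INT   <- 1L
.LY_IEL   <- 2L
.LY_MED   <- 3L
.LY_EXT   <- 4L

.OCC_LEVELS   <- c("lumen", "SMC", "ECM", "IEL", "MP", "exterior")
.LAYER_LEVELS <- c("lumen", "intima", "IEL", "media", "exterior")

# micrometres per lattice site
.SITE_UM <- 2

#' Hexagonal lattice specification
#'
#' Describes the grid the vessel cross-section is built on: an odd-row-offset
#' hexagonal lattice with a physical pitch of 2 um per site (one cell per
#' site).  The default 141 x 141 grid comfortably contains a vessel with a
#' 40-site lumen radius and a 16-site wall.
#'
#' @param n_rows,n_cols Grid dimensions in sites.
#' @param site_pitch_um Physical pitch, micrometres per site.
#' @return A `lattice_spec` object carrying the grid dimensions together with
#'   precomputed site coordinates, the 6-neighbourhood table and distances
#'   from the grid centre.
#' @export
lattice_spec <- function(n_rows = 141L, n_cols = 141L, site_pitch_um = 2) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 5L, n_cols >= 5L, site_pitch_um > 0)
  geo <- hex_geometry(n_rows, n_cols)
  structure(
    list(n_rows = n_rows, n_cols = n_cols, site_pitch_um = site_pitch_um,
         geo = geo),
    class = "lattice_spec"
  )
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("<lattice_spec> %d x %d hexagonal grid, %g um/site\n",
              x$n_rows, x$n_cols, x$site_pitch_um))
  invisible(x)
}

# Build the static geometry of an n_rows x n_cols odd-row-offset hex grid.
# Linear site index is row-major in columns: idx = row + (col - 1) * n_rows.
hex_geometry <- function(nr, nc) {
  row <- rep.int(seq_len(nr), nc)
  col <- rep(seq_len(nc), each = nr)
  x <- col + 0.5 * (row %% 2)     # odd rows shifted right by half a pitch
  y <- row * (sqrt(3) / 2)
  n <- nr * nc

  centre_row <- (nr + 1L) %/% 2L
  centre_col <- (nc + 1L) %/% 2L
  centre <- centre_row + (centre_col - 1L) * nr
  dc <- sqrt((x - x[centre])^2 + (y - y[centre])^2)

  # 6-neighbourhood as an n x 6 matrix of linear indices, 0L when off-grid.
  # Column offsets of the two diagonal pairs depend on row parity.
  odd <- row %% 2L == 1L
  nb <- matrix(0L, n, 6L)
  add_nb <- function(k, dr, dcol) {
    r2 <- row + dr
    c2 <- col + dcol
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    v <- integer(n)
    v[ok] <- r2[ok] + (c2[ok] - 1L) * nr
    nb[, k] <<- v
  }
  add_nb(1L, 0L, -1L)                       # W
  add_nb(2L, 0L, +1L)                       # E
  add_nb(3L, -1L, ifelse(odd, 0L, -1L))     # NW
  add_nb(4L, -1L, ifelse(odd, 1L, 0L))      # NE
  add_nb(5L, +1L, ifelse(odd, 0L, -1L))     # SW
  add_nb(6L, +1L, ifelse(odd, 1L, 0L))      # SE

  list(nr = nr, nc = nc, n = n, row = row, col = col, x = x, y = y,
       centre = centre, dc = dc, nb = nb,
       angle = atan2(y - y[centre], x - x[centre]))
}

# resolve user-facing site coordinates (row, col) to linear indices
site_index <- function(geo, site) {
  if (is.matrix(site)) {
    r <- site[, 1L]; c <- site[, 2L]
  } else if (length(site) == 2L && is.numeric(site)) {
    r <- site[1L]; c <- site[2L]
  } else {
    r <- NULL
  }
  if (!is.null(r)) {
    if (any(r < 1 | r > geo$nr | c < 1 | c > geo$nc))
      stop("site coordinates fall outside the lattice", call. = FALSE)
    return(as.integer(r) + (as.integer(c) - 1L) * geo$nr)
  }
  idx <- as.integer(site)
  if (any(idx < 1L | idx > geo$n))
    stop("site index falls outside the lattice", call. = FALSE)
  idx
}

#' Euclidean distance between hexagonal lattice sites
#'
#' Distance between site centres in site units (adjacent neighbours are at
#' distance exactly 1; multiply by the 2 um pitch for physical distance).
#'
#' @param v A [vessel_section] (or a [lattice_spec]).
#' @param a,b Sites, given either as `(row, col)` pairs (length-2 vectors or
#'   two-column matrices) or as linear site indices.
#' @return Numeric vector of distances in sites.
#' @export
site_distance <- function(v, a, b) {
  geo <- section_geo(v)
  ia <- site_index(geo, a)
  ib <- site_index(geo, b)
  sqrt((geo$x[ia] - geo$x[ib])^2 + (geo$y[ia] - geo$y[ib])^2)
}

section_geo <- function(v) {
  if (inherits(v, "vessel_section")) v$geo
  else if (inherits(v, "lattice_spec")) v$geo
  else stop("expected a vessel_section or lattice_spec", call. = FALSE)
}

#' Build the idealized coronary cross-section
#'
#' Lays out concentric lumen, intima, internal elastic lamina (IEL) and media
#' on the hexagonal grid and populates the intima and media with smooth muscle
#' cell (SMC) and extracellular matrix (ECM) agents.  The realized SMC count
#' in each layer equals `round(smc_fraction * layer size)` with random
#' placement, and every agent receives a random initial cell-cycle clock so
#' the population is desynchronized.
#'
#' @param spec A [lattice_spec].
#' @param lumen_radius_sites Lumen radius in sites (default 40, i.e. 80 um).
#' @param wall_thickness_sites Total wall thickness in sites (default 16,
#'   i.e. 32 um).
#' @param smc_fraction Fraction of wall agents that are SMC (default 0.6).
#' @param layer_split Named integer vector `c(intima=, iel=, media=)` giving
#'   how the wall thickness divides into layers; must sum to
#'   `wall_thickness_sites`.
#' @param rng_seed Optional seed; when supplied the construction is
#'   reproducible.
#' @return A `vessel_section` object.
#' @export
build_cross_section <- function(spec = lattice_spec(),
                                lumen_radius_sites = 40,
                                wall_thickness_sites = 16,
                                smc_fraction = 0.6,
                                layer_split = c(intima = 5L, iel = 1L,
                                                media = 10L),
                                rng_seed = NULL) {
  stopifnot(inherits(spec, "lattice_spec"),
            smc_fraction >= 0, smc_fraction <= 1,
            lumen_radius_sites > 0, wall_thickness_sites >= 3)
  if (sum(layer_split) != wall_thickness_sites)
    stop("layer_split must sum to wall_thickness_sites", call. = FALSE)
  if (layer_split[["iel"]] < 1L)
    stop("the IEL must be at least one site thick", call. = FALSE)
  geo <- spec$geo
  # clearance from centre to the nearest grid edge, in real units
  edge <- min(geo$x[geo$centre] - min(geo$x), max(geo$x) - geo$x[geo$centre],
              geo$y[geo$centre] - min(geo$y), max(geo$y) - geo$y[geo$centre])
  if (lumen_radius_sites + wall_thickness_sites >= edge)
    stop("vessel geometry exceeds the lattice bounds", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)

  r_int <- lumen_radius_sites + layer_split[["intima"]]
  r_iel <- r_int + layer_split[["iel"]]
  r_med <- r_iel + layer_split[["media"]]

  # half-open distance bands; the epsilon keeps sites that land exactly on
  # a band boundary (collinear knife-edge cases) on a consistent side, so
  # adjacent sites (distance 1) can never straddle a whole band
  eps <- 1e-6
  layer <- rep(.LY_EXT, geo$n)
  layer[geo$dc < r_med + eps] <- .LY_MED
  layer[geo$dc < r_iel + eps] <- .LY_IEL
  layer[geo$dc < r_int + eps] <- .LY_INT
  layer[geo$dc < lumen_radius_sites + eps] <- .LY_LUMEN

  occ <- rep(.EXT, geo$n)
  occ[layer == .LY_LUMEN] <- .LUMEN
  occ[layer == .LY_IEL] <- .IEL
  clock <- rep(NA_real_, geo$n)

  populate <- function(idx) {
    n <- length(idx)
    n_smc <- round(smc_fraction * n)
    kinds <- rep(.ECM, n)
    kinds[sample.int(n, n_smc)] <- .SMC
    occ[idx] <<- kinds
    clock[idx[kinds == .SMC]] <<- sample(0:(T_SMC - 1L),
                                         sum(kinds == .SMC), replace = TRUE)
    clock[idx[kinds == .ECM]] <<- sample(0:(T_ECM - 1L),
                                         sum(kinds == .ECM), replace = TRUE)
  }
  populate(which(layer == .LY_INT))
  populate(which(layer == .LY_MED))

  v <- structure(
    list(occ = occ, layer = layer, clock = clock, geo = geo, spec = spec,
         lumen_radius_sites = lumen_radius_sites,
         wall_thickness_sites = wall_thickness_sites,
         layer_split = layer_split,
         initial_lumen_area = sum(occ == .LUMEN),
         iel_ring = which(layer == .LY_IEL),
         stimulus_support = layer == .LY_INT),
    class = "vessel_section"
  )
  v
}

#' @export
print.vessel_section <- function(x, ...) {
  a <- section_areas(x)
  cat(sprintf(
    paste0("<vessel_section> %d x %d hex grid | lumen %d sites ",
           "(initial %d) | intima %d | media %d\n"),
    x$geo$nr, x$geo$nc, a$lumen_area, x$initial_lumen_area,
    a$intima_area, a$media_area))
  cat(sprintf("  intima: %d SMC / %d ECM / %d MP; media: %d SMC / %d ECM\n",
              a$intima_smc, a$intima_ecm, a$intima_mp,
              a$media_smc, a$media_ecm))
  invisible(x)
}

#' Areas and per-layer agent counts of a cross-section
#'
#' @param v A `vessel_section`.
#' @return A one-row tibble with lumen/intima/media areas (in sites) and the
#'   per-layer SMC, ECM and MP counts.
#' @export
section_areas <- function(v) {
  occ <- v$occ; layer <- v$layer
  int <- layer == .LY_INT
  med <- layer == .LY_MED
  tibble::tibble(
    lumen_area  = sum(occ == .LUMEN),
    intima_area = sum(int),
    media_area  = sum(med),
    intima_smc  = sum(occ == .SMC & int),
    intima_ecm  = sum(occ == .ECM & int),
    intima_mp   = sum(occ == .MP & int),
    media_smc   = sum(occ == .SMC & med),
    media_ecm   = sum(occ == .ECM & med),
    media_mp    = sum(occ == .MP & med)
  )
}

#' Tidy per-site view of a cross-section
#'
#' @param x A `vessel_section`.
#' @param ... Unused.
#' @return A tibble with one row per site: row, col, real-space x/y, layer and
#'   occupant labels.
#' @export
as_tibble.vessel_section <- function(x, ...) {
  geo <- x$geo
  layer <- factor(.LAYER_LEVELS[x$layer + 1L], levels = .LAYER_LEVELS)
  occupant <- factor(.OCC_LEVELS[x$occ + 1L], levels = .OCC_LEVELS)
  tibble::tibble(
    site = seq_len(geo$n), row = geo$row, col = geo$col,
    x = geo$x, y = geo$y, layer = layer, occupant = occupant
  )
}

# lumen sites that touch the wall (used for border profiles)
lumen_border_sites <- function(v) {
  lum <- which(v$occ == .LUMEN)
  if (length(lum) == 0L) return(integer(0))
  nb <- v$geo$nb[lum, , drop = FALSE]
  occ_nb <- matrix(.EXT, nrow(nb), 6L)
  on <- nb > 0L
  occ_nb[on] <- v$occ[nb[on]]
  lum[rowSums(occ_nb != .LUMEN & on) > 0L]
}

# intima sites that touch the lumen ("lumen wall", first intima layer)
lumen_wall_sites <- function(v) {
  int <- which(v$layer == .LY_INT & v$occ != .LUMEN)
  if (length(int) == 0L) return(integer(0))
  nb <- v$geo$nb[int, , drop = FALSE]
  occ_nb <- matrix(.EXT, nrow(nb), 6L)
  on <- nb > 0L
  occ_nb[on] <- v$occ[nb[on]]
  int[rowSums(occ_nb == .LUMEN & on) > 0L]
}

#' Polar profile of the lumen border
#'
#' Bins the lumen border sites by angle around the cross-section centre and
#' reports the mean centre distance per bin; empty bins are filled by
#' circular linear interpolation.  This is the basis of the non-symmetry
#' (NS) index.
#'
#' @param v A `vessel_section`.
#' @param n_bins Number of angular bins (default 360, one-degree resolution).
#' @return A `polar_profile` tibble with columns `bin`, `angle` (bin-centre
#'   radians in (-pi, pi]) and `radius` (sites).
#' @export
polar_profile <- function(v, n_bins = 360L) {
  if (sum(v$occ == .LUMEN) == 0L)
    stop("lumen is fully occluded; polar profile undefined", call. = FALSE)
  border <- lumen_border_sites(v)
  geo <- v$geo
  ang <- geo$angle[border]
  rad <- geo$dc[border]
  bin <- pmin(n_bins, floor((ang + pi) / (2 * pi) * n_bins) + 1L)
  radius <- rep(NA_real_, n_bins)
  agg <- tapply(rad, bin, mean)
  radius[as.integer(names(agg))] <- agg
  radius <- fill_circular(radius)
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    angle = -pi + (seq_len(n_bins) - 0.5) * 2 * pi / n_bins,
    radius = radius
  )
  class(out) <- c("polar_profile", class(out))
  out
}

# circular linear interpolation over NA runs
fill_circular <- function(x) {
  n <- length(x)
  ok <- which(!is.na(x))
  if (length(ok) == 0L) stop("no border sites in any angular bin")
  if (length(ok) == n) return(x)
  for (i in which(is.na(x))) {
    lo <- if (any(ok < i)) max(ok[ok < i]) else max(ok) - n
    hi <- if (any(ok > i)) min(ok[ok > i]) else min(ok) + n
    w <- (i - lo) / (hi - lo)
    x[i] <- (1 - w) * x[(lo - 1L) %% n + 1L] + w * x[(hi - 1L) %% n + 1L]
  }
  x
}

#' Export the lattice occupancy as an integer-coded matrix
#'
#' Codes: 0 lumen, 1 SMC, 2 ECM, 3 IEL, 4 MP, 5 exterior (documented in the
#' object's `"legend"` attribute).
#'
#' @param v A `vessel_section`.
#' @return An `n_rows x n_cols` integer matrix.
#' @export
occupancy_matrix <- function(v) {
  m <- matrix(v$occ, v$geo$nr, v$geo$nc)
  attr(m, "legend") <- stats::setNames(0:5, .OCC_LEVELS)
  m
}
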