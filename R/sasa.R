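# Solvent-accessible surface area. The production path is a deterministic
# Shrake-Rupley implementation on a golden-spiral point lattice; an
# independent latitude-longitude quadrature implementation is exposed as a
# cross-check and supplies ground truth for the synthetic generators.

#' Deterministic golden-spiral points on the unit sphere
#'
#' @param n Number of points (>= 1).
#' @return `n` x 3 matrix of unit vectors. Bit-reproducible for fixed `n`.
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area parameters
#'
#' @param probe_radius Solvent probe radius in angstrom (default 1.4, water).
#' @param n_sphere_points Test points per atom (default 960; >= 100).
#' @param radii Named van der Waals radii table, see [vdw_radii()].
#' @return A list of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_sphere_points = 960,
                        radii = vdw_radii()) {
  stopifnot(probe_radius > 0, n_sphere_points >= 100)
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = n_sphere_points,
                 radii = radii),
            class = "sasa_params")
}

# Deterministic canonical orientation: principal axes of the coordinate
# cloud, eigenvector signs fixed by the sign of the third central moment
# along each axis (+1 when the moment vanishes), third axis completing a
# right-handed frame. Because the test-point lattice is laid out in this
# frame, surface areas are invariant under rigid motion of the input (up to
# floating-point error) as well as under atom reordering.
canonical_coords <- function(xyz) {
  if (nrow(xyz) < 3) return(xyz)
  ctr <- colMeans(xyz)
  x0 <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(x0) / nrow(x0), symmetric = TRUE)
  V <- ev$vectors
  for (k in 1:2) {
    m3 <- sum((x0 %*% V[, k])^3)
    if (abs(m3) > 1e-8 && m3 < 0) V[, k] <- -V[, k]
  }
  V[, 3] <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
              V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
              V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
  x0 %*% V
}

# Shared core: for each atom, which of its expanded-sphere test points are
# occluded by any other atom's expanded sphere. pts is an n_pts x 3 unit
# matrix. Returns per-atom accessible fraction.
accessible_fraction <- function(xyz, rad_exp, pts) {
  n <- nrow(xyz)
  max_cut <- 2 * max(rad_exp)
  nb <- neighbor_pairs(xyz, max_cut)
  nb <- nb[nb$dist < rad_exp[nb$i] + rad_exp[nb$j], , drop = FALSE]
  nbl <- vector("list", n)
  if (nrow(nb) > 0) {
    both <- c(nb$i, nb$j)
    other <- c(nb$j, nb$i)
    nbl <- split(other, factor(both, levels = seq_len(n)))
  } else {
    nbl <- rep(list(integer(0)), n)
  }
  frac <- numeric(n)
  for (a in seq_len(n)) {
    neigh <- nbl[[a]]
    if (length(neigh) == 0) {
      frac[a] <- 1
      next
    }
    p <- pts * rad_exp[a]
    p <- sweep(p, 2, xyz[a, ], "+")
    access <- rep(TRUE, nrow(p))
    for (b in neigh) {
      if (!any(access)) break
      db2 <- (p[access, 1] - xyz[b, 1])^2 + (p[access, 2] - xyz[b, 2])^2 +
        (p[access, 3] - xyz[b, 3])^2
      access[access] <- db2 >= rad_exp[b]^2
    }
    frac[a] <- mean(access)
  }
  frac
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over every polymer heavy atom of the selected chains:
#' each atom's van der Waals sphere is expanded by the probe radius, sampled
#' with a deterministic golden-spiral lattice, and the accessible fraction of
#' sample points (those outside every other expanded sphere) is converted to
#' area. Only atoms of `chains` occlude each other, so the same call computes
#' a subcomplex in isolation.
#'
#' @param structure An `allo_structure`.
#' @param params A [sasa_params()] object.
#' @param chains Roles and/or chain ids defining the subset (default: all
#'   polymer chains).
#' @return The selected atoms with an added `sasa` column (angstrom squared).
#' @export
compute_sasa <- function(structure, params = sasa_params(), chains = NULL) {
  at <- polymer_heavy(structure)
  if (!is.null(chains)) {
    at <- filter(at, .data$chain %in% resolve_chains(structure, chains))
  }
  if (nrow(at) == 0) abort("Empty atom subset for SASA.")
  rad <- lookup_radii(at$element, params$radii) + params$probe_radius
  pts <- sphere_points(params$n_sphere_points)
  frac <- accessible_fraction(canonical_coords(atom_xyz(at)), rad, pts)
  mutate(at, sasa = 4 * pi * rad^2 * frac)
}

#' Per-atom SASA by latitude-longitude quadrature (independent cross-check)
#'
#' Numerically integrates the accessible portion of each expanded sphere on a
#' regular latitude-longitude grid with cos(latitude) area weights. The point
#' construction and the integration rule share nothing with the golden-spiral
#' Shrake-Rupley path, so this serves as an independent numerical oracle; it
#' also provides buried-area ground truth for synthetic toy complexes.
#'
#' @inheritParams compute_sasa
#' @param n_lat Number of latitude bands (default 64; longitudes are `2 *
#'   n_lat`).
#' @return The selected atoms with an added `sasa` column.
#' @export
sasa_quadrature <- function(structure, params = sasa_params(), chains = NULL,
                            n_lat = 64) {
  at <- polymer_heavy(structure)
  if (!is.null(chains)) {
    at <- filter(at, .data$chain %in% resolve_chains(structure, chains))
  }
  if (nrow(at) == 0) abort("Empty atom subset for SASA.")
  rad <- lookup_radii(at$element, params$radii) + params$probe_radius
  # midpoint rule in latitude and longitude; weight = cos(lat) dlat dlon
  lat <- (seq_len(n_lat) - 0.5) / n_lat * pi - pi / 2
  lon <- (seq_len(2 * n_lat) - 0.5) / (2 * n_lat) * 2 * pi
  grid <- expand.grid(lat = lat, lon = lon)
  pts <- cbind(cos(grid$lat) * cos(grid$lon),
               cos(grid$lat) * sin(grid$lon),
               sin(grid$lat))
  w <- cos(grid$lat) * (pi / n_lat) * (2 * pi / (2 * n_lat))
  w <- w / sum(w)  # normalized so sum(w) * 4*pi*R^2 is the full sphere
  xyz <- atom_xyz(at)
  n <- nrow(xyz)
  max_cut <- 2 * max(rad)
  nb <- neighbor_pairs(xyz, max_cut)
  nb <- nb[nb$dist < rad[nb$i] + rad[nb$j], , drop = FALSE]
  area <- numeric(n)
  for (a in seq_len(n)) {
    neigh <- c(nb$j[nb$i == a], nb$i[nb$j == a])
    if (length(neigh) == 0) {
      area[a] <- 4 * pi * rad[a]^2
      next
    }
    p <- sweep(pts * rad[a], 2, xyz[a, ], "+")
    access <- rep(TRUE, nrow(p))
    for (b in neigh) {
      db2 <- (p[, 1] - xyz[b, 1])^2 + (p[, 2] - xyz[b, 2])^2 +
        (p[, 3] - xyz[b, 3])^2
      access <- access & (db2 >= rad[b]^2)
    }
    area[a] <- 4 * pi * rad[a]^2 * sum(w[access])
  }
  mutate(at, sasa = area)
}
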