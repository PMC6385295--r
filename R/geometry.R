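# Spatial-grid neighbor search. Cell lists give O(n) pair enumeration at a
# fixed cutoff and are used by the SASA, contact and clash routines; the
# brute-force variant is the oracle the grid must reproduce exactly.

#' All atom pairs within a distance cutoff (cell-list search)
#'
#' Bins coordinates into a cubic grid of cell edge `cutoff` and enumerates
#' pairs within the same or adjacent cells, then filters on true distance.
#' Output is identical (as a set) to [brute_force_pairs()].
#'
#' @param xyz Numeric matrix, one row per point.
#' @param cutoff Distance cutoff in angstrom (> 0).
#' @return Tibble with columns `i`, `j` (`i < j`) and `dist`.
#' @export
neighbor_pairs <- function(xyz, cutoff) {
  stopifnot(cutoff > 0)
  n <- nrow(xyz)
  if (n < 2) return(tibble(i = integer(), j = integer(), dist = numeric()))
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
  cells <- split(seq_len(n), key)
  cell_of <- match(key, names(cells))
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  coords <- do.call(rbind, strsplit(names(cells), ","))
  storage.mode(coords) <- "integer"
  ii <- integer(0); jj <- integer(0)
  for (c_idx in seq_along(cells)) {
    a <- cells[[c_idx]]
    # pairs within the cell
    if (length(a) > 1) {
      p <- combn(a, 2)
      ii <- c(ii, p[1, ]); jj <- c(jj, p[2, ])
    }
    # pairs with neighboring cells of higher index (each cell pair once)
    nb_keys <- sweep(offsets, 2, coords[c_idx, ], "+")
    nb_keys <- paste(nb_keys[, 1], nb_keys[, 2], nb_keys[, 3], sep = ",")
    nb_idx <- match(nb_keys, names(cells))
    nb_idx <- nb_idx[!is.na(nb_idx) & nb_idx > c_idx]
    for (d_idx in nb_idx) {
      b <- cells[[d_idx]]
      ii <- c(ii, rep(a, times = length(b)))
      jj <- c(jj, rep(b, each = length(a)))
    }
  }
  swap <- ii > jj
  tmp <- ii[swap]; ii[swap] <- jj[swap]; jj[swap] <- tmp
  d2 <- rowSums((xyz[ii, , drop = FALSE] - xyz[jj, , drop = FALSE])^2)
  keep <- d2 <= cutoff^2
  tibble(i = ii[keep], j = jj[keep], dist = sqrt(d2[keep])) |>
    arrange(.data$i, .data$j)
}

#' All atom pairs within a cutoff by exhaustive comparison
#'
#' Quadratic reference implementation against which the cell-list search is
#' validated.
#'
#' @inheritParams neighbor_pairs
#' @return Tibble with columns `i`, `j` (`i < j`) and `dist`.
#' @export
brute_force_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2) return(tibble(i = integer(), j = integer(), dist = numeric()))
  p <- combn(n, 2)
  d <- sqrt(rowSums((xyz[p[1, ], , drop = FALSE] -
                       xyz[p[2, ], , drop = FALSE])^2))
  keep <- d <= cutoff
  tibble(i = p[1, keep], j = p[2, keep], dist = d[keep]) |>
    arrange(.data$i, .data$j)
}

vec_angle <- function(a, b) {
  # angle in degrees between row vectors a and b
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a^2)) * sqrt(rowSums(b^2))
  acos(pmin(1, pmax(-1, num / den))) * 180 / pi
}
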