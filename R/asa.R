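#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom accessible area from M quasi-uniform test points (Fibonacci
#' sphere) placed on each atom's solvent-exposed sphere of radius
#' \eqn{r_{vdw} + r_{probe}}; a point counts as accessible when it lies
#' outside every other atom's probe-inflated sphere. Areas are summed per
#' residue.
#'
#' @param structure A \code{protein_structure}.
#' @param n_points Test points per atom (quadrature resolution).
#' @param probe_radius Solvent probe radius in Angstrom.
#' @return Numeric vector of length L: per-residue ASA in Angstrom^2.
#' @export
#' @examples
#' pdb <- generate_structure(fold_spec_library()[["beta_hairpins"]], seed = 1)
#' asa <- compute_accessible_area(parse_structure(pdb))
#' head(round(asa, 1))
compute_accessible_area <- function(structure, n_points = 960, probe_radius = 1.4) {
  at <- structure$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(xyz)
  rad <- element_vdw_radius[at$element] + probe_radius
  sphere <- fibonacci_sphere(n_points)

  atom_asa <- numeric(n)
  if (n == 1) {
    atom_asa <- 4 * pi * rad^2
  } else {
    d2 <- as.matrix(stats::dist(xyz))^2
    for (i in seq_len(n)) {
      # Neighbours whose inflated sphere can clip atom i's surface.
      nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
      if (length(nb) == 0) {
        atom_asa[i] <- 4 * pi * rad[i]^2
        next
      }
      pts <- sphere * rad[i]
      pts <- sweep(pts, 2, xyz[i, ], "+")
      # Squared distances of all test points to all neighbours.
      pd2 <- outer(rowSums(pts^2), rowSums(xyz[nb, , drop = FALSE]^2), "+") -
        2 * pts %*% t(xyz[nb, , drop = FALSE])
      buried <- rowSums(sweep(pd2, 2, rad[nb]^2, "<")) > 0
      atom_asa[i] <- 4 * pi * rad[i]^2 * mean(!buried)
    }
  }

  L <- nchar(structure$sequence)
  asa <- numeric(L)
  agg <- rowsum(atom_asa, group = at$residue_ordinal)
  asa[as.integer(rownames(agg))] <- agg[, 1]
  asa
}

# Quasi-uniform points on the unit sphere (Fibonacci / golden-angle spiral).
fibonacci_sphere <- function(m) {
  i <- seq_len(m) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(m) - 1)
  z <- 1 - 2 * i / m
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}
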