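#' Build the 53-feature point cloud for one protein
#'
#' One row per retained heavy atom, columns in canonical order (see
#' \code{\link{point_cloud_columns}}): raw coordinates; raw B factor
#' (min-max scaled later by \code{\link{apply_normalization}}); occupancy;
#' distance from the N-terminus as residue ordinal / L; the two-group
#' secondary-structure indicators; accessible area as a fraction of the
#' residue-type theoretical maximum (clipped at 1); the 20-column amino-acid
#' one-hot; charge, polarity, polarizability and hydrophobicity from the
#' embedded lookup tables; and the 20 PSSM columns squashed to (0, 1) by the
#' elementwise logistic \eqn{1/(1+e^{-s})}. Every atom inherits the
#' residue-level features of its residue. Unknown residues get an all-zero
#' one-hot and zero physicochemical features.
#'
#' @param structure A \code{protein_structure}.
#' @param pssm L x 20 matrix from \code{\link{read_pssm}} (or \code{NULL} for
#'   the zero-fill sentinel).
#' @param annotation An \code{ss_annotation}; computed from the structure if
#'   omitted. If the annotation carries DSSP areas those are used, otherwise
#'   areas come from \code{\link{compute_accessible_area}}.
#' @param label Optional fold label carried on the cloud.
#' @return A \code{point_cloud}.
#' @export
featurize <- function(structure, pssm = NULL, annotation = NULL,
                      label = NA_character_) {
  L <- nchar(structure$sequence)
  if (is.null(pssm)) pssm <- read_pssm(NULL, L)
  if (nrow(pssm) != L) stop("PSSM row count must equal sequence length", call. = FALSE)
  if (is.null(annotation)) annotation <- assign_secondary_structure(structure)
  if (length(annotation$label) != L) {
    stop("annotation length must equal sequence length", call. = FALSE)
  }

  at <- structure$atoms
  res <- at$residue_ordinal
  seq1 <- strsplit(structure$sequence, "")[[1]]
  aa_idx <- match(seq1, aa_order)          # NA for unknown residues

  asa <- annotation$asa
  if (anyNA(asa)) asa <- compute_accessible_area(structure)
  max_asa <- ifelse(is.na(aa_idx), mean(aa_max_asa), aa_max_asa[aa_idx])
  asa_frac <- pmin(asa / max_asa, 1)

  onehot <- matrix(0, nrow = L, ncol = 20)
  known <- which(!is.na(aa_idx))
  onehot[cbind(known, aa_idx[known])] <- 1

  phys <- cbind(
    charge         = ifelse(is.na(aa_idx), 0, aa_charge[aa_idx]),
    polarity       = ifelse(is.na(aa_idx), 0, aa_polarity[aa_idx]),
    polarizability = ifelse(is.na(aa_idx), 0, aa_polarizability[aa_idx]),
    hydrophobicity = ifelse(is.na(aa_idx), 0, aa_hydrophobicity[aa_idx])
  )

  is_helix <- as.numeric(annotation$label == "helix")
  is_sheet <- as.numeric(annotation$label == "sheet")
  pssm01 <- 1 / (1 + exp(-pssm))

  pts <- cbind(
    at$x, at$y, at$z,
    at$b_factor,
    at$occupancy,
    res / L,
    is_helix[res],
    is_sheet[res],
    asa_frac[res],
    onehot[res, , drop = FALSE],
    phys[res, , drop = FALSE],
    pssm01[res, , drop = FALSE]
  )
  new_point_cloud(pts, label = label, source_id = structure$identifier)
}

#' Fit dataset-level normalization statistics on training clouds
#'
#' Each protein is first centred at its own coordinate centroid; the global
#' coordinate scale is the 95th percentile (linear-interpolation definition,
#' \code{quantile} type 7) of the pooled centred atom radii across all
#' training clouds, so that after scaling 95\% of training atoms fall inside
#' the unit sphere while the relative size of any two proteins is preserved.
#' The B-factor range is the pooled (min, max) over training atoms.
#'
#' @param training_clouds List of \code{point_cloud} objects (training set
#'   only; fitting on test data is a protocol violation).
#' @return An object of class \code{bios2net_norm} with \code{global_scale}
#'   (Angstrom) and \code{b_factor_range}.
#' @export
fit_normalization <- function(training_clouds) {
  if (length(training_clouds) == 0) stop("no training clouds supplied", call. = FALSE)
  radii <- unlist(lapply(training_clouds, function(cl) {
    xyz <- cl$points[, 1:3, drop = FALSE]
    ctr <- colMeans(xyz)
    sqrt(rowSums(sweep(xyz, 2, ctr)^2))
  }))
  gs <- unname(stats::quantile(radii, 0.95, type = 7))
  if (gs <= 0) stop("degenerate training set: 95th-percentile radius is 0", call. = FALSE)
  b <- unlist(lapply(training_clouds, function(cl) cl$points[, 4]))
  structure(list(global_scale = gs, b_factor_range = range(b)),
            class = "bios2net_norm")
}

#' @export
print.bios2net_norm <- function(x, ...) {
  cat(sprintf("<bios2net_norm> global scale %.4f A; B-factor range [%.2f, %.2f]\n",
              x$global_scale, x$b_factor_range[1], x$b_factor_range[2]))
  invisible(x)
}

#' Apply fitted normalization to a point cloud
#'
#' Coordinates are centred at the cloud's own centroid and divided by the
#' single fitted global scale (the same divisor for every protein, so
#' between-protein size ratios are preserved exactly). B factors are min-max
#' scaled by the fitted training range and clipped to [0, 1]; zero-filled B
#' factors of unannotated structures stay 0 only if 0 is the training
#' minimum, which holds whenever such structures are present in training.
#'
#' @param cloud A \code{point_cloud}.
#' @param stats A \code{bios2net_norm} from \code{\link{fit_normalization}}.
#' @return The normalized \code{point_cloud}.
#' @export
apply_normalization <- function(cloud, stats) {
  stopifnot(inherits(stats, "bios2net_norm"))
  pts <- cloud$points
  xyz <- pts[, 1:3, drop = FALSE]
  pts[, 1:3] <- sweep(xyz, 2, colMeans(xyz)) / stats$global_scale
  rng <- stats$b_factor_range
  den <- rng[2] - rng[1]
  pts[, 4] <- if (den > 0) pmin(pmax((pts[, 4] - rng[1]) / den, 0), 1) else 0
  new_point_cloud(pts, label = cloud$label, source_id = cloud$source_id)
}
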