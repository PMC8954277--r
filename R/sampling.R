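# Run a block of code under a locally-seeded RNG without disturbing the
# caller's RNG stream; seed = NULL uses (and advances) the caller's stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Reduce a point cloud to a fixed point count, preserving atom order
#'
#' When the cloud has at least \code{n_points} atoms, a uniform random subset
#' without replacement is drawn and re-sorted ascending by original atom
#' index, so the sequence order of the retained atoms is never shuffled.
#' Smaller clouds are padded by cyclic repetition of their rows in order.
#'
#' @param cloud A \code{point_cloud}.
#' @param n_points Target point count.
#' @param seed Integer seed for reproducible subsetting, or \code{NULL} to
#'   draw from the current RNG stream.
#' @return A \code{point_cloud} with exactly \code{n_points} rows and an
#'   attribute \code{source_index} giving each row's original atom index.
#' @export
sample_points <- function(cloud, n_points, seed = NULL) {
  stopifnot(inherits(cloud, "point_cloud"), n_points >= 1)
  n <- nrow(cloud$points)
  if (n == 0) stop("cannot sample from an empty cloud", call. = FALSE)
  idx <- if (n >= n_points) {
    with_local_seed(seed, sort(sample.int(n, n_points)))
  } else {
    rep_len(seq_len(n), n_points)
  }
  out <- new_point_cloud(cloud$points[idx, , drop = FALSE],
                         label = cloud$label, source_id = cloud$source_id)
  attr(out, "source_index") <- idx
  out
}

#' Augmentation configuration
#'
#' Training-time point-cloud augmentation: random rotation about the three
#' axes by independent angles uniform on \eqn{[0, 2\pi)}, random isotropic
#' scaling, random translation, and slight per-point Gaussian jitter clipped
#' at \code{jitter_clip}. Only the three coordinate columns are ever
#' touched. Defaults quantify "slight" in normalized coordinate units.
#'
#' @param rotation Enable random rotation.
#' @param scale_range Length-2 numeric (lo, hi) for uniform scale draw.
#' @param translation_range Half-width of the uniform translation per axis.
#' @param jitter_sigma Jitter standard deviation.
#' @param jitter_clip Absolute clip applied to jitter draws.
#' @return A list of class \code{augmentation_config}.
#' @export
augmentation_config <- function(rotation = TRUE, scale_range = c(0.9, 1.1),
                                translation_range = 0.1, jitter_sigma = 0.005,
                                jitter_clip = 0.02) {
  stopifnot(length(scale_range) == 2, scale_range[1] <= scale_range[2],
            jitter_sigma >= 0, jitter_clip >= jitter_sigma)
  structure(list(rotation = rotation, scale_range = scale_range,
                 translation_range = translation_range,
                 jitter_sigma = jitter_sigma, jitter_clip = jitter_clip),
            class = "augmentation_config")
}

# Rotation matrix R_z(g) R_y(b) R_x(a).
rotation_matrix <- function(a, b, g) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Apply random augmentation to a point cloud
#'
#' @param cloud A \code{point_cloud} with normalized coordinates.
#' @param config An \code{\link{augmentation_config}}.
#' @param seed Integer seed, or \code{NULL} to use the current RNG stream
#'   (the mode used inside the training loop).
#' @return The augmented \code{point_cloud}; rows and all non-coordinate
#'   columns are bitwise unchanged.
#' @export
augment <- function(cloud, config = augmentation_config(), seed = NULL) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(config, "augmentation_config"))
  with_local_seed(seed, {
    pts <- cloud$points
    xyz <- pts[, 1:3, drop = FALSE]
    if (config$rotation) {
      ang <- stats::runif(3, 0, 2 * pi)
      xyz <- xyz %*% t(rotation_matrix(ang[1], ang[2], ang[3]))
    }
    s <- stats::runif(1, config$scale_range[1], config$scale_range[2])
    xyz <- xyz * s
    tr <- stats::runif(3, -config$translation_range, config$translation_range)
    xyz <- sweep(xyz, 2, tr, "+")
    if (config$jitter_sigma > 0) {
      j <- matrix(stats::rnorm(length(xyz), sd = config$jitter_sigma), ncol = 3)
      j <- pmin(pmax(j, -config$jitter_clip), config$jitter_clip)
      xyz <- xyz + j
    }
    pts[, 1:3] <- xyz
    out <- new_point_cloud(pts, label = cloud$label, source_id = cloud$source_id)
    attr(out, "source_index") <- attr(cloud, "source_index")
    out
  })
}
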