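test_that("featurized clouds have 53 columns with in-range feature blocks", {
  for (cl in fixture_clouds()[c(1, 5, 9)]) {
    pts <- cl$points
    expect_equal(ncol(pts), 53)
    expect_equal(colnames(pts), point_cloud_columns())
    expect_true(all(pts[, 5:29] >= 0 & pts[, 5:29] <= 1))
    expect_true(all(pts[, 30] >= -1 & pts[, 30] <= 1))
    expect_true(all(pts[, 31:53] >= 0 & pts[, 31:53] <= 1))
    expect_true(all(pts[, 7] %in% c(0, 1) & pts[, 8] %in% c(0, 1)))
    expect_true(all(pts[, 7] + pts[, 8] <= 1))
    expect_true(all(rowSums(pts[, 10:29]) %in% c(0, 1)))
  }
})

test_that("residue-level features propagate to atoms as specified", {
  s <- fixture_ideal_hairpin()
  L <- nchar(s$sequence)
  pssm <- read_pssm(NULL, L)
  cl <- featurize(s, pssm)
  # N-terminus distance of residue-1 atoms is 1/L; of residue r, r/L
  r1 <- cl$points[s$atoms$residue_ordinal == 1, "nterm_distance"]
  expect_equal(unique(r1), 1 / L)
  r5 <- cl$points[s$atoms$residue_ordinal == 5, "nterm_distance"]
  expect_equal(unique(r5), 5 / L)
  # zero raw PSSM score maps to 0.5 under the logistic squashing
  expect_true(all(cl$points[, 34:53] == 0.5))
  # one-hot matches the sequence
  aa1 <- strsplit(s$sequence, "")[[1]]
  idx <- match(aa1, bios2net:::aa_order)
  onehot <- cl$points[, 10:29]
  expect_true(all(onehot[cbind(seq_len(nrow(onehot)),
                               idx[s$atoms$residue_ordinal])] == 1))
})

test_that("featurization is deterministic", {
  s <- fixture_ideal_bundle()
  pssm <- read_pssm(generate_pssm(s$sequence, 0.8, 3), nchar(s$sequence))
  a <- featurize(s, pssm)
  b <- featurize(s, pssm)
  expect_identical(a$points, b$points)
})

test_that("isolated-atom accessible area matches the analytic sphere", {
  s <- structure(list(
    atoms = data.frame(element = "C", x = 0, y = 0, z = 0, b_factor = 10,
                       occupancy = 1, residue_ordinal = 1,
                       residue_name = "ALA", chain_id = "A", atom_name = "CA",
                       stringsAsFactors = FALSE),
    sequence = "A", identifier = "one-atom"), class = "protein_structure")
  asa <- compute_accessible_area(s)
  expect_equal(asa, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
})

test_that("a fully enclosed atom has zero accessible area", {
  # central C atom caged by a dense shell of atoms at 3 A
  sph <- bios2net:::fibonacci_sphere(60) * 3
  at <- data.frame(element = "C", x = c(0, sph[, 1]), y = c(0, sph[, 2]),
                   z = c(0, sph[, 3]), b_factor = 10, occupancy = 1,
                   residue_ordinal = c(1, rep(2, 60)),
                   residue_name = "ALA", chain_id = "A",
                   atom_name = c("CA", rep("CB", 60)),
                   stringsAsFactors = FALSE)
  s <- structure(list(atoms = at, sequence = "AA", identifier = "caged"),
                 class = "protein_structure")
  asa <- compute_accessible_area(s)
  expect_equal(asa[1], 0)
})

test_that("per-residue area agrees with a Monte-Carlo quadrature oracle", {
  s <- parse_structure(tiny_pdb_lines())
  asa <- compute_accessible_area(s)
  # oracle: random sphere points instead of the deterministic spiral
  at <- s$atoms
  rad <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)[at$element] + 1.4
  xyz <- as.matrix(at[, c("x", "y", "z")])
  set.seed(42)
  m <- 100000
  oracle <- vapply(seq_len(nrow(at)), function(i) {
    pts <- matrix(rnorm(m * 3), ncol = 3)
    pts <- pts / sqrt(rowSums(pts^2)) * rad[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    free <- rep(TRUE, m)
    for (j in seq_len(nrow(at))[-i]) {
      free <- free & (rowSums(sweep(pts, 2, xyz[j, ])^2) > rad[j]^2)
    }
    4 * pi * rad[i]^2 * mean(free)
  }, 0)
  oracle_res <- as.numeric(rowsum(oracle, at$residue_ordinal))
  expect_equal(asa, oracle_res, tolerance = 0.02)
})

test_that("normalization scale is the interpolated 95th percentile radius", {
  # 100 atoms at radii 0.01 * k (after centering they keep those radii by
  # symmetry: pairs at +/- r on x keep the centroid at the origin)
  r <- 0.01 * (1:100)
  pts <- matrix(0, 200, 53)
  pts[, 1] <- c(r, -r)                      # symmetric -> centroid at origin
  cl <- new_point_cloud(pts)
  st <- fit_normalization(list(cl))
  # oracle: sort + linear interpolation at rank (n-1)*p + 1, by hand
  x <- sort(c(r, r))
  h <- (length(x) - 1) * 0.95 + 1
  manual <- x[floor(h)] + (h - floor(h)) * (x[floor(h) + 1] - x[floor(h)])
  expect_equal(st$global_scale, manual)
  expect_equal(manual, 0.9505)
  # constant-radius cloud: scale equals that radius
  pts2 <- matrix(0, 10, 53); pts2[, 1] <- rep(c(2, -2), 5)
  expect_equal(fit_normalization(list(new_point_cloud(pts2)))$global_scale, 2)
  # degenerate single point at the origin
  expect_error(fit_normalization(list(new_point_cloud(matrix(0, 1, 53)))),
               "degenerate")
})

test_that("apply_normalization centres, rescales and min-max scales B factors", {
  clouds <- fixture_clouds()
  st <- fit_normalization(clouds)
  normed <- lapply(clouds, apply_normalization, stats = st)
  radii <- unlist(lapply(normed, function(cl) sqrt(rowSums(cl$points[, 1:3]^2))))
  # within one atom of 95% (percentile interpolation slack)
  expect_gte(mean(radii <= 1), 0.95 - 1 / length(radii))
  b <- unlist(lapply(normed, function(cl) cl$points[, 4]))
  expect_true(all(b >= 0 & b <= 1))
  expect_equal(max(b), 1)                   # training max maps to 1
  # between-protein scale ratios are preserved exactly (same divisor)
  span <- function(cl) max(dist(cl$points[1:20, 1:3]))
  i <- 1; j <- 5
  expect_equal(span(normed[[i]]) / span(normed[[j]]),
               span(clouds[[i]]) / span(clouds[[j]]))
})
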