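# Shared fixtures, built once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture_cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small 3-class synthetic dataset (4 structures per class).
fixture_dataset <- function() {
  fixture_cached("dataset", function() {
    generate_dataset(n_classes = 3, n_per_class = 4, seed = 11,
                     dir = file.path(tempdir(), "bios2net-fixture-ds"))
  })
}

# Featurized clouds for the fixture dataset.
fixture_clouds <- function() {
  fixture_cached("clouds", function() {
    bios2net:::featurize_manifest(fixture_dataset())
  })
}

# One noiseless ideal structure per element type, for geometry oracles.
fixture_ideal_bundle <- function() {
  fixture_cached("ideal_bundle", function() {
    specs <- fold_spec_library(noise_sigma = 0)
    sp <- specs$alpha_bundle
    sp$len_jitter <- 0
    parse_structure(generate_structure(sp, seed = 21))
  })
}

fixture_ideal_hairpin <- function() {
  fixture_cached("ideal_hairpin", function() {
    el <- function(type, len) list(type = type, len = len)
    sp <- structure(list(name = "hairpin2",
                         topology = list(el("strand", 7), el("coil", 3),
                                         el("strand", 7)),
                         noise_sigma = 0, conservation = 0.9, len_jitter = 0),
                    class = "fold_spec")
    parse_structure(generate_structure(sp, seed = 22))
  })
}

# Two tiny fold classes (< 128 atoms each) so clouds pad deterministically;
# used by the training-determinism tests.
fixture_tiny_manifest <- function() {
  fixture_cached("tiny_manifest", function() {
    el <- function(type, len) list(type = type, len = len)
    mk <- function(name, ...) structure(
      list(name = name, topology = list(...), noise_sigma = 0.3,
           conservation = 0.9, len_jitter = 1), class = "fold_spec")
    specs <- list(mini_helix = mk("mini_helix", el("helix", 20)),
                  mini_sheet = mk("mini_sheet", el("strand", 8), el("coil", 3),
                                  el("strand", 8)))
    generate_dataset(n_classes = 2, n_per_class = 6, seed = 31,
                     dir = file.path(tempdir(), "bios2net-fixture-tiny"),
                     specs = specs)
  })
}

fixture_tiny_clouds <- function() {
  fixture_cached("tiny_clouds", function() {
    bios2net:::featurize_manifest(fixture_tiny_manifest())
  })
}

# A random valid 53-column cloud (feature columns in range, not meaningful).
random_cloud <- function(n, seed = 1) {
  with_seed_local(seed, {
    pts <- cbind(matrix(rnorm(n * 3, sd = 0.5), ncol = 3),
                 matrix(runif(n * 50), ncol = 50))
    onehot <- matrix(0, n, 20)
    onehot[cbind(seq_len(n), sample.int(20, n, replace = TRUE))] <- 1
    pts[, 10:29] <- onehot
    pts[, 30] <- runif(n, -1, 1)
    new_point_cloud(pts, source_id = sprintf("random-%d", seed))
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Minimal hand-written PDB text used by the parser tests.
tiny_pdb_lines <- function() {
  c("HEADER    TEST",
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00 12.00           C",
    "ATOM      3  H   GLY A   1       2.000   1.000   0.000  1.00 10.00           H",
    "ATOM      4  C   GLY A   1       2.009   1.420   0.000  1.00 11.00           C",
    "ATOM      5  O   GLY A   1       1.251   2.390   0.000  1.00 11.00           O",
    "ATOM      6  N   ALA A   2       3.332   1.536   0.000  1.00 10.00           N",
    "ATOM      7  CA  ALA A   2       4.046   2.803   0.000  1.00 12.00           C",
    "ATOM      8  CB  ALA A   2       5.520   2.600   0.300  1.00 13.00           C",
    "HETATM    9  O   HOH A   3       8.000   8.000   8.000  1.00 20.00           O",
    "END")
}
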