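# Synthetic fold classes: parametric backbone geometries written as valid
# PDB text, plus PSI-BLAST-dialect PSSM files. Classes differ topologically
# (order and packing of secondary-structure elements), not compositionally,
# so a classifier has to learn structure rather than memorize sequences.

# -- internal-coordinate backbone construction --------------------------------

# Place atom d given atoms a-b-c, bond length |c-d|, angle b-c-d (deg) and
# torsion a-b-c-d (deg). Standard NeRF construction.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- pracma::cross(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma::cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + cbind(bc, m, n) %*% d2
}

# Build an element backbone (N, CA, C, O, CB matrices, n x 3) from phi/psi.
build_element <- function(n_res, phi, psi, omega = 180) {
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- as.numeric(place_atom(c(0, 1, 0), N[1, ], CA[1, ], 1.525, 111.2, -60))
  for (i in seq_len(n_res)[-1]) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], 1.329, 116.2, psi)
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], 1.458, 121.7, omega)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.2, phi)
  }
  for (i in seq_len(n_res)) {
    nn <- if (i < n_res) N[i + 1, ] else
      as.numeric(place_atom(N[i, ], CA[i, ], C[i, ], 1.329, 116.2, psi))
    u1 <- (C[i, ] - CA[i, ]); u1 <- u1 / sqrt(sum(u1^2))
    u2 <- (C[i, ] - nn); u2 <- u2 / sqrt(sum(u2^2))
    dir <- u1 + u2
    O[i, ] <- C[i, ] + 1.231 * dir / sqrt(sum(dir^2))
    CB[i, ] <- place_atom(C[i, ], N[i, ], CA[i, ], 1.521, 110.5, 123)
  }
  list(N = N, CA = CA, C = C, O = O, CB = CB, n = n_res)
}

elem_apply <- function(el, R = diag(3), t = c(0, 0, 0)) {
  for (nm in c("N", "CA", "C", "O", "CB")) {
    el[[nm]] <- sweep(el[[nm]] %*% t(R), 2, t, "+")
  }
  el
}

# Rotation taking unit vector a onto unit vector b.
rot_a_to_b <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- pracma::cross(a, b)
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- pracma::cross(a, p); v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

elem_axis <- function(el) {
  ax <- el$CA[el$n, ] - el$CA[1, ]
  ax / sqrt(sum(ax^2))
}

# Count simplified Kabsch-Sander H-bonds between two placed elements.
interelement_hbonds <- function(elA, elB) {
  bb <- list(N = rbind(elA$N, elB$N), CA = rbind(elA$CA, elB$CA),
             C = rbind(elA$C, elB$C), O = rbind(elA$O, elB$O),
             L = elA$n + elB$n)
  hb <- hbond_matrix(bb)
  ia <- seq_len(elA$n); ib <- elA$n + seq_len(elB$n)
  sum(hb[ia, ib]) + sum(hb[ib, ia])
}

#' Synthetic fold specifications
#'
#' A small library of topologically distinct synthetic "folds" mirroring the
#' SCOP class axes: an all-alpha three-helix bundle, an all-beta four-strand
#' antiparallel sheet, an alpha/beta alternation, a two-helix hairpin and a
#' beta-alpha-beta sandwich. Elements are listed in chain order; helices use
#' ideal (-57, -47) dihedrals (1.5 A rise per residue), strands (-139, 135)
#' (~3.3 A rise); strand pairs are packed antiparallel with the inter-strand
#' offset refined to maximize backbone hydrogen bonding.
#'
#' @param noise_sigma Gaussian coordinate noise added per atom (Angstrom).
#' @param conservation PSSM self-substitution strength in [0, 1].
#' @return Named list of \code{fold_spec} objects.
#' @export
fold_spec_library <- function(noise_sigma = 0.3, conservation = 0.9) {
  el <- function(type, len) list(type = type, len = len)
  mk <- function(name, ...) {
    structure(list(name = name, topology = list(...),
                   noise_sigma = noise_sigma, conservation = conservation,
                   len_jitter = 1),
              class = "fold_spec")
  }
  list(
    alpha_bundle = mk("alpha_bundle",
                      el("helix", 14), el("coil", 3), el("helix", 14),
                      el("coil", 3), el("helix", 14)),
    beta_hairpins = mk("beta_hairpins",
                       el("strand", 7), el("coil", 3), el("strand", 7),
                       el("coil", 4), el("strand", 7), el("coil", 3),
                       el("strand", 7)),
    alpha_beta = mk("alpha_beta",
                    el("strand", 6), el("coil", 3), el("helix", 12),
                    el("coil", 3), el("strand", 6), el("coil", 3),
                    el("helix", 12)),
    helix_hairpin = mk("helix_hairpin",
                       el("helix", 20), el("coil", 4), el("helix", 20)),
    beta_alpha_beta = mk("beta_alpha_beta",
                         el("strand", 8), el("coil", 3), el("helix", 8),
                         el("coil", 3), el("strand", 8), el("coil", 3),
                         el("strand", 8))
  )
}

# Per-element-type residue samplers (favoring the usual propensities).
element_sequence <- function(type, n) {
  probs <- switch(type,
    helix = c(A = 0.20, E = 0.15, L = 0.15, K = 0.10, Q = 0.10, R = 0.10,
              M = 0.05, I = 0.05, D = 0.05, F = 0.05),
    strand = c(V = 0.20, I = 0.15, F = 0.10, Y = 0.10, T = 0.10, L = 0.10,
               W = 0.05, C = 0.05, S = 0.075, A = 0.075),
    coil = c(G = 0.30, P = 0.20, S = 0.15, N = 0.15, D = 0.10, T = 0.10))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic protein structure as PDB text
#'
#' Backbone atoms (N, CA, C, O) plus CB (except glycine) are built on ideal
#' element geometry, elements are packed with alternating axis directions,
#' strand pairs are registered by an H-bond-maximizing offset search, coils
#' are interpolated between element ends, Gaussian coordinate noise is
#' added, and fixed-column ATOM records are emitted with B factors drawn
#' from U(5, 60) and occupancy 1. Deterministic per seed.
#'
#' @param spec A \code{fold_spec} (see \code{\link{fold_spec_library}}).
#' @param seed Integer seed.
#' @return Character vector of PDB lines.
#' @export
generate_structure <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "fold_spec"))
  with_local_seed(seed, {
    topo <- spec$topology
    jit <- spec$len_jitter %||% 0
    lens <- vapply(topo, function(e) {
      j <- if (jit > 0 && e$type != "coil") sample(seq(-jit, jit), 1) else 0
      as.integer(max(2, e$len + j))
    }, 0L)
    types <- vapply(topo, `[[`, "", "type")

    placed <- vector("list", length(topo))
    helix_x <- 0; sheet_x <- 0
    dirn <- 1
    prev_strand <- NULL
    for (i in seq_along(topo)) {
      if (types[i] == "coil") next
      if (types[i] == "helix") {
        el <- build_element(lens[i], -57, -47)
        span <- 1.5 * (lens[i] - 1)
        base <- c(helix_x, 10, if (dirn > 0) 0 else span)
        helix_x <- helix_x + 10
      } else {
        el <- build_element(lens[i], -139, 135)
        span <- 3.3 * (lens[i] - 1)
        base <- c(sheet_x, 0, if (dirn > 0) 0 else span)
        sheet_x <- sheet_x + 4.8
      }
      R0 <- rot_a_to_b(elem_axis(el), c(0, 0, dirn))
      el0 <- elem_apply(el, R0)
      el0 <- elem_apply(el0, diag(3), base - el0$CA[1, ])   # first CA at base
      if (types[i] == "strand" && !is.null(prev_strand)) {
        el0 <- register_strand(prev_strand, el0, dirn)
      }
      if (types[i] == "strand") prev_strand <- el0
      placed[[i]] <- el0
      dirn <- -dirn
    }

    # Coils: interpolate CA positions between flanking element ends and hang
    # plausible peptide frames on them.
    for (i in seq_along(topo)) {
      if (types[i] != "coil") next
      a <- if (i > 1) placed[[i - 1]] else NULL
      b <- if (i < length(topo)) placed[[i + 1]] else NULL
      p0 <- if (!is.null(a)) a$C[a$n, ] else c(-5, 5, 0)
      p1 <- if (!is.null(b)) b$N[1, ] else p0 + c(5, 5, 0)
      placed[[i]] <- build_coil(lens[i], p0, p1)
    }

    seq1 <- unlist(lapply(seq_along(topo), function(i)
      element_sequence(types[i], lens[i])))
    L <- sum(lens)

    # Assemble atoms in chain order with coordinate noise.
    lines <- character(0)
    serial <- 1L
    resno <- 0L
    for (i in seq_along(topo)) {
      el <- placed[[i]]
      for (r in seq_len(el$n)) {
        resno <- resno + 1L
        aa1 <- seq1[resno]
        res3 <- aa_one_to_three[aa1]
        atoms <- list(N = el$N[r, ], CA = el$CA[r, ], C = el$C[r, ],
                      O = el$O[r, ])
        if (aa1 != "G" && !anyNA(el$CB[r, ])) atoms$CB <- el$CB[r, ]
        for (nm in names(atoms)) {
          xyz <- atoms[[nm]] + stats::rnorm(3, sd = spec$noise_sigma)
          elem <- substr(nm, 1, 1)
          lines <- c(lines, sprintf(
            "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, nm, res3, "A", resno, xyz[1], xyz[2], xyz[3],
            1.00, stats::runif(1, 5, 60), elem))
          serial <- serial + 1L
        }
      }
    }
    c(sprintf("HEADER    SYNTHETIC FOLD %-24s", toupper(spec$name)),
      lines, "TER", "END")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Refine an antiparallel strand placement against its sheet neighbour by
# scanning spin about its own axis and small in-plane offsets, keeping the
# placement with the most inter-strand backbone H-bonds.
register_strand <- function(prev, el, dirn) {
  axis <- c(0, 0, dirn)
  base <- el$CA[1, ]
  best <- el; best_n <- interelement_hbonds(prev, el)
  for (spin in seq(0, 315, by = 45)) {
    th <- spin * pi / 180
    K <- rbind(c(0, -axis[3], axis[2]), c(axis[3], 0, -axis[1]),
               c(-axis[2], axis[1], 0))
    Rs <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    for (dx in c(-0.6, -0.3, 0, 0.3, 0.6)) {
      for (dz in c(-2, -1, 0, 1, 2)) {
        cand <- elem_apply(el, diag(3), -base)
        cand <- elem_apply(cand, Rs, base + c(dx, 0, dz))
        nh <- interelement_hbonds(prev, cand)
        if (nh > best_n) {
          best <- cand; best_n <- nh
        }
      }
    }
  }
  best
}

# A coil of n residues bridging p0 (previous C) to p1 (next N): CA positions
# on a bowed path, N/C/O hung off the local tangent.
build_coil <- function(n, p0, p1) {
  tvec <- p1 - p0
  d <- sqrt(sum(tvec^2))
  u <- if (d > 1e-6) tvec / d else c(1, 0, 0)
  perp <- pracma::cross(u, c(0, 0, 1))
  if (sqrt(sum(perp^2)) < 1e-6) perp <- pracma::cross(u, c(0, 1, 0))
  perp <- perp / sqrt(sum(perp^2))
  bow <- max(0, (3.6 * (n + 1) - d)) / 2
  ts <- seq_len(n) / (n + 1)
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  for (r in seq_len(n)) {
    ctr <- p0 + ts[r] * tvec + bow * sin(pi * ts[r]) * perp
    CA[r, ] <- ctr
    N[r, ] <- ctr - 1.2 * u + 0.5 * perp
    C[r, ] <- ctr + 1.2 * u + 0.5 * perp
    O[r, ] <- C[r, ] + 1.23 * perp
    CB[r, ] <- ctr + 1.5 * pracma::cross(u, perp)
  }
  list(N = N, CA = CA, C = C, O = O, CB = CB, n = n)
}

#' Generate a synthetic PSI-BLAST-dialect PSSM
#'
#' One row per residue; all columns are drawn at the background mean of -2
#' (sd 1) except the residue's own column, whose mean interpolates from the
#' background (-2, no self-preference) at \code{conservation = 0} up to 6 at
#' \code{conservation = 1}. Scores are integer-rounded and formatted in the
#' ASCII matrix dialect accepted by \code{\link{read_pssm}}.
#'
#' @param sequence 1-letter amino-acid string.
#' @param conservation Real in [0, 1]; 0 removes any self-preference.
#' @param seed Integer seed.
#' @return Character vector of PSSM file lines.
#' @export
generate_pssm <- function(sequence, conservation = 0.9, seed = 1) {
  stopifnot(nchar(sequence) >= 1, conservation >= 0, conservation <= 1)
  with_local_seed(seed, {
    aas <- strsplit(sequence, "")[[1]]
    L <- length(aas)
    hdr <- c("",
             "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
             paste0("            ", paste(rep(sprintf("%3s", aa_order), 2), collapse = "")))
    rows <- vapply(seq_len(L), function(i) {
      mu <- ifelse(aa_order == aas[i] & !is.na(match(aas[i], aa_order)),
                   -2 + 8 * conservation, -2)
      sc <- round(stats::rnorm(20, mean = mu, sd = 1))
      pct <- round(stats::runif(20, 0, 100))
      sprintf("%5d %s %s  %s  %4.2f %4.2f", i, aas[i],
              paste(sprintf("%3d", sc), collapse = ""),
              paste(sprintf("%3d", pct), collapse = ""),
              stats::runif(1, 0, 2), stats::runif(1, 0.5, 1.5))
    }, "")
    c(hdr, rows, "", "                      K         Lambda")
  })
}

#' Generate a synthetic fold-classification dataset
#'
#' Writes \code{n_classes} x \code{n_per_class} structures (PDB) with
#' matching PSSMs and a manifest TSV to \code{dir}. Classes are drawn in
#' order from \code{\link{fold_spec_library}}; instances vary in sequence,
#' element-length jitter, coordinate noise and B factors through
#' per-instance seeds.
#'
#' @param n_classes Number of fold classes (2 to 5).
#' @param n_per_class Structures per class.
#' @param seed Integer base seed.
#' @param dir Output directory (created if absent).
#' @param specs Optional list of \code{fold_spec}s overriding the library.
#' @return The manifest as a \code{dataset_manifest} (invisibly also written
#'   to \code{file.path(dir, "manifest.tsv")}).
#' @export
generate_dataset <- function(n_classes = 3, n_per_class = 30, seed = 7,
                             dir = tempfile("synthfolds"), specs = NULL) {
  if (n_classes < 2) stop("need at least 2 fold classes", call. = FALSE)
  if (is.null(specs)) specs <- fold_spec_library()
  if (n_classes > length(specs)) {
    stop(sprintf("at most %d classes available", length(specs)), call. = FALSE)
  }
  specs <- specs[seq_len(n_classes)]
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (ci in seq_along(specs)) {
    sp <- specs[[ci]]
    for (k in seq_len(n_per_class)) {
      iseed <- (seed * 10000L + ci * 1000L + k) %% .Machine$integer.max
      pdb <- generate_structure(sp, seed = iseed)
      id <- sprintf("%s_%03d", sp$name, k)
      pdb_path <- file.path(dir, paste0(id, ".pdb"))
      writeLines(pdb, pdb_path)
      s <- parse_structure(pdb_path)
      pssm <- generate_pssm(s$sequence, conservation = sp$conservation,
                            seed = iseed + 1L)
      pssm_path <- file.path(dir, paste0(id, ".pssm"))
      writeLines(pssm, pssm_path)
      rows[[length(rows) + 1]] <- data.frame(
        id = id, structure_path = basename(pdb_path),
        pssm_path = basename(pssm_path), label = sp$name,
        stringsAsFactors = FALSE)
    }
  }
  m <- do.call(rbind, rows)
  utils::write.table(m, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  read_manifest(file.path(dir, "manifest.tsv"))
}
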