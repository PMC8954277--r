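#' Secondary-structure assignment and two-group mapping
#'
#' Built-in simplified Kabsch-Sander assignment from backbone geometry.
#' A backbone hydrogen bond between the carbonyl of residue i (acceptor) and
#' the amide of residue j (donor) exists when the electrostatic energy
#' \deqn{E = 0.084 (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN}) \cdot 332}
#' (kcal/mol) is below -0.5. The amide hydrogen is reconstructed from peptide
#' geometry: 1.0 Angstrom from N along the unit vector C(i-1) - O(i-1).
#' Helix labels come from runs of two consecutive i -> i+n turns (n = 3, 4,
#' 5; DSSP classes G, H, I); sheet labels from parallel/antiparallel bridge
#' patterns (classes E, B). Helix takes priority so the two indicator columns
#' are mutually exclusive. Alternatively a precomputed DSSP output file can
#' be supplied, in which case only the two-group mapping
#' \{G,H,I\} -> helix, \{E,B\} -> sheet is applied (and the DSSP accessible
#' areas are carried along).
#'
#' @param structure A \code{protein_structure}.
#' @param dssp_file Optional path to a classic-format DSSP output file.
#' @return A list of class \code{ss_annotation}: \code{label} (factor with
#'   levels helix/sheet/other, length L) and \code{asa} (per-residue
#'   accessible area in Angstrom^2, \code{NA} unless imported from DSSP).
#' @export
assign_secondary_structure <- function(structure, dssp_file = NULL) {
  L <- nchar(structure$sequence)
  if (!is.null(dssp_file)) {
    d <- read_dssp(dssp_file)
    if (length(d$label) != L) {
      stop(sprintf("DSSP file has %d residues but structure has %d",
                   length(d$label), L), call. = FALSE)
    }
    return(d)
  }

  bb <- backbone_coords(structure)
  missing_bb <- apply(is.na(bb$N[, 1, drop = FALSE]) |
                        is.na(bb$CA[, 1, drop = FALSE]) |
                        is.na(bb$C[, 1, drop = FALSE]) |
                        is.na(bb$O[, 1, drop = FALSE]), 1, any)
  if (any(missing_bb)) {
    warning(sprintf("%d residue(s) missing backbone atoms; labelled 'other'",
                    sum(missing_bb)), call. = FALSE)
  }

  hb <- hbond_matrix(bb)          # hb[i, j]: CO of i accepts from NH of j
  lab <- rep("other", L)

  # n-turns and helices: two consecutive i -> i+n turns mark i+1 .. i+n.
  for (n in c(3, 4, 5)) {
    turn <- rep(FALSE, L)
    idx <- seq_len(max(0, L - n))
    if (length(idx)) turn[idx] <- hb[cbind(idx, idx + n)]
    for (i in seq_len(max(0, L - n - 1))) {
      if (turn[i] && turn[i + 1]) lab[(i + 1):(i + n)] <- "helix"
    }
  }

  # Bridges (parallel / antiparallel) between non-adjacent residues.
  sheet <- rep(FALSE, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (abs(i - j) < 3) next
      par <- (i > 1 && i < L && hb[i - 1, j] && hb[j, i + 1]) ||
             (j > 1 && j < L && hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) ||
              (i > 1 && i < L && j > 1 && j < L &&
                 hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (par || anti) sheet[c(i, j)] <- TRUE
    }
  }
  lab[sheet & lab != "helix"] <- "sheet"
  lab[missing_bb] <- "other"

  structure(list(label = factor(lab, levels = c("helix", "sheet", "other")),
                 asa = rep(NA_real_, L)),
            class = "ss_annotation")
}

# Per-residue backbone coordinate matrices (L x 3; NA where absent).
backbone_coords <- function(structure) {
  at <- structure$atoms
  L <- nchar(structure$sequence)
  out <- list()
  for (nm in c("N", "CA", "C", "O")) {
    m <- matrix(NA_real_, nrow = L, ncol = 3)
    sel <- at$atom_name == nm
    rows <- which(sel)[!duplicated(at$residue_ordinal[sel])]
    m[at$residue_ordinal[rows], ] <- as.matrix(at[rows, c("x", "y", "z")])
    out[[nm]] <- m
  }
  out$L <- L
  out
}

# Kabsch-Sander H-bond matrix: hb[i, j] TRUE when CO(i) ... HN(j) bonded.
hbond_matrix <- function(bb, cutoff = -0.5) {
  L <- bb$L
  # Amide H of residue j from the preceding peptide plane.
  H <- matrix(NA_real_, nrow = L, ncol = 3)
  if (L >= 2) {
    prev_co <- bb$C[-L, , drop = FALSE] - bb$O[-L, , drop = FALSE]
    nrm <- sqrt(rowSums(prev_co^2))
    H[-1, ] <- bb$N[-1, , drop = FALSE] + prev_co / nrm
  }
  dmat <- function(A, B) {
    a2 <- rowSums(A^2); b2 <- rowSums(B^2)
    d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
    sqrt(pmax(d2, 0))
  }
  rON <- dmat(bb$O, bb$N)
  rCN <- dmat(bb$C, bb$N)
  rOH <- dmat(bb$O, H)
  rCH <- dmat(bb$C, H)
  E <- 0.084 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN) * 332
  E[!is.finite(E)] <- 0
  hb <- E < cutoff
  hb[is.na(hb)] <- FALSE
  # No bond to self or to the immediately following residue's own amide.
  diag(hb) <- FALSE
  if (L >= 2) hb[cbind(seq_len(L - 1), seq_len(L - 1) + 1)] <- FALSE
  hb
}

#' @rdname assign_secondary_structure
#' @param path Path to a classic DSSP output file.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) != 1) stop("not a classic DSSP file (missing residue table header)",
                             call. = FALSE)
  body <- lines[(hdr + 1):length(lines)]
  body <- body[nchar(body) >= 38]
  # Chain-break rows carry '!' in the AA column (14).
  body <- body[substr(body, 14, 14) != "!"]
  code <- substr(body, 17, 17)
  lab <- ifelse(code %in% c("G", "H", "I"), "helix",
                ifelse(code %in% c("E", "B"), "sheet", "other"))
  asa <- suppressWarnings(as.numeric(substr(body, 35, 38)))
  structure(list(label = factor(lab, levels = c("helix", "sheet", "other")),
                 asa = asa),
            class = "ss_annotation")
}
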