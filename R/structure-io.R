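#' Parse a PDB structure into an ordered heavy-atom list
#'
#' Reads ATOM records (via \pkg{bio3d}) and applies the filtering rules used
#' throughout the package: hydrogens/deuteriums, HETATM records and waters are
#' discarded; for alternate locations only the highest-occupancy altloc of
#' each atom is kept (ties broken by file order); only the first model of a
#' multi-model (NMR) file is used; multiple chains are concatenated in file
#' order with residue ordinals continuing cumulatively. Atom order always
#' follows file order.
#'
#' @param pdb_text Character vector (lines) or single string of PDB text, or
#'   a path to a PDB file.
#' @return An object of class \code{protein_structure}: a list with
#'   \code{atoms} (data.frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z}, \code{b_factor}, \code{occupancy}, \code{residue_ordinal},
#'   \code{residue_name}, \code{chain_id}, \code{atom_name}),
#'   \code{sequence} (1-letter string, \code{X} for unknown residues) and
#'   \code{identifier}.
#' @export
#' @examples
#' pdb <- generate_structure(fold_spec_library()[["alpha_bundle"]], seed = 1)
#' s <- parse_structure(pdb)
#' s
parse_structure <- function(pdb_text) {
  if (length(pdb_text) == 1 && !grepl("\n", pdb_text) && file.exists(pdb_text)) {
    identifier <- sub("\\.(pdb|ent)$", "", basename(pdb_text))
    path <- pdb_text
  } else {
    identifier <- "structure"
    if (length(pdb_text) == 1) pdb_text <- strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(pdb_text, path)
  }
  raw <- readLines(path, warn = FALSE)
  if (!any(startsWith(raw, "ATOM"))) {
    stop("no ATOM records found in PDB input", call. = FALSE)
  }
  pdb <- suppressWarnings(suppressMessages(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  ))
  at <- pdb$atom
  at$file_order <- seq_len(nrow(at))

  elem <- toupper(trimws(at$elesy))
  miss <- is.na(elem) | elem == ""
  if (any(miss)) {
    # Fall back to the first letter of the stripped atom name.
    elem[miss] <- substr(gsub("[^A-Za-z].*$", "",
                              gsub("^[0-9]+", "", trimws(at$elety[miss]))), 1, 1)
  }
  at$element <- elem

  keep <- at$type == "ATOM" &
    !(toupper(at$resid) %in% c("HOH", "WAT", "DOD")) &
    at$element %in% heavy_elements
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("no heavy-atom ATOM records after filtering", call. = FALSE)

  # Alternate locations: keep the highest-occupancy altloc per atom site,
  # ties resolved by file order.
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    site <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(site, -occ, at$file_order)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")), , drop = FALSE]
    at <- at[order(at$file_order), , drop = FALSE]
  }

  # Residue ordinals: cumulative over chains in file order.
  res_key <- paste(at$chain, at$resno, at$insert, sep = "\r")
  new_res <- c(TRUE, res_key[-1] != res_key[-length(res_key)])
  res_ordinal <- cumsum(new_res)

  res_three <- toupper(at$resid)
  res_one <- aa_three_to_one[res_three]
  unknown <- is.na(res_one)
  res_one[unknown] <- "X"
  if (any(unknown[new_res])) {
    warning(sprintf("%d residue(s) with unknown residue name; one-hot will be all-zero",
                    sum(unknown[new_res])), call. = FALSE)
  }
  sequence <- paste(res_one[new_res], collapse = "")

  atoms <- data.frame(
    element = at$element,
    x = at$x, y = at$y, z = at$z,
    b_factor = ifelse(is.na(at$b), 0, at$b),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    residue_ordinal = res_ordinal,
    residue_name = res_three,
    chain_id = ifelse(is.na(at$chain), " ", at$chain),
    atom_name = trimws(at$elety),
    stringsAsFactors = FALSE
  )
  structure(
    list(atoms = atoms, sequence = sequence, identifier = identifier),
    class = "protein_structure"
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure> %s: %d heavy atoms, %d residues\n",
              x$identifier, nrow(x$atoms), nchar(x$sequence)))
  invisible(x)
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the classic PSI-BLAST ASCII matrix dialect (header, one row per
#' sequence position with 20 log-odds score columns, footer). Only the 20
#' score columns are used; column order follows the file header and is
#' remapped to the package's canonical amino-acid order.
#'
#' @param pssm_text Lines, a single string, a file path, or \code{NULL} /
#'   \code{NA} as the missing-PSSM sentinel.
#' @param expected_length Sequence length \code{L}; parsing fails if the row
#'   count differs.
#' @return An L x 20 numeric matrix of raw log-odds scores (columns named by
#'   one-letter code in canonical order), with attribute \code{synthetic_zero
#'   = TRUE} when the sentinel was supplied (the matrix is then all zero).
#' @export
read_pssm <- function(pssm_text, expected_length) {
  if (is.null(pssm_text) || (length(pssm_text) == 1 && is.na(pssm_text))) {
    m <- matrix(0, nrow = expected_length, ncol = 20,
                dimnames = list(NULL, aa_order))
    attr(m, "synthetic_zero") <- TRUE
    return(m)
  }
  if (length(pssm_text) == 1 && !grepl("\n", pssm_text) && file.exists(pssm_text)) {
    lines <- readLines(pssm_text, warn = FALSE)
  } else if (length(pssm_text) == 1) {
    lines <- strsplit(pssm_text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- pssm_text
  }

  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  is_row <- vapply(toks, function(tk) {
    length(tk) >= 22 && grepl("^[0-9]+$", tk[1]) && grepl("^[A-Za-z]$", tk[2])
  }, logical(1))
  rows <- which(is_row)
  if (length(rows) == 0) stop("no PSSM score rows found", call. = FALSE)

  # Column order from the header line of one-letter codes above the rows.
  col_order <- aa_order
  hdr <- rev(which(!is_row & seq_along(lines) < rows[1]))
  for (h in hdr) {
    tk <- toks[[h]]
    if (length(tk) >= 20 && all(grepl("^[A-Za-z]$", tk[seq_len(20)]))) {
      col_order <- toupper(tk[seq_len(20)])
      break
    }
  }
  if (!setequal(col_order, aa_order)) {
    stop("PSSM header does not list the 20 standard amino acids", call. = FALSE)
  }

  scores <- matrix(NA_real_, nrow = length(rows), ncol = 20)
  for (i in seq_along(rows)) {
    tk <- toks[[rows[i]]]
    v <- suppressWarnings(as.numeric(tk[3:22]))
    if (anyNA(v)) {
      stop(sprintf("malformed PSSM row at line %d", rows[i]), call. = FALSE)
    }
    scores[i, ] <- v
  }
  if (nrow(scores) != expected_length) {
    stop(sprintf("PSSM has %d rows but expected sequence length is %d",
                 nrow(scores), expected_length), call. = FALSE)
  }
  colnames(scores) <- col_order
  scores <- scores[, aa_order, drop = FALSE]
  attr(scores, "synthetic_zero") <- FALSE
  scores
}

#' Write / read the intermediate point-cloud table
#'
#' Tab-separated text with one header row naming the 53 features in canonical
#' order and one row per atom, written to 6 decimal places. The header order
#' is part of the format: a permuted or truncated header is a format error.
#'
#' @param cloud A \code{point_cloud}.
#' @param path Output file path.
#' @return \code{write_point_cloud} returns \code{path} invisibly;
#'   \code{read_point_cloud} returns a \code{point_cloud}.
#' @export
write_point_cloud <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  m <- format(round(cloud$points, 6), trim = TRUE, scientific = FALSE, nsmall = 6)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(point_cloud_columns(), collapse = "\t"), con)
  writeLines(apply(m, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_point_cloud
#' @param label,source_id Optional metadata attached to the cloud on read.
#' @export
read_point_cloud <- function(path, label = NA_character_, source_id = basename(path)) {
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, point_cloud_columns())) {
    stop("point-cloud file header does not match the 53 canonical columns in order",
         call. = FALSE)
  }
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE, colClasses = "numeric"))
  if (ncol(m) != 53) stop("point-cloud file must have 53 columns", call. = FALSE)
  new_point_cloud(m, label = label, source_id = source_id)
}

#' Construct a point cloud
#'
#' @param points N x 53 numeric matrix in canonical column order.
#' @param label Fold-class label or \code{NA}.
#' @param source_id Identifier of the source structure.
#' @return An object of class \code{point_cloud}.
#' @export
new_point_cloud <- function(points, label = NA_character_, source_id = "cloud") {
  stopifnot(is.matrix(points), ncol(points) == 53)
  colnames(points) <- point_cloud_columns()
  structure(list(points = points, label = label, source_id = source_id),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %s: %d atoms x 53 features%s\n", x$source_id,
              nrow(x$points),
              if (is.na(x$label)) "" else sprintf(" [label: %s]", x$label)))
  invisible(x)
}
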