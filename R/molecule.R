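# Molecule container and geometry/Hessian file formats.

# Default per-element masses (amu): most abundant isotope, as is customary
# for vibrational sampling and dynamics.  Override per atom via the XYZ
# comment-line directive "masses: i=<amu> ..." or the masses_amu argument.
.atomic_masses_amu <- c(
  H  = 1.00782503, D = 2.01410178, T = 3.01604928,
  He = 4.00260325, Li = 7.01600344, Be = 9.01218306,
  B  = 11.00930536, C = 12.0, N = 14.00307401, O = 15.99491462,
  F  = 18.99840316, Ne = 19.99244018, Na = 22.98976928,
  Mg = 23.98504170, Al = 26.98153853, Si = 27.97692653,
  P  = 30.97376200, S = 31.97207117, Cl = 34.96885268,
  Ar = 39.96238312, K = 38.96370649, Ca = 39.96259086,
  Ti = 47.94794198, V = 50.94395704, Cr = 51.94050623,
  Mn = 54.93804391, Fe = 55.93493633, Co = 58.93319429,
  Ni = 57.93534241, Cu = 62.92959772, Zn = 63.92914201,
  Br = 78.91833760, I = 126.90447190, Hg = 201.97064340
)

#' Construct a molecule
#'
#' Atoms, masses and a Cartesian reference geometry, stored internally in
#' atomic units (coordinates in bohr, masses in electron masses).
#'
#' @param symbols character vector of element symbols.
#' @param coords n_atoms x 3 numeric matrix of Cartesian coordinates.
#' @param units_in length unit of \code{coords} (default \code{"bohr"}).
#' @param masses_amu optional numeric vector of per-atom masses in amu;
#'   defaults to the per-element table (most abundant isotope).
#' @param comment optional comment string.
#' @return an object of class \code{"molecule"} with fields
#'   \code{symbols}, \code{coords} (bohr), \code{masses} (m_e),
#'   \code{comment}.
#' @export
molecule <- function(symbols, coords, units_in = "bohr", masses_amu = NULL,
                     comment = "") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) != length(symbols)) {
    stop(vib_error("geometry_shape",
      "coordinate array must be n_atoms x 3 and match the symbol count"))
  }
  if (is.null(masses_amu)) {
    masses_amu <- .atomic_masses_amu[symbols]
    if (anyNA(masses_amu)) {
      bad <- symbols[is.na(masses_amu)]
      stop(vib_error("unknown_element",
        sprintf("no default mass for element(s): %s", paste(unique(bad), collapse = ", "))))
    }
  }
  if (length(masses_amu) != length(symbols) || any(!is.finite(masses_amu)) ||
      any(masses_amu <= 0)) {
    stop(vib_error("bad_masses", "masses must be finite, positive, one per atom"))
  }
  structure(list(
    symbols = as.character(symbols),
    coords  = unname(unit_convert(coords, units_in, "bohr")),
    masses  = unname(unit_convert(masses_amu, "amu", "me")),
    comment = comment
  ), class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %d atoms (%s)\n", length(x$symbols),
              paste(x$symbols, collapse = " ")))
  invisible(x)
}

n_atoms <- function(mol) length(mol$symbols)

#' Read an XYZ geometry file
#'
#' Standard XYZ: atom count line, comment line, then one
#' \code{element x y z} line per atom, coordinates in Angstrom by default.
#' Per-atom mass overrides may be given on the comment line as
#' \code{masses: 1=2.014 3=13.003} (1-based atom index = mass in amu).
#'
#' @param path file path.
#' @param units_in length unit of the file (default Angstrom).
#' @return a \code{\link{molecule}}.
#' @export
read_xyz <- function(path, units_in = "angstrom") {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop(vib_error("xyz_count", "empty XYZ file"))
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) {
    stop(vib_error("xyz_count", sprintf("malformed atom count line: '%s'", lines[1])))
  }
  comment <- if (length(lines) >= 2L) lines[2] else ""
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) {
    stop(vib_error("xyz_count",
      sprintf("XYZ declares %d atoms but lists %d", n, length(body))))
  }
  body <- body[seq_len(n)]
  toks <- strsplit(trimws(body), "\\s+")
  symbols <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    if (length(tk) < 4L) {
      stop(vib_error("xyz_coordinate", sprintf("atom line %d has too few fields", i)))
    }
    symbols[i] <- tk[1]
    xyz <- suppressWarnings(as.numeric(tk[2:4]))
    if (anyNA(xyz)) {
      stop(vib_error("xyz_coordinate",
        sprintf("cannot parse coordinates on atom line %d", i)))
    }
    coords[i, ] <- xyz
  }
  masses <- .atomic_masses_amu[symbols]
  if (anyNA(masses)) {
    bad <- symbols[is.na(masses)]
    stop(vib_error("unknown_element",
      sprintf("unknown element symbol(s): %s", paste(unique(bad), collapse = ", "))))
  }
  masses <- unname(masses)
  # comment-line isotope directives
  m <- regmatches(comment, regexpr("masses:\\s*([0-9]+=[0-9.eE+-]+\\s*)+", comment))
  if (length(m) == 1L && nzchar(m)) {
    pairs <- regmatches(m, gregexpr("[0-9]+=[0-9.eE+-]+", m))[[1]]
    for (p in pairs) {
      kv <- strsplit(p, "=", fixed = TRUE)[[1]]
      idx <- as.integer(kv[1])
      if (idx >= 1L && idx <= n) masses[idx] <- as.numeric(kv[2])
    }
  }
  molecule(symbols, coords, units_in = units_in, masses_amu = masses,
           comment = comment)
}

#' Write an XYZ geometry file
#'
#' @param mol a \code{\link{molecule}}.
#' @param path output path.
#' @param units_out length unit for the file (default Angstrom).
#' @export
write_xyz <- function(mol, path, units_out = "angstrom") {
  xyz <- unit_convert(mol$coords, "bohr", units_out)
  lines <- c(
    sprintf("%d", n_atoms(mol)),
    mol$comment,
    sprintf("%-3s %22.15e %22.15e %22.15e",
            mol$symbols, xyz[, 1], xyz[, 2], xyz[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text Cartesian Hessian
#'
#' Format: first line is the atom count N, followed by 3N lines of 3N
#' whitespace-separated reals in E_h/bohr^2, row-major.  The matrix must be
#' symmetric within tolerance and is symmetrized on read by
#' \eqn{(H + H^T)/2}.
#'
#' @param path file path.
#' @param tol asymmetry tolerance relative to the largest element.
#' @return 3N x 3N symmetric numeric matrix (E_h/bohr^2).
#' @export
read_hessian <- function(path, tol = 1e-8) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) {
    stop(vib_error("hessian_format", "malformed atom count line in Hessian file"))
  }
  dim3 <- 3L * n
  if (length(lines) < 1L + dim3) {
    stop(vib_error("hessian_format",
      sprintf("expected %d Hessian rows, found %d", dim3, length(lines) - 1L)))
  }
  vals <- lapply(lines[2:(1 + dim3)], function(l)
    suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (any(vapply(vals, length, 1L) != dim3) || anyNA(unlist(vals))) {
    stop(vib_error("hessian_format", "Hessian rows must hold 3N parseable reals"))
  }
  H <- do.call(rbind, vals)
  asym <- max(abs(H - t(H)))
  if (asym > tol * max(1, max(abs(H)))) {
    stop(vib_error("hessian_asymmetric",
      sprintf("Hessian asymmetry %.3e exceeds tolerance", asym)))
  }
  (H + t(H)) / 2
}

#' Write a plain-text Cartesian Hessian
#'
#' @param H 3N x 3N matrix (E_h/bohr^2).
#' @param path output path.
#' @export
write_hessian <- function(H, path) {
  n <- nrow(H) / 3L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d", n), con)
  apply(H, 1, function(r) writeLines(paste(sprintf("%22.15e", r), collapse = " "), con))
  invisible(path)
}

#' Read a Molden vibrational-frequency file
#'
#' Parses the \code{[FR-COORD]} (geometry, bohr), \code{[FREQ]}
#' (frequencies, cm^-1) and \code{[FR-NORM-COORD]} (Cartesian displacement
#' vectors) sections.  Negative frequency entries are parsed and flagged
#' imaginary rather than rejected.  Displacements are returned as read;
#' re-orthonormalization happens downstream.
#'
#' @param path file path.
#' @return list with \code{molecule}, \code{freq_cm} (signed, cm^-1),
#'   \code{imaginary} (logical), \code{displacements} (3N x n_freq matrix).
#' @export
read_molden_freq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tags <- grep("^\\s*\\[", lines)
  find_section <- function(name) {
    hit <- grep(sprintf("^\\s*\\[%s\\]", name), lines, ignore.case = TRUE)
    if (length(hit) == 0L) {
      stop(vib_error("molden_missing_section",
        sprintf("Molden file lacks required section [%s]", name)))
    }
    start <- hit[1] + 1L
    nxt <- tags[tags > hit[1]]
    end <- if (length(nxt)) nxt[1] - 1L else length(lines)
    if (end < start) return(character(0))
    out <- lines[start:end]
    out[nzchar(trimws(out))]
  }
  geo <- find_section("FR-COORD")
  toks <- strsplit(trimws(geo), "\\s+")
  symbols <- vapply(toks, `[`, "", 1)
  coords <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  freq <- as.numeric(trimws(find_section("FREQ")))
  disp_lines <- find_section("FR-NORM-COORD")
  vib_idx <- grep("vibration", disp_lines, ignore.case = TRUE)
  if (length(vib_idx) != length(freq)) {
    stop(vib_error("molden_format",
      sprintf("found %d displacement blocks for %d frequencies",
              length(vib_idx), length(freq))))
  }
  nats <- length(symbols)
  disp <- matrix(0, 3 * nats, length(freq))
  bounds <- c(vib_idx, length(disp_lines) + 1L)
  for (k in seq_along(vib_idx)) {
    blk <- disp_lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    v <- as.numeric(unlist(strsplit(trimws(blk), "\\s+")))
    if (length(v) != 3 * nats) {
      stop(vib_error("molden_format",
        sprintf("displacement block %d holds %d values, expected %d",
                k, length(v), 3 * nats)))
    }
    disp[, k] <- v
  }
  list(
    molecule = molecule(symbols, coords, units_in = "bohr"),
    freq_cm = freq,
    imaginary = freq < 0,
    displacements = disp
  )
}

#' Write a Molden vibrational-frequency file
#'
#' Counterpart of \code{\link{read_molden_freq}}; used to exchange normal
#' modes and to build test fixtures.
#'
#' @param path output path.
#' @param mol a \code{\link{molecule}}.
#' @param freq_cm signed frequencies in cm^-1 (negative = imaginary).
#' @param displacements 3N x n_freq Cartesian displacement matrix.
#' @export
write_molden_freq <- function(path, mol, freq_cm, displacements) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("[Molden Format]", con)
  writeLines("[FREQ]", con)
  writeLines(sprintf("%18.10f", freq_cm), con)
  writeLines("[FR-COORD]", con)
  writeLines(sprintf("%-3s %20.12f %20.12f %20.12f", mol$symbols,
                     mol$coords[, 1], mol$coords[, 2], mol$coords[, 3]), con)
  writeLines("[FR-NORM-COORD]", con)
  for (k in seq_along(freq_cm)) {
    writeLines(sprintf("vibration %d", k), con)
    d <- matrix(displacements[, k], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%20.12f %20.12f %20.12f", d[, 1], d[, 2], d[, 3]), con)
  }
  invisible(path)
}

#' Read/write a two-column (x, y) text table
#'
#' Used for actinic-flux and cross-section curves.  Lines starting with
#' \code{#} are comments.
#'
#' @param path file path.
#' @return data.frame with columns \code{x}, \code{y}.
#' @export
read_xy_table <- function(path) {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("x", "y"),
                          colClasses = "numeric")
  if (nrow(df) < 1L) stop(vib_error("table_empty", "empty two-column table"))
  df
}

#' @rdname read_xy_table
#' @param df data.frame with two numeric columns.
#' @param header optional comment header (written after \code{#}).
#' @export
write_xy_table <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  writeLines(sprintf("%22.15e %22.15e", df[[1]], df[[2]]), con)
  invisible(path)
}
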