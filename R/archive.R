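# Persistent archives.  Ensembles, mode sets and trajectories are stored
# in a self-describing JSON container (schema-versioned, 17-significant-
# digit numbers so doubles round-trip losslessly).

.ARCHIVE_SCHEMA <- 1L

.mol_to_list <- function(mol) {
  list(symbols = mol$symbols,
       coords_bohr = unname(apply(mol$coords, 1, as.numeric, simplify = FALSE)),
       masses_me = as.numeric(mol$masses),
       comment = mol$comment)
}

.mol_from_list <- function(l) {
  mol <- molecule(unlist(l$symbols),
                  do.call(rbind, lapply(l$coords_bohr, as.numeric)),
                  units_in = "bohr",
                  masses_amu = unit_convert(as.numeric(l$masses_me), "me", "amu"))
  mol$comment <- if (is.null(l$comment)) "" else l$comment
  mol
}

.modes_to_list <- function(modes) {
  list(molecule = .mol_to_list(modes$molecule),
       omega = as.numeric(modes$omega),
       freq_cm = as.numeric(modes$freq_cm),
       L = unname(apply(modes$L, 2, as.numeric, simplify = FALSE)),
       imaginary = as.logical(modes$imaginary),
       n_external = modes$n_external)
}

.modes_from_list <- function(l) {
  structure(list(
    molecule = .mol_from_list(l$molecule),
    omega = as.numeric(l$omega),
    freq_cm = as.numeric(l$freq_cm),
    L = do.call(cbind, lapply(l$L, as.numeric)),
    imaginary = as.logical(l$imaginary),
    n_external = as.integer(l$n_external)
  ), class = "normal_modes")
}

.write_archive <- function(obj, path, kind) {
  obj$schema_version <- .ARCHIVE_SCHEMA
  obj$kind <- kind
  # I(17) significant digits: doubles survive the text round trip bitwise
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

.read_archive <- function(path, kind) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  ver <- obj$schema_version
  if (is.null(ver) || as.integer(ver) != .ARCHIVE_SCHEMA) {
    stop(vib_error("archive_version",
      sprintf("archive schema version %s, this build reads version %d",
              if (is.null(ver)) "<missing>" else ver, .ARCHIVE_SCHEMA)))
  }
  if (!identical(obj$kind, kind)) {
    stop(vib_error("archive_kind",
      sprintf("archive holds '%s', expected '%s'", obj$kind, kind)))
  }
  obj
}

#' Write / read an initial-condition ensemble archive
#'
#' Lossless JSON round trip of every sample field (normal-mode and
#' Cartesian views, per-mode energies, phases or Wigner acceptance
#' probabilities, method tag, temperature, RNG seed) plus the generating
#' mode set.  The archive is schema-versioned; reading an archive written
#' by a different schema is an error, as is a corrupted sample record
#' (reported by index).
#'
#' @param ens an \code{ic_ensemble}.
#' @param path archive path.
#' @export
write_ensemble <- function(ens, path) {
  recs <- lapply(seq_len(ens$n), function(i) {
    r <- list(Q = as.numeric(ens$Q[i, ]), P = as.numeric(ens$P[i, ]),
              x = as.numeric(ens$x[i, ]), p = as.numeric(ens$p[i, ]),
              E_modes = as.numeric(ens$E_modes[i, ]),
              scale = ens$scale[i], draw_index = i)
    if (!is.null(ens$phase)) r$phase <- as.numeric(ens$phase[i, ])
    if (!is.null(ens$W)) r$W <- as.numeric(ens$W[i, ])
    r
  })
  .write_archive(list(
    method = ens$method, temperature = ens$temperature,
    seed = ens$seed, scheme = ens$scheme, n = ens$n,
    modes = .modes_to_list(ens$modes), samples = recs
  ), path, "ic_ensemble")
}

#' @rdname write_ensemble
#' @return \code{read_ensemble}: the reconstructed \code{ic_ensemble}.
#' @export
read_ensemble <- function(path) {
  obj <- .read_archive(path, "ic_ensemble")
  modes <- .modes_from_list(obj$modes)
  k <- n_modes(modes); d3 <- nrow(modes$L)
  n <- as.integer(obj$n)
  if (length(obj$samples) != n) {
    stop(vib_error("archive_corrupt",
      sprintf("archive declares %d samples but holds %d", n, length(obj$samples))))
  }
  grab <- function(i, field, len) {
    v <- obj$samples[[i]][[field]]
    if (is.null(v) || length(v) != len || anyNA(vv <- as.numeric(v))) {
      stop(vib_error("archive_corrupt",
        sprintf("corrupted sample record %d (field '%s')", i, field)))
    }
    vv
  }
  if (n == 0L) {
    return(.new_ensemble(modes, matrix(0, 0, k), matrix(0, 0, k),
                         matrix(0, 0, d3), matrix(0, 0, d3),
                         E_modes = matrix(0, 0, k), phase = NULL, W = NULL,
                         method = obj$method, temperature = obj$temperature,
                         seed = obj$seed, scheme = obj$scheme,
                         scale = numeric(0)))
  }
  pull <- function(field, len) {
    t(matrix(vapply(seq_len(n), grab, numeric(len), field = field, len = len),
             nrow = len))
  }
  Q <- pull("Q", k)
  P <- pull("P", k)
  x <- pull("x", d3)
  p <- pull("p", d3)
  E <- pull("E_modes", k)
  phase <- if (!is.null(obj$samples[[1]]$phase)) pull("phase", k) else NULL
  W <- if (!is.null(obj$samples[[1]]$W)) pull("W", k) else NULL
  scale <- vapply(seq_len(n), grab, numeric(1), field = "scale", len = 1L)
  seed <- obj$seed
  .new_ensemble(modes, Q, P, x, p, E_modes = E, phase = phase, W = W,
                method = obj$method, temperature = as.numeric(obj$temperature),
                seed = if (is.null(seed) || is.na(suppressWarnings(as.integer(seed))))
                  NULL else as.integer(seed),
                scheme = if (is.null(obj$scheme) || is.na(obj$scheme)) NULL else obj$scheme,
                scale = scale)
}

#' Write / read a normal-mode archive
#'
#' @param modes a \code{\link{compute_modes}} result.
#' @param path archive path.
#' @export
write_modes <- function(modes, path) {
  .write_archive(.modes_to_list(modes), path, "normal_modes")
}

#' @rdname write_modes
#' @export
read_modes <- function(path) {
  obj <- .read_archive(path, "normal_modes")
  .modes_from_list(obj)
}

#' Write / read a trajectory archive
#'
#' Stores the recorded stride of a surface-hopping trajectory: times,
#' normal-coordinate phase space, active states, complex electronic
#' coefficients, total energies, hop record, seed, and termination reason.
#'
#' @param traj a \code{\link{run_trajectory}} result.
#' @param path archive path.
#' @export
write_trajectory <- function(traj, path) {
  .write_archive(list(
    time = as.numeric(traj$time),
    Q = unname(apply(traj$Q, 1, as.numeric, simplify = FALSE)),
    P = unname(apply(traj$P, 1, as.numeric, simplify = FALSE)),
    active = as.integer(traj$active),
    c_re = unname(apply(Re(traj$coeff), 1, as.numeric, simplify = FALSE)),
    c_im = unname(apply(Im(traj$coeff), 1, as.numeric, simplify = FALSE)),
    energy = as.numeric(traj$energy),
    hops = traj$hops, n_frustrated = traj$n_frustrated,
    seed = traj$seed, dt = traj$dt, tdc = traj$tdc,
    termination = traj$termination
  ), path, "trajectory")
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  obj <- .read_archive(path, "trajectory")
  out <- list(
    time = as.numeric(obj$time),
    Q = do.call(rbind, lapply(obj$Q, as.numeric)),
    P = do.call(rbind, lapply(obj$P, as.numeric)),
    active = as.integer(obj$active),
    coeff = do.call(rbind, lapply(obj$c_re, as.numeric)) +
      1i * do.call(rbind, lapply(obj$c_im, as.numeric)),
    energy = as.numeric(obj$energy),
    hops = obj$hops, n_frustrated = as.integer(obj$n_frustrated),
    seed = obj$seed, dt = as.numeric(obj$dt), tdc = obj$tdc,
    termination = obj$termination
  )
  class(out) <- "sh_trajectory"
  out
}
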