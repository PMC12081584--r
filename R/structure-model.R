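#' Atomic structure container
#'
#' A `structure_model` is a plain data frame with one row per atom and columns
#' `atom_id`, `name`, `residue_name`, `residue_id`, `chain_id`, `x`, `y`, `z`
#' (angstrom), `radius` (angstrom, `NA` when unknown) and `charge` (elementary
#' charges, `NA` when unknown). It is the common currency of the I/O,
#' geometry and energetics functions.
#'
#' @param atom_id integer atom serial numbers, unique within a model.
#' @param name atom names (e.g. `"CA"`).
#' @param residue_name residue names (e.g. `"GLN"`).
#' @param residue_id integer residue numbers, taken verbatim from input files.
#' @param chain_id chain identifiers.
#' @param xyz numeric matrix with one row per atom and columns x, y, z (angstrom).
#' @param radius per-atom radii in angstrom, or `NA`.
#' @param charge per-atom partial charges in elementary charges, or `NA`.
#' @return A data frame of class `structure_model`.
#' @export
structure_model <- function(atom_id, name, residue_name, residue_id, chain_id,
                            xyz, radius = NA_real_, charge = NA_real_) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("xyz must have three columns")
  n <- nrow(xyz)
  m <- data.frame(
    atom_id = as.integer(atom_id),
    name = as.character(name),
    residue_name = as.character(residue_name),
    residue_id = as.integer(residue_id),
    chain_id = as.character(chain_id),
    x = as.numeric(xyz[, 1]), y = as.numeric(xyz[, 2]), z = as.numeric(xyz[, 3]),
    radius = rep_len(as.numeric(radius), n),
    charge = rep_len(as.numeric(charge), n),
    stringsAsFactors = FALSE
  )
  class(m) <- c("structure_model", "data.frame")
  validate_structure_model(m)
}

validate_structure_model <- function(m) {
  if (!all(is.finite(m$x) & is.finite(m$y) & is.finite(m$z)))
    stop("all coordinates must be finite")
  if (anyDuplicated(m$atom_id))
    stop("atom_ids must be unique within a model")
  r <- m$radius[!is.na(m$radius)]
  if (any(r < 0)) stop("radii must be >= 0")
  m
}

#' Extract the coordinate matrix of a structure or of selected atoms
#'
#' @param model a `structure_model`.
#' @param selection optional atom selection: integer indices, a logical vector,
#'   or a character vector of atom names (e.g. `"CA"`).
#' @return Numeric n x 3 matrix of coordinates (angstrom).
#' @export
coords <- function(model, selection = NULL) {
  idx <- resolve_selection(model, selection)
  cbind(x = model$x[idx], y = model$y[idx], z = model$z[idx])
}

resolve_selection <- function(model, selection) {
  if (is.null(selection)) return(seq_len(nrow(model)))
  if (is.character(selection)) {
    idx <- which(model$name %in% selection)
  } else if (is.logical(selection)) {
    if (length(selection) != nrow(model)) stop("logical selection length mismatch")
    idx <- which(selection)
  } else {
    idx <- as.integer(selection)
    if (any(idx < 1L | idx > nrow(model))) stop("selection index out of range")
  }
  if (length(idx) == 0L) stop("selection matches no atoms")
  idx
}

#' Ordered multi-frame coordinate trajectory
#'
#' Couples a list of coordinate frames to a fixed atom roster (a
#' [structure_model()]) and strictly increasing frame times in nanoseconds.
#'
#' @param frames list of n_atoms x 3 coordinate matrices (angstrom).
#' @param times numeric vector of frame times in ns, strictly increasing.
#' @param roster the reference [structure_model()]; every frame must carry the
#'   same number of atoms.
#' @return An object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(frames, times, roster) {
  if (!inherits(roster, "structure_model")) stop("roster must be a structure_model")
  if (length(frames) != length(times)) stop("frames and times lengths differ")
  if (length(times) >= 2 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  n <- nrow(roster)
  for (i in seq_along(frames)) {
    frames[[i]] <- as.matrix(frames[[i]])
    if (nrow(frames[[i]]) != n || ncol(frames[[i]]) != 3L)
      stop(sprintf("frame %d does not match the roster atom count (%d)", i, n))
  }
  structure(list(frames = frames, times = as.numeric(times), roster = roster),
            class = "trajectory_ensemble")
}

#' @export
length.trajectory_ensemble <- function(x) length(x$frames)

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("trajectory_ensemble: %d frames x %d atoms, t = [%g, %g] ns\n",
              length(x$frames), nrow(x$roster),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA))
  invisible(x)
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d chains, %d residues\n",
              nrow(x), length(unique(x$chain_id)),
              length(unique(paste(x$chain_id, x$residue_id)))))
  NextMethod()
}

# Evaluate expr under a fixed RNG seed without touching the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
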