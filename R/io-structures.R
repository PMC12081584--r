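#' Read a PDB file into one or more structure models
#'
#' Fixed-column ATOM/HETATM parsing (delegated to \pkg{bio3d} after a
#' validation pre-scan). Multi-model files (MODEL/ENDMDL blocks) yield one
#' model per block; atom order and residue numbering are taken verbatim.
#'
#' @param path path to a PDB file.
#' @param multi if `TRUE` (default) a multi-model file returns a list of
#'   [structure_model()]s; a single-model file always returns one model.
#' @return A `structure_model`, or a list of them for multi-model input.
#' @export
read_pdb <- function(path, multi = TRUE) {
  lines <- read_atom_lines(path, format = "pdb")
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = multi, verbose = FALSE))
  roster <- pdb_atom_to_model(pdb$atom)
  nmod <- if (multi && !is.null(pdb$xyz) && is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (!multi || nmod <= 1L) return(roster)
  lapply(seq_len(nmod), function(i) {
    m <- roster
    xyz <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
    m$x <- xyz[, 1]; m$y <- xyz[, 2]; m$z <- xyz[, 3]
    m
  })
}

#' Read a PQR file (whitespace-delimited, per-atom charge and radius)
#'
#' @param path path to a PQR file.
#' @return A [structure_model()] with `charge` and `radius` populated.
#' @export
read_pqr <- function(path) {
  read_atom_lines(path, format = "pqr")
  pqr <- suppressWarnings(bio3d::read.pqr(path, verbose = FALSE))
  m <- pdb_atom_to_model(pqr$atom)
  # bio3d stores PQR charge in the occupancy slot and radius in the b slot
  m$charge <- as.numeric(pqr$atom$o)
  m$radius <- as.numeric(pqr$atom$b)
  if (any(is.na(m$charge)) || any(is.na(m$radius)))
    stop("PQR record missing charge or radius column")
  validate_structure_model(m)
}

pdb_atom_to_model <- function(atom) {
  chain <- atom$chain
  chain[is.na(chain)] <- " "
  structure_model(
    atom_id = atom$eleno, name = atom$elety, residue_name = atom$resid,
    residue_id = atom$resno, chain_id = chain,
    xyz = cbind(atom$x, atom$y, atom$z)
  )
}

# Pre-scan ATOM/HETATM records so malformed lines fail with a line number.
read_atom_lines <- function(path, format = c("pdb", "pqr")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  if (!any(rec)) stop(sprintf("no ATOM/HETATM records in %s", path))
  for (i in which(rec)) {
    ln <- lines[i]
    if (format == "pdb") {
      ok <- nchar(ln) >= 54 &&
        !anyNA(suppressWarnings(as.numeric(c(
          substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)))))
    } else {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      ok <- length(f) >= 10 &&
        !anyNA(suppressWarnings(as.numeric(f[(length(f) - 4):length(f)])))
    }
    if (!ok) stop(sprintf("malformed %s record at line %d of %s",
                          toupper(format), i, path))
  }
  lines[rec]
}

#' Write one or several structure models as a (multi-model) PDB file
#'
#' @param model a [structure_model()] or a list of them (written as
#'   MODEL/ENDMDL blocks).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  models <- if (inherits(model, "structure_model")) list(model) else model
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1L
  for (i in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(format_pdb_records(models[[i]]), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

format_pdb_records <- function(m) {
  nm <- ifelse(nchar(m$name) < 4, paste0(" ", m$name), m$name)
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          m$atom_id %% 100000L, nm, m$residue_name,
          substr(m$chain_id, 1, 1), m$residue_id %% 10000L,
          m$x, m$y, m$z, 1.00, 0.00)
}

#' Write a structure model in PQR format (charge and radius columns)
#'
#' @param model a [structure_model()] with `charge` and `radius` populated.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(model, path) {
  if (any(is.na(model$charge)) || any(is.na(model$radius)))
    stop("model must have charge and radius on every atom to write PQR")
  nm <- ifelse(nchar(model$name) < 4, paste0(" ", model$name), model$name)
  lines <- sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f %7.4f %6.4f",
                   model$atom_id %% 100000L, nm, model$residue_name,
                   substr(model$chain_id, 1, 1), model$residue_id %% 10000L,
                   model$x, model$y, model$z, model$charge, model$radius)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a multi-frame XYZ trajectory against a fixed atom roster
#'
#' Plain XYZ dialect: each frame is an atom count line, a comment line
#' (`t= <ns>` is recognised for frame times), then `name x y z` records.
#'
#' @param path path to the XYZ file.
#' @param roster the [structure_model()] the frames belong to.
#' @param times optional frame times (ns); overrides times parsed from
#'   comment lines. Defaults to 0, 1, 2, ... when absent.
#' @return A [trajectory_ensemble()].
#' @export
read_xyz_traj <- function(path, roster, times = NULL) {
  lines <- readLines(path, warn = FALSE)
  n <- nrow(roster)
  frames <- list()
  parsed_times <- numeric()
  i <- 1L
  k <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    k <- k + 1L
    cnt <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(cnt) || cnt != n)
      stop(sprintf("frame %d: atom count %s does not match roster (%d)",
                   k, trimws(lines[i]), n))
    comment <- if (i + 1L <= length(lines)) lines[i + 1L] else ""
    tm <- regmatches(comment, regexec("t=\\s*([-0-9.eE+]+)", comment))[[1]]
    parsed_times[k] <- if (length(tm) == 2) as.numeric(tm[2]) else k - 1
    if (i + 1L + n > length(lines))
      stop(sprintf("frame %d truncated: expected %d atom records", k, n))
    rec <- lines[(i + 2L):(i + 1L + n)]
    fields <- strsplit(trimws(rec), "\\s+")
    if (any(lengths(fields) < 4))
      stop(sprintf("frame %d: malformed atom record", k))
    xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    if (anyNA(xyz)) stop(sprintf("frame %d: non-numeric coordinate", k))
    frames[[k]] <- xyz
    i <- i + 2L + n
  }
  if (k == 0L) stop("no frames found")
  trajectory_ensemble(frames, if (is.null(times)) parsed_times else times, roster)
}

#' Write a trajectory ensemble as a multi-frame XYZ file
#'
#' @param traj a [trajectory_ensemble()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz_traj <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(traj$roster)
  for (i in seq_along(traj$frames)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("frame %d t= %.6f ns", i, traj$times[i]), con)
    f <- traj$frames[[i]]
    writeLines(sprintf("%-4s %12.6f %12.6f %12.6f",
                       traj$roster$name, f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}
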