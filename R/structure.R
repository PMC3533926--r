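#' Molecular structure container
#'
#' A `tec_structure` holds an ordered atom table (one coordinate set) for a
#' ternary elongation complex or any other molecule.  Atoms are addressed by
#' a `chain:resid:name` key, e.g. `"A:1079:NZ"` or `"M:1:MG"`; insertion
#' codes, when present, are appended to the residue number (`"A:100A:CA"`).
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`,
#'   `chain`, `resid`, `inscode`, `element`, `het` (logical HETATM flag),
#'   `x`, `y`, `z`.
#' @param title optional title string.
#' @param box optional length-3 numeric box vector (Angstrom).
#' @return An object of class `tec_structure`.
#' @export
tec_structure <- function(atoms, title = "", box = NULL) {
  need <- c("serial", "name", "resname", "chain", "resid", "inscode",
            "element", "het", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("a structure must contain at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("all atom coordinates must be finite")
  atoms$name <- normalize_atom_name(atoms$name)
  keys <- atom_keys_from_table(atoms)
  dup <- duplicated(keys)
  if (any(dup))
    stop("duplicate atom keys after altloc resolution: ",
         paste(unique(keys[dup]), collapse = ", "))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = title, box = box),
            class = "tec_structure")
}

# Prime-character normalisation: "C3*" and "C3'" address the same atom.
normalize_atom_name <- function(x) gsub("*", "'", x, fixed = TRUE)

atom_keys_from_table <- function(atoms) {
  paste(atoms$chain,
        paste0(atoms$resid, ifelse(is.na(atoms$inscode), "", atoms$inscode)),
        atoms$name, sep = ":")
}

#' Atom keys of a structure
#'
#' @param structure a [tec_structure()].
#' @return Character vector of `chain:resid:name` keys in atom order.
#' @export
atom_keys <- function(structure) {
  stopifnot(inherits(structure, "tec_structure"))
  atom_keys_from_table(structure$atoms)
}

#' Resolve atom keys to row indices
#'
#' @param structure a [tec_structure()].
#' @param keys character vector of `chain:resid:name` keys (prime and star
#'   spellings of sugar atoms are equivalent).
#' @return Integer vector of atom indices.
#' @export
atom_index <- function(structure, keys) {
  keys <- normalize_atom_name(keys)
  idx <- match(keys, atom_keys(structure))
  if (anyNA(idx))
    stop("atom key(s) not found in structure: ",
         paste(keys[is.na(idx)], collapse = ", "))
  idx
}

#' Coordinates of a structure
#'
#' @param structure a [tec_structure()].
#' @return Numeric n x 3 matrix of coordinates (Angstrom).
#' @export
coords <- function(structure) {
  stopifnot(inherits(structure, "tec_structure"))
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#'
#' @param structure a [tec_structure()].
#' @param xyz n x 3 coordinate matrix.
#' @return The structure with coordinates replaced.
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(inherits(structure, "tec_structure"))
  xyz <- as.matrix(xyz)
  if (!all(dim(xyz) == c(nrow(structure$atoms), 3L)))
    stop("coordinate matrix must be n_atoms x 3")
  structure$atoms[, c("x", "y", "z")] <- xyz
  structure
}

#' Number of atoms
#' @param structure a [tec_structure()].
#' @return Integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' @export
print.tec_structure <- function(x, ...) {
  cat(sprintf("<tec_structure> %d atoms, %d chains%s\n",
              n_atoms(x), length(unique(x$atoms$chain)),
              if (nzchar(x$title)) paste0(": ", x$title) else ""))
  invisible(x)
}

water_resnames <- function() c("HOH", "WAT", "TIP3", "SOL")

is_water_atom <- function(atoms) toupper(atoms$resname) %in% water_resnames()

# Residue-level table (one row per residue, in atom order of first
# occurrence).  Used by dihedral/secondary-structure code.
residue_table <- function(structure) {
  a <- structure$atoms
  rid <- paste0(a$chain, ":", a$resid,
                ifelse(is.na(a$inscode), "", a$inscode))
  first <- !duplicated(rid)
  data.frame(chain = a$chain[first], resid = a$resid[first],
             inscode = a$inscode[first], resname = a$resname[first],
             key = rid[first], stringsAsFactors = FALSE)
}

#' Trajectory container
#'
#' A `tec_trajectory` is an ordered list of coordinate frames sharing one
#' topology.  Frame 1 is the reference frame used by all
#' relative-to-initial-structure metrics.
#'
#' @param topology a [tec_structure()] supplying atom addressing.
#' @param frames list of n_atoms x 3 coordinate matrices, in time order.
#' @param frame_interval time between consecutive frames, ps. The default
#'   20 ps matches the sampling stride used throughout the trajectory
#'   analyses.
#' @return An object of class `tec_trajectory`.
#' @export
tec_trajectory <- function(topology, frames, frame_interval = 20) {
  stopifnot(inherits(topology, "tec_structure"))
  if (!length(frames)) stop("a trajectory needs at least one frame")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be a positive time in ps")
  na <- n_atoms(topology)
  for (k in seq_along(frames)) {
    frames[[k]] <- as.matrix(frames[[k]])
    if (!all(dim(frames[[k]]) == c(na, 3L)))
      stop(sprintf("frame %d has %d atoms; topology has %d", k,
                   nrow(frames[[k]]), na))
  }
  structure(list(topology = topology, frames = frames,
                 frame_interval = frame_interval),
            class = "tec_trajectory")
}

#' Number of frames in a trajectory
#' @param traj a [tec_trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Frame times
#' @param traj a [tec_trajectory()].
#' @return Numeric vector of frame times in ps (frame 1 is t = 0).
#' @export
frame_times <- function(traj) (seq_len(n_frames(traj)) - 1L) * traj$frame_interval

#' @export
print.tec_trajectory <- function(x, ...) {
  cat(sprintf("<tec_trajectory> %d frames x %d atoms, %g ps/frame (%g ns)\n",
              n_frames(x), n_atoms(x$topology), x$frame_interval,
              (n_frames(x) - 1L) * x$frame_interval / 1000))
  invisible(x)
}

# Time-series result shared by all per-frame monitors.
series_result <- function(times, values, label) {
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(data.frame(time_ps = times, value = values, label = label,
                       stringsAsFactors = FALSE),
            class = c("tec_series", "data.frame"))
}

#' Write a time series as tidy delimited text
#'
#' @param series a series data.frame with `time_ps`, `value`, `label`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_series <- function(series, path) {
  utils::write.table(series, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Frames sampled by a stride (in frames), always including frame 1.
stride_frames <- function(traj, stride = 1L) {
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1 frame")
  seq(1L, n_frames(traj), by = stride)
}
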