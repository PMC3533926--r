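#' Read a molecular structure
#'
#' Reads a PDB file (fixed-column, via bio3d) or a plain XYZ file into a
#' [tec_structure()].  All ATOM and HETATM records are retained, including
#' waters and ions.  Alternate locations are resolved to the highest
#' occupancy (ties broken alphabetically by altloc id) and prime characters
#' in atom names are normalised (`C3*` becomes `C3'`).
#'
#' @param path input file path.
#' @param format `"pdb"` or `"xyz"`; defaults from the file extension.
#' @return A [tec_structure()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         pdb = read_structure_pdb(path),
         xyz = read_structure_xyz(path),
         stop("unsupported format: ", format))
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext == "xyz") return("xyz")
  stop("unsupported format for file: ", path,
       " (expected .pdb/.ent or .xyz, or pass format=)")
}

# Pre-scan for malformed ATOM/HETATM records so that errors carry a line
# number; the actual parse is delegated to bio3d.
validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54L)
      stop(sprintf("malformed PDB record at line %d: too short", i))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop(sprintf("malformed PDB record at line %d: bad coordinates", i))
  }
  invisible(lines)
}

read_structure_pdb <- function(path) {
  validate_pdb_lines(path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("PDB parse error in ", path, ": ",
                             conditionMessage(e)))
  a <- pdb$atom
  atoms <- data.frame(serial = as.integer(a$eleno),
                      name = normalize_atom_name(as.character(a$elety)),
                      resname = as.character(a$resid),
                      chain = ifelse(is.na(a$chain), " ", as.character(a$chain)),
                      resid = as.integer(a$resno),
                      inscode = ifelse(is.na(a$insert), "", as.character(a$insert)),
                      element = ifelse(is.na(a$elesy), "", as.character(a$elesy)),
                      het = a$type == "HETATM",
                      x = a$x, y = a$y, z = a$z,
                      occupancy = ifelse(is.na(a$o), 1, a$o),
                      altloc = ifelse(is.na(a$alt), "", as.character(a$alt)),
                      stringsAsFactors = FALSE)
  atoms <- resolve_altlocs(atoms)
  atoms$occupancy <- NULL
  atoms$altloc <- NULL
  tec_structure(atoms, title = basename(path))
}

# Keep, per (chain, resid, inscode, name), the altloc with the highest
# occupancy; ties broken alphabetically by altloc id.
resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resid, atoms$inscode, atoms$name, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(match(key, unique(key)), -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, ]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resid, atoms$inscode,
                                   atoms$name, sep = "\r")), ]
  atoms[order(atoms$serial), ]
}

# Plain XYZ dialect: count line / comment (optionally "t= <ps>") / one
# "element x y z" line per atom.  Atom metadata beyond the element is not
# representable, so resid/chain default to a single pseudo-residue.
read_structure_xyz <- function(path) {
  fr <- read_xyz_frames(path)
  f1 <- fr$frames[[1L]]
  n <- nrow(f1)
  atoms <- data.frame(serial = seq_len(n), name = fr$elements,
                      resname = "UNK", chain = "X", resid = 1L,
                      inscode = "", element = fr$elements, het = FALSE,
                      x = f1[, 1L], y = f1[, 2L], z = f1[, 3L],
                      stringsAsFactors = FALSE)
  # element repeated as name would collide; disambiguate with the serial
  atoms$name <- paste0(atoms$name, atoms$serial)
  tec_structure(atoms, title = fr$comments[1L])
}

read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  comments <- character()
  times <- numeric()
  elements <- NULL
  i <- 1L
  k <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop(sprintf("malformed XYZ count at line %d", i))
    k <- k + 1L
    if (i + 1L + n > length(lines))
      stop(sprintf("truncated XYZ frame %d starting at line %d", k, i))
    comment <- lines[i + 1L]
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(vapply(parts, length, 1L) < 4L)
    if (length(bad))
      stop(sprintf("malformed XYZ atom record at line %d", i + 1L + bad[1L]))
    el <- vapply(parts, `[[`, "", 1L)
    xyz <- matrix(suppressWarnings(as.numeric(unlist(
      lapply(parts, function(p) p[2:4])))), ncol = 3L, byrow = TRUE)
    if (anyNA(xyz))
      stop(sprintf("non-numeric coordinates in XYZ frame %d", k))
    if (is.null(elements)) elements <- el
    frames[[k]] <- xyz
    comments[k] <- comment
    tm <- regmatches(comment, regexec("t\\s*=\\s*(-?[0-9.eE+]+)", comment))[[1L]]
    times[k] <- if (length(tm) == 2L) as.numeric(tm[2L]) else NA_real_
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames found in XYZ file: ", path)
  list(frames = frames, comments = comments, times = times,
       elements = elements)
}

#' Write a molecular structure
#'
#' @param structure a [tec_structure()].
#' @param path output file path.
#' @param format `"pdb"` or `"xyz"`; defaults from the file extension.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(structure, path, format = c("auto", "pdb", "xyz")) {
  stopifnot(inherits(structure, "tec_structure"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
         pdb = write_structure_pdb(structure, path),
         xyz = write_xyz(structure, list(coords(structure)), 0, path))
  invisible(path)
}

write_structure_pdb <- function(structure, path, xyz = NULL) {
  a <- structure$atoms
  if (any(a$resid > 9999L) || any(a$resid < -999L))
    stop("residue number out of PDB range (resid > 9999): cannot encode")
  if (any(a$serial > 99999L))
    stop("atom serial out of PDB range (> 99999): cannot encode")
  if (is.null(xyz)) xyz <- coords(structure)
  if (any(abs(xyz) >= 10000))
    stop("coordinate magnitude too large for PDB fixed columns")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(xyz)),
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   eleno = a$serial, elety = a$name, resid = a$resname,
                   chain = a$chain, resno = a$resid,
                   insert = ifelse(a$inscode == "", NA, a$inscode),
                   elesy = a$element, o = rep(1, nrow(a)),
                   b = rep(0, nrow(a)))
  invisible(path)
}

write_xyz <- function(structure, frames, times, path) {
  a <- structure$atoms
  el <- ifelse(nzchar(a$element), a$element, substr(a$name, 1L, 1L))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    writeLines(as.character(nrow(a)), con)
    writeLines(sprintf("frame %d t= %.6g", k, times[k]), con)
    writeLines(sprintf("%-4s %12.6f %12.6f %12.6f", el,
                       frames[[k]][, 1L], frames[[k]][, 2L],
                       frames[[k]][, 3L]), con)
  }
  invisible(path)
}

#' Read a trajectory against a known topology
#'
#' Supported dialects are multi-model PDB (one MODEL per frame) and the
#' plain XYZ dialect written by [write_trajectory()].  Frames are kept in
#' file order and every frame must carry exactly the topology's atom count.
#'
#' @param topology a [tec_structure()] providing atom addressing.
#' @param path trajectory file.
#' @param dialect `"multi-model-pdb"` or `"xyz"`; defaults from extension.
#' @param frame_interval frame spacing in ps; used when the file does not
#'   carry its own time stamps. Default 20 ps.
#' @return A [tec_trajectory()].
#' @export
read_trajectory <- function(topology, path,
                            dialect = c("auto", "multi-model-pdb", "xyz"),
                            frame_interval = 20) {
  stopifnot(inherits(topology, "tec_structure"))
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (guess_format(path) == "pdb") "multi-model-pdb" else "xyz"
  na <- n_atoms(topology)
  if (dialect == "multi-model-pdb") {
    validate_pdb_lines(path)
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    nat_file <- ncol(pdb$xyz) / 3L
    if (nat_file != na)
      stop(sprintf("atom-count mismatch at frame 1: file has %d atoms, topology %d",
                   nat_file, na))
    frames <- lapply(seq_len(nrow(pdb$xyz)), function(k)
      matrix(pdb$xyz[k, ], ncol = 3L, byrow = TRUE))
  } else {
    fr <- read_xyz_frames(path)
    for (k in seq_along(fr$frames)) {
      if (nrow(fr$frames[[k]]) != na)
        stop(sprintf("atom-count mismatch at frame %d: file has %d atoms, topology %d",
                     k, nrow(fr$frames[[k]]), na))
    }
    frames <- fr$frames
    tt <- fr$times
    if (length(tt) >= 2L && !anyNA(tt) && tt[2L] > tt[1L])
      frame_interval <- tt[2L] - tt[1L]
  }
  tec_trajectory(topology, frames, frame_interval = frame_interval)
}

#' Write a trajectory
#'
#' @param traj a [tec_trajectory()].
#' @param path output file.
#' @param dialect `"multi-model-pdb"` or `"xyz"`; defaults from extension.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path,
                             dialect = c("auto", "multi-model-pdb", "xyz")) {
  stopifnot(inherits(traj, "tec_trajectory"))
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (guess_format(path) == "pdb") "multi-model-pdb" else "xyz"
  if (dialect == "xyz") {
    write_xyz(traj$topology, traj$frames, frame_times(traj), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (k in seq_len(n_frames(traj))) {
      tmp <- tempfile(fileext = ".pdb")
      write_structure_pdb(traj$topology, tmp, xyz = traj$frames[[k]])
      body <- readLines(tmp, warn = FALSE)
      unlink(tmp)
      body <- body[!grepl("^END", body)]
      writeLines(sprintf("MODEL %8d", k), con)
      writeLines(body, con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}
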