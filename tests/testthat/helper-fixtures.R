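# Shared fixtures.  Everything is generated in code; small systems keep the
# default suite fast while the acceptance tests use full-size runs.

# A small toy TEC (few waters) for structure-level tests.
small_toy_params <- function(seed = 1L, n_frames = 20L, ...) {
  args <- utils::modifyList(list(seed = seed, n_frames = n_frames,
                                 n_transient_waters = 40L), list(...))
  do.call(toy_tec_params, args)
}

small_toy <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1L) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      p <- small_toy_params(seed = seed)
      cache[[key]] <- list(params = p, structure = build_toy_tec(p))
    }
    cache[[key]]
  }
})

# Hand-written 3-atom PDB content.
three_atom_pdb <- function() c(
  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
  "ATOM      3  C   ALA A   1      10.729   6.768  -4.123  1.00  0.00           C",
  "END")

# Two-water structure with a given O-O separation.
water_dimer <- function(sep = 2.8) {
  atoms <- data.frame(serial = 1:2, name = "O", resname = "HOH",
                      chain = "W", resid = 1:2, inscode = "",
                      element = "O", het = TRUE,
                      x = c(0, sep), y = 0, z = 0,
                      stringsAsFactors = FALSE)
  tec_structure(atoms, title = "water dimer")
}

# Minimal Lys/Asp side-chain pair at a given NZ-OD1 separation.
lys_asp_pair <- function(sep = 3.0, resname_b = "ASP", name_b = "OD1") {
  atoms <- data.frame(serial = 1:2, name = c("NZ", name_b),
                      resname = c("LYS", resname_b), chain = "A",
                      resid = c(1L, 2L), inscode = "",
                      element = substr(c("NZ", name_b), 1L, 1L), het = FALSE,
                      x = c(0, sep), y = 0, z = 0,
                      stringsAsFactors = FALSE)
  tec_structure(atoms)
}

# Static trajectory: n identical frames of a structure.
static_traj <- function(structure, n = 5L, frame_interval = 20) {
  tec_trajectory(structure, rep(list(coords(structure)), n),
                 frame_interval = frame_interval)
}

# Brute-force per-pair hydrogen-bond scan (plain double loop; no matrix
# shortcuts) used as the independent oracle.
brute_force_hbonds <- function(structure, criteria, tables, xyz = NULL) {
  if (is.null(xyz)) xyz <- coords(structure)
  a <- structure$atoms
  keys <- atom_keys(structure)
  rk <- tecdyn:::residue_key_of_atoms(a)
  don <- tecdyn:::typed_atom_indices(structure, tables$donors)
  acc <- tecdyn:::typed_atom_indices(structure, tables$acceptors)
  bb <- tecdyn:::backbone_index_table(structure)
  Hmat <- tecdyn:::reconstruct_amide_h(bb, xyz)
  hof <- rep(NA_integer_, nrow(a))
  hof[bb$N[!is.na(bb$N)]] <- which(!is.na(bb$N))
  out <- character()
  for (d in don) for (ac in acc) {
    if (rk[d] == rk[ac]) next
    if (a$chain[d] == a$chain[ac] && abs(a$resid[d] - a$resid[ac]) <= 1L &&
        a$name[d] %in% c("N", "O") && a$name[ac] %in% c("N", "O") &&
        !a$het[d] && !a$het[ac]) next
    r <- sqrt(sum((xyz[d, ] - xyz[ac, ])^2))
    if (r > criteria$hbond_da_cutoff) next
    hrow <- hof[d]
    if (a$name[d] == "N" && !a$het[d] && !is.na(hrow) &&
        !is.na(Hmat[hrow, 1L])) {
      h <- Hmat[hrow, ]
      v1 <- xyz[d, ] - h
      v2 <- xyz[ac, ] - h
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
        (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
      if (ang < criteria$hbond_angle_min) next
    }
    pair <- sort(c(keys[d], keys[ac]))
    out <- c(out, paste(pair[1L], pair[2L]))
  }
  sort(unique(out))
}

# Brute-force ion-pair scan over charged groups.
brute_force_ionpairs <- function(structure, criteria, tables, xyz = NULL) {
  if (is.null(xyz)) xyz <- coords(structure)
  grp <- tecdyn:::charge_groups(structure, tables$charges)
  out <- character()
  if (length(grp) >= 2L) for (i in seq_along(grp)) for (j in seq_along(grp)) {
    if (i >= j) next
    if (grp[[i]]$sign * grp[[j]]$sign >= 0) next
    if (grp[[i]]$residue == grp[[j]]$residue) next
    dmin <- Inf
    for (p in grp[[i]]$atoms) for (q in grp[[j]]$atoms)
      dmin <- min(dmin, sqrt(sum((xyz[p, ] - xyz[q, ])^2)))
    if (dmin <= criteria$ionpair_cutoff) {
      pair <- sort(c(grp[[i]]$residue, grp[[j]]$residue))
      out <- c(out, paste(pair[1L], pair[2L]))
    }
  }
  sort(unique(out))
}

# Unordered-pair signatures of package contact records, for set equality.
hbond_pair_set <- function(rec) {
  if (!nrow(rec)) return(character())
  unord <- ifelse(rec$atom_i < rec$atom_j,
                  paste(rec$atom_i, rec$atom_j),
                  paste(rec$atom_j, rec$atom_i))
  sort(unique(unord))
}

ionpair_residue_set <- function(rec) {
  if (!nrow(rec)) return(character())
  unord <- ifelse(rec$residue_i < rec$residue_j,
                  paste(rec$residue_i, rec$residue_j),
                  paste(rec$residue_j, rec$residue_i))
  sort(unique(unord))
}

# Python DSSP reference (mdtraj) on a PDB file; returns simplified H/E/C
# labels, or NULL if the interpreter is unavailable.
mdtraj_dssp <- function(pdb_path) {
  py <- Sys.which("python")
  if (!nzchar(py)) return(NULL)
  code <- sprintf(
    "import mdtraj as md; print(''.join(md.compute_dssp(md.load('%s'), simplified=True)[0]))",
    pdb_path)
  out <- tryCatch(suppressWarnings(system2(py, c("-c", shQuote(code)),
                                           stdout = TRUE, stderr = FALSE)),
                  error = function(e) NULL)
  if (is.null(out) || !length(out)) return(NULL)
  strsplit(out[length(out)], "")[[1L]]
}
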