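#' Geometric contact criteria
#'
#' Cutoffs for calling hydrogen bonds and ion pairs.  The defaults (3.5 A
#' donor-acceptor, 120 degrees D-H...A, 4.0 A between charged-group heavy
#' atoms) are common first-shell conventions; all are exposed here and in
#' run configs.
#'
#' @param hbond_da_cutoff donor-acceptor heavy-atom distance cutoff, A.
#' @param hbond_angle_min minimum D-H...A angle at the (reconstructed)
#'   hydrogen, degrees.  Donors whose hydrogen cannot be placed (side
#'   chains and waters in hydrogen-free inputs) are judged on distance
#'   alone.
#' @param ionpair_cutoff max distance between opposite-sign charged-group
#'   heavy atoms, A.
#' @return An object of class `contact_criteria`.
#' @export
contact_criteria <- function(hbond_da_cutoff = 3.5, hbond_angle_min = 120,
                             ionpair_cutoff = 4.0) {
  stopifnot(hbond_da_cutoff > 0, ionpair_cutoff > 0,
            hbond_angle_min > 0, hbond_angle_min <= 180)
  structure(list(hbond_da_cutoff = hbond_da_cutoff,
                 hbond_angle_min = hbond_angle_min,
                 ionpair_cutoff = ionpair_cutoff),
            class = "contact_criteria")
}

#' Default donor/acceptor/charge typing tables
#'
#' Read from the editable delimited files shipped in
#' `system.file("extdata", package = "tecdyn")`.  Donors/acceptors cover
#' the protein backbone, common side chains, nucleic-acid heteroatoms and
#' water; charge groups cover Lys/Arg/Asp/Glu side chains, optionally
#' protonated His, Mg ions and phosphates.
#'
#' @param protonated_his optional character vector of residue keys
#'   (`chain:resid`) of histidines to treat as +1 charged; by default
#'   histidines are neutral.
#' @return List with data.frames `donors`, `acceptors`, `charges`.
#' @export
default_contact_tables <- function(protonated_his = character()) {
  dir <- system.file("extdata", package = "tecdyn")
  rd <- function(f) utils::read.table(file.path(dir, f), header = TRUE,
                                      sep = "\t", stringsAsFactors = FALSE)
  charges <- rd("charge_groups.tsv")
  # HIS rows are only activated for residues listed in protonated_his
  attr(charges, "protonated_his") <- protonated_his
  list(donors = rd("hbond_donors.tsv"), acceptors = rd("hbond_acceptors.tsv"),
       charges = charges)
}

# Logical: which residues look like amino acids (have N, CA and C).
protein_residue_keys <- function(structure) {
  bb <- backbone_index_table(structure)
  bb$key[!is.na(bb$N) & !is.na(bb$CA) & !is.na(bb$C)]
}

residue_key_of_atoms <- function(atoms) {
  paste0(atoms$chain, ":", atoms$resid,
         ifelse(is.na(atoms$inscode), "", atoms$inscode))
}

# Indices of atoms matched by a (resname, atom) typing table; resname "*"
# matches protein residues only (backbone typing), "HOH" expands to every
# recognised water residue name.
typed_atom_indices <- function(structure, table) {
  a <- structure$atoms
  rk <- residue_key_of_atoms(a)
  protk <- protein_residue_keys(structure)
  hit <- rep(FALSE, nrow(a))
  for (r in seq_len(nrow(table))) {
    rn <- table$resname[r]
    at <- normalize_atom_name(table$atom[r])
    if (rn == "*") hit <- hit | (a$name == at & rk %in% protk)
    else if (rn == "HOH") hit <- hit | (a$name == at & is_water_atom(a))
    else hit <- hit | (a$name == at & toupper(a$resname) == rn)
  }
  which(hit)
}

pair_dist_matrix <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Charged-group instances: one row per (residue, group) with sign and the
# member heavy-atom indices.
charge_groups <- function(structure, charges) {
  a <- structure$atoms
  rk <- residue_key_of_atoms(a)
  out <- list()
  prot_his <- attr(charges, "protonated_his")
  for (g in unique(paste(charges$resname, charges$group))) {
    rows <- charges[paste(charges$resname, charges$group) == g, ,
                    drop = FALSE]
    rn <- rows$resname[1L]
    sgn <- rows$sign[1L]
    sel <- toupper(a$resname) == rn &
      a$name %in% normalize_atom_name(rows$atom)
    if (!any(sel)) next
    for (res in unique(rk[sel])) {
      if (rn == "HIS" && !(res %in% prot_his)) next
      out[[length(out) + 1L]] <-
        list(residue = res, resname = rn, sign = sgn,
             atoms = which(sel & rk == res), group = rows$group[1L])
    }
  }
  out
}

# Static per-topology typing context reused across frames.
contact_context <- function(structure, tables = default_contact_tables()) {
  a <- structure$atoms
  bb <- backbone_index_table(structure)
  hof <- rep(NA_integer_, nrow(a))       # atom index -> row in bb
  hof[bb$N[!is.na(bb$N)]] <- which(!is.na(bb$N))
  list(structure = structure,
       keys = atom_keys(structure),
       rk = residue_key_of_atoms(a),
       don = typed_atom_indices(structure, tables$donors),
       acc = typed_atom_indices(structure, tables$acceptors),
       groups = charge_groups(structure, tables$charges),
       bb = bb, hof = hof)
}

empty_contacts <- function() {
  data.frame(kind = character(), atom_i = character(),
             atom_j = character(), residue_i = character(),
             residue_j = character(), distance = numeric(),
             angle = numeric(), stringsAsFactors = FALSE)
}

# Hydrogen-bond records between the given donor/acceptor atom subsets.
frame_hbonds <- function(ctx, xyz, criteria, don, acc) {
  if (!length(don) || !length(acc)) return(empty_contacts())
  a <- ctx$structure$atoms
  dm <- pair_dist_matrix(xyz[don, , drop = FALSE], xyz[acc, , drop = FALSE])
  hits <- which(dm <= criteria$hbond_da_cutoff, arr.ind = TRUE)
  if (!nrow(hits)) return(empty_contacts())
  di <- don[hits[, 1L]]
  ai <- acc[hits[, 2L]]
  keep <- ctx$rk[di] != ctx$rk[ai]
  bbname <- c("N", "O")
  adj_bb <- a$chain[di] == a$chain[ai] &
    abs(a$resid[di] - a$resid[ai]) <= 1L &
    a$name[di] %in% bbname & a$name[ai] %in% bbname &
    !a$het[di] & !a$het[ai]
  keep <- keep & !adj_bb
  di <- di[keep]; ai <- ai[keep]
  if (!length(di)) return(empty_contacts())

  Hmat <- reconstruct_amide_h(ctx$bb, xyz)
  ang <- rep(NA_real_, length(di))
  pass <- rep(TRUE, length(di))
  for (q in seq_along(di)) {
    hrow <- ctx$hof[di[q]]
    if (a$name[di[q]] == "N" && !a$het[di[q]] && !is.na(hrow) &&
        !is.na(Hmat[hrow, 1L])) {
      h <- Hmat[hrow, ]
      v1 <- xyz[di[q], ] - h
      v2 <- xyz[ai[q], ] - h
      ang[q] <- rad2deg(acos(pmin(1, pmax(-1,
        sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))))
      pass[q] <- ang[q] >= criteria$hbond_angle_min
    }
  }
  di <- di[pass]; ai <- ai[pass]; ang <- ang[pass]
  if (!length(di)) return(empty_contacts())
  dist <- sqrt(rowSums((xyz[di, , drop = FALSE] - xyz[ai, , drop = FALSE])^2))
  rec <- data.frame(kind = "hbond", atom_i = ctx$keys[di],
                    atom_j = ctx$keys[ai], residue_i = ctx$rk[di],
                    residue_j = ctx$rk[ai], distance = dist, angle = ang,
                    stringsAsFactors = FALSE)
  dedupe_contacts(rec)
}

# Collapse symmetric duplicates of the same unordered atom pair (water
# pairs qualify in both donor/acceptor directions) and order records.
dedupe_contacts <- function(rec) {
  if (!nrow(rec)) return(rec)
  unord <- ifelse(rec$atom_i < rec$atom_j,
                  paste(rec$atom_i, rec$atom_j),
                  paste(rec$atom_j, rec$atom_i))
  rec <- rec[!duplicated(paste(rec$kind, unord)), , drop = FALSE]
  rec <- rec[order(rec$atom_i, rec$atom_j), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

# Ion-pair records between two charged-group index subsets (positions in
# ctx$groups).  Pairs must have opposite sign and distinct residues.
frame_ionpairs <- function(ctx, xyz, criteria, gi, gj) {
  grp <- ctx$groups
  if (!length(gi) || !length(gj)) return(empty_contacts())
  recs <- list()
  done <- character()
  for (i in gi) for (j in gj) {
    if (i == j) next
    if (grp[[i]]$sign * grp[[j]]$sign >= 0) next
    if (grp[[i]]$residue == grp[[j]]$residue) next
    id <- paste(min(i, j), max(i, j))
    if (id %in% done) next
    done <- c(done, id)
    dm <- pair_dist_matrix(xyz[grp[[i]]$atoms, , drop = FALSE],
                           xyz[grp[[j]]$atoms, , drop = FALSE])
    w <- which(dm == min(dm), arr.ind = TRUE)[1L, , drop = TRUE]
    if (dm[w[1L], w[2L]] > criteria$ionpair_cutoff) next
    pos_first <- grp[[i]]$sign > 0
    ii <- if (pos_first) i else j
    jj <- if (pos_first) j else i
    wi <- if (pos_first) grp[[i]]$atoms[w[1L]] else grp[[j]]$atoms[w[2L]]
    wj <- if (pos_first) grp[[j]]$atoms[w[2L]] else grp[[i]]$atoms[w[1L]]
    recs[[length(recs) + 1L]] <- data.frame(
      kind = "ionpair", atom_i = ctx$keys[wi], atom_j = ctx$keys[wj],
      residue_i = grp[[ii]]$residue, residue_j = grp[[jj]]$residue,
      distance = dm[w[1L], w[2L]], angle = NA_real_,
      stringsAsFactors = FALSE)
  }
  if (!length(recs)) return(empty_contacts())
  dedupe_contacts(do.call(rbind, recs))
}

#' Detect hydrogen bonds in one frame
#'
#' All donor-acceptor pairs with D-A distance within the cutoff and, where
#' the amide hydrogen can be reconstructed (backbone N donors), a D-H...A
#' angle at or above the angle minimum.  Same-residue pairs and
#' backbone-backbone pairs between sequence-adjacent residues are
#' excluded; symmetric duplicates (water-water pairs qualify in both
#' directions) are collapsed to one record.  Records are ordered by
#' (donor key, acceptor key).
#'
#' @param structure a [tec_structure()].
#' @param criteria a [contact_criteria()].
#' @param tables typing tables from [default_contact_tables()] (default).
#' @param xyz optional coordinate matrix overriding the structure's own.
#' @return data.frame with `kind`, `atom_i`, `atom_j`, `residue_i`,
#'   `residue_j`, `distance`, `angle` (NA when no hydrogen was placed).
#' @export
hydrogen_bonds <- function(structure, criteria = contact_criteria(),
                           tables = default_contact_tables(), xyz = NULL) {
  stopifnot(inherits(criteria, "contact_criteria"))
  if (is.null(xyz)) xyz <- coords(structure)
  ctx <- contact_context(structure, tables)
  frame_hbonds(ctx, xyz, criteria, ctx$don, ctx$acc)
}

#' Detect ion pairs in one frame
#'
#' Pairs of opposite formal sign whose minimum inter-group heavy-atom
#' distance is within the cutoff.  Charged groups (Arg guanidinium, Lys
#' amine, Asp/Glu carboxylate, optionally protonated His, Mg ions,
#' phosphates) come from the charge typing table; the reported atom keys
#' give the closest heavy-atom pair, cation first.
#'
#' @inheritParams hydrogen_bonds
#' @return data.frame as in [hydrogen_bonds()] (`angle` is `NA`).
#' @export
ion_pairs <- function(structure, criteria = contact_criteria(),
                      tables = default_contact_tables(), xyz = NULL) {
  stopifnot(inherits(criteria, "contact_criteria"))
  if (is.null(xyz)) xyz <- coords(structure)
  ctx <- contact_context(structure, tables)
  gidx <- seq_along(ctx$groups)
  frame_ionpairs(ctx, xyz, criteria, gidx, gidx)
}

# Per-frame contacts restricted to those touching the focus residues;
# O(n_focus x n_typed) instead of a full scan.
focus_contacts <- function(ctx, xyz, focus, criteria) {
  in_focus <- ctx$rk %in% focus
  don_f <- ctx$don[in_focus[ctx$don]]
  acc_f <- ctx$acc[in_focus[ctx$acc]]
  hb <- rbind(frame_hbonds(ctx, xyz, criteria, don_f, ctx$acc),
              frame_hbonds(ctx, xyz, criteria, ctx$don, acc_f))
  hb <- dedupe_contacts(hb)
  grp_res <- vapply(ctx$groups, `[[`, "", "residue")
  gf <- which(grp_res %in% focus)
  ip <- frame_ionpairs(ctx, xyz, criteria, gf, seq_along(ctx$groups))
  rbind(hb, ip)
}

#' Occupancy of one contact over a trajectory
#'
#' Fraction of sampled frames in which the named residue pair is in
#' contact (any qualifying hydrogen bond or ion pair between them, or
#' restricted to one kind).
#'
#' @param traj a [tec_trajectory()].
#' @param residue_a,residue_b residue keys (`chain:resid`).
#' @param criteria a [contact_criteria()].
#' @param tables typing tables (default [default_contact_tables()]).
#' @param kind `"any"`, `"hbond"` or `"ionpair"`.
#' @param stride sampling stride in frames.
#' @return Occupancy fraction in \[0, 1\].
#' @export
contact_occupancy <- function(traj, residue_a, residue_b,
                              criteria = contact_criteria(),
                              tables = default_contact_tables(),
                              kind = c("any", "hbond", "ionpair"),
                              stride = 1L) {
  stopifnot(inherits(traj, "tec_trajectory"))
  kind <- match.arg(kind)
  top <- traj$topology
  ctx <- contact_context(top, tables)
  for (r in c(residue_a, residue_b))
    if (!r %in% ctx$rk) stop("residue key not found in topology: ", r)
  ks <- stride_frames(traj, stride)
  hitn <- 0L
  for (k in ks) {
    rec <- focus_contacts(ctx, traj$frames[[k]], c(residue_a, residue_b),
                          criteria)
    if (kind != "any") rec <- rec[rec$kind == kind, , drop = FALSE]
    both <- (rec$residue_i == residue_a & rec$residue_j == residue_b) |
            (rec$residue_i == residue_b & rec$residue_j == residue_a)
    if (any(both)) hitn <- hitn + 1L
  }
  hitn / length(ks)
}

#' Detect switch residues between two ensembles
#'
#' A switch residue is a side chain whose ionic or hydrogen-bond partners
#' differ between two trajectory ensembles (e.g. closed versus open
#' trigger loop).  For each candidate residue the per-partner contact
#' occupancy is computed in each ensemble; the switch score is the largest
#' absolute occupancy difference over partners and a residue is flagged
#' when that difference reaches `occupancy_delta`.
#'
#' @param traj_a,traj_b two [tec_trajectory()] objects sharing residue
#'   naming for the candidates.
#' @param candidates character vector of residue keys (`chain:resid`).
#' @param criteria a [contact_criteria()].
#' @param tables typing tables (default [default_contact_tables()]).
#' @param occupancy_delta switch-call threshold on |occ_A - occ_B|
#'   (default 0.5, i.e. a contact mostly present in one ensemble and
#'   mostly absent in the other).
#' @param stride sampling stride in frames.
#' @param include_waters if `TRUE`, water residues are counted as
#'   partners.  Off by default: switch residues are defined by their
#'   side-chain contacts to other residues, and solvent turnover would
#'   otherwise dominate the occupancy differences between independently
#'   simulated ensembles.
#' @return data.frame sorted by `switch_score` descending with one row per
#'   candidate: `residue`, `switch_score`, `is_switch`, `top_partner`,
#'   `occ_a`, `occ_b`; full partner occupancy maps in attribute
#'   `"partners"`.
#' @export
switch_residues <- function(traj_a, traj_b, candidates,
                            criteria = contact_criteria(),
                            tables = default_contact_tables(),
                            occupancy_delta = 0.5, stride = 1L,
                            include_waters = FALSE) {
  stopifnot(inherits(traj_a, "tec_trajectory"),
            inherits(traj_b, "tec_trajectory"))
  bb_names <- c("N", "CA", "C", "O")
  occ_map <- function(traj) {
    ctx <- contact_context(traj$topology, tables)
    missing <- setdiff(candidates, ctx$rk)
    if (length(missing))
      stop("candidate residue(s) absent from a topology: ",
           paste(missing, collapse = ", "))
    protk <- protein_residue_keys(traj$topology)
    wat <- unique(ctx$rk[is_water_atom(traj$topology$atoms)])
    ks <- stride_frames(traj, stride)
    counts <- list()
    for (k in ks) {
      rec <- focus_contacts(ctx, traj$frames[[k]], candidates, criteria)
      if (!nrow(rec)) next
      # a switch residue is judged by its side chain: drop records where
      # the candidate-side atom is a backbone atom of a protein residue
      name_i <- sub("^.*:", "", rec$atom_i)
      name_j <- sub("^.*:", "", rec$atom_j)
      bb_i <- rec$residue_i %in% protk & name_i %in% bb_names
      bb_j <- rec$residue_j %in% protk & name_j %in% bb_names
      seen <- unique(rbind(
        data.frame(cand = rec$residue_i[!bb_i],
                   partner = rec$residue_j[!bb_i],
                   stringsAsFactors = FALSE),
        data.frame(cand = rec$residue_j[!bb_j],
                   partner = rec$residue_i[!bb_j],
                   stringsAsFactors = FALSE)))
      seen <- seen[seen$cand %in% candidates, , drop = FALSE]
      if (!include_waters)
        seen <- seen[!(seen$partner %in% wat), , drop = FALSE]
      for (q in seq_len(nrow(seen))) {
        id <- paste(seen$cand[q], seen$partner[q], sep = "|")
        counts[[id]] <- (counts[[id]] %||% 0L) + 1L
      }
    }
    lapply(counts, function(x) x / length(ks))
  }
  occ_a <- occ_map(traj_a)
  occ_b <- occ_map(traj_b)
  rows <- list()
  partner_maps <- list()
  for (cand in candidates) {
    ids <- union(names(occ_a), names(occ_b))
    ids <- ids[startsWith(ids, paste0(cand, "|"))]
    partners <- sub("^.*\\|", "", ids)
    oa <- vapply(ids, function(i) occ_a[[i]] %||% 0, numeric(1L))
    ob <- vapply(ids, function(i) occ_b[[i]] %||% 0, numeric(1L))
    if (length(ids)) {
      ord <- order(-abs(oa - ob), partners)
      dmax <- ord[1L]
      score <- abs(oa - ob)[dmax]
      top <- partners[dmax]
      toa <- oa[dmax]; tob <- ob[dmax]
    } else {
      score <- 0; top <- NA_character_; toa <- 0; tob <- 0
    }
    partner_maps[[cand]] <- data.frame(partner = partners,
                                       occ_a = unname(oa),
                                       occ_b = unname(ob),
                                       stringsAsFactors = FALSE)
    rows[[cand]] <- data.frame(residue = cand, switch_score = score,
                               is_switch = score >= occupancy_delta,
                               top_partner = top, occ_a = unname(toa),
                               occ_b = unname(tob), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$switch_score, out$residue), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "partners") <- partner_maps
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
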