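# Kabsch-Sander style secondary-structure assignment over the five classes
# named on hinge timeline plots: H (alpha-helix), G (3-10 helix), E
# (beta-sheet/ladder), T (turn), C (coil).  Pi-helix is folded into H.

# Backbone amide H reconstruction: H sits 1.0 A from N, anti to the C=O of
# the preceding residue (H = N + unit(C_prev - O_prev)).  Inputs lack
# hydrogens, so every module that needs the amide H uses this rule.
reconstruct_amide_h <- function(bb, xyz) {
  n <- nrow(bb)
  H <- matrix(NA_real_, n, 3L)
  if (n < 2L) return(H)
  prev_ok <- c(FALSE, bb$chain[-n] == bb$chain[-1L] &
                      bb$resid[-n] == bb$resid[-1L] - 1L)
  for (i in which(prev_ok)) {
    Cp <- bb$C[i - 1L]; Op <- bb$O[i - 1L]; Ni <- bb$N[i]
    if (anyNA(c(Cp, Op, Ni))) next
    d <- xyz[Cp, ] - xyz[Op, ]
    nd <- vnorm(d)
    if (nd < 1e-6) next
    H[i, ] <- xyz[Ni, ] + d / nd
  }
  H
}

# Kabsch-Sander electrostatic H-bond energy (kcal/mol) between the C=O of
# residue i and the N-H of residue j: E = 0.084 * 332 *
# (1/rON + 1/rCH - 1/rOH - 1/rCN); a bond is called below -0.5 kcal/mol.
ks_hbond_matrix <- function(bb, xyz, Hmat, cutoff_energy = -0.5) {
  n <- nrow(bb)
  hb <- matrix(FALSE, n, n)
  if (n < 3L) return(hb)
  okCO <- !is.na(bb$C) & !is.na(bb$O)
  okNH <- !is.na(bb$N) & !is.na(Hmat[, 1L])
  Cx <- xyz[ifelse(okCO, bb$C, 1L), , drop = FALSE]
  Ox <- xyz[ifelse(okCO, bb$O, 1L), , drop = FALSE]
  Nx <- xyz[ifelse(okNH, bb$N, 1L), , drop = FALSE]
  q <- 0.084 * 332
  for (i in which(okCO)) {
    # CA-CA distance pre-filter keeps this O(n) per donor in practice
    for (j in which(okNH)) {
      if (abs(i - j) < 2L && bb$chain[i] == bb$chain[j]) next
      rON <- vnorm(Ox[i, ] - Nx[j, ])
      if (rON > 5.2) next
      rCH <- vnorm(Cx[i, ] - Hmat[j, ])
      rOH <- vnorm(Ox[i, ] - Hmat[j, ])
      rCN <- vnorm(Cx[i, ] - Nx[j, ])
      if (min(rON, rCH, rOH, rCN) < 0.5) next   # clash; KS marks as no bond
      e <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      if (e < cutoff_energy) hb[i, j] <- TRUE
    }
  }
  hb
}

#' Assign secondary structure to one frame
#'
#' Kabsch-Sander style assignment on the five-class alphabet `H` (alpha
#' helix), `G` (3-10 helix), `E` (beta sheet), `T` (turn), `C` (coil).
#' Backbone hydrogen bonds are called from the electrostatic energy
#' criterion (E < -0.5 kcal/mol) with the amide hydrogen reconstructed
#' geometrically when absent; two consecutive i,i+4 turns make a helix,
#' i,i+3 turns a 3-10 helix, bridge/ladder patterns a sheet, and isolated
#' turn hydrogen bonds a turn.  Residues missing a backbone O are labelled
#' `C` with a warning.
#'
#' @param structure a [tec_structure()].
#' @param xyz optional coordinate matrix overriding the structure's own.
#' @return Character vector of labels, named by residue key, one element
#'   per protein residue (those with N, CA, C backbone atoms).
#' @export
assign_secondary_structure <- function(structure, xyz = NULL) {
  if (is.null(xyz)) xyz <- coords(structure)
  bb <- backbone_index_table(structure)
  bb <- bb[!is.na(bb$N) & !is.na(bb$CA) & !is.na(bb$C), , drop = FALSE]
  n <- nrow(bb)
  lab <- rep("C", n)
  names(lab) <- bb$key
  if (!n) return(lab)
  if (anyNA(bb$O))
    warning("residues missing backbone O are labelled C")
  Hmat <- reconstruct_amide_h(bb, xyz)
  hb <- ks_hbond_matrix(bb, xyz, Hmat)
  same_chain <- function(i, j) bb$chain[i] == bb$chain[j] &&
    bb$resid[j] - bb$resid[i] == j - i
  turn4 <- vapply(seq_len(n), function(i)
    i + 4L <= n && same_chain(i, i + 4L) && hb[i, i + 4L], logical(1L))
  turn3 <- vapply(seq_len(n), function(i)
    i + 3L <= n && same_chain(i, i + 3L) && hb[i, i + 3L], logical(1L))
  turn5 <- vapply(seq_len(n), function(i)
    i + 5L <= n && same_chain(i, i + 5L) && hb[i, i + 5L], logical(1L))

  isH <- rep(FALSE, n)   # two consecutive 4-turns at i-1, i -> i..i+3
  for (i in seq_len(n - 1L))
    if (i >= 2L && turn4[i - 1L] && turn4[i]) isH[i:(i + 3L)] <- TRUE
  isG <- rep(FALSE, n)
  for (i in seq_len(n))
    if (i >= 2L && turn3[i - 1L] && turn3[i]) isG[i:(i + 2L)] <- TRUE
  isI <- rep(FALSE, n)   # pi helix, folded into H
  for (i in seq_len(n))
    if (i >= 2L && turn5[i - 1L] && turn5[i]) isI[i:(i + 4L)] <- TRUE

  # bridges: parallel / antiparallel ladder patterns
  isE <- rep(FALSE, n)
  if (n >= 5L) for (i in 2:(n - 1L)) {
    for (j in 2:(n - 1L)) {
      if (abs(i - j) < 3L) next
      par <- (hb[i - 1L, j] && hb[j, i + 1L]) ||
             (hb[j - 1L, i] && hb[i, j + 1L])
      anti <- (hb[i, j] && hb[j, i]) ||
              (hb[i - 1L, j + 1L] && hb[j - 1L, i + 1L])
      if (par || anti) { isE[i] <- TRUE; isE[j] <- TRUE }
    }
  }

  # turn: residues covered by any isolated n-turn
  isT <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (turn3[i] && i + 2L <= n) isT[(i + 1L):(i + 2L)] <- TRUE
    if (turn4[i] && i + 3L <= n) isT[(i + 1L):(i + 3L)] <- TRUE
    if (turn5[i] && i + 4L <= n) isT[(i + 1L):(i + 4L)] <- TRUE
  }

  lab[isT] <- "T"
  lab[isG] <- "G"
  lab[isE] <- "E"
  lab[isH | isI] <- "H"
  lab
}

#' Secondary-structure timeline
#'
#' Runs [assign_secondary_structure()] on sampled frames and assembles a
#' residue-by-time character matrix, the per-residue secondary-structure
#' timeline used to watch hinge segments melt or reform during a
#' trajectory.
#'
#' @param traj a [tec_trajectory()].
#' @param chain optional chain filter.
#' @param residues optional length-2 inclusive resid range filter.
#' @param stride sampling stride in frames.
#' @return Object of class `ss_timeline`: a list with `labels` (residue x
#'   frame character matrix, rownames = residue keys), `times` (ps) and
#'   `resids`.
#' @export
ss_timeline <- function(traj, chain = NULL, residues = NULL, stride = 1L) {
  stopifnot(inherits(traj, "tec_trajectory"))
  top <- traj$topology
  ks <- stride_frames(traj, stride)
  one <- assign_secondary_structure(top, xyz = traj$frames[[1L]])
  keep <- rep(TRUE, length(one))
  bb <- backbone_index_table(top)
  bb <- bb[!is.na(bb$N) & !is.na(bb$CA) & !is.na(bb$C), , drop = FALSE]
  if (!is.null(chain)) keep <- keep & bb$chain == chain
  if (!is.null(residues))
    keep <- keep & bb$resid >= residues[1L] & bb$resid <= residues[2L]
  m <- matrix(NA_character_, sum(keep), length(ks),
              dimnames = list(names(one)[keep], NULL))
  for (c0 in seq_along(ks)) {
    lab <- assign_secondary_structure(top, xyz = traj$frames[[ks[c0]]])
    m[, c0] <- lab[keep]
  }
  structure(list(labels = m, times = frame_times(traj)[ks],
                 resids = bb$resid[keep]),
            class = "ss_timeline")
}

#' Write a secondary-structure timeline
#'
#' Residue-by-frame character matrix as tab-delimited text, one residue
#' per row, preceded by a header row of frame times.
#'
#' @param timeline an [ss_timeline()] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_ss_timeline <- function(timeline, path) {
  m <- timeline$labels
  df <- data.frame(residue = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("residue", sprintf("t%g", timeline$times))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
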