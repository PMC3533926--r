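#' Hinge definition
#'
#' Names a hinge segment (e.g. the trigger-loop hinges H1 1230-GEPGTQ-1235
#' and H2 1255-GLP-1257, or the bridge-helix hinges H3 1076-GA-1077 and H4
#' 1080-GG-1081) together with the flanking residue ranges used to fit
#' helix axes on either side of it.
#'
#' @param name hinge tag (`"H1"` ... `"H4"` or custom).
#' @param chain chain id.
#' @param residues length-2 integer range of hinge residues (inclusive).
#' @param flank_pre,flank_post length-2 inclusive resid ranges used for
#'   axis fitting; each flank needs at least 4 residues and the flanks
#'   must not overlap.
#' @return An object of class `hinge_definition`.
#' @export
hinge_definition <- function(name, chain, residues, flank_pre, flank_post) {
  stopifnot(length(residues) == 2L, length(flank_pre) == 2L,
            length(flank_post) == 2L)
  if (diff(flank_pre) < 3L || diff(flank_post) < 3L)
    stop("each flank must span at least 4 residues")
  if (max(flank_pre) >= min(flank_post))
    stop("flank_pre and flank_post must be disjoint, pre before post")
  structure(list(name = name, chain = chain, residues = residues,
                 flank_pre = flank_pre, flank_post = flank_post),
            class = "hinge_definition")
}

# Indices of one backbone atom type for each protein residue, NA if absent.
backbone_index_table <- function(structure) {
  a <- structure$atoms
  res <- residue_table(structure)
  out <- res
  for (nm in c("N", "CA", "C", "O")) {
    hit <- a$name == nm & !a$het
    key <- paste0(a$chain[hit], ":", a$resid[hit],
                  ifelse(is.na(a$inscode[hit]), "", a$inscode[hit]))
    out[[nm]] <- which(hit)[match(res$key, key)]
  }
  out[!is.na(out$CA) | !is.na(out$N) | !is.na(out$C), , drop = FALSE]
}

#' Backbone phi/psi dihedrals of one frame
#'
#' Standard phi (C-,N,CA,C) and psi (N,CA,C,N+) torsions in degrees in
#' (-180, 180].  Chain termini and residues with missing backbone atoms
#' yield `NA` (with a warning for missing atoms rather than an abort).
#'
#' @param structure a [tec_structure()] (protein residues are detected by
#'   their backbone atoms).
#' @param xyz optional n x 3 coordinate matrix overriding the structure's
#'   own coordinates (e.g. one trajectory frame).
#' @param chain optional chain id filter.
#' @param residues optional length-2 inclusive resid range filter.
#' @return data.frame with `chain`, `resid`, `phi`, `psi` (degrees).
#' @export
backbone_dihedrals <- function(structure, xyz = NULL, chain = NULL,
                               residues = NULL) {
  bb <- backbone_index_table(structure)
  if (!is.null(chain)) bb <- bb[bb$chain == chain, , drop = FALSE]
  if (!is.null(residues))
    bb <- bb[bb$resid >= residues[1L] & bb$resid <= residues[2L], ,
             drop = FALSE]
  if (is.null(xyz)) xyz <- coords(structure)
  n <- nrow(bb)
  phi <- psi <- rep(NA_real_, n)
  if (!n) return(data.frame(chain = character(), resid = integer(),
                            phi = numeric(), psi = numeric()))
  # neighbours must be sequential residues on the same chain
  prev_ok <- c(FALSE, bb$chain[-n] == bb$chain[-1L] &
                      bb$resid[-n] == bb$resid[-1L] - 1L)
  next_ok <- c(prev_ok[-1L], FALSE)
  missing_bb <- FALSE
  for (i in seq_len(n)) {
    Ni <- bb$N[i]; CAi <- bb$CA[i]; Ci <- bb$C[i]
    if (anyNA(c(Ni, CAi, Ci))) { missing_bb <- TRUE; next }
    if (prev_ok[i] && !is.na(bb$C[i - 1L]))
      phi[i] <- torsion_angle(xyz[bb$C[i - 1L], ], xyz[Ni, ], xyz[CAi, ],
                              xyz[Ci, ])
    if (next_ok[i] && !is.na(bb$N[i + 1L]))
      psi[i] <- torsion_angle(xyz[Ni, ], xyz[CAi, ], xyz[Ci, ],
                              xyz[bb$N[i + 1L], ])
  }
  if (missing_bb)
    warning("residues with missing backbone atoms were marked undefined")
  data.frame(chain = bb$chain, resid = bb$resid, phi = phi, psi = psi,
             stringsAsFactors = FALSE)
}

#' Delta-psi time series of one residue
#'
#' Change of a residue's backbone psi dihedral relative to the reference
#' frame, wrapped into (-180, 180], as a hinge-motion metric.  The
#' reference frame maps to exactly 0; frames where psi is undefined yield
#' `NA` gaps.
#'
#' @param traj a [tec_trajectory()].
#' @param chain chain id of the residue.
#' @param resid residue number.
#' @param reference_frame reference frame index (default 1).
#' @param stride sampling stride in frames.
#' @return A series data.frame (`time_ps`, `value` in degrees, `label`).
#' @export
delta_psi_series <- function(traj, chain, resid, reference_frame = 1L,
                             stride = 1L) {
  stopifnot(inherits(traj, "tec_trajectory"))
  top <- traj$topology
  bb <- backbone_index_table(top)
  i <- which(bb$chain == chain & bb$resid == resid)
  if (length(i) != 1L)
    stop(sprintf("residue %s:%d not found or ambiguous", chain, resid))
  if (i == nrow(bb) || bb$chain[i + 1L] != chain ||
      bb$resid[i + 1L] != resid + 1L || anyNA(c(bb$N[i], bb$CA[i], bb$C[i])) ||
      is.na(bb$N[i + 1L]))
    stop(sprintf("psi undefined for residue %s:%d (chain terminus or missing backbone atoms)",
                 chain, resid))
  at <- c(bb$N[i], bb$CA[i], bb$C[i], bb$N[i + 1L])
  psi_of <- function(xyz) torsion_angle(xyz[at[1L], ], xyz[at[2L], ],
                                        xyz[at[3L], ], xyz[at[4L], ])
  psi_ref <- psi_of(traj$frames[[reference_frame]])
  ks <- stride_frames(traj, stride)
  vals <- vapply(ks, function(k) wrap_angle(psi_of(traj$frames[[k]]) - psi_ref),
                 numeric(1L))
  vals[ks == reference_frame] <- 0
  series_result(frame_times(traj)[ks], vals,
                sprintf("dpsi %s:%d", chain, resid))
}

#' Helix bend angle at a hinge
#'
#' Fits an axis to the Calpha atoms of each flank (principal axis of the
#' Calpha cloud, oriented N to C; eigenvalue ties broken by the
#' end-to-end vector) and returns the angle between the two axes in
#' degrees.  A straight ideal helix gives approximately 0; bridge-helix
#' bending modes show up as distinct nonzero plateaus.
#'
#' @param structure a [tec_structure()].
#' @param hinge a [hinge_definition()].
#' @param xyz optional coordinate matrix overriding the structure's own.
#' @return Bend angle in degrees, in \[0, 180).
#' @export
helix_bend_angle <- function(structure, hinge, xyz = NULL) {
  stopifnot(inherits(hinge, "hinge_definition"))
  if (is.null(xyz)) xyz <- coords(structure)
  a <- structure$atoms
  ca_of <- function(range) {
    idx <- which(a$chain == hinge$chain & a$name == "CA" & !a$het &
                 a$resid >= range[1L] & a$resid <= range[2L])
    if (length(idx) < 4L)
      stop(sprintf("flank %d-%d has fewer than 4 Calpha atoms",
                   range[1L], range[2L]))
    idx[order(a$resid[idx])]
  }
  ax1 <- flank_axis(xyz[ca_of(hinge$flank_pre), , drop = FALSE])
  ax2 <- flank_axis(xyz[ca_of(hinge$flank_post), , drop = FALSE])
  rad2deg(acos(pmin(1, pmax(-1, sum(ax1 * ax2)))))
}

# Axis of a helical flank: CA positions are first smoothed with a
# one-turn (4-residue) running mean, which cancels the helical spiral, and
# the principal axis of the smoothed points is taken, oriented N -> C.
flank_axis <- function(ca) {
  n <- nrow(ca)
  if (n >= 7L) {
    sm <- t(vapply(seq_len(n - 3L), function(i)
      colMeans(ca[i:(i + 3L), , drop = FALSE]), numeric(3L)))
    principal_axis(sm)
  } else principal_axis(ca)
}

#' Bend-angle time series
#'
#' @param traj a [tec_trajectory()].
#' @param hinge a [hinge_definition()].
#' @param stride sampling stride in frames.
#' @return A series data.frame (`time_ps`, `value` degrees, `label`).
#' @export
bend_angle_series <- function(traj, hinge, stride = 1L) {
  ks <- stride_frames(traj, stride)
  vals <- vapply(ks, function(k)
    helix_bend_angle(traj$topology, hinge, xyz = traj$frames[[k]]),
    numeric(1L))
  series_result(frame_times(traj)[ks], vals, paste0("bend ", hinge$name))
}
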