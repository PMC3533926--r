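#' Hydration parameters
#'
#' Cutoffs for hydration-shell counting and tightly-bound water detection
#' around active-site centers (e.g. ATP N3, RNA 3'-O, Mg-I).  Defaults
#' follow first-solvation-shell conventions: 3.5 A water-O-to-center for
#' the shell, 2.5 A for Mg inner-sphere coordination, and a water counts
#' as tightly bound when it stays coordinated in at least 80 percent of
#' sampled frames.
#'
#' @param shell_cutoff shell radius, A (water O to center).
#' @param bound_cutoff coordination radius for bound waters, A; must not
#'   exceed `shell_cutoff`.
#' @param residence_min minimum residence fraction in (0, 1\] for a water
#'   to be called bound.
#' @return An object of class `hydration_params`.
#' @export
hydration_params <- function(shell_cutoff = 3.5, bound_cutoff = 2.5,
                             residence_min = 0.8) {
  stopifnot(shell_cutoff > 0, bound_cutoff > 0,
            bound_cutoff <= shell_cutoff,
            residence_min > 0, residence_min <= 1)
  structure(list(shell_cutoff = shell_cutoff, bound_cutoff = bound_cutoff,
                 residence_min = residence_min),
            class = "hydration_params")
}

# Water oxygen atom indices and their residue keys.  A water's position is
# its O atom (robust to absent hydrogens).
water_oxygens <- function(structure) {
  a <- structure$atoms
  idx <- which(is_water_atom(a) & (a$name == "O" | a$element == "O" |
                                   startsWith(a$name, "OW")))
  list(idx = idx, residue = residue_key_of_atoms(a)[idx])
}

#' Count waters in a shell around a center
#'
#' Number of distinct water residues whose O atom lies within `cutoff` of
#' the named center atom in one frame.
#'
#' @param structure a [tec_structure()].
#' @param center atom key of the shell center (e.g. `"L:1:N3"` for an
#'   ATP N3, `"M:1:MG"` for Mg-I).
#' @param cutoff shell radius, A (default 3.5).
#' @param xyz optional coordinate matrix overriding the structure's own.
#' @return Integer count.
#' @export
water_count <- function(structure, center, cutoff = 3.5, xyz = NULL) {
  if (is.null(xyz)) xyz <- coords(structure)
  ic <- atom_index(structure, center)
  w <- water_oxygens(structure)
  if (!length(w$idx)) return(0L)
  d <- sqrt(rowSums((xyz[w$idx, , drop = FALSE] -
                     matrix(xyz[ic, ], length(w$idx), 3L, byrow = TRUE))^2))
  length(unique(w$residue[d <= cutoff]))
}

#' Hydration-shell time series
#'
#' [water_count()] per sampled frame; used to compare active-site
#' hydration between closed and open trigger-loop ensembles.
#'
#' @param traj a [tec_trajectory()].
#' @param center atom key of the shell center.
#' @param cutoff shell radius, A.
#' @param stride sampling stride in frames.
#' @return A series data.frame (`time_ps`, `value` = water count, `label`).
#' @export
hydration_series <- function(traj, center, cutoff = 3.5, stride = 1L) {
  stopifnot(inherits(traj, "tec_trajectory"))
  ks <- stride_frames(traj, stride)
  vals <- vapply(ks, function(k)
    water_count(traj$topology, center, cutoff, xyz = traj$frames[[k]]),
    integer(1L))
  series_result(frame_times(traj)[ks], vals, paste0("waters@", center))
}

#' Tightly bound waters at a center
#'
#' A water is bound when its O stays within `bound_cutoff` of the center
#' in at least `residence_min` of the sampled frames.  This residence
#' criterion distinguishes ordered inner-sphere waters (e.g. the one to
#' three waters coordinating Mg-I) from transient shell visitors.
#'
#' @param traj a [tec_trajectory()].
#' @param center atom key of the coordination center.
#' @param params a [hydration_params()].
#' @param stride sampling stride in frames.
#' @return List with `count` and data.frame `waters` (`residue`,
#'   `residence` fraction) for all waters ever seen inside the cutoff,
#'   sorted by residence descending.
#' @export
bound_waters <- function(traj, center, params = hydration_params(),
                         stride = 1L) {
  stopifnot(inherits(traj, "tec_trajectory"),
            inherits(params, "hydration_params"))
  top <- traj$topology
  ic <- atom_index(top, center)
  w <- water_oxygens(top)
  ks <- stride_frames(traj, stride)
  if (!length(w$idx))
    return(list(count = 0L,
                waters = data.frame(residue = character(),
                                    residence = numeric())))
  inside <- matrix(FALSE, length(w$idx), length(ks))
  for (q in seq_along(ks)) {
    xyz <- traj$frames[[ks[q]]]
    d <- sqrt(rowSums((xyz[w$idx, , drop = FALSE] -
                       matrix(xyz[ic, ], length(w$idx), 3L,
                              byrow = TRUE))^2))
    inside[, q] <- d <= params$bound_cutoff
  }
  res <- rowMeans(inside)
  seen <- res > 0
  waters <- data.frame(residue = w$residue[seen], residence = res[seen],
                       stringsAsFactors = FALSE)
  waters <- waters[order(-waters$residence, waters$residue), , drop = FALSE]
  rownames(waters) <- NULL
  list(count = sum(waters$residence >= params$residence_min),
       waters = waters)
}
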