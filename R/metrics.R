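#' Least-squares rigid-body superposition
#'
#' Kabsch superposition of a mobile coordinate set onto a reference over a
#' fit selection.  The returned rotation is proper (det = +1) and the rmsd
#' is computed over the fit atoms after the transform.
#'
#' @param mobile n x 3 coordinate matrix.
#' @param reference n x 3 coordinate matrix with matching atom order.
#' @param fit_indices integer indices of atoms used for the fit (default:
#'   all atoms).  At least 3 non-collinear atoms are required.
#' @return List with `rotation` (3 x 3), `translation` (length 3) and
#'   `rmsd` (Angstrom).  Apply with `xyz %*% t(rotation) + translation`
#'   (rows are atoms), or use [superpose_apply()].
#' @export
superpose <- function(mobile, reference, fit_indices = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (is.null(fit_indices)) fit_indices <- seq_len(nrow(mobile))
  if (length(fit_indices) < 3L)
    stop("degenerate fit: need at least 3 fit atoms")
  kabsch_fit(mobile[fit_indices, , drop = FALSE],
             reference[fit_indices, , drop = FALSE])
}

#' Apply a superposition transform to coordinates
#' @param xyz n x 3 coordinate matrix.
#' @param fit result of [superpose()].
#' @return Transformed n x 3 matrix.
#' @export
superpose_apply <- function(xyz, fit) apply_fit(as.matrix(xyz), fit)

resolve_selection <- function(structure, sel, what = "selection") {
  if (is.null(sel)) return(seq_len(n_atoms(structure)))
  if (inherits(sel, "atom_selection")) idx <- sel$indices
  else if (is.character(sel) && length(sel) == 1L)
    idx <- select_atoms(structure, sel)$indices
  else if (is.numeric(sel)) idx <- as.integer(sel)
  else stop(what, " must be an atom_selection, expression string or indices")
  if (!length(idx)) stop(what, " matches no atoms")
  idx
}

#' RMSD time series over a trajectory
#'
#' Each sampled frame is superposed onto the reference frame using
#' `fit_selection`, and the rmsd is then reported over
#' `measure_selection`.  Fitting on the protein backbone while measuring
#' nucleic-acid atoms separates protein from nucleic-acid mobility.
#'
#' @param traj a [tec_trajectory()].
#' @param reference_frame frame index of the reference (default 1).
#' @param fit_selection selection (expression, [select_atoms()] result or
#'   indices) used for the superposition.
#' @param measure_selection selection over which the rmsd is reported
#'   (default: the fit selection).
#' @param stride sampling stride in frames.
#' @return A series data.frame (`time_ps`, `value` in Angstrom, `label`).
#' @export
rmsd_series <- function(traj, reference_frame = 1L, fit_selection = NULL,
                        measure_selection = NULL, stride = 1L) {
  stopifnot(inherits(traj, "tec_trajectory"))
  fit_idx <- resolve_selection(traj$topology, fit_selection, "fit_selection")
  meas_idx <- if (is.null(measure_selection)) fit_idx
              else resolve_selection(traj$topology, measure_selection,
                                     "measure_selection")
  ref <- traj$frames[[reference_frame]]
  ks <- stride_frames(traj, stride)
  vals <- vapply(ks, function(k) {
    f <- traj$frames[[k]]
    ft <- superpose(f, ref, fit_idx)
    moved <- apply_fit(f[meas_idx, , drop = FALSE], ft)
    sqrt(mean(rowSums((moved - ref[meas_idx, , drop = FALSE])^2)))
  }, numeric(1L))
  series_result(frame_times(traj)[ks], vals, "rmsd")
}

#' Inter-atom distance time series
#'
#' Euclidean distance between two named atoms at every sampled frame, e.g.
#' the RNA 3'-O to NTP alpha-phosphate distance or the Mg-I to Mg-II
#' separation used to monitor catalytic geometry.
#'
#' @param traj a [tec_trajectory()].
#' @param atom_a,atom_b atom keys (`chain:resid:name`).
#' @param stride sampling stride in frames.
#' @param minimum_image if `TRUE` and the topology carries a box, distances
#'   use the minimum-image convention (for boxed synthetic systems).
#' @return A series data.frame (`time_ps`, `value` in Angstrom, `label`).
#' @export
distance_series <- function(traj, atom_a, atom_b, stride = 1L,
                            minimum_image = FALSE) {
  stopifnot(inherits(traj, "tec_trajectory"))
  ia <- atom_index(traj$topology, atom_a)
  ib <- atom_index(traj$topology, atom_b)
  box <- traj$topology$box
  if (minimum_image && is.null(box))
    stop("minimum_image requested but the topology has no box")
  ks <- stride_frames(traj, stride)
  vals <- vapply(ks, function(k) {
    d <- traj$frames[[k]][ia, ] - traj$frames[[k]][ib, ]
    if (minimum_image) d <- d - box * round(d / box)
    sqrt(sum(d^2))
  }, numeric(1L))
  series_result(frame_times(traj)[ks], vals,
                paste(atom_a, atom_b, sep = "--"))
}
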