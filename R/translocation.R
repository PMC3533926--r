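#' Define a translocation vector
#'
#' A translocation vector is drawn through two anchor atoms in the
#' reference frame; translocation is then measured as the displacement of
#' an orthogonal projection of a probe atom onto that vector, relative to
#' the reference structure.  For the downstream DNA/DNA duplex the anchors
#' are typically the 3' carbons of a template DNA base and an RNA base
#' bracketing the hybrid, with a non-template DNA 3' carbon as the probe;
#' an analogous construction monitors the upstream RNA/DNA hybrid.
#'
#' @param anchor_a,anchor_b atom keys defining the axis (a -> b is the
#'   forward, positive direction).
#' @param probe atom key whose projected displacement is reported.
#' @param label `"upstream"`, `"downstream"` or a custom tag.
#' @return An object of class `translocation_spec`.
#' @export
translocation_spec <- function(anchor_a, anchor_b, probe,
                               label = "custom") {
  keys <- normalize_atom_name(c(anchor_a, anchor_b, probe))
  if (anyDuplicated(keys))
    stop("anchor_a, anchor_b and probe must be three distinct atoms")
  structure(list(anchor_a = keys[1L], anchor_b = keys[2L], probe = keys[3L],
                 label = label),
            class = "translocation_spec")
}

# Unit axis a -> b in the reference frame.
translocation_axis <- function(topology, reference, spec) {
  ia <- atom_index(topology, spec$anchor_a)
  ib <- atom_index(topology, spec$anchor_b)
  ax <- reference[ib, ] - reference[ia, ]
  if (vnorm(ax) < 1e-6)
    stop("degenerate translocation vector: anchors coincide in reference")
  vunit(ax)
}

#' Projected displacement of the probe along a translocation vector
#'
#' The axis `u` is the unit vector from `anchor_a` to `anchor_b` computed
#' in the reference frame and held fixed; the returned value is
#' `dot(probe_frame - probe_reference, u)` so the reference frame maps to
#' exactly 0 and positive values mean forward translocation.  The frame is
#' expected to be already superposed onto the reference on a protein-core
#' fit selection (see [translocation_series()], which does this per frame).
#'
#' @param frame n x 3 coordinate matrix of the (superposed) frame.
#' @param reference n x 3 reference coordinate matrix.
#' @param spec a [translocation_spec()].
#' @param topology the [tec_structure()] naming the atoms.
#' @param per_frame_axis recompute the axis in `frame` instead of the
#'   reference (off by default: a per-frame axis conflates axis rotation
#'   with translocation).
#' @return Displacement in Angstrom.
#' @export
projected_displacement <- function(frame, reference, spec, topology,
                                   per_frame_axis = FALSE) {
  stopifnot(inherits(spec, "translocation_spec"))
  u <- translocation_axis(topology, if (per_frame_axis) frame else reference,
                          spec)
  ip <- atom_index(topology, spec$probe)
  sum((frame[ip, ] - reference[ip, ]) * u)
}

#' Translocation time series
#'
#' Each sampled frame is superposed onto the reference frame over
#' `fit_selection` (default: all protein Calpha atoms), then the projected
#' displacement is evaluated for each supplied vector spec.
#'
#' @param traj a [tec_trajectory()].
#' @param downstream,upstream [translocation_spec()] objects (either may be
#'   omitted).
#' @param fit_selection protein-core selection used for the per-frame
#'   superposition; defaults to all Calpha atoms.
#' @param stride sampling stride in frames (default 1; with the default
#'   20 ps frame interval each point then represents a 20 ps interval).
#' @param reference_frame index of the reference frame (default 1).
#' @return data.frame with columns `time_ps` and one column per supplied
#'   spec label, class `translocation_points`.
#' @export
translocation_series <- function(traj, downstream = NULL, upstream = NULL,
                                 fit_selection = NULL, stride = 1L,
                                 reference_frame = 1L) {
  stopifnot(inherits(traj, "tec_trajectory"))
  specs <- Filter(Negate(is.null), list(downstream = downstream,
                                        upstream = upstream))
  if (!length(specs)) stop("supply at least one translocation_spec")
  top <- traj$topology
  fit_idx <- if (is.null(fit_selection)) {
    idx <- which(top$atoms$name == "CA" & !top$atoms$het)
    if (length(idx) < 3L) stop("no usable default Calpha fit selection; pass fit_selection")
    idx
  } else resolve_selection(top, fit_selection, "fit_selection")
  ref <- traj$frames[[reference_frame]]
  ks <- stride_frames(traj, stride)
  out <- data.frame(time_ps = frame_times(traj)[ks])
  vals <- lapply(specs, function(sp) vapply(ks, function(k) {
    ft <- superpose(traj$frames[[k]], ref, fit_idx)
    moved <- apply_fit(traj$frames[[k]], ft)
    tryCatch(projected_displacement(moved, ref, sp, top),
             error = function(e)
               stop(sprintf("frame %d: %s", k, conditionMessage(e))))
  }, numeric(1L)))
  for (nm in names(vals)) out[[sp_label <- nm]] <- vals[[nm]]
  class(out) <- c("translocation_points", "data.frame")
  out
}

#' Summarise translocation points
#'
#' Reports arithmetic means of each component and the final point (the
#' trajectory endpoint, the "X" in a translocation scatter plot).
#'
#' @param points result of [translocation_series()].
#' @param window `"full"` for means over all points, or an integer k for
#'   means over the last k points.
#' @return List with `mean` (named numeric), `endpoint` (named numeric)
#'   and `n` points used for the mean.
#' @export
translocation_summary <- function(points, window = "full") {
  if (!nrow(points)) stop("no translocation points to summarise")
  comp <- setdiff(names(points), "time_ps")
  n <- nrow(points)
  use <- if (identical(window, "full")) seq_len(n)
         else seq(max(1L, n - as.integer(window) + 1L), n)
  list(mean = vapply(comp, function(cn) mean(points[[cn]][use]), numeric(1L)),
       endpoint = vapply(comp, function(cn) points[[cn]][n], numeric(1L)),
       n = length(use))
}

#' Per-base-pair projected displacement
#'
#' Displacement of each base-pair midpoint along the translocation axis,
#' relative to the reference frame.  Used to ask whether individual
#' downstream base pairs advance a full step while others lag.
#'
#' @param frame n x 3 (superposed) frame coordinates.
#' @param reference n x 3 reference coordinates.
#' @param basepair_atom_pairs list of length-2 character vectors of atom
#'   keys, one pair per base pair.
#' @param spec a [translocation_spec()] supplying the axis.
#' @param topology the [tec_structure()].
#' @return Numeric vector, one signed displacement (Angstrom) per pair.
#' @export
per_basepair_displacement <- function(frame, reference, basepair_atom_pairs,
                                      spec, topology) {
  u <- translocation_axis(topology, reference, spec)
  vapply(basepair_atom_pairs, function(pr) {
    if (length(pr) != 2L) stop("each base pair needs exactly two atom keys")
    idx <- atom_index(topology, pr)
    mid_f <- colMeans(frame[idx, , drop = FALSE])
    mid_r <- colMeans(reference[idx, , drop = FALSE])
    sum((mid_f - mid_r) * u)
  }, numeric(1L))
}
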