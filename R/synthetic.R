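# Synthetic toy elongation-complex generator.  Produces a small TEC-like
# system -- a bendable alpha-helix (bridge-helix stand-in), a rigid
# base-paired nucleic ladder that can drift along a translocation axis,
# two Mg ions, an ATP-like ligand, planted switch side chains and explicit
# waters -- with every planted truth recoverable by the analysis modules.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Ideal backbone internal coordinates (Engh-Huber-like averages).
BB_GEOM <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                b_c_o = 1.231, a_n_ca_c = 111.2, a_ca_c_n = 116.2,
                a_c_n_ca = 121.7, a_ca_c_o = 120.8)

# Build an ideal polypeptide backbone from phi/psi (degrees; scalars or
# per-residue vectors).  Returns a list of n x 3 matrices N, CA, C, O.
build_backbone <- function(n, phi, psi, omega = 180) {
  g <- BB_GEOM
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  omega <- rep_len(omega, n)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(g$b_n_ca, 0, 0)
  th <- deg2rad(g$a_n_ca_c)
  C[1L, ] <- CA[1L, ] + g$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o,
                         psi[i] + 180)
    if (i == n) break
    N[i + 1L, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], g$b_c_n, g$a_ca_c_n,
                              psi[i])
    CA[i + 1L, ] <- nerf_place(CA[i, ], C[i, ], N[i + 1L, ], g$b_n_ca,
                               g$a_c_n_ca, omega[i])
    C[i + 1L, ] <- nerf_place(C[i, ], N[i + 1L, ], CA[i + 1L, ], g$b_ca_c,
                              g$a_n_ca_c, phi[i + 1L])
  }
  list(N = N, CA = CA, C = C, O = O)
}

backbone_atom_table <- function(bb, chain, resname = "ALA",
                                start_resid = 1L, start_serial = 1L) {
  n <- nrow(bb$N)
  ord <- c("N", "CA", "C", "O")
  rows <- lapply(seq_len(n), function(i) {
    xyz <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ])
    data.frame(serial = 0L, name = ord, resname = resname, chain = chain,
               resid = start_resid + i - 1L, inscode = "",
               element = c("N", "C", "C", "O"), het = FALSE,
               x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
               stringsAsFactors = FALSE)
  })
  at <- do.call(rbind, rows)
  at$serial <- start_serial + seq_len(nrow(at)) - 1L
  at
}

# Rigid transform of an atom table so the CA principal axis runs along +z
# (N terminus at low z) and the CA centroid sits at `center`.
align_backbone_z <- function(at, center = c(0, 0, 0)) {
  ca <- as.matrix(at[at$name == "CA", c("x", "y", "z")])
  ax <- principal_axis(ca)
  z <- c(0, 0, 1)
  v <- vcross(ax, z)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (vnorm(v) > 1e-8) {
    ang <- rad2deg(atan2(vnorm(v), sum(ax * z)))
    xyz <- rotate_points(xyz, colMeans(ca), v, ang)
  } else if (sum(ax * z) < 0) {
    xyz <- rotate_points(xyz, colMeans(ca), c(1, 0, 0), 180)
  }
  ca2 <- xyz[at$name == "CA", , drop = FALSE]
  xyz <- sweep(xyz, 2L, colMeans(ca2) - center, "-")
  at[, c("x", "y", "z")] <- xyz
  at
}

#' Build an ideal alpha-helix
#'
#' Canonical helix built from ideal backbone geometry with phi = -57.8,
#' psi = -47 degrees (1.5 A rise, ~100 degree twist per residue), axis
#' along +z.
#'
#' @param n number of residues.
#' @param chain chain id.
#' @param center helix CA centroid.
#' @return A [tec_structure()] with N, CA, C, O atoms per residue.
#' @export
build_ideal_helix <- function(n = 20L, chain = "A", center = c(0, 0, 0)) {
  bb <- build_backbone(n, phi = -57.8, psi = -47.0)
  at <- align_backbone_z(backbone_atom_table(bb, chain), center)
  tec_structure(at, title = sprintf("ideal alpha-helix, %d residues", n))
}

#' Build an extended (beta-like) chain
#'
#' @param n number of residues.
#' @param chain chain id.
#' @return A [tec_structure()]; interior residues have |psi| > 120.
#' @export
build_extended_chain <- function(n = 12L, chain = "A") {
  bb <- build_backbone(n, phi = -135, psi = 135)
  tec_structure(backbone_atom_table(bb, chain),
                title = sprintf("extended chain, %d residues", n))
}

#' Build an ideal two-strand antiparallel beta sheet
#'
#' Two ideal strands (phi = -139, psi = 135) in antiparallel register.
#' The second strand's rigid placement is found deterministically by
#' least-squares refinement of the canonical narrow-pair hydrogen-bond
#' pattern (N(H)...O and O...(H)N at 2.9 A between alternating opposite
#' residues, i with n+1-i), with a clash penalty, from a small fixed set
#' of flip-axis starting guesses.
#'
#' @param n residues per strand (even values give a clean register).
#' @return A [tec_structure()] with chains `A` and `B`.
#' @export
build_antiparallel_sheet <- function(n = 8L) {
  bb <- build_backbone(n, phi = -139, psi = 135)
  atA <- backbone_atom_table(bb, "A")
  xyzA <- as.matrix(atA[, c("x", "y", "z")])
  caA <- xyzA[atA$name == "CA", , drop = FALSE]
  d <- principal_axis(caA)
  e1 <- vunit(vcross(d, if (abs(d[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  e2 <- vcross(d, e1)
  cen <- colMeans(caA)
  N_idx <- which(atA$name == "N")
  O_idx <- which(atA$name == "O")
  C_idx <- which(atA$name == "C")
  # amide H of residue i >= 2: N + unit(C_prev - O_prev)
  H_A <- matrix(NA_real_, n, 3L)
  for (i in 2:n)
    H_A[i, ] <- xyzA[N_idx[i], ] +
      vunit(xyzA[C_idx[i - 1L], ] - xyzA[O_idx[i - 1L], ])
  # narrow (doubly hydrogen-bonded) pairs: alternating i, partner n+1-i
  narrow <- seq(2L, n - 1L, by = 2L)
  place <- function(p, X) {
    rv <- p[1:3]
    th <- sqrt(sum(rv^2))
    x <- sweep(X, 2L, cen)
    if (th > 1e-9) x <- x %*% t(rotation_matrix(rv / th, rad2deg(th)))
    sweep(x, 2L, cen + p[4:6], "+")
  }
  # target both the N...O separation and a collinear N-H...O approach
  # (H...O 1.9 A); distance alone leaves the amide pointing the wrong way
  objective <- function(p) {
    xb <- place(p, xyzA)
    hB <- place(p, H_A)
    sc <- 0
    for (i in narrow) {
      j <- n + 1L - i
      if (i >= 2L)
        sc <- sc + (vnorm(xyzA[N_idx[i], ] - xb[O_idx[j], ]) - 2.9)^2 +
                   (vnorm(H_A[i, ] - xb[O_idx[j], ]) - 1.9)^2
      if (j >= 2L)
        sc <- sc + (vnorm(xb[N_idx[j], ] - xyzA[O_idx[i], ]) - 2.9)^2 +
                   (vnorm(hB[j, ] - xyzA[O_idx[i], ]) - 1.9)^2
    }
    sc + sum(pmax(0, 2.6 - pair_dist_matrix(xyzA, xb))^2)
  }
  # the 2-fold axis relating antiparallel strands is close to the sheet
  # normal (e2), so those starts are tried first
  starts <- list()
  for (axv in list(e2, e1, vunit(e1 + e2), vunit(e1 - e2)))
    for (s1 in c(4.8, -4.8)) for (s2 in c(0, -1.7, 1.7))
      starts[[length(starts) + 1L]] <- c(axv * pi, s1 * e1 + s2 * d)
  best <- NULL
  for (p0 in starts) {
    o1 <- stats::optim(p0, objective, method = "Nelder-Mead",
                       control = list(maxit = 1000, reltol = 1e-10))
    o2 <- stats::optim(o1$par, objective, method = "BFGS",
                       control = list(maxit = 300, reltol = 1e-12))
    if (is.null(best) || o2$value < best$value) best <- o2
    # residual ~1e-4 A^2 over 12 targets is already sub-0.01 A precision
    if (best$value < 1e-3) break
  }
  atB <- atA
  atB$chain <- "B"
  atB[, c("x", "y", "z")] <- place(best$par, xyzA)
  at <- rbind(atA, atB)
  at$serial <- seq_len(nrow(at))
  tec_structure(at, title = sprintf("antiparallel sheet, 2 x %d residues", n))
}

#' Parameters of the toy elongation complex
#'
#' Defaults mirror the scale of the real analyses: a 38-residue helix
#' (the bridge-helix length), a 10 base-pair nucleic ladder (an RNA/DNA
#' hybrid-sized duplex), 500 frames at 20 ps (a 10 ns production run),
#' a forward drift of 0.3 A/ns along the duplex axis (a ~3 A forward
#' translocation over the run, the magnitude seen for an open-trigger-loop
#' complex), three resident waters coordinating Mg-I, a bath of transient
#' waters bringing the system to roughly 2,000 atoms, and 0.2 A thermal
#' jitter per coordinate.
#'
#' @param helix_length helix residues.
#' @param hinge_position resid of the hinge residue within the helix.
#' @param bend_schedule list of `c(frame, degrees)` steps: from `frame`
#'   onward the post-hinge half is rotated by `degrees` about a
#'   perpendicular axis through the hinge CA.
#' @param psi_schedule list of `c(resid, frame, degrees)` steps: from
#'   `frame` onward the backbone is rotated about that residue's CA-C
#'   bond, changing its psi by exactly `degrees`.
#' @param duplex_length ladder base pairs.
#' @param translocation_drift ladder drift along its axis, A/ns.
#' @param n_waters shell spec: list of `list(center = key, distance = A,
#'   count = n, resident = TRUE/FALSE)` planted waters.
#' @param n_transient_waters randomly-walking bath waters.
#' @param contact_swap list with `residue`, `partner_a`, `partner_b`
#'   (resids on the helix) and `swap_frame` (first frame at which the
#'   switch side chain contacts partner_b instead of partner_a; `Inf`
#'   means never).
#' @param noise_sigma isotropic Gaussian jitter per coordinate, A.
#' @param n_frames number of frames.
#' @param frame_interval ps between frames.
#' @param seed integer seed fixing the entire output bit-for-bit.
#' @return List of class `toy_tec_params`.
#' @export
toy_tec_params <- function(helix_length = 38L, hinge_position = 19L,
                           bend_schedule = list(), psi_schedule = list(),
                           duplex_length = 10L, translocation_drift = 0.3,
                           n_waters = list(list(center = "M:1:MG",
                                                distance = 2.0, count = 3L,
                                                resident = TRUE)),
                           n_transient_waters = 1600L,
                           contact_swap = list(residue = 10L,
                                               partner_a = 14L,
                                               partner_b = 6L,
                                               swap_frame = Inf),
                           noise_sigma = 0.2, n_frames = 500L,
                           frame_interval = 20, seed = 1L) {
  stopifnot(helix_length >= 12L, hinge_position > 4L,
            hinge_position < helix_length - 4L, duplex_length >= 2L,
            n_transient_waters >= 0L, noise_sigma >= 0, n_frames >= 1L,
            frame_interval > 0)
  structure(list(helix_length = as.integer(helix_length),
                 hinge_position = as.integer(hinge_position),
                 bend_schedule = bend_schedule,
                 psi_schedule = psi_schedule,
                 duplex_length = as.integer(duplex_length),
                 translocation_drift = translocation_drift,
                 n_waters = n_waters,
                 n_transient_waters = as.integer(n_transient_waters),
                 contact_swap = contact_swap,
                 noise_sigma = noise_sigma,
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 seed = as.integer(seed)),
            class = "toy_tec_params")
}

#' Build the toy elongation complex
#'
#' Assembles the helix (chain A, ALA backbone with LYS/ASP pseudo side
#' chains on the planted switch residues), the base-paired ladder (chains
#' T and N, DT/DA residues carrying C3' atoms), Mg-I and Mg-II (chain M),
#' an ATP-like ligand with an N3 atom (chain L), planted shell waters and
#' the transient water bath (chain W, HOH).  Placement is deterministic
#' given the seed; overlapping placements closer than 1.5 A abort.
#'
#' @param params a [toy_tec_params()].
#' @return A [tec_structure()] with a `"toy_info"` attribute recording the
#'   planted ground truth (axis, anchors, switch atoms, resident waters).
#' @export
build_toy_tec <- function(params = toy_tec_params()) {
  stopifnot(inherits(params, "toy_tec_params"))
  with_seed(params$seed, build_toy_tec_impl(params))
}

build_toy_tec_impl <- function(params) {
  L <- params$helix_length
  bb <- build_backbone(L, phi = -57.8, psi = -47.0)
  helix <- align_backbone_z(backbone_atom_table(bb, "A"), c(-8, 0, 0))

  # pseudo side chains: NZ on the switch residue (LYS), OD1 on partners
  sw <- params$contact_swap
  helix$resname[helix$resid == sw$residue] <- "LYS"
  helix$resname[helix$resid %in% c(sw$partner_a, sw$partner_b)] <- "ASP"
  hx <- as.matrix(helix[, c("x", "y", "z")])
  axis_pt <- c(-8, 0, 0)
  radial <- function(resid) {
    ca <- hx[helix$name == "CA" & helix$resid == resid, ]
    vunit(c(ca[1L] - axis_pt[1L], ca[2L] - axis_pt[2L], 0))
  }
  side_atom <- function(resid, name, resname, pos) {
    data.frame(serial = 0L, name = name, resname = resname, chain = "A",
               resid = resid, inscode = "", element = substr(name, 1L, 1L),
               het = FALSE, x = pos[1L], y = pos[2L], z = pos[3L],
               stringsAsFactors = FALSE)
  }
  od1 <- function(resid) {
    ca <- hx[helix$name == "CA" & helix$resid == resid, ]
    ca + 2.4 * radial(resid)
  }
  posA <- od1(sw$partner_a)
  posB <- od1(sw$partner_b)
  nz0 <- posA + 2.8 * radial(sw$partner_a)
  side <- rbind(side_atom(sw$partner_a, "OD1", "ASP", posA),
                side_atom(sw$partner_b, "OD1", "ASP", posB),
                side_atom(sw$residue, "NZ", "LYS", nz0))

  # nucleic ladder along +z at x = +8: template chain T (DT), non-template
  # chain N (DA); one C3' pseudo-atom per nucleotide
  D <- params$duplex_length
  zlad <- 3.4 * (seq_len(D) - (D + 1) / 2)
  ladder <- do.call(rbind, lapply(seq_len(D), function(i) {
    data.frame(serial = 0L, name = "C3'", resname = c("DT", "DA"),
               chain = c("T", "N"), resid = i, inscode = "",
               element = "C", het = FALSE,
               x = 8, y = c(-2, 2), z = zlad[i],
               stringsAsFactors = FALSE)
  }))

  hetrow <- function(name, resname, chain, resid, pos, element = name) {
    data.frame(serial = 0L, name = name, resname = resname, chain = chain,
               resid = resid, inscode = "", element = element, het = TRUE,
               x = pos[1L], y = pos[2L], z = pos[3L],
               stringsAsFactors = FALSE)
  }
  mg <- rbind(hetrow("MG", "MG", "M", 1L, c(0, 0, 0), "MG"),
              hetrow("MG", "MG", "M", 2L, c(3.9, 0, 0), "MG"))
  atp <- rbind(hetrow("N3", "ATP", "L", 1L, c(0, 5, 0), "N"),
               hetrow("PA", "ATP", "L", 1L, c(2.5, 5, 1.5), "P"))

  solute <- rbind(helix, side, ladder, mg, atp)
  solute_xyz <- as.matrix(solute[, c("x", "y", "z")])

  # planted shell waters: spread on a sphere of the requested radius
  # around each center by a golden-angle spiral
  waters <- list()
  resident_info <- list()
  wresid <- 0L
  for (spec in params$n_waters) {
    ic <- which(atom_keys_from_table(solute) ==
                normalize_atom_name(spec$center))
    if (length(ic) != 1L)
      stop("shell-spec center not found in solute: ", spec$center)
    cpos <- solute_xyz[ic, ]
    cnt <- spec$count
    if (cnt == 0L) next
    gold <- pi * (3 - sqrt(5))
    for (q in seq_len(cnt)) {
      zz <- if (cnt == 1L) 0 else (2 * (q - 1) / (cnt - 1) - 1) * 0.8
      rr <- sqrt(1 - zz^2)
      dir <- c(rr * cos(gold * (q - 1)), rr * sin(gold * (q - 1)), zz)
      wresid <- wresid + 1L
      waters[[length(waters) + 1L]] <-
        hetrow("O", "HOH", "W", wresid, cpos + spec$distance * dir, "O")
      if (isTRUE(spec$resident))
        resident_info[[length(resident_info) + 1L]] <-
          list(residue = paste0("W:", wresid), center = spec$center,
               offset = spec$distance * dir)
    }
  }
  planted <- if (length(waters)) do.call(rbind, waters) else NULL
  planted_xyz <- if (!is.null(planted))
    as.matrix(planted[, c("x", "y", "z")]) else matrix(0, 0L, 3L)

  # transient bath: jittered grid inside a 20 A sphere around the active
  # site, keeping 2.5 A clear of everything already placed
  nT <- params$n_transient_waters
  trans <- NULL
  if (nT > 0L) {
    g <- seq(-19.5, 19.5, by = 2.6)
    grid <- as.matrix(expand.grid(x = g, y = g, z = g))
    grid <- grid + matrix(stats::runif(length(grid), -0.4, 0.4),
                          nrow(grid), 3L)
    grid <- grid[sqrt(rowSums(grid^2)) <= 20, , drop = FALSE]
    occupied <- rbind(solute_xyz, planted_xyz)
    dmat <- pair_dist_matrix(grid, occupied)
    keep <- apply(dmat, 1L, min) >= 2.5
    # keep the bath out of the occupied inner coordination spheres
    for (spec in params$n_waters) {
      ic <- which(atom_keys_from_table(solute) ==
                  normalize_atom_name(spec$center))
      dc <- sqrt(rowSums(sweep(grid, 2L, solute_xyz[ic, ])^2))
      keep <- keep & dc >= 4.5
    }
    grid <- grid[keep, , drop = FALSE]
    if (nrow(grid) < nT)
      stop(sprintf("cannot place %d transient waters (%d clash-free sites)",
                   nT, nrow(grid)))
    pick <- sort(sample.int(nrow(grid), nT))
    trans <- do.call(rbind, lapply(seq_len(nT), function(q) {
      hetrow("O", "HOH", "W", wresid + q, grid[pick[q], ], "O")
    }))
  }

  at <- rbind(solute, planted, trans)
  at$serial <- seq_len(nrow(at))
  st <- tec_structure(at, title = "synthetic toy TEC")

  # overlap check on planted placements (bonded backbone pairs excluded by
  # only checking het/side-chain placements against everything)
  xyz <- coords(st)
  extra <- which(at$het | at$name %in% c("NZ", "OD1") | at$chain %in% c("T", "N"))
  if (length(extra)) {
    dm <- pair_dist_matrix(xyz[extra, , drop = FALSE], xyz)
    dm[cbind(seq_along(extra), extra)] <- Inf
    if (min(dm) < 1.5)
      stop("geometric impossibility: planted atoms closer than 1.5 A")
  }

  attr(st, "toy_info") <- list(
    params = params,
    axis = c(0, 0, 1),
    helix_chain = "A",
    ladder_chains = c("T", "N"),
    anchor_a = sprintf("T:%d:C3'", 1L),
    anchor_b = sprintf("T:%d:C3'", D),
    probe = sprintf("N:%d:C3'", max(1L, D %/% 2L)),
    switch_atom = sprintf("A:%d:NZ", sw$residue),
    od1_a = sprintf("A:%d:OD1", sw$partner_a),
    od1_b = sprintf("A:%d:OD1", sw$partner_b),
    switch_off_a = 2.8 * radial(sw$partner_a),
    switch_off_b = 2.8 * radial(sw$partner_b),
    partner_a = sprintf("A:%d", sw$partner_a),
    partner_b = sprintf("A:%d", sw$partner_b),
    resident_waters = resident_info)
  st
}

#' Simulate a toy trajectory with planted ground truth
#'
#' Per frame: apply the scheduled hinge bend (rigid rotation of the
#' post-hinge half about a perpendicular axis through the hinge CA) and
#' any scheduled psi rotation (about the residue's CA-C bond, changing
#' its psi by exactly the scheduled angle), translate the ladder by
#' `drift * t` along the translocation axis, teleport the planted switch
#' side chain between its two partners at `swap_frame`, let resident
#' waters track their center and transient waters random-walk (reflected
#' at a 20 A sphere), then jitter all atoms with isotropic Gaussian noise.
#' Fully deterministic given the seed carried by `params`.
#'
#' @param structure a [build_toy_tec()] structure.
#' @param params the [toy_tec_params()] used to build it (defaults to the
#'   parameters recorded in the structure).
#' @return A [tec_trajectory()] (frame 1 is the unperturbed-but-jittered
#'   reference at t = 0), carrying the same `"toy_info"` attribute.
#' @export
simulate_trajectory <- function(structure, params = NULL) {
  info <- attr(structure, "toy_info")
  if (is.null(info)) stop("structure was not built by build_toy_tec")
  if (is.null(params)) params <- info$params
  with_seed(params$seed + 104729L,
            simulate_trajectory_impl(structure, params, info))
}

simulate_trajectory_impl <- function(structure, params, info) {
  at <- structure$atoms
  xyz0 <- coords(structure)
  n <- nrow(at)
  keys <- atom_keys(structure)
  rk <- residue_key_of_atoms(at)

  helix_idx <- which(at$chain == info$helix_chain)
  post_idx <- helix_idx[at$resid[helix_idx] > params$hinge_position]
  hinge_ca <- which(at$chain == info$helix_chain & at$name == "CA" &
                    at$resid == params$hinge_position)
  ladder_idx <- which(at$chain %in% info$ladder_chains)
  nz_idx <- which(keys == info$switch_atom)
  od1a_idx <- which(keys == info$od1_a)
  od1b_idx <- which(keys == info$od1_b)
  res_w <- info$resident_waters
  res_w_idx <- vapply(res_w, function(w)
    which(rk == w$residue & at$name == "O")[1L], integer(1L))
  res_center_idx <- vapply(res_w, function(w)
    which(keys == normalize_atom_name(w$center))[1L], integer(1L))
  all_w_idx <- which(at$chain == "W")
  trans_idx <- setdiff(all_w_idx, res_w_idx)

  # psi-schedule rotations: atoms moved are O of the residue plus every
  # later residue of the chain (rotation about the CA-C bond)
  psi_moves <- lapply(params$psi_schedule, function(s) {
    r <- s[[1L]]
    ca <- which(at$chain == info$helix_chain & at$resid == r &
                at$name == "CA")
    cc <- which(at$chain == info$helix_chain & at$resid == r &
                at$name == "C")
    mv <- which(at$chain == info$helix_chain &
                (at$resid > r | (at$resid == r & at$name == "O")))
    list(frame = s[[2L]], deg = s[[3L]], ca = ca, cc = cc, move = mv)
  })
  bend_sched <- params$bend_schedule

  sched_value <- function(sched, k, iframe, ideg) {
    val <- 0
    for (s in sched) if (k >= s[[iframe]]) val <- s[[ideg]]
    val
  }

  drift_per_ns <- params$translocation_drift
  u <- info$axis
  frames <- vector("list", params$n_frames)
  trans_pos <- xyz0[trans_idx, , drop = FALSE]
  walk_sigma <- 0.5

  for (k in seq_len(params$n_frames)) {
    t_ns <- (k - 1) * params$frame_interval / 1000
    xyz <- xyz0

    bend <- sched_value(bend_sched, k, 1L, 2L)
    if (bend != 0) {
      xyz[post_idx, ] <- rotate_points(xyz[post_idx, , drop = FALSE],
                                       xyz0[hinge_ca, ], c(1, 0, 0), bend)
    }
    for (pm in psi_moves) {
      if (k < pm$frame || pm$deg == 0) next
      ax <- xyz[pm$cc, ] - xyz[pm$ca, ]
      xyz[pm$move, ] <- rotate_points(xyz[pm$move, , drop = FALSE],
                                      xyz[pm$ca, ], ax, pm$deg)
    }
    if (drift_per_ns != 0 && t_ns > 0)
      xyz[ladder_idx, ] <- sweep(xyz[ladder_idx, , drop = FALSE], 2L,
                                 drift_per_ns * t_ns * u, "+")
    if (length(nz_idx)) {
      # the switch side chain tracks its current partner's carboxylate so
      # the planted contact survives hinge bending
      xyz[nz_idx, ] <- if (k >= params$contact_swap$swap_frame)
        xyz[od1b_idx, ] + info$switch_off_b
      else xyz[od1a_idx, ] + info$switch_off_a
    }
    if (length(res_w_idx))
      xyz[res_w_idx, ] <- xyz[res_center_idx, , drop = FALSE] +
        do.call(rbind, lapply(res_w, `[[`, "offset"))
    if (length(trans_idx)) {
      if (k > 1L) {
        step <- matrix(stats::rnorm(length(trans_idx) * 3L, 0, walk_sigma),
                       ncol = 3L)
        trans_pos <- trans_pos + step
        rr <- sqrt(rowSums(trans_pos^2))
        out <- rr > 20
        if (any(out))
          trans_pos[out, ] <- trans_pos[out, , drop = FALSE] *
            ((40 - rr[out]) / rr[out])
      }
      xyz[trans_idx, ] <- trans_pos
    }
    if (params$noise_sigma > 0)
      xyz <- xyz + matrix(stats::rnorm(n * 3L, 0, params$noise_sigma),
                          n, 3L)
    frames[[k]] <- xyz
  }
  traj <- tec_trajectory(structure, frames,
                         frame_interval = params$frame_interval)
  attr(traj, "toy_info") <- info
  traj
}

#' Parameters for simulated assay data
#'
#' @param true_k true runoff rate, 1/s.
#' @param amplitude runoff plateau amplitude.
#' @param noise_sigma additive Gaussian noise on runoff fractions.
#' @param times runoff sampling times, s (default the 5, 10, 20, 40 s
#'   grid).
#' @param misincorporation_p true misincorporation probability.
#' @param n_products number of product molecules sampled per fidelity
#'   lane.
#' @param post_without,post_with planted post-translocated fractions
#'   without/with the incoming NTP (defaults 0.25 and 0.51, the planted
#'   approximately 2-fold stimulation scenario).
#' @param band_total total band intensity per footprint lane.
#' @param band_noise_cv multiplicative (lognormal-free, Gaussian CV) band
#'   noise; 0 gives exact intensities.
#' @param replicates replicate lanes/courses.
#' @param seed integer seed.
#' @return List of class `assay_sim_params`.
#' @export
assay_sim_params <- function(true_k = 0.1, amplitude = 0.9,
                             noise_sigma = 0.02, times = c(5, 10, 20, 40),
                             misincorporation_p = 0.1, n_products = 1000L,
                             post_without = 0.25, post_with = 0.51,
                             band_total = 1000, band_noise_cv = 0.05,
                             replicates = 3L, seed = 1L) {
  stopifnot(true_k > 0, amplitude > 0, amplitude <= 1, noise_sigma >= 0,
            misincorporation_p >= 0, misincorporation_p <= 1,
            post_without > 0, post_without <= 1, post_with > 0,
            post_with <= 1, replicates >= 1L)
  structure(as.list(environment()), class = "assay_sim_params")
}

#' Simulate runoff, fidelity and footprinting assay tables
#'
#' Runoff courses follow `A (1 - exp(-k t))` plus Gaussian noise (clamped
#' to \[0, 1\]); competition-fidelity lanes draw the misincorporated
#' product count binomially from `n_products`; exonuclease III lanes carry
#' pre/post intensities around the planted fractions with multiplicative
#' noise.  Deterministic given the seed.
#'
#' @param params an [assay_sim_params()].
#' @return List with `runoff` (list of [runoff_course()]), `fidelity`
#'   (list of [band_table()] with `G10`/`A10` bands) and `exo3` (list of
#'   lists with `without`/`with` [band_table()]s), one entry per
#'   replicate.
#' @export
simulate_assay <- function(params = assay_sim_params()) {
  stopifnot(inherits(params, "assay_sim_params"))
  with_seed(params$seed + 7919L, {
    runoff <- lapply(seq_len(params$replicates), function(r) {
      f <- params$amplitude * (1 - exp(-params$true_k * params$times))
      if (params$noise_sigma > 0)
        f <- f + stats::rnorm(length(f), 0, params$noise_sigma)
      runoff_course(params$times, pmin(1, pmax(0, f)),
                    enzyme = sprintf("sim%d", r))
    })
    fidelity <- lapply(seq_len(params$replicates), function(r) {
      nerr <- stats::rbinom(1L, params$n_products, params$misincorporation_p)
      g <- params$n_products - nerr
      noise <- function(x) if (params$band_noise_cv > 0)
        x * pmax(0, 1 + stats::rnorm(1L, 0, params$band_noise_cv)) else x
      band_table(sprintf("fid%d", r),
                 c(G10 = noise(g), A10 = noise(nerr)))
    })
    exo3 <- lapply(seq_len(params$replicates), function(r) {
      mk <- function(post, tag) {
        pre <- params$band_total * (1 - post)
        pst <- params$band_total * post
        if (params$band_noise_cv > 0) {
          pre <- pre * pmax(0, 1 + stats::rnorm(1L, 0, params$band_noise_cv))
          pst <- pst * pmax(0, 1 + stats::rnorm(1L, 0, params$band_noise_cv))
        }
        band_table(sprintf("exo3_%s_%d", tag, r), c(pre = pre, post = pst))
      }
      list(without = mk(params$post_without, "noNTP"),
           with = mk(params$post_with, "NTP"))
    })
    list(runoff = runoff, fidelity = fidelity, exo3 = exo3)
  })
}
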