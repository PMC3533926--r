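#' Run configuration for the closed-vs-open comparison pipeline
#'
#' Validated container for everything [run_compare()] needs.  Unknown
#' fields are rejected so that typos in config files fail before any
#' computation.  Trajectories may be given as in-memory
#' [tec_trajectory()] objects or as `topology`/`trajectory` file paths.
#'
#' @param traj_a,traj_b the two ensembles (e.g. closed and open trigger
#'   loop): [tec_trajectory()] objects, or lists
#'   `list(topology = path, trajectory = path)`.
#' @param downstream,upstream optional lists `list(anchor_a =, anchor_b =,
#'   probe =)` of atom keys defining translocation vectors.
#' @param fit_selection selection expression for the per-frame
#'   superposition (default: all Calpha atoms).
#' @param hinges named list of [hinge_definition()] objects.
#' @param dpsi_residues character vector of `chain:resid` residue keys to
#'   monitor with delta-psi.
#' @param ss_chain chain id for the secondary-structure timeline (NULL
#'   disables it).
#' @param switch_candidates residue keys screened for switching contacts.
#' @param hydration_centers atom keys of hydration centers.
#' @param criteria a [contact_criteria()].
#' @param hydration a [hydration_params()].
#' @param occupancy_delta switch-call threshold.
#' @param stride analysis stride, frames.
#' @param out_dir output directory.
#' @param seed integer recorded in the manifest (analyses themselves are
#'   deterministic).
#' @return List of class `run_config`.
#' @export
run_config <- function(traj_a, traj_b, downstream = NULL, upstream = NULL,
                       fit_selection = NULL, hinges = list(),
                       dpsi_residues = character(), ss_chain = NULL,
                       switch_candidates = character(),
                       hydration_centers = character(),
                       criteria = contact_criteria(),
                       hydration = hydration_params(),
                       occupancy_delta = 0.5, stride = 1L,
                       out_dir = "tecdyn_compare", seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  known <- c("traj_a", "traj_b", "downstream", "upstream", "fit_selection",
             "hinges", "dpsi_residues", "ss_chain", "switch_candidates",
             "hydration_centers", "criteria", "hydration",
             "occupancy_delta", "stride", "out_dir", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown run_config field(s): ", paste(unknown, collapse = ", "))
  for (side in c("traj_a", "traj_b")) {
    tr <- cfg[[side]]
    if (inherits(tr, "tec_trajectory")) next
    if (is.list(tr) && all(c("topology", "trajectory") %in% names(tr))) {
      for (p in unlist(tr[c("topology", "trajectory")]))
        if (!file.exists(p)) stop(side, ": input file not found: ", p)
    } else stop(side, " must be a tec_trajectory or list(topology=, trajectory=)")
  }
  for (sp in c("downstream", "upstream")) {
    v <- cfg[[sp]]
    if (!is.null(v) && !all(c("anchor_a", "anchor_b", "probe") %in% names(v)))
      stop(sp, " needs fields anchor_a, anchor_b, probe")
  }
  invisible(cfg)
}

#' Load a run configuration from a YAML file
#'
#' Scalar fields map directly onto [run_config()] arguments; `hinges`
#' entries are lists with `name`, `chain`, `residues`, `flank_pre`,
#' `flank_post`; `criteria` and `hydration` are key-value blocks.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  if (!is.null(y$hinges))
    y$hinges <- lapply(y$hinges, function(h)
      hinge_definition(h$name, h$chain, unlist(h$residues),
                       unlist(h$flank_pre), unlist(h$flank_post)))
  if (!is.null(y$criteria)) y$criteria <- do.call(contact_criteria, y$criteria)
  if (!is.null(y$hydration)) y$hydration <- do.call(hydration_params, y$hydration)
  do.call(run_config, y)
}

load_config_traj <- function(tr) {
  if (inherits(tr, "tec_trajectory")) return(tr)
  top <- read_structure(tr$topology)
  read_trajectory(top, tr$trajectory)
}

#' Run the full closed-vs-open comparison
#'
#' Runs translocation series/summary, hinge bend and delta-psi metrics,
#' secondary-structure timelines, switch-residue detection and hydration
#' analysis on two trajectories and writes one TSV per metric plus a
#' combined summary table and a JSON run manifest (package version,
#' config hash, input hashes).  Output is written to a staging directory
#' and moved into place only on success, so a failing run leaves no
#' partial outputs.  Re-running an identical config on identical inputs
#' reproduces byte-identical outputs.
#'
#' @param config a [run_config()] (or path to a YAML config).
#' @return Invisibly, the output directory path.
#' @export
run_compare <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  validate_run_config(config)
  ta <- load_config_traj(config$traj_a)
  tb <- load_config_traj(config$traj_b)

  stage <- tempfile("tecdyn_compare_")
  dir.create(stage, recursive = TRUE)
  emit <- function(df, name) {
    utils::write.table(df, file.path(stage, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  summary_rows <- list()
  note <- function(metric, ensemble, value) {
    summary_rows[[length(summary_rows) + 1L]] <<-
      data.frame(metric = metric, ensemble = ensemble,
                 value = formatC(value, digits = 6, format = "g"),
                 stringsAsFactors = FALSE)
  }

  mk_spec <- function(v, label) if (is.null(v)) NULL else
    translocation_spec(v$anchor_a, v$anchor_b, v$probe, label)
  spec_d <- mk_spec(config$downstream, "downstream")
  spec_u <- mk_spec(config$upstream, "upstream")

  for (side in c("a", "b")) {
    tr <- if (side == "a") ta else tb
    if (!is.null(spec_d) || !is.null(spec_u)) {
      pts <- translocation_series(tr, downstream = spec_d, upstream = spec_u,
                                  fit_selection = config$fit_selection,
                                  stride = config$stride)
      emit(pts, sprintf("translocation_%s.tsv", side))
      sm <- translocation_summary(pts)
      for (cn in names(sm$mean)) {
        note(paste0("translocation_mean_", cn), side, sm$mean[[cn]])
        note(paste0("translocation_endpoint_", cn), side, sm$endpoint[[cn]])
      }
    }
    for (h in config$hinges) {
      bs <- bend_angle_series(tr, h, stride = config$stride)
      emit(bs, sprintf("bend_%s_%s.tsv", h$name, side))
      note(paste0("bend_final_", h$name), side, bs$value[nrow(bs)])
    }
    for (rk in config$dpsi_residues) {
      parts <- strsplit(rk, ":", fixed = TRUE)[[1L]]
      ds <- delta_psi_series(tr, parts[1L], as.integer(parts[2L]),
                             stride = config$stride)
      emit(ds, sprintf("dpsi_%s_%s.tsv", gsub(":", "_", rk), side))
      note(paste0("dpsi_final_", rk), side, ds$value[nrow(ds)])
    }
    if (!is.null(config$ss_chain)) {
      tl <- ss_timeline(tr, chain = config$ss_chain, stride = config$stride)
      write_ss_timeline(tl, file.path(stage,
                                      sprintf("ss_timeline_%s.tsv", side)))
    }
    for (ct in config$hydration_centers) {
      hs <- hydration_series(tr, ct, cutoff = config$hydration$shell_cutoff,
                             stride = config$stride)
      emit(hs, sprintf("hydration_%s_%s.tsv", gsub("[:']", "_", ct), side))
      bw <- bound_waters(tr, ct, config$hydration, stride = config$stride)
      note(paste0("bound_waters_", ct), side, bw$count)
    }
  }

  if (length(config$switch_candidates)) {
    sw <- switch_residues(ta, tb, config$switch_candidates,
                          criteria = config$criteria,
                          occupancy_delta = config$occupancy_delta,
                          stride = config$stride)
    emit(sw, "switches.tsv")
    for (i in seq_len(nrow(sw)))
      note(paste0("switch_score_", sw$residue[i]), "a_vs_b",
           sw$switch_score[i])
  }

  emit(do.call(rbind, summary_rows), "summary.tsv")

  manifest <- list(
    package = "tecdyn",
    version = as.character(utils::packageVersion("tecdyn")),
    seed = config$seed,
    stride = config$stride,
    config_hash = config_hash(config),
    input_hashes = input_hashes(config),
    outputs = sort(list.files(stage)))
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  out <- config$out_dir
  if (dir.exists(out)) unlink(out, recursive = TRUE)
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  ok <- file.rename(stage, out)
  if (!ok) {            # staging may sit on another filesystem
    dir.create(out, recursive = TRUE)
    file.copy(list.files(stage, full.names = TRUE), out)
    unlink(stage, recursive = TRUE)
  }
  invisible(out)
}

config_hash <- function(config) {
  cfg <- config
  # inputs are hashed separately; the output path must not affect the hash
  cfg$traj_a <- cfg$traj_b <- cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(cfg, file = tmp)
  unname(tools::md5sum(tmp))
}

input_hashes <- function(config) {
  hs <- list()
  for (side in c("traj_a", "traj_b")) {
    tr <- config[[side]]
    if (inherits(tr, "tec_trajectory")) {
      tmp <- tempfile(fileext = ".xyz")
      write_trajectory(tr, tmp)
      hs[[side]] <- unname(tools::md5sum(tmp))
      unlink(tmp)
    } else {
      hs[[side]] <- list(topology = unname(tools::md5sum(tr$topology)),
                         trajectory = unname(tools::md5sum(tr$trajectory)))
    }
  }
  hs
}
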