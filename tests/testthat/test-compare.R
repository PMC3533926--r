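# End-to-end closed-vs-open comparison pipeline on synthetic fixtures.

compare_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$fx)) {
      # ensemble A: catalytic-like (no drift, no bend, partner A)
      pa <- small_toy_params(seed = 51, n_frames = 30,
                             translocation_drift = 0)
      # ensemble B: translocating-like (forward drift, bend, partner B)
      pb <- small_toy_params(seed = 52, n_frames = 30,
                             translocation_drift = 3,
                             bend_schedule = list(c(10, 25)),
                             contact_swap = list(residue = 10L,
                                                 partner_a = 14L,
                                                 partner_b = 6L,
                                                 swap_frame = 1L))
      sa <- build_toy_tec(pa)
      sb <- build_toy_tec(pb)
      cache$fx <- list(
        pa = pa, pb = pb, sa = sa, sb = sb,
        ta = simulate_trajectory(sa, pa),
        tb = simulate_trajectory(sb, pb),
        info = attr(sa, "toy_info"))
    }
    cache$fx
  }
})

fixture_config <- function(fx, out_dir) {
  info <- fx$info
  run_config(
    traj_a = fx$ta, traj_b = fx$tb,
    downstream = list(anchor_a = info$anchor_a, anchor_b = info$anchor_b,
                      probe = info$probe),
    fit_selection = "chain A and name CA and resid 2-17",
    hinges = list(hinge_definition("H3", "A", c(19, 19), c(5, 17),
                                   c(21, 34))),
    dpsi_residues = "A:19",
    ss_chain = "A",
    switch_candidates = c("A:10", "A:25"),
    hydration_centers = "M:1:MG",
    out_dir = out_dir, seed = 7L)
}

test_that("run_config rejects unknown fields and missing inputs", {
  fx <- compare_fixture()
  cfg <- fixture_config(fx, withr::local_tempdir())
  expect_s3_class(cfg, "run_config")
  cfg$bogus_key <- 1
  expect_error(run_compare(cfg), "unknown run_config field")
  expect_error(run_config(traj_a = list(topology = "/nonexistent.pdb",
                                        trajectory = "/nonexistent.xyz"),
                          traj_b = fx$tb),
               "not found")
})

test_that("the compare pipeline flags planted differences between ensembles", {
  fx <- compare_fixture()
  out <- file.path(withr::local_tempdir(), "cmp")
  run_compare(fixture_config(fx, out))

  sw <- utils::read.table(file.path(out, "switches.tsv"), header = TRUE,
                          sep = "\t")
  expect_equal(sw$residue[1L], "A:10")
  expect_true(sw$is_switch[1L])
  expect_false(any(sw$is_switch[sw$residue == "A:25"]))

  ta_pts <- utils::read.table(file.path(out, "translocation_a.tsv"),
                              header = TRUE, sep = "\t")
  tb_pts <- utils::read.table(file.path(out, "translocation_b.tsv"),
                              header = TRUE, sep = "\t")
  # the open-like run translocates forward; the closed-like one does not
  expect_gt(mean(tb_pts$downstream) - mean(ta_pts$downstream), 0.5)

  expect_true(file.exists(file.path(out, "manifest.json")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$package, "tecdyn")
  expect_true(all(c("summary.tsv", "ss_timeline_a.tsv") %in%
                  unlist(man$outputs)))
})

test_that("identical ensembles give empty switch calls and ~zero differences", {
  fx <- compare_fixture()
  out <- file.path(withr::local_tempdir(), "same")
  cfg <- fixture_config(fx, out)
  cfg$traj_b <- fx$ta
  run_compare(cfg)
  sw <- utils::read.table(file.path(out, "switches.tsv"), header = TRUE,
                          sep = "\t")
  expect_true(all(sw$switch_score == 0))
  ta_pts <- utils::read.table(file.path(out, "translocation_a.tsv"),
                              header = TRUE, sep = "\t")
  tb_pts <- utils::read.table(file.path(out, "translocation_b.tsv"),
                              header = TRUE, sep = "\t")
  expect_equal(ta_pts$downstream, tb_pts$downstream)
})

test_that("failed runs leave no partial outputs", {
  fx <- compare_fixture()
  out <- file.path(withr::local_tempdir(), "fail")
  cfg <- fixture_config(fx, out)
  cfg$hydration_centers <- "Z:1:XX"
  expect_error(run_compare(cfg))
  expect_false(dir.exists(out))
})

test_that("reruns are byte-identical", {
  fx <- compare_fixture()
  base <- withr::local_tempdir()
  out1 <- file.path(base, "r1")
  out2 <- file.path(base, "r2")
  cfg1 <- fixture_config(fx, out1)
  cfg2 <- fixture_config(fx, out2)
  run_compare(cfg1)
  run_compare(cfg2)
  f1 <- sort(list.files(out1))
  expect_identical(f1, sort(list.files(out2)))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))),
                     label = f)
})

test_that("YAML configs load with validation", {
  fx <- compare_fixture()
  # config referencing on-disk inputs
  dir <- withr::local_tempdir()
  top_a <- file.path(dir, "top_a.pdb")
  trj_a <- file.path(dir, "traj_a.xyz")
  write_structure(fx$sa, top_a)
  write_trajectory(fx$ta, trj_a)
  cfgf <- file.path(dir, "run.yaml")
  writeLines(c(
    "traj_a:", sprintf("  topology: %s", top_a),
    sprintf("  trajectory: %s", trj_a),
    "traj_b:", sprintf("  topology: %s", top_a),
    sprintf("  trajectory: %s", trj_a),
    "dpsi_residues: A:19",
    sprintf("out_dir: %s", file.path(dir, "out")),
    "stride: 5"), cfgf)
  run_compare(cfgf)
  expect_true(file.exists(file.path(dir, "out", "summary.tsv")))
  writeLines(c("traj_a: 1", "nonsense: 2"), cfgf)
  expect_error(run_compare(cfgf), "unknown config key")
})
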