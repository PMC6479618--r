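test_that("RMSD series is zero for rigid-only motion and tracks drift", {
  s <- hairpin_fixture()$structure
  # per-frame random rigid transforms of one conformation: superposition
  # must precede the RMSD
  e_rigid <- make_ensemble(s, ensemble_spec(n_frames = 8, amplitude_sigma = 0,
                                            rigid_jitter = TRUE), seed = 5)
  expect_lt(max(rmsd_series(e_rigid)), 1e-9)

  # linearly growing deformation: monotone trend
  e_drift <- make_ensemble(s, ensemble_spec(n_frames = 50,
                                            amplitude_sigma = 0.02,
                                            drift_rate = 0.05), seed = 5)
  r <- rmsd_series(e_drift)
  expect_gt(suppressWarnings(cor(seq_along(r), r, method = "spearman")), 0.9)

  expect_error(rmsd_series(e_rigid, selection = "XX"), "empty")
})

test_that("external-reference mode compares against the reference structure", {
  s <- hairpin_fixture()$structure
  e <- make_ensemble(s, ensemble_spec(n_frames = 5, amplitude_sigma = 0.1),
                     seed = 2)
  r_ext <- rmsd_series(e, "external_reference")
  r_first <- rmsd_series(e, "first_frame")
  # frame 1 already fluctuates about the reference, so only the external
  # mode sees a nonzero first value
  expect_gt(r_ext[1], 0)
  expect_lt(r_first[1], 1e-12)
})

test_that("Rg series is mass-weighted and rigid-invariant", {
  s <- hairpin_fixture()$structure
  e <- make_ensemble(s, ensemble_spec(n_frames = 4, amplitude_sigma = 0,
                                      rigid_jitter = TRUE), seed = 9)
  rg <- rg_series(e)
  # all frames are rigid copies: identical Rg, equal to the reference's
  masses <- dsbscan:::element_mass(s$atoms$elesy)
  rg_ref <- rg_direct(as.matrix(s$atoms[, c("x", "y", "z")]), masses)
  expect_equal(rg, rep(rg_ref, 4), tolerance = 1e-9)
  # uniform weighting differs from mass weighting
  expect_false(isTRUE(all.equal(rg_series(e, mass_weighted = FALSE)[1],
                                rg[1])))
})

test_that("S-S distances are internal coordinates with exact retention counts", {
  s <- hairpin_fixture(disulfides = list(c(4, 20)))$structure
  # zero amplitude, rigid jitter on: constant bond length
  e0 <- make_ensemble(s, ensemble_spec(n_frames = 6, amplitude_sigma = 0,
                                       rigid_jitter = TRUE), seed = 1)
  ss0 <- ss_distance_series(e0, list(c(4, 20)))[["4-20"]]
  expect_equal(ss0, rep(ss0[1], 6), tolerance = 1e-9)
  expect_equal(ss0[1], 2.05, tolerance = 0.02)

  # protected bonds: noise elsewhere never moves the SG pair
  e1 <- make_ensemble(s, ensemble_spec(n_frames = 10, amplitude_sigma = 0.3,
                                       protect_ss = TRUE), seed = 1)
  ss1 <- ss_distance_series(e1, list(c(4, 20)))[["4-20"]]
  expect_equal(ss1, rep(ss1[1], 10), tolerance = 1e-9)
  expect_equal(ss_retention(ss1), 1.0)

  # breaking-bond generator: the bond separates monotonically
  e2 <- make_ensemble(s, ensemble_spec(n_frames = 30, amplitude_sigma = 0,
                                       drift_rate = 0.05,
                                       protect_ss = FALSE), seed = 1)
  ss2 <- ss_distance_series(e2, list(c(4, 20)))[["4-20"]]
  expect_gt(ss2[30], ss2[1])
  expect_lt(ss_retention(ss2), 1.0)

  expect_error(ss_distance_series(e0, list(c(3, 20))), "SG atom missing")
})

test_that("retention counts frames at or below the threshold", {
  series <- c(rep(2.0, 150), rep(2.5, 50))
  expect_equal(ss_retention(series, 2.15), 0.75)
  expect_equal(ss_retention(rep(3, 5), 2.15), 0.0)
  expect_equal(ss_retention(rep(2.1, 200), 2.15), 1.0)
  # monotone non-decreasing in the threshold
  ths <- seq(1.8, 3.0, by = 0.1)
  rets <- vapply(ths, function(t) ss_retention(series, t), numeric(1))
  expect_true(all(diff(rets) >= 0))
  expect_error(ss_retention(numeric(0)), "empty")
})

test_that("summaries flag drifting ensembles only", {
  s <- hairpin_fixture(disulfides = list(c(4, 20)))$structure
  stable <- make_ensemble(s, ensemble_spec(n_frames = 40,
                                           amplitude_sigma = 0.1), seed = 2)
  drift <- make_ensemble(s, ensemble_spec(n_frames = 40,
                                          amplitude_sigma = 0.1,
                                          drift_rate = 0.08,
                                          protect_ss = FALSE), seed = 2)
  reports <- list(stability_report(stable, bonds = list(c(4, 20)),
                                   label = "stable"),
                  stability_report(drift, bonds = list(c(4, 20)),
                                   label = "drift"))
  tab <- summarize_stability(reports)
  expect_equal(tab$unstable, c(FALSE, TRUE))
  expect_equal(tab$ss_retention_min[1], 1.0)
  expect_lt(tab$ss_retention_min[2], 1.0)
})

test_that("identical ensembles at two labels give identical rows except label", {
  s <- hairpin_fixture()$structure
  e <- make_ensemble(s, ensemble_spec(n_frames = 10, amplitude_sigma = 0.1),
                     seed = 4)
  ea <- e; ea$temperature <- 26.85
  eb <- e; eb$temperature <- 70
  tab <- summarize_stability(list(stability_report(ea, label = "x"),
                                  stability_report(eb, label = "x")))
  expect_equal(tab$rmsd_mean[1], tab$rmsd_mean[2])
  expect_equal(tab$rg_mean[1], tab$rg_mean[2])
  expect_false(tab$temperature[1] == tab$temperature[2])
})

test_that("single-frame ensembles report zero spread and no flag", {
  s <- hairpin_fixture()$structure
  e <- make_ensemble(s, ensemble_spec(n_frames = 1), seed = 1)
  tab <- summarize_stability(list(stability_report(e, label = "one")))
  expect_equal(tab$rmsd_sd, 0)
  expect_equal(tab$rg_sd, 0)
  expect_false(tab$unstable)
})
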