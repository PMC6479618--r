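test_that("native disulfide detection finds planted bonds and only those", {
  built <- hairpin_fixture(disulfides = list(c(4, 20)))
  nb <- detect_native_disulfides(built$structure)
  expect_equal(nrow(nb), 1L)
  expect_equal(c(nb$res_i, nb$res_j), c(4, 20))
  expect_equal(nb$d_ss, 2.05, tolerance = 0.02)

  # no cysteines -> empty
  free <- hairpin_fixture()$structure
  expect_equal(nrow(detect_native_disulfides(free)), 0L)

  # two free cysteines far apart -> empty
  a <- free$atoms
  a$resid[a$resno %in% c(2, 12)] <- "CYS"
  expect_equal(nrow(detect_native_disulfides(new_structure(a))), 0L)
})

test_that("each cysteine joins at most one native bond (closest wins)", {
  # three SG atoms in a row, 2.0 A apart: middle one must pair only once
  mk <- function(resno, sg_x) data.frame(
    chain = "A", resno = resno, insert = "", resid = "CYS",
    elety = c("N", "CA", "CB", "SG"), elesy = c("N", "C", "C", "S"),
    x = c(sg_x - 3, sg_x - 2, sg_x - 1, sg_x),
    y = c(0, 1, 0, 0) + resno * 1e-3, z = 0, o = 1, b = 0)
  s <- new_structure(rbind(mk(1, 0), mk(5, 2.0), mk(9, 4.05)))
  nb <- detect_native_disulfides(s)
  expect_equal(nrow(nb), 1L)
  expect_setequal(c(nb$res_i, nb$res_j), c(1, 5))
})

test_that("pair enumeration equals the brute-force oracle and respects thresholds", {
  for (built in list(hairpin_fixture(),
                     build_structure(synthetic_spec("helix", 12)))) {
    s <- built$structure
    got <- enumerate_pairs(s, design_config())
    want <- brute_force_pairs(s, 5.0, 4L)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$res_i, want$res_i)
      expect_equal(got$res_j, want$res_j)
      expect_equal(got$d_cb, want$d_cb, tolerance = 1e-9)
    }
  }

  # threshold monotonicity: tighter cutoff yields a subset
  s <- hairpin_fixture()$structure
  loose <- enumerate_pairs(s, design_config(max_cb_cb = 5.0))
  tight <- enumerate_pairs(s, design_config(max_cb_cb = 4.0))
  expect_true(all(paste(tight$res_i, tight$res_j) %in%
                  paste(loose$res_i, loose$res_j)))
  expect_true(all(tight$d_cb <= 4.0))
  # planted pair at ~4.05 A: in at 5.0, out at 4.0
  expect_true(any(loose$res_i == 4 & loose$res_j == 20))
  expect_false(any(tight$res_i == 4 & tight$res_j == 20))
})

test_that("glycine scans from CA and proline is excluded", {
  s <- toy_structure(c(1, 10, 20), c("GLY", "ALA", "PRO"),
                     list(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0)))
  got <- enumerate_pairs(s, design_config(min_seq_sep = 4))
  # only GLY1-ALA10 qualifies: PRO excluded entirely
  expect_equal(nrow(got), 1L)
  expect_equal(c(got$res_i, got$res_j), c(1, 10))
  # distance measured from GLY's CA
  ca1 <- as.numeric(s$atoms[s$atoms$resno == 1 & s$atoms$elety == "CA",
                            c("x", "y", "z")])
  cb10 <- as.numeric(s$atoms[s$atoms$resno == 10 & s$atoms$elety == "CB",
                             c("x", "y", "z")])
  expect_equal(got$d_cb, sqrt(sum((ca1 - cb10)^2)), tolerance = 1e-9)
})

test_that("strain energy is zero exactly at ideal geometry", {
  cfg <- design_config()
  expect_equal(strain_energy(2.05, 104.15, 104.15, 87, cfg), 0)
  # the torsion term has period 180 degrees: -93 is also ideal
  expect_equal(strain_energy(2.05, 104.15, 104.15, -93, cfg), 0,
               tolerance = 1e-12)
  expect_equal(strain_energy(2.15, 104.15, 104.15, 87, cfg), 1.0,
               tolerance = 1e-9)
  expect_gt(strain_energy(2.05, 120, 104.15, 87, cfg), 0)
  expect_error(strain_energy(NA, 104.15, 104.15, 87, cfg), "NA")
})

test_that("interaction energy reproduces hand-computed cases", {
  cfg <- design_config()
  # isolated pair: nothing within 6 A of either SG -> 0
  s_iso <- toy_structure(c(1, 10), c("ALA", "ALA"),
                         list(c(0, 0, 0), c(4, 0, 0)))
  pair <- c(1, 10)
  expect_equal(interaction_energy(s_iso, c(100, 100, 100), c(104, 100, 100),
                                  pair, cfg), 0)

  # one environment atom at 2.0 A from sg_i, all else far -> 50 * 1^2
  s_one <- toy_structure(c(1, 10, 30), c("ALA", "ALA", "ALA"),
                         list(c(0, 0, 0), c(4, 0, 0), c(200, 0, 0)))
  a <- s_one$atoms
  a <- a[!(a$resno == 30 & a$elety != "CA"), ]  # single env atom
  a[a$resno == 30, c("x", "y", "z")] <- c(100, 100, 102)
  s_one <- new_structure(a)
  expect_equal(interaction_energy(s_one, c(100, 100, 100), c(0, 0, 50),
                                  pair, cfg), 50, tolerance = 1e-9)

  # ten environment atoms each 4 A from sg_i, none clashing -> -1.0
  env <- lapply(1:10, function(k) c(300, 300, 300))
  s_ten <- toy_structure(c(1, 10, 31:40), rep("ALA", 12),
                         c(list(c(0, 0, 0), c(4, 0, 0)), env))
  a <- s_ten$atoms
  keep <- a$resno < 30 | a$elety == "CA"
  a <- a[keep, ]
  for (k in 1:10) {  # ring of radius 4 around sg_i
    ang <- 2 * pi * k / 10
    a[a$resno == 30 + k, c("x", "y", "z")] <-
      c(100 + 4 * cos(ang), 100 + 4 * sin(ang), 100)
  }
  s_ten <- new_structure(a)
  expect_equal(interaction_energy(s_ten, c(100, 100, 100), c(0, 0, 50),
                                  pair, cfg), -1.0, tolerance = 1e-9)
})

test_that("quality classification implements the screening rule exactly", {
  # independent restatement of the rule as the oracle
  oracle <- function(ei, st) {
    if (ei < 0 && st < 20) "Good"
    else if (ei > 40 || st > 40 || (ei > 20 && st > 20)) "Bad"
    else "Medium"
  }
  vals <- c(-5, -1e-9, 0, 1e-9, 10, 19.999, 20, 20.001, 25, 39.999, 40,
            40.001, 45)
  for (ei in vals) for (st in vals) {
    expect_identical(classify_quality(ei, st), oracle(ei, st))
  }
  # published worked cases
  expect_identical(classify_quality(-5, 10), "Good")
  expect_identical(classify_quality(45, 10), "Bad")
  expect_identical(classify_quality(25, 25), "Bad")
  expect_identical(classify_quality(0, 20), "Medium")
  expect_error(classify_quality(NaN, 1), "finite")

  # the classes partition the plane: exactly one fires for random input
  set.seed(3)
  for (k in 1:200) {
    ei <- runif(1, -50, 80); st <- runif(1, 0, 80)
    expect_identical(classify_quality(ei, st), oracle(ei, st))
  }
})

test_that("disulfide modelling recovers a plantable conformation", {
  built <- hairpin_fixture()
  s <- built$structure
  m <- model_disulfide(s, c(4, 20))
  expect_equal(m$d_ss, 2.05, tolerance = 0.1)
  expect_lt(m$e_strain, 20)
  # chi1/chi3 are genuine dihedrals of the modelled geometry
  fr <- dsbscan:::residue_frame(s, "A", 4)
  expect_equal(dsbscan:::vec_dihedral(fr$n, fr$ca, fr$cb, m$sg_i), m$chi1_i,
               tolerance = 1e-6)

  # a far pair cannot reach the ideal bond: geometry lower bound
  far <- model_disulfide(s, c(2, 8))
  d_cb_far <- sqrt(sum((dsbscan:::atom_xyz(s, "A", 2, "CB") -
                        dsbscan:::atom_xyz(s, "A", 8, "CB"))^2))
  expect_gte(far$d_ss, d_cb_far - 2 * 1.81 - 0.1)
  expect_gt(far$e_strain, 100)
})

test_that("refining the chi1 grid never increases the best strain", {
  s <- hairpin_fixture()$structure
  for (pair in list(c(4, 20), c(2, 20))) {
    coarse <- model_disulfide(s, pair, design_config(chi1_grid_step = 15))
    mid <- model_disulfide(s, pair, design_config(chi1_grid_step = 5))
    fine <- model_disulfide(s, pair, design_config(chi1_grid_step = 1))
    expect_lte(mid$e_strain, coarse$e_strain + 1e-12)
    expect_lte(fine$e_strain, mid$e_strain + 1e-12)
  }
})

test_that("design geometry and energies are rigid-motion invariant", {
  built <- hairpin_fixture()
  s <- built$structure
  cfg <- design_config()
  m0 <- model_disulfide(s, c(4, 20), cfg)
  e0 <- interaction_energy(s, m0$sg_i, m0$sg_j, c(4, 20), cfg)
  p0 <- enumerate_pairs(s, cfg)
  for (seed in 1:3) {
    st <- transform_structure(s, seed = seed)
    m <- model_disulfide(st, c(4, 20), cfg)
    expect_equal(m$d_ss, m0$d_ss, tolerance = 1e-6)
    expect_equal(m$chi3, m0$chi3, tolerance = 1e-6)
    expect_equal(m$e_strain, m0$e_strain, tolerance = 1e-6)
    e <- interaction_energy(st, m$sg_i, m$sg_j, c(4, 20), cfg)
    expect_equal(e, e0, tolerance = 1e-6)
    p <- enumerate_pairs(st, cfg)
    expect_equal(p$d_cb, p0$d_cb, tolerance = 1e-6)
  }
})

test_that("filters annotate without deleting and resolve the active site", {
  built <- hairpin_fixture(disulfides = list(c(2, 20)))
  s <- built$structure
  cands <- enumerate_pairs(s, design_config())
  native <- detect_native_disulfides(s)

  # no catalytic residues configured -> all near_active_site FALSE
  f0 <- apply_filters(cands, s, design_config(), native = native)
  expect_equal(nrow(f0), nrow(cands))
  expect_false(any(f0$near_active_site))
  expect_true(any(f0$involves_native_cys))  # pairs touching Cys2/Cys20

  # catalytic residue at 10: flags must match an independent distance
  # oracle (any atom of either pair residue within 10 A of the
  # catalytic side chain, here CB of residue 10)
  cfg_as <- design_config(active_site_residues = 10)
  f1 <- apply_filters(cands, s, cfg_as, native = native)
  cb10 <- as.numeric(s$atoms[s$atoms$resno == 10 & s$atoms$elety == "CB",
                             c("x", "y", "z")])
  want <- vapply(seq_len(nrow(f1)), function(k) {
    own <- s$atoms[s$atoms$resno %in% c(f1$res_i[k], f1$res_j[k]), ]
    dmin <- min(sqrt((own$x - cb10[1])^2 + (own$y - cb10[2])^2 +
                     (own$z - cb10[3])^2))
    dmin <= 10
  }, logical(1))
  expect_equal(f1$near_active_site, want)
  expect_true(any(want) && !all(want))  # the fixture exercises both sides

  # absent catalytic residue is a configuration error
  expect_error(apply_filters(cands, s, design_config(active_site_residues = 99)),
               "absent")

  # disorder adjacency (+/- 2 residues)
  dis <- data.frame(chain = "A", start = 8, end = 9)
  f2 <- apply_filters(cands, s, design_config(), disordered = dis)
  hit <- f2$res_i %in% 6:11 | f2$res_j %in% 6:11
  expect_equal(f2$in_disordered_region, hit)
})

test_that("ranking orders by quality, demotion flags, then score", {
  base <- data.frame(
    chain_i = "A", res_i = c(1, 2, 3, 4, 5), aa_i = "ALA",
    chain_j = "A", res_j = c(11, 12, 13, 14, 15), aa_j = "ALA",
    d_cb = c(4.5, 4.4, 4.3, 4.2, 4.1),
    d_ss = 2.05, chi1_i = 0, chi1_j = 0, chi3 = 87,
    e_strain = c(10, 5, 1, 30, 50),
    e_interaction = c(-1, -2, -3, 10, 50),
    quality = c("Good", "Good", "Good", "Medium", "Bad"),
    near_active_site = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    involves_native_cys = FALSE, buried_i = FALSE, buried_j = FALSE,
    in_disordered_region = FALSE)
  r <- rank_candidates(base)
  # strain 5 unflagged Good first, then strain 10; flagged Good (strain 1)
  # still precedes Medium and Bad
  expect_equal(r$res_i, c(2, 1, 3, 4, 5))
  expect_equal(r$rank, 1:5)
  # empty input passes through
  expect_equal(nrow(rank_candidates(base[0, ])), 0L)
})

test_that("cysteine mutation produces a closed design loop", {
  built <- hairpin_fixture()
  s <- built$structure
  m <- model_disulfide(s, c(4, 20))
  mut <- mutate_to_cys(s, c(4, 20), m)

  for (r in c(4, 20)) {
    res_atoms <- mut$atoms[mut$atoms$resno == r, ]
    expect_setequal(res_atoms$elety, c("N", "CA", "C", "O", "CB", "SG"))
    expect_true(all(res_atoms$resid == "CYS"))
  }
  # untouched residues identical
  others <- mut$atoms[!(mut$atoms$resno %in% c(4, 20)), ]
  orig <- s$atoms[!(s$atoms$resno %in% c(4, 20)), ]
  expect_equal(others$x, orig$x)

  # SG distance equals the modelled bond, and detection closes the loop
  sg <- mut$atoms[mut$atoms$elety == "SG", ]
  d <- sqrt(sum((as.numeric(sg[1, c("x", "y", "z")]) -
                 as.numeric(sg[2, c("x", "y", "z")]))^2))
  expect_equal(d, m$d_ss, tolerance = 1e-9)
  if (m$d_ss <= 2.3) {
    nb <- detect_native_disulfides(mut)
    expect_true(any(nb$res_i == 4 & nb$res_j == 20))
  }

  # mutating an existing CYS replaces its SG (idempotent planting)
  mut2 <- mutate_to_cys(mut, c(4, 20), m)
  expect_equal(nrow(mut2$atoms), nrow(mut$atoms))
})
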