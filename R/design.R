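## Cysteine-pair (disulfide) design: enumerate residue pairs passing the
## Cbeta-Cbeta feasibility screen, model the S-S bridge geometrically
## over a chi1 rotamer grid, score it with explicit strain/interaction
## energy surrogates, classify by the Good/Medium/Bad quality rule, and
## annotate the screening filters (active-site proximity, burial, native
## cysteines, disorder).

## Ideal disulfide stereochemistry used throughout the module.
.ss_ideal <- list(
  cb_sg   = 1.81,    # CB-SG bond, Angstrom
  ss      = 2.05,    # SG-SG bond, Angstrom
  ca_cb_sg = 114.0,  # CA-CB-SG angle, degrees
  cb_sg_sg = 104.15, # CB-SG-SG angle, degrees
  chi3    = 87.0     # CB-SG-SG-CB torsion magnitude, degrees
)

#' Design configuration for disulfide scanning
#'
#' Bundles the geometric screening thresholds and surrogate-energy
#' constants. The feasibility screen is the classic Cbeta-Cbeta
#' criterion (at most 5 Angstrom; the Calpha is used for glycine).
#'
#' @param max_cb_cb maximum Cbeta-Cbeta distance for a candidate pair
#'   (Angstrom, default 5.0).
#' @param min_seq_sep minimum sequence separation in residues (default
#'   4); closer pairs cannot form an unstrained bridge.
#' @param active_site_residues integer vector of author residue numbers
#'   forming the catalytic core (e.g. `c(142, 249)` for a GH5
#'   endoglucanase with catalytic glutamates E142/E249), or NULL.
#' @param active_site_chain chain of the catalytic residues (default first
#'   chain present).
#' @param active_site_radius flag candidates with any atom within this
#'   distance of a catalytic side chain (Angstrom, default 10).
#' @param native_ss_max maximum SG-SG distance for an existing cystine
#'   (Angstrom, default 2.3).
#' @param chi1_grid_step chi1 rotamer grid step in degrees (default 5;
#'   must divide 360).
#' @param burial_neighbor_cutoff,burial_neighbor_max burial proxy: a
#'   residue is buried when more than `burial_neighbor_max` other CB
#'   atoms lie within `burial_neighbor_cutoff` Angstrom of its CB.
#' @param k_ss,k_ang,k_tor strain-energy force constants (units/A^2,
#'   units/deg^2, units).
#' @param k_clash,eps_pack interaction-energy constants (units/A^2,
#'   units).
#' @return list of class `dsb_design_config`.
#' @export
design_config <- function(max_cb_cb = 5.0,
                          min_seq_sep = 4L,
                          active_site_residues = NULL,
                          active_site_chain = NULL,
                          active_site_radius = 10.0,
                          native_ss_max = 2.3,
                          chi1_grid_step = 5,
                          burial_neighbor_cutoff = 10.0,
                          burial_neighbor_max = 16L,
                          k_ss = 100, k_ang = 0.02, k_tor = 2,
                          k_clash = 50, eps_pack = 0.1) {
  stopifnot(max_cb_cb > 0, min_seq_sep >= 1, active_site_radius > 0,
            native_ss_max > 0, burial_neighbor_cutoff > 0)
  if (360 %% chi1_grid_step != 0) {
    stop("chi1_grid_step must divide 360")
  }
  structure(
    list(max_cb_cb = max_cb_cb, min_seq_sep = as.integer(min_seq_sep),
         active_site_residues = active_site_residues,
         active_site_chain = active_site_chain,
         active_site_radius = active_site_radius,
         native_ss_max = native_ss_max,
         chi1_grid_step = chi1_grid_step,
         burial_neighbor_cutoff = burial_neighbor_cutoff,
         burial_neighbor_max = as.integer(burial_neighbor_max),
         k_ss = k_ss, k_ang = k_ang, k_tor = k_tor,
         k_clash = k_clash, eps_pack = eps_pack),
    class = "dsb_design_config"
  )
}

#' Detect native disulfide bonds
#'
#' Finds all cysteine pairs whose SG-SG distance is at most `max_ss`.
#' Each cysteine participates in at most one returned pair (the closest
#' partner wins).
#'
#' @param s a `dsb_structure`.
#' @param max_ss SG-SG distance cutoff in Angstrom (default 2.3).
#' @return data.frame with columns `chain_i`, `res_i`, `chain_j`,
#'   `res_j`, `d_ss`; zero rows when the structure has no bonded
#'   cysteines.
#' @export
detect_native_disulfides <- function(s, max_ss = 2.3) {
  a <- s$atoms
  sg <- a[a$resid == "CYS" & a$elety == "SG", , drop = FALSE]
  empty <- data.frame(chain_i = character(), res_i = integer(),
                      chain_j = character(), res_j = integer(),
                      d_ss = numeric())
  if (nrow(sg) < 2L) return(empty)
  cand <- NULL
  for (i in seq_len(nrow(sg) - 1L)) {
    for (j in seq((i + 1L), nrow(sg))) {
      d <- vnorm(as.numeric(sg[i, c("x", "y", "z")]) -
                 as.numeric(sg[j, c("x", "y", "z")]))
      if (d <= max_ss) {
        cand <- rbind(cand, data.frame(
          chain_i = sg$chain[i], res_i = sg$resno[i],
          chain_j = sg$chain[j], res_j = sg$resno[j], d_ss = d))
      }
    }
  }
  if (is.null(cand)) return(empty)
  cand <- cand[order(cand$d_ss), , drop = FALSE]
  used <- character()
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    ki <- paste(cand$chain_i[k], cand$res_i[k])
    kj <- paste(cand$chain_j[k], cand$res_j[k])
    if (!(ki %in% used) && !(kj %in% used)) {
      keep[k] <- TRUE
      used <- c(used, ki, kj)
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Scanning-position table: one row per residue with the CB coordinate
## (CA fallback for glycine). Prolines are excluded as mutation targets
## (their backbone nitrogen cannot accommodate the cysteine). Residues
## missing both CB and CA are skipped with a warning.
scan_positions <- function(s) {
  res <- residue_table(s)
  keep <- res$resid != "PRO"
  res <- res[keep, , drop = FALSE]
  xs <- ys <- zs <- rep(NA_real_, nrow(res))
  for (i in seq_len(nrow(res))) {
    cb <- atom_xyz(s, res$chain[i], res$resno[i], "CB")
    if (is.null(cb) && res$resid[i] == "GLY") {
      cb <- atom_xyz(s, res$chain[i], res$resno[i], "CA")
    }
    if (is.null(cb)) cb <- atom_xyz(s, res$chain[i], res$resno[i], "CA")
    if (is.null(cb)) next
    xs[i] <- cb[1L]; ys[i] <- cb[2L]; zs[i] <- cb[3L]
  }
  dropped <- is.na(xs)
  if (any(dropped)) {
    warning(sprintf("skipping %d residue(s) lacking both CB and CA (e.g. %s %d)",
                    sum(dropped), res$chain[which(dropped)[1L]],
                    res$resno[which(dropped)[1L]]))
    res <- res[!dropped, , drop = FALSE]
    xs <- xs[!dropped]; ys <- ys[!dropped]; zs <- zs[!dropped]
  }
  cbind(res, data.frame(cb_x = xs, cb_y = ys, cb_z = zs))
}

#' Enumerate candidate residue pairs by the Cbeta-Cbeta screen
#'
#' All residue pairs (same chain) with sequence separation at least
#' `cfg$min_seq_sep` and Cbeta-Cbeta distance at most `cfg$max_cb_cb`
#' (glycine measured from Calpha), sorted by distance. Proline is
#' excluded as a mutation target.
#'
#' @param s a `dsb_structure`.
#' @param cfg a [design_config()].
#' @return data.frame with columns `chain_i`, `res_i`, `aa_i`,
#'   `chain_j`, `res_j`, `aa_j`, `d_cb`, sorted by `d_cb` ascending;
#'   `res_i < res_j` within a chain.
#' @export
enumerate_pairs <- function(s, cfg = design_config()) {
  pos <- scan_positions(s)
  out <- data.frame(chain_i = character(), res_i = integer(),
                    aa_i = character(), chain_j = character(),
                    res_j = integer(), aa_j = character(),
                    d_cb = numeric())
  if (nrow(pos) < 2L) return(out)
  cb <- as.matrix(pos[, c("cb_x", "cb_y", "cb_z")])
  dmat <- as.matrix(stats::dist(cb))
  for (i in seq_len(nrow(pos) - 1L)) {
    for (j in seq((i + 1L), nrow(pos))) {
      if (pos$chain[i] != pos$chain[j]) next
      if (abs(pos$resno[j] - pos$resno[i]) < cfg$min_seq_sep) next
      if (dmat[i, j] > cfg$max_cb_cb) next
      lo <- if (pos$resno[i] <= pos$resno[j]) i else j
      hi <- if (pos$resno[i] <= pos$resno[j]) j else i
      out <- rbind(out, data.frame(
        chain_i = pos$chain[lo], res_i = pos$resno[lo], aa_i = pos$resid[lo],
        chain_j = pos$chain[hi], res_j = pos$resno[hi], aa_j = pos$resid[hi],
        d_cb = dmat[i, j]))
    }
  }
  out <- out[order(out$d_cb), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strain energy of a modelled disulfide
#'
#' Harmonic/torsional surrogate with its zero point at ideal disulfide
#' stereochemistry:
#' `E = k_ss*(d_ss - 2.05)^2 + k_ang*((theta_i - 104.15)^2 +
#' (theta_j - 104.15)^2) + k_tor*(1 - cos(2*(chi3 - 87)))`.
#' The torsion term has period 180 degrees, so the two ideal chi3
#' conformers (+87 and -93) both score zero.
#'
#' @param d_ss SG-SG distance (Angstrom).
#' @param theta_i,theta_j CB-SG-SG angles at each side (degrees).
#' @param chi3 CB-SG-SG-CB torsion (degrees).
#' @param cfg a [design_config()] carrying the force constants.
#' @return non-negative energy in surrogate units; zero only at ideal
#'   geometry.
#' @export
strain_energy <- function(d_ss, theta_i, theta_j, chi3,
                          cfg = design_config()) {
  if (anyNA(c(d_ss, theta_i, theta_j, chi3))) stop("NA input to strain_energy")
  stopifnot(d_ss >= 0)
  cfg$k_ss * (d_ss - .ss_ideal$ss)^2 +
    cfg$k_ang * ((theta_i - .ss_ideal$cb_sg_sg)^2 +
                 (theta_j - .ss_ideal$cb_sg_sg)^2) +
    cfg$k_tor * (1 - cos(2 * (chi3 - .ss_ideal$chi3) * pi / 180))
}

## SG position for one residue at a given chi1 (N-CA-CB-SG torsion),
## from the residue's own N/CA/CB frame with ideal internal coordinates.
place_sg <- function(n_xyz, ca_xyz, cb_xyz, chi1) {
  nerf_place(n_xyz, ca_xyz, cb_xyz,
             .ss_ideal$cb_sg, .ss_ideal$ca_cb_sg, chi1)
}

#' Model a disulfide bridge for a residue pair
#'
#' Places SG atoms for both residues by ideal internal coordinates
#' (CB-SG 1.81 Angstrom, CA-CB-SG 114 degrees) over a chi1 grid for
#' each side, and returns the conformer that minimises
#' [strain_energy()].
#'
#' @param s a `dsb_structure`.
#' @param pair list or vector giving `chain_i`, `res_i`, `chain_j`,
#'   `res_j`; a two-element numeric vector is interpreted as residue
#'   numbers on the first chain.
#' @param cfg a [design_config()] (controls the grid step and force
#'   constants).
#' @return list with `chi1_i`, `chi1_j`, `chi3` (degrees), `d_ss`
#'   (Angstrom), `theta_i`, `theta_j` (degrees), `e_strain`, and `sg_i`,
#'   `sg_j` (modelled SG coordinates).
#' @export
model_disulfide <- function(s, pair, cfg = design_config()) {
  pr <- normalise_pair(s, pair)
  fr_i <- residue_frame(s, pr$chain_i, pr$res_i)
  fr_j <- residue_frame(s, pr$chain_j, pr$res_j)
  chis <- seq(-180, 180 - cfg$chi1_grid_step, by = cfg$chi1_grid_step)
  sg_i <- t(vapply(chis, function(c1) place_sg(fr_i$n, fr_i$ca, fr_i$cb, c1),
                   numeric(3L)))
  sg_j <- t(vapply(chis, function(c2) place_sg(fr_j$n, fr_j$ca, fr_j$cb, c2),
                   numeric(3L)))
  best <- NULL
  best_e <- Inf
  for (a in seq_along(chis)) {
    dvec <- sweep(sg_j, 2L, sg_i[a, ])
    dss <- sqrt(rowSums(dvec^2))
    for (b in seq_along(chis)) {
      ti <- vec_angle(fr_i$cb, sg_i[a, ], sg_j[b, ])
      tj <- vec_angle(fr_j$cb, sg_j[b, ], sg_i[a, ])
      x3 <- vec_dihedral(fr_i$cb, sg_i[a, ], sg_j[b, ], fr_j$cb)
      e <- strain_energy(dss[b], ti, tj, x3, cfg)
      if (e < best_e) {
        best_e <- e
        best <- list(chi1_i = chis[a], chi1_j = chis[b], chi3 = x3,
                     d_ss = dss[b], theta_i = ti, theta_j = tj,
                     e_strain = e, sg_i = sg_i[a, ], sg_j = sg_j[b, ])
      }
    }
  }
  best
}

#' Interaction energy of modelled SG atoms with their environment
#'
#' Soft-sphere clash penalty plus a weak packing reward, summed over all
#' heavy atoms of residues other than the candidate pair, for both SG
#' atoms:
#' `sum(k_clash * max(0, 3.0 - d)^2 - eps_pack * (3.5 <= d <= 6.0))`.
#' Negative values indicate favourable, unclashed packing.
#'
#' @param s a `dsb_structure`.
#' @param sg_i,sg_j modelled SG coordinates (3-vectors).
#' @param pair as in [model_disulfide()].
#' @param cfg a [design_config()].
#' @return energy in surrogate units.
#' @export
interaction_energy <- function(s, sg_i, sg_j, pair, cfg = design_config()) {
  pr <- normalise_pair(s, pair)
  a <- s$atoms
  own <- (a$chain == pr$chain_i & a$resno == pr$res_i) |
         (a$chain == pr$chain_j & a$resno == pr$res_j)
  env <- as.matrix(a[!own, c("x", "y", "z"), drop = FALSE])
  if (nrow(env) == 0L) return(0)
  e <- 0
  for (sg in list(sg_i, sg_j)) {
    d <- sqrt(colSums((t(env) - sg)^2))
    e <- e + cfg$k_clash * sum(pmax(0, 3.0 - d)^2) -
      cfg$eps_pack * sum(d >= 3.5 & d <= 6.0)
  }
  e
}

#' Classify candidate quality from the two surrogate energies
#'
#' Good: interaction < 0 and strain < 20. Bad: interaction > 40, or
#' strain > 40, or (interaction > 20 and strain > 20). Medium: anything
#' else. The rules are evaluated in the order Good, Bad, Medium; the
#' three classes partition the plane.
#'
#' @param e_interaction interaction energy (surrogate units).
#' @param e_strain strain energy (surrogate units).
#' @return one of `"Good"`, `"Medium"`, `"Bad"`.
#' @export
classify_quality <- function(e_interaction, e_strain) {
  if (anyNA(c(e_interaction, e_strain)) ||
      any(!is.finite(c(e_interaction, e_strain)))) {
    stop("non-finite input to classify_quality")
  }
  if (e_interaction < 0 && e_strain < 20) return("Good")
  if (e_interaction > 40 || e_strain > 40 ||
      (e_interaction > 20 && e_strain > 20)) return("Bad")
  "Medium"
}

#' Annotate candidates with screening filters
#'
#' Adds boolean flags without deleting any candidate (final pair choice
#' mixes criteria with expert judgment, so ranking demotes flagged
#' candidates instead of removing them):
#' `near_active_site` (any atom of either residue within
#' `cfg$active_site_radius` of a catalytic side-chain atom),
#' `involves_native_cys` (either residue is a cysteine in a detected
#' native bond), `buried_i`/`buried_j` (CB-neighbour count proxy), and
#' `in_disordered_region` (either residue within 2 residues of a
#' missing region).
#'
#' @param cands data.frame of candidates (from [enumerate_pairs()],
#'   possibly already scored).
#' @param s a `dsb_structure`.
#' @param cfg a [design_config()]; `cfg$active_site_residues` must be
#'   resolvable in `s` when set.
#' @param disordered optional data.frame from [detect_missing_regions()].
#' @param native optional data.frame from [detect_native_disulfides()].
#' @return `cands` with the five flag columns appended.
#' @export
apply_filters <- function(cands, s, cfg = design_config(),
                          disordered = NULL, native = NULL) {
  n <- nrow(cands)
  flags <- data.frame(near_active_site = rep(FALSE, n),
                      involves_native_cys = rep(FALSE, n),
                      buried_i = rep(FALSE, n), buried_j = rep(FALSE, n),
                      in_disordered_region = rep(FALSE, n))
  if (n == 0L) return(cbind(cands, flags))
  a <- s$atoms

  ## catalytic side-chain atoms (side chain = beyond the backbone)
  as_coords <- NULL
  if (!is.null(cfg$active_site_residues) && length(cfg$active_site_residues)) {
    as_chain <- cfg$active_site_chain
    if (is.null(as_chain)) as_chain <- a$chain[1L]
    for (r in cfg$active_site_residues) {
      sel <- a$chain == as_chain & a$resno == r &
        !(a$elety %in% c("N", "CA", "C", "O"))
      if (!any(a$chain == as_chain & a$resno == r)) {
        stop(sprintf("active-site residue %s %d absent from structure",
                     as_chain, r))
      }
      if (!any(sel)) {  # glycine-like: fall back to CA
        sel <- a$chain == as_chain & a$resno == r & a$elety == "CA"
      }
      as_coords <- rbind(as_coords, as.matrix(a[sel, c("x", "y", "z")]))
    }
  }

  native_keys <- character()
  if (!is.null(native) && nrow(native)) {
    native_keys <- c(paste(native$chain_i, native$res_i),
                     paste(native$chain_j, native$res_j))
  }

  ## CB coordinates for the burial proxy
  pos <- scan_positions(s)
  cbm <- as.matrix(pos[, c("cb_x", "cb_y", "cb_z")])
  burial_count <- function(chain, resno) {
    k <- which(pos$chain == chain & pos$resno == resno)
    if (length(k) == 0L) return(0L)
    d <- sqrt(colSums((t(cbm) - cbm[k, ])^2))
    sum(d <= cfg$burial_neighbor_cutoff) - 1L
  }

  near_disorder <- function(chain, resno) {
    if (is.null(disordered) || nrow(disordered) == 0L) return(FALSE)
    any(disordered$chain == chain &
        resno >= disordered$start - 2L & resno <= disordered$end + 2L)
  }

  for (k in seq_len(n)) {
    ci <- cands$chain_i[k]; ri <- cands$res_i[k]
    cj <- cands$chain_j[k]; rj <- cands$res_j[k]
    if (!is.null(as_coords)) {
      own <- (a$chain == ci & a$resno == ri) | (a$chain == cj & a$resno == rj)
      pc <- as.matrix(a[own, c("x", "y", "z"), drop = FALSE])
      dmin <- min(apply(pc, 1L, function(p)
        min(sqrt(colSums((t(as_coords) - p)^2)))))
      flags$near_active_site[k] <- dmin <= cfg$active_site_radius
    }
    flags$involves_native_cys[k] <-
      paste(ci, ri) %in% native_keys || paste(cj, rj) %in% native_keys
    flags$buried_i[k] <- burial_count(ci, ri) > cfg$burial_neighbor_max
    flags$buried_j[k] <- burial_count(cj, rj) > cfg$burial_neighbor_max
    flags$in_disordered_region[k] <-
      near_disorder(ci, ri) || near_disorder(cj, rj)
  }
  cbind(cands, flags)
}

#' Rank scored candidates
#'
#' Stable sort by quality class (Good before Medium before Bad), then a
#' combined score `e_strain + max(e_interaction, 0)` ascending, then
#' `d_cb` ascending. Candidates flagged `near_active_site` or
#' `involves_native_cys` sort after all unflagged candidates within
#' their class.
#'
#' @param cands scored, classified, filter-annotated candidate
#'   data.frame.
#' @return the same data.frame, reordered, with a `rank` column.
#' @export
rank_candidates <- function(cands) {
  if (nrow(cands) == 0L) {
    cands$rank <- integer(0)
    return(cands)
  }
  qual_ord <- match(cands$quality, c("Good", "Medium", "Bad"))
  demoted <- as.integer(cands$near_active_site | cands$involves_native_cys)
  score <- cands$e_strain + pmax(cands$e_interaction, 0)
  ord <- order(qual_ord, demoted, score, cands$d_cb)
  out <- cands[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Mutate a residue pair to cysteine with modelled SG atoms
#'
#' Renames both residues to CYS, removes side-chain atoms beyond CB, and
#' adds SG atoms at the modelled coordinates. All other residues are
#' untouched. Residues that are already cysteine keep their name and
#' have their SG replaced.
#'
#' @param s a `dsb_structure`.
#' @param pair as in [model_disulfide()].
#' @param model result of [model_disulfide()] (supplies the SG
#'   coordinates); computed on the fly when NULL.
#' @param cfg a [design_config()], used when `model` is NULL.
#' @return a new `dsb_structure`.
#' @export
mutate_to_cys <- function(s, pair, model = NULL, cfg = design_config()) {
  pr <- normalise_pair(s, pair)
  if (is.null(model)) model <- model_disulfide(s, pair, cfg)
  a <- s$atoms
  backbone <- c("N", "CA", "C", "O", "OXT", "CB")
  for (side in list(list(ch = pr$chain_i, r = pr$res_i, sg = model$sg_i),
                    list(ch = pr$chain_j, r = pr$res_j, sg = model$sg_j))) {
    own <- a$chain == side$ch & a$resno == side$r
    drop <- own & !(a$elety %in% backbone)
    insert_after <- max(which(own & !drop))
    a <- a[!drop, , drop = FALSE]
    own <- a$chain == side$ch & a$resno == side$r
    a$resid[own] <- "CYS"
    proto <- a[which(own)[1L], , drop = FALSE]
    proto$elety <- "SG"; proto$elesy <- "S"
    proto$x <- side$sg[1L]; proto$y <- side$sg[2L]; proto$z <- side$sg[3L]
    proto$o <- 1; proto$b <- 0
    pos <- max(which(own))
    a <- rbind(a[seq_len(pos), , drop = FALSE], proto,
               if (pos < nrow(a)) a[(pos + 1L):nrow(a), , drop = FALSE])
  }
  rownames(a) <- NULL
  new_structure(a, seqres = s$seqres, identifier = s$identifier)
}

## --- internal helpers ------------------------------------------------------

## Accepts pair as c(res_i, res_j), list(res_i=, res_j=, chain_i=,
## chain_j=), or a one-row data.frame slice; fills chains with the
## structure's first chain.
normalise_pair <- function(s, pair) {
  first_chain <- s$atoms$chain[1L]
  if (is.numeric(pair) && length(pair) == 2L) {
    return(list(chain_i = first_chain, res_i = as.integer(pair[1L]),
                chain_j = first_chain, res_j = as.integer(pair[2L])))
  }
  pair <- as.list(pair)
  list(chain_i = if (!is.null(pair$chain_i)) pair$chain_i else first_chain,
       res_i = as.integer(pair$res_i),
       chain_j = if (!is.null(pair$chain_j)) pair$chain_j else first_chain,
       res_j = as.integer(pair$res_j))
}

## N/CA/CB coordinates of one residue (CB required: callers operate on
## modelled cysteines).
residue_frame <- function(s, chain, resno) {
  n <- atom_xyz(s, chain, resno, "N")
  ca <- atom_xyz(s, chain, resno, "CA")
  cb <- atom_xyz(s, chain, resno, "CB")
  if (is.null(n) || is.null(ca) || is.null(cb)) {
    stop(sprintf("residue %s %d lacks N/CA/CB needed for SG modelling",
                 chain, resno))
  }
  if (vnorm(vcross(ca - n, cb - ca)) < 1e-8) {
    stop(sprintf("degenerate (collinear) backbone frame at %s %d", chain, resno))
  }
  list(n = n, ca = ca, cb = cb)
}
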