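# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: the quaternion superposition oracle
# checks the SVD-based Kabsch implementation, and the brute-force pair
# scan checks enumerate_pairs.

# Optimal-superposition RMSD by Horn's quaternion method: the residual
# follows from the largest eigenvalue of the 4x4 key matrix. Returns
# the RMSD only (unweighted).
quaternion_rmsd <- function(ref, mob) {
  n <- nrow(ref)
  p <- sweep(ref, 2, colMeans(ref))
  q <- sweep(mob, 2, colMeans(mob))
  m <- t(q) %*% p
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  e0 <- sum(p^2) + sum(q^2)
  sqrt(max(0, (e0 - 2 * lambda)) / n)
}

# Direct-formula radius of gyration (independent arithmetic path).
rg_direct <- function(coords, masses = rep(1, nrow(coords))) {
  com <- c(
    sum(coords[, 1] * masses), sum(coords[, 2] * masses),
    sum(coords[, 3] * masses)) / sum(masses)
  acc <- 0
  for (i in seq_len(nrow(coords))) {
    acc <- acc + masses[i] * sum((coords[i, ] - com)^2)
  }
  sqrt(acc / sum(masses))
}

# Brute-force candidate-pair scan on a single-chain structure: all
# residue pairs, CB coordinate (CA for GLY), plain double loop.
brute_force_pairs <- function(s, max_cb = 5.0, min_sep = 4L) {
  res <- residue_table(s)
  res <- res[res$resid != "PRO", ]
  out <- NULL
  for (i in seq_len(nrow(res) - 1)) {
    for (j in (i + 1):nrow(res)) {
      if (abs(res$resno[j] - res$resno[i]) < min_sep) next
      name_i <- if (res$resid[i] == "GLY") "CA" else "CB"
      name_j <- if (res$resid[j] == "GLY") "CA" else "CB"
      a <- s$atoms
      pi_ <- a[a$resno == res$resno[i] & a$elety == name_i, c("x", "y", "z")]
      pj_ <- a[a$resno == res$resno[j] & a$elety == name_j, c("x", "y", "z")]
      d <- sqrt(sum((as.numeric(pi_) - as.numeric(pj_))^2))
      if (d <= max_cb) {
        out <- rbind(out, data.frame(res_i = res$resno[i],
                                     res_j = res$resno[j], d_cb = d))
      }
    }
  }
  if (is.null(out)) out <- data.frame(res_i = integer(), res_j = integer(),
                                      d_cb = numeric())
  out[order(out$d_cb), ]
}

# Random proper rigid transform applied to a structure's coordinates.
transform_structure <- function(s, seed = 1) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  trans <- runif(3, -20, 20)
  m <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(rot)
  m <- sweep(m, 2, trans, "+")
  s$atoms$x <- m[, 1]; s$atoms$y <- m[, 2]; s$atoms$z <- m[, 3]
  s
}

# Small fixture builders -----------------------------------------------

hairpin_fixture <- function(planted = list(c(4, 20)), disulfides = list()) {
  build_structure(synthetic_spec("hairpin", 22, planted_pairs = planted,
                                 planted_disulfides = disulfides))
}

# Minimal hand-built structure: residues at given CA positions with a
# local N/C/CB frame, for targeted geometry tests.
toy_structure <- function(resnos, resids, origins) {
  rows <- list()
  for (k in seq_along(resnos)) {
    o <- origins[[k]]
    gly <- resids[k] == "GLY"
    names_k <- c("N", "CA", "C", if (!gly) "CB")
    dx <- c(-1.458, 0, 0.53, if (!gly) -0.54)
    dy <- c(0, 0, 1.43, if (!gly) -0.78)
    dz <- c(0, 0, 0, if (!gly) 1.2)
    atoms <- data.frame(
      chain = "A", resno = resnos[k], insert = "", resid = resids[k],
      elety = names_k,
      elesy = substr(names_k, 1, 1),
      x = o[1] + dx, y = o[2] + dy, z = o[3] + dz,
      o = 1, b = 0)
    rows[[k]] <- atoms
  }
  new_structure(do.call(rbind, rows))
}
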