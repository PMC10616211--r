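#' Rigid-body pose of one ligand copy in a C2 assembly
#'
#' The receptor dimer is fixed with its two-fold axis along z through the
#' origin; a pose is the rigid placement (unit quaternion + translation) of
#' ligand copy 1. Copy 2 is always the exact 180-degree rotation of copy 1
#' about z, so C2 closure holds by construction.
#'
#' @param quaternion length-4 unit quaternion (w, x, y, z).
#' @param translation length-3 vector (Angstroms).
#' @return list of class `pose_c2`.
#' @export
pose_c2 <- function(quaternion, translation) {
  q <- quaternion / sqrt(sum(quaternion^2))
  structure(list(quaternion = q, translation = as.numeric(translation)),
            class = "pose_c2")
}

#' @export
print.pose_c2 <- function(x, ...) {
  cat(sprintf("C2 pose: q = (%.3f, %.3f, %.3f, %.3f), t = (%.1f, %.1f, %.1f) A\n",
              x$quaternion[1L], x$quaternion[2L], x$quaternion[3L],
              x$quaternion[4L], x$translation[1L], x$translation[2L],
              x$translation[3L]))
  invisible(x)
}

# Coordinates of ligand copy 1 under a pose (ligand must be centered).
pose_ligand_xyz <- function(ligand_xyz, pose) {
  apply_transform(ligand_xyz, quat_to_rot(pose$quaternion)) +
    matrix(pose$translation, nrow(ligand_xyz), 3L, byrow = TRUE)
}

#' Prepare a receptor dimer: center it and align its C2 axis with z
#'
#' Computes the rigid transform mapping the first receptor chain onto the
#' second (matched by residue number and atom name), checks that the
#' rotation angle is within `angle_tol` of 180 degrees (a genuine two-fold),
#' and re-frames the whole dimer so the two-fold axis is the z axis through
#' the origin.
#'
#' @param receptor a two-chain `tstruct` with two copies of the same
#'   protein.
#' @param angle_tol maximal deviation of the inter-chain rotation from 180
#'   degrees, in degrees (default 5).
#' @return the re-framed `tstruct`.
#' @export
prepare_receptor <- function(receptor, angle_tol = 5) {
  chains <- unique(receptor$chain)
  if (length(chains) != 2L)
    stop("receptor must contain exactly 2 chains", call. = FALSE)
  i1 <- atom_select(receptor, chain = chains[1L])
  i2 <- atom_select(receptor, chain = chains[2L])
  k1 <- paste(receptor$resno[i1], receptor$elety[i1])
  k2 <- paste(receptor$resno[i2], receptor$elety[i2])
  common <- intersect(k1, k2)
  if (length(common) < 3L)
    stop("receptor chains do not share matched atoms", call. = FALSE)
  a <- coords(receptor, i1[match(common, k1)])
  b <- coords(receptor, i2[match(common, k2)])
  sp <- superpose(a, b)
  ang <- acos(pmin(1, pmax(-1, (sum(diag(sp$rotation)) - 1) / 2))) * 180 / pi
  if (abs(ang - 180) > angle_tol)
    stop(sprintf(
      "receptor chains are not related by a two-fold (rotation %.1f deg)",
      ang), call. = FALSE)
  # axis direction: eigenvector of R for eigenvalue +1
  ev <- eigen(sp$rotation)
  axis <- Re(ev$vectors[, which.min(abs(Re(ev$values) - 1))])
  axis <- axis / sqrt(sum(axis^2))
  # a point on the axis: solve (I - R) p = t in the plane orthogonal to axis
  # via pseudo-inverse (the axis direction is the null space)
  p <- MASS_ginv(diag(3) - sp$rotation) %*% sp$translation
  # rotation taking axis -> z
  z <- c(0, 0, 1)
  v <- pracma_cross(axis, z)
  s <- sqrt(sum(v^2))
  U <- if (s < 1e-12) {
    if (sum(axis * z) > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    vx <- matrix(c(0, -v[3L], v[2L], v[3L], 0, -v[1L], -v[2L], v[1L], 0),
                 3L, 3L, byrow = TRUE)
    diag(3) + vx + vx %*% vx * ((1 - sum(axis * z)) / s^2)
  }
  xyz <- apply_transform(sweep(coords(receptor), 2L, as.vector(p)), U)
  # drop any residual axial offset so the dimer is centered along z too
  xyz[, 3L] <- xyz[, 3L] - mean(xyz[, 3L])
  set_coords(receptor, xyz)
}

# Minimal local implementations of ginv / cross so MASS and pracma are not
# hard dependencies for two one-liners.
MASS_ginv <- function(m, tol = 1e-10) {
  sv <- svd(m)
  keep <- sv$d > tol * max(sv$d)
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}
pracma_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Build the A2B2 assembly coordinates for a pose
#'
#' Receptor dimer (prepared, C2 axis = z) plus two ligand copies: copy 1
#' placed by the pose, copy 2 its exact C2 image. Ligand chains are named
#' `lig_chains` (default C and D).
#'
#' @param receptor prepared two-chain `tstruct` (see [prepare_receptor()]).
#' @param ligand one-chain `tstruct`, centered (its coordinates are taken
#'   as the body frame).
#' @param pose a `pose_c2`.
#' @param lig_chains chain ids for the two ligand copies.
#' @return 4-chain `tstruct`.
#' @export
make_c2_assembly <- function(receptor, ligand, pose,
                             lig_chains = c("C", "D")) {
  if (length(unique(receptor$chain)) != 2L)
    stop("receptor must have exactly 2 chains", call. = FALSE)
  lxyz <- coords(ligand)
  copy1 <- pose_ligand_xyz(lxyz, pose)
  copy2 <- apply_transform(copy1, C2_Z)
  lig1 <- as.data.frame(ligand); lig2 <- as.data.frame(ligand)
  lig1$chain <- lig_chains[1L]; lig2$chain <- lig_chains[2L]
  lig1[, c("x", "y", "z")] <- copy1
  lig2[, c("x", "y", "z")] <- copy2
  s <- rbind(as.data.frame(receptor), lig1, lig2)
  rownames(s) <- NULL
  class(s) <- c("tstruct", "data.frame")
  s
}

#' Docking configuration
#'
#' @param n_starts number of random initial poses (>= 1).
#' @param seed RNG seed; the whole run is deterministic given (seed,
#'   config).
#' @param refine_iterations Nelder-Mead iteration cap per refined start.
#' @param n_refine how many of the best-scoring starts are refined
#'   (default 16; the rest are kept at their sampled pose).
#' @param w_r,w_c,w_e,w_a weights of the restraint, clash, electrostatic
#'   and contact-attraction score terms.
#' @param cluster_cutoff single-linkage ligand-RMSD cutoff (Angstroms).
#' @param correction restraint bound correction for violation reports.
#' @param ionic_strength molar ionic strength for the screened-Coulomb
#'   term (default 0.3).
#' @param clash_contact soft-sphere contact distance (sum of the two bead
#'   radii, Angstroms); pairs closer than this are penalized. The default
#'   4.0 (with clash weight 5) puts the packing equilibrium of Calpha bead
#'   models near 3.8 A, comfortably above the 3.5 A clash-free floor of
#'   the synthetic assemblies.
#' @return list of class `docking_config`.
#' @export
docking_config <- function(n_starts = 64L, seed = 1L,
                           refine_iterations = 300L, n_refine = 16L,
                           w_r = 10, w_c = 5, w_e = 0, w_a = 0.2,
                           cluster_cutoff = 7.5, correction = 5.0,
                           ionic_strength = 0.3, clash_contact = 4.0) {
  stopifnot(n_starts >= 1L, cluster_cutoff > 0)
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 refine_iterations = as.integer(refine_iterations),
                 n_refine = as.integer(min(n_refine, n_starts)),
                 w_r = w_r, w_c = w_c, w_e = w_e, w_a = w_a,
                 cluster_cutoff = cluster_cutoff, correction = correction,
                 ionic_strength = ionic_strength,
                 clash_contact = clash_contact), class = "docking_config")
}

# Residue formal charges for the optional Debye-Hueckel term.
RESIDUE_CHARGE <- c(ASP = -1, GLU = -1, LYS = 1, ARG = 1, HIS = 0.1)

# Inverse Debye length (1/A) from molar ionic strength in water at 298 K.
debye_kappa <- function(ionic_strength) sqrt(ionic_strength) / 3.04

# Score terms computed on raw coordinate blocks for speed: bodies is a list
# of n x 3 matrices (receptor chains and ligand copies). `contact` is the
# sum of the two bead radii: pairs closer than it are overlapping.
clash_energy <- function(bodies, contact) {
  e <- 0
  nb <- length(bodies)
  for (i in seq_len(nb - 1L)) for (j in (i + 1L):nb) {
    d <- cross_dist(bodies[[i]], bodies[[j]])
    ov <- contact - d
    e <- e + sum(ov[ov > 0]^2)
  }
  e
}

# Short-range attractive contact well (the coarse analogue of the
# attractive vdW/desolvation terms of docking force fields): each
# inter-body bead pair near the contact distance contributes up to -1.
# Without it every clash-free restraint-satisfying pose ties at zero and
# the score cannot rank interface burial.
contact_energy <- function(bodies, well = 4.5, width = 1.5) {
  e <- 0
  nb <- length(bodies)
  for (i in seq_len(nb - 1L)) for (j in (i + 1L):nb) {
    d <- cross_dist(bodies[[i]], bodies[[j]])
    e <- e - sum(exp(-(d - well)^2 / (2 * width^2)))
  }
  e
}

elec_energy <- function(bodies, charges, kappa, dielectric = 80) {
  e <- 0
  nb <- length(bodies)
  for (i in seq_len(nb - 1L)) for (j in (i + 1L):nb) {
    qq <- outer(charges[[i]], charges[[j]])
    nz <- qq != 0
    if (!any(nz)) next
    d <- cross_dist(bodies[[i]], bodies[[j]])
    d <- pmax(d, 1)
    # 332 kcal/mol A converts e^2/A to kcal/mol in vacuum
    e <- e + sum((332 / dielectric) * qq[nz] * exp(-kappa * d[nz]) / d[nz])
  }
  e
}

# Flat-bottom quadratic restraint energy from precomputed restraint
# geometry (see compile_restraints): vectorized over UIR atom pairs and
# looped over AIR groups.
restraint_energy <- function(compiled, rec_xyz, copy1, copy2) {
  all_xyz <- rbind(rec_xyz, copy1, copy2)
  viol <- numeric(length(compiled$groups))
  for (g in seq_along(compiled$groups)) {
    grp <- compiled$groups[[g]]
    best <- Inf
    for (cp in grp) {
      d <- if (cp$kind == "AIR")
        effective_distance(all_xyz[cp$ia, , drop = FALSE],
                           all_xyz[cp$ib, , drop = FALSE])
      else min(cross_dist(all_xyz[cp$ia, , drop = FALSE],
                          all_xyz[cp$ib, , drop = FALSE]))
      v <- max(0, d - cp$upper, cp$lower - d)
      if (v < best) best <- v
    }
    viol[g] <- best
  }
  sum(viol^2)
}

# Pre-resolve restraint selections once per dock run. Atom indices refer to
# rbind(receptor, copy1, copy2) with copy blocks of nrow(ligand).
compile_restraints <- function(receptor, ligand, restraints,
                               lig_chains = c("C", "D"),
                               fallback_slack = 1.0) {
  nrec <- nrow(receptor)
  nlig <- nrow(ligand)
  probe <- make_c2_assembly(receptor, ligand,
                            pose_c2(c(1, 0, 0, 0), c(0, 0, 0)), lig_chains)
  side_idx <- function(side, kind) {
    r <- resolve_restraint_side(probe, side, kind, fallback_slack)
    list(idx = r$idx, slack = r$slack)
  }
  groups <- list()
  for (r in restraints) {
    sa <- side_idx(r$selA, r$kind)
    sb <- side_idx(r$selB, r$kind)
    if (length(sa$idx) == 0L || length(sb$idx) == 0L)
      stop("unresolvable selection in restraint ", r$group, call. = FALSE)
    entry <- list(kind = r$kind, ia = sa$idx, ib = sb$idx,
                  lower = r$lower, upper = r$upper + sa$slack + sb$slack)
    groups[[r$group]] <- c(groups[[r$group]], list(entry))
  }
  list(groups = groups, nrec = nrec, nlig = nlig)
}

#' Score one pose of the C2 assembly
#'
#' Total = `w_r * E_restraint + w_c * E_clash + w_a * E_contact +
#' w_e * E_elec`. `E_restraint` is the sum of squared flat-bottom
#' violations (one term per restraint group, each group evaluated by its
#' best symmetry copy); `E_clash` a quadratic soft-sphere overlap over
#' inter-body bead pairs; `E_contact` a shallow attractive well rewarding
#' interface burial (always <= 0); `E_elec` an optional screened-Coulomb
#' (Debye-Hueckel) term over formal residue charges at the configured
#' ionic strength.
#'
#' @param receptor,ligand prepared receptor and centered ligand
#'   (`tstruct`).
#' @param pose a `pose_c2`.
#' @param restraints a `restraints` list.
#' @param config a `docking_config`.
#' @return list of class `score_breakdown`: `E_restraint`, `E_clash`,
#'   `E_contact`, `E_elec`, `total`.
#' @export
score_pose <- function(receptor, ligand, pose, restraints,
                       config = docking_config()) {
  compiled <- compile_restraints(receptor, ligand, restraints)
  ctx <- score_context(receptor, ligand, compiled, config)
  score_pose_fast(ctx, pose)
}

# Everything constant across poses in one dock run.
score_context <- function(receptor, ligand, compiled, config) {
  rec_xyz <- coords(receptor)
  lig_xyz <- coords(ligand)
  chains <- unique(receptor$chain)
  rec_bodies <- lapply(chains, function(ch)
    coords(receptor, atom_select(receptor, chain = ch)))
  charges <- c(lapply(chains, function(ch) {
    sub <- receptor[receptor$chain == ch, ]
    q <- RESIDUE_CHARGE[sub$resid]; q[is.na(q)] <- 0; unname(q)
  }), list(local({
    q <- RESIDUE_CHARGE[ligand$resid]; q[is.na(q)] <- 0; unname(q)
  })))
  charges <- c(charges, charges[length(charges)])
  list(rec_xyz = rec_xyz, lig_xyz = lig_xyz, rec_bodies = rec_bodies,
       charges = charges, compiled = compiled, config = config,
       kappa = debye_kappa(config$ionic_strength))
}

score_pose_fast <- function(ctx, pose) {
  cfg <- ctx$config
  copy1 <- pose_ligand_xyz(ctx$lig_xyz, pose)
  copy2 <- apply_transform(copy1, C2_Z)
  bodies <- c(ctx$rec_bodies, list(copy1, copy2))
  er <- restraint_energy(ctx$compiled, ctx$rec_xyz, copy1, copy2)
  ec <- clash_energy(bodies, cfg$clash_contact)
  ea <- if (cfg$w_a != 0) contact_energy(bodies) else 0
  ee <- if (cfg$w_e != 0)
    elec_energy(bodies, ctx$charges, ctx$kappa) else 0
  structure(list(E_restraint = er, E_clash = ec, E_contact = ea,
                 E_elec = ee,
                 total = cfg$w_r * er + cfg$w_c * ec + cfg$w_a * ea +
                   cfg$w_e * ee),
            class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf(
    "score: total %.3f (restraint %.3f, clash %.3f, contact %.3f, elec %.3f)\n",
    x$total, x$E_restraint, x$E_clash, x$E_contact, x$E_elec))
  invisible(x)
}

# 6-DOF parameter vector <-> pose. Rotation as a rotation-vector update of
# the start quaternion keeps Nelder-Mead steps well-scaled.
params_to_pose <- function(par, base_pose) {
  R0 <- quat_to_rot(base_pose$quaternion)
  R <- rotvec_to_rot(par[1:3]) %*% R0
  pose_c2(rot_to_quat(R), base_pose$translation + par[4:6])
}

rot_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    if (i == 1L) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2L) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / sqrt(sum(q^2))
}

#' Ligand RMSD between two poses, modulo the C2 symmetry
#'
#' RMSD between the copy-1 coordinates of two poses, taking the smaller of
#' the direct comparison and the comparison against the C2 image (the two
#' labelings of the same assembly).
#'
#' @param ligand centered ligand `tstruct`.
#' @param pose1,pose2 `pose_c2` objects.
#' @return RMSD in Angstroms.
#' @export
ligand_rmsd <- function(ligand, pose1, pose2) {
  l <- coords(ligand)
  a <- pose_ligand_xyz(l, pose1)
  b <- pose_ligand_xyz(l, pose2)
  min(rmsd(a, b), rmsd(a, apply_transform(b, C2_Z)))
}

#' Interface RMSD between two poses of the same ligand
#'
#' RMSD restricted to the ligand residues that form the interface in the
#' reference pose (beads within `contact_cutoff` of the receptor), modulo
#' the C2 relabeling of the two ligand copies. This is the recovery metric
#' for docking benchmarks: it ignores lever-arm motion of residues far
#' from the binding site.
#'
#' @param receptor prepared receptor `tstruct`.
#' @param ligand centered ligand `tstruct`.
#' @param pose,ref `pose_c2` objects (candidate and reference).
#' @param contact_cutoff interface definition distance in Angstroms
#'   (default 10, the usual interface-RMSD convention).
#' @return RMSD in Angstroms over the interface beads.
#' @export
interface_rmsd <- function(receptor, ligand, pose, ref,
                           contact_cutoff = 10.0) {
  l <- coords(ligand)
  rxyz <- coords(receptor)
  b <- pose_ligand_xyz(l, ref)
  dmin <- apply(cross_dist(b, rxyz), 1L, min)
  sel <- which(dmin <= contact_cutoff)
  if (length(sel) == 0L) sel <- order(dmin)[seq_len(min(5L, nrow(l)))]
  a <- pose_ligand_xyz(l, pose)
  min(rmsd(a[sel, , drop = FALSE], b[sel, , drop = FALSE]),
      rmsd(apply_transform(a, C2_Z)[sel, , drop = FALSE],
           b[sel, , drop = FALSE]))
}

#' Single-linkage clustering of poses by ligand RMSD
#'
#' Poses are merged while their ligand-RMSD (modulo C2 relabeling) is at or
#' below `cutoff`. The representative of a cluster is its lowest-total
#' member; clusters are ranked by representative total (ties broken by
#' lower restraint energy, then by pose hash).
#'
#' @param ligand centered ligand `tstruct`.
#' @param poses list of `pose_c2`.
#' @param scores list of `score_breakdown`, parallel to `poses`.
#' @param cutoff ligand-RMSD cutoff in Angstroms (default 7.5).
#' @return list of class `pose_clusters`: `membership` (integer vector,
#'   cluster rank per pose), `clusters` (list with `members`,
#'   `representative` indices), ordered by representative total.
#' @export
cluster_poses <- function(ligand, poses, scores, cutoff = 7.5) {
  n <- length(poses)
  stopifnot(n >= 1L, length(scores) == n)
  if (n == 1L) {
    return(structure(list(membership = 1L,
                          clusters = list(list(members = 1L,
                                               representative = 1L))),
                     class = "pose_clusters"))
  }
  dm <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    dm[i, j] <- dm[j, i] <- ligand_rmsd(ligand, poses[[i]], poses[[j]])
  hc <- hclust(as.dist(dm), method = "single")
  raw <- cutree(hc, h = cutoff)
  totals <- vapply(scores, function(s) s$total, 0)
  restr <- vapply(scores, function(s) s$E_restraint, 0)
  cl <- lapply(unique(raw), function(k) {
    members <- which(raw == k)
    rep_ix <- members[order(totals[members], restr[members],
                            vapply(members, function(m)
                              pose_hash(poses[[m]]), ""))][1L]
    list(members = members, representative = rep_ix)
  })
  ord <- order(vapply(cl, function(c_) totals[c_$representative], 0),
               vapply(cl, function(c_) restr[c_$representative], 0),
               vapply(cl, function(c_) pose_hash(poses[[c_$representative]]),
                      ""))
  cl <- cl[ord]
  membership <- integer(n)
  for (k in seq_along(cl)) membership[cl[[k]]$members] <- k
  structure(list(membership = membership, clusters = cl),
            class = "pose_clusters")
}

pose_hash <- function(pose) {
  paste(sprintf("%.6f", c(pose$quaternion, pose$translation)), collapse = ",")
}

#' Restrained multi-start rigid-body docking with exact C2 symmetry
#'
#' Samples `n_starts` random poses (uniform quaternions, translations in a
#' shell around the receptor), scores them, refines the best `n_refine` by
#' derivative-free Nelder-Mead over the 6 rigid degrees of freedom, scores
#' and clusters all poses, and returns the ranked result. Deterministic
#' given (seed, config).
#'
#' @param receptor two-chain `tstruct`; prepared with [prepare_receptor()]
#'   unless `prepare = FALSE` (the toy generator emits prepared dimers).
#' @param ligand centered one-chain `tstruct`.
#' @param restraints a `restraints` list (UIRs and/or AIRs). At least one
#'   restraint is required unless `config$w_c > 0`.
#' @param config a `docking_config`.
#' @param prepare logical: run [prepare_receptor()] first (default FALSE).
#' @return list of class `docking_result`: `poses`, `scores`,
#'   `violations` (per-pose `violation_report` of the representative
#'   evaluation mode `"each"`), `clusters` (a `pose_clusters`), `ranking`
#'   (pose indices of cluster representatives, best first), `config`.
#' @export
dock <- function(receptor, ligand, restraints, config = docking_config(),
                 prepare = FALSE) {
  if (length(restraints) == 0L && config$w_c <= 0)
    stop("need at least one restraint or a positive clash weight",
         call. = FALSE)
  if (prepare) receptor <- prepare_receptor(receptor)
  lig0 <- set_coords(ligand, sweep(coords(ligand), 2L,
                                   colMeans(coords(ligand))))
  compiled <- compile_restraints(receptor, lig0, restraints)
  ctx <- score_context(receptor, lig0, compiled, config)
  rec_xyz <- coords(receptor)
  r_rec <- max(sqrt(rowSums(rec_xyz^2)))
  r_lig <- max(sqrt(rowSums(coords(lig0)^2)))
  set.seed(config$seed)
  starts <- lapply(seq_len(config$n_starts), function(i) {
    q <- random_quaternion()
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    rad <- (r_rec + r_lig) * runif(1, 0.55, 1.05)
    pose_c2(q, rad * u)
  })
  # stage 1: translate each start to the restraint-satisfying region
  # (restraint term only, 3 translational DOF -- cheap, few atom pairs)
  starts <- lapply(starts, function(p) {
    obj_t <- function(tr) {
      p2 <- pose_c2(p$quaternion, tr)
      copy1 <- pose_ligand_xyz(ctx$lig_xyz, p2)
      restraint_energy(ctx$compiled, ctx$rec_xyz, copy1,
                       apply_transform(copy1, C2_Z))
    }
    opt <- optim(p$translation, obj_t, method = "Nelder-Mead",
                 control = list(maxit = 150, reltol = 1e-8))
    pose_c2(p$quaternion, opt$par)
  })
  init_scores <- lapply(starts, function(p) score_pose_fast(ctx, p))
  init_tot <- vapply(init_scores, function(s) s$total, 0)
  refine_ix <- order(init_tot)[seq_len(config$n_refine)]
  poses <- starts
  scores <- init_scores
  refine_pose <- function(base, cycles = 2L) {
    obj <- function(par) score_pose_fast(ctx, params_to_pose(par, base))$total
    par <- rep(0, 6)
    for (cycle in seq_len(cycles)) {  # simplex restarts escape collapse
      opt <- optim(par, obj, method = "Nelder-Mead",
                   control = list(maxit = config$refine_iterations,
                                  reltol = 1e-8))
      par <- opt$par
    }
    params_to_pose(par, base)
  }
  for (i in refine_ix) {
    poses[[i]] <- refine_pose(starts[[i]])
    scores[[i]] <- score_pose_fast(ctx, poses[[i]])
  }
  # orientational polish: at the best translations, restart from random
  # ligand orientations and keep improvements -- rigid-body searches find
  # the right site long before the right orientation
  tot <- vapply(scores, function(s) s$total, 0)
  for (i in order(tot)[seq_len(min(3L, length(poses)))]) {
    for (j in seq_len(6L)) {
      cand <- pose_c2(random_quaternion(),
                      poses[[i]]$translation + rnorm(3) * 1.5)
      p2 <- refine_pose(cand)
      s2 <- score_pose_fast(ctx, p2)
      if (s2$total < scores[[i]]$total) {
        poses[[i]] <- p2; scores[[i]] <- s2
      }
    }
  }
  cl <- cluster_poses(lig0, poses, scores, cutoff = config$cluster_cutoff)
  ranking <- vapply(cl$clusters, function(c_) c_$representative, 0L)
  top_assembly <- make_c2_assembly(receptor, lig0, poses[[ranking[1L]]])
  violations <- evaluate_restraints(top_assembly, restraints,
                                    correction = config$correction)
  structure(list(poses = poses, scores = scores, clusters = cl,
                 ranking = ranking, violations = violations,
                 receptor = receptor, ligand = lig0, config = config),
            class = "docking_result")
}

#' @export
print.docking_result <- function(x, ...) {
  best <- x$ranking[1L]
  cat(sprintf(
    "Docking result: %d poses, %d cluster(s); best total %.3f (pose %d)\n",
    length(x$poses), length(x$clusters$clusters),
    x$scores[[best]]$total, best))
  print(x$violations)
  invisible(x)
}

#' Write cluster representatives as a multi-model PDB
#'
#' @param result a `docking_result`.
#' @param path output PDB path.
#' @param n_clusters how many top clusters to write (default all).
#' @return `path`, invisibly.
#' @export
write_docking_models <- function(result, path,
                                 n_clusters = length(result$ranking)) {
  n_clusters <- min(n_clusters, length(result$ranking))
  models <- lapply(result$ranking[seq_len(n_clusters)], function(i)
    coords(make_c2_assembly(result$receptor, result$ligand,
                            result$poses[[i]])))
  template <- make_c2_assembly(result$receptor, result$ligand,
                               result$poses[[result$ranking[1L]]])
  write_structure(template, path, models = models)
}
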