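# Rotation helpers shared by the generators and the docking engine.
rot_z <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3L, 3L, byrow = TRUE)
}
C2_Z <- rot_z(pi)  # the two-fold operation about z

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3L, 3L, byrow = TRUE)
}

# Shoemake's method: uniform random unit quaternion.
random_quaternion <- function() {
  u <- runif(3)
  c(sqrt(1 - u[1L]) * sin(2 * pi * u[2L]),
    sqrt(1 - u[1L]) * cos(2 * pi * u[2L]),
    sqrt(u[1L]) * sin(2 * pi * u[3L]),
    sqrt(u[1L]) * cos(2 * pi * u[3L]))[c(4L, 1L, 2L, 3L)]
}

rotvec_to_rot <- function(v) {
  theta <- sqrt(sum(v^2))
  if (theta < 1e-12) return(diag(3))
  k <- v / theta
  K <- matrix(c(0, -k[3L], k[2L], k[3L], 0, -k[1L], -k[2L], k[1L], 0),
              3L, 3L, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Smoothed self-avoiding random walk: a Calpha-bead chain with 3.8 A bonds.
random_chain <- function(n_res, bond = 3.8, min_sep = 3.5, smooth = 0.6) {
  pts <- matrix(0, n_res, 3L)
  dir <- c(1, 0, 0)
  for (i in 2:n_res) {
    for (attempt in 1:200) {
      step <- smooth * dir + (1 - smooth) * rnorm(3)
      step <- step / sqrt(sum(step^2))
      cand <- pts[i - 1L, ] + bond * step
      prev <- pts[seq_len(max(1L, i - 2L)), , drop = FALSE]
      if (min(sqrt(rowSums(sweep(prev, 2L, cand)^2))) >= min_sep) break
    }
    pts[i, ] <- cand
    dir <- step
  }
  sweep(pts, 2L, colMeans(pts))
}

min_body_distance <- function(a, b) min(cross_dist(a, b))

beads_to_structure <- function(xyz_list, chains) {
  parts <- lapply(seq_along(xyz_list), function(i) {
    xyz <- xyz_list[[i]]
    data.frame(chain = chains[i], resno = as.character(seq_len(nrow(xyz))),
               resid = "ALA", elety = "CA", element = "C",
               x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
               stringsAsFactors = FALSE)
  })
  s <- do.call(rbind, parts)
  rownames(s) <- NULL
  class(s) <- c("tstruct", "data.frame")
  s
}

#' Specification of a synthetic C2-symmetric toy tetramer
#'
#' Calpha-bead chains on smoothed random walks emulate the A2B2 topology of
#' a receptor homodimer engaging two ligand copies. Not real folds: just
#' clash-free, contact-forming rigid bodies for geometry and docking tests.
#'
#' @param seed RNG seed.
#' @param n_res_receptor_chain beads per receptor chain (>= 10).
#' @param n_res_ligand beads per ligand copy (>= 10).
#' @param contact_offset target gap (Angstroms) between a ligand copy and
#'   the receptor dimer at the planted interface.
#' @return list of class `toy_spec`.
#' @export
toy_complex_spec <- function(seed = 7L, n_res_receptor_chain = 24L,
                             n_res_ligand = 16L, contact_offset = 4.0) {
  stopifnot(n_res_receptor_chain >= 10L, n_res_ligand >= 10L,
            contact_offset >= 3.5)
  structure(list(seed = as.integer(seed),
                 n_res_receptor_chain = as.integer(n_res_receptor_chain),
                 n_res_ligand = as.integer(n_res_ligand),
                 contact_offset = contact_offset), class = "toy_spec")
}

#' Generate a ground-truth C2-symmetric toy tetramer
#'
#' Builds a receptor dimer exactly C2-symmetric about the z axis (chain B is
#' the 180-degree image of chain A) and places one ligand copy in contact
#' with it; the second ligand copy is the C2 image. Placement is retried
#' until the whole assembly is clash-free (min inter-body bead distance
#' >= 3.5 A). Deterministic given the seed.
#'
#' @param spec a `toy_spec`.
#' @return list of class `toy_complex`: `assembly` (4-chain `tstruct`,
#'   chains A/B receptor, C/D ligand copies), `receptor` (prepared 2-chain
#'   `tstruct`), `ligand` (centered 1-chain `tstruct`, chain C), and
#'   `pose` (the ground-truth `pose_c2` reconstructing the assembly).
#' @export
make_toy_tetramer <- function(spec = toy_complex_spec()) {
  set.seed(spec$seed)
  # receptor chain offset from the C2 axis so its image cannot clash
  for (attempt in 1:1000) {
    chainA <- random_chain(spec$n_res_receptor_chain)
    span <- max(sqrt(rowSums(chainA^2)))
    chainA <- sweep(chainA, 2L, c(span * 0.8 + 4, 0, 0), "+")
    chainB <- apply_transform(chainA, C2_Z)
    if (min_body_distance(chainA, chainB) >= 3.5) break
    if (attempt == 1000L) stop("could not build clash-free receptor dimer")
  }
  ligand0 <- random_chain(spec$n_res_ligand)  # centered
  receptor <- beads_to_structure(list(chainA, chainB), c("A", "B"))
  rec_xyz <- rbind(chainA, chainB)
  # Sample candidate contact placements and keep the one with the largest
  # interface (most bead pairs within contact range): protein complexes
  # bury an extended surface, not a tangential point contact. Each ligand
  # copy must engage its own receptor monomer -- copy 1 touches chain A
  # only, and the two copies stay apart -- the A2B2 topology in which the
  # two B subunits sit on opposite faces of the A2 dimer.
  best <- NULL
  n_cand <- 0L
  centA <- colMeans(chainA)
  for (attempt in 1:2000) {
    q <- random_quaternion()
    rotL <- quat_to_rot(q)
    lig_rot <- apply_transform(ligand0, rotL)
    # approach direction biased toward chain A's outboard face, slide
    # inward by bisection until the gap to chain A matches contact_offset
    u <- centA + sqrt(sum(centA^2)) * 0.5 * rnorm(3)
    u[3L] <- u[3L] * 0.5
    u <- u / sqrt(sum(u^2))
    lo <- 0; hi <- 2 * (max(sqrt(rowSums(rec_xyz^2))) +
                          max(sqrt(rowSums(lig_rot^2)))) + 20
    if (min_body_distance(sweep(lig_rot, 2L, hi * u, "+"), chainA) <
        spec$contact_offset) next
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      d <- min_body_distance(sweep(lig_rot, 2L, mid * u, "+"), chainA)
      if (d < spec$contact_offset) lo <- mid else hi <- mid
    }
    t1 <- hi * u
    copy1 <- sweep(lig_rot, 2L, t1, "+")
    copy2 <- apply_transform(copy1, C2_Z)
    if (min_body_distance(copy1, chainA) < 3.5) next
    if (min_body_distance(copy1, chainA) > spec$contact_offset + 1.5) next
    if (min_body_distance(copy1, chainB) < 8) next
    if (min_body_distance(copy1, copy2) < 8) next
    n_contact <- sum(cross_dist(copy1, chainA) <=
                       spec$contact_offset + 4.0)
    best <- c(best, list(list(q = q, t1 = t1, n_contact = n_contact)))
    n_cand <- n_cand + 1L
    if (n_cand >= 48L) break
  }
  if (is.null(best))
    stop("clash-free ligand placement failed after 1000 attempts",
         call. = FALSE)
  # Relax every candidate placement under the packing energy (soft clash +
  # contact attraction, with a hard floor keeping inter-body separations
  # above 3.5 A) and keep the global minimum: the ground truth must be the
  # native-like optimum of the model physics, as a real complex is of its
  # force field. The multi-start budget matches the docking engine's so
  # the planted state is the same basin restraint-guided search converges
  # to.
  relax_obj <- function(par, cand) {
    p <- params_to_pose(par, cand)
    c1 <- pose_ligand_xyz(ligand0, p)
    c2 <- apply_transform(c1, C2_Z)
    if (min_body_distance(c1, chainB) < 6 ||
        min_body_distance(c1, c2) < 6) return(1e6)
    bodies <- list(chainA, chainB, c1, c2)
    # the docking energy (same clash and attraction terms and weights),
    # plus a hard floor keeping the planted assembly clash-free at 3.5 A
    # (inactive at the packing equilibrium, ~3.8 A)
    5 * clash_energy(bodies, 4.0) + 0.2 * contact_energy(bodies) +
      1000 * clash_energy(bodies, 3.5)
  }
  relax_one <- function(cand, par, maxit, cycles) {
    for (cycle in seq_len(cycles)) {
      opt <- optim(par, relax_obj, cand = cand, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-9))
      par <- opt$par
    }
    list(pose = params_to_pose(par, cand), value = opt$value, par = par,
         cand = cand)
  }
  pose_valid <- function(p) {
    c1 <- pose_ligand_xyz(ligand0, p)
    c2 <- apply_transform(c1, C2_Z)
    min(min_body_distance(c1, chainA), min_body_distance(c1, chainB),
        min_body_distance(c1, c2)) >= 3.5 &&
      min_body_distance(c1, chainA) <= spec$contact_offset + 3.0
  }
  stage1 <- lapply(best, function(b)
    relax_one(pose_c2(b$q, b$t1), rep(0, 6), maxit = 300, cycles = 1))
  ord <- order(vapply(stage1, function(r) r$value, 0))
  pose <- NULL
  pose_e <- Inf
  for (r in stage1[ord[seq_len(min(8L, length(stage1)))]]) {
    r2 <- relax_one(r$cand, r$par, maxit = 500, cycles = 2)
    if (pose_valid(r2$pose) && r2$value < pose_e) {
      pose <- r2$pose; pose_e <- r2$value
    }
  }
  if (is.null(pose))
    for (r in stage1[ord]) if (pose_valid(r$pose)) { pose <- r$pose; break }
  if (is.null(pose)) pose <- pose_c2(best[[1L]]$q, best[[1L]]$t1)
  # Local orientational multistart at the chosen site: random ligand
  # orientations near the selected position, each fully relaxed, so the
  # planted pose is the best packing optimum of its own basin -- the same
  # kind of search a docking run performs there.
  for (j in 1:32) {
    cand <- pose_c2(random_quaternion(),
                    pose$translation + rnorm(3) * 2)
    r <- relax_one(cand, rep(0, 6), maxit = 300, cycles = 2)
    if (pose_valid(r$pose) && r$value < pose_e) {
      pose <- r$pose; pose_e <- r$value
    }
  }
  r <- relax_one(pose, rep(0, 6), maxit = 600, cycles = 2)
  if (pose_valid(r$pose) && r$value < pose_e) { pose <- r$pose; pose_e <- r$value }
  ligand <- beads_to_structure(list(ligand0), "C")
  assembly <- make_c2_assembly(receptor, ligand, pose)
  structure(list(assembly = assembly, receptor = receptor,
                 ligand = ligand, pose = pose, spec = spec),
            class = "toy_complex")
}

#' Specification of planted cross-links on a toy complex
#'
#' @param linker linker name (default `"DSG"`).
#' @param n_true number of true links (>= 1) sampled from bead pairs whose
#'   ground-truth distance is at most the spacer length.
#' @param n_decoy number of decoy links sampled without the distance
#'   condition (default 0).
#' @param seed RNG seed.
#' @return list of class `planted_spec`.
#' @export
planted_crosslink_spec <- function(linker = "DSG", n_true = 4L, n_decoy = 0L,
                                   seed = 7L) {
  stopifnot(n_true >= 1L, n_decoy >= 0L)
  structure(list(linker = linker, n_true = as.integer(n_true),
                 n_decoy = as.integer(n_decoy), seed = as.integer(seed)),
            class = "planted_spec")
}

#' Plant cross-links consistent with a toy complex's ground truth
#'
#' True links are sampled from receptor-chain-A / ligand-copy-C bead pairs
#' whose ground-truth distance is within the linker spacer; decoys are
#' sampled from pairs farther than spacer + 5 A and flagged in the `decoy`
#' column. All beads are treated as lysines (the bead model carries no side
#' chains; restraint evaluation falls back to Calpha). Links are chosen to
#' be spread over the interface (greedy max-min selection on link
#' midpoints, seeded start), emulating identifications at distinct sites
#' rather than repeated hits on one residue pair.
#'
#' @param toy a `toy_complex`.
#' @param spec a `planted_spec`.
#' @return a `crosslinks` data.frame with protein names `"REC"`, `"LIG"`.
#' @export
plant_crosslinks <- function(toy, spec = planted_crosslink_spec()) {
  set.seed(spec$seed)
  lk <- get_linker(spec$linker)
  a <- coords(toy$assembly, atom_select(toy$assembly, chain = "A"))
  c1 <- coords(toy$assembly, atom_select(toy$assembly, chain = "C"))
  d <- cross_dist(a, c1)
  ok <- which(d <= lk$spacer, arr.ind = TRUE)
  if (nrow(ok) < spec$n_true)
    stop("only ", nrow(ok), " candidate pairs within ", lk$spacer,
         " A; cannot plant ", spec$n_true, " links", call. = FALSE)
  mids <- (a[ok[, 1L], , drop = FALSE] + c1[ok[, 2L], , drop = FALSE]) / 2
  chosen <- sample(nrow(ok), 1L)
  while (length(chosen) < spec$n_true) {
    dd <- cross_dist(mids, mids[chosen, , drop = FALSE])
    cand <- setdiff(seq_len(nrow(ok)), chosen)
    sep <- apply(dd[cand, , drop = FALSE], 1L, min)
    chosen <- c(chosen, cand[which.max(sep)])
  }
  pick <- ok[chosen, , drop = FALSE]
  links <- crosslink("REC", pick[, 1L], "K", "LIG", pick[, 2L], "K",
                     spec$linker)
  if (spec$n_decoy > 0L) {
    far <- which(d > lk$spacer + 5, arr.ind = TRUE)
    if (nrow(far) < spec$n_decoy)
      stop("too few distant pairs for decoys", call. = FALSE)
    dp <- far[sample(nrow(far), spec$n_decoy), , drop = FALSE]
    links <- rbind(links,
                   crosslink("REC", dp[, 1L], "K", "LIG", dp[, 2L], "K",
                             spec$linker, decoy = TRUE))
    class(links) <- c("crosslinks", "data.frame")
  }
  links
}

#' Specification of a simulated saturation-binding plate
#'
#' Defaults mirror the assay conditions the package models: a 12-point
#' log-spaced concentration grid, unit Bmax, 1 percent-per-nM nonspecific
#' slope, a small constant background, and Gaussian noise with standard
#' deviation expressed as a fraction of Bmax.
#'
#' @param Kd ground-truth dissociation constant (nM).
#' @param Bmax,NS,B0 remaining model parameters.
#' @param X concentration grid (nM); default 12 log-spaced points
#'   0.001-100 nM.
#' @param noise_sd Gaussian noise as a fraction of Bmax (default 0.02).
#' @param n_replicates curves per plate (default 1).
#' @param seed RNG seed.
#' @return list of class `sim_binding_spec`.
#' @export
sim_binding_spec <- function(Kd = 0.7, Bmax = 1.0, NS = 0.01, B0 = 0.05,
                             X = 10^seq(-3, 2, length.out = 12),
                             noise_sd = 0.02, n_replicates = 1L, seed = 1L) {
  stopifnot(Kd > 0, noise_sd >= 0, all(X >= 0))
  structure(list(Kd = Kd, Bmax = Bmax, NS = NS, B0 = B0, X = X,
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)), class = "sim_binding_spec")
}

#' Simulate a saturation-binding plate
#'
#' `Y = total_binding(X; Kd, Bmax, NS, B0) + N(0, noise_sd * Bmax)`,
#' seeded and deterministic.
#'
#' @param spec a `sim_binding_spec`.
#' @return list of `binding_curve` objects, one per replicate.
#' @export
simulate_binding_plate <- function(spec = sim_binding_spec()) {
  set.seed(spec$seed)
  lapply(seq_len(spec$n_replicates), function(r) {
    mu <- total_binding(spec$X, spec$Kd, spec$Bmax, spec$NS, spec$B0)
    binding_curve(spec$X, mu + rnorm(length(spec$X), 0,
                                     spec$noise_sd * spec$Bmax),
                  replicate = r)
  })
}
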