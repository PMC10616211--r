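test_that("C2 assemblies are exact by construction", {
  toy <- std_toy()
  # identity pose leaves ligand copy 1 at the body frame
  id_pose <- pose_c2(c(1, 0, 0, 0), c(0, 0, 0))
  asm <- make_c2_assembly(toy$receptor, toy$ligand, id_pose)
  expect_equal(coords(asm, atom_select(asm, chain = "C")),
               coords(toy$ligand), ignore_attr = TRUE)
  # translated pose: copy 2 is the 180-degree image through the z axis
  p <- pose_c2(c(1, 0, 0, 0), c(10, 0, 0))
  asm2 <- make_c2_assembly(toy$receptor, toy$ligand, p)
  cen2 <- colMeans(coords(asm2, atom_select(asm2, chain = "D")))
  expect_equal(unname(cen2), c(-10, 0, 0), tolerance = 1e-9)
  # closure for random poses
  set.seed(31)
  for (i in 1:5) {
    p <- pose_c2(rnorm(4), rnorm(3) * 20)
    asm3 <- make_c2_assembly(toy$receptor, toy$ligand, p)
    c1 <- coords(asm3, atom_select(asm3, chain = "C"))
    c2 <- coords(asm3, atom_select(asm3, chain = "D"))
    expect_equal(rmsd(apply_transform(c1, tetherdock:::C2_Z), c2), 0,
                 tolerance = 1e-12)
  }
})

test_that("receptor preparation recovers an off-frame two-fold axis", {
  toy <- std_toy()
  tr <- random_rigid(13)
  moved <- set_coords(toy$receptor,
                      apply_transform(coords(toy$receptor), tr$R, tr$t))
  prep <- prepare_receptor(moved)
  a <- coords(prep, atom_select(prep, chain = "A"))
  b <- coords(prep, atom_select(prep, chain = "B"))
  expect_equal(b, apply_transform(a, tetherdock:::C2_Z), tolerance = 1e-6,
               ignore_attr = TRUE)
  # a non-symmetric pair of chains is rejected
  broken <- toy$receptor
  xyz <- coords(broken)
  ib <- atom_select(broken, chain = "B")
  xyz[ib, ] <- xyz[ib, ] %*% t(tetherdock:::rot_z(0.5)) + 5
  expect_error(prepare_receptor(set_coords(broken, xyz)), "two-fold")
})

test_that("the ground-truth pose satisfies its planted restraints at zero
           restraint energy", {
  toy <- std_toy()
  uirs <- std_uirs()
  sb <- score_pose(toy$receptor, toy$ligand, toy$pose, uirs)
  expect_equal(sb$E_restraint, 0)
  expect_gte(sb$E_clash, 0)
  expect_lte(sb$E_contact, 0)
  # fully overlapping bodies clash: drop the ligand onto a receptor bead
  sb0 <- score_pose(toy$receptor, toy$ligand,
                    pose_c2(c(1, 0, 0, 0),
                            coords(toy$receptor,
                                   atom_select(toy$receptor,
                                               chain = "A"))[1, ]),
                    uirs)
  expect_gt(sb0$E_clash, 0)
})

test_that("restraint energy equals its term-by-term recomputation", {
  toy <- std_toy()
  uirs <- std_uirs()
  set.seed(17)
  for (i in 1:3) {
    p <- pose_c2(rnorm(4), rnorm(3) * 15)
    sb <- score_pose(toy$receptor, toy$ligand, p, uirs)
    rep_ <- evaluate_restraints(make_c2_assembly(toy$receptor, toy$ligand, p),
                                uirs, correction = 0, group_mode = "min")
    expect_equal(sb$E_restraint, sum(rep_$table$violation^2),
                 tolerance = 1e-9)
  }
})

test_that("restraint energy is monotone in satisfaction and distance", {
  toy <- std_toy()
  uirs <- std_uirs()
  set.seed(23)
  p <- pose_c2(rnorm(4), rnorm(3) * 15)
  base <- score_pose(toy$receptor, toy$ligand, p, uirs)$E_restraint
  # adding a restraint that the pose satisfies leaves the energy unchanged
  asm <- make_c2_assembly(toy$receptor, toy$ligand, p)
  sat <- structure(c(uirs, airs_from_actives(
    data.frame(chain = "A", resno = "1"),
    data.frame(chain = "B", resno = as.character(1:5)),
    upper = 1e4)), class = "restraints")
  expect_equal(score_pose(toy$receptor, toy$ligand, p, sat)$E_restraint,
               base, tolerance = 1e-9)
  # pulling the ligand away strictly increases a violated restraint term
  p_far <- pose_c2(p$quaternion, p$translation * 3)
  expect_gt(score_pose(toy$receptor, toy$ligand, p_far, uirs)$E_restraint,
            base)
})

test_that("pose clustering matches brute-force single linkage", {
  toy <- std_toy()
  set.seed(41)
  poses <- lapply(1:20, function(i) pose_c2(rnorm(4), rnorm(3) * 25))
  scores <- lapply(seq_along(poses), function(i)
    structure(list(E_restraint = i, E_clash = 0, E_contact = 0, E_elec = 0,
                   total = as.numeric(i)), class = "score_breakdown"))
  cutoff <- 15
  cl <- cluster_poses(toy$ligand, poses, scores, cutoff = cutoff)
  # brute force: repeated merging until stable
  n <- length(poses)
  dm <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    dm[i, j] <- dm[j, i] <- ligand_rmsd(toy$ligand, poses[[i]], poses[[j]])
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (dm[i, j] <= cutoff && lab[i] != lab[j]) {
        lab[lab == lab[j]] <- lab[i]; changed <- TRUE
      }
    if (!changed) break
  }
  want <- split(seq_len(n), lab)
  got <- lapply(cl$clusters, function(c_) sort(c_$members))
  expect_setequal(lapply(want, sort), got)
  # representative is the lowest-total member; ranking ascends
  reps <- vapply(cl$clusters, function(c_) c_$representative, 0L)
  expect_true(all(diff(vapply(reps, function(r) scores[[r]]$total, 0)) >= 0))
  for (c_ in cl$clusters)
    expect_equal(c_$representative, c_$members[which.min(
      vapply(c_$members, function(m) scores[[m]]$total, 0))])
  # singletons and duplicates
  one <- cluster_poses(toy$ligand, poses[1], scores[1])
  expect_length(one$clusters, 1L)
  two <- cluster_poses(toy$ligand, poses[c(1, 1)], scores[1:2])
  expect_length(two$clusters, 1L)
  expect_equal(sort(two$clusters[[1]]$members), c(1L, 2L))
})

test_that("docking reruns are bit-identical and recover the planted pose", {
  toy <- std_toy()
  uirs <- std_uirs()
  cfg <- docking_config(n_starts = 64, seed = 1)
  res <- dock(toy$receptor, toy$ligand, uirs, cfg)
  # C2 closure of every output pose
  for (p in res$poses[res$ranking[1:3]]) {
    asm <- make_c2_assembly(toy$receptor, toy$ligand, p)
    expect_equal(rmsd(apply_transform(coords(asm, atom_select(asm, chain = "C")),
                                      tetherdock:::C2_Z),
                      coords(asm, atom_select(asm, chain = "D"))), 0,
                 tolerance = 1e-12)
  }
  # every pose in exactly one cluster; ranking sorted by total
  expect_equal(sort(unlist(lapply(res$clusters$clusters,
                                  function(c_) c_$members))),
               seq_along(res$poses))
  reps <- vapply(res$clusters$clusters, function(c_) c_$representative, 0L)
  expect_true(all(diff(vapply(reps, function(r) res$scores[[r]]$total, 0))
                  >= 0))
  # the top representative recovers the planted interface
  best <- res$ranking[1]
  expect_lte(interface_rmsd(toy$receptor, toy$ligand, res$poses[[best]],
                            toy$pose), 5)
  # determinism contract
  res2 <- dock(toy$receptor, toy$ligand, uirs, cfg)
  expect_identical(res$ranking, res2$ranking)
  expect_identical(res$poses, res2$poses)
  expect_identical(res$scores, res2$scores)
  # the recovered assembly spans wider than one ligand diameter
  asm <- make_c2_assembly(toy$receptor, toy$ligand, res$poses[[best]])
  lig_diam <- max_pair_distance(toy$ligand, seq_len(nrow(toy$ligand)),
                                seq_len(nrow(toy$ligand)))
  expect_gt(max_pair_distance(asm, atom_select(asm, chain = "C"),
                              atom_select(asm, chain = "D")), lig_diam)
})

test_that("empty searches are rejected", {
  toy <- std_toy()
  none <- structure(list(), class = "restraints")
  expect_error(dock(toy$receptor, toy$ligand, none,
                    docking_config(w_c = 0)), "restraint")
})
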