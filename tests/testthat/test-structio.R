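test_that("PDB reading parses records and rejects degenerate files", {
  f <- write_mini_pdb(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C")
  s <- read_structure(f)
  expect_equal(nrow(s), 1L)
  expect_equal(unname(coords(s)[1, ]), c(0, 0, 0))
  expect_equal(s$chain, "A")
  expect_equal(s$elety, "CA")

  expect_error(read_structure(tempfile()), "not found")
  f2 <- write_mini_pdb("REMARK nothing here")
  expect_error(read_structure(f2), "empty structure")
})

test_that("write/read round trip preserves atoms, names and coordinates", {
  toy <- std_toy()
  f <- tempfile(fileext = ".pdb")
  write_structure(toy$assembly, f)
  s2 <- read_structure(f)
  expect_equal(nrow(s2), nrow(toy$assembly))
  expect_identical(s2$chain, toy$assembly$chain)
  expect_identical(s2$resno, toy$assembly$resno)
  expect_identical(s2$elety, toy$assembly$elety)
  expect_equal(coords(s2), round(coords(toy$assembly), 3),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("multi-pose writing emits MODEL blocks that re-read correctly", {
  toy <- std_toy()
  f <- tempfile(fileext = ".pdb")
  xyz <- coords(toy$ligand)
  write_structure(toy$ligand, f, models = list(xyz, xyz + 5, xyz - 5))
  expect_equal(sum(grepl("^MODEL", readLines(f))), 3L)
  m3 <- read_structure(f, model = 3)
  expect_equal(coords(m3), round(xyz, 3) - 5, ignore_attr = TRUE)
  expect_error(read_structure(f, model = 4), "not present")
})

test_that("oversized structures are refused by the PDB writer", {
  big <- new_structure(chain = "A", resno = seq_len(100000L),
                       x = seq_len(100000L), y = 0, z = 0)
  expect_error(write_structure(big, tempfile()), "99999")
})

test_that("min and max cross-pair distances match hand values and oracle", {
  s <- new_structure(chain = c("A", "A", "B", "B"), resno = c(1, 2, 1, 2),
                     x = c(0, 0, 3, 6), y = c(0, 1, 4, 8), z = 0)
  expect_equal(min_distance(s, 1, 1), 0)           # self distance
  expect_equal(min_distance(s, 1, 3), 5)           # 3-4-5 triangle
  expect_equal(max_pair_distance(s, 1, 4), 10)     # scaled 3-4-5

  toy <- std_toy()
  ia <- atom_select(toy$assembly, chain = "A")
  ic <- atom_select(toy$assembly, chain = "C")
  a <- coords(toy$assembly, ia); b <- coords(toy$assembly, ic)
  expect_equal(min_distance(toy$assembly, ia, ic), brute_min_dist(a, b),
               tolerance = 1e-9)
  expect_equal(max_pair_distance(toy$assembly, ia, ic), brute_max_dist(a, b),
               tolerance = 1e-9)
  expect_error(min_distance(toy$assembly, ia, integer(0)), "empty selection")
})

test_that("distances are symmetric and rigid-transform invariant", {
  toy <- std_toy()
  ia <- atom_select(toy$assembly, chain = "A")
  ic <- atom_select(toy$assembly, chain = "C")
  expect_equal(min_distance(toy$assembly, ia, ic),
               min_distance(toy$assembly, ic, ia))
  expect_equal(max_pair_distance(toy$assembly, ia, ic),
               max_pair_distance(toy$assembly, ic, ia))
  for (seed in 1:3) {
    tr <- random_rigid(seed)
    moved <- set_coords(toy$assembly,
                        apply_transform(coords(toy$assembly), tr$R, tr$t))
    expect_equal(min_distance(moved, ia, ic),
                 min_distance(toy$assembly, ia, ic), tolerance = 1e-6)
    expect_equal(max_pair_distance(moved, ia, ic),
                 max_pair_distance(toy$assembly, ia, ic), tolerance = 1e-6)
  }
})

test_that("interface residues follow the inclusive atom-to-atom cutoff", {
  s <- new_structure(chain = c("A", "B"), resno = c(10, 20),
                     x = c(0, 4.9), y = 0, z = 0)
  hit <- interface_residues(s, 1, 2, cutoff = 5.0)
  expect_equal(hit$resno, "10")
  s$x[2] <- 5.0   # boundary is inclusive
  expect_equal(nrow(interface_residues(s, 1, 2, cutoff = 5.0)), 1L)
  s$x[2] <- 5.1
  expect_equal(nrow(interface_residues(s, 1, 2, cutoff = 5.0)), 0L)
  expect_error(interface_residues(s, 1, 1, cutoff = 5.0), "disjoint")
})

test_that("interface calls match an exhaustive residue-pair scan and are
           monotone in the cutoff", {
  toy <- std_toy()
  asm <- toy$assembly
  ia <- atom_select(asm, chain = "A")
  ic <- atom_select(asm, chain = "C")
  got <- interface_residues(asm, ia, ic, cutoff = 5.0)
  # oracle: loop every residue of A over every atom of C
  want <- character(0)
  for (r in unique(asm$resno[ia])) {
    ra <- coords(asm, atom_select(asm, chain = "A", resno = r))
    if (brute_min_dist(ra, coords(asm, ic)) <= 5.0) want <- c(want, r)
  }
  expect_setequal(got$resno, want)
  wider <- interface_residues(asm, ia, ic, cutoff = 8.0)
  expect_true(all(got$resno %in% wider$resno))
})

test_that("Kabsch superposition recovers exact rigid motions", {
  set.seed(42)
  a <- matrix(rnorm(30), 10, 3)
  sp0 <- superpose(a, a)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-9)

  R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  b <- a %*% t(R90) + matrix(c(5, -2, 1), 10, 3, byrow = TRUE)
  sp <- superpose(a, b)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
  expect_equal(apply_transform(a, sp$rotation, sp$translation), b,
               tolerance = 1e-9)
})

test_that("superposition rmsd equals apply-and-remeasure and stays proper", {
  set.seed(11)
  a <- matrix(rnorm(150), 50, 3)
  b <- matrix(rnorm(150), 50, 3)
  sp <- superpose(a, b)
  moved <- apply_transform(a, sp$rotation, sp$translation)
  expect_equal(sp$rmsd, sqrt(mean(rowSums((moved - b)^2))), tolerance = 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  # reflective optimum still yields a proper rotation
  bm <- a; bm[, 1] <- -bm[, 1]
  expect_equal(det(superpose(a, bm)$rotation), 1, tolerance = 1e-9)
  # invariance under a common rigid transform
  tr <- random_rigid(5)
  sp2 <- superpose(apply_transform(a, tr$R, tr$t),
                   apply_transform(b, tr$R, tr$t))
  expect_equal(sp2$rmsd, sp$rmsd, tolerance = 1e-6)
  expect_error(superpose(a[1:2, ], b[1:2, ]), "at least 3")
  expect_error(superpose(a, b[1:10, ]), "equal-sized")
})

test_that("superposition agrees with an independent least-squares fitter", {
  set.seed(99)
  a <- matrix(rnorm(90), 30, 3)
  b <- a %*% t(tetherdock:::rot_z(0.7)) +
    matrix(c(3, 1, -2), 30, 3, byrow = TRUE) + matrix(rnorm(90, 0, 0.3), 30, 3)
  sp <- superpose(a, b)
  ref <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(b)), mobile = as.vector(t(a))))
  ref_rmsd <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) - b)^2)))
  expect_equal(sp$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("selection tokens resolve chains, ranges and atom names", {
  toy <- std_toy()
  asm <- toy$assembly
  expect_equal(length(parse_selection(asm, "A")),
               sum(asm$chain == "A"))
  expect_equal(length(parse_selection(asm, "A:3-7")), 5L)
  expect_equal(length(parse_selection(asm, "C:2:CA")), 1L)
})
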