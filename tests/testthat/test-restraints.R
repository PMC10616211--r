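test_that("the linker table holds the seven reagents with their chemistry", {
  tab <- builtin_linkers()
  expect_equal(nrow(tab), 7L)
  expect_setequal(tab$name,
                  c("DSG", "BS3", "BS(PEG)5", "BS(PEG)9", "KMUS", "SMCC",
                    "SMPB"))
  aa <- tab[tab$chem_b == "amine", ]
  expect_equal(setNames(aa$spacer, aa$name),
               c(DSG = 7.7, BS3 = 11.4, `BS(PEG)5` = 21.7, `BS(PEG)9` = 35.8))
  as_ <- tab[tab$chem_b == "sulfhydryl", ]
  expect_equal(setNames(as_$spacer, as_$name),
               c(KMUS = 16.3, SMCC = 8.3, SMPB = 11.6))
  expect_error(get_linker("EDC"), "unknown linker")
})

test_that("bridge masses derive from their elemental compositions", {
  tab <- builtin_linkers()
  # frozen against an independent elemental-mass computation
  expect_equal(tab["DSG", "bridge_mass_mono"], 96.02113, tolerance = 1e-5)
  expect_equal(tab["BS3", "bridge_mass_mono"], 138.06808, tolerance = 1e-5)
  expect_equal(tab["BS(PEG)5", "bridge_mass_mono"], 302.13655,
               tolerance = 1e-5)
  expect_equal(tab["BS(PEG)9", "bridge_mass_mono"], 478.24141,
               tolerance = 1e-5)
  expect_equal(tab["SMCC", "bridge_mass_mono"], 219.08954, tolerance = 1e-5)
  expect_true(all(tab$bridge_mass_mono <= tab$bridge_mass_avg + 0.5))
  expect_true(all(tab$spacer > 0))
})

test_that("cross-link records enforce linker end chemistry", {
  expect_silent(crosslink("DID", 377, "K", "MFN2", 79, "K", "DSG"))
  expect_silent(crosslink("DID", 164, "C", "MFN2", 37, "K", "SMCC"))
  # SMCC cannot bridge two lysines
  expect_error(crosslink("DID", 228, "K", "MFN2", 37, "K", "SMCC"),
               "chemistry mismatch")
  # DSG cannot touch a cysteine
  expect_error(crosslink("DID", 164, "C", "MFN2", 79, "K", "DSG"),
               "chemistry mismatch")
})

test_that("UIR generation assigns spacer upper bounds and reactive atoms", {
  links <- crosslink(c("DID", "DID"), c(377, 228), c("K", "K"),
                     c("MFN2", "MFN2"), c(79, 132), c("K", "C"),
                     c("DSG", "SMCC"))
  uirs <- uirs_from_crosslinks(links,
                               list(DID = "A", MFN2 = "B"))
  expect_length(uirs, 2L)
  expect_equal(uirs[[1]]$upper, 7.7)
  expect_equal(uirs[[1]]$selA$atom, "NZ")
  expect_equal(uirs[[1]]$selB$atom, "NZ")
  expect_equal(uirs[[2]]$upper, 8.3)
  expect_equal(uirs[[2]]$selB$atom, "SG")
  expect_true(all(vapply(uirs, function(r) r$lower, 0) == 0))

  empty <- uirs_from_crosslinks(crosslink(character(0), integer(0),
                                          character(0), character(0),
                                          integer(0), character(0),
                                          character(0)),
                                list(DID = "A", MFN2 = "B"))
  expect_length(empty, 0L)
})

test_that("every UIR copy inherits the linker spacer as its upper bound", {
  uirs <- std_uirs()
  links <- std_links()
  expect_length(uirs, nrow(links) * 4L)   # 2 x 2 chain pairings
  spacers <- setNames(builtin_linkers()$spacer, builtin_linkers()$name)
  for (r in uirs) expect_equal(r$upper, unname(spacers[links$linker[1]]))
  # symmetry copies share a group id
  expect_equal(length(unique(vapply(uirs, function(r) r$group, ""))),
               nrow(links))
})

test_that("AIR construction anchors each A-side active against the B pool", {
  a3 <- data.frame(chain = "A", resno = c("1", "2", "3"))
  b2 <- data.frame(chain = "C", resno = c("5", "6"))
  airs <- airs_from_actives(a3, b2)
  expect_length(airs, 3L)
  expect_equal(airs[[1]]$kind, "AIR")
  expect_equal(airs[[2]]$selA$resno, "2")
  expect_equal(airs[[2]]$selB$resno, c("5", "6"))
  expect_equal(airs[[1]]$upper, 2.0)
  expect_error(airs_from_actives(a3[0, ], b2), "non-empty")
})

test_that("effective distance matches closed forms and bounds the minimum", {
  one <- matrix(0, 1, 3)
  at3 <- matrix(c(3, 0, 0), 1, 3)
  expect_equal(effective_distance(one, at3), 3.0, tolerance = 1e-12)
  two_at3 <- matrix(c(3, 0, 0, 0, 3, 0), 2, 3, byrow = TRUE)
  expect_equal(effective_distance(one, two_at3), 3 * 2^(-1 / 6),
               tolerance = 1e-12)
  set.seed(8)
  for (i in 1:5) {
    a <- matrix(rnorm(15, sd = 4), 5, 3)
    b <- matrix(rnorm(15, sd = 4), 5, 3)
    expect_lte(effective_distance(a, b), brute_min_dist(a, b))
  }
  expect_error(effective_distance(one[0, , drop = FALSE], at3), "empty")
})

test_that("violation accounting encodes the bound-correction rule", {
  # single link at an exactly known distance; vary the gap
  mk <- function(d) new_structure(chain = c("A", "B"), resno = c(1, 1),
                                  elety = "NZ", x = c(0, d), y = 0, z = 0)
  r <- uirs_from_crosslinks(crosslink("P", 1, "K", "Q", 1, "K", "DSG"),
                            list(P = "A", Q = "B"))
  at <- function(d) evaluate_restraints(mk(d), r, correction = 5.0)
  expect_equal(at(7.7)$table$violation, 0)          # d = upper
  expect_true(at(7.7)$table$followed)
  expect_equal(at(12.7)$table$violation, 5.0)       # d = upper + 5.0
  expect_true(at(12.7)$table$followed)              # "at or below 5 A"
  expect_equal(at(12.8)$table$violation, 5.1, tolerance = 1e-9)
  expect_false(at(12.8)$table$followed)             # 5.1 A is not followed
})

test_that("followed counts are monotone in the correction", {
  toy <- std_toy()
  uirs <- std_uirs()
  prev <- 0L
  for (corr in c(0, 1, 2, 5, 10, Inf)) {
    rep_ <- evaluate_restraints(toy$assembly, uirs, correction = corr)
    expect_gte(rep_$n_followed, prev)
    prev <- rep_$n_followed
  }
  expect_equal(evaluate_restraints(toy$assembly, uirs,
                                   correction = Inf)$n_followed,
               length(uirs))
})

test_that("restraint evaluation agrees with exhaustive recomputation", {
  toy <- std_toy()
  uirs <- std_uirs()
  rep_ <- evaluate_restraints(toy$assembly, uirs, correction = 5)
  for (k in seq_along(uirs)) {
    r <- uirs[[k]]
    a <- coords(toy$assembly,
                atom_select(toy$assembly, chain = r$selA$chain,
                            resno = r$selA$resno))
    b <- coords(toy$assembly,
                atom_select(toy$assembly, chain = r$selB$chain,
                            resno = r$selB$resno))
    expect_equal(rep_$table$distance[k], brute_min_dist(a, b),
                 tolerance = 1e-6)
  }
})

test_that("group-min evaluation is at least as permissive as per-copy", {
  toy <- std_toy()
  uirs <- std_uirs()
  each <- evaluate_restraints(toy$assembly, uirs, correction = 0)
  grp <- evaluate_restraints(toy$assembly, uirs, correction = 0,
                             group_mode = "min")
  expect_equal(grp$n_total, length(unique(each$table$group)))
  for (g in unique(each$table$group)) {
    per_copy <- each$table$followed[each$table$group == g]
    expect_gte(grp$table$followed[grp$table$group == g], max(per_copy))
  }
})

test_that("restraint TSV round trip preserves every field", {
  uirs <- std_uirs()
  f <- tempfile(fileext = ".tsv")
  write_restraints(uirs, f)
  back <- read_restraints(f)
  expect_length(back, length(uirs))
  for (k in seq_along(uirs)) {
    expect_equal(back[[k]]$upper, uirs[[k]]$upper)
    expect_equal(back[[k]]$selA$chain, uirs[[k]]$selA$chain)
    expect_equal(back[[k]]$selB$resno, uirs[[k]]$selB$resno)
    expect_equal(back[[k]]$group, uirs[[k]]$group)
  }
})

test_that("cross-link CSV input reproduces the printed restraint bounds", {
  links <- read_crosslinks(system.file("extdata", "did_mfn2_crosslinks.csv",
                                       package = "tetherdock"))
  expect_equal(nrow(links), 5L)
  uirs <- uirs_from_crosslinks(links, list(DID = "A", MFN2 = "B"))
  ups <- vapply(uirs, function(r) r$upper, 0)
  expect_equal(ups, c(7.7, 35.8, 8.3, 8.3, 8.3))
})
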