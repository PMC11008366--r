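# Binding-energy definitions, the surrogate scorer, pose selection and
# quantum-chemistry table ingestion.

test_that("binding energy is E_X + E_Y - E_complex, positive when bound", {
  expect_equal(binding_energy(-10, -12, -30), 8)
  expect_equal(binding_energy(0, 0, 0), 0)
  expect_equal(binding_energy(-5, -5, -10), 0)
})

test_that("counterpoise binding energies require their fields", {
  rec <- list(E_X_isolated = -100, E_Y_isolated = -200, E_complex_CP = -315,
              E_X_in_complex = -99, E_Y_in_complex = -198)
  expect_equal(be_relax(rec), 15)
  expect_equal(be_rigid(rec), 18)
  expect_error(be_relax(list(E_X_isolated = -1, E_Y_isolated = -2)),
               "undefined")
  # rigid >= relax whenever in-complex fragments lie above relaxed monomers
  set.seed(31)
  for (rep in 1:20) {
    ex <- runif(1, -300, -100); ey <- runif(1, -300, -100)
    defo <- runif(2, 0, 5)
    rec <- list(E_X_isolated = ex, E_Y_isolated = ey,
                E_X_in_complex = ex + defo[1], E_Y_in_complex = ey + defo[2],
                E_complex_CP = ex + ey - runif(1, 0, 20))
    expect_gte(be_rigid(rec), be_relax(rec))
  }
})

test_that("surrogate reproduces hand-summed worked examples", {
  # DDD vs AAA (pyridinic): 3 primary bonds + 4 attractive cross-terms
  x <- parse_code("HHH-hh"); y <- parse_code("NNN-hhh")
  a3 <- Filter(function(z) z$n_contacts == 3,
               enumerate_alignments(x$pattern, y$pattern))[[1]]
  expect_equal(surrogate_pair_energy(x, y, a3), 3 * 6 + 4 * 1.5)
  # keto acceptors score P_O
  yo <- parse_code("OOO-hh")
  a3o <- Filter(function(z) z$n_contacts == 3,
                enumerate_alignments(x$pattern, yo$pattern))[[1]]
  expect_equal(surrogate_pair_energy(x, yo, a3o), 3 * 5 + 4 * 1.5)
  # AA homo pair, 2 contacts: two penalties + two repulsive cross-terms
  aa <- parse_code("NN-h")
  a2 <- Filter(function(z) z$n_contacts == 2,
               enumerate_alignments(aa$pattern, aa$pattern))[[1]]
  expect_equal(surrogate_pair_energy(aa, aa, a2), -(2 * 1) - 2 * 1.5)
})

test_that("planar pure-donor homo pairs score exactly zero at best", {
  dd <- parse_code("HH-hh", planarity = 1)
  aligns <- enumerate_alignments(dd$pattern, dd$pattern)
  e <- sapply(aligns, function(a) surrogate_pair_energy(dd, dd, a))
  expect_true(all(e <= 0))
  expect_equal(max(e), 0)   # single-contact pose: gated primary term is 0
  # pyramidal donors open the amine-as-acceptor channel
  ddp <- parse_code("HH-hh", planarity = 0)
  ep <- sapply(enumerate_alignments(ddp$pattern, ddp$pattern),
               function(a) surrogate_pair_energy(ddp, ddp, a))
  expect_gt(max(ep), 0)
})

test_that("surrogate is symmetric under pair exchange with mirrored poses", {
  set.seed(32)
  roster <- load_roster()
  for (rep in 1:25) {
    cds <- sample(roster$code, 2)
    x <- parse_code(cds[1], planarity = runif(1))
    y <- parse_code(cds[2], planarity = runif(1))
    params <- surrogate_params(sigma_noise = 0.3, seed = 99)
    for (a in enumerate_alignments(x$pattern, y$pattern)) {
      expect_equal(surrogate_pair_energy(x, y, a, params),
                   surrogate_pair_energy(y, x, mirror_alignment(a), params))
    }
  }
})

test_that("surrogate noise is reproducible per seed and zero-noise is exact", {
  x <- parse_code("HNH-hh"); y <- parse_code("OHO-h")
  a <- enumerate_alignments(x$pattern, y$pattern)[[2]]
  p1 <- surrogate_params(sigma_noise = 1, seed = 7)
  e1 <- surrogate_pair_energy(x, y, a, p1)
  e2 <- surrogate_pair_energy(x, y, a, p1)
  expect_identical(e1, e2)
  e3 <- surrogate_pair_energy(x, y, a, surrogate_params(sigma_noise = 1,
                                                        seed = 8))
  expect_false(identical(e1, e3))
  # noiseless scoring is bit-reproducible and unaffected by the global RNG
  set.seed(1); ea <- surrogate_pair_energy(x, y, a)
  set.seed(2); eb <- surrogate_pair_energy(x, y, a)
  expect_identical(ea, eb)
})

test_that("alignment/pattern mismatch is rejected", {
  a <- enumerate_alignments("DD", "AA")[[1]]
  expect_error(surrogate_pair_energy(parse_code("HHH-h"), parse_code("NN-h"), a),
               "lengths")
})

test_that("best-pose selection follows energy then the tie-break rules", {
  aligns <- enumerate_alignments("DDA", "AAD")
  e <- rep(1, 10)
  e[c(3, 5, 8)] <- 8   # tie at the top with different contact counts
  best <- select_best_pose(aligns, e)
  ties <- aligns[c(3, 5, 8)]
  ord <- order(sapply(ties, function(a) a$n_contacts),
               sapply(ties, function(a) a$flip),
               sapply(ties, function(a) a$shift))
  expect_identical(attr(best, "index"), c(3L, 5L, 8L)[ord][1])
  expect_equal(attr(best, "energy"), 8)
  # single pose
  one <- select_best_pose(aligns[1], 5)
  expect_identical(attr(one, "index"), 1L)
})

test_that("pose selection agrees with the brute-force filter-then-max oracle", {
  set.seed(33)
  for (rep in 1:40) {
    x <- rand_pattern(); y <- rand_pattern()
    aligns <- enumerate_alignments(x, y)
    e <- round(runif(length(aligns), 0, 5) * 2) / 2   # force ties
    ok <- runif(length(aligns)) > 0.3
    if (!any(ok)) ok[1] <- TRUE
    best <- select_best_pose(aligns, e, function(p) {
      ok[which(vapply(aligns, identical, logical(1), p))[1]]
    })
    expect_identical(attr(best, "index"), oracle_best_pose(aligns, e, ok))
  }
})

test_that("selection fails loudly when no pose is planar", {
  aligns <- enumerate_alignments("DD", "AA")
  err <- tryCatch(select_best_pose(aligns, seq_along(aligns),
                                   function(p) FALSE),
                  no_planar_pose = function(e) e)
  expect_s3_class(err, "no_planar_pose")
  expect_length(err$rejected, length(aligns))
})

test_that("energy tables round-trip, convert units, and flag conflicts", {
  recs <- data.frame(group_x = c("HH-hh", "HH-hh"), group_y = "NN-h",
                     pose_id = c("f0.s0", "f0.s1"),
                     E_complex = c(-30, -25), E_X_isolated = -10,
                     E_Y_isolated = -12, E_complex_CP = c(-29, -24),
                     note = c("a", "b"))
  path <- temp_path("e.csv")
  write_energy_table(recs, path)
  back <- read_energy_table(path)
  expect_equal(back$E_complex, recs$E_complex)
  expect_equal(back$BE, c(8, 3))
  expect_equal(back$BE_relax, c(7, 2))
  expect_identical(back$note, c("a", "b"))   # unknown columns preserved

  # hartree conversion
  h <- temp_path("h.csv")
  writeLines(c("group_x,group_y,pose_id,E_complex,E_X_isolated,E_Y_isolated",
               "X-h,Y-h,f0.s0,-3,-1,-1"), h)
  expect_error(read_energy_table(h), NA)
  expect_equal(read_energy_table(h, unit = "hartree")$BE, 627.509474)

  # conflicting duplicates name both rows
  d <- temp_path("d.csv")
  writeLines(c("group_x,group_y,pose_id,E_complex,E_X_isolated,E_Y_isolated",
               "X-h,Y-h,f0.s0,-3,-1,-1",
               "X-h,Y-h,f0.s0,-4,-1,-1"), d)
  expect_error(read_energy_table(d), "rows 1 and 2")

  # missing column and non-numeric cells are row-addressed
  m <- temp_path("m.csv")
  writeLines(c("group_x,group_y,E_complex", "X-h,Y-h,-3"), m)
  expect_error(read_energy_table(m), "pose_id")
  nn <- temp_path("nn.csv")
  writeLines(c("group_x,group_y,pose_id,E_complex,E_X_isolated,E_Y_isolated",
               "X-h,Y-h,f0.s0,oops,-1,-1"), nn)
  expect_error(read_energy_table(nn), "row 1")
})
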