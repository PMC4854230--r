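# objective and simulated-annealing engine

test_that("objective components vanish at the ground truth", {
  fx <- helix_fx(12L)
  em <- gt_map(fx)
  rs <- build_restraints(fx$structure)
  obj <- objective(fx$structure, em, rs, w_em = 1, resolution = 3)
  expect_lt(obj$density, 1e-9)
  expect_equal(obj$stereo, 0, tolerance = 1e-9)
  expect_equal(obj$ccc, 1, tolerance = 1e-9)
})

test_that("rigid translation raises only the density term", {
  fx <- helix_fx(12L)
  em <- gt_map(fx)
  rs <- build_restraints(fx$structure)
  moved <- fx$structure
  coords(moved) <- sweep(coords(fx$structure), 2L, c(2, 0, 0), `+`)
  obj0 <- objective(fx$structure, em, rs, w_em = 1, resolution = 3)
  obj1 <- objective(moved, em, rs, w_em = 1, resolution = 3)
  expect_gt(obj1$density, obj0$density + 0.01)
  expect_equal(obj1$stereo, 0, tolerance = 1e-8)
})

test_that("a translated helix is recovered by a single-body anneal", {
  fx <- helix_fx(20L)
  em <- gt_map(fx)
  start <- perturb(fx$structure, "translate", 2, seed = 7)
  expect_equal(rmsd(fx$structure, start), 2, tolerance = 1e-9)
  rs <- build_restraints(start)
  sch <- rigid_body_scheme(list(data.frame(chain_id = "A", start = 1, end = 20)),
                           structure = start)
  cfg <- anneal_config(max_step = 0.39, steps_heat = 100L, steps_cool = 100L,
                       cycles = 3L, resolution = 3, seed = 11L)
  out <- anneal(start, em, sch, rs, cfg)
  expect_lt(rmsd(fx$structure, out$structure, "calpha"), 0.5)
  expect_lte(max(out$trace$max_step), 0.39)
})

test_that("annealing from the optimum is a fixed point", {
  fx <- helix_fx(20L)
  em <- gt_map(fx)
  rs <- build_restraints(fx$structure)
  sch <- rigid_body_scheme(list(data.frame(chain_id = "A", start = 1, end = 20)),
                           structure = fx$structure)
  cfg <- anneal_config(max_step = 0.39, steps_heat = 60L, steps_cool = 60L,
                       cycles = 1L, resolution = 3, seed = 5L)
  out <- anneal(fx$structure, em, sch, rs, cfg)
  expect_lt(rmsd(fx$structure, out$structure, "calpha"), 0.2)
  ccc0 <- global_ccc(em, simulate_density(fx$structure, 3, grid = em))
  expect_lt(abs(utils::tail(out$trace$ccc, 1) - ccc0), 0.005)
})

test_that("identical inputs and seed give byte-identical coordinates", {
  fx <- helix_fx(12L)
  em <- gt_map(fx)
  start <- perturb(fx$structure, "translate", 1.5, seed = 3)
  rs <- build_restraints(start)
  sch <- rigid_body_scheme(list(data.frame(chain_id = "A", start = 1, end = 12)),
                           structure = start)
  cfg <- anneal_config(steps_heat = 40L, steps_cool = 40L, cycles = 1L,
                       resolution = 3, seed = 42L)
  a <- anneal(start, em, sch, rs, cfg)
  b <- anneal(start, em, sch, rs, cfg)
  expect_identical(coords(a$structure), coords(b$structure))
})

test_that("rigid bodies conserve intra-body distances through many steps", {
  fx <- hairpin_fx()
  em <- gt_map(fx)
  start <- perturb(fx$structure, "translate", 1.5, seed = 9)
  rs <- build_restraints(start)
  sch <- cluster_sses(start, fx$sses)
  cfg <- anneal_config(steps_heat = 100L, steps_cool = 100L, cycles = 2L,
                       resolution = 3, seed = 2L)
  out <- anneal(start, em, sch, rs, cfg)
  rows <- flexsmoc:::atom_rows_of_uids(start,
                                       flexsmoc:::body_uids(sch$bodies[[1]],
                                                            start))
  d0 <- stats::dist(coords(start)[rows, ])
  d1 <- stats::dist(coords(out$structure)[rows, ])
  expect_lt(max(abs(d1 - d0)), 1e-6)
})

test_that("per-step per-axis displacement never exceeds the stage cap", {
  fx <- helix_fx(12L)
  em <- gt_map(fx)
  start <- perturb(fx$structure, "translate", 1.5, seed = 3)
  rs <- build_restraints(start)
  for (cap in c(0.39, 0.15, 0.1)) {
    cfg <- anneal_config(max_step = cap, steps_heat = 30L, steps_cool = 30L,
                         cycles = 1L, resolution = 3, seed = 8L)
    sch <- rigid_body_scheme(list(data.frame(chain_id = "A", start = 1,
                                             end = 12)), structure = start)
    out <- anneal(start, em, sch, rs, cfg)
    expect_lte(max(out$trace$max_step), cap)
  }
})

test_that("annealing without a density term stays restraint-anchored", {
  fx <- helix_fx(16L)
  em <- gt_map(fx)
  rs <- build_restraints(fx$structure)
  cfg <- anneal_config(max_step = 0.1, steps_heat = 80L, steps_cool = 80L,
                       cycles = 1L, w_em = 0, resolution = 3, seed = 13L)
  out <- anneal(fx$structure, em, rigid_body_scheme(list(), level = "all_atom"),
                rs, cfg)
  expect_lt(rmsd(fx$structure, out$structure, "calpha"), 0.3)
})

test_that("zero cycles return the input unchanged with an empty trace", {
  fx <- helix_fx(12L)
  em <- gt_map(fx)
  rs <- build_restraints(fx$structure)
  cfg <- anneal_config(cycles = 0L, resolution = 3)
  out <- anneal(fx$structure, em, rigid_body_scheme(list(), level = "all_atom"),
                rs, cfg)
  expect_identical(coords(out$structure), coords(fx$structure))
  expect_length(out$trace$ccc, 0L)
})

test_that("a structure outside the map support aborts with a diagnostic", {
  fx <- helix_fx(12L)
  em <- gt_map(fx)
  far <- fx$structure
  coords(far) <- coords(fx$structure) + 300
  rs <- build_restraints(far)
  cfg <- anneal_config(steps_heat = 5L, steps_cool = 5L, cycles = 1L,
                       resolution = 3, seed = 1L)
  expect_error(anneal(far, em, rigid_body_scheme(list(), level = "all_atom"),
                      rs, cfg),
               "support|variance")
})
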