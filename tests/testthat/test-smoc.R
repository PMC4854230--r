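# SMOC scoring, profiles, Z-scores, flagging, profile comparison

test_that("segment voxel masks follow the occupancy geometry", {
  at <- data.frame(serial = 1L, name = "CA", element = "C", alt_loc = "",
                   res_name = "ALA", chain_id = "A", res_seq = 1L,
                   insertion_code = "", x = 0, y = 0, z = 0, occupancy = 1,
                   b_iso = 0)
  s <- model_structure(at)
  g <- density_grid(array(1, c(9L, 9L, 9L)), spacing = 1, origin = c(-4, -4, -4))
  seg <- residue_segment("A", 1L)
  ## radius just under the spacing: only the central voxel
  v1 <- segment_voxels(g, s, seg, radius = 0.99)
  expect_equal(length(v1$idx), 1L)
  ## radius just over: center + 6 face neighbours (brute-force distance scan)
  v7 <- segment_voxels(g, s, seg, radius = 1.01)
  expect_equal(length(v7$idx), 7L)
  centers <- expand.grid(x = -4:4, y = -4:4, z = -4:4)
  brute <- which(sqrt(rowSums(centers^2)) <= 1.01)
  expect_equal(v7$idx, sort(brute))
})

test_that("overlapping atom spheres union without duplicates", {
  at <- data.frame(serial = 1:2, name = c("CA", "CB"), element = "C",
                   alt_loc = "", res_name = "ALA", chain_id = "A",
                   res_seq = 1L, insertion_code = "", x = c(0, 0.5), y = 0,
                   z = 0, occupancy = 1, b_iso = 0)
  s <- model_structure(at)
  g <- density_grid(array(1, c(9L, 9L, 9L)), spacing = 1, origin = c(-4, -4, -4))
  v <- segment_voxels(g, s, residue_segment("A", 1L), radius = 1.3)
  expect_equal(anyDuplicated(v$idx), 0L)
  expect_true(length(v$idx) < 2L * 7L)
})

test_that("smoc_segment matches the brute-force oracle to 1e-12", {
  for (seed in 1:4) {
    em <- random_grid(c(13L, 16L, 11L), seed = seed)
    md <- random_grid(c(13L, 16L, 11L), seed = seed + 100L)
    set.seed(seed + 200L)
    idx <- sample(prod(em$dims), 150L)
    vox <- grid_index_set(idx, em)
    expect_equal(smoc_segment(em, md, vox), smoc_oracle(em, md, idx),
                 tolerance = 1e-12)
  }
})

test_that("smoc_segment on hand-set 2x2x2 values matches a direct sum", {
  em <- density_grid(array(c(1, 0, 0.5, 0, 0, 0, 0, 0), c(2L, 2L, 2L)))
  md <- density_grid(array(c(1, 1, 0.25, 0, 0, 0, 0, 0), c(2L, 2L, 2L)))
  vox <- grid_index_set(c(1L, 3L), em)
  expect_equal(smoc_segment(em, md, vox),
               (1 * 1 + 0.5 * 0.25) / sqrt((1 + 0.25) * (1 + 0.0625)))
})

test_that("SMOC is scale-invariant but offset-sensitive; CCC is both", {
  fx <- helix_fx(10L)
  em <- gt_map(fx)
  md <- simulate_density(fx$structure, 3, grid = em)
  vox <- segment_voxels(em, fx$structure, residue_segment("A", 3:7))
  base <- smoc_segment(em, md, vox)
  scaled <- density_grid(2 * em$values, em$spacing, em$origin)
  offset <- density_grid(em$values + 0.5, em$spacing, em$origin)
  expect_equal(smoc_segment(scaled, md, vox), base, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(smoc_segment(offset, md, vox), base,
                                tolerance = 1e-4)))
  expect_equal(global_ccc(em, scaled), 1.0)
  expect_equal(global_ccc(em, offset), 1.0)
})

test_that("the SCCC flag mean-subtracts before the overlap sum", {
  em <- random_grid(c(6L, 6L, 6L), seed = 3)
  md <- random_grid(c(6L, 6L, 6L), seed = 4)
  vox <- grid_index_set(1:40, em)
  a <- as.numeric(em$values)[1:40]; b <- as.numeric(md$values)[1:40]
  a <- a - mean(a); b <- b - mean(b)
  expect_equal(smoc_segment(em, md, vox, mean_subtract = TRUE),
               sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
})

test_that("flat density over the mask errors", {
  em <- density_grid(array(0, c(4L, 4L, 4L)))
  md <- density_grid(array(1, c(4L, 4L, 4L)))
  expect_error(smoc_segment(em, md, grid_index_set(1:5, em)), "flat")
})

test_that("a perfect-fit profile scores 1 everywhere and is total", {
  fx <- hlh_fx()
  em <- gt_map(fx)
  p <- smoc_profile(em, fx$structure, fx$sses, 3)
  expect_equal(nrow(p$residues), nrow(residues(fx$structure)))
  expect_equal(anyDuplicated(p$residues$uid), 0L)
  expect_true(all(abs(p$residues$smoc - 1) < 1e-6))
})

test_that("windows shrink on short chains but the profile stays total", {
  fx <- helix_fx(5L)
  em <- gt_map(fx)
  sses <- sse_annotation(data.frame(kind = character(), chain_id = character(),
                                    start = integer(), end = integer()))
  p <- smoc_profile(em, fx$structure, sses, 3, window = 9L)
  expect_equal(nrow(p$residues), 5L)
  expect_true(all(is.finite(p$residues$smoc)))
  ## with the whole chain shorter than the window all residues share a score
  expect_equal(length(unique(round(p$residues$smoc, 12))), 1L)
})

test_that("averaged window assignment stays within the per-window range", {
  fx <- hlh_fx()
  em <- gt_map(fx)
  bad <- perturb(fx, "loop_displace", 5, seed = 3)
  p_c <- smoc_profile(em, bad, fx$sses, 3)
  p_a <- smoc_profile(em, bad, fx$sses, 3, loop_assign = "average")
  loop <- fx$meta$loops[[1]]
  in_loop <- p_c$residues$res_seq %in% loop$res_seq
  expect_true(all(p_a$residues$smoc[in_loop] >=
                    min(p_c$residues$smoc[in_loop]) - 1e-12))
  expect_true(all(p_a$residues$smoc[in_loop] <=
                    max(p_c$residues$smoc[in_loop]) + 1e-12))
})

test_that("a displaced loop scores strictly below every SSE residue", {
  fx <- hlh_fx()
  em <- gt_map(fx)
  bad <- perturb(fx, "loop_displace", 5, seed = 3)
  p <- smoc_profile(em, bad, fx$sses, 3)
  loop <- fx$meta$loops[[1]]
  in_loop <- p$residues$res_seq %in% loop$res_seq
  expect_true(max(p$residues$smoc[in_loop]) < min(p$residues$smoc[!in_loop]))
})

test_that("Z-scores reproduce the hand-computed worked example", {
  fx <- helix_fx(5L)
  em <- gt_map(fx)
  p <- smoc_profile(em, fx$structure, fx$sses, 3)
  p$residues$smoc <- c(0.8, 0.8, 0.8, 0.8, 0.4)
  z <- smoc_zscores(p)
  expect_equal(z$mu, 0.72)
  expect_equal(z$sigma, 0.16)
  expect_equal(z$residues$z, c(0.5, 0.5, 0.5, 0.5, -2.0))
})

test_that("Z-score normalisation identities hold for random profiles", {
  fx <- helix_fx(20L)
  em <- gt_map(fx)
  p0 <- smoc_profile(em, fx$structure, fx$sses, 3)
  for (seed in 1:5) {
    set.seed(seed)
    p <- p0
    p$residues$smoc <- stats::runif(20, 0.3, 1)
    z <- smoc_zscores(p)
    expect_equal(mean(z$residues$z), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(z$residues$z^2)), 1, tolerance = 1e-9)
  }
})

test_that("a constant profile warns and yields all-zero Z", {
  fx <- helix_fx(5L)
  em <- gt_map(fx)
  p <- smoc_profile(em, fx$structure, fx$sses, 3)
  p$residues$smoc <- rep(0.9, 5)
  expect_warning(z <- smoc_zscores(p), "constant")
  expect_equal(z$residues$z, rep(0, 5))
})

test_that("flagging drops short runs and returns empty when all fit", {
  fx <- helix_fx(20L)
  em <- gt_map(fx)
  p <- smoc_profile(em, fx$structure, fx$sses, 3)
  ## all fit: nothing flagged
  p$residues$smoc <- rep(0.9, 20)
  p$residues$smoc[3] <- 0.91
  z <- smoc_zscores(p)
  expect_length(flag_poor_segments(z, fx$sses), 0L)
  ## one isolated low residue is dropped at min_run = 3
  p$residues$smoc <- c(rep(0.9, 9), 0.2, rep(0.9, 10))
  z <- smoc_zscores(p)
  expect_length(flag_poor_segments(z, fx$sses, min_run = 3L), 0L)
  expect_length(flag_poor_segments(z, fx$sses, min_run = 1L), 1L)
  ## a 4-residue run is kept with its bounds
  p$residues$smoc <- c(rep(0.9, 8), rep(0.2, 4), rep(0.9, 8))
  z <- smoc_zscores(p)
  fl <- flag_poor_segments(z, fx$sses)
  expect_length(fl, 1L)
  expect_equal(range(fl[[1]]$res_seq), c(9L, 12L))
  expect_error(flag_poor_segments(z, fx$sses, threshold = 0.5))
})

test_that("profile comparison reports deltas and improvement fraction", {
  fx <- helix_fx(10L)
  em <- gt_map(fx)
  a <- smoc_profile(em, fx$structure, fx$sses, 3)
  d0 <- compare_profiles(a, a)
  expect_true(all(d0$delta == 0))
  expect_equal(attr(d0, "fraction_improved"), 0)
  b <- a
  b$residues$smoc <- a$residues$smoc - 0.1  # so that b -> a improves by 0.1
  d1 <- compare_profiles(b, a)
  expect_true(all(abs(d1$delta - 0.1) < 1e-12))
  expect_equal(attr(d1, "fraction_improved"), 1.0)
  expect_equal(attr(d1, "mean_delta"), 0.1)
  short <- a
  short$residues <- a$residues[-1, ]
  expect_error(compare_profiles(a, short), "different residues")
})
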