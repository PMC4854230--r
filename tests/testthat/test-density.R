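# map I/O, model-density simulation, sharpening, global correlation

test_that("MRC write/read round-trips values and header geometry", {
  g <- random_grid(c(8L, 8L, 8L), seed = 1, spacing = c(1.1, 1.2, 0.9),
                   origin = c(-3, 2.5, 0))
  f <- tempfile(fileext = ".mrc")
  write_mrc(g, f)
  g2 <- read_mrc(f)
  expect_equal(g2$dims, g$dims)
  expect_equal(g2$spacing, g$spacing, tolerance = 1e-6)
  expect_equal(g2$origin, g$origin, tolerance = 1e-5)
  expect_equal(g2$values, g$values, tolerance = 1e-6)
})

## independent minimal MRC writer used to exercise the header rules
write_raw_mrc <- function(path, dims, values, nstart = c(0L, 0L, 0L),
                          origin = c(0, 0, 0), spacing = 1, mode = 2L,
                          mapcrs = 1:3) {
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(c(dims, mode, nstart, dims))
  wf(dims * spacing)
  wf(c(90, 90, 90))
  wi(mapcrs)
  wf(c(min(values), max(values), mean(values)))
  wi(c(1L, 0L))
  writeBin(raw(100L), con)
  wf(origin)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(0)
  wi(0L)
  writeBin(raw(800L), con)
  if (mode == 2L) writeBin(as.numeric(values), con, size = 4L,
                           endian = "little")
  else writeBin(as.integer(values), con, size = 2L, endian = "little")
}

test_that("origin follows NxSTART when the ORIGIN record is zero", {
  f <- tempfile(fileext = ".mrc")
  write_raw_mrc(f, c(6L, 6L, 6L), seq_len(216), nstart = c(-4L, -4L, -4L))
  g <- read_mrc(f)
  expect_equal(g$origin, c(-4, -4, -4))
})

test_that("a non-zero ORIGIN record takes precedence over NxSTART", {
  f <- tempfile(fileext = ".mrc")
  write_raw_mrc(f, c(6L, 6L, 6L), seq_len(216), nstart = c(-4L, -4L, -4L),
                origin = c(10.5, 0, 0))
  g <- read_mrc(f)
  expect_equal(g$origin, c(10.5, 0, 0))
})

test_that("16-bit integer maps are read and exotic modes rejected", {
  f <- tempfile(fileext = ".mrc")
  write_raw_mrc(f, c(4L, 4L, 4L), seq_len(64), mode = 1L)
  g <- read_mrc(f)
  expect_equal(as.numeric(g$values), as.numeric(seq_len(64)))
  write_raw_mrc(f, c(4L, 4L, 4L), seq_len(64), mode = 2L)
  ## corrupt the mode word to an unsupported value
  con <- file(f, "r+b"); seek(con, 12, rw = "write")
  writeBin(4L, con, size = 4L, endian = "little"); close(con)
  expect_error(read_mrc(f), "mode")
  ## truncated data block
  write_raw_mrc(f, c(40L, 40L, 40L), seq_len(64), mode = 2L)
  expect_error(read_mrc(f), "smaller")
})

test_that("axis-permuted maps are normalised to x-fastest", {
  arr <- array(stats::rnorm(4 * 5 * 6), c(4L, 5L, 6L))  # (x, y, z)
  ## store sections as x: file order (z, y, x) with mapc=3, mapr=2, maps=1
  perm <- aperm(arr, c(3L, 2L, 1L))
  f <- tempfile(fileext = ".mrc")
  write_raw_mrc(f, dim(perm), as.numeric(perm), mapcrs = c(3L, 2L, 1L))
  g <- read_mrc(f)
  expect_equal(g$dims, dim(arr))
  expect_equal(g$values, arr, tolerance = 1e-6)
})

test_that("a single atom's density peaks at the atom and integrates to Z", {
  at <- data.frame(serial = 1L, name = "C", element = "C", alt_loc = "",
                   res_name = "UNK", chain_id = "A", res_seq = 1L,
                   insertion_code = "", x = 0, y = 0, z = 0, occupancy = 1,
                   b_iso = 0)
  s <- model_structure(at)
  grid <- density_grid(array(0, c(21L, 21L, 21L)), spacing = 1,
                       origin = c(-10, -10, -10))
  g <- simulate_density(s, resolution = 3, grid = grid)
  expect_equal(unname(which(g$values == max(g$values), arr.ind = TRUE)[1, ]),
               c(11L, 11L, 11L))
  expect_equal(sum(g$values) * prod(g$spacing), 6, tolerance = 0.01)
})

test_that("density is equivariant under whole-voxel translations", {
  fx <- helix_fx(8L)
  grid <- bounding_grid(fx$structure, spacing = 1, pad = 8)
  g1 <- simulate_density(fx$structure, 3, grid = grid)
  shifted <- fx$structure
  coords(shifted) <- sweep(coords(fx$structure), 2L, c(1, 0, 0), `+`)
  g2 <- simulate_density(shifted, 3, grid = grid)
  n <- g1$dims[1L]
  expect_equal(g2$values[2:n, , ], g1$values[1:(n - 1L), , ],
               tolerance = 1e-10)
})

test_that("density is linear in atoms (superposition oracle)", {
  mk <- function(xx) {
    at <- data.frame(serial = 1L, name = "C", element = "C", alt_loc = "",
                     res_name = "UNK", chain_id = "A", res_seq = 1L,
                     insertion_code = "", x = xx, y = 0, z = 0,
                     occupancy = 1, b_iso = 0)
    model_structure(at)
  }
  grid <- density_grid(array(0, c(40L, 12L, 12L)), spacing = 1,
                       origin = c(-5, -5, -5))
  g1 <- simulate_density(mk(0), 3, grid = grid)
  g2 <- simulate_density(mk(20), 3, grid = grid)
  both <- mk(0)
  b2 <- mk(20); b2$atoms$serial <- 2L; b2$atoms$res_seq <- 2L
  pair <- model_structure(rbind(both$atoms, b2$atoms))
  g12 <- simulate_density(pair, 3, grid = grid)
  expect_equal(g12$values, g1$values + g2$values, tolerance = 1e-6)
})

test_that("atoms outside the grid warn and non-positive resolution errors", {
  fx <- helix_fx(8L)
  tiny <- density_grid(array(0, c(4L, 4L, 4L)), origin = c(500, 500, 500))
  expect_warning(simulate_density(fx$structure, 3, grid = tiny), "outside")
  expect_error(simulate_density(fx$structure, -1), "positive")
})

test_that("map noise is seeded, additive and degrades self-correlation", {
  g <- gt_map(helix_fx(10L))
  n1 <- add_map_noise(g, sd = 0.05, seed = 3L)
  n2 <- add_map_noise(g, sd = 0.05, seed = 3L)
  expect_identical(n1$values, n2$values)
  expect_equal(mean(n1$values - g$values), 0, tolerance = 1e-3)
  expect_lt(global_ccc(g, n1), 1)
  expect_gt(global_ccc(g, n1), 0.5)
})

test_that("sharpening: B = 0 identity and inverse-pair recovery", {
  g <- gt_map(helix_fx(10L))
  expect_equal(sharpen_map(g, 0)$values, g$values)
  back <- sharpen_map(sharpen_map(g, -105), 105)
  expect_equal(back$values, g$values, tolerance = 1e-8)
  ## the mean (s = 0 term) is preserved by sharpening
  sh <- sharpen_map(g, -105)
  expect_equal(mean(sh$values), mean(g$values), tolerance = 1e-10)
})

test_that("global CCC: identity, negation, mean invariance, affine invariance", {
  g <- gt_map(helix_fx(10L))
  neg <- density_grid(-g$values, g$spacing, g$origin)
  plus <- density_grid(g$values + 5, g$spacing, g$origin)
  aff <- density_grid(2.5 * g$values + 1, g$spacing, g$origin)
  expect_equal(global_ccc(g, g), 1.0)
  expect_equal(global_ccc(g, neg), -1.0)
  expect_equal(global_ccc(g, plus), 1.0)
  expect_equal(global_ccc(g, aff), 1.0)
  flat <- density_grid(array(1, g$dims), g$spacing, g$origin)
  expect_error(global_ccc(g, flat), "variance")
  ## masked correlation on an 8^3 sub-block agrees with a direct sum
  idx <- which(array(seq_len(prod(g$dims)), g$dims) %% 7L == 0L)
  mask <- grid_index_set(idx, g)
  a <- as.numeric(g$values)[mask$idx]
  b <- as.numeric(aff$values)[mask$idx]
  expect_equal(global_ccc(g, aff, mask),
               sum((a - mean(a)) * (b - mean(b))) /
                 sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))
})
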