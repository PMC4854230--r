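# SSE assignment and RIBFIND-style rigid-body clustering

test_that("an ideal poly-Ala helix is assigned as one full-length helix", {
  fx <- helix_fx(20L)
  sses <- assign_sses(fx$structure)
  expect_equal(nrow(sses$segments), 1L)
  expect_equal(sses$segments$kind, "helix")
  expect_equal(sses$segments$start, 1L)
  expect_equal(sses$segments$end, 20L)
})

test_that("a fully extended chain gets no helix", {
  bb <- flexsmoc:::nerf_backbone(rep(-180, 10), rep(180, 10))
  deco <- flexsmoc:::decorate_backbone(bb, rep(180, 10))
  s <- flexsmoc:::backbone_to_structure(bb, deco)
  sses <- assign_sses(s)
  expect_false(any(sses$segments$kind == "helix"))
})

test_that("a helix-loop-helix fixture yields exactly two helix segments", {
  fx <- hlh_fx()
  sses <- assign_sses(fx$structure)
  hel <- sses$segments[sses$segments$kind == "helix", ]
  expect_equal(nrow(hel), 2L)
  ## each found helix overlaps one of the built helices and not the loop core
  built <- fx$sses$segments
  expect_true(hel$start[1] <= built$end[1] && hel$end[1] >= built$start[1])
  expect_true(hel$start[2] <= built$end[2] && hel$end[2] >= built$start[2])
})

test_that("tiny chains produce no SSEs with a warning", {
  fx <- helix_fx(20L)
  small <- model_structure(fx$structure$atoms[1:15, ])
  expect_warning(sses <- assign_sses(small), "fewer than 4")
  expect_equal(nrow(sses$segments), 0L)
})

test_that("contact weights are symmetric fractions in [0, 1]", {
  fx <- hinge_fx()
  g <- sse_contact_graph(fx$structure, fx$sses)
  expect_true(all(g$weight >= 0 & g$weight <= 1))
  expect_equal(g$weight, t(g$weight))
})

test_that("two distant helices stay singleton bodies with a free loop", {
  fx <- helix_fx(12L)
  far <- fx$structure
  ## second helix 30 A away, same chain, residues 21-32 (chain break)
  b <- fx$structure$atoms
  b$res_seq <- b$res_seq + 20L
  b$serial <- b$serial + nrow(b)
  b$x <- b$x + 30
  far <- model_structure(rbind(fx$structure$atoms, b))
  sses <- sse_annotation(data.frame(kind = "helix", chain_id = "A",
                                    start = c(1L, 21L), end = c(12L, 32L)),
                         far)
  sch <- cluster_sses(far, sses)
  expect_length(sch$bodies, 2L)
  expect_equal(vapply(sch$bodies, nrow, 1L), c(1L, 1L))
})

test_that("a packed hairpin clusters into one body including its loop", {
  fx <- hairpin_fx()
  sch <- cluster_sses(fx$structure, fx$sses)
  expect_length(sch$bodies, 1L)
  covered <- unlist(lapply(seq_len(nrow(sch$bodies[[1]])), function(i)
    sch$bodies[[1]]$start[i]:sch$bodies[[1]]$end[i]))
  expect_setequal(covered, 1:25)  # both helices plus the hairpin loop
})

test_that("clusters agree with a union-find oracle on the contact matrix", {
  fx <- make_fixture("four_helix_bundle")
  ## add a displaced helix 30 A away as residues 60-69 of the same chain
  h <- helix_fx(10L)$structure$atoms
  h$res_seq <- h$res_seq + 59L
  h$serial <- h$serial + 1000L
  h$x <- h$x + 60
  combo <- model_structure(rbind(fx$structure$atoms, h))
  seg <- rbind(fx$sses$segments,
               data.frame(kind = "helix", chain_id = "A", start = 60L,
                          end = 69L))
  sses <- sse_annotation(seg, combo)
  sch <- cluster_sses(combo, sses)
  expect_length(sch$bodies, 2L)
  sizes <- sort(vapply(sch$bodies, function(b)
    sum(b$end - b$start + 1L), integer(1L)))
  expect_equal(sizes[1], 10L)          # the singleton helix
  expect_true(sizes[2] >= 40L)         # the 4-helix cluster (plus loops)
  ## union-find oracle on the explicit contact matrix
  g <- sse_contact_graph(combo, sses)
  n <- nrow(g$segments)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (g$weight[i, j] >= 0.1) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  comps <- length(unique(vapply(seq_len(n), find, 1L)))
  expect_equal(length(sch$bodies), comps)
})

test_that("clustering is invariant under global rotation and translation", {
  fx <- hairpin_fx()
  moved <- fx$structure
  R <- flexsmoc:::rotation_matrix(c(1, 2, 3), 1.1)
  coords(moved) <- sweep(coords(fx$structure) %*% t(R), 2L, c(15, -8, 4), `+`)
  sch0 <- cluster_sses(fx$structure, fx$sses)
  sch1 <- cluster_sses(moved, fx$sses)
  expect_equal(sch1$bodies, sch0$bodies)
})

test_that("increasing the cutoff never shrinks the largest cluster", {
  fx <- hinge_fx()
  largest <- function(cutoff) {
    sch <- cluster_sses(fx$structure, fx$sses, cutoff = cutoff)
    max(vapply(sch$bodies, function(b) sum(b$end - b$start + 1L), integer(1L)))
  }
  sizes <- vapply(c(5, 6.5, 8, 10, 14), largest, numeric(1L))
  expect_true(all(diff(sizes) >= 0))
})

test_that("hierarchy levels produce the expected schemes", {
  fx <- hairpin_fx()
  clusters <- cluster_sses(fx$structure, fx$sses)
  expect_length(scheme_for_level(fx$sses, clusters, "all_atom")$bodies, 0L)
  sse_sch <- scheme_for_level(fx$sses, clusters, "sse")
  expect_length(sse_sch$bodies, 2L)
  expect_equal(sse_sch$bodies[[1]]$start, fx$sses$segments$start[1])
  rb <- scheme_for_level(fx$sses, clusters, "ribfind_clusters")
  expect_equal(rb$bodies, clusters$bodies)
  ## every SSE residue belongs to exactly one body at both levels
  for (sch in list(sse_sch, rb)) {
    cov <- unlist(lapply(sch$bodies, function(b)
      unlist(mapply(seq, b$start, b$end, SIMPLIFY = FALSE))))
    sse_res <- unlist(mapply(seq, fx$sses$segments$start,
                             fx$sses$segments$end, SIMPLIFY = FALSE))
    expect_equal(anyDuplicated(cov), 0L)
    expect_true(all(sse_res %in% cov))
  }
})
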