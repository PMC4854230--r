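# Shared fixtures.  make_fixture() memoises construction per (kind, n), so
# these helpers are cheap after the first call in a session.

helix_fx <- function(n = 20L) make_fixture("helix", n)
hlh_fx <- function() make_fixture("helix_loop_helix")
hairpin_fx <- function() make_fixture("helix_loop_helix", n = c(10L, 5L, 10L))
hinge_fx <- function() make_fixture("two_domain_hinge")

gt_map <- function(fx, resolution = 3) simulate_density(fx$structure, resolution)

## small deterministic random grid for oracle tests
random_grid <- function(dims, seed, spacing = 1, origin = c(0, 0, 0)) {
  set.seed(seed)
  density_grid(array(stats::runif(prod(dims)), dims), spacing = spacing,
               origin = origin)
}

## independent direct-sum SMOC oracle over explicit voxel indices
smoc_oracle <- function(em, model, idx) {
  num <- 0; sa <- 0; sb <- 0
  ev <- as.numeric(em$values); mv <- as.numeric(model$values)
  for (i in idx) {
    num <- num + ev[i] * mv[i]
    sa <- sa + ev[i]^2
    sb <- sb + mv[i]^2
  }
  num / sqrt(sa * sb)
}

## tiny PDB text fixture writer
write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, res_name, chain, res_seq, x, y, z,
                          occ = 1, b = 0, element = "C", alt = "") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name), alt,
          res_name, chain, res_seq, x, y, z, occ, b, element)
}
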