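# Synthetic ground-truth fixtures: ideal poly-Ala structures built from
# internal coordinates, perturbations that emulate the conformational
# difference between a starting model and the map's state, and the RMSD
# metrics used to report recovery.

## ideal poly-Ala backbone geometry (Angstrom / degrees)
BB_GEOM <- list(b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231,
                b_CACB = 1.521, a_CNCA = 121.7, a_NCAC = 111.2,
                a_CACN = 116.2, a_CACO = 120.8, a_NCACB = 110.4,
                t_CNCACB = -122.6, omega = 180)

HELIX_PHI <- -57; HELIX_PSI <- -47

## Extend a backbone by k residues from the previous residue triad.
## psi_prev places N1; phi/psi/omega are length-k vectors (psi[k] is used for
## the carbonyl O and, when ghost=TRUE, to place the next residue's N).
## Returns list(N, CA, C [k x 3], ghost [3 x 3 or NULL]).
nerf_extend <- function(prev, psi_prev, phi, psi,
                        omega = rep(BB_GEOM$omega, length(phi)),
                        ghost = FALSE, phi_ghost = -100) {
  k <- length(phi)
  g <- BB_GEOM
  N <- CA <- C <- matrix(0, k, 3L)
  pN <- prev$N; pCA <- prev$CA; pC <- prev$C
  tor_to_N <- psi_prev
  for (i in seq_len(k)) {
    N[i, ] <- place_atom(pN, pCA, pC, g$b_CN, g$a_CACN, tor_to_N)
    CA[i, ] <- place_atom(pCA, pC, N[i, ], g$b_NCA, g$a_CNCA, omega[i])
    C[i, ] <- place_atom(pC, N[i, ], CA[i, ], g$b_CAC, g$a_NCAC, phi[i])
    pN <- N[i, ]; pCA <- CA[i, ]; pC <- C[i, ]
    tor_to_N <- psi[i]
  }
  gh <- NULL
  if (ghost) {
    gN <- place_atom(pN, pCA, pC, g$b_CN, g$a_CACN, psi[k])
    gCA <- place_atom(pCA, pC, gN, g$b_NCA, g$a_CNCA, g$omega)
    gC <- place_atom(pC, gN, gCA, g$b_CAC, g$a_NCAC, phi_ghost)
    gh <- rbind(gN, gCA, gC)
  }
  list(N = N, CA = CA, C = C, ghost = gh)
}

## Backbone for n residues starting at a canonical origin frame.
nerf_backbone <- function(phi, psi, omega = rep(BB_GEOM$omega, length(phi))) {
  g <- BB_GEOM
  n <- length(phi)
  ang <- deg2rad(g$a_NCAC)
  N1 <- c(0, 0, 0)
  CA1 <- c(g$b_NCA, 0, 0)
  C1 <- CA1 + g$b_CAC * c(-cos(ang), sin(ang), 0)
  if (n == 1L) return(list(N = rbind(N1), CA = rbind(CA1), C = rbind(C1)))
  ext <- nerf_extend(list(N = N1, CA = CA1, C = C1), psi_prev = psi[1L],
                     phi = phi[-1L], psi = psi[-1L], omega = omega[-1L])
  list(N = rbind(N1, ext$N), CA = rbind(CA1, ext$CA), C = rbind(C1, ext$C))
}

## Carbonyl O and Cbeta from a backbone, given per-residue psi (psi of the
## last residue defaults to the helix value when unknown).
decorate_backbone <- function(bb, psi) {
  g <- BB_GEOM
  n <- nrow(bb$N)
  O <- CB <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    O[i, ] <- place_atom(bb$N[i, ], bb$CA[i, ], bb$C[i, ], g$b_CO, g$a_CACO,
                         psi[i] + 180)
    CB[i, ] <- place_atom(bb$C[i, ], bb$N[i, ], bb$CA[i, ], g$b_CACB,
                          g$a_NCACB, g$t_CNCACB)
  }
  list(O = O, CB = CB)
}

## measured psi for each residue that has a following N
measured_psi <- function(bb) {
  n <- nrow(bb$N)
  psi <- rep(HELIX_PSI, n)
  if (n > 1L)
    for (i in seq_len(n - 1L))
      psi[i] <- dihedral_deg(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$N[i + 1L, ])
  psi
}

## Assemble N/CA/C/O/CB matrices into a model_structure (poly-Ala, chain A).
backbone_to_structure <- function(bb, deco, chain = "A", start_res = 1L,
                                  title = "fixture") {
  n <- nrow(bb$N)
  per <- list(N = list(bb$N, "N"), CA = list(bb$CA, "C"), C = list(bb$C, "C"),
              O = list(deco$O, "O"), CB = list(deco$CB, "C"))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    xyz <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], deco$O[i, ], deco$CB[i, ])
    rows[[i]] <- data.frame(serial = 0L,
                            name = c("N", "CA", "C", "O", "CB"),
                            element = c("N", "C", "C", "O", "C"),
                            alt_loc = "", res_name = "ALA", chain_id = chain,
                            res_seq = start_res + i - 1L, insertion_code = "",
                            x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                            occupancy = 1, b_iso = 0,
                            stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  model_structure(atoms, title = title)
}

## helix axis from CA positions: centroid plus first principal component,
## oriented from the N- to the C-terminal end
helix_axis <- function(CA) {
  ctr <- colMeans(CA)
  pc <- svd(sweep(CA, 2L, ctr))$v[, 1L]
  if (sum(pc * (CA[nrow(CA), ] - CA[1L, ])) < 0) pc <- -pc
  span <- range((CA %*% pc) - sum(ctr * pc))
  list(dir = unit(pc), center = ctr, half = diff(span) / 2)
}

## Place an ideal helix fragment antiparallel to a previous helix at a given
## perpendicular offset, then build a connecting loop closed by CCD.
## bb: current backbone matrices; prev_range: residue rows of the previous
## helix.  Returns extended backbone matrices plus the new element ranges.
append_packed_helix <- function(bb, prev_range, loop_len, helix_len,
                                offset = 7.5, offset_dir = NULL) {
  ax <- helix_axis(bb$CA[prev_range, , drop = FALSE])
  if (is.null(offset_dir)) {
    e <- if (abs(ax$dir[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    offset_dir <- unit(e - sum(e * ax$dir) * ax$dir)
  } else offset_dir <- unit(offset_dir - sum(offset_dir * ax$dir) * ax$dir)
  ## ideal fragment in its own frame
  frag <- nerf_backbone(rep(HELIX_PHI, helix_len), rep(HELIX_PSI, helix_len))
  fax <- helix_axis(frag$CA)
  ## rotate fragment axis onto -prev axis
  target_dir <- -ax$dir
  cr <- vcross(fax$dir, target_dir)
  dt <- sum(fax$dir * target_dir)
  rot <- if (vnorm(cr) < 1e-8) {
    if (dt > 0) diag(3L) else rotation_matrix(
      unit(if (abs(fax$dir[1L]) < 0.9) vcross(fax$dir, c(1, 0, 0))
           else vcross(fax$dir, c(0, 1, 0))), pi)
  } else rotation_matrix(cr, acos(max(-1, min(1, dt))))
  apply_rt <- function(M, R, t) sweep(M %*% t(R), 2L, t, `+`)
  ## antiparallel placement: fragment axis line offset laterally from the
  ## previous helix axis, axial extents side by side.  The roll (rotation
  ## about the fragment's own axis) is chosen to pack the most CA pairs
  ## against the previous helix while keeping the decorated fragment (O and
  ## CB included) clash-free against everything built so far.
  target_center <- ax$center + offset * offset_dir
  prev_CA <- bb$CA[prev_range, , drop = FALSE]
  bb_deco <- decorate_backbone(bb, measured_psi(bb))
  bb_pts <- rbind(bb$N, bb$CA, bb$C, bb_deco$O, bb_deco$CB)
  best_roll <- NULL
  for (roll in seq(0, 345, by = 15)) {
    R <- rotation_matrix(target_dir, deg2rad(roll)) %*% rot
    ctr <- as.numeric(helix_axis(frag$CA %*% t(R))$center)
    sh <- target_center - ctr
    fr <- list(N = apply_rt(frag$N, R, sh), CA = apply_rt(frag$CA, R, sh),
               C = apply_rt(frag$C, R, sh))
    d <- sqrt(outer(rowSums(prev_CA^2), rowSums(fr$CA^2), `+`) -
                2 * prev_CA %*% t(fr$CA))
    frac <- mean(d <= 6.5)
    fr_deco <- decorate_backbone(fr, measured_psi(fr))
    fr_pts <- rbind(fr$N, fr$CA, fr$C, fr_deco$O, fr_deco$CB)
    cross <- sqrt(max(0, min(outer(rowSums(fr_pts^2), rowSums(bb_pts^2), `+`) -
                               2 * fr_pts %*% t(bb_pts))))
    feasible <- cross >= 2.45 && min(d) >= 3.2
    key <- c(feasible, frac, cross)
    if (is.null(best_roll) ||
        (key[1L] > best_roll$key[1L]) ||
        (key[1L] == best_roll$key[1L] && key[2L] > best_roll$key[2L]) ||
        (key[1L] == best_roll$key[1L] && key[2L] == best_roll$key[2L] &&
         key[3L] > best_roll$key[3L]))
      best_roll <- list(frag = fr, key = key)
  }
  frag <- best_roll$frag
  ## connecting loop with CCD closure onto the fragment's first residue;
  ## seeded random torsion restarts until the closed loop is clash-free
  last <- nrow(bb$N)
  nb <- last
  prev <- list(N = bb$N[last, ], CA = bb$CA[last, ], C = bb$C[last, ])
  targets <- rbind(frag$N[1L, ], frag$CA[1L, ], frag$C[1L, ])
  frag_deco <- decorate_backbone(frag, measured_psi(frag))
  other_pts <- rbind(bb_pts,
                     rbind(frag$N, frag$CA, frag$C, frag_deco$O, frag_deco$CB))
  ## global residue id per row of other_pts (loop occupies nb+1 .. nb+k)
  other_rid <- c(rep(seq_len(nb), 5L),
                 rep(nb + loop_len + seq_len(nrow(frag$N)), 5L))
  clearance <- function(loop_bb) {
    k <- nrow(loop_bb$N)
    psi_l <- numeric(k)
    for (i in seq_len(k)) {
      nN <- if (i < k) loop_bb$N[i + 1L, ] else frag$N[1L, ]
      psi_l[i] <- dihedral_deg(loop_bb$N[i, ], loop_bb$CA[i, ],
                               loop_bb$C[i, ], nN)
    }
    dl <- decorate_backbone(loop_bb, psi_l)
    pts <- rbind(loop_bb$N, loop_bb$CA, loop_bb$C, dl$O, dl$CB)
    rid <- rep(nb + seq_len(k), 5L)
    dx <- outer(rowSums(pts^2), rowSums(other_pts^2), `+`) -
      2 * pts %*% t(other_pts)
    dx[abs(outer(rid, other_rid, `-`)) <= 1L] <- Inf
    di <- outer(rowSums(pts^2), rowSums(pts^2), `+`) - 2 * pts %*% t(pts)
    di[abs(outer(rid, rid, `-`)) <= 1L] <- Inf
    sqrt(max(0, min(min(dx), min(di))))
  }
  oldseed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed,
                                        envir = globalenv()))
  set.seed(7177L + 13L * loop_len + helix_len)
  best <- NULL
  for (attempt in 1:80) {
    phi0 <- stats::runif(loop_len, -160, -50)
    psi0 <- stats::runif(loop_len, -60, 170)
    ext <- nerf_extend(prev, psi_prev = stats::runif(1L, -70, 160),
                       phi = phi0, psi = psi0, ghost = TRUE,
                       phi_ghost = HELIX_PHI)
    cc <- close_loop_ccd(prev, ext, targets, tol = 0.08, max_iter = 120L)
    if (cc$rmsd >= 0.2) next
    cl <- clearance(cc$loop)
    if (is.null(best) || cl > best$clearance)
      best <- list(cc = cc, clearance = cl)
    if (cl >= 2.5) break
  }
  if (is.null(best))
    stop("loop closure failed while building packed helix fixture")
  loop_bb <- best$cc$loop
  list(N = rbind(bb$N, loop_bb$N, frag$N),
       CA = rbind(bb$CA, loop_bb$CA, frag$CA),
       C = rbind(bb$C, loop_bb$C, frag$C),
       loop_range = last + seq_len(loop_len),
       helix_range = last + loop_len + seq_len(helix_len))
}

## Run CCD on an extended loop (output of nerf_extend with ghost) against the
## fixed downstream anchor.  Mobile rows: loop N/CA/C then ghost N/CA/C;
## anchor triad occupies rows 1:3 (fixed).
close_loop_ccd <- function(prev, ext, targets, tol = 0.08, max_iter = 300L) {
  k <- nrow(ext$N)
  mob <- matrix(0, 3L + 3L * k + 3L, 3L)
  mob[1L, ] <- prev$N; mob[2L, ] <- prev$CA; mob[3L, ] <- prev$C
  for (i in seq_len(k))
    mob[3L + 3L * (i - 1L) + 1:3, ] <- rbind(ext$N[i, ], ext$CA[i, ], ext$C[i, ])
  gr <- 3L + 3L * k + 1:3
  mob[gr, ] <- ext$ghost
  rowN <- function(i) 3L + 3L * (i - 1L) + 1L
  rowCA <- function(i) 3L + 3L * (i - 1L) + 2L
  rowC <- function(i) 3L + 3L * (i - 1L) + 3L
  nrow_tot <- nrow(mob)
  pivots <- list(list(p1 = 2L, p2 = 3L, moved = 4:nrow_tot))  # psi of anchor
  for (i in seq_len(k)) {
    pivots[[length(pivots) + 1L]] <-
      list(p1 = rowN(i), p2 = rowCA(i), moved = rowC(i):nrow_tot)       # phi_i
    if (rowC(i) + 1L <= nrow_tot)
      pivots[[length(pivots) + 1L]] <-
        list(p1 = rowCA(i), p2 = rowC(i), moved = (rowC(i) + 1L):nrow_tot) # psi_i
  }
  pivots[[length(pivots) + 1L]] <-
    list(p1 = gr[1L], p2 = gr[2L], moved = gr[3L])  # phi of ghost residue
  res <- ccd_close(mob, pivots, gr, targets, tol = tol, max_iter = max_iter)
  m <- res$coords
  list(loop = list(N = m[vapply(seq_len(k), rowN, 1L), , drop = FALSE],
                   CA = m[vapply(seq_len(k), rowCA, 1L), , drop = FALSE],
                   C = m[vapply(seq_len(k), rowC, 1L), , drop = FALSE]),
       rmsd = res$rmsd, iterations = res$iterations)
}

#' Generate a synthetic ground-truth fixture
#'
#' Builds an ideal poly-Ala structure (N, CA, C, O, CB per residue) with the
#' matching secondary-structure annotation:
#' \describe{
#'   \item{helix}{one ideal alpha-helix of `n` residues.}
#'   \item{helix_loop_helix}{a packed antiparallel helix hairpin,
#'     helix(`n[1]`)-loop(`n[2]`)-helix(`n[3]`), closed by cyclic coordinate
#'     descent.}
#'   \item{two_domain_hinge}{two helix-hairpin domains joined by an extended
#'     linker, the substrate for hinge-rotation recovery benchmarks.}
#'   \item{four_helix_bundle}{four packed helices connected by loops.}
#' }
#' Construction is deterministic: the same `kind`, counts and `seed` always
#' yield identical coordinates.
#'
#' @param kind fixture kind.
#' @param n residue counts per element (defaults per kind, see Details).
#' @param seed integer seed (reserved for randomized decorations; the
#'   backbone build itself is deterministic).
#' @return list with `structure` (a `model_structure`), `sses`
#'   (an `sse_annotation`), and `meta` (element table, linker and loop
#'   segments).
#' @export
make_fixture <- function(kind = c("helix", "helix_loop_helix",
                                  "two_domain_hinge", "four_helix_bundle"),
                         n = NULL, seed = 1L) {
  kind <- match.arg(kind)
  ## construction is deterministic per (kind, n): cache it
  cache_key <- paste(kind, paste(n, collapse = "-"))
  cached <- get0(cache_key, envir = .fixture_cache, inherits = FALSE)
  if (!is.null(cached)) {
    cached$meta$seed <- seed
    return(cached)
  }
  hel <- function(len) nerf_backbone(rep(HELIX_PHI, len), rep(HELIX_PSI, len))
  sse_row <- function(s, e) data.frame(kind = "helix", chain_id = "A",
                                       start = s, end = e)
  loops <- list(); linker <- NULL
  if (kind == "helix") {
    if (is.null(n)) n <- 20L
    bb <- hel(n[1L])
    sseg <- sse_row(1L, n[1L])
  } else if (kind == "helix_loop_helix") {
    if (is.null(n)) n <- c(12L, 6L, 12L)
    bb <- hel(n[1L])
    bb <- append_packed_helix(bb, seq_len(n[1L]), n[2L], n[3L])
    sseg <- rbind(sse_row(1L, n[1L]),
                  sse_row(n[1L] + n[2L] + 1L, n[1L] + n[2L] + n[3L]))
    loops <- list(residue_segment("A", (n[1L] + 1L):(n[1L] + n[2L]), "loop1"))
  } else if (kind == "two_domain_hinge") {
    if (is.null(n)) n <- c(10L, 5L, 10L, 6L, 10L, 5L, 10L)
    ## domain 1: packed hairpin
    bb <- hel(n[1L])
    bb <- append_packed_helix(bb, seq_len(n[1L]), n[2L], n[3L])
    h2 <- bb$helix_range; l1 <- bb$loop_range
    d1_end <- n[1L] + n[2L] + n[3L]
    ## extended linker
    last <- nrow(bb$N)
    prev <- list(N = bb$N[last, ], CA = bb$CA[last, ], C = bb$C[last, ])
    lk <- nerf_extend(prev, psi_prev = HELIX_PSI,
                      phi = rep(-140, n[4L]), psi = rep(135, n[4L]))
    bb <- list(N = rbind(bb$N, lk$N), CA = rbind(bb$CA, lk$CA),
               C = rbind(bb$C, lk$C))
    lk_range <- d1_end + seq_len(n[4L])
    ## domain 2: helix continuing from the linker, then its packed partner
    last <- nrow(bb$N)
    prev <- list(N = bb$N[last, ], CA = bb$CA[last, ], C = bb$C[last, ])
    h3 <- nerf_extend(prev, psi_prev = 135, phi = rep(HELIX_PHI, n[5L]),
                      psi = rep(HELIX_PSI, n[5L]))
    bb <- list(N = rbind(bb$N, h3$N), CA = rbind(bb$CA, h3$CA),
               C = rbind(bb$C, h3$C))
    h3_range <- d1_end + n[4L] + seq_len(n[5L])
    bb <- append_packed_helix(bb, h3_range, n[6L], n[7L])
    sseg <- rbind(sse_row(1L, n[1L]),
                  sse_row(min(h2), max(h2)),
                  sse_row(min(h3_range), max(h3_range)),
                  sse_row(min(bb$helix_range), max(bb$helix_range)))
    loops <- list(residue_segment("A", l1, "loop1"),
                  residue_segment("A", bb$loop_range, "loop2"))
    linker <- c(min(lk_range), max(lk_range))
  } else {  # four_helix_bundle
    if (is.null(n)) n <- c(10L, 5L, 10L, 5L, 10L, 5L, 10L)
    hl <- n[c(1L, 3L, 5L, 7L)]; ll <- n[c(2L, 4L, 6L)]
    bb <- hel(hl[1L])
    ranges <- list(seq_len(hl[1L]))
    ## walk around a square of packed helices: sides +p, +q, -p
    a1 <- helix_axis(bb$CA)$dir
    e <- if (abs(a1[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    p <- unit(e - sum(e * a1) * a1)
    q <- unit(vcross(a1, p))
    dirs <- list(p, q, -p)
    for (k in 1:3) {
      bb <- append_packed_helix(bb, ranges[[k]], ll[k], hl[k + 1L],
                                offset_dir = dirs[[k]])
      loops[[length(loops) + 1L]] <-
        residue_segment("A", bb$loop_range, paste0("loop", k))
      ranges[[k + 1L]] <- bb$helix_range
    }
    sseg <- do.call(rbind, lapply(ranges, function(r) sse_row(min(r), max(r))))
  }
  psi <- measured_psi(bb)
  deco <- decorate_backbone(bb, psi)
  structure <- backbone_to_structure(bb, deco, title = paste0("fixture:", kind))
  sses <- sse_annotation(sseg, structure)
  out <- list(structure = structure, sses = sses,
              meta = list(kind = kind, n = n, seed = seed, loops = loops,
                          linker = linker))
  assign(cache_key, out, envir = .fixture_cache)
  out
}

.fixture_cache <- new.env(parent = emptyenv())

## minimum heavy-atom distance between atoms more than one residue apart
min_nonlocal_distance <- function(structure) {
  a <- structure$atoms
  xyz <- coords(structure)
  ridx <- match(residue_uid(a$chain_id, a$res_seq, a$insertion_code),
                structure$residue_index$uid)
  d <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(ridx, ridx, `-`))
  d[sep <= 1L] <- Inf
  min(d)
}

#' Perturb a fixture structure
#'
#' Emulates the conformational difference between a starting model and the
#' conformation represented by the target map.
#'
#' @param structure a `model_structure`, or the list returned by
#'   [make_fixture()] (whose `meta` supplies the linker and loops).
#' @param mode `"hinge"` (rotate the second domain about the linker axis by
#'   `magnitude` degrees), `"translate"` (rigid shift by `magnitude`
#'   Angstrom in a seeded random direction), or `"loop_displace"` (move a
#'   named loop by about `magnitude` Angstrom via seeded dihedral
#'   perturbation with endpoint closure, so covalent geometry stays ideal).
#' @param magnitude degrees (hinge) or Angstrom (translate, loop_displace).
#' @param seed integer seed.
#' @param linker length-2 residue range of the hinge linker (taken from the
#'   fixture `meta` when available).
#' @param loop a `residue_segment` naming the loop to displace (defaults to
#'   the fixture's first loop).
#' @return a perturbed `model_structure`.
#' @export
perturb <- function(structure, mode = c("hinge", "translate", "loop_displace"),
                    magnitude, seed = 1L, linker = NULL, loop = NULL) {
  mode <- match.arg(mode)
  meta <- NULL
  if (!inherits(structure, "model_structure")) {
    meta <- structure$meta
    structure <- structure$structure
  }
  out <- structure
  if (mode == "translate") {
    set.seed(as.integer(seed))
    v <- stats::rnorm(3L)
    shift <- unit(v) * magnitude
    coords(out) <- sweep(coords(structure), 2L, shift, `+`)
  } else if (mode == "hinge") {
    if (is.null(linker)) linker <- meta$linker
    if (is.null(linker)) stop("hinge mode needs a linker residue range")
    a <- structure$atoms
    ca1 <- which(a$name == "CA" & a$res_seq == linker[1L])[1L]
    ca2 <- which(a$name == "CA" & a$res_seq == linker[2L])[1L]
    if (is.na(ca1) || is.na(ca2)) stop("linker residues lack CA atoms")
    axis_p <- as.numeric(coords(structure)[ca1, ])
    axis_d <- as.numeric(coords(structure)[ca2, ]) - axis_p
    move <- a$res_seq > linker[2L]
    xyz <- coords(structure)
    xyz[move, ] <- rotate_about_axis(xyz[move, , drop = FALSE], axis_p, axis_d,
                                     deg2rad(magnitude))
    coords(out) <- xyz
  } else {
    if (is.null(loop)) loop <- meta$loops[[1L]]
    if (is.null(loop)) stop("loop_displace mode needs a loop segment")
    out <- displace_loop_dihedral(structure, loop, magnitude, seed)
  }
  if (min_nonlocal_distance(out) < 1.5)
    stop("perturbation causes steric collapse (non-bonded pair < 1.5 A)")
  out
}

## Displace a loop by ~magnitude Angstrom: scale a fixed Gaussian dihedral
## perturbation by bisection until the maximum CA displacement matches.
displace_loop_dihedral <- function(structure, loop, magnitude, seed) {
  k <- length(loop$res_seq)
  base_ca <- loop_ca(structure, loop)
  ## deterministic sub-seed retries: a given dihedral direction may drive
  ## the loop into the rest of the structure before reaching `magnitude`
  for (try in 0:9) {
    set.seed(as.integer(seed) + 7919L * try)
    z <- stats::rnorm(2L * k + 1L)  # psi_prev + (phi, psi) per loop residue
    build <- function(amp) rebuild_loop(structure, loop, amp * z,
                                        close_tol = 0.15)
    f <- function(amp) {
      trial <- build(amp)
      if (is.null(trial)) return(NA_real_)
      max(sqrt(rowSums((loop_ca(trial, loop) - base_ca)^2)))
    }
    lo <- 0; hi <- 20
    fhi <- f(hi)
    grow <- 0L
    while ((is.na(fhi) || fhi < magnitude) && hi < 320 && grow < 6L) {
      hi <- hi * 2; fhi <- f(hi); grow <- grow + 1L
    }
    if (is.na(fhi) || fhi < magnitude) next
    for (it in 1:25) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (is.na(fm) || fm < magnitude) lo <- mid else hi <- mid
    }
    out <- build(hi)
    if (!is.null(out) && min_nonlocal_distance(out) >= 1.5) return(out)
  }
  stop("could not reach the requested loop displacement without steric ",
       "collapse; try another seed")
}

loop_ca <- function(structure, loop) {
  a <- structure$atoms
  sel <- a$chain_id == loop$chain_id & a$res_seq %in% loop$res_seq &
    a$name == "CA"
  coords(structure)[sel, , drop = FALSE]
}

## Rebuild a loop's backbone with perturbed dihedrals and CCD closure;
## returns the modified structure, or NULL when closure fails.
## delta: perturbations in degrees, c(psi_prev, phi_1..k, psi_1..k).
rebuild_loop <- function(structure, loop, delta, close_tol = 0.1) {
  ri <- structure$residue_index
  ch <- loop$chain_id
  prev_seq <- min(loop$res_seq) - 1L
  next_seq <- max(loop$res_seq) + 1L
  need <- c(prev_seq, loop$res_seq, next_seq)
  if (!all(need %in% ri$res_seq[ri$chain_id == ch]))
    stop("loop must be interior to the chain (flanking residues required)")
  tri <- function(rs) {
    rows <- atom_rows_of_range(structure, ch, rs, rs)
    a <- structure$atoms[rows, ]
    xyz <- as.matrix(a[, c("x", "y", "z")])
    list(N = as.numeric(xyz[which(a$name == "N")[1L], ]),
         CA = as.numeric(xyz[which(a$name == "CA")[1L], ]),
         C = as.numeric(xyz[which(a$name == "C")[1L], ]),
         rows = rows, names = a$name)
  }
  prev <- tri(prev_seq); nxt <- tri(next_seq)
  k <- length(loop$res_seq)
  ## current torsions
  tris <- lapply(loop$res_seq, tri)
  allN <- rbind(prev$N, t(vapply(tris, `[[`, numeric(3L), "N")), nxt$N)
  allCA <- rbind(prev$CA, t(vapply(tris, `[[`, numeric(3L), "CA")), nxt$CA)
  allC <- rbind(prev$C, t(vapply(tris, `[[`, numeric(3L), "C")), nxt$C)
  psi_prev <- dihedral_deg(allN[1L, ], allCA[1L, ], allC[1L, ], allN[2L, ])
  phi <- psi <- numeric(k)
  for (i in seq_len(k)) {
    phi[i] <- dihedral_deg(allC[i, ], allN[i + 1L, ], allCA[i + 1L, ],
                           allC[i + 1L, ])
    psi[i] <- dihedral_deg(allN[i + 1L, ], allCA[i + 1L, ], allC[i + 1L, ],
                           allN[i + 2L, ])
  }
  if (all(delta == 0)) return(structure)
  psi_prev <- psi_prev + delta[1L]
  phi <- phi + delta[1L + seq_len(k)]
  psi <- psi + delta[1L + k + seq_len(k)]
  phi_next <- dihedral_deg(allC[k + 1L, ], nxt$N, nxt$CA, nxt$C)
  ext <- nerf_extend(prev, psi_prev = psi_prev, phi = phi, psi = psi,
                     ghost = TRUE, phi_ghost = phi_next)
  targets <- rbind(nxt$N, nxt$CA, nxt$C)
  cc <- close_loop_ccd(prev, ext, targets, tol = close_tol)
  if (cc$rmsd > max(close_tol, 0.15)) return(NULL)
  bb <- cc$loop
  psi_fin <- numeric(k)
  for (i in seq_len(k)) {
    nxtN <- if (i < k) bb$N[i + 1L, ] else nxt$N
    psi_fin[i] <- dihedral_deg(bb$N[i, ], bb$CA[i, ], bb$C[i, ], nxtN)
  }
  deco <- decorate_backbone(bb, psi_fin)
  out <- structure
  xyz <- coords(out)
  for (i in seq_len(k)) {
    rows <- atom_rows_of_range(structure, ch, loop$res_seq[i], loop$res_seq[i])
    nm <- structure$atoms$name[rows]
    rep_xyz <- rbind(N = bb$N[i, ], CA = bb$CA[i, ], C = bb$C[i, ],
                     O = deco$O[i, ], CB = deco$CB[i, ])
    hit <- nm %in% rownames(rep_xyz)
    xyz[rows[hit], ] <- rep_xyz[nm[hit], , drop = FALSE]
  }
  ## re-place the carbonyl O of the residue preceding the loop (its psi moved)
  prev_rows <- atom_rows_of_range(structure, ch, prev_seq, prev_seq)
  prev_names <- structure$atoms$name[prev_rows]
  if ("O" %in% prev_names) {
    psi_p <- dihedral_deg(prev$N, prev$CA, prev$C, bb$N[1L, ])
    xyz[prev_rows[prev_names == "O"], ] <-
      place_atom(prev$N, prev$CA, prev$C, BB_GEOM$b_CO, BB_GEOM$a_CACO,
                 psi_p + 180)
  }
  coords(out) <- xyz
  out
}

#' Root-mean-square deviation between two structures
#'
#' By default the RMSD is computed in the shared map frame (no
#' superposition), the meaningful comparison when both models are positioned
#' in the same density.  Optional least-squares superposition gives the
#' frame-free value.
#'
#' @param a,b `model_structure` objects with matching atoms under the
#'   selection.
#' @param selection `"calpha"`, `"all_atom"`, or a `residue_segment`
#'   (all atoms of the listed residues).
#' @param superpose superpose `b` onto `a` (Kabsch) before measuring.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, selection = c("calpha", "all_atom"), superpose = FALSE) {
  key <- function(s) paste(s$atoms$chain_id, s$atoms$res_seq,
                           s$atoms$insertion_code, s$atoms$name)
  if (inherits(selection, "residue_segment")) {
    pick <- function(s) {
      at <- s$atoms
      which(at$chain_id == selection$chain_id & at$res_seq %in% selection$res_seq)
    }
  } else {
    selection <- match.arg(selection)
    pick <- function(s)
      if (selection == "calpha") which(s$atoms$name == "CA")
      else seq_len(nrow(s$atoms))
  }
  ia <- pick(a); ib <- pick(b)
  ka <- key(a)[ia]; kb <- key(b)[ib]
  if (length(ka) != length(kb) || !setequal(ka, kb)) {
    miss <- c(setdiff(ka, kb), setdiff(kb, ka))
    stop("atom selections do not match; unmatched: ",
         paste(utils::head(miss, 8L), collapse = "; "))
  }
  xa <- coords(a)[ia, , drop = FALSE]
  xb <- coords(b)[ib, , drop = FALSE][match(ka, kb), , drop = FALSE]
  if (superpose) {
    fit <- bio3d::fit.xyz(fixed = as.numeric(t(xa)), mobile = as.numeric(t(xb)),
                          fixed.inds = seq_len(3L * nrow(xa)),
                          mobile.inds = seq_len(3L * nrow(xb)))
    xb <- matrix(fit, ncol = 3L, byrow = TRUE)
  }
  sqrt(mean(rowSums((xa - xb)^2)))
}
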