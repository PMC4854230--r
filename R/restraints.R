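# Stereochemical restraints anchoring the annealing engine: harmonic
# bond/angle/improper terms with means taken from the current structure,
# flat-bottom Ramachandran basins, and one-sided van der Waals lower bounds.
# All harmonic terms use the convention E = k * delta^2 (no 1/2 factor), so
# the non-bonded force constant 400 kcal/mol/A^2 has one unambiguous
# meaning.

VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, FE = 1.50, ZN = 1.40, MG = 1.50)

## typical covalent force constants, E = k * delta^2
FORCE_K <- list(bond = 300,      # kcal/mol/A^2
                angle = 50,      # kcal/mol/rad^2
                improper = 30,   # kcal/mol/rad^2
                nonbonded = 400, # kcal/mol/A^2
                rama = 5)        # kcal/mol per squared basin-exit unit

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

## broad allowed Ramachandran basins: center (phi, psi) and radii, degrees
RAMA_BASINS <- list(alpha = list(c = c(-63, -43), r = c(40, 45)),
                    beta = list(c = c(-120, 130), r = c(65, 60)),
                    alphaL = list(c = c(60, 45), r = c(35, 40)))

vdw_radius <- function(elements) {
  r <- VDW_RADII[toupper(elements)]
  r[is.na(r)] <- 1.70
  unname(r)
}

## distance-based covalent bond detection within +/- 1 residue
detect_bonds <- function(structure) {
  a <- structure$atoms
  xyz <- coords(structure)
  ri <- structure$residue_index
  res_of <- rep(seq_len(nrow(ri)), times = ri$last - ri$first + 1L)
  pairs_i <- integer(); pairs_j <- integer()
  for (r in seq_len(nrow(ri))) {
    rows_r <- ri$first[r]:ri$last[r]
    nxt <- if (r < nrow(ri) && ri$chain_id[r + 1L] == ri$chain_id[r])
      ri$first[r + 1L]:ri$last[r + 1L] else integer()
    cand <- c(rows_r, nxt)
    for (ii in seq_along(rows_r)) {
      i <- rows_r[ii]
      js <- cand[cand > i]
      if (!length(js)) next
      d <- sqrt(colSums((t(xyz[js, , drop = FALSE]) - xyz[i, ])^2))
      lim <- ifelse(toupper(a$element[i]) == "S" |
                      toupper(a$element[js]) == "S", 2.3,
                    ifelse(toupper(a$element[i]) == "H" |
                             toupper(a$element[js]) == "H", 1.3, 1.9))
      hit <- js[d < lim & d > 0.4]
      pairs_i <- c(pairs_i, rep(i, length(hit)))
      pairs_j <- c(pairs_j, hit)
    }
  }
  list(i = pairs_i, j = pairs_j, res_of = res_of)
}

## bond-graph neighbour lists up to distance 3 (for non-bonded exclusions)
excluded_pairs <- function(nb_i, nb_j, natoms) {
  adj <- vector("list", natoms)
  for (k in seq_along(nb_i)) {
    adj[[nb_i[k]]] <- c(adj[[nb_i[k]]], nb_j[k])
    adj[[nb_j[k]]] <- c(adj[[nb_j[k]]], nb_i[k])
  }
  excl <- vector("list", natoms)
  for (s in seq_len(natoms)) {
    d1 <- adj[[s]]
    d2 <- unique(unlist(adj[d1]))
    d3 <- unique(unlist(adj[d2]))
    excl[[s]] <- setdiff(unique(c(d1, d2, d3)), s)
  }
  excl
}

#' Build the stereochemical restraint set of a structure
#'
#' Bond, angle and improper-dihedral terms are harmonic with the mean equal
#' to the value in the input conformation (so the input structure has zero
#' covalent restraint energy) and typical covalent force constants.
#' Amino-acid residues additionally get peptide planarity/omega impropers, a
#' CA chirality improper, and a flat-bottom Ramachandran basin restraint.
#' Non-bonded heavy-atom pairs more than three bonds apart get a one-sided
#' harmonic lower bound at the sum of their van der Waals radii with
#' k = 400 kcal/mol/A^2.
#'
#' @param structure a `model_structure`.
#' @param nb_scale scale factor applied to the van der Waals lower bound.
#' @param k force-constant list overriding the packaged defaults.
#' @return a `restraint_set`.
#' @export
build_restraints <- function(structure, nb_scale = 1.0, k = FORCE_K) {
  a <- structure$atoms
  xyz <- coords(structure)
  n <- nrow(a)
  ri <- structure$residue_index
  ## amino-acid residues must carry a heavy-atom backbone
  is_aa <- ri$res_name %in% AA3
  for (r in which(is_aa)) {
    nm <- a$name[ri$first[r]:ri$last[r]]
    if (!all(c("N", "CA", "C") %in% nm))
      stop("residue ", ri$uid[r], " (", ri$res_name[r],
           ") lacks backbone atoms N/CA/C")
  }
  bd <- detect_bonds(structure)
  dvec <- function(i, j) sqrt(rowSums((xyz[i, , drop = FALSE] -
                                         xyz[j, , drop = FALSE])^2))
  bonds <- data.frame(i = bd$i, j = bd$j,
                      r0 = if (length(bd$i)) dvec(bd$i, bd$j) else numeric(),
                      k = rep(k$bond, length(bd$i)))
  ## angles: all bonded-neighbour pairs around each central atom
  adj <- vector("list", n)
  for (t in seq_along(bd$i)) {
    adj[[bd$i[t]]] <- c(adj[[bd$i[t]]], bd$j[t])
    adj[[bd$j[t]]] <- c(adj[[bd$j[t]]], bd$i[t])
  }
  ai <- aj <- ak <- integer()
  for (c0 in seq_len(n)) {
    nb <- adj[[c0]]
    if (length(nb) < 2L) next
    cmb <- utils::combn(sort(nb), 2L)
    ai <- c(ai, cmb[1L, ]); aj <- c(aj, rep(c0, ncol(cmb))); ak <- c(ak, cmb[2L, ])
  }
  theta0 <- if (length(ai))
    vapply(seq_along(ai), function(t)
      angle_deg(xyz[ai[t], ], xyz[aj[t], ], xyz[ak[t], ]), numeric(1L))
  else numeric()
  angles <- data.frame(i = ai, j = aj, k_ = ak, theta0 = theta0,
                       k = rep(k$angle, length(ai)))
  ## impropers: carbonyl planarity, peptide omega, CA chirality
  at_row <- function(r, name) {
    rows <- ri$first[r]:ri$last[r]
    hit <- rows[a$name[rows] == name]
    if (length(hit)) hit[1L] else NA_integer_
  }
  ii <- list()
  for (r in seq_len(nrow(ri))) {
    if (!is_aa[r]) next
    Nr <- at_row(r, "N"); CAr <- at_row(r, "CA"); Cr <- at_row(r, "C")
    Or <- at_row(r, "O"); CBr <- at_row(r, "CB")
    nxt <- if (r < nrow(ri) && ri$chain_id[r + 1L] == ri$chain_id[r] &&
                 is_aa[r + 1L]) r + 1L else NA_integer_
    if (!is.na(nxt)) {
      Nn <- at_row(nxt, "N"); CAn <- at_row(nxt, "CA")
      if (!anyNA(c(CAr, Nn, Cr, Or)) && vnorm(xyz[Nn, ] - xyz[Cr, ]) < 2.5) {
        ii[[length(ii) + 1L]] <- c(CAr, Nn, Cr, Or)          # carbonyl plane
        if (!is.na(CAn))
          ii[[length(ii) + 1L]] <- c(CAr, Cr, Nn, CAn)       # omega
      }
    }
    if (!anyNA(c(Nr, Cr, CAr, CBr)))
      ii[[length(ii) + 1L]] <- c(Cr, Nr, CAr, CBr)           # CA chirality
  }
  impropers <- if (length(ii)) {
    m <- do.call(rbind, ii)
    phi0 <- dihedral_vec(xyz, m[, 1L], m[, 2L], m[, 3L], m[, 4L])$phi_deg
    data.frame(i = m[, 1L], j = m[, 2L], k_ = m[, 3L], l = m[, 4L],
               phi0 = phi0, k = k$improper)
  } else data.frame(i = integer(), j = integer(), k_ = integer(),
                    l = integer(), phi0 = numeric(), k = numeric())
  ## Ramachandran quadruples (one row per scored residue)
  rq_rows <- list()
  for (r in seq_len(nrow(ri))) {
    if (!is_aa[r] || ri$res_name[r] == "PRO") next
    prv <- if (r > 1L && ri$chain_id[r - 1L] == ri$chain_id[r] &&
                 is_aa[r - 1L]) r - 1L else NA_integer_
    nxt <- if (r < nrow(ri) && ri$chain_id[r + 1L] == ri$chain_id[r] &&
                 is_aa[r + 1L]) r + 1L else NA_integer_
    if (is.na(prv) || is.na(nxt)) next
    Cp <- at_row(prv, "C"); Nr <- at_row(r, "N"); CAr <- at_row(r, "CA")
    Cr <- at_row(r, "C"); Nn <- at_row(nxt, "N")
    if (anyNA(c(Cp, Nr, CAr, Cr, Nn))) next
    if (vnorm(xyz[Nr, ] - xyz[Cp, ]) > 2.5 ||
        vnorm(xyz[Nn, ] - xyz[Cr, ]) > 2.5) next
    rq_rows[[length(rq_rows) + 1L]] <-
      data.frame(p1 = Cp, p2 = Nr, p3 = CAr, p4 = Cr,
                 s1 = Nr, s2 = CAr, s3 = Cr, s4 = Nn,
                 glycine = ri$res_name[r] == "GLY")
  }
  rq <- if (length(rq_rows)) do.call(rbind, rq_rows) else
    data.frame(p1 = integer(), p2 = integer(), p3 = integer(),
               p4 = integer(), s1 = integer(), s2 = integer(),
               s3 = integer(), s4 = integer(), glycine = logical())
  ## non-bonded lower bounds: heavy pairs >= 4 bonds apart
  heavy <- which(toupper(a$element) != "H")
  excl <- excluded_pairs(bd$i, bd$j, n)
  rad <- vdw_radius(a$element)
  nb_i <- integer(); nb_j <- integer()
  if (length(heavy) > 1L) {
    hv <- heavy
    for (s in seq_len(length(hv) - 1L)) {
      i <- hv[s]
      js <- hv[(s + 1L):length(hv)]
      js <- setdiff(js, excl[[i]])
      nb_i <- c(nb_i, rep(i, length(js)))
      nb_j <- c(nb_j, js)
    }
  }
  ## lower bound capped at the anchor distance: pairs already closer than the
  ## van der Waals sum in the conformation the restraints are built from are
  ## not treated as violations (the bonded terms anchor that geometry), so
  ## the input structure has zero restraint energy and the term only blocks
  ## the formation of NEW clashes during refinement.
  d_anchor <- if (length(nb_i)) dvec(nb_i, nb_j) else numeric()
  nonbonded <- data.frame(i = nb_i, j = nb_j,
                          dmin = pmin(nb_scale * (rad[nb_i] + rad[nb_j]),
                                      d_anchor),
                          k = rep(k$nonbonded, length(nb_i)))
  x <- list(bonds = bonds, angles = angles, impropers = impropers,
            rama = rq, nonbonded = nonbonded, k = k,
            natoms = n, adjacency = list(i = bd$i, j = bd$j))
  class(x) <- "restraint_set"
  x
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("restraint_set: %d bonds, %d angles, %d impropers, %d Ramachandran residues, %d non-bonded lower bounds\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$impropers),
              nrow(x$rama), nrow(x$nonbonded)))
  invisible(x)
}

# --------------------------------------------------------------------------
# vectorised value + gradient primitives

row_cross <- function(A, B)
  cbind(A[, 2L] * B[, 3L] - A[, 3L] * B[, 2L],
        A[, 3L] * B[, 1L] - A[, 1L] * B[, 3L],
        A[, 1L] * B[, 2L] - A[, 2L] * B[, 1L])

## dihedral values (deg) and gradients (rad per Angstrom) for index vectors
dihedral_vec <- function(xyz, i, j, k, l, grad = FALSE) {
  b1 <- xyz[j, , drop = FALSE] - xyz[i, , drop = FALSE]
  b2 <- xyz[k, , drop = FALSE] - xyz[j, , drop = FALSE]
  b3 <- xyz[l, , drop = FALSE] - xyz[k, , drop = FALSE]
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  nb2 <- sqrt(rowSums(b2^2))
  m1 <- row_cross(n1, b2 / nb2)
  phi <- atan2(rowSums(m1 * n2), rowSums(n1 * n2))
  out <- list(phi_deg = rad2deg(phi))
  if (grad) {
    n1sq <- rowSums(n1^2)
    n2sq <- rowSums(n2^2)
    F1 <- n1 * (nb2 / n1sq)
    F4 <- -n2 * (nb2 / n2sq)
    c12 <- rowSums(b1 * b2) / nb2^2
    c32 <- rowSums(b3 * b2) / nb2^2
    out$g1 <- F1
    out$g2 <- -(1 + c12) * F1 + c32 * F4
    out$g3 <- c12 * F1 - (1 + c32) * F4
    out$g4 <- F4
  }
  out
}

## angle values (deg) and gradients (rad per Angstrom)
angle_vec <- function(xyz, i, j, k, grad = FALSE) {
  u <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
  v <- xyz[k, , drop = FALSE] - xyz[j, , drop = FALSE]
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  uh <- u / nu; vh <- v / nv
  ct <- pmax(-1, pmin(1, rowSums(uh * vh)))
  th <- acos(ct)
  out <- list(theta_deg = rad2deg(th))
  if (grad) {
    st <- pmax(sqrt(1 - ct^2), 1e-8)
    gi <- -(vh - ct * uh) / (nu * st)
    gk <- -(uh - ct * vh) / (nv * st)
    out$gi <- gi
    out$gj <- -(gi + gk)
    out$gk <- gk
  }
  out
}

## scaled distance of (phi, psi) vectors from the nearest allowed basin;
## returns per-residue rho plus the scaled offsets and radii of that basin
rama_rho <- function(phi, psi, glycine) {
  n <- length(phi)
  nb <- length(RAMA_BASINS)
  rho_m <- dphi_m <- dpsi_m <- matrix(Inf, n, nb)
  for (b in seq_len(nb)) {
    bs <- RAMA_BASINS[[b]]
    dphi <- wrap_deg(phi - bs$c[1L]) / bs$r[1L]
    dpsi <- wrap_deg(psi - bs$c[2L]) / bs$r[2L]
    rho_m[, b] <- sqrt(dphi^2 + dpsi^2)
    dphi_m[, b] <- dphi
    dpsi_m[, b] <- dpsi
  }
  ## the alphaL basin is allowed for glycine only
  gl <- which(names(RAMA_BASINS) == "alphaL")
  if (length(gl)) rho_m[!glycine, gl] <- Inf
  pick <- max.col(-rho_m, ties.method = "first")
  sel <- cbind(seq_len(n), pick)
  rphi <- vapply(RAMA_BASINS, function(b) b$r[1L], numeric(1L))[pick]
  rpsi <- vapply(RAMA_BASINS, function(b) b$r[2L], numeric(1L))[pick]
  list(rho = rho_m[sel], dphi = dphi_m[sel], dpsi = dpsi_m[sel],
       rphi = rphi, rpsi = rpsi)
}

#' Evaluate restraint energy and gradient in one pass
#'
#' Shared workhorse for [restraint_energy()] and [restraint_gradient()]; the
#' annealing engine calls it directly so each MD step measures every term
#' once.
#'
#' @param restraints a `restraint_set`.
#' @param xyz coordinate matrix.
#' @param grad also compute the analytic gradient.
#' @return list with `total`, per-term components, and (when requested)
#'   `gradient` (n x 3, kcal/mol/Angstrom).
#' @export
restraint_eval <- function(restraints, xyz, grad = TRUE) {
  rs <- restraints
  e_bond <- e_ang <- e_imp <- e_rama <- e_nb <- 0
  G <- if (grad) matrix(0, nrow(xyz), 3L) else NULL
  acc <- function(idx, val) {
    s <- rowsum(val, idx, reorder = FALSE)
    rows <- as.integer(rownames(s))
    G[rows, ] <<- G[rows, ] + s
  }
  if (nrow(rs$bonds)) {
    i <- rs$bonds$i; j <- rs$bonds$j
    dv <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    e_bond <- sum(rs$bonds$k * (d - rs$bonds$r0)^2)
    if (grad) {
      f <- 2 * rs$bonds$k * (d - rs$bonds$r0) / pmax(d, 1e-9)
      acc(i, f * dv); acc(j, -f * dv)
    }
  }
  if (nrow(rs$angles)) {
    av <- angle_vec(xyz, rs$angles$i, rs$angles$j, rs$angles$k_, grad = grad)
    e_ang <- sum(rs$angles$k * deg2rad(av$theta_deg - rs$angles$theta0)^2)
    if (grad) {
      f <- 2 * rs$angles$k * deg2rad(av$theta_deg - rs$angles$theta0)
      acc(rs$angles$i, f * av$gi)
      acc(rs$angles$j, f * av$gj)
      acc(rs$angles$k_, f * av$gk)
    }
  }
  if (nrow(rs$impropers)) {
    dvh <- dihedral_vec(xyz, rs$impropers$i, rs$impropers$j, rs$impropers$k_,
                        rs$impropers$l, grad = grad)
    delta <- deg2rad(wrap_deg(dvh$phi_deg - rs$impropers$phi0))
    e_imp <- sum(rs$impropers$k * delta^2)
    if (grad) {
      f <- 2 * rs$impropers$k * delta
      acc(rs$impropers$i, f * dvh$g1)
      acc(rs$impropers$j, f * dvh$g2)
      acc(rs$impropers$k_, f * dvh$g3)
      acc(rs$impropers$l, f * dvh$g4)
    }
  }
  if (nrow(rs$rama)) {
    rq <- rs$rama
    dphi <- dihedral_vec(xyz, rq$p1, rq$p2, rq$p3, rq$p4, grad = grad)
    dpsi <- dihedral_vec(xyz, rq$s1, rq$s2, rq$s3, rq$s4, grad = grad)
    rr <- rama_rho(dphi$phi_deg, dpsi$phi_deg, rq$glycine)
    out_b <- rr$rho > 1
    if (any(out_b)) {
      e_rama <- sum(rs$k$rama * (rr$rho[out_b] - 1)^2)
      if (grad) {
        pref <- 2 * rs$k$rama * (rr$rho - 1) / rr$rho
        pref[!out_b] <- 0
        fphi <- pref * rr$dphi / rr$rphi * 180 / pi
        fpsi <- pref * rr$dpsi / rr$rpsi * 180 / pi
        for (t in 1:4) {
          acc(rq[[paste0("p", t)]], fphi * dphi[[paste0("g", t)]])
          acc(rq[[paste0("s", t)]], fpsi * dpsi[[paste0("g", t)]])
        }
      }
    }
  }
  if (nrow(rs$nonbonded)) {
    i <- rs$nonbonded$i; j <- rs$nonbonded$j
    dv <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
    d2 <- rowSums(dv^2)
    viol <- which(d2 < rs$nonbonded$dmin^2)
    if (length(viol)) {
      d <- sqrt(d2[viol])
      gap <- rs$nonbonded$dmin[viol] - d
      e_nb <- sum(rs$nonbonded$k[viol] * gap^2)
      if (grad) {
        f <- -2 * rs$nonbonded$k[viol] * gap / pmax(d, 1e-9)
        acc(i[viol], f * dv[viol, , drop = FALSE])
        acc(j[viol], -f * dv[viol, , drop = FALSE])
      }
    }
  }
  list(total = e_bond + e_ang + e_imp + e_rama + e_nb, bonds = e_bond,
       angles = e_ang, impropers = e_imp, rama = e_rama, nonbonded = e_nb,
       gradient = G)
}

#' Restraint energy of a conformation
#'
#' @param restraints a `restraint_set`.
#' @param xyz coordinate matrix (`coords(structure)`).
#' @return list with `total` and per-term components (kcal/mol under the
#'   E = k delta^2 convention).
#' @export
restraint_energy <- function(restraints, xyz) {
  out <- restraint_eval(restraints, xyz, grad = FALSE)
  out$gradient <- NULL
  out
}

#' Analytic gradient of the restraint energy
#' @param restraints a `restraint_set`.
#' @param xyz coordinate matrix.
#' @return n x 3 gradient matrix (kcal/mol/Angstrom).
#' @export
restraint_gradient <- function(restraints, xyz) {
  restraint_eval(restraints, xyz, grad = TRUE)$gradient
}
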