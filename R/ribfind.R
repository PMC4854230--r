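# Rigid-body identification: geometric SSE assignment (fallback when no
# annotation is supplied), spatial clustering of SSEs into rigid bodies with
# absorption of cluster-internal loops, and the hierarchy levels used by the
# refinement protocol.

#' Backbone dihedral angles
#'
#' Per-residue phi/psi in degrees; `NA` at chain termini and across chain
#' breaks (peptide C-N distance > 2.5 Angstrom).
#'
#' @param structure a `model_structure`.
#' @return data.frame with `chain_id`, `res_seq`, `uid`, `phi`, `psi`.
#' @export
backbone_dihedrals <- function(structure) {
  ri <- structure$residue_index
  xyz <- coords(structure)
  nm <- structure$atoms$name
  pick <- function(i, what) {
    rows <- ri$first[i]:ri$last[i]
    hit <- rows[nm[rows] == what]
    if (!length(hit)) return(rep(NA_real_, 3L))
    xyz[hit[1L], ]
  }
  n <- nrow(ri)
  N <- t(vapply(seq_len(n), pick, numeric(3L), what = "N"))
  CA <- t(vapply(seq_len(n), pick, numeric(3L), what = "CA"))
  C <- t(vapply(seq_len(n), pick, numeric(3L), what = "C"))
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    prev_ok <- i > 1L && ri$chain_id[i - 1L] == ri$chain_id[i] &&
      all(is.finite(C[i - 1L, ])) && all(is.finite(N[i, ])) &&
      vnorm(N[i, ] - C[i - 1L, ]) < 2.5
    next_ok <- i < n && ri$chain_id[i + 1L] == ri$chain_id[i] &&
      all(is.finite(C[i, ])) && all(is.finite(N[i + 1L, ])) &&
      vnorm(N[i + 1L, ] - C[i, ]) < 2.5
    if (prev_ok && all(is.finite(CA[i, ])))
      phi[i] <- dihedral_deg(C[i - 1L, ], N[i, ], CA[i, ], C[i, ])
    if (next_ok && all(is.finite(CA[i, ])))
      psi[i] <- dihedral_deg(N[i, ], CA[i, ], C[i, ], N[i + 1L, ])
  }
  data.frame(chain_id = ri$chain_id, res_seq = ri$res_seq, uid = ri$uid,
             phi = phi, psi = psi, stringsAsFactors = FALSE)
}

#' Assign secondary-structure elements from geometry
#'
#' Fallback assigner used when no HELIX/SHEET records or TSV annotation are
#' available: residues whose backbone dihedrals fall in the alpha-helical
#' (phi -100..-30, psi -90..10) or extended (phi -180..-80, psi 90..180 or
#' below -150) region are collected into runs; helices need >= 4 residues,
#' strands >= 3.  Terminal residues with only one defined dihedral join a
#' run when that dihedral is consistent.
#'
#' @param structure a `model_structure`.
#' @return an `sse_annotation`.
#' @export
assign_sses <- function(structure) {
  dh <- backbone_dihedrals(structure)
  in_rng <- function(x, lo, hi) !is.na(x) & x >= lo & x <= hi
  helixish <- function(phi, psi) {
    okp <- is.na(phi) | in_rng(phi, -100, -30)
    oks <- is.na(psi) | in_rng(psi, -90, 10)
    okp & oks & !(is.na(phi) & is.na(psi))
  }
  strandish <- function(phi, psi) {
    okp <- is.na(phi) | in_rng(phi, -180, -80)
    oks <- is.na(psi) | in_rng(psi, 90, 180) | in_rng(psi, -180, -150)
    okp & oks & !(is.na(phi) & is.na(psi))
  }
  segs <- list()
  for (ch in unique(dh$chain_id)) {
    sub <- dh[dh$chain_id == ch, , drop = FALSE]
    if (nrow(sub) < 4L) {
      warning("chain ", ch, " has fewer than 4 residues: no SSE assigned")
      next
    }
    h <- helixish(sub$phi, sub$psi)
    s <- strandish(sub$phi, sub$psi) & !h
    collect <- function(flag, min_len, kind) {
      rl <- rle(flag)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      for (k in seq_along(rl$values))
        if (rl$values[k] && rl$lengths[k] >= min_len)
          segs[[length(segs) + 1L]] <<-
            data.frame(kind = kind, chain_id = ch,
                       start = sub$res_seq[starts[k]],
                       end = sub$res_seq[ends[k]])
    }
    collect(h, 4L, "helix")
    collect(s, 3L, "strand")
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(kind = character(), chain_id = character(), start = integer(),
               end = integer())
  sse_annotation(segments, structure)
}

#' SSE contact graph
#'
#' Nodes are SSE segments; the weight of an edge is the fraction of
#' inter-SSE residue pairs whose CA-CA distance is at most `cutoff`
#' Angstrom.  Only SSEs of the same chain are compared (bodies never span
#' chains).
#'
#' @param structure a `model_structure`.
#' @param sses an `sse_annotation`.
#' @param cutoff CA-CA contact distance, Angstrom.
#' @return list with `segments` (the node table) and `weight` (symmetric
#'   matrix in `[0, 1]`).
#' @export
sse_contact_graph <- function(structure, sses, cutoff = 6.5) {
  seg <- sses$segments
  if (!nrow(seg)) stop("no SSE segments to cluster")
  a <- structure$atoms
  xyz <- coords(structure)
  ca_of <- function(s) {
    sel <- a$name == "CA" & a$chain_id == seg$chain_id[s] &
      a$res_seq >= seg$start[s] & a$res_seq <= seg$end[s]
    xyz[sel, , drop = FALSE]
  }
  cas <- lapply(seq_len(nrow(seg)), ca_of)
  w <- diag(1, nrow(seg))
  for (i in seq_len(nrow(seg) - 1L)) {
    for (j in (i + 1L):nrow(seg)) {
      if (seg$chain_id[i] != seg$chain_id[j]) { w[i, j] <- w[j, i] <- 0; next }
      d2 <- outer(rowSums(cas[[i]]^2), rowSums(cas[[j]]^2), `+`) -
        2 * cas[[i]] %*% t(cas[[j]])
      w[i, j] <- w[j, i] <- mean(d2 <= cutoff^2)
    }
  }
  list(segments = seg, weight = w)
}

## compress a set of residue uids into (chain, start, end) ranges following
## the structure's residue order
uids_to_ranges <- function(structure, uids) {
  ri <- structure$residue_index
  hit <- ri$uid %in% uids
  pos <- which(hit)
  if (!length(pos)) return(data.frame(chain_id = character(), start = integer(),
                                      end = integer()))
  brk <- c(TRUE, diff(pos) != 1L | ri$chain_id[pos[-1L]] != ri$chain_id[pos[-length(pos)]])
  grp <- cumsum(brk)
  do.call(rbind, lapply(split(pos, grp), function(p)
    data.frame(chain_id = ri$chain_id[p[1L]], start = ri$res_seq[p[1L]],
               end = ri$res_seq[p[length(p)]])))
}

#' Cluster SSEs into rigid bodies
#'
#' Two SSEs are in contact when their contact weight (see
#' [sse_contact_graph()]) reaches `min_pair_fraction`; clusters are the
#' connected components of that graph.  Each cluster's rigid body contains
#' its SSE residues plus every loop residue lying strictly between two SSEs
#' of the same cluster along the chain; isolated SSEs become singleton
#' bodies and loops not enclosed within a cluster stay free.
#'
#' @param structure a `model_structure`.
#' @param sses an `sse_annotation` (>= 1 segment).
#' @param cutoff CA-CA contact distance, Angstrom.
#' @param min_pair_fraction minimum fraction of inter-SSE CA pairs in
#'   contact for an edge.
#' @return a `rigid_body_scheme` at level `"ribfind_clusters"`.
#' @export
cluster_sses <- function(structure, sses, cutoff = 6.5,
                         min_pair_fraction = 0.1) {
  g <- sse_contact_graph(structure, sses, cutoff)
  seg <- g$segments
  adj <- g$weight >= min_pair_fraction
  diag(adj) <- FALSE
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(ig)$membership
  ri <- structure$residue_index
  bodies <- list()
  for (cl in sort(unique(comp))) {
    members <- which(comp == cl)
    uids <- character()
    for (s in members)
      uids <- c(uids, ri$uid[ri$chain_id == seg$chain_id[s] &
                               ri$res_seq >= seg$start[s] &
                               ri$res_seq <= seg$end[s]])
    if (length(members) > 1L) {
      ## absorb loops strictly between sequence-adjacent SSEs of this cluster
      for (ch in unique(seg$chain_id[members])) {
        in_ch <- which(seg$chain_id == ch)
        ord <- in_ch[order(seg$start[in_ch])]
        for (k in seq_len(length(ord) - 1L)) {
          s1 <- ord[k]; s2 <- ord[k + 1L]
          if (!(s1 %in% members && s2 %in% members)) next
          lo <- seg$end[s1] + 1L; hi <- seg$start[s2] - 1L
          if (lo > hi) next
          uids <- c(uids, ri$uid[ri$chain_id == ch & ri$res_seq >= lo &
                                   ri$res_seq <= hi])
        }
      }
    }
    bodies[[length(bodies) + 1L]] <- uids_to_ranges(structure, unique(uids))
  }
  rigid_body_scheme(bodies, level = "ribfind_clusters", structure = structure)
}

#' Rigid-body scheme for a refinement level
#'
#' `ribfind_clusters` returns the cluster scheme as given; `sse` makes one
#' body per SSE segment (loops free); `all_atom` returns an empty body list
#' (every atom free).
#'
#' @param sses an `sse_annotation`.
#' @param clusters a `rigid_body_scheme` from [cluster_sses()].
#' @param level `"ribfind_clusters"`, `"sse"` or `"all_atom"`.
#' @return a `rigid_body_scheme`.
#' @export
scheme_for_level <- function(sses, clusters,
                             level = c("ribfind_clusters", "sse", "all_atom")) {
  level <- match.arg(level)
  if (level == "ribfind_clusters") return(clusters)
  if (level == "all_atom") return(rigid_body_scheme(list(), level = "all_atom"))
  seg <- sses$segments
  bodies <- lapply(seq_len(nrow(seg)), function(s)
    data.frame(chain_id = seg$chain_id[s], start = seg$start[s],
               end = seg$end[s]))
  rigid_body_scheme(bodies, level = "sse")
}
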