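# Local goodness-of-fit: segment-based Manders' overlap coefficient (SMOC),
# per-residue profiles, Z-score flagging and profile comparison between
# refinement stages.

default_mask_radius <- function(grid) max(2.5, 1.5 * max(grid$spacing))

## voxel indices (linear) whose centers lie within `radius` of any row of xyz
voxels_near_atoms <- function(grid, xyz, radius) {
  d <- grid$dims
  sp <- grid$spacing
  or <- grid$origin
  r2 <- radius^2
  out <- vector("list", nrow(xyz))
  for (a in seq_len(nrow(xyz))) {
    p <- xyz[a, ]
    lo <- pmax(1L, as.integer(ceiling((p - radius - or) / sp)) + 1L)
    hi <- pmin(d, as.integer(floor((p + radius - or) / sp)) + 1L)
    if (any(lo > hi)) next
    ix <- lo[1L]:hi[1L]; iy <- lo[2L]:hi[2L]; iz <- lo[3L]:hi[3L]
    dx2 <- (or[1L] + (ix - 1L) * sp[1L] - p[1L])^2
    dy2 <- (or[2L] + (iy - 1L) * sp[2L] - p[2L])^2
    dz2 <- (or[3L] + (iz - 1L) * sp[3L] - p[3L])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    keep <- which(d2 <= r2, arr.ind = TRUE)
    if (!nrow(keep)) next
    out[[a]] <- ix[keep[, 1L]] +
      d[1L] * ((iy[keep[, 2L]] - 1L) + d[2L] * (iz[keep[, 3L]] - 1L))
  }
  unique(unlist(out))
}

#' Voxels occupied by a residue segment
#'
#' All voxels whose center lies within `radius` of any atom of the segment;
#' this defines the mask `vox_sr` the SMOC score is computed over.
#'
#' @param grid the `density_grid` supplying the voxel lattice.
#' @param structure a `model_structure`.
#' @param segment a `residue_segment`.
#' @param radius occupancy radius in Angstrom; default
#'   `max(2.5, 1.5 * max(spacing))`.
#' @return a `grid_index_set`.
#' @export
segment_voxels <- function(grid, structure, segment,
                           radius = default_mask_radius(grid)) {
  stopifnot(radius > 0)
  rows <- atom_rows_of_uids(structure, segment_uids(segment, structure))
  idx <- voxels_near_atoms(grid, coords(structure)[rows, , drop = FALSE], radius)
  if (!length(idx))
    stop("segment ", segment$label, " occupies no voxel of the grid")
  grid_index_set(idx, grid)
}

#' SMOC score of a voxel set
#'
#' The Manders' overlap coefficient between the experimental and the
#' model-derived density over the listed voxels:
#' `sum(em * model) / sqrt(sum(em^2) * sum(model^2))`.
#' Unlike the global CCC no mean is subtracted, so the score is invariant to
#' positive rescaling of either map but sensitive to additive offsets.
#'
#' @param em experimental `density_grid`.
#' @param model_density model-derived `density_grid` on identical geometry.
#' @param vox a `grid_index_set`.
#' @param mean_subtract subtract each map's mean over the mask first, which
#'   turns the score into the segment-based cross-correlation (SCCC) variant
#'   instead of the Manders' overlap (default off).
#' @return score in `[-1, 1]` (`[0, 1]` when both maps are non-negative).
#' @export
smoc_segment <- function(em, model_density, vox, mean_subtract = FALSE) {
  if (!same_geometry(em, model_density))
    stop("grids do not share geometry (dims/spacing/origin)")
  stopifnot(inherits(vox, "grid_index_set"), length(vox$idx) > 0L)
  a <- as.numeric(em$values)[vox$idx]
  b <- as.numeric(model_density$values)[vox$idx]
  if (mean_subtract) {
    a <- a - mean(a)
    b <- b - mean(b)
  }
  saa <- sum(a * a)
  sbb <- sum(b * b)
  if (saa == 0 || sbb == 0)
    stop("flat density over the segment mask: SMOC undefined")
  sum(a * b) / sqrt(saa * sbb)
}

#' Per-residue SMOC profile
#'
#' Residues inside an SSE get that SSE's segment score; loop residues are
#' scored over overlapping windows of `window` consecutive chain residues
#' centered on each (shifted inward at chain termini, shrunk when the chain
#' is shorter than the window).  The model density is simulated at
#' `resolution` on the grid of `em`, so voxel-wise products need no
#' interpolation.
#'
#' @param em experimental `density_grid`.
#' @param structure a `model_structure`.
#' @param sses an `sse_annotation`.
#' @param resolution map resolution (Angstrom) for the simulated model
#'   density.
#' @param window odd loop window length (>= 3), default 9.
#' @param radius voxel occupancy radius (see [segment_voxels()]).
#' @param stage free-text stage label stored with the profile.
#' @param model_density optional precomputed model density on the `em` grid.
#' @param loop_assign `"center"` (default) gives each loop residue the score
#'   of the window centered on it; `"average"` averages the scores of every
#'   window covering the residue.
#' @return a `smoc_profile`: data.frame of per-residue scores plus a
#'   segment table.
#' @export
smoc_profile <- function(em, structure, sses, resolution, window = 9L,
                         radius = default_mask_radius(em), stage = "model",
                         model_density = NULL,
                         loop_assign = c("center", "average")) {
  loop_assign <- match.arg(loop_assign)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3")
  if (is.null(model_density))
    model_density <- simulate_density(structure, resolution, grid = em)
  else if (!same_geometry(em, model_density))
    stop("model_density does not share the em grid geometry")
  ri <- structure$residue_index
  ## check every residue has at least one heavy atom
  heavy <- structure$atoms$element != "H"
  n_heavy <- vapply(seq_len(nrow(ri)), function(i)
    sum(heavy[ri$first[i]:ri$last[i]]), integer(1L))
  if (any(n_heavy == 0L))
    stop("residue(s) without heavy atoms: ",
         paste(utils::head(ri$uid[n_heavy == 0L], 5L), collapse = ", "))
  xyz <- coords(structure)
  ## per-residue voxel sets (heavy atoms only)
  res_vox <- lapply(seq_len(nrow(ri)), function(i) {
    rows <- (ri$first[i]:ri$last[i])
    rows <- rows[heavy[rows]]
    voxels_near_atoms(em, xyz[rows, , drop = FALSE], radius)
  })
  emv <- as.numeric(em$values)
  mdv <- as.numeric(model_density$values)
  score_vox <- function(idx) {
    idx <- unique(unlist(idx))
    if (!length(idx)) return(NA_real_)
    a <- emv[idx]; b <- mdv[idx]
    saa <- sum(a * a); sbb <- sum(b * b)
    if (saa == 0 || sbb == 0) return(NA_real_)
    sum(a * b) / sqrt(saa * sbb)
  }
  ## SSE membership per residue
  seg_tab <- sses$segments
  seg_id <- rep(NA_integer_, nrow(ri))
  for (s in seq_len(nrow(seg_tab)))
    seg_id[ri$chain_id == seg_tab$chain_id[s] &
             ri$res_seq >= seg_tab$start[s] &
             ri$res_seq <= seg_tab$end[s]] <- s
  smoc <- rep(NA_real_, nrow(ri))
  label <- rep("loop", nrow(ri))
  seg_scores <- data.frame(label = character(), kind = character(),
                           chain_id = character(), start = integer(),
                           end = integer(), smoc = double())
  for (s in seq_len(nrow(seg_tab))) {
    members <- which(seg_id == s)
    if (!length(members)) next
    sc <- score_vox(res_vox[members])
    smoc[members] <- sc
    lab <- sprintf("%s%d %s:%d-%d", substr(seg_tab$kind[s], 1L, 1L), s,
                   seg_tab$chain_id[s], seg_tab$start[s], seg_tab$end[s])
    label[members] <- lab
    seg_scores <- rbind(seg_scores,
                        data.frame(label = lab, kind = seg_tab$kind[s],
                                   chain_id = seg_tab$chain_id[s],
                                   start = seg_tab$start[s],
                                   end = seg_tab$end[s], smoc = sc))
  }
  ## loop residues: sliding windows over chain positions
  half <- (window - 1L) %/% 2L
  for (ch in unique(ri$chain_id)) {
    pos <- which(ri$chain_id == ch)
    nch <- length(pos)
    win_of <- function(j) {
      w <- min(window, nch)
      lo <- max(1L, min(j - half, nch - w + 1L))
      lo:(lo + w - 1L)
    }
    loop_j <- which(is.na(seg_id[pos]))
    if (!length(loop_j)) next
    wscore <- vapply(loop_j, function(j) score_vox(res_vox[pos[win_of(j)]]),
                     numeric(1L))
    if (loop_assign == "center") {
      smoc[pos[loop_j]] <- wscore
    } else {
      for (t in seq_along(loop_j)) {
        j <- loop_j[t]
        covering <- vapply(seq_along(loop_j), function(u)
          j %in% win_of(loop_j[u]), logical(1L))
        smoc[pos[j]] <- mean(wscore[covering])
      }
    }
  }
  if (any(is.na(smoc)))
    stop("residue(s) could not be scored (empty or flat mask): ",
         paste(utils::head(ri$uid[is.na(smoc)], 5L), collapse = ", "))
  prof <- data.frame(chain_id = ri$chain_id, res_seq = ri$res_seq,
                     insertion_code = ri$insertion_code, uid = ri$uid,
                     segment_label = label, smoc = smoc,
                     stringsAsFactors = FALSE)
  x <- list(residues = prof, segments = seg_scores, stage = stage,
            window = window, radius = radius)
  class(x) <- "smoc_profile"
  x
}

#' @export
print.smoc_profile <- function(x, ...) {
  cat(sprintf("smoc_profile '%s': %d residues, mean SMOC %.4f (min %.4f at %s)\n",
              x$stage, nrow(x$residues), mean(x$residues$smoc),
              min(x$residues$smoc),
              x$residues$uid[which.min(x$residues$smoc)]))
  invisible(x)
}

#' Z-scores of a SMOC profile
#'
#' `Z = (s_r - mu) / sigma` with the population standard deviation over all
#' residues.  When all scores are equal, all Z are zero (with a warning).
#'
#' @param profile a `smoc_profile`.
#' @return a `zscore_profile` with per-residue `z`, `mu` and `sigma`.
#' @export
smoc_zscores <- function(profile) {
  s <- profile$residues$smoc
  if (length(s) < 2L) stop("need at least 2 residues for Z-scores")
  mu <- mean(s)
  sigma <- sqrt(mean((s - mu)^2))
  if (sigma == 0) {
    warning("constant SMOC profile: all Z-scores set to 0")
    z <- rep(0, length(s))
  } else z <- (s - mu) / sigma
  out <- profile$residues
  out$z <- z
  x <- list(residues = out, mu = mu, sigma = sigma, stage = profile$stage)
  class(x) <- "zscore_profile"
  x
}

#' Flag poorly fitting segments from a Z-score profile
#'
#' Maximal runs of consecutive chain residues with `Z < threshold`, each
#' labelled with its containing SSE (or "loop").  Runs shorter than
#' `min_run` residues are dropped.
#'
#' @param z a `zscore_profile`.
#' @param sses the `sse_annotation` used for labelling.
#' @param threshold flagging threshold in Z units (must be negative).
#' @param min_run minimum run length kept (default 3).
#' @return list of `residue_segment` objects (possibly empty).
#' @export
flag_poor_segments <- function(z, sses, threshold = -1, min_run = 3L) {
  stopifnot(threshold < 0)
  r <- z$residues
  out <- list()
  for (ch in unique(r$chain_id)) {
    sub <- r[r$chain_id == ch, , drop = FALSE]
    low <- sub$z < threshold
    rl <- rle(low)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (k in seq_along(rl$values)) {
      if (!rl$values[k] || rl$lengths[k] < min_run) next
      rows <- starts[k]:ends[k]
      labs <- unique(sub$segment_label[rows])
      out[[length(out) + 1L]] <-
        residue_segment(ch, sub$res_seq[rows],
                        label = sprintf("%s:%d-%d [%s]", ch,
                                        sub$res_seq[starts[k]],
                                        sub$res_seq[ends[k]],
                                        paste(labs, collapse = ",")),
                        allow_gaps = TRUE)
    }
  }
  out
}

#' Compare two SMOC profiles
#'
#' Per-residue score difference `b - a` between two refinement stages, with
#' the fraction of residues improved and the mean delta as attributes.
#'
#' @param a,b `smoc_profile` objects over the same residue set.
#' @return data.frame with per-residue `smoc_a`, `smoc_b`, `delta`;
#'   attributes `fraction_improved` and `mean_delta`.
#' @export
compare_profiles <- function(a, b) {
  ra <- a$residues
  rb <- b$residues
  if (!setequal(ra$uid, rb$uid) || nrow(ra) != nrow(rb)) {
    miss <- c(setdiff(ra$uid, rb$uid), setdiff(rb$uid, ra$uid))
    stop("profiles cover different residues: ",
         paste(utils::head(miss, 8L), collapse = ", "))
  }
  rb <- rb[match(ra$uid, rb$uid), , drop = FALSE]
  out <- data.frame(chain_id = ra$chain_id, res_seq = ra$res_seq, uid = ra$uid,
                    smoc_a = ra$smoc, smoc_b = rb$smoc,
                    delta = rb$smoc - ra$smoc, stringsAsFactors = FALSE)
  attr(out, "fraction_improved") <- mean(out$delta > 0)
  attr(out, "mean_delta") <- mean(out$delta)
  out
}

#' Write a SMOC (or Z-score) profile as TSV
#' @param profile a `smoc_profile` or `zscore_profile`.
#' @param path output path.
#' @export
write_profile_tsv <- function(profile, path) {
  r <- profile$residues
  cols <- intersect(c("chain_id", "res_seq", "segment_label", "smoc", "z"),
                    names(r))
  utils::write.table(r[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
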