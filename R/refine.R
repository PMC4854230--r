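# The hierarchical multi-stage protocol, interface freezing, and SMOC-ranked
# loop-ensemble refinement.

STAGE_CAPS <- c(ribfind_clusters = 0.39, sse = 0.15, all_atom = 0.10)

#' Add frozen segments to a rigid-body scheme
#'
#' Each listed segment becomes an additional rigid body, active even at the
#' all-atom level — used to keep exposed interface loops rigid so that their
#' atoms cannot drift into density belonging to an interacting partner.
#'
#' @param scheme a `rigid_body_scheme`.
#' @param segments list of `residue_segment` objects (empty list leaves the
#'   scheme unchanged).
#' @return the extended `rigid_body_scheme`.
#' @export
freeze_interface <- function(scheme, segments) {
  if (!length(segments)) return(scheme)
  bodies <- scheme$bodies
  for (seg in segments) {
    stopifnot(inherits(seg, "residue_segment"))
    for (b in bodies) {
      clash <- b$chain_id == seg$chain_id &
        b$start <= max(seg$res_seq) & b$end >= min(seg$res_seq)
      if (any(clash))
        stop("frozen segment ", seg$label, " overlaps an existing rigid body (",
             b$chain_id[clash][1L], ":", b$start[clash][1L], "-",
             b$end[clash][1L], ")")
    }
    bodies[[length(bodies) + 1L]] <-
      data.frame(chain_id = seg$chain_id, start = min(seg$res_seq),
                 end = max(seg$res_seq))
  }
  rigid_body_scheme(bodies, level = scheme$level)
}

#' Hierarchical flexible-fitting refinement
#'
#' Runs the annealing engine over progressively smaller rigid bodies:
#' RIBFIND clusters (per-axis step cap 0.39 Angstrom), then individual SSEs
#' (0.15), then all atoms free (0.10).  Each stage iterates annealing cycles
#' until the global CCC plateaus (`ccc_tol`) or `cycles` is reached.  When
#' the model has no multiple cluster bodies the first stage is skipped and
#' refinement starts by constraining SSEs as rigid bodies.  Per-stage SMOC
#' profiles are appended to the trace.
#'
#' @param structure starting `model_structure`.
#' @param em target `density_grid`.
#' @param sses an `sse_annotation`.
#' @param clusters optional `rigid_body_scheme` from [cluster_sses()]
#'   (computed from `sses` when `NULL`).
#' @param config an `anneal_config`; its `max_step` is overridden per stage.
#' @param freeze list of `residue_segment`s kept rigid at every stage.
#' @param stages subset of stages to run, in order.
#' @return list with the refined `structure` and a `trace` holding per-stage
#'   CCC series, displacement logs and SMOC profiles.
#' @export
hierarchical_refine <- function(structure, em, sses, clusters = NULL,
                                config = anneal_config(),
                                freeze = list(),
                                stages = c("ribfind_clusters", "sse",
                                           "all_atom")) {
  res <- config$resolution
  if (is.null(res) || is.na(res)) res <- em$resolution_hint
  if (is.null(res) || is.na(res))
    stop("no resolution given and the map has no resolution_hint")
  config$resolution <- res
  trace <- list(stages = list(), smoc = list())
  if (config$cycles == 0L) return(list(structure = structure, trace = trace))
  if (is.null(clusters) && "ribfind_clusters" %in% stages)
    clusters <- cluster_sses(structure, sses)
  trace$smoc[["initial"]] <-
    smoc_profile(em, structure, sses, res, stage = "initial")
  restraints <- build_restraints(structure)
  current <- structure
  for (si in seq_along(stages)) {
    level <- stages[si]
    scheme <- scheme_for_level(sses, clusters, level)
    if (level == "ribfind_clusters" && length(scheme$bodies) < 2L) {
      message("fewer than two cluster bodies: skipping the cluster stage ",
              "and starting at the SSE level")
      next
    }
    scheme <- freeze_interface(scheme, freeze)
    cfg <- config
    cfg$max_step <- unname(STAGE_CAPS[level])
    cfg$seed <- config$seed + si - 1L
    stage_out <- anneal(current, em, scheme, restraints, cfg)
    current <- stage_out$structure
    trace$stages[[level]] <- stage_out$trace
    trace$smoc[[level]] <-
      smoc_profile(em, current, sses, res, stage = level)
  }
  list(structure = current, trace = trace)
}

#' Score a set of loop conformations by SMOC
#'
#' Each conformation is a full `model_structure` differing from `structure`
#' only in the loop; the SMOC of the loop segment (voxels occupied by that
#' conformation's loop atoms) against the target map ranks them.
#'
#' @param em target `density_grid`.
#' @param loop the `residue_segment` being sampled.
#' @param conformations list of `model_structure` objects.
#' @param resolution simulation resolution, Angstrom.
#' @return data.frame with `conformation`, `smoc`, `rank` (1 = best).
#' @export
score_loop_ensemble <- function(em, loop, conformations,
                                resolution = em$resolution_hint) {
  if (is.null(resolution) || is.na(resolution))
    stop("no resolution given and the map has no resolution_hint")
  smoc <- vapply(conformations, function(s) {
    md <- simulate_density(s, resolution, grid = em)
    vox <- segment_voxels(em, s, loop)
    smoc_segment(em, md, vox)
  }, numeric(1L))
  out <- data.frame(conformation = seq_along(conformations), smoc = smoc)
  out$rank <- rank(-out$smoc, ties.method = "first")
  out[order(out$rank), ]
}

#' SMOC-ranked loop-ensemble refinement
#'
#' Samples `n` conformations of a loop by seeded random backbone-dihedral
#' perturbation with cyclic-coordinate-descent endpoint closure and clash
#' rejection, scores each by the loop-segment SMOC against the target map,
#' and substitutes the top-scoring conformation into the model.
#'
#' @param structure a `model_structure`.
#' @param em target `density_grid`.
#' @param loop a `residue_segment` interior to a chain.
#' @param n ensemble size (default 200).
#' @param amplitude dihedral perturbation SD in degrees (0 keeps the input
#'   conformation).
#' @param resolution simulation resolution, Angstrom.
#' @param seed integer seed.
#' @param conformations optional pre-built ensemble (list of
#'   `model_structure`s); when given, sampling is skipped.
#' @param clash_dist reject samples with any non-local atom pair closer than
#'   this, Angstrom.
#' @return list with the substituted `structure`, the ranked `table`, and
#'   the `conformations` scored.
#' @export
refine_loop_ensemble <- function(structure, em, loop, n = 200L,
                                 amplitude = 30, resolution = em$resolution_hint,
                                 seed = 1L, conformations = NULL,
                                 clash_dist = 1.5) {
  stopifnot(n >= 1L)
  if (is.null(resolution) || is.na(resolution))
    stop("no resolution given and the map has no resolution_hint")
  if (is.null(conformations)) {
    set.seed(as.integer(seed))
    k <- length(loop$res_seq)
    conformations <- list()
    tries <- 0L
    while (length(conformations) < n && tries < 20L * n) {
      tries <- tries + 1L
      if (amplitude == 0) {
        conformations[[length(conformations) + 1L]] <- structure
        next
      }
      delta <- stats::rnorm(2L * k + 1L, sd = amplitude)
      cand <- rebuild_loop(structure, loop, delta, close_tol = 0.1)
      if (is.null(cand)) next
      if (min_nonlocal_distance(cand) < clash_dist) next
      conformations[[length(conformations) + 1L]] <- cand
    }
    if (!length(conformations))
      stop("loop closure failed for every sample; increase n or widen the ",
           "perturbation amplitude")
    if (length(conformations) < n)
      warning("only ", length(conformations), " of ", n,
              " samples closed without clashes")
  }
  tab <- score_loop_ensemble(em, loop, conformations, resolution)
  best <- tab$conformation[1L]
  list(structure = conformations[[best]], table = tab,
       conformations = conformations)
}
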