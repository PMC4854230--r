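# The refinement engine: combined density + stereochemistry objective and
# capped-step simulated-annealing optimisation of rigid bodies and free
# atoms.

#' Annealing configuration
#'
#' @param max_step maximum atom displacement along one axis per MD step,
#'   Angstrom (0.39 for the large rigid-body stage; 0.15 at the SSE stage;
#'   0.1 at the all-atom stage).
#' @param t_max peak temperature of the 0K -> t_max -> 0K piecewise-linear
#'   schedule, Kelvin.
#' @param steps_heat,steps_cool MD steps in the heating / cooling leg.
#' @param w_em weight of the density term `w_em * (1 - CCC)` relative to the
#'   (unweighted) stereochemical energy, kcal/mol per unit of lost
#'   correlation.  The default 10000 makes the density force on a domain
#'   dominate the covalent restoring forces at its junctions while the
#'   stereochemical terms still control local geometry.
#' @param cycles maximum annealing cycles per stage.
#' @param ccc_tol stop when the cycle-to-cycle change in global CCC falls
#'   below this (plateau criterion).
#' @param seed integer seed; identical inputs and seed give bit-identical
#'   trajectories.
#' @param resolution resolution (Angstrom) at which the model density is
#'   simulated; defaults to the map's `resolution_hint`.
#' @param sigma_factor Gaussian width per Angstrom of resolution.
#' @param noise_frac amplitude of the temperature-scaled displacement noise,
#'   as a fraction of `max_step` at `t_max`.
#' @param accept_slack uphill energy tolerance (kcal/mol) at `t_max`;
#'   scaled linearly with temperature (0 at 0K gives strict descent).
#' @export
anneal_config <- function(max_step = 0.39, t_max = 1000, steps_heat = 200L,
                          steps_cool = 200L, w_em = 10000, cycles = 5L,
                          ccc_tol = 1e-4, seed = 1L, resolution = NULL,
                          sigma_factor = 0.356, noise_frac = 0.03,
                          accept_slack = 10) {
  stopifnot(max_step > 0, t_max > 0, ccc_tol >= 0, steps_heat >= 1L,
            steps_cool >= 1L, cycles >= 0L)
  x <- list(max_step = max_step, t_max = t_max, steps_heat = as.integer(steps_heat),
            steps_cool = as.integer(steps_cool), w_em = w_em,
            cycles = as.integer(cycles), ccc_tol = ccc_tol,
            seed = as.integer(seed), resolution = resolution,
            sigma_factor = sigma_factor, noise_frac = noise_frac,
            accept_slack = accept_slack)
  class(x) <- "anneal_config"
  x
}

#' Density + stereochemistry objective
#'
#' `total = w_em * (1 - CCC(em, simulated model density)) + stereochemical
#' energy`; the components are reported separately for logging.
#'
#' @param structure a `model_structure`.
#' @param em target `density_grid` (needs a resolution, either via
#'   `resolution` or its `resolution_hint`).
#' @param restraints a `restraint_set` built for this structure.
#' @param w_em density-term weight.
#' @param resolution simulation resolution, Angstrom.
#' @param sigma_factor Gaussian width convention.
#' @return list with `total`, `density`, `ccc` and the stereochemical
#'   components.
#' @export
objective <- function(structure, em, restraints, w_em = 1,
                      resolution = em$resolution_hint, sigma_factor = 0.356) {
  if (is.null(resolution) || is.na(resolution))
    stop("no resolution given and the map has no resolution_hint")
  xyz <- coords(structure)
  w <- atomic_numbers(structure$atoms$element)
  dens <- .density_ccc_grad_cpp(xyz, w, as.numeric(em$values),
                                as.integer(em$dims), em$origin, em$spacing,
                                sigma_factor * resolution, 3)
  st <- restraint_energy(restraints, xyz)
  list(total = w_em * (1 - dens$ccc) + st$total,
       density = w_em * (1 - dens$ccc), ccc = dens$ccc, stereo = st$total,
       components = st)
}

## atom row indices of each rigid body; attribute "free" holds the rest
body_atom_rows <- function(structure, scheme) {
  uids <- validate_scheme(scheme, structure)
  rows <- lapply(uids, function(u) atom_rows_of_uids(structure, u))
  free <- setdiff(seq_len(nrow(structure$atoms)),
                  if (length(rows)) unlist(rows) else integer())
  list(bodies = rows, free = free)
}

## piecewise-linear 0 -> t_max -> 0 schedule
schedule_temperature <- function(step, config) {
  h <- config$steps_heat; c0 <- config$steps_cool
  if (step <= h) config$t_max * step / h
  else config$t_max * (1 - (step - h) / c0)
}

#' Simulated-annealing refinement of rigid bodies and free atoms
#'
#' Rigid bodies move as units (translation plus rotation about the body
#' centroid, driven by the net force and torque); atoms outside every body
#' move individually.  Forces are the negative gradient of the objective;
#' per-step per-axis displacements are clipped to `config$max_step` (body
#' motions are scaled uniformly so rigidity is exact).  Displacement noise
#' scales with the temperature schedule; moves that raise the objective by
#' more than the temperature-scaled slack are rejected, so the schedule ends
#' in strict descent.
#'
#' @param structure starting `model_structure`.
#' @param em target `density_grid`.
#' @param scheme a `rigid_body_scheme` (validated against `structure`).
#' @param restraints a `restraint_set`.
#' @param config an `anneal_config`.
#' @return list with the refined `structure` and a `trace` (per-cycle CCC,
#'   per-step max displacement log).
#' @export
anneal <- function(structure, em, scheme, restraints, config = anneal_config()) {
  res <- config$resolution
  if (is.null(res) || is.na(res)) res <- em$resolution_hint
  if (is.null(res) || is.na(res))
    stop("no resolution given and the map has no resolution_hint")
  trace <- list(ccc = numeric(), max_step = numeric(), stage = scheme$level)
  if (config$cycles == 0L) return(list(structure = structure, trace = trace))
  set.seed(config$seed)
  sigma <- config$sigma_factor * res
  xyz <- coords(structure)
  wz <- atomic_numbers(structure$atoms$element)
  memb <- body_atom_rows(structure, scheme)
  lo <- em$origin - 3 * sigma
  hi <- em$origin + (em$dims - 1L) * em$spacing + 3 * sigma
  check_support <- function(X) {
    out <- X[, 1L] < lo[1L] | X[, 2L] < lo[2L] | X[, 3L] < lo[3L] |
      X[, 1L] > hi[1L] | X[, 2L] > hi[2L] | X[, 3L] > hi[3L]
    if (any(out))
      stop("structure escaped the map support (", sum(out),
           " atom(s) outside the grid plus margin)")
  }
  check_support(xyz)
  evaluate <- function(X) {
    dens <- .density_ccc_grad_cpp(X, wz, as.numeric(em$values),
                                  as.integer(em$dims), em$origin, em$spacing,
                                  sigma, 3)
    if (any(!is.finite(dens$grad))) stop("non-finite density force: aborting")
    st <- restraint_eval(restraints, X, grad = TRUE)
    if (any(!is.finite(st$gradient)))
      stop("non-finite restraint force: aborting")
    list(total = config$w_em * (1 - dens$ccc) + st$total, ccc = dens$ccc,
         force = config$w_em * dens$grad - st$gradient)
  }
  cur <- evaluate(xyz)
  cap <- config$max_step
  gain0 <- 0.3 * cap / max(max(abs(cur$force)), 1e-9)
  gain <- gain0
  nsteps <- config$steps_heat + config$steps_cool
  prev_ccc <- cur$ccc
  for (cycle in seq_len(config$cycles)) {
    for (step in seq_len(nsteps)) {
      temp <- schedule_temperature(step, config)
      noise_amp <- config$noise_frac * cap * sqrt(temp / config$t_max)
      disp <- matrix(0, nrow(xyz), 3L)
      if (length(memb$free)) {
        d <- gain * cur$force[memb$free, , drop = FALSE] +
          matrix(stats::rnorm(3L * length(memb$free), sd = max(noise_amp, 1e-12)),
                 ncol = 3L)
        disp[memb$free, ] <- pmax(pmin(d, cap), -cap)
      }
      for (b in memb$bodies) {
        Fb <- cur$force[b, , drop = FALSE]
        Xb <- xyz[b, , drop = FALSE]
        ctr <- colMeans(Xb)
        rel <- sweep(Xb, 2L, ctr)
        tr <- gain * colMeans(Fb) +
          stats::rnorm(3L, sd = max(noise_amp, 1e-12))
        tau <- colSums(row_cross(rel, Fb))
        inertia <- max(sum(rel^2), 1e-9)
        omega <- gain * tau / inertia +
          stats::rnorm(3L, sd = max(noise_amp, 1e-12)) / sqrt(inertia / length(b))
        for (rep in 1:4) {
          ang <- vnorm(omega)
          db <- if (ang > 1e-12)
            sweep(rel %*% t(rotation_matrix(omega, ang)) - rel, 2L, tr, `+`)
          else matrix(tr, length(b), 3L, byrow = TRUE)
          mx <- max(abs(db))
          if (mx <= cap) break
          sc <- cap / mx * 0.999
          tr <- tr * sc
          omega <- omega * sc
        }
        disp[b, ] <- db
      }
      trace$max_step <- c(trace$max_step, max(abs(disp)))
      xyz_new <- xyz + disp
      new <- evaluate(xyz_new)
      slack <- config$accept_slack * temp / config$t_max
      if (new$total <= cur$total + slack) {
        xyz <- xyz_new
        cur <- new
        gain <- min(gain * 1.1, gain0 * 100)
      } else {
        gain <- max(gain * 0.5, gain0 * 0.01)
      }
    }
    check_support(xyz)
    trace$ccc <- c(trace$ccc, cur$ccc)
    if (abs(cur$ccc - prev_ccc) < config$ccc_tol) break
    prev_ccc <- cur$ccc
  }
  out <- structure
  coords(out) <- xyz
  list(structure = out, trace = trace)
}
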