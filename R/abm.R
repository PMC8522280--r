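# Off-lattice cell-center agent-based model of macrophage infiltration into
# an avascular tumor spheroid under a CSF-1 chemotactic gradient.
#
# Units: lengths in cell diameters, time in simulation time units. All
# kinetic and mechanical defaults are this package's own documented
# parameterization, chosen so that a burn-in produces a spheroid with a
# proliferating rim, a hypoxic CSF-1-secreting annulus and a necrotic core,
# and so that macrophage infiltration speed increases with the chemotactic
# sensitivity chi (see the methods vignette).

#' Parameters of the spheroid-macrophage agent-based model
#'
#' @param chi chemotactic sensitivity: force per unit CSF-1 gradient on a
#'   macrophage (0 = insensitive).
#' @param n_macrophages macrophages placed at the spheroid edge (default
#'   100).
#' @param obs_interval observation spacing in time units (default 4).
#' @param duration observed simulation length in time units (default 100,
#'   giving 26 observations at t = 0, 4, ..., 100).
#' @param mislabel_p probability that a tumor cell is mislabeled as a
#'   macrophage in a noisy observation (default 0.01).
#' @param dt mechanics timestep.
#' @param drag drag coefficient of the overdamped position update.
#' @param spring_k linear spring stiffness between cell centers.
#' @param rest_length spring rest length = cell diameter = 1.
#' @param r_interact interaction (adhesion) cutoff.
#' @param domain_half half-side of the square domain.
#' @param grid_h field grid spacing.
#' @param oxygen_diffusion,oxygen_consumption,oxygen_boundary quasi-steady
#'   oxygen field: diffusion rate, per-unit-viable-density consumption
#'   (linear sink), and the fixed far-field boundary value (1 =
#'   nondimensional well-oxygenated).
#' @param csf1_diffusion,csf1_decay,csf1_secretion quasi-steady CSF-1
#'   field: diffusion, uniform decay and per-unit-hypoxic-density secretion
#'   (zero-flux boundary).
#' @param thr_necrosis,thr_hypoxia,thr_prolif oxygen thresholds, ordered
#'   necrosis < hypoxia < proliferation: below `thr_necrosis` the hypoxia
#'   clock runs, below `thr_hypoxia` viable cells secrete CSF-1, above
#'   `thr_prolif` (and given free space) cells may divide.
#' @param hypoxia_duration time a cell must spend below the necrosis
#'   threshold before becoming necrotic.
#' @param division_rate division probability per unit time for eligible
#'   cells.
#' @param max_neighbors contact inhibition: division requires at most this
#'   many neighbors within `ncount_radius`.
#' @param ncount_radius neighborhood radius for contact inhibition.
#' @param daughter_sep initial separation of a daughter cell.
#' @param necrotic_removal_rate removal rate of necrotic material (default
#'   0: necrotic cells are retained as inert obstacles).
#' @param field_interval how often the quasi-steady fields are re-solved,
#'   in time units (fields are frozen between solves; diffusion is fast
#'   relative to cell motion).
#' @param init_radius initial spheroid radius for the burn-in.
#' @param burnin_max_steps,burnin_window,burnin_tol equilibrium detection:
#'   burn-in stops when the viable-cell count changes by less than
#'   `burnin_tol` (relative) over `burnin_window` consecutive steps.
#' @return a validated `abm_params` list.
#' @export
abm_params <- function(chi = 20,
                       n_macrophages = 100L, obs_interval = 4,
                       duration = 100, mislabel_p = 0.01,
                       dt = 0.05, drag = 1, spring_k = 8,
                       rest_length = 1, r_interact = 1.5,
                       domain_half = 17, grid_h = 1,
                       oxygen_diffusion = 100, oxygen_consumption = 3,
                       oxygen_boundary = 1,
                       csf1_diffusion = 20, csf1_decay = 0.4,
                       csf1_secretion = 1,
                       thr_necrosis = 0.3, thr_hypoxia = 0.5,
                       thr_prolif = 0.7,
                       hypoxia_duration = 4,
                       division_rate = 0.1, max_neighbors = 4L,
                       ncount_radius = 1.2, daughter_sep = 0.3,
                       necrotic_removal_rate = 0,
                       field_interval = 4,
                       init_radius = 12,
                       burnin_max_steps = 4000L, burnin_window = 50L,
                       burnin_tol = 0.02) {
  p <- as.list(environment())
  rates <- c(chi, mislabel_p, dt, drag, spring_k, oxygen_diffusion,
             oxygen_consumption, csf1_diffusion, csf1_decay, csf1_secretion,
             division_rate, necrotic_removal_rate, hypoxia_duration)
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (!(thr_necrosis < thr_hypoxia && thr_hypoxia < thr_prolif))
    stop("oxygen thresholds must be ordered necrosis < hypoxia < proliferation")
  if (mislabel_p > 1) stop("mislabel_p must be a probability")
  if (abs(obs_interval / dt - round(obs_interval / dt)) > 1e-9)
    stop("obs_interval must be a multiple of dt")
  structure(p, class = "abm_params")
}

#' Solve a quasi-steady diffusion-reaction field on a regular grid
#'
#' Solves `diffusion * Laplacian(c) - decay * c + sources = 0` on a square
#' grid with either a fixed boundary value (Dirichlet; used for oxygen,
#' which is replenished at the far boundary) or zero-flux boundaries
#' (Neumann; used for CSF-1, which is removed by decay alone). `decay` may
#' be a matrix, which is how oxygen consumption proportional to the local
#' viable-cell density enters as a spatially varying linear sink.
#'
#' @param sources matrix of source density per grid node (>= 0 for sources,
#'   < 0 for explicit sinks).
#' @param diffusion scalar diffusion rate (> 0).
#' @param decay scalar or matrix decay rate (>= 0).
#' @param boundary fixed boundary value (Dirichlet only).
#' @param h grid spacing.
#' @param bc `"dirichlet"` or `"neumann"`.
#' @return matrix of the same shape as `sources`; the residual of the
#'   linear system is checked to be below 1e-8 of the right-hand side norm.
#' @export
solve_quasi_steady_field <- function(sources, diffusion, decay = 0,
                                     boundary = 0, h = 1,
                                     bc = c("dirichlet", "neumann")) {
  bc <- match.arg(bc)
  if (diffusion <= 0) stop("diffusion must be > 0")
  nx <- nrow(sources); ny <- ncol(sources)
  if (is.matrix(decay)) {
    if (!all(dim(decay) == c(nx, ny))) stop("decay matrix shape mismatch")
    if (any(decay < 0)) stop("decay must be >= 0")
    dec <- as.numeric(decay)
  } else {
    if (decay < 0) stop("decay must be >= 0")
    dec <- rep(decay, nx * ny)
  }
  id <- function(i, j) i + (j - 1L) * nx
  ii <- rep(seq_len(nx), ny)
  jj <- rep(seq_len(ny), each = nx)
  on_boundary <- ii == 1L | ii == nx | jj == 1L | jj == ny
  rows <- list(); cols <- list(); vals <- list()
  push <- function(r, c, v) {
    n <- length(rows) + 1L
    rows[[n]] <<- r; cols[[n]] <<- c; vals[[n]] <<- v
  }
  rhs <- -as.numeric(sources)
  if (bc == "dirichlet") {
    interior <- !on_boundary
    # boundary rows: identity
    push(which(on_boundary), which(on_boundary), rep(1, sum(on_boundary)))
    rhs[on_boundary] <- boundary
    ci <- which(interior)
    push(ci, ci, -4 * diffusion / h^2 - dec[ci])
    for (shift in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      nb <- id(ii[ci] + shift[1], jj[ci] + shift[2])
      push(ci, nb, rep(diffusion / h^2, length(ci)))
    }
  } else {
    ci <- seq_len(nx * ny)
    deg <- numeric(nx * ny)
    for (shift in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      ok <- ii + shift[1] >= 1L & ii + shift[1] <= nx &
        jj + shift[2] >= 1L & jj + shift[2] <= ny
      nb <- id(ii[ok] + shift[1], jj[ok] + shift[2])
      push(ci[ok], nb, rep(diffusion / h^2, sum(ok)))
      deg <- deg + ok
    }
    push(ci, ci, -deg * diffusion / h^2 - dec)
  }
  A <- Matrix::sparseMatrix(i = unlist(rows), j = unlist(cols),
                            x = unlist(vals), dims = c(nx * ny, nx * ny))
  if (bc == "neumann" && all(dec == 0))
    stop("neumann problem with zero decay is singular")
  sol <- tryCatch(as.numeric(Matrix::solve(A, rhs)),
                  error = function(e) stop("field solve failed: ",
                                           conditionMessage(e)))
  res <- sqrt(sum((as.numeric(A %*% sol) - rhs)^2))
  ref <- max(sqrt(sum(rhs^2)), 1e-12)
  if (res > 1e-8 * ref) stop("field solve residual too large: ", res)
  matrix(sol, nx, ny)
}

# bilinear interpolation of a grid field at arbitrary points
interp_field <- function(field, gx, gy, px, py) {
  h <- gx[2] - gx[1]
  fx <- pmin(pmax((px - gx[1]) / h, 0), length(gx) - 1 - 1e-9)
  fy <- pmin(pmax((py - gy[1]) / h, 0), length(gy) - 1 - 1e-9)
  i <- floor(fx); j <- floor(fy)
  tx <- fx - i; ty <- fy - j
  i <- as.integer(i) + 1L; j <- as.integer(j) + 1L
  f00 <- field[cbind(i, j)]; f10 <- field[cbind(i + 1L, j)]
  f01 <- field[cbind(i, j + 1L)]; f11 <- field[cbind(i + 1L, j + 1L)]
  f00 * (1 - tx) * (1 - ty) + f10 * tx * (1 - ty) +
    f01 * (1 - tx) * ty + f11 * tx * ty
}

# central-difference gradient of a grid field
grad_field <- function(field, h) {
  nx <- nrow(field); ny <- ncol(field)
  gx <- field; gy <- field
  gx[2:(nx - 1), ] <- (field[3:nx, ] - field[1:(nx - 2), ]) / (2 * h)
  gx[1, ] <- (field[2, ] - field[1, ]) / h
  gx[nx, ] <- (field[nx, ] - field[nx - 1, ]) / h
  gy[, 2:(ny - 1)] <- (field[, 3:ny] - field[, 1:(ny - 2)]) / (2 * h)
  gy[, 1] <- (field[, 2] - field[, 1]) / h
  gy[, ny] <- (field[, ny] - field[, ny - 1]) / h
  list(x = gx, y = gy)
}

# bin cell positions to grid-node density (cells per unit area)
density_on_grid <- function(px, py, gx, gy, h) {
  nx <- length(gx); ny <- length(gy)
  out <- matrix(0, nx, ny)
  if (length(px) == 0L) return(out)
  i <- pmin(pmax(round((px - gx[1]) / h), 0), nx - 1) + 1L
  j <- pmin(pmax(round((py - gy[1]) / h), 0), ny - 1) + 1L
  tab <- table(factor(i, levels = seq_len(nx)), factor(j, levels = seq_len(ny)))
  out + as.numeric(tab) / h^2
}

# re-solve the quasi-steady oxygen and CSF-1 fields from the current cells
refresh_fields <- function(state, params) {
  gx <- state$grid$x; gy <- state$grid$y; h <- state$grid$h
  viable <- state$type == "viable_tumor"
  dens_v <- density_on_grid(state$pos[viable, 1], state$pos[viable, 2],
                            gx, gy, h)
  state$oxygen <- solve_quasi_steady_field(
    sources = matrix(0, length(gx), length(gy)),
    diffusion = params$oxygen_diffusion,
    decay = params$oxygen_consumption * dens_v,
    boundary = params$oxygen_boundary, h = h, bc = "dirichlet")
  ox <- interp_field(state$oxygen, gx, gy, state$pos[, 1], state$pos[, 2])
  secreting <- viable & ox < params$thr_hypoxia
  dens_s <- density_on_grid(state$pos[secreting, 1], state$pos[secreting, 2],
                            gx, gy, h)
  state$csf1 <- solve_quasi_steady_field(
    sources = params$csf1_secretion * dens_s,
    diffusion = params$csf1_diffusion, decay = params$csf1_decay,
    h = h, bc = "neumann")
  state$csf1_grad <- grad_field(state$csf1, h)
  state$fields_time <- state$time
  state
}

new_abm_state <- function(pos, type, params, time = 0) {
  gx <- seq(-params$domain_half, params$domain_half, by = params$grid_h)
  structure(list(time = time, pos = pos, type = type,
                 cycle_clock = numeric(nrow(pos)),
                 hypoxia_clock = numeric(nrow(pos)),
                 oxygen = NULL, csf1 = NULL, csf1_grad = NULL,
                 grid = list(x = gx, y = gx, h = params$grid_h),
                 fields_time = -Inf),
            class = "abm_state")
}

#' @export
print.abm_state <- function(x, ...) {
  tab <- table(x$type)
  cat(sprintf("abm_state at t = %.2f: %s\n", x$time,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' One timestep of the agent-based model
#'
#' Refreshes the quasi-steady fields when due, runs the cell rules
#' (hypoxia-clocked necrosis, contact-inhibited oxygen-gated division,
#' CSF-1 secretion via the field source term) and performs the overdamped
#' position update under pairwise spring forces, with the chemotactic force
#' `chi * grad(CSF-1)` added for macrophages. Consumes random numbers
#' (division and daughter placement); seed control belongs to the caller.
#'
#' @param state an `abm_state`.
#' @param params an [abm_params()].
#' @return the advanced `abm_state`.
#' @export
abm_step <- function(state, params) {
  if (is.null(state$oxygen) ||
      state$time - state$fields_time >= params$field_interval - 1e-9)
    state <- refresh_fields(state, params)
  n <- nrow(state$pos)
  f <- cpp_abm_forces(state$pos[, 1], state$pos[, 2], params$spring_k,
                      params$rest_length, params$r_interact,
                      params$ncount_radius)
  gx <- state$grid$x; gy <- state$grid$y
  ox <- interp_field(state$oxygen, gx, gy, state$pos[, 1], state$pos[, 2])

  viable <- state$type == "viable_tumor"
  # hypoxia clock and necrosis (one-way transition)
  low <- viable & ox < params$thr_necrosis
  state$hypoxia_clock[low] <- state$hypoxia_clock[low] + params$dt
  state$hypoxia_clock[viable & !low] <- 0
  dies <- viable & state$hypoxia_clock >= params$hypoxia_duration
  state$type[dies] <- "necrotic_tumor"

  # division: oxygen-gated, contact-inhibited
  eligible <- which(state$type == "viable_tumor" & ox > params$thr_prolif &
                      f$ncount <= params$max_neighbors)
  state$cycle_clock[eligible] <- state$cycle_clock[eligible] + params$dt
  divide <- eligible[runif(length(eligible)) < params$division_rate * params$dt]

  # chemotactic force on macrophages
  fx <- f$fx; fy <- f$fy
  macro <- state$type == "macrophage"
  if (any(macro) && params$chi > 0) {
    fx[macro] <- fx[macro] + params$chi *
      interp_field(state$csf1_grad$x, gx, gy, state$pos[macro, 1],
                   state$pos[macro, 2])
    fy[macro] <- fy[macro] + params$chi *
      interp_field(state$csf1_grad$y, gx, gy, state$pos[macro, 1],
                   state$pos[macro, 2])
  }
  lim <- params$domain_half - 0.5
  state$pos[, 1] <- pmin(pmax(state$pos[, 1] + params$dt / params$drag * fx,
                              -lim), lim)
  state$pos[, 2] <- pmin(pmax(state$pos[, 2] + params$dt / params$drag * fy,
                              -lim), lim)

  if (length(divide) > 0L) {
    ang <- runif(length(divide), 0, 2 * pi)
    daughters <- state$pos[divide, , drop = FALSE] +
      params$daughter_sep * cbind(cos(ang), sin(ang))
    state$pos <- rbind(state$pos, daughters)
    state$type <- c(state$type, rep("viable_tumor", length(divide)))
    state$cycle_clock[divide] <- 0
    state$cycle_clock <- c(state$cycle_clock, numeric(length(divide)))
    state$hypoxia_clock <- c(state$hypoxia_clock, numeric(length(divide)))
  }
  if (params$necrotic_removal_rate > 0) {
    nec <- which(state$type == "necrotic_tumor")
    drop <- nec[runif(length(nec)) < params$necrotic_removal_rate * params$dt]
    if (length(drop) > 0L) {
      keep <- setdiff(seq_len(nrow(state$pos)), drop)
      state$pos <- state$pos[keep, , drop = FALSE]
      state$type <- state$type[keep]
      state$cycle_clock <- state$cycle_clock[keep]
      state$hypoxia_clock <- state$hypoxia_clock[keep]
    }
  }
  state$time <- state$time + params$dt
  if (!all(is.finite(state$pos)))
    stop(sprintf("non-finite cell position at t = %.3f (%d cells)",
                 state$time, nrow(state$pos)))
  state
}

#' Initialize a spheroid at equilibrium with macrophages at its edge
#'
#' Runs a macrophage-free burn-in from a hexagonally packed disc until the
#' viable-cell count is stationary (net proliferation balancing net death
#' by necrosis: relative change below `burnin_tol` over `burnin_window`
#' steps, evaluated after the first necrosis wave can have occurred), then
#' places `n_macrophages` in contact with the spheroid boundary at uniform
#' random angles. The returned state has `time = 0`.
#'
#' @param params an [abm_params()].
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (as when called from [run_abm()]).
#' @return an `abm_state` at t = 0 with macrophages placed.
#' @export
initialize_spheroid <- function(params, seed = NULL) {
  run <- function() {
    # hexagonal packing of the initial disc
    dy <- sqrt(3) / 2
    rows <- seq(-params$init_radius - 1, params$init_radius + 1, by = dy)
    pts <- do.call(rbind, lapply(seq_along(rows), function(k) {
      xs <- seq(-params$init_radius - 1, params$init_radius + 1, by = 1) +
        (k %% 2) / 2
      cbind(xs, rows[k])
    }))
    pts <- pts[sqrt(rowSums(pts^2)) <= params$init_radius, , drop = FALSE]
    pts <- pts + matrix(rnorm(length(pts), 0, 0.02), ncol = 2)
    state <- new_abm_state(pts, rep("viable_tumor", nrow(pts)), params)
    # burn-in to a stationary viable count
    history <- integer(0)
    min_time <- params$hypoxia_duration + 2
    converged <- FALSE
    for (step in seq_len(params$burnin_max_steps)) {
      state <- abm_step(state, params)
      history <- c(history, sum(state$type == "viable_tumor"))
      w <- params$burnin_window
      if (state$time >= min_time && length(history) >= w) {
        recent <- history[(length(history) - w + 1):length(history)]
        if ((max(recent) - min(recent)) / mean(recent) < params$burnin_tol) {
          converged <- TRUE
          break
        }
      }
    }
    if (!converged)
      stop("spheroid burn-in failed to stabilize within burnin_max_steps")
    # place macrophages touching the local spheroid boundary
    ang_cell <- atan2(state$pos[, 2], state$pos[, 1])
    r_cell <- sqrt(rowSums(state$pos^2))
    theta <- runif(params$n_macrophages, 0, 2 * pi)
    r_macro <- vapply(theta, function(th) {
      dd <- abs(((ang_cell - th + pi) %% (2 * pi)) - pi)
      local <- r_cell[dd < 0.35]
      (if (length(local) > 0) max(local) else max(r_cell)) +
        params$rest_length / 2
    }, numeric(1))
    state$pos <- rbind(state$pos, cbind(r_macro * cos(theta),
                                        r_macro * sin(theta)))
    state$type <- c(state$type, rep("macrophage", params$n_macrophages))
    state$cycle_clock <- c(state$cycle_clock,
                           numeric(params$n_macrophages))
    state$hypoxia_clock <- c(state$hypoxia_clock,
                             numeric(params$n_macrophages))
    state$time <- 0
    refresh_fields(state, params)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# point cloud of one cell type from a state
state_cloud <- function(state, params, types, labels = types) {
  sel <- state$type %in% types
  L <- params$domain_half
  point_cloud(state$pos[sel, , drop = FALSE],
              labels = labels[match(state$type[sel], types)],
              window = c(-L, L, -L, L), units = "cell_diameter")
}

#' Run the agent-based model and observe macrophage point clouds
#'
#' Initializes a spheroid at equilibrium, then simulates for `duration`
#' time units, observing the macrophage coordinates every `obs_interval`
#' time units (26 observations at the defaults). Tumor-cell clouds are kept
#' alongside so that misclassification noise (every tumor cell, viable or
#' necrotic, mislabeled as a macrophage with probability `mislabel_p`) can
#' be applied per observation, matched to the same underlying simulation.
#'
#' @param chi chemotactic sensitivity (>= 0).
#' @param seed integer seed; the run is fully reproducible.
#' @param params an [abm_params()]; its `chi` entry is overridden by the
#'   `chi` argument.
#' @param noise if `TRUE`, `noisy_clouds` are included in the result.
#' @return an `abm_run`: list with `times`, `clouds` (noise-free macrophage
#'   clouds), `tumor_clouds`, optionally `noisy_clouds`, plus `chi`,
#'   `seed` and `params`.
#' @export
run_abm <- function(chi, seed, params = abm_params(), noise = FALSE) {
  if (chi < 0) stop("chi must be >= 0")
  params$chi <- chi
  n_obs <- as.integer(round(params$duration / params$obs_interval)) + 1L
  steps_per_obs <- as.integer(round(params$obs_interval / params$dt))
  run <- with_seed(seed, {
    state <- initialize_spheroid(params)
    times <- numeric(n_obs)
    clouds <- vector("list", n_obs)
    tumor <- vector("list", n_obs)
    grab <- function(k) {
      times[k] <<- state$time
      clouds[[k]] <<- state_cloud(state, params, "macrophage")
      tumor[[k]] <<- state_cloud(state, params,
                                 c("viable_tumor", "necrotic_tumor"))
    }
    grab(1L)
    for (k in seq_len(n_obs - 1L)) {
      for (s in seq_len(steps_per_obs)) state <- abm_step(state, params)
      grab(k + 1L)
    }
    list(times = times, clouds = clouds, tumor_clouds = tumor,
         final_state = state)
  })
  out <- structure(list(times = run$times, clouds = run$clouds,
                        tumor_clouds = run$tumor_clouds,
                        final_state = run$final_state,
                        chi = chi, seed = seed, params = params),
                   class = "abm_run")
  if (noise) out$noisy_clouds <- observe_with_noise(out)$clouds
  out
}

#' @export
print.abm_run <- function(x, ...) {
  cat(sprintf("abm_run: chi = %.3g, %d observations at t = %s ... %s\n",
              x$chi, length(x$times), format(x$times[1]),
              format(x$times[length(x$times)])))
  invisible(x)
}

#' Apply misclassification noise to the observations of a run
#'
#' Produces the noisy counterpart of a run's macrophage observations,
#' matched to the same simulation: at every observation each tumor cell
#' (viable or necrotic) is independently mislabeled as a macrophage with
#' probability `p`.
#'
#' @param run an `abm_run`.
#' @param p mislabeling probability; defaults to the run's `mislabel_p`.
#' @param seed optional seed; defaults to a seed derived from the run seed.
#' @return the run with `clouds` replaced by noisy clouds.
#' @export
observe_with_noise <- function(run, p = run$params$mislabel_p, seed = NULL) {
  if (is.null(seed)) seed <- derive_seed(run$seed, 999983L)
  noisy <- lapply(seq_along(run$clouds), function(k) {
    add_misclassification_noise(run$clouds[[k]], run$tumor_clouds[[k]],
                                p = p, seed = derive_seed(seed, k),
                                label = "macrophage")
  })
  out <- run
  out$clouds <- noisy
  out$noisy <- TRUE
  out
}

#' Time for the mean macrophage radial distance to halve
#'
#' Infiltration summary of a run: the first observation time at which the
#' mean distance of the macrophages from the tumor-cell centroid falls to
#' half its initial value, linearly interpolated between observations;
#' `Inf` if it never does.
#'
#' @param run an `abm_run`.
#' @return time in simulation units, possibly `Inf`.
#' @export
infiltration_half_time <- function(run) {
  center <- colMeans(run$tumor_clouds[[1]]$points)
  mean_r <- vapply(run$clouds, function(cl) {
    mean(sqrt((cl$points[, 1] - center[1])^2 +
                (cl$points[, 2] - center[2])^2))
  }, numeric(1))
  target <- mean_r[1] / 2
  below <- which(mean_r <= target)
  if (length(below) == 0L) return(Inf)
  k <- below[1]
  if (k == 1L) return(run$times[1])
  t0 <- run$times[k - 1]; t1 <- run$times[k]
  r0 <- mean_r[k - 1]; r1 <- mean_r[k]
  t0 + (r0 - target) / (r0 - r1) * (t1 - t0)
}
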