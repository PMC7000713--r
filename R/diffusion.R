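#' Gridded spatial domain for nutrient transport
#'
#' A regular rectangular grid of square cells (cell-centered coordinates,
#' row 1 / column 1 at the north-west corner) with a land mask and a mask
#' of fixed-concentration source cells (e.g. a river floodplain that
#' resupplies the nutrient).  Source cells must be a subset of land cells.
#'
#' @param nx,ny Cell counts in x (columns) and y (rows); each >= 3.
#' @param dx Cell size in km (> 0).
#' @param land_mask Logical `ny x nx` matrix, `TRUE` = land.  Default: all
#'   land.
#' @param source_mask Logical `ny x nx` matrix, `TRUE` = source cell.
#'   Default: no sources (a domain without sources supports transient
#'   stepping but not a steady-state solve).
#' @return An object of class `grid_domain`.
#' @export
grid_domain <- function(nx, ny, dx, land_mask = NULL, source_mask = NULL) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 3 || ny < 3) stop("'nx' and 'ny' must each be >= 3")
  if (!is.numeric(dx) || dx <= 0) stop("'dx' must be > 0")
  if (is.null(land_mask)) land_mask <- matrix(TRUE, ny, nx)
  if (is.null(source_mask)) source_mask <- matrix(FALSE, ny, nx)
  storage.mode(land_mask) <- "logical"
  storage.mode(source_mask) <- "logical"
  if (!identical(dim(land_mask), c(ny, nx)) ||
      !identical(dim(source_mask), c(ny, nx)))
    stop("masks must be ny x nx matrices")
  if (any(source_mask & !land_mask))
    stop("source cells must be a subset of land cells")
  structure(list(nx = nx, ny = ny, dx = dx, land_mask = land_mask,
                 source_mask = source_mask),
            class = "grid_domain")
}

#' Diffusion-loss simulation configuration
#'
#' Parameters of the steady-state problem
#' \eqn{\partial P/\partial t = \nabla \cdot (\Phi \nabla P) - \lambda P}
#' with Dirichlet sources and no-flux land boundaries.  The default loss
#' rate gives a decay length \eqn{\sqrt{\Phi/\lambda} = 1000} km at
#' \eqn{\Phi = 4.4} km^2 yr^-1, i.e. basin-scale fertility gradients.
#'
#' @param phi Lateral diffusivity in km^2 yr^-1: a scalar or an `ny x nx`
#'   per-cell field (>= 0 everywhere).
#' @param loss_rate First-order nutrient loss \eqn{\lambda} in yr^-1 (> 0;
#'   default 4.4e-6).
#' @param source_concentration Fixed concentration at source cells
#'   (arbitrary units, default 1).
#' @param dt Explicit time step in yr, or `"auto"` (0.2 dx^2 / max(phi),
#'   capped at 0.1 / loss_rate).
#' @param tolerance Convergence criterion: maximum relative per-cell change
#'   over one explicit step (default 1e-8).
#' @param max_steps Iteration cap for explicit stepping (default 5e5).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(phi = 4.4, loss_rate = 4.4e-6,
                       source_concentration = 1, dt = "auto",
                       tolerance = 1e-8, max_steps = 500000L) {
  if (any(!is.finite(phi)) || any(phi < 0)) stop("'phi' must be >= 0 everywhere")
  if (!is.finite(loss_rate) || loss_rate <= 0) stop("'loss_rate' must be > 0")
  if (!is.finite(source_concentration) || source_concentration <= 0)
    stop("'source_concentration' must be > 0")
  if (!identical(dt, "auto") && (!is.numeric(dt) || dt <= 0))
    stop("'dt' must be \"auto\" or a positive number")
  if (!is.finite(tolerance) || tolerance <= 0) stop("'tolerance' must be > 0")
  structure(list(phi = phi, loss_rate = loss_rate,
                 source_concentration = source_concentration, dt = dt,
                 tolerance = tolerance, max_steps = as.integer(max_steps)),
            class = "sim_config")
}

# per-cell diffusivity field as an ny x nx matrix
.phi_field <- function(domain, config) {
  if (is.matrix(config$phi)) {
    if (!identical(dim(config$phi), c(domain$ny, domain$nx)))
      stop("per-cell 'phi' must be an ny x nx matrix")
    config$phi
  } else matrix(config$phi, domain$ny, domain$nx)
}

.auto_dt <- function(domain, config, Dmax) {
  cap <- 0.1 / config$loss_rate
  if (Dmax > 0) min(0.2 * domain$dx^2 / Dmax, cap) else cap
}

#' Advance the explicit diffusion-loss integrator
#'
#' One or more forward-Euler steps of the 5-point finite-difference
#' discretization, with no-flux conditions at land/non-land interfaces and
#' domain edges and source cells (if any) held at the configured
#' concentration.  Exposed so transient properties (e.g. mass conservation
#' with zero loss and no sources) can be checked directly.
#'
#' @param domain A [grid_domain()].
#' @param config A [sim_config()].
#' @param field Initial `ny x nx` concentration field (default: zeros with
#'   sources at `source_concentration`).
#' @param n_steps Number of steps to take.
#' @param loss_rate Loss rate override; pass 0 for pure diffusion.
#' @return The updated `ny x nx` field, with attribute `max_rel_change`
#'   from the final step.
#' @export
step_diffusion <- function(domain, config, field = NULL, n_steps = 1,
                           loss_rate = config$loss_rate) {
  stopifnot(inherits(domain, "grid_domain"), inherits(config, "sim_config"))
  ny <- domain$ny; nx <- domain$nx
  land <- domain$land_mask; src <- domain$source_mask
  D <- .phi_field(domain, config)
  D[!land] <- 0
  Dmax <- max(D)
  dt <- if (identical(config$dt, "auto")) .auto_dt(domain, config, Dmax)
        else config$dt
  # explicit stability: dt * (4 Dmax / dx^2 + lambda) <= 1
  if (dt * (4 * Dmax / domain$dx^2 + loss_rate) > 1 + 1e-12)
    stop("explicit time step dt = ", dt, " exceeds the stability bound")
  if (is.null(field)) {
    field <- matrix(0, ny, nx)
    field[src] <- config$source_concentration
  }
  stopifnot(identical(dim(field), c(ny, nx)))
  inv_dx2 <- 1 / domain$dx^2
  interior <- land & !src
  floor_p <- 1e-6 * config$source_concentration
  P <- field
  P[!land] <- 0
  for (s in seq_len(n_steps)) {
    dP <- matrix(0, ny, nx)
    # vertical neighbours (rows i, i+1)
    Df <- 0.5 * (D[-ny, ] + D[-1, ])
    Df[!(land[-ny, ] & land[-1, ])] <- 0
    fl <- Df * (P[-1, ] - P[-ny, ]) * inv_dx2
    dP[-ny, ] <- dP[-ny, ] + fl
    dP[-1, ] <- dP[-1, ] - fl
    # horizontal neighbours (cols j, j+1)
    Df <- 0.5 * (D[, -nx] + D[, -1])
    Df[!(land[, -nx] & land[, -1])] <- 0
    fl <- Df * (P[, -1] - P[, -nx]) * inv_dx2
    dP[, -nx] <- dP[, -nx] + fl
    dP[, -1] <- dP[, -1] - fl
    dP <- dP - loss_rate * P
    Pn <- P
    Pn[interior] <- P[interior] + dt * dP[interior]
    Pn[src] <- config$source_concentration
    rel <- abs(Pn[interior] - P[interior]) / pmax(abs(Pn[interior]), floor_p)
    P <- Pn
  }
  attr(P, "max_rel_change") <- if (any(interior)) max(rel, 0) else 0
  attr(P, "dt") <- dt
  P
}

#' Solve the steady-state diffusion-loss equation
#'
#' Computes the steady state of
#' \eqn{\nabla \cdot (\Phi \nabla P) - \lambda P = 0} on land cells, with
#' \eqn{P} fixed at the source concentration on source cells (Dirichlet)
#' and no-flux conditions at land/non-land interfaces and domain edges.
#'
#' Two solution branches are provided: `"direct"` (default) assembles the
#' sparse 5-point system and solves it exactly, and `"explicit"` integrates
#' forward in time until the maximum relative per-cell change in one step
#' falls below `config$tolerance`.  The two agree to well within the
#' explicit tolerance; the direct branch is used for production sweeps.
#'
#' @param domain A [grid_domain()] with at least one source cell.
#' @param config A [sim_config()].
#' @param method `"direct"` or `"explicit"`.
#' @return An object of class `steady_state_result` with fields
#'   `concentration` (`ny x nx`; `NA` off land), `iterations`, `converged`.
#' @export
solve_steady_state <- function(domain, config, method = c("direct", "explicit")) {
  stopifnot(inherits(domain, "grid_domain"), inherits(config, "sim_config"))
  method <- match.arg(method)
  if (!any(domain$source_mask))
    stop("steady-state solve requires at least one source cell")
  if (method == "direct") {
    res <- .solve_direct(domain, config)
  } else {
    res <- .solve_explicit(domain, config)
  }
  # maximum principle: steady state is bounded by [0, source_concentration]
  conc <- res$concentration[domain$land_mask]
  tol <- 1e-9 * config$source_concentration
  if (any(conc < -tol) || any(conc > config$source_concentration + tol))
    warning("maximum principle violated beyond numerical tolerance")
  res
}

.solve_direct <- function(domain, config) {
  ny <- domain$ny; nx <- domain$nx
  land <- domain$land_mask; src <- domain$source_mask
  D <- .phi_field(domain, config)
  inv_dx2 <- 1 / domain$dx^2
  unknown <- land & !src
  n_u <- sum(unknown)
  P <- matrix(NA_real_, ny, nx)
  P[src] <- config$source_concentration
  P[land & !src] <- 0
  if (n_u == 0)
    return(structure(list(concentration = P, iterations = 0L,
                          converged = TRUE), class = "steady_state_result"))
  uid <- matrix(0L, ny, nx)
  uid[unknown] <- seq_len(n_u)
  lin <- which(unknown)
  ci <- ((lin - 1L) %% ny) + 1L
  cj <- ((lin - 1L) %/% ny) + 1L
  diag_v <- rep(-config$loss_rate, n_u)
  rhs <- numeric(n_u)
  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    ni <- ci + d[1]; nj <- cj + d[2]
    ok <- ni >= 1L & ni <= ny & nj >= 1L & nj <= nx
    nb <- (nj[ok] - 1L) * ny + ni[ok]
    is_land <- land[nb]
    cells <- which(ok)[is_land]          # indices into the unknown list
    nb <- nb[is_land]
    if (!length(cells)) next
    Df <- 0.5 * (D[lin[cells]] + D[nb]) * inv_dx2
    diag_v[cells] <- diag_v[cells] - Df
    nb_u <- uid[nb]
    fixed <- nb_u == 0L                   # neighbour is a source cell
    if (any(!fixed)) {
      ti <- c(ti, cells[!fixed])
      tj <- c(tj, nb_u[!fixed])
      tv <- c(tv, Df[!fixed])
    }
    if (any(fixed))
      rhs[cells[fixed]] <- rhs[cells[fixed]] -
        Df[fixed] * config$source_concentration
  }
  A <- Matrix::sparseMatrix(i = c(seq_len(n_u), ti), j = c(seq_len(n_u), tj),
                            x = c(diag_v, tv), dims = c(n_u, n_u))
  x <- as.numeric(Matrix::solve(A, rhs))
  # the system is an M-matrix, so the bounds can only fail by roundoff;
  # clamp within tolerance (genuine violations are warned about upstream)
  tol <- 1e-9 * config$source_concentration
  x[x > -tol & x < 0] <- 0
  hi <- config$source_concentration
  x[x > hi & x < hi + tol] <- hi
  P[unknown] <- x
  structure(list(concentration = P, iterations = 0L, converged = TRUE),
            class = "steady_state_result")
}

.solve_explicit <- function(domain, config) {
  field <- NULL
  iterations <- 0L
  converged <- FALSE
  chunk <- 200L
  while (iterations < config$max_steps) {
    n <- min(chunk, config$max_steps - iterations)
    field <- step_diffusion(domain, config, field, n_steps = n)
    iterations <- iterations + n
    if (attr(field, "max_rel_change") < config$tolerance) {
      converged <- TRUE
      break
    }
  }
  P <- matrix(NA_real_, domain$ny, domain$nx)
  P[domain$land_mask] <- field[domain$land_mask]
  structure(list(concentration = P, iterations = iterations,
                 converged = converged), class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  conc <- x$concentration[!is.na(x$concentration)]
  cat(sprintf(
    "Steady-state field: %d land cells, mean = %.4g, range = [%.4g, %.4g], %s (%d iterations)\n",
    length(conc), mean(conc), min(conc), max(conc),
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Scenario concentration as a percentage of baseline
#'
#' Compares two steady states on the same domain by the area mean of
#' concentration over non-source land cells: `100 * mean(result) /
#' mean(baseline)`.
#'
#' @param result,baseline [solve_steady_state()] results on `domain`.
#' @param domain The shared [grid_domain()].
#' @return Percentage of the baseline mean concentration.
#' @export
percent_of_baseline <- function(result, baseline, domain) {
  stopifnot(inherits(result, "steady_state_result"),
            inherits(baseline, "steady_state_result"),
            inherits(domain, "grid_domain"))
  cells <- domain$land_mask & !domain$source_mask
  if (!any(cells)) stop("no non-source land cells to evaluate")
  if (!identical(dim(result$concentration), dim(baseline$concentration)) ||
      !identical(dim(result$concentration), dim(domain$land_mask)))
    stop("results and domain have mismatched dimensions")
  mb <- mean(baseline$concentration[cells])
  if (mb <= 0) stop("baseline mean concentration is zero")
  100 * mean(result$concentration[cells]) / mb
}

#' Size-threshold extinction experiment on the nutrient field
#'
#' For each body-size threshold: remove all cohorts above it, recompute the
#' community diffusivity \eqn{\Phi}, solve the steady-state nutrient field
#' at that \eqn{\Phi}, and express the mean concentration as a percentage
#' of the full-community baseline.  Reproduces the monotone decline of soil
#' fertility as the fauna is downsized.
#'
#' @param domain A [grid_domain()].
#' @param config A [sim_config()]; its `phi` is replaced per scenario by
#'   the community value.
#' @param community The full (baseline) [herbivore_community()].
#' @param model A (typically calibrated) [diffusivity_model()].
#' @param thresholds Body-mass thresholds in kg; processed in descending
#'   order.
#' @param method Solver branch, passed to [solve_steady_state()].
#' @return A data frame with columns `threshold_kg`, `phi_km2_yr`,
#'   `percent_of_baseline`, one row per threshold (descending).
#' @export
run_threshold_experiment <- function(domain, config, community, model,
                                     thresholds, method = "direct") {
  stopifnot(inherits(community, "herbivore_community"),
            inherits(model, "diffusivity_model"))
  thresholds <- sort(as.numeric(thresholds), decreasing = TRUE)
  cfg_at <- function(phi) {
    cfg <- config
    cfg$phi <- phi
    cfg
  }
  phi0 <- community_diffusivity(community, model)
  baseline <- solve_steady_state(domain, cfg_at(phi0), method = method)
  rows <- lapply(thresholds, function(th) {
    phi <- community_diffusivity(apply_size_threshold(community, th), model)
    res <- solve_steady_state(domain, cfg_at(phi), method = method)
    data.frame(threshold_kg = th, phi_km2_yr = phi,
               percent_of_baseline = percent_of_baseline(res, baseline, domain))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
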