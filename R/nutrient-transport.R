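#' Herbivore community (cohort table)
#'
#' A community is a table of cohorts, each a (body mass, population
#' density) pair.  Masses need not be unique; zero densities are allowed.
#'
#' @param mass Body masses in kg (> 0).
#' @param density Population densities in individuals km^-2 (>= 0),
#'   recycled to the length of `mass`.
#' @param label Scenario name.
#' @return An object of class `herbivore_community`: a data frame with
#'   columns `mass_kg` and `density_per_km2` and a `label` attribute.
#' @export
herbivore_community <- function(mass = numeric(), density = numeric(),
                                label = "") {
  mass <- as.numeric(mass)
  if (length(mass) > 0) {
    density <- rep_len(as.numeric(density), length(mass))
    if (any(!is.finite(mass)) || any(mass <= 0))
      stop("cohort masses must be finite and > 0")
    if (any(!is.finite(density)) || any(density < 0))
      stop("cohort densities must be finite and >= 0")
  } else density <- numeric()
  out <- data.frame(mass_kg = mass, density_per_km2 = density)
  attr(out, "label") <- as.character(label)
  class(out) <- c("herbivore_community", "data.frame")
  out
}

#' Allometric nutrient-diffusivity model
#'
#' Per-cohort lateral nutrient diffusivity scales with herbivore body mass
#' as \eqn{\phi(m) = k\, m^{1.17}} (km^2 yr^-1): larger animals move
#' nutrients much farther per unit time through ingestion, transport and
#' defecation.  Community diffusivity aggregates cohorts as a
#' density-weighted sum (see [community_diffusivity()]); `reference_phi`
#' records the community-level diffusivity the model is calibrated to
#' reproduce (4.4 km^2 yr^-1 for the intact Pleistocene-like community).
#'
#' @param k Normalization, km^2 yr^-1 kg^-(exponent) per unit density
#'   weight (> 0, or 0 for degenerate test models).
#' @param exponent Mass-scaling exponent (default 1.17, > 0).
#' @param reference_phi Reference community diffusivity in km^2 yr^-1
#'   (default 4.4).
#' @param density_weighting Logical; weight cohort contributions by
#'   density / `reference_density`? (default `TRUE`).
#' @param reference_density Density scale in individuals km^-2 used to make
#'   the weights dimensionless (default 1).
#' @return An object of class `diffusivity_model`.
#' @export
diffusivity_model <- function(k = 1, exponent = 1.17, reference_phi = 4.4,
                              density_weighting = TRUE,
                              reference_density = 1) {
  if (!is.finite(k) || k < 0) stop("'k' must be finite and >= 0")
  if (!is.finite(exponent) || exponent <= 0) stop("'exponent' must be > 0")
  if (!is.finite(reference_density) || reference_density <= 0)
    stop("'reference_density' must be > 0")
  structure(list(k = k, exponent = exponent, reference_phi = reference_phi,
                 density_weighting = isTRUE(density_weighting),
                 reference_density = reference_density),
            class = "diffusivity_model")
}

#' Per-cohort nutrient diffusivity
#'
#' @param mass Body mass in kg (> 0, vectorized).
#' @param model A [diffusivity_model()].
#' @return Diffusivity `k * mass^exponent` in km^2 yr^-1.
#' @export
cohort_diffusivity <- function(mass, model = diffusivity_model()) {
  stopifnot(inherits(model, "diffusivity_model"))
  if (any(!is.finite(mass)) || any(mass <= 0)) stop("'mass' must be > 0")
  model$k * mass^model$exponent
}

#' Community-level lateral nutrient diffusivity
#'
#' Aggregates per-cohort diffusivities into the community-level scalar
#' \eqn{\Phi = \sum_i w_i\, k\, m_i^{1.17}}, with weights
#' `w_i = density_i / reference_density` when density weighting is on and
#' `w_i = 1` otherwise.  The linear density-weighted sum preserves the
#' per-cohort mass exponent and makes calibration to a reference
#' \eqn{\Phi} well-posed; an empty community has \eqn{\Phi = 0}.
#'
#' @param community A [herbivore_community()].
#' @param model A [diffusivity_model()].
#' @return \eqn{\Phi} in km^2 yr^-1.
#' @export
community_diffusivity <- function(community, model = diffusivity_model()) {
  stopifnot(inherits(community, "herbivore_community"),
            inherits(model, "diffusivity_model"))
  if (nrow(community) == 0) return(0)
  w <- if (model$density_weighting)
    community$density_per_km2 / model$reference_density
  else rep(1, nrow(community))
  sum(w * cohort_diffusivity(community$mass_kg, model))
}

#' Calibrate the diffusivity normalization to a target community value
#'
#' Rescales `k` so that [community_diffusivity()] of the given community
#' equals `target_phi` exactly (the aggregation is linear in `k`).
#'
#' @param community A [herbivore_community()] with nonzero aggregate
#'   diffusivity weight.
#' @param target_phi Target community diffusivity in km^2 yr^-1 (> 0);
#'   defaults to the model's `reference_phi`.
#' @param model A [diffusivity_model()] providing exponent and weighting.
#' @return The calibrated [diffusivity_model()].
#' @export
calibrate_model <- function(community, target_phi = model$reference_phi,
                            model = diffusivity_model()) {
  stopifnot(inherits(community, "herbivore_community"),
            inherits(model, "diffusivity_model"))
  if (!is.finite(target_phi) || target_phi <= 0)
    stop("'target_phi' must be finite and > 0")
  unit <- model
  unit$k <- 1
  phi1 <- community_diffusivity(community, unit)
  if (phi1 <= 0)
    stop("cannot calibrate: community has zero aggregate diffusivity")
  out <- model
  out$k <- target_phi / phi1
  out$reference_phi <- target_phi
  out
}

#' Remove all cohorts above a body-size threshold
#'
#' Simulates a size-selective extinction: a 5000 kg threshold removes all
#' animals heavier than 5000 kg.  The input community is not modified.
#'
#' @param community A [herbivore_community()].
#' @param threshold Body-mass threshold in kg (>= 0; `Inf` keeps everything).
#' @return The thresholded [herbivore_community()].
#' @export
apply_size_threshold <- function(community, threshold) {
  stopifnot(inherits(community, "herbivore_community"))
  if (!is.numeric(threshold) || is.na(threshold) || threshold < 0)
    stop("'threshold' must be a single number >= 0")
  keep <- community$mass_kg <= threshold
  out <- community[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "label") <- attr(community, "label")
  class(out) <- c("herbivore_community", "data.frame")
  out
}

#' Synthetic Pleistocene-like herbivore community
#'
#' The packaged reference fauna: cohort masses log-spaced from 10 kg up to
#' 10,000 kg (the size of the largest terrestrial Pleistocene herbivore)
#' with densities falling off as mass^-0.75, normalized to a total
#' community density.  This is an explicitly synthetic stand-in with the
#' statistical structure of a pre-extinction megafauna assemblage, not a
#' real species list.
#'
#' @param n_cohorts Number of cohorts (default 20).
#' @param m_min,m_max Smallest and largest cohort masses in kg
#'   (defaults 10 and 10,000).
#' @param density_exponent Density-mass exponent (default 0.75).
#' @param total_density Total community density in individuals km^-2
#'   (default 10).
#' @return A [herbivore_community()] labelled `"pleistocene-synthetic"`.
#' @export
pleistocene_community <- function(n_cohorts = 20, m_min = 10, m_max = 1e4,
                                  density_exponent = 0.75,
                                  total_density = 10) {
  generate_animal_community(n_cohorts = n_cohorts, m_min = m_min,
                            m_max = m_max,
                            density_exponent = density_exponent,
                            total_density = total_density,
                            label = "pleistocene-synthetic")
}
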