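# Synthetic farm survey with a controlled Spearman correlation structure
# between farm-practice indicators and forest carbon loss in the farm
# neighbourhood. Only rank (Spearman) structure is asserted downstream, so
# the correlations are induced by a Gaussian copula: a single latent
# "forest-loss exposure" factor plus monotone marginal transforms, which
# preserve Spearman correlations exactly in population.

#' Default indicator effect sizes
#'
#' Target Spearman correlations between each farm indicator and the
#' grazing-attributed forest C loss in the farm neighbourhood. Signs and
#' magnitudes mirror the observed pattern: herd size correlates positively
#' with forest loss, while intensification indicators (improved cattle,
#' milk yield, fodder and concentrate use) correlate negatively.
#'
#' @return named numeric vector of Spearman rho targets.
#' @export
default_effect_sizes <- function() {
  c(n_cattle = 0.15, n_improved_cattle = -0.37, milk_yield = -0.26,
    fodder_fraction_diet = -0.39, concentrate_supplementation = -0.21,
    area_fodder = -0.34, farm_size = 0.10, fuelwood_extraction = 0.20)
}

#' Generate a synthetic farm survey
#'
#' Farms carry the indicators of the 216-farm survey structure: herd size,
#' improved dairy cattle, milk yield, fodder fraction of the diet,
#' concentrate supplementation, fodder area, farm size and fuelwood
#' extraction, plus a farm type in \{small, large, intensified\} and a
#' location. A latent exposure variable (`c_loss_neigh`, kg C ha⁻¹ yr⁻¹)
#' represents grazing-attributed forest C loss around the farm; each
#' indicator attains its target Spearman correlation with it via a
#' single-factor Gaussian copula.
#'
#' @param config a [landscape_config()] (supplies the seed and, with
#'   `landscape`, the georeference).
#' @param n_farms number of farms (>= 30).
#' @param effect_sizes named vector of target Spearman correlations
#'   (indicator vs exposure), all strictly inside (-1, 1). Names must be a
#'   subset of [default_effect_sizes()]'s names; unnamed indicators default
#'   to 0.
#' @param landscape optional `landscape`; farm locations are then drawn on
#'   non-forest pixels of its grid.
#' @param exposure optional numeric vector (length `n_farms`) of real
#'   per-farm exposure values (e.g. neighbourhood means of an attributed
#'   loss layer); its normal scores then drive the copula, coupling the
#'   survey to the landscape.
#' @return a `data.frame` with class `farm_survey`.
#' @export
generate_farm_survey <- function(config, n_farms = 216,
                                 effect_sizes = default_effect_sizes(),
                                 landscape = NULL, exposure = NULL) {
  if (!inherits(config, "landscape_config"))
    config <- do.call(landscape_config, config)
  if (n_farms < 30)
    stop("n_farms must be >= 30 for a usable correlation structure")
  base <- default_effect_sizes() * 0
  unknown <- setdiff(names(effect_sizes), names(base))
  if (length(unknown))
    stop("unknown indicator(s): ", paste(unknown, collapse = ", "))
  base[names(effect_sizes)] <- effect_sizes
  rho_s <- base
  if (any(abs(rho_s) >= 1)) stop("|rho| targets must be < 1")
  rho_p <- 2 * sin(pi * rho_s / 6)   # Spearman -> Pearson on the copula

  # implied (p+1)x(p+1) Gaussian correlation matrix of [Z, X_1..X_p]
  p <- length(rho_p)
  R <- diag(p + 1)
  R[1, -1] <- rho_p; R[-1, 1] <- rho_p
  R[-1, -1][upper.tri(diag(p))] <- (rho_p %o% rho_p)[upper.tri(diag(p))]
  R[-1, -1][lower.tri(diag(p))] <- t(R[-1, -1])[lower.tri(diag(p))]
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("requested rank-correlation targets are not jointly attainable ",
         "(implied correlation matrix is not positive semidefinite)")

  set.seed(child_seed(config$seed, "survey"))
  if (!is.null(exposure)) {
    if (length(exposure) != n_farms)
      stop("`exposure` must have length n_farms")
    z <- stats::qnorm(rank(exposure, ties.method = "average") /
                        (n_farms + 1))
  } else {
    z <- stats::rnorm(n_farms)
  }
  X <- vapply(rho_p, function(r)
    r * z + sqrt(1 - r^2) * stats::rnorm(n_farms), numeric(n_farms))
  colnames(X) <- names(rho_s)
  U <- stats::pnorm(X)

  n_cattle <- pmax(1, round(stats::qlnorm(U[, "n_cattle"], log(5), 0.6)))
  n_improved <- round(stats::qlnorm(U[, "n_improved_cattle"], log(2), 0.8))
  n_improved <- pmin(n_improved, n_cattle)
  milk <- stats::qlnorm(U[, "milk_yield"], log(1600), 0.45)
  fodder <- stats::qbeta(U[, "fodder_fraction_diet"], 2, 3)
  conc <- stats::qgamma(U[, "concentrate_supplementation"],
                        shape = 1.5, scale = 120)
  area_fodder <- stats::qlnorm(U[, "area_fodder"], log(0.5), 0.7)
  farm_size <- area_fodder +
    stats::qlnorm(U[, "farm_size"], log(1.2), 0.6)
  fuelwood <- stats::qgamma(U[, "fuelwood_extraction"],
                            shape = 2, scale = 900)

  if (is.null(exposure))
    exposure <- stats::qlnorm(stats::pnorm(z), log(700), 0.5)

  # farm types: intensified = top tercile of the joint milk/fodder rank,
  # remainder split by farm size into large vs small
  score <- rank(milk) + rank(fodder)
  intens <- score >= stats::quantile(score, 2 / 3)
  type <- ifelse(intens, "intensified",
                 ifelse(farm_size > stats::median(farm_size[!intens]),
                        "large", "small"))
  if (length(unique(type)) < 3) {   # degenerate tie pattern at tiny n
    type[order(score, decreasing = TRUE)[1]] <- "intensified"
    type[order(farm_size, decreasing = TRUE)[1]] <- "large"
    type[order(farm_size)[1]] <- "small"
  }

  if (!is.null(landscape)) {
    fm <- landscape$forest_mask$values == 1
    idx <- which(!fm)
    if (!length(idx)) idx <- seq_along(fm)
    pick <- sample(idx, n_farms, replace = length(idx) < n_farms)
    ctr <- pixel_centers(landscape$forest_mask)
    cs <- landscape$forest_mask$cellsize
    x <- ctr$x[pick] + stats::runif(n_farms, -0.4, 0.4) * cs
    y <- ctr$y[pick] + stats::runif(n_farms, -0.4, 0.4) * cs
  } else {
    ext <- sqrt(config$pixel_area * 1e4) *
      c(config$grid_cols, config$grid_rows)
    x <- stats::runif(n_farms, 0, ext[1])
    y <- stats::runif(n_farms, 0, ext[2])
  }

  out <- data.frame(
    farm_id = seq_len(n_farms), farm_type = type, x = x, y = y,
    n_cattle = n_cattle, n_improved_cattle = n_improved,
    milk_yield = milk, fodder_fraction_diet = fodder,
    concentrate_supplementation = conc, area_fodder = area_fodder,
    farm_size = farm_size, fuelwood_extraction = fuelwood,
    c_loss_neigh = exposure, stringsAsFactors = FALSE)
  class(out) <- c("farm_survey", "data.frame")
  out
}

#' Write a farm survey as CSV
#' @param survey a `farm_survey` data.frame.
#' @param path output path.
#' @export
write_farm_survey <- function(survey, path) {
  utils::write.csv(as.data.frame(survey), path, row.names = FALSE)
  invisible(path)
}
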