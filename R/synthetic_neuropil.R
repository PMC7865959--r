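#' Synthetic spine populations and neuropil volumes
#'
#' The generator produces populations of dendritic spine heads with the
#' statistical structure measured in adult mouse CA1 stratum radiatum:
#' right-skewed head volumes on 0.004--0.300 um^3 with mean 0.066 um^3,
#' synaptic apposition surfaces (SAS) coupled to volume through a surface
#' scaling law, and a small fraction of shaft synapses. Spine heads are
#' spheres carrying an oriented apposition cap; the population is the ground
#' truth against which the 2D stereological estimators are validated.
#'
#' @name synthetic_neuropil
#' @keywords internal
NULL

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Mean of a doubly truncated distribution, by numerical integration.
.trunc_mean <- function(dens, pfun, lo, hi, ...) {
  Z <- pfun(hi, ...) - pfun(lo, ...)
  stats::integrate(function(x) x * dens(x, ...) / Z, lo, hi,
                   rel.tol = 1e-10)$value
}

#' Configuration of the synthetic spine generator
#'
#' Builds the distributional configuration used by [generate_population()].
#' Head volumes follow a lognormal (default) or gamma distribution truncated
#' to `[v_min, v_max]`; the free location parameter is solved numerically so
#' that the truncated mean equals `v_mean`. SAS areas follow the surface
#' scaling law `SAS = c * V^(2/3) * exp(eps)`, `eps ~ N(0, sas_sigma^2)`,
#' with `c` solved so that the expected SAS equals `sas_mean`.
#'
#' Defaults reproduce the measured CA1 conditions: volume support
#' `[0.004, 0.300]` um^3 with mean 0.066 um^3 (`v_sdlog = 0.85` sets the
#' right skew; under it ~80\% of volumes fall below 0.1 um^3), mean SAS
#' 0.089 um^2, and `sas_sigma = 0.48`, which yields a Spearman rank
#' correlation between SAS and volume of about 0.73 at large n.
#'
#' @param v_min,v_max Truncation bounds of the head-volume distribution, um^3.
#' @param v_mean Target mean head volume after truncation, um^3.
#' @param v_family `"lognormal"` (default) or `"gamma"`.
#' @param v_sdlog Log-scale standard deviation (lognormal family).
#' @param v_shape Shape parameter (gamma family).
#' @param sas_mean Target mean SAS, um^2.
#' @param sas_sigma Standard deviation of the multiplicative log-noise
#'   coupling SAS to volume.
#' @param shaft_fraction Fraction of synapses sitting on dendritic shafts
#'   rather than spine heads.
#' @param shape_thresholds Named numeric vector `c(thin = ..., mushroom =
#'   ...)`: heads below the first volume are labelled `"thin"`, at or above
#'   the second `"mushroom"`, `"stubby"` in between. Metadata only; the
#'   labels carry no geometric consequence.
#' @return An object of class `"spine_params"`: the validated configuration
#'   with the solved location parameter (`v_meanlog` or `v_rate`) and SAS
#'   scale `sas_c` attached.
#' @examples
#' p <- spine_params()
#' p$sas_c
#' @export
spine_params <- function(v_min = 0.004, v_max = 0.300, v_mean = 0.066,
                         v_family = c("lognormal", "gamma"),
                         v_sdlog = 0.85, v_shape = 1.5,
                         sas_mean = 0.089, sas_sigma = 0.48,
                         shaft_fraction = 0.07,
                         shape_thresholds = c(thin = 0.04, mushroom = 0.08)) {
  v_family <- match.arg(v_family)
  if (!(v_min >= 0 && v_max > v_min)) {
    stop("invalid truncation interval [v_min, v_max]", call. = FALSE)
  }
  if (!(v_mean > v_min && v_mean < v_max)) {
    stop("infeasible configuration: v_mean must lie strictly inside ",
         "[v_min, v_max]", call. = FALSE)
  }
  if (sas_sigma < 0 || sas_mean <= 0) {
    stop("invalid SAS configuration", call. = FALSE)
  }
  if (shaft_fraction < 0 || shaft_fraction >= 1) {
    stop("shaft_fraction must be in [0, 1)", call. = FALSE)
  }

  p <- list(v_min = v_min, v_max = v_max, v_mean = v_mean,
            v_family = v_family, v_sdlog = v_sdlog, v_shape = v_shape,
            sas_mean = sas_mean, sas_sigma = sas_sigma,
            shaft_fraction = shaft_fraction,
            shape_thresholds = shape_thresholds)

  # solve the free location parameter for the truncated mean, bracketing
  # over a grid first: far outside the bracket the truncation mass
  # underflows and the objective is not finite
  solve_loc <- function(f, grid) {
    vals <- vapply(grid, function(g) {
      tryCatch(f(g), error = function(e) NaN)
    }, numeric(1))
    ok <- is.finite(vals)
    sign_change <- which(ok[-1] & ok[-length(ok)] &
                           vals[-1] * vals[-length(vals)] <= 0)
    if (length(sign_change) == 0) stop("no sign change on the search grid")
    i <- sign_change[1]
    stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-10)$root
  }
  solved <- tryCatch({
    if (v_family == "lognormal") {
      f <- function(ml) {
        .trunc_mean(stats::dlnorm, stats::plnorm, v_min, v_max,
                    meanlog = ml, sdlog = v_sdlog) - v_mean
      }
      list(v_meanlog = solve_loc(f, seq(-12, 2, by = 0.5)))
    } else {
      f <- function(lrate) {
        .trunc_mean(stats::dgamma, stats::pgamma, v_min, v_max,
                    shape = v_shape, rate = exp(lrate)) - v_mean
      }
      list(v_rate = exp(solve_loc(f, seq(-5, 10, by = 0.5))))
    }
  }, error = function(e) {
    stop("infeasible configuration: cannot calibrate the volume ",
         "distribution to the requested truncated mean (", conditionMessage(e),
         ")", call. = FALSE)
  })
  p <- c(p, solved)

  # SAS scale so that E[c * V^(2/3) * exp(eps)] = sas_mean
  ev23 <- if (v_family == "lognormal") {
    Z <- stats::plnorm(v_max, p$v_meanlog, v_sdlog) -
      stats::plnorm(v_min, p$v_meanlog, v_sdlog)
    stats::integrate(function(x) {
      x^(2 / 3) * stats::dlnorm(x, p$v_meanlog, v_sdlog) / Z
    }, v_min, v_max, rel.tol = 1e-10)$value
  } else {
    Z <- stats::pgamma(v_max, v_shape, p$v_rate) -
      stats::pgamma(v_min, v_shape, p$v_rate)
    stats::integrate(function(x) {
      x^(2 / 3) * stats::dgamma(x, v_shape, p$v_rate) / Z
    }, v_min, v_max, rel.tol = 1e-10)$value
  }
  p$sas_c <- sas_mean / (ev23 * exp(sas_sigma^2 / 2))
  class(p) <- "spine_params"
  p
}

# Inverse-CDF sampler of the truncated head-volume distribution.
.sample_volumes <- function(n, p) {
  u <- stats::runif(n)
  if (p$v_family == "lognormal") {
    plo <- stats::plnorm(p$v_min, p$v_meanlog, p$v_sdlog)
    phi <- stats::plnorm(p$v_max, p$v_meanlog, p$v_sdlog)
    stats::qlnorm(plo + u * (phi - plo), p$v_meanlog, p$v_sdlog)
  } else {
    plo <- stats::pgamma(p$v_min, p$v_shape, p$v_rate)
    phi <- stats::pgamma(p$v_max, p$v_shape, p$v_rate)
    stats::qgamma(plo + u * (phi - plo), p$v_shape, p$v_rate)
  }
}

# Uniform random unit vectors.
.sample_axes <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(x = s * cos(phi), y = s * sin(phi), z = z)
}

#' Generate a synthetic spine population
#'
#' Draws `n` synapses: head volumes from the truncated distribution in
#' `params`, SAS areas from the coupled scaling law (clipped, where
#' necessary, to the spherical-cap bound `SAS <= 4 pi r^2`; the number of
#' clipped rows is recorded in the `"n_sas_clipped"` attribute), uniformly
#' random apposition-cap orientations, and a Bernoulli shaft-synapse flag.
#' Shaft synapses carry an SAS drawn from the same marginal but no head
#' (head volume and radius are `NA`). Positions are `NA` until the
#' population is placed by [place_in_volume()].
#'
#' @param n Number of synapses (>= 1).
#' @param params A [spine_params()] configuration.
#' @param seed Integer seed; identical seeds give identical populations.
#' @return A `data.frame` (class `"spine_table"`) with columns `spine_id`,
#'   `x`, `y`, `z`, `head_volume_um3`, `head_radius_um`, `sas_um2`,
#'   `axis_x`, `axis_y`, `axis_z`, `on_shaft`, `shape_class`.
#' @examples
#' pop <- generate_population(50, spine_params(), seed = 1)
#' mean(pop$head_volume_um3, na.rm = TRUE)
#' @export
generate_population <- function(n, params = spine_params(), seed = NULL) {
  stopifnot(inherits(params, "spine_params"))
  if (!(is.numeric(n) && length(n) == 1 && n >= 1 && n == round(n))) {
    stop("n must be a positive integer", call. = FALSE)
  }
  .with_seed(seed, {
    v <- .sample_volumes(n, params)
    eps <- stats::rnorm(n, 0, params$sas_sigma)
    sas <- params$sas_c * v^(2 / 3) * exp(eps)
    r <- sphere_radius_from_volume(v)
    cap_bound <- 4 * pi * r^2
    clipped <- sas > cap_bound
    sas[clipped] <- cap_bound[clipped]
    axes <- .sample_axes(n)
    on_shaft <- stats::runif(n) < params$shaft_fraction

    th <- params$shape_thresholds
    shape <- ifelse(v < th[["thin"]], "thin",
                    ifelse(v >= th[["mushroom"]], "mushroom", "stubby"))
    v[on_shaft] <- NA_real_
    r[on_shaft] <- NA_real_
    shape[on_shaft] <- NA_character_

    pop <- data.frame(
      spine_id = seq_len(n),
      x = NA_real_, y = NA_real_, z = NA_real_,
      head_volume_um3 = v,
      head_radius_um = r,
      sas_um2 = sas,
      axis_x = axes[, "x"], axis_y = axes[, "y"], axis_z = axes[, "z"],
      on_shaft = on_shaft,
      shape_class = shape,
      stringsAsFactors = FALSE
    )
    class(pop) <- c("spine_table", "data.frame")
    attr(pop, "n_sas_clipped") <- sum(clipped & !on_shaft)
    attr(pop, "params") <- params
    pop
  })
}

#' Place a spine population in a neuropil volume
#'
#' Assigns uniform random centres inside an axis-aligned box. By default
#' (`contain = TRUE`) centres are inset from every face by the head radius,
#' so spine heads lie wholly within the simulated tissue block, as
#' reconstructed heads do in a segmented volume (shaft synapses, having no
#' head, are inset by nothing); with `contain = FALSE` centres are uniform
#' over the full box and heads may poke through its faces, emulating an
#' unbounded medium. When `tolerance > 0`, placement is hard-core: any
#' candidate centre closer than `tolerance` to an already placed centre is
#' rejected and redrawn, up to `max_attempts` draws per spine.
#'
#' @param spines A spine table from [generate_population()].
#' @param extent Numeric length-3: box edge lengths `(Lx, Ly, Lz)`, um.
#' @param seed Integer seed; placement is deterministic given the seed.
#' @param tolerance Minimum pairwise centre distance, um (default 0: no
#'   hard-core constraint, touching heads allowed).
#' @param contain Keep whole heads inside the box (default) or allow them
#'   to cross its faces.
#' @param max_attempts Rejection-sampling budget per spine.
#' @return An object of class `"neuropil"`: a list with elements `spines`
#'   (the table with filled coordinates), `extent`, `true_density`
#'   (synapses per um^3, all synapses counted), `seed`, `tolerance`.
#' @examples
#' pop <- generate_population(20, spine_params(), seed = 2)
#' np <- place_in_volume(pop, extent = c(5, 5, 5), seed = 2)
#' np$true_density
#' @export
place_in_volume <- function(spines, extent, seed = NULL, tolerance = 0,
                            contain = TRUE, max_attempts = 10000) {
  stopifnot(is.data.frame(spines), length(extent) == 3, all(extent > 0))
  n <- nrow(spines)
  inset <- if (contain) {
    ifelse(is.na(spines$head_radius_um), 0, spines$head_radius_um)
  } else {
    rep(0, n)
  }
  if (any(2 * inset >= pmin(extent[1], extent[2], extent[3]))) {
    stop("density-infeasible: a spine head is larger than the volume extent",
         call. = FALSE)
  }
  .with_seed(seed, {
    xs <- numeric(n); ys <- numeric(n); zs <- numeric(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (a in seq_len(max_attempts)) {
        cx <- stats::runif(1, inset[i], extent[1] - inset[i])
        cy <- stats::runif(1, inset[i], extent[2] - inset[i])
        cz <- stats::runif(1, inset[i], extent[3] - inset[i])
        if (tolerance > 0 && i > 1) {
          j <- seq_len(i - 1)
          d2 <- (xs[j] - cx)^2 + (ys[j] - cy)^2 + (zs[j] - cz)^2
          if (min(d2) < tolerance^2) next
        }
        xs[i] <- cx; ys[i] <- cy; zs[i] <- cz
        ok <- TRUE
        break
      }
      if (!ok) {
        stop("density-infeasible: placement budget exhausted at spine ", i,
             call. = FALSE)
      }
    }
    spines$x <- xs; spines$y <- ys; spines$z <- zs
    out <- list(spines = spines,
                extent = as.numeric(extent),
                true_density = n / prod(extent),
                seed = seed,
                tolerance = tolerance)
    class(out) <- "neuropil"
    out
  })
}

#' @export
print.neuropil <- function(x, ...) {
  cat(sprintf(
    "Synthetic neuropil: %d synapses in %.3g x %.3g x %.3g um (%.1f um^3)\n",
    nrow(x$spines), x$extent[1], x$extent[2], x$extent[3], prod(x$extent)))
  cat(sprintf("  true density %.3f synapses/um^3; %d on shafts\n",
              x$true_density, sum(x$spines$on_shaft)))
  invisible(x)
}
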