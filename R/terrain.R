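# Ground models: flat, slip transition (friction drop after the 5 m run-in),
# and uneven terrain (seeded 1-D Perlin gradient-noise heightfield after the
# run-in, amplitude normalised to a height scale).

# Classic 1-D Perlin gradient noise with smoothstep fading.
perlin1d <- function(x, gradients, wavelength) {
  u <- x / wavelength
  i0 <- floor(u)
  t <- u - i0
  n <- length(gradients)
  g0 <- gradients[(as.integer(i0) %% n) + 1L]
  g1 <- gradients[(as.integer(i0 + 1) %% n) + 1L]
  fade <- t^3 * (t * (t * 6 - 15) + 10)
  (1 - fade) * g0 * t + fade * g1 * (t - 1)
}

#' Build a ground model
#'
#' All terrains start flat with the normal friction coefficient 0.8; after a
#' 5 m run-in the ground either turns slippery (`kind = "slip"`, friction
#' drops to `mu`) or uneven (`kind = "uneven"`, a seeded Perlin heightfield
#' of two octaves, amplitude-normalised so `max|h| = height_scale` and blended
#' in over 0.3 m so the height is exactly zero before the transition).
#'
#' @param kind `"flat"`, `"slip"` or `"uneven"`.
#' @param mu slippery-region friction coefficient, in `(0, 1]` (slip kind).
#' @param height_scale heightfield amplitude bound (m, >= 0; uneven kind).
#' @param seed integer seed for the heightfield gradients (uneven kind).
#' @param transition_x run-in length (m, default 5).
#' @param mu_normal friction before the transition (default 0.8).
#' @param x_max extent of the precomputed heightfield (m).
#' @return object of class `walker_terrain`.
#' @export
make_terrain <- function(kind = c("flat", "slip", "uneven"), mu = NULL,
                         height_scale = NULL, seed = NULL, transition_x = 5,
                         mu_normal = 0.8, x_max = 60) {
  kind <- match.arg(kind)
  t <- list(kind_name = kind, mu0 = mu_normal, mu1 = mu_normal,
            transition_x = transition_x, height_scale = 0, seed = seed,
            hx0 = transition_x, hdx = 0.01, hgrid = numeric(0))
  if (kind == "flat") {
    t$kind <- 0L
  } else if (kind == "slip") {
    if (is.null(mu)) stop("slip terrain needs mu")
    if (mu <= 0 || mu > 1) stop("mu must lie in (0, 1]")
    t$kind <- 1L
    t$mu1 <- mu
  } else {
    if (is.null(height_scale)) stop("uneven terrain needs height_scale")
    if (height_scale < 0) stop("height_scale must be >= 0")
    t$kind <- 2L
    t$height_scale <- height_scale
    x <- seq(transition_x, x_max, by = t$hdx)
    if (height_scale == 0) {
      h <- numeric(length(x))
    } else {
      wl <- 0.9  # base wavelength (m); second octave at half scale
      g <- with_seed(seed %||% 0, function() list(runif(257, -1, 1),
                                                  runif(521, -1, 1)))
      h <- perlin1d(x, g[[1]], wl) + 0.5 * perlin1d(x, g[[2]], wl / 2)
      m <- max(abs(h))
      if (m > 0) h <- h * (height_scale / m)
      ramp <- pmin(1, pmax(0, (x - transition_x) / 0.3))
      h <- h * (ramp^2 * (3 - 2 * ramp))
    }
    t$hgrid <- h
  }
  structure(t, class = "walker_terrain")
}

#' Terrain height at world x
#' @param terrain a `walker_terrain`.
#' @param x numeric vector of world x positions (m).
#' @return heights (m); identically zero before the transition.
#' @export
terrain_height <- function(terrain, x) {
  if (terrain$kind != 2L || !length(terrain$hgrid)) return(numeric(length(x)) * 0)
  xs <- terrain$hx0 + terrain$hdx * (seq_along(terrain$hgrid) - 1)
  h <- approx(xs, terrain$hgrid, x, rule = 2)$y
  h[x <= terrain$transition_x] <- 0
  h
}

#' Terrain friction coefficient at world x
#' @inheritParams terrain_height
#' @return friction coefficients.
#' @export
terrain_mu <- function(terrain, x) {
  mu <- rep(terrain$mu0, length(x))
  if (terrain$kind == 1L) mu[x >= terrain$transition_x] <- terrain$mu1
  mu
}

terrain_core <- function(terrain) {
  list(kind = terrain$kind, mu0 = terrain$mu0, mu1 = terrain$mu1,
       transition_x = terrain$transition_x, hx0 = terrain$hx0,
       hdx = terrain$hdx, hgrid = terrain$hgrid)
}
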