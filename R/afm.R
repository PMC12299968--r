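#' Simulate an AFM topograph of globular particles
#'
#' Places non-overlapping spherical-cap particles on a flat background with
#' Gaussian roughness, emulating dried protein oligomers imaged on mica.
#' Apex heights are drawn from a normal law truncated at zero; defaults are
#' the oligomer population values (3.28 +/- 0.49 nm).
#'
#' @param n_particles Number of particles.
#' @param height_mean_nm,height_sd_nm Apex height law (nm).
#' @param radius_px_range Base radius range in pixels (uniform draw).
#' @param grid_size Edge length of the square grid, pixels.
#' @param pixel_size_nm Lateral pixel size (nm).
#' @param roughness_sd_nm Background roughness SD (nm).
#' @param seed Integer seed; fully determines the map.
#' @return A list of class `blm_afm_sim`: `map` (a `blm_heightmap` matrix
#'   with a `pixel_size_nm` attribute) and `truth` (tibble of planted
#'   particles: `row`, `col`, `radius_px`, `height_nm`).
#' @examples
#' sim <- synth_height_map(25, seed = 1)
#' max(sim$map)
#' @export
synth_height_map <- function(n_particles, height_mean_nm = 3.28,
                             height_sd_nm = 0.49,
                             radius_px_range = c(3, 6),
                             grid_size = 256, pixel_size_nm = 4,
                             roughness_sd_nm = 0.05, seed = 1L) {
  stopifnot(n_particles >= 0, height_mean_nm > 0, height_sd_nm >= 0,
    roughness_sd_nm >= 0, grid_size >= 8)
  set.seed(seed)
  grid <- matrix(0, grid_size, grid_size)
  truth <- tibble::tibble(row = numeric(), col = numeric(),
    radius_px = numeric(), height_nm = numeric())
  if (n_particles > 0) {
    rmax <- max(radius_px_range)
    placed <- matrix(numeric(0), ncol = 3)  # row, col, radius
    for (i in seq_len(n_particles)) {
      h <- rnorm_trunc0(1, height_mean_nm, max(height_sd_nm, 1e-12))
      a <- runif(1, radius_px_range[1], radius_px_range[2])
      ok <- FALSE
      for (try in 1:10000) {
        r0 <- runif(1, rmax + 1, grid_size - rmax)
        c0 <- runif(1, rmax + 1, grid_size - rmax)
        if (nrow(placed) == 0 ||
            all(sqrt((placed[, 1] - r0)^2 + (placed[, 2] - c0)^2) >
                  placed[, 3] + a + 2)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort("could not place particles without overlap; reduce n or enlarge grid",
          class = "blm_error_placement")
      }
      placed <- rbind(placed, c(r0, c0, a))
      grid <- add_spherical_cap(grid, r0, c0, a, h, pixel_size_nm)
      truth <- dplyr::bind_rows(truth, tibble::tibble(
        row = r0, col = c0, radius_px = a, height_nm = h))
    }
  }
  if (roughness_sd_nm > 0) {
    grid <- grid + matrix(rnorm(grid_size^2, sd = roughness_sd_nm),
      grid_size, grid_size)
  }
  structure(list(map = new_heightmap(grid, pixel_size_nm), truth = truth),
    class = "blm_afm_sim")
}

# spherical cap of apex height h (nm) and base radius a (px) at (r0, c0);
# lateral distances are converted to nm so the cap geometry is physical
add_spherical_cap <- function(grid, r0, c0, a, h, px_nm) {
  rr <- max(1, floor(r0 - a)):min(nrow(grid), ceiling(r0 + a))
  cc <- max(1, floor(c0 - a)):min(ncol(grid), ceiling(c0 + a))
  rho2_nm <- outer((rr - r0)^2, (cc - c0)^2, "+") * px_nm^2
  a_nm <- a * px_nm
  rad <- (a_nm^2 + h^2) / (2 * h)              # sphere radius, nm
  z <- sqrt(pmax(rad^2 - rho2_nm, 0)) - (rad - h)
  grid[rr, cc] <- grid[rr, cc] + pmax(z, 0) * (rho2_nm <= a_nm^2)
  grid
}

#' Detect particles in an AFM height map
#'
#' Subtracts the median background plane, thresholds, groups
#' above-threshold pixels by 8-connectivity, drops regions smaller than
#' `min_area_px`, and records each region's maximum height above background
#' (the z-height, in the AFM convention of apex height).
#'
#' @param map A `blm_heightmap`.
#' @param threshold_nm Detection threshold above background (nm); choose at
#'   least ~5x the background roughness SD.
#' @param min_area_px Minimum region area in pixels.
#' @return A tibble of particles: `centroid_row`, `centroid_col`,
#'   `area_px`, `z_height_nm`.
#' @export
detect_particles <- function(map, threshold_nm = 0.5, min_area_px = 4) {
  stopifnot(inherits(map, "blm_heightmap"))
  if (threshold_nm <= 0) {
    abort("threshold must be positive", class = "blm_error_threshold")
  }
  g <- unclass(map) - median(map)
  labels <- label_components(g > threshold_nm)
  if (max(labels) == 0) {
    return(tibble::tibble(centroid_row = numeric(), centroid_col = numeric(),
      area_px = integer(), z_height_nm = numeric()))
  }
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  out <- tibble::tibble(
    lab = lab, row = idx[, 1], col = idx[, 2],
    z = g[labels > 0]
  ) |>
    dplyr::group_by(.data$lab) |>
    dplyr::summarise(
      centroid_row = mean(.data$row), centroid_col = mean(.data$col),
      area_px = dplyr::n(), z_height_nm = max(.data$z), .groups = "drop"
    ) |>
    dplyr::filter(.data$area_px >= min_area_px) |>
    dplyr::select(-"lab")
  out
}

# label connected components of a logical matrix, 8-connectivity (BFS)
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  nbr_dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  nbr_dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  cur <- 0L
  fg <- which(mask)
  for (p in fg) {
    if (labels[p] != 0L) next
    cur <- cur + 1L
    queue <- p
    labels[p] <- cur
    while (length(queue) > 0) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((q - 1L) %% nr) + 1L
      cl <- ((q - 1L) %/% nr) + 1L
      rr <- r + nbr_dr
      cc <- cl + nbr_dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      nb <- (cc[ok] - 1L) * nr + rr[ok]
      nb <- nb[mask[nb] & labels[nb] == 0L]
      if (length(nb) > 0) {
        labels[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  labels
}

#' Summary statistics of particle z-heights
#'
#' @param particles Tibble from [detect_particles()] (needs `z_height_nm`),
#'   or a numeric vector of heights.
#' @param bin_width_nm Histogram bin width (nm); default 0.5.
#' @return A list of class `blm_height_stats`: `mean_nm`, `sd_nm` (0 with a
#'   `singleton` flag when n = 1), `n`, and `histogram` (tibble:
#'   `bin_mid_nm`, `count`).
#' @export
height_stats <- function(particles, bin_width_nm = 0.5) {
  z <- if (is.numeric(particles)) particles else particles$z_height_nm
  if (length(z) == 0) {
    abort("no particles supplied", class = "blm_error_empty")
  }
  breaks <- seq(0, (max(z) %/% bin_width_nm + 1) * bin_width_nm,
    by = bin_width_nm)
  counts <- table(cut(z, breaks, right = FALSE))
  structure(list(
    mean_nm = mean(z),
    sd_nm = if (length(z) < 2) 0 else sd(z),
    n = length(z),
    singleton = length(z) == 1,
    histogram = tibble::tibble(
      bin_mid_nm = head(breaks, -1) + bin_width_nm / 2,
      count = as.integer(counts)
    )
  ), class = "blm_height_stats")
}

#' @export
print.blm_height_stats <- function(x, ...) {
  cat(sprintf("Particle z-heights: %.2f +/- %.2f nm (n = %d)%s\n",
    x$mean_nm, x$sd_nm, x$n, if (x$singleton) " [single particle]" else ""))
  invisible(x)
}

#' @rdname height_stats
#' @param x A `blm_height_stats`.
#' @param ... Unused.
#' @export
tidy.blm_height_stats <- function(x, ...) {
  tibble::tibble(mean_nm = x$mean_nm, sd_nm = x$sd_nm, n = x$n)
}
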