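#' Scene specification for synthetic fields
#'
#' Describes the geometry and biology of one simulated field: how many
#' cells, how tightly packed (epithelial monolayers grow as tight adherent
#' sheets, which is what defeats intensity-only segmentation), nuclear and
#' cytoplasmic sizes, and the per-cell oxidized fraction and TMRM level.
#'
#' @param n_cells number of cells to place (>= 0).
#' @param field_shape image shape in pixels, \code{c(rows, cols)}.
#' @param nucleus_radius_px mean and sd of the nuclear radius in pixels.
#' @param cyto_extent_px width of the cytoplasmic/mitochondrial halo beyond
#'   the nuclear radius, pixels.
#' @param crowding_px minimum allowed spacing between nucleus centers,
#'   pixels. Values below about twice the cell radius
#'   (\code{nucleus_radius + cyto_extent}) force touching cell bodies.
#' @param oxidized_fraction per-cell oxidized fractions: a numeric vector
#'   (recycled), a \code{function(n)} returning \code{n} values in
#'   \code{[0, 1]}, or \code{NULL} for resting cells scattered around the
#'   calibration's baseline fraction (sd 0.03).
#' @param tmrm_level per-cell TMRM emission level: numeric vector,
#'   \code{function(n)}, or \code{NULL} for polarized mitochondria
#'   (mean 2.0, sd 0.3, arbitrary units).
#' @param background_level uniform background, counts.
#' @param background_gradient planar background slope,
#'   \code{c(per_row, per_col)} counts per pixel.
#' @param expression_sdlog lognormal sd of the per-cell probe expression
#'   gain (clonal lines still show residual expression spread).
#' @param speckle_shape gamma shape of the per-pixel mitochondrial speckle
#'   texture (mean 1; smaller = grainier).
#' @param nucleus_gfp_weight relative roGFP emission over the nuclear
#'   footprint (mitochondria are excluded from the nucleus, but out-of-focus
#'   signal leaks in).
#' @param nuclear_level H2B marker emission level (arbitrary units).
#' @return An object of class \code{scene_spec}.
#' @export
scene_spec <- function(n_cells = 40, field_shape = c(256, 256),
                       nucleus_radius_px = c(mean = 7, sd = 1),
                       cyto_extent_px = 6, crowding_px = 28,
                       oxidized_fraction = NULL, tmrm_level = NULL,
                       background_level = 100, background_gradient = c(0, 0),
                       expression_sdlog = 0.3, speckle_shape = 4,
                       nucleus_gfp_weight = 0.3, nuclear_level = 4) {
  stopifnot(n_cells >= 0, length(field_shape) == 2, all(field_shape >= 16),
            nucleus_radius_px[[1]] > 0, cyto_extent_px > 0, crowding_px > 0,
            background_level >= 0, speckle_shape > 0,
            nucleus_gfp_weight >= 0, nuclear_level > 0)
  if (is.numeric(oxidized_fraction) &&
      (any(oxidized_fraction < 0) || any(oxidized_fraction > 1)))
    stop("oxidized fractions must lie in [0, 1]")
  structure(list(n_cells = as.integer(n_cells),
                 field_shape = as.integer(field_shape),
                 nucleus_radius_px = c(mean = unname(nucleus_radius_px[[1]]),
                                       sd = if (length(nucleus_radius_px) > 1)
                                         unname(nucleus_radius_px[[2]]) else 0),
                 cyto_extent_px = cyto_extent_px, crowding_px = crowding_px,
                 oxidized_fraction = oxidized_fraction,
                 tmrm_level = tmrm_level,
                 background_level = background_level,
                 background_gradient = background_gradient,
                 expression_sdlog = expression_sdlog,
                 speckle_shape = speckle_shape,
                 nucleus_gfp_weight = nucleus_gfp_weight,
                 nuclear_level = nuclear_level),
            class = "scene_spec")
}

#' Camera noise specification
#'
#' Scaled-Poisson shot noise plus additive Gaussian read noise, the
#' standard CCD model: expected counts are
#' \code{background + photon_scale * emission}; each pixel is Poisson
#' sampled at that expectation, read noise is added, and the result is
#' rounded and clipped to the detector bit depth.
#'
#' @param photon_scale counts per unit of expected emission (> 0).
#' @param read_noise_sd additive Gaussian sd, counts (>= 0).
#' @param bit_depth detector bit depth; pixel values are clipped to
#'   \code{[0, 2^bit_depth - 1]}.
#' @param seed integer RNG seed; every generator output is a pure function
#'   of (spec, seed).
#' @return An object of class \code{noise_spec}.
#' @export
noise_spec <- function(photon_scale = 150, read_noise_sd = 3,
                       bit_depth = 16L, seed = 1L) {
  stopifnot(photon_scale > 0, read_noise_sd >= 0, bit_depth >= 8)
  structure(list(photon_scale = photon_scale, read_noise_sd = read_noise_sd,
                 bit_depth = as.integer(bit_depth), seed = as.integer(seed)),
            class = "noise_spec")
}

# sample per-cell values from a vector / function / default sampler
sample_per_cell <- function(spec_value, n, default_fn) {
  if (is.null(spec_value)) default_fn(n)
  else if (is.function(spec_value)) spec_value(n)
  else rep_len(as.numeric(spec_value), n)
}

# rejection-sample n centers with minimum spacing; 1-based pixel coords
place_centers <- function(n, shape, margin, min_spacing) {
  if (n == 0) return(cbind(row = numeric(), col = numeric()))
  lo <- margin + 1; hi_r <- shape[1] - margin; hi_c <- shape[2] - margin
  if (hi_r <= lo || hi_c <= lo)
    stop(sprintf("field %dx%d too small for cells of radius ~%.0f px",
                 shape[1], shape[2], margin))
  rows <- numeric(n); cols <- numeric(n); placed <- 0; tries <- 0
  max_tries <- 500 * n
  while (placed < n) {
    if ((tries <- tries + 1) > max_tries)
      stop(sprintf(paste0("could not place %d cells at minimum spacing ",
                          "%.1f px in a %dx%d field (placed %d); relax ",
                          "crowding_px, n_cells or field_shape"),
                   n, min_spacing, shape[1], shape[2], placed))
    r <- stats::runif(1, lo, hi_r); c <- stats::runif(1, lo, hi_c)
    if (placed == 0 ||
        min((rows[seq_len(placed)] - r)^2 + (cols[seq_len(placed)] - c)^2) >=
          min_spacing^2) {
      placed <- placed + 1; rows[placed] <- r; cols[placed] <- c
    }
  }
  cbind(row = rows, col = cols)
}

#' Render one synthetic multichannel field with ground truth
#'
#' Places cells, renders nuclei as filled ellipses in the nuclear channel,
#' and renders the roGFP channels as a perinuclear annulus with gamma
#' speckle texture mimicking mitochondria; per-cell 405/488 emissions come
#' from \code{\link{probe_response}} at that cell's true oxidized fraction.
#' TMRM is rendered over the same mitochondrial annulus. Ground-truth label
#' maps assign contested pixels to the nearest nucleus center.
#'
#' @param scene a \code{\link{scene_spec}}.
#' @param cal a \code{\link{probe_calibration}}.
#' @param noise a \code{\link{noise_spec}}; its \code{seed} drives all
#'   randomness (geometry, per-cell draws, speckle, photon noise).
#' @param noiseless if \code{TRUE}, return expected counts (no Poisson or
#'   read noise, no quantization); geometry and texture are still drawn
#'   from the seed, so a noiseless render is comparable across different
#'   oxidized fractions.
#' @return A list with components \code{field} (a \code{\link{field_image}}
#'   with channels ex405, ex488, nuclear, tmrm) and \code{truth} (nucleus
#'   and cell \code{\link{label_map}}s plus per-cell true oxidized
#'   fraction, true ratio, true TMRM level, expression gain and centers,
#'   indexed by label).
#' @export
generate_field <- function(scene, cal = probe_calibration(),
                           noise = noise_spec(), noiseless = FALSE) {
  stopifnot(inherits(scene, "scene_spec"), inherits(noise, "noise_spec"))
  with_seed(noise$seed, {
    nr <- scene$field_shape[1]; nc <- scene$field_shape[2]
    n <- scene$n_cells
    r_mu <- scene$nucleus_radius_px["mean"]; r_sd <- scene$nucleus_radius_px["sd"]
    cell_r_nom <- r_mu + scene$cyto_extent_px

    # nuclei stay fully inside the field; cytoplasm may clip at the border,
    # as it does in real fields
    centers <- place_centers(n, c(nr, nc), margin = r_mu + 2,
                             min_spacing = scene$crowding_px)
    r_nuc <- pmax(3, stats::rnorm(n, r_mu, r_sd))
    ecc <- stats::runif(n, 0.85, 1.15)
    theta <- stats::runif(n, 0, pi)
    f <- sample_per_cell(scene$oxidized_fraction, n, function(m)
      pmin(1, pmax(0, stats::rnorm(m, cal$f_baseline, 0.03))))
    if (any(f < 0 | f > 1)) stop("oxidized fractions must lie in [0, 1]")
    tmrm <- pmax(0, sample_per_cell(scene$tmrm_level, n, function(m)
      stats::rnorm(m, 2, 0.3)))
    gain <- stats::rlnorm(n, 0, scene$expression_sdlog)
    gain_nuc <- stats::rlnorm(n, 0, scene$expression_sdlog)
    em <- probe_response(f, cal)

    e405 <- matrix(0, nr, nc); e488 <- matrix(0, nr, nc)
    enuc <- matrix(0, nr, nc); etmrm <- matrix(0, nr, nc)
    nuc_lab <- matrix(0L, nr, nc); cell_lab <- matrix(0L, nr, nc)
    nuc_d2 <- matrix(Inf, nr, nc); cell_d2 <- matrix(Inf, nr, nc)

    for (k in seq_len(n)) {
      R <- r_nuc[k] + scene$cyto_extent_px
      a <- min(r_nuc[k] * ecc[k], R - 1); b <- r_nuc[k] / ecc[k]
      i0 <- max(1, floor(centers[k, "row"] - R)); i1 <- min(nr, ceiling(centers[k, "row"] + R))
      j0 <- max(1, floor(centers[k, "col"] - R)); j1 <- min(nc, ceiling(centers[k, "col"] + R))
      di <- (i0:i1) - centers[k, "row"]; dj <- (j0:j1) - centers[k, "col"]
      DX <- matrix(di, length(di), length(dj))
      DY <- matrix(dj, length(di), length(dj), byrow = TRUE)
      d2 <- DX^2 + DY^2
      u <- DX * cos(theta[k]) + DY * sin(theta[k])
      v <- -DX * sin(theta[k]) + DY * cos(theta[k])
      in_nuc <- (u / a)^2 + (v / b)^2 <= 1
      in_cell <- d2 <= R^2

      ii <- rep(i0:i1, times = length(dj)); jj <- rep(j0:j1, each = length(di))
      idx <- cbind(ii, jj)[as.vector(in_cell), , drop = FALSE]
      lin <- idx[, 1] + nr * (idx[, 2] - 1)
      speck <- stats::rgamma(length(lin), shape = scene$speckle_shape,
                             rate = scene$speckle_shape)
      w <- ifelse(as.vector(in_nuc[in_cell]), scene$nucleus_gfp_weight, 1) * speck
      e405[lin] <- e405[lin] + em$em405[k] * gain[k] * w
      e488[lin] <- e488[lin] + em$em488[k] * gain[k] * w
      etmrm[lin] <- etmrm[lin] +
        ifelse(as.vector(in_nuc[in_cell]), 0, tmrm[k] * gain[k] * speck)

      nlin <- (cbind(ii, jj)[as.vector(in_nuc & in_cell), , drop = FALSE])
      nlin <- nlin[, 1] + nr * (nlin[, 2] - 1)
      enuc[nlin] <- enuc[nlin] + scene$nuclear_level * gain_nuc[k]

      dd <- as.vector(d2[in_cell])
      upd <- dd < cell_d2[lin]
      cell_lab[lin[upd]] <- k; cell_d2[lin[upd]] <- dd[upd]
      ddn <- as.vector(d2[in_nuc & in_cell])
      updn <- ddn < nuc_d2[nlin]
      nuc_lab[nlin[updn]] <- k; nuc_d2[nlin[updn]] <- ddn[updn]
    }

    bg <- scene$background_level +
      outer((seq_len(nr) - 1) * scene$background_gradient[1],
            (seq_len(nc) - 1) * scene$background_gradient[2], "+")
    render <- function(e) {
      lambda <- pmax(bg + noise$photon_scale * e, 0)
      if (noiseless) return(lambda)
      x <- stats::rpois(length(lambda), lambda) +
        stats::rnorm(length(lambda), 0, noise$read_noise_sd)
      matrix(pmin(2^noise$bit_depth - 1, pmax(0, round(x))), nr, nc)
    }
    channels <- list(ex405 = render(e405), ex488 = render(e488),
                     nuclear = render(enuc), tmrm = render(etmrm))

    truth <- list(nucleus_labels = label_map(nuc_lab, "nucleus"),
                  cell_labels = label_map(cell_lab, "cell"),
                  true_oxidized_fraction = f,
                  true_ratio = as.numeric(probe_ratio(f, cal)),
                  true_tmrm = tmrm, expression_gain = gain,
                  centers = centers, nucleus_radius_px = r_nuc)
    list(field = field_image(channels), truth = truth)
  })
}
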