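#' Configuration of the synthetic TMS phantom
#'
#' Describes a synthetic subject: a motor-strip-like cortical ribbon inside a
#' 64 mm cube, a 7 x 7 stimulation grid (10 mm spacing, 60 x 60 mm extent)
#' centred on the ribbon hotspot plus optional jittered extra stimulations,
#' four stimulation intensities, a smooth focal E-field surrogate, and a
#' saturating per-muscle recruitment map with additive noise producing
#' many-muscle activation near the map centre and sparse or zero activation
#' at the fringes.
#'
#' @param scale `"test"` (16 cube, 4 mm voxels, 5\% mask, no jitter: 196
#'   records) or `"full"` (64 cube, 1 mm voxels, 2\% mask, 251 jittered
#'   stimulations per intensity: 1200 records).
#' @param shape cube side in voxels (side divisible by 4).
#' @param mask_fraction target nonzero fraction of the cortical mask.
#' @param n_jitter extra randomly placed stimulations per intensity, beyond
#'   the 49 grid vertices.
#' @param intensities stimulation intensities in \%RMT, ascending.
#' @param grid_extent,grid_spacing stimulation grid geometry, mm.
#' @param field_sigma focal spread of the field kernel, mm.
#' @param field_amp peak field amplitude scale, V/m.
#' @param coil_sigma attenuation length of peak intensity with coil-to-cortex
#'   distance, mm; makes fringe stimulations weak so some fall below the
#'   10 mV/m outlier cutoff.
#' @param coil_cutoff coil-to-mask distance beyond which the field is all
#'   zero, mm.
#' @param orient_gain gain of the orientation sensitivity factor.
#' @param m number of muscles.
#' @param weight_sigma spatial spread of each muscle's cortical
#'   representation, mm.
#' @param gain_range,threshold_range,slope per-muscle recruitment-curve
#'   parameters: MEP gain range (uV), drive threshold range (V/m), logistic
#'   slope (V/m).
#' @param noise_sd MEP additive noise SD, uV.
#' @param rectify_floor amount subtracted from the recruitment sigmoid before
#'   rectification; creates exact zero MEPs for weak drives.
#' @param seed integer seed making the whole phantom deterministic.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(scale = c("test", "full"),
                           shape = NULL, mask_fraction = NULL, n_jitter = NULL,
                           intensities = c(110, 120, 130, 140),
                           grid_extent = 60, grid_spacing = 10,
                           field_sigma = 8, field_amp = 0.08,
                           coil_sigma = 10, coil_cutoff = 28,
                           orient_gain = 0.3,
                           m = 15L, weight_sigma = 6,
                           gain_range = c(300, 3000),
                           threshold_range = c(0.010, 0.040),
                           slope = 0.008,
                           noise_sd = 15, rectify_floor = 0.02,
                           seed = 1L) {
  scale <- match.arg(scale)
  shape <- shape %||% if (scale == "full") 64L else 16L
  mask_fraction <- mask_fraction %||% if (scale == "full") 0.02 else 0.05
  n_jitter <- n_jitter %||% if (scale == "full") 251L else 0L
  if (shape %% 4L != 0L) stop_mf("cube side must be divisible by 4, got %d", shape)
  if (is.unsorted(intensities)) stop_mf("intensities must be ascending")
  stopifnot(mask_fraction > 0, field_sigma > 0, field_amp > 0, slope > 0,
            noise_sd >= 0, m >= 1)
  structure(list(
    scale = scale, shape = as.integer(shape),
    voxel_size = 64 / shape, # the phantom cube is always 64 mm across
    mask_fraction = mask_fraction, n_jitter = as.integer(n_jitter),
    intensities = intensities,
    grid_extent = grid_extent, grid_spacing = grid_spacing,
    field_sigma = field_sigma, field_amp = field_amp,
    coil_sigma = coil_sigma, coil_cutoff = coil_cutoff,
    orient_gain = orient_gain,
    m = as.integer(m), weight_sigma = weight_sigma,
    gain_range = gain_range, threshold_range = threshold_range,
    slope = slope, noise_sd = noise_sd, rectify_floor = rectify_floor,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

# mm coordinates of all voxel centres (0-based voxel index * voxel size)
voxel_coords_mm <- function(dim, voxel_size) {
  idx <- arrayInd(seq_len(prod(dim)), dim)
  (idx - 1) * voxel_size
}

# Sample the ribbon centreline: a gently curved strip running along y,
# bending in x and tilting in z, with seeded jitter.
ribbon_centerline <- function(seed, n = 200L) {
  with_seed(seed, {
    bend <- stats::runif(1, 6, 10)
    phase <- stats::runif(1, -0.4, 0.4)
    tilt <- stats::runif(1, -6, 6)
    wob <- stats::runif(1, 1, 3)
    t <- seq(0, 1, length.out = n)
    pts <- cbind(x = 32 + bend * sin(pi * t + phase),
                 y = 6 + 52 * t,
                 z = 32 + tilt * (t - 0.5) + wob * sin(2 * pi * t))
    # unit tangents by finite differences
    d <- apply(pts, 2, function(col) c(diff(col)[1], diff(col)))
    tan <- d / sqrt(rowSums(d^2))
    list(points = pts, tangents = tan)
  })
}

#' Generate a motor-strip phantom mask
#'
#' Builds a single connected, curved-ribbon binary mask (thin in x, deep in
#' z, long in y) whose nonzero fraction matches `mask_fraction` as closely as
#' the voxel lattice allows. The ribbon half-widths are scaled exactly to the
#' rank statistic of the anisotropic distance-to-centreline, so the achieved
#' fraction is within one voxel of the target (well inside the +/-25\% band).
#' Deterministic given `seed`.
#'
#' @param shape cube side in voxels.
#' @param mask_fraction target nonzero fraction, in (0, 0.2).
#' @param seed integer seed.
#' @param voxel_size mm per voxel edge (default keeps the cube 64 mm across).
#' @return A [cortex_mask()] carrying `centerline`, per-voxel `tangent`
#'   vectors and `inside` indices for the field simulator.
#' @export
make_phantom_mask <- function(shape, mask_fraction, seed = 1L,
                              voxel_size = 64 / shape) {
  if (mask_fraction <= 0 || mask_fraction >= 0.2)
    stop_mf("mask_fraction must be in (0, 0.2), got %g", mask_fraction)
  dim3 <- rep(as.integer(shape), 3L)
  V <- prod(dim3)
  n_target <- round(mask_fraction * V)
  if (n_target < 8L)
    stop_mf("shape %d too small for mask_fraction %g (target %d voxels)",
            shape, mask_fraction, n_target)
  cl <- ribbon_centerline(seed)
  co <- voxel_coords_mm(dim3, voxel_size)
  # base half-widths: thin across the strip, deep along the sulcus
  rx <- 4; ry <- 2.5; rz <- 12
  npts <- nrow(cl$points)
  qv <- numeric(V)   # required squared width multiplier per voxel
  nearest <- integer(V)
  chunk <- 16384L
  for (st in seq(1L, V, by = chunk)) {
    en <- min(st + chunk - 1L, V)
    ix <- st:en
    dx <- outer(co[ix, 1], cl$points[, 1], "-") / rx
    dy <- outer(co[ix, 2], cl$points[, 2], "-") / ry
    dz <- outer(co[ix, 3], cl$points[, 3], "-") / rz
    a <- dx^2 + dz^2
    b <- dy^2
    # voxel joins the mask once s^2 >= a/(1-b) at some centreline point
    q <- a / (1 - b)
    q[b >= 1] <- Inf
    j <- max.col(-q, ties.method = "first")
    qv[ix] <- q[cbind(seq_along(ix), j)]
    nearest[ix] <- j
  }
  qs <- sort(qv)[n_target]
  if (!is.finite(qs) || sqrt(qs) > 4)
    stop_mf("mask_fraction %g unreachable for shape %d", mask_fraction, shape)
  inside <- which(qv <= qs)
  grid <- array(0L, dim3)
  grid[inside] <- 1L
  msk <- cortex_mask(grid)
  msk$voxel_size <- voxel_size
  msk$centerline <- cl$points
  msk$inside <- inside
  msk$tangent <- cl$tangents[nearest[inside], , drop = FALSE]
  msk
}

# 6-connectivity flood fill; TRUE if the mask is one connected component
mask_connected <- function(mask) {
  g <- mask$grid
  d <- dim(g)
  inside <- which(g != 0)
  if (length(inside) == 0L) return(FALSE)
  lab <- array(FALSE, d)
  queue <- inside[1]
  lab[queue] <- TRUE
  offs <- c(1, -1, d[1], -d[1], d[1] * d[2], -d[1] * d[2])
  coord <- arrayInd(seq_len(prod(d)), d)
  while (length(queue)) {
    v <- queue[length(queue)]
    queue <- queue[-length(queue)]
    for (o in offs) {
      w <- v + o
      if (w < 1 || w > prod(d)) next
      # guard against wrapping across faces
      if (sum(abs(coord[w, ] - coord[v, ])) != 1L) next
      if (g[w] != 0 && !lab[w]) {
        lab[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  sum(lab) == length(inside)
}

#' Simulate one stimulation's E-field
#'
#' Surrogate for the finite-element field model: a smooth unimodal kernel on
#' the cortical ribbon,
#' `E(v) = A s(I) g(coil) exp(-d(v)^2 / (2 sigma^2)) (1 + gamma cos theta)`,
#' where `d(v)` is the mm distance from voxel `v` to the peak voxel (the mask
#' voxel nearest the coil's in-plane projection), `s(I) = (I/100)^2` grows
#' monotonically with stimulation intensity, `g(coil)` attenuates the peak
#' with the coil-to-cortex in-plane distance, and `theta` is the angle
#' between the coil orientation and the ribbon tangent at the peak voxel.
#' Zero outside the mask. A coil farther than `coil_cutoff` from the mask
#' yields an all-zero field flagged with `attr(, "fringe")`.
#'
#' @param coil_position length-3 position in mm.
#' @param coil_orientation in-plane coil handle angle, degrees.
#' @param intensity_pct_rmt stimulation intensity, \%RMT.
#' @param mask a phantom [cortex_mask()] from [make_phantom_mask()].
#' @param config a [phantom_config()].
#' @return An [efield_volume()] in raw V/m.
#' @export
simulate_efield <- function(coil_position, coil_orientation, intensity_pct_rmt,
                            mask, config) {
  stopifnot(inherits(mask, "cortex_mask"), inherits(config, "phantom_config"))
  dim3 <- dim(mask$grid)
  vx <- mask$voxel_size %||% config$voxel_size
  co <- voxel_coords_mm(dim3, vx)
  inside <- mask$inside %||% which(mask$grid != 0)
  pos <- as.numeric(coil_position)
  dxy <- sqrt((co[inside, 1] - pos[1])^2 + (co[inside, 2] - pos[2])^2)
  grid <- array(0, dim3)
  if (min(dxy) > config$coil_cutoff) {
    vol <- efield_volume(grid, vx, scaled = FALSE)
    attr(vol, "fringe") <- TRUE
    return(vol)
  }
  peak <- which.min(dxy)
  pstar <- co[inside[peak], ]
  d2 <- rowSums(sweep(co[inside, , drop = FALSE], 2L, pstar)^2)
  s <- (intensity_pct_rmt / 100)^2
  g <- exp(-dxy[peak]^2 / (2 * config$coil_sigma^2))
  ofac <- 1
  if (!is.null(mask$tangent)) {
    u <- c(cos(coil_orientation * pi / 180), sin(coil_orientation * pi / 180), 0)
    ofac <- 1 + config$orient_gain * sum(u * mask$tangent[peak, ])
  }
  grid[inside] <- config$field_amp * s * g * ofac *
    exp(-d2 / (2 * config$field_sigma^2))
  vol <- efield_volume(grid, vx, scaled = FALSE)
  attr(vol, "fringe") <- FALSE
  vol
}

#' Cortical representation maps of the muscles
#'
#' One normalized nonnegative weight blob per muscle, centred at distinct
#' locations spread along the ribbon with seeded jitter. Neighbouring blobs
#' overlap, so stimulations near the map centre co-activate several muscles
#' (a mosaic of overlapping muscle territories).
#'
#' @param m number of muscles.
#' @param mask a phantom [cortex_mask()].
#' @param seed integer seed.
#' @param sigma blob spread in mm.
#' @return List of `m` maps, each with `w` (length-V weight vector summing to
#'   1, zero outside the mask), `center` (mm) and `muscle`.
#' @export
make_muscle_weight_maps <- function(m, mask, seed = 1L, sigma = 6) {
  stopifnot(inherits(mask, "cortex_mask"))
  dim3 <- dim(mask$grid)
  vx <- mask$voxel_size %||% (64 / dim3[1])
  co <- voxel_coords_mm(dim3, vx)
  inside <- mask$inside %||% which(mask$grid != 0)
  cl <- mask$centerline
  if (is.null(cl)) cl <- co[inside, , drop = FALSE]
  muscles <- default_muscles(m)
  with_seed(seed, {
    tpos <- ((seq_len(m) - 0.5) / m + stats::runif(m, -0.3 / m, 0.3 / m))
    tpos <- pmin(pmax(tpos, 0), 1)
    used <- integer(0)
    maps <- vector("list", m)
    for (k in seq_len(m)) {
      target <- cl[pmax(1L, round(tpos[k] * (nrow(cl) - 1L)) + 1L), ] +
        stats::rnorm(3, 0, 2)
      d2 <- rowSums(sweep(co[inside, , drop = FALSE], 2L, target)^2)
      ord <- order(d2)
      cidx <- ord[!(inside[ord] %in% used)][1] # distinct centres
      used <- c(used, inside[cidx])
      cmm <- co[inside[cidx], ]
      w <- numeric(prod(dim3))
      w[inside] <- exp(-rowSums(sweep(co[inside, , drop = FALSE], 2L, cmm)^2) /
                         (2 * sigma^2))
      w <- w / sum(w)
      maps[[k]] <- list(w = w, center = cmm, muscle = muscles[k])
    }
    maps
  })
}

#' Simulate the multi-muscle MEP response to one field
#'
#' Each muscle integrates the field over its cortical representation
#' (`drive_k = <w_k, E>`) and responds through a saturating logistic
#' recruitment curve with additive Gaussian noise, floored and rectified so
#' weak drives give exact zeros:
#' `mep_k = max(0, gain_k (sigmoid((drive - thr_k)/slope) - sigmoid(-thr_k/slope)
#' - rectify_floor) + eps)`.
#'
#' @param efield an [efield_volume()] in raw V/m.
#' @param weight_maps output of [make_muscle_weight_maps()].
#' @param recruitment list with per-muscle `gain`, `threshold`, `slope`.
#' @param noise_sd additive noise SD in uV.
#' @param rectify_floor sigmoid floor subtracted before rectification.
#' @param seed integer seed for the noise draw (NULL = current RNG stream).
#' @return A [mep_vector()] in raw uV.
#' @export
simulate_mep <- function(efield, weight_maps, recruitment,
                         noise_sd = 0, rectify_floor = 0.02, seed = NULL) {
  m <- length(weight_maps)
  if (length(recruitment$gain) != m || length(recruitment$threshold) != m)
    stop_mf("recruitment parameters (%d) do not match number of muscles (%d)",
            length(recruitment$gain), m)
  ev <- as.numeric(efield$grid)
  drive <- vapply(weight_maps, function(mp) sum(mp$w * ev), numeric(1))
  sig <- stats::plogis((drive - recruitment$threshold) / recruitment$slope)
  sig0 <- stats::plogis(-recruitment$threshold / recruitment$slope)
  eps <- if (noise_sd > 0) {
    if (is.null(seed)) stats::rnorm(m, 0, noise_sd)
    else with_seed(seed, stats::rnorm(m, 0, noise_sd))
  } else rep(0, m)
  vals <- pmax(0, recruitment$gain * (sig - sig0 - rectify_floor) + eps)
  mep_vector(vals, vapply(weight_maps, `[[`, character(1), "muscle"))
}

# Draw the per-muscle recruitment parameters for one phantom subject
phantom_recruitment <- function(config) {
  with_seed(config$seed + 1L, list(
    gain = stats::runif(config$m, config$gain_range[1], config$gain_range[2]),
    threshold = stats::runif(config$m, config$threshold_range[1],
                             config$threshold_range[2]),
    slope = rep(config$slope, config$m)
  ))
}

#' Generate a complete phantom stimulation dataset
#'
#' Emulates one mapping session: for every intensity, one stimulation at each
#' of the 49 vertices of the 7 x 7 grid centred on the ribbon hotspot, plus
#' `n_jitter` stimulations at random in-extent positions, each with a jittered
#' coil orientation around 45 degrees. Fields and MEPs are simulated in raw
#' physical units; the result feeds [preprocess_dataset()]. Fully
#' reproducible from `config$seed`.
#'
#' @param config a [phantom_config()].
#' @return A raw [stim_dataset()]; the phantom ground truth (config and
#'   recruitment parameters) is attached as `$phantom`.
#' @export
generate_dataset <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  mask <- make_phantom_mask(config$shape, config$mask_fraction, config$seed)
  wmaps <- make_muscle_weight_maps(config$m, mask, config$seed + 2L,
                                   config$weight_sigma)
  recr <- phantom_recruitment(config)
  inside <- mask$inside
  co <- voxel_coords_mm(dim(mask$grid), mask$voxel_size)
  hotspot <- colMeans(co[inside, , drop = FALSE])[1:2]
  coil_z <- max(co[inside, 3]) + 15
  half <- config$grid_extent / 2
  gx <- seq(-half, half, by = config$grid_spacing)
  grid_xy <- as.matrix(expand.grid(x = hotspot[1] + gx, y = hotspot[2] + gx))

  with_seed(config$seed + 3L, {
    pos_list <- list(); orient <- c(); intens <- c()
    for (I in config$intensities) {
      xy <- grid_xy
      if (config$n_jitter > 0) {
        jit <- cbind(stats::runif(config$n_jitter, hotspot[1] - half, hotspot[1] + half),
                     stats::runif(config$n_jitter, hotspot[2] - half, hotspot[2] + half))
        xy <- rbind(xy, jit)
      }
      pos_list[[length(pos_list) + 1L]] <- xy
      orient <- c(orient, 45 + stats::rnorm(nrow(xy), 0, 8))
      intens <- c(intens, rep(I, nrow(xy)))
    }
    xy <- do.call(rbind, pos_list)
    n <- nrow(xy)
    V <- prod(dim(mask$grid))
    X <- matrix(0, n, V)
    meps <- matrix(0, n, config$m)
    fringe <- logical(n)
    for (i in seq_len(n)) {
      vol <- simulate_efield(c(xy[i, 1], xy[i, 2], coil_z), orient[i],
                             intens[i], mask, config)
      fringe[i] <- isTRUE(attr(vol, "fringe"))
      X[i, ] <- as.numeric(vol$grid)
      meps[i, ] <- simulate_mep(vol, wmaps, recr, config$noise_sd,
                                config$rectify_floor)
    }
    coil <- data.frame(id = seq_len(n), x = xy[, 1], y = xy[, 2], z = coil_z,
                       orientation_deg = orient, intensity_pct_rmt = intens,
                       fringe = fringe)
    ds <- stim_dataset(X, dim(mask$grid), meps, coil, mask,
                       voxel_size = mask$voxel_size,
                       muscles = default_muscles(config$m))
    ds$phantom <- list(config = config, recruitment = recr)
    ds
  })
}
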