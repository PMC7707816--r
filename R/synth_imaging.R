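# Synthetic multichannel confocal volumes of inhibitory boutons with known
# class labels, emulating 60x confocal z-stacks (0.1 um/px, 0.2 um/section,
# 8 bit). Used as ground truth for the co-localization pipeline.

#' Volume acquisition geometry for synthetic imaging
#'
#' Describes the geometry and background statistics of a synthetic confocal
#' stack. Defaults mirror a typical acquisition: 1016 x 1016 pixels at
#' 0.1 um/pixel, 15 sections at 0.2 um spacing, 8-bit intensities.
#'
#' @param shape_xy integer length-2, image size in pixels (y, x).
#' @param n_z number of z sections.
#' @param voxel_size_um numeric length-3, voxel size in um along (y, x, z).
#' @param background_mean,background_sd background intensity mean and
#'   Gaussian noise SD, in 8-bit intensity units.
#' @return An object of class `volume_spec`.
#' @export
volume_spec <- function(shape_xy = c(1016L, 1016L), n_z = 15L,
                        voxel_size_um = c(0.1, 0.1, 0.2),
                        background_mean = 10, background_sd = 3) {
  stopifnot(length(shape_xy) == 2L, all(shape_xy >= 1),
            n_z >= 1, length(voxel_size_um) == 3L,
            all(voxel_size_um > 0), background_sd >= 0,
            background_mean >= 0, background_mean <= 255)
  structure(list(shape_xy = as.integer(shape_xy), n_z = as.integer(n_z),
                 voxel_size_um = as.numeric(voxel_size_um),
                 bit_depth = 8L,
                 background_mean = background_mean,
                 background_sd = background_sd),
            class = "volume_spec")
}

#' Bouton population parameters for the volume generator
#'
#' @param count number of target boutons to place.
#' @param p_glyt2,p_syt12,p_yfp marginal probabilities that a bouton carries
#'   the glycinergic reporter (Syp-TdT), Syt1/2, or YFP. Ignored when
#'   `class_table` is given.
#' @param class_table optional data.frame with logical columns
#'   `glyt2`, `syt12`, `yfp` (one row per bouton) fixing the class flags
#'   exactly; overrides the marginal probabilities.
#' @param alpha marker gain: a class-true marker channel carries
#'   `alpha` times the bouton's Vgat signal.
#' @param rho marker co-localization strength in \[-1, 1\]. At 1 the marker
#'   copies the Vgat punctum exactly (scaled by `alpha`); smaller positive
#'   values mix in an independent punctum, degrading the voxelwise
#'   correlation; negative values invert the punctum (anticorrelated).
#' @param bleed fraction of the Vgat punctum leaking into class-false marker
#'   channels (0 = pure background; used to stress the classifier's
#'   unclassified band).
#' @param epsilon_sd extra Gaussian noise added to class-true marker signal
#'   inside the punctum, intensity units.
#' @param peak_mean,peak_sd Vgat peak intensity distribution (truncated to
#'   stay within 8-bit range after background).
#' @param sigma_xy_um,sigma_z_um Gaussian punctum widths in um.
#' @param noise_sd acquisition noise SD added to every channel, intensity
#'   units (applied before 8-bit quantization).
#' @param neighbor_fraction fraction of target boutons that receive one
#'   contaminating Vgat-only neighbor placed within one VOI footprint.
#' @param neighbor_distance_um range of center-to-center distances (xy, um)
#'   for contaminating neighbors.
#' @param min_separation_um minimum center-to-center distance between target
#'   boutons.
#' @param margin_um minimum distance of centroids from each volume face
#'   (y, x, z), so every bouton admits a full VOI.
#' @param max_attempts placement attempt budget per bouton before a
#'   placement error is raised.
#' @param region_label region assigned to all boutons in the volume.
#' @return A list of class `bouton_population`.
#' @export
bouton_population <- function(count = 50L, p_glyt2 = 0.5, p_syt12 = 0.5,
                              p_yfp = 0, class_table = NULL,
                              alpha = 1, rho = 1, bleed = 0, epsilon_sd = 0,
                              peak_mean = 180, peak_sd = 20,
                              sigma_xy_um = 0.3, sigma_z_um = 0.4,
                              noise_sd = 5,
                              neighbor_fraction = 0,
                              neighbor_distance_um = c(1.0, 1.4),
                              min_separation_um = 2,
                              margin_um = c(0.85, 0.85, 0.5),
                              max_attempts = 500L,
                              region_label = "unassigned") {
  if (rho < -1 || rho > 1) stop("rho must lie in [-1, 1]", call. = FALSE)
  stopifnot(count >= 0, alpha >= 0, bleed >= 0, bleed <= 1,
            sigma_xy_um > 0, sigma_z_um > 0, noise_sd >= 0,
            neighbor_fraction >= 0, neighbor_fraction <= 1,
            min_separation_um > 0, length(margin_um) == 3L)
  if (!is.null(class_table)) {
    stopifnot(is.data.frame(class_table),
              all(c("glyt2", "syt12", "yfp") %in% names(class_table)),
              nrow(class_table) == count)
  }
  structure(as.list(environment()), class = "bouton_population")
}

# render one anisotropic Gaussian punctum into `arr` (modified in place by
# the caller via returned bounding-box contribution)
render_punctum <- function(dim_yxz, voxel, center_um, peak, sigma_xy, sigma_z) {
  # voxel centers at (i - 0.5) * delta
  ry <- ceiling(4 * sigma_xy / voxel[1L]); rx <- ceiling(4 * sigma_xy / voxel[2L])
  rz <- ceiling(4 * sigma_z / voxel[3L])
  cy <- center_um[2L] / voxel[1L] + 0.5; cx <- center_um[1L] / voxel[2L] + 0.5
  cz <- center_um[3L] / voxel[3L] + 0.5
  iy <- max(1L, floor(cy - ry)):min(dim_yxz[1L], ceiling(cy + ry))
  ix <- max(1L, floor(cx - rx)):min(dim_yxz[2L], ceiling(cx + rx))
  iz <- max(1L, floor(cz - rz)):min(dim_yxz[3L], ceiling(cz + rz))
  dy <- ((iy - 0.5) * voxel[1L] - center_um[2L])
  dx <- ((ix - 0.5) * voxel[2L] - center_um[1L])
  dz <- ((iz - 0.5) * voxel[3L] - center_um[3L])
  gy <- exp(-dy^2 / (2 * sigma_xy^2))
  gx <- exp(-dx^2 / (2 * sigma_xy^2))
  gz <- exp(-dz^2 / (2 * sigma_z^2))
  block <- peak * (gy %o% gx %o% gz)
  list(iy = iy, ix = ix, iz = iz, block = block)
}

#' Generate a synthetic multichannel bouton volume with ground truth
#'
#' Renders a population of inhibitory boutons as anisotropic 3-d Gaussian
#' puncta in a Vgat channel, with marker channels (Syp-TdT, Syt1/2, optional
#' YFP) that copy each bouton's Vgat signal (scaled by `alpha`) when the
#' bouton carries the marker and contain only background otherwise. Gaussian
#' acquisition noise is added and intensities are clipped and quantized to
#' 8 bit. Output is bit-identical for a fixed seed.
#'
#' @param spec a [volume_spec()].
#' @param population a [bouton_population()].
#' @param include_yfp logical; add a YFP channel. Defaults to TRUE when the
#'   population can produce YFP-positive boutons.
#' @param seed integer seed for reproducibility (NULL = use current RNG
#'   state).
#' @return A list with elements `stack` (named list of 3-d intensity arrays
#'   `[y, x, z]`, integers in 0..255: `vgat`, `syp_tdt`, `syt12`, optionally
#'   `yfp`), `truth` (data.frame: id, x_um, y_um, z_um, glyt2, syt12, yfp,
#'   region, is_neighbor, peak), `spec`, and `population`.
#' @export
generate_volume <- function(spec, population = bouton_population(),
                            include_yfp = NULL, seed = NULL) {
  stopifnot(inherits(spec, "volume_spec"), inherits(population, "bouton_population"))
  seed_rng(seed)
  p <- population
  d <- c(spec$shape_xy[1L], spec$shape_xy[2L], spec$n_z)
  voxel <- spec$voxel_size_um
  extent <- c(d[2L] * voxel[2L], d[1L] * voxel[1L], d[3L] * voxel[3L]) # x, y, z um
  margin <- p$margin_um[c(2L, 1L, 3L)] # to (x, y, z) order
  if (any(extent <= 2 * margin) && p$count > 0)
    stop("volume too small to place boutons with the required margin", call. = FALSE)

  # class flags
  if (!is.null(p$class_table)) {
    cls <- p$class_table
  } else {
    cls <- data.frame(glyt2 = runif(p$count) < p$p_glyt2,
                      syt12 = runif(p$count) < p$p_syt12,
                      yfp   = runif(p$count) < p$p_yfp)
  }
  if (is.null(include_yfp)) {
    include_yfp <- (p$count > 0 && any(cls$yfp)) ||
      (is.null(p$class_table) && p$p_yfp > 0)
  }

  # place target boutons by rejection sampling with a hard-core distance
  centers <- matrix(numeric(0), ncol = 3L)
  for (i in seq_len(p$count)) {
    placed <- FALSE
    for (a in seq_len(p$max_attempts)) {
      cand <- margin + runif(3L) * (extent - 2 * margin)
      if (nrow(centers) == 0L ||
          min(sqrt(colSums((t(centers) - cand)^2))) >= p$min_separation_um) {
        centers <- rbind(centers, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("failed to place bouton %d of %d within %d attempts: reduce count or min_separation_um",
                   i, p$count, p$max_attempts), call. = FALSE)
  }

  peaks <- if (p$count > 0) {
    pmin(pmax(rnorm(p$count, p$peak_mean, p$peak_sd), 20), 255 - spec$background_mean)
  } else numeric(0)

  # contaminating neighbors: Vgat-only puncta one VOI footprint away
  n_nb <- round(p$neighbor_fraction * p$count)
  nb_centers <- matrix(numeric(0), ncol = 3L)
  nb_host <- integer(0)
  if (n_nb > 0) {
    hosts <- sample(seq_len(p$count), n_nb)
    for (h in hosts) {
      dist <- runif(1L, p$neighbor_distance_um[1L], p$neighbor_distance_um[2L])
      th <- runif(1L, 0, 2 * pi)
      cand <- centers[h, ] + c(dist * cos(th), dist * sin(th), 0)
      cand <- pmin(pmax(cand, margin), extent - margin)
      nb_centers <- rbind(nb_centers, cand)
      nb_host <- c(nb_host, h)
    }
  }

  channel_names <- c("vgat", "syp_tdt", "syt12", if (include_yfp) "yfp")
  sig <- lapply(channel_names, function(ch) array(0, dim = d))
  names(sig) <- channel_names

  add_block <- function(arr, pb, scale = 1) {
    arr[pb$iy, pb$ix, pb$iz] <- arr[pb$iy, pb$ix, pb$iz] + scale * pb$block
    arr
  }

  marker_of <- c(glyt2 = "syp_tdt", syt12 = "syt12", yfp = "yfp")
  for (i in seq_len(p$count)) {
    pb <- render_punctum(d, voxel, centers[i, ], peaks[i], p$sigma_xy_um, p$sigma_z_um)
    sig$vgat <- add_block(sig$vgat, pb)
    # independent punctum used to degrade correlation when rho < 1
    if (p$rho < 1 && p$rho > -1) {
      off <- centers[i, ] + c(p$sigma_xy_um, -p$sigma_xy_um, 0)
      pb_ind <- render_punctum(d, voxel, off, peaks[i], p$sigma_xy_um, p$sigma_z_um)
    }
    for (flag in names(marker_of)) {
      ch <- marker_of[[flag]]
      if (!ch %in% channel_names) next
      if (isTRUE(cls[[flag]][i])) {
        if (p$rho >= 1) {
          sig[[ch]] <- add_block(sig[[ch]], pb, p$alpha)
        } else if (p$rho <= -1) {
          inv <- pb; inv$block <- max(pb$block) - pb$block
          sig[[ch]] <- add_block(sig[[ch]], inv, p$alpha)
        } else {
          w <- abs(p$rho)
          base <- if (p$rho >= 0) pb else { inv <- pb; inv$block <- max(pb$block) - pb$block; inv }
          sig[[ch]] <- add_block(sig[[ch]], base, p$alpha * w)
          sig[[ch]] <- add_block(sig[[ch]], pb_ind, p$alpha * (1 - w))
        }
        if (p$epsilon_sd > 0) {
          eps <- array(rnorm(length(pb$block), 0, p$epsilon_sd), dim = dim(pb$block))
          sig[[ch]][pb$iy, pb$ix, pb$iz] <- sig[[ch]][pb$iy, pb$ix, pb$iz] + eps
        }
      } else if (p$bleed > 0) {
        sig[[ch]] <- add_block(sig[[ch]], pb, p$alpha * p$bleed)
      }
    }
  }
  for (j in seq_len(n_nb)) {
    pk <- pmin(pmax(rnorm(1L, p$peak_mean, p$peak_sd), 20), 255 - spec$background_mean)
    pb <- render_punctum(d, voxel, nb_centers[j, ], pk, p$sigma_xy_um, p$sigma_z_um)
    sig$vgat <- add_block(sig$vgat, pb)
  }

  stack <- lapply(sig, function(a) {
    a <- a + spec$background_mean
    if (p$noise_sd > 0) a <- a + array(rnorm(length(a), 0, p$noise_sd), dim = d)
    array(as.integer(pmin(pmax(round(a), 0), 255)), dim = d)
  })
  class(stack) <- "channel_stack"

  truth <- data.frame(
    id = seq_len(p$count + n_nb),
    x_um = c(centers[, 1L], nb_centers[, 1L]),
    y_um = c(centers[, 2L], nb_centers[, 2L]),
    z_um = c(centers[, 3L], nb_centers[, 3L]),
    glyt2 = c(as.logical(cls$glyt2), rep(FALSE, n_nb)),
    syt12 = c(as.logical(cls$syt12), rep(FALSE, n_nb)),
    yfp = c(as.logical(cls$yfp), rep(FALSE, n_nb)),
    region = rep(p$region_label, p$count + n_nb),
    is_neighbor = c(rep(FALSE, p$count), rep(TRUE, n_nb)),
    peak = c(peaks, rep(NA_real_, n_nb)))

  list(stack = stack, truth = truth, spec = spec, population = p)
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x[[1L]])
  cat(sprintf("<channel_stack> %d channel(s) [%s], %d x %d x %d voxels\n",
              length(x), paste(names(x), collapse = ", "), d[1L], d[2L], d[3L]))
  invisible(x)
}
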