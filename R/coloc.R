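# Per-bouton co-localization scoring and classification.
#
# Boutons are detected as 3-d local maxima of the Vgat channel. Around each
# centroid a fixed volume of interest (VOI, 1.5 x 1.5 x 1 um) is extracted;
# voxels in the outer 0.25 um shell whose Vgat intensity exceeds a set
# threshold (neighboring-bouton contamination) are excluded; the marker
# channel is regressed on Vgat over the included voxels and the coefficient
# of determination R^2 is the co-localization score. Anticorrelated VOIs
# (negative regression slope) are floored at R^2 = 0.01.

#' Configuration for bouton detection and co-localization scoring
#'
#' @param voi_um volume of interest edge lengths in um (x, y, z);
#'   default 1.5 x 1.5 x 1 um.
#' @param edge_shell_um width of the VOI edge shell in um; shell voxels with
#'   supra-threshold Vgat signal are excluded from the regression.
#' @param anticorrelation_floor score reported when the fitted slope is
#'   negative.
#' @param glyt2_pos,glyt2_neg R^2 thresholds for GlyT2+ (score strictly
#'   above) and GlyT2- (strictly below) classification of the Vgat/Syp-TdT
#'   score; scores between are left unclassified.
#' @param yfp_pos,syt_pos R^2 thresholds (strictly above) for YFP+ and
#'   Syt1/2+ classification.
#' @param smooth_sigma_vox Gaussian smoothing (voxels, per axis y/x/z)
#'   applied to the Vgat channel before local-maximum detection.
#' @param min_peak minimum smoothed intensity for a detected maximum; NULL
#'   uses background + 5 robust SD.
#' @param min_separation_um minimum distance between detected centroids;
#'   the brighter peak wins.
#' @param edge_intensity_k edge-shell exclusion threshold in multiples of
#'   the background SD above the background mean (both estimated
#'   volume-wide by median/MAD).
#' @param min_voxels minimum number of included voxels for a valid score.
#' @return An object of class `coloc_config`.
#' @export
coloc_config <- function(voi_um = c(1.5, 1.5, 1.0), edge_shell_um = 0.25,
                         anticorrelation_floor = 0.01,
                         glyt2_pos = 0.4, glyt2_neg = 0.1,
                         yfp_pos = 0.4, syt_pos = 0.4,
                         smooth_sigma_vox = c(1, 1, 0.5),
                         min_peak = NULL, min_separation_um = 0.5,
                         edge_intensity_k = 2, min_voxels = 10L) {
  stopifnot(length(voi_um) == 3L, all(voi_um > 0), edge_shell_um >= 0,
            all(voi_um > 2 * edge_shell_um),
            glyt2_neg > 0, glyt2_neg < glyt2_pos, glyt2_pos <= 1,
            anticorrelation_floor > 0, anticorrelation_floor < glyt2_neg,
            yfp_pos > 0, yfp_pos <= 1, syt_pos > 0, syt_pos <= 1,
            min_separation_um >= 0, min_voxels >= 3L)
  structure(list(voi_um = voi_um, edge_shell_um = edge_shell_um,
                 anticorrelation_floor = anticorrelation_floor,
                 thresholds = list(glyt2_pos = glyt2_pos, glyt2_neg = glyt2_neg,
                                   yfp_pos = yfp_pos, syt_pos = syt_pos),
                 smooth_sigma_vox = smooth_sigma_vox, min_peak = min_peak,
                 min_separation_um = min_separation_um,
                 edge_intensity_k = edge_intensity_k,
                 min_voxels = as.integer(min_voxels)),
            class = "coloc_config")
}

# VOI half-widths in voxels per array axis (y, x, z); footprint is forced odd
voi_radius <- function(config, voxel_size_um) {
  n <- round(config$voi_um[c(2L, 1L, 3L)] / voxel_size_um)
  n <- n + (1L - n %% 2L) # make odd so the VOI centers on the peak voxel
  as.integer((n - 1L) / 2L)
}

# robust volume-wide background estimate
background_stats <- function(x) {
  v <- as.numeric(x)
  list(mean = median(v), sd = mad(v))
}

#' Detect Vgat-positive boutons as 3-d local maxima
#'
#' The Vgat channel is Gaussian-smoothed, 26-neighborhood local maxima above
#' the minimum peak intensity are extracted, maxima closer than the minimum
#' separation are pruned (keeping the brighter), and maxima too close to a
#' volume face to admit a full VOI are dropped.
#'
#' @param vgat 3-d intensity array `[y, x, z]`.
#' @param config a [coloc_config()].
#' @param voxel_size_um voxel size in um (y, x, z).
#' @return data.frame with voxel indices (`vy`, `vx`, `vz`), physical
#'   centroids (`x_um`, `y_um`, `z_um`) and smoothed peak intensity.
#' @export
detect_boutons <- function(vgat, config = coloc_config(),
                           voxel_size_um = c(0.1, 0.1, 0.2)) {
  stopifnot(length(dim(vgat)) == 3L, length(voxel_size_um) == 3L)
  r <- voi_radius(config, voxel_size_um)
  d <- dim(vgat)
  if (any(d < 2L * r + 1L))
    stop("volume smaller than one VOI footprint", call. = FALSE)
  sm <- gauss_smooth3(vgat * 1.0, config$smooth_sigma_vox)
  thr <- config$min_peak
  if (is.null(thr)) {
    bg <- background_stats(vgat)
    thr <- bg$mean + 5 * max(bg$sd, 1)
  }
  mx <- maxfilt3(sm)
  is_peak <- (sm >= mx) & (sm > thr)
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(vy = integer(0), vx = integer(0), vz = integer(0),
                      x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      peak = numeric(0)))
  }
  val <- sm[idx]
  ord <- order(val, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]; val <- val[ord]
  # physical coordinates of voxel centers
  pos <- cbind(x = (idx[, 2L] - 0.5) * voxel_size_um[2L],
               y = (idx[, 1L] - 0.5) * voxel_size_um[1L],
               z = (idx[, 3L] - 0.5) * voxel_size_um[3L])
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    dmin <- min(sqrt(colSums((t(pos[keep, , drop = FALSE]) - pos[i, ])^2)))
    keep[i] <- dmin >= config$min_separation_um
  }
  idx <- idx[keep, , drop = FALSE]; val <- val[keep]; pos <- pos[keep, , drop = FALSE]
  # drop boutons whose VOI would cross a face
  ok <- idx[, 1L] > r[1L] & idx[, 1L] <= d[1L] - r[1L] &
        idx[, 2L] > r[2L] & idx[, 2L] <= d[2L] - r[2L] &
        idx[, 3L] > r[3L] & idx[, 3L] <= d[3L] - r[3L]
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(sprintf("detect_boutons: dropped %d maxima within half a VOI of a volume face", n_dropped))
  idx <- idx[ok, , drop = FALSE]; val <- val[ok]; pos <- pos[ok, , drop = FALSE]
  out <- data.frame(vy = idx[, 1L], vx = idx[, 2L], vz = idx[, 3L],
                    x_um = pos[, 1L], y_um = pos[, 2L], z_um = pos[, 3L],
                    peak = val)
  rownames(out) <- NULL
  out[order(out$vz, out$vy, out$vx), , drop = FALSE]
}

# logical mask of edge-shell voxels for a VOI of dims `nd` (y, x, z):
# voxel centers strictly within edge_shell_um of any VOI face
shell_mask <- function(nd, voxel_size_um, edge_shell_um) {
  near_face <- function(n, delta) {
    ctr <- (seq_len(n) - 0.5) * delta
    (ctr < edge_shell_um) | ((n * delta - ctr) < edge_shell_um)
  }
  fy <- near_face(nd[1L], voxel_size_um[1L])
  fx <- near_face(nd[2L], voxel_size_um[2L])
  fz <- near_face(nd[3L], voxel_size_um[3L])
  outer(outer(fy, fx, `|`), fz, `|`)
}

#' Score co-localization of a marker with Vgat in one bouton VOI
#'
#' Extracts the VOI around the bouton centroid in the Vgat and marker
#' channels, excludes edge-shell voxels whose Vgat intensity exceeds the
#' contamination threshold, regresses marker on Vgat over the included
#' voxels by ordinary least squares and returns the coefficient of
#' determination. A negative fitted slope returns the anticorrelation floor
#' (0.01) exactly; a slope of exactly zero returns the computed R^2.
#'
#' @param stack named list of 3-d channel arrays (must contain `vgat` and
#'   the requested marker).
#' @param centroid integer voxel indices (y, x, z) of the bouton center.
#' @param marker marker channel name, e.g. `"syp_tdt"`, `"syt12"`, `"yfp"`.
#' @param config a [coloc_config()].
#' @param voxel_size_um voxel size in um (y, x, z).
#' @param background optional list(mean, sd) of volume-wide Vgat background;
#'   computed by median/MAD when NULL.
#' @return list of class `bouton_score`: `score`, `slope`, `n_included`,
#'   `included_mask` (logical VOI block), `marker`.
#' @export
score_bouton <- function(stack, centroid, marker, config = coloc_config(),
                         voxel_size_um = c(0.1, 0.1, 0.2), background = NULL) {
  if (!marker %in% names(stack))
    stop(sprintf("marker channel '%s' absent from stack", marker), call. = FALSE)
  vgat <- stack$vgat
  r <- voi_radius(config, voxel_size_um)
  d <- dim(vgat)
  centroid <- as.integer(round(centroid))
  if (any(centroid - r < 1L) || any(centroid + r > d))
    stop("centroid does not admit a full VOI inside the volume", call. = FALSE)
  iy <- (centroid[1L] - r[1L]):(centroid[1L] + r[1L])
  ix <- (centroid[2L] - r[2L]):(centroid[2L] + r[2L])
  iz <- (centroid[3L] - r[3L]):(centroid[3L] + r[3L])
  v <- vgat[iy, ix, iz] * 1.0
  m <- stack[[marker]][iy, ix, iz] * 1.0
  if (is.null(background)) background <- background_stats(vgat)
  edge_thr <- background$mean + config$edge_intensity_k * background$sd
  sh <- shell_mask(dim(v), voxel_size_um, config$edge_shell_um)
  included <- !(sh & (v > edge_thr))
  n_inc <- sum(included)
  if (n_inc < config$min_voxels)
    stop(sprintf("degenerate VOI: only %d included voxels (min %d)", n_inc, config$min_voxels),
         call. = FALSE)
  a <- v[included]; b <- m[included]
  if (var(a) == 0)
    stop("degenerate VOI: zero Vgat variance over included voxels", call. = FALSE)
  fit <- stats::lm(b ~ a)
  slope <- unname(coef(fit)[2L])
  sst <- sum((b - mean(b))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 0
  score <- if (is.finite(slope) && slope < 0) config$anticorrelation_floor else r2
  structure(list(score = score, slope = slope, n_included = n_inc,
                 included_mask = included, marker = marker),
            class = "bouton_score")
}

#' Classify a bouton from its co-localization scores
#'
#' GlyT2 class: positive when the Vgat/Syp-TdT R^2 strictly exceeds the
#' positive threshold, negative when strictly below the negative threshold,
#' unclassified in between. Syt1/2 and YFP positivity use single strict
#' thresholds. A missing score (channel absent, value NA) leaves the
#' corresponding label NA, except that classifying GlyT2 requires the
#' Syp-TdT score.
#'
#' @param scores named list or vector with entries `r2_syp_tdt`,
#'   `r2_syt12`, `r2_yfp` (NA allowed for absent channels).
#' @param config a [coloc_config()].
#' @return list: `glyt2` ("pos", "neg" or "unclassified"), `syt12_pos`,
#'   `yfp_pos` (logical or NA).
#' @export
classify_bouton <- function(scores, config = coloc_config()) {
  th <- config$thresholds
  s <- as.list(scores)
  if (is.null(s$r2_syp_tdt) || is.na(s$r2_syp_tdt))
    stop("cannot classify GlyT2: score 'r2_syp_tdt' is missing", call. = FALSE)
  glyt2 <- if (s$r2_syp_tdt > th$glyt2_pos) "pos"
           else if (s$r2_syp_tdt < th$glyt2_neg) "neg"
           else "unclassified"
  syt12_pos <- if (is.null(s$r2_syt12) || is.na(s$r2_syt12)) NA else s$r2_syt12 > th$syt_pos
  yfp_pos <- if (is.null(s$r2_yfp) || is.na(s$r2_yfp)) NA else s$r2_yfp > th$yfp_pos
  list(glyt2 = glyt2, syt12_pos = syt12_pos, yfp_pos = yfp_pos)
}

#' Detect, score and classify every bouton in a volume
#'
#' End-to-end per-volume analysis: bouton detection on the Vgat channel,
#' per-marker R^2 scoring with edge masking, threshold classification, and
#' optional region assignment from a 2-d integer label image.
#'
#' @param stack named list of 3-d channel arrays; `vgat` required.
#' @param config a [coloc_config()].
#' @param voxel_size_um voxel size in um (y, x, z).
#' @param region_labels optional: either a 2-d integer/character label image
#'   `[y, x]` (region looked up at each centroid; 0 or "" means
#'   unassigned) or a character vector, one region per detected bouton.
#' @return data.frame, one row per bouton: centroid, per-marker scores
#'   (`r2_syp_tdt`, `r2_syt12`, `r2_yfp`; NA when the channel is absent),
#'   labels (`glyt2_label`, `syt12_pos`, `yfp_pos`), `n_included_voxels`,
#'   `region`.
#' @export
analyze_volume <- function(stack, config = coloc_config(),
                           voxel_size_um = c(0.1, 0.1, 0.2),
                           region_labels = NULL) {
  stopifnot("vgat" %in% names(stack))
  cent <- detect_boutons(stack$vgat, config, voxel_size_um)
  bg <- background_stats(stack$vgat)
  markers <- intersect(c("syp_tdt", "syt12", "yfp"), names(stack))
  n <- nrow(cent)
  sc <- matrix(NA_real_, nrow = n, ncol = 3L,
               dimnames = list(NULL, c("r2_syp_tdt", "r2_syt12", "r2_yfp")))
  n_inc <- integer(n)
  for (i in seq_len(n)) {
    ctr <- c(cent$vy[i], cent$vx[i], cent$vz[i])
    for (mk in markers) {
      s <- score_bouton(stack, ctr, mk, config, voxel_size_um, background = bg)
      sc[i, paste0("r2_", mk)] <- s$score
      n_inc[i] <- s$n_included
    }
  }
  glyt2 <- character(n); syt12_pos <- rep(NA, n); yfp_pos <- rep(NA, n)
  for (i in seq_len(n)) {
    lb <- classify_bouton(as.list(sc[i, ]), config)
    glyt2[i] <- lb$glyt2; syt12_pos[i] <- lb$syt12_pos; yfp_pos[i] <- lb$yfp_pos
  }
  region <- rep("unassigned", n)
  if (!is.null(region_labels)) {
    if (is.matrix(region_labels)) {
      lab <- region_labels[cbind(cent$vy, cent$vx)]
      region <- ifelse(is.na(lab) | lab == 0 | lab == "", "unassigned", as.character(lab))
    } else {
      stopifnot(length(region_labels) == n)
      region <- as.character(region_labels)
    }
  }
  out <- data.frame(id = seq_len(n), cent[, c("vy", "vx", "vz", "x_um", "y_um", "z_um")],
                    r2_syt12 = sc[, "r2_syt12"], r2_syp_tdt = sc[, "r2_syp_tdt"],
                    r2_yfp = sc[, "r2_yfp"], glyt2_label = glyt2,
                    syt12_pos = syt12_pos, yfp_pos = yfp_pos,
                    n_included_voxels = n_inc, region = region)
  rownames(out) <- NULL
  out
}

#' Summarize bouton composition per region
#'
#' Per region: bouton count, fraction GlyT2+ (among GlyT2-classified
#' boutons), R^2 histograms split by GlyT2 class, and contingency counts of
#' (YFP+ x Syt1/2+) and (GlyT2 class x Syt1/2+).
#'
#' @param boutons data.frame as returned by [analyze_volume()].
#' @param breaks histogram breaks for R^2 (default 0 to 1 by 0.05).
#' @return list of class `region_summary_list`: per-region lists with
#'   `region`, `n_boutons`, `fraction_glyt2_pos`, `r2_hist` (per class),
#'   `contingency_yfp_syt`, `contingency_glyt2_syt`; plus `$table`, a
#'   data.frame with one row per region.
#' @export
summarize_regions <- function(boutons, breaks = seq(0, 1, by = 0.05)) {
  stopifnot(is.data.frame(boutons))
  regions <- unique(boutons$region)
  per <- lapply(regions, function(rg) {
    b <- boutons[boutons$region == rg, , drop = FALSE]
    classified <- b$glyt2_label %in% c("pos", "neg")
    frac <- if (any(classified)) mean(b$glyt2_label[classified] == "pos") else NA_real_
    hist_by <- lapply(split(b$r2_syt12, b$glyt2_label), function(v) {
      v <- v[is.finite(v)]
      if (!length(v)) return(NULL)
      hist(pmin(pmax(v, min(breaks)), max(breaks)), breaks = breaks, plot = FALSE)$counts
    })
    cy <- table(factor(b$yfp_pos, levels = c(FALSE, TRUE)),
                factor(b$syt12_pos, levels = c(FALSE, TRUE)),
                dnn = c("yfp_pos", "syt12_pos"))
    cg <- table(factor(b$glyt2_label, levels = c("pos", "neg", "unclassified")),
                factor(b$syt12_pos, levels = c(FALSE, TRUE)),
                dnn = c("glyt2", "syt12_pos"))
    list(region = rg, n_boutons = nrow(b), fraction_glyt2_pos = frac,
         r2_hist = hist_by, r2_breaks = breaks,
         contingency_yfp_syt = cy, contingency_glyt2_syt = cg)
  })
  names(per) <- regions
  tab <- data.frame(
    region = regions,
    n_boutons = vapply(per, `[[`, 0L, "n_boutons"),
    fraction_glyt2_pos = vapply(per, `[[`, 0, "fraction_glyt2_pos"),
    n_yfp_pos = vapply(per, function(x) sum(x$contingency_yfp_syt["TRUE", ]), 0),
    n_syt12_pos = vapply(per, function(x) sum(x$contingency_yfp_syt[, "TRUE"]), 0),
    n_yfp_and_syt12 = vapply(per, function(x) x$contingency_yfp_syt["TRUE", "TRUE"], 0))
  rownames(tab) <- NULL
  structure(c(per, list(table = tab)), class = "region_summary_list")
}

#' @importFrom graphics hist
NULL
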