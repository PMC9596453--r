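# Synthetic two-channel fluorescence fields: nuclei blobs plus
# mitochondrial puncta whose radial dispersion around each nucleus is the
# phenotype (pathogenic = perinuclear, i.e. low dispersion).

# Add a radially symmetric Gaussian spot to a matrix, in place.
addSpot <- function(img, cx, cy, sigma, amplitude) {
  r <- ceiling(3 * sigma)
  xs <- max(1L, floor(cx - r)):min(nrow(img), ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(ncol(img), ceiling(cy + r))
  if (!length(xs) || !length(ys)) return(img)
  d2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
  img[xs, ys] <- img[xs, ys] + amplitude * exp(-d2 / (2 * sigma^2))
  img
}

#' Simulate one two-channel imaging field
#'
#' Channel 1 holds nuclei rendered as smooth Gaussian blobs; channel 2 holds
#' mitochondrial puncta placed around each nucleus at radial distances
#' `nucleus radius + Exp(mean = dispersion_um)`, so a small
#' `dispersion_um` yields perinuclear aggregation. Additive Gaussian
#' background noise on both channels; optional raft-grid walls and a
#' fiduciary mark. The returned truth lists every nucleus centroid and every
#' punctum.
#'
#' @param n_nuclei number of nuclei in the field.
#' @param dispersion_um mean radial dispersion of puncta beyond the nuclear
#'   boundary, in um (pathogenic default ~2, wild type ~8).
#' @param puncta_per_nucleus mean puncta count (Poisson; use a negative
#'   value `-k` for exactly k puncta per nucleus).
#' @param field_px field edge length in pixels (square field).
#' @param pixel_size_um microns per pixel (default 0.65).
#' @param nucleus_radius_um nuclear radius in um (default 6).
#' @param noise_sd additive Gaussian background noise SD (0 = noiseless).
#' @param raft_pitch_um raft edge length for wall rendering; 0 disables.
#' @param fiduciary render a fiduciary corner mark (default FALSE).
#' @param seed RNG seed.
#' @return list(nuclei, mito, truth): two numeric matrices and a truth list
#'   with `centroids` (x, y in pixels), `puncta_count` per nucleus and
#'   `puncta` (x, y, nucleus index).
#' @export
simulateImageField <- function(n_nuclei, dispersion_um = 8,
                               puncta_per_nucleus = 12, field_px = 256L,
                               pixel_size_um = 0.65, nucleus_radius_um = 6,
                               noise_sd = 0, raft_pitch_um = 0,
                               fiduciary = FALSE, seed = 1L) {
  if (field_px < 2L * nucleus_radius_um / pixel_size_um)
    stop("field smaller than one raft/nucleus")
  withSeed(seed, {
    nuc <- matrix(0, field_px, field_px)
    mito <- matrix(0, field_px, field_px)
    r_px <- nucleus_radius_um / pixel_size_um
    margin <- 3 * r_px
    # place nuclei with minimum separation so truth objects stay disjoint
    cx <- numeric(0); cy <- numeric(0)
    tries <- 0L
    while (length(cx) < n_nuclei && tries < 2000L) {
      px <- runif(1, margin, field_px - margin)
      py <- runif(1, margin, field_px - margin)
      if (!length(cx) || min((cx - px)^2 + (cy - py)^2) > (5 * r_px)^2) {
        cx <- c(cx, px); cy <- c(cy, py)
      }
      tries <- tries + 1L
    }
    n_placed <- length(cx)
    pts <- NULL
    counts <- integer(n_placed)
    for (i in seq_len(n_placed)) {
      nuc <- addSpot(nuc, cx[i], cy[i], sigma = r_px / 1.6, amplitude = 3000)
      k <- if (puncta_per_nucleus < 0) as.integer(-puncta_per_nucleus)
           else rpois(1, puncta_per_nucleus)
      counts[i] <- k
      if (k > 0) {
        # rejection-sample puncta positions with >= 4 px separation so each
        # punctum is a distinct object in the rendered image
        qx <- numeric(0); qy <- numeric(0)
        tries2 <- 0L
        while (length(qx) < k && tries2 < 400L) {
          ang <- runif(1, 0, 2 * pi)
          rad <- r_px + rexp(1, rate = pixel_size_um / max(dispersion_um, 1e-6))
          px <- min(max(cx[i] + rad * cos(ang), 2), field_px - 1)
          py <- min(max(cy[i] + rad * sin(ang), 2), field_px - 1)
          if (!length(qx) || min((qx - px)^2 + (qy - py)^2) >= 16) {
            qx <- c(qx, px); qy <- c(qy, py)
          }
          tries2 <- tries2 + 1L
        }
        counts[i] <- length(qx)
        for (j in seq_along(qx))
          mito <- addSpot(mito, qx[j], qy[j], sigma = 1, amplitude = 2000)
        pts <- rbind(pts, data.frame(x = qx, y = qy, nucleus = i))
      }
    }
    if (raft_pitch_um > 0) {
      pitch_px <- round(raft_pitch_um / pixel_size_um)
      idx <- seq(1L, field_px, by = pitch_px)
      nuc[idx, ] <- nuc[idx, ] + 400; nuc[, idx] <- nuc[, idx] + 400
      mito[idx, ] <- mito[idx, ] + 400; mito[, idx] <- mito[, idx] + 400
    }
    if (fiduciary) {
      sq <- seq_len(max(4L, round(10 / pixel_size_um)))
      nuc[sq, sq] <- 4000
    }
    if (noise_sd > 0) {
      nuc <- nuc + matrix(rnorm(field_px^2, 0, noise_sd), field_px)
      mito <- mito + matrix(rnorm(field_px^2, 0, noise_sd), field_px)
    }
    nuc <- pmax(nuc, 0); mito <- pmax(mito, 0)
    list(nuclei = nuc, mito = mito,
         truth = list(centroids = data.frame(x = cx, y = cy),
                      puncta_count = counts,
                      puncta = if (is.null(pts))
                        data.frame(x = numeric(0), y = numeric(0),
                                   nucleus = integer(0)) else pts))
  })
}

#' Simulate a set of fields for both phenotype classes
#'
#' Convenience wrapper producing `n_fields` fields per class with the
#' package's default pathogenic (perinuclear) and wild-type dispersions.
#'
#' @param n_fields fields per class.
#' @param n_nuclei nuclei per field.
#' @param dispersion_wt,dispersion_pathogenic mean radial dispersions (um).
#' @param seed master seed.
#' @param ... passed to [simulateImageField()].
#' @return named list of fields; names encode class and field index.
#' @export
simulateImages <- function(n_fields = 2L, n_nuclei = 8L, dispersion_wt = 8,
                           dispersion_pathogenic = 2, seed = 1L, ...) {
  out <- list()
  for (i in seq_len(n_fields)) {
    out[[paste0("WT_f", i)]] <- simulateImageField(
      n_nuclei, dispersion_um = dispersion_wt,
      seed = childSeed(seed, i), ...)
    out[[paste0("pathogenic_f", i)]] <- simulateImageField(
      n_nuclei, dispersion_um = dispersion_pathogenic,
      seed = childSeed(seed, 100 + i), ...)
  }
  out
}

#' Write a simulated field as 16-bit TIFF files (one per channel)
#'
#' @param field output of [simulateImageField()].
#' @param prefix path prefix; files `<prefix>_ch1.tif`, `<prefix>_ch2.tif`.
#' @return invisibly, the written paths.
#' @export
writeFieldTiff <- function(field, prefix) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF output")
  paths <- paste0(prefix, c("_ch1.tif", "_ch2.tif"))
  mx <- max(field$nuclei, field$mito, 1)
  tiff::writeTIFF(field$nuclei / mx, paths[1], bits.per.sample = 16L)
  tiff::writeTIFF(field$mito / mx, paths[2], bits.per.sample = 16L)
  invisible(paths)
}
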