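# Image front-end: nucleus segmentation, mitochondrial puncta detection and
# raft-grid mapping. A deliberately parameter-light stand-in for commercial
# tracing software, producing the same table schema as the simulator.

#' Encode raft grid indices as a four-character Raft ID
#'
#' Each axis (row, column; 0-based) is encoded as letter + digit with a
#' base-9 digit: index i maps to letter `'A' + i %/% 9` and digit
#' `(i %% 9) + 1`, so (0, 0) becomes "A1A1". The encoding is invertible for
#' up to 234 indices per axis ([decodeRaftId()]).
#'
#' @param row,col 0-based grid indices (vectorized).
#' @return character vector of 4-character raft IDs.
#' @examples
#' encodeRaftId(0, 0)   # "A1A1"
#' decodeRaftId("B3A7") # row 11, col 6
#' @export
encodeRaftId <- function(row, col) {
  enc <- function(i) {
    stopifnot(all(i >= 0L), all(i < 234L))
    paste0(LETTERS[i %/% 9L + 1L], i %% 9L + 1L)
  }
  paste0(enc(as.integer(row)), enc(as.integer(col)))
}

#' @rdname encodeRaftId
#' @param id character vector of raft IDs.
#' @return for `decodeRaftId`, a data.frame with 0-based `row`, `col`.
#' @export
decodeRaftId <- function(id) {
  stopifnot(all(nchar(id) == 4L))
  dec <- function(s) {
    (match(substr(s, 1, 1), LETTERS) - 1L) * 9L +
      as.integer(substr(s, 2, 2)) - 1L
  }
  data.frame(row = dec(substr(id, 1, 2)), col = dec(substr(id, 3, 4)))
}

#' Segment nuclei in a single-channel image
#'
#' Automatic bimodal (Otsu) thresholding, connected components and hole
#' filling, then per-object geometry and intensity. A blank image yields an
#' empty table, not an error.
#'
#' @param img numeric matrix (first index = x).
#' @param min_area minimum object area in pixels (default 10; smaller
#'   components are treated as noise specks).
#' @return data.frame: label, x, y (centroid, pixels), area, perimeter,
#'   form_factor (4*pi*A/P^2, clamped to 1 for discretization), mean and
#'   total intensity.
#' @export
segmentNuclei <- function(img, min_area = 10) {
  empty <- data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area = numeric(0), perimeter = numeric(0),
                      form_factor = numeric(0), mean_intensity = numeric(0),
                      total_intensity = numeric(0))
  if (diff(range(img)) == 0) return(empty)
  im <- EBImage::Image(img / max(img))
  th <- EBImage::otsu(im)
  mask <- EBImage::fillHull(EBImage::bwlabel(im > th))
  sh <- EBImage::computeFeatures.shape(mask)
  if (is.null(sh) || nrow(sh) == 0L) return(empty)
  mo <- EBImage::computeFeatures.moment(mask, im)
  labs <- as.numeric(EBImage::imageData(mask))
  ints <- as.numeric(img)
  tot <- tapply(ints[labs > 0], labs[labs > 0], sum)
  keep <- sh[, "s.area"] >= min_area
  out <- data.frame(
    label = seq_len(nrow(sh)),
    x = mo[, "m.cx"], y = mo[, "m.cy"],
    area = sh[, "s.area"], perimeter = sh[, "s.perimeter"],
    form_factor = pmin(1, 4 * pi * sh[, "s.area"] / sh[, "s.perimeter"]^2),
    mean_intensity = as.numeric(tot)[seq_len(nrow(sh))] / sh[, "s.area"],
    total_intensity = as.numeric(tot)[seq_len(nrow(sh))])
  rownames(out) <- NULL
  out[keep, , drop = FALSE]
}

#' Detect mitochondrial puncta and assign them to nuclei
#'
#' Puncta are local maxima of a band-pass (difference-of-Gaussians) filtered
#' image above an adaptive threshold (median + k * MAD of the filtered
#' image). Each punctum is assigned to the nearest nucleus if it lies within
#' 20 um of that nucleus's boundary (boundary distance = centroid distance
#' minus the equivalent circular radius), otherwise it is discarded.
#'
#' @param img mitochondria-channel matrix, aligned with the nuclei channel.
#' @param nuclei output of [segmentNuclei()] on the nuclei channel.
#' @param pixel_size_um microns per pixel.
#' @param k_mad adaptive threshold multiplier (default 5).
#' @param sigma_small,sigma_large band-pass scales in pixels (punctum radius
#'   and ~3x that).
#' @param max_dist_um assignment limit from the nucleus boundary (20 um).
#' @param band_um perinuclear band width from the boundary (default 5 um).
#' @return list with `puncta` (x, y, intensity, nucleus, centroid and
#'   boundary distances in um) and `per_nucleus` aggregation (count,
#'   total/mean intensity, mean and SD of centroid distance, fraction in the
#'   perinuclear band).
#' @export
detectMitoPuncta <- function(img, nuclei, pixel_size_um = 0.65, k_mad = 5,
                             sigma_small = 1, sigma_large = 3,
                             max_dist_um = 20, band_um = 5) {
  per0 <- data.frame(nucleus = integer(0), count = integer(0),
                     total_intensity = numeric(0), mean_intensity = numeric(0),
                     mean_dist_um = numeric(0), sd_dist_um = numeric(0),
                     frac_perinuclear = numeric(0))
  pts0 <- data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0),
                     nucleus = integer(0), dist_centroid_um = numeric(0),
                     dist_boundary_um = numeric(0))
  if (is.null(nuclei) || nrow(nuclei) == 0L)
    return(list(puncta = pts0, per_nucleus = per0))
  im <- EBImage::Image(img / max(img, 1))
  f <- EBImage::gblur(im, sigma = sigma_small) -
    EBImage::gblur(im, sigma = sigma_large)
  fm <- EBImage::imageData(f)
  s <- mad(fm)
  # noiseless fields have (numerically) zero MAD; fall back to a fraction
  # of the peak response so float-level ripples cannot pass
  thr <- if (s > 1e-9) median(fm) + k_mad * s else 0.1 * max(fm)
  loc <- EBImage::imageData(EBImage::dilate(f, EBImage::makeBrush(3, "box")))
  cand <- which(fm >= loc & fm > thr, arr.ind = TRUE)
  if (nrow(cand) > 1L) {
    # non-maximum suppression: one punctum per 2.5 px neighborhood
    o <- order(fm[cand], decreasing = TRUE)
    cand <- cand[o, , drop = FALSE]
    keep <- rep(TRUE, nrow(cand))
    for (i in seq_len(nrow(cand))[-1]) {
      prev <- cand[seq_len(i - 1L), , drop = FALSE][keep[seq_len(i - 1L)], ,
                                                    drop = FALSE]
      if (nrow(prev) &&
          min((prev[, 1] - cand[i, 1])^2 + (prev[, 2] - cand[i, 2])^2) <=
          2.5^2)
        keep[i] <- FALSE
    }
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(cand) == 0L) {
    per <- data.frame(nucleus = nuclei$label, count = 0L,
                      total_intensity = 0, mean_intensity = NA_real_,
                      mean_dist_um = NA_real_, sd_dist_um = NA_real_,
                      frac_perinuclear = NA_real_)
    return(list(puncta = pts0, per_nucleus = per))
  }
  px <- cand[, 1]; py <- cand[, 2]
  r_eq_um <- sqrt(nuclei$area / pi) * pixel_size_um
  dcent <- sqrt(outer(px, nuclei$x, "-")^2 + outer(py, nuclei$y, "-")^2) *
    pixel_size_um
  dbound <- sweep(dcent, 2, r_eq_um, "-")
  nearest <- apply(dbound, 1, which.min)
  dmin <- dbound[cbind(seq_along(nearest), nearest)]
  keep <- dmin <= max_dist_um
  pts <- data.frame(
    x = px[keep], y = py[keep],
    intensity = img[cbind(px, py)][keep],
    nucleus = nuclei$label[nearest[keep]],
    dist_centroid_um = dcent[cbind(seq_along(nearest), nearest)][keep],
    dist_boundary_um = dmin[keep])
  agg <- lapply(nuclei$label, function(l) {
    s <- pts[pts$nucleus == l, , drop = FALSE]
    data.frame(nucleus = l, count = nrow(s),
               total_intensity = sum(s$intensity),
               mean_intensity = if (nrow(s)) mean(s$intensity) else NA_real_,
               mean_dist_um = if (nrow(s)) mean(s$dist_centroid_um) else NA_real_,
               sd_dist_um = if (nrow(s) > 1) sd(s$dist_centroid_um) else NA_real_,
               frac_perinuclear = if (nrow(s))
                 mean(s$dist_boundary_um <= band_um) else NA_real_)
  })
  list(puncta = pts, per_nucleus = do.call(rbind, agg))
}

#' Fit the affine image-to-raft-grid transform from fiduciary marks
#'
#' Least-squares fit of continuous grid coordinates (u, v) against pixel or
#' stage coordinates (x, y). Needs at least three non-collinear points.
#'
#' @param fiducials data.frame with columns x, y (observed) and row, col
#'   (known 0-based grid indices of each fiduciary mark).
#' @return a 2x3 coefficient matrix `A` such that
#'   `c(u, v) = A %*% c(1, x, y)`.
#' @export
fitRaftTransform <- function(fiducials) {
  stopifnot(all(c("x", "y", "row", "col") %in% colnames(fiducials)))
  if (nrow(fiducials) < 3L)
    stop("calibration failure: need >= 3 fiduciary points")
  M <- cbind(1, fiducials$x, fiducials$y)
  if (qr(M)$rank < 3L)
    stop("calibration failure: fiduciary points are collinear")
  coef_u <- qr.solve(M, fiducials$row)
  coef_v <- qr.solve(M, fiducials$col)
  rbind(u = coef_u, v = coef_v)
}

#' Map cell detections to raft identities
#'
#' Converts per-field pixel coordinates to plate coordinates using the field
#' positions, fits the affine plate-to-grid transform from fiduciary
#' detections, de-duplicates cells appearing in overlapping field margins by
#' nearest-centroid matching, and encodes raft IDs.
#'
#' @param detections data.frame with columns x, y (pixels within the field)
#'   and optionally `field`.
#' @param fiducials fiduciary detections in plate coordinates (see
#'   [fitRaftTransform()]).
#' @param field_positions optional data.frame (field, offset_x, offset_y) in
#'   pixels; omitted if detections are already in plate coordinates.
#' @param dedup_tol_px centroid distance below which two detections from
#'   different fields are treated as the same cell (default 3).
#' @return list with `transform` (2x3 matrix), and `cells`: the retained
#'   detections with raft `row`, `col` and `raft_id` columns.
#' @export
mapRafts <- function(detections, fiducials, field_positions = NULL,
                     dedup_tol_px = 3) {
  det <- detections
  if (!is.null(field_positions)) {
    i <- match(det$field, field_positions$field)
    det$x <- det$x + field_positions$offset_x[i]
    det$y <- det$y + field_positions$offset_y[i]
  }
  A <- fitRaftTransform(fiducials)
  uv <- cbind(1, det$x, det$y) %*% t(A)
  det$row <- as.integer(round(uv[, 1]))
  det$col <- as.integer(round(uv[, 2]))
  # de-duplicate overlap-margin detections: same cell seen from two fields
  keep <- rep(TRUE, nrow(det))
  if (nrow(det) > 1L && !is.null(det$field)) {
    o <- order(det$field)
    for (a in seq_along(o)[-1]) {
      i <- o[a]
      prev <- o[seq_len(a - 1L)][keep[o[seq_len(a - 1L)]]]
      prev <- prev[det$field[prev] != det$field[i]]
      if (length(prev)) {
        d2 <- (det$x[prev] - det$x[i])^2 + (det$y[prev] - det$y[i])^2
        if (min(d2) <= dedup_tol_px^2) keep[i] <- FALSE
      }
    }
  }
  det <- det[keep, , drop = FALSE]
  det$raft_id <- encodeRaftId(det$row, det$col)
  rownames(det) <- NULL
  list(transform = A, cells = det)
}
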