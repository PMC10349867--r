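#' Binarize a single-channel image
#'
#' Default automatic threshold is Otsu's criterion (maximizing
#' between-class variance on a 256-bin histogram, equivalently minimizing
#' the intra-class variance), with a manual override.  Applying an
#' automatic method to a constant image is an error naming the degenerate
#' input.
#'
#' @param image numeric matrix (one channel).
#' @param method `"otsu"` or `"manual"`.
#' @param threshold numeric threshold, required for `method = "manual"`.
#' @return a list of class `binary_mask`: logical `mask` (foreground =
#'   biomass, `image > threshold`), the `threshold` used and the `method`.
#' @export
binarize <- function(image, method = c("otsu", "manual"), threshold = NULL) {
  method <- match.arg(method)
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix (single channel)")
  if (method == "manual") {
    stop_if_not_scalar_num(threshold, "threshold")
  } else {
    if (diff(range(image)) == 0)
      stop("constant image: automatic (Otsu) thresholding is undefined")
    threshold <- otsu_threshold(image)
  }
  structure(list(mask = image > threshold, threshold = threshold,
                 method = method), class = "binary_mask")
}

# Otsu threshold on a 256-bin histogram; returns a cut between populations
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.vector(image)
  rng <- range(v)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w <- cumsum(h); m <- cumsum(h * mids)
  n <- w[n_bins]; mu <- m[n_bins]
  w0 <- w[-n_bins]; m0 <- m[-n_bins]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, n_bins - 1L)
  between[valid] <- (mu * w0[valid] - n * m0[valid])^2 /
    (w0[valid] * w1[valid])
  k <- which.max(between)
  breaks[k + 1L]
}

as_mask <- function(x) {
  if (inherits(x, "binary_mask")) return(x$mask)
  if (is.matrix(x) && is.logical(x)) return(x)
  if (is.matrix(x) && is.numeric(x) && all(x %in% c(0, 1)))
    return(x > 0.5)
  stop("expected a logical mask or a binary_mask object")
}

shift_mat <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  ys <- seq_len(H) - dy; xs <- seq_len(W) - dx
  oky <- ys >= 1 & ys <= H; okx <- xs >= 1 & xs <= W
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

dilate8 <- function(m) {
  out <- m
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- out | shift_mat(m, dy, dx)
  }
  out
}

# connected component (8-connectivity) of `mask` that touches the seed region
connected_component <- function(mask, seed) {
  comp <- mask & seed
  repeat {
    grown <- mask & dilate8(comp)
    if (!any(grown & !comp)) break
    comp <- grown
  }
  comp
}

disk_mask <- function(H, W, cx, cy, r) {
  xs <- matrix(rep(seq_len(W) - 1, each = H), nrow = H)
  ys <- matrix(rep(seq_len(H) - 1, times = W), nrow = H)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

#' Detect circular grains in a binary mask
#'
#' Grain positions are normally known chip geometry; when a layout is
#' supplied it is validated against the image bounds and detection is
#' bypassed.  Otherwise candidate centers are the pixels whose full disk of
#' radius `expected_radius - tolerance` is foreground (morphological
#' erosion by a Euclidean disk); candidates are clustered by proximity and
#' each cluster contributes one geometry.  The radius estimate is refined
#' as the largest radius within the tolerance band whose disk stays
#' (almost) fully foreground — only meaningful where little biofilm
#' surrounds the grain, since a single biomass channel cannot separate
#' pillar from biofilm.
#'
#' @param mask logical matrix or [binarize()] result.
#' @param expected_radius expected grain radius in microns.
#' @param pixel_size microns per pixel.
#' @param tolerance radius tolerance in microns (default 2 px equivalent).
#' @param layout optional data frame `(x, y, radius_um)` of known grain
#'   geometry; bypasses detection after bounds validation.
#' @return a data frame `(grain_id, x, y, radius_um)`; empty (with a
#'   warning) when nothing is found.
#' @export
detect_grains <- function(mask, expected_radius, pixel_size = 0.5,
                          tolerance = NULL, layout = NULL) {
  mask <- as_mask(mask)
  H <- nrow(mask); W <- ncol(mask)
  stop_if_not_scalar_num(expected_radius, "expected_radius")
  if (expected_radius <= 0) stop("expected_radius must be > 0")
  if (!is.null(layout)) {
    r_px <- layout$radius_um / pixel_size
    bad <- layout$x - r_px < 0 | layout$x + r_px > W - 1 |
      layout$y - r_px < 0 | layout$y + r_px > H - 1
    if (any(bad)) stop("supplied layout places grain(s) outside image bounds")
    out <- data.frame(grain_id = seq_len(nrow(layout)), x = layout$x,
                      y = layout$y, radius_um = layout$radius_um)
    return(out)
  }
  tolerance <- tolerance %||% (2 * pixel_size)
  R_px <- expected_radius / pixel_size
  r_in <- max(1, R_px - tolerance / pixel_size)
  # erosion by a Euclidean disk via AND over all integer offsets inside it
  offs <- expand.grid(dy = -ceiling(r_in):ceiling(r_in),
                      dx = -ceiling(r_in):ceiling(r_in))
  offs <- offs[offs$dy^2 + offs$dx^2 <= r_in^2, ]
  eroded <- mask
  for (i in seq_len(nrow(offs))) {
    eroded <- eroded & shift_mat(mask, offs$dy[i], offs$dx[i])
    if (!any(eroded)) break
  }
  idx <- which(eroded, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warning("no grain candidate within tolerance")
    return(data.frame(grain_id = integer(0), x = numeric(0), y = numeric(0),
                      radius_um = numeric(0)))
  }
  pts <- data.frame(x = idx[, 2] - 1, y = idx[, 1] - 1)
  # cluster candidate centers: points within one radius of a cluster center
  centers <- list()
  members <- list()
  for (i in seq_len(nrow(pts))) {
    placed <- FALSE
    for (k in seq_along(centers)) {
      if (sum((unlist(centers[[k]]) - c(pts$x[i], pts$y[i]))^2) < R_px^2) {
        members[[k]] <- rbind(members[[k]], pts[i, ])
        centers[[k]] <- colMeans(members[[k]])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centers[[length(centers) + 1]] <- c(x = pts$x[i], y = pts$y[i])
      members[[length(members) + 1]] <- pts[i, ]
    }
  }
  out <- do.call(rbind, lapply(seq_along(centers), function(k) {
    cx <- centers[[k]][["x"]]; cy <- centers[[k]][["y"]]
    # refine radius over the tolerance band: largest disk ~fully foreground
    radii <- seq(r_in, R_px + tolerance / pixel_size, by = 0.25)
    best <- r_in
    for (r in radii) {
      d <- disk_mask(H, W, cx, cy, r)
      if (sum(mask & d) / sum(d) >= 0.995) best <- r else break
    }
    data.frame(x = cx, y = cy, radius_um = best * pixel_size)
  }))
  out <- out[order(out$y, out$x), , drop = FALSE]
  out <- data.frame(grain_id = seq_len(nrow(out)), out, row.names = NULL)
  out
}

#' Radial biofilm thickness profile around one grain
#'
#' Casts rays from the grain center at `n_angles` evenly spaced angles.
#' Along each ray the biofilm edge is the outermost point (sub-pixel, by
#' bilinear interpolation of the mask restricted to the connected component
#' touching the grain) that is still foreground; thickness is its distance
#' to the grain circle.  Distances are capped at `cap` (flagged per angle)
#' so that biofilm bridging neighboring grains is truncated rather than
#' attributed to one grain.
#'
#' @param mask logical matrix or [binarize()] result (foreground = grain
#'   pillars plus biomass).
#' @param center grain center `c(x, y)` in pixels (0-based).
#' @param radius_um grain radius in microns.
#' @param pixel_size microns per pixel.
#' @param n_angles number of rays (>= 36; default 360, i.e. 1 degree).
#' @param cap_um maximum measurable thickness in microns; default the
#'   distance from the grain surface to the nearest image border.
#' @param component restrict the measurement to the connected component
#'   (8-connectivity) touching the grain (default TRUE).
#' @return an object of class `biofilm_profile`: `angles` (radians),
#'   `thickness_um`, `capped` flags, plus the geometry and cap used.
#' @export
radial_profile <- function(mask, center, radius_um, pixel_size = 0.5,
                           n_angles = 360L, cap_um = NULL,
                           component = TRUE) {
  mask <- as_mask(mask)
  H <- nrow(mask); W <- ncol(mask)
  if (n_angles < 36) stop("n_angles must be >= 36")
  cx <- center[1]; cy <- center[2]
  R_px <- radius_um / pixel_size
  if (cx < 0 || cx > W - 1 || cy < 0 || cy > H - 1)
    stop("grain center outside mask bounds")
  border_px <- min(cx, cy, (W - 1) - cx, (H - 1) - cy)
  cap_um <- cap_um %||% ((border_px - R_px) * pixel_size)
  if (cap_um <= 0) stop("cap must be positive")
  cap_px <- cap_um / pixel_size

  if (!mask[round(cy) + 1, round(cx) + 1])
    warning("grain center is not on foreground (no pillar?); profile still computed")

  comp <- if (component) {
    connected_component(mask, disk_mask(H, W, cx, cy, R_px))
  } else mask
  compn <- comp * 1

  angles <- (seq_len(n_angles) - 1) * 2 * pi / n_angles
  step <- 0.1
  radii <- seq(R_px, R_px + cap_px, by = step)
  n_r <- length(radii)
  px_x <- cx + outer(cos(angles), radii)   # n_angles x n_r
  px_y <- cy + outer(sin(angles), radii)
  x0 <- floor(px_x); y0 <- floor(px_y)
  fx <- px_x - x0; fy <- px_y - y0
  at <- function(yy, xx) {
    ok <- yy >= 0 & yy <= H - 1 & xx >= 0 & xx <= W - 1
    out <- matrix(0, nrow(yy), ncol(yy))
    out[ok] <- compn[cbind(yy[ok] + 1, xx[ok] + 1)]
    out
  }
  interp <- at(y0, x0) * (1 - fx) * (1 - fy) +
    at(y0, x0 + 1) * fx * (1 - fy) +
    at(y0 + 1, x0) * (1 - fx) * fy +
    at(y0 + 1, x0 + 1) * fx * fy
  inside <- interp >= 0.5
  last <- apply(inside, 1, function(row) {
    w <- which(row)
    if (length(w) == 0) 0L else max(w)
  })
  thick_px <- ifelse(last == 0, 0, radii[pmax(last, 1)] - R_px)
  capped <- last == n_r
  structure(list(angles = angles,
                 thickness_um = pmin(thick_px, cap_px) * pixel_size,
                 capped = capped, center = c(x = cx, y = cy),
                 radius_um = radius_um, cap_um = cap_um,
                 pixel_size = pixel_size),
            class = "biofilm_profile")
}

#' Summary statistics of a biofilm thickness profile
#'
#' Mean thickness is the arithmetic mean over angles; roughness is the
#' population (divide-by-n) standard deviation of thickness over angles,
#' the interface-complexity proxy used for grain-scale biofilms.  Capped
#' angles enter with their capped value and are counted.
#'
#' @param profile a [radial_profile()] result.
#' @return a list `(mean_thickness_um, roughness_um, n_capped, n_angles)`.
#' @export
thickness_stats <- function(profile) {
  stopifnot(inherits(profile, "biofilm_profile"))
  th <- profile$thickness_um
  if (length(th) == 0) stop("empty profile")
  list(mean_thickness_um = mean(th), roughness_um = pop_sd(th),
       n_capped = sum(profile$capped), n_angles = length(th))
}

#' Genus area fractions within the biofilm
#'
#' The fraction of genus `g` is `area(channel_g & biofilm) / sum_h
#' area(channel_h & biofilm)` over the labeled genera, so fractions sum to
#' 1 whenever any labeled biofilm area exists.  Biofilm pixels labeled by
#' no probe are reported separately as `unassigned`.  A pixel positive in
#' several genus channels is assigned to the brightest one when channel
#' intensities are supplied (the count of such overlaps is reported);
#' without intensities it is counted for every positive channel.
#'
#' @param channel_masks named list of logical genus masks.
#' @param biofilm_mask logical biofilm mask of the same dimensions.
#' @param intensities optional named list of intensity matrices used to
#'   resolve multi-probe pixels.
#' @return a list with `fractions` (named, summing to 1), `areas_px`,
#'   `unassigned_px`, `overlap_px` and `flag` (`"ok"` or
#'   `"no_labeled_area"`, in which case fractions are `NA`).
#' @export
genus_area_fractions <- function(channel_masks, biofilm_mask,
                                 intensities = NULL) {
  biofilm_mask <- as_mask(biofilm_mask)
  masks <- lapply(channel_masks, as_mask)
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    stop("channel_masks must be a named list")
  for (m in masks)
    if (!identical(dim(m), dim(biofilm_mask)))
      stop("channel masks must match the biofilm mask dimensions")
  inb <- lapply(masks, function(m) m & biofilm_mask)
  count_pos <- Reduce(`+`, lapply(inb, function(m) m * 1L))
  overlap_px <- sum(count_pos > 1)
  if (overlap_px > 0 && !is.null(intensities)) {
    # winner-takes-all on brightness at contested pixels
    contested <- which(count_pos > 1)
    bright <- sapply(names(masks), function(nm) intensities[[nm]][contested])
    bright <- matrix(bright, nrow = length(contested))
    winner <- max.col(bright, ties.method = "first")
    for (k in seq_along(inb)) {
      drop <- contested[winner != k]
      inb[[k]][drop] <- FALSE
    }
  }
  areas <- vapply(inb, sum, numeric(1))
  total <- sum(areas)
  unassigned <- sum(biofilm_mask & count_pos == 0)
  if (total == 0) {
    return(list(fractions = setNames(rep(NA_real_, length(areas)),
                                     names(areas)),
                areas_px = areas, unassigned_px = unassigned,
                overlap_px = overlap_px, flag = "no_labeled_area"))
  }
  list(fractions = areas / total, areas_px = areas,
       unassigned_px = unassigned, overlap_px = overlap_px, flag = "ok")
}

#' Per-grain biofilm morphometrics for a whole scene
#'
#' Convenience wrapper: binarizes the biomass channel (Otsu, or a manual
#' 0.5 cut for noiseless synthetic scenes), measures every grain in the
#' layout via [radial_profile()] + [thickness_stats()], and appends genus
#' area fractions when genus channels are present.  The per-angle cap
#' defaults to half the minimum grain spacing minus the radius, so merged
#' biofilms between neighboring grains are truncated symmetrically.
#'
#' @param scene a `grain_scene` (or a list with `channels`, `layout`,
#'   `pixel_size`).
#' @param n_angles rays per grain (default 360).
#' @param threshold optional manual binarization threshold.
#' @return a data frame with one row per grain: `grain_id`,
#'   `mean_thickness_um`, `roughness_um`, `n_capped`, and `frac_*`
#'   columns for labeled genera.
#' @export
analyze_scene <- function(scene, n_angles = 360L, threshold = NULL) {
  bw <- if (is.null(threshold)) binarize(scene$channels$biomass)
        else binarize(scene$channels$biomass, "manual", threshold)
  layout <- scene$layout
  px <- scene$pixel_size
  cap_um <- NULL
  if (nrow(layout) > 1) {
    dmat <- as.matrix(dist(layout[, c("x", "y")]))
    diag(dmat) <- Inf
    cap_um <- min(dmat) / 2 * px - layout$radius_um[1]
  }
  res <- lapply(seq_len(nrow(layout)), function(g) {
    prof <- radial_profile(bw, c(layout$x[g], layout$y[g]),
                           layout$radius_um[g], px, n_angles = n_angles,
                           cap_um = cap_um)
    st <- thickness_stats(prof)
    data.frame(grain_id = layout$grain_id[g],
               mean_thickness_um = st$mean_thickness_um,
               roughness_um = st$roughness_um, n_capped = st$n_capped)
  })
  res <- do.call(rbind, res)
  if (!is.null(scene$genus_names)) {
    ch_masks <- lapply(scene$channels[scene$genus_names],
                       function(ch) ch > 0.5)
    fr <- genus_area_fractions(ch_masks, scene$masks$biofilm,
                               intensities = scene$channels[scene$genus_names])
    for (nm in names(fr$fractions))
      res[[paste0("frac_", nm)]] <- fr$fractions[[nm]]
  }
  res
}
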