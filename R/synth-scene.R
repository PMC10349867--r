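#' Specify a synthetic grain scene
#'
#' Describes a confocal-style 2-D field of view over an array of cylindrical
#' grains (pillars), each optionally coated by a biofilm annulus whose
#' thickness varies with angle.  The rendered scene is the stated world for
#' the imaging module: hard (non-anti-aliased) masks so that areas and
#' ground truth are exact.
#'
#' @param image_size integer `c(height, width)` in pixels.
#' @param pixel_size microns per pixel (default 0.5).
#' @param grain_centers numeric matrix with columns `x`, `y` (pixel
#'   coordinates, 0-based, pixel centers at integers).
#' @param grain_radius grain radius in microns.  The chip design uses
#'   pillars of 50 um diameter, hence the default 25.
#' @param thickness biofilm thickness field: a single number (uniform
#'   annulus), a function `f(theta)` returning microns for angles in
#'   radians, or a list with one entry per grain.
#' @param channel_mix named numeric vector of per-genus label probabilities
#'   for biofilm pixels (must sum to 1), e.g. `c(genusA = 0.7, genusB =
#'   0.3)`, or `NULL` for a single biomass channel.
#' @param noise_sd additive Gaussian intensity noise (intensity units).
#' @param seed integer seed; the whole render is deterministic given it.
#' @param allow_overlap logical; by default overlapping grains (including
#'   their biofilm annuli) are rejected.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(192L, 192L),
                       pixel_size = 0.5,
                       grain_centers = NULL,
                       grain_radius = 25,
                       thickness = 10,
                       channel_mix = NULL,
                       noise_sd = 0,
                       seed = 1L,
                       allow_overlap = FALSE) {
  stop_if_not_scalar_num(pixel_size, "pixel_size")
  stop_if_not_scalar_num(grain_radius, "grain_radius")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (grain_radius <= 0) stop("grain_radius must be > 0")
  image_size <- as.integer(image_size)
  if (is.null(grain_centers)) {
    grain_centers <- matrix((rev(image_size) - 1) / 2, ncol = 2)
  }
  grain_centers <- matrix(as.numeric(grain_centers), ncol = 2)
  colnames(grain_centers) <- c("x", "y")
  if (!is.null(channel_mix)) {
    if (is.null(names(channel_mix)) || any(!nzchar(names(channel_mix))))
      stop("channel_mix must be a named vector")
    if (any(channel_mix < 0) || abs(sum(channel_mix) - 1) > 1e-8)
      stop("channel_mix probabilities must be nonnegative and sum to 1")
  }
  structure(list(image_size = image_size, pixel_size = pixel_size,
                 grain_centers = grain_centers, grain_radius = grain_radius,
                 thickness = thickness, channel_mix = channel_mix,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 allow_overlap = isTRUE(allow_overlap)),
            class = "scene_spec")
}

# normalise the thickness field to a list of vectorised functions, one per grain
thickness_functions <- function(spec) {
  n <- nrow(spec$grain_centers)
  th <- spec$thickness
  as_fun <- function(x) {
    if (is.function(x)) return(x)
    stopifnot(is.numeric(x), length(x) == 1, x >= 0)
    function(theta) rep(x, length(theta))
  }
  if (is.list(th)) {
    if (length(th) != n) stop("thickness list must have one entry per grain")
    lapply(th, as_fun)
  } else {
    rep(list(as_fun(th)), n)
  }
}

#' Render a synthetic grain scene with analytic ground truth
#'
#' Foreground is the union of the grain disks and their biofilm annuli
#' (`r <= R + t(theta)`), rendered as hard masks on the pixel grid.  Ground
#' truth (per-grain mean thickness and roughness) is computed analytically
#' from the noiseless thickness field on a fine angular grid, never from the
#' rendered image.  Genus labels, when requested, are allocated exactly:
#' `round(p * n)` biofilm pixels per genus, so realized area fractions equal
#' the requested mix up to integer rounding.
#'
#' @param spec a [scene_spec()].
#' @return an object of class `grain_scene`: intensity `channels` (matrices,
#'   background 0.1, foreground 0.9 before noise), logical `masks`
#'   (`foreground`, `grain`, `biofilm`), a per-pixel genus `labels` matrix,
#'   the grain `layout`, and a `ground_truth` data frame with per-grain
#'   `mean_thickness_um`, `roughness_um` and genus area fractions.
#' @examples
#' sc <- make_grain_scene(scene_spec(thickness = 10, seed = 1))
#' sc$ground_truth
#' @export
make_grain_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, render_grain_scene(spec))
}

render_grain_scene <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  px <- spec$pixel_size
  R_px <- spec$grain_radius / px
  tfun <- thickness_functions(spec)
  n_grain <- nrow(spec$grain_centers)

  # analytic ground truth on a fine angular grid
  grid <- seq(0, 2 * pi, length.out = 3601)[-3601]
  gt <- lapply(seq_len(n_grain), function(g) {
    tt <- tfun[[g]](grid)
    if (any(tt < 0)) stop("thickness must be >= 0 everywhere")
    data.frame(grain_id = g, mean_thickness_um = mean(tt),
               roughness_um = pop_sd(tt), max_thickness_um = max(tt))
  })
  gt <- do.call(rbind, gt)

  # geometry checks: no overlap, grains inside bounds
  max_ext_px <- R_px + gt$max_thickness_um / px
  cx <- spec$grain_centers[, 1]; cy <- spec$grain_centers[, 2]
  if (any(cx - R_px < 0 | cx + R_px > W - 1 | cy - R_px < 0 | cy + R_px > H - 1))
    stop("grain disk extends outside image bounds")
  if (n_grain > 1 && !spec$allow_overlap) {
    dmat <- as.matrix(dist(spec$grain_centers))
    diag(dmat) <- Inf
    min_space <- min(dmat)
    if (any(max_ext_px >= min_space / 2))
      stop("grains (or their biofilm annuli) overlap; set allow_overlap = TRUE to force")
  }
  if (any(cx - max_ext_px < 0 | cx + max_ext_px > W - 1 |
          cy - max_ext_px < 0 | cy + max_ext_px > H - 1))
    warning("biofilm annulus clipped by the image border")

  xs <- matrix(rep(seq_len(W) - 1, each = H), nrow = H)
  ys <- matrix(rep(seq_len(H) - 1, times = W), nrow = H)

  fg <- matrix(FALSE, H, W)
  grain_mask <- matrix(FALSE, H, W)
  owner <- matrix(0L, H, W)   # grain id owning each foreground pixel
  for (g in seq_len(n_grain)) {
    dx <- xs - cx[g]; dy <- ys - cy[g]
    r <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx) %% (2 * pi)
    t_px <- tfun[[g]](as.vector(theta)) / px
    fg_g <- r <= R_px + matrix(t_px, H, W)
    grain_mask <- grain_mask | (r <= R_px)
    owner[fg_g] <- g
    fg <- fg | fg_g
  }
  biofilm <- fg & !grain_mask

  labels <- matrix(0L, H, W)
  genus_names <- names(spec$channel_mix)
  if (!is.null(spec$channel_mix)) {
    idx <- which(biofilm)
    n_bio <- length(idx)
    n_per <- round(spec$channel_mix * n_bio)
    # fix rounding drift on the last genus
    if (length(n_per) > 0) n_per[length(n_per)] <- n_bio - sum(n_per[-length(n_per)])
    shuffled <- sample(idx)
    offset <- 0L
    for (k in seq_along(n_per)) {
      if (n_per[k] > 0) labels[shuffled[offset + seq_len(n_per[k])]] <- k
      offset <- offset + n_per[k]
    }
  }

  noise <- function() {
    if (spec$noise_sd > 0) matrix(rnorm(H * W, 0, spec$noise_sd), H, W) else 0
  }
  channels <- list(biomass = 0.1 + 0.8 * fg + noise())
  if (!is.null(genus_names)) {
    for (k in seq_along(genus_names)) {
      channels[[genus_names[k]]] <- 0.1 + 0.8 * (labels == k) + noise()
    }
  }

  # per-grain realized genus fractions (structural labels, noise-free)
  if (!is.null(genus_names)) {
    for (nm in genus_names) gt[[paste0("frac_", nm)]] <- NA_real_
    for (g in seq_len(n_grain)) {
      sel <- owner == g & biofilm
      tot <- sum(labels[sel] > 0)
      for (k in seq_along(genus_names)) {
        gt[[paste0("frac_", genus_names[k])]][g] <-
          if (tot > 0) sum(labels[sel] == k) / tot else NA_real_
      }
    }
  }

  layout <- data.frame(grain_id = seq_len(n_grain), x = cx, y = cy,
                       radius_um = spec$grain_radius)
  structure(list(channels = channels,
                 channel_roles = c(biomass = "biomass",
                                   setNames(rep("genus", length(genus_names)),
                                            genus_names))[c("biomass", genus_names)],
                 pixel_size = px,
                 masks = list(foreground = fg, grain = grain_mask,
                              biofilm = biofilm),
                 labels = labels, genus_names = genus_names,
                 layout = layout, ground_truth = gt, spec = spec),
            class = "grain_scene")
}

#' @export
print.grain_scene <- function(x, ...) {
  cat(sprintf("grain_scene: %d x %d px (%.2f um/px), %d grain(s), %d channel(s)\n",
              nrow(x$channels[[1]]), ncol(x$channels[[1]]), x$pixel_size,
              nrow(x$layout), length(x$channels)))
  print(x$ground_truth, row.names = FALSE)
  invisible(x)
}

#' Write / read a grain scene as plain-text CSV
#'
#' Images are stored as one CSV matrix per channel plus a layout and a
#' ground-truth table.  (TIFF is deliberately not used: the package keeps
#' all artifacts in text formats.)
#'
#' @param scene a `grain_scene`.
#' @param dir output directory (created if missing).
#' @param name file-name stem.
#' @return `write_scene` returns the vector of files written (invisibly);
#'   `read_scene_channel` returns a numeric matrix.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (ch in names(scene$channels)) {
    f <- file.path(dir, sprintf("%s_%s.csv", name, ch))
    write.table(round(scene$channels[[ch]], 4), f, sep = ",",
                row.names = FALSE, col.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, sprintf("%s_layout.csv", name))
  write.csv(scene$layout, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, sprintf("%s_ground_truth.csv", name))
  write.csv(scene$ground_truth, f, row.names = FALSE)
  invisible(c(files, f))
}

#' @rdname write_scene
#' @param path CSV file holding a single channel matrix.
#' @export
read_scene_channel <- function(path) {
  as.matrix(read.csv(path, header = FALSE))
}
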