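#' Vessel phantom primitives
#'
#' Continuous-geometry building blocks for synthetic OCTA-like phantoms.
#' Coordinates are `(row, col)` in pixels (origin top-left); angles use the
#' mathematical convention (x = columns rightwards, y = rows upwards).
#'
#' @param from,to segment endpoints, `c(row, col)`.
#' @param width full vessel width in pixels (>= 1).
#' @name phantom_primitives
NULL

#' @rdname phantom_primitives
#' @export
ph_segment <- function(from, to, width = 5) {
  stopifnot(length(from) == 2, length(to) == 2, width >= 1)
  structure(list(type = "segment", from = as.numeric(from),
                 to = as.numeric(to), width = width), class = "ph_primitive")
}

#' @rdname phantom_primitives
#' @param center arc/disc centre, `c(row, col)`.
#' @param radius arc/disc radius in pixels.
#' @param theta_start,theta_end arc angular range in radians
#'   (`theta_end > theta_start`, span at most `2*pi`).
#' @export
ph_arc <- function(center, radius, theta_start, theta_end, width = 5) {
  stopifnot(length(center) == 2, radius > 0, theta_end > theta_start,
            theta_end - theta_start <= 2 * pi + 1e-9, width >= 1)
  structure(list(type = "arc", center = as.numeric(center), radius = radius,
                 theta_start = theta_start, theta_end = theta_end,
                 width = width), class = "ph_primitive")
}

#' @rdname phantom_primitives
#' @export
ph_disc <- function(center, radius) {
  stopifnot(length(center) == 2, radius > 0)
  structure(list(type = "disc", center = as.numeric(center), radius = radius),
            class = "ph_primitive")
}

#' @rdname phantom_primitives
#' @param root tree root, `c(row, col)`.
#' @param angle trunk direction in radians.
#' @param length trunk length in pixels.
#' @param levels number of bifurcation generations (`levels = 2` gives 3
#'   internal branch points).
#' @param spread half-angle between sibling branches, radians.
#' @param decay length ratio of child to parent branch.
#' @export
ph_tree <- function(root, angle = pi / 2, length = 200, levels = 2,
                    spread = 0.5, decay = 0.7, width = 5) {
  stopifnot(levels >= 0, length > 0, decay > 0, width >= 1)
  segs <- list()
  grow <- function(p, ang, len, lev) {
    tip <- c(p[1] - len * sin(ang), p[2] + len * cos(ang))
    segs[[base::length(segs) + 1L]] <<- ph_segment(p, tip, width)
    if (lev > 0) {
      grow(tip, ang + spread, len * decay, lev - 1)
      grow(tip, ang - spread, len * decay, lev - 1)
    }
  }
  grow(as.numeric(root), angle, length, levels)
  structure(list(type = "tree", segments = segs, width = width),
            class = "ph_primitive")
}

#' Specification of a synthetic vascular phantom
#'
#' Defines a phantom emulating the imaging characteristics of en-face OCTA:
#' bright vessels (default intensity 200) on a dark lesion background
#' (default 20), 8-bit depth, 1024x1024 canvas at 170 px/mm, multiplicative
#' speckle-like noise. Geometry and noise are independent: the seed affects
#' only the noise realization.
#'
#' @param primitives list of [ph_segment()]/[ph_arc()]/[ph_disc()]/[ph_tree()].
#' @param canvas `c(rows, cols)` in pixels.
#' @param scale pixels per mm.
#' @param speckle multiplicative speckle strength `s`: each ROI pixel is
#'   multiplied by `1 + s * U(-1, 1)`; 0 disables.
#' @param background_sigma additive Gaussian noise sd inside the ROI.
#' @param vessel_intensity,background_intensity 8-bit levels of vessel and
#'   lesion background.
#' @param roi optional explicit logical ROI mask (canvas shape); by default
#'   the bounding box of the rendered vessels padded by `roi_pad` pixels.
#' @param roi_pad padding of the automatic bounding-box ROI, pixels.
#' @param seed integer seed for the noise realization.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(primitives, canvas = c(1024, 1024), scale = 170,
                         speckle = 0, background_sigma = 0,
                         vessel_intensity = 200, background_intensity = 20,
                         roi = NULL, roi_pad = 25, seed = 1) {
  stopifnot(length(canvas) == 2, all(canvas >= 8), scale > 0,
            speckle >= 0, background_sigma >= 0)
  if (inherits(primitives, "ph_primitive")) primitives <- list(primitives)
  structure(list(primitives = primitives, canvas = as.integer(canvas),
                 scale = scale, speckle = speckle,
                 background_sigma = background_sigma,
                 vessel_intensity = vessel_intensity,
                 background_intensity = background_intensity,
                 roi = roi, roi_pad = roi_pad, seed = as.integer(seed)),
            class = "phantom_spec")
}

# flatten trees into their segments; returns list of segment/arc/disc parts
flatten_primitives <- function(primitives) {
  out <- list()
  for (p in primitives) {
    if (p$type == "tree") out <- c(out, p$segments) else out <- c(out, list(p))
  }
  out
}

# rasterize one primitive into a logical canvas (distance-based, round caps
# for segments, butt ends for arcs)
rasterize_primitive <- function(p, canvas) {
  h <- canvas[1]; w <- canvas[2]
  mask <- matrix(FALSE, h, w)
  if (p$type == "segment") {
    hw <- p$width / 2
    r0 <- max(1, floor(min(p$from[1], p$to[1]) - hw - 1))
    r1 <- min(h, ceiling(max(p$from[1], p$to[1]) + hw + 1))
    c0 <- max(1, floor(min(p$from[2], p$to[2]) - hw - 1))
    c1 <- min(w, ceiling(max(p$from[2], p$to[2]) + hw + 1))
    rr <- r0:r1; cc <- c0:c1
    dr <- p$to[1] - p$from[1]; dc <- p$to[2] - p$from[2]
    len2 <- dr^2 + dc^2
    R <- matrix(rr, length(rr), length(cc))
    C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
    t <- if (len2 == 0) 0 else
      pmin(pmax(((R - p$from[1]) * dr + (C - p$from[2]) * dc) / len2, 0), 1)
    d2 <- (R - (p$from[1] + t * dr))^2 + (C - (p$from[2] + t * dc))^2
    mask[rr, cc] <- d2 <= hw^2
  } else if (p$type == "arc") {
    hw <- p$width / 2
    e <- p$radius + hw + 1
    r0 <- max(1, floor(p$center[1] - e)); r1 <- min(h, ceiling(p$center[1] + e))
    c0 <- max(1, floor(p$center[2] - e)); c1 <- min(w, ceiling(p$center[2] + e))
    rr <- r0:r1; cc <- c0:c1
    R <- matrix(rr, length(rr), length(cc))
    C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
    x <- C - p$center[2]; y <- p$center[1] - R  # math convention, y upward
    th <- atan2(y, x)
    span <- p$theta_end - p$theta_start
    rel <- (th - p$theta_start) %% (2 * pi)
    d <- abs(sqrt(x^2 + y^2) - p$radius)
    mask[rr, cc] <- d <= hw & rel <= span
  } else if (p$type == "disc") {
    e <- p$radius + 1
    r0 <- max(1, floor(p$center[1] - e)); r1 <- min(h, ceiling(p$center[1] + e))
    c0 <- max(1, floor(p$center[2] - e)); c1 <- min(w, ceiling(p$center[2] + e))
    rr <- r0:r1; cc <- c0:c1
    R <- matrix(rr, length(rr), length(cc))
    C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
    mask[rr, cc] <- (R - p$center[1])^2 + (C - p$center[2])^2 <= p$radius^2
  }
  mask
}

# analytic centerline-topology analysis of segments and arcs: returns
# junction and endpoint counts from continuous geometry (tol in pixels)
centerline_topology <- function(parts, tol = 0.75) {
  arms <- list()  # each: list(pt = c(r, c), n = arm count)
  add_arms <- function(pt, n) arms[[length(arms) + 1L]] <<- list(pt = pt, n = n)
  segs <- Filter(function(p) p$type == "segment", parts)
  arcs <- Filter(function(p) p$type == "arc", parts)
  for (s in segs) { add_arms(s$from, 1); add_arms(s$to, 1) }
  for (a in arcs) {
    for (th in c(a$theta_start, a$theta_end))
      add_arms(c(a$center[1] - a$radius * sin(th),
                 a$center[2] + a$radius * cos(th)), 1)
  }
  ns <- length(segs)
  on_interior <- function(pt, s) {
    dr <- s$to[1] - s$from[1]; dc <- s$to[2] - s$from[2]
    len2 <- dr^2 + dc^2
    t <- ((pt[1] - s$from[1]) * dr + (pt[2] - s$from[2]) * dc) / len2
    if (t < tol / sqrt(len2) || t > 1 - tol / sqrt(len2)) return(FALSE)
    d2 <- (pt[1] - (s$from[1] + t * dr))^2 + (pt[2] - (s$from[2] + t * dc))^2
    d2 <= tol^2
  }
  if (ns >= 2) {
    for (i in 1:(ns - 1)) for (j in (i + 1):ns) {
      a <- segs[[i]]; b <- segs[[j]]
      d1 <- a$to - a$from; d2v <- b$to - b$from
      den <- d1[1] * d2v[2] - d1[2] * d2v[1]
      if (abs(den) > 1e-12) {
        w0 <- b$from - a$from
        t <- (w0[1] * d2v[2] - w0[2] * d2v[1]) / den
        u <- (w0[1] * d1[2] - w0[2] * d1[1]) / den
        la <- sqrt(sum(d1^2)); lb <- sqrt(sum(d2v^2))
        ta <- tol / la; tb <- tol / lb
        if (t > ta && t < 1 - ta && u > tb && u < 1 - tb) {
          add_arms(a$from + t * d1, 4)     # proper interior crossing
        } else {
          # T contact: an endpoint of one lying on the interior of the other
          for (pt in list(b$from, b$to))
            if (on_interior(pt, a)) add_arms(pt, 2)
          for (pt in list(a$from, a$to))
            if (on_interior(pt, b)) add_arms(pt, 2)
        }
      } else {
        for (pt in list(b$from, b$to))
          if (on_interior(pt, a)) add_arms(pt, 2)
        for (pt in list(a$from, a$to))
          if (on_interior(pt, b)) add_arms(pt, 2)
      }
    }
  }
  if (length(arms) == 0)
    return(list(n_junctions = 0L, n_endpoints = 0L))
  pts <- do.call(rbind, lapply(arms, `[[`, "pt"))
  cnt <- vapply(arms, `[[`, numeric(1), "n")
  used <- rep(FALSE, nrow(pts))
  deg <- integer(0)
  for (i in seq_len(nrow(pts))) {
    if (used[i]) next
    near <- which(!used &
                    (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2 <= tol^2)
    used[near] <- TRUE
    deg <- c(deg, sum(cnt[near]))
  }
  list(n_junctions = sum(deg >= 3), n_endpoints = sum(deg == 1))
}

#' Render a phantom with analytic ground truth
#'
#' Rasterizes the phantom's vessels on the lesion background, clears everything
#' outside the ROI, applies seeded multiplicative speckle (and optional
#' additive Gaussian) noise, and returns the exact ground truth computed from
#' the continuous primitives (not from the rendered pixels), so downstream
#' tolerance checks honestly absorb discretization error.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `image` ([raster_image()]), `roi` ([roi_mask()]),
#'   `vessel_mask` (noiseless logical vessel mask), and `truth`: lesion area
#'   mm^2, vessel area mm^2 (pixel count of the true mask), centerline
#'   length mm, mean width um, junction and endpoint counts, mean arc-chord
#'   ratio (`tortuosity`).
#' @export
render_phantom <- function(spec) {
  h <- spec$canvas[1]; w <- spec$canvas[2]
  parts <- flatten_primitives(spec$primitives)
  vmask <- matrix(FALSE, h, w)
  for (p in parts) vmask <- vmask | rasterize_primitive(p, spec$canvas)

  if (is.null(spec$roi)) {
    idx <- which(vmask, arr.ind = TRUE)
    if (nrow(idx) == 0) stop("phantom renders no vessel pixels")
    r0 <- max(1, min(idx[, 1]) - spec$roi_pad)
    r1 <- min(h, max(idx[, 1]) + spec$roi_pad)
    c0 <- max(1, min(idx[, 2]) - spec$roi_pad)
    c1 <- min(w, max(idx[, 2]) + spec$roi_pad)
    roi <- matrix(FALSE, h, w)
    roi[r0:r1, c0:c1] <- TRUE
  } else {
    roi <- spec$roi
    if (!all(dim(roi) == c(h, w))) stop("explicit ROI shape mismatch")
    if (any(vmask & !roi))
      stop("primitive outside ROI: vessels must lie inside the lesion mask")
  }

  px <- matrix(0, h, w)
  px[roi] <- spec$background_intensity
  px[vmask] <- spec$vessel_intensity

  if (spec$speckle > 0 || spec$background_sigma > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(spec$seed)
    n <- sum(roi)
    v <- px[roi]
    if (spec$speckle > 0)
      v <- v * (1 + spec$speckle * stats::runif(n, -1, 1))
    if (spec$background_sigma > 0)
      v <- v + stats::rnorm(n, 0, spec$background_sigma)
    px[roi] <- v
    px <- pmin(pmax(round(px), 0), 255)
  }

  # ground truth from continuous geometry
  seg_len <- function(p) switch(p$type,
    segment = sqrt(sum((p$to - p$from)^2)),
    arc = p$radius * (p$theta_end - p$theta_start),
    disc = 0)
  lens <- vapply(parts, seg_len, numeric(1))
  widths <- vapply(parts, function(p) if (p$type == "disc") NA_real_ else p$width,
                   numeric(1))
  total_len_px <- sum(lens)
  mean_width_um <- if (total_len_px > 0)
    sum(widths * lens, na.rm = TRUE) / total_len_px / spec$scale * 1000 else NA_real_
  arcchord <- vapply(parts, function(p) {
    if (p$type == "segment") return(1)
    if (p$type == "arc") {
      span <- p$theta_end - p$theta_start
      chord <- 2 * p$radius * sin(min(span, 2 * pi - 1e-9) / 2)
      if (chord <= 0) return(NA_real_)
      return(p$radius * span / chord)
    }
    NA_real_
  }, numeric(1))
  topo <- centerline_topology(parts)
  has_centerline <- any(vapply(parts, function(p)
    p$type %in% c("segment", "arc"), logical(1)))
  if (!has_centerline) {
    # disc-only phantoms define no centerline: skeletal truths are missing
    topo <- list(n_junctions = NA_integer_, n_endpoints = NA_integer_)
    total_len_px <- NA_real_
  }

  truth <- list(
    mcnv_area_mm2 = sum(roi) / spec$scale^2,
    vessel_area_mm2 = sum(vmask) / spec$scale^2,
    length_mm = total_len_px / spec$scale,
    mean_width_um = mean_width_um,
    n_junctions = topo$n_junctions,
    n_endpoints = topo$n_endpoints,
    tortuosity = if (all(is.na(arcchord))) NA_real_ else mean(arcchord, na.rm = TRUE)
  )
  list(image = raster_image(px, spec$scale),
       roi = roi_mask(roi, if (is.null(spec$roi))
         "derived-from-cleared-background" else "explicit-mask-file"),
       vessel_mask = vmask,
       truth = truth)
}

#' Standard phantom battery
#'
#' The geometric battery used throughout the test suite: straight line,
#' half-circle arc, "+" cross, "H" shape, a 2-level bifurcating tree
#' (3 internal branch points) and a filled disc — each noiseless and with
#' multiplicative speckle of the given strength. Geometry never depends on
#' the seed; only noise realizations do.
#'
#' @param canvas,scale,width canvas size (px), pixel scale (px/mm) and vessel
#'   width (px) shared by all items.
#' @param speckle speckle strength of the noisy variants.
#' @param seed noise seed.
#' @return Named list of [phantom_spec()] objects (`*_noisy` variants
#'   included).
#' @export
battery_specs <- function(canvas = c(1024, 1024), scale = 170, width = 5,
                          speckle = 0.2, seed = 1) {
  h <- canvas[1]; w <- canvas[2]
  cr <- round(h / 2); cc <- round(w / 2)
  u <- min(h, w)
  s <- function(...) phantom_spec(list(...), canvas = canvas, scale = scale,
                                  seed = seed)
  geom <- list(
    line = s(ph_segment(c(cr, cc - round(0.29 * u)), c(cr, cc + round(0.29 * u)),
                        width)),
    arc = s(ph_arc(c(cr + round(0.17 * u), cc), round(0.2 * u), 0, pi, width)),
    cross = s(ph_segment(c(cr, cc - round(0.2 * u)), c(cr, cc + round(0.2 * u)),
                         width),
              ph_segment(c(cr - round(0.2 * u), cc), c(cr + round(0.2 * u), cc),
                         width)),
    h = s(ph_segment(c(cr - round(0.2 * u), cc - round(0.1 * u)),
                     c(cr + round(0.2 * u), cc - round(0.1 * u)), width),
          ph_segment(c(cr - round(0.2 * u), cc + round(0.1 * u)),
                     c(cr + round(0.2 * u), cc + round(0.1 * u)), width),
          ph_segment(c(cr, cc - round(0.1 * u)), c(cr, cc + round(0.1 * u)),
                     width)),
    tree = s(ph_tree(c(cr + round(0.33 * u), cc), angle = pi / 2,
                     length = round(0.21 * u), levels = 2, spread = 0.5,
                     decay = 0.7, width = width)),
    disc = s(ph_disc(c(cr, cc), round(0.15 * u)))
  )
  noisy <- lapply(geom, function(sp) { sp$speckle <- speckle; sp })
  names(noisy) <- paste0(names(geom), "_noisy")
  c(geom, noisy)
}

#' Write the phantom battery to disk
#'
#' Renders the [battery_specs()] battery and writes, per item, the image
#' (`<name>.tif`), its ROI mask (`<name>_mask.tif`) and one row in a
#' tab-delimited ground-truth table (`ground_truth.tsv`). Changing the seed
#' changes only the noise realizations, never the geometry columns.
#'
#' @param out_dir output directory (created if needed).
#' @param seed noise seed.
#' @param canvas,scale,width,speckle forwarded to [battery_specs()].
#' @return Invisibly, the ground-truth data frame.
#' @export
make_test_suite <- function(out_dir, seed = 1, canvas = c(1024, 1024),
                            scale = 170, width = 5, speckle = 0.2) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  specs <- battery_specs(canvas = canvas, scale = scale, width = width,
                         speckle = speckle, seed = seed)
  rows <- list()
  for (nm in names(specs)) {
    ph <- render_phantom(specs[[nm]])
    write_image(ph$image, file.path(out_dir, paste0(nm, ".tif")))
    write_image(ph$roi$mask * 255, file.path(out_dir, paste0(nm, "_mask.tif")))
    tr <- ph$truth
    rows[[nm]] <- data.frame(name = nm, speckle = specs[[nm]]$speckle,
                             mcnv_area_mm2 = tr$mcnv_area_mm2,
                             vessel_area_mm2 = tr$vessel_area_mm2,
                             length_mm = tr$length_mm,
                             mean_width_um = tr$mean_width_um,
                             n_junctions = tr$n_junctions,
                             n_endpoints = tr$n_endpoints,
                             tortuosity = tr$tortuosity,
                             stringsAsFactors = FALSE)
  }
  gt <- do.call(rbind, rows)
  rownames(gt) <- NULL
  write.table(gt, file.path(out_dir, "ground_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(gt)
}
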