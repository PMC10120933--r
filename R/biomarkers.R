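#' Lesion (mCNV) area
#'
#' Area of the delineated lesion in mm^2, obtained by counting the pixels
#' inside the contour and dividing by the squared pixel scale.
#'
#' @param roi a [roi_mask()].
#' @param scale pixels per mm.
#' @return Area in mm^2.
#' @export
mcnv_area <- function(roi, scale) {
  n <- sum(roi$mask)
  if (n == 0) stop("empty ROI")
  n / scale^2
}

#' Vessel area and vessel density
#'
#' Vessel area is the vessel-pixel count divided by the squared pixel scale;
#' vessel density is the ratio of vessel area to the lesion area, a
#' dimensionless value in `[0, 1]`.
#'
#' @param vessels a [vessel_map()]; pixels outside the ROI are ignored.
#' @param roi a [roi_mask()].
#' @return A list with `vessel_area_mm2` and `vessel_density`.
#' @export
vessel_area_and_density <- function(vessels, roi) {
  m <- vessels$mask & roi$mask
  area <- sum(m) / vessels$scale^2
  list(vessel_area_mm2 = area,
       vessel_density = area / mcnv_area(roi, vessels$scale))
}

#' Total vessel (centerline) length
#'
#' Sum of the geodesic lengths of all skeleton branches, in mm; the total
#' neovascular length of the lesion.
#'
#' @param graph a pruned `skeleton_graph`.
#' @return Length in mm (0 for an empty graph).
#' @export
vessel_length <- function(graph) {
  if (nrow(graph$branches) == 0) return(0)
  sum(graph$branches$geodesic_mm)
}

#' Number of vessel junctions
#'
#' Count of junction nodes — points where three or more branches meet. Each
#' 8-connected cluster of junction pixels counts once.
#'
#' @param graph a pruned `skeleton_graph`.
#' @return Integer count.
#' @export
count_junctions <- function(graph) {
  sum(graph$nodes$kind == "junction")
}

#' Junction density
#'
#' Junctions per millimetre of vessel: the number of junctions divided by
#' the total vessel length. Undefined (NA) when the length is zero.
#'
#' @param junctions junction count.
#' @param length vessel length in mm.
#' @return Junctions per mm, or `NA` when `length` is not positive.
#' @export
junction_density <- function(junctions, length) {
  if (!is.finite(length) || length <= 0) return(NA_real_)
  junctions / length
}

#' Mean vessel diameter
#'
#' Mean vessel caliber in micrometres, estimated as the vessel-mask area
#' divided by the centerline length: `diameter_um = area / length * 1000`.
#' Undefined (NA) when the length is zero.
#'
#' @param vessel_area vessel area in mm^2.
#' @param length vessel (centerline) length in mm.
#' @return Diameter in micrometres, or `NA`.
#' @export
vessel_diameter <- function(vessel_area, length) {
  if (!is.finite(length) || length <= 0) return(NA_real_)
  vessel_area / length * 1000
}

#' Vascular tortuosity
#'
#' Mean over branches of the arc-chord ratio: geodesic branch length divided
#' by the straight-line distance between the branch's end nodes. Straight
#' vessels give 1; larger values indicate more convoluted microvasculature.
#' Closed loops (zero Euclidean length) are excluded.
#'
#' @param graph a pruned `skeleton_graph`.
#' @param weighted if `TRUE`, branches are weighted by geodesic length.
#' @return Dimensionless ratio `>= 1`, or `NA` when no branch qualifies.
#' @export
tortuosity <- function(graph, weighted = FALSE) {
  b <- graph$branches
  q <- b$euclidean_mm > 0
  if (!any(q)) return(NA_real_)
  ratio <- b$geodesic_mm[q] / b$euclidean_mm[q]
  if (weighted) sum(ratio * b$geodesic_mm[q]) / sum(b$geodesic_mm[q])
  else mean(ratio)
}

#' Box-counting fractal dimension
#'
#' Covers the skeleton with an `s x s` grid anchored at the image origin and
#' counts the occupied cells `N(s)` for each box size. The fractal dimension
#' `D_box` is the least-squares slope of `log N(s)` against `log(1/s)`, so a
#' straight line gives about 1 and a filled region about 2. The default box
#' sizes `{2, 3, 4, 6, 8, 12, 16, 32, 64}` are clipped to at most half the
#' smaller image side; at least 3 usable sizes are required.
#'
#' @param skeleton a [vessel_map()] (or logical matrix) of the pruned
#'   skeleton.
#' @param box_sizes box edge lengths in pixels.
#' @return An object of class `fractal_dimension`: list with `d_box`,
#'   `box_sizes`, `counts` and `fit_r2`.
#' @export
fractal_dimension <- function(skeleton, box_sizes = NULL) {
  mask <- if (inherits(skeleton, "vessel_map")) skeleton$mask else skeleton
  if (!any(mask)) stop("empty skeleton: fractal dimension is undefined")
  if (is.null(box_sizes)) box_sizes <- c(2, 3, 4, 6, 8, 12, 16, 32, 64)
  box_sizes <- sort(unique(as.integer(box_sizes)))
  box_sizes <- box_sizes[box_sizes >= 1 & box_sizes <= min(dim(mask)) / 2]
  if (length(box_sizes) < 3)
    stop("fewer than 3 usable box sizes for a ",
         paste(dim(mask), collapse = "x"), " image")
  counts <- vapply(box_sizes, function(s) box_count(mask, s), numeric(1))
  fit <- lm(log(counts) ~ log(1 / box_sizes))
  structure(list(d_box = unname(coef(fit)[2]),
                 box_sizes = box_sizes,
                 counts = counts,
                 fit_r2 = suppressWarnings(summary(fit)$r.squared)),
            class = "fractal_dimension")
}

# number of s x s grid cells (grid anchored at the origin) containing at
# least one foreground pixel
box_count <- function(mask, s) {
  idx <- which(mask)
  r <- ((idx - 1L) %% nrow(mask)) %/% s
  c <- ((idx - 1L) %/% nrow(mask)) %/% s
  length(unique(r * (ncol(mask) %/% s + 1L) + c))
}

#' @export
print.fractal_dimension <- function(x, ...) {
  cat(sprintf("<fractal_dimension> D_box = %.4f (R^2 = %.4f) over %d box sizes\n",
              x$d_box, x$fit_r2, length(x$box_sizes)))
  invisible(x)
}

#' Assemble the nine-biomarker record for one image
#'
#' Collects the nine lesion biomarkers into a one-row data frame (column
#' order of the batch CSV) and enforces their defining identities:
#' vessel area cannot exceed lesion area, vessel density must equal their
#' ratio, junction density must equal junctions/length, tortuosity must be
#' >= 1 and the fractal dimension must lie in (0, 2]. Missing values (`NA`)
#' propagate without error; a non-positive fractal dimension from a
#' degenerate skeleton is reported as missing.
#'
#' @param image_id identifier for the image (typically the file stem).
#' @param mcnv_area_mm2,vessel_area_mm2,vessel_junctions,vessel_length_mm
#'   components as computed by the corresponding functions.
#' @param fractal_dim,tort,vessel_density,junction_dens,vessel_diameter_um
#'   remaining components; `vessel_density` and `junction_dens` default to
#'   their defining ratios when `NULL`.
#' @return A one-row data frame of class `biomarker_record` with columns
#'   `image`, `mcnv_area_mm2`, `vessel_area_mm2`, `vessel_junctions`,
#'   `vessel_length_mm`, `fractal_dimension`, `tortuosity`,
#'   `vessel_density`, `junction_density_per_mm`, `vessel_diameter_um`.
#' @export
assemble_record <- function(image_id, mcnv_area_mm2, vessel_area_mm2,
                            vessel_junctions, vessel_length_mm,
                            fractal_dim = NA_real_, tort = NA_real_,
                            vessel_density = NULL, junction_dens = NULL,
                            vessel_diameter_um = NULL) {
  eps <- 1e-9
  if (is.null(vessel_density)) vessel_density <- vessel_area_mm2 / mcnv_area_mm2
  if (is.null(junction_dens))
    junction_dens <- junction_density(vessel_junctions, vessel_length_mm)
  if (is.null(vessel_diameter_um))
    vessel_diameter_um <- vessel_diameter(vessel_area_mm2, vessel_length_mm)

  chk <- function(ok, metric) {
    if (!is.na(ok) && !ok)
      stop("internal consistency violated for biomarker '", metric, "'")
  }
  chk(vessel_area_mm2 <= mcnv_area_mm2 + eps, "vessel_area")
  chk(abs(vessel_density - vessel_area_mm2 / mcnv_area_mm2) <= eps,
      "vessel_density")
  if (is.finite(vessel_length_mm) && vessel_length_mm > 0)
    chk(abs(junction_dens - vessel_junctions / vessel_length_mm) <= eps,
        "junction_density")
  chk(is.na(tort) | tort >= 1 - 1e-6, "tortuosity")
  if (!is.na(fractal_dim) && fractal_dim <= 0) fractal_dim <- NA_real_
  # the box-count slope can exceed the theoretical planar dimension slightly
  # when box sizes do not divide the image side (grid-ceiling bias)
  chk(is.na(fractal_dim) | fractal_dim <= 2 + 0.01, "fractal_dimension")

  out <- data.frame(image = as.character(image_id),
                    mcnv_area_mm2 = mcnv_area_mm2,
                    vessel_area_mm2 = vessel_area_mm2,
                    vessel_junctions = vessel_junctions,
                    vessel_length_mm = vessel_length_mm,
                    fractal_dimension = fractal_dim,
                    tortuosity = tort,
                    vessel_density = vessel_density,
                    junction_density_per_mm = junction_dens,
                    vessel_diameter_um = vessel_diameter_um,
                    stringsAsFactors = FALSE)
  class(out) <- c("biomarker_record", class(out))
  out
}
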