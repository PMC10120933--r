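#' Full pipeline configuration
#'
#' Collects every tunable of the batch pipeline, mirroring the interactive
#' parameter dialog of the original macro: directories, image format, pixel
#' scale, stage saving, the filter and prune parameter blocks, the contrast
#' saturation fraction and the fractal box sizes.
#'
#' The pipeline defaults depart from the bare filter defaults in two places,
#' both noise-robustness choices for single-frame OCTA input: the
#' binarization margin is `threshold_offset = -5` (a pixel must exceed its
#' local median by more than 5 of 255 intensity levels, i.e. by more than the
#' quantization-level noise floor of homogeneous speckle regions — a pure
#' median rule marks half of any noisy homogeneous region by construction),
#' and skeleton spurs shorter than 0.05 mm are pruned (short end-branch
#' artifacts that thinning produces where vessels meet, the usual
#' "prune ends" convention of skeleton analysis).
#'
#' @param input_dir,output_dir input and output directories.
#' @param image_format `"tiff"` (default) or `"png"`.
#' @param scale pixels per mm (study default 170).
#' @param save_stages save the 5 intermediate stage images per input.
#' @param filter a [filter_config()].
#' @param prune a [prune_config()].
#' @param contrast_saturation saturation fraction of the contrast stretch.
#' @param box_sizes fractal box sizes in pixels (`NULL` = defaults).
#' @param mask_suffix suffix identifying a sibling ROI mask file, e.g. an
#'   input `lesion.tif` may carry `lesion_mask.tif`; mask files are excluded
#'   from batch discovery.
#' @param fill_holes_smaller_than enclosed background holes below this pixel
#'   count are filled in the branch-2 binary map before thinning (see
#'   [fill_small_holes()]); holes this small are binarization artifacts, not
#'   avascular gaps.
#' @param length_method geodesic length estimator, `"polyline"` or `"chain"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = ".", output_dir = ".",
                            image_format = c("tiff", "png"), scale = 170,
                            save_stages = FALSE,
                            filter = filter_config(threshold_offset = -5),
                            prune = prune_config(
                              prune_end_branches_shorter_than = 0.05),
                            contrast_saturation = 0.0035, box_sizes = NULL,
                            mask_suffix = "_mask",
                            fill_holes_smaller_than = 10,
                            length_method = c("polyline", "chain")) {
  image_format <- match.arg(image_format)
  length_method <- match.arg(length_method)
  if (scale <= 0) stop("`scale` must be positive")
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 image_format = image_format, scale = scale,
                 save_stages = save_stages, filter = filter, prune = prune,
                 contrast_saturation = contrast_saturation,
                 box_sizes = box_sizes, mask_suffix = mask_suffix,
                 fill_holes_smaller_than = fill_holes_smaller_than,
                 length_method = length_method),
            class = "pipeline_config")
}

#' Quantify one delineated image
#'
#' Runs the branched pipeline on an in-memory image: after 8-bit conversion
#' and percentile contrast adjustment (shared preprocessing), branch 1
#' applies Gaussian blur, Frangi vesselness and local median thresholding to
#' measure the area biomarkers, while branch 2 applies the Mexican-hat filter
#' to the same preprocessed input, binarizes it with the same local median
#' thresholder, skeletonizes, tags and prunes the skeleton graph, and
#' measures the skeletal biomarkers. Vessel diameter and junction density
#' are derived from the previously computed area and length.
#'
#' @param image a [raster_image()].
#' @param roi a [roi_mask()].
#' @param config a [pipeline_config()].
#' @param image_id identifier used in the output record.
#' @return A list with `record` (a [assemble_record()] row), `graph` (the
#'   pruned `skeleton_graph`) and `stages` (named list of the five
#'   intermediate images: `stage1A`, `stage1B`, `stage1C`, `stage2A`,
#'   `stage2B`).
#' @export
quantify_image <- function(image, roi, config = pipeline_config(),
                           image_id = "image") {
  fc <- config$filter
  img <- to_8bit(image)
  px <- img$pixels
  px[!roi$mask] <- 0                       # clearing outside the delineation
  img <- raster_image(px, img$scale)
  pre <- adjust_contrast(img, config$contrast_saturation, roi)

  # branch 1: denoise -> vesselness -> binarize -> area biomarkers
  s1a <- gaussian_blur(pre, fc$gaussian_sigma)
  s1b <- frangi_vesselness(s1a, fc$frangi_scales, fc$frangi_beta, fc$frangi_c)
  s1c <- local_median_threshold(s1b, fc$threshold_radius, fc$threshold_offset,
                                roi)

  # branch 2: Mexican hat -> binarize -> skeleton -> skeletal biomarkers
  s2a <- mexican_hat(pre, fc$mexican_hat_radius)
  s2bin <- local_median_threshold(s2a, fc$threshold_radius,
                                  fc$threshold_offset, roi)
  s2bin <- fill_small_holes(s2bin, config$fill_holes_smaller_than)
  skel <- skeletonize(s2bin)
  graph <- tag_skeleton(skel, length_method = config$length_method)
  graph <- prune_skeleton(graph, config$prune)

  area_mm2 <- mcnv_area(roi, image$scale)
  va <- vessel_area_and_density(s1c, roi)
  vl <- vessel_length(graph)
  vj <- count_junctions(graph)
  fd <- tryCatch(fractal_dimension(vessel_map(graph$mask, image$scale),
                                   config$box_sizes)$d_box,
                 error = function(e) NA_real_)
  record <- assemble_record(image_id,
                            mcnv_area_mm2 = area_mm2,
                            vessel_area_mm2 = va$vessel_area_mm2,
                            vessel_junctions = vj,
                            vessel_length_mm = vl,
                            fractal_dim = fd,
                            tort = tortuosity(graph))
  list(record = record, graph = graph,
       stages = list(stage1A = s1a, stage1B = s1b,
                     stage1C = raster_image(s1c$mask * 255, image$scale),
                     stage2A = s2a,
                     stage2B = raster_image(graph$mask * 255, image$scale)))
}

#' Process a single image file
#'
#' Loads the image, derives the ROI (an explicit `<stem><mask_suffix>.<ext>`
#' sibling file wins; otherwise the nonzero support of the cleared image) and
#' runs [quantify_image()]. When stage saving is enabled the five
#' intermediates are written to the output directory as
#' `<stem>_stage{1A,1B,1C,2A,2B}.tif`.
#'
#' @param path image file path.
#' @param config a [pipeline_config()].
#' @return The list returned by [quantify_image()].
#' @export
run_single <- function(path, config = pipeline_config()) {
  image <- load_image(path, config$scale)
  stem <- tools::file_path_sans_ext(basename(path))
  ext <- tools::file_ext(path)
  mask_path <- file.path(dirname(path),
                         paste0(stem, config$mask_suffix, ".", ext))
  roi <- derive_roi(image, if (file.exists(mask_path)) mask_path else NULL)
  res <- quantify_image(image, roi, config, image_id = stem)
  if (isTRUE(config$save_stages)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(res$stages))
      write_image(res$stages[[nm]],
                  file.path(config$output_dir,
                            paste0(stem, "_", nm, ".tif")))
  }
  res
}

format_num <- function(x) {
  ifelse(is.na(x), "",
         ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
                sprintf("%.6f", x)))
}

#' Run the pipeline over a batch of images
#'
#' Discovers every image of the configured format in the input directory
#' (mask files excluded), processes them in lexicographic filename order, and
#' writes `octa_biomarkers.csv` (one row per successful image, columns
#' `image` + the nine biomarkers, with a `#`-prefixed unit header line), a
#' per-biomarker summary `octa_biomarkers_summary.csv` (mean/SD/min/max) and
#' a plain-text run log `run_log.txt` holding per-image status, timings and
#' the configuration snapshot. A failure on one image is recorded and the
#' batch continues; identical input and configuration reproduce the CSV
#' byte-identically.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `records` (data frame), `log` (data frame
#'   of file/status/seconds) and `csv` (path of the biomarker CSV).
#' @export
run_batch <- function(config = pipeline_config()) {
  ext_re <- if (config$image_format == "tiff") "\\.tiff?$" else "\\.png$"
  files <- list.files(config$input_dir, pattern = ext_re, ignore.case = TRUE)
  files <- files[!grepl(paste0(config$mask_suffix, "\\.[A-Za-z]+$"), files)]
  if (length(files) == 0)
    stop("no ", config$image_format, " images found in ", config$input_dir)
  files <- files[order(files, method = "radix")]
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  records <- list(); status <- character(length(files))
  secs <- numeric(length(files))
  for (i in seq_along(files)) {
    f <- files[i]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(run_single(file.path(config$input_dir, f), config),
                    error = function(e) e)
    secs[i] <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      status[i] <- paste0("failed:", conditionMessage(res))
      message("[octaquant] FAILED ", f, ": ", conditionMessage(res))
    } else {
      status[i] <- "ok"
      records[[f]] <- res$record
      message(sprintf("[octaquant] ok %s (%.1f s)", f, secs[i]))
    }
  }

  csv <- file.path(config$output_dir, "octa_biomarkers.csv")
  units <- paste("# units: mcnv_area_mm2=mm^2; vessel_area_mm2=mm^2;",
                 "vessel_junctions=count; vessel_length_mm=mm;",
                 "fractal_dimension=dimensionless; tortuosity=dimensionless;",
                 "vessel_density=ratio; junction_density_per_mm=n/mm;",
                 "vessel_diameter_um=um")
  tab <- if (length(records)) do.call(rbind, records) else NULL
  con <- file(csv, "wb")                   # binary mode: byte-stable EOLs
  writeLines(units, con)
  cols <- c("image", "mcnv_area_mm2", "vessel_area_mm2", "vessel_junctions",
            "vessel_length_mm", "fractal_dimension", "tortuosity",
            "vessel_density", "junction_density_per_mm", "vessel_diameter_um")
  writeLines(paste(cols, collapse = ","), con)
  if (!is.null(tab)) {
    for (i in seq_len(nrow(tab))) {
      vals <- c(tab$image[i],
                vapply(tab[i, cols[-1]], function(v) format_num(as.numeric(v)),
                       character(1)))
      writeLines(paste(vals, collapse = ","), con)
    }
  }
  close(con)

  if (!is.null(tab)) {
    sm <- file.path(config$output_dir, "octa_biomarkers_summary.csv")
    stats_tab <- do.call(rbind, lapply(cols[-1], function(cn) {
      v <- as.numeric(tab[[cn]])
      data.frame(biomarker = cn,
                 mean = format_num(mean(v, na.rm = TRUE)),
                 sd = format_num(if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE)
                                 else NA_real_),
                 min = format_num(suppressWarnings(min(v, na.rm = TRUE))),
                 max = format_num(suppressWarnings(max(v, na.rm = TRUE))),
                 stringsAsFactors = FALSE)
    }))
    con <- file(sm, "wb")
    writeLines(paste(colnames(stats_tab), collapse = ","), con)
    for (i in seq_len(nrow(stats_tab)))
      writeLines(paste(unlist(stats_tab[i, ]), collapse = ","), con)
    close(con)
  }

  logf <- file.path(config$output_dir, "run_log.txt")
  con <- file(logf, "wb")
  writeLines("# octaquant run log", con)
  fc <- config$filter; pc <- config$prune
  snap <- c(sprintf("config.scale=%g", config$scale),
            sprintf("config.image_format=%s", config$image_format),
            sprintf("config.save_stages=%s", config$save_stages),
            sprintf("config.contrast_saturation=%g", config$contrast_saturation),
            sprintf("config.gaussian_sigma=%g", fc$gaussian_sigma),
            sprintf("config.threshold_radius=%g", fc$threshold_radius),
            sprintf("config.threshold_offset=%g", fc$threshold_offset),
            sprintf("config.mexican_hat_radius=%g", fc$mexican_hat_radius),
            sprintf("config.frangi_scales=%s",
                    paste(fc$frangi_scales, collapse = ",")),
            sprintf("config.frangi_beta=%g", fc$frangi_beta),
            sprintf("config.frangi_c=%s", fc$frangi_c),
            sprintf("config.min_component_pixels=%g", pc$min_component_pixels),
            sprintf("config.prune_end_branches_shorter_than=%g",
                    pc$prune_end_branches_shorter_than),
            sprintf("config.length_method=%s", config$length_method))
  writeLines(snap, con)
  for (i in seq_along(files))
    writeLines(sprintf("file=%s\tstatus=%s\tseconds=%.2f",
                       files[i], status[i], secs[i]), con)
  close(con)

  if (!any(status == "ok"))
    warning("no image processed successfully")
  invisible(list(records = tab, log = data.frame(file = files, status = status,
                                                 seconds = secs,
                                                 stringsAsFactors = FALSE),
                 csv = csv))
}
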