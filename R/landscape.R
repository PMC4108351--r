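#' Overlay projected urban growth on land cover
#'
#' Cells flagged urban are reassigned to the urban class; every other cell
#' keeps its land-cover class.
#'
#' @param landcover `landcover_class` raster.
#' @param urban `urban_flag` raster on the same grid.
#' @param urban_class Class code to assign (default the legend's `urban`
#'   entry, else 6).
#' @return A `landcover_class` [raster_layer()].
#' @export
overlay_urban <- function(landcover, urban, urban_class = NULL) {
  stopifnot(inherits(landcover, "raster_layer"),
            landcover$kind == "landcover_class",
            inherits(urban, "raster_layer"), urban$kind == "urban_flag")
  stop_if_misaligned(landcover, urban)
  if (is.null(urban_class)) {
    urban_class <- if (!is.null(landcover$legend) &&
                       "urban" %in% names(landcover$legend))
      landcover$legend[["urban"]] else 6
  }
  m <- landcover$values
  m[urban$values == 1] <- urban_class
  raster_layer(landcover$spec, m, kind = "landcover_class",
               legend = landcover$legend)
}

#' Label the patches of one class
#'
#' Connected components of cells carrying class `cls`, under 4- or
#' 8-connectivity. `NA` cells belong to no patch.
#'
#' @param classmap `landcover_class` (or any) raster.
#' @param cls Class code to label.
#' @param connectivity 4 or 8 (default 8, matching the automaton's Moore
#'   neighborhood).
#' @return List with `labels` (integer matrix, 0 = not this class) and
#'   `sizes` (cells per patch, indexed by label).
#' @export
label_patches <- function(classmap, cls, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  m <- if (inherits(classmap, "raster_layer")) classmap$values else classmap
  mi <- matrix(0L, nrow(m), ncol(m))
  mi[!is.na(m) & m == cls] <- 1L
  labels <- label_components_cpp(mi, 1, as.integer(connectivity))
  sizes <- if (max(labels) > 0) tabulate(labels[labels > 0]) else integer(0)
  list(labels = labels, sizes = sizes)
}

#' Patch metrics per land-cover class
#'
#' The four fragmentation summaries per class: total area, number of
#' patches, mean patch area and maximum patch area (km^2). Classes absent
#' from the map get zero patches and `NA` mean/max.
#'
#' @param classmap `landcover_class` raster with a legend (or supply
#'   `legend`).
#' @param legend Class codes (optionally named) to tabulate.
#' @param connectivity 4 or 8.
#' @return A data frame of class `patch_metrics_table`.
#' @export
patch_metrics <- function(classmap, legend = NULL, connectivity = 8L) {
  stopifnot(inherits(classmap, "raster_layer"))
  if (is.null(legend)) legend <- classmap$legend
  if (is.null(legend))
    legend <- sort(unique(as.vector(
      classmap$values[!is.na(classmap$values)])))
  a_cell <- cell_area_km2(classmap$spec)
  rows <- lapply(seq_along(legend), function(i) {
    lp <- label_patches(classmap, legend[[i]], connectivity)
    n <- length(lp$sizes)
    data.frame(
      class = if (!is.null(names(legend))) names(legend)[i]
              else as.character(legend[[i]]),
      class_code = legend[[i]],
      total_area_km2 = sum(lp$sizes) * a_cell,
      n_patches = n,
      mean_patch_area_km2 = if (n) mean(lp$sizes) * a_cell else NA_real_,
      max_patch_area_km2 = if (n) max(lp$sizes) * a_cell else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("patch_metrics_table", "data.frame")
  out
}

#' Percent change in patch metrics between two dates
#'
#' `100 * (after - before) / before` per class and metric; `NA` where the
#' before value is 0 or missing (undefined, not 0).
#'
#' @param before,after [patch_metrics()] tables sharing one legend.
#' @return Data frame of per-class percent changes.
#' @export
metric_change <- function(before, after) {
  stopifnot(inherits(before, "patch_metrics_table"),
            inherits(after, "patch_metrics_table"))
  if (!identical(before$class_code, after$class_code))
    stop("patch metric tables have different legends", call. = FALSE)
  pct <- function(b, a) ifelse(is.na(b) | b == 0, NA_real_,
                               100 * (a - b) / b)
  data.frame(class = before$class,
             class_code = before$class_code,
             total_area_pct = pct(before$total_area_km2,
                                  after$total_area_km2),
             n_patches_pct = pct(before$n_patches, after$n_patches),
             mean_patch_area_pct = pct(before$mean_patch_area_km2,
                                       after$mean_patch_area_km2),
             max_patch_area_pct = pct(before$max_patch_area_km2,
                                      after$max_patch_area_km2))
}
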