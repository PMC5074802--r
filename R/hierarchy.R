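# Projection-density hierarchy analysis: optical-density maps, L2-4:L1
# density ratios (DR), the source x target DR matrix, and the hierarchy
# ordering with pairwise rank-sum tests.

#' Layer band annotation for a density image
#'
#' Bands are depth intervals in um from the pia: each named value is the
#' bottom of its band, the top being the previous boundary (0 for the
#' first). `L1` and `L2-4` must both be present; intervals are disjoint by
#' construction.
#'
#' @param boundaries Named, positive, strictly increasing numeric vector.
#' @return Object of class `layer_bands`.
#' @export
layer_bands <- function(boundaries = c(L1 = 150, `L2-4` = 600, L5 = 850,
                                       L6 = 1100)) {
  if (is.null(names(boundaries)) || is.unsorted(boundaries, strictly = TRUE) ||
      any(boundaries <= 0))
    abort("'boundaries' must be named, positive, strictly increasing",
          "scracmap_config_error")
  if (!all(c("L1", "L2-4") %in% names(boundaries)))
    abort("bands must include 'L1' and 'L2-4'", "scracmap_config_error")
  structure(list(boundaries = boundaries), class = "layer_bands")
}

# Row indices of each band given row-centre depths (um from pia).
band_row_masks <- function(bands, row_depth_um) {
  b <- bands$boundaries
  lower <- c(0, head(b, -1L))
  out <- lapply(seq_along(b), function(i)
    which(row_depth_um >= lower[i] & row_depth_um < b[i]))
  names(out) <- names(b)
  out
}

# Uniform circular-disk moving average ("circular averaging 2-D filter").
# Normalized convolution: each output pixel is the mean over the disk
# offsets that fall inside the image, so a uniform image maps to itself and
# image borders carry no zero-padding artifact. Vectorized as a sum over
# kernel offsets.
disk_filter <- function(img, radius) {
  if (length(img) == 0L) abort("empty image", "scracmap_input_error")
  r <- as.integer(radius)
  if (r < 1L) abort("'radius' must be >= 1 px", "scracmap_config_error")
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(0, nr + 2L * r, nc + 2L * r)
  cnt_pad <- matrix(0, nr + 2L * r, nc + 2L * r)
  pad[(r + 1L):(r + nr), (r + 1L):(r + nc)] <- img
  cnt_pad[(r + 1L):(r + nr), (r + 1L):(r + nc)] <- 1
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= r^2, ]
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (i in seq_len(nrow(off))) {
    dy <- off$dy[i]; dx <- off$dx[i]
    acc <- acc + pad[(r + 1L + dy):(r + nr + dy),
                     (r + 1L + dx):(r + nc + dx)]
    cnt <- cnt + cnt_pad[(r + 1L + dy):(r + nr + dy),
                         (r + 1L + dx):(r + nc + dx)]
  }
  acc / cnt
}

#' Optical-density map of an axonal projection image
#'
#' Convolves the grayscale image with a uniform circular averaging filter
#' (normalized at the borders so a uniform image is unchanged) and scales
#' the result to its peak density, the form in which laminar termination
#' patterns are contoured and compared.
#'
#' @param image A `density_image` (from [generate_projection_image()] or
#'   [read_density_image()]) or a bare intensity matrix.
#' @param filter_radius Disk radius in px (default 10).
#' @param normalize Divide by the peak after filtering (default TRUE).
#' @param pixel_size_um,bands Metadata when `image` is a bare matrix.
#' @return Object of class `density_map`: `values`, `pixel_size_um`, `bands`.
#' @export
optical_density_map <- function(image, filter_radius = 10, normalize = TRUE,
                                pixel_size_um = NULL, bands = NULL) {
  if (inherits(image, "density_image")) {
    pixel_size_um <- image$pixel_size_um
    bands <- bands %||% image$bands
    image <- image$pixels
  }
  if (!is.matrix(image) || length(image) == 0L)
    abort("empty image", "scracmap_input_error")
  if (any(image < 0)) abort("intensities must be >= 0", "scracmap_input_error")
  f <- disk_filter(image, filter_radius)
  if (normalize) {
    mx <- max(f)
    if (mx <= 0) abort("image is all zero", "scracmap_input_error")
    f <- f / mx
  }
  structure(list(values = f, pixel_size_um = pixel_size_um, bands = bands,
                 filter_radius = as.integer(filter_radius)),
            class = "density_map")
}

resolve_band_rows <- function(dmap, band, margin_px = 0L) {
  if (is.character(band)) {
    if (is.null(dmap$bands) || is.null(dmap$pixel_size_um))
      abort("density map carries no band annotation", "scracmap_input_error")
    depths <- (seq_len(nrow(dmap$values)) - 0.5) * dmap$pixel_size_um
    rows <- band_row_masks(dmap$bands, depths)[[band]]
    if (is.null(rows)) abort(sprintf("unknown band '%s'", band),
                             "scracmap_input_error")
    if (margin_px > 0L && length(rows) > 2L * margin_px)
      rows <- rows[(margin_px + 1L):(length(rows) - margin_px)]
    rows
  } else band
}

#' Mean optical density within a band's top-70% contour
#'
#' Within the band, pixels whose OD is at least `(1 - fraction)` of the
#' band's maximum lie inside the contour bounding the highest `fraction` of
#' the intensity range; their mean OD is returned. `fraction = 1` degrades
#' to the plain band mean. The alternative reading (top `fraction` of pixels
#' by rank) is available via `method = "rank"`.
#'
#' @param dmap A [optical_density_map()].
#' @param band Band name (e.g. `"L1"`, `"L2-4"`), logical mask over the
#'   image, or integer row indices.
#' @param fraction Contour fraction of the intensity range (default 0.70).
#' @param method `"range"` (default, contour of the intensity range) or
#'   `"rank"` (top fraction of pixels).
#' @param margin_px Rows eroded from each side of a named band before
#'   measuring, excluding pixels whose disk neighbourhood straddles a layer
#'   boundary. Defaults to the map's filter radius; ignored for explicit
#'   masks/indices.
#' @return Mean OD inside the contour; `NA` with a too-weak warning if the
#'   band is all zero.
#' @export
band_density <- function(dmap, band, fraction = 0.70,
                         method = c("range", "rank"),
                         margin_px = NULL) {
  method <- match.arg(method)
  if (fraction <= 0 || fraction > 1)
    abort("'fraction' must be in (0, 1]", "scracmap_config_error")
  margin_px <- margin_px %||% dmap$filter_radius %||% 0L
  vals <- if (is.logical(band)) dmap$values[band] else
    dmap$values[resolve_band_rows(dmap, band, margin_px), , drop = FALSE]
  if (length(vals) == 0L) abort("band is empty", "scracmap_input_error")
  mx <- max(vals)
  if (mx <= 0)
    return(undefined_result("band signal too weak (all zero)"))
  sel <- if (method == "range") vals >= (1 - fraction) * mx else
    vals >= stats::quantile(vals, 1 - fraction, names = FALSE)
  mean(vals[sel])
}

#' L2-4 : L1 termination density ratio of one slice
#'
#' DR = mean OD inside the L2-4 top-70% contour divided by that of L1.
#' DR > 1 marks feedforward-like termination (L2-4 dominated), DR < 1
#' feedback-like (L1 dominated).
#'
#' @inheritParams band_density
#' @param source,target Optional area labels carried into the record.
#' @return Object of class `dr_record`: `dr`, `l24_density`, `l1_density`,
#'   `too_weak`, `source`, `target`, `n_slices`.
#' @export
density_ratio <- function(dmap, fraction = 0.70, source = NA_character_,
                          target = NA_character_, margin_px = NULL) {
  l24 <- band_density(dmap, "L2-4", fraction, margin_px = margin_px)
  l1 <- band_density(dmap, "L1", fraction, margin_px = margin_px)
  too_weak <- is.na(l24) || is.na(l1) || l1 == 0
  structure(list(
    dr = if (too_weak) NA_real_ else l24 / l1,
    l24_density = l24, l1_density = l1, too_weak = too_weak,
    source = source, target = target, n_slices = 1L
  ), class = "dr_record")
}

#' Assemble a source x target DR table
#'
#' Collapses per-slice `dr_record`s to one row per pathway (mean DR over
#' usable slices; too-weak slices excluded but counted). Self-projections
#' (source == target) are rejected.
#'
#' @param records List of `dr_record`s with source/target labels.
#' @return data.frame with columns source, target, dr, n_slices, n_too_weak.
#' @export
dr_table <- function(records) {
  df <- do.call(rbind, lapply(records, function(r) {
    data.frame(source = r$source, target = r$target, dr = r$dr,
               too_weak = r$too_weak)
  }))
  if (any(df$source == df$target, na.rm = TRUE))
    abort("self-projections (source == target) are not part of the matrix",
          "scracmap_input_error")
  out <- do.call(rbind, lapply(split(df, df[c("source", "target")],
                                     drop = TRUE), function(d) {
    ok <- !d$too_weak
    data.frame(source = d$source[1], target = d$target[1],
               dr = if (any(ok)) mean(d$dr[ok]) else NA_real_,
               n_slices = sum(ok), n_too_weak = sum(!ok))
  }))
  rownames(out) <- NULL
  out
}

#' Mean DR (and SEM) of one source area over its targets
#'
#' @param drs A [dr_table()] data.frame (or any data.frame with `source` and
#'   `dr` columns).
#' @param source Source-area label.
#' @return List `mean`, `sem` (`NA` for a single entry), `n`.
#' @export
mean_dr <- function(drs, source) {
  v <- drs$dr[drs$source == source & !is.na(drs$dr)]
  if (length(v) == 0L)
    abort(sprintf("no usable DR entries for source '%s'", source),
          "scracmap_input_error")
  list(mean = mean(v),
       sem = if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_,
       n = length(v))
}

#' Hierarchy ordering of source areas by mean DR
#'
#' Sorts sources by descending mean DR over their targets and reports all
#' pairwise two-sided Mann-Whitney U p-values on the per-target DR sets.
#' Sources with exactly equal mean DR are reported as ties, not silently
#' broken.
#'
#' @param drs A [dr_table()] data.frame.
#' @return List: `order` (sources, descending mean DR), `mean_dr` (named
#'   means), `sem` (named SEMs), `pairwise_p` (matrix), `ties` (list of
#'   tied source groups, empty if none).
#' @export
hierarchy_order <- function(drs) {
  drs <- drs[!is.na(drs$dr), , drop = FALSE]
  sets <- split(drs$dr, drs$source)
  sets <- sets[lengths(sets) >= 2L]
  if (length(sets) < 2L)
    abort("need >= 2 sources with >= 2 usable DR entries",
          "scracmap_input_error")
  mus <- vapply(sets, mean, numeric(1))
  sems <- vapply(sets, function(v) sd(v) / sqrt(length(v)), numeric(1))
  ord <- names(sort(mus, decreasing = TRUE))
  k <- length(sets)
  p <- matrix(NA_real_, k, k, dimnames = list(ord, ord))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    pv <- wilcox.test(sets[[ord[i]]], sets[[ord[j]]], exact = FALSE)$p.value
    p[i, j] <- p[j, i] <- pv
  }
  tied <- split(names(mus), mus)
  tied <- unname(tied[lengths(tied) > 1L])
  list(order = ord, mean_dr = mus[ord], sem = sems[ord], pairwise_p = p,
       ties = tied)
}

#' Classify a pathway as feedforward or feedback from its DR
#'
#' FF iff `dr > ff_threshold` (strict; a DR exactly at the threshold is
#' called FB). Vectorized.
#'
#' @param dr Density ratio(s), > 0.
#' @param ff_threshold Decision boundary (default 1).
#' @return Character vector of `"FF"` / `"FB"`.
#' @export
classify_pathway <- function(dr, ff_threshold = 1) {
  if (any(dr <= 0, na.rm = TRUE))
    abort("'dr' must be > 0", "scracmap_input_error")
  ifelse(dr > ff_threshold, "FF", "FB")
}
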