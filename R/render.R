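#' Geometry of a rendered synthetic field of view
#'
#' @param width,height Frame size in pixels.
#' @param cell_radii Semi-axes of the elliptical cells, pixels.
#' @param spacing Minimum gap between cell bounding boxes, pixels.
#' @param bg_roi_size Side length of the square background ROIs placed in
#'   the four frame corners.
#' @return A plain list of geometry settings.
#' @export
render_geometry <- function(width = 96, height = 96, cell_radii = c(7, 5),
                            spacing = 4, bg_roi_size = 6) {
  stopifnot(width > 0, height > 0, all(cell_radii > 0), spacing >= 0, bg_roi_size >= 2)
  list(
    width = as.integer(width), height = as.integer(height),
    cell_radii = cell_radii, spacing = spacing,
    bg_roi_size = as.integer(bg_roi_size)
  )
}

.corner_background_rois <- function(geometry) {
  s <- geometry$bg_roi_size
  w <- geometry$width
  h <- geometry$height
  list(
    c(row0 = 2L, row1 = 1L + s, col0 = 2L, col1 = 1L + s),
    c(row0 = 2L, row1 = 1L + s, col0 = w - s, col1 = w - 1L),
    c(row0 = h - s, row1 = h - 1L, col0 = 2L, col1 = 1L + s),
    c(row0 = h - s, row1 = h - 1L, col0 = w - s, col1 = w - 1L)
  )
}

#' Render a trace set as a two-channel image stack
#'
#' Paints each cell as a uniform ellipse whose per-frame intensity is the
#' cell's trace value, on top of a constant background offset, optionally
#' with Poisson (shot-like) pixel noise. Channel pages are interleaved CFP
#' then YFP per timepoint. The emitted label masks and corner background
#' ROIs are exact, so extract-then-quantify on the rendered stack
#' reproduces the trace-level quantities (exactly, when `shot_noise =
#' FALSE`).
#'
#' @param traces Trace tibble (`cell_id`, `time_min`, `cfp`, `yfp`) or a
#'   `trace_set`.
#' @param geometry A [render_geometry()].
#' @param background_offset Constant background level added to every pixel.
#' @param shot_noise Draw each pixel from a Poisson with the noise-free
#'   pixel value as mean.
#' @param seed Optional seed (shot noise only).
#' @return List with `stack` (array height x width x 2T, attribute
#'   `times`), `masks` (integer label matrix; labels follow the order of
#'   `levels(factor(cell_id))`), `cell_ids`, `background_rois`.
#' @export
render_image_stack <- function(traces, geometry = render_geometry(),
                               background_offset = 100, shot_noise = TRUE,
                               seed = NULL) {
  if (inherits(traces, "trace_set")) traces <- traces$traces
  stopifnot(all(c("cell_id", "time_min", "cfp", "yfp") %in% names(traces)))
  if (!is.null(seed)) set.seed(as.integer(seed))
  cells <- sort(unique(traces$cell_id))
  times <- sort(unique(traces$time_min))
  rx <- geometry$cell_radii[1]
  ry <- geometry$cell_radii[2]
  margin <- geometry$bg_roi_size + geometry$spacing

  # candidate centres on a grid clear of the corner background ROIs
  step_x <- 2 * rx + geometry$spacing
  step_y <- 2 * ry + geometry$spacing
  cx <- seq(margin + rx + 1, geometry$width - rx - margin, by = step_x)
  cy <- seq(margin + ry + 1, geometry$height - ry - margin, by = step_y)
  centres <- expand.grid(x = cx, y = cy)
  if (nrow(centres) < length(cells)) {
    stop(sprintf(
      "cannot place %d cells without overlap (room for %d); enlarge the frame",
      length(cells), nrow(centres)
    ), call. = FALSE)
  }

  masks <- matrix(0L, geometry$height, geometry$width)
  px_col <- matrix(rep(seq_len(geometry$width), each = geometry$height),
    geometry$height, geometry$width
  )
  px_row <- matrix(rep(seq_len(geometry$height), geometry$width),
    geometry$height, geometry$width
  )
  for (i in seq_along(cells)) {
    inside <- ((px_col - centres$x[i]) / rx)^2 + ((px_row - centres$y[i]) / ry)^2 <= 1
    masks[inside] <- i
  }

  cfp <- stats::xtabs(cfp ~ factor(time_min, levels = times) +
    factor(cell_id, levels = cells), data = traces)
  yfp <- stats::xtabs(yfp ~ factor(time_min, levels = times) +
    factor(cell_id, levels = cells), data = traces)

  stack <- array(background_offset,
    dim = c(geometry$height, geometry$width, 2L * length(times))
  )
  for (t in seq_along(times)) {
    for (ch in 1:2) {
      img <- matrix(background_offset, geometry$height, geometry$width)
      vals <- if (ch == 1) cfp[t, ] else yfp[t, ]
      nz <- masks > 0L
      img[nz] <- background_offset + vals[masks[nz]]
      if (shot_noise) img[] <- stats::rpois(length(img), pmax(img, 0))
      stack[, , 2L * (t - 1L) + ch] <- img
    }
  }
  attr(stack, "times") <- times
  list(
    stack = stack, masks = masks, cell_ids = cells,
    background_rois = .corner_background_rois(geometry)
  )
}

.bg_pixel_index <- function(rois, dim_hw) {
  idx <- integer(0)
  for (r in rois) {
    rows <- r[["row0"]]:r[["row1"]]
    cols <- r[["col0"]]:r[["col1"]]
    idx <- c(idx, as.vector(outer(rows, (cols - 1L) * dim_hw[1], "+")))
  }
  unique(idx)
}

#' Subtract the pooled background from a frame
#'
#' The background of a frame is the mean over all pixels of all background
#' ROIs (pooled, not a mean of ROI means), subtracted from every pixel.
#'
#' @param frame Numeric matrix.
#' @param background_rois List of ROIs, each `c(row0, row1, col0, col1)`.
#' @return The corrected matrix; attribute `background` holds the scalar.
#' @export
subtract_background <- function(frame, background_rois) {
  stopifnot(is.matrix(frame))
  if (length(background_rois) == 0L) {
    stop("at least one background ROI is required", call. = FALSE)
  }
  idx <- .bg_pixel_index(background_rois, dim(frame))
  bg <- mean(frame[idx])
  out <- frame - bg
  attr(out, "background") <- bg
  out
}

#' Extract background-corrected per-cell traces from an image stack
#'
#' For every frame the pooled background-ROI mean is subtracted and the
#' corrected pixel intensities are averaged over each labelled cell ROI,
#' per channel. Cells whose corrected CFP becomes non-positive at any
#' retained timepoint are dropped with a reason (they cannot yield a
#' ratio); the dropped table is attached as attribute `"dropped"`.
#'
#' @param stack Array `height x width x 2T` with CFP/YFP pages interleaved
#'   per timepoint (CFP first), e.g. from [render_image_stack()] or
#'   [read_stack()].
#' @param masks Integer label matrix (0 = background) of the same frame
#'   geometry.
#' @param background_rois List of background ROIs
#'   (`c(row0, row1, col0, col1)`), disjoint from cell ROIs.
#' @param times Frame times (min); defaults to the stack's `times`
#'   attribute, else `0:(T-1)`.
#' @param cell_ids Optional labels for mask values `1..K`.
#' @return Tibble `cell_id`, `time_min`, `cfp`, `yfp` with attribute
#'   `dropped` (tibble `cell_id`, `reason`).
#' @export
extract_cell_traces <- function(stack, masks, background_rois, times = NULL,
                                cell_ids = NULL) {
  stopifnot(length(dim(stack)) == 3L, is.matrix(masks))
  if (!all(dim(stack)[1:2] == dim(masks))) {
    stop("stack and masks must share frame geometry", call. = FALSE)
  }
  n_pages <- dim(stack)[3]
  if (n_pages == 0L || n_pages %% 2L != 0L) {
    stop("stack must contain an even, positive number of pages (CFP/YFP pairs)",
      call. = FALSE
    )
  }
  nt <- n_pages %/% 2L
  if (is.null(times)) times <- attr(stack, "times") %||% (seq_len(nt) - 1)
  stopifnot(length(times) == nt)
  labels <- sort(unique(masks[masks > 0L]))
  if (length(labels) == 0L) stop("masks contain no cell ROIs", call. = FALSE)
  if (is.null(cell_ids)) cell_ids <- sprintf("c%03d", labels)
  roi_idx <- lapply(labels, function(l) which(masks == l))
  empty <- lengths(roi_idx) == 0L
  if (any(empty)) {
    stop(sprintf("empty ROI for cell %s", paste(cell_ids[empty], collapse = ", ")),
      call. = FALSE
    )
  }
  bg_idx <- .bg_pixel_index(background_rois, dim(masks))
  if (any(masks[bg_idx] > 0L)) {
    stop("background ROIs must be disjoint from cell ROIs", call. = FALSE)
  }

  cfp <- matrix(NA_real_, nt, length(labels))
  yfp <- matrix(NA_real_, nt, length(labels))
  for (t in seq_len(nt)) {
    for (ch in 1:2) {
      img <- stack[, , 2L * (t - 1L) + ch]
      corr <- img - mean(img[bg_idx])
      means <- vapply(roi_idx, function(ix) mean(corr[ix]), numeric(1))
      if (ch == 1) cfp[t, ] <- means else yfp[t, ] <- means
    }
  }
  bad <- apply(cfp <= 0, 2, any)
  out <- tibble::tibble(
    cell_id = rep(cell_ids[!bad], each = nt),
    time_min = rep(times, sum(!bad)),
    cfp = as.vector(cfp[, !bad, drop = FALSE]),
    yfp = as.vector(yfp[, !bad, drop = FALSE])
  )
  attr(out, "dropped") <- tibble::tibble(
    cell_id = cell_ids[bad],
    reason = rep("non-positive corrected CFP", sum(bad))
  )
  out
}
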