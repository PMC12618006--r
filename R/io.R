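#' Write a two-channel image stack as a multi-page TIFF
#'
#' Pages are channel-interleaved, CFP then YFP per timepoint, stored as
#' 16-bit unsigned integers. Integer-valued input in `[0, 65535]`
#' round-trips losslessly through [read_stack()].
#'
#' @param stack Numeric array `height x width x pages` with an even number
#'   of pages.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3L)
  if (dim(stack)[3] %% 2L != 0L) {
    stop("stack must have an even page count (CFP/YFP pairs)", call. = FALSE)
  }
  if (any(stack < 0) || any(stack > 65535)) {
    stop("pixel values must lie in [0, 65535] for 16-bit storage", call. = FALSE)
  }
  pages <- lapply(seq_len(dim(stack)[3]), function(p) stack[, , p] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a two-channel multi-page TIFF stack
#'
#' @param path TIFF file with channel-interleaved pages (CFP then YFP per
#'   timepoint).
#' @param channels Number of interleaved channels (default 2); the page
#'   count must be a positive multiple.
#' @return Numeric array `height x width x pages` on the original 16-bit
#'   integer scale.
#' @export
read_stack <- function(path, channels = 2L) {
  if (!file.exists(path) || file.size(path) == 0) {
    stop(sprintf("not a readable TIFF file: %s", path), call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L || length(pages) %% channels != 0L) {
    stop(sprintf(
      "page count %d is not a positive multiple of %d channels",
      length(pages), channels
    ), call. = FALSE)
  }
  d <- dim(pages[[1]])
  stack <- array(NA_real_, c(d[1], d[2], length(pages)))
  for (p in seq_along(pages)) stack[, , p] <- round(pages[[p]] * 65535)
  stack
}

#' Write a labelled ROI mask as TIFF
#' @param masks Integer label matrix (0 = background).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_masks <- function(masks, path) {
  stopifnot(is.matrix(masks), all(masks >= 0), all(masks <= 65535))
  tiff::writeTIFF(masks / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a labelled ROI mask from TIFF
#' @param path Mask TIFF written by [write_masks()].
#' @return Integer label matrix.
#' @export
read_masks <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Read or write a perfusion/clamp protocol file
#'
#' Protocols are stored as JSON or YAML (by file extension) with a
#' `frame_interval_min` scalar and a `phases` array of objects with keys
#' `start_min`, `end_min`, `role` and `k_out_mM` or `voltage_mV`
#' (optionally `label`, `egf`). Validation errors name the offending phase
#' index.
#'
#' @param path File ending in `.json`, `.yaml` or `.yml`.
#' @return A [perfusion_protocol()].
#' @export
read_protocol <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop(sprintf("unsupported protocol format '.%s' (use json/yaml)", ext),
      call. = FALSE
    )
  )
  if (is.null(raw$phases)) stop("protocol file has no `phases`", call. = FALSE)
  phases <- raw$phases
  if (!is.data.frame(phases)) {
    phases <- dplyr::bind_rows(lapply(phases, function(p) {
      tibble::as_tibble(p[!vapply(p, is.null, logical(1))])
    }))
  }
  for (key in c("start_min", "end_min", "role")) {
    if (!key %in% names(phases) || anyNA(phases[[key]])) {
      bad <- if (key %in% names(phases)) which(is.na(phases[[key]]))[1] else 1L
      stop(sprintf("phase %d: missing required key `%s`", bad, key), call. = FALSE)
    }
  }
  perfusion_protocol(phases, raw$frame_interval_min %||% 1)
}

#' @rdname read_protocol
#' @param protocol A [perfusion_protocol()] to serialise.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "perfusion_protocol"))
  ext <- tolower(tools::file_ext(path))
  obj <- list(
    frame_interval_min = protocol$frame_interval_min,
    phases = as.data.frame(protocol$phases)
  )
  if (ext == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else if (ext %in% c("yaml", "yml")) {
    obj$phases <- lapply(seq_len(nrow(obj$phases)), function(i) {
      row <- as.list(obj$phases[i, ])
      row[!vapply(row, function(v) is.na(v) || is.null(v), logical(1))]
    })
    yaml::write_yaml(obj, path)
  } else {
    stop(sprintf("unsupported protocol format '.%s' (use json/yaml)", ext),
      call. = FALSE
    )
  }
  invisible(path)
}

#' CSV readers for the pipeline's tabular inputs
#'
#' Thin, validating wrappers around [utils::read.csv()] for the three
#' tabular formats the pipeline consumes: per-cell traces
#' (`time_min, cell_id, dish_id, cfp, yfp`), photon-decay histograms
#' (`bin_start_ns, count`), and mitosis events
#' (`experiment_id, condition, event_time_h`). Comma-separated,
#' dot-decimal, mandatory header.
#'
#' @param path CSV file path.
#' @return A tibble with the validated columns.
#' @export
read_traces_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  need <- c("time_min", "cell_id", "cfp", "yfp")
  if (!all(need %in% names(df))) {
    stop(sprintf(
      "trace CSV must have columns %s", paste(need, collapse = ", ")
    ), call. = FALSE)
  }
  df
}

#' @rdname read_traces_csv
#' @export
read_decay_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  if (!all(c("bin_start_ns", "count") %in% names(df))) {
    stop("decay CSV must have columns bin_start_ns, count", call. = FALSE)
  }
  df
}

#' @rdname read_traces_csv
#' @export
read_events_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  if (!all(c("experiment_id", "condition", "event_time_h") %in% names(df))) {
    stop("events CSV must have columns experiment_id, condition, event_time_h",
      call. = FALSE
    )
  }
  df
}
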