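# Triple coding: (ADL, LOC, HRL) <-> integer code 0..119, ADL-major layout.

.ADL <- c("AE", "AH", "AP", "AR", "AS", "AT")
.LOC <- c("BR", "KI", "LR", "TO")
.HRL <- c("VL", "LO", "ME", "HI", "VH")

#' Vocabularies of the coded behavior alphabet
#'
#' Six activities of daily living (eating AE, housekeeping AH, physical
#' exercise AP, resting AR, sleeping AS, toileting AT), four home locations
#' (bedroom BR, kitchen KI, living room LR, toilet TO) and five heart-rate
#' level bands (very low VL to very high VH). A 5-minute observation slot is
#' coded as one integer in `0..119` combining the three components.
#'
#' @return Character vector of symbols, in code order.
#' @export
adl_levels <- function() .ADL

#' @rdname adl_levels
#' @export
loc_levels <- function() .LOC

#' @rdname adl_levels
#' @export
hrl_levels <- function() .HRL

#' Size of the combined triple alphabet (6 x 4 x 5)
#' @return Integer scalar.
#' @export
n_triple_codes <- function() length(.ADL) * length(.LOC) * length(.HRL)

#' Encode (ADL, LOC, HRL) symbols as integer codes
#'
#' The layout is ADL-major: `code = adl * 20 + loc * 5 + hrl` with 0-based
#' component indices in vocabulary order, so `("AE","BR","VL")` is 0 and
#' `("AT","TO","VH")` is 119.
#'
#' @param adl,loc,hrl Character vectors of symbols (recycled to a common
#'   length).
#' @return Integer vector of codes in `0..119`.
#' @export
#' @examples
#' encode_triple("AE", "KI", "ME") # breakfast in the kitchen, medium HR
encode_triple <- function(adl, loc, hrl) {
  n <- max(length(adl), length(loc), length(hrl))
  adl <- rep_len(as.character(adl), n)
  loc <- rep_len(as.character(loc), n)
  hrl <- rep_len(as.character(hrl), n)
  ia <- match(adl, .ADL)
  il <- match(loc, .LOC)
  ih <- match(hrl, .HRL)
  bad <- is.na(ia) | is.na(il) | is.na(ih)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("unknown symbol in triple (%s, %s, %s): not in the ADL/LOC/HRL vocabularies",
                 adl[i], loc[i], hrl[i]), call. = FALSE)
  }
  as.integer((ia - 1L) * 20L + (il - 1L) * 5L + (ih - 1L))
}

#' Decode integer codes back to (ADL, LOC, HRL) symbols
#'
#' Inverse of [encode_triple()]; `encode_triple()` after `decode_triple()` is
#' the identity on `0..119`.
#'
#' @param code Integer vector of codes in `0..119`.
#' @return A data.frame with character columns `adl`, `loc`, `hrl`.
#' @export
decode_triple <- function(code) {
  code <- as.integer(code)
  if (any(is.na(code)) || any(code < 0L) || any(code > 119L))
    stop("triple code out of range 0..119", call. = FALSE)
  data.frame(
    adl = .ADL[code %/% 20L + 1L],
    loc = .LOC[(code %/% 5L) %% 4L + 1L],
    hrl = .HRL[code %% 5L + 1L],
    stringsAsFactors = FALSE
  )
}

#' Combined label such as "AE_KI_ME" for a triple code
#' @param code Integer vector of codes in `0..119`.
#' @return Character vector of underscore-joined labels.
#' @export
triple_label <- function(code) {
  d <- decode_triple(code)
  paste(d$adl, d$loc, d$hrl, sep = "_")
}

# ---------------------------------------------------------------------------
# BehaviorDataset container

#' Construct a behavior dataset (day x slot grid of triple codes)
#'
#' A dataset is one simulated year (or any number of days) of coded behavior:
#' a matrix with one row per day and 288 columns (5-minute slots), each cell
#' an integer code in `0..119`, plus provenance metadata (seed, model
#' fingerprint, change description, region boundaries).
#'
#' @param grid Integer matrix, `n_days x 288`, values in `0..119`.
#' @param meta Named list of metadata. Recognised entries: `seed`,
#'   `model_fingerprint`, `change` (`"normal"` or a change description),
#'   `onset_day`, `stable_day`.
#' @return An object of class `behavior_dataset`.
#' @export
behavior_dataset <- function(grid, meta = list()) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "integer"
  if (ncol(grid) != 288L)
    stop("a behavior dataset must have 288 slots per day (5-minute sampling)", call. = FALSE)
  if (any(is.na(grid)) || any(grid < 0L) || any(grid > 119L))
    stop("grid codes must lie in 0..119", call. = FALSE)
  if (is.null(meta$change)) meta$change <- "normal"
  structure(list(grid = grid, n_days = nrow(grid), meta = meta),
            class = "behavior_dataset")
}

#' @export
print.behavior_dataset <- function(x, ...) {
  cat(sprintf("<behavior_dataset> %d days x %d slots (%d cells), change: %s\n",
              x$n_days, ncol(x$grid), length(x$grid),
              if (is.character(x$meta$change)) x$meta$change else "perturbed"))
  invisible(x)
}

#' Per-day region labels of a dataset
#'
#' Days before the perturbation onset are `normal`, days from the onset up to
#' (but excluding) the stabilization day are `prediction`, later days are
#' `abnormal`. Datasets generated without a change are entirely `normal`.
#'
#' @param ds A `behavior_dataset`.
#' @return Character vector, one label per day.
#' @export
region_labels <- function(ds) {
  stopifnot(inherits(ds, "behavior_dataset"))
  days <- seq_len(ds$n_days)
  if (identical(ds$meta$change, "normal") ||
      is.null(ds$meta$onset_day) || is.null(ds$meta$stable_day))
    return(rep("normal", ds$n_days))
  onset <- ds$meta$onset_day
  stable <- ds$meta$stable_day
  ifelse(days < onset, "normal", ifelse(days < stable, "prediction", "abnormal"))
}

#' Split a dataset grid into per-component channel grids
#'
#' Decomposes the combined 120-level grid into three aligned grids holding the
#' 0-based component indices: activity (6 levels), location (4 levels) and
#' heart-rate level (5 levels). Recombining the channels as
#' `adl * 20 + loc * 5 + hrl` reproduces the original codes.
#'
#' @param ds A `behavior_dataset`.
#' @return A list of three integer matrices `adl`, `loc`, `hrl`.
#' @export
to_channel_grids <- function(ds) {
  stopifnot(inherits(ds, "behavior_dataset"))
  g <- ds$grid
  list(adl = g %/% 20L, loc = (g %/% 5L) %% 4L, hrl = g %% 5L)
}

# ---------------------------------------------------------------------------
# Persistence: comma-delimited integer grid + JSON metadata sidecar

#' Write / read a behavior dataset as delimited text plus a JSON sidecar
#'
#' The grid file holds one comma-delimited row of integer codes per day; the
#' sidecar (default `<path>.json`) carries the metadata. The round trip is
#' lossless.
#'
#' @param ds A `behavior_dataset`.
#' @param path Path of the grid file.
#' @param meta_path Path of the JSON sidecar; default `paste0(path, ".json")`.
#' @return `write_grid` returns `path` invisibly; `read_grid` returns the
#'   reconstructed `behavior_dataset`.
#' @export
write_grid <- function(ds, path, meta_path = paste0(path, ".json")) {
  stopifnot(inherits(ds, "behavior_dataset"))
  utils::write.table(ds$grid, file = path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(ds$meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path, meta_path = paste0(path, ".json")) {
  rows <- utils::read.table(path, sep = ",", header = FALSE,
                            colClasses = "integer")
  grid <- as.matrix(rows)
  dimnames(grid) <- NULL
  bad <- which(is.na(grid) | grid < 0L | grid > 119L, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("invalid triple code at row %d, column %d of %s",
                 bad[1, 1], bad[1, 2], path), call. = FALSE)
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  behavior_dataset(grid, meta)
}

# ---------------------------------------------------------------------------
# Image export

# Fixed 120-entry palette: hue by activity, saturation by location,
# brightness by heart-rate level; injective by construction.
.triple_palette <- function() {
  code <- 0:119
  adl <- code %/% 20L
  loc <- (code %/% 5L) %% 4L
  hrl <- code %% 5L
  grDevices::hsv(h = adl / 6, s = 0.35 + 0.65 * loc / 3, v = 0.35 + 0.65 * hrl / 4)
}

.channel_palettes <- function() {
  list(adl = grDevices::hsv(h = (0:5) / 6, s = 0.85, v = 0.9),
       loc = grDevices::gray.colors(4, start = 0.1, end = 0.95),
       hrl = grDevices::hsv(h = 2 / 3 - (0:4) * (2 / 3) / 4, s = 0.9, v = 0.9))
}

.grid_to_rgb <- function(grid, palette) {
  rgb <- grDevices::col2rgb(palette) / 255
  arr <- array(0, dim = c(nrow(grid), ncol(grid), 3))
  idx <- grid + 1L
  for (ch in 1:3) arr[, , ch] <- matrix(rgb[ch, idx], nrow(grid), ncol(grid))
  arr
}

#' Export a dataset as a PNG image (one pixel per cell)
#'
#' In `combined` mode one image with a fixed 120-entry palette is written; in
#' `channels` mode three images (`<stem>_adl.png`, `<stem>_loc.png`,
#' `<stem>_hrl.png`) with per-channel palettes. Image width is the number of
#' slots (288) and height the number of days, so a one-year dataset renders as
#' a 288 x 365 image.
#'
#' @param ds A `behavior_dataset`.
#' @param path Output path; in `channels` mode the `.png` suffix is replaced
#'   by per-channel suffixes.
#' @param mode `"combined"` or `"channels"`.
#' @return Character vector of written paths, invisibly.
#' @export
export_image <- function(ds, path, mode = c("combined", "channels")) {
  stopifnot(inherits(ds, "behavior_dataset"))
  mode <- match.arg(mode)
  if (mode == "combined") {
    png::writePNG(.grid_to_rgb(ds$grid, .triple_palette()), path)
    return(invisible(path))
  }
  stem <- sub("\\.png$", "", path)
  pals <- .channel_palettes()
  chans <- to_channel_grids(ds)
  paths <- character(0)
  for (nm in names(chans)) {
    p <- paste0(stem, "_", nm, ".png")
    png::writePNG(.grid_to_rgb(chans[[nm]], pals[[nm]]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
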