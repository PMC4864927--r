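#' Construct a section stack
#'
#' A section stack holds the registered channels of one whole tumor
#' cryosection as named intensity matrices, together with the physical
#' pixel size and the cohort metadata used downstream (section id, tumor
#' line, treatment arm, staining group).
#'
#' @param channels Named list of numeric matrices, one per channel.
#'   Names must come from the fixed vocabulary `DiOC7`, `CD31`,
#'   `pimonidazole`, `BrdUrd`, `HIF1a`, `Hoechst`; all matrices must
#'   share the same dimensions and contain non-negative intensities.
#' @param pixel_size_um Physical size of one pixel edge in micrometers
#'   (default 0.75, the acquisition resolution the pipeline assumes).
#' @param section_id Identifier of the section.
#' @param tumor_line Tumor line label, e.g. `"SCCVII"` or `"U87"`.
#' @param arm Treatment arm label, e.g. `"control"`, `"90min"`, `"12h"`.
#' @param staining_group `"group1"` (DiOC7/CD31/pimonidazole/BrdUrd/Hoechst),
#'   `"group2"` (DiOC7/CD31/HIF1a/Hoechst), or `NA` for an unconstrained
#'   channel subset.
#' @return An object of class `section_stack`.
#' @export
section_stack <- function(channels, pixel_size_um = 0.75, section_id = "section",
                          tumor_line = NA_character_, arm = NA_character_,
                          staining_group = NA_character_) {
  s <- structure(
    list(channels = channels, pixel_size_um = pixel_size_um,
         section_id = as.character(section_id),
         tumor_line = as.character(tumor_line),
         arm = as.character(arm),
         staining_group = as.character(staining_group)),
    class = "section_stack")
  validate_section_stack(s)
  s
}

validate_section_stack <- function(s) {
  stopifnot(is.list(s$channels), length(s$channels) >= 1)
  nms <- names(s$channels)
  if (is.null(nms) || any(nms == "")) stop("all channels must be named")
  bad <- setdiff(nms, CHANNEL_NAMES)
  if (length(bad)) {
    stop("unknown channel name(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(CHANNEL_NAMES, collapse = ", "), ")")
  }
  if (anyDuplicated(nms)) stop("duplicate channel names")
  dims <- lapply(s$channels, dim)
  if (any(vapply(dims, is.null, logical(1)))) stop("channels must be matrices")
  d0 <- dims[[1]]
  for (i in seq_along(dims)) {
    if (!identical(dims[[i]], d0)) {
      stop("channel dimension mismatch: '", nms[i], "' is ",
           paste(dims[[i]], collapse = "x"), ", expected ",
           paste(d0, collapse = "x"))
    }
  }
  if (!is.numeric(s$pixel_size_um) || length(s$pixel_size_um) != 1 ||
      !is.finite(s$pixel_size_um) || s$pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number")
  }
  for (nm in nms) {
    if (any(s$channels[[nm]] < 0, na.rm = TRUE)) {
      stop("channel '", nm, "' contains negative intensities")
    }
  }
  if (!is.na(s$staining_group)) {
    if (!s$staining_group %in% names(GROUP_CHANNELS)) {
      stop("staining_group must be 'group1', 'group2' or NA")
    }
    extra <- setdiff(nms, GROUP_CHANNELS[[s$staining_group]])
    if (length(extra)) {
      stop("channel(s) ", paste(extra, collapse = ", "),
           " not part of staining ", s$staining_group)
    }
  }
  invisible(s)
}

#' @export
print.section_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("section_stack '", x$section_id, "' (", x$tumor_line, ", ", x$arm,
      ", ", x$staining_group, ")\n", sep = "")
  cat("  ", d[1], "x", d[2], " px at ", x$pixel_size_um, " um/px; channels: ",
      paste(names(x$channels), collapse = ", "), "\n", sep = "")
  invisible(x)
}

stack_sidecar_path <- function(path) paste0(path, ".json")

#' Write a section stack to a multi-page TIFF
#'
#' Each channel is stored as one 16-bit grayscale page (losslessly for
#' integer intensities in `[0, 65535]`). Channel names, pixel size and
#' section metadata are written to a JSON sidecar (`<path>.json`), the
#' portable rendering of image metadata available to this toolchain.
#'
#' @param stack A [section_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  validate_section_stack(stack)
  for (nm in names(stack$channels)) {
    ch <- stack$channels[[nm]]
    if (any(ch > INTENSITY_MAX)) {
      stop("channel '", nm, "' exceeds the 16-bit ceiling of ", INTENSITY_MAX)
    }
  }
  pages <- lapply(stack$channels, function(ch) ch / INTENSITY_MAX)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                            compression = "deflate"),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write TIFF to '", path, "'")
  meta <- list(
    channels = as.list(names(stack$channels)),
    pixel_size_um = stack$pixel_size_um,
    section_id = stack$section_id,
    tumor_line = stack$tumor_line,
    arm = stack$arm,
    staining_group = stack$staining_group
  )
  jsonlite::write_json(meta, stack_sidecar_path(path),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Read a section stack from a multi-page TIFF
#'
#' Channel names and pixel size are taken from the JSON sidecar written
#' by [write_stack()], or from a `key=value` TIFF description tag
#' (`channel=...`, `pixel_size_um=...`) if one is present. A manifest
#' entry can supply or override section metadata; when both the file
#' metadata and the manifest state a pixel size they must agree.
#'
#' @param path TIFF path.
#' @param manifest_entry Optional named list / one-row data.frame with
#'   any of `section_id`, `tumor_line`, `arm`, `staining_group`,
#'   `pixel_size_um`.
#' @return A [section_stack()].
#' @export
read_stack <- function(path, manifest_entry = NULL) {
  if (!file.exists(path)) stop("cannot read TIFF: '", path, "' does not exist")
  pages <- try(tiff::readTIFF(path, all = TRUE, info = TRUE), silent = TRUE)
  if (inherits(pages, "try-error")) stop("unreadable TIFF file: '", path, "'")
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  for (i in seq_along(dims)) {
    if (length(dims[[i]]) != 2) {
      stop("page ", i, " of '", path, "' is not single-channel grayscale")
    }
    if (!identical(dims[[i]], dims[[1]])) {
      stop("channel dimension mismatch between pages of '", path, "'")
    }
  }

  meta <- list()
  sc <- stack_sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  } else {
    # fall back to a key=value description tag (e.g. from other writers)
    desc <- attr(pages[[1]], "description")
    if (!is.null(desc)) meta <- parse_description_tag(desc)
  }

  chan_names <- unlist(meta$channels)
  if (is.null(chan_names)) {
    if (length(pages) == length(CHANNEL_NAMES)) {
      chan_names <- CHANNEL_NAMES
    } else {
      stop("no channel names in metadata for '", path, "'")
    }
  }
  if (length(chan_names) != length(pages)) {
    stop("metadata names ", length(chan_names), " channels but file has ",
         length(pages), " pages")
  }

  me <- as.list(manifest_entry)
  px_meta <- meta$pixel_size_um
  px_man <- me$pixel_size_um
  if (!is.null(px_man) && is.na(px_man)) px_man <- NULL
  if (!is.null(px_meta) && !is.null(px_man) &&
      abs(as.numeric(px_meta) - as.numeric(px_man)) > 1e-9) {
    stop("pixel size conflict for '", path, "': metadata says ", px_meta,
         " um/px, manifest says ", px_man)
  }
  px <- if (!is.null(px_meta)) as.numeric(px_meta) else as.numeric(px_man %||% NA)
  if (is.na(px)) stop("pixel size missing from both metadata and manifest")

  pick <- function(field) {
    v <- me[[field]] %||% meta[[field]] %||% NA_character_
    if (is.null(v) || length(v) == 0) NA_character_ else as.character(v)
  }
  channels <- lapply(pages, function(p) {
    m <- round(unclass(p) * INTENSITY_MAX)
    attributes(m) <- list(dim = dim(p))
    m
  })
  names(channels) <- chan_names
  section_stack(channels, pixel_size_um = px,
                section_id = pick("section_id"),
                tumor_line = pick("tumor_line"),
                arm = pick("arm"),
                staining_group = pick("staining_group"))
}

parse_description_tag <- function(desc) {
  parts <- strsplit(strsplit(desc, "[;\n]")[[1]], "=")
  kv <- list()
  for (p in parts) {
    if (length(p) == 2) kv[[trimws(p[1])]] <- trimws(p[2])
  }
  out <- list()
  if (!is.null(kv$channels)) out$channels <- strsplit(kv$channels, ",")[[1]]
  if (!is.null(kv$pixel_size_um)) out$pixel_size_um <- as.numeric(kv$pixel_size_um)
  for (f in c("section_id", "tumor_line", "arm", "staining_group")) {
    if (!is.null(kv[[f]])) out[[f]] <- kv[[f]]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cohort manifest CSV
#'
#' Columns: `section_id, tumor_line, arm, staining_group, path,
#' pixel_size_um`.
#'
#' @param path CSV path.
#' @return A data.frame with one row per section.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest '", path, "' does not exist")
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("section_id", "tumor_line", "arm", "staining_group", "path",
            "pixel_size_um")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  m
}

#' Construct one microscope field of view
#'
#' @param pixels Non-negative intensity matrix.
#' @param pixel_size_um Micrometers per pixel edge.
#' @param grid_position Integer `(row, col)` of the field within the
#'   acquisition grid (1-based).
#' @return An object of class `field_image`.
#' @export
field_image <- function(pixels, pixel_size_um = 0.75, grid_position = c(1L, 1L)) {
  stopifnot(is.matrix(pixels), all(pixels >= 0), pixel_size_um > 0,
            length(grid_position) == 2)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 grid_position = as.integer(grid_position)),
            class = "field_image")
}

#' Tile adjacent fields of view into one mosaic
#'
#' Fields are placed on a regular grid; within overlap bands the
#' later-placed field (raster order: rows, then columns) wins. No
#' blending is performed, so binary masks tile without interpolation
#' artifacts.
#'
#' @param fields List of [field_image()] objects forming a complete
#'   rectangular grid (every `(row, col)` combination present once).
#' @param overlap_px Overlap between adjacent fields, in pixels.
#' @return A [field_image()] covering the full mosaic.
#' @export
tile_mosaic <- function(fields, overlap_px = 0L) {
  stopifnot(length(fields) >= 1, overlap_px >= 0)
  pos <- t(vapply(fields, function(f) f$grid_position, integer(2)))
  nr <- max(pos[, 1]); nc <- max(pos[, 2])
  key <- paste(pos[, 1], pos[, 2])
  want <- as.vector(outer(seq_len(nr), seq_len(nc), paste))
  if (anyDuplicated(key) || !setequal(key, want) || length(fields) != nr * nc) {
    stop("fields do not form a complete rectangular grid")
  }
  d0 <- dim(fields[[1]]$pixels)
  for (f in fields) {
    if (!identical(dim(f$pixels), d0)) stop("inconsistent field sizes")
    if (f$pixel_size_um != fields[[1]]$pixel_size_um) {
      stop("inconsistent pixel sizes")
    }
  }
  H <- d0[1]; W <- d0[2]
  if (overlap_px >= H || overlap_px >= W) {
    stop("overlap_px must be smaller than the field dimensions")
  }
  out <- matrix(0, nr * (H - overlap_px) + overlap_px,
                nc * (W - overlap_px) + overlap_px)
  ord <- order(pos[, 1], pos[, 2])
  for (i in ord) {
    r0 <- (pos[i, 1] - 1) * (H - overlap_px)
    c0 <- (pos[i, 2] - 1) * (W - overlap_px)
    out[r0 + seq_len(H), c0 + seq_len(W)] <- fields[[i]]$pixels
  }
  field_image(out, fields[[1]]$pixel_size_um, c(1L, 1L))
}

#' Register two imaging rounds by integer translation
#'
#' Finds the integer pixel shift `(dy, dx)` of `moving` relative to
#' `fixed` that maximizes the normalized cross-correlation computed on
#' the overlap region, searching all shifts within `±max_shift_px`.
#' Slides re-imaged after re-staining shift by a few pixels at most;
#' rotation and scale changes are assumed negligible.
#'
#' @param fixed,moving Two intensity matrices of identical dimensions.
#' @param max_shift_px Maximum absolute shift searched on each axis.
#' @return A list with `shift` (integer `(dy, dx)`; add it to `moving`
#'   row/col coordinates to land on `fixed`), `confidence` (correlation
#'   at the optimum, `NA` when undefined), and `ncc` (the full score
#'   matrix, shifts as dimnames).
#' @export
register_rounds <- function(fixed, moving, max_shift_px = 50L) {
  stopifnot(is.matrix(fixed), is.matrix(moving), max_shift_px >= 0)
  if (!identical(dim(fixed), dim(moving))) stop("dimension mismatch")
  if (stats::sd(fixed) == 0 || stats::sd(moving) == 0) {
    warning("zero-variance image: registration undefined, returning (0, 0)")
    return(list(shift = c(dy = 0L, dx = 0L), confidence = NA_real_, ncc = NULL))
  }
  H <- nrow(fixed); W <- ncol(fixed); S <- as.integer(max_shift_px)
  shifts <- -S:S

  # cross terms for every shift at once, via zero-padded FFT correlation
  P1 <- stats::nextn(H + S, 2); P2 <- stats::nextn(W + S, 2)
  pf <- matrix(0, P1, P2); pm <- matrix(0, P1, P2)
  pf[1:H, 1:W] <- fixed; pm[1:H, 1:W] <- moving
  cc <- Re(stats::fft(stats::fft(pf) * Conj(stats::fft(pm)), inverse = TRUE)) /
    (P1 * P2)
  cross <- cc[(shifts %% P1) + 1, (shifts %% P2) + 1, drop = FALSE]

  # overlap-rectangle moment sums via integral images
  If <- integral_image(fixed);  If2 <- integral_image(fixed^2)
  Im <- integral_image(moving); Im2 <- integral_image(moving^2)
  n <- matrix(0, length(shifts), length(shifts))
  sf <- n; sf2 <- n; sm <- n; sm2 <- n
  for (i in seq_along(shifts)) {
    dy <- shifts[i]
    r1 <- max(1, 1 + dy); r2 <- min(H, H + dy)
    for (j in seq_along(shifts)) {
      dx <- shifts[j]
      c1 <- max(1, 1 + dx); c2 <- min(W, W + dx)
      n[i, j] <- (r2 - r1 + 1) * (c2 - c1 + 1)
      sf[i, j] <- rect_sum(If, r1, r2, c1, c2)
      sf2[i, j] <- rect_sum(If2, r1, r2, c1, c2)
      sm[i, j] <- rect_sum(Im, r1 - dy, r2 - dy, c1 - dx, c2 - dx)
      sm2[i, j] <- rect_sum(Im2, r1 - dy, r2 - dy, c1 - dx, c2 - dx)
    }
  }
  vf <- sf2 - sf^2 / n
  vm <- sm2 - sm^2 / n
  ncc <- (cross - sf * sm / n) / sqrt(pmax(vf, 0) * pmax(vm, 0))
  eps <- 1e-9 * max(abs(fixed))^2 * pmax(n, 1)
  ncc[vf <= eps | vm <= eps | n < 2] <- NA_real_
  dimnames(ncc) <- list(shifts, shifts)

  if (all(is.na(ncc))) {
    warning("no shift with defined correlation; returning (0, 0)")
    return(list(shift = c(dy = 0L, dx = 0L), confidence = NA_real_, ncc = ncc))
  }
  best <- max(ncc, na.rm = TRUE)
  cand <- which(ncc > best - 1e-12, arr.ind = TRUE)
  dy <- shifts[cand[, 1]]; dx <- shifts[cand[, 2]]
  k <- order(abs(dy) + abs(dx), dy, dx)[1]  # tie-break: smallest shift
  list(shift = c(dy = dy[k], dx = dx[k]),
       confidence = ncc[cand[k, 1], cand[k, 2]],
       ncc = ncc)
}

integral_image <- function(m) {
  apply(apply(m, 2, cumsum), 1, cumsum) |> t()
}

rect_sum <- function(ii, r1, r2, c1, c2) {
  s <- ii[r2, c2]
  if (r1 > 1) s <- s - ii[r1 - 1, c2]
  if (c1 > 1) s <- s - ii[r2, c1 - 1]
  if (r1 > 1 && c1 > 1) s <- s + ii[r1 - 1, c1 - 1]
  s
}

#' Apply an integer translation to an image
#'
#' Shifts the image by `(dy, dx)` pixels, filling vacated pixels with
#' `fill`. `apply_shift(moving, register_rounds(fixed, moving)$shift)`
#' overlays `moving` onto `fixed`.
#'
#' @param img Intensity matrix.
#' @param shift Integer `(dy, dx)`.
#' @param fill Fill value for uncovered pixels.
#' @return Shifted matrix of the same dimensions.
#' @export
apply_shift <- function(img, shift, fill = 0) {
  dy <- as.integer(shift[1]); dx <- as.integer(shift[2])
  H <- nrow(img); W <- ncol(img)
  out <- matrix(fill, H, W)
  rs <- intersect(seq_len(H), seq_len(H) + dy)
  cs <- intersect(seq_len(W), seq_len(W) + dx)
  if (length(rs) && length(cs)) out[rs, cs] <- img[rs - dy, cs - dx]
  out
}
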