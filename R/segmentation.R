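# Binarization and boundary tracing for nucleus-stained grayscale images.
#
# Frame convention used throughout: image row r, column c maps to the y-up
# Cartesian point (x, y) = (c - 1, -(r - 1)), origin at the top-left pixel
# center. All geometry (chain codes, contours, angles) lives in that frame;
# only the raster containers are row-major.

#' Otsu discriminant-analysis threshold
#'
#' Selects the grey level that maximizes the between-class variance of the
#' grey-level histogram (discriminant-analysis binarization). Foreground is
#' the bright class: pixels with value greater than or equal to the
#' threshold. Ties are broken toward the lowest maximizing level.
#'
#' @param image Integer/numeric matrix of grey values in 0..255 with at
#'   least two distinct levels.
#' @return A list with \code{threshold} (grey level in 1..255) and
#'   \code{mask} (logical matrix of foreground pixels).
#' @export
otsu_threshold <- function(image) {
  img <- round(as.matrix(image))
  if (any(!is.finite(img)) || any(img < 0) || any(img > 255))
    stop("image values must be finite grey levels in 0..255")
  counts <- tabulate(as.integer(img) + 1L, nbins = 256L)
  if (sum(counts > 0) < 2L) stop("degenerate histogram: image has a single grey level")
  ntot <- sum(counts)
  lv <- 0:255
  cw <- cumsum(counts)              # pixels with level <= lv
  cm <- cumsum(counts * lv)         # first moment up to lv
  # threshold k splits {< k} vs {>= k}; k in 1..255
  w0 <- cw[1:255] / ntot
  mu0 <- ifelse(cw[1:255] > 0, cm[1:255] / cw[1:255], 0)
  w1 <- 1 - w0
  mu1 <- ifelse(cw[1:255] < ntot, (cm[256] - cm[1:255]) / (ntot - cw[1:255]), 0)
  sigma_b <- w0 * w1 * (mu0 - mu1)^2
  k <- which.max(sigma_b)           # first maximum = lowest level
  list(threshold = k, mask = img >= k)
}

#' Label 8-connected foreground components
#'
#' Frontier breadth-first labeling; diagonal neighbors are connected.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of the same shape: 0 for background, 1..K for
#'   components (numbered in raster-scan order of their first pixel).
#' @export
label_components <- function(mask) {
  mask <- as.matrix(mask)
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  off <- c(-1L, 1L, -H, H, -H - 1L, -H + 1L, H - 1L, H + 1L)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  plab <- matrix(0L, H + 2L, W + 2L)
  Hp <- H + 2L
  offp <- c(-1L, 1L, -Hp, Hp, -Hp - 1L, -Hp + 1L, Hp - 1L, Hp + 1L)
  todo <- which(pad)
  # raster-scan order of first pixels: column-major in the padded frame;
  # convert to row-major ordering for deterministic numbering
  rc <- cbind((todo - 1L) %% Hp + 1L, (todo - 1L) %/% Hp + 1L)
  todo <- todo[order(rc[, 1L], rc[, 2L])]
  k <- 0L
  for (s in todo) {
    if (plab[s] != 0L) next
    k <- k + 1L
    plab[s] <- k
    frontier <- s
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, offp, `+`)))
      nb <- nb[pad[nb] & plab[nb] == 0L]
      plab[nb] <- k
      frontier <- nb
    }
  }
  lab[] <- plab[2:(H + 1L), 2:(W + 1L)]
  lab
}

# Moore-neighbor boundary trace of one labeled component, clockwise in image
# (row, col) coordinates, which is counter-clockwise in the y-up frame.
# Returns the ordered (r, c) boundary pixel matrix.
.moore_trace <- function(fg, start_rc) {
  # clockwise neighbor order starting west: W NW N NE E SE S SW
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  H <- nrow(fg); W <- ncol(fg)
  inside <- function(r, c) r >= 1L && r <= H && c >= 1L && c <= W && fg[r, c]
  path_r <- integer(0); path_c <- integer(0)
  cur <- start_rc
  back_dir <- 1L                       # backtrack points west of the start
  first_move <- NA_integer_
  max_steps <- 8L * sum(fg) + 8L
  steps <- 0L
  repeat {
    found <- FALSE
    for (i in 0:7) {
      dir <- ((back_dir - 1L + i) %% 8L) + 1L
      r2 <- cur[1L] + dr[dir]; c2 <- cur[2L] + dc[dir]
      if (inside(r2, c2)) {
        if (!is.na(first_move) && all(cur == start_rc) && dir == first_move) {
          return(cbind(r = path_r, c = path_c))   # Jacob's stopping criterion
        }
        path_r <- c(path_r, cur[1L]); path_c <- c(path_c, cur[2L])
        if (is.na(first_move)) first_move <- dir
        # new backtrack: the neighbor examined just before the hit,
        # expressed as a direction from the new pixel
        pr <- cur[1L] + dr[((dir - 2L) %% 8L) + 1L]
        pc <- cur[2L] + dc[((dir - 2L) %% 8L) + 1L]
        ddr <- pr - r2; ddc <- pc - c2
        back_dir <- which(dr == ddr & dc == ddc)
        cur <- c(r2, c2)
        found <- TRUE
        break
      }
    }
    if (!found) return(cbind(r = cur[1L], c = cur[2L]))   # isolated pixel
    steps <- steps + 1L
    if (steps > max_steps) stop("boundary trace failed to terminate")
  }
}

#' Extract object boundaries as Freeman chain codes
#'
#' Labels 8-connected foreground components, drops those smaller than
#' \code{min_area}, and traces the outer boundary of each retained component
#' (Moore-neighbor tracing). Chains are emitted counter-clockwise in the
#' y-up frame (positive signed area after decoding); holes are ignored.
#'
#' @param mask Logical matrix (or the \code{mask} element returned by
#'   [otsu_threshold()]).
#' @param min_area Minimum component area in pixels squared (default 200).
#' @param id_prefix Prefix for generated specimen ids.
#' @return A list of [chain_code()] objects (possibly empty).
#' @export
extract_contours <- function(mask, min_area = 200, id_prefix = "obj") {
  if (is.list(mask) && !is.null(mask$mask)) mask <- mask$mask
  mask <- as.matrix(mask)
  if (!any(mask)) stop("empty mask: nothing to trace")
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  out <- list()
  for (k in keep) {
    fg <- lab == k
    idx <- which(fg, arr.ind = TRUE)
    ord <- order(idx[, 1L], idx[, 2L])    # topmost, then leftmost
    px <- .moore_trace(fg, idx[ord[1L], ])
    if (nrow(px) < 3L) next
    # to y-up coordinates
    xs <- px[, 2L] - 1L
    ys <- -(px[, 1L] - 1L)
    # enforce counter-clockwise orientation
    area <- polygon_area(unique(cbind(xs, ys)))
    if (area < 0) { xs <- rev(xs); ys <- rev(ys) }
    dxy <- cbind(diff(c(xs, xs[1L])), diff(c(ys, ys[1L])))
    codes <- .delta_to_code(dxy)
    out[[length(out) + 1L]] <- chain_code(
      specimen_id = sprintf("%s_%d", id_prefix, k),
      start = c(xs[1L], ys[1L]),
      codes = codes
    )
  }
  out
}

#' Read an 8-bit grayscale image (PNG or TIFF)
#'
#' @param path File path; format chosen by extension.
#' @return Integer matrix of grey values in 0..255.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]    # first channel
  img <- round(arr * 255)
  storage.mode(img) <- "integer"
  img
}

#' Write an 8-bit grayscale image (PNG or TIFF)
#'
#' @param image Integer matrix of grey values in 0..255.
#' @param path Destination path; format chosen by extension.
#' @export
write_gray_image <- function(image, path) {
  arr <- as.matrix(image) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, path),
    tif = , tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    stop("unsupported image format: ", ext))
  invisible(path)
}
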