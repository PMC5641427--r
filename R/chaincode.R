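# Freeman chain codes and the .chc text dialect.
#
# Directions are in the y-up frame: 0 = +x, 1 = +x+y, 2 = +y, 3 = -x+y,
# 4 = -x, 5 = -x-y, 6 = -y, 7 = +x-y (odd codes are diagonals).
# File dialect (one record per line, ASCII, single-space separated):
#   specimen_id start_x start_y code1 code2 ... codeK
# '#' begins a comment line; blank lines are ignored; the reader tolerates
# CRLF endings and repeated whitespace, the writer emits the canonical form
# with LF endings.

.code_dx <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
.code_dy <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

.delta_to_code <- function(dxy) {
  code <- integer(nrow(dxy))
  for (i in seq_len(nrow(dxy))) {
    m <- which(.code_dx == dxy[i, 1L] & .code_dy == dxy[i, 2L])
    if (!length(m)) stop("step (", dxy[i, 1L], ",", dxy[i, 2L],
                         ") is not an 8-neighbor move")
    code[i] <- m - 1L
  }
  code
}

#' Construct a Freeman chain code
#'
#' @param specimen_id Record identifier.
#' @param start Integer (x, y) start pixel in the y-up frame.
#' @param codes Integer vector of directions in 0..7.
#' @return An object of class \code{"chain_code"}.
#' @export
chain_code <- function(specimen_id, start, codes) {
  codes <- as.integer(codes)
  if (length(codes) && (any(codes < 0L) || any(codes > 7L)))
    stop("chain codes must be digits 0-7")
  disp <- c(sum(.code_dx[codes + 1L]), sum(.code_dy[codes + 1L]))
  if (any(disp != 0L))
    stop("chain '", specimen_id, "' is not closed (net displacement ",
         disp[1L], ",", disp[2L], ")")
  structure(list(specimen_id = as.character(specimen_id),
                 start = as.integer(start), codes = codes),
            class = "chain_code")
}

#' Parse a .chc chain-code file
#'
#' Reads the documented dialect (see the package-level notes in this file):
#' one record per line, \code{id start_x start_y codes...}. Blank and
#' comment lines are skipped. Every chain is validated for closure;
#' duplicated specimen ids are suffixed deterministically (\code{_2},
#' \code{_3}, ...).
#'
#' @param input Path to a file, or a character vector of lines.
#' @return A list of [chain_code()] objects.
#' @export
parse_chc <- function(input) {
  lines <- if (length(input) == 1L && file.exists(input)) readLines(input, warn = FALSE)
           else as.character(input)
  lines <- sub("\r$", "", lines)
  out <- list()
  seen <- character(0)
  for (ln in seq_along(lines)) {
    s <- trimws(lines[[ln]])
    if (s == "" || startsWith(s, "#")) next
    tok <- strsplit(s, "[ \t]+")[[1L]]
    if (length(tok) < 4L)
      stop("parse error at line ", ln, ": expected 'id start_x start_y codes...'")
    id <- tok[1L]
    start <- suppressWarnings(as.integer(tok[2:3]))
    if (any(is.na(start)))
      stop("parse error at line ", ln, ": start pixel is not integer")
    if (any(!grepl("^[0-7]$", tok[-(1:3)])))
      stop("parse error at line ", ln, ": chain digit outside 0-7")
    codes <- as.integer(tok[-(1:3)])
    if (id %in% seen) {
      k <- 2L
      while (paste0(id, "_", k) %in% seen) k <- k + 1L
      id <- paste0(id, "_", k)
    }
    seen <- c(seen, id)
    out[[length(out) + 1L]] <- chain_code(id, start, codes)
  }
  out
}

#' Write chain codes in the canonical .chc dialect
#'
#' Emits one single-space-separated record per line with LF endings;
#' [parse_chc()] inverts the output exactly.
#'
#' @param chains List of [chain_code()] objects.
#' @param path Destination file path, or \code{NULL} to return the lines.
#' @return Invisibly, the character vector of lines.
#' @export
write_chc <- function(chains, path = NULL) {
  lines <- vapply(chains, function(ch) {
    paste(c(ch$specimen_id, ch$start, ch$codes), collapse = " ")
  }, character(1L))
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (length(lines)) writeLines(lines, con, sep = "\n", useBytes = TRUE)
  }
  invisible(lines)
}

#' Decode a chain code into a contour
#'
#' Accumulates the displacements from the start pixel (y-up frame) into a
#' vertex list; the closing vertex is not duplicated. Counter-clockwise
#' orientation is enforced by reversing the vertex order when the signed
#' area is negative. Self-crossing chains are accepted but flagged via the
#' \code{"self_crossing"} attribute.
#'
#' @param chain A [chain_code()] object.
#' @return A contour matrix with attribute \code{self_crossing}.
#' @export
chain_to_contour <- function(chain) {
  stopifnot(inherits(chain, "chain_code"))
  x <- chain$start[1L] + cumsum(c(0L, .code_dx[chain$codes + 1L]))
  y <- chain$start[2L] + cumsum(c(0L, .code_dy[chain$codes + 1L]))
  x <- x[-length(x)]; y <- y[-length(y)]      # drop the repeated closing vertex
  xy <- cbind(x = as.numeric(x), y = as.numeric(y))
  dup <- duplicated(xy)
  test_xy <- xy[!dup, , drop = FALSE]
  if (nrow(test_xy) < 3L || abs(polygon_area(test_xy)) < .Machine$double.eps)
    stop("chain '", chain$specimen_id, "' encloses zero area")
  if (polygon_area(test_xy) < 0) {
    n <- nrow(xy)
    xy <- xy[c(1L, n:2L), , drop = FALSE]
  }
  simple <- !any(dup) && is_simple_polygon(xy)
  attr(xy, "self_crossing") <- !simple
  xy
}

#' Export contours as a long-format CSV table
#'
#' @param contours Named list of contour matrices (names = specimen ids).
#' @param path Destination CSV path.
#' @return Invisibly, the written data frame (columns \code{specimen_id},
#'   \code{vertex_index}, \code{x}, \code{y}).
#' @export
write_contour_csv <- function(contours, path) {
  df <- do.call(rbind, lapply(names(contours), function(id) {
    xy <- as_contour(contours[[id]])
    data.frame(specimen_id = id, vertex_index = seq_len(nrow(xy)),
               x = xy[, 1L], y = xy[, 2L], stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read contours from a long-format CSV table
#'
#' @param path CSV with columns \code{specimen_id}, \code{vertex_index},
#'   \code{x}, \code{y}.
#' @return Named list of contour matrices.
#' @export
read_contour_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "vertex_index", "x", "y")
  if (!all(need %in% names(df)))
    stop("contour CSV must have columns: ", paste(need, collapse = ", "))
  df <- df[order(df$specimen_id, df$vertex_index), ]
  lapply(split(df, df$specimen_id), function(d) as_contour(cbind(d$x, d$y)))
}
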