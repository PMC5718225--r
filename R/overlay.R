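# Colour-coded slice overlays: grayscale anatomy, vortex intensity washed
# from blue (low) to red (high), plus a colourbar with numeric bounds.
# Rendering is pure pixel arithmetic (png::writePNG), so output is
# deterministic byte-for-byte for fixed inputs.

# 3x5 bitmap glyphs for colourbar labels
.glyphs <- list(
  "0" = c("111", "101", "101", "101", "111"),
  "1" = c("010", "110", "010", "010", "111"),
  "2" = c("111", "001", "111", "100", "111"),
  "3" = c("111", "001", "111", "001", "111"),
  "4" = c("101", "101", "111", "001", "001"),
  "5" = c("111", "100", "111", "001", "111"),
  "6" = c("111", "100", "111", "101", "111"),
  "7" = c("111", "001", "010", "010", "010"),
  "8" = c("111", "101", "111", "101", "111"),
  "9" = c("111", "101", "111", "001", "111"),
  "." = c("000", "000", "000", "000", "010"),
  "-" = c("000", "000", "111", "000", "000"),
  "e" = c("000", "111", "111", "100", "111"),
  "+" = c("000", "010", "111", "010", "000"),
  " " = c("000", "000", "000", "000", "000"))

draw_text <- function(canvas, text, row, col, value = 1) {
  chars <- strsplit(text, "")[[1]]
  for (ch in chars) {
    g <- .glyphs[[ch]] %||% .glyphs[[" "]]
    for (r in 1:5) {
      bits <- strsplit(g[r], "")[[1]] == "1"
      for (cc in which(bits)) {
        rr <- row + r - 1L; c2 <- col + cc - 1L
        if (rr >= 1 && rr <= dim(canvas)[1] && c2 >= 1 && c2 <= dim(canvas)[2])
          canvas[rr, c2, 1:3] <- value
      }
    }
    col <- col + 4L
  }
  canvas
}

#' Blue-to-red colormap
#'
#' Maps `[0, 1]` through blue -> cyan -> green -> yellow -> red, the
#' conventional jet-like coding of vortex intensity.
#'
#' @param t numeric vector in `[0, 1]` (clamped).
#' @return An n x 3 matrix of RGB values in `[0, 1]`.
#' @export
blue_red_colormap <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  r <- pmin(pmax(1.5 - abs(4 * t - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * t - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * t - 1), 0), 1)
  cbind(r, g, b)
}

extract_slice <- function(vals, axis, index) {
  switch(axis,
         sagittal = vals[index, , ],
         coronal  = vals[, index, ],
         axial    = vals[, , index])
}

#' Render colour-coded vortex overlays on anatomy slices
#'
#' For each requested slice the anatomy is windowed to grayscale and the
#' vortex map is colour-washed (blue = low to red = high over
#' `[0, display_max]`) wherever it exceeds `display_threshold`, so plausible
#' background stays uncoloured. A colourbar with numeric bounds is drawn on
#' the right. One PNG per slice is written.
#'
#' @param image anatomy [image_volume()]; `NULL` renders on black.
#' @param map the `vortex_map` on the same grid.
#' @param out_dir output directory (created if absent).
#' @param axis `"axial"` (z slices), `"coronal"` (y) or `"sagittal"` (x).
#' @param slices 1-based slice indices along the chosen axis.
#' @param display_threshold map value below which nothing is coloured
#'   (default 3, the borderline band minimum).
#' @param display_max map value mapped to red; defaults to `max(map)`.
#'   Fix it across cases for comparability.
#' @param alpha overlay opacity in `[0, 1]`.
#' @param window grayscale window `c(low, high)`; defaults to image range.
#' @return Invisibly, the written file paths.
#' @export
render_overlay <- function(image, map, out_dir, axis = "axial",
                           slices = NULL, display_threshold = 3,
                           display_max = NULL, alpha = 0.6,
                           window = NULL) {
  stopifnot(inherits(map, "image_volume"))
  axis <- match.arg(axis, c("axial", "coronal", "sagittal"))
  if (!is.null(image)) stop_if_incompatible(map, image, "image/map grids")
  n_axis <- switch(axis, sagittal = map$shape[1], coronal = map$shape[2],
                   axial = map$shape[3])
  if (is.null(slices)) slices <- ceiling(n_axis / 2)
  if (any(slices < 1L | slices > n_axis))
    stop("slice index out of range (1..", n_axis, ")")
  if (is.null(display_max) || !is.finite(display_max))
    display_max <- max(map$values)
  if (display_max <= 0) display_max <- 1
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  for (sl in slices) {
    ms <- extract_slice(map$values, axis, sl)
    base <- if (is.null(image)) array(0, dim(ms))
            else extract_slice(image$values, axis, sl)
    win <- if (is.null(window)) range(base) else window
    if (diff(win) <= 0) win <- win + c(0, 1)
    gray <- pmin(pmax((base - win[1]) / (win[2] - win[1]), 0), 1)
    # image rows top-to-bottom: second slice axis reversed, first across
    nx <- dim(ms)[1]; ny <- dim(ms)[2]
    canvas <- array(0, c(ny, nx, 3))
    gs <- t(gray)[ny:1, , drop = FALSE]
    for (k in 1:3) canvas[, , k] <- gs
    sel <- t(ms)[ny:1, , drop = FALSE] > display_threshold
    if (any(sel)) {
      cols <- blue_red_colormap(t(ms)[ny:1, , drop = FALSE][sel] / display_max)
      for (k in 1:3)
        canvas[, , k][sel] <- (1 - alpha) * gs[sel] + alpha * cols[, k]
    }
    # colourbar: 8 px wide with 2 px gap, labelled with bounds
    barw <- 10L
    full <- array(0, c(ny, nx + barw + 30L, 3))
    full[, seq_len(nx), ] <- canvas
    tvals <- seq(1, 0, length.out = ny)
    barcols <- blue_red_colormap(tvals)
    for (k in 1:3)
      full[, nx + 3L:barw, k] <- matrix(barcols[, k], ny, barw - 2L)
    full <- draw_text(full, format_label(display_max), 1L, nx + barw + 2L)
    full <- draw_text(full, format_label(display_threshold), ny - 5L,
                      nx + barw + 2L)
    f <- file.path(out_dir, sprintf("%s_%03d.png", axis, sl))
    png::writePNG(full, f)
    paths <- c(paths, f)
  }
  invisible(paths)
}

format_label <- function(x) {
  s <- formatC(x, format = "g", digits = 3)
  gsub("[^0-9.e+-]", "", s)
}
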