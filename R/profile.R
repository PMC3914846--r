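#' Windowed percent-identity profile of an alignment
#'
#' For each non-gap element Q'_i of the aligned query, the fraction of
#' matching columns (M = 1) in a window of `w` alignment columns centred on
#' i is computed; at the alignment ends the window is clipped to the
#' alignment and normalised by the clipped column count, which reproduces
#' the edge-branch normalisers `1/(z + i)` and `1/(z + m - i + 1)` of the
#' windowed-identity formula (z = floor(w/2)). Window sums run over
#' alignment columns, so gap columns inside a window depress local identity.
#' Collecting the values in query order gives a vector P whose length equals
#' the ungapped query length q.
#'
#' @param a An `alignment_result` from [global_align()].
#' @param w Odd window size (alignment columns). Default 21, roughly
#'   codon-scale smoothing.
#' @param on Which sequence's non-gap positions index the profile:
#'   `"query"` (default) or `"reference"` (used for the reciprocal strip).
#' @return An object of class `identity_profile`: `values` (P, in `[0,1]`),
#'   `window` (w), `half_window` (z), `query_positions` (0-based ungapped
#'   positions).
#' @export
compute_profile <- function(a, w = 21L, on = c("query", "reference")) {
  stopifnot(inherits(a, "alignment_result"))
  on <- match.arg(on)
  w <- as.integer(w)
  if (is.na(w) || w < 1L || w %% 2L == 0L)
    stop("window size w must be a positive odd integer", call. = FALSE)
  z <- w %/% 2L
  m <- a$m
  M <- a$match_seq
  cs <- c(0, cumsum(M))
  i <- seq_len(m)
  lo <- pmax(1L, i - z)
  hi <- pmin(m, i + z)
  vals <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  chars <- strsplit(if (on == "query") a$q_aligned else a$r_aligned, "")[[1]]
  keep <- chars != "-"
  structure(list(values = vals[keep], window = w, half_window = z,
                 query_positions = seq_len(sum(keep)) - 1L, on = on),
            class = "identity_profile")
}

#' @export
print.identity_profile <- function(x, ...) {
  cat(sprintf("<identity_profile> q = %d, w = %d, mean identity %.1f%%\n",
              length(x$values), x$window, 100 * mean(x$values)))
  invisible(x)
}

#' Profile as a position/identity table
#'
#' @param p An `identity_profile`.
#' @return Data frame with `position` (1-based on the ungapped sequence) and
#'   `identity` in `[0, 1]`.
#' @export
profile_table <- function(p) {
  stopifnot(inherits(p, "identity_profile"))
  data.frame(position = p$query_positions + 1L, identity = p$values)
}

#' Colour gradient for identity values
#'
#' @param name An `hcl.colors` palette name; the default "Viridis" is
#'   perceptually uniform from low to high identity.
#' @return A function mapping values in `[0,1]` to hex colours on a fixed
#'   0-100% scale.
#' @export
identity_gradient <- function(name = "Viridis") {
  pal <- grDevices::hcl.colors(256L, palette = name)
  function(v) {
    v <- pmin(1, pmax(0, v))
    pal[1L + as.integer(round(v * 255))]
  }
}

#' Render identity profiles as an annotated heatmap PNG
#'
#' One coloured strip per profile, one cell per ungapped nucleotide, with
#' solid black bars above each strip marking ORFs at their transcript
#' coordinates and a 0-100% gradient scale bar at the bottom. With two
#' profiles the reciprocal (reference-as-query) strip is drawn below the
#' query strip. The raster is written directly so every cell's colour is
#' exact and reproducible.
#'
#' @param profiles An `identity_profile` or list of one or two.
#' @param features ORF annotations for the first strip: a list of
#'   `list(label, interval)` pairs with [orf_interval()] coordinates on the
#'   ungapped sequence; or a list of two such lists (one per strip).
#' @param gradient Palette name passed to [identity_gradient()].
#' @param out Output PNG path.
#' @param cell_width,cell_height Pixel size of one nucleotide cell.
#' @return (Invisibly) the layout: image size and the pixel row/column
#'   ranges of each strip, usable to inspect rendered cell colours.
#' @export
render_heatmap <- function(profiles, features = list(), gradient = "Viridis",
                           out, cell_width = 1L, cell_height = 12L) {
  if (inherits(profiles, "identity_profile")) profiles <- list(profiles)
  if (!length(profiles) || length(profiles) > 2L ||
      !all(vapply(profiles, inherits, TRUE, "identity_profile")))
    stop("profiles must be one or two identity_profile objects", call. = FALSE)
  is_feat <- function(f)
    is.list(f) && length(f) >= 2L && inherits(f[[2]], "orf_interval")
  feats <- if (!length(features)) list(list(), list())
  else if (all(vapply(features, is_feat, TRUE))) list(features, list())
  else features
  grad <- identity_gradient(gradient)

  bar_h <- 4L; gap_h <- 2L; scale_h <- 6L
  qs <- vapply(profiles, function(p) length(p$values), 1L)
  width <- max(qs) * cell_width
  height <- length(profiles) * (bar_h + gap_h + cell_height + gap_h) +
    gap_h + scale_h
  img <- array(1, dim = c(height, width, 3))  # white background
  layout <- list(file = out, width = width, height = height,
                 cell_width = cell_width, strips = list())

  row <- 0L
  for (k in seq_along(profiles)) {
    p <- profiles[[k]]
    ncol_k <- qs[k] * cell_width
    # ORF bars
    fk <- if (k <= length(feats)) feats[[k]] else list()
    bar_rows <- (row + 1L):(row + bar_h)
    for (f in fk) {
      iv <- if (!is.null(f$interval)) f$interval else f[[2]]
      lo <- iv$start * cell_width + 1L
      hi <- min(iv$end * cell_width, width)
      if (lo <= hi) img[bar_rows, lo:hi, ] <- 0
    }
    row <- row + bar_h + gap_h
    strip_rows <- (row + 1L):(row + cell_height)
    cols_rgb <- grDevices::col2rgb(grad(p$values)) / 255
    for (ch in 1:3) {
      rowvals <- rep(cols_rgb[ch, ], each = cell_width)
      img[strip_rows, seq_len(ncol_k), ch] <-
        matrix(rowvals, nrow = cell_height, ncol = ncol_k, byrow = TRUE)
    }
    layout$strips[[k]] <- list(bar_rows = bar_rows, strip_rows = strip_rows,
                               q = qs[k])
    row <- row + cell_height + gap_h
  }
  # scale bar: 0 -> 100% left to right across the full width
  row <- row + gap_h
  ramp <- grDevices::col2rgb(grad(seq(0, 1, length.out = width))) / 255
  for (ch in 1:3)
    img[(row + 1L):(row + scale_h), , ch] <-
      matrix(ramp[ch, ], nrow = scale_h, ncol = width, byrow = TRUE)
  layout$scale_rows <- (row + 1L):(row + scale_h)

  ok <- tryCatch({ png::writePNG(img, out); TRUE },
                 error = function(e) stop("cannot write heatmap to '", out,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  invisible(layout)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
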