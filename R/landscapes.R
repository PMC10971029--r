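#' Free-energy landscape over a pair of PC scores
#'
#' Builds the empirical joint probability of two principal-component
#' scores over pooled trajectory frames (2-D histogram over the data
#' range, padded by 1% of the span per side) and converts it to a relative
#' free energy `F = -ln(P / P_max)` in kT units: the most occupied bin has
#' F = 0, empty bins are undefined (`NA`), never capped. Temperature
#' enters only through the kT unit label.
#'
#' @param proj a `projection_series` or list of them (pooled).
#' @param pc_pair integer pair `(i, j)`, `i != j`.
#' @param bins bins per axis (default 50).
#' @param pad fractional range padding per side (default 0.01).
#' @return object of class `fel_grid`: `pc_pair`, `x_edges`, `y_edges`,
#'   `x_centers`, `y_centers`, `probability` (sums to 1), `free_energy`
#'   (kT, min over occupied bins = 0, NA where empty), `n_frames`.
#' @export
compute_fel <- function(proj, pc_pair = c(1L, 2L), bins = 50L, pad = 0.01) {
  pc_pair <- as.integer(pc_pair)
  if (length(pc_pair) != 2L || pc_pair[1] == pc_pair[2])
    stop("pc_pair must name two distinct PCs")
  x <- pooled_scores(proj, pc_pair[1])
  y <- pooled_scores(proj, pc_pair[2])
  n <- length(x)
  if (n < 1L) stop("no frames to histogram")
  if (n < bins) warning("fewer pooled frames than bins per axis")
  xr <- range(x); yr <- range(y)
  xspan <- max(diff(xr), .Machine$double.eps)
  yspan <- max(diff(yr), .Machine$double.eps)
  x_edges <- seq(xr[1] - pad * xspan, xr[2] + pad * xspan, length.out = bins + 1L)
  y_edges <- seq(yr[1] - pad * yspan, yr[2] + pad * yspan, length.out = bins + 1L)
  ix <- findInterval(x, x_edges, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, y_edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0, bins, bins)
  tab <- table(factor(ix, levels = seq_len(bins)), factor(iy, levels = seq_len(bins)))
  counts[] <- as.numeric(tab)
  p <- counts / n
  fe <- -log(p / max(p))
  fe[counts == 0] <- NA_real_
  structure(list(pc_pair = pc_pair, x_edges = x_edges, y_edges = y_edges,
                 x_centers = (x_edges[-1] + x_edges[-length(x_edges)]) / 2,
                 y_centers = (y_edges[-1] + y_edges[-length(y_edges)]) / 2,
                 probability = p, free_energy = fe, n_frames = n),
            class = "fel_grid")
}

#' @export
print.fel_grid <- function(x, ...) {
  cat(sprintf("fel_grid PC%d vs PC%d: %dx%d bins over %d frames, %d occupied, max F %.2f kT\n",
              x$pc_pair[1], x$pc_pair[2], nrow(x$probability), ncol(x$probability),
              x$n_frames, sum(!is.na(x$free_energy)),
              max(x$free_energy, na.rm = TRUE)))
  invisible(x)
}

#' Image plot of a free-energy landscape
#' @param x a `fel_grid`.
#' @param y ignored.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.fel_grid <- function(x, y, ...) {
  graphics::image(x$x_centers, x$y_centers, x$free_energy,
                  xlab = paste0("PC", x$pc_pair[1], " score (A)"),
                  ylab = paste0("PC", x$pc_pair[2], " score (A)"),
                  ...)
  invisible(x)
}

#' Export a free-energy landscape as TSV (+ JSON metadata)
#' @param fel a `fel_grid`.
#' @param path output TSV path (columns: x_center, y_center, probability,
#'   free_energy_kT); metadata written alongside as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_fel <- function(fel, path) {
  grid <- expand.grid(ix = seq_along(fel$x_centers), iy = seq_along(fel$y_centers))
  df <- data.frame(x_center = fel$x_centers[grid$ix],
                   y_center = fel$y_centers[grid$iy],
                   probability = fel$probability[cbind(grid$ix, grid$iy)],
                   free_energy_kT = fel$free_energy[cbind(grid$ix, grid$iy)])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(pc_pair = fel$pc_pair, n_frames = fel$n_frames,
                            x_edges = fel$x_edges, y_edges = fel$y_edges),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}
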