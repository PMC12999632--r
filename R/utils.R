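#' @importFrom stats rnorm lm coef setNames uniroot sd
#' @importFrom utils read.csv write.csv modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sarscan <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "sarscan_error")))
}

#' Atomic text/CSV/JSON write: write to a temp file in the same directory,
#' then rename over the target.
#' @noRd
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = paste0(".tmp-", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

# Grid nodes at integer multiples of `spacing` inside [lim[1], lim[2]].
# Phase-anchored at 0 so the measurement origin is always a node.
axis_nodes <- function(lim, spacing, tol = 1e-9) {
  stopifnot(spacing > 0)
  k1 <- ceiling(lim[1] / spacing - tol)
  k2 <- floor(lim[2] / spacing + tol)
  if (k2 < k1) return(numeric(0))
  (k1:k2) * spacing
}

# Exact bilinear interpolation of a complete rectangular grid.
# x (len nx), y (len ny) strictly increasing; z matrix nx x ny.
# Returns matrix length(xout) x length(yout).
bilinear_interp <- function(x, y, z, xout, yout) {
  nx <- length(x); ny <- length(y)
  stopifnot(nrow(z) == nx, ncol(z) == ny)
  ix <- findInterval(xout, x, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(yout, y, rightmost.closed = TRUE, all.inside = TRUE)
  wx <- (xout - x[ix]) / (x[ix + 1L] - x[ix])
  wy <- (yout - y[iy]) / (y[iy + 1L] - y[iy])
  wx <- pmin(pmax(wx, 0), 1)
  wy <- pmin(pmax(wy, 0), 1)
  nxo <- length(xout); nyo <- length(yout)
  IX <- rep.int(ix, nyo); IY <- rep(iy, each = nxo)
  WX <- rep.int(wx, nyo); WY <- rep(wy, each = nxo)
  v <- (1 - WX) * (1 - WY) * z[cbind(IX, IY)] +
    WX * (1 - WY) * z[cbind(IX + 1L, IY)] +
    (1 - WX) * WY * z[cbind(IX, IY + 1L)] +
    WX * WY * z[cbind(IX + 1L, IY + 1L)]
  matrix(v, nxo, nyo)
}

# Connected components (4-connectivity) of a logical matrix.
# Returns list(n, labels) where labels is an integer matrix (0 = background).
label_components <- function(mask) {
  idx <- which(mask)
  n_cells <- length(idx)
  labels <- matrix(0L, nrow(mask), ncol(mask))
  if (n_cells == 0L) return(list(n = 0L, labels = labels))
  nr <- nrow(mask)
  id <- integer(length(mask)); id[idx] <- seq_len(n_cells)
  rows <- ((idx - 1L) %% nr) + 1L
  # vertical neighbours (same column, next row)
  v_from <- idx[rows < nr]
  v_from <- v_from[mask[v_from + 1L]]
  # horizontal neighbours (same row, next column)
  h_from <- idx[idx + nr <= length(mask)]
  h_from <- h_from[mask[h_from + nr]]
  edges <- rbind(
    if (length(v_from)) cbind(id[v_from], id[v_from + 1L]),
    if (length(h_from)) cbind(id[h_from], id[h_from + nr])
  )
  g <- igraph::make_empty_graph(n = n_cells, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L) {
    g <- igraph::add_edges(g, t(edges))
  }
  comp <- igraph::components(g)
  labels[idx] <- comp$membership
  list(n = comp$no, labels = labels)
}

fmt17 <- function(x) sprintf("%.17g", x)
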