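#' Cubic-interpolated MPSP surface over (IRR, UPC)
#'
#' Interpolates scattered MPSP support points onto a regular (IRR, UPC)
#' grid with an exact thin-plate-spline interpolant (the surface reproduces
#' the support values).  Large scatters are first aggregated to grid-cell
#' means so the interpolant passes through local averages rather than
#' through every noisy point; grid nodes outside the convex hull of the
#' support are masked (`NA`), never extrapolated.
#'
#' @param irr,upc,mpsp Numeric vectors of support coordinates and values,
#'   or pass a `tea_scenarios` data.frame as `irr` and leave the others
#'   `NULL`.
#' @param grid_n Grid resolution per axis.
#' @param max_support Aggregation threshold: scatters larger than this are
#'   binned to roughly `max_support` cell-mean support points.
#' @return An object of class `tea_heatmap`: `irr`, `upc` (axis vectors),
#'   `mpsp` (`grid_n` x `grid_n` matrix, `NA` outside the hull) and
#'   `support` (the interpolated points).
#' @examples
#' \donttest{
#' ds <- tea_scenarios(400, seed = 9)
#' hm <- interpolate_heatmap(ds)
#' feasible_mpsp_range(hm, 0.30, c(140, 240))
#' }
#' @export
interpolate_heatmap <- function(irr, upc = NULL, mpsp = NULL,
                                grid_n = 100, max_support = 400) {
  if (is.data.frame(irr)) {
    df <- irr
    irr <- df$irr; upc <- df$upc; mpsp <- df$mpsp
  }
  stopifnot(length(irr) == length(upc), length(upc) == length(mpsp))
  ok <- is.finite(irr) & is.finite(upc) & is.finite(mpsp)
  irr <- irr[ok]; upc <- upc[ok]; mpsp <- mpsp[ok]
  if (length(irr) < 16)
    stop("need at least 16 support points spanning both axes")

  if (length(irr) > max_support) {
    nb <- max(4L, floor(sqrt(max_support)))
    bx <- cut(irr, nb, labels = FALSE, include.lowest = TRUE)
    by <- cut(upc, nb, labels = FALSE, include.lowest = TRUE)
    key <- interaction(bx, by, drop = TRUE)
    irr <- as.numeric(tapply(irr, key, mean))
    upc <- as.numeric(tapply(upc, key, mean))
    mpsp <- as.numeric(tapply(mpsp, key, mean))
  }
  support <- data.frame(irr = irr, upc = upc, mpsp = mpsp)

  # scale both axes to [0, 1] for conditioning
  rx <- range(irr); ry <- range(upc)
  if (diff(rx) == 0 || diff(ry) == 0)
    stop("support points must span both axes")
  sx <- (irr - rx[1]) / diff(rx)
  sy <- (upc - ry[1]) / diff(ry)

  w <- .tps_fit(sx, sy, mpsp)
  gx <- seq(0, 1, length.out = grid_n)
  gy <- seq(0, 1, length.out = grid_n)
  g <- expand.grid(x = gx, y = gy)
  z <- .tps_eval(w, sx, sy, g$x, g$y)

  hull <- grDevices::chull(sx, sy)
  inside <- .in_convex_hull(g$x, g$y, sx[hull], sy[hull])
  z[!inside] <- NA_real_
  structure(list(irr = rx[1] + gx * diff(rx),
                 upc = ry[1] + gy * diff(ry),
                 mpsp = matrix(z, grid_n, grid_n),
                 support = support),
            class = "tea_heatmap")
}

# thin-plate spline phi(r) = r^2 log(r); exact interpolation with an
# affine polynomial part, solved as one dense linear system
.tps_kernel <- function(d2) {
  k <- matrix(0, nrow(d2), ncol(d2))
  pos <- d2 > 0
  k[pos] <- 0.5 * d2[pos] * log(d2[pos])
  k
}

.tps_fit <- function(x, y, z) {
  n <- length(x)
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  K <- .tps_kernel(d2)
  P <- cbind(1, x, y)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  # tiny ridge on the kernel block guards against coincident points
  diag(A)[1:n] <- diag(A)[1:n] + 1e-12
  solve(A, c(z, 0, 0, 0))
}

.tps_eval <- function(w, x, y, qx, qy) {
  n <- length(x)
  d2 <- outer(qx, x, "-")^2 + outer(qy, y, "-")^2
  drop(.tps_kernel(d2) %*% w[1:n] + w[n + 1] + qx * w[n + 2] +
         qy * w[n + 3])
}

# point-in-convex-polygon via half-plane tests (hull vertices in order)
.in_convex_hull <- function(px, py, hx, hy, tol = 1e-9) {
  m <- length(hx)
  inside <- rep(TRUE, length(px))
  # orientation of the hull
  area <- sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)
  s <- if (area >= 0) 1 else -1
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    inside <- inside & (s * cross >= -tol)
  }
  inside
}

#' @export
print.tea_heatmap <- function(x, ...) {
  cat("MPSP(IRR, UPC) interpolated surface\n")
  cat("  grid: ", length(x$irr), "x", length(x$upc), ", support points: ",
      nrow(x$support), "\n", sep = "")
  cat("  IRR axis: ", format(range(x$irr), digits = 3)[1], " - ",
      format(range(x$irr), digits = 3)[2], "\n", sep = "")
  cat("  UPC axis: ", format(range(x$upc), digits = 4)[1], " - ",
      format(range(x$upc), digits = 4)[2], " USD/kg\n", sep = "")
  cat("  MPSP range on hull: ",
      paste(format(range(x$mpsp, na.rm = TRUE), digits = 4),
            collapse = " - "), " USD/kg\n", sep = "")
  invisible(x)
}

#' @export
plot.tea_heatmap <- function(x, ...) {
  graphics::image(x$irr, x$upc, x$mpsp,
                  col = grDevices::hcl.colors(64, "RdYlBu", rev = TRUE),
                  xlab = "IRR (after taxes)", ylab = "UPC [USD/kg]",
                  main = "MPSP [USD/kg]", ...)
  invisible(x)
}

#' MPSP range over the economically feasible region
#'
#' Minimum and maximum of the interpolated MPSP surface over grid cells
#' whose IRR meets the minimum attractive rate of return and whose UPC lies
#' inside the requested window.
#'
#' @param grid A `tea_heatmap`.
#' @param irr_min Feasibility threshold on the IRR (MARR).
#' @param upc_window `c(low, high)` window on the UPC, USD/kg.
#' @return Named vector `c(lower, upper)` in USD/kg.
#' @export
feasible_mpsp_range <- function(grid, irr_min = 0.30,
                                upc_window = c(140, 240)) {
  stopifnot(inherits(grid, "tea_heatmap"))
  ri <- grid$irr >= irr_min
  rj <- grid$upc >= upc_window[1] & grid$upc <= upc_window[2]
  cells <- grid$mpsp[ri, rj]
  cells <- cells[is.finite(cells)]
  if (!length(cells)) stop("no feasible cells in the requested window")
  c(lower = min(cells), upper = max(cells))
}
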