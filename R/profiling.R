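# From neuron coordinates to 1-D cell-density profiles: bin the (x, y)
# positions of labeled neurons within a rectangular ROI into subcells,
# convert counts to densities per unit volume using the section thickness,
# and average across the ROI width.

#' Bin neuron coordinates into a subcell count grid
#'
#' Half-open bins [lo, hi) along both axes; the trailing bin is closed so
#' neurons exactly on the far ROI edge are kept. Subcells default to the
#' 45.1 x 49.3 x 50 um counting volume.
#'
#' @param table Data frame with \code{x_um}, \code{y_um} (and optional ROI
#'   attributes \code{W}, \code{L}).
#' @param subcell Numeric length 3: subcell dx, dy, dz [um].
#' @param W,L ROI width and length [um]; default to the table attributes.
#' @return Integer matrix (x-bins x y-bins) of counts, with the binning
#'   geometry attached as attributes.
#' @export
bin_neurons <- function(table, subcell = c(45.1, 49.3, 50),
                        W = attr(table, "W"), L = attr(table, "L")) {
  stopifnot(length(subcell) == 3, all(subcell > 0))
  if (is.null(W)) W <- max(table$x_um, 0)
  if (is.null(L)) L <- max(table$y_um, 0)
  bad <- which(table$x_um < 0 | table$x_um > W | table$y_um < 0 | table$y_um > L)
  if (length(bad) > 0)
    stop("neuron coordinates outside the ROI at rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  nx <- max(1L, as.integer(ceiling(W / subcell[1])))
  ny <- max(1L, as.integer(ceiling(L / subcell[2])))
  ix <- pmin(1L + as.integer(floor(table$x_um / subcell[1])), nx)
  iy <- pmin(1L + as.integer(floor(table$y_um / subcell[2])), ny)
  grid <- matrix(0L, nx, ny)
  if (nrow(table) > 0)
    for (k in seq_len(nrow(table))) grid[ix[k], iy[k]] <- grid[ix[k], iy[k]] + 1L
  attr(grid, "subcell") <- subcell
  attr(grid, "W") <- W
  attr(grid, "L") <- L
  grid
}

#' Density profile from a subcell count grid
#'
#' Converts counts to densities (count / subcell volume) and averages
#' across the x-bins; positions are y-bin centers normalized by the ROI
#' length. Partial trailing subcells (when the ROI is not a multiple of the
#' subcell size) use their true, smaller volume.
#'
#' @param grid Count grid from \code{\link{bin_neurons}}.
#' @param subcell Subcell dimensions [um] (defaults to the grid attribute).
#' @param L ROI length [um] (defaults to the grid attribute).
#' @param W ROI width [um] (defaults to the grid attribute).
#' @return Data frame with \code{normalized_position} and \code{density}
#'   [1/um^3], with \code{length} attached as an attribute.
#' @export
profile_from_counts <- function(grid, subcell = attr(grid, "subcell"),
                                L = attr(grid, "L"), W = attr(grid, "W")) {
  if (is.null(L) || L <= 0) stop("'L' must be positive", call. = FALSE)
  nx <- nrow(grid); ny <- ncol(grid)
  dx <- rep(subcell[1], nx)
  if (!is.null(W)) dx[nx] <- W - (nx - 1) * subcell[1]
  dy <- rep(subcell[2], ny)
  dy[ny] <- L - (ny - 1) * subcell[2]
  vol <- outer(dx, dy) * subcell[3]
  dens <- colMeans(grid / vol)
  centers <- cumsum(dy) - dy / 2
  out <- data.frame(normalized_position = centers / L, density = dens)
  attr(out, "length") <- L
  out
}

#' Group profiles by timepoint and normalize by the group mean length
#'
#' ROI lengths are averaged within each imaging timepoint; each profile's
#' positions are re-normalized by its group mean length (positions keep
#' their absolute location, \code{y / L_group}).
#'
#' @param profiles List of profile data frames, each with attributes
#'   \code{length} and elements/attributes \code{cohort}, \code{timepoint}
#'   (or columns of those names).
#' @return List with \code{profiles} (positions re-normalized, with
#'   \code{group_length} attribute) and \code{group_lengths} (data frame
#'   \code{timepoint}, \code{length_um}).
#' @export
group_normalize <- function(profiles) {
  get_meta <- function(p, what) {
    v <- attr(p, what)
    if (is.null(v)) v <- unique(p[[what]])
    if (length(v) != 1) stop("profile needs a single '", what, "'", call. = FALSE)
    v
  }
  tps <- vapply(profiles, get_meta, numeric(1), what = "timepoint")
  lens <- vapply(profiles, function(p) attr(p, "length"), numeric(1))
  gl <- tapply(lens, tps, mean)
  if (any(is.na(gl))) stop("empty timepoint group", call. = FALSE)
  out <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    Lg <- gl[[as.character(tps[i])]]
    p$normalized_position <- p$normalized_position * lens[i] / Lg
    attr(p, "group_length") <- Lg
    p
  })
  list(profiles = out,
       group_lengths = data.frame(timepoint = as.numeric(names(gl)),
                                  length_um = as.numeric(gl)))
}
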