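# Mesh generation for the two computational domains: a slender bar (the
# calibration geometry, solved as a 1-D column of elements) and a
# plane-strain half disc (the folding geometry, meshed with a butterfly
# pattern: a structured half-square core surrounded by body-fitted rings so
# that no element degenerates at the center).

#' Bar mesh for the calibration geometry
#'
#' A slender bar along +x of length \code{R0} with unit (1 um x 1 um)
#' cross-section, discretized into \code{n_elems} 8-node brick elements.
#' One end is fully fixed and the four long faces carry symmetry conditions,
#' so the solution varies only along the length. The fiber field is
#' \code{N = (1, 0, 0)} everywhere.
#'
#' @param R0 Initial length [um].
#' @param n_elems Number of elements along the bar.
#' @return A list of class \code{cortexfold_mesh}, \code{type = "bar"}.
#' @export
make_bar_mesh <- function(R0 = 239, n_elems = 60) {
  stopifnot(n_elems >= 1, R0 > 0)
  x <- seq(0, R0, length.out = n_elems + 1)
  # explicit hex representation (unit cross-section): 4 nodes per axial plane
  sec <- cbind(y = c(0, 1, 1, 0), z = c(0, 0, 1, 1))
  nodes <- do.call(rbind, lapply(x, function(xi) cbind(x = xi, sec)))
  hex <- t(vapply(seq_len(n_elems), function(e) {
    a <- (e - 1L) * 4L
    c(a + 1:4, a + 5:8)
  }, integer(8)))
  structure(list(type = "bar", R0 = R0, n_elems = n_elems,
                 x = x, nodes = nodes, elements = hex,
                 N = c(1, 0, 0),
                 boundary = list(fixed = 1L, free = n_elems + 1L)),
            class = "cortexfold_mesh")
}

# Run expr with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Plane-strain half-disc mesh for the folding geometry
#'
#' Half disc of radius \code{R0} (flat cut edge on y = 0, curved free
#' surface above), meshed with 4-node quadrilaterals in a butterfly layout.
#' The cut edge carries symmetry conditions; the arc is traction-free. Each
#' element carries a radial referential fiber vector evaluated at its
#' centroid. A deterministic radial perturbation of the surface nodes
#' (amplitude \code{perturb_amp}, uniform white noise from
#' \code{perturb_seed}) can be requested to break symmetry reproducibly in
#' buckling runs.
#'
#' @param R0 Radius [um].
#' @param target_elems Requested element count; the generated count is
#'   within a few percent of it.
#' @param perturb_amp Radial surface perturbation amplitude [um] (0 = none).
#' @param perturb_seed Integer seed for the perturbation noise.
#' @return A list of class \code{cortexfold_mesh}, \code{type = "halfcircle"}.
#' @export
make_halfcircle_mesh <- function(R0 = 239, target_elems = 1147,
                                 perturb_amp = 0, perturb_seed = 20339L) {
  stopifnot(target_elems >= 16, R0 > 0)
  # choose core half-width m and ring count n_r to hit the target count
  best <- NULL
  for (m in 2:60) {
    n_r <- max(2L, as.integer(round((target_elems - 2 * m^2) / (4 * m))))
    # keep the ring region and the core balanced: flattened layouts cannot
    # resolve the thin stiff cortex, needle layouts starve the arc
    if (n_r < 0.4 * m || n_r > 1.3 * m) next
    n_el <- 2 * m^2 + 4 * m * n_r
    score <- abs(n_el - target_elems)
    if (is.null(best) || score < best$score)
      best <- list(m = m, n_r = n_r, score = score)
  }
  if (is.null(best)) best <- list(m = 2L, n_r = 2L)
  m <- best$m; n_r <- best$n_r
  a <- 0.5 * R0

  # core: half square [-a, a] x [0, a], (2m+1) x (m+1) nodes
  xs <- seq(-a, a, length.out = 2 * m + 1)
  ys <- seq(0, a, length.out = m + 1)
  core_id <- function(ix, iy) iy * (2 * m + 1) + ix + 1L  # 0-based ix, iy
  core_nodes <- cbind(rep(xs, m + 1), rep(ys, each = 2 * m + 1))

  # interface polyline (4m+1 points): left edge up, top, right edge down
  k_seq <- 0:(4 * m)
  poly_ix <- ifelse(k_seq <= m, 0L, ifelse(k_seq <= 3 * m, k_seq - m, 2L * m))
  poly_iy <- ifelse(k_seq <= m, k_seq, ifelse(k_seq <= 3 * m, m, 4L * m - k_seq))
  poly_id <- core_id(poly_ix, poly_iy)
  qx <- xs[poly_ix + 1]; qy <- ys[poly_iy + 1]
  theta <- pi - pi * k_seq / (4 * m)
  sx <- R0 * cos(theta); sy <- R0 * sin(theta)

  n_core <- nrow(core_nodes)
  outer_nodes <- NULL
  outer_id <- matrix(0L, nrow = 4 * m + 1, ncol = n_r + 1)
  outer_id[, 1] <- poly_id
  nid <- n_core
  # boundary-layer grading: cluster rings toward the outer surface so the
  # stiff cortical film (outer ~7% of the radius) holds ~3 element layers
  p_grade <- max(1, log(0.15) / log(3 / n_r))
  for (j in 1:n_r) {
    w <- 1 - (1 - j / n_r)^p_grade
    px <- (1 - w) * qx + w * sx
    py <- (1 - w) * qy + w * sy
    outer_nodes <- rbind(outer_nodes, cbind(px, py))
    outer_id[, j + 1] <- nid + seq_along(k_seq)
    nid <- nid + length(k_seq)
  }
  nodes <- rbind(core_nodes, outer_nodes)
  # snap the cut edge exactly onto y = 0
  nodes[abs(nodes[, 2]) < 1e-9 * R0, 2] <- 0

  elems <- matrix(0L, nrow = 2 * m^2 + 4 * m * n_r, ncol = 4)
  e <- 0L
  for (iy in 0:(m - 1)) for (ix in 0:(2 * m - 1)) {
    e <- e + 1L
    elems[e, ] <- c(core_id(ix, iy), core_id(ix + 1L, iy),
                    core_id(ix + 1L, iy + 1L), core_id(ix, iy + 1L))
  }
  for (j in 1:n_r) for (k in 1:(4 * m)) {
    e <- e + 1L
    elems[e, ] <- c(outer_id[k, j], outer_id[k + 1, j],
                    outer_id[k + 1, j + 1], outer_id[k, j + 1])
  }

  surface <- outer_id[, n_r + 1]                     # ordered theta = pi..0
  symmetry <- which(nodes[, 2] == 0)
  if (perturb_amp > 0) {
    noise <- with_seed(perturb_seed, stats::runif(length(surface), -1, 1))
    rr <- sqrt(rowSums(nodes[surface, ]^2))
    scale <- 1 + perturb_amp * noise / rr
    nodes[surface, ] <- nodes[surface, ] * scale
  }

  cent <- (nodes[elems[, 1], ] + nodes[elems[, 2], ] +
           nodes[elems[, 3], ] + nodes[elems[, 4], ]) / 4
  rc <- sqrt(rowSums(cent^2))
  N <- cbind(cent / rc, 0)

  mesh <- structure(list(type = "halfcircle", R0 = R0,
                         m = m, n_r = n_r,
                         nodes = nodes, elements = elems, N = N,
                         boundary = list(symmetry = symmetry,
                                         surface = surface,
                                         surface_theta = theta,
                                         pin = core_id(m, 0L)),
                         n_elems = nrow(elems)),
                    class = "cortexfold_mesh")
  jac <- element_jacobians(mesh)
  if (any(jac <= 0)) stop("half-circle mesh has non-positive Jacobians", call. = FALSE)
  mesh
}

# 2x2 Gauss quadrature on the bi-unit quad
quad_gauss <- function() {
  g <- 1 / sqrt(3)
  list(xi = cbind(c(-g, g, g, -g), c(-g, -g, g, g)), w = rep(1, 4))
}

# shape-function derivatives wrt (xi, eta) at one quadrature point: 4 x 2
quad_dN <- function(xi, eta) {
  cbind(c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4,
        c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4)
}

quad_shape <- function(xi, eta) {
  c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
    (1 + xi) * (1 + eta), (1 - xi) * (1 + eta)) / 4
}

# minimum mapping Jacobian per element over the quadrature points
element_jacobians <- function(mesh) {
  stopifnot(mesh$type == "halfcircle")
  gp <- quad_gauss()
  jmin <- rep(Inf, nrow(mesh$elements))
  X <- mesh$nodes
  for (q in 1:4) {
    dN <- quad_dN(gp$xi[q, 1], gp$xi[q, 2])
    x1 <- X[mesh$elements[, 1], ]; x2 <- X[mesh$elements[, 2], ]
    x3 <- X[mesh$elements[, 3], ]; x4 <- X[mesh$elements[, 4], ]
    J11 <- x1[, 1] * dN[1, 1] + x2[, 1] * dN[2, 1] + x3[, 1] * dN[3, 1] + x4[, 1] * dN[4, 1]
    J12 <- x1[, 1] * dN[1, 2] + x2[, 1] * dN[2, 2] + x3[, 1] * dN[3, 2] + x4[, 1] * dN[4, 2]
    J21 <- x1[, 2] * dN[1, 1] + x2[, 2] * dN[2, 1] + x3[, 2] * dN[3, 1] + x4[, 2] * dN[4, 1]
    J22 <- x1[, 2] * dN[1, 2] + x2[, 2] * dN[2, 2] + x3[, 2] * dN[3, 2] + x4[, 2] * dN[4, 2]
    jmin <- pmin(jmin, J11 * J22 - J12 * J21)
  }
  jmin
}

# total reference area of a half-circle mesh (sum of element areas)
mesh_area <- function(mesh) {
  stopifnot(mesh$type == "halfcircle")
  gp <- quad_gauss()
  area <- 0
  X <- mesh$nodes
  for (q in 1:4) {
    dN <- quad_dN(gp$xi[q, 1], gp$xi[q, 2])
    x1 <- X[mesh$elements[, 1], ]; x2 <- X[mesh$elements[, 2], ]
    x3 <- X[mesh$elements[, 3], ]; x4 <- X[mesh$elements[, 4], ]
    J11 <- x1[, 1] * dN[1, 1] + x2[, 1] * dN[2, 1] + x3[, 1] * dN[3, 1] + x4[, 1] * dN[4, 1]
    J12 <- x1[, 1] * dN[1, 2] + x2[, 1] * dN[2, 2] + x3[, 1] * dN[3, 2] + x4[, 1] * dN[4, 2]
    J21 <- x1[, 2] * dN[1, 1] + x2[, 2] * dN[2, 1] + x3[, 2] * dN[3, 1] + x4[, 2] * dN[4, 1]
    J22 <- x1[, 2] * dN[1, 2] + x2[, 2] * dN[2, 2] + x3[, 2] * dN[3, 2] + x4[, 2] * dN[4, 2]
    area <- area + sum(J11 * J22 - J12 * J21)
  }
  area
}

#' @export
print.cortexfold_mesh <- function(x, ...) {
  cat(sprintf("<cortexfold %s mesh> %d elements, %d nodes, R0 = %g um\n",
              x$type, x$n_elems,
              if (x$type == "bar") length(x$x) else nrow(x$nodes), x$R0))
  invisible(x)
}

#' Write a mesh (plus optional nodal/element fields) as legacy ASCII VTK
#'
#' @param mesh A \code{cortexfold_mesh}.
#' @param path Output file path (.vtk).
#' @param point_data Named list of per-node scalar vectors.
#' @param cell_data Named list of per-element scalar vectors.
#' @param displacements Optional nodal displacement matrix added to the
#'   reference coordinates before writing.
#' @return \code{path}, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list(),
                      displacements = NULL) {
  if (mesh$type == "bar") {
    pts <- cbind(mesh$x, 0, 0)
    if (!is.null(displacements)) pts[, 1] <- pts[, 1] + displacements
    cells <- cbind(2L, seq_len(length(mesh$x) - 1) - 1L, seq_len(length(mesh$x) - 1))
    ctype <- 3L  # VTK_LINE
  } else {
    pts <- cbind(mesh$nodes, 0)
    if (!is.null(displacements)) pts[, 1:2] <- pts[, 1:2] + displacements
    cells <- cbind(4L, mesh$elements - 1L)
    ctype <- 9L  # VTK_QUAD
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "cortexfold output", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(pts))), con)
  utils::write.table(format(pts, digits = 10), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", nrow(cells), length(cells)), con)
  utils::write.table(cells, con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", nrow(cells)), con)
  writeLines(as.character(rep(ctype, nrow(cells))), con)
  if (length(point_data) > 0) {
    writeLines(sprintf("POINT_DATA %d", nrow(pts)), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], digits = 10), con)
    }
  }
  if (length(cell_data) > 0) {
    writeLines(sprintf("CELL_DATA %d", nrow(cells)), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(cell_data[[nm]], digits = 10), con)
    }
  }
  invisible(path)
}

#' Export / import a mesh in a simple plain-text node/element format
#'
#' Two whitespace-separated blocks: node coordinates, then 1-based element
#' connectivity, each preceded by a count line.
#'
#' @param mesh A \code{cortexfold_mesh}.
#' @param path File path.
#' @return \code{write_mesh_text} returns \code{path} invisibly;
#'   \code{read_mesh_text} returns a list with \code{nodes} and
#'   \code{elements}.
#' @export
write_mesh_text <- function(mesh, path) {
  nodes <- if (mesh$type == "bar") cbind(mesh$x) else mesh$nodes
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(nodes), ncol(nodes)), con)
  utils::write.table(format(nodes, digits = 12), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  elems <- if (mesh$type == "bar")
    cbind(seq_len(mesh$n_elems), seq_len(mesh$n_elems) + 1L) else mesh$elements
  writeLines(sprintf("%d %d", nrow(elems), ncol(elems)), con)
  utils::write.table(elems, con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mesh_text
#' @export
read_mesh_text <- function(path) {
  tok <- scan(path, quiet = TRUE)
  nn <- tok[1]; nc <- tok[2]
  nodes <- matrix(tok[2 + seq_len(nn * nc)], nrow = nn, ncol = nc, byrow = TRUE)
  off <- 2 + nn * nc
  ne <- tok[off + 1]; npe <- tok[off + 2]
  elements <- matrix(as.integer(tok[off + 2 + seq_len(ne * npe)]),
                     nrow = ne, ncol = npe, byrow = TRUE)
  list(nodes = nodes, elements = elements)
}
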