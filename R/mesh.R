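# Structured 8-node hexahedral meshes with tagged boundary surfaces.
#
# Node numbering is x-fastest on the (nx+1) x (ny+1) x (nz+1) grid; the
# z axis is the depth axis (z = 0 bottom, z = height top / free surface).
# Element-local node ordering follows the usual hexahedron convention:
# nodes 1..4 on the bottom face (counter-clockwise seen from +z), 5..8 above.

FIELDS <- c("ux", "uy", "uz", "eps_w", "eps_plus", "eps_minus")
N_FIELDS <- 6L

#' Global dof indices of one field
#'
#' Dofs are packed node-major: node `i` owns dofs `6(i-1) + 1..6` in the order
#' `ux, uy, uz, eps_w, eps_plus, eps_minus`.
#'
#' @param mesh a hex mesh.
#' @param field one of `"ux", "uy", "uz", "eps_w", "eps_plus", "eps_minus"`.
#' @param nodes optional node subset (default all nodes).
#' @return integer vector of global dof indices.
#' @export
dof_indices <- function(mesh, field, nodes = seq_len(mesh$n_nodes)) {
  f <- match(field, FIELDS)
  if (is.na(f)) stop("unknown field: ", field, call. = FALSE)
  (nodes - 1L) * N_FIELDS + f
}

build_grid_mesh <- function(nx, ny, nz, Lx, Ly, Lz) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1)
  if (Lx <= 0 || Ly <= 0 || Lz <= 0) {
    stop("invalid parameter: mesh dimensions must be positive", call. = FALSE)
  }
  xs <- seq(0, Lx, length.out = nx + 1L)
  ys <- seq(0, Ly, length.out = ny + 1L)
  zs <- seq(0, Lz, length.out = nz + 1L)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs,
                                 KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) i + (nx + 1L) * ((j - 1L) + (ny + 1L) * (k - 1L))
  elems <- matrix(0L, nrow = nx * ny * nz, ncol = 8L)
  eid <- 0L
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    eid <- eid + 1L
    elems[eid, ] <- c(nid(i, j, k),     nid(i + 1L, j, k),
                      nid(i + 1L, j + 1L, k), nid(i, j + 1L, k),
                      nid(i, j, k + 1L), nid(i + 1L, j, k + 1L),
                      nid(i + 1L, j + 1L, k + 1L), nid(i, j + 1L, k + 1L))
  }
  # boundary facets: (element, 4 facet nodes, outward normal axis)
  face_local <- list(bottom = c(1L, 4L, 3L, 2L), top = c(5L, 6L, 7L, 8L),
                     xmin = c(1L, 5L, 8L, 4L), xmax = c(2L, 3L, 7L, 6L),
                     ymin = c(1L, 2L, 6L, 5L), ymax = c(4L, 8L, 7L, 3L))
  elem_grid <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  facets_for <- function(sel, face) {
    es <- which(sel)
    cbind(elem = es, matrix(elems[es, face_local[[face]]], ncol = 4L))
  }
  lateral <- rbind(facets_for(elem_grid$i == 1L, "xmin"),
                   facets_for(elem_grid$i == nx, "xmax"),
                   facets_for(elem_grid$j == 1L, "ymin"),
                   facets_for(elem_grid$j == ny, "ymax"))
  tags <- list(bottom = facets_for(elem_grid$k == 1L, "bottom"),
               top = facets_for(elem_grid$k == nz, "top"),
               lateral = lateral)
  node_sets <- list(
    bottom = which(nodes[, 3] == 0),
    top = which(nodes[, 3] == Lz),
    lateral = which(nodes[, 1] == 0 | nodes[, 1] == Lx |
                    nodes[, 2] == 0 | nodes[, 2] == Ly))
  structure(list(nodes = nodes, elems = elems,
                 n_nodes = nrow(nodes), n_elems = nrow(elems),
                 dims = c(nx = nx, ny = ny, nz = nz),
                 spacing = c(hx = Lx / nx, hy = Ly / ny, hz = Lz / nz),
                 extent = c(Lx = Lx, Ly = Ly, Lz = Lz),
                 tags = tags, node_sets = node_sets),
            class = "hex_mesh")
}

#' Single-column hexahedral mesh
#'
#' A stack of `n_elems` hexahedra, one element per row, used for the quasi-1D
#' free-swelling validation (cross-section much smaller than the height). A
#' column of `n` elements has `4 (n + 1)` nodes.
#'
#' @param n_elems number of elements in depth (>= 1).
#' @param height column height (m), the depth axis `z`.
#' @param width edge length of the square cross-section (m).
#' @return An object of class `hex_mesh`.
#' @examples
#' m <- build_column_mesh(50, 0.5e-3, 0.0005e-3)
#' m$n_nodes  # 204
#' @export
build_column_mesh <- function(n_elems, height, width) {
  if (n_elems < 1) stop("invalid parameter: n_elems must be >= 1",
                        call. = FALSE)
  build_grid_mesh(1L, 1L, as.integer(n_elems), width, width, height)
}

#' Structured block mesh for the full 3D confined sample
#'
#' A structured block with the height of the sample and a square footprint of
#' area equal to the circular sample cross-section (`side = sqrt(pi)/2 *
#' diameter`). Under the confined lateral boundary conditions the solution is
#' uniform in-plane, so the in-plane resolution does not affect the response;
#' it is configurable nonetheless.
#'
#' @param nx,ny,nz element counts (>= 1).
#' @param diameter sample diameter (m).
#' @param height sample height (m).
#' @return An object of class `hex_mesh`.
#' @export
build_block_mesh <- function(nx, ny, nz, diameter, height) {
  if (nx < 1 || ny < 1 || nz < 1) {
    stop("invalid parameter: element counts must be >= 1", call. = FALSE)
  }
  side <- sqrt(pi) * diameter / 2
  build_grid_mesh(as.integer(nx), as.integer(ny), as.integer(nz),
                  side, side, height)
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("Hexahedral mesh: %d elements (%d x %d x %d), %d nodes\n",
              x$n_elems, x$dims[1], x$dims[2], x$dims[3], x$n_nodes))
  cat(sprintf("  extent %.4g x %.4g x %.4g mm, spacing %.4g / %.4g / %.4g mm\n",
              1e3 * x$extent[1], 1e3 * x$extent[2], 1e3 * x$extent[3],
              1e3 * x$spacing[1], 1e3 * x$spacing[2], 1e3 * x$spacing[3]))
  invisible(x)
}

# --- trilinear shape functions -------------------------------------------

HEX_LOCAL <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1,  -1, 1, -1,
                      -1, -1,  1,  1, -1,  1,  1, 1,  1,  -1, 1,  1),
                    ncol = 3, byrow = TRUE)

#' Trilinear hexahedron shape functions and local gradients
#'
#' Evaluates the 8 trilinear shape functions and their gradients with respect
#' to the local coordinates at a point of the reference cube `[-1, 1]^3`.
#' The values form a partition of unity and the gradients sum to zero.
#'
#' @param local_coords numeric length-3 vector `(xi, eta, zeta)` in
#'   `[-1, 1]^3`.
#' @return A list with `values` (length 8) and `gradients` (8 x 3, d/dxi).
#' @export
shape_eval <- function(local_coords) {
  stopifnot(length(local_coords) == 3)
  xi <- local_coords[1]; eta <- local_coords[2]; zeta <- local_coords[3]
  a <- HEX_LOCAL[, 1]; b <- HEX_LOCAL[, 2]; c <- HEX_LOCAL[, 3]
  values <- (1 + a * xi) * (1 + b * eta) * (1 + c * zeta) / 8
  gradients <- cbind(a * (1 + b * eta) * (1 + c * zeta),
                     (1 + a * xi) * b * (1 + c * zeta),
                     (1 + a * xi) * (1 + b * eta) * c) / 8
  list(values = values, gradients = gradients)
}

# 2x2x2 Gauss points of the reference cube (weight 1 each)
gauss_hex <- function() {
  g <- 1 / sqrt(3)
  list(points = HEX_LOCAL * g, weights = rep(1, 8))
}

# Shape matrices at a set of local points for a uniform axis-aligned brick
# mesh: N (npts x 8), physical-gradient matrices Gx, Gy, Gz (npts x 8) and
# the Jacobian determinant (constant). The mesh generators above only produce
# uniform bricks, which is asserted here.
element_shape_ops <- function(mesh, points) {
  h <- mesh$spacing
  npts <- nrow(points)
  N <- matrix(0, npts, 8); Gx <- Gy <- Gz <- matrix(0, npts, 8)
  for (p in seq_len(npts)) {
    se <- shape_eval(points[p, ])
    N[p, ] <- se$values
    Gx[p, ] <- se$gradients[, 1] * 2 / h[1]
    Gy[p, ] <- se$gradients[, 2] * 2 / h[2]
    Gz[p, ] <- se$gradients[, 3] * 2 / h[3]
  }
  list(N = N, Gx = Gx, Gy = Gy, Gz = Gz,
       detJ = prod(h) / 8)
}
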