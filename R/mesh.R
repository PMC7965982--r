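HEAD_RADIUS <- 0.09  # outer radius of the toy head (m)

# normalized radius bands labelling the two-shell toy head, centre outwards
REGION_BANDS <- c(white = 0.55, gray = 0.82, csf = 0.90, skull = Inf)

kuhn_tets <- function() {
  # 6 tetrahedra per cube cell, all sharing the main diagonal (0,0,0)-(1,1,1);
  # rows are vertex offsets in (dx, dy, dz) order along axis permutations
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lapply(perms, function(p) {
    v <- matrix(0L, 4, 3)
    v[2, p[1]] <- 1L
    v[3, p[1]] <- 1L; v[3, p[2]] <- 1L
    v[4, ] <- 1L
    v
  })
}

tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], ] - nodes[tets[, 1], ]
  b <- nodes[tets[, 3], ] - nodes[tets[, 1], ]
  c_ <- nodes[tets[, 4], ] - nodes[tets[, 1], ]
  cx <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  rowSums(a * cx) / 6
}

#' Build a toy two-shell tetrahedral head mesh
#'
#' A desk-scale stand-in for an anatomical finite-element head mesh: a ball
#' of radius 0.09 m voxelized into cube cells (each split into 6 tetrahedra)
#' and labelled by normalized centroid radius into a white-matter core, a
#' cortical gray rind, a thin CSF shell and an outer skull shell. White
#' elements carry radial unit fiber directions (the axonal structural
#' tensor). Interior nodes receive a small seeded jitter (2% of the cell
#' size) so the mesh is not perfectly symmetric; the construction is
#' deterministic for a fixed `(resolution, seed)`.
#'
#' @param resolution integer >= 2; the grid has `4 * resolution` cells per
#'   axis, so element count grows as `resolution^3`.
#' @param seed integer seed for the node jitter.
#' @return an object of class `head_mesh`: list with `nodes` (n x 3 m),
#'   `tets` (m x 4 node indices), `region` (factor gray/white/csf/skull),
#'   `fiber` (m x 3, `NA` rows outside white matter), `centroids`,
#'   `volumes`, `radius`, `resolution`, `seed`.
#' @export
build_toy_head_mesh <- function(resolution, seed = 0L) {
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution < 2) {
    abort("`resolution` must be a single integer >= 2.")
  }
  resolution <- as.integer(resolution)
  n <- 4L * resolution
  R <- HEAD_RADIUS
  h <- 2 * R / n
  xs <- seq(-R, R, length.out = n + 1L)

  # linear index of grid node (i, j, k), 1-based
  nid <- function(i, j, k) i + (n + 1L) * ((j - 1L) + (n + 1L) * (k - 1L))

  grid <- expand.grid(i = seq_len(n + 1L), j = seq_len(n + 1L),
                      k = seq_len(n + 1L))
  nodes <- cbind(xs[grid$i], xs[grid$j], xs[grid$k])

  nodes <- local_seed(seed, {
    jit <- matrix(stats::runif(length(nodes), -0.02 * h, 0.02 * h),
                  ncol = 3L)
    nodes + jit
  })

  cells <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
  # keep cells whose centre lies inside the ball
  cc <- cbind((xs[cells$i] + xs[cells$i + 1L]) / 2,
              (xs[cells$j] + xs[cells$j + 1L]) / 2,
              (xs[cells$k] + xs[cells$k + 1L]) / 2)
  keep <- rowSums(cc^2) <= R^2
  cells <- cells[keep, , drop = FALSE]

  offsets <- kuhn_tets()
  tets <- do.call(rbind, lapply(offsets, function(off) {
    cbind(nid(cells$i + off[1, 1], cells$j + off[1, 2], cells$k + off[1, 3]),
          nid(cells$i + off[2, 1], cells$j + off[2, 2], cells$k + off[2, 3]),
          nid(cells$i + off[3, 1], cells$j + off[3, 2], cells$k + off[3, 3]),
          nid(cells$i + off[4, 1], cells$j + off[4, 2], cells$k + off[4, 3]))
  }))

  # orient all tets positively
  vol <- tet_volumes(nodes, tets)
  flip <- vol < 0
  if (any(flip)) {
    tmp <- tets[flip, 3L]
    tets[flip, 3L] <- tets[flip, 4L]
    tets[flip, 4L] <- tmp
    vol <- abs(vol)
  }
  if (any(vol <= 0)) abort("degenerate (zero-volume) element produced.")

  # drop unreferenced nodes, reindex
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(nodes))
  remap[used] <- seq_along(used)
  nodes <- nodes[used, , drop = FALSE]
  tets <- matrix(remap[tets], ncol = 4L)

  centroids <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] +
                nodes[tets[, 3], ] + nodes[tets[, 4], ]) / 4
  rhat <- sqrt(rowSums(centroids^2)) / R
  region <- cut(rhat, breaks = c(-Inf, REGION_BANDS),
                labels = names(REGION_BANDS))
  region <- factor(as.character(region),
                   levels = c("gray", "white", "skull", "csf"))

  fiber <- matrix(NA_real_, nrow(tets), 3L)
  wh <- which(region == "white")
  if (length(wh)) {
    d <- centroids[wh, , drop = FALSE]
    nrm <- sqrt(rowSums(d^2))
    zero <- nrm < 1e-12
    d[zero, ] <- rep(c(0, 0, 1), each = sum(zero))
    nrm[zero] <- 1
    fiber[wh, ] <- d / nrm
  }

  structure(
    list(nodes = nodes, tets = tets, region = region, fiber = fiber,
         centroids = centroids, volumes = tet_volumes(nodes, tets),
         radius = R, resolution = resolution, seed = as.integer(seed)),
    class = "head_mesh"
  )
}

#' @export
print.head_mesh <- function(x, ...) {
  cat(sprintf("<head_mesh> %d nodes, %d tetrahedra (resolution %d, seed %d)\n",
              nrow(x$nodes), nrow(x$tets), x$resolution, x$seed))
  print(table(x$region))
  invisible(x)
}

#' Representative impact locations on the toy head
#'
#' Fixed outward unit directions for the five impact-location labels; the
#' impact point is the surface point `radius * direction` and the impact
#' direction (motion of the impactor) points inward, `-direction`.
#'
#' @return tibble with `location`, `dx`, `dy`, `dz` (outward unit vector).
#'   Head frame: +x right (temporal), +y anterior (fronto-polar),
#'   +z superior (vertex).
#' @export
impact_locations <- function() {
  lfp <- c(0.70, 0.45, 0.55)
  lfp <- lfp / sqrt(sum(lfp^2))
  tibble::tribble(
    ~location,                 ~dx,    ~dy,    ~dz,
    "lateral_fronto_parietal", lfp[1], lfp[2], lfp[3],
    "fronto_polar",            0,      1,      0,
    "vertex",                  0,      0,      1,
    "occipital",               0,     -1,      0,
    "temporal",                1,      0,      0
  )
}

#' Impactor shapes and their radii of curvature
#'
#' The impactor geometry enters the models through its radius of curvature;
#' the flat impactor is assigned a nominal 1 m radius.
#'
#' @return tibble with `impactor` and `radius_m`.
#' @export
impactor_shapes <- function() {
  tibble::tribble(
    ~impactor,      ~radius_m,
    "blunt_corner", 0.010,
    "round",        0.036,
    "flat",         1.000,
    "sharp_corner", 0.003
  )
}

impact_geometry <- function(location, radius = HEAD_RADIUS) {
  locs <- impact_locations()
  row <- locs[locs$location == location, ]
  if (nrow(row) != 1L) {
    abort(sprintf("unknown impact location '%s'.", location))
  }
  dir_out <- c(row$dx, row$dy, row$dz)
  list(point = radius * dir_out, direction = -dir_out)
}

#' Write / read a head mesh as legacy ASCII VTK
#'
#' Plain-text VTK unstructured grid with the region label as integer cell
#' data (gray=1, white=2, skull=3, csf=4) and fiber directions as cell
#' vectors (zero outside white matter).
#'
#' @param mesh a `head_mesh`.
#' @param path output / input file path.
#' @return `write_mesh_vtk` returns `path` invisibly; `read_mesh_vtk`
#'   returns a `head_mesh` (volumes and centroids recomputed).
#' @export
write_mesh_vtk <- function(mesh, path) {
  stopifnot(inherits(mesh, "head_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "dmnimpact toy head mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  np <- nrow(mesh$nodes); ne <- nrow(mesh$tets)
  writeLines(sprintf("POINTS %d double", np), con)
  writeLines(apply(mesh$nodes, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", ne, 5L * ne), con)
  writeLines(apply(mesh$tets - 1L, 1, function(r)
    paste(c(4L, r), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("10", ne), con)
  writeLines(sprintf("CELL_DATA %d", ne), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  codes <- c(gray = 1L, white = 2L, skull = 3L, csf = 4L)
  writeLines(as.character(codes[as.character(mesh$region)]), con)
  writeLines("VECTORS fiber double", con)
  fib <- mesh$fiber
  fib[is.na(fib)] <- 0
  writeLines(apply(fib, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_mesh_vtk
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  tok <- function(pattern) grep(pattern, lines)[1]
  ip <- tok("^POINTS")
  np <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  nodes <- matrix(scan(text = lines[(ip + 1):(ip + np)], quiet = TRUE),
                  ncol = 3L, byrow = TRUE)
  ic <- tok("^CELLS")
  ne <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cells <- matrix(as.integer(scan(text = lines[(ic + 1):(ic + ne)],
                                  quiet = TRUE)),
                  ncol = 5L, byrow = TRUE)
  tets <- cells[, 2:5, drop = FALSE] + 1L
  ir <- tok("^SCALARS region")
  codes <- as.integer(lines[(ir + 2):(ir + 1 + ne)])
  region <- factor(c("gray", "white", "skull", "csf")[codes],
                   levels = c("gray", "white", "skull", "csf"))
  iv <- tok("^VECTORS fiber")
  fib <- matrix(scan(text = lines[(iv + 1):(iv + ne)], quiet = TRUE),
                ncol = 3L, byrow = TRUE)
  fib[region != "white", ] <- NA_real_
  centroids <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] +
                nodes[tets[, 3], ] + nodes[tets[, 4], ]) / 4
  structure(
    list(nodes = nodes, tets = tets, region = region, fiber = fib,
         centroids = centroids, volumes = tet_volumes(nodes, tets),
         radius = max(sqrt(rowSums(nodes^2))), resolution = NA_integer_,
         seed = NA_integer_),
    class = "head_mesh"
  )
}
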