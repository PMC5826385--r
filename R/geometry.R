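#' Build a 2D plane-strain head-section mesh
#'
#' Triangulates the chosen cross-section profile (graded polar rings of
#' interior points, Delaunay triangulation restricted to the star-shaped
#' domain) and constructs the rigid skull boundary: an offset polyline at
#' `skull_gap` mm outside the brain outline, whose superior arc is tagged
#' as the falx segment (the dural fold housing the superior sagittal
#' sinus, treated as rigidly tied to the skull).
#'
#' @param profile Section profile (see [section_radius()]).
#' @param target_edge Target element edge length (mm).  The default
#'   2.7 mm gives a brain-surface connector density near 0.37 per mm of
#'   boundary arclength, matching the boundary-connector density scale of
#'   the reference 3D model.
#' @param base_radius Section scale (mm).
#' @param skull_gap Radial brain-skull gap (mm), the subarachnoid space.
#' @param falx_range Angular range (rad) of the superior skull arc tagged
#'   as falx, anterior to posterior.
#' @return List of class `head_mesh`: `nodes` (n x 2 mm), `tri` (m x 3
#'   indices, positively oriented), `surface` (perimeter node indices
#'   ordered by angle from the anterior), `skull` (s x 2 mm rest
#'   positions), `falx` (indices into skull rows, ordered
#'   anterior->posterior), `falx_arclength` (mm along the falx per falx
#'   node), `skull_polar` (table `theta`, `r_mm` for contact queries),
#'   `center` (c(0,0)), `profile`, `target_edge`.
#' @export
build_geometry <- function(profile = c("sagittal", "axial", "circle"),
                           target_edge = 2.7, base_radius = 25,
                           skull_gap = 1.5,
                           falx_range = c(50, 130) * pi / 180) {
  profile <- match.arg(profile)
  stopifnot(target_edge > 0, target_edge < base_radius)

  outline <- section_outline(profile, base_radius, n = 1440)
  perim <- max(outline$s_mm) * 1440 / 1439
  n_surf <- max(12L, round(perim / target_edge))
  # boundary nodes at even arclength
  s_b <- (seq_len(n_surf) - 1) / n_surf * perim
  th_b <- approx(c(outline$s_mm, perim), c(outline$theta, 2 * pi), xout = s_b)$y
  r_b <- section_radius(th_b, profile, base_radius)

  # interior rings, graded by normalized radius
  m <- max(2L, round(mean(r_b) / target_edge))
  pts <- list(tibble(x = 0, y = 0, boundary = FALSE))
  for (j in seq_len(m - 1)) {
    u <- j / m
    nj <- max(6L, round(u * perim / target_edge))
    th <- (seq_len(nj) - 0.5 * (j %% 2)) / nj * 2 * pi
    r <- u * section_radius(th, profile, base_radius)
    pts[[j + 1]] <- tibble(x = r * cos(th), y = r * sin(th), boundary = FALSE)
  }
  pts[[m + 1]] <- tibble(x = r_b * cos(th_b), y = r_b * sin(th_b), boundary = TRUE)
  nodes <- bind_rows(pts)

  dxy <- deldir::deldir(nodes$x, nodes$y, suppressMsge = TRUE)
  tl <- deldir::triang.list(dxy)
  tri <- t(vapply(tl, function(tr) as.integer(tr$ptNum), integer(3)))
  # restrict to the star-shaped domain: triangle centroid inside outline
  cx <- (nodes$x[tri[, 1]] + nodes$x[tri[, 2]] + nodes$x[tri[, 3]]) / 3
  cy <- (nodes$y[tri[, 1]] + nodes$y[tri[, 2]] + nodes$y[tri[, 3]]) / 3
  rc <- sqrt(cx^2 + cy^2)
  thc <- atan2(cy, cx)
  inside <- rc < section_radius(thc, profile, base_radius) * 0.999
  tri <- tri[inside, , drop = FALSE]
  # enforce positive orientation
  ax <- nodes$x[tri[, 2]] - nodes$x[tri[, 1]]
  ay <- nodes$y[tri[, 2]] - nodes$y[tri[, 1]]
  bx <- nodes$x[tri[, 3]] - nodes$x[tri[, 1]]
  by <- nodes$y[tri[, 3]] - nodes$y[tri[, 1]]
  neg <- (ax * by - ay * bx) < 0
  tri[neg, 2:3] <- tri[neg, 3:2]

  surface <- which(nodes$boundary)[order(th_b)]

  # skull: offset polyline, denser than the brain surface
  th_s <- (seq_len(2 * n_surf) - 1) / (2 * n_surf) * 2 * pi
  r_s <- section_radius(th_s, profile, base_radius) + skull_gap
  skull <- cbind(x = r_s * cos(th_s), y = r_s * sin(th_s))

  falx <- which(th_s >= falx_range[1] & th_s <= falx_range[2])
  falx <- falx[order(th_s[falx])]   # anterior (small theta) -> posterior
  fx <- skull[falx, , drop = FALSE]
  falx_arc <- cumsum(c(0, sqrt(diff(fx[, 1])^2 + diff(fx[, 2])^2)))

  th_dense <- seq(0, 2 * pi, length.out = 721)
  structure(list(
    nodes = cbind(x = nodes$x, y = nodes$y),
    tri = tri,
    surface = surface,
    skull = skull,
    falx = falx,
    falx_arclength = falx_arc,
    skull_polar = tibble(theta = th_dense,
                         r_mm = section_radius(th_dense, profile, base_radius) + skull_gap),
    center = c(0, 0),
    profile = profile,
    target_edge = target_edge,
    base_radius = base_radius,
    skull_gap = skull_gap),
    class = "head_mesh")
}

#' Triangle quality of a mesh
#'
#' Normalized quality `4*sqrt(3)*A / (a^2+b^2+c^2)` (1 for equilateral).
#' @param mesh A `head_mesh`.
#' @return Numeric vector, one quality per triangle.
#' @export
mesh_quality <- function(mesh) {
  p <- mesh$nodes
  t <- mesh$tri
  e <- function(i, j) (p[t[, i], 1] - p[t[, j], 1])^2 + (p[t[, i], 2] - p[t[, j], 2])^2
  l2 <- e(1, 2) + e(2, 3) + e(3, 1)
  ax <- p[t[, 2], 1] - p[t[, 1], 1]; ay <- p[t[, 2], 2] - p[t[, 1], 2]
  bx <- p[t[, 3], 1] - p[t[, 1], 1]; by <- p[t[, 3], 2] - p[t[, 1], 2]
  A <- (ax * by - ay * bx) / 2
  4 * sqrt(3) * A / l2
}

#' Write / read a mesh as a node/element CSV pair plus JSON tag map
#'
#' @param mesh A `head_mesh`.
#' @param basename Path prefix; writes `<basename>_nodes.csv`,
#'   `<basename>_elements.csv`, `<basename>_tags.json`.
#' @return Invisibly, the written paths.
#' @export
write_mesh <- function(mesh, basename) {
  nodes_path <- paste0(basename, "_nodes.csv")
  elem_path <- paste0(basename, "_elements.csv")
  tags_path <- paste0(basename, "_tags.json")
  readr::write_csv(tibble(node = seq_len(nrow(mesh$nodes)),
                          x_mm = mesh$nodes[, 1], y_mm = mesh$nodes[, 2]),
                   nodes_path)
  readr::write_csv(tibble(n1 = mesh$tri[, 1], n2 = mesh$tri[, 2],
                          n3 = mesh$tri[, 3]), elem_path)
  jsonlite::write_json(
    list(surface = mesh$surface, falx = mesh$falx,
         skull = list(x = mesh$skull[, 1], y = mesh$skull[, 2]),
         profile = mesh$profile, target_edge = mesh$target_edge,
         base_radius = mesh$base_radius, skull_gap = mesh$skull_gap),
    tags_path, auto_unbox = TRUE, digits = NA)
  invisible(c(nodes_path, elem_path, tags_path))
}
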