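#' Attach linear elastic brain-skull connectors
#'
#' One linear spring per non-reserved brain surface node, tied to the
#' nearest skull/falx node at rest — the lumped representation of the
#' pia-arachnoid complex and CSF.  Connectors act along the current chord
#' in both tension and compression with force `-k * (length - rest
#' length)`.
#'
#' Two formulations are available.  `mode = "vector"` (default) is a
#' component spring: the force is `-k` times the vector deviation of the
#' current chord from the rigidly co-rotated rest chord, so the connector
#' resists normal and tangential relative motion equally and the boundary
#' locks as `k` grows (the rigid limit).  `mode = "axial"` acts only along
#' the current chord with force `-k * (length - rest length)`; an axial
#' spring at its rest length has no tangential stiffness, so even a very
#' stiff axial boundary lets the soft brain skate along smooth boundary
#' arcs — useful for studying geometry-dominated sliding, but not a rigid
#' limit.
#'
#' @param mesh A `head_mesh`.
#' @param k Connector stiffness (N/m), applied per connector.
#' @param reserved Surface node indices excluded from connectors (the
#'   bridging-vein anchor nodes; see [place_bridging_veins()]).
#' @param mode `"vector"` (component spring) or `"axial"` (chord spring).
#' @return Tibble of class `connector_set`: `brain_node`, `skull_node`,
#'   `rest_length_mm`, `k`; attribute `mode`.
#' @examples
#' mesh <- build_geometry("circle", target_edge = 6)
#' con <- attach_connectors(mesh, k = 46.133)
#' @export
attach_connectors <- function(mesh, k, reserved = integer(0),
                              mode = c("vector", "axial")) {
  mode <- match.arg(mode)
  stopifnot(k >= 0)
  surf <- setdiff(mesh$surface, reserved)
  sx <- mesh$nodes[surf, 1]; sy <- mesh$nodes[surf, 2]
  D <- outer(sx, mesh$skull[, 1], "-")^2 + outer(sy, mesh$skull[, 2], "-")^2
  nearest <- apply(D, 1, which.min)
  out <- tibble(
    brain_node = surf,
    skull_node = nearest,
    rest_length_mm = sqrt(D[cbind(seq_along(surf), nearest)]),
    k = k)
  attr(out, "mode") <- mode
  class(out) <- c("connector_set", class(out))
  out
}

#' Axial connector force
#'
#' Linear spring force along the current chord:
#' `-k * (length - rest_length)`, positive = tension pulling the
#' endpoints together.
#' @param current_length_mm Current chord length(s), mm.
#' @param rest_length_mm Rest length(s), mm.
#' @param k Stiffness (N/m).
#' @return Force magnitude (N) along the chord (negative in compression).
#' @export
connector_force <- function(current_length_mm, rest_length_mm, k) {
  k * (current_length_mm - rest_length_mm) * 1e-3
}

#' Bridging-vein stress-stretch curves
#'
#' Piecewise-linear nominal stress vs stretch curves for the parasagittal
#' bridging veins.  The published source curves are not tabulated in any
#' printed table, so these defaults are SYNTHETIC stand-ins with the
#' qualitative structure reported for newborn porcine veins: the
#' `post_cyclic` variant has a long low-stress toe region (worst case for
#' mechanical tethering), the `high_rate` variant a short toe and the
#' stiffest rise.  Both pass through (1, 0) and are non-decreasing; knots
#' are fully configurable.
#'
#' @param variant `"post_cyclic"` or `"high_rate"`, or a two-column matrix
#'   of custom knots (stretch, stress MPa) starting at `(1, 0)`.
#' @return Matrix with columns `stretch`, `stress_mpa`.
#' @export
vein_curve <- function(variant = c("post_cyclic", "high_rate")) {
  if (is.matrix(variant)) {
    stopifnot(ncol(variant) == 2, variant[1, 1] == 1, variant[1, 2] == 0,
              all(diff(variant[, 1]) > 0), all(diff(variant[, 2]) >= 0))
    colnames(variant) <- c("stretch", "stress_mpa")
    return(variant)
  }
  variant <- match.arg(variant)
  switch(variant,
    post_cyclic = cbind(stretch = c(1, 1.15, 1.30, 1.45, 1.60),
                        stress_mpa = c(0, 0.05, 0.25, 1.20, 3.00)),
    high_rate = cbind(stretch = c(1, 1.05, 1.15, 1.30, 1.45),
                      stress_mpa = c(0, 0.10, 0.80, 2.80, 6.00)))
}

#' Place bridging-vein elements along the falx
#'
#' Divides the falx arc anterior to posterior into four segments of
#' `fractions` of its total length and distributes `counts` vein anchor
#' points evenly in arclength inside each populated segment (at interior
#' fractions i/(n+1), so segment endpoints — including the exact midline
#' nodes — carry no vein).  Each anchor is tied to the nearest falx node
#' and to the nearest distinct brain surface node; those brain nodes are
#' reserved (excluded from the general connectors).  The default
#' 5/0/6/0 pattern over 20/20/30/30% segments yields 11 veins, matching
#' the anterior and posterior clustering observed in adult cadavers.
#'
#' @param mesh A `head_mesh`.
#' @param counts Veins per segment (length 4).
#' @param fractions Segment length fractions (length 4, summing to 1).
#' @param variant Stress-stretch curve variant (see [vein_curve()]).
#' @param area_mm2 Cross-sectional area per vein (mm^2); identical for all
#'   veins.  Default 0.5 mm^2 (synthetic stand-in; the published average
#'   is not printed).
#' @return Tibble of class `vein_set`: `vein_id`, `brain_node`,
#'   `falx_node` (index into `mesh$skull` rows), `L0_mm`, `area_mm2`,
#'   `anchor_arclength_mm`, `variant`; attribute `curve` (knot matrix) and
#'   `reserved` (brain surface nodes to exclude from connectors).
#' @export
place_bridging_veins <- function(mesh, counts = c(5, 0, 6, 0),
                                 fractions = c(0.20, 0.20, 0.30, 0.30),
                                 variant = "post_cyclic", area_mm2 = 0.5) {
  stopifnot(length(counts) == 4, length(fractions) == 4,
            abs(sum(fractions) - 1) < 1e-9, all(counts >= 0))
  total <- sum(counts)
  if (total == 0) {
    out <- tibble(vein_id = integer(), brain_node = integer(),
                  falx_node = integer(), L0_mm = numeric(),
                  area_mm2 = numeric(), anchor_arclength_mm = numeric(),
                  variant = character())
    return(structure(out, curve = vein_curve(variant), reserved = integer(0),
                     class = c("vein_set", class(out))))
  }
  if (total > length(mesh$falx)) {
    abort(sprintf("Requested %d veins but the falx segment has only %d nodes.",
                  total, length(mesh$falx)))
  }
  L <- max(mesh$falx_arclength)
  seg_ends <- cumsum(fractions) * L
  seg_starts <- c(0, seg_ends[-4])
  anchors <- unlist(lapply(1:4, function(s) {
    n <- counts[s]
    if (n == 0) return(numeric(0))
    seg_starts[s] + seq_len(n) / (n + 1) * (seg_ends[s] - seg_starts[s])
  }))

  # nearest falx node per anchor arclength
  falx_node <- vapply(anchors, function(a) {
    mesh$falx[which.min(abs(mesh$falx_arclength - a))]
  }, integer(1))

  # nearest distinct brain surface node per anchor position
  fx <- mesh$skull[falx_node, , drop = FALSE]
  surf <- mesh$surface
  reserved <- integer(0)
  brain_node <- integer(length(anchors))
  for (i in seq_along(anchors)) {
    d2 <- (mesh$nodes[surf, 1] - fx[i, 1])^2 + (mesh$nodes[surf, 2] - fx[i, 2])^2
    d2[surf %in% reserved] <- Inf
    brain_node[i] <- surf[which.min(d2)]
    reserved <- c(reserved, brain_node[i])
  }
  L0 <- sqrt((mesh$nodes[brain_node, 1] - fx[, 1])^2 +
             (mesh$nodes[brain_node, 2] - fx[, 2])^2)
  out <- tibble(vein_id = seq_along(anchors), brain_node = brain_node,
                falx_node = falx_node, L0_mm = L0, area_mm2 = area_mm2,
                anchor_arclength_mm = anchors,
                variant = if (is.matrix(variant)) "custom" else variant)
  structure(out, curve = vein_curve(variant), reserved = reserved,
            class = c("vein_set", class(out)))
}

#' Tension-only axial vein force
#'
#' `lambda = length / L0`; force = area x curve stress for `lambda > 1`
#' and exactly 0 in compression (`lambda <= 1`) — flaccid veins bear no
#' compressive load.  Stretches beyond the last curve knot are clamped
#' with a warning (failure flagging is a separate check).
#'
#' @param current_length_mm Current chord length(s), mm.
#' @param L0_mm Initial length(s), mm.
#' @param area_mm2 Cross-sectional area, mm^2.
#' @param curve Knot matrix from [vein_curve()].
#' @return Axial force (N), same length as the inputs.
#' @export
vein_force <- function(current_length_mm, L0_mm, area_mm2, curve) {
  stopifnot(all(current_length_mm > 0))
  lam <- current_length_mm / L0_mm
  lam_max <- max(curve[, 1])
  if (any(lam > lam_max)) {
    warn(sprintf("Vein stretch %.3f beyond curve domain (max %.3f); clamped.",
                 max(lam), lam_max))
    lam <- pmin(lam, lam_max)
  }
  stress <- approx(curve[, 1], curve[, 2], xout = pmax(lam, 1),
                   yleft = 0, rule = 2)$y   # MPa = N/mm^2
  ifelse(lam > 1, area_mm2 * stress, 0)
}
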