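#' Simulation configuration
#'
#' Parameters of the explicit plane-strain solver.  Geometry and material
#' are SI-converted internally; lengths at the interface are mm.
#'
#' @param dt Time step (s); `NULL` selects `safety` x the stability bound
#'   from the smallest element edge and dilatational wave speed, capped by
#'   the stiffest spring (connector/contact) frequency.
#' @param friction_mu Coulomb friction coefficient of the brain-skull
#'   contact fallback (default 0.2).
#' @param contact_penalty Normal penalty stiffness (N/m per surface node).
#' @param contact_tangent_visc Tangential viscous regularization of
#'   sticking friction (N s/m).
#' @param damping_ratio Mass-proportional damping as a fraction of
#'   critical at the fundamental bulk frequency (default 0.01).
#' @param output_rate Output sampling rate (Hz), default 2500 to mirror
#'   the high-speed video.
#' @param lead_in Static time before the pulse (s); 0.02 s gives the 50
#'   pre-motion baseline frames at 2500 Hz.
#' @param hold Static-skull time after the pulse (s).
#' @param cfc_class CFC class for input-pulse filtering; `NULL` disables
#'   filtering.
#' @param brain_mass_g Mass of the modelled (hemisected) brain (g); the
#'   out-of-plane thickness is set so the section carries this mass.
#'   Default 22.3 g, half the 44.6 g intact neonatal brain.
#' @param rotation_center Rotation centre `c(x, y)` mm in mesh
#'   coordinates; default 40 mm inferior to the section centroid.
#' @param safety Fraction of the stability bound used for the auto `dt`.
#' @param seed Integer seed (the solver itself is deterministic; the seed
#'   namespaces any downstream noise).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(dt = NULL, friction_mu = 0.2, contact_penalty = 1e4,
                       contact_tangent_visc = 50, damping_ratio = 0.01,
                       output_rate = 2500, lead_in = 0.02, hold = 0.03,
                       cfc_class = 200, brain_mass_g = 22.3,
                       rotation_center = c(0, -40), safety = 0.8, seed = 0) {
  stopifnot(friction_mu >= 0, contact_penalty >= 0, output_rate > 0,
            lead_in >= 0, hold >= 0, brain_mass_g > 0)
  structure(list(dt = dt, friction_mu = friction_mu,
                 contact_penalty = contact_penalty,
                 contact_tangent_visc = contact_tangent_visc,
                 damping_ratio = damping_ratio, output_rate = output_rate,
                 lead_in = lead_in, hold = hold, cfc_class = cfc_class,
                 brain_mass_g = brain_mass_g,
                 rotation_center = rotation_center, safety = safety,
                 seed = seed),
            class = "sim_config")
}

#' Simulate a head rotation
#'
#' Explicit central-difference (leapfrog) integration of the deformable
#' brain section inside a rigidly rotating skull.  Element stresses follow
#' the first-order Ogden model with two-term Prony viscoelasticity applied
#' to the deviatoric Kirchhoff stress via recursive internal variables and
#' a volumetric penalty for near-incompressibility (plane-strain
#' kinematics, out-of-plane stretch 1).  Brain surface nodes are tied to
#' the nearest skull node by linear spring connectors; bridging veins pull
#' (never push) along their chords; residual brain-skull approach is
#' resisted by penalty contact with Coulomb friction (coefficient 0.2 by
#' default); light mass-proportional damping stabilizes the response.
#' The input pulse is CFC-filtered before driving the skull.
#'
#' @param mesh A [build_geometry()] mesh.
#' @param material An [ogden_prony_material()]; set `C1 = C2 = 0` for a
#'   purely elastic diagnostic run.
#' @param connectors An [attach_connectors()] set.
#' @param veins Optional [place_bridging_veins()] set.
#' @param pulse A [generate_pulse()] rotation pulse.
#' @param config A [sim_config()].
#' @param initial_displacement Optional n x 2 matrix (mm) added to the
#'   node rest positions at t = 0 (free-vibration / energy diagnostics).
#' @return List of class `rotation_sim`: `times` (s), `brain` (array
#'   steps x nodes x 2, mm, lab frame), `skull` (steps x skull nodes x 2,
#'   mm), `theta` (rad), `energy` (tibble: time, kinetic, elastic,
#'   connector, total — joules), `vein_stretch` (tibble per output step
#'   and vein, when veins present), `dt`, `n_steps`, plus the inputs.
#' @export
simulate_rotation <- function(mesh, material, connectors, veins = NULL,
                              pulse, config = sim_config(),
                              initial_displacement = NULL) {
  stopifnot(inherits(mesh, "head_mesh"), inherits(material, "ogden_prony"),
            inherits(pulse, "rotation_pulse"))
  mm <- 1e-3
  X <- mesh$nodes * mm                     # reference positions (m)
  tri <- mesh$tri
  n_nodes <- nrow(X); n_el <- nrow(tri)
  i1 <- tri[, 1]; i2 <- tri[, 2]; i3 <- tri[, 3]

  # reference edge matrices, inverses, areas
  d1x <- X[i2, 1] - X[i1, 1]; d1y <- X[i2, 2] - X[i1, 2]
  d2x <- X[i3, 1] - X[i1, 1]; d2y <- X[i3, 2] - X[i1, 2]
  detD <- d1x * d2y - d1y * d2x
  if (any(detD <= 0)) abort("Mesh has non-positively oriented elements.")
  A0 <- detD / 2
  Dmi11 <- d2y / detD; Dmi12 <- -d2x / detD
  Dmi21 <- -d1y / detD; Dmi22 <- d1x / detD

  area_tot <- sum(A0)
  t0 <- config$brain_mass_g * 1e-3 / (material$rho * area_tot)  # thickness (m)
  mass <- rowsum(rep(material$rho * t0 * A0 / 3, 3), c(i1, i2, i3))[, 1]
  K <- bulk_modulus(material)
  mu0 <- material$mu0; alpha <- material$alpha

  # stable time step
  c_dil <- sqrt((K + 4 * mu0 / 3) / material$rho)
  h_min <- sqrt(min(
    d1x^2 + d1y^2, d2x^2 + d2y^2, (d1x - d2x)^2 + (d1y - d2y)^2))
  k_stiff <- max(connectors$k, config$contact_penalty,
                 if (!is.null(veins) && nrow(veins) > 0) {
                   crv <- attr(veins, "curve")
                   max(diff(crv[, 2]) / diff(crv[, 1])) * 1e6 *  # MPa -> Pa
                     max(veins$area_mm2) * 1e-6 / (min(veins$L0_mm) * mm)
                 } else 0)
  dt <- config$dt %||% (config$safety * min(
    h_min / c_dil,
    if (k_stiff > 0) sqrt(min(mass) / k_stiff) else Inf))
  # snap dt so output samples land exactly on the output-rate grid
  interval <- 1 / config$output_rate
  dt <- interval / ceiling(interval / dt)

  # prescribed skull rotation from the (filtered) pulse
  t_total <- config$lead_in + pulse_phases(pulse)$duration + config$hold
  n_steps <- ceiling(t_total / dt)
  tgrid <- seq(0, by = dt, length.out = n_steps + 1)
  omega_raw <- pulse$omega
  if (!is.null(config$cfc_class)) {
    fs <- 1 / (pulse$time[2] - pulse$time[1])
    omega_raw <- cfc_filter(omega_raw, fs, config$cfc_class)
  }
  omega <- approx(pulse$time + config$lead_in, omega_raw, xout = tgrid,
                  yleft = 0, yright = 0)$y
  theta <- pulse_angle(tgrid, omega)

  ctr <- config$rotation_center * mm
  rot_about <- function(P, th) {
    px <- P[, 1] - ctr[1]; py <- P[, 2] - ctr[2]
    cbind(cos(th) * px - sin(th) * py + ctr[1],
          sin(th) * px + cos(th) * py + ctr[2])
  }

  # connectors / veins / contact precomputation (SI)
  cb <- connectors$brain_node
  cs_rest <- mesh$skull[connectors$skull_node, , drop = FALSE] * mm
  cL0 <- connectors$rest_length_mm * mm
  ck <- connectors$k
  c_vector <- identical(attr(connectors, "mode") %||% "vector", "vector")
  cr0x <- X[cb, 1] - cs_rest[, 1]          # rest chord (m)
  cr0y <- X[cb, 2] - cs_rest[, 2]
  has_veins <- !is.null(veins) && nrow(veins) > 0
  if (has_veins) {
    vb <- veins$brain_node
    vf_rest <- mesh$skull[veins$falx_node, , drop = FALSE] * mm
    vL0 <- veins$L0_mm
    v_area <- veins$area_mm2
    v_curve <- attr(veins, "curve")
    v_maxstretch <- rep(1, nrow(veins))
  }
  surf <- mesh$surface
  sp_theta <- mesh$skull_polar$theta
  sp_r <- mesh$skull_polar$r_mm * mm
  # tangential slope dr/dtheta for contact normals
  sp_dr <- finite_diff(sp_r, sp_theta)
  damping <- 2 * config$damping_ratio * c_dil / (max(mesh$nodes[, 1]) * mm)

  # output bookkeeping
  out_every <- max(1L, round(interval / dt))
  out_idx <- seq(1, n_steps + 1, by = out_every)
  n_out <- length(out_idx)
  brain_out <- array(NA_real_, c(n_out, n_nodes, 2))
  theta_out <- theta[out_idx]
  energy <- matrix(0, n_out, 4)
  if (has_veins) stretch_out <- matrix(NA_real_, n_out, nrow(veins))

  x <- X
  if (!is.null(initial_displacement)) {
    stopifnot(nrow(initial_displacement) == n_nodes)
    x <- X + initial_displacement * mm
  }
  v <- matrix(0, n_nodes, 2)
  hv11 <- hv22 <- hv12 <- matrix(0, n_el, 2)    # Prony internal variables
  td_prev11 <- td_prev22 <- td_prev12 <- rep(0, n_el)
  e1 <- exp(-dt / material$tau1); e2 <- exp(-dt / material$tau2)
  C1 <- material$C1; C2 <- material$C2
  visc <- (C1 + C2) > 0
  o3 <- 1 / 3
  group3 <- c(i1, i2, i3)
  out_ptr <- 1L

  for (step in seq_len(n_steps + 1)) {
    # --- element internal forces ---
    e1x <- x[i2, 1] - x[i1, 1]; e1y <- x[i2, 2] - x[i1, 2]
    e2x <- x[i3, 1] - x[i1, 1]; e2y <- x[i3, 2] - x[i1, 2]
    F11 <- e1x * Dmi11 + e2x * Dmi21
    F12 <- e1x * Dmi12 + e2x * Dmi22
    F21 <- e1y * Dmi11 + e2y * Dmi21
    F22 <- e1y * Dmi12 + e2y * Dmi22
    J <- F11 * F22 - F12 * F21
    if (any(J <= 0) || any(!is.finite(J))) {
      bad <- which(J <= 0 | !is.finite(J))[1]
      abort(sprintf("Element %d inverted at step %d (t = %.5f s); reduce dt or stiffness.",
                    bad, step, tgrid[step]))
    }
    # left Cauchy-Green eigenstructure
    B11 <- F11^2 + F12^2
    B22 <- F21^2 + F22^2
    B12 <- F11 * F21 + F12 * F22
    tr2 <- (B11 + B22) / 2
    disc <- sqrt(pmax(((B11 - B22) / 2)^2 + B12^2, 0))
    lam1 <- sqrt(pmax(tr2 + disc, 1e-300))
    lam2 <- sqrt(pmax(tr2 - disc, 1e-300))
    Ji3 <- J^o3
    lb1 <- (lam1 / Ji3)^alpha
    lb2 <- (lam2 / Ji3)^alpha
    lb3 <- (1 / Ji3)^alpha
    mean3 <- (lb1 + lb2 + lb3) * o3
    tfac <- 2 * mu0 / alpha
    tdev1 <- tfac * (lb1 - mean3)
    tdev2 <- tfac * (lb2 - mean3)
    # principal direction of lam1: solve (B - lam1^2 I) v = 0
    vx <- ifelse(abs(B12) > 1e-14, B12, ifelse(B11 >= B22, 1, 0))
    vy <- ifelse(abs(B12) > 1e-14, lam1^2 - B11, ifelse(B11 >= B22, 0, 1))
    nv <- sqrt(vx^2 + vy^2)
    vx <- vx / nv; vy <- vy / nv
    # deviatoric Kirchhoff tensor: tdev2*I + (tdev1 - tdev2) v v^T
    dte <- tdev1 - tdev2
    td11 <- tdev2 + dte * vx * vx
    td22 <- tdev2 + dte * vy * vy
    td12 <- dte * vx * vy
    if (visc && step > 1) {
      m11 <- (td11 + td_prev11) / 2
      m22 <- (td22 + td_prev22) / 2
      m12 <- (td12 + td_prev12) / 2
      hv11[, 1] <- e1 * hv11[, 1] + C1 * (1 - e1) * m11
      hv22[, 1] <- e1 * hv22[, 1] + C1 * (1 - e1) * m22
      hv12[, 1] <- e1 * hv12[, 1] + C1 * (1 - e1) * m12
      hv11[, 2] <- e2 * hv11[, 2] + C2 * (1 - e2) * m11
      hv22[, 2] <- e2 * hv22[, 2] + C2 * (1 - e2) * m22
      hv12[, 2] <- e2 * hv12[, 2] + C2 * (1 - e2) * m12
    }
    td_prev11 <- td11; td_prev22 <- td22; td_prev12 <- td12
    p_vol <- K * (J - 1)
    s11 <- (td11 - hv11[, 1] - hv11[, 2]) / J + p_vol
    s22 <- (td22 - hv22[, 1] - hv22[, 2]) / J + p_vol
    s12 <- (td12 - hv12[, 1] - hv12[, 2]) / J
    # P = J sigma F^-T = sigma . adjT(F)
    P11 <- s11 * F22 - s12 * F12
    P12 <- -s11 * F21 + s12 * F11
    P21 <- s12 * F22 - s22 * F12
    P22 <- -s12 * F21 + s22 * F11
    cA <- A0 * t0
    f2x <- -cA * (P11 * Dmi11 + P12 * Dmi12)
    f2y <- -cA * (P21 * Dmi11 + P22 * Dmi12)
    f3x <- -cA * (P11 * Dmi21 + P12 * Dmi22)
    f3y <- -cA * (P21 * Dmi21 + P22 * Dmi22)
    f1x <- -f2x - f3x
    f1y <- -f2y - f3y
    fi <- rowsum(cbind(c(f1x, f2x, f3x), c(f1y, f2y, f3y)), group3)
    fx <- fi[, 1]; fy <- fi[, 2]

    th <- theta[step]
    # --- connectors ---
    cs <- rot_about(cs_rest, th)
    dxs <- x[cb, 1] - cs[, 1]; dys <- x[cb, 2] - cs[, 2]
    L <- sqrt(dxs^2 + dys^2)
    if (c_vector) {
      cth0 <- cos(th); sth0 <- sin(th)
      fcx <- -ck * (dxs - (cth0 * cr0x - sth0 * cr0y))
      fcy <- -ck * (dys - (sth0 * cr0x + cth0 * cr0y))
    } else {
      fc <- -ck * (L - cL0) / pmax(L, 1e-12)
      fcx <- fc * dxs
      fcy <- fc * dys
    }
    fcx_sum <- rowsum(fcx, cb); fcy_sum <- rowsum(fcy, cb)
    cbu <- as.integer(rownames(fcx_sum))
    fx[cbu] <- fx[cbu] + fcx_sum[, 1]
    fy[cbu] <- fy[cbu] + fcy_sum[, 1]

    # --- bridging veins (tension only) ---
    if (has_veins) {
      vfp <- rot_about(vf_rest, th)
      dvx <- x[vb, 1] - vfp[, 1]; dvy <- x[vb, 2] - vfp[, 2]
      Lv_mm <- sqrt(dvx^2 + dvy^2) / mm
      lamv <- Lv_mm / vL0
      v_maxstretch <- pmax(v_maxstretch, lamv)
      fvmag <- vein_force_clamped(Lv_mm, vL0, v_area, v_curve)
      fv <- -fvmag / pmax(Lv_mm * mm, 1e-12)
      fx[vb] <- fx[vb] + fv * dvx
      fy[vb] <- fy[vb] + fv * dvy
    }

    # --- penalty contact with Coulomb friction against the skull ---
    if (config$contact_penalty > 0) {
      xs <- x[surf, , drop = FALSE]
      cth <- cos(-th); sth <- sin(-th)
      px <- xs[, 1] - ctr[1]; py <- xs[, 2] - ctr[2]
      qx <- cth * px - sth * py + ctr[1]   # skull-frame position
      qy <- sth * px + cth * py + ctr[2]
      rr <- sqrt(qx^2 + qy^2)
      phi <- atan2(qy, qx) %% (2 * pi)
      rsk <- approx(sp_theta, sp_r, xout = phi, rule = 2)$y
      pen <- rr - rsk
      hit <- which(pen > 0)
      if (length(hit) > 0) {
        drdth <- approx(sp_theta, sp_dr, xout = phi[hit], rule = 2)$y
        # inward normal of r = r_s(theta):  -(rhat - (r'/r) that), normalized
        rhx <- qx[hit] / rr[hit]; rhy <- qy[hit] / rr[hit]
        thx <- -rhy; thy <- rhx
        gx <- rhx - (drdth / rsk[hit]) * thx
        gy <- rhy - (drdth / rsk[hit]) * thy
        gn <- sqrt(gx^2 + gy^2)
        nx_s <- -gx / gn; ny_s <- -gy / gn  # inward, skull frame
        # rotate normal back to lab frame
        nx <- cos(th) * nx_s - sin(th) * ny_s
        ny <- sin(th) * nx_s + cos(th) * ny_s
        fn <- config$contact_penalty * pen[hit]
        nodes_hit <- surf[hit]
        fx[nodes_hit] <- fx[nodes_hit] + fn * nx
        fy[nodes_hit] <- fy[nodes_hit] + fn * ny
        # friction: oppose tangential slip relative to the skull surface
        om <- omega[step]
        vskx <- -om * (x[nodes_hit, 2] - ctr[2])
        vsky <- om * (x[nodes_hit, 1] - ctr[1])
        vrx <- v[nodes_hit, 1] - vskx
        vry <- v[nodes_hit, 2] - vsky
        vt_x <- vrx - (vrx * nx + vry * ny) * nx
        vt_y <- vry - (vrx * nx + vry * ny) * ny
        vt <- sqrt(vt_x^2 + vt_y^2)
        ft <- pmin(config$contact_tangent_visc * vt, config$friction_mu * fn)
        nz <- vt > 1e-9
        fx[nodes_hit[nz]] <- fx[nodes_hit[nz]] - ft[nz] * vt_x[nz] / vt[nz]
        fy[nodes_hit[nz]] <- fy[nodes_hit[nz]] - ft[nz] * vt_y[nz] / vt[nz]
      }
    }

    # --- leapfrog velocity update (mass-proportional damping) ---
    v_half_old <- v
    if (step <= n_steps) {
      ax <- fx / mass; ay <- fy / mass
      fac <- 1 / (1 + damping * dt / 2)
      v[, 1] <- fac * ((1 - damping * dt / 2) * v[, 1] + dt * ax)
      v[, 2] <- fac * ((1 - damping * dt / 2) * v[, 2] + dt * ay)
    }

    # --- record output (kinetic energy from the centred velocity) ---
    if (out_ptr <= n_out && step == out_idx[out_ptr]) {
      brain_out[out_ptr, , ] <- x / mm
      vc1 <- (v[, 1] + v_half_old[, 1]) / 2
      vc2 <- (v[, 2] + v_half_old[, 2]) / 2
      ke <- 0.5 * sum(mass * (vc1^2 + vc2^2))
      lam3 <- cbind(lam1, lam2, 1)
      ee <- sum(A0 * t0 * ogden_energy(lam3, mu0, alpha, K))
      ce <- if (c_vector) {
        exx <- dxs - (cos(th) * cr0x - sin(th) * cr0y)
        exy <- dys - (sin(th) * cr0x + cos(th) * cr0y)
        0.5 * sum(ck * (exx^2 + exy^2))
      } else {
        0.5 * sum(ck * (L - cL0)^2)
      }
      energy[out_ptr, ] <- c(ke, ee, ce, ke + ee + ce)
      if (has_veins) stretch_out[out_ptr, ] <- lamv
      out_ptr <- out_ptr + 1L
    }
    if (step > n_steps) break

    x <- x + dt * v
    if (max(abs(v)) > 1e3) {
      abort(sprintf("Energy blow-up at step %d (t = %.5f s): |v| = %.1f m/s.",
                    step, tgrid[step], max(abs(v))))
    }
  }

  skull_out <- array(NA_real_, c(n_out, nrow(mesh$skull), 2))
  for (i in seq_len(n_out)) {
    skull_out[i, , ] <- rot_about(mesh$skull * mm, theta_out[i]) / mm
  }

  structure(list(
    times = tgrid[out_idx],
    brain = brain_out,
    skull = skull_out,
    theta = theta_out,
    energy = tibble(time = tgrid[out_idx], kinetic = energy[, 1],
                    elastic = energy[, 2], connector = energy[, 3],
                    total = energy[, 4]),
    vein_stretch = if (has_veins) stretch_out else NULL,
    vein_max_stretch = if (has_veins) v_maxstretch else NULL,
    dt = dt, n_steps = n_steps, thickness_m = t0,
    mesh = mesh, config = config, material = material, veins = veins),
    class = "rotation_sim")
}

# vein_force without the per-step warning overhead
vein_force_clamped <- function(current_length_mm, L0_mm, area_mm2, curve) {
  lam <- pmin(current_length_mm / L0_mm, max(curve[, 1]))
  stress <- approx(curve[, 1], curve[, 2], xout = pmax(lam, 1),
                   yleft = 0, rule = 2)$y
  ifelse(lam > 1, area_mm2 * stress, 0)
}

#' Extract virtual-marker relative displacements from a simulation
#'
#' Mirrors the physical measurement on the simulated fields: virtual brain
#' markers (mean position of up to a few mapped nodes, default one surface
#' node each) and virtual rigid markers (skull nodes) are assembled into
#' tracks and passed through the identical displacement pipeline —
#' nearest-rigid pairing, 50-frame baseline, signed relative displacement,
#' per-pair maxima.
#'
#' @param sim A `rotation_sim`.
#' @param n_brain_markers Number of brain virtual markers, spread evenly
#'   over the surface nodes (default 13, mirroring the physical dot
#'   counts); `NULL` uses every surface node.
#' @param n_rigid_markers Number of skull virtual markers.
#' @param marker_map Optional explicit map: list with `brain` = list of
#'   node-index vectors (averaged per marker) and `rigid` = list of skull
#'   row-index vectors.
#' @param n_baseline Baseline frames (default 50).
#' @return Tibble of per-pair maxima (see [extract_maxima()]), with the
#'   `displacement_series` attached as attribute `series`.
#' @export
extract_model_displacements <- function(sim, n_brain_markers = 13,
                                        n_rigid_markers = 8,
                                        marker_map = NULL, n_baseline = 50) {
  mesh <- sim$mesh
  if (is.null(marker_map)) {
    # ink dots do not coincide with bridging-vein anchor points
    surf <- setdiff(mesh$surface,
                    if (!is.null(sim$veins)) sim$veins$brain_node else integer(0))
    bsel <- if (is.null(n_brain_markers)) surf
            else surf[unique(round(seq(1, length(surf),
                                       length.out = min(n_brain_markers, length(surf)))))]
    rsel <- unique(round(seq(1, nrow(mesh$skull),
                             length.out = n_rigid_markers + 1)))[seq_len(n_rigid_markers)]
    marker_map <- list(brain = as.list(bsel), rigid = as.list(rsel))
  }
  if (any(lengths(marker_map$brain) == 0) || any(lengths(marker_map$rigid) == 0)) {
    abort("Empty node set in marker_map.")
  }
  n_out <- length(sim$times)
  marker_pos <- function(arr, sets) {
    do.call(rbind, lapply(seq_along(sets), function(k) {
      nodes <- sets[[k]]
      tibble(marker = k, frame = seq_len(n_out) - 1L,
             x_px = rowMeans(arr[, nodes, 1, drop = FALSE]),
             y_px = rowMeans(arr[, nodes, 2, drop = FALSE]))
    }))
  }
  nb <- length(marker_map$brain)
  tracks <- bind_rows(
    marker_pos(sim$brain, marker_map$brain) %>%
      mutate(track_id = .data$marker, label = "brain"),
    marker_pos(sim$skull, marker_map$rigid) %>%
      mutate(track_id = .data$marker + nb, label = "rigid")) %>%
    select("track_id", "frame", "x_px", "y_px", "label")
  pairs <- pair_markers(tracks, y_down = FALSE)
  m0 <- sum(sim$times < sim$config$lead_in - 1e-9)
  disp <- relative_displacement(tracks, pairs, motion_start_frame = m0,
                                n_baseline = min(n_baseline, m0),
                                mm_per_unit = 1)
  out <- extract_maxima(disp)
  attr(out, "series") <- disp
  out
}
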