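# Model 3: diffusion-limited volume loss of a simplified Mg-alloy implant.
#
# A single diffusion equation for Mg2+ is solved over implant + electrolyte
# (finite-volume, backward Euler, sparse Cholesky factored once). The implant
# starts at concentration c0 and the electrolyte at zero; the residual implant
# volume is V(t) = integral of c over the implant region / c0 and
# VL(t) = 100 * (V(0) - V(t)) / V(0).
#
# Working units: mm, seconds, D_Mg in mm2 s-1 (the printed testing range
# 1e-12..1e-4 and optima ~6e-9 are consistent with mm2 s-1 and with the
# mol mm-3 initial concentrations).

#' Simplified implant geometries for the diffusion model
#'
#' `geom_cylinder()` places an axisymmetric cylindrical implant (the
#' CAD screw reduced to its envelope) at the centre of a cylindrical
#' electrolyte of equal volume to the requested box. `geom_slab()` is a 1D
#' reduction used for closed-form diffusion checks. `geom_voxel()` takes a
#' logical 3D implant mask on a regular grid inside an electrolyte box.
#'
#' @param radius,length Implant radius and length, mm.
#' @param electrolyte Electrolyte box dimensions `c(x, y, z)`, mm.
#' @param nr,nz Radial and axial grid cells.
#' @param thickness Slab (implant) thickness, mm.
#' @param l_electrolyte Electrolyte layer thickness on top of the slab, mm
#'   (may be 0 to expose the implant surface directly to the sink).
#' @param nx_implant,nx_electrolyte Grid cells per region.
#' @param mask Logical 3D array marking implant voxels.
#' @param dx Voxel edge length, mm.
#' @param boundary `"sink"` (zero concentration at the outer boundary,
#'   emulating medium exchange) or `"closed"` (zero flux).
#' @return A geometry description list.
#' @name diffusion_geometry
NULL

#' @rdname diffusion_geometry
#' @export
geom_cylinder <- function(radius = 1, length = 4, electrolyte = c(3, 3, 5),
                          nr = 24L, nz = 36L, boundary = "sink") {
  assert_num(radius, lower = 1e-9); assert_num(length, lower = 1e-9)
  assert_num(electrolyte, len = 3L, lower = 1e-9)
  r_out <- sqrt(electrolyte[1] * electrolyte[2] / pi)
  h_out <- electrolyte[3]
  if (radius >= r_out || length >= h_out)
    stop("implant must fit inside the electrolyte box", call. = FALSE)
  list(type = "cylinder", radius = radius, length = length,
       r_out = r_out, h_out = h_out, nr = as.integer(nr),
       nz = as.integer(nz), boundary = match.arg(boundary,
                                                 c("sink", "closed")))
}

#' @rdname diffusion_geometry
#' @export
geom_slab <- function(thickness = 0.5, l_electrolyte = 0.5,
                      nx_implant = 100L, nx_electrolyte = 100L,
                      boundary = "sink") {
  assert_num(thickness, lower = 1e-9); assert_num(l_electrolyte, lower = 0)
  list(type = "slab", thickness = thickness, l_electrolyte = l_electrolyte,
       nx_implant = as.integer(nx_implant),
       nx_electrolyte = as.integer(if (l_electrolyte > 0) nx_electrolyte else 0),
       boundary = match.arg(boundary, c("sink", "closed")))
}

#' @rdname diffusion_geometry
#' @export
geom_voxel <- function(mask, dx, electrolyte = NULL, boundary = "sink") {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("'mask' must be a logical 3D array", call. = FALSE)
  if (!any(mask)) stop("implant mask is empty", call. = FALSE)
  assert_num(dx, lower = 1e-9)
  list(type = "voxel", mask = mask, dx = dx,
       boundary = match.arg(boundary, c("sink", "closed")))
}

#' Configuration for the diffusion-based volume-loss model
#'
#' @param D_Mg Diffusion coefficient of Mg2+, mm2 s-1.
#' @param geometry One of [geom_cylinder()], [geom_slab()], [geom_voxel()].
#' @param alloy `"Mg5Gd"` or `"Mg10Gd"`; sets the density (1.81 / 1.87
#'   g cm-3) and initial implant concentration (7.13e-5 / 7.07e-5 mol mm-3).
#' @param rho_alloy,c0_implant Optional explicit overrides of the alloy
#'   presets.
#' @param t_end Horizon, days (default 56).
#' @param n_t Number of implicit time steps.
#' @return An object of class `mguq_diffusion_config`.
#' @examples
#' cfg <- diffusion_config(6.05e-9, geometry = geom_cylinder(nr = 8, nz = 12))
#' @export
diffusion_config <- function(D_Mg, geometry = geom_cylinder(),
                             alloy = c("Mg5Gd", "Mg10Gd"),
                             rho_alloy = NULL, c0_implant = NULL,
                             t_end = 56, n_t = 120L) {
  assert_num(D_Mg, lower = 0)
  alloy <- match.arg(alloy)
  preset <- if (alloy == "Mg5Gd") c(1.81, 7.13e-5) else c(1.87, 7.07e-5)
  rho_alloy <- rho_alloy %||% preset[1]
  c0_implant <- c0_implant %||% preset[2]
  assert_num(rho_alloy, lower = 1e-9); assert_num(c0_implant, lower = 1e-12)
  assert_num(t_end, lower = 1e-9); assert_num(n_t, lower = 2)
  structure(list(D_Mg = D_Mg, geometry = geometry, alloy = alloy,
                 rho_alloy = rho_alloy, c0_implant = c0_implant,
                 c0_electrolyte = 0, t_end = t_end, n_t = as.integer(n_t)),
            class = "mguq_diffusion_config")
}

# Discretise a geometry into cells: volumes V, symmetric face list
# (i, j, conductance), boundary conductances (for sink BC), implant indices,
# initial V(0) and surface area A(0).
discretise_geometry <- function(geom) {
  if (geom$type == "slab") {
    nx <- geom$nx_implant + geom$nx_electrolyte
    dx_i <- geom$thickness / geom$nx_implant
    dx_e <- if (geom$nx_electrolyte > 0)
      geom$l_electrolyte / geom$nx_electrolyte else 0
    dx <- c(rep(dx_i, geom$nx_implant), rep(dx_e, geom$nx_electrolyte))
    V <- dx                                   # unit cross-section
    faces <- cbind(seq_len(nx - 1), seq_len(nx - 1) + 1,
                   1 / ((dx[-nx] + dx[-1]) / 2))
    bnd <- if (geom$boundary == "sink") cbind(nx, 1 / (dx[nx] / 2)) else NULL
    list(V = V, faces = faces, bnd = bnd,
         implant = seq_len(geom$nx_implant),
         V0 = geom$thickness, A0 = 1)
  } else if (geom$type == "cylinder") {
    # graded axisymmetric mesh: the implant surface lies exactly on cell
    # faces and cells are refined geometrically toward it, where the initial
    # concentration jump makes the flux steepest
    g <- 1.35  # coarsening ratio away from the surface
    graded <- function(span, n, fine_first = TRUE) {
      w <- g^(0:(n - 1)); w <- w / sum(w) * span
      if (fine_first) w else rev(w)
    }
    R <- geom$radius; len <- geom$length
    n_ri <- max(3L, as.integer(ceiling(geom$nr / 2)))
    n_re <- max(3L, geom$nr - n_ri)
    dr_w <- c(graded(R, n_ri, fine_first = FALSE),      # fine at r = R
              graded(geom$r_out - R, n_re, fine_first = TRUE))
    r_face <- c(0, cumsum(dr_w))
    nr <- length(dr_w)
    gap <- (geom$h_out - len) / 2
    n_zi <- max(4L, as.integer(ceiling(geom$nz / 2)))
    n_zi <- n_zi + n_zi %% 2L
    n_zg <- max(2L, as.integer(ceiling((geom$nz - n_zi) / 2)))
    dz_w <- c(graded(gap, n_zg, fine_first = FALSE),    # fine at implant base
              graded(len / 2, n_zi %/% 2L, fine_first = TRUE),
              graded(len / 2, n_zi %/% 2L, fine_first = FALSE),
              graded(gap, n_zg, fine_first = TRUE))
    nz <- length(dz_w)
    zc <- cumsum(dz_w) - dz_w / 2
    rc <- (r_face[-1] + r_face[-(nr + 1)]) / 2
    ring <- pi * diff(r_face^2)             # annulus area per radial cell
    idx <- function(i, k) (k - 1L) * nr + i
    V <- as.vector(outer(ring, dz_w))
    faces <- list()
    for (k in seq_len(nz)) for (i in seq_len(nr - 1)) {
      faces[[length(faces) + 1L]] <- c(
        idx(i, k), idx(i + 1, k),
        2 * pi * r_face[i + 1] * dz_w[k] / (rc[i + 1] - rc[i]))
    }
    for (k in seq_len(nz - 1)) for (i in seq_len(nr)) {
      faces[[length(faces) + 1L]] <- c(
        idx(i, k), idx(i, k + 1), ring[i] / (zc[k + 1] - zc[k]))
    }
    bnd <- NULL
    if (geom$boundary == "sink") {
      bnd <- list()
      for (k in seq_len(nz))
        bnd[[length(bnd) + 1L]] <- c(
          idx(nr, k), 2 * pi * r_face[nr + 1] * dz_w[k] /
            (r_face[nr + 1] - rc[nr]))
      for (i in seq_len(nr)) {
        bnd[[length(bnd) + 1L]] <- c(idx(i, 1L), ring[i] / (dz_w[1] / 2))
        bnd[[length(bnd) + 1L]] <- c(idx(i, nz), ring[i] / (dz_w[nz] / 2))
      }
      bnd <- do.call(rbind, bnd)
    }
    impl <- which(as.vector(outer(seq_len(nr) <= n_ri,
                                  seq_len(nz) %in% (n_zg + seq_len(n_zi)),
                                  `&`)))
    list(V = V, faces = do.call(rbind, faces), bnd = bnd, implant = impl,
         V0 = sum(V[impl]), A0 = 2 * pi * R * len + 2 * pi * R^2)
  } else if (geom$type == "voxel") {
    dm <- dim(geom$mask); dx <- geom$dx
    n <- prod(dm)
    idx <- function(i, j, k) i + (j - 1L) * dm[1] + (k - 1L) * dm[1] * dm[2]
    V <- rep(dx^3, n)
    faces <- list()
    for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) for (i in seq_len(dm[1])) {
      if (i < dm[1]) faces[[length(faces) + 1L]] <-
          c(idx(i, j, k), idx(i + 1L, j, k), dx)
      if (j < dm[2]) faces[[length(faces) + 1L]] <-
          c(idx(i, j, k), idx(i, j + 1L, k), dx)
      if (k < dm[3]) faces[[length(faces) + 1L]] <-
          c(idx(i, j, k), idx(i, j, k + 1L), dx)
    }
    bnd <- NULL
    if (geom$boundary == "sink") {
      onb <- array(FALSE, dm)
      onb[c(1, dm[1]), , ] <- TRUE; onb[, c(1, dm[2]), ] <- TRUE
      onb[, , c(1, dm[3])] <- TRUE
      bnd <- cbind(which(onb), 2 * dx)  # dx^2 / (dx/2)
    }
    impl <- which(geom$mask)
    nf <- 0L  # exposed implant faces for A(0)
    for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) for (i in seq_len(dm[1])) {
      if (!geom$mask[i, j, k]) next
      for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
        ii <- i + d[1]; jj <- j + d[2]; kk <- k + d[3]
        out <- ii < 1 || ii > dm[1] || jj < 1 || jj > dm[2] ||
          kk < 1 || kk > dm[3]
        if (out || !geom$mask[ii, jj, kk]) nf <- nf + 1L
      }
    }
    list(V = V, faces = do.call(rbind, faces), bnd = bnd, implant = impl,
         V0 = length(impl) * dx^3, A0 = nf * dx^2)
  } else stop("unknown geometry type", call. = FALSE)
}

#' Simulate implant volume loss (model 3)
#'
#' Finite-volume backward-Euler solution of the diffusion equation for Mg2+
#' over the implant and electrolyte, with the sparse system factored once and
#' reused across time steps.
#'
#' @param config A [diffusion_config()].
#' @param output_times Days at which VL is recorded (default: the full step
#'   grid).
#' @return A [time_series()] of volume loss in percent
#'   (`qoi_label = "VL_percent"`), with attributes `V0` (initial implant
#'   volume, mm3) and `A0` (initial surface area, mm2).
#' @export
simulate_volume_loss <- function(config, output_times = NULL) {
  stopifnot(inherits(config, "mguq_diffusion_config"))
  mesh <- discretise_geometry(config$geometry)
  n <- length(mesh$V)
  D <- config$D_Mg

  tt <- seq(0, config$t_end, length.out = config$n_t + 1L)
  dt <- days_to_seconds(config$t_end) / config$n_t

  c_vec <- numeric(n)
  c_vec[mesh$implant] <- config$c0_implant

  if (D > 0) {
    fi <- mesh$faces[, 1]; fj <- mesh$faces[, 2]; g <- D * mesh$faces[, 3]
    diag_g <- numeric(n)
    tab_i <- tapply(g, fi, sum); tab_j <- tapply(g, fj, sum)
    diag_g[as.integer(names(tab_i))] <- diag_g[as.integer(names(tab_i))] + tab_i
    diag_g[as.integer(names(tab_j))] <- diag_g[as.integer(names(tab_j))] + tab_j
    if (!is.null(mesh$bnd)) {
      gb <- D * mesh$bnd[, 2]
      tab_b <- tapply(gb, mesh$bnd[, 1], sum)
      diag_g[as.integer(names(tab_b))] <- diag_g[as.integer(names(tab_b))] + tab_b
    }
    A <- Matrix::sparseMatrix(
      i = c(seq_len(n), fi, fj), j = c(seq_len(n), fj, fi),
      x = c(mesh$V + dt * diag_g, -dt * g, -dt * g), dims = c(n, n))
    ch <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(A), "CsparseMatrix"),
                           LDL = FALSE)
  }

  vol <- function(cv) sum(cv[mesh$implant] * mesh$V[mesh$implant]) /
    config$c0_implant
  vl <- numeric(config$n_t + 1L)
  for (s in seq_len(config$n_t)) {
    if (D > 0)
      c_vec <- as.numeric(Matrix::solve(ch, mesh$V * c_vec, system = "A"))
    vl[s + 1L] <- 100 * (mesh$V0 - vol(c_vec)) / mesh$V0
  }
  vl <- pmin(pmax(cummax(vl), 0), 100)

  if (!is.null(output_times)) {
    keep <- stats::approx(tt, vl, xout = output_times, rule = 2)$y
    out <- time_series(output_times, keep, qoi_label = "VL_percent")
  } else out <- time_series(tt, vl, qoi_label = "VL_percent")
  attr(out, "V0") <- mesh$V0
  attr(out, "A0") <- mesh$A0
  out
}

#' Degradation rate from a volume-loss trajectory
#'
#' `DR(t) = (V(0) - V(t)) / (A(0) * t)` in mm per year; the `t = 0` point is
#' excluded (division by zero).
#'
#' @param vl A VL [time_series()] in percent (e.g. from
#'   [simulate_volume_loss()]).
#' @param A0 Initial surface area, mm2 (default: the `A0` attribute of `vl`).
#' @param V0 Initial volume, mm3 (default: the `V0` attribute of `vl`).
#' @return A [time_series()] of DR in mm/yr (`qoi_label = "DR_mm_per_yr"`).
#' @export
degradation_rate <- function(vl, A0 = attr(vl, "A0"), V0 = attr(vl, "V0")) {
  stopifnot(inherits(vl, "mguq_ts"))
  if (is.null(A0) || is.null(V0))
    stop("A0 and V0 must be supplied or attached to 'vl'", call. = FALSE)
  assert_num(A0, lower = 1e-12); assert_num(V0, lower = 1e-12)
  keep <- vl$times > 0
  t_yr <- vl$times[keep] / 365.25
  dr <- (V0 * vl$values[keep, 1] / 100) / (A0 * t_yr)
  time_series(vl$times[keep], dr, qoi_label = "DR_mm_per_yr")
}
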