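# Scalar successive-order-of-scattering (SOS) solver for a plane-parallel
# atmosphere coupled to an ocean through a flat Fresnel interface.
#
# Numerical scheme:
#   - Gauss quadrature in each hemisphere of direction cosines; azimuth by
#     Fourier cosine modes built from normalized associated Legendre
#     expansions of the phase function.
#   - delta-M truncation of forward-peaked phase functions at 2*n_mu terms,
#     with the first scattering order of the direct beams evaluated with the
#     exact closed-form phase function (TMS-style correction).
#   - The unscattered solar beam is tracked analytically in air and water
#     (Snell refraction, Fresnel transmitted-flux weighting); diffuse orders
#     operate on the quadrature field. The specular unscattered glint beam
#     is excluded from viewing radiances but its scattered orders are kept.
#   - Within one order, light crossing the interface is redistributed with
#     flux-conserving Fresnel transmission/reflection matrices, including
#     total internal reflection of in-water upward directions beyond the
#     critical angle. The lower boundary is black.
#   - Radiances at requested viewing cosines are obtained by integrating the
#     converged source function along the exact line of sight.

#' Angular quadrature grid
#'
#' @param n_mu Gauss nodes per hemisphere
#' @param n_modes number of azimuth Fourier cosine modes (1 = azimuth
#'   average, sufficient for nadir viewing and irradiances)
#' @return object of class `angular_grid`
#' @export
angular_grid <- function(n_mu = 16, n_modes = 1) {
  gq <- gauss_hemisphere(n_mu)
  structure(list(mu = gq$mu, w = gq$w, n_mu = n_mu, n_modes = n_modes),
            class = "angular_grid")
}

#' Unpolarized Fresnel coefficients
#'
#' Average of the two polarization-component reflectances, Snell refraction,
#' and total internal reflection (reflectance 1) when the refraction angle
#' is imaginary.
#'
#' @param mu cosine of the incidence angle (0 < mu <= 1)
#' @param n_ratio refractive index of the transmission side over the
#'   incidence side (1.34 for air to water, 1/1.34 for water to air)
#' @return list with `R` (reflectance), `Tf` (transmitted flux fraction,
#'   1 - R), and `mu_t` (refracted cosine, NA under total internal
#'   reflection)
#' @export
fresnel <- function(mu, n_ratio) {
  stopifnot(all(mu > 0), all(mu <= 1))
  sin2_t <- (1 - mu^2) / n_ratio^2
  tir <- sin2_t >= 1
  mu_t <- ifelse(tir, NA_real_, sqrt(pmax(1 - sin2_t, 0)))
  rs <- (mu - n_ratio * mu_t) / (mu + n_ratio * mu_t)
  rp <- (n_ratio * mu - mu_t) / (n_ratio * mu + mu_t)
  R <- ifelse(tir, 1, (rs^2 + rp^2) / 2)
  list(R = R, Tf = 1 - R, mu_t = mu_t)
}

#' Combine atmosphere and ocean layers into one stack
#'
#' @param air data.frame of air layers (top first), as from
#'   [build_atmosphere_stack()]
#' @param water data.frame of water layers (surface first) with columns
#'   `tau`, `omega`, phase mixture columns, `dz` [m] and `cext` [m-1], or
#'   `NULL` for an atmosphere-only stack
#' @param n_water refractive index of water
#' @return object of class `layer_stack`
#' @export
layer_stack <- function(air, water = NULL, n_water = 1.34) {
  layers <- if (is.null(water)) air else rbind(air, water)
  if (any(layers$tau < 0) || any(layers$omega < 0) || any(layers$omega > 1)) {
    stop("invalid layer inputs: need tau >= 0 and 0 <= omega <= 1")
  }
  med <- layers$medium
  if (any(med == "water") &&
      max(which(med == "air")) > min(which(med == "water"))) {
    stop("air layers must be contiguous above water layers")
  }
  structure(list(layers = layers, n_water = n_water), class = "layer_stack")
}

# Interface redistribution matrices on the quadrature grid.
# Flux-conserving deposition: radiance at an incident node is refracted to
# its Snell cosine and its transmitted partial flux is shared between the
# two bracketing nodes of the other medium.
interface_matrices <- function(mu, w, n_water) {
  n <- length(mu)
  deposit <- function(Tmat, j_from, mu_t, flux_frac, mu_w_to, w_to) {
    # distribute flux_frac (fraction of incident partial flux) at cosine
    # mu_t onto the receiving grid
    idx <- findInterval(mu_t, mu_w_to)
    if (idx == 0) {
      lo <- 1; alpha <- 1
    } else if (idx >= n) {
      lo <- n; alpha <- 1
    } else {
      lo <- idx
      alpha <- (mu_w_to[lo + 1] - mu_t) / (mu_w_to[lo + 1] - mu_w_to[lo])
    }
    Tmat[lo, j_from] <- Tmat[lo, j_from] + alpha * flux_frac
    if (alpha < 1) {
      Tmat[lo + 1, j_from] <- Tmat[lo + 1, j_from] + (1 - alpha) * flux_frac
    }
    Tmat
  }
  # air -> water
  T_aw <- matrix(0, n, n)
  fr_a <- fresnel(mu, n_water)
  for (j in seq_len(n)) {
    T_aw <- deposit(T_aw, j, fr_a$mu_t[j], fr_a$Tf[j], mu, w)
  }
  # water -> air (total internal reflection handled by R_w = 1)
  T_wa <- matrix(0, n, n)
  fr_w <- fresnel(mu, 1 / n_water)
  for (j in seq_len(n)) {
    if (!is.na(fr_w$mu_t[j])) {
      T_wa <- deposit(T_wa, j, fr_w$mu_t[j], fr_w$Tf[j], mu, w)
    }
  }
  # convert flux-share matrices to radiance operators:
  # L_out[i] = sum_j M[i,j] * (mu_j w_j / (mu_i w_i)) * L_in[j]
  fw <- mu * w
  T_aw <- T_aw * outer(1 / fw, fw)
  T_wa <- T_wa * outer(1 / fw, fw)
  list(T_aw = T_aw, T_wa = T_wa, R_a = fr_a$R, R_w = fr_w$R)
}

# Azimuth-mode projection of the exact layer phase function against a beam
# direction: p^m(s*mu_i, s_b*mu_b) for all nodes and both signs s.
# Returns list(same =, opp =) vectors relative to the beam's sign.
beam_phase_mode <- function(phase_row, mu, mu_b, m, nphi = 64) {
  phi <- 2 * pi * (seq_len(nphi) - 0.5) / nphi
  cph <- cos(phi)
  cmph <- cos(m * phi)
  s <- sqrt(pmax(1 - mu^2, 0)) * sqrt(max(1 - mu_b^2, 0))
  proj <- function(sign_prod) {
    base <- sign_prod * mu * mu_b
    ca <- outer(base, rep(1, nphi)) + outer(s, cph)
    p <- phase_exact(ca, phase_row$w_iso, phase_row$w_ray, phase_row$gamma,
                     phase_row$w_hg, phase_row$g)
    as.vector(p %*% cmph) / nphi
  }
  list(same = proj(1), opp = proj(-1))
}

# Build per-layer delta-M scaled quantities and scattering kernels for all
# azimuth modes; kernels are shared between layers with identical optical
# signatures (e.g. a homogeneous water column).
prepare_layers <- function(stack, grid) {
  ly <- stack$layers
  nl <- nrow(ly)
  M <- 2 * grid$n_mu                      # truncation order (terms 0..M-1)
  chi <- matrix(0, nl, M + 1)
  for (k in seq_len(nl)) {
    chi[k, ] <- phase_moments_components(ly$w_iso[k], ly$w_ray[k],
                                         ly$gamma[k], ly$w_hg[k], ly$g[k], M)
  }
  f <- chi[, M + 1]
  omega_s <- ly$omega * (1 - f) / (1 - ly$omega * f)
  tau_s <- ly$tau * (1 - ly$omega * f)
  chi_s <- (chi[, seq_len(M), drop = FALSE] - f) / (1 - f)
  sig <- apply(cbind(round(omega_s, 14), round(chi_s, 14)), 1, paste,
               collapse = ",")
  uid <- match(sig, unique(sig))
  list(layers = ly, n = nl, M = M, f = f, omega_s = omega_s, tau_s = tau_s,
       chi_s = chi_s, uid = uid, n_uid = max(uid))
}

# Scattering kernel matrices for one azimuth mode and one unique layer type.
mode_kernels <- function(prep, grid, m) {
  M <- prep$M
  Lam <- legendre_norm(grid$mu, M - 1, m)      # n_mu x (M-m)
  l <- m:(M - 1)
  lapply(seq_len(prep$n_uid), function(u) {
    k <- which(prep$uid == u)[1]
    cl <- (2 * l + 1) * prep$chi_s[k, l + 1]
    P_same <- Lam %*% (cl * t(Lam))
    P_opp <- Lam %*% ((cl * (-1)^(l - m)) * t(Lam))
    half_omega <- prep$omega_s[k] / 2
    list(P_same = P_same * half_omega, P_opp = P_opp * half_omega)
  })
}

# extract boundary slab b of a [n_mu x n_layer x 2] source array as a matrix
source_slab <- function(A, b) {
  array(A[, , b], dim = dim(A)[1:2])
}

# One transport sweep through a set of layers for a matrix field
# I [n_mu x n_level]; J arrays are [n_mu x n_layer] at the near and far
# boundaries in sweep direction. Linear-in-tau source integration.
sweep_field <- function(I0, tau_s, mu, J_near, J_far) {
  nl <- length(tau_s)
  out <- matrix(0, length(mu), nl + 1)
  out[, 1] <- I0
  for (k in seq_len(nl)) {
    x <- tau_s[k] / mu
    E <- exp(-x)
    r <- expm1_ratio(x)
    out[, k + 1] <- out[, k] * E + J_near[, k] * (r - E) + J_far[, k] * (1 - r)
  }
  out
}

#' Solve the coupled radiative transfer problem by successive orders
#'
#' Iterates scattering orders on a layered air/water stack until the
#' order-n contribution to the requested outputs falls below `tol`
#' (relative) or `max_orders` is reached. Returns the diffuse radiance
#' field at every level, irradiances in water, and viewing radiances at the
#' top of the atmosphere and just below the interface obtained by
#' source-function integration.
#'
#' @param stack a [layer_stack()]
#' @param theta0 solar zenith angle [deg], 0-89
#' @param grid an [angular_grid()]
#' @param extra_source isotropic volume source at the water level grid
#'   [W m-3 nm-1 sr-1] (length n_water_layers + 1), or `NULL`
#' @param F0 extraterrestrial solar irradiance normal to the beam
#'   [W m-2 nm-1]; set 0 for a source-only (emission) solve
#' @param max_orders,tol iteration controls
#' @param out_mu viewing cosines for output radiances (1 = nadir)
#' @param nphi azimuth quadrature points for exact-phase beam projections
#' @return object of class `sos_field`
#' @export
solve_sos <- function(stack, theta0, grid = angular_grid(),
                      extra_source = NULL, F0 = 1, max_orders = 100,
                      tol = 1e-4, out_mu = 1, nphi = 64) {
  stopifnot(inherits(stack, "layer_stack"), theta0 >= 0, theta0 <= 89,
            tol > 0)
  mu0 <- cos(theta0 * pi / 180)
  ly <- stack$layers
  ia <- which(ly$medium == "air")
  iw <- which(ly$medium == "water")
  na <- length(ia); nw <- length(iw)
  if (na == 0) stop("stack needs at least one air layer")
  prep <- prepare_layers(stack, grid)
  mu <- grid$mu; w <- grid$w; n <- grid$n_mu
  tau_a <- prep$tau_s[ia]; tau_w <- prep$tau_s[iw]
  cumA <- c(0, cumsum(tau_a)); cumW <- c(0, cumsum(tau_w))
  nla <- na + 1; nlw <- nw + 1

  ifc <- if (nw > 0) interface_matrices(mu, w, stack$n_water) else NULL

  # --- analytic beams (normal flux at each level, delta-M scaled paths) ---
  Fa_dn <- F0 * exp(-cumA / mu0)
  if (nw > 0) {
    fr0 <- fresnel(mu0, stack$n_water)
    mu0w <- fr0$mu_t
    Fw_dn <- Fa_dn[nla] * fr0$Tf * (mu0 / mu0w) * exp(-cumW / mu0w)
    Fa_up <- Fa_dn[nla] * fr0$R * exp(-(cumA[nla] - cumA) / mu0)
  } else {
    mu0w <- NA_real_
    Fw_dn <- numeric(0)
    Fa_up <- rep(0, nla)                  # black lower boundary
  }
  has_beam <- F0 > 0

  # per-layer scaled extinction [m-1] for volume-source conversion
  cext_s <- ly$cext * (1 - ly$omega * prep$f)

  n_modes <- max(grid$n_modes, 1L)
  # accumulated fields per mode: list of list(Ia_dn, Ia_up, Iw_dn, Iw_up)
  tot <- vector("list", n_modes)
  order_contrib <- numeric(0)
  converged <- FALSE
  residual <- NA_real_

  # cache of exact-phase beam projections, per (mode, uid, beam)
  bp_cache <- new.env(parent = emptyenv())
  beam_proj <- function(m, k, mu_b) {
    key <- paste(m, prep$uid[k], signif(mu_b, 12), sep = "|")
    if (is.null(bp_cache[[key]])) {
      bp_cache[[key]] <- beam_phase_mode(ly[k, ], mu, mu_b, m, nphi)
    }
    bp_cache[[key]]
  }

  # first-order (beam + volume emission) source arrays for one mode
  first_order_sources <- function(m) {
    twodelta <- if (m == 0) 1 else 2
    Jd_a <- array(0, c(n, na, 2)); Ju_a <- array(0, c(n, na, 2))
    Jd_w <- if (nw > 0) array(0, c(n, nw, 2)) else NULL
    Ju_w <- if (nw > 0) array(0, c(n, nw, 2)) else NULL
    if (has_beam) {
      for (j in seq_len(na)) {
        k <- ia[j]
        fac <- ly$omega[k] / (1 - ly$omega[k] * prep$f[k]) / (4 * pi) *
          twodelta
        bp <- beam_proj(m, k, mu0)
        for (b in 1:2) {                  # level indices j, j+1
          lev <- j + b - 1
          # downward solar beam (down-going nodes: same sign as beam)
          Jd_a[, j, b] <- Jd_a[, j, b] + fac * bp$same * Fa_dn[lev]
          Ju_a[, j, b] <- Ju_a[, j, b] + fac * bp$opp * Fa_dn[lev]
          # upward specular beam
          if (nw > 0 && Fa_up[lev] > 0) {
            Jd_a[, j, b] <- Jd_a[, j, b] + fac * bp$opp * Fa_up[lev]
            Ju_a[, j, b] <- Ju_a[, j, b] + fac * bp$same * Fa_up[lev]
          }
        }
      }
      if (nw > 0) {
        for (j in seq_len(nw)) {
          k <- iw[j]
          fac <- ly$omega[k] / (1 - ly$omega[k] * prep$f[k]) / (4 * pi) *
            twodelta
          bp <- beam_proj(m, k, mu0w)
          for (b in 1:2) {
            lev <- j + b - 1
            Jd_w[, j, b] <- Jd_w[, j, b] + fac * bp$same * Fw_dn[lev]
            Ju_w[, j, b] <- Ju_w[, j, b] + fac * bp$opp * Fw_dn[lev]
          }
        }
      }
    }
    if (!is.null(extra_source) && m == 0 && nw > 0) {
      if (length(extra_source) != nlw) {
        stop("extra_source must have one value per water level (",
             nlw, ")")
      }
      for (j in seq_len(nw)) {
        k <- iw[j]
        if (!is.finite(cext_s[k]) || cext_s[k] <= 0) {
          stop("water layers need a positive extinction cext for ",
               "volume sources")
        }
        for (b in 1:2) {
          sv <- extra_source[j + b - 1] / cext_s[k]
          Jd_w[, j, b] <- Jd_w[, j, b] + sv
          Ju_w[, j, b] <- Ju_w[, j, b] + sv
        }
      }
    }
    list(Jd_a = Jd_a, Ju_a = Ju_a, Jd_w = Jd_w, Ju_w = Ju_w)
  }

  # transport one order's sources into a field
  transport <- function(src) {
    Ia_dn <- sweep_field(rep(0, n), tau_a, mu,
                         source_slab(src$Jd_a, 1), source_slab(src$Jd_a, 2))
    if (nw > 0) {
      Iw_dn <- sweep_field(as.vector(ifc$T_aw %*% Ia_dn[, nla]), tau_w, mu,
                           source_slab(src$Jd_w, 1),
                           source_slab(src$Jd_w, 2))
      # upward through water (sweep from bottom): reverse layer order
      rw <- rev(seq_len(nw))
      Iw_up_r <- sweep_field(rep(0, n), tau_w[rw], mu,
                             source_slab(src$Ju_w, 2)[, rw, drop = FALSE],
                             source_slab(src$Ju_w, 1)[, rw, drop = FALSE])
      Iw_up <- Iw_up_r[, rev(seq_len(nlw)), drop = FALSE]
      # interface: transmit up into air, reflect back down into water
      up0 <- as.vector(ifc$T_wa %*% Iw_up[, 1]) + ifc$R_a * Ia_dn[, nla]
      refl <- ifc$R_w * Iw_up[, 1]
      add <- matrix(0, n, nlw)
      add[, 1] <- refl
      for (k in seq_len(nw)) {
        add[, k + 1] <- add[, k] * exp(-tau_w[k] / mu)
      }
      Iw_dn <- Iw_dn + add
    } else {
      Iw_dn <- NULL; Iw_up <- NULL
      up0 <- rep(0, n)
    }
    ra <- rev(seq_len(na))
    Ia_up_r <- sweep_field(up0, tau_a[ra], mu,
                           source_slab(src$Ju_a, 2)[, ra, drop = FALSE],
                           source_slab(src$Ju_a, 1)[, ra, drop = FALSE])
    Ia_up <- Ia_up_r[, rev(seq_len(nla)), drop = FALSE]
    list(Ia_dn = Ia_dn, Ia_up = Ia_up, Iw_dn = Iw_dn, Iw_up = Iw_up)
  }

  # scattering source of the next order from a field, for one mode
  next_sources <- function(fld, kernels) {
    Jd_a <- array(0, c(n, na, 2)); Ju_a <- array(0, c(n, na, 2))
    # air: per-level source per unique kernel
    Ja_cache <- list()
    for (j in seq_len(na)) {
      u <- prep$uid[ia[j]]
      if (is.null(Ja_cache[[as.character(u)]])) {
        K <- kernels[[u]]
        wd <- w * fld$Ia_dn; wu <- w * fld$Ia_up
        Ja_cache[[as.character(u)]] <- list(
          dn = K$P_same %*% wd + K$P_opp %*% wu,
          up = K$P_opp %*% wd + K$P_same %*% wu)
      }
      Jc <- Ja_cache[[as.character(u)]]
      Jd_a[, j, 1] <- Jc$dn[, j];     Ju_a[, j, 1] <- Jc$up[, j]
      Jd_a[, j, 2] <- Jc$dn[, j + 1]; Ju_a[, j, 2] <- Jc$up[, j + 1]
    }
    if (nw > 0) {
      Jd_w <- array(0, c(n, nw, 2)); Ju_w <- array(0, c(n, nw, 2))
      Jw_cache <- list()
      for (j in seq_len(nw)) {
        u <- prep$uid[iw[j]]
        if (is.null(Jw_cache[[as.character(u)]])) {
          K <- kernels[[u]]
          wd <- w * fld$Iw_dn; wu <- w * fld$Iw_up
          Jw_cache[[as.character(u)]] <- list(
            dn = K$P_same %*% wd + K$P_opp %*% wu,
            up = K$P_opp %*% wd + K$P_same %*% wu)
        }
        Jc <- Jw_cache[[as.character(u)]]
        Jd_w[, j, 1] <- Jc$dn[, j];     Ju_w[, j, 1] <- Jc$up[, j]
        Jd_w[, j, 2] <- Jc$dn[, j + 1]; Ju_w[, j, 2] <- Jc$up[, j + 1]
      }
    } else {
      Jd_w <- NULL; Ju_w <- NULL
    }
    list(Jd_a = Jd_a, Ju_a = Ju_a, Jd_w = Jd_w, Ju_w = Ju_w)
  }

  add_fields <- function(a, b) {
    if (is.null(a)) return(b)
    out <- a
    for (nm in names(b)) if (!is.null(b[[nm]])) out[[nm]] <- a[[nm]] + b[[nm]]
    out
  }

  # --- order iteration per mode ---
  for (m in seq_len(n_modes) - 1L) {
    kernels <- mode_kernels(prep, grid, m)
    src <- first_order_sources(m)
    acc <- NULL
    fld <- transport(src)
    acc <- add_fields(acc, fld)
    if (max_orders >= 2) for (ord in 2:max_orders) {
      src <- next_sources(fld, kernels)
      fld <- transport(src)
      # contribution metric on requested outputs (m = 0 dominates)
      top <- 2 * pi * sum(w * mu * fld$Ia_up[, 1])
      top_tot <- 2 * pi * sum(w * mu * acc$Ia_up[, 1]) + top
      if (nw > 0) {
        eo <- 2 * pi * colSums(w * (fld$Iw_dn + fld$Iw_up))
        eo_tot <- 2 * pi * colSums(w * (acc$Iw_dn + acc$Iw_up)) + eo +
          Fw_dn
        rel <- max(abs(top) / max(abs(top_tot), 1e-300),
                   max(abs(eo) / pmax(abs(eo_tot), 1e-300)))
      } else {
        rel <- abs(top) / max(abs(top_tot), 1e-300)
      }
      acc <- add_fields(acc, fld)
      if (m == 0) order_contrib <- c(order_contrib, rel)
      if (rel < tol) { converged <- TRUE; residual <- rel; break }
      residual <- rel
      if (ord == max_orders) {
        warning(sprintf(
          "SOS not converged after %d orders (mode %d, residual %.3g)",
          max_orders, m, rel))
      }
    }
    tot[[m + 1]] <- acc
  }

  # --- irradiances (mode 0 only) ---
  t0 <- tot[[1]]
  if (nw > 0) {
    Eo_w <- 2 * pi * colSums(w * (t0$Iw_dn + t0$Iw_up)) + Fw_dn
    Ed_w <- 2 * pi * colSums(w * mu * t0$Iw_dn) + Fw_dn * mu0w
    Eu_w <- 2 * pi * colSums(w * mu * t0$Iw_up)
  } else {
    Eo_w <- Ed_w <- Eu_w <- numeric(0)
  }
  Eo_a <- 2 * pi * colSums(w * (t0$Ia_dn + t0$Ia_up)) + Fa_dn + Fa_up
  Ed_a <- 2 * pi * colSums(w * mu * t0$Ia_dn) + Fa_dn * mu0
  Eu_a <- 2 * pi * colSums(w * mu * t0$Ia_up) + Fa_up * mu0

  # --- output radiances by source-function integration ---
  # Because the transfer is linear, the total source at an output direction
  # equals the truncated kernel applied to the accumulated field (all
  # scattered orders) plus the exact first-order beam/volume source.
  # J at both boundaries of every layer of one medium, for one direction.
  dir_sources <- function(mu_d, m, acc, idx, I_dn, I_up, beams, up,
                          S_extra) {
    twodelta <- if (m == 0) 1 else 2
    M <- prep$M
    Lam_v <- legendre_norm(mu_d, M - 1, m)
    Lam_n <- legendre_norm(mu, M - 1, m)
    l <- m:(M - 1)
    nly <- length(idx)
    Jl <- matrix(0, nly, 2)
    for (jj in seq_len(nly)) {
      k <- idx[jj]
      cl <- (2 * l + 1) * prep$chi_s[k, l + 1]
      same <- as.vector(Lam_v %*% (cl * t(Lam_n)))
      opp <- as.vector(Lam_v %*% (((-1)^(l - m) * cl) * t(Lam_n)))
      vs_dn <- if (up) opp else same
      vs_up <- if (up) same else opp
      fac <- ly$omega[k] / (1 - ly$omega[k] * prep$f[k]) / (4 * pi) *
        twodelta
      for (b in 1:2) {
        lev <- jj + b - 1
        val <- prep$omega_s[k] / 2 *
          (sum(vs_dn * w * I_dn[, lev]) + sum(vs_up * w * I_up[, lev]))
        for (bm in beams) {
          if (bm$F[lev] > 0) {
            bp <- beam_phase_mode(ly[k, ], mu_d, bm$mu, m, nphi)
            pv <- if (bm$up == up) bp$same else bp$opp
            val <- val + fac * pv * bm$F[lev]
          }
        }
        if (!is.null(S_extra) && m == 0) {
          val <- val + S_extra[lev] / cext_s[k]
        }
        Jl[jj, b] <- val
      }
    }
    Jl
  }
  # integrate a line of sight through layers j1..j2 (in sweep order)
  los_integrate <- function(L0, taus, mu_d, J_near, J_far) {
    L <- L0
    for (jj in seq_along(taus)) {
      x <- taus[jj] / mu_d
      E <- exp(-x); r <- expm1_ratio(x)
      L <- L * E + J_near[jj] * (r - E) + J_far[jj] * (1 - r)
    }
    L
  }
  out_radiance <- function(mu_v, m, acc) {
    air_beams <- list()
    if (has_beam) {
      air_beams <- list(list(mu = mu0, up = FALSE, F = Fa_dn),
                        list(mu = mu0, up = TRUE, F = Fa_up))
    }
    Lw_toa <- 0; Lw_too <- NA_real_
    if (nw > 0) {
      frv <- fresnel(mu_v, stack$n_water)
      mu_wv <- frv$mu_t
      w_beams <- if (has_beam) {
        list(list(mu = mu0w, up = FALSE, F = Fw_dn))
      } else list()
      # TOA branch: in-water path at the Snell-matched cosine
      Jw <- dir_sources(mu_wv, m, acc, iw, acc$Iw_dn, acc$Iw_up, w_beams,
                        up = TRUE, S_extra = extra_source)
      rw <- rev(seq_len(nw))
      Lw_toa <- los_integrate(0, tau_w[rw], mu_wv, Jw[rw, 2], Jw[rw, 1])
      # TOO branch: below-surface viewing at mu_v directly
      if (abs(mu_wv - mu_v) < 1e-12) {
        Jw_v <- Jw
      } else {
        Jw_v <- dir_sources(mu_v, m, acc, iw, acc$Iw_dn, acc$Iw_up,
                            w_beams, up = TRUE, S_extra = extra_source)
      }
      Lw_too <- los_integrate(0, tau_w[rw], mu_v, Jw_v[rw, 2], Jw_v[rw, 1])
    }
    # downward air radiance at 0+, for the specular reflection into view
    if (nw > 0) {
      Ja_dn <- dir_sources(mu_v, m, acc, ia, acc$Ia_dn, acc$Ia_up,
                           air_beams, up = FALSE, S_extra = NULL)
      La_dn <- los_integrate(0, tau_a, mu_v, Ja_dn[, 1], Ja_dn[, 2])
      frv <- fresnel(mu_v, stack$n_water)
      L0 <- frv$Tf / stack$n_water^2 * Lw_toa + frv$R * La_dn
    } else {
      L0 <- 0
    }
    Ja_up <- dir_sources(mu_v, m, acc, ia, acc$Ia_dn, acc$Ia_up, air_beams,
                         up = TRUE, S_extra = NULL)
    ra <- rev(seq_len(na))
    La <- los_integrate(L0, tau_a[ra], mu_v, Ja_up[ra, 2], Ja_up[ra, 1])
    c(toa = La, too = Lw_too)
  }

  toa <- matrix(0, length(out_mu), n_modes)
  too <- matrix(NA_real_, length(out_mu), n_modes)
  for (m in seq_len(n_modes) - 1L) {
    for (v in seq_along(out_mu)) {
      r <- out_radiance(out_mu[v], m, tot[[m + 1]])
      toa[v, m + 1] <- r["toa"]
      too[v, m + 1] <- r["too"]
    }
  }

  z_w <- if (nw > 0) c(0, cumsum(ly$dz[iw])) else numeric(0)
  structure(list(
    grid = grid, mu0 = mu0, mu0w = mu0w, F0 = F0, n_water = stack$n_water,
    out_mu = out_mu,
    air = list(I_dn = t0$Ia_dn, I_up = t0$Ia_up, tau = cumA),
    water = list(I_dn = t0$Iw_dn, I_up = t0$Iw_up, tau = cumW, z = z_w),
    beams = list(air_dn = Fa_dn, air_up = Fa_up, water_dn = Fw_dn),
    Eo_water = Eo_w, Ed_water = Ed_w, Eu_water = Eu_w,
    Eo_air = Eo_a, Ed_air = Ed_a, Eu_air = Eu_a,
    toa = toa, too = too,
    orders = length(order_contrib) + 1L, converged = converged,
    residual = residual, order_contrib = order_contrib),
    class = "sos_field")
}

#' Scalar irradiance at a level
#'
#' \eqn{E_o = \oint L\,d\Omega} by quadrature, including the direct beam.
#'
#' @param field an `sos_field` from [solve_sos()]
#' @param level level index (1 = surface/top of the medium)
#' @param medium "water" (default) or "air"
#' @return scalar irradiance [W m-2 nm-1]
#' @export
scalar_irradiance <- function(field, level, medium = "water") {
  v <- if (medium == "water") field$Eo_water else field$Eo_air
  if (any(level < 1) || any(level > length(v))) stop("level not in field")
  v[level]
}

#' Downwelling plane irradiance at a level
#'
#' \eqn{E_d = \int_{2\pi^-} L\,\mu\,d\Omega} plus the direct-beam term.
#'
#' @inheritParams scalar_irradiance
#' @return downwelling irradiance [W m-2 nm-1]
#' @export
downwelling_irradiance <- function(field, level, medium = "water") {
  v <- if (medium == "water") field$Ed_water else field$Ed_air
  if (any(level < 1) || any(level > length(v))) stop("level not in field")
  v[level]
}

#' Reflectance from radiance and downwelling irradiance
#'
#' \eqn{\rho = \pi I / E_d}.
#'
#' @param radiance radiance [W m-2 nm-1 sr-1]
#' @param Ed downwelling irradiance [W m-2 nm-1], > 0
#' @return reflectance (dimensionless)
#' @export
reflectance <- function(radiance, Ed) {
  if (any(Ed <= 0)) stop("reflectance undefined: Ed must be positive")
  pi * radiance / Ed
}

#' Viewing radiance from a solved field
#'
#' Assembles the azimuth-mode sum \eqn{L = \sum_m L^m \cos m(\phi_0-\phi)}
#' for the requested level.
#'
#' @param field an `sos_field`
#' @param where "toa" (top of atmosphere) or "too" (just below the surface)
#' @param phi relative viewing azimuth [rad]
#' @return radiance per output cosine [W m-2 nm-1 sr-1]
#' @export
viewing_radiance <- function(field, where = c("toa", "too"), phi = 0) {
  where <- match.arg(where)
  Lm <- if (where == "toa") field$toa else field$too
  m <- seq_len(ncol(Lm)) - 1
  as.vector(Lm %*% cos(m * phi))
}
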