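# Monte-Carlo photon-tracing oracle for a plane-parallel slab without an
# interface, and small shared fixtures.
#
# Independent of the SOS solver: explicit photon random walks with
# Henyey-Greenstein (or isotropic) scattering, batched to estimate standard
# errors.

mc_slab <- function(tau, omega, g, mu0, n_photons = 4e5, n_batch = 20,
                    seed = 1, mu_bins = c(0, 0.5, 1)) {
  stopifnot(length(tau) == length(omega), length(tau) == length(g))
  bounds <- c(0, cumsum(tau))
  Ttot <- bounds[length(bounds)]
  per <- ceiling(n_photons / n_batch)
  nb <- length(mu_bins) - 1
  res <- matrix(0, n_batch, 2 + nb,
                dimnames = list(NULL, c("R", "T", paste0("bin", seq_len(nb)))))
  set.seed(seed)
  for (b in seq_len(n_batch)) {
    pos <- rep(0, per)          # optical depth from top
    mu <- rep(mu0, per)         # direction cosine, > 0 down
    wgt <- rep(1, per)
    alive <- rep(TRUE, per)
    accR <- 0; accT <- 0; accBin <- numeric(nb)
    for (it in 1:2000) {
      idx <- which(alive)
      if (!length(idx)) break
      s <- -log(stats::runif(length(idx)))
      m <- mu[idx]
      sb <- ifelse(m > 0, (Ttot - pos[idx]) / m, -pos[idx] / m)
      esc <- s >= sb
      # escapes
      up <- esc & m < 0
      dn <- esc & m > 0
      if (any(up)) {
        accR <- accR + sum(wgt[idx][up])
        ab <- abs(m[up])
        for (k in seq_len(nb)) {
          inb <- ab > mu_bins[k] & ab <= mu_bins[k + 1]
          accBin[k] <- accBin[k] + sum(wgt[idx][up][inb])
        }
      }
      if (any(dn)) accT <- accT + sum(wgt[idx][dn])
      alive[idx[esc]] <- FALSE
      # scatter the rest
      sc <- idx[!esc]
      if (!length(sc)) next
      pos[sc] <- pos[sc] + s[!esc] * mu[sc]
      lay <- findInterval(pos[sc], bounds, rightmost.closed = TRUE)
      lay <- pmin(pmax(lay, 1), length(tau))
      wgt[sc] <- wgt[sc] * omega[lay]
      gl <- g[lay]
      u <- stats::runif(length(sc))
      ct <- ifelse(abs(gl) < 1e-9, 2 * u - 1,
                   (1 + gl^2 - ((1 - gl^2) / (1 - gl + 2 * gl * u))^2) /
                     (2 * gl))
      phi <- 2 * pi * stats::runif(length(sc))
      st <- sqrt(pmax(1 - ct^2, 0))
      smu <- sqrt(pmax(1 - mu[sc]^2, 0))
      mu[sc] <- mu[sc] * ct + smu * st * cos(phi)
      # roulette
      low <- wgt[sc] < 1e-4
      if (any(low)) {
        keep <- stats::runif(sum(low)) < 0.5
        wgt[sc][low] <- ifelse(keep, wgt[sc][low] * 2, 0)
        alive[sc[low][!keep]] <- FALSE
      }
    }
    # flux fractions of the incident beam; bin-average radiances for F0 = 1
    res[b, "R"] <- accR / per
    res[b, "T"] <- accT / per
    for (k in seq_len(nb)) {
      res[b, 2 + k] <- mu0 * accBin[k] /
        (per * pi * (mu_bins[k + 1]^2 - mu_bins[k]^2))
    }
  }
  list(mean = colMeans(res), se = apply(res, 2, stats::sd) / sqrt(n_batch))
}

# a uniform slab as an air-only layer stack, subdivided for transport
# accuracy
slab_stack <- function(tau, omega, nsub = 10, w_iso = 1, w_ray = 0,
                       gamma = 0, w_hg = 0, g = 0) {
  one <- function(tt, oo, wi, wr, wh, gg) {
    data.frame(tau = tt / nsub, omega = oo, medium = "air", w_iso = wi,
               w_ray = wr, gamma = gamma, w_hg = wh, g = gg,
               dz = NA_real_, cext = NA_real_)[rep(1, nsub), ]
  }
  dfs <- mapply(one, tau, omega, w_iso, w_ray, w_hg, g, SIMPLIFY = FALSE)
  layer_stack(do.call(rbind, dfs))
}

# small scene for fast property tests
mini_scene <- function(...) {
  scene(excitation_grid = seq(390, 690, by = 30),
        emission_grid = seq(650, 720, by = 10),
        n_mu = 8, n_water_layers = 16, ...)
}
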