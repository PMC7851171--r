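#' Luminescence photon energy deposition (Monte Carlo)
#'
#' Transports proton-induced luminescence photons through the layered
#' scenario and scores the energy they re-deposit on absorption. Photon
#' emission density is proportional to the locally deposited proton energy
#' times the material light yield; each photon draws a wavelength from the
#' lambda^-2 luminescence spectrum on 300-700 nm, an isotropic direction,
#' and an exponential free path governed by the medium- and
#' wavelength-dependent absorption coefficient. The full photon energy is
#' deposited at the absorption site; photons leaving the simulated domain
#' are discarded. Scattering, refraction and re-emission are not modelled:
#' the contrast of interest is dominated by the enormous absorption
#' difference between water and India ink.
#'
#' In 1D mode the photon direction cosine along the axis is uniform on
#' \[-1, 1\] (isotropic 3D emission projected on the beam axis) and the
#' medium is laterally unbounded; in 2D mode directions are isotropic in
#' the simulated plane and photons also escape laterally.
#'
#' @param dose an [ia_dosemap()] of the proton beam (1D or 2D).
#' @param scenario the generating [ia_scenario()].
#' @param light_yield photons emitted per MeV of deposited energy; when
#'   `NULL`, each material's own `light_yield` is used (per-material
#'   override of the uniform default).
#' @param n_photons number of Monte Carlo photon histories.
#' @param seed integer seed for the photon sampling.
#' @return An object of class `ia_optical_dosemap` (an [ia_dosemap()] with
#'   extra fields): `values` in Gy, plus the energy bookkeeping
#'   `emitted_J`, `absorbed_J`, `escaped_J` and the sampled wavelengths'
#'   summary.
#' @export
optical_energy_deposition <- function(dose, scenario, light_yield = NULL,
                                      n_photons = 1e6, seed = 1L) {
  if (!is.null(light_yield) && light_yield < 0) stop("light_yield must be >= 0")
  if (n_photons < 0) stop("n_photons must be >= 0")
  x <- dose$x
  dx <- x[2] - x[1]
  two_d <- is.matrix(dose$values)
  rho <- scenario_property(scenario, x, "rho")
  yield <- if (is.null(light_yield))
    scenario_property(scenario, x, "light_yield")
  else rep(light_yield, length(x))

  # energy deposited per cell (J): dose Gy * rho * cell volume
  aeff <- 2 * pi * dose$lateral_sigma^2
  if (two_d) {
    dy <- dose$y[2] - dose$y[1]
    vol <- dx * dy * dy                       # slab thickness = dy convention
    edep <- dose$values * rho * vol           # matrix
    w_emit <- edep * yield                    # photons (per MeV) weighting
  } else {
    vol <- dx * aeff
    edep <- dose$values * rho * vol
    w_emit <- edep * yield
  }
  MeV <- 1.602176634e-13
  n_phys <- sum(w_emit) / MeV                 # physical photon count
  out <- dose
  class(out) <- c("ia_optical_dosemap", "ia_dosemap")
  out$values <- if (two_d) 0 * dose$values else numeric(length(x))
  out$wavelength_range <- c(300, 700)
  out$spectrum_exponent <- -2
  out$n_photons_sampled <- n_photons
  out$seed <- seed
  out$light_yield <- light_yield
  if (n_photons == 0 || n_phys == 0 || sum(w_emit) == 0) {
    out$emitted_J <- 0; out$absorbed_J <- 0; out$escaped_J <- 0
    return(out)
  }

  set.seed(seed)
  # emission cells ~ deposited energy x yield
  pcell <- as.numeric(w_emit) / sum(w_emit)
  cell <- sample.int(length(pcell), n_photons, replace = TRUE, prob = pcell)
  if (two_d) {
    nx <- length(x)
    ix <- (cell - 1L) %% nx + 1L
    iy <- (cell - 1L) %/% nx + 1L
    px <- x[ix] + (stats::runif(n_photons) - 0.5) * dx
    py <- dose$y[iy] + (stats::runif(n_photons) - 0.5) * dy
  } else {
    px <- x[cell] + (stats::runif(n_photons) - 0.5) * dx
    py <- NULL
  }

  # lambda ~ lambda^-2 on [300, 700] nm by inverse CDF
  lo <- 300; hi <- 700
  u <- stats::runif(n_photons)
  lambda <- 1 / (1 / lo - u * (1 / lo - 1 / hi))
  e_photon <- 1239.841984 / lambda * 1.602176634e-19   # J (hc/lambda)
  w <- n_phys / n_photons                               # photons per history

  # absorption table per (layer, photon wavelength)
  nlay <- length(scenario$layers)
  mu_tab <- matrix(0, nlay, n_photons)
  for (il in seq_len(nlay))
    mu_tab[il, ] <- material_mu_a(scenario$layers[[il]]$material, lambda) * 1e3  # 1/m
  lx0 <- vapply(scenario$layers, `[[`, numeric(1), "x0")
  lx1 <- vapply(scenario$layers, `[[`, numeric(1), "x1")

  if (two_d) {
    phi <- stats::runif(n_photons, 0, 2 * pi)
    ex <- cos(phi); ey <- sin(phi)
  } else {
    ex <- stats::runif(n_photons, -1, 1)                # direction cosine
    ey <- rep(0, n_photons)
  }
  tau <- stats::rexp(n_photons)

  # march photons through the axial layer structure
  alive <- rep(TRUE, n_photons)
  absorbed_at_x <- rep(NA_real_, n_photons)
  absorbed_at_y <- rep(NA_real_, n_photons)
  xmin <- lx0[1]; xmax <- lx1[nlay]
  guard <- 0L
  cx <- px; cy <- if (two_d) py else rep(0, n_photons)
  while (any(alive) && guard < 10L * nlay + 20L) {
    guard <- guard + 1L
    ia <- which(alive)
    lay <- scenario_layer_index(scenario, cx[ia])
    mu <- mu_tab[cbind(lay, ia)]
    # path length to the axial boundary of the current layer
    bnd <- ifelse(ex[ia] > 0, lx1[lay], lx0[lay])
    sb <- ifelse(abs(ex[ia]) > 1e-12, (bnd - cx[ia]) / ex[ia], Inf)
    sb <- pmax(sb, 0)
    s_abs <- tau[ia] / pmax(mu, 1e-300)
    hit <- s_abs <= sb
    # absorbed inside this layer
    ha <- ia[hit]
    if (length(ha)) {
      sa <- s_abs[hit]
      absorbed_at_x[ha] <- cx[ha] + sa * ex[ha]
      absorbed_at_y[ha] <- cy[ha] + sa * ey[ha]
      alive[ha] <- FALSE
    }
    # moved to the next layer
    hm <- ia[!hit]
    if (length(hm)) {
      sbm <- sb[!hit]
      tau[hm] <- tau[hm] - sbm * mu[!hit]
      eps <- 1e-9 * max(dx, 1e-6)
      cx[hm] <- cx[hm] + (sbm + 0) * ex[hm] + sign(ex[hm]) * eps
      cy[hm] <- cy[hm] + sbm * ey[hm]
      gone <- cx[hm] <= xmin | cx[hm] >= xmax
      alive[hm[gone]] <- FALSE
    }
  }

  ok <- !is.na(absorbed_at_x)
  if (two_d) {
    ymin <- dose$y[1] - dy / 2; ymax <- dose$y[length(dose$y)] + dy / 2
    ok <- ok & absorbed_at_y >= ymin & absorbed_at_y <= ymax &
      absorbed_at_x >= x[1] - dx / 2 & absorbed_at_x <= x[length(x)] + dx / 2
  } else {
    ok <- ok & absorbed_at_x >= x[1] - dx / 2 & absorbed_at_x <= x[length(x)] + dx / 2
  }
  eJ <- w * e_photon
  emitted <- sum(eJ)
  absorbed <- sum(eJ[ok])
  if (any(ok)) {
    ixa <- pmin(pmax(round((absorbed_at_x[ok] - x[1]) / dx) + 1L, 1L), length(x))
    if (two_d) {
      iya <- pmin(pmax(round((absorbed_at_y[ok] - dose$y[1]) / dy) + 1L, 1L),
                  length(dose$y))
      lin <- ixa + (iya - 1L) * length(x)
      dep <- matrix(0, length(x), length(dose$y))
      agg <- rowsum(eJ[ok], lin)
      dep[as.integer(rownames(agg))] <- agg[, 1]
      out$values <- dep / (rho * vol)
    } else {
      dep <- numeric(length(x))
      agg <- rowsum(eJ[ok], ixa)
      dep[as.integer(rownames(agg))] <- agg[, 1]
      out$values <- dep / (rho * vol)
    }
  }
  out$emitted_J <- emitted
  out$absorbed_J <- absorbed
  out$escaped_J <- sum(eJ[!ok])
  out$mean_wavelength_nm <- mean(lambda)
  out
}
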