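# Synthetic data: PET tumor phantoms with known hotspot geometry, and
# simulated patient cohorts with the statistical structure the recurrence
# analysis assumes.
#
# The phantom is a deliberate idealization of a resected-lung-lesion PET
# image: an ellipsoidal lesion whose uptake is a smooth unimodal field
# peaking at a planted hotspot, never falling below half the peak inside
# the lesion (so the whole planted shape survives the 40%-of-SUVmax
# threshold and segmented geometry equals planted geometry up to blur),
# on a low constant background, convolved with a Gaussian point-spread
# function and degraded with additive Gaussian noise clipped at zero.

#' Generate a synthetic PET tumor phantom with known geometry
#'
#' Builds an ellipsoidal lesion centered in the grid with a hotspot planted
#' at a controllable normalized offset from the centroid along
#' `offset_direction`. Ground-truth NHOC/NHOP are computed from the
#' continuum shape: for a sphere, `true_nhoc = offset` and
#' `true_nhop = 1 - offset` analytically; for an ellipsoid the distance to
#' the surface is found by 1D root finding on the Lagrange condition.
#' Deterministic given `seed`.
#'
#' @param radii_mm lesion semi-axes in mm; a scalar gives a sphere.
#'   Default 21 (a sphere comfortably resolved at 3 mm voxels).
#' @param hotspot_offset_frac normalized hotspot offset in `[0, 1)`: the
#'   planted hotspot sits at this fraction of the center-to-surface ray.
#' @param spacing_mm isotropic grid spacing, mm (default 3, the clinical
#'   reconstruction grid).
#' @param psf_fwhm_mm Gaussian point-spread FWHM, mm (default 4, mild
#'   post-reconstruction blur).
#' @param noise_sd_suv additive Gaussian noise SD in SUV units
#'   (default 0.05).
#' @param peak_suv lesion SUV at the hotspot (default 10, a typical avid
#'   lung adenocarcinoma).
#' @param background_suv background SUV (default 1; must stay below 40% of
#'   `peak_suv` so the lesion is separable at the default threshold).
#' @param offset_direction unit-intent direction of the planted offset
#'   (normalized internally); default along the first axis.
#' @param margin_vox background margin around the lesion, voxels.
#' @param plateau_frac uptake at the lesion edge as a fraction of peak, in
#'   `[0.5, 1)`; default 0.80 so the blurred 40%-of-SUVmax contour sits at
#'   the planted surface rather than eroding into it.
#' @param seed integer RNG seed for the noise.
#' @return List with `volume` (a [pet_volume()]) and `truth` (generator
#'   parameters plus `true_nhoc`, `true_nhop`, `hotspot_mm`, `center_mm`).
#' @export
make_phantom <- function(radii_mm = 21, hotspot_offset_frac = 0,
                         spacing_mm = 3, psf_fwhm_mm = 4,
                         noise_sd_suv = 0.05, peak_suv = 10,
                         background_suv = 1,
                         offset_direction = c(1, 0, 0),
                         margin_vox = 5L, plateau_frac = 0.80, seed = 1L) {
  if (length(radii_mm) == 1L) radii_mm <- rep(radii_mm, 3L)
  radii_mm <- as.numeric(radii_mm)
  if (length(radii_mm) != 3L || any(radii_mm <= 0))
    stop_invalid("'radii_mm' must be a positive triple (or scalar)")
  if (any(radii_mm < 4 * spacing_mm))
    stop_invalid("each radius must be >= 4x the grid spacing for a resolvable lesion")
  if (!is.finite(hotspot_offset_frac) || hotspot_offset_frac < 0 ||
      hotspot_offset_frac >= 1)
    stop_invalid("'hotspot_offset_frac' must lie in [0, 1)")
  if (background_suv < 0 || peak_suv <= 0 ||
      background_suv >= 0.4 * peak_suv)
    stop_invalid("'background_suv' must be in [0, 0.4*peak_suv) for separability")
  if (psf_fwhm_mm < 0 || noise_sd_suv < 0)
    stop_invalid("'psf_fwhm_mm' and 'noise_sd_suv' must be >= 0")
  u <- as.numeric(offset_direction)
  if (length(u) != 3L || sum(u^2) == 0)
    stop_invalid("'offset_direction' must be a nonzero triple")
  u <- u / sqrt(sum(u^2))

  n <- ceiling(2 * radii_mm / spacing_mm) + 2L * as.integer(margin_vox) + 1L
  center_mm <- (n - 1) / 2 * spacing_mm
  # center-to-surface ray length along u, and the planted hotspot point
  ray <- 1 / sqrt(sum((u / radii_mm)^2))
  hotspot_mm <- center_mm + hotspot_offset_frac * ray * u

  ax <- lapply(1:3, function(a) (seq_len(n[a]) - 1) * spacing_mm)
  e2 <- outer(outer((ax[[1]] - center_mm[1])^2 / radii_mm[1]^2,
                    (ax[[2]] - center_mm[2])^2 / radii_mm[2]^2, `+`),
              (ax[[3]] - center_mm[3])^2 / radii_mm[3]^2, `+`)
  inside <- e2 <= 1

  # squared distance from each voxel center to the hotspot point
  d2 <- outer(outer((ax[[1]] - hotspot_mm[1])^2,
                    (ax[[2]] - hotspot_mm[2])^2, `+`),
              (ax[[3]] - hotspot_mm[3])^2, `+`)
  # Unimodal interior profile: a steep Gaussian peak at the hotspot on top
  # of a high plateau. The short decay length (6 mm half-width) keeps the
  # SUVmax voxel pinned at the planted hotspot under noise; the plateau
  # keeps the lesion edge far enough above 40% of peak that the blurred
  # iso-contour sits at (marginally outside) the planted surface instead
  # of ~half the PSF width inside it (a profile decaying to the minimal
  # 0.5 floor erodes the segmented shape under blur).
  if (plateau_frac < 0.5 || plateau_frac >= 1)
    stop_invalid("'plateau_frac' must lie in [0.5, 1)")
  r_peak <- 4.5                                # mm, half-decay of the peak
  g <- plateau_frac + (1 - plateau_frac) * exp(-log(2) * d2 / r_peak^2)
  vol <- array(background_suv, n)
  vol[inside] <- background_suv + (peak_suv - background_suv) * g[inside]

  if (psf_fwhm_mm > 0) {
    sigma_vox <- rep(psf_fwhm_mm / (2 * sqrt(2 * log(2))) / spacing_mm, 3L)
    vol <- gaussian_blur3(vol, sigma_vox)
  }
  if (noise_sd_suv > 0) {
    noise <- with_local_seed(seed, array(stats::rnorm(prod(n), 0, noise_sd_suv), n))
    vol <- vol + noise
  }
  vol <- pmax(vol, 0)

  r_equiv <- prod(radii_mm)^(1 / 3)        # (3V/4pi)^(1/3) for an ellipsoid
  p_rel <- hotspot_mm - center_mm
  true_nhoc <- sqrt(sum(p_rel^2)) / r_equiv
  true_nhop <- distance_to_ellipsoid_surface(p_rel, radii_mm) / r_equiv

  truth <- list(shape_kind = if (length(unique(radii_mm)) == 1L) "sphere" else "ellipsoid",
                radii_mm = radii_mm, hotspot_offset_frac = hotspot_offset_frac,
                spacing_mm = spacing_mm, psf_fwhm_mm = psf_fwhm_mm,
                noise_sd_suv = noise_sd_suv, peak_suv = peak_suv,
                background_suv = background_suv, seed = as.integer(seed),
                offset_direction = u, center_mm = center_mm,
                hotspot_mm = hotspot_mm,
                true_nhoc = true_nhoc, true_nhop = true_nhop)
  list(volume = pet_volume(vol, spacing_mm), truth = truth)
}

#' Distance from an interior point to an ellipsoid surface
#'
#' Minimum Euclidean distance from point `p` (relative to the ellipsoid
#' center) to the surface x^2/a^2 + y^2/b^2 + z^2/c^2 = 1. Solves the
#' Lagrange stationarity condition by 1D root finding; degenerate axes
#' (zero components of `p`) contribute additional critical-point
#' candidates which are also examined.
#'
#' @param p numeric triple, the interior point (center-relative), mm.
#' @param radii numeric triple of semi-axes, mm.
#' @return Distance in mm.
#' @export
distance_to_ellipsoid_surface <- function(p, radii) {
  p <- as.numeric(p); a <- as.numeric(radii)
  if (sum((p / a)^2) > 1 + 1e-9) stop_invalid("point must lie inside the ellipsoid")
  cand <- numeric(0)
  nz <- abs(p) > 1e-12
  if (any(nz)) {
    # constraint sum_i x_i^2/a_i^2 = 1 with x_i = a_i^2 p_i/(a_i^2 + t):
    # f(t) = sum_i (a_i p_i / (a_i^2 + t))^2 - 1, root on (t_lo, 0]
    f <- function(t) sum((a[nz] * p[nz] / (a[nz]^2 + t))^2) - 1
    t_lo <- -min(a[nz]^2)
    lo <- t_lo + 1e-10 * max(a^2)
    while (f(lo) < 0) lo <- t_lo + (lo - t_lo) / 10   # approach singularity
    root <- stats::uniroot(f, c(lo, 0), tol = 1e-12)$root
    x <- ifelse(nz, a^2 * p / (a^2 + root), 0)
    cand <- c(cand, sqrt(sum((x - p)^2)))
  }
  for (j in which(!nz)) {
    # critical points with x_j != 0 on a degenerate axis: t = -a_j^2
    s <- sum((a[nz] * p[nz] / (a[nz]^2 - a[j]^2))^2)
    if (is.finite(s) && s <= 1) {
      x <- ifelse(nz, a^2 * p / (a^2 - a[j]^2), 0)
      x[j] <- a[j] * sqrt(1 - s)
      cand <- c(cand, sqrt(sum((x - p)^2)))
    }
  }
  if (!length(cand)) min(a)   # p at the exact center
  else min(cand)
}

#' Simulate a patient cohort with NHOP-dependent recurrence and survival
#'
#' Draws per-patient metric vectors (NHOPmax, NHOCmax, SUVmax, MTV, TLG)
#' from marginals matching a typical resected lung adenocarcinoma cohort
#' (normal for the normalized distances, truncated to their range;
#' log-normal for SUVmax and MTV; TLG proportional to MTV x SUVmax with
#' multiplicative noise), coupled by a Gaussian copula with a single weak
#' exchangeable correlation. Recurrence follows a logistic model in NHOP
#' (protective, odds ratio < 1) and SUVmax; disease-free survival is
#' exponential among recurrent patients with the hazard scaled by
#' `hr_nhop^z` where z is standardized NHOP, administratively censored at
#' `censor_months`. Events occur only in recurrent patients. Deterministic
#' given `seed`.
#'
#' Alternative `design = "binormal"` draws recurrence first (rate
#' `p_event`) and replaces NHOP by an untruncated normal score, shifted
#' down by `delta` standard deviations in the cases: the classical
#' binormal ROC design with analytic AUC = pnorm(delta / sqrt(2)).
#'
#' @param n number of patients (>= 10).
#' @param effect list with `intercept`, `beta_nhop`, `beta_suv` (log-odds
#'   scale). Defaults give ~20% recurrence with a strongly protective NHOP.
#' @param survival_model list with `baseline_hazard` (events/month among
#'   recurrent patients, > 0) and `hr_nhop` (hazard ratio per SD of NHOP).
#' @param censor_months administrative censoring horizon (default 96, the
#'   longest plausible follow-up).
#' @param rho exchangeable copula correlation between metrics (default 0.1).
#' @param design `"logistic"` (default) or `"binormal"`.
#' @param delta binormal group separation in SD units (design = "binormal").
#' @param p_event marginal event rate for the binormal design.
#' @param seed integer RNG seed.
#' @return A `data.frame` (`CohortTable`): `patient_id`, `nhop_max`,
#'   `nhoc_max`, `suv_max`, `mtv_ml`, `tlg`, `recurrence`, `dfs_months`,
#'   `event`.
#' @export
simulate_cohort <- function(n,
                            effect = list(intercept = -0.85,
                                          beta_nhop = log(0.033),
                                          beta_suv = log(1.1)),
                            survival_model = list(baseline_hazard = 0.03,
                                                  hr_nhop = 0.4),
                            censor_months = 96, rho = 0.1,
                            design = c("logistic", "binormal"),
                            delta = 0.669, p_event = 0.2,
                            seed = 1L) {
  design <- match.arg(design)
  if (n < 10) stop_invalid("'n' must be >= 10")
  eff <- unlist(effect)
  if (!all(is.finite(eff))) stop_invalid("effect parameters must be finite")
  if (!is.finite(survival_model$baseline_hazard) ||
      survival_model$baseline_hazard <= 0)
    stop_invalid("'baseline_hazard' must be > 0")
  if (rho < 0 || rho >= 1) stop_invalid("'rho' must lie in [0, 1)")

  with_local_seed(seed, {
    # Gaussian copula with exchangeable correlation rho across 4 latent axes
    z_common <- stats::rnorm(n)
    z <- sqrt(rho) * matrix(z_common, n, 4) +
      sqrt(1 - rho) * matrix(stats::rnorm(4L * n), n, 4)

    # marginals: NHOP 0.34 +/- 0.23 and NHOC 0.55 +/- 0.28 (truncated),
    # SUVmax ~ lognormal(mean 6.54, sd 4.62), MTV ~ lognormal(5.43, 10.61)
    nhop <- pmin(pmax(0.34 + 0.23 * z[, 1], 0.01), 0.99)
    nhoc <- pmin(pmax(0.55 + 0.28 * z[, 2], 0.01), 1.50)
    suv <- lognormal_from_moments(z[, 3], 6.54, 4.62)
    mtv <- lognormal_from_moments(z[, 4], 5.43, 10.61)
    tlg <- mtv * 0.72 * suv * exp(stats::rnorm(n, 0, 0.2))

    if (design == "binormal") {
      # genuinely binormal: untruncated normal marginal, cases shifted down
      # by delta SDs, so AUC = pnorm(delta / sqrt(2)) holds exactly
      recurrence <- stats::rbinom(n, 1, p_event)
      nhop <- 0.34 + 0.23 * z[, 1] - delta * 0.23 * recurrence
    } else {
      lp <- eff[["intercept"]] + eff[["beta_nhop"]] * nhop +
        eff[["beta_suv"]] * suv
      recurrence <- stats::rbinom(n, 1, stats::plogis(lp))
    }

    z_nhop <- (nhop - mean(nhop)) / stats::sd(nhop)
    rate <- survival_model$baseline_hazard * survival_model$hr_nhop^z_nhop
    t_event <- stats::rexp(n, rate)
    t_event[recurrence == 0] <- Inf
    dfs <- pmin(t_event, censor_months)
    event <- as.integer(t_event <= censor_months)
    dfs <- pmax(dfs, 1e-6)

    data.frame(patient_id = seq_len(n),
               nhop_max = nhop, nhoc_max = nhoc, suv_max = suv,
               mtv_ml = mtv, tlg = tlg,
               recurrence = as.integer(recurrence),
               dfs_months = dfs, event = event)
  })
}

# latent standard normal -> lognormal with the requested mean and sd
lognormal_from_moments <- function(z, m, s) {
  sdlog2 <- log(1 + (s / m)^2)
  exp(log(m) - sdlog2 / 2 + sqrt(sdlog2) * z)
}
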