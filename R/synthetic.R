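# Truncated-normal draws by inverse-CDF; sd = 0 degenerates to the mean.
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Simulation configuration
#'
#' Builds the parameter set for the synthetic eye/cohort generator. The
#' defaults describe a university cohort of young adult myopic eyes:
#' biometry means/SDs, sector vessel-density means/SDs per layer, disc
#' geometry distributions, and the planted association models (a logistic
#' model for disc tilt on nasal/temporal superficial density and relative
#' lens position, expressed as odds ratios per unit; and a linear model for
#' rotation degree on deep-density sectors, sex, axial length and IOP).
#' The planted linear model's residual SD is derived from the target R^2
#' and the planted coefficients' explained variance unless overridden.
#'
#' @param n_eyes number of eyes to simulate.
#' @param seed integer seed; all generator randomness derives from it.
#' @param ... replacements for any top-level config element (`biometry`,
#'   `densities`, `geometry`, `planted_logistic`, `planted_linear`, `map`,
#'   `female_p`, `right_eye_p`).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_eyes = 871, seed = 1, ...) {
  cfg <- list(
    n_eyes = as.integer(n_eyes),
    seed = as.integer(seed),
    female_p = 0.646,
    right_eye_p = 0.538,
    biometry = list(
      age = c(mean = 18.26, sd = 0.63, lo = 17, hi = 20),
      AL  = c(mean = 25.16, sd = 1.10, lo = 21.0, hi = 28.5),
      CCT = c(mean = 539.92, sd = 33.54, lo = 420, hi = 660),
      ACD = c(mean = 3.68, sd = 0.26, lo = 2.6, hi = 4.6),
      LT  = c(mean = 3.46, sd = 0.18, lo = 2.8, hi = 4.2),
      SE  = c(mean = -4.22, sd = 2.42, lo = -12, hi = 1),
      IOP = c(mean = 15.52, sd = 1.79, lo = 8, hi = 21),
      SBP = c(mean = 118, sd = 9, lo = 91, hi = 150),
      DBP = c(mean = 70, sd = 7, lo = 50, hi = 89)
    ),
    densities = list(
      S_DVD = c(mean = 27.65, sd = 8.09), N_DVD = c(mean = 31.93, sd = 7.47),
      T_DVD = c(mean = 40.06, sd = 5.90), I_DVD = c(mean = 29.69, sd = 7.46),
      S_SVD = c(mean = 46.06, sd = 5.68), N_SVD = c(mean = 45.58, sd = 3.76),
      T_SVD = c(mean = 45.02, sd = 3.95), I_SVD = c(mean = 45.92, sd = 4.91),
      S_RPC = c(mean = 48.82, sd = 4.46), N_RPC = c(mean = 45.95, sd = 2.96),
      T_RPC = c(mean = 46.90, sd = 3.57), I_RPC = c(mean = 48.40, sd = 3.91)
    ),
    geometry = list(
      tilt = c(mean = 0.80, sd = 0.08),
      rotation = c(mean = -5.48, sd = 20.06),
      tilt_given_tilted = c(mean = 0.74, sd = 0.05, lo = 0.30, hi = 0.80),
      tilt_given_non = c(mean = 0.87, sd = 0.04, lo = 0.801, hi = 1.00),
      long_mm = 1.8, n_points = 360, radial_noise_sd = 0,
      fovea_dist_mm = 4.7, fovea_drop_mm = 0.3
    ),
    planted_logistic = list(
      or = c(N_SVD = 0.90, T_SVD = 1.08, RLP = 0.13),
      prevalence = 0.505
    ),
    planted_linear = list(
      B = c(S_DVD = -0.70, T_DVD = 0.41, I_DVD = 0.70, sex_male = -5.46,
            AL = 2.46, IOP = 1.22),
      r2 = 0.121, mean = -5.48, resid_sd = NULL
    ),
    map = list(shape = c(232L, 232L), mm_per_px = 6 / 232)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config element: ", nm)
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else cfg[[nm]] <- over[[nm]]
  }
  stopifnot(cfg$n_eyes >= 2)
  for (v in cfg$biometry) if (v[["sd"]] < 0) stop("biometry SDs must be >= 0")
  for (v in cfg$densities) if (v[["sd"]] < 0) stop("density SDs must be >= 0")
  if (any(cfg$planted_logistic$or <= 0)) stop("planted ORs must be positive")
  class(cfg) <- "simulation_config"
  cfg
}

#' Sample synthetic biometry
#'
#' Independent truncated-normal draws per biometric variable (the joint
#' covariance of real biometry is not modeled), Bernoulli sex and eye
#' laterality. Deterministic under the config seed.
#'
#' @param config a [simulation_config].
#' @return data.frame, one row per eye, with `subject_id`, `eye`, `sex` and
#'   the biometry columns.
#' @export
sample_biometry <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_eyes
  out <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    eye = ifelse(stats::runif(n) < config$right_eye_p, "OD", "OS"),
    sex = ifelse(stats::runif(n) < config$female_p, "female", "male"),
    stringsAsFactors = FALSE
  )
  for (nm in names(config$biometry)) {
    p <- config$biometry[[nm]]
    out[[nm]] <- rtrunc_norm(n, p[["mean"]], p[["sd"]], p[["lo"]], p[["hi"]])
  }
  # keep ACD + LT < AL (truncation ranges almost guarantee it; nudge rare
  # violators by shrinking the lens position terms)
  bad <- out$ACD + out$LT >= out$AL
  if (any(bad)) {
    k <- 0.95 * out$AL[bad] / (out$ACD[bad] + out$LT[bad])
    out$ACD[bad] <- out$ACD[bad] * k
    out$LT[bad] <- out$LT[bad] * k
  }
  out
}

#' Synthesize a disc contour with known tilt ratio and rotation
#'
#' Builds an elliptical contour whose semi-axis ratio equals `tilt_ratio`
#' and whose long axis is oriented so that [rotation_degree()] against the
#' given fovea recovers `rotation_deg` (inverse of the morphometry). With
#' `tilt_ratio = 1` the contour is a circle and the recovered axis is
#' flagged degenerate.
#'
#' @param tilt_ratio semi-minor/semi-major ratio in (0, 1].
#' @param rotation_deg planted signed rotation, degrees in \[-90, 90\].
#' @param center disc center c(x, y), mm.
#' @param fovea fovea c(x, y) or [fovea_location], mm.
#' @param n_points vertices on the contour.
#' @param radial_noise_sd fractional SD of multiplicative radial Gaussian
#'   noise (0 = exact ellipse).
#' @param seed optional seed for the noise.
#' @param long_mm longest diameter of the disc, mm.
#' @param laterality `"OD"` or `"OS"`.
#' @param source_id identifier.
#' @return a [disc_contour].
#' @export
synth_contour <- function(tilt_ratio, rotation_deg, center = c(0, 0),
                          fovea = c(-4.7, -0.3), n_points = 360,
                          radial_noise_sd = 0, seed = NULL, long_mm = 1.8,
                          laterality = "OD", source_id = "synthetic") {
  if (!is.finite(tilt_ratio) || tilt_ratio <= 0 || tilt_ratio > 1)
    stop("tilt_ratio must lie in (0, 1]")
  if (!is.finite(rotation_deg) || abs(rotation_deg) > 90)
    stop("rotation_deg must lie in [-90, 90]")
  if (inherits(fovea, "fovea_location")) fovea <- unname(fovea$point)
  h <- fovea - center
  hn <- sqrt(sum(h^2))
  if (hn == 0) stop("fovea coincides with disc center")
  h <- h / hn
  r <- c(h[2], -h[1])   # same fovea-anchored reference as rotation_degree
  a <- rotation_deg * pi / 180
  d <- cos(a) * r + sin(a) * h          # long-axis direction
  dp <- c(-d[2], d[1])
  A <- long_mm / 2
  B <- A * tilt_ratio
  th <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  xy <- outer(A * cos(th), d) + outer(B * sin(th), dp)
  if (radial_noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    xy <- xy * (1 + stats::rnorm(n_points, 0, radial_noise_sd))
  }
  xy <- sweep(xy, 2, center, `+`)
  disc_contour(xy, laterality = laterality, source_id = source_id,
               check_simple = FALSE)
}

#' Synthesize a vessel map with planted sector densities
#'
#' Builds a binary en-face map whose annulus quadrant densities equal the
#' requested targets to within half a pixel: the exact on-pixel count per
#' sector is planted at uniformly random positions within the sector.
#'
#' @param sector_targets named numeric, percent, with names `superior`,
#'   `inferior`, `nasal`, `temporal` (or `S`, `I`, `N`, `T`).
#' @param shape grid dimensions c(nrow, ncol).
#' @param mm_per_px pixel pitch, mm.
#' @param laterality `"OD"` or `"OS"`.
#' @param layer retinal layer label.
#' @param seed optional seed for pixel placement.
#' @param source_id identifier.
#' @return a [vessel_map].
#' @export
synth_vessel_map <- function(sector_targets, shape = c(232L, 232L),
                             mm_per_px = 6 / 232,
                             laterality = c("OD", "OS"),
                             layer = c("RPC", "SVD", "DVD"), seed = NULL,
                             source_id = "synthetic") {
  laterality <- match.arg(laterality)
  layer <- match.arg(layer)
  nm <- names(sector_targets)
  if (!is.null(nm) && all(c("S", "I", "N", "T") %in% nm))
    names(sector_targets) <- c(S = "superior", I = "inferior", N = "nasal",
                               T = "temporal")[nm]
  if (is.null(names(sector_targets)) && length(sector_targets) == 4L)
    names(sector_targets) <- c("superior", "inferior", "nasal", "temporal")
  if (any(sector_targets < 0 | sector_targets > 100))
    stop("sector targets must lie in [0, 100]")
  if (!is.null(seed)) set.seed(seed)
  center <- (shape + 1) / 2
  qs <- quadrant_masks(shape, center, mm_per_px, laterality)
  grid <- matrix(0, shape[1], shape[2])
  for (sec in names(qs)) {
    idx <- which(qs[[sec]])
    k <- round(sector_targets[[sec]] / 100 * length(idx))
    if (k > length(idx)) stop("target exceeds sector pixel count")
    if (k > 0) grid[sample(idx, k)] <- 1
  }
  vessel_map(grid, mm_per_px, center, layer = layer,
             laterality = laterality, source_id = source_id)
}

#' Generate a synthetic cohort with planted associations
#'
#' Draws biometry and per-layer sector densities, assigns tilt status from
#' the planted logistic model (on nasal/temporal superficial density and
#' relative lens position) and rotation degree from the planted linear
#' model (on deep-density sectors, sex, axial length and IOP) plus Gaussian
#' residual, then draws each disc's tilt ratio consistently with its class
#' (<= 0.80 iff tilted). Optionally emits per-eye contours and vessel maps
#' consistent with the assigned morphometry and densities.
#'
#' @param config a [simulation_config].
#' @param geometry `"none"` (cohort table only), `"contours"` (adds a list
#'   of per-eye contours + foveas), or `"full"` (also per-eye RPC/SVD/DVD
#'   vessel maps; memory-heavy, intended for small `n_eyes`).
#' @return list with `cohort` (data.frame, one row per eye, including
#'   derived indices, classes and densities), `truth` (planted per-eye
#'   parameters and model coefficients, plus the seed), and — depending on
#'   `geometry` — `contours` (list of `list(contour, fovea)`) and `maps`
#'   (list of per-eye lists of [vessel_map]s).
#' @export
generate_cohort <- function(config = simulation_config(),
                            geometry = c("none", "contours", "full")) {
  stopifnot(inherits(config, "simulation_config"))
  geometry <- match.arg(geometry)
  bio <- sample_biometry(config)   # seeds the RNG stream
  n <- config$n_eyes

  dens <- lapply(config$densities, function(p)
    rtrunc_norm(n, p[["mean"]], p[["sd"]], 0, 100))
  cohort <- cbind(bio, as.data.frame(dens))
  cohort <- derive_ocular(cohort)

  # planted logistic model for tilt: linear predictor in log-odds
  pl <- config$planted_logistic
  beta <- log(pl$or)
  mu <- c(N_SVD = config$densities$N_SVD[["mean"]],
          T_SVD = config$densities$T_SVD[["mean"]],
          RLP = relative_lens_position(config$biometry$ACD[["mean"]],
                                       config$biometry$LT[["mean"]],
                                       config$biometry$AL[["mean"]]))
  b0 <- stats::qlogis(pl$prevalence) - sum(beta * mu[names(beta)])
  X <- as.matrix(cohort[, names(beta)])
  eta <- b0 + drop(X %*% beta)
  tilted <- stats::rbinom(n, 1, stats::plogis(eta)) == 1

  g <- config$geometry
  tr <- numeric(n)
  pt <- g$tilt_given_tilted; pn <- g$tilt_given_non
  tr[tilted] <- rtrunc_norm(sum(tilted), pt[["mean"]], pt[["sd"]],
                            pt[["lo"]], pt[["hi"]])
  tr[!tilted] <- rtrunc_norm(sum(!tilted), pn[["mean"]], pn[["sd"]],
                             pn[["lo"]], pn[["hi"]])

  # planted linear model for rotation degree
  ln <- config$planted_linear
  B <- ln$B
  Xl <- cbind(as.matrix(cohort[, setdiff(names(B), "sex_male")]),
              sex_male = as.numeric(cohort$sex == "male"))[, names(B)]
  sds <- c(S_DVD = config$densities$S_DVD[["sd"]],
           T_DVD = config$densities$T_DVD[["sd"]],
           I_DVD = config$densities$I_DVD[["sd"]],
           sex_male = sqrt(config$female_p * (1 - config$female_p)),
           AL = config$biometry$AL[["sd"]],
           IOP = config$biometry$IOP[["sd"]])
  explained <- sum((B * sds[names(B)])^2)
  resid_sd <- ln$resid_sd
  if (is.null(resid_sd)) {
    resid_sd <- if (explained > 0 && ln$r2 > 0 && ln$r2 < 1)
      sqrt(explained * (1 - ln$r2) / ln$r2) else g$rotation[["sd"]]
  }
  mul <- c(S_DVD = config$densities$S_DVD[["mean"]],
           T_DVD = config$densities$T_DVD[["mean"]],
           I_DVD = config$densities$I_DVD[["mean"]],
           sex_male = 1 - config$female_p,
           AL = config$biometry$AL[["mean"]],
           IOP = config$biometry$IOP[["mean"]])
  a0 <- ln$mean - sum(B * mul[names(B)])
  rot <- a0 + drop(Xl %*% B) + stats::rnorm(n, 0, resid_sd)
  rot <- pmin(pmax(rot, -89.99), 89.99)   # disc axis angle is acute

  cohort$tilt_ratio <- tr
  cohort$rotation_deg <- rot
  cohort$tilt_class <- classify_tilt(tr)
  cohort$rotation_class <- classify_rotation(rot)

  truth <- list(
    seed = config$seed,
    tilt_ratio = tr, rotation_deg = rot, tilted = tilted,
    logistic = list(intercept = b0, beta = beta, or = pl$or),
    linear = list(intercept = a0, B = B, resid_sd = resid_sd, r2 = ln$r2),
    densities = as.data.frame(dens)
  )
  out <- list(cohort = cohort, truth = truth)

  if (geometry != "none") {
    out$contours <- lapply(seq_len(n), function(i) {
      temporal_sign <- if (cohort$eye[i] == "OD") -1 else 1
      fov <- c(temporal_sign * g$fovea_dist_mm, -g$fovea_drop_mm)
      ctr <- synth_contour(tr[i], rot[i], center = c(0, 0), fovea = fov,
                           n_points = g$n_points,
                           radial_noise_sd = g$radial_noise_sd,
                           long_mm = g$long_mm,
                           laterality = cohort$eye[i],
                           source_id = sprintf("%s_%s", cohort$subject_id[i],
                                               cohort$eye[i]))
      list(contour = ctr, fovea = fovea_location(fov))
    })
  }
  if (geometry == "full") {
    out$maps <- lapply(seq_len(n), function(i) {
      lapply(c(RPC = "RPC", SVD = "SVD", DVD = "DVD"), function(ly) {
        tg <- c(S = cohort[[paste0("S_", ly)]][i],
                I = cohort[[paste0("I_", ly)]][i],
                N = cohort[[paste0("N_", ly)]][i],
                T = cohort[[paste0("T_", ly)]][i])
        synth_vessel_map(tg, shape = config$map$shape,
                         mm_per_px = config$map$mm_per_px,
                         laterality = cohort$eye[i], layer = ly,
                         source_id = sprintf("%s_%s_%s", cohort$subject_id[i],
                                             cohort$eye[i], ly))
      })
    })
  }
  out
}
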