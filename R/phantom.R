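# Synthetic sinus CT phantom: a bone-density block containing air-filled
# cavities partially filled, from below upward, with soft-tissue-density
# material at a known fill fraction. Ground truth (labels, counts, masks)
# is exact by construction, so every downstream stage is testable without
# patient data.

#' Default per-class HU noise model
#'
#' Gaussian HU per tissue class, clipped to the class band so that the
#' noise can never move a voxel across a classification boundary (ground
#' truth stays exact): air N(-1000, 30) clipped to \[-2000, -250\], soft
#' tissue N(+40, 50) clipped to \[-249, +250\], bone N(+700, 100) clipped
#' to \[+251, +2000\].
#'
#' @param air,soft,bone length-2 numerics `c(mean, sd)`.
#' @return a named list with per-class `mean`, `sd` and `clip` range.
#' @export
hu_model <- function(air = c(-1000, 30), soft = c(40, 50),
                     bone = c(700, 100)) {
  m <- list(air = list(mean = air[1], sd = air[2], clip = c(-2000, -250)),
            soft = list(mean = soft[1], sd = soft[2], clip = c(-249, 250)),
            bone = list(mean = bone[1], sd = bone[2], clip = c(251, 2000)))
  if (!(m$air$mean >= -2000 && m$air$mean <= -250))
    stop("air HU mean must lie in [-2000, -250]")
  if (!(m$soft$mean > -250 && m$soft$mean <= 250))
    stop("soft-tissue HU mean must lie in (-250, +250]")
  if (!(m$bone$mean > 250 && m$bone$mean <= 2000))
    stop("bone HU mean must lie in (+250, +2000]")
  if (any(vapply(m, function(x) x$sd < 0, logical(1))))
    stop("HU standard deviations must be non-negative")
  structure(m, class = "hu_model")
}

# default cavity geometry in fractions of the grid physical extent:
# 5 sinus pairs (ellipsoids) + 2 ostiomeatal channels (cuboids), a
# desk-scale caricature of sinonasal anatomy (x: left-right, y:
# anterior-posterior, z: inferior-superior)
default_cavity_geometry <- function() {
  g <- rbind(
    data.frame(name = "maxillary", side = c("left", "right"),
               cx = c(.28, .72), cy = .38, cz = .32,
               ax = .12, ay = .15, az = .17, shape = "ellipsoid",
               type = "sinus"),
    data.frame(name = "frontal", side = c("left", "right"),
               cx = c(.34, .66), cy = .25, cz = .80,
               ax = .09, ay = .09, az = .10, shape = "ellipsoid",
               type = "sinus"),
    data.frame(name = "anterior_ethmoid", side = c("left", "right"),
               cx = c(.42, .58), cy = .34, cz = .58,
               ax = .055, ay = .08, az = .09, shape = "ellipsoid",
               type = "sinus"),
    data.frame(name = "posterior_ethmoid", side = c("left", "right"),
               cx = c(.42, .58), cy = .56, cz = .58,
               ax = .055, ay = .09, az = .09, shape = "ellipsoid",
               type = "sinus"),
    data.frame(name = "sphenoid", side = c("left", "right"),
               cx = c(.41, .59), cy = .76, cz = .46,
               ax = .075, ay = .10, az = .09, shape = "ellipsoid",
               type = "sinus"),
    data.frame(name = "omc", side = c("left", "right"),
               cx = c(.305, .695), cy = .38, cz = .56,
               ax = .02, ay = .04, az = .06, shape = "cuboid",
               type = "omc")
  )
  g
}

#' Specification of a synthetic sinus phantom
#'
#' Defines the voxel grid, the cavities (centres and semi-axes in mm, one
#' fill fraction each), the two ostiomeatal channels, the per-class HU
#' noise model and the RNG seed. The default geometry is a 128^3 grid at
#' 0.5 mm isotropic spacing holding 10 ellipsoidal cavities (5 sinus
#' pairs) and 2 cuboid OMC channels.
#'
#' @param fill fill fraction(s) in `[0, 1]`: scalar applied to every
#'   cavity, or one value per cavity row.
#' @param grid_dim voxels per axis (length 3 or scalar).
#' @param spacing voxel edge length, mm (length 3 or scalar).
#' @param hu HU noise model from [hu_model()].
#' @param seed integer RNG seed.
#' @param cavities optional cavity table in physical mm with columns
#'   `name, side, cx, cy, cz, ax, ay, az, shape, type, fill`; when `NULL`
#'   the default geometry is scaled to the grid extent.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(fill = 0.5, grid_dim = c(128, 128, 128),
                         spacing = c(0.5, 0.5, 0.5), hu = hu_model(),
                         seed = 1L, cavities = NULL) {
  grid_dim <- as.integer(rep(grid_dim, length.out = 3))
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(grid_dim < 4) || any(spacing <= 0))
    stop("grid_dim must be >= 4 voxels and spacing positive")
  if (!inherits(hu, "hu_model")) stop("'hu' must come from hu_model()")
  L <- grid_dim * spacing
  if (is.null(cavities)) {
    g <- default_cavity_geometry()
    cavities <- data.frame(
      name = g$name, side = g$side,
      cx = g$cx * L[1], cy = g$cy * L[2], cz = g$cz * L[3],
      ax = g$ax * L[1], ay = g$ay * L[2], az = g$az * L[3],
      shape = g$shape, type = g$type,
      stringsAsFactors = FALSE)
  }
  fill <- rep(as.numeric(fill), length.out = nrow(cavities))
  if (any(!is.finite(fill)) || any(fill < 0) || any(fill > 1))
    stop("fill fractions must lie in [0, 1]")
  cavities$fill <- fill
  # cavities must lie fully inside the grid physical extent [0, L]
  lo <- cbind(cavities$cx - cavities$ax, cavities$cy - cavities$ay,
              cavities$cz - cavities$az)
  hi <- cbind(cavities$cx + cavities$ax, cavities$cy + cavities$ay,
              cavities$cz + cavities$az)
  if (any(lo < 0) || any(sweep(hi, 2, L) > 1e-9))
    stop("cavities must lie fully inside the grid")
  structure(list(grid_dim = grid_dim, spacing = spacing, hu = hu,
                 seed = as.integer(seed), cavities = cavities),
            class = "phantom_spec")
}

# run code with a locally seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic sinus phantom with exact ground truth
#'
#' Rasterizes each cavity onto the grid (voxel-centre inclusion), fills it
#' with soft-tissue material from its lowest z extent upward (gravity-like,
#' contiguous fill) until the realized fill fraction is the closest
#' achievable to nominal, leaves the remainder air, and embeds everything
#' in bone. HU values are drawn per voxel from the class's Gaussian and
#' clipped to the class band, so the noise-free labels are recovered
#' exactly by threshold classification. Identical seeds give identical
#' output.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `ct` (a [ct_volume()]) and `truth` (a
#'   `phantom_truth`: noise-free `labels`, per-cavity counts and realized
#'   fills in `cavities`, `masks` (total / per-sinus / OMC) and `overall`
#'   ground-truth soft fraction).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_dim
  sp <- spec$spacing
  origin <- sp / 2    # voxel centres at sp/2 + (i-1)*sp; extent [0, L]
  cx <- origin[1] + (seq_len(dm[1]) - 1) * sp[1]
  cy <- origin[2] + (seq_len(dm[2]) - 1) * sp[2]
  cz <- origin[3] + (seq_len(dm[3]) - 1) * sp[3]

  labels <- array(LABEL_CODES[["bone"]], dim = dm)
  claimed <- array(FALSE, dim = dm)
  cav <- spec$cavities
  cav$n_total <- cav$n_soft <- cav$n_air <- 0L
  cav$realized_fill <- NA_real_
  masks <- vector("list", nrow(cav))

  for (i in seq_len(nrow(cav))) {
    # restrict to the cavity's bounding sub-grid, then test voxel centres
    ix <- which(cx >= cav$cx[i] - cav$ax[i] & cx <= cav$cx[i] + cav$ax[i])
    iy <- which(cy >= cav$cy[i] - cav$ay[i] & cy <= cav$cy[i] + cav$ay[i])
    iz <- which(cz >= cav$cz[i] - cav$az[i] & cz <= cav$cz[i] + cav$az[i])
    if (length(ix) == 0 || length(iy) == 0 || length(iz) == 0)
      stop("cavity ", cav$name[i], "_", cav$side[i],
           " rasterizes to zero voxels: unachievable fill")
    sub <- expand.grid(x = ix, y = iy, z = iz)
    if (cav$shape[i] == "ellipsoid") {
      d2 <- ((cx[sub$x] - cav$cx[i]) / cav$ax[i])^2 +
            ((cy[sub$y] - cav$cy[i]) / cav$ay[i])^2 +
            ((cz[sub$z] - cav$cz[i]) / cav$az[i])^2
      sub <- sub[d2 <= 1, , drop = FALSE]
    }
    if (nrow(sub) == 0)
      stop("cavity ", cav$name[i], "_", cav$side[i],
           " rasterizes to zero voxels: unachievable fill")
    idx <- sub$x + (sub$y - 1L) * dm[1] + (sub$z - 1L) * dm[1] * dm[2]
    if (any(claimed[idx]))
      stop("cavity ", cav$name[i], "_", cav$side[i],
           " overlaps a previously placed cavity")
    claimed[idx] <- TRUE
    # gravity fill: soft tissue from the inferior (low z) extent upward
    ord <- order(sub$z, sub$y, sub$x)
    idx <- idx[ord]
    n <- length(idx)
    n_soft <- as.integer(round(cav$fill[i] * n))
    if (n_soft > 0) labels[idx[seq_len(n_soft)]] <- LABEL_CODES[["soft"]]
    if (n_soft < n) labels[idx[(n_soft + 1L):n]] <- LABEL_CODES[["air"]]
    cav$n_total[i] <- n
    cav$n_soft[i] <- n_soft
    cav$n_air[i] <- n - n_soft
    cav$realized_fill[i] <- n_soft / n
    mk <- array(FALSE, dm); mk[idx] <- TRUE
    masks[[i]] <- voi_mask(mk, spacing = sp, origin = origin)
  }

  hu <- with_local_seed(spec$seed, {
    out <- array(0, dim = dm)
    for (cls in c("air", "soft", "bone")) {
      w <- which(labels == LABEL_CODES[[cls]])
      p <- spec$hu[[cls]]
      out[w] <- pmin(pmax(stats::rnorm(length(w), p$mean, p$sd),
                          p$clip[1]), p$clip[2])
    }
    out
  })

  total_mask <- voi_mask(claimed, spacing = sp, origin = origin)
  sinus_masks <- masks[cav$type == "sinus"]
  names(sinus_masks) <- paste(cav$name[cav$type == "sinus"],
                              cav$side[cav$type == "sinus"], sep = "_")
  omc_masks <- masks[cav$type == "omc"]
  names(omc_masks) <- cav$side[cav$type == "omc"]

  overall_soft <- sum(cav$n_soft)
  overall_air <- sum(cav$n_air)
  truth <- structure(list(
    labels = labels,
    cavities = cav,
    masks = list(total = total_mask, sinus = sinus_masks, omc = omc_masks),
    overall = list(n_air = overall_air, n_soft = overall_soft,
                   pabcd = overall_soft / (overall_soft + overall_air))
  ), class = "phantom_truth")

  list(ct = ct_volume(hu, spacing = sp, origin = origin), truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("Phantom truth: %d cavities, overall soft fraction %.4f\n",
              nrow(x$cavities), x$overall$pabcd))
  invisible(x)
}

#' Region set from phantom ground truth
#'
#' @param truth a `phantom_truth`.
#' @return a [region_set()] of the phantom's total VOI, per-sinus masks and
#'   OMC channels.
#' @export
as_region_set <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  region_set(truth$masks$total, sinus = truth$masks$sinus,
             omc = truth$masks$omc)
}

#' Write a phantom to disk (NIfTI volumes + JSON truth record)
#'
#' Writes `ct.nii.gz`, `labels.nii.gz`, `mask_total.nii.gz`, one NIfTI per
#' sub-ROI, and `truth.json` into `dir`.
#'
#' @param phantom output of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ct <- phantom$ct; truth <- phantom$truth
  write_nifti_volume(ct, file.path(dir, "ct.nii.gz"))
  lab <- ct_volume(array(as.double(truth$labels), dim(truth$labels)),
                   spacing = ct$spacing, origin = ct$origin)
  write_nifti_volume(lab, file.path(dir, "labels.nii.gz"))
  write_nifti_volume(truth$masks$total, file.path(dir, "mask_total.nii.gz"))
  for (nm in names(truth$masks$sinus))
    write_nifti_volume(truth$masks$sinus[[nm]],
                       file.path(dir, paste0("mask_", nm, ".nii.gz")))
  for (nm in names(truth$masks$omc))
    write_nifti_volume(truth$masks$omc[[nm]],
                       file.path(dir, paste0("mask_omc_", nm, ".nii.gz")))
  rec <- list(schema_version = SCHEMA_VERSION, record_type = "phantom_truth",
              cavities = truth$cavities, overall = truth$overall)
  jsonlite::write_json(rec, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Read/write a phantom specification (JSON or YAML)
#'
#' The config mirrors [phantom_spec()] field for field.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return for `read_phantom_spec`, a [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  hu <- if (is.null(lst$hu)) hu_model() else
    hu_model(air = unlist(lst$hu$air), soft = unlist(lst$hu$soft),
             bone = unlist(lst$hu$bone))
  cav <- if (is.null(lst$cavities)) NULL else as.data.frame(lst$cavities)
  fill <- lst$fill %||% cav$fill %||% 0.5
  phantom_spec(fill = fill,
               grid_dim = unlist(lst$grid_dim) %||% c(128, 128, 128),
               spacing = unlist(lst$spacing) %||% c(0.5, 0.5, 0.5),
               hu = hu, seed = lst$seed %||% 1L, cavities = cav)
}

#' @rdname read_phantom_spec
#' @param spec a [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  lst <- list(grid_dim = spec$grid_dim, spacing = spec$spacing,
              seed = spec$seed,
              hu = list(air = c(spec$hu$air$mean, spec$hu$air$sd),
                        soft = c(spec$hu$soft$mean, spec$hu$soft$sd),
                        bone = c(spec$hu$bone$mean, spec$hu$bone$sd)),
              cavities = spec$cavities)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(lst, path)
  else jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                            dataframe = "columns")
  invisible(path)
}

# Beta shape parameters from a mean/sd parameterization
beta_shapes <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) stop("Beta mean must lie in (0, 1)")
  k <- mean * (1 - mean) / sd^2 - 1
  if (k <= 0)
    stop("sd ", sd, " too large for a Beta with mean ", mean)
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}

#' Paired pre/post phantom cohort
#'
#' Emulates a before-and-after treatment design in which each patient is
#' their own control. Baseline fill fractions are drawn from a Beta
#' distribution around the pre-treatment mean; treatment acts
#' multiplicatively, with a per-patient response ratio drawn from a scaled
#' Beta whose mean is `post/pre` (so the cohort post mean matches the
#' requested value) and whose support extends above 1, allowing a minority
#' of patients to worsen. Deterministic under `seed`.
#'
#' @param n_patients number of patients (>= 1).
#' @param effect length-2 numeric: cohort mean fill fraction pre and post
#'   treatment, both in `[0, 1]` (defaults 0.68 and 0.52).
#' @param seed integer RNG seed.
#' @param sd_pre between-patient SD of the baseline fill (default 0.15).
#' @param sd_ratio SD of the response ratio (default 0.18).
#' @param ratio_max upper support of the response ratio (default 1.25).
#' @param grid_dim,spacing forwarded to [phantom_spec()] for each phantom.
#' @return a `phantom_cohort`: list of per-patient records with `id`,
#'   nominal `fill_pre`/`fill_post` and paired `pre`/`post`
#'   [phantom_spec()]s.
#' @export
default_cohort <- function(n_patients, effect = c(pre = 0.68, post = 0.52),
                           seed = 1L, sd_pre = 0.15, sd_ratio = 0.18,
                           ratio_max = 1.25, grid_dim = c(128, 128, 128),
                           spacing = c(0.5, 0.5, 0.5)) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  effect <- as.numeric(effect)
  if (length(effect) != 2L || any(effect < 0) || any(effect > 1))
    stop("effect means must be two values in [0, 1]")
  if (effect[1] <= 0)
    stop("pre-treatment mean fill must be positive")
  mean_ratio <- effect[2] / effect[1]
  if (mean_ratio >= ratio_max)
    stop("post/pre ratio ", round(mean_ratio, 3),
         " is not below ratio_max = ", ratio_max)
  sh_pre <- beta_shapes(effect[1], sd_pre)
  sh_rat <- beta_shapes(mean_ratio / ratio_max, sd_ratio / ratio_max)
  with_local_seed(seed, {
    p_pre <- stats::rbeta(n_patients, sh_pre[1], sh_pre[2])
    ratio <- ratio_max * stats::rbeta(n_patients, sh_rat[1], sh_rat[2])
    p_post <- pmin(1, p_pre * ratio)
    seeds <- sample.int(2147483646L, 2L * n_patients)
    cohort <- lapply(seq_len(n_patients), function(i) {
      list(id = i, fill_pre = p_pre[i], fill_post = p_post[i],
           pre = phantom_spec(fill = p_pre[i], grid_dim = grid_dim,
                              spacing = spacing, seed = seeds[2L * i - 1L]),
           post = phantom_spec(fill = p_post[i], grid_dim = grid_dim,
                               spacing = spacing, seed = seeds[2L * i]))
    })
    structure(cohort, class = "phantom_cohort")
  })
}

#' Nominal fill fractions of a phantom cohort
#'
#' @param cohort a `phantom_cohort` from [default_cohort()].
#' @return data frame with columns `id`, `pre`, `post`.
#' @export
cohort_fills <- function(cohort) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  data.frame(id = vapply(cohort, `[[`, numeric(1), "id"),
             pre = vapply(cohort, `[[`, numeric(1), "fill_pre"),
             post = vapply(cohort, `[[`, numeric(1), "fill_post"))
}
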