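#' Configuration for the synthetic hip phantom
#'
#' The phantom emulates a single proximal-hip axial cross-section: an outer
#' subcutaneous fat ring, a fascial envelope containing muscle with speckled
#' IMAT islands, one femoral cross-section with a cortical shell, a
#' trabecular zone and a marrow cavity split into HBM and MAT, plus three
#' hydroxyapatite calibration rods outside the body. Default tissue HU means
#' sit well inside the threshold-scheme intervals (>= 3 sigma margins at the
#' default noise level), and the acquisition defaults mirror the protocol:
#' 3 mm slices, 5-slice stacks, rods at 150/75/0 mg/cm3.
#'
#' @param image_size Pixels per side (default 128; up to 512).
#' @param pixel_spacing mm per pixel; default `340/image_size` (a 34 cm field
#'   of view regardless of resolution).
#' @param slice_thickness Slice thickness in mm.
#' @param n_slices Slices per stack; must be odd so a central reference slice
#'   exists.
#' @param noise_sigma Standard deviation (HU) of additive Gaussian noise.
#' @param domain_shift List with `hu_offset` (HU added to every pixel of
#'   domain-B images) and `spacing_factor` (multiplier on domain-B pixel
#'   spacing), emulating a second scanner.
#' @param tissue_hu_means Named numeric vector of mean HU per tissue (names
#'   as in [tissue_classes()]); each mean must lie strictly inside that
#'   tissue's threshold interval.
#' @param rod_concentrations Nominal rod concentrations in mg/cm3, strictly
#'   decreasing, length 3.
#' @param rod_hu_per_mg Scanner law mapping concentration to rod HU
#'   (HU = concentration * rod_hu_per_mg + rod_hu_intercept).
#' @param rod_hu_intercept Intercept of the rod HU law.
#' @param seed RNG seed for cohort generation.
#' @param scheme The [threshold_scheme()] used to validate separability.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 128,
                           pixel_spacing = NULL,
                           slice_thickness = 3,
                           n_slices = 5,
                           noise_sigma = 10,
                           domain_shift = list(hu_offset = 40,
                                               spacing_factor = 1.05),
                           tissue_hu_means = c(cortical = 600,
                                               trabecular = 220, hbm = 100,
                                               mat = 20, muscle = 50,
                                               imat = -80, sat = -80,
                                               background = -1000),
                           rod_concentrations = c(150, 75, 0),
                           rod_hu_per_mg = 1,
                           rod_hu_intercept = 0,
                           seed = NULL,
                           scheme = threshold_scheme()) {
  if (image_size < 32 || image_size > 512)
    stop("image_size must lie in [32, 512]")
  if (is.null(pixel_spacing)) pixel_spacing <- 340 / image_size
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (n_slices < 1 || n_slices %% 2 == 0)
    stop("n_slices must be odd so a central reference slice exists")
  if (length(rod_concentrations) != 3 ||
      any(diff(rod_concentrations) >= 0))
    stop("rod_concentrations must be strictly decreasing, length 3")
  needed <- c("cortical", "trabecular", "hbm", "mat", "muscle", "imat",
              "sat", "background")
  if (!all(needed %in% names(tissue_hu_means)))
    stop("tissue_hu_means must name: ", paste(needed, collapse = ", "))
  m <- tissue_hu_means
  ok <- m["cortical"] > scheme$cortical_min &&
    m["trabecular"] > scheme$trabecular_range[1] &&
    m["trabecular"] < scheme$trabecular_range[2] &&
    m["hbm"] > scheme$hbm_range[1] && m["hbm"] < scheme$hbm_range[2] &&
    m["mat"] < scheme$mat_max && m["mat"] > scheme$fat_max &&
    m["muscle"] > scheme$muscle_range[1] &&
    m["muscle"] < scheme$muscle_range[2] &&
    m["imat"] < scheme$fat_max && m["sat"] < scheme$fat_max &&
    m["imat"] > scheme$air_cutoff && m["sat"] > scheme$air_cutoff &&
    m["background"] < scheme$air_cutoff
  if (!ok)
    stop("tissue_hu_means violate threshold separability: every mean must ",
         "lie strictly inside its tissue's threshold interval")
  structure(
    list(image_size = as.integer(image_size),
         pixel_spacing = pixel_spacing,
         slice_thickness = slice_thickness,
         n_slices = as.integer(n_slices),
         noise_sigma = noise_sigma,
         domain_shift = domain_shift,
         tissue_hu_means = m,
         rod_concentrations = rod_concentrations,
         rod_hu_per_mg = rod_hu_per_mg,
         rod_hu_intercept = rod_hu_intercept,
         seed = seed,
         scheme = scheme),
    class = "phantom_config")
}

# filled ellipse raster; centers/semi-axes in pixel units (row, col)
ellipse_mask <- function(n, center, semi) {
  i <- matrix(seq_len(n), n, n)
  j <- matrix(seq_len(n), n, n, byrow = TRUE)
  ((i - center[1]) / semi[1])^2 + ((j - center[2]) / semi[2])^2 <= 1
}

# baseline geometry in units of image_size; jit() returns U(1-a, 1+a) factors
phantom_geometry <- function(n, jitter = TRUE) {
  jf <- function(a = 0.10) if (jitter) stats::runif(1, 1 - a, 1 + a) else 1
  js <- function(a) if (jitter) stats::runif(1, -a, a) * n else 0
  body_c <- c(0.50 * n + js(0.02), 0.50 * n + js(0.02))
  body_s <- c(0.30 * n * jf(), 0.40 * n * jf())
  fas_c <- body_c + c(js(0.01), js(0.01))
  fas_s <- body_s * 0.80 * jf(0.05)
  bone_c <- c(fas_c[1] - 0.02 * n + js(0.01),
              fas_c[2] + 0.11 * n * jf())
  bone_s <- c(0.115 * n * jf(), 0.135 * n * jf())
  cort_t <- 0.030 * n
  trab_t <- 0.030 * n
  mat_c <- bone_c + c(0.01 * n, 0.012 * n)
  mat_s <- c(0.030 * n, 0.042 * n) * jf(0.08)
  list(body_c = body_c, body_s = body_s, fas_c = fas_c, fas_s = fas_s,
       bone_c = bone_c, bone_s = bone_s, cort_t = cort_t, trab_t = trab_t,
       mat_c = mat_c, mat_s = mat_s,
       rod_r = 0.030 * n,
       rod_centers = rbind(c(0.92 * n, 0.25 * n),
                           c(0.92 * n, 0.50 * n),
                           c(0.92 * n, 0.75 * n)),
       imat_r = 0.030 * n, imat_k = 10L)
}

# rasterize one slice: returns list(labels (int matrix, 0..7; rods coded -1,
# -2, -3 temporarily), compartments)
phantom_slice <- function(n, geo, bone_scale, imat_xy) {
  body <- ellipse_mask(n, geo$body_c, geo$body_s)
  fascia_env <- ellipse_mask(n, geo$fas_c, geo$fas_s)
  bone_s <- geo$bone_s * bone_scale
  bone <- ellipse_mask(n, geo$bone_c, bone_s)
  # guarantee nesting with a margin even under jitter
  while (any(bone & !merode(fascia_env, 2))) {
    bone_s <- bone_s * 0.95
    bone <- ellipse_mask(n, geo$bone_c, bone_s)
  }
  trab_outer <- ellipse_mask(n, geo$bone_c, pmax(bone_s - geo$cort_t, 1))
  marrow <- ellipse_mask(n, geo$bone_c,
                         pmax(bone_s - geo$cort_t - geo$trab_t, 1))
  mat_s <- geo$mat_s * bone_scale
  mat <- ellipse_mask(n, geo$mat_c, mat_s) & marrow
  while (!any(mat)) {  # tiny marrow after shrink: recentre MAT on the marrow
    mat <- ellipse_mask(n, geo$bone_c, mat_s) & marrow
    mat_s <- mat_s * 1.25
  }

  lab <- matrix(0L, n, n)
  lab[body] <- 7L                                   # SAT ring
  lab[fascia_env] <- 5L                             # muscle
  # IMAT speckles (positions precomputed, inside fascia, outside bone)
  for (k in seq_len(nrow(imat_xy))) {
    sp <- ellipse_mask(n, imat_xy[k, ], rep(geo$imat_r, 2))
    lab[sp & fascia_env & !bone] <- 6L
  }
  lab[bone] <- 1L                                   # cortical shell
  lab[trab_outer] <- 2L                             # trabecular zone
  lab[marrow] <- 3L                                 # HBM
  lab[mat] <- 4L                                    # MAT

  comp <- list(body = body, bone = bone, marrow = marrow,
               fascia = fascia_env & !bone,
               subcutaneous = body & !fascia_env)
  list(labels = lab, compartments = comp)
}

# sample non-overlapping IMAT speckle centres inside the fascia envelope
place_imat <- function(n, geo) {
  centers <- matrix(NA_real_, 0, 2)
  margin <- geo$imat_r + 2
  tries <- 0L
  while (nrow(centers) < geo$imat_k && tries < 400L) {
    tries <- tries + 1L
    th <- stats::runif(1, 0, 2 * pi)
    rr <- sqrt(stats::runif(1))
    cand <- c(geo$fas_c[1] + rr * (geo$fas_s[1] - margin) * sin(th),
              geo$fas_c[2] + rr * (geo$fas_s[2] - margin) * cos(th))
    # keep clear of the bone (worst-case slice scale 1.0) and other speckles
    din <- ((cand[1] - geo$bone_c[1]) / (geo$bone_s[1] + margin))^2 +
      ((cand[2] - geo$bone_c[2]) / (geo$bone_s[2] + margin))^2
    if (din <= 1) next
    if (nrow(centers) > 0 &&
        any((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 <
            (2.5 * geo$imat_r)^2)) next
    centers <- rbind(centers, cand)
  }
  centers
}

#' Generate one synthetic phantom subject
#'
#' Deterministic for a fixed `config$seed` and subject index: the same call
#' yields bit-identical images and labels. Anatomy (ellipse centres and axes)
#' is jittered around the baseline geometry by about +/-10% per subject; in a
#' stack, the bone cross-section is largest at the central slice.
#'
#' @param config A [phantom_config()].
#' @param subject_id Identifier stored in the sample metadata.
#' @param domain Domain tag; `"A"` is the native scanner, `"B"` applies the
#'   configured HU offset and spacing multiplier.
#' @param .subject_index Integer used, together with `config$seed`, to seed
#'   the per-subject RNG (so cohorts are reproducible subject-by-subject).
#' @return Object of class `phantom_sample`: `image` (a [ct_image()]),
#'   `labels` (a [label_mask()]), `compartments` (per-slice list of
#'   compartment masks) and `meta` (subject id, height in m, domain).
#' @export
generate_phantom <- function(config, subject_id = "s1", domain = "A",
                             .subject_index = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  if (!domain %in% c("A", "B")) stop("unknown domain tag: ", domain)
  if (!is.null(config$seed))
    set.seed((config$seed + 7919L * .subject_index) %% .Machine$integer.max)
  n <- config$image_size
  ns <- config$n_slices
  geo <- phantom_geometry(n, jitter = TRUE)
  imat_xy <- place_imat(n, geo)
  height_m <- stats::runif(1, 1.55, 1.90)
  mid <- (ns + 1) / 2

  vol <- array(0, c(n, n, ns))
  labs <- array(0L, c(n, n, ns))
  comps <- vector("list", ns)
  m <- config$tissue_hu_means
  mean_of <- c(m["cortical"], m["trabecular"], m["hbm"], m["mat"],
               m["muscle"], m["imat"], m["sat"])
  rod_hu <- config$rod_concentrations * config$rod_hu_per_mg +
    config$rod_hu_intercept

  for (s in seq_len(ns)) {
    bone_scale <- 1 - 0.05 * abs(s - mid)
    sl <- phantom_slice(n, geo, bone_scale, imat_xy)
    hu <- matrix(m["background"], n, n)
    for (cls in 1:7) {
      px <- sl$labels == cls
      hu[px] <- mean_of[cls]
    }
    for (r in 1:3) {
      rod <- ellipse_mask(n, geo$rod_centers[r, ], rep(geo$rod_r, 2))
      hu[rod] <- rod_hu[r]                # rods stay class 0 in the labels
    }
    if (config$noise_sigma > 0)
      hu <- hu + matrix(stats::rnorm(n * n, 0, config$noise_sigma), n, n)
    vol[, , s] <- hu
    labs[, , s] <- sl$labels
    comps[[s]] <- sl$compartments
  }

  spacing <- rep(config$pixel_spacing, 2)
  if (domain == "B") {
    vol <- vol + config$domain_shift$hu_offset
    spacing <- spacing * config$domain_shift$spacing_factor
  }
  if (ns == 1L) {
    vol <- vol[, , 1]
    labs <- labs[, , 1]
  }
  structure(
    list(image = ct_image(vol, spacing, config$slice_thickness,
                          origin = paste0("phantom:", subject_id)),
         labels = label_mask(labs, spacing, config$slice_thickness),
         compartments = if (ns == 1L) comps[[1]] else comps,
         meta = list(subject_id = subject_id, height_m = height_m,
                     domain = domain)),
    class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %s (domain %s, height %.2f m)\n",
              x$meta$subject_id, x$meta$domain, x$meta$height_m))
  print(x$image)
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Subjects are assigned to the requested scanner domains round-robin; domain
#' `"B"` images receive the configured HU offset and pixel-spacing multiplier.
#' Reproducible for a fixed `config$seed`.
#'
#' @param config A [phantom_config()].
#' @param n_subjects Number of subjects (>= 1).
#' @param domains Character vector of domain tags (subset of `c("A", "B")`).
#' @return List of [generate_phantom()] samples.
#' @export
generate_cohort <- function(config, n_subjects, domains = "A") {
  stopifnot(inherits(config, "phantom_config"), n_subjects >= 1)
  if (!all(domains %in% c("A", "B")))
    stop("unknown domain tag: ", paste(setdiff(domains, c("A", "B")),
                                       collapse = ", "))
  lapply(seq_len(n_subjects), function(i) {
    generate_phantom(config,
                     subject_id = sprintf("s%03d", i),
                     domain = domains[((i - 1L) %% length(domains)) + 1L],
                     .subject_index = i)
  })
}

#' Nominal class pixel fractions of the default phantom geometry
#'
#' Analytic areas (pi a b for ellipses) of the unjittered baseline geometry,
#' as fractions of the image. Useful as geometric targets for generated
#' cohorts: jitter moves individual subjects by up to ~20%, but cohort means
#' stay close to these values.
#'
#' @param config A [phantom_config()].
#' @return Named numeric vector over the 8 classes, summing to 1.
#' @export
phantom_class_fractions <- function(config = phantom_config()) {
  n <- 1  # work in units of image area
  g <- phantom_geometry(1, jitter = FALSE)
  ea <- function(s) pi * s[1] * s[2]
  body <- ea(g$body_s); fascia <- ea(g$fas_s); bone <- ea(g$bone_s)
  trab_o <- ea(g$bone_s - g$cort_t)
  marrow <- ea(g$bone_s - g$cort_t - g$trab_t)
  mat <- ea(g$mat_s)
  imat <- g$imat_k * pi * g$imat_r^2
  rods <- 3 * pi * g$rod_r^2
  fr <- c(background = 1 - body + rods * 0,  # rods are background-labelled
          cortical = bone - trab_o,
          trabecular = trab_o - marrow,
          hbm = marrow - mat,
          mat = mat,
          muscle = fascia - bone - imat,
          imat = imat,
          sat = body - fascia)
  fr["background"] <- 1 - sum(fr[-1])
  fr
}

#' Write a cohort to disk (NIfTI images/masks + CSV manifest)
#'
#' @param cohort List of `phantom_sample`s.
#' @param dir Output directory (created if missing).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    img <- file.path(dir, paste0(s$meta$subject_id, "_image.nii.gz"))
    msk <- file.path(dir, paste0(s$meta$subject_id, "_mask.nii.gz"))
    write_image(s$image, img)
    write_mask(s$labels, msk)
    data.frame(subject_id = s$meta$subject_id, domain = s$meta$domain,
               height_m = s$meta$height_m, image = basename(img),
               mask = basename(msk))
  })
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Directory containing `manifest.csv`.
#' @return List of samples (image, labels, meta), compartments omitted.
#' @export
read_cohort <- function(dir) {
  manifest <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest)) stop("no manifest.csv in ", dir)
  tab <- read.csv(manifest, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    structure(
      list(image = read_image(file.path(dir, tab$image[i])),
           labels = read_mask(file.path(dir, tab$mask[i])),
           compartments = NULL,
           meta = list(subject_id = tab$subject_id[i],
                       height_m = tab$height_m[i],
                       domain = tab$domain[i])),
      class = "phantom_sample")
  })
}
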