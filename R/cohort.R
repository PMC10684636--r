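# Synthetic multi-centre cohort: paired non-ASC / CT-ASC coronal phantoms
# with per-centre scanner heterogeneity and halo / mismatch artefact
# injectors.

TABLE1_MATRIX <- c(180L, 168L, 256L, 440L, 168L, 200L, 192L, 192L)
TABLE1_TRACER <- c("PSMA", "PSMA", "PSMA", "PSMA", "PSMA", "PSMA", "DOTATATE", "PSMA")
TABLE1_CLEAN <- c(16L, 71L, 49L, 49L, 51L, 57L, 89L, 39L)
TABLE1_SCANNER <- c(
  "Siemens Horizon", "Siemens Biograph 6", "Siemens mCT", "Siemens Vision",
  "Siemens Biograph 6", "Siemens mCT", "GE Discovery 690", "GE Discovery IQ"
)
GA68_HALF_LIFE_MIN <- 67.71

#' Build simulated imaging-centre profiles
#'
#' Each profile describes one centre of a heterogeneous multi-centre 68Ga
#' PET cohort: matrix size, tracer, an effective point-spread blur, a
#' relative noise level and the number of artefact-free ("clean") and
#' artefact-bearing patients to simulate.  With `n_centres = 8` and no
#' overrides the profiles carry the eight reference matrix sizes, tracers
#' (seven PSMA centres, one DOTA-TATE centre) and clean counts
#' (16, 71, 49, 49, 51, 57, 89, 39) of the study design the generator
#' emulates; other values of `n_centres` recycle those templates.
#'
#' @param n_centres number of centres, between 1 and 16.
#' @param seed integer seed controlling the blur/noise draws.
#' @param n_clean optional vector overriding the per-centre clean counts.
#' @param n_artefact optional vector overriding the per-centre artefact
#'   counts (default `ceiling(n_clean / 8)`).
#' @param matrix_size optional vector overriding the per-centre matrix sizes
#'   (pixels per side, minimum 64).
#' @param tracer optional vector overriding the per-centre tracers
#'   (`"PSMA"` / `"DOTATATE"`).
#' @param psf_fwhm,noise_scale optional vectors overriding the seed-drawn
#'   scanner blur (FWHM, pixels) and relative noise level.
#' @return a list of `centre_profile` objects.
#' @examples
#' profs <- make_centre_profiles(8, seed = 0)
#' profs[[2]]$matrix_size # 168
#' profs[[7]]$tracer # "DOTATATE"
#' @export
make_centre_profiles <- function(n_centres, seed = 0L, n_clean = NULL,
                                 n_artefact = NULL, matrix_size = NULL,
                                 tracer = NULL, psf_fwhm = NULL,
                                 noise_scale = NULL) {
  if (!is.numeric(n_centres) || length(n_centres) != 1L ||
      n_centres < 1 || n_centres > 16) {
    stop_invalid("`n_centres` must be a single integer in [1, 16]")
  }
  n_centres <- as.integer(n_centres)
  idx <- ((seq_len(n_centres) - 1L) %% 8L) + 1L
  msize <- if (is.null(matrix_size)) TABLE1_MATRIX[idx] else
    as.integer(rep_len(matrix_size, n_centres))
  if (any(msize < 64L)) stop_invalid("matrix_size must be >= 64")
  ncl <- if (is.null(n_clean)) TABLE1_CLEAN[idx] else
    as.integer(rep_len(n_clean, n_centres))
  if (any(ncl < 2L)) stop_invalid("n_clean must be >= 2 for every centre")
  nart <- if (is.null(n_artefact)) pmax(1L, ceiling(ncl / 8)) else
    as.integer(rep_len(n_artefact, n_centres))
  if (any(nart < 0L)) stop_invalid("n_artefact must be >= 0")
  trc <- if (is.null(tracer)) TABLE1_TRACER[idx] else rep_len(tracer, n_centres)
  if (any(!trc %in% c("PSMA", "DOTATATE"))) {
    stop_invalid("tracer must be PSMA or DOTATATE")
  }
  with_seed(seed, {
    psf <- if (is.null(psf_fwhm)) round(runif(n_centres, 1.2, 2.8), 2) else
      rep_len(psf_fwhm, n_centres)
    noise <- if (is.null(noise_scale)) round(runif(n_centres, 0.01, 0.05), 4) else
      rep_len(noise_scale, n_centres)
    if (any(psf <= 0) || any(noise < 0)) {
      stop_invalid("psf_fwhm must be > 0 and noise_scale >= 0")
    }
    lapply(seq_len(n_centres), function(i) {
      structure(list(
        centre_id = i,
        scanner_label = TABLE1_SCANNER[idx[i]],
        matrix_size = msize[i],
        tracer = trc[i],
        psf_fwhm = psf[i],
        noise_scale = noise[i],
        n_clean = ncl[i],
        n_artefact = nart[i]
      ), class = "centre_profile")
    })
  })
}

#' @export
print.centre_profile <- function(x, ...) {
  cat(sprintf(
    "<centre_profile %d: %s, %dx%d, %s, psf %.2f px, noise %.3f, %d clean / %d artefact>\n",
    x$centre_id, x$scanner_label, x$matrix_size, x$matrix_size, x$tracer,
    x$psf_fwhm, x$noise_scale, x$n_clean, x$n_artefact
  ))
  invisible(x)
}

#' Patient metadata for SUV conversion
#'
#' @param weight body weight in grams.
#' @param injected_dose injected activity in Bq.
#' @param delay injection-to-scan delay in minutes.
#' @param half_life tracer half-life in minutes (68Ga default 67.71).
#' @return a `patient_meta` list.
#' @export
patient_meta <- function(weight, injected_dose, delay,
                         half_life = GA68_HALF_LIFE_MIN) {
  vals <- c(weight = weight, injected_dose = injected_dose,
            delay = delay, half_life = half_life)
  if (any(!is.finite(vals)) || any(vals[c(1, 2, 4)] <= 0) || delay < 0) {
    stop_invalid("weight, dose and half-life must be positive; delay must be >= 0")
  }
  structure(as.list(vals), class = "patient_meta")
}

# Draw plausible 68Ga patient metadata from the current RNG stream.
sample_patient_meta <- function() {
  patient_meta(
    weight = max(4e4, rnorm(1, 7.5e4, 1.2e4)),
    injected_dose = max(5e7, rnorm(1, 1.5e8, 2e7)),
    delay = runif(1, 45, 75)
  )
}

# --- phantom geometry ------------------------------------------------------

# Rasterize an ellipse mask on an n x n grid (rows = cranio-caudal axis of a
# coronal view).
ellipse_mask <- function(n, cr, cc, rr, rc) {
  r <- matrix(seq_len(n), n, n)
  c_ <- t(r)
  ((r - cr) / rr)^2 + ((c_ - cc) / rc)^2 <= 1
}

# Piecewise-constant anthropomorphic coronal scene in SUV units.
# Returns intensities plus the organ masks needed downstream.
phantom_scene <- function(n, tracer, lesion_max = 3) {
  cr <- (n + 1) / 2
  cc <- (n + 1) / 2
  rr <- 0.45 * n # cranio-caudal semi-axis
  rc <- 0.30 * n # lateral semi-axis
  at <- function(u, v, ru, rv) ellipse_mask(n, cr + u * rr, cc + v * rc, ru * rr, rv * rc)
  body <- ellipse_mask(n, cr, cc, rr, rc)
  lung_l <- at(-0.50, -0.38, 0.16, 0.25)
  lung_r <- at(-0.50, +0.38, 0.16, 0.25)
  lungs <- (lung_l | lung_r) & body
  liver <- at(-0.12, -0.38, 0.16, 0.30) & body
  spleen <- at(-0.10, +0.42, 0.08, 0.12) & body
  kid_l <- at(+0.08, -0.30, 0.10, 0.11) & body
  kid_r <- at(+0.08, +0.30, 0.10, 0.11) & body
  kidneys <- kid_l | kid_r
  bladder <- at(+0.62, 0, 0.07, 0.10) & body
  suv <- matrix(0, n, n)
  suv[body] <- 1.0
  suv[lungs] <- 0.25
  suv[liver] <- 2.2
  suv[spleen] <- if (identical(tracer, "DOTATATE")) 6.0 else 1.8
  suv[kidneys] <- 7.0
  lesions <- body & FALSE
  n_les <- if (lesion_max > 0) sample(0:lesion_max, 1) else 0L
  if (n_les > 0) {
    for (i in seq_len(n_les)) {
      lu <- runif(1, -0.7, 0.7)
      lv <- runif(1, -0.7, 0.7)
      lr <- runif(1, 0.03, 0.06)
      li <- runif(1, 4, 8)
      m <- at(lu, lv, lr, lr * rr / rc) & body
      suv[m] <- li
      lesions <- lesions | m
    }
  }
  suv[bladder] <- 11.0
  list(
    suv = suv, body = body, lungs = lungs, liver = liver, spleen = spleen,
    kidneys = kidneys, bladder = bladder, lesions = lesions,
    centre = c(cr, cc), semi = c(rr, rc)
  )
}

# Smooth attenuation-suppression field A(x, y) in (0, 1]: A = exp(-mu * d)
# where d is an effective tissue depth (mm) that increases toward the body
# centre and is reduced inside the lungs (air attenuates less).  Equals 1
# outside the body.
attenuation_field <- function(body, lungs, centre, semi, pixel_spacing,
                              mu_eff = 0.008, lung_relief = 0.6) {
  n <- nrow(body)
  r <- matrix(seq_len(n), n, n)
  c_ <- t(r)
  rho <- sqrt(((r - centre[1]) / semi[1])^2 + ((c_ - centre[2]) / semi[2])^2)
  rho <- pmin(rho, 1)
  depth <- (1 - rho) * semi[2] * pixel_spacing
  depth[lungs] <- depth[lungs] * (1 - lung_relief)
  a <- exp(-mu_eff * depth)
  a[!body] <- 1
  a
}

apply_noise <- function(x, noise_scale, body) {
  if (noise_scale <= 0) return(x)
  eps <- matrix(rnorm(length(x)), nrow(x))
  y <- x + noise_scale * sqrt(pmax(x, 0)) * eps
  y[!body] <- 0
  pmax(y, 0)
}

# Blur restricted to the body support: mask-renormalized separable Gaussian,
# so activity is redistributed within the body rather than smeared into the
# background (keeps the whole-body mean stable).
masked_blur <- function(x, sigma, body) {
  if (sigma <= 0) return(x)
  num <- gaussian_blur(x * body, sigma)
  den <- gaussian_blur(body * 1, sigma)
  out <- matrix(0, nrow(x), ncol(x))
  out[body] <- num[body] / den[body]
  out
}

#' Generate one clean paired phantom patient
#'
#' Builds a piecewise-constant coronal phantom in SUV units (body ellipse,
#' photopenic lungs, liver, hot kidneys and bladder, spleen hot for
#' DOTA-TATE, 0-3 random lesions), applies the centre's point-spread blur,
#' converts to activity (Bq/ml) with sampled patient metadata, and forms the
#' pair: `ct_asc` is the corrected reference, `non_asc = ct_asc * A` with
#' `A` a smooth attenuation-suppression field that deepens toward the body
#' centre.  Poisson-like noise (SD proportional to the square root of
#' intensity) is added independently to both images.
#'
#' @param profile a `centre_profile`.
#' @param patient_id identifier string.
#' @param meta optional `patient_meta`; sampled if `NULL`.
#' @param seed optional integer; when given, the patient is drawn under a
#'   private RNG stream, otherwise the current stream is used.
#' @param lesion_max maximum number of random hot lesions (default 3).
#' @param pixel_spacing pixel size in mm.
#' @return an `image_pair` with empty `artefact_labels`.
#' @export
generate_patient <- function(profile, patient_id = "P001", meta = NULL,
                             seed = NULL, lesion_max = 3, pixel_spacing = 4.0) {
  stopifnot(inherits(profile, "centre_profile"))
  gen <- function() {
    n <- profile$matrix_size
    if (is.null(meta)) meta <- sample_patient_meta()
    scene <- phantom_scene(n, profile$tracer, lesion_max)
    sigma <- profile$psf_fwhm / (2 * sqrt(2 * log(2)))
    suv_blur <- masked_blur(scene$suv, sigma, scene$body)
    a_field <- attenuation_field(scene$body, scene$lungs, scene$centre,
                                 scene$semi, pixel_spacing)
    # Bq/ml per SUV unit for this patient (decay-corrected dose per weight)
    act_scale <- meta$injected_dose * 2^(-meta$delay / meta$half_life) / meta$weight
    ct_clean <- suv_blur * act_scale
    non_clean <- suv_blur * a_field * act_scale
    ct <- apply_noise(ct_clean, profile$noise_scale * sqrt(act_scale), scene$body)
    non <- apply_noise(non_clean, profile$noise_scale * sqrt(act_scale), scene$body)
    structure(list(
      non_asc = non,
      ct_asc = ct,
      meta = meta,
      pixel_spacing = pixel_spacing,
      artefact_labels = list(),
      centre_id = profile$centre_id,
      patient_id = patient_id,
      aux = list(
        scene = scene, a_field = a_field, act_scale = act_scale,
        ct_noisefree = ct_clean, non_noisefree = non_clean,
        psf_sigma = sigma
      )
    ), class = "image_pair")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf(
    "<image_pair %s/C%d: %s px, artefacts: %s>\n",
    x$patient_id, x$centre_id, dim_str(x$ct_asc),
    if (length(x$artefact_labels)) paste(names(x$artefact_labels), collapse = ",") else "none"
  ))
  invisible(x)
}

#' Inject a halo (photopenic annulus) artefact
#'
#' Emulates the scatter over-correction halo seen around very hot structures
#' in 68Ga PET: the corrected image is multiplied by `1 - severity * K(x, y)`
#' where `K` is an annular kernel (triangular radial profile, peak 1 at the
#' annulus mid-radius) centred on the hottest organ (bladder or kidneys).
#' The uncorrected image is unchanged; the annulus mask is recorded under
#' `artefact_labels$halo`.
#'
#' @param pair a clean `image_pair`.
#' @param severity suppression fraction in (0, 1].
#' @param inner_scale inner annulus radius as a multiple of the organ
#'   equivalent radius.
#' @param width_px annulus width in pixels (default scales with matrix size).
#' @return the artefacted `image_pair`.
#' @export
inject_halo <- function(pair, severity = 0.6, inner_scale = 1.3,
                        width_px = NULL) {
  stopifnot(inherits(pair, "image_pair"))
  if (length(pair$artefact_labels)) stop_invalid("`pair` must be clean")
  if (!is.numeric(severity) || length(severity) != 1L ||
      severity <= 0 || severity > 1) {
    stop_invalid("`severity` must lie in (0, 1]")
  }
  scene <- pair$aux$scene
  n <- nrow(pair$ct_asc)
  if (is.null(width_px)) width_px <- max(3, round(0.08 * n))
  organs <- list(bladder = scene$bladder, kidneys = scene$kidneys)
  hot <- names(which.max(vapply(
    organs, function(m) mean(pair$aux$ct_noisefree[m]), numeric(1)
  )))
  mask_org <- organs[[hot]]
  idx <- which(mask_org, arr.ind = TRUE)
  ctr <- colMeans(idx)
  r_org <- sqrt(sum(mask_org) / pi)
  r1 <- inner_scale * r_org
  r2 <- r1 + width_px
  r <- matrix(seq_len(n), n, n)
  c_ <- t(r)
  rad <- sqrt((r - ctr[1])^2 + (c_ - ctr[2])^2)
  mask <- rad >= r1 & rad <= r2
  rm <- (r1 + r2) / 2
  k <- pmax(0, 1 - abs(rad - rm) / ((r2 - r1) / 2))
  k[!mask] <- 0
  pair$ct_asc <- pmax(pair$ct_asc * (1 - severity * k), 0)
  pair$artefact_labels$halo <- list(
    mask = mask, severity = severity, centre = ctr, r_inner = r1, r_outer = r2,
    organ = hot
  )
  pair
}

#' Inject a PET/CT mismatch artefact at the diaphragm
#'
#' Emulates respiratory mismatch between the emission data and the CT used
#' for correction: the corrected image is recomputed with the diaphragm
#' boundary of the attenuation field displaced by `shift_px` rows
#' (positive = lungs extended caudally), producing a band of over- or
#' under-correction at the lung base.  The band mask (exactly `|shift_px|`
#' rows per affected column) is recorded under `artefact_labels$mismatch`.
#'
#' @param pair a clean `image_pair`.
#' @param shift_px non-zero integer displacement in rows; must not exceed
#'   half the lung height.
#' @return the artefacted `image_pair`.
#' @export
inject_mismatch <- function(pair, shift_px = 4L) {
  stopifnot(inherits(pair, "image_pair"))
  if (length(pair$artefact_labels)) stop_invalid("`pair` must be clean")
  shift_px <- as.integer(shift_px)
  if (length(shift_px) != 1L || shift_px == 0L) {
    stop_invalid("`shift_px` must be a non-zero integer")
  }
  scene <- pair$aux$scene
  lungs <- scene$lungs
  rows_per_col <- apply(lungs, 2, function(col) if (any(col)) range(which(col)) else c(NA, NA))
  heights <- rows_per_col[2, ] - rows_per_col[1, ] + 1
  if (abs(shift_px) > max(heights, na.rm = TRUE) / 2) {
    stop_invalid("|shift_px| exceeds half the lung height")
  }
  n <- nrow(lungs)
  shifted <- lungs
  for (cc in which(!is.na(rows_per_col[2, ]))) {
    d <- rows_per_col[2, cc]
    if (shift_px > 0) {
      rows <- (d + 1):(d + shift_px)
      rows <- rows[rows <= n]
      shifted[rows, cc] <- TRUE
    } else {
      rows <- (d + shift_px + 1):d
      shifted[rows, cc] <- FALSE
    }
  }
  a_true <- pair$aux$a_field
  a_wrong <- attenuation_field(scene$body, shifted, scene$centre, scene$semi,
                               pair$pixel_spacing)
  band <- a_true != a_wrong
  ratio <- a_true / a_wrong
  pair$ct_asc <- pair$ct_asc * ratio
  pair$artefact_labels$mismatch <- list(
    mask = band, shift_px = shift_px, lungs_shifted = shifted
  )
  pair$aux$a_wrong <- a_wrong
  pair
}

#' Generate a full multi-centre cohort
#'
#' Draws, per centre, `n_clean` clean pairs and `n_artefact` artefacted
#' pairs (artefact type alternating halo / mismatch with the configured
#' defaults), returning the pairs and a tidy manifest.  The whole cohort is
#' a pure function of `(profiles, seed)`.  When `dir` is given, every image
#' is written as NIfTI (`.nii.gz`) and the manifest as `manifest.csv`.
#'
#' @param profiles list of `centre_profile` objects.
#' @param seed integer master seed.
#' @param dir optional output directory.
#' @param halo_severity,mismatch_shift artefact injector defaults.
#' @param artefact_type `"mixed"` (alternating halo / mismatch), `"halo"` or
#'   `"mismatch"`.
#' @param lesion_max maximum lesions per phantom.
#' @return list with `pairs` (named list of `image_pair`) and `manifest`
#'   (tibble with centre_id, patient_id, role, artefact_labels, path, seed).
#' @export
generate_cohort <- function(profiles, seed = 0L, dir = NULL,
                            halo_severity = 0.6, mismatch_shift = 4L,
                            artefact_type = c("mixed", "halo", "mismatch"),
                            lesion_max = 3) {
  artefact_type <- match.arg(artefact_type)
  stopifnot(length(profiles) >= 1, all(vapply(profiles, inherits, TRUE, "centre_profile")))
  pairs <- list()
  rows <- list()
  for (prof in profiles) {
    total <- prof$n_clean + prof$n_artefact
    for (i in seq_len(total)) {
      pid <- sprintf("C%02dP%03d", prof$centre_id, i)
      pseed <- child_seed(seed, prof$centre_id * 1000L + i)
      pair <- generate_patient(prof, patient_id = pid, seed = pseed,
                               lesion_max = lesion_max)
      if (i > prof$n_clean) {
        k <- i - prof$n_clean
        use_halo <- switch(artefact_type,
                           mixed = k %% 2L == 1L,
                           halo = TRUE,
                           mismatch = FALSE)
        pair <- if (use_halo) {
          inject_halo(pair, severity = halo_severity)
        } else {
          inject_mismatch(pair, shift_px = mismatch_shift)
        }
      }
      pairs[[pid]] <- pair
      labs <- paste(names(pair$artefact_labels), collapse = ";")
      for (role in c("non_asc", "ct_asc")) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          centre_id = prof$centre_id, patient_id = pid, role = role,
          artefact_labels = labs,
          path = if (is.null(dir)) NA_character_ else
            file.path(dir, sprintf("centre_%02d", prof$centre_id),
                      sprintf("%s_%s.nii.gz", pid, role)),
          seed = pseed,
          weight = pair$meta$weight, injected_dose = pair$meta$injected_dose,
          delay = pair$meta$delay, half_life = pair$meta$half_life
        )
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(dir)) {
    for (j in seq_len(nrow(manifest))) {
      p <- manifest$path[j]
      dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
      pair <- pairs[[manifest$patient_id[j]]]
      write_image(pair[[manifest$role[j]]], p,
                  pixel_spacing = pair$pixel_spacing)
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(pairs = pairs, manifest = manifest)
}
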