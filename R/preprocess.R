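# Preprocessing chain: SUV conversion, body-contour crop, zero-padding to a
# common bounding box, fixed-divisor normalization, per-centre splits.

SUV_DIVISORS <- c(non_asc = 2.0, ct_asc = 5.0)

#' Convert an activity image (Bq/ml) to SUV units
#'
#' `SUV(x) = activity(x) * weight / (dose * 2^(-delay / half_life))`, i.e.
#' the injected dose is decay-corrected to scan time and tissue density is
#' taken as 1 g/ml.
#'
#' @param activity numeric matrix in Bq/ml.
#' @param meta a [patient_meta()].
#' @return matrix in SUV units.
#' @export
to_suv <- function(activity, meta) {
  if (!inherits(meta, "patient_meta")) meta <- do.call(patient_meta, meta)
  decayed_dose <- meta$injected_dose * 2^(-meta$delay / meta$half_life)
  activity * meta$weight / decayed_dose
}

#' Crop an image to its body contour
#'
#' Thresholds at `threshold_frac` of the image maximum, keeps the largest
#' 4-connected component, and crops to its tight axis-aligned bounding box.
#'
#' @param image numeric matrix.
#' @param threshold_frac fraction of the maximum used as foreground
#'   threshold (default 0.01).
#' @return list with `image` (cropped) and `box`
#'   (`c(row_min, row_max, col_min, col_max)`).
#' @export
crop_to_body <- function(image, threshold_frac = 0.01) {
  mx <- max(image)
  mask <- image > threshold_frac * mx
  if (mx <= 0 || !any(mask)) {
    stop_degenerate("no above-threshold pixels: cannot locate a body contour")
  }
  comp <- largest_component(mask)
  idx <- which(comp, arr.ind = TRUE)
  box <- c(min(idx[, 1]), max(idx[, 1]), min(idx[, 2]), max(idx[, 2]))
  list(image = image[box[1]:box[2], box[3]:box[4], drop = FALSE], box = box)
}

#' Apply a previously computed crop box to another (co-registered) image
#' @param image numeric matrix.
#' @param box crop box from [crop_to_body()].
#' @return cropped matrix.
#' @export
apply_crop <- function(image, box) {
  image[box[1]:box[2], box[3]:box[4], drop = FALSE]
}

#' Zero-pad an image to a fixed bounding box
#'
#' Centres the input in a `target[1] x target[2]` zero matrix.  No
#' resampling is performed, preserving both resolution and body shape; an
#' input larger than the target is an error, never silently resized.
#'
#' @param image numeric matrix with dimensions at most `target`.
#' @param target target dimensions, default `c(232, 168)`.
#' @return padded matrix of dimension `target`.
#' @export
pad_to_box <- function(image, target = c(232L, 168L)) {
  d <- dim(image)
  if (any(d > target)) {
    stop_size(sprintf("input %s exceeds target %s", dim_str(image),
                      paste(target, collapse = "x")))
  }
  out <- matrix(0, target[1], target[2])
  r0 <- floor((target[1] - d[1]) / 2)
  c0 <- floor((target[2] - d[2]) / 2)
  out[r0 + seq_len(d[1]), c0 + seq_len(d[2])] <- image
  out
}

#' Fixed-divisor intensity normalization
#'
#' Divides non-ASC images by 2 SUV and CT-ASC images by 5 SUV (divisors
#' chosen so that roughly 90% of clinical intensities land in `[0, 1]`),
#' then clips to `[0, 1]`.  The clipped fraction is attached as attribute
#' `"clipped_frac"`.  [denormalize_suv()] multiplies back; values above the
#' cap are not recoverable (clipping is not invertible).
#'
#' @param image matrix in SUV units.
#' @param role `"non_asc"` or `"ct_asc"`.
#' @return matrix in `[0, 1]`.
#' @export
normalize_suv <- function(image, role = c("non_asc", "ct_asc")) {
  role <- match.arg(role)
  x <- image / SUV_DIVISORS[[role]]
  clipped <- mean(x > 1)
  x <- pmin(pmax(x, 0), 1)
  attr(x, "clipped_frac") <- clipped
  x
}

#' @rdname normalize_suv
#' @export
denormalize_suv <- function(image, role = c("non_asc", "ct_asc")) {
  role <- match.arg(role)
  out <- image * SUV_DIVISORS[[role]]
  attr(out, "clipped_frac") <- NULL
  out
}

#' Per-centre train / validation / test split
#'
#' Per centre, `floor(train_frac * n)` patients form the training share and
#' the remainder the test set; `floor(val_frac * |train share|)` of the
#' training share is held out for validation.  Assignment is by seeded
#' shuffle and deterministic per seed.
#'
#' @param counts named integer vector (or list) of clean patient counts per
#'   centre, or a cohort manifest tibble (clean patients are counted per
#'   centre).
#' @param train_frac training fraction (default 0.8).
#' @param val_frac validation fraction of the training share (default 0.1).
#' @param seed integer seed.
#' @param ids optional named list of patient-id vectors per centre; defaults
#'   to `sprintf("C%02dP%03d", centre, i)`.
#' @return a `cohort_split`: tibble with columns centre_id, patient_id,
#'   subset plus attributes `fractions` and `seed`.
#' @export
split_cohort <- function(counts, train_frac = 0.8, val_frac = 0.1,
                         seed = 0L, ids = NULL) {
  if (is.data.frame(counts)) {
    clean <- counts %>%
      dplyr::filter(.data$artefact_labels == "", .data$role == "ct_asc")
    ids <- split(clean$patient_id, clean$centre_id)
    counts <- vapply(ids, length, integer(1))
  }
  counts <- unlist(counts)
  if (any(counts < 2)) stop_invalid("every centre needs at least 2 clean patients")
  centre_keys <- if (!is.null(names(counts)) && !any(names(counts) == "")) {
    names(counts)
  } else {
    as.character(seq_along(counts))
  }
  rows <- with_seed(seed, {
    lapply(seq_along(counts), function(i) {
      n <- counts[[i]]
      pid <- if (!is.null(ids)) {
        ids[[centre_keys[i]]]
      } else if (!is.na(suppressWarnings(as.integer(centre_keys[i])))) {
        sprintf("C%02dP%03d", as.integer(centre_keys[i]), seq_len(n))
      } else {
        sprintf("%s_P%03d", centre_keys[i], seq_len(n))
      }
      ord <- sample(pid)
      n_train_share <- floor(train_frac * n)
      n_val <- floor(val_frac * n_train_share)
      share <- ord[seq_len(n_train_share)]
      test <- setdiff(ord, share)
      val <- share[seq_len(n_val)]
      train <- setdiff(share, val)
      tibble::tibble(
        centre_id = centre_keys[i],
        patient_id = c(train, val, test),
        subset = c(rep("train", length(train)), rep("validation", n_val),
                   rep("test", length(test)))
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fractions") <- c(train = train_frac, validation = val_frac)
  attr(out, "seed") <- seed
  class(out) <- c("cohort_split", class(out))
  out
}

#' Summarize a cohort split
#' @param x a `cohort_split`.
#' @param ... unused.
#' @return tibble of per-centre subset sizes.
#' @export
split_sizes <- function(x, ...) {
  x %>%
    dplyr::count(.data$centre_id, .data$subset) %>%
    tidyr::pivot_wider(names_from = "subset", values_from = "n",
                       values_fill = 0L)
}

#' Save / load a cohort split as JSON
#' @param split a `cohort_split`.
#' @param path JSON file path.
#' @export
write_split <- function(split, path) {
  by_centre <- split(split, split$centre_id)
  payload <- list(
    fractions = as.list(attr(split, "fractions")),
    seed = attr(split, "seed"),
    centres = lapply(by_centre, function(d) {
      split(d$patient_id, d$subset)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- purrr::imap(payload$centres, function(subsets, cid) {
    purrr::imap(subsets, function(pids, sub) {
      tibble::tibble(centre_id = cid, patient_id = unlist(pids), subset = sub)
    }) %>% dplyr::bind_rows()
  }) %>% dplyr::bind_rows()
  attr(rows, "fractions") <- unlist(payload$fractions)
  attr(rows, "seed") <- payload$seed
  class(rows) <- c("cohort_split", class(rows))
  rows
}

#' Run the full preprocessing chain on a cohort
#'
#' For each patient: convert both roles to SUV, crop to the body contour of
#' the non-ASC image (the same box is applied to both roles so the pair
#' stays co-registered), zero-pad to `target`, and normalize with the fixed
#' divisors.  Returns model-ready `(x, y)` pairs in `[0, 1]`.
#'
#' @param cohort result of [generate_cohort()].
#' @param target common bounding box, default `c(232, 168)`.
#' @return named list (per patient) of lists with elements `x` (normalized
#'   non-ASC), `y` (normalized CT-ASC), `mask` (body support inside the
#'   padded frame), `centre_id`, `patient_id`, `artefacts`.
#' @export
preprocess_cohort <- function(cohort, target = c(232L, 168L)) {
  purrr::map(cohort$pairs, function(pair) {
    preprocess_pair(pair, target)
  })
}

#' @rdname preprocess_cohort
#' @param pair a single `image_pair`.
#' @export
preprocess_pair <- function(pair, target = c(232L, 168L)) {
  suv_non <- to_suv(pair$non_asc, pair$meta)
  suv_ct <- to_suv(pair$ct_asc, pair$meta)
  cr <- crop_to_body(suv_non)
  x <- normalize_suv(pad_to_box(cr$image, target), "non_asc")
  y <- normalize_suv(pad_to_box(apply_crop(suv_ct, cr$box), target), "ct_asc")
  mask <- pad_to_box(apply_crop(
    (pair$aux$scene$body * 1), cr$box), target) > 0
  art_masks <- purrr::map(pair$artefact_labels, function(a) {
    pad_to_box(apply_crop(a$mask * 1, cr$box), target) > 0
  })
  # for artefacted pairs the pre-artefact noise-free CT-ASC gives the clean
  # reference against which correction is scored
  y_clean <- if (length(pair$artefact_labels)) {
    unclass_attr(normalize_suv(pad_to_box(apply_crop(
      to_suv(pair$aux$ct_noisefree, pair$meta), cr$box), target), "ct_asc"))
  } else {
    NULL
  }
  list(x = unclass_attr(x), y = unclass_attr(y), mask = mask,
       centre_id = pair$centre_id, patient_id = pair$patient_id,
       artefacts = art_masks, box = cr$box, y_clean = y_clean)
}

unclass_attr <- function(x) {
  attr(x, "clipped_frac") <- NULL
  x
}
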