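# Synthetic fundus-image generator.
#
# Renders fundus-like images sufficient to exercise the whole pipeline: a
# reddish circular retina field on a dark background, a brighter elliptical
# optic disc, a still brighter concentric optic cup whose radius is
# cup_to_disc_ratio times the disc's geometric-mean radius (so the
# sqrt(cup area / disc area) oracle recovers the ratio exactly up to
# pixelation), dark curvilinear vessels radiating from the disc, a
# multiplicative illumination gradient and additive Gaussian noise. The
# class label follows the clinical screening rule: glaucoma iff the
# cup-to-disc ratio exceeds 0.6.

CDR_THRESHOLD <- 0.6

#' Specify one synthetic fundus image
#'
#' @param image_size side of the square image in pixels.
#' @param disc_center optic-disc centre as (row, col) fractions of the image.
#' @param disc_radius disc semi-major radius as a fraction of the image size.
#' @param cup_to_disc_ratio cup radius over disc radius, in (0, 1); values
#'   above 0.6 are labelled glaucoma.
#' @param n_vessels number of vessel tracks radiating from the disc.
#' @param illumination_gain strength of the multiplicative illumination
#'   gradient (0 = flat).
#' @param noise_sigma standard deviation of the additive Gaussian pixel noise.
#' @param seed integer seed; rendering is fully deterministic given the spec.
#' @return an object of class `fundus_spec`.
#' @export
fundus_spec <- function(image_size = 64L, disc_center = c(0.5, 0.62),
                        disc_radius = 0.15, cup_to_disc_ratio = 0.4,
                        n_vessels = 6L, illumination_gain = 0.1,
                        noise_sigma = 0.02, seed = 1L) {
  if (cup_to_disc_ratio <= 0 || cup_to_disc_ratio >= 1) {
    stopf("cup_to_disc_ratio must be strictly inside (0, 1)")
  }
  if (noise_sigma < 0 || illumination_gain < 0) {
    stopf("noise_sigma and illumination_gain must be nonnegative")
  }
  field_r <- 0.48
  if (any(disc_center - disc_radius < 0.5 - field_r) ||
      any(disc_center + disc_radius > 0.5 + field_r)) {
    stopf("optic disc (centre %.2f, %.2f, radius %.2f) leaves the retina field",
          disc_center[1], disc_center[2], disc_radius)
  }
  structure(list(image_size = as.integer(image_size),
                 disc_center = as.numeric(disc_center),
                 disc_radius = as.numeric(disc_radius),
                 cup_to_disc_ratio = as.numeric(cup_to_disc_ratio),
                 n_vessels = as.integer(n_vessels),
                 illumination_gain = as.numeric(illumination_gain),
                 noise_sigma = as.numeric(noise_sigma),
                 seed = as.integer(seed)),
            class = "fundus_spec")
}

#' Render a synthetic fundus image
#'
#' @param spec a [fundus_spec()].
#' @return a list of class `synthetic_sample`: `image` (an
#'   `(S, S, 3)` array in `[0, 1]`, quantized to 8 bits), `label`
#'   (1 iff `cup_to_disc_ratio > 0.6`), `disc_mask` and `cup_mask`
#'   (logical matrices of the noise-free geometry) and the `spec`.
#' @export
generate_fundus <- function(spec) {
  stopifnot(inherits(spec, "fundus_spec"))
  S <- spec$image_size
  with_seed(spec$seed, {
    rw <- matrix(rep(seq_len(S) - 0.5, S), S, S)          # row coordinate
    cl <- matrix(rep(seq_len(S) - 0.5, each = S), S, S)   # col coordinate
    ctr <- S / 2
    field_r <- 0.48 * S
    dfield <- sqrt((rw - ctr)^2 + (cl - ctr)^2)
    field <- pmin(pmax((field_r - dfield) / 1.5, 0), 1)   # soft rim

    # retina base with mild radial shading
    shade <- 1 - 0.35 * (dfield / field_r)^2
    img <- array(0.04, c(S, S, 3))
    base_col <- c(0.72, 0.33, 0.18)
    for (ch in 1:3) {
      img[, , ch] <- img[, , ch] * (1 - field) + base_col[ch] * shade * field
    }

    # optic disc: ellipse with slight eccentricity, soft 1.5-px edge
    dc <- spec$disc_center * S
    a <- spec$disc_radius * S          # semi-axis along columns
    b <- 0.92 * a                      # semi-axis along rows
    de <- sqrt(((rw - dc[1]) / b)^2 + ((cl - dc[2]) / a)^2)
    # distance in pixels from the ellipse boundary, approximately
    disc_w <- pmin(pmax((1 - de) * sqrt(a * b) / 1.5, 0), 1)
    disc_col <- c(0.95, 0.82, 0.55)
    for (ch in 1:3) {
      img[, , ch] <- img[, , ch] * (1 - disc_w) + disc_col[ch] * disc_w
    }

    # optic cup: concentric circle of radius CDR * geometric-mean disc radius
    rc <- spec$cup_to_disc_ratio * sqrt(a * b)
    dcup <- sqrt((rw - dc[1])^2 + (cl - dc[2])^2)
    cup_w <- pmin(pmax((rc - dcup) / 1.5, 0), 1)
    cup_col <- c(1.0, 0.95, 0.78)
    for (ch in 1:3) {
      img[, , ch] <- img[, , ch] * (1 - cup_w) + cup_col[ch] * cup_w
    }

    # vessels: curvilinear dark tracks radiating from the disc centre
    if (spec$n_vessels > 0) {
      vmask <- matrix(0, S, S)
      angles <- seq(0, 2 * pi, length.out = spec$n_vessels + 1L)[-1L] +
        runif(spec$n_vessels, -0.3, 0.3)
      for (v in seq_len(spec$n_vessels)) {
        curv <- runif(1, -0.6, 0.6)
        phase <- runif(1, 0, 2 * pi)
        tt <- seq(0, 1, length.out = 50L)
        th <- angles[v] + curv * tt + 0.15 * sin(3 * tt * pi + phase)
        rad <- tt * (field_r * 0.92)
        pr <- dc[1] + rad * sin(th)
        pc <- dc[2] + rad * cos(th)
        wpx <- pmax(1, S / 96) * (1.4 - 0.8 * tt)
        for (q in seq_along(tt)) {
          r0 <- round(pr[q]); c0 <- round(pc[q]); wq <- wpx[q]
          lo_r <- max(1, r0 - 2); hi_r <- min(S, r0 + 2)
          lo_c <- max(1, c0 - 2); hi_c <- min(S, c0 + 2)
          if (lo_r > hi_r || lo_c > hi_c) next
          for (rr in lo_r:hi_r) for (cc in lo_c:hi_c) {
            d2 <- (rr - pr[q])^2 + (cc - pc[q])^2
            m <- max(0, 1 - d2 / (wq^2))
            if (m > vmask[rr, cc]) vmask[rr, cc] <- m
          }
        }
      }
      vmask <- vmask * as.numeric(dfield < field_r)
      vessel_col <- c(0.38, 0.10, 0.07)
      for (ch in 1:3) {
        img[, , ch] <- img[, , ch] * (1 - 0.85 * vmask) +
          vessel_col[ch] * 0.85 * vmask
      }
    }

    # multiplicative illumination gradient in a random direction
    theta <- runif(1, 0, 2 * pi)
    grad <- ((rw - ctr) * sin(theta) + (cl - ctr) * cos(theta)) / S
    gain <- 1 + spec$illumination_gain * 2 * grad
    for (ch in 1:3) img[, , ch] <- img[, , ch] * gain

    # additive Gaussian noise, clamp and 8-bit quantization
    if (spec$noise_sigma > 0) {
      img <- img + array(rnorm(length(img), sd = spec$noise_sigma), dim(img))
    }
    img <- round(clamp01(img) * 255) / 255

    structure(list(image = img,
                   label = as.integer(spec$cup_to_disc_ratio > CDR_THRESHOLD),
                   disc_mask = de <= 1,
                   cup_mask = dcup <= rc,
                   spec = spec),
              class = "synthetic_sample")
  })
}

#' Draw the specifications of a synthetic dataset
#'
#' Samples per-image parameters for `n` images organised as two eyes per
#' patient (both eyes share the patient's class; disc positions are
#' mirrored), with cup-to-disc ratios drawn uniformly from the class range.
#'
#' @param n number of images.
#' @param class_balance fraction of glaucoma (label 1) images.
#' @param cdr_normal,cdr_glaucoma uniform CDR ranges for the two classes;
#'   must lie strictly below / above the 0.6 threshold.
#' @param image_size image side in pixels.
#' @param dataset_id dataset identifier written to the manifest.
#' @param seed master seed; per-image render seeds are derived from it.
#' @return data frame with one row per image (patient_id, eye, label, cdr,
#'   geometry and noise parameters, per-image seed).
#' @export
sample_fundus_specs <- function(n, class_balance = 0.5,
                                cdr_normal = c(0.2, 0.5),
                                cdr_glaucoma = c(0.65, 0.9),
                                image_size = 64L, dataset_id = "synthetic",
                                seed = 1L) {
  if (cdr_normal[1] <= 0 || cdr_normal[2] >= CDR_THRESHOLD) {
    stopf("cdr_normal must lie strictly inside (0, %.1f)", CDR_THRESHOLD)
  }
  if (cdr_glaucoma[1] <= CDR_THRESHOLD || cdr_glaucoma[2] >= 1) {
    stopf("cdr_glaucoma must lie strictly inside (%.1f, 1)", CDR_THRESHOLD)
  }
  n_pos <- round(n * class_balance)
  labels <- c(rep(1L, n_pos), rep(0L, n - n_pos))
  with_seed(seed, {
    n_img <- length(labels)
    # pair consecutive same-class images into patients (two eyes each)
    patient <- integer(n_img)
    eye <- character(n_img)
    next_id <- 1L
    for (lab in c(1L, 0L)) {
      idx <- which(labels == lab)
      for (i in seq_along(idx)) {
        patient[idx[i]] <- next_id + (i - 1L) %/% 2L
        eye[idx[i]] <- if (i %% 2L == 1L) "OD" else "OS"
      }
      if (length(idx)) next_id <- next_id + (length(idx) + 1L) %/% 2L
    }
    cdr <- ifelse(labels == 1L,
                  runif(n_img, cdr_glaucoma[1], cdr_glaucoma[2]),
                  runif(n_img, cdr_normal[1], cdr_normal[2]))
    # both eyes of a patient get a similar but not identical CDR
    disc_row <- runif(n_img, 0.44, 0.56)
    disc_col <- ifelse(eye == "OD", runif(n_img, 0.58, 0.68),
                       runif(n_img, 0.32, 0.42))
    df <- data.frame(
      sample = sprintf("s%05d", seq_len(n_img)),
      patient_id = sprintf("P%04d", patient),
      eye = eye,
      dataset_id = dataset_id,
      label = labels,
      cdr = cdr,
      image_size = as.integer(image_size),
      disc_row = disc_row,
      disc_col = disc_col,
      disc_radius = runif(n_img, 0.12, 0.17),
      n_vessels = sample(5:8, n_img, replace = TRUE),
      illumination_gain = runif(n_img, 0.05, 0.2),
      noise_sigma = 0.02,
      seed = vapply(seq_len(n_img), function(i) derive_seed(seed, i), integer(1)),
      stringsAsFactors = FALSE)
    # shuffle rows so class blocks are not ordered on disk
    df[sample(n_img), , drop = FALSE]
  })
}

spec_from_row <- function(row) {
  fundus_spec(image_size = row$image_size,
              disc_center = c(row$disc_row, row$disc_col),
              disc_radius = row$disc_radius,
              cup_to_disc_ratio = row$cdr,
              n_vessels = row$n_vessels,
              illumination_gain = row$illumination_gain,
              noise_sigma = row$noise_sigma,
              seed = row$seed)
}

#' Generate a synthetic fundus dataset on disk
#'
#' Renders `n` images (PNG) plus a manifest CSV compatible with
#' [load_manifest()]. Samples are organised as two eyes per patient so
#' patient-level split protocols are exercised.
#'
#' @inheritParams sample_fundus_specs
#' @param out_dir output directory (created if needed).
#' @return the manifest path, invisibly a full path to `manifest.csv`.
#' @export
generate_dataset <- function(n, class_balance = 0.5,
                             cdr_normal = c(0.2, 0.5),
                             cdr_glaucoma = c(0.65, 0.9),
                             image_size = 64L, out_dir, seed = 1L,
                             dataset_id = "synthetic") {
  specs <- sample_fundus_specs(n, class_balance, cdr_normal, cdr_glaucoma,
                               image_size, dataset_id, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(specs))
  for (i in seq_len(nrow(specs))) {
    row <- specs[i, ]
    sm <- generate_fundus(spec_from_row(row))
    paths[i] <- file.path(out_dir, paste0(row$sample, ".png"))
    png::writePNG(sm$image, paths[i])
  }
  manifest <- data.frame(image_path = paths,
                         label = specs$label,
                         patient_id = specs$patient_id,
                         dataset_id = specs$dataset_id,
                         cdr = specs$cdr,
                         eye = specs$eye,
                         stringsAsFactors = FALSE)
  mpath <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  mpath
}

#' Read an image file as an (H, W, 3) array in [0, 1]
#'
#' Accepts 8-bit RGB, RGBA (alpha dropped) or grayscale (replicated) PNGs.
#' @param path image path.
#' @return `(H, W, 3)` double array.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), c(dim(img), 3L))
  } else if (dim(img)[3] == 4L) {
    img <- img[, , 1:3, drop = FALSE]
  } else if (dim(img)[3] == 2L) {
    img <- array(rep(img[, , 1L], 3L), c(dim(img)[1:2], 3L))
  }
  img
}
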