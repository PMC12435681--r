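# Class-conditional synthetic histopathology patches. IHC patches show blue
# elliptical nuclei on a pale background; a score-dependent fraction of cells
# carries a brown DAB membrane ring whose staining intensity and arc
# completeness grow with the HER2 score (the ASCO/CAP factors). H&E patches
# show purple nuclei on pink cytoplasm, with the class signal carried only by
# subtle morphology (nucleus density and size), mimicking the absence of
# explicit HER2 markers in routine stains.

#' Default HER2 class profiles for the synthetic generator
#'
#' Each score maps to the three ASCO/CAP generative factors: the fraction of
#' cells with membrane staining, the DAB staining intensity, and the arc
#' completeness of each cell's ring. Intensity and completeness are
#' non-decreasing in score.
#'
#' @return A data frame with columns `her2_score`, `positive_cell_fraction`,
#'   `membrane_intensity`, `membrane_completeness`.
#' @export
class_profiles <- function() {
  data.frame(
    her2_score = c("0", "1+", "2+", "3+"),
    positive_cell_fraction = c(0.02, 0.3, 0.5, 0.7),
    membrane_intensity = c(0.05, 0.3, 0.5, 0.9),
    membrane_completeness = c(0.1, 0.4, 0.9, 1.0),
    stringsAsFactors = FALSE)
}

# benign/malignant H&E profiles with a strong morphological gap, emulating a
# routine-stain tumour-detection corpus used for domain-specific pretraining
breakhis_like_profiles <- function() {
  data.frame(label = c("benign", "malignant"),
             density_mult = c(0.6, 1.7),
             size_mult = c(0.85, 1.35),
             stringsAsFactors = FALSE)
}

#' Draw a per-patient style
#'
#' One small hue rotation (about the gray axis) and brightness offset drawn
#' per patient; all patches of a patient share it. This is what makes random
#' patch-wise splits optimistic relative to subject-wise splits.
#'
#' @return A list with `hue` (radians) and `brightness`.
#' @export
patient_style <- function() {
  list(hue = stats::rnorm(1, 0, 0.10), brightness = stats::rnorm(1, 0, 0.05))
}

# rotate RGB about the gray axis by `angle` radians, then shift brightness
apply_style <- function(img, style) {
  if (is.null(style)) return(img)
  ca <- cos(style$hue); sa <- sin(style$hue)
  s3 <- 1 / sqrt(3)
  # Rodrigues rotation matrix about (1,1,1)/sqrt(3)
  K <- matrix(c(0, s3, -s3, -s3, 0, s3, s3, -s3, 0), 3, 3)
  R <- diag(3) + sa * K + (1 - ca) * (K %*% K)
  d <- dim(img)
  m <- matrix(img, ncol = 3) %*% t(R) + style$brightness
  array(pmin(pmax(m, 0), 1), d)
}

#' Generate one synthetic histopathology patch
#'
#' Draws non-overlapping elliptical cells on a stain-appropriate background.
#' For IHC, a `positive_cell_fraction` of cells carries a brown membrane ring
#' of the profile's intensity and arc completeness; the returned mask is the
#' union of ring pixels. For H&E the class signal is morphological only
#' (nucleus density and size grow mildly with score) and the mask is empty.
#' Uses the current R random number stream: seed it for reproducibility.
#'
#' @param profile One row of [class_profiles()] (or a list with the same
#'   fields).
#' @param stain `"IHC"` or `"HE"`.
#' @param size Patch side in pixels (>= 64).
#' @param style Optional [patient_style()].
#' @param density_mult,size_mult Morphology multipliers (used by the H&E
#'   pretraining task; default 1).
#' @return A list: `image`, an `(size, size, 3)` array in 0-1, and `mask`, a
#'   `(size, size)` 0/1 matrix of membrane-ring pixels.
#' @export
#' @examples
#' set.seed(1)
#' p <- generate_patch(class_profiles()[4, ], "IHC", size = 64)
#' dim(p$image)
generate_patch <- function(profile, stain = c("IHC", "HE"), size = 128,
                           style = NULL, density_mult = 1, size_mult = 1) {
  stain <- match.arg(stain)
  if (size < 64) stop("size must be >= 64 to place at least one cell")
  img <- array(0, c(size, size, 3))
  mask <- matrix(0, size, size)
  bg <- if (stain == "IHC") c(0.93, 0.90, 0.92) else c(0.93, 0.78, 0.85)
  for (k in 1:3) img[, , k] <- bg[k] + stats::rnorm(size^2, 0, 0.015)
  if (stain == "HE") {
    # low-frequency eosin texture
    gx <- outer(seq_len(size), rep(1, size)) / size
    tex <- 0.04 * sin(2 * pi * (gx * stats::runif(1, 1, 3) +
                                t(gx) * stats::runif(1, 1, 3) +
                                stats::runif(1)))
    img[, , 1] <- img[, , 1] + tex
    img[, , 3] <- img[, , 3] + tex
  }
  score_idx <- match(profile$her2_score %||% "0", c("0", "1+", "2+", "3+"))
  if (is.na(score_idx)) score_idx <- 1
  base_density <- if (stain == "IHC") 30 else 26 + 3 * (score_idx - 1)
  n_cells <- max(1L, round(base_density * density_mult * (size / 128)^2 *
                           stats::runif(1, 0.85, 1.15)))
  szm <- size_mult * if (stain == "HE") 1 + 0.05 * (score_idx - 1) else 1
  centers <- matrix(NA_real_, 0, 2)
  radius <- numeric(0)
  tries <- 0
  while (nrow(centers) < n_cells && tries < n_cells * 30) {
    tries <- tries + 1
    r <- stats::runif(1, 0.045, 0.07) * 128 * szm * (size / 128)
    cx <- stats::runif(1, r + 2, size - r - 2)
    cy <- stats::runif(1, r + 2, size - r - 2)
    if (nrow(centers) == 0 ||
        all((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2 >
            (1.9 * pmax(radius, r))^2)) {
      centers <- rbind(centers, c(cx, cy))
      radius <- c(radius, r)
    }
  }
  n_placed <- nrow(centers)
  if (n_placed == 0) stop("patch too small to place one cell")
  positive <- stats::runif(n_placed) < (profile$positive_cell_fraction %||% 0)
  nucleus_col <- if (stain == "IHC") c(0.36, 0.36, 0.68) else c(0.45, 0.30, 0.62)
  dab <- c(0.45, 0.27, 0.10)
  xs <- seq_len(size)
  for (i in seq_len(n_placed)) {
    cx <- centers[i, 1]; cy <- centers[i, 2]; r <- radius[i]
    asp <- stats::runif(1, 0.8, 1.25)
    th <- stats::runif(1, 0, pi)
    lo <- pmax(1L, floor(c(cx, cy) - 1.6 * r))
    hi <- pmin(size, ceiling(c(cx, cy) + 1.6 * r))
    ix <- xs[lo[1]:hi[1]]; iy <- xs[lo[2]:hi[2]]
    dx <- outer(ix - cx, rep(1, length(iy)))
    dy <- outer(rep(1, length(ix)), iy - cy)
    u <- dx * cos(th) + dy * sin(th)
    v <- (-dx * sin(th) + dy * cos(th)) / asp
    rad <- sqrt(u^2 + v^2)
    inside <- rad <= 0.85 * r
    blend <- function(ch, col, m, amount = 1) {
      blk <- img[lo[1]:hi[1], lo[2]:hi[2], ch]
      blk[m] <- (1 - amount) * blk[m] + amount * col
      img[lo[1]:hi[1], lo[2]:hi[2], ch] <<- blk
    }
    for (k in 1:3)
      blend(k, nucleus_col[k] + stats::rnorm(1, 0, 0.02), inside)
    if (stain == "IHC" && positive[i]) {
      comp <- profile$membrane_completeness %||% 1
      inten <- profile$membrane_intensity %||% 1
      ring <- rad > 0.85 * r & rad <= 1.25 * r
      if (comp < 1) {
        ang <- atan2(v, u)
        start <- stats::runif(1, -pi, pi)
        span <- ((ang - start) %% (2 * pi))
        ring <- ring & span <= comp * 2 * pi
      }
      for (k in 1:3) blend(k, dab[k], ring, amount = 0.25 + 0.75 * inten)
      mb <- mask[lo[1]:hi[1], lo[2]:hi[2]]
      mb[ring] <- 1
      mask[lo[1]:hi[1], lo[2]:hi[2]] <- mb
    }
  }
  img <- apply_style(img, style)
  list(image = pmin(pmax(img, 0), 1), mask = mask)
}

#' Generate a synthetic patient cohort
#'
#' Assigns each patient one HER2 score according to `class_mix`, draws one
#' style per patient, and renders `patches_per_patient` patches (with masks
#' for IHC). Fully reproducible from `seed`.
#'
#' @param n_patients Number of patients (at least one per class in
#'   `class_mix`).
#' @param patches_per_patient Patches rendered per patient.
#' @param stain `"IHC"` or `"HE"`.
#' @param class_mix Named proportions over HER2 scores (default balanced over
#'   all four). Patient counts are allocated by largest remainder; a class
#'   that would receive no patients is an error.
#' @param size Patch side in pixels.
#' @param seed Integer seed.
#' @param dir Optional directory: when given, images and masks are written as
#'   PNGs and a `manifest.csv` is written alongside.
#' @return A list of class `her2_cohort`: `manifest` (data frame with columns
#'   `path`, `patient_id`, `stain`, `her2_score`, `mask_path`), `images` and
#'   `masks` (lists, in manifest order), and the generation parameters.
#' @export
generate_cohort <- function(n_patients, patches_per_patient,
                            stain = c("IHC", "HE"),
                            class_mix = NULL, size = 128, seed = 1L,
                            dir = NULL) {
  stain <- match.arg(stain)
  if (is.null(class_mix))
    class_mix <- stats::setNames(rep(0.25, 4), c("0", "1+", "2+", "3+"))
  bad <- setdiff(names(class_mix), her2_scores)
  if (length(bad)) stop("unknown scores in class_mix: ",
                        paste(bad, collapse = ", "))
  if (n_patients < length(class_mix))
    stop("need at least one patient per class: ", n_patients, " patients for ",
         length(class_mix), " classes")
  prop <- class_mix / sum(class_mix)
  raw <- prop * n_patients
  cnt <- floor(raw)
  rem <- n_patients - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  if (any(cnt == 0)) stop("impossible class_mix: some class receives no patients")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  scores <- rep(names(class_mix), cnt)
  profiles <- class_profiles()
  images <- list(); masks <- list(); rows <- list()
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%03d", p)
    sc <- scores[p]
    style <- patient_style()
    prof <- profiles[profiles$her2_score == sc, ]
    for (j in seq_len(patches_per_patient)) {
      g <- generate_patch(prof, stain, size, style)
      idx <- length(images) + 1L
      images[[idx]] <- g$image
      masks[[idx]] <- g$mask
      rows[[idx]] <- data.frame(
        path = sprintf("%s_patch%02d.png", pid, j),
        patient_id = pid, stain = stain, her2_score = sc,
        mask_path = if (stain == "IHC") sprintf("%s_patch%02d_mask.png", pid, j)
                    else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(manifest))) {
      png::writePNG(images[[i]], file.path(dir, manifest$path[i]))
      if (!is.na(manifest$mask_path[i]))
        png::writePNG(masks[[i]], file.path(dir, manifest$mask_path[i]))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(manifest = manifest, images = images, masks = masks,
                 stain = stain, size = size, seed = seed, dir = dir),
            class = "her2_cohort")
}

#' @export
print.her2_cohort <- function(x, ...) {
  cat(sprintf("Synthetic %s cohort: %d patches, %d patients, %dx%d px\n",
              x$stain, nrow(x$manifest),
              length(unique(x$manifest$patient_id)), x$size, x$size))
  print(table(score = x$manifest$her2_score))
  invisible(x)
}

#' Generate a benign/malignant H&E pretraining cohort
#'
#' A routine-stain tumour-detection task with a strong morphological class
#' signal (benign: sparse small regular nuclei; malignant: dense enlarged
#' nuclei), used as the source task for domain-specific pretraining before
#' fine-tuning on the subtle-signal HER2 H&E task.
#'
#' @inheritParams generate_cohort
#' @return A `her2_cohort` whose manifest carries `her2_score` values
#'   `"benign"`/`"malignant"` (labels, not HER2 scores).
#' @export
generate_tumor_cohort <- function(n_patients, patches_per_patient,
                                  size = 128, seed = 1L, dir = NULL) {
  if (n_patients < 2) stop("need at least 2 patients (one per class)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  prof <- breakhis_like_profiles()
  lab <- rep(prof$label, length.out = n_patients)
  images <- list(); masks <- list(); rows <- list()
  neutral <- list(her2_score = "0", positive_cell_fraction = 0)
  for (p in seq_len(n_patients)) {
    pid <- sprintf("S%03d", p)
    pr <- prof[prof$label == lab[p], ]
    style <- patient_style()
    for (j in seq_len(patches_per_patient)) {
      g <- generate_patch(neutral, "HE", size, style,
                          density_mult = pr$density_mult,
                          size_mult = pr$size_mult)
      idx <- length(images) + 1L
      images[[idx]] <- g$image
      masks[[idx]] <- g$mask
      rows[[idx]] <- data.frame(
        path = sprintf("%s_patch%02d.png", pid, j), patient_id = pid,
        stain = "HE", her2_score = lab[p], mask_path = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(manifest)))
      png::writePNG(images[[i]], file.path(dir, manifest$path[i]))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(manifest = manifest, images = images, masks = masks,
                 stain = "HE", size = size, seed = seed, dir = dir),
            class = "her2_cohort")
}

#' Binary benign/malignant arrays from a tumour cohort
#'
#' @param cohort A cohort from [generate_tumor_cohort()].
#' @return The same structure as [cohort_data()].
#' @export
tumor_data <- function(cohort) {
  lab <- factor(cohort$manifest$her2_score, c("benign", "malignant"))
  x <- array(unlist(cohort$images), c(dim(cohort$images[[1]]),
                                      nrow(cohort$manifest)))
  list(x = x, y = as.integer(lab) - 1L, labels = lab,
       patient = cohort$manifest$patient_id,
       index = seq_len(nrow(cohort$manifest)),
       levels = levels(lab))
}

#' Load a cohort written to disk
#'
#' @param dir Directory containing `manifest.csv` and the PNGs written by
#'   [generate_cohort()].
#' @return A `her2_cohort`.
#' @export
load_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  images <- lapply(manifest$path, function(p) {
    im <- png::readPNG(file.path(dir, p))
    if (length(dim(im)) == 2) array(im, c(dim(im), 3)) else im[, , 1:3]
  })
  masks <- lapply(seq_len(nrow(manifest)), function(i) {
    mp <- manifest$mask_path[i]
    if (is.na(mp)) matrix(0, dim(images[[i]])[1], dim(images[[i]])[2])
    else round(png::readPNG(file.path(dir, mp)))
  })
  structure(list(manifest = manifest, images = images, masks = masks,
                 stain = manifest$stain[1], size = dim(images[[1]])[1],
                 seed = NA_integer_, dir = dir),
            class = "her2_cohort")
}

#' Assemble model-ready arrays from a cohort
#'
#' Applies a HER2 label scheme (dropping excluded scores), and stacks images
#' into an `(H, W, 3, N)` batch with 0-based integer labels.
#'
#' @param cohort A `her2_cohort`.
#' @param scheme A [label_scheme()] or its name.
#' @param records Optional manifest subset (e.g. one side of a split).
#' @return A list: `x`, `y` (0-based integers), `labels` (factor), `patient`,
#'   `index` (rows of the cohort manifest used), `levels`.
#' @export
cohort_data <- function(cohort, scheme = "binary", records = NULL) {
  man <- records %||% cohort$manifest
  idx <- match(interaction(man$patient_id, man$path),
               interaction(cohort$manifest$patient_id, cohort$manifest$path))
  g <- group_labels(man$her2_score, scheme)
  idx <- idx[g$keep]
  x <- array(unlist(cohort$images[idx]),
             c(dim(cohort$images[[1]]), length(idx)))
  list(x = x, y = as.integer(g$labels) - 1L, labels = g$labels,
       patient = man$patient_id[g$keep], index = idx,
       levels = levels(g$labels))
}

split_fraction_check <- function(test_fraction) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly between 0 and 1")
}

#' Random patch-wise train/test split
#'
#' Splits individual patches at random, so one patient's patches can appear on
#' both sides (the optimistic protocol).
#'
#' @param manifest A cohort manifest data frame.
#' @param test_fraction Fraction of patches assigned to test (0 < f < 1).
#' @param seed Integer seed.
#' @return A list of class `split_result`: `train`, `test` (manifest subsets)
#'   and `mode`.
#' @export
split_random <- function(manifest, test_fraction, seed = 1L) {
  split_fraction_check(test_fraction)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- nrow(manifest)
  ts <- sample(n, round(n * test_fraction))
  structure(list(train = manifest[-ts, , drop = FALSE],
                 test = manifest[ts, , drop = FALSE], mode = "random"),
            class = "split_result")
}

#' Subject-wise train/test split
#'
#' Splits whole patients (class-stratified over patients), so the patient-id
#' sets of train and test are disjoint — the protocol that measures
#' generalization to unseen patients.
#'
#' @inheritParams split_random
#' @export
split_subjectwise <- function(manifest, test_fraction, seed = 1L) {
  split_fraction_check(test_fraction)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pat <- unique(manifest[, c("patient_id", "her2_score")])
  if (any(table(pat$her2_score) < 2))
    stop("too few patients for a stratified subject-wise split: ",
         "every class needs at least 2 patients")
  target <- round(nrow(pat) * test_fraction)
  raw <- tapply(rep(1, nrow(pat)), pat$her2_score, sum) * test_fraction
  cnt <- floor(raw)
  rem <- target - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    ord <- order(raw - cnt)
    k <- 0
    for (j in ord) {
      if (k == -rem) break
      if (cnt[j] > 0) { cnt[j] <- cnt[j] - 1; k <- k + 1 }
    }
  }
  test_pat <- character()
  for (sc in names(cnt)) {
    pool <- pat$patient_id[pat$her2_score == sc]
    if (cnt[sc] >= length(pool))
      stop("too few patients in class ", sc, " for test_fraction ",
           test_fraction)
    test_pat <- c(test_pat, sample(pool, cnt[sc]))
  }
  ts <- manifest$patient_id %in% test_pat
  structure(list(train = manifest[!ts, , drop = FALSE],
                 test = manifest[ts, , drop = FALSE], mode = "subject_wise"),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("%s split: %d train / %d test patches (%d / %d patients)\n",
              x$mode, nrow(x$train), nrow(x$test),
              length(unique(x$train$patient_id)),
              length(unique(x$test$patient_id))))
  invisible(x)
}
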