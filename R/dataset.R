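#' Micro-Doppler signature dataset container
#'
#' A lightweight container: `images` is an integer array `75 x 75 x n`
#' (grayscale 0..255), `labels` a factor over [activity_classes()],
#' `subject` and `repetition` integer vectors of length `n`.
#'
#' @param images integer array `h x w x n`.
#' @param labels factor or character vector of length `n`.
#' @param subject integer vector of subject identifiers.
#' @param repetition integer vector of repetition indices.
#' @return object of class `md_dataset`.
#' @export
md_dataset <- function(images, labels, subject, repetition) {
  n <- dim(images)[3]
  labels <- factor(as.character(labels), levels = activity_classes())
  stopifnot(length(labels) == n, length(subject) == n, length(repetition) == n,
            !anyNA(labels))
  structure(list(images = images, labels = labels,
                 subject = as.integer(subject),
                 repetition = as.integer(repetition)),
            class = "md_dataset")
}

#' @export
length.md_dataset <- function(x) dim(x$images)[3]

#' @export
`[.md_dataset` <- function(x, i) {
  md_dataset(x$images[, , i, drop = FALSE], x$labels[i],
             x$subject[i], x$repetition[i])
}

#' @export
print.md_dataset <- function(x, ...) {
  cat(sprintf("md_dataset: %d signatures (%d x %d), %d subjects\n",
              length(x), dim(x$images)[1], dim(x$images)[2],
              length(unique(x$subject))))
  print(table(x$labels))
  invisible(x)
}

#' Generate a labeled synthetic micro-Doppler dataset
#'
#' Simulates the full signal chain (baseband superposition, range DFT,
#' range-bin summation, spectrogram, 75 x 75 grayscale export) for a
#' population of subjects performing the six activities. Per-subject
#' kinematic parameters (speed scale, limb-amplitude scale, standoff range,
#' onset time) are drawn once per subject and shared across that subject's
#' repetitions; each repetition adds small onset/phase jitters and a fresh
#' noise realization. The default geometry emulates a 570-signature corpus:
#' 95 signatures per class from 33 subjects, each repeating an activity two
#' or three times.
#'
#' @param templates named list from [activity_templates()].
#' @param n_subjects number of simulated subjects.
#' @param per_class signatures per class (must be achievable with 2-3
#'   repetitions per subject).
#' @param seed integer seed; the dataset is a deterministic function of it.
#' @param params radar parameters; default [radar_params()].
#' @param sp spectrogram parameters; default [spectrogram_params()].
#' @param snr_db per-sample signal-to-noise ratio of the complex baseband.
#' @param doppler_lim Doppler crop passed to [export_signature()].
#' @param progress print a dot per 50 signatures.
#' @return an [md_dataset()].
#' @export
generate_dataset <- function(templates = activity_templates(),
                             n_subjects = 33L, per_class = 95L,
                             seed = 1L, params = radar_params(),
                             sp = spectrogram_params(), snr_db = 18,
                             doppler_lim = c(-250, 250), progress = FALSE) {
  stopifnot(n_subjects >= 1, all(activity_classes() %in% names(templates)))
  if (per_class < 2L * n_subjects || per_class > 3L * n_subjects)
    stop("per_class must lie in [2, 3] repetitions x n_subjects")
  set.seed(as.integer(seed))
  subjects <- lapply(seq_len(n_subjects), function(i) list(
    speed = stats::runif(1, 0.85, 1.15),
    amp = stats::runif(1, 0.8, 1.2),
    r0 = stats::runif(1, 2.6, 3.4),
    t0 = stats::runif(1, 0.25, 0.55)
  ))
  classes <- activity_classes()
  n_total <- length(classes) * per_class
  images <- array(0L, c(75, 75, n_total))
  labels <- character(n_total); subj_id <- integer(n_total)
  rep_id <- integer(n_total)
  k <- 0L
  for (cl in classes) {
    # choose which subjects contribute 3 repetitions (the rest give 2)
    n3 <- per_class - 2L * n_subjects
    three <- sample(n_subjects, n3)
    for (s in seq_len(n_subjects)) {
      nrep <- if (s %in% three) 3L else 2L
      for (r in seq_len(nrep)) {
        rng <- function(lo, hi) stats::runif(1, lo, hi)
        scs <- templates[[cl]](subjects[[s]], rng)
        sb <- simulate_baseband(scs, params)
        # complex white noise at the requested per-sample SNR
        psig <- mean(Mod(sb)^2)
        nsd <- sqrt(psig / (10^(snr_db / 10)) / 2)
        sb <- sb + nsd * (matrix(stats::rnorm(length(sb)), nrow(sb)) +
                            1i * matrix(stats::rnorm(length(sb)), nrow(sb)))
        gate <- range_gate(scs, params)
        v <- sum_range_bins(compute_range_map(sb, params), gate$p1, gate$p2)
        D <- compute_spectrogram(v, sp)
        img <- export_signature(D, sp, params$prf, doppler_lim = doppler_lim)
        k <- k + 1L
        images[, , k] <- img
        labels[k] <- cl; subj_id[k] <- s; rep_id[k] <- r
        if (progress && k %% 50L == 0L) cat(".")
      }
    }
  }
  if (progress) cat("\n")
  md_dataset(images, labels, subj_id, rep_id)
}

#' Write a dataset as PNG files plus a CSV manifest
#'
#' One 8-bit grayscale PNG per signature and a `manifest.csv` with columns
#' `path, class_label, subject_id, repetition_id`.
#'
#' @param ds an [md_dataset()].
#' @param dir output directory (created if missing).
#' @return the manifest data frame, invisibly.
#' @export
write_signatures <- function(ds, dir) {
  stopifnot(inherits(ds, "md_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(ds)
  paths <- sprintf("%s_s%02d_r%d_%04d.png", as.character(ds$labels),
                   ds$subject, ds$repetition, seq_len(n))
  for (i in seq_len(n))
    png::writePNG(ds$images[, , i] / 255, file.path(dir, paths[i]))
  manifest <- data.frame(path = paths, class_label = as.character(ds$labels),
                         subject_id = ds$subject,
                         repetition_id = ds$repetition)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a signature dataset from PNG files
#'
#' Reads 75 x 75 grayscale images listed in a `manifest.csv` (as written by
#' [write_signatures()]); externally produced corpora in the same layout —
#' e.g. measured micro-Doppler images following the identical 75 x 75
#' grayscale contract — are ingested the same way. Images of other sizes
#' are bilinearly rescaled to 75 x 75; RGB images are converted to
#' luminance.
#'
#' @param dir directory containing `manifest.csv` and the images.
#' @return an [md_dataset()].
#' @export
read_signatures <- function(dir) {
  mf <- utils::read.csv(file.path(dir, "manifest.csv"),
                        stringsAsFactors = FALSE)
  n <- nrow(mf)
  images <- array(0L, c(75, 75, n))
  for (i in seq_len(n)) {
    img <- png::readPNG(file.path(dir, mf$path[i]))
    if (length(dim(img)) == 3L) img <- apply(img[, , 1:3], c(1, 2), mean)
    if (!all(dim(img) == c(75, 75))) {
      img <- t(EBImage::imageData(EBImage::resize(EBImage::Image(t(img)),
                                                  w = 75, h = 75)))
    }
    images[, , i] <- as.integer(round(img * 255))
  }
  md_dataset(images, mf$class_label, mf$subject_id, mf$repetition_id)
}

#' Subject-wise train/test split
#'
#' Partitions a dataset by subject identity: `n_train` subjects are drawn
#' at random for training and `n_test` of the remaining subjects for
#' testing, so no subject contributes to both sides. Measures
#' generalization to unseen persons.
#'
#' @param ds an [md_dataset()].
#' @param n_train,n_test numbers of training and test subjects.
#' @param seed integer seed for the subject draw.
#' @return list with elements `train`, `test` ([md_dataset()]s) and the
#'   drawn `train_subjects`, `test_subjects`.
#' @export
subject_wise_split <- function(ds, n_train = 27L, n_test = 6L, seed = 1L) {
  subs <- sort(unique(ds$subject))
  if (length(subs) < n_train + n_test)
    stop("fewer subjects than requested for the split")
  set.seed(as.integer(seed))
  tr <- subs[sample.int(length(subs), n_train)]
  pool <- setdiff(subs, tr)
  te <- pool[sample.int(length(pool), n_test)]
  list(train = ds[ds$subject %in% tr], test = ds[ds$subject %in% te],
       train_subjects = sort(tr), test_subjects = sort(te))
}
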