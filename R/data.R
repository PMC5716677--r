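#' Synthetic class-structured dataset
#'
#' A no-download stand-in for image data: each class has a fixed random
#' smooth prototype intensity vector in `[0,1]` (Gaussian noise smoothed
#' with a circular moving average, then min-max rescaled) and samples are
#' the prototype plus i.i.d. Gaussian pixel noise, clipped to `[0,1]`.
#' Class prototypes can be shrunk toward their common mean by
#' `class_contrast`, which sets the task difficulty: at the default 1 the
#' prototypes are independent and a few training epochs suffice for
#' near-perfect classification; lower values (around 0.2 the task reaches
#' the generator's separability floor: a one-pass nearest-class-mean
#' classifier on the training draw must reach at least 95% accuracy) expose
#' the slow-learning transient regime.
#'
#' @param n_classes Number of classes (>= 2).
#' @param input_dim Intensity-vector dimensionality.
#' @param n_per_class Samples per class.
#' @param noise_sd Pixel noise standard deviation.
#' @param class_contrast Prototype spread around the shared background, in
#'   (0, 1].
#' @param check_separability Verify centroid separability (disable only for
#'   deliberately hard datasets).
#' @param prototypes Optional `n_classes x input_dim` prototype matrix to
#'   reuse (e.g. to draw an independent test set from the same classes as a
#'   training set); new prototypes are drawn when `NULL`.
#' @return A `dendrite_dataset`: list with `images` (`n x input_dim` matrix
#'   in `[0,1]`), `labels` (0-based integers), `n_classes`, `input_dim`, and
#'   the class `prototypes`.
#' @examples
#' set.seed(1)
#' d <- synthetic_dataset(3, 16, 10)
#' table(d$labels)
#' @export
synthetic_dataset <- function(n_classes = 10, input_dim = 64,
                              n_per_class = 200, noise_sd = 0.08,
                              class_contrast = 1,
                              check_separability = TRUE,
                              prototypes = NULL) {
  stopifnot(n_classes >= 2, input_dim >= 2, n_per_class >= 1, noise_sd >= 0,
            class_contrast > 0, class_contrast <= 1)
  if (is.null(prototypes)) {
    w <- max(3L, input_dim %/% 8L)
    protos <- t(vapply(seq_len(n_classes), function(k) {
      z <- stats::rnorm(input_dim)
      z <- as.numeric(stats::filter(z, rep(1 / w, w), circular = TRUE))
      (z - min(z)) / (max(z) - min(z))
    }, numeric(input_dim)))
    bg <- colMeans(protos)
    protos <- sweep(class_contrast * sweep(protos, 2, bg), 2, bg, "+")
  } else {
    protos <- as.matrix(prototypes)
    stopifnot(nrow(protos) == n_classes, ncol(protos) == input_dim)
  }

  n <- n_classes * n_per_class
  labels <- rep(seq_len(n_classes) - 1L, each = n_per_class)
  images <- protos[labels + 1L, , drop = FALSE] +
    matrix(stats::rnorm(n * input_dim, 0, noise_sd), n, input_dim)
  images[] <- pmin(1, pmax(0, images))

  ds <- structure(list(images = images, labels = labels,
                       n_classes = n_classes, input_dim = input_dim,
                       prototypes = protos),
                  class = "dendrite_dataset")
  if (check_separability) {
    cent <- t(vapply(seq_len(n_classes) - 1L, function(k) {
      colMeans(images[labels == k, , drop = FALSE])
    }, numeric(input_dim)))
    d2 <- outer(rowSums(images^2), rep(1, n_classes)) -
      2 * images %*% t(cent) + outer(rep(1, n), rowSums(cent^2))
    acc <- mean(max.col(-d2) - 1L == labels)
    if (acc < 0.95) {
      stop("synthetic classes are not separable (centroid accuracy ",
           round(100 * acc, 1), "%); lower noise_sd", call. = FALSE)
    }
  }
  ds
}

#' @export
print.dendrite_dataset <- function(x, ...) {
  cat("<dendrite_dataset> ", nrow(x$images), " samples x ", x$input_dim,
      " intensities, ", x$n_classes, " classes\n", sep = "")
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.dendrite_dataset <- function(x, ...) {
  m <- tibble::as_tibble(as.data.frame(x$images),
                         .name_repair = ~ paste0("x", seq_along(.x)))
  dplyr::bind_cols(tibble::tibble(label = x$labels), m)
}

#' Encode intensities as input firing rates
#'
#' Input-unit firing rates are proportional to pixel brightness:
#' `rate = intensity * phi_max`, spanning `[0, phi_max]` spikes/ms.
#'
#' @param image Intensity vector in `[0, 1]`.
#' @param phi_max Maximum firing rate (spikes/ms).
#' @return Rate vector (spikes/ms).
#' @export
rates_from_image <- function(image, phi_max = 0.2) {
  if (any(image < 0) || any(image > 1)) {
    stop("intensities must lie in [0, 1]", call. = FALSE)
  }
  image * phi_max
}

read_be_int <- function(con, n = 1) {
  readBin(con, "integer", n = n, size = 4, endian = "big")
}

#' Read an MNIST-style IDX dataset
#'
#' Parses the big-endian IDX (ubyte) containers used by the MNIST database:
#' magic 2051 for images (count x rows x cols) and 2049 for labels. Pixel
#' bytes are scaled to intensities in `[0, 1]`.
#'
#' @param images_path,labels_path Paths to the image and label files
#'   (uncompressed).
#' @return A `dendrite_dataset`.
#' @export
read_idx <- function(images_path, labels_path) {
  ic <- file(images_path, "rb"); on.exit(close(ic), add = TRUE)
  magic <- read_be_int(ic)
  if (!identical(magic, 2051L)) {
    stop("bad image magic number at offset 0: ", magic, call. = FALSE)
  }
  n <- read_be_int(ic); nr <- read_be_int(ic); nc <- read_be_int(ic)
  npix <- n * nr * nc
  raw_px <- readBin(ic, "raw", n = npix)
  if (length(raw_px) < npix) {
    stop("truncated image payload at offset ", 16 + length(raw_px),
         call. = FALSE)
  }
  lc <- file(labels_path, "rb"); on.exit(close(lc), add = TRUE)
  lmagic <- read_be_int(lc)
  if (!identical(lmagic, 2049L)) {
    stop("bad label magic number at offset 0: ", lmagic, call. = FALSE)
  }
  nl <- read_be_int(lc)
  if (!identical(nl, n)) {
    stop("image/label count mismatch: ", n, " vs ", nl, call. = FALSE)
  }
  raw_lb <- readBin(lc, "raw", n = nl)
  if (length(raw_lb) < nl) {
    stop("truncated label payload at offset ", 8 + length(raw_lb),
         call. = FALSE)
  }
  images <- matrix(as.integer(raw_px), nrow = n, ncol = nr * nc,
                   byrow = TRUE) / 255
  labels <- as.integer(raw_lb)
  structure(list(images = images, labels = labels,
                 n_classes = max(labels) + 1L, input_dim = nr * nc,
                 prototypes = NULL),
            class = "dendrite_dataset")
}

#' Write a dataset in IDX format
#'
#' Inverse of [read_idx()]; intensities are quantised to bytes. Useful for
#' building fixtures and for round-trip testing.
#'
#' @param dataset A `dendrite_dataset`.
#' @param images_path,labels_path Output paths.
#' @param rows,cols Image shape; defaults to a 1 x input_dim layout.
#' @return Invisibly, the two paths.
#' @export
write_idx <- function(dataset, images_path, labels_path,
                      rows = 1L, cols = dataset$input_dim) {
  stopifnot(rows * cols == dataset$input_dim)
  n <- nrow(dataset$images)
  ic <- file(images_path, "wb"); on.exit(close(ic), add = TRUE)
  writeBin(c(2051L, n, as.integer(rows), as.integer(cols)), ic,
           size = 4, endian = "big")
  writeBin(as.raw(round(t(dataset$images) * 255)), ic)
  lc <- file(labels_path, "wb"); on.exit(close(lc), add = TRUE)
  writeBin(c(2049L, n), lc, size = 4, endian = "big")
  writeBin(as.raw(dataset$labels), lc)
  invisible(c(images_path, labels_path))
}

#' Persist a run to disk
#'
#' Writes the network weights and RNG state (RDS), the configuration (JSON),
#' any per-epoch metrics (CSV) and a manifest with md5 hashes of every file.
#'
#' @param net A `dendrite_net` (or the `$net` of a fit).
#' @param out_dir Output directory (created if needed).
#' @param metrics Optional data frame of per-epoch metrics.
#' @param config Optional list of run settings stored alongside.
#' @return The manifest, invisibly.
#' @export
persist_run <- function(net, out_dir, metrics = NULL, config = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  snap <- list(net = net,
               rng_state = if (exists(".Random.seed", globalenv()))
                 get(".Random.seed", globalenv()) else NULL)
  saveRDS(snap, file.path(out_dir, "weights.rds"))
  cfg <- c(config, list(sizes = net$sizes, feedback = net$feedback,
                        g_a = net$params$g_a, plateau = net$plateau))
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(metrics)) {
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
  }
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(files = lapply(files, function(f) {
    path <- file.path(out_dir, f)
    list(file = f, md5 = unname(tools::md5sum(path)),
         bytes = file.size(path))
  }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Load a persisted run
#'
#' @param dir Directory written by [persist_run()].
#' @param restore_rng Restore the RNG state saved with the snapshot so a
#'   resumed run continues the original stream.
#' @return A list with `net`, `config` and (if present) `metrics`.
#' @export
load_run <- function(dir, restore_rng = FALSE) {
  snap <- readRDS(file.path(dir, "weights.rds"))
  if (restore_rng && !is.null(snap$rng_state)) {
    assign(".Random.seed", snap$rng_state, envir = globalenv())
  }
  out <- list(net = snap$net,
              config = jsonlite::read_json(file.path(dir, "config.json")))
  mpath <- file.path(dir, "metrics.csv")
  if (file.exists(mpath)) out$metrics <- utils::read.csv(mpath)
  out
}
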