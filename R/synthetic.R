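# Deterministic synthetic organ/tumor segmentation samples: a smooth
# elliptical "organ" with intensity contrast against the background, a
# smaller irregular (perturbed-boundary) "tumor" nested inside it, and
# Gaussian pixel noise.  Shape parameters and noise are drawn from
# separate seeded streams so the noiseless scene of a given seed is
# invariant to the noise setting.

#' Generate one synthetic segmentation sample
#'
#' @param seed integer seed; the sample is a pure function of it.
#' @param size image side length (>= 16).
#' @param noiseSD standard deviation of the additive Gaussian pixel
#'   noise (intensity units in \[0, 1\]).
#' @return a [`SegmentationSample-class`].
#' @examples
#' s <- generateSegSample(7, size = 32)
#' mean(organMask(s))
#' @export
generateSegSample <- function(seed, size = 32L, noiseSD = 0.05) {
  size <- as.integer(size)
  if (size < 16L) stop("size must be >= 16")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)

  set.seed(seed %% .Machine$integer.max)
  # organ: ellipse with random center, semi-axes and orientation; the
  # semi-axis range keeps the organ between ~5% and ~30% of the frame
  cx <- stats::runif(1, 0.40, 0.60) * size
  cy <- stats::runif(1, 0.40, 0.60) * size
  a <- stats::runif(1, 0.14, 0.27) * size
  b <- stats::runif(1, 0.14, 0.27) * size
  phi <- stats::runif(1, 0, pi)
  gx <- matrix(seq_len(size), size, size)
  gy <- matrix(seq_len(size), size, size, byrow = TRUE)
  xr <- (gx - cx) * cos(phi) + (gy - cy) * sin(phi)
  yr <- -(gx - cx) * sin(phi) + (gy - cy) * cos(phi)
  organ <- (xr / a)^2 + (yr / b)^2 <= 1

  # tumor: smaller blob with a sinusoidally perturbed boundary, centered
  # inside the organ; intersecting with the organ guarantees nesting
  tcx <- cx + stats::runif(1, -0.25, 0.25) * a
  tcy <- cy + stats::runif(1, -0.25, 0.25) * b
  tr0 <- stats::runif(1, 0.30, 0.55) * min(a, b)
  nharm <- 3L
  amp <- stats::runif(nharm, 0.05, 0.18)
  pha <- stats::runif(nharm, 0, 2 * pi)
  ang <- atan2(gy - tcy, gx - tcx)
  rad <- sqrt((gx - tcx)^2 + (gy - tcy)^2)
  rb <- tr0 * (1 + Reduce(`+`, lapply(seq_len(nharm), function(k)
    amp[k] * sin(k * ang + pha[k]))))
  tumor <- (rad <= rb) & organ

  img <- 0.25 + 0.35 * organ + 0.25 * tumor
  # independent noise stream so the scene is invariant to noiseSD
  set.seed((seed + 987653L) %% .Machine$integer.max)
  img <- img + stats::rnorm(size * size, sd = noiseSD)
  img <- pmin(pmax(img, 0), 1)
  new("SegmentationSample",
      image = matrix(img, size, size),
      organMask = matrix(as.numeric(organ), size, size),
      tumorMask = matrix(as.numeric(tumor), size, size),
      seed = as.integer(seed))
}

# nearest-neighbour resize of a matrix
.resizeNearest <- function(m, size) {
  d <- dim(m)
  ri <- pmin(d[1], pmax(1L, round((seq_len(size) - 0.5) * d[1] / size + 0.5)))
  ci <- pmin(d[2], pmax(1L, round((seq_len(size) - 0.5) * d[2] / size + 0.5)))
  m[ri, ci, drop = FALSE]
}

# bilinear resize of a matrix
.resizeBilinear <- function(m, size) {
  d <- dim(m)
  sx <- (seq_len(size) - 0.5) * d[1] / size + 0.5
  sy <- (seq_len(size) - 0.5) * d[2] / size + 0.5
  x0 <- pmin(d[1] - 1L, pmax(1L, floor(sx))); fx <- pmin(pmax(sx - x0, 0), 1)
  y0 <- pmin(d[2] - 1L, pmax(1L, floor(sy))); fy <- pmin(pmax(sy - y0, 0), 1)
  m00 <- m[x0, y0, drop = FALSE]; m10 <- m[x0 + 1L, y0, drop = FALSE]
  m01 <- m[x0, y0 + 1L, drop = FALSE]; m11 <- m[x0 + 1L, y0 + 1L, drop = FALSE]
  FX <- matrix(fx, size, size); FY <- matrix(fy, size, size, byrow = TRUE)
  m00 * (1 - FX) * (1 - FY) + m10 * FX * (1 - FY) +
    m01 * (1 - FX) * FY + m11 * FX * FY
}

# crop the tight bounding box of the organ-tumor union and resize back,
# emulating the region-of-interest preparation of the tumor task
.cropToROI <- function(sample, size) {
  roi <- (sample@organMask + sample@tumorMask) > 0
  rows <- range(which(rowSums(roi) > 0))
  cols <- range(which(colSums(roi) > 0))
  img <- .resizeBilinear(sample@image[rows[1]:rows[2], cols[1]:cols[2],
                                      drop = FALSE], size)
  om <- .resizeNearest(sample@organMask[rows[1]:rows[2], cols[1]:cols[2],
                                        drop = FALSE], size)
  tm <- .resizeNearest(sample@tumorMask[rows[1]:rows[2], cols[1]:cols[2],
                                        drop = FALSE], size)
  tm[om == 0] <- 0
  new("SegmentationSample", image = pmin(pmax(img, 0), 1),
      organMask = om, tumorMask = tm, seed = sample@seed)
}

#' Build a synthetic train/test dataset
#'
#' Generates `n` deterministic samples and splits them 9:1 — the first
#' `floor(0.9 n)` are the training set, the remainder the test set.  For
#' `task = "tumor"` each frame is first cropped to the tight bounding box
#' of the organ-tumor union and resized back to `size`, emulating a
#' region-of-interest pipeline; the target mask is then the tumor,
#' otherwise the organ.
#'
#' @param n number of samples (>= 10).
#' @param size image side length.
#' @param seed global seed; sample i uses `seed + i`.
#' @param task `"organ"` (default) or `"tumor"`.
#' @param noiseSD Gaussian pixel-noise level.
#' @return list with `train` and `test` (lists of
#'   [`SegmentationSample-class`]), `task`, and a `manifest` list
#'   (sample count, image size, split ratio, seed, task).
#' @examples
#' ds <- buildDataset(10, size = 32, seed = 1)
#' length(ds$train)  # 9
#' @export
buildDataset <- function(n, size = 32L, seed = 1L,
                         task = c("organ", "tumor"), noiseSD = 0.05) {
  task <- match.arg(task)
  if (n < 10L) stop("n must be >= 10")
  samples <- lapply(seq_len(n), function(i)
    generateSegSample(seed + i, size = size, noiseSD = noiseSD))
  if (task == "tumor")
    samples <- lapply(samples, .cropToROI, size = size)
  nTrain <- floor(0.9 * n)
  list(train = samples[seq_len(nTrain)],
       test = samples[(nTrain + 1L):n],
       task = task,
       manifest = list(n = as.integer(n), size = as.integer(size),
                       splitRatio = "9:1", seed = as.integer(seed),
                       task = task, noiseSD = noiseSD))
}

#' Stack samples into model-ready arrays
#'
#' @param samples list of [`SegmentationSample-class`] objects.
#' @param task which mask becomes the target: `"organ"` or `"tumor"`.
#' @return list with `x` and `y`, both `(H, W, 1, n)` arrays.
#' @export
stackSamples <- function(samples, task = c("organ", "tumor")) {
  task <- match.arg(task)
  n <- length(samples)
  d <- dim(samples[[1]]@image)
  x <- array(0, c(d[1], d[2], 1L, n))
  y <- array(0, c(d[1], d[2], 1L, n))
  for (i in seq_len(n)) {
    x[, , 1, i] <- samples[[i]]@image
    y[, , 1, i] <- if (task == "organ") samples[[i]]@organMask
                   else samples[[i]]@tumorMask
  }
  list(x = x, y = y)
}

#' Write a segmentation sample to disk
#'
#' `"png"` writes three 8-bit PNG files (`<stem>_image.png`,
#' `<stem>_organ.png`, `<stem>_tumor.png`; masks as 0/255); `"rds"`
#' writes one native serialized archive that round-trips bit-exactly.
#'
#' @param sample a [`SegmentationSample-class`].
#' @param stem path stem (no extension).
#' @param format `"png"` or `"rds"`.
#' @return invisibly, the paths written.
#' @export
writeSegSample <- function(sample, stem, format = c("png", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    path <- paste0(stem, ".rds")
    saveRDS(list(image = sample@image, organMask = sample@organMask,
                 tumorMask = sample@tumorMask, seed = sample@seed), path)
    return(invisible(path))
  }
  paths <- paste0(stem, c("_image.png", "_organ.png", "_tumor.png"))
  png::writePNG(sample@image, paths[1])
  png::writePNG(sample@organMask, paths[2])
  png::writePNG(sample@tumorMask, paths[3])
  invisible(paths)
}

#' Read a segmentation sample back from disk
#'
#' @param stem path stem used in [writeSegSample()].
#' @param format `"png"` or `"rds"`.
#' @return a [`SegmentationSample-class`].  Masks round-trip exactly in
#'   both formats; PNG images round-trip within 8-bit quantization.
#' @export
readSegSample <- function(stem, format = c("png", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    path <- paste0(stem, ".rds")
    if (!file.exists(path)) stop("no such file: ", path)
    l <- readRDS(path)
    return(new("SegmentationSample", image = l$image,
               organMask = l$organMask, tumorMask = l$tumorMask,
               seed = l$seed))
  }
  paths <- paste0(stem, c("_image.png", "_organ.png", "_tumor.png"))
  if (!all(file.exists(paths)))
    stop("missing file(s): ", paste(paths[!file.exists(paths)], collapse = ", "))
  new("SegmentationSample",
      image = png::readPNG(paths[1]),
      organMask = round(png::readPNG(paths[2])),
      tumorMask = round(png::readPNG(paths[3])),
      seed = NA_integer_)
}

#' Write a dataset manifest as YAML
#'
#' @param manifest the `manifest` component of [buildDataset()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeManifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a NIfTI volume (optional adapter)
#'
#' Minimal hook for ingesting real CT volumes in place of the synthetic
#' generator.  Not used by any core routine; requires an external NIfTI
#' reader package at call time.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return a 3-D numeric array.
#' @export
readNIfTIVolume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI volumes requires the RNifti package")
  as.array(RNifti::readNifti(path))
}
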