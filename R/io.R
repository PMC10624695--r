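to_gray <- function(a) {
  if (is.matrix(a)) return(a)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L)  # luminance (Rec. 709) for color inputs
      return(0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3])
    return(a[, , 1])
  }
  stop("unsupported image array layout")
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    bmp = stop("BMP input is not supported; convert to PNG or TIFF"),
    stop(sprintf("unsupported image format '.%s'", ext))
  )
  # readers return intensities already scaled to [0,1] by the bit-depth max
  to_gray(a)
}

resize_image <- function(m, shape) {
  out <- EBImage::resize(EBImage::Image(m), w = shape[1], h = shape[2],
                         antialias = TRUE)
  matrix(EBImage::imageData(out), shape[1], shape[2])
}

#' Load an image dataset from a directory or CSV manifest
#'
#' Two layouts are supported: a root directory whose immediate
#' subdirectories are class names containing image files, or a CSV manifest
#' with columns `path,label[,case_id]` (paths relative to the manifest's
#' directory). Images are converted to grayscale (luminance for color
#' inputs), scaled to `[0,1]` by the bit-depth maximum, optionally resized
#' (anti-aliased bilinear), and returned in a deterministic order (sorted
#' paths within sorted classes). Unreadable files are skipped with a
#' warning; an empty class is an error.
#'
#' @param root_or_manifest dataset root directory or manifest CSV path.
#' @param resize `NULL` to keep native sizes, or target `c(H, W)`.
#' @return A list with `images` (list of `oct_image`), `labels`, and
#'   `manifest` (data frame `path`, `label`, `case_id`).
#' @export
load_dataset <- function(root_or_manifest, resize = NULL) {
  if (dir.exists(root_or_manifest)) {
    root <- root_or_manifest
    classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
    if (length(classes) == 0) stop("no class subdirectories found")
    manifest <- do.call(rbind, lapply(classes, function(cls) {
      files <- sort(list.files(file.path(root, cls),
                               pattern = "\\.(png|tiff?|jpe?g|bmp)$",
                               ignore.case = TRUE))
      if (length(files) == 0) stop(sprintf("class '%s' contains no images", cls))
      data.frame(path = file.path(cls, files), label = cls,
                 case_id = tools::file_path_sans_ext(files))
    }))
  } else if (file.exists(root_or_manifest)) {
    manifest <- utils::read.csv(root_or_manifest, stringsAsFactors = FALSE)
    if (!all(c("path", "label") %in% names(manifest)))
      stop("manifest must have columns 'path' and 'label'")
    if (is.null(manifest$case_id)) manifest$case_id <- manifest$path
    if (any(!nzchar(manifest$label))) stop("manifest labels must be nonempty")
    root <- dirname(root_or_manifest)
    manifest <- manifest[order(manifest$label, manifest$path), , drop = FALSE]
    rownames(manifest) <- NULL
  } else stop("'root_or_manifest' is neither a directory nor a file")

  images <- vector("list", nrow(manifest))
  ok <- logical(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(root, manifest$path[i])
    px <- tryCatch(read_image_file(f), error = function(e) {
      warning(sprintf("skipping unreadable image '%s': %s",
                      manifest$path[i], conditionMessage(e)))
      NULL
    })
    if (is.null(px)) next
    if (!is.null(resize)) px <- resize_image(px, as.integer(resize))
    images[[i]] <- structure(
      list(pixels = px, source_id = manifest$path[i],
           label = manifest$label[i]),
      class = "oct_image")
    ok[i] <- TRUE
  }
  if (sum(!ok) > 0)
    message(sprintf("skipped %d unreadable image(s)", sum(!ok)))
  manifest <- manifest[ok, , drop = FALSE]
  images <- images[ok]
  dims <- vapply(images, function(im) dim(im$pixels), integer(2))
  if (is.null(resize) &&
      (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])))
    stop("images have heterogeneous sizes; pass a 'resize' target")
  list(images = images, labels = manifest$label, manifest = manifest)
}
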