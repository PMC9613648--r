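#' Labelled image datasets
#'
#' A `cell_dataset` bundles a directory-per-class image collection: an ordered
#' character vector of class names, a per-class list of images (`H x W x 3`
#' arrays) and a set of minority flags. Class and file ordering is always
#' lexicographic so seeded runs are reproducible.
#'
#' @param images Named list; one element per class, each a list of
#'   `H x W x 3` arrays.
#' @param minority Character vector of minority class names (may be empty).
#'   Minority status is declared, not inferred from counts, matching explicit
#'   minority-class lists used in practice.
#' @return An object of class `cell_dataset`.
#' @export
cell_dataset <- function(images, minority = character()) {
  if (!is.list(images) || is.null(names(images)) || any(names(images) == "")) {
    abort("images must be a named list (one element per class)")
  }
  images <- images[order(names(images))]
  for (cls in names(images)) {
    if (!is.list(images[[cls]])) abort(sprintf("class '%s' pool must be a list", cls))
    for (img in images[[cls]]) assert_rgb_image(img, sprintf("image in class '%s'", cls))
  }
  bad <- setdiff(minority, names(images))
  if (length(bad)) abort(sprintf("unknown minority class(es): %s", paste(bad, collapse = ", ")))
  structure(
    list(classes = names(images), images = images, minority = sort(minority)),
    class = "cell_dataset"
  )
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat(sprintf(
    "<cell_dataset> %d classes, %d images (%d minority class%s)\n",
    length(x$classes), sum(dataset_counts(x)$count),
    length(x$minority), if (length(x$minority) == 1) "" else "es"
  ))
  print(dataset_counts(x))
  invisible(x)
}

#' Per-class image counts
#'
#' @param dataset A `cell_dataset`.
#' @return A tibble with `class`, `count` and `minority` columns.
#' @export
dataset_counts <- function(dataset) {
  stopifnot(inherits(dataset, "cell_dataset"))
  tibble(
    class = dataset$classes,
    count = unname(map_int(dataset$images[dataset$classes], length)),
    minority = dataset$classes %in% dataset$minority
  )
}

#' @export
as_tibble.cell_dataset <- function(x, ...) dataset_counts(x)

#' Load a directory-per-class image dataset
#'
#' Expects `root/<class>/<image>.(png|tif|tiff)`. Classes and files are read
#' in lexicographic order; grayscale files are promoted to RGB.
#'
#' @param root Dataset root directory.
#' @param expected_size Optional integer `(H, W)`; images of any other size
#'   raise an error naming the file.
#' @param minority Character vector of minority class names.
#' @return A `cell_dataset`.
#' @export
load_dataset <- function(root, expected_size = NULL, minority = character()) {
  if (!dir.exists(root)) abort(sprintf("dataset root does not exist: %s", root))
  class_dirs <- sort(list.dirs(root, recursive = FALSE))
  if (!length(class_dirs)) abort(sprintf("no class subdirectories under %s", root))
  images <- list()
  for (cd in class_dirs) {
    cls <- basename(cd)
    files <- sort(list.files(cd, pattern = "\\.(png|tif|tiff)$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) abort(sprintf("class directory '%s' contains no images", cls))
    pool <- map(files, read_cell_image)
    if (!is.null(expected_size)) {
      for (i in seq_along(pool)) {
        d <- dim(pool[[i]])
        if (!all(d[1:2] == as.integer(expected_size))) {
          abort(sprintf(
            "%s is %dx%d, expected %dx%d",
            files[i], d[1], d[2], expected_size[1], expected_size[2]
          ))
        }
      }
    }
    images[[cls]] <- pool
  }
  cell_dataset(images, minority = minority)
}

#' Write a dataset in the directory-per-class PNG convention
#'
#' @param dataset A `cell_dataset`.
#' @param root Output root directory (created if needed).
#' @return `root`, invisibly.
#' @export
write_dataset <- function(dataset, root) {
  stopifnot(inherits(dataset, "cell_dataset"))
  for (cls in dataset$classes) {
    dir.create(file.path(root, cls), recursive = TRUE, showWarnings = FALSE)
    pool <- dataset$images[[cls]]
    for (i in seq_along(pool)) {
      write_cell_image(pool[[i]], file.path(root, cls, sprintf("%s_%04d.png", cls, i)))
    }
  }
  invisible(root)
}

#' Imbalance ratio per class
#'
#' The imbalance ratio of a class is the largest class count divided by that
#' class's count; majority classes therefore have ratio 1 and rare classes
#' large ratios.
#'
#' @param dataset A `cell_dataset`.
#' @return A tibble with `class`, `count`, `imbalance_ratio`.
#' @export
imbalance_ratio <- function(dataset) {
  counts <- dataset_counts(dataset)
  if (any(counts$count == 0L)) {
    abort(sprintf(
      "class(es) with no images: %s",
      paste(counts$class[counts$count == 0L], collapse = ", ")
    ))
  }
  mutate(counts, imbalance_ratio = max(.data$count) / .data$count)[
    , c("class", "count", "imbalance_ratio")
  ]
}
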