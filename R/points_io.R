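#' Read a particle coordinate table
#'
#' Reads per-image particle coordinates for two labels from a CSV/TSV table
#' with columns `image_id`, `label`, `x`, `y` (case-insensitive; comment
#' lines starting with `#` are ignored).  An ImageJ-Results-style dialect
#' (extra unnamed leading index column, capitalised `X`/`Y`) is
#' auto-detected.  Coordinates are converted to nm by `scale`.
#'
#' @param source Path to a delimited text file, or a data frame already in
#'   the table layout (useful for piping).
#' @param window A [study_window()] applied to every image, or a data frame
#'   with columns `image_id`, `width`, `height` giving per-image windows
#'   (in nm, i.e. after scaling).
#' @param scale nm per coordinate unit; must be supplied explicitly when
#'   the table is in pixels.  Default 1 (coordinates already in nm).
#' @param label_a,label_b Which label names map to types A and B.  Defaults
#'   `"A"`/`"B"`.  Any label in the table outside these two is an error.
#'
#' @return A `coloc_particles` tibble with columns `image_id` (character),
#'   `label` (factor with levels `"A"`, `"B"`), `x`, `y` (nm), and the
#'   window(s) stored in the `windows` attribute (tibble `image_id`,
#'   `width`, `height`, with `image_id = NA` meaning "all images").  Images
#'   are ordered by first appearance; rows within an image keep file order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("image_id,label,x,y", "img1,A,10,10", "img1,B,20,20"), f)
#' read_particles(f, study_window(100, 100))
#' @export
read_particles <- function(source, window, scale = 1,
                           label_a = "A", label_b = "B") {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    abort("`scale` must be a single positive number (nm per unit).")
  }
  if (is.data.frame(source)) {
    raw <- as_tibble(source)
  } else {
    if (is.character(source) && !file.exists(source)) {
      abort(sprintf("particle table not found: %s", source))
    }
    first <- readLines(source, n = 50L)
    first <- first[!startsWith(trimws(first), "#")]
    delim <- if (length(first) && grepl("\t", first[1])) "\t" else ","
    raw <- readr::read_delim(source, delim = delim, comment = "#",
                             show_col_types = FALSE, trim_ws = TRUE,
                             name_repair = "unique_quiet")
  }
  names(raw) <- tolower(names(raw))
  # ImageJ Results dialect: drop a leading unnamed / running-index column
  if (ncol(raw) >= 1 && grepl("^(\\.\\.\\.1|x1|v1|index| |)$", names(raw)[1]) &&
      !"image_id" %in% names(raw)[1]) {
    raw <- raw[-1]
  }
  needed <- c("image_id", "label", "x", "y")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("particle table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  raw <- raw[needed]
  if (nrow(raw) == 0) {
    out <- tibble(image_id = character(), label = factor(levels = c("A", "B")),
                  x = numeric(), y = numeric())
    return(new_particles(out, resolve_windows(window, character())))
  }
  labs <- unique(as.character(raw$label))
  unknown <- setdiff(labs, c(label_a, label_b))
  if (length(unknown)) {
    abort(sprintf(
      "unmapped label(s) %s: supply label_a/label_b mappings for all labels",
      paste(sQuote(unknown), collapse = ", ")))
  }
  out <- raw |>
    mutate(image_id = as.character(.data$image_id),
           label = factor(ifelse(as.character(.data$label) == label_a,
                                 "A", "B"), levels = c("A", "B")),
           x = as.numeric(.data$x) * scale,
           y = as.numeric(.data$y) * scale)
  windows <- resolve_windows(window, unique(out$image_id))
  check_inside(out, windows)
  new_particles(out, windows)
}

new_particles <- function(df, windows) {
  structure(df, windows = windows,
            class = c("coloc_particles", class(tibble())))
}

resolve_windows <- function(window, image_ids) {
  if (is.data.frame(window)) {
    need <- c("image_id", "width", "height")
    if (!all(need %in% names(window))) {
      abort("per-image window table needs columns image_id, width, height")
    }
    w <- as_tibble(window[need]) |>
      mutate(image_id = as.character(.data$image_id))
    missing_w <- setdiff(image_ids, w$image_id)
    if (length(missing_w)) {
      abort(sprintf("no window supplied for image(s): %s",
                    paste(missing_w, collapse = ", ")))
    }
    if (any(w$width <= 0 | w$height <= 0)) abort("window extents must be > 0")
    return(w)
  }
  window <- as_window(window)
  tibble(image_id = NA_character_, width = window$width,
         height = window$height)
}

window_for <- function(windows, id) {
  row <- if (all(is.na(windows$image_id))) windows[1, ] else
    windows[windows$image_id %in% id, ]
  study_window(row$width[[1]], row$height[[1]])
}

check_inside <- function(df, windows) {
  for (id in unique(df$image_id)) {
    w <- window_for(windows, id)
    sub <- df[df$image_id == id, ]
    bad <- sub$x < 0 | sub$x > w$width | sub$y < 0 | sub$y > w$height
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf(
        "particle outside window: image %s, label %s, (%g, %g) not in [0,%g]x[0,%g]",
        id, as.character(sub$label[i]), sub$x[i], sub$y[i],
        w$width, w$height))
    }
  }
  invisible(df)
}

particles_windows <- function(particles) {
  w <- attr(particles, "windows")
  if (is.null(w)) abort("particle table carries no window metadata; build it with read_particles() or as_particles()")
  w
}

#' Construct a particle table from a data frame in memory
#'
#' Convenience constructor equivalent to [read_particles()] on an in-memory
#' data frame: validates labels and window containment and attaches the
#' window metadata used by all downstream coefficients.
#'
#' @inheritParams read_particles
#' @param data Data frame with columns `image_id`, `label`, `x`, `y`
#'   (coordinates in nm).
#' @return A `coloc_particles` tibble.
#' @export
as_particles <- function(data, window, label_a = "A", label_b = "B") {
  read_particles(data, window, scale = 1, label_a = label_a,
                 label_b = label_b)
}

# Split a particle tibble into per-image coordinate lists.
split_images <- function(particles) {
  windows <- particles_windows(particles)
  ids <- unique(particles$image_id)
  lapply(ids, function(id) {
    sub <- particles[particles$image_id == id, ]
    a <- sub[sub$label == "A", ]
    b <- sub[sub$label == "B", ]
    list(image_id = id,
         window = window_for(windows, id),
         xa = a$x, ya = a$y, xb = b$x, yb = b$y)
  })
}

#' Write a coefficient set to JSON or CSV
#'
#' JSON output nests `parameters` (band, edge mode, number of images, tool
#' version), `per_image` rows and the image-averaged `aggregate` (with
#' per-coefficient effective image counts).  CSV output is flat: one row
#' per image plus a final `aggregate` row.
#'
#' @param results A `coloc_coefficients` object from [em_coloc()].
#' @param sink Output file path.
#' @param format `"json"` or `"csv"`.
#' @return `sink`, invisibly.
#' @seealso [read_results()] for the JSON round-trip.
#' @export
write_results <- function(results, sink, format = c("json", "csv")) {
  format <- match.arg(format)
  if (!inherits(results, "coloc_coefficients")) {
    abort("`results` must come from em_coloc()")
  }
  if (nrow(results$per_image) == 0) abort("no per-image results to write")
  if (format == "json") {
    payload <- list(
      parameters = results$parameters,
      per_image = results$per_image,
      aggregate = as.list(results$aggregate),
      effective_k = as.list(results$effective_k)
    )
    jsonlite::write_json(payload, sink, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    agg <- results$aggregate
    agg_row <- tibble(image_id = "aggregate") |>
      dplyr::bind_cols(as_tibble(as.list(agg)))
    flat <- bind_rows(results$per_image, agg_row)
    readr::write_csv(flat, sink)
  }
  invisible(sink)
}

#' Read back a JSON coefficient file
#'
#' Inverse of [write_results()] for the JSON format; returns a
#' `coloc_coefficients` object equal (to numeric precision) to the one
#' written.
#'
#' @param path Path to a JSON file written by [write_results()].
#' @return A `coloc_coefficients` object.
#' @export
read_results <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(parameters = x$parameters,
                 per_image = as_tibble(x$per_image),
                 aggregate = unlist(x$aggregate),
                 effective_k = unlist(x$effective_k)),
            class = "coloc_coefficients")
}
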