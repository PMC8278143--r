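# Alias table for hand-labelled class tags; matched case-insensitively.
.CLASS_ALIASES <- c(liv = "liv", living = "liv",
                    round = "round",
                    div = "div", dividing = "div",
                    dead = "dead")

#' Normalize class tags
#'
#' Maps hand-labelled class tags onto the four canonical labels. Matching is
#' case-insensitive over the alias table \code{liv/living -> liv, round ->
#' round, div/dividing -> div, dead -> dead}.
#'
#' @param tags character vector of raw tags.
#' @param context character used in the error message (e.g. "frame 3").
#' @return Character vector of canonical labels.
#' @export
normalizeClassTags <- function(tags, context = NULL) {
  key <- tolower(trimws(tags))
  out <- .CLASS_ALIASES[key]
  if (anyNA(out)) {
    bad <- unique(tags[is.na(out)])
    stop(sprintf("unknown class tag(s) %s%s; known tags: %s",
                 paste(sQuote(bad), collapse = ", "),
                 if (is.null(context)) "" else paste0(" in ", context),
                 paste(names(.CLASS_ALIASES), collapse = ", ")),
         call. = FALSE)
  }
  unname(out)
}

#' Read bounding-box annotations
#'
#' Reads a video's labelled boxes from one of three dialects into a
#' [CellVideo-class]:
#' \describe{
#'   \item{via}{VGG Image Annotator region-JSON export: one record per
#'     image with \code{regions}, each a \code{rect} shape
#'     (\code{x, y, width, height}) plus a region attribute holding the
#'     class tag. Frame index and acquisition metadata are taken from
#'     \code{file_attributes} when present, else the frame index is parsed
#'     from digits in the file name.}
#'   \item{coco}{COCO-style detection JSON: \code{images},
#'     \code{annotations} with \code{bbox = [x, y, w, h]},
#'     \code{category_id} mapped 1..4 in the order liv, round, div, dead,
#'     and an optional \code{score} for the confidence.}
#'   \item{csv}{Plain CSV with columns \code{frame, time_min, x_min, y_min,
#'     x_max, y_max, class, confidence, object_id}; leading \code{#}
#'     comment lines carry video metadata.}
#' }
#' All coordinates become 0-based half-open corner coordinates. Unknown
#' class tags and non-rectangular regions raise validation errors naming the
#' offending record; they are never silently dropped. Missing confidences
#' default to 1 (ground truth).
#'
#' @param path file to read.
#' @param format one of \code{"via"}, \code{"coco"}, \code{"csv"}; default
#'   guessed from the file extension (.json -> via unless the file has a
#'   COCO \code{annotations} key; .csv -> csv).
#' @param frame_interval,image_size,sampleMeta fallbacks used when the file
#'   does not carry the corresponding metadata (foreign exports).
#' @return A validated [CellVideo-class].
#' @seealso [writeAnnotations()]
#' @export
readAnnotations <- function(path, format = c("auto", "via", "coco", "csv"),
                            frame_interval = 5,
                            image_size = c(1388, 1040),
                            sampleMeta = list()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    if (grepl("\\.csv$", path, ignore.case = TRUE)) {
      format <- "csv"
    } else {
      js <- tryCatch(jsonlite::read_json(path),
                     error = function(e) stop("malformed JSON in ", path,
                                              ": ", conditionMessage(e),
                                              call. = FALSE))
      format <- if (!is.null(js$annotations) && !is.null(js$images))
        "coco" else "via"
    }
  }
  switch(format,
         via = .read_via(path, frame_interval, image_size, sampleMeta),
         coco = .read_coco(path, frame_interval, image_size, sampleMeta),
         csv = .read_csv(path, frame_interval, image_size, sampleMeta))
}

#' Write bounding-box annotations
#'
#' Serializes a [CellVideo-class] to one of the dialects understood by
#' [readAnnotations()], losslessly for boxes, classes, confidences and
#' object ids (numbers are written at full precision). Frames without
#' objects are preserved.
#'
#' @param video a \code{CellVideo}.
#' @param path output file.
#' @param format \code{"via"}, \code{"coco"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
writeAnnotations <- function(video, path, format = c("via", "coco", "csv")) {
  stopifnot(is(video, "CellVideo"))
  validObject(video)
  format <- match.arg(format)
  switch(format,
         via = .write_via(video, path),
         coco = .write_coco(video, path),
         csv = .write_csv(video, path))
  invisible(path)
}

.meta_list <- function(video) {
  list(frame_interval_min = video@frameInterval,
       image_width = video@imageSize[1],
       image_height = video@imageSize[2],
       frame_indices = video@frameIndices,
       sample_id = video@sampleMeta$sample_id,
       dose_gy = video@sampleMeta$dose_gy,
       irradiated = video@sampleMeta$irradiated)
}

.video_from_parts <- function(objects, meta, frame_interval, image_size,
                              sampleMeta) {
  fi <- meta$frame_indices
  if (is.null(fi)) fi <- sort(unique(objects$frame))
  sm <- list(
    sample_id = if (is.null(meta$sample_id)) sampleMeta$sample_id else
      meta$sample_id,
    dose_gy = if (is.null(meta$dose_gy)) sampleMeta$dose_gy else
      meta$dose_gy,
    irradiated = if (is.null(meta$irradiated)) sampleMeta$irradiated else
      meta$irradiated)
  sm <- sm[!vapply(sm, is.null, logical(1))]
  cellVideo(objects, frameIndices = as.integer(unlist(fi)),
            frameInterval = if (is.null(meta$frame_interval_min))
              frame_interval else as.numeric(meta$frame_interval_min),
            imageSize = if (is.null(meta$image_width)) image_size else
              c(as.numeric(meta$image_width), as.numeric(meta$image_height)),
            sampleMeta = sm)
}

## ---- VIA ----

.write_via <- function(video, path) {
  entries <- list()
  for (fi in video@frameIndices) {
    fobj <- getFrame(video, fi)
    fname <- sprintf("frame_%06d.png", fi)
    regions <- lapply(seq_len(nrow(fobj)), function(i) {
      r <- fobj[i, ]
      list(shape_attributes = list(
             name = "rect", x = r$x_min, y = r$y_min,
             width = r$x_max - r$x_min, height = r$y_max - r$y_min),
           region_attributes = list(
             class = r$class, confidence = r$confidence,
             object_id = if (is.na(r$object_id)) NULL else r$object_id))
    })
    entries[[paste0(fname, "-1")]] <- list(
      filename = fname, size = -1, regions = regions,
      file_attributes = list(frame_index = fi,
                             time_min = fi * video@frameInterval))
  }
  entries[["_video_meta_"]] <- .meta_list(video)
  writeLines(jsonlite::toJSON(entries, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
}

.read_via <- function(path, frame_interval, image_size, sampleMeta) {
  js <- tryCatch(jsonlite::read_json(path),
                 error = function(e) stop("malformed VIA file ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  # tolerate full VIA project files
  if (!is.null(js[["_via_img_metadata"]])) js <- js[["_via_img_metadata"]]
  meta <- js[["_video_meta_"]]
  if (is.null(meta)) meta <- list()
  js <- js[!grepl("^_", names(js))]
  rows <- list()
  for (key in names(js)) {
    ent <- js[[key]]
    fa <- ent$file_attributes
    frame <- if (!is.null(fa$frame_index)) as.integer(fa$frame_index) else {
      digits <- regmatches(ent$filename,
                           regexpr("[0-9]+", ent$filename))
      if (!length(digits))
        stop("VIA record ", sQuote(key),
             ": no frame_index attribute and no digits in filename",
             call. = FALSE)
      as.integer(digits)
    }
    regs <- ent$regions
    if (!length(regs)) next
    for (j in seq_along(regs)) {
      sa <- regs[[j]]$shape_attributes
      ra <- regs[[j]]$region_attributes
      if (is.null(sa$name) || sa$name != "rect")
        stop(sprintf("VIA record %s region %d: non-rectangular shape %s",
                     sQuote(key), j, sQuote(sa$name %||% "?")),
             call. = FALSE)
      tag <- ra$class %||% ra$type %||% ra[[1]]
      if (is.null(tag))
        stop(sprintf("VIA record %s region %d: no class attribute",
                     sQuote(key), j), call. = FALSE)
      cls <- normalizeClassTags(as.character(tag),
                                sprintf("record %s (frame %d), region %d",
                                        sQuote(key), frame, j))
      rows[[length(rows) + 1L]] <- data.frame(
        frame = frame,
        x_min = as.numeric(sa$x), y_min = as.numeric(sa$y),
        x_max = as.numeric(sa$x) + as.numeric(sa$width),
        y_max = as.numeric(sa$y) + as.numeric(sa$height),
        class = cls,
        confidence = as.numeric(ra$confidence %||% 1),
        object_id = as.character(ra$object_id %||% NA_character_),
        stringsAsFactors = FALSE)
    }
  }
  objects <- if (length(rows)) do.call(rbind, rows) else NULL
  .video_from_parts(objects, meta, frame_interval, image_size, sampleMeta)
}

## ---- COCO ----

.write_coco <- function(video, path) {
  classes <- cellClasses()
  obj <- video@objects
  images <- lapply(video@frameIndices, function(fi) {
    list(id = fi, file_name = sprintf("frame_%06d.png", fi),
         width = video@imageSize[1], height = video@imageSize[2])
  })
  annotations <- lapply(seq_len(nrow(obj)), function(i) {
    r <- obj[i, ]
    list(id = i, image_id = r$frame,
         bbox = c(r$x_min, r$y_min, r$x_max - r$x_min, r$y_max - r$y_min),
         category_id = match(r$class, classes),
         score = r$confidence,
         object_id = if (is.na(r$object_id)) NULL else r$object_id)
  })
  out <- list(info = .meta_list(video),
              images = images,
              annotations = annotations,
              categories = lapply(seq_along(classes), function(i)
                list(id = i, name = classes[i])))
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
}

.read_coco <- function(path, frame_interval, image_size, sampleMeta) {
  js <- tryCatch(jsonlite::read_json(path),
                 error = function(e) stop("malformed COCO file ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(js$annotations) || is.null(js$images))
    stop("not a COCO detection file (missing images/annotations): ", path,
         call. = FALSE)
  cat_names <- cellClasses()
  if (!is.null(js$categories)) {
    ids <- vapply(js$categories, function(x) as.integer(x$id), integer(1))
    nms <- vapply(js$categories, function(x) as.character(x$name),
                  character(1))
    cat_names <- normalizeClassTags(nms, "COCO categories")[order(ids)]
  }
  meta <- if (is.null(js$info)) list() else js$info
  if (is.null(meta$frame_indices))
    meta$frame_indices <- vapply(js$images, function(x) as.integer(x$id),
                                 integer(1))
  if (is.null(meta$image_width) && length(js$images)) {
    meta$image_width <- js$images[[1]]$width
    meta$image_height <- js$images[[1]]$height
  }
  rows <- lapply(seq_along(js$annotations), function(i) {
    a <- js$annotations[[i]]
    bbox <- as.numeric(unlist(a$bbox))
    if (length(bbox) != 4L)
      stop(sprintf("COCO annotation %d: bbox must have 4 entries", i),
           call. = FALSE)
    cid <- as.integer(a$category_id)
    if (is.na(cid) || cid < 1L || cid > length(cat_names))
      stop(sprintf("COCO annotation %d: category_id %s out of range", i,
                   a$category_id), call. = FALSE)
    data.frame(frame = as.integer(a$image_id),
               x_min = bbox[1], y_min = bbox[2],
               x_max = bbox[1] + bbox[3], y_max = bbox[2] + bbox[4],
               class = cat_names[cid],
               confidence = as.numeric(a$score %||% 1),
               object_id = as.character(a$object_id %||% NA_character_),
               stringsAsFactors = FALSE)
  })
  objects <- if (length(rows)) do.call(rbind, rows) else NULL
  .video_from_parts(objects, meta, frame_interval, image_size, sampleMeta)
}

## ---- CSV ----

.write_csv <- function(video, path) {
  meta <- .meta_list(video)
  meta$frame_indices <- paste(meta$frame_indices, collapse = ",")
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s=%s", nm, meta[[nm]]), con)
  obj <- video@objects
  out <- data.frame(frame = obj$frame,
                    time_min = obj$frame * video@frameInterval,
                    obj[c("x_min", "y_min", "x_max", "y_max", "class")],
                    confidence = obj$confidence,
                    object_id = obj$object_id)
  utils::write.csv(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE, na = "")
}

.read_csv <- function(path, frame_interval, image_size, sampleMeta) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    meta[[key]] <- val
  }
  if (!is.null(meta$frame_indices))
    meta$frame_indices <- as.integer(strsplit(meta$frame_indices, ",")[[1]])
  if (!is.null(meta$irradiated))
    meta$irradiated <- as.logical(meta$irradiated)
  for (nm in c("frame_interval_min", "image_width", "image_height",
               "dose_gy"))
    if (!is.null(meta[[nm]])) meta[[nm]] <- as.numeric(meta[[nm]])
  df <- tryCatch(
    utils::read.csv(textConnection(lines[!grepl("^#", lines)]),
                    stringsAsFactors = FALSE, colClasses = NA),
    error = function(e) stop("malformed CSV ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  needed <- c("frame", "x_min", "y_min", "x_max", "y_max", "class")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("CSV ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df)) {
    df$class <- normalizeClassTags(df$class, path)
    if (is.null(df$confidence)) df$confidence <- 1
    df$confidence[is.na(df$confidence)] <- 1
    if (is.null(df$object_id)) df$object_id <- NA_character_
    df$object_id <- as.character(df$object_id)
    df$object_id[!nzchar(df$object_id) | is.na(df$object_id)] <-
      NA_character_
  }
  .video_from_parts(if (nrow(df)) df else NULL, meta, frame_interval,
                    image_size, sampleMeta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate (and optionally clip) the boxes of one frame
#'
#' Checks that every box has strictly positive area and lies inside the
#' image. With \code{clip = TRUE}, boxes crossing the image border are
#' clipped to \code{[0, width) x [0, height)} and boxes left with zero area
#' are removed with a message; with \code{clip = FALSE} an out-of-bounds box
#' is an error. A zero-area input box is always an error.
#'
#' @param frame data.frame of one frame's objects (box columns required).
#' @param image_size numeric (width, height) in pixels.
#' @param clip logical; clip out-of-bounds boxes instead of failing.
#' @return The validated (possibly clipped and filtered) data.frame.
#' @examples
#' f <- data.frame(x_min = -5, y_min = 0, x_max = 10, y_max = 10)
#' validateFrame(f, c(100, 100), clip = TRUE)  # clipped to x_min = 0
#' @export
validateFrame <- function(frame, image_size, clip = FALSE) {
  zero <- frame$x_max <= frame$x_min | frame$y_max <= frame$y_min
  if (any(zero))
    stop("zero-area input box(es) at row(s) ",
         paste(which(zero), collapse = ", "), call. = FALSE)
  w <- image_size[1]; h <- image_size[2]
  oob <- frame$x_min < 0 | frame$y_min < 0 | frame$x_max > w |
    frame$y_max > h
  if (!clip) {
    if (any(oob))
      stop("out-of-bounds box(es) at row(s) ",
           paste(which(oob), collapse = ", "),
           " (use clip = TRUE to clip to the image)", call. = FALSE)
    return(frame)
  }
  frame$x_min <- pmax(0, pmin(frame$x_min, w))
  frame$x_max <- pmax(0, pmin(frame$x_max, w))
  frame$y_min <- pmax(0, pmin(frame$y_min, h))
  frame$y_max <- pmax(0, pmin(frame$y_max, h))
  empty <- frame$x_max <= frame$x_min | frame$y_max <= frame$y_min
  if (any(empty)) {
    message(sum(empty), " box(es) removed: zero area after clipping")
    frame <- frame[!empty, , drop = FALSE]
  }
  frame
}
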