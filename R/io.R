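# Readers and writers: LabelMe-style annotation JSON, COCO instances and
# results JSON, plain-text heatmap bundles with a JSON sidecar, spectrum
# reference JSON and the run configuration file. Every format written here
# is read back by the suite.

DIRECTION_LABELS <- c("top", "left", "bottom", "right")

#' Write a scene as LabelMe-style JSON
#'
#' One polygon shape per instance (label = class) plus four point shapes
#' labeled `"top"`, `"left"`, `"bottom"`, `"right"`, all sharing the
#' instance's `group_id`.
#'
#' @param scene a `cell_scene`.
#' @param path output file.
#' @param image_path value of the `imagePath` field (no image is written).
#' @return `path`, invisibly.
#' @export
write_labelme <- function(scene, path, image_path = "scene.png") {
  stopifnot(inherits(scene, "cell_scene"))
  shapes <- list()
  for (i in seq_along(scene$instances)) {
    inst <- scene$instances[[i]]
    shapes[[length(shapes) + 1L]] <- list(
      label = inst$class, group_id = i, shape_type = "polygon",
      points = unname(lapply(seq_len(nrow(inst$polygon)),
                             function(k) as.numeric(inst$polygon[k, ]))))
    for (d in DIRECTION_LABELS) {
      shapes[[length(shapes) + 1L]] <- list(
        label = d, group_id = i, shape_type = "point",
        points = list(as.numeric(inst$extremes[[d]])))
    }
  }
  rec <- list(version = "5.0.0", flags = stats::setNames(list(), character(0)),
              shapes = shapes, imagePath = image_path,
              imageHeight = scene$height, imageWidth = scene$width)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read LabelMe-style annotations
#'
#' Accepts both dialects: instances carrying four direction-labeled point
#' shapes (grouped by `group_id`), and polygon-only instances whose extreme
#' points are derived with [extreme_points()]. Records with neither are
#' skipped with a warning.
#'
#' @param path a LabelMe JSON file.
#' @return list with `width`, `height`, `image_path` and `instances`, each
#'   instance a list with `class`, `extremes` ([extreme_set]) and `polygon`
#'   (matrix or NULL).
#' @export
read_labelme <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = FALSE)
  shapes <- rec$shapes %||% list()
  gid <- vapply(shapes, function(s) {
    g <- s$group_id
    if (is.null(g)) NA_integer_ else as.integer(g)
  }, integer(1))
  # ungrouped shapes become their own instances
  if (any(is.na(gid))) {
    gid[is.na(gid)] <- max(c(0L, gid), na.rm = TRUE) + seq_len(sum(is.na(gid)))
  }
  instances <- list()
  for (g in unique(gid)) {
    grp <- shapes[gid == g]
    labels <- vapply(grp, function(s) as.character(s$label), character(1))
    pts <- lapply(grp, function(s) {
      do.call(rbind, lapply(s$points, function(p) as.numeric(unlist(p))))
    })
    poly_i <- which(vapply(grp, function(s)
      identical(s$shape_type, "polygon"), logical(1)))
    polygon <- if (length(poly_i)) pts[[poly_i[1]]] else NULL
    dir_i <- match(DIRECTION_LABELS, labels)
    if (!anyNA(dir_i)) {
      es <- extreme_set(top = pts[[dir_i[1]]][1, ], left = pts[[dir_i[2]]][1, ],
                        bottom = pts[[dir_i[3]]][1, ], right = pts[[dir_i[4]]][1, ])
    } else if (!is.null(polygon)) {
      es <- extreme_points(polygon)
    } else {
      warning(sprintf("instance group %d has no direction points and no polygon: skipped", g),
              call. = FALSE)
      next
    }
    cls <- if (length(poly_i)) labels[poly_i[1]] else {
      other <- setdiff(labels, DIRECTION_LABELS)
      if (length(other)) other[1] else "cell"
    }
    instances[[length(instances) + 1L]] <-
      list(class = cls, extremes = es, polygon = polygon)
  }
  list(width = as.integer(rec$imageWidth %||% NA),
       height = as.integer(rec$imageHeight %||% NA),
       image_path = rec$imagePath %||% NA_character_,
       instances = instances)
}

category_table <- function(classes) {
  classes <- sort(unique(as.character(classes)))
  data.frame(id = seq_along(classes), name = classes)
}

#' Write ground-truth boxes as COCO instances JSON
#'
#' @param gts data.frame with `image_id`, `class`, `xmin`, `ymin`, `xmax`,
#'   `ymax` (e.g. from [scene_boxes()]).
#' @param path output file.
#' @param image_sizes data.frame `image_id`, `width`, `height`; defaults to
#'   a placeholder per referenced image.
#' @return `path`, invisibly.
#' @export
write_coco_gt <- function(gts, path, image_sizes = NULL) {
  cats <- category_table(gts$class)
  ids <- sort(unique(gts$image_id))
  if (is.null(image_sizes)) {
    image_sizes <- data.frame(image_id = ids, width = NA_integer_,
                              height = NA_integer_)
  }
  images <- lapply(ids, function(i) {
    sz <- image_sizes[image_sizes$image_id == i, , drop = FALSE]
    list(id = i, width = sz$width[1], height = sz$height[1],
         file_name = sprintf("image_%d.png", i))
  })
  anns <- lapply(seq_len(nrow(gts)), function(k) {
    w <- gts$xmax[k] - gts$xmin[k]; h <- gts$ymax[k] - gts$ymin[k]
    list(id = k, image_id = gts$image_id[k],
         category_id = cats$id[match(as.character(gts$class[k]), cats$name)],
         bbox = c(gts$xmin[k], gts$ymin[k], w, h), area = w * h, iscrowd = 0L)
  })
  jsonlite::write_json(
    list(images = images, annotations = anns,
         categories = lapply(seq_len(nrow(cats)),
                             function(k) list(id = cats$id[k], name = cats$name[k]))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read COCO instances JSON as a ground-truth data.frame
#'
#' Boxes convert from `[x, y, w, h]` to `[xmin, ymin, xmax, ymax]` with
#' `xmax = x + w`.
#'
#' @param path a COCO instances file.
#' @return data.frame `image_id`, `class`, `xmin`, `ymin`, `xmax`, `ymax`.
#' @export
read_coco_gt <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cats <- vapply(obj$categories, function(c) as.character(c$name), character(1))
  names(cats) <- vapply(obj$categories, function(c) as.character(c$id), character(1))
  if (!length(obj$annotations)) {
    return(data.frame(image_id = integer(0), class = character(0),
                      xmin = numeric(0), ymin = numeric(0),
                      xmax = numeric(0), ymax = numeric(0)))
  }
  rows <- lapply(obj$annotations, function(a) {
    bb <- as.numeric(unlist(a$bbox))
    validate_bbox(bb)
    data.frame(image_id = a$image_id, class = cats[[as.character(a$category_id)]],
               xmin = bb[1], ymin = bb[2], xmax = bb[1] + bb[3], ymax = bb[2] + bb[4])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

validate_bbox <- function(bb) {
  if (length(bb) != 4L || any(!is.finite(bb)) || bb[3] < 0 || bb[4] < 0) {
    abort2(sprintf("invalid bbox [%s]: need finite [x, y, w, h] with w, h >= 0",
                   paste(bb, collapse = ", ")), "validation_error")
  }
  invisible(bb)
}

#' Write detections as COCO results JSON
#'
#' @param dets detection data.frame with `image_id`, `class`, `score` and
#'   box columns.
#' @param path output file.
#' @param categories data.frame `id`, `name` fixing the category ids (so
#'   detections and ground truth agree); defaults to ids from the sorted
#'   class names present.
#' @return `path`, invisibly.
#' @export
write_coco_detections <- function(dets, path, categories = NULL) {
  if (is.null(categories)) categories <- category_table(dets$class)
  res <- lapply(seq_len(nrow(dets)), function(k) {
    list(image_id = dets$image_id[k],
         category_id = categories$id[match(as.character(dets$class[k]), categories$name)],
         bbox = c(dets$xmin[k], dets$ymin[k],
                  dets$xmax[k] - dets$xmin[k], dets$ymax[k] - dets$ymin[k]),
         score = dets$score[k])
  })
  jsonlite::write_json(res, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read COCO results JSON as a detection data.frame
#'
#' @param path a COCO results file.
#' @param categories data.frame `id`, `name` mapping category ids back to
#'   class names.
#' @return data.frame `image_id`, `class`, `score`, `xmin`, `ymin`, `xmax`,
#'   `ymax`.
#' @export
read_coco_detections <- function(path, categories) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!length(obj)) {
    return(data.frame(image_id = integer(0), class = character(0),
                      score = numeric(0), xmin = numeric(0), ymin = numeric(0),
                      xmax = numeric(0), ymax = numeric(0)))
  }
  rows <- lapply(obj, function(a) {
    bb <- as.numeric(unlist(a$bbox))
    validate_bbox(bb)
    data.frame(image_id = a$image_id,
               class = categories$name[match(a$category_id, categories$id)],
               score = as.numeric(a$score),
               xmin = bb[1], ymin = bb[2], xmax = bb[1] + bb[3], ymax = bb[2] + bb[4])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

fmt_matrix <- function(M) {
  apply(M, 1, function(row) paste(sprintf("%.17g", row), collapse = " "))
}

parse_matrix <- function(lines) {
  do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
}

#' Write a heatmap bundle to a directory
#'
#' One whitespace-separated text matrix per map (`%.17g` formatting, so
#' doubles round-trip bit-exactly) plus a `sidecar.json` recording the
#' geometry (width, height, s, sigma, noise sigma, seed, classes), so the
#' decoder never has to guess.
#'
#' @param bundle a `heatmap_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_heatmap_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "heatmap_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sidecar <- list(width = bundle$width, height = bundle$height, s = bundle$s,
                  sigma = bundle$sigma, noise_sigma = bundle$noise_sigma,
                  seed = bundle$seed, classes = as.list(bundle$classes),
                  keypoint_types = as.list(KEYPOINT_TYPES))
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (cl in bundle$classes) {
    for (tp in KEYPOINT_TYPES) {
      writeLines(fmt_matrix(bundle$heatmaps[[cl]][[tp]]),
                 file.path(dir, sprintf("heatmap_%s_%s.txt", cl, tp)))
      writeLines(fmt_matrix(bundle$gt[[cl]][[tp]]),
                 file.path(dir, sprintf("gt_%s_%s.txt", cl, tp)))
    }
  }
  for (tp in KEYPOINT_TYPES) {
    writeLines(fmt_matrix(bundle$offsets[[tp]]$dx),
               file.path(dir, sprintf("offset_%s_dx.txt", tp)))
    writeLines(fmt_matrix(bundle$offsets[[tp]]$dy),
               file.path(dir, sprintf("offset_%s_dy.txt", tp)))
  }
  invisible(dir)
}

#' Read a heatmap bundle written by [write_heatmap_bundle()]
#'
#' @param dir bundle directory.
#' @return a `heatmap_bundle`.
#' @export
read_heatmap_bundle <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                                 simplifyVector = TRUE)
  classes <- as.character(sidecar$classes)
  read_mat <- function(name) parse_matrix(readLines(file.path(dir, name)))
  heatmaps <- lapply(stats::setNames(classes, classes), function(cl) {
    lapply(stats::setNames(KEYPOINT_TYPES, KEYPOINT_TYPES), function(tp) {
      read_mat(sprintf("heatmap_%s_%s.txt", cl, tp))
    })
  })
  gt <- lapply(stats::setNames(classes, classes), function(cl) {
    lapply(stats::setNames(KEYPOINT_TYPES, KEYPOINT_TYPES), function(tp) {
      read_mat(sprintf("gt_%s_%s.txt", cl, tp))
    })
  })
  offsets <- lapply(stats::setNames(KEYPOINT_TYPES, KEYPOINT_TYPES), function(tp) {
    list(dx = read_mat(sprintf("offset_%s_dx.txt", tp)),
         dy = read_mat(sprintf("offset_%s_dy.txt", tp)))
  })
  structure(list(width = as.integer(sidecar$width),
                 height = as.integer(sidecar$height),
                 s = as.integer(sidecar$s), sigma = sidecar$sigma,
                 noise_sigma = sidecar$noise_sigma,
                 seed = as.integer(sidecar$seed), classes = classes,
                 heatmaps = heatmaps, gt = gt, offsets = offsets),
            class = "heatmap_bundle")
}

#' Write a spectrum reference to JSON
#'
#' @param ref a `spectrum_reference`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectrum_reference <- function(ref, path) {
  stopifnot(inherits(ref, "spectrum_reference"))
  obj <- list(class = ref$class, centroid = ref$centroid, radius = ref$radius,
              rule = ref$rule, q = ref$q, multiplier = ref$multiplier,
              n_train = ref$n_train, normalized = ref$normalized,
              mode = ref$mode,
              spectra = lapply(seq_len(nrow(ref$spectra)),
                               function(k) as.numeric(ref$spectra[k, ])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a spectrum reference written by [write_spectrum_reference()]
#'
#' @param path reference JSON file.
#' @return a `spectrum_reference`.
#' @export
read_spectrum_reference <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spectra <- obj$spectra
  if (is.list(spectra)) spectra <- do.call(rbind, lapply(spectra, as.numeric))
  spectra <- matrix(as.numeric(spectra), ncol = 4)
  structure(list(class = obj$class,
                 spectra = spectra,
                 centroid = as.numeric(obj$centroid),
                 radius = obj$radius, rule = obj$rule, q = obj$q,
                 multiplier = obj$multiplier, normalized = obj$normalized,
                 mode = obj$mode, n_train = obj$n_train),
            class = "spectrum_reference")
}

RUN_CONFIG_KEYS <- list(
  seed = "integer",
  verbosity = "integer",
  render = c("sigma", "s", "noise_sigma", "salt_pepper"),
  grouping = c("peak_threshold", "center_threshold", "score_threshold",
               "suppression_iou", "max_peaks", "verify", "strict_center"),
  reference = c("radius_rule", "q", "multiplier", "normalize", "mode")
)

#' Read the run configuration file
#'
#' A single human-readable YAML file holding every tunable of the render,
#' grouping and reference modules plus the seed. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return nested named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path) %||% list()
  bad <- setdiff(names(cfg), names(RUN_CONFIG_KEYS))
  if (length(bad)) {
    abort2(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")),
           "validation_error")
  }
  for (section in c("render", "grouping", "reference")) {
    bad <- setdiff(names(cfg[[section]]), RUN_CONFIG_KEYS[[section]])
    if (length(bad)) {
      abort2(sprintf("unknown config keys in '%s': %s", section,
                     paste(bad, collapse = ", ")), "validation_error")
    }
  }
  defaults <- default_run_config()
  for (nm in names(defaults)) {
    if (is.list(defaults[[nm]])) {
      for (k in names(cfg[[nm]])) defaults[[nm]][[k]] <- cfg[[nm]][[k]]
    } else if (!is.null(cfg[[nm]])) {
      defaults[[nm]] <- cfg[[nm]]
    }
  }
  defaults
}

#' Default run configuration
#' @return nested named list of all tunables.
#' @export
default_run_config <- function() {
  list(seed = 1L, verbosity = 1L,
       render = list(sigma = 1.2, s = 4L, noise_sigma = 0, salt_pepper = 0),
       grouping = list(peak_threshold = 0.1, center_threshold = 0.1,
                       score_threshold = 0.1, suppression_iou = 0.5,
                       max_peaks = 40L, verify = FALSE, strict_center = TRUE),
       reference = list(radius_rule = "quantile", q = 0.95, multiplier = 1.1,
                        normalize = FALSE, mode = "centroid"))
}

#' Write a run configuration file
#' @param cfg nested list as from [default_run_config()].
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Export a heatmap as a grayscale PNG for inspection
#'
#' Write-only convenience; requires the optional `png` package.
#'
#' @param heatmap numeric matrix in `[0, 1]`.
#' @param path output PNG file.
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(heatmap, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort2("the 'png' package is required for PNG export", "configuration_error")
  }
  png::writePNG(pmin(pmax(heatmap, 0), 1), path)
  invisible(path)
}
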