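#' Construct a multi-view specimen dataset
#'
#' A `mv_dataset` holds one record per specimen: its genus label (an integer
#' in `1..L`) and, for each of the three views (head, dorsum, profile), a
#' list of grayscale images. Images are numeric matrices with intensities in
#' `[0, 1]`. A specimen may hold zero, one or several pictures per view;
#' the cardinalities per view are conventionally written N_h, N_d, N_p.
#'
#' @param specimens A list of specimen records as built by [new_specimen()].
#' @param label_names Character vector naming the genus labels `1..L`.
#' @return An object of class `mv_dataset`.
#' @seealso [generate_dataset()], [read_manifest()], [split_dataset()]
#' @export
mv_dataset <- function(specimens, label_names) {
  ids <- vapply(specimens, function(s) s$specimen_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate specimen ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(specimens) <- ids
  genera <- vapply(specimens, function(s) s$genus, integer(1))
  L <- length(label_names)
  if (length(genera) > 0 && (any(genera < 1L) || any(genera > L))) {
    stop("genus labels must lie in 1..", L, call. = FALSE)
  }
  structure(
    list(specimens = specimens, n_labels = L, label_names = label_names),
    class = "mv_dataset"
  )
}

#' Construct one specimen record
#'
#' @param specimen_id Character identifier, unique within a dataset.
#' @param genus Integer genus label.
#' @param images Named list `list(head = , dorsum = , profile = )` of lists
#'   of grayscale image matrices (values in `[0, 1]`).
#' @return A specimen record (plain list).
#' @export
new_specimen <- function(specimen_id, genus,
                         images = list(head = list(), dorsum = list(),
                                       profile = list())) {
  for (v in mv_views()) {
    if (is.null(images[[v]])) images[[v]] <- list()
    for (img in images[[v]]) {
      if (!is.matrix(img) || !is.numeric(img)) {
        stop("images must be numeric matrices (specimen ", specimen_id, ")",
             call. = FALSE)
      }
      if (min(img) < 0 || max(img) > 1) {
        stop("image intensities must lie in [0, 1] (specimen ", specimen_id,
             ")", call. = FALSE)
      }
    }
  }
  list(specimen_id = as.character(specimen_id),
       genus = as.integer(genus),
       images = images[mv_views()])
}

#' @export
print.mv_dataset <- function(x, ...) {
  n <- length(x$specimens)
  npic <- sum(vapply(x$specimens,
                     function(s) sum(lengths(s$images)), numeric(1)))
  cat("<mv_dataset> ", n, " specimens, ", x$n_labels, " genera, ",
      npic, " pictures\n", sep = "")
  invisible(x)
}

#' Number of specimens in a dataset
#' @param ds A [mv_dataset()].
#' @return Integer count.
#' @export
n_specimens <- function(ds) length(ds$specimens)

#' Per-specimen picture counts per view
#'
#' @param ds A [mv_dataset()].
#' @return A tibble with columns `specimen_id`, `genus`, `n_head`,
#'   `n_dorsum`, `n_profile`.
#' @export
specimen_view_counts <- function(ds) {
  tibble::tibble(
    specimen_id = vapply(ds$specimens, `[[`, character(1), "specimen_id"),
    genus       = vapply(ds$specimens, `[[`, integer(1), "genus"),
    n_head    = vapply(ds$specimens, function(s) length(s$images$head), integer(1)),
    n_dorsum  = vapply(ds$specimens, function(s) length(s$images$dorsum), integer(1)),
    n_profile = vapply(ds$specimens, function(s) length(s$images$profile), integer(1))
  )
}

#' @export
as_tibble.mv_dataset <- function(x, ...) {
  rows <- purrr::map_dfr(x$specimens, function(s) {
    purrr::map_dfr(mv_views(), function(v) {
      n <- length(s$images[[v]])
      if (n == 0L) return(tibble::tibble())
      tibble::tibble(
        specimen_id = s$specimen_id,
        genus = s$genus,
        genus_name = x$label_names[s$genus],
        view = v,
        picture = seq_len(n),
        height = vapply(s$images[[v]], nrow, integer(1)),
        width = vapply(s$images[[v]], ncol, integer(1))
      )
    })
  })
  rows
}

# ---------------------------------------------------------------------------
# image loading

# Luminance-weighted grayscale conversion (Rec. 601 weights), pad-to-square
# with zeros, then bilinear resize to the configured square side.
load_gray_image <- function(path, image_size = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, " (use PNG or TIFF)",
         call. = FALSE)
  )
  img <- to_grayscale(img)
  if (!is.null(image_size)) img <- conform_image(img, image_size)
  img
}

to_grayscale <- function(img) {
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc >= 3L) {
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  pmin(pmax(img, 0), 1)
}

# Pad to square with zeros (image centred), then bilinear-resize.
conform_image <- function(img, image_size) {
  h <- nrow(img); w <- ncol(img)
  if (h != w) {
    side <- max(h, w)
    sq <- matrix(0, side, side)
    r0 <- (side - h) %/% 2
    c0 <- (side - w) %/% 2
    sq[r0 + seq_len(h), c0 + seq_len(w)] <- img
    img <- sq
  }
  if (nrow(img) != image_size) {
    img <- EBImage::imageData(
      EBImage::resize(img, w = image_size, h = image_size)
    )
  }
  pmin(pmax(img, 0), 1)
}

# ---------------------------------------------------------------------------
# manifest I/O

#' Read a dataset manifest
#'
#' A manifest lists one picture per row with fields `specimen_id`, `genus`,
#' `view` (one of head/dorsum/profile) and `path` (PNG or TIFF image file,
#' relative paths resolved against the manifest's directory). Both delimited
#' text (CSV) and JSON-lines manifests are accepted; the format is inferred
#' from the file extension (`.jsonl`/`.ndjson` vs anything else).
#'
#' Genus tokens are mapped to contiguous integer labels `1..L` in sorted
#' token order; the original tokens are kept as `label_names`.
#'
#' @param path Manifest file.
#' @param image_size Optional square side to conform every image to
#'   (pad-to-square then bilinear resize); `NULL` keeps native sizes.
#' @return A [mv_dataset()].
#' @export
read_manifest <- function(path, image_size = NULL) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "ndjson")) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    rows <- purrr::map_dfr(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) stop("manifest row ", i,
                                               ": invalid JSON (", conditionMessage(e), ")",
                                               call. = FALSE))
      tibble::as_tibble(rec)
    })
  } else {
    rows <- tibble::as_tibble(
      utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    )
  }
  required <- c("specimen_id", "genus", "view", "path")
  missing_cols <- setdiff(required, names(rows))
  if (length(missing_cols) > 0) {
    stop("manifest lacks required field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_view <- which(!(rows$view %in% mv_views()))
  if (length(bad_view) > 0) {
    stop("manifest row ", bad_view[1], ": unknown view token ",
         shQuote(rows$view[bad_view[1]]),
         " (admissible: head, dorsum, profile)", call. = FALSE)
  }

  base <- dirname(path)
  genus_tokens <- as.character(rows$genus)
  label_names <- sort(unique(genus_tokens))
  genus_idx <- match(genus_tokens, label_names)

  specimens <- list()
  for (i in seq_len(nrow(rows))) {
    sid <- as.character(rows$specimen_id[i])
    img_path <- rows$path[i]
    if (!file.exists(img_path)) img_path <- file.path(base, rows$path[i])
    img <- tryCatch(load_gray_image(img_path, image_size),
                    error = function(e) stop("manifest row ", i, ": ",
                                             conditionMessage(e), call. = FALSE))
    if (is.null(specimens[[sid]])) {
      specimens[[sid]] <- new_specimen(sid, genus_idx[i])
    } else if (specimens[[sid]]$genus != genus_idx[i]) {
      stop("manifest row ", i, ": specimen ", sid,
           " listed with conflicting genus labels", call. = FALSE)
    }
    v <- rows$view[i]
    specimens[[sid]]$images[[v]] <-
      c(specimens[[sid]]$images[[v]], list(img))
  }
  mv_dataset(unname(specimens), label_names)
}

#' Write a dataset to disk as images plus a manifest
#'
#' Writes one PNG per picture under `dir/images/`, a CSV manifest
#' `dir/manifest.csv`, and a JSON sidecar `dir/labels.json` recording the
#' genus-label mapping.
#'
#' @param ds A [mv_dataset()].
#' @param dir Target directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(ds, dir) {
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in ds$specimens) {
    for (v in mv_views()) {
      for (j in seq_along(s$images[[v]])) {
        fname <- sprintf("%s_%s_%d.png", s$specimen_id, v, j)
        png::writePNG(s$images[[v]][[j]], file.path(img_dir, fname))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          specimen_id = s$specimen_id,
          genus = ds$label_names[s$genus],
          view = v,
          path = file.path("images", fname)
        )
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(label_names = ds$label_names,
         labels = seq_len(ds$n_labels)),
    file.path(dir, "labels.json"),
    auto_unbox = FALSE, pretty = TRUE
  )
  invisible(manifest_path)
}

# ---------------------------------------------------------------------------
# filtering and summaries

#' Drop genera with too few specimens
#'
#' Retains only specimens whose genus has at least `min_specimens` specimens
#' in the dataset, then re-indexes the surviving labels to a contiguous
#' `1..L'`. The old-to-new label mapping is attached as attribute
#' `"label_map"` (a tibble with `old_label`, `name`, `new_label`).
#'
#' @param ds A [mv_dataset()].
#' @param min_specimens Minimum specimen count for a genus to be retained.
#' @return The filtered [mv_dataset()].
#' @export
filter_labels_by_support <- function(ds, min_specimens) {
  stopifnot(min_specimens >= 1)
  genera <- vapply(ds$specimens, `[[`, integer(1), "genus")
  counts <- tabulate(genera, nbins = ds$n_labels)
  keep_labels <- which(counts >= min_specimens)
  if (length(keep_labels) == 0L) {
    rlang::abort("no genus meets the minimum-support threshold; dataset empty",
                 class = "triview_empty_dataset")
  }
  new_of_old <- rep(NA_integer_, ds$n_labels)
  new_of_old[keep_labels] <- seq_along(keep_labels)
  kept <- purrr::keep(ds$specimens, function(s) s$genus %in% keep_labels)
  kept <- purrr::map(kept, function(s) {
    s$genus <- new_of_old[s$genus]
    s
  })
  out <- mv_dataset(unname(kept), ds$label_names[keep_labels])
  attr(out, "label_map") <- tibble::tibble(
    old_label = keep_labels,
    name = ds$label_names[keep_labels],
    new_label = seq_along(keep_labels)
  )
  out
}

#' Dataset cardinality summary
#'
#' Tabulates, for the standard per-view picture-count constraints, how many
#' specimens satisfy each and the corresponding rate over all specimens:
#' at least one picture overall; exactly one picture in every view; at least
#' one picture in every view; and at least one head / profile / dorsal
#' picture.
#'
#' @param ds A [mv_dataset()].
#' @return A tibble with columns `constraint`, `n_specimens`, `rate`.
#' @export
cardinality_summary <- function(ds) {
  cnt <- specimen_view_counts(ds)
  total <- nrow(cnt)
  n_of <- function(keep) if (total == 0L) 0L else sum(keep)
  rows <- tibble::tibble(
    constraint = c("N_h + N_p + N_d >= 1",
                   "N_h = N_p = N_d = 1",
                   "N_h >= 1 and N_p >= 1 and N_d >= 1",
                   "N_h >= 1",
                   "N_p >= 1",
                   "N_d >= 1"),
    n_specimens = c(
      n_of(cnt$n_head + cnt$n_profile + cnt$n_dorsum >= 1),
      n_of(cnt$n_head == 1 & cnt$n_profile == 1 & cnt$n_dorsum == 1),
      n_of(cnt$n_head >= 1 & cnt$n_profile >= 1 & cnt$n_dorsum >= 1),
      n_of(cnt$n_head >= 1),
      n_of(cnt$n_profile >= 1),
      n_of(cnt$n_dorsum >= 1)
    )
  )
  rows$rate <- if (total == 0L) 0 else rows$n_specimens / total
  rows
}

# ---------------------------------------------------------------------------
# splitting

# Largest-remainder apportionment of n items into quotas proportional to
# `fractions`; deterministic (ties go to the earlier part).
largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  short <- n - sum(base)
  if (short > 0) {
    ord <- order(-(exact - base), seq_along(fractions))
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

subset_dataset <- function(ds, ids) {
  mv_dataset(unname(ds$specimens[ids]), ds$label_names)
}

#' Split a dataset into train, validation and test parts
#'
#' Specimens are partitioned per genus (stratified) with largest-remainder
#' quotas. The validation and test parts are drawn only from specimens with
#' exactly one picture per view; training keeps everything else, including
#' specimens with extra or missing pictures. The split is deterministic for
#' a fixed seed.
#'
#' @param ds A [mv_dataset()].
#' @param fractions Numeric vector of three non-negative fractions
#'   (train, validation, test) summing to 1.
#' @param seed Integer seed.
#' @return A `dataset_split`: list with elements `train`, `validation`,
#'   `test` (each a [mv_dataset()]), plus `fractions` and `seed`.
#' @export
split_dataset <- function(ds, fractions = c(0.7, 0.2, 0.1), seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` must be three non-negative numbers summing to 1",
         call. = FALSE)
  }
  if (n_specimens(ds) == 0L) stop("cannot split an empty dataset", call. = FALSE)
  cnt <- specimen_view_counts(ds)
  one_per_view <- cnt$n_head == 1 & cnt$n_dorsum == 1 & cnt$n_profile == 1

  train_ids <- character(0); val_ids <- character(0); test_ids <- character(0)
  starved <- character(0)
  for (g in sort(unique(cnt$genus))) {
    in_g <- cnt$genus == g
    ids <- sort(cnt$specimen_id[in_g])
    q <- largest_remainder(length(ids), fractions)
    # keep every genus with >= 3 specimens represented in training
    if (fractions[1] > 0 && length(ids) >= 3L && q[1] == 0L) {
      donor <- which.max(q[2:3]) + 1L
      q[donor] <- q[donor] - 1L
      q[1] <- q[1] + 1L
    }
    eligible <- sort(cnt$specimen_id[in_g & one_per_view])
    eligible <- with_local_seed(hash_seed(seed, "split", g), sample(eligible))
    q_val <- min(q[2], length(eligible))
    q_test <- min(q[3], length(eligible) - q_val)
    if (q_val < q[2] || q_test < q[3]) {
      starved <- c(starved, ds$label_names[g])
    }
    val_ids <- c(val_ids, utils::head(eligible, q_val))
    test_ids <- c(test_ids, eligible[seq_len(q_test) + q_val])
    train_ids <- c(train_ids, setdiff(ids, c(utils::head(eligible, q_val + q_test))))
  }
  if (length(starved) > 0) {
    warning("too few exactly-one-per-view specimens for the requested ",
            "validation/test quota in genus: ",
            paste(starved, collapse = ", "), call. = FALSE)
  }
  structure(
    list(train = subset_dataset(ds, train_ids),
         validation = subset_dataset(ds, val_ids),
         test = subset_dataset(ds, test_ids),
         fractions = fractions,
         seed = as.integer(seed)),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split> train ", n_specimens(x$train),
      " / validation ", n_specimens(x$validation),
      " / test ", n_specimens(x$test), " specimens\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# flattening

#' Flatten a dataset into one row per picture
#'
#' @param ds A [mv_dataset()].
#' @param views Optional subset of [mv_views()] to keep.
#' @param shuffle_seed Optional integer; when given, rows are shuffled
#'   deterministically.
#' @return A tibble with columns `specimen_id`, `genus`, `view`, `picture`
#'   and a list-column `pixels` of grayscale matrices.
#' @export
flatten_to_samples <- function(ds, views = NULL, shuffle_seed = NULL) {
  if (is.null(views)) views <- mv_views() else views <- as_view(views, TRUE)
  rows <- purrr::map_dfr(ds$specimens, function(s) {
    purrr::map_dfr(views, function(v) {
      n <- length(s$images[[v]])
      if (n == 0L) return(tibble::tibble())
      tibble::tibble(
        specimen_id = s$specimen_id,
        genus = s$genus,
        view = v,
        picture = seq_len(n),
        pixels = s$images[[v]]
      )
    })
  })
  if (!is.null(shuffle_seed) && nrow(rows) > 1L) {
    rows <- rows[with_local_seed(hash_seed(shuffle_seed, "flatten"),
                                 sample.int(nrow(rows))), ]
  }
  rows
}

# Stack the `pixels` list-column of flatten_to_samples() output into an
# H x W x N array for the CNN engine, conforming sizes when needed.
samples_to_array <- function(samples, image_size) {
  n <- nrow(samples)
  arr <- array(0, dim = c(image_size, image_size, max(n, 1L)))
  for (i in seq_len(n)) {
    img <- samples$pixels[[i]]
    if (nrow(img) != image_size || ncol(img) != image_size) {
      img <- conform_image(img, image_size)
    }
    arr[, , i] <- img
  }
  arr
}
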