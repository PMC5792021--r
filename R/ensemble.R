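#' Build a multi-view classifier ensemble
#'
#' Four configurations are supported. `G` applies the single
#' general-purpose model to each of the three view images (3 members, one
#' weight set); `S` uses the three view-specific models (3 members); `T`
#' the three transfer models (3 members); `All` every regime x view
#' combination (9 members). Members are `(regime, view)` pairs; a
#' specimen is classified by summing the members' softmax outputs.
#'
#' @param kind One of `"G"`, `"S"`, `"T"`, `"All"`.
#' @param general A general-purpose `trained_model` (required for G, All).
#' @param specific Named list of view-specific models over
#'   `c(head, dorsum, profile)` (required for S, All).
#' @param transfer Named list of transfer models over the three views
#'   (required for T, All).
#' @return An `mv_ensemble`: a list with `kind` and a `members` tibble
#'   (`regime`, `view`, `model` list-column).
#' @export
build_ensemble <- function(kind = c("G", "S", "T", "All"), general = NULL,
                           specific = NULL, transfer = NULL) {
  kind <- match.arg(kind)
  need <- switch(kind,
    G = list(g = TRUE, s = FALSE, t = FALSE),
    S = list(g = FALSE, s = TRUE, t = FALSE),
    T = list(g = FALSE, s = FALSE, t = TRUE),
    All = list(g = TRUE, s = TRUE, t = TRUE)
  )
  check_model <- function(m, regime, view = NULL) {
    if (is.null(m)) {
      stop("missing model for (", regime,
           if (!is.null(view)) paste0(", ", view), ")", call. = FALSE)
    }
    if (!inherits(m, "trained_model") || m$regime != regime) {
      stop("model for (", regime,
           if (!is.null(view)) paste0(", ", view),
           ") is not a trained ", regime, " model", call. = FALSE)
    }
    if (!is.null(view) && !identical(m$view, view)) {
      stop("model supplied for view ", view, " was trained on view ",
           m$view %||% "<none>", call. = FALSE)
    }
    m
  }
  rows <- list()
  if (need$g) {
    check_model(general, "general")
    for (v in mv_views()) {
      rows[[length(rows) + 1L]] <-
        tibble::tibble(regime = "general", view = v, model = list(general))
    }
  }
  for (spec in list(list(flag = need$s, set = specific, regime = "specific"),
                    list(flag = need$t, set = transfer, regime = "transfer"))) {
    if (!spec$flag) next
    for (v in mv_views()) {
      m <- check_model(spec$set[[v]], spec$regime, v)
      rows[[length(rows) + 1L]] <-
        tibble::tibble(regime = spec$regime, view = v, model = list(m))
    }
  }
  structure(list(kind = kind, members = dplyr::bind_rows(rows)),
            class = "mv_ensemble")
}

#' @export
print.mv_ensemble <- function(x, ...) {
  cat("<mv_ensemble> kind ", x$kind, ", ", nrow(x$members), " members\n",
      sep = "")
  print(dplyr::select(x$members, "regime", "view"))
  invisible(x)
}

#' Sum member score vectors
#'
#' Element-wise summation of softmax outputs — no renormalization, since
#' the ranking is invariant to positive scaling. The aggregated vector's
#' total mass equals the member count.
#'
#' @param scores List of equal-length numeric score vectors (>= 1).
#' @return Numeric vector with attribute `member_count`.
#' @export
aggregate_scores <- function(scores) {
  if (length(scores) < 1L) stop("no score vectors to aggregate", call. = FALSE)
  len <- vapply(scores, length, integer(1))
  if (length(unique(len)) != 1L) {
    stop("score vectors have differing lengths", call. = FALSE)
  }
  out <- Reduce(`+`, scores)
  attr(out, "member_count") <- length(scores)
  out
}

# Aggregated score matrix of an ensemble over eligible specimens.
ensemble_scores <- function(ensemble, ds) {
  check_one_per_view(ds)
  ids <- names(ds$specimens)
  L <- ds$n_labels
  total <- matrix(0, length(ids), L)
  for (j in seq_len(nrow(ensemble$members))) {
    v <- ensemble$members$view[j]
    m <- ensemble$members$model[[j]]
    imgs <- lapply(ds$specimens, function(s) s$images[[v]][[1]])
    total <- total + score_images(m, imgs)
  }
  rownames(total) <- ids
  total
}

#' Classify one specimen with an ensemble
#'
#' Each member scores its designated view's single picture; the softmax
#' outputs are summed and the top-t list of the aggregated score returned.
#'
#' @param ensemble An [build_ensemble()] result.
#' @param specimen A specimen record with exactly one picture per view.
#' @param t List size.
#' @return Integer vector: the top-t label list.
#' @export
predict_specimen <- function(ensemble, specimen, t = 1L) {
  for (v in unique(ensemble$members$view)) {
    if (length(specimen$images[[v]]) != 1L) {
      stop("specimen ", specimen$specimen_id, " needs exactly one ", v,
           " picture (has ", length(specimen$images[[v]]), ")",
           call. = FALSE)
    }
  }
  member_scores <- purrr::map(seq_len(nrow(ensemble$members)), function(j) {
    v <- ensemble$members$view[j]
    score_image(ensemble$members$model[[j]], specimen$images[[v]][[1]])
  })
  top_t(as.numeric(aggregate_scores(member_scores)), t)
}

#' Evaluate an ensemble on a test dataset
#'
#' Aggregates member scores per specimen (the specimen, not the picture, is
#' the evaluation unit here) and computes the top-t metrics report.
#'
#' @param ensemble An [build_ensemble()] result.
#' @param test A [mv_dataset()] whose specimens have exactly one picture
#'   per view.
#' @param ts List sizes (default 1, 3, 5).
#' @return A [metrics_report()] tibble with an `ensemble` column prepended.
#' @export
evaluate_ensemble <- function(ensemble, test, ts = c(1L, 3L, 5L)) {
  if (n_specimens(test) == 0L) stop("empty test set", call. = FALSE)
  scores <- ensemble_scores(ensemble, test)
  truths <- vapply(test$specimens, `[[`, integer(1), "genus")
  rep <- metrics_report(scores, truths, ts)
  dplyr::mutate(rep, ensemble = ensemble$kind, .before = 1)
}

#' Evaluate a single model per view on a dataset
#'
#' The per-picture counterpart of [evaluate_ensemble()]: scores every
#' picture of the requested views with one model and reports the top-t
#' metrics (the picture is the evaluation unit).
#'
#' @param model A `trained_model`.
#' @param ds A [mv_dataset()].
#' @param views Views to include (default: the model's own view, or all
#'   views for a general model).
#' @param ts List sizes.
#' @return A [metrics_report()] tibble with `regime` and `view` columns.
#' @export
evaluate_model <- function(model, ds, views = NULL, ts = c(1L, 3L, 5L)) {
  if (is.null(views)) views <- model$view %||% mv_views()
  samples <- flatten_to_samples(ds, views)
  if (nrow(samples) == 0L) stop("no pictures to evaluate", call. = FALSE)
  sc <- score_images(model, samples)
  rep <- metrics_report(sc, samples$genus, ts)
  dplyr::mutate(rep, regime = model$regime,
                view = paste(views, collapse = "+"), .before = 1)
}
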