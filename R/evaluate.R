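#' Top-t label list for one score vector
#'
#' Labels sorted by descending score; ties broken by ascending label index
#' (a documented, stable rule that also makes every top-t list a prefix of
#' the top-(t+1) list). With `t >= L` the full ranking is returned.
#'
#' @param scores Numeric score vector over labels (softmax or aggregated).
#' @param t List size (>= 1).
#' @return Integer vector of `min(t, L)` distinct label indices, most
#'   likely first.
#' @export
#' @examples
#' top_t(c(0.1, 0.7, 0.2), 2) # c(2, 3)
#' top_t(c(0.4, 0.4, 0.2), 1) # 1 (tie -> lower index)
top_t <- function(scores, t) {
  stopifnot(t >= 1)
  ord <- order(-scores, seq_along(scores))
  ord[seq_len(min(t, length(scores)))]
}

#' Top-t lists for a score matrix
#'
#' @param scores `N x L` score matrix (one row per sample).
#' @param t List size.
#' @return `N x min(t, L)` integer matrix; row i is [top_t()] of row i.
#' @export
top_t_lists <- function(scores, t) {
  t_eff <- min(t, ncol(scores))
  out <- matrix(0L, nrow(scores), t_eff)
  for (i in seq_len(nrow(scores))) out[i, ] <- top_t(scores[i, ], t)
  out
}

#' Per-sample correctness of top-t predictions
#'
#' A prediction is correct when the true label appears anywhere in the
#' sample's top-t list.
#'
#' @param lists Integer matrix of top-t lists ([top_t_lists()]).
#' @param truths Integer vector of true labels, one per row of `lists`.
#' @return Logical vector.
#' @export
correctness <- function(lists, truths) {
  stopifnot(nrow(lists) == length(truths))
  vapply(seq_along(truths),
         function(i) truths[i] %in% lists[i, ], logical(1))
}

#' Top-t accuracy
#'
#' @inheritParams correctness
#' @return Fraction of samples whose true label is in their list.
#' @export
accuracy_at <- function(lists, truths) {
  if (length(truths) == 0L) stop("no samples to evaluate", call. = FALSE)
  mean(correctness(lists, truths))
}

#' Per-label precision of top-t list predictions
#'
#' Label `g` counts as predicted for a sample whenever `g` appears in the
#' sample's top-t list; precision is the fraction of those predictions whose
#' true label is `g`. At `t = 1` this is ordinary per-class precision. A
#' label never appearing in any list has precision 0 (the 0/0 convention,
#' which penalizes never-predicted labels).
#'
#' @inheritParams correctness
#' @param label Label index `g`.
#' @return Precision in `[0, 1]`.
#' @export
label_precision <- function(lists, truths, label) {
  predicted <- vapply(seq_len(nrow(lists)),
                      function(i) label %in% lists[i, ], logical(1))
  if (!any(predicted)) return(0)
  sum(predicted & truths == label) / sum(predicted)
}

#' Accuracy, average precision and minimum precision at several list sizes
#'
#' For each requested list size t, computes the top-t accuracy, the
#' unweighted (macro) mean of per-label precisions, and the minimum
#' per-label precision, over the labels present in `truths`. The per-label
#' precision vectors are kept in a list-column.
#'
#' @param scores `N x L` score matrix.
#' @param truths Integer vector of true labels.
#' @param ts List sizes to evaluate (default 1, 3, 5).
#' @return A `metrics_report` tibble with columns `t`, `accuracy`,
#'   `average_precision`, `minimum_precision`, `label_precision`.
#' @export
metrics_report <- function(scores, truths, ts = c(1L, 3L, 5L)) {
  if (length(truths) == 0L) stop("no samples to evaluate", call. = FALSE)
  stopifnot(nrow(scores) == length(truths))
  labels <- sort(unique(truths))
  rows <- purrr::map_dfr(ts, function(t) {
    lists <- top_t_lists(scores, t)
    prec <- vapply(labels, function(g) label_precision(lists, truths, g),
                   numeric(1))
    names(prec) <- labels
    tibble::tibble(
      t = as.integer(t),
      accuracy = accuracy_at(lists, truths),
      average_precision = mean(prec),
      minimum_precision = min(prec),
      label_precision = list(prec)
    )
  })
  class(rows) <- c("metrics_report", class(rows))
  rows
}

# ---------------------------------------------------------------------------
# diversity

#' Pairwise double-fault diversity measures
#'
#' Over the per-sample correctness indicators of two classifiers: `bc` both
#' correct, `df` both at fault, `sc` at least one correct, `oc` exactly one
#' correct. The identities `bc + oc + df = 1` and `sc = bc + oc` hold
#' exactly. `bc` reads as a consensus measure, `oc` as useful diversity /
#' complementarity.
#'
#' @param a,b Logical correctness vectors of equal, positive length.
#' @return A one-row tibble with columns `bc`, `df`, `sc`, `oc`.
#' @export
#' @examples
#' pairwise_diversity(c(TRUE, TRUE, FALSE, FALSE),
#'                    c(TRUE, FALSE, TRUE, FALSE))
pairwise_diversity <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (length(a) == 0L) stop("empty correctness vectors", call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  bc <- mean(a & b)
  oc <- mean(xor(a, b))
  # sc and df are derived from bc and oc so that the identities
  # sc = bc + oc and bc + oc + df = 1 hold to the last bit
  sc <- bc + oc
  tibble::tibble(bc = bc, df = 1 - sc, sc = sc, oc = oc)
}

#' Ensemble-level diversity report
#'
#' Computes the four pairwise measures for every pair of members and their
#' unweighted averages over all pairs (the ensemble-level diversity).
#'
#' @param members Named list (>= 2) of logical correctness vectors of equal
#'   length.
#' @param t Optional list size this correctness context corresponds to
#'   (recorded in the report).
#' @return A `diversity_report` tibble with one row per pair (`member_a`,
#'   `member_b`, `bc`, `df`, `sc`, `oc`, `t`); the pair-averaged measures
#'   are attached as attribute `"average"` (a one-row tibble).
#' @export
ensemble_diversity <- function(members, t = NA_integer_) {
  if (length(members) < 2L) {
    stop("at least two ensemble members required", call. = FALSE)
  }
  if (is.null(names(members)) || any(!nzchar(names(members)))) {
    names(members) <- paste0("m", seq_along(members))
  }
  pairs <- utils::combn(names(members), 2)
  rows <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    pa <- pairs[1, j]; pb <- pairs[2, j]
    dplyr::bind_cols(
      tibble::tibble(t = as.integer(t), member_a = pa, member_b = pb),
      pairwise_diversity(members[[pa]], members[[pb]])
    )
  })
  avg <- dplyr::summarise(rows, t = t[1], bc = mean(bc), df = mean(df),
                          sc = mean(sc), oc = mean(oc))
  attr(rows, "average") <- avg
  class(rows) <- c("diversity_report", class(rows))
  rows
}

#' Pair-averaged diversity of a report
#' @param report A [ensemble_diversity()] result.
#' @return The one-row tibble of pair-averaged `bc`, `df`, `sc`, `oc`.
#' @export
diversity_average <- function(report) {
  attr(report, "average")
}

#' Correctness vectors of single-view classifiers over a dataset
#'
#' Scores every eligible specimen's single picture per view with the given
#' model/view assignments and returns one correctness vector per member —
#' the inputs to [ensemble_diversity()].
#'
#' @param members Named list of `list(model = , view = )` entries.
#' @param ds A [mv_dataset()] whose specimens have exactly one picture per
#'   view.
#' @param t List size.
#' @return Named list of logical vectors (one entry per specimen, in
#'   specimen order).
#' @export
member_correctness <- function(members, ds, t = 1L) {
  check_one_per_view(ds)
  truths <- vapply(ds$specimens, `[[`, integer(1), "genus")
  lapply(members, function(m) {
    imgs <- lapply(ds$specimens, function(s) s$images[[m$view]][[1]])
    sc <- score_images(m$model, imgs)
    correctness(top_t_lists(sc, t), truths)
  })
}

check_one_per_view <- function(ds) {
  cnt <- specimen_view_counts(ds)
  bad <- cnt$n_head != 1 | cnt$n_dorsum != 1 | cnt$n_profile != 1
  if (any(bad)) {
    stop("specimens without exactly one picture per view: ",
         paste(utils::head(cnt$specimen_id[bad], 5), collapse = ", "),
         if (sum(bad) > 5) ", ...",
         call. = FALSE)
  }
  invisible(ds)
}
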