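#' Configuration for the synthetic multi-view generator
#'
#' The generator emulates the statistical structure of multi-view specimen
#' photograph collections: every genus has a shared body shape visible in all
#' three views plus view-specific discriminative detail (texture frequency,
#' orientation and a marking spot), and each rendered picture adds small
#' random pose jitter and optional Gaussian pixel noise.
#'
#' @param n_genera Number of genus labels L (>= 2).
#' @param specimens_per_genus Specimens per genus.
#' @param image_size Square image side in pixels (>= 16).
#' @param view_informativeness Either a named numeric vector over
#'   `c(head, dorsum, profile)` with entries in `[0, 1]`, or an
#'   `n_genera x 3` matrix (columns in canonical view order) giving per-genus
#'   per-view scaling of the view-specific content. 0 removes all
#'   view-specific detail from that view; 1 renders it at full contrast.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (clipped to `[0, 1]` after addition).
#' @param extra_picture_prob Probability that a view holds a second picture
#'   of the specimen. The default 3.35/3 - 1 reproduces an average of 3.35
#'   pictures per specimen over the three views.
#' @param jitter_rotation Half-range (radians) of the uniform per-picture
#'   rotation jitter.
#' @param jitter_shift Half-range (fraction of the image half-side) of the
#'   uniform per-picture translation jitter.
#' @param seed Master integer seed; every specimen/view/picture derives its
#'   own seed from it by hashing, so generation is order-independent.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_genera = 5L,
                         specimens_per_genus = 60L,
                         image_size = 64L,
                         view_informativeness = c(head = 1, dorsum = 0.6,
                                                  profile = 0.8),
                         noise_sd = 0.05,
                         extra_picture_prob = 3.35 / 3 - 1,
                         jitter_rotation = 0.05,
                         jitter_shift = 0.03,
                         seed = 1L) {
  stopifnot(n_genera >= 2, specimens_per_genus >= 1, image_size >= 16,
            noise_sd >= 0, extra_picture_prob >= 0, extra_picture_prob <= 1,
            jitter_rotation >= 0, jitter_shift >= 0)
  vi <- view_informativeness
  if (is.matrix(vi)) {
    stopifnot(nrow(vi) == n_genera, ncol(vi) == 3)
    colnames(vi) <- mv_views()
  } else {
    stopifnot(all(mv_views() %in% names(vi)))
    vi <- matrix(rep(vi[mv_views()], each = n_genera), nrow = n_genera,
                 dimnames = list(NULL, mv_views()))
  }
  if (any(vi < 0) || any(vi > 1)) {
    stop("view_informativeness entries must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_genera = as.integer(n_genera),
         specimens_per_genus = as.integer(specimens_per_genus),
         image_size = as.integer(image_size),
         view_informativeness = vi,
         noise_sd = noise_sd,
         extra_picture_prob = extra_picture_prob,
         jitter_rotation = jitter_rotation,
         jitter_shift = jitter_shift,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Parameter ranges for archetype sampling. Shared parameters control the
# body ellipse; view parameters control a masked sinusoidal texture and a
# marking spot.
SHARED_RANGES <- list(
  body_a = c(0.35, 0.70), body_b = c(0.25, 0.55),
  body_theta = c(-0.6, 0.6), body_intensity = c(0.45, 0.80)
)
VIEW_RANGES <- list(
  freq = c(1.5, 5.0), angle = c(0, pi), phase = c(0, 2 * pi),
  amp = c(0.25, 0.45), spot_x = c(-0.45, 0.45), spot_y = c(-0.45, 0.45),
  spot_r = c(0.10, 0.22)
)

runif_ranges <- function(ranges) {
  vapply(ranges, function(r) stats::runif(1, r[1], r[2]), numeric(1))
}

# Distance between archetypes in range-normalised parameter space.
archetype_distance <- function(a, b) {
  norm_vec <- function(p, ranges) {
    (p - vapply(ranges, `[`, numeric(1), 1)) /
      vapply(ranges, function(r) r[2] - r[1], numeric(1))
  }
  d2 <- sum((norm_vec(a$shared_params, SHARED_RANGES) -
               norm_vec(b$shared_params, SHARED_RANGES))^2)
  for (v in mv_views()) {
    d2 <- d2 + sum((norm_vec(a$view_params[[v]], VIEW_RANGES) -
                      norm_vec(b$view_params[[v]], VIEW_RANGES))^2)
  }
  sqrt(d2)
}

# Minimum pairwise separation (normalised parameter distance) enforced
# between archetypes.
MIN_ARCHETYPE_SEPARATION <- 0.8

#' Draw genus archetypes
#'
#' Each archetype holds the shared body-shape parameters (visible in every
#' view) and three view-specific parameter vectors. Archetypes are drawn by
#' rejection sampling until all pairwise distances in range-normalised
#' parameter space reach the documented minimum separation (0.8, the
#' constant `MIN_ARCHETYPE_SEPARATION`), so distinct genera are
#' distinguishable by construction.
#'
#' @param n_genera Number of archetypes (>= 2).
#' @param seed Integer seed; the draw is deterministic given it.
#' @return A list of `genus_archetype` objects.
#' @export
make_archetypes <- function(n_genera, seed = 1L) {
  if (n_genera < 2) stop("n_genera must be at least 2", call. = FALSE)
  with_local_seed(hash_seed(seed, "archetypes"), {
    out <- list()
    attempts <- 0L
    while (length(out) < n_genera) {
      cand <- structure(
        list(genus = length(out) + 1L,
             shared_params = runif_ranges(SHARED_RANGES),
             view_params = stats::setNames(
               lapply(mv_views(), function(v) runif_ranges(VIEW_RANGES)),
               mv_views())),
        class = "genus_archetype"
      )
      dists <- vapply(out, archetype_distance, numeric(1), b = cand)
      if (length(dists) == 0L || min(dists) >= MIN_ARCHETYPE_SEPARATION) {
        out[[length(out) + 1L]] <- cand
      }
      attempts <- attempts + 1L
      if (attempts > 1000L * n_genera) {
        stop("could not place ", n_genera, " archetypes at separation ",
             MIN_ARCHETYPE_SEPARATION, call. = FALSE)
      }
    }
    out
  })
}

#' Draw strictly complementary genus archetypes
#'
#' Builds `n_groups * per_group` archetypes organised into groups, each group
#' assigned one designated view (cycling through head, dorsum, profile).
#' Within a group all genera share identical body parameters and identical
#' view parameters in the two non-designated views; they differ only in the
#' designated view. A classifier restricted to one view can therefore
#' separate genera within that view's group (and tell groups apart), but is
#' blind to the within-group identity of the other groups — the substrate
#' for testing ensemble complementarity.
#'
#' @param n_groups Number of groups (one designated view each, cycling).
#' @param per_group Genera per group (>= 2).
#' @param seed Integer seed.
#' @return A list of `genus_archetype` objects with attributes `group` and
#'   `designated_view` on each element.
#' @export
make_complementary_archetypes <- function(n_groups = 3L, per_group = 2L,
                                          seed = 1L) {
  stopifnot(n_groups >= 1, per_group >= 2)
  with_local_seed(hash_seed(seed, "comp-arch"), {
    out <- list()
    group_shared <- list()
    for (grp in seq_len(n_groups)) {
      repeat {
        shared <- runif_ranges(SHARED_RANGES)
        seps <- vapply(group_shared, function(s)
          sqrt(sum(((shared - s) /
                      vapply(SHARED_RANGES, function(r) r[2] - r[1],
                             numeric(1)))^2)), numeric(1))
        if (length(seps) == 0L || min(seps) >= 0.4) break
      }
      group_shared[[grp]] <- shared
      desig <- mv_views()[(grp - 1L) %% 3L + 1L]
      base_views <- stats::setNames(
        lapply(mv_views(), function(v) runif_ranges(VIEW_RANGES)), mv_views())
      desig_params <- list()
      for (m in seq_len(per_group)) {
        repeat {
          cand <- runif_ranges(VIEW_RANGES)
          seps <- vapply(desig_params, function(p)
            sqrt(sum(((cand - p) /
                        vapply(VIEW_RANGES, function(r) r[2] - r[1],
                               numeric(1)))^2)), numeric(1))
          if (length(seps) == 0L || min(seps) >= 0.6) break
        }
        desig_params[[m]] <- cand
        vp <- base_views
        vp[[desig]] <- cand
        a <- structure(
          list(genus = length(out) + 1L, shared_params = shared,
               view_params = vp),
          class = "genus_archetype",
          group = grp, designated_view = desig
        )
        out[[length(out) + 1L]] <- a
      }
    }
    out
  })
}

#' Render one synthetic picture
#'
#' Deterministically renders the grayscale picture of an archetype in one
#' view: a soft-edged body ellipse from the shared parameters, plus the
#' view's sinusoidal texture and marking spot scaled by the configured view
#' informativeness, small rotation/translation jitter, and additive Gaussian
#' noise clipped to `[0, 1]`.
#'
#' @param archetype A `genus_archetype`.
#' @param view One of [mv_views()].
#' @param config A [synth_config()].
#' @param seed Integer per-sample seed (jitter and noise derive from it).
#' @param canonical If `TRUE`, render without jitter and noise (the genus
#'   template used by the nearest-archetype oracle).
#' @return A grayscale image matrix in `[0, 1]`.
#' @export
render_view <- function(archetype, view, config, seed = 1L,
                        canonical = FALSE) {
  view <- as_view(view)
  px <- config$image_size
  sp <- archetype$shared_params
  vp <- archetype$view_params[[view]]
  info <- config$view_informativeness[archetype$genus, view]

  with_local_seed(seed, {
    if (canonical) {
      tj <- 0; dx <- 0; dy <- 0
    } else {
      tj <- stats::runif(1, -config$jitter_rotation, config$jitter_rotation)
      dx <- stats::runif(1, -config$jitter_shift, config$jitter_shift)
      dy <- stats::runif(1, -config$jitter_shift, config$jitter_shift)
    }
    ax <- seq(-1, 1, length.out = px)
    X <- matrix(ax, px, px, byrow = TRUE)
    Y <- matrix(ax, px, px)
    u <- cos(tj) * (X - dx) + sin(tj) * (Y - dy)
    w <- -sin(tj) * (X - dx) + cos(tj) * (Y - dy)

    ct <- cos(sp[["body_theta"]]); st <- sin(sp[["body_theta"]])
    p <- ct * u + st * w
    q <- -st * u + ct * w
    ell <- (p / sp[["body_a"]])^2 + (q / sp[["body_b"]])^2
    mask <- 1 / (1 + exp((ell - 1) * 8))
    body <- sp[["body_intensity"]] * mask

    grating <- sin(2 * pi * vp[["freq"]] *
                     (cos(vp[["angle"]]) * u + sin(vp[["angle"]]) * w) +
                     vp[["phase"]])
    spot <- exp(-(((u - vp[["spot_x"]])^2 + (w - vp[["spot_y"]])^2) /
                    vp[["spot_r"]]^2))

    img <- 0.08 + body + info * (vp[["amp"]] * mask * grating + 0.35 * spot)
    if (!canonical && config$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(px * px, 0, config$noise_sd), px, px)
    }
    pmin(pmax(img, 0), 1)
  })
}

#' Generate a synthetic multi-view dataset
#'
#' Renders `n_genera * specimens_per_genus` specimens, each with at least one
#' picture per view and, with probability `extra_picture_prob`, a second
#' picture per view. Every picture's seed is hashed from
#' `(seed, specimen_id, view, picture index)`, so the result is deterministic
#' and independent of generation order. The archetypes and config used are
#' attached as attributes `"archetypes"` and `"config"`.
#'
#' @param config A [synth_config()].
#' @param archetypes Optional pre-built archetype list (e.g. from
#'   [make_complementary_archetypes()]); drawn with [make_archetypes()]
#'   when absent. Its length must equal `config$n_genera`.
#' @return A [mv_dataset()].
#' @export
generate_dataset <- function(config, archetypes = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(archetypes)) {
    archetypes <- make_archetypes(config$n_genera, config$seed)
  }
  if (length(archetypes) != config$n_genera) {
    stop("length(archetypes) must equal config$n_genera", call. = FALSE)
  }
  specimens <- list()
  for (g in seq_len(config$n_genera)) {
    for (i in seq_len(config$specimens_per_genus)) {
      sid <- sprintf("g%02d_s%03d", g, i)
      images <- stats::setNames(vector("list", 3L), mv_views())
      for (v in mv_views()) {
        n_pics <- 1L + with_local_seed(
          hash_seed(config$seed, "npics", sid, v),
          stats::rbinom(1, 1, config$extra_picture_prob))
        images[[v]] <- lapply(seq_len(n_pics), function(j) {
          render_view(archetypes[[g]], v, config,
                      seed = hash_seed(config$seed, "pic", sid, v, j))
        })
      }
      specimens[[length(specimens) + 1L]] <- new_specimen(sid, g, images)
    }
  }
  out <- mv_dataset(specimens, sprintf("genus_%02d", seq_len(config$n_genera)))
  attr(out, "archetypes") <- archetypes
  attr(out, "config") <- config
  out
}

#' Nearest-archetype oracle classification
#'
#' A brute-force reference classifier: every picture is compared against the
#' canonical (jitter- and noise-free) rendering of each genus in the
#' picture's view, and assigned the genus with the smallest L2 distance.
#' Images and templates are block-averaged to a coarse grid first, which
#' makes the matching tolerant to the small pose jitter without any
#' learning. At zero noise this oracle identifies the generating genus
#' perfectly, which pins down the generator's identifiability.
#'
#' @param ds A dataset from [generate_dataset()] (or any [mv_dataset()] if
#'   `archetypes`/`config` are supplied).
#' @param archetypes,config Default to the attributes stored on `ds`.
#' @param coarse Side of the block-averaged comparison grid.
#' @return A tibble with one row per picture: `specimen_id`, `view`,
#'   `picture`, `genus`, `predicted`, `correct`.
#' @export
nearest_archetype_classify <- function(ds, archetypes = attr(ds, "archetypes"),
                                       config = attr(ds, "config"),
                                       coarse = 16L) {
  if (is.null(archetypes) || is.null(config)) {
    stop("archetypes/config not found; pass them explicitly", call. = FALSE)
  }
  shrink <- function(img) {
    f <- nrow(img) %/% coarse
    if (f <= 1L) return(img)
    idx <- (seq_len(coarse) - 1L) * f
    out <- matrix(0, coarse, coarse)
    for (a in seq_len(f)) for (b in seq_len(f)) {
      out <- out + img[idx + a, idx + b]
    }
    out / f^2
  }
  templates <- lapply(mv_views(), function(v) {
    lapply(archetypes, function(a)
      shrink(render_view(a, v, config, canonical = TRUE)))
  })
  names(templates) <- mv_views()
  samples <- flatten_to_samples(ds)
  pred <- integer(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    img <- shrink(samples$pixels[[i]])
    d <- vapply(templates[[samples$view[i]]],
                function(tm) sum((img - tm)^2), numeric(1))
    pred[i] <- which.min(d)
  }
  dplyr::mutate(
    dplyr::select(samples, -"pixels"),
    predicted = pred, correct = pred == .data$genus
  )
}
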