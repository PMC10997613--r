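# Patch/split machinery shared by the trainable detector backend.

#' Cut an image (and its annotation mask) into training patches
#'
#' Non-overlapping `patch_px` x `patch_px` tiles; right/bottom
#' remainders are padded by reflection. Patches are standardised to zero
#' mean and unit variance per channel, and annotation masks are expanded
#' by `dilation_iters` iterations of a 3x3 dilation — small-object masks
#' are grown so that a pixel model sees enough positive context.
#'
#' @param image H x W x C numeric array.
#' @param mask logical H x W annotation mask (or NULL).
#' @param patch_px tile edge, pixels.
#' @param dilation_iters iterations of the unit (3x3) dilation applied
#'   to the mask before tiling; 0 disables.
#' @param standardize standardise each patch per channel.
#' @return list of `list(patch, mask, r0, c0)` (offsets 0-based).
#' @export
#' @examples
#' img <- array(runif(256 * 256 * 3), c(256, 256, 3))
#' length(make_patches(img, patch_px = 128)) # 4 tiles
make_patches <- function(image, mask = NULL, patch_px = 128L,
                         dilation_iters = 5L, standardize = TRUE) {
  d <- dim(image)
  stopifnot(length(d) == 3L)
  H <- d[1]; W <- d[2]; C <- d[3]

  reflect_pad <- function(x, n_r, n_c) {
    if (n_r > 0) x <- rbind(x, x[nrow(x):(nrow(x) - n_r + 1L), , drop = FALSE])
    if (n_c > 0) x <- cbind(x, x[, ncol(x):(ncol(x) - n_c + 1L), drop = FALSE])
    x
  }
  n_r <- (patch_px - H %% patch_px) %% patch_px
  n_c <- (patch_px - W %% patch_px) %% patch_px
  Hp <- H + n_r; Wp <- W + n_c

  img_p <- array(0, c(Hp, Wp, C))
  for (ch in seq_len(C)) img_p[, , ch] <- reflect_pad(image[, , ch], n_r, n_c)

  if (!is.null(mask)) {
    if (dilation_iters > 0) {
      brush <- EBImage::makeBrush(2L * as.integer(dilation_iters) + 1L, shape = "box")
      mask <- as.matrix(EBImage::imageData(
        EBImage::dilate(EBImage::Image(mask * 1), brush))) > 0.5
    }
    mask_p <- reflect_pad(mask, n_r, n_c)
  }

  out <- list()
  for (r0 in seq(0L, Hp - patch_px, by = patch_px)) {
    for (c0 in seq(0L, Wp - patch_px, by = patch_px)) {
      ri <- (r0 + 1L):(r0 + patch_px)
      ci <- (c0 + 1L):(c0 + patch_px)
      patch <- img_p[ri, ci, , drop = FALSE]
      if (standardize) {
        for (ch in seq_len(C)) {
          v <- patch[, , ch]
          s <- stats::sd(v)
          patch[, , ch] <- (v - mean(v)) / (if (s > 0) s else 1)
        }
      }
      out[[length(out) + 1L]] <- list(
        patch = patch,
        mask = if (is.null(mask)) NULL else mask_p[ri, ci, drop = FALSE],
        r0 = r0, c0 = c0)
    }
  }
  out
}

#' Split items into train/validation/test sets
#'
#' Sizes are `floor(n * ratio)` with the remainder assigned train-first;
#' the partition is disjoint, exhaustive, and deterministic for a given
#' seed.
#'
#' @param items a list (or vector) of items.
#' @param ratios length-3 ratios summing to 1.
#' @param seed integer seed.
#' @return `list(train = , val = , test = )`.
#' @export
#' @examples
#' lengths(split_dataset(as.list(1:100), seed = 1)) # 80, 10, 10
split_dataset <- function(items, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  n <- length(items)
  if (n < 3) stop("need at least 3 items to form train/val/test", call. = FALSE)
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1", call. = FALSE)
  sizes <- floor(n * ratios)
  rem <- n - sum(sizes)
  if (rem > 0) for (i in seq_len(rem)) sizes[(i - 1L) %% 3L + 1L] <- sizes[(i - 1L) %% 3L + 1L] + 1L
  perm <- with_seed(seed, sample.int(n))
  take <- function(k, from) if (k > 0) sort(perm[from:(from + k - 1L)]) else integer(0)
  list(train = items[take(sizes[1], 1L)],
       val = items[take(sizes[2], sizes[1] + 1L)],
       test = items[take(sizes[3], sizes[1] + sizes[2] + 1L)])
}

pixel_features <- function(px) {
  R <- px[, , 1]; G <- px[, , 2]; B <- px[, , 3]
  lum <- 0.2126 * R + 0.7152 * G + 0.0722 * B
  # channels plus two non-linear descriptors (linear combinations of the
  # channels would be aliased in the logistic fit)
  cbind(R = as.vector(R), G = as.vector(G), B = as.vector(B),
        range = as.vector(pmax(R, G, B) - pmin(R, G, B)),
        spot = as.vector(lum - blur2(lum, 2)))
}

#' Train a pixel-classifier detector backend on annotated patches
#'
#' A deliberately small reference model: logistic regression on per-pixel
#' colour and local-contrast features, trained on patches from
#' [make_patches()]. The returned backend plugs into [detect_eggs()],
#' [detect_feces()] and [segment_damage()] in place of the classical
#' backend; its probability maps pass through the same component
#' labelling, size gates and significance levels, so threshold
#' monotonicity and mask clipping hold identically.
#'
#' @param train,val lists of `list(patch, mask)` pairs (masks logical).
#' @param trait one of `"damage"`, `"egg"`, `"black_feces"` (stored for
#'   bookkeeping).
#' @param max_pixels subsample cap on training pixels.
#' @param seed seed for the pixel subsample.
#' @return a `patch_model`: coefficient vector, feature names, decision
#'   threshold (0.5), validation pixel IOU (`val_iou`), and a format
#'   version tag.
#' @export
train_patch_model <- function(train, val = list(), trait = "damage",
                              max_pixels = 200000L, seed = 1L) {
  if (!length(train)) stop("empty training set", call. = FALSE)
  feats <- list(); labs <- list()
  for (p in train) {
    stopifnot(!is.null(p$mask))
    feats[[length(feats) + 1L]] <- pixel_features(p$patch)
    labs[[length(labs) + 1L]] <- as.vector(p$mask)
  }
  X <- do.call(rbind, feats)
  y <- unlist(labs)
  if (length(y) > max_pixels) {
    keep <- with_seed(seed, {
      pos <- which(y); neg <- which(!y)
      n_pos <- min(length(pos), max_pixels %/% 2)
      n_neg <- min(length(neg), max_pixels - n_pos)
      c(sample(pos, n_pos), sample(neg, n_neg))
    })
    X <- X[keep, , drop = FALSE]; y <- y[keep]
  }
  if (!any(y) || all(y)) stop("training masks are degenerate (all one class)", call. = FALSE)
  fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y, family = stats::binomial()))
  coefs <- unname(fit$coefficients)   # (intercept, then feature columns)
  coefs[is.na(coefs)] <- 0   # aliased features carry no information
  model <- structure(list(trait = trait, coef = coefs,
                          features = colnames(X), threshold = 0.5,
                          val_iou = NA_real_, version = "mitescan-pixel-glm-1"),
                     class = "patch_model")
  if (length(val)) {
    inter <- uni <- 0
    for (p in val) {
      pred <- predict_pixels(model, p$patch) >= model$threshold
      inter <- inter + sum(pred & p$mask)
      uni <- uni + sum(pred | p$mask)
    }
    model$val_iou <- if (uni > 0) inter / uni else 1.0   # pooled pixel IOU
  }
  model
}

#' @keywords internal
predict_pixels <- function(model, px) {
  X <- pixel_features(px)
  eta <- as.vector(cbind(1, X) %*% model$coef)
  matrix(stats::plogis(eta), nrow = dim(px)[1])
}

#' Serialize a trained backend to a single portable file
#'
#' Plain JSON with a version header; coefficients survive the round
#' trip at full precision.
#'
#' @param model a `patch_model`.
#' @param path output file.
#' @export
write_patch_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_patch_model
#' @export
read_patch_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$coef <- as.numeric(m$coef)
  structure(m, class = "patch_model")
}
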