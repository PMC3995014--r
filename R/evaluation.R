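## Agreement statistics between segmentations: Dice overlap, volume
## correlation, Bland-Altman bias/limits, and rater reliability summaries.

#' Dice overlap between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`. Masks on different grids are first
#' resampled (`b` onto `a`'s grid, nearest-neighbour). Two empty masks
#' agree perfectly (Dice 1); empty vs nonempty is 0.
#'
#' @param a,b Binary [label_volume]s (or logical/numeric arrays on one
#'   grid).
#' @return `dice_result`: `dice`, `intersection`, `size_a`, `size_b`.
#' @export
dice <- function(a, b) {
  if (inherits(a, "volume3d") && inherits(b, "volume3d")) {
    if (!same_grid(a, b)) b <- resample(b, a, mode = "nearest")
    av <- a$data > 0; bv <- b$data > 0
  } else {
    av <- as.array(a) > 0; bv <- as.array(b) > 0
    if (!identical(dim(av), dim(bv))) stop("mask shapes differ")
  }
  na <- sum(av); nb <- sum(bv); ni <- sum(av & bv)
  d <- if (na + nb == 0) 1 else 2 * ni / (na + nb)
  structure(list(dice = d, intersection = ni, size_a = na, size_b = nb),
            class = "dice_result")
}

#' @export
print.dice_result <- function(x, ...) {
  cat(sprintf("Dice %.4f (|A|=%d, |B|=%d, |A&B|=%d)\n",
              x$dice, x$size_a, x$size_b, x$intersection))
  invisible(x)
}

#' Agreement summary over paired segmentations / volume series
#'
#' Mean and SD of Dice; Pearson correlation between the two volume
#' series (with a one-tailed p value, descriptive only); Bland-Altman
#' bias (mean of a - b) and 95\% limits of agreement (bias +/- 1.96 SD of
#' the differences); and the OLS regression of Dice on volume when both
#' are supplied.
#'
#' @param dice_values Numeric vector of Dice coefficients (optional).
#' @param vol_a,vol_b Paired volume series (optional).
#' @param vol_for_dice Volumes paired with `dice_values` for the
#'   Dice-on-volume regression (optional).
#' @return `agreement_summary` list.
#' @export
agreement_summary <- function(dice_values = NULL, vol_a = NULL, vol_b = NULL,
                              vol_for_dice = NULL) {
  out <- list()
  if (!is.null(dice_values)) {
    out$dice_mean <- mean(dice_values)
    out$dice_sd <- if (length(dice_values) > 1) sd(dice_values) else NA_real_
    out$n <- length(dice_values)
  }
  if (!is.null(vol_a) && !is.null(vol_b)) {
    stopifnot(length(vol_a) == length(vol_b), length(vol_a) >= 2)
    if (sd(vol_a) < 1e-12 || sd(vol_b) < 1e-12) {
      out$pearson_r <- NA_real_
      out$pearson_p <- NA_real_
      out$note <- "constant volume series; correlation undefined"
    } else {
      ct <- stats::cor.test(vol_a, vol_b, alternative = "greater")
      out$pearson_r <- unname(ct$estimate)
      out$pearson_p <- ct$p.value
    }
    diffs <- vol_a - vol_b
    sd_d <- if (length(diffs) > 1) sd(diffs) else 0
    out$ba_bias <- mean(diffs)
    out$ba_limits <- out$ba_bias + c(-1.96, 1.96) * sd_d
  }
  if (!is.null(dice_values) && !is.null(vol_for_dice)) {
    fit <- lm(dice_values ~ vol_for_dice)
    out$dice_on_volume <- unname(coef(fit))  # intercept, slope per cm^3
  }
  structure(out, class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  if (!is.null(x$dice_mean))
    cat(sprintf("Dice: mean %.3f (SD %.3f), n = %d\n",
                x$dice_mean, x$dice_sd, x$n))
  if (!is.null(x$pearson_r))
    cat(sprintf("Pearson r = %.3f (one-tailed p = %.3g)\n",
                x$pearson_r, x$pearson_p))
  if (!is.null(x$ba_bias))
    cat(sprintf("Bland-Altman bias %.3f, limits [%.3f, %.3f]\n",
                x$ba_bias, x$ba_limits[1], x$ba_limits[2]))
  if (!is.null(x$dice_on_volume))
    cat(sprintf("Dice on volume: slope %.4f per cm^3\n", x$dice_on_volume[2]))
  invisible(x)
}

#' Interrater and intrarater reliability from repeated segmentations
#'
#' `segs` is a nested list: subject -> rater -> repeat, each a binary
#' [label_volume]. Intrarater Dice compares a rater's repeats with each
#' other; interrater Dice compares segmentations across raters over all
#' cross-pairings of repeats. Missing cells are handled pairwise-complete
#' with the pair count reported.
#'
#' @param segs Nested list of segmentations.
#' @return Data frame with one row per subject: mean intrarater and
#'   interrater Dice and the pair counts.
#' @export
rater_reliability <- function(segs) {
  rows <- lapply(seq_along(segs), function(si) {
    sub <- segs[[si]]
    intra <- c(); inter <- c()
    nr <- length(sub)
    for (r in seq_len(nr)) {
      reps <- sub[[r]]
      if (length(reps) >= 2)
        for (i in 1:(length(reps) - 1)) for (j in (i + 1):length(reps))
          intra <- c(intra, dice(reps[[i]], reps[[j]])$dice)
    }
    if (nr >= 2)
      for (r1 in 1:(nr - 1)) for (r2 in (r1 + 1):nr)
        for (x in sub[[r1]]) for (y in sub[[r2]])
          inter <- c(inter, dice(x, y)$dice)
    data.frame(subject = if (!is.null(names(segs))) names(segs)[si] else si,
               intrarater = mean(intra), n_intra = length(intra),
               interrater = mean(inter), n_inter = length(inter))
  })
  do.call(rbind, rows)
}
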