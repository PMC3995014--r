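## The fusion core: locally ranked STAPLE. At each voxel the k_local
## templates with the highest locally normalized cross-correlation (LNCC)
## to the subject are selected, and their propagated label probabilities
## are fused by STAPLE-style EM — alternating the consensus probability
## with per-template sensitivity/specificity estimates — under a mean-field
## Markov random field spatial prior.

#' Fusion configuration
#'
#' Defaults follow the published operating point of the method this
#' package implements: 15 locally selected templates, LNCC Gaussian kernel
#' SD of 2 voxels, MRF strength beta = 0.5.
#'
#' @param k_local Templates fused at each voxel.
#' @param lncc_sigma Gaussian kernel SD in voxels for the local similarity.
#' @param beta MRF strength (0 disables spatial coupling).
#' @param p_init,q_init Initial sensitivity/specificity.
#' @param max_iter,tol EM stopping rule (mean |change in consensus| < tol).
#' @param threshold Binarization threshold on the consensus probability
#'   (inclusive: ties go to foreground).
#' @param prior_weight Weight of the propagated spatial prior in the
#'   fusion prior field (the remainder goes to the label prevalence).
#'   The default 0 uses prevalence alone: the propagated prior serves
#'   localization (ROI extraction), and injecting it into the EM inflates
#'   the foreground prior where the groupwise prior over- or
#'   under-estimates the subject's anatomy.
#' @export
fusion_config <- function(k_local = 15, lncc_sigma = 2, beta = 0.5,
                          p_init = 0.95, q_init = 0.95,
                          max_iter = 50, tol = 1e-4, threshold = 0.5,
                          prior_weight = 0) {
  stopifnot(k_local >= 1, lncc_sigma > 0, beta >= 0,
            p_init > 0, p_init < 1, q_init > 0, q_init < 1,
            prior_weight >= 0, prior_weight <= 1)
  structure(list(k_local = as.integer(k_local), lncc_sigma = lncc_sigma,
                 beta = beta, p_init = p_init, q_init = q_init,
                 max_iter = as.integer(max_iter), tol = tol,
                 threshold = threshold, prior_weight = prior_weight),
            class = "fusion_config")
}

PQ_CLAMP <- c(0.05, 0.999)

#' Locally normalized cross-correlation map
#'
#' Pearson correlation of intensities within Gaussian-weighted windows
#' (kernel SD `sigma` voxels, truncated at 3 sigma): at each voxel,
#' (E\[ab\]-E\[a\]E\[b\]) / sqrt((E\[a2\]-E\[a\]2)(E\[b2\]-E\[b\]2)) with E the
#' Gaussian-window average. Windows with (numerically) zero variance map
#' to 0, so the map is NaN-free.
#'
#' @param a,b [volume3d]s on one grid.
#' @param sigma Kernel SD in voxels.
#' @return [volume3d] with values in \[-1, 1\].
#' @export
lncc <- function(a, b, sigma = 2) {
  if (!same_grid(a, b)) stop("lncc requires volumes on the same grid")
  d <- dim(a$data)
  g <- function(x) gauss_blur3_cpp(as.double(x), d, sigma)
  av <- as.double(a$data); bv <- as.double(b$data)
  ea <- g(av); eb <- g(bv)
  va <- pmax(g(av * av) - ea * ea, 0)
  vb <- pmax(g(bv * bv) - eb * eb, 0)
  cov <- g(av * bv) - ea * eb
  den <- sqrt(va * vb)
  out <- ifelse(den < 1e-10, 0, cov / den)
  out <- pmin(pmax(out, -1), 1)
  volume3d(array(out, d), affine = a$affine)
}

#' Per-voxel top-k template selection
#'
#' Marks, at each voxel, the `k_local` templates with the largest LNCC
#' values (ties broken by ascending template index).
#'
#' @param lncc_maps List of [lncc] maps (one per template) or a
#'   voxels-x-templates numeric matrix.
#' @param k_local Templates to select per voxel.
#' @return Logical matrix (voxels x templates) with exactly `k_local`
#'   `TRUE` per row.
#' @export
local_rank_select <- function(lncc_maps, k_local) {
  L <- if (is.matrix(lncc_maps)) lncc_maps
       else vapply(lncc_maps, function(m) as.vector(m$data),
                   numeric(length(lncc_maps[[1]]$data)))
  if (ncol(L) < k_local)
    stop("need at least k_local = ", k_local, " templates, got ", ncol(L))
  topk_rows_cpp(L, as.integer(k_local))
}

#' Mean-field MRF prior update
#'
#' pi_i = exp(beta S1_i) / (exp(beta S1_i) + exp(beta S0_i)) with S1 the
#' sum of consensus probabilities over the 6-connected neighbours and S0
#' the sum of their complements. With beta = 0 the prior is uniformly 0.5.
#'
#' @param W Consensus probability array (3D).
#' @param beta MRF strength.
#' @return Prior field, same shape as `W`.
#' @export
mrf_regularize <- function(W, beta) {
  stopifnot(length(dim(W)) == 3)
  d <- dim(W)
  s1 <- array(0, d); nn <- array(0, d)
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2) next
    to_lo <- to_hi <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    to_lo[[ax]] <- 1:(n - 1)   # receives from upper neighbour
    to_hi[[ax]] <- 2:n         # receives from lower neighbour
    w_hi <- do.call(`[`, c(list(W), to_hi, list(drop = FALSE)))
    w_lo <- do.call(`[`, c(list(W), to_lo, list(drop = FALSE)))
    add <- function(arr, ix, val)
      do.call(`[<-`, c(list(arr), ix,
                       list(do.call(`[`, c(list(arr), ix, list(drop = FALSE))) + val)))
    s1 <- add(s1, to_lo, w_hi); nn <- add(nn, to_lo, 1)
    s1 <- add(s1, to_hi, w_lo); nn <- add(nn, to_hi, 1)
  }
  s0 <- nn - s1
  1 / (1 + exp(-beta * (s1 - s0)))
}

#' STAPLE-style EM fusion of selected label maps
#'
#' E-step: the consensus probability at voxel i is
#' `W_i = a_i / (a_i + b_i)` with
#' `a_i = pi_i * prod_j p_j^d_ij (1-p_j)^(1-d_ij)` and
#' `b_i = (1-pi_i) * prod_j (1-q_j)^d_ij q_j^(1-d_ij)`, products over the
#' templates selected at i, `d_ij` the (continuous) propagated label.
#' M-step: `p_j` / `q_j` re-estimated over the voxels where template j is
#' selected. Performance parameters are global per template but estimated
#' only where the template is locally selected. When `beta > 0` a
#' mean-field MRF update is interleaved between EM iterations: the
#' pairwise term [mrf_regularize] is combined with the static prior in
#' log-odds, so the prior acts as the external field of the MRF. With
#' `beta = 0` the prior stays fixed and the observed-data log-likelihood
#' is non-decreasing (classic EM guarantee).
#'
#' @param D Voxels-x-templates matrix of propagated label probabilities in
#'   \[0,1\].
#' @param S Logical selection matrix from [local_rank_select] (`NULL` =
#'   all selected).
#' @param prior Per-voxel prior probability vector (or 3D array) in
#'   \[0,1\], or `NULL` for a flat prior at the global prevalence of `D`.
#' @param config A [fusion_config].
#' @param dims 3D dims of the voxel grid (needed for the MRF when
#'   `beta > 0`).
#' @param consensus_exclude Fix the consensus at voxels where every
#'   selected template (effectively) agrees and estimate the performance
#'   parameters over the remaining, ambiguous voxels only. Global
#'   estimation lets the huge error-free background drive specificity to
#'   its clamp, which biases the decision threshold toward
#'   over-segmentation; restricting the estimates to the band where
#'   templates actually disagree keeps them informative about boundary
#'   behaviour (default `TRUE`).
#' @return `fusion_state`: `W` (consensus vector), `p`, `q`,
#'   `loglik_trace`, `iterations`, `converged`, `prior` (final field).
#' @export
staple_em <- function(D, S = NULL, prior = NULL, config = fusion_config(),
                      dims = NULL, consensus_exclude = TRUE) {
  D <- as.matrix(D)
  nvox <- nrow(D); ntpl <- ncol(D)
  if (is.null(S)) S <- matrix(TRUE, nvox, ntpl)
  if (config$beta > 0 && is.null(dims))
    stop("dims is required when beta > 0 (MRF neighbourhood)")
  # default prior: the global prevalence of the candidate labels (a flat
  # 0.5 misbehaves when foreground is a tiny fraction of the region)
  if (is.null(prior)) prior <- mean(D)
  pri <- rep_len(as.vector(prior), nvox)
  pri <- pmin(pmax(pri, 1e-6), 1 - 1e-6)
  p <- rep(config$p_init, ntpl); q <- rep(config$q_init, ntpl)
  degenerate <- all(D >= 1 - 1e-9) || all(D <= 1e-9)
  if (degenerate)
    warning("all propagated labels are uniformly fore/background; ",
            "returning trivially converged state")
  ## consensus voxels: every selected template (effectively) agrees; their
  ## consensus is fixed and they are excluded from parameter estimation
  Dsel <- D; Dsel[!S] <- NA
  fg_cons <- bg_cons <- rep(FALSE, nvox)
  if (consensus_exclude && !degenerate) {
    rng_lo <- suppressWarnings(apply(Dsel, 1, min, na.rm = TRUE))
    rng_hi <- suppressWarnings(apply(Dsel, 1, max, na.rm = TRUE))
    fg_cons <- rng_lo > 0.99
    bg_cons <- rng_hi < 0.01
  }
  amb <- which(!(fg_cons | bg_cons))
  W <- pri
  W[fg_cons] <- 1; W[bg_cons] <- 0
  lodds0 <- log(pri / (1 - pri))
  ll <- numeric(0)
  converged <- FALSE
  Da <- D[amb, , drop = FALSE]; Sa <- S[amb, , drop = FALSE]
  DS <- Da * Sa; CS <- (1 - Da) * Sa
  iter <- 0L
  while (iter < config$max_iter && !degenerate && length(amb) > 0) {
    iter <- iter + 1L
    ## E-step over the ambiguous voxels
    la <- log(pri[amb]) + DS %*% log(p) + CS %*% log(1 - p)
    lb <- log1p(-pri[amb]) + DS %*% log(1 - q) + CS %*% log(q)
    m <- pmax(la, lb)
    ll <- c(ll, sum(m + log(exp(la - m) + exp(lb - m))))
    Wa <- as.vector(1 / (1 + exp(lb - la)))
    ## M-step over ambiguous, selected voxels only
    sw <- colSums(Sa * Wa); sc <- colSums(Sa * (1 - Wa))
    p <- pmin(pmax(colSums(DS * Wa) / pmax(sw, 1e-12),
                   PQ_CLAMP[1]), PQ_CLAMP[2])
    q <- pmin(pmax(colSums(CS * (1 - Wa)) / pmax(sc, 1e-12),
                   PQ_CLAMP[1]), PQ_CLAMP[2])
    delta <- mean(abs(Wa - W[amb]))
    W[amb] <- Wa
    ## MRF: one mean-field update per EM iteration; the pairwise term is
    ## combined with the static prior in log-odds (external field)
    if (config$beta > 0) {
      mrf <- as.vector(mrf_regularize(array(W, dims), config$beta))
      mrf <- pmin(pmax(mrf, 1e-6), 1 - 1e-6)
      pri <- 1 / (1 + exp(-(lodds0 + log(mrf / (1 - mrf)))))
      pri <- pmin(pmax(pri, 1e-6), 1 - 1e-6)
    }
    if (delta < config$tol) { converged <- TRUE; break }
  }
  if (length(amb) == 0 && !degenerate) {
    # every voxel is a consensus voxel: the templates agree perfectly with
    # the consensus, so the performance estimates sit at the upper clamp
    p[] <- PQ_CLAMP[2]; q[] <- PQ_CLAMP[2]
  }
  structure(list(W = as.vector(W), p = p, q = q, loglik_trace = ll,
                 iterations = iter,
                 converged = converged || degenerate || length(amb) == 0,
                 prior = pri, config = config,
                 n_consensus = sum(fg_cons) + sum(bg_cons)),
            class = "fusion_state")
}

#' @export
print.fusion_state <- function(x, ...) {
  cat(sprintf("<fusion_state> %d EM iterations%s, %d templates\n",
              x$iterations, if (x$converged) " (converged)" else "",
              length(x$p)))
  cat(sprintf("  p-hat: %s\n  q-hat: %s\n",
              paste(signif(x$p, 3), collapse = " "),
              paste(signif(x$q, 3), collapse = " ")))
  if (length(x$loglik_trace))
    cat(sprintf("  log-likelihood: %.4g -> %.4g\n",
                x$loglik_trace[1], x$loglik_trace[length(x$loglik_trace)]))
  invisible(x)
}

#' @export
summary.fusion_state <- function(object, ...) {
  data.frame(template = seq_along(object$p),
             sensitivity = object$p, specificity = object$q)
}

## keep the largest 6-connected component of a binary array
largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- cc_label_cpp(array(as.integer(mask), dim(mask)), dim(mask))
  tab <- tabulate(lab[lab > 0])
  array(lab == which.max(tab), dim(mask))
}

#' Fuse refined templates into a consensus segmentation
#'
#' Runs the full local-fusion stage on a subject ROI: LNCC maps against
#' every propagated template, per-voxel top-`k_local` selection, STAPLE EM
#' with interleaved MRF, binarization (threshold inclusive) and
#' largest-connected-component cleanup, and re-embedding of the ROI mask
#' into the full subject grid (0 outside the ROI).
#'
#' @param subject Full-grid subject [volume3d].
#' @param roi The [extract_roi] box the templates were refined on.
#' @param refined A [refine_templates] result.
#' @param prior Optional probability map on the ROI grid (e.g. the
#'   propagated groupwise prior); blended 50/50 with a flat 0.5 field.
#' @param config A [fusion_config].
#' @return List: `mask` (binary [label_volume] on the subject grid),
#'   `state` (the `fusion_state`), `roi`.
#' @export
fuse <- function(subject, roi, refined, prior = NULL,
                 config = fusion_config()) {
  stopifnot(inherits(refined, "refined_templates"))
  if (length(refined) < config$k_local)
    stop("need at least k_local = ", config$k_local, " refined templates")
  subject_roi <- roi_crop(subject, roi)
  d <- dim(subject_roi$data)
  # local similarity of each warped template image to the subject
  lmaps <- lapply(refined, function(r) lncc(subject_roi, r$warped,
                                            config$lncc_sigma))
  S <- local_rank_select(lmaps, config$k_local)
  D <- vapply(refined, function(r) as.vector(r$prob$data),
              numeric(prod(d)))
  # prior field: label prevalence, optionally mixed with the propagated
  # spatial prior (see fusion_config)
  prev <- mean(D)
  w <- config$prior_weight
  pri <- if (!is.null(prior) && w > 0)
    (1 - w) * prev + w * pmin(pmax(as.vector(prior$data), 0), 1)
  else rep(prev, prod(d))
  state <- staple_em(D, S, pri, config, dims = d)
  m <- array(state$W >= config$threshold, d)
  if (!any(m)) warning("fused mask is empty")
  m <- largest_component(m)
  full <- roi_embed(as.integer(m), roi, subject)
  mask <- label_volume(full, grid = subject, labels = 1L)
  list(mask = mask, state = state, roi = roi)
}

#' Majority-vote fusion (baseline)
#'
#' Unweighted mean of the propagated label probabilities, thresholded at
#' 0.5 (inclusive). Used as the comparison baseline for the locally ranked
#' STAPLE fusion.
#'
#' @inheritParams fuse
#' @return Binary [label_volume] on the subject grid.
#' @export
fuse_majority <- function(subject, roi, refined) {
  subject_roi <- roi_crop(subject, roi)
  d <- dim(subject_roi$data)
  D <- vapply(refined, function(r) as.vector(r$prob$data), numeric(prod(d)))
  m <- array(rowMeans(D) >= 0.5, d)
  m <- largest_component(m)
  label_volume(roi_embed(as.integer(m), roi, subject), grid = subject,
               labels = 1L)
}
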