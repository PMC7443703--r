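#' Histogram mutual information between two signals
#'
#' Both signals are rank-transformed to (0, 1] (removing marginal
#' distribution effects) and binned on an equal-width 2-D grid; mutual
#' information is computed from the joint histogram in bits. The estimate
#' is non-negative and exactly symmetric in its arguments; for a signal
#' against itself it approaches `log2(bins)`.
#'
#' @param x,y Numeric vectors of equal length (>= 1000 samples for a
#'   usable estimate).
#' @param bins Number of bins per axis.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y, bins = 64) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 1000) stop("mutual_information needs at least 1000 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; mutual information is 0")
    return(0)
  }
  ix <- pmin(bins, ceiling(rank(x, ties.method = "average") / n * bins))
  iy <- pmin(bins, ceiling(rank(y, ties.method = "average") / n * bins))
  joint <- tabulate((ix - 1L) * bins + iy, nbins = bins * bins) / n
  px <- tabulate(ix, nbins = bins) / n
  py <- tabulate(iy, nbins = bins) / n
  prod_marg <- as.vector(outer(py, px))  # matches (ix-1)*bins + iy layout
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / prod_marg[nz]))
}

# Extended Infomax ICA on sphered data (natural-gradient ascent with
# sub/super-Gaussian switching, runica-style annealing). `X` is
# components x samples with identity covariance. Returns the square
# unmixing matrix `W` such that S = W X has maximally independent rows.
infomax_ica <- function(X, seed = 1, max_iter = 200, tol = 1e-6,
                        verbose = FALSE) {
  nc <- nrow(X)
  n <- ncol(X)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  W <- qr.Q(qr(matrix(stats::rnorm(nc * nc), nc)))
  block <- as.integer(min(512, max(8, floor(sqrt(n / 3)) * 4)))
  lrate <- 0.00065 / log(nc)
  anneal <- 0.98
  signs <- rep(1, nc)                    # +1 super-Gaussian, -1 sub-Gaussian
  ext_interval <- 5
  oldW <- W
  olddelta <- NULL
  blowup <- FALSE

  for (it in seq_len(max_iter)) {
    perm <- sample.int(n)
    nblocks <- n %/% block
    for (b in seq_len(nblocks)) {
      idx <- perm[seq((b - 1) * block + 1, b * block)]
      u <- W %*% X[, idx, drop = FALSE]
      y <- tanh(u)
      BI <- diag(block, nc)
      W <- W + lrate * (BI - (signs * y) %*% t(u) - u %*% t(u)) %*% W
      if (!all(is.finite(W)) || max(abs(W)) > 1e8) {
        blowup <- TRUE
        break
      }
    }
    if (blowup) {
      lrate <- lrate * 0.5
      W <- qr.Q(qr(matrix(stats::rnorm(nc * nc), nc)))
      oldW <- W
      olddelta <- NULL
      blowup <- FALSE
      if (lrate < 1e-10) break
      next
    }
    if (it %% ext_interval == 0) {
      # kurtosis signs on a subsample of the current sources
      sub <- sample.int(n, min(n, 6000))
      u <- W %*% X[, sub, drop = FALSE]
      k <- rowMeans(u^4) / rowMeans(u^2)^2 - 3
      signs <- ifelse(k > 0, 1, -1)
    }
    delta <- as.vector(W - oldW)
    change <- sum(delta^2)
    if (!is.null(olddelta)) {
      denom <- sqrt(sum(delta^2) * sum(olddelta^2))
      if (denom > 0) {
        angle <- acos(pmin(1, pmax(-1, sum(delta * olddelta) / denom)))
        if (angle * 180 / pi > 60) lrate <- lrate * anneal
      }
    }
    olddelta <- delta
    oldW <- W
    if (verbose && it %% 10 == 0) {
      message(sprintf("infomax iter %d, wchange %.3g, lrate %.3g",
                      it, change, lrate))
    }
    if (change < tol) {
      return(list(W = W, iterations = it, converged = TRUE))
    }
  }
  list(W = W, iterations = max_iter, converged = all(is.finite(W)))
}

#' Parameters for ICA with mutual-information component rejection
#'
#' @param R Rejection rate: percentage of independent components removed
#'   (those with the highest mutual information against the DBS
#'   reference channel).
#' @param pca_fraction Fraction of the channel count kept as principal
#'   components before ICA (the full decomposition is rank deficient).
#' @param mi_bins Histogram bins per axis for [mutual_information()].
#' @param notch_freq Frequency notched out of the reference channel before
#'   ranking, so residual dipole leakage does not attract rejection.
#' @param seed Seed for the ICA initialisation and block order.
#' @param max_iter Iteration cap for the Infomax ascent.
#' @return A list of class `ica_mi_params`.
#' @export
ica_mi_params <- function(R = 20, pca_fraction = 0.75, mi_bins = 64,
                          notch_freq = 12, seed = 1, max_iter = 200) {
  stopifnot(R >= 0, R <= 100, pca_fraction > 0, pca_fraction <= 1)
  structure(list(R = R, pca_fraction = pca_fraction, mi_bins = mi_bins,
                 notch_freq = notch_freq, seed = seed, max_iter = max_iter),
            class = "ica_mi_params")
}

#' ICA-MI artefact rejection
#'
#' (1) PCA to `ceil(pca_fraction * n_channels)` components; (2) extended
#' Infomax ICA of the sphered PCA space; (3) the DBS reference channel is
#' notch filtered at the dipole frequency; (4) mutual information between
#' every independent component and the notched reference; (5) the
#' `ceil(R/100 * n_components)` highest-MI components are removed;
#' (6) the remaining components are back-projected to the sensor level.
#' With `R = 0` the output is exactly the PCA-truncate-and-restore
#' round trip.
#'
#' @param rec A [recording()].
#' @param ref_channel Numeric vector, sample-aligned DBS reference signal.
#' @param p An [ica_mi_params()].
#' @return The cleaned [recording()], with attributes `"rejected"` (indices
#'   of removed components) and `"mi"` (the MI of every component).
#' @export
ica_mi_clean <- function(rec, ref_channel, p = ica_mi_params()) {
  if (length(ref_channel) != ncol(rec$data)) {
    stop("ref_channel must be sample-aligned with the recording")
  }
  X <- rec$data
  nch <- nrow(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  ncomp <- ceiling(p$pca_fraction * nch)

  C <- tcrossprod(Xc) / ncol(Xc)
  eg <- eigen(C, symmetric = TRUE)
  U <- eg$vectors[, seq_len(ncomp), drop = FALSE]
  d <- pmax(eg$values[seq_len(ncomp)], 1e-30 * eg$values[1])
  Z <- (t(U) %*% Xc) / sqrt(d)           # sphered PCA scores

  fit <- infomax_ica(Z, seed = p$seed, max_iter = p$max_iter)
  if (!fit$converged) {
    fit <- infomax_ica(Z, seed = p$seed + 1, max_iter = p$max_iter)
    if (!fit$converged) stop("Infomax ICA failed to converge twice")
  }
  S <- fit$W %*% Z

  n_rej <- ceiling(p$R / 100 * ncomp)
  mi <- rep(NA_real_, ncomp)
  rejected <- integer(0)
  if (n_rej > 0) {
    ref_n <- notch_filter(ref_channel, base = p$notch_freq,
                          max_harmonic = p$notch_freq, fs = rec$fs)
    mi <- vapply(seq_len(ncomp), function(i) {
      mutual_information(S[i, ], ref_n, bins = p$mi_bins)
    }, numeric(1))
    rejected <- order(mi, decreasing = TRUE)[seq_len(n_rej)]
    S[rejected, ] <- 0
  }
  Zk <- solve(fit$W) %*% S
  rec$data <- U %*% (Zk * sqrt(d)) + mu
  attr(rec, "rejected") <- rejected
  attr(rec, "mi") <- mi
  rec
}
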