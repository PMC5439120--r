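# Montage optimization: per-channel bootstrap difference estimates and
# spatial PCA loadings over the 10-20 montage.

#' Per-channel bootstrap deviant-minus-standard difference estimate
#'
#' For each channel, the mean over `n_boot` bootstrap draws of (randomly
#' selected deviant trial - randomly selected standard trial), drawn with
#' replacement. Optionally normalized to unit Frobenius norm so per-subject
#' estimates can be concatenated for a group analysis.
#'
#' @param block a multichannel `eeg_epochs` (see [eeg_epoch()]).
#' @param n_boot number of bootstrap draws (default 1001).
#' @param seed RNG seed.
#' @param normalize divide the channels x time estimate by its Frobenius
#'   norm (default TRUE, the group-concatenation convention).
#' @return channels x time numeric matrix.
#' @export
bootstrap_channel_differences <- function(block, n_boot = 1001, seed = NULL,
                                          normalize = TRUE) {
  stopifnot(inherits(block, "eeg_epochs"))
  if (is.matrix(block$trials)) {
    stop("multichannel epochs required (got single-channel)")
  }
  keep <- which(block$retained)
  dev <- keep[block$labels[keep] == "deviant"]
  std <- keep[block$labels[keep] == "standard"]
  if (length(dev) == 0 || length(std) == 0) {
    stop("both deviant and standard trials must be present")
  }
  n_tr <- dim(block$trials)[1]
  w <- with_seed(seed, {
    rd <- sample(dev, n_boot, replace = TRUE)
    rs <- sample(std, n_boot, replace = TRUE)
    (tabulate(rd, n_tr) - tabulate(rs, n_tr)) / n_boot
  })
  # weighted sum over the trial dimension = the bootstrap mean difference
  n_ch <- dim(block$trials)[2]
  n_t <- dim(block$trials)[3]
  flat <- matrix(block$trials, nrow = n_tr)       # trials x (ch*time)
  est <- matrix(as.vector(w %*% flat), n_ch, n_t)
  rownames(est) <- block$channel_names
  if (normalize) {
    fn <- sqrt(sum(est^2))
    if (fn > 0) est <- est / fn
  }
  est
}

#' Spatial PCA loadings of group difference estimates
#'
#' Eigendecomposition of the channel covariance of (time-)concatenated
#' per-subject bootstrap difference estimates. Components are sorted by the
#' fraction of variance accounted for (pvaf); the smallest prefix reaching
#' `cum_pvaf` cumulative variance is retained. Loading magnitude per channel
#' is the mean over retained components of the squared eigenvector weight;
#' the sign is taken from the first retained eigenvector (whose own sign is
#' fixed by making its largest-magnitude element positive), which reproduces
#' the polarity inversion between central and mastoid sites.
#'
#' @param group_estimates channels x time matrix: per-subject estimates from
#'   [bootstrap_channel_differences()] concatenated along time (a list of
#'   matrices is accepted and cbound).
#' @param cum_pvaf cumulative variance target for retention (default 0.90).
#' @return object of class `channel_loadings`: `channels`, `loadings`
#'   (signed), `pvaf` (all components), `retained_components`.
#' @export
spatial_pca_loadings <- function(group_estimates, cum_pvaf = 0.90) {
  if (is.list(group_estimates)) {
    group_estimates <- do.call(cbind, group_estimates)
  }
  X <- as.matrix(group_estimates)
  if (nrow(X) < 2) stop("at least 2 channels required")
  Xc <- X - rowMeans(X)
  C <- tcrossprod(Xc) / (ncol(Xc) - 1)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  pvaf <- ev / sum(ev)
  n_pos <- sum(ev > .Machine$double.eps * max(ev) * nrow(X))
  n_keep <- which(cumsum(pvaf) >= cum_pvaf)[1]
  if (is.na(n_keep) || n_keep > n_pos) {
    warning("covariance rank-deficient; retaining the ", n_pos,
            " available component(s)")
    n_keep <- max(n_pos, 1L)
  }
  V <- e$vectors[, seq_len(n_keep), drop = FALSE]
  # sign convention: largest-magnitude element of each eigenvector positive
  for (j in seq_len(ncol(V))) {
    V[, j] <- V[, j] * sign(V[which.max(abs(V[, j])), j])
  }
  mag <- rowMeans(V^2)
  sgn <- sign(V[, 1])
  sgn[sgn == 0] <- 1
  structure(list(channels = rownames(X) %||% paste0("ch", seq_len(nrow(X))),
                 loadings = unname(mag * sgn),
                 pvaf = pvaf,
                 retained_components = n_keep),
            class = "channel_loadings")
}

#' @export
print.channel_loadings <- function(x, ...) {
  cat("Spatial PCA channel loadings (", x$retained_components,
      " component(s), cum. pvaf = ",
      round(sum(x$pvaf[seq_len(x$retained_components)]), 3), ")\n", sep = "")
  print(data.frame(channel = x$channels, loading = round(x$loadings, 4)))
  invisible(x)
}

#' @export
plot.channel_loadings <- function(x, ...) {
  graphics::barplot(x$loadings, names.arg = x$channels,
                    ylab = "loading (signed mean squared weight)",
                    main = "Spatial PCA channel loadings", ...)
  invisible(x)
}
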