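# Quasi-likelihood map, thresholded feature masks, marginal distributions,
# centroids, and the surprise statistic.

#' Minimum bound surface
#'
#' Elementwise maximum over the condition projection surfaces.
#'
#' @param g_list list of equally shaped condition surfaces.
#' @return matrix B with B[i, j] = max over conditions of g[[d]][i, j].
#' @export
minimum_bound <- function(g_list) {
  stopifnot(length(g_list) >= 1)
  dims <- lapply(g_list, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("condition surfaces must share one shape")
  }
  Reduce(pmax, g_list)
}

#' Quasi-likelihood map
#'
#' Maps each value of the grand compromise G through the squared
#' kernel-density CDF of the pooled minimum-bound values:
#' qLE = CDF(B)(G)^2, a [0, 1] likelihood that an RP value reflects a true
#' deviant-standard difference relative to the rest of the plane.
#'
#' @param G grand compromise surface.
#' @param B minimum bound from [minimum_bound()].
#' @param cdf_method "kde" (default) or "ecdf".
#' @return matrix of qLE values in [0, 1].
#' @export
qle_map <- function(G, B, cdf_method = c("kde", "ecdf")) {
  stopifnot(all(dim(G) == dim(B)))
  cdf_method <- match.arg(cdf_method)
  if (max(B) == min(B)) {
    warning("degenerate minimum bound (all values equal); qLE = 0.25")
    return(matrix(0.25, nrow(G), ncol(G)))
  }
  C <- kde_cdf(as.vector(B), method = cdf_method)
  matrix(C(G)^2, nrow(G), ncol(G))
}

# 8-connected component labelling of a logical matrix (BFS flood fill).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (i - 1L) %% nr + 1L
      c <- (i - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
          j <- (cc - 1L) * nr + rr
          if (mask[j] && lab[j] == 0L) {
            lab[j] <- cur
            stack <- c(stack, j)
          }
        }
      }
    }
  }
  lab
}

#' Extract supra-threshold time-frequency features
#'
#' Thresholds the qLE map (H = 1 where qLE >= threshold), labels
#' 8-connected supra-threshold regions as distinct features, splits any
#' region spanning the 12 Hz theta/beta boundary, and assigns band labels:
#' "theta" for features confined below 12 Hz, "beta_gamma" for features at
#' or above it. Theta features are numbered in order of their earliest time
#' point (theta1, theta2, ...).
#'
#' @param qle qLE map (scales x time).
#' @param scale_freqs_hz frequency axis (length nrow(qle)).
#' @param time_ms time axis (length ncol(qle)).
#' @param threshold qLE threshold (default 0.8).
#' @param split_freq_hz band boundary for splitting/labelling (default 12).
#' @return list of class `tf_features`: `H` (binary mask), `masks` (named
#'   list of per-feature logical matrices), `bands` (band label per
#'   feature), plus the axes and threshold. Empty when nothing survives
#'   (with a warning).
#' @export
extract_features <- function(qle, scale_freqs_hz, time_ms, threshold = 0.8,
                             split_freq_hz = 12) {
  stopifnot(nrow(qle) == length(scale_freqs_hz),
            ncol(qle) == length(time_ms))
  H <- qle >= threshold
  out <- structure(list(H = H, masks = list(), bands = character(0),
                        scale_freqs_hz = scale_freqs_hz, time_ms = time_ms,
                        threshold = threshold),
                   class = "tf_features")
  if (!any(H)) {
    warning("no time-frequency point reaches qLE >= ", threshold)
    return(out)
  }
  lab <- label_components(H)
  masks <- list()
  bands <- character(0)
  hi_rows <- scale_freqs_hz >= split_freq_hz
  for (k in seq_len(max(lab))) {
    m <- lab == k
    rows <- which(rowSums(m) > 0)
    spans <- any(hi_rows[rows]) && any(!hi_rows[rows])
    parts <- if (spans) {
      lo <- m; lo[hi_rows, ] <- FALSE
      hi <- m; hi[!hi_rows, ] <- FALSE
      list(lo, hi)
    } else list(m)
    for (pm in parts) {
      if (!any(pm)) next
      band <- if (any(hi_rows & rowSums(pm) > 0)) "beta_gamma" else "theta"
      masks[[length(masks) + 1L]] <- pm
      bands <- c(bands, band)
    }
  }
  # stable naming: theta features by onset time, beta_gamma likewise
  onset <- vapply(masks, function(m) min(which(colSums(m) > 0)), 1L)
  nm <- character(length(masks))
  for (b in unique(bands)) {
    idx <- which(bands == b)
    idx <- idx[order(onset[idx])]
    nm[idx] <- if (length(idx) == 1) b else paste0(b, seq_along(idx))
  }
  names(masks) <- nm
  out$masks <- masks
  out$bands <- bands
  out
}

#' Temporal and spectral marginal distributions of a masked feature
#'
#' The masked surface (h * g) averaged across the frequency axis gives the
#' temporal distribution y_T (one value per time point); averaged across
#' the time axis it gives the spectral distribution y_F (one value per
#' scale).
#'
#' @param h logical feature mask.
#' @param g condition projection surface, same shape.
#' @return list with `y_T` (length ncol) and `y_F` (length nrow).
#' @export
feature_distributions <- function(h, g) {
  stopifnot(all(dim(h) == dim(g)))
  if (!any(h)) {
    warning("empty feature mask; zero distributions")
    return(list(y_T = numeric(ncol(g)), y_F = numeric(nrow(g))))
  }
  masked <- ifelse(h, g, 0)
  list(y_T = colMeans(masked), y_F = rowMeans(masked))
}

# Local maxima of y at indices `allowed`, keeping peaks separated by a
# valley dipping below `dip` times the smaller of the two peak heights.
# Ties are kept; a flat distribution returns its first allowed index.
find_peaks <- function(y, allowed = seq_along(y), dip = 0.75) {
  ya <- y[allowed]
  if (length(ya) == 0) return(integer(0))
  if (max(ya) == min(ya)) return(allowed[1])
  n <- length(ya)
  cand <- which(ya >= c(-Inf, ya[-n]) & ya >= c(ya[-1], -Inf) & ya > 0)
  # drop plateau duplicates: keep first index of each run
  cand <- cand[c(TRUE, diff(cand) > 1 | ya[cand[-1]] != ya[cand[-length(cand)]])[seq_along(cand)]]
  cand <- cand[order(-ya[cand])]
  kept <- integer(0)
  for (i in cand) {
    ok <- TRUE
    for (j in kept) {
      seg <- ya[min(i, j):max(i, j)]
      if (min(seg) > dip * min(ya[i], ya[j])) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  sort(allowed[kept])
}

#' Feature centroids by joint marginal maxima
#'
#' The primary centroid of a feature is (argmax frequency of y_F, argmax
#' time of y_T, RP = g at that joint point). A local-maxima search splits
#' composite features: when a feature's spectral or temporal distribution
#' shows two or more separated peaks, the mask is partitioned at the valleys
#' between them and the search recurses on each part. This is what
#' separates a merged gamma-beta region into its gamma and beta centroids
#' (spectral peaks) and a swept theta region into its onset and offset
#' centroids (temporal peaks). Equal peaks are all reported, ordered by
#' frequency descending; a flat distribution falls back to the earliest /
#' lowest-frequency point with a warning.
#'
#' @param h logical feature mask.
#' @param g condition projection surface.
#' @param scale_freqs_hz,time_ms axes.
#' @param dip valley depth (fraction of the smaller peak) required to
#'   separate two local maxima (default 0.75, i.e. a 25% dip).
#' @param max_depth recursion limit for the splitting search.
#' @return data.frame with columns freq_hz, latency_ms, rp (one row per
#'   centroid, frequency-descending).
#' @export
feature_centroids <- function(h, g, scale_freqs_hz, time_ms,
                              dip = 0.75, max_depth = 2L) {
  if (!any(h)) return(data.frame(freq_hz = numeric(0),
                                 latency_ms = numeric(0), rp = numeric(0)))
  d <- feature_distributions(h, g)
  if (max(d$y_F) == min(d$y_F) && max(d$y_T) == min(d$y_T)) {
    warning("flat feature distribution; earliest/lowest-frequency point used")
  }
  res <- centroid_search(h, g, dip, max_depth)
  res$freq_hz <- scale_freqs_hz[res$fi]
  res$latency_ms <- time_ms[res$ti]
  res <- res[order(-res$freq_hz), c("freq_hz", "latency_ms", "rp")]
  rownames(res) <- NULL
  res
}

# recursive local-maxima search: split the mask at marginal valleys along
# whichever dimension shows the more separated peak structure
centroid_search <- function(h, g, dip, depth) {
  ds <- feature_distributions(h, g)
  fi <- which(rowSums(h) > 0)
  ti <- which(colSums(h) > 0)
  pF <- find_peaks(ds$y_F, fi, dip)
  pT <- find_peaks(ds$y_T, ti, dip)
  axis <- if (length(pF) >= 2 && length(pF) >= length(pT)) "F"
          else if (length(pT) >= 2) "T" else NA
  if (depth > 0 && !is.na(axis)) {
    y <- if (axis == "F") ds$y_F else ds$y_T
    peaks <- if (axis == "F") pF else pT
    allowed <- if (axis == "F") fi else ti
    cuts <- vapply(seq_len(length(peaks) - 1), function(i) {
      seg <- peaks[i]:peaks[i + 1]
      seg[which.min(y[seg])]
    }, 1L)
    bounds <- c(min(allowed) - 1L, cuts, max(allowed))
    out <- lapply(seq_len(length(peaks)), function(i) {
      sub <- h
      sel <- (bounds[i] + 1L):bounds[i + 1L]
      if (axis == "F") sub[-sel, ] <- FALSE else sub[, -sel] <- FALSE
      if (!any(sub)) return(NULL)
      centroid_search(sub, g, dip, depth - 1L)
    })
    return(do.call(rbind, out))
  }
  fbest <- fi[which.max(ds$y_F[fi])]
  tbest <- ti[which.max(ds$y_T[ti])]
  data.frame(fi = fbest, ti = tbest, rp = g[fbest, tbest])
}

#' Surprise statistic
#'
#' S = -log(dF / (C dT)) with the natural logarithm and the proportionality
#' constant fixed to 1: the log-ratio of the probability of the
#' theta-1/theta-2 frequency difference to the (CFC-latency-scaled)
#' probability of their latency difference.
#'
#' @param dF probability of the theta-1 vs theta-2 frequency difference,
#'   in (0, 1].
#' @param dT probability of the theta-1 vs theta-2 latency difference,
#'   in (0, 1].
#' @param C_cfc positive constant encoding the cross-frequency-coupling
#'   latency (default 1).
#' @return scalar S.
#' @export
surprise <- function(dF, dT, C_cfc = 1) {
  if (!is.finite(dF) || dF <= 0 || dF > 1) stop("dF must lie in (0, 1]")
  if (!is.finite(dT) || dT <= 0 || dT > 1) stop("dT must lie in (0, 1]")
  if (!is.finite(C_cfc) || C_cfc <= 0) stop("C_cfc must be positive")
  -log(dF / (C_cfc * dT))
}

#' Feature extraction from a group analysis
#'
#' Computes the minimum bound over condition projections, the qLE map,
#' extracts supra-threshold features, and tabulates per-condition feature
#' centroids and marginal distributions.
#'
#' @param group an [mmr_group()] result.
#' @param threshold qLE threshold (default 0.8).
#' @param cdf_method "kde" or "ecdf" for the qLE mapping.
#' @param dip peak-separation parameter for [feature_centroids()].
#' @return object of class `mmr_features`: `qle`, `B`, `features` (the
#'   `tf_features`), `centroids` (data.frame feature x condition), and
#'   `distributions` (nested list feature -> condition -> y_T/y_F).
#' @export
mmr_features <- function(group, threshold = 0.8,
                         cdf_method = c("kde", "ecdf"), dip = 0.75) {
  stopifnot(inherits(group, "mmr_group"))
  cdf_method <- match.arg(cdf_method)
  B <- minimum_bound(group$g)
  qle <- qle_map(group$G, B, cdf_method = cdf_method)
  feats <- extract_features(qle, group$scale_freqs_hz, group$time_ms,
                            threshold = threshold)
  cents <- list()
  dists <- list()
  for (f in names(feats$masks)) {
    h <- feats$masks[[f]]
    dists[[f]] <- list()
    for (d in names(group$g)) {
      cc <- feature_centroids(h, group$g[[d]], group$scale_freqs_hz,
                              group$time_ms, dip = dip)
      if (nrow(cc)) {
        cc$feature <- f
        cc$condition <- d
        cc$peak <- seq_len(nrow(cc))
        cents[[length(cents) + 1L]] <- cc
      }
      dists[[f]][[d]] <- feature_distributions(h, group$g[[d]])
    }
  }
  centroids <- if (length(cents)) {
    do.call(rbind, cents)[, c("feature", "peak", "condition", "freq_hz",
                              "latency_ms", "rp")]
  } else {
    data.frame(feature = character(0), peak = integer(0),
               condition = character(0), freq_hz = numeric(0),
               latency_ms = numeric(0), rp = numeric(0))
  }
  rownames(centroids) <- NULL
  structure(list(qle = qle, B = B, features = feats,
                 centroids = centroids, distributions = dists,
                 threshold = threshold,
                 scale_freqs_hz = group$scale_freqs_hz,
                 time_ms = group$time_ms),
            class = "mmr_features")
}

#' @export
print.mmr_features <- function(x, ...) {
  cat("MMR-TF features (qLE threshold ", x$threshold, "): ",
      length(x$features$masks), " feature(s)\n", sep = "")
  if (nrow(x$centroids)) {
    df <- x$centroids
    df$freq_hz <- round(df$freq_hz, 2)
    df$rp <- round(df$rp, 3)
    print(df)
  }
  invisible(x)
}

#' @export
summary.mmr_features <- function(object, ...) print(object)

#' @export
plot.mmr_features <- function(x, ...) {
  plot_tf_surface(x$qle, x$scale_freqs_hz, x$time_ms,
                  main = paste0("qLE map (threshold ", x$threshold, ")"), ...)
  if (nrow(x$centroids)) {
    graphics::points(x$centroids$latency_ms, log2(x$centroids$freq_hz),
                     pch = 21, bg = "white")
  }
  invisible(x)
}

#' Overlap-based estimate of the surprise inputs (experimental)
#'
#' Estimates dF as the overlap coefficient (sum of pointwise minima of the
#' sum-normalized spectral distributions) of the theta-1 and theta-2
#' features, and dT likewise from their temporal distributions. This is one
#' admissible operationalization of "probability of a frequency/latency
#' difference": identical distributions give overlap 1 (no difference,
#' dF = 1), disjoint ones give overlap near 0 (clamped to `floor`).
#'
#' @param featureset an [mmr_features()] result with at least two theta
#'   features.
#' @param condition which condition's distributions to use.
#' @param C_cfc positive CFC-latency constant (default 1).
#' @param floor lower clamp for the overlap probabilities (default 1e-6).
#' @return list with `dF`, `dT`, `C_cfc`, and `S` (the surprise).
#' @export
mmr_surprise <- function(featureset, condition, C_cfc = 1, floor = 1e-6) {
  stopifnot(inherits(featureset, "mmr_features"))
  th <- grep("^theta", names(featureset$distributions), value = TRUE)
  if (length(th) < 2) {
    stop("need two theta features (theta1, theta2) to estimate surprise")
  }
  d1 <- featureset$distributions[[th[1]]][[condition]]
  d2 <- featureset$distributions[[th[2]]][[condition]]
  if (is.null(d1) || is.null(d2)) stop("unknown condition '", condition, "'")
  ovl <- function(a, b) {
    if (sum(a) == 0 || sum(b) == 0) return(floor)
    max(sum(pmin(a / sum(a), b / sum(b))), floor)
  }
  dF <- ovl(d1$y_F, d2$y_F)
  dT <- ovl(d1$y_T, d2$y_T)
  list(dF = dF, dT = dT, C_cfc = C_cfc, S = surprise(dF, dT, C_cfc))
}
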