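#' Median-center log fold changes
#'
#' Centers a vector of per-gene log fold changes on its median, under the
#' assumption that the majority of genes are not perturbed by the
#' treatment; the output median is exactly 0.
#'
#' @param fcs numeric vector of log fold changes (NAs allowed).
#' @return centered vector, same length and missingness.
#' @export
center_log_fold_changes <- function(fcs) {
  if (all(is.na(fcs))) abort("all fold changes are missing")
  fcs - median(fcs, na.rm = TRUE)
}

#' Fit a Gaussian to a fold-change histogram
#'
#' Bins the values at a fixed bin width and fits
#' `A * exp(-(x - center)^2 / (2 * width^2))` to the bin counts by
#' nonlinear least squares (Levenberg-Marquardt), initialized at the
#' sample mean/sd and the maximum bin count. `width` is the Gaussian
#' sigma; the full width at half maximum is also reported. A fit whose
#' residual RMSE exceeds 15% of the fitted amplitude is flagged
#' `poor_fit` (the data are then visibly non-Gaussian).
#'
#' @param values numeric vector of log2 fold changes (>= 50 finite values).
#' @param bin_width histogram bin width in log2 units (default 0.1).
#' @return a `gaussian_fit` list: `amplitude`, `center`, `width`, `fwhm`,
#'   `fit_rmse`, `poor_fit`, `n`, plus the binned histogram.
#' @export
fit_gaussian_to_histogram <- function(values, bin_width = 0.1) {
  v <- values[is.finite(values)]
  if (length(v) < 50) abort("need at least 50 finite values")
  breaks <- seq(floor(min(v) / bin_width) * bin_width - bin_width / 2,
                max(v) + bin_width, by = bin_width)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  dat <- tibble(x = h$mids, count = h$counts)
  start <- list(A = max(dat$count), mu = mean(v), sig = max(sd(v), bin_width))
  fit <- tryCatch(
    minpack.lm::nlsLM(count ~ A * exp(-(x - mu)^2 / (2 * sig^2)),
                      data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      abort(paste0("Gaussian fit did not converge (start: A=",
                   signif(start$A, 4), ", mu=", signif(start$mu, 4),
                   ", sig=", signif(start$sig, 4), "): ",
                   conditionMessage(e)))
    })
  cf <- coef(fit)
  rmse <- sqrt(mean(resid(fit)^2))
  structure(list(amplitude = unname(abs(cf["A"])),
                 center = unname(cf["mu"]),
                 width = unname(abs(cf["sig"])),
                 fwhm = 2 * sqrt(2 * log(2)) * unname(abs(cf["sig"])),
                 fit_rmse = rmse,
                 poor_fit = rmse > 0.15 * abs(cf["A"]),
                 n = length(v), histogram = dat),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat("Gaussian fit to fold-change histogram\n",
      "  center: ", signif(x$center, 4),
      "  width (sigma): ", signif(x$width, 4),
      "  FWHM: ", signif(x$fwhm, 4), "\n",
      "  amplitude: ", signif(x$amplitude, 4),
      "  RMSE: ", signif(x$fit_rmse, 4),
      if (x$poor_fit) "  [poor fit]", "\n", sep = "")
  invisible(x)
}

#' Transcript-protein fold-change correlation
#'
#' Squared Pearson correlation between paired transcript and protein log2
#' fold changes.
#'
#' @param pairs data frame whose first two numeric columns (or
#'   `transcript_log2fc` / `protein_log2fc`) hold the paired values;
#'   incomplete pairs are dropped.
#' @return R-squared (scalar).
#' @export
transcript_protein_correlation <- function(pairs) {
  nm <- names(pairs)
  if (all(c("transcript_log2fc", "protein_log2fc") %in% nm)) {
    x <- pairs$transcript_log2fc; y <- pairs$protein_log2fc
  } else {
    num <- which(vapply(pairs, is.numeric, TRUE))
    if (length(num) < 2) abort("need two numeric columns")
    x <- pairs[[num[1]]]; y <- pairs[[num[2]]]
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in one of the vectors")
  unname(cor(x, y)^2)
}

#' K-means clustering of protein time courses
#'
#' Clusters proteins by their log2 fold-change profile across timepoints
#' with K-means (multiple restarts), choosing the cluster count that
#' maximizes the mean silhouette width (Euclidean) over the candidate
#' range. Proteins with any missing timepoint are dropped with a message.
#' Deterministic under a fixed seed. If the silhouette criterion is
#' degenerate (e.g. all profiles identical), selection is flagged.
#'
#' @param mat numeric matrix or data frame, proteins x timepoints;
#'   rownames identify proteins.
#' @param k_range candidate cluster counts (default 2:8); the maximum must
#'   not exceed half the number of complete profiles.
#' @param restarts K-means restarts per candidate k (default 25).
#' @param seed integer seed.
#' @return a `timecourse_clustering` list: `k_selected`, `centroids`,
#'   `labels`, `selection_score` per candidate k, `degenerate`, `seed`.
#' @export
cluster_timecourse <- function(mat, k_range = 2:8, restarts = 25, seed = 1L) {
  m <- as.matrix(mat)
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  complete <- complete.cases(m)
  if (any(!complete)) {
    inform(paste0(sum(!complete), " profile(s) with missing timepoints dropped"))
    m <- m[complete, , drop = FALSE]
  }
  if (max(k_range) > nrow(m) / 2) {
    abort("max(k_range) exceeds half the number of complete profiles")
  }
  withr::with_seed(as.integer(seed), {
    d <- dist(m)
    n_distinct_rows <- nrow(unique(m))
    degenerate <- n_distinct_rows < 2
    if (degenerate) {
      inform("all profiles identical; clustering degenerates to one cluster")
      return(structure(list(k_selected = 1L,
                            centroids = matrix(colMeans(m), 1,
                                               dimnames = list(NULL, colnames(m))),
                            labels = setNames(rep(1L, nrow(m)), rownames(m)),
                            selection_score = setNames(rep(NA_real_, length(k_range)),
                                                       k_range),
                            tot_withinss = 0,
                            degenerate = TRUE,
                            seed = as.integer(seed)),
                       class = "timecourse_clustering"))
    }
    k_ok <- k_range[k_range <= n_distinct_rows]
    scores <- vapply(k_range, function(k) {
      if (!k %in% k_ok) return(NA_real_)
      km <- kmeans(m, centers = k, nstart = restarts, iter.max = 100)
      if (length(unique(km$cluster)) < 2) return(NA_real_)
      mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
    }, numeric(1))
    if (all(is.na(scores))) {
      inform("silhouette selection degenerate; returning k = min(k_range)")
      k_sel <- min(k_range)
    } else {
      k_sel <- k_range[which.max(scores)]
    }
    km <- kmeans(m, centers = k_sel, nstart = restarts, iter.max = 100)
    structure(list(k_selected = k_sel,
                   centroids = km$centers,
                   labels = setNames(km$cluster, rownames(m)),
                   selection_score = setNames(scores, k_range),
                   tot_withinss = km$tot.withinss,
                   degenerate = degenerate,
                   seed = as.integer(seed)),
              class = "timecourse_clustering")
  })
}

#' @export
print.timecourse_clustering <- function(x, ...) {
  cat("Time-course K-means clustering\n",
      "  k selected: ", x$k_selected,
      if (x$degenerate) "  [degenerate geometry]", "\n",
      "  mean silhouette by k: ",
      paste(names(x$selection_score), signif(x$selection_score, 3),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
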