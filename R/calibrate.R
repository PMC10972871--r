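# Calibration of the depth-to-size slope and ploidy inference. Reference
# monoploid sizes come from C-value databases (1Cx = 2*1C/ploidy); the slope
# beta is fitted per lineage by robust regression of the theoretical depth
# (L / reference 1Cx) on the observed single-copy-protein depth; ploidy of a
# specimen follows from a flow-cytometry 1C and an estimated 1Cx.

#' Monoploid genome size from a C-value and a ploidy level
#'
#' 1Cx = 2 * 1C / ploidy; by definition 1C = 1Cx for a diploid.
#'
#' @param one_c Holoploid genome size (any unit; the result is in the same
#'   unit).
#' @param ploidy Integer ploidy level, at least 2.
#' @return The monoploid genome size.
#' @export
kew_one_cx <- function(one_c, ploidy) {
  if (any(ploidy < 2)) stop("ploidy must be >= 2")
  if (any(one_c <= 0)) stop("1C must be positive")
  2 * one_c / ploidy
}

#' Consensus monoploid size across cytotypes of a species
#'
#' Per-cytotype 1Cx values are computed with [kew_one_cx()]; when their
#' range exceeds `max_variation` of the mean the species is rejected
#' (intraspecific monoploid size variation makes it unusable as a
#' calibration reference), otherwise the arithmetic mean 1Cx is returned.
#'
#' @param one_c Vector of holoploid sizes, one per cytotype.
#' @param ploidy Matching vector of ploidy levels.
#' @param max_variation Maximum tolerated (max - min)/mean (default 0.10).
#' @return A list with `accepted` (logical), `one_cx` (mean 1Cx or `NA`) and
#'   `variation`.
#' @export
cytotype_consensus <- function(one_c, ploidy, max_variation = 0.10) {
  stopifnot(length(one_c) >= 1L, length(one_c) == length(ploidy))
  cx <- kew_one_cx(one_c, ploidy)
  variation <- if (length(cx) == 1L) 0 else (max(cx) - min(cx)) / mean(cx)
  if (variation > max_variation)
    list(accepted = FALSE, one_cx = NA_real_, variation = variation)
  else
    list(accepted = TRUE, one_cx = mean(cx), variation = variation)
}

#' Theoretical sequencing depth from a reference genome size
#'
#' L / reference 1Cx: the depth the read set would have on a genome of the
#' reference size; the response variable of the calibration regression.
#'
#' @param L Cumulative read length (nt).
#' @param ref_one_cx_bp Reference monoploid size in bp (> 0).
#' @return The theoretical fold-coverage.
#' @export
theoretical_depth <- function(L, ref_one_cx_bp) {
  if (any(ref_one_cx_bp <= 0)) stop("reference 1Cx must be positive")
  L / ref_one_cx_bp
}

#' Robust slope of theoretical depth on observed SCP depth
#'
#' M-estimation with Tukey bisquare weights by iteratively reweighted least
#' squares: weights w(r) = (1 - (r/(c*s))^2)^2 for |r| < c*s, else 0, with
#' scale s = 1.4826 x median(|r|) (MAD about zero) recomputed each
#' iteration, initialised at the median of y/x so the fit is deterministic.
#' The regression goes through the origin by default, because the estimator
#' uses a single multiplicative slope; an intercept is available for
#' diagnostics only.
#'
#' @param x Observed SCP depths (> 0).
#' @param y Theoretical depths.
#' @param with_intercept Fit an intercept (diagnostic use).
#' @param tuning_c Bisquare tuning constant (default 4.685, 95% Gaussian
#'   efficiency).
#' @param tol Convergence tolerance on the slope (default 1e-8).
#' @param max_iter Maximum IRLS iterations (default 100).
#' @return An object of class `robust_fit`: list with `beta`, `intercept`,
#'   `n_points`, `n_downweighted` (points given zero weight), `converged`,
#'   `iterations`.
#' @export
robust_slope <- function(x, y, with_intercept = FALSE, tuning_c = 4.685,
                         tol = 1e-8, max_iter = 100L) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 calibration points")
  if (any(x <= 0)) stop("observed depths must be positive")
  beta <- median(y / x)
  alpha <- 0
  w <- rep(1, length(x))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    r <- y - alpha - beta * x
    s <- 1.4826 * median(abs(r))
    if (s == 0) { converged <- TRUE; break }   # (near-)exact fit
    u <- r / (tuning_c * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (all(w == 0)) stop("degenerate fit: all points rejected")
    if (with_intercept) {
      fit <- stats::lm.wfit(cbind(1, x), y, w)
      alpha_new <- fit$coefficients[1]; beta_new <- fit$coefficients[2]
    } else {
      alpha_new <- 0
      beta_new <- sum(w * x * y) / sum(w * x^2)
    }
    done <- abs(beta_new - beta) < tol && abs(alpha_new - alpha) < tol
    beta <- unname(beta_new); alpha <- unname(alpha_new)
    if (done) { converged <- TRUE; break }
  }
  if (beta <= 0) stop("degenerate fit: non-positive slope")
  structure(list(beta = beta, intercept = alpha, n_points = length(x),
                 n_downweighted = sum(w == 0), converged = converged,
                 iterations = iter),
            class = "robust_fit")
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("Robust slope fit: beta = %.6g (n = %d, %d rejected, %s in %d iterations)\n",
              x$beta, x$n_points, x$n_downweighted,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Per-group slope calibration
#'
#' Fits [robust_slope()] separately for each group (lineage or family) of
#' calibration points, plus an `all` entry fitted on the union, and returns
#' the result as a slope table. Groups with fewer than 3 points are skipped
#' with a warning. The theoretical depth is computed as `L / ref_one_cx_bp`
#' when not supplied directly.
#'
#' @param points A `data.frame` with columns `group`, `scp_depth` and either
#'   `theoretical_depth` or both `L` and `ref_one_cx_bp`.
#' @param ... Passed to [robust_slope()].
#' @return A `slope_table` with columns `group`, `slope`, `n_points`.
#' @export
calibrate_groups <- function(points, ...) {
  stopifnot(all(c("group", "scp_depth") %in% names(points)))
  if (!"theoretical_depth" %in% names(points)) {
    stopifnot(all(c("L", "ref_one_cx_bp") %in% names(points)))
    points$theoretical_depth <-
      theoretical_depth(points$L, points$ref_one_cx_bp)
  }
  fit_one <- function(d) robust_slope(d$scp_depth, d$theoretical_depth, ...)
  rows <- list()
  for (g in unique(points$group)) {
    d <- points[points$group == g, , drop = FALSE]
    if (nrow(d) < 3L) {
      warning("group '", g, "' has fewer than 3 points; skipped",
              call. = FALSE)
      next
    }
    f <- fit_one(d)
    rows[[g]] <- data.frame(group = g, slope = f$beta, n_points = f$n_points)
  }
  f_all <- fit_one(points)
  rows[["all"]] <- data.frame(group = "all", slope = f_all$beta,
                              n_points = f_all$n_points)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  out <- as_slope_table(tab[, c("group", "slope")])
  out$n_points <- tab$n_points[match(tolower(out$group), tolower(tab$group))]
  out$n_points[is.na(out$n_points)] <- 0L
  out
}

#' Convert picograms of DNA to megabases
#' @param pg DNA amount in picograms.
#' @return Megabases (1 pg = 978 Mb).
#' @export
pg_to_mb <- function(pg) pg * PG_TO_MB

#' Ploidy level from a cytometry 1C and an estimated 1Cx
#'
#' ploidy = 2 * 1C / 1Cx: the inverse of [kew_one_cx()]. Both values must
#' be in the same unit.
#'
#' @param one_c_cytometry Holoploid size measured by flow cytometry.
#' @param one_cx_estimate Estimated monoploid size.
#' @param round_result Round to the nearest (positive) integer ploidy.
#' @return The estimated ploidy (real, or integer when rounded).
#' @export
estimate_ploidy <- function(one_c_cytometry, one_cx_estimate,
                            round_result = FALSE) {
  stopifnot(all(one_c_cytometry > 0), all(one_cx_estimate > 0))
  p <- 2 * one_c_cytometry / one_cx_estimate
  if (round_result) pmax(1L, as.integer(round(p))) else p
}
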