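#' Detection p-values from a background model
#'
#' For each probe the total intensity `T = U + M` is tested against the
#' estimated normal background distribution `B` with a one-sided upper-tail
#' z-test: a small p-value means `T` is unlikely to be pure background and
#' the probe is *detected*. The background for `T` combines the per-channel
#' components of its design:
#' \itemize{
#'   \item Type II: `mu = mu_grn + mu_red`, `sigma^2 = sigma_grn^2 + sigma_red^2`
#'     (M is read in green, U in red);
#'   \item Type I Grn: `mu = 2 mu_grn`, `sigma^2 = 2 sigma_grn^2` (both
#'     alleles in green, independence assumed); Type I Red mirrored.
#' }
#' `bug_mode = TRUE` reproduces a historical misspecification in which the
#' component standard deviations were added instead of the variances
#' (`sigma = sigma_grn + sigma_red`, `sigma = 2 sigma_c` for Type I). The
#' inflated spread yields systematically larger p-values for above-background
#' intensities, so the buggy test calls fewer probes detected at a given
#' cut-off — which historically pushed recommended cut-offs to extremes such
#' as 1e-16. It is provided only for comparison studies.
#'
#' A probe is *detected* when `p < cutoff` (strictly below the chosen
#' significance level). P-values are not multiplicity-adjusted: cut-offs are
#' operating points for filtering, not inference.
#'
#' @param x a [sample_intensities] object.
#' @param manifest an [array_manifest].
#' @param bg a `background_model` from [estimate_background_nsp()],
#'   [estimate_background_neg()] or [estimate_background()].
#' @param cutoff significance level in `(0, 1]` (default 0.01).
#' @param bug_mode reproduce the standard-deviation-addition bug.
#' @return object of class `detection_result`: list with `probe_id`, `p`,
#'   `detected` (`p < cutoff`; `NA` p counts as not detected), `method`,
#'   `cutoff`, `bug_mode`, `sample_id`.
#' @export
detection_p <- function(x, manifest, bg, cutoff = 0.01, bug_mode = FALSE) {
  .check_cutoff(cutoff)
  a <- manifest[assay_rows(manifest), , drop = FALSE]
  stopifnot(length(x$U) == nrow(a))
  tt <- total_intensity(x)
  mu <- sigma <- rep(NA_real_, nrow(a))

  i2 <- a$design == "II"
  mu[i2] <- bg$mu_grn + bg$mu_red
  sigma[i2] <- if (bug_mode) bg$sigma_grn + bg$sigma_red
               else sqrt(bg$sigma_grn^2 + bg$sigma_red^2)

  ig <- a$design == "I" & a$channel == "Grn"
  mu[ig] <- 2 * bg$mu_grn
  sigma[ig] <- if (bug_mode) 2 * bg$sigma_grn else sqrt(2) * bg$sigma_grn

  ir <- a$design == "I" & a$channel == "Red"
  mu[ir] <- 2 * bg$mu_red
  sigma[ir] <- if (bug_mode) 2 * bg$sigma_red else sqrt(2) * bg$sigma_red

  if (any(sigma <= 0, na.rm = TRUE)) stop("background sigma must be positive")
  p <- stats::pnorm(tt, mean = mu, sd = sigma, lower.tail = FALSE)
  out <- list(probe_id = a$probe_id, p = p,
              detected = !is.na(p) & p < cutoff,
              method = bg$method, cutoff = cutoff, bug_mode = bug_mode,
              sample_id = x$sample_id)
  class(out) <- "detection_result"
  out
}

.check_cutoff <- function(cutoff) {
  if (length(cutoff) != 1L || is.na(cutoff) || cutoff <= 0 || cutoff > 1) {
    stop("cutoff must be a single value in (0, 1]")
  }
}

.p_from <- function(det) {
  if (inherits(det, "detection_result")) det$p else as.numeric(det)
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(
    "detection_result '%s' [%s%s, cutoff %g]: %d/%d detected, %d missing\n",
    x$sample_id, x$method, if (x$bug_mode) "/bug-compat" else "", x$cutoff,
    sum(x$detected), length(x$p), sum(is.na(x$p))))
  invisible(x)
}

#' Mask undetected observations in a beta vector
#'
#' Sets beta to `NA` wherever the detection p-value is missing or at/above
#' the cut-off. Retained values are returned bit-identically: the NEG and
#' NSP filters differ only in *which* observations they deem undetected,
#' never in the values that survive.
#'
#' @param beta numeric beta vector aligned to the detection result.
#' @param det a `detection_result` or a bare p-value vector.
#' @param cutoff significance level; defaults to the one recorded in `det`.
#' @return masked beta vector of the same length.
#' @export
mask_undetected <- function(beta, det, cutoff = NULL) {
  p <- .p_from(det)
  if (is.null(cutoff)) {
    cutoff <- if (inherits(det, "detection_result")) det$cutoff else
      stop("cutoff required when det is a bare p-value vector")
  }
  .check_cutoff(cutoff)
  stopifnot(length(beta) == length(p))
  beta[is.na(p) | p >= cutoff] <- NA_real_
  beta
}

#' Per-sample counts of undetected probes
#'
#' Counts, per sample, the probes within a chromosomal scope whose p-value
#' is missing or at/above the cut-off. The default scope — autosomes plus X —
#' is the set on which data loss is reported, since Y-chromosome probes are
#' legitimately undetected in females.
#'
#' @param p_matrix numeric matrix of detection p-values, probes x samples,
#'   rownames = probe ids.
#' @param manifest an [array_manifest].
#' @param cutoff significance level (default 0.01).
#' @param scope `"autosomal_x"` (default), `"autosomal"` or `"all"`.
#' @return data.frame with `sample_id`, `n_undetected`, `n_scope`,
#'   `fraction`; the across-sample median count is attached as attribute
#'   `"median"`.
#' @export
undetected_counts <- function(p_matrix, manifest, cutoff = 0.01,
                              scope = c("autosomal_x", "autosomal", "all")) {
  scope <- match.arg(scope)
  .check_cutoff(cutoff)
  a <- manifest[assay_rows(manifest), , drop = FALSE]
  keep <- switch(scope,
    autosomal_x = a$chromosome %in% c(as.character(1:22), "X"),
    autosomal = a$chromosome %in% as.character(1:22),
    all = rep(TRUE, nrow(a)))
  ids <- a$probe_id[keep]
  sub <- p_matrix[rownames(p_matrix) %in% ids, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no probes in scope '", scope, "'")
  n_undet <- colSums(is.na(sub) | sub >= cutoff)
  out <- data.frame(sample_id = colnames(sub), n_undetected = n_undet,
                    n_scope = nrow(sub), fraction = n_undet / nrow(sub),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "median") <- stats::median(out$n_undetected)
  out
}

#' Detection p-value matrix for a set of samples
#'
#' Convenience wrapper: estimates the background per sample (NSP probe sets
#' and peaks from that sample's own beta values) and stacks the detection
#' p-values into a probe-by-sample matrix.
#'
#' @param samples list of [sample_intensities] sharing one manifest.
#' @param manifest an [array_manifest].
#' @param method "NSP" or "NEG".
#' @param cutoff significance level recorded with the results.
#' @param bug_mode reproduce the standard-deviation-addition bug.
#' @param k,offset passed to [estimate_background()].
#' @return numeric matrix of p-values (probes x samples) with attribute
#'   `"method"`.
#' @export
detection_p_matrix <- function(samples, manifest, method = c("NSP", "NEG"),
                               cutoff = 0.01, bug_mode = FALSE, k = 1000,
                               offset = 100) {
  method <- match.arg(method)
  p <- sample_matrix(samples, function(s) {
    bg <- estimate_background(s, manifest, method = method, k = k,
                              offset = offset)
    detection_p(s, manifest, bg, cutoff = cutoff, bug_mode = bug_mode)$p
  })
  attr(p, "method") <- tolower(method)
  p
}
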