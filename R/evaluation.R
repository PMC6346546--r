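#' Y-chromosome detection benchmark
#'
#' Probes targeting the Y chromosome should be detected in males but not in
#' females, which makes them a ground-truth benchmark for detection p-value
#' cut-offs: a good cut-off classifies most Y probes among females as
#' undetected while retaining most of them among males. For every cut-off
#' and sex the per-sample count of detected Y probes is summarized (median
#' and 2.5th/97.5th percentiles, linear-interpolation quantiles). Among
#' females the per-probe *call rate* (fraction of samples in which the probe
#' is detected) is also computed; probes with call rate above 98% despite
#' the absent chromosome are candidates for cross-reactivity with autosomal
#' loci, while call rates below 2% indicate well-behaved probes.
#'
#' @param p_matrix detection p-values, probes x samples, rownames probe ids,
#'   colnames sample ids.
#' @param manifest an [array_manifest].
#' @param sex character vector (`"male"`/`"female"`) aligned to the columns
#'   of `p_matrix`, or named by sample id.
#' @param cutoffs numeric vector of significance levels (default 0.01).
#' @return object of class `y_benchmark`: list with
#'   \describe{
#'     \item{summary}{data.frame `cutoff`, `sex`, `n_samples`, `median`,
#'       `q025`, `q975` of detected-Y counts per sample;}
#'     \item{counts}{matrix of detected-Y counts, samples x cutoffs;}
#'     \item{call_rate}{matrix of female call rates, Y probes x cutoffs;}
#'     \item{classification}{per cutoff, probe-id lists `low` (< 2%) and
#'       `high` (> 98%);}
#'     \item{n_y}{number of Y probes.}
#'   }
#' @export
y_benchmark <- function(p_matrix, manifest, sex, cutoffs = 0.01) {
  sex <- .align_sex(sex, colnames(p_matrix))
  if (length(cutoffs) == 0L) stop("empty cutoff grid")
  for (a in cutoffs) .check_cutoff(a)
  y_ids <- manifest$probe_id[!is.na(manifest$chromosome) &
                               manifest$chromosome == "Y"]
  if (length(y_ids) == 0L) stop("manifest contains no Y-chromosome probes")
  yp <- p_matrix[rownames(p_matrix) %in% y_ids, , drop = FALSE]

  counts <- vapply(cutoffs,
                   function(a) colSums(!is.na(yp) & yp < a),
                   numeric(ncol(yp)))
  counts <- matrix(counts, nrow = ncol(yp),
                   dimnames = list(colnames(yp), format(cutoffs)))

  summary <- do.call(rbind, lapply(seq_along(cutoffs), function(i) {
    do.call(rbind, lapply(c("male", "female"), function(s) {
      v <- counts[sex == s, i]
      data.frame(cutoff = cutoffs[i], sex = s, n_samples = length(v),
                 median = stats::median(v),
                 q025 = unname(stats::quantile(v, 0.025, type = 7)),
                 q975 = unname(stats::quantile(v, 0.975, type = 7)),
                 stringsAsFactors = FALSE)
    }))
  }))

  fem <- yp[, sex == "female", drop = FALSE]
  call_rate <- vapply(cutoffs,
                      function(a) rowMeans(!is.na(fem) & fem < a),
                      numeric(nrow(fem)))
  call_rate <- matrix(call_rate, nrow = nrow(fem),
                      dimnames = list(rownames(fem), format(cutoffs)))
  classification <- lapply(seq_along(cutoffs), function(i) {
    list(low = rownames(call_rate)[call_rate[, i] < 0.02],
         high = rownames(call_rate)[call_rate[, i] > 0.98])
  })
  names(classification) <- format(cutoffs)

  out <- list(summary = summary, counts = counts, call_rate = call_rate,
              classification = classification, n_y = nrow(yp))
  class(out) <- "y_benchmark"
  out
}

.align_sex <- function(sex, sample_ids) {
  if (!is.null(names(sex)) && !is.null(sample_ids)) {
    missing <- setdiff(sample_ids, names(sex))
    if (length(missing) > 0L) {
      stop("no sex label for sample(s): ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
    sex <- sex[sample_ids]
  }
  if (length(sex) != length(sample_ids)) {
    stop("sex labels must align with the samples")
  }
  sex <- tolower(as.character(sex))
  bad <- setdiff(unique(sex), c("male", "female"))
  if (length(bad) > 0L) {
    stop("unknown sex label(s): ", paste(bad, collapse = ", "))
  }
  unname(sex)
}

#' @export
print.y_benchmark <- function(x, ...) {
  cat(sprintf("y_benchmark: %d Y probes, %d cutoffs\n", x$n_y,
              length(unique(x$summary$cutoff))))
  print(utils::head(x$summary, 10L))
  invisible(x)
}

#' Default cut-off grids for the two background methods
#'
#' NEG-based p-values are so permissive that cut-offs down to 1e-80 are worth
#' sweeping; NSP-based p-values are larger (the estimated background is
#' higher), so the useful range ends around 1e-3.
#'
#' @param method "nsp" or "neg" (case-insensitive).
#' @return decreasing numeric vector of cut-offs starting at 1.
#' @export
default_cutoff_grid <- function(method = c("nsp", "neg")) {
  method <- match.arg(tolower(method), c("nsp", "neg"))
  if (method == "neg") 10^seq(0, -80, by = -2) else 10^seq(0, -3, by = -0.25)
}

#' Sweep detection cut-offs for the Y benchmark and data-loss curves
#'
#' Tabulates [y_benchmark()] summaries over a cut-off grid together with the
#' per-sample undetected counts (autosomes + X) at each cut-off — the two
#' ingredients of a cut-off choice: stringency on the Y benchmark vs.
#' overall data loss.
#'
#' @inheritParams y_benchmark
#' @param cutoffs cut-off grid (default [default_cutoff_grid()] for the
#'   method recorded in `attr(p_matrix, "method")`, else the NSP grid).
#' @param scope passed to [undetected_counts()].
#' @return list with `y` (a `y_benchmark` over the grid) and `undetected`
#'   (data.frame `cutoff`, `sample_id`, `n_undetected`, `n_scope`).
#' @export
cutoff_sweep <- function(p_matrix, manifest, sex, cutoffs = NULL,
                         scope = "autosomal_x") {
  if (is.null(cutoffs)) {
    method <- attr(p_matrix, "method")
    cutoffs <- default_cutoff_grid(if (is.null(method)) "nsp" else method)
  }
  if (length(cutoffs) == 0L) stop("empty cutoff grid")
  y <- y_benchmark(p_matrix, manifest, sex, cutoffs = cutoffs)
  undet <- do.call(rbind, lapply(cutoffs, function(a) {
    u <- undetected_counts(p_matrix, manifest, cutoff = a, scope = scope)
    cbind(cutoff = a, u)
  }))
  list(y = y, undetected = undet)
}

#' Technical-replicate concordance and outlier masking
#'
#' Compares paired measurements of the same biological sample. Probes are
#' stratified into those detected in *both* members versus all others; the
#' median absolute beta difference is reported for each stratum (detected
#' probes should be far more concordant). *Large outliers* are pairs whose
#' absolute beta difference exceeds `outlier_threshold` (default 0.20, i.e.
#' 20 percentage points — well outside the measurement precision of the
#' platform); the report counts how many of them are caught by the filter,
#' i.e. are undetected in at least one member.
#'
#' @param beta_a,beta_b unmasked beta vectors of the two replicates, aligned.
#' @param det_a,det_b `detection_result`s or bare p-value vectors, aligned.
#' @param cutoff significance level (default 0.01).
#' @param outlier_threshold absolute beta difference defining a large
#'   outlier, in `(0, 1)`.
#' @return object of class `replicate_report`: list with `n_compared`,
#'   `median_absdiff_detected`, `median_absdiff_other`, `n_outliers`,
#'   `n_outliers_masked`, `masked_fraction`, `cutoff`, `outlier_threshold`.
#' @export
replicate_concordance <- function(beta_a, beta_b, det_a, det_b,
                                  cutoff = 0.01, outlier_threshold = 0.20) {
  .check_cutoff(cutoff)
  if (length(outlier_threshold) != 1L || outlier_threshold <= 0 ||
      outlier_threshold >= 1) {
    stop("outlier_threshold must lie in (0, 1)")
  }
  p_a <- .p_from(det_a)
  p_b <- .p_from(det_b)
  stopifnot(length(beta_a) == length(beta_b),
            length(p_a) == length(beta_a), length(p_b) == length(beta_b))
  if (all(is.na(beta_a)) || all(is.na(beta_b))) {
    stop("all probes missing in one replicate member")
  }
  cmp <- !is.na(beta_a) & !is.na(beta_b)
  d <- abs(beta_a - beta_b)
  both_det <- !is.na(p_a) & p_a < cutoff & !is.na(p_b) & p_b < cutoff
  outlier <- cmp & d > outlier_threshold
  masked <- outlier & !both_det          # undetected in at least one member
  out <- list(
    n_compared = sum(cmp),
    median_absdiff_detected = stats::median(d[cmp & both_det]),
    median_absdiff_other = stats::median(d[cmp & !both_det]),
    n_outliers = sum(outlier),
    n_outliers_masked = sum(masked),
    masked_fraction = if (sum(outlier) > 0L) sum(masked) / sum(outlier)
                      else NA_real_,
    cutoff = cutoff, outlier_threshold = outlier_threshold)
  class(out) <- "replicate_report"
  out
}

#' @export
print.replicate_report <- function(x, ...) {
  cat(sprintf("replicate_report (cutoff %g, outlier > %.0f pp)\n",
              x$cutoff, 100 * x$outlier_threshold))
  cat(sprintf("  %d probe pairs compared\n", x$n_compared))
  cat(sprintf("  median |dbeta|: %.1f pp (both detected), %.1f pp (other)\n",
              100 * x$median_absdiff_detected, 100 * x$median_absdiff_other))
  cat(sprintf("  large outliers: %d, of which %d (%.0f%%) masked\n",
              x$n_outliers, x$n_outliers_masked,
              100 * x$masked_fraction))
  invisible(x)
}

#' Plot the detected-Y-count curves of a cut-off sweep
#'
#' Median detected Y-probe count per sex (with 2.5/97.5 percentile ribbons as
#' dashed lines) against `-log10(cutoff)`.
#'
#' @param x a `y_benchmark` computed over a cut-off grid.
#' @param ... passed to [graphics::plot()].
#' @export
plot_y_benchmark <- function(x, ...) {
  s <- x$summary
  lx <- -log10(s$cutoff)
  graphics::plot(range(lx), c(0, x$n_y), type = "n",
                 xlab = "-log10 detection p-value cutoff",
                 ylab = "detected Y-chromosome probes", ...)
  for (sexi in c("male", "female")) {
    ss <- s[s$sex == sexi, ]
    o <- order(-log10(ss$cutoff))
    col <- if (sexi == "male") "#2166ac" else "#b2182b"
    graphics::lines(-log10(ss$cutoff)[o], ss$median[o], col = col, lwd = 2)
    graphics::lines(-log10(ss$cutoff)[o], ss$q025[o], col = col, lty = 2)
    graphics::lines(-log10(ss$cutoff)[o], ss$q975[o], col = col, lty = 2)
  }
  graphics::legend("right", legend = c("male", "female"), lwd = 2,
                   col = c("#2166ac", "#b2182b"))
  invisible(x)
}

#' Plot female call-rate curves of Y-chromosome probes
#'
#' Probes ordered by increasing call rate; a stringent filter separates the
#' curve into a low plateau (genuinely undetected) and a high plateau
#' (probes probably cross-reactive with autosomal loci).
#'
#' @param x a `y_benchmark`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_call_rates <- function(x, ...) {
  cr <- x$call_rate
  graphics::plot(c(1, nrow(cr)), c(0, 1), type = "n",
                 xlab = "Y-chromosome probes (ordered by call rate)",
                 ylab = "call rate among females", ...)
  cols <- grDevices::hcl.colors(ncol(cr), "Dark 2")
  for (i in seq_len(ncol(cr))) {
    graphics::lines(sort(cr[, i]), col = cols[i], lwd = 2)
  }
  graphics::legend("topleft", legend = paste("cutoff", colnames(cr)),
                   lwd = 2, col = cols)
  invisible(x)
}
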