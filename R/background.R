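#' Locate the two modes of a bimodal beta-value distribution
#'
#' Methylation beta values on Infinium arrays are strongly bimodal: a low
#' mode from unmethylated CpGs and a high mode from methylated ones. The
#' modes are found as the argmax of a Gaussian kernel density estimate
#' (Silverman's rule-of-thumb bandwidth, 512-point grid on `[0, 1]`),
#' searched separately below and above 0.5. The search is restricted to
#' `[bounds[1], 0.5)` and `[0.5, bounds[2]]` to avoid edge artifacts; a mode
#' landing on a search-interval boundary signals a likely non-bimodal input
#' and is an error.
#'
#' @param betas numeric vector of beta values in `[0, 1]` (`NA` allowed).
#' @param bounds length-2 numeric, search interval limits (default
#'   `c(0.05, 0.95)`).
#' @param min_n minimum number of non-missing values (default 1000).
#' @param n_grid density grid size.
#' @return object of class `peak_pair`: list with `peak_lo`, `peak_hi`.
#' @export
find_beta_peaks <- function(betas, bounds = c(0.05, 0.95), min_n = 1000,
                            n_grid = 512) {
  b <- betas[!is.na(betas)]
  if (length(b) < min_n) {
    stop("need at least ", min_n, " non-missing beta values, got ", length(b))
  }
  if (any(b < 0 | b > 1)) stop("beta values must lie in [0, 1]")
  if (stats::sd(b) == 0) {
    stop("degenerate beta distribution (constant values); cannot locate peaks")
  }
  stopifnot(length(bounds) == 2L, bounds[1] < 0.5, bounds[2] > 0.5)
  d <- stats::density(b, bw = "nrd0", n = n_grid, from = 0, to = 1)
  lo_idx <- which(d$x >= bounds[1] & d$x < 0.5)
  hi_idx <- which(d$x >= 0.5 & d$x <= bounds[2])
  peak_lo_i <- lo_idx[which.max(d$y[lo_idx])]
  peak_hi_i <- hi_idx[which.max(d$y[hi_idx])]
  at_boundary <- peak_lo_i %in% range(lo_idx) || peak_hi_i %in% range(hi_idx)
  if (at_boundary) {
    stop("density mode at a search-interval boundary; ",
         "beta distribution looks non-bimodal")
  }
  out <- list(peak_lo = d$x[peak_lo_i], peak_hi = d$x[peak_hi_i])
  class(out) <- "peak_pair"
  out
}

#' Select background probe sets: CpGs closest to the two beta peaks
#'
#' Identifies, within one color channel, the completely methylated and
#' completely unmethylated CpG sites whose silent-allele beads carry only
#' non-specific fluorescence. Following the rationale that probes at the
#' extremes of the beta distribution exhibit atypically low background, the
#' `k` Type I probes of the channel with beta values *closest to each peak*
#' are taken (default `k = 1000` per peak). Only Type I probes are eligible:
#' they are read in a single channel and so do not suffer cross-talk from dye
#' bound at the same bead. A probe eligible for both sets is assigned to the
#' nearer peak; ties are broken deterministically by (distance, probe id).
#'
#' @param betas numeric vector aligned to the assay probes of `manifest`.
#' @param manifest an [array_manifest].
#' @param peaks a `peak_pair` from [find_beta_peaks()].
#' @param channel "Grn" or "Red".
#' @param k probes selected per peak (default 1000).
#' @param min_n minimum acceptable set size (default 30); fewer than `k`
#'   eligible probes triggers a warning, fewer than `min_n` an error.
#' @return object of class `background_probe_sets`: list with `channel`,
#'   `fully_meth`, `fully_unmeth` (character probe-id vectors), `k`.
#' @export
select_background_probes <- function(betas, manifest, peaks, channel,
                                     k = 1000, min_n = 30) {
  channel <- match.arg(channel, c("Grn", "Red"))
  stopifnot(k >= 1)
  a <- manifest[assay_rows(manifest), , drop = FALSE]
  if (length(betas) != nrow(a)) {
    stop("betas must align with the manifest's assay probes")
  }
  elig <- which(a$design == "I" & a$channel == channel & !is.na(betas))
  if (length(elig) == 0L) stop("no eligible Type I ", channel, " probes")
  id <- a$probe_id[elig]
  d_lo <- abs(betas[elig] - peaks$peak_lo)
  d_hi <- abs(betas[elig] - peaks$peak_hi)
  # nearer-peak assignment; exact ties go to the unmethylated side
  to_hi <- d_hi < d_lo
  pick <- function(ids, d, label) {
    ord <- order(d, ids)              # stable (distance, probe_id) tie-break
    sel <- ids[ord][seq_len(min(k, length(ids)))]
    if (length(sel) < k) {
      warning(sprintf("only %d eligible probes for the %s set (k = %d)",
                      length(sel), label, k))
    }
    if (length(sel) < min_n) {
      stop(sprintf("fewer than %d probes available for the %s set", min_n,
                   label))
    }
    sel
  }
  out <- list(channel = channel,
              fully_meth = pick(id[to_hi], d_hi[to_hi], "fully-methylated"),
              fully_unmeth = pick(id[!to_hi], d_lo[!to_hi],
                                  "fully-unmethylated"),
              k = k)
  class(out) <- "background_probe_sets"
  out
}

# median + normal-consistent MAD, or Tukey biweight alternatives
.robust_loc_scale <- function(v, estimator = c("median_mad", "biweight")) {
  estimator <- match.arg(estimator)
  v <- v[!is.na(v)]
  if (estimator == "median_mad") {
    c(mu = stats::median(v), sigma = stats::mad(v))   # constant = 1.4826
  } else {
    c(mu = .biweight_location(v), sigma = sqrt(.biweight_midvariance(v)))
  }
}

.biweight_location <- function(v, c_tune = 6, eps = 1e-8) {
  t0 <- stats::median(v)
  s <- stats::mad(v)
  if (s < eps) return(t0)
  for (i in 1:20) {
    u <- (v - t0) / (c_tune * s)
    w <- (1 - u^2)^2
    w[abs(u) >= 1] <- 0
    t1 <- sum(w * v) / sum(w)
    if (abs(t1 - t0) < eps * s) break
    t0 <- t1
  }
  t0
}

.biweight_midvariance <- function(v, c_tune = 9) {
  m <- stats::median(v)
  s <- stats::mad(v)
  if (s == 0) return(0)
  u <- (v - m) / (c_tune * s)
  keep <- abs(u) < 1
  n <- length(v)
  num <- n * sum(((v - m)^2 * (1 - u^2)^4)[keep])
  den <- sum(((1 - u^2) * (1 - 5 * u^2))[keep])^2
  num / den
}

.new_background_model <- function(method, grn, red, extra = list()) {
  out <- c(list(method = method,
                mu_grn = unname(grn["mu"]), sigma_grn = unname(grn["sigma"]),
                n_grn = unname(grn["n"]),
                mu_red = unname(red["mu"]), sigma_red = unname(red["sigma"]),
                n_red = unname(red["n"])),
           extra)
  class(out) <- "background_model"
  out
}

.check_bg_pool <- function(v, channel, method, min_n) {
  v <- v[!is.na(v)]
  if (length(v) < min_n) {
    stop(method, " background pool for channel ", channel, " has fewer than ",
         min_n, " observations")
  }
  v
}

#' Background model from non-specific fluorescence (NSP)
#'
#' Pools, per color channel, the in-band intensities of the silent alleles:
#' `U` of the fully-methylated probes and `M` of the fully-unmethylated
#' probes selected by [select_background_probes()]. These beads face a locus
#' whose complementary sequence is absent, so their fluorescence is
#' non-specific binding — real background signal, markedly higher than the
#' negative controls. Location and spread are robust (median and
#' 1.4826*MAD by default, normal-consistent).
#'
#' @param x a [sample_intensities] object.
#' @param manifest an [array_manifest].
#' @param sets_grn,sets_red `background_probe_sets` for the two channels.
#' @param min_n minimum pool size per channel (default 30).
#' @param estimator `"median_mad"` (default) or `"biweight"`.
#' @return object of class `background_model` with `method = "NSP"`,
#'   per-channel `mu`, `sigma`, `n`, and the subset sizes.
#' @export
estimate_background_nsp <- function(x, manifest, sets_grn, sets_red,
                                    min_n = 30,
                                    estimator = c("median_mad", "biweight")) {
  estimator <- match.arg(estimator)
  stopifnot(sets_grn$channel == "Grn", sets_red$channel == "Red")
  one_channel <- function(sets) {
    iu <- match(sets$fully_meth, x$probe_id)      # U bead silent when fully methylated
    im <- match(sets$fully_unmeth, x$probe_id)    # M bead silent when fully unmethylated
    pool <- .check_bg_pool(c(x$U[iu], x$M[im]), sets$channel, "NSP", min_n)
    est <- .robust_loc_scale(pool, estimator)
    if (est["sigma"] <= 0) {
      stop("zero background spread in channel ", sets$channel,
           "; constant background is not plausible")
    }
    c(est, n = length(pool))
  }
  .new_background_model(
    "NSP", one_channel(sets_grn), one_channel(sets_red),
    extra = list(k = sets_grn$k,
                 set_sizes = c(grn_meth = length(sets_grn$fully_meth),
                               grn_unmeth = length(sets_grn$fully_unmeth),
                               red_meth = length(sets_red$fully_meth),
                               red_unmeth = length(sets_red$fully_unmeth))))
}

#' Background model from negative control probes (NEG)
#'
#' The conventional approach: robust location and spread of the
#' negative-control intensities per color channel. Negative controls are
#' designed not to match the human genome and consequently sit at the very
#' low end of the fluorescence spectrum — below genuine non-specific
#' binding, which is why detection p-values derived from them are permissive.
#'
#' @inheritParams estimate_background_nsp
#' @return object of class `background_model` with `method = "NEG"`.
#' @export
estimate_background_neg <- function(x, min_n = 30,
                                    estimator = c("median_mad", "biweight")) {
  estimator <- match.arg(estimator)
  one_channel <- function(v, channel) {
    pool <- .check_bg_pool(v, channel, "NEG", min_n)
    est <- .robust_loc_scale(pool, estimator)
    if (est["sigma"] <= 0) {
      stop("zero background spread in channel ", channel,
           "; constant background is not plausible")
    }
    c(est, n = length(pool))
  }
  .new_background_model("NEG", one_channel(x$neg_grn, "Grn"),
                        one_channel(x$neg_red, "Red"))
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background_model [%s]\n", x$method))
  cat(sprintf("  Grn: mu = %.1f, sigma = %.1f (n = %d)\n",
              x$mu_grn, x$sigma_grn, as.integer(x$n_grn)))
  cat(sprintf("  Red: mu = %.1f, sigma = %.1f (n = %d)\n",
              x$mu_red, x$sigma_red, as.integer(x$n_red)))
  invisible(x)
}

#' Serialize a background model to JSON
#'
#' @param bg a `background_model`.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @export
background_model_json <- function(bg, path = NULL) {
  payload <- unclass(bg)
  if (is.null(path)) {
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Cross-talk diagnostic: out-of-band intensity ratios at silent vs. loud beads
#'
#' For Type I probes, the out-of-band channel should carry only background —
#' yet dye bound at a bright bead bleeds into the opposite channel (spectral
#' overlap). Among fully-unmethylated probes the U bead is bright, so the
#' ratio `median(oob at U beads) / median(oob at M beads)` exceeds 1 under
#' cross-talk; among fully-methylated probes the mirrored ratio
#' `median(oob at M) / median(oob at U)` does. Ratios near 1 indicate no
#' leakage.
#'
#' @param x a [sample_intensities] object.
#' @param manifest an [array_manifest].
#' @param probe_sets one `background_probe_sets` or a list of them (one per
#'   channel).
#' @return data.frame with one row per channel: `channel`, `unmeth_ratio`,
#'   `meth_ratio`, `n_unmeth`, `n_meth`.
#' @export
crosstalk_ratio <- function(x, manifest, probe_sets) {
  if (inherits(probe_sets, "background_probe_sets")) {
    probe_sets <- list(probe_sets)
  }
  one <- function(sets) {
    if (length(sets$fully_unmeth) == 0L || length(sets$fully_meth) == 0L) {
      stop("empty background probe set for channel ", sets$channel)
    }
    iu <- match(sets$fully_unmeth, x$probe_id)
    im <- match(sets$fully_meth, x$probe_id)
    if (all(is.na(x$oob_U[iu]))) {
      stop("no out-of-band intensities available for channel ", sets$channel)
    }
    data.frame(
      channel = sets$channel,
      unmeth_ratio = stats::median(x$oob_U[iu], na.rm = TRUE) /
        stats::median(x$oob_M[iu], na.rm = TRUE),
      meth_ratio = stats::median(x$oob_M[im], na.rm = TRUE) /
        stats::median(x$oob_U[im], na.rm = TRUE),
      n_unmeth = sum(!is.na(x$oob_U[iu])),
      n_meth = sum(!is.na(x$oob_M[im])),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(probe_sets, one))
}

#' One-call background estimation for a sample
#'
#' Convenience wrapper running the full NSP pipeline on a single sample:
#' per-channel beta-peak finding on the channel's Type I probes, selection of
#' the `k` probes closest to each peak, and robust pooling — or, for
#' `method = "NEG"`, the negative-control estimate.
#'
#' @param x a [sample_intensities] object.
#' @param manifest an [array_manifest].
#' @param method "NSP" or "NEG".
#' @param k probes per peak for NSP (default 1000).
#' @param offset beta offset (default 100).
#' @param min_n minimum pool size.
#' @param ... passed to [estimate_background_nsp()] / [estimate_background_neg()].
#' @return a `background_model`; for NSP the selected `probe_sets` and
#'   per-channel `peaks` are attached as attributes.
#' @export
estimate_background <- function(x, manifest, method = c("NSP", "NEG"),
                                k = 1000, offset = 100, min_n = 30, ...) {
  method <- match.arg(method)
  if (method == "NEG") return(estimate_background_neg(x, min_n = min_n, ...))
  beta <- compute_beta(x, offset = offset)
  a <- manifest[assay_rows(manifest), , drop = FALSE]
  sets <- lapply(c(Grn = "Grn", Red = "Red"), function(ch) {
    in_ch <- a$design == "I" & a$channel == ch
    peaks <- find_beta_peaks(beta[in_ch], min_n = min(1000, sum(in_ch)))
    list(peaks = peaks,
         sets = select_background_probes(beta, manifest, peaks, ch, k = k,
                                         min_n = min_n))
  })
  bg <- estimate_background_nsp(x, manifest, sets$Grn$sets, sets$Red$sets,
                                min_n = min_n, ...)
  attr(bg, "probe_sets") <- list(Grn = sets$Grn$sets, Red = sets$Red$sets)
  attr(bg, "peaks") <- list(Grn = sets$Grn$peaks, Red = sets$Red$peaks)
  bg
}
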