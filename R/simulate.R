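#' Simulation parameters for a synthetic Infinium-like array
#'
#' The generator states a small, explicit world that reproduces the
#' structural features detection p-values depend on: a bimodal methylation
#' distribution with genuine point masses of completely methylated and
#' completely unmethylated CpGs (so that "silent" allele beads carry pure
#' background), per-channel normal background noise with the non-specific
#' floor strictly above the negative-control floor, a mixture of Type I
#' (two beads, one channel) and Type II (one bead, two channels) designs,
#' linear cross-talk leakage into the out-of-band channel, sex-dependent
#' Y-chromosome signal (pure background in females), random dropouts, and
#' paired technical replicates with occasional injected large outliers —
#' some driven by background-level intensity (maskable by a detection
#' filter) and some not (a flipped methylation state at full signal).
#'
#' Defaults (fluorescence units): negative controls Grn N(300, 60^2) / Red
#' N(450, 75^2); non-specific background Grn N(450, 80^2) / Red
#' N(600, 100^2); signal lognormal(meanlog = log(5000), sdlog = 0.6);
#' methylation mixture P(m = 0) = 0.35, P(m = 1) = 0.45, remainder
#' Beta(2, 2); cross-talk lambda = 0.15; dropout rate 0.15%; replicate outlier
#' injection rate 0.2% with 30% of injected outliers intensity-driven. The
#' default array has 30000 autosomal, 600 X and 416 Y probes plus 600
#' negative controls, with design proportions I-Grn/I-Red/II =
#' 0.10/0.18/0.72. Signal variability is deliberately large relative to the
#' background spread, as on real arrays: the beta values of completely
#' (un)methylated sites then vary mostly through their signal level, so
#' picking the k sites closest to the beta peak does not condition on the
#' silent-bead background and the background spread stays recoverable.
#'
#' @param n_autosomal,n_x,n_y number of autosomal/X/Y CpG probes.
#' @param n_neg number of negative-control probes.
#' @param prop_design length-3 proportions (Type I Grn, Type I Red, Type II),
#'   summing to 1.
#' @param neg_grn,neg_red,nsp_grn,nsp_red length-2 `c(mu, sigma)` of the
#'   negative-control and non-specific background laws per channel;
#'   `mu_nsp >= mu_neg` is required in both channels.
#' @param signal length-2 `c(meanlog, sdlog)` of the lognormal full-signal
#'   law.
#' @param meth_mix length-2 `c(w_unmeth, w_meth)` point-mass weights at
#'   m = 0 and m = 1; the remainder is Beta(2, 2) intermediate methylation.
#' @param lambda cross-talk leakage coefficient in `[0, 1)`.
#' @param dropout_rate per-probe probability of a background-only dropout.
#' @param outlier_rate per-probe probability of an injected large outlier in
#'   a technical replicate.
#' @param outlier_maskable_fraction fraction of injected outliers driven by
#'   background-level intensity (catchable by a detection filter).
#' @param offset beta-value offset.
#' @return validated object of class `sim_params`.
#' @export
sim_params <- function(n_autosomal = 30000, n_x = 600, n_y = 416,
                       n_neg = 600,
                       prop_design = c(0.10, 0.18, 0.72),
                       neg_grn = c(300, 60), neg_red = c(450, 75),
                       nsp_grn = c(450, 80), nsp_red = c(600, 100),
                       signal = c(log(5000), 0.6),
                       meth_mix = c(0.35, 0.45),
                       lambda = 0.15,
                       dropout_rate = 0.0015,
                       outlier_rate = 0.002,
                       outlier_maskable_fraction = 0.3,
                       offset = 100) {
  p <- list(n_autosomal = n_autosomal, n_x = n_x, n_y = n_y, n_neg = n_neg,
            prop_design = prop_design,
            neg_grn = neg_grn, neg_red = neg_red,
            nsp_grn = nsp_grn, nsp_red = nsp_red,
            signal = signal, meth_mix = meth_mix, lambda = lambda,
            dropout_rate = dropout_rate, outlier_rate = outlier_rate,
            outlier_maskable_fraction = outlier_maskable_fraction,
            offset = offset)
  stopifnot(n_autosomal >= 0, n_x >= 0, n_y >= 0, n_neg >= 0)
  if (length(prop_design) != 3L || any(prop_design < 0) ||
      abs(sum(prop_design) - 1) > 1e-8) {
    stop("prop_design must be 3 non-negative proportions summing to 1")
  }
  for (nm in c("neg_grn", "neg_red", "nsp_grn", "nsp_red")) {
    v <- p[[nm]]
    if (length(v) != 2L || v[2] <= 0) {
      stop(nm, " must be c(mu, sigma) with sigma > 0")
    }
  }
  if (p$nsp_grn[1] < p$neg_grn[1] || p$nsp_red[1] < p$neg_red[1]) {
    stop("non-specific background mean must be >= negative-control mean")
  }
  stopifnot(length(signal) == 2L, signal[2] > 0)
  if (length(meth_mix) != 2L || any(meth_mix < 0) || sum(meth_mix) > 1) {
    stop("meth_mix point-mass weights must be non-negative and sum to <= 1")
  }
  stopifnot(lambda >= 0, lambda < 1,
            dropout_rate >= 0, dropout_rate <= 1,
            outlier_rate >= 0, outlier_rate <= 1,
            outlier_maskable_fraction >= 0, outlier_maskable_fraction <= 1,
            offset >= 0)
  class(p) <- "sim_params"
  p
}

#' Generate a synthetic array manifest
#'
#' Deterministic under a seed: CpG probes are numbered sequentially, design
#' types are assigned by shuffling fixed per-type counts (so proportions are
#' exact up to rounding), chromosomes cycle through 1..22 for the autosomal
#' block followed by the X and Y blocks, bead addresses are unique, and
#' negative controls are appended as chromosome-free single-bead probes.
#'
#' @param params a [sim_params] object.
#' @param seed optional integer seed.
#' @return an [array_manifest].
#' @export
simulate_manifest <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  n_cg <- params$n_autosomal + params$n_x + params$n_y
  if (n_cg < 1L) stop("need at least one CpG probe")
  counts <- floor(params$prop_design * n_cg)
  rem <- n_cg - sum(counts)
  if (rem > 0) {  # distribute rounding remainder to the largest strata
    ord <- order(params$prop_design * n_cg - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
  }
  if (any(counts == 0 & params$prop_design > 0)) {
    stop("infeasible design proportions for ", n_cg, " probes")
  }
  design_code <- sample(rep.int(c("IG", "IR", "II"), counts))
  chrom <- c(rep_len(as.character(1:22), params$n_autosomal),
             rep("X", params$n_x), rep("Y", params$n_y))

  probe_id <- sprintf("cg%08d", seq_len(n_cg))
  is1 <- design_code != "II"
  n_addr <- n_cg + sum(is1) + params$n_neg
  addr <- sprintf("A%07d", seq_len(n_addr))
  address_U <- addr[seq_len(n_cg)]
  address_M <- address_U
  address_M[is1] <- addr[n_cg + seq_len(sum(is1))]

  cg <- data.frame(
    probe_id = probe_id,
    design = ifelse(is1, "I", "II"),
    channel = c(IG = "Grn", IR = "Red", II = NA_character_)[design_code],
    address_U = address_U, address_M = address_M,
    chromosome = chrom, probe_class = "cg",
    stringsAsFactors = FALSE)

  if (params$n_neg > 0) {
    neg_addr <- addr[n_cg + sum(is1) + seq_len(params$n_neg)]
    neg <- data.frame(
      probe_id = sprintf("neg%05d", seq_len(params$n_neg)),
      design = "II", channel = NA_character_,
      address_U = neg_addr, address_M = neg_addr,
      chromosome = NA_character_, probe_class = "negative_control",
      stringsAsFactors = FALSE)
    cg <- rbind(cg, neg)
  }
  as_array_manifest(cg)
}

.rtrunc0 <- function(n, mu_sigma) {
  pmax(0, stats::rnorm(n, mu_sigma[1], mu_sigma[2]))
}

# One sample at the bead level. m/S may be supplied (technical replicates
# share them); forced_background / flip_m inject replicate outliers.
.sim_sample_core <- function(manifest, params, sex, sample_id,
                             m = NULL, S = NULL,
                             forced_background = NULL, flip_m = NULL) {
  a <- manifest[assay_rows(manifest), , drop = FALSE]
  n <- nrow(a)
  if (is.null(m)) {
    u <- stats::runif(n)
    m <- ifelse(u < params$meth_mix[1], 0,
                ifelse(u < sum(params$meth_mix), 1,
                       stats::rbeta(n, 2, 2)))
  }
  if (is.null(S)) {
    S <- stats::rlnorm(n, params$signal[1], params$signal[2])
  }
  if (!is.null(flip_m)) m[flip_m] <- 1 - m[flip_m]
  bg_only <- (!is.na(a$chromosome) & a$chromosome == "Y" & sex == "female") |
    (stats::runif(n) < params$dropout_rate)
  if (!is.null(forced_background)) bg_only <- bg_only | forced_background

  nsp <- list(Grn = params$nsp_grn, Red = params$nsp_red)
  neg <- list(Grn = params$neg_grn, Red = params$neg_red)
  grn <- red <- list()

  for (ch in c("Grn", "Red")) {
    i <- which(a$design == "I" & a$channel == ch)
    if (length(i) == 0L) next
    opp <- if (ch == "Grn") "Red" else "Grn"
    in_U <- (1 - m[i]) * S[i] + stats::rnorm(length(i), nsp[[ch]][1],
                                             nsp[[ch]][2])
    in_M <- m[i] * S[i] + stats::rnorm(length(i), nsp[[ch]][1], nsp[[ch]][2])
    bo <- bg_only[i]
    in_U[bo] <- stats::rnorm(sum(bo), nsp[[ch]][1], nsp[[ch]][2])
    in_M[bo] <- stats::rnorm(sum(bo), nsp[[ch]][1], nsp[[ch]][2])
    in_U <- pmax(0, in_U)
    in_M <- pmax(0, in_M)
    oob_U <- pmax(0, params$lambda * in_U +
                    stats::rnorm(length(i), neg[[opp]][1], neg[[opp]][2]))
    oob_M <- pmax(0, params$lambda * in_M +
                    stats::rnorm(length(i), neg[[opp]][1], neg[[opp]][2]))
    inb <- stats::setNames(c(in_U, in_M), c(a$address_U[i], a$address_M[i]))
    oob <- stats::setNames(c(oob_U, oob_M), c(a$address_U[i], a$address_M[i]))
    if (ch == "Grn") {
      grn <- c(grn, list(inb))
      red <- c(red, list(oob))
    } else {
      red <- c(red, list(inb))
      grn <- c(grn, list(oob))
    }
  }

  i2 <- which(a$design == "II")
  if (length(i2) > 0L) {
    g2 <- m[i2] * S[i2] + stats::rnorm(length(i2), nsp$Grn[1], nsp$Grn[2])
    r2 <- (1 - m[i2]) * S[i2] + stats::rnorm(length(i2), nsp$Red[1],
                                             nsp$Red[2])
    bo <- bg_only[i2]
    g2[bo] <- stats::rnorm(sum(bo), nsp$Grn[1], nsp$Grn[2])
    r2[bo] <- stats::rnorm(sum(bo), nsp$Red[1], nsp$Red[2])
    grn <- c(grn, list(stats::setNames(pmax(0, g2), a$address_U[i2])))
    red <- c(red, list(stats::setNames(pmax(0, r2), a$address_U[i2])))
  }

  neg_addr <- manifest$address_U[manifest$probe_class == "negative_control"]
  if (length(neg_addr) > 0L) {
    grn <- c(grn, list(stats::setNames(.rtrunc0(length(neg_addr),
                                                params$neg_grn), neg_addr)))
    red <- c(red, list(stats::setNames(.rtrunc0(length(neg_addr),
                                                params$neg_red), neg_addr)))
  }

  grn <- unlist(grn)
  red <- unlist(red)
  grn_df <- data.frame(address = names(grn), intensity = unname(grn),
                       stringsAsFactors = FALSE)
  red_df <- data.frame(address = names(red), intensity = unname(red),
                       stringsAsFactors = FALSE)
  attr(grn_df, "channel") <- "Grn"
  attr(red_df, "channel") <- "Red"

  truth <- data.frame(probe_id = a$probe_id, background_only = bg_only,
                      true_m = m, injected_outlier = "none",
                      stringsAsFactors = FALSE)
  if (!is.null(forced_background)) {
    truth$injected_outlier[forced_background] <- "maskable"
  }
  if (!is.null(flip_m)) truth$injected_outlier[flip_m] <- "unmaskable"

  list(intensities = load_sample(grn_df, red_df, manifest, sample_id),
       truth = truth, sex = sex, m = m, S = S)
}

#' Simulate one sample with ground truth
#'
#' Draws a methylation state and full-signal intensity per probe and emits
#' bead-level channel intensities per the manifest's design rules (see
#' [sim_params] for the generative model). In females every Y-chromosome
#' probe is background-only; an additional `dropout_rate` fraction of probes
#' is background-only in any sample.
#'
#' @param manifest an [array_manifest], typically from [simulate_manifest()].
#' @param params a [sim_params] object.
#' @param sex "male" or "female".
#' @param sample_id sample label.
#' @param seed optional integer seed.
#' @return list with `intensities` (a [sample_intensities]), `truth`
#'   (data.frame `probe_id`, `background_only`, `true_m`,
#'   `injected_outlier`), and `sex`.
#' @export
simulate_sample <- function(manifest, params, sex = c("female", "male"),
                            sample_id = "s1", seed = NULL) {
  sex <- match.arg(sex)
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  out <- .sim_sample_core(manifest, params, sex, sample_id)
  out[c("intensities", "truth", "sex")]
}

#' Simulate a cohort with optional technical replicate pairs
#'
#' Draws `n_male + n_female` independent samples; the first
#' `n_replicate_pairs` of them additionally get a technical replicate that
#' shares the biological methylation state and signal level but redraws all
#' measurement noise. Large outliers are injected into each replicate at
#' `outlier_rate`: a `outlier_maskable_fraction` share is *intensity-driven*
#' (the replicate's probe collapses to background level, so a detection
#' filter can catch it), the rest flips the methylation state at full signal
#' (invisible to any intensity-based filter) — mirroring the empirical
#' finding that a majority of large replicate outliers is not explained by
#' low fluorescence.
#'
#' @param manifest an [array_manifest].
#' @param params a [sim_params] object.
#' @param n_male,n_female samples per sex.
#' @param n_replicate_pairs technical replicate pairs (default 0).
#' @param seed optional integer seed governing all randomness.
#' @return object of class `sim_cohort`: list with `samples` (named list of
#'   [sample_intensities]), `truth` (named list of per-sample truth
#'   data.frames), `sample_table` (data.frame `sample_id`, `sex`,
#'   `replicate_of`), `manifest`, `params`, `seed`.
#' @export
simulate_cohort <- function(manifest, params, n_male, n_female,
                            n_replicate_pairs = 0, seed = NULL) {
  stopifnot(inherits(params, "sim_params"), n_male >= 0, n_female >= 0,
            n_male + n_female >= 1,
            n_replicate_pairs <= n_male + n_female)
  if (!is.null(seed)) set.seed(seed)
  sexes <- c(rep("male", n_male), rep("female", n_female))
  ids <- sprintf("%s%02d", ifelse(sexes == "male", "m", "f"),
                 c(seq_len(n_male), seq_len(n_female)))
  n_assay <- sum(assay_rows(manifest))

  samples <- list()
  truth <- list()
  tab <- data.frame(sample_id = character(), sex = character(),
                    replicate_of = character(), stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    s <- .sim_sample_core(manifest, params, sexes[i], ids[i])
    samples[[ids[i]]] <- s$intensities
    truth[[ids[i]]] <- s$truth
    tab <- rbind(tab, data.frame(sample_id = ids[i], sex = sexes[i],
                                 replicate_of = NA_character_,
                                 stringsAsFactors = FALSE))
    if (i <= n_replicate_pairs) {
      rid <- paste0(ids[i], "r")
      n_out <- stats::rbinom(1L, n_assay, params$outlier_rate)
      out_idx <- sample.int(n_assay, n_out)
      n_mask <- stats::rbinom(1L, n_out, params$outlier_maskable_fraction)
      forced <- flip <- rep(FALSE, n_assay)
      forced[out_idx[seq_len(n_mask)]] <- TRUE
      if (n_out > n_mask) flip[out_idx[(n_mask + 1):n_out]] <- TRUE
      r <- .sim_sample_core(manifest, params, sexes[i], rid,
                            m = s$m, S = s$S,
                            forced_background = forced, flip_m = flip)
      samples[[rid]] <- r$intensities
      truth[[rid]] <- r$truth
      tab <- rbind(tab, data.frame(sample_id = rid, sex = sexes[i],
                                   replicate_of = ids[i],
                                   stringsAsFactors = FALSE))
    }
  }
  out <- list(samples = samples, truth = truth, sample_table = tab,
              manifest = manifest, params = params, seed = seed)
  class(out) <- "sim_cohort"
  out
}

#' @export
print.sim_cohort <- function(x, ...) {
  tab <- x$sample_table
  cat(sprintf(
    "sim_cohort: %d samples (%d male, %d female, %d replicates), %d probes\n",
    nrow(tab), sum(tab$sex == "male" & is.na(tab$replicate_of)),
    sum(tab$sex == "female" & is.na(tab$replicate_of)),
    sum(!is.na(tab$replicate_of)), sum(assay_rows(x$manifest))))
  invisible(x)
}

#' Write a simulated cohort to disk / read it back
#'
#' Lays out a directory with `manifest.tsv` (minimal manifest dialect),
#' `samples.tsv` (sample id, sex, replicate pairing), `params.json`
#' (including the seed), per-sample channel tables `<id>_Grn.tsv` /
#' `<id>_Red.tsv` under `intensities/`, and per-sample ground-truth tables
#' under `truth/` — exactly the formats the readers of this package consume,
#' so a written cohort round-trips.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "intensities"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_manifest(cohort$manifest, file.path(dir, "manifest.tsv"))
  data.table::fwrite(cohort$sample_table, file.path(dir, "samples.tsv"),
                     sep = "\t", na = "NA", quote = FALSE)
  jsonlite::write_json(
    c(unclass(cohort$params), list(seed = cohort$seed)),
    file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA)
  for (id in names(cohort$samples)) {
    s <- cohort$samples[[id]]
    chans <- .sample_to_channels(s, cohort$manifest)
    write_channel_table(chans$grn,
                        file.path(dir, "intensities",
                                  paste0(id, "_Grn.tsv")), "Grn")
    write_channel_table(chans$red,
                        file.path(dir, "intensities",
                                  paste0(id, "_Red.tsv")), "Red")
    data.table::fwrite(cohort$truth[[id]],
                       file.path(dir, "truth", paste0(id, "_truth.tsv")),
                       sep = "\t", quote = FALSE)
  }
  invisible(dir)
}

# invert load_sample(): rebuild the two address-keyed channel tables
.sample_to_channels <- function(x, manifest) {
  a <- manifest[assay_rows(manifest), , drop = FALSE]
  g <- r <- list()
  ig <- a$design == "I" & a$channel == "Grn"
  ir <- a$design == "I" & a$channel == "Red"
  i2 <- a$design == "II"
  g$inb <- stats::setNames(c(x$U[ig], x$M[ig]),
                           c(a$address_U[ig], a$address_M[ig]))
  g$oob <- stats::setNames(c(x$oob_U[ir], x$oob_M[ir]),
                           c(a$address_U[ir], a$address_M[ir]))
  g$t2 <- stats::setNames(x$M[i2], a$address_U[i2])
  r$inb <- stats::setNames(c(x$U[ir], x$M[ir]),
                           c(a$address_U[ir], a$address_M[ir]))
  r$oob <- stats::setNames(c(x$oob_U[ig], x$oob_M[ig]),
                           c(a$address_U[ig], a$address_M[ig]))
  r$t2 <- stats::setNames(x$U[i2], a$address_U[i2])
  neg_addr <- manifest$address_U[manifest$probe_class == "negative_control"]
  g$neg <- stats::setNames(x$neg_grn, neg_addr)
  r$neg <- stats::setNames(x$neg_red, neg_addr)
  gv <- unlist(g)
  rv <- unlist(r)
  # unlist() prefixes list names; recover bare addresses
  gn <- sub("^[a-z0-9]+\\.", "", names(gv))
  rn <- sub("^[a-z0-9]+\\.", "", names(rv))
  keep_g <- !is.na(gv)
  keep_r <- !is.na(rv)
  list(grn = data.frame(address = gn[keep_g], intensity = unname(gv[keep_g]),
                        stringsAsFactors = FALSE),
       red = data.frame(address = rn[keep_r], intensity = unname(rv[keep_r]),
                        stringsAsFactors = FALSE))
}

#' @rdname write_cohort
#' @param manifest optional manifest to use instead of `dir/manifest.tsv`.
#' @return `read_cohort()`: list with `manifest`, `samples` (named list of
#'   [sample_intensities]), `sample_table`, and `truth` (if present).
#' @export
read_cohort <- function(dir, manifest = NULL) {
  if (is.null(manifest)) {
    manifest <- read_manifest(file.path(dir, "manifest.tsv"))
  }
  tab <- data.table::fread(file.path(dir, "samples.tsv"), data.table = FALSE,
                           na.strings = "NA", colClasses = "character")
  samples <- lapply(tab$sample_id, function(id) {
    load_sample(file.path(dir, "intensities", paste0(id, "_Grn.tsv")),
                file.path(dir, "intensities", paste0(id, "_Red.tsv")),
                manifest, sample_id = id)
  })
  names(samples) <- tab$sample_id
  truth_files <- file.path(dir, "truth", paste0(tab$sample_id, "_truth.tsv"))
  truth <- NULL
  if (all(file.exists(truth_files))) {
    truth <- lapply(truth_files, data.table::fread, data.table = FALSE)
    names(truth) <- tab$sample_id
  }
  list(manifest = manifest, samples = samples, sample_table = tab,
       truth = truth)
}
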