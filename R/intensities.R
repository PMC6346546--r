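#' Per-sample intensity objects
#'
#' A `sample_intensities` object carries, aligned to the assay probes of a
#' manifest (negative controls are kept separately): the in-band unmethylated
#' (`U`) and methylated (`M`) fluorescence intensities, the out-of-band
#' intensities `oob_U`/`oob_M` (Type I probes only: the opposite color
#' channel measured at the same beads, `NA` for Type II), and the
#' negative-control intensities per channel. Intensities are non-negative or
#' `NA` (bead address absent from the scan).
#'
#' @name sample_intensities
NULL

#' Read / write a single-channel intensity table
#'
#' The dependency-free intensity dialect is a TSV with columns `address` and
#' `intensity`, one file per color channel, preceded by a comment line
#' `# channel=Grn` (or `Red`) declaring which channel was scanned. The
#' declaration lets [load_sample()] catch swapped green/red arguments, which
#' would otherwise silently corrupt every Type II probe.
#'
#' @param path file path.
#' @return data.frame with columns `address`, `intensity` and attribute
#'   `channel` (`NA` if the file carries no declaration).
#' @export
read_channel_table <- function(path) {
  first <- readLines(path, n = 1L)
  channel <- NA_character_
  if (startsWith(first, "#")) {
    hit <- regmatches(first, regexec("channel\\s*=\\s*(Grn|Red)", first))[[1]]
    if (length(hit) == 2L) channel <- hit[2]
  }
  df <- data.table::fread(path, skip = if (startsWith(first, "#")) 1L else 0L,
                          colClasses = list(character = "address"),
                          data.table = FALSE)
  if (!all(c("address", "intensity") %in% names(df))) {
    stop("channel table must have columns 'address' and 'intensity': ", path)
  }
  attr(df, "channel") <- channel
  df
}

#' @rdname read_channel_table
#' @param df data.frame with columns `address`, `intensity`.
#' @param channel "Grn" or "Red", written as the metadata comment line.
#' @export
write_channel_table <- function(df, path, channel) {
  channel <- match.arg(channel, c("Grn", "Red"))
  out <- df[c("address", "intensity")]
  # %.17g guarantees the doubles survive the text round-trip bit-exactly
  out$intensity <- sprintf("%.17g", out$intensity)
  writeLines(sprintf("# channel=%s", channel), path)
  data.table::fwrite(out, path, sep = "\t", append = TRUE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

.as_channel_df <- function(x, which) {
  if (is.character(x) && length(x) == 1L) x <- read_channel_table(x)
  if (!is.data.frame(x) || !all(c("address", "intensity") %in% names(x))) {
    stop(which, " source must be a path or a data.frame with columns ",
         "'address' and 'intensity'")
  }
  x$address <- as.character(x$address)
  x
}

#' Resolve raw channel intensities into per-probe U/M/out-of-band values
#'
#' Maps the two scanned color channels onto the manifest's design rules:
#' Type I Grn probes read both alleles in green (out-of-band = red at the
#' same beads); Type I Red probes mirror that; Type II probes read M in green
#' and U in red at their single shared bead. Negative-control addresses are
#' collected per channel. An address listed in the manifest but absent from a
#' channel table yields `NA` intensities for that probe (reported via
#' `message()`, not fatal); a green/red channel declaration that contradicts
#' the argument order is fatal.
#'
#' @param grn_source,red_source path to a channel table (see
#'   [read_channel_table()]) or an equivalent data.frame; an attribute or
#'   metadata line `channel=` is checked against the argument slot.
#' @param manifest an [array_manifest].
#' @param sample_id sample label stored in the result.
#' @return a [sample_intensities] object: list with `sample_id`, `probe_id`,
#'   `U`, `M`, `oob_U`, `oob_M`, `neg_grn`, `neg_red`.
#' @export
load_sample <- function(grn_source, red_source, manifest,
                        sample_id = "sample") {
  validate_manifest(manifest)
  grn <- .as_channel_df(grn_source, "grn")
  red <- .as_channel_df(red_source, "red")
  for (chk in list(list(attr(grn, "channel"), "Grn", "grn_source"),
                   list(attr(red, "channel"), "Red", "red_source"))) {
    declared <- chk[[1]]
    if (!is.null(declared) && !is.na(declared) && declared != chk[[2]]) {
      stop("channel mismatch: ", chk[[3]], " declares channel '", declared,
           "' — green/red inputs appear swapped")
    }
  }
  g <- stats::setNames(grn$intensity, grn$address)
  r <- stats::setNames(red$intensity, red$address)
  if (any(g < 0, na.rm = TRUE) || any(r < 0, na.rm = TRUE)) {
    stop("negative fluorescence intensities in input")
  }

  a <- manifest[assay_rows(manifest), , drop = FALSE]
  n <- nrow(a)
  U <- M <- oob_U <- oob_M <- rep(NA_real_, n)

  ig <- which(a$design == "I" & a$channel == "Grn")
  U[ig] <- g[a$address_U[ig]]
  M[ig] <- g[a$address_M[ig]]
  oob_U[ig] <- r[a$address_U[ig]]
  oob_M[ig] <- r[a$address_M[ig]]

  ir <- which(a$design == "I" & a$channel == "Red")
  U[ir] <- r[a$address_U[ir]]
  M[ir] <- r[a$address_M[ir]]
  oob_U[ir] <- g[a$address_U[ir]]
  oob_M[ir] <- g[a$address_M[ir]]

  i2 <- which(a$design == "II")
  M[i2] <- g[a$address_U[i2]]
  U[i2] <- r[a$address_U[i2]]

  n_miss <- sum(is.na(U) | is.na(M))
  if (n_miss > 0L) {
    message(sprintf("%s: %d probe(s) with bead address missing from data",
                    sample_id, n_miss))
  }

  neg_addr <- manifest$address_U[manifest$probe_class == "negative_control"]
  out <- list(sample_id = sample_id, probe_id = a$probe_id,
              U = unname(U), M = unname(M),
              oob_U = unname(oob_U), oob_M = unname(oob_M),
              neg_grn = unname(g[neg_addr]), neg_red = unname(r[neg_addr]))
  class(out) <- "sample_intensities"
  out
}

#' @export
print.sample_intensities <- function(x, ...) {
  cat(sprintf("sample_intensities '%s': %d probes (%d missing), %d/%d negative controls (Grn/Red)\n",
              x$sample_id, length(x$probe_id), sum(is.na(x$U) | is.na(x$M)),
              sum(!is.na(x$neg_grn)), sum(!is.na(x$neg_red))))
  invisible(x)
}

#' Total fluorescence intensity
#'
#' `T = U + M` per probe; the total is largely independent of the
#' methylation level and is the statistic tested against the background
#' distribution. Missing where either allele intensity is missing.
#'
#' @param x a [sample_intensities] object.
#' @return numeric vector aligned to `x$probe_id`.
#' @export
total_intensity <- function(x) x$U + x$M

#' Methylation beta values
#'
#' `beta = M / (M + U + offset)`. The additive offset (default 100, the
#' widespread platform convention) stabilizes the ratio at low intensities;
#' with `offset = 0` and both intensities zero the value is defined as 0.
#'
#' @param x a [sample_intensities] object, or a numeric vector of methylated
#'   intensities (then `U` must be supplied).
#' @param U unmethylated intensities when `x` is a bare numeric vector.
#' @param offset non-negative additive constant in the denominator.
#' @return numeric vector in `[0, 1]`, `NA` where either intensity is `NA`.
#' @export
compute_beta <- function(x, U = NULL, offset = 100) {
  if (length(offset) != 1L || is.na(offset) || offset < 0) {
    stop("offset must be a single non-negative number")
  }
  if (inherits(x, "sample_intensities")) {
    M <- x$M
    U <- x$U
  } else {
    M <- x
    if (is.null(U)) stop("U intensities required when x is a numeric vector")
  }
  denom <- M + U + offset
  beta <- ifelse(denom > 0, M / denom, 0)
  beta[is.na(M) | is.na(U)] <- NA_real_
  beta
}

#' Assemble per-sample vectors into probe-by-sample matrices
#'
#' @param samples list of [sample_intensities] objects sharing one manifest.
#' @param fun function mapping one sample to a numeric vector (for example
#'   [compute_beta()] or [total_intensity()]).
#' @param ... passed on to `fun`.
#' @return numeric matrix, rownames probe ids, colnames sample ids.
#' @export
sample_matrix <- function(samples, fun, ...) {
  stopifnot(length(samples) > 0L)
  vals <- lapply(samples, fun, ...)
  out <- do.call(cbind, vals)
  rownames(out) <- samples[[1]]$probe_id
  colnames(out) <- vapply(samples, function(s) s$sample_id, character(1))
  out
}

#' Write a probe-by-sample matrix as TSV
#'
#' @param m numeric matrix with probe-id rownames.
#' @param path output file.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- data.table::fread(path, data.table = FALSE, na.strings = "NA")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
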