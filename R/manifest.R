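#' Array manifest objects
#'
#' An `array_manifest` is a `data.frame` (one row per probe) describing an
#' Infinium-style methylation array: probe identifier, Infinium design type,
#' color channel (Type I only), bead addresses for the unmethylated (U) and
#' methylated (M) alleles, chromosome, and probe class. Type I probes use two
#' separate beads read in a single color channel; Type II probes use one bead
#' read in both channels, so their two addresses coincide and they carry no
#' design channel. Negative control probes target no genomic locus and have no
#' chromosome.
#'
#' Columns: `probe_id` (character, unique), `design` ("I" or "II"),
#' `channel` ("Grn"/"Red" for Type I, `NA` for Type II), `address_U`,
#' `address_M` (character bead addresses), `chromosome` (canonical
#' "1".."22", "X", "Y", or `NA`), `probe_class` ("cg", "ch", "rs",
#' "negative_control").
#'
#' @name array_manifest
NULL

MANIFEST_COLS <- c("probe_id", "design", "channel", "address_U", "address_M",
                   "chromosome", "probe_class")

CANONICAL_CHROMS <- c(as.character(1:22), "X", "Y")

#' Normalize chromosome labels
#'
#' Strips any "chr" prefix and upper-cases X/Y so that manifests from
#' different dialects agree on "1".."22", "X", "Y". Unrecognized labels are
#' kept as-is (upper-cased) so callers can decide how to treat e.g. "MT".
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector of normalized labels (`NA` stays `NA`).
#' @export
normalize_chromosome <- function(chrom) {
  chrom <- as.character(chrom)
  chrom[!is.na(chrom) & chrom == ""] <- NA_character_
  out <- sub("^chr", "", chrom, ignore.case = TRUE)
  out <- toupper(out)
  out
}

#' Construct and validate an array manifest
#'
#' @param df data.frame with the columns documented in [array_manifest].
#' @return validated `array_manifest` object.
#' @export
as_array_manifest <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(MANIFEST_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- df[MANIFEST_COLS]
  df$probe_id <- as.character(df$probe_id)
  df$design <- as.character(df$design)
  df$channel <- as.character(df$channel)
  df$channel[!is.na(df$channel) & df$channel == ""] <- NA_character_
  df$address_U <- as.character(df$address_U)
  df$address_M <- as.character(df$address_M)
  df$chromosome <- normalize_chromosome(df$chromosome)
  df$probe_class <- as.character(df$probe_class)
  rownames(df) <- NULL
  class(df) <- c("array_manifest", "data.frame")
  validate_manifest(df)
  df
}

#' @rdname as_array_manifest
#' @param manifest object to validate.
#' @export
validate_manifest <- function(manifest) {
  m <- manifest
  if (anyNA(m$probe_id)) stop("manifest contains missing probe ids")
  if (anyDuplicated(m$probe_id)) {
    dup <- unique(m$probe_id[duplicated(m$probe_id)])
    stop("duplicate probe ids in manifest: ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  ok_class <- m$probe_class %in% c("cg", "ch", "rs", "negative_control")
  if (!all(ok_class)) {
    stop("unknown probe_class value(s): ",
         paste(unique(m$probe_class[!ok_class]), collapse = ", "))
  }
  if (!all(m$design %in% c("I", "II"))) {
    stop("unparseable design code(s): ",
         paste(unique(setdiff(m$design, c("I", "II"))), collapse = ", "))
  }
  i1 <- m$design == "I"
  if (any(i1 & (is.na(m$channel) | !(m$channel %in% c("Grn", "Red"))))) {
    stop("Type I probes must declare channel 'Grn' or 'Red'")
  }
  if (any(i1 & m$address_U == m$address_M)) {
    stop("Type I probes must have distinct U and M bead addresses")
  }
  i2 <- m$design == "II"
  if (any(i2 & !is.na(m$channel))) {
    stop("Type II probes must not declare a color channel")
  }
  if (any(i2 & m$address_U != m$address_M)) {
    stop("Type II probes must share a single bead address for U and M")
  }
  neg <- m$probe_class == "negative_control"
  if (any(neg & !is.na(m$chromosome))) {
    stop("negative control probes must have no chromosome")
  }
  chrom <- m$chromosome[!neg & !is.na(m$chromosome)]
  bad <- setdiff(unique(chrom), CANONICAL_CHROMS)
  if (length(bad) > 0L) {
    stop("non-canonical chromosome label(s): ", paste(bad, collapse = ", "))
  }
  invisible(manifest)
}

#' Read an array manifest
#'
#' Two dialects are supported and auto-detected from the header:
#' \describe{
#'   \item{minimal TSV}{tab-separated with the columns of [array_manifest]
#'     (`probe_id`, `design`, `channel`, `address_U`, `address_M`,
#'     `chromosome`, `probe_class`). Empty channel/chromosome fields read as
#'     `NA`.}
#'   \item{Illumina-style CSV}{comma-separated with columns `IlmnID`,
#'     `Infinium_Design_Type` ("I"/"II"), `Color_Channel` ("Grn"/"Red" or
#'     empty), `AddressA_ID` (U bead; sole bead for Type II), `AddressB_ID`
#'     (M bead, empty for Type II), `CHR`. The probe class is derived from
#'     the id prefix (cg/ch/rs); rows whose id starts with "NEGATIVE" or
#'     whose optional `Probe_Class` column says so become negative controls.}
#' }
#' Chromosome labels are normalized (any "chr" prefix stripped, X/Y
#' upper-cased).
#'
#' @param path path to the manifest file.
#' @return an [array_manifest].
#' @export
read_manifest <- function(path) {
  hdr <- names(data.table::fread(path, nrows = 0L))
  if (all(MANIFEST_COLS %in% hdr)) {
    df <- data.table::fread(path, colClasses = "character",
                            na.strings = c("", "NA"), data.table = FALSE)
    return(as_array_manifest(df))
  }
  ilmn <- c("IlmnID", "Infinium_Design_Type", "AddressA_ID")
  if (all(ilmn %in% hdr)) {
    raw <- data.table::fread(path, colClasses = "character",
                             na.strings = c("", "NA"), data.table = FALSE)
    return(as_array_manifest(.from_illumina(raw)))
  }
  stop("unrecognized manifest dialect; expected columns ",
       paste(MANIFEST_COLS, collapse = "/"), " or Illumina-style IlmnID/...")
}

.from_illumina <- function(raw) {
  id <- raw$IlmnID
  cls <- rep(NA_character_, length(id))
  cls[startsWith(id, "cg")] <- "cg"
  cls[startsWith(id, "ch")] <- "ch"
  cls[startsWith(id, "rs")] <- "rs"
  if (!is.null(raw$Probe_Class)) {
    cls[!is.na(raw$Probe_Class) &
          tolower(raw$Probe_Class) == "negative_control"] <- "negative_control"
  }
  cls[is.na(cls) & startsWith(toupper(id), "NEGATIVE")] <- "negative_control"
  if (anyNA(cls)) {
    stop("cannot derive probe class for id(s): ",
         paste(utils::head(id[is.na(cls)], 5L), collapse = ", "))
  }
  design <- raw$Infinium_Design_Type
  addr_u <- raw$AddressA_ID
  addr_m <- ifelse(design == "II" | is.na(raw$AddressB_ID),
                   raw$AddressA_ID, raw$AddressB_ID)
  chrom <- if (is.null(raw$CHR)) rep(NA_character_, length(id)) else raw$CHR
  chrom[cls == "negative_control"] <- NA_character_
  data.frame(probe_id = id, design = design,
             channel = if (is.null(raw$Color_Channel))
               rep(NA_character_, length(id)) else raw$Color_Channel,
             address_U = addr_u, address_M = addr_m,
             chromosome = chrom, probe_class = cls,
             stringsAsFactors = FALSE)
}

#' Write an array manifest in the minimal TSV dialect
#'
#' @param manifest an [array_manifest].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  data.table::fwrite(as.data.frame(manifest), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

# rows that interrogate a CpG/CpH/SNP locus (everything but controls)
assay_rows <- function(manifest) manifest$probe_class != "negative_control"

#' @export
print.array_manifest <- function(x, ...) {
  n_assay <- sum(assay_rows(x))
  cat(sprintf(
    "array_manifest: %d probes (%d assay, %d negative controls)\n",
    nrow(x), n_assay, nrow(x) - n_assay))
  cat(sprintf("  design: I-Grn %d, I-Red %d, II %d\n",
              sum(x$design == "I" & x$channel == "Grn", na.rm = TRUE),
              sum(x$design == "I" & x$channel == "Red", na.rm = TRUE),
              sum(x$design == "II" & assay_rows(x))))
  chr <- x$chromosome[assay_rows(x)]
  cat(sprintf("  chromosomes: %d autosomal, %d X, %d Y\n",
              sum(chr %in% as.character(1:22), na.rm = TRUE),
              sum(chr == "X", na.rm = TRUE), sum(chr == "Y", na.rm = TRUE)))
  invisible(x)
}
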