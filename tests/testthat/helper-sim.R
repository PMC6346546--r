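# Shared fixtures: a small simulated array keeps the unit tests fast; the
# acceptance suite builds larger cohorts itself.

tiny_params <- function(...) {
  sim_params(n_autosomal = 3000, n_x = 100, n_y = 50, n_neg = 200, ...)
}

tiny_manifest <- function(seed = 42, params = tiny_params()) {
  simulate_manifest(params, seed = seed)
}

# the 6-probe minimal manifest from inst/extdata
mini_manifest_path <- function() {
  system.file("extdata", "manifest_mini.tsv", package = "methdetect")
}

# hand-built manifest: n Type I probes in one channel plus negative controls
flat_manifest <- function(n = 40, channel = "Grn", n_neg = 0) {
  df <- data.frame(
    probe_id = sprintf("cg%06d", seq_len(n)),
    design = "I", channel = channel,
    address_U = sprintf("U%05d", seq_len(n)),
    address_M = sprintf("M%05d", seq_len(n)),
    chromosome = "1", probe_class = "cg",
    stringsAsFactors = FALSE)
  if (n_neg > 0) {
    df <- rbind(df, data.frame(
      probe_id = sprintf("neg%04d", seq_len(n_neg)),
      design = "II", channel = NA_character_,
      address_U = sprintf("N%05d", seq_len(n_neg)),
      address_M = sprintf("N%05d", seq_len(n_neg)),
      chromosome = NA_character_, probe_class = "negative_control",
      stringsAsFactors = FALSE))
  }
  as_array_manifest(df)
}

# minimal background model for direct detection tests
bg_model <- function(mu_grn = 500, sigma_grn = 100, mu_red = 600,
                     sigma_red = 120, method = "NSP") {
  structure(list(method = method, mu_grn = mu_grn, sigma_grn = sigma_grn,
                 n_grn = 1000, mu_red = mu_red, sigma_red = sigma_red,
                 n_red = 1000),
            class = "background_model")
}

# sample_intensities wrapper for hand-made vectors
make_intens <- function(manifest, U, M, oob_U = NULL, oob_M = NULL,
                        neg_grn = numeric(), neg_red = numeric(),
                        sample_id = "t1") {
  a <- manifest[manifest$probe_class != "negative_control", , drop = FALSE]
  n <- nrow(a)
  structure(list(sample_id = sample_id, probe_id = a$probe_id,
                 U = U, M = M,
                 oob_U = if (is.null(oob_U)) rep(NA_real_, n) else oob_U,
                 oob_M = if (is.null(oob_M)) rep(NA_real_, n) else oob_M,
                 neg_grn = neg_grn, neg_red = neg_red),
            class = "sample_intensities")
}
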