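# hand-built p matrix: 3 Y probes + 2 autosomal, 5 samples (3 F, 2 M)
toy_y_setup <- function() {
  man <- as_array_manifest(data.frame(
    probe_id = c("y1", "y2", "y3", "a1", "a2"),
    design = "II", channel = NA_character_,
    address_U = sprintf("A%d", 1:5), address_M = sprintf("A%d", 1:5),
    chromosome = c("Y", "Y", "Y", "1", "2"), probe_class = "cg",
    stringsAsFactors = FALSE))
  p <- rbind(
    y1 = c(0.001, 0.20, 0.001, 0.001, 0.001),
    y2 = c(0.50, 0.60, 0.009, 0.002, 0.001),
    y3 = c(0.70, 0.80, 0.90, 0.003, 0.004),
    a1 = c(0.001, 0.001, 0.001, 0.001, 0.001),
    a2 = c(0.20, 0.001, 0.001, 0.001, 0.001))
  colnames(p) <- c("f1", "f2", "f3", "m1", "m2")
  sex <- c(f1 = "female", f2 = "female", f3 = "female",
           m1 = "male", m2 = "male")
  list(man = man, p = p, sex = sex)
}

test_that("y_benchmark counts, percentiles and call rates match by hand", {
  s <- toy_y_setup()
  yb <- y_benchmark(s$p, s$man, s$sex, cutoffs = 0.01)
  # detected-Y counts per sample at 0.01: f1=1, f2=0, f3=2, m1=3, m2=3
  expect_equal(unname(yb$counts[, 1]), c(1, 0, 2, 3, 3))
  sm <- yb$summary
  expect_equal(sm$median[sm$sex == "female"], 1)
  expect_equal(sm$median[sm$sex == "male"], 3)
  # inclusive linear-interpolation percentiles on the female counts {0,1,2}
  expect_equal(sm$q025[sm$sex == "female"],
               unname(quantile(c(1, 0, 2), 0.025, type = 7)))
  expect_equal(sm$q975[sm$sex == "female"],
               unname(quantile(c(1, 0, 2), 0.975, type = 7)))
  # female call rates: y1 = 2/3, y2 = 1/3, y3 = 0
  expect_equal(unname(yb$call_rate[, 1]), c(2 / 3, 1 / 3, 0))
  expect_identical(yb$classification[[1]]$low, "y3")
  expect_length(yb$classification[[1]]$high, 0)
  expect_equal(yb$n_y, 3)
})

test_that("y_benchmark validates its inputs", {
  s <- toy_y_setup()
  expect_error(y_benchmark(s$p, s$man, c(s$sex[-5], m2 = "unknown")),
               "unknown sex")
  noy <- s$man[s$man$chromosome %in% c("1", "2"), ]
  expect_error(y_benchmark(s$p, noy, s$sex), "no Y-chromosome probes")
  expect_error(y_benchmark(s$p, s$man, s$sex, cutoffs = numeric()), "empty")
  # named labels are realigned to column order
  yb1 <- y_benchmark(s$p, s$man, s$sex, cutoffs = 0.01)
  yb2 <- y_benchmark(s$p, s$man, rev(s$sex), cutoffs = 0.01)
  expect_identical(yb1$summary, yb2$summary)
})

test_that("call-rate classification is invariant to sample order", {
  s <- toy_y_setup()
  perm <- c("m2", "f3", "f1", "m1", "f2")
  yb1 <- y_benchmark(s$p, s$man, s$sex, cutoffs = 0.01)
  yb2 <- y_benchmark(s$p[, perm], s$man, s$sex[perm], cutoffs = 0.01)
  expect_identical(yb1$classification, yb2$classification)
  expect_equal(yb1$call_rate, yb2$call_rate)
})

test_that("a single-cutoff sweep reduces to the plain benchmark", {
  s <- toy_y_setup()
  sw <- cutoff_sweep(s$p, s$man, s$sex, cutoffs = 0.01)
  yb <- y_benchmark(s$p, s$man, s$sex, cutoffs = 0.01)
  expect_identical(sw$y$summary, yb$summary)
  expect_identical(sw$undetected$n_undetected,
                   undetected_counts(s$p, s$man, 0.01)$n_undetected)
})

test_that("default sweep grids span the published cut-off ranges", {
  neg <- default_cutoff_grid("neg")
  nsp <- default_cutoff_grid("nsp")
  expect_equal(max(neg), 1)
  expect_equal(min(neg), 1e-80)
  expect_equal(max(nsp), 1)
  expect_equal(min(nsp), 1e-3)
  expect_true(all(diff(neg) < 0) && all(diff(nsp) < 0))
})

test_that("detected counts are monotone non-increasing in the cutoff", {
  params <- tiny_params()
  man <- tiny_manifest(params = params)
  co <- simulate_cohort(man, params, n_male = 2, n_female = 2, seed = 91)
  p <- detection_p_matrix(co$samples, man, "NSP", k = 100)
  sex <- setNames(co$sample_table$sex, co$sample_table$sample_id)
  grid <- 10^seq(0, -3, length.out = 10)
  sw <- cutoff_sweep(p, man, sex, cutoffs = grid)
  for (sexi in c("male", "female")) {
    med <- sw$y$summary$median[sw$y$summary$sex == sexi]
    expect_true(all(diff(med) <= 0))  # grid is decreasing in cutoff
  }
  # oracle: recount detected Y probes directly at each cutoff
  yp <- p[rownames(p) %in% man$probe_id[!is.na(man$chromosome) &
                                          man$chromosome == "Y"], ]
  for (i in c(1, 5, 10)) {
    expect_equal(unname(sw$y$counts[, i]), unname(colSums(yp < grid[i])))
  }
  # undetected counts grow as the cutoff shrinks
  u <- sw$undetected
  for (id in colnames(p)) {
    expect_true(all(diff(u$n_undetected[u$sample_id == id]) >= 0))
  }
})

test_that("replicate concordance matches a brute-force count", {
  # constructed 10-probe pair; outliers are the |diff| > 0.2 positions
  beta_a <- c(0.50, 0.50, 0.50, 0.50, 0.50, 0.50, 0.50, 0.50, 0.50, 0.50)
  dbeta <- c(0.00, 0.05, 0.10, 0.15, 0.22, 0.25, 0.30, 0.01, 0.02, 0.03)
  beta_b <- beta_a + dbeta
  p_a <- rep(0.001, 10)
  p_b <- rep(0.001, 10)
  p_b[c(5, 6, 7)] <- 0.5        # the three outliers are undetected in b
  rep_ <- replicate_concordance(beta_a, beta_b, p_a, p_b, cutoff = 0.01)
  expect_equal(rep_$n_outliers, sum(dbeta > 0.2))
  expect_equal(rep_$n_outliers_masked, 3)
  expect_equal(rep_$masked_fraction, 1)
  expect_equal(rep_$median_absdiff_detected,
               median(dbeta[-c(5, 6, 7)]))
  expect_equal(rep_$median_absdiff_other, median(dbeta[c(5, 6, 7)]))
  # default threshold is the 20-percentage-point rule
  expect_equal(formals(replicate_concordance)$outlier_threshold, 0.20)
  # partially masked outliers: detected pairs among the outliers stay
  p_b2 <- rep(0.001, 10)
  p_b2[5] <- 0.5
  rep2 <- replicate_concordance(beta_a, beta_b, p_a, p_b2, cutoff = 0.01)
  expect_equal(rep2$n_outliers_masked, 1)
  expect_equal(rep2$masked_fraction, 1 / 3)
})

test_that("replicate edge cases behave: identity, missingness, errors", {
  beta <- runif(20)
  p <- rep(0.001, 20)
  r <- replicate_concordance(beta, beta, p, p)
  expect_equal(r$median_absdiff_detected, 0)
  expect_equal(r$n_outliers, 0)
  expect_true(is.na(r$masked_fraction))
  expect_error(replicate_concordance(rep(NA_real_, 20), beta, p, p),
               "all probes missing")
  expect_error(replicate_concordance(beta, beta, p, p,
                                     outlier_threshold = 1.2),
               "outlier_threshold")
})
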