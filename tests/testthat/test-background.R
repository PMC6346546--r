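test_that("beta peaks of a bimodal mixture are located at the modes", {
  set.seed(101)
  b <- ifelse(runif(10000) < 0.5, rnorm(10000, 0.15, 0.05),
              rnorm(10000, 0.85, 0.05))
  b <- pmin(1, pmax(0, b))
  peaks <- find_beta_peaks(b)
  # independent oracle: argmax of a fine-grid KDE per half
  d <- density(b, n = 4096, from = 0, to = 1)
  lo <- d$x[d$x < 0.5][which.max(d$y[d$x < 0.5])]
  hi <- d$x[d$x >= 0.5][which.max(d$y[d$x >= 0.5])]
  expect_equal(peaks$peak_lo, lo, tolerance = 0.01)
  expect_equal(peaks$peak_hi, hi, tolerance = 0.01)
  expect_equal(peaks$peak_lo, 0.15, tolerance = 0.02)
  expect_equal(peaks$peak_hi, 0.85, tolerance = 0.02)
})

test_that("degenerate or non-bimodal beta inputs are flagged", {
  expect_error(find_beta_peaks(rep(0.5, 2000)), "degenerate|boundary")
  # unimodal mass centered at 0.5: at least one mode lands on a boundary
  set.seed(3)
  expect_error(find_beta_peaks(pmin(1, pmax(0, rnorm(5000, 0.5, 0.01)))),
               "boundary")
  expect_error(find_beta_peaks(runif(100)), "at least")
})

test_that("a symmetric two-point mixture yields symmetric peaks", {
  set.seed(4)
  b <- sample(c(0.1, 0.9), 5000, replace = TRUE)
  b <- pmin(1, pmax(0, b + rnorm(5000, 0, 0.01)))
  peaks <- find_beta_peaks(b)
  expect_equal(peaks$peak_lo, 0.1, tolerance = 0.03)
  expect_equal(peaks$peak_hi, 0.9, tolerance = 0.03)
})

test_that("k-closest probe selection matches the exhaustive-sort oracle", {
  # 10-probe toy instance, k = 3, peaks (0.2, 0.8)
  man <- flat_manifest(10)
  betas <- c(0.10, 0.22, 0.35, 0.50, 0.61, 0.74, 0.79, 0.81, 0.95, 0.19)
  peaks <- structure(list(peak_lo = 0.2, peak_hi = 0.8),
                     class = "peak_pair")
  sets <- select_background_probes(betas, man, peaks, "Grn", k = 3,
                                   min_n = 3)
  # oracle: assign each probe to its nearer peak, exhaustively sort
  d_lo <- abs(betas - 0.2)
  d_hi <- abs(betas - 0.8)
  hi_pool <- which(d_hi < d_lo)
  lo_pool <- which(d_hi >= d_lo)
  oracle_hi <- man$probe_id[hi_pool[order(d_hi[hi_pool],
                                          man$probe_id[hi_pool])][1:3]]
  oracle_lo <- man$probe_id[lo_pool[order(d_lo[lo_pool],
                                          man$probe_id[lo_pool])][1:3]]
  expect_identical(sets$fully_meth, oracle_hi)
  expect_identical(sets$fully_unmeth, oracle_lo)
  # the default k follows the published selection size
  expect_equal(formals(select_background_probes)$k, 1000)
})

test_that("selection is restricted to Type I probes of the stated channel", {
  params <- tiny_params()
  man <- tiny_manifest(params = params)
  a <- man[man$probe_class != "negative_control", ]
  set.seed(6)
  betas <- runif(nrow(a))
  peaks <- structure(list(peak_lo = 0.1, peak_hi = 0.9),
                     class = "peak_pair")
  sets <- select_background_probes(betas, man, peaks, "Red", k = 50)
  chan <- a$channel[match(c(sets$fully_meth, sets$fully_unmeth), a$probe_id)]
  des <- a$design[match(c(sets$fully_meth, sets$fully_unmeth), a$probe_id)]
  expect_true(all(chan == "Red" & des == "I"))
  expect_length(intersect(sets$fully_meth, sets$fully_unmeth), 0)
})

test_that("edge cases in probe selection warn or fail as appropriate", {
  man <- flat_manifest(40)
  peaks <- structure(list(peak_lo = 0.1, peak_hi = 0.9),
                     class = "peak_pair")
  # fewer eligible than k: take all with a warning
  betas <- c(rep(0.1, 35), rep(0.9, 5))
  expect_warning(
    sets <- select_background_probes(betas, man, peaks, "Grn", k = 10,
                                     min_n = 3),
    "eligible")
  expect_length(sets$fully_meth, 5)
  # all betas on one side: the other set collapses below the minimum
  expect_error(
    suppressWarnings(
      select_background_probes(rep(0.9, 40), man, peaks, "Grn", k = 10,
                               min_n = 3)),
    "fewer than")
})

test_that("NSP pooling recovers a known background and matches median/MAD", {
  set.seed(21)
  man <- flat_manifest(4000, channel = "Grn")
  man$channel[2001:4000] <- "Red"
  man <- as_array_manifest(man)
  draw_g <- rnorm(2000, 500, 100)
  draw_r <- rnorm(2000, 500, 100)
  # fully-methylated probes contribute U, fully-unmethylated contribute M
  U <- M <- rep(NA_real_, 4000)
  U[1:1000] <- draw_g[1:1000]
  M[1001:2000] <- draw_g[1001:2000]
  U[2001:3000] <- draw_r[1:1000]
  M[3001:4000] <- draw_r[1001:2000]
  x <- make_intens(man, U, M)
  sets_g <- structure(list(channel = "Grn",
                           fully_meth = man$probe_id[1:1000],
                           fully_unmeth = man$probe_id[1001:2000], k = 1000),
                      class = "background_probe_sets")
  sets_r <- structure(list(channel = "Red",
                           fully_meth = man$probe_id[2001:3000],
                           fully_unmeth = man$probe_id[3001:4000], k = 1000),
                      class = "background_probe_sets")
  bg <- estimate_background_nsp(x, man, sets_g, sets_r)
  # exact agreement with the direct median/MAD of the pooled draw
  expect_identical(bg$mu_grn, median(draw_g))
  expect_identical(bg$sigma_grn, mad(draw_g))
  expect_identical(bg$mu_red, median(draw_r))
  expect_identical(bg$sigma_red, mad(draw_r))
  expect_identical(bg$method, "NSP")
  expect_equal(bg$n_grn, 2000)
  # and recovery of the generating parameters
  expect_equal(bg$mu_grn, 500, tolerance = 10 / 500)
  expect_equal(bg$sigma_grn, 100, tolerance = 10 / 100)

  # 5% contamination at 50000 leaves the robust estimates unmoved while
  # moment estimators shift grossly
  contaminated <- draw_g
  contaminated[1:100] <- 50000
  U2 <- U
  U2[1:1000] <- contaminated[1:1000]
  x2 <- make_intens(man, U2, M)
  bg2 <- estimate_background_nsp(x2, man, sets_g, sets_r)
  expect_equal(bg2$mu_grn, bg$mu_grn, tolerance = 0.03)
  expect_equal(bg2$sigma_grn, bg$sigma_grn, tolerance = 0.06)
  expect_gt(mean(contaminated) / mean(draw_g), 5)
  expect_gt(sd(contaminated) / sd(draw_g), 10)
})

test_that("constant or undersized background pools are errors", {
  man <- flat_manifest(100, channel = "Grn")
  man$channel[51:100] <- "Red"
  man <- as_array_manifest(man)
  U <- c(rep(300, 50), rnorm(50, 500, 80))
  M <- rep(NA_real_, 100)
  sets_g <- structure(list(channel = "Grn", fully_meth = man$probe_id[1:50],
                           fully_unmeth = character(), k = 50),
                      class = "background_probe_sets")
  sets_r <- structure(list(channel = "Red",
                           fully_meth = man$probe_id[51:100],
                           fully_unmeth = character(), k = 50),
                      class = "background_probe_sets")
  x <- make_intens(man, U, M)
  expect_error(estimate_background_nsp(x, man, sets_g, sets_r),
               "constant background")
  expect_error(estimate_background_nsp(x, man, sets_g, sets_r, min_n = 200),
               "fewer than")
})

test_that("NEG estimation recovers the negative-control law per channel", {
  set.seed(31)
  man <- flat_manifest(40, n_neg = 1000)
  ng <- rnorm(1000, 300, 50)
  nr <- rnorm(1000, 400, 60)
  x <- make_intens(man, rep(1000, 40), rep(1000, 40),
                   neg_grn = ng, neg_red = nr)
  bg <- estimate_background_neg(x)
  expect_identical(bg$mu_grn, median(ng))
  expect_identical(bg$sigma_grn, mad(ng))
  expect_equal(bg$mu_grn, 300, tolerance = 10 / 300)
  expect_equal(bg$sigma_grn, 50, tolerance = 10 / 50)
  expect_equal(bg$mu_red, 400, tolerance = 10 / 400)
  expect_identical(bg$method, "NEG")
  # no negative controls at all
  x0 <- make_intens(flat_manifest(40), rep(1000, 40), rep(1000, 40))
  expect_error(estimate_background_neg(x0), "fewer than")
})

test_that("robust estimators resist permutation and 25% contamination", {
  set.seed(41)
  v <- rnorm(2000, 600, 90)
  man <- flat_manifest(2000, channel = "Grn")
  man2 <- flat_manifest(2000, channel = "Red")
  man2$probe_id <- sprintf("cr%06d", 1:2000)
  man2$address_U <- sprintf("V%05d", 1:2000)
  man2$address_M <- sprintf("W%05d", 1:2000)
  man_all <- as_array_manifest(rbind(as.data.frame(man),
                                     as.data.frame(man2)))
  mk_sets <- function(ids, ch) structure(
    list(channel = ch, fully_meth = ids, fully_unmeth = character(),
         k = length(ids)), class = "background_probe_sets")
  run <- function(vals) {
    x <- make_intens(man_all, c(vals, vals), rep(NA_real_, 4000))
    bg <- estimate_background_nsp(
      x, man_all, mk_sets(man_all$probe_id[1:2000], "Grn"),
      mk_sets(man_all$probe_id[2001:4000], "Red"))
    c(bg$mu_grn, bg$sigma_grn)
  }
  base <- run(v)
  perm <- run(sample(v))
  expect_equal(perm, base)
  v_cont <- v
  v_cont[1:500] <- 1e6  # 25% arbitrary contamination: below breakdown point
  cont <- run(v_cont)
  # location stays near truth; spread stays bounded (MAD carries a known
  # finite bias under heavy contamination) while the classical moments explode
  expect_equal(cont[1], base[1], tolerance = 0.10)
  expect_lt(cont[2], 2 * base[2])
  expect_gt(mean(v_cont) / mean(v), 100)
  expect_gt(sd(v_cont) / sd(v), 1000)
})

test_that("NSP sits above NEG when non-specific binding exceeds controls", {
  params <- tiny_params()
  man <- tiny_manifest(params = params)
  s <- simulate_sample(man, params, sex = "male", seed = 51)
  nsp <- estimate_background(s$intensities, man, method = "NSP", k = 100)
  neg <- estimate_background(s$intensities, man, method = "NEG")
  expect_gt(nsp$mu_grn, neg$mu_grn)
  expect_gt(nsp$mu_red, neg$mu_red)
})

test_that("cross-talk ratios track the generator's leakage coefficient", {
  params0 <- tiny_params(lambda = 0)
  man <- tiny_manifest(params = params0)
  s0 <- simulate_sample(man, params0, sex = "male", seed = 61)
  bg0 <- estimate_background(s0$intensities, man, method = "NSP", k = 100)
  r0 <- crosstalk_ratio(s0$intensities, man, attr(bg0, "probe_sets"))
  expect_equal(r0$unmeth_ratio, c(1, 1), tolerance = 0.1)
  expect_equal(r0$meth_ratio, c(1, 1), tolerance = 0.1)

  params3 <- tiny_params(lambda = 0.3)
  s3 <- simulate_sample(man, params3, sex = "male", seed = 62)
  bg3 <- estimate_background(s3$intensities, man, method = "NSP", k = 100)
  r3 <- crosstalk_ratio(s3$intensities, man, attr(bg3, "probe_sets"))
  # generator arithmetic: oob_loud ~ lambda*(S+b) + neg, oob_silent ~
  # lambda*b + neg, evaluated at medians of the selected probes
  med_S <- exp(params3$signal[1])
  expected <- function(nsp, neg) {
    (params3$lambda * (med_S + nsp[1]) + neg[1]) /
      (params3$lambda * nsp[1] + neg[1])
  }
  exp_g <- expected(params3$nsp_grn, params3$neg_red)   # Grn probes, oob red
  exp_r <- expected(params3$nsp_red, params3$neg_grn)
  expect_equal(r3$unmeth_ratio[r3$channel == "Grn"], exp_g, tolerance = 0.2)
  expect_equal(r3$unmeth_ratio[r3$channel == "Red"], exp_r, tolerance = 0.2)
  expect_true(all(r3$unmeth_ratio > 2))
  expect_error(crosstalk_ratio(
    s3$intensities, man,
    structure(list(channel = "Grn", fully_meth = character(),
                   fully_unmeth = character(), k = 0),
              class = "background_probe_sets")),
    "empty")
})
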