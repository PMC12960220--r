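mk_events <- function(embryo_id, chrom, left, right, parent = "maternal") {
  data.frame(embryo_id = embryo_id, parent = parent, chrom = chrom,
             left = as.integer(left), right = as.integer(right),
             stringsAsFactors = FALSE)
}

test_that("crossover count phenotype averages per-embryo totals", {
  emb <- data.frame(embryo_id = c("e1", "e2", "e3"), family_id = "f1",
                    stringsAsFactors = FALSE)
  ev <- do.call(rbind, Map(function(e, n)
    mk_events(rep(e, n), "chr1", seq_len(n) * 100, seq_len(n) * 100 + 50),
    c("e1", "e2", "e3"), c(50, 48, 52)))
  out <- crossover_count_phenotype(ev, emb, parent = "maternal")
  expect_equal(out$mean_count, 50)
  expect_equal(out$n_embryos, 3L)
  expect_error(crossover_count_phenotype(ev, emb[1:2, ]), "fewer than 3")
})

test_that("hotspot occupancy respects half-open overlap", {
  hs <- interval_track("chr1", c(10, 100), c(20, 200))
  inside <- mk_events("e1", "chr1", 12, 18)       # inside [10,20)
  expect_equal(hotspot_occupancy(inside, hs), 1.0)
  # interval starting at 1-based 21 abuts hotspot end 20 (exclusive)
  abut <- mk_events("e1", "chr1", 21, 30)
  expect_equal(hotspot_occupancy(abut, hs), 0.0)
  empty <- interval_track(character(), numeric(), numeric())
  expect_equal(hotspot_occupancy(inside, empty), 0.0)

  # invariant under splitting a hotspot into adjacent pieces
  split_hs <- interval_track("chr1", c(10, 15, 100), c(15, 20, 200))
  ev <- mk_events(c("e1", "e1", "e2"), "chr1",
                  c(12, 21, 150), c(18, 30, 260))
  expect_equal(hotspot_occupancy(ev, hs), hotspot_occupancy(ev, split_hs))

  # midpoint rule differs when only a flank grazes the hotspot
  graze <- mk_events("e1", "chr1", 18, 90)  # midpoint 54 outside [10,20)
  expect_equal(hotspot_occupancy(graze, hs), 1.0)
  expect_equal(hotspot_occupancy(graze, hs, rule = "midpoint"), 0.0)
})

test_that("crossover context reads GC windows and covering track values", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1",
               paste(rep("GC", 1500), collapse = ""),
               ">chr2",
               paste(rep("AT", 1500), collapse = "")), fa)
  ev <- rbind(mk_events("e1", "chr1", 1000, 2000),
              mk_events("e1", "chr2", 1000, 2000))
  track <- interval_track(c("chr1", "chr2"), c(0, 0), c(3000, 3000),
                          value = c(0.5, 0.5))
  ctx <- crossover_context(ev, track = track, fasta = fa)
  expect_equal(ctx$gc, c(1.0, 0.0))
  expect_equal(ctx$mean_timing, 0.5)

  # event midpoint not covered by the track is skipped
  track2 <- interval_track("chr1", 0, 3000, value = 0.25)
  ctx2 <- crossover_context(ev, track = track2)
  expect_equal(ctx2$timing, c(0.25, NA))
  expect_equal(ctx2$mean_timing, 0.25)

  far <- mk_events("e1", "chr1", 99000, 99100)
  expect_error(crossover_context(far, fasta = fa), "outside")
})

test_that("aneuploidy summary reproduces published-scale ratio arithmetic", {
  # the ratio helper applied to aggregate counts
  tri <- binomial_ratio(57974, 57974 + 34511)
  expect_equal(round(tri$fraction, 3), 0.627)
  expect_lt(tri$p_value, 1e-100)
  mat <- binomial_ratio(84044, 84044 + 8441)
  expect_equal(round(mat$fraction, 3), 0.909)

  calls <- data.frame(
    embryo_id = rep(c("e1", "e2", "e3"), each = 2),
    chrom = rep(c("chr1", "chr2"), 3),
    call = c("trisomy_m", "disomy", "monosomy_m", "trisomy_m",
             "disomy", "disomy"),
    origin = c("maternal", NA, "maternal", "maternal", NA, NA),
    stringsAsFactors = FALSE
  )
  s <- aneuploidy_summary(calls)
  expect_equal(s$ratios$fraction[s$ratios$ratio == "trisomy"], 2 / 3)
  expect_equal(s$ratios$fraction[s$ratios$ratio == "maternal"], 1)
  expect_equal(s$fraction_embryos_aneuploid, 2 / 3)
  expect_equal(sum(s$by_chrom$count), 3)

  none <- calls; none$call <- "disomy"; none$origin <- NA
  s0 <- aneuploidy_summary(none)
  expect_equal(s0$fraction_embryos_aneuploid, 0)
  expect_true(all(is.na(s0$ratios$fraction)))
})

test_that("flagged embryos are excluded from the aneuploidy summary", {
  calls <- data.frame(
    embryo_id = rep(c("e1", "e2"), each = 2),
    chrom = rep(c("chr1", "chr2"), 2),
    call = c("trisomy_m", "trisomy_m", "monosomy_p", "disomy"),
    origin = c("maternal", "maternal", "paternal", NA),
    complex_aneuploid = c(TRUE, TRUE, FALSE, FALSE),
    genome_wide_abnormal = FALSE,
    stringsAsFactors = FALSE
  )
  s <- aneuploidy_summary(calls)
  expect_equal(s$excluded, "e1")
  expect_equal(sum(s$by_chrom$count), 1)
})

test_that("Pearson dispersion matches the hand-computed toy table", {
  # 3 patients, successes/trials 1/2, 0/2, 2/2, intercept-only p_hat = 0.5:
  # phi = (0 + 2 + 2) / (3 - 1) = 2 under the age model collapsing to the
  # intercept (constant age column would be singular; use +/- tiny ages)
  affected <- c(1, 0, 2); total <- c(2, 2, 2)
  fit <- glm(cbind(affected, total - affected) ~ 1, family = binomial())
  phi_hand <- sum(residuals(fit, "pearson")^2) / (3 - 1)
  expect_equal(phi_hand, 2)
})

test_that("overdispersion test is calibrated under the binomial null", {
  set.seed(50)
  n <- 300
  age <- runif(n, 25, 42)
  total <- rpois(n, 5) + 1
  p <- plogis(-8 + 0.1 * age + 0.002 * age^2)
  affected <- rbinom(n, total, p)
  res <- overdispersion_test(affected, total, age, B = 199)
  expect_s3_class(res, "overdispersion_test")
  expect_gt(res$phi, 0)
  expect_gt(res$p_value, 0.001)  # null data should rarely be extreme
  expect_length(res$coefficients, 3L)

  # beta-binomial alternative is detected
  set.seed(51)
  n2 <- 800
  total2 <- rpois(n2, 6) + 1
  rho <- 0.1
  pp <- rbeta(n2, 0.3 * (1 - rho) / rho, 0.7 * (1 - rho) / rho)
  aff2 <- rbinom(n2, total2, pp)
  res2 <- overdispersion_test(aff2, total2, runif(n2, 25, 42), B = 199)
  expect_gt(res2$phi, 1)
  expect_lt(res2$p_value, 0.05)
})

test_that("ICC(1) hits the exchangeable-correlation truth", {
  set.seed(52)
  n <- 4000; k <- 8
  # identical values within embryos -> ICC ~ 1
  u <- rnorm(n)
  same <- matrix(u, n, k)
  expect_gt(crossover_icc(same, n_boot = 0)$icc, 0.999)
  # independent values -> ICC ~ 0
  indep <- matrix(rnorm(n * k), n, k)
  expect_lt(abs(crossover_icc(indep, n_boot = 0)$icc), 0.02)
  # exchangeable rho = 0.15
  rho <- 0.15
  ex <- sqrt(rho) * u + sqrt(1 - rho) * matrix(rnorm(n * k), n, k)
  icc <- crossover_icc(ex, n_boot = 50)
  expect_lt(abs(icc$icc - rho), 0.02)
  expect_true(icc$ci[1] <= icc$icc && icc$icc <= icc$ci[2])
  expect_error(crossover_icc(matrix(1, 5, 1)), "two chromosomes")
})

test_that("count matrix assembles events including zero-count embryos", {
  ev <- mk_events(c("e1", "e1", "e2"), c("chr1", "chr2", "chr1"),
                  c(10, 20, 30), c(15, 25, 35))
  ev$family_id <- "f1"
  m <- crossover_count_matrix(ev, c("e1", "e2", "e3"), c("chr1", "chr2"))
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m["e1", "chr1"], 1L)
  expect_equal(unname(m["e3", ]), c(0L, 0L))
})
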