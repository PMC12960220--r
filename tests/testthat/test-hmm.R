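test_that("state spaces have the expected size and composition", {
  expect_length(enumerate_states("disomy")$labels, 4L)
  expect_length(enumerate_states("monosomy_m")$labels, 2L)
  expect_length(enumerate_states("monosomy_p")$labels, 2L)
  expect_length(enumerate_states("trisomy_m")$labels, 6L)
  expect_length(enumerate_states("trisomy_p")$labels, 6L)
  expect_length(enumerate_states("nullisomy")$labels, 1L)
  # monosomy_m = maternal homologue lost: remaining copy is paternal
  expect_equal(ncol(enumerate_states("monosomy_m")$mat), 0L)
  expect_equal(ncol(enumerate_states("monosomy_m")$pat), 1L)
  st <- enumerate_states("trisomy_m")
  expect_equal(ncol(st$mat), 2L)
  expect_equal(ncol(st$pat), 1L)
})

test_that("transition matrices follow the Haldane model and normalize", {
  expect_equal(haldane_r(50), (1 - exp(-1)) / 2, tolerance = 1e-12)
  for (h in cn_hypotheses()) {
    st <- enumerate_states(h)
    K <- length(st$labels)
    expect_equal(transition_matrix(st, 0), diag(K), tolerance = 1e-12)
    for (d in c(0.01, 1, 50, 500)) {
      P <- transition_matrix(st, d)
      expect_equal(rowSums(P), rep(1, K), tolerance = 1e-12)
      expect_true(all(P >= 0))
    }
    expect_error(transition_matrix(st, -1), "negative")
  }
  # disomy: both copies switch independently
  st2 <- enumerate_states("disomy")
  r <- haldane_r(50)
  P <- transition_matrix(st2, 50)
  expect_equal(P[1, 1], (1 - r)^2, tolerance = 1e-12)
  expect_equal(P[1, 4], r^2, tolerance = 1e-12)
})

test_that("emission density matches the truncated-normal mixture", {
  p <- emission_params(sigma = 0.1, pi0 = 0)
  Z <- pnorm(5) - pnorm(-5)
  expect_equal(emission_logdens(0.5, matrix(0.5, 1, 1), p)[1, 1],
               log(dnorm(0) / 0.1 / Z), tolerance = 1e-10)
  # pure uniform component: density 1 everywhere
  p1 <- emission_params(sigma = 0.1, pi0 = 1)
  expect_equal(emission_logdens(c(0.1, 0.9), matrix(0.5, 2, 1), p1),
               matrix(0, 2, 1))
  # nullisomy and missing observations contribute log 1 = 0
  expect_equal(emission_logdens(NA_real_, matrix(0.5, 1, 1), p)[1, 1], 0)
  st0 <- enumerate_states("nullisomy")
  panel <- toy_panel(3, seed = 1)
  expect_equal(emission_logdens(c(0.2, 0.5, 0.9),
                                state_dosage(st0, panel), p),
               matrix(0, 3, 1))
  expect_error(emission_params(sigma = 0), "positive")
})

test_that("forward likelihood matches brute-force path enumeration", {
  set.seed(20)
  for (h in cn_hypotheses()) {
    for (rep in 1:4) {
      n <- sample(2:6, 1)
      panel <- toy_panel(n)
      map <- toy_map(panel, cM_per_Mb = runif(1, 0.5, 30))
      b <- runif(n)
      b[sample(n, 1)] <- NA  # missing data handled identically
      params <- emission_params(sigma = runif(1, 0.05, 0.3),
                                pi0 = runif(1, 0, 0.5))
      expect_equal(forward_loglik(b, panel, map, h, params),
                   brute_force_loglik(b, panel, map, h, params),
                   tolerance = 1e-9)
    }
  }
})

test_that("uninformative emissions give zero log-likelihood", {
  panel <- toy_panel(20, seed = 21)
  map <- toy_map(panel)
  b <- runif(20)
  p1 <- emission_params(sigma = 0.1, pi0 = 1)
  for (h in cn_hypotheses())
    expect_equal(forward_loglik(b, panel, map, h, p1), 0, tolerance = 1e-10)
})

test_that("likelihood is invariant to prepending a missing-BAF site", {
  set.seed(22)
  panel <- toy_panel(30)
  map <- toy_map(panel)
  b <- runif(30)
  params <- emission_params(0.12, 0.1)
  base <- forward_loglik(b, panel, map, "disomy", params)
  panel2 <- snp_panel(c("chr1", panel$chrom), c(5L, panel$pos), "A", "B",
                      m1 = c(1L, panel$m1), m2 = c(0L, panel$m2),
                      p1 = c(1L, panel$p1), p2 = c(0L, panel$p2))
  expect_equal(forward_loglik(c(NA, b), panel2, map, "disomy", params),
               base, tolerance = 1e-9)
})

test_that("posterior decoding is normalized and tracks simulated truth", {
  cfg <- sim_config(n_chrom = 1, n_sites = 800, n_embryos = 1, sigma = 0.05,
                    pi0 = 0, aneuploidy = c(maternal_monosomy = 0),
                    seed = 23)
  fam <- simulate_family(cfg)
  params <- emission_params(sigma = 0.05, pi0 = 0.01)
  dec <- posterior_decode(fam$bafs[[1]]$baf, fam$panel, fam$map, "disomy",
                          params)
  expect_equal(rowSums(dec$gamma), rep(1, 800), tolerance = 1e-10)

  tr <- fam$truth[[1]]$chromosomes$chr1
  truth_path <- tr$m[[1]]$path
  xo <- tr$m_crossovers
  off_switch <- rep(TRUE, 800)
  for (x in xo)
    off_switch[abs(fam$panel$pos - x) < 2e6] <- FALSE
  inf <- fam$panel$m1 != fam$panel$m2
  post_true <- dec$maternal[cbind(seq_len(800), truth_path)]
  expect_gt(min(post_true[off_switch & inf]), 0.99)
})

test_that("swapping the parents mirrors the marginals exactly", {
  set.seed(24)
  panel <- toy_panel(40)
  map <- toy_map(panel)
  b <- runif(40)
  params <- emission_params(0.1, 0.05)
  a <- posterior_decode(b, panel, map, "trisomy_m", params)
  swapped <- snp_panel(panel$chrom, panel$pos, "A", "B",
                       m1 = panel$p1, m2 = panel$p2,
                       p1 = panel$m1, p2 = panel$m2)
  bsw <- posterior_decode(b, swapped, map, "trisomy_p", params)
  expect_equal(a$loglik, bsw$loglik, tolerance = 1e-9)
  expect_equal(a$maternal, bsw$paternal, tolerance = 1e-9)
  expect_equal(a$paternal, bsw$maternal, tolerance = 1e-9)
})

test_that("viterbi path switches at true crossovers and bounds the likelihood", {
  cfg <- sim_config(n_chrom = 1, n_sites = 600, n_embryos = 1, sigma = 0.05,
                    pi0 = 0, aneuploidy = c(maternal_monosomy = 0),
                    seed = 25)
  fam <- simulate_family(cfg)
  params <- emission_params(0.05, 0.01)
  v <- viterbi_path(fam$bafs[[1]]$baf, fam$panel, fam$map, "disomy", params)
  ll <- forward_loglik(fam$bafs[[1]]$baf, fam$panel, fam$map, "disomy",
                       params)
  expect_lte(v$logp, ll)
  v2 <- viterbi_path(fam$bafs[[1]]$baf, fam$panel, fam$map, "disomy", params)
  expect_identical(v$path, v2$path)

  st <- enumerate_states("disomy")
  tr <- fam$truth[[1]]$chromosomes$chr1
  true_state <- st$mat[v$path, 1]  # decoded maternal haplotype
  n_switch <- sum(diff(true_state) != 0)
  expect_equal(n_switch, length(tr$m_crossovers))
})

test_that("noise grid search recovers the generating parameters", {
  cfg <- sim_config(n_chrom = 1, n_sites = 5000, n_embryos = 1, sigma = 0.1,
                    pi0 = 0.1, aneuploidy = c(maternal_monosomy = 0),
                    seed = 26)
  fam <- simulate_family(cfg)
  est <- fit_noise(fam$bafs[[1]]$baf, fam$panel, fam$map)
  expect_equal(est$sigma, 0.1)
  expect_equal(est$pi0, 0.1)
  G <- attr(est, "loglik_grid")
  expect_equal(max(G), G[as.character(est$sigma), as.character(est$pi0)])
  expect_error(fit_noise(rep(NA_real_, nrow(fam$panel)), fam$panel, fam$map),
               "missing")
})

test_that("no underflow on very long chromosomes", {
  set.seed(27)
  n <- 50000
  panel <- toy_panel(n, spacing = 2000)
  map <- toy_map(panel)
  b <- runif(n)
  ll <- forward_loglik(b, panel, map, "disomy", emission_params(0.1, 0.05))
  expect_true(is.finite(ll))
  dec <- posterior_decode(b, panel, map, "disomy", emission_params(0.1, 0.05))
  expect_true(all(is.finite(dec$gamma)))
  expect_equal(range(rowSums(dec$gamma)), c(1, 1), tolerance = 1e-8)
})

test_that("average likelihood peaks at the generating sigma across the grid", {
  set.seed(28)
  sigma_grid <- seq(0.05, 0.3, by = 0.025)
  gen <- 0.15
  G <- matrix(0, 50, length(sigma_grid))
  for (r in 1:50) {
    cfg <- sim_config(n_chrom = 1, n_sites = 400, n_embryos = 1,
                      sigma = gen, pi0 = 0.05,
                      aneuploidy = c(maternal_monosomy = 0))
    fam <- simulate_family(cfg)
    G[r, ] <- vapply(sigma_grid, function(s)
      forward_loglik(fam$bafs[[1]]$baf, fam$panel, fam$map, "disomy",
                     emission_params(s, 0.05)), 0)
  }
  avg <- colMeans(G)
  expect_equal(sigma_grid[which.max(avg)], gen)
  # expected likelihood rises toward the generating value from both sides
  expect_true(all(diff(avg[sigma_grid <= gen]) > 0))
  expect_true(all(diff(avg[sigma_grid >= gen]) < 0))
})
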