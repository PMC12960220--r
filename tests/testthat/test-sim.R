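test_that("crossover draws follow the map's Poisson intensity", {
  map0 <- uniform_genetic_map("chr1", 1e8, 0)
  set.seed(1)
  expect_true(all(vapply(1:50, function(i)
    length(draw_crossovers(map0, "chr1")), 0L) == 0))

  map <- uniform_genetic_map("chr1", 1e8, 100)
  set.seed(2)
  counts <- vapply(1:10000, function(i)
    length(draw_crossovers(map, "chr1")), 0L)
  # Poisson(1): mean 1, MC s.e. = 1/100
  expect_lt(abs(mean(counts) - 1), 3 * 0.01)
  set.seed(3)
  pos <- draw_crossovers(map, "chr1", rate_multiplier = 20)
  expect_true(all(pos > 0 & pos < 1e8))
  expect_false(is.unsorted(pos))
})

test_that("gametes switch haplotype exactly at crossovers", {
  site_pos <- seq(1e5, 1e7, by = 1e5)
  expect_equal(form_gamete(site_pos, numeric(0), start_hap = 1),
               rep(1L, length(site_pos)))
  g <- form_gamete(site_pos, 5e6 + 1, start_hap = 2)
  expect_equal(unique(g[site_pos <= 5e6]), 2L)
  expect_equal(unique(g[site_pos > 5e6]), 1L)
  g2 <- form_gamete(site_pos, c(3e6 + 1, 7e6 + 1), start_hap = 1)
  expect_equal(g2[site_pos > 7e6][1], 1L)  # back on the starting haplotype
  expect_error(form_gamete(site_pos, c(5e6, 3e6)), "sorted")
})

test_that("mis-segregation modes produce the stated copy configurations", {
  set.seed(4)
  site_pos <- seq(1e5, 1e8, by = 1e5)
  map <- uniform_genetic_map("chr1", 1e8, 100)
  gam <- function() {
    xo <- draw_crossovers(map, "chr1")
    s <- sample(1:2, 1)
    list(start = s, crossovers = xo, path = form_gamete(site_pos, xo, s))
  }
  cen <- 4e7
  gm <- gam(); gp <- gam(); gm2 <- gam()

  mi <- apply_missegregation("maternal_MI_BPH", gm, gp, cen, gm2 = gm2)
  expect_equal(mi$k, 3L)
  i_cen <- which.min(abs(site_pos - cen))
  expect_true(mi$m[[1]]$path[i_cen] != mi$m[[2]]$path[i_cen])

  mii <- apply_missegregation("maternal_MII", gm, gp, cen, gm2 = gm2)
  expect_true(mii$m[[1]]$path[i_cen] == mii$m[[2]]$path[i_cen])

  mono <- apply_missegregation("maternal_monosomy", gm, gp, cen)
  expect_equal(mono$k, 1L)
  expect_length(mono$m, 0L)
  expect_equal(mono$origin, "maternal")

  mit <- apply_missegregation("mitotic_trisomy", gm, gp, cen)
  expect_equal(mit$m[[1]]$path, mit$m[[2]]$path)  # SPH everywhere

  nul <- apply_missegregation("nullisomy", gm, gp, cen)
  expect_equal(nul$k, 0L)

  expect_error(apply_missegregation("banana", gm, gp, cen), "unknown")
})

test_that("synthesized BAF matches transmitted dosage as noise vanishes", {
  panel <- snp_panel("chr1", c(100L, 200L, 300L), "A", "B",
                     m1 = c(1L, 1L, 0L), m2 = c(0L, 0L, 0L),
                     p1 = c(0L, 1L, 1L), p2 = c(0L, 1L, 1L))
  gm <- list(start = 1L, crossovers = numeric(0), path = rep(1L, 3))
  gp <- list(start = 1L, crossovers = numeric(0), path = rep(1L, 3))
  tr <- apply_missegregation("euploid", gm, gp, 150)
  set.seed(5)
  b <- synthesize_baf(tr, panel, sigma = 1e-9, pi0 = 0)
  expect_equal(b, c(0.5, 1, 0.5), tolerance = 1e-6)

  tr3 <- apply_missegregation("maternal_MI_BPH", gm, gp, 150,
                              gm2 = list(start = 2L, crossovers = numeric(0),
                                         path = rep(2L, 3)))
  b3 <- synthesize_baf(tr3, panel, sigma = 1e-9, pi0 = 0)
  # maternal m1+m2 plus paternal p1: dosages (1+0+0)/3, (1+0+1)/3, (0+0+1)/3
  expect_equal(b3, c(1, 2, 1) / 3, tolerance = 1e-6)

  set.seed(6)
  bn <- synthesize_baf(tr, panel, sigma = 0.5, pi0 = 0.2)
  expect_true(all(bn >= 0 & bn <= 1))
})

test_that("families are reproducible and honour the configured spectrum", {
  cfg <- sim_config(n_chrom = 1, n_sites = 50, n_embryos = 5,
                    aneuploidy = c(maternal_monosomy = 0), seed = 11)
  f1 <- simulate_family(cfg)
  f2 <- simulate_family(cfg)
  expect_identical(f1$bafs[["embryo03"]]$baf, f2$bafs[["embryo03"]]$baf)
  expect_length(f1$bafs, 5L)
  expect_length(f1$truth, 5L)
  expect_true(all(vapply(f1$truth, function(t) t$mode, "") == "euploid"))

  cfg2 <- sim_config(n_chrom = 1, n_sites = 30, n_embryos = 200,
                     aneuploidy = c(maternal_monosomy = 0.5), seed = 12)
  f3 <- simulate_family(cfg2)
  frac <- mean(vapply(f3$truth, function(t) t$mode, "") == "maternal_monosomy")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 200))

  # monomorphic sites possible when the MAF bound includes 0
  cfg3 <- sim_config(n_chrom = 1, n_sites = 2000, n_embryos = 1,
                     maf_range = c(0, 0.05), seed = 13)
  f4 <- simulate_family(cfg3)
  mono <- with(f4$panel, m1 == m2 & p1 == p2 & m1 == p1)
  expect_gt(sum(mono), 0)
})

test_that("maternal crossover counts scale with the sex-specific map", {
  cfg <- sim_config(n_chrom = 1, n_sites = 20, n_embryos = 400,
                    maternal_cM = 150, paternal_cM = 50,
                    aneuploidy = c(maternal_monosomy = 0), seed = 14)
  fam <- simulate_family(cfg)
  nm <- vapply(fam$truth, function(t)
    length(t$chromosomes$chr1$m_crossovers), 0L)
  np <- vapply(fam$truth, function(t)
    length(t$chromosomes$chr1$p_crossovers), 0L)
  expect_lt(abs(mean(nm) - 1.5), 3 * sqrt(1.5 / 400))
  expect_lt(abs(mean(np) - 0.5), 3 * sqrt(0.5 / 400))
})
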