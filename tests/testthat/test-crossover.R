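test_that("phasing requires three siblings and recovers simulated phase", {
  cfg <- sim_config(n_chrom = 1, n_sites = 1500, n_embryos = 3,
                    maternal_cM = 0, paternal_cM = 0,  # zero crossovers
                    sigma = 0.02, pi0 = 0,
                    aneuploidy = c(maternal_monosomy = 0), seed = 40)
  fam <- simulate_family(cfg)
  expect_error(phase_by_transmission(fam$panel, fam$bafs[1:2]),
               "at least three sibling embryos")

  scrambled <- fam$panel
  set.seed(41)
  fl <- runif(nrow(scrambled)) < 0.5  # destroy the phase
  tmp <- scrambled$m1[fl]; scrambled$m1[fl] <- scrambled$m2[fl]
  scrambled$m2[fl] <- tmp
  ph <- phase_by_transmission(scrambled, fam$bafs)
  # exact recovery up to one global flip at sites carrying phase
  # information (mother het, father hom; at double-het sites only
  # embryos with homozygous genotypes vote, which can leave a site blank)
  het <- fam$panel$m1 != fam$panel$m2 & fam$panel$p1 == fam$panel$p2
  agree <- ph$m1[het] == fam$panel$m1[het]
  expect_gte(max(mean(agree), 1 - mean(agree)), 0.999)
  expect_true(isTRUE(attr(ph, "phase_flip_arbitrary")))

  # majority voting is independent of embryo input order
  ph2 <- phase_by_transmission(scrambled, rev(fam$bafs))
  expect_equal(ph$m1, ph2$m1)
  expect_equal(ph$p1, ph2$p1)
})

test_that("crossover events bracket posterior haplotype flips", {
  pos <- (1:10) * 1000L
  marg <- cbind(c(rep(0.99, 5), rep(0.01, 5)),
                c(rep(0.01, 5), rep(0.99, 5)))
  inf <- rep(TRUE, 10)
  ev <- call_crossovers(marg, pos, inf, gamma = 0.9)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$left, 5000L)
  expect_equal(ev$right, 6000L)

  # low-confidence flank widens the interval to the confident sites
  marg2 <- marg; marg2[5, ] <- c(0.6, 0.4)
  ev2 <- call_crossovers(marg2, pos, inf, gamma = 0.9)
  expect_equal(ev2$left, 4000L)
  expect_equal(ev2$right, 6000L)

  # gamma = 1 suppresses every event on imperfect posteriors
  expect_equal(nrow(call_crossovers(marg * 0.999 + 5e-4, pos, inf,
                                    gamma = 1)), 0L)
  expect_equal(nrow(call_crossovers(marg[1:5, ], pos[1:5], inf[1:5])), 0L)
  expect_error(call_crossovers(NULL, pos, inf), "unphased")
})

test_that("shared sibling intervals are filtered; outlier embryos flagged", {
  embryos <- data.frame(embryo_id = paste0("e", 1:4),
                        family_id = "f1", stringsAsFactors = FALSE)
  shared <- data.frame(embryo_id = c("e1", "e2", "e3"), family_id = "f1",
                       parent = "maternal", chrom = "chr1",
                       left = 100L, right = 200L,
                       stringsAsFactors = FALSE)
  private <- data.frame(embryo_id = "e4", family_id = "f1",
                        parent = "maternal", chrom = "chr1",
                        left = 900L, right = 1000L,
                        stringsAsFactors = FALSE)
  fl <- filter_artifacts(rbind(shared, private), embryos)
  expect_equal(nrow(fl$removed), 3L)      # shared by 3 of 4 siblings
  expect_equal(fl$events$embryo_id, "e4") # private event kept

  # all counts comparable: nothing removed, nothing excluded
  fl2 <- filter_artifacts(private, embryos)
  expect_equal(nrow(fl2$removed), 0L)
  expect_equal(nrow(fl2$excluded_embryos), 0L)

  # an embryo 4+ s.d. above the cohort mean is excluded
  set.seed(42)
  emb <- data.frame(embryo_id = paste0("e", 1:40),
                    family_id = paste0("f", rep(1:20, each = 2)),
                    stringsAsFactors = FALSE)
  counts <- c(rpois(39, 25), 80)
  ev <- do.call(rbind, lapply(seq_len(40), function(i) {
    if (counts[i] == 0) return(NULL)
    data.frame(embryo_id = emb$embryo_id[i], family_id = emb$family_id[i],
               parent = "maternal", chrom = "chr1",
               left = seq_len(counts[i]) * 10L,
               right = seq_len(counts[i]) * 10L + 5L,
               stringsAsFactors = FALSE)
  }))
  fl3 <- filter_artifacts(ev, emb)
  expect_true("e40" %in% fl3$excluded_embryos$embryo_id)
  expect_false("e1" %in% fl3$excluded_embryos$embryo_id)
})

test_that("a family analysis recovers simulated crossovers", {
  cfg <- sim_config(n_chrom = 1, n_sites = 2500, n_embryos = 5,
                    sigma = 0.06, pi0 = 0.02,
                    aneuploidy = c(maternal_monosomy = 0), seed = 43)
  fam <- simulate_family(cfg)
  cs <- analyze_family(fam$panel, fam$bafs, fam$map,
                       centromeres = fam$centromeres,
                       params = emission_params(0.075, 0.05))
  embryos <- data.frame(embryo_id = names(fam$bafs), family_id = "fam1")
  fl <- filter_artifacts(cs$events, embryos)
  for (e in names(fam$truth)) {
    tr <- fam$truth[[e]]$chromosomes$chr1
    for (par in c("maternal", "paternal")) {
      # crossovers outside the span of the parent's informative sites
      # leave no transmitted-haplotype flip and are undetectable
      inf <- if (par == "maternal") fam$panel$m1 != fam$panel$m2
             else fam$panel$p1 != fam$panel$p2
      span <- range(fam$panel$pos[inf])
      txo_all <- if (par == "maternal") tr$m_crossovers else tr$p_crossovers
      txo <- txo_all[txo_all >= span[1] & txo_all <= span[2]]
      ev <- fl$events[fl$events$embryo_id == e & fl$events$parent == par, ]
      expect_equal(nrow(ev), length(txo))
      if (nrow(ev) == length(txo) && length(txo)) {
        ord <- order(ev$left)
        expect_true(all(txo >= ev$left[ord] & txo <= ev$right[ord]))
      }
    }
  }
})
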