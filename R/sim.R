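#' Simulation configuration
#'
#' Defines the family structure, SNP panel, genetic maps, noise model and
#' mis-segregation spectrum used by [simulate_family()]. Defaults emulate a
#' clinical PGT cohort: dense biallelic array sites, maternal genetic maps
#' about 1.5x longer than paternal, bulk-biopsy BAF noise, and a
#' maternally dominated aneuploidy spectrum totalling 25\% of embryos.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp physical length per chromosome.
#' @param n_sites panel sites per chromosome.
#' @param maf_range bounds of the per-site alt-allele frequency (uniform).
#' @param maternal_cM,paternal_cM sex-specific genetic lengths per
#'   chromosome.
#' @param sigma,pi0 BAF noise: truncated-normal scale and uniform-mixture
#'   weight (see [emission_params()]).
#' @param n_embryos sibling embryos per family.
#' @param aneuploidy named probability vector over mis-segregation modes
#'   (see [apply_missegregation()]); the remainder is euploid.
#' @param centromere_frac centromere location as a fraction of chromosome
#'   length.
#' @param maternal_age,paternal_age parental ages (years).
#' @param propensity_sd s.d. of the per-meiosis log crossover-propensity
#'   shared across chromosomes (0 = independent chromosomes).
#' @param coupling coupling of maternal crossover propensity to
#'   mis-segregation risk: the log-odds of aneuploidy are shifted by
#'   `-coupling * z_m` where `z_m` is the maternal propensity; positive
#'   values make low-crossover meioses error-prone.
#' @param seed RNG seed used by [simulate_family()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 2, chrom_length_bp = 1e8, n_sites = 5000,
                       maf_range = c(0.1, 0.5),
                       maternal_cM = 120, paternal_cM = 80,
                       sigma = 0.1, pi0 = 0.05, n_embryos = 8,
                       aneuploidy = c(maternal_MI_BPH = 0.06,
                                      maternal_MII = 0.04,
                                      maternal_monosomy = 0.05,
                                      paternal_trisomy = 0.03,
                                      paternal_monosomy = 0.02,
                                      mitotic_trisomy = 0.03,
                                      nullisomy = 0.01,
                                      triploid = 0.01),
                       centromere_frac = 0.4,
                       maternal_age = 35, paternal_age = 37,
                       propensity_sd = 0, coupling = 0, seed = NULL) {
  stopifnot(sigma > 0, pi0 >= 0, pi0 <= 1, n_embryos >= 1,
            sum(aneuploidy) <= 1, all(aneuploidy >= 0))
  known <- c("maternal_MI_BPH", "maternal_MII", "maternal_monosomy",
             "paternal_trisomy", "paternal_monosomy", "mitotic_trisomy",
             "nullisomy", "triploid")
  if (length(aneuploidy) && !all(names(aneuploidy) %in% known))
    stop("unknown mis-segregation mode: ",
         paste(setdiff(names(aneuploidy), known), collapse = ", "))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate phased parental haplotypes
#'
#' Four haplotypes with per-site alt-allele frequency drawn uniformly from
#' `maf_range`; positions are a sorted uniform draw along each chromosome.
#'
#' @param config a [sim_config()].
#' @return a phased [snp_panel()].
#' @export
simulate_parental_haplotypes <- function(config) {
  out <- lapply(seq_len(config$n_chrom), function(ci) {
    ch <- paste0("chr", ci)
    pos <- sort(sample.int(config$chrom_length_bp - 2L, config$n_sites)) + 1L
    f <- runif(config$n_sites, config$maf_range[1], config$maf_range[2])
    data.frame(chrom = ch, pos = pos,
               m1 = rbinom(config$n_sites, 1, f),
               m2 = rbinom(config$n_sites, 1, f),
               p1 = rbinom(config$n_sites, 1, f),
               p2 = rbinom(config$n_sites, 1, f))
  })
  df <- do.call(rbind, out)
  snp_panel(df$chrom, df$pos, ref = "A", alt = "B",
            m1 = df$m1, m2 = df$m2, p1 = df$p1, p2 = df$p2,
            phased_m = TRUE, phased_p = TRUE)
}

#' Draw crossover positions for one meiosis product
#'
#' Count is Poisson with mean `rate_multiplier * L / 100` for a chromosome
#' of genetic length L cM (no interference); positions are uniform on the
#' cM scale and mapped back to bp by inverse interpolation.
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome label.
#' @param rate_multiplier per-meiosis propensity multiplier.
#' @return sorted numeric bp positions (possibly empty).
#' @export
draw_crossovers <- function(map, chrom, rate_multiplier = 1) {
  i <- map$chrom == chrom
  if (!any(i)) stop("chromosome ", chrom, " not in genetic map")
  L <- max(map$pos_cM[i]) - min(map$pos_cM[i])
  n <- rpois(1, rate_multiplier * L / 100)
  if (n == 0 || L == 0) return(numeric(0))
  u <- runif(n, min(map$pos_cM[i]), max(map$pos_cM[i]))
  bp <- stats::approx(map$pos_cM[i], map$pos_bp[i], xout = u,
                      ties = "ordered")$y
  sort(bp)
}

#' Transmitted haplotype path of a gamete
#'
#' The path starts on `start_hap` (uniform when NULL) and switches parental
#' haplotype at each crossover.
#'
#' @param site_pos panel site positions of the chromosome.
#' @param crossovers sorted crossover bp positions.
#' @param start_hap 1 or 2, or NULL to draw uniformly.
#' @return integer vector of haplotype indices (1/2) per site.
#' @export
form_gamete <- function(site_pos, crossovers, start_hap = NULL) {
  if (is.unsorted(crossovers)) stop("crossovers must be sorted")
  if (is.null(start_hap)) start_hap <- sample(1:2, 1)
  1L + (start_hap - 1L + findInterval(site_pos, crossovers)) %% 2L
}

# haplotype index at an arbitrary position
hap_at <- function(pos, crossovers, start_hap) {
  1L + (start_hap - 1L + sum(crossovers <= pos)) %% 2L
}

# one meiotic product: start haplotype, crossovers, per-site path
draw_gamete <- function(map, chrom, site_pos, rate_multiplier = 1) {
  xo <- draw_crossovers(map, chrom, rate_multiplier)
  s <- sample(1:2, 1)
  list(start = s, crossovers = xo,
       path = form_gamete(site_pos, xo, s))
}

# flip a gamete's haplotype labels globally
flip_gamete <- function(g) {
  list(start = 3L - g$start, crossovers = g$crossovers, path = 3L - g$path)
}

#' Apply a mis-segregation mode to one chromosome's meioses
#'
#' Builds the transmitted-copy configuration for one chromosome given the
#' already drawn maternal and paternal gametes and a mode. Meiosis-I-type
#' trisomies place both homologues of the gaining parent at the
#' centromere; meiosis-II-type trisomies place two copies of one
#' homologue at the centromere with possible recombinant (both-homologue)
#' distal segments; mitotic trisomies duplicate one transmitted chromatid
#' exactly.
#'
#' @param mode one of `"euploid"`, `"maternal_MI_BPH"`, `"maternal_MII"`,
#'   `"maternal_monosomy"`, `"paternal_trisomy"`, `"paternal_monosomy"`,
#'   `"mitotic_trisomy"`, `"nullisomy"`, `"triploid"`.
#' @param gm,gp maternal and paternal gametes (from the internal gamete
#'   sampler); `triploid` expects `gm2`, an extra maternal gamete.
#' @param centromere_bp centromere position.
#' @param gm2 optional second maternal gamete.
#' @param mitotic_parent parent duplicated under `mitotic_trisomy`.
#' @return list with `m` (list of maternal paths), `p` (list of paternal
#'   paths), `k`, `origin`, `class_truth`, `m_crossovers`, `p_crossovers`.
#' @export
apply_missegregation <- function(mode, gm, gp, centromere_bp, gm2 = NULL,
                                 mitotic_parent = c("maternal", "paternal")) {
  mitotic_parent <- match.arg(mitotic_parent)
  second <- function(g1, g2, want_equal_at_cen) {
    h1 <- hap_at(centromere_bp, g1$crossovers, g1$start)
    h2 <- hap_at(centromere_bp, g2$crossovers, g2$start)
    if ((h1 == h2) != want_equal_at_cen) flip_gamete(g2) else g2
  }
  res <- switch(
    mode,
    euploid = list(m = list(gm), p = list(gp), k = 2L, origin = NA_character_,
                   class_truth = NA_character_),
    maternal_MI_BPH = {
      g2 <- second(gm, gm2, want_equal_at_cen = FALSE)
      list(m = list(gm, g2), p = list(gp), k = 3L, origin = "maternal",
           class_truth = "meiotic_MI_like")
    },
    maternal_MII = {
      g2 <- second(gm, gm2, want_equal_at_cen = TRUE)
      list(m = list(gm, g2), p = list(gp), k = 3L, origin = "maternal",
           class_truth = "meiotic_MII_like")
    },
    maternal_monosomy = list(m = list(), p = list(gp), k = 1L,
                             origin = "maternal", class_truth = NA_character_),
    paternal_trisomy = {
      g2 <- second(gp, gm2, want_equal_at_cen = FALSE)
      list(m = list(gm), p = list(gp, g2), k = 3L, origin = "paternal",
           class_truth = "meiotic_MI_like")
    },
    paternal_monosomy = list(m = list(gm), p = list(), k = 1L,
                             origin = "paternal", class_truth = NA_character_),
    mitotic_trisomy = {
      if (mitotic_parent == "maternal")
        list(m = list(gm, gm), p = list(gp), k = 3L, origin = "maternal",
             class_truth = "putative_mitotic")
      else
        list(m = list(gm), p = list(gp, gp), k = 3L, origin = "paternal",
             class_truth = "putative_mitotic")
    },
    nullisomy = list(m = list(), p = list(), k = 0L, origin = NA_character_,
                     class_truth = NA_character_),
    triploid = list(m = list(gm, gm2), p = list(gp), k = 3L,
                    origin = "maternal", class_truth = NA_character_),
    stop("unknown mis-segregation mode: ", mode)
  )
  res$m_crossovers <- if (length(res$m) == 1) res$m[[1]]$crossovers
                      else numeric(0)
  res$p_crossovers <- if (length(res$p) == 1) res$p[[1]]$crossovers
                      else numeric(0)
  res
}

#' Synthesize a noisy BAF vector from a transmitted-copy configuration
#'
#' Expected BAF is the alt-allele count among transmitted copies divided by
#' the copy number; observations are uniform on \[0, 1\] with probability
#' `pi0`, otherwise truncated-normal around the expectation. Nullisomic
#' chromosomes emit pure uniform noise.
#'
#' @param truth chromosome truth from [apply_missegregation()].
#' @param panel_chrom panel rows of the chromosome.
#' @param sigma,pi0 noise parameters.
#' @return numeric BAF vector.
#' @export
synthesize_baf <- function(truth, panel_chrom, sigma, pi0) {
  n <- nrow(panel_chrom)
  if (truth$k == 0L) return(runif(n))
  hapm <- cbind(panel_chrom$m1, panel_chrom$m2)
  happ <- cbind(panel_chrom$p1, panel_chrom$p2)
  alt <- rep(0L, n)
  for (g in truth$m) alt <- alt + hapm[cbind(seq_len(n), g$path)]
  for (g in truth$p) alt <- alt + happ[cbind(seq_len(n), g$path)]
  mu <- alt / truth$k
  u <- runif(n)
  b <- ifelse(u < pi0, runif(n), rtruncnorm01(mu, sigma))
  pmin(pmax(b, 0), 1)
}

# inverse-CDF sampler of N(mu, sigma) truncated to [0,1]
rtruncnorm01 <- function(mu, sigma) {
  lo <- pnorm((0 - mu) / sigma)
  hi <- pnorm((1 - mu) / sigma)
  qnorm(lo + runif(length(mu)) * (hi - lo)) * sigma + mu
}

#' Simulate a family of sibling embryos with full ground truth
#'
#' Shared phased parents, independent meioses per embryo, configurable
#' mis-segregation spectrum, optional shared per-meiosis crossover
#' propensity and propensity-aneuploidy coupling.
#'
#' @param config a [sim_config()].
#' @return list with `panel`, `map` (sex-averaged), `map_m`, `map_p`,
#'   `centromeres` (named bp vector), `bafs` (list of [embryo_baf()]),
#'   and `truth` (per embryo: mode, per-chromosome copy configuration).
#' @export
simulate_family <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  panel <- simulate_parental_haplotypes(config)
  chroms <- unique(panel$chrom)
  map_m <- uniform_genetic_map(chroms, config$chrom_length_bp,
                               config$maternal_cM)
  map_p <- uniform_genetic_map(chroms, config$chrom_length_bp,
                               config$paternal_cM)
  map <- uniform_genetic_map(chroms, config$chrom_length_bp,
                             (config$maternal_cM + config$paternal_cM) / 2)
  centromeres <- setNames(rep(round(config$centromere_frac *
                                      config$chrom_length_bp), length(chroms)),
                          chroms)
  spectrum <- config$aneuploidy
  q_base <- sum(spectrum)

  bafs <- vector("list", config$n_embryos)
  truth <- vector("list", config$n_embryos)
  for (e in seq_len(config$n_embryos)) {
    zm <- if (config$propensity_sd > 0) rnorm(1, 0, config$propensity_sd) else 0
    zp <- if (config$propensity_sd > 0) rnorm(1, 0, config$propensity_sd) else 0
    mult_m <- exp(zm - config$propensity_sd^2 / 2)
    mult_p <- exp(zp - config$propensity_sd^2 / 2)
    q <- if (config$coupling != 0 && q_base > 0 && q_base < 1)
      plogis(qlogis(q_base) - config$coupling * zm) else q_base
    mode <- if (q_base > 0 && runif(1) < q)
      sample(names(spectrum), 1, prob = spectrum) else "euploid"
    target <- if (mode %in% c("euploid", "triploid")) NA_character_
              else sample(chroms, 1)

    eid <- sprintf("embryo%02d", e)
    baf <- rep(NA_real_, nrow(panel))
    chrom_truth <- vector("list", length(chroms))
    names(chrom_truth) <- chroms
    for (ch in chroms) {
      i <- panel$chrom == ch
      sub <- panel[i, , drop = FALSE]
      gm <- draw_gamete(map_m, ch, sub$pos, mult_m)
      gp <- draw_gamete(map_p, ch, sub$pos, mult_p)
      ch_mode <- if (mode == "triploid") "triploid"
                 else if (!is.na(target) && ch == target) mode else "euploid"
      gm2 <- if (ch_mode %in% c("maternal_MI_BPH", "maternal_MII",
                                "paternal_trisomy", "triploid")) {
        src <- if (ch_mode == "paternal_trisomy") map_p else map_m
        mlt <- if (ch_mode == "paternal_trisomy") mult_p else mult_m
        draw_gamete(src, ch, sub$pos, mlt)
      } else NULL
      mit_parent <- if (ch_mode == "mitotic_trisomy")
        sample(c("maternal", "paternal"), 1) else "maternal"
      tr <- apply_missegregation(ch_mode, gm, gp, centromeres[[ch]],
                                 gm2 = gm2, mitotic_parent = mit_parent)
      tr$mode <- ch_mode
      chrom_truth[[ch]] <- tr
      baf[i] <- synthesize_baf(tr, sub, config$sigma, config$pi0)
    }
    bafs[[e]] <- embryo_baf(eid, "fam1", baf,
                            maternal_age = config$maternal_age,
                            paternal_age = config$paternal_age)
    truth[[e]] <- list(embryo_id = eid, mode = mode, target = target,
                       z_maternal = zm, z_paternal = zp,
                       chromosomes = chrom_truth)
  }
  names(bafs) <- names(truth) <- vapply(truth, `[[`, "", "embryo_id")
  list(panel = panel, map = map, map_m = map_m, map_p = map_p,
       centromeres = centromeres, bafs = bafs, truth = truth,
       config = config)
}
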