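#' Phase parents by transmission to sibling embryos
#'
#' For each parent and chromosome, derives per-embryo transmitted-allele
#' indicators at the parent's heterozygous sites from hard-thresholded BAF
#' (BAF < 0.25 -> 0 alt alleles, 0.25-0.75 -> 1, > 0.75 -> 2; when the
#' other parent is heterozygous only homozygous embryo calls are
#' informative), then chooses the site-to-site phase orientation that
#' minimizes the implied number of haplotype switches summed over
#' siblings (greedy left-to-right majority vote). The global orientation
#' per chromosome and parent is arbitrary and recorded in the
#' `"phase_flip_arbitrary"` attribute.
#'
#' @param panel a [snp_panel()] (phase flags ignored on input).
#' @param bafs list of [embryo_baf()] from sibling embryos.
#' @param min_siblings minimum sibling embryos required (default 3).
#' @return a phased [snp_panel()] with attribute `"phase_confidence"`
#'   (per-site vote margin in \[0, 1\], NA at uninformative sites).
#' @export
phase_by_transmission <- function(panel, bafs, min_siblings = 3) {
  if (length(bafs) < min_siblings)
    stop("at least three sibling embryos required (got ", length(bafs), ")")
  B <- vapply(bafs, function(e) e$baf, numeric(nrow(panel)))
  G <- matrix(NA_integer_, nrow(panel), ncol(B))
  G[!is.na(B) & B < 0.25] <- 0L
  G[!is.na(B) & B >= 0.25 & B <= 0.75] <- 1L
  G[!is.na(B) & B > 0.75] <- 2L

  out <- panel
  conf_m <- rep(NA_real_, nrow(panel))
  conf_p <- rep(NA_real_, nrow(panel))
  votes_m <- rep(NA_integer_, nrow(panel))
  votes_p <- rep(NA_integer_, nrow(panel))
  for (ch in unique(panel$chrom)) {
    i <- which(panel$chrom == ch)
    sub <- panel[i, , drop = FALSE]
    for (parent in c("m", "p")) {
      foc <- if (parent == "m") cbind(sub$m1, sub$m2) else cbind(sub$p1, sub$p2)
      oth <- if (parent == "m") cbind(sub$p1, sub$p2) else cbind(sub$m1, sub$m2)
      het <- foc[, 1] != foc[, 2]
      if (!any(het)) next
      ohet <- oth[, 1] != oth[, 2]
      Tm <- transmitted_indicator(G[i, , drop = FALSE], het, ohet, oth[, 1])
      ph <- consensus_phase(Tm[het, , drop = FALSE])
      phi <- ph$phi
      if (parent == "m") {
        out$m1[i][het] <- phi; out$m2[i][het] <- 1L - phi
        out$phased_m[i] <- TRUE
        conf_m[i][het] <- ph$conf
        votes_m[i][het] <- ph$votes
      } else {
        out$p1[i][het] <- phi; out$p2[i][het] <- 1L - phi
        out$phased_p[i] <- TRUE
        conf_p[i][het] <- ph$conf
        votes_p[i][het] <- ph$votes
      }
    }
  }
  attr(out, "phase_confidence") <- data.frame(maternal = conf_m,
                                              paternal = conf_p,
                                              maternal_votes = votes_m,
                                              paternal_votes = votes_p)
  attr(out, "phase_flip_arbitrary") <- TRUE
  out
}

# transmitted alt-allele indicator per embryo at focal-het sites
transmitted_indicator <- function(G, het, ohet, ohom_allele) {
  Tm <- matrix(NA_integer_, nrow(G), ncol(G))
  hom_rows <- het & !ohet
  if (any(hom_rows)) {
    t <- G[hom_rows, , drop = FALSE] - ohom_allele[hom_rows]
    t[t < 0L | t > 1L] <- NA_integer_
    Tm[hom_rows, ] <- t
  }
  dh <- het & ohet
  if (any(dh)) {
    g <- G[dh, , drop = FALSE]
    t <- matrix(NA_integer_, nrow(g), ncol(g))
    t[g == 0L] <- 0L
    t[g == 2L] <- 1L
    Tm[dh, ] <- t
  }
  Tm
}

# phi[s] = alt-allele indicator of haplotype 1 at het site s, chosen to
# minimize implied switches across siblings. Each embryo carries an
# exponentially smoothed haplotype score v in [-1, 1] (+1 = haplotype 1);
# the orientation at each site is the weighted majority vote against those
# scores, so an isolated mis-thresholded site cannot flip the chain.
# conf = per-site normalized vote margin.
greedy_phase <- function(Tm, lambda = 0.3) {
  n <- nrow(Tm); ne <- ncol(Tm)
  phi <- integer(n)
  conf <- rep(NA_real_, n)
  votes <- integer(n)
  v <- rep(0, ne)
  for (s in seq_len(n)) {
    t <- Tm[s, ]
    have <- !is.na(t) & abs(v) > 0  # voters with an established score
    eta <- ifelse(t[have] == 1L, 1, -1)  # sign under phi = 1
    score <- sum(eta * v[have])
    phi[s] <- if (score >= 0) 1L else 0L
    votes[s] <- sum(have)
    denom <- sum(abs(v[have]))
    conf[s] <- if (denom > 0) abs(score) / denom else NA_real_
    upd <- !is.na(t)
    agree <- ifelse(t[upd] == phi[s], 1, -1)
    v[upd] <- (1 - lambda) * v[upd] + lambda * agree
  }
  list(phi = phi, conf = conf, votes = votes)
}

# run the greedy chain in both directions; a chain vote error persists to
# the end of its pass, so the two passes disagree exactly on mis-phased
# segments. Conflicting sites keep the forward orientation but get zero
# confidence, which removes them from the informative set downstream.
consensus_phase <- function(Tm) {
  fw <- greedy_phase(Tm)
  n <- nrow(Tm)
  bwv <- greedy_phase(Tm[rev(seq_len(n)), , drop = FALSE])
  bw_phi <- rev(bwv$phi)
  bw_conf <- rev(bwv$conf)
  agree <- fw$phi == bw_phi
  flip <- mean(agree, na.rm = TRUE) < 0.5  # passes differ by a global flip
  consensus <- if (flip) !agree else agree
  conf <- pmin(fw$conf, bw_conf)
  conf[!consensus] <- 0
  list(phi = fw$phi, conf = conf,
       votes = pmin(fw$votes, rev(bwv$votes)))
}

#' Call crossovers from posterior haplotype marginals
#'
#' On a chromosome called disomic, a crossover is detected between
#' consecutive confidently decoded informative sites (focal parent
#' heterozygous, max marginal >= `gamma`) where the maximum-posterior
#' source haplotype flips. The reported resolution interval is widened
#' from the detection sites to the nearest informative site on each side
#' whose marginal reaches `flank_conf`: a single aberrant observation next
#' to the true switch can clear `gamma` for the wrong haplotype (the
#' uniform mixture component caps the per-site likelihood ratio) but not
#' `flank_conf`, so the widened interval still contains the true
#' crossover. On clean data the next informative site is already decoded
#' near certainty and the interval is unchanged.
#'
#' @param marginal n x 2 haplotype marginal matrix from
#'   [posterior_decode()] (`maternal` or `paternal` element).
#' @param pos site positions of the chromosome.
#' @param informative logical; focal-parent heterozygous sites.
#' @param gamma detection threshold on both flank marginals (default 0.9).
#' @param flank_conf marginal level to which the reported flanks are
#'   extended (default 0.999; falls back to the detection site near
#'   chromosome ends).
#' @return data frame with `left`, `right`, `gamma_left`, `gamma_right`.
#' @export
call_crossovers <- function(marginal, pos, informative, gamma = 0.9,
                            flank_conf = 0.999) {
  if (is.null(marginal)) stop("no haplotype marginals: unphased input?")
  conf <- pmax(marginal[, 1], marginal[, 2])
  src <- ifelse(marginal[, 1] >= 0.5, 1L, 2L)
  use <- which(informative & conf >= gamma)
  ev <- data.frame(left = integer(0), right = integer(0),
                   gamma_left = numeric(0), gamma_right = numeric(0))
  if (length(use) < 2) return(ev)
  flip <- which(diff(src[use]) != 0L)
  if (!length(flip)) return(ev)
  inf_idx <- which(informative)
  li <- vapply(flip, function(f) {
    i <- use[f]
    cand <- inf_idx[inf_idx <= i & src[inf_idx] == src[i] &
                      conf[inf_idx] >= flank_conf]
    if (length(cand)) max(cand) else i
  }, 0L)
  ri <- vapply(flip, function(f) {
    j <- use[f + 1L]
    cand <- inf_idx[inf_idx >= j & src[inf_idx] == src[j] &
                      conf[inf_idx] >= flank_conf]
    if (length(cand)) min(cand) else j
  }, 0L)
  data.frame(left = pos[li], right = pos[ri],
             gamma_left = conf[li], gamma_right = conf[ri])
}

#' Filter artifact crossovers and flag outlier embryos
#'
#' Two cohort-level filters: (i) clusters of events with overlapping
#' intervals shared by more than half of at least three siblings are
#' parental phase errors, not crossovers (true crossovers are
#' meiosis-specific), and are removed; (ii) embryos whose per-parent total
#' autosomal crossover count deviates more than `sd_cut` standard
#' deviations from the cohort parent-specific mean are flagged for
#' exclusion from phenotype tables.
#'
#' @param events data frame with columns `embryo_id`, `family_id`,
#'   `parent`, `chrom`, `left`, `right` (plus any others, preserved).
#' @param embryos data frame with columns `embryo_id`, `family_id` listing
#'   all embryos contributing (so zero-count embryos enter the cohort
#'   mean).
#' @param sd_cut exclusion threshold in standard deviations (default 3).
#' @param share_frac sibling-sharing fraction above which an interval is an
#'   artifact (default 0.5).
#' @return list with `events` (kept), `removed` (artifact events),
#'   `excluded_embryos` (data frame `embryo_id`, `parent`, `count`,
#'   `cohort_mean`, `cohort_sd`).
#' @export
filter_artifacts <- function(events, embryos, sd_cut = 3, share_frac = 0.5) {
  keep <- rep(TRUE, nrow(events))
  if (nrow(events)) {
    nsib <- table(embryos$family_id)
    grp <- paste(events$family_id, events$parent, events$chrom)
    for (g in unique(grp)) {
      idx <- which(grp == g)
      fam <- events$family_id[idx[1]]
      ns <- as.integer(nsib[fam])
      if (is.na(ns) || ns < 3) next
      # cluster events whose intervals overlap (a parental phase error
      # produces the same switch in every sibling, but noisy flank
      # posteriors can shift the reported flanking SNPs slightly)
      o <- idx[order(events$left[idx])]
      cl <- integer(length(o)); cur <- 1L; cl[1] <- 1L
      if (length(o) > 1) {
        hi <- events$right[o[1]]
        for (j in 2:length(o)) {
          if (events$left[o[j]] > hi) cur <- cur + 1L
          cl[j] <- cur
          hi <- max(hi, events$right[o[j]])
        }
      }
      for (cc in unique(cl)) {
        ii <- o[cl == cc]
        nshare <- length(unique(events$embryo_id[ii]))
        if (nshare > share_frac * ns) keep[ii] <- FALSE
      }
    }
  }
  kept <- events[keep, , drop = FALSE]
  removed <- events[!keep, , drop = FALSE]

  excluded <- data.frame(embryo_id = character(), parent = character(),
                         count = numeric(), cohort_mean = numeric(),
                         cohort_sd = numeric(), stringsAsFactors = FALSE)
  for (par in c("maternal", "paternal")) {
    cnt <- setNames(rep(0, nrow(embryos)), embryos$embryo_id)
    if (nrow(kept)) {
      tb <- table(kept$embryo_id[kept$parent == par])
      cnt[names(tb)] <- as.numeric(tb)
    }
    mu <- mean(cnt); s <- sd(cnt)
    if (is.na(s) || s == 0) next
    out <- which(abs(cnt - mu) > sd_cut * s)
    if (length(out))
      excluded <- rbind(excluded, data.frame(
        embryo_id = names(cnt)[out], parent = par,
        count = as.numeric(cnt[out]), cohort_mean = mu, cohort_sd = s,
        stringsAsFactors = FALSE))
  }
  list(events = kept, removed = removed, excluded_embryos = excluded)
}

#' Analyze one family: phase, fit, call ploidy and crossovers
#'
#' End-to-end driver: phases the parents from the sibling embryos, fits
#' [karyohmm()] per embryo, optionally re-phases each chromosome using
#' only embryos called disomic there and refits, then calls crossovers on
#' disomic chromosomes.
#'
#' @param panel a [snp_panel()] (unphased input is phased from the
#'   siblings; phased input is used as-is when `phase = FALSE`).
#' @param bafs list of [embryo_baf()].
#' @param map a [genetic_map()].
#' @param centromeres named bp vector.
#' @param params [emission_params()] or NULL (per-embryo [fit_noise()]).
#' @param tau ploidy call threshold.
#' @param gamma crossover flank posterior threshold.
#' @param phase phase the panel from siblings (default TRUE).
#' @param refine re-phase using disomic embryos and refit (default TRUE).
#' @param min_phase_conf,min_phase_votes heterozygous sites whose
#'   transmission-phasing vote margin falls below `min_phase_conf`, or
#'   that were phased on fewer than `min_phase_votes` voting embryos, are
#'   unreliable: their BAF is masked for the HMM fits and they are left
#'   out of the informative set for crossover calling (resolution
#'   intervals simply span them). A locally inverted site would otherwise
#'   displace the decoded switch. Ignored for pre-phased input
#'   (`phase = FALSE`).
#' @param family_id family identifier stamped on outputs.
#' @return a [callset()]; the calls table carries per-embryo flags
#'   (`complex_aneuploid`, `genome_wide_abnormal`) and `meta` the fitted
#'   noise parameters.
#' @export
analyze_family <- function(panel, bafs, map, centromeres = NULL,
                           params = NULL, tau = 0.9, gamma = 0.9,
                           phase = TRUE, refine = TRUE,
                           min_phase_conf = 0.75, min_phase_votes = 3,
                           family_id = bafs[[1]]$family_id) {
  work <- if (phase) phase_by_transmission(panel, bafs) else panel
  phconf <- attr(work, "phase_confidence")
  if (is.null(phconf))
    phconf <- data.frame(maternal = rep(1, nrow(panel)),
                         paternal = rep(1, nrow(panel)),
                         maternal_votes = rep(Inf, nrow(panel)),
                         paternal_votes = rep(Inf, nrow(panel)))
  phase_bad <- function() {
    bm <- work$m1 != work$m2 &
      (is.na(phconf$maternal) | phconf$maternal < min_phase_conf |
         phconf$maternal_votes < min_phase_votes)
    bp <- work$p1 != work$p2 &
      (is.na(phconf$paternal) | phconf$paternal < min_phase_conf |
         phconf$paternal_votes < min_phase_votes)
    list(m = bm, p = bp, mask = bm | bp)
  }
  bad <- phase_bad()
  fit_params <- params
  fit_all <- function() {
    lapply(bafs, function(eb) {
      b <- eb$baf
      b[bad$mask] <- NA_real_
      masked <- embryo_baf(eb$embryo_id, eb$family_id, b,
                           eb$maternal_age, eb$paternal_age)
      p <- if (is.null(fit_params)) fit_noise(b, work, map) else fit_params
      karyohmm(masked, work, map, params = p, tau = tau,
               centromeres = centromeres)
    })
  }
  fits <- fit_all()

  if (phase && refine) {
    for (ch in unique(panel$chrom)) {
      dis <- vapply(fits, function(f) f$chromosomes[[ch]]$call == "disomy",
                    TRUE)
      if (sum(dis) >= 3 && any(!dis)) {
        i <- panel$chrom == ch
        sub_phased <- phase_by_transmission(
          panel[i, , drop = FALSE],
          lapply(bafs[dis], function(e)
            embryo_baf(e$embryo_id, e$family_id, e$baf[i])))
        work$m1[i] <- sub_phased$m1; work$m2[i] <- sub_phased$m2
        work$p1[i] <- sub_phased$p1; work$p2[i] <- sub_phased$p2
        phconf[i, ] <- attr(sub_phased, "phase_confidence")
      }
    }
    bad <- phase_bad()
    prev <- fits
    fit_params_each <- lapply(prev, function(f) f$params)
    fits <- lapply(seq_along(bafs), function(j) {
      eb <- bafs[[j]]
      b <- eb$baf
      b[bad$mask] <- NA_real_
      masked <- embryo_baf(eb$embryo_id, eb$family_id, b,
                           eb$maternal_age, eb$paternal_age)
      karyohmm(masked, work, map, params = fit_params_each[[j]], tau = tau,
               centromeres = centromeres)
    })
    names(fits) <- names(bafs)
  }

  calls <- do.call(rbind, lapply(fits, summary))
  rownames(calls) <- NULL
  flags <- do.call(rbind, lapply(split(calls, calls$embryo_id), function(d) {
    f <- flag_embryo(d)
    data.frame(embryo_id = d$embryo_id[1],
               complex_aneuploid = f$complex_aneuploid,
               genome_wide_abnormal = f$genome_wide_abnormal,
               stringsAsFactors = FALSE)
  }))
  calls <- merge(calls, flags, by = "embryo_id", sort = FALSE)
  calls$family_id <- family_id

  events <- empty_events()
  events$family_id <- character(0)
  for (f in fits) {
    for (r in f$chromosomes) {
      if (r$call != "disomy") next
      i <- work$chrom == r$chrom
      sub <- work[i, , drop = FALSE]
      for (par in c("maternal", "paternal")) {
        marg <- r$decode[[par]]
        inf <- if (par == "maternal") sub$m1 != sub$m2 else sub$p1 != sub$p2
        inf <- inf & !(if (par == "maternal") bad$m[i] else bad$p[i])
        ev <- call_crossovers(marg, sub$pos, inf, gamma = gamma)
        if (nrow(ev))
          events <- rbind(events, data.frame(
            embryo_id = f$embryo_id, parent = par, chrom = r$chrom,
            left = ev$left, right = ev$right,
            gamma_left = ev$gamma_left, gamma_right = ev$gamma_right,
            family_id = family_id, stringsAsFactors = FALSE))
      }
    }
  }
  sig <- vapply(fits, function(f) f$params$sigma, 0)
  pi0 <- vapply(fits, function(f) f$params$pi0, 0)
  callset(calls, events,
          meta = list(family_id = family_id, tau = tau, gamma = gamma,
                      sigma = as.list(setNames(sig, names(fits))),
                      pi0 = as.list(setNames(pi0, names(fits))),
                      version = as.character(utils::packageVersion("meiotrace"))))
}
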