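#' Per-parent crossover count phenotype
#'
#' Mean autosomal crossover count across a subject's euploid embryos,
#' computed per parent. Embryos listed in `exclude` (for example from
#' [filter_artifacts()]) are dropped before averaging.
#'
#' @param events filtered crossover events (columns `embryo_id`, `parent`).
#' @param embryos data frame listing the euploid embryos entering the
#'   phenotype (`embryo_id`, `family_id`); zero-count embryos contribute 0.
#' @param parent `"maternal"` or `"paternal"`.
#' @param exclude embryo ids to drop.
#' @param min_embryos minimum embryos per subject (default 3).
#' @return data frame with `family_id`, `mean_count`, `n_embryos`.
#' @export
crossover_count_phenotype <- function(events, embryos,
                                      parent = c("maternal", "paternal"),
                                      exclude = character(),
                                      min_embryos = 3) {
  parent <- match.arg(parent)
  embryos <- embryos[!embryos$embryo_id %in% exclude, , drop = FALSE]
  cnt <- setNames(rep(0, nrow(embryos)), embryos$embryo_id)
  ev <- events[events$parent == parent &
                 events$embryo_id %in% embryos$embryo_id, , drop = FALSE]
  if (nrow(ev)) {
    tb <- table(ev$embryo_id)
    cnt[names(tb)] <- as.numeric(tb)
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(embryos)),
                                     embryos$family_id), function(i) {
    if (length(i) < min_embryos)
      stop("fewer than ", min_embryos, " embryos for subject ",
           embryos$family_id[i[1]])
    data.frame(family_id = embryos$family_id[i[1]],
               mean_count = mean(cnt[embryos$embryo_id[i]]),
               n_embryos = length(i), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of crossovers overlapping recombination hotspots
#'
#' An event counts as in-hotspot when its resolution interval overlaps at
#' least one hotspot interval by at least 1 bp (`rule = "overlap"`), or
#' when its midpoint falls inside a hotspot (`rule = "midpoint"`).
#'
#' @param events crossover events (`chrom`, `left`, `right`, 1-based).
#' @param hotspots an [interval_track()] (merged BED).
#' @param rule membership rule.
#' @return fraction in \[0, 1\] (0 when the track or event set is empty).
#' @export
hotspot_occupancy <- function(events, hotspots,
                              rule = c("overlap", "midpoint")) {
  rule <- match.arg(rule)
  if (nrow(events) == 0) return(NA_real_)
  if (nrow(hotspots) == 0) return(0)
  hs <- track_to_granges(hotspots)
  q <- if (rule == "overlap") {
    GenomicRanges::GRanges(events$chrom,
                           IRanges::IRanges(events$left, events$right))
  } else {
    mid <- floor((events$left + events$right) / 2)
    GenomicRanges::GRanges(events$chrom, IRanges::IRanges(mid, mid))
  }
  hits <- GenomicRanges::countOverlaps(q, hs, minoverlap = 1L)
  mean(hits > 0)
}

#' Sequence and replication-timing context of crossovers
#'
#' At each event midpoint (`floor((left + right) / 2)`), reads the value of
#' the covering replication-timing interval (events without a covering
#' interval are skipped) and the G+C fraction of the +/- `flank` bp window
#' around the midpoint (window clipped at contig ends).
#'
#' @param events crossover events.
#' @param track replication-timing [interval_track()] (bedGraph values) or
#'   NULL.
#' @param fasta path to a FASTA file, or a `Biostrings::DNAStringSet`, or
#'   NULL.
#' @param flank half-window for GC content (default 500 bp).
#' @return list with `mean_timing`, `mean_gc`, and the per-event vectors
#'   `timing`, `gc`.
#' @export
crossover_context <- function(events, track = NULL, fasta = NULL,
                              flank = 500) {
  mid <- floor((events$left + events$right) / 2)
  timing <- rep(NA_real_, nrow(events))
  gc <- rep(NA_real_, nrow(events))
  if (!is.null(track) && nrow(events)) {
    for (ch in unique(events$chrom)) {
      tr <- track[track$chrom == ch, , drop = FALSE]
      ei <- which(events$chrom == ch)
      if (nrow(tr) == 0 || !length(ei)) next
      # midpoint (1-based) inside [start, end) 0-based half-open
      j <- findInterval(mid[ei] - 1L, tr$start)
      ok <- j >= 1 & (mid[ei] - 1L) < tr$end[pmax(j, 1)]
      timing[ei[ok]] <- tr$value[j[ok]]
    }
  }
  if (!is.null(fasta) && nrow(events)) {
    seqs <- if (inherits(fasta, "DNAStringSet")) fasta
            else Biostrings::readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    for (ch in unique(events$chrom)) {
      if (!ch %in% names(seqs))
        stop("chromosome ", ch, " not in FASTA")
      L <- length(seqs[[ch]])
      ei <- which(events$chrom == ch)
      if (any(mid[ei] < 1 | mid[ei] > L))
        stop("crossover midpoint outside FASTA contig ", ch)
      lo <- pmax(mid[ei] - flank, 1)
      hi <- pmin(mid[ei] + flank, L)
      v <- Biostrings::Views(seqs[[ch]], start = lo, end = hi)
      gc[ei] <- Biostrings::letterFrequency(v, "GC", as.prob = TRUE)[, 1]
    }
  }
  list(mean_timing = if (all(is.na(timing))) NA_real_
                     else mean(timing, na.rm = TRUE),
       mean_gc = if (all(is.na(gc))) NA_real_ else mean(gc, na.rm = TRUE),
       timing = timing, gc = gc)
}

#' Aneuploidy summary tables and ratio tests
#'
#' Excludes embryos flagged complex-aneuploid or genome-wide abnormal,
#' tabulates aneuploid chromosome calls by chromosome, type and parental
#' origin, and tests the trisomy:monosomy and maternal:paternal ratios
#' against 0.5 with exact two-sided binomial tests.
#'
#' @param calls per-chromosome call table (columns `embryo_id`, `chrom`,
#'   `call`, `origin`, and optionally the flag columns from
#'   [analyze_family()]).
#' @return list with `by_chrom` (counts), `ratios` (fractions with
#'   binomial p-values and 95\% CIs), `fraction_embryos_aneuploid`, and
#'   the excluded embryo ids.
#' @export
aneuploidy_summary <- function(calls) {
  excl <- character()
  if (all(c("complex_aneuploid", "genome_wide_abnormal") %in% names(calls))) {
    bad <- calls$complex_aneuploid | calls$genome_wide_abnormal
    excl <- unique(calls$embryo_id[bad])
    calls <- calls[!calls$embryo_id %in% excl, , drop = FALSE]
  }
  type <- ifelse(calls$call %in% c("trisomy_m", "trisomy_p"), "trisomy",
                 ifelse(calls$call %in% c("monosomy_m", "monosomy_p"),
                        "monosomy", NA))
  aneu <- !is.na(type)
  if (!any(aneu)) {
    return(list(by_chrom = data.frame(), ratios = data.frame(
      ratio = c("trisomy", "maternal"), fraction = NA_real_, n = 0L,
      p_value = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_),
      fraction_embryos_aneuploid = 0, excluded = excl))
  }
  by_chrom <- as.data.frame(table(chrom = calls$chrom[aneu],
                                  type = type[aneu],
                                  origin = calls$origin[aneu]),
                            stringsAsFactors = FALSE)
  names(by_chrom)[4] <- "count"

  ratio_row <- function(label, x, n) {
    bt <- if (n > 0) binom.test(x, n, p = 0.5) else NULL
    data.frame(ratio = label, fraction = if (n > 0) x / n else NA_real_,
               n = n,
               p_value = if (n > 0) bt$p.value else NA_real_,
               ci_lo = if (n > 0) bt$conf.int[1] else NA_real_,
               ci_hi = if (n > 0) bt$conf.int[2] else NA_real_,
               stringsAsFactors = FALSE)
  }
  n_tri <- sum(type == "trisomy", na.rm = TRUE)
  n_mono <- sum(type == "monosomy", na.rm = TRUE)
  n_mat <- sum(aneu & calls$origin == "maternal", na.rm = TRUE)
  n_pat <- sum(aneu & calls$origin == "paternal", na.rm = TRUE)
  ratios <- rbind(ratio_row("trisomy", n_tri, n_tri + n_mono),
                  ratio_row("maternal", n_mat, n_mat + n_pat))

  frac_aneu <- mean(tapply(aneu, calls$embryo_id, any))
  list(by_chrom = by_chrom, ratios = ratios,
       fraction_embryos_aneuploid = as.numeric(frac_aneu), excluded = excl)
}

#' Binomial ratio with exact test
#'
#' Convenience for aggregate published-style counts: fraction `x / n` with
#' an exact two-sided binomial test against 0.5.
#'
#' @param x successes, `n` trials.
#' @param n trials.
#' @return list with `fraction`, `p_value`, `conf_int`.
#' @export
binomial_ratio <- function(x, n) {
  bt <- binom.test(x, n, p = 0.5)
  list(fraction = x / n, p_value = bt$p.value,
       conf_int = as.numeric(bt$conf.int))
}

#' Overdispersion of per-patient aneuploidy incidence
#'
#' Fits a binomial GLM (logit link) of affected embryo counts on maternal
#' age and age squared, computes the Pearson dispersion
#' `phi = sum(r_pearson^2) / (n - p)`, and compares it with a parametric
#' bootstrap null: `B` datasets simulated as pure binomial at the fitted
#' means, each refitted, giving `p = (1 + #(phi_b >= phi)) / (B + 1)`.
#'
#' @param affected,total per-patient affected and total embryo counts.
#' @param age maternal ages (years).
#' @param B bootstrap replicates (default 999).
#' @return list of class `overdispersion_test` with `phi`, `p_value`,
#'   `B`, `coefficients`, `phi_null` (bootstrap draws).
#' @export
overdispersion_test <- function(affected, total, age, B = 999) {
  keep <- total > 0
  affected <- affected[keep]; total <- total[keep]; age <- age[keep]
  n <- length(affected)
  X <- cbind(1, age, age^2)
  p <- ncol(X)
  if (n <= p) stop("need more patients than model parameters")
  fit <- glm.fit(X, cbind(affected, total - affected), family = binomial())
  mu_hat <- fit$fitted.values
  phi_of <- function(y) {
    # bootstrap refits start from the generating means: same IRLS optimum,
    # fewer iterations
    f <- glm.fit(X, cbind(y, total - y), family = binomial(),
                 mustart = mu_hat)
    mu <- f$fitted.values
    sum((y / total - mu)^2 * total / (mu * (1 - mu))) / (n - p)
  }
  phi <- sum((affected / total - mu_hat)^2 * total /
               (mu_hat * (1 - mu_hat))) / (n - p)
  phi_null <- vapply(seq_len(B), function(b)
    phi_of(rbinom(n, total, mu_hat)), 0)
  structure(list(phi = phi,
                 p_value = (1 + sum(phi_null >= phi)) / (B + 1),
                 B = B,
                 coefficients = setNames(fit$coefficients,
                                         c("(Intercept)", "age", "age2")),
                 phi_null = phi_null),
            class = "overdispersion_test")
}

#' @export
print.overdispersion_test <- function(x, ...) {
  cat("Binomial overdispersion test (parametric bootstrap, B = ", x$B,
      ")\n  dispersion phi = ", signif(x$phi, 4),
      ", p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Cross-chromosome intraclass correlation of crossover counts
#'
#' Counts are z-standardized within chromosome (column), then a one-way
#' random-effects ICC(1) with embryo as the grouping factor is computed
#' from the ANOVA mean squares: `(MSB - MSW) / (MSB + (k - 1) MSW)` for k
#' observations (chromosomes) per embryo. The CI is a percentile bootstrap
#' over embryos.
#'
#' @param counts numeric matrix, embryos x chromosomes.
#' @param n_boot bootstrap replicates for the CI (0 = skip).
#' @param conf confidence level.
#' @return list of class `icc_result` with `icc`, `ci`, `n_embryos`,
#'   `n_chrom`.
#' @export
crossover_icc <- function(counts, n_boot = 200, conf = 0.95) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("ICC needs at least two chromosomes")
  z <- scale(counts)
  icc1 <- function(zz) {
    n <- nrow(zz); k <- ncol(zz)
    gm <- mean(zz); rm <- rowMeans(zz)
    msb <- k * sum((rm - gm)^2) / (n - 1)
    msw <- sum((zz - rm)^2) / (n * (k - 1))
    (msb - msw) / (msb + (k - 1) * msw)
  }
  est <- icc1(z)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    bs <- vapply(seq_len(n_boot), function(b) {
      icc1(z[sample.int(nrow(z), replace = TRUE), , drop = FALSE])
    }, 0)
    a <- (1 - conf) / 2
    ci <- as.numeric(quantile(bs, c(a, 1 - a)))
  }
  structure(list(icc = est, ci = ci, conf = conf,
                 n_embryos = nrow(counts), n_chrom = ncol(counts)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat("One-way random-effects ICC(1): ", signif(x$icc, 4), sep = "")
  if (!all(is.na(x$ci)))
    cat("  (", 100 * x$conf, "% CI ", signif(x$ci[1], 3), ", ",
        signif(x$ci[2], 3), ")", sep = "")
  cat("\n  ", x$n_embryos, " embryos x ", x$n_chrom, " chromosomes\n",
      sep = "")
  invisible(x)
}

#' Per-embryo per-chromosome crossover count matrix
#'
#' Helper assembling the input of [crossover_icc()] from filtered events.
#'
#' @param events crossover events.
#' @param embryo_ids embryos to include (rows).
#' @param chroms chromosomes to include (columns).
#' @param parent `"maternal"` or `"paternal"`.
#' @return integer matrix, embryos x chromosomes.
#' @export
crossover_count_matrix <- function(events, embryo_ids, chroms,
                                   parent = c("maternal", "paternal")) {
  parent <- match.arg(parent)
  m <- matrix(0L, length(embryo_ids), length(chroms),
              dimnames = list(embryo_ids, chroms))
  ev <- events[events$parent == parent &
                 events$embryo_id %in% embryo_ids &
                 events$chrom %in% chroms, , drop = FALSE]
  if (nrow(ev)) {
    tb <- table(factor(ev$embryo_id, embryo_ids),
                factor(ev$chrom, chroms))
    m[] <- as.integer(tb)
  }
  m
}
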