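#' Fit the haplotype-transmission HMM to one embryo
#'
#' For every chromosome of the panel, scores the six copy-number
#' hypotheses ([cn_hypotheses()]) by forward log-likelihood, converts them
#' to posterior probabilities under `prior`, calls the chromosome when the
#' maximum posterior reaches `tau`, and decodes the called hypothesis by
#' forward-backward. For trisomy calls a per-site BPH posterior (the
#' probability that the two same-parent copies are distinct haplotypes) is
#' retained; with centromere coordinates the trisomy is classified as
#' MI-like, MII-like or putative mitotic (see
#' [classify_trisomy_origin()]).
#'
#' @param baf an [embryo_baf()] or a numeric BAF vector aligned to `panel`.
#' @param panel a phased [snp_panel()].
#' @param map a [genetic_map()].
#' @param params [emission_params()]; when `NULL`, estimated by
#'   [fit_noise()].
#' @param prior named prior over hypotheses (default uniform).
#' @param tau posterior threshold below which a chromosome is "nocall".
#' @param centromeres optional named vector of centromere bp positions per
#'   chromosome (enables meiotic-class labels).
#' @param bph_window half-width (bp) of the pericentromeric window used for
#'   trisomy classification.
#' @return an object of class `karyohmm`; see [summary.karyohmm()].
#' @export
karyohmm <- function(baf, panel, map, params = NULL, prior = NULL,
                     tau = 0.9, centromeres = NULL, bph_window = 5e6) {
  eb <- if (inherits(baf, "embryo_baf")) baf else embryo_baf("embryo", "fam", baf)
  if (length(eb$baf) != nrow(panel))
    stop("BAF length does not match panel")
  if (is.null(params)) params <- fit_noise(eb$baf, panel, map)
  hyps <- cn_hypotheses()
  if (is.null(prior)) prior <- setNames(rep(1 / length(hyps), length(hyps)), hyps)

  chroms <- unique(panel$chrom)
  res <- lapply(chroms, function(ch) {
    i <- panel$chrom == ch
    sub <- panel[i, , drop = FALSE]
    b <- eb$baf[i]
    ll <- vapply(hyps, function(h)
      forward_loglik(b, sub, map, h, params, chrom = ch), 0)
    cc <- call_copy_number(ll, prior = prior, tau = tau)
    dec_h <- if (cc$call == "nocall") "disomy" else cc$call
    dec <- posterior_decode(b, sub, map, dec_h, params, chrom = ch)
    stD <- enumerate_states(dec_h)
    fit_mu <- if (stD$k == 0L) rep(0.5, nrow(sub))
              else rowSums(dec$gamma * state_dosage(stD, sub))
    bph <- bph_profile(dec)
    cls <- NA_character_
    if (!is.null(bph) && cc$call %in% c("trisomy_m", "trisomy_p") &&
        !is.null(centromeres) && ch %in% names(centromeres)) {
      cls <- classify_trisomy_origin(bph, sub$pos, centromeres[[ch]],
                                     window = bph_window)
    }
    list(chrom = ch, loglik = ll, posterior = cc$posterior, call = cc$call,
         origin = cc$origin, k = cc$k, call_posterior = cc$call_posterior,
         decoded_hypothesis = dec_h, decode = dec, bph = bph,
         meiotic_class = cls, pos = sub$pos, fitted = fit_mu)
  })
  names(res) <- chroms
  structure(list(embryo_id = eb$embryo_id, family_id = eb$family_id,
                 params = params, prior = prior, tau = tau,
                 chromosomes = res, baf = eb$baf, panel_chrom = panel$chrom),
            class = "karyohmm")
}

# posterior probability that the two same-parent copies of a trisomy state
# are distinct haplotypes (both parental homologues present)
bph_profile <- function(decode) {
  st <- decode$states
  pair <- if (ncol(st$mat) == 2) st$mat else if (ncol(st$pat) == 2) st$pat
  else return(NULL)
  as.numeric(decode$gamma %*% as.numeric(pair[, 1] != pair[, 2]))
}

#' @export
print.karyohmm <- function(x, ...) {
  cat("<karyohmm> embryo ", x$embryo_id, ": ", length(x$chromosomes),
      " chromosome(s); sigma = ", x$params$sigma, ", pi0 = ", x$params$pi0,
      "\n", sep = "")
  print(summary(x))
  invisible(x)
}

#' Summarize a karyohmm fit
#'
#' @param object a [karyohmm()] fit.
#' @param ... unused.
#' @return data frame of per-chromosome calls with posterior support.
#' @export
summary.karyohmm <- function(object, ...) {
  do.call(rbind, lapply(object$chromosomes, function(r) {
    data.frame(embryo_id = object$embryo_id, chrom = r$chrom, call = r$call,
               origin = r$origin, k = r$k,
               meiotic_class = r$meiotic_class,
               posterior = r$call_posterior,
               loglik = max(r$loglik), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}

#' @export
coef.karyohmm <- function(object, ...) {
  c(sigma = object$params$sigma, pi0 = object$params$pi0)
}

#' @export
logLik.karyohmm <- function(object, ...) {
  # model evidence: per chromosome, log sum_h prior(h) exp(logL_h)
  val <- sum(vapply(object$chromosomes, function(r) {
    lp <- r$loglik + log(object$prior[names(r$loglik)])
    m <- max(lp)
    m + log(sum(exp(lp - m)))
  }, 0))
  structure(val, df = 2L, class = "logLik")
}

#' @export
fitted.karyohmm <- function(object, ...) {
  out <- rep(NA_real_, length(object$baf))
  for (r in object$chromosomes)
    out[object$panel_chrom == r$chrom] <- r$fitted
  out
}

#' @export
residuals.karyohmm <- function(object, ...) object$baf - fitted(object)

#' @export
plot.karyohmm <- function(x, chrom = names(x$chromosomes)[1], ...) {
  r <- x$chromosomes[[chrom]]
  i <- which(x$panel_chrom == chrom)
  graphics::plot(r$pos, x$baf[i], pch = 16, cex = 0.3,
                 col = grDevices::grey(0.4), xlab = paste0(chrom, " position (bp)"),
                 ylab = "BAF", ylim = c(0, 1),
                 main = paste0(x$embryo_id, ": ", r$call,
                               " (posterior ", signif(r$call_posterior, 3), ")"),
                 ...)
  mm <- r$decode$maternal
  if (!is.null(mm))
    graphics::lines(r$pos, mm[, 1], col = "purple", lwd = 1.5)
  pp <- r$decode$paternal
  if (!is.null(pp))
    graphics::lines(r$pos, pp[, 1], col = "steelblue", lwd = 1.5)
  invisible(x)
}
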