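#' Copy-number model selection for one chromosome
#'
#' Converts the six hypothesis log-likelihoods to posterior probabilities,
#' `posterior(h) proportional to exp(logL_h) * prior(h)`, and calls the
#' argmax hypothesis when its posterior reaches `tau`, otherwise
#' `"nocall"`.
#'
#' @param loglik named numeric vector of log-likelihoods covering all of
#'   [cn_hypotheses()].
#' @param prior named prior (default uniform).
#' @param tau call threshold on the maximum posterior.
#' @return list with `posterior` (named, sums to 1), `call`,
#'   `call_posterior`, `origin` (`"maternal"`, `"paternal"` or NA) and `k`.
#' @export
call_copy_number <- function(loglik, prior = NULL, tau = 0.9) {
  hyps <- cn_hypotheses()
  if (!all(hyps %in% names(loglik)))
    stop("missing hypothesis log-likelihood: ",
         paste(setdiff(hyps, names(loglik)), collapse = ", "))
  loglik <- loglik[hyps]
  if (is.null(prior)) prior <- setNames(rep(1 / length(hyps), length(hyps)), hyps)
  lp <- loglik + log(prior[hyps])
  m <- max(lp)
  post <- exp(lp - m); post <- post / sum(post)
  best <- which.max(post)
  call <- if (post[best] >= tau) hyps[best] else "nocall"
  origin <- switch(call,
                   trisomy_m = "maternal", monosomy_m = "maternal",
                   trisomy_p = "paternal", monosomy_p = "paternal",
                   NA_character_)
  k <- if (call == "nocall") NA_integer_ else hypothesis_k(call)
  list(posterior = post, call = call, call_posterior = unname(post[best]),
       origin = origin, k = k)
}

#' Classify a trisomy as MI-like, MII-like or putative mitotic
#'
#' Uses the per-site BPH posterior (probability that both homologues of the
#' gaining parent are present among its two transmitted copies). Both
#' parental homologues at the centromere are the signature of a
#' meiosis-I-type error; single homologue at the centromere with BPH in a
#' distal (recombinant) segment indicates a meiosis-II-type error; single
#' homologue throughout indicates a mitotic duplication.
#'
#' @param bph numeric BPH posterior per site.
#' @param pos site bp positions.
#' @param centromere_bp centromere position.
#' @param window half-width (bp) of the pericentromeric window (default
#'   5 Mb); also the bin width used to scan for distal BPH segments.
#' @param cut posterior cut-off (default 0.5).
#' @return one of `"meiotic_MI_like"`, `"meiotic_MII_like"`,
#'   `"putative_mitotic"`.
#' @export
classify_trisomy_origin <- function(bph, pos, centromere_bp,
                                    window = 5e6, cut = 0.5) {
  if (length(bph) != length(pos)) stop("bph/pos length mismatch")
  cen <- abs(pos - centromere_bp) <= window
  if (any(cen) && mean(bph[cen]) >= cut) return("meiotic_MI_like")
  distal <- which(!cen)
  if (length(distal)) {
    bins <- floor(pos[distal] / window)
    bm <- tapply(bph[distal], bins, mean)
    if (any(bm >= cut)) return("meiotic_MII_like")
  }
  "putative_mitotic"
}

#' Embryo-level exclusion flags
#'
#' `complex_aneuploid` marks embryos with more than five aneuploid
#' chromosomes; `genome_wide_abnormal` marks ploidy-scale patterns: at
#' least 80\% of called chromosomes are same-parent trisomies (triploidy
#' pattern) or same-parent monosomies (haploidy pattern).
#'
#' @param calls data frame of one embryo's per-chromosome calls (columns
#'   `call`, `origin`).
#' @return list with logical `complex_aneuploid`, `genome_wide_abnormal`
#'   and the aneuploid chromosome count `n_aneuploid`.
#' @export
flag_embryo <- function(calls) {
  aneu <- calls$call %in% c("trisomy_m", "trisomy_p", "monosomy_m",
                            "monosomy_p", "nullisomy")
  called <- calls$call != "nocall"
  gw <- FALSE
  if (any(called)) {
    for (org in c("_m", "_p")) {
      tri <- mean(calls$call[called] == paste0("trisomy", org))
      mono <- mean(calls$call[called] == paste0("monosomy", org))
      if (tri >= 0.8 || mono >= 0.8) gw <- TRUE
    }
  }
  list(complex_aneuploid = sum(aneu) > 5L,
       genome_wide_abnormal = gw,
       n_aneuploid = sum(aneu))
}

#' Tabulate maternal meiotic aneuploidy per embryo
#'
#' An embryo is affected when any chromosome carries a maternal-origin
#' trisomy of meiotic class MI/MII, or (by default) a maternal monosomy,
#' whose meiotic status cannot be read from transmission data and is
#' attributed to meiosis under `count_monosomies = TRUE`.
#'
#' @param calls data frame of per-chromosome calls (columns `embryo_id`,
#'   `call`, `origin`, `meiotic_class`).
#' @param count_monosomies count maternal monosomies as meiotic.
#' @return logical vector named by embryo, TRUE = affected.
#' @export
maternal_meiotic_affected <- function(calls, count_monosomies = TRUE) {
  tri <- calls$call == "trisomy_m" &
    calls$meiotic_class %in% c("meiotic_MI_like", "meiotic_MII_like")
  mono <- count_monosomies & calls$call == "monosomy_m"
  aff <- tapply(tri | mono, calls$embryo_id, any)
  setNames(as.logical(aff), names(aff))
}
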