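chrom_inputs <- function(baf, panel, map, chrom) {
  i <- panel$chrom == chrom
  if (!any(i)) stop("chromosome ", chrom, " has no panel sites")
  pos <- panel$pos[i]
  cm <- interpolate_cM(map, chrom, pos)
  list(panel = panel[i, , drop = FALSE], baf = baf[i],
       pos = pos, d_cM = pmax(diff(cm), 0))
}

#' Forward log-likelihood of one chromosome under one hypothesis
#'
#' Numerically stable (scaled) forward recursion with a uniform initial
#' state distribution; equals log sum over all state paths of the path
#' probability times the emission product.
#'
#' @param baf BAF vector for the chromosome's panel sites (NA = missing).
#' @param panel panel rows for the chromosome.
#' @param map a [genetic_map()].
#' @param hypothesis one of [cn_hypotheses()].
#' @param params [emission_params()].
#' @param chrom chromosome label; defaults to the panel's (single)
#'   chromosome.
#' @return scalar log-likelihood.
#' @export
forward_loglik <- function(baf, panel, map, hypothesis, params,
                           chrom = panel$chrom[1]) {
  ci <- chrom_inputs(baf, panel, map, chrom)
  if (length(ci$baf) == 0) stop("empty chromosome")
  st <- enumerate_states(hypothesis)
  E <- emission_logdens(ci$baf, state_dosage(st, ci$panel), params)
  .hmm_forward_cpp(E, as.numeric(st$N), haldane_r(ci$d_cM))
}

#' Posterior state decoding (forward-backward)
#'
#' @inheritParams forward_loglik
#' @return list with `loglik`, `gamma` (n x K posterior matrix, rows sum to
#'   1), `states`, and per-parent haplotype marginals `maternal` /
#'   `paternal` (n x 2 matrices of the posterior mass transmitting
#'   haplotype 1 vs 2 of that parent, averaged over same-parent copies;
#'   NULL when the hypothesis transmits no copy of that parent).
#' @export
posterior_decode <- function(baf, panel, map, hypothesis, params,
                             chrom = panel$chrom[1]) {
  ci <- chrom_inputs(baf, panel, map, chrom)
  if (length(ci$baf) == 0) stop("empty chromosome")
  st <- enumerate_states(hypothesis)
  E <- emission_logdens(ci$baf, state_dosage(st, ci$panel), params)
  fb <- .hmm_fb_cpp(E, as.numeric(st$N), haldane_r(ci$d_cM))
  out <- list(loglik = fb$loglik, gamma = fb$gamma, states = st)
  out$maternal <- hap_marginal(fb$gamma, st$mat)
  out$paternal <- hap_marginal(fb$gamma, st$pat)
  out
}

# posterior mass on haplotype 1 vs 2 of one parent, averaged over that
# parent's transmitted copies
hap_marginal <- function(gamma, copies) {
  if (ncol(copies) == 0) return(NULL)
  w1 <- rowMeans(matrix(copies == 1L, nrow = nrow(copies)))
  m1 <- gamma %*% w1
  cbind(hap1 = as.numeric(m1), hap2 = 1 - as.numeric(m1))
}

#' Viterbi path
#'
#' Maximum a posteriori state sequence; ties broken toward the lowest
#' state index.
#'
#' @inheritParams forward_loglik
#' @return list with `path` (integer state indices), `labels`, `logp`.
#' @export
viterbi_path <- function(baf, panel, map, hypothesis, params,
                         chrom = panel$chrom[1]) {
  ci <- chrom_inputs(baf, panel, map, chrom)
  if (length(ci$baf) == 0) stop("empty chromosome")
  st <- enumerate_states(hypothesis)
  E <- emission_logdens(ci$baf, state_dosage(st, ci$panel), params)
  v <- .hmm_viterbi_cpp(E, as.numeric(st$N), haldane_r(ci$d_cM))
  list(path = v$path, labels = st$labels[v$path], logp = v$logp)
}

#' Grid-search noise estimation
#'
#' Per embryo, selects the (sigma, pi0) pair maximizing the summed disomy
#' forward log-likelihood across the given chromosomes. Emission densities
#' reuse the three disomy dosage levels \{0, 1/2, 1\} so the grid sweep is
#' cheap.
#'
#' @param baf full-panel BAF vector of one embryo.
#' @param panel a [snp_panel()].
#' @param map a [genetic_map()].
#' @param sigma_grid,pi0_grid candidate values.
#' @param chroms chromosomes to use (default: all in the panel).
#' @return [emission_params()] at the best grid point, with attribute
#'   `"loglik_grid"` (matrix sigma x pi0).
#' @export
fit_noise <- function(baf, panel, map,
                      sigma_grid = seq(0.05, 0.3, by = 0.025),
                      pi0_grid = c(0.01, 0.05, 0.1, 0.2, 0.35, 0.5),
                      chroms = unique(panel$chrom)) {
  if (all(is.na(baf))) stop("all BAF values missing")
  st <- enumerate_states("disomy")
  G <- matrix(0, length(sigma_grid), length(pi0_grid),
              dimnames = list(sigma_grid, pi0_grid))
  for (ch in chroms) {
    ci <- chrom_inputs(baf, panel, map, ch)
    D <- state_dosage(st, ci$panel)
    obs <- !is.na(ci$baf)
    if (!any(obs)) next
    b <- ci$baf[obs]
    Dob <- D[obs, , drop = FALSE]
    r <- haldane_r(ci$d_cM)
    for (si in seq_along(sigma_grid)) {
      # distinct disomy dosages are 0, 0.5, 1: three density vectors
      lev <- c(0, 0.5, 1)
      dens <- vapply(lev, function(m) dtruncnorm01(b, m, sigma_grid[si]),
                     numeric(length(b)))
      idx <- match(round(Dob * 2), round(lev * 2))
      dim(idx) <- dim(Dob)
      for (pi in seq_along(pi0_grid)) {
        E <- matrix(0, length(ci$baf), ncol(D))
        E[obs, ] <- log(pi0_grid[pi] + (1 - pi0_grid[pi]) *
                          matrix(dens[cbind(rep(seq_along(b), ncol(Dob)),
                                            as.vector(idx))],
                                 nrow = length(b)))
        G[si, pi] <- G[si, pi] + .hmm_forward_cpp(E, as.numeric(st$N), r)
      }
    }
  }
  best <- arrayInd(which.max(G), dim(G))
  out <- emission_params(sigma = sigma_grid[best[1]], pi0 = pi0_grid[best[2]])
  attr(out, "loglik_grid") <- G
  out
}
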