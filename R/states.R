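#' Copy-number hypotheses
#'
#' The six per-chromosome hypotheses scored by the HMM. `monosomy_m` means
#' the maternal homologue is lost (only a paternal copy transmitted);
#' `trisomy_m` means an extra maternal copy (two maternal + one paternal).
#'
#' @return character vector of hypothesis labels.
#' @export
cn_hypotheses <- function() {
  c("nullisomy", "monosomy_m", "monosomy_p", "disomy",
    "trisomy_m", "trisomy_p")
}

hypothesis_k <- function(hypothesis) {
  switch(hypothesis,
         nullisomy = 0L, monosomy_m = 1L, monosomy_p = 1L, disomy = 2L,
         trisomy_m = 3L, trisomy_p = 3L,
         stop("unknown copy-number hypothesis: ", hypothesis))
}

#' Enumerate transmitted-haplotype states for a hypothesis
#'
#' Each state is a multiset of transmitted parental haplotype identifiers
#' from \{m1, m2, p1, p2\}. Same-parent copy pairs (trisomies) are
#' unordered. Returns the per-state haplotype index matrices (1 or 2 within
#' each parent), the total copy number `k`, and the ordered switch-count
#' coefficient array `N` used by the transition model: the probability of
#' moving from state i to state j over a gap with recombination fraction r
#' is `sum_h N[i,j,h+1] r^h (1-r)^(k-h)`.
#'
#' @param hypothesis one of [cn_hypotheses()].
#' @return list with elements `hypothesis`, `k`, `mat`, `pat` (state x copy
#'   haplotype-index matrices), `labels`, and `N`.
#' @export
enumerate_states <- function(hypothesis) {
  k <- hypothesis_k(hypothesis)
  n_mat <- switch(hypothesis, nullisomy = 0L, monosomy_m = 0L,
                  monosomy_p = 1L, disomy = 1L, trisomy_m = 2L,
                  trisomy_p = 1L)
  n_pat <- k - n_mat

  combos <- function(n_copies) {
    if (n_copies == 0L) matrix(integer(0), nrow = 1, ncol = 0)
    else if (n_copies == 1L) matrix(1:2, ncol = 1)
    else matrix(c(1L, 1L, 1L, 2L, 2L, 2L), ncol = 2, byrow = TRUE)  # unordered
  }
  mc <- combos(n_mat); pc <- combos(n_pat)
  idx <- expand.grid(m = seq_len(nrow(mc)), p = seq_len(nrow(pc)))
  mat <- mc[idx$m, , drop = FALSE]
  pat <- pc[idx$p, , drop = FALSE]
  K <- nrow(mat)

  labels <- vapply(seq_len(K), function(s) {
    paste(c(if (n_mat) paste0("m", mat[s, ]), if (n_pat) paste0("p", pat[s, ])),
          collapse = "+")
  }, "")

  N <- switch_count_array(mat, pat, k)
  structure(list(hypothesis = hypothesis, k = k, mat = mat, pat = pat,
                 labels = labels, N = N), class = "hmm_states")
}

# Count, for each (source state, target state), the number of ordered
# per-copy switch assignments with h total switches. Each transmitted copy
# independently stays (1-r) or switches to the other haplotype of its
# parent (r); unordered same-parent pairs aggregate ordered outcomes.
switch_count_array <- function(mat, pat, k) {
  K <- nrow(mat)
  N <- array(0, dim = c(K, K, k + 1L))
  if (k == 0L) { N[1, 1, 1] <- 1; return(N) }
  statekey <- function(m, p) paste(paste(sort(m), collapse = ","),
                                   paste(sort(p), collapse = ","), sep = ";")
  keys <- vapply(seq_len(K), function(s)
    statekey(mat[s, ], pat[s, ]), "")
  flips <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
  for (i in seq_len(K)) {
    src <- c(mat[i, ], pat[i, ])
    n_m <- ncol(mat)
    for (f in seq_len(nrow(flips))) {
      fl <- flips[f, ]
      tgt <- ifelse(fl, 3L - src, src)
      key <- statekey(tgt[seq_len(n_m)], tgt[setdiff(seq_len(k), seq_len(n_m))])
      j <- match(key, keys)
      h <- sum(fl)
      N[i, j, h + 1L] <- N[i, j, h + 1L] + 1
    }
  }
  N
}

#' Inter-site transition matrix
#'
#' Each transmitted copy switches its source haplotype independently with
#' the Haldane recombination fraction r = (1 - exp(-2 d/100)) / 2 for a gap
#' of d cM; transitions between unordered multiset states sum the ordered
#' outcomes. Rows sum to 1.
#'
#' @param states an [enumerate_states()] object.
#' @param d_cM non-negative genetic distance of the gap.
#' @return K x K transition probability matrix.
#' @export
transition_matrix <- function(states, d_cM) {
  if (d_cM < 0) stop("negative genetic distance")
  r <- haldane_r(d_cM)
  K <- dim(states$N)[1]
  k <- states$k
  P <- matrix(0, K, K)
  for (h in 0:k)
    P <- P + states$N[, , h + 1L] * r^h * (1 - r)^(k - h)
  P
}

#' Haldane map function
#'
#' @param d_cM genetic distance in cM.
#' @return recombination fraction in \[0, 0.5).
#' @export
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' Per-state expected BAF dosage
#'
#' mu = (alt alleles among transmitted copies) / k at each site. For
#' nullisomy (k = 0) the matrix has one column of NA (emission is uniform).
#'
#' @param states an [enumerate_states()] object.
#' @param panel a [snp_panel()] (or subset rows for one chromosome).
#' @return n_sites x K matrix of expected BAF.
#' @export
state_dosage <- function(states, panel) {
  n <- nrow(panel)
  K <- length(states$labels)
  if (states$k == 0L) return(matrix(NA_real_, n, 1))
  hapm <- cbind(panel$m1, panel$m2)
  happ <- cbind(panel$p1, panel$p2)
  D <- matrix(0, n, K)
  for (s in seq_len(K)) {
    tot <- 0
    for (c in seq_len(ncol(states$mat))) tot <- tot + hapm[, states$mat[s, c]]
    for (c in seq_len(ncol(states$pat))) tot <- tot + happ[, states$pat[s, c]]
    D[, s] <- tot / states$k
  }
  D
}

#' Emission parameters
#'
#' The BAF emission is a two-component mixture: with probability `pi0` a
#' uniform draw on \[0, 1\] (array artifacts, contamination), otherwise a
#' normal with mean mu (the state dosage) and scale `sigma`, truncated to
#' \[0, 1\].
#'
#' @param sigma truncated-normal scale, > 0.
#' @param pi0 uniform-mixture weight in \[0, 1\].
#' @return object of class `emission_params`.
#' @export
emission_params <- function(sigma = 0.1, pi0 = 0.05) {
  if (sigma <= 0) stop("sigma must be positive")
  if (pi0 < 0 || pi0 > 1) stop("pi0 must lie in [0, 1]")
  structure(list(sigma = sigma, pi0 = pi0), class = "emission_params")
}

#' @export
print.emission_params <- function(x, ...) {
  cat("<emission_params> sigma =", x$sigma, ", pi0 =", x$pi0, "\n")
  invisible(x)
}

# density of N(mu, sigma) truncated to [0,1], vectorized over b and mu
dtruncnorm01 <- function(b, mu, sigma) {
  Z <- pnorm((1 - mu) / sigma) - pnorm((0 - mu) / sigma)
  dnorm((b - mu) / sigma) / (sigma * Z)
}

#' Emission log-density matrix
#'
#' log(pi0 + (1 - pi0) * TN(b; mu, sigma, \[0,1\])) per site and state;
#' missing BAF and nullisomy states contribute log 1 = 0.
#'
#' @param b numeric BAF vector (NA = missing).
#' @param dosage n x K matrix from [state_dosage()].
#' @param params [emission_params()].
#' @return n x K matrix of log-densities.
#' @export
emission_logdens <- function(b, dosage, params) {
  n <- length(b); K <- ncol(dosage)
  E <- matrix(0, n, K)
  obs <- !is.na(b)
  if (!any(obs) || all(is.na(dosage[1, ]))) return(E)
  for (s in seq_len(K)) {
    E[obs, s] <- log(params$pi0 +
                       (1 - params$pi0) *
                         dtruncnorm01(b[obs], dosage[obs, s], params$sigma))
  }
  E
}
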