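# Brute-force forward likelihood by exhaustive path enumeration.
# Independent of the package's recursion: sums P(path) * prod(emissions)
# over every state path, in log space.
brute_force_loglik <- function(baf, panel, map, hypothesis, params,
                               chrom = panel$chrom[1]) {
  i <- panel$chrom == chrom
  sub <- panel[i, , drop = FALSE]
  b <- baf[i]
  st <- enumerate_states(hypothesis)
  E <- emission_logdens(b, state_dosage(st, sub), params)
  n <- nrow(E); K <- ncol(E)
  cm <- interpolate_cM(map, chrom, sub$pos)
  Tl <- lapply(seq_len(max(n - 1, 0)), function(t)
    log(transition_matrix(st, max(cm[t + 1] - cm[t], 0))))
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  lp <- rep(-log(K), nrow(paths))
  for (t in seq_len(n)) lp <- lp + E[t, paths[, t]]
  for (t in seq_len(n - 1))
    lp <- lp + Tl[[t]][cbind(paths[, t], paths[, t + 1])]
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# quick single-chromosome panel for unit tests
toy_panel <- function(n, chrom = "chr1", spacing = 1e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  snp_panel(chrom = rep(chrom, n), pos = seq_len(n) * spacing,
            ref = "A", alt = "B",
            m1 = rbinom(n, 1, 0.5), m2 = rbinom(n, 1, 0.5),
            p1 = rbinom(n, 1, 0.5), p2 = rbinom(n, 1, 0.5))
}

toy_map <- function(panel, cM_per_Mb = 1) {
  uniform_genetic_map(unique(panel$chrom),
                      length_bp = max(panel$pos) + 1,
                      length_cM = (max(panel$pos) + 1) / 1e6 * cM_per_Mb)
}
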