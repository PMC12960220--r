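# maximum number of true crossovers containable by a 1:1 matching of
# events to truth (exhaustive over permutations; counts are small)
best_containment <- function(txo, ee) {
  m <- length(txo)
  inside <- outer(txo, seq_len(m), function(x, j)
    x >= ee$left[j] & x <= ee$right[j])
  if (m == 1) return(sum(inside))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  max(vapply(perms(seq_len(m)), function(p)
    sum(inside[cbind(seq_len(m), p)]), 0))
}

#' Simulate a cohort and measure end-to-end recovery
#'
#' Simulates `n_families` independent families under `config`, runs the
#' full pipeline ([phase_by_transmission()] via [analyze_family()],
#' [karyohmm()], [call_crossovers()], [filter_artifacts()]), and scores
#' the calls against the simulation truth: per-chromosome copy-number and
#' parental-origin accuracy, meiotic-class accuracy for the MI and
#' mitotic extremes, the fraction of truly disomic chromosomes whose
#' per-parent crossover counts are recovered exactly, and the fraction of
#' 1:1-matched events whose resolution interval contains the true
#' crossover position.
#'
#' @param config a [sim_config()] (its `seed` field is ignored here).
#' @param n_families number of families.
#' @param seed RNG seed for the whole cohort.
#' @param params emission parameters; NULL (default) estimates them per
#'   embryo with [fit_noise()].
#' @param tau,gamma calling thresholds, as in [analyze_family()].
#' @return list with accuracy fields (`cn_accuracy`, `origin_accuracy`,
#'   `class_accuracy_mi`, `class_accuracy_mitotic`, `xo_exact_fraction`,
#'   `xo_containment`), the per-chromosome `records` data frame, the
#'   pooled filtered `events`, the per-embryo truth/crossover table
#'   `embryo_truth`, and the pooled `calls`.
#' @export
benchmark_recovery <- function(config, n_families, seed = NULL,
                               params = NULL, tau = 0.9, gamma = 0.9) {
  if (!is.null(seed)) set.seed(seed)
  config$seed <- NULL
  records <- list(); all_events <- list(); all_emb <- list()
  all_calls <- list(); truth_tab <- list()
  for (fi in seq_len(n_families)) {
    fid <- sprintf("fam%03d", fi)
    fam <- simulate_family(config)
    bafs <- lapply(fam$bafs, function(e)
      embryo_baf(paste0(fid, "_", e$embryo_id), fid, e$baf,
                 e$maternal_age, e$paternal_age))
    names(bafs) <- vapply(bafs, `[[`, "", "embryo_id")
    cs <- analyze_family(fam$panel, bafs, fam$map,
                         centromeres = fam$centromeres, params = params,
                         tau = tau, gamma = gamma, family_id = fid)
    all_calls[[fi]] <- cs$calls
    all_events[[fi]] <- cs$events
    all_emb[[fi]] <- data.frame(embryo_id = names(bafs), family_id = fid,
                                stringsAsFactors = FALSE)
    recs <- list()
    for (e in names(fam$truth)) {
      eid <- paste0(fid, "_", e)
      tr_e <- fam$truth[[e]]
      for (ch in names(tr_e$chromosomes)) {
        tr <- tr_e$chromosomes[[ch]]
        truth_call <- switch(as.character(tr$k),
                             "0" = "nullisomy",
                             "1" = paste0("monosomy_",
                                          substr(tr$origin, 1, 1)),
                             "2" = "disomy",
                             "3" = paste0("trisomy_",
                                          substr(tr$origin, 1, 1)))
        row <- cs$calls[cs$calls$embryo_id == eid & cs$calls$chrom == ch, ]
        recs[[paste(eid, ch)]] <- data.frame(
          embryo_id = eid, family_id = fid, chrom = ch,
          truth_call = truth_call, truth_origin = tr$origin,
          truth_class = tr$class_truth, truth_k = tr$k,
          truth_mode = tr$mode,
          n_xo_m = length(tr$m_crossovers), n_xo_p = length(tr$p_crossovers),
          call = row$call, origin = row$origin,
          meiotic_class = row$meiotic_class,
          stringsAsFactors = FALSE)
      }
      truth_tab[[eid]] <- data.frame(
        embryo_id = eid, family_id = fid, mode = tr_e$mode,
        z_maternal = tr_e$z_maternal,
        xo_list_m = I(list(lapply(tr_e$chromosomes, `[[`, "m_crossovers"))),
        xo_list_p = I(list(lapply(tr_e$chromosomes, `[[`, "p_crossovers"))),
        stringsAsFactors = FALSE)
    }
    records[[fi]] <- do.call(rbind, recs)
  }
  records <- do.call(rbind, records); rownames(records) <- NULL
  events <- do.call(rbind, all_events)
  embryos <- do.call(rbind, all_emb)
  calls <- do.call(rbind, all_calls)
  truth_tab <- do.call(rbind, truth_tab)
  fl <- filter_artifacts(events, embryos)
  ev <- fl$events

  cn_acc <- mean(records$call == records$truth_call)
  aneu <- records$truth_k %in% c(1L, 3L)
  origin_acc <- mean(records$origin[aneu] == records$truth_origin[aneu],
                     na.rm = FALSE)
  is_mi <- !is.na(records$truth_class) &
    records$truth_class == "meiotic_MI_like"
  is_mit <- !is.na(records$truth_class) &
    records$truth_class == "putative_mitotic"
  class_mi <- if (any(is_mi))
    mean(records$meiotic_class[is_mi] == "meiotic_MI_like", na.rm = FALSE)
  else NA_real_
  class_mit <- if (any(is_mit))
    mean(records$meiotic_class[is_mit] == "putative_mitotic", na.rm = FALSE)
  else NA_real_

  # crossover recovery on truly disomic chromosomes
  dis <- records[records$truth_k == 2L, , drop = FALSE]
  n_contained <- 0L; n_matched <- 0L; exact <- logical(nrow(dis))
  for (i in seq_len(nrow(dis))) {
    r <- dis[i, ]
    ok <- TRUE
    tl <- truth_tab[truth_tab$embryo_id == r$embryo_id, ]
    for (par in c("maternal", "paternal")) {
      txo <- if (par == "maternal") tl$xo_list_m[[1]][[r$chrom]]
             else tl$xo_list_p[[1]][[r$chrom]]
      ee <- ev[ev$embryo_id == r$embryo_id & ev$chrom == r$chrom &
                 ev$parent == par, , drop = FALSE]
      if (nrow(ee) != length(txo)) ok <- FALSE
      else if (length(txo)) {
        n_matched <- n_matched + length(txo)
        n_contained <- n_contained + best_containment(txo, ee)
      }
    }
    exact[i] <- ok
  }

  list(cn_accuracy = cn_acc, origin_accuracy = origin_acc,
       class_accuracy_mi = class_mi, class_accuracy_mitotic = class_mit,
       xo_exact_fraction = mean(exact),
       xo_containment = if (n_matched) n_contained / n_matched else NA_real_,
       n_chromosomes = nrow(records), n_disomic = nrow(dis),
       n_matched_events = n_matched,
       records = records, events = ev, calls = calls,
       embryo_truth = truth_tab, excluded = fl$excluded_embryos)
}
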