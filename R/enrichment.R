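#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson Eulerian-path shuffle: the returned sequence has exactly
#' the same mono- and dinucleotide composition as the input, with the first
#' and last characters fixed. Runs of masked bases (lowercase, `N`/`n`) stay
#' in place and the unmasked segments between them are shuffled
#' independently; a masked output base is written as `n`.
#'
#' @param seq a DNA string.
#' @param seed optional integer seed; when supplied the shuffle is
#'   deterministic and the caller's RNG state is untouched.
#' @return The shuffled string (unchanged when shorter than 2 bases).
#' @export
dinuc_shuffle <- function(seq, seed = NULL) {
  if (nchar(seq) < 2) return(seq)
  run <- function() decode_seq(dinuc_shuffle_cpp(encode_seq(seq)))
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' One-tailed binomial enrichment against the preceding region
#'
#' Tests whether `n_promoter` sites in the promoter regions is larger than
#' expected given `n_control` sites in the equally-sized preceding regions,
#' under the null that a site is equally likely to fall in either region:
#' `p = P(X >= n_promoter)` with `X ~ Binomial(n_promoter + n_control, 1/2)`,
#' computed as an exact tail sum (accurate down to ~1e-300).
#'
#' @param n_promoter,n_control non-negative site counts (vectorized).
#' @return data.frame with `fold` (`n_promoter / n_control`, `Inf` when the
#'   control count is 0) and `p`. Rows where both counts are 0 get `NA`s;
#'   such families are skipped in reports.
#' @export
binomial_enrichment <- function(n_promoter, n_control) {
  stopifnot(length(n_promoter) == length(n_control),
            all(n_promoter >= 0), all(n_control >= 0))
  n <- n_promoter + n_control
  p <- ifelse(n == 0, NA_real_,
              pbinom(n_promoter - 1, n, 0.5, lower.tail = FALSE))
  fold <- ifelse(n == 0, NA_real_,
                 ifelse(n_control == 0, Inf, n_promoter / n_control))
  data.frame(fold = fold, p = p)
}

#' Empirical enrichment against dinucleotide-shuffled promoter sets
#'
#' @param observed site count in the real promoter set.
#' @param shuffled_counts vector of per-replicate site counts over `B >= 100`
#'   shuffled promoter sets.
#' @param ge if `TRUE` (default) a replicate counts against the observation
#'   when its count is greater than *or equal to* the observed count; if
#'   `FALSE`, strictly greater.
#' @return list with `fold` (`observed / mean(shuffled)`, `Inf` if the mean
#'   is 0 with a positive observation), `p` (`#extreme / B`), `p_display`
#'   (`"<1/B"` rendered at the replicate resolution when no replicate was as
#'   extreme) and `B`.
#' @export
shuffle_null_test <- function(observed, shuffled_counts, ge = TRUE) {
  B <- length(shuffled_counts)
  stopifnot(B >= 100)
  extreme <- if (ge) sum(shuffled_counts >= observed) else
    sum(shuffled_counts > observed)
  p <- extreme / B
  mu <- mean(shuffled_counts)
  fold <- if (mu == 0) { if (observed > 0) Inf else NA_real_ } else observed / mu
  list(fold = fold, p = p,
       p_display = if (extreme == 0) sprintf("<%s", format(1 / B)) else
         format(p), B = B)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of tests (e.g. the number of matrix families).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(m >= 1)
  alpha / m
}

#' Per-family site counts in a dinucleotide-shuffle null
#'
#' Shuffles every promoter sequence `B` times (each replicate is one shuffled
#' dataset), scans each shuffled dataset with the whole library at the given
#' stringency, applies the same family-level overlap pruning as on real
#' data, and tabulates pruned per-family counts. Masking follows the
#' mask-after-shuffle order: the full sequence is shuffled and the masked
#' TSS-relative positions are then blanked in the shuffled copy, so every
#' replicate analyses exactly the same amount of sequence as the real set.
#'
#' @param pset a [promoter_set].
#' @param pwms a [pwm_library()].
#' @param B number of shuffled datasets.
#' @param threshold_mode `"opt"` or `"opt-0.1"`.
#' @param seed integer seed (one stream drives all replicates).
#' @param mask optional `mask_set` from [build_mask()], applied to each
#'   shuffled dataset.
#' @param core_threshold core similarity gate.
#' @param default_opt fallback threshold for uncalibrated matrices.
#' @return numeric matrix, families x B, with family ids as row names.
#' @export
shuffle_count_matrix <- function(pset, pwms, B = 10000,
                                 threshold_mode = c("opt", "opt-0.1"),
                                 seed = 1L, mask = NULL,
                                 core_threshold = 0.75, default_opt = 0.85) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(inherits(pset, "promoter_set"), inherits(pwms, "pwm_library"))
  seqs <- lapply(pset$promoters$sequence, encode_seq)
  ids <- pset$promoters$id
  L <- pset$L
  fam_ids <- sort(unique(vapply(pwms$pwms, `[[`, character(1), "family_id")))
  packs <- lapply(pwms$pwms, pwm_scan_pack)
  thr <- vapply(pwms$pwms, pwm_threshold, numeric(1),
                threshold_mode = threshold_mode, default_opt = default_opt)
  fam_idx <- match(vapply(pwms$pwms, `[[`, character(1), "family_id"), fam_ids)
  masks <- lapply(ids, function(pid) {
    if (is.null(mask)) return(integer(0))
    iv <- mask$intervals[[pid]]
    if (is.null(iv) || nrow(iv) == 0) return(integer(0))
    # TSS-relative [-L, 0) -> 1-based sequence index
    pos <- unlist(lapply(seq_len(nrow(iv)), function(i)
      seq.int(iv$start[i], iv$end[i] - 1L)))
    pos <- pos[pos >= -L & pos < 0] + L + 1L
    as.integer(pos)
  })
  counts <- with_seed(seed, shuffle_family_counts_cpp(
    seqs,
    lapply(packs, `[[`, "w"), lapply(packs, `[[`, "w_rc"),
    lapply(packs, `[[`, "colmax"), lapply(packs, `[[`, "colmax_rc"),
    lapply(packs, `[[`, "core"), lapply(packs, `[[`, "core_rc"),
    thr, as.integer(fam_idx), length(fam_ids), masks, as.integer(B),
    core_threshold))
  rownames(counts) <- fam_ids
  counts
}

#' Assemble the per-family enrichment table (binomial + shuffle tests)
#'
#' @param promoter_hits pruned `site_hits` in the promoter regions.
#' @param control_hits pruned `site_hits` in the preceding control regions.
#' @param shuffle_counts matrix from [shuffle_count_matrix()] (or `NULL` to
#'   skip the empirical test).
#' @param families character vector of family ids to report (defaults to the
#'   union seen in the inputs).
#' @param ge passed to [shuffle_null_test()].
#' @return data.frame with one row per family: observed counts, number of
#'   promoters with at least one site, control counts, folds and p-values of
#'   both tests.
#' @export
enrichment_table <- function(promoter_hits, control_hits,
                             shuffle_counts = NULL, families = NULL,
                             ge = TRUE) {
  families <- families %||%
    sort(unique(c(promoter_hits$family_id, control_hits$family_id,
                  rownames(shuffle_counts))))
  n_prom <- table(factor(promoter_hits$family_id, levels = families))
  n_ctrl <- table(factor(control_hits$family_id, levels = families))
  n_with <- vapply(families, function(f) {
    length(unique(promoter_hits$promoter_id[promoter_hits$family_id == f]))
  }, integer(1))
  bin <- binomial_enrichment(as.integer(n_prom), as.integer(n_ctrl))
  out <- data.frame(family_id = families,
                    n_promoter = as.integer(n_prom),
                    n_promoters_with_site = n_with,
                    n_control_region = as.integer(n_ctrl),
                    fold_vs_region = bin$fold, p_binomial = bin$p,
                    shuffle_mean = NA_real_, fold_vs_shuffle = NA_real_,
                    p_empirical = NA_real_, p_empirical_display = NA_character_,
                    B = NA_integer_, stringsAsFactors = FALSE)
  if (!is.null(shuffle_counts)) {
    for (i in seq_along(families)) {
      f <- families[i]
      if (!f %in% rownames(shuffle_counts)) next
      sc <- shuffle_counts[f, ]
      st <- shuffle_null_test(out$n_promoter[i], sc, ge = ge)
      out$shuffle_mean[i] <- mean(sc)
      out$fold_vs_shuffle[i] <- st$fold
      out$p_empirical[i] <- st$p
      out$p_empirical_display[i] <- st$p_display
      out$B[i] <- st$B
    }
  }
  rownames(out) <- NULL
  out
}
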