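#' Run the full promoter motif-enrichment analysis
#'
#' Orchestrates the complete workflow on a promoter set and matrix library:
#' scan at the requested stringencies, prune to the best family hit per
#' overlapping region, test every family for enrichment against the
#' preceding regions (one-tailed binomial) and against dinucleotide-shuffled
#' promoters (empirical null), test conservation-score elevation inside
#' sites (one-tailed rank-sum, whole-site and core variants), then — when
#' masking is configured — mask the dominant motifs identically from
#' promoters, controls and score tracks and repeat the whole analysis on
#' the masked data.
#'
#' @param pset a [promoter_set]; conservation tests run only when
#'   `$scores` is present.
#' @param pwms a [pwm_library()].
#' @param threshold_modes stringencies to analyse (default `"opt-0.1"`;
#'   use `c("opt", "opt-0.1")` for both).
#' @param B shuffle replicates for the empirical null (default 1000;
#'   10000 reproduces the original design at ten times the cost).
#' @param alpha nominal significance level (default 0.05).
#' @param m number of tests for the Bonferroni correction; defaults to the
#'   number of families actually tested.
#' @param seed master seed for the shuffle null.
#' @param mask_families families whose lower-stringency ("opt-0.1") hits are
#'   masked over their full extent before the re-run (`NULL` disables
#'   masking and the post-mask stage).
#' @param tata_family family whose "opt" hits are masked where they touch
#'   `tata_window` (TATA-box analog; optional).
#' @param tata_window closed TSS-relative range, default `c(-61, -10)`.
#' @param ge empirical-p counting rule, see [shuffle_null_test()].
#' @param default_opt fallback threshold for uncalibrated matrices.
#' @param subset optional character vector of promoter ids to analyse.
#' @param out_dir optional directory; when given, all intermediate tables
#'   are written as TSV.
#' @return A `promoscan_report`: list with `pre` and (if masking ran)
#'   `post`, each a named list per threshold mode of summary tables (see
#'   [summarize_tests()]), plus `hits`, `mask`, `params` and `log`.
#' @export
run_pipeline <- function(pset, pwms, threshold_modes = "opt-0.1",
                         B = 1000L, alpha = 0.05, m = NULL, seed = 1L,
                         mask_families = NULL, tata_family = NULL,
                         tata_window = c(-61, -10), ge = TRUE,
                         default_opt = 0.85, subset = NULL, out_dir = NULL) {
  stopifnot(inherits(pset, "promoter_set"), inherits(pwms, "pwm_library"),
            length(pwms$pwms) >= 1)
  if (!is.null(subset)) {
    keep <- pset$promoters$id %in% subset
    pset$promoters <- pset$promoters[keep, , drop = FALSE]
    pset$scores <- pset$scores[pset$promoters$id]
  }
  fam_ids <- sort(unique(vapply(pwms$pwms, `[[`, character(1), "family_id")))
  m <- m %||% length(fam_ids)
  log <- list(seed = seed, B = B, alpha = alpha, m = m,
              n_promoters = nrow(pset$promoters), L = pset$L,
              n_families = length(fam_ids))

  analyse <- function(ps, mask, stage) {
    res <- list()
    for (mode in threshold_modes) {
      hits <- family_prune(scan_sequences(ps, pwms, threshold_mode = mode,
                                          default_opt = default_opt))
      ctrl <- family_prune(scan_sequences(ps, pwms, threshold_mode = mode,
                                          region = "preceding",
                                          default_opt = default_opt))
      sc <- shuffle_count_matrix(ps, pwms, B = B, threshold_mode = mode,
                                 seed = derive_seed(seed, paste0(stage, mode)),
                                 mask = mask, default_opt = default_opt)
      enr <- enrichment_table(hits, ctrl, sc, families = fam_ids, ge = ge)
      cons <- NULL
      if (!is.null(ps$scores)) {
        cons <- conservation_table(ps, hits, pwms, families = fam_ids)
      }
      res[[mode]] <- list(
        hits = hits, control_hits = ctrl,
        table = summarize_tests(enr, cons, alpha = alpha, m = m))
    }
    res
  }

  pre <- analyse(pset, mask = NULL, stage = "pre")
  post <- NULL; mask <- NULL
  if (!is.null(mask_families) || !is.null(tata_family)) {
    # mask the full extent of EVERY lower-stringency hit (unpruned): pruning
    # keeps one hit per overlap group, but a remnant of a discarded overlap
    # partner could otherwise re-fire after masking
    primary <- scan_sequences(pset, pwms, threshold_mode = "opt-0.1",
                              default_opt = default_opt)
    primary <- primary[primary$family_id %in% (mask_families %||%
                                                 character(0)), ,
                       drop = FALSE]
    tata <- NULL
    if (!is.null(tata_family)) {
      th <- scan_sequences(pset, pwms, threshold_mode = "opt",
                           default_opt = default_opt)
      tata <- th[th$family_id %in% tata_family, , drop = FALSE]
    }
    mask <- build_mask(primary, tata, tata_window = tata_window)
    masked <- apply_mask_everywhere(mask, pset)$pset
    post <- analyse(masked, mask = mask, stage = "post")
    log$masked_bases <- sum(vapply(mask$intervals, function(iv) {
      sum(pmin(iv$end, 0) - pmax(iv$start, -pset$L))
    }, numeric(1)))
  }
  report <- structure(list(pre = pre, post = post, mask = mask,
                           params = list(threshold_modes = threshold_modes,
                                         B = B, alpha = alpha, m = m,
                                         seed = seed, ge = ge),
                           log = log),
                      class = "promoscan_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Combine the three tests into a Table-1-style summary with codes
#'
#' Per family the table carries the counts, folds and p-values of the
#' binomial, shuffle and conservation tests plus a 3-character significance
#' code: for each test, `X` means `p < alpha/m` (Bonferroni-significant),
#' `+` means `p < alpha` (nominal), `.` means neither. A family passes the
#' conservation test when either the whole-site or the core variant passes.
#' The attribute `"venn"` carries the sizes of all intersections of the
#' three Bonferroni-significant family sets.
#'
#' @param enrichment output of [enrichment_table()].
#' @param conservation output of [conservation_table()] (or `NULL`).
#' @param alpha,m nominal level and test count.
#' @return data.frame, one row per family, with a `code` column.
#' @export
summarize_tests <- function(enrichment, conservation = NULL, alpha = 0.05,
                            m = 1L) {
  thr <- bonferroni_threshold(alpha, m)
  out <- enrichment
  if (!is.null(conservation)) {
    out <- merge(out, conservation, by = "family_id", all.x = TRUE,
                 sort = FALSE)
  } else {
    out$p_whole <- NA_real_; out$p_core <- NA_real_
  }
  p_cons <- pmin(out$p_whole, out$p_core, na.rm = TRUE)
  p_cons[is.na(out$p_whole) & is.na(out$p_core)] <- NA_real_
  code1 <- function(p) {
    ifelse(is.na(p), ".", ifelse(p < thr, "X", ifelse(p < alpha, "+", ".")))
  }
  sig <- cbind(binomial = code1(out$p_binomial),
               shuffle = code1(out$p_empirical),
               conservation = code1(p_cons))
  out$p_conservation <- p_cons
  out$code <- apply(sig, 1, paste, collapse = " ")
  out <- out[order(out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  sets <- list(binomial = out$family_id[sig[, 1] == "X"],
               shuffle = out$family_id[sig[, 2] == "X"],
               conservation = out$family_id[sig[, 3] == "X"])
  venn <- c(
    binomial = length(sets$binomial), shuffle = length(sets$shuffle),
    conservation = length(sets$conservation),
    binomial_shuffle = length(intersect(sets$binomial, sets$shuffle)),
    binomial_conservation = length(intersect(sets$binomial,
                                             sets$conservation)),
    shuffle_conservation = length(intersect(sets$shuffle,
                                            sets$conservation)),
    all_three = length(Reduce(intersect, sets)))
  attr(out, "venn") <- venn
  attr(out, "threshold") <- thr
  out
}

#' @export
print.promoscan_report <- function(x, ...) {
  cat("<promoscan_report>\n")
  cat(sprintf("  %d promoters (L = %d), %d families, B = %d, alpha/m = %.3g\n",
              x$log$n_promoters, x$log$L, x$log$n_families, x$params$B,
              bonferroni_threshold(x$params$alpha, x$params$m)))
  for (stage in c("pre", "post")) {
    if (is.null(x[[stage]])) next
    for (mode in names(x[[stage]])) {
      tb <- x[[stage]][[mode]]$table
      venn <- attr(tb, "venn")
      cat(sprintf("  [%s-mask, %s] %d families tested; %d pass all three tests\n",
                  stage, mode, nrow(tb), venn[["all_three"]]))
    }
  }
  invisible(x)
}

#' @export
summary.promoscan_report <- function(object, stage = "pre",
                                     mode = names(object[[stage]])[1], ...) {
  tb <- object[[stage]][[mode]]$table
  sig <- tb[grepl("X", tb$code), , drop = FALSE]
  cat(sprintf("Stage %s, stringency %s: %d/%d families Bonferroni-significant in >=1 test\n",
              stage, mode, nrow(sig), nrow(tb)))
  cols <- c("family_id", "n_promoter", "n_control_region", "fold_vs_region",
            "p_binomial", "shuffle_mean", "fold_vs_shuffle",
            "p_empirical_display", "p_whole", "p_core", "code")
  print(sig[, intersect(cols, names(sig)), drop = FALSE], digits = 3)
  invisible(sig)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (stage in c("pre", "post")) {
    if (is.null(report[[stage]])) next
    for (mode in names(report[[stage]])) {
      tag <- paste0(stage, "_", gsub("[^a-z0-9]+", "", mode))
      el <- report[[stage]][[mode]]
      write.table(el$table, file.path(out_dir, paste0(tag, "_summary.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_hits(el$hits, tsv = file.path(out_dir, paste0(tag, "_hits.tsv")))
    }
  }
  if (!is.null(report$mask)) {
    write_mask_bed(report$mask, file.path(out_dir, "mask.bed"))
  }
  invisible(report)
}

#' Annotate a report with expression levels of the matching factors
#'
#' Joins each family's transcription-factor gene symbol to an expression
#' table (one column per cell type, values in fpkm) and flags the family
#' `expressed` when any cell type reaches `min_fpkm` (default 10 fpkm),
#' `not expressed` otherwise, or `no data` when the symbol is absent.
#' Duplicate symbols take the per-column maximum with a warning.
#'
#' @param tbl a summary table (from [summarize_tests()]).
#' @param symbols named character vector mapping `family_id` to gene symbol.
#' @param expr data.frame with a `symbol` column and >= 1 numeric columns.
#' @param min_fpkm expression call threshold.
#' @return the table with `symbol`, `max_fpkm` and `expression` columns.
#' @export
annotate_expression <- function(tbl, symbols, expr, min_fpkm = 10) {
  stopifnot("symbol" %in% names(expr),
            ncol(expr) >= 2)
  num_cols <- names(expr)[vapply(expr, is.numeric, logical(1))]
  stopifnot(length(num_cols) >= 1)
  if (anyDuplicated(expr$symbol)) {
    warning("duplicate symbols in expression table; taking per-column maxima")
    expr <- aggregate(expr[num_cols], by = list(symbol = expr$symbol), max)
  }
  tbl$symbol <- unname(symbols[tbl$family_id])
  hit <- match(tbl$symbol, expr$symbol)
  mx <- apply(expr[num_cols], 1, max)
  tbl$max_fpkm <- mx[hit]
  tbl$expression <- ifelse(is.na(tbl$symbol) | is.na(hit), "no data",
                           ifelse(tbl$max_fpkm >= min_fpkm, "expressed",
                                  "not expressed"))
  tbl
}
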