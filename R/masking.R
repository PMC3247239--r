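#' Build a mask from dominant-motif predictions
#'
#' The mask for each promoter is the union of (a) the full extent of every
#' hit in `primary_hits` — typically the dominant family's lower-stringency
#' ("opt-0.1") predictions, masked loosely so no residual high-scoring
#' fragments remain — and (b) the full extent of every hit in `tata_hits`
#' (TATA-box predictions at "opt") that touches the window `tata_window` of
#' TSS-relative base positions (default -61..-10, the region where
#' functional TATA boxes sit). Overlapping intervals are merged.
#'
#' @param primary_hits `site_hits` to mask over their whole extent (may be
#'   empty).
#' @param tata_hits `site_hits` masked only where they intersect
#'   `tata_window` (may be `NULL`).
#' @param tata_window closed TSS-relative base range, default `c(-61, -10)`.
#' @return A `mask_set`: list with `intervals` (named list per promoter of
#'   data.frames `start`, `end`, half-open TSS-relative) and `provenance`
#'   (per-interval origin tags before merging).
#' @export
build_mask <- function(primary_hits, tata_hits = NULL,
                       tata_window = c(-61, -10)) {
  take <- primary_hits[, c("promoter_id", "start", "end", "family_id"),
                       drop = FALSE]
  take$origin <- if (nrow(take)) paste0(take$family_id, "|opt-0.1") else
    character(0)
  if (!is.null(tata_hits) && nrow(tata_hits)) {
    # hit covers bases start..end-1; keep it if any lies in the closed window
    sel <- tata_hits$start <= tata_window[2] &
      (tata_hits$end - 1L) >= tata_window[1]
    tt <- tata_hits[sel, c("promoter_id", "start", "end", "family_id"),
                    drop = FALSE]
    if (nrow(tt)) {
      tt$origin <- paste0(tt$family_id, "|opt")
      take <- rbind(take, tt)
    }
  }
  intervals <- lapply(split(take, take$promoter_id), function(g) {
    merge_intervals(g$start, g$end)
  })
  structure(list(intervals = intervals,
                 provenance = take[, c("promoter_id", "start", "end",
                                       "origin"), drop = FALSE]),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  n_iv <- sum(vapply(x$intervals, nrow, integer(1)))
  cat(sprintf("<mask_set> %d interval(s) over %d promoter(s)\n",
              n_iv, length(x$intervals)))
  invisible(x)
}

# Mask one sequence given intervals in the TSS-relative frame [frame_start,
# frame_start + nchar). Masked bases become 'n'.
mask_string <- function(s, intervals, frame_start) {
  if (is.null(intervals) || nrow(intervals) == 0 || is.na(s)) return(s)
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  for (i in seq_len(nrow(intervals))) {
    lo <- max(intervals$start[i] - frame_start + 1L, 1L)
    hi <- min(intervals$end[i] - frame_start, n)
    if (lo <= hi) ch[lo:hi] <- "n"
  }
  paste(ch, collapse = "")
}

#' Apply a mask identically to promoters, controls and score tracks
#'
#' Masked positions become `n` in sequences (scored zero by the scanner,
#' coordinates preserved) and `NA` in conservation score vectors. The same
#' TSS-relative positions are blanked in the real promoters, in the
#' preceding control regions (at the equivalent within-region offsets, i.e.
#' the mask shifted by `-L`), and in any supplied pre-generated shuffled
#' datasets, so that exactly the same amount of sequence is analysed in
#' every dataset kind. (The shuffle-null pipeline normally applies the mask
#' inside [shuffle_count_matrix()] instead of materializing shuffled sets.)
#'
#' @param mask a `mask_set` from [build_mask()].
#' @param pset a [promoter_set] (scores masked too when present).
#' @param shuffled_sets optional list of character vectors (one shuffled
#'   dataset each, parallel to the promoter table) to mask identically.
#' @return list with `pset` (masked copy) and `shuffled_sets` (masked
#'   copies, `NULL` if none supplied).
#' @export
apply_mask_everywhere <- function(mask, pset, shuffled_sets = NULL) {
  stopifnot(inherits(mask, "mask_set"), inherits(pset, "promoter_set"))
  L <- pset$L
  ids <- pset$promoters$id
  out <- pset
  for (i in seq_along(ids)) {
    iv <- mask$intervals[[ids[i]]]
    if (is.null(iv) || nrow(iv) == 0) next
    out$promoters$sequence[i] <-
      mask_string(pset$promoters$sequence[i], iv, -L)
    # "equivalent region" of the preceding sequence: same within-region
    # offsets, i.e. the mask shifted upstream by L
    iv_prec <- data.frame(start = iv$start - L, end = iv$end - L)
    out$promoters$preceding[i] <-
      mask_string(pset$promoters$preceding[i], iv_prec, -2L * L)
    if (!is.null(out$scores[[ids[i]]])) {
      v <- out$scores[[ids[i]]]
      for (k in seq_len(nrow(iv))) {
        lo <- max(iv$start[k] + L + 1L, 1L); hi <- min(iv$end[k] + L, L)
        if (lo <= hi) v[lo:hi] <- NA_real_
      }
      out$scores[[ids[i]]] <- v
    }
  }
  masked_shuffles <- NULL
  if (!is.null(shuffled_sets)) {
    masked_shuffles <- lapply(shuffled_sets, function(ss) {
      vapply(seq_along(ids), function(i) {
        mask_string(ss[i], mask$intervals[[ids[i]]], -L)
      }, character(1))
    })
  }
  list(pset = out, shuffled_sets = masked_shuffles)
}

#' Serialize a mask as TSS-relative BED with provenance in the name field
#'
#' @param mask a `mask_set`.
#' @param path output path.
#' @export
write_mask_bed <- function(mask, path) {
  pv <- mask$provenance
  df <- data.frame(chrom = pv$promoter_id, start = pv$start, end = pv$end,
                   name = pv$origin)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(mask)
}
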