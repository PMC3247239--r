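#' Construct a position weight matrix object
#'
#' Wraps a 4 x L count matrix (rows A, C, G, T) into a `pwm` object carrying
#' everything the scanner needs: column frequencies with pseudocount, the
#' per-position information weight used by the MatInspector-style similarity
#' score, the core positions (most information-rich columns), an optimized
#' similarity threshold, and an IUPAC consensus string.
#'
#' The information weight of column i is
#' \deqn{C_i = \frac{100}{\ln 4} \sum_b f(i,b) \ln(4 f(i,b)),}
#' i.e. 100 times the relative entropy of the column against the uniform
#' background (0 for an uninformative column, 100 for a deterministic one).
#'
#' @param counts 4 x L non-negative numeric matrix; rows in A, C, G, T order.
#' @param id matrix identifier (e.g. `"V$NOLF_01"`).
#' @param family_id family identifier; defaults to `id` with any trailing
#'   `_NN` version suffix removed (e.g. `"V$NOLF"`).
#' @param pseudocount per-cell pseudocount added before column normalization.
#' @param opt_threshold optimized similarity threshold in `[0, 1]`; `NA`
#'   means "not calibrated yet" and scanning falls back to 0.85.
#' @param core_size number of core positions (the `core_size` highest-`Ci`
#'   columns, leftmost on ties); capped at the matrix length.
#' @return An object of class `pwm`.
#' @export
pwm <- function(counts, id, family_id = NULL, pseudocount = 0.01,
                opt_threshold = NA_real_, core_size = 4) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4 || any(counts < 0) || any(!is.finite(counts))) {
    stop("matrix '", id, "': counts must be a non-negative 4 x L matrix")
  }
  rownames(counts) <- DNA_BASES
  L <- ncol(counts)
  freq <- apply(counts + pseudocount, 2, function(col) col / sum(col))
  freq <- matrix(freq, nrow = 4, dimnames = list(DNA_BASES, NULL))
  info <- pmax(0, (100 / log(4)) * colSums(freq * log(4 * freq)))
  k <- min(core_size, L)
  core <- order(-info, seq_len(L))[seq_len(k)]  # leftmost wins ties
  core <- sort(core)
  structure(list(
    id = id,
    family_id = family_id %||% sub("_[0-9]+$", "", id),
    counts = counts,
    freq = freq,
    info = info,
    core_positions = core,
    opt_threshold = opt_threshold,
    consensus = pwm_consensus(freq, core)
  ), class = "pwm")
}

# IUPAC consensus: single base if its frequency >= 0.5, a two-letter
# ambiguity code if the top two sum to >= 0.75, otherwise 'n'.
# Core positions are uppercased, MatInspector-style.
pwm_consensus <- function(freq, core) {
  two <- c(AC = "m", AG = "r", AT = "w", CG = "s", CT = "y", GT = "k")
  letters_out <- vapply(seq_len(ncol(freq)), function(i) {
    f <- freq[, i]
    o <- order(-f)
    if (f[o[1]] >= 0.5) {
      tolower(DNA_BASES[o[1]])
    } else if (f[o[1]] + f[o[2]] >= 0.75) {
      key <- paste(sort(DNA_BASES[o[1:2]]), collapse = "")
      unname(two[key])
    } else "n"
  }, character(1))
  letters_out[core] <- toupper(letters_out[core])
  paste(letters_out, collapse = "")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (family %s), %d bp, consensus %s, opt %s\n",
              x$id, x$family_id, ncol(x$counts), x$consensus,
              ifelse(is.na(x$opt_threshold), "uncalibrated",
                     sprintf("%.2f", x$opt_threshold))))
  invisible(x)
}

#' Bundle matrices and their family grouping into a library
#'
#' @param pwms list of [pwm()] objects.
#' @param families optional data.frame with columns `family_id` and
#'   `description`; derived from the matrices when omitted.
#' @return An object of class `pwm_library`.
#' @export
pwm_library <- function(pwms, families = NULL) {
  stopifnot(length(pwms) > 0)
  ids <- vapply(pwms, `[[`, character(1), "id")
  names(pwms) <- ids
  fam <- vapply(pwms, `[[`, character(1), "family_id")
  if (is.null(families)) {
    families <- data.frame(family_id = unique(fam),
                           description = unique(fam),
                           stringsAsFactors = FALSE)
  }
  structure(list(pwms = pwms, families = families), class = "pwm_library")
}

#' @export
print.pwm_library <- function(x, ...) {
  cat(sprintf("<pwm_library> %d matrices in %d families\n",
              length(x$pwms), nrow(x$families)))
  invisible(x)
}

#' Read a PWM library from a TRANSFAC flat file or JASPAR .pfm file
#'
#' TRANSFAC records are delimited by `//` and carry an `ID` line followed by
#' a `P0  A  C  G  T` header and numbered count rows. JASPAR records start
#' with a `>` header followed by four count rows (optionally in the
#' `A [ ... ]` style). Families come from a mapping table if supplied,
#' otherwise from the matrix id with any trailing `_NN` suffix stripped.
#'
#' @param path file path.
#' @param format `"transfac"` or `"jaspar"`.
#' @param family_map optional path to (or data.frame of) a tab-separated
#'   table with columns `matrix_id`, `family_id`, `description`.
#' @param pseudocount passed to [pwm()].
#' @return A [pwm_library()].
#' @export
read_pwms <- function(path, format = c("transfac", "jaspar"),
                      family_map = NULL, pseudocount = 0.01) {
  format <- match.arg(format)
  lines <- readLines(path)
  fam_tbl <- NULL
  if (!is.null(family_map)) {
    fam_tbl <- if (is.data.frame(family_map)) family_map else
      read.table(family_map, sep = "\t", header = TRUE,
                 stringsAsFactors = FALSE, quote = "", comment.char = "")
  }
  recs <- if (format == "transfac") parse_transfac(lines) else parse_jaspar(lines)
  pwms <- lapply(recs, function(r) {
    fid <- NULL
    if (!is.null(fam_tbl)) {
      hit <- match(r$id, fam_tbl$matrix_id)
      if (!is.na(hit)) fid <- fam_tbl$family_id[hit]
    }
    pwm(r$counts, id = r$id, family_id = fid, pseudocount = pseudocount)
  })
  families <- NULL
  if (!is.null(fam_tbl)) {
    keep <- fam_tbl$family_id %in% vapply(pwms, `[[`, character(1), "family_id")
    families <- unique(fam_tbl[keep, c("family_id", "description")])
  }
  pwm_library(pwms, families)
}

parse_transfac <- function(lines) {
  lines <- trimws(lines, which = "right")
  breaks <- c(0, which(grepl("^//", lines)), length(lines) + 1)
  recs <- list()
  for (i in seq_len(length(breaks) - 1)) {
    chunk <- lines[seq(breaks[i] + 1, min(breaks[i + 1] - 1, length(lines)))]
    chunk <- chunk[nzchar(chunk)]
    if (!length(chunk)) next
    idl <- grep("^ID\\s+", chunk, value = TRUE)
    if (!length(idl)) next
    id <- sub("^ID\\s+", "", idl[1])
    p0 <- grep("^P0", chunk)
    if (!length(p0)) stop("TRANSFAC record '", id, "': missing P0 header")
    hdr <- strsplit(trimws(chunk[p0[1]]), "\\s+")[[1]][-1]
    rows <- chunk[grep("^[0-9]+\\s", chunk)]
    if (!length(rows)) stop("TRANSFAC record '", id, "': no count rows")
    vals <- lapply(rows, function(r) {
      f <- strsplit(trimws(r), "\\s+")[[1]][-1]
      v <- suppressWarnings(as.numeric(f[seq_len(min(4, length(f)))]))
      if (length(v) != 4 || any(is.na(v))) {
        stop("TRANSFAC record '", id, "': malformed count row '", r, "'")
      }
      v
    })
    m <- do.call(cbind, vals)          # 4 x L in header base order
    ord <- match(DNA_BASES, toupper(hdr)[1:4])
    if (any(is.na(ord))) stop("TRANSFAC record '", id, "': bad P0 header")
    recs[[length(recs) + 1]] <- list(id = id, counts = m[ord, , drop = FALSE])
  }
  recs
}

parse_jaspar <- function(lines) {
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no '>' headers found in JASPAR file")
  bounds <- c(hdr, length(lines) + 1)
  recs <- list()
  for (i in seq_along(hdr)) {
    id <- strsplit(sub("^>\\s*", "", lines[hdr[i]]), "\\s+")[[1]][1]
    body <- lines[seq(hdr[i] + 1, bounds[i + 1] - 1)]
    body <- body[nzchar(trimws(body))]
    if (length(body) != 4) {
      stop("JASPAR record '", id, "': expected 4 count rows, got ", length(body))
    }
    # accept "A [ 1 2 3 ]" or bare "1 2 3"
    base_order <- toupper(sub("^\\s*([A-Za-z]).*$", "\\1", body))
    if (!all(base_order %in% DNA_BASES)) base_order <- DNA_BASES
    vals <- lapply(body, function(r) {
      r <- gsub("[^0-9.Ee+-]", " ", r)
      v <- suppressWarnings(as.numeric(strsplit(trimws(r), "\\s+")[[1]]))
      if (any(is.na(v)) || !length(v)) {
        stop("JASPAR record '", id, "': malformed count row")
      }
      v
    })
    if (length(unique(lengths(vals))) != 1) {
      stop("JASPAR record '", id, "': ragged count rows")
    }
    m <- do.call(rbind, vals)[match(DNA_BASES, base_order), , drop = FALSE]
    recs[[length(recs) + 1]] <- list(id = id, counts = m)
  }
  recs
}

# Scanner payload for one matrix: information-weighted frequency products for
# the forward matrix and its reverse complement (rows A,C,G,T reversed =
# complemented; columns reversed).
pwm_scan_pack <- function(p) {
  w <- p$freq * rep(p$info, each = 4)
  colmax <- apply(w, 2, max)
  L <- ncol(w)
  list(w = w, w_rc = w[4:1, L:1, drop = FALSE],
       colmax = colmax, colmax_rc = rev(colmax),
       core = as.integer(p$core_positions),
       core_rc = as.integer(sort(L + 1L - p$core_positions)),
       L = L)
}

pwm_threshold <- function(p, threshold_mode, default_opt = 0.85) {
  opt <- if (is.na(p$opt_threshold)) default_opt else p$opt_threshold
  if (threshold_mode == "opt") opt else max(opt - 0.1, 0.5)
}

#' Calibrate a matrix's optimized similarity threshold on background sequence
#'
#' Chooses the smallest threshold on a 0.01 grid in `[0.60, 1.00]` such that
#' the match rate (both strands, core gate applied) on the supplied
#' background sequences does not exceed `target_rate` matches per kilobase,
#' mirroring the "minimize matches in non-promoter regions" optimization.
#' Returns 1.00 when no grid value attains the target.
#'
#' @param p a [pwm()].
#' @param background character vector of background DNA sequences.
#' @param target_rate maximum tolerated matches per kb (default 0.3).
#' @param core_threshold core similarity gate (default 0.75).
#' @return The calibrated threshold (also usable via
#'   `relaxed_threshold()` for the lower-stringency scan).
#' @export
calibrate_threshold <- function(p, background, target_rate = 0.3,
                                core_threshold = 0.75) {
  if (length(background) == 0 || sum(nchar(background)) == 0) {
    stop("empty background: supply sequences or use the fixed default 0.85")
  }
  stopifnot(target_rate > 0)
  total_kb <- sum(nchar(background)) / 1000
  if (total_kb < 10) {
    warning("background is shorter than 10 kb; calibration will be noisy")
  }
  pack <- pwm_scan_pack(p)
  scores <- numeric(0)
  for (s in background) {
    v <- encode_seq(s)
    for (m in list(
      mss_scan_cpp(v, pack$w, pack$colmax, pack$core, 0.60, core_threshold),
      mss_scan_cpp(v, pack$w_rc, pack$colmax_rc, pack$core_rc, 0.60,
                   core_threshold))) {
      scores <- c(scores, m$score)
    }
  }
  grid <- seq(0.60, 1.00, by = 0.01)
  for (t in grid) {
    if (sum(scores >= t - 1e-9) / total_kb <= target_rate) return(t)
  }
  1.00
}

#' @rdname calibrate_threshold
#' @param opt an optimized threshold.
#' @export
relaxed_threshold <- function(opt) pmax(opt - 0.1, 0.5)

#' Scan sequences with a PWM library
#'
#' Slides every matrix over both strands of every sequence and reports
#' windows whose core similarity reaches `core_threshold` (default 0.75) and
#' whose full-matrix similarity reaches the matrix's threshold at the chosen
#' stringency (`"opt"` or the 0.1-lower `"opt-0.1"`, floored at 0.5).
#' Lowercase and `N` bases are treated as masked and contribute zero
#' frequency wherever they fall inside a window.
#'
#' @param seqs a [promoter_set] (its promoter sequences are scanned in the
#'   TSS-relative frame `[-L, 0)`), or a named character vector of sequences.
#' @param pwms a [pwm_library()] or a single [pwm()].
#' @param threshold_mode `"opt"` or `"opt-0.1"`.
#' @param core_threshold core similarity gate.
#' @param offset TSS-relative coordinate of the first base of each sequence
#'   (only used for character input; defaults to 0).
#' @param region for promoter-set input, scan the promoter region
#'   (`"promoter"`, frame `[-L, 0)`) or the preceding control region
#'   (`"preceding"`, frame `[-2L, -L)`).
#' @param default_opt threshold used for matrices with no calibrated
#'   `opt_threshold` (default 0.85).
#' @return A `site_hits` data.frame: `promoter_id`, `start`, `end`
#'   (TSS-relative, 0-based half-open), `strand`, `pwm_id`, `family_id`,
#'   `score`.
#' @export
scan_sequences <- function(seqs, pwms, threshold_mode = c("opt", "opt-0.1"),
                           core_threshold = 0.75, offset = NULL,
                           region = c("promoter", "preceding"),
                           default_opt = 0.85) {
  threshold_mode <- match.arg(threshold_mode)
  region <- match.arg(region)
  if (inherits(seqs, "promoter_set")) {
    L <- seqs$L
    sq <- if (region == "promoter") seqs$promoters$sequence else
      seqs$promoters$preceding
    names(sq) <- seqs$promoters$id
    offset <- if (region == "promoter") -L else -2L * L
    seqs <- sq
  }
  offset <- offset %||% 0L
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  bad <- grepl("[^ACGTNacgtn]", seqs)
  if (any(bad)) {
    stop("non-nucleotide characters in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  if (inherits(pwms, "pwm")) pwms <- pwm_library(list(pwms))
  out <- vector("list", 0)
  enc <- lapply(seqs, encode_seq)
  for (p in pwms$pwms) {
    pack <- pwm_scan_pack(p)
    t <- pwm_threshold(p, threshold_mode, default_opt)
    for (sid in names(enc)) {
      fwd <- mss_scan_cpp(enc[[sid]], pack$w, pack$colmax, pack$core,
                          t, core_threshold)
      rev <- mss_scan_cpp(enc[[sid]], pack$w_rc, pack$colmax_rc, pack$core_rc,
                          t, core_threshold)
      n_f <- length(fwd$start); n_r <- length(rev$start)
      if (n_f + n_r == 0) next
      out[[length(out) + 1]] <- data.frame(
        promoter_id = sid,
        start = offset + c(fwd$start, rev$start) - 1L,
        end = offset + c(fwd$start, rev$start) - 1L + pack$L,
        strand = rep(c("+", "-"), c(n_f, n_r)),
        pwm_id = p$id, family_id = p$family_id,
        score = c(fwd$score, rev$score),
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(out)) do.call(rbind, out) else empty_hits()
  hits <- hits[order(hits$promoter_id, hits$family_id, hits$start,
                     hits$end, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("site_hits", "data.frame")
  hits
}

empty_hits <- function() {
  data.frame(promoter_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), pwm_id = character(0),
             family_id = character(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Keep the best matrix match per family in any overlapping region
#'
#' Within each promoter and matrix family, hits whose intervals overlap
#' (transitively, on either strand) are grouped and only the highest-scoring
#' hit of each group is retained. Ties break toward the longer matrix, then
#' the leftmost start, then the + strand.
#'
#' @param hits a `site_hits` data.frame from [scan_sequences()].
#' @return The pruned `site_hits` data.frame.
#' @export
family_prune <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  key <- paste(hits$promoter_id, hits$family_id, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(hits)), key), function(idx) {
    h <- hits[idx, , drop = FALSE]
    o <- order(h$start, h$end)
    h <- h[o, ]; idx <- idx[o]
    grp <- integer(nrow(h)); g <- 1L; maxend <- h$end[1]; grp[1] <- 1L
    for (i in seq_len(nrow(h))[-1]) {
      if (h$start[i] >= maxend) { g <- g + 1L; maxend <- h$end[i] }
      else maxend <- max(maxend, h$end[i])
      grp[i] <- g
    }
    vapply(split(seq_along(grp), grp), function(gi) {
      hh <- h[gi, , drop = FALSE]
      best <- order(-hh$score, -(hh$end - hh$start), hh$start,
                    hh$strand != "+")[1]
      idx[gi[best]]
    }, integer(1))
  }), use.names = FALSE)
  out <- hits[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write predicted sites as BED6 (TSS-relative) and/or full TSV
#'
#' BED scores are the similarity score scaled by 1000; the name field
#' carries `pwm_id|family_id`.
#'
#' @param hits a `site_hits` data.frame.
#' @param bed,tsv output paths (either may be `NULL`).
#' @export
write_hits <- function(hits, bed = NULL, tsv = NULL) {
  if (!is.null(bed)) {
    df <- data.frame(chrom = hits$promoter_id, start = hits$start,
                     end = hits$end,
                     name = paste(hits$pwm_id, hits$family_id, sep = "|"),
                     score = round(hits$score * 1000), strand = hits$strand)
    write.table(df, bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv)) {
    write.table(as.data.frame(hits), tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(hits)
}
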