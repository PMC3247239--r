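#' Project a raw conservation track onto a promoter set
#'
#' Reads per-base scores (bedGraph intervals or fixed/variable-step wiggle)
#' and projects them into each promoter's TSS-relative frame, reversing the
#' vector for minus-strand promoters so index 1 is always the most upstream
#' base. Raw values are interpreted as neutral-evolution P-values and
#' transformed to `1 - P` (higher = more conserved) unless
#' `already_conserved = TRUE`. Uncovered bases become `NA`.
#'
#' @param track a bedGraph/wiggle file path, or a data.frame with columns
#'   `chrom`, `start`, `end` (0-based half-open), `value`.
#' @param pset a [promoter_set] with genomic coordinates (`chrom`, `tss`,
#'   `strand`).
#' @param already_conserved set `TRUE` when the track is already on the
#'   "higher is more conserved" scale (skips the `1 - P` transform).
#' @return The promoter set with `$scores`: a named list of length-`L`
#'   numeric vectors. The number of track bases falling outside all
#'   promoters is reported via `message()`.
#' @export
prepare_scores <- function(track, pset, already_conserved = FALSE) {
  if (is.character(track)) track <- read_score_track(track)
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  if (!already_conserved) track$value <- 1 - track$value
  if (any(track$value < -1e-9 | track$value > 1 + 1e-9)) {
    stop("conservation scores outside [0, 1] after transform; ",
         "check `already_conserved`")
  }
  L <- pset$L
  scores <- list()
  used <- logical(nrow(track))
  for (i in seq_len(nrow(pset$promoters))) {
    p <- pset$promoters[i, ]
    gstart <- if (p$strand == "+") p$tss - L else p$tss  # genomic [gstart, gstart+L)
    v <- rep(NA_real_, L)
    sel <- which(track$chrom == p$chrom & track$start < gstart + L &
                   track$end > gstart)
    for (k in sel) {
      lo <- max(track$start[k], gstart); hi <- min(track$end[k], gstart + L)
      v[(lo - gstart + 1):(hi - gstart)] <- track$value[k]
      used[k] <- TRUE
    }
    if (p$strand == "-") v <- rev(v)
    scores[[p$id]] <- v
  }
  n_out <- sum(!used)
  if (n_out > 0) {
    message(n_out, " track interval(s) fall outside the promoter set")
  }
  pset$scores <- scores
  pset
}

# Minimal bedGraph / wiggle reader returning chrom,start,end,value
# (0-based half-open).
read_score_track <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines)]
  out <- list()
  mode <- "bedgraph"; chrom <- NULL; pos <- NULL; step <- NULL; span <- 1L
  for (ln in lines) {
    if (grepl("^fixedStep", ln) || grepl("^variableStep", ln)) {
      kv <- strsplit(trimws(ln), "\\s+")[[1]]
      mode <- sub("Step", "", kv[1])
      get <- function(key, default = NA) {
        m <- grep(paste0("^", key, "="), kv, value = TRUE)
        if (length(m)) sub(".*=", "", m[1]) else default
      }
      chrom <- get("chrom")
      span <- as.integer(get("span", "1"))
      if (mode == "fixed") {
        pos <- as.integer(get("start")) - 1L   # wiggle is 1-based
        step <- as.integer(get("step", "1"))
      }
      next
    }
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (mode == "bedgraph") {
      out[[length(out) + 1]] <- data.frame(
        chrom = f[1], start = as.integer(f[2]), end = as.integer(f[3]),
        value = as.numeric(f[4]), stringsAsFactors = FALSE)
    } else if (mode == "fixed") {
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = pos, end = pos + span,
        value = as.numeric(f[1]), stringsAsFactors = FALSE)
      pos <- pos + step
    } else {                                  # variableStep
      p <- as.integer(f[1]) - 1L
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = p, end = p + span,
        value = as.numeric(f[2]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Exact one-tailed rank-sum p-value by enumeration over group assignments of
# the pooled mid-ranks (handles ties; feasible for both groups <= 10).
exact_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  obs <- sum(r[seq_len(nx)])
  idx <- combn(length(pooled), nx)
  stats <- colSums(matrix(r[idx], nrow = nx))
  mean(stats >= obs - 1e-9)
}

#' One-tailed rank-sum test of conservation inside vs. outside sites
#'
#' Pools per-base conservation scores across all promoters, splits them into
#' bases covered by at least one hit of the tested family versus all
#' remaining promoter bases, and asks whether in-site scores are higher
#' (one-tailed Mann-Whitney). In `core` mode only the bases under each hit's
#' core matrix positions count as in-site. When both groups have at most 10
#' non-missing values an exact enumeration over rank assignments is used
#' (valid under ties); otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param pset a [promoter_set] with `$scores` (see [prepare_scores()]).
#' @param hits `site_hits` for one family (TSS-relative coordinates).
#' @param pwms a [pwm_library()]; required in `core` mode to locate each
#'   matrix's core positions (strand-aware).
#' @param mode `"whole_site"` or `"core"`.
#' @param exact_max exact enumeration cutoff per group (default 10).
#' @return list with `p` (`NA` when either group is empty), `n_in`, `n_out`.
#' @export
wilcoxon_site_conservation <- function(pset, hits, pwms = NULL,
                                       mode = c("whole_site", "core"),
                                       exact_max = 10L) {
  mode <- match.arg(mode)
  stopifnot(!is.null(pset$scores))
  if (mode == "core" && is.null(pwms)) {
    stop("core mode needs the pwm_library to locate core positions")
  }
  L <- pset$L
  ids <- pset$promoters$id
  in_site <- matrix(FALSE, nrow = length(ids), ncol = L,
                    dimnames = list(ids, NULL))
  for (k in seq_len(nrow(hits))) {
    i <- match(hits$promoter_id[k], ids)
    if (is.na(i)) next
    if (mode == "whole_site") {
      rel <- seq(hits$start[k], hits$end[k] - 1L)
    } else {
      p <- pwms$pwms[[hits$pwm_id[k]]]
      if (is.null(p)) stop("matrix '", hits$pwm_id[k], "' not in library")
      Lp <- ncol(p$counts)
      core <- p$core_positions
      if (hits$strand[k] == "-") core <- Lp + 1L - core
      rel <- hits$start[k] + core - 1L
    }
    cols <- rel[rel >= -L & rel < 0] + L + 1L
    in_site[i, cols] <- TRUE
  }
  sc <- t(vapply(ids, function(id) {
    v <- pset$scores[[id]]
    if (is.null(v)) rep(NA_real_, L) else v
  }, numeric(L)))
  x <- sc[in_site]; x <- x[!is.na(x)]       # in-site
  y <- sc[!in_site]; y <- y[!is.na(y)]      # out-of-site
  if (length(x) == 0 || length(y) == 0) {
    return(list(p = NA_real_, n_in = length(x), n_out = length(y)))
  }
  p <- if (length(x) <= exact_max && length(y) <= exact_max) {
    exact_ranksum_p(x, y)
  } else {
    suppressWarnings(
      wilcox.test(x, y, alternative = "greater", exact = FALSE)$p.value)
  }
  list(p = p, n_in = length(x), n_out = length(y))
}

#' Per-family conservation test table
#'
#' Runs [wilcoxon_site_conservation()] in both whole-site and core modes for
#' every family present in `hits`. A family is recorded significant when
#' either variant passes the caller's threshold (both p-values are
#' reported).
#'
#' @param pset a [promoter_set] with scores.
#' @param hits pruned `site_hits` (all families).
#' @param pwms a [pwm_library()].
#' @param families families to report (default: those present in `hits`).
#' @return data.frame: `family_id`, `p_whole`, `p_core`, `n_in_whole`,
#'   `n_in_core`, `n_out`.
#' @export
conservation_table <- function(pset, hits, pwms, families = NULL) {
  families <- families %||% sort(unique(hits$family_id))
  rows <- lapply(families, function(f) {
    fh <- hits[hits$family_id == f, , drop = FALSE]
    w <- wilcoxon_site_conservation(pset, fh, pwms, mode = "whole_site")
    cr <- wilcoxon_site_conservation(pset, fh, pwms, mode = "core")
    data.frame(family_id = f, p_whole = w$p, p_core = cr$p,
               n_in_whole = w$n_in, n_in_core = cr$n_in, n_out = w$n_out,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
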