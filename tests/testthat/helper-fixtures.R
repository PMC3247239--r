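# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's code paths (no C++ scanner, no union-find, no ape pruning).

mk_counts <- function(bases, n = 12) {
  m <- matrix(1, 4, length(bases), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(bases)) m[bases[i], i] <- n
  m
}

# A long, specific planted motif (21 bp) and a short AT-rich one (TATA-like).
fixture_oe_pwm <- function() {
  pwm(mk_counts(strsplit("TCCCTGGGGAGATTCCCTAGG", "")[[1]], 40),
      id = "SYN$OE_01", family_id = "S$OE")
}
fixture_tata_pwm <- function() {
  pwm(mk_counts(strsplit("TATAAAT", "")[[1]], 40),
      id = "SYN$TATA_01", family_id = "S$TATA")
}

random_dna <- function(n, seed = NULL, prob = rep(0.25, 4)) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, TRUE, prob),
                           collapse = "")
  if (is.null(seed)) draw() else { set.seed(seed); draw() }
}

revcomp_chr <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(x, "")[[1]]),
                                       collapse = ""))
}

dinuc_counts <- function(s) {
  n <- nchar(s)
  table(substring(s, 1:(n - 1), 2:n))
}

# Brute-force window scorer, independent of the C++ scanner: scores the
# forward strand directly and the minus strand by scanning the
# reverse-complemented sequence with the forward matrix, mirroring
# coordinates back.
oracle_scan <- function(seq, p, threshold, core_threshold = 0.75) {
  L <- ncol(p$freq)
  score_one <- function(chars, idx) {
    num <- 0
    for (i in idx) {
      b <- match(chars[i], c("A", "C", "G", "T"))
      num <- num + if (is.na(b)) 0 else p$info[i] * p$freq[b, i]
    }
    den <- sum(p$info[idx] * apply(p$freq[, idx, drop = FALSE], 2, max))
    if (den == 0) 0 else num / den
  }
  scan_strand <- function(s) {
    chars <- strsplit(toupper(s), "")[[1]]
    chars[grepl("[acgtn]", strsplit(s, "")[[1]])] <- "N"  # lowercase masked
    n <- length(chars)
    hits <- NULL
    for (st in seq_len(max(n - L + 1, 0))) {
      win <- chars[st:(st + L - 1)]
      if (score_one(win, p$core_positions) >= core_threshold - 1e-9 &&
          (sc <- score_one(win, seq_len(L))) >= threshold - 1e-9) {
        hits <- rbind(hits, data.frame(start = st, score = sc))
      }
    }
    hits
  }
  fwd <- scan_strand(seq)
  n <- nchar(seq)
  rc <- scan_strand(revcomp_chr(seq))
  if (!is.null(rc)) rc$start <- n - L + 2 - rc$start  # mirror to + frame
  list(fwd = fwd, rev = rc)
}

# Transitive-closure connected components by repeated boolean matrix squaring.
oracle_components <- function(ids, pairs) {
  n <- length(ids)
  adj <- diag(TRUE, n)
  for (k in seq_len(nrow(pairs))) {
    i <- match(pairs$id1[k], ids); j <- match(pairs$id2[k], ids)
    adj[i, j] <- adj[j, i] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj > 0)) break
    adj <- nxt
  }
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) { cid <- cid + 1; comp[which(adj[i, ])] <- cid }
  }
  unname(split(ids, comp))
}

# Small synthetic 5-species tree. Branch lengths are chosen so the worked
# subtree lengths match the published mammalian examples: mouse-rat 0.161,
# mouse-human 0.453, mouse-rat-human 0.537.
fixture_tree <- function() {
  ape::read.tree(text = paste0(
    "(((mouse:0.077,rat:0.084):0.2,human:0.176):0.05,",
    "(dog:0.15,cow:0.18):0.08);"))
}

toy_promoter_set <- function(seqs, L = nchar(seqs[1])) {
  promoter_set(data.frame(id = names(seqs), chrom = NA_character_,
                          tss = NA_integer_, strand = "+",
                          sequence = unname(seqs),
                          preceding = NA_character_,
                          stringsAsFactors = FALSE), L = L)
}
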