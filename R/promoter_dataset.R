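#' Assign a genomic domain to each gene of a tandemly arrayed family
#'
#' Each gene's domain runs, on the gene strand, from an upstream edge to 1 kb
#' downstream of its ORF end. The upstream edge lies 1 kb closer than the
#' nearest edge of the next family ORF upstream, or 100 kb upstream of the
#' ORF start when no other family member lies within that distance. cDNAs
#' mapping inside a domain on the gene strand are later attributed to that
#' gene.
#'
#' @param orfs data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open genomic ORF coordinates) and `strand` (`"+"`/`"-"`).
#' @param max_upstream upstream default when no neighbour is found (100 kb).
#' @param downstream_pad extension past the ORF end (1 kb).
#' @return data.frame of `GeneDomain` rows: `gene_id`, `chrom`, `strand`,
#'   `orf_start`, `orf_end`, `domain_start`, `domain_end` (genomic, 0-based
#'   half-open).
#' @export
assign_gene_domains <- function(orfs, max_upstream = 100000L,
                                downstream_pad = 1000L) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(orfs)))
  out <- lapply(split(orfs, orfs$chrom), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    n <- nrow(g)
    up <- integer(n); down <- integer(n)
    for (i in seq_len(n)) {
      if (g$strand[i] == "+") {
        prev_end <- if (i > 1) max(g$end[seq_len(i - 1)]) else -Inf
        gap <- g$start[i] - prev_end
        ext <- min(max_upstream, gap - downstream_pad)
        if (ext < 0) {
          warning("gene '", g$gene_id[i],
                  "': neighbouring ORF closer than 1 kb; upstream extent clipped to 0")
          ext <- 0
        }
        up[i] <- g$start[i] - ext
        down[i] <- g$end[i] + downstream_pad
      } else {
        nxt_start <- if (i < n) min(g$start[seq(i + 1, n)]) else Inf
        gap <- nxt_start - g$end[i]
        ext <- min(max_upstream, gap - downstream_pad)
        if (ext < 0) {
          warning("gene '", g$gene_id[i],
                  "': neighbouring ORF closer than 1 kb; upstream extent clipped to 0")
          ext <- 0
        }
        up[i] <- g$start[i] - downstream_pad
        down[i] <- g$end[i] + ext
      }
    }
    data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
               orf_start = g$start, orf_end = g$end,
               domain_start = pmax(0L, as.integer(up)),
               down = as.integer(down), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  names(out)[names(out) == "down"] <- "domain_end"
  rownames(out) <- NULL
  out
}

#' Infer transcription start sites from cDNA/RACE alignments
#'
#' Implements the TSS-calling rules: cDNAs overlapping more than one gene
#' domain (or mapping to the wrong strand of their domain) are discarded;
#' per gene, cDNA alignment blocks are pooled with the ORF and transcribed
#' segments separated by gaps of fewer than 10 bp are merged (small indels in
#' the cDNA-to-genome alignment, not real introns); genes left with a single
#' merged exon, genes flagged as pseudogenes, and genes with an intron
#' downstream of the ORF are removed; the TSS of each surviving gene is the
#' most upstream transcribed base.
#'
#' @param cdna data.frame with columns `cdna_id`, `chrom`, `strand`,
#'   `blockStarts` (comma-separated 0-based genomic starts) and `blockSizes`.
#' @param domains output of [assign_gene_domains()]; a logical column
#'   `pseudo` may flag pseudogenes (absent means all intact).
#' @param merge_gap gaps strictly smaller than this are merged (10 bp).
#' @return list with `tss` (data.frame `gene_id`, `chrom`, `tss`, `strand`)
#'   and `discarded` (named counts of each filtering rule's casualties).
#' @export
infer_tss <- function(cdna, domains, merge_gap = 10L) {
  if (!"pseudo" %in% names(domains)) domains$pseudo <- FALSE
  parse_blocks <- function(row) {
    s <- as.integer(strsplit(row$blockStarts, ",")[[1]])
    w <- as.integer(strsplit(row$blockSizes, ",")[[1]])
    stopifnot(length(s) == length(w))
    data.frame(start = s, end = s + w)
  }
  disc <- c(multi_domain = 0L, wrong_strand = 0L, unmapped = 0L,
            single_exon = 0L, pseudogene = 0L, intron_downstream = 0L)
  assigned <- vector("list", nrow(domains))
  names(assigned) <- domains$gene_id
  for (i in seq_len(nrow(cdna))) {
    row <- cdna[i, ]
    bl <- parse_blocks(row)
    lo <- min(bl$start); hi <- max(bl$end)
    ov <- which(domains$chrom == row$chrom &
                  domains$domain_start < hi & lo < domains$domain_end)
    if (length(ov) == 0) { disc["unmapped"] <- disc["unmapped"] + 1L; next }
    if (length(ov) > 1) { disc["multi_domain"] <- disc["multi_domain"] + 1L; next }
    if (domains$strand[ov] != row$strand) {
      disc["wrong_strand"] <- disc["wrong_strand"] + 1L
      message("cDNA '", row$cdna_id, "' maps to the wrong strand of domain '",
              domains$gene_id[ov], "'; discarded")
      next
    }
    g <- domains$gene_id[ov]
    assigned[[g]] <- rbind(assigned[[g]], bl)
  }
  res <- list()
  for (i in seq_len(nrow(domains))) {
    g <- domains$gene_id[i]
    bl <- assigned[[g]]
    if (is.null(bl)) next                      # no transcript evidence
    bl <- rbind(bl, data.frame(start = domains$orf_start[i],
                               end = domains$orf_end[i]))
    ir <- IRanges::reduce(IRanges::IRanges(bl$start + 1L, bl$end),
                          min.gapwidth = merge_gap)
    ex <- data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    if (nrow(ex) == 1) { disc["single_exon"] <- disc["single_exon"] + 1L; next }
    if (domains$pseudo[i]) { disc["pseudogene"] <- disc["pseudogene"] + 1L; next }
    downstream_intron <- if (domains$strand[i] == "+") {
      any(ex$start >= domains$orf_end[i])
    } else {
      any(ex$end <= domains$orf_start[i])
    }
    if (downstream_intron) {
      disc["intron_downstream"] <- disc["intron_downstream"] + 1L; next
    }
    tss <- if (domains$strand[i] == "+") min(ex$start) else max(ex$end)
    res[[length(res) + 1]] <- data.frame(
      gene_id = g, chrom = domains$chrom[i], tss = tss,
      strand = domains$strand[i], stringsAsFactors = FALSE)
  }
  tss <- if (length(res)) do.call(rbind, res) else
    data.frame(gene_id = character(0), chrom = character(0),
               tss = integer(0), strand = character(0))
  list(tss = tss, discarded = disc)
}

# ---- NG86 synonymous divergence ------------------------------------------

GENETIC_CODE <- Biostrings::GENETIC_CODE

codon_syn_sites <- function(codon) {
  aa <- GENETIC_CODE[[codon]]
  s <- 0
  for (pos in 1:3) {
    base <- substr(codon, pos, pos)
    alts <- setdiff(DNA_BASES, base)
    syn <- 0
    for (b in alts) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (GENETIC_CODE[[mut]] == aa) syn <- syn + 1
    }
    s <- s + syn / 3
  }
  s
}

# Average synonymous/non-synonymous differences between two codons over all
# substitution pathways; pathways passing through stop codons are excluded
# unless every pathway does.
codon_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0) return(c(syn = 0, nonsyn = 0))
  perms <- permutations_of(pos)
  tallies <- list()
  for (r in seq_len(nrow(perms))) {
    cur <- c1; syn <- 0; nonsyn <- 0; stopped <- FALSE
    for (p in perms[r, ]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (GENETIC_CODE[[nxt]] == "*" || GENETIC_CODE[[cur]] == "*") {
        stopped <- TRUE
      }
      if (GENETIC_CODE[[nxt]] == GENETIC_CODE[[cur]]) syn <- syn + 1
      else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    tallies[[r]] <- c(syn = syn, nonsyn = nonsyn, stopped = stopped)
  }
  tl <- do.call(rbind, tallies)
  use <- if (any(tl[, "stopped"] == 0)) tl[tl[, "stopped"] == 0, , drop = FALSE]
  else tl
  c(syn = mean(use[, "syn"]), nonsyn = mean(use[, "nonsyn"]))
}

permutations_of <- function(v) {
  if (length(v) == 1) return(matrix(v, nrow = 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- permutations_of(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

#' Pairwise synonymous divergence (NG86 with Jukes-Cantor correction)
#'
#' Nei-Gojobori (1986) counting of synonymous sites and differences on an
#' in-frame pairwise comparison, with the Jukes-Cantor multiple-hit
#' correction `dS = -3/4 log(1 - 4/3 pS)`. Codons containing non-ACGT
#' characters or stop codons in either sequence are skipped.
#'
#' @param seq1,seq2 in-frame coding sequences of equal length (multiple of 3).
#' @return list with `ds` (`NA` with `note = "saturated"` when the JC
#'   argument is non-positive), `ps`, `syn_sites`, `syn_diffs`.
#' @export
ng86_ds <- function(seq1, seq2) {
  stopifnot(nchar(seq1) == nchar(seq2), nchar(seq1) %% 3 == 0)
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  n_cod <- nchar(seq1) / 3
  S <- 0; Sd <- 0
  for (i in seq_len(n_cod)) {
    c1 <- substr(seq1, 3 * i - 2, 3 * i)
    c2 <- substr(seq2, 3 * i - 2, 3 * i)
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
    if (GENETIC_CODE[[c1]] == "*" || GENETIC_CODE[[c2]] == "*") next
    S <- S + (codon_syn_sites(c1) + codon_syn_sites(c2)) / 2
    Sd <- Sd + codon_diffs(c1, c2)[["syn"]]
  }
  if (S == 0) return(list(ds = NA_real_, ps = NA_real_, syn_sites = 0,
                          syn_diffs = Sd, note = "no synonymous sites"))
  ps <- Sd / S
  arg <- 1 - 4 * ps / 3
  if (arg <= 0) {
    return(list(ds = NA_real_, ps = ps, syn_sites = S, syn_diffs = Sd,
                note = "saturated"))
  }
  list(ds = -0.75 * log(arg), ps = ps, syn_sites = S, syn_diffs = Sd,
       note = NA_character_)
}

#' Flag recently duplicated gene pairs by coding divergence or flank identity
#'
#' A pair is "similar" when its NG86 synonymous divergence is below `ds_max`
#' (default 0.3 substitutions per synonymous site) OR a local alignment of
#' the TSS-flanking sequences covers at least `min_len` bp at `min_ident`
#' identity (defaults 200 bp, 70%). Flank alignment uses +1/-1
#' match/mismatch scoring and is only attempted for pairs sharing at least
#' one exact 12-mer (a seed prefilter). A saturated dS never flags a pair.
#'
#' @param orf_seqs named character vector of in-frame coding sequences
#'   (`NULL` to skip the dS criterion).
#' @param flank_seqs named character vector of TSS-flanking sequences, ORF
#'   sequence removed (`NULL` to skip the identity criterion).
#' @param ds_max,min_len,min_ident decision thresholds.
#' @param seed_width width of the exact-match prefilter seed.
#' @return data.frame of flagged pairs: `id1`, `id2`, `criterion`
#'   (`"ds"`, `"identity"` or `"both"`), `ds`.
#' @export
pairwise_similarity <- function(orf_seqs = NULL, flank_seqs = NULL,
                                ds_max = 0.3, min_len = 200,
                                min_ident = 0.70, seed_width = 12L) {
  ids <- unique(c(names(orf_seqs), names(flank_seqs)))
  stopifnot(length(ids) >= 2)
  kmers <- NULL
  if (!is.null(flank_seqs)) {
    kmers <- lapply(flank_seqs, function(s) {
      s <- toupper(s)
      n <- nchar(s)
      if (n < seed_width) return(character(0))
      unique(substring(s, 1:(n - seed_width + 1), seed_width:n))
    })
  }
  out <- list()
  cmb <- combn(ids, 2)
  for (k in seq_len(ncol(cmb))) {
    a <- cmb[1, k]; b <- cmb[2, k]
    ds <- NA_real_; by_ds <- FALSE; by_id <- FALSE
    if (!is.null(orf_seqs) && a %in% names(orf_seqs) && b %in% names(orf_seqs)) {
      r <- ng86_ds(orf_seqs[[a]], orf_seqs[[b]])
      ds <- r$ds
      by_ds <- !is.na(ds) && ds < ds_max
    }
    if (!is.null(flank_seqs) && a %in% names(flank_seqs) &&
        b %in% names(flank_seqs) &&
        length(intersect(kmers[[a]], kmers[[b]])) > 0) {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(toupper(flank_seqs[[a]])),
        Biostrings::DNAString(toupper(flank_seqs[[b]])),
        type = "local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -1),
        gapOpening = 2, gapExtension = 1)
      w <- Biostrings::nchar(al)
      if (w >= min_len && Biostrings::pid(al) >= min_ident * 100) {
        by_id <- TRUE
      }
    }
    if (by_ds || by_id) {
      out[[length(out) + 1]] <- data.frame(
        id1 = a, id2 = b,
        criterion = if (by_ds && by_id) "both" else if (by_ds) "ds" else
          "identity",
        ds = ds, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(id1 = character(0), id2 = character(0),
               criterion = character(0), ds = numeric(0))
}

#' Single-linkage deduplication of similar items
#'
#' Builds connected components of the similarity-pair graph (single-linkage
#' clusters) and keeps one representative per component, chosen by a seeded
#' RNG so the "arbitrary" choice is reproducible. Singletons represent
#' themselves.
#'
#' @param ids character vector of all items.
#' @param pairs data.frame with columns `id1`, `id2` (may be empty).
#' @param seed RNG seed for representative choice (default 42).
#' @return list with `clusters` (list of character vectors) and
#'   `representatives` (character vector, one per cluster).
#' @export
dedup_single_linkage <- function(ids, pairs, seed = 42L) {
  stopifnot(all(c(pairs$id1, pairs$id2) %in% ids))
  parent <- seq_along(ids)
  names(parent) <- ids
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(match(pairs$id1[k], ids)); b <- find(match(pairs$id2[k], ids))
    if (a != b) parent[b] <- a
  }
  root <- vapply(seq_along(ids), find, integer(1))
  clusters <- split(ids, root)
  names(clusters) <- NULL
  reps <- with_seed(seed, vapply(clusters, function(cl) {
    cl[sample.int(length(cl), 1)]
  }, character(1)))
  list(clusters = clusters, representatives = reps)
}

#' Extract TSS-anchored promoter and preceding-region sequences
#'
#' For each TSS, takes the `L` bp immediately upstream (genomic
#' `[tss - L, tss)` on the + strand, `[tss, tss + L)` reverse-complemented on
#' the - strand, 0-based half-open) so all promoters read 5'->3' toward the
#' TSS, plus the preceding `L` bp (`[-2L, -L)` in the TSS-relative frame) as
#' the matched control region. Promoters running off a contig edge are
#' dropped with a warning.
#'
#' @param genome named character vector or `Biostrings::DNAStringSet` (or a
#'   FASTA path) of contig sequences.
#' @param tss_table data.frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @param L promoter length in bp (default 200).
#' @return A `promoter_set`: list with `promoters` (data.frame `id`, `chrom`,
#'   `tss`, `strand`, `sequence`, `preceding`), `L`, and optional `scores`.
#' @export
extract_promoters <- function(genome, tss_table, L = 200L) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome),
                       sub("\\s.*$", "", names(genome)))
  }
  rows <- list()
  for (i in seq_len(nrow(tss_table))) {
    r <- tss_table[i, ]
    contig <- genome[[r$chrom]]
    n <- nchar(contig)
    if (r$strand == "+") {
      ps <- r$tss - L; pe <- r$tss          # promoter  [tss-L, tss)
      cs <- r$tss - 2 * L; ce <- r$tss - L  # preceding [tss-2L, tss-L)
    } else {
      ps <- r$tss; pe <- r$tss + L
      cs <- r$tss + L; ce <- r$tss + 2 * L
    }
    if (cs < 0 || ce > n || ps < 0 || pe > n) {
      warning("promoter '", r$gene_id, "' runs off contig '", r$chrom,
              "'; dropped")
      next
    }
    sq <- substr(contig, ps + 1, pe)
    pc <- substr(contig, cs + 1, ce)
    if (r$strand == "-") { sq <- revcomp(sq); pc <- revcomp(pc) }
    rows[[length(rows) + 1]] <- data.frame(
      id = r$gene_id, chrom = r$chrom, tss = r$tss, strand = r$strand,
      sequence = sq, preceding = pc, stringsAsFactors = FALSE)
  }
  promoter_set(do.call(rbind, rows), L = L)
}

#' Construct a promoter_set container
#'
#' @param promoters data.frame with at least `id` and `sequence` (length-`L`
#'   strings reading toward the TSS); optional `preceding`, `chrom`, `tss`,
#'   `strand`.
#' @param L promoter length.
#' @param scores optional named list of per-base conservation score vectors.
#' @export
promoter_set <- function(promoters, L, scores = NULL) {
  stopifnot(all(c("id", "sequence") %in% names(promoters)),
            all(nchar(promoters$sequence) == L))
  if (!"preceding" %in% names(promoters)) promoters$preceding <- NA_character_
  rownames(promoters) <- NULL
  structure(list(promoters = promoters, L = as.integer(L), scores = scores),
            class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("<promoter_set> %d promoters, L = %d bp%s\n",
              nrow(x$promoters), x$L,
              if (!is.null(x$scores)) ", with conservation scores" else ""))
  invisible(x)
}

#' Positional profile of a per-base track across promoters
#'
#' Averages per-base values across promoters at each TSS-relative position,
#' then smooths with a sliding window, reporting values at window centers.
#' Used with an indicator track (promoter has >= 1 site covering the base;
#' window 20, slide 1) for site-coverage profiles, and with a GC indicator
#' (window 50, slide 10) for GC profiles.
#'
#' @param tracks numeric matrix, promoters x positions (`NA` allowed), with
#'   an `offset` attribute giving the TSS-relative coordinate of column 1
#'   (default `-ncol`).
#' @param window,slide window width and step in bp.
#' @return data.frame with `position` (window center, TSS-relative) and
#'   `value`.
#' @export
positional_profile <- function(tracks, window = 20L, slide = 1L) {
  tracks <- as.matrix(tracks)
  npos <- ncol(tracks)
  if (window > npos) stop("window (", window, ") exceeds track length (",
                          npos, ")")
  offset <- attr(tracks, "offset") %||% -npos
  colmean <- colMeans(tracks, na.rm = TRUE)
  starts <- seq(1, npos - window + 1, by = slide)
  data.frame(
    position = offset + starts - 1 + (window - 1) / 2,
    value = vapply(starts, function(s) {
      mean(colmean[s:(s + window - 1)], na.rm = TRUE)
    }, numeric(1)))
}

#' @rdname positional_profile
#' @param hits pruned `site_hits` (TSS-relative coordinates).
#' @param pset a [promoter_set].
#' @param families optional family subset.
#' @return `coverage_track()`: promoters x L 0/1 matrix (offset `-L`) marking
#'   bases covered by at least one hit.
#' @export
coverage_track <- function(hits, pset, families = NULL) {
  L <- pset$L
  ids <- pset$promoters$id
  m <- matrix(0, nrow = length(ids), ncol = L,
              dimnames = list(ids, NULL))
  if (!is.null(families)) hits <- hits[hits$family_id %in% families, ]
  for (k in seq_len(nrow(hits))) {
    i <- match(hits$promoter_id[k], ids)
    if (is.na(i)) next
    cols <- seq(max(hits$start[k], -L), min(hits$end[k], 0) - 1) + L + 1
    cols <- cols[cols >= 1 & cols <= L]
    m[i, cols] <- 1
  }
  attr(m, "offset") <- -L
  m
}

#' @rdname positional_profile
#' @return `gc_track()`: promoters x L 0/1 matrix (1 = G or C; masked bases
#'   `NA`).
#' @export
gc_track <- function(pset) {
  L <- pset$L
  m <- t(vapply(pset$promoters$sequence, function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    v <- ifelse(ch %in% c("G", "C"), 1, ifelse(ch %in% c("A", "T"), 0, NA))
    as.numeric(v)
  }, numeric(L)))
  rownames(m) <- pset$promoters$id
  attr(m, "offset") <- -L
  m
}
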