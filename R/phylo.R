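#' Coordinate maps between ungapped sequences and alignment columns
#'
#' For each row of a promoter alignment, returns the bijection between the
#' row's ungapped positions and alignment columns: `u2c[i]` is the column of
#' ungapped position `i`, and `c2u[j]` the ungapped position at column `j`
#' (`NA` at gaps; "exact only" — no nearest-column fallback).
#'
#' @param aln named character vector of equal-length gapped rows
#'   (`A/C/G/T/N/-`), reference species first.
#' @return named list per species: `list(u2c = ..., c2u = ...)`.
#' @export
alignment_coordinate_maps <- function(aln) {
  if (length(unique(nchar(aln))) != 1) {
    stop("alignment rows have inconsistent lengths")
  }
  lapply(aln, function(row) {
    ch <- strsplit(row, "")[[1]]
    bad <- !ch %in% c("A", "C", "G", "T", "N", "-", "a", "c", "g", "t", "n")
    if (any(bad)) stop("invalid alignment character(s): ",
                       paste(unique(ch[bad]), collapse = ""))
    isbase <- ch != "-"
    u2c <- which(isbase)
    c2u <- rep(NA_integer_, length(ch))
    c2u[isbase] <- seq_len(sum(isbase))
    list(u2c = u2c, c2u = c2u)
  })
}

#' Which species support each reference site, allowing positional slide
#'
#' A species supports a reference site when one of its own predicted sites,
#' mapped to alignment columns, lies within `slide_w` columns of the
#' reference site's column interval (`slide_w = 0` requires overlap). This
#' accommodates evolutionary turnover, where a functional site persists
#' nearby rather than at the exactly orthologous position. The reference
#' species always supports its own sites.
#'
#' @param ref_sites data.frame with `start`, `end` (0-based half-open,
#'   ungapped reference coordinates within the aligned region).
#' @param species_sites named list (species -> data.frame with
#'   `start`,`end` in that species' ungapped coordinates). Species absent
#'   from the alignment contribute no support.
#' @param maps output of [alignment_coordinate_maps()].
#' @param ref reference species name (default: first map).
#' @param slide_w allowed slide in alignment columns (default 50).
#' @return list of character vectors: supporting species per reference site.
#' @export
cross_species_presence <- function(ref_sites, species_sites, maps,
                                   ref = names(maps)[1], slide_w = 50) {
  to_cols <- function(sites, map) {
    n <- length(map$u2c)
    lapply(seq_len(nrow(sites)), function(i) {
      u <- seq(sites$start[i] + 1L, sites$end[i])   # 1-based ungapped
      u <- u[u >= 1 & u <= n]
      if (!length(u)) return(NULL)
      range(map$u2c[u])
    })
  }
  ref_cols <- to_cols(ref_sites, maps[[ref]])
  lapply(seq_len(nrow(ref_sites)), function(i) {
    rc <- ref_cols[[i]]
    if (is.null(rc)) return(character(0))
    supp <- ref
    for (sp in names(species_sites)) {
      if (sp == ref || !sp %in% names(maps)) next
      sc <- to_cols(species_sites[[sp]], maps[[sp]])
      for (cc in sc) {
        if (is.null(cc)) next
        # closed column intervals within slide_w of each other
        if (rc[1] <= cc[2] + slide_w && cc[1] <= rc[2] + slide_w) {
          supp <- c(supp, sp); break
        }
      }
    }
    unique(supp)
  })
}

#' Total branch length of the minimal subtree connecting a species subset
#'
#' Sums the branch lengths of the spanning subtree connecting the given
#' leaves, excluding everything above their most recent common ancestor.
#' A singleton subset has length 0. This is the site-conservation measure:
#' larger subtree length means the site is shared across more deeply
#' diverged species.
#'
#' @param tree an `ape::phylo` tree with branch lengths
#'   (substitutions/site).
#' @param species character vector of leaf names (must all be in the tree).
#' @return total branch length (numeric).
#' @export
subtree_branch_length <- function(tree, species) {
  stopifnot(inherits(tree, "phylo"), length(species) >= 1)
  missing <- setdiff(species, tree$tip.label)
  if (length(missing)) {
    stop("species not in tree: ", paste(missing, collapse = ", "))
  }
  species <- unique(species)
  if (length(species) == 1) return(0)
  tips <- match(species, tree$tip.label)
  n_tip <- length(tree$tip.label)
  # count subset members below each edge's child node
  n_node <- max(tree$edge)
  below <- integer(n_node)
  below[tips] <- 1L
  # process edges child-first (post-order): order by child node via repeated
  # relaxation is unnecessary -- use ape's reorder
  tr <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    below[tr$edge[k, 1]] <- below[tr$edge[k, 1]] + below[tr$edge[k, 2]]
  }
  m <- length(species)
  keep <- below[tr$edge[, 2]] >= 1 & below[tr$edge[, 2]] < m
  sum(tr$edge.length[keep])
}

#' Filter sites by the subtree length of their supporting species
#'
#' Keeps reference sites whose supporting-species subtree length is at least
#' `min_tree_len` (default 0.17, i.e. conserved beyond the mouse-rat clade
#' in the placental tree used here) at the slide allowance already applied
#' when computing support.
#'
#' @param sites data.frame of reference sites with a `promoter_id` column.
#' @param support list of supporting-species vectors, parallel to `sites`
#'   (from [cross_species_presence()]).
#' @param tree `ape::phylo` species tree.
#' @param min_tree_len minimum subtree branch length (default 0.17).
#' @return list with `sites` (kept rows plus `tree_length` and `n_species`),
#'   `per_promoter` (conserved-site counts for every promoter id present in
#'   `sites`), and `fraction_with_site` (fraction of those promoters with at
#'   least one conserved site).
#' @export
filter_conserved_sites <- function(sites, support, tree, min_tree_len = 0.17) {
  stopifnot(nrow(sites) == length(support))
  tl <- vapply(support, function(sp) {
    if (length(sp) == 0) return(0)
    subtree_branch_length(tree, sp)
  }, numeric(1))
  keep <- tl >= min_tree_len
  kept <- sites[keep, , drop = FALSE]
  kept$tree_length <- tl[keep]
  kept$n_species <- lengths(support)[keep]
  all_ids <- unique(sites$promoter_id)
  per <- table(factor(kept$promoter_id, levels = all_ids))
  list(sites = kept,
       per_promoter = setNames(as.integer(per), all_ids),
       fraction_with_site = mean(per >= 1))
}

#' Merge lifted orthologous promoter regions, keeping the most upstream span
#'
#' Overlapping same-strand regions (e.g. several reference promoters lifting
#' to the same orthologous locus after a lineage-specific duplication) are
#' merged, and each merged run is replaced by its most upstream window of
#' the original width: the leftmost on + strand, the rightmost on - strand.
#'
#' @param regions data.frame (or BED path) with `chrom`, `start`, `end`,
#'   `strand`; all regions must share one width (typically 4 kb around a
#'   lifted TSS).
#' @return data.frame of non-redundant regions.
#' @export
ortholog_region_merge <- function(regions) {
  if (is.character(regions)) regions <- read_bed(regions)
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(regions)))
  w <- unique(regions$end - regions$start)
  if (length(w) != 1) stop("regions must share a single width; got ",
                           paste(w, collapse = ", "))
  out <- lapply(split(regions, paste(regions$chrom, regions$strand)), function(g) {
    mi <- merge_intervals(g$start, g$end)
    start <- if (g$strand[1] == "+") mi$start else mi$end - w
    data.frame(chrom = g$chrom[1], start = start, end = start + w,
               strand = g$strand[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# BED6 reader (only the columns we use) with line-numbered parse errors.
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 3 || is.na(suppressWarnings(as.integer(f[2]))) ||
        is.na(suppressWarnings(as.integer(f[3])))) {
      stop("malformed BED at line ", i, ": '", lines[i], "'")
    }
    data.frame(chrom = f[1], start = as.integer(f[2]), end = as.integer(f[3]),
               name = if (length(f) >= 4) f[4] else NA_character_,
               score = if (length(f) >= 5) f[5] else NA_character_,
               strand = if (length(f) >= 6) f[6] else "+",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read pre-cut MAF alignment blocks, one alignment per reference region
#'
#' Minimal MAF reader for per-promoter alignment blocks: each `a` paragraph
#' becomes one alignment; `s` lines contribute rows named by the source
#' (text before the first `.` is taken as the species). The first `s` line
#' of a block is the reference row. Blocks are keyed by the reference
#' source's sequence name when present.
#'
#' @param path MAF file path.
#' @return list of named character vectors (gapped rows, reference first).
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- character(0); cur_names <- character(0)
  flush <- function() {
    if (length(cur)) {
      blocks[[length(blocks) + 1]] <<- setNames(cur, cur_names)
    }
    cur <<- character(0); cur_names <<- character(0)
  }
  for (ln in lines) {
    if (grepl("^a", ln)) { flush(); next }
    if (grepl("^s\\s", ln)) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      cur <- c(cur, f[7])
      cur_names <- c(cur_names, sub("\\..*$", "", f[2]))
    }
  }
  flush()
  blocks
}
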