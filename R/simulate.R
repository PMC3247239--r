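#' Configuration for the synthetic promoter-set generator
#'
#' The defaults emulate the measured properties of the promoter family the
#' pipeline was designed around: AT-rich promoters (36.4% GC), a dominant
#' long motif planted at a mean of 1.38 sites per 200-bp promoter with a
#' TSS-proximal positional bias, elevated conservation inside planted sites,
#' cross-species site sets with positional turnover, and recent-duplicate
#' sequence pairs.
#'
#' @param n_promoters number of promoters (default 300).
#' @param L promoter length in bp (default 200).
#' @param gc_target stationary GC fraction of the background chain
#'   (default 0.364).
#' @param kappa same-base stickiness of the first-order background chain in
#'   `[0, 1)`; 0 gives an i.i.d. background (default 0.2).
#' @param planted list of planting specs, each
#'   `list(pwm = <pwm>, mean = sites/promoter, law = "uniform"` or
#'   `list("gaussian", mu = center bp, sd = bp))`.
#' @param conservation `list(base = c(shapeA, shapeB), boost = delta)`:
#'   background scores are Beta(shapeA, shapeB), planted-site bases gain
#'   `boost` (clipped at 1).
#' @param tree `ape::phylo` species tree for turnover simulation (`NULL`
#'   to skip).
#' @param turnover `list(loss_rate = per unit branch length,
#'   slide_jitter = sd in bp)`.
#' @param duplicates `list(n_pairs = count, sub_rate = per-base rate)`.
#' @param seed master seed; all sub-streams derive from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_promoters = 300L, L = 200L, gc_target = 0.364,
                       kappa = 0.2, planted = list(),
                       conservation = list(base = c(2, 8), boost = 0.4),
                       tree = NULL,
                       turnover = list(loss_rate = 1.0, slide_jitter = 10),
                       duplicates = list(n_pairs = 0L, sub_rate = 0.05),
                       seed = 1L) {
  stopifnot(gc_target > 0, gc_target < 1, kappa >= 0, kappa < 1,
            n_promoters >= 1, L >= 10)
  for (pl in planted) {
    stopifnot(inherits(pl$pwm, "pwm"), pl$mean >= 0)
    if (ncol(pl$pwm$counts) > L) {
      stop("planted site '", pl$pwm$id, "' is longer than the promoter")
    }
  }
  structure(list(n_promoters = as.integer(n_promoters), L = as.integer(L),
                 gc_target = gc_target, kappa = kappa, planted = planted,
                 conservation = conservation, tree = tree,
                 turnover = turnover, duplicates = duplicates,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# One background sequence from the first-order chain: stationary base
# frequencies ((1-gc)/2, gc/2, gc/2, (1-gc)/2); each base repeats the
# previous one with probability kappa, otherwise draws fresh.
markov_background <- function(m, gc, kappa) {
  pi <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  fresh <- sample.int(4, m, replace = TRUE, prob = pi)
  if (kappa > 0 && m > 1) {
    cp <- c(FALSE, runif(m - 1) < kappa)
    anchor <- cummax(ifelse(cp, 0L, seq_len(m)))
    fresh <- fresh[anchor]
  }
  paste(DNA_BASES[fresh], collapse = "")
}

sample_site <- function(p) {
  paste(DNA_BASES[vapply(seq_len(ncol(p$freq)), function(i) {
    sample.int(4, 1, prob = p$freq[, i])
  }, integer(1))], collapse = "")
}

#' Simulate a promoter set with planted motif instances
#'
#' Draws `2L` bp of background per promoter from the first-order chain (the
#' upstream half is the preceding control region, the downstream half the
#' promoter), then plants motif instances: per promoter and planting spec,
#' the site count is Poisson(`mean`), site centers follow the positional law
#' (uniform over the promoter, or Gaussian in TSS-relative bp), strands are
#' random, and site sequences are sampled column-wise from the PWM and
#' spliced in. Planting is restricted to the promoter region.
#'
#' @param cfg a [sim_config()].
#' @return list with `pset` (a [promoter_set]) and `truth` (`site_hits`-like
#'   data.frame of planted intervals with TSS-relative coordinates).
#' @export
simulate_promoters <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- cfg$L
  with_seed(derive_seed(cfg$seed, "promoters"), {
    ids <- sprintf("prom%04d", seq_len(cfg$n_promoters))
    truth <- list()
    rows <- lapply(seq_len(cfg$n_promoters), function(i) {
      full <- markov_background(2 * L, cfg$gc_target, cfg$kappa)
      prom <- substr(full, L + 1, 2 * L)
      for (pl in cfg$planted) {
        w <- ncol(pl$pwm$counts)
        k <- rpois(1, pl$mean)
        if (k == 0) next
        for (s in seq_len(k)) {
          center <- if (identical(pl$law, "uniform") || is.null(pl$law)) {
            runif(1, -L + w / 2, -w / 2)
          } else {
            rnorm(1, pl$law$mu, pl$law$sd)
          }
          start <- round(center - w / 2)
          start <- max(-L, min(start, -w))      # clip to fit the promoter
          strand <- sample(c("+", "-"), 1)
          site <- sample_site(pl$pwm)
          if (strand == "-") site <- revcomp(site)
          idx <- start + L + 1                   # 1-based within promoter
          substr(prom, idx, idx + w - 1) <- site
          truth[[length(truth) + 1]] <<- data.frame(
            promoter_id = ids[i], start = as.integer(start),
            end = as.integer(start + w), strand = strand,
            pwm_id = pl$pwm$id, family_id = pl$pwm$family_id,
            stringsAsFactors = FALSE)
        }
      }
      data.frame(id = ids[i], chrom = NA_character_, tss = NA_integer_,
                 strand = "+", sequence = prom,
                 preceding = substr(full, 1, L), stringsAsFactors = FALSE)
    })
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(promoter_id = character(0), start = integer(0),
                 end = integer(0), strand = character(0),
                 pwm_id = character(0), family_id = character(0))
    list(pset = promoter_set(do.call(rbind, rows), L = L), truth = truth)
  })
}

#' Simulate per-base conservation scores with boosted planted sites
#'
#' Background scores are i.i.d. Beta(shapeA, shapeB); every base inside a
#' planted site gains `boost`, clipped at 1. With `boost = 0` the in-site
#' and out-of-site distributions are identical (a null for the rank-sum
#' test).
#'
#' @param pset a [promoter_set].
#' @param truth planted-site table from [simulate_promoters()].
#' @param base length-2 Beta shape parameters.
#' @param boost additive in-site score increment (>= 0).
#' @param seed integer seed.
#' @return the promoter set with `$scores` filled in.
#' @export
simulate_conservation <- function(pset, truth, base = c(2, 8), boost = 0.4,
                                  seed = 1L) {
  stopifnot(boost >= 0)
  L <- pset$L
  with_seed(derive_seed(seed, "conservation"), {
    scores <- lapply(pset$promoters$id, function(pid) {
      v <- rbeta(L, base[1], base[2])
      th <- truth[truth$promoter_id == pid, , drop = FALSE]
      for (k in seq_len(nrow(th))) {
        cols <- seq(th$start[k], th$end[k] - 1L) + L + 1L
        cols <- cols[cols >= 1 & cols <= L]
        v[cols] <- pmin(1, v[cols] + boost)
      }
      v
    })
    names(scores) <- pset$promoters$id
    pset$scores <- scores
    pset
  })
}

#' Simulate cross-species site sets with turnover
#'
#' Each planted reference site survives on every non-reference leaf with
#' probability `exp(-loss_rate * d)`, where `d` is the patristic distance
#' from the reference leaf; surviving sites are jittered by
#' `round(Normal(0, slide_jitter))` bp to emulate positional turnover.
#' Gapless alignments are emitted (every species row equals the reference
#' promoter sequence), so alignment column equals ungapped position.
#'
#' @param pset a [promoter_set].
#' @param truth planted-site table (TSS-relative coordinates).
#' @param tree `ape::phylo` species tree.
#' @param ref reference species (a tip label; default the first tip).
#' @param loss_rate site-loss rate per unit branch length.
#' @param slide_jitter sd (bp) of the positional jitter.
#' @param seed integer seed.
#' @return list per promoter: `alignment` (named gapped rows, reference
#'   first), `ref_sites` (0-based within-region coordinates plus the truth
#'   columns), `species_sites` (named list of site tables in each species'
#'   own ungapped coordinates).
#' @export
simulate_species_sets <- function(pset, truth, tree, ref = tree$tip.label[1],
                                  loss_rate = 1.0, slide_jitter = 10,
                                  seed = 1L) {
  stopifnot(inherits(tree, "phylo"), ref %in% tree$tip.label,
            loss_rate >= 0, slide_jitter >= 0)
  L <- pset$L
  d <- ape::cophenetic.phylo(tree)[ref, ]
  others <- setdiff(tree$tip.label, ref)
  with_seed(derive_seed(seed, "species"), {
    out <- lapply(seq_len(nrow(pset$promoters)), function(i) {
      pid <- pset$promoters$id[i]
      seqrow <- pset$promoters$sequence[i]
      aln <- setNames(rep(seqrow, length(tree$tip.label)),
                      c(ref, others))
      th <- truth[truth$promoter_id == pid, , drop = FALSE]
      ref_sites <- data.frame(start = th$start + L, end = th$end + L,
                              promoter_id = th$promoter_id,
                              family_id = th$family_id,
                              stringsAsFactors = FALSE)
      species_sites <- lapply(others, function(sp) {
        keep <- runif(nrow(ref_sites)) < exp(-loss_rate * d[sp])
        ss <- ref_sites[keep, c("start", "end"), drop = FALSE]
        if (nrow(ss)) {
          w <- ss$end - ss$start
          jit <- round(rnorm(nrow(ss), 0, slide_jitter))
          ss$start <- pmin(pmax(ss$start + jit, 0L), L - w)
          ss$end <- ss$start + w
        }
        ss
      })
      names(species_sites) <- others
      list(promoter_id = pid, alignment = aln, ref_sites = ref_sites,
           species_sites = species_sites)
    })
    names(out) <- pset$promoters$id
    out
  })
}

#' Augment a sequence set with mutated duplicate copies
#'
#' Copies `n_pairs` sequences, substituting each base independently with
#' probability `sub_rate` (to a uniformly chosen different base), and
#' records the true duplicate pairs — a test bed for the
#' similarity-flagging and single-linkage deduplication steps.
#'
#' @param seqs named character vector.
#' @param n_pairs number of duplicates to create (the first `n_pairs`
#'   sequences are copied).
#' @param sub_rate per-base substitution probability in `[0, 0.3]`.
#' @param seed integer seed.
#' @return list with `seqs` (augmented, copies named `<id>_dup`) and
#'   `pairs` (data.frame `id1`, `id2`).
#' @export
simulate_duplicates <- function(seqs, n_pairs, sub_rate = 0.05, seed = 1L) {
  stopifnot(sub_rate >= 0, sub_rate <= 0.3, n_pairs <= length(seqs))
  with_seed(derive_seed(seed, "duplicates"), {
    pairs <- list()
    for (i in seq_len(n_pairs)) {
      id <- names(seqs)[i]
      ch <- strsplit(toupper(seqs[[i]]), "")[[1]]
      mut <- runif(length(ch)) < sub_rate & ch %in% DNA_BASES
      ch[mut] <- vapply(ch[mut], function(b) {
        sample(setdiff(DNA_BASES, b), 1)
      }, character(1))
      dup_id <- paste0(id, "_dup")
      seqs[[dup_id]] <- paste(ch, collapse = "")
      pairs[[i]] <- data.frame(id1 = id, id2 = dup_id,
                               stringsAsFactors = FALSE)
    }
    list(seqs = seqs,
         pairs = if (length(pairs)) do.call(rbind, pairs) else
           data.frame(id1 = character(0), id2 = character(0)))
  })
}

#' A library of random decoy matrices for null-calibration runs
#'
#' Generates `n` synthetic PWMs of the given lengths: each column is a
#' Dirichlet draw sharpened toward a random preferred base, giving matrices
#' with realistic information content but no relationship to the simulated
#' promoters.
#'
#' @param n number of decoy matrices (one family each).
#' @param lengths vector of candidate matrix lengths, sampled uniformly.
#' @param seed integer seed.
#' @param concentration sharpness of columns (larger = more specific).
#' @return a [pwm_library()].
#' @export
decoy_library <- function(n = 50L, lengths = 8:14, seed = 1L,
                          concentration = 8) {
  with_seed(derive_seed(seed, "decoys"), {
    pwms <- lapply(seq_len(n), function(i) {
      Lw <- sample(lengths, 1)
      counts <- vapply(seq_len(Lw), function(j) {
        pref <- sample.int(4, 1)
        alpha <- rep(0.5, 4); alpha[pref] <- concentration
        g <- rgamma(4, alpha)
        round(100 * g / sum(g), 2)
      }, numeric(4))
      pwm(counts, id = sprintf("DECOY%03d_01", i),
          family_id = sprintf("D$DEC%03d", i))
    })
    pwm_library(pwms)
  })
}
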