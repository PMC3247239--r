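test_that("alignment coordinate maps round-trip on gapped rows", {
  # "AC-GT": ungapped position 3 (the G) sits in column 4
  m <- alignment_coordinate_maps(c(sp = "AC-GT"))$sp
  expect_equal(m$u2c[3], 4)
  expect_equal(m$c2u[4], 3)
  expect_true(is.na(m$c2u[3]))

  # gapless row: identity map
  mg <- alignment_coordinate_maps(c(sp = "ACGT"))$sp
  expect_equal(mg$u2c, 1:4)
  expect_equal(mg$c2u, 1:4)

  # random gapped rows: map then inverse is the identity on defined positions
  set.seed(15)
  for (rep in 1:10) {
    chars <- sample(c("A", "C", "G", "T", "-"), 60, TRUE,
                    prob = c(0.2, 0.2, 0.2, 0.2, 0.2))
    row <- paste(chars, collapse = "")
    if (!grepl("[ACGT]", row)) next
    m <- alignment_coordinate_maps(c(x = row))$x
    expect_equal(m$c2u[m$u2c], seq_along(m$u2c))
  }

  expect_error(alignment_coordinate_maps(c(a = "ACGT", b = "ACG")),
               "inconsistent")
})

test_that("cross-species support honours the slide allowance", {
  aln <- c(mouse = strrep("A", 200), human = strrep("A", 200))
  maps <- alignment_coordinate_maps(aln)
  ref <- data.frame(start = 100, end = 121)

  # exactly aligned: supported even with no slide
  sup0 <- cross_species_presence(ref, list(human = data.frame(start = 100,
                                                              end = 121)),
                                 maps, ref = "mouse", slide_w = 0)
  expect_setequal(sup0[[1]], c("mouse", "human"))

  # displaced by 30 columns: supported at slide 50, not at slide 0
  disp <- list(human = data.frame(start = 151, end = 172))
  expect_setequal(cross_species_presence(ref, disp, maps, "mouse", 50)[[1]],
                  c("mouse", "human"))
  expect_identical(cross_species_presence(ref, disp, maps, "mouse", 0)[[1]],
                   "mouse")

  # brute-force all-pairs column distance on random placements
  set.seed(16)
  for (rep in 1:10) {
    w <- 10
    rs <- sort(sample(0:180, 3)); ref2 <- data.frame(start = rs, end = rs + w)
    hs <- sort(sample(0:180, 4)); hum <- data.frame(start = hs, end = hs + w)
    sw <- sample(c(0, 10, 50), 1)
    got <- cross_species_presence(ref2, list(human = hum), maps, "mouse", sw)
    for (i in seq_len(3)) {
      # oracle: gap between closed column intervals <= slide (overlap if 0)
      a1 <- rs[i] + 1; a2 <- rs[i] + w
      ok <- any(vapply(seq_len(4), function(j) {
        b1 <- hs[j] + 1; b2 <- hs[j] + w
        a1 <= b2 + sw && b1 <= a2 + sw
      }, logical(1)))
      expect_identical("human" %in% got[[i]], ok)
    }
  }

  # support sets only grow with slide_w
  for (rep in 1:5) {
    rs <- sort(sample(0:180, 3)); ref3 <- data.frame(start = rs, end = rs + 10)
    hs <- sort(sample(0:180, 3)); hum <- list(human = data.frame(start = hs,
                                                                 end = hs + 10))
    sup <- lapply(c(0, 10, 50), function(sw)
      cross_species_presence(ref3, hum, maps, "mouse", sw))
    for (i in 1:3) {
      expect_true(all(sup[[1]][[i]] %in% sup[[2]][[i]]))
      expect_true(all(sup[[2]][[i]] %in% sup[[3]][[i]]))
    }
  }
})

test_that("subtree branch length matches the worked mammalian examples and ape pruning", {
  tr <- fixture_tree()
  expect_equal(subtree_branch_length(tr, c("mouse", "rat")), 0.161)
  expect_equal(subtree_branch_length(tr, c("mouse", "human")), 0.453)
  expect_equal(subtree_branch_length(tr, c("mouse", "rat", "human")), 0.537)
  expect_equal(subtree_branch_length(tr, "mouse"), 0)

  # simple two-leaf tree: sum of pendant branches
  t2 <- ape::read.tree(text = "(a:0.10,b:0.05);")
  expect_equal(subtree_branch_length(t2, c("a", "b")), 0.15)

  expect_error(subtree_branch_length(tr, c("mouse", "yeti")), "yeti")

  # random trees: agree with ape::keep.tip and be monotone under inclusion
  set.seed(18)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    rt <- ape::rtree(n)
    k <- sample(2:n, 1)
    tips <- sample(rt$tip.label, k)
    expect_equal(subtree_branch_length(rt, tips),
                 sum(ape::keep.tip(rt, tips)$edge.length),
                 tolerance = 1e-12)
    if (k > 2) {
      expect_lte(subtree_branch_length(rt, tips[-1]),
                 subtree_branch_length(rt, tips) + 1e-12)
    }
  }
})

test_that("conserved-site filtering applies the tree-length threshold and reports per-promoter counts", {
  tr <- fixture_tree()
  sites <- data.frame(promoter_id = c("p1", "p1", "p2", "p3"),
                      start = c(10, 60, 20, 30),
                      end = c(31, 81, 41, 51))
  support <- list(c("mouse"),                      # 0 -> dropped
                  c("mouse", "rat"),               # 0.161 < 0.17 -> dropped
                  c("mouse", "rat", "human"),      # 0.537 -> kept
                  c("mouse", "human"))             # 0.453 -> kept
  r <- filter_conserved_sites(sites, support, tr, min_tree_len = 0.17)
  expect_equal(nrow(r$sites), 2)
  expect_equal(unname(r$per_promoter), c(0L, 1L, 1L))
  expect_equal(r$fraction_with_site, 2 / 3)
  # mouse-rat passes at a threshold of 0.15
  r2 <- filter_conserved_sites(sites, support, tr, min_tree_len = 0.15)
  expect_equal(nrow(r2$sites), 3)
})

test_that("conserved-site counts are monotone in slide and tree-length threshold", {
  tr <- fixture_tree()
  oe <- fixture_oe_pwm()
  cfg <- sim_config(n_promoters = 40, L = 200, seed = 19, tree = tr,
                    planted = list(list(pwm = oe, mean = 1.4,
                                        law = list(mu = -70, sd = 30))))
  sim <- simulate_promoters(cfg)
  sp <- simulate_species_sets(sim$pset, sim$truth, tr, loss_rate = 1.0,
                              slide_jitter = 10, seed = 19)
  count_kept <- function(slide_w, min_len) {
    tot <- 0
    for (pr in sp) {
      if (nrow(pr$ref_sites) == 0) next
      maps <- alignment_coordinate_maps(pr$alignment)
      sup <- cross_species_presence(pr$ref_sites, pr$species_sites, maps,
                                    ref = "mouse", slide_w = slide_w)
      tot <- tot + nrow(filter_conserved_sites(pr$ref_sites, sup, tr,
                                               min_len)$sites)
    }
    tot
  }
  by_slide <- vapply(c(0, 10, 50), count_kept, numeric(1), min_len = 0.17)
  expect_true(all(diff(by_slide) >= 0))
  by_len <- vapply(c(0.17, 0.5, 1.5), function(ml) count_kept(50, ml),
                   numeric(1))
  expect_true(all(diff(by_len) <= 0))
  expect_gt(by_slide[3], 0)
})

test_that("ortholog region merging keeps the most upstream window per strand", {
  # two + regions offset by 1 kb merge into the left window
  r <- data.frame(chrom = "chr1", start = c(1000, 2000),
                  end = c(5000, 6000), strand = "+")
  m <- ortholog_region_merge(r)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 1000); expect_equal(m$end, 5000)

  # '-' strand: most upstream is the rightmost window
  rm <- transform(r, strand = "-")
  mm <- ortholog_region_merge(rm)
  expect_equal(mm$start, 2000); expect_equal(mm$end, 6000)

  # disjoint regions unchanged
  rd <- data.frame(chrom = "chr1", start = c(0, 10000),
                   end = c(4000, 14000), strand = "+")
  expect_equal(nrow(ortholog_region_merge(rd)), 2)

  # random overlapping sets vs a sweep oracle
  set.seed(20)
  for (rep in 1:10) {
    st <- sample(seq(0, 50000, by = 500), 8)
    rr <- data.frame(chrom = "c", start = st, end = st + 4000, strand = "+")
    got <- ortholog_region_merge(rr)
    runs <- promoscan:::merge_intervals(rr$start, rr$end)
    expect_equal(got$start, sort(runs$start))
    expect_true(all(got$end - got$start == 4000))
  }

  # malformed BED reports the line number
  tmp <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t4000\tx\t0\t+", "chr1\toops\t8000"), tmp)
  expect_error(ortholog_region_merge(tmp), "line 2")
})

test_that("MAF blocks parse into reference-first alignments", {
  tmp <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("##maf version=1", "a score=1.0",
               "s mouse.chr1 0 4 + 100 AC-GT",
               "s human.chr7 0 5 + 100 ACAGT",
               "", "a score=2.0",
               "s mouse.chr2 0 3 + 50 AAA",
               "s rat.chr2   0 3 + 50 AAA"), tmp)
  b <- read_maf(tmp)
  expect_length(b, 2)
  expect_identical(names(b[[1]]), c("mouse", "human"))
  expect_identical(unname(b[[1]]["mouse"]), "AC-GT")
})
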