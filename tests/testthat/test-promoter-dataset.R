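test_that("gene domains follow the 1-kb-closer / 100-kb-default edge rules", {
  # isolated ORF: 100 kb upstream default
  orfs <- data.frame(gene_id = "g1", chrom = "chr1", start = 1000000,
                     end = 1000900, strand = "+")
  d <- assign_gene_domains(orfs)
  expect_equal(d$domain_start, 900000)
  expect_equal(d$domain_end, 1001900)

  # neighbour ending 5 kb upstream: upstream edge 4 kb upstream of the ORF
  orfs2 <- rbind(orfs,
                 data.frame(gene_id = "g0", chrom = "chr1", start = 990000,
                            end = 995000, strand = "+"))
  d2 <- assign_gene_domains(orfs2)
  expect_equal(d2$domain_start[d2$gene_id == "g1"], 996000)

  # three-gene toy chromosome, mixed strands, hand-computed intervals
  orfs3 <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr2",
                      start = c(50000, 120000, 123000),
                      end = c(51000, 121000, 124000),
                      strand = c("+", "-", "+"))
  d3 <- assign_gene_domains(orfs3)
  expect_equal(d3$domain_start[d3$gene_id == "a"], 0)       # 100 kb clipped at 0
  expect_equal(d3$domain_end[d3$gene_id == "a"], 52000)
  # b is '-': upstream is to the right; next ORF upstream starts at 123000
  expect_equal(d3$domain_start[d3$gene_id == "b"], 119000)
  expect_equal(d3$domain_end[d3$gene_id == "b"], 122000)    # 123000 - 1000
  # c is '+': previous ORF ends 121000, gap 2000 -> extent 1000
  expect_equal(d3$domain_start[d3$gene_id == "c"], 122000)

  # neighbour closer than 1 kb clips the upstream extent to zero
  orfs4 <- data.frame(gene_id = c("x", "y"), chrom = "chr3",
                      start = c(1000, 2500), end = c(2000, 3500),
                      strand = "+")
  expect_warning(d4 <- assign_gene_domains(orfs4), "clipped")
  expect_equal(d4$domain_start[d4$gene_id == "y"], 2500)
})

test_that("TSS inference applies the merge and discard rules as specified", {
  domains <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                        orf_start = 10000, orf_end = 10900,
                        domain_start = 5000, domain_end = 11900,
                        pseudo = FALSE)
  # two blocks separated by 8 bp merge into one exon -> single-exon discard
  cdna <- data.frame(cdna_id = "c1", chrom = "chr1", strand = "+",
                     blockStarts = "9500,9708", blockSizes = "200,400")
  r <- infer_tss(cdna, domains)
  expect_equal(nrow(r$tss), 0)
  expect_equal(unname(r$discarded["single_exon"]), 1)

  # a distal block with a 2400-bp gap gives two exons; TSS = most upstream base
  cdna2 <- data.frame(cdna_id = "c2", chrom = "chr1", strand = "+",
                      blockStarts = "7000,9500", blockSizes = "100,550")
  r2 <- infer_tss(cdna2, domains)
  expect_equal(r2$tss$tss, 7000)

  # synthetic multi-gene trace: multi-domain cDNA, wrong strand, pseudogene,
  # downstream intron, and one clean gene
  domains5 <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD"), chrom = "chr1",
    strand = c("+", "+", "-", "+"),
    orf_start = c(10000, 30000, 50000, 70000),
    orf_end = c(10900, 30900, 50900, 70900),
    domain_start = c(5000, 25000, 45000, 65000),
    domain_end = c(11900, 31900, 51900, 71900),
    pseudo = c(FALSE, FALSE, FALSE, TRUE))
  cdna5 <- data.frame(
    cdna_id = c("mA", "mBbad", "mC", "mD", "mSpan"),
    chrom = "chr1",
    strand = c("+", "-", "-", "+", "+"),
    blockStarts = c("8000,9800", "28000,29800", "51200,49950",
                    "68000,69800", "11000,30000"),
    blockSizes = c("150,300", "150,300", "400,1000", "150,300", "500,500"))
  r5 <- infer_tss(cdna5, domains5)
  # gA survives with TSS 8000; gB's only cDNA was wrong-strand (no evidence);
  # gC ('-') survives, TSS = rightmost transcribed base; gD is a pseudogene;
  # mSpan overlaps two domains and is dropped
  expect_setequal(r5$tss$gene_id, c("gA", "gC"))
  expect_equal(r5$tss$tss[r5$tss$gene_id == "gA"], 8000)
  expect_equal(r5$tss$tss[r5$tss$gene_id == "gC"], 51600)
  expect_equal(unname(r5$discarded["wrong_strand"]), 1)
  expect_equal(unname(r5$discarded["multi_domain"]), 1)
  expect_equal(unname(r5$discarded["pseudogene"]), 1)

  # an intron strictly downstream of the ORF disqualifies the gene
  cdna6 <- data.frame(cdna_id = c("c6", "c6b"), chrom = "chr1", strand = "+",
                      blockStarts = c("8000,9800", "11200"),
                      blockSizes = c("150,300", "100"))
  r6 <- infer_tss(cdna6, domains)
  expect_equal(nrow(r6$tss), 0)
  expect_equal(unname(r6$discarded["intron_downstream"]), 1)
})

test_that("NG86 synonymous divergence matches codon-table bookkeeping", {
  # identical sequences: dS = 0
  s <- strrep("CTA", 20)
  expect_equal(ng86_ds(s, s)$ds, 0)

  # 2 of 20 Leu codons changed CTA->CTG (synonymous, 4-fold site):
  # per codon S = 1 (pos 3) + 1/3 (pos 1, TTA/TTG Leu) + 0 = 4/3
  s2 <- paste0(strrep("CTA", 18), "CTGCTG")
  r <- ng86_ds(s, s2)
  S_exp <- 20 * (4 / 3)
  ps_exp <- 2 / S_exp
  expect_equal(r$syn_sites, S_exp, tolerance = 1e-9)
  expect_equal(r$ps, ps_exp, tolerance = 1e-9)
  expect_equal(r$ds, -0.75 * log(1 - 4 * ps_exp / 3), tolerance = 1e-9)

  # all 20 codons differ synonymously: ps = 20/(80/3) = 0.75 -> JC saturates
  s3 <- strrep("CTG", 20)
  r3 <- ng86_ds(s, s3)
  expect_true(is.na(r3$ds))
  expect_identical(r3$note, "saturated")

  # a non-synonymous single change counts zero synonymous differences
  r4 <- ng86_ds("ATGAAA", "ATGGAA")  # Lys -> Glu at pos 1 of codon 2
  expect_equal(r4$syn_diffs, 0)
})

test_that("similar pairs are flagged by dS or flank identity and dedup matches transitive closure", {
  orfs <- c(a = strrep("CTA", 40), b = strrep("CTA", 40),
            c = strrep("GAC", 40))
  pr <- pairwise_similarity(orf_seqs = orfs)
  expect_true(any(pr$id1 == "a" & pr$id2 == "b"))   # dS = 0
  expect_false(any(pr$id1 == "a" & pr$id2 == "c" |
                     pr$id1 == "c" & pr$id2 == "a"))

  # flanks sharing an exact 250-bp block are similar via the identity rule
  set.seed(8)
  block <- random_dna(250)
  fl <- c(x = paste0(random_dna(300), block, random_dna(200)),
          y = paste0(block, random_dna(500)),
          z = random_dna(750))
  pf <- pairwise_similarity(flank_seqs = fl)
  expect_true(any((pf$id1 == "x" & pf$id2 == "y") |
                    (pf$id1 == "y" & pf$id2 == "x")))
  expect_false("z" %in% c(pf$id1, pf$id2))

  # single-linkage: {A-B, B-C} + isolated D -> 2 clusters
  dd <- dedup_single_linkage(c("A", "B", "C", "D"),
                             data.frame(id1 = c("A", "B"),
                                        id2 = c("B", "C")))
  expect_equal(length(dd$clusters), 2)
  expect_length(dd$representatives, 2)

  # empty pair list: everyone represents themselves
  ids314 <- sprintf("g%03d", 1:314)
  dd2 <- dedup_single_linkage(ids314, data.frame(id1 = character(0),
                                                 id2 = character(0)))
  expect_setequal(dd2$representatives, ids314)

  # random graphs vs brute-force reachability; representative determinism
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(10:50, 1)
    ids <- sprintf("n%02d", seq_len(n))
    m <- sample(0:40, 1)
    pairs <- data.frame(id1 = sample(ids, m, TRUE),
                        id2 = sample(ids, m, TRUE))
    pairs <- pairs[pairs$id1 != pairs$id2, , drop = FALSE]
    got <- dedup_single_linkage(ids, pairs, seed = 7)
    want <- oracle_components(ids, pairs)
    canon <- function(cl) sort(vapply(cl, function(x)
      paste(sort(x), collapse = ","), character(1)))
    expect_identical(canon(got$clusters), canon(want))
    # exactly one representative per component
    for (cl in got$clusters) {
      expect_equal(sum(got$representatives %in% cl), 1)
    }
    again <- dedup_single_linkage(ids, pairs, seed = 7)
    expect_identical(got$representatives, again$representatives)
  }
})

test_that("promoter extraction is strand-aware and round-trips to the genome", {
  set.seed(12)
  chr <- random_dna(20000)
  genome <- c(chrT = chr)
  tss <- data.frame(gene_id = c("p", "m"), chrom = "chrT",
                    tss = c(10000, 10000), strand = c("+", "-"))
  ps <- extract_promoters(genome, tss, L = 200)
  expect_equal(ps$promoters$sequence[1], substr(chr, 9801, 10000))
  expect_equal(ps$promoters$preceding[1], substr(chr, 9601, 9800))
  expect_equal(ps$promoters$sequence[2],
               revcomp_chr(substr(chr, 10001, 10200)))
  expect_equal(ps$promoters$preceding[2],
               revcomp_chr(substr(chr, 10201, 10400)))
  # round trip: re-locate each extracted sequence at its recorded coords
  for (i in 1:2) {
    s <- ps$promoters$sequence[i]
    if (ps$promoters$strand[i] == "-") s <- revcomp_chr(s)
    expect_equal(unname(regexpr(s, chr, fixed = TRUE)) > 0, TRUE)
  }
  # out-of-contig promoters are dropped with a warning
  tss2 <- data.frame(gene_id = "edge", chrom = "chrT", tss = 100,
                     strand = "+")
  expect_warning(ps2 <- extract_promoters(genome, rbind(tss, tss2), L = 200),
                 "edge")
  expect_equal(nrow(ps2$promoters), 2)
})

test_that("positional profiles equal brute-force window averaging", {
  # one 21-bp site: coverage 1 at window centers fully inside the site
  seqs <- c(p1 = strrep("A", 200))
  ps <- toy_promoter_set(seqs)
  hits <- data.frame(promoter_id = "p1", start = -120, end = -99,
                     strand = "+", pwm_id = "M", family_id = "F",
                     score = 1)
  cov <- coverage_track(hits, ps)
  prof <- positional_profile(cov, window = 20, slide = 1)
  # windows fully inside the site start at -120 or -119 (centers -110.5/-109.5)
  full <- prof$position >= -110.5 & prof$position <= -109.5
  expect_equal(sum(full), 2)
  expect_true(all(prof$value[full] == 1))
  expect_true(all(prof$value >= 0 & prof$value <= 1))

  # all-G promoters have a constant GC profile of 1
  psG <- toy_promoter_set(c(g1 = strrep("G", 100), g2 = strrep("G", 100)))
  profG <- positional_profile(gc_track(psG), window = 50, slide = 10)
  expect_true(all(profG$value == 1))

  # GC profile equals 1 - AT profile
  set.seed(3)
  psr <- toy_promoter_set(setNames(replicate(5, random_dna(200)),
                                   paste0("r", 1:5)))
  g <- gc_track(psr)
  at <- 1 - g
  attr(at, "offset") <- attr(g, "offset")
  pg <- positional_profile(g, 50, 10)
  pa <- positional_profile(at, 50, 10)
  expect_equal(pg$value, 1 - pa$value, tolerance = 1e-12)

  # random indicator matrix vs direct window averaging
  set.seed(9)
  m <- matrix(rbinom(10 * 200, 1, 0.3), 10, 200)
  attr(m, "offset") <- -200
  got <- positional_profile(m, window = 20, slide = 1)
  cm <- colMeans(m)
  want <- vapply(1:181, function(s) mean(cm[s:(s + 19)]), numeric(1))
  expect_equal(got$value, want, tolerance = 1e-12)
  expect_equal(got$position, -200 + (1:181) - 1 + 9.5)

  expect_error(positional_profile(m, window = 300), "window")
})
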