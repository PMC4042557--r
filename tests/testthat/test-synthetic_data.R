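test_that("probe layout tiles regions at fixed spacing", {
  rs <- region_set(data.frame(chrom = "chr1", start = 0, end = 1700,
                              gene_id = "g1"), flank = 0)
  lay <- generate_probe_layout(rs, spacing = 170)
  expect_equal(nrow(lay), 10)
  expect_true(all(diff(lay$start) == 170))

  # short region still gets one probe
  rs2 <- region_set(data.frame(chrom = "chr1", start = 0, end = 100,
                               gene_id = "g1"), flank = 0)
  expect_equal(nrow(generate_probe_layout(rs2, spacing = 170)), 1)

  # two 1 kb regions: floor(1000/170) = 5 probes each, ids distinct
  rs3 <- region_set(data.frame(chrom = "chr1", start = c(0, 50000),
                               end = c(1000, 51000),
                               gene_id = c("g1", "g2")), flank = 0)
  lay3 <- generate_probe_layout(rs3, spacing = 170)
  expect_equal(as.vector(table(lay3$region_id)), c(5, 5))

  expect_error(generate_probe_layout(
    region_set(data.frame(chrom = "c", start = 0, end = 1,
                          gene_id = "g")[0, ], flank = 0)), "empty")
})

test_that("region flanks are applied and overlapping regions merge", {
  rs <- region_set(data.frame(chrom = "chr1", start = c(20000, 25000),
                              end = c(21000, 26000),
                              gene_id = c("a", "b")), flank = 10000)
  expect_equal(nrow(rs), 1)          # flanked intervals overlap -> merged
  expect_equal(rs$start, 10000)
  expect_equal(rs$end, 36000)
  expect_match(rs$gene_id, "a,b")
})

test_that("simulate_cgh places truth shifts on the right probes", {
  lay <- generate_probe_layout(
    region_set(data.frame(chrom = "chr1", start = 0, end = 3400,
                          gene_id = "g1"), flank = 0))
  cfg <- sim_config(noise_sd = 1e-12, seed = 42)
  # heterozygous deletion spanning probes 6-10 (starts 850-1530)
  truth <- data.frame(sample_id = "pop1_s1", chrom = "chr1", start = 850,
                      end = 1590, copy_state = 1)
  out <- simulate_cgh(lay, cfg, truth = truth)
  tr <- out$tracks[out$tracks$sample_id == "pop1_s1", ]
  hit <- tr$start < 1590 & tr$end > 850
  expect_equal(sum(hit), 5)
  expect_equal(tr$log2_ratio[hit], rep(-1, 5), tolerance = 1e-6)
  expect_equal(tr$log2_ratio[!hit], rep(0, sum(!hit)), tolerance = 1e-6)
  # other samples untouched
  other <- out$tracks[out$tracks$sample_id != "pop1_s1", ]
  expect_equal(max(abs(other$log2_ratio)), 0, tolerance = 1e-6)

  # copy-state 3 -> +log2(3/2); copy-state 0 -> configured floor
  expect_equal(cnvsweep:::copy_state_shift(3L), log2(3 / 2))
  expect_equal(cnvsweep:::copy_state_shift(0L, -3), -3)

  # injection outside the layout span is rejected
  expect_error(simulate_cgh(lay, cfg, truth = data.frame(
    sample_id = "pop1_s1", chrom = "chrX", start = 0, end = 100,
    copy_state = 1)), "outside")
})

test_that("generators are deterministic under a fixed seed", {
  lay <- generate_probe_layout(region_set(demo_regions(), flank = 1000))
  cfg <- sim_config(seed = 7)
  a <- simulate_cgh(lay, cfg); b <- simulate_cgh(lay, cfg)
  expect_identical(a, b)

  mc <- microsat_sim_config(n_individuals_per_pop = 10, n_neutral = 5,
                            n_candidate = 2, seed = 7)
  expect_identical(simulate_microsats(mc), simulate_microsats(mc))

  genes <- data.frame(gene_id = sprintf("g%02d", 1:20),
                      cnv_carrier = rep(c(TRUE, FALSE), 10))
  expect_identical(simulate_expression_stats(genes, coupling = 0.5, seed = 7),
                   simulate_expression_stats(genes, coupling = 0.5, seed = 7))
})

test_that("microsat alleles sit on the motif ladder and configs validate", {
  mc <- microsat_sim_config(n_individuals_per_pop = 12, n_neutral = 6,
                            n_candidate = 2, motif = 2, seed = 3)
  g <- simulate_microsats(mc)$genotypes
  for (l in unique(g$locus)) {
    al <- c(g$allele1_bp[g$locus == l], g$allele2_bp[g$locus == l])
    expect_true(all(diff(sort(unique(al))) %% 2 == 0))
  }
  expect_error(microsat_sim_config(n_individuals_per_pop = 1), "< 2")
  expect_error(microsat_sim_config(sweep_factor = 0), "sweep_factor")
  expect_error(microsat_sim_config(sweep_factor = 1.5), "sweep_factor")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(simulate_expression_stats(
    data.frame(gene_id = "g"), coupling = 2), "coupling")
})

test_that("swept loci lose diversity in the target population", {
  # Monte-Carlo under the generator itself: strong sweep on candidate 1
  lower <- vapply(1:200, function(i) {
    mc <- microsat_sim_config(n_individuals_per_pop = 20, n_neutral = 2,
                              n_candidate = 1, sweep_factor = 0.05,
                              swept_loci = 1, swept_pop = "pop2", seed = i)
    g <- simulate_microsats(mc)$genotypes
    g <- g[g$locus == "cand001", ]
    h <- vapply(c("pop1", "pop2"), function(p) {
      gp <- g[g$population == p, ]
      expected_heterozygosity(c(gp$allele1_bp, gp$allele2_bp))$H
    }, numeric(1))
    h["pop2"] < h["pop1"]
  }, logical(1))
  expect_gte(mean(lower), 0.95)
})

test_that("neutral microsat construction is symmetric between populations", {
  # per-locus H difference has mean ~0 over replicates (|mean| < 2 SE)
  diffs <- vapply(1:200, function(i) {
    mc <- microsat_sim_config(n_individuals_per_pop = 15, n_neutral = 4,
                              n_candidate = 0, sweep_factor = 1, seed = i)
    g <- simulate_microsats(mc)$genotypes
    mean(vapply(unique(g$locus), function(l) {
      gl <- g[g$locus == l, ]
      h <- vapply(c("pop1", "pop2"), function(p) {
        gp <- gl[gl$population == p, ]
        expected_heterozygosity(c(gp$allele1_bp, gp$allele2_bp))$H
      }, numeric(1))
      h[1] - h[2]
    }, numeric(1)))
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 2 * se)
})

test_that("expression generator nulls are calibrated", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:200),
                      cnv_carrier = FALSE, de = FALSE)
  # non-DE p-values uniform: KS uniformity test passes at alpha 0.01
  ok <- vapply(1:100, function(i) {
    s <- simulate_expression_stats(genes, coupling = 0, seed = i)
    suppressWarnings(
      ks.test(s$p_value[s$status == "invariant"], "punif")$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("coupled expression shifts follow the copy change", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:60),
                      cnv_carrier = TRUE,
                      cnv_sign = rep(c("amplification", "deletion"), 30),
                      de = FALSE)
  agree <- vapply(1:200, function(i) {
    s <- simulate_expression_stats(genes, coupling = 1, effect_size = 6,
                                   seed = i)
    m <- tapply(s$t_statistic, s$gene_id, mean)
    expect_dir <- ifelse(genes$cnv_sign == "deletion", -1, 1)
    mean(sign(m[genes$gene_id]) == expect_dir)
  }, numeric(1))
  expect_gte(mean(agree), 0.95)
})

test_that("gene models partition the gene body", {
  regions <- demo_regions(3)
  feats <- make_gene_models(regions, exons_per_gene = 3, exon_length = 200)
  for (g in regions$gene_id) {
    f <- feats[feats$gene_id == g, ]
    f <- f[order(f$start), ]
    expect_equal(f$start[1], regions$start[regions$gene_id == g])
    expect_equal(f$end[nrow(f)], regions$end[regions$gene_id == g])
    expect_true(all(f$start[-1] == head(f$end, -1)))  # contiguous, no overlap
    expect_setequal(unique(f$class), c("exon5", "exon", "exon3", "intron"))
  }
  # zero internal exons -> exon5 + intron + exon3
  f0 <- make_gene_models(regions[1, ], exons_per_gene = 0)
  expect_equal(f0$class[order(f0$start)], c("exon5", "intron", "exon3"))
  # exon budget exceeding the gene is rejected
  expect_error(make_gene_models(
    data.frame(chrom = "c", start = 0, end = 500, gene_id = "g"),
    exons_per_gene = 3, exon_length = 200), "exceeds")
})
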