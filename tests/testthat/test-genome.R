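# genome_mode: definitions, pooling, presence gate, relative abundance

make_contig_stats <- function(depths_list, counts = NULL,
                              end_exclusion = 0L) {
  nm <- names(depths_list)
  data.frame(
    contig = nm,
    length = vapply(depths_list, length, integer(1)),
    count = if (is.null(counts)) rep(10L, length(nm)) else counts,
    hist = I(lapply(depths_list, function(d) {
      r <- effective_region(length(d), end_exclusion)
      depth_histogram(if (r[2] > r[1]) d[(r[1] + 1):r[2]] else integer())
    })),
    stringsAsFactors = FALSE
  )
}

test_that("genome_definition supports all three conventions", {
  # FASTA mode
  dir <- tempfile(); dir.create(dir)
  w <- function(file, contigs) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(rep("ACGT", length(contigs)),
                                        contigs)),
      file.path(dir, file))
    file.path(dir, file)
  }
  f1 <- w("g1.fna", c("a", "b"))
  f2 <- w("g2.fna", "c")
  gd <- genome_definition(fasta_files = c(f1, f2))
  expect_identical(gd$contig_to_genome, c(a = "g1", b = "g1", c = "g2"))
  expect_identical(gd$genomes, c("g1", "g2"))

  # duplicate contig across FASTAs is fatal
  f3 <- w("g3.fna", "a")
  expect_error(genome_definition(fasta_files = c(f1, f3)),
               "claimed by two genomes")

  # separator mode
  gd2 <- genome_definition(separator = "~", contigs = c("g1~c7", "g2~c1"))
  expect_identical(unname(gd2$contig_to_genome["g1~c7"]), "g1")
  expect_error(genome_definition(separator = "~", contigs = "plain"),
               "lacks separator")

  # definition-file mode (genome TAB contig)
  def <- tempfile()
  writeLines(c("gA\tc1", "gA\tc2", "gB\tc3"), def)
  gd3 <- genome_definition(definition_file = def)
  expect_identical(gd3$genomes, c("gA", "gB"))
  expect_identical(unname(gd3$contig_to_genome["c2"]), "gA")

  # exactly one convention
  expect_error(genome_definition(), "exactly one")
  expect_error(genome_definition(separator = "~", definition_file = def),
               "exactly one")
})

test_that("aggregate_genomes pools bases across contigs", {
  def <- genome_definition(separator = "~",
                           contigs = c("g~c1", "g~c2"))
  # weighted mean: equal effective lengths, means 1 and 3 -> 2
  cs <- make_contig_stats(list(`g~c1` = rep(1L, 850L),
                               `g~c2` = rep(3L, 850L)))
  gs <- aggregate_genomes(cs, def)
  expect_equal(gs$mean, 2)
  expect_equal(gs$length, 1700L)
  expect_equal(gs$count, 20L)
  # pooled variance of two constant contigs is positive
  cs2 <- make_contig_stats(list(`g~c1` = rep(0L, 100L),
                                `g~c2` = rep(2L, 100L)))
  gs2 <- aggregate_genomes(cs2, def)
  pooled <- c(rep(0L, 100L), rep(2L, 100L))
  expect_equal(gs2$variance, var(pooled))
  expect_equal(gs2$mean, mean(pooled))
  expect_equal(gs2$covered_fraction, 0.5)
  expect_equal(gs2$trimmed_mean, oracle_trimmed_mean(pooled, 0.05, 0.05))
})

test_that("singleton genome equals its contig's metrics", {
  set.seed(3)
  d <- rpois(2000L, 4)
  def <- genome_definition(separator = "~", contigs = "g~c1")
  gs <- aggregate_genomes(make_contig_stats(list(`g~c1` = d),
                                            end_exclusion = 75L), def)
  expect_equal(gs$mean, mean_coverage(d))
  expect_equal(gs$variance, coverage_variance(d))
  expect_equal(gs$trimmed_mean, trimmed_mean(d))
  expect_equal(gs$covered_fraction, covered_stats(d)$covered_fraction)
})

test_that("contigs absent from the definition are excluded with a warning", {
  def <- genome_definition(separator = "~", contigs = "g~c1")
  cs <- make_contig_stats(list(`g~c1` = rep(1L, 100L),
                               stray = rep(9L, 100L)))
  expect_warning(gs <- aggregate_genomes(cs, def), "absent from the genome")
  expect_equal(gs$mean, 1)
})

test_that("the presence gate zeroes genomes below threshold, inclusively", {
  gs <- data.frame(
    genome = c("lo", "edge", "hi"),
    length = 10000L, eff_length = 10000L,
    count = c(5L, 5L, 50L),
    mean = c(0.1, 0.2, 5), trimmed_mean = c(0.1, 0.2, 5),
    variance = c(0.1, 0.1, 1),
    covered_bases = c(999L, 1000L, 9000L),
    covered_fraction = c(0.0999, 0.10, 0.9),
    stringsAsFactors = FALSE
  )
  out <- apply_min_covered_fraction(gs, 0.10)
  expect_identical(out$detected, c(FALSE, TRUE, TRUE))
  expect_equal(out$mean, c(0, 0.2, 5))
  expect_equal(out$count, c(0, 5, 50))
  # threshold 0 changes nothing
  expect_equal(apply_min_covered_fraction(gs, 0)$mean, gs$mean)
  # lowering the threshold never decreases abundance
  ra_hi <- relative_abundance(setNames(out$mean, out$genome),
                              sum(out$count), 100L)
  out0 <- apply_min_covered_fraction(gs, 0)
  ra_lo <- relative_abundance(setNames(out0$mean, out0$genome),
                              sum(out0$count), 100L)
  expect_true(all(ra_lo$abundance >= ra_hi$abundance - 1e-12))
})

test_that("relative_abundance implements the scaled coverage-share formula", {
  ra <- relative_abundance(c(A = 2, B = 6), 800L, 1000L)
  expect_equal(unname(ra$abundance), c(20, 60))
  expect_equal(ra$unmapped, 20)

  expect_equal(relative_abundance(c(A = 3), 50L, 50L)$abundance[["A"]], 100)
  z <- relative_abundance(c(A = 0, B = 0), 0L, 1000L)
  expect_equal(unname(z$abundance), c(0, 0))
  expect_equal(z$unmapped, 100)
  expect_error(relative_abundance(c(A = 1), 0L, 0L), "empty library")
})

test_that("abundances conserve mass and depend only on coverage ratios", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(1:8, 1L)
    means <- runif(n, 0, 30)
    total <- sample(500:5000, 1L)
    aligned <- sample(0:total, 1L)
    ra <- relative_abundance(means, aligned, total)
    expect_equal(sum(ra$abundance) + ra$unmapped, 100, tolerance = 1e-9)
    k <- runif(1, 0.1, 50)
    expect_equal(relative_abundance(means * k, aligned, total)$abundance,
                 ra$abundance, tolerance = 1e-9)
  }
})
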